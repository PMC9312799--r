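---
title: "Solubility-aware peptide binder design: model and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Solubility-aware peptide binder design: model and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(solpep)
library(dplyr)
```

## The problem

Protein–protein interaction (PPI) interfaces are typically flat, wide and
hydrophobic. When a peptide binder is hallucinated against such an
interface by gradient-optimizing its sequence through a
structure-prediction oracle, the optimizer happily loads the designed
positions with leucine and the aromatics tryptophan, tyrosine and
phenylalanine — residues the interface rewards but which make the peptide
poorly soluble, and solubility is what decides whether a designed
therapeutic peptide can actually be produced, kept in solution and dosed.
Filtering after design throws away almost everything; the practical remedy
is to optimize binding and solubility *simultaneously*. `solpep`
implements that co-optimization at desk scale, with the expensive
structure-prediction oracle abstracted behind a pluggable contract and
replaced by a deterministic surrogate for development and testing.

## The solubility loss

Three per-residue scales are bundled (`inst/extdata/indices/`, sources in
each file header):

* **Hydrophobicity** — the membrane-buried preference parameters of Argos
  et al. (1982): high = hydrophobic;
* **Hydropathy** — the Kyte–Doolittle (1982) scale: high = hydrophobic;
* **SWI** — the solubility-weighted index of Bhandari et al. (2020): high
  = *soluble*, i.e. the opposite sense.

Each scale is min–max normalized to span exactly $[0,1]$, and SWI is then
inverted ($1-x$) so that for every oriented table a larger value always
means "worse for solubility". The loss of a discrete peptide
$s = (s_1 \dots s_N)$ is the arithmetic mean of the oriented values,

$$\mathrm{SolubilityLoss}(s) \;=\; \frac{1}{N}\sum_{i=1}^{N} f(s_i),$$

where $f$ is the oriented index and $N$ the binder length (the binding
target never enters the loss). A geometric-mean variant
(`type = "geometric"`) is exposed for sensitivity checks because the two
summaries are sometimes conflated in the literature; the arithmetic form
is the definition used everywhere in this package.

During optimization the sequence is *soft*: position $i$ carries a
probability row $p_i$ over the 20 canonical residues (fixed alphabetical
order `ACDEFGHIKLMNPQRSTVWY` everywhere), and the loss generalizes
linearly to $\frac1N\sum_i \langle p_i, f\rangle$ — the expectation of the
discrete loss, exactly equal to it at one-hot rows and differentiable in
the logits.

## The design engine

`design_binder()` optimizes an $N\times 20$ logits matrix by plain
gradient descent through three stages:

1. **soft** (default 100 iterations): rows are tempered softmaxes
   $p_i = \mathrm{softmax}(z_i / T)$ at fixed $T = T_\text{start}$;
2. **annealed** (default 100): $T$ decreases linearly from
   $T_\text{start}$ to $T_\text{end}$, sharpening the distributions;
3. **hard** (default 10): the forward pass uses the one-hot argmax
   sequence while gradients flow straight-through the tempered softmax,
   so recorded hard-stage losses are true discrete-sequence losses.

The total loss is the weighted sum of the oracle losses and the
solubility loss,
$L = \sum_k w_k\,L^{\text{oracle}}_k + w_\text{sol}\,L_\text{sol}$, and
the best sequence of a run is the hard-stage iterate with the lowest
total (ties to the earliest iteration) — selection over the final 10
discrete sequences, not over soft iterates.

Choices the underlying method leaves open, fixed here as package policy:

* **Optimizer** — fixed step (`step_size = 0.1`) along the globally
  L2-normalized gradient. A minimal deterministic optimizer keeps every
  contract exactly reproducible; since both bundled losses are linear in
  the probabilities, each row's optimum is a vertex of the simplex and
  normalized gradient descent reaches it reliably within the default
  schedule.
* **Temperature endpoints** — linear anneal from $T_\text{start}=1$ to
  $T_\text{end}=0.01$. Any monotone anneal reproduces the soft-to-hard
  transition; linear is the least surprising.
* **Logit initialization** — i.i.d. Normal(0, 0.01), seeded, drawn from a
  local RNG stream that never disturbs the caller's RNG. The spread is
  small enough that early gradients dominate the draw, yet the noise
  breaks ties between equally preferred residues differently per seed,
  which is what makes unconstrained designs vary across seeds.
* **Argmax ties** — broken toward the lowest alphabetical index, for
  determinism.

## The surrogate oracle

Any binding backend can drive the loop by satisfying the oracle contract:
`evaluate(soft_seq)` returning finite non-negative named losses and
d(loss)/d(probabilities) matrices. The bundled surrogate emulates the one
behaviour of real structure-prediction oracles that matters for this
package's purpose — hydrophobic interface preference. Its profile gives
preference 1.0 to W/Y/F/L in a central core (positions 4–11), 0.1 to the
hydrophilic residues R/K/D/E/N/Q there, and a flat 0.8 floor at the
flanks; the interface loss is one minus the mean preference under the
soft sequence. A constant-zero "confidence" loss is also reported purely
so multi-component weighting is exercised. Because W/Y/F/L score badly
(above the 20-residue mean) on all three oriented indices, the surrogate
and the solubility loss are in deliberate tension and weight sweeps show
a genuine trade-off:

```{r tradeoff, eval = FALSE}
tab <- solubility_index("hydropathy")
orc <- surrogate_oracle(length = 13)
sweep <- function(w) purrr::map_dfr(1:20, function(s)
  glance(design_binder(13, s, orc, tab, weights = loss_weights(solubility = w))))
sweep(0) |> summarise(sol = mean(best_solubility))   # high: W/Y/F/L-rich
sweep(1) |> summarise(sol = mean(best_solubility))   # low: hydrophilic flanks
```

The surrogate makes no claim to approximate binding free energies. What
passing tests show is that the *engine* behaves correctly — gradients are
exact, the weight dial moves composition in the right direction, optima
are recovered — not that designs against the surrogate would bind a real
target. Real logS and docking-affinity scores are ingested as external
CSV columns (`solubility_score`, `affinity_score`), never computed here.

## Evaluation harness

* `gen_random_sequences()` — uniform-random baselines, seeded.
* `gen_single_substitutions()` — the full saturation set of single-residue
  variants ($19N$ sequences; 247 for the 13-mer p53 peptide). Full
  enumeration is the deterministic superset of any sampled substitution
  baseline; sampling can be had by sub-setting.
* `filter_candidates()` — a record survives iff `solubility_score >`
  threshold **and** `affinity_score <` threshold. Comparisons are strict:
  "higher than" is read literally, so records exactly at a threshold
  fail, and affinity is a binding free energy (more negative = stronger),
  which prevents sign-flip bugs when ingesting docking tables. The
  reference thresholds shipped with the fixture generator are the logS
  (0.4420) and affinity (−22.5) of the PDIQ+'N' control peptide.
* `build_pfm()` / `autoplot()` — position frequency matrices and
  frequency-logo plots over any equal-length sequence set, with the
  conventional hydrophilic/neutral/hydrophobic colouring.

Degenerate and dirty inputs are rejected loudly: non-canonical residue
codes (X, B, Z, U) error with the offending position, constant index
tables cannot be normalized, ragged PFM inputs and unscored records are
validation errors.

## Synthetic data and problem sizes

`make_fixture()` writes everything the pipeline needs to run
self-contained: 1000 random 13-mer candidates whose synthetic logS and
affinity scores are drawn *after* each record's verdict is decided
(strictly inside the pass or fail region, ~10% survivors), the planted
survivor count in a manifest, the p53 reference FASTA and the default
profile. The filter can therefore be checked against the generator's own
bookkeeping. The synthetic scores emulate only the dual-threshold
geometry of a real screen — they carry no chemistry, no
sequence–solubility correlation, and passing the filter test says nothing
about real logS distributions.

Default problem sizes mirror the study conditions the engine targets:
binder length 13 (p53/MDM2 setting; 17 for the PD-1 setting), schedule
100/100/10, solubility-weight sweep {0, 0.1, 0.3, 0.5, 0.7, 1.0}. The
full published-scale sweep uses 100 seeds per weight and index; the test
suite and acceptance script run 20 seeds at weights {0, 1}, which is
ample to establish the monotone direction of the trade-off while keeping
a complete run to well under a minute.

## Known limitations

* The surrogate's preference profile is hand-shaped, not learned; it
  reproduces the direction of interface-hydrophobicity enrichment, not
  its magnitude or position-specific detail.
* The straight-through hard stage inherits the usual bias of
  straight-through estimators; with linear losses this is harmless, but a
  strongly non-linear oracle may see soft/hard loss mismatches.
* The Kyte–Doolittle hydropathy scale places tryptophan and tyrosine near
  the middle of its range, so a hydropathy-weighted design penalizes
  leucine far more than the aromatics — a property of the scale itself
  (and the reason hydropathy-guided designs keep their aromatic core
  residues) that any aromatics-must-rank-high expectation will trip over.
* Min–max normalization is sensitive to the extreme residues of each
  scale; a different normalization (z-scoring, rank) would change the
  relative pricing of mid-scale residues.
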