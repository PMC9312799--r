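# solpep

Solubility-aware gradient-based design of protein-binding peptides.

Peptides hallucinated against protein–protein interaction (PPI)
interfaces by gradient sequence design tend to come out loaded with
leucine and the aromatics W/Y/F — exactly what a flat, hydrophobic
interface rewards and exactly what ruins aqueous solubility. `solpep`
co-optimizes binding and solubility: a differentiable solubility loss
built from normalized amino-acid indices is added, with a tunable weight,
to the losses of a pluggable binding oracle, and the sequence is
optimized through a three-stage soft → annealed → hard schedule.

The solubility loss of a peptide *s* = (s₁ … s_N) is

```
SolubilityLoss(s) = (1/N) · Σᵢ f(sᵢ)
```

where *f* is a per-residue solubility index min–max normalized to [0, 1]
and oriented so that larger always means worse for solubility. Three
indices are bundled: the Argos membrane-buried hydrophobicity scale, the
Kyte–Doolittle hydropathy scale, and the solubility-weighted index (SWI,
inverted after normalization because high SWI favours solubility).
During optimization the sequence is *soft* — a per-position probability
distribution over the 20 canonical residues — and the loss generalizes
linearly to its expectation, coinciding with the discrete loss at
one-hot.

The package also ships the evaluation harness around the engine: random
and saturation single-substitution baselines, dual-threshold filtering of
candidates on external solubility (logS) and docking-affinity scores,
position-frequency-matrix construction with sequence-logo plots, FASTA /
CSV / YAML I/O, a deterministic surrogate binding oracle that emulates
interface hydrophobicity preference, and a seeded fixture generator so
everything runs self-contained. Structure prediction, logS calculation
and docking are deliberately **not** reimplemented; their outputs enter
as external CSV columns.

## Worked example

Design 13-mer binders (the p53/MDM2 setting) against the surrogate
oracle at three solubility weights, five seeds each, with the hydropathy
index:

```r
library(solpep)
library(dplyr)

best <- run_design(design_config(length = 13, seeds = 1:5,
                                 weights = c(0, 0.5, 1),
                                 index = "hydropathy"))
best |>
  group_by(weight) |>
  summarise(mean_solubility = mean(best_solubility),
            mean_hydrophilic = mean(hydrophilic_fraction(best_sequence)))
#> # A tibble: 3 × 3
#>   weight mean_solubility mean_hydrophilic
#>    <dbl>           <dbl>            <dbl>
#> 1    0             0.639            0
#> 2    0.5           0.356            0
#> 3    1             0.219            0.385
```

At weight 0 the designs are pure aromatic/hydrophobic core sequences
(e.g. `FLFFWYWWFFWYL`, seed-dependent); raising the weight first swaps
the costly aromatics for tyrosine (cheapest under hydropathy) and by
weight 1 converts the flanks to arginine (`RRRYYYYYYYYRR`): mean
solubility loss falls from 0.639 to 0.219 while the hydrophilic residue
fraction (R/K/D/E/N/Q) rises from 0 to 0.385 — the engine-level
trade-off the weight dial is for. Single runs expose the full trajectory:

```r
res <- design_binder(13, seed = 1, oracle = surrogate_oracle(length = 13),
                     table = solubility_index("hydropathy"),
                     weights = loss_weights(solubility = 0.5))
res
#> <design_result: N=13 seed=1 index=hydropathy>
#>   best sequence: YYYYYYYYYYYYY (total loss 0.177778)
tidy(res)       # per-iteration stage, losses, decoded sequence
autoplot(res)   # loss curves with stage boundaries
score_sequence("ETFSDLWKLLPEN", solubility_index("hydropathy"))
#> [1] 0.4341880
```

Baselines, filtering and logos follow the same tabular grammar:

```r
subs <- gen_single_substitutions("ETFSDLWKLLPEN")   # 247 Hamming-1 variants
pass <- filter_candidates(scored, sol_threshold = 0.4420,
                          aff_threshold = -22.5)    # strict dual threshold
autoplot(build_pfm(pass))                           # sequence logo
```

A thin command-line surface wraps the same functions
(`inst/cli/solpep.R`; subcommands `design`, `evaluate`, `filter`,
`baseline`, `logo`, `fixture`).

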