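# Baseline generators, discrete scoring, dual-threshold filtering, PFMs.

test_that("discrete scoring agrees with the soft loss at one-hot across modules", {
  tabs <- oriented_tables()
  seqs <- c(P53_PEPTIDE, gen_random_sequences(100, 13, seed = 17)$sequence)
  for (tab in tabs) {
    soft <- vapply(seqs, function(sq) solubility_loss(hard_seq(sq), tab),
                   numeric(1), USE.NAMES = FALSE)
    expect_equal(unname(score_sequence(seqs, tab)), soft, tolerance = 1e-12)
  }
  # homopolymer of the 0-valued residue scores exactly 0
  expect_equal(unname(score_sequence(strrep("R", 13),
                                     tabs$hydropathy)), 0)
})

test_that("non-canonical residues are rejected with the position named", {
  tab <- solubility_index("swi")
  err <- expect_error(score_sequence("ETFSDLWKLLPEX", tab),
                      class = "solpep_validation_error")
  expect_match(conditionMessage(err), "position 13")
  expect_error(hydrophilic_fraction("ABZ"), class = "solpep_validation_error")
  expect_error(gen_single_substitutions("AXA"),
               class = "solpep_validation_error")
})

test_that("random baselines are deterministic, canonical and near-uniform", {
  a <- gen_random_sequences(100, 13, seed = 1)
  b <- gen_random_sequences(100, 13, seed = 1)
  expect_identical(a, b)
  expect_false(identical(a$sequence,
                         gen_random_sequences(100, 13, seed = 2)$sequence))
  expect_true(all(nchar(a$sequence) == 13))
  expect_identical(a$origin, rep("random", 100))

  # binomial 3-sigma bound on per-residue frequency over 20,000 draws
  big <- gen_random_sequences(20000, 13, seed = 123)
  chars <- unlist(strsplit(big$sequence, ""))
  freq <- table(factor(chars, levels = aa_alphabet)) / length(chars)
  sigma <- sqrt(0.05 * 0.95 / length(chars))
  expect_true(all(abs(freq - 0.05) < 3 * sigma))
})

test_that("single-substitution enumeration is complete, unique and Hamming-1", {
  subs <- gen_single_substitutions(P53_PEPTIDE)
  expect_equal(nrow(subs), 13 * 19)  # combinatorial count oracle
  expect_equal(length(unique(subs$sequence)), 247)
  expect_false(P53_PEPTIDE %in% subs$sequence)
  ref <- strsplit(P53_PEPTIDE, "")[[1]]
  hamming <- vapply(strsplit(subs$sequence, ""),
                    function(ch) sum(ch != ref), integer(1))
  expect_true(all(hamming == 1L))
  # single-position degenerate case
  expect_equal(nrow(gen_single_substitutions("A")), 19)
})

test_that("dual-threshold filter is strict, order-preserving and idempotent", {
  # the reference thresholds: solubility 0.4420, affinity -22.5
  rec <- tibble::tibble(
    sequence = c("AAAA", "CCCC", "DDDD", "EEEE", "FFFF"),
    solubility_score = c(0.50, 0.4420, 0.80, 0.30, 1.2),
    affinity_score = c(-23.0, -25.0, -22.5, -30.0, -24.0))
  out <- filter_candidates(rec, 0.4420, -22.5)
  # passes: strictly higher solubility AND strictly lower (stronger) affinity
  expect_identical(out$sequence, c("AAAA", "FFFF"))
  expect_true(all(out$passed_filter))
  # records exactly at a threshold fail (CCCC on solubility, DDDD on affinity)
  ann <- filter_candidates(rec, 0.4420, -22.5, keep_all = TRUE)
  expect_identical(ann$sequence, rec$sequence)  # order preserved
  expect_identical(ann$passed_filter, c(TRUE, FALSE, FALSE, FALSE, TRUE))
  # idempotent
  expect_identical(filter_candidates(out, 0.4420, -22.5)$sequence,
                   out$sequence)
  # empty input -> empty output
  expect_equal(nrow(filter_candidates(rec[0, ], 0.4420, -22.5)), 0L)
})

test_that("filter matches an independent linear scan on 1,000 seeded records", {
  withr::local_seed(71)
  rec <- gen_random_sequences(1000, 13, seed = 9)
  rec$solubility_score <- runif(1000, -2, 3)
  rec$affinity_score <- runif(1000, -30, -15)
  got <- filter_candidates(rec, 0.4420, -22.5)$sequence
  keep <- character(0)
  for (i in seq_len(1000)) {  # brute-force scan oracle
    if (rec$solubility_score[i] > 0.4420 && rec$affinity_score[i] < -22.5) {
      keep <- c(keep, rec$sequence[i])
    }
  }
  expect_identical(got, keep)
})

test_that("missing scores are a validation error naming the record", {
  rec <- gen_random_sequences(3, 13, seed = 2)
  rec$solubility_score <- c(0.5, NA, 0.7)
  rec$affinity_score <- c(-23, -24, -25)
  err <- expect_error(filter_candidates(rec, 0.4, -22),
                      class = "solpep_validation_error")
  expect_match(conditionMessage(err), "Record 2")
})

test_that("position frequency matrices count what the sequences contain", {
  # single sequence: one-hot rows
  p1 <- build_pfm(P53_PEPTIDE)
  expect_equal(rowSums(p1$counts), rep(1, 13))
  expect_equal(unname(p1$frequencies[1, "E"]), 1)
  # hand count: ["AA", "AC"] -> position 2 splits A/C evenly
  p2 <- build_pfm(c("AA", "AC"))
  expect_equal(unname(p2$frequencies[2, c("A", "C")]), c(0.5, 0.5))
  expect_equal(unname(p2$frequencies[1, "A"]), 1)
  # frequency rows sum to 1; counts conserve the residue total
  seqs <- gen_random_sequences(50, 13, seed = 3)$sequence
  p3 <- build_pfm(seqs)
  expect_true(all(abs(rowSums(p3$frequencies) - 1) < 1e-9))
  expect_equal(rowSums(p3$counts), rep(50, 13))
  expect_equal(sum(p3$counts), 50 * 13)
  # ragged input rejected
  expect_error(build_pfm(c("AAA", "AAAA")), class = "solpep_validation_error")
  expect_s3_class(autoplot(p3), "ggplot")
  td <- tidy(p3)
  expect_equal(sum(td$count), 50 * 13)
})

test_that("hydrophilic fraction counts exactly the R/K/D/E/N/Q class", {
  expect_equal(hydrophilic_fraction("RKDENQ"), 1)
  expect_equal(hydrophilic_fraction("WFYLIV"), 0)
  # hand count on the p53 peptide: E, D, K, E, N
  expect_equal(hydrophilic_fraction(P53_PEPTIDE), 5 / 13)
  expect_equal(residue_fraction("WWAA", c("W")), 0.5)
})
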