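test_that("zero-noise experiments reproduce planted folds exactly", {
  sim <- generate_tmt_experiment(100, 10, 4, 8, noise_cv = 0,
                                 n_replicates = 2, seed = 7)
  folds <- compute_fold_change(sim$table)
  planted <- sim$truth$planted_fold[folds$accession]
  expect_equal(folds$fold, unname(planted), tolerance = 1e-12)
  for (i in seq_len(nrow(folds))) {
    expect_equal(folds$per_replicate_fold[[i]],
                 rep(unname(planted[i]), 2), tolerance = 1e-12)
  }
})

test_that("an experiment without substrates has an empty truth set", {
  sim <- generate_tmt_experiment(50, 0, 4, 8, noise_cv = 0.1,
                                 n_replicates = 2, seed = 1)
  expect_length(sim$truth$substrate_accessions, 0)
  expect_equal(nrow(sim$table$quant), 50)
  expect_equal(nrow(sim$table$design), 4)
  expect_true(all(sim$truth$planted_fold == 1))
})

test_that("observed substrate ratios track planted folds under noise", {
  sim <- generate_tmt_experiment(200, 20, 5, 10, noise_cv = 0.1,
                                 n_replicates = 2, seed = 11)
  folds <- compute_fold_change(sim$table)
  sub <- folds$fold[folds$accession %in% sim$truth$substrate_accessions]
  planted <- sim$truth$planted_fold[sim$truth$substrate_accessions]
  expect_lt(abs(mean(sub) - mean(planted)) / mean(planted), 0.10)
})

test_that("generators are deterministic given the seed and leave global RNG alone", {
  a <- generate_tmt_experiment(30, 5, seed = 42)
  b <- generate_tmt_experiment(30, 5, seed = 42)
  expect_identical(a$table$quant, b$table$quant)
  expect_identical(a$truth$planted_fold, b$truth$planted_fold)
  ca <- generate_proteome_cohort(40, seed = 42)
  cb <- generate_proteome_cohort(40, seed = 42)
  expect_identical(as.data.frame(ca), as.data.frame(cb))
  set.seed(99); before <- stats::runif(1)
  set.seed(99); invisible(generate_tmt_experiment(5, 1, seed = 3))
  expect_identical(stats::runif(1), before)
})

test_that("negative noise is a parameter error", {
  expect_error(generate_tmt_experiment(10, 1, noise_cv = -0.1, seed = 1),
               "noise_cv")
  expect_error(generate_blot_quants(10, noise_cv = -1), "noise_cv")
})

test_that("a degenerate soluble-secreted composition yields uniform records", {
  cmp <- cohort_composition(
    localization = c(PLASMA_MEMBRANE = 0, SECRETED = 1, ER = 0, GOLGI = 0,
                     LYSOSOME = 0, NUCLEAR_MEMBRANE = 0, MULTIPLE = 0,
                     OTHER = 0),
    topology = c(SOLUBLE = 1, TYPE_I = 0, TYPE_II = 0, MULTIPASS = 0,
                 UNDEFINED = 0),
    length_fixed = 200L, signal_span = c(1L, 25L),
    fraction_mitochondrial = 0, fraction_short = 0, fraction_isoform = 0)
  co <- generate_proteome_cohort(10, cmp, seed = 2)
  expect_true(all(purrr::map_int(co$tm_segments, nrow) == 0))
  expect_true(all(co$signal_start == 1L & co$signal_end == 25L))
  expect_true(all(co$length == 200L))
  expect_true(all(classify_localization(co) == "SECRETED"))
})

test_that("fraction_mitochondrial = 1 marks every record mitochondrial", {
  cmp <- cohort_composition(fraction_mitochondrial = 1,
                            fraction_short = 0, fraction_isoform = 0)
  co <- generate_proteome_cohort(20, cmp, seed = 4)
  expect_true(all(co$is_mitochondrial))
})

test_that("realized class frequencies sit inside exact binomial 99% bounds", {
  n <- 500
  co <- generate_proteome_cohort(n, seed = 5)
  truth <- attr(co, "truth")
  cmp <- cohort_composition()
  regular <- truth[truth$category == "regular", ]
  for (cls in names(cmp$topology)) {
    p <- cmp$topology[[cls]]
    k <- sum(regular$topology == cls)
    bounds <- stats::qbinom(c(0.005, 0.995), nrow(regular), p)
    expect_gte(k, bounds[1])
    expect_lte(k, bounds[2])
  }
  for (cls in c("PLASMA_MEMBRANE", "SECRETED", "OTHER")) {
    p <- cmp$localization[[cls]]
    k <- sum(regular$localization == cls)
    bounds <- stats::qbinom(c(0.005, 0.995), nrow(regular), p)
    expect_gte(k, bounds[1])
    expect_lte(k, bounds[2])
  }
})

test_that("planted sequence composition matches truth (Cys counts, sequons)", {
  co <- generate_proteome_cohort(150, seed = 8)
  truth <- attr(co, "truth")
  expect_equal(count_cys(co), truth$n_cys)
  expect_equal(count_nglycans(co, mode = "sequon_scan"), truth$n_glycans)
  expect_equal(count_nglycans(co, mode = "annotated"), truth$n_glycans)
  # every planted glycosite is a valid sequon in the emitted sequence
  for (i in seq_len(nrow(co))) {
    for (p in co$glyco_sites[[i]]) {
      triplet <- substr(co$sequence[i], p, p + 2)
      expect_match(triplet, "^N[^P][STC]$")
    }
  }
})

test_that("infeasible compositions are rejected", {
  expect_error(cohort_composition(length_fixed = 30L,
                                  signal_span = c(1L, 40L)), "infeasible")
  expect_error(cohort_composition(
    topology = c(SOLUBLE = 0.9, TYPE_I = 0, TYPE_II = 0, MULTIPASS = 0,
                 UNDEFINED = 0)), "sum to 1")
})

test_that("blot-lane generation inverts through the percentage formula", {
  expect_equal(percent_reglucosylation(generate_blot_quants(10, 0, seed = 1)),
               10)
  q0 <- generate_blot_quants(0, 0, seed = 1)
  expect_equal(q0$wt_pulldown, q0$y109a_pulldown)
  # Monte-Carlo: recovered percent is unbiased to within one point
  rec <- vapply(seq_len(1000), function(i) {
    percent_reglucosylation(generate_blot_quants(34, 0.05, seed = 2000 + i))
  }, numeric(1))
  expect_lt(abs(mean(rec) - 34), 1)
})
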