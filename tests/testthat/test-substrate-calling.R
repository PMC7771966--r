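test_that("fold change is bait over control, averaged across replicates", {
  expect_equal(compute_fold_change(tiny_table(9, 3))$fold, 3)
  expect_equal(compute_fold_change(tiny_table(5, 5))$fold, 1)

  # two replicates (10,2) and (6,3): per-replicate 5 and 2, mean 3.5
  quant <- tibble::tibble(accession = "P1", `126` = 10, `127` = 2,
                          `128` = 6, `129` = 3)
  folds <- compute_fold_change(tmt_table(quant, tiny_design(2L)))
  expect_equal(folds$per_replicate_fold[[1]], c(5, 2))
  expect_equal(folds$fold, 3.5)
  # brute-force cross-check over each replicate pair
  brute <- mean(c(10 / 2, 6 / 3))
  expect_equal(folds$fold, brute)
})

test_that("zero control intensity drops the replicate, never invents a fold", {
  quant <- tibble::tibble(accession = c("A", "B"),
                          `126` = c(10, 10), `127` = c(0, 2),
                          `128` = c(6, 6), `129` = c(3, 3))
  folds <- compute_fold_change(tmt_table(quant, tiny_design(2L)))
  expect_equal(folds$per_replicate_fold[[1]], 2)  # only replicate 2 usable
  expect_equal(folds$n_replicates_used, c(1L, 2L))

  all_zero <- tiny_table(10, 0)
  res <- compute_fold_change(all_zero)
  expect_true(is.na(res$fold))
  expect_equal(res$excluded_reason, "ZERO_CONTROL")
})

test_that("empty tables and designs without controls are handled", {
  empty <- tmt_table(tibble::tibble(accession = character(),
                                    `126` = numeric(), `127` = numeric()),
                     tiny_design(1L))
  expect_equal(nrow(compute_fold_change(empty)), 0)
})

test_that("substrates are called at an inclusive cutoff", {
  folds <- tibble::tibble(accession = c("A", "B", "C"),
                          per_replicate_fold = list(3.5, 2.9, 26),
                          fold = c(3.5, 2.9, 26),
                          n_replicates_used = 1L,
                          excluded_reason = NA_character_)
  set <- call_substrates(folds, cutoff = 3)
  expect_setequal(substrate_accessions(set), c("A", "C"))
  expect_equal(set$members$accession[1], "C")  # ranked by fold

  at_cutoff <- dplyr::mutate(folds, fold = c(3, 2, 4))
  expect_true("A" %in% substrate_accessions(call_substrates(at_cutoff, 3)))
  expect_false("A" %in% substrate_accessions(
    call_substrates(at_cutoff, 3, inclusive = FALSE)))

  empty <- folds[0, ]
  expect_equal(call_substrates(empty, 3)$n_post_filter, 0)
})

test_that("the secretory annotation filter applies after the cutoff", {
  sim <- generate_tmt_experiment(40, 8, 4, 8, noise_cv = 0, seed = 13)
  folds <- compute_fold_change(sim$table)
  called <- substrate_accessions(call_substrates(folds, 3))
  ann <- proteome_records(tibble::tibble(
    accession = sim$table$quant$accession,
    length = 100L,
    glyco_sites = lapply(seq_len(40), function(i)
      if (i %% 2 == 0) 10L else integer())))
  set <- call_substrates(folds, 3, annotations = ann)
  expect_equal(set$n_pre_filter, length(called))
  expect_lte(set$n_post_filter, set$n_pre_filter)
  expect_true(all(substrate_accessions(set) %in%
                    ann$accession[vapply(ann$glyco_sites, length,
                                         integer(1)) > 0]))
})

test_that("planted substrates are recovered exactly on clean synthetic data", {
  sim <- generate_tmt_experiment(200, 20, 5, 10, noise_cv = 0.1,
                                 n_replicates = 2, seed = 7)
  set <- call_substrates(compute_fold_change(sim$table), cutoff = 3)
  called <- substrate_accessions(set)
  expect_setequal(called, sim$truth$substrate_accessions)
})

test_that("fold change is invariant to per-protein intensity scaling", {
  sim <- generate_tmt_experiment(30, 6, 4, 8, noise_cv = 0.1, seed = 21)
  f1 <- compute_fold_change(sim$table)
  scaled <- sim$table
  chans <- scaled$design$channel
  for (ch in chans) scaled$quant[[ch]] <- scaled$quant[[ch]] * 137.5
  f2 <- compute_fold_change(tmt_table(scaled$quant, scaled$design))
  expect_equal(f1$fold, f2$fold, tolerance = 1e-12)
})

test_that("raising the cutoff never adds substrates", {
  sim <- generate_tmt_experiment(100, 25, 2, 12, noise_cv = 0.2, seed = 31)
  folds <- compute_fold_change(sim$table)
  cutoffs <- c(1.5, 2, 3, 5, 8)
  sets <- lapply(cutoffs, function(ct)
    substrate_accessions(call_substrates(folds, ct)))
  for (i in seq_along(sets)[-1]) {
    expect_true(all(sets[[i]] %in% sets[[i - 1]]))
  }
})

test_that("the enrichment index has the documented sign and scale", {
  mk <- function(vals) tmt_table(
    tibble::tibble(accession = paste0("P", seq_along(vals)), `126` = vals,
                   `127` = rep(1, length(vals))), tiny_design(1L))
  idx <- enrichment_index(mk(c(10, 100, 1)), mk(c(10, 10, 1000)))
  expect_equal(idx$log10_ratio, c(0, 1, -3))
})

test_that("zero intensities are flagged out of the enrichment index", {
  a <- tmt_table(tibble::tibble(accession = c("P1", "P2"), `126` = c(0, 10),
                                `127` = c(1, 1)), tiny_design(1L))
  b <- tmt_table(tibble::tibble(accession = c("P1", "P2"), `126` = c(5, 10),
                                `127` = c(1, 1)), tiny_design(1L))
  idx <- enrichment_index(a, b)
  expect_equal(idx$accession, "P2")
  expect_equal(attr(idx, "flagged"), "P1")
})

test_that("set overlaps partition the union", {
  ov <- overlap_sets(c("a", "b", "c"), c("b", "c", "d"))
  expect_equal(ov[c("a_only", "shared", "b_only")],
               list(a_only = 1L, shared = 2L, b_only = 1L))
  same <- overlap_sets(c("x", "y"), c("x", "y"))
  expect_equal(same$shared, 2L)
  expect_equal(same$a_only + same$b_only, 0L)
})

test_that("random overlaps match brute-force set arithmetic", {
  withr::with_seed(9, {
    universe <- sprintf("U%03d", 1:200)
    for (rep in 1:100) {
      shared <- sample(universe, 20)
      a <- union(shared, sample(setdiff(universe, shared), 20))
      b <- union(shared, sample(setdiff(universe, c(shared, a)), 15))
      ov <- overlap_sets(a, b)
      expect_equal(ov$shared, length(intersect(a, b)))
      expect_equal(ov$a_only + ov$shared + ov$b_only, length(union(a, b)))
      expect_equal(ov$a_only + ov$shared, length(a))
      expect_equal(ov$b_only + ov$shared, length(b))
    }
  })
})
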