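test_that("glycan counting honours both annotation and sequon-scan modes", {
  rec <- make_record(length = 9L, sequence = "AANGSAAAA",
                     glyco_sites = c(2L, 4L, 6L))
  expect_equal(count_nglycans(rec, mode = "annotated"), 3L)
  expect_equal(count_sequons("NGS"), 1L)
  expect_equal(count_sequons("NPS"), 0L)
  expect_equal(count_sequons("NGC"), 1L)
  expect_equal(count_sequons("NG"), 0L)
  no_seq <- make_record(length = 10L)
  expect_error(count_nglycans(no_seq, mode = "sequon_scan"), "sequence")
})

test_that("sequon scan equals the brute-force triple loop on random sequences", {
  for (seed in c(4, 40, 400)) {
    s <- random_aa_string(500, seed)
    expect_equal(count_sequons(s), brute_sequons(s))
  }
})

test_that("cysteine counting is a character count with a sequence precondition", {
  expect_equal(count_cys(make_record(length = 4L, sequence = "CACA")), 2L)
  expect_equal(count_cys(make_record(length = 4L, sequence = "AAAA")), 0L)
  expect_error(count_cys(make_record(length = 10L)), "sequence")
  s <- random_aa_string(1000, 2)
  expect_equal(count_cys(make_record(length = 1000L, sequence = s)),
               as.integer(table(strsplit(s, "")[[1]])[["C"]]))
})

test_that("pI of a di-glycine is the closed-form acid/base midpoint", {
  # one acid (C-term 3.55) + one base (N-term 7.5): pI = midpoint 5.525
  expect_equal(theoretical_pi("GG"), (3.55 + 7.5) / 2, tolerance = 2e-3)
  expect_gt(theoretical_pi("KK"), 7.5)
})

test_that("the returned pI is a genuine root of the charge function", {
  for (seed in 1:5) {
    s <- random_aa_string(80, seed)
    pi <- theoretical_pi(s, tol = 1e-4)
    expect_lt(abs(net_charge(s, pi)), 0.01)
  }
})

test_that("bisection matches a dense grid-scan oracle on random sequences", {
  withr::with_seed(17, {
    lengths <- sample(30:300, 100, replace = TRUE)
  })
  for (i in seq_along(lengths)) {
    s <- random_aa_string(lengths[i], 1000 + i)
    expect_equal(theoretical_pi(s), grid_pi_oracle(s), tolerance = 2e-3)
  }
})

test_that("acidic residues never raise the pI and basic never lower it", {
  for (seed in 1:20) {
    s <- random_aa_string(60, 300 + seed)
    base <- theoretical_pi(s)
    expect_lte(theoretical_pi(paste0(s, "D")), base + 2e-3)
    expect_lte(theoretical_pi(paste0(s, "E")), base + 2e-3)
    expect_gte(theoretical_pi(paste0(s, "K")), base - 2e-3)
    expect_gte(theoretical_pi(paste0(s, "R")), base - 2e-3)
  }
})

test_that("topology classes follow the annotation rules", {
  soluble <- make_record(length = 100L, signal = c(1L, 20L))
  expect_equal(classify_topology(soluble), "SOLUBLE")

  type1 <- make_record(length = 100L, tm = cbind(71, 91),
                       topo = tibble::tibble(
                         start = c(21L, 92L), end = c(70L, 100L),
                         side = c("LUMENAL_EXTRACELLULAR", "CYTOPLASMIC")))
  expect_equal(classify_topology(type1), "TYPE_I")

  type2 <- make_record(length = 100L, tm = cbind(25, 45),
                       topo = tibble::tibble(
                         start = c(1L, 46L), end = c(24L, 100L),
                         side = c("CYTOPLASMIC", "LUMENAL_EXTRACELLULAR")))
  expect_equal(classify_topology(type2), "TYPE_II")

  multipass <- make_record(length = 200L, tm = cbind(c(20, 60), c(40, 80)))
  expect_equal(classify_topology(multipass), "MULTIPASS")

  # annotated transmembrane but no topology information
  undefined <- make_record(length = 100L, tm = cbind(25, 45))
  expect_equal(classify_topology(undefined), "UNDEFINED")
})

test_that("partial domain annotation still orients single-pass proteins", {
  lum_before_only <- make_record(length = 100L, tm = cbind(71, 91),
                                 topo = tibble::tibble(
                                   start = 21L, end = 70L,
                                   side = "LUMENAL_EXTRACELLULAR"))
  expect_equal(classify_topology(lum_before_only), "TYPE_I")
  cyto_before_only <- make_record(length = 100L, tm = cbind(25, 45),
                                  topo = tibble::tibble(
                                    start = 1L, end = 24L,
                                    side = "CYTOPLASMIC"))
  expect_equal(classify_topology(cyto_before_only), "TYPE_II")
})

test_that("luminal exposure is span arithmetic per topology class", {
  type1 <- make_record(length = 100L, tm = cbind(71, 91),
                       signal = c(1L, 20L),
                       topo = tibble::tibble(
                         start = c(21L, 92L), end = c(70L, 100L),
                         side = c("LUMENAL_EXTRACELLULAR", "CYTOPLASMIC")))
  expect_equal(luminal_exposure(type1), 50L)

  soluble <- make_record(length = 200L, signal = c(1L, 25L))
  expect_equal(luminal_exposure(soluble), 175L)

  multipass <- make_record(length = 300L,
                           tm = cbind(c(40, 100, 160), c(60, 120, 180)),
                           topo = tibble::tibble(
                             start = c(61L, 121L), end = c(90L, 165L),
                             side = c("LUMENAL_EXTRACELLULAR",
                                      "LUMENAL_EXTRACELLULAR")))
  expect_equal(luminal_exposure(multipass), 30L + 45L)

  undefined <- make_record(length = 100L, tm = cbind(25, 45))
  expect_true(is.na(luminal_exposure(undefined)))
})

test_that("luminal exposure never exceeds non-membrane length", {
  co <- generate_proteome_cohort(200, seed = 12, sequences = FALSE)
  topo <- classify_topology(co)
  lum <- luminal_exposure(co, topo)
  mem <- topo %in% c("TYPE_I", "TYPE_II", "MULTIPASS")
  tm_len <- purrr::map_int(co$tm_segments,
                           ~ as.integer(sum(.x$end - .x$start + 1L)))
  expect_true(all(lum[mem] <= co$length[mem] - tm_len[mem]))
})

test_that("topology and luminal exposure equal generator truth on a cohort", {
  co <- generate_proteome_cohort(500, seed = 5, sequences = FALSE)
  truth <- attr(co, "truth")
  expect_equal(classify_topology(co), truth$topology)
  expect_equal(luminal_exposure(co), truth$luminal_residues)
})

test_that("localization keywords map terms to classes, with MULTIPLE for >= 2", {
  expect_equal(classify_localization(list("Lysosome membrane")), "LYSOSOME")
  expect_equal(classify_localization(list("Secreted")), "SECRETED")
  expect_equal(classify_localization(
    list(c("Cell membrane", "Lysosome", "Golgi apparatus"))), "MULTIPLE")
  expect_equal(classify_localization(list(character())), "OTHER")
  expect_equal(classify_localization(list("Cytosol")), "OTHER")
})

test_that("feature profiles assemble all columns coherently", {
  co <- generate_proteome_cohort(60, seed = 9)
  prof <- feature_profiles(co)
  truth <- attr(co, "truth")
  expect_equal(prof$n_glycans, truth$n_glycans)
  expect_equal(prof$n_cys, truth$n_cys)
  expect_equal(prof$topology, truth$topology)
  expect_true(all(prof$pI > 0 & prof$pI < 14))
  expect_true(all(prof$n_cys <= prof$length))
  mature <- feature_profiles(co, pi_mature = TRUE)
  has_sp <- !is.na(co$signal_start)
  expect_true(any(mature$pI[has_sp] != prof$pI[has_sp]))
})
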