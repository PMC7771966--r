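#' Composition of a synthetic proteome cohort
#'
#' Bundles the class probabilities and distribution parameters used by
#' [generate_proteome_cohort()]. The defaults emulate the reviewed human
#' proteome as the pipeline sees it: localization fractions of the
#' N-glycoproteome (plasma membrane 37%, secreted 20%, ER 5%, Golgi 4%,
#' lysosome 2%), a membrane/soluble topology split of roughly 70/30 with
#' half the membrane proteins multi-pass, about 22% of proteins carrying
#' at least one N-glycan, glycan counts with median 2, a cysteine rate
#' giving a median of ~11 Cys on a median-length protein, and a log-normal
#' length distribution with median 443 residues.
#'
#' @param localization Named probability vector over
#'   [localization_classes()].
#' @param topology Named probability vector over
#'   `SOLUBLE, TYPE_I, TYPE_II, MULTIPASS, UNDEFINED`.
#' @param p_glycosylated Probability that a protein carries >= 1 N-glycan.
#' @param glycan_lambda Glycosylated proteins carry `1 + Poisson(lambda)`
#'   glycans.
#' @param cys_rate Per-residue Bernoulli rate of cysteines.
#' @param length_meanlog,length_sdlog Log-normal length parameters
#'   (residues).
#' @param length_fixed Optional fixed length overriding the distribution.
#' @param signal_span Signal-peptide span given to soluble-secretory and
#'   type I records.
#' @param fraction_mitochondrial,fraction_short,fraction_isoform Fractions
#'   of records that are mitochondrial, shorter than 50 residues, or
#'   redundant isoform duplicates of an earlier record.
#' @return A `cohort_composition` list.
#' @export
cohort_composition <- function(
    localization = c(PLASMA_MEMBRANE = 0.37, SECRETED = 0.20, ER = 0.05,
                     GOLGI = 0.04, LYSOSOME = 0.02, NUCLEAR_MEMBRANE = 0.02,
                     MULTIPLE = 0.06, OTHER = 0.24),
    topology = c(SOLUBLE = 0.30, TYPE_I = 0.23, TYPE_II = 0.11,
                 MULTIPASS = 0.33, UNDEFINED = 0.03),
    p_glycosylated = 0.222,
    glycan_lambda = 1.5,
    cys_rate = 0.025,
    length_meanlog = log(443),
    length_sdlog = 0.8,
    length_fixed = NULL,
    signal_span = c(1L, 20L),
    fraction_mitochondrial = 0.02,
    fraction_short = 0.01,
    fraction_isoform = 0.01) {
  check_probs <- function(p, what) {
    if (any(p < 0) || abs(sum(p) - 1) > 1e-8) {
      stop(what, " probabilities must be non-negative and sum to 1",
           call. = FALSE)
    }
  }
  check_probs(localization, "localization")
  check_probs(topology, "topology")
  stopifnot(p_glycosylated >= 0, p_glycosylated <= 1, glycan_lambda >= 0,
            cys_rate >= 0, cys_rate <= 1,
            fraction_mitochondrial >= 0, fraction_short >= 0,
            fraction_isoform >= 0,
            fraction_mitochondrial + fraction_short + fraction_isoform <= 1)
  if (!is.null(length_fixed)) {
    if (length_fixed < 3) stop("infeasible composition: length too small",
                               call. = FALSE)
    if (signal_span[2] >= length_fixed) {
      stop("infeasible composition: signal peptide spans the whole protein",
           call. = FALSE)
    }
  }
  structure(list(localization = localization, topology = topology,
                 p_glycosylated = p_glycosylated,
                 glycan_lambda = glycan_lambda, cys_rate = cys_rate,
                 length_meanlog = length_meanlog,
                 length_sdlog = length_sdlog, length_fixed = length_fixed,
                 signal_span = as.integer(signal_span),
                 fraction_mitochondrial = fraction_mitochondrial,
                 fraction_short = fraction_short,
                 fraction_isoform = fraction_isoform),
            class = "cohort_composition")
}

# Seed the RNG for the calling function's scope and restore the previous
# global state on exit, so generators use one explicit stream per call.
local_seed_restore <- function(seed, envir = parent.frame()) {
  old <- if (exists(".Random.seed", globalenv(), inherits = FALSE)) {
    get(".Random.seed", globalenv())
  } else NULL
  set.seed(seed)
  withr::defer({
    if (is.null(old)) {
      rm(".Random.seed", envir = globalenv())
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  }, envir = envir)
}

lognormal_multiplier <- function(n, cv) {
  if (cv == 0) return(rep(1, n))
  sigma <- sqrt(log(1 + cv^2))
  stats::rlnorm(n, meanlog = -sigma^2 / 2, sdlog = sigma)  # mean 1
}

#' Simulate a TMT affinity-purification experiment with planted substrates
#'
#' Emulates the pull-down design: each replicate pairs a wild-type GST-CRT
#' bait channel with a lectin-dead GST-CRT-Y109A control channel.
#' Background proteins have an expected bait/control ratio of 1; planted
#' substrates have a ratio drawn uniformly from `[fold_low, fold_high]`.
#' Channel noise is multiplicative log-normal with the requested
#' coefficient of variation, mean-corrected so the expected multiplier is
#' 1; with `noise_cv = 0` every observed per-replicate ratio equals its
#' planted fold exactly.
#'
#' @param n_proteins,n_substrates Cohort size and number of planted
#'   substrates (`0 <= n_substrates <= n_proteins`).
#' @param fold_low,fold_high Planted fold range (`fold_low >= 1`).
#' @param noise_cv Per-channel coefficient of variation (>= 0).
#' @param n_replicates Number of bait/control channel pairs.
#' @param seed Integer seed; a single RNG stream is used per call and
#'   global RNG state is restored afterwards.
#' @param genotype Genotype label written into the design.
#' @param background_bias Expected bait/control ratio of background
#'   proteins (a nonspecific-binding bias knob; defaults to 1, i.e. off).
#' @return List with `table` (a [tmt_table()]) and `truth` (a
#'   `synthetic_truth` with `substrate_accessions`, `planted_fold` -- a
#'   named vector over all accessions, 1 for background -- and `seed`).
#' @export
generate_tmt_experiment <- function(n_proteins, n_substrates,
                                    fold_low = 5, fold_high = 10,
                                    noise_cv = 0.1, n_replicates = 2,
                                    seed = 1, genotype = "ALG6-KO",
                                    background_bias = 1) {
  stopifnot(n_proteins >= 0, n_substrates >= 0, n_substrates <= n_proteins,
            fold_low >= 1, fold_high >= fold_low, n_replicates >= 1)
  if (noise_cv < 0) stop("noise_cv must be >= 0", call. = FALSE)
  local_seed_restore(seed)

  accession <- sprintf("SYNP%05d", seq_len(n_proteins))
  substrate_idx <- if (n_substrates > 0) {
    sort(sample.int(n_proteins, n_substrates))
  } else integer()
  planted <- stats::setNames(rep(background_bias, n_proteins), accession)
  planted[substrate_idx] <- stats::runif(n_substrates, fold_low, fold_high)

  base <- stats::rlnorm(n_proteins, meanlog = log(1e5), sdlog = 1)

  tmt_labels <- c("126", "127N", "127C", "128N", "128C", "129N", "129C",
                  "130N", "130C", "131")
  n_chan <- 2L * n_replicates
  labels <- if (n_chan <= length(tmt_labels)) tmt_labels[seq_len(n_chan)] else
    sprintf("ch%02d", seq_len(n_chan))

  quant <- tibble::tibble(accession = accession)
  design <- tibble::tibble(channel = labels,
                           condition = rep(c("CRT_WT", "CRT_Y109A"),
                                           n_replicates),
                           replicate = rep(seq_len(n_replicates), each = 2L),
                           genotype = genotype)
  for (r in seq_len(n_replicates)) {
    quant[[labels[2L * r - 1L]]] <-
      unname(base * planted * lognormal_multiplier(n_proteins, noise_cv))
    quant[[labels[2L * r]]] <-
      base * lognormal_multiplier(n_proteins, noise_cv)
  }

  truth <- structure(list(substrate_accessions = accession[substrate_idx],
                          planted_fold = planted, seed = seed),
                     class = "synthetic_truth")
  list(table = tmt_table(quant, design), truth = truth)
}

random_sequence <- function(length, glyco_sites, n_cys) {
  # alphabet excludes N and C so planted sequons and cysteines are exact
  alphabet <- c("A", "D", "E", "F", "G", "H", "I", "K", "L", "M", "P", "Q",
                "R", "S", "T", "V", "W", "Y")
  aa <- sample(alphabet, length, replace = TRUE)
  reserved <- unique(unlist(lapply(glyco_sites, function(p) p:(p + 2L))))
  reserved <- reserved[reserved <= length]
  free <- setdiff(seq_len(length), reserved)
  n_cys <- min(n_cys, length(free))
  if (n_cys > 0) {
    aa[free[sample.int(length(free), n_cys)]] <- "C"
  }
  for (p in glyco_sites) {
    aa[p] <- "N"
    if (p + 1L <= length && aa[p + 1L] == "P") aa[p + 1L] <- "G"
    if (p + 2L <= length) aa[p + 2L] <- sample(c("S", "T"), 1)
  }
  list(sequence = paste(aa, collapse = ""), n_cys = n_cys)
}

loc_terms_for_class <- function(class) {
  switch(class,
         PLASMA_MEMBRANE = "Cell membrane",
         SECRETED = "Secreted",
         ER = "Endoplasmic reticulum membrane",
         GOLGI = "Golgi apparatus",
         LYSOSOME = "Lysosome",
         NUCLEAR_MEMBRANE = "Nucleus membrane",
         MULTIPLE = c("Cell membrane", "Lysosome", "Golgi apparatus"),
         OTHER = "Cytoplasm")
}

# Glycosite candidates spaced >= 3 within allowed regions, capped at what fits
place_glycosites <- function(regions, n_sites, length) {
  if (n_sites == 0 || nrow(regions) == 0) return(integer())
  grid <- unlist(purrr::map2(regions$start, regions$end, function(s, e) {
    e <- min(e, length - 2L)
    if (e < s) return(integer())
    seq.int(s, e, by = 3L)
  }))
  if (length(grid) == 0) return(integer())
  sort(grid[sample.int(length(grid), min(n_sites, length(grid)))])
}

#' Generate a proteome cohort with known ground truth
#'
#' Builds self-consistent annotation records: a type I record carries a
#' signal peptide, one transmembrane segment, an N-terminal
#' luminal/extracellular domain and a C-terminal cytoplasmic domain; a
#' multi-pass record alternates loop sides starting cytoplasmic at the
#' N-terminus; an "undefined" record has a transmembrane segment but no
#' topological domains; glycosites land in luminal regions; emitted
#' sequences contain exactly the planted number of cysteines and a valid
#' sequon at every planted glycosite.
#'
#' @param n Number of records.
#' @param composition A [cohort_composition()].
#' @param seed Integer seed (single RNG stream per call).
#' @param sequences Emit amino-acid sequences? (Skipping them speeds up
#'   large cohorts; sequence-dependent features then return `NA`.)
#' @return A [proteome_records()] tibble with the generation truth in
#'   `attr(x, "truth")`: a tibble of planted per-record values
#'   (`category`, `topology`, `localization`, `n_glycans`, `n_cys`,
#'   `luminal_residues`, `passes_filters`) plus
#'   `attr(x, "n_expected_retained")`, the number of distinct canonical
#'   accessions expected to survive N-glycoproteome curation.
#' @export
generate_proteome_cohort <- function(n, composition = cohort_composition(),
                                     seed = 1, sequences = TRUE) {
  stopifnot(n >= 0, inherits(composition, "cohort_composition"))
  local_seed_restore(seed)
  cmp <- composition

  category <- sample(c("short", "mitochondrial", "isoform", "regular"), n,
                     replace = TRUE,
                     prob = c(cmp$fraction_short, cmp$fraction_mitochondrial,
                              cmp$fraction_isoform,
                              1 - cmp$fraction_short -
                                cmp$fraction_mitochondrial -
                                cmp$fraction_isoform))
  # isoforms duplicate an earlier non-isoform record; without one they
  # degrade to regular
  first_non_iso <- which(category != "isoform")[1]
  if (!is.na(first_non_iso)) {
    category[seq_len(first_non_iso)][
      category[seq_len(first_non_iso)] == "isoform"] <- "regular"
  } else {
    category[category == "isoform"] <- "regular"
  }

  draw_length <- function(min_len) {
    if (!is.null(cmp$length_fixed)) return(as.integer(cmp$length_fixed))
    max(min_len,
        as.integer(round(stats::rlnorm(1, cmp$length_meanlog,
                                       cmp$length_sdlog))))
  }

  rows <- vector("list", n)
  truth <- vector("list", n)
  sp <- cmp$signal_span

  for (i in seq_len(n)) {
    cat_i <- category[i]
    if (cat_i == "isoform") {
      candidates <- which(category[seq_len(i - 1)] != "isoform")
      parent_i <- candidates[sample.int(length(candidates), 1)]
      parent <- rows[[parent_i]]
      row <- parent
      row$accession <- paste0(parent$accession, "-2")
      row$name <- paste0(parent$name, "-2")
      row$canonical_accession <- parent$accession
      row$is_isoform <- TRUE
      rows[[i]] <- row
      tr <- truth[[parent_i]]
      tr$accession <- row$accession
      tr$category <- "isoform"
      truth[[i]] <- tr
      next
    }

    acc <- sprintf("SYNR%05d", i)
    is_mito <- cat_i == "mitochondrial"
    is_short <- cat_i == "short"

    topo <- if (is_mito || is_short) "SOLUBLE" else
      sample(names(cmp$topology), 1, prob = cmp$topology)
    loc_class <- if (is_mito) "OTHER" else
      sample(names(cmp$localization), 1, prob = cmp$localization)
    loc_terms <- if (is_mito) "Mitochondrion" else
      loc_terms_for_class(loc_class)

    min_len <- switch(topo, SOLUBLE = max(60L, sp[2] + 10L),
                      TYPE_I = 120L, TYPE_II = 120L, MULTIPASS = 160L,
                      UNDEFINED = 120L)
    len <- if (is_short) sample(20:49, 1) else draw_length(min_len)

    tm <- empty_spans()
    td <- empty_domains()
    sig <- c(NA_integer_, NA_integer_)
    lum_regions <- empty_spans()
    if (topo == "SOLUBLE") {
      if (!is_mito && !is_short) sig <- sp
      mature_start <- if (is.na(sig[1])) 1L else sig[2] + 1L
      lum_regions <- tibble::tibble(start = mature_start, end = len)
      planted_luminal <- len - (if (is.na(sig[1])) 0L else
        sig[2] - sig[1] + 1L)
    } else if (topo == "TYPE_I") {
      sig <- sp
      tm <- tibble::tibble(start = len - 45L, end = len - 25L)
      td <- tibble::tibble(start = c(sig[2] + 1L, tm$end + 1L),
                           end = c(tm$start - 1L, len),
                           side = c("LUMENAL_EXTRACELLULAR", "CYTOPLASMIC"))
      lum_regions <- td[1, c("start", "end")]
      planted_luminal <- td$end[1] - td$start[1] + 1L
    } else if (topo == "TYPE_II") {
      tm <- tibble::tibble(start = 25L, end = 45L)
      td <- tibble::tibble(start = c(1L, 46L), end = c(24L, len),
                           side = c("CYTOPLASMIC", "LUMENAL_EXTRACELLULAR"))
      lum_regions <- td[2, c("start", "end")]
      planted_luminal <- len - 45L
    } else if (topo == "MULTIPASS") {
      k <- 2L + stats::rpois(1, 2)
      loop_w <- (len - 21L * k) %/% (k + 1L)
      while (loop_w < 8L && k > 2L) {
        k <- k - 1L
        loop_w <- (len - 21L * k) %/% (k + 1L)
      }
      starts <- loop_w + 1L + (0:(k - 1L)) * (21L + loop_w)
      tm <- tibble::tibble(start = starts, end = starts + 20L)
      loop_start <- c(1L, tm$end + 1L)
      loop_end <- c(tm$start - 1L, len)
      side <- rep(c("CYTOPLASMIC", "LUMENAL_EXTRACELLULAR"),
                  length.out = k + 1L)
      td <- tibble::tibble(start = loop_start, end = loop_end, side = side)
      lum_regions <- td[td$side == "LUMENAL_EXTRACELLULAR",
                        c("start", "end")]
      planted_luminal <- as.integer(sum(lum_regions$end -
                                          lum_regions$start + 1L))
    } else { # UNDEFINED: membrane protein lacking topology information
      tm <- tibble::tibble(start = 25L, end = 45L)
      planted_luminal <- NA_integer_
      lum_regions <- tibble::tibble(start = 50L, end = len)
    }

    glycosylated <- stats::runif(1) < cmp$p_glycosylated
    n_gly_target <- if (glycosylated) 1L + stats::rpois(1, cmp$glycan_lambda)
      else 0L
    sites <- place_glycosites(lum_regions, n_gly_target, len)

    n_cys_target <- stats::rbinom(1, len, cmp$cys_rate)
    if (sequences) {
      sq <- random_sequence(len, sites, n_cys_target)
      sequence <- sq$sequence
      n_cys_planted <- sq$n_cys
    } else {
      sequence <- NA_character_
      n_cys_planted <- n_cys_target
    }

    rows[[i]] <- list(accession = acc, name = acc, length = len,
                      sequence = sequence, glyco_sites = sites,
                      tm_segments = tm, topo_domains = td,
                      signal_start = sig[1], signal_end = sig[2],
                      localization_terms = loc_terms,
                      is_mitochondrial = is_mito, is_isoform = FALSE,
                      canonical_accession = acc)
    truth[[i]] <- list(accession = acc, category = cat_i, topology = topo,
                       localization = if (is_mito) "OTHER" else loc_class,
                       n_glycans = length(sites), n_cys = n_cys_planted,
                       luminal_residues = planted_luminal, length = len,
                       is_mitochondrial = is_mito)
  }

  records <- proteome_records(tibble::tibble(
    accession = purrr::map_chr(rows, "accession"),
    name = purrr::map_chr(rows, "name"),
    length = purrr::map_int(rows, "length"),
    sequence = purrr::map_chr(rows, "sequence"),
    glyco_sites = purrr::map(rows, "glyco_sites"),
    tm_segments = purrr::map(rows, "tm_segments"),
    topo_domains = purrr::map(rows, "topo_domains"),
    signal_start = purrr::map_int(rows, "signal_start"),
    signal_end = purrr::map_int(rows, "signal_end"),
    localization_terms = purrr::map(rows, "localization_terms"),
    is_mitochondrial = purrr::map_lgl(rows, "is_mitochondrial"),
    is_isoform = purrr::map_lgl(rows, "is_isoform"),
    canonical_accession = purrr::map_chr(rows, "canonical_accession")
  ))

  truth_tbl <- tibble::tibble(
    accession = purrr::map_chr(truth, "accession"),
    category = purrr::map_chr(truth, "category"),
    topology = purrr::map_chr(truth, "topology"),
    localization = purrr::map_chr(truth, "localization"),
    n_glycans = purrr::map_int(truth, "n_glycans"),
    n_cys = purrr::map_int(truth, "n_cys"),
    luminal_residues = purrr::map_int(truth, "luminal_residues"),
    length = purrr::map_int(truth, "length"),
    is_mitochondrial = purrr::map_lgl(truth, "is_mitochondrial")
  )
  passes <- truth_tbl$n_glycans >= 1 & !truth_tbl$is_mitochondrial &
    truth_tbl$length >= 50
  truth_tbl$passes_filters <- passes
  attr(records, "truth") <- truth_tbl
  attr(records, "n_expected_retained") <-
    length(unique(records$canonical_accession[passes]))
  records
}

#' Simulate densitometry lanes with a known reglucosylation percentage
#'
#' Constructs whole-cell-lysate and pull-down lane values so that
#' [percent_reglucosylation()] recovers `true_percent` exactly at zero
#' noise and in expectation otherwise. The control pull-down carries a
#' small nonspecific background; log-normal noise with the requested CV is
#' applied per lane.
#'
#' @param true_percent Planted reglucosylation percentage in `[0, 100]`.
#' @param noise_cv Per-lane coefficient of variation (>= 0).
#' @param wcl_fraction Fraction of lysate loaded in the WCL lane.
#' @param n_pulldowns Number of pull-downs the remainder is split between.
#' @param seed Integer seed.
#' @return One-row tibble of lanes compatible with
#'   [percent_reglucosylation()].
#' @export
generate_blot_quants <- function(true_percent, noise_cv = 0,
                                 wcl_fraction = 0.10, n_pulldowns = 2L,
                                 seed = 1) {
  stopifnot(true_percent >= 0, true_percent <= 100, wcl_fraction > 0,
            n_pulldowns >= 1)
  if (noise_cv < 0) stop("noise_cv must be >= 0", call. = FALSE)
  local_seed_restore(seed)
  total <- 1000
  per_pulldown <- total / n_pulldowns
  y109a <- 0.02 * per_pulldown
  wt <- y109a + true_percent / 100 * per_pulldown
  wcl <- total * wcl_fraction
  noise <- lognormal_multiplier(3, noise_cv)
  tibble::tibble(genotype = "synthetic", protein = "synthetic",
                 wcl = wcl * noise[1], wt_pulldown = wt * noise[2],
                 y109a_pulldown = y109a * noise[3],
                 wcl_fraction = wcl_fraction,
                 n_pulldowns = as.integer(n_pulldowns))
}
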