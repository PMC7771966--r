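#' Per-protein fold increase (bait over lectin-dead control)
#'
#' For every protein, each replicate's fold increase is the reporter
#' intensity in the wild-type GST-CRT channel divided by the intensity in
#' the paired GST-CRT-Y109A control channel; the aggregate fold is the
#' arithmetic mean of the per-replicate folds. A replicate whose control
#' intensity is zero or missing is dropped (no pseudo-count is added); a
#' protein that loses every replicate is excluded with reason
#' `ZERO_CONTROL`.
#'
#' @param table A [tmt_table()].
#' @param median_center If `TRUE`, divide each channel by its median over
#'   proteins before forming ratios (off by default; no normalization is
#'   applied unless requested).
#' @return Tibble with columns `accession`, `gene` (if present),
#'   `per_replicate_fold` (list column), `fold`, `n_replicates_used`,
#'   `excluded_reason` (`NA`, `"ZERO_CONTROL"` or `"MISSING_CHANNEL"`).
#' @export
#' @examples
#' quant <- tibble::tibble(accession = "P1", `126` = 9, `127` = 3)
#' design <- tibble::tibble(channel = c("126", "127"),
#'                          condition = c("CRT_WT", "CRT_Y109A"),
#'                          replicate = 1L, genotype = "ALG6-KO")
#' compute_fold_change(tmt_table(quant, design))$fold  # 3
compute_fold_change <- function(table, median_center = FALSE) {
  stopifnot(inherits(table, "tmt_table"))
  quant <- table$quant
  wt <- design_channels(table$design, "CRT_WT")
  ctl <- design_channels(table$design, "CRT_Y109A")
  if (nrow(ctl) == 0) {
    stop("design has no CRT_Y109A control channel", call. = FALSE)
  }
  pairs <- dplyr::inner_join(wt, ctl, by = c("replicate", "genotype"),
                             suffix = c("_wt", "_ctl"))

  if (nrow(quant) == 0) {
    return(tibble::tibble(accession = character(),
                          per_replicate_fold = list(),
                          fold = numeric(), n_replicates_used = integer(),
                          excluded_reason = character()))
  }

  get_channel <- function(ch) {
    v <- quant[[ch]]
    if (median_center) {
      m <- stats::median(v[v > 0], na.rm = TRUE)
      if (is.finite(m) && m > 0) v <- v / m
    }
    v
  }
  wt_mat <- vapply(pairs$channel_wt, get_channel, numeric(nrow(quant)))
  ctl_mat <- vapply(pairs$channel_ctl, get_channel, numeric(nrow(quant)))
  wt_mat <- matrix(wt_mat, nrow = nrow(quant))
  ctl_mat <- matrix(ctl_mat, nrow = nrow(quant))

  res <- purrr::map(seq_len(nrow(quant)), function(i) {
    w <- wt_mat[i, ]
    ctl <- ctl_mat[i, ]
    usable <- !is.na(w) & !is.na(ctl) & ctl > 0
    folds <- w[usable] / ctl[usable]
    list(per_replicate_fold = folds,
         fold = if (length(folds) > 0) mean(folds) else NA_real_,
         n_replicates_used = length(folds),
         excluded_reason = if (length(folds) > 0) NA_character_ else
           "ZERO_CONTROL")
  })

  out <- tibble::tibble(
    accession = quant$accession,
    per_replicate_fold = purrr::map(res, "per_replicate_fold"),
    fold = purrr::map_dbl(res, "fold"),
    n_replicates_used = purrr::map_int(res, "n_replicates_used"),
    excluded_reason = purrr::map_chr(res, "excluded_reason")
  )
  if ("gene" %in% names(quant)) {
    out <- dplyr::mutate(out, gene = quant$gene, .after = "accession")
  }
  out
}

#' Call reglucosylation substrates at a fold-change cutoff
#'
#' Applies the fold cutoff (threefold by default, the conservative
#' threshold below which increasing fractions of non-secretory proteins
#' appear), then optionally intersects with an annotation-based secretory
#' filter. The cutoff is applied first and the filter second, so both the
#' pre-filter and post-filter counts are reported.
#'
#' @param folds Result of [compute_fold_change()].
#' @param cutoff Fold-change threshold (> 0).
#' @param inclusive If `TRUE` (default) a fold exactly equal to the cutoff
#'   passes.
#' @param annotations Optional [proteome_records()] used by the filter.
#' @param secretory_filter Optional predicate taking `annotations` and
#'   returning a logical vector; the default (used only when `annotations`
#'   is supplied) keeps proteins with at least one annotated N-glycosite
#'   that are not mitochondrial.
#' @param genotype_label Label stored on the resulting set.
#' @return A `substrate_set`: list with `genotype_label`, `members` (fold
#'   results of the called substrates, ranked by decreasing fold),
#'   `cutoff`, `n_pre_filter`, `n_post_filter`.
#' @export
call_substrates <- function(folds, cutoff = 3.0, inclusive = TRUE,
                            annotations = NULL, secretory_filter = NULL,
                            genotype_label = "experiment") {
  stopifnot(cutoff > 0)
  passed <- folds |>
    dplyr::filter(is.na(.data$excluded_reason),
                  if (inclusive) .data$fold >= cutoff else .data$fold > cutoff)
  n_pre <- nrow(passed)

  if (!is.null(annotations) || !is.null(secretory_filter)) {
    if (is.null(secretory_filter)) {
      secretory_filter <- function(rec) {
        purrr::map_int(rec$glyco_sites, length) >= 1L & !rec$is_mitochondrial
      }
    }
    if (is.null(annotations)) {
      stop("secretory_filter needs annotations", call. = FALSE)
    }
    keep_acc <- annotations$accession[secretory_filter(annotations)]
    passed <- dplyr::filter(passed, .data$accession %in% keep_acc)
  }

  members <- dplyr::arrange(passed, dplyr::desc(.data$fold))
  structure(list(genotype_label = genotype_label, members = members,
                 cutoff = cutoff, n_pre_filter = n_pre,
                 n_post_filter = nrow(members)),
            class = "substrate_set")
}

#' @export
print.substrate_set <- function(x, ...) {
  cat("<substrate_set> ", x$genotype_label, ": ", x$n_post_filter,
      " substrates at fold >= ", x$cutoff,
      if (x$n_pre_filter != x$n_post_filter)
        paste0(" (", x$n_pre_filter, " before annotation filter)") else "",
      "\n", sep = "")
  if (nrow(x$members) > 0) {
    top <- x$members[1, ]
    cat("  top: ", top$accession, " (", signif(top$fold, 3), "-fold)\n",
        sep = "")
  }
  invisible(x)
}

#' Accessions of a substrate set
#' @param x A `substrate_set`.
#' @return Character vector.
#' @export
substrate_accessions <- function(x) {
  stopifnot(inherits(x, "substrate_set"))
  x$members$accession
}

#' Paralog enrichment index from two knockout experiments
#'
#' Compares the same bait condition across two experiments (e.g. the
#' UGGT1-knockout line, where remaining reglucosylation is UGGT2's, against
#' the UGGT2-knockout line): for each shared protein the mean wild-type
#' bait intensity in the first table is divided by that in the second, on a
#' log10 scale. Positive values mean enrichment in the first (UGGT1-KO)
#' experiment, negative values enrichment in the second (UGGT2-KO)
#' experiment. Proteins with a zero numerator or denominator are flagged
#' and not emitted (reported via `attr(, "flagged")`).
#'
#' @param table_u1ko,table_u2ko [tmt_table()] objects for the two lines.
#' @param condition Channel condition to compare (default `"CRT_WT"`).
#' @return Tibble with columns `accession` and `log10_ratio`.
#' @export
enrichment_index <- function(table_u1ko, table_u2ko, condition = "CRT_WT") {
  mean_intensity <- function(table) {
    chans <- design_channels(table$design, condition)$channel
    if (length(chans) == 0) {
      stop("table has no ", condition, " channel", call. = FALSE)
    }
    tibble::tibble(
      accession = table$quant$accession,
      value = rowMeans(as.matrix(table$quant[, chans, drop = FALSE]),
                       na.rm = TRUE))
  }
  joined <- dplyr::inner_join(mean_intensity(table_u1ko),
                              mean_intensity(table_u2ko),
                              by = "accession", suffix = c("_u1ko", "_u2ko"))
  if (nrow(joined) == 0) {
    stop("no shared accessions between the two tables", call. = FALSE)
  }
  bad <- !is.finite(joined$value_u1ko) | !is.finite(joined$value_u2ko) |
    joined$value_u1ko <= 0 | joined$value_u2ko <= 0
  out <- joined |>
    dplyr::filter(!bad) |>
    dplyr::transmute(.data$accession,
                     log10_ratio = log10(.data$value_u1ko / .data$value_u2ko))
  attr(out, "flagged") <- joined$accession[bad]
  out
}

#' Overlap of two substrate sets
#'
#' Partition of the union of two substrate sets, as drawn in a
#' two-set Venn diagram.
#'
#' @param a,b `substrate_set` objects (or character vectors of accessions).
#' @return List with counts `a_only`, `shared`, `b_only` and the
#'   corresponding member vectors `a_only_members`, `shared_members`,
#'   `b_only_members`.
#' @export
#' @examples
#' overlap_sets(c("a", "b", "c"), c("b", "c", "d"))[1:3]
overlap_sets <- function(a, b) {
  acc <- function(x) if (inherits(x, "substrate_set"))
    substrate_accessions(x) else as.character(x)
  a <- unique(acc(a)); b <- unique(acc(b))
  shared <- intersect(a, b)
  list(a_only = length(setdiff(a, b)),
       shared = length(shared),
       b_only = length(setdiff(b, a)),
       a_only_members = setdiff(a, b),
       shared_members = shared,
       b_only_members = setdiff(b, a))
}
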