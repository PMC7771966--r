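#' Curate the N-glycoproteome from annotation records
#'
#' Applies the curation rules that define the secretory-pathway
#' N-glycoproteome from a whole-proteome annotation set: keep proteins
#' with at least one annotated N-linked glycosite, remove proteins
#' predicted to be mitochondrial, remove proteins shorter than 50 amino
#' acids, and collapse redundant isoforms to one record per canonical
#' accession. Each filter is a pure predicate; deduplication is applied
#' last, keeping the canonical record when present, otherwise the longest
#' isoform (ties broken by lexicographic accession).
#'
#' @param records A [proteome_records()] tibble.
#' @param min_length Minimum retained length in residues (proteins with
#'   fewer are removed).
#' @return List with `records` (the retained [proteome_records()]) and
#'   `report`, a `curation_report` holding the stage counts `n_input`,
#'   `n_glycosylated`, `n_after_mito_filter`, `n_after_length_filter`,
#'   `n_after_isoform_dedup` and `fraction_of_proteome`
#'   (= retained / input).
#' @export
build_nglycoproteome <- function(records, min_length = 50L) {
  n_input <- nrow(records)

  glyco <- records[purrr::map_int(records$glyco_sites, length) >= 1L, ]
  n_glyco <- nrow(glyco)

  nonmito <- glyco[!glyco$is_mitochondrial, ]
  n_mito <- nrow(nonmito)

  longenough <- nonmito[nonmito$length >= min_length, ]
  n_len <- nrow(longenough)

  # one record per canonical accession: canonical > longest > lexicographic
  retained <- longenough |>
    dplyr::mutate(.row = dplyr::row_number()) |>
    dplyr::group_by(.data$canonical_accession) |>
    dplyr::arrange(.data$is_isoform, dplyr::desc(.data$length),
                   .data$accession, .by_group = TRUE) |>
    dplyr::slice(1) |>
    dplyr::ungroup() |>
    dplyr::arrange(.data$.row) |>
    dplyr::select(-".row")
  class(retained) <- class(longenough)

  report <- structure(list(
    n_input = n_input,
    n_glycosylated = n_glyco,
    n_after_mito_filter = n_mito,
    n_after_length_filter = n_len,
    n_after_isoform_dedup = nrow(retained),
    fraction_of_proteome = if (n_input > 0) nrow(retained) / n_input else
      NA_real_
  ), class = "curation_report")

  list(records = retained, report = report)
}

#' @export
print.curation_report <- function(x, ...) {
  cat("<curation_report>\n",
      "  input proteins:       ", x$n_input, "\n",
      "  N-glycosylated:       ", x$n_glycosylated, "\n",
      "  after mito filter:    ", x$n_after_mito_filter, "\n",
      "  after length filter:  ", x$n_after_length_filter, "\n",
      "  after isoform dedup:  ", x$n_after_isoform_dedup, "\n",
      "  fraction of proteome: ",
      sprintf("%.1f%%", 100 * x$fraction_of_proteome), "\n", sep = "")
  invisible(x)
}

#' Fraction of the proteome that is N-glycosylated
#'
#' @param report A `curation_report` from [build_nglycoproteome()].
#' @return The retained fraction as a percentage.
#' @export
#' @examples
#' # 4361 retained of 20353 input -> 21.4%
proteome_fraction <- function(report) {
  stopifnot(inherits(report, "curation_report"))
  if (report$n_input == 0) {
    stop("proteome fraction undefined for an empty input", call. = FALSE)
  }
  100 * report$fraction_of_proteome
}
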