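#' TMT quantification table
#'
#' Container for a protein-level isobaric-label (TMT) quantification
#' experiment: one row per protein with reporter-channel intensities, plus a
#' design that maps every channel to a bait condition (`CRT_WT` or
#' `CRT_Y109A`), a replicate number and a genotype label.
#'
#' @param quant Tibble/data frame with an `accession` column, an optional
#'   `gene` column, and one numeric column per reporter channel.
#' @param design Tibble/data frame with columns `channel`, `condition`
#'   (`"CRT_WT"` or `"CRT_Y109A"`), `replicate` (integer >= 1) and
#'   `genotype` (free-text label, e.g. `"ALG6-KO"`).
#'
#' @details Invariants enforced at construction: every channel in `design`
#'   is a column of `quant`; each replicate carries exactly one `CRT_WT` and
#'   one `CRT_Y109A` channel; all intensities are non-negative (zeros are
#'   retained here -- how to treat a zero control intensity is a
#'   substrate-calling policy, see [compute_fold_change()]).
#'
#' @return An object of class `tmt_table`: a list with elements `quant` and
#'   `design`.
#' @seealso [read_quant_table()], [generate_tmt_experiment()]
#' @export
#' @examples
#' quant <- tibble::tibble(accession = c("P1", "P2"),
#'                         `126` = c(9, 5), `127` = c(3, 5))
#' design <- tibble::tibble(channel = c("126", "127"),
#'                          condition = c("CRT_WT", "CRT_Y109A"),
#'                          replicate = 1L, genotype = "ALG6-KO")
#' tmt_table(quant, design)
tmt_table <- function(quant, design) {
  quant <- tibble::as_tibble(quant)
  design <- tibble::as_tibble(design)

  if (!"accession" %in% names(quant)) {
    stop("quant table must have an 'accession' column", call. = FALSE)
  }
  needed <- c("channel", "condition", "replicate", "genotype")
  missing_cols <- setdiff(needed, names(design))
  if (length(missing_cols) > 0) {
    stop("design is missing column(s): ", paste(missing_cols, collapse = ", "),
         call. = FALSE)
  }
  design$channel <- as.character(design$channel)
  design$replicate <- as.integer(design$replicate)
  bad_cond <- setdiff(unique(design$condition), c("CRT_WT", "CRT_Y109A"))
  if (length(bad_cond) > 0) {
    stop("unknown condition(s) in design: ", paste(bad_cond, collapse = ", "),
         call. = FALSE)
  }

  absent <- setdiff(design$channel, names(quant))
  if (length(absent) > 0) {
    stop("design channel(s) absent from quant table: ",
         paste(absent, collapse = ", "), call. = FALSE)
  }

  # each replicate must pair one bait channel with one control channel
  pair_ok <- design |>
    dplyr::count(.data$genotype, .data$replicate, .data$condition) |>
    tidyr::pivot_wider(names_from = "condition", values_from = "n",
                       values_fill = 0L)
  if (!all(c("CRT_WT", "CRT_Y109A") %in% names(pair_ok)) ||
      any(pair_ok$CRT_WT != 1L) || any(pair_ok$CRT_Y109A != 1L)) {
    stop("each replicate needs exactly one CRT_WT and one CRT_Y109A channel",
         call. = FALSE)
  }

  for (ch in design$channel) {
    v <- quant[[ch]]
    if (!is.numeric(v)) {
      stop("channel column '", ch, "' is not numeric", call. = FALSE)
    }
    if (any(v < 0, na.rm = TRUE)) {
      stop("negative intensity in channel '", ch, "'", call. = FALSE)
    }
  }

  structure(list(quant = quant, design = design), class = "tmt_table")
}

#' @export
print.tmt_table <- function(x, ...) {
  cat("<tmt_table> ", nrow(x$quant), " proteins, ",
      nrow(x$design), " channels (",
      max(x$design$replicate), " replicate(s); genotype ",
      paste(unique(x$design$genotype), collapse = "/"), ")\n", sep = "")
  print(x$quant, n = 5)
  invisible(x)
}

#' Channels of a TMT design for one condition
#'
#' @param design Design tibble of a [tmt_table()].
#' @param condition `"CRT_WT"` or `"CRT_Y109A"`.
#' @return Tibble with columns `channel`, `replicate`, `genotype`, ordered by
#'   replicate.
#' @keywords internal
design_channels <- function(design, condition) {
  design |>
    dplyr::filter(.data$condition == !!condition) |>
    dplyr::arrange(.data$replicate) |>
    dplyr::select("channel", "replicate", "genotype")
}

#' Read a protein-level TMT quantification table
#'
#' Reads a delimited text export (tab- or comma-separated, header required)
#' of protein-level reporter intensities and binds it to an experimental
#' design. Rows whose designated channel values are non-numeric or negative
#' are rejected and reported, not silently dropped.
#'
#' @param path Path to the delimited quantification table. Must contain an
#'   `accession` column and one numeric column per design channel.
#' @param design Either a design tibble (see [tmt_table()]) or a path to a
#'   tab-separated design file with columns `channel`, `condition`,
#'   `replicate`, `genotype`.
#' @param delim Field delimiter; `"\t"` (default) or `","`.
#'
#' @return A [tmt_table()] object. Rejected rows (if any) are attached as a
#'   tibble in `attr(x, "rejected")` with columns `row`, `accession`,
#'   `reason`.
#' @export
read_quant_table <- function(path, design, delim = "\t") {
  raw <- readr::read_delim(path, delim = delim, col_types = readr::cols(),
                           progress = FALSE, show_col_types = FALSE)
  if (!"accession" %in% names(raw)) {
    stop("quantification table has no 'accession' column: ", path,
         call. = FALSE)
  }
  if (is.character(design) && length(design) == 1) {
    design <- read_design(design)
  }
  design <- tibble::as_tibble(design)
  design$channel <- as.character(design$channel)
  absent <- setdiff(design$channel, names(raw))
  if (length(absent) > 0) {
    stop("design channel(s) not found in table header: ",
         paste(absent, collapse = ", "), call. = FALSE)
  }

  # coerce channel columns; non-numeric entries become NA and reject the row
  chans <- design$channel
  numeric_chans <- raw
  for (ch in chans) {
    numeric_chans[[ch]] <- suppressWarnings(as.numeric(raw[[ch]]))
  }
  bad_nonnum <- rowSums(vapply(chans, function(ch) is.na(numeric_chans[[ch]]) &
                                 !is.na(raw[[ch]]), logical(nrow(raw)))) > 0
  bad_neg <- rowSums(vapply(chans, function(ch) {
    v <- numeric_chans[[ch]]
    !is.na(v) & v < 0
  }, logical(nrow(raw)))) > 0

  reject <- bad_nonnum | bad_neg
  rejected <- tibble::tibble(
    row = which(reject),
    accession = as.character(numeric_chans$accession[reject]),
    reason = ifelse(bad_nonnum[reject], "non-numeric intensity",
                    "negative intensity")
  )

  kept <- numeric_chans[!reject, , drop = FALSE]
  keep_cols <- c("accession", intersect("gene", names(kept)), chans)
  tab <- tmt_table(kept[, keep_cols, drop = FALSE], design)
  attr(tab, "rejected") <- rejected
  tab
}

#' Read a TMT design file
#'
#' @param path Tab-separated file with header columns `channel`,
#'   `condition`, `replicate`, `genotype`.
#' @return A design tibble.
#' @export
read_design <- function(path) {
  d <- readr::read_tsv(path, col_types = "ccic", progress = FALSE,
                       show_col_types = FALSE)
  needed <- c("channel", "condition", "replicate", "genotype")
  if (!all(needed %in% names(d))) {
    stop("design file must have columns ", paste(needed, collapse = ", "),
         call. = FALSE)
  }
  d
}

#' Write a TMT quantification table (and optionally its design) as TSV
#'
#' @param table A [tmt_table()].
#' @param path Output path for the quantification TSV.
#' @param design_path Optional output path for the design TSV.
#' @return `table`, invisibly.
#' @export
write_quant_table <- function(table, path, design_path = NULL) {
  stopifnot(inherits(table, "tmt_table"))
  readr::write_tsv(table$quant, path, progress = FALSE)
  if (!is.null(design_path)) {
    readr::write_tsv(table$design, design_path, progress = FALSE)
  }
  invisible(table)
}
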