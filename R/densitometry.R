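#' Percent reglucosylation from immunoblot densitometry
#'
#' Implements the pull-down quantification: the signal bound by the
#' lectin-dead control (Y109A) is subtracted from the signal bound by
#' wild-type GST-CRT, divided by the total substrate present in the lysate
#' fed to each pull-down, and expressed as a percentage. The lysate total
#' is reconstructed from the whole-cell-lysate (WCL) lane: with the default
#' design (10% of the lysate loaded as WCL, the remainder split between two
#' pull-downs) the divisor is `WCL x 5`, i.e.
#' `100 * (WT - Y109A) / (5 * WCL)`. The dilution factor is derived from
#' `wcl_fraction` and `n_pulldowns` rather than hard-coded so other split
#' designs are expressible. A negative difference (control above bait) is
#' returned as-is; clamping is the caller's decision.
#'
#' @param q A data frame of blot lanes with columns `wcl`, `wt_pulldown`,
#'   `y109a_pulldown` and optional `wcl_fraction` (default 0.10) and
#'   `n_pulldowns` (default 2), e.g. from [generate_blot_quants()] or
#'   [read_blot_quants()]; or a named list with those fields.
#' @return Numeric vector of percentages.
#' @export
#' @examples
#' percent_reglucosylation(list(wcl = 40, wt_pulldown = 30,
#'                              y109a_pulldown = 10))  # 10
percent_reglucosylation <- function(q) {
  q <- tibble::as_tibble(q)
  if (!all(c("wcl", "wt_pulldown", "y109a_pulldown") %in% names(q))) {
    stop("need columns wcl, wt_pulldown, y109a_pulldown", call. = FALSE)
  }
  wcl_fraction <- if ("wcl_fraction" %in% names(q)) q$wcl_fraction else 0.10
  n_pulldowns <- if ("n_pulldowns" %in% names(q)) q$n_pulldowns else 2L
  if (any(q$wcl <= 0)) {
    stop("percent reglucosylation undefined for wcl <= 0", call. = FALSE)
  }
  if (any(wcl_fraction <= 0) || any(n_pulldowns < 1)) {
    stop("wcl_fraction must be > 0 and n_pulldowns >= 1", call. = FALSE)
  }
  per_pulldown_total <- q$wcl / wcl_fraction / n_pulldowns
  100 * (q$wt_pulldown - q$y109a_pulldown) / per_pulldown_total
}

#' Percent mature protein from a pulse-chase lane
#'
#' @param mature Densitometry of the mature (processed) band; or a data
#'   frame / list with columns `mature` and `pro`.
#' @param pro Densitometry of the unprocessed pro-form band.
#' @return `100 * mature / (mature + pro)` as a numeric vector.
#' @export
#' @examples
#' percent_mature(59, 41)  # 59
percent_mature <- function(mature, pro = NULL) {
  if (is.null(pro)) {
    q <- tibble::as_tibble(mature)
    mature <- q$mature
    pro <- q$pro
  }
  if (any(mature < 0) || any(pro < 0)) {
    stop("band densities must be non-negative", call. = FALSE)
  }
  if (any(mature + pro == 0)) {
    stop("percent mature undefined when total signal is zero", call. = FALSE)
  }
  100 * mature / (mature + pro)
}

#' Read densitometry lane values
#'
#' @param path Tab-separated file with header columns `protein`,
#'   `genotype`, `wcl`, `wt_pulldown`, `y109a_pulldown` and optional
#'   `wcl_fraction`, `n_pulldowns`.
#' @return Tibble of lanes.
#' @export
read_blot_quants <- function(path) {
  q <- readr::read_tsv(path, col_types = readr::cols(), progress = FALSE,
                       show_col_types = FALSE)
  needed <- c("protein", "genotype", "wcl", "wt_pulldown", "y109a_pulldown")
  if (!all(needed %in% names(q))) {
    stop("blot file must have columns ", paste(needed, collapse = ", "),
         call. = FALSE)
  }
  if (any(q$wcl < 0 | q$wt_pulldown < 0 | q$y109a_pulldown < 0)) {
    stop("lane values must be non-negative", call. = FALSE)
  }
  q
}
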