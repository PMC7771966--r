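#' Five-number distribution summary of one group
#'
#' Median and quartiles use the linear-interpolation convention
#' (`stats::quantile` type 7), exact for odd and even n; this matches the
#' box-and-whisker summaries used to compare substrate sets against the
#' N-glycoproteome.
#'
#' @param values Non-empty numeric vector (`NA`s dropped with a warning).
#' @param label Group label.
#' @return One-row tibble with `group_label`, `n`, `median`, `q1`, `q3`,
#'   `min`, `max`.
#' @export
#' @examples
#' summarize_group(c(1, 2, 3, 4), "demo")$median  # 2.5
summarize_group <- function(values, label = "group") {
  if (anyNA(values)) {
    warning("dropping NA values in group '", label, "'", call. = FALSE)
    values <- values[!is.na(values)]
  }
  if (length(values) == 0) {
    stop("summarize_group needs at least one value", call. = FALSE)
  }
  q <- stats::quantile(values, c(0.25, 0.5, 0.75), type = 7, names = FALSE)
  tibble::tibble(group_label = label, n = length(values), median = q[2],
                 q1 = q[1], q3 = q[3], min = min(values), max = max(values))
}

#' Two-group distribution comparison
#'
#' Default method is the two-sided Mann-Whitney U test with normal
#' approximation and tie correction, suited to the skewed counts and
#' lengths being compared; Welch's t and Kolmogorov-Smirnov are available
#' as alternatives. Direction reports which group has the larger median.
#'
#' @param a,b Numeric vectors with at least two values each.
#' @param method `"wilcox"` (default), `"t"` or `"ks"`.
#' @return List with `statistic`, `p_value`, `direction` (`"a>b"`,
#'   `"b>a"` or `"none"`), `method`.
#' @export
compare_groups <- function(a, b, method = c("wilcox", "t", "ks")) {
  method <- match.arg(method)
  a <- a[!is.na(a)]; b <- b[!is.na(b)]
  if (length(a) < 2 || length(b) < 2) {
    stop("compare_groups needs at least two values per group", call. = FALSE)
  }
  if (length(unique(c(a, b))) == 1) {
    warning("all values tied across both groups; p = 1", call. = FALSE)
    return(list(statistic = NA_real_, p_value = 1,
                direction = "none", method = method))
  }
  res <- switch(method,
    wilcox = suppressWarnings(
      stats::wilcox.test(a, b, exact = FALSE, correct = FALSE)),
    t = stats::t.test(a, b),
    ks = suppressWarnings(stats::ks.test(a, b)))
  md <- stats::median(a) - stats::median(b)
  list(statistic = unname(res$statistic),
       p_value = res$p.value,
       direction = if (md > 0) "a>b" else if (md < 0) "b>a" else "none",
       method = method)
}

#' Localization distribution of a profile set
#'
#' @param profiles A [feature_profiles()] tibble (or any data frame with a
#'   `localization` column).
#' @return Named numeric vector of percentages over
#'   [localization_classes()]; sums to 100.
#' @export
localization_distribution <- function(profiles) {
  if (nrow(profiles) == 0) {
    stop("localization_distribution needs a non-empty profile set",
         call. = FALSE)
  }
  classes <- localization_classes()
  counts <- table(factor(profiles$localization, levels = classes))
  stats::setNames(100 * as.numeric(counts) / nrow(profiles), classes)
}

#' Feature summary report across groups
#'
#' Summarizes each numeric feature per group and compares every substrate
#' group against the reference group (typically the curated
#' N-glycoproteome).
#'
#' @param profile_groups Named list of [feature_profiles()] tibbles; the
#'   first element is the reference.
#' @param features Feature columns to summarize.
#' @param method Test passed to [compare_groups()].
#' @return List with `summaries` (tibble of group summaries per feature)
#'   and `comparisons` (tibble of test results vs the reference).
#' @export
feature_report <- function(profile_groups,
                           features = c("length", "n_glycans", "n_cys",
                                        "pI", "luminal_residues"),
                           method = "wilcox") {
  stopifnot(length(profile_groups) >= 1, !is.null(names(profile_groups)))
  summaries <- purrr::map_dfr(features, function(f) {
    purrr::imap_dfr(profile_groups, function(p, lab) {
      v <- p[[f]]
      v <- v[!is.na(v)]
      if (length(v) == 0) return(NULL)
      dplyr::mutate(summarize_group(v, lab), feature = f, .before = 1)
    })
  })
  ref_lab <- names(profile_groups)[1]
  comparisons <- NULL
  if (length(profile_groups) > 1) {
    comparisons <- purrr::map_dfr(features, function(f) {
      purrr::map_dfr(names(profile_groups)[-1], function(lab) {
        a <- profile_groups[[lab]][[f]]
        b <- profile_groups[[ref_lab]][[f]]
        a <- a[!is.na(a)]; b <- b[!is.na(b)]
        if (length(a) < 2 || length(b) < 2) return(NULL)
        res <- compare_groups(a, b, method = method)
        tibble::tibble(feature = f, group = lab, reference = ref_lab,
                       statistic = res$statistic, p_value = res$p_value,
                       direction = res$direction)
      })
    })
  }
  list(summaries = summaries, comparisons = comparisons)
}

#' Scatter-plus-box plot of one feature across groups
#'
#' Renders the figure style used for substrate-versus-proteome feature
#' comparisons: jittered points overlaid with a box-and-whisker summary.
#' Requires ggplot2.
#'
#' @param profile_groups Named list of [feature_profiles()] tibbles.
#' @param feature Feature column to plot.
#' @param log_scale Use a log10 y axis (sensible for lengths and counts).
#' @return A ggplot object.
#' @export
plot_feature_distribution <- function(profile_groups, feature = "length",
                                      log_scale = TRUE) {
  if (!requireNamespace("ggplot2", quietly = TRUE)) {
    stop("plot_feature_distribution requires ggplot2", call. = FALSE)
  }
  df <- purrr::imap_dfr(profile_groups, function(p, lab) {
    tibble::tibble(group = lab, value = p[[feature]])
  }) |> dplyr::filter(!is.na(.data$value))
  gg <- ggplot2::ggplot(df, ggplot2::aes(x = .data$group, y = .data$value)) +
    ggplot2::geom_jitter(width = 0.25, alpha = 0.3, size = 0.6) +
    ggplot2::geom_boxplot(outlier.shape = NA, fill = NA, width = 0.5) +
    ggplot2::labs(x = NULL, y = feature) +
    ggplot2::theme_classic()
  if (log_scale) gg <- gg + ggplot2::scale_y_log10()
  gg
}

#' Enrichment scatter of shared substrates between two knockout lines
#'
#' Plots the per-protein log10 enrichment index, colored by localization
#' and shaped by soluble/transmembrane topology, mirroring the
#' paralog-preference scatter. Requires ggplot2.
#'
#' @param enrichment Result of [enrichment_index()].
#' @param profiles Optional [feature_profiles()] to supply localization
#'   and topology.
#' @return A ggplot object.
#' @export
plot_enrichment <- function(enrichment, profiles = NULL) {
  if (!requireNamespace("ggplot2", quietly = TRUE)) {
    stop("plot_enrichment requires ggplot2", call. = FALSE)
  }
  df <- enrichment
  if (!is.null(profiles)) {
    df <- dplyr::left_join(df, profiles[, c("accession", "localization",
                                            "topology")], by = "accession")
    df$topology_group <- ifelse(df$topology == "SOLUBLE", "SOLUBLE",
                                "TRANSMEMBRANE")
  } else {
    df$localization <- "unknown"
    df$topology_group <- "unknown"
  }
  df <- dplyr::arrange(df, .data$log10_ratio)
  df$rank <- seq_len(nrow(df))
  ggplot2::ggplot(df, ggplot2::aes(x = .data$rank, y = .data$log10_ratio,
                                   color = .data$localization,
                                   shape = .data$topology_group)) +
    ggplot2::geom_point() +
    ggplot2::geom_hline(yintercept = 0, linetype = "dashed") +
    ggplot2::labs(x = "substrate rank", y = "log10 enrichment") +
    ggplot2::theme_classic()
}
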