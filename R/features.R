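#' pKa table for theoretical isoelectric-point calculation
#'
#' Returns the dissociation constants used by [theoretical_pi()]. The
#' default set follows the Bjellqvist-style constants popularized by the
#' ExPASy pI/MW tool: acidic groups (C-terminus, Asp, Glu, Cys, Tyr) and
#' basic groups (N-terminus, His, Lys, Arg). Residue-specific N-terminal
#' refinements are deliberately not applied; supply your own table to
#' change any constant.
#'
#' @param Cterm,D,E,C,Y Acidic-group pKa values (pH units).
#' @param Nterm,H,K,R Basic-group pKa values (pH units).
#' @return Named list with numeric vectors `acidic` and `basic`.
#' @export
#' @examples
#' pka_table()
pka_table <- function(Cterm = 3.55, D = 4.05, E = 4.45, C = 9.0, Y = 10.0,
                      Nterm = 7.5, H = 5.98, K = 10.0, R = 12.0) {
  vals <- c(Cterm, D, E, C, Y, Nterm, H, K, R)
  if (any(vals <= 0 | vals >= 14)) {
    stop("all pKa values must lie in (0, 14)", call. = FALSE)
  }
  list(acidic = c(Cterm = Cterm, D = D, E = E, C = C, Y = Y),
       basic = c(Nterm = Nterm, H = H, K = K, R = R))
}

ionizable_counts <- function(sequence) {
  aa <- strsplit(toupper(sequence), "")[[1]]
  tab <- table(aa)
  count <- function(x) if (x %in% names(tab)) as.integer(tab[[x]]) else 0L
  list(acidic = c(Cterm = 1L, D = count("D"), E = count("E"),
                  C = count("C"), Y = count("Y")),
       basic = c(Nterm = 1L, H = count("H"), K = count("K"),
                 R = count("R")))
}

#' Henderson-Hasselbalch net charge of a sequence at given pH values
#'
#' @param sequence Amino-acid string.
#' @param pH Numeric vector of pH values.
#' @param pka A [pka_table()].
#' @return Numeric vector of net charges; strictly decreasing in pH.
#' @export
net_charge <- function(sequence, pH, pka = pka_table()) {
  n <- ionizable_counts(sequence)
  z <- numeric(length(pH))
  for (g in names(pka$basic)) {
    z <- z + n$basic[[g]] / (1 + 10^(pH - pka$basic[[g]]))
  }
  for (g in names(pka$acidic)) {
    z <- z - n$acidic[[g]] / (1 + 10^(pka$acidic[[g]] - pH))
  }
  z
}

#' Theoretical isoelectric point by bisection
#'
#' Finds the pH at which the Henderson-Hasselbalch net charge of the
#' sequence crosses zero. The charge function is strictly decreasing in pH,
#' so the root is unique; bisection on \[0, 14\] converges to within `tol`.
#'
#' @param sequence Amino-acid string (or vector of strings).
#' @param pka A [pka_table()].
#' @param tol Half-width of the final bracket, in pH units.
#' @param mature If `TRUE` and `signal` is given, strip the signal peptide
#'   before computing (the default computes on the full submitted
#'   sequence, as the ExPASy tool does).
#' @param signal Optional integer vector `c(start, end)` of the signal
#'   peptide, used only when `mature = TRUE`.
#' @return Isoelectric point(s) in pH units.
#' @export
#' @examples
#' theoretical_pi("GG")  # (pKa_Nterm + pKa_Cterm) / 2 = 5.525
theoretical_pi <- function(sequence, pka = pka_table(), tol = 1e-3,
                           mature = FALSE, signal = NULL) {
  if (length(sequence) > 1) {
    return(vapply(sequence, theoretical_pi, numeric(1), pka = pka,
                  tol = tol, USE.NAMES = FALSE))
  }
  if (is.na(sequence) || !nzchar(sequence)) {
    stop("theoretical_pi needs a non-empty sequence", call. = FALSE)
  }
  if (mature && !is.null(signal) && !any(is.na(signal))) {
    sequence <- substring(sequence, signal[2] + 1)
    if (!nzchar(sequence)) {
      stop("mature sequence is empty after removing the signal peptide",
           call. = FALSE)
    }
  }
  lo <- 0; hi <- 14
  while (hi - lo > tol) {
    mid <- (lo + hi) / 2
    if (net_charge(sequence, mid, pka) > 0) lo <- mid else hi <- mid
  }
  (lo + hi) / 2
}

#' Count N-glycans of a protein
#'
#' @param record One row of a [proteome_records()] tibble (or the tibble
#'   itself, in which case a vector is returned).
#' @param mode `"annotated"` counts annotated N-linked glycosites;
#'   `"sequon_scan"` scans the sequence for the acceptor motif
#'   Asn-Xxx-Ser/Thr/Cys with Xxx != Pro.
#' @return Integer count(s).
#' @export
count_nglycans <- function(record, mode = c("annotated", "sequon_scan")) {
  mode <- match.arg(mode)
  if (mode == "annotated") {
    return(purrr::map_int(record$glyco_sites, length))
  }
  vapply(record$sequence, function(sq) {
    if (is.na(sq)) {
      stop("sequon_scan mode needs a sequence", call. = FALSE)
    }
    count_sequons(sq)
  }, integer(1), USE.NAMES = FALSE)
}

#' Count N-glycosylation sequons in a sequence
#'
#' The acceptor motif is Asn-Xxx-Ser/Thr/Cys where Xxx is not Pro;
#' overlapping matches are all counted.
#'
#' @param sequence Amino-acid string.
#' @return Integer count.
#' @export
#' @examples
#' count_sequons("NGS")  # 1
#' count_sequons("NPS")  # 0
count_sequons <- function(sequence) {
  aa <- strsplit(toupper(sequence), "")[[1]]
  n <- length(aa)
  if (n < 3) return(0L)
  i <- seq_len(n - 2)
  sum(aa[i] == "N" & aa[i + 1] != "P" & aa[i + 2] %in% c("S", "T", "C"))
}

#' Count cysteine residues
#'
#' @param record One or more rows of a [proteome_records()] tibble.
#' @return Integer count(s) of `C` characters in the sequence.
#' @export
count_cys <- function(record) {
  vapply(record$sequence, function(sq) {
    if (is.na(sq) || !nzchar(sq)) {
      stop("count_cys needs a non-empty sequence", call. = FALSE)
    }
    sum(strsplit(toupper(sq), "")[[1]] == "C")
  }, integer(1), USE.NAMES = FALSE)
}

#' Classify membrane topology from annotation
#'
#' Rules: no transmembrane segment gives `SOLUBLE`; two or more give
#' `MULTIPASS`; exactly one is oriented by the topological domains flanking
#' it -- a luminal/extracellular domain before the segment (or a
#' cytoplasmic one after) gives `TYPE_I`, the reverse gives `TYPE_II`; a
#' membrane protein with no usable domain sides is `UNDEFINED`. Orientation
#' is decided by domain order relative to the segment rather than by
#' N-terminus keywords so that records with partial domain annotation still
#' classify.
#'
#' @param record One or more rows of a [proteome_records()] tibble.
#' @return Character vector with values `"SOLUBLE"`, `"TYPE_I"`,
#'   `"TYPE_II"`, `"MULTIPASS"`, `"UNDEFINED"`.
#' @export
classify_topology <- function(record) {
  purrr::map2_chr(record$tm_segments, record$topo_domains, function(tm, td) {
    n_tm <- nrow(tm)
    if (n_tm == 0) return("SOLUBLE")
    if (n_tm >= 2) return("MULTIPASS")
    usable <- td[!is.na(td$side), , drop = FALSE]
    if (nrow(usable) == 0) return("UNDEFINED")
    before <- usable[usable$end < tm$start[1], , drop = FALSE]
    after <- usable[usable$start > tm$end[1], , drop = FALSE]
    type1 <- any(before$side == "LUMENAL_EXTRACELLULAR") ||
      any(after$side == "CYTOPLASMIC")
    type2 <- any(before$side == "CYTOPLASMIC") ||
      any(after$side == "LUMENAL_EXTRACELLULAR")
    if (type1 && !type2) return("TYPE_I")
    if (type2 && !type1) return("TYPE_II")
    "UNDEFINED"
  })
}

#' Luminally exposed residues of a protein
#'
#' For membrane proteins, the total number of residues in
#' luminal/extracellular topological domains; for soluble secretory
#' proteins, the whole mature chain (annotated length minus the signal
#' peptide); "Extracellular" counts as luminal because plasma-membrane
#' ectodomains transited the ER lumen, the compartment of interest.
#' Membrane proteins with undefined topology return `NA` so they can be
#' excluded from distributions rather than contributing a fabricated zero.
#'
#' @param record One or more rows of a [proteome_records()] tibble.
#' @param topology Optional precomputed [classify_topology()] result.
#' @return Integer vector (`NA` for `UNDEFINED` topology).
#' @export
luminal_exposure <- function(record, topology = classify_topology(record)) {
  out <- integer(nrow(record))
  for (i in seq_len(nrow(record))) {
    topo <- topology[i]
    if (topo == "UNDEFINED") {
      out[i] <- NA_integer_
    } else if (topo == "SOLUBLE") {
      sp_len <- if (is.na(record$signal_start[i])) 0L else
        record$signal_end[i] - record$signal_start[i] + 1L
      out[i] <- record$length[i] - sp_len
    } else {
      td <- record$topo_domains[[i]]
      lum <- td[!is.na(td$side) & td$side == "LUMENAL_EXTRACELLULAR", ,
                drop = FALSE]
      out[i] <- as.integer(sum(lum$end - lum$start + 1L))
    }
  }
  out
}

#' Localization keyword map
#'
#' Reads the keyword-to-class map used by [classify_localization()]. The
#' map ships as a plain TSV config (`localization_keywords.tsv` under the
#' package's `extdata`) so curation changes do not require code changes.
#'
#' @param path Optional path to an alternative map (columns `class`,
#'   `keyword`; keywords are matched case-insensitively as substrings).
#' @return Tibble with columns `class` and `keyword`.
#' @export
localization_keywords <- function(path = NULL) {
  if (is.null(path)) {
    path <- system.file("extdata", "localization_keywords.tsv",
                        package = "uggtquant", mustWork = TRUE)
  }
  readr::read_tsv(path, col_types = "cc", progress = FALSE,
                  show_col_types = FALSE)
}

#' Classify subcellular localization from annotation terms
#'
#' Terms are matched case-insensitively against a keyword map covering six
#' compartment classes (plasma membrane, secreted, ER, Golgi, lysosome,
#' nuclear membrane). A protein matching two or more distinct compartments
#' is `MULTIPLE` (e.g. receptors that traffic between the Golgi, lysosome
#' and cell surface); a protein matching none is `OTHER`.
#'
#' @param record One or more rows of a [proteome_records()] tibble, or a
#'   list of character vectors of terms.
#' @param keywords Keyword map from [localization_keywords()].
#' @return Character vector over
#'   `PLASMA_MEMBRANE, SECRETED, ER, GOLGI, LYSOSOME, NUCLEAR_MEMBRANE,
#'   MULTIPLE, OTHER`.
#' @export
classify_localization <- function(record, keywords = localization_keywords()) {
  terms_list <- if (is.data.frame(record)) record$localization_terms else record
  vapply(terms_list, function(terms) {
    if (length(terms) == 0) return("OTHER")
    blob <- tolower(paste(terms, collapse = " ; "))
    hit <- unique(keywords$class[vapply(
      tolower(keywords$keyword),
      function(k) grepl(k, blob, fixed = TRUE), logical(1))])
    if (length(hit) == 0) return("OTHER")
    if (length(hit) >= 2) return("MULTIPLE")
    hit
  }, character(1))
}

#' Localization classes recognized by the pipeline
#' @return Character vector of the eight class labels.
#' @export
localization_classes <- function() {
  c("PLASMA_MEMBRANE", "SECRETED", "ER", "GOLGI", "LYSOSOME",
    "NUCLEAR_MEMBRANE", "MULTIPLE", "OTHER")
}

#' Per-protein feature profiles
#'
#' Computes the characteristics used to compare substrate sets against the
#' N-glycoproteome: length, N-glycan count, Cys count, theoretical pI,
#' membrane topology, localization class, and luminally exposed residues.
#'
#' @param records A [proteome_records()] tibble.
#' @param pka A [pka_table()] for the pI calculation.
#' @param glycan_mode Passed to [count_nglycans()].
#' @param pi_mature If `TRUE`, compute pI on the mature chain (signal
#'   peptide removed); default uses the full annotated sequence.
#' @param keywords Localization keyword map.
#' @return Tibble with columns `accession`, `length`, `n_glycans`, `n_cys`,
#'   `pI`, `topology`, `localization`, `luminal_residues`. `n_cys` and `pI`
#'   are `NA` for records without a sequence.
#' @export
feature_profiles <- function(records, pka = pka_table(),
                             glycan_mode = "annotated", pi_mature = FALSE,
                             keywords = localization_keywords()) {
  topo <- classify_topology(records)
  has_seq <- !is.na(records$sequence)
  n_cys <- rep(NA_integer_, nrow(records))
  pI <- rep(NA_real_, nrow(records))
  if (any(has_seq)) {
    n_cys[has_seq] <- count_cys(records[has_seq, ])
    pI[has_seq] <- vapply(which(has_seq), function(i) {
      theoretical_pi(records$sequence[i], pka = pka, mature = pi_mature,
                     signal = c(records$signal_start[i],
                                records$signal_end[i]))
    }, numeric(1))
  }
  tibble::tibble(
    accession = records$accession,
    length = records$length,
    n_glycans = count_nglycans(records, mode = glycan_mode),
    n_cys = n_cys,
    pI = pI,
    topology = topo,
    localization = classify_localization(records, keywords),
    luminal_residues = luminal_exposure(records, topo)
  )
}
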