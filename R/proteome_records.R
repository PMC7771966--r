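#' Proteome annotation records
#'
#' A `proteome_records` object is a tibble with one row per protein and the
#' annotation fields the pipeline consumes, following UniProtKB conventions
#' (all coordinates 1-based, spans inclusive):
#'
#' * `accession`, `name` -- identifiers; isoform accessions carry a `-n`
#'   suffix and share `canonical_accession` with their parent.
#' * `length` -- sequence length in residues.
#' * `sequence` -- amino-acid string or `NA`; when present its number of
#'   characters equals `length`.
#' * `glyco_sites` -- list column of integer positions annotated as
#'   N-linked glycosylation sites.
#' * `tm_segments` -- list column of tibbles `start`, `end` (transmembrane
#'   helices).
#' * `topo_domains` -- list column of tibbles `start`, `end`, `side`, where
#'   `side` is `"LUMENAL_EXTRACELLULAR"`, `"CYTOPLASMIC"`, or `NA` for an
#'   annotation whose description could not be mapped.
#' * `signal_start`, `signal_end` -- signal peptide span or `NA`.
#' * `localization_terms` -- list column of character vectors of
#'   subcellular-location terms.
#' * `is_mitochondrial`, `is_isoform`, `canonical_accession` -- curation
#'   flags.
#'
#' @param x A data frame with the columns above (missing flag columns are
#'   derived: mitochondrial from localization terms containing
#'   "mitochondri", isoform/canonical from a `-` in the accession).
#' @return A validated `proteome_records` tibble.
#' @export
proteome_records <- function(x) {
  x <- tibble::as_tibble(x)
  if (!all(c("accession", "length") %in% names(x))) {
    stop("records need at least 'accession' and 'length' columns",
         call. = FALSE)
  }
  n <- nrow(x)
  if (!"name" %in% names(x)) x$name <- x$accession
  if (!"sequence" %in% names(x)) x$sequence <- NA_character_
  if (!"glyco_sites" %in% names(x)) x$glyco_sites <- rep(list(integer()), n)
  if (!"tm_segments" %in% names(x)) x$tm_segments <- rep(list(empty_spans()), n)
  if (!"topo_domains" %in% names(x)) x$topo_domains <- rep(list(empty_domains()), n)
  if (!"signal_start" %in% names(x)) x$signal_start <- NA_integer_
  if (!"signal_end" %in% names(x)) x$signal_end <- NA_integer_
  if (!"localization_terms" %in% names(x)) {
    x$localization_terms <- rep(list(character()), n)
  }
  if (!"is_mitochondrial" %in% names(x)) {
    x$is_mitochondrial <- purrr::map_lgl(
      x$localization_terms,
      function(tt) any(grepl("mitochondri", tt, ignore.case = TRUE))
    )
  }
  if (!"canonical_accession" %in% names(x)) {
    x$canonical_accession <- sub("-.*$", "", x$accession)
  }
  if (!"is_isoform" %in% names(x)) {
    x$is_isoform <- grepl("-", x$accession, fixed = TRUE)
  }
  x$length <- as.integer(x$length)
  x$signal_start <- as.integer(x$signal_start)
  x$signal_end <- as.integer(x$signal_end)

  validate_proteome_records(x)
  class(x) <- c("proteome_records", class(tibble::tibble()))
  x
}

empty_spans <- function() tibble::tibble(start = integer(), end = integer())
empty_domains <- function() {
  tibble::tibble(start = integer(), end = integer(), side = character())
}

validate_proteome_records <- function(x) {
  check_spans <- function(acc, len, spans, what) {
    if (nrow(spans) == 0) return(invisible())
    ok <- spans$start >= 1 & spans$start <= spans$end & spans$end <= len
    if (!all(ok)) {
      stop("record ", acc, ": ", what, " span outside [1, ", len, "]",
           call. = FALSE)
    }
  }
  for (i in seq_len(nrow(x))) {
    acc <- x$accession[i]
    len <- x$length[i]
    if (is.na(len) || len < 1) {
      stop("record ", acc, ": invalid length", call. = FALSE)
    }
    gs <- x$glyco_sites[[i]]
    if (length(gs) > 0 && (any(gs < 1) || any(gs > len))) {
      stop("record ", acc, ": glycosite outside [1, ", len, "]",
           call. = FALSE)
    }
    check_spans(acc, len, x$tm_segments[[i]], "TRANSMEM")
    check_spans(acc, len, x$topo_domains[[i]], "TOPO_DOM")
    if (!is.na(x$signal_start[i])) {
      if (x$signal_start[i] < 1 || x$signal_end[i] > len ||
          x$signal_start[i] > x$signal_end[i]) {
        stop("record ", acc, ": SIGNAL span outside [1, ", len, "]",
             call. = FALSE)
      }
    }
    sq <- x$sequence[i]
    if (!is.na(sq) && nchar(sq) != len) {
      stop("record ", acc, ": sequence length ", nchar(sq),
           " != annotated length ", len, call. = FALSE)
    }
  }
  invisible(x)
}

# ---- feature mini-grammar ("KEYWORD start..end; /note=\"...\"") ------------

#' Parse UniProt-style feature strings
#'
#' Parses the compact feature notation used by UniProtKB TSV exports:
#' `KEYWORD start..end; /note="description"` items separated by `"; "`,
#' where single-residue features may give just `start`.
#'
#' @param s Character scalar (may be `NA`/empty).
#' @param keyword Feature keyword, e.g. `"CARBOHYD"`.
#' @return Tibble with columns `start`, `end` (integers) and `note`
#'   (character, `NA` when absent).
#' @keywords internal
parse_feature_string <- function(s, keyword) {
  if (is.na(s) || !nzchar(s)) {
    return(tibble::tibble(start = integer(), end = integer(),
                          note = character()))
  }
  pat <- paste0(keyword,
                "\\s+(\\d+)(?:\\.\\.(\\d+))?",
                "(?:;\\s*/note=\"([^\"]*)\")?")
  m <- stringr::str_match_all(s, pat)[[1]]
  if (nrow(m) == 0) {
    return(tibble::tibble(start = integer(), end = integer(),
                          note = character()))
  }
  start <- as.integer(m[, 2])
  end <- ifelse(is.na(m[, 3]), start, as.integer(m[, 3]))
  tibble::tibble(start = start, end = as.integer(end), note = m[, 4])
}

topo_side_from_note <- function(note) {
  dplyr::case_when(
    grepl("extracellular|lumenal|luminal", note, ignore.case = TRUE) ~
      "LUMENAL_EXTRACELLULAR",
    grepl("cytoplasmic", note, ignore.case = TRUE) ~ "CYTOPLASMIC",
    TRUE ~ NA_character_
  )
}

glyco_sites_from_features <- function(feats) {
  as.integer(feats$start[!is.na(feats$note) &
                           grepl("N-linked", feats$note, fixed = TRUE)])
}

# ---- TSV dialect -----------------------------------------------------------

read_proteome_tsv <- function(path) {
  raw <- readr::read_tsv(path, col_types = readr::cols(.default = "c"),
                         progress = FALSE, show_col_types = FALSE)
  if (!all(c("accession", "length") %in% names(raw))) {
    stop("proteome TSV needs 'accession' and 'length' columns", call. = FALSE)
  }
  get <- function(col) if (col %in% names(raw)) raw[[col]] else
    rep(NA_character_, nrow(raw))

  glyco <- purrr::map(get("glycosylation"),
                      ~ glyco_sites_from_features(
                          parse_feature_string(.x, "CARBOHYD")))
  tms <- purrr::map(get("transmembrane"), function(s) {
    f <- parse_feature_string(s, "TRANSMEM")
    tibble::tibble(start = f$start, end = f$end)
  })
  topo <- purrr::map(get("topo_dom"), function(s) {
    f <- parse_feature_string(s, "TOPO_DOM")
    tibble::tibble(start = f$start, end = f$end,
                   side = topo_side_from_note(f$note))
  })
  sig <- purrr::map(get("signal_peptide"),
                    ~ parse_feature_string(.x, "SIGNAL"))
  loc <- purrr::map(get("subcellular_location"), function(s) {
    if (is.na(s) || !nzchar(s)) return(character())
    trimws(strsplit(s, ";", fixed = TRUE)[[1]])
  })

  proteome_records(tibble::tibble(
    accession = get("accession"),
    name = dplyr::coalesce(get("name"), get("accession")),
    length = as.integer(get("length")),
    sequence = dplyr::na_if(get("sequence"), ""),
    glyco_sites = glyco,
    tm_segments = tms,
    topo_domains = topo,
    signal_start = purrr::map_int(sig, ~ if (nrow(.x)) .x$start[1] else NA_integer_),
    signal_end = purrr::map_int(sig, ~ if (nrow(.x)) .x$end[1] else NA_integer_),
    localization_terms = loc
  ))
}

format_span <- function(start, end) {
  ifelse(start == end, as.character(start), paste0(start, "..", end))
}

glyco_feature_string <- function(sites) {
  if (length(sites) == 0) return(NA_character_)
  paste(sprintf('CARBOHYD %d; /note="N-linked (GlcNAc...) asparagine"',
                sites), collapse = "; ")
}

tm_feature_string <- function(spans) {
  if (nrow(spans) == 0) return(NA_character_)
  paste(sprintf('TRANSMEM %s; /note="Helical"',
                format_span(spans$start, spans$end)), collapse = "; ")
}

topo_feature_string <- function(doms) {
  if (nrow(doms) == 0) return(NA_character_)
  note <- dplyr::case_when(
    doms$side == "LUMENAL_EXTRACELLULAR" ~ "Extracellular",
    doms$side == "CYTOPLASMIC" ~ "Cytoplasmic",
    TRUE ~ "Unknown"
  )
  paste(sprintf('TOPO_DOM %s; /note="%s"',
                format_span(doms$start, doms$end), note), collapse = "; ")
}

#' Write proteome records as a UniProtKB-style TSV export
#'
#' @param records A [proteome_records()] tibble.
#' @param path Output path.
#' @return `records`, invisibly.
#' @export
write_proteome_records <- function(records, path) {
  out <- tibble::tibble(
    accession = records$accession,
    name = records$name,
    length = records$length,
    sequence = records$sequence,
    glycosylation = purrr::map_chr(records$glyco_sites, glyco_feature_string),
    transmembrane = purrr::map_chr(records$tm_segments, tm_feature_string),
    topo_dom = purrr::map_chr(records$topo_domains, topo_feature_string),
    signal_peptide = ifelse(
      is.na(records$signal_start), NA_character_,
      sprintf("SIGNAL %s",
              format_span(records$signal_start, records$signal_end))),
    subcellular_location = purrr::map_chr(
      records$localization_terms,
      ~ if (length(.x) == 0) NA_character_ else paste(.x, collapse = "; "))
  )
  # UniProtKB exports are unquoted tab-separated text; fields contain no tabs
  readr::write_tsv(out, path, progress = FALSE, quote = "none",
                   escape = "none")
  invisible(records)
}

# ---- flat-file dialect -----------------------------------------------------

parse_flatfile_block <- function(lines) {
  tag <- substr(lines, 1, 2)
  body <- trimws(substring(lines, 6))

  acc <- NA_character_
  ac_lines <- body[tag == "AC"]
  if (length(ac_lines) > 0) {
    acc <- trimws(sub(";.*$", "", ac_lines[1]))
  }
  name <- if (any(tag == "ID")) sub("\\s.*$", "", body[tag == "ID"][1]) else acc

  # FT features: position line + /note continuations (blank feature key)
  ft_idx <- which(tag == "FT")
  feats <- list()
  cur <- NULL
  for (i in ft_idx) {
    line <- lines[i]
    key <- trimws(substr(line, 6, 20))
    rest <- trimws(substring(line, 21))
    if (nzchar(key)) {
      if (!is.null(cur)) feats[[length(feats) + 1]] <- cur
      cur <- list(key = key, pos = rest, note = NA_character_)
    } else if (!is.null(cur) && grepl("^/note=", rest)) {
      cur$note <- sub('^/note="', "", sub('"$', "", rest))
    }
  }
  if (!is.null(cur)) feats[[length(feats) + 1]] <- cur

  span_of <- function(pos) {
    m <- stringr::str_match(pos, "^(\\d+)(?:\\.\\.(\\d+))?$")
    s <- as.integer(m[2])
    e <- if (is.na(m[3])) s else as.integer(m[3])
    c(s, e)
  }
  pick <- function(key) feats[vapply(feats, function(f) f$key == key,
                                     logical(1))]

  glyco <- integer()
  for (f in pick("CARBOHYD")) {
    if (!is.na(f$note) && grepl("N-linked", f$note, fixed = TRUE)) {
      glyco <- c(glyco, span_of(f$pos)[1])
    }
  }
  tm <- purrr::map(pick("TRANSMEM"), ~ span_of(.x$pos))
  tms <- if (length(tm) > 0) {
    tibble::tibble(start = vapply(tm, `[`, integer(1), 1),
                   end = vapply(tm, `[`, integer(1), 2))
  } else empty_spans()
  td <- pick("TOPO_DOM")
  topo <- if (length(td) > 0) {
    sp <- purrr::map(td, ~ span_of(.x$pos))
    tibble::tibble(
      start = vapply(sp, `[`, integer(1), 1),
      end = vapply(sp, `[`, integer(1), 2),
      side = topo_side_from_note(vapply(td, function(f) {
        if (is.na(f$note)) "" else f$note
      }, character(1))))
  } else empty_domains()
  sig <- pick("SIGNAL")
  sig_span <- if (length(sig) > 0) span_of(sig[[1]]$pos) else c(NA_integer_, NA_integer_)

  # CC SUBCELLULAR LOCATION
  cc <- body[tag == "CC"]
  loc <- character()
  sl <- cc[grepl("SUBCELLULAR LOCATION:", cc)]
  if (length(sl) > 0) {
    s <- sub("^-!-\\s*SUBCELLULAR LOCATION:\\s*", "", sl[1])
    s <- sub("\\.$", "", s)
    loc <- trimws(strsplit(s, ";", fixed = TRUE)[[1]])
  }

  # SQ block: "SQ   SEQUENCE   <len> AA;" then residue lines (tag "  ")
  seq_chr <- NA_character_
  len <- NA_integer_
  sq_i <- which(tag == "SQ")
  if (length(sq_i) > 0) {
    len <- as.integer(stringr::str_match(lines[sq_i[1]],
                                         "SEQUENCE\\s+(\\d+) AA")[2])
    res_lines <- lines[seq_along(lines) > sq_i[1] & tag == "  "]
    if (length(res_lines) > 0) {
      seq_chr <- gsub("\\s", "", paste(res_lines, collapse = ""))
      if (!nzchar(seq_chr)) seq_chr <- NA_character_
    }
  }
  if (is.na(len) && !is.na(seq_chr)) len <- nchar(seq_chr)

  tibble::tibble(
    accession = acc, name = name, length = len, sequence = seq_chr,
    glyco_sites = list(glyco), tm_segments = list(tms),
    topo_domains = list(topo),
    signal_start = sig_span[1], signal_end = sig_span[2],
    localization_terms = list(loc)
  )
}

read_proteome_flatfile <- function(path) {
  lines <- readr::read_lines(path, progress = FALSE)
  ends <- which(trimws(lines) == "//")
  starts <- c(1L, utils::head(ends, -1) + 1L)
  blocks <- purrr::map2(starts, ends, ~ lines[.x:(.y - 1)])
  blocks <- blocks[vapply(blocks, function(b) any(nzchar(trimws(b))),
                          logical(1))]
  proteome_records(dplyr::bind_rows(purrr::map(blocks, parse_flatfile_block)))
}

#' Read proteome annotation records
#'
#' @param path Input file.
#' @param dialect `"tsv"` for a UniProtKB-style tab-separated export with
#'   feature-string columns (`glycosylation`, `transmembrane`, `topo_dom`,
#'   `signal_peptide`, `subcellular_location`), or `"flatfile"` for
#'   UniProtKB flat-file records (`AC`/`ID`/`FT`/`CC`/`SQ` lines, records
#'   terminated by `//`).
#' @return A [proteome_records()] tibble.
#' @details Only `CARBOHYD` features described as `N-linked` are counted as
#'   glycosites; `TOPO_DOM` descriptions containing "Extracellular" or
#'   "Lumenal" map to the luminal/extracellular side, "Cytoplasmic" to the
#'   cytoplasmic side, and anything else is kept with an `NA` side so the
#'   record is flagged rather than silently dropped.
#' @export
read_proteome_records <- function(path, dialect = c("tsv", "flatfile")) {
  dialect <- match.arg(dialect)
  switch(dialect,
         tsv = read_proteome_tsv(path),
         flatfile = read_proteome_flatfile(path))
}

#' Write proteome records in the flat-file dialect
#'
#' @param records A [proteome_records()] tibble.
#' @param path Output path.
#' @return `records`, invisibly.
#' @export
write_proteome_flatfile <- function(records, path) {
  fmt_ft <- function(key, pos, note = NULL) {
    out <- sprintf("FT   %-15s%s", key, pos)
    if (!is.null(note)) {
      out <- c(out, sprintf('FT   %-15s/note="%s"', "", note))
    }
    out
  }
  blocks <- purrr::map(seq_len(nrow(records)), function(i) {
    r <- records[i, ]
    lines <- c(sprintf("ID   %s", r$name),
               sprintf("AC   %s;", r$accession))
    for (p in r$glyco_sites[[1]]) {
      lines <- c(lines, fmt_ft("CARBOHYD", p,
                               "N-linked (GlcNAc...) asparagine"))
    }
    tm <- r$tm_segments[[1]]
    for (j in seq_len(nrow(tm))) {
      lines <- c(lines, fmt_ft("TRANSMEM",
                               paste0(tm$start[j], "..", tm$end[j]),
                               "Helical"))
    }
    td <- r$topo_domains[[1]]
    for (j in seq_len(nrow(td))) {
      note <- switch(td$side[j],
                     LUMENAL_EXTRACELLULAR = "Extracellular",
                     CYTOPLASMIC = "Cytoplasmic", "Unknown")
      if (is.na(td$side[j])) note <- "Unknown"
      lines <- c(lines, fmt_ft("TOPO_DOM",
                               paste0(td$start[j], "..", td$end[j]), note))
    }
    if (!is.na(r$signal_start)) {
      lines <- c(lines, fmt_ft("SIGNAL",
                               paste0(r$signal_start, "..", r$signal_end)))
    }
    loc <- r$localization_terms[[1]]
    if (length(loc) > 0) {
      lines <- c(lines, sprintf("CC   -!- SUBCELLULAR LOCATION: %s.",
                                paste(loc, collapse = "; ")))
    }
    lines <- c(lines, sprintf("SQ   SEQUENCE   %d AA;", r$length))
    if (!is.na(r$sequence)) {
      chunks <- substring(r$sequence,
                          seq(1, nchar(r$sequence), 60),
                          pmin(seq(1, nchar(r$sequence), 60) + 59,
                               nchar(r$sequence)))
      lines <- c(lines, paste0("     ", chunks))
    }
    c(lines, "//")
  })
  readr::write_lines(unlist(blocks), path)
  invisible(records)
}
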