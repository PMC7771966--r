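# Shared fixtures and independent oracles.

tiny_design <- function(n_replicates = 1L, genotype = "ALG6-KO") {
  labels <- c("126", "127", "128", "129", "130", "131")[
    seq_len(2L * n_replicates)]
  tibble::tibble(channel = labels,
                 condition = rep(c("CRT_WT", "CRT_Y109A"), n_replicates),
                 replicate = rep(seq_len(n_replicates), each = 2L),
                 genotype = genotype)
}

tiny_table <- function(wt, y109a, accession = paste0("P", seq_along(wt))) {
  stopifnot(length(wt) == length(y109a))
  tmt_table(tibble::tibble(accession = accession, `126` = wt, `127` = y109a),
            tiny_design(1L))
}

# independent record builder (bypasses the generator)
make_record <- function(accession = "R1", length = 100L, sequence = NA,
                        glyco_sites = integer(), tm = NULL, topo = NULL,
                        signal = c(NA_integer_, NA_integer_),
                        loc = character(), mito = FALSE) {
  proteome_records(tibble::tibble(
    accession = accession, name = accession, length = as.integer(length),
    sequence = as.character(sequence),
    glyco_sites = list(as.integer(glyco_sites)),
    tm_segments = list(if (is.null(tm))
      tibble::tibble(start = integer(), end = integer()) else
        tibble::tibble(start = as.integer(tm[, 1]),
                       end = as.integer(tm[, 2]))),
    topo_domains = list(if (is.null(topo))
      tibble::tibble(start = integer(), end = integer(),
                     side = character()) else topo),
    signal_start = as.integer(signal[1]), signal_end = as.integer(signal[2]),
    localization_terms = list(loc),
    is_mitochondrial = mito))
}

# Grid-scan isoelectric-point oracle: independent of the bisection path.
# Evaluates protonation fractions over a dense pH grid and returns the
# grid point where the net charge changes sign.
grid_pi_oracle <- function(sequence, n_grid = 1e5) {
  aa <- strsplit(toupper(sequence), "")[[1]]
  groups <- rbind(
    data.frame(pka = 3.55, acid = TRUE,  n = 1),              # C-terminus
    data.frame(pka = 4.05, acid = TRUE,  n = sum(aa == "D")),
    data.frame(pka = 4.45, acid = TRUE,  n = sum(aa == "E")),
    data.frame(pka = 9.0,  acid = TRUE,  n = sum(aa == "C")),
    data.frame(pka = 10.0, acid = TRUE,  n = sum(aa == "Y")),
    data.frame(pka = 7.5,  acid = FALSE, n = 1),              # N-terminus
    data.frame(pka = 5.98, acid = FALSE, n = sum(aa == "H")),
    data.frame(pka = 10.0, acid = FALSE, n = sum(aa == "K")),
    data.frame(pka = 12.0, acid = FALSE, n = sum(aa == "R")))
  ph <- seq(0, 14, length.out = n_grid)
  z <- rep(0, n_grid)
  for (i in seq_len(nrow(groups))) {
    ratio <- 10^(ph - groups$pka[i])     # [A-]/[HA] or [B]/[BH+]
    frac_deprot <- ratio / (1 + ratio)
    z <- z + if (groups$acid[i]) -groups$n[i] * frac_deprot else
      groups$n[i] * (1 - frac_deprot)
  }
  ph[which.min(abs(z))]
}

# brute-force sequon counter (triple explicit loop)
brute_sequons <- function(sequence) {
  aa <- strsplit(toupper(sequence), "")[[1]]
  count <- 0L
  if (length(aa) < 3) return(count)
  for (i in 1:(length(aa) - 2)) {
    if (aa[i] == "N" && aa[i + 1] != "P" &&
        aa[i + 2] %in% c("S", "T", "C")) {
      count <- count + 1L
    }
  }
  count
}

random_aa_string <- function(n, seed) {
  withr::with_seed(seed, paste(
    sample(strsplit("ACDEFGHIKLMNPQRSTVWY", "")[[1]], n, replace = TRUE),
    collapse = ""))
}
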