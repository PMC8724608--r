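# Independent oracles, written from scratch against the same published
# monoisotopic constants. They share no code with the package internals.

ORACLE_AA <- c(
  G = 57.02146, A = 71.03711, S = 87.03203, P = 97.05276, V = 99.06841,
  T = 101.04768, C = 103.00919, L = 113.08406, I = 113.08406,
  N = 114.04293, D = 115.02694, Q = 128.05858, K = 128.09496,
  E = 129.04259, M = 131.04049, H = 137.05891, F = 147.06841,
  R = 156.10111, Y = 163.06333, W = 186.07931
)
ORACLE_SUGAR <- c(Hex = 162.05282, HexNAc = 203.07937, dHex = 146.05791,
                  Pent = 132.04226)
ORACLE_PROTON <- 1.0072765
ORACLE_WATER <- 18.010565
ORACLE_HYP <- 97.05276 + 15.99491

# per-character summation, looping explicitly
oracle_peptide_mass <- function(seq) {
  total <- ORACLE_WATER
  for (ch in strsplit(seq, "")[[1]]) {
    total <- total + if (ch == "p") ORACLE_HYP else ORACLE_AA[[ch]]
  }
  total
}

oracle_glycan_mass <- function(hex = 0, hexnac = 0, dhex = 0, pent = 0) {
  hex * ORACLE_SUGAR[["Hex"]] + hexnac * ORACLE_SUGAR[["HexNAc"]] +
    dhex * ORACLE_SUGAR[["dHex"]] + pent * ORACLE_SUGAR[["Pent"]]
}

oracle_mz <- function(neutral, z) (neutral + z * ORACLE_PROTON) / z

# brute-force fragment masses: b_i = prefix residues, y_i = suffix
# residues + water, plus any attached glycan mass
oracle_fragment_mz <- function(seq, series, index, glycan_mass, z) {
  aa <- strsplit(seq, "")[[1]]
  res <- function(ch) if (ch == "p") ORACLE_HYP else ORACLE_AA[[ch]]
  neutral <- if (series == "b") {
    sum(vapply(aa[seq_len(index)], res, 0))
  } else if (series == "y") {
    sum(vapply(aa[seq.int(length(aa) - index + 1, length(aa))], res, 0)) +
      ORACLE_WATER
  } else { # Y: whole peptide (+ index HexNAc handled via glycan_mass)
    sum(vapply(aa, res, 0)) + ORACLE_WATER
  }
  (neutral + glycan_mass + z * ORACLE_PROTON) / z
}

# literal re-statement of the acceptance rules, counting matched ion
# classes with plain tolerance arithmetic
oracle_verdict <- function(peaks_mz, oxonium_mz, anchor_mz, b_mz, y_mz,
                           ragged = FALSE, strict_fallback = FALSE,
                           tol_ppm = 50) {
  near <- function(target) {
    any(abs(peaks_mz - target) / target * 1e6 <= tol_ppm)
  }
  oxo_ok <- all(vapply(oxonium_mz, near, TRUE))
  anchor <- any(vapply(anchor_mz, near, TRUE))
  nb <- sum(vapply(b_mz, near, TRUE))
  ny <- sum(vapply(y_mz, near, TRUE))
  if (ragged) return(oxo_ok && anchor && nb >= 3 && ny >= 3)
  if (anchor) return(oxo_ok && (nb + ny) >= 3)
  if (strict_fallback) return(oxo_ok && nb >= 3 && ny >= 3)
  oxo_ok && (nb + ny) >= 3 && nb >= 1 && ny >= 1
}

random_peptide <- function(n) {
  paste(sample(names(ORACLE_AA), n, replace = TRUE), collapse = "")
}

# split a "SEQ[Glycan]" modified sequence into its parts
seq_part <- function(ms) sub("\\[[^]]*\\]$", "", ms)
glyco_part <- function(ms) {
  g <- regmatches(ms, regexpr("\\[[^]]*\\]$", ms))
  out <- character(length(ms))
  out[regexpr("\\[[^]]*\\]$", ms) > 0] <- substr(g, 2, nchar(g) - 1)
  out
}

# build a spectrum tibble from raw m/z values
peaks_tbl <- function(mz, intensity = NULL) {
  if (is.null(intensity)) intensity <- rep(100, length(mz))
  tibble::tibble(mz = mz, intensity = intensity)[order(mz), ]
}
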