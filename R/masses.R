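# Monoisotopic mass constants. Stated once so that downstream ppm
# comparisons are stable to the fifth decimal.

#' @keywords internal
.PROTON <- 1.0072765

#' @keywords internal
.WATER <- 18.010565

# Glycan residue (dehydrated monosaccharide) monoisotopic masses, Da
.GLYCAN_RESIDUES <- c(
  Hex    = 162.05282,
  HexNAc = 203.07937,
  dHex   = 146.05791,
  Pent   = 132.04226
)

# Amino-acid residue monoisotopic masses, Da. Lowercase 'p' is
# hydroxyproline (Pro + 15.99491), the attachment residue of plant
# O-glycans; I and L are distinct letters with identical mass.
.RESIDUES <- c(
  G = 57.02146, A = 71.03711, S = 87.03203, P = 97.05276, V = 99.06841,
  T = 101.04768, C = 103.00919, L = 113.08406, I = 113.08406,
  N = 114.04293, D = 115.02694, Q = 128.05858, K = 128.09496,
  E = 129.04259, M = 131.04049, H = 137.05891, F = 147.06841,
  R = 156.10111, Y = 163.06333, W = 186.07931,
  p = 97.05276 + 15.99491
)

# Deltas for the variable modifications used in the searches
.MOD_DELTAS <- c(
  oxidation   = 15.99491,
  deamidation = 0.98402,
  dehydro     = -1.00783
)

#' Monoisotopic mass constants
#'
#' Returns the fixed table of monoisotopic masses used throughout the
#' package: amino-acid residues (including lowercase `p` for
#' hydroxyproline), glycan residues (Hex, HexNAc, dHex, Pent), the proton
#' and water. The same table ships as a TSV in
#' `system.file("extdata", "mass_constants.tsv", package = "glycodia")`.
#'
#' @return A tibble with columns `name`, `kind` and `mass` (Da).
#' @export
#' @examples
#' mass_constants()
mass_constants <- function() {
  dplyr::bind_rows(
    tibble::tibble(name = names(.RESIDUES), kind = "residue",
                   mass = unname(.RESIDUES)),
    tibble::tibble(name = names(.GLYCAN_RESIDUES), kind = "glycan",
                   mass = unname(.GLYCAN_RESIDUES)),
    tibble::tibble(name = c("proton", "water"), kind = "constant",
                   mass = c(.PROTON, .WATER)),
    tibble::tibble(name = names(.MOD_DELTAS), kind = "modification",
                   mass = unname(.MOD_DELTAS))
  )
}

#' Parse a glycan composition string
#'
#' Composition strings concatenate monosaccharide names, each followed by a
#' positive integer count, in any order: `"HexNAc2Hex3dHex1Pent1"`,
#' `"Hex6"`, `"Pent3"`. The empty string is the empty (zero-mass)
#' composition, i.e. an unmodified peptide.
#'
#' @param text Character vector of composition strings.
#' @return A tibble with one row per input and integer columns `hex`,
#'   `hexnac`, `dhex`, `pent`; omitted monosaccharides are zero.
#' @export
#' @examples
#' parse_glycan(c("Hex6", "HexNAc2Hex3dHex1Pent1", ""))
parse_glycan <- function(text) {
  stopifnot(is.character(text))
  parse_one <- function(s) {
    counts <- c(hex = 0L, hexnac = 0L, dhex = 0L, pent = 0L)
    if (is.na(s) || !nzchar(s)) return(counts)
    # longest names first so "HexNAc" is not split into "Hex" + "NAc"
    tokens <- stringr::str_match_all(s, "(HexNAc|dHex|Hex|Pent)(\\d+)")[[1]]
    consumed <- sum(nchar(tokens[, 1]))
    if (consumed != nchar(s)) {
      bad <- stringr::str_remove_all(s, "(HexNAc|dHex|Hex|Pent)\\d+")
      stop("unknown monosaccharide token in glycan composition: '",
           bad, "' (in '", s, "')", call. = FALSE)
    }
    key <- c(HexNAc = "hexnac", dHex = "dhex", Hex = "hex", Pent = "pent")
    for (i in seq_len(nrow(tokens))) {
      counts[[key[[tokens[i, 2]]]]] <-
        counts[[key[[tokens[i, 2]]]]] + as.integer(tokens[i, 3])
    }
    counts
  }
  out <- purrr::map(text, parse_one)
  tibble::tibble(
    hex    = purrr::map_int(out, "hex"),
    hexnac = purrr::map_int(out, "hexnac"),
    dhex   = purrr::map_int(out, "dhex"),
    pent   = purrr::map_int(out, "pent")
  )
}

#' Format a glycan composition as a canonical string
#'
#' Inverse of [parse_glycan()]; names appear in the fixed order HexNAc,
#' Hex, dHex, Pent and zero counts are omitted. The empty composition
#' formats as `""`.
#'
#' @param g A tibble with columns `hex`, `hexnac`, `dhex`, `pent`, or a
#'   character vector already in composition-string form (returned as is
#'   after canonicalisation).
#' @return Character vector of composition strings.
#' @export
format_glycan <- function(g) {
  if (is.character(g)) g <- parse_glycan(g)
  part <- function(name, n) ifelse(n > 0, paste0(name, n), "")
  paste0(part("HexNAc", g$hexnac), part("Hex", g$hex),
         part("dHex", g$dhex), part("Pent", g$pent))
}

#' Monoisotopic mass of a glycan composition
#'
#' Sum of counts times the monoisotopic residue masses (Hex 162.05282,
#' HexNAc 203.07937, dHex 146.05791, Pent 132.04226 Da). Mass is linear in
#' the counts, so consecutive Hex glycoforms of one peptide are spaced by
#' 162.05282 Da and consecutive Pent glycoforms by 132.04226 Da.
#'
#' @param g A composition string vector or a tibble as returned by
#'   [parse_glycan()].
#' @return Numeric vector of masses in Da.
#' @export
#' @examples
#' glycan_mass("Hex6") # 6 * 162.05282
glycan_mass <- function(g) {
  if (is.character(g)) g <- parse_glycan(g)
  g$hex * .GLYCAN_RESIDUES[["Hex"]] +
    g$hexnac * .GLYCAN_RESIDUES[["HexNAc"]] +
    g$dhex * .GLYCAN_RESIDUES[["dHex"]] +
    g$pent * .GLYCAN_RESIDUES[["Pent"]]
}

#' Neutral monoisotopic mass of a (modified) peptide
#'
#' Residue masses are summed and one water is added. Lowercase `p` in the
#' sequence denotes hydroxyproline and contributes Pro + 15.99491 Da.
#' Additional positional modifications are supplied as `(position, delta)`
#' pairs; positions are 1-based and only their `delta` enters the mass.
#'
#' @param sequence Character vector of peptide sequences in one-letter
#'   code (uppercase, plus lowercase `p`).
#' @param mods Either `NULL`, a single tibble with columns `position` and
#'   `delta` applied to a length-one `sequence`, or a list of such tibbles
#'   parallel to `sequence` (use `NULL` elements for unmodified peptides).
#' @return Numeric vector of neutral masses in Da.
#' @export
#' @examples
#' peptide_neutral_mass("VITGVPWYSSR") # 1263.66116
#' peptide_neutral_mass("VVRPppTpKPpT") # hydroxyprolines via lowercase p
peptide_neutral_mass <- function(sequence, mods = NULL) {
  stopifnot(is.character(sequence))
  if (is.data.frame(mods)) {
    stopifnot(length(sequence) == 1L)
    mods <- list(mods)
  }
  if (is.null(mods)) mods <- vector("list", length(sequence))
  stopifnot(length(mods) == length(sequence))
  purrr::map2_dbl(sequence, mods, function(s, m) {
    aa <- strsplit(s, "")[[1]]
    known <- aa %in% names(.RESIDUES)
    if (!all(known)) {
      stop("unknown residue '", aa[which(!known)[1]], "' at position ",
           which(!known)[1], " in '", s, "'", call. = FALSE)
    }
    total <- sum(.RESIDUES[aa]) + .WATER
    if (!is.null(m) && nrow(m) > 0) {
      stopifnot(all(m$position >= 1 & m$position <= length(aa)))
      total <- total + sum(m$delta)
    }
    total
  })
}

#' Theoretical precursor m/z from a neutral mass and charge
#'
#' `(neutral_mass + z * 1.0072765) / z`; strictly decreasing in `z`.
#'
#' @param neutral_mass Neutral monoisotopic mass in Da.
#' @param z Positive integer charge (vectors recycle).
#' @return Numeric vector of m/z values.
#' @export
#' @examples
#' precursor_mz(peptide_neutral_mass("VITGVPWYSSR") + glycan_mass("Hex6"), 3)
precursor_mz <- function(neutral_mass, z) {
  if (any(z < 1)) stop("charge must be >= 1", call. = FALSE)
  (neutral_mass + z * .PROTON) / z
}

#' Relative mass error in parts per million
#'
#' `(observed - theoretical) / theoretical * 1e6`, reported to two
#' decimals. Negative values mean the observed m/z is below theory.
#'
#' @param observed,theoretical Observed and theoretical m/z.
#' @return Numeric vector of ppm errors, rounded to 2 decimals.
#' @export
#' @examples
#' ppm_error(746.3205, 746.33330) # about -17.15
ppm_error <- function(observed, theoretical) {
  if (any(theoretical <= 0)) stop("theoretical m/z must be > 0", call. = FALSE)
  round((observed - theoretical) / theoretical * 1e6, 2)
}
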