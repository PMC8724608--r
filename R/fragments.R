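# Theoretical fragment enumeration and library slot allocation.
#
# A PeakView-style transition list has a fixed set of ion-type labels, so
# glycopeptide-specific fragments are carried in repurposed slots:
#   Y0 -> "a1", Y1 -> "a2", Y2 -> "a3"
#   b/y + HexNAc1 (N-linked, fragment index >= 4) -> "a<index>"
#   b/y + intact glycan -> "c<index>"
#   b/y + HexNAc1 at index 1..3 are excluded from the library.
# Plain b/y ions (complete glycan loss) keep their own "b<N>"/"y<N>" slots.

.empty_glycan <- function() {
  tibble::tibble(hex = 0L, hexnac = 0L, dhex = 0L, pent = 0L)
}

.hexnac_n <- function(n) {
  tibble::tibble(hex = 0L, hexnac = as.integer(n), dhex = 0L, pent = 0L)
}

#' Enumerate theoretical glycopeptide fragment ions
#'
#' Generates, at charges 1+ and 2+ by default:
#' * plain `b`/`y` ions over indices `1..n-1` (glycan fully lost);
#' * the intact-peptide `Y` series: Y0 for O-linked, Y0/Y1/Y2 (bare
#'   peptide, peptide + HexNAc1, peptide + HexNAc2) for N-linked;
#' * for N-linked glycopeptides with a known site, `b`/`y` ions retaining
#'   a single HexNAc on fragments that contain the site;
#' * `b`/`y` ions carrying the intact glycan on fragments that contain the
#'   site (O- and N-linked, known site only).
#'
#' Each fragment is allocated a library slot (see [allocate_slot()]);
#' b/y + HexNAc ions at peptide positions 1–3 receive `slot = NA` and
#' `excluded = TRUE`.
#'
#' @param sequence Peptide sequence (one-letter, lowercase `p` allowed).
#' @param glycan Glycan composition string or one-row composition tibble.
#' @param linkage `"N"` or `"O"`.
#' @param site Optional 1-based glycosylation site; `NA` means
#'   site-ambiguous, in which case only plain b/y and Y ions are emitted.
#' @param mods Optional modification tibble (see
#'   [peptide_neutral_mass()]).
#' @param charges Fragment charges to emit (default `1:2`).
#' @return A tibble with columns `series` ("b", "y" or "Y"), `index`
#'   (b/y position or Y-number 0/1/2), `glycan_remainder` (composition
#'   string attached to the fragment), `charge`, `mz`, `slot`, `excluded`.
#' @export
#' @examples
#' enumerate_fragments("VITGVPWYSSR", "Hex6", linkage = "O", site = 9)
enumerate_fragments <- function(sequence, glycan, linkage = c("O", "N"),
                                site = NA, mods = NULL, charges = 1:2) {
  linkage <- match.arg(linkage)
  aa <- strsplit(sequence, "")[[1]]
  n <- length(aa)
  if (n < 2) stop("peptide must have at least 2 residues", call. = FALSE)
  if (is.character(glycan)) glycan <- parse_glycan(glycan)
  glycan_str <- format_glycan(glycan)

  pep_mass <- peptide_neutral_mass(sequence, mods)
  mod_at <- function(idx) {
    if (is.null(mods) || nrow(mods) == 0) return(0)
    sum(mods$delta[mods$position %in% idx])
  }
  # neutral fragment masses: b = sum(residues); y = sum(residues) + water
  b_neutral <- function(i) sum(.RESIDUES[aa[seq_len(i)]]) + mod_at(seq_len(i))
  y_neutral <- function(i) {
    idx <- seq.int(n - i + 1L, n)
    sum(.RESIDUES[aa[idx]]) + mod_at(idx) + .WATER
  }

  rows <- list()
  add <- function(series, index, remainder, neutral) {
    rows[[length(rows) + 1L]] <<- tibble::tibble(
      series = series, index = as.integer(index),
      glycan_remainder = format_glycan(remainder),
      charge = as.integer(charges),
      mz = (neutral + glycan_mass(remainder) + charges * .PROTON) / charges
    )
  }

  for (i in seq_len(n - 1L)) {
    add("b", i, .empty_glycan(), b_neutral(i))
    add("y", i, .empty_glycan(), y_neutral(i))
  }
  add("Y", 0L, .empty_glycan(), pep_mass)
  if (linkage == "N") {
    add("Y", 1L, .hexnac_n(1), pep_mass)
    add("Y", 2L, .hexnac_n(2), pep_mass)
  }
  if (!is.na(site)) {
    b_has_site <- function(i) site <= i
    y_has_site <- function(i) site >= n - i + 1L
    for (i in seq_len(n - 1L)) {
      if (linkage == "N") {
        if (b_has_site(i)) add("b", i, .hexnac_n(1), b_neutral(i))
        if (y_has_site(i)) add("y", i, .hexnac_n(1), y_neutral(i))
      }
      if (b_has_site(i)) add("b", i, glycan, b_neutral(i))
      if (y_has_site(i)) add("y", i, glycan, y_neutral(i))
    }
  }

  out <- dplyr::bind_rows(rows) |>
    # a fragment can be generated by two classes when the intact glycan
    # is itself a single HexNAc; it is one physical ion
    dplyr::distinct(.data$series, .data$index, .data$glycan_remainder,
                    .data$charge, .keep_all = TRUE)
  out$slot <- allocate_slot(out, glycan_str)
  out$excluded <- is.na(out$slot)
  out
}

#' Allocate a fragment to its library ion slot
#'
#' Implements the allocation table used when packing glycopeptide
#' fragments into a peptide-centric transition list: plain b/y keep
#' `"bN"`/`"yN"`; Y0, Y1, Y2 map to `"a1"`, `"a2"`, `"a3"`; b/y retaining
#' one HexNAc map to `"aN"` when the fragment index is 4 or more and are
#' excluded (`NA`) at indices 1–3, where they would collide with the Y
#' slots; b/y carrying the intact glycan map to `"cN"`. The labels do not
#' denote true a/c ions — the letters are repurposed slot names.
#'
#' @param fragments A tibble with columns `series`, `index`,
#'   `glycan_remainder` as produced by [enumerate_fragments()].
#' @param intact_glycan The intact glycan composition string of the
#'   precursor (used to distinguish intact-glycan from HexNAc-remainder
#'   fragments).
#' @return Character vector of slot labels, `NA` for excluded fragments.
#' @export
allocate_slot <- function(fragments, intact_glycan) {
  if (is.data.frame(intact_glycan) || !is.character(intact_glycan)) {
    intact_glycan <- format_glycan(intact_glycan)
  }
  hexnac1 <- format_glycan(.hexnac_n(1))
  purrr::pmap_chr(
    fragments[c("series", "index", "glycan_remainder")],
    function(series, index, glycan_remainder) {
      if (series == "Y") return(paste0("a", index + 1L))
      if (!nzchar(glycan_remainder)) return(paste0(series, index))
      if (glycan_remainder == intact_glycan &&
          intact_glycan != hexnac1) {
        return(paste0("c", index))
      }
      if (glycan_remainder == hexnac1) {
        if (index >= 4L) return(paste0("a", index)) else return(NA_character_)
      }
      paste0("c", index)
    }
  )
}

#' Parse a library slot label back to its fragment meaning
#'
#' Round-trips the labels produced by [allocate_slot()]: `"b3"`/`"y6"`
#' are plain peptide ions, `"a1"`/`"a2"`/`"a3"` are Y0/Y1/Y2, `"a7"` is a
#' b- or y-ion + HexNAc1 (series not recoverable from the label alone),
#' `"c4"` is a b/y ion with the intact glycan.
#'
#' @param slot Character vector of slot labels.
#' @return A tibble with columns `slot`, `class` (one of `"plain"`,
#'   `"Y"`, `"hexnac"`, `"intact"`), `series` (`NA` where ambiguous) and
#'   `index` (fragment position, or Y-number for the Y class).
#' @export
parse_slot <- function(slot) {
  m <- stringr::str_match(slot, "^([abcy])(\\d+)$")
  if (anyNA(m[, 1])) {
    stop("malformed slot label: ", slot[which(is.na(m[, 1]))[1]],
         call. = FALSE)
  }
  letter <- m[, 2]
  num <- as.integer(m[, 3])
  cls <- dplyr::case_when(
    letter %in% c("b", "y") ~ "plain",
    letter == "a" & num <= 3 ~ "Y",
    letter == "a" ~ "hexnac",
    TRUE ~ "intact"
  )
  tibble::tibble(
    slot = slot,
    class = cls,
    series = dplyr::if_else(letter %in% c("b", "y"), letter, NA_character_),
    index = dplyr::if_else(cls == "Y", num - 1L, num)
  )
}

#' Oxonium-ion reference table for a glycan composition
#'
#' Singly protonated oxonium m/z for each monosaccharide present in the
#' composition (residue mass + proton): Hex 163.06010, HexNAc 204.08665,
#' dHex 147.06519, Pent 133.04954. For N-glycans the dHex and Pent
#' oxonium ions are marked non-required (`required = FALSE`): their
#' presence is not demanded during validation.
#'
#' @param glycan Composition string or tibble.
#' @param linkage `"O"` or `"N"`; controls the dHex/Pent exemption.
#' @return A tibble with columns `monosaccharide`, `mz`, `required`.
#' @export
#' @examples
#' oxonium_table("HexNAc2Hex3dHex1Pent1", linkage = "N")
oxonium_table <- function(glycan, linkage = c("O", "N")) {
  linkage <- match.arg(linkage)
  if (is.character(glycan)) glycan <- parse_glycan(glycan)
  stopifnot(nrow(glycan) == 1L)
  counts <- c(Hex = glycan$hex, HexNAc = glycan$hexnac,
              dHex = glycan$dhex, Pent = glycan$pent)
  present <- names(counts)[counts > 0]
  exempt <- if (linkage == "N") c("dHex", "Pent") else character()
  tibble::tibble(
    monosaccharide = present,
    mz = unname(.GLYCAN_RESIDUES[present]) + .PROTON,
    required = !(present %in% exempt)
  )
}
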