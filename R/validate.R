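# Deterministic rule engine for glycopeptide spectrum-match validation.
#
# Acceptance requires, on top of the search-engine assignment:
#   1. every required oxonium ion of the glycan present in the spectrum
#      (dHex/Pent of N-glycans are exempt);
#   2. the anchor Y ion — Y0 for O-glycopeptides, Y1 for N-glycopeptides —
#      plus at least 3 matched b/y peptide ions ("standard" path); or
#   3. with no anchor Y ion, at least 3 matched b/y ions with both series
#      represented ("no_Y_fallback"; `strict_fallback = TRUE` demands >= 3
#      of each series); and
#   4. peptides from Lys/Arg–Pro or N-ragged cleavage take the strict
#      "ragged_strict" path: anchor Y AND >= 3 b AND >= 3 y.

#' Match a target m/z list against a centroided spectrum
#'
#' A target matches when some peak lies within `tol_ppm`; each peak is
#' consumed by at most one target, with pairs assigned greedily in order
#' of increasing absolute ppm deviation (nearest-m/z tie-break).
#'
#' @param peaks A tibble with columns `mz` and `intensity` (ascending
#'   `mz`, positive intensities).
#' @param targets Numeric vector of target m/z values.
#' @param tol_ppm Matching tolerance in ppm (> 0).
#' @return A tibble with one row per target: `target`, `matched`,
#'   `peak_mz`, `peak_intensity`, `ppm`.
#' @export
match_peaks <- function(peaks, targets, tol_ppm) {
  if (tol_ppm <= 0) stop("tol_ppm must be > 0", call. = FALSE)
  out <- tibble::tibble(
    target = targets, matched = FALSE,
    peak_mz = NA_real_, peak_intensity = NA_real_, ppm = NA_real_
  )
  if (length(targets) == 0 || is.null(peaks) || nrow(peaks) == 0) return(out)
  cand <- tidyr::crossing(
    ti = seq_along(targets),
    pi = seq_len(nrow(peaks))
  )
  cand$ppm <- (peaks$mz[cand$pi] - targets[cand$ti]) /
    targets[cand$ti] * 1e6
  cand <- cand[abs(cand$ppm) <= tol_ppm, , drop = FALSE]
  cand <- cand[order(abs(cand$ppm), cand$ti, cand$pi), , drop = FALSE]
  used_peak <- logical(nrow(peaks))
  for (k in seq_len(nrow(cand))) {
    ti <- cand$ti[k]; pi <- cand$pi[k]
    if (out$matched[ti] || used_peak[pi]) next
    out$matched[ti] <- TRUE
    out$peak_mz[ti] <- peaks$mz[pi]
    out$peak_intensity[ti] <- peaks$intensity[pi]
    out$ppm[ti] <- cand$ppm[k]
    used_peak[pi] <- TRUE
  }
  out
}

#' Validate a glycopeptide assignment against its spectrum
#'
#' Applies the oxonium / Y-ion / b,y-count decision tree described above
#' and returns a one-row verdict tibble with the evidence counts from
#' which the decision can be re-derived.
#'
#' @param sequence Peptide sequence (lowercase `p` = hydroxyproline).
#' @param glycan Glycan composition string or tibble.
#' @param linkage `"O"` or `"N"`.
#' @param peaks Spectrum tibble with columns `mz`, `intensity`.
#' @param site Optional glycosylation site (passed to the fragment model).
#' @param mods Optional modification tibble.
#' @param cleavage One of `"tryptic"`, `"semitryptic"`, `"KR_P"`,
#'   `"N_ragged"`; the latter two trigger the strict path.
#' @param tol_ppm Fragment matching tolerance in ppm (default 50).
#' @param strict_fallback If `TRUE`, the no-anchor fallback requires at
#'   least 3 matched ions from each of the b and y series instead of 3 in
#'   total with both series represented.
#' @param co_elution_support Advisory flag recorded in `notes`; never
#'   sufficient for acceptance on its own.
#' @return A one-row tibble: `accepted`, `rule_path` (`"standard"`,
#'   `"no_Y_fallback"` or `"ragged_strict"`), `n_oxonium_required`,
#'   `n_oxonium_matched`, `anchor_matched`, `n_b`, `n_y`, `notes`.
#' @export
validate_psm <- function(sequence, glycan, linkage = c("O", "N"), peaks,
                         site = NA, mods = NULL,
                         cleavage = c("tryptic", "semitryptic",
                                      "KR_P", "N_ragged"),
                         tol_ppm = 50, strict_fallback = FALSE,
                         co_elution_support = FALSE) {
  linkage <- match.arg(linkage)
  cleavage <- match.arg(cleavage)
  if (tol_ppm <= 0) stop("tol_ppm must be > 0", call. = FALSE)
  if (is.character(glycan)) glycan <- parse_glycan(glycan)

  notes <- character()
  oxo <- oxonium_table(glycan, linkage)
  oxo_req <- oxo[oxo$required, , drop = FALSE]
  oxo_match <- match_peaks(peaks, oxo_req$mz, tol_ppm)
  n_oxo <- sum(oxo_match$matched)

  frags <- enumerate_fragments(sequence, glycan, linkage, site = site,
                               mods = mods)
  # anchor: Y0 for O-linked, Y1 for N-linked, at either charge
  anchor_idx <- if (linkage == "O") 0L else 1L
  anchor_mz <- frags$mz[frags$series == "Y" & frags$index == anchor_idx]
  anchor_matched <- any(match_peaks(peaks, anchor_mz, tol_ppm)$matched)

  # count distinct matched plain b and y ions (by series + index)
  plain <- frags[frags$series %in% c("b", "y") &
                   !nzchar(frags$glycan_remainder), , drop = FALSE]
  pm <- match_peaks(peaks, plain$mz, tol_ppm)
  matched_ids <- unique(paste0(plain$series, plain$index)[pm$matched])
  n_b <- sum(startsWith(matched_ids, "b"))
  n_y <- sum(startsWith(matched_ids, "y"))

  # advisory: confirm monosaccharides through non-anchor Y ions
  other_y <- frags$mz[frags$series == "Y" & frags$index != anchor_idx]
  if (length(other_y) > 0 &&
      any(match_peaks(peaks, other_y, tol_ppm)$matched)) {
    notes <- c(notes, "additional Y-ion support")
  }
  if (co_elution_support) notes <- c(notes, "co-elution support (advisory)")

  oxonium_ok <- n_oxo == nrow(oxo_req)
  if (cleavage %in% c("KR_P", "N_ragged")) {
    rule_path <- "ragged_strict"
    accepted <- oxonium_ok && anchor_matched && n_b >= 3 && n_y >= 3
  } else if (anchor_matched) {
    rule_path <- "standard"
    accepted <- oxonium_ok && (n_b + n_y) >= 3
  } else {
    rule_path <- "no_Y_fallback"
    accepted <- oxonium_ok &&
      if (strict_fallback) n_b >= 3 && n_y >= 3
      else (n_b + n_y) >= 3 && n_b >= 1 && n_y >= 1
  }
  if (!oxonium_ok) notes <- c(notes, "missing required oxonium ion(s)")

  tibble::tibble(
    accepted = accepted,
    rule_path = rule_path,
    n_oxonium_required = nrow(oxo_req),
    n_oxonium_matched = n_oxo,
    anchor_matched = anchor_matched,
    n_b = n_b,
    n_y = n_y,
    notes = paste(notes, collapse = "; ")
  )
}
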