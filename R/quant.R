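# DIA isolation-window scheme, transition-level quantification and
# rollup to peptide and protein abundances, plus site-specific glycoform
# relative abundances.

#' Generate a DIA isolation-window scheme
#'
#' Window `i` spans `[low + i*(width - overlap),
#' low + i*(width - overlap) + width]`, so consecutive windows overlap by
#' exactly `overlap` m/z and together cover `[low, high]`. The default
#' arguments give the acquisition scheme used throughout the package: 34
#' windows of 26 m/z with 1 m/z overlap across 400–1250 m/z.
#'
#' @param low,high Scheme bounds in m/z (`high > low`).
#' @param width Isolation-window width in m/z.
#' @param overlap Overlap between consecutive windows in m/z
#'   (`width > overlap >= 0`).
#' @return A tibble with columns `window` (1-based index), `start`,
#'   `end`.
#' @export
#' @examples
#' nrow(make_windows(400, 1250, 26, 1)) # 34
make_windows <- function(low = 400, high = 1250, width = 26, overlap = 1) {
  if (high <= low) stop("high must exceed low", call. = FALSE)
  if (overlap < 0 || width <= overlap) {
    stop("need width > overlap >= 0", call. = FALSE)
  }
  n <- ceiling((high - low - overlap) / (width - overlap))
  i <- seq_len(n) - 1L
  tibble::tibble(
    window = seq_len(n),
    start = low + i * (width - overlap),
    end = low + i * (width - overlap) + width
  )
}

#' Quantify library transitions across DIA samples
#'
#' Two input modes are supported per sample:
#' * a *peak stream*: columns `sample`, `mz`, `rt_min`, `intensity`
#'   (optionally `q1_window`, the 1-based acquisition-window index) —
#'   intensity is the sum of all signal within `xic_ppm` of the
#'   transition's Q3 and within half the retention-time window of the
#'   library RT, restricted to the acquisition window containing Q1 when
#'   window indices are present;
#' * a *pre-extracted transition table*: columns `sample`,
#'   `modified_sequence`, `prec_z`, `slot`, `intensity` — intensities are
#'   joined directly onto the library.
#'
#' Absent signal yields 0. A library Q1 falling in no or in more than one
#' acquisition window (possible at window boundaries because of the 1 m/z
#' overlap) triggers a warning; the lowest containing window is used.
#'
#' @param lib Ion-library tibble from [build_library()].
#' @param samples Long-format tibble in one of the two modes above.
#' @param rt_window Total retention-time extraction window in minutes
#'   (default 6, i.e. +/- 3 min).
#' @param xic_ppm Extraction width around Q3 in ppm (default 75).
#' @param windows Acquisition scheme from [make_windows()].
#' @return A transition-level abundance tibble: `modified_sequence`,
#'   `prec_z`, `slot`, `protein`, `stripped_sequence`, `sample`,
#'   `intensity`, with `level` attribute `"transition"`.
#' @export
quantify_transitions <- function(lib, samples, rt_window = 6, xic_ppm = 75,
                                 windows = make_windows()) {
  stopifnot(nrow(lib) > 0)
  if (!"sample" %in% names(samples)) {
    stop("samples input needs a 'sample' column", call. = FALSE)
  }
  sample_ids <- unique(samples$sample)
  key_cols <- c("modified_sequence", "prec_z", "slot", "protein",
                "stripped_sequence")

  if (all(c("modified_sequence", "prec_z", "slot", "intensity") %in%
            names(samples))) {
    obs <- samples |>
      dplyr::group_by(.data$sample, .data$modified_sequence, .data$prec_z,
                      .data$slot) |>
      dplyr::summarise(intensity = sum(.data$intensity), .groups = "drop")
    grid <- tidyr::crossing(
      dplyr::distinct(lib[key_cols]),
      sample = sample_ids
    )
    out <- grid |>
      dplyr::left_join(obs, by = c("modified_sequence", "prec_z", "slot",
                                   "sample")) |>
      dplyr::mutate(intensity = tidyr::replace_na(.data$intensity, 0))
  } else if (all(c("mz", "rt_min", "intensity") %in% names(samples))) {
    win_of <- function(q1) {
      hits <- which(windows$start <= q1 & q1 <= windows$end)
      if (length(hits) != 1) {
        warning("Q1 ", format(q1), " falls in ", length(hits),
                " acquisition window(s)", call. = FALSE)
      }
      if (length(hits) == 0) NA_integer_ else hits[1]
    }
    lib$q1_window <- purrr::map_int(lib$q1, win_of)
    has_window <- "q1_window" %in% names(samples)
    extract_one <- function(q3, rt, q1_window, sm) {
      sel <- abs(sm$mz - q3) / q3 * 1e6 <= xic_ppm &
        abs(sm$rt_min - rt) <= rt_window / 2
      if (has_window && !is.na(q1_window)) {
        sel <- sel & sm$q1_window == q1_window
      }
      sum(sm$intensity[sel])
    }
    out <- purrr::map(sample_ids, function(sid) {
      sm <- samples[samples$sample == sid, , drop = FALSE]
      tibble::tibble(
        lib[key_cols],
        sample = sid,
        intensity = purrr::pmap_dbl(
          list(lib$q3, lib$rt, lib$q1_window),
          function(q3, rt, w) extract_one(q3, rt, w, sm)
        )
      )
    }) |> dplyr::bind_rows()
  } else {
    stop("samples input matches neither the peak-stream nor the ",
         "transition-table schema", call. = FALSE)
  }
  structure(out, level = "transition")
}

#' Roll transition intensities up to peptide and protein level
#'
#' Peptide(-precursor) intensity is the sum of its `top_k` transitions,
#' selected by decreasing library reference intensity (not by observed
#' signal, so the selection is identical across samples). Protein
#' intensity is the sum over its peptide precursors; peptides shared
#' between proteins (semicolon-separated accessions in the library's
#' `protein` field) contribute fully to every parent.
#'
#' @param transitions Transition-level abundance tibble from
#'   [quantify_transitions()].
#' @param lib The ion library the transitions were extracted with.
#' @param top_k Transitions summed per peptide precursor (default 6).
#' @return A list with elements `peptide` (columns `modified_sequence`,
#'   `prec_z`, `protein`, `stripped_sequence`, `sample`, `intensity`) and
#'   `protein` (columns `protein`, `sample`, `intensity`).
#' @export
rollup <- function(transitions, lib, top_k = 6) {
  ranked <- lib |>
    dplyr::group_by(.data$modified_sequence, .data$prec_z, .data$slot) |>
    dplyr::summarise(relative_intensity = max(.data$relative_intensity),
                     .groups = "drop_last") |>
    dplyr::arrange(dplyr::desc(.data$relative_intensity), .data$slot,
                   .by_group = TRUE) |>
    dplyr::mutate(.rank = dplyr::row_number()) |>
    dplyr::ungroup() |>
    dplyr::select(dplyr::all_of(c("modified_sequence", "prec_z", "slot",
                                  ".rank")))
  peptide <- transitions |>
    dplyr::inner_join(ranked, by = c("modified_sequence", "prec_z",
                                     "slot")) |>
    dplyr::filter(.data$.rank <= top_k) |>
    dplyr::group_by(.data$modified_sequence, .data$prec_z, .data$protein,
                    .data$stripped_sequence, .data$sample) |>
    dplyr::summarise(intensity = sum(.data$intensity), .groups = "drop")

  protein <- peptide |>
    tidyr::separate_longer_delim("protein", delim = ";") |>
    dplyr::group_by(.data$protein, .data$sample) |>
    dplyr::summarise(intensity = sum(.data$intensity), .groups = "drop")

  list(peptide = structure(peptide, level = "peptide"),
       protein = structure(protein, level = "protein"))
}

#' Normalize protein abundances to a reference protein
#'
#' Divides each protein's intensity by the reference protein's intensity
#' in the same sample (so the reference row becomes 1 everywhere). The
#' usual reference is the added protease, trypsin, whose amount is
#' constant across samples.
#'
#' @param proteins Protein-level abundance tibble (columns `protein`,
#'   `sample`, `intensity`).
#' @param reference Protein id to normalize to.
#' @return The tibble with `intensity` replaced by the ratio.
#' @export
normalize_to_reference <- function(proteins, reference) {
  ref <- proteins[proteins$protein == reference, , drop = FALSE]
  bad <- setdiff(unique(proteins$sample), ref$sample[ref$intensity > 0])
  if (length(bad) > 0) {
    stop("reference protein '", reference,
         "' absent or zero in sample(s): ", paste(bad, collapse = ", "),
         call. = FALSE)
  }
  proteins |>
    dplyr::left_join(
      dplyr::select(ref, dplyr::all_of(c("sample", "intensity"))) |>
        dplyr::rename(.ref = "intensity"),
      by = "sample"
    ) |>
    dplyr::mutate(intensity = .data$intensity / .data$.ref) |>
    dplyr::select(-".ref")
}

#' Site-specific glycoform relative abundances
#'
#' All charge states of one glycoform are summed first; the fraction of
#' glycoform g in sample s is then its summed intensity divided by the
#' summed intensity of all detected forms (including the unmodified
#' peptide, when present) of the same site-peptide family. Families with
#' zero total signal in a sample get `NA` fractions, not 0/0.
#'
#' @param peptides Peptide-precursor abundance tibble (the `peptide`
#'   element of [rollup()]).
#' @param grouping Optional tibble mapping `modified_sequence` to
#'   `family` and `glycoform`; defaults to family = stripped sequence
#'   and glycoform = the glycan annotation of the modified sequence
#'   (`"unmodified"` when none). An explicit grouping pools peptide
#'   variants that differ only at the cleavage boundary into one family.
#' @return A tibble `family`, `glycoform`, `sample`, `intensity`,
#'   `fraction`, with fractions summing to 1 per (family, sample) where
#'   detected.
#' @export
glycoform_fractions <- function(peptides, grouping = NULL) {
  if (is.null(grouping)) {
    grouping <- peptides |>
      dplyr::distinct(.data$modified_sequence, .data$stripped_sequence) |>
      dplyr::mutate(
        family = .data$stripped_sequence,
        glycoform = .glycan_annotation(.data$modified_sequence)
      ) |>
      dplyr::select(dplyr::all_of(c("modified_sequence", "family",
                                    "glycoform")))
  }
  missing_map <- setdiff(unique(peptides$modified_sequence),
                         grouping$modified_sequence)
  if (length(missing_map) > 0) {
    stop("grouping lacks entries for: ",
         paste(utils::head(missing_map, 5), collapse = ", "),
         call. = FALSE)
  }
  peptides |>
    dplyr::inner_join(grouping, by = "modified_sequence") |>
    dplyr::group_by(.data$family, .data$glycoform, .data$sample) |>
    dplyr::summarise(intensity = sum(.data$intensity), .groups = "drop") |>
    dplyr::group_by(.data$family, .data$sample) |>
    dplyr::mutate(.total = sum(.data$intensity)) |>
    dplyr::ungroup() |>
    dplyr::mutate(
      fraction = dplyr::if_else(.data$.total > 0,
                                .data$intensity / .data$.total,
                                NA_real_)
    ) |>
    dplyr::select(-".total")
}

# glycan composition annotation at the end of a modified sequence, e.g.
# "VITGVPWYSSR[Hex6]" -> "Hex6"; "unmodified" when absent
.glycan_annotation <- function(modified_sequence) {
  g <- stringr::str_match(modified_sequence,
                          "\\[((?:HexNAc|dHex|Hex|Pent)\\d+)+\\]$")[, 1]
  out <- ifelse(is.na(g), "unmodified",
                stringr::str_sub(g, 2, -2))
  out
}
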