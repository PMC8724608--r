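# Identification-report parsing and PeakView-dialect ion-library
# construction.
#
# The identification report is a documented TSV dialect carrying the
# content a search-engine debug export provides, one row per fragment
# ion, grouped into PSMs by scan number:
#   scan, peptide, mods, glycan, linkage, z, observed_mz, score, rt_min,
#   protein, frag_series, frag_index, frag_remainder, frag_z,
#   frag_intensity
# `mods` encodes positional modifications as "pos:delta:label"
# semicolon-separated ("" = none); `frag_remainder` is the glycan
# composition still attached to the fragment ("" = none).

.REPORT_COLS <- c("scan", "peptide", "mods", "glycan", "linkage", "z",
                  "observed_mz", "score", "rt_min", "protein",
                  "frag_series", "frag_index", "frag_remainder", "frag_z",
                  "frag_intensity")

.PEAKVIEW_COLS <- c("Q1", "Q3", "RT_detected", "protein_name", "isotype",
                    "relative_intensity", "stripped_sequence",
                    "modification_sequence", "prec_z", "frg_type", "frg_z",
                    "frg_nr", "shared", "decoy")

.parse_mods <- function(s) {
  if (is.na(s) || !nzchar(s)) {
    return(tibble::tibble(position = integer(), delta = double(),
                          label = character()))
  }
  parts <- strsplit(strsplit(s, ";", fixed = TRUE)[[1]], ":", fixed = TRUE)
  tibble::tibble(
    position = as.integer(purrr::map_chr(parts, 1)),
    delta = as.double(purrr::map_chr(parts, 2)),
    label = purrr::map_chr(parts, 3)
  )
}

.format_mods <- function(m) {
  if (is.null(m) || nrow(m) == 0) return("")
  paste(sprintf("%d:%s:%s", m$position, format(m$delta), m$label),
        collapse = ";")
}

# display form: sequence with "[+delta]" after modified residues and the
# glycan composition appended in brackets
.modified_sequence <- function(sequence, mods, glycan_str) {
  s <- sequence
  if (!is.null(mods) && nrow(mods) > 0) {
    aa <- strsplit(sequence, "")[[1]]
    for (i in order(mods$position, decreasing = TRUE)) {
      pos <- mods$position[i]
      aa[pos] <- sprintf("%s[%+.5f]", aa[pos], mods$delta[i])
    }
    s <- paste(aa, collapse = "")
  }
  if (nzchar(glycan_str)) s <- paste0(s, "[", glycan_str, "]")
  s
}

#' Read a glycopeptide identification report
#'
#' Parses the tab-separated identification dialect (one row per fragment
#' ion, PSMs grouped by scan number) into a nested PSM tibble. Malformed
#' rows — unparseable glycan tokens, non-positive charges, unknown
#' residues — are collected into a rejects table attached as
#' `attr(x, "rejects")`, not silently dropped.
#'
#' @param path Path to the TSV report.
#' @return A tibble with one row per PSM (`scan`, `peptide`, `mods`
#'   list-column, `glycan`, `linkage`, `z`, `observed_mz`, `score`,
#'   `rt_min`, `protein`) and a `fragments` list-column of per-fragment
#'   tibbles (`frag_series`, `frag_index`, `frag_remainder`, `frag_z`,
#'   `frag_intensity`). Rejected rows are in `attr(, "rejects")`.
#' @export
read_id_report <- function(path) {
  raw <- readr::read_tsv(path, col_types = readr::cols(
    scan = readr::col_integer(), peptide = readr::col_character(),
    mods = readr::col_character(), glycan = readr::col_character(),
    linkage = readr::col_character(), z = readr::col_integer(),
    observed_mz = readr::col_double(), score = readr::col_double(),
    rt_min = readr::col_double(), protein = readr::col_character(),
    frag_series = readr::col_character(),
    frag_index = readr::col_integer(),
    frag_remainder = readr::col_character(),
    frag_z = readr::col_integer(),
    frag_intensity = readr::col_double()
  ), na = "NA", progress = FALSE)
  missing_cols <- setdiff(.REPORT_COLS, names(raw))
  if (length(missing_cols) > 0) {
    stop("identification report is missing mandatory column(s): ",
         paste(missing_cols, collapse = ", "), call. = FALSE)
  }
  raw$mods[is.na(raw$mods)] <- ""
  raw$glycan[is.na(raw$glycan)] <- ""
  raw$frag_remainder[is.na(raw$frag_remainder)] <- ""

  check_row <- function(glycan, linkage, z, peptide, frag_remainder) {
    ok <- try({
      parse_glycan(glycan)
      parse_glycan(frag_remainder)
      peptide_neutral_mass(peptide)
    }, silent = TRUE)
    if (inherits(ok, "try-error")) {
      return(conditionMessage(attr(ok, "condition")))
    }
    if (is.na(z) || z < 1) return("charge must be >= 1")
    if (!linkage %in% c("N", "O", "none")) {
      return(paste0("unknown linkage '", linkage, "'"))
    }
    NA_character_
  }
  reason <- purrr::pmap_chr(
    raw[c("glycan", "linkage", "z", "peptide", "frag_remainder")],
    check_row
  )
  rejects <- dplyr::mutate(raw[!is.na(reason), , drop = FALSE],
                           reason = reason[!is.na(reason)])
  good <- raw[is.na(reason), , drop = FALSE]

  psms <- good |>
    tidyr::nest(fragments = c("frag_series", "frag_index",
                              "frag_remainder", "frag_z",
                              "frag_intensity")) |>
    dplyr::mutate(mods = purrr::map(.data$mods, .parse_mods))
  attr(psms, "rejects") <- rejects
  psms
}

#' Build a transition library from validated PSMs
#'
#' For every unique (modified sequence, precursor charge) the
#' best-scoring PSM is kept (ties broken by lowest scan number); Q1 is
#' the theoretical precursor m/z of peptide + glycan; each reported
#' fragment is matched to the theoretical fragment model to obtain its
#' Q3 and library slot. Fragments whose slot is excluded (b/y + HexNAc at
#' positions 1–3) are dropped. When two distinct fragments collide on one
#' slot (possible for the repurposed `a`-slots above a3), the one with
#' higher reported intensity is retained and the collision is recorded in
#' `attr(, "slot_collisions")`. Duplicate transitions — identical
#' (modified sequence, precursor charge, slot, fragment charge) — keep
#' the highest intensity.
#'
#' @param psms PSM tibble from [read_id_report()] (or the synthetic
#'   generator).
#' @param validated_scans Optional integer vector of scans that passed
#'   validation; scans absent from the report produce a warning and are
#'   skipped. `NULL` keeps all PSMs.
#' @param max_transitions Maximum transitions kept per precursor, by
#'   decreasing intensity (default unlimited; selection to the top 6
#'   happens at quantification).
#' @return An ion-library tibble with columns `q1`, `q3`, `rt`,
#'   `protein`, `slot`, `relative_intensity`, `stripped_sequence`,
#'   `modified_sequence`, `prec_z`, `frg_type`, `frg_z`, `frg_nr`,
#'   `shared`, `decoy`. All m/z, RT and intensity values are rounded to 5
#'   decimals.
#' @export
build_library <- function(psms, validated_scans = NULL,
                          max_transitions = Inf) {
  if (!is.null(validated_scans)) {
    absent <- setdiff(validated_scans, psms$scan)
    if (length(absent) > 0) {
      warning("validated scan(s) absent from report, skipped: ",
              paste(absent, collapse = ", "), call. = FALSE)
    }
    psms <- psms[psms$scan %in% validated_scans, , drop = FALSE]
  }
  if (nrow(psms) == 0) {
    return(.empty_library())
  }

  psms <- psms |>
    dplyr::mutate(
      glycan_str = format_glycan(.data$glycan),
      modified_sequence = purrr::pmap_chr(
        list(.data$peptide, .data$mods, .data$glycan_str),
        .modified_sequence
      )
    )
  best <- psms |>
    dplyr::group_by(.data$modified_sequence, .data$z) |>
    dplyr::arrange(dplyr::desc(.data$score), .data$scan,
                   .by_group = TRUE) |>
    dplyr::slice(1L) |>
    dplyr::ungroup()

  one_psm <- function(peptide, mods, glycan_str, linkage, z, rt_min,
                      protein, fragments, modified_sequence, ...) {
    glycan <- parse_glycan(glycan_str)
    neutral <- peptide_neutral_mass(peptide, mods) + glycan_mass(glycan)
    q1 <- precursor_mz(neutral, z)
    link <- if (identical(linkage, "N")) "N" else "O"
    site <- .default_site(peptide, link, glycan_str)
    theo <- enumerate_fragments(peptide, glycan, link, site = site,
                                mods = mods)
    obs <- dplyr::inner_join(
      fragments, theo,
      by = c(frag_series = "series", frag_index = "index",
             frag_remainder = "glycan_remainder", frag_z = "charge")
    )
    obs <- obs[!obs$excluded & !is.na(obs$slot), , drop = FALSE]
    if (nrow(obs) == 0) return(NULL)
    tibble::tibble(
      q1 = q1, q3 = obs$mz, rt = rt_min, protein = protein,
      slot = obs$slot, relative_intensity = obs$frag_intensity,
      stripped_sequence = toupper(peptide),
      modified_sequence = modified_sequence,
      prec_z = as.integer(z), frg_z = obs$frag_z
    )
  }
  recs <- purrr::pmap(best, one_psm) |> dplyr::bind_rows()
  if (nrow(recs) == 0) return(.empty_library())

  # resolve slot collisions (distinct fragments sharing one slot label
  # within a precursor/fragment-charge) by keeping the higher intensity
  key <- c("modified_sequence", "prec_z", "slot", "frg_z")
  dup <- recs |> dplyr::count(dplyr::across(dplyr::all_of(key))) |>
    dplyr::filter(.data$n > 1)
  collisions <- dplyr::semi_join(recs, dup, by = key)
  recs <- recs |>
    dplyr::group_by(dplyr::across(dplyr::all_of(key))) |>
    dplyr::arrange(dplyr::desc(.data$relative_intensity),
                   .by_group = TRUE) |>
    dplyr::slice(1L) |>
    dplyr::ungroup()
  if (nrow(collisions) > 0) {
    message(nrow(collisions) - nrow(dup),
            " slot collision(s) resolved by intensity")
  }

  if (is.finite(max_transitions)) {
    recs <- recs |>
      dplyr::group_by(.data$modified_sequence, .data$prec_z) |>
      dplyr::arrange(dplyr::desc(.data$relative_intensity),
                     .by_group = TRUE) |>
      dplyr::slice_head(n = max_transitions) |>
      dplyr::ungroup()
  }

  parsed <- parse_slot(recs$slot)
  out <- recs |>
    dplyr::mutate(
      q1 = round(.data$q1, 5), q3 = round(.data$q3, 5),
      rt = round(.data$rt, 5),
      relative_intensity = round(.data$relative_intensity, 5),
      frg_type = substr(.data$slot, 1, 1),
      frg_nr = parsed$index + ifelse(parsed$class == "Y", 1L, 0L),
      shared = FALSE, decoy = FALSE
    ) |>
    dplyr::select(dplyr::all_of(c(
      "q1", "q3", "rt", "protein", "slot", "relative_intensity",
      "stripped_sequence", "modified_sequence", "prec_z", "frg_type",
      "frg_z", "frg_nr", "shared", "decoy"
    ))) |>
    dplyr::arrange(.data$modified_sequence, .data$prec_z,
                   dplyr::desc(.data$relative_intensity), .data$slot)
  attr(out, "slot_collisions") <- collisions
  out
}

# a glycosylation site consistent with the linkage class, used when the
# report does not localise the site: first N of an N-X-S/T sequon for
# N-linked; first hydroxyproline, else first S/T, for O-linked; NA when
# no eligible residue exists or the peptide is unglycosylated
.default_site <- function(peptide, linkage, glycan_str) {
  if (!nzchar(glycan_str)) return(NA_integer_)
  aa <- strsplit(peptide, "")[[1]]
  n <- length(aa)
  if (linkage == "N") {
    for (i in seq_len(max(0, n - 2))) {
      if (aa[i] == "N" && aa[i + 1] != "P" &&
          toupper(aa[i + 2]) %in% c("S", "T")) {
        return(i)
      }
    }
    return(NA_integer_)
  }
  hyp <- which(aa == "p")
  if (length(hyp) > 0) return(hyp[1])
  st <- which(aa %in% c("S", "T"))
  if (length(st) > 0) st[1] else NA_integer_
}

.empty_library <- function() {
  tibble::tibble(
    q1 = double(), q3 = double(), rt = double(), protein = character(),
    slot = character(), relative_intensity = double(),
    stripped_sequence = character(), modified_sequence = character(),
    prec_z = integer(), frg_type = character(), frg_z = integer(),
    frg_nr = integer(), shared = logical(), decoy = logical()
  )
}

#' Write / read a PeakView-dialect transition library
#'
#' The on-disk format is a tab-delimited UTF-8 text file with Unix
#' newlines and the fixed 14-column schema `Q1, Q3, RT_detected,
#' protein_name, isotype, relative_intensity, stripped_sequence,
#' modification_sequence, prec_z, frg_type, frg_z, frg_nr, shared,
#' decoy`; floats carry 5 decimals. The `isotype` column carries the
#' library slot label. `read_peakview(write_peakview(lib))` reproduces
#' `lib` field for field.
#'
#' @param lib An ion-library tibble from [build_library()].
#' @param path Output (input) file path.
#' @return `write_peakview` returns `path` invisibly; `read_peakview`
#'   returns the ion-library tibble.
#' @export
write_peakview <- function(lib, path) {
  out <- tibble::tibble(
    Q1 = sprintf("%.5f", lib$q1),
    Q3 = sprintf("%.5f", lib$q3),
    RT_detected = sprintf("%.5f", lib$rt),
    protein_name = lib$protein,
    isotype = lib$slot,
    relative_intensity = sprintf("%.5f", lib$relative_intensity),
    stripped_sequence = lib$stripped_sequence,
    modification_sequence = lib$modified_sequence,
    prec_z = lib$prec_z,
    frg_type = lib$frg_type,
    frg_z = lib$frg_z,
    frg_nr = lib$frg_nr,
    shared = lib$shared,
    decoy = lib$decoy
  )
  readr::write_tsv(out, path, progress = FALSE)
  invisible(path)
}

#' @rdname write_peakview
#' @export
read_peakview <- function(path) {
  raw <- readr::read_tsv(path, col_types = readr::cols(
    Q1 = readr::col_double(), Q3 = readr::col_double(),
    RT_detected = readr::col_double(),
    protein_name = readr::col_character(),
    isotype = readr::col_character(),
    relative_intensity = readr::col_double(),
    stripped_sequence = readr::col_character(),
    modification_sequence = readr::col_character(),
    prec_z = readr::col_integer(), frg_type = readr::col_character(),
    frg_z = readr::col_integer(), frg_nr = readr::col_integer(),
    shared = readr::col_logical(), decoy = readr::col_logical()
  ), progress = FALSE)
  missing_cols <- setdiff(.PEAKVIEW_COLS, names(raw))
  if (length(missing_cols) > 0) {
    stop("library file is missing column(s): ",
         paste(missing_cols, collapse = ", "), call. = FALSE)
  }
  tibble::tibble(
    q1 = raw$Q1, q3 = raw$Q3, rt = raw$RT_detected,
    protein = raw$protein_name, slot = raw$isotype,
    relative_intensity = raw$relative_intensity,
    stripped_sequence = raw$stripped_sequence,
    modified_sequence = raw$modification_sequence,
    prec_z = raw$prec_z, frg_type = raw$frg_type, frg_z = raw$frg_z,
    frg_nr = raw$frg_nr, shared = raw$shared, decoy = raw$decoy
  )
}

#' Merge a glycopeptide library with a peptide-centric library
#'
#' Union of the two libraries under the duplicate-transition key
#' (modified sequence, precursor charge, slot, fragment charge). When
#' both libraries carry the same key, the glycopeptide record wins; the
#' displaced peptide records are attached as `attr(, "conflicts")`.
#'
#' @param glyco,peptide Ion-library tibbles.
#' @return The merged ion-library tibble.
#' @export
merge_libraries <- function(glyco, peptide) {
  key <- c("modified_sequence", "prec_z", "slot", "frg_z")
  conflicts <- dplyr::semi_join(peptide, glyco, by = key)
  merged <- dplyr::bind_rows(glyco, dplyr::anti_join(peptide, glyco,
                                                     by = key))
  if (nrow(conflicts) > 0) {
    message(nrow(conflicts),
            " conflicting transition(s): glycopeptide record retained")
  }
  attr(merged, "conflicts") <- conflicts
  merged
}
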