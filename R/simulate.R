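# Seeded synthetic-data generator.
#
# Emulates the glycoproteome structure of sparkling wine: yeast
# O-glycopeptides carrying Hex1-9 oligomannose, a grape
# hydroxyproline-linked O-glycopeptide carrying Pent1-6 arabinose, a
# grape N-glycopeptide with plant-type compositions, and unmodified
# reference peptides from the added trypsin. The three worked
# glycopeptides (VITGVPWYSSR, VNLVELGVYVSDIR, VVRPppTpKPpT) are part of
# the default inventory so fixtures double as mass-arithmetic checks.
# All outputs are deterministic functions of the config seed.

#' Default synthetic glycopeptide inventory
#'
#' One row per (peptide, glycoform). The grape N-glycopeptide sequence
#' TGNLSEVLAK is a synthetic stand-in constructed to carry an N-X-S/T
#' sequon; the other sequences are real wine-glycoproteome peptides.
#'
#' @return A tibble with columns `peptide`, `protein`, `linkage`
#'   (`"O"`, `"N"` or `"none"`), `glycan`, `site`.
#' @export
sim_peptides <- function() {
  dplyr::bind_rows(
    # yeast O-glycopeptide, Hex1-9 (site S9)
    tibble::tibble(peptide = "VITGVPWYSSR", protein = "Pau5",
                   linkage = "O", glycan = paste0("Hex", 1:9), site = 9L),
    # shared seripauperin peptide, unmodified + Hex1-4 (site S11)
    tibble::tibble(peptide = "VNLVELGVYVSDIR", protein = "Pau1;Pau5",
                   linkage = "O", glycan = c("", paste0("Hex", 1:4)),
                   site = 11L),
    # grape hydroxyproline O-glycopeptide, Pent1-6 (site p5)
    tibble::tibble(peptide = "VVRPppTpKPpT",
                   protein = "PRP_Vitvi",
                   linkage = "O", glycan = paste0("Pent", 1:6), site = 5L),
    # synthetic grape N-glycopeptide (sequon N3-L-S5)
    tibble::tibble(peptide = "TGNLSEVLAK", protein = "Inv_Vitvi",
                   linkage = "N",
                   glycan = c("HexNAc1", "HexNAc2Hex3dHex1Pent1",
                              "HexNAc3Hex3dHex1Pent1"),
                   site = 3L),
    # unmodified reference peptides (porcine trypsin autolysis)
    tibble::tibble(peptide = c("VATVSLPR", "LSSPATLNSR"),
                   protein = "trypsin", linkage = "none", glycan = "",
                   site = NA_integer_)
  )
}

#' Simulation configuration
#'
#' Bundles the study-design parameters of the synthetic glycoproteome:
#' technical triplicates of two conditions, 10% intensity coefficient of
#' variation, and precursor mass errors drawn from N(-15, 3) ppm
#' (matching the systematic negative errors of a TripleTOF acquisition).
#'
#' @param seed Integer seed; the same seed and config give identical
#'   outputs.
#' @param peptides Glycopeptide inventory, defaults to [sim_peptides()].
#' @param conditions Condition labels (default `c("A", "B")`).
#' @param n_replicates Replicates per condition (default 3).
#' @param cv Intensity coefficient of variation (default 0.10).
#' @param ppm_mean,ppm_sd Precursor ppm-error distribution (default -15,
#'   3).
#' @param noise_peaks Random noise peaks added per simulated spectrum
#'   (default 30).
#' @param dropout Probability that a transition intensity is zeroed in a
#'   sample (default 0).
#' @param effects Planted fold changes: tibble with columns
#'   `stripped_sequence`, `glycoform`, `condition`, `fold` (default
#'   none).
#' @return A `sim_config` list.
#' @export
sim_config <- function(seed = 1, peptides = sim_peptides(),
                       conditions = c("A", "B"), n_replicates = 3,
                       cv = 0.10, ppm_mean = -15, ppm_sd = 3,
                       noise_peaks = 30, dropout = 0,
                       effects = NULL) {
  if (is.null(effects)) {
    effects <- tibble::tibble(stripped_sequence = character(),
                              glycoform = character(),
                              condition = character(), fold = double())
  }
  structure(list(seed = as.integer(seed), peptides = peptides,
                 conditions = conditions,
                 n_replicates = as.integer(n_replicates), cv = cv,
                 ppm_mean = ppm_mean, ppm_sd = ppm_sd,
                 noise_peaks = as.integer(noise_peaks), dropout = dropout,
                 effects = effects),
            class = "sim_config")
}

#' Sample sheet for a simulation config
#'
#' @param cfg A [sim_config()].
#' @return A design tibble with columns `sample` and `condition`.
#' @export
sim_design <- function(cfg) {
  tidyr::crossing(condition = cfg$conditions,
                  replicate = seq_len(cfg$n_replicates)) |>
    dplyr::mutate(sample = paste0(.data$condition, "_",
                                  .data$replicate)) |>
    dplyr::select(dplyr::all_of(c("sample", "condition")))
}

# smallest charge in 2..4 whose precursor m/z lies in the acquisition
# range; falls back to 2
.pick_charge <- function(neutral, low = 400, high = 1250) {
  for (z in 2:4) {
    mz <- precursor_mz(neutral, z)
    if (mz >= low && mz <= high) return(z)
  }
  2L
}

#' Simulate a glycopeptide identification report
#'
#' Emits one PSM per inventory row in the identification-report dialect
#' of [read_id_report()]: the observed precursor m/z is the theoretical
#' m/z perturbed by a drawn ppm error, fragment rows come from the
#' theoretical fragment model (slot-eligible fragments at 1+) with
#' log-normal reference intensities, and a ground-truth table carries
#' the theoretical values.
#'
#' @param cfg A [sim_config()].
#' @return A list with `report` (flat TSV-dialect tibble, one row per
#'   fragment) and `truth` (per-PSM theoretical masses, m/z and drawn
#'   ppm errors).
#' @export
simulate_identifications <- function(cfg) {
  withr::with_seed(cfg$seed, {
    inv <- cfg$peptides
    n <- nrow(inv)
    neutral <- peptide_neutral_mass(inv$peptide) + glycan_mass(inv$glycan)
    z <- purrr::map_int(neutral, .pick_charge)
    theo_mz <- precursor_mz(neutral, z)
    ppm <- stats::rnorm(n, cfg$ppm_mean, cfg$ppm_sd)
    truth <- tibble::tibble(
      scan = seq_len(n) * 100L,
      peptide = inv$peptide, protein = inv$protein,
      linkage = inv$linkage, glycan = inv$glycan, site = inv$site,
      neutral_mass = neutral, z = z, theoretical_mz = theo_mz,
      ppm_error = ppm,
      observed_mz = theo_mz * (1 + ppm / 1e6),
      score = round(stats::runif(n, 200, 600), 1),
      rt_min = round(stats::runif(n, 4, 16), 2)
    )
    frag_rows <- purrr::pmap(truth, function(scan, peptide, protein,
                                             linkage, glycan, site, z,
                                             observed_mz, score, rt_min,
                                             ...) {
      link <- if (linkage == "N") "N" else "O"
      fr <- enumerate_fragments(peptide, glycan, link, site = site)
      fr <- fr[!fr$excluded & fr$charge == 1L, , drop = FALSE]
      tibble::tibble(
        scan = scan, peptide = peptide, mods = "", glycan = glycan,
        linkage = linkage, z = z, observed_mz = observed_mz,
        score = score, rt_min = rt_min, protein = protein,
        frag_series = fr$series, frag_index = fr$index,
        frag_remainder = fr$glycan_remainder, frag_z = fr$charge,
        frag_intensity = round(stats::rlnorm(nrow(fr), log(1000), 0.8), 3)
      )
    })
    list(report = dplyr::bind_rows(frag_rows), truth = truth)
  })
}

#' Simulate centroided MS2 spectra with planted evidence
#'
#' For each PSM of [simulate_identifications()] plants oxonium, Y and
#' b/y peaks from the fragment model, adds uniform noise peaks, and can
#' delete whole ion classes per scan to construct known-reject cases.
#'
#' @param cfg A [sim_config()].
#' @param ids Output of [simulate_identifications()] (regenerated from
#'   `cfg` when `NULL`).
#' @param drop_classes Named list `scan -> character vector` of classes
#'   to delete among `"oxonium"`, `"anchor"` (the Y0/Y1 anchor ion),
#'   `"b"`, `"y"`.
#' @return A tibble with one row per scan: `scan`, `rt`, `precursor_mz`,
#'   `precursor_z` and a `peaks` list-column of (mz, intensity) tibbles
#'   sorted by ascending m/z.
#' @export
simulate_spectra <- function(cfg, ids = NULL, drop_classes = list()) {
  if (is.null(ids)) ids <- simulate_identifications(cfg)
  withr::with_seed(cfg$seed + 1L, {
    truth <- ids$truth[ids$truth$linkage != "none", , drop = FALSE]
    spectra <- purrr::pmap(truth, function(scan, peptide, protein,
                                           linkage, glycan, site, z,
                                           observed_mz, rt_min, ...) {
      link <- if (linkage == "N") "N" else "O"
      fr <- enumerate_fragments(peptide, glycan, link, site = site)
      fr1 <- fr[fr$charge == 1L, , drop = FALSE]
      anchor_idx <- if (link == "O") 0L else 1L
      drop <- drop_classes[[as.character(scan)]] %||% character()

      targets <- list()
      oxo <- oxonium_table(glycan, link)
      if (!"oxonium" %in% drop) targets$oxonium <- oxo$mz
      anchor <- fr1$mz[fr1$series == "Y" & fr1$index == anchor_idx]
      if (!"anchor" %in% drop) targets$anchor <- anchor
      plain_b <- fr1$mz[fr1$series == "b" &
                          !nzchar(fr1$glycan_remainder)]
      plain_y <- fr1$mz[fr1$series == "y" &
                          !nzchar(fr1$glycan_remainder)]
      if (!"b" %in% drop) targets$b <- plain_b
      if (!"y" %in% drop) targets$y <- plain_y

      planted <- unlist(targets, use.names = FALSE)
      noise_mz <- stats::runif(cfg$noise_peaks, 100, 2000)
      peaks <- tibble::tibble(
        mz = c(planted, noise_mz),
        intensity = c(stats::rlnorm(length(planted), log(500), 0.6),
                      stats::rlnorm(cfg$noise_peaks, log(50), 0.8))
      ) |> dplyr::arrange(.data$mz)
      tibble::tibble(scan = scan, rt = rt_min,
                     precursor_mz = observed_mz, precursor_z = z,
                     peaks = list(peaks))
    })
    dplyr::bind_rows(spectra)
  })
}

#' Simulate per-sample DIA transition tables
#'
#' Ground-truth transition intensities are the product of a per-family
#' base abundance (log-normal across peptide families, declining
#' geometrically by 0.8 per step along the glycoform-size series), the
#' library's relative
#' fragment intensities, and any planted condition fold changes; observed
#' intensities multiply in mean-1 log-normal noise at the configured CV
#' and are zeroed at the dropout rate. `cv = 0` with no dropout returns
#' the truth exactly.
#'
#' @param cfg A [sim_config()].
#' @param lib An ion library built from this config's identifications
#'   (regenerated when `NULL`).
#' @return A list with `samples` (long tibble: `sample`,
#'   `modified_sequence`, `prec_z`, `slot`, `intensity`), `truth`
#'   (noiseless expected intensities per transition and sample), and
#'   `design` (the sample sheet).
#' @export
simulate_dia <- function(cfg, lib = NULL) {
  if (is.null(lib)) {
    ids <- simulate_identifications(cfg)
    lib <- build_library(ids$report |> .nest_report())
  }
  design <- sim_design(cfg)
  withr::with_seed(cfg$seed + 2L, {
    # per-family base abundance, with a geometrically declining profile
    # across the glycoform series (larger glycans are less abundant)
    fam <- lib |>
      dplyr::distinct(.data$stripped_sequence)
    fam$fam_base <- stats::rlnorm(nrow(fam), log(1e5), 0.5)
    prec <- lib |>
      dplyr::distinct(.data$modified_sequence, .data$prec_z,
                      .data$stripped_sequence) |>
      dplyr::mutate(
        glycoform = .glycan_annotation(.data$modified_sequence),
        .gmass = glycan_mass(dplyr::if_else(.data$glycoform ==
                                              "unmodified", "",
                                            .data$glycoform))
      ) |>
      dplyr::inner_join(fam, by = "stripped_sequence") |>
      dplyr::group_by(.data$stripped_sequence) |>
      dplyr::arrange(.data$.gmass, .by_group = TRUE) |>
      dplyr::mutate(base = .data$fam_base *
                      0.8^(dplyr::row_number() - 1)) |>
      dplyr::ungroup() |>
      dplyr::select(-".gmass", -"fam_base")

    grid <- lib |>
      dplyr::select(dplyr::all_of(c("modified_sequence", "prec_z", "slot",
                                    "stripped_sequence",
                                    "relative_intensity"))) |>
      dplyr::distinct() |>
      dplyr::inner_join(prec, by = c("modified_sequence", "prec_z",
                                     "stripped_sequence")) |>
      tidyr::crossing(design)
    grid <- grid |>
      dplyr::left_join(cfg$effects,
                       by = c("stripped_sequence", "glycoform",
                              "condition")) |>
      dplyr::mutate(
        fold = tidyr::replace_na(.data$fold, 1),
        expected = .data$base * .data$fold *
          .data$relative_intensity /
          max(lib$relative_intensity)
      )
    sigma <- sqrt(log(1 + cfg$cv^2))
    noise <- if (cfg$cv > 0) {
      stats::rlnorm(nrow(grid), -sigma^2 / 2, sigma)
    } else {
      rep(1, nrow(grid))
    }
    keep <- if (cfg$dropout > 0) {
      stats::runif(nrow(grid)) >= cfg$dropout
    } else {
      rep(TRUE, nrow(grid))
    }
    grid$intensity <- grid$expected * noise * keep
    list(
      samples = grid |>
        dplyr::select(dplyr::all_of(c("sample", "modified_sequence",
                                      "prec_z", "slot", "intensity"))),
      truth = grid |>
        dplyr::select(dplyr::all_of(c("sample", "condition",
                                      "modified_sequence", "prec_z",
                                      "slot", "expected"))),
      design = design
    )
  })
}

# nest a flat dialect report tibble into the PSM shape of
# read_id_report() without a filesystem round-trip
.nest_report <- function(report) {
  report |>
    tidyr::nest(fragments = c("frag_series", "frag_index",
                              "frag_remainder", "frag_z",
                              "frag_intensity")) |>
    dplyr::mutate(mods = purrr::map(.data$mods, .parse_mods))
}

#' Write a simulated identification report to a TSV file
#'
#' @param report The `report` element of [simulate_identifications()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_id_report <- function(report, path) {
  readr::write_tsv(report, path, progress = FALSE)
  invisible(path)
}
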