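test_that("window schemes tile the acquisition range", {
  w <- make_windows(400, 1250, 26, 1)
  expect_equal(nrow(w), 34)
  expect_equal(w$start[1], 400)
  expect_true(w$end[34] >= 1250)
  expect_equal(nrow(make_windows(400, 426, 26, 1)), 1)
  w4 <- make_windows(0, 100, 26, 1)
  expect_equal(w4$start, c(0, 25, 50, 75))
  expect_error(make_windows(400, 1250, 1, 26), "overlap")
  expect_error(make_windows(1250, 400, 26, 1), "high")
})

test_that("random window schemes cover their range with fixed overlap", {
  set.seed(51)
  for (i in 1:20) {
    low <- runif(1, 100, 500)
    width <- runif(1, 5, 50)
    overlap <- runif(1, 0, width * 0.9)
    high <- low + runif(1, width, 900)
    w <- make_windows(low, high, width, overlap)
    # brute force: every precursor m/z in [low, high] is inside a window
    for (q in seq(low, high, length.out = 50)) {
      expect_true(any(w$start <= q & q <= w$end))
    }
    expect_true(all(abs((w$end - w$start) - width) < 1e-9))
    if (nrow(w) > 1) {
      expect_true(all(abs((w$end[-nrow(w)] - w$start[-1]) - overlap)
                      < 1e-9))
    }
  }
})

small_lib <- function() {
  build_library(glycodia:::.nest_report(tibble::tibble(
    scan = 100L, peptide = "VITGVPWYSSR", mods = "", glycan = "Hex6",
    linkage = "O", z = 3L, observed_mz = 746.3205, score = 500,
    rt_min = 10, protein = "Pau5",
    frag_series = c("b", "y"), frag_index = c(3L, 6L),
    frag_remainder = "", frag_z = 1L, frag_intensity = c(300, 900)
  )))
}

test_that("peak-stream extraction sums signal inside the XIC tolerances", {
  lib <- small_lib()
  q3 <- lib$q3[lib$slot == "y6"]
  stream <- tibble::tibble(
    sample = "s1",
    mz = c(q3, q3 * (1 + 100e-6), q3),        # on-target, 100 ppm off,
    rt_min = c(10.2, 10.0, 16.0),             # and outside the RT window
    intensity = c(1000, 500, 800)
  )
  q <- quantify_transitions(lib, stream, rt_window = 6, xic_ppm = 75)
  expect_equal(q$intensity[q$slot == "y6"], 1000)
  expect_equal(q$intensity[q$slot == "b3"], 0)
})

test_that("acquisition-window indices gate the extraction", {
  lib <- small_lib() # Q1 746.33 -> window 14 of the default scheme
  q3 <- lib$q3[lib$slot == "y6"]
  stream <- tibble::tibble(
    sample = "s1", mz = q3, rt_min = 10, intensity = 1000,
    q1_window = c(14L, 2L)
  )
  q <- quantify_transitions(lib, stream)
  expect_equal(q$intensity[q$slot == "y6"], 1000)
})

test_that("transition tables from the generator are recovered exactly", {
  cfg <- sim_config(seed = 7)
  ids <- simulate_identifications(cfg)
  lib <- suppressMessages(
    build_library(glycodia:::.nest_report(ids$report))
  )
  dia <- simulate_dia(cfg, lib)
  q <- quantify_transitions(lib, dia$samples)
  cmp <- dplyr::inner_join(
    q, dia$samples,
    by = c("modified_sequence", "prec_z", "slot", "sample"),
    suffix = c("", ".in")
  )
  expect_equal(cmp$intensity, cmp$intensity.in, tolerance = 1e-9)
})

test_that("rollup sums the top-k transitions by library intensity", {
  lib <- small_lib()
  q <- tibble::tibble(
    modified_sequence = "VITGVPWYSSR[Hex6]", prec_z = 3L,
    slot = c("b3", "y6"), protein = "Pau5",
    stripped_sequence = "VITGVPWYSSR", sample = "s1",
    intensity = c(10, 20)
  )
  ru <- rollup(q, lib, top_k = 6)
  expect_equal(ru$peptide$intensity, 30)
  ru1 <- rollup(q, lib, top_k = 1) # keeps y6, the higher library ref
  expect_equal(ru1$peptide$intensity, 20)
})

test_that("eight equal transitions cap at the six highest-ranked", {
  frag <- tibble::tibble(
    scan = 1L, peptide = "TGNLSEVLAK", mods = "", glycan = "",
    linkage = "none", z = 2L, observed_mz = 500, score = 100, rt_min = 5,
    protein = "P1",
    frag_series = rep(c("b", "y"), each = 4),
    frag_index = rep(c(3L, 4L, 5L, 6L), 2),
    frag_remainder = "", frag_z = 1L, frag_intensity = 1
  )
  lib <- build_library(glycodia:::.nest_report(frag))
  q <- tibble::tibble(
    modified_sequence = unique(lib$modified_sequence), prec_z = 2L,
    slot = lib$slot, protein = "P1", stripped_sequence = "TGNLSEVLAK",
    sample = "s1", intensity = 1
  )
  expect_equal(rollup(q, lib, top_k = 6)$peptide$intensity, 6)
})

test_that("shared peptides contribute fully to every parent protein", {
  lib <- small_lib()
  lib$protein <- "Pau1;Pau5"
  q <- tibble::tibble(
    modified_sequence = "VITGVPWYSSR[Hex6]", prec_z = 3L,
    slot = c("b3", "y6"), protein = "Pau1;Pau5",
    stripped_sequence = "VITGVPWYSSR", sample = "s1", intensity = c(1, 2)
  )
  prot <- rollup(q, lib)$protein
  expect_equal(nrow(prot), 2)
  expect_equal(prot$intensity, c(3, 3))
})

test_that("reference normalization divides per sample", {
  m <- tibble::tibble(
    protein = rep(c("trypsin", "Pau5"), each = 2),
    sample = rep(c("s1", "s2"), 2),
    intensity = c(2, 4, 4, 4)
  )
  n <- normalize_to_reference(m, "trypsin")
  expect_equal(n$intensity[n$protein == "Pau5"], c(2, 1))
  expect_equal(n$intensity[n$protein == "trypsin"], c(1, 1))
  # scale invariance: scaling one sample's column leaves ratios unchanged
  m2 <- m
  m2$intensity[m2$sample == "s2"] <- m2$intensity[m2$sample == "s2"] * 7
  expect_equal(normalize_to_reference(m2, "trypsin")$intensity,
               n$intensity)
  # elementwise oracle on a random matrix
  set.seed(61)
  big <- tidyr::crossing(protein = c("ref", paste0("P", 1:9)),
                         sample = paste0("s", 1:3)) |>
    dplyr::mutate(intensity = runif(dplyr::n(), 1, 100))
  nb <- normalize_to_reference(big, "ref")
  for (k in seq_len(nrow(nb))) {
    ref_val <- big$intensity[big$protein == "ref" &
                               big$sample == nb$sample[k]]
    orig <- big$intensity[big$protein == nb$protein[k] &
                            big$sample == nb$sample[k]]
    expect_equal(nb$intensity[k], orig / ref_val)
  }
  m_bad <- m
  m_bad$intensity[1] <- 0
  expect_error(normalize_to_reference(m_bad, "trypsin"), "s1")
})

test_that("glycoform fractions normalize within site-peptide families", {
  pep <- tibble::tibble(
    modified_sequence = c("AGSR[Hex2]", "AGSR[Hex3]"),
    prec_z = 2L, protein = "P", stripped_sequence = "AGSR",
    sample = "s1", intensity = c(100, 300)
  )
  fr <- glycoform_fractions(pep)
  expect_equal(sort(fr$fraction), c(0.25, 0.75))
  # single detected glycoform -> 1
  fr1 <- glycoform_fractions(pep[1, ])
  expect_equal(fr1$fraction, 1)
})

test_that("charge states of one glycoform are pooled before normalizing", {
  pep <- tibble::tibble(
    modified_sequence = c("AGSR[Hex2]", "AGSR[Hex2]", "AGSR[Hex3]"),
    prec_z = c(2L, 3L, 2L), protein = "P", stripped_sequence = "AGSR",
    sample = "s1", intensity = c(60, 40, 100)
  )
  fr <- glycoform_fractions(pep)
  expect_equal(fr$fraction[fr$glycoform == "Hex2"], 0.5)
  expect_equal(fr$fraction[fr$glycoform == "Hex3"], 0.5)
})

test_that("undetected families yield missing fractions, not 0/0", {
  pep <- tibble::tibble(
    modified_sequence = c("AGSR[Hex2]", "AGSR[Hex3]"),
    prec_z = 2L, protein = "P", stripped_sequence = "AGSR",
    sample = "s1", intensity = 0
  )
  fr <- glycoform_fractions(pep)
  expect_true(all(is.na(fr$fraction)))
})

test_that("an explicit grouping pools cleavage-boundary variants", {
  pep <- tibble::tibble(
    modified_sequence = c("VNLVELGVYVSDIR[Hex1]", "ERVNLVELGVYVSDIR[Hex1]",
                          "VNLVELGVYVSDIR"),
    prec_z = 2L, protein = "Pau", stripped_sequence =
      c("VNLVELGVYVSDIR", "ERVNLVELGVYVSDIR", "VNLVELGVYVSDIR"),
    sample = "s1", intensity = c(30, 20, 50)
  )
  grouping <- tibble::tibble(
    modified_sequence = pep$modified_sequence,
    family = "seripauperin-site",
    glycoform = c("Hex1", "Hex1", "unmodified")
  )
  fr <- glycoform_fractions(pep, grouping)
  expect_equal(nrow(fr), 2)
  expect_equal(fr$fraction[fr$glycoform == "Hex1"], 0.5)
  expect_equal(fr$fraction[fr$glycoform == "unmodified"], 0.5)
  expect_error(glycoform_fractions(pep, grouping[1:2, ]), "lacks")
})
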