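# small in-code report fixtures in the documented TSV dialect

tiny_report <- function() {
  tibble::tibble(
    scan = 100L, peptide = "VITGVPWYSSR", mods = "", glycan = "Hex6",
    linkage = "O", z = 3L, observed_mz = 746.3205, score = 500,
    rt_min = 10.5, protein = "Pau5",
    frag_series = c("b", "y", "Y"), frag_index = c(3L, 6L, 0L),
    frag_remainder = "", frag_z = 1L,
    frag_intensity = c(300, 900, 600)
  )
}

test_that("reports parse into PSMs and malformed rows are rejected", {
  rep3 <- tiny_report()
  bad <- rep3[1, ]
  bad$scan <- 101L
  bad$glycan <- "Sialic5"
  path <- withr::local_tempfile(fileext = ".tsv")
  readr::write_tsv(dplyr::bind_rows(rep3, bad), path)
  psms <- read_id_report(path)
  expect_equal(nrow(psms), 1)
  expect_equal(nrow(psms$fragments[[1]]), 3)
  rejects <- attr(psms, "rejects")
  expect_equal(nrow(rejects), 1)
  expect_match(rejects$reason, "monosaccharide")
})

test_that("a missing mandatory column is reported by name", {
  path <- withr::local_tempfile(fileext = ".tsv")
  readr::write_tsv(dplyr::select(tiny_report(), -"score"), path)
  expect_error(suppressWarnings(read_id_report(path)), "score")
})

test_that("synthetic reports round-trip through the reader", {
  cfg <- sim_config(seed = 1)
  ids <- simulate_identifications(cfg)
  path <- withr::local_tempfile(fileext = ".tsv")
  write_id_report(ids$report, path)
  psms <- read_id_report(path)
  expect_equal(nrow(psms), nrow(ids$truth))
  expect_equal(nrow(attr(psms, "rejects")), 0)
})

test_that("library records carry the theoretical Q1", {
  lib <- build_library(glycodia:::.nest_report(tiny_report()))
  expect_equal(nrow(lib), 3)
  expect_equal(unique(lib$q1), 746.33330, tolerance = 1e-5)
  expect_equal(unique(lib$stripped_sequence), "VITGVPWYSSR")
  expect_equal(unique(lib$modified_sequence), "VITGVPWYSSR[Hex6]")
  expect_setequal(lib$slot, c("b3", "y6", "a1"))
  expect_false(any(lib$decoy))
})

test_that("the best-scoring PSM wins per precursor, ties to lowest scan", {
  r1 <- tiny_report()
  r2 <- tiny_report()
  r2$scan <- 200L
  r2$score <- 300
  r2$rt_min <- 99
  lib <- build_library(glycodia:::.nest_report(dplyr::bind_rows(r1, r2)))
  expect_equal(unique(lib$rt), 10.5) # from the score-500 PSM
  r2$score <- 500 # tie -> lowest scan (100) wins
  lib2 <- build_library(glycodia:::.nest_report(dplyr::bind_rows(r2, r1)))
  expect_equal(unique(lib2$rt), 10.5)
})

test_that("validated-scan filtering warns about absent scans", {
  psms <- glycodia:::.nest_report(tiny_report())
  expect_warning(lib <- build_library(psms, validated_scans = c(100L, 999L)),
                 "999")
  expect_equal(nrow(lib), 3)
  expect_equal(nrow(build_library(psms, validated_scans = integer())), 0)
})

test_that("duplicate transitions are removed keeping highest intensity", {
  rep2 <- dplyr::bind_rows(tiny_report(), tiny_report()[1, ])
  rep2$frag_intensity[4] <- 50
  lib <- build_library(glycodia:::.nest_report(rep2))
  key <- paste(lib$modified_sequence, lib$prec_z, lib$slot, lib$frg_z)
  expect_equal(anyDuplicated(key), 0)
  expect_equal(lib$relative_intensity[lib$slot == "b3"], 300)
})

test_that("excluded near-terminal HexNAc fragments never reach the library", {
  cfg <- sim_config(seed = 5)
  ids <- simulate_identifications(cfg)
  lib <- suppressMessages(
    build_library(glycodia:::.nest_report(ids$report))
  )
  # an N-linked b2/b3 + HexNAc would surface as slot a2/a3 with frg_type
  # "a" but a non-Y meaning; Y slots a1-a3 are the only legal a<=3
  a_low <- lib[lib$slot %in% c("a1", "a2", "a3"), ]
  expect_true(all(parse_slot(a_low$slot)$class == "Y"))
  # no slot beyond the peptide length
  lens <- nchar(lib$stripped_sequence)
  expect_true(all(lib$frg_nr <= pmax(lens - 1, 3)))
})

test_that("library build is idempotent on its own output", {
  cfg <- sim_config(seed = 3)
  ids <- simulate_identifications(cfg)
  lib <- suppressMessages(
    build_library(glycodia:::.nest_report(ids$report))
  )
  # keep only report fragment rows that made it into the library, then
  # rebuild: the library must be unchanged
  psms <- glycodia:::.nest_report(ids$report)
  kept <- purrr::pmap(psms, function(peptide, glycan, z, fragments, ...) {
    sel <- lib[lib$stripped_sequence == toupper(peptide) &
                 lib$prec_z == z, ]
    fragments[round(fragments$frag_intensity, 5) %in%
                sel$relative_intensity, ]
  })
  psms$fragments <- kept
  relib <- suppressMessages(build_library(psms))
  expect_equal(as.data.frame(relib), as.data.frame(lib),
               ignore_attr = TRUE)
})

test_that("peakview files round-trip field for field", {
  # empty library -> header-only file
  empty <- glycodia:::.empty_library()
  p0 <- withr::local_tempfile(fileext = ".txt")
  write_peakview(empty, p0)
  expect_equal(length(readLines(p0)), 1)
  expect_equal(nrow(read_peakview(p0)), 0)
  # one-record file has exactly 14 tab-separated columns
  lib1 <- build_library(glycodia:::.nest_report(tiny_report()))[1, ]
  p1 <- withr::local_tempfile(fileext = ".txt")
  write_peakview(lib1, p1)
  lines <- readLines(p1)
  expect_equal(length(strsplit(lines[2], "\t")[[1]]), 14)
  expect_equal(strsplit(lines[1], "\t")[[1]][1:3],
               c("Q1", "Q3", "RT_detected"))
  # 200-record synthetic round-trip equality
  cfg <- sim_config(seed = 9)
  ids <- simulate_identifications(cfg)
  lib <- suppressMessages(
    build_library(glycodia:::.nest_report(ids$report))
  )
  lib200 <- lib[seq_len(200), ]
  p2 <- withr::local_tempfile(fileext = ".txt")
  write_peakview(lib200, p2)
  expect_equal(as.data.frame(read_peakview(p2)), as.data.frame(lib200),
               ignore_attr = TRUE)
})

test_that("merging prefers glycopeptide records on key conflicts", {
  lib <- build_library(glycodia:::.nest_report(tiny_report()))
  expect_equal(as.data.frame(merge_libraries(lib,
                                             glycodia:::.empty_library())),
               as.data.frame(lib), ignore_attr = TRUE)
  other <- lib
  other$modified_sequence <- paste0(other$modified_sequence, "X")
  merged <- merge_libraries(lib, other)
  expect_equal(nrow(merged), nrow(lib) + nrow(other))
  clash <- lib
  clash$rt <- 77
  expect_message(m2 <- merge_libraries(lib, clash), "conflict")
  expect_equal(nrow(m2), nrow(lib))
  expect_equal(unique(m2$rt), 10.5)
  expect_equal(nrow(attr(m2, "conflicts")), nrow(lib))
})
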