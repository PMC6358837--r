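test_that("CSV parsing preserves order, flags invalid structures, handles empty input", {
  f <- withr::local_tempfile(fileext = ".csv")
  readr::write_csv(tibble::tibble(
    id = c("FQ1", "FQ2"),
    smiles = c("c1ccccc1", "C1CC"),
    year = c(2005L, 2010L)
  ), f)
  lib <- read_library(f)
  expect_equal(nrow(lib), 2L)
  expect_equal(lib$id, c("FQ1", "FQ2"))
  expect_true(lib$valid[1])
  expect_false(lib$valid[2])  # unclosed ring retained, flagged, not dropped

  empty <- withr::local_tempfile(fileext = ".csv")
  readr::write_csv(tibble::tibble(id = character(), smiles = character()), empty)
  expect_equal(nrow(read_library(empty)), 0L)
})

test_that("a CSV without the mapped SMILES column raises a schema error naming it", {
  f <- withr::local_tempfile(fileext = ".csv")
  readr::write_csv(tibble::tibble(id = "x", structure = "CCO"), f)
  expect_error(read_library(f), "smiles")
  expect_silent(lib <- read_library(f, schema = c(smiles = "structure")))
  expect_equal(lib$smiles, "CCO")
})

test_that("write/read round trip preserves structures and schema fields in all formats", {
  lib <- curate_library(make_library(
    c("c1ccccc1O", "CCO", "CC(=O)Nc1ccccc1", "C1CCCCC1", "c1ccncc1"),
    kingdom = c("Plantae", "Fungi", NA, "Plantae", "Other"),
    year = c(2001L, 2002L, NA, 2004L, 2005L),
    activity = c("cytotoxic", NA, NA, NA, NA)
  ))
  for (fmt in c("csv", "smiles", "sdf")) {
    f <- withr::local_tempfile(fileext = paste0(".", switch(fmt,
      csv = "csv", smiles = "smi", sdf = "sdf")))
    write_library(lib, f, format = fmt)
    back <- read_library(f, format = fmt)
    expect_setequal(canonical_smiles(back$smiles), lib$smiles)
    expect_setequal(back$id, lib$id)
    if (fmt != "smiles") {
      expect_equal(back$year[match(lib$id, back$id)], lib$year)
      expect_equal(back$kingdom[match(lib$id, back$id)], lib$kingdom)
    }
  }
})

test_that("missing optional fields export as empty cells, not literal NA strings", {
  lib <- make_library("CCO", activity = NA_character_)
  f <- withr::local_tempfile(fileext = ".csv")
  write_library(lib, f, "csv")
  raw <- readr::read_lines(f)
  expect_false(any(grepl("NA|None", raw[2])))

  fempty <- withr::local_tempfile(fileext = ".csv")
  write_library(lib[0, ], fempty, "csv")
  expect_equal(readr::read_lines(fempty)[1],
               paste(c("id", "name", "smiles", "journal", "doi", "year",
                       "kingdom", "genus", "species", "location",
                       "activity"), collapse = ","))
})

test_that("metadata summary counts partition the library", {
  lib <- make_library(c("CCO", "CCC", "CCN"),
                      year = c(2001L, 2001L, 2005L),
                      kingdom = c("Fungi", "Fungi", "Fungi"),
                      genus = c("Xylaria", " xylaria", "Aspergillus"))
  ms <- metadata_summary(lib)
  expect_equal(ms$by_year$n[ms$by_year$year == "2001"], 2L)
  expect_equal(ms$by_year$n[ms$by_year$year == "2005"], 1L)
  expect_equal(sum(ms$by_year$n), nrow(lib))
  # all-Fungi library still reports a zero Plantae level
  expect_equal(ms$by_kingdom$n[ms$by_kingdom$kingdom == "Plantae"], 0L)
  expect_equal(ms$by_kingdom$n[ms$by_kingdom$kingdom == "Fungi"], 3L)
  # genus dedup is case-insensitive after trimming
  expect_equal(ms$genera_per_kingdom$n_genera, 2L)
})

test_that("record validation enforces unique non-empty ids and the year range", {
  expect_error(curate_library(make_library(c("CCO", "CCC"), ids = c("A", "A"))),
               "duplicated")
  f <- withr::local_tempfile(fileext = ".csv")
  readr::write_csv(tibble::tibble(id = c("a", "b"), smiles = c("CCO", "CCC"),
                                  year = c(2005L, 1805L)), f)
  expect_warning(lib <- read_library(f, year_range = c(2000, 2018)), "year")
  expect_true(is.na(lib$year[2]))
  expect_equal(lib$year[1], 2005L)
})
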