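test_that("dataset constructor enforces invariants", {
  ds <- make_ds("D", c("CCO", "c1ccccc1"), c(-0.24, -1.64))
  expect_s3_class(ds, "solubility_dataset")
  expect_equal(ds$records$weight, c(1, 1))
  expect_equal(ds$records$source_id, c("D", "D"))

  expect_error(make_ds("D", "CCO", Inf), "finite")
  expect_error(make_ds("D", "CCO", -1, weight = -0.5), "weight")
  expect_error(solubility_dataset("K", data.frame(smiles = "C", logS = -1),
                                  quality_weight = 0.5, group = "kinetic"),
               "kinetic")
})

test_that("curation config validates its windows and tolerances", {
  cfg <- curation_config()
  expect_equal(cfg$identical_tol, 0.01)
  expect_equal(cfg$merge_gap_d, 0.5)
  expect_equal(cfg$temp_center, 25)
  expect_equal(cfg$ph_halfwidth, 1)
  expect_error(curation_config(identical_tol = 0.6), "identical_tol")
  expect_error(curation_config(temp_halfwidth = -1))
})

test_that("csv reading applies defaults, skip rule and schema errors", {
  f <- withr::local_tempfile(fileext = ".csv")
  writeLines(c("Smiles,LogS", "CCO,-0.24", "c1ccccc1,-1.64"), f)
  ds <- read_dataset(f, "csv", id = "tiny")
  expect_equal(n_records(ds), 2L)
  expect_equal(ds$records$weight, c(1, 1))
  expect_equal(attr(ds, "n_skipped"), 0L)

  writeLines(c("Smiles,LogS", "CCO,-0.24", "CCN,n/a", "CCC,-2.0"), f)
  ds <- read_dataset(f, "csv", id = "tiny")
  expect_equal(n_records(ds), 2L)
  expect_equal(attr(ds, "n_skipped"), 1L)

  writeLines(c("Smiles,Value", "CCO,-0.24"), f)
  expect_error(read_dataset(f, "csv", id = "x"), "LogS")
  writeLines("Smiles,LogS", f)
  expect_error(read_dataset(f, "csv", id = "x"), "empty")
})

test_that("extra columns ride along and temperature/pH are mapped", {
  f <- withr::local_tempfile(fileext = ".csv")
  writeLines(c("Smiles,LogS,temperature,pH,star_flag",
               "CCO,-0.24,25,7.4,3", "CCC,-2.5,37,7,1"), f)
  ds <- read_dataset(f, "csv", id = "env")
  expect_equal(ds$records$temperature, c(25, 37))
  expect_equal(ds$records$pH, c(7.4, 7))
  expect_equal(ds$records$star_flag, c("3", "1"))
})

test_that("write/read round trip is the identity on the Table-2 columns", {
  ds <- make_ds("rt", c("CCO", "CCC", "CCN", "c1ccccc1", "CCCC"),
                c(-0.24, -2.5, -1.33333333313, -1.64, 0.3333333333),
                weight = c(1, 0.3333333333, 0.25, 1e-3, 2))
  f <- withr::local_tempfile(fileext = ".csv")
  write_dataset(ds, f)
  back <- read_dataset(f, "csv", id = "rt")
  expect_identical(back$records$smiles, ds$records$smiles)
  expect_equal(back$records$logS, ds$records$logS, tolerance = 1e-9)
  expect_equal(back$records$weight, ds$records$weight, tolerance = 1e-9)

  empty <- solubility_dataset("e", data.frame(smiles = character(0),
                                              logS = numeric(0)))
  write_dataset(empty, f)
  expect_identical(readLines(f), "Smiles,LogS,Weight")
})

test_that("sdf input is read with LogS property and skip tally", {
  block <- function(title, logs) {
    paste(c(title, "  test", "",
            "  1  0  0  0  0  0  0  0  0  0999 V2000",
            "    0.0000    0.0000    0.0000 C   0  0  0  0  0  0  0  0  0  0  0  0",
            "M  END",
            "> <LogS>", logs, "", "$$$$"), collapse = "\n")
  }
  f <- withr::local_tempfile(fileext = ".sdf")
  writeLines(c(block("mol1", "-0.5"), block("mol2", "bad")), f)
  ds <- read_dataset(f, "sdf", id = "sdf")
  expect_equal(n_records(ds), 1L)
  expect_equal(ds$records$logS, -0.5)
  expect_equal(attr(ds, "n_skipped"), 1L)
})
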