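test_that("generation is deterministic under seed and validates input", {
  spec <- synthetic_spec(n_molecules = 40, seed = 21)
  c1 <- generate_collection(spec)
  c2 <- generate_collection(spec)
  expect_identical(c1, c2)
  expect_false(identical(
    generate_collection(synthetic_spec(n_molecules = 40, seed = 22)), c1))
  expect_error(synthetic_spec(n_molecules = 10000), "vocabulary capacity")
  expect_error(synthetic_spec(datasets = list(
    list(id = "X", p_overlap = 1.5))))
})

test_that("planted structure: truth, weights, quality metadata", {
  spec <- synthetic_spec(n_molecules = 50, seed = 8)
  coll <- generate_collection(spec)
  expect_equal(nrow(coll$truth), 50L)
  expect_length(coll$datasets, 3L)
  ds <- coll$datasets[[1]]
  expect_equal(ds$quality_weight, 1.0)
  expect_true(all(ds$records$weight == 1))
  # exact records match planted truth
  truth <- setNames(coll$truth$logS, coll$truth$smiles)
  in_pool <- ds$records$smiles %in% names(truth)
  diffs <- abs(ds$records$logS[in_pool] - truth[ds$records$smiles[in_pool]])
  expect_true(any(diffs == 0))
})

test_that("contamination rates drive the filter as stated", {
  spec <- synthetic_spec(
    n_molecules = 100,
    datasets = list(list(id = "C", quality_weight = 0.8, group = "high",
                         p_overlap = 1, p_same_value = 1, noise_sd = 0,
                         metal_rate = 0.1, env_outlier_rate = 0.1)),
    seed = 31)
  coll <- generate_collection(spec)
  ds <- coll$datasets[[1]]
  n_metal <- sum(contains_blacklisted_element(ds$records$smiles))
  n_env <- sum(!passes_environment(ds$records))
  # binomial draws around 10 of 100; exact counts fixed by the seed
  expect_gt(n_metal, 0)
  expect_gt(n_env, 0)
  res <- filter_dataset(ds)
  expect_equal(n_records(res$dataset),
               100L - res$report$n_removed_env -
                 res$report$n_removed_element - res$report$n_removed_group)
  expect_equal(res$report$n_removed_element, n_metal)
})

test_that("limiting cases of expected redundancy", {
  mk <- function(psame, sd, pov = 0.5) {
    synthetic_spec(n_molecules = 50, datasets = list(
      list(id = "P", quality_weight = 1, group = "high", p_overlap = pov,
           p_same_value = psame, noise_sd = sd),
      list(id = "Q", quality_weight = 1, group = "high", p_overlap = pov,
           p_same_value = psame, noise_sd = sd)), seed = 1)
  }
  ex <- expected_redundancy(mk(1, 0))
  expect_equal(ex$A["P", "Q"], 50)
  expect_equal(ex$B["P", "Q"], 0)

  ex <- expected_redundancy(mk(0, 5))
  expect_lt(ex$A["P", "Q"], 0.5)
  expect_equal(ex$A["P", "Q"] + ex$B["P", "Q"], 50)

  ex <- expected_redundancy(mk(0.4, 5, pov = 1))
  expect_equal(ex$A["P", "Q"], 40, tolerance = 0.01)
  expect_equal(ex$B["P", "Q"], 60, tolerance = 0.01)
})

test_that("no-conflict generation yields A = overlap, B = 0 exactly", {
  spec <- synthetic_spec(
    n_molecules = 80,
    datasets = list(
      list(id = "U", quality_weight = 1, group = "high", p_overlap = 1,
           p_same_value = 1, noise_sd = 0),
      list(id = "V", quality_weight = 1, group = "high", p_overlap = 1,
           p_same_value = 1, noise_sd = 0)),
    seed = 3)
  coll <- generate_collection(spec)
  norm <- lapply(coll$datasets, normalize_dataset)
  red <- redundancy_matrices(norm)
  expect_equal(red$A["U", "V"], 100)
  expect_equal(red$B["U", "V"], 0)
})
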