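test_that("partial clustering: worked traces and parameter defaults", {
  out <- partial_cluster(c(-3.0, -3.4), d = 0.5)
  expect_equal(out$logS, -3.2)
  expect_equal(out$weight, 2)

  out <- partial_cluster(c(-2.0, -2.4, -3.5), d = 0.5)
  expect_equal(out$logS, c(-3.5, -2.2))
  expect_equal(out$weight, c(1, 2))

  out <- partial_cluster(c(-3.0, -3.4), weight = c(3, 1), d = 0.5)
  expect_equal(out$logS, -3.1)  # 3:1 weighted mean
  expect_equal(out$weight, 4)

  # strict inequality: a gap of exactly d does not merge
  out <- partial_cluster(c(-3.0, -3.5), d = 0.5)
  expect_equal(nrow(out), 2L)
  expect_error(partial_cluster(numeric(0)), "length")
})

test_that("partial clustering matches the brute-force oracle", {
  set.seed(23)
  for (rep in 1:300) {
    n <- sample(1:6, 1)
    v <- round(rnorm(n, -3, 1.2), 2)
    w <- round(runif(n, 0.1, 2), 2)
    d <- sample(c(0.1, 0.5, 2.0), 1)
    expect_equal(partial_cluster(v, w, d), brute_cluster(v, w, d),
                 tolerance = 1e-12)
  }
})

test_that("clustering conserves weight and centroid; limits behave", {
  set.seed(29)
  for (rep in 1:50) {
    n <- sample(2:10, 1)
    v <- rnorm(n, -3, 1)
    w <- runif(n, 0.1, 2)
    out <- partial_cluster(v, w, d = 0.5)
    expect_equal(sum(out$weight), sum(w), tolerance = 1e-12)
    expect_equal(sum(out$logS * out$weight) / sum(out$weight),
                 sum(v * w) / sum(w), tolerance = 1e-12)
    expect_lte(nrow(out), n)
    # d -> 0: unchanged (values drawn continuous, so no exact ties)
    tiny <- partial_cluster(v, w, d = 1e-300)
    expect_equal(tiny$logS, sort(v))
    # d -> Inf: single global weighted mean
    all_in <- partial_cluster(v, w, d = Inf)
    expect_equal(nrow(all_in), 1L)
    expect_equal(all_in$logS, sum(v * w) / sum(w), tolerance = 1e-12)
  }
})

test_that("curation schedule rules on the reference sources", {
  src <- reference_sources()
  names(src) <- vapply(src, function(d) d$id, character(1))
  expect_true(is_allowed_source(src$AQUA, src$ESOL))
  expect_false(is_allowed_source(src$AQUA, src$OCHEM))
  expect_true(is_allowed_source(src$AQSOL, src$ESOL))
  expect_true(is_allowed_source(src$AQSOL, src$CHEMBL))
  expect_false(is_allowed_source(src$CHEMBL, src$AQSOL))
  expect_false(is_allowed_source(src$ESOL, src$AQSOL))   # low never cures high
  expect_true(is_allowed_source(src$KINECT, src$KINECT)) # self always allowed
  expect_false(is_allowed_source(src$KINECT, src$AQUA))
  expect_false(is_allowed_source(src$AQUA, src$KINECT))
})

test_that("effective weight multiplies record by dataset weight", {
  ds <- make_ds("w", "CCO", -1, quality_weight = 0.8)
  expect_equal(effective_weight(0.5, ds), 0.4)
  expect_equal(effective_weight(c(1, 1 / 3), ds), c(0.8, 0.8 / 3))
  kin <- make_ds("k", "CCO", -1, quality_weight = NULL, group = "kinetic")
  expect_error(effective_weight(1, kin), "kinetic")
})

test_that("weight cap rescales proportionally above the threshold", {
  rec <- data.frame(smiles = c("A", "A", "B", "C", "C"),
                    weight = c(1, 1, 0.3, 0.8, 0.4),
                    stringsAsFactors = FALSE)
  out <- apply_weight_cap(rec, 1.0)
  expect_equal(out$weight, c(0.5, 0.5, 0.3, 0.8 / 1.2, 0.4 / 1.2))
  sums <- tapply(out$weight, out$smiles, sum)
  expect_true(all(sums <= 1 + 1e-12))
})

test_that("curate_dataset implements the three-step workflow", {
  target <- make_ds("T", "CCO", -3.0, quality_weight = 1.0)
  src <- make_ds("S", "CCO", -3.2, quality_weight = 1.0)
  cured <- curate_dataset(target, list(src))
  expect_equal(cured$id, "T.cure")
  expect_equal(cured$records$logS, -3.1)
  expect_equal(cured$records$weight, 1.0)

  # gap too large: no merge, cap rescales 2.0 -> 1.0
  src2 <- make_ds("S", "CCO", -5.0, quality_weight = 1.0)
  cured2 <- curate_dataset(target, list(src2))
  expect_equal(cured2$records$logS, c(-5.0, -3.0))
  expect_equal(cured2$records$weight, c(0.5, 0.5))

  # molecules absent from the target never appear
  src3 <- make_ds("S", c("CCO", "CCC"), c(-3.2, -9), quality_weight = 1.0)
  cured3 <- curate_dataset(target, list(src3))
  expect_false("CCC" %in% cured3$records$smiles)

  # schedule violation names the pair
  low <- make_ds("L", "CCO", -3.0, quality_weight = 0.4, group = "low")
  expect_error(curate_dataset(target, list(low)), "'L'.*'T'")
  # curated weights live in (0, 1] for threshold 1
  expect_true(all(cured2$records$weight > 0 & cured2$records$weight <= 1))
})

test_that("curated consensus beats a raw record against planted truth", {
  # low-noise conflicting copies, sigma << d: consensus must come closer
  spec <- synthetic_spec(
    n_molecules = 60,
    datasets = list(
      list(id = "HI", quality_weight = 1.0, group = "high", p_overlap = 1,
           p_same_value = 0, noise_sd = 0.2),
      list(id = "LO", quality_weight = 0.4, group = "low", p_overlap = 1,
           p_same_value = 0, noise_sd = 0.2)),
    seed = 99)
  coll <- generate_collection(spec)
  norm <- lapply(coll$datasets, normalize_dataset)
  cured <- curate_dataset(norm[[2]], norm[1])
  consensus <- vapply(split(cured$records, cured$records$smiles),
                      function(g) sum(g$logS * g$weight) / sum(g$weight),
                      numeric(1))
  truth <- setNames(coll$truth$logS, coll$truth$smiles)
  raw <- setNames(norm[[2]]$records$logS, norm[[2]]$records$smiles)
  mols <- names(consensus)
  expect_lt(mean(abs(consensus - truth[mols])),
            mean(abs(raw[mols] - truth[mols])))
})
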