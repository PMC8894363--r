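test_that("random split: ratios, determinism, exhaustiveness", {
  vocab <- smiles_vocabulary()
  ds <- make_ds("s", vocab[1:10], -(1:10) / 2)
  sp <- random_split(ds, c(0.8, 0.1, 0.1), seed = 3)
  expect_equal(lengths(sp[c("train", "val", "test")]),
               c(train = 8L, val = 1L, test = 1L))
  expect_setequal(c(sp$train, sp$val, sp$test), 1:10)
  expect_identical(random_split(ds, seed = 3), sp)
  expect_false(identical(random_split(ds, seed = 4)$train, sp$train))

  # small dataset: floor allocation then top-up of empty nonzero bins
  ds5 <- make_ds("s5", vocab[1:5], -(1:5))
  sp5 <- random_split(ds5, c(0.8, 0.1, 0.1), seed = 1)
  expect_equal(lengths(sp5[c("train", "val", "test")]),
               c(train = 3L, val = 1L, test = 1L))
  expect_error(random_split(make_ds("t", vocab[1:2], c(-1, -2))),
               "too small")
})

test_that("scaffold split keeps scaffolds whole and honors quotas", {
  # two scaffold families (benzene-core and acyclic) sized 8 and 2
  smi <- c("c1ccccc1", "Cc1ccccc1", "CCc1ccccc1", "CCCc1ccccc1",
           "Oc1ccccc1", "Nc1ccccc1", "COc1ccccc1", "Clc1ccccc1",
           "CCO", "CCN")
  ds <- make_ds("sc", smi, -(1:10) / 2)
  sp <- scaffold_split(ds, c(0.8, 0.1, 0.1), seed = 5)
  # the size-8 benzene family exactly fills the train quota
  expect_setequal(sp$train, 1:8)
  expect_setequal(c(sp$val, sp$test), 9:10)
  # the acyclic pair must stay together in one bin
  expect_true(all(9:10 %in% sp$val) || all(9:10 %in% sp$test))
  expect_identical(scaffold_split(ds, seed = 5)$train,
                   sp$train)

  # one scaffold beyond the train ratio: warning + oversized train bin
  big <- make_ds("big", c(smi[1:8], "Brc1ccccc1", "CCO"), -(1:10))
  expect_warning(spb <- scaffold_split(big, seed = 1), "oversized")
  expect_gte(length(spb$train), 9L)
})

test_that("unique scaffolds behave like a deterministic grouped split", {
  smi <- c("c1ccccc1", "c1ccncc1", "c1ccc2ccccc2c1", "C1CCNCC1",
           "C1CCOCC1", "c1ccc2[nH]ccc2c1", "c1ccc(-c2ccccc2)cc1",
           "CC(=O)Oc1ccccc1C(=O)O", "Cn1cnc2c1c(=O)n(C)c(=O)n2C",
           "c1ccc(N2CCNCC2)cc1")
  ds <- make_ds("u", smi, -(1:10) / 3)
  sp <- scaffold_split(ds, seed = 11)
  expect_equal(sort(unname(lengths(sp[c("train", "val", "test")]))),
               c(1L, 1L, 8L))
  expect_setequal(c(sp$train, sp$val, sp$test), 1:10)
})

test_that("apply_split materializes three disjoint datasets", {
  vocab <- smiles_vocabulary()
  ds <- make_ds("m", vocab[1:12], -(1:12) / 4)
  parts <- apply_split(ds, random_split(ds, seed = 2))
  expect_equal(parts$train$id, "m.train")
  expect_equal(n_records(parts$train) + n_records(parts$val) +
                 n_records(parts$test), 12L)
  expect_length(intersect(parts$train$records$smiles,
                          parts$test$records$smiles), 0L)
})
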