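# chemistry-free stand-in records: splitting and fold planning operate on
# canonical strings only, so opaque identifiers are sufficient here
dummy_records <- function(n) {
  lapply(seq_len(n), function(i) {
    rxn_record(sprintf("R%04d", i), character(0), sprintf("P%04d", i),
               canonicalize = FALSE)
  })
}

test_that("8:1:1 split sizes follow the floor rule", {
  sp <- split_dataset(dummy_records(1000), seed = 3)
  expect_length(sp$train, 800L)
  expect_length(sp$valid, 100L)
  expect_length(sp$test, 100L)

  sp10 <- split_dataset(dummy_records(10), seed = 3)
  expect_identical(lengths(sp10[c("train", "valid", "test")]),
                   c(train = 8L, valid = 1L, test = 1L))

  # remainder goes to train, evaluation sets never exceed nominal
  sp95 <- split_dataset(dummy_records(95), seed = 3)
  expect_length(sp95$valid, 9L)
  expect_length(sp95$test, 9L)
  expect_length(sp95$train, 77L)

  expect_error(split_dataset(dummy_records(9)), "too few")
})

test_that("splits are deterministic in the seed and disjoint", {
  recs <- dummy_records(200)
  a <- split_dataset(recs, seed = 42)
  b <- split_dataset(recs, seed = 42)
  expect_identical(record_keys(a$train), record_keys(b$train))
  expect_identical(record_keys(a$valid), record_keys(b$valid))

  c2 <- split_dataset(recs, seed = 43)
  expect_false(identical(record_keys(a$train), record_keys(c2$train)))

  keys <- c(record_keys(a$train), record_keys(a$valid),
            record_keys(a$test))
  expect_identical(anyDuplicated(keys), 0L)
})

test_that("duplicated input is refused", {
  recs <- dummy_records(20)
  expect_error(split_dataset(c(recs, recs[1])), "not deduplicated")
})

test_that("k-fold plans cover every record exactly once", {
  recs <- dummy_records(100)
  plan <- kfold_plan(recs, k = 10, seed = 5)
  expect_identical(vapply(plan$splits, function(s) length(s$test),
                          integer(1)),
                   rep(10L, 10))
  held_out <- unlist(lapply(plan$splits, function(s) record_keys(s$test)))
  expect_setequal(held_out, record_keys(recs))
  expect_identical(anyDuplicated(held_out), 0L)

  # uneven n: fold sizes differ by at most one
  plan2 <- kfold_plan(dummy_records(103), k = 10, seed = 5)
  sizes <- vapply(plan2$splits, function(s) length(s$test), integer(1))
  expect_setequal(unique(sizes), c(10L, 11L))
  expect_identical(sum(sizes), 103L)

  expect_error(kfold_plan(dummy_records(5), k = 10), "at least")
})

test_that("train-only augmentation leaves valid/test byte-identical", {
  recs <- fixture_dataset("hiyama", 4, 5, seed = 31)
  sp <- split_dataset(recs, seed = 9)
  valid_lines <- vapply(sp$valid, write_reaction_smiles, character(1))
  test_lines <- vapply(sp$test, write_reaction_smiles, character(1))

  aug <- augment_split(sp)
  expect_identical(vapply(aug$valid, write_reaction_smiles, character(1)),
                   valid_lines)
  expect_identical(vapply(aug$test, write_reaction_smiles, character(1)),
                   test_lines)
  expect_gte(length(aug$train), length(sp$train))

  added <- aug$train[-seq_along(sp$train)]
  expect_true(all(vapply(added, `[[`, character(1), "provenance") ==
                    "fake"))

  # no canonical reaction string in two partitions, fakes included
  keys <- c(record_keys(aug$train), record_keys(aug$valid),
            record_keys(aug$test))
  expect_identical(anyDuplicated(keys), 0L)
})

test_that("per-fold augmentation never touches the held-out fold", {
  recs <- fixture_dataset("suzuki", 4, 5, seed = 33)
  plan <- kfold_plan(recs, k = 5, seed = 2)
  for (s in plan$splits[1:2]) {
    aug <- augment_split(s)
    expect_identical(record_keys(aug$test), record_keys(s$test))
    expect_length(intersect(record_keys(aug$train),
                            record_keys(aug$test)), 0L)
  }
})

test_that("statistics report raw/virtual counts and growth factor", {
  recs <- fixture_dataset("hiyama")
  st0 <- dataset_stats(recs, recs)
  expect_equal(st0$growth_factor, 1.0)
  expect_identical(st0$fake_count, 0L)

  fakes <- augment_records(recs)
  merged <- dedup_and_merge(recs, fakes)
  st <- dataset_stats(recs, merged)
  expect_identical(st$raw_count, length(recs))
  expect_identical(st$virtual_count, length(merged))
  expect_identical(st$fake_count, length(merged) - length(recs))
  expect_equal(st$growth_factor, length(merged) / length(recs))
})

test_that("parallel export is line-aligned, lossless and reproducible", {
  recs <- fixture_dataset("hiyama", 4, 5, seed = 31)
  sp <- split_dataset(recs, seed = 9)
  d1 <- withr::local_tempdir()
  export_pairs(sp, d1)
  src <- readLines(file.path(d1, "src-train.txt"))
  tgt <- readLines(file.path(d1, "tgt-train.txt"))
  expect_length(src, length(sp$train))
  expect_length(tgt, length(sp$train))
  expect_length(readLines(file.path(d1, "src-valid.txt")),
                length(sp$valid))

  # detokenizing any line reproduces the canonical species string
  i <- 1L
  expect_identical(detokenize_smiles(src[i]),
                   paste(c(sp$train[[i]]$reactants,
                           sp$train[[i]]$reagents), collapse = "."))
  expect_identical(detokenize_smiles(tgt[i]), sp$train[[i]]$product)

  d2 <- withr::local_tempdir()
  export_pairs(sp, d2)
  for (f in list.files(d1)) {
    expect_identical(readLines(file.path(d2, f)),
                     readLines(file.path(d1, f)))
  }
})
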