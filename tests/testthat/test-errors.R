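test_that("the error cascade labels canonical failure modes", {
  expect_identical(classify_prediction("CCO", "CCO"), "correct")
  expect_identical(classify_prediction("OCC", "CCO"), "correct")
  expect_identical(classify_prediction("CC((", "CCO"), "invalid_smiles")
  expect_identical(
    classify_prediction("C[C@@H](N)C(=O)O", "C[C@H](N)C(=O)O"),
    "chirality")
  # carbon counts 9 vs 8
  expect_identical(classify_prediction("CCCc1ccccc1", "CCc1ccccc1"),
                   "atom_count")
  # same formula C8H10, different connectivity
  expect_identical(classify_prediction("Cc1ccccc1C", "Cc1ccc(C)cc1"),
                   "group_isomerism")
  expect_identical(classify_prediction("CCO", "CCN"), "other")
})

test_that("chirality is tested before carbon count in the cascade", {
  # an enantiomer pair also has equal carbon counts and formulas; the
  # cascade must stop at chirality, not fall through
  expect_identical(classify_prediction("F/C=C/F", "F/C=C\\F"), "chirality")
})

test_that("an invalid reference is a caller error", {
  expect_error(classify_prediction("CCO", "CC(("), "invalid reference")
})

test_that("self-comparison is always correct", {
  species <- unique(unlist(lapply(fixture_dataset("kumada"), function(r) {
    c(r$reactants, r$product)
  })))
  for (s in species) {
    expect_identical(classify_prediction(s, s), "correct")
  }
})

test_that("label invariants hold on a labeled corpus", {
  suite <- generate_prediction_suite()
  for (i in seq_len(nrow(suite))) {
    got <- classify_prediction(suite$predicted[i], suite$reference[i])
    expect_identical(got, suite$expected[i],
                     label = paste(suite$predicted[i], "vs",
                                   suite$reference[i]))
    if (got == "group_isomerism") {
      expect_identical(molecular_formula(suite$predicted[i]),
                       molecular_formula(suite$reference[i]))
    }
    if (got == "atom_count") {
      expect_false(carbon_count(suite$predicted[i]) ==
                     carbon_count(suite$reference[i]))
    }
  }
})

test_that("error summaries count per label and normalize over wrong", {
  suite <- generate_prediction_suite()
  rep <- summarize_errors(suite$predicted, suite$reference)
  expected_counts <- table(factor(suite$expected,
                                  levels = names(rep$counts)))
  expect_identical(as.integer(rep$counts),
                   as.integer(expected_counts))
  expect_identical(rep$n, nrow(suite))
  expect_identical(rep$n_wrong, sum(suite$expected != "correct"))
  expect_equal(sum(rep$percent), 100, tolerance = 5e-4)
  # percentages exclude correct predictions from the denominator
  expect_false("correct" %in% names(rep$percent))
})

test_that("degenerate error summaries are well formed", {
  all_ok <- summarize_errors(c("CCO", "CCN"), c("CCO", "CCN"))
  expect_identical(all_ok$n_wrong, 0L)
  expect_length(all_ok$percent, 0L)

  empty <- summarize_errors(character(0), character(0))
  expect_identical(empty$n, 0L)
  expect_identical(empty$n_wrong, 0L)
})

test_that("error reports serialize to JSON", {
  suite <- generate_prediction_suite()
  rep <- summarize_errors(suite$predicted, suite$reference)
  path <- withr::local_tempfile(fileext = ".json")
  write_error_report(rep, path)
  back <- jsonlite::read_json(path)
  expect_identical(back$n_wrong, rep$n_wrong)
  expect_equal(back$counts$group_isomerism,
               unname(rep$counts["group_isomerism"]))
})
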