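tpls <- default_templates()
cls <- default_fg_classes()

test_that("the printed Hiyama reaction has exactly one halide site", {
  r <- classify_record(parse_reaction_smiles(HIYAMA_REF_B))
  sites <- find_augmentable_sites(r, tpls$hiyama, cls$halogen)
  expect_length(sites, 1L)
  expect_identical(sites[[1]]$member, "bromo")
  expect_identical(sites[[1]]$role, "aryl_halide")
  expect_true(sites[[1]]$leaving_group_confirmed)
})

test_that("single augmentation of the printed reaction yields Cl and I twins", {
  r <- classify_record(parse_reaction_smiles(HIYAMA_REF_B))
  fakes <- single_augment(r, tpls$hiyama, "aryl_halide", cls)
  expect_length(fakes, 2L)
  halides <- sort(vapply(fakes, function(f) {
    s <- f$reactants[f$roles[["aryl_halide"]]]
    if (grepl("Cl", s)) "Cl" else if (grepl("I", s)) "I" else "?"
  }, character(1)))
  expect_identical(halides, c("Cl", "I"))
  for (f in fakes) {
    expect_identical(f$product, r$product)
    expect_identical(f$provenance, "fake")
    reparsed <- parse_reaction_smiles(write_reaction_smiles(f))
    expect_identical(reparsed$canonical_string, f$canonical_string)
  }
})

test_that("substitution performs exact graph surgery", {
  r <- classify_record(parse_reaction_smiles(HIYAMA_REF_B))
  site <- find_augmentable_sites(r, tpls$hiyama, cls$halogen)[[1]]
  out <- substitute_group(r$reactants[site$species], site, "I")
  expect_identical(out, canonicalize_smiles("N#Cc1ccc(I)cc1"))
  # identity replacement is forbidden
  expect_error(substitute_group(r$reactants[site$species], site, "Br"),
               "identity replacement")
})

test_that("boron-ester substitution yields valence-valid molecules", {
  r <- classify_record(parse_reaction_smiles(
    "OB(O)c1ccccc1.Brc1ccccc1>>c1ccc(-c2ccccc2)cc1"))
  site <- find_augmentable_sites(r, tpls$suzuki, cls$boron)[[1]]
  expect_identical(site$member, "boronic_acid")
  out <- substitute_group(r$reactants[site$species], site,
                          cls$boron$members[["pinacol_boronate"]])
  expect_true(is_valid_smiles(out))
  g <- parse_molgraph(out)
  expect_identical(sum(g$elem == "B"), 1L)
  expect_identical(sum(g$elem == "O"), 2L)
})

test_that("augmentation agrees with the brute-force oracle per type", {
  for (ty in c("hiyama", "suzuki", "kumada")) {
    for (r in fixture_dataset(ty)) {
      gt <- attr(r, "ground_truth")
      fakes <- simultaneous_augment(r, tpls[[ty]], classes = cls)
      expect_identical(sort(record_keys(fakes)),
                       oracle_expected_fakes(ty, gt, "simultaneous"),
                       label = paste(ty, "simultaneous"))
    }
  }
  for (ty in c("buchwald_hartwig", "chan_lam")) {
    for (r in fixture_dataset(ty)) {
      gt <- attr(r, "ground_truth")
      role <- names(tpls[[ty]]$augmentable_roles)[1]
      fakes <- single_augment(r, tpls[[ty]], role, cls)
      expect_identical(sort(record_keys(fakes)),
                       oracle_expected_fakes(ty, gt, "single"),
                       label = paste(ty, "single"))
    }
  }
})

test_that("spectator halogens are never substituted", {
  recs <- fixture_dataset("suzuki", 2, 4, seed = 21,
                          spectator_fraction = 0.5)
  spect <- Filter(function(r) attr(r, "ground_truth")$spectator, recs)
  expect_gt(length(spect), 0)
  for (r in spect) {
    # the partner carries a ring chlorine that survives into the product
    expect_match(r$product, "Cl")
    fakes <- simultaneous_augment(r, tpls$suzuki, classes = cls)
    expect_length(fakes, attr(r, "ground_truth")$n_simultaneous)
    for (f in fakes) {
      expect_identical(f$product, r$product)
      # spectator chlorine still present in the fake's boron species
      expect_match(f$reactants[f$roles[["organoboron"]]], "Cl")
    }
  }
})

test_that("ambiguous-site records yield no fakes", {
  r <- classify_record(parse_reaction_smiles(
    "Clc1ccc(Br)cc1.OB(O)c1ccccc1>>Clc1ccc(-c2ccccc2)cc1"))
  expect_length(find_augmentable_sites(r, tpls$suzuki, cls$halogen), 0L)
  expect_length(single_augment(r, tpls$suzuki, "aryl_halide", cls), 0L)
})

test_that("fakes re-parse and re-classify with the parent's type", {
  for (ty in c("hiyama", "buchwald_hartwig")) {
    recs <- fixture_dataset(ty)
    fakes <- augment_records(recs)
    expect_gt(length(fakes), 0)
    for (f in fakes[seq_len(min(6, length(fakes)))]) {
      back <- classify_record(parse_reaction_smiles(
        write_reaction_smiles(f)))
      expect_identical(back$rxn_type, ty)
    }
  }
})

test_that("merging deletes repeats, guard collisions and is idempotent", {
  recs <- fixture_dataset("hiyama")
  fakes <- augment_records(recs)
  expect_identical(record_keys(dedup_and_merge(recs, list())),
                   record_keys(recs))

  merged <- dedup_and_merge(recs, fakes)
  keys <- record_keys(merged)
  expect_false(anyDuplicated(keys) > 0)
  # a fake identical to a raw reaction is absent from the merged tail
  tail_keys <- keys[-seq_along(recs)]
  expect_length(intersect(tail_keys, record_keys(recs)), 0L)

  # idempotence: merging the fakes twice changes nothing
  merged2 <- dedup_and_merge(merged, fakes)
  expect_identical(record_keys(merged2), keys)

  # guard: fakes colliding with a held-out reaction are dropped
  guard <- record_keys(fakes)[1]
  merged_g <- dedup_and_merge(recs, fakes, guard = guard)
  expect_false(guard %in% record_keys(merged_g))
})

test_that("per-parent cap bounds the number of fakes", {
  recs <- fixture_dataset("hiyama")
  capped <- augment_records(recs[1], cap = 3)
  expect_length(capped, 3L)
})

test_that("functional-group classes validate and round-trip", {
  for (cl in cls) expect_true(validate_fg_class(cl))
  path <- withr::local_tempfile(fileext = ".yaml")
  write_fg_classes(cls, path)
  back <- read_fg_classes(path)
  expect_identical(names(back), names(cls))
  expect_identical(back$halogen$members, cls$halogen$members)

  dup <- cls$halogen
  dup$members <- c(chloro = "Cl", also_chloro = "Cl")
  expect_error(validate_fg_class(dup), "identical after")
})
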