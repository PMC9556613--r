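test_that("canonicalization is idempotent and atom-order invariant", {
  # hand-written atom reorderings of bromobenzene
  perms <- c("Brc1ccccc1", "c1ccc(Br)cc1", "c1cc(Br)ccc1", "c1ccccc1Br")
  canon <- canonicalize_smiles(perms)
  expect_length(unique(canon), 1L)
  expect_identical(canonicalize_smiles(canon), canon)

  expect_identical(canonicalize_smiles("C"), "C")
  s <- "N#Cc1ccc(Br)cc1"
  expect_identical(canonicalize_smiles(canonicalize_smiles(s)),
                   canonicalize_smiles(s))

  # property over generated species
  species <- unique(unlist(lapply(fixture_dataset("suzuki"), function(r) {
    c(r$reactants, r$product)
  })))
  canon <- canonicalize_smiles(species)
  expect_identical(canonicalize_smiles(canon), canon)
})

test_that("invalid SMILES are rejected with an informative error", {
  expect_error(canonicalize_smiles("bogus(("), "invalid SMILES")
  expect_error(canonicalize_smiles("CC(("), "invalid SMILES")
  expect_false(is_valid_smiles("c1ccccc"))
  expect_true(all(is_valid_smiles(c("[K+]", "[F-]", "Brc1ccccc1"))))
})

test_that("stereo is preserved by default and removed on request", {
  l <- canonicalize_smiles("C[C@@H](N)C(=O)O")
  d <- canonicalize_smiles("C[C@H](N)C(=O)O")
  expect_false(identical(l, d))
  expect_identical(canonicalize_smiles("C[C@@H](N)C(=O)O", strip_stereo = TRUE),
                   canonicalize_smiles("C[C@H](N)C(=O)O", strip_stereo = TRUE))
})

test_that("reaction parsing handles both dialects and role bookkeeping", {
  r <- parse_reaction_smiles(HIYAMA_REF_B)
  expect_length(c(r$reactants, r$reagents), 4L)
  expect_length(r$product, 1L)
  expect_identical(r$provenance, "raw")

  # three-field dialect assigns reagents from the middle segment
  r3 <- parse_reaction_smiles("CCO>[Na+]>CC=O")
  expect_identical(r3$reagents, "[Na+]")

  ri <- parse_reaction_smiles("CCO>>CCO")
  expect_length(ri$reactants, 1L)
  expect_length(ri$reagents, 0L)
})

test_that("malformed reactions raise distinct error conditions", {
  expect_error(parse_reaction_smiles("CCO.CC>>"),
               class = "rxnaug_error_product_count")
  expect_error(parse_reaction_smiles("CCO.CC>>CO.CC"),
               class = "rxnaug_error_product_count")
  expect_error(parse_reaction_smiles("CCO"),
               class = "rxnaug_error_separator")
  expect_error(parse_reaction_smiles("CCO>>C>>O"),
               class = "rxnaug_error_separator")
  expect_error(parse_reaction_smiles(">>CCO"),
               class = "rxnaug_error_no_reactants")
  expect_error(parse_reaction_smiles("zz9((>>CCO"),
               class = "rxnaug_error_species_parse")
})

test_that("parse/write round-trips at the canonical-string level", {
  r <- parse_reaction_smiles(HIYAMA_REF_B)
  line <- write_reaction_smiles(r)
  expect_identical(parse_reaction_smiles(line)$canonical_string,
                   r$canonical_string)
  # reagents are emitted on the left side before '>>'
  cr <- classify_record(r)
  out <- write_reaction_smiles(cr)
  expect_match(out, "\\[F-\\].*>>")
  parts <- strsplit(out, ">>", fixed = TRUE)[[1]]
  expect_length(parts, 2L)
  expect_false(any(grepl(">", parts, fixed = TRUE)))

  for (rec in fixture_dataset("kumada")) {
    expect_identical(
      parse_reaction_smiles(write_reaction_smiles(rec))$canonical_string,
      rec$canonical_string)
  }
})

test_that("canonical_string is invariant under species order", {
  a <- rxn_record(c("CCO", "CCN"), "[Na+]", "CCOC")
  b <- rxn_record(c("CCN", "CCO"), "[Na+]", "CCOC")
  c2 <- rxn_record(c("CCN", "[Na+]"), "CCO", "CCOC")
  expect_identical(a$canonical_string, b$canonical_string)
  expect_identical(a$canonical_string, c2$canonical_string)
})

test_that("tokenizer emits atomic tokens and is lossless", {
  expect_identical(tokenize_smiles("Brc1ccccc1"),
                   c("Br", "c", "1", "c", "c", "c", "c", "c", "1"))
  expect_identical(tokenize_smiles("[K+]"), "[K+]")
  expect_true("%12" %in% tokenize_smiles("C%12CCCCC%12"))
  expect_true("[C@@H]" %in% tokenize_smiles("C[C@@H](N)C(=O)O"))

  species <- unique(unlist(lapply(
    c(fixture_dataset("hiyama"), fixture_dataset("chan_lam")),
    function(r) c(r$reactants, r$reagents, r$product))))
  species <- c(species, "[F-]", "[K+]", "CC[Si](Cl)(Cl)c1ccc(C)cc1")
  for (s in species) {
    expect_identical(detokenize_smiles(tokenize_smiles(s)), s)
  }
})

test_that("molgraph round-trips structures including charges", {
  for (s in c("N#Cc1ccc(Br)cc1", "[F-]", "O=[N+]([O-])c1ccccc1",
              "CC[Si](Cl)(Cl)c1ccc(C)cc1", "Br[Mg]c1ccccc1")) {
    can <- canonicalize_smiles(s)
    expect_identical(molgraph_to_smiles(parse_molgraph(s)), can)
  }
})

test_that("pendant matching finds substituents exactly once", {
  g <- parse_molgraph("N#Cc1ccc(Br)cc1")
  frag <- parse_molgraph("Br")
  m <- match_pendant(g, frag, attach_elem = "C")
  expect_length(m, 1L)
  expect_identical(g$elem[m[[1]]$atoms], "Br")
  expect_identical(g$elem[m[[1]]$anchor], "C")
  expect_length(match_pendant(parse_molgraph("c1ccccc1"), frag), 0L)
  # boronic acid fragment on phenylboronic acid, symmetry collapsed
  mb <- match_pendant(parse_molgraph("OB(O)c1ccccc1"),
                      parse_molgraph("B(O)O"), attach_elem = "C")
  expect_length(mb, 1L)
})

test_that("training config exports the reference hyperparameters", {
  path <- withr::local_tempfile(fileext = ".yaml")
  export_training_config(path)
  cfg <- read_training_config(path)
  expect_equal(cfg$beta2, 0.997)
  expect_equal(cfg$epsilon, 1e-9)
  expect_equal(cfg$num_layers, 6L)

  export_training_config(path, training_config(n_heads = 4))
  expect_equal(read_training_config(path)$n_heads, 4L)
})
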