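# Shared fixtures and an independent brute-force oracle.
#
# The oracle builds reactions and their expected augmentation variants by
# plain SMILES *string templates* (member fragment text prepended to a
# substituted-benzene core), canonicalized directly through ChemmineOB.
# It never touches the package's graph-surgery path, so agreement between
# the two is a genuine cross-check of the substitution engine.

HIYAMA_REF_B <- paste0("CC[Si](Cl)(Cl)c1ccc(C)cc1.N#Cc1ccc(Br)cc1.[F-].[K+]",
                ">>Cc1ccc(-c2ccc(C#N)cc2)cc1")
# companion raw Hiyama reaction (triphenylfluorosilane + aryl iodide);
# the neutral-looking "[F]" reagent is normalized to fluoride in this
# shipped form
HIYAMA_REF_A <- paste0("CC(=O)c1ccc(I)cc1.F[Si](c1ccccc1)(c1ccccc1)c1ccccc1.",
                "[F-].[K+]>>CC(=O)c1ccc(c2ccccc2)cc1")

.fx <- new.env(parent = emptyenv())

fixture <- function(name, builder) {
  if (is.null(.fx[[name]])) .fx[[name]] <- force(builder)
  .fx[[name]]
}

## small screened datasets per type, memoized across test files
fixture_dataset <- function(type, n_aryl = 3, n_partner = 3, seed = 11,
                            spectator_fraction = 0) {
  key <- paste(type, n_aryl, n_partner, seed, spectator_fraction,
               sep = "_")
  fixture(key, {
    recs <- generate_coupling_dataset(type, n_aryl, n_partner, seed = seed,
                                      spectator_fraction = spectator_fraction)
    lapply(recs, function(r) {
      cr <- classify_record(r)
      attr(cr, "ground_truth") <- attr(r, "ground_truth")
      cr
    })
  })
}

## ---- independent oracle ----

.oracle_canon_cache <- new.env(parent = emptyenv())

oracle_canon <- function(s) {
  hit <- .oracle_canon_cache[[s]]
  if (!is.null(hit)) return(hit)
  out <- sub("[\t\n ].*$", "", ChemmineOB::convertFormat("SMI", "CAN", s))
  stopifnot(nzchar(out))
  .oracle_canon_cache[[s]] <- out
  out
}

oracle_core <- function(sub, pos, spectator = FALSE) {
  if (spectator) {
    return(if (pos == "para") sprintf("c1cc(Cl)c(%s)cc1", sub)
           else sprintf("c1cc(%s)cc(Cl)c1", sub))
  }
  if (pos == "para") sprintf("c1ccc(%s)cc1", sub)
  else sprintf("c1cccc(%s)c1", sub)
}

## member fragment prepended textually to an aryl core
oracle_attached <- function(class_name, member, core) {
  switch(class_name,
    halogen = paste0(c(chloro = "Cl", bromo = "Br", iodo = "I")[[member]],
                     core),
    boron = switch(member,
                   boronic_acid = paste0("OB(O)", core),
                   pinacol_boronate = sprintf("CC4(C)C(C)(C)OB(%s)O4", core),
                   dioxaborinane = sprintf("C4COB(%s)OC4", core)),
    silicon = switch(member,
                     trimethoxysilyl = paste0("CO[Si](OC)(OC)", core),
                     triethoxysilyl = paste0("CCO[Si](OCC)(OCC)", core),
                     trichlorosilyl = paste0("Cl[Si](Cl)(Cl)", core),
                     dimethylfluorosilyl = paste0("C[Si](C)(F)", core)),
    grignard_halide = paste0(
      c(chloro = "Cl", bromo = "Br", iodo = "I")[[member]], "[Mg]", core),
    amine = paste0("N", core))
}

oracle_first_class <- function(type) {
  if (type == "chan_lam") "boron" else "halogen"
}

oracle_partner_class <- function(type) {
  switch(type, hiyama = "silicon", suzuki = "boron",
         kumada = "grignard_halide", buchwald_hartwig = "amine",
         chan_lam = "amine")
}

oracle_reagents <- function(type) {
  switch(type,
         hiyama = c("[F-]", "[K+]"),
         suzuki = c("[OH-]", "[K+]"),
         kumada = character(0),
         buchwald_hartwig = c("CC(C)(C)[O-]", "[Na+]"),
         chan_lam = character(0))
}

## canonical reaction identity string, mirrored from first principles
oracle_key <- function(left, product) {
  paste0(paste(sort(vapply(left, oracle_canon, character(1)),
                    method = "radix"), collapse = "."),
         ">>", oracle_canon(product))
}

## one reaction from ground-truth coordinates with given member choices
oracle_reaction_key <- function(type, gt, first_member, partner_member) {
  core_a <- oracle_core(gt$first_sub, gt$first_pos)
  core_b <- oracle_core(gt$partner_sub, gt$partner_pos, gt$spectator)
  core_b3 <- gsub("1", "3", core_b, fixed = TRUE)
  sp1 <- oracle_attached(oracle_first_class(type), first_member, core_a)
  sp2 <- oracle_attached(oracle_partner_class(type), partner_member, core_b)
  # join at the attachment carbons (atom 1 of each core): write core_a
  # with the partner ring (or N-partner) spliced in as a branch on its
  # first atom
  product <- if (type %in% c("hiyama", "suzuki", "kumada")) {
    sub("^c1", paste0("c1(", core_b3, ")"), core_a)
  } else {
    sub("^c1", paste0("c1(N", core_b3, ")"), core_a)
  }
  oracle_key(c(sp1, sp2, oracle_reagents(type)), product)
}

## expected fake identity strings for one generated record
oracle_expected_fakes <- function(type, gt,
                                  mode = c("single", "simultaneous"),
                                  classes = default_fg_classes()) {
  mode <- match.arg(mode)
  first_members <- names(classes[[oracle_first_class(type)]]$members)
  partner_cls <- oracle_partner_class(type)
  partner_members <- if (partner_cls == "amine") "amine"
                     else names(classes[[partner_cls]]$members)
  combos <- if (mode == "single") {
    data.frame(first = setdiff(first_members, gt$first_member),
               partner = gt$partner_member, stringsAsFactors = FALSE)
  } else {
    g <- expand.grid(first = first_members, partner = partner_members,
                     stringsAsFactors = FALSE)
    g[!(g$first == gt$first_member & g$partner == gt$partner_member), ]
  }
  keys <- vapply(seq_len(nrow(combos)), function(i) {
    oracle_reaction_key(type, gt, combos$first[i], combos$partner[i])
  }, character(1))
  sort(unique(keys))
}
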