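## Synthetic coupling-reaction fixtures with exact ground truth.
##
## Stands in for a reaction-database extraction: combinatorial aryl
## halides x coupling partners whose products are built by deterministic
## formal coupling (join the two role carbons, delete both leaving
## groups) — never by a prediction heuristic — so reaction type, site
## locations and expected augmentation counts are exact by construction.

#' Default ring-substituent vocabulary for the generator
#'
#' Named fragment SMILES placed para or meta on the aryl rings. The
#' partner pool additionally carries a spectator chlorine variant, which
#' survives into the product and exercises the leaving-group-confirmation
#' rule of the augmentation engine.
#'
#' @return Named character vector.
#' @export
default_substituents <- function() {
  c(methyl = "C", methoxy = "OC", cyano = "C#N", acetyl = "C(C)=O",
    nitro = "[N+](=O)[O-]", tert_butyl = "C(C)(C)C",
    trifluoromethyl = "C(F)(F)F", fluoro = "F", phenyl = "c2ccccc2")
}

## substituted benzene core; the attachment carbon for the leaving group /
## partner handle is atom 1
aryl_core <- function(sub, pos = c("para", "meta")) {
  pos <- match.arg(pos)
  if (pos == "para") sprintf("c1ccc(%s)cc1", sub)
  else sprintf("c1cccc(%s)c1", sub)
}

## species = core with a fragment grafted onto atom 1; returns the graph
## and its canonical SMILES
graft_species <- function(core_smiles, frag_smiles) {
  g <- attach_fragment(parse_molgraph(core_smiles), 1L,
                       parse_molgraph(frag_smiles), 1L)
  list(graph = g, smiles = molgraph_to_smiles(g))
}

## formal coupling: bond atom `a` of g1 to atom `b` of g2
join_fragments <- function(g1, a, g2, b) {
  off <- length(g1$elem)
  g <- attach_fragment(g1, a, g2, b)
  molgraph_to_smiles(g)
}

type_reagents <- function(rxn_type) {
  switch(rxn_type,
         hiyama = c("[F-]", "[K+]"),
         suzuki = c("[OH-]", "[K+]"),
         kumada = character(0),
         buchwald_hartwig = c("CC(C)(C)[O-]", "[Na+]"),
         chan_lam = character(0))
}

#' Generate a synthetic coupling-reaction dataset
#'
#' Builds `n_aryl x n_partner` unique reactions of one coupling class.
#' Aryl halides enumerate (substituent, ring position, halide); partners
#' enumerate (substituent, ring position, leaving-group member of the
#' type's partner class). Products are assembled by formal coupling of
#' the two retained fragments. The seed only shuffles which combinations
#' are drawn; generation is byte-deterministic per seed.
#'
#' @param rxn_type One of `"hiyama"`, `"suzuki"`, `"kumada"`,
#'   `"buchwald_hartwig"`, `"chan_lam"`.
#' @param n_aryl Number of halide-side (for Chan-Lam: boron-side)
#'   variants.
#' @param n_partner Number of partner variants.
#' @param vocab Ring-substituent vocabulary ([default_substituents()]).
#' @param seed Integer seed.
#' @param classes Functional-group classes (members drawn for partner
#'   handles).
#' @param spectator_fraction Fraction of partner variants carrying an
#'   additional spectator chlorine substituent that survives into the
#'   product. Default 0.
#' @return List of `rxn_record` (provenance `"raw"`, `rxn_type` set to
#'   the generated class, roles unassigned). Each record carries an
#'   attribute `ground_truth`: list with the per-role member names and
#'   the expected single/simultaneous fake counts under `classes`.
#' @export
generate_coupling_dataset <- function(rxn_type, n_aryl, n_partner,
                                      vocab = default_substituents(),
                                      seed = 0,
                                      classes = default_fg_classes(),
                                      spectator_fraction = 0) {
  stopifnot(rxn_type %in% c("hiyama", "suzuki", "kumada",
                            "buchwald_hartwig", "chan_lam"))
  halogens <- classes$halogen$members
  partner_class <- switch(rxn_type,
                          hiyama = classes$silicon,
                          suzuki = classes$boron,
                          kumada = classes$grignard_halide,
                          buchwald_hartwig = NULL,
                          chan_lam = NULL)
  # chan_lam's first side carries the boron handle instead of a halide
  first_members <- if (rxn_type == "chan_lam") {
    classes$boron$members
  } else {
    halogens
  }

  aryl_combos <- expand.grid(sub = names(vocab), pos = c("para", "meta"),
                             member = names(first_members),
                             stringsAsFactors = FALSE)
  partner_combos <- expand.grid(sub = names(vocab),
                                pos = c("para", "meta"),
                                member = if (is.null(partner_class)) "amine"
                                         else names(partner_class$members),
                                stringsAsFactors = FALSE)
  if (nrow(aryl_combos) < n_aryl) {
    stop("substituent vocabulary too small for n_aryl = ", n_aryl,
         " (", nrow(aryl_combos), " combinations available)")
  }
  if (nrow(partner_combos) < n_partner) {
    stop("substituent vocabulary too small for n_partner = ", n_partner,
         " (", nrow(partner_combos), " combinations available)")
  }
  ai <- with_seed(seed, sample.int(nrow(aryl_combos)))[seq_len(n_aryl)]
  pi_ <- with_seed(seed + 1L,
                   sample.int(nrow(partner_combos)))[seq_len(n_partner)]
  spectate <- rep(FALSE, n_partner)
  if (spectator_fraction > 0) {
    spectate[seq_len(floor(n_partner * spectator_fraction))] <- TRUE
  }

  records <- list()
  gt_counts <- augmentation_count_laws(rxn_type, classes)
  for (i in seq_len(n_aryl)) {
    a <- aryl_combos[ai[i], ]
    core1 <- aryl_core(vocab[[a$sub]], a$pos)
    sp1 <- build_first_species(rxn_type, core1, a$member, classes)
    for (j in seq_len(n_partner)) {
      p <- partner_combos[pi_[j], ]
      sub2 <- vocab[[p$sub]]
      core2 <- if (spectate[j]) {
        # spectator chlorine placement depends on the ring position so
        # para/meta variants remain distinct species
        if (p$pos == "para") sprintf("c1cc(Cl)c(%s)cc1", sub2)
        else sprintf("c1cc(%s)cc(Cl)c1", sub2)
      } else {
        aryl_core(sub2, p$pos)
      }
      sp2 <- build_partner_species(rxn_type, core2, p$member, classes)
      prod <- build_product(rxn_type, sp1, sp2)
      rec <- rxn_record(reactants = c(sp1$smiles, sp2$smiles),
                        reagents = type_reagents(rxn_type),
                        product = prod, rxn_type = rxn_type,
                        provenance = "raw", canonicalize = TRUE)
      attr(rec, "ground_truth") <- list(
        first_member = a$member, partner_member = p$member,
        first_sub = vocab[[a$sub]], first_pos = a$pos,
        partner_sub = sub2, partner_pos = p$pos,
        spectator = spectate[j],
        n_single = gt_counts$n_single,
        n_simultaneous = gt_counts$n_simultaneous)
      records[[length(records) + 1L]] <- rec
    }
  }
  keys <- record_keys(records)
  if (anyDuplicated(keys)) {
    stop("generated reactions are not unique; enlarge the vocabulary")
  }
  records
}

## expected per-record fake counts with unique sites
augmentation_count_laws <- function(rxn_type, classes) {
  n_hal <- length(classes$halogen$members)
  switch(rxn_type,
         hiyama = list(n_single = n_hal - 1L,
                       n_simultaneous =
                         n_hal * length(classes$silicon$members) - 1L),
         suzuki = list(n_single = n_hal - 1L,
                       n_simultaneous =
                         n_hal * length(classes$boron$members) - 1L),
         kumada = list(n_single = n_hal - 1L,
                       n_simultaneous =
                         n_hal * length(classes$grignard_halide$members) - 1L),
         buchwald_hartwig = list(n_single = n_hal - 1L,
                                 n_simultaneous = NA_integer_),
         chan_lam = list(n_single = length(classes$boron$members) - 1L,
                         n_simultaneous = NA_integer_))
}

build_first_species <- function(rxn_type, core, member, classes) {
  frag <- if (rxn_type == "chan_lam") {
    classes$boron$members[[member]]
  } else {
    classes$halogen$members[[member]]
  }
  graft_species(core, frag)
}

build_partner_species <- function(rxn_type, core, member, classes) {
  if (rxn_type == "hiyama") {
    graft_species(core, classes$silicon$members[[member]])
  } else if (rxn_type == "suzuki") {
    graft_species(core, classes$boron$members[[member]])
  } else if (rxn_type == "kumada") {
    # aryl-Mg-X: graft Mg onto the ring, then the halide onto Mg
    g <- attach_fragment(parse_molgraph(core), 1L,
                         parse_molgraph("[Mg]"), 1L)
    mg <- length(g$elem)
    g <- attach_fragment(
      g, mg, parse_molgraph(classes$grignard_halide$members[[member]]), 1L)
    list(graph = g, smiles = molgraph_to_smiles(g))
  } else {
    # buchwald_hartwig / chan_lam: primary aryl amine
    graft_species(core, "N")
  }
}

## formal coupling product: retained fragment of side 1 joined to the
## retained fragment (or nucleophile atom) of side 2
build_product <- function(rxn_type, sp1, sp2) {
  core1 <- remove_pendant_fragment(sp1$graph)
  if (rxn_type %in% c("hiyama", "suzuki", "kumada")) {
    core2 <- remove_pendant_fragment(sp2$graph)
    join_fragments(core1$graph, core1$anchor, core2$graph, core2$anchor)
  } else {
    # C-N coupling: the whole amine is retained, bonded through N
    n_at <- which(sp2$graph$elem == "N")
    stopifnot(length(n_at) >= 1)
    join_fragments(core1$graph, core1$anchor, sp2$graph,
                   n_at[length(n_at)])
  }
}

## delete the grafted leaving-group fragment (everything attached to the
## species' atom-1 anchor beyond the core); the generator grafts onto
## atom 1, so the pendant is the component reachable from atom 1's
## non-core neighbour added last
remove_pendant_fragment <- function(g) {
  # by construction the core occupies the first n_core atoms and the
  # grafted fragment the rest; the fragment root bonds to atom 1
  nb <- graph_neighbors(g, 1L)
  # fragment atoms are those with indices above the core: the grafted
  # fragment was appended after the core, so its atoms form the tail
  frag_root <- max(nb)
  frag_atoms <- reachable_atoms(g, frag_root, blocked = 1L)
  list(graph = remove_atoms(g, frag_atoms), anchor = 1L)
}

#' Generate decoy reactions that fail every coupling template
#'
#' Simple esterifications, reductions, amidations and cycloadditions
#' lacking any coupling motif: negative controls for template screening.
#'
#' @param n Number of decoys.
#' @param vocab Ring-substituent vocabulary.
#' @param seed Integer seed.
#' @return List of `rxn_record` (rxn_type `"unknown"`).
#' @export
generate_decoys <- function(n, vocab = default_substituents(), seed = 0) {
  if (n == 0) return(list())
  scaffolds <- list(
    function(R) sprintf("CC(=O)O.OCc1ccc(%s)cc1>>CC(=O)OCc1ccc(%s)cc1",
                        R, R),
    function(R) sprintf("CC(=O)c1ccc(%s)cc1>>CC(O)c1ccc(%s)cc1", R, R),
    function(R) sprintf("N#Cc1ccc(%s)cc1.O>>NC(=O)c1ccc(%s)cc1", R, R),
    function(R) sprintf("CC(=O)O.NCc1ccc(%s)cc1>>CC(=O)NCc1ccc(%s)cc1",
                        R, R),
    function(R) sprintf("C=CC=C.C=C%s>>C1CC(%s)CC=C1", R, R))
  combos <- expand.grid(s = seq_along(scaffolds), v = names(vocab),
                        stringsAsFactors = FALSE)
  if (nrow(combos) < n) {
    stop("substituent vocabulary too small for ", n, " decoys")
  }
  idx <- with_seed(seed, sample.int(nrow(combos)))[seq_len(n)]
  out <- lapply(idx, function(k) {
    sc <- scaffolds[[combos$s[k]]]
    parse_reaction_smiles(sc(vocab[[combos$v[k]]]))
  })
  keys <- vapply(out, `[[`, character(1), "canonical_string")
  out[!duplicated(keys)]
}

#' Constructed prediction suite for the error cascade
#'
#' A fixed set of (predicted, reference) product pairs with known labels,
#' at least two per label, patterned on the four observed failure modes
#' of coupling-product prediction (stereo flips, malformed strings,
#' carbon-count slips, positional/functional-group isomers) plus correct
#' and unclassifiable cases.
#'
#' @return A data.frame with columns `predicted`, `reference`,
#'   `expected`.
#' @export
generate_prediction_suite <- function() {
  rows <- list(
    c("Cc1ccc(-c2ccc(C#N)cc2)cc1", "Cc1ccc(-c2ccc(C#N)cc2)cc1", "correct"),
    c("OCC", "CCO", "correct"),
    c("c1ccc(Br)cc1", "Brc1ccccc1", "correct"),
    c("CC((", "CCO", "invalid_smiles"),
    c("c1ccccc", "c1ccccc1", "invalid_smiles"),
    c("C1CC", "CCC", "invalid_smiles"),
    c("C[C@@H](N)C(=O)O", "C[C@H](N)C(=O)O", "chirality"),
    c("F/C=C/F", "F/C=C\\F", "chirality"),
    c("CCCc1ccccc1", "CCc1ccccc1", "atom_count"),
    c("CCO", "CO", "atom_count"),
    c("CC(C)c1ccc(C)cc1", "Cc1ccc(C)cc1", "atom_count"),
    c("Cc1ccccc1C", "Cc1ccc(C)cc1", "group_isomerism"),
    c("CCO", "COC", "group_isomerism"),
    c("CCCO", "CC(C)O", "group_isomerism"),
    c("CCO", "CCN", "other"),
    c("Oc1ccccc1", "Nc1ccccc1", "other"),
    c("CCS", "CCO", "other"))
  out <- as.data.frame(do.call(rbind, rows), stringsAsFactors = FALSE)
  names(out) <- c("predicted", "reference", "expected")
  out
}
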