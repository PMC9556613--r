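## Coupling-reaction templates and template screening.
##
## A template defines one coupling class by: a SMARTS pattern per reactant
## role, a product check, and which roles may be augmented with which
## functional-group class. Screening a corpus against a template is the
## curation step that keeps only reactions of that class.
##
## The product check is formal rather than atom-mapped: for a candidate
## role assignment it verifies that the product's heavy-atom element
## counts equal the sum of the two transferred fragments — each role
## species minus its leaving group (the halide atom; the metal plus
## everything attached to it except one carbon branch; nothing for N/O
## nucleophiles, which lose only hydrogen). A passing assignment therefore
## certifies both the loss of both leaving groups and the formation of the
## new bond joining the two retained fragments into the single product.

TEMPLATE_PRECEDENCE <- c("suzuki", "hiyama", "kumada", "buchwald_hartwig",
                         "chan_lam")

#' Default coupling-reaction templates
#'
#' The five shipped templates (role SMARTS are user-overridable via
#' [write_templates()] / [read_templates()]):
#'
#' * **suzuki** — aryl/vinyl halide + organoboron, C-C bond.
#' * **hiyama** — aryl/vinyl halide + organosilicon, C-C bond.
#' * **kumada** — organic halide (aryl, vinyl, or primary alkyl) +
#'   Grignard reagent `C-Mg-X`, C-C bond.
#' * **buchwald_hartwig** — aryl halide + N-H amine, C-N bond.
#' * **chan_lam** — organoboron + N-H or O-H nucleophile, C-N/C-O bond.
#'
#' Halide patterns cover Cl/Br/I on aromatic or vinylic carbon (plus
#' primary alkyl for Kumada only); fluorine is never a leaving group.
#'
#' @return Named list of `rxn_template` objects.
#' @export
default_templates <- function() {
  halide_aryl <- c("[Cl,Br,I][c]", "[Cl,Br,I][CX3]=[CX3]")
  halide_kumada <- c(halide_aryl, "[Cl,Br,I][CX4;H2][#6]")
  # metal-role patterns are anchored on the metal atom itself so that the
  # match count equals the number of metal groups in the species (the
  # ambiguous-site criterion), not the number of C-metal bonds
  boron <- "[$([B]([OX2])([OX2])[#6]),$([B-](F)(F)(F)[#6])]"
  amine <- "[NX3;H1,H2;!$([N]=*);!$([N][!#6;!#1])]"
  n_or_o <- paste0("[$([NX3;H1,H2;!$([N]=*);!$([N][!#6;!#1])]),",
                   "$([OX2H][#6;!$([#6]=[O])])]")
  mk <- function(name, roles, bond, augmentable_roles, default_mode) {
    structure(list(name = name, roles = roles, bond = bond,
                   augmentable_roles = augmentable_roles,
                   default_mode = default_mode),
              class = "rxn_template")
  }
  role <- function(pattern, kind, metal = NULL) {
    list(pattern = pattern, kind = kind, metal = metal)
  }
  list(
    suzuki = mk("suzuki",
                list(aryl_halide = role(halide_aryl, "halide"),
                     organoboron = role(boron, "metal", "B")),
                bond = "C-C",
                augmentable_roles = c(aryl_halide = "halogen",
                                      organoboron = "boron"),
                default_mode = "simultaneous"),
    hiyama = mk("hiyama",
                list(aryl_halide = role(halide_aryl, "halide"),
                     organosilicon = role("[Si;$([Si][#6])]", "metal", "Si")),
                bond = "C-C",
                augmentable_roles = c(aryl_halide = "halogen",
                                      organosilicon = "silicon"),
                default_mode = "simultaneous"),
    kumada = mk("kumada",
                list(organic_halide = role(halide_kumada, "halide"),
                     grignard = role("[Mg;$([Mg]([#6])[Cl,Br,I])]",
                                     "metal", "Mg")),
                bond = "C-C",
                augmentable_roles = c(organic_halide = "halogen",
                                      grignard = "grignard_halide"),
                default_mode = "simultaneous"),
    buchwald_hartwig = mk("buchwald_hartwig",
                          list(aryl_halide = role(halide_aryl, "halide"),
                               amine = role(amine, "nucleophile")),
                          bond = "C-N",
                          augmentable_roles = c(aryl_halide = "halogen"),
                          default_mode = "single"),
    chan_lam = mk("chan_lam",
                  list(organoboron = role(boron, "metal", "B"),
                       nucleophile = role(n_or_o, "nucleophile")),
                  bond = "C-N/C-O",
                  augmentable_roles = c(organoboron = "boron"),
                  default_mode = "single")
  )
}

#' Write templates to a versioned YAML file
#'
#' @param templates Named list of `rxn_template`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_templates <- function(templates, path) {
  out <- list(schema_version = 1L,
              templates = lapply(templates, function(tp) {
                list(name = tp$name,
                     roles = lapply(tp$roles, function(r) {
                       list(pattern = as.list(r$pattern), kind = r$kind,
                            metal = r$metal)
                     }),
                     bond = tp$bond,
                     augmentable_roles = as.list(tp$augmentable_roles),
                     default_mode = tp$default_mode)
              }))
  yaml::write_yaml(out, path)
  invisible(path)
}

#' Read templates from YAML
#'
#' @param path Path written by [write_templates()] (or hand-edited).
#' @return Named list of `rxn_template`.
#' @export
read_templates <- function(path) {
  raw <- yaml::read_yaml(path)
  if (is.null(raw$schema_version) || raw$schema_version != 1L) {
    stop("unsupported template schema version")
  }
  templates <- lapply(raw$templates, function(tp) {
    structure(list(name = tp$name,
                   roles = lapply(tp$roles, function(r) {
                     list(pattern = unlist(r$pattern), kind = r$kind,
                          metal = r$metal)
                   }),
                   bond = tp$bond,
                   augmentable_roles = unlist(tp$augmentable_roles),
                   default_mode = tp$default_mode),
              class = "rxn_template")
  })
  names(templates) <- vapply(templates, `[[`, character(1), "name")
  templates
}

## total SMARTS match count of a role pattern (vector of alternatives)
## within one species
role_match_count <- function(smiles, patterns) {
  key <- paste0("SM>", smiles, ">", paste(patterns, collapse = "|"))
  hit <- .rxnaug_cache[[key]]
  if (!is.null(hit)) return(hit)
  mol <- ChemmineOB::forEachMol("SMILES", smiles, identity)
  n <- sum(vapply(patterns, function(p) {
    as.integer(ChemmineOB::smartsSearch_OB(mol, p, uniqueMatches = TRUE))
  }, integer(1)))
  .rxnaug_cache[[key]] <- n
  n
}

## candidate retained-fragment element counts for one role species.
## halide: species minus one terminal halogen on carbon (per halogen);
## metal: one carbon branch of the metal atom (per metal, per C neighbour);
## nucleophile: the whole species (only H is lost).
retained_fragment_counts <- function(g, role) {
  if (role$kind == "nucleophile") {
    return(list(element_counts(g)))
  }
  out <- list()
  if (role$kind == "halide") {
    for (h in which(g$elem %in% c("Cl", "Br", "I"))) {
      nb <- graph_neighbors(g, h)
      if (length(nb) == 1L && g$elem[nb] == "C") {
        out[[length(out) + 1L]] <-
          element_counts(g, setdiff(seq_along(g$elem), h))
      }
    }
  } else if (role$kind == "metal") {
    for (m in which(g$elem == role$metal)) {
      for (c_at in graph_neighbors(g, m)) {
        if (g$elem[c_at] != "C") next
        branch <- reachable_atoms(g, c_at, blocked = m)
        out[[length(out) + 1L]] <- element_counts(g, branch)
      }
    }
  }
  out
}

## does any combination of retained fragments across the two roles balance
## the product's heavy-atom counts?
product_check <- function(left_smiles, assignment, product_smiles, template) {
  pg <- parse_molgraph(product_smiles)
  target <- element_counts(pg)
  role_names <- names(template$roles)
  cand <- lapply(role_names, function(rn) {
    g <- parse_molgraph(left_smiles[assignment[[rn]]])
    retained_fragment_counts(g, template$roles[[rn]])
  })
  if (any(lengths(cand) == 0L)) return(FALSE)
  for (a in cand[[1]]) {
    for (b in cand[[2]]) {
      if (counts_equal(counts_add(a, b), target)) return(TRUE)
    }
  }
  FALSE
}

## enumerate injective role -> species assignments for one template;
## returns the first assignment (deterministic order) passing
## product_check, or NULL
find_role_assignment <- function(left_smiles, template, product_smiles) {
  role_names <- names(template$roles)
  cands <- lapply(role_names, function(rn) {
    which(vapply(left_smiles, role_match_count, integer(1),
                 patterns = template$roles[[rn]]$pattern) > 0L)
  })
  names(cands) <- role_names
  if (any(lengths(cands) == 0L)) return(NULL)
  for (i in cands[[1]]) {
    for (j in cands[[2]]) {
      if (i == j) next
      asg <- stats::setNames(list(i, j), role_names)
      if (product_check(left_smiles, asg, product_smiles, template)) {
        return(asg)
      }
    }
  }
  NULL
}

#' Classify a reaction against the coupling templates
#'
#' Tries each template in the fixed precedence order (suzuki, hiyama,
#' kumada, buchwald_hartwig, chan_lam) and returns the name of the first
#' whose role patterns each match a distinct left-side species and whose
#' product check passes. If more than one template accepts the reaction, a
#' warning is emitted and precedence decides.
#'
#' @param r A `rxn_record`.
#' @param templates Named list of templates ([default_templates()]).
#' @return The reaction-type name, or `NA_character_` if no template
#'   applies.
#' @seealso [classify_record()] for the role-annotated record.
#' @export
classify_reaction <- function(r, templates = default_templates()) {
  out <- classify_record(r, templates)
  if (is.null(out)) NA_character_ else out$rxn_type
}

#' Classify a record and annotate roles
#'
#' Like [classify_reaction()] but returns the updated record: `rxn_type`
#' set; species matched to a role become the `reactants` (in template role
#' order), all other left-side species are demoted to `reagents`; `roles`
#' maps role name to reactant index; `ambiguous_sites` flags roles whose
#' pattern matches more than once within the assigned species (such
#' records pass screening but are excluded from augmentation).
#'
#' @param r A `rxn_record`.
#' @param templates Named list of templates.
#' @return The annotated `rxn_record`, or `NULL` if no template applies.
#' @export
classify_record <- function(r, templates = default_templates()) {
  left <- c(r$reactants, r$reagents)
  matched <- list()
  for (nm in intersect(TEMPLATE_PRECEDENCE, names(templates))) {
    asg <- find_role_assignment(left, templates[[nm]], r$product)
    if (!is.null(asg)) matched[[nm]] <- asg
  }
  if (!length(matched)) return(NULL)
  if (length(matched) > 1L) {
    warning("reaction matches multiple templates (",
            paste(names(matched), collapse = ", "),
            "); precedence picks '", names(matched)[1], "': ",
            r$canonical_string)
  }
  nm <- names(matched)[1]
  template <- templates[[nm]]
  asg <- matched[[1]]
  idx <- unlist(asg)
  r$reactants <- left[idx]
  r$reagents <- left[-idx]
  r$rxn_type <- nm
  r$roles <- stats::setNames(seq_along(idx), names(asg))
  r$ambiguous_sites <- vapply(names(asg), function(rn) {
    role_match_count(left[asg[[rn]]], template$roles[[rn]]$pattern) > 1L
  }, logical(1))
  r$canonical_string <- canonical_reaction_string(r)
  r
}

#' Screen a reaction corpus against one template
#'
#' @param records List of `rxn_record`.
#' @param type Reaction-type name to keep (a template name).
#' @param templates Named list of templates.
#' @return A list with `kept` (annotated records classified as `type`, in
#'   input order), `rejected` (everything else, in input order), and
#'   `report` (counts: total, kept, rejected, ambiguous_site).
#' @export
screen_dataset <- function(records, type, templates = default_templates()) {
  stopifnot(type %in% names(templates))
  kept <- list()
  rejected <- list()
  n_ambig <- 0L
  for (r in records) {
    cr <- classify_record(r, templates)
    if (!is.null(cr) && cr$rxn_type == type) {
      if (any(cr$ambiguous_sites)) n_ambig <- n_ambig + 1L
      kept[[length(kept) + 1L]] <- cr
    } else {
      rejected[[length(rejected) + 1L]] <- r
    }
  }
  list(kept = kept, rejected = rejected,
       report = list(total = length(records), kept = length(kept),
                     rejected = length(rejected),
                     ambiguous_site = n_ambig))
}
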