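## Virtual data augmentation: generate fake reactions by substituting
## equivalent leaving-group functional groups in reactants, leaving the
## product untouched.
##
## A site qualifies for substitution only when (a) the role's pattern
## matches its species unambiguously, (b) exactly one class member occurs
## in that species, and (c) the matched group is confirmed to leave (it
## occurs fewer times in the product than on the left side). Species
## failing any check are skipped, never guessed, so fakes can never move a
## reaction site or alter an atom valence.

#' Find augmentable leaving-group sites in a classified reaction
#'
#' @param r A `rxn_record` annotated by [classify_record()].
#' @param template The record's `rxn_template`.
#' @param fg_class The functional-group class to substitute
#'   (an `fg_class`).
#' @param role Role name; defaults to the template's augmentable role
#'   bound to this class.
#' @return A list of site objects (`role`, `species` index into
#'   `r$reactants`, `member`, `member_smiles`, `atoms`, `anchor`,
#'   `leaving_group_confirmed`); empty when no unambiguous confirmed site
#'   exists.
#' @export
find_augmentable_sites <- function(r, template, fg_class, role = NULL) {
  if (is.null(r$roles)) {
    stop("record has no role assignment; run classify_record() or ",
         "screen_dataset() before augmenting")
  }
  if (is.null(role)) {
    hit <- names(template$augmentable_roles)[
      template$augmentable_roles == fg_class$name]
    if (!length(hit)) return(list())
    role <- hit[1]
  }
  if (!role %in% names(r$roles)) return(list())
  if (isTRUE(r$ambiguous_sites[[role]])) return(list())
  sp_idx <- r$roles[[role]]
  g <- parse_molgraph(r$reactants[sp_idx])

  hits <- list()
  for (mn in names(fg_class$members)) {
    frag <- parse_molgraph(fg_class$members[[mn]])
    for (m in match_pendant(g, frag, attach = 1L,
                            attach_elem = fg_class$attach_elem)) {
      hits[[length(hits) + 1L]] <- list(member = mn, match = m)
    }
  }
  # the member must occur exactly once in the species (across the class)
  if (length(hits) != 1L) return(list())
  mn <- hits[[1]]$member
  frag <- parse_molgraph(fg_class$members[[mn]])

  # leaving-group confirmation: the member occurs fewer times in the
  # product than on the whole left side (spectator groups survive and
  # fail this check)
  pendant_count <- function(smiles) {
    length(match_pendant(parse_molgraph(smiles), frag, attach = 1L,
                         attach_elem = fg_class$attach_elem))
  }
  n_left <- sum(vapply(c(r$reactants, r$reagents), pendant_count,
                       integer(1)))
  n_prod <- pendant_count(r$product)
  if (n_prod >= n_left) return(list())

  list(list(role = role, species = sp_idx, member = mn,
            member_smiles = fg_class$members[[mn]],
            atoms = hits[[1]]$match$atoms,
            anchor = hits[[1]]$match$anchor,
            leaving_group_confirmed = TRUE))
}

#' Substitute one functional group in a molecule
#'
#' Graph surgery: removes the matched member's atoms from the species and
#' grafts the replacement fragment onto the same anchor atom with a single
#' bond. The result is re-canonicalized; a substitution yielding a
#' structure the backend cannot render is an error, never silently
#' emitted.
#'
#' @param smiles Species SMILES the site was found in.
#' @param site A site from [find_augmentable_sites()].
#' @param new_member Fragment SMILES of the replacement (attachment atom
#'   first). Must differ structurally from the matched member.
#' @return Canonical SMILES of the substituted species.
#' @export
substitute_group <- function(smiles, site, new_member) {
  old_frag <- parse_molgraph(site$member_smiles)
  new_frag <- parse_molgraph(new_member)
  if (identical(molgraph_to_smiles(old_frag), molgraph_to_smiles(new_frag))) {
    stop("identity replacement: new member equals the matched member (",
         new_member, ")")
  }
  g <- parse_molgraph(smiles)
  anchor <- site$anchor - sum(site$atoms < site$anchor)
  g2 <- remove_atoms(g, site$atoms)
  g3 <- attach_fragment(g2, anchor, new_frag, 1L)
  molgraph_to_smiles(g3)
}

## build a fake record from a parent with some reactant species replaced
make_fake <- function(parent, new_reactants) {
  r <- parent
  r$reactants <- new_reactants
  r$provenance <- "fake"
  r$canonical_string <- canonical_reaction_string(r)
  r
}

dedup_records <- function(records) {
  keys <- vapply(records, `[[`, character(1), "canonical_string")
  records[!duplicated(keys)]
}

sort_records <- function(records) {
  keys <- vapply(records, `[[`, character(1), "canonical_string")
  records[order(keys, method = "radix")]
}

#' Single augmentation of one reaction
#'
#' Replaces the functional group of exactly one reactant role: one fake
#' reaction per alternative class member at the role's confirmed site.
#' The product is copied unchanged; fakes carry `provenance = "fake"`;
#' the parent reaction itself is never emitted. With a unique site the
#' number of fakes is `|members| - 1`.
#'
#' @param r A classified `rxn_record`.
#' @param template The record's template.
#' @param role The single role to augment.
#' @param classes Functional-group classes ([default_fg_classes()]).
#' @return List of fake `rxn_record`, deduplicated and sorted by
#'   canonical string; empty when the role has no augmentable site.
#' @export
single_augment <- function(r, template, role,
                           classes = default_fg_classes()) {
  stopifnot(role %in% names(template$augmentable_roles))
  cls <- classes[[template$augmentable_roles[[role]]]]
  sites <- find_augmentable_sites(r, template, cls, role = role)
  if (!length(sites)) return(list())
  site <- sites[[1]]
  fakes <- list()
  for (mn in setdiff(names(cls$members), site$member)) {
    new_sp <- substitute_group(r$reactants[site$species], site,
                               cls$members[[mn]])
    reac <- r$reactants
    reac[site$species] <- new_sp
    fakes[[length(fakes) + 1L]] <- make_fake(r, reac)
  }
  keys <- vapply(fakes, `[[`, character(1), "canonical_string")
  fakes <- fakes[keys != r$canonical_string]
  sort_records(dedup_records(fakes))
}

#' Simultaneous augmentation of one reaction
#'
#' Cartesian substitution across two or more reactant roles at once: one
#' fake per combination of class members over the roles, minus the
#' original combination. Products are copied unchanged. With unique sites
#' the number of fakes is `prod(|members|) - 1`.
#'
#' @param r A classified `rxn_record`.
#' @param template The record's template.
#' @param roles Character vector (length >= 2) of roles to augment;
#'   defaults to all augmentable roles of the template.
#' @param classes Functional-group classes.
#' @return List of fake `rxn_record`, deduplicated and sorted; empty when
#'   any requested role lacks an augmentable site.
#' @export
simultaneous_augment <- function(r, template,
                                 roles = names(template$augmentable_roles),
                                 classes = default_fg_classes()) {
  stopifnot(length(roles) >= 2,
            all(roles %in% names(template$augmentable_roles)))
  site_of <- list()
  cls_of <- list()
  for (role in roles) {
    cls <- classes[[template$augmentable_roles[[role]]]]
    sites <- find_augmentable_sites(r, template, cls, role = role)
    if (!length(sites)) return(list())
    site_of[[role]] <- sites[[1]]
    cls_of[[role]] <- cls
  }
  grid <- expand.grid(lapply(roles, function(role) {
    names(cls_of[[role]]$members)
  }), stringsAsFactors = FALSE)
  names(grid) <- roles
  orig <- vapply(roles, function(role) site_of[[role]]$member, character(1))
  fakes <- list()
  for (i in seq_len(nrow(grid))) {
    combo <- unlist(grid[i, , drop = FALSE])
    if (all(combo == orig)) next
    reac <- r$reactants
    for (role in roles) {
      if (combo[[role]] == orig[[role]]) next
      site <- site_of[[role]]
      reac[site$species] <- substitute_group(
        r$reactants[site$species], site,
        cls_of[[role]]$members[[combo[[role]]]])
    }
    fakes[[length(fakes) + 1L]] <- make_fake(r, reac)
  }
  keys <- vapply(fakes, `[[`, character(1), "canonical_string")
  fakes <- fakes[keys != r$canonical_string]
  sort_records(dedup_records(fakes))
}

#' Augment a list of classified records
#'
#' Driver applying single or simultaneous augmentation to every record of
#' a screened corpus. Records with ambiguous or unconfirmed sites simply
#' contribute no fakes.
#'
#' @param records List of classified `rxn_record` of one reaction type.
#' @param templates Named list of templates.
#' @param classes Functional-group classes.
#' @param mode `"single"` or `"simultaneous"`; default is the template's
#'   shipped mode for the reaction type (simultaneous for Hiyama, Kumada
#'   and Suzuki; single for Buchwald-Hartwig and Chan-Lam).
#' @param roles Roles to augment; default all augmentable roles (single
#'   mode uses the first).
#' @param cap Optional maximum number of fakes kept per parent reaction
#'   (default unlimited); fakes are kept in canonical-string order.
#' @return List of fake records (per-parent deduplicated; merge with
#'   [dedup_and_merge()] for corpus-level dedup and guards).
#' @export
augment_records <- function(records, templates = default_templates(),
                            classes = default_fg_classes(), mode = NULL,
                            roles = NULL, cap = Inf) {
  out <- list()
  for (r in records) {
    template <- templates[[r$rxn_type]]
    if (is.null(template)) next
    m <- if (is.null(mode)) template$default_mode else mode
    rl <- if (is.null(roles)) names(template$augmentable_roles) else roles
    fakes <- if (m == "single") {
      single_augment(r, template, rl[1], classes)
    } else {
      if (length(rl) < 2) {
        single_augment(r, template, rl[1], classes)
      } else {
        simultaneous_augment(r, template, rl, classes)
      }
    }
    if (is.finite(cap) && length(fakes) > cap) {
      fakes <- fakes[seq_len(cap)]
    }
    out <- c(out, fakes)
  }
  out
}

#' Merge raw reactions with fakes, deleting repeats
#'
#' Corpus-level deduplication of augmentation output: fakes whose
#' canonical string collides with a raw reaction, with the guard set
#' (validation/test reactions — the leakage guard), or with an
#' already-kept fake are deleted. Raw order is preserved; surviving fakes
#' are appended in canonical-string order, so merging is idempotent and
#' deterministic.
#'
#' @param raw List of raw `rxn_record` (the training partition).
#' @param fakes List of fake `rxn_record`.
#' @param guard Character vector of canonical reaction strings that fakes
#'   must not collide with (typically validation + test).
#' @return Merged list of records.
#' @export
dedup_and_merge <- function(raw, fakes, guard = character(0)) {
  raw_keys <- vapply(raw, `[[`, character(1), "canonical_string")
  fakes <- sort_records(dedup_records(fakes))
  fkeys <- vapply(fakes, `[[`, character(1), "canonical_string")
  keep <- !(fkeys %in% c(raw_keys, guard))
  c(raw, fakes[keep])
}

#' Canonical strings of a record list
#'
#' @param records List of `rxn_record`.
#' @return Character vector of canonical reaction strings.
#' @export
record_keys <- function(records) {
  vapply(records, `[[`, character(1), "canonical_string")
}
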