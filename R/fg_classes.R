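## Functional-group equivalence classes.
##
## A class names a set of mutually substitutable leaving-group substituent
## patterns, each written as a fragment SMILES whose FIRST atom is the
## attachment point. Swapping one member for another at a confirmed
## leaving-group site is the augmentation primitive. The shipped defaults
## cover the four classes used by the five coupling templates; all are
## user-overridable through a YAML file.

#' Default functional-group equivalence classes
#'
#' * `halogen` — aryl/vinyl halides: `-Cl`, `-Br`, `-I` (fluorine is not a
#'   leaving group in these couplings and is excluded).
#' * `boron` — organoboron handles: boronic acid `-B(OH)2`, pinacol
#'   boronate, 1,3,2-dioxaborinane ester.
#' * `silicon` — organosilicon handles: `-Si(OMe)3`, `-Si(OEt)3`,
#'   `-SiCl3`, `-SiMe2F`.
#' * `grignard_halide` — the halide bound to magnesium in `C-Mg-X`,
#'   X in {Cl, Br, I}.
#'
#' Each member is a fragment SMILES with exactly one open attachment
#' point, its first atom; `attach_elem` restricts the element the
#' substituent may hang from (carbon, or magnesium for the Grignard
#' halide).
#'
#' @return Named list of `fg_class` objects with fields `name`,
#'   `attach_elem`, `members` (named character vector of fragment SMILES).
#' @export
default_fg_classes <- function() {
  mk <- function(name, attach_elem, members) {
    structure(list(name = name, attach_elem = attach_elem,
                   members = members),
              class = "fg_class")
  }
  list(
    halogen = mk("halogen", "C",
                 c(chloro = "Cl", bromo = "Br", iodo = "I")),
    boron = mk("boron", "C",
               c(boronic_acid = "B(O)O",
                 pinacol_boronate = "B1OC(C)(C)C(C)(C)O1",
                 dioxaborinane = "B1OCCCO1")),
    silicon = mk("silicon", "C",
                 c(trimethoxysilyl = "[Si](OC)(OC)OC",
                   triethoxysilyl = "[Si](OCC)(OCC)OCC",
                   trichlorosilyl = "[Si](Cl)(Cl)Cl",
                   dimethylfluorosilyl = "[Si](C)(C)F")),
    grignard_halide = mk("grignard_halide", "Mg",
                         c(chloro = "Cl", bromo = "Br", iodo = "I"))
  )
}

#' Validate a functional-group class
#'
#' Checks that every member fragment parses, is connected, and that
#' members are pairwise distinct after canonicalization.
#'
#' @param cls An `fg_class`.
#' @return `TRUE` invisibly; errors otherwise.
#' @export
validate_fg_class <- function(cls) {
  stopifnot(inherits(cls, "fg_class"), length(cls$members) >= 2)
  canon <- vapply(cls$members, function(m) {
    g <- parse_molgraph(m)
    # connectivity: all atoms reachable from the attachment atom
    if (length(reachable_atoms(g, 1L)) != length(g$elem)) {
      stop("member fragment is not connected: ", m)
    }
    molgraph_to_smiles(g)
  }, character(1))
  if (anyDuplicated(canon)) {
    stop("class '", cls$name, "' has members identical after ",
         "canonicalization: ",
         paste(names(canon)[duplicated(canon)], collapse = ", "))
  }
  invisible(TRUE)
}

#' Write functional-group classes to YAML
#'
#' @param classes Named list of `fg_class` (see [default_fg_classes()]).
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_fg_classes <- function(classes, path) {
  out <- list(schema_version = 1L,
              classes = lapply(classes, function(cl) {
                list(name = cl$name, attach_elem = cl$attach_elem,
                     members = as.list(cl$members))
              }))
  yaml::write_yaml(out, path)
  invisible(path)
}

#' Read functional-group classes from YAML
#'
#' @param path Path written by [write_fg_classes()] (or hand-edited).
#' @return Named list of validated `fg_class` objects.
#' @export
read_fg_classes <- function(path) {
  raw <- yaml::read_yaml(path)
  if (is.null(raw$schema_version) || raw$schema_version != 1L) {
    stop("unsupported functional-group class schema version")
  }
  classes <- lapply(raw$classes, function(cl) {
    structure(list(name = cl$name, attach_elem = cl$attach_elem,
                   members = unlist(cl$members)),
              class = "fg_class")
  })
  names(classes) <- vapply(classes, `[[`, character(1), "name")
  lapply(classes, validate_fg_class)
  classes
}
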