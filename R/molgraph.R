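## Lightweight molecular-graph layer.
##
## Molecules are held as Kekule heavy-atom graphs obtained from (and written
## back through) Open Babel MOL V2000 blocks. Implicit hydrogens are never
## materialised: Open Babel re-derives them from valence when a graph is
## converted back to SMILES. All graph surgery in the augmentation engine
## (deleting a leaving group, attaching a replacement substituent, formal
## coupling of two fragments) operates on this representation.

#' Parse a SMILES string into a molecular graph
#'
#' Converts a single-species SMILES to a Kekule heavy-atom graph via an
#' Open Babel MOL block. Atom order follows the SMILES atom order.
#'
#' @param smiles A single SMILES string (one species, no `.`).
#' @return An object of class `molgraph`: a list with `elem` (character
#'   vector of element symbols), `charge` (integer vector of formal
#'   charges), and `bonds` (integer matrix with columns `a1`, `a2`,
#'   `order`).
#' @export
parse_molgraph <- function(smiles) {
  stopifnot(is.character(smiles), length(smiles) == 1L)
  key <- paste0("G>", smiles)
  hit <- .rxnaug_cache[[key]]
  if (!is.null(hit)) return(hit)
  block <- ob_convert("SMI", "MOL", smiles)
  if (!nzchar(trimws(block))) {
    stop("invalid SMILES (Open Babel could not parse): ", smiles)
  }
  g <- molblock_to_graph(block)
  .rxnaug_cache[[key]] <- g
  g
}

#' Convert a molecular graph back to canonical SMILES
#'
#' @param g A `molgraph`.
#' @return A canonical SMILES string.
#' @export
molgraph_to_smiles <- function(g) {
  out <- ob_convert("MOL", "CAN", graph_to_molblock(g))
  s <- strip_ob_title(out)
  if (!nzchar(s)) stop("graph could not be rendered as SMILES (invalid structure)")
  s
}

molblock_to_graph <- function(block) {
  lines <- strsplit(block, "\n", fixed = TRUE)[[1]]
  counts <- lines[4]
  natoms <- as.integer(substr(counts, 1, 3))
  nbonds <- as.integer(substr(counts, 4, 6))
  if (is.na(natoms)) stop("malformed MOL block")
  elem <- character(natoms)
  charge <- integer(natoms)
  for (i in seq_len(natoms)) {
    ln <- lines[4 + i]
    elem[i] <- trimws(substr(ln, 32, 34))
  }
  bonds <- matrix(0L, nrow = nbonds, ncol = 3,
                  dimnames = list(NULL, c("a1", "a2", "order")))
  for (i in seq_len(nbonds)) {
    ln <- lines[4 + natoms + i]
    bonds[i, ] <- c(as.integer(substr(ln, 1, 3)),
                    as.integer(substr(ln, 4, 6)),
                    as.integer(substr(ln, 7, 9)))
  }
  # formal charges from M  CHG property lines (authoritative in V2000)
  for (ln in grep("^M  CHG", lines, value = TRUE)) {
    flds <- as.integer(strsplit(trimws(substr(ln, 7, nchar(ln))), "\\s+")[[1]])
    n <- flds[1]
    for (k in seq_len(n)) {
      charge[flds[2 * k]] <- flds[2 * k + 1]
    }
  }
  structure(list(elem = elem, charge = charge, bonds = bonds),
            class = "molgraph")
}

graph_to_molblock <- function(g) {
  n <- length(g$elem)
  nb <- nrow(g$bonds)
  hdr <- c("", "  rxnaug", "")
  cnt <- sprintf("%3d%3d  0  0  0  0  0  0  0  0999 V2000", n, nb)
  at <- sprintf("%10.4f%10.4f%10.4f %-3s 0  0  0  0  0  0  0  0  0  0  0  0",
                0, 0, 0, g$elem)
  bd <- character(0)
  if (nb > 0) {
    bd <- sprintf("%3d%3d%3d  0  0  0  0",
                  g$bonds[, 1], g$bonds[, 2], g$bonds[, 3])
  }
  chg <- character(0)
  ci <- which(g$charge != 0L)
  if (length(ci)) {
    # at most 8 entries per M CHG line
    grp <- split(ci, ceiling(seq_along(ci) / 8))
    chg <- vapply(grp, function(ii) {
      paste0("M  CHG", sprintf("%3d", length(ii)),
             paste0(sprintf("%4d%4d", ii, g$charge[ii]), collapse = ""))
    }, character(1))
  }
  paste(c(hdr, cnt, at, bd, chg, "M  END", ""), collapse = "\n")
}

#' @export
print.molgraph <- function(x, ...) {
  cat("<molgraph> ", length(x$elem), " atoms, ", nrow(x$bonds), " bonds: ",
      molgraph_to_smiles(x), "\n", sep = "")
  invisible(x)
}

## ---- basic graph utilities ----

graph_neighbors <- function(g, i) {
  b <- g$bonds
  c(b[b[, 1] == i, 2], b[b[, 2] == i, 1])
}

graph_degree <- function(g, i) length(graph_neighbors(g, i))

bond_order_between <- function(g, i, j) {
  b <- g$bonds
  hit <- (b[, 1] == i & b[, 2] == j) | (b[, 1] == j & b[, 2] == i)
  if (!any(hit)) return(0L)
  b[hit, 3][1]
}

## atoms reachable from `start` without traversing any atom in `blocked`
reachable_atoms <- function(g, start, blocked = integer(0)) {
  seen <- rep(FALSE, length(g$elem))
  seen[blocked] <- TRUE
  stack <- start
  out <- integer(0)
  while (length(stack)) {
    a <- stack[[1]]
    stack <- stack[-1]
    if (seen[a]) next
    seen[a] <- TRUE
    out <- c(out, a)
    stack <- c(stack, graph_neighbors(g, a))
  }
  sort(out)
}

## heavy-atom element counts for a subset of atoms (default: all)
element_counts <- function(g, atoms = seq_along(g$elem)) {
  tab <- table(g$elem[atoms])
  out <- as.integer(tab)
  names(out) <- names(tab)
  out
}

counts_add <- function(a, b) {
  els <- union(names(a), names(b))
  out <- stats::setNames(integer(length(els)), els)
  out[names(a)] <- out[names(a)] + a
  out[names(b)] <- out[names(b)] + b
  out
}

counts_equal <- function(a, b) {
  a <- a[a != 0L]
  b <- b[b != 0L]
  length(a) == length(b) && setequal(names(a), names(b)) &&
    all(a[names(b)] == b)
}

## delete atoms (1-based indices); bonds incident to them are dropped and
## remaining atom indices are compacted
remove_atoms <- function(g, idx) {
  if (!length(idx)) return(g)
  keep <- setdiff(seq_along(g$elem), idx)
  map <- integer(length(g$elem))
  map[keep] <- seq_along(keep)
  b <- g$bonds
  b <- b[!(b[, 1] %in% idx | b[, 2] %in% idx), , drop = FALSE]
  b[, 1] <- map[b[, 1]]
  b[, 2] <- map[b[, 2]]
  structure(list(elem = g$elem[keep], charge = g$charge[keep], bonds = b),
            class = "molgraph")
}

## graft `frag` onto `g`: bond g's atom `anchor` to frag's atom
## `frag_attach` with a single bond; returns the combined graph
attach_fragment <- function(g, anchor, frag, frag_attach) {
  off <- length(g$elem)
  fb <- frag$bonds
  if (nrow(fb)) {
    fb[, 1] <- fb[, 1] + off
    fb[, 2] <- fb[, 2] + off
  }
  newb <- rbind(g$bonds, fb,
                matrix(c(anchor, frag_attach + off, 1L), ncol = 3))
  colnames(newb) <- c("a1", "a2", "order")
  structure(list(elem = c(g$elem, frag$elem),
                 charge = c(g$charge, frag$charge),
                 bonds = newb),
            class = "molgraph")
}

## ---- pendant-substituent subgraph matching ----

## Find occurrences of `frag` (a molgraph with one designated attachment
## atom, `attach`) inside `g` as a *pendant substituent*: an induced
## subgraph isomorphic to frag in elements, charges and bond orders, whose
## only connection to the rest of g is one single bond from the image of
## the attachment atom. `attach_elem`, if given, constrains the element of
## the external anchor atom the substituent hangs from.
##
## Returns a list of matches: list(atoms = mapped indices in frag-atom
## order, anchor = the external neighbour atom). Matches are deduplicated
## by atom set (internal symmetries of the fragment collapse to one).
match_pendant <- function(g, frag, attach = 1L, attach_elem = NULL) {
  nf <- length(frag$elem)
  # BFS order over fragment starting at the attachment atom, so each
  # subsequent atom has a matched neighbour to hang from
  ordr <- integer(0)
  seen <- rep(FALSE, nf)
  queue <- attach
  while (length(queue)) {
    a <- queue[[1]]; queue <- queue[-1]
    if (seen[a]) next
    seen[a] <- TRUE
    ordr <- c(ordr, a)
    queue <- c(queue, graph_neighbors(frag, a))
  }
  if (length(ordr) < nf) stop("fragment is not connected")

  matches <- list()
  sets_seen <- character(0)

  extend <- function(map) {
    k <- sum(!is.na(map))
    if (k == nf) {
      mapped <- map[ordr]  # includes all fragment atoms
      atoms <- map         # frag index -> g index
      # pendant condition: every fragment atom's g-degree equals its
      # frag-degree, except the attachment atom which has exactly one
      # extra (external) single-bond neighbour
      for (fa in seq_len(nf)) {
        dg <- graph_degree(g, atoms[fa])
        df <- graph_degree(frag, fa)
        if (fa == attach) {
          if (dg != df + 1L) return(invisible(NULL))
        } else if (dg != df) {
          return(invisible(NULL))
        }
      }
      anchor <- setdiff(graph_neighbors(g, atoms[attach]), atoms)
      if (length(anchor) != 1L) return(invisible(NULL))
      if (bond_order_between(g, atoms[attach], anchor) != 1L) {
        return(invisible(NULL))
      }
      if (!is.null(attach_elem) && !(g$elem[anchor] %in% attach_elem)) {
        return(invisible(NULL))
      }
      key <- paste(sort(atoms), collapse = ",")
      if (!(key %in% sets_seen)) {
        sets_seen <<- c(sets_seen, key)
        matches[[length(matches) + 1L]] <<- list(atoms = atoms, anchor = anchor)
      }
      return(invisible(NULL))
    }
    fa <- ordr[k + 1L]
    # candidates: neighbours in g of some already-mapped frag neighbour
    fnbrs <- intersect(graph_neighbors(frag, fa), ordr[seq_len(k)])
    ref <- fnbrs[1]
    cands <- graph_neighbors(g, map[ref])
    for (ga in cands) {
      if (ga %in% map) next
      if (g$elem[ga] != frag$elem[fa]) next
      if (g$charge[ga] != frag$charge[fa]) next
      ok <- TRUE
      for (fn in fnbrs) {
        if (bond_order_between(g, ga, map[fn]) !=
            bond_order_between(frag, fa, fn)) {
          ok <- FALSE
          break
        }
      }
      # also: no bonds to mapped atoms that are not frag neighbours
      if (ok) {
        mapped_now <- map[!is.na(map)]
        extra <- intersect(graph_neighbors(g, ga), setdiff(mapped_now, map[fnbrs]))
        if (length(extra)) ok <- FALSE
      }
      if (ok) {
        map2 <- map
        map2[fa] <- ga
        extend(map2)
      }
    }
    invisible(NULL)
  }

  root <- ordr[1]
  for (ga in seq_along(g$elem)) {
    if (g$elem[ga] != frag$elem[root] || g$charge[ga] != frag$charge[root]) next
    map <- rep(NA_integer_, nf)
    map[root] <- ga
    extend(map)
  }
  matches
}
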