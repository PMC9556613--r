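## Core SMILES handling: canonicalization, reaction-record parsing and
## serialization, tokenization, training-config export.
##
## The canonicalization backend is pinned to a single toolkit (Open Babel,
## through ChemmineOB) for the lifetime of the package: every identity
## comparison, dedup and guard check in the pipeline goes through
## canonicalize_smiles(), so all canonical strings are mutually comparable.

# session-level cache: Open Babel conversions are pure, so memoise them
.rxnaug_cache <- new.env(parent = emptyenv())

ob_convert <- function(from, to, source) {
  key <- paste0(from, ">", to, ">", source)
  hit <- .rxnaug_cache[[key]]
  if (!is.null(hit)) return(hit)
  out <- ChemmineOB::convertFormat(from, to, source)
  .rxnaug_cache[[key]] <- out
  out
}

strip_ob_title <- function(x) {
  # Open Babel emits "SMILES\ttitle\n"; keep the SMILES field only
  sub("[\t\n ].*$", "", x)
}

#' Name and version of the pinned canonicalization backend
#'
#' All canonical SMILES produced by this package come from one toolkit, so
#' that canonical strings are valid identity keys for deduplication. The
#' backend identity is embedded in pipeline manifests.
#'
#' @return A single string.
#' @export
canonicalization_backend <- function() {
  paste0("OpenBabel/ChemmineOB ",
         as.character(utils::packageVersion("ChemmineOB")))
}

## Open Babel tolerates some malformed strings (e.g. dangling empty
## branches "CC(("); reject anything whose branch parentheses do not
## balance outside bracket atoms before handing it to the backend.
smiles_parens_balanced <- function(s) {
  bare <- gsub("\\[[^\\]]*\\]", "", s)
  open <- lengths(regmatches(bare, gregexpr("(", bare, fixed = TRUE)))
  close <- lengths(regmatches(bare, gregexpr(")", bare, fixed = TRUE)))
  open == close
}

#' Canonicalize SMILES strings
#'
#' Maps each input SMILES to the unique canonical form assigned by the
#' pinned backend. Canonicalization is idempotent and invariant under
#' input atom reordering. Stereochemistry is preserved unless
#' `strip_stereo = TRUE`, which removes tetrahedral (`@`) and double-bond
#' (`/`, `\`) annotations before canonicalizing.
#'
#' @param smiles Character vector of SMILES (single species or
#'   `.`-separated multi-species strings).
#' @param strip_stereo Drop stereo annotations first? Default `FALSE`.
#' @return Character vector of canonical SMILES.
#' @export
canonicalize_smiles <- function(smiles, strip_stereo = FALSE) {
  stopifnot(is.character(smiles))
  vapply(smiles, function(s) {
    if (strip_stereo) {
      s <- gsub("@", "", s, fixed = TRUE)
      s <- gsub("/", "", s, fixed = TRUE)
      s <- gsub("\\", "", s, fixed = TRUE)
    }
    if (!smiles_parens_balanced(s)) {
      stop("invalid SMILES (unbalanced branch parentheses): ", s)
    }
    out <- strip_ob_title(ob_convert("SMI", "CAN", s))
    if (!nzchar(out)) stop("invalid SMILES (Open Babel could not parse): ", s)
    out
  }, character(1), USE.NAMES = FALSE)
}

#' Test whether SMILES strings parse
#'
#' @param smiles Character vector.
#' @return Logical vector, `TRUE` where the backend can parse the string.
#' @export
is_valid_smiles <- function(smiles) {
  vapply(smiles, function(s) {
    smiles_parens_balanced(s) &&
      nzchar(strip_ob_title(ob_convert("SMI", "CAN", s)))
  }, logical(1), USE.NAMES = FALSE)
}

#' Molecular formula of a species
#'
#' @param smiles A single-species SMILES string.
#' @return The Hill-order molecular formula (implicit hydrogens included),
#'   e.g. `"C8H10"`.
#' @export
molecular_formula <- function(smiles) {
  key <- paste0("MF>", smiles)
  hit <- .rxnaug_cache[[key]]
  if (!is.null(hit)) return(hit)
  mols <- ChemmineOB::forEachMol("SMILES", smiles, identity)
  mf <- ChemmineOB::prop_OB(mols)$formula[1]
  .rxnaug_cache[[key]] <- mf
  mf
}

#' Number of carbon atoms in a species
#'
#' @param smiles A single-species SMILES string.
#' @return Integer count of carbon atoms.
#' @export
carbon_count <- function(smiles) {
  g <- parse_molgraph(smiles)
  sum(g$elem == "C")
}

## ---- reaction records ----

RXN_TYPES <- c("hiyama", "buchwald_hartwig", "chan_lam", "kumada",
               "suzuki", "unknown")

#' Construct a reaction record
#'
#' A `rxn_record` holds one curated reaction: canonical reactant species,
#' canonical reagent species, exactly one canonical product species, a
#' reaction-type label, and a provenance flag distinguishing raw data from
#' virtual ("fake") reactions created by augmentation. Its
#' `canonical_string` — left-side species sorted and dot-joined, then
#' `>>`, then the product — is a pure function of the species multisets
#' and serves as the record's identity key.
#'
#' @param reactants Character vector (length >= 1) of reactant SMILES.
#' @param reagents Character vector (length >= 0) of reagent SMILES.
#' @param product A single product SMILES.
#' @param rxn_type One of `"hiyama"`, `"buchwald_hartwig"`, `"chan_lam"`,
#'   `"kumada"`, `"suzuki"`, `"unknown"`.
#' @param provenance `"raw"` or `"fake"`.
#' @param canonicalize Canonicalize all species first? Default `TRUE`.
#' @return An object of class `rxn_record`.
#' @export
rxn_record <- function(reactants, reagents = character(0), product,
                       rxn_type = "unknown", provenance = "raw",
                       canonicalize = TRUE) {
  stopifnot(length(reactants) >= 1, length(product) == 1,
            rxn_type %in% RXN_TYPES, provenance %in% c("raw", "fake"))
  if (canonicalize) {
    reactants <- canonicalize_smiles(reactants)
    if (length(reagents)) reagents <- canonicalize_smiles(reagents)
    product <- canonicalize_smiles(product)
  }
  r <- structure(list(reactants = reactants, reagents = reagents,
                      product = product, rxn_type = rxn_type,
                      provenance = provenance, roles = NULL),
                 class = "rxn_record")
  r$canonical_string <- canonical_reaction_string(r)
  r
}

#' Canonical identity string of a reaction record
#'
#' @param r A `rxn_record`.
#' @return `sorted(left species)>>product`, all canonical.
#' @export
canonical_reaction_string <- function(r) {
  left <- sort(c(r$reactants, r$reagents), method = "radix")
  paste0(paste(left, collapse = "."), ">>", r$product)
}

#' Parse one reaction SMILES line
#'
#' Accepts both reaction dialects: `reactants[.reagents]>>product` (all
#' left-side species before `>>`) and `reactants>reagents>product`. Each
#' species is parsed and canonicalized. For the `>>` dialect all left-side
#' species start as reactants; template classification
#' ([classify_record()]) later demotes species that contribute no heavy
#' atom to the product (fluoride, bases, catalysts) to reagents.
#'
#' @param line A reaction SMILES string; an optional leading tab-separated
#'   ID field is ignored.
#' @return A `rxn_record`.
#' @export
parse_reaction_smiles <- function(line) {
  stopifnot(is.character(line), length(line) == 1L)
  line <- trimws(line)
  if (grepl("\t", line)) {
    line <- utils::tail(strsplit(line, "\t", fixed = TRUE)[[1]], 1)
  }
  n_sep <- lengths(regmatches(line, gregexpr(">", line, fixed = TRUE)))
  if (n_sep != 2L) {
    stop(errorCondition(
      paste0("malformed reaction separator (expected 'left>>product' or ",
             "'reactants>reagents>product'): ", line),
      class = c("rxnaug_error_separator", "error")))
  }
  if (grepl(">>", line, fixed = TRUE)) {
    at <- regexpr(">>", line, fixed = TRUE)
    left <- substr(line, 1, at - 1)
    mid <- ""
    right <- substr(line, at + 2, nchar(line))
  } else {
    parts <- strsplit(paste0(line, " "), ">", fixed = TRUE)[[1]]
    left <- parts[1]
    mid <- parts[2]
    right <- trimws(parts[3])
  }
  if (!nzchar(left)) {
    stop(errorCondition(paste0("reaction has no reactants: ", line),
                        class = c("rxnaug_error_no_reactants", "error")))
  }
  prods <- strsplit(right, ".", fixed = TRUE)[[1]]
  if (length(prods) != 1L || !nzchar(right)) {
    stop(errorCondition(
      paste0("reaction must have exactly one product species, got ",
             length(prods), ": ", line),
      class = c("rxnaug_error_product_count", "error")))
  }
  reactants <- strsplit(left, ".", fixed = TRUE)[[1]]
  reagents <- if (nzchar(mid)) {
    strsplit(mid, ".", fixed = TRUE)[[1]]
  } else {
    character(0)
  }
  tryCatch(
    rxn_record(reactants, reagents, prods),
    error = function(e) {
      if (inherits(e, "rxnaug_error")) stop(e)
      stop(errorCondition(conditionMessage(e),
                          class = c("rxnaug_error_species_parse", "error")))
    })
}

#' Serialize a reaction record to a reaction SMILES line
#'
#' Always emits the `reactants.reagents>>product` dialect (reagents on the
#' left side, dot-joined after the reactants).
#'
#' @param r A `rxn_record`.
#' @return A single reaction SMILES string.
#' @export
write_reaction_smiles <- function(r) {
  left <- c(r$reactants, r$reagents)
  paste0(paste(left, collapse = "."), ">>", r$product)
}

#' @export
print.rxn_record <- function(x, ...) {
  cat("<rxn_record> [", x$rxn_type, ", ", x$provenance, "]\n",
      "  ", write_reaction_smiles(x), "\n", sep = "")
  invisible(x)
}

#' @export
format.rxn_record <- function(x, ...) write_reaction_smiles(x)

#' Read a reaction SMILES file
#'
#' One reaction per line; blank lines and `#` comment lines are skipped;
#' an optional leading tab-separated ID column is ignored.
#'
#' @param path File path.
#' @return A list of `rxn_record`.
#' @export
read_reactions <- function(path) {
  lines <- readLines(path, encoding = "UTF-8")
  lines <- trimws(lines)
  lines <- lines[nzchar(lines) & !startsWith(lines, "#")]
  lapply(lines, parse_reaction_smiles)
}

#' Write reaction records to a file
#'
#' @param records List of `rxn_record`.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_reactions <- function(records, path) {
  writeLines(vapply(records, write_reaction_smiles, character(1)), path)
  invisible(path)
}

## ---- tokenizer ----

# one token per atom or structural symbol: bracket atoms, two-letter
# halogens, %nn ring closures, ring digits, bonds/branches, then any
# single character
.token_regex <- paste0(
  "\\[[^\\]]*\\]|Br|Cl|%[0-9]{2}|[0-9]|\\(|\\)|\\.|=|#|-|\\+|\\\\|/|:|~|",
  "@|\\?|>|\\*|\\$|[A-Za-z]")

#' Tokenize a SMILES string for seq2seq export
#'
#' Splits a SMILES string into the conventional reaction-prediction token
#' alphabet: bracket atoms (`[K+]`, `[Si]`, `[C@@H]`) and two-letter
#' halogens (`Br`, `Cl`) are single tokens, as are `%nn` ring closures,
#' ring digits, and bond/branch symbols. Tokenization is lossless:
#' concatenating the tokens reproduces the input exactly.
#'
#' @param s A single SMILES string.
#' @return Character vector of tokens.
#' @export
tokenize_smiles <- function(s) {
  stopifnot(is.character(s), length(s) == 1L)
  m <- gregexpr(.token_regex, s, perl = TRUE)[[1]]
  toks <- regmatches(s, list(m))[[1]]
  joined <- paste(toks, collapse = "")
  if (!identical(joined, s)) {
    # locate first untokenizable character for the error message
    pos <- 1L
    n <- min(nchar(joined), nchar(s))
    while (pos <= n &&
           substr(joined, pos, pos) == substr(s, pos, pos)) pos <- pos + 1L
    stop("untokenizable character at position ", pos, " in: ", s)
  }
  toks
}

#' Reassemble a token sequence into a SMILES string
#'
#' @param tokens Character vector of tokens (or one space-separated string).
#' @return The concatenated SMILES string.
#' @export
detokenize_smiles <- function(tokens) {
  if (length(tokens) == 1L && grepl(" ", tokens)) {
    tokens <- strsplit(tokens, " ", fixed = TRUE)[[1]]
  }
  paste(tokens, collapse = "")
}

## ---- training configuration ----

#' Transformer training hyperparameters
#'
#' The reference seq2seq training configuration exported with the curated
#' datasets: Adam optimizer moments and epsilon, attention-head count,
#' embedding width and layer count.
#'
#' @param beta1,beta2,epsilon Adam optimizer parameters.
#' @param n_heads Number of attention heads.
#' @param emb_dim Embedding dimension.
#' @param num_layers Encoder/decoder layer count.
#' @return A named list of class `training_config`.
#' @export
training_config <- function(beta1 = 0.9, beta2 = 0.997, epsilon = 1e-9,
                            n_heads = 8L, emb_dim = 256L, num_layers = 6L) {
  structure(list(beta1 = beta1, beta2 = beta2, epsilon = epsilon,
                 n_heads = as.integer(n_heads),
                 emb_dim = as.integer(emb_dim),
                 num_layers = as.integer(num_layers)),
            class = "training_config")
}

#' Export the training configuration as a key-value YAML file
#'
#' @param path Output path.
#' @param config A [training_config()]; defaults are exported when omitted.
#' @return `path`, invisibly.
#' @export
export_training_config <- function(path, config = training_config()) {
  yaml::write_yaml(unclass(config), path)
  invisible(path)
}

#' Read back a training configuration file
#'
#' @param path Path written by [export_training_config()].
#' @return A `training_config`.
#' @export
read_training_config <- function(path) {
  v <- yaml::read_yaml(path)
  do.call(training_config, v)
}
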