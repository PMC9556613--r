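## Dataset assembly: random 8:1:1 splits, 10-fold cross-validation plans,
## train-only augmentation with leakage guards, statistics, tokenized
## parallel-corpus export.

## run code under a fixed RNG seed without disturbing the caller's stream
with_seed <- function(seed, code) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) {
      assign(".Random.seed", old, envir = globalenv())
    } else if (exists(".Random.seed", envir = globalenv(),
                      inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  })
  set.seed(as.integer(seed))
  force(code)
}

#' Randomly split a corpus into train/validation/test
#'
#' Shuffles the deduplicated raw records with the given seed and
#' partitions them at the requested ratios. Validation and test each
#' receive `floor(N * ratio / sum(ratios))` records (so evaluation sets
#' are never larger than nominal); train takes the remainder. Records
#' within each partition keep their input order.
#'
#' @param records List of `rxn_record` (deduplicated raw data).
#' @param ratios Numeric length-3 vector, default `c(8, 1, 1)`.
#' @param seed Integer seed; the shuffle is its only use.
#' @return A `split_dataset`: list with `train`, `valid`, `test` (record
#'   lists), `seed`, `ratios`.
#' @export
split_dataset <- function(records, ratios = c(8, 1, 1), seed = 0) {
  stopifnot(length(ratios) == 3, all(ratios > 0))
  n <- length(records)
  n_valid <- floor(n * ratios[2] / sum(ratios))
  n_test <- floor(n * ratios[3] / sum(ratios))
  if (n_valid < 1 || n_test < 1) {
    stop("too few records (", n, ") to honor split ratios ",
         paste(ratios, collapse = ":"))
  }
  keys <- record_keys(records)
  if (anyDuplicated(keys)) {
    stop("input records are not deduplicated (",
         sum(duplicated(keys)), " repeated canonical strings)")
  }
  perm <- with_seed(seed, sample.int(n))
  valid_idx <- sort(perm[seq_len(n_valid)])
  test_idx <- sort(perm[n_valid + seq_len(n_test)])
  train_idx <- sort(perm[-(seq_len(n_valid + n_test))])
  structure(list(train = records[train_idx],
                 valid = records[valid_idx],
                 test = records[test_idx],
                 seed = as.integer(seed), ratios = ratios),
            class = "split_dataset")
}

#' @export
print.split_dataset <- function(x, ...) {
  cat("<split_dataset> train ", length(x$train), " / valid ",
      length(x$valid), " / test ", length(x$test),
      " (seed ", x$seed, ")\n", sep = "")
  invisible(x)
}

#' Augment the training partition of a split
#'
#' Applies virtual data augmentation to the training records only:
#' `train` becomes `dedup_and_merge(train, fakes-of-train)` with the
#' validation and test canonical strings as the leakage guard.
#' Validation and test are returned untouched.
#'
#' @param split A `split_dataset` of raw classified records.
#' @param templates,classes,mode,roles,cap Passed to [augment_records()].
#' @return The augmented `split_dataset`.
#' @export
augment_split <- function(split, templates = default_templates(),
                          classes = default_fg_classes(), mode = NULL,
                          roles = NULL, cap = Inf) {
  fakes <- augment_records(split$train, templates, classes, mode, roles,
                           cap)
  guard <- c(record_keys(split$valid), record_keys(split$test))
  split$train <- dedup_and_merge(split$train, fakes, guard)
  split
}

#' Build a k-fold cross-validation plan
#'
#' Shuffles the records once with the seed and assigns them to `k` folds
#' of size `floor(N/k)` or `ceiling(N/k)`. Each record is held out in
#' exactly one fold. Every fold yields a `split_dataset` whose `test` is
#' the held-out fold and whose `train` is the rest (with an empty
#' `valid`); per-fold augmentation via [augment_split()] then guards
#' fakes against that fold's held-out records.
#'
#' @param records List of `rxn_record`.
#' @param k Number of folds, default 10.
#' @param seed Integer seed.
#' @return A `fold_plan`: list with `k`, `assignments` (integer fold index
#'   per record), and `splits` (list of `k` `split_dataset`).
#' @export
kfold_plan <- function(records, k = 10, seed = 0) {
  n <- length(records)
  if (n < k) stop("need at least k = ", k, " records, got ", n)
  perm <- with_seed(seed, sample.int(n))
  fold_sizes <- rep(floor(n / k), k)
  extra <- n - sum(fold_sizes)
  if (extra > 0) fold_sizes[seq_len(extra)] <- fold_sizes[seq_len(extra)] + 1L
  assignments <- integer(n)
  pos <- 0L
  for (f in seq_len(k)) {
    assignments[perm[pos + seq_len(fold_sizes[f])]] <- f
    pos <- pos + fold_sizes[f]
  }
  splits <- lapply(seq_len(k), function(f) {
    structure(list(train = records[assignments != f],
                   valid = list(),
                   test = records[assignments == f],
                   seed = as.integer(seed), ratios = NULL),
              class = "split_dataset")
  })
  structure(list(k = as.integer(k), assignments = assignments,
                 splits = splits, seed = as.integer(seed)),
            class = "fold_plan")
}

#' Summary statistics of raw vs. augmented corpora
#'
#' @param raw List of raw records.
#' @param augmented List of records after augmentation (raw + fakes).
#' @return A `rxnaug_stats` list: `raw_count`, `virtual_count` (the
#'   augmented total), `fake_count`, `growth_factor`, and per-type counts.
#' @export
dataset_stats <- function(raw, augmented) {
  prov <- vapply(augmented, `[[`, character(1), "provenance")
  types <- vapply(augmented, `[[`, character(1), "rxn_type")
  structure(list(raw_count = length(raw),
                 virtual_count = length(augmented),
                 fake_count = sum(prov == "fake"),
                 growth_factor = if (length(raw)) {
                   length(augmented) / length(raw)
                 } else {
                   NA_real_
                 },
                 by_type = table(types)),
            class = "rxnaug_stats")
}

#' @export
print.rxnaug_stats <- function(x, ...) {
  cat("Reaction dataset statistics\n")
  cat(sprintf("  %-16s %8s\n", "", "count"))
  cat(sprintf("  %-16s %8d\n", "raw dataset", x$raw_count))
  cat(sprintf("  %-16s %8d\n", "virtual dataset", x$virtual_count))
  cat(sprintf("  %-16s %8.2f\n", "growth factor", x$growth_factor))
  invisible(x)
}

#' Export a split as tokenized parallel text files
#'
#' Writes the conventional seq2seq layout: `src-train.txt` /
#' `tgt-train.txt`, `src-valid.txt` / `tgt-valid.txt`, `src-test.txt` /
#' `tgt-test.txt`. Line i of a `src` file is the space-separated token
#' sequence of the dot-joined left side (reactants then reagents) of
#' record i; line i of the matching `tgt` file is the tokenized product.
#'
#' @param split A `split_dataset`.
#' @param out_dir Output directory (created if missing).
#' @return Named character vector of the six file paths, invisibly.
#' @export
export_pairs <- function(split, out_dir) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  paths <- character(0)
  for (part in c("train", "valid", "test")) {
    records <- split[[part]]
    src <- vapply(records, function(r) {
      paste(tokenize_smiles(paste(c(r$reactants, r$reagents),
                                  collapse = ".")), collapse = " ")
    }, character(1))
    tgt <- vapply(records, function(r) {
      paste(tokenize_smiles(r$product), collapse = " ")
    }, character(1))
    sp <- file.path(out_dir, paste0("src-", part, ".txt"))
    tp <- file.path(out_dir, paste0("tgt-", part, ".txt"))
    writeLines(src, sp)
    writeLines(tgt, tp)
    paths[paste0("src-", part)] <- sp
    paths[paste0("tgt-", part)] <- tp
  }
  invisible(paths)
}
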