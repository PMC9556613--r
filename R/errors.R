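## Four-category classification of wrong product predictions.
##
## A predicted product is compared with the reference through a fixed
## decision cascade; every (predicted, reference) pair with a valid
## reference receives exactly one label:
##   1. predicted does not parse               -> invalid_smiles
##   2. canonical forms equal                  -> correct
##   3. equal after stripping stereochemistry  -> chirality
##   4. carbon counts differ                   -> atom_count
##   5. same molecular formula, different
##      connectivity (constitutional isomer)   -> group_isomerism
##   6. anything else                          -> other
## Chirality is tested before the carbon count so stereo-only mistakes are
## never masked by later rules.

ERROR_LABELS <- c("correct", "invalid_smiles", "chirality", "atom_count",
                  "group_isomerism", "other")

#' Classify one predicted product against its reference
#'
#' @param predicted Predicted product SMILES (may be unparsable).
#' @param reference Reference product SMILES (must be valid; an invalid
#'   reference is a caller error, not a prediction error).
#' @return One of `"correct"`, `"invalid_smiles"`, `"chirality"`,
#'   `"atom_count"`, `"group_isomerism"`, `"other"`.
#' @export
classify_prediction <- function(predicted, reference) {
  stopifnot(is.character(predicted), length(predicted) == 1L,
            is.character(reference), length(reference) == 1L)
  ref_can <- tryCatch(canonicalize_smiles(reference), error = function(e) {
    stop("invalid reference SMILES: ", reference)
  })
  pred_can <- tryCatch(canonicalize_smiles(predicted),
                       error = function(e) NULL)
  if (is.null(pred_can)) return("invalid_smiles")
  if (identical(pred_can, ref_can)) return("correct")
  if (identical(canonicalize_smiles(predicted, strip_stereo = TRUE),
                canonicalize_smiles(reference, strip_stereo = TRUE))) {
    return("chirality")
  }
  if (carbon_count(predicted) != carbon_count(reference)) {
    return("atom_count")
  }
  if (identical(molecular_formula(predicted),
                molecular_formula(reference))) {
    return("group_isomerism")
  }
  "other"
}

#' Tabulate prediction errors over a test set
#'
#' Labels every (predicted, reference) pair with
#' [classify_prediction()] and reports counts per label plus percentages.
#' Percentages are computed over the wrong predictions only (the
#' `correct` label is excluded from the denominator), the convention used
#' when profiling a model's failure modes.
#'
#' @param predicted Character vector of predicted product SMILES.
#' @param reference Character vector of reference product SMILES (same
#'   length).
#' @return An `error_report`: list with `n` (pairs evaluated), `n_wrong`,
#'   `counts` (named integer vector over all six labels), `percent`
#'   (named numeric vector over the five error labels, summing to 100
#'   when any prediction is wrong), and `labels` (per-pair labels).
#' @export
summarize_errors <- function(predicted, reference) {
  stopifnot(length(predicted) == length(reference))
  labels <- vapply(seq_along(predicted), function(i) {
    classify_prediction(predicted[[i]], reference[[i]])
  }, character(1))
  counts <- vapply(ERROR_LABELS, function(l) sum(labels == l), integer(1))
  n_wrong <- sum(counts[setdiff(ERROR_LABELS, "correct")])
  percent <- if (n_wrong > 0) {
    100 * counts[setdiff(ERROR_LABELS, "correct")] / n_wrong
  } else {
    stats::setNames(numeric(0), character(0))
  }
  structure(list(n = length(labels), n_wrong = n_wrong, counts = counts,
                 percent = percent, labels = labels),
            class = "error_report")
}

#' @export
print.error_report <- function(x, ...) {
  cat("Prediction error report (", x$n, " pairs, ", x$n_wrong,
      " wrong)\n", sep = "")
  for (l in names(x$counts)) {
    pct <- if (l %in% names(x$percent)) {
      sprintf(" %6.2f%% of wrong", x$percent[[l]])
    } else {
      ""
    }
    cat(sprintf("  %-16s %6d%s\n", l, x$counts[[l]], pct))
  }
  invisible(x)
}

#' Write an error report as JSON
#'
#' @param report An `error_report`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_error_report <- function(report, path) {
  jsonlite::write_json(
    list(n = report$n, n_wrong = report$n_wrong,
         counts = as.list(report$counts),
         percent_of_wrong = as.list(report$percent)),
    path, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(path)
}
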