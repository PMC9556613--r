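## End-to-end pipeline: generate or load -> screen -> split -> augment
## (train only) -> export, with a reproducibility manifest.
##
## All randomness flows from one top-level seed, expanded per stage by a
## fixed scheme: the generator uses `seed`, the splitter `seed + 1`, the
## k-fold planner `seed + 2`. Outputs are byte-deterministic for a fixed
## config, and the manifest records seed, config digest, backend identity,
## per-stage counts and output digests (no wall-clock fields, so reruns
## produce identical manifests).

#' Validate a pipeline configuration
#'
#' Required fields: `schema_version` (1), `seed`, `rxn_type` (one of the
#' five templates), and either `generator` (`n_aryl`, `n_partner`,
#' optional `spectator_fraction`, `n_decoys`) or `input` (a reaction
#' SMILES file). Optional: `ratios` (must be the shipped 8:1:1 policy),
#' `augment` (`mode`, `roles`, `cap`).
#'
#' @param config A list (or path to a YAML file).
#' @return The normalized config list; errors with condition class
#'   `rxnaug_error_config` on schema violations.
#' @export
validate_pipeline_config <- function(config) {
  if (is.character(config)) config <- yaml::read_yaml(config)
  fail <- function(...) {
    stop(errorCondition(paste0(...),
                        class = c("rxnaug_error_config", "error")))
  }
  if (is.null(config$schema_version) || config$schema_version != 1) {
    fail("config schema_version must be 1")
  }
  if (is.null(config$seed)) fail("config must set a seed")
  if (is.null(config$rxn_type) ||
      !config$rxn_type %in% c("hiyama", "suzuki", "kumada",
                              "buchwald_hartwig", "chan_lam")) {
    fail("config rxn_type must name one of the five coupling templates")
  }
  if (is.null(config$generator) && is.null(config$input)) {
    fail("config needs either a generator block or an input file")
  }
  if (!is.null(config$input) && !file.exists(config$input)) {
    stop(errorCondition(paste0("input file not found: ", config$input),
                        class = c("rxnaug_error_missing_input", "error")))
  }
  ratios <- config$ratios
  if (is.null(ratios)) ratios <- c(8, 1, 1)
  ratios <- as.numeric(unlist(ratios))
  if (length(ratios) != 3 || !all(ratios == c(8, 1, 1))) {
    fail("ratios must be the 8:1:1 split policy")
  }
  config$ratios <- ratios
  if (!is.null(config$augment$mode) &&
      !config$augment$mode %in% c("single", "simultaneous")) {
    fail("augment mode must be 'single' or 'simultaneous'")
  }
  config
}

#' Run the full curation and augmentation pipeline
#'
#' Stages, in order: (1) generate synthetic fixtures (plus decoys) or
#' load an input reaction file; (2) template-screen to the configured
#' reaction type; (3) split 8:1:1; (4) augment the training partition
#' with the validation/test guard; (5) export reaction files, tokenized
#' parallel files and the training config; (6) write statistics and the
#' run manifest.
#'
#' @param config Config list or YAML path (see
#'   [validate_pipeline_config()]).
#' @param out_dir Output directory.
#' @param templates,classes Template and functional-group definitions.
#' @return The manifest list, invisibly.
#' @export
run_pipeline <- function(config, out_dir,
                         templates = default_templates(),
                         classes = default_fg_classes()) {
  config <- validate_pipeline_config(config)
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  seed <- as.integer(config$seed)

  # stage 1: acquire records
  if (!is.null(config$generator)) {
    gen <- config$generator
    records <- generate_coupling_dataset(
      config$rxn_type, n_aryl = gen$n_aryl, n_partner = gen$n_partner,
      seed = seed, classes = classes,
      spectator_fraction = if (is.null(gen$spectator_fraction)) 0
                           else gen$spectator_fraction)
    n_decoys <- if (is.null(gen$n_decoys)) 0L else gen$n_decoys
    if (n_decoys > 0) {
      records <- c(records, generate_decoys(n_decoys, seed = seed))
    }
  } else {
    records <- read_reactions(config$input)
  }
  n_input <- length(records)

  # stage 2: template screening
  screened <- screen_dataset(records, config$rxn_type, templates)
  write_reactions(screened$kept, file.path(out_dir, "screened.txt"))
  write_reactions(screened$rejected, file.path(out_dir, "rejected.txt"))

  # dedup raw reactions before splitting
  kept <- screened$kept
  kept <- kept[!duplicated(record_keys(kept))]

  # stage 3: split (floor(N/10) to valid and test, remainder to train)
  split <- split_dataset(kept, ratios = config$ratios, seed = seed + 1L)
  raw_train_n <- length(split$train)

  # stage 4: train-only augmentation with leakage guard
  aug <- config$augment
  split_aug <- augment_split(
    split, templates, classes,
    mode = aug$mode, roles = unlist(aug$roles),
    cap = if (is.null(aug$cap)) Inf else aug$cap)

  # stage 5: export
  write_reactions(split_aug$train, file.path(out_dir, "train.txt"))
  write_reactions(split_aug$valid, file.path(out_dir, "valid.txt"))
  write_reactions(split_aug$test, file.path(out_dir, "test.txt"))
  pair_files <- export_pairs(split_aug, out_dir)
  export_training_config(file.path(out_dir, "training_config.yaml"))

  # stage 6: stats + manifest
  stats <- dataset_stats(kept, c(split_aug$train, split_aug$valid,
                                 split_aug$test))
  jsonlite::write_json(
    list(raw_count = stats$raw_count, virtual_count = stats$virtual_count,
         fake_count = stats$fake_count,
         growth_factor = stats$growth_factor),
    file.path(out_dir, "stats.json"), auto_unbox = TRUE, digits = NA,
    pretty = TRUE)

  config_path <- file.path(out_dir, "config.json")
  jsonlite::write_json(config, config_path, auto_unbox = TRUE,
                       digits = NA, pretty = TRUE)
  outputs <- c("screened.txt", "rejected.txt", "train.txt", "valid.txt",
               "test.txt", basename(pair_files), "training_config.yaml",
               "stats.json", "config.json")
  digests <- tools::md5sum(file.path(out_dir, outputs))
  names(digests) <- outputs

  manifest <- list(
    tool = "rxnaug",
    version = as.character(utils::packageVersion("rxnaug")),
    backend = canonicalization_backend(),
    seed = seed,
    stage_seeds = list(generator = seed, split = seed + 1L,
                       kfold = seed + 2L),
    config_digest = unname(tools::md5sum(config_path)),
    counts = list(
      input = n_input,
      screened_kept = screened$report$kept,
      screened_rejected = screened$report$rejected,
      ambiguous_site = screened$report$ambiguous_site,
      train_raw = raw_train_n,
      train_augmented = length(split_aug$train),
      valid = length(split_aug$valid),
      test = length(split_aug$test)),
    output_digests = as.list(digests))
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(manifest)
}
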