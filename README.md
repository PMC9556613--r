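# rxnaug

Virtual data augmentation for cross-coupling reaction prediction
datasets.

Sequence-to-sequence models that predict reaction products from reaction
SMILES are data-hungry, and curated corpora for specific coupling
classes (Hiyama, Suzuki, Kumada, Buchwald–Hartwig, Chan–Lam) are often
small — thousands of reactions, not millions. `rxnaug` enlarges the
*training* partition of such a corpus with chemically valid *fake*
reactions: in each reactant it substitutes the leaving-group functional
group with an equivalent member of the same class, leaving the product,
the reaction site and all atom valences untouched. An aryl chloride
becomes the corresponding bromide and iodide; a boronic acid becomes its
pinacol or dioxaborinane ester; a trimethoxysilane becomes the
triethoxy-, trichloro- or dimethylfluoro-silane; the halide on a
Grignard reagent is exchanged likewise.

Formally, for a reaction with reactant roles \(r_1, r_2\) carrying
leaving groups \(g_1 \in C_1\), \(g_2 \in C_2\) from equivalence classes
\(C_1, C_2\) (halogen = {Cl, Br, I}, boron, silicon, Grignard halide):

* **single augmentation** replaces the group on one role:
  \(|C_1| - 1\) fakes per reaction;
* **simultaneous augmentation** substitutes across both roles at once:
  \(|C_1|\,|C_2| - 1\) fakes (the Cartesian product minus the original
  combination).

Fakes are generated only from training reactions, deduplicated against
the raw data and against the validation/test partitions (leakage guard),
and are emitted only when the site is unambiguous: the matched group
must occur exactly once in its species and must be absent from the
product (spectator halogens are never touched).

Around this core the package provides the full curation pipeline:
reaction-SMILES parsing and canonicalization (Open Babel backend via
ChemmineOB), template screening for the five coupling classes with
auditable SMARTS role patterns, 8:1:1 and 10-fold splits, tokenized
parallel-corpus export for seq2seq trainers, a reference
transformer-hyperparameter export, a synthetic fixture generator with
exact ground truth, and a four-category classifier for wrong product
predictions (invalid SMILES / chirality / carbon count / functional
group isomerism).

## Worked example

```r
library(rxnaug)

path <- system.file("extdata", "coupling_examples.txt", package = "rxnaug")
rec <- classify_record(read_reactions(path)[[2]])
rec
#> <rxn_record> [hiyama, raw]
#>   N#Cc1ccc(cc1)Br.CC[Si](c1ccc(cc1)C)(Cl)Cl.[F-].[K+]>>N#Cc1ccc(cc1)c1ccc(cc1)C
```

The aryl bromide was identified as the halide role, the silane as the
organosilicon role, and fluoride/potassium were demoted to reagents.
Single augmentation of the halide role with the halogen class yields
exactly the chloride and iodide twins, products untouched:

```r
fakes <- single_augment(rec, default_templates()$hiyama, "aryl_halide")
for (f in fakes) cat(write_reaction_smiles(f), "\n")
#> N#Cc1ccc(cc1)Cl.CC[Si](c1ccc(cc1)C)(Cl)Cl.[F-].[K+]>>N#Cc1ccc(cc1)c1ccc(cc1)C
#> N#Cc1ccc(cc1)I.CC[Si](c1ccc(cc1)C)(Cl)Cl.[F-].[K+]>>N#Cc1ccc(cc1)c1ccc(cc1)C
```

A complete run on a synthetic Suzuki corpus — generate, screen, split
8:1:1, augment the training partition only:

```r
recs <- generate_coupling_dataset("suzuki", n_aryl = 10, n_partner = 10,
                                  seed = 0)
screened <- screen_dataset(recs, "suzuki")$kept
split <- split_dataset(screened, seed = 0)
aug <- augment_split(split)
dataset_stats(split$train, aug$train)
#> Reaction dataset statistics
#>                       count
#>   raw dataset            80
#>   virtual dataset       606
#>   growth factor        7.58
```

Each of the 80 raw training reactions admits 3 × 3 − 1 = 8 simultaneous
halogen × boron substitutions; collisions with other raw reactions and
with the held-out partitions are deleted, leaving 526 fakes. Validation
and test stay byte-identical. `export_pairs(aug, "out/")` then writes
the six line-aligned `src-*`/`tgt-*` token files for a seq2seq trainer.

Scoring a model's predictions against references:

```r
summarize_errors(
  c("CCO", "C[C@@H](N)C(=O)O", "Cc1ccccc1C", "CC(("),
  c("CCO", "C[C@H](N)C(=O)O",  "Cc1ccc(C)cc1", "CCO"))
#> Prediction error report (4 pairs, 3 wrong)
#>   correct               1
#>   invalid_smiles        1  33.33% of wrong
#>   chirality             1  33.33% of wrong
#>   atom_count            0   0.00% of wrong
#>   group_isomerism       1  33.33% of wrong
#>   other                 0   0.00% of wrong
```

A thin command-line wrapper is installed as `exec/rxnaug`
(subcommands `fixtures`, `filter`, `split`, `kfold`, `augment`,
`export`, `stats`, `errors`, `run`); `rxnaug run --config cfg.yaml
--out-dir out/` executes the whole pipeline and writes a reproducibility
manifest.

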