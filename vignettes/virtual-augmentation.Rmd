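---
title: "Virtual data augmentation of coupling-reaction corpora: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Virtual data augmentation of coupling-reaction corpora: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(rxnaug)
```

## The problem and the method

Product prediction for named cross-coupling classes is usually trained
on a few thousand curated reactions per class — far below what
sequence-to-sequence models want. `rxnaug` enlarges the training
partition with *fake* reactions obtained by substituting the
leaving-group functional group of a reactant with another member of the
same equivalence class. Because the substituted group is exactly the
part of the molecule that departs during coupling, the product, the
reaction site and every atom valence are untouched: the fake is a
chemically plausible reaction with a known, correct outcome. This is
deliberately different from SMILES-enumeration augmentation (rewriting
the same molecule as different strings): every fake here is a *new
reaction*, not a re-spelling.

Two modes are provided. *Single* augmentation substitutes on one role
(used for Buchwald–Hartwig, halogen role, and Chan–Lam, boron role,
where only one reactant carries a swappable handle). *Simultaneous*
augmentation substitutes on two roles at once (Hiyama: halogen ×
silicon; Suzuki: halogen × boron; Kumada: halogen on the organic halide
× halide on the Grignard reagent) and emits the Cartesian product of
member choices minus the original combination. With unique sites the
counts are exactly `|C| - 1` and `prod(|C_i|) - 1`; both identities are
verified against an independent brute-force enumerator in the test
suite.

## Functional-group classes

The shipped equivalence classes, all user-overridable through a YAML
file (`write_fg_classes()` / `read_fg_classes()`):

| class | members | attaches to |
|---|---|---|
| halogen | –Cl, –Br, –I | carbon |
| boron | –B(OH)₂, –Bpin, –B(1,3,2-dioxaborinane) | carbon |
| silicon | –Si(OMe)₃, –Si(OEt)₃, –SiCl₃, –SiMe₂F | carbon |
| grignard_halide | –Cl, –Br, –I | magnesium |

Fluorine is excluded from the halogen class: aryl fluorides are not
substrates in these couplings, so –F is never treated as a leaving
group (it may of course occur as a spectator substituent). The boron
and silicon member lists are pragmatic defaults covering the common
transmetalation handles; the method is the substitution engine, not one
fixed list, which is why the classes ship as editable configuration.

## Reaction-site safety

A substitution site must satisfy three conditions, checked
independently:

1. the role's SMARTS pattern matches its species exactly once (a ring
   carrying both Br and Cl is *ambiguous-site*: it passes screening but
   is excluded from augmentation);
2. exactly one class member occurs in the species, as a pendant
   substituent (matched on the molecular graph, internal symmetries
   collapsed);
3. the matched group is confirmed to leave: it occurs fewer times in
   the product than on the whole left side, so spectator groups — which
   survive into the product — are never substituted.

Species failing any check contribute no fakes; the engine never
guesses.

## Template screening

Each coupling class is a template: one SMARTS pattern per reactant role
plus a product check. Role patterns are anchored so the match count
equals the number of candidate groups (e.g. the organosilicon pattern
matches the Si atom, not each C–Si bond). The product check is formal
rather than atom-mapped: a role assignment passes when the product's
heavy-atom element counts equal the sum of the two *retained
fragments* — each role species minus its leaving group (the halide
atom; the metal atom plus everything attached to it except one carbon
branch, enumerated over branches; nothing for N–H/O–H nucleophiles,
which lose only hydrogen). A passing assignment certifies loss of both
leaving groups and formation of the new C–C or C–N/C–O bond joining the
retained fragments into the single product. Heavy atoms only are
balanced; hydrogen bookkeeping is left to the valence model of the
backend. When several templates accept a reaction the fixed precedence
order (suzuki, hiyama, kumada, buchwald_hartwig, chan_lam) decides and
a warning is emitted; precedence is arbitrary but deterministic, and
ambiguity is logged for audit. For Kumada the halide pattern also
admits primary alkyl halides (flagged in the shipped template file);
the other classes accept aryl/vinylic halides only.

## Canonicalization, identity and determinism

All canonical SMILES come from one pinned backend (Open Babel through
ChemmineOB; identity recorded in every pipeline manifest), because
canonical strings differ between toolkits and every deduplication,
guard and comparison in the package uses them as identity keys. A
reaction's identity is `sorted(left species)>>product`, a pure function
of the species multisets. Stereochemistry is preserved by default; a
`strip_stereo` option removes tetrahedral and double-bond marks for
corpora curated without chirality. Beyond the backend's parser, a
branch-parenthesis balance check rejects strings like `CC((` that Open
Babel would silently tolerate. Fakes are sorted by canonical string
before writing, so identical inputs and configuration give
byte-identical output files; the run manifest records seeds, config and
output digests and deliberately contains no wall-clock fields, making
reruns fully comparable.

## Splits and leakage

The shipped split policy is 8:1:1: validation and test each receive
`floor(N/10)` records (evaluation sets never exceed nominal size) and
train takes the remainder; the shuffle is the seed's only use. A
10-fold planner assigns each record to exactly one held-out fold.
Augmentation is applied strictly *after* splitting and only to train;
fakes colliding with raw training reactions are deleted (the
"repeated-reaction" rule) and fakes colliding with validation or test
are dropped by a guard. The guard is a deliberate strengthening: fakes
equal to held-out reactions would leak evaluation data into training
and inflate accuracy. Per fold, augmentation is recomputed with that
fold's held-out set as the guard. All randomness flows from one
top-level seed expanded by a fixed scheme (generator = seed, split =
seed + 1, k-fold = seed + 2).

## The synthetic generator

Real coupling corpora are proprietary database extractions, so the
package ships a generator whose ground truth is exact by construction:
aryl halides (substituent × ring position × halide) crossed with
partners (substituent × ring position × leaving-group member), products
assembled by deterministic formal coupling — join the two role carbons,
delete both leaving groups — never by a prediction heuristic. A
configurable fraction of partners carries a spectator ring chlorine
that survives into the product, exercising the leaving-group
confirmation rule. Decoy reactions (esterifications, reductions,
amidations, cycloadditions) provide negative controls for screening.

What the generator does *not* emulate: the structural diversity of real
extractions (fused rings, heterocycles, multiple competing sites,
protecting groups), noisy or wrongly atom-typed entries, and realistic
substituent distributions. Passing tests therefore demonstrate the
correctness of the curation and substitution machinery under clean
conditions, not the downstream accuracy gain of a trained model on real
data — that requires the proprietary corpora and GPU training, both out
of scope here.

## Error taxonomy

Wrong product predictions are labelled by a fixed cascade: unparsable →
`invalid_smiles`; canonical-equal → `correct`; equal after stereo
stripping → `chirality`; differing carbon counts → `atom_count`; equal
molecular formula with different connectivity (constitutional isomer)
→ `group_isomerism`; else `other`. Two orderings were genuinely open:
chirality is tested before the carbon count so stereo-only mistakes are
never masked, and the atom-count rule keys on *carbon* atoms (the
quantity tabulated in practice for these corpora) with full-formula
mismatches falling through to `other`. Report percentages are computed
over wrong predictions only, the convention under which error-type
columns sum to 100%.

## Numerical and scale choices

Test and acceptance runs use deliberately modest problem sizes — 200
generated reactions for the counting identities, N = 1000 for split
hygiene, 500 molecules for cascade reflexivity — chosen so the full
suite completes in about a minute while still exercising every rule
(spectators, ambiguity, collisions, guards) many times over. The
per-parent fake cap defaults to unlimited; real corpora show growth
factors that vary widely per class, so a cap is exposed but not
imposed. The degenerate cases are all defined: empty inputs screen and
merge to empty outputs, a corpus smaller than ten records refuses to
split, identity replacements and substitutions yielding unrenderable
structures are errors, never silent output.

## Known limitations

* The product check balances heavy-atom counts; it would accept a
  pathological assignment where two wrong fragments happen to balance
  exactly. Atom-mapped verification would close this gap at the cost of
  a mapping dependency.
* Pendant matching requires the leaving group to be a literal member of
  the configured class; exotic boronates or silanes outside the list
  are (safely) invisible to augmentation.
* One canonicalization backend is pinned; corpora canonicalized
  elsewhere should be re-canonicalized on import (this happens
  automatically when records are parsed).
* Reagents are never augmented, with the single designed exception of
  the Mg-bound halide, which is chemically part of the Grignard
  reactant.
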