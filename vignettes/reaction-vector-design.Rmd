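---
title: "Reaction vectors, class recommenders and filtered de novo design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Reaction vectors, class recommenders and filtered de novo design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(rvdesign)
```

## The method

Reaction-based de novo design builds new molecules by applying
transformation rules harvested from real reactions, on the premise that
products reachable through known chemistry are more likely to be
synthesisable than products assembled atom by atom.  `rvdesign` implements
the *reaction vector* formulation of such rules together with a multi-label
*reaction class recommender* that decides which rules are worth applying to
a given starting material.

### Reaction vectors

Molecules are described by topological atom-pair descriptors over two-atom
(AP2) and three-atom (AP3) heavy-atom paths.  Atoms are typed by the
Carhart-style triple (element, heavy-atom degree, pi-electron count);
hydrogens are never typed, and the degree is measured on the parent
molecule, so a feature encodes a small piece of the chemical environment,
not just a bond.  A molecule's descriptor is the multiset of its canonically
oriented path features.

For a carbon-balanced reaction the descriptors of all products are summed,
the reactant descriptors subtracted, and the signed difference split into

* the **negative** part — features lost from the reactants, and
* the **positive** part — features gained in the products.

This pair is the reaction vector.  It captures exactly what changes at the
reaction centre (plus the re-typing ripple one bond outward caused by degree
changes) and nothing else.  The conservation identity

> descriptor(products) − descriptor(reactants) = positive − negative

holds exactly, by construction, and is asserted in the tests.

A vector is **applicable** to a starting material when its negative features
are wholly present — count-aware multiset containment, not mere presence —
in the starting material alone or combined with one reagent.  The
count-aware reading matters: a vector consuming two C–Br features must not
fire on a molecule with one.

### Structure generation

Applying a vector is a search over bounded bond edits.  Candidate
reaction-centre atoms are those participating in negative features (plus
atoms typable into a positive feature by gaining a bond); the generator
enumerates combinations of bond breaks and formations over those atoms —
at most three of each, at most four changes in total, smallest edit sets
first — and accepts an edit exactly when the descriptor delta of the whole
edited graph equals `positive − negative`.  Two pruning rules keep this
cheap: only existing bonds whose AP2 feature is a lost feature may break,
and the number of formations minus breaks must equal the vector's net AP2
count change (bond-count conservation).  By-products (water, hydrogen
halides, boronate residues, ...) are reconstructed implicitly because the
identity is checked over all fragments; only the fragment retaining the
most starting-material atoms is reported, the rest travel along as a
`byproducts` attribute.  Edits are validated against an explicit valence
model, so every product is a sanitizable molecule.

The returned set is the complete, deduplicated set of products reachable at
the smallest consistent edit size, in byte order of canonical identifiers —
deterministic by construction.

### The recommender

Reaction vectors see only the reaction centre.  The recommender reintroduces
the whole molecule: starting materials are extracted from classified
reactions (the reactant with strictly the most mapped atoms; ties are
ambiguous and discarded), fingerprinted, and pivot-merged — identical
fingerprints become one training entry whose labels are unioned.  The
pivoting step is what encodes competing functionality: if amino alcohols
only ever appear in protection reactions, an entry showing both N–H and O–H
features will never carry a coupling label, and the trained model will not
recommend coupling chemistry for such molecules.

Labels live in a four-level hierarchy (`"C-C Bond Formation (Coupling)
(Suzuki) (Iodo)"`); truncation merges subclasses into parents, and all
matching is truncation-then-equality.

Four problem-transformation strategies are provided over a pluggable binary
base learner: binary relevance (BR), classifier chains (CC), and the
disjoint/overlapping random k-labelset ensembles (RAkELd/RAkELo).  An empty
prediction — every binary decision negative — is legitimate output and
means *no recommendation*; in design mode it disables filtering rather than
blocking the molecule.

### Filtered design

`single_step_enumerate()` runs the design loop: recommend, filter the
vector set, test applicability, apply, collect.  Because filtering only
removes vectors, a recommended library is always a subset of the control
(unfiltered) library — asserted as a property test, not assumed.
`renate_run()` is the retrosynthetic mode: fragment a reference at
recognised junction bonds (amide, ester, ether, benzylic/biaryl, amine)
with a minimum fragment size, rank fragments by attachment points then
size, retrieve nearest reagents for each fragment by Euclidean distance
over count fingerprints, and reassemble combinatorially through the
(optionally filtered) vectors, keeping a beam of the products closest to
the reference between iterations.

## Tunable parameters

| Parameter | Default | Meaning |
|---|---|---|
| `level` | 3 | label hierarchy level for training and filtering; 3 keeps reaction subclasses distinct while remaining generalisable upward |
| `labelset_size` (RAkEL) | 3 | labels per powerset subset |
| `model_count` (RAkELo) | 2·|vocabulary| | ensemble size, the standard RAkEL sizing |
| `ntree` (rf base) | 10 | forest size of the bundled tree learner |
| `cost` (linear base) | 1 | margin cost of the bundled linear learner |
| `seed` | 11 | RNG seed for subset draws and learners |
| `min_fragment_atoms` | 5 | smallest fragment the retrosynthetic cleavage may create |
| `analogs_per_fragment` | 1000 | reagents retrieved per reference fragment |
| `beam_width` | 25 | intermediates kept between assembly iterations |

The bundled base-learner defaults (10 trees; linear margin with unit cost;
seed 11) mirror the configuration the recommender methodology was tuned
with.  All of them are exposed rather than hard-coded so the model grid
(strategy × base × scheme × level) can be re-run.

## Fingerprint schemes

Schemes live in a registry with a fixed contract (identifier, length,
determinism): a 166-key structural dictionary (`keys166`), a 36-key
functional-group dictionary (`fg`), hashed AP2+AP3 schemes at 1024/2048/4096
bits, feature-class circular schemes of radius 1 and 2, and a radius-2
typed circular *count* scheme (`morgan1024c`) used for similarity retrieval
with Euclidean distance.  The two dictionary schemes are this package's own
key sets, written against its descriptor and functional-group machinery;
they play the structural role of the classic public key dictionaries
without reproducing any particular vendor's bit layout.

## What the synthetic generator emulates — and what it does not

`generate_classified_reactions()` draws from eight functional-group-defined
templates (amide coupling, N-alkylation, esterification, nitro reduction,
Suzuki-type coupling, Boc protection/deprotection, Williamson ether), with
a strongly skewed class distribution (C–N chemistry ≈ 35%, functional
conversions ≈ 20%, deprotections ≈ 13%) and substituent slots that create
duplicate starting materials across classes.  Reactions are built by
applying the template's bond edits with the package's own graph editor, so
they are born atom-mapped, carbon-balanced, and regenerable from their own
reaction vectors.  Amino alcohols are routed exclusively through
protection/deprotection chemistry, which plants the competing-functionality
signal the recommender is expected to learn.

The generator emulates the *statistical shape* of patent-derived training
data — class skew, duplicate starting materials, label-set structure — and
a feature-to-label mapping that is essentially deterministic at the
fingerprint level.  It does not emulate: atom-mapping noise, mislabelled
reactions, stereochemistry, reagent/solvent/catalyst effects, or the
property distributions of real lead-optimisation series.  Passing the
recovery tests therefore demonstrates that the pipeline is implemented
correctly and can extract a learnable signal; it does not predict absolute
performance on real reaction corpora, where micro-F1 is far below the
near-perfect values achievable on clean synthetic data.

For the recovery experiments the linear-margin base learner on the
`keys166` dictionary is used: fixture classes are determined by functional
groups, hence margin-separable in a functional-group-aware dictionary, and
a linear learner recovers the mapping stably on the modest number of
pivoted entries the fixture yields.  The tree learner with its 10-tree
default is noisier on data of this size and is exercised by the mechanical
and determinism tests instead.

## Numerical and design choices

* **Canonical identifiers.** Deduplication keys are the package's canonical
  SMILES, produced by individualization–refinement canonical ranking (all
  members of the smallest ambiguous class are branched on, so the form is
  order-invariant).  An identifier is a pure function of the structure,
  which is all the dedup contract requires; a test cross-checks the
  equivalence classes against an external toolkit's InChIKeys.
* **Aromaticity** is taken from the SMILES notation (lowercase / `:`);
  kekulized input is not re-perceived.  All fixtures and I/O use aromatic
  notation.
* **Chain order and votes.**  The CC chain runs in vocabulary order and
  feeds its own predictions forward at training and prediction time;
  RAkELo predicts a label positive on a strict majority of the subsets
  covering it (uncovered labels stay negative).  Both are conventions of
  this package; the degeneracy property (chain-blinded CC equals BR
  exactly) pins the implementation down testably.
* **Zero denominators** in micro metrics return 0, never NaN, keeping
  aggregation total under degenerate predictions.
* **Tie-breaks** are bytewise-lexicographic on canonical identifiers
  everywhere (product ordering, analog retrieval, beam selection), and
  random-forest predictions are RNG-pinned because the underlying library
  breaks exact vote ties randomly.
* **Round trips** designate the template's first reactant as the starting
  material, since mapped-atom ties make the extraction rule deliberately
  ambiguous on a subset of reactions (those reactions are discarded when
  building training data, matching the source methodology).
* **Problem sizes.**  The reference experiments run at 2000 generated
  reactions, a 220-reaction round-trip sample, 80/20 stratified splits,
  and a retrosynthetic case with 25 analogs per fragment and beam width
  15 over a ~90-reagent pool; these sizes exercise every code path while
  keeping the whole suite comfortably reproducible on a single CPU.

## Known limitations

* The SMILES dialect is the pragmatic organic subset (no stereo, no
  isotopes, single-digit charges); wedge/at-sign annotations are ignored.
* The valence model is a fixed table; exotic oxidation states beyond
  N(3,5), P(3,5), S(2,4,6) are rejected.
* Structure generation bounds the edit search at four bond changes, which
  covers the bundled chemistry (and most single-step transformations) but
  not cascade reactions.
* The fragmenter recognises a fixed set of junction-bond patterns rather
  than a full retrosynthetic rule base.
* The recommender's accuracy on real data is bounded by label noise and
  coverage, which the synthetic fixtures intentionally do not model.
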