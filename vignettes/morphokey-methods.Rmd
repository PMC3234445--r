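---
title: "Descriptive knowledge bases and free-access identification with morphokey"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Descriptive knowledge bases and free-access identification with morphokey}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(morphokey)
```

## The problem

Archaeocyaths — the earliest calcified sponges, confined to the Cambrian —
are described from thin sections cut at poorly controlled angles through a
complex three-dimensional skeleton. Specimens are routinely incomplete, and
the characters a classical dichotomous key would ask for first (say, the
outer wall) are often simply not preserved. Identification therefore calls
for a *free-access* (multi-access) key: the user answers whichever
descriptors the specimen shows, in any order, and the system maintains the
set of genera still compatible with the observations.

morphokey implements the machinery behind such a key as a general model of
*structured descriptive data*: a registry of descriptors (multi-state
categorical or numeric characters), taxa, and one standardized description
per taxon over the shared registry. Because every taxon is coded over the
same descriptors, descriptions become comparable by automatic means — the
basis for screening a genus-level compendium for possible synonymies,
coding errors and diagnostic states.

## The data model

A cell of the taxa-by-descriptors matrix carries one of four codings:

* a **state set** — one state, or several for a polymorphic taxon;
* an **interval** — for numeric descriptors (genus descriptions in this
  domain are categorical, but species-level work separates taxa by
  numerical coefficients, so intervals are first-class);
* **unknown** — the default for any cell never filled in; fossil
  descriptions are sparse and unknown must never count against a taxon;
* **inapplicable** — the structure the descriptor refers to is absent.

Inapplicability is governed by *dependency rules*: a child descriptor (bump
shape) lists the parent states (bumps: present) under which it is
meaningful. Applicability is three-valued — `applicable`, `inapplicable`,
`undetermined` (the parent is unknown) — and evaluated transitively along
dependency chains, with inapplicability propagating downwards. A
polymorphic parent that straddles enabling and non-enabling states keeps
the child applicable: the structure *may* be present, and tolerant matching
is the right default for variable genera.

`validate_kb()` enforces the semantic contract (states belong to their
descriptor, no empty state sets, codings consistent with applicability,
acyclic dependencies, no dangling references) and returns violations as
data rather than exceptions, so a base under construction can be repaired
iteratively. `completeness_report()` measures the described fraction per
taxon, per descriptor and overall; an explicit *inapplicable* is a
described cell, an unknown is not.

## The identification engine

A session starts from all taxa and applies `answer(session, descriptor,
selection)` steps. The elementary test is `compatible(coding, selection)`:

* unknown coding → compatible (incomplete specimens stay identifiable);
* state sets → compatible iff they intersect; selecting several states
  expresses *doubt* and keeps any taxon matching one of them;
* intervals → compatible iff they overlap;
* inapplicable coding → incompatible under the default policy: answering a
  descriptor asserts the specimen *shows* that structure, so taxa coded as
  lacking it are eliminated (the chambered vs non-chambered case below
  behaves this way). `na_tolerant = TRUE` inverts the policy, for users who
  would rather never lose a taxon to an applicability judgement. The exact
  rule used by legacy identification software is not documented, so this
  is declared as a design decision, not a reconstruction.

The partition into remaining and eliminated taxa is recomputed from the
full answer set, so it is independent of answer order, shrinks
monotonically as answers accumulate, and re-answering a descriptor simply
replaces the earlier selection. Every elimination is explainable:
`reasons()` lists *all* answered descriptors whose selection conflicts with
the taxon's coding (`DISJOINT_STATES`, `INAPPLICABLE_FOR_TAXON`,
`INTERVAL_MISMATCH`), reproducible from the answer and the coding alone.

`recommend_descriptors()` ranks unanswered descriptors by separating power
over the remaining taxa: the fraction of comparable pairs (both codings
described, descriptor applicable for both) whose codings are disjoint.
This is an engineering aid — descriptor choice remains free — and the
simple pairwise definition was chosen over entropy-style scores because it
is directly interpretable as "answering this can split that fraction of
the surviving pairs".

```{r identify}
kb <- build_fixture()
s <- new_session(kb)
s <- answer(s, "d65", "septa")    # radial structures, visible in section
s <- answer(s, "d2", "absent")    # chambers
c("Coscinocyathus" %in% remaining(s), "Erismacoscinus" %in% remaining(s))
reasons(s, "Coscinocyathus")
```

## Screening descriptions: checkbase, special features, comparative tables

`classify_pair()` compares two descriptions descriptor by descriptor.
Disjoint described codings — or a structure present on one side and coded
inapplicable on the other — are *separating*: one observation can tell the
taxa apart. Unequal but intersecting codings, and unknown-versus-described
cells, are *differing but compatible*. The verdict is `distinct` when a
separating descriptor exists, `identical` when both buckets are empty, and
`overlapping` otherwise. Two principles fix the edge cases:

* an unknown never separates and never certifies identity — the purpose of
  the screen is flagging *possible* synonymy, and unknowns must neither
  hide nor fabricate it. One consequence is worth knowing: two taxa with
  no described cells at all classify as `identical` (nothing distinguishes
  them *as coded*), which is why `checkbase()` reports completeness
  alongside the pair lists;
* inapplicable versus described is separating — structural absence is
  taxonomically real (chambers alone sort genera into different orders).

`checkbase()` applies the classification to every unordered pair and
reports identical and overlapping pairs with the validator output and the
completeness summary, ordered lexicographically for reproducible diffs.
`special_features()` extracts states recorded for exactly one taxon —
diagnostic characters — judged against described cells only, with the
number of unknown cells on that descriptor reported as a caution.
`comparative_table()` renders a taxon subset side by side with per-row
flags (`same` / `partial` / `different` / `not_comparable`), exportable as
colour-coded HTML.

```{r checkbase}
checkbase(build_fixture("post_revision"))$identical_pairs
checkbase(build_fixture("pre_revision"))$identical_pairs
```

The shipped fixture encodes the canonical worked cases: the
*Graphoscyphia* / *Dictyocyathus* / *Molybdocyathus* trio that differs only
in outer carcass structure (the two fixture variants code *Dictyocyathus*
as in the older literature vs after re-examination, moving the identical
pair from {Graphoscyphia, Dictyocyathus} to {Dictyocyathus,
Molybdocyathus}); the *Taylorcyathus* / *Connanulofungia* pair separated
only after a new annuli-stacking state (cone in cone, `d49`) was
introduced; and the *Coscinocyathus* / *Erismacoscinus* transverse-section
confusion resolved by the chamber descriptor.

## The terminology mapping

Classical wall terms pack several notions into one word: "cambroid pores"
says pore shape *and* distribution *and* arrangement. The standardized
registry stores one notion per descriptor, and `term_registry()` ships the
machine-readable bridge: each classical term expands into descriptor-state
assignments (`expand_term()`), optionally restricted to the outer wall,
inner wall or intervallum, with *trigger* descriptors recording which
detail descriptions become relevant once the term applies.
`match_terms()` runs the reverse direction — which classical vocabulary is
compatible with a given (partial) description — using the same
intersection semantics as the identification engine, so a blank
description matches everything and every expansion is recovered from its
own application.

Rows whose classical sources do not pin every cell down are shipped with
`confidence: "low"` rather than omitted: coverage of the vocabulary was
judged more useful than false precision, and the flag travels with the
expansion. Terms made redundant by the decomposition (tumuli, pustulae,
cambroid/anthoid pores, pseudotaeniae) are kept as entries that expand to
their basic-descriptor content, with a note saying why the term itself is
no longer needed.

One registry choice deserves a note: the outer and inner carcass
*structure* is modelled as single descriptors (`d6`, `d7`) with states
rudimentary / simple / basic / concentrical, where "rudimentary" is the
not-well-defined carcass. The finer decomposition (pore shape `d12`/`d32`,
distribution `d15`, rows per intersept `d17`/`d33`) is carried by the same
expansions, so the classical rudimentary/basic distinction is expressed
both ways; the single-descriptor form is what makes "the only difference
between these genera is the outer carcass wall" a statement about one
descriptor.

```{r terms}
expand_term("cambroid pores", context = "outer")$assignments
head(match_terms(kb, taxon = "Agastrocyathus"), 3)
```

## The fixture and the synthetic generator

`archaeo_registry()` rebuilds the 120-slot descriptor registry — 85
morphology/ontogeny, 8 stratigraphy/geography, 27 classification — with
the published numbering wherever a number is tied to a meaning (`d6`,
`d7`, `d11`–`d28`, `d31`–`d63`, `d65`/`d66`, `d70`/`d71`, `d79`–`d81`);
slots the sources never name are neutral 2–4-state placeholders kept so
the group arithmetic stays exact, without inventing anatomy. The fixture
(`build_fixture()`) adds fifteen genera: the seven of the worked cases,
coded from their published characterizations with everything unstated left
unknown, plus eight genera named in the surrounding tables and figures to
cover the class's six orders and twelve suborders (suborder labels are
schematic `<Order>_A/_B` placeholders — only their count is fixed by the
modelled resource). Classification is coded both as taxon metadata and as
descriptors `d94`–`d96`, which mirrors how such bases mix morphological
and classification descriptors and keeps cross-suborder pairs
distinguishable, so the checkbase reports contain exactly the worked-case
pairs.

`generate_kb()` emulates this structure at arbitrary sizes for property
testing: categorical descriptors in groups, a chosen fraction with
acyclic dependency rules, polymorphic cells, unknown cells, and *planted*
ground truth — identical pairs, overlapping pairs (a copy with cells
blanked to unknown) and unique states (a reserved state forbidden to all
but one taxon). Defaults (2–5 states, 10% polymorphism, 20% unknown, 10%
dependencies) sit in the range observed in real genus-level bases, where
roughly a fifth of cells are unrecorded. After filling, a repair pass
removes accidental structure: any non-planted state recorded in exactly
one taxon is re-homed, and any non-planted pair that came out
indistinguishable is separated on a dependency-free descriptor, with
planted partners always edited in step. The result is verified against
`checkbase()` and `special_features()` before it is returned; for a small
fraction of random layouts the pass does not settle, in which case the
draw restarts from a seed derived arithmetically from the user's seed (at
most eight attempts, the first being the seed itself), keeping the output
a pure function of seed and parameters — the same seed always yields a
bitwise-identical serialization. Infeasible requests (more planted
structure than the dimensions allow) fail with an explicit error.

What the generator does *not* emulate: correlated characters (real
descriptors covary along the classification), phylogenetic signal in the
unknown pattern (real unknowns concentrate in poorly preserved taxa), and
numeric descriptors. Passing property suites on these bases therefore
demonstrates the *logic* of the engine and the screens — set semantics,
dependency handling, exact recovery of planted structure — not
performance on any particular real compendium.

## Numerical and procedural choices

* Ties in `recommend_descriptors()` break by descriptor id; all reports
  order taxa lexicographically by name, so outputs diff cleanly.
* Intervals are closed; two intervals sharing an endpoint overlap, and
  interval equality is exact on the bounds. No floating-point tolerance is
  applied — bounds in this domain are measured coefficients, not computed
  quantities.
* State sets are stored sorted and deduplicated, which makes coding
  equality, serialization and set arithmetic canonical.
* Serialized bases omit unknown cells; a missing map entry *is* unknown,
  matching how sparse fossil descriptions are actually recorded.
* `read_kb()` validates the document structurally before constructing the
  base and reports the JSON path of the first offence; the JSON Schema in
  `inst/schema/` documents the same contract for non-R consumers.
* Test problem sizes: the engine-versus-naive-filtering suite runs 1000
  random sessions over ten generated bases of 20 taxa by 24 descriptors
  (plus ~280 pair-duality checks); the planted-recovery suite runs 100
  seeded bases of 14 by 18. These sizes give wide coverage of layouts
  while keeping the default suite around a minute.

## Known limitations

* Identification is exact: there is no error-tolerant ("allow k
  mismatches") matching, and no probabilistic weighting of descriptors.
* The terminology mapping covers the wall vocabulary and the intervallum
  terms its sources decompose; it is not a general historical-literature
  thesaurus, and low-confidence rows should be reviewed before being used
  as authoritative codings.
* `checkbase()` suggests; it never synonymizes. Whether an identical pair
  is a synonymy, a duplicated description or two genuinely
  indistinguishable genera is a taxonomic judgement outside the package.
* The fixture is a faithful *structural* model (registry arithmetic,
  dependency rules, the worked cases) but only the worked-case cells carry
  published codings; filler genera are deliberately sparse.
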