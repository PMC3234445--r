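# morphokey

Structured descriptive knowledge bases and free-access identification keys
for morphological taxonomy, modelled on the workflow used for Cambrian
archaeocyathan sponges.

## The problem

Archaeocyaths are identified from thin sections cut at uncontrolled angles
through an intricate calcareous skeleton; specimens are usually
incomplete, so any key that asks its questions in a fixed order fails as
soon as the first-asked structure is not preserved. The working solution
in this field is a *knowledge base*: every genus gets one standardized
description over a shared registry of single-notion descriptors
(multi-state characters with explicit handling of polymorphism, unknown
cells and inapplicability dependencies), and identification becomes
*free-access* — answer whatever the specimen shows, in any order, and the
system maintains the compatible genera. Because all descriptions share one
registry, they can also be compared automatically, which is how candidate
synonymies and coding errors are found.

morphokey implements that machinery end to end:

* **Domain model** — taxa × descriptors with codings
  `state set | interval | unknown | inapplicable`, dependency rules
  (three-valued applicability, evaluated transitively), a semantic
  validator and a completeness report.
* **Identification engine** — sessions with doubt (multi-state answers),
  unknown-tolerant matching, per-taxon elimination reasons, undo, and
  descriptor recommendation by separating power: for descriptor *d* over
  the remaining taxa *R*,
  `power(d) = #(comparable pairs with disjoint codings) / #(comparable pairs)`,
  a comparable pair being one where both codings are described and *d* is
  applicable for both.
* **Description screening** — `classify_pair()` (verdicts *distinct* /
  *identical* / *overlapping* with the separating descriptors),
  `checkbase()` over all pairs, `special_features()` (states recorded in
  exactly one taxon), and colour-coded comparative tables.
* **Interchange** — a versioned JSON format (schema in `inst/schema/`), a
  CSV matrix dialect (`a/b` polymorphism, `?` unknown, `-` inapplicable,
  `[lo..hi]` intervals), and per-taxon Markdown/HTML sheets.
* **Terminology** — a machine-readable expansion of the classical wall
  vocabulary (cambroid/anthoid pores, rudimentary vs basic walls,
  tumuli/pustulae, pseudotaeniae, sheath and tabulae terms) into basic
  descriptor-state assignments, and the reverse matching.
* **Fixtures and synthesis** — a 120-descriptor, 15-genus worked fixture
  (`build_fixture()`, two variants around a published recoding) and a
  seeded synthetic generator with planted, verified ground truth
  (`generate_kb()`).

## Worked example

```r
library(morphokey)
kb <- build_fixture("post_revision")
kb
#> <morphokey knowledge base> archaeocyathan fixture (post_revision)
#>   15 taxa, 120 descriptors (3 groups), 16 dependency rules

checkbase(kb)$identical_pairs
#>              t1             t2 n_differing
#> 1 Dictyocyathus Molybdocyathus           0
```

The screen reports exactly one pair of indistinguishable descriptions:
after the outer carcass wall of *Dictyocyathus* was recoded from basic to
rudimentary, its description collapses onto *Molybdocyathus* — the
signature of a junior synonym. (In the `"pre_revision"` variant the same
screen pairs *Dictyocyathus* with *Graphoscyphia* instead.)

An identification session, narrowed to that trio's suborder:

```r
s <- answer(new_session(kb), "d95", "Archaeocyathida_A")
remaining(s)
#> [1] "Graphoscyphia"  "Dictyocyathus"  "Molybdocyathus"

recommend_descriptors(s)[1, ]
#>   descriptor     power
#> 1         d6 0.6666667
```

The engine recommends the outer carcass structure (`d6`): it separates 2
of the 3 surviving pairs — everything except the synonym pair itself.
Answering it eliminates the basic-walled genus, with the reason kept:

```r
s <- answer(s, "d6", "rudimentary")
reasons(s, "Graphoscyphia")
#>   descriptor            code      answer coding
#> 1         d6 DISJOINT_STATES rudimentary  basic
```

Classical terms expand into the standardized registry and back:

```r
expand_term("cambroid pores", context = "outer")$assignments
#> $d12
#> [1] "polygonal" "simple"
#> $d15
#> [1] "regular"
#> $d16
#> [1] "random"
```

A command-line front end wraps the same functions
(`system.file("cli", "morphokey", package = "morphokey")`):

```sh
morphokey checkbase --kb kb.json --format json
morphokey identify --kb kb.json --answers "d2:absent" --format json
morphokey gen-synthetic --seed 7 --taxa 20 --descriptors 30 --out kb.json --manifest gt.json
```

## Scope

The package models descriptive data and its analysis. It does not perform
taxonomic acts (an `identical` verdict is a prompt for revision, not a
synonymization), does not handle images or multimedia, and does not parse
the file formats of legacy identification software.
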