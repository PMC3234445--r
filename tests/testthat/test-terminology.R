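# helper: wrap a partial description in a one-taxon kb over the full registry
wrap_description <- function(codings) {
  reg <- archaeo_registry()
  new_kb(groups = reg$groups, descriptors = reg$descriptors,
         dependencies = reg$dependencies, taxa = list(mk_taxon("probe")),
         descriptions = list(probe = codings))
}

test_that("composite pore terms decompose into shape, distribution and arrangement", {
  e <- expand_term("cambroid pores", context = "outer")
  expect_setequal(names(e$assignments), c("d12", "d15", "d16"))
  expect_setequal(e$assignments$d12, c("simple", "polygonal"))
  expect_equal(e$assignments$d15, "regular")
  expect_equal(e$assignments$d16, "random")

  e <- expand_term("anthoid pores", context = "outer")
  expect_setequal(names(e$assignments), c("d12", "d15"))
  expect_equal(e$assignments$d12, "polygonal")
  expect_equal(e$assignments$d15, "irregular")
})

test_that("rudimentary and basic walls expand over both wall descriptor series", {
  e <- expand_term("rudimentary wall")
  expect_setequal(names(e$assignments),
                  c("d6", "d7", "d12", "d32", "d15", "d17", "d33"))
  expect_equal(e$assignments$d6, "rudimentary")
  expect_equal(e$assignments$d7, "rudimentary")
  expect_equal(e$assignments$d12, "irregular")
  expect_equal(e$assignments$d32, "irregular")
  expect_equal(e$assignments$d15, "irregular")
  expect_equal(e$assignments$d17, "one_row")
  expect_equal(e$assignments$d33, "one_row")
  # the alias used in older descriptions resolves to the same expansion
  expect_identical(expand_term("Rudimentary Perforate Wall")$assignments,
                   e$assignments)
  b <- expand_term("basic wall")
  expect_equal(b$assignments$d17, "two_or_more")
  expect_equal(b$assignments$d33, "two_or_more")
})

test_that("pseudotaeniae and simple tabular outer wall expand to their descriptor associations", {
  e <- expand_term("pseudotaeniae")
  expect_setequal(names(e$assignments), c("d65", "d66", "d70", "d71"))
  expect_equal(e$assignments$d65, "taeniae")
  expect_equal(e$assignments$d66, "taeniae")
  expect_equal(e$assignments$d70, "synapticulae")
  expect_equal(e$assignments$d71, "each_interpore_node")

  e <- expand_term("simple tabular outer wall", context = "outer")
  expect_setequal(names(e$assignments), c("d52", "d11", "d12", "d79", "d80"))
  expect_equal(e$assignments$d52, "absent")
  expect_equal(e$assignments$d11, "pores")
  expect_equal(e$assignments$d12, "simple")
  expect_equal(e$assignments$d79, "present")
  expect_equal(e$assignments$d80, "outer_wall_derived")
})

test_that("the shipped mapping covers the classical wall vocabulary", {
  terms <- names(term_registry())
  expected <- c("rudimentary wall", "simple wall", "basic wall",
                "concentrical wall", "wall with canals",
                "wall with simple tumuli", "wall with multiperforate tumuli",
                "pustular wall", "wall with bracts, scales or poretubes",
                "wall with annuli", "compound wall",
                "wall with microporous sheath", "tellelar wall",
                "clathrate wall", "pseudoclathrate wall", "tabular wall",
                "cambroid pores", "anthoid pores", "pseudotaeniae",
                "non porous canals", "porous canals", "spongiose canals")
  expect_true(all(expected %in% terms))
})

test_that("redundant bump terms expand to bump assignments only", {
  for (tm in c("tumuli", "pustulae")) {
    e <- expand_term(tm)
    expect_true(all(names(e$assignments) %in% c("d22", "d23", "d24")),
                info = tm)
    expect_equal(e$assignments$d22, "present", info = tm)
  }
  expect_equal(expand_term("tumuli")$assignments$d24, "downward")
  expect_equal(expand_term("pustulae")$assignments$d24, "central")
})

test_that("every shipped expansion is validator-clean and recovered by match_terms", {
  for (tm in names(term_registry())) {
    codings <- apply_expansion(expand_term(tm))
    kb <- wrap_description(codings)
    v <- validate_kb(kb)
    expect_equal(nrow(v), 0L,
                 info = sprintf("%s -> %s", tm,
                                paste(v$code, v$descriptor, collapse = "; ")))
    expect_true(tm %in% match_terms(codings)$term, info = tm)
  }
})

test_that("match_terms filters on compatibility, context aware", {
  # polygonal + irregular distribution: anthoid, not cambroid
  d <- list(d12 = coding_states("polygonal"), d15 = coding_states("irregular"))
  hits <- match_terms(d, context = "outer")$term
  expect_true("anthoid pores" %in% hits)
  expect_false("cambroid pores" %in% hits)
  # regular distribution alone excludes anthoid pores
  expect_false("anthoid pores" %in%
                 match_terms(list(d15 = coding_states("regular")))$term)
  # a blank description is compatible with every term
  expect_setequal(match_terms(list())$term, names(term_registry()))
  # matching straight from a knowledge base taxon
  kb <- build_fixture()
  expect_true("cambroid pores" %in%
                match_terms(kb, taxon = "Agastrocyathus")$term)
  expect_true("pseudotaeniae" %in%
                match_terms(kb, taxon = "Archaeocyathus")$term)
})

test_that("unknown terms fail with suggestions; low-confidence rows are flagged", {
  expect_error(expand_term("cambroid proes"), "nearest known terms")
  expect_equal(expand_term("concentrical wall")$confidence, "low")
  expect_equal(expand_term("cambroid pores")$confidence, "normal")
})

test_that("context restricts expansions to one wall", {
  e_any <- expand_term("rudimentary wall", "any")
  e_out <- expand_term("rudimentary wall", "outer")
  e_in <- expand_term("rudimentary wall", "inner")
  expect_true(all(c("d6", "d12", "d15", "d17") %in% names(e_out$assignments)))
  expect_false(any(c("d7", "d32", "d33") %in% names(e_out$assignments)))
  expect_true(all(c("d7", "d32", "d33") %in% names(e_in$assignments)))
  expect_setequal(names(e_any$assignments),
                  union(names(e_out$assignments), names(e_in$assignments)))
})
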