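test_that("codings enforce their invariants", {
  expect_error(coding_states(), "at least one")
  expect_error(coding_states(""), "at least one")
  expect_error(coding_interval(2, 1), "min <= max")
  expect_true(coding_states("b", "a") == coding_states("a", "b"))
  expect_false(coding_states("a") == coding_states("a", "b"))
  expect_true(is_described(coding_inapplicable()))
  expect_false(is_described(coding_unknown()))
  expect_equal(format(coding_states("x", "y")), "x/y")
  expect_equal(format(coding_interval(0.5, 2)), "[0.5..2]")
})

test_that("categorical descriptors need two states and unique ids", {
  expect_error(mk_descriptor("d", states = list("only")), "at least 2")
  expect_error(mk_descriptor("d", states = list("a", "a")), "duplicate")
  expect_error(mk_descriptor("d", kind = "numeric", states = list("a", "b")),
               "must not define states")
  expect_error(mk_dependency("d", "d", "x"), "cannot depend on itself")
})

test_that("applicability follows the dependency rules", {
  kb <- toy_kb()
  # no rule -> applicable for everyone
  expect_equal(applicability(kb, "a", "wall"), "applicable")
  # parent coded outside the enabling states -> inapplicable
  expect_equal(applicability(kb, "a", "bump_shape"), "inapplicable")
  # parent coded inside -> applicable
  expect_equal(applicability(kb, "b", "bump_shape"), "applicable")
  # parent unknown -> undetermined
  expect_equal(applicability(kb, "d", "bump_shape"), "undetermined")
  expect_error(applicability(kb, "nope", "wall"), "unknown taxon")
  expect_error(applicability(kb, "a", "nope"), "unknown descriptor")
})

test_that("a polymorphic parent straddling the enabling states keeps the child applicable", {
  kb <- toy_kb()
  kb$descriptions$c$bumps <- coding_states("none", "present")
  expect_equal(applicability(kb, "c", "bump_shape"), "applicable")
})

test_that("inapplicability propagates down dependency chains", {
  kb <- new_kb(
    descriptors = list(
      mk_descriptor("p", states = c("off", "on")),
      mk_descriptor("q", states = c("x", "y")),
      mk_descriptor("r", states = c("u", "v"))
    ),
    dependencies = list(mk_dependency("q", "p", "on"),
                        mk_dependency("r", "q", "x")),
    taxa = list(mk_taxon("t")),
    descriptions = list(t = list(p = coding_states("off")))
  )
  expect_equal(applicability(kb, "t", "q"), "inapplicable")
  expect_equal(applicability(kb, "t", "r"), "inapplicable")
  # with the root unknown, everything below is undetermined
  kb$descriptions$t$p <- NULL
  expect_equal(applicability(kb, "t", "r"), "undetermined")
})

test_that("applicability agrees with the independent recursive oracle", {
  set.seed(402)
  for (rep in 1:5) {
    g <- generate_kb(n_taxa = 10, n_descriptors = 15,
                     dependency_fraction = 0.3, seed = 500 + rep)
    for (t in sample(kb_taxon_ids(g$kb), 4)) {
      for (d in kb_descriptor_ids(g$kb)) {
        expect_equal(applicability(g$kb, t, d),
                     naive_applicability(g$kb, t, d),
                     info = sprintf("seed %d taxon %s descriptor %s",
                                    500 + rep, t, d))
      }
    }
  }
})

test_that("validate_kb reports each violation class and nothing on clean bases", {
  expect_equal(nrow(validate_kb(toy_kb())), 0L)

  kb <- toy_kb()
  kb$descriptions$a$bump_shape <- coding_states("round")  # bumps = none
  v <- validate_kb(kb)
  expect_equal(v$code, "CODED_BUT_INAPPLICABLE")
  expect_equal(v$taxon, "a")
  expect_equal(v$descriptor, "bump_shape")

  kb <- toy_kb()
  kb$descriptions$b$bump_shape <- coding_inapplicable()  # bumps = present
  expect_equal(validate_kb(kb)$code, "INAPPLICABLE_BUT_APPLICABLE")

  kb <- toy_kb()
  kb$descriptions$c$wall <- coding_states("no_such_state")
  expect_equal(validate_kb(kb)$code, "STATE_NOT_IN_DESCRIPTOR")

  kb <- toy_kb()
  kb$descriptions$c$wall$states <- character()  # bypass the constructor
  expect_equal(validate_kb(kb)$code, "EMPTY_STATESET")

  kb <- toy_kb()
  kb$dependencies <- list(mk_dependency("bumps", "bump_shape", "round"),
                          mk_dependency("bump_shape", "bumps", "present"))
  expect_true("DEPENDENCY_CYCLE" %in% validate_kb(kb)$code)

  kb <- toy_kb()
  kb$dependencies <- list(mk_dependency("bump_shape", "ghost", "x"))
  expect_true("DANGLING_REF" %in% validate_kb(kb)$code)
})

test_that("an inapplicable coding on a rule-free descriptor is flagged", {
  kb <- toy_kb()
  kb$descriptions$a$wall <- coding_inapplicable()
  expect_true("INAPPLICABLE_BUT_APPLICABLE" %in% validate_kb(kb)$code)
})

test_that("completeness counts described cells, inapplicable included", {
  kb <- toy_kb()
  rep <- completeness_report(kb)
  # taxon a: all 5 cells described (one of them explicitly inapplicable)
  expect_equal(unname(rep$per_taxon[["a"]]), 1.0)
  # taxon d: 1 described cell out of 5
  expect_equal(unname(rep$per_taxon[["d"]]), 0.2)
  # taxon c: 4 of 5 (width unknown)
  expect_equal(unname(rep$per_taxon[["c"]]), 0.8)
  expect_equal(rep$overall, mean(rep$per_taxon))
  expect_true(all(rep$per_descriptor >= 0 & rep$per_descriptor <= 1))
  expect_error(completeness_report(new_kb()), "empty")
})

test_that("completeness is invariant under taxon and descriptor reordering", {
  kb <- toy_kb()
  rep1 <- completeness_report(kb)
  perm <- rev(names(kb$taxa))
  kb2 <- new_kb(metadata = kb$metadata, groups = kb$groups,
                descriptors = rev(kb$descriptors), dependencies = kb$dependencies,
                taxa = kb$taxa[perm], descriptions = kb$descriptions[perm])
  rep2 <- completeness_report(kb2)
  expect_equal(rep1$overall, rep2$overall)
  expect_equal(rep1$per_taxon[sort(names(rep1$per_taxon))],
               rep2$per_taxon[sort(names(rep2$per_taxon))])
})
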