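test_that("compatible implements doubt, unknown tolerance and the inapplicable policy", {
  # doubt: several selected states keep any taxon matching one of them
  expect_true(compatible(coding_states("rudimentary"),
                         c("rudimentary", "basic")))
  # unknown cells never eliminate (incomplete specimens must be identifiable)
  expect_true(compatible(coding_unknown(), "basic"))
  expect_true(compatible(coding_unknown(), coding_interval(1, 2)))
  # disjoint states eliminate
  expect_false(compatible(coding_states("simple"), "canals"))
  # inapplicable structure: eliminated by default, kept when na-tolerant
  expect_false(compatible(coding_inapplicable(), "basic"))
  expect_true(compatible(coding_inapplicable(), "basic", na_tolerant = TRUE))
  # intervals match on overlap
  expect_true(compatible(coding_interval(1, 3), 2.5))
  expect_false(compatible(coding_interval(1, 3), c(4, 6)))
  expect_true(compatible(coding_interval(1, 3), coding_interval(3, 9)))
  # kind mismatch is a user error
  expect_error(compatible(coding_states("a"), 1), "does not match")
})

test_that("answers eliminate incompatible taxa with reproducible reasons", {
  kb <- build_fixture("post_revision")
  s <- new_session(kb)
  expect_setequal(remaining(s), kb_taxon_ids(kb))

  # chambers absent: Coscinocyathus (chambered) goes, Erismacoscinus stays
  s <- answer(s, "d2", "absent")
  expect_false("Coscinocyathus" %in% remaining(s))
  expect_true("Erismacoscinus" %in% remaining(s))
  r <- reasons(s, "Coscinocyathus")
  expect_equal(r$descriptor, "d2")
  expect_equal(r$code, "DISJOINT_STATES")
  expect_error(reasons(s, "Erismacoscinus"), "not been eliminated")

  # rudimentary outer carcass: Graphoscyphia (basic) goes, the synonyms stay
  s2 <- answer(new_session(kb), "d6", "rudimentary")
  expect_false("Graphoscyphia" %in% remaining(s2))
  expect_true(all(c("Dictyocyathus", "Molybdocyathus") %in% remaining(s2)))
  expect_equal(reasons(s2, "Graphoscyphia")$code, "DISJOINT_STATES")
})

test_that("a taxon failing several answers gets one reason per failing descriptor", {
  kb <- toy_kb()
  s <- answer(new_session(kb), "wall", "smooth")
  s <- answer(s, "septa", "absent")
  r <- reasons(s, "c")  # spiny wall and present septa both conflict
  expect_setequal(r$descriptor, c("wall", "septa"))
  # every listed reason independently fails compatible()
  for (i in seq_len(nrow(r))) {
    expect_false(compatible(kb$descriptions$c[[r$descriptor[[i]]]],
                            s$answers[[r$descriptor[[i]]]]))
  }
})

test_that("answering a structure eliminates taxa coded inapplicable unless na-tolerant", {
  kb <- toy_kb()
  s <- answer(new_session(kb), "bump_shape", "round")
  expect_false("a" %in% remaining(s))  # bumps none -> shape inapplicable
  expect_equal(reasons(s, "a")$code, "INAPPLICABLE_FOR_TAXON")
  expect_true("d" %in% remaining(s))   # unknown bumps: kept

  s_tol <- answer(new_session(kb, na_tolerant = TRUE), "bump_shape", "round")
  expect_true("a" %in% remaining(s_tol))
})

test_that("a full-state-set answer only removes taxa for which the descriptor is inapplicable", {
  kb <- toy_kb()
  s <- answer(new_session(kb), "bump_shape", c("round", "conical"))
  expect_setequal(eliminated(s), "a")
  s2 <- answer(new_session(kb), "wall", c("smooth", "ridged", "spiny"))
  expect_equal(length(eliminated(s2)), 0L)
})

test_that("answering a descriptor inapplicable for every remaining taxon is a warned no-op", {
  kb <- toy_kb()
  kb$descriptions$d$bumps <- coding_states("none")
  s <- answer(new_session(kb), "wall", "smooth")  # a and mostly-unknown d remain
  expect_setequal(remaining(s), c("a", "d"))      # both without bumps
  before <- remaining(s)
  expect_warning(s2 <- answer(s, "bump_shape", "round"), "inapplicable for every")
  expect_identical(remaining(s2), before)
})

test_that("selections are checked against the descriptor", {
  kb <- toy_kb()
  expect_error(answer(new_session(kb), "wall", "no_such"), "not defined")
  expect_error(answer(new_session(kb), "wall", 3), "categorical")
  expect_error(answer(new_session(kb), "width", "smooth"), "numeric")
  expect_silent(answer(new_session(kb), "width", c(1.5, 2)))
})

test_that("undo replays all answers but the last", {
  kb <- build_fixture()
  s0 <- new_session(kb)
  s1 <- answer(s0, "d65", "dictyonal_network")
  s2 <- answer(s1, "d6", "rudimentary")
  s3 <- answer(s2, "d33", "one_row")
  expect_identical(remaining(undo(s3)), remaining(s2))
  expect_identical(remaining(undo(undo(s3))), remaining(s1))
  expect_identical(remaining(undo(s1)), remaining(s0))
  expect_error(undo(s0), "nothing to undo")
})

test_that("re-answering a descriptor replaces the previous answer", {
  kb <- build_fixture()
  s <- answer(new_session(kb), "d6", "rudimentary")
  s <- answer(s, "d6", "basic")
  expect_identical(sort(remaining(s)),
                   sort(remaining(answer(new_session(kb), "d6", "basic"))))
})

test_that("the final partition does not depend on the answer order", {
  kb <- build_fixture()
  answers <- list(d65 = "dictyonal_network", d6 = "rudimentary",
                  d96 = "irregulares")
  perms <- list(c(1, 2, 3), c(3, 1, 2), c(2, 3, 1))
  parts <- lapply(perms, function(p) {
    s <- new_session(kb)
    for (i in p) s <- answer(s, names(answers)[[i]], answers[[i]])
    sort(remaining(s))
  })
  expect_identical(parts[[1]], parts[[2]])
  expect_identical(parts[[1]], parts[[3]])
})

test_that("remaining shrinks monotonically as answers accumulate", {
  g <- generate_kb(n_taxa = 15, n_descriptors = 20, seed = 901)
  set.seed(77)
  for (rep in 1:10) {
    s <- new_session(g$kb)
    prev <- remaining(s)
    answers <- random_answers(g$kb, 5)
    for (d in names(answers)) {
      s <- suppressWarnings(answer(s, d, answers[[d]]))
      expect_true(all(remaining(s) %in% prev))
      prev <- remaining(s)
    }
  }
})

test_that("recommend_descriptors ranks by separating power over the remaining taxa", {
  kb <- build_fixture("post_revision")
  # isolate the synonymy trio, then the outer carcass structure separates
  # exactly the two pairs involving Graphoscyphia: power 2/3
  s <- answer(new_session(kb), "d95", "Archaeocyathida_A")
  expect_setequal(remaining(s),
                  c("Graphoscyphia", "Dictyocyathus", "Molybdocyathus"))
  rec <- recommend_descriptors(s)
  expect_equal(rec$descriptor[[1]], "d6")
  expect_equal(rec$power[[1]], 2 / 3)
  # descriptors unknown everywhere have no power
  expect_equal(rec$power[rec$descriptor == "d22"], 0)
  # answered descriptors are excluded
  expect_false("d95" %in% rec$descriptor)
  expect_true(all(rec$power >= 0 & rec$power <= 1))
})

test_that("recommendation needs at least two remaining taxa", {
  kb <- toy_kb()
  s <- answer(new_session(kb), "wall", "smooth")
  s <- answer(s, "width", c(1, 2))
  # only taxon a (and unknowns) remain; force singleton by a second filter
  s <- answer(s, "bumps", "none")
  if (length(remaining(s)) < 2) {
    expect_equal(nrow(recommend_descriptors(s)), 0L)
  }
  # a perfectly separating descriptor ranks first with power 1
  kb2 <- new_kb(
    descriptors = list(mk_descriptor("k", states = c("x", "y", "z")),
                       mk_descriptor("m", states = c("u", "v"))),
    taxa = list(mk_taxon("p"), mk_taxon("q"), mk_taxon("r")),
    descriptions = list(p = list(k = coding_states("x"), m = coding_states("u")),
                        q = list(k = coding_states("y"), m = coding_states("u")),
                        r = list(k = coding_states("z"), m = coding_states("v")))
  )
  rec <- recommend_descriptors(new_session(kb2))
  expect_equal(rec$descriptor, c("k", "m"))
  expect_equal(rec$power, c(1, 2 / 3))
})
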