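test_that("classify_pair reproduces the synonymy trio verdicts", {
  post <- build_fixture("post_revision")
  pc <- classify_pair(post, "Dictyocyathus", "Molybdocyathus")
  expect_equal(pc$verdict, "identical")
  expect_length(pc$separating, 0)

  pc <- classify_pair(post, "Graphoscyphia", "Dictyocyathus")
  expect_equal(pc$verdict, "distinct")
  expect_equal(pc$separating, "d6")  # basic vs rudimentary, nothing else

  pre <- build_fixture("pre_revision")
  expect_equal(classify_pair(pre, "Graphoscyphia", "Dictyocyathus")$verdict,
               "identical")
  expect_equal(classify_pair(pre, "Dictyocyathus", "Molybdocyathus")$separating,
               "d6")
})

test_that("unknown cells make pairs overlap, never identical or separated", {
  kb <- new_kb(
    descriptors = list(mk_descriptor("x", states = c("simple", "canals")),
                       mk_descriptor("y", states = c("a", "b"))),
    taxa = list(mk_taxon("t1"), mk_taxon("t2")),
    descriptions = list(t1 = list(x = coding_states("simple"),
                                  y = coding_states("a")),
                        t2 = list(y = coding_states("a")))  # x unknown
  )
  pc <- classify_pair(kb, "t1", "t2")
  expect_equal(pc$verdict, "overlapping")
  expect_equal(pc$differing_but_compatible, "x")
})

test_that("structural absence separates: inapplicable vs described", {
  kb <- toy_kb()
  pc <- classify_pair(kb, "a", "b")
  expect_true("bump_shape" %in% pc$separating)  # inapplicable vs round
  # both inapplicable counts as equal
  kb$descriptions$b$bumps <- coding_states("none")
  kb$descriptions$b$bump_shape <- coding_inapplicable()
  pc2 <- classify_pair(kb, "a", "b")
  expect_false("bump_shape" %in% pc2$separating)
})

test_that("classify_pair is symmetric and rejects degenerate input", {
  kb <- build_fixture()
  p1 <- classify_pair(kb, "Taylorcyathus", "Connanulofungia")
  p2 <- classify_pair(kb, "Connanulofungia", "Taylorcyathus")
  expect_equal(p1$verdict, p2$verdict)
  expect_setequal(p1$separating, p2$separating)
  expect_setequal(p1$differing_but_compatible, p2$differing_but_compatible)
  expect_error(classify_pair(kb, "Taylorcyathus", "Taylorcyathus"),
               "two different taxa")
  expect_error(classify_pair(kb, "Taylorcyathus", "Nobody"), "unknown taxon")
})

test_that("classify_pair agrees with the independent cell-arithmetic oracle", {
  g <- generate_kb(n_taxa = 12, n_descriptors = 18, n_identical_pairs = 1,
                   n_overlapping_pairs = 1, dependency_fraction = 0.2,
                   seed = 313)
  taxa <- kb_taxon_ids(g$kb)
  for (i in seq_len(length(taxa) - 1)) {
    for (j in seq(i + 1, length(taxa))) {
      expect_equal(classify_pair(g$kb, taxa[[i]], taxa[[j]])$verdict,
                   naive_verdict(g$kb, taxa[[i]], taxa[[j]]),
                   info = paste(taxa[[i]], taxa[[j]]))
    }
  }
})

test_that("checkbase finds exactly the planted near-synonymies in the fixture", {
  cb_post <- checkbase(build_fixture("post_revision"))
  expect_equal(nrow(cb_post$identical_pairs), 1L)
  expect_setequal(unlist(cb_post$identical_pairs[1, c("t1", "t2")]),
                  c("Dictyocyathus", "Molybdocyathus"))
  cb_pre <- checkbase(build_fixture("pre_revision"))
  expect_equal(nrow(cb_pre$identical_pairs), 1L)
  expect_setequal(unlist(cb_pre$identical_pairs[1, c("t1", "t2")]),
                  c("Dictyocyathus", "Graphoscyphia"))
  # the report carries validation and completeness alongside
  expect_equal(nrow(cb_post$violations), 0L)
  expect_true(cb_post$completeness$overall > 0 &&
              cb_post$completeness$overall < 1)
})

test_that("special_features extracts states recorded in a single taxon", {
  kb <- build_fixture()
  sf <- special_features(kb)
  hit <- sf[sf$descriptor == "d49" & sf$state == "cone_in_cone", ]
  expect_equal(hit$taxon, "Connanulofungia")
  # n_unknown_others counts the taxa that might yet share the state
  expect_equal(hit$n_unknown_others,
               sum(vapply(kb_taxon_ids(kb), function(t)
                 !is_described(kb_coding(kb, t, "d49")), NA)))
  # a base where every state is shared yields nothing
  kb2 <- new_kb(
    descriptors = list(mk_descriptor("x", states = c("a", "b"))),
    taxa = list(mk_taxon("t1"), mk_taxon("t2")),
    descriptions = list(t1 = list(x = coding_states("a")),
                        t2 = list(x = coding_states("a")))
  )
  expect_equal(nrow(special_features(kb2)), 0L)
  expect_error(special_features(kb2, taxa = "t1"), "at least two")
})

test_that("comparative tables flag rows same / partial / different / not_comparable", {
  kb <- build_fixture("post_revision")
  ct <- comparative_table(kb, c("Dictyocyathus", "Molybdocyathus"))
  expect_setequal(unique(ct$table$flag), c("same", "not_comparable"))

  ct2 <- comparative_table(kb, c("Graphoscyphia", "Molybdocyathus"))
  expect_equal(ct2$table$flag[ct2$table$descriptor == "d6"], "different")

  kb3 <- new_kb(
    descriptors = list(mk_descriptor("x", states = c("a", "b", "c"))),
    taxa = list(mk_taxon("t1"), mk_taxon("t2")),
    descriptions = list(t1 = list(x = coding_states("a", "b")),
                        t2 = list(x = coding_states("b", "c")))
  )
  ct3 <- comparative_table(kb3, c("t1", "t2"))
  expect_equal(ct3$table$flag, "partial")
  expect_error(comparative_table(kb, "Graphoscyphia"), "at least two")
  expect_error(comparative_table(kb, c("Graphoscyphia", "Nobody")),
               "unknown taxon")
})

test_that("a row is different exactly when the descriptor separates some pair in the subset", {
  kb <- build_fixture("post_revision")
  subset <- c("Graphoscyphia", "Dictyocyathus", "Taylorcyathus")
  ct <- comparative_table(kb, subset)
  sep_union <- character()
  for (i in 1:2) {
    for (j in seq(i + 1, 3)) {
      sep_union <- union(sep_union,
                         classify_pair(kb, subset[[i]], subset[[j]])$separating)
    }
  }
  expect_setequal(ct$table$descriptor[ct$table$flag == "different"], sep_union)
})
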