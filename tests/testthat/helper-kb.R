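# Shared fixtures and independent oracles for the test suite.
#
# The naive_* functions re-derive identification and comparison results by
# direct set arithmetic on the stored codings, on purpose without going
# through the package's session or pair machinery, so they can serve as
# independent checks of those paths.

# A small hand-built base: 4 taxa, 5 descriptors, one dependency chain,
# polymorphism, an unknown cell and an explicit inapplicable cell.
toy_kb <- function() {
  new_kb(
    metadata = list(name = "toy"),
    groups = list(mk_group("g", "main")),
    descriptors = list(
      mk_descriptor("wall", states = c("smooth", "ridged", "spiny"), group = "g"),
      mk_descriptor("bumps", states = c("none", "present"), group = "g"),
      mk_descriptor("bump_shape", states = c("round", "conical"), group = "g"),
      mk_descriptor("septa", states = c("absent", "present"), group = "g"),
      mk_descriptor("width", kind = "numeric", unit = "mm", group = "g")
    ),
    dependencies = list(mk_dependency("bump_shape", "bumps", "present")),
    taxa = list(mk_taxon("a"), mk_taxon("b"), mk_taxon("c"), mk_taxon("d")),
    descriptions = list(
      a = list(wall = coding_states("smooth"), bumps = coding_states("none"),
               bump_shape = coding_inapplicable(),
               septa = coding_states("present"),
               width = coding_interval(1, 2)),
      b = list(wall = coding_states("ridged", "spiny"),
               bumps = coding_states("present"),
               bump_shape = coding_states("round"),
               septa = coding_states("absent"),
               width = coding_interval(3, 5)),
      c = list(wall = coding_states("spiny"),
               bumps = coding_states("present"),
               bump_shape = coding_states("conical"),
               septa = coding_states("present")),
      d = list(septa = coding_states("present"))  # mostly unknown
    )
  )
}

# independent three-valued applicability (recursive, reading raw rules)
naive_applicability <- function(kb, taxon, descriptor) {
  rules <- Filter(function(r) r$child == descriptor, kb$dependencies)
  if (!length(rules)) return("applicable")
  out <- "applicable"
  for (r in rules) {
    pa <- naive_applicability(kb, taxon, r$parent)
    if (pa == "inapplicable") return("inapplicable")
    pc <- kb$descriptions[[taxon]][[r$parent]]
    if (pa == "undetermined" || is.null(pc) || pc$type == "unknown") {
      out <- "undetermined"
    } else if (pc$type == "inapplicable") {
      return("inapplicable")
    } else if (!length(intersect(pc$states, r$enabling_states))) {
      return("inapplicable")
    }
  }
  out
}

naive_cell <- function(kb, taxon, descriptor) {
  cd <- kb$descriptions[[taxon]][[descriptor]]
  if (!is.null(cd)) return(cd)
  if (naive_applicability(kb, taxon, descriptor) == "inapplicable") {
    return(coding_inapplicable())
  }
  coding_unknown()
}

naive_compatible <- function(cd, sel_states, na_tolerant = FALSE) {
  if (cd$type == "unknown") return(TRUE)
  if (cd$type == "inapplicable") return(na_tolerant)
  if (cd$type == "interval") stop("state answer on numeric cell")
  length(intersect(cd$states, sel_states)) > 0
}

# remaining taxa by brute-force filtering over an answer list
# answers: named list descriptor -> character vector of states
naive_remaining <- function(kb, answers, na_tolerant = FALSE) {
  Filter(function(t) {
    for (d in names(answers)) {
      if (!naive_compatible(naive_cell(kb, t, d), answers[[d]], na_tolerant)) {
        return(FALSE)
      }
    }
    TRUE
  }, names(kb$taxa))
}

# independent pair verdict by direct cell arithmetic
naive_verdict <- function(kb, t1, t2) {
  sep <- FALSE; diffc <- FALSE
  for (d in names(kb$descriptors)) {
    c1 <- naive_cell(kb, t1, d); c2 <- naive_cell(kb, t2, d)
    if (c1$type == "unknown" || c2$type == "unknown") {
      if (c1$type != c2$type) diffc <- TRUE
      next
    }
    if (c1$type == "inapplicable" || c2$type == "inapplicable") {
      if (c1$type != c2$type) sep <- TRUE
      next
    }
    if (c1$type == "states" && c2$type == "states") {
      common <- intersect(c1$states, c2$states)
      if (!length(common)) sep <- TRUE
      else if (!setequal(c1$states, c2$states)) diffc <- TRUE
    } else if (c1$type == "interval" && c2$type == "interval") {
      if (c1$max < c2$min || c2$max < c1$min) sep <- TRUE
      else if (c1$min != c2$min || c1$max != c2$max) diffc <- TRUE
    }
  }
  if (sep) "distinct" else if (diffc) "overlapping" else "identical"
}

# random answer set over a kb: k descriptors, each with a random non-empty
# proper-or-full state selection
random_answers <- function(kb, k) {
  cand <- names(kb$descriptors)
  picked <- sample(cand, min(k, length(cand)))
  answers <- list()
  for (d in picked) {
    states <- names(kb$descriptors[[d]]$states)
    if (length(states) < 1) next
    n <- sample.int(min(2L, length(states)), 1L)
    answers[[d]] <- sample(states, n)
  }
  answers
}

# registry-only kb for matrix imports
registry_kb <- function() {
  reg <- archaeo_registry()
  new_kb(groups = reg$groups, descriptors = reg$descriptors,
         dependencies = reg$dependencies)
}
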