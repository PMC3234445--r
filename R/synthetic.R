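#' Generate a synthetic knowledge base with planted ground truth
#'
#' Emulates the structure of a real descriptive knowledge base — taxa by
#' categorical descriptors in groups, polymorphic cells, unknown cells,
#' inapplicability dependencies — while planting a known set of identical
#' pairs, overlapping pairs and unique states, recorded in a manifest.
#' Before returning, the generator verifies the manifest against a full
#' pairwise classification and the validator, repairing accidental
#' structure (a non-planted pair that came out indistinguishable, a state
#' that ended up recorded in a single taxon) by perturbing cells; it
#' errors rather than return a base whose manifest does not hold.
#'
#' The same seed and parameters always produce the identical base,
#' bitwise, so serialized copies are reproducible artifacts.
#'
#' @param n_taxa number of taxa (>= 4 recommended).
#' @param n_descriptors number of categorical descriptors.
#' @param states_per_descriptor integer vector of candidate state counts,
#'   sampled per descriptor (default `2:5`).
#' @param polymorphism_rate probability that a described cell carries two
#'   states instead of one.
#' @param unknown_rate probability that a cell is left unknown.
#' @param dependency_fraction fraction of descriptors given a parent
#'   dependency rule.
#' @param n_identical_pairs,n_overlapping_pairs,n_unique_states planted
#'   counts; pair members are disjoint taxa, unique states sit on taxa
#'   outside the planted pairs and on dependency-free descriptors with at
#'   least three states.
#' @param seed integer seed (required; there is no silent default).
#' @return A list with `kb` (a validator-clean knowledge base) and
#'   `manifest`: data frames `identical_pairs` (`t1`, `t2`),
#'   `overlapping_pairs` (`t1`, `t2`), `unique_states` (`taxon`,
#'   `descriptor`, `state`), plus `params`.
#' @examples
#' g <- generate_kb(n_taxa = 12, n_descriptors = 15, n_identical_pairs = 1,
#'                  n_unique_states = 2, seed = 7)
#' checkbase(g$kb)$identical_pairs
#' g$manifest$identical_pairs
#' @export
generate_kb <- function(n_taxa, n_descriptors,
                        states_per_descriptor = 2:5,
                        polymorphism_rate = 0.1,
                        unknown_rate = 0.2,
                        dependency_fraction = 0.1,
                        n_identical_pairs = 0,
                        n_overlapping_pairs = 0,
                        n_unique_states = 0,
                        seed) {
  if (missing(seed)) stop("a seed is required", call. = FALSE)
  stopifnot(n_taxa >= 2, n_descriptors >= 1,
            all(states_per_descriptor >= 2), all(states_per_descriptor <= 10))
  for (r in c(polymorphism_rate, unknown_rate, dependency_fraction)) {
    if (r < 0 || r > 1) stop("rates must lie in [0, 1]", call. = FALSE)
  }
  if (2 * (n_identical_pairs + n_overlapping_pairs) > n_taxa) {
    stop("not enough taxa for the requested planted pairs", call. = FALSE)
  }
  if ((n_identical_pairs + n_overlapping_pairs) > 0 &&
      2 * (n_identical_pairs + n_overlapping_pairs) == n_taxa &&
      n_unique_states > 0) {
    stop("no taxa left outside the planted pairs to carry unique states",
         call. = FALSE)
  }
  # The cell-level repair is iterative and can, for a small fraction of
  # random layouts, fail to settle; in that case the draw is restarted from
  # a seed derived deterministically from the user's, so the output is still
  # a pure function of (seed, params). Attempt 1 uses the seed unchanged.
  last_error <- NULL
  for (attempt in seq_len(8L)) {
    seed_eff <- if (attempt == 1L) as.integer(seed) else
      as.integer((as.double(seed) + attempt * 7919) %% .Machine$integer.max)
    out <- tryCatch(
      generate_kb_attempt(seed_eff, seed, n_taxa, n_descriptors,
                          states_per_descriptor, polymorphism_rate,
                          unknown_rate, dependency_fraction,
                          n_identical_pairs, n_overlapping_pairs,
                          n_unique_states),
      morphokey_infeasible = function(e) e)
    if (!inherits(out, "condition")) return(out)
    last_error <- out
  }
  stop(conditionMessage(last_error), call. = FALSE)
}

generate_kb_attempt <- function(seed_eff, seed, n_taxa, n_descriptors,
                                states_per_descriptor, polymorphism_rate,
                                unknown_rate, dependency_fraction,
                                n_identical_pairs, n_overlapping_pairs,
                                n_unique_states) {
  set.seed(seed_eff)

  taxa_ids <- sprintf("t%03d", seq_len(n_taxa))
  desc_ids <- sprintf("d%03d", seq_len(n_descriptors))
  groups <- list(mk_group("g1", "group 1"), mk_group("g2", "group 2"),
                 mk_group("g3", "group 3"))
  resample <- function(x, ...) x[sample.int(length(x), ...)]
  n_states <- resample(as.integer(states_per_descriptor), n_descriptors,
                       replace = TRUE)
  descriptors <- lapply(seq_len(n_descriptors), function(i) {
    mk_descriptor(desc_ids[[i]], sprintf("descriptor %d", i), "categorical",
                  states = as.list(paste0("s", seq_len(n_states[[i]]))),
                  group = sprintf("g%d", 1L + (i - 1L) %% 3L))
  })
  names(descriptors) <- desc_ids

  # dependencies: child depends on an earlier descriptor, so index order is
  # a topological order and the graph is acyclic by construction
  n_dep <- min(round(dependency_fraction * n_descriptors), n_descriptors - 1L)
  dep_children <- if (n_dep > 0) {
    sort(sample(2:n_descriptors, n_dep))
  } else integer()
  dependencies <- lapply(dep_children, function(i) {
    parent <- sample.int(i - 1L, 1L)
    k <- n_states[[parent]]
    n_enable <- sample.int(k - 1L, 1L)
    mk_dependency(desc_ids[[i]], desc_ids[[parent]],
                  paste0("s", sort(sample.int(k, n_enable))))
  })
  parent_of <- stats::setNames(
    lapply(dependencies, function(r) r[c("parent", "enabling_states")]),
    vapply(dependencies, `[[`, "", "child"))
  has_children <- unique(vapply(dependencies, `[[`, "", "parent"))

  # planted roles
  shuffled <- sample(taxa_ids)
  id_pairs <- ov_pairs <- list()
  k <- 0L
  for (i in seq_len(n_identical_pairs)) {
    id_pairs[[i]] <- shuffled[k + 1:2]; k <- k + 2L
  }
  for (i in seq_len(n_overlapping_pairs)) {
    ov_pairs[[i]] <- shuffled[k + 1:2]; k <- k + 2L
  }
  free_taxa <- shuffled[seq(k + 1L, length.out = n_taxa - k)]
  # planted-pair partner of each taxon (NA outside pairs); partners are
  # edited in step during repair so planted verdicts survive
  partner <- stats::setNames(rep(NA_character_, n_taxa), taxa_ids)
  for (p in c(id_pairs, ov_pairs)) {
    partner[[p[[1]]]] <- p[[2]]; partner[[p[[2]]]] <- p[[1]]
  }

  eligible_unique <- desc_ids[n_states >= 3 &
                              !desc_ids %in% has_children &
                              !desc_ids %in% names(parent_of)]
  if (n_unique_states > length(eligible_unique)) {
    infeasible(sprintf(paste("cannot plant %d unique states: only %d dependency-free",
                             "descriptors with >= 3 states"),
                       n_unique_states, length(eligible_unique)))
  }
  uniq_desc <- if (n_unique_states > 0) {
    sample(eligible_unique, n_unique_states)
  } else character()
  uniq_taxon <- if (n_unique_states > 0) {
    sample(free_taxa, n_unique_states, replace = TRUE)
  } else character()
  # reserved[[d]] = the state of d that only its planted carrier may use
  reserved <- stats::setNames(rep(NA_character_, n_descriptors), desc_ids)
  for (i in seq_along(uniq_desc)) {
    d <- uniq_desc[[i]]
    reserved[[d]] <- paste0("s", sample.int(n_states[[match(d, desc_ids)]], 1L))
  }

  # --- base fill, parents before children ---------------------------------
  cells <- stats::setNames(vector("list", n_taxa), taxa_ids)
  for (t in taxa_ids) cells[[t]] <- stats::setNames(vector("list", 0L), character())

  state_pool <- function(d) {
    pool <- paste0("s", seq_len(n_states[[match(d, desc_ids)]]))
    if (!is.na(reserved[[d]])) pool <- setdiff(pool, reserved[[d]])
    pool
  }
  draw_states <- function(d) {
    pool <- state_pool(d)
    n_pick <- if (length(pool) >= 2 && stats::runif(1) < polymorphism_rate) 2L else 1L
    sort(sample(pool, n_pick))
  }
  cell_applicability <- function(t, d) {
    rule <- parent_of[[d]]
    if (is.null(rule)) return("applicable")
    pa <- cell_applicability(t, rule$parent)
    if (pa != "applicable") return(pa)
    pc <- cells[[t]][[rule$parent]]
    if (is.null(pc)) return("undetermined")
    if (identical(pc, "-")) return("inapplicable")
    if (length(intersect(pc, rule$enabling_states)) == 0L) return("inapplicable")
    "applicable"
  }

  for (d in desc_ids) {
    for (t in taxa_ids) {
      app <- cell_applicability(t, d)
      if (app == "inapplicable") {
        cells[[t]][[d]] <- "-"
      } else if (app == "undetermined") {
        # parent unknown: leave unknown rather than claim the structure
        next
      } else if (!is.na(reserved[[d]])) {
        next  # unique-state descriptors are filled below
      } else if (stats::runif(1) < unknown_rate) {
        next
      } else {
        cells[[t]][[d]] <- draw_states(d)
      }
    }
  }
  # unique-state descriptors: carrier gets the reserved state, the others a
  # described non-reserved state (kept dense so uniqueness is meaningful)
  for (i in seq_along(uniq_desc)) {
    d <- uniq_desc[[i]]
    for (t in taxa_ids) {
      if (!is.null(cells[[t]][[d]])) next  # inapplicable never happens (no parent)
      if (stats::runif(1) < unknown_rate && t != uniq_taxon[[i]]) next
      cells[[t]][[d]] <- draw_states(d)
    }
    cells[[uniq_taxon[[i]]]][[d]] <- reserved[[d]]
  }

  # --- plant pairs --------------------------------------------------------
  for (p in id_pairs) cells[[p[[2]]]] <- cells[[p[[1]]]]
  blank_leafs <- setdiff(desc_ids, c(has_children, uniq_desc))
  for (p in ov_pairs) {
    cells[[p[[2]]]] <- cells[[p[[1]]]]
    described <- intersect(blank_leafs,
                           names(Filter(function(x) !identical(x, "-"),
                                        cells[[p[[1]]]])))
    if (length(described) == 0L) {
      # force one: describe a fresh leaf cell on both, then blank one side
      d <- if (length(blank_leafs)) blank_leafs[[1]] else
        infeasible("cannot plant an overlapping pair without a dependency-free descriptor")
      v <- draw_states(d)
      cells[[p[[1]]]][[d]] <- v
      described <- d
    }
    blank <- sample(described, min(length(described),
                                   1L + stats::rbinom(1L, 2L, 0.5)))
    for (d in blank) cells[[p[[2]]]][[d]] <- NULL
  }

  # --- repair loop --------------------------------------------------------
  planted_pair_key <- vapply(c(id_pairs, ov_pairs),
                             function(p) paste(sort(p), collapse = "|"), "")
  uniq_key <- if (n_unique_states > 0) {
    paste(uniq_taxon, uniq_desc, vapply(uniq_desc, function(d) reserved[[d]], ""))
  } else character()

  # dependency children in index order = topological order (parents have
  # smaller indices by construction), so one sweep renormalizes a whole row
  dep_children_sorted <- desc_ids[desc_ids %in% names(parent_of)]
  set_cell <- function(t, d, value) {
    cells[[t]][[d]] <<- value
    for (ch in dep_children_sorted) {
      app <- cell_applicability(t, ch)
      cur <- cells[[t]][[ch]]
      if (app == "inapplicable" && !identical(cur, "-")) {
        cells[[t]][[ch]] <<- "-"
      } else if (app != "inapplicable" && identical(cur, "-")) {
        cells[[t]][[ch]] <<- NULL
      }
    }
  }

  compare_pair_cells <- function(a, b) {
    sep <- 0L; diffn <- 0L
    for (d in desc_ids) {
      ca <- cells[[a]][[d]]; cb <- cells[[b]][[d]]
      if (is.null(ca) && is.null(cb)) next
      if (is.null(ca) || is.null(cb)) { diffn <- diffn + 1L; next }
      ia <- identical(ca, "-"); ib <- identical(cb, "-")
      if (ia || ib) { if (!(ia && ib)) sep <- sep + 1L; next }
      if (length(intersect(ca, cb)) == 0L) sep <- sep + 1L
      else if (!identical(ca, cb)) diffn <- diffn + 1L
    }
    if (sep > 0L) "distinct" else if (diffn > 0L) "overlapping" else "identical"
  }

  # separate two taxa on a leaf descriptor, keeping planted partners in step;
  # never describes an unknown cell of a pair member (that could flip the
  # planted verdict of its own pair)
  separate <- function(a, b) {
    for (d in sample(blank_leafs)) {
      pool <- state_pool(d)
      if (length(pool) < 2L) next
      ca <- cells[[a]][[d]]; cb <- cells[[b]][[d]]
      if (identical(ca, "-") || identical(cb, "-")) next
      if (is.null(ca) && !is.na(partner[[a]])) next
      if (is.null(cb) && !is.na(partner[[b]])) next
      va <- if (is.null(ca)) pool[[1]] else ca
      vb_pool <- setdiff(pool, va)
      if (length(vb_pool) == 0L) next
      apply_to <- function(t, v) {
        set_cell(t, d, v)
        pt <- partner[[t]]
        if (!is.na(pt) && !is.null(cells[[pt]][[d]]) &&
            !identical(cells[[pt]][[d]], "-")) {
          set_cell(pt, d, v)
        }
      }
      if (is.null(ca)) apply_to(a, va)
      apply_to(b, vb_pool[[1]])
      return(TRUE)
    }
    FALSE
  }

  for (iteration in seq_len(100L)) {
    changed <- FALSE

    # (a) states recorded in exactly one taxon that were not planted
    for (di in seq_len(n_descriptors)) {
      d <- desc_ids[[di]]
      carriers <- list()
      for (t in taxa_ids) {
        v <- cells[[t]][[d]]
        if (is.null(v) || identical(v, "-")) next
        for (s in v) carriers[[s]] <- c(carriers[[s]], t)
      }
      for (s in names(carriers)) {
        if (length(carriers[[s]]) != 1L) next
        if (!is.na(reserved[[d]]) && s == reserved[[d]] &&
            carriers[[s]] == uniq_taxon[[match(d, uniq_desc)]]) next
        t <- carriers[[s]]
        cur <- cells[[t]][[d]]
        rest <- setdiff(cur, s)
        well_used <- names(carriers)[vapply(names(carriers), function(x)
          length(carriers[[x]]) >= 2L, NA)]
        replacement <- if (length(rest)) rest else if (length(well_used)) {
          sample(well_used, 1L)
        } else {
          # no state of d is safely shared yet: duplicate s into another taxon
          others <- setdiff(taxa_ids, c(t, if (!is.na(reserved[[d]])) uniq_taxon))
          others <- Filter(function(o) !is.null(cells[[o]][[d]]) &&
                             !identical(cells[[o]][[d]], "-"), others)
          if (length(others)) {
            o <- sample(others, 1L)
            set_cell(o, d, sort(unique(c(cells[[o]][[d]], s))))
            po <- partner[[o]]
            if (!is.na(po) && !is.null(cells[[po]][[d]]) &&
                !identical(cells[[po]][[d]], "-")) {
              set_cell(po, d, cells[[o]][[d]])
            }
            changed <- TRUE
            next
          }
          NULL
        }
        if (is.null(replacement)) next
        set_cell(t, d, sort(unique(replacement)))
        pt <- partner[[t]]
        if (!is.na(pt) && !is.null(cells[[pt]][[d]]) &&
            !identical(cells[[pt]][[d]], "-")) {
          set_cell(pt, d, cells[[t]][[d]])
        }
        changed <- TRUE
      }
    }

    # (b) non-planted pairs must be distinct
    ok_pairs <- TRUE
    for (i in seq_len(n_taxa - 1L)) {
      for (j in seq(i + 1L, n_taxa)) {
        a <- taxa_ids[[i]]; b <- taxa_ids[[j]]
        key <- paste(sort(c(a, b)), collapse = "|")
        verdict <- compare_pair_cells(a, b)
        if (key %in% planted_pair_key) next
        if (verdict != "distinct") {
          if (!separate(a, b)) ok_pairs <- FALSE else changed <- TRUE
        }
      }
    }

    if (!changed && ok_pairs) break
  }

  # --- materialize and verify --------------------------------------------
  descriptions <- lapply(cells, function(row) {
    lapply(row, function(v) {
      if (identical(v, "-")) coding_inapplicable() else coding_states(v)
    })
  })
  kb <- new_kb(
    metadata = list(name = sprintf("synthetic kb (seed %d)", as.integer(seed)),
                    version = "1.0"),
    groups = groups, descriptors = descriptors, dependencies = dependencies,
    taxa = lapply(taxa_ids, mk_taxon), descriptions = descriptions)

  manifest <- list(
    identical_pairs = pair_frame(id_pairs),
    overlapping_pairs = pair_frame(ov_pairs),
    unique_states = if (n_unique_states > 0) {
      data.frame(taxon = uniq_taxon, descriptor = uniq_desc,
                 state = vapply(uniq_desc, function(d) reserved[[d]], ""),
                 stringsAsFactors = FALSE)
    } else {
      data.frame(taxon = character(), descriptor = character(),
                 state = character(), stringsAsFactors = FALSE)
    },
    params = list(n_taxa = n_taxa, n_descriptors = n_descriptors,
                  states_per_descriptor = states_per_descriptor,
                  polymorphism_rate = polymorphism_rate,
                  unknown_rate = unknown_rate,
                  dependency_fraction = dependency_fraction,
                  seed = as.integer(seed))
  )
  verify_manifest(kb, manifest)
  list(kb = kb, manifest = manifest)
}

pair_frame <- function(pairs) {
  if (length(pairs) == 0L) {
    return(data.frame(t1 = character(), t2 = character(),
                      stringsAsFactors = FALSE))
  }
  df <- do.call(rbind, lapply(pairs, function(p) {
    p <- sort(p)
    data.frame(t1 = p[[1]], t2 = p[[2]], stringsAsFactors = FALSE)
  }))
  df[order(df$t1, df$t2), , drop = FALSE]
}

# the generated base must be valid and its manifest must hold exactly
verify_manifest <- function(kb, manifest) {
  v <- validate_kb(kb)
  if (nrow(v)) {
    stop(sprintf("generator produced an invalid base (%s)",
                 paste(unique(v$code), collapse = ", ")), call. = FALSE)
  }
  cb <- checkbase(kb)
  seen_id <- paste(cb$identical_pairs$t1, cb$identical_pairs$t2)
  want_id <- paste(manifest$identical_pairs$t1, manifest$identical_pairs$t2)
  seen_ov <- paste(cb$overlapping_pairs$t1, cb$overlapping_pairs$t2)
  want_ov <- paste(manifest$overlapping_pairs$t1, manifest$overlapping_pairs$t2)
  sf <- special_features(kb)
  seen_u <- paste(sf$taxon, sf$descriptor, sf$state)
  want_u <- paste(manifest$unique_states$taxon, manifest$unique_states$descriptor,
                  manifest$unique_states$state)
  if (!setequal(seen_id, want_id) || !setequal(seen_ov, want_ov) ||
      !setequal(seen_u, want_u)) {
    infeasible(paste("planting infeasible for these parameters: the repaired base",
                     "does not reproduce its manifest; try different sizes or seed"))
  }
  invisible(TRUE)
}

# classed condition so the retry wrapper can tell "retry may help" apart
# from programming errors
infeasible <- function(msg) {
  stop(structure(class = c("morphokey_infeasible", "error", "condition"),
                 list(message = msg, call = NULL)))
}
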