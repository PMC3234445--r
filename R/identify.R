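#' Compatibility of a recorded coding with an answer
#'
#' The elementary test of the free-access key: does the coding recorded for
#' a taxon allow the observation the user reports? Unknown cells are
#' compatible with everything — this is what lets incomplete fossil
#' specimens be identified. A polymorphic coding or a multi-state answer
#' (doubt) match as soon as the two state sets intersect; intervals match
#' when they overlap.
#'
#' An inapplicable coding is incompatible by default: answering a
#' descriptor asserts the specimen shows that structure, so taxa lacking it
#' are eliminated. Set `na_tolerant = TRUE` to keep them instead.
#'
#' @param coding the taxon's [coding] for the descriptor.
#' @param selection the answer: a character vector of state ids, a numeric
#'   scalar (a point) or length-2 vector (an interval), or a [coding]
#'   built with [coding_states()] / [coding_interval()].
#' @param na_tolerant keep taxa whose coding is inapplicable?
#' @return `TRUE` if the taxon survives this answer.
#' @examples
#' compatible(coding_states("rudimentary"), c("rudimentary", "basic"))
#' compatible(coding_unknown(), "basic")
#' compatible(coding_states("simple"), "canals")
#' @export
compatible <- function(coding, selection, na_tolerant = FALSE) {
  selection <- as_selection(selection)
  ty <- coding_type(coding)
  if (ty == "unknown") return(TRUE)
  if (ty == "inapplicable") return(isTRUE(na_tolerant))
  if (ty != coding_type(selection)) {
    stop("answer kind does not match the coding (states vs interval)",
         call. = FALSE)
  }
  !codings_disjoint(coding, selection)
}

as_selection <- function(selection) {
  if (is_coding(selection)) {
    if (!coding_type(selection) %in% c("states", "interval")) {
      stop("an answer must be a state set or an interval", call. = FALSE)
    }
    return(selection)
  }
  if (is.character(selection)) return(coding_states(selection))
  if (is.numeric(selection)) {
    if (length(selection) == 1L) return(coding_interval(selection))
    if (length(selection) == 2L) return(coding_interval(min(selection), max(selection)))
  }
  stop("cannot interpret the answer: give state ids or numeric bounds",
       call. = FALSE)
}

#' Free-access identification sessions
#'
#' `new_session()` opens an identification session over a knowledge base:
#' all taxa start as remaining, and descriptors can then be answered in any
#' order with [answer()]. The session keeps the partition of taxa into
#' remaining and eliminated, with a reproducible reason for every
#' elimination.
#'
#' @param kb a knowledge base.
#' @param na_tolerant if `TRUE`, taxa coded inapplicable for an answered
#'   descriptor are kept rather than eliminated (see [compatible()]).
#' @return An object of class `mk_session`.
#' @seealso [answer()], [reasons()], [recommend_descriptors()], [undo()]
#' @export
new_session <- function(kb, na_tolerant = FALSE) {
  structure(
    list(kb = kb, na_tolerant = isTRUE(na_tolerant), answers = list()),
    class = "mk_session"
  )
}

#' @export
print.mk_session <- function(x, ...) {
  cat(sprintf("<identification session> %d answered, %d remaining / %d eliminated\n",
              length(x$answers), length(remaining(x)), length(eliminated(x))))
  invisible(x)
}

# effective coding used during identification: explicit coding if present,
# otherwise inapplicable when the dependency rules settle it, else unknown
effective_coding <- function(kb, taxon, descriptor) {
  cd <- kb$descriptions[[taxon]][[descriptor]]
  if (!is.null(cd)) return(cd)
  if (applicability_from_codings(kb, kb$descriptions[[taxon]], descriptor) ==
      "inapplicable") {
    return(coding_inapplicable())
  }
  coding_unknown()
}

#' Answer a descriptor
#'
#' Records an observation and updates the partition: every remaining taxon
#' whose coding is incompatible with the selection is eliminated. Selecting
#' several states expresses doubt — a taxon survives if any selected state
#' matches. Re-answering a descriptor replaces the previous answer and the
#' partition is recomputed from the full answer set, so the order in which
#' descriptors are answered never changes the outcome.
#'
#' Answering a descriptor that is inapplicable for every remaining taxon is
#' a no-op with a warning (nothing can be learned from it).
#'
#' @param session an identification session.
#' @param descriptor descriptor id.
#' @param selection the observed state id(s) or numeric value/interval.
#' @return The updated session.
#' @examples
#' kb <- build_fixture()
#' s <- answer(new_session(kb), "d2", "absent") # chambers absent
#' remaining(s)
#' @export
answer <- function(session, descriptor, selection) {
  kb <- session$kb
  stop_unless_descriptor(kb, descriptor)
  selection <- as_selection(selection)
  desc <- kb$descriptors[[descriptor]]
  if (coding_type(selection) == "states") {
    if (desc$kind != "categorical") {
      stop(sprintf("descriptor '%s' is numeric; answer with a value or interval",
                   descriptor), call. = FALSE)
    }
    bad <- setdiff(selection$states, descriptor_state_ids(desc))
    if (length(bad)) {
      stop(sprintf("states not defined by descriptor '%s': %s",
                   descriptor, paste(bad, collapse = ", ")), call. = FALSE)
    }
  } else if (desc$kind != "numeric") {
    stop(sprintf("descriptor '%s' is categorical; answer with state ids",
                 descriptor), call. = FALSE)
  }

  rem <- remaining(session)
  if (length(rem)) {
    app <- vapply(rem, function(t) {
      coding_type(effective_coding(kb, t, descriptor)) == "inapplicable"
    }, NA)
    if (all(app)) {
      warning(sprintf("descriptor '%s' is inapplicable for every remaining taxon; answer ignored",
                      descriptor), call. = FALSE)
      return(session)
    }
  }
  session$answers[[descriptor]] <- selection
  session
}

#' @rdname answer
#' @export
remaining <- function(session) {
  kb <- session$kb
  keep <- vapply(names(kb$taxa), function(t) {
    for (d in names(session$answers)) {
      if (!compatible(effective_coding(kb, t, d), session$answers[[d]],
                      session$na_tolerant)) {
        return(FALSE)
      }
    }
    TRUE
  }, NA)
  names(kb$taxa)[keep]
}

#' @rdname answer
#' @export
eliminated <- function(session) {
  setdiff(names(session$kb$taxa), remaining(session))
}

#' Why was a taxon eliminated?
#'
#' Lists every answered descriptor whose selection is incompatible with the
#' taxon's coding — not just the first one met — so the user can check each
#' conflicting character against the specimen.
#'
#' @param session an identification session.
#' @param taxon an eliminated taxon (id or name).
#' @return A data frame with columns `descriptor`, `code`
#'   (`DISJOINT_STATES`, `INAPPLICABLE_FOR_TAXON` or `INTERVAL_MISMATCH`),
#'   `answer` and `coding` (both formatted).
#' @export
reasons <- function(session, taxon) {
  kb <- session$kb
  taxon <- resolve_taxon(kb, taxon)
  if (taxon %in% remaining(session)) {
    stop(sprintf("taxon '%s' has not been eliminated", taxon), call. = FALSE)
  }
  rows <- list()
  for (d in names(session$answers)) {
    sel <- session$answers[[d]]
    cd <- effective_coding(kb, taxon, d)
    if (compatible(cd, sel, session$na_tolerant)) next
    code <- if (coding_type(cd) == "inapplicable") {
      "INAPPLICABLE_FOR_TAXON"
    } else if (coding_type(sel) == "interval") {
      "INTERVAL_MISMATCH"
    } else {
      "DISJOINT_STATES"
    }
    rows[[length(rows) + 1L]] <- data.frame(
      descriptor = d, code = code, answer = format(sel), coding = format(cd),
      stringsAsFactors = FALSE)
  }
  do.call(rbind, rows)
}

#' Recommend the next descriptors to answer
#'
#' Ranks the unanswered descriptors by separating power over the remaining
#' taxa: for descriptor `d`, the comparable pairs are the unordered pairs
#' of remaining taxa in which both codings are described (state set or
#' interval) and `d` is applicable for both; the power is the fraction of
#' comparable pairs with disjoint codings (0 when no pair is comparable).
#' Ties are broken by descriptor id.
#'
#' @param session an identification session with at least two remaining
#'   taxa (otherwise an empty ranking is returned).
#' @return A data frame with columns `descriptor` and `power`, sorted by
#'   decreasing power.
#' @export
recommend_descriptors <- function(session) {
  kb <- session$kb
  rem <- remaining(session)
  empty <- data.frame(descriptor = character(), power = numeric(),
                      stringsAsFactors = FALSE)
  if (length(rem) < 2L) return(empty)
  cand <- setdiff(names(kb$descriptors), names(session$answers))
  if (length(cand) == 0L) return(empty)
  power <- vapply(cand, function(d) {
    cods <- lapply(rem, function(t) effective_coding(kb, t, d))
    usable <- vapply(cods, function(cd) {
      coding_type(cd) %in% c("states", "interval")
    }, NA)
    cods <- cods[usable]
    n <- length(cods)
    if (n < 2L) return(0)
    disjoint <- 0L; total <- 0L
    for (i in seq_len(n - 1L)) {
      for (j in seq((i + 1L), n)) {
        total <- total + 1L
        if (codings_disjoint(cods[[i]], cods[[j]])) disjoint <- disjoint + 1L
      }
    }
    disjoint / total
  }, 0)
  ord <- order(-power, cand)
  data.frame(descriptor = cand[ord], power = unname(power[ord]),
             stringsAsFactors = FALSE)
}

#' Undo the last answer
#'
#' Equivalent to replaying all answers but the last from a fresh session.
#'
#' @param session a session with at least one answer.
#' @return The session without its most recent answer.
#' @export
undo <- function(session) {
  n <- length(session$answers)
  if (n == 0L) stop("nothing to undo: no descriptor has been answered", call. = FALSE)
  session$answers[[n]] <- NULL
  session
}
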