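#' Compare two taxon descriptions
#'
#' Classifies a pair of taxa by walking every descriptor and sorting it
#' into one of two buckets:
#'
#' * `separating` — the recorded codings are incompatible, so a single
#'   observation can tell the taxa apart: described codings that are
#'   disjoint, or a structure recorded for one taxon and recorded absent
#'   (inapplicable) for the other;
#' * `differing_but_compatible` — the codings are not equal but no
#'   observation could separate them: intersecting state sets, overlapping
#'   intervals, or an unknown cell facing a described one.
#'
#' The verdict follows: `distinct` when a separating descriptor exists,
#' `identical` when both buckets are empty, `overlapping` otherwise. An
#' `identical` or `overlapping` verdict means some specimens are compatible
#' with both taxa — a possible synonymy or a coding error worth review.
#'
#' @param kb a knowledge base.
#' @param t1,t2 two different taxa (ids or names).
#' @return An object of class `mk_pair`: a list with `t1`, `t2`, `verdict`,
#'   `separating` and `differing_but_compatible` (character vectors of
#'   descriptor ids).
#' @examples
#' kb <- build_fixture("post_revision")
#' classify_pair(kb, "Dictyocyathus", "Molybdocyathus")$verdict
#' classify_pair(kb, "Graphoscyphia", "Dictyocyathus")$separating
#' @export
classify_pair <- function(kb, t1, t2) {
  t1 <- resolve_taxon(kb, t1)
  t2 <- resolve_taxon(kb, t2)
  if (t1 == t2) stop("classify_pair needs two different taxa", call. = FALSE)
  separating <- character()
  differing <- character()
  for (d in names(kb$descriptors)) {
    cls <- compare_cell(effective_coding(kb, t1, d), effective_coding(kb, t2, d))
    if (cls == "separating") separating <- c(separating, d)
    else if (cls == "differing") differing <- c(differing, d)
  }
  verdict <- if (length(separating)) "distinct"
             else if (length(differing)) "overlapping"
             else "identical"
  structure(list(t1 = t1, t2 = t2, verdict = verdict, separating = separating,
                 differing_but_compatible = differing),
            class = "mk_pair")
}

#' @export
print.mk_pair <- function(x, ...) {
  cat(sprintf("%s vs %s: %s\n", x$t1, x$t2, x$verdict))
  if (length(x$separating)) {
    cat("  separating:", paste(x$separating, collapse = ", "), "\n")
  }
  if (length(x$differing_but_compatible)) {
    cat("  differing but compatible:",
        paste(x$differing_but_compatible, collapse = ", "), "\n")
  }
  invisible(x)
}

# classify one descriptor cell pair: "separating", "differing" or "equal"
compare_cell <- function(a, b) {
  ta <- coding_type(a); tb <- coding_type(b)
  if (ta == "unknown" || tb == "unknown") {
    # an unknown can hide anything: never separates, never certifies identity
    if (ta == "unknown" && tb == "unknown") return("equal")
    return("differing")
  }
  if (ta == "inapplicable" || tb == "inapplicable") {
    # structure present on one side, absent on the other, is a real difference
    if (ta == "inapplicable" && tb == "inapplicable") return("equal")
    return("separating")
  }
  if (coding_equal(a, b)) return("equal")
  if (codings_disjoint(a, b)) return("separating")
  "differing"
}

#' Checkbase: screen a whole knowledge base
#'
#' Compares every unordered pair of taxon descriptions and reports the
#' pairs that cannot be told apart — `identical` pairs (candidate
#' synonymies or duplicated descriptions) and `overlapping` pairs (some
#' specimens would match both) — together with the validator output and
#' the completeness summary. Pairs are listed lexicographically by taxon
#' name so that reports diff cleanly.
#'
#' @param kb a knowledge base.
#' @return An object of class `mk_checkbase`: a list with data frames
#'   `identical_pairs` and `overlapping_pairs` (columns `t1`, `t2`,
#'   `n_differing`), `violations` (see [validate_kb()]) and `completeness`
#'   (see [completeness_report()]).
#' @examples
#' cb <- checkbase(build_fixture("post_revision"))
#' cb$identical_pairs
#' @export
checkbase <- function(kb) {
  taxa <- names(kb$taxa)
  ord <- order(vapply(kb$taxa, `[[`, "", "name"))
  taxa <- taxa[ord]
  idn <- list(); ovl <- list()
  if (length(taxa) >= 2L) {
    for (i in seq_len(length(taxa) - 1L)) {
      for (j in seq((i + 1L), length(taxa))) {
        pc <- classify_pair(kb, taxa[[i]], taxa[[j]])
        if (pc$verdict == "identical") {
          idn[[length(idn) + 1L]] <- data.frame(
            t1 = taxa[[i]], t2 = taxa[[j]], n_differing = 0L,
            stringsAsFactors = FALSE)
        } else if (pc$verdict == "overlapping") {
          ovl[[length(ovl) + 1L]] <- data.frame(
            t1 = taxa[[i]], t2 = taxa[[j]],
            n_differing = length(pc$differing_but_compatible),
            stringsAsFactors = FALSE)
        }
      }
    }
  }
  empty <- data.frame(t1 = character(), t2 = character(),
                      n_differing = integer(), stringsAsFactors = FALSE)
  structure(
    list(identical_pairs = if (length(idn)) do.call(rbind, idn) else empty,
         overlapping_pairs = if (length(ovl)) do.call(rbind, ovl) else empty,
         violations = validate_kb(kb),
         completeness = completeness_report(kb)),
    class = "mk_checkbase"
  )
}

#' @export
print.mk_checkbase <- function(x, ...) {
  cat("<checkbase report>\n")
  cat(sprintf("  identical pairs:   %d\n", nrow(x$identical_pairs)))
  cat(sprintf("  overlapping pairs: %d\n", nrow(x$overlapping_pairs)))
  cat(sprintf("  violations:        %d\n", nrow(x$violations)))
  cat(sprintf("  completeness:      %.3f\n", x$completeness$overall))
  invisible(x)
}

#' Special features: states unique to a single taxon
#'
#' A special feature is a state recorded for exactly one taxon among the
#' described cells of a descriptor — a diagnostic character for that
#' taxon. Uniqueness is judged against described codings only; the number
#' of other taxa whose cell is unknown is reported alongside, as a caution
#' (any of them might turn out to share the state).
#'
#' @param kb a knowledge base.
#' @param taxa optional subset of taxon ids/names to restrict the scope
#'   (at least two).
#' @return A data frame with columns `taxon`, `descriptor`, `state`,
#'   `n_unknown_others`, ordered by taxon name then descriptor id.
#' @examples
#' sf <- special_features(build_fixture())
#' sf[sf$taxon == "Connanulofungia", ]
#' @export
special_features <- function(kb, taxa = NULL) {
  scope <- if (is.null(taxa)) names(kb$taxa) else
    vapply(taxa, function(t) resolve_taxon(kb, t), "")
  if (length(scope) < 2L) {
    stop("special features need at least two taxa in scope", call. = FALSE)
  }
  rows <- list()
  for (d in names(kb$descriptors)) {
    desc <- kb$descriptors[[d]]
    if (desc$kind != "categorical") next
    carriers <- list()
    n_unknown <- 0L
    for (t in scope) {
      cd <- effective_coding(kb, t, d)
      ty <- coding_type(cd)
      if (ty == "unknown") {
        n_unknown <- n_unknown + 1L
      } else if (ty == "states") {
        for (s in cd$states) carriers[[s]] <- c(carriers[[s]], t)
      }
    }
    for (s in names(carriers)) {
      if (length(carriers[[s]]) == 1L) {
        rows[[length(rows) + 1L]] <- data.frame(
          taxon = carriers[[s]], descriptor = d, state = s,
          n_unknown_others = n_unknown, stringsAsFactors = FALSE)
      }
    }
  }
  if (length(rows) == 0L) {
    return(data.frame(taxon = character(), descriptor = character(),
                      state = character(), n_unknown_others = integer(),
                      stringsAsFactors = FALSE))
  }
  out <- do.call(rbind, rows)
  tnames <- vapply(out$taxon, function(t) kb$taxa[[t]]$name, "")
  out <- out[order(tnames, out$descriptor, out$state), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Comparative table over a subset of taxa
#'
#' The side-by-side view used to separate the last few candidates of an
#' identification, or to survey a family: one row per descriptor, flagged
#' `same` (all described codings equal), `different` (some pair of
#' described codings disjoint, or structure present vs absent), `partial`
#' (unequal but compatible) or `not_comparable` (fewer than two described
#' codings).
#'
#' @param kb a knowledge base.
#' @param taxa at least two taxon ids or names.
#' @return An object of class `mk_comparative`: a list with `taxa` and a
#'   data frame `table` (columns `descriptor`, `flag`, then one formatted
#'   coding column per taxon).
#' @export
comparative_table <- function(kb, taxa) {
  taxa <- vapply(taxa, function(t) resolve_taxon(kb, t), "")
  if (length(taxa) < 2L) stop("a comparative table needs at least two taxa", call. = FALSE)
  rows <- lapply(names(kb$descriptors), function(d) {
    cods <- lapply(taxa, function(t) effective_coding(kb, t, d))
    described <- Filter(function(cd) coding_type(cd) != "unknown", cods)
    flag <- if (length(described) < 2L) {
      "not_comparable"
    } else {
      cls <- "same"
      for (i in seq_len(length(described) - 1L)) {
        for (j in seq((i + 1L), length(described))) {
          c_ij <- compare_cell(described[[i]], described[[j]])
          if (c_ij == "separating") { cls <- "different"; break }
          if (c_ij == "differing") cls <- "partial"
        }
        if (cls == "different") break
      }
      cls
    }
    cells <- vapply(cods, format, "")
    df <- data.frame(descriptor = d, flag = flag, stringsAsFactors = FALSE)
    for (k in seq_along(taxa)) df[[taxa[[k]]]] <- cells[[k]]
    df
  })
  structure(list(taxa = taxa, table = do.call(rbind, rows)),
            class = "mk_comparative")
}

#' @export
print.mk_comparative <- function(x, ...) {
  cat(sprintf("<comparative table> %s\n", paste(x$taxa, collapse = " | ")))
  shown <- x$table[x$table$flag != "not_comparable", , drop = FALSE]
  print.data.frame(shown, row.names = FALSE)
  invisible(x)
}
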