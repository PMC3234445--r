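#' Validate a knowledge base
#'
#' Runs the semantic consistency checks over a structurally sound knowledge
#' base and returns every violation found (never throws: violations are
#' data). An empty result means the base is valid.
#'
#' Violation codes:
#' \describe{
#'   \item{`EMPTY_STATESET`}{a state-set coding with no states.}
#'   \item{`STATE_NOT_IN_DESCRIPTOR`}{a coded state id that the descriptor
#'     does not define, or an interval on a categorical descriptor (and
#'     vice versa).}
#'   \item{`CODED_BUT_INAPPLICABLE`}{a cell carries a state set or interval
#'     although the dependency rules make the descriptor inapplicable for
#'     that taxon.}
#'   \item{`INAPPLICABLE_BUT_APPLICABLE`}{a cell is coded inapplicable
#'     although the descriptor is applicable for that taxon.}
#'   \item{`DEPENDENCY_CYCLE`}{the child-to-parent dependency graph has a
#'     cycle.}
#'   \item{`DANGLING_REF`}{a dependency or coding refers to a descriptor,
#'     state or taxon that does not exist.}
#' }
#'
#' @param kb a knowledge base.
#' @return A data frame with columns `code`, `taxon`, `descriptor`,
#'   `detail`; zero rows iff the base is valid.
#' @seealso [completeness_report()], [checkbase()]
#' @export
validate_kb <- function(kb) {
  out <- list()
  add <- function(code, taxon = NA_character_, descriptor = NA_character_,
                  detail = "") {
    out[[length(out) + 1L]] <<- data.frame(
      code = code, taxon = taxon, descriptor = descriptor, detail = detail,
      stringsAsFactors = FALSE)
  }

  desc_ids <- names(kb$descriptors)

  # dependency structure
  for (r in kb$dependencies) {
    if (!r$child %in% desc_ids) {
      add("DANGLING_REF", descriptor = r$child,
          detail = "dependency child does not exist")
      next
    }
    if (!r$parent %in% desc_ids) {
      add("DANGLING_REF", descriptor = r$parent,
          detail = sprintf("dependency parent of '%s' does not exist", r$child))
      next
    }
    parent <- kb$descriptors[[r$parent]]
    bad <- setdiff(r$enabling_states, descriptor_state_ids(parent))
    if (length(bad)) {
      add("DANGLING_REF", descriptor = r$parent,
          detail = sprintf("enabling states not defined by parent: %s",
                           paste(bad, collapse = ", ")))
    }
  }
  cyclic <- !dependencies_acyclic(kb)
  if (cyclic) {
    add("DEPENDENCY_CYCLE", detail = "dependency graph child->parent has a cycle")
  }

  # cell-level checks
  for (t in names(kb$taxa)) {
    codings <- kb$descriptions[[t]]
    for (d in names(codings)) {
      cd <- codings[[d]]
      if (!d %in% desc_ids) {
        add("DANGLING_REF", taxon = t, descriptor = d,
            detail = "coding refers to unknown descriptor")
        next
      }
      desc <- kb$descriptors[[d]]
      ty <- coding_type(cd)
      if (ty == "states") {
        if (length(cd$states) == 0L) {
          add("EMPTY_STATESET", taxon = t, descriptor = d)
          next
        }
        if (desc$kind != "categorical") {
          add("STATE_NOT_IN_DESCRIPTOR", taxon = t, descriptor = d,
              detail = "state set coded on a numeric descriptor")
          next
        }
        bad <- setdiff(cd$states, descriptor_state_ids(desc))
        if (length(bad)) {
          add("STATE_NOT_IN_DESCRIPTOR", taxon = t, descriptor = d,
              detail = paste(bad, collapse = ", "))
          next
        }
      } else if (ty == "interval" && desc$kind != "numeric") {
        add("STATE_NOT_IN_DESCRIPTOR", taxon = t, descriptor = d,
            detail = "interval coded on a categorical descriptor")
        next
      }
      if (!cyclic) {
        app <- applicability_from_codings(kb, codings, d)
        if (ty %in% c("states", "interval") && app == "inapplicable") {
          add("CODED_BUT_INAPPLICABLE", taxon = t, descriptor = d,
              detail = "cell is coded although a dependency rule makes it inapplicable")
        } else if (ty == "inapplicable" && app == "applicable" &&
                   length(Filter(function(r) r$child == d, kb$dependencies))) {
          add("INAPPLICABLE_BUT_APPLICABLE", taxon = t, descriptor = d,
              detail = "cell is coded inapplicable although its dependency rules are met")
        } else if (ty == "inapplicable" &&
                   length(Filter(function(r) r$child == d, kb$dependencies)) == 0L) {
          add("INAPPLICABLE_BUT_APPLICABLE", taxon = t, descriptor = d,
              detail = "cell is coded inapplicable but the descriptor has no dependency rule")
        }
      }
    }
  }

  if (length(out) == 0L) {
    return(data.frame(code = character(), taxon = character(),
                      descriptor = character(), detail = character(),
                      stringsAsFactors = FALSE))
  }
  do.call(rbind, out)
}

#' Completeness of a knowledge base
#'
#' Fraction of described cells (state set, interval or explicit
#' inapplicable — anything but unknown) per taxon, per descriptor and
#' overall. Useful to spot under-described taxa and never-recorded
#' descriptors.
#'
#' @param kb a knowledge base with at least one taxon and one descriptor.
#' @return A list with `per_taxon` and `per_descriptor` (named numeric
#'   vectors of fractions in `[0, 1]`) and `overall` (the mean over all
#'   taxon-by-descriptor cells).
#' @export
completeness_report <- function(kb) {
  taxa <- names(kb$taxa)
  descs <- names(kb$descriptors)
  if (length(taxa) == 0L || length(descs) == 0L) {
    stop("completeness is undefined for an empty knowledge base", call. = FALSE)
  }
  described <- matrix(FALSE, nrow = length(taxa), ncol = length(descs),
                      dimnames = list(taxa, descs))
  for (t in taxa) {
    codings <- kb$descriptions[[t]]
    for (d in intersect(names(codings), descs)) {
      described[t, d] <- is_described(codings[[d]])
    }
  }
  list(per_taxon = rowMeans(described),
       per_descriptor = colMeans(described),
       overall = mean(described))
}
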