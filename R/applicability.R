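#' Applicability of a descriptor for a taxon
#'
#' A descriptor bound to a parent by a dependency rule is only meaningful
#' when the parent's coding meets the rule's enabling states (e.g. bump
#' shape is only meaningful when bumps are present). Applicability is
#' three-valued:
#'
#' * `"applicable"` — no rule, or every rule is met (a polymorphic parent
#'   that straddles enabling and non-enabling states counts as met: the
#'   structure may be present);
#' * `"inapplicable"` — some rule fires: the parent is itself inapplicable,
#'   is coded inapplicable, or its states are disjoint from the enabling
#'   set. Inapplicability propagates down dependency chains;
#' * `"undetermined"` — no rule fires but at least one parent is unknown.
#'
#' @param kb a knowledge base.
#' @param taxon,descriptor ids.
#' @return One of `"applicable"`, `"inapplicable"`, `"undetermined"`.
#' @examples
#' kb <- build_fixture()
#' applicability(kb, "Erismacoscinus", "d23") # bump shape without bumps
#' @export
applicability <- function(kb, taxon, descriptor) {
  stop_unless_taxon(kb, taxon)
  stop_unless_descriptor(kb, descriptor)
  applicability_from_codings(kb, kb$descriptions[[taxon]], descriptor)
}

# Same evaluation against an arbitrary set of codings (used for partial
# descriptions, e.g. terminology expansions, and by the validator).
applicability_from_codings <- function(kb, codings, descriptor,
                                       .seen = character()) {
  if (descriptor %in% .seen) {
    # dependency cycle: treated as undetermined here; validate_kb() reports it
    return("undetermined")
  }
  rules <- Filter(function(r) r$child == descriptor, kb$dependencies)
  if (length(rules) == 0L) return("applicable")
  status <- "applicable"
  for (r in rules) {
    parent_app <- applicability_from_codings(kb, codings, r$parent,
                                             c(.seen, descriptor))
    if (parent_app == "inapplicable") return("inapplicable")
    if (parent_app == "undetermined") {
      status <- "undetermined"
      next
    }
    parent_coding <- codings[[r$parent]] %||% coding_unknown()
    ptype <- coding_type(parent_coding)
    if (ptype == "inapplicable") return("inapplicable")
    if (ptype == "unknown") {
      status <- "undetermined"
    } else if (ptype == "states") {
      if (length(intersect(parent_coding$states, r$enabling_states)) == 0L) {
        return("inapplicable")
      }
    } else {
      # numeric parent: enabling states are undefined for intervals
      stop(sprintf("dependency parent '%s' is numeric; enabling states need a categorical parent",
                   r$parent), call. = FALSE)
    }
  }
  status
}

# applicability for every taxon on one descriptor (vectorised helper)
applicability_all <- function(kb, descriptor) {
  vapply(names(kb$taxa),
         function(t) applicability_from_codings(kb, kb$descriptions[[t]], descriptor),
         "")
}

dependency_children <- function(kb) {
  unique(vapply(kb$dependencies, `[[`, "", "child"))
}

# child -> parent edges as a two-column matrix
dependency_edges <- function(kb) {
  if (length(kb$dependencies) == 0L) {
    return(matrix(character(), ncol = 2, dimnames = list(NULL, c("child", "parent"))))
  }
  cbind(child = vapply(kb$dependencies, `[[`, "", "child"),
        parent = vapply(kb$dependencies, `[[`, "", "parent"))
}

# TRUE iff the child->parent graph is acyclic (Kahn's algorithm)
dependencies_acyclic <- function(kb) {
  edges <- dependency_edges(kb)
  if (nrow(edges) == 0L) return(TRUE)
  nodes <- unique(c(edges[, 1], edges[, 2]))
  # iteratively delete nodes with no outgoing child->parent edge
  repeat {
    if (nrow(edges) == 0L || length(nodes) == 0L) return(TRUE)
    no_out <- setdiff(nodes, edges[, "child"])
    if (length(no_out) == 0L) return(FALSE)
    edges <- edges[!(edges[, "parent"] %in% no_out), , drop = FALSE]
    nodes <- setdiff(nodes, no_out)
  }
}
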