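#' Building blocks of a knowledge base
#'
#' Constructors for the components of a descriptive knowledge base:
#' descriptor groups, descriptors with their states, inapplicability
#' dependencies, and taxa with their classification path.
#'
#' @param id stable string identifier.
#' @param label display text.
#' @name kb-components
NULL

#' @rdname kb-components
#' @export
mk_group <- function(id, label = id) {
  stopifnot(is.character(id), length(id) == 1L, nzchar(id))
  list(id = id, label = label)
}

#' @rdname kb-components
#' @param definition optional free-text definition of a state.
#' @export
mk_state <- function(id, label = id, definition = NULL) {
  stopifnot(is.character(id), length(id) == 1L, nzchar(id))
  if (!nzchar(label)) stop("state label must be non-empty", call. = FALSE)
  list(id = id, label = label, definition = definition)
}

#' @rdname kb-components
#' @param kind `"categorical"` (with `states`) or `"numeric"` (with `unit`).
#' @param states for categorical descriptors, a list of [mk_state()] entries
#'   (bare strings are promoted to states); at least two are required.
#' @param unit measurement unit for numeric descriptors.
#' @param group id of the descriptor group.
#' @param taxonomic_value `FALSE` flags descriptors kept for their visual
#'   help during identification but carrying no taxonomic signal; they take
#'   part in every computation and are only marked in reports.
#' @export
mk_descriptor <- function(id, label = id, kind = c("categorical", "numeric"),
                          states = list(), unit = NULL, group = NULL,
                          taxonomic_value = TRUE) {
  kind <- match.arg(kind)
  stopifnot(is.character(id), length(id) == 1L, nzchar(id))
  states <- lapply(states, function(s) if (is.character(s)) mk_state(s) else s)
  if (kind == "categorical") {
    if (length(states) < 2L) {
      stop(sprintf("categorical descriptor '%s' needs at least 2 states", id),
           call. = FALSE)
    }
    ids <- vapply(states, `[[`, "", "id")
    if (anyDuplicated(ids)) {
      stop(sprintf("duplicate state ids in descriptor '%s'", id), call. = FALSE)
    }
    names(states) <- ids
  } else if (length(states) > 0L) {
    stop(sprintf("numeric descriptor '%s' must not define states", id),
         call. = FALSE)
  }
  list(id = id, label = label, kind = kind, states = states, unit = unit,
       group = group, taxonomic_value = isTRUE(taxonomic_value))
}

#' @rdname kb-components
#' @param child,parent descriptor ids; `child` is applicable only when the
#'   coding of `parent` meets `enabling_states`.
#' @param enabling_states non-empty set of `parent` state ids under which
#'   `child` is applicable.
#' @export
mk_dependency <- function(child, parent, enabling_states) {
  stopifnot(is.character(child), is.character(parent))
  if (child == parent) stop("a descriptor cannot depend on itself", call. = FALSE)
  enabling_states <- unique(as.character(enabling_states))
  if (length(enabling_states) == 0L) {
    stop("dependency needs at least one enabling state", call. = FALSE)
  }
  list(child = child, parent = parent, enabling_states = sort(enabling_states))
}

#' @rdname kb-components
#' @param name taxon name (unique within the base).
#' @param classification ordered rank:name pairs from the highest rank down,
#'   given as a named character vector (names are ranks) or a two-column
#'   data frame with columns `rank` and `name`.
#' @param notes free text.
#' @export
mk_taxon <- function(id, name = id, classification = NULL, notes = NULL) {
  stopifnot(is.character(id), length(id) == 1L, nzchar(id))
  if (is.null(classification)) {
    classification <- data.frame(rank = character(), name = character(),
                                 stringsAsFactors = FALSE)
  } else if (is.character(classification)) {
    classification <- data.frame(rank = names(classification),
                                 name = unname(classification),
                                 stringsAsFactors = FALSE)
  }
  stopifnot(is.data.frame(classification),
            all(c("rank", "name") %in% names(classification)))
  if (anyDuplicated(classification$rank)) {
    stop(sprintf("taxon '%s': classification ranks must be distinct", id),
         call. = FALSE)
  }
  list(id = id, name = name, classification = classification, notes = notes)
}

#' Assemble a knowledge base
#'
#' A knowledge base bundles a descriptor registry (groups, descriptors,
#' dependencies) with a set of taxa and exactly one description per taxon.
#' Structural integrity (resolvable ids, one description per taxon) is
#' enforced here; semantic consistency is the job of [validate_kb()].
#'
#' @param metadata named list; `name`, `version` and `license` are
#'   conventional entries.
#' @param groups list of [mk_group()] entries.
#' @param descriptors list of [mk_descriptor()] entries.
#' @param dependencies list of [mk_dependency()] entries.
#' @param taxa list of [mk_taxon()] entries.
#' @param descriptions named list (by taxon id); each element is a named list
#'   (by descriptor id) of [coding] objects. A missing entry means the cell
#'   is unknown.
#' @return An object of class `morphokey_kb`.
#' @seealso [validate_kb()], [read_kb()], [build_fixture()]
#' @export
new_kb <- function(metadata = list(), groups = list(), descriptors = list(),
                   dependencies = list(), taxa = list(), descriptions = list()) {
  names(groups) <- vapply(groups, `[[`, "", "id")
  names(descriptors) <- vapply(descriptors, `[[`, "", "id")
  names(taxa) <- vapply(taxa, `[[`, "", "id")
  if (anyDuplicated(names(groups))) stop("duplicate group ids", call. = FALSE)
  if (anyDuplicated(names(descriptors))) stop("duplicate descriptor ids", call. = FALSE)
  if (anyDuplicated(names(taxa))) stop("duplicate taxon ids", call. = FALSE)
  tnames <- vapply(taxa, `[[`, "", "name")
  if (anyDuplicated(tnames)) stop("duplicate taxon names", call. = FALSE)

  for (d in descriptors) {
    if (!is.null(d$group) && !d$group %in% names(groups)) {
      stop(sprintf("descriptor '%s' refers to unknown group '%s'", d$id, d$group),
           call. = FALSE)
    }
  }
  # at most one rule per (child, parent) pair
  if (length(dependencies)) {
    key <- vapply(dependencies, function(r) paste(r$child, r$parent), "")
    if (anyDuplicated(key)) {
      stop("duplicate dependency rule for the same child/parent pair", call. = FALSE)
    }
  }
  # every described taxon exists, every taxon has (possibly empty) codings
  extra <- setdiff(names(descriptions), names(taxa))
  if (length(extra)) {
    stop(sprintf("descriptions for unknown taxa: %s", paste(extra, collapse = ", ")),
         call. = FALSE)
  }
  for (t in setdiff(names(taxa), names(descriptions))) descriptions[[t]] <- list()
  descriptions <- descriptions[names(taxa)]
  # canonical cell order (registry order) so serializations are stable
  descriptions <- lapply(descriptions, function(codings) {
    codings[order(match(names(codings), names(descriptors)), na.last = TRUE)]
  })

  kb <- structure(
    list(metadata = metadata, groups = groups, descriptors = descriptors,
         dependencies = dependencies, taxa = taxa, descriptions = descriptions),
    class = "morphokey_kb"
  )
  kb
}

#' @export
print.morphokey_kb <- function(x, ...) {
  name <- x$metadata$name %||% "<unnamed>"
  cat(sprintf("<morphokey knowledge base> %s\n", name))
  cat(sprintf("  %d taxa, %d descriptors (%d groups), %d dependency rules\n",
              length(x$taxa), length(x$descriptors), length(x$groups),
              length(x$dependencies)))
  invisible(x)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Accessors
#'
#' @param kb a knowledge base.
#' @return `kb_taxon_ids()` and `kb_descriptor_ids()` return character
#'   vectors; `kb_coding()` returns the coding of one cell (an explicit
#'   [coding_unknown()] when the cell has no entry).
#' @name kb-access
NULL

#' @rdname kb-access
#' @export
kb_taxon_ids <- function(kb) names(kb$taxa)

#' @rdname kb-access
#' @export
kb_descriptor_ids <- function(kb) names(kb$descriptors)

#' @rdname kb-access
#' @param taxon,descriptor ids.
#' @export
kb_coding <- function(kb, taxon, descriptor) {
  stop_unless_taxon(kb, taxon)
  stop_unless_descriptor(kb, descriptor)
  kb$descriptions[[taxon]][[descriptor]] %||% coding_unknown()
}

stop_unless_taxon <- function(kb, taxon) {
  if (!taxon %in% names(kb$taxa)) {
    stop(sprintf("unknown taxon id '%s'", taxon), call. = FALSE)
  }
}

stop_unless_descriptor <- function(kb, descriptor) {
  if (!descriptor %in% names(kb$descriptors)) {
    stop(sprintf("unknown descriptor id '%s'", descriptor), call. = FALSE)
  }
}

# resolve a taxon given either an id or a name
resolve_taxon <- function(kb, taxon) {
  if (taxon %in% names(kb$taxa)) return(taxon)
  hit <- names(kb$taxa)[vapply(kb$taxa, function(t) t$name == taxon, NA)]
  if (length(hit) == 1L) return(hit)
  stop(sprintf("unknown taxon '%s'", taxon), call. = FALSE)
}

descriptor_state_ids <- function(d) names(d$states) %||% character()
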