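#' The classical-terminology mapping
#'
#' The classical vocabulary of archaeocyathan walls packs several notions
#' into single terms ("cambroid pores" says shape *and* distribution *and*
#' arrangement). The standardized registry stores one notion per
#' descriptor, so every classical term expands into a set of
#' descriptor-state assignments; this table is that expansion, one row per
#' shipped term.
#'
#' Each entry carries:
#' * `term` and `aliases` — matched case-insensitively;
#' * `context` — `outer`, `inner`, `intervallum` or `any`: the wall (or
#'   region) the term can describe;
#' * `assignments` — descriptor id, state set and the context each
#'   assignment belongs to;
#' * `triggers` — descriptors whose detailed description becomes relevant
#'   once the term applies (the "dependent characters" of the classical
#'   table), without being fixed by the term itself;
#' * `confidence` — `"low"` where the classical sources do not pin the
#'   row down precisely; such rows are kept for coverage but flagged;
#' * `note` — e.g. that a term is redundant once decomposed (tumuli,
#'   pustulae, cambroid/anthoid pores).
#'
#' @return A named list of term entries.
#' @seealso [expand_term()], [match_terms()]
#' @export
term_registry <- function() {
  cached <- get0("term_registry_cache", envir = .morphokey_env)
  if (!is.null(cached)) return(cached)

  a <- function(descriptor, states, context) {
    list(descriptor = descriptor, states = sort(unique(as.character(states))),
         context = context)
  }
  entry <- function(term, context, assignments, aliases = character(),
                    triggers = character(), confidence = "normal", note = NULL) {
    list(term = term, aliases = aliases, context = context,
         assignments = assignments, triggers = triggers,
         confidence = confidence, note = note)
  }

  terms <- list(
    entry("rudimentary wall", "any",
          aliases = "rudimentary perforate wall",
          list(a("d6", "rudimentary", "outer"), a("d7", "rudimentary", "inner"),
               a("d12", "irregular", "outer"), a("d32", "irregular", "inner"),
               a("d15", "irregular", "outer"),
               a("d17", "one_row", "outer"), a("d33", "one_row", "inner")),
          note = "carcass not well defined: tips of intervallar structures serve as carcass"),
    entry("basic wall", "any",
          list(a("d6", "basic", "outer"), a("d7", "basic", "inner"),
               a("d12", "irregular", "outer"), a("d32", "irregular", "inner"),
               a("d15", "irregular", "outer"),
               a("d17", "two_or_more", "outer"), a("d33", "two_or_more", "inner")),
          note = "carcass well defined: intervallar tips plus additional lintels"),
    entry("simple wall", "any",
          list(a("d6", "simple", "outer"), a("d7", "simple", "inner"),
               a("d11", "pores", "outer"), a("d31", "pores", "inner"),
               a("d22", "none", "outer"), a("d25", "none", "outer"),
               a("d28", "none", "outer"), a("d52", "absent", "outer"))),
    entry("concentrical wall", "any",
          list(a("d6", "concentrical", "outer"), a("d7", "concentrical", "inner")),
          confidence = "low"),
    entry("wall with canals", "any",
          list(a("d11", "canals", "outer"), a("d31", "canals", "inner")),
          triggers = c("d18", "d19"), confidence = "low"),
    entry("wall with simple tumuli", "outer",
          list(a("d22", "present", "outer"), a("d23", "simple", "outer"),
               a("d24", "downward", "outer")),
          triggers = c("d23", "d24")),
    entry("wall with multiperforate tumuli", "outer",
          list(a("d22", "present", "outer"), a("d23", "multiperforate", "outer"),
               a("d24", "downward", "outer")),
          triggers = c("d23", "d24")),
    entry("pustular wall", "outer",
          list(a("d22", "present", "outer"), a("d23", "simple", "outer"),
               a("d24", "central", "outer")),
          triggers = c("d23", "d24")),
    entry("wall with bracts, scales or poretubes", "outer",
          list(a("d25", "present", "outer"),
               a("d26", c("bracts", "scales"), "outer")),
          triggers = c("d26", "d27", "d28"), confidence = "low"),
    entry("wall with annuli", "any",
          list(a("d25", "present", "outer"), a("d26", "annuli", "outer"),
               a("d45", "present", "inner"), a("d46", "annuli", "inner")),
          triggers = "d49", confidence = "low"),
    entry("compound wall", "any",
          list(a("d52", "present", "outer")),
          triggers = paste0("d", 53:63), confidence = "low",
          note = "additional sheath present; carcass and sheath described separately"),
    entry("wall with microporous sheath", "any",
          list(a("d52", "present", "outer"),
               a("d53", "microporous_sheath", "outer"))),
    entry("tellelar wall", "any",
          list(a("d52", "present", "outer"), a("d53", "mesh", "outer"),
               a("d61", "tabellae", "outer")), confidence = "low"),
    entry("clathrate wall", "any",
          list(a("d52", "present", "outer"), a("d53", "mesh", "outer"),
               a("d61", "clathri", "outer")), confidence = "low"),
    entry("pseudoclathrate wall", "any",
          aliases = "pseudoclathate wall",
          list(a("d52", "present", "outer"), a("d53", "mesh", "outer"),
               a("d61", "pseudoclathri", "outer")), confidence = "low"),
    entry("tabular wall", "any",
          list(a("d79", "present", "intervallum"),
               a("d80", c("outer_wall_derived", "inner_wall_derived",
                          "both_walls_derived"), "intervallum")),
          triggers = c("d80", "d81"),
          note = "cross-reference: tabular walls are tabulae extending a wall, not a wall-local structure"),
    entry("simple tabular outer wall", "outer",
          list(a("d52", "absent", "outer"), a("d11", "pores", "outer"),
               a("d12", "simple", "outer"),
               a("d79", "present", "intervallum"),
               a("d80", "outer_wall_derived", "intervallum"))),
    entry("cambroid pores", "outer",
          list(a("d12", c("simple", "polygonal"), "outer"),
               a("d15", "regular", "outer"), a("d16", "random", "outer")),
          note = "redundant once decomposed into shape, distribution and arrangement"),
    entry("anthoid pores", "outer",
          list(a("d12", "polygonal", "outer"), a("d15", "irregular", "outer")),
          note = "redundant once decomposed into shape and distribution"),
    entry("pseudotaeniae", "intervallum",
          list(a("d65", "taeniae", "intervallum"),
               a("d66", "taeniae", "intervallum"),
               a("d70", "synapticulae", "intervallum"),
               a("d71", "each_interpore_node", "intervallum")),
          note = "taeniae with synapticulae at each interpore node"),
    entry("non porous canals", "any",
          aliases = "non-communicating canals",
          list(a("d11", "canals", "outer"), a("d18", "non_porous", "outer"))),
    entry("porous canals", "any",
          aliases = "simple communicating canals",
          list(a("d11", "canals", "outer"), a("d18", "porous", "outer"))),
    entry("spongiose canals", "any",
          aliases = "anastomosing canals",
          list(a("d11", "canals", "outer"), a("d18", "spongiose", "outer"))),
    entry("curved canals", "any",
          aliases = "sub-spherical chambered canals",
          list(a("d11", "canals", "outer"), a("d19", "curved", "outer"))),
    entry("tumuli", "outer",
          list(a("d22", "present", "outer"), a("d24", "downward", "outer")),
          triggers = c("d23", "d24"),
          note = "redundant: a bump with its opening directed downward"),
    entry("pustulae", "outer",
          list(a("d22", "present", "outer"), a("d24", "central", "outer")),
          triggers = c("d23", "d24"),
          note = "redundant: a bump with a central opening"),
    entry("imperforate wall", "any",
          list(a("d11", "none", "outer"), a("d31", "none", "inner")),
          note = "carcass well defined, without perforations"),
    entry("spines", "outer",
          list(a("d25", "present", "outer"), a("d26", "spines", "outer"))),
    entry("protrusions", "any",
          list(a("d52", "present", "outer"), a("d53", "sieve", "outer")),
          note = "skeletal elements subdividing pores to form an additional sheath")
  )
  names(terms) <- vapply(terms, `[[`, "", "term")
  assign("term_registry_cache", terms, envir = .morphokey_env)
  terms
}

.morphokey_env <- new.env(parent = emptyenv())

#' Expand a classical term into descriptor-state assignments
#'
#' Looks a classical term up (case-insensitively, aliases included) and
#' returns its assignments, restricted to the requested wall context.
#' Applying the assignments of any shipped term to a blank description
#' yields a validator-clean partial description.
#'
#' @param term classical term, e.g. `"cambroid pores"`.
#' @param context `"any"` (default), `"outer"`, `"inner"` or
#'   `"intervallum"`; `"outer"`/`"inner"` keep wall-specific assignments
#'   for that wall plus region-neutral ones.
#' @return A list with `term`, `context`, `assignments` (named list:
#'   descriptor id to character vector of state ids), `triggers`,
#'   `confidence` and `note`.
#' @examples
#' expand_term("cambroid pores", context = "outer")$assignments
#' @export
expand_term <- function(term, context = c("any", "outer", "inner", "intervallum")) {
  context <- match.arg(context)
  terms <- term_registry()
  key <- tolower(trimws(term))
  hit <- NULL
  for (e in terms) {
    if (key %in% tolower(c(e$term, e$aliases))) { hit <- e; break }
  }
  if (is.null(hit)) {
    known <- names(terms)
    near <- known[utils::adist(key, tolower(known), partial = TRUE) <= 3]
    if (length(near) == 0L) near <- utils::head(known, 5L)
    stop(sprintf("unknown term '%s'; nearest known terms: %s", term,
                 paste(near, collapse = ", ")), call. = FALSE)
  }
  keep <- switch(context,
    any = hit$assignments,
    # a wall context keeps that wall's assignments plus region-neutral and
    # intervallum cross-references (e.g. the tabulae behind tabular walls)
    outer = ,
    inner = Filter(function(x) x$context %in% c(context, "intervallum", "any"),
                   hit$assignments),
    intervallum = Filter(function(x) x$context %in% c("intervallum", "any"),
                         hit$assignments)
  )
  assignments <- stats::setNames(lapply(keep, `[[`, "states"),
                                 vapply(keep, `[[`, "", "descriptor"))
  list(term = hit$term, context = context, assignments = assignments,
       triggers = hit$triggers, confidence = hit$confidence, note = hit$note)
}

#' Apply a term expansion to a (partial) description
#'
#' Turns the assignments of [expand_term()] into codings, merged over an
#' existing partial description if given (term states are intersected
#' with states already present; disjoint constraints raise an error).
#'
#' @param expansion result of [expand_term()].
#' @param description optional named list of codings to merge into.
#' @return A named list of codings (a partial description).
#' @export
apply_expansion <- function(expansion, description = list()) {
  for (d in names(expansion$assignments)) {
    states <- expansion$assignments[[d]]
    prev <- description[[d]]
    if (!is.null(prev) && coding_type(prev) == "states") {
      states <- intersect(prev$states, states)
      if (length(states) == 0L) {
        stop(sprintf("term '%s' conflicts with the description on %s",
                     expansion$term, d), call. = FALSE)
      }
    }
    description[[d]] <- coding_states(states)
  }
  description
}

#' Which classical terms match a description?
#'
#' The reverse direction of the terminology mapping: a term is listed when
#' every one of its assignments (in the requested context) is compatible
#' with the description's codings — unknown cells are compatible with
#' everything, so a blank description matches every term.
#'
#' @param description a named list of codings (descriptor id to [coding]),
#'   or a knowledge base together with `taxon`.
#' @param context as in [expand_term()].
#' @param taxon when `description` is a knowledge base: the taxon whose
#'   description to match.
#' @return A data frame with columns `term`, `context`, `confidence`.
#' @examples
#' kb <- build_fixture()
#' match_terms(kb, taxon = "Agastrocyathus")   # includes "cambroid pores"
#' @export
match_terms <- function(description, context = c("any", "outer", "inner",
                                                 "intervallum"),
                        taxon = NULL) {
  context <- match.arg(context)
  if (inherits(description, "morphokey_kb")) {
    if (is.null(taxon)) stop("give a taxon when matching a knowledge base",
                             call. = FALSE)
    tid <- resolve_taxon(description, taxon)
    description <- description$descriptions[[tid]]
  }
  terms <- term_registry()
  rows <- list()
  for (e in terms) {
    exp <- expand_term(e$term, context)
    ok <- TRUE
    for (d in names(exp$assignments)) {
      cd <- description[[d]] %||% coding_unknown()
      if (coding_type(cd) == "unknown") next
      if (coding_type(cd) != "states" ||
          length(intersect(cd$states, exp$assignments[[d]])) == 0L) {
        ok <- FALSE
        break
      }
    }
    if (ok && length(exp$assignments)) {
      rows[[length(rows) + 1L]] <- data.frame(
        term = e$term, context = context, confidence = e$confidence,
        stringsAsFactors = FALSE)
    }
  }
  if (length(rows) == 0L) {
    return(data.frame(term = character(), context = character(),
                      confidence = character(), stringsAsFactors = FALSE))
  }
  do.call(rbind, rows)
}
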