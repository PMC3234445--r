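#' Cell codings
#'
#' A coding is the value recorded for one taxon on one descriptor. Four kinds
#' exist: a non-empty set of state ids (more than one state = polymorphism),
#' a closed numeric interval (numeric descriptors only), *unknown* (the cell
#' has not been described, the default for missing entries), and
#' *inapplicable* (the structure the descriptor refers to is absent, e.g.
#' bump shape for a taxon without bumps).
#'
#' @param states character vector of state ids; must be non-empty.
#' @param min,max interval bounds, `min <= max`.
#' @return An object of class `mk_coding`.
#' @examples
#' coding_states("simple", "polygonal")
#' coding_interval(0.1, 0.4)
#' coding_unknown()
#' coding_inapplicable()
#' @name coding
NULL

#' @rdname coding
#' @export
coding_states <- function(...) {
  states <- unique(as.character(c(...)))
  if (length(states) == 0L || any(is.na(states)) || any(!nzchar(states))) {
    stop("a state-set coding needs at least one non-empty state id", call. = FALSE)
  }
  structure(list(type = "states", states = sort(states)), class = "mk_coding")
}

#' @rdname coding
#' @export
coding_interval <- function(min, max = min) {
  min <- as.numeric(min); max <- as.numeric(max)
  if (length(min) != 1L || length(max) != 1L || is.na(min) || is.na(max) || min > max) {
    stop("interval coding needs numeric scalars with min <= max", call. = FALSE)
  }
  structure(list(type = "interval", min = min, max = max), class = "mk_coding")
}

#' @rdname coding
#' @export
coding_unknown <- function() {
  structure(list(type = "unknown"), class = "mk_coding")
}

#' @rdname coding
#' @export
coding_inapplicable <- function() {
  structure(list(type = "inapplicable"), class = "mk_coding")
}

#' @rdname coding
#' @param x object to test.
#' @export
is_coding <- function(x) inherits(x, "mk_coding")

coding_type <- function(x) {
  if (!is_coding(x)) stop("not a coding", call. = FALSE)
  x$type
}

#' Is a coding described?
#'
#' Described means the describer committed to a value: a state set, an
#' interval, or an explicit *inapplicable*. Unknown cells are not described.
#'
#' @param coding an [coding] object.
#' @return `TRUE` or `FALSE`.
#' @export
is_described <- function(coding) {
  coding_type(coding) %in% c("states", "interval", "inapplicable")
}

#' @export
print.mk_coding <- function(x, ...) {
  cat(format(x), "\n")
  invisible(x)
}

#' @export
format.mk_coding <- function(x, ...) {
  switch(x$type,
    states = paste(x$states, collapse = "/"),
    interval = sprintf("[%g..%g]", x$min, x$max),
    unknown = "?",
    inapplicable = "-"
  )
}

#' @export
`==.mk_coding` <- function(e1, e2) coding_equal(e1, e2)

coding_equal <- function(a, b) {
  if (a$type != b$type) return(FALSE)
  switch(a$type,
    states = identical(a$states, b$states),
    interval = isTRUE(a$min == b$min && a$max == b$max),
    TRUE
  )
}

# Disjointness of two *described, non-inapplicable* codings of the same kind.
codings_disjoint <- function(a, b) {
  if (a$type == "states" && b$type == "states") {
    return(length(intersect(a$states, b$states)) == 0L)
  }
  if (a$type == "interval" && b$type == "interval") {
    return(a$max < b$min || b$max < a$min)
  }
  stop("cannot compare a state-set coding with an interval coding", call. = FALSE)
}
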