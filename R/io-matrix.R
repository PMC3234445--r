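#' Import and export the CSV character-matrix dialect
#'
#' The matrix dialect is a taxa-by-descriptors CSV with two header rows:
#' the first carries descriptor ids (first cell `taxon`), the second the
#' group id of each descriptor (first cell `group`). Each remaining row is
#' one taxon. Cell grammar:
#'
#' * `a/b` — state ids separated by `/` (polymorphism),
#' * `?` or an empty cell — unknown,
#' * `-` — inapplicable,
#' * `[lo..hi]` — a numeric interval.
#'
#' Cells use state ids, not positional indices, so the matrix survives
#' state reordering. `import_matrix()` needs a descriptor registry (any
#' knowledge base over the same descriptors, e.g. [archaeo_registry()]
#' wrapped in [new_kb()], or a base read with [read_kb()]); taxa present
#' in the registry KB are ignored — only its descriptor definitions are
#' used. The round trip `import_matrix(export_matrix(kb))` reproduces
#' `kb`'s descriptions exactly.
#'
#' @param path CSV file path.
#' @param registry a knowledge base supplying groups, descriptors and
#'   dependencies.
#' @return `import_matrix()` returns a knowledge base with the registry's
#'   descriptor model and the file's taxa; `export_matrix()` returns
#'   `path` invisibly.
#' @export
import_matrix <- function(path, registry) {
  if (!file.exists(path)) {
    stop(sprintf("matrix file not found: %s", path), call. = FALSE)
  }
  rows <- utils::read.csv(path, header = FALSE, colClasses = "character",
                          check.names = FALSE, fileEncoding = "UTF-8")
  if (nrow(rows) < 2L) {
    stop("matrix needs a descriptor header row and a group header row",
         call. = FALSE)
  }
  header <- as.character(rows[1L, ])
  if (header[[1L]] != "taxon") {
    stop("first header cell must be 'taxon'", call. = FALSE)
  }
  desc_ids <- header[-1L]
  unknown_ids <- setdiff(desc_ids, names(registry$descriptors))
  if (length(unknown_ids)) {
    stop(sprintf("matrix columns not in the registry: %s",
                 paste(unknown_ids, collapse = ", ")), call. = FALSE)
  }
  body_start <- if (as.character(rows[2L, 1L]) == "group") 3L else 2L

  taxa <- list()
  descriptions <- list()
  for (i in seq(body_start, nrow(rows))) {
    tid <- as.character(rows[i, 1L])
    if (!nzchar(tid)) next
    codings <- list()
    for (j in seq_along(desc_ids)) {
      cell <- as.character(rows[i, j + 1L])
      coding <- parse_matrix_cell(cell, registry$descriptors[[desc_ids[[j]]]],
                                  row = i, column = desc_ids[[j]])
      if (!is.null(coding)) codings[[desc_ids[[j]]]] <- coding
    }
    taxa[[length(taxa) + 1L]] <- mk_taxon(tid)
    descriptions[[tid]] <- codings
  }
  new_kb(metadata = list(name = basename(path)),
         groups = registry$groups, descriptors = registry$descriptors,
         dependencies = registry$dependencies,
         taxa = taxa, descriptions = descriptions)
}

parse_matrix_cell <- function(cell, descriptor, row, column) {
  cell <- trimws(cell)
  if (cell == "" || cell == "?") return(NULL)  # unknown
  if (cell == "-") return(coding_inapplicable())
  if (grepl("^\\[.*\\.\\..*\\]$", cell)) {
    if (descriptor$kind != "numeric") {
      stop(sprintf("row %d, column %s: interval cell on a categorical descriptor",
                   row, column), call. = FALSE)
    }
    bounds <- strsplit(sub("^\\[(.*)\\]$", "\\1", cell), "..", fixed = TRUE)[[1L]]
    lo <- suppressWarnings(as.numeric(bounds[[1L]]))
    hi <- suppressWarnings(as.numeric(bounds[[2L]]))
    if (is.na(lo) || is.na(hi)) {
      stop(sprintf("row %d, column %s: cannot parse interval '%s'",
                   row, column, cell), call. = FALSE)
    }
    return(coding_interval(lo, hi))
  }
  states <- strsplit(cell, "/", fixed = TRUE)[[1L]]
  bad <- setdiff(states, descriptor_state_ids(descriptor))
  if (length(bad)) {
    stop(sprintf("row %d, column %s: states not defined by descriptor: %s",
                 row, column, paste(bad, collapse = ", ")), call. = FALSE)
  }
  coding_states(states)
}

#' @rdname import_matrix
#' @param kb a knowledge base to export.
#' @export
export_matrix <- function(kb, path) {
  desc_ids <- names(kb$descriptors)
  groups <- vapply(kb$descriptors, function(d) d$group %||% "", "")
  lines <- c(
    paste(c("taxon", desc_ids), collapse = ","),
    paste(c("group", groups), collapse = ",")
  )
  for (tid in names(kb$taxa)) {
    cells <- vapply(desc_ids, function(d) {
      format_matrix_cell(kb$descriptions[[tid]][[d]] %||% coding_unknown())
    }, "")
    lines <- c(lines, paste(c(tid, cells), collapse = ","))
  }
  writeLines(lines, path, useBytes = TRUE)
  invisible(path)
}

format_matrix_cell <- function(coding) {
  switch(coding_type(coding),
    states = paste(coding$states, collapse = "/"),
    interval = sprintf("[%.15g..%.15g]", coding$min, coding$max),
    unknown = "?",
    inapplicable = "-"
  )
}
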