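#' Export one detailed sheet per taxon
#'
#' Writes a human-readable form for every taxon: name, classification
#' path, the described descriptors grouped as in the knowledge base (with
#' state labels), and a closing section listing the taxon's special
#' features (states recorded for no other taxon). Output is a pure
#' function of the knowledge base — no timestamps — so re-exporting the
#' same base yields byte-identical files.
#'
#' @param kb a knowledge base.
#' @param out_dir output directory (created if needed).
#' @param format `"markdown"` or `"html"`.
#' @return Invisibly, the paths written (one file per taxon).
#' @export
export_sheets <- function(kb, out_dir, format = c("markdown", "html")) {
  format <- match.arg(format)
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  sf <- if (length(kb$taxa) >= 2L) special_features(kb) else
    data.frame(taxon = character(), descriptor = character(),
               state = character(), n_unknown_others = integer())
  ext <- if (format == "markdown") ".md" else ".html"
  paths <- vapply(names(kb$taxa), function(tid) {
    path <- file.path(out_dir, paste0(slugify(tid), ext))
    lines <- taxon_sheet(kb, tid, sf[sf$taxon == tid, , drop = FALSE])
    if (format == "html") lines <- sheet_to_html(lines)
    writeLines(lines, path, useBytes = TRUE)
    path
  }, "")
  invisible(unname(paths))
}

slugify <- function(x) {
  x <- gsub("[^A-Za-z0-9._-]+", "_", x)
  gsub("^_+|_+$", "", x)
}

# markdown body of one sheet
taxon_sheet <- function(kb, tid, features) {
  taxon <- kb$taxa[[tid]]
  lines <- c(sprintf("# %s", taxon$name), "")
  if (nrow(taxon$classification)) {
    lines <- c(lines, "## Classification", "",
               sprintf("- %s: %s", taxon$classification$rank,
                       taxon$classification$name), "")
  }
  codings <- kb$descriptions[[tid]]
  described <- names(codings)[vapply(codings, is_described, NA)]
  for (g in names(kb$groups)) {
    in_group <- Filter(function(d) identical(kb$descriptors[[d]]$group, g),
                       described)
    if (length(in_group) == 0L) next
    lines <- c(lines, sprintf("## %s", kb$groups[[g]]$label), "")
    for (d in in_group) {
      desc <- kb$descriptors[[d]]
      flag <- if (!desc$taxonomic_value) " *(no taxonomic value)*" else ""
      lines <- c(lines, sprintf("- %s (%s): %s%s", desc$label, d,
                                format_cell_labels(codings[[d]], desc), flag))
    }
    lines <- c(lines, "")
  }
  if (nrow(features)) {
    lines <- c(lines, "## Special features", "",
               vapply(seq_len(nrow(features)), function(i) {
                 d <- kb$descriptors[[features$descriptor[[i]]]]
                 sprintf("- %s (%s): %s — recorded in no other taxon", d$label,
                         features$descriptor[[i]],
                         state_label(d, features$state[[i]]))
               }, ""), "")
  }
  lines
}

state_label <- function(descriptor, state_id) {
  s <- descriptor$states[[state_id]]
  if (is.null(s)) state_id else s$label
}

format_cell_labels <- function(coding, descriptor) {
  switch(coding_type(coding),
    states = paste(vapply(coding$states, function(s) state_label(descriptor, s), ""),
                   collapse = " / "),
    interval = sprintf("%g to %g %s", coding$min, coding$max,
                       descriptor$unit %||% ""),
    unknown = "unknown",
    inapplicable = "not applicable"
  )
}

# minimal, dependency-free markdown -> html for the sheet subset we emit
sheet_to_html <- function(lines) {
  esc <- function(x) {
    x <- gsub("&", "&amp;", x, fixed = TRUE)
    x <- gsub("<", "&lt;", x, fixed = TRUE)
    gsub(">", "&gt;", x, fixed = TRUE)
  }
  body <- character()
  in_list <- FALSE
  close_list <- function() {
    if (in_list) { body <<- c(body, "</ul>"); in_list <<- FALSE }
  }
  for (ln in lines) {
    if (grepl("^# ", ln)) {
      close_list(); body <- c(body, sprintf("<h1>%s</h1>", esc(sub("^# ", "", ln))))
    } else if (grepl("^## ", ln)) {
      close_list(); body <- c(body, sprintf("<h2>%s</h2>", esc(sub("^## ", "", ln))))
    } else if (grepl("^- ", ln)) {
      if (!in_list) { body <- c(body, "<ul>"); in_list <- TRUE }
      item <- esc(sub("^- ", "", ln))
      item <- gsub("\\*\\(([^)]*)\\)\\*", "<em>(\\1)</em>", item)
      body <- c(body, sprintf("<li>%s</li>", item))
    } else if (nzchar(ln)) {
      close_list(); body <- c(body, sprintf("<p>%s</p>", esc(ln)))
    }
  }
  close_list()
  c("<!DOCTYPE html>", "<html><head><meta charset=\"utf-8\"/></head><body>",
    body, "</body></html>")
}

#' Export a comparative table as HTML
#'
#' Renders the output of [comparative_table()] with the three-way
#' highlighting used to eyeball shared and separating characters: rows are
#' coloured by flag (`same`, `partial`, `different`); rows with fewer than
#' two described codings are greyed out.
#'
#' @param ct an object from [comparative_table()].
#' @param kb the knowledge base the table was built from (for labels).
#' @param path output file.
#' @return `path`, invisibly.
#' @export
export_comparative_html <- function(ct, kb, path) {
  esc <- function(x) {
    x <- gsub("&", "&amp;", x, fixed = TRUE)
    x <- gsub("<", "&lt;", x, fixed = TRUE)
    gsub(">", "&gt;", x, fixed = TRUE)
  }
  colours <- c(same = "#d8f0d8", partial = "#fdf3cf", different = "#f5cccc",
               not_comparable = "#eeeeee")
  head_cells <- c("descriptor", vapply(ct$taxa, function(t) kb$taxa[[t]]$name, ""))
  rows <- vapply(seq_len(nrow(ct$table)), function(i) {
    r <- ct$table[i, , drop = FALSE]
    label <- kb$descriptors[[r$descriptor]]$label
    cells <- vapply(ct$taxa, function(t) esc(r[[t]]), "")
    sprintf("<tr style=\"background:%s\"><td>%s (%s)</td>%s</tr>",
            colours[[r$flag]], esc(label), r$descriptor,
            paste(sprintf("<td>%s</td>", cells), collapse = ""))
  }, "")
  html <- c(
    "<!DOCTYPE html>",
    "<html><head><meta charset=\"utf-8\"/><style>",
    "table{border-collapse:collapse}td,th{border:1px solid #999;padding:2px 6px}",
    "</style></head><body>",
    "<table>",
    sprintf("<tr>%s</tr>",
            paste(sprintf("<th>%s</th>", esc(head_cells)), collapse = "")),
    rows,
    "</table></body></html>"
  )
  writeLines(html, path, useBytes = TRUE)
  invisible(path)
}
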