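#' Read and write the JSON interchange format
#'
#' Knowledge bases are exchanged as a versioned JSON document
#' (`"morphokey-kb/1"`); the corresponding JSON Schema ships with the
#' package (`system.file("schema", "morphokey-kb-1.schema.json", package =
#' "morphokey")`). `read_kb()` checks the document against the format's
#' structural rules before returning and reports the JSON path of the
#' first offending element; `write_kb()` followed by `read_kb()` is the
#' identity up to key ordering. Unknown cells are omitted on disk.
#'
#' Cell encoding: a state set as `{"states": [...]}`, an interval as
#' `{"interval": [lo, hi]}`, unknown as `"?"`, inapplicable as `"-"`.
#'
#' @param path file path.
#' @param kb a knowledge base.
#' @return `read_kb()` returns a knowledge base; `write_kb()` returns
#'   `path` invisibly.
#' @export
read_kb <- function(path) {
  if (!file.exists(path)) {
    stop(sprintf("knowledge base file not found: %s", path), call. = FALSE)
  }
  doc <- jsonlite::fromJSON(path, simplifyVector = FALSE)
  parse_kb_document(doc)
}

KB_FORMAT <- "morphokey-kb/1"

parse_kb_document <- function(doc) {
  fail <- function(jpath, msg) {
    stop(sprintf("invalid knowledge base at %s: %s", jpath, msg), call. = FALSE)
  }
  if (!is.list(doc)) fail("$", "top level must be an object")
  if (!identical(doc$format, KB_FORMAT)) {
    fail("$.format", sprintf("expected \"%s\", got \"%s\"", KB_FORMAT,
                             if (is.null(doc$format)) "<missing>" else doc$format))
  }
  need_string <- function(x, jpath) {
    if (!is.character(x) || length(x) != 1L || !nzchar(x)) {
      fail(jpath, "expected a non-empty string")
    }
    x
  }

  groups <- lapply(seq_along(doc$groups), function(i) {
    g <- doc$groups[[i]]
    jp <- sprintf("$.groups[%d]", i)
    mk_group(need_string(g$id, paste0(jp, ".id")), g$label %||% g$id)
  })
  group_ids <- vapply(groups, `[[`, "", "id")

  descriptors <- lapply(seq_along(doc$descriptors), function(i) {
    d <- doc$descriptors[[i]]
    jp <- sprintf("$.descriptors[%d]", i)
    id <- need_string(d$id, paste0(jp, ".id"))
    kind <- d$kind %||% "categorical"
    if (!kind %in% c("categorical", "numeric")) {
      fail(paste0(jp, ".kind"), "must be \"categorical\" or \"numeric\"")
    }
    states <- lapply(seq_along(d$states), function(k) {
      s <- d$states[[k]]
      sp <- sprintf("%s.states[%d]", jp, k)
      if (is.character(s)) return(mk_state(s))
      mk_state(need_string(s$id, paste0(sp, ".id")), s$label %||% s$id,
               s$definition)
    })
    if (!is.null(d$group) && !d$group %in% group_ids) {
      fail(paste0(jp, ".group"), sprintf("unknown group '%s'", d$group))
    }
    tryCatch(
      mk_descriptor(id, d$label %||% id, kind, states = states,
                    unit = d$unit, group = d$group,
                    taxonomic_value = d$taxonomic_value %||% TRUE),
      error = function(e) fail(jp, conditionMessage(e)))
  })
  desc_ids <- vapply(descriptors, `[[`, "", "id")
  names(descriptors) <- desc_ids

  dependencies <- lapply(seq_along(doc$dependencies), function(i) {
    r <- doc$dependencies[[i]]
    jp <- sprintf("$.dependencies[%d]", i)
    child <- need_string(r$child, paste0(jp, ".child"))
    parent <- need_string(r$parent, paste0(jp, ".parent"))
    if (!child %in% desc_ids) fail(paste0(jp, ".child"), "unknown descriptor")
    if (!parent %in% desc_ids) fail(paste0(jp, ".parent"), "unknown descriptor")
    enabling <- unlist(r$enabling_states)
    bad <- setdiff(enabling, descriptor_state_ids(descriptors[[parent]]))
    if (length(bad)) {
      fail(paste0(jp, ".enabling_states"),
           sprintf("states not defined by parent '%s': %s", parent,
                   paste(bad, collapse = ", ")))
    }
    tryCatch(mk_dependency(child, parent, enabling),
             error = function(e) fail(jp, conditionMessage(e)))
  })

  taxa <- lapply(seq_along(doc$taxa), function(i) {
    t <- doc$taxa[[i]]
    jp <- sprintf("$.taxa[%d]", i)
    id <- need_string(t$id, paste0(jp, ".id"))
    cls <- NULL
    if (!is.null(t$classification)) {
      cls <- data.frame(
        rank = vapply(t$classification, function(p) p$rank %||% "", ""),
        name = vapply(t$classification, function(p) p$name %||% "", ""),
        stringsAsFactors = FALSE)
    }
    mk_taxon(id, t$name %||% id, cls, t$notes)
  })
  taxon_ids <- vapply(taxa, `[[`, "", "id")

  descriptions <- list()
  for (tid in names(doc$descriptions %||% list())) {
    if (!tid %in% taxon_ids) {
      fail(sprintf("$.descriptions.%s", tid), "unknown taxon id")
    }
    cells <- doc$descriptions[[tid]]
    parsed <- list()
    for (did in names(cells)) {
      jp <- sprintf("$.descriptions.%s.%s", tid, did)
      if (!did %in% desc_ids) fail(jp, "unknown descriptor id")
      parsed[[did]] <- parse_cell_json(cells[[did]], descriptors[[did]], jp, fail)
    }
    descriptions[[tid]] <- parsed
  }

  new_kb(metadata = doc$metadata %||% list(), groups = groups,
         descriptors = descriptors, dependencies = dependencies,
         taxa = taxa, descriptions = descriptions)
}

parse_cell_json <- function(cell, descriptor, jpath, fail) {
  if (is.character(cell) && length(cell) == 1L) {
    if (cell == "?") return(coding_unknown())
    if (cell == "-") return(coding_inapplicable())
    fail(jpath, sprintf("unexpected cell string \"%s\"", cell))
  }
  if (is.list(cell) && !is.null(cell$states)) {
    states <- unlist(cell$states)
    bad <- setdiff(states, descriptor_state_ids(descriptor))
    if (length(bad)) {
      fail(jpath, sprintf("states not defined by descriptor '%s': %s",
                          descriptor$id, paste(bad, collapse = ", ")))
    }
    return(coding_states(states))
  }
  if (is.list(cell) && !is.null(cell$interval)) {
    iv <- unlist(cell$interval)
    if (length(iv) != 2L || !is.numeric(iv)) {
      fail(jpath, "interval must be [lo, hi]")
    }
    if (descriptor$kind != "numeric") {
      fail(jpath, "interval coded on a categorical descriptor")
    }
    return(coding_interval(iv[[1]], iv[[2]]))
  }
  fail(jpath, "cell must be \"?\", \"-\", {\"states\": ...} or {\"interval\": ...}")
}

#' @rdname read_kb
#' @export
write_kb <- function(kb, path) {
  doc <- list(
    format = KB_FORMAT,
    metadata = kb$metadata,
    groups = lapply(unname(kb$groups), function(g) g[!vapply(g, is.null, NA)]),
    descriptors = lapply(unname(kb$descriptors), function(d) {
      out <- list(id = d$id, label = d$label, kind = d$kind)
      if (d$kind == "categorical") {
        out$states <- lapply(unname(d$states), function(s) {
          s[!vapply(s, is.null, NA)]
        })
      }
      if (!is.null(d$unit)) out$unit <- d$unit
      if (!is.null(d$group)) out$group <- d$group
      out$taxonomic_value <- d$taxonomic_value
      out
    }),
    dependencies = lapply(unname(kb$dependencies), function(r) {
      list(child = r$child, parent = r$parent,
           enabling_states = as.list(r$enabling_states))
    }),
    taxa = lapply(unname(kb$taxa), function(t) {
      out <- list(id = t$id, name = t$name)
      if (nrow(t$classification)) {
        out$classification <- lapply(seq_len(nrow(t$classification)), function(i) {
          list(rank = t$classification$rank[[i]],
               name = t$classification$name[[i]])
        })
      }
      if (!is.null(t$notes)) out$notes <- t$notes
      out
    }),
    descriptions = lapply(kb$descriptions, function(codings) {
      cells <- lapply(codings, cell_to_json)
      cells[!vapply(cells, is.null, NA)]
    })
  )
  json <- jsonlite::toJSON(doc, auto_unbox = TRUE, pretty = TRUE, digits = NA)
  writeLines(json, path, useBytes = TRUE)
  invisible(path)
}

cell_to_json <- function(coding) {
  switch(coding_type(coding),
    states = list(states = as.list(coding$states)),
    interval = list(interval = list(coding$min, coding$max)),
    unknown = NULL,  # omitted on disk; missing means unknown
    inapplicable = "-"
  )
}
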