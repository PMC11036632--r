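#' Construct a text span
#'
#' A verbatim span of a document, the textual kind of slot filler. Character
#' offsets are 0-based half-open; token indices are 1-based inclusive (the
#' convention of the start/end tagging scheme). `text` must equal the covered
#' substring when `full_text` is supplied.
#'
#' @param doc_id document identifier.
#' @param char_start,char_end 0-based half-open character offsets.
#' @param token_start,token_end 1-based inclusive token indices (may be `NA`
#'   for spans not yet aligned to tokens).
#' @param text the covered string.
#' @param full_text optional document text used to verify `text`.
#' @return an object of class `pico_span`.
#' @export
text_span <- function(doc_id, char_start, char_end, text,
                      token_start = NA_integer_, token_end = NA_integer_,
                      full_text = NULL) {
  if (char_end < char_start) stop("char_end < char_start")
  if (!is.na(token_start) && !is.na(token_end) && token_end < token_start) {
    stop("token_end < token_start")
  }
  if (!is.null(full_text)) {
    covered <- substr(full_text, char_start + 1L, char_end)
    if (!identical(covered, text)) {
      stop("span text '", text, "' does not match document substring '",
           covered, "'")
    }
  }
  structure(list(doc_id = doc_id,
                 char_start = as.integer(char_start),
                 char_end = as.integer(char_end),
                 token_start = as.integer(token_start),
                 token_end = as.integer(token_end),
                 text = text),
            class = "pico_span")
}

is_span <- function(x) inherits(x, "pico_span")

#' @export
print.pico_span <- function(x, ...) {
  cat(sprintf("<pico_span> \"%s\" chars [%d,%d) tokens [%s,%s]\n",
              x$text, x$char_start, x$char_end,
              x$token_start, x$token_end))
  invisible(x)
}

# Reference to another instance (template-valued slot filler).
instance_ref <- function(id) structure(list(ref = id), class = "pico_ref")

is_ref <- function(x) inherits(x, "pico_ref")

#' Construct a template instance
#'
#' @param id instance identifier, unique within a forest.
#' @param type template type name.
#' @param slots named list mapping slot names to lists of fillers; each
#'   filler is a [text_span()] or an instance reference created with
#'   `instance_ref()` (or a bare character id, which is promoted).
#' @return an object of class `pico_instance`.
#' @export
template_instance <- function(id, type, slots = list()) {
  slots <- lapply(slots, function(fillers) {
    lapply(fillers, function(f) {
      if (is.character(f) && length(f) == 1L) instance_ref(f) else f
    })
  })
  structure(list(id = id, type = type, slots = slots),
            class = "pico_instance")
}

#' Construct an instance forest
#'
#' The extraction target for one document: a set of template instances whose
#' containment graph (instances as nodes, template-valued slot fillers as
#' edges) must be acyclic and connected with a single root — the conditions
#' under which linearization is well defined. Construction does not enforce
#' these conditions; [validate_forest()] reports violations.
#'
#' @param doc_id document identifier.
#' @param instances list of [template_instance()] objects.
#' @param root id of the root instance.
#' @return an object of class `pico_forest`.
#' @export
instance_forest <- function(doc_id, instances, root) {
  ids <- vapply(instances, `[[`, character(1), "id")
  if (anyDuplicated(ids)) stop("duplicate instance ids")
  names(instances) <- ids
  structure(list(doc_id = doc_id, instances = instances, root = root),
            class = "pico_forest")
}

#' @export
print.pico_forest <- function(x, ...) {
  types <- vapply(x$instances, `[[`, character(1), "type")
  cat("<pico_forest> doc ", x$doc_id, ": ", length(x$instances),
      " instances (", paste(names(sort(table(types), decreasing = TRUE)),
                            sort(table(types), decreasing = TRUE),
                            sep = ":", collapse = ", "),
      "), root = ", x$root, "\n", sep = "")
  invisible(x)
}

#' Validate an instance forest against a schema
#'
#' Checks the structural conditions required by the linearizer — the
#' containment graph must be acyclic and connected from the root — plus slot
#' typing: filled slots must belong to the instance's template, textual slots
#' must hold text spans and template-valued slots instances of the declared
#' child type. Violations are report entries, not errors; an empty report
#' means the forest is linearizable.
#'
#' @param forest a [pico_forest()][instance_forest()].
#' @param schema a [pico_schema()].
#' @return character vector of violation messages (empty if valid), classed
#'   `pico_validation`.
#' @export
validate_forest <- function(forest, schema) {
  v <- character(0)
  inst <- forest$instances
  if (!forest$root %in% names(inst)) {
    v <- c(v, paste0("root instance '", forest$root, "' not present"))
  }
  for (ti in inst) {
    spec <- schema$templates[[ti$type]]
    if (is.null(spec)) {
      v <- c(v, paste0("instance '", ti$id, "': unknown template type '",
                       ti$type, "'"))
      next
    }
    snames <- vapply(spec$slots, `[[`, character(1), "name")
    for (sn in names(ti$slots)) {
      if (!sn %in% snames) {
        v <- c(v, paste0("instance '", ti$id, "': slot '", sn,
                         "' does not belong to template ", ti$type))
        next
      }
      sspec <- spec$slots[[match(sn, snames)]]
      for (f in ti$slots[[sn]]) {
        if (sspec$kind == "textual" && !is_span(f)) {
          v <- c(v, paste0("instance '", ti$id, "': textual slot '", sn,
                           "' holds a non-span filler"))
        } else if (sspec$kind == "template") {
          if (!is_ref(f)) {
            v <- c(v, paste0("instance '", ti$id, "': template slot '", sn,
                             "' holds a non-instance filler"))
          } else if (!f$ref %in% names(inst)) {
            v <- c(v, paste0("instance '", ti$id, "': dangling reference '",
                             f$ref, "'"))
          } else if (inst[[f$ref]]$type != sspec$child) {
            v <- c(v, paste0("instance '", ti$id, "': slot '", sn,
                             "' expects ", sspec$child, " but holds ",
                             inst[[f$ref]]$type))
          }
        }
      }
    }
  }

  children <- lapply(inst, function(ti) {
    unlist(lapply(ti$slots, function(fl) {
      vapply(Filter(is_ref, fl), `[[`, character(1), "ref")
    }), use.names = FALSE) %||% character(0)
  })

  # cycle detection over containment edges
  color <- setNames(rep(0L, length(inst)), names(inst))
  cyc <- FALSE
  visit <- function(id) {
    if (cyc || !id %in% names(inst)) return(invisible())
    if (color[[id]] == 1L) { cyc <<- TRUE; return(invisible()) }
    if (color[[id]] == 2L) return(invisible())
    color[id] <<- 1L
    for (ch in children[[id]]) visit(ch)
    color[id] <<- 2L
    invisible()
  }
  for (id in names(inst)) visit(id)
  if (cyc) v <- c(v, "cycle: an instance transitively contains itself")

  # connectivity from the root (only meaningful in the absence of cycles)
  if (!cyc && forest$root %in% names(inst)) {
    seen <- character(0)
    queue <- forest$root
    while (length(queue)) {
      id <- queue[[1]]; queue <- queue[-1]
      if (id %in% seen || !id %in% names(inst)) next
      seen <- c(seen, id)
      queue <- c(queue, children[[id]])
    }
    for (id in setdiff(names(inst), seen)) {
      v <- c(v, paste0("disconnected: instance '", id,
                       "' is not reachable from the root"))
    }
  }
  structure(v, class = "pico_validation")
}

#' @export
print.pico_validation <- function(x, ...) {
  if (!length(x)) {
    cat("forest is valid (acyclic, connected, well-typed)\n")
  } else {
    cat(length(x), "violation(s):\n")
    for (m in x) cat("  -", m, "\n")
  }
  invisible(x)
}

#' Collect the textual slot fillers of a forest
#'
#' @param forest a forest.
#' @return data.frame with columns `instance`, `type`, `slot`, `text`,
#'   `char_start`, `char_end`, `token_start`, `token_end`.
#' @export
forest_fillers <- function(forest) {
  rows <- list()
  for (ti in forest$instances) {
    for (sn in names(ti$slots)) {
      for (f in ti$slots[[sn]]) {
        if (is_span(f)) {
          rows[[length(rows) + 1L]] <- data.frame(
            instance = ti$id, type = ti$type, slot = sn, text = f$text,
            char_start = f$char_start, char_end = f$char_end,
            token_start = f$token_start, token_end = f$token_end,
            stringsAsFactors = FALSE)
        }
      }
    }
  }
  if (!length(rows)) {
    return(data.frame(instance = character(0), type = character(0),
                      slot = character(0), text = character(0),
                      char_start = integer(0), char_end = integer(0),
                      token_start = integer(0), token_end = integer(0)))
  }
  do.call(rbind, rows)
}

# Count instances per template type.
forest_cardinality <- function(forest) {
  table(vapply(forest$instances, `[[`, character(1), "type"))
}

# Canonical nested representation used for order-insensitive equality:
# instances are replaced by their (type, sorted slot contents), textual
# fillers by slot text (optionally with character offsets).
canonical_instance <- function(forest, id, with_spans = FALSE) {
  ti <- forest$instances[[id]]
  # empty slot entries are indistinguishable from absent slots
  ti$slots <- Filter(length, ti$slots)
  slots <- lapply(names(ti$slots), function(sn) {
    items <- lapply(ti$slots[[sn]], function(f) {
      if (is_span(f)) {
        if (with_spans) paste0(sn, "|", f$char_start, ":", f$char_end,
                               "|", f$text)
        else paste0(sn, "|", f$text)
      } else {
        paste0(sn, "|<", paste(deparse(
          canonical_instance(forest, f$ref, with_spans)), collapse = ""), ">")
      }
    })
    sort(unlist(items))
  })
  names(slots) <- names(ti$slots)
  list(type = ti$type, slots = slots[order(names(slots))])
}

#' Compare two forests for semantic equality
#'
#' Equality up to the canonical orderings: instance ids and the order of
#' fillers within a slot are ignored; structure, template types, slot names
#' and filler strings (and optionally character spans) must agree.
#'
#' @param a,b forests.
#' @param with_spans compare character offsets of textual fillers too.
#' @return logical.
#' @export
forest_equal <- function(a, b, with_spans = FALSE) {
  if (!a$root %in% names(a$instances) || !b$root %in% names(b$instances)) {
    return(FALSE)
  }
  if (length(a$instances) != length(b$instances)) return(FALSE)
  identical(canonical_instance(a, a$root, with_spans),
            canonical_instance(b, b$root, with_spans))
}
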