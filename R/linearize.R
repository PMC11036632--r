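special_start <- function(name) paste0("[start:", name, "]")
special_end <- function(name) paste0("[end:", name, "]")

is_special <- function(token) grepl("^\\[(start|end):[^]]+\\]$", token)

special_parts <- function(token) {
  m <- regmatches(token, regexec("^\\[(start|end):([^]]+)\\]$", token))[[1]]
  if (!length(m)) return(NULL)
  list(kind = m[2], name = m[3])
}

#' Derive the decoding grammar from a schema
#'
#' Builds the right-linear context-free grammar whose derivations are
#' exactly the valid linearizations of instance forests under the schema.
#' Four rule shapes are instantiated: for each template type a HEAD rule
#' (`T_HEAD := [start:T] T`) and a terminator rule (`T := [end:T]`), for
#' each textual slot `T := [start:s] TEXT [end:s] T`, and for each
#' template-valued slot with child type C `T := [start:s] C_HEAD [end:s] T`.
#' `TEXT` stands for any token sequence from the input document. The start
#' symbol is the HEAD non-terminal of the root template.
#'
#' @param schema a [pico_schema()].
#' @param vocabulary optional character vector of ordinary (non-special)
#'   terminals; recorded for decoding backends.
#' @return an object of class `pico_grammar`.
#' @export
build_grammar <- function(schema, vocabulary = NULL) {
  rules <- list()
  add <- function(lhs, rhs) {
    rules[[length(rules) + 1L]] <<- list(lhs = lhs, rhs = rhs)
  }
  for (t in schema$templates) {
    add(paste0(t$name, "_HEAD"), c(special_start(t$name), t$name))
    add(t$name, special_end(t$name))
    for (s in t$slots) {
      if (s$kind == "textual") {
        add(t$name, c(special_start(s$name), "TEXT",
                      special_end(s$name), t$name))
      } else {
        add(t$name, c(special_start(s$name), paste0(s$child, "_HEAD"),
                      special_end(s$name), t$name))
      }
    }
  }
  specials <- unique(unlist(lapply(rules, function(r) {
    r$rhs[vapply(r$rhs, is_special, logical(1))]
  })))
  structure(list(schema = schema, rules = rules,
                 start = paste0(schema$root, "_HEAD"),
                 specials = specials, vocabulary = vocabulary),
            class = "pico_grammar")
}

#' @export
print.pico_grammar <- function(x, ...) {
  cat("<pico_grammar> start = ", x$start, ", ", length(x$rules),
      " rules, ", length(x$specials), " special tokens\n", sep = "")
  invisible(x)
}

# Earliest token position of any textual descendant of an instance
# (Inf if the subtree holds no textual filler); the sort key of the
# filler-ordering operator for template-valued fillers.
earliest_textual_position <- function(forest, id) {
  ti <- forest$instances[[id]]
  best <- Inf
  for (fl in ti$slots) {
    for (f in fl) {
      if (is_span(f)) {
        p <- if (is.na(f$token_start)) f$char_start else f$token_start
        best <- min(best, p)
      } else {
        best <- min(best, earliest_textual_position(forest, f$ref))
      }
    }
  }
  best
}

#' Linearize an instance forest into a token sequence
#'
#' Depth-first serialization: an instance emits its template's start
#' special, then each of its slots in schema declaration order (the slot
#' ordering operator), each filler list ordered by document position —
#' textual fillers by token start, template-valued fillers by the position
#' of their earliest textual descendant, ties by creation order — and each
#' filler wrapped in its slot's start/end special tokens; finally the
#' template's end special. Textual fillers emit their document tokens
#' verbatim. The forest must be acyclic and connected (see
#' [validate_forest()]); otherwise linearization would not terminate or
#' would drop isolated instances.
#'
#' @param forest a validated forest.
#' @param schema a [pico_schema()].
#' @param doc optional [tokenize_document()] result; when given, textual
#'   fillers emit the exact document token surfaces, otherwise the filler
#'   text is whitespace-split.
#' @return character vector of tokens (surfaces, with special tokens as
#'   atomic elements).
#' @export
linearize <- function(forest, schema, doc = NULL) {
  viol <- validate_forest(forest, schema)
  if (length(viol)) {
    stop("forest does not linearize: ", paste(viol, collapse = "; "))
  }
  filler_tokens <- function(f) {
    if (!is.null(doc) && !is.na(f$token_start)) {
      doc$tokens$surface[f$token_start:f$token_end]
    } else {
      strsplit(normalize_filler(f$text), " ", fixed = TRUE)[[1]]
    }
  }
  lin_instance <- function(id) {
    ti <- forest$instances[[id]]
    spec <- template_spec(schema, ti$type)
    out <- special_start(ti$type)
    for (s in spec$slots) {
      fillers <- ti$slots[[s$name]]
      if (is.null(fillers) || !length(fillers)) next
      keys <- vapply(fillers, function(f) {
        if (is_span(f)) {
          if (is.na(f$token_start)) as.numeric(f$char_start)
          else as.numeric(f$token_start)
        } else {
          earliest_textual_position(forest, f$ref)
        }
      }, numeric(1))
      for (f in fillers[order(keys)]) {  # stable: ties keep creation order
        inner <- if (is_span(f)) filler_tokens(f) else lin_instance(f$ref)
        out <- c(out, special_start(s$name), inner, special_end(s$name))
      }
    }
    c(out, special_end(ti$type))
  }
  lin_instance(forest$root)
}

#' Parse a linearized token sequence back into an instance forest
#'
#' Inverse of [linearize()]: runs the grammar's stack automaton over the
#' sequence and reconstructs instances, slots and fillers. Textual fillers
#' are matched back to document spans at the earliest contiguous occurrence
#' of their token sequence; filler text that does not occur verbatim in the
#' document is retained as a free-text span flagged with attribute
#' `free_text` (generative decoders without document masking can produce
#' such fillers; evaluation counts them like any other predicted string).
#'
#' @param tokens character vector of tokens.
#' @param grammar a [build_grammar()] result.
#' @param doc the [tokenize_document()] result the sequence describes.
#' @return a [instance_forest()].
#' @export
parse_linearization <- function(tokens, grammar, doc) {
  schema <- grammar$schema
  state <- new_decoding_state()
  n_inst <- 0L
  instances <- list()
  # frame-parallel payload stack: for template frames the instance under
  # construction; for slot frames the collected content
  payload <- list()
  finish_error <- function(i, msg) {
    allowed <- allowed_next_tokens(state, grammar, NULL)
    stop("parse error at position ", i, ": ", msg,
         " (expected one of: ",
         paste(utils::head(allowed, 8L), collapse = " "),
         if (length(allowed) > 8L) " ..." else "", ")")
  }
  match_back <- function(words) {
    if (length(words)) {
      surf <- doc$tokens$surface
      nw <- length(words)
      limit <- length(surf) - nw + 1L
      if (limit >= 1L) {
        for (p in seq_len(limit)) {
          if (all(surf[p:(p + nw - 1L)] == words)) {
            return(span_from_tokens(doc, p, p + nw - 1L))
          }
        }
      }
    }
    sp <- structure(list(doc_id = doc$doc_id, char_start = NA_integer_,
                         char_end = NA_integer_, token_start = NA_integer_,
                         token_end = NA_integer_,
                         text = paste(words, collapse = " ")),
                    class = "pico_span")
    attr(sp, "free_text") <- TRUE
    sp
  }
  for (i in seq_along(tokens)) {
    tok <- tokens[i]
    # permissive over ordinary tokens: free text inside a textual slot is
    # retained and flagged rather than rejected
    allowed <- allowed_next_tokens(state, grammar, NULL)
    ok <- tok %in% allowed ||
      (any(allowed == TEXT_MARKER) && !is_special(tok))
    if (!ok) finish_error(i, paste0("unexpected token '", tok, "'"))
    top <- length(state$frames)
    sp <- special_parts(tok)
    if (is.null(sp)) {
      payload[[top]]$words <- c(payload[[top]]$words, tok)
    } else if (sp$kind == "start" && sp$name %in% template_names(schema)) {
      n_inst <- n_inst + 1L
      payload[[top + 1L]] <- list(instance = template_instance(
        paste0("i", n_inst), sp$name, list()))
    } else if (sp$kind == "start") {
      payload[[top + 1L]] <- list(words = character(0), child = NULL)
    } else if (sp$name %in% template_names(schema)) {
      inst <- payload[[top]]$instance
      instances[[inst$id]] <- inst
      payload[top] <- list(NULL)
      if (top > 1L) payload[[top - 1L]]$child <- inst$id
    } else {
      sspec <- slot_spec(schema, sp$name)
      filler <- if (sspec$kind == "textual") {
        match_back(payload[[top]]$words)
      } else {
        instance_ref(payload[[top]]$child)
      }
      payload[top] <- list(NULL)
      inst <- payload[[top - 1L]]$instance
      inst$slots[[sp$name]] <- c(inst$slots[[sp$name]] %||% list(),
                                 list(filler))
      payload[[top - 1L]]$instance <- inst
    }
    state <- decoding_step(state, tok, grammar)
  }
  if (!state$finished) {
    finish_error(length(tokens) + 1L, "unexpected end of input")
  }
  root_id <- names(instances)[[length(instances)]]  # root closes last
  instance_forest(doc$doc_id, unname(instances), root_id)
}

#' Is a token sequence derivable from the grammar?
#'
#' Runs the stack automaton without building a forest.
#'
#' @param tokens character vector.
#' @param grammar a [build_grammar()] result.
#' @param doc optional document (or character vector of token surfaces)
#'   restricting the tokens allowed inside textual slots; when `NULL`, any
#'   non-special token is accepted there.
#' @return logical: `TRUE` iff the full sequence is derivable from the start
#'   symbol (complete, balanced, schema-conformant).
#' @export
validate_sequence <- function(tokens, grammar, doc = NULL) {
  state <- new_decoding_state()
  for (tok in tokens) {
    allowed <- allowed_next_tokens(state, grammar, doc)
    ok <- tok %in% allowed ||
      (any(allowed == TEXT_MARKER) && !is_special(tok))
    if (!ok) return(FALSE)
    state <- decoding_step(state, tok, grammar)
  }
  isTRUE(state$finished)
}
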