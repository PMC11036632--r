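#' Tokenize a document with character alignment and sentence boundaries
#'
#' Whitespace tokenization: maximal runs of non-whitespace characters become
#' tokens, each carrying its 0-based half-open character range so that
#' character spans and token spans round-trip exactly. Sentence boundaries
#' follow a deterministic rule: a boundary is placed after a token ending in
#' `.`, `?` or `!` when the next token begins with an uppercase letter or a
#' digit. Sentence-wise processing is what the start/end joining rule of the
#' tagger relies on.
#'
#' @param doc_id document identifier.
#' @param text document text; must contain at least one token.
#' @return an object of class `pico_document` with fields `doc_id`, `text`,
#'   `tokens` (data.frame `surface`, `char_start`, `char_end`),
#'   `sentences` (data.frame `token_start`, `token_end`, inclusive) and
#'   `tokenizer_id`.
#' @export
tokenize_document <- function(doc_id, text) {
  stop_if_not_scalar_chr(text, "text")
  m <- gregexpr("\\S+", text, perl = TRUE)[[1]]
  if (m[1] == -1L) stop("document '", doc_id, "' contains no tokens")
  starts <- as.integer(m)
  lens <- attr(m, "match.length")
  surfaces <- substring(text, starts, starts + lens - 1L)
  tokens <- data.frame(surface = surfaces,
                       char_start = starts - 1L,
                       char_end = starts + lens - 1L,
                       stringsAsFactors = FALSE)
  n <- nrow(tokens)
  boundary_after <- logical(n)
  if (n > 1L) {
    ends_sentence <- grepl("[.?!]$", surfaces[-n])
    next_upper <- grepl("^[[:upper:][:digit:]]", surfaces[-1])
    boundary_after[-n] <- ends_sentence & next_upper
  }
  sent_start <- c(1L, which(boundary_after) + 1L)
  sent_end <- c(which(boundary_after), n)
  sentences <- data.frame(token_start = sent_start, token_end = sent_end)
  structure(list(doc_id = doc_id, text = text, tokens = tokens,
                 sentences = sentences, tokenizer_id = "whitespace-v1"),
            class = "pico_document")
}

#' @export
print.pico_document <- function(x, ...) {
  cat("<pico_document> ", x$doc_id, ": ", nrow(x$tokens), " tokens, ",
      nrow(x$sentences), " sentences, ", nchar(x$text), " chars\n", sep = "")
  invisible(x)
}

n_tokens <- function(doc) nrow(doc$tokens)

# Sentence index (1-based) of each token.
token_sentence <- function(doc) {
  out <- integer(n_tokens(doc))
  for (i in seq_len(nrow(doc$sentences))) {
    out[doc$sentences$token_start[i]:doc$sentences$token_end[i]] <- i
  }
  out
}

#' Align a character interval to the minimal covering token interval
#'
#' @param doc a [tokenize_document()] result.
#' @param char_start,char_end 0-based half-open character offsets.
#' @return integer vector `c(token_start, token_end)`, 1-based inclusive.
#' @export
align_span <- function(doc, char_start, char_end) {
  if (char_start < 0 || char_end > nchar(doc$text) || char_end <= char_start) {
    stop("character interval [", char_start, ",", char_end,
         ") outside document")
  }
  hit <- which(doc$tokens$char_end > char_start &
               doc$tokens$char_start < char_end)
  if (!length(hit)) stop("character interval covers no token")
  c(min(hit), max(hit))
}

# Character span of an inclusive token interval.
token_char_range <- function(doc, token_start, token_end) {
  c(doc$tokens$char_start[token_start], doc$tokens$char_end[token_end])
}

# Build a pico_span from a token interval of a document.
span_from_tokens <- function(doc, token_start, token_end) {
  cr <- token_char_range(doc, token_start, token_end)
  text_span(doc$doc_id, cr[1], cr[2],
            substr(doc$text, cr[1] + 1L, cr[2]),
            token_start, token_end)
}

forest_to_list <- function(forest) {
  list(
    doc_id = forest$doc_id,
    root = forest$root,
    instances = lapply(unname(forest$instances), function(ti) {
      list(id = ti$id, type = ti$type,
           slots = lapply(ti$slots, function(fl) {
             lapply(fl, function(f) {
               if (is_span(f)) list(span = c(f$char_start, f$char_end))
               else list(ref = f$ref)
             })
           }))
    })
  )
}

forest_from_list <- function(lst, doc) {
  instances <- lapply(lst$instances, function(il) {
    slots <- lapply(il$slots, function(fl) {
      lapply(fl, function(f) {
        if (!is.null(f$ref)) {
          instance_ref(f$ref)
        } else {
          cs <- f$span[[1]]; ce <- f$span[[2]]
          if (ce > nchar(doc$text)) {
            stop("span [", cs, ",", ce, ") outside document '",
                 doc$doc_id, "'")
          }
          tk <- align_span(doc, cs, ce)
          text_span(doc$doc_id, cs, ce, substr(doc$text, cs + 1L, ce),
                    tk[1], tk[2], full_text = doc$text)
        }
      })
    })
    template_instance(il$id, il$type, slots)
  })
  instance_forest(lst$doc_id, instances, lst$root)
}

#' Read a corpus from a JSONL file
#'
#' One JSON object per line: `{"doc_id", "text", "root", "instances": [...]}`
#' with instances carrying `id`, `type` and `slots` mapping slot names to
#' lists of fillers, each `{"span": [cs, ce]}` (0-based half-open character
#' offsets) or `{"ref": id}`. `root`/`instances` may be absent for
#' unannotated documents.
#'
#' @param path JSONL file path.
#' @param schema optional [pico_schema()]; when given, annotated forests are
#'   validated and violations raise an error.
#' @return list of `list(document =, forest = or NULL)` records, classed
#'   `pico_corpus`.
#' @export
read_corpus <- function(path, schema = NULL) {
  lines <- readLines(path, warn = FALSE, encoding = "UTF-8")
  lines <- lines[nzchar(trimws(lines))]
  recs <- lapply(lines, function(ln) {
    obj <- jsonlite::fromJSON(ln, simplifyVector = FALSE)
    doc <- tokenize_document(obj$doc_id, obj$text)
    forest <- NULL
    if (!is.null(obj$instances)) {
      forest <- forest_from_list(obj, doc)
      if (!is.null(schema)) {
        viol <- validate_forest(forest, schema)
        if (length(viol)) {
          stop("document '", obj$doc_id, "': ",
               paste(viol, collapse = "; "))
        }
      }
    }
    list(document = doc, forest = forest)
  })
  structure(recs, class = "pico_corpus")
}

#' Write a corpus (or predictions) to a JSONL file
#'
#' Inverse of [read_corpus()]; annotations round-trip losslessly.
#'
#' @param corpus list of `list(document, forest)` records; `forest` may be
#'   `NULL`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_corpus <- function(corpus, path) {
  con <- file(path, open = "w", encoding = "UTF-8")
  on.exit(close(con))
  for (rec in corpus) {
    obj <- list(doc_id = rec$document$doc_id, text = rec$document$text)
    if (!is.null(rec$forest)) {
      fl <- forest_to_list(rec$forest)
      obj$root <- fl$root
      obj$instances <- fl$instances
    }
    writeLines(jsonlite::toJSON(obj, auto_unbox = TRUE, null = "null"),
               con)
  }
  invisible(path)
}

#' @export
print.pico_corpus <- function(x, ...) {
  ann <- sum(vapply(x, function(r) !is.null(r$forest), logical(1)))
  cat("<pico_corpus> ", length(x), " documents (", ann, " annotated)\n",
      sep = "")
  invisible(x)
}
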