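# Sentinel returned by allowed_next_tokens() when no document is supplied:
# stands for "any ordinary (non-special) token" inside a textual slot.
TEXT_MARKER <- "<TEXT>"

# Fresh automaton state: empty stack, before the root's start special.
new_decoding_state <- function() {
  list(frames = list(), started = FALSE, finished = FALSE)
}

push_frame <- function(state, kind, name) {
  state$frames[[length(state$frames) + 1L]] <-
    list(kind = kind, name = name, child_done = FALSE)
  state
}

pop_frame <- function(state) {
  state$frames[[length(state$frames)]] <- NULL
  state
}

top_frame <- function(state) {
  n <- length(state$frames)
  if (!n) NULL else state$frames[[n]]
}

#' Grammar-allowed next tokens for a decoding state
#'
#' The decoding stack determines the admissible continuations: before
#' anything is emitted only the root template's start special is allowed;
#' inside a template frame, the start specials of that template's slots plus
#' the template's end special; inside a textual slot, the distinct tokens of
#' the input document plus that slot's end special; a template-valued slot
#' frame first requires the child template's start special and, once the
#' child instance is closed, that slot's end special. The set is never empty
#' until the root frame has been popped.
#'
#' @param state decoding state as evolved by the automaton (opaque; obtain a
#'   fresh one via `constrained_decode()`'s internals or pass `NULL` for the
#'   initial state).
#' @param grammar a [build_grammar()] result.
#' @param doc a [tokenize_document()] result, a character vector of token
#'   surfaces, or `NULL`, in which case the sentinel `"<TEXT>"` stands for
#'   any ordinary token.
#' @return character vector of allowed tokens.
#' @export
allowed_next_tokens <- function(state, grammar, doc = NULL) {
  if (is.null(state)) state <- new_decoding_state()
  schema <- grammar$schema
  if (state$finished) return(character(0))
  if (!state$started) return(special_start(schema$root))
  top <- top_frame(state)
  if (is.null(top)) stop("inconsistent stack: started but empty")  # nocov
  if (top$kind == "template") {
    spec <- template_spec(schema, top$name)
    starts <- vapply(spec$slots, function(s) special_start(s$name),
                     character(1))
    return(c(starts, special_end(top$name)))
  }
  if (top$kind == "tslot") {
    words <- if (is.null(doc)) {
      TEXT_MARKER
    } else if (is.character(doc)) {
      unique(doc)
    } else {
      unique(doc$tokens$surface)
    }
    return(c(words, special_end(top$name)))
  }
  # template-valued slot frame
  if (!top$child_done) {
    sspec <- slot_spec(schema, top$name)
    return(special_start(sspec$child))
  }
  special_end(top$name)
}

# Advance the automaton by one token. The caller guarantees the token is
# allowed; inconsistencies are programming errors and stop().
decoding_step <- function(state, token, grammar) {
  schema <- grammar$schema
  sp <- special_parts(token)
  if (is.null(sp)) {
    top <- top_frame(state)
    if (is.null(top) || top$kind != "tslot") {
      stop("ordinary token '", token, "' outside a textual slot")
    }
    return(state)
  }
  if (sp$kind == "start") {
    if (sp$name %in% template_names(schema)) {
      state <- push_frame(state, "template", sp$name)
      state$started <- TRUE
    } else {
      sspec <- slot_spec(schema, sp$name)
      state <- push_frame(state,
                          if (sspec$kind == "textual") "tslot" else "cslot",
                          sp$name)
    }
    return(state)
  }
  top <- top_frame(state)
  if (is.null(top) || top$name != sp$name) {
    stop("end special '", token, "' does not match open frame '",
         if (is.null(top)) "<none>" else top$name, "'")
  }
  state <- pop_frame(state)
  if (!length(state$frames)) {
    state$finished <- TRUE
  } else if (top$kind == "template") {
    n <- length(state$frames)
    if (state$frames[[n]]$kind == "cslot") {
      state$frames[[n]]$child_done <- TRUE
    }
  }
  state
}

# Closing token sequence that completes every open frame so a truncated
# decode still parses: an open template-valued slot with no child yet gets
# an empty child instance.
auto_close_tokens <- function(state, grammar) {
  out <- character(0)
  schema <- grammar$schema
  while (length(state$frames)) {
    top <- top_frame(state)
    if (top$kind == "cslot" && !top$child_done) {
      child <- slot_spec(schema, top$name)$child
      out <- c(out, special_start(child), special_end(child))
      state <- decoding_step(state, special_start(child), grammar)
      state <- decoding_step(state, special_end(child), grammar)
    }
    out <- c(out, special_end(top$name))
    state <- decoding_step(state, special_end(top$name), grammar)
  }
  out
}

#' Grammar-constrained greedy decoding
#'
#' At each step the grammar-allowed token set is computed from the decoding
#' stack, the provider's scores for all disallowed tokens are masked to
#' negative infinity, and the maximum-scoring allowed token is emitted
#' (greedy selection; ties go to the first allowed token in deterministic
#' order). Start specials push a frame, matching end specials pop one;
#' decoding stops when the root frame is popped. The output is therefore
#' always derivable from the grammar — if `max_len` is reached mid-structure
#' the open frames are auto-closed and the result carries attribute
#' `truncated = TRUE`.
#'
#' @param provider a logit provider: list with `next_scores(prefix)`
#'   returning a named numeric vector of scores per token (see
#'   [teacher_provider()], [uniform_provider()], or a trained
#'   [pico_generative()] model's provider).
#' @param grammar a [build_grammar()] result.
#' @param doc the input document.
#' @param max_len maximum number of emitted tokens before auto-closing
#'   (default 4x the document length).
#' @return character vector of tokens; attribute `truncated` is `TRUE` if
#'   the length cap was hit.
#' @export
constrained_decode <- function(provider, grammar, doc,
                               max_len = 4L * n_tokens(doc)) {
  if (max_len < 2L) stop("max_len must be at least 2")
  state <- new_decoding_state()
  tokens <- character(0)
  truncated <- FALSE
  while (!state$finished) {
    if (length(tokens) >= max_len) {
      truncated <- TRUE
      break
    }
    allowed <- allowed_next_tokens(state, grammar, doc)
    if (!length(allowed)) stop("empty allowed set: grammar bug")  # nocov
    scores <- provider$next_scores(tokens)
    s <- scores[allowed]
    s[is.na(s)] <- -Inf
    tok <- allowed[which.max(s)]
    tokens <- c(tokens, tok)
    state <- decoding_step(state, tok, grammar)
  }
  if (truncated) tokens <- c(tokens, auto_close_tokens(state, grammar))
  attr(tokens, "truncated") <- truncated
  tokens
}

#' Decode a document into an instance forest
#'
#' Composition of [constrained_decode()] and [parse_linearization()];
#' truncated decodes are auto-closed before parsing so parsing never fails.
#'
#' @inheritParams constrained_decode
#' @return a forest; attribute `truncated` is propagated.
#' @export
decode_document <- function(provider, grammar, doc,
                            max_len = 4L * n_tokens(doc)) {
  tokens <- constrained_decode(provider, grammar, doc, max_len)
  forest <- parse_linearization(as.character(tokens), grammar, doc)
  attr(forest, "truncated") <- attr(tokens, "truncated")
  forest
}

#' Adversarial uniform-random logit provider
#'
#' Scores every token of `vocab` with pseudo-random values that are a
#' deterministic function of the seed and the generated prefix. Used to
#' property-test that constrained decoding yields derivable output no matter
#' what the model prefers.
#'
#' @param vocab character vector of tokens to score.
#' @param seed integer seed.
#' @return a logit provider.
#' @export
uniform_provider <- function(vocab, seed = 1L) {
  vocab <- unique(vocab)
  list(next_scores = function(prefix) {
    key <- hash_string(paste(prefix, collapse = "\u1f"), salt = seed)
    with_seed(key, stats::setNames(stats::runif(length(vocab)), vocab))
  })
}

#' Teacher logit provider for a gold sequence
#'
#' Scores the gold continuation highest at every prefix of the gold
#' sequence; off the gold path, scores are seeded pseudo-random values.
#' Constrained decoding with this provider must reproduce the gold
#' linearization exactly.
#'
#' @param gold character vector, the gold token sequence.
#' @param vocab extra tokens to score (defaults to the gold tokens).
#' @param seed integer seed for the off-gold scores.
#' @return a logit provider.
#' @export
teacher_provider <- function(gold, vocab = NULL, seed = 1L) {
  vocab <- unique(c(gold, vocab))
  list(next_scores = function(prefix) {
    key <- hash_string(paste(prefix, collapse = "\u1f"), salt = seed)
    scores <- with_seed(key,
      stats::setNames(stats::runif(length(vocab), 0, 0.5), vocab))
    k <- length(prefix)
    if (k < length(gold) && (k == 0L || identical(prefix, gold[seq_len(k)]))) {
      scores[gold[k + 1L]] <- 1.0
    }
    scores
  })
}
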