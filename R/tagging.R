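NO_SLOT <- "O"

#' Convert slot-filler spans to start/end boundary tags
#'
#' The tagging scheme labels only the first and the last token of each
#' slot-filler sequence — `start:SLOT` on the start token and `end:SLOT` on
#' the end token — while all interior tokens carry the no-slot label, unlike
#' IOB where interior tokens are labelled too. A single-token filler carries
#' both its start and its end label. One token may simultaneously be the
#' start of one filler and the end of another (the two label sequences are
#' independent), but two fillers may not share a start token or share an end
#' token.
#'
#' @param doc a [tokenize_document()] result.
#' @param fillers data.frame with columns `slot`, `token_start`, `token_end`
#'   (1-based inclusive), e.g. from [forest_fillers()].
#' @return an object of class `pico_tags`: list with `start` and `end`,
#'   character vectors over tokens holding slot names or the no-slot label
#'   `"O"`.
#' @export
spans_to_tags <- function(doc, fillers) {
  n <- n_tokens(doc)
  start_labels <- rep(NO_SLOT, n)
  end_labels <- rep(NO_SLOT, n)
  if (nrow(fillers)) {
    for (i in seq_len(nrow(fillers))) {
      s <- fillers$token_start[i]; e <- fillers$token_end[i]
      if (is.na(s) || is.na(e) || s < 1L || e > n || e < s) {
        stop("filler token span [", s, ",", e, "] outside document")
      }
      if (start_labels[s] != NO_SLOT) {
        stop("conflicting start labels at token ", s, " ('",
             start_labels[s], "' vs '", fillers$slot[i], "')")
      }
      if (end_labels[e] != NO_SLOT) {
        stop("conflicting end labels at token ", e, " ('",
             end_labels[e], "' vs '", fillers$slot[i], "')")
      }
      start_labels[s] <- fillers$slot[i]
      end_labels[e] <- fillers$slot[i]
    }
  }
  structure(list(start = start_labels, end = end_labels),
            class = "pico_tags")
}

#' @export
print.pico_tags <- function(x, ...) {
  n <- length(x$start)
  marked <- which(x$start != NO_SLOT | x$end != NO_SLOT)
  cat("<pico_tags> ", n, " tokens, ", sum(x$start != NO_SLOT),
      " starts, ", sum(x$end != NO_SLOT), " ends\n", sep = "")
  for (i in marked) {
    cat(sprintf("  token %d: start=%s end=%s\n", i, x$start[i], x$end[i]))
  }
  invisible(x)
}

#' Join boundary tags into slot-filler spans
#'
#' Start and end tokens are joined sentence-wise: within each sentence,
#' start tokens are processed left to right and each consumes the nearest
#' unconsumed end token of the same label at position `j >= i` (minimal
#' `j - i`). Starts with no matching end and ends never consumed are
#' discarded; matches never cross sentence boundaries. When two starts
#' compete for one end, the earlier start wins (it is processed first).
#'
#' @param doc a [tokenize_document()] result.
#' @param tags a [spans_to_tags()] result (or predicted tags).
#' @return data.frame with columns `slot`, `token_start`, `token_end`,
#'   `char_start`, `char_end`, `text`.
#' @export
tags_to_spans <- function(doc, tags) {
  stopifnot(length(tags$start) == n_tokens(doc),
            length(tags$end) == n_tokens(doc))
  out <- list()
  for (si in seq_len(nrow(doc$sentences))) {
    lo <- doc$sentences$token_start[si]
    hi <- doc$sentences$token_end[si]
    starts <- lo:hi
    starts <- starts[tags$start[starts] != NO_SLOT]
    end_used <- logical(hi - lo + 1L)
    for (s in starts) {
      lab <- tags$start[s]
      cand <- s:hi
      cand <- cand[tags$end[cand] == lab & !end_used[cand - lo + 1L]]
      if (!length(cand)) next  # unmatched start: discard
      e <- cand[1]  # minimal distance j - i
      end_used[e - lo + 1L] <- TRUE
      cr <- token_char_range(doc, s, e)
      out[[length(out) + 1L]] <- data.frame(
        slot = lab, token_start = s, token_end = e,
        char_start = cr[1], char_end = cr[2],
        text = substr(doc$text, cr[1] + 1L, cr[2]),
        stringsAsFactors = FALSE)
    }
  }
  if (!length(out)) {
    return(data.frame(slot = character(0), token_start = integer(0),
                      token_end = integer(0), char_start = integer(0),
                      char_end = integer(0), text = character(0)))
  }
  do.call(rbind, out)
}
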