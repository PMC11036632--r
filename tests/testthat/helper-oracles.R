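# Independent oracles used across tests; these deliberately avoid the
# implementation paths they check.

# All token sequences derivable from the grammar start symbol, up to a
# length bound, by leftmost rewriting of sentential forms. Textual slots
# expand to any (possibly empty) sequence of the given document token
# types. Returns a character vector of space-joined terminal sequences.
enumerate_derivations <- function(schema, doc_types, max_len = 8L) {
  grammar <- build_grammar(schema)
  # symbols: terminals are specials or doc types; non-terminals are
  # template names, template HEAD names, or "TEXT"
  nonterminals <- c(template_names(schema),
                    paste0(template_names(schema), "_HEAD"), "TEXT")
  expansions <- function(sym) {
    if (sym == "TEXT") {
      return(c(list(character(0)),
               lapply(doc_types, function(w) c(w, "TEXT"))))
    }
    lapply(Filter(function(r) r$lhs == sym, grammar$rules), `[[`, "rhs")
  }
  results <- character(0)
  queue <- list(grammar$start)
  while (length(queue)) {
    form <- queue[[1]]
    queue <- queue[-1]
    nt_pos <- which(form %in% nonterminals)
    if (!length(nt_pos)) {
      if (length(form) <= max_len) {
        results <- c(results, paste(form, collapse = " "))
      }
      next
    }
    # terminal prefix bound prunes the search
    if (nt_pos[1] - 1L > max_len) next
    i <- nt_pos[1]
    for (rhs in expansions(form[i])) {
      queue[[length(queue) + 1L]] <-
        append(form[-i], rhs, after = i - 1L)
    }
  }
  unique(results)
}

# Continuation set after a terminal prefix, read off the enumerated
# derivable sequences (sequences given as token vectors).
oracle_continuations <- function(seqs, prefix) {
  out <- character(0)
  k <- length(prefix)
  for (s in seqs) {
    if (length(s) > k && identical(s[seq_len(k)], prefix)) {
      out <- c(out, s[k + 1L])
    }
  }
  sort(unique(out))
}

# Brute-force start/end matching: over all injective assignments of starts
# to same-label ends at j >= i within a sentence, maximize the number of
# matched pairs, then minimize the total distance. Returns c(count, total).
oracle_matching_value <- function(starts, ends) {
  best <- c(0L, Inf)
  n <- length(starts)
  recurse <- function(si, used, count, total) {
    if (si > n) {
      if (count > best[1] || (count == best[1] && total < best[2])) {
        best <<- c(count, total)
      }
      return(invisible())
    }
    recurse(si + 1L, used, count, total)  # leave this start unmatched
    for (ei in seq_along(ends)) {
      if (!used[ei] && ends[ei] >= starts[si]) {
        used[ei] <- TRUE
        recurse(si + 1L, used, count + 1L, total + ends[ei] - starts[si])
        used[ei] <- FALSE
      }
    }
    invisible()
  }
  recurse(1L, logical(length(ends)), 0L, 0)
  best
}
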