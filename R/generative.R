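# Feature layout of the generative decoder state: fixed hashed embedding of
# the previously emitted token, a one-hot of the open frame (slot or
# template) on top of the decoding stack, a bag-of-embeddings summary of the
# document tokens not yet copied, and a bias. The output distribution is
# softmax(V d + b) with d a learned linear map of these features — the
# standard output-embedding-times-decoder-state form of seq2seq models, at
# desk scale.

GEN_BOS <- "<BOS>"

N_SHAPE_FEAT <- 6L

# Surface-shape features of a token: numeric tokens carry their (scaled)
# magnitude so that value ranges — patient counts, doses, percentages —
# remain separable even for surfaces never seen in training, the way a
# subword tokenizer would expose digit structure.
shape_features <- function(s) {
  is_num <- grepl("^[0-9]+([.][0-9]+)?$", s)
  val <- if (is_num) min(as.numeric(s), 2000) / 2000 else 0
  c(is_num,
    grepl("^[0-9]+[.][0-9]+$", s),          # decimal
    val,
    min(nchar(s), 10) / 10,
    grepl("^[[:upper:]]", s),
    grepl("^[[:lower:]]+$", s))
}

# Fixed per-token input/output feature embedding: hashed block + shape.
token_feature_matrix <- function(vocab, k, salt = 11L) {
  E <- matrix(0, length(vocab), k + N_SHAPE_FEAT,
              dimnames = list(vocab, NULL))
  for (v in vocab) {
    E[v, ] <- c(hashed_embedding(v, k, salt), shape_features(v))
  }
  E
}

gen_frame_names <- function(schema) {
  c(names(schema$slot_owner), template_names(schema), "<none>")
}

# Word types observed inside each textual slot of the training
# linearizations, closed over the schema's containment structure: a
# template-valued slot or template inherits the union of its subtree's
# inventories. Start specials are then scored with a learned bias on how
# many such words remain uncopied in the document — the signal that decides
# whether another instance or filler is still to be generated.
gen_slot_inventories <- function(ys, schema) {
  inv <- list()
  for (y in ys) {
    stack <- character(0)
    kinds <- character(0)
    for (tok in y) {
      sp <- special_parts(tok)
      if (is.null(sp)) {
        top <- stack[length(stack)]
        if (length(top) && kinds[length(kinds)] == "tslot") {
          inv[[top]] <- c(inv[[top]], tok)
        }
      } else if (sp$kind == "start") {
        stack <- c(stack, sp$name)
        kinds <- c(kinds,
                   if (sp$name %in% template_names(schema)) "template"
                   else if (slot_spec(schema, sp$name)$kind == "textual")
                     "tslot" else "cslot")
      } else {
        stack <- stack[-length(stack)]
        kinds <- kinds[-length(kinds)]
      }
    }
  }
  inv <- lapply(inv, unique)
  memo <- list()
  tpl_inv <- function(type) {
    if (!is.null(memo[[type]])) return(memo[[type]])
    words <- character(0)
    for (s in schema$templates[[type]]$slots) {
      words <- c(words, if (s$kind == "textual") inv[[s$name]] %||%
                   character(0) else tpl_inv(s$child))
    }
    memo[[type]] <<- unique(words)
    memo[[type]]
  }
  out <- list()
  for (t in template_names(schema)) {
    out[[special_start(t)]] <- tpl_inv(t)
    for (s in schema$templates[[t]]$slots) {
      out[[special_start(s$name)]] <- if (s$kind == "textual") {
        inv[[s$name]] %||% character(0)
      } else {
        tpl_inv(s$child)
      }
    }
  }
  out
}

# Scan a prefix into (last token, stack, remaining bag counts, tokens
# emitted inside the open slot).
gen_scan_prefix <- function(prefix, bag0) {
  state <- list(last = GEN_BOS, stack = character(0), bag = bag0,
                inslot = 0L)
  for (tok in prefix) state <- gen_advance(state, tok)
  state
}

# Advance the scanned state by one emitted token.
gen_advance <- function(state, tok) {
  sp <- special_parts(tok)
  if (is.null(sp)) {
    if (!is.null(state$bag[[tok]]) && state$bag[[tok]] > 0L) {
      state$bag[[tok]] <- state$bag[[tok]] - 1L
    }
    state$inslot <- state$inslot + 1L
  } else if (sp$kind == "start") {
    state$stack <- c(state$stack, sp$name)
    state$inslot <- 0L
  } else {
    state$stack <- state$stack[-length(state$stack)]
    state$inslot <- 0L
  }
  state$last <- tok
  state
}

gen_feature_dim <- function(ke, n_frames) 2L * ke + n_frames + 4L + 1L

# One feature row from a scanned state. `inslot` is the number of ordinary
# tokens emitted inside the currently open slot (one-hot 0/1/2/3+): the
# fillers of trial records are short, and this feature carries the
# end-of-filler decision.
gen_feature_row <- function(state, E, frames) {
  ke <- ncol(E)
  fr <- numeric(length(frames))
  fr[match(state$frame, frames)] <- 1
  bagvec <- numeric(ke)
  nz <- names(state$bag)[state$bag > 0L]
  if (length(nz)) {
    bagvec <- as.numeric(state$bag[nz] %*% E[nz, , drop = FALSE])
  }
  lastvec <- if (state$last %in% rownames(E)) {
    E[state$last, ]
  } else {
    c(hashed_embedding(state$last, ke - N_SHAPE_FEAT, salt = 11L),
      shape_features(state$last))
  }
  inslot <- numeric(4L)
  inslot[min(state$inslot %||% 0L, 3L) + 1L] <- 1
  c(lastvec, fr, bagvec, inslot, 1)
}

# Feature matrix for all teacher-forcing steps of one gold sequence.
gen_doc_features <- function(doc, y, E, frames) {
  bag <- table(doc$tokens$surface)
  bag <- stats::setNames(as.integer(bag), names(bag))
  Fmat <- matrix(0, length(y), gen_feature_dim(ncol(E), length(frames)))
  state <- list(last = GEN_BOS, frame = "<none>", bag = bag, inslot = 0L)
  stack <- character(0)
  for (t in seq_along(y)) {
    Fmat[t, ] <- gen_feature_row(state, E, frames)
    tok <- y[[t]]
    sp <- special_parts(tok)
    if (is.null(sp)) {
      if (!is.null(state$bag[[tok]]) && state$bag[[tok]] > 0L) {
        state$bag[[tok]] <- state$bag[[tok]] - 1L
      }
      state$inslot <- state$inslot + 1L
    } else if (sp$kind == "start") {
      stack <- c(stack, sp$name)
      state$inslot <- 0L
    } else {
      stack <- stack[-length(stack)]
      state$inslot <- 0L
    }
    state$last <- tok
    state$frame <- if (length(stack)) stack[[length(stack)]] else "<none>"
  }
  Fmat
}

#' Fit the generative template-extraction model
#'
#' Trains a lightweight autoregressive decoder by teacher forcing: the
#' target for each document is the linearization of its gold forest, and the
#' loss is token-level cross-entropy between the predicted vocabulary
#' distribution and the gold next token. The decoder state is a learned
#' linear map of deterministic prefix features (previous token embedding,
#' open grammar frame, bag of not-yet-copied document tokens); the
#' vocabulary distribution is `softmax(V d + b)` with learned output
#' embeddings `V`. Inference uses [constrained_decode()], which masks the
#' distribution to the grammar-allowed token set at every step.
#'
#' @param corpus annotated corpus.
#' @param schema a [pico_schema()].
#' @param k fixed token-embedding dimension.
#' @param d2 decoder state dimension.
#' @param epochs training epochs (0 returns the initialization).
#' @param lr,lambda initial learning rate and decay of the schedule
#'   `lr(epoch) = lr * lambda^epoch`.
#' @param seed seed for initialization and data order.
#' @return an object of class `pico_generative` with the grammar, the
#'   learned parameters and the per-epoch loss trace.
#' @seealso [predict.pico_generative()], [generative_provider()]
#' @export
pico_generative <- function(corpus, schema = default_pico_schema(),
                            k = 24L, d2 = 64L, epochs = 40L, lr = 0.03,
                            lambda = 0.95, seed = 1L) {
  ann <- Filter(function(r) !is.null(r$forest), corpus)
  if (!length(ann)) stop("corpus has no annotated documents")
  grammar <- build_grammar(schema)
  words <- unique(unlist(lapply(ann,
                                function(r) r$document$tokens$surface)))
  vocab <- unique(c(words, grammar$specials))
  frames <- gen_frame_names(schema)
  E <- token_feature_matrix(c(vocab, GEN_BOS), k, salt = 11L)

  docs <- lapply(ann, function(r) {
    y <- linearize(r$forest, schema, r$document)
    # segments of constant remaining-bag: the copy-presence bias is shared
    # by all steps between two copied word tokens
    is_word <- !vapply(y, is_special, logical(1))
    seg_id <- c(1L, 1L + cumsum(is_word))[seq_along(y)]
    bag <- table(r$document$tokens$surface)
    cnt0 <- numeric(length(vocab))
    cnt0[match(names(bag), vocab)] <- as.integer(bag)
    list(Fmat = gen_doc_features(r$document, y, E, frames),
         targets = match(y, vocab), seg_id = seg_id,
         seg_words = match(y[is_word], vocab), cnt0 = cnt0)
  })

  # inventories of the start specials, as vocabulary-id lists
  inventories <- gen_slot_inventories(lapply(docs, function(d)
    vocab[d$targets]), schema)
  inv_ids <- lapply(inventories, function(w) match(w, vocab))
  inv_cols <- match(names(inventories), vocab)

  # per-segment features of a doc: presence/count of each remaining word
  # (copy bias) and remaining slot-inventory mass under each start special
  doc_psi <- function(dd) {
    S <- max(dd$seg_id)
    P1 <- matrix(0, S, length(dd$cnt0))
    P2 <- P1
    P3 <- P1
    P4 <- P1
    cnt <- dd$cnt0
    for (s in seq_len(S)) {
      P1[s, ] <- as.numeric(cnt > 0)
      P2[s, ] <- pmin(cnt, 3) / 3
      rem <- vapply(inv_ids, function(ids) sum(cnt[ids]), numeric(1))
      P3[s, inv_cols] <- pmin(rem, 3) / 3
      P4[s, inv_cols] <- as.numeric(rem > 0)
      if (s <= length(dd$seg_words) && !is.na(dd$seg_words[s])) {
        w <- dd$seg_words[s]
        cnt[w] <- max(cnt[w] - 1, 0)
      }
    }
    list(P1 = P1, P2 = P2, P3 = P3, P4 = P4)
  }

  nf <- gen_feature_dim(ncol(E), length(frames))
  Evoc <- E[vocab, , drop = FALSE]
  with_seed(seed, {
    params <- list(Wf = matrix(stats::rnorm(d2 * nf, sd = 0.01), d2, nf),
                   V = matrix(stats::rnorm(length(vocab) * d2, sd = 0.01),
                              length(vocab), d2),
                   # feature-tied output embeddings: score unseen-at-test
                   # surfaces through their shape/hash features
                   C = matrix(stats::rnorm(d2 * ncol(E), sd = 0.01),
                              d2, ncol(E)),
                   b = numeric(length(vocab)),
                   w_copy = c(0, 0, 0, 0))
  })
  losses <- numeric(0)
  if (epochs > 0L) {
    st <- make_adam(params)
    psis <- lapply(docs, doc_psi)
    for (ep in seq_len(epochs)) {
      lr_ep <- lr_at_epoch(lr, lambda, ep - 1L)
      ord <- with_seed(seed + 5000L + ep, sample(seq_along(docs)))
      ep_loss <- 0; n_tok <- 0L
      for (di in ord) {
        dd <- docs[[di]]
        psi <- psis[[di]]
        D <- dd$Fmat %*% t(params$Wf)
        Vt <- params$V + Evoc %*% t(params$C)
        L <- sweep(D %*% t(Vt), 2L, params$b, `+`) +
          params$w_copy[1] * psi$P1[dd$seg_id, , drop = FALSE] +
          params$w_copy[2] * psi$P2[dd$seg_id, , drop = FALSE] +
          params$w_copy[3] * psi$P3[dd$seg_id, , drop = FALSE] +
          params$w_copy[4] * psi$P4[dd$seg_id, , drop = FALSE]
        P <- softmax_rows(L)
        Tn <- nrow(P)
        ep_loss <- ep_loss -
          sum(log(pmax(P[cbind(seq_len(Tn), dd$targets)], 1e-12)))
        n_tok <- n_tok + Tn
        G <- P
        G[cbind(seq_len(Tn), dd$targets)] <-
          G[cbind(seq_len(Tn), dd$targets)] - 1
        G <- G / Tn
        Gseg <- rowsum(G, dd$seg_id)
        dD <- G %*% Vt
        dVt <- t(G) %*% D
        grads <- list(Wf = t(dD) %*% dd$Fmat,
                      V = dVt,
                      C = t(dVt) %*% Evoc,
                      b = colSums(G),
                      w_copy = c(sum(Gseg * psi$P1), sum(Gseg * psi$P2),
                                 sum(Gseg * psi$P3), sum(Gseg * psi$P4)))
        upd <- adam_step(st, params, clip_gradients(grads), lr_ep)
        st <- upd$state
        params <- upd$params
      }
      losses <- c(losses, ep_loss / n_tok)
    }
  }
  structure(list(schema = schema, grammar = grammar, vocab = vocab,
                 frames = frames, E = E, params = params, k = k,
                 inventories = inventories, losses = losses,
                 config = list(k = k, d2 = d2, epochs = epochs, lr = lr,
                               lambda = lambda, seed = seed)),
            class = "pico_generative")
}

#' @export
print.pico_generative <- function(x, ...) {
  cat("<pico_generative> |vocab| = ", length(x$vocab), ", state dim = ",
      x$config$d2, "\n", sep = "")
  if (length(x$losses)) {
    cat("  teacher-forcing loss: ", round(x$losses[1], 4), " -> ",
        round(utils::tail(x$losses, 1), 4), " over ", length(x$losses),
        " epochs\n", sep = "")
  }
  invisible(x)
}

#' Logit provider backed by a fitted generative model
#'
#' Returns scores for every vocabulary token given the generated prefix;
#' deterministic given (document, prefix). Tokens outside the training
#' vocabulary receive a very low finite score so that constrained decoding
#' still prefers any known allowed token but never fails.
#'
#' @param model a fitted [pico_generative()].
#' @param doc the input document.
#' @return a logit provider for [constrained_decode()].
#' @export
generative_provider <- function(model, doc) {
  bag0 <- table(doc$tokens$surface)
  bag0 <- stats::setNames(as.integer(bag0), names(bag0))
  k <- model$k
  E <- model$E
  unseen <- setdiff(names(bag0), rownames(E))
  if (length(unseen)) {
    E <- rbind(E, token_feature_matrix(unseen, k, salt = 11L))
  }
  # slot inventories restricted to this document's token types
  inv_doc <- lapply(model$inventories,
                    function(w) intersect(w, names(bag0)))
  memo <- new.env(parent = emptyenv())
  memo$len <- -1L
  memo$prefix <- character(0)
  memo$state <- NULL
  list(next_scores = function(prefix) {
    # incremental rescan: constrained decoding extends the prefix by one
    state <- if (memo$len >= 0L && length(prefix) == memo$len + 1L &&
                 identical(prefix[seq_len(memo$len)], memo$prefix)) {
      gen_advance(memo$state, prefix[[length(prefix)]])
    } else {
      gen_scan_prefix(prefix, bag0)
    }
    memo$len <- length(prefix)
    memo$prefix <- prefix
    memo$state <- state
    fstate <- list(last = state$last,
                   frame = if (length(state$stack))
                     state$stack[[length(state$stack)]] else "<none>",
                   bag = state$bag, inslot = state$inslot)
    f <- gen_feature_row(fstate, E, model$frames)
    d <- as.numeric(model$params$Wf %*% f)
    tied <- as.numeric(E %*% (t(model$params$C) %*% d))
    names(tied) <- rownames(E)
    scores <- as.numeric(model$params$V %*% d) + model$params$b +
      tied[model$vocab]
    names(scores) <- model$vocab
    extra <- setdiff(names(bag0), model$vocab)
    if (length(extra)) {
      # surfaces unseen in training score through the feature-tied output
      # embeddings only
      scores <- c(scores, tied[extra])
    }
    nz <- names(state$bag)[state$bag > 0L]
    hit <- match(nz, names(scores))
    ok <- !is.na(hit)
    if (any(ok)) {
      cnts <- state$bag[nz][ok]
      scores[hit[ok]] <- scores[hit[ok]] + model$params$w_copy[1] +
        model$params$w_copy[2] * pmin(cnts, 3) / 3
    }
    rem <- vapply(inv_doc, function(w) {
      if (!length(w)) 0 else sum(state$bag[w])
    }, numeric(1))
    scores[names(inv_doc)] <- scores[names(inv_doc)] +
      model$params$w_copy[3] * pmin(rem, 3) / 3 +
      model$params$w_copy[4] * as.numeric(rem > 0)
    scores
  })
}

#' Predict method for the generative model
#'
#' Runs grammar-constrained greedy decoding on each document and parses the
#' result into an instance forest.
#'
#' @param object a fitted [pico_generative()].
#' @param newdata a `pico_document` or a corpus.
#' @param max_len_factor output length cap as a multiple of the document
#'   length.
#' @param ... unused.
#' @return a forest, or a list of forests.
#' @export
predict.pico_generative <- function(object, newdata, max_len_factor = 4,
                                    ...) {
  decode1 <- function(doc) {
    provider <- generative_provider(object, doc)
    decode_document(provider, object$grammar, doc,
                    max_len = ceiling(max_len_factor * n_tokens(doc)))
  }
  if (inherits(newdata, "pico_document")) return(decode1(newdata))
  lapply(newdata, function(r) {
    decode1(if (is.list(r) && !is.null(r$document)) r$document else r)
  })
}
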