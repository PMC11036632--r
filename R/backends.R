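#' Deterministic mock token encoder
#'
#' Produces a pseudo-embedding per token from a seeded hash of the token
#' surface (and, by default, its position), with no trainable state. Serves
#' as a deterministic stand-in for a contextual encoder in tests of the
#' downstream machinery.
#'
#' @param doc a [tokenize_document()] result.
#' @param dim embedding dimension (default 32).
#' @param position mix the token position into the hash; when `FALSE`, equal
#'   surfaces get equal vectors regardless of position.
#' @param seed integer salt.
#' @return numeric matrix, one row per token.
#' @export
mock_encoder <- function(doc, dim = 32L, position = TRUE, seed = 0L) {
  surf <- doc$tokens$surface
  H <- matrix(0, length(surf), dim)
  for (i in seq_along(surf)) {
    key <- if (position) paste0(surf[i], "\u1f", i) else surf[i]
    H[i, ] <- hashed_embedding(key, dim, salt = seed)
  }
  H
}

# Random Fourier position features: sin/cos of scaled relative position.
# Sums of these features over token pairs retain their distance, which is
# what the compatibility head needs to learn same-sentence grouping.
position_features <- function(n, n_freq = 4L) {
  pos <- seq_len(n) / max(n, 1L)
  do.call(cbind, c(lapply(seq_len(n_freq), function(k) sin(2^k * pi * pos)),
                   lapply(seq_len(n_freq), function(k) cos(2^k * pi * pos))))
}

N_POS_FEAT <- 8L

# --- tiny trainable encoder ------------------------------------------------
# Two layers: a trainable token-embedding lookup over (previous, current,
# next) surfaces plus fixed position features, then a tanh projection to the
# output dimension d. Token ids are resolved against the training
# vocabulary; unseen surfaces map to a dedicated UNK row.

new_tiny_encoder <- function(vocab, d = 32L, m = 16L, seed = 1L) {
  vocab <- unique(vocab)
  with_seed(seed, {
    Emb <- matrix(stats::rnorm((length(vocab) + 1L) * m, sd = 0.5),
                  length(vocab) + 1L, m)
    W2 <- matrix(stats::rnorm(d * (3L * m + N_POS_FEAT), sd = 0.2),
                 d, 3L * m + N_POS_FEAT)
    b2 <- numeric(d)
  })
  structure(list(vocab = vocab, d = d, m = m, Emb = Emb, W2 = W2, b2 = b2),
            class = "tiny_encoder")
}

token_ids <- function(enc, surfaces) {
  i <- match(surfaces, enc$vocab)
  i[is.na(i)] <- length(enc$vocab) + 1L  # UNK row
  i
}

# Context ids and fixed features for a document; UNK id pads the borders.
encoder_inputs <- function(enc, doc) {
  n <- n_tokens(doc)
  ids <- token_ids(enc, doc$tokens$surface)
  pad <- length(enc$vocab) + 1L
  list(prev = c(pad, ids[-n]), cur = ids, nxt = c(ids[-1], pad),
       pos = position_features(n))
}

encoder_forward <- function(enc, inp) {
  X <- cbind(enc$Emb[inp$prev, , drop = FALSE],
             enc$Emb[inp$cur, , drop = FALSE],
             enc$Emb[inp$nxt, , drop = FALSE],
             inp$pos)
  A <- X %*% t(enc$W2)
  A <- sweep(A, 2L, enc$b2, `+`)
  list(X = X, H = tanh(A))
}

#' Encode a document with a backend
#'
#' @param backend a tiny encoder (from [pico_extractive()]'s checkpoint) or
#'   the string `"mock"`.
#' @param doc a [tokenize_document()] result.
#' @return numeric matrix of contextualized token representations, one row
#'   per token.
#' @export
encode_document <- function(backend, doc) {
  if (identical(backend, "mock")) return(mock_encoder(doc))
  stopifnot(inherits(backend, "tiny_encoder"))
  encoder_forward(backend, encoder_inputs(backend, doc))$H
}

# --- Adam optimizer over a named list of arrays ----------------------------

make_adam <- function(params, beta1 = 0.9, beta2 = 0.999, eps = 1e-8) {
  st <- list(m = lapply(params, function(p) p * 0),
             v = lapply(params, function(p) p * 0),
             t = 0L, beta1 = beta1, beta2 = beta2, eps = eps)
  st
}

adam_step <- function(st, params, grads, lr) {
  st$t <- st$t + 1L
  for (nm in names(grads)) {
    g <- grads[[nm]]
    st$m[[nm]] <- st$beta1 * st$m[[nm]] + (1 - st$beta1) * g
    st$v[[nm]] <- st$beta2 * st$v[[nm]] + (1 - st$beta2) * g^2
    mhat <- st$m[[nm]] / (1 - st$beta1^st$t)
    vhat <- st$v[[nm]] / (1 - st$beta2^st$t)
    params[[nm]] <- params[[nm]] - lr * mhat / (sqrt(vhat) + st$eps)
  }
  list(state = st, params = params)
}

# Learning-rate schedule: lr(epoch) = lr0 * lambda^epoch, epoch 0-based.
lr_at_epoch <- function(lr0, lambda, epoch) lr0 * lambda^epoch

# Rescale a gradient list so its global L2 norm is at most max_norm;
# guards the per-document updates against loss spikes.
clip_gradients <- function(grads, max_norm = 5) {
  total <- sqrt(sum(vapply(grads, function(g) sum(g^2), numeric(1))))
  if (is.finite(total) && total > max_norm) {
    grads <- lapply(grads, function(g) g * (max_norm / total))
  }
  grads
}
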