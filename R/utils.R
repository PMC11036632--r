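`%||%` <- function(x, y) if (is.null(x)) y else x

#' Deterministic 31-bit hash of a string
#'
#' Polynomial rolling hash over UTF-8 code points. Used to seed per-token
#' pseudo-embeddings so that backends are deterministic across sessions
#' without storing an embedding table.
#'
#' @param s character scalar.
#' @param salt integer mixed into the hash so independent embedding blocks
#'   decorrelate.
#' @return integer in \[0, 2^31 - 1\].
#' @keywords internal
#' @noRd
hash_string <- function(s, salt = 0L) {
  codes <- utf8ToInt(enc2utf8(s))
  h <- (salt %% 2147483647) + 1
  for (cp in codes) {
    h <- (h * 131 + cp) %% 2147483647
  }
  as.integer(h)
}

# Seeded standard-normal vector for a token surface; deterministic per
# (surface, salt, dim). Restores the caller's RNG state.
hashed_embedding <- function(surface, dim, salt = 0L) {
  old <- if (exists(".Random.seed", envir = globalenv())) {
    get(".Random.seed", envir = globalenv())
  } else {
    NULL
  }
  on.exit({
    if (!is.null(old)) assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(hash_string(surface, salt))
  stats::rnorm(dim) / sqrt(dim)
}

# Embedding matrix (|vocab| x dim) built row-wise by hashed_embedding.
hashed_embedding_matrix <- function(vocab, dim, salt = 0L) {
  E <- matrix(0, nrow = length(vocab), ncol = dim,
              dimnames = list(vocab, NULL))
  for (v in vocab) E[v, ] <- hashed_embedding(v, dim, salt)
  E
}

# Evaluate expr with a local seed, restoring the caller's RNG state.
with_seed <- function(seed, expr) {
  old <- if (exists(".Random.seed", envir = globalenv())) {
    get(".Random.seed", envir = globalenv())
  } else {
    NULL
  }
  on.exit({
    if (!is.null(old)) {
      assign(".Random.seed", old, envir = globalenv())
    } else if (exists(".Random.seed", envir = globalenv())) {
      rm(".Random.seed", envir = globalenv())
    }
  })
  set.seed(seed)
  expr
}

relu <- function(x) pmax(x, 0)

sigmoid <- function(x) 1 / (1 + exp(-x))

# Row-wise softmax of a matrix of logits, numerically stabilised.
softmax_rows <- function(L) {
  m <- apply(L, 1L, max)
  E <- exp(L - m)
  E / rowSums(E)
}

softmax_vec <- function(x) {
  e <- exp(x - max(x))
  e / sum(e)
}

# Collapse runs of whitespace and trim; the normalisation applied before
# string-matching predicted against gold slot fillers.
normalize_filler <- function(x) {
  gsub("^\\s+|\\s+$", "", gsub("\\s+", " ", x))
}

stop_if_not_scalar_chr <- function(x, what) {
  if (!is.character(x) || length(x) != 1L || is.na(x)) {
    stop(what, " must be a single character string", call. = FALSE)
  }
}
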