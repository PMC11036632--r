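#' Predict boundary tags from token representations
#'
#' Two independent affine-plus-softmax heads score each token's
#' representation against the label set of all slots plus the no-slot
#' label; the prediction per token is the argmax of each distribution
#' (ties resolved to the first label in the head's fixed label order).
#'
#' @param H numeric matrix of token representations (tokens x d).
#' @param heads list with `W_s`, `b_s`, `W_e`, `b_e` (each `|labels| x d` /
#'   `|labels|`) and `labels`, the label order with the no-slot label
#'   included.
#' @return a `pico_tags` object; attribute `probs` carries the two
#'   softmax matrices.
#' @export
predict_boundaries <- function(H, heads) {
  if (ncol(H) != ncol(heads$W_s)) stop("dimension mismatch: d = ", ncol(H),
                                       " vs heads d = ", ncol(heads$W_s))
  Ls <- sweep(H %*% t(heads$W_s), 2L, heads$b_s, `+`)
  Le <- sweep(H %*% t(heads$W_e), 2L, heads$b_e, `+`)
  Ps <- softmax_rows(Ls)
  Pe <- softmax_rows(Le)
  tags <- structure(list(start = heads$labels[max.col(Ps, "first")],
                         end = heads$labels[max.col(Pe, "first")]),
                    class = "pico_tags")
  attr(tags, "probs") <- list(start = Ps, end = Pe)
  tags
}

#' Slot-filler representation from its boundary token representations
#'
#' The filler vector is a rectified affine map of the sum of the start and
#' end token representations; the sum makes it symmetric in the two tokens
#' and the ReLU keeps it entrywise non-negative.
#'
#' @param h_s,h_e numeric vectors (the boundary token representations).
#' @param W_r,b_r projection weights (`d x d` / `d`).
#' @return numeric vector of length `d`.
#' @export
filler_representation <- function(h_s, h_e, W_r, b_r) {
  if (length(h_s) != length(h_e) || ncol(W_r) != length(h_s)) {
    stop("dimension mismatch")
  }
  relu(as.numeric(W_r %*% (h_s + h_e)) + b_r)
}

#' Pairwise compatibility of two slot fillers
#'
#' Two linear layers with a ReLU in between and a final sigmoid, applied to
#' the sum of the two filler representations. Because addition commutes the
#' score is exactly symmetric: `compatibility(a, b) == compatibility(b, a)`
#' bit for bit.
#'
#' @param e_i,e_j filler representation vectors.
#' @param model list with `W_h` (`d x d`), `b_h` (`d`), `w` (`d`), `b`
#'   (scalar).
#' @return similarity in (0, 1).
#' @export
compatibility <- function(e_i, e_j, model) {
  if (length(e_i) != length(e_j) || ncol(model$W_h) != length(e_i)) {
    stop("dimension mismatch")
  }
  z <- relu(as.numeric(model$W_h %*% (e_i + e_j)) + model$b_h)
  sigmoid(sum(model$w * z) + model$b)
}

# Pairwise compatibility matrix over rows of a representation matrix.
compatibility_matrix <- function(E, model) {
  n <- nrow(E)
  Q <- diag(1, n)
  if (n > 1L) {
    for (i in seq_len(n - 1L)) {
      for (j in (i + 1L):n) {
        Q[i, j] <- Q[j, i] <- compatibility(E[i, ], E[j, ], model)
      }
    }
  }
  Q
}

#' Assemble clustered slot fillers into an instance forest
#'
#' One template instance is created per cluster; each member filler lands in
#' the slot the tagger assigned it. Instances are then attached under the
#' root along the schema's containment chain: an instance whose template has
#' exactly one (parent template, slot) in the schema is attached to the
#' parent instance when that parent is unique, with empty chain instances
#' (and the root) synthesized when missing. When several parent instances
#' exist the attachment is ambiguous and the instance is left unattached and
#' reported via attribute `unattached` (such forests fail the connectivity
#' check; textual-slot evaluation is unaffected).
#'
#' @param doc the document.
#' @param fillers data.frame of extracted fillers (from [tags_to_spans()]).
#' @param clusters named list: template type -> list of integer vectors
#'   indexing rows of `fillers`.
#' @param schema a [pico_schema()].
#' @return a [instance_forest()] with attribute `unattached`.
#' @export
assemble_instances <- function(doc, fillers, clusters, schema) {
  unknown <- setdiff(fillers$slot, names(schema$slot_owner))
  if (length(unknown)) {
    stop("filler label(s) not in schema: ", paste(unknown, collapse = ", "))
  }
  instances <- list()
  counter <- 0L
  new_instance <- function(type, slots = list()) {
    counter <<- counter + 1L
    id <- paste0("x", counter, "_", tolower(type))
    instances[[id]] <<- template_instance(id, type, slots)
    id
  }
  for (type in intersect(template_names(schema), names(clusters))) {
    for (members in clusters[[type]]) {
      rows <- fillers[members, , drop = FALSE]
      rows <- rows[order(rows$token_start), , drop = FALSE]
      slots <- list()
      for (k in seq_len(nrow(rows))) {
        sp <- span_from_tokens(doc, rows$token_start[k], rows$token_end[k])
        slots[[rows$slot[k]]] <- c(slots[[rows$slot[k]]] %||% list(),
                                   list(sp))
      }
      new_instance(type, slots)
    }
  }
  ids_of <- function(type) {
    names(instances)[vapply(instances, function(i) i$type == type,
                            logical(1))]
  }
  # synthesize the root and missing chain ancestors
  ensure_type <- function(type) {
    ids <- ids_of(type)
    if (length(ids)) return(ids[1])
    id <- new_instance(type)
    if (type != schema$root) {
      parents <- template_parents(schema, type)
      if (length(parents) == 1L) {
        pid <- ensure_type(parents[[1]]$template)
        inst <- instances[[pid]]
        inst$slots[[parents[[1]]$slot]] <-
          c(inst$slots[[parents[[1]]$slot]] %||% list(),
            list(instance_ref(id)))
        instances[[pid]] <<- inst
      }
    }
    id
  }
  root_id <- ensure_type(schema$root)
  unattached <- character(0)
  for (id in names(instances)) {
    type <- instances[[id]]$type
    if (type == schema$root) next
    parents <- template_parents(schema, type)
    if (length(parents) != 1L) {
      unattached <- c(unattached, id)
      next
    }
    ptype <- parents[[1]]$template
    pids <- ids_of(ptype)
    if (!length(pids)) pids <- ensure_type(ptype)
    if (length(pids) > 1L) {
      unattached <- c(unattached, id)
      next
    }
    pinst <- instances[[pids]]
    have <- vapply(pinst$slots[[parents[[1]]$slot]] %||% list(),
                   function(f) f$ref, character(1))
    if (!id %in% have) {
      pinst$slots[[parents[[1]]$slot]] <-
        c(pinst$slots[[parents[[1]]$slot]] %||% list(),
          list(instance_ref(id)))
      instances[[pids]] <- pinst
    }
  }
  forest <- instance_forest(doc$doc_id, unname(instances), root_id)
  attr(forest, "unattached") <- unattached
  forest
}

# --- training --------------------------------------------------------------

init_extractive_params <- function(vocab, labels, d, m, seed) {
  enc <- new_tiny_encoder(vocab, d = d, m = m, seed = seed)
  nl <- length(labels)
  with_seed(seed + 1L, {
    heads <- list(W_s = matrix(stats::rnorm(nl * d, sd = 0.05), nl, d),
                  b_s = numeric(nl),
                  W_e = matrix(stats::rnorm(nl * d, sd = 0.05), nl, d),
                  b_e = numeric(nl), labels = labels)
    compat <- list(W_r = matrix(stats::rnorm(d * d, sd = 0.2), d, d),
                   b_r = rep(0.1, d),
                   W_h = matrix(stats::rnorm(d * d, sd = 0.2), d, d),
                   b_h = rep(0.1, d),
                   w = stats::rnorm(d, sd = 0.2), b = 0)
  })
  list(encoder = enc, heads = heads, compat = compat)
}

#' Fit the extractive template-extraction model
#'
#' Two-stage training of the extractive pipeline on an annotated corpus.
#' Stage one trains the tiny contextual encoder jointly with the two
#' boundary heads by cross-entropy on gold start/end labels (per-document
#' updates, Adam, exponentially decaying learning rate
#' `lr(epoch) = lr * lambda^epoch`). Stage two trains the filler projection
#' and the compatibility head with binary cross-entropy on same-template
#' filler pairs, positive iff the pair shares a gold instance, with seeded
#' negative subsampling for class balance. Finally the clustering threshold
#' is fitted as the midpoint of the mean same-instance and mean
#' different-instance compatibilities on the training pairs.
#'
#' @param corpus annotated corpus (list of `list(document, forest)`).
#' @param schema a [pico_schema()] (default [default_pico_schema()]).
#' @param d encoder output dimension.
#' @param m token-embedding dimension of the tiny encoder.
#' @param epochs tagger training epochs (0 returns the initialization).
#' @param lr,lambda initial learning rate and decay of the schedule.
#' @param compat_epochs full-batch epochs for the compatibility stage.
#' @param compat_lr learning rate for the compatibility stage.
#' @param negative_ratio negatives kept per positive pair.
#' @param seed seed governing initialization, data order and subsampling.
#' @return an object of class `pico_extractive`: the trained encoder, heads,
#'   compatibility model, threshold `tau` and training-loss traces.
#' @seealso [predict.pico_extractive()], [extract_forest()]
#' @export
pico_extractive <- function(corpus, schema = default_pico_schema(),
                            d = 32L, m = 16L, epochs = 20L, lr = 0.02,
                            lambda = 0.95, compat_epochs = 300L,
                            compat_lr = 0.01, negative_ratio = 2,
                            seed = 1L) {
  ann <- Filter(function(r) !is.null(r$forest), corpus)
  if (!length(ann)) stop("corpus has no annotated documents")
  labels <- c(textual_slots(schema), NO_SLOT)
  vocab <- unique(unlist(lapply(ann, function(r) r$document$tokens$surface)))
  params <- init_extractive_params(vocab, labels, d, m, seed)
  enc <- params$encoder
  heads <- params$heads

  prep <- lapply(ann, function(r) {
    fillers <- forest_fillers(r$forest)
    tags <- spans_to_tags(r$document, fillers)
    list(inp = encoder_inputs(enc, r$document),
         ys = match(tags$start, labels), ye = match(tags$end, labels),
         fillers = fillers)
  })

  tag_loss <- numeric(0)
  if (epochs > 0L) {
    pnames <- c("Emb", "W2", "b2", "W_s", "b_s", "W_e", "b_e")
    get_params <- function() list(Emb = enc$Emb, W2 = enc$W2, b2 = enc$b2,
                                  W_s = heads$W_s, b_s = heads$b_s,
                                  W_e = heads$W_e, b_e = heads$b_e)
    st <- make_adam(get_params())
    for (ep in seq_len(epochs)) {
      lr_ep <- lr_at_epoch(lr, lambda, ep - 1L)
      ord <- with_seed(seed + 1000L + ep, sample(seq_along(prep)))
      ep_loss <- 0
      for (di in ord) {
        p <- prep[[di]]
        fw <- encoder_forward(enc, p$inp)
        H <- fw$H
        n <- nrow(H)
        Ls <- sweep(H %*% t(heads$W_s), 2L, heads$b_s, `+`)
        Le <- sweep(H %*% t(heads$W_e), 2L, heads$b_e, `+`)
        Ps <- softmax_rows(Ls); Pe <- softmax_rows(Le)
        ep_loss <- ep_loss -
          mean(log(pmax(Ps[cbind(seq_len(n), p$ys)], 1e-12))) -
          mean(log(pmax(Pe[cbind(seq_len(n), p$ye)], 1e-12)))
        Gs <- Ps; Gs[cbind(seq_len(n), p$ys)] <-
          Gs[cbind(seq_len(n), p$ys)] - 1
        Ge <- Pe; Ge[cbind(seq_len(n), p$ye)] <-
          Ge[cbind(seq_len(n), p$ye)] - 1
        Gs <- Gs / n; Ge <- Ge / n
        dH <- Gs %*% heads$W_s + Ge %*% heads$W_e
        dA <- dH * (1 - fw$H^2)
        dW2 <- t(dA) %*% fw$X
        db2 <- colSums(dA)
        dX <- dA %*% enc$W2
        dEmb <- enc$Emb * 0
        mm <- enc$m
        for (blk in 1:3) {
          idx <- p$inp[[c("prev", "cur", "nxt")[blk]]]
          cols <- ((blk - 1L) * mm + 1L):(blk * mm)
          acc <- rowsum(dX[, cols, drop = FALSE], group = idx)
          rid <- as.integer(rownames(acc))
          dEmb[rid, ] <- dEmb[rid, ] + acc
        }
        grads <- list(Emb = dEmb, W2 = dW2, b2 = db2,
                      W_s = t(Gs) %*% H, b_s = colSums(Gs),
                      W_e = t(Ge) %*% H, b_e = colSums(Ge))
        upd <- adam_step(st, get_params(), grads, lr_ep)
        st <- upd$state
        enc$Emb <- upd$params$Emb; enc$W2 <- upd$params$W2
        enc$b2 <- upd$params$b2
        heads$W_s <- upd$params$W_s; heads$b_s <- upd$params$b_s
        heads$W_e <- upd$params$W_e; heads$b_e <- upd$params$b_e
      }
      tag_loss <- c(tag_loss, ep_loss / length(prep))
    }
  }

  # stage two: filler representations + compatibility on gold pairs
  U <- NULL; pair_i <- integer(0); pair_j <- integer(0); pair_y <- numeric(0)
  offset <- 0L
  for (di in seq_along(prep)) {
    p <- prep[[di]]
    if (!nrow(p$fillers)) next
    H <- encoder_forward(enc, p$inp)$H
    Ud <- H[p$fillers$token_start, , drop = FALSE] +
      H[p$fillers$token_end, , drop = FALSE]
    U <- rbind(U, Ud)
    types <- unname(schema$slot_owner[p$fillers$slot])
    for (type in unique(types)) {
      idx <- which(types == type)
      if (length(idx) < 2L) next
      pr <- utils::combn(idx, 2L)
      pair_i <- c(pair_i, pr[1, ] + offset)
      pair_j <- c(pair_j, pr[2, ] + offset)
      pair_y <- c(pair_y, as.numeric(
        p$fillers$instance[pr[1, ]] == p$fillers$instance[pr[2, ]]))
    }
    offset <- offset + nrow(p$fillers)
  }
  compat <- params$compat
  compat_loss <- numeric(0)
  tau_fit <- list(tau = 0.5, same_mean = NA_real_, diff_mean = NA_real_)
  if (length(pair_y) && any(pair_y == 1) && any(pair_y == 0)) {
    pos <- which(pair_y == 1); neg <- which(pair_y == 0)
    keep_neg <- with_seed(seed + 77L,
      sample(neg, min(length(neg), ceiling(negative_ratio * length(pos)))))
    sel <- sort(c(pos, keep_neg))
    ii <- pair_i[sel]; jj <- pair_j[sel]; yy <- pair_y[sel]
    np <- length(sel)
    get_c <- function() compat
    st <- make_adam(compat)
    for (ep in seq_len(compat_epochs)) {
      E <- pmax(sweep(U %*% t(compat$W_r), 2L, compat$b_r, `+`), 0)
      S <- E[ii, , drop = FALSE] + E[jj, , drop = FALSE]
      Zpre <- sweep(S %*% t(compat$W_h), 2L, compat$b_h, `+`)
      Z <- pmax(Zpre, 0)
      q <- sigmoid(as.numeric(Z %*% compat$w) + compat$b)
      compat_loss <- c(compat_loss,
                       -mean(yy * log(pmax(q, 1e-12)) +
                             (1 - yy) * log(pmax(1 - q, 1e-12))))
      dq <- (q - yy) / np
      dZ <- (dq %o% compat$w) * (Zpre > 0)
      dS <- dZ %*% compat$W_h
      dE <- rowsum(rbind(dS, dS), group = c(ii, jj))
      dEfull <- U * 0
      rid <- as.integer(rownames(dE))
      dEfull[rid, ] <- dE
      Epre_pos <- (sweep(U %*% t(compat$W_r), 2L, compat$b_r, `+`) > 0)
      dApre <- dEfull * Epre_pos
      grads <- list(W_r = t(dApre) %*% U, b_r = colSums(dApre),
                    W_h = t(dZ) %*% S, b_h = colSums(dZ),
                    w = as.numeric(t(Z) %*% dq), b = sum(dq))
      upd <- adam_step(st, compat, grads, compat_lr)
      st <- upd$state
      compat <- upd$params
    }
    # threshold from all training pairs (not just the balanced subsample)
    E <- pmax(sweep(U %*% t(compat$W_r), 2L, compat$b_r, `+`), 0)
    S <- E[pair_i, , drop = FALSE] + E[pair_j, , drop = FALSE]
    q_all <- sigmoid(as.numeric(pmax(
      sweep(S %*% t(compat$W_h), 2L, compat$b_h, `+`), 0) %*% compat$w) +
      compat$b)
    tau_fit <- fit_threshold(q_all, pair_y == 1)
  }

  structure(list(schema = schema, encoder = enc, heads = heads,
                 compat = compat, tau = tau_fit$tau, threshold = tau_fit,
                 losses = list(tagging = tag_loss,
                               compatibility = compat_loss),
                 config = list(d = d, m = m, epochs = epochs, lr = lr,
                               lambda = lambda, seed = seed)),
            class = "pico_extractive")
}

#' @export
print.pico_extractive <- function(x, ...) {
  cat("<pico_extractive> d = ", x$config$d, ", |labels| = ",
      length(x$heads$labels), ", tau = ", round(x$tau, 4), "\n", sep = "")
  if (length(x$losses$tagging)) {
    cat("  tagging loss: ", round(x$losses$tagging[1], 4), " -> ",
        round(utils::tail(x$losses$tagging, 1), 4), " over ",
        length(x$losses$tagging), " epochs\n", sep = "")
  }
  invisible(x)
}

#' Extract an instance forest from one document
#'
#' The full extractive pipeline: encode, predict boundary tags, join them
#' into slot fillers, compute filler representations, route fillers to their
#' owning template, cluster per template (templates with fixed cardinality
#' one pool all fillers into a single instance; others are clustered by
#' [hac_cluster()] at the fitted threshold) and assemble the clusters into a
#' forest.
#'
#' @param model a fitted [pico_extractive()].
#' @param doc a [tokenize_document()] result.
#' @param tau clustering threshold override (default: the fitted one).
#' @return a forest (see [assemble_instances()] for attachment semantics).
#' @export
extract_forest <- function(model, doc, tau = model$tau) {
  schema <- model$schema
  H <- encode_document(model$encoder, doc)
  tags <- predict_boundaries(H, model$heads)
  fillers <- tags_to_spans(doc, tags)
  if (!nrow(fillers)) {
    return(assemble_instances(doc, fillers, list(), schema))
  }
  U <- H[fillers$token_start, , drop = FALSE] +
    H[fillers$token_end, , drop = FALSE]
  E <- pmax(sweep(U %*% t(model$compat$W_r), 2L, model$compat$b_r, `+`), 0)
  types <- unname(schema$slot_owner[fillers$slot])
  clusters <- list()
  for (type in unique(types)) {
    idx <- which(types == type)
    fixed <- !is.null(schema$templates[[type]]$fixed_cardinality)
    clusters[[type]] <- if (fixed || length(idx) == 1L) {
      list(idx)
    } else {
      Q <- compatibility_matrix(E[idx, , drop = FALSE], model$compat)
      lapply(hac_cluster(Q, tau), function(mem) idx[mem])
    }
  }
  assemble_instances(doc, fillers, clusters, schema)
}

#' Predict method for the extractive model
#'
#' @param object a fitted [pico_extractive()].
#' @param newdata a `pico_document`, or a corpus (list of records with a
#'   `document` field).
#' @param ... unused.
#' @return a forest, or a list of forests for a corpus.
#' @export
predict.pico_extractive <- function(object, newdata, ...) {
  if (inherits(newdata, "pico_document")) {
    return(extract_forest(object, newdata))
  }
  lapply(newdata, function(r) {
    extract_forest(object, if (is.list(r) && !is.null(r$document))
      r$document else r)
  })
}
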