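f1_from_counts <- function(tp, fp, fn) {
  p <- if (tp + fp > 0) tp / (tp + fp) else 0
  r <- if (tp + fn > 0) tp / (tp + fn) else 0
  if (p + r == 0) 0 else 2 * p * r / (p + r)
}

# Multiset intersection size of two character vectors.
multiset_tp <- function(pred, gold) {
  if (!length(pred) || !length(gold)) return(0L)
  tp <- 0L
  tg <- table(gold)
  tp_tab <- table(pred)
  common <- intersect(names(tg), names(tp_tab))
  if (length(common)) tp <- sum(pmin(tg[common], tp_tab[common]))
  as.integer(tp)
}

# Per-slot TP/FP/FN for one document pair under the instance-agnostic
# string criterion.
count_doc_string <- function(pred_df, gold_df, slots) {
  out <- matrix(0L, length(slots), 3L,
                dimnames = list(slots, c("tp", "fp", "fn")))
  for (s in union(unique(pred_df$slot), unique(gold_df$slot))) {
    p <- normalize_filler(pred_df$text[pred_df$slot == s])
    g <- normalize_filler(gold_df$text[gold_df$slot == s])
    tp <- multiset_tp(p, g)
    out[s, ] <- c(tp, length(p) - tp, length(g) - tp)
  }
  out
}

# Strict criterion: greedily align predicted to gold instances per template
# by maximal filler overlap, then score within aligned pairs only.
count_doc_strict <- function(pred, gold, slots, schema) {
  out <- matrix(0L, length(slots), 3L,
                dimnames = list(slots, c("tp", "fp", "fn")))
  pf <- forest_fillers(pred)
  gf <- forest_fillers(gold)
  add <- function(slot, tp, fp, fn) {
    out[slot, ] <<- out[slot, ] + c(tp, fp, fn)
  }
  inst_sets <- function(df) {
    split(data.frame(slot = df$slot, text = normalize_filler(df$text)),
          df$instance)
  }
  for (type in union(unique(pf$type), unique(gf$type))) {
    pi <- inst_sets(pf[pf$type == type, , drop = FALSE])
    gi <- inst_sets(gf[gf$type == type, , drop = FALSE])
    if (length(pi) && length(gi)) {
      ov <- matrix(0L, length(pi), length(gi))
      for (a in seq_along(pi)) {
        for (b in seq_along(gi)) {
          ov[a, b] <- multiset_tp(paste(pi[[a]]$slot, pi[[a]]$text),
                                  paste(gi[[b]]$slot, gi[[b]]$text))
        }
      }
      while (length(pi) && length(gi) && max(ov) > 0L) {
        hit <- which(ov == max(ov), arr.ind = TRUE)[1, ]
        a <- hit[1]; b <- hit[2]
        for (s in union(pi[[a]]$slot, gi[[b]]$slot)) {
          p <- pi[[a]]$text[pi[[a]]$slot == s]
          g <- gi[[b]]$text[gi[[b]]$slot == s]
          tp <- multiset_tp(p, g)
          add(s, tp, length(p) - tp, length(g) - tp)
        }
        pi <- pi[-a]; gi <- gi[-b]
        ov <- ov[-a, -b, drop = FALSE]
      }
    }
    for (rest in pi) for (s in unique(rest$slot)) {
      add(s, 0L, sum(rest$slot == s), 0L)
    }
    for (rest in gi) for (s in unique(rest$slot)) {
      add(s, 0L, 0L, sum(rest$slot == s))
    }
  }
  out
}

#' Score predicted forests against gold forests
#'
#' Computes slot-level precision/recall/F1. The default criterion matches
#' predicted to gold fillers one-to-one per slot by exact
#' whitespace-normalized string equality, ignoring instance grouping
#' (appropriate for the extractive engine, whose inter-instance links are
#' heuristic). The strict criterion first aligns predicted to gold
#' instances per template type by greedy maximal filler overlap and only
#' scores fillers inside aligned instance pairs, so mis-grouped fillers
#' count as errors. Absolute scores are not comparable across criteria.
#'
#' Reported: micro F1 (TP/FP/FN pooled over all slots), per-slot F1, and
#' per-template mean F1 (mean over the template's slots with any gold or
#' predicted filler).
#'
#' @param pred,gold single forests or aligned lists of forests.
#' @param schema a [pico_schema()].
#' @param criterion `"string"` (default) or `"strict"`.
#' @return an object of class `pico_eval`: list with `micro_f1`, `counts`
#'   (per-slot TP/FP/FN), `per_slot`, `per_template`, `criterion`.
#' @export
evaluate_forests <- function(pred, gold, schema = default_pico_schema(),
                             criterion = c("string", "strict")) {
  criterion <- match.arg(criterion)
  if (inherits(pred, "pico_forest")) pred <- list(pred)
  if (inherits(gold, "pico_forest")) gold <- list(gold)
  if (length(pred) != length(gold)) stop("pred and gold must align")
  slots <- names(schema$slot_owner)
  counts <- matrix(0L, length(slots), 3L,
                   dimnames = list(slots, c("tp", "fp", "fn")))
  for (i in seq_along(pred)) {
    counts <- counts + if (criterion == "string") {
      count_doc_string(forest_fillers(pred[[i]]),
                       forest_fillers(gold[[i]]), slots)
    } else {
      count_doc_strict(pred[[i]], gold[[i]], slots, schema)
    }
  }
  micro <- f1_from_counts(sum(counts[, "tp"]), sum(counts[, "fp"]),
                          sum(counts[, "fn"]))
  per_slot <- apply(counts, 1L, function(r) f1_from_counts(r[1], r[2], r[3]))
  active <- rowSums(counts) > 0
  per_template <- vapply(template_names(schema), function(t) {
    sl <- intersect(textual_slots(schema, t), slots[active])
    if (!length(sl)) return(NA_real_)
    mean(per_slot[sl])
  }, numeric(1))
  structure(list(micro_f1 = micro, counts = counts, per_slot = per_slot,
                 per_template = per_template, criterion = criterion),
            class = "pico_eval")
}

#' @export
print.pico_eval <- function(x, digits = 3, ...) {
  cat("<pico_eval> criterion = ", x$criterion, "\n", sep = "")
  cat("  micro F1: ", round(x$micro_f1, digits), "  (TP ",
      sum(x$counts[, "tp"]), ", FP ", sum(x$counts[, "fp"]), ", FN ",
      sum(x$counts[, "fn"]), ")\n", sep = "")
  pt <- x$per_template[!is.na(x$per_template)]
  if (length(pt)) {
    cat("  per-template mean F1:\n")
    for (t in names(pt)) {
      cat(sprintf("    %-20s %.3f\n", t, pt[[t]]))
    }
  }
  invisible(x)
}

#' Mean absolute deviation of inferred template cardinality
#'
#' For each template type, the mean over documents of the absolute
#' difference between the predicted and the gold number of instances.
#' Templates whose cardinality is structurally fixed at one (marked
#' `fixed_cardinality` in the schema) are excluded by default since both
#' sides always agree on them.
#'
#' @param pred,gold aligned lists of forests.
#' @param schema a [pico_schema()].
#' @param templates template types to report (default: all non-fixed).
#' @return named numeric vector of mean absolute deviations.
#' @export
cardinality_mad <- function(pred, gold, schema = default_pico_schema(),
                            templates = NULL) {
  if (inherits(pred, "pico_forest")) pred <- list(pred)
  if (inherits(gold, "pico_forest")) gold <- list(gold)
  if (length(pred) != length(gold)) stop("pred and gold must align")
  if (is.null(templates)) {
    templates <- Filter(function(t)
      is.null(schema$templates[[t]]$fixed_cardinality),
      template_names(schema))
  }
  out <- stats::setNames(numeric(length(templates)), templates)
  for (t in templates) {
    devs <- vapply(seq_along(pred), function(i) {
      np <- sum(vapply(pred[[i]]$instances, function(x) x$type == t,
                       logical(1)))
      ng <- sum(vapply(gold[[i]]$instances, function(x) x$type == t,
                       logical(1)))
      abs(np - ng)
    }, numeric(1))
    out[t] <- mean(devs)
  }
  out
}
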