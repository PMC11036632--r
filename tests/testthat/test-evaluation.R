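mini_forest <- function(doc, fillers, id = "f") {
  # one Outcome instance per unique group value
  inst <- lapply(split(seq_len(nrow(fillers)), fillers$group), function(ix) {
    slots <- list()
    for (i in ix) {
      sp <- picostruct:::span_from_tokens(doc, fillers$ts[i], fillers$te[i])
      slots[[fillers$slot[i]]] <- c(slots[[fillers$slot[i]]] %||% list(),
                                    list(sp))
    }
    template_instance(paste0(id, ix[1]), "Outcome", slots)
  })
  `%||%` <- function(x, y) if (is.null(x)) y else x
  instance_forest(doc$doc_id, c(inst, list(
    template_instance("root", "Publication", list()))), "root")
}

`%||%` <- function(x, y) if (is.null(x)) y else x

test_that("slot F1 counts true/false positives per slot string", {
  sch <- default_pico_schema()
  doc <- tokenize_document("d", "week 24 16 week 12 8")
  gold <- mini_forest(doc, data.frame(
    slot = c("TimePoint", "PercentageAffected"), ts = c(1L, 3L),
    te = c(2L, 3L), group = c(1, 1)), "g")

  perfect <- evaluate_forests(gold, gold, sch)
  expect_equal(perfect$micro_f1, 1.0)

  empty <- instance_forest("d", list(
    template_instance("root", "Publication", list())), "root")
  expect_equal(evaluate_forests(empty, gold, sch)$micro_f1, 0)

  # one exact hit, one spurious, one missed: P = R = 0.5, F1 = 0.5
  pred <- mini_forest(doc, data.frame(
    slot = c("TimePoint", "PercentageAffected"), ts = c(1L, 6L),
    te = c(2L, 6L), group = c(1, 1)), "p")
  ev <- evaluate_forests(pred, gold, sch)
  expect_equal(ev$micro_f1, 0.5)
  expect_equal(sum(ev$counts[, "tp"]), 1L)
  expect_equal(sum(ev$counts[, "fp"]), 1L)
  expect_equal(sum(ev$counts[, "fn"]), 1L)

  # a duplicated prediction against a single gold filler: one TP, one FP
  dup <- mini_forest(doc, data.frame(
    slot = c("TimePoint", "TimePoint"), ts = c(1L, 1L), te = c(2L, 2L),
    group = c(1, 2)), "p")
  goldt <- mini_forest(doc, data.frame(
    slot = "TimePoint", ts = 1L, te = 2L, group = 1), "g")
  ev2 <- evaluate_forests(dup, goldt, sch)
  expect_equal(unname(ev2$counts["TimePoint", ]), c(1L, 1L, 0L))
})

test_that("micro F1 is invariant to document order and monotone in quality", {
  sch <- default_pico_schema()
  corpus <- small_corpus(6, seed = 47)
  gold <- lapply(corpus, `[[`, "forest")
  # a deliberately partial prediction: drop every second document's forest
  pred <- gold
  empty <- instance_forest("x", list(
    template_instance("root", "Publication", list())), "root")
  pred[c(2, 4, 6)] <- list(empty)
  base <- evaluate_forests(pred, gold, sch)$micro_f1
  perm <- sample(seq_along(gold))
  expect_equal(evaluate_forests(pred[perm], gold[perm], sch)$micro_f1,
               base)
  # restoring one correct forest never lowers the score
  better <- pred
  better[[2]] <- gold[[2]]
  expect_gte(evaluate_forests(better, gold, sch)$micro_f1, base)
})

test_that("strict scoring penalizes mis-grouped fillers", {
  sch <- default_pico_schema()
  doc <- tokenize_document("d", "week 24 16 week 12 8")
  fillers <- data.frame(slot = c("TimePoint", "PercentageAffected",
                                 "TimePoint", "PercentageAffected"),
                        ts = c(1L, 3L, 4L, 6L), te = c(2L, 3L, 5L, 6L),
                        group = c(1, 1, 2, 2))
  gold <- mini_forest(doc, fillers, "g")
  swapped <- fillers
  swapped$group <- c(1, 2, 2, 1)  # right strings, wrong grouping
  pred <- mini_forest(doc, swapped, "p")
  expect_equal(evaluate_forests(pred, gold, sch)$micro_f1, 1.0)
  strict <- evaluate_forests(pred, gold, sch, criterion = "strict")
  expect_lt(strict$micro_f1, 1.0)
})

test_that("cardinality deviation averages per-document count differences", {
  sch <- default_pico_schema()
  corpus <- small_corpus(5, seed = 53)
  gold <- lapply(corpus, `[[`, "forest")
  expect_true(all(cardinality_mad(gold, gold, sch) == 0))
  # templates with fixed cardinality are excluded from the report
  expect_false(any(c("Publication", "ClinicalTrial", "Population") %in%
                     names(cardinality_mad(gold, gold, sch))))

  doc <- tokenize_document("d", "week 24 16 week 12 8")
  one <- mini_forest(doc, data.frame(slot = "TimePoint", ts = 1L, te = 2L,
                                     group = 1), "g")
  three <- mini_forest(doc, data.frame(
    slot = rep("TimePoint", 3), ts = c(1L, 1L, 4L), te = c(2L, 2L, 5L),
    group = 1:3), "p")
  mad <- cardinality_mad(list(three), list(one), sch,
                         templates = "Outcome")
  expect_equal(unname(mad), 2)

  # hand-computed fixture check across documents
  mad2 <- cardinality_mad(list(three, one), list(one, one), sch,
                          templates = "Outcome")
  expect_equal(unname(mad2), mean(c(2, 0)))
})
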