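test_that("boundary heads compute affine-softmax argmax per token", {
  d <- 8L
  labels <- c("A", "B", "O")
  zero <- list(W_s = matrix(0, 3, d), b_s = numeric(3),
               W_e = matrix(0, 3, d), b_e = numeric(3), labels = labels)
  H <- matrix(rnorm(5 * d), 5, d)
  tags <- predict_boundaries(H, zero)
  # uniform distributions: argmax falls on the first label
  expect_true(all(tags$start == "A") && all(tags$end == "A"))
  probs <- attr(tags, "probs")
  expect_equal(rowSums(probs$start), rep(1, 5), tolerance = 1e-6)
  expect_equal(rowSums(probs$end), rep(1, 5), tolerance = 1e-6)

  # random heads versus a direct affine+softmax oracle
  set.seed(4)
  heads <- list(W_s = matrix(rnorm(3 * d), 3, d), b_s = rnorm(3),
                W_e = matrix(rnorm(3 * d), 3, d), b_e = rnorm(3),
                labels = labels)
  tags <- predict_boundaries(H, heads)
  for (i in 1:5) {
    ls <- as.numeric(heads$W_s %*% H[i, ] + heads$b_s)
    le <- as.numeric(heads$W_e %*% H[i, ] + heads$b_e)
    expect_identical(tags$start[i], labels[which.max(ls)])
    expect_identical(tags$end[i], labels[which.max(le)])
    expect_equal(attr(tags, "probs")$start[i, ],
                 exp(ls) / sum(exp(ls)), tolerance = 1e-6)
  }
  expect_error(predict_boundaries(matrix(0, 2, 4), heads), "mismatch")
})

test_that("filler representations follow the rectified sum formula", {
  d <- 6L
  expect_equal(filler_representation(numeric(d), numeric(d),
                                     matrix(1, d, d), numeric(d)),
               numeric(d))
  set.seed(9)
  W <- matrix(rnorm(d * d), d, d); b <- rnorm(d)
  for (rep in 1:20) {
    hs <- rnorm(d); he <- rnorm(d)
    e <- filler_representation(hs, he, W, b)
    oracle <- pmax(as.numeric(W %*% (hs + he)) + b, 0)
    expect_lt(max(abs(e - oracle)), 1e-6)
    expect_true(all(e >= 0))
    # symmetric in the two boundary tokens
    expect_identical(e, filler_representation(he, hs, W, b))
  }
})

test_that("compatibility is a sigmoid two-layer score, exactly symmetric", {
  d <- 6L
  zero <- list(W_h = matrix(0, d, d), b_h = numeric(d), w = numeric(d),
               b = 0)
  expect_equal(compatibility(rnorm(d), rnorm(d), zero), 0.5)
  set.seed(14)
  model <- list(W_h = matrix(rnorm(d * d), d, d), b_h = rnorm(d),
                w = rnorm(d), b = rnorm(1))
  for (rep in 1:25) {
    a <- abs(rnorm(d)); b2 <- abs(rnorm(d))
    q <- compatibility(a, b2, model)
    z <- pmax(as.numeric(model$W_h %*% (a + b2)) + model$b_h, 0)
    oracle <- 1 / (1 + exp(-(sum(model$w * z) + model$b)))
    expect_lt(abs(q - oracle), 1e-6)
    expect_true(q > 0 && q < 1)
    # symmetry holds bit for bit, not approximately
    expect_identical(q, compatibility(b2, a, model))
  }
})

test_that("clusters assemble into typed instances under the root chain", {
  sch <- default_pico_schema()
  doc <- tokenize_document(
    "d", "At week 24 , 16 percent and at week 12 , 8 percent .")
  fillers <- data.frame(
    slot = c("PercentageAffected", "PercentageAffected", "TimePoint",
             "TimePoint"),
    token_start = c(5L, 12L, 2L, 9L), token_end = c(5L, 12L, 3L, 10L),
    stringsAsFactors = FALSE)
  clusters <- list(Outcome = list(c(1L, 3L), c(2L, 4L)))
  forest <- assemble_instances(doc, fillers, clusters, sch)
  types <- vapply(forest$instances, `[[`, character(1), "type")
  expect_identical(sum(types == "Outcome"), 2L)
  oc <- forest$instances[types == "Outcome"]
  texts <- lapply(oc, function(ti) {
    sort(unname(vapply(unlist(ti$slots, recursive = FALSE), `[[`,
                       character(1), "text")))
  })
  expect_true(any(vapply(texts, identical, logical(1), c("16", "week 24"))))
  expect_true(any(vapply(texts, identical, logical(1), c("8", "week 12"))))
  # chain ancestors synthesized: Publication root, ClinicalTrial, Arm
  expect_identical(unname(forest$instances[[forest$root]]$type),
                   "Publication")
  expect_length(validate_forest(forest, sch), 0L)

  # no fillers: a bare root instance
  bare <- assemble_instances(doc, fillers[0, ], list(), sch)
  expect_length(bare$instances, 1L)
  expect_identical(bare$instances[[1]]$type, "Publication")

  # labels outside the schema are refused
  expect_error(assemble_instances(
    doc, data.frame(slot = "Bogus", token_start = 1L, token_end = 1L),
    list(Outcome = list(1L)), sch), "not in schema")
})

test_that("gold-indicator similarity recovers gold partitions exactly", {
  corpus <- small_corpus(12, seed = 33)
  for (r in corpus) {
    fillers <- forest_fillers(r$forest)
    for (type in unique(fillers$type)) {
      f <- fillers[fillers$type == type, , drop = FALSE]
      cl <- hac_cluster(picostruct:::oracle_qmat(f), tau = 0.5)
      gold_parts <- split(seq_len(nrow(f)), f$instance)
      expect_identical(length(cl), length(gold_parts))
      canon <- function(p) sort(vapply(p, paste, character(1),
                                       collapse = ","))
      expect_identical(canon(cl), canon(unname(gold_parts)))
    }
  }
})

test_that("extraction is deterministic and degrades gracefully", {
  corpus <- small_corpus(16, seed = 51)
  fit <- pico_extractive(corpus[1:12], epochs = 4L, compat_epochs = 40L,
                         seed = 3L)
  f1 <- extract_forest(fit, corpus[[13]]$document)
  f2 <- extract_forest(fit, corpus[[13]]$document)
  expect_true(forest_equal(f1, f2, with_spans = TRUE))
  preds <- predict(fit, corpus[13:16])
  expect_length(preds, 4L)
  for (p in preds) expect_s3_class(p, "pico_forest")
})
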