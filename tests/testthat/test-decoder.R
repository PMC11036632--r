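step_state <- function(grammar, tokens) {
  state <- picostruct:::new_decoding_state()
  for (tok in tokens) state <- picostruct:::decoding_step(state, tok,
                                                          grammar)
  state
}

test_that("allowed-token sets follow the decoding stack", {
  sch <- default_pico_schema()
  g <- build_grammar(sch)
  doc <- tokenize_document("d", "insulin 10 mg daily")

  expect_identical(allowed_next_tokens(NULL, g, doc),
                   "[start:Publication]")

  # inside an open textual slot: document token types plus the end special
  st <- step_state(g, c("[start:Publication]", "[start:describes]",
                        "[start:ClinicalTrial]", "[start:hasArm]",
                        "[start:Arm]", "[start:hasIntervention]",
                        "[start:Intervention]", "[start:hasMedication]",
                        "[start:Medication]", "[start:Drug]"))
  expect_setequal(allowed_next_tokens(st, g, doc),
                  c("insulin", "10", "mg", "daily", "[end:Drug]"))

  # inside a template frame: its slots' starts plus its end special
  st <- step_state(g, c("[start:Publication]", "[start:describes]",
                        "[start:ClinicalTrial]"))
  expect_setequal(allowed_next_tokens(st, g, doc),
                  c("[start:NumberPatientsCT]", "[start:CTDuration]",
                    "[start:hasPopulation]", "[start:hasEvidenceQuality]",
                    "[start:hasArm]", "[start:hasDiffBetweenGroups]",
                    "[end:ClinicalTrial]"))

  # a template-valued slot admits only its child's start, then its own end
  st <- step_state(g, c("[start:Publication]", "[start:describes]"))
  expect_identical(allowed_next_tokens(st, g, doc),
                   "[start:ClinicalTrial]")
  st <- step_state(g, c("[start:Publication]", "[start:describes]",
                        "[start:ClinicalTrial]", "[end:ClinicalTrial]"))
  expect_identical(allowed_next_tokens(st, g, doc), "[end:describes]")

  # after the root closes nothing is allowed
  st <- step_state(g, c("[start:Publication]", "[end:Publication]"))
  expect_length(allowed_next_tokens(st, g, doc), 0L)
})

test_that("allowed sets equal the exhaustive derivation oracle", {
  sch <- tiny_schema_2()
  g <- build_grammar(sch)
  doc_types <- c("aleph", "beth")
  seqs <- enumerate_derivations(sch, doc_types, max_len = 12L)
  seqs <- lapply(strsplit(seqs, " ", fixed = TRUE), identity)
  expect_gt(length(seqs), 10L)
  prefixes <- unique(unlist(lapply(seqs, function(s) {
    lapply(0:(length(s) - 1L), function(k) s[seq_len(k)])
  }), recursive = FALSE))
  expect_gt(length(prefixes), 50L)
  for (pre in prefixes) {
    oracle <- oracle_continuations(seqs, pre)
    state <- step_state(g, pre)
    got <- allowed_next_tokens(state, g, doc_types)
    # every continuation the enumeration finds must be allowed
    expect_true(all(oracle %in% got))
    # for prefixes short enough that any allowed continuation completes
    # within the enumeration bound, the sets are exactly equal
    if (length(pre) <= 6L) expect_setequal(got, oracle)
  }
})

test_that("teacher-forced decoding reproduces gold linearizations", {
  sch <- default_pico_schema()
  g <- build_grammar(sch)
  for (r in small_corpus(8, seed = 61)) {
    gold <- linearize(r$forest, sch, r$document)
    provider <- teacher_provider(gold,
                                 vocab = unique(r$document$tokens$surface))
    out <- constrained_decode(provider, g, r$document,
                              max_len = 4L * nrow(r$document$tokens))
    expect_identical(as.character(out), gold)
    expect_false(attr(out, "truncated"))
    forest <- decode_document(provider, g, r$document)
    expect_true(forest_equal(forest, r$forest))
  }
})

test_that("adversarial providers still yield derivable output", {
  sch <- default_pico_schema()
  g <- build_grammar(sch)
  r <- small_corpus(1, seed = 71)[[1]]
  vocab <- c(unique(r$document$tokens$surface), g$specials)
  for (seed in 1:20) {
    out <- constrained_decode(uniform_provider(vocab, seed), g, r$document,
                              max_len = 150L)
    expect_true(validate_sequence(as.character(out), g, r$document))
    forest <- decode_document(uniform_provider(vocab, seed), g, r$document,
                              max_len = 150L)
    expect_length(validate_forest(forest, sch), 0L)
  }
})

test_that("decoding is deterministic and respects the length cap", {
  sch <- default_pico_schema()
  g <- build_grammar(sch)
  r <- small_corpus(1, seed = 81)[[1]]
  vocab <- c(unique(r$document$tokens$surface), g$specials)
  p <- uniform_provider(vocab, seed = 5)
  a <- constrained_decode(p, g, r$document, max_len = 120L)
  b <- constrained_decode(uniform_provider(vocab, seed = 5), g, r$document,
                          max_len = 120L)
  expect_identical(a, b)

  # max_len = 2: root start plus one token, then auto-closed and flagged
  out <- constrained_decode(p, g, r$document, max_len = 2L)
  expect_true(attr(out, "truncated"))
  expect_identical(as.character(out)[1], "[start:Publication]")
  expect_true(validate_sequence(as.character(out), g, r$document))
  expect_error(constrained_decode(p, g, r$document, max_len = 1L),
               "max_len")
})

test_that("stack depth stays within the schema containment depth", {
  sch <- default_pico_schema()
  g <- build_grammar(sch)
  r <- small_corpus(1, seed = 91)[[1]]
  vocab <- c(unique(r$document$tokens$surface), g$specials)
  bound <- 2L * picostruct:::schema_depth(sch)
  for (seed in 1:5) {
    out <- constrained_decode(uniform_provider(vocab, seed), g, r$document,
                              max_len = 200L)
    depth <- 0L
    for (tok in as.character(out)) {
      sp <- picostruct:::special_parts(tok)
      if (is.null(sp)) next
      depth <- depth + if (sp$kind == "start") 1L else -1L
      expect_lte(depth, bound)
    }
  }
})
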