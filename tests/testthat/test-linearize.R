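test_that("grammar rules instantiate the four rule shapes per template", {
  # one template, one textual slot: HEAD + terminator + one slot rule
  g1 <- build_grammar(tiny_schema_1())
  expect_length(g1$rules, 3L)
  expect_identical(g1$start, "Medication_HEAD")

  sch <- default_pico_schema()
  g <- build_grammar(sch)
  expected <- sum(vapply(sch$templates,
                         function(t) 2L + length(t$slots), integer(1)))
  expect_length(g$rules, expected)

  # a template with zero slots derives only its empty bracket pair
  z <- pico_schema(list(list(name = "Empty", slots = list())),
                   root = "Empty")
  gz <- build_grammar(z)
  expect_length(gz$rules, 2L)
  seqs <- enumerate_derivations(z, character(0), max_len = 6)
  expect_identical(seqs, "[start:Empty] [end:Empty]")
})

test_that("linearization emits bracketed slots in canonical order", {
  sch <- tiny_schema_1()
  doc <- tokenize_document("d", "patients received insulin daily")
  f <- instance_forest("d", list(template_instance(
    "m1", "Medication",
    list(Drug = list(picostruct:::span_from_tokens(doc, 3, 3))))), "m1")
  expect_identical(
    linearize(f, sch, doc),
    c("[start:Medication]", "[start:Drug]", "insulin", "[end:Drug]",
      "[end:Medication]"))

  # an instance with no filled slots is just its bracket pair
  empty <- instance_forest("d", list(template_instance("m1", "Medication")),
                           "m1")
  expect_identical(linearize(empty, sch, doc),
                   c("[start:Medication]", "[end:Medication]"))

  # two fillers of one slot serialize in document order
  f2 <- instance_forest("d", list(template_instance(
    "m1", "Medication",
    list(Drug = list(picostruct:::span_from_tokens(doc, 3, 3),
                     picostruct:::span_from_tokens(doc, 1, 1))))), "m1")
  lin <- linearize(f2, sch, doc)
  expect_identical(lin[c(3, 6)], c("patients", "insulin"))
})

test_that("parsing inverts linearization on generated forests", {
  sch <- default_pico_schema()
  g <- build_grammar(sch)
  corpus <- small_corpus(25, seed = 77)
  for (r in corpus) {
    lin <- linearize(r$forest, sch, r$document)
    expect_true(validate_sequence(lin, g, r$document))
    back <- parse_linearization(lin, g, r$document)
    expect_true(forest_equal(r$forest, back))
    expect_length(validate_forest(back, sch), 0L)
  }
})

test_that("derivability checking accepts exactly the bracket-balanced forms", {
  sch <- default_pico_schema()
  g <- build_grammar(sch)
  expect_true(validate_sequence(c("[start:Publication]",
                                  "[end:Publication]"), g))
  expect_false(validate_sequence(c("[start:Publication]"), g))
  expect_false(validate_sequence(c("[start:Publication]", "[end:Arm]"), g))
  expect_false(validate_sequence(c("[start:Arm]", "[end:Arm]"), g))
  # ordinary tokens are only allowed inside textual slots
  expect_false(validate_sequence(c("[start:Publication]", "insulin",
                                   "[end:Publication]"), g))
})

test_that("parse errors carry position and expectation; free text is flagged", {
  sch <- tiny_schema_1()
  g <- build_grammar(sch)
  doc <- tokenize_document("d", "insulin given daily")
  expect_error(parse_linearization(
    c("[start:Medication]", "[start:Drug]", "insulin"), g, doc),
    "unexpected end of input")
  expect_error(parse_linearization(
    c("[start:Medication]", "[end:Drug]"), g, doc), "position 2")

  # filler text absent from the document parses but is flagged free text
  got <- parse_linearization(
    c("[start:Medication]", "[start:Drug]", "aspirin", "[end:Drug]",
      "[end:Medication]"), g, doc)
  dr <- got$instances[[got$root]]$slots$Drug[[1]]
  expect_identical(dr$text, "aspirin")
  expect_true(isTRUE(attr(dr, "free_text")))
  # in-document fillers are grounded to spans
  got2 <- parse_linearization(
    c("[start:Medication]", "[start:Drug]", "insulin", "[end:Drug]",
      "[end:Medication]"), g, doc)
  dr2 <- got2$instances[[got2$root]]$slots$Drug[[1]]
  expect_identical(dr2$token_start, 1L)
})

test_that("nesting depth of derivable sequences respects the schema", {
  sch <- default_pico_schema()
  g <- build_grammar(sch)
  corpus <- small_corpus(5, seed = 15)
  max_depth <- picostruct:::schema_depth(sch) * 2L  # template + slot frames
  for (r in corpus) {
    lin <- linearize(r$forest, sch, r$document)
    depth <- 0L; worst <- 0L
    for (tok in lin) {
      sp <- picostruct:::special_parts(tok)
      if (is.null(sp)) next
      depth <- depth + if (sp$kind == "start") 1L else -1L
      worst <- max(worst, depth)
    }
    expect_identical(depth, 0L)
    expect_lte(worst, max_depth)
  }
})
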