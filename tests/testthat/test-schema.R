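test_that("the default schema declares the ten trial templates", {
  sch <- default_pico_schema()
  expect_setequal(template_names(sch),
                  c("Arm", "ClinicalTrial", "DiffBetweenGroups", "Endpoint",
                    "EvidenceQuality", "Intervention", "Medication",
                    "Outcome", "Population", "Publication"))
  expect_identical(sch$root, "Publication")
  fixed <- names(Filter(function(t) !is.null(t$fixed_cardinality),
                        sch$templates))
  expect_setequal(fixed, c("Publication", "ClinicalTrial", "Population"))
})

test_that("schema construction validates its structural invariants", {
  one <- pico_schema(list(list(name = "T", slots = list(
    list(name = "s", kind = "textual")))), root = "T")
  expect_s3_class(one, "pico_schema")
  expect_length(template_names(one), 1L)

  # self-referential template slot is a cycle
  expect_error(pico_schema(list(list(name = "A", slots = list(
    list(name = "x", kind = "template", child = "A")))), root = "A"),
    "cyclic")
  # slot owned by two templates
  expect_error(pico_schema(list(
    list(name = "A", slots = list(list(name = "s", kind = "textual"),
                                  list(name = "c", kind = "template",
                                       child = "B"))),
    list(name = "B", slots = list(list(name = "s", kind = "textual")))),
    root = "A"), "more than one template")
  # unknown child template
  expect_error(pico_schema(list(list(name = "A", slots = list(
    list(name = "x", kind = "template", child = "Z")))), root = "A"),
    "unknown template")
  # unreachable template
  expect_error(pico_schema(list(
    list(name = "A", slots = list(list(name = "s", kind = "textual"))),
    list(name = "B", slots = list(list(name = "t", kind = "textual")))),
    root = "A"), "not reachable")
})

test_that("schema files round-trip through YAML and JSON", {
  sch <- default_pico_schema()
  for (ext in c(".yaml", ".json")) {
    path <- tempfile(fileext = ext)
    write_schema(sch, path)
    expect_equal(load_schema(path), sch)
    # idempotence: loading the re-serialized schema is stable
    path2 <- tempfile(fileext = ext)
    write_schema(load_schema(path), path2)
    expect_equal(load_schema(path2), sch)
  }
})

test_that("forest validation reports typing, cycle and connectivity faults", {
  sch <- tiny_schema_2()
  doc <- tokenize_document("d", "drug alpha 10 mg")
  sp <- function(s, e) picostruct:::span_from_tokens(doc, s, e)

  ok <- instance_forest("d", list(
    template_instance("t1", "Trial",
                      list(Name = list(sp(2, 2)),
                           hasDose = list(instance_ref("d1")))),
    template_instance("d1", "Dose", list(Amount = list(sp(3, 3))))), "t1")
  expect_length(validate_forest(ok, sch), 0L)

  disconnected <- instance_forest("d", list(
    template_instance("t1", "Trial", list(Name = list(sp(2, 2)))),
    template_instance("d1", "Dose", list(Amount = list(sp(3, 3))))), "t1")
  expect_match(paste(validate_forest(disconnected, sch), collapse = ";"),
               "disconnected")

  # an instance that transitively contains itself (necessarily also a
  # typing fault, since template graphs are acyclic by construction)
  cyc <- instance_forest("d", list(
    template_instance("t1", "Trial",
                      list(hasDose = list(instance_ref("d1")))),
    template_instance("d1", "Dose",
                      list(Amount = list(instance_ref("t1"))))), "t1")
  expect_match(paste(validate_forest(cyc, sch), collapse = ";"), "cycle")

  # textual slot holding an instance reference
  bad <- instance_forest("d", list(
    template_instance("t1", "Trial",
                      list(Name = list(instance_ref("d1")),
                           hasDose = list(instance_ref("d1")))),
    template_instance("d1", "Dose", list())), "t1")
  expect_match(paste(validate_forest(bad, sch), collapse = ";"),
               "non-span")
})

test_that("forests accepted by validation are exactly the linearizable ones", {
  sch <- default_pico_schema()
  corpus <- small_corpus(15, seed = 9)
  for (r in corpus) {
    expect_length(validate_forest(r$forest, sch), 0L)
    expect_silent(linearize(r$forest, sch, r$document))
  }
  # breaking connectivity must make linearize refuse
  r <- corpus[[1]]
  broken <- r$forest
  orphan <- template_instance("orphan", "Medication", list())
  broken$instances <- c(broken$instances, list(orphan = orphan))
  expect_gt(length(validate_forest(broken, sch)), 0L)
  expect_error(linearize(broken, sch, r$document), "does not linearize")
})
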