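#' Default slot-filler vocabulary pools for the synthetic corpus
#'
#' Invented filler values for every textual slot of the default schema,
#' constructed so that no token occurs in more than one pool and no pool
#' token occurs in the sentence scaffolds, and so that multi-word fillers
#' have unambiguous continuations (the first token determines the rest
#' within any document). These properties make string-match evaluation on
#' fixtures unambiguous. The vocabulary is synthetic scaffolding: it
#' exercises the structure of trial abstracts, not their language.
#'
#' @return named list mapping slot names to character vectors.
#' @export
default_filler_pools <- function() {
  list(
    Author = c("Smithson", "Alvarez", "Okafor", "Petrov", "Tanaka",
               "Lindqvist"),
    Journal = c("Trialia", "Medicorum", "Clinica", "Evidentia"),
    PublicationYear = as.character(1991:2024),
    PMID = as.character(9100001:9100040),
    NumberPatientsCT = as.character(seq(200L, 398L, 2L)),
    CTDuration = c("26 weeks", "78 weeks", "104 weeks"),
    Country = c("Atlantis", "Borduria", "Syldavia", "Elbonia", "Genovia"),
    Ethnicity = c("Nordic", "Andean", "Polynesian"),
    Precondition = c("elevated glycemia", "ocular hypertension",
                     "impaired tolerance"),
    RandomizationMethod = c("computer allocation", "sealed envelopes"),
    Blinding = c("double masking", "open label"),
    FinalNumPatientsArm = as.character(400:499),
    Frequency = c("once daily", "twice daily", "thrice weekly"),
    Drug = c("metfarin", "glybexol", "latanox", "timodrine", "insuletta",
             "dorzomide"),
    DoseValue = as.character(600:699),
    DoseUnit = c("mg", "IU", "mcg"),
    PercentageAffected = c("12.5", "8.3", "21.7", "5.4", "33.6", "17.9",
                           "26.8", "44.2"),
    NumberAffected = as.character(110:199),
    TimePoint = paste("week", c(12, 24, 36, 48, 60, 72, 96)),
    ObservedResult = c("marked improvement", "moderate decline",
                       "stable response", "partial remission",
                       "notable worsening"),
    EndpointDescription = c("glycated hemoglobin", "intraocular pressure",
                            "plasma lipids"),
    MeasurementDevice = c("tonometer", "photometer", "glucometer"),
    AggregationMethod = c("mean change", "median change"),
    DiffGroupAbsValue = c("0.451", "1.302", "2.150", "0.875"),
    PValueChangeValue = c("0.001", "0.013", "0.042", "0.210")
  )
}

#' Configuration for the synthetic-corpus generator
#'
#' @param n_documents number of documents to generate.
#' @param seed mandatory integer seed; the corpus is a deterministic
#'   function of the configuration.
#' @param cardinality named list of integer ranges `c(lo, hi)` for the
#'   per-document instance counts of the multi-instance templates (`Arm`,
#'   `Outcome`, `DiffBetweenGroups`) and for the number of `Country`
#'   fillers of the Population instance. Publication, ClinicalTrial and
#'   Population are structurally fixed at one instance; EvidenceQuality is
#'   generated once per document; Intervention/Medication are one per arm
#'   and Endpoint one per outcome.
#' @param pools filler vocabulary pools, see [default_filler_pools()].
#' @return a `fixture_config` list.
#' @export
fixture_config <- function(n_documents, seed,
                           cardinality = list(),
                           pools = default_filler_pools()) {
  if (missing(seed)) stop("seed is mandatory")
  card <- utils::modifyList(list(Arm = c(1L, 2L), Outcome = c(1L, 4L),
                                 DiffBetweenGroups = c(1L, 2L),
                                 Country = c(1L, 2L)),
                            cardinality)
  for (nm in names(card)) {
    if (any(card[[nm]] < 1L)) stop("cardinality ranges must be >= 1")
  }
  structure(list(n_documents = n_documents, seed = seed,
                 cardinality = card, pools = pools),
            class = "fixture_config")
}

# Draw n values from a pool, without replacement when possible.
sample_pool <- function(pool, n) {
  if (!length(pool)) stop("empty vocabulary pool")
  sample(pool, n, replace = n > length(pool))
}

rint <- function(range) {
  if (range[1] == range[2]) range[1] else sample(range[1]:range[2], 1L)
}

# One templated sentence. `parts` alternates literal scaffold strings and
# list(slot=, value=, instance=) filler parts; returns the sentence text and
# the character offsets of each filler relative to the sentence start.
render_sentence <- function(parts) {
  text <- ""
  fillers <- list()
  for (p in parts) {
    if (nzchar(text)) text <- paste0(text, " ")
    if (is.character(p)) {
      text <- paste0(text, p)
    } else {
      cs <- nchar(text)
      text <- paste0(text, p$value)
      fillers[[length(fillers) + 1L]] <-
        list(slot = p$slot, instance = p$instance,
             char_start = cs, char_end = nchar(text), text = p$value)
    }
  }
  list(text = paste0(text, " ."), fillers = fillers)
}

#' Generate a synthetic corpus of trial-like abstracts with gold forests
#'
#' Each document is a multi-sentence abstract assembled from templated
#' sentences in which every gold textual slot filler occurs verbatim at its
#' recorded character span. Each gold forest has a single Publication root,
#' one ClinicalTrial, Population and EvidenceQuality instance, a sampled
#' number of Arm, Outcome and DiffBetweenGroups instances (one Intervention
#' and Medication per arm, one Endpoint per outcome), and is acyclic and
#' connected by construction. The textual fillers of one instance share a
#' sentence, mirroring how trial abstracts state one result per sentence.
#'
#' @param config a [fixture_config()].
#' @return list of `list(document, forest)` records, classed `pico_corpus`.
#' @export
generate_corpus <- function(config) {
  stopifnot(inherits(config, "fixture_config"))
  with_seed(config$seed, {
    recs <- lapply(seq_len(config$n_documents), function(k) {
      generate_document(paste0("syn", k), config)
    })
  })
  structure(recs, class = "pico_corpus")
}

generate_document <- function(doc_id, config) {
  pools <- config$pools
  card <- config$cardinality
  n_arms <- rint(card$Arm)
  n_out <- rint(card$Outcome)
  n_diff <- rint(card$DiffBetweenGroups)
  n_ctry <- rint(card$Country)
  arm_of_outcome <- sort(sample(seq_len(n_arms), n_out, replace = TRUE))

  draw <- function(slot, n = 1L) sample_pool(pools[[slot]], n)
  sentences <- list()
  say <- function(...) {
    sentences[[length(sentences) + 1L]] <<- render_sentence(list(...))
  }
  fill <- function(slot, inst, value) {
    list(slot = slot, value = value, instance = inst)
  }

  say("Report by", fill("Author", "pub", draw("Author")), "in",
      fill("Journal", "pub", draw("Journal")), "(",
      fill("PublicationYear", "pub", draw("PublicationYear")),
      ") under identifier", fill("PMID", "pub", draw("PMID")))
  say("This trial enrolled",
      fill("NumberPatientsCT", "ct", draw("NumberPatientsCT")),
      "participants over", fill("CTDuration", "ct", draw("CTDuration")))
  ctry <- draw("Country", n_ctry)
  pop_parts <- list("Participants from", fill("Country", "pop", ctry[1]))
  if (n_ctry > 1L) {
    pop_parts <- c(pop_parts, list("and", fill("Country", "pop", ctry[2])))
  }
  pop_parts <- c(pop_parts,
                 list("with", fill("Precondition", "pop",
                                   draw("Precondition")),
                      "were recruited"))
  sentences[[length(sentences) + 1L]] <- render_sentence(pop_parts)
  say("Most were of", fill("Ethnicity", "pop", draw("Ethnicity")),
      "descent")
  say("Allocation used",
      fill("RandomizationMethod", "eq", draw("RandomizationMethod")),
      "with", fill("Blinding", "eq", draw("Blinding")))

  drugs <- draw("Drug", n_arms)
  doses <- draw("DoseValue", n_arms)
  pct <- draw("PercentageAffected", n_out)
  tps <- draw("TimePoint", n_out)
  naff <- draw("NumberAffected", n_out)
  obs <- draw("ObservedResult", n_out)
  epd <- draw("EndpointDescription", n_out)
  dev <- draw("MeasurementDevice", n_out)
  agg <- draw("AggregationMethod", n_out)
  fnp <- draw("FinalNumPatientsArm", n_arms)
  freq <- draw("Frequency", n_arms)
  for (a in seq_len(n_arms)) {
    arm_id <- paste0("arm", a)
    say("One arm retained",
        fill("FinalNumPatientsArm", arm_id, fnp[a]), "subjects")
    say("Treatment was administered",
        fill("Frequency", paste0("iv", a), freq[a]))
    say("Subjects received", fill("Drug", paste0("med", a), drugs[a]),
        "at", fill("DoseValue", paste0("med", a), doses[a]),
        fill("DoseUnit", paste0("med", a), draw("DoseUnit")))
    for (o in which(arm_of_outcome == a)) {
      out_id <- paste0("out", o)
      say("At", fill("TimePoint", out_id, tps[o]), ",",
          fill("PercentageAffected", out_id, pct[o]),
          "percent responded (", fill("NumberAffected", out_id, naff[o]),
          "cases ) with", fill("ObservedResult", out_id, obs[o]))
      say("The endpoint",
          fill("EndpointDescription", paste0("ep", o), epd[o]),
          "was assessed by",
          fill("MeasurementDevice", paste0("ep", o), dev[o]), "as",
          fill("AggregationMethod", paste0("ep", o), agg[o]))
    }
  }
  dva <- draw("DiffGroupAbsValue", n_diff)
  pvs <- draw("PValueChangeValue", n_diff)
  for (dd in seq_len(n_diff)) {
    say("Between groups the difference was",
        fill("DiffGroupAbsValue", paste0("dbg", dd), dva[dd]),
        "with significance",
        fill("PValueChangeValue", paste0("dbg", dd), pvs[dd]))
  }

  # assemble text and absolute filler offsets
  text <- ""
  fillers <- list()
  for (s in sentences) {
    off <- nchar(text) + if (nzchar(text)) 1L else 0L
    text <- if (nzchar(text)) paste(text, s$text) else s$text
    for (f in s$fillers) {
      f$char_start <- f$char_start + off
      f$char_end <- f$char_end + off
      fillers[[length(fillers) + 1L]] <- f
    }
  }
  doc <- tokenize_document(doc_id, text)

  slots_of <- function(inst) {
    mine <- Filter(function(f) f$instance == inst, fillers)
    out <- list()
    for (f in mine) {
      tk <- align_span(doc, f$char_start, f$char_end)
      sp <- text_span(doc_id, f$char_start, f$char_end, f$text,
                      tk[1], tk[2], full_text = text)
      out[[f$slot]] <- c(out[[f$slot]] %||% list(), list(sp))
    }
    out
  }
  instances <- list()
  addi <- function(id, type, slots) {
    instances[[length(instances) + 1L]] <<-
      template_instance(id, type, slots)
  }
  for (o in seq_len(n_out)) {
    addi(paste0("ep", o), "Endpoint", slots_of(paste0("ep", o)))
    addi(paste0("out", o), "Outcome",
         c(slots_of(paste0("out", o)),
           list(hasEndpoint = list(instance_ref(paste0("ep", o))))))
  }
  for (a in seq_len(n_arms)) {
    addi(paste0("med", a), "Medication", slots_of(paste0("med", a)))
    addi(paste0("iv", a), "Intervention",
         c(slots_of(paste0("iv", a)),
           list(hasMedication = list(instance_ref(paste0("med", a))))))
    outs <- which(arm_of_outcome == a)
    addi(paste0("arm", a), "Arm",
         c(slots_of(paste0("arm", a)),
           list(hasIntervention = list(instance_ref(paste0("iv", a))),
                # sprintf keeps zero-length outs zero-length (paste0 would
                # recycle to a single dangling "out")
                hasOutcome = lapply(sprintf("out%d", outs), instance_ref))))
  }
  for (dd in seq_len(n_diff)) {
    addi(paste0("dbg", dd), "DiffBetweenGroups", slots_of(paste0("dbg", dd)))
  }
  addi("pop", "Population", slots_of("pop"))
  addi("eq", "EvidenceQuality", slots_of("eq"))
  addi("ct", "ClinicalTrial",
       c(slots_of("ct"),
         list(hasPopulation = list(instance_ref("pop")),
              hasEvidenceQuality = list(instance_ref("eq")),
              hasArm = lapply(paste0("arm", seq_len(n_arms)), instance_ref),
              hasDiffBetweenGroups = lapply(paste0("dbg", seq_len(n_diff)),
                                            instance_ref))))
  addi("pub", "Publication",
       c(slots_of("pub"), list(describes = list(instance_ref("ct")))))
  list(document = doc, forest = instance_forest(doc_id, instances, "pub"))
}

#' Gold-indicator compatibility oracle
#'
#' Returns the compatibility function a perfect model would learn: 1 for two
#' fillers belonging to the same gold instance, 0 otherwise (symmetric by
#' construction). Used to test that threshold clustering recovers gold
#' partitions and cardinalities independently of any trained weights.
#'
#' @param forest the gold forest.
#' @return function taking two rows of [forest_fillers()] (or any objects
#'   with an `instance` field) and returning 0 or 1.
#' @export
oracle_similarity <- function(forest) {
  known <- unique(forest_fillers(forest)$instance)
  function(a, b) {
    ia <- if (is.list(a)) a$instance else a
    ib <- if (is.list(b)) b$instance else b
    if (!ia %in% known || !ib %in% known) stop("filler not in gold forest")
    as.numeric(identical(ia, ib))
  }
}

# Similarity matrix over a filler data.frame under the gold oracle.
oracle_qmat <- function(fillers) {
  outer(fillers$instance, fillers$instance,
        function(a, b) as.numeric(a == b))
}
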