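#' Construct a template schema
#'
#' A schema declares the template types of the data model, the slots of each
#' template and, for template-valued slots, the child template type. It is the
#' single source of truth for the tagging label set, for routing extracted
#' slot fillers to templates, for the linearization orderings and for the
#' production rules of the decoding grammar.
#'
#' Structural requirements enforced here:
#' * slot names are globally unique — every slot is owned by exactly one
#'   template type;
#' * template-valued slots reference a declared template type and the
#'   template-reference graph is acyclic;
#' * the root template exists and every template type is reachable from it
#'   through template-valued slots.
#'
#' @param templates list of template specifications. Each element is a list
#'   with `name` (character), `slots` (list of `list(name, kind, child)`,
#'   where `kind` is `"textual"` or `"template"` and `child` names the child
#'   template type for template-valued slots) and optionally
#'   `fixed_cardinality` (positive integer; templates whose instance count per
#'   document is structurally fixed, e.g. a single Publication record).
#' @param root name of the root template type.
#' @return an object of class `pico_schema`.
#' @seealso [default_pico_schema()], [load_schema()], [validate_forest()]
#' @export
pico_schema <- function(templates, root) {
  stop_if_not_scalar_chr(root, "root")
  tnames <- vapply(templates, function(t) t$name, character(1))
  if (anyDuplicated(tnames)) {
    stop("duplicate template names: ",
         paste(unique(tnames[duplicated(tnames)]), collapse = ", "))
  }
  specs <- list()
  slot_owner <- character(0)
  for (tpl in templates) {
    slots <- lapply(tpl$slots %||% list(), function(s) {
      kind <- match.arg(s$kind, c("textual", "template"))
      if (kind == "template") {
        if (is.null(s$child)) {
          stop("template-valued slot '", s$name, "' lacks a child template")
        }
        if (!s$child %in% tnames) {
          stop("slot '", s$name, "' references unknown template '",
               s$child, "'")
        }
      }
      list(name = s$name, kind = kind, child = s$child %||% NA_character_,
           owner = tpl$name)
    })
    snames <- vapply(slots, `[[`, character(1), "name")
    if (anyDuplicated(snames)) {
      stop("duplicate slot names within template '", tpl$name, "'")
    }
    clash <- intersect(snames, names(slot_owner))
    if (length(clash)) {
      stop("slot name(s) owned by more than one template: ",
           paste(clash, collapse = ", "))
    }
    slot_owner[snames] <- tpl$name
    fc <- tpl$fixed_cardinality %||% NULL
    if (!is.null(fc) && (!is.numeric(fc) || fc < 1)) {
      stop("fixed_cardinality must be a positive integer")
    }
    specs[[tpl$name]] <- list(name = tpl$name, slots = slots,
                              fixed_cardinality = fc)
  }
  if (!root %in% tnames) stop("root template '", root, "' not declared")

  # acyclicity of the template-reference graph (depth-first search)
  color <- setNames(rep(0L, length(tnames)), tnames)  # 0 new, 1 open, 2 done
  visit <- function(t) {
    if (color[[t]] == 1L) stop("cyclic template references involving '",
                               t, "'")
    if (color[[t]] == 2L) return(invisible())
    color[t] <<- 1L
    for (s in specs[[t]]$slots) {
      if (s$kind == "template") visit(s$child)
    }
    color[t] <<- 2L
    invisible()
  }
  for (t in tnames) visit(t)

  # reachability from root
  reach <- character(0)
  queue <- root
  while (length(queue)) {
    t <- queue[[1]]; queue <- queue[-1]
    if (t %in% reach) next
    reach <- c(reach, t)
    for (s in specs[[t]]$slots) {
      if (s$kind == "template") queue <- c(queue, s$child)
    }
  }
  unreachable <- setdiff(tnames, reach)
  if (length(unreachable)) {
    stop("template(s) not reachable from root: ",
         paste(unreachable, collapse = ", "))
  }

  structure(list(templates = specs, root = root, slot_owner = slot_owner),
            class = "pico_schema")
}

#' @export
print.pico_schema <- function(x, ...) {
  cat("<pico_schema> ", length(x$templates), " templates, ",
      length(x$slot_owner), " slots, root = ", x$root, "\n", sep = "")
  for (t in x$templates) {
    kinds <- vapply(t$slots, `[[`, character(1), "kind")
    fc <- if (!is.null(t$fixed_cardinality)) {
      paste0(" [cardinality ", t$fixed_cardinality, "]")
    } else ""
    cat("  ", t$name, fc, ": ", sum(kinds == "textual"), " textual, ",
        sum(kinds == "template"), " template slot(s)\n", sep = "")
  }
  invisible(x)
}

#' Template type names of a schema
#' @param schema a [pico_schema()].
#' @return character vector.
#' @export
template_names <- function(schema) names(schema$templates)

template_spec <- function(schema, type) {
  spec <- schema$templates[[type]]
  if (is.null(spec)) stop("unknown template type '", type, "'")
  spec
}

slot_spec <- function(schema, slot) {
  owner <- schema$slot_owner[[slot]]
  if (is.null(owner)) stop("unknown slot '", slot, "'")
  for (s in schema$templates[[owner]]$slots) if (s$name == slot) return(s)
  stop("internal: slot index inconsistent")  # nocov
}

#' Textual slot names of a schema (optionally for one template)
#' @param schema a [pico_schema()].
#' @param template optional template type name.
#' @return character vector of slot names.
#' @export
textual_slots <- function(schema, template = NULL) {
  tpls <- if (is.null(template)) schema$templates
          else schema$templates[template]
  unlist(lapply(tpls, function(t) {
    vapply(Filter(function(s) s$kind == "textual", t$slots),
           `[[`, character(1), "name")
  }), use.names = FALSE)
}

# (parent template, slot) pairs referencing `type`; used to find the unique
# containment path when the extractive engine attaches instances.
template_parents <- function(schema, type) {
  out <- list()
  for (t in schema$templates) {
    for (s in t$slots) {
      if (s$kind == "template" && identical(s$child, type)) {
        out[[length(out) + 1L]] <- list(template = t$name, slot = s$name)
      }
    }
  }
  out
}

# Maximum nesting depth of the containment graph, root = depth 1.
schema_depth <- function(schema) {
  depth <- function(type) {
    kids <- Filter(function(s) s$kind == "template",
                   schema$templates[[type]]$slots)
    if (!length(kids)) return(1L)
    1L + max(vapply(kids, function(s) depth(s$child), integer(1)))
  }
  depth(schema$root)
}

schema_to_list <- function(schema) {
  list(
    root = schema$root,
    templates = lapply(unname(schema$templates), function(t) {
      tl <- list(
        name = t$name,
        slots = lapply(t$slots, function(s) {
          sl <- list(name = s$name, kind = s$kind)
          if (s$kind == "template") sl$child <- s$child
          sl
        })
      )
      if (!is.null(t$fixed_cardinality)) {
        tl$fixed_cardinality <- t$fixed_cardinality
      }
      tl
    })
  )
}

#' Load a template schema from YAML or JSON
#'
#' The file must contain keys `root` and `templates`, each template with
#' `name` and `slots` (`name`, `kind`, and `child` for template-valued
#' slots), optionally `fixed_cardinality`. Loading validates all structural
#' schema invariants. `load_schema()` and [write_schema()] round-trip.
#'
#' @param path file path (`.yaml`/`.yml` or `.json`), or a list already in
#'   that shape.
#' @return a [pico_schema()].
#' @export
load_schema <- function(path) {
  cfg <- if (is.list(path)) {
    path
  } else {
    stop_if_not_scalar_chr(path, "path")
    if (grepl("\\.ya?ml$", path, ignore.case = TRUE)) {
      yaml::read_yaml(path)
    } else {
      jsonlite::read_json(path, simplifyVector = FALSE)
    }
  }
  if (is.null(cfg$templates) || is.null(cfg$root)) {
    stop("schema config needs 'templates' and 'root'")
  }
  pico_schema(cfg$templates, cfg$root)
}

#' Write a schema to YAML or JSON
#' @param schema a [pico_schema()].
#' @param path output path; format chosen by extension as in [load_schema()].
#' @return `path`, invisibly.
#' @export
write_schema <- function(schema, path) {
  lst <- schema_to_list(schema)
  if (grepl("\\.ya?ml$", path, ignore.case = TRUE)) {
    yaml::write_yaml(lst, path)
  } else {
    jsonlite::write_json(lst, path, auto_unbox = TRUE, pretty = TRUE)
  }
  invisible(path)
}

#' The default 10-template PICO schema
#'
#' The shipped data model covers the design and key results of a randomized
#' controlled trial with ten template types derived from the C-TrO ontology
#' of clinical-trial concepts: Publication (the root record), ClinicalTrial,
#' Population, EvidenceQuality, Arm, Intervention, Medication, Outcome,
#' Endpoint and DiffBetweenGroups. Publication, ClinicalTrial and Population
#' always occur exactly once per document and carry `fixed_cardinality = 1`.
#'
#' The slot inventory is a documented, config-overridable subset of the full
#' ontology (the complete inventory lives with the annotated corpus); it
#' retains the slots needed to express a complete trial record, e.g. `Drug`,
#' `DoseValue`, `DoseUnit` and `Frequency` for treatments, `PercentageAffected`,
#' `NumberAffected`, `TimePoint` and `ObservedResult` for outcomes, and
#' bibliographic slots such as `Journal`, `PMID` and `PublicationYear`.
#' Use [load_schema()] to substitute the full inventory.
#'
#' @return a [pico_schema()] with 10 template types.
#' @export
default_pico_schema <- function() {
  txt <- function(name) list(name = name, kind = "textual")
  tpl <- function(name, child) list(name = name, kind = "template",
                                    child = child)
  pico_schema(list(
    list(name = "Publication",
         slots = list(txt("Author"), txt("Journal"), txt("PublicationYear"),
                      txt("PMID"), tpl("describes", "ClinicalTrial")),
         fixed_cardinality = 1),
    list(name = "ClinicalTrial",
         slots = list(txt("NumberPatientsCT"), txt("CTDuration"),
                      tpl("hasPopulation", "Population"),
                      tpl("hasEvidenceQuality", "EvidenceQuality"),
                      tpl("hasArm", "Arm"),
                      tpl("hasDiffBetweenGroups", "DiffBetweenGroups")),
         fixed_cardinality = 1),
    list(name = "Population",
         slots = list(txt("Country"), txt("Ethnicity"), txt("Precondition")),
         fixed_cardinality = 1),
    list(name = "EvidenceQuality",
         slots = list(txt("RandomizationMethod"), txt("Blinding"))),
    list(name = "Arm",
         slots = list(txt("FinalNumPatientsArm"),
                      tpl("hasIntervention", "Intervention"),
                      tpl("hasOutcome", "Outcome"))),
    list(name = "Intervention",
         slots = list(txt("Frequency"), tpl("hasMedication", "Medication"))),
    list(name = "Medication",
         slots = list(txt("Drug"), txt("DoseValue"), txt("DoseUnit"))),
    list(name = "Outcome",
         slots = list(txt("PercentageAffected"), txt("NumberAffected"),
                      txt("TimePoint"), txt("ObservedResult"),
                      tpl("hasEndpoint", "Endpoint"))),
    list(name = "Endpoint",
         slots = list(txt("EndpointDescription"), txt("MeasurementDevice"),
                      txt("AggregationMethod"))),
    list(name = "DiffBetweenGroups",
         slots = list(txt("DiffGroupAbsValue"), txt("PValueChangeValue")))
  ), root = "Publication")
}
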