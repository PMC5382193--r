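#' @title Minimal openEHR object model
#' @description
#' openEHR uses two-level modelling: generic reference models (RMs) plus
#' domain archetypes constraining them.  This module carries just enough
#' of the RM and archetype structure for metadata modelling: the closed
#' ten-RM registry, `atNNNN` internal codes, ontology terms with optional
#' external terminology bindings, datapoints (elements, clusters, slots)
#' and the archetype itself with its five mandatory sections (archetype
#' ID, concept, language, definition, ontology) and four optional ones
#' (specialization, description, invariants, revision history).
#' @name openehr-model
NULL

# Closed reference-model registry: five entry RMs, two structure RMs,
# three data RMs.
RM_TABLE <- data.frame(
  name = c("Observation", "Evaluation", "Action", "Instruction",
           "Admin Entry",
           "Composition", "Section",
           "Element", "Cluster", "Structure"),
  category = c(rep("entry", 5L), rep("structure", 2L), rep("data", 3L)),
  stringsAsFactors = FALSE
)

#' The openEHR reference-model registry
#'
#' @return A data frame with columns `name` and `category` (`entry`,
#'   `structure`, `data`); five entry RMs, two structure RMs and three
#'   data-structure RMs.
#' @export
#' @examples
#' table(rm_registry()$category)
rm_registry <- function() RM_TABLE

#' Reference a reference model by name
#'
#' @param name One of the registry names (case-sensitive).
#' @return An object of class `reference_model` with fields `name` and
#'   `category`.
#' @export
reference_model <- function(name) {
  i <- match(name, RM_TABLE$name)
  if (is.na(i)) {
    stop("unknown reference model '", name, "'; valid: ",
         paste(RM_TABLE$name, collapse = ", "), call. = FALSE)
  }
  structure(list(name = RM_TABLE$name[i], category = RM_TABLE$category[i]),
            class = "reference_model")
}

#' @export
print.reference_model <- function(x, ...) {
  cat(sprintf("<RM %s (%s)>\n", x$name, x$category))
  invisible(x)
}

is_internal_code <- function(x) {
  is.character(x) & grepl("^at[0-9]{4}$", x)
}

#' Sequential internal-code allocator
#'
#' Archetype datapoints are denoted by `atNNNN` internal codes;
#' allocation is sequential in document order so serialisation is
#' deterministic.  `at0000` is reserved for the archetype concept and is
#' handed out first.
#'
#' @return An allocator object; call `alloc$new_code()` for the next
#'   code.
#' @export
code_allocator <- function() {
  env <- new.env(parent = emptyenv())
  env$n <- 0L
  env$new_code <- function() {
    code <- sprintf("at%04d", env$n)
    env$n <- env$n + 1L
    code
  }
  class(env) <- "code_allocator"
  env
}

#' Construct an ontology term
#'
#' Pairs an internal code with its real name and definition, and
#' optionally with an external terminology binding (an `ODMLID` alias).
#'
#' @param code Internal code (`atNNNN`).
#' @param name Term name.
#' @param definition Term definition (defaults to the name).
#' @param binding_alias Optional `ODMLID` alias string.
#' @return An object of class `ontology_term`.
#' @export
ontology_term <- function(code, name, definition = name,
                          binding_alias = NULL) {
  stopifnot(is_internal_code(code), is.character(name), nzchar(name))
  if (!is.null(binding_alias) && !is_alias(binding_alias)) {
    stop("binding alias '", binding_alias,
         "' is not a valid ODMLID alias", call. = FALSE)
  }
  structure(list(code = code, name = name, definition = definition,
                 binding_alias = binding_alias),
            class = "ontology_term")
}

# openEHR datatypes reachable through the odML datatype mapping, plus the
# interval form prescribed for start/end time pairs.
OPENEHR_DATATYPES <- c("text", "count", "quantity", "date_time",
                       "multimedia", "URI", "boolean",
                       "interval_of_date_time", "coded_text")

#' Construct a datapoint
#'
#' A datapoint is one node of an archetype definition: an *element*
#' (typed leaf, possibly with predefined enumeration codes), a *cluster*
#' (named grouping with children) or a *slot* (a plug-in point for other
#' archetypes).
#'
#' @param code Internal code (`atNNNN`).
#' @param kind One of `"element"`, `"cluster"`, `"slot"`.
#' @param datatype openEHR datatype, required for elements.
#' @param occurrences Integer vector `c(lower, upper)`; `NA` upper means
#'   unbounded.
#' @param enum_codes Optional character vector of internal codes, one per
#'   predefined enumeration item (elements only).
#' @param children List of child datapoints (clusters only).
#' @param allowed_archetypes Character vector of archetype id patterns
#'   (slots only).
#' @return An object of class `datapoint`.
#' @export
datapoint <- function(code, kind = c("element", "cluster", "slot"),
                      datatype = NULL, occurrences = c(0L, 1L),
                      enum_codes = NULL, children = list(),
                      allowed_archetypes = character()) {
  kind <- match.arg(kind)
  stopifnot(is_internal_code(code))
  occurrences <- as.integer(occurrences)
  stopifnot(length(occurrences) == 2L, occurrences[1L] >= 0L)
  if (!is.na(occurrences[2L]) && occurrences[2L] < occurrences[1L]) {
    stop("occurrences upper bound below lower bound for ", code,
         call. = FALSE)
  }
  if (kind == "element") {
    if (is.null(datatype)) {
      stop("element ", code, " needs a datatype", call. = FALSE)
    }
    if (length(children) > 0L) {
      stop("element ", code, " cannot have children", call. = FALSE)
    }
  }
  if (kind == "cluster" && !is.null(datatype)) {
    stop("cluster ", code, " cannot carry a datatype", call. = FALSE)
  }
  if (kind == "slot" && length(allowed_archetypes) == 0L) {
    stop("slot ", code, " needs allowed_archetypes", call. = FALSE)
  }
  structure(
    list(code = code, kind = kind, datatype = datatype,
         occurrences = occurrences, enum_codes = enum_codes,
         children = children, allowed_archetypes = allowed_archetypes),
    class = "datapoint"
  )
}

# All internal codes appearing in a definition tree (node codes plus
# enumeration codes), in document order.
definition_codes <- function(dp) {
  codes <- dp$code
  if (!is.null(dp$enum_codes)) codes <- c(codes, dp$enum_codes)
  for (child in dp$children) codes <- c(codes, definition_codes(child))
  codes
}

#' Construct an archetype
#'
#' The five mandatory sections (archetype ID, concept, language,
#' definition, ontology) must be populated; the four optional ones
#' (specialization, description, invariants, revision history) may be
#' absent.
#'
#' @param archetype_id Archetype identifier, e.g.
#'   `"openEHR-EHR-CLUSTER.electrode.v1"`.
#' @param concept Internal code of the concept (normally `at0000`).
#' @param definition Root [datapoint()].
#' @param ontology List of [ontology_term()] objects covering every code
#'   used in the definition.
#' @param rm A [reference_model()] or RM name.
#' @param language Language code (default `"en"`).
#' @param specialization,description,invariants_section,revision_history
#'   Optional section texts.
#' @param lifecycle_state Free-text lifecycle state (default
#'   `"author_draft"`).
#' @return An object of class `archetype`.
#' @export
archetype <- function(archetype_id, concept, definition, ontology, rm,
                      language = "en", specialization = NULL,
                      description = NULL, invariants_section = NULL,
                      revision_history = NULL,
                      lifecycle_state = "author_draft") {
  if (is.character(rm)) rm <- reference_model(rm)
  stopifnot(is.character(archetype_id), nzchar(archetype_id),
            is_internal_code(concept), inherits(definition, "datapoint"),
            is.list(ontology), inherits(rm, "reference_model"),
            is.character(language), nzchar(language))
  structure(
    list(archetype_id = archetype_id, concept = concept,
         language = language, definition = definition,
         ontology = ontology, rm = rm,
         specialization = specialization, description = description,
         invariants_section = invariants_section,
         revision_history = revision_history,
         lifecycle_state = lifecycle_state),
    class = "archetype"
  )
}

#' @export
print.archetype <- function(x, ...) {
  cat(sprintf("<archetype %s>\n  RM: %s  concept: %s  terms: %d\n",
              x$archetype_id, x$rm$name, x$concept, length(x$ontology)))
  invisible(x)
}

ontology_codes <- function(a) {
  vapply(a$ontology, function(t) t$code, character(1))
}
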