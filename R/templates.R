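#' @title Report templates
#' @description
#' Templates are the third openEHR layer: they wire archetypes together,
#' add constraints, and reduce datapoint sets for a concrete use case.
#' The EEG/ERP experiment is modelled as a `Report` Composition whose
#' four slots take a Problem/Diagnosis Evaluation, a Medication order
#' Instruction, an Experiment scenario Cluster and an EEG/ERP result
#' Observation.  Stimulus-focused templates then reduce the Stimulus
#' archetype's datapoints to the subset a particular stimulus family
#' (movie, pulse, ramp, ...) needs; reductions only ever remove
#' datapoints.
#' @name templates
NULL

# Slot name -> reference model the filling archetype must be based on.
REPORT_SLOT_RMS <- c(evaluation = "Evaluation", instruction = "Instruction",
                     cluster = "Cluster", observation = "Observation")

#' Compose a Report template
#'
#' @param fills Named character vector mapping slot names (`evaluation`,
#'   `instruction`, `cluster`, `observation`) to registry archetype
#'   names.  May be empty for a bare Report template.
#' @param reductions Named list: archetype name to character vector of
#'   retained datapoint codes (see [reduce_template()]).
#' @param registry An [load_registry()] data frame used to check slot
#'   fills; defaults to the packaged registry.
#' @param archetypes Named list of [archetype()] objects (names as in
#'   the registry) backing generated entries; required for code-level
#'   reduction checks.
#' @return An object of class `ehr_template`.
#' @export
#' @examples
#' t <- compose_report_template(c(observation = "EEG/ERP result"))
#' t$slot_fills
compose_report_template <- function(fills = character(),
                                    reductions = list(),
                                    registry = load_registry(),
                                    archetypes = list()) {
  fills <- unlist(fills)
  if (length(fills) > 0L) {
    if (is.null(names(fills)) || any(!nzchar(names(fills)))) {
      stop("composition error: fills must be named by slot", call. = FALSE)
    }
    unknown_slots <- setdiff(names(fills), names(REPORT_SLOT_RMS))
    if (length(unknown_slots)) {
      stop("composition error: unknown slot(s): ",
           paste(unknown_slots, collapse = ", "), call. = FALSE)
    }
    for (slot in names(fills)) {
      nm <- fills[[slot]]
      i <- match(nm, registry$name)
      if (is.na(i)) {
        stop("composition error: '", nm,
             "' is not a registry archetype", call. = FALSE)
      }
      want <- REPORT_SLOT_RMS[[slot]]
      got <- registry$rm[i]
      if (!identical(got, want)) {
        stop("composition error: slot '", slot, "' expects a ", want,
             "-RM archetype but '", nm, "' is based on ", got,
             call. = FALSE)
      }
    }
  }
  t <- structure(
    list(base = "Report", slot_fills = fills, reductions = list(),
         registry = registry, archetypes = archetypes),
    class = "ehr_template"
  )
  for (nm in names(reductions)) {
    t <- reduce_template(t, nm, reductions[[nm]])
  }
  t
}

#' @export
print.ehr_template <- function(x, ...) {
  cat(sprintf("<template on %s Composition> %d filled slot(s)\n",
              x$base, length(x$slot_fills)))
  for (slot in names(x$slot_fills)) {
    cat(sprintf("  %s -> %s\n", slot, x$slot_fills[[slot]]))
  }
  for (nm in names(x$reductions)) {
    cat(sprintf("  reduction: %s keeps %d datapoint(s)\n", nm,
                length(x$reductions[[nm]])))
  }
  invisible(x)
}

#' Reduce an archetype's datapoint set within a template
#'
#' Records that only the `keep` codes of `archetype_name` survive in
#' this template.  Every kept code must exist among the archetype's
#' datapoint codes; repeated reductions intersect, so a template can
#' only ever shrink the datapoint set.
#'
#' @param t An `ehr_template`.
#' @param archetype_name Registry name of the archetype being reduced;
#'   its object must be available in `t$archetypes`.
#' @param keep Character vector of retained internal codes.
#' @return The updated template.
#' @export
reduce_template <- function(t, archetype_name, keep) {
  stopifnot(inherits(t, "ehr_template"))
  a <- t$archetypes[[archetype_name]]
  if (is.null(a)) {
    stop("reduction error: no archetype object available for '",
         archetype_name, "'", call. = FALSE)
  }
  codes <- definition_codes(a$definition)
  unknown <- setdiff(keep, codes)
  if (length(unknown)) {
    stop("reduction error: unknown code(s) in keep set: ",
         paste(unknown, collapse = ", "), call. = FALSE)
  }
  prev <- t$reductions[[archetype_name]]
  t$reductions[[archetype_name]] <- if (is.null(prev)) {
    unique(keep)
  } else {
    intersect(prev, keep)
  }
  t
}

#' Datapoint codes retained for an archetype under a template
#'
#' @param t An `ehr_template`.
#' @param archetype_name Registry name; its object must be in
#'   `t$archetypes`.
#' @return Character vector of retained codes (all codes when the
#'   template records no reduction).
#' @export
template_retained <- function(t, archetype_name) {
  stopifnot(inherits(t, "ehr_template"))
  a <- t$archetypes[[archetype_name]]
  if (is.null(a)) {
    stop("reduction error: no archetype object available for '",
         archetype_name, "'", call. = FALSE)
  }
  codes <- definition_codes(a$definition)
  red <- t$reductions[[archetype_name]]
  if (is.null(red)) codes else intersect(codes, red)
}

#' Write a template description file
#'
#' Line-oriented plain-text description: the base composition, the slot
#' wiring and the per-archetype retained datapoint codes.
#'
#' @param t An `ehr_template`.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_template <- function(t, path) {
  stopifnot(inherits(t, "ehr_template"))
  lines <- c(paste0("template on ", t$base, " Composition"))
  for (slot in names(t$slot_fills)) {
    lines <- c(lines, sprintf("slot\t%s\t%s", slot, t$slot_fills[[slot]]))
  }
  for (nm in names(t$reductions)) {
    lines <- c(lines, sprintf("reduce\t%s\t%s", nm,
                              paste(t$reductions[[nm]], collapse = ",")))
  }
  writeLines(lines, path)
  invisible(path)
}
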