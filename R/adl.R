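#' @title ADL serialisation and structural validation
#' @description
#' Archetypes are written out in an ADL 1.4-style surface syntax with the
#' five mandatory section blocks (`archetype`, `concept`, `language`,
#' `definition`, `ontology`) and only those optional blocks
#' (`specialise`, `description`, `invariant`, `revision_history`) that
#' are populated.  External terminology bindings are emitted under a
#' named terminology `"odML"` whose codes are `ODMLID` aliases -- raw
#' merged pointer strings are rejected as codes by mainstream archetype
#' tooling, which is why the alias layer exists.  Serialisation is
#' deterministic.  A full ADL parser is deliberately out of scope;
#' validation operates on the object model.
#' @name adl
NULL

ADL_TYPE_NAMES <- c(
  text = "DV_TEXT", coded_text = "DV_CODED_TEXT", count = "DV_COUNT",
  quantity = "DV_QUANTITY", date_time = "DV_DATE_TIME",
  multimedia = "DV_MULTIMEDIA", URI = "DV_URI", boolean = "DV_BOOLEAN",
  interval_of_date_time = "DV_INTERVAL<DV_DATE_TIME>"
)

adl_quote <- function(x) gsub('"', '\\\\"', x)

occurrences_str <- function(occ) {
  upper <- if (is.na(occ[2L])) "*" else occ[2L]
  sprintf("%d..%s", occ[1L], upper)
}

term_name_of <- function(a, code) {
  for (t in a$ontology) if (t$code == code) return(t$name)
  code
}

serialize_datapoint <- function(dp, a, indent, rm_type = NULL) {
  pad <- strrep("    ", indent)
  nm <- term_name_of(a, dp$code)
  if (dp$kind == "slot") {
    pats <- paste(dp$allowed_archetypes, collapse = "|")
    return(c(
      sprintf("%sallow_archetype CLUSTER[%s] occurrences matches {%s} matches {    -- %s",
              pad, dp$code, occurrences_str(dp$occurrences), nm),
      sprintf("%s    include", pad),
      sprintf("%s        archetype_id/value matches {/%s/}", pad, pats),
      sprintf("%s}", pad)
    ))
  }
  if (dp$kind == "cluster") {
    type_name <- if (is.null(rm_type)) "CLUSTER" else rm_type
    lines <- c(
      sprintf("%s%s[%s] occurrences matches {%s} matches {    -- %s",
              pad, type_name, dp$code, occurrences_str(dp$occurrences), nm))
    if (length(dp$children) > 0L) {
      lines <- c(lines, sprintf("%s    items cardinality matches {0..*; ordered} matches {", pad))
      for (child in dp$children) {
        lines <- c(lines, serialize_datapoint(child, a, indent + 2L))
      }
      lines <- c(lines, sprintf("%s    }", pad))
    }
    return(c(lines, sprintf("%s}", pad)))
  }
  # element
  dt <- dp$datatype
  value_line <- if (!is.null(dp$enum_codes) && length(dp$enum_codes) > 0L) {
    sprintf("DV_CODED_TEXT matches {defining_code matches {[local::%s]}}",
            paste(dp$enum_codes, collapse = ", "))
  } else {
    sprintf("%s matches {*}", ADL_TYPE_NAMES[[dt]])
  }
  c(
    sprintf("%sELEMENT[%s] occurrences matches {%s} matches {    -- %s",
            pad, dp$code, occurrences_str(dp$occurrences), nm),
    sprintf("%s    value matches {%s}", pad, value_line),
    sprintf("%s}", pad)
  )
}

#' Serialise an archetype to ADL text
#'
#' Refuses to serialise invalid archetypes (the violated rule is named).
#' Output always carries exactly the five mandatory section blocks and a
#' block per populated optional section, in fixed order, so equal
#' archetypes yield byte-equal text.
#'
#' @param a An [archetype()].
#' @return A character scalar of ADL text.
#' @export
serialize_adl <- function(a) {
  stopifnot(inherits(a, "archetype"))
  issues <- validate_archetype(a)
  if (length(issues) > 0L) {
    stop("serialization refused, archetype invalid: ", issues[[1L]],
         call. = FALSE)
  }
  out <- c(
    "archetype (adl_version=1.4)",
    paste0("    ", a$archetype_id),
    ""
  )
  if (!is.null(a$specialization)) {
    out <- c(out, "specialise", paste0("    ", a$specialization), "")
  }
  out <- c(out,
    "concept",
    sprintf("    [%s]    -- %s", a$concept, term_name_of(a, a$concept)),
    "",
    "language",
    sprintf("    original_language = <[ISO_639-1::%s]>", a$language),
    ""
  )
  if (!is.null(a$description)) {
    out <- c(out,
      "description",
      sprintf("    lifecycle_state = <\"%s\">", adl_quote(a$lifecycle_state)),
      sprintf("    purpose = <\"%s\">", adl_quote(a$description)),
      "")
  }
  out <- c(out,
    "definition",
    serialize_datapoint(a$definition, a, 1L,
                        rm_type = toupper(gsub(" ", "_", a$rm$name))),
    ""
  )
  if (!is.null(a$invariants_section)) {
    out <- c(out, "invariant", paste0("    ", a$invariants_section), "")
  }
  out <- c(out,
    "ontology",
    "    term_definitions = <",
    sprintf("        [\"%s\"] = <", a$language),
    "            items = <")
  for (t in a$ontology) {
    out <- c(out, sprintf(
      "                [\"%s\"] = <text = <\"%s\">; description = <\"%s\">>",
      t$code, adl_quote(t$name), adl_quote(t$definition)))
  }
  out <- c(out, "            >", "        >", "    >")
  bound <- Filter(function(t) !is.null(t$binding_alias), a$ontology)
  if (length(bound) > 0L) {
    out <- c(out,
      "    term_bindings = <",
      "        [\"odML\"] = <",
      "            items = <")
    for (t in bound) {
      out <- c(out, sprintf("                [\"%s\"] = <[odML::%s]>",
                            t$code, t$binding_alias))
    }
    out <- c(out, "            >", "        >", "    >")
  }
  if (!is.null(a$revision_history)) {
    out <- c(out, "", "revision_history",
             paste0("    ", a$revision_history))
  }
  paste0(paste(out, collapse = "\n"), "\n")
}

#' Validate an archetype's structure
#'
#' Checks that the mandatory sections are populated, that internal codes
#' in the definition and ontology pair up exactly, that element datatypes
#' come from the closed openEHR datatype set, that terminology binding
#' aliases are syntactically valid, and that occurrence intervals are
#' sane.  Issues are returned as data, never thrown.
#'
#' @param a An [archetype()].
#' @return Character vector of issues; empty means valid.
#' @export
validate_archetype <- function(a) {
  issues <- character()
  if (!inherits(a, "archetype")) return("not an archetype object")
  if (!nzchar(a$archetype_id)) issues <- c(issues, "empty archetype ID")
  if (!nzchar(a$language)) issues <- c(issues, "empty language")
  if (length(a$ontology) == 0L) issues <- c(issues, "empty ontology")

  onto <- ontology_codes(a)
  if (anyDuplicated(onto)) {
    issues <- c(issues, paste0("duplicate ontology code: ",
                               paste(unique(onto[duplicated(onto)]),
                                     collapse = ", ")))
  }
  if (!a$concept %in% onto) {
    issues <- c(issues, paste0("concept code ", a$concept,
                               " missing from ontology"))
  }
  def <- definition_codes(a$definition)
  if (anyDuplicated(def)) {
    issues <- c(issues, paste0("duplicate definition code: ",
                               paste(unique(def[duplicated(def)]),
                                     collapse = ", ")))
  }
  for (code in setdiff(def, onto)) {
    issues <- c(issues, paste0("unpaired internal code: ", code,
                               " used in definition but absent from ontology"))
  }
  for (code in setdiff(onto, def)) {
    if (code == a$concept) next  # concept may describe the root itself
    issues <- c(issues, paste0("orphan ontology term: ", code,
                               " never used in definition"))
  }
  issues <- c(issues, validate_datapoint(a$definition))
  for (t in a$ontology) {
    if (!is.null(t$binding_alias) && !is_alias(t$binding_alias)) {
      issues <- c(issues, paste0("invalid binding alias on ", t$code,
                                 ": '", t$binding_alias, "'"))
    }
  }
  issues
}

validate_datapoint <- function(dp) {
  issues <- character()
  occ <- dp$occurrences
  if (occ[1L] < 0L || (!is.na(occ[2L]) && occ[2L] < occ[1L])) {
    issues <- c(issues, paste0("bad occurrence interval on ", dp$code))
  }
  if (dp$kind == "element") {
    if (is.null(dp$datatype) ||
        !dp$datatype %in% OPENEHR_DATATYPES) {
      issues <- c(issues, paste0("unknown datatype on element ", dp$code,
                                 ": '", dp$datatype %||% "<none>", "'"))
    }
  } else if (dp$kind == "slot") {
    if (length(dp$allowed_archetypes) == 0L) {
      issues <- c(issues, paste0("slot ", dp$code,
                                 " allows no archetypes"))
    }
  }
  for (child in dp$children) {
    issues <- c(issues, validate_datapoint(child))
  }
  issues
}

`%||%` <- function(a, b) if (is.null(a)) b else a
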