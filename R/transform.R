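#' @title odML to Cluster-archetype transformation
#' @description
#' Any odML section tree can be expressed as a Cluster-RM archetype
#' without loss of structure: the root section becomes the archetype
#' (its attributes the archetype metadata), sections and subsections
#' become clusters and nested clusters, properties become typed element
#' datapoints, and enumerated properties become elements whose items are
#' predefined internal codes.  Datatypes follow a fixed twelve-pair
#' odML-to-openEHR mapping; person-typed properties become slots for
#' demographic archetypes, 2-tuples expand to a two-element cluster, and
#' a sibling start/end time pair can merge into a single
#' interval-of-datetimes element.  Optionally every enumeration item is
#' bound to the odML terminology through the pointer/alias machinery.
#' @name odml2adl
NULL

DATATYPE_MAP <- c(
  person = "SLOT", date = "date_time", text = "text", int = "count",
  string = "text", float = "quantity", binary = "multimedia",
  url = "URI", datetime = "date_time", time = "date_time",
  boolean = "boolean", `2-tuple` = "CLUSTER_OF_TWO"
)

#' The odML to openEHR datatype map
#'
#' @return Named character vector over exactly the twelve odML datatypes;
#'   values are openEHR datatypes or the structural directives `SLOT`
#'   (demographic-archetype slot) and `CLUSTER_OF_TWO` (two-element
#'   cluster substitution).
#' @export
datatype_map <- function() DATATYPE_MAP

#' Map one odML datatype to its openEHR counterpart
#'
#' @param odml_type Lowercase odML datatype name.
#' @param has_start_and_end Flag: a `time` property that is one half of a
#'   sibling start/end pair maps to an interval of datetimes instead of a
#'   plain datetime.
#' @return The openEHR datatype or structural directive.
#' @export
#' @examples
#' map_datatype("int")                            # "count"
#' map_datatype("time", has_start_and_end = TRUE) # interval of date_time
map_datatype <- function(odml_type, has_start_and_end = FALSE) {
  if (!odml_type %in% names(DATATYPE_MAP)) {
    stop("mapping error: no openEHR pairing for odML type '", odml_type,
         "'", call. = FALSE)
  }
  if (odml_type %in% c("time", "datetime") && has_start_and_end) {
    return("interval_of_date_time")
  }
  DATATYPE_MAP[[odml_type]]
}

#' Options controlling the odML to archetype transformation
#'
#' @param terminology_url URL under which the source odML document is
#'   (notionally) published; used to build term pointers for bindings.
#' @param section_no Alias section number allocated to this document's
#'   terms, in `[0, 999]`.
#' @param bind_terms Bind every enumeration item to the odML terminology
#'   (pointer, alias, ontology binding)?
#' @param start_end_merge Merge sibling `StartTime`/`EndTime` properties
#'   (case-insensitive) into one interval-of-datetimes element?
#' @return An object of class `transform_options`.
#' @export
transform_options <- function(terminology_url = "file:///odml/terminology.xml",
                              section_no = 0L, bind_terms = FALSE,
                              start_end_merge = TRUE) {
  section_no <- as.integer(section_no)
  stopifnot(section_no >= 0L, section_no <= 999L,
            is.character(terminology_url), nzchar(terminology_url))
  structure(
    list(terminology_url = terminology_url, section_no = section_no,
         bind_terms = isTRUE(bind_terms),
         start_end_merge = isTRUE(start_end_merge)),
    class = "transform_options"
  )
}

# Allocate the next alias term number (sequential from 1) and register
# the enumeration item; >999 terms exceed the 3-digit alias field.
bind_enum_item <- function(ctx, section_name, property_name, item) {
  if (ctx$next_term > 999L) {
    stop("capacity error: alias term numbers exhausted (>999 terms ",
         "for section number ", ctx$opts$section_no, ")", call. = FALSE)
  }
  p <- term_pointer(ctx$opts$terminology_url, section_name,
                    property_name, item)
  entry <- register_term(ctx$table, p, ctx$opts$section_no, ctx$next_term)
  ctx$next_term <- ctx$next_term + 1L
  entry$alias
}

add_term <- function(ctx, code, name, definition = name,
                     binding_alias = NULL) {
  ctx$ontology[[length(ctx$ontology) + 1L]] <-
    ontology_term(code, name, definition, binding_alias)
  invisible(code)
}

# Component datatype guess for a 2-tuple "(a; b)" content string.
tuple_component_type <- function(content) {
  inner <- gsub("^\\s*\\(|\\)\\s*$", "", content)
  parts <- trimws(strsplit(inner, "[;,]")[[1L]])
  if (length(parts) == 2L && all(grepl("^-?[0-9]+$", parts))) return("count")
  if (length(parts) == 2L &&
      all(grepl("^-?[0-9]*\\.?[0-9]+([eE][+-]?[0-9]+)?$", parts))) {
    return("quantity")
  }
  "text"
}

transform_property <- function(p, owning_section, alloc, ctx, path) {
  ppath <- paste0(path, "/", p$name)
  dtype <- p$values[[1L]]$dtype
  defn <- p$definition %||% p$name
  if (is_enumeration(p)) {
    code <- alloc$new_code()
    items <- vapply(p$values, function(v) v$content, character(1))
    enum_codes <- character(length(items))
    for (i in seq_along(items)) {
      ecode <- alloc$new_code()
      alias <- if (ctx$opts$bind_terms) {
        bind_enum_item(ctx, owning_section, p$name, items[[i]])
      } else NULL
      add_term(ctx, ecode, items[[i]],
               paste0("enumeration item of ", p$name),
               binding_alias = alias)
      enum_codes[[i]] <- ecode
    }
    add_term(ctx, code, p$name, defn)
    return(datapoint(code, "element", datatype = "coded_text",
                     enum_codes = enum_codes))
  }
  directive <- tryCatch(
    map_datatype(dtype),
    error = function(e) {
      stop(conditionMessage(e), " (at property ", ppath, ")",
           call. = FALSE)
    }
  )
  if (identical(directive, "SLOT")) {
    code <- alloc$new_code()
    add_term(ctx, code, p$name, defn)
    return(datapoint(code, "slot",
                     allowed_archetypes = "openEHR-DEMOGRAPHIC-PERSON\\.person\\.v1"))
  }
  if (identical(directive, "CLUSTER_OF_TWO")) {
    code <- alloc$new_code()
    comp <- tuple_component_type(p$values[[1L]]$content)
    c1 <- alloc$new_code(); c2 <- alloc$new_code()
    add_term(ctx, code, p$name, defn)
    add_term(ctx, c1, paste(p$name, "#1"), paste("first component of", p$name))
    add_term(ctx, c2, paste(p$name, "#2"), paste("second component of", p$name))
    return(datapoint(code, "cluster", children = list(
      datapoint(c1, "element", datatype = comp),
      datapoint(c2, "element", datatype = comp)
    )))
  }
  unit <- p$values[[1L]]$unit
  if (!is.null(unit)) defn <- paste0(defn, " [unit: ", unit, "]")
  code <- alloc$new_code()
  add_term(ctx, code, p$name, defn)
  datapoint(code, "element", datatype = directive)
}

#' Transform one odML section into a cluster datapoint
#'
#' Sections become clusters, subsections nested clusters, properties
#' element children (with enumeration items as fresh internal codes);
#' the section's name, type and definition populate the cluster's
#' ontology term.  Normally called through [transform_document()].
#'
#' @param s An [odml_section()].
#' @param alloc A [code_allocator()].
#' @param opts [transform_options()].
#' @param ctx Internal accumulation context; created when missing.
#' @param occurrences Occurrence interval for the produced cluster.
#' @return A cluster [datapoint()].  When `ctx` is omitted, the
#'   accumulated ontology terms are attached as attribute
#'   `"ontology"` and the alias table as `"alias_table"`.
#' @export
transform_section <- function(s, alloc, opts = transform_options(),
                              ctx = NULL, occurrences = c(0L, 1L)) {
  stopifnot(inherits(s, "odml_section"))
  standalone <- is.null(ctx)
  if (standalone) {
    ctx <- new.env(parent = emptyenv())
    ctx$ontology <- list()
    ctx$table <- alias_table()
    ctx$next_term <- 1L
    ctx$opts <- opts
  }
  code <- alloc$new_code()
  defn <- s$definition %||% s$name
  if (!is.null(s$type)) defn <- paste0(defn, " (type: ", s$type, ")")
  add_term(ctx, code, s$name, defn)

  children <- list()
  props <- s$properties
  merged_idx <- integer()
  if (ctx$opts$start_end_merge && length(props) >= 2L) {
    nms <- tolower(vapply(props, function(p) p$name, character(1)))
    i_start <- match("starttime", nms)
    i_end <- match("endtime", nms)
    if (!is.na(i_start) && !is.na(i_end)) {
      merged_idx <- c(i_start, i_end)
    }
  }
  for (i in seq_along(props)) {
    if (length(merged_idx) && i == min(merged_idx)) {
      # start/end pair collapses into one interval-of-datetimes element
      icode <- alloc$new_code()
      add_term(ctx, icode, "StartTime/EndTime",
               "recording interval merged from start and end times")
      children <- c(children, list(
        datapoint(icode, "element", datatype = "interval_of_date_time")))
      next
    }
    if (i %in% merged_idx) next
    children <- c(children, list(
      transform_property(props[[i]], s$name, alloc, ctx, s$name)))
  }
  for (sub in s$subsections) {
    children <- c(children, list(
      transform_section(sub, alloc, opts, ctx)))
  }
  dp <- datapoint(code, "cluster", occurrences = occurrences,
                  children = children)
  if (standalone) {
    attr(dp, "ontology") <- ctx$ontology
    attr(dp, "alias_table") <- ctx$table
  }
  dp
}

slugify <- function(x) {
  s <- tolower(x)
  s <- gsub("[^a-z0-9]+", "_", s)
  gsub("^_+|_+$", "", s)
}

#' Transform an odML document into a Cluster-RM archetype
#'
#' The root section becomes the archetype: its name is the concept, its
#' attributes (definition, type, document author/date) populate the
#' description metadata, and its content is transformed by
#' [transform_section()].  With `bind_terms`, every enumeration item
#' receives a terminology pointer, a registered `ODMLID` alias and an
#' ontology binding; the alias table is returned alongside the
#' archetype.  The result always passes [validate_archetype()].
#'
#' @param doc An [odml_document()].
#' @param opts [transform_options()].
#' @return A list with elements `archetype` and `alias_table`, of class
#'   `odml_transform`.
#' @export
#' @examples
#' doc <- generate_fixture(fixture_spec(depth = 1, seed = 42))
#' tr <- transform_document(doc)
#' validate_archetype(tr$archetype)   # character(0)
transform_document <- function(doc, opts = transform_options()) {
  stopifnot(inherits(doc, "odml_document"),
            inherits(opts, "transform_options"))
  alloc <- code_allocator()
  ctx <- new.env(parent = emptyenv())
  ctx$ontology <- list()
  ctx$table <- alias_table()
  ctx$next_term <- 1L
  ctx$opts <- opts
  root_dp <- transform_section(doc$root, alloc, opts, ctx,
                               occurrences = c(1L, 1L))
  meta <- c(
    doc$root$definition %||% doc$root$name,
    if (!is.null(doc$author)) paste("author:", doc$author),
    if (!is.null(doc$date)) paste("date:", doc$date),
    if (length(doc$root$extra)) {
      paste(names(doc$root$extra), unname(doc$root$extra),
            sep = ": ", collapse = "; ")
    }
  )
  a <- archetype(
    archetype_id = paste0("openEHR-EHR-CLUSTER.", slugify(doc$root$name),
                          ".v1"),
    concept = root_dp$code,
    definition = root_dp,
    ontology = ctx$ontology,
    rm = "Cluster",
    description = paste(meta, collapse = "; ")
  )
  structure(list(archetype = a, alias_table = ctx$table),
            class = "odml_transform")
}

#' @export
print.odml_transform <- function(x, ...) {
  cat("odML -> openEHR transformation\n")
  print(x$archetype)
  print(x$alias_table)
  invisible(x)
}
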