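#' @title odML document model
#' @description
#' odML (open metaData Markup Language) organises scientific metadata as a
#' tree of *sections*, each holding *properties*, each holding one or more
#' typed *values*.  The model here covers the four basic elements of the
#' odML v1 dialect: document (root section plus document attributes),
#' section, property, value.  Objects are plain lists with S3 classes so
#' they print readably and can be assembled programmatically.
#' @name odml-model
NULL

# Closed set of odML datatype names (lowercase).
ODML_DTYPES <- c("person", "date", "text", "int", "string", "float",
                 "binary", "url", "datetime", "time", "boolean", "2-tuple")

#' Construct an odML value
#'
#' @param content Character scalar; the value text. Must be non-empty for
#'   values that participate in enumerations.
#' @param dtype odML datatype name, one of the closed twelve-type set
#'   (`person`, `date`, `text`, `int`, `string`, `float`, `binary`, `url`,
#'   `datetime`, `time`, `boolean`, `2-tuple`).
#' @param unit Optional unit string.
#' @param uncertainty Optional numeric uncertainty.
#' @return An object of class `odml_value`.
#' @export
#' @examples
#' odml_value("Reference", "string")
odml_value <- function(content, dtype = "string", unit = NULL,
                       uncertainty = NULL) {
  stopifnot(is.character(content), length(content) == 1L)
  dtype <- tolower(dtype)
  if (!dtype %in% ODML_DTYPES) {
    stop("unknown odML datatype: '", dtype, "'", call. = FALSE)
  }
  if (!is.null(uncertainty)) uncertainty <- as.numeric(uncertainty)
  structure(
    list(content = content, dtype = dtype, unit = unit,
         uncertainty = uncertainty),
    class = "odml_value"
  )
}

#' Construct an odML property
#'
#' All values of one property share a single datatype; this is enforced at
#' construction.  Character vectors are promoted to value lists.
#'
#' @param name Property name (non-empty).
#' @param values A list of [odml_value()] objects, or a character vector
#'   that is promoted using `dtype`.
#' @param definition Optional free-text definition.
#' @param dtype Datatype used when promoting a character vector.
#' @return An object of class `odml_property`.
#' @export
#' @examples
#' odml_property("Usage", c("Reference", "Recording"), dtype = "string")
odml_property <- function(name, values, definition = NULL,
                          dtype = "string") {
  stopifnot(is.character(name), length(name) == 1L, nzchar(name))
  if (is.character(values)) {
    values <- lapply(values, odml_value, dtype = dtype)
  }
  if (length(values) < 1L) {
    stop("property '", name, "' must carry at least one value",
         call. = FALSE)
  }
  dtypes <- unique(vapply(values, function(v) v$dtype, character(1)))
  if (length(dtypes) != 1L) {
    stop("values of property '", name,
         "' mix datatypes: ", paste(dtypes, collapse = ", "),
         call. = FALSE)
  }
  structure(
    list(name = name, definition = definition, values = values),
    class = "odml_property"
  )
}

#' Construct an odML section
#'
#' @param name Section name (non-empty).
#' @param type Optional section type string.
#' @param definition Optional free-text definition.
#' @param properties List of [odml_property()] objects (order preserved).
#' @param subsections List of nested `odml_section` objects.
#' @param extra Named character vector of additional odML section
#'   attributes (reference, dependency, ...) carried through verbatim.
#' @return An object of class `odml_section`.
#' @export
odml_section <- function(name, type = NULL, definition = NULL,
                         properties = list(), subsections = list(),
                         extra = character()) {
  stopifnot(is.character(name), length(name) == 1L, nzchar(name))
  stopifnot(is.list(properties), is.list(subsections))
  structure(
    list(name = name, type = type, definition = definition,
         properties = properties, subsections = subsections,
         extra = extra),
    class = "odml_section"
  )
}

#' Construct an odML document
#'
#' A document owns exactly one root section; the dialect version is fixed
#' to "1".
#'
#' @param root The root [odml_section()].
#' @param author Optional author string.
#' @param date Optional document date (ISO-8601 string or `Date`).
#' @param version Dialect version; must be `"1"`.
#' @return An object of class `odml_document`.
#' @export
odml_document <- function(root, author = NULL, date = NULL, version = "1") {
  if (!identical(version, "1")) {
    stop("odML dialect version must be \"1\"", call. = FALSE)
  }
  if (!inherits(root, "odml_section")) {
    stop("root must be an odml_section", call. = FALSE)
  }
  if (!is.null(date)) date <- as.character(date)
  structure(
    list(version = version, author = author, date = date, root = root),
    class = "odml_document"
  )
}

#' Is a property an enumeration?
#'
#' A property is treated as an enumeration of a closed item set when it is
#' string/text-typed and carries two or more values (the pattern the
#' electrode terminology uses for its `Usage` property).  Downstream, the
#' archetype transformation turns each enumeration item into a predefined
#' internal code.
#'
#' @param p An [odml_property()].
#' @return Logical scalar.
#' @export
is_enumeration <- function(p) {
  stopifnot(inherits(p, "odml_property"))
  dt <- p$values[[1L]]$dtype
  dt %in% c("string", "text") && length(p$values) >= 2L
}

# Recursive node census: sections, properties, values.
odml_counts <- function(s) {
  stopifnot(inherits(s, "odml_section"))
  n <- c(sections = 1L,
         properties = length(s$properties),
         values = sum(vapply(s$properties,
                             function(p) length(p$values), integer(1))))
  for (sub in s$subsections) n <- n + odml_counts(sub)
  n
}

#' @export
print.odml_document <- function(x, ...) {
  cts <- odml_counts(x$root)
  cat(sprintf("<odML v%s> root section '%s': %d section(s), %d propert%s, %d value(s)\n",
              x$version, x$root$name, cts[["sections"]], cts[["properties"]],
              if (cts[["properties"]] == 1L) "y" else "ies",
              cts[["values"]]))
  invisible(x)
}

#' @export
print.odml_section <- function(x, ...) {
  cat(sprintf("<odml section '%s'> %d propert%s, %d subsection(s)\n",
              x$name, length(x$properties),
              if (length(x$properties) == 1L) "y" else "ies",
              length(x$subsections)))
  invisible(x)
}

#' @export
print.odml_property <- function(x, ...) {
  vals <- vapply(x$values, function(v) v$content, character(1))
  cat(sprintf("<odml property '%s'> [%s] %s\n", x$name,
              x$values[[1L]]$dtype, paste(vals, collapse = ", ")))
  invisible(x)
}

# Structural equality on the model (ignores 'extra' ordering, keeps value
# order). Used by round-trip tests and by write determinism checks.
odml_equal <- function(a, b) {
  identical(strip_odml(a), strip_odml(b))
}

strip_odml <- function(x) {
  if (inherits(x, "odml_document")) {
    list(version = x$version, author = x$author, date = x$date,
         root = strip_odml(x$root))
  } else if (inherits(x, "odml_section")) {
    extra <- if (length(x$extra)) x$extra[order(names(x$extra))] else character()
    list(name = x$name, type = x$type, definition = x$definition,
         extra = extra,
         properties = lapply(x$properties, strip_odml),
         subsections = lapply(x$subsections, strip_odml))
  } else if (inherits(x, "odml_property")) {
    list(name = x$name, definition = x$definition,
         values = lapply(x$values, strip_odml))
  } else if (inherits(x, "odml_value")) {
    list(content = x$content, dtype = x$dtype, unit = x$unit,
         uncertainty = x$uncertainty)
  } else x
}
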