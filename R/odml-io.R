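#' Parse an odML v1 XML document
#'
#' Reads the odML v1 element dialect (`odML`/`section`/`property`/`name`/
#' `value`, with `type`, `definition`, `unit` and `uncertainty` as
#' qualifiers).  Element order is preserved.  Section child elements
#' outside the core vocabulary whose content is plain text are retained in
#' an open key/value bag and re-emitted by [write_odml()]; anything else
#' unknown is skipped with a warning.
#'
#' @param xml_text A character scalar holding odML XML, or a path to an
#'   XML file.
#' @return An [odml_document()].
#' @export
#' @examples
#' doc <- parse_odml(
#'   '<odML version="1"><section><name>S</name></section></odML>')
#' doc$root$name
parse_odml <- function(xml_text) {
  x <- xml2::read_xml(xml_text)  # malformed input errors with line info
  if (xml2::xml_name(x) != "odML") {
    stop("dialect error: root element must be <odML>, found <",
         xml2::xml_name(x), ">", call. = FALSE)
  }
  version <- xml2::xml_attr(x, "version")
  if (is.na(version)) {
    stop("dialect error: <odML> element lacks the mandatory version attribute",
         call. = FALSE)
  }
  if (!identical(version, "1")) {
    stop("dialect error: unsupported odML version '", version, "'",
         call. = FALSE)
  }
  author <- NULL
  date <- NULL
  sections <- list()
  for (child in xml2::xml_children(x)) {
    nm <- xml2::xml_name(child)
    if (nm == "section") {
      sections <- c(sections, list(parse_section(child)))
    } else if (nm == "author") {
      author <- xml2::xml_text(child)
    } else if (nm == "date") {
      date <- xml2::xml_text(child)
    } else {
      warning("ignoring unknown odML document child element <", nm, ">",
              call. = FALSE)
    }
  }
  if (length(sections) != 1L) {
    stop("dialect error: an odML document must carry exactly one root ",
         "section, found ", length(sections), call. = FALSE)
  }
  odml_document(sections[[1L]], author = author, date = date,
                version = version)
}

parse_section <- function(node) {
  name <- NULL; type <- NULL; definition <- NULL
  properties <- list(); subsections <- list()
  extra <- character()
  for (child in xml2::xml_children(node)) {
    nm <- xml2::xml_name(child)
    if (nm == "name") {
      name <- xml2::xml_text(child)
    } else if (nm == "type") {
      type <- xml2::xml_text(child)
    } else if (nm == "definition") {
      definition <- xml2::xml_text(child)
    } else if (nm == "property") {
      properties <- c(properties, list(parse_property(child)))
    } else if (nm == "section") {
      subsections <- c(subsections, list(parse_section(child)))
    } else if (length(xml2::xml_children(child)) == 0L) {
      extra[[nm]] <- xml2::xml_text(child)  # open attribute bag
    } else {
      warning("ignoring unknown section child element <", nm, ">",
              call. = FALSE)
    }
  }
  if (is.null(name) || !nzchar(name)) {
    stop("dialect error: section without a <name> element", call. = FALSE)
  }
  odml_section(name, type = type, definition = definition,
               properties = properties, subsections = subsections,
               extra = extra)
}

parse_property <- function(node) {
  name <- NULL; definition <- NULL
  values <- list()
  for (child in xml2::xml_children(node)) {
    nm <- xml2::xml_name(child)
    if (nm == "name") {
      name <- xml2::xml_text(child)
    } else if (nm == "definition") {
      definition <- xml2::xml_text(child)
    } else if (nm == "value") {
      values <- c(values, list(parse_value(child)))
    } else {
      warning("ignoring unknown property child element <", nm, ">",
              call. = FALSE)
    }
  }
  if (is.null(name) || !nzchar(name)) {
    stop("dialect error: property without a <name> element", call. = FALSE)
  }
  odml_property(name, values, definition = definition)
}

parse_value <- function(node) {
  # direct text nodes only -- value qualifiers sit in child elements
  txt <- xml2::xml_find_all(node, "text()")
  content <- trimws(paste(vapply(txt, xml2::xml_text, character(1)),
                          collapse = ""))
  dtype <- "string"; unit <- NULL; uncertainty <- NULL
  for (child in xml2::xml_children(node)) {
    nm <- xml2::xml_name(child)
    if (nm == "type") {
      dtype <- xml2::xml_text(child)
    } else if (nm == "unit") {
      unit <- xml2::xml_text(child)
    } else if (nm == "uncertainty") {
      uncertainty <- as.numeric(xml2::xml_text(child))
    } else {
      warning("ignoring unknown value child element <", nm, ">",
              call. = FALSE)
    }
  }
  odml_value(content, dtype = dtype, unit = unit, uncertainty = uncertainty)
}

#' Serialise an odML document to XML text
#'
#' Output is deterministic: structurally equal documents produce
#' byte-equal XML (section attribute bags are emitted in lexical key
#' order), and the result re-parses to a structurally equal document.
#'
#' @param doc An [odml_document()].
#' @return A character scalar of UTF-8 XML.
#' @export
write_odml <- function(doc) {
  stopifnot(inherits(doc, "odml_document"))
  root <- xml2::xml_new_root("odML", version = doc$version)
  if (!is.null(doc$author)) {
    xml2::xml_add_child(root, "author", doc$author)
  }
  if (!is.null(doc$date)) {
    xml2::xml_add_child(root, "date", doc$date)
  }
  emit_section(root, doc$root)
  as.character(root)
}

emit_section <- function(parent, s) {
  if (!nzchar(s$name)) {
    stop("serialization error: section with empty name", call. = FALSE)
  }
  node <- xml2::xml_add_child(parent, "section")
  xml2::xml_add_child(node, "name", s$name)
  if (!is.null(s$type)) xml2::xml_add_child(node, "type", s$type)
  if (!is.null(s$definition)) {
    xml2::xml_add_child(node, "definition", s$definition)
  }
  for (key in sort(names(s$extra))) {
    xml2::xml_add_child(node, key, s$extra[[key]])
  }
  for (p in s$properties) emit_property(node, p)
  for (sub in s$subsections) emit_section(node, sub)
  node
}

emit_property <- function(parent, p) {
  if (!nzchar(p$name)) {
    stop("serialization error: property with empty name", call. = FALSE)
  }
  node <- xml2::xml_add_child(parent, "property")
  xml2::xml_add_child(node, "name", p$name)
  if (!is.null(p$definition)) {
    xml2::xml_add_child(node, "definition", p$definition)
  }
  for (v in p$values) {
    vnode <- xml2::xml_add_child(node, "value", v$content)
    xml2::xml_add_child(vnode, "type", v$dtype)
    if (!is.null(v$unit)) xml2::xml_add_child(vnode, "unit", v$unit)
    if (!is.null(v$uncertainty)) {
      xml2::xml_add_child(vnode, "uncertainty",
                          format(v$uncertainty, scientific = FALSE))
    }
  }
  node
}
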