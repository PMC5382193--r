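#' @title Terminology referencing for odML terms
#' @description
#' Terms in an odML terminology file (an XML element holding, say, the
#' enumeration item `Reference` of the `Usage` property in the
#' `Electrode` section) have no native dereferenceable identifiers.  This
#' module builds them in four steps: (1) a human-readable pointer string
#' (`<file url>#<section>:<property>/<item>`), (2) an XPath 1.0 query
#' selecting the element inside the file, (3) a merged machine-resolvable
#' string (`<file url>#/<xpath>`), and (4) a short `ODMLID` alias usable
#' as an external terminology code inside archetype bindings, since
#' archetype tooling rejects raw merged strings as codes.  Aliases and
#' their expansions live in a bijective alias table.
#' @name term-pointer
NULL

#' Construct a terminology pointer
#'
#' @param file_url URL of the terminology XML file (non-empty).
#' @param section_name,property_name Names locating the term (non-empty).
#' @param value_item Optional enumerated item text; when absent the
#'   pointer addresses the property itself.
#' @return An object of class `term_pointer`.
#' @export
#' @examples
#' p <- term_pointer(
#'   "http://portal.g-node.org/odml/terminologies/v1.0/electrode/electrode.xml",
#'   "Electrode", "Usage", "Reference")
#' build_pointer(p)
term_pointer <- function(file_url, section_name, property_name,
                         value_item = NULL) {
  for (f in list(file_url, section_name, property_name)) {
    if (!is.character(f) || length(f) != 1L || !nzchar(f)) {
      stop("grammar error: file_url, section_name and property_name must ",
           "be non-empty strings", call. = FALSE)
    }
  }
  if (!is.null(value_item)) {
    stopifnot(is.character(value_item), length(value_item) == 1L,
              nzchar(value_item))
  }
  structure(
    list(file_url = file_url, section_name = section_name,
         property_name = property_name, value_item = value_item),
    class = "term_pointer"
  )
}

#' Build the step-1 pointer string
#'
#' The hash separates the section name from the file URL, the colon
#' separates the property name from the section name, and a slash
#' separates the enumerated item from the property name.
#'
#' @param p A [term_pointer()].
#' @return The pointer string.
#' @export
build_pointer <- function(p) {
  stopifnot(inherits(p, "term_pointer"))
  out <- paste0(p$file_url, "#", p$section_name, ":", p$property_name)
  if (!is.null(p$value_item)) out <- paste0(out, "/", p$value_item)
  out
}

#' Parse a pointer string back into its components
#'
#' Inverse of [build_pointer()] on the pointer grammar: the split happens
#' at the first `#`, then the first `:`, then the first `/` of the
#' remainder.
#'
#' @param text A pointer string.
#' @return A [term_pointer()].
#' @export
parse_pointer <- function(text) {
  stopifnot(is.character(text), length(text) == 1L)
  m <- regexpr("#", text, fixed = TRUE)
  if (m < 0L) stop("grammar error: pointer lacks '#'", call. = FALSE)
  file_url <- substr(text, 1L, m - 1L)
  rest <- substr(text, m + 1L, nchar(text))
  mc <- regexpr(":", rest, fixed = TRUE)
  if (mc < 0L) stop("grammar error: pointer lacks ':'", call. = FALSE)
  section <- substr(rest, 1L, mc - 1L)
  rest <- substr(rest, mc + 1L, nchar(rest))
  ms <- regexpr("/", rest, fixed = TRUE)
  if (ms < 0L) {
    term_pointer(file_url, section, rest)
  } else {
    term_pointer(file_url, section,
                 substr(rest, 1L, ms - 1L),
                 substr(rest, ms + 1L, nchar(rest)))
  }
}

#' Build the step-2 XPath query
#'
#' Produces an XPath 1.0 expression selecting the `value` element whose
#' text equals `value_item` under the `property` whose `name` element's
#' text equals `property_name`, rooted at the versioned `odML` element.
#' Without `value_item` it selects the property's `name` element.  String
#' literals use plain double quotes; spacing around `=` is fixed so
#' outputs are byte-comparable.
#'
#' @param property_name Property name (non-empty).
#' @param value_item Optional enumerated item text.
#' @param version odML dialect version (default `"1"`).
#' @return The XPath string.
#' @export
#' @examples
#' build_xpath("Usage", "Reference")
build_xpath <- function(property_name, value_item = NULL, version = "1") {
  stopifnot(is.character(property_name), length(property_name) == 1L,
            nzchar(property_name))
  base <- sprintf('odML[@version = "%s"]/section/property/name[text() = "%s"]',
                  version, property_name)
  if (is.null(value_item)) {
    base
  } else {
    sprintf('%s/../value[text() = "%s"]', base, value_item)
  }
}

#' Merge a file URL and an XPath into one dereferenceable string (step 3)
#'
#' @param file_url Terminology file URL.
#' @param xpath XPath query within that file.
#' @return `file_url` + `"#/"` + `xpath`.
#' @export
merge_pointer <- function(file_url, xpath) {
  stopifnot(is.character(file_url), nzchar(file_url),
            is.character(xpath), nzchar(xpath))
  paste0(file_url, "#/", xpath)
}

#' Split a merged pointer string
#'
#' Inverse of [merge_pointer()]: splits at the first `"#/"`.
#'
#' @param merged A merged pointer string.
#' @return A list with elements `file_url` and `xpath`.
#' @export
split_merged <- function(merged) {
  m <- regexpr("#/", merged, fixed = TRUE)
  if (m < 0L) {
    stop("grammar error: merged pointer lacks '#/'", call. = FALSE)
  }
  list(file_url = substr(merged, 1L, m - 1L),
       xpath = substr(merged, m + 2L, nchar(merged)))
}

#' Build an ODMLID alias (step 4)
#'
#' An alias is the prefix `ODMLID` followed by a zero-padded 3-digit
#' section number and a zero-padded 3-digit term number -- 12 characters
#' in total.
#'
#' @param section_no,term_no Integers in `[0, 999]`.
#' @return The 12-character alias.
#' @export
#' @examples
#' make_alias(7, 13)   # "ODMLID007013"
make_alias <- function(section_no, term_no) {
  section_no <- as.integer(section_no)
  term_no <- as.integer(term_no)
  if (is.na(section_no) || section_no < 0L || section_no > 999L ||
      is.na(term_no) || term_no < 0L || term_no > 999L) {
    stop("range error: section and term numbers must lie in [0, 999]",
         call. = FALSE)
  }
  sprintf("ODMLID%03d%03d", section_no, term_no)
}

#' Parse an ODMLID alias
#'
#' @param alias A 12-character `ODMLID` alias.
#' @return Integer vector `c(section_no, term_no)`.
#' @export
parse_alias <- function(alias) {
  stopifnot(is.character(alias), length(alias) == 1L)
  m <- regmatches(alias, regexec("^ODMLID([0-9]{3})([0-9]{3})$", alias))[[1L]]
  if (length(m) != 3L) {
    stop("format error: '", alias, "' is not a valid ODMLID alias",
         call. = FALSE)
  }
  c(section_no = as.integer(m[2L]), term_no = as.integer(m[3L]))
}

is_alias <- function(x) {
  is.character(x) && length(x) == 1L && grepl("^ODMLID[0-9]{6}$", x)
}

#' Create an empty alias table
#'
#' The alias table keeps, per registered term, the alias, its section and
#' term numbers, and the three reference forms (pointer, XPath, merged
#' string).  Aliases and `(section_no, term_no)` pairs are bijective.
#' The table is a mutable registry: [register_term()] updates it in
#' place.
#'
#' @return An object of class `alias_table`.
#' @export
alias_table <- function() {
  env <- new.env(parent = emptyenv())
  env$entries <- data.frame(
    alias = character(), section_no = integer(), term_no = integer(),
    pointer = character(), xpath = character(), merged = character(),
    stringsAsFactors = FALSE
  )
  class(env) <- "alias_table"
  env
}

#' @export
print.alias_table <- function(x, ...) {
  cat(sprintf("<alias_table> %d registered term(s)\n", nrow(x$entries)))
  invisible(x)
}

#' Number of registered aliases
#' @param table An [alias_table()].
#' @return Integer count.
#' @export
alias_count <- function(table) {
  stopifnot(inherits(table, "alias_table"))
  nrow(table$entries)
}

#' Register a terminology term in an alias table
#'
#' Runs all four referencing steps for one term and records the result:
#' the pointer string, the XPath query, the merged string and the
#' `ODMLID` alias.  Numbers are caller-assigned; registering an already
#' used `(section_no, term_no)` pair is a conflict.
#'
#' @param table An [alias_table()] (modified in place).
#' @param p A [term_pointer()].
#' @param section_no,term_no Alias numbering, each in `[0, 999]`.
#' @return The new entry as a one-row data frame (invisibly the table is
#'   updated).
#' @export
register_term <- function(table, p, section_no, term_no) {
  stopifnot(inherits(table, "alias_table"), inherits(p, "term_pointer"))
  alias <- make_alias(section_no, term_no)
  if (alias %in% table$entries$alias) {
    stop("conflict error: alias ", alias, " already registered",
         call. = FALSE)
  }
  pointer <- build_pointer(p)
  xpath <- build_xpath(p$property_name, p$value_item)
  merged <- merge_pointer(p$file_url, xpath)
  entry <- data.frame(alias = alias,
                      section_no = as.integer(section_no),
                      term_no = as.integer(term_no),
                      pointer = pointer, xpath = xpath, merged = merged,
                      stringsAsFactors = FALSE)
  table$entries <- rbind(table$entries, entry)
  entry
}

#' Look up an alias
#'
#' @param table An [alias_table()].
#' @param ref Either an alias string or an integer pair
#'   `c(section_no, term_no)`.
#' @return The matching entry (one-row data frame), or an error.
#' @export
lookup_alias <- function(table, ref) {
  stopifnot(inherits(table, "alias_table"))
  if (is.numeric(ref) && length(ref) == 2L) {
    ref <- make_alias(ref[[1L]], ref[[2L]])
  }
  hit <- table$entries[table$entries$alias == ref, , drop = FALSE]
  if (nrow(hit) != 1L) {
    stop("resolution error: alias '", ref, "' not registered",
         call. = FALSE)
  }
  hit
}

#' Write / read an alias table as TSV
#'
#' The on-disk form is a tab-separated table with columns `alias`,
#' `section_no`, `term_no`, `pointer`, `xpath`, `merged` -- the
#' supplemental resource shipped alongside archetypes and templates.
#'
#' @param table An [alias_table()].
#' @param path File path.
#' @return `write_alias_table` returns `path` invisibly;
#'   `read_alias_table` returns an [alias_table()].
#' @export
write_alias_table <- function(table, path) {
  stopifnot(inherits(table, "alias_table"))
  utils::write.table(table$entries, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, fileEncoding = "UTF-8")
  invisible(path)
}

#' @rdname write_alias_table
#' @export
read_alias_table <- function(path) {
  # quote = "": XPath strings contain literal double quotes
  df <- utils::read.delim(path, sep = "\t", stringsAsFactors = FALSE,
                          quote = "", comment.char = "",
                          colClasses = c(alias = "character",
                                         section_no = "integer",
                                         term_no = "integer",
                                         pointer = "character",
                                         xpath = "character",
                                         merged = "character"))
  tab <- alias_table()
  if (anyDuplicated(df$alias)) {
    stop("conflict error: duplicate aliases in ", path, call. = FALSE)
  }
  tab$entries <- df
  tab
}

#' Dereference a terminology reference against local files
#'
#' Resolves either a registered `ODMLID` alias (via `table`) or a merged
#' pointer string to the text content of the XML element its XPath
#' selects.  Resolution is strictly offline: the URL must be mapped to a
#' local file path in `store`; nothing is fetched over the network.
#' Exactly one node must match.
#'
#' @param ref An alias or a merged pointer string.
#' @param store Named character vector mapping terminology URLs to local
#'   file paths.
#' @param table An [alias_table()], required when `ref` is an alias.
#' @return The matched element's text content.
#' @export
dereference <- function(ref, store, table = NULL) {
  if (is_alias(ref)) {
    if (is.null(table)) {
      stop("resolution error: alias dereference needs an alias table",
           call. = FALSE)
    }
    ref <- lookup_alias(table, ref)$merged
  }
  parts <- split_merged(ref)
  if (!parts$file_url %in% names(store)) {
    stop("resolution error: URL '", parts$file_url,
         "' is not mapped to a local file (offline store)", call. = FALSE)
  }
  path <- store[[parts$file_url]]
  doc <- xml2::read_xml(path)
  # evaluate the stored (document-relative) XPath from the document root
  nodes <- xml2::xml_find_all(doc, paste0("/", parts$xpath))
  if (length(nodes) != 1L) {
    stop("ambiguity error: XPath matched ", length(nodes),
         " node(s), expected exactly 1", call. = FALSE)
  }
  node_direct_text(nodes[[1L]])
}

# Direct text of a node, excluding child-element text (odML value
# elements carry their qualifiers as child elements in mixed content).
node_direct_text <- function(node) {
  txt <- xml2::xml_find_all(node, "text()")
  trimws(paste(vapply(txt, xml2::xml_text, character(1)), collapse = ""))
}
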