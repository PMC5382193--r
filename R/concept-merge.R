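#' @title Multi-source attribute aggregation
#' @description
#' Building one archetype concept from several electrophysiology format
#' vocabularies (NIX, EEGBase/BrainVision, EDF+) requires merging their
#' attribute lists.  The rules: identical attributes collapse to one;
#' single attributes are kept; semantically identical attributes (same
#' meaning, different representation -- declared through an explicit
#' synonym table, never inferred by string similarity) collapse keeping
#' the highest-priority source (NIX before EEGBase before EDF+); and
#' attributes with no explicit meaning, such as resource-internal IDs,
#' are dropped.
#' @name concept-merge
NULL

MERGE_SOURCES <- c("NIX", "EEGBase", "EDF+")

# Default patterns for unimportant / resource-structure attributes.
DEFAULT_DROP_PATTERNS <- c("(^|[._-])u?u?id$", "^internal[._-]")

normalize_attr_name <- function(x) {
  s <- gsub("([a-z0-9])([A-Z])", "\\1_\\2", trimws(x))  # camelCase split
  s <- tolower(s)
  gsub("[^a-z0-9]+", "_", s)
}

#' Construct a source attribute table
#'
#' @param name Character vector of attribute names.
#' @param source Character vector (recycled) of sources, each one of
#'   `"NIX"`, `"EEGBase"`, `"EDF+"`.
#' @return A data frame with columns `name` and `source`, of class
#'   `source_attributes`.
#' @export
#' @examples
#' source_attributes(c("SamplingRate", "sampling_rate"),
#'                   c("NIX", "EEGBase"))
source_attributes <- function(name, source) {
  source <- rep_len(source, length(name))
  bad <- setdiff(unique(source), MERGE_SOURCES)
  if (length(bad)) {
    stop("unknown source(s): ", paste(bad, collapse = ", "),
         "; valid: ", paste(MERGE_SOURCES, collapse = ", "),
         call. = FALSE)
  }
  structure(data.frame(name = as.character(name), source = source,
                       stringsAsFactors = FALSE),
            class = c("source_attributes", "data.frame"))
}

#' Construct a synonym table
#'
#' Maps per-source attribute names to a shared semantic key.  Lookup is
#' deterministic; names not listed map to themselves after
#' normalisation (lowercase, non-alphanumerics to `_`).
#'
#' @param names Character vector of attribute names.
#' @param keys Character vector of semantic keys, same length.
#' @return A named character vector of class `synonym_table`.
#' @export
#' @examples
#' syn <- synonym_table(c("SamplingRate", "sampling_rate"),
#'                      c("sampling-rate", "sampling-rate"))
synonym_table <- function(names = character(), keys = character()) {
  stopifnot(length(names) == length(keys))
  out <- stats::setNames(as.character(keys), as.character(names))
  class(out) <- c("synonym_table", class(out))
  out
}

#' Read a synonym table from TSV
#'
#' Expects columns `name` and `semantic_key`.
#'
#' @param path TSV file path.
#' @return A [synonym_table()].
#' @export
read_synonym_table <- function(path) {
  df <- utils::read.delim(path, sep = "\t", stringsAsFactors = FALSE)
  if (!all(c("name", "semantic_key") %in% names(df))) {
    stop("synonym table needs columns 'name' and 'semantic_key'",
         call. = FALSE)
  }
  synonym_table(df$name, df$semantic_key)
}

semantic_key_of <- function(name, syn) {
  if (!is.null(syn) && name %in% names(syn)) {
    unname(syn[[name]])
  } else {
    normalize_attr_name(name)
  }
}

#' Construct a merge policy
#'
#' @param priority Permutation of the three sources; earlier wins among
#'   semantically identical attributes.  Default `NIX`, `EEGBase`,
#'   `EDF+`.
#' @param drop_patterns Regular expressions (applied to normalised
#'   names); matching attributes are eliminated as unimportant.  The
#'   default drops ID/UUID-style and internal resource-structure fields.
#' @return An object of class `merge_policy`.
#' @export
merge_policy <- function(priority = MERGE_SOURCES,
                         drop_patterns = DEFAULT_DROP_PATTERNS) {
  if (!setequal(priority, MERGE_SOURCES) ||
      length(priority) != length(MERGE_SOURCES)) {
    stop("priority must be a permutation of ",
         paste(MERGE_SOURCES, collapse = ", "), call. = FALSE)
  }
  structure(list(priority = priority, drop_patterns = drop_patterns),
            class = "merge_policy")
}

#' Aggregate attributes from multiple source vocabularies
#'
#' Applies the aggregation and elimination rules: at most one surviving
#' attribute per semantic key, with the highest-priority source winning
#' among duplicates; unimportant attributes (matching the policy's drop
#' patterns) removed; singletons preserved.  Output order is the
#' first-occurrence order of the surviving semantic keys.
#'
#' @param attrs A [source_attributes()] data frame (or any data frame
#'   with `name` and `source` columns).
#' @param syn Optional [synonym_table()].
#' @param policy A [merge_policy()].
#' @return A data frame with columns `name`, `source`, `semantic_key`;
#'   idempotent under re-aggregation.
#' @export
#' @examples
#' attrs <- source_attributes(c("SamplingRate", "sampling_rate"),
#'                            c("NIX", "EEGBase"))
#' syn <- synonym_table(c("SamplingRate", "sampling_rate"),
#'                      c("sampling-rate", "sampling-rate"))
#' aggregate_attributes(attrs, syn)   # the NIX spelling survives
aggregate_attributes <- function(attrs, syn = NULL,
                                 policy = merge_policy()) {
  stopifnot(is.data.frame(attrs),
            all(c("name", "source") %in% names(attrs)),
            inherits(policy, "merge_policy"))
  if (nrow(attrs) == 0L) {
    return(data.frame(name = character(), source = character(),
                      semantic_key = character(),
                      stringsAsFactors = FALSE))
  }
  keys <- vapply(attrs$name, semantic_key_of, character(1), syn = syn)
  norm <- normalize_attr_name(attrs$name)
  dropped <- rep(FALSE, nrow(attrs))
  for (pat in policy$drop_patterns) dropped <- dropped | grepl(pat, norm)
  df <- data.frame(name = attrs$name, source = attrs$source,
                   semantic_key = keys, stringsAsFactors = FALSE)
  df <- df[!dropped, , drop = FALSE]
  if (nrow(df) == 0L) {
    rownames(df) <- NULL
    return(df)
  }
  prio <- match(df$source, policy$priority)
  keep <- logical(nrow(df))
  for (key in unique(df$semantic_key)) {
    idx <- which(df$semantic_key == key)
    winner <- idx[which.min(prio[idx])]  # ties: first occurrence wins
    keep[winner] <- TRUE
  }
  out <- df[keep, , drop = FALSE]
  # first-occurrence order of surviving keys
  out <- out[order(match(out$semantic_key, unique(df$semantic_key))), ,
             drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Read an attribute list from TSV
#'
#' Expects columns `name` and `source`.
#'
#' @param path TSV file path.
#' @return A [source_attributes()] data frame.
#' @export
read_attributes <- function(path) {
  df <- utils::read.delim(path, sep = "\t", stringsAsFactors = FALSE)
  if (!all(c("name", "source") %in% names(df))) {
    stop("attribute list needs columns 'name' and 'source'",
         call. = FALSE)
  }
  source_attributes(df$name, df$source)
}
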