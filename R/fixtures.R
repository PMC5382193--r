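#' Specification for a synthetic odML fixture
#'
#' Describes the shape of a generated odML document: a complete
#' `sections_per_level`-ary section tree of the given depth (the root is
#' depth 0), with a fixed number of properties per section and a given
#' fraction of enumerated (multi-value string) properties.  Identical
#' specifications always generate identical documents.
#'
#' @param depth Tree depth below the root (`>= 0`).
#' @param sections_per_level Subsections per section (`>= 1`).
#' @param props_per_section Properties per section (`>= 0`).
#' @param enum_fraction Fraction of properties drawn as enumerations, in
#'   `[0, 1]`.
#' @param seed Integer random seed.
#' @return An object of class `fixture_spec`.
#' @export
#' @examples
#' spec <- fixture_spec(depth = 2, sections_per_level = 2)
#' doc <- generate_fixture(spec)
fixture_spec <- function(depth = 1L, sections_per_level = 2L,
                         props_per_section = 3L, enum_fraction = 0.3,
                         seed = 1L) {
  depth <- as.integer(depth)
  sections_per_level <- as.integer(sections_per_level)
  props_per_section <- as.integer(props_per_section)
  seed <- as.integer(seed)
  stopifnot(depth >= 0L, sections_per_level >= 1L, props_per_section >= 0L,
            enum_fraction >= 0, enum_fraction <= 1, !is.na(seed))
  structure(
    list(depth = depth, sections_per_level = sections_per_level,
         props_per_section = props_per_section,
         enum_fraction = enum_fraction, seed = seed),
    class = "fixture_spec"
  )
}

# Run code under a private RNG stream, restoring global RNG state after.
with_fixture_seed <- function(seed, expr) {
  old <- if (exists(".Random.seed", envir = globalenv())) {
    get(".Random.seed", envir = globalenv())
  } else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv())) {
        rm(".Random.seed", envir = globalenv())
      }
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  set.seed(seed)
  force(expr)
}

FIXTURE_WORDS <- c("amplifier", "cap", "channel", "electrode", "filter",
                   "gain", "impedance", "latency", "montage", "protocol",
                   "rate", "reference", "session", "stimulus", "subject")

fixture_content <- function(dtype) {
  switch(dtype,
    int      = as.character(sample.int(1000L, 1L)),
    float    = format(round(stats::runif(1, 0, 100), 3), scientific = FALSE),
    boolean  = sample(c("true", "false"), 1L),
    date     = sprintf("20%02d-%02d-%02d", sample.int(30L, 1L),
                       sample.int(12L, 1L), sample.int(28L, 1L)),
    datetime = sprintf("20%02d-%02d-%02dT%02d:%02d:00", sample.int(30L, 1L),
                       sample.int(12L, 1L), sample.int(28L, 1L),
                       sample.int(23L, 1L), sample(0:59, 1L)),
    time     = sprintf("%02d:%02d:%02d", sample.int(23L, 1L),
                       sample(0:59, 1L), sample(0:59, 1L)),
    url      = paste0("http://example.org/", sample(FIXTURE_WORDS, 1L)),
    person   = paste(sample(c("Alice", "Bob", "Carol", "Dan"), 1L),
                     sample(c("Novak", "Svoboda", "Dvorak"), 1L)),
    binary   = paste(sample(c(LETTERS, letters, 0:9), 12L, replace = TRUE),
                     collapse = ""),
    `2-tuple` = sprintf("(%d; %d)", sample.int(100L, 1L),
                        sample.int(100L, 1L)),
    # string / text
    sample(FIXTURE_WORDS, 1L)
  )
}

# Scalar dtypes the generator draws from; enumerations are always string.
FIXTURE_SCALAR_DTYPES <- c("int", "float", "string", "text", "boolean",
                           "date", "datetime", "time", "url", "person",
                           "binary", "2-tuple")

fixture_property <- function(id, enum_fraction) {
  name <- paste0("P", id, "_", sample(FIXTURE_WORDS, 1L))
  if (stats::runif(1) < enum_fraction) {
    k <- sample(2:4, 1L)
    items <- paste0(sample(FIXTURE_WORDS, k), "_", seq_len(k))
    odml_property(name, items, dtype = "string")
  } else {
    dtype <- sample(FIXTURE_SCALAR_DTYPES, 1L)
    unit <- if (dtype == "float" && stats::runif(1) < 0.5) "mV" else NULL
    unc <- if (!is.null(unit) && stats::runif(1) < 0.5) {
      round(stats::runif(1, 0, 1), 3)
    } else NULL
    odml_property(name, list(odml_value(fixture_content(dtype),
                                        dtype = dtype, unit = unit,
                                        uncertainty = unc)))
  }
}

fixture_section <- function(spec, level, counter) {
  id <- counter$n
  counter$n <- counter$n + 1L
  props <- lapply(seq_len(spec$props_per_section), function(i) {
    fixture_property(paste0(id, "_", i), spec$enum_fraction)
  })
  subs <- if (level < spec$depth) {
    lapply(seq_len(spec$sections_per_level), function(i) {
      fixture_section(spec, level + 1L, counter)
    })
  } else list()
  odml_section(paste0("S", id, "_", sample(FIXTURE_WORDS, 1L)),
               type = sample(c("recording", "hardware", "analysis"), 1L),
               definition = paste("synthetic section", id),
               properties = props, subsections = subs)
}

#' Generate a synthetic odML document
#'
#' Emulates experiment-metadata documents (section trees with typed
#' properties, occasional units/uncertainties and enumerated string
#' properties) for property-based testing.  The same [fixture_spec()]
#' always yields the identical document; the global RNG state is left
#' untouched.
#'
#' @param spec A [fixture_spec()].
#' @return An [odml_document()] with
#'   `sum(sections_per_level^(0:depth))` sections.
#' @export
generate_fixture <- function(spec) {
  stopifnot(inherits(spec, "fixture_spec"))
  with_fixture_seed(spec$seed, {
    counter <- new.env(parent = emptyenv())
    counter$n <- 1L
    root <- fixture_section(spec, 0L, counter)
    odml_document(root, author = "fixture-generator",
                  date = "2026-01-01")
  })
}
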