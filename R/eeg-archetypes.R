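#' @title The EEG/ERP archetype registry
#' @description
#' Eleven archetypes cover the experimental EEG/ERP domain: six reused
#' unchanged from the public Clinical Knowledge Manager (Report,
#' Medication order, Problem/Diagnosis, Device, Environmental
#' conditions, Person), one extended (Device details), and four new ones
#' built here (EEG/ERP result on the Observation RM; Experiment
#' scenario, Software and Stimulus on the Cluster RM).  Reused CKM
#' archetypes are represented as manifest stubs -- name, reference model
#' and slot signature -- since their content is maintained upstream; the
#' four new archetypes are constructed programmatically, Software and
#' Stimulus directly from the packaged odML terminology fixtures.
#' @name eeg-archetypes
NULL

REGISTRY_STATUSES <- c("ckm_reused", "extended", "new")

default_manifest_path <- function() {
  system.file("extdata", "archetype_registry.tsv", package = "odml2ehr",
              mustWork = TRUE)
}

terminology_fixture_path <- function(which) {
  system.file("extdata", "terminology",
              paste0(which, "_synthetic.xml"), package = "odml2ehr",
              mustWork = TRUE)
}

# Published-terminology-style URLs the packaged fixtures stand in for;
# dereferencing maps them to the local files (offline store).
TERMINOLOGY_URLS <- c(
  electrode = "http://portal.g-node.org/odml/terminologies/v1.0/electrode/electrode.xml",
  software = "http://portal.g-node.org/odml/terminologies/v1.0/software/software.xml",
  stimulus = "http://portal.g-node.org/odml/terminologies/v1.0/stimulus/stimulus.xml"
)

#' The packaged terminology store
#'
#' @return Named character vector mapping terminology URLs to the local
#'   synthetic fixture paths, suitable as the `store` argument of
#'   [dereference()].
#' @export
terminology_store <- function() {
  stats::setNames(
    vapply(names(TERMINOLOGY_URLS), terminology_fixture_path, character(1)),
    unname(TERMINOLOGY_URLS)
  )
}

#' Load the archetype registry
#'
#' @param manifest_path Path to a registry manifest TSV with columns
#'   `name`, `rm`, `status`, `source`; defaults to the packaged
#'   manifest.
#' @return A data frame of registry entries, of class
#'   `archetype_registry`.  The packaged manifest yields 11 entries:
#'   6 reused, 1 extended, 4 new.
#' @export
#' @examples
#' reg <- load_registry()
#' table(reg$status)
load_registry <- function(manifest_path = default_manifest_path()) {
  if (!file.exists(manifest_path)) {
    stop("config error: manifest not found: ", manifest_path,
         call. = FALSE)
  }
  df <- tryCatch(
    utils::read.delim(manifest_path, sep = "\t",
                      stringsAsFactors = FALSE),
    error = function(e) {
      stop("config error: cannot read manifest: ", conditionMessage(e),
           call. = FALSE)
    }
  )
  if (nrow(df) == 0L) {
    warning("empty registry manifest: ", manifest_path, call. = FALSE)
    df <- data.frame(name = character(), rm = character(),
                     status = character(), source = character(),
                     stringsAsFactors = FALSE)
    class(df) <- c("archetype_registry", "data.frame")
    return(df)
  }
  required <- c("name", "rm", "status", "source")
  if (!all(required %in% names(df))) {
    stop("config error: manifest needs columns ",
         paste(required, collapse = ", "), call. = FALSE)
  }
  if (anyDuplicated(df$name)) {
    stop("config error: duplicate archetype names in manifest",
         call. = FALSE)
  }
  bad_status <- setdiff(unique(df$status), REGISTRY_STATUSES)
  if (length(bad_status)) {
    stop("config error: unknown status(es): ",
         paste(bad_status, collapse = ", "), call. = FALSE)
  }
  bad_rm <- setdiff(unique(df$rm), rm_registry()$name)
  if (length(bad_rm)) {
    stop("config error: unknown reference model(s): ",
         paste(bad_rm, collapse = ", "), call. = FALSE)
  }
  class(df) <- c("archetype_registry", "data.frame")
  df
}

read_result_datapoints <- function(path = NULL) {
  if (is.null(path)) {
    path <- system.file("extdata", "eegerp_result_datapoints.tsv",
                        package = "odml2ehr", mustWork = TRUE)
  }
  utils::read.delim(path, sep = "\t", stringsAsFactors = FALSE)
}

build_eegerp_result <- function(datapoints_path = NULL) {
  manifest <- read_result_datapoints(datapoints_path)
  alloc <- code_allocator()
  terms <- list()
  root_code <- alloc$new_code()  # at0000
  terms[[1L]] <- ontology_term(
    root_code, "EEG/ERP result",
    "EEG/ERP recording: conditions, results, time events and subject state")

  new_cluster <- function(name, definition, children,
                          occurrences = c(0L, 1L)) {
    code <- alloc$new_code()
    terms[[length(terms) + 1L]] <<- ontology_term(code, name, definition)
    datapoint(code, "cluster", occurrences = occurrences,
              children = children)
  }
  new_element <- function(name, definition, datatype,
                          enum_items = NULL) {
    code <- alloc$new_code()
    enum_codes <- NULL
    if (!is.null(enum_items)) {
      enum_codes <- vapply(enum_items, function(item) {
        ec <- alloc$new_code()
        terms[[length(terms) + 1L]] <<-
          ontology_term(ec, item, paste0("predefined ", name, " value"))
        ec
      }, character(1))
    }
    terms[[length(terms) + 1L]] <<- ontology_term(code, name, definition)
    datapoint(code, "element", datatype = datatype,
              enum_codes = unname(enum_codes))
  }
  new_slot <- function(name, definition, pattern,
                       occurrences = c(0L, 1L)) {
    code <- alloc$new_code()
    terms[[length(terms) + 1L]] <<- ontology_term(code, name, definition)
    datapoint(code, "slot", occurrences = occurrences,
              allowed_archetypes = pattern)
  }

  # protocol: how the recording was conducted; at least one electrode
  # per recording, hence the raised lower occurrence bound on that slot
  protocol <- new_cluster("Protocol",
    "Recording conditions and acquisition set-up", list(
    new_slot("Hardware", "Recording hardware (amplifier, cap, ...)",
             "openEHR-EHR-CLUSTER\\.device\\.v1"),
    new_slot("Electrode", "Electrodes used for the recording",
             "openEHR-EHR-CLUSTER\\.device\\.v1",
             occurrences = c(1L, NA)),
    new_slot("Software", "Software used for recording or presentation",
             "openEHR-EHR-CLUSTER\\.software\\.v1"),
    new_slot("Environment", "Environmental conditions of the recording",
             "openEHR-EHR-CLUSTER\\.environmental_conditions\\.v1")
  ))

  branch_cluster <- function(branch, name, definition) {
    rows <- manifest[manifest$branch == branch, , drop = FALSE]
    kids <- lapply(seq_len(nrow(rows)), function(i) {
      row <- rows[i, ]
      new_element(row$name, row$definition, map_datatype(row$dtype))
    })
    new_cluster(name, definition, kids)
  }
  data_part <- new_cluster("Data", "Observation results", list(
    branch_cluster("data_array", "Data Array",
                   "Binary data storage compatible with NIX data arrays"),
    branch_cluster("results", "Results",
                   "Summary of the recording results")
  ))
  events <- new_cluster("Events",
    "Time events during the observation", list(
    new_element("Recording interval",
                "Time interval over which the recording ran",
                "interval_of_date_time")
  ))
  state <- new_cluster("State",
    "Subject state restricted to position and textual description", list(
    new_element("Position", "Subject's position during recording",
                "coded_text",
                enum_items = c("sitting", "standing", "lying")),
    new_element("Description", "Free-text subject state description",
                "text")
  ))

  root <- datapoint(root_code, "cluster", occurrences = c(1L, 1L),
                    children = list(protocol, data_part, events, state))
  archetype(
    archetype_id = "openEHR-EHR-OBSERVATION.eeg_erp_result.v1",
    concept = root_code, definition = root, ontology = terms,
    rm = "Observation",
    description = "EEG/ERP recording with protocol, data, events and state")
}

build_experiment_scenario <- function() {
  alloc <- code_allocator()
  terms <- list()
  root_code <- alloc$new_code()
  terms[[1L]] <- ontology_term(
    root_code, "Experiment scenario",
    "Description of the experiment/trial scenario and its stimulation")
  el <- function(name, definition, datatype) {
    code <- alloc$new_code()
    terms[[length(terms) + 1L]] <<- ontology_term(code, name, definition)
    datapoint(code, "element", datatype = datatype)
  }
  sl <- function(name, definition, pattern) {
    code <- alloc$new_code()
    terms[[length(terms) + 1L]] <<- ontology_term(code, name, definition)
    datapoint(code, "slot", allowed_archetypes = pattern)
  }
  root <- datapoint(root_code, "cluster", occurrences = c(1L, 1L),
                    children = list(
    el("Name", "Scenario name", "text"),
    el("Description", "Free-text scenario description", "text"),
    el("Scenario file",
       "Original scenario file attached as multimedia (format varies by design tool)",
       "multimedia"),
    sl("Software", "Software the scenario was built in",
       "openEHR-EHR-CLUSTER\\.software\\.v1"),
    sl("Stimulus", "Stimulus used by the scenario",
       "openEHR-EHR-CLUSTER\\.stimulus\\.v1")
  ))
  archetype(
    archetype_id = "openEHR-EHR-CLUSTER.experiment_scenario.v1",
    concept = root_code, definition = root, ontology = terms,
    rm = "Cluster",
    description = "Experiment scenario with multimedia attachment and software/stimulus slots")
}

# Alias section numbers for the packaged terminology sections.  The
# electrode section is number 7 (its Reference term is term 13 in the
# published numbering); software and stimulus get the following free
# numbers.
TERMINOLOGY_SECTION_NO <- c(electrode = 7L, software = 8L, stimulus = 9L)

#' Build the four new EEG/ERP archetypes
#'
#' Constructs `EEG/ERP result` (Observation RM, with the four protocol
#' slots, the Data Array / Results data branches, events and the
#' position-plus-text state), `Experiment scenario` (Cluster RM, with a
#' multimedia scenario attachment and Software/Stimulus slots), and
#' `Software` and `Stimulus` (Cluster RM), the latter two transformed
#' directly from the packaged odML terminology fixtures with full term
#' binding.  All four validate cleanly.
#'
#' @param software_path,stimulus_path Paths to odML terminology files
#'   for the Software and Stimulus sections; default to the packaged
#'   synthetic fixtures.
#' @param datapoints_path Optional path to the EEG/ERP result datapoint
#'   manifest TSV.
#' @return Named list of four [archetype()] objects
#'   (`eeg_erp_result`, `experiment_scenario`, `software`, `stimulus`)
#'   with attributes `alias_tables` (named list of [alias_table()]s for
#'   the transformed pair) and `store` (URL to local path mapping for
#'   dereferencing).
#' @export
build_new_archetypes <- function(software_path = terminology_fixture_path("software"),
                                 stimulus_path = terminology_fixture_path("stimulus"),
                                 datapoints_path = NULL) {
  for (p in c(software_path, stimulus_path)) {
    if (!file.exists(p)) {
      stop("build error: terminology fixture missing: ", p, call. = FALSE)
    }
  }
  sw_doc <- parse_odml(software_path)
  st_doc <- parse_odml(stimulus_path)
  if (sw_doc$root$name != "Software") {
    stop("build error: expected a Software root section in ",
         software_path, call. = FALSE)
  }
  if (st_doc$root$name != "Stimulus") {
    stop("build error: expected a Stimulus root section in ",
         stimulus_path, call. = FALSE)
  }
  sw <- transform_document(sw_doc, transform_options(
    terminology_url = TERMINOLOGY_URLS[["software"]],
    section_no = TERMINOLOGY_SECTION_NO[["software"]],
    bind_terms = TRUE))
  st <- transform_document(st_doc, transform_options(
    terminology_url = TERMINOLOGY_URLS[["stimulus"]],
    section_no = TERMINOLOGY_SECTION_NO[["stimulus"]],
    bind_terms = TRUE))
  out <- list(
    eeg_erp_result = build_eegerp_result(datapoints_path),
    experiment_scenario = build_experiment_scenario(),
    software = sw$archetype,
    stimulus = st$archetype
  )
  attr(out, "alias_tables") <- list(software = sw$alias_table,
                                    stimulus = st$alias_table)
  store <- terminology_store()
  store[[TERMINOLOGY_URLS[["software"]]]] <- software_path
  store[[TERMINOLOGY_URLS[["stimulus"]]]] <- stimulus_path
  attr(out, "store") <- store
  out
}
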