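# Shared fixtures and independent oracles.

ELECTRODE_URL <-
  "http://portal.g-node.org/odml/terminologies/v1.0/electrode/electrode.xml"

electrode_fixture_path <- function() {
  system.file("extdata", "terminology", "electrode_synthetic.xml",
              package = "odml2ehr", mustWork = TRUE)
}

# Electrode/Usage/Reference document built in code (mirrors the packaged
# fixture's core structure).
electrode_doc <- function() {
  odml_document(
    odml_section("Electrode", type = "hardware",
                 definition = "EEG electrode",
                 properties = list(
                   odml_property("Usage",
                                 c("Reference", "Recording", "Ground")),
                   odml_property("Impedance",
                                 list(odml_value("5.2", "float",
                                                 unit = "kOhm")))
                 )))
}

# Independent dereference oracle: structural tree walk by element names
# only -- no XPath involved.  Returns the matched value texts.
walk_lookup <- function(path, section_name, property_name, item) {
  child_named <- function(node, nm) {
    kids <- xml2::xml_children(node)
    kids[xml2::xml_name(kids) == nm]
  }
  direct_text <- function(node) {
    txt <- xml2::xml_find_all(node, "text()")
    trimws(paste(vapply(txt, xml2::xml_text, character(1)), collapse = ""))
  }
  root <- xml2::read_xml(path)
  hits <- character()
  for (sec in child_named(root, "section")) {
    nm <- direct_text(child_named(sec, "name")[[1L]])
    if (nm != section_name) next
    for (prop in child_named(sec, "property")) {
      pnm <- direct_text(child_named(prop, "name")[[1L]])
      if (pnm != property_name) next
      for (val in child_named(prop, "value")) {
        if (direct_text(val) == item) hits <- c(hits, direct_text(val))
      }
    }
  }
  hits
}

# Write a document under the session temp dir and return an offline
# store mapping `url` to it.
local_store <- function(doc, url) {
  path <- tempfile(fileext = ".xml")
  writeLines(write_odml(doc), path)
  stats::setNames(path, url)
}
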