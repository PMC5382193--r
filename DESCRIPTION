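Package: odml2ehr
Title: Represent EEG/ERP Experiment Metadata as openEHR Archetypes
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "maintainer@example.org")
Description: Tools for bridging electrophysiology experiment metadata and
    two-level electronic health record modelling.  Reads and writes odML
    (open metaData Markup Language) v1 XML documents, transforms odML
    section trees into openEHR Cluster-reference-model archetypes with a
    fixed odML-to-openEHR datatype mapping, serialises archetypes to an
    ADL 1.4-style text form and validates their structure, implements a
    four-step terminology referencing scheme (pointer strings, XPath
    queries, merged dereferenceable references, and a bijective ODMLID
    alias registry), aggregates attribute vocabularies from multiple
    electrophysiology data formats (NIX, EEGBase/BrainVision, EDF+) under
    priority and elimination rules, and ships an EEG/ERP archetype
    registry with Report-composition template composition and reduction.
    A seeded synthetic odML fixture generator supports property-based
    testing; a command-line entry point exposes every operation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    xml2,
    jsonlite,
    yaml,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
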