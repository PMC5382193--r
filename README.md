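# odml2ehr

Experimental EEG/ERP (electroencephalography / event-related potential)
recordings carry rich metadata — electrodes, amplifiers, software,
stimuli, subject state — typically stored as odML (open metaData Markup
Language) trees of sections, properties and values. Clinical
informatics, meanwhile, standardises such content with openEHR two-level
modelling: generic reference models (RMs) constrained by domain
*archetypes*, deployed through *templates*. `odml2ehr` bridges the two
worlds for researchers and data stewards who want experimental
electrophysiology metadata expressed as standard health-record
structures.

The package provides:

- **odML v1 I/O** — read and write the XML dialect
  (`odML`/`section`/`property`/`value`), plus a seeded synthetic
  document generator for property-based testing.
- **The odML → archetype transformation** — any odML section tree maps
  losslessly onto a Cluster-RM archetype: root section → archetype
  metadata, sections → (nested) clusters, properties → typed element
  datapoints, enumerations → predefined internal `atNNNN` codes. A
  fixed twelve-pair datatype mapping covers all odML types
  (`int → count`, `float → quantity`, `binary → multimedia`,
  `person → demographic slot`, `2-tuple → two-element cluster`, …),
  with sibling start/end times merged into an interval of datetimes.
- **Terminology referencing** — odML terminology terms have no native
  IDs, so references are built in four steps:
  1. pointer string `⟨file URL⟩#⟨section⟩:⟨property⟩/⟨item⟩`,
  2. XPath query
     `odML[@version = "1"]/section/property/name[text() = "⟨property⟩"]/../value[text() = "⟨item⟩"]`,
  3. merged dereferenceable string `⟨file URL⟩#/⟨XPath⟩`,
  4. a 12-character alias `ODMLID` + 3-digit section number + 3-digit
     term number, kept in a bijective alias table (archetype tooling
     rejects raw merged strings as terminology codes).
  Dereferencing is strictly offline against a URL → local-file store.
- **ADL serialisation and validation** — ADL 1.4-style output with the
  five mandatory sections (archetype ID, concept, language, definition,
  ontology) and structural validation (code/ontology pairing, closed
  datatype set, binding syntax, occurrence intervals).
- **Concept aggregation** — merge attribute vocabularies from NIX,
  EEGBase/BrainVision and EDF+ under explicit synonym tables, source
  priority (NIX ≻ EEGBase ≻ EDF+) and ID-elimination rules.
- **The EEG/ERP archetype registry** — eleven archetypes (six reused
  from the public CKM, one extended, four new: EEG/ERP result,
  Experiment scenario, Software, Stimulus), with Report-composition
  templates and stimulus-specific datapoint reductions.

## Worked example

The reference electrode term lives in the `Electrode` terminology
section under the `Usage` property as the enumeration item `Reference`:

```r
library(odml2ehr)

url <- "http://portal.g-node.org/odml/terminologies/v1.0/electrode/electrode.xml"
p   <- term_pointer(url, "Electrode", "Usage", "Reference")
build_pointer(p)
#> [1] "http://portal.g-node.org/odml/terminologies/v1.0/electrode/electrode.xml#Electrode:Usage/Reference"

xp <- build_xpath("Usage", "Reference")
xp
#> [1] "odML[@version = \"1\"]/section/property/name[text() = \"Usage\"]/../value[text() = \"Reference\"]"

make_alias(7, 13)
#> [1] "ODMLID007013"

# offline dereference against the packaged terminology fixture
store <- terminology_store()
dereference(merge_pointer(url, xp), store)
#> [1] "Reference"
```

The pointer names the file, section, property and item; the alias is
the short form archetype bindings use; dereferencing evaluates the
stored XPath against the local copy of the terminology file and
recovers the original item text.

Transforming an odML document into an archetype:

```r
doc <- parse_odml(system.file("extdata", "terminology",
                              "electrode_synthetic.xml",
                              package = "odml2ehr"))
tr  <- transform_document(doc, transform_options(
         terminology_url = url, section_no = 7, bind_terms = TRUE))
tr$archetype
#> <archetype openEHR-EHR-CLUSTER.electrode.v1>
#>   RM: Cluster  concept: at0000  terms: 7
validate_archetype(tr$archetype)
#> character(0)
tr$alias_table
#> <alias_table> 3 registered term(s)
```

The three-item `Usage` enumeration became an element with three
predefined internal codes, each bound to a registered `ODMLID` alias;
an empty validation report means the archetype is structurally sound.
The registry census:

```r
reg <- load_registry()
table(reg$status)
#>
#> ckm_reused   extended        new
#>          6          1          4
```

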