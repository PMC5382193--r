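---
title: "From odML metadata trees to openEHR archetypes: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{From odML metadata trees to openEHR archetypes: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(odml2ehr)
```

## The modelling problem

Experimental EEG/ERP metadata is commonly kept as odML: a generic tree
of *sections* (each with a name, type and definition), holding
*properties*, holding typed *values*. openEHR models the same kind of
content with two levels: a small set of generic reference models (RMs)
— five entry types (Observation, Evaluation, Action, Instruction,
Admin Entry), two structural (Composition, Section) and three
data-structure models (Element, Cluster, Structure) — constrained by
domain *archetypes* written in ADL, and deployed through *templates*
that wire archetypes together and prune their datapoint sets.

Because an odML document is a finite ordered tree, the Cluster RM can
represent any odML structure without loss of expressive power. This
package implements that correspondence as an executable
transformation, together with the referencing machinery needed to bind
archetype terms to odML terminology entries, the aggregation rules for
building concepts from several source vocabularies, and a packaged
EEG/ERP archetype registry.

## The odML dialect

We implement the v1 XML element vocabulary subset: `odML` (with a
mandatory `version="1"` attribute), `section`, `property`, `name`,
`type`, `definition`, `value`, `unit`, `uncertainty`. Other simple
section child elements (`reference`, `dependency`, …) are parsed into
an open key/value bag and re-emitted verbatim; that bag is a
containment strategy for attributes the dialect never pins down, not a
schema claim. Unknown structured children are skipped with a warning.
Encoding is fixed to UTF-8, element order is significant and
preserved, and serialisation is deterministic: equal documents yield
byte-equal XML (the attribute bag is emitted in lexical key order, so
equality is modulo bag ordering). Datatypes form the closed
twelve-name set `person`, `date`, `text`, `int`, `string`, `float`,
`binary`, `url`, `datetime`, `time`, `boolean`, `2-tuple`; all values
of one property share one datatype.

A property is treated as an **enumeration** when it is string- or
text-typed and carries at least two values — the pattern the electrode
terminology uses for its `Usage` property (`Reference`, `Recording`,
`Ground`). This is the trigger for the predefined-internal-code rule
in the transformation. A single-valued string property is an ordinary
text datapoint.

## The transformation

`transform_document()` maps the tree onto a Cluster-RM archetype:

- the **root section** becomes the archetype: its name is the concept
  (code `at0000`), its definition/type and the document author/date
  populate the description metadata, and the archetype id is
  `openEHR-EHR-CLUSTER.<slug>.v1` (CKM-style naming; the slug is the
  lowercased root name with non-alphanumerics collapsed to `_`);
- **sections and subsections** become clusters and nested clusters, in
  order; the section name/type/definition land in the cluster's
  ontology term;
- **properties** become element datapoints with the mapped datatype;
- **enumerations** become elements whose items are freshly allocated
  internal codes, one per item, each with its own ontology term.

Internal codes are allocated sequentially in document order
(`at0000`, `at0001`, …), so output is deterministic and bit-comparable
across runs. The pipeline ordering — root attributes to metadata, then
sections to clusters, properties to elements, enumeration items to
codes, then bindings — is this package's own; the correspondence
constrains what maps to what, not the traversal order, and any
depth-first order yields the same structure.

The datatype mapping is total over exactly the twelve odML types:

| odML | openEHR |
|------|---------|
| date, datetime, time | date_time |
| text, string | text |
| int | count |
| float | quantity |
| binary | multimedia |
| url | URI |
| boolean | boolean |
| person | slot for demographic archetypes |
| 2-tuple | cluster of two elements |

Three special cases:

- **start/end merging**: when sibling properties named `StartTime` and
  `EndTime` (case-insensitive) coexist, they merge into a single
  element of type *interval of date_time*. The name-based trigger is
  our choice — the merge rule itself says only "when start and end
  time are present at once", so some trigger had to be fixed; exact
  sibling names are predictable and never fire accidentally on
  unrelated time properties. `start_end_merge = FALSE` disables it.
- **person** properties become slots constrained to demographic
  archetypes rather than text elements: a person is an independent
  demographic entity, not a string of the recording.
- **2-tuple** expands to a cluster of two elements whose shared
  datatype is guessed from the tuple content (`(1; 5)` → count,
  `(0.5; 2.5)` → quantity, otherwise text). The mapping admits all
  three without a selection rule, so text is the safe default when the
  content is not numeric.

Every transformed archetype passes `validate_archetype()` with zero
issues; this is enforced as a property-based test over the synthetic
generator and is a hard postcondition, not a tendency.

## Terminology referencing

odML terminology terms have no dereferenceable identifiers, so
references are constructed in four steps, all implemented in
`term_pointer`/`build_pointer`/`build_xpath`/`merge_pointer`/`make_alias`:

1. the **pointer string** `⟨file URL⟩#⟨section⟩:⟨property⟩/⟨item⟩` —
   hash, colon and slash are the separators;
2. the **XPath query**
   `odML[@version = "1"]/section/property/name[text() = "…"]/../value[text() = "…"]`,
   fixed to XPath 1.0 with double-quoted literals and spaces around
   `=` exactly as documented, so outputs are byte-comparable;
3. the **merged string** `⟨file URL⟩#/⟨XPath⟩`, splittable at the
   first `#/`;
4. the **alias** `ODMLID` + zero-padded 3-digit section number +
   zero-padded 3-digit term number (12 characters), because archetype
   editors and libraries reject raw merged strings as terminology
   codes.

Aliases and `(section, term)` pairs are bijective by construction;
the table persists as TSV (`alias`, `section_no`, `term_no`,
`pointer`, `xpath`, `merged`). Section numbers are caller-assigned —
no published allocation rule exists, and the known worked example
(electrode section 7, reference term 13) implies an enumeration nobody
printed. Inside `transform_document()` term numbers are allocated
sequentially from 1 in registration order; the packaged registry
assigns section 7 to electrode, 8 to software, 9 to stimulus.

**Dereferencing is offline-first**: a reference resolves only through
an explicit URL → local-file store; nothing is ever fetched over the
network. This makes every resolution reproducible and keeps the test
suite hermetic. Exactly one node must match; zero or several matches
raise an ambiguity error rather than returning a guess.

One scope consequence worth stating: the XPath grammar of step 2 is
rooted at `odML/section`, i.e. it addresses terms in *flat,
one-concept-per-file* terminology documents — which is how terminology
files are organised (each file carries one root section). Enumerations
sitting in nested subsections of a larger document are still
transformed and aliased, but their stored XPath will not locate them
in that deep document; binding inverses are therefore guaranteed for
terminology-shaped inputs, and the acceptance checks measure them
there.

## Validation and ADL output

`validate_archetype()` returns issues as data (a character vector,
empty when valid): mandatory sections populated; definition and
ontology codes pairing up exactly (both directions); element datatypes
drawn from the closed openEHR set reachable through the mapping (plus
`coded_text` for enumerations and the interval form); binding aliases
syntactically valid; occurrence intervals sane. `serialize_adl()`
refuses invalid archetypes, naming the violated rule, and otherwise
emits deterministic ADL 1.4-style text: always exactly the five
mandatory blocks (`archetype`, `concept`, `language`, `definition`,
`ontology`), optional blocks (`specialise`, `description`,
`invariant`, `revision_history`) only when populated, and bindings
under the named external terminology `"odML"` with alias codes. A
full ADL *parser* is deliberately out of scope; validation operates on
the object model, which is also what the serialiser consumes, so
everything written was validated first.

## Concept aggregation

`aggregate_attributes()` merges attribute lists from NIX, EEGBase
(BrainVision) and EDF+ under four rules: identical attributes collapse
to one; singletons are kept; semantically identical attributes
collapse keeping the highest-priority source (default order NIX,
EEGBase, EDF+); and unimportant attributes — IDs and
resource-structure fields, matched by overridable drop patterns — are
removed. Semantic identity is declared through an explicit synonym
table mapping names to shared keys; unlisted names map to themselves
after normalisation (camelCase split, lowercased, non-alphanumerics to
`_`). We deliberately do **no** fuzzy matching: the original
aggregation judgement was manual, and silent string-similarity
inference would be unverifiable. Aggregation is idempotent, keys in
the output are unique, and priority dominance is tested exhaustively
over every source multiset of size up to three.

The packaged `recording_attributes.tsv`/`recording_synonyms.tsv` pair
is a small illustrative manifest, not a transcription of any published
merged attribute set (those figures are not available as text).

## The archetype registry

The packaged manifest lists eleven archetypes: six CKM archetypes
reused as-is (Report, Medication order, Problem/Diagnosis, Device,
Environmental conditions, Person), one extended (Device details), and
four new ones. Reused CKM entries are manifest stubs — name, RM, slot
signature — because their content is maintained upstream and
reimplementing it would be both out of scope and version-unstable.
The published census (eleven archetypes: 6 + 1 + 4) does not itemise
all eleven names; the printed table stops at nine and the running text
adds Device details. Our manifest therefore *declares* a resolution:
Device details carries the `extended` flag, and the eleventh entry is
Person, the demographic archetype that person-typed datapoints slot
to. Both choices are configurable through a custom manifest.

The four new archetypes:

- **EEG/ERP result** (Observation RM) carries all four Observation
  facets. *Protocol* holds four slots — Hardware and Electrode
  (both constrained to the Device archetype; the Electrode slot's
  lower occurrence bound is 1, encoding that a recording needs at
  least one electrode), Software, and Environment. *Data* splits into
  the Data Array branch (NIX-compatible storage: dimensions, source,
  tags, plus BrainVision-style attributes) and the Results branch
  (experiment-level summaries). *Events* models the recording
  interval; *State* is restricted to the subject's position (a coded
  sitting/standing/lying enumeration) and a textual description. The
  leaf datapoints are manifest-driven
  (`inst/extdata/eegerp_result_datapoints.tsv`) because the full leaf
  list is not recoverable from any printed source; the manifest is the
  single point of truth and is deliberately editable.
- **Experiment scenario** (Cluster RM): name, description, the
  original scenario file as a multimedia attachment (scenario formats
  vary from flashing lights to scripted game levels, so multimedia is
  the only honest type), and Software and Stimulus slots.
- **Software** and **Stimulus** (Cluster RM) are produced by
  `transform_document()` over the packaged terminology fixtures with
  full term binding — they are the transformation eating its own dog
  food, and their bindings dereference back into the fixture files.

The packaged terminology files are *synthetic* stand-ins (labelled so
in their filenames): they reproduce the section/property/value
structure the real terminology uses — including the
Electrode/Usage/Reference worked example and the movie/pulse/ramp
stimulus families — without copying any published file.

Templates wire the archetypes into a Report composition with four
RM-checked slots (Evaluation → Problem/Diagnosis, Instruction →
Medication order, Cluster → Experiment scenario, Observation →
EEG/ERP result); mismatched fills are rejected naming the slot and RM.
`reduce_template()` records retained datapoint codes per archetype;
repeated reductions intersect, so the retained set is monotone
non-increasing — a template can specialise the Stimulus archetype down
to one stimulus family (movie, pulse, ramp, …) but can never add
datapoints.

## The synthetic generator

`generate_fixture()` emulates experiment-metadata documents: a
complete k-ary section tree of configurable depth, a fixed number of
properties per section, datatypes drawn across the full twelve-type
set, occasional units and uncertainties on quantities, and a
configurable fraction of enumerated properties (default 0.3, roughly
the density the terminology fixtures themselves show; default shape
depth 1, two sections per level, three properties per section — a
small realistic metadata document). Generation is seed-deterministic
and leaves the global RNG state untouched.

What the generator does *not* emulate: real odML terminology
inheritance/`include` links, cross-file references, multi-root
documents, or the actual vocabulary of any published terminology.
Passing round-trip and transformation tests on generated documents
therefore demonstrates structural correctness of the pipeline, not
coverage of any real repository's content.

## Numerical and procedural choices

- Fixture shapes in the test suite are kept small (depths ≤ 3, a few
  hundred documents): the properties under test are structural, so
  breadth of shapes matters and raw size does not. The acceptance
  run uses 200 round-trip fixtures, 40 transformation fixtures, 100
  alias registrations and the exhaustive 39-case merge enumeration.
- Ties in concept merging (two candidates from the *same* source for
  one key) resolve to the first occurrence, keeping output order
  stable.
- Degenerate inputs: empty sections transform to childless clusters
  (permitted); an empty attribute list aggregates to an empty result;
  an empty registry manifest loads as an empty registry with a
  warning; alias capacity (1000 terms per section number) raises an
  explicit capacity error rather than wrapping around.
- The merged-string inverse (`split_merged`) splits at the *first*
  `#/`, which is unambiguous for any URL not itself containing `#/`.

## Known limitations

- No ADL parsing: archetypes enter the system through the object
  model or the odML transformation, not from ADL text.
- No odML ≥ 1.1 RDF/JSON serialisations, and no resolution of
  terminology includes across files.
- The registry's reused CKM archetypes are stubs; templates check RMs
  and datapoint codes, not deep CKM content.
- Operational template export (.oet/OPT) and ADL 2 are out of scope.
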