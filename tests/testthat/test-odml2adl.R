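test_that("the datatype map is total over exactly the twelve odML types", {
  m <- datatype_map()
  expect_length(m, 12L)
  expect_setequal(names(m),
                  c("person", "date", "text", "int", "string", "float",
                    "binary", "url", "datetime", "time", "boolean",
                    "2-tuple"))
  expect_identical(map_datatype("int"), "count")
  expect_identical(map_datatype("binary"), "multimedia")
  expect_identical(map_datatype("float"), "quantity")
  expect_identical(map_datatype("url"), "URI")
  expect_identical(map_datatype("time"), "date_time")
  expect_identical(map_datatype("time", has_start_and_end = TRUE),
                   "interval_of_date_time")
  expect_identical(map_datatype("person"), "SLOT")
  expect_identical(map_datatype("2-tuple"), "CLUSTER_OF_TWO")
  expect_error(map_datatype("complex"), "mapping error.*complex")
})

test_that("sections become clusters with one child per property", {
  s <- odml_section("Rec", properties = list(
    odml_property("Channels", list(odml_value("32", "int"))),
    odml_property("Notes", list(odml_value("ok", "text")))))
  dp <- transform_section(s, code_allocator())
  expect_identical(dp$kind, "cluster")
  expect_length(dp$children, 2L)
  expect_true(all(vapply(dp$children, function(x) x$kind, character(1)) ==
                  "element"))
  expect_identical(dp$children[[1L]]$datatype, "count")
  expect_identical(dp$children[[2L]]$datatype, "text")

  # an empty section is a cluster with no children
  empty <- transform_section(odml_section("Empty"), code_allocator())
  expect_length(empty$children, 0L)
})

test_that("enumerated properties get one fresh internal code per item", {
  doc <- electrode_doc()
  tr <- transform_document(doc)
  usage <- tr$archetype$definition$children[[1L]]
  expect_identical(usage$datatype, "coded_text")
  expect_length(usage$enum_codes, 3L)
  # each enumeration code is paired with the item's name in the ontology
  onto <- tr$archetype$ontology
  names_by_code <- stats::setNames(
    vapply(onto, function(t) t$name, character(1)),
    vapply(onto, function(t) t$code, character(1)))
  expect_setequal(unname(names_by_code[usage$enum_codes]),
                  c("Reference", "Recording", "Ground"))
})

test_that("person properties become demographic slots and 2-tuples two-element clusters", {
  s <- odml_section("Meta", properties = list(
    odml_property("Experimenter", list(odml_value("Jane Roe", "person"))),
    odml_property("Range", list(odml_value("(1; 5)", "2-tuple"))),
    odml_property("Window", list(odml_value("(0.5; 2.5)", "2-tuple"))),
    odml_property("Labels", list(odml_value("(lo; hi)", "2-tuple")))))
  dp <- transform_section(s, code_allocator())
  expect_identical(dp$children[[1L]]$kind, "slot")
  expect_match(dp$children[[1L]]$allowed_archetypes, "DEMOGRAPHIC")
  tuples <- dp$children[2:4]
  for (tp in tuples) {
    expect_identical(tp$kind, "cluster")
    expect_length(tp$children, 2L)
  }
  # component datatype follows the tuple contents: count / quantity / text
  expect_identical(tuples[[1L]]$children[[1L]]$datatype, "count")
  expect_identical(tuples[[2L]]$children[[1L]]$datatype, "quantity")
  expect_identical(tuples[[3L]]$children[[1L]]$datatype, "text")
})

test_that("sibling start/end times merge into one interval element when enabled", {
  s <- odml_section("Timing", properties = list(
    odml_property("StartTime", list(odml_value("10:00:00", "time"))),
    odml_property("EndTime", list(odml_value("11:00:00", "time"))),
    odml_property("Note", list(odml_value("x", "text")))))
  merged <- transform_section(s, code_allocator())
  expect_length(merged$children, 2L)
  expect_identical(merged$children[[1L]]$datatype, "interval_of_date_time")

  plain <- transform_section(s, code_allocator(),
                             transform_options(start_end_merge = FALSE))
  expect_length(plain$children, 3L)
  expect_identical(plain$children[[1L]]$datatype, "date_time")
})

test_that("the root section maps to archetype metadata and concept", {
  doc <- electrode_doc()
  tr <- transform_document(doc)
  a <- tr$archetype
  expect_identical(a$archetype_id, "openEHR-EHR-CLUSTER.electrode.v1")
  expect_identical(a$rm$name, "Cluster")
  expect_identical(a$concept, "at0000")
  concept_term <- Filter(function(t) t$code == a$concept, a$ontology)[[1L]]
  expect_identical(concept_term$name, "Electrode")
  expect_match(a$description, "EEG electrode")
})

test_that("top-level subsections become top-level clusters", {
  doc <- generate_fixture(fixture_spec(depth = 1, sections_per_level = 2,
                                       props_per_section = 0, seed = 3))
  tr <- transform_document(doc)
  kinds <- vapply(tr$archetype$definition$children,
                  function(x) x$kind, character(1))
  expect_identical(kinds, c("cluster", "cluster"))
})

test_that("bound enumeration items dereference back to their item text", {
  doc <- electrode_doc()
  store <- local_store(doc, ELECTRODE_URL)
  tr <- transform_document(doc, transform_options(
    terminology_url = ELECTRODE_URL, section_no = 7, bind_terms = TRUE))
  bound <- Filter(function(t) !is.null(t$binding_alias),
                  tr$archetype$ontology)
  expect_length(bound, 3L)
  for (t in bound) {
    expect_identical(dereference(t$binding_alias, store, tr$alias_table),
                     t$name)
    # the tree-walk oracle agrees
    oracle <- walk_lookup(store[[1L]], "Electrode", "Usage", t$name)
    expect_identical(oracle, t$name)
  }
  # alias numbering: section 7, terms sequential from 1
  expect_identical(tr$alias_table$entries$alias,
                   c("ODMLID007001", "ODMLID007002", "ODMLID007003"))
})

test_that("transformation is total and code/ontology-complete over generated fixtures", {
  for (seed in 1:20) {
    spec <- fixture_spec(depth = seed %% 3, sections_per_level = 1L + seed %% 3,
                         props_per_section = 1L + seed %% 4,
                         enum_fraction = (seed %% 5) / 5, seed = seed)
    tr <- transform_document(generate_fixture(spec), transform_options(
      bind_terms = TRUE, section_no = seed))
    expect_identical(validate_archetype(tr$archetype), character(0),
                     info = paste("seed", seed))
    def <- sort(getFromNamespace("definition_codes", "odml2ehr")(
      tr$archetype$definition))
    onto <- sort(vapply(tr$archetype$ontology, function(t) t$code,
                        character(1)))
    expect_identical(def, onto, info = paste("seed", seed))
  }
})

test_that("datatype errors carry the property path", {
  s <- odml_section("S", properties = list(
    odml_property("Bad", list(structure(
      list(content = "x", dtype = "complex", unit = NULL,
           uncertainty = NULL), class = "odml_value")))))
  expect_error(transform_section(s, code_allocator()), "S/Bad")
})

test_that("alias capacity is enforced at 999 terms per section number", {
  big <- odml_section("Big", properties = lapply(1:500, function(i) {
    odml_property(paste0("P", i), paste0("v", i, "_", 1:2))
  }))
  doc <- odml_document(big)
  expect_error(
    transform_document(doc, transform_options(bind_terms = TRUE)),
    "capacity error")
})
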