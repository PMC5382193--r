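built <- build_new_archetypes()

test_that("the default registry holds 11 archetypes partitioned 6/1/4", {
  reg <- load_registry()
  expect_identical(nrow(reg), 11L)
  cts <- table(reg$status)
  expect_identical(as.integer(cts[["ckm_reused"]]), 6L)
  expect_identical(as.integer(cts[["extended"]]), 1L)
  expect_identical(as.integer(cts[["new"]]), 4L)
  expect_setequal(reg$name[reg$status == "new"],
                  c("EEG/ERP result", "Experiment scenario", "Software",
                    "Stimulus"))
  expect_identical(reg$rm[reg$name == "EEG/ERP result"], "Observation")
  expect_identical(reg$rm[reg$name == "Report"], "Composition")
})

test_that("manifest loading validates structure and tolerates an empty file", {
  empty <- tempfile(fileext = ".tsv")
  writeLines("name\trm\tstatus\tsource", empty)
  expect_warning(reg <- load_registry(empty), "empty registry")
  expect_identical(nrow(reg), 0L)

  bad <- tempfile(fileext = ".tsv")
  writeLines(c("name\trm\tstatus\tsource", "X\tCluster\tweird\tmanifest"),
             bad)
  expect_error(load_registry(bad), "unknown status")
  expect_error(load_registry(tempfile()), "config error")
})

test_that("all four new archetypes validate cleanly and serialise to ADL", {
  expect_named(built, c("eeg_erp_result", "experiment_scenario",
                        "software", "stimulus"))
  for (nm in names(built)) {
    expect_identical(validate_archetype(built[[nm]]), character(0),
                     info = nm)
    adl <- serialize_adl(built[[nm]])
    expect_match(adl, "^archetype \\(adl_version=1\\.4\\)")
    expect_match(adl, "\nontology\n")
  }
})

test_that("the EEG/ERP result archetype carries the Observation facets", {
  a <- built$eeg_erp_result
  expect_identical(a$rm$name, "Observation")
  facets <- vapply(a$definition$children, function(x)
    odml2ehr:::term_name_of(a, x$code), character(1))
  expect_identical(facets, c("Protocol", "Data", "Events", "State"))

  protocol <- a$definition$children[[1L]]
  slot_names <- vapply(protocol$children, function(x)
    odml2ehr:::term_name_of(a, x$code), character(1))
  expect_identical(slot_names,
                   c("Hardware", "Electrode", "Software", "Environment"))
  expect_true(all(vapply(protocol$children, function(x) x$kind,
                         character(1)) == "slot"))
  # at least one electrode per recording
  electrode <- protocol$children[[2L]]
  expect_gte(electrode$occurrences[1L], 1L)

  data_part <- a$definition$children[[2L]]
  branches <- vapply(data_part$children, function(x)
    odml2ehr:::term_name_of(a, x$code), character(1))
  expect_identical(branches, c("Data Array", "Results"))

  state <- a$definition$children[[4L]]
  state_names <- vapply(state$children, function(x)
    odml2ehr:::term_name_of(a, x$code), character(1))
  expect_identical(state_names, c("Position", "Description"))
})

test_that("the experiment scenario archetype has a multimedia attachment and two slots", {
  a <- built$experiment_scenario
  expect_identical(a$rm$name, "Cluster")
  kinds <- vapply(a$definition$children, function(x) x$kind, character(1))
  expect_identical(sum(kinds == "slot"), 2L)
  dtypes <- unlist(lapply(a$definition$children, function(x) x$datatype))
  expect_true("multimedia" %in% dtypes)
})

test_that("Software and Stimulus derive from the terminology fixtures with working bindings", {
  tabs <- attr(built, "alias_tables")
  store <- attr(built, "store")
  for (nm in c("software", "stimulus")) {
    a <- built[[nm]]
    bound <- Filter(function(t) !is.null(t$binding_alias), a$ontology)
    expect_gt(length(bound), 0L)
    for (t in bound) {
      expect_identical(dereference(t$binding_alias, store, tabs[[nm]]),
                       t$name)
    }
  }
  # the stimulus type enumeration covers the template-relevant families
  st_terms <- vapply(built$stimulus$ontology, function(t) t$name,
                     character(1))
  expect_true(all(c("movie", "pulse", "ramp") %in% st_terms))
})

test_that("report templates wire the four archetypes and reject RM mismatches", {
  archs <- list("EEG/ERP result" = built$eeg_erp_result,
                "Experiment scenario" = built$experiment_scenario,
                "Stimulus" = built$stimulus)
  full <- compose_report_template(
    c(evaluation = "Problem/Diagnosis", instruction = "Medication order",
      cluster = "Experiment scenario", observation = "EEG/ERP result"),
    archetypes = archs)
  expect_length(full$slot_fills, 4L)

  bare <- compose_report_template()
  expect_length(bare$slot_fills, 0L)

  expect_error(
    compose_report_template(c(observation = "Experiment scenario")),
    "composition error.*observation.*Observation")
  expect_error(compose_report_template(c(observation = "Nonexistent")),
               "not a registry archetype")
})

test_that("template reductions keep exactly the requested codes and intersect monotonically", {
  archs <- list("Stimulus" = built$stimulus)
  t <- compose_report_template(archetypes = archs)
  codes <- odml2ehr:::definition_codes(built$stimulus$definition)

  # keep everything: unchanged
  t_all <- reduce_template(t, "Stimulus", codes)
  expect_setequal(template_retained(t_all, "Stimulus"), codes)

  # a pulse-style subset keeps exactly the given codes
  subset1 <- codes[1:6]
  t1 <- reduce_template(t, "Stimulus", subset1)
  expect_setequal(template_retained(t1, "Stimulus"), subset1)

  # successive reductions intersect (set-algebra oracle)
  subset2 <- codes[4:9]
  t2 <- reduce_template(t1, "Stimulus", subset2)
  expect_setequal(template_retained(t2, "Stimulus"),
                  intersect(subset1, subset2))
  # monotone non-increasing
  expect_lte(length(template_retained(t2, "Stimulus")),
             length(template_retained(t1, "Stimulus")))

  expect_error(reduce_template(t, "Stimulus", c("at9999")),
               "reduction error")
})
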