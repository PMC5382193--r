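test_that("pointer strings follow the grammar", {
  p <- term_pointer(ELECTRODE_URL, "Electrode", "Usage", "Reference")
  expect_identical(build_pointer(p),
                   paste0(ELECTRODE_URL, "#Electrode:Usage/Reference"))
  # without the enumerated item the pointer truncates at the property
  p2 <- term_pointer(ELECTRODE_URL, "Electrode", "Usage")
  expect_identical(build_pointer(p2), paste0(ELECTRODE_URL, "#Electrode:Usage"))
  expect_identical(build_pointer(term_pointer("file:///t.xml", "A", "B", "C")),
                   "file:///t.xml#A:B/C")
  expect_error(term_pointer("", "A", "B"), "grammar error")
})

test_that("pointer grammar round-trips", {
  cases <- list(
    term_pointer(ELECTRODE_URL, "Electrode", "Usage", "Reference"),
    term_pointer("file:///t.xml", "A", "B"),
    term_pointer("http://x/y.xml", "Sec Name", "Prop-1", "item/with/slash")
  )
  for (p in cases) {
    expect_identical(parse_pointer(build_pointer(p))[1:3], p[1:3])
  }
  # the first slash after the colon starts the item
  rt <- parse_pointer(build_pointer(cases[[3L]]))
  expect_identical(rt$value_item, "item/with/slash")
  expect_error(parse_pointer("no-hash-here"), "grammar error")
})

test_that("XPath construction matches the documented form and selects uniquely", {
  xp <- build_xpath("Usage", "Reference")
  expect_identical(
    xp,
    'odML[@version = "1"]/section/property/name[text() = "Usage"]/../value[text() = "Reference"]')
  expect_identical(
    build_xpath("Usage"),
    'odML[@version = "1"]/section/property/name[text() = "Usage"]')
  # evaluated over the electrode fixture it selects exactly one node
  nodes <- xml2::xml_find_all(xml2::read_xml(electrode_fixture_path()),
                              paste0("/", xp))
  expect_length(nodes, 1L)
  txt <- xml2::xml_find_all(nodes[[1L]], "text()")
  expect_identical(trimws(xml2::xml_text(txt[[1L]])), "Reference")
})

test_that("merged strings split back into their parts", {
  m <- merge_pointer("file:///t.xml", "a/b")
  expect_identical(m, "file:///t.xml#/a/b")
  s <- split_merged(m)
  expect_identical(s$file_url, "file:///t.xml")
  expect_identical(s$xpath, "a/b")
  # any url without "#/" recovers under split(merge(...))
  for (u in c("http://h/p.xml", "file:///x", "ftp://f/odml.xml#frag")) {
    x <- build_xpath("P", "V")
    expect_identical(split_merged(merge_pointer(u, x)),
                     list(file_url = u, xpath = x))
  }
})

test_that("aliases are 12 characters, zero padded, and invert exactly", {
  expect_identical(make_alias(7, 13), "ODMLID007013")
  expect_identical(make_alias(0, 0), "ODMLID000000")
  expect_identical(make_alias(123, 456), "ODMLID123456")
  expect_error(make_alias(1000, 0), "range error")
  expect_error(make_alias(-1, 0), "range error")
  expect_identical(unname(parse_alias("ODMLID007013")), c(7L, 13L))
  expect_error(parse_alias("ODML007013"), "format error")
  # property: parse_alias . make_alias = identity over random pairs
  set.seed(42)
  for (i in 1:50) {
    s <- sample(0:999, 1L); t <- sample(0:999, 1L)
    expect_identical(unname(parse_alias(make_alias(s, t))), c(s, t))
  }
})

test_that("registration keeps the alias table bijective and rejects conflicts", {
  tab <- alias_table()
  p <- term_pointer(ELECTRODE_URL, "Electrode", "Usage", "Reference")
  entry <- register_term(tab, p, 7, 13)
  expect_identical(entry$alias, "ODMLID007013")
  expect_identical(entry$pointer, build_pointer(p))
  expect_identical(entry$merged,
                   merge_pointer(ELECTRODE_URL, build_xpath("Usage", "Reference")))
  expect_error(register_term(tab, p, 7, 13), "conflict error")

  # 100 random distinct registrations stay bijective
  set.seed(7)
  keys <- unique(data.frame(s = sample(0:999, 300, replace = TRUE),
                            t = sample(0:999, 300, replace = TRUE)))[1:100, ]
  tab2 <- alias_table()
  for (i in seq_len(nrow(keys))) {
    register_term(tab2, term_pointer("file:///t.xml", "S", paste0("P", i),
                                     paste0("V", i)),
                  keys$s[i], keys$t[i])
  }
  expect_identical(alias_count(tab2), 100L)
  df <- tab2$entries
  expect_false(anyDuplicated(df$alias) > 0)
  recon <- t(vapply(df$alias, parse_alias, integer(2)))
  expect_identical(unname(recon[, 1L]), df$section_no)
  expect_identical(unname(recon[, 2L]), df$term_no)
})

test_that("alias tables survive a TSV round trip", {
  tab <- alias_table()
  register_term(tab, term_pointer(ELECTRODE_URL, "Electrode", "Usage",
                                  "Reference"), 7, 13)
  register_term(tab, term_pointer(ELECTRODE_URL, "Electrode", "Usage",
                                  "Ground"), 7, 14)
  path <- tempfile(fileext = ".tsv")
  write_alias_table(tab, path)
  tab2 <- read_alias_table(path)
  expect_identical(tab2$entries, tab$entries)
})

test_that("dereference resolves merged strings and aliases offline", {
  store <- stats::setNames(electrode_fixture_path(), ELECTRODE_URL)
  merged <- merge_pointer(ELECTRODE_URL, build_xpath("Usage", "Reference"))
  expect_identical(dereference(merged, store), "Reference")

  tab <- alias_table()
  register_term(tab, term_pointer(ELECTRODE_URL, "Electrode", "Usage",
                                  "Reference"), 7, 13)
  expect_identical(dereference("ODMLID007013", store, tab), "Reference")

  # unmapped URL: never goes to the network
  expect_error(dereference(merged, c("file:///other.xml" = "/nope")),
               "resolution error")
  # no such value -> zero matches
  none <- merge_pointer(ELECTRODE_URL, build_xpath("Usage", "Bipolar"))
  expect_error(dereference(none, store), "ambiguity error.*0 node")
})

test_that("dereference agrees with a structural tree-walk oracle", {
  doc <- parse_odml(electrode_fixture_path())
  store <- stats::setNames(electrode_fixture_path(), ELECTRODE_URL)
  usage <- doc$root$properties[[1L]]
  for (v in usage$values) {
    merged <- merge_pointer(ELECTRODE_URL,
                            build_xpath(usage$name, v$content))
    oracle <- walk_lookup(electrode_fixture_path(), doc$root$name,
                          usage$name, v$content)
    expect_length(oracle, 1L)
    expect_identical(dereference(merged, store), oracle)
  }
})
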