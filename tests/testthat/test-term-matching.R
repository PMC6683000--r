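# Flattening, term-matching tables and report generation.

test_that("flatten_group emits depth-first canonical rows and inverts exactly", {
  expect_identical(nrow(flatten_group(structure(list(), names = character()))),
                   0L)
  ft <- flatten_group(list(MS = list(Tune = list("Spray voltage" = "2.1"))))
  expect_identical(ft$path, "MS/Tune/Spray voltage")
  expect_identical(ft$value, "2.1")
  # keys containing the separator are escaped, losslessly
  ft2 <- flatten_group(list("Full MS" = list("Scan range (m/z)" = "300 to 1750")))
  expect_identical(ft2$path, "Full MS/Scan range (m\\/z)")
  withr::with_seed(77, {
    for (rep in 1:40) {
      t <- random_tree()
      ft <- flatten_group(t)
      # flatten is injective up to canonical value rendering
      expect_identical(flatten_group(unflatten_table(ft))$path, ft$path)
      expect_identical(flatten_group(unflatten_table(ft))$value, ft$value)
      # rows sorted in canonical depth-first order
      expect_false(is.unsorted(vapply(strsplit(ft$path, "(?<!\\\\)/",
                                               perl = TRUE), `[[`, "",
                                      1)))
    }
  })
})

test_that("unflatten rebuilds the tree itself for separator-free string trees", {
  t <- list(MS = list(Tune = list(a = "x", b = "y"), c = "z"))
  expect_true(deep_equal_oracle(unflatten_table(flatten_group(t)), t))
})

test_that("create_term_matching_table filters by origin and instruments", {
  tmt <- create_term_matching_table(
    c("Thermo EASY-nLC", "Q Exactive - Orbitrap_MS"), "miape")
  expect_true(all(tmt$origin_key == "miape"))
  expect_true(all(tmt$instrument %in%
                  c("Thermo EASY-nLC", "Q Exactive - Orbitrap_MS")))
  expect_false(is.unsorted(tmt$display_order))
  expect_gt(nrow(tmt), 10)

  err <- expect_error(create_term_matching_table("X", "nonsense"),
                      class = "msgroupr_unknown_origin_error")
  expect_match(conditionMessage(err), "miape")
  expect_warning(empty <- create_term_matching_table("Imaginary MS", "miape"),
                 "Imaginary MS")
  expect_identical(nrow(empty), 0L)
})

test_that("user registry files override bundled rows", {
  d <- withr::local_tempdir()
  uf <- file.path(d, "user.tsv")
  writeLines(c(
    "origin_key\tinstrument\tterm_label\tsource_path\tdisplay_order\trequired",
    "miape\tQ Exactive - Orbitrap_MS\tMS1 resolution\tCustom/Path\t50\ttrue",
    "miape\tQ Exactive - Orbitrap_MS\tLab-specific flag\tMethod/Polarity\t999\tfalse"),
    uf)
  tmt <- create_term_matching_table("Q Exactive - Orbitrap_MS", "miape",
                                    user_files = uf)
  row <- tmt[tmt$term_label == "MS1 resolution", ]
  expect_identical(nrow(row), 1L)            # override, not duplicate
  expect_identical(row$source_path, "Custom/Path")
  expect_true(row$required)
  expect_true("Lab-specific flag" %in% tmt$term_label)  # extension appended
})

test_that("match_terms resolves exact and suffix paths, marks required gaps", {
  gc <- group_files(list(make_fixture_meta("a.json")))
  tmt <- create_term_matching_table(
    c("Thermo EASY-nLC", "Q Exactive - Orbitrap_MS"), "miape")
  reports <- match_terms(flatten_collection(gc), tmt)
  expect_length(reports, 1)
  rep1 <- reports[[1]]
  expect_identical(rep1$value[rep1$term_label == "Ion source spray voltage (kV)"],
                   "2.1")
  expect_identical(rep1$value[rep1$term_label == "Instrument model"],
                   "Q Exactive - Orbitrap_MS")
  # required but nowhere in the fixture tree
  expect_identical(rep1$value[rep1$term_label == "Polarity"],
                   "(not recorded)")
  # empty term table -> zero-row reports
  empty <- tmt[0, ]
  expect_identical(nrow(match_terms(flatten_collection(gc), empty)[[1]]), 0L)
})

test_that("report values equal a brute-force per-term lookup oracle across groups", {
  d <- withr::local_tempdir()
  generate_collection(
    generator_spec(30, templates = c(qex_nlc_1 = 1, qex_nlc_2 = 1,
                                     qex_nlc_5 = 1, qex_nlc_6 = 1),
                   seed = 13), d)
  gc <- group_collection(d)
  expect_length(gc$groups, 4)
  tmt <- create_term_matching_table(
    c("Thermo EASY-nLC", "Q Exactive - Orbitrap_MS"), "miape")
  reports <- match_terms(flatten_collection(gc), tmt)
  for (i in seq_along(reports)) {
    flat <- flatten_group(gc$groups[[i]]$shared)
    for (r in seq_len(nrow(reports[[i]]))) {
      label <- reports[[i]]$term_label[r]
      src <- tmt$source_path[match(label, tmt$term_label)]
      hits <- flat$value[flat$path == src |
                           endsWith(flat$path, paste0("/", src))]
      expected <- if (length(hits) == 0) "(not recorded)" else hits[1]
      expect_identical(reports[[i]]$value[r], expected)
    }
  }
  # report content is a function of the shared tree only, not group size
  solo <- match_terms(list(flatten_group(gc$groups[[1]]$shared, 1L)), tmt)
  expect_identical(solo[[1]]$value, reports[[1]]$value)
})

test_that("ambiguous suffix matches raise an error listing candidates", {
  flat <- flatten_group(list(A = list(x = list(NCE = 27)),
                             B = list(y = list(NCE = 30))))
  tmt <- structure(data.frame(
    origin_key = "custom", instrument = "A", term_label = "NCE",
    source_path = "NCE", display_order = 1L, required = TRUE,
    stringsAsFactors = FALSE),
    class = c("term_matching_table", "data.frame"))
  expect_error(match_terms(list(flat), tmt),
               class = "msgroupr_ambiguous_term_error")
})
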