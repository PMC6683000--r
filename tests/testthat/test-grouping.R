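# Partitioning into minimal parameter groups, grouped-JSON interchange,
# and drift diffing.

test_that("files differing only in header fields form one group; one leaf splits them", {
  same <- lapply(sprintf("f%02d.json", 1:5), function(fn) {
    make_fixture_meta(fn, date = sprintf("2019-01-%02dT08:00:00Z",
                                         sample.int(28, 1)))
  })
  gc <- group_files(same)
  expect_length(gc$groups, 1)
  expect_identical(gc$groups[[1]]$file_names, sprintf("f%02d.json", 1:5))

  two <- list(make_fixture_meta("a.json", nce = 27),
              make_fixture_meta("b.json", nce = 28))
  gc2 <- group_files(two)
  expect_length(gc2$groups, 2)
  expect_identical(vapply(gc2$groups, function(g) length(g$file_names),
                          integer(1)), c(1L, 1L))
})

test_that("group ids follow first occurrence in lexicographic manifest order", {
  metas <- list(make_fixture_meta("c.json", nce = 30),
                make_fixture_meta("a.json", nce = 27),
                make_fixture_meta("b.json", nce = 30))
  gc <- group_files(metas)
  # manifest order a, b, c: group 1 holds a (nce 27), group 2 holds b+c
  expect_identical(gc$groups[[1]]$file_names, "a.json")
  expect_identical(gc$groups[[2]]$file_names, c("b.json", "c.json"))
  expect_identical(vapply(gc$groups, `[[`, integer(1), "group_id"), 1:2)
})

test_that("grouping is invariant under input permutation", {
  withr::with_seed(55, {
    metas <- lapply(1:12, function(i) {
      make_fixture_meta(sprintf("r%02d.json", i), nce = c(27, 30)[1 + i %% 2])
    })
    ref <- group_files(metas)
    for (rep in 1:5) {
      shuffled <- group_files(metas[sample(length(metas))])
      expect_identical(lapply(shuffled$groups, `[`, c("group_id", "file_names", "hash")),
                       lapply(ref$groups, `[`, c("group_id", "file_names", "hash")))
    }
  })
})

test_that("duplicate file names and empty input are errors", {
  expect_error(group_files(list()), class = "msgroupr_structure_error")
  expect_error(group_files(list(make_fixture_meta("a.json"),
                                make_fixture_meta("a.json"))),
               class = "msgroupr_structure_error")
})

test_that("grouping a doubled collection preserves structure with doubled membership", {
  metas <- lapply(1:6, function(i) {
    make_fixture_meta(sprintf("r%02d.json", i), nce = c(27, 30, 32)[1 + i %% 3])
  })
  once <- group_files(metas)
  doubled <- c(metas, lapply(metas, function(m) {
    m$file_name <- sub("\\.json$", "_copy.json", m$file_name)
    m
  }))
  twice <- group_files(doubled)
  expect_length(twice$groups, length(once$groups))
  expect_identical(
    lapply(twice$groups, function(g) sub("_copy", "", g$file_names)),
    lapply(once$groups, function(g) rep(g$file_names, each = 2)))
})

test_that("unreadable files land in the failed section, not silently dropped", {
  d <- withr::local_tempdir()
  generate_collection(generator_spec(4, seed = 3), d)
  writeLines("{ not json", file.path(d, "corrupt.json"))
  gc <- group_collection(d)
  expect_length(gc$failed, 1)
  expect_identical(gc$failed[[1]]$file_name, "corrupt.json")
  expect_identical(sum(vapply(gc$groups, function(g) length(g$file_names),
                              integer(1))), 4L)
  # the failed section survives the JSON round trip
  p <- file.path(d, "grouped.json")
  write_grouped_json(gc, p)
  back <- read_grouped_json(p)
  expect_identical(back$failed[[1]]$file_name, "corrupt.json")
})

test_that("grouped JSON round-trips with identical hashes and group order", {
  d <- withr::local_tempdir()
  generate_collection(
    generator_spec(20, templates = c(qex_nlc_1 = 1, qex_nlc_2 = 1,
                                     qex_nlc_4 = 2), seed = 21), d)
  gc <- group_collection(d)
  p <- file.path(d, "grouped.json")
  write_grouped_json(gc, p)
  back <- read_grouped_json(p)
  expect_identical(length(back$groups), length(gc$groups))
  for (i in seq_along(gc$groups)) {
    expect_identical(back$groups[[i]]$group_id, gc$groups[[i]]$group_id)
    expect_identical(back$groups[[i]]$file_names, gc$groups[[i]]$file_names)
    expect_identical(back$groups[[i]]$hash, gc$groups[[i]]$hash)
  }
  # writing the reread collection reproduces the same bytes
  p2 <- file.path(d, "grouped2.json")
  write_grouped_json(back, p2)
  expect_identical(readBin(p, "raw", file.size(p)),
                   readBin(p2, "raw", file.size(p2)))
})

test_that("overlapping file names across groups are a read error", {
  d <- withr::local_tempdir()
  p <- file.path(d, "bad.json")
  writeLines(paste0(
    '{"Version": "1.0", "Groups": [',
    '{"GroupId": 1, "FileNames": ["a"], "SharedParameters": {"x": 1}},',
    '{"GroupId": 2, "FileNames": ["a"], "SharedParameters": {"x": 2}}',
    '], "Failed": []}'), p)
  expect_error(read_grouped_json(p), class = "msgroupr_validation_error")
})

test_that("diff_groups reports exactly the differing paths (tree-walk oracle)", {
  t0 <- strip_file_specific(make_fixture_meta(nce = 27))
  expect_identical(nrow(diff_groups(t0, t0)), 0L)
  t1 <- strip_file_specific(make_fixture_meta(nce = 30))
  d <- diff_groups(t0, t1)
  expect_identical(d$path, "Q Exactive - Orbitrap_MS/Method/NCE")
  expect_identical(d$value_a, "27")
  expect_identical(d$value_b, "30")
  # one-sided presence carries the absent marker
  t2 <- msgroupr:::tree_drop(t0, c("Q Exactive - Orbitrap_MS", "Tune"))
  d2 <- diff_groups(t0, t2)
  expect_identical(d2$path, "Q Exactive - Orbitrap_MS/Tune")
  expect_identical(d2$value_b, "(absent)")
  # independent oracle: leaf paths whose values disagree
  withr::with_seed(66, {
    for (rep in 1:20) {
      a <- random_tree()
      b <- perturb_leaf(a)
      d3 <- diff_groups(a, b)
      oracle <- oracle_diff_paths(a, b)
      expect_setequal(d3$path, oracle)
      expect_identical(nrow(diff_groups(a, shuffle_tree(a))), 0L)
    }
  })
})
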