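# Canonical serialization, content hashing and file-specific stripping.

test_that("canonical serialization is order-independent and fixed for the empty tree", {
  expect_identical(rawToChar(canonical_serialize(structure(list(), names = character()))),
                   "{}")
  a <- list(b = 1, a = 2)
  b <- list(a = 2, b = 1)
  expect_identical(canonical_serialize(a), canonical_serialize(b))
  # nested insertion order is irrelevant too
  t1 <- list(x = list(q = "v", p = 1), y = TRUE)
  t2 <- list(y = TRUE, x = list(p = 1, q = "v"))
  expect_identical(canonical_serialize(t1), canonical_serialize(t2))
})

test_that("scalar rendering follows the fixed rule", {
  expect_identical(msgroupr:::render_scalar(3000000), "3000000")
  expect_identical(msgroupr:::render_scalar(5L), "5")
  expect_identical(msgroupr:::render_scalar(2.1), "2.1")
  expect_identical(msgroupr:::render_scalar(TRUE), "true")
  expect_identical(msgroupr:::render_scalar(NULL), "null")
  # shortest round-trip for awkward doubles
  x <- 1 / 3
  expect_identical(as.numeric(msgroupr:::render_scalar(x)), x)
  expect_error(msgroupr:::render_scalar(NaN), class = "msgroupr_type_error")
  expect_error(canonical_serialize(list(a = list(1, 2))),
               class = "msgroupr_structure_error")
})

test_that("duplicate sibling keys are rejected, not last-wins", {
  tr <- list(a = 1)
  tr <- c(tr, list(a = 2))
  expect_error(validate_tree(tr), class = "msgroupr_duplicate_key_error")
  expect_error(canonical_serialize(tr), class = "msgroupr_duplicate_key_error")
})

test_that("serialization equality matches the deep-equality oracle on random trees", {
  withr::with_seed(101, {
    trees <- replicate(60, random_tree(), simplify = FALSE)
    for (rep in 1:250) {
      i <- sample.int(60, 1)
      j <- sample.int(60, 1)
      bytes_equal <- identical(canonical_serialize(trees[[i]]),
                               canonical_serialize(trees[[j]]))
      expect_identical(bytes_equal,
                       deep_equal_oracle(trees[[i]], trees[[j]]))
    }
    # shuffled copies must serialize identically
    for (rep in 1:50) {
      t <- trees[[sample.int(60, 1)]]
      expect_identical(canonical_serialize(t),
                       canonical_serialize(shuffle_tree(t)))
    }
  })
})

test_that("content hash is stable, canonicalizing, and collision-free over perturbations", {
  withr::with_seed(202, {
    t <- random_tree()
    expect_identical(content_hash(t), content_hash(t))
    expect_match(content_hash(t), "^[0-9a-f]{64}$")
    expect_identical(content_hash(t), content_hash(shuffle_tree(t)))
    for (rep in 1:100) {
      mutated <- perturb_leaf(t)
      expect_false(content_hash(mutated) == content_hash(t))
    }
  })
})

test_that("strip_file_specific drops header fields and merges instruments by model", {
  expect_identical(strip_file_specific(file_metadata("x.json")),
                   structure(list(), names = character()))
  m1 <- make_fixture_meta("a.json", "2019-01-07T09:00:00Z")
  m2 <- make_fixture_meta("b.json", "2020-12-31T23:59:00Z")
  expect_identical(content_hash(strip_file_specific(m1)),
                   content_hash(strip_file_specific(m2)))
  st <- strip_file_specific(m1)
  expect_setequal(names(st), c("Q Exactive - Orbitrap_MS", "Thermo EASY-nLC"))
  expect_identical(st[["Q Exactive - Orbitrap_MS"]][["Instrument model"]],
                   "Q Exactive - Orbitrap_MS")
  expect_match(st[["Thermo EASY-nLC"]][["Method text"]], "^Gradient:")
  # duplicate models are auto-suffixed, never an error
  dup <- file_metadata("d.json", instruments = list(
    instrument_metadata("M", parameters = list(a = 1)),
    instrument_metadata("M", parameters = list(a = 2))))
  expect_setequal(names(strip_file_specific(dup)), c("M", "M#2"))
})

test_that("exclusion paths are removed exactly, siblings kept (path-copy oracle)", {
  meta <- file_metadata("x.json", instruments = list(
    instrument_metadata("MS", parameters = list(
      Tune = list("File name" = "C:\\tune\\qe.tune", "Spray voltage" = 2.1),
      Method = list(NCE = 27)))))
  excl <- "MS/Tune/File name"
  st <- strip_file_specific(meta, exclude_paths = excl)
  expect_null(msgroupr:::tree_get(st, c("MS", "Tune", "File name"),
                                  missing = NULL))
  expect_identical(st$MS$Tune$`Spray voltage`, 2.1)
  oracle <- path_copy_oracle(strip_file_specific(meta), exclude = excl)
  expect_true(deep_equal_oracle(st, oracle))
})

test_that("strip_file_specific is idempotent through rewrapping", {
  m <- make_fixture_meta()
  once <- strip_file_specific(m)
  rewrapped <- file_metadata("y.json", instruments = list(
    instrument_metadata("wrap", parameters = once)))
  # stripping ignores header fields only; the tree itself passes through
  twice <- strip_file_specific(rewrapped)[["wrap"]]
  twice[["Instrument model"]] <- NULL
  expect_true(deep_equal_oracle(once, twice))
})
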