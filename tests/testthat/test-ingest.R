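# Native-dialect JSON reading/writing, mzML header reading, and
# collection scanning.

test_that("minimal native document and schema violations behave as specified", {
  d <- withr::local_tempdir()
  p <- file.path(d, "min.json")
  writeLines('{"FileName": "min.raw", "Instruments": []}', p)
  meta <- read_native_json(p)
  expect_s3_class(meta, "file_metadata")
  expect_identical(meta$file_name, "min.raw")
  expect_length(meta$instruments, 0)

  writeLines('{"Instruments": []}', file.path(d, "nofn.json"))
  err <- expect_error(read_native_json(file.path(d, "nofn.json")),
                      class = "msgroupr_validation_error")
  expect_match(conditionMessage(err), "/FileName", fixed = TRUE)

  writeLines('{"FileName": "x", "Instruments": [{"Model": "M", "ModuleType": "UV"}]}',
             file.path(d, "badmod.json"))
  err <- expect_error(read_native_json(file.path(d, "badmod.json")),
                      class = "msgroupr_validation_error")
  expect_match(conditionMessage(err), "/Instruments/0/ModuleType", fixed = TRUE)

  writeLines('{"FileName": "x", "Instruments": [], "AcquiredDate": "yesterday"}',
             file.path(d, "baddate.json"))
  expect_error(read_native_json(file.path(d, "baddate.json")),
               class = "msgroupr_validation_error")
})

test_that("duplicate keys in a parameter tree are a read error", {
  d <- withr::local_tempdir()
  p <- file.path(d, "dup.json")
  writeLines(paste0('{"FileName": "x", "Instruments": [{"Model": "M",',
                    '"ModuleType": "MS", "Parameters": {"a": 1, "a": 2}}]}'),
             p)
  expect_error(read_native_json(p), class = "msgroupr_validation_error")
})

test_that("generator documents round-trip bit-identically through write-then-read", {
  d <- withr::local_tempdir()
  res <- generate_collection(generator_spec(3, seed = 11), d)
  for (fn in res$manifest$file_name) {
    p <- file.path(d, fn)
    meta <- read_native_json(p)
    p2 <- file.path(d, paste0(fn, ".rt"))
    write_native_json(meta, p2)
    expect_identical(readBin(p, "raw", file.size(p)),
                     readBin(p2, "raw", file.size(p2)))
  }
})

test_that("mzML header mapping: instrument params, accessions, sample, timestamps", {
  d <- withr::local_tempdir()
  p <- file.path(d, "two.mzML")
  writeLines(c(
    '<?xml version="1.0" encoding="utf-8"?>',
    '<indexedmzML xmlns="http://psi.hupo.org/ms/mzml">',
    '<mzML xmlns="http://psi.hupo.org/ms/mzml" version="1.1.0">',
    '  <instrumentConfigurationList count="1">',
    '    <instrumentConfiguration id="IC1">',
    '      <cvParam cvRef="MS" accession="MS:1000016" name="scan start time" value="0.5"/>',
    '      <cvParam cvRef="MS" accession="MS:1000045" name="collision energy" value="27"/>',
    '      <userParam name="Tune/Spray voltage (kV)" value="2.1"/>',
    '    </instrumentConfiguration>',
    '  </instrumentConfigurationList>',
    '  <run id="r" startTimeStamp="2019-02-03T10:11:12Z"/>',
    "</mzML></indexedmzML>"), p)
  meta <- read_mzml_metadata(p)
  expect_identical(meta$acquired_date, "2019-02-03T10:11:12Z")
  expect_length(meta$sample_info, 0)
  expect_length(meta$instruments, 1)
  inst <- meta$instruments[[1]]
  expect_identical(inst$module_type, "MS")
  expect_identical(inst$model, "IC1")  # no instrument-model param: id fallback
  pt <- inst$parameters
  expect_identical(pt[["scan start time"]], 0.5)
  expect_identical(pt[["scan start time@accession"]], "MS:1000016")
  expect_identical(pt[["collision energy"]], 27)
  expect_identical(pt$Tune[["Spray voltage (kV)"]], 2.1)

  # not-mzML and missing instrumentConfigurationList are format errors
  writeLines("<foo/>", file.path(d, "foo.mzML"))
  expect_error(read_mzml_metadata(file.path(d, "foo.mzML")),
               class = "msgroupr_format_error")
  writeLines('<mzML xmlns="http://psi.hupo.org/ms/mzml" version="1.1.0"><run id="r"/></mzML>',
             file.path(d, "noicl.mzML"))
  expect_error(read_mzml_metadata(file.path(d, "noicl.mzML")),
               class = "msgroupr_format_error")
})

test_that("cvParam without accession warns and keeps the name verbatim", {
  d <- withr::local_tempdir()
  p <- file.path(d, "noacc.mzML")
  writeLines(c(
    '<mzML xmlns="http://psi.hupo.org/ms/mzml" version="1.1.0">',
    '  <instrumentConfigurationList count="1">',
    '    <instrumentConfiguration id="IC1">',
    '      <cvParam name="mystery term" value="7"/>',
    '    </instrumentConfiguration>',
    '  </instrumentConfigurationList>',
    "</mzML>"), p)
  expect_warning(meta <- read_mzml_metadata(p), "mystery term")
  expect_identical(meta$instruments[[1]]$parameters[["mystery term"]], 7)
})

test_that("collection scanning sorts, tags formats, and refuses empty matches", {
  d <- withr::local_tempdir()
  res <- generate_collection(
    generator_spec(3, seed = 5, emit_formats = c("json", "mzML")), d)
  man <- scan_collection(d)
  expect_identical(man$file_name, sort(man$file_name, method = "radix"))
  expect_identical(nrow(man), 6L)
  # format tags agree with a directory-listing oracle
  listing <- sort(list.files(d))
  expect_identical(man$file_name, listing)
  expect_identical(man$source_format,
                   ifelse(grepl("json$", listing), "json", "mzML"))
  one <- scan_collection(file.path(d, man$file_name[1]))
  expect_identical(nrow(one), 1L)
  empty <- withr::local_tempdir()
  expect_error(scan_collection(empty), class = "msgroupr_no_input_error")
})

test_that("JSON and mzML readers agree on the stripped tree for the same record", {
  d <- withr::local_tempdir()
  generate_collection(
    generator_spec(2, templates = c(qex_nlc_3 = 1), seed = 9,
                   emit_formats = c("json", "mzML")), d)
  mj <- read_native_json(file.path(d, "run_0001.json"))
  mx <- read_mzml_metadata(file.path(d, "run_0001.mzML"))
  expect_identical(content_hash(strip_file_specific(mj)),
                   content_hash(strip_file_specific(mx)))
  expect_true(deep_equal_oracle(strip_file_specific(mj),
                                strip_file_specific(mx)))
})
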