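## Ingestion: the native per-file metadata JSON dialect, mzML header
## metadata, and directory scanning.
##
## The native dialect is a top-level object with members "FileName",
## "AcquiredDate" (ISO-8601 or null), "SampleInfo" (flat string map) and
## "Instruments" (array of {Model, ModuleType, MethodText, Parameters}).
## Its JSON-Schema lives in inst/extdata/schemas/file-metadata.schema.json.

validation_error <- function(pointer, what) {
  ms_abort(sprintf("invalid metadata document at %s: %s", pointer, what),
           "msgroupr_validation_error", pointer = pointer)
}

iso8601_like <- function(s) {
  grepl("^\\d{4}-\\d{2}-\\d{2}([T ]\\d{2}:\\d{2}(:\\d{2}(\\.\\d+)?)?(Z|[+-]\\d{2}:?\\d{2})?)?$",
        s)
}

# Convert a parsed JSON "Parameters" object into a validated tree.
json_to_tree <- function(x, pointer) {
  if (is.null(x)) return(empty_tree())
  if (!is.list(x)) validation_error(pointer, "expected an object")
  keys <- names(x)
  if (length(x) > 0L && (is.null(keys) || any(!nzchar(keys)))) {
    validation_error(pointer, "object members must have non-empty keys")
  }
  if (anyDuplicated(stringi::stri_trans_nfc(keys))) {
    dup <- keys[duplicated(stringi::stri_trans_nfc(keys))][1]
    validation_error(paste0(pointer, "/", dup), "duplicate sibling key")
  }
  out <- empty_tree()
  for (i in seq_along(x)) {
    v <- x[[i]]
    child_ptr <- paste0(pointer, "/", keys[i])
    if (is.list(v)) {
      out[[keys[i]]] <- json_to_tree(v, child_ptr)
    } else if (is_leaf(v)) {
      if (!is.null(v) && is.na(v)) validation_error(child_ptr, "null-like NA leaf")
      out[keys[i]] <- list(v)
    } else {
      validation_error(child_ptr, "arrays are not valid parameter values")
    }
  }
  out
}

#' Read a per-file metadata record from the native JSON dialect
#'
#' Parses and validates one metadata document.  Validation failures are
#' reported with JSON-pointer paths; duplicate sibling keys anywhere in
#' the document are rejected (silent loss of parameters would defeat the
#' tool's purpose).
#'
#' @param path path to a `.json` metadata document.
#' @return a [file_metadata()] record.
#' @export
read_native_json <- function(path) {
  if (!file.exists(path)) {
    ms_abort(sprintf("no such file: %s", path), "msgroupr_io_error")
  }
  doc <- tryCatch(
    jsonlite::parse_json(paste(read_utf8(path), collapse = "\n")),
    error = function(e) ms_abort(
      sprintf("not parseable as JSON: %s (%s)", path, conditionMessage(e)),
      "msgroupr_validation_error")
  )
  parse_native_document(doc)
}

parse_native_document <- function(doc) {
  if (!is.list(doc)) validation_error("/", "top level must be an object")
  nm <- names(doc)
  if (anyDuplicated(nm)) {
    validation_error(paste0("/", nm[duplicated(nm)][1]), "duplicate member")
  }
  if (!"FileName" %in% nm || !is_string(doc[["FileName"]]) || !nzchar(doc[["FileName"]])) {
    validation_error("/FileName", "required non-empty string")
  }
  acq <- doc[["AcquiredDate"]]
  if (!is.null(acq)) {
    if (!is_string(acq)) validation_error("/AcquiredDate", "string or null")
    if (!iso8601_like(acq)) {
      validation_error("/AcquiredDate", "not an ISO-8601 timestamp")
    }
  }
  si <- doc[["SampleInfo"]]
  if (!is.null(si)) {
    if (!is.list(si)) validation_error("/SampleInfo", "expected an object")
    if (length(si) > 0L && (is.null(names(si)) || any(!nzchar(names(si))))) {
      validation_error("/SampleInfo", "members must be named")
    }
    bad <- which(!vapply(si, is_string, logical(1)))
    if (length(bad) > 0L) {
      validation_error(paste0("/SampleInfo/", names(si)[bad[1]]),
                       "values must be strings")
    }
  }
  if (!"Instruments" %in% nm) validation_error("/Instruments", "required array")
  insts <- doc[["Instruments"]]
  if (!is.list(insts) || (length(insts) > 0L && !is.null(names(insts)))) {
    validation_error("/Instruments", "expected an array of objects")
  }
  instruments <- lapply(seq_along(insts), function(i) {
    obj <- insts[[i]]
    ptr <- sprintf("/Instruments/%d", i - 1L)
    if (!is.list(obj)) validation_error(ptr, "expected an object")
    if (!is_string(obj[["Model"]]) || !nzchar(obj[["Model"]])) {
      validation_error(paste0(ptr, "/Model"), "required non-empty string")
    }
    if (!is_string(obj[["ModuleType"]]) ||
        !obj[["ModuleType"]] %in% c("MS", "LC", "OTHER")) {
      validation_error(paste0(ptr, "/ModuleType"),
                       "must be one of \"MS\", \"LC\", \"OTHER\"")
    }
    mt <- obj[["MethodText"]]
    if (!is.null(mt) && !is_string(mt)) {
      validation_error(paste0(ptr, "/MethodText"), "string or null")
    }
    instrument_metadata(
      model = obj[["Model"]], module_type = obj[["ModuleType"]], method_text = mt,
      parameters = json_to_tree(obj[["Parameters"]], paste0(ptr, "/Parameters"))
    )
  })
  file_metadata(file_name = doc[["FileName"]], acquired_date = acq,
                sample_info = if (is.null(si)) list() else si,
                instruments = instruments)
}

#' Write a per-file metadata record as the native JSON dialect
#'
#' Deterministic pretty-printed UTF-8 output; a record round-trips
#' bit-identically through write-then-read-then-write.
#'
#' @param meta a [file_metadata()] record.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_native_json <- function(meta, path) {
  if (!inherits(meta, "file_metadata")) {
    ms_abort("meta must be a file_metadata record", "msgroupr_structure_error")
  }
  doc <- list(
    FileName = meta$file_name,
    AcquiredDate = meta$acquired_date,
    SampleInfo = meta$sample_info,
    Instruments = ms_array(lapply(meta$instruments, function(inst) {
      list(Model = inst$model, ModuleType = inst$module_type,
           MethodText = inst$method_text, Parameters = inst$parameters)
    }))
  )
  # NULL members (AcquiredDate/MethodText) must appear explicitly as null:
  # emit via a wrapper list so [[<- does not drop them.
  write_utf8(emit_native_document(doc), path)
}

emit_native_document <- function(doc) {
  inst_json <- vapply(doc[["Instruments"]]$items, function(inst) {
    paste0(
      "{\n      \"Model\": ", json_escape_string(inst$Model),
      ",\n      \"ModuleType\": ", json_escape_string(inst$ModuleType),
      ",\n      \"MethodText\": ",
      if (is.null(inst$MethodText)) "null"
      else json_escape_string(render_scalar(inst$MethodText)),
      ",\n      \"Parameters\": ",
      indent_block(emit_json_tree(inst$Parameters, sort_keys = FALSE,
                                  indent = "  "), "      "),
      "\n    }")
  }, character(1))
  paste0(
    "{\n",
    "  \"FileName\": ", json_escape_string(doc[["FileName"]]), ",\n",
    "  \"AcquiredDate\": ",
    if (is.null(doc[["AcquiredDate"]])) "null"
    else json_escape_string(doc[["AcquiredDate"]]), ",\n",
    "  \"SampleInfo\": ",
    indent_block(emit_json_tree(doc[["SampleInfo"]], sort_keys = FALSE,
                                indent = "  "), "  "), ",\n",
    "  \"Instruments\": ",
    if (length(inst_json) == 0L) "[]"
    else paste0("[\n    ", paste(inst_json, collapse = ",\n    "), "\n  ]"),
    "\n}")
}

# Re-indent a multi-line JSON block so it nests under `pad`.
indent_block <- function(txt, pad) {
  gsub("\n", paste0("\n", pad), txt, fixed = TRUE)
}

## ---- mzML -----------------------------------------------------------------

#' Read run and instrument metadata from an mzML file
#'
#' Reads only the header sections of an mzML 1.1 document (indexed
#' `indexedmzML` wrappers are accepted transparently); spectra are never
#' touched.  `run@startTimeStamp` maps to the acquisition date, each
#' `instrumentConfiguration` becomes one MS instrument whose
#' `cvParam`/`userParam` entries (including those pulled in via
#' `referenceableParamGroupRef`) become parameter leaves keyed by term
#' name, with the CV accession retained as a `"<name>@accession"` sibling
#' leaf.  A `userParam` whose name contains `/` is interpreted as a tree
#' path, which is how nested parameter trees survive mzML's flat
#' parameter model.  A param named `"instrument model"` is consumed as
#' the instrument's model rather than stored as a leaf.  The first
#' `sample` element maps to the sample-info header fields.
#'
#' @param path path to an mzML file.
#' @return a [file_metadata()] record.
#' @export
read_mzml_metadata <- function(path) {
  if (!file.exists(path)) {
    ms_abort(sprintf("no such file: %s", path), "msgroupr_io_error")
  }
  doc <- tryCatch(xml2::read_xml(path), error = function(e) {
    ms_abort(sprintf("not well-formed XML: %s (%s)", path,
                     conditionMessage(e)), "msgroupr_format_error")
  })
  xml2::xml_ns_strip(doc)
  root <- doc
  if (xml2::xml_name(root) == "indexedmzML") {
    root <- xml2::xml_find_first(root, "./mzML")
    if (inherits(root, "xml_missing")) {
      ms_abort(sprintf("indexedmzML without mzML child: %s", path),
               "msgroupr_format_error")
    }
  }
  if (xml2::xml_name(root) != "mzML") {
    ms_abort(sprintf("not an mzML document: %s", path),
             "msgroupr_format_error")
  }
  icl <- xml2::xml_find_first(root, "./instrumentConfigurationList")
  if (inherits(icl, "xml_missing")) {
    ms_abort(sprintf("missing instrumentConfigurationList: %s", path),
             "msgroupr_format_error")
  }
  run <- xml2::xml_find_first(root, "./run")
  acquired <- NULL
  if (!inherits(run, "xml_missing")) {
    ts <- xml2::xml_attr(run, "startTimeStamp")
    if (!is.na(ts)) acquired <- ts
  }
  # referenceableParamGroup definitions, resolved on demand
  rpg <- list()
  for (g in xml2::xml_find_all(root,
         "./referenceableParamGroupList/referenceableParamGroup")) {
    rpg[[xml2::xml_attr(g, "id")]] <- g
  }
  sample_info <- list()
  smp <- xml2::xml_find_first(root, "./sampleList/sample")
  if (!inherits(smp, "xml_missing")) {
    nm <- xml2::xml_attr(smp, "name")
    if (!is.na(nm)) sample_info[["Sample name"]] <- nm
    for (p in xml2::xml_find_all(smp, "./cvParam | ./userParam")) {
      pname <- xml2::xml_attr(p, "name")
      pval <- xml2::xml_attr(p, "value")
      if (!is.na(pname)) {
        sample_info[[pname]] <- if (is.na(pval)) "" else pval
      }
    }
  }
  instruments <- lapply(
    xml2::xml_find_all(icl, "./instrumentConfiguration"),
    function(cfg) mzml_config_to_instrument(cfg, rpg)
  )
  file_metadata(file_name = basename(path), acquired_date = acquired,
                sample_info = sample_info, instruments = instruments)
}

mzml_config_to_instrument <- function(cfg, rpg) {
  params <- xml2::xml_find_all(cfg, "./cvParam | ./userParam")
  for (ref in xml2::xml_find_all(cfg, "./referenceableParamGroupRef")) {
    gid <- xml2::xml_attr(ref, "ref")
    if (!is.null(rpg[[gid]])) {
      params <- c(params,
                  xml2::xml_find_all(rpg[[gid]], "./cvParam | ./userParam"))
    }
  }
  model <- NA_character_
  tree <- empty_tree()
  for (p in params) {
    name <- xml2::xml_attr(p, "name")
    value <- xml2::xml_attr(p, "value")
    accession <- xml2::xml_attr(p, "accession")
    is_cv <- xml2::xml_name(p) == "cvParam"
    if (is.na(name) || !nzchar(name)) next
    if (is_cv && is.na(accession)) {
      warning(sprintf("cvParam '%s' without CV accession; name kept verbatim",
                      name), call. = FALSE)
    }
    if (identical(name, "instrument model")) {
      model <- if (is.na(value) || !nzchar(value)) name else value
      next
    }
    keys <- if (!is_cv && grepl("/", name)) split_path(name) else name
    leaf <- if (is.na(value)) "" else parse_scalar_text(value)
    tree <- tree_set(tree, keys, leaf)
    if (is_cv && !is.na(accession)) {
      acc_keys <- keys
      acc_keys[length(acc_keys)] <- paste0(keys[length(keys)], "@accession")
      tree <- tree_set(tree, acc_keys, accession)
    }
  }
  if (is.na(model)) {
    model <- xml2::xml_attr(cfg, "id")
    if (is.na(model) || !nzchar(model)) model <- "unknown instrument"
  }
  instrument_metadata(model = model, module_type = "MS",
                      method_text = NULL, parameters = tree)
}

## ---- collection scanning --------------------------------------------------

#' Enumerate the metadata files of a collection
#'
#' A single file yields a one-entry manifest; a directory yields all
#' files whose extension matches `pattern` (case-insensitive `.json` /
#' `.mzML` by default), sorted lexicographically by file name so that
#' iteration order is independent of the operating system's directory
#' order.
#'
#' @param path a metadata file or a directory of them.
#' @param pattern optional regular expression on file names; default
#'   matches the two supported extensions.
#' @return a `collection_manifest`: a data frame with columns
#'   `file_name`, `path`, `source_format` (`"json"` or `"mzML"`).
#' @export
scan_collection <- function(path, pattern = NULL) {
  if (!file.exists(path)) {
    ms_abort(sprintf("no such path: %s", path), "msgroupr_io_error")
  }
  fmt_of <- function(f) {
    ifelse(grepl("\\.json$", f, ignore.case = TRUE), "json",
           ifelse(grepl("\\.mzml$", f, ignore.case = TRUE), "mzML",
                  NA_character_))
  }
  if (dir.exists(path)) {
    pat <- if (is.null(pattern)) "\\.(json|mzml)$" else pattern
    files <- list.files(path, pattern = pat, ignore.case = TRUE,
                        full.names = FALSE)
    files <- sort(files, method = "radix")
    if (length(files) == 0L) {
      ms_abort(sprintf("no input files under %s", path),
               "msgroupr_no_input_error")
    }
    man <- data.frame(file_name = files,
                      path = file.path(path, files),
                      source_format = fmt_of(files),
                      stringsAsFactors = FALSE)
  } else {
    man <- data.frame(file_name = basename(path), path = path,
                      source_format = fmt_of(basename(path)),
                      stringsAsFactors = FALSE)
  }
  if (anyNA(man$source_format)) {
    ms_abort(sprintf("unrecognized input format: %s",
                     man$file_name[is.na(man$source_format)][1]),
             "msgroupr_format_error")
  }
  if (anyDuplicated(man$file_name)) {
    ms_abort("duplicate file names in collection", "msgroupr_structure_error")
  }
  structure(man, class = c("collection_manifest", "data.frame"),
            root_path = if (dir.exists(path)) path else dirname(path))
}

#' Read one manifest entry (dispatching on source format)
#'
#' @param path path to a metadata file.
#' @param source_format `"json"` or `"mzML"`; inferred from the
#'   extension when missing.
#' @return a [file_metadata()] record.
#' @export
read_file_metadata <- function(path, source_format = NULL) {
  if (is.null(source_format)) {
    source_format <- if (grepl("\\.mzml$", path, ignore.case = TRUE)) "mzML"
                     else "json"
  }
  switch(source_format,
    json = read_native_json(path),
    mzML = read_mzml_metadata(path),
    ms_abort(sprintf("unknown source format '%s'", source_format),
             "msgroupr_format_error")
  )
}
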