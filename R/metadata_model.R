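## Metadata data model: parameter trees, per-file metadata records,
## canonical serialization and content hashing.
##
## A "metadata tree" is an ordered named list whose leaves are scalar
## strings, numbers, booleans or NULL, and whose internal nodes are nested
## named lists.  This single carrier abstracts over the instrument-class
## specific layouts found in acquisition files.

#' Validate a metadata tree
#'
#' Checks that `tree` is a (possibly empty) named list with non-empty,
#' unique sibling keys and scalar leaves of supported type.  Errors name
#' the offending path.
#'
#' @param tree nested named list.
#' @param path prefix used in error messages.
#' @return `tree`, invisibly.
#' @export
validate_tree <- function(tree, path = "") {
  if (is_leaf(tree) && !is.list(tree)) {
    render_scalar(tree, path)  # type check only
    return(invisible(tree))
  }
  if (!is.list(tree)) {
    ms_abort(sprintf("node at '%s' is neither leaf nor mapping (type %s)",
                     path, typeof(tree)), "msgroupr_structure_error")
  }
  if (length(tree) == 0L) return(invisible(tree))
  keys <- names(tree)
  if (is.null(keys) || any(is.na(keys)) || any(!nzchar(keys))) {
    ms_abort(sprintf("unnamed or empty key among children of '%s'", path),
             "msgroupr_structure_error")
  }
  nkeys <- stringi::stri_trans_nfc(keys)
  if (anyDuplicated(nkeys)) {
    dup <- nkeys[duplicated(nkeys)][1]
    ms_abort(sprintf("duplicate sibling key '%s' under '%s'", dup, path),
             "msgroupr_duplicate_key_error")
  }
  for (i in seq_along(tree)) {
    child_path <- if (nzchar(path)) paste0(path, "/", escape_key(keys[i]))
                  else escape_key(keys[i])
    validate_tree(tree[[i]], child_path)
  }
  invisible(tree)
}

empty_tree <- function() structure(list(), names = character())

#' Construct an instrument metadata record
#'
#' @param model instrument model string, e.g. `"Q Exactive - Orbitrap_MS"`.
#' @param module_type one of `"MS"`, `"LC"`, `"OTHER"`.
#' @param method_text verbatim instrument method string, or `NULL`.
#' @param parameters metadata tree of instrument parameters.
#' @return object of class `instrument_metadata`.
#' @export
instrument_metadata <- function(model, module_type = "MS",
                                method_text = NULL,
                                parameters = empty_tree()) {
  if (!is_string(model) || !nzchar(model)) {
    ms_abort("instrument model must be a non-empty string",
             "msgroupr_structure_error")
  }
  if (!module_type %in% c("MS", "LC", "OTHER")) {
    ms_abort(sprintf("module_type '%s' not one of MS, LC, OTHER", module_type),
             "msgroupr_structure_error")
  }
  if (!is.null(method_text) && !is_string(method_text)) {
    ms_abort("method_text must be a single string or NULL",
             "msgroupr_structure_error")
  }
  validate_tree(parameters, escape_key(model))
  structure(list(model = model, module_type = module_type,
                 method_text = method_text, parameters = parameters),
            class = "instrument_metadata")
}

#' Construct a per-file metadata record
#'
#' One acquisition file's full metadata: file-specific header fields
#' (name, acquisition date, sample information) plus an ordered list of
#' per-instrument parameter trees.
#'
#' @param file_name non-empty file name, unique within a collection.
#' @param acquired_date ISO-8601 timestamp string or `NULL`.
#' @param sample_info named list/character vector of sample fields
#'   (sample id, vial, comment, ...), values coerced to strings.
#' @param instruments list of [instrument_metadata()] records (may be
#'   empty, never `NULL`).
#' @return object of class `file_metadata`.
#' @export
file_metadata <- function(file_name, acquired_date = NULL,
                          sample_info = list(), instruments = list()) {
  if (!is_string(file_name) || !nzchar(file_name)) {
    ms_abort("file_name must be a non-empty string",
             "msgroupr_structure_error")
  }
  if (!is.null(acquired_date) && !is_string(acquired_date)) {
    ms_abort("acquired_date must be a single string or NULL",
             "msgroupr_structure_error")
  }
  sample_info <- as.list(sample_info)
  if (length(sample_info) > 0L &&
      (is.null(names(sample_info)) || any(!nzchar(names(sample_info))))) {
    ms_abort("sample_info entries must be named", "msgroupr_structure_error")
  }
  sample_info <- lapply(sample_info, function(v) {
    if (!is_leaf(v)) ms_abort("sample_info values must be scalars",
                              "msgroupr_structure_error")
    if (is.null(v)) "" else as.character(v)
  })
  if (!is.list(instruments)) {
    ms_abort("instruments must be a list (possibly empty)",
             "msgroupr_structure_error")
  }
  for (inst in instruments) {
    if (!inherits(inst, "instrument_metadata")) {
      ms_abort("instruments must contain instrument_metadata records",
               "msgroupr_structure_error")
    }
  }
  structure(list(file_name = file_name, acquired_date = acquired_date,
                 sample_info = sample_info, instruments = instruments),
            class = "file_metadata")
}

#' @export
print.file_metadata <- function(x, ...) {
  cat(sprintf("<file_metadata> %s\n", x$file_name))
  cat(sprintf("  acquired: %s\n",
              if (is.null(x$acquired_date)) "(none)" else x$acquired_date))
  for (inst in x$instruments) {
    cat(sprintf("  [%s] %s (%d parameters)\n", inst$module_type, inst$model,
                length(tree_paths(inst$parameters))))
  }
  invisible(x)
}

## ---- tree utilities -------------------------------------------------------

# Get a subtree/leaf by key vector; `missing` returned when absent.
tree_get <- function(tree, keys, missing = NULL) {
  node <- tree
  for (k in keys) {
    if (!is.list(node) || !k %in% names(node)) return(missing)
    node <- node[[k]]
  }
  node
}

# Set (replace or create) a leaf/subtree at a key vector.
tree_set <- function(tree, keys, value) {
  if (length(keys) == 0L) return(value)
  k <- keys[[1]]
  if (!is.list(tree)) tree <- empty_tree()
  rest <- if (k %in% names(tree)) tree[[k]] else empty_tree()
  tree[k] <- list(tree_set(rest, keys[-1], value))  # list() keeps NULL leaves
  tree
}

# Remove the node at a key vector; empty intermediate nodes are kept so
# the surviving siblings' layout is untouched.
tree_drop <- function(tree, keys) {
  if (!is.list(tree) || length(keys) == 0L) return(tree)
  k <- keys[[1]]
  if (!k %in% names(tree)) return(tree)
  if (length(keys) == 1L) {
    tree[[k]] <- NULL
    return(tree)
  }
  tree[[k]] <- tree_drop(tree[[k]], keys[-1])
  tree
}

# All leaf paths of a tree as escaped slash-joined strings, depth-first
# in stored key order.
tree_paths <- function(tree, prefix = character()) {
  if (is_leaf(tree) && !is.list(tree)) return(join_path(prefix))
  if (!is.list(tree) || length(tree) == 0L) return(character())
  unlist(lapply(names(tree), function(k) {
    tree_paths(tree[[k]], c(prefix, k))
  }), use.names = FALSE)
}

## ---- stripping, serialization, hashing ------------------------------------

#' Reduce a file's metadata to its group-relevant parameter tree
#'
#' Merges all instruments' parameter trees into one tree keyed by
#' instrument model (a second occurrence of the same model gets a `"#2"`
#' suffix, and so on), drops the file-specific header fields (file name,
#' acquisition date, sample information), and removes any additional
#' `exclude_paths`.  Each instrument subtree gains an `"Instrument model"`
#' leaf so reports can cite the model; the verbatim method string, when
#' present, is kept as a `"Method text"` leaf.  The module-type tag
#' (MS/LC/OTHER) is a classification, not an acquisition parameter, and
#' does not participate.
#'
#' The result is what the grouping engine hashes: two files fall in the
#' same parameter group exactly when their stripped trees are equal.
#'
#' @param meta a [file_metadata()] record.
#' @param exclude_paths character vector of slash-joined tree paths
#'   (relative to the merged tree) to remove before hashing, e.g.
#'   per-run tune-file paths.  `/` inside a key is escaped as `\/`.
#' @return a metadata tree.  The input is not modified.
#' @export
strip_file_specific <- function(meta, exclude_paths = character()) {
  if (!inherits(meta, "file_metadata")) {
    ms_abort("meta must be a file_metadata record", "msgroupr_structure_error")
  }
  merged <- empty_tree()
  seen <- character()
  for (inst in meta$instruments) {
    key <- inst$model
    n_prev <- sum(seen == inst$model)
    if (n_prev > 0L) key <- sprintf("%s#%d", inst$model, n_prev + 1L)
    seen <- c(seen, inst$model)
    sub <- inst$parameters
    validate_tree(sub, escape_key(key))
    if ("Instrument model" %in% names(sub)) {
      ms_abort(sprintf(
        "instrument '%s' parameters already contain reserved key 'Instrument model'",
        inst$model), "msgroupr_structure_error")
    }
    sub[["Instrument model"]] <- inst$model
    if (!is.null(inst$method_text)) {
      if ("Method text" %in% names(sub)) {
        ms_abort(sprintf(
          "instrument '%s' parameters already contain reserved key 'Method text'",
          inst$model), "msgroupr_structure_error")
      }
      sub[["Method text"]] <- inst$method_text
    }
    merged[[key]] <- sub
  }
  for (p in exclude_paths) {
    merged <- tree_drop(merged, split_path(p))
  }
  merged
}

#' Canonically serialize a metadata tree
#'
#' Produces a deterministic UTF-8 byte sequence: compact JSON with keys
#' NFC-normalized and sorted lexicographically by Unicode code point at
#' every level, and scalars rendered by the fixed rule of
#' [render_scalar()].  Trees with the same content yield the same bytes
#' regardless of key insertion order.
#'
#' @param tree metadata tree.
#' @return raw vector (UTF-8 bytes).
#' @export
canonical_serialize <- function(tree) {
  validate_tree(tree)
  charToRaw(enc2utf8(emit_json_tree(tree, sort_keys = TRUE)))
}

#' Content hash of a metadata tree
#'
#' SHA-256 digest of [canonical_serialize()]; stable across runs and
#' platforms.  Used as the grouping key: hash equality stands in for
#' deep tree equality.
#'
#' @param tree metadata tree.
#' @return lowercase 64-character hexadecimal string.
#' @export
content_hash <- function(tree) {
  digest::digest(canonical_serialize(tree), algo = "sha256",
                 serialize = FALSE)
}
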