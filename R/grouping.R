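## Grouping engine: partition a collection into the minimal set of
## parameter groups whose members share all relevant instrument
## settings, keyed by the content hash of each file's stripped tree.

GROUPED_FORMAT_VERSION <- "1.0"

#' Partition per-file metadata into minimal parameter groups
#'
#' Files are keyed by `content_hash(strip_file_specific(meta))`: two
#' files land in the same group exactly when all their relevant
#' parameters agree.  The result is deterministic for a given input set
#' regardless of input order or concurrency: groups are numbered by
#' first occurrence in lexicographic file-name (manifest) order, and
#' member lists are sorted.
#'
#' @param metadata non-empty list of [file_metadata()] records with
#'   unique file names.
#' @param exclude_paths extra tree paths stripped before hashing (see
#'   [strip_file_specific()]).
#' @param attach_gradients parse LC method text into gradient parameter
#'   subtrees before hashing (default `TRUE`).
#' @param failed optional list of `list(file_name=, error=)` records for
#'   files that could not be read; carried into the result.
#' @return a `grouped_collection`: list with `version`, `groups` (each a
#'   `parameter_group` with `group_id`, `file_names`, `shared`, `hash`,
#'   `first_seen`) and `failed`.
#' @export
group_files <- function(metadata, exclude_paths = character(),
                        attach_gradients = TRUE, failed = list()) {
  if (!is.list(metadata) || length(metadata) == 0L) {
    ms_abort("metadata must be a non-empty list", "msgroupr_structure_error")
  }
  for (m in metadata) {
    if (!inherits(m, "file_metadata")) {
      ms_abort("metadata must contain file_metadata records",
               "msgroupr_structure_error")
    }
  }
  file_names <- vapply(metadata, function(m) m$file_name, character(1))
  if (anyDuplicated(file_names)) {
    ms_abort(sprintf("duplicate file name '%s'",
                     file_names[duplicated(file_names)][1]),
             "msgroupr_structure_error")
  }
  # manifest order: lexicographic by file name, independent of input order
  ord <- order(file_names, method = "radix")
  metadata <- metadata[ord]
  file_names <- file_names[ord]

  stripped <- lapply(metadata, function(m) {
    if (attach_gradients) {
      m$instruments <- lapply(m$instruments, attach_gradient)
    }
    strip_file_specific(m, exclude_paths = exclude_paths)
  })
  hashes <- vapply(stripped, content_hash, character(1))

  first_seen <- match(unique(hashes), hashes)
  groups <- lapply(seq_along(first_seen), function(g) {
    idx <- which(hashes == hashes[first_seen[g]])
    structure(list(group_id = g,
                   file_names = file_names[idx],  # already sorted
                   shared = stripped[[first_seen[g]]],
                   hash = hashes[first_seen[g]],
                   first_seen = first_seen[g]),
              class = "parameter_group")
  })
  structure(list(version = GROUPED_FORMAT_VERSION, groups = groups,
                 failed = failed),
            class = "grouped_collection")
}

#' Group a whole collection from disk
#'
#' Scans `path` (file or directory), reads every manifest entry, and
#' groups the readable files.  Files that fail to read are excluded
#' from grouping and listed in the result's `failed` section with their
#' error message — one corrupt file must not abort a multi-hundred-file
#' report, and silent omission would be worse.
#'
#' @param path metadata file or directory.
#' @param pattern optional file-name filter (see [scan_collection()]).
#' @param jobs number of parallel workers for per-file ingestion;
#'   results are identical to sequential execution.
#' @inheritParams group_files
#' @return a `grouped_collection`.
#' @export
group_collection <- function(path, exclude_paths = character(),
                             pattern = NULL, attach_gradients = TRUE,
                             jobs = 1L) {
  manifest <- scan_collection(path, pattern = pattern)
  reader <- function(i) {
    tryCatch(
      list(ok = TRUE,
           meta = read_file_metadata(manifest$path[i],
                                     manifest$source_format[i])),
      error = function(e) list(ok = FALSE, file = manifest$file_name[i],
                               error = conditionMessage(e))
    )
  }
  results <- if (jobs > 1L && requireNamespace("parallel", quietly = TRUE) &&
                 .Platform$OS.type == "unix") {
    parallel::mclapply(seq_len(nrow(manifest)), reader, mc.cores = jobs)
  } else {
    lapply(seq_len(nrow(manifest)), reader)
  }
  ok <- vapply(results, function(r) isTRUE(r$ok), logical(1))
  failed <- lapply(results[!ok], function(r) {
    list(file_name = r$file, error = r$error)
  })
  if (!any(ok)) {
    ms_abort("no readable input files in collection",
             "msgroupr_no_input_error")
  }
  group_files(lapply(results[ok], function(r) r$meta),
              exclude_paths = exclude_paths,
              attach_gradients = attach_gradients, failed = failed)
}

#' @export
print.grouped_collection <- function(x, ...) {
  n_files <- sum(vapply(x$groups, function(g) length(g$file_names),
                        integer(1)))
  cat(sprintf("<grouped_collection> %d file(s) in %d parameter group(s)\n",
              n_files, length(x$groups)))
  for (g in x$groups) {
    cat(sprintf("  group %d: %d file(s), hash %s...\n", g$group_id,
                length(g$file_names), substr(g$hash, 1, 12)))
  }
  if (length(x$failed) > 0L) {
    cat(sprintf("  failed: %d file(s)\n", length(x$failed)))
  }
  invisible(x)
}

## ---- grouped JSON interchange --------------------------------------------

#' Write a grouped collection as JSON
#'
#' Interchange format consumed by the reporting functions: top-level
#' `{"Version", "Groups": [{"GroupId", "FileNames", "SharedParameters"}],
#' "Failed": [...]}`.  Shared parameter trees are written in canonical
#' (sorted-key) order so output bytes are deterministic for identical
#' content.  The JSON-Schema lives in
#' inst/extdata/schemas/grouped-collection.schema.json.
#'
#' @param gc a `grouped_collection`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_grouped_json <- function(gc, path) {
  if (!inherits(gc, "grouped_collection")) {
    ms_abort("gc must be a grouped_collection", "msgroupr_structure_error")
  }
  group_json <- vapply(gc$groups, function(g) {
    names_json <- paste(vapply(g$file_names, json_escape_string,
                               character(1)), collapse = ",\n        ")
    paste0(
      "{\n      \"GroupId\": ", g$group_id,
      ",\n      \"FileNames\": [\n        ", names_json, "\n      ]",
      ",\n      \"SharedParameters\": ",
      indent_block(emit_json_tree(g$shared, sort_keys = TRUE,
                                  indent = "  "), "      "),
      "\n    }")
  }, character(1))
  failed_json <- vapply(gc$failed, function(f) {
    paste0("{\"FileName\": ", json_escape_string(f$file_name),
           ", \"Error\": ", json_escape_string(f$error), "}")
  }, character(1))
  txt <- paste0(
    "{\n  \"Version\": ", json_escape_string(gc$version), ",\n",
    "  \"Groups\": ",
    if (length(group_json) == 0L) "[]"
    else paste0("[\n    ", paste(group_json, collapse = ",\n    "),
                "\n  ]"),
    ",\n  \"Failed\": ",
    if (length(failed_json) == 0L) "[]"
    else paste0("[\n    ", paste(failed_json, collapse = ",\n    "),
                "\n  ]"),
    "\n}")
  write_utf8(txt, path)
}

#' Read a grouped collection from JSON
#'
#' Validates the interchange invariants: group ids numbered 1..G in
#' order, member lists non-empty, sorted and disjoint across groups.
#'
#' @param path path to a grouped-collection JSON file.
#' @return a `grouped_collection`.
#' @export
read_grouped_json <- function(path) {
  doc <- tryCatch(
    jsonlite::parse_json(paste(read_utf8(path), collapse = "\n")),
    error = function(e) ms_abort(
      sprintf("not parseable as JSON: %s", path), "msgroupr_validation_error")
  )
  if (!is.list(doc) || !is_string(doc[["Version"]])) {
    validation_error("/Version", "required string")
  }
  grs <- doc[["Groups"]]
  if (!is.list(grs) || (length(grs) > 0L && !is.null(names(grs)))) {
    validation_error("/Groups", "expected an array")
  }
  seen_names <- character()
  groups <- lapply(seq_along(grs), function(i) {
    g <- grs[[i]]
    ptr <- sprintf("/Groups/%d", i - 1L)
    gid <- g[["GroupId"]]
    if (!is.numeric(gid) || length(gid) != 1L || gid != i) {
      validation_error(paste0(ptr, "/GroupId"),
                       sprintf("groups must be numbered 1..G in order (expected %d)", i))
    }
    fns <- g[["FileNames"]]
    if (!is.list(fns) || length(fns) == 0L) {
      validation_error(paste0(ptr, "/FileNames"), "non-empty array required")
    }
    fns <- vapply(fns, function(x) {
      if (!is_string(x)) validation_error(paste0(ptr, "/FileNames"),
                                          "entries must be strings")
      x
    }, character(1))
    if (anyDuplicated(fns)) {
      validation_error(paste0(ptr, "/FileNames"), "duplicate member")
    }
    fns <- sort(fns, method = "radix")
    shared <- json_to_tree(g[["SharedParameters"]],
                           paste0(ptr, "/SharedParameters"))
    structure(list(group_id = as.integer(gid), file_names = fns,
                   shared = shared, hash = content_hash(shared),
                   first_seen = NA_integer_),
              class = "parameter_group")
  })
  all_names <- unlist(lapply(groups, function(g) g$file_names))
  if (anyDuplicated(all_names)) {
    ms_abort(sprintf("file '%s' appears in more than one group",
                     all_names[duplicated(all_names)][1]),
             "msgroupr_validation_error")
  }
  failed <- lapply(doc[["Failed"]], function(f) {
    list(file_name = f[["FileName"]], error = f[["Error"]])
  })
  structure(list(version = doc[["Version"]], groups = groups,
                 failed = failed),
            class = "grouped_collection")
}

## ---- drift diffing --------------------------------------------------------

#' Differences between two parameter groups
#'
#' Walks both shared trees and reports exactly the leaf paths on which
#' they differ, including one-sided presence (signalled by the
#' `"(absent)"` marker).  An empty result is equivalent to hash
#' equality.  This is the parameter-drift report: a collection expected
#' to be homogeneous that splits into several groups can be inspected
#' pairwise to see which settings moved.
#'
#' @param a,b `parameter_group` records (or bare metadata trees).
#' @return data frame with columns `path`, `value_a`, `value_b`, sorted
#'   by path; zero rows iff the trees are equal.
#' @export
diff_groups <- function(a, b) {
  tree_a <- if (inherits(a, "parameter_group")) a$shared else a
  tree_b <- if (inherits(b, "parameter_group")) b$shared else b
  validate_tree(tree_a)
  validate_tree(tree_b)
  rows <- diff_trees(tree_a, tree_b, character())
  out <- if (length(rows) == 0L) {
    data.frame(path = character(), value_a = character(),
               value_b = character(), stringsAsFactors = FALSE)
  } else {
    do.call(rbind, lapply(rows, function(r) {
      data.frame(path = r[[1]], value_a = r[[2]], value_b = r[[3]],
                 stringsAsFactors = FALSE)
    }))
  }
  out[order(out$path, method = "radix"), , drop = FALSE]
}

ABSENT_MARKER <- "(absent)"

# Render a subtree/leaf for diff output.
diff_render <- function(x) {
  if (is_leaf(x) && !is.list(x)) {
    render_scalar(x)
  } else {
    rawToChar(canonical_serialize(x))
  }
}

diff_trees <- function(a, b, prefix) {
  is_map_a <- is.list(a)
  is_map_b <- is.list(b)
  if (!is_map_a || !is_map_b) {
    # compare on the canonical rendering (string-typed "300" differs from
    # the number 300, matching hash behaviour), display the plain form
    same <- !is_map_a && !is_map_b &&
      identical(json_render_leaf(a, ""), json_render_leaf(b, ""))
    if (same) return(list())
    return(list(list(join_path(prefix), diff_render(a), diff_render(b))))
  }
  keys <- sort(unique(c(names(a), names(b))), method = "radix")
  out <- list()
  for (k in keys) {
    in_a <- k %in% names(a)
    in_b <- k %in% names(b)
    sub_prefix <- c(prefix, k)
    if (in_a && in_b) {
      out <- c(out, diff_trees(a[[k]], b[[k]], sub_prefix))
    } else if (in_a) {
      out <- c(out, list(list(join_path(sub_prefix), diff_render(a[[k]]),
                              ABSENT_MARKER)))
    } else {
      out <- c(out, list(list(join_path(sub_prefix), ABSENT_MARKER,
                              diff_render(b[[k]]))))
    }
  }
  out
}

`%||%` <- function(x, y) if (is.null(x)) y else x
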