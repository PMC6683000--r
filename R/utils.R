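#' @keywords internal
"_PACKAGE"

## Internal helpers shared across modules: scalar rendering, tree-path
## escaping, and a deterministic JSON emitter.  All serialization in the
## package funnels through these so that hashing, file output and
## round-trips agree byte for byte.

# Abort with a classed condition so callers/tests can distinguish error kinds.
ms_abort <- function(message, class, ...) {
  stop(structure(
    class = c(class, "msgroupr_error", "error", "condition"),
    list(message = message, call = sys.call(-1), ...)
  ))
}

is_string <- function(x) is.character(x) && length(x) == 1L && !is.na(x)

# Scalar leaf check: length-1 atomic or NULL.  NA leaves are rejected
# upstream (they have no JSON rendering).
is_leaf <- function(x) {
  is.null(x) || (is.atomic(x) && length(x) == 1L)
}

#' Render a scalar leaf as its canonical text
#'
#' Integers render as plain decimal text; doubles by the shortest digit
#' string that round-trips through `as.numeric()`; booleans as
#' `"true"`/`"false"`; `NULL` as `"null"`.  Strings are NFC-normalized and
#' returned verbatim (no case folding).  This fixed rule makes canonical
#' serialization, and therefore content hashes, reproducible across
#' platforms.
#'
#' @param x a scalar leaf value.
#' @param path tree path used in error messages.
#' @return single character string.
#' @keywords internal
render_scalar <- function(x, path = "") {
  if (is.null(x)) return("null")
  if (length(x) != 1L || !is.atomic(x)) {
    ms_abort(sprintf("unsupported leaf at '%s': not a scalar", path),
             "msgroupr_type_error")
  }
  if (is.na(x)) {
    ms_abort(sprintf("unsupported leaf at '%s': NA has no rendering", path),
             "msgroupr_type_error")
  }
  if (is.logical(x)) return(if (x) "true" else "false")
  if (is.numeric(x)) return(render_number(x, path))
  if (is.character(x)) return(stringi::stri_trans_nfc(x))
  ms_abort(sprintf("unsupported leaf at '%s': type %s", path, typeof(x)),
           "msgroupr_type_error")
}

# Shortest round-trip decimal rendering.  Whole numbers (within exact
# double range) drop the fractional part entirely so that the integer 300
# and the double 300.0 hash identically -- required for cross-format
# agreement, where mzML carries untyped value text.
render_number <- function(x, path = "") {
  if (!is.finite(x)) {
    ms_abort(sprintf("unsupported leaf at '%s': non-finite number", path),
             "msgroupr_type_error")
  }
  if (is.integer(x)) return(sprintf("%d", x))
  if (x == trunc(x) && abs(x) < 2^53) return(sprintf("%.0f", x))
  for (d in 1:17) {
    s <- sprintf("%.*g", d, x)
    if (as.numeric(s) == x) return(s)
  }
  sprintf("%.17g", x)
}

# Parse mzML / text scalar values with a strict syntax-driven rule:
# integer or decimal syntax -> numeric, "true"/"false" -> logical,
# anything else verbatim string.
parse_scalar_text <- function(s) {
  if (!is_string(s)) return(s)
  if (s == "true") return(TRUE)
  if (s == "false") return(FALSE)
  if (grepl("^-?(0|[1-9][0-9]*)(\\.[0-9]+)?([eE][+-]?[0-9]+)?$", s)) {
    return(as.numeric(s))
  }
  s
}

## ---- tree paths -----------------------------------------------------------

#' Escape a tree key for use inside a slash-separated path
#'
#' Literal `/` and `\` in keys are backslash-escaped, so flattened paths
#' are unambiguous and [split_path()] inverts [join_path()] exactly.
#' @param key character vector of keys.
#' @keywords internal
escape_key <- function(key) {
  gsub("/", "\\\\/", gsub("\\\\", "\\\\\\\\", key))
}

unescape_key <- function(key) {
  gsub("\\\\(.)", "\\1", key)
}

join_path <- function(keys) paste(escape_key(keys), collapse = "/")

# Split an escaped path back into keys (inverse of join_path).
split_path <- function(path) {
  if (!is_string(path)) ms_abort("path must be a single string",
                                 "msgroupr_type_error")
  keys <- character()
  buf <- character()
  chars <- strsplit(path, "", fixed = TRUE)[[1]]
  i <- 1L
  n <- length(chars)
  while (i <= n) {
    ch <- chars[i]
    if (ch == "\\" && i < n) {
      buf <- c(buf, chars[i + 1L])
      i <- i + 2L
    } else if (ch == "/") {
      keys <- c(keys, paste(buf, collapse = ""))
      buf <- character()
      i <- i + 1L
    } else {
      buf <- c(buf, ch)
      i <- i + 1L
    }
  }
  c(keys, paste(buf, collapse = ""))
}

## ---- deterministic JSON emitter ------------------------------------------

json_escape_string <- function(s) {
  s <- gsub("\\\\", "\\\\\\\\", s)
  s <- gsub("\"", "\\\\\"", s)
  s <- gsub("\n", "\\\\n", s)
  s <- gsub("\r", "\\\\r", s)
  s <- gsub("\t", "\\\\t", s)
  # remaining C0 control characters -> \u00XX
  if (grepl("[\x01-\x1f]", s, useBytes = TRUE)) {
    chars <- strsplit(s, "", fixed = TRUE)[[1]]
    codes <- utf8ToInt(paste(chars, collapse = ""))
    chars <- vapply(codes, function(cp) {
      if (cp < 32L) sprintf("\\u%04x", cp) else intToUtf8(cp)
    }, character(1))
    s <- paste(chars, collapse = "")
  }
  paste0("\"", s, "\"")
}

json_render_leaf <- function(x, path) {
  if (is.character(x)) json_escape_string(render_scalar(x, path))
  else render_scalar(x, path)
}

# Explicit JSON array marker for document writers (metadata trees
# themselves never contain arrays).
ms_array <- function(items = list()) {
  structure(list(items = items), class = "ms_json_array")
}

# Emit a nested named list ("tree") as JSON text.  sort_keys = TRUE gives
# the canonical form used for hashing; FALSE preserves insertion order
# (used by the pretty writers).  indent = NULL emits compact one-line JSON.
# ms_array() nodes emit as JSON arrays.
emit_json_tree <- function(x, sort_keys = TRUE, indent = NULL, path = "") {
  emit <- function(x, path, depth) {
    if (inherits(x, "ms_json_array")) {
      items <- x$items
      if (length(items) == 0L) return("[]")
      parts <- vapply(seq_along(items), function(i) {
        emit(items[[i]], paste0(path, "[", i, "]"), depth + 1L)
      }, character(1))
      if (is.null(indent)) {
        return(paste0("[", paste(parts, collapse = ","), "]"))
      }
      pad <- strrep(indent, depth + 1L)
      return(paste0("[\n", pad, paste(parts, collapse = paste0(",\n", pad)),
                    "\n", strrep(indent, depth), "]"))
    }
    if (is_leaf(x) && !is.list(x)) return(json_render_leaf(x, path))
    if (!is.list(x)) {
      ms_abort(sprintf("unsupported node at '%s': type %s", path, typeof(x)),
               "msgroupr_type_error")
    }
    if (length(x) == 0L) return("{}")
    keys <- names(x)
    if (is.null(keys) || any(!nzchar(keys))) {
      ms_abort(sprintf("unnamed or empty key among children of '%s'", path),
               "msgroupr_structure_error")
    }
    keys <- stringi::stri_trans_nfc(keys)
    if (anyDuplicated(keys)) {
      dup <- keys[duplicated(keys)][1]
      ms_abort(sprintf("duplicate sibling key '%s' under '%s'", dup, path),
               "msgroupr_duplicate_key_error")
    }
    ord <- if (sort_keys) order(keys, method = "radix") else seq_along(keys)
    parts <- vapply(ord, function(i) {
      child_path <- if (nzchar(path)) paste0(path, "/", escape_key(keys[i]))
                    else escape_key(keys[i])
      paste0(json_escape_string(keys[i]), ":",
             if (is.null(indent)) "" else " ",
             emit(x[[i]], child_path, depth + 1L))
    }, character(1))
    if (is.null(indent)) {
      paste0("{", paste(parts, collapse = ","), "}")
    } else {
      pad <- strrep(indent, depth + 1L)
      paste0("{\n", pad, paste(parts, collapse = paste0(",\n", pad)),
             "\n", strrep(indent, depth), "}")
    }
  }
  emit(x, path, 0L)
}

# Write text to a file as UTF-8 with LF line endings, no BOM.
write_utf8 <- function(lines, path) {
  con <- file(path, open = "wb")
  on.exit(close(con))
  writeLines(enc2utf8(lines), con, sep = "\n", useBytes = TRUE)
  invisible(path)
}

read_utf8 <- function(path) {
  readLines(path, encoding = "UTF-8", warn = FALSE)
}

# Run fn with the RNG seeded, restoring the caller's RNG state afterwards.
with_seed <- function(seed, fn) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  fn()
}
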