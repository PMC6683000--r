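## EASY-nLC style method-text parsing.
##
## Vendor method strings embed the LC gradient program as text.  The
## line dialect understood here (and emitted by the synthetic generator):
##
##   Gradient:
##     <time_min> / <duration_min> / <flow_nl_min> / <percent_B>
##     ...
##   Sample pickup: <v> µl
##   Equilibration: <v> µl
##
## Unknown lines are never dropped: they are preserved verbatim in the
## `unparsed` remainder so they can still participate in grouping.
## Additional vendor dialects can be registered per instrument model via
## `lc_dialect_registry`.

num_re <- "-?[0-9]+(\\.[0-9]+)?"

lc_parse_error <- function(line_no, line, what) {
  ms_abort(sprintf("LC method line %d ('%s'): %s", line_no, trimws(line), what),
           "msgroupr_lc_parse_error", line = line_no)
}

parse_dialect_number <- function(tok, line_no, line) {
  tok <- trimws(tok)
  if (grepl(",", tok, fixed = TRUE)) {
    lc_parse_error(line_no, line,
                   "comma decimal separator; use a decimal point")
  }
  if (!grepl(paste0("^", num_re, "$"), tok)) {
    lc_parse_error(line_no, line, sprintf("'%s' is not a number", tok))
  }
  as.numeric(tok)
}

#' Parse LC method text into a gradient program
#'
#' @param method_text verbatim method string (non-empty).
#' @return a `gradient_program`: list with `steps` (data frame with
#'   columns `time_min`, `duration_min`, `flow_nl_min`, `percent_b`),
#'   `sample_volume_ul`, `column_equilibration_ul` (each numeric or
#'   `NULL`) and `unparsed` (character vector of lines not covered by
#'   the dialect).
#' @export
parse_lc_method <- function(method_text) {
  if (!is_string(method_text) || !nzchar(method_text)) {
    ms_abort("method_text must be a non-empty string",
             "msgroupr_structure_error")
  }
  lines <- strsplit(method_text, "\n", fixed = TRUE)[[1]]
  steps <- list()
  sample_volume <- NULL
  equilibration <- NULL
  unparsed <- character()
  in_gradient <- FALSE
  grad_row_re <- paste0("^\\s*", num_re, "\\s*(/\\s*", num_re, "\\s*){3}$")
  row_shape_re <- "^\\s*[-0-9.,eE ]+(\\s*/\\s*[-0-9.,eE ]+){1,}\\s*$"
  for (i in seq_along(lines)) {
    line <- lines[i]
    stripped <- trimws(line)
    if (!nzchar(stripped)) next
    if (grepl("^Gradient\\s*:\\s*$", stripped)) {
      in_gradient <- TRUE
      next
    }
    vol <- regmatches(stripped,
      regexec(paste0("^(Sample pickup|Equilibration)\\s*:\\s*(\\S+)\\s*(µl|ul)?$"),
              stripped))[[1]]
    if (length(vol) > 0L) {
      v <- parse_dialect_number(vol[3], i, line)
      if (v < 0) lc_parse_error(i, line, "volume must be non-negative")
      if (vol[2] == "Sample pickup") sample_volume <- v else equilibration <- v
      in_gradient <- FALSE
      next
    }
    if (in_gradient) {
      if (grepl(grad_row_re, stripped)) {
        toks <- strsplit(stripped, "/", fixed = TRUE)[[1]]
        vals <- vapply(toks, parse_dialect_number, numeric(1),
                       line_no = i, line = line, USE.NAMES = FALSE)
        steps[[length(steps) + 1L]] <- vals
        next
      }
      if (grepl(row_shape_re, stripped)) {
        # shaped like a gradient row but fails numeric parse: hard error,
        # a silently mis-read gradient is worse than a rejection
        toks <- strsplit(stripped, "/", fixed = TRUE)[[1]]
        if (length(toks) != 4L) {
          lc_parse_error(i, line, sprintf("expected 4 fields, got %d",
                                          length(toks)))
        }
        for (tok in toks) parse_dialect_number(tok, i, line)
      }
      in_gradient <- FALSE
    }
    unparsed <- c(unparsed, stripped)
  }
  step_df <- if (length(steps) == 0L) {
    data.frame(time_min = numeric(), duration_min = numeric(),
               flow_nl_min = numeric(), percent_b = numeric())
  } else {
    m <- do.call(rbind, steps)
    data.frame(time_min = m[, 1], duration_min = m[, 2],
               flow_nl_min = m[, 3], percent_b = m[, 4])
  }
  gp <- structure(list(steps = step_df, sample_volume_ul = sample_volume,
                       column_equilibration_ul = equilibration,
                       unparsed = unparsed),
                  class = "gradient_program")
  validate_gradient(gp)
  gp
}

validate_gradient <- function(gp) {
  s <- gp$steps
  if (nrow(s) > 0L) {
    if (s$time_min[1] != 0) {
      ms_abort("gradient must start at time 0", "msgroupr_lc_validation_error")
    }
    if (nrow(s) > 1L && any(diff(s$time_min) <= 0)) {
      ms_abort("gradient step times must be strictly increasing",
               "msgroupr_lc_validation_error")
    }
    if (any(s$percent_b < 0 | s$percent_b > 100)) {
      ms_abort("percent B must lie in [0, 100]",
               "msgroupr_lc_validation_error")
    }
    if (any(s$flow_nl_min <= 0)) {
      ms_abort("flow must be positive", "msgroupr_lc_validation_error")
    }
    if (any(s$duration_min < 0)) {
      ms_abort("step durations must be non-negative",
               "msgroupr_lc_validation_error")
    }
  }
  invisible(gp)
}

#' Render a gradient program back to method text
#'
#' Inverse of [parse_lc_method()] up to whitespace: re-parsing the
#' rendered text reproduces the same program.
#'
#' @param gp a `gradient_program`.
#' @return single string in the method-text dialect.
#' @export
render_lc_method <- function(gp) {
  out <- character()
  if (nrow(gp$steps) > 0L) {
    out <- c(out, "Gradient:",
             sprintf("  %s / %s / %s / %s",
                     vapply(gp$steps$time_min, render_number, character(1)),
                     vapply(gp$steps$duration_min, render_number, character(1)),
                     vapply(gp$steps$flow_nl_min, render_number, character(1)),
                     vapply(gp$steps$percent_b, render_number, character(1))))
  }
  if (!is.null(gp$sample_volume_ul)) {
    out <- c(out, sprintf("Sample pickup: %s µl",
                          render_number(gp$sample_volume_ul)))
  }
  if (!is.null(gp$column_equilibration_ul)) {
    out <- c(out, sprintf("Equilibration: %s µl",
                          render_number(gp$column_equilibration_ul)))
  }
  out <- c(out, gp$unparsed)
  paste(out, collapse = "\n")
}

#' @export
print.gradient_program <- function(x, ...) {
  cat(sprintf("<gradient_program> %d step(s)\n", nrow(x$steps)))
  if (nrow(x$steps) > 0L) print(x$steps)
  invisible(x)
}

# Convert a gradient program into the parameter subtree used for
# grouping and reporting.
gradient_to_tree <- function(gp) {
  tree <- empty_tree()
  n <- nrow(gp$steps)
  width <- max(2L, nchar(as.character(max(0L, n - 1L))))
  for (i in seq_len(n)) {
    tree[[sprintf("%0*d", width, i - 1L)]] <- list(
      "Time (min)" = gp$steps$time_min[i],
      "Duration (min)" = gp$steps$duration_min[i],
      "Flow (nl/min)" = gp$steps$flow_nl_min[i],
      "Percent B" = gp$steps$percent_b[i]
    )
  }
  tree
}

# Parameter leaves carried alongside the Gradient subtree.
gradient_extras <- function(gp) {
  extras <- list()
  if (!is.null(gp$sample_volume_ul)) {
    extras[["Sample pickup (µl)"]] <- gp$sample_volume_ul
  }
  if (!is.null(gp$column_equilibration_ul)) {
    extras[["Equilibration (µl)"]] <- gp$column_equilibration_ul
  }
  if (length(gp$unparsed) > 0L) {
    extras[["Unparsed method lines"]] <- paste(gp$unparsed, collapse = "\n")
  }
  extras
}

#' Attach the parsed gradient to an LC instrument's parameter tree
#'
#' For an LC instrument with method text, parses the text and extends
#' the parameter tree with a `"Gradient"` subtree (one child per step,
#' zero-padded index keys), plus sample-pickup / equilibration leaves
#' and an `"Unparsed method lines"` leaf when applicable — so gradients
#' participate in grouping and term matching.  Parse failures leave the
#' instrument unchanged and emit a warning: one unreadable method must
#' not abort the grouping of a whole collection (the verbatim method
#' string still participates in hashing via its `"Method text"` leaf).
#'
#' @param inst an [instrument_metadata()] record.
#' @param registry optional named list of parser functions keyed by
#'   instrument model; each takes the method text and returns a
#'   `gradient_program`.  Defaults to [parse_lc_method()] for all
#'   models.
#' @return an [instrument_metadata()] record (a modified copy).
#' @export
attach_gradient <- function(inst, registry = NULL) {
  if (!inherits(inst, "instrument_metadata")) {
    ms_abort("inst must be an instrument_metadata record",
             "msgroupr_structure_error")
  }
  if (inst$module_type != "LC" || is.null(inst$method_text)) return(inst)
  if ("Gradient" %in% names(inst$parameters)) return(inst)
  parser <- parse_lc_method
  if (!is.null(registry) && inst$model %in% names(registry)) {
    parser <- registry[[inst$model]]
  }
  gp <- tryCatch(parser(inst$method_text), error = function(e) {
    warning(sprintf("could not parse LC method of '%s': %s",
                    inst$model, conditionMessage(e)), call. = FALSE)
    NULL
  })
  if (is.null(gp)) return(inst)
  params <- inst$parameters
  params[["Gradient"]] <- gradient_to_tree(gp)
  for (k in names(gradient_extras(gp))) {
    params[[k]] <- gradient_extras(gp)[[k]]
  }
  inst$parameters <- params
  inst
}
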