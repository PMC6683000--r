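## Reporting: flatten grouped metadata into path/value tables and reduce
## them to guideline-specific (MIAPE / JPR / custom) report tables via a
## term-matching table.
##
## A term-matching table maps (origin_key, instrument, term label) to a
## path into the flattened tree and thereby defines a reporting
## guideline.  Bundled registries under inst/extdata/term_registries are
## re-derived from the MIAPE-MS guideline vocabulary; users can extend
## or override them with their own TSV files.

NOT_RECORDED <- "(not recorded)"

#' Flatten a shared parameter tree into a path/value table
#'
#' Depth-first canonical (sorted-key) order; keys are joined with `/`,
#' with literal `/` and `\` inside keys backslash-escaped, so the
#' flattening is lossless for every tree: [unflatten_table()] inverts it
#' exactly.
#'
#' @param shared metadata tree (or a `parameter_group`).
#' @param group_id group identifier attached to the result.
#' @return a `flat_table`: data frame with columns `path`, `value`
#'   (canonical text rendering), attribute `group_id`.
#' @export
flatten_group <- function(shared, group_id = NA_integer_) {
  if (inherits(shared, "parameter_group")) {
    if (is.na(group_id)) group_id <- shared$group_id
    shared <- shared$shared
  }
  validate_tree(shared)
  walk <- function(tree, prefix) {
    if (is_leaf(tree) && !is.list(tree)) {
      return(list(list(join_path(prefix), render_scalar(tree))))
    }
    if (length(tree) == 0L) return(list())
    keys <- names(tree)
    ord <- order(stringi::stri_trans_nfc(keys), method = "radix")
    unlist(lapply(ord, function(i) walk(tree[[i]], c(prefix, keys[i]))),
           recursive = FALSE)
  }
  rows <- walk(shared, character())
  out <- if (length(rows) == 0L) {
    data.frame(path = character(), value = character(),
               stringsAsFactors = FALSE)
  } else {
    data.frame(path = vapply(rows, `[[`, character(1), 1),
               value = vapply(rows, `[[`, character(1), 2),
               stringsAsFactors = FALSE)
  }
  structure(out, class = c("flat_table", "data.frame"),
            group_id = as.integer(group_id))
}

#' Rebuild a tree from a flattened table
#'
#' Inverse of [flatten_group()] up to leaf type: values come back as
#' their canonical text rendering (numbers re-typed by syntax), so
#' `flatten(unflatten(flatten(t)))` equals `flatten(t)` exactly.
#'
#' @param flat a `flat_table` (or any data frame with `path`, `value`).
#' @return a metadata tree.
#' @export
unflatten_table <- function(flat) {
  tree <- empty_tree()
  for (i in seq_len(nrow(flat))) {
    tree <- tree_set(tree, split_path(flat$path[i]),
                     parse_scalar_text(flat$value[i]))
  }
  tree
}

#' Flatten every group of a grouped collection
#'
#' @param gc a `grouped_collection`.
#' @return list of `flat_table`s, one per group, each carrying
#'   `group_id` and `file_names` attributes.
#' @export
flatten_collection <- function(gc) {
  if (!inherits(gc, "grouped_collection")) {
    ms_abort("gc must be a grouped_collection", "msgroupr_structure_error")
  }
  lapply(gc$groups, function(g) {
    ft <- flatten_group(g$shared, g$group_id)
    attr(ft, "file_names") <- g$file_names
    ft
  })
}

## ---- term-matching tables -------------------------------------------------

registry_dir <- function() {
  system.file("extdata", "term_registries", package = "msgroupr",
              mustWork = TRUE)
}

read_registry_tsv <- function(path) {
  df <- utils::read.delim(path, header = TRUE, sep = "\t",
                          colClasses = "character", quote = "",
                          fileEncoding = "UTF-8",
                          stringsAsFactors = FALSE)
  required_cols <- c("origin_key", "instrument", "term_label",
                     "source_path", "display_order", "required")
  missing <- setdiff(required_cols, names(df))
  if (length(missing) > 0L) {
    ms_abort(sprintf("term table %s lacks column(s): %s", path,
                     paste(missing, collapse = ", ")),
             "msgroupr_validation_error")
  }
  df$display_order <- as.integer(df$display_order)
  df$required <- tolower(df$required) %in% c("true", "1", "yes")
  df[required_cols]
}

load_registries <- function(user_files = NULL) {
  bundled <- list.files(registry_dir(), pattern = "\\.tsv$",
                        full.names = TRUE)
  tabs <- lapply(sort(bundled, method = "radix"), read_registry_tsv)
  reg <- do.call(rbind, tabs)
  for (uf in user_files) {
    user <- read_registry_tsv(uf)
    key <- function(d) paste(d$origin_key, d$instrument, d$term_label,
                             sep = "\r")
    reg <- reg[!key(reg) %in% key(user), , drop = FALSE]  # override wins
    reg <- rbind(reg, user)
  }
  reg
}

#' Build a guideline- and instrument-specific term-matching table
#'
#' Selects the registry rows for one reporting guideline (`origin_key`,
#' e.g. `"miape"` or `"jpr"`) restricted to the instruments of interest,
#' ordered by display order.  User TSV files extend or override bundled
#' rows (matched on origin/instrument/label).
#'
#' @param instrument_list character vector of instrument models, e.g.
#'   `c("Thermo EASY-nLC", "Q Exactive - Orbitrap_MS")`.
#' @param origin_key reporting-guideline key present in the registry.
#' @param user_files optional paths to user registry TSVs
#'   (columns `origin_key`, `instrument`, `term_label`, `source_path`,
#'   `display_order`, `required`).
#' @return a `term_matching_table` data frame.
#' @export
create_term_matching_table <- function(instrument_list, origin_key,
                                       user_files = NULL) {
  if (length(instrument_list) == 0L) {
    ms_abort("instrument_list must be non-empty", "msgroupr_structure_error")
  }
  reg <- load_registries(user_files)
  origins <- sort(unique(reg$origin_key))
  if (!origin_key %in% origins) {
    ms_abort(sprintf("unknown origin_key '%s'; available: %s", origin_key,
                     paste(origins, collapse = ", ")),
             "msgroupr_unknown_origin_error")
  }
  reg <- reg[reg$origin_key == origin_key, , drop = FALSE]
  for (inst in setdiff(instrument_list, unique(reg$instrument))) {
    warning(sprintf("no '%s' terms for instrument '%s' in the registry",
                    origin_key, inst), call. = FALSE)
  }
  out <- reg[reg$instrument %in% instrument_list, , drop = FALSE]
  out <- out[order(out$display_order, out$term_label, method = "radix"), ,
             drop = FALSE]
  rownames(out) <- NULL
  structure(out, class = c("term_matching_table", "data.frame"))
}

## ---- matching -------------------------------------------------------------

# Resolve one term against a flat table: exact path match wins; otherwise
# the source_path is treated as a path suffix (covers instrument-class
# layout variants).  Multiple suffix hits with one common value collapse;
# conflicting values are an ambiguity error.
resolve_term <- function(flat, source_path) {
  exact <- which(flat$path == source_path)
  if (length(exact) > 0L) return(flat$value[exact[1]])
  hits <- which(endsWith(flat$path, paste0("/", source_path)))
  if (length(hits) == 0L) return(NULL)
  vals <- unique(flat$value[hits])
  if (length(vals) > 1L) {
    ms_abort(sprintf(
      "term path '%s' matches multiple paths with different values: %s",
      source_path, paste(flat$path[hits], collapse = "; ")),
      "msgroupr_ambiguous_term_error")
  }
  vals
}

#' Reduce flattened groups to guideline-specific report tables
#'
#' For each group, resolves every term of the matching table against the
#' group's flat table (exact path match first, then path-suffix match)
#' and arranges the results by display order.  Required terms with no
#' match appear with the `"(not recorded)"` marker — publication tables
#' must show gaps explicitly — while optional unmatched terms are
#' dropped.
#'
#' @param flat_tables list of `flat_table`s (see [flatten_collection()]),
#'   or a `grouped_collection`.
#' @param tmt a `term_matching_table`.
#' @return list of `group_report`s: data frames with columns
#'   `term_label`, `value`, attributes `group_id` and `file_names`.
#' @export
match_terms <- function(flat_tables, tmt) {
  if (inherits(flat_tables, "grouped_collection")) {
    flat_tables <- flatten_collection(flat_tables)
  }
  if (inherits(flat_tables, "flat_table")) flat_tables <- list(flat_tables)
  lapply(flat_tables, function(flat) {
    labels <- character()
    values <- character()
    for (i in seq_len(nrow(tmt))) {
      v <- resolve_term(flat, tmt$source_path[i])
      if (is.null(v)) {
        if (!tmt$required[i]) next
        v <- NOT_RECORDED
      }
      labels <- c(labels, tmt$term_label[i])
      values <- c(values, v)
    }
    structure(data.frame(term_label = labels, value = values,
                         stringsAsFactors = FALSE),
              class = c("group_report", "data.frame"),
              group_id = attr(flat, "group_id"),
              file_names = attr(flat, "file_names"))
  })
}
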