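## Export of group reports: tab-delimited text (one file per group),
## a spreadsheet workbook (one sheet per group plus a file/group index
## sheet), and JSON.  TSV bytes are deterministic given identical input.

#' Save all group reports
#'
#' Writes, per group, `group_<id>.txt` (UTF-8, LF line endings, two
#' columns `term_label` TAB `value`, no quoting; tab characters inside
#' values are replaced by single spaces with a warning) and/or one
#' workbook `groups.xlsx` with a `group_<id>` sheet per group and a
#' `files` sheet mapping each file name to its group id, and/or
#' `reports.json`.
#'
#' @param reports list of `group_report`s (see [match_terms()]).
#' @param out_dir output directory (created if missing).
#' @param formats subset of `c("tsv", "xlsx", "json")`.
#' @param force overwrite existing files (default errors on collision).
#' @return character vector of written paths, invisibly.
#' @export
save_all_groups <- function(reports, out_dir, formats = "tsv",
                            force = FALSE) {
  if (!is.list(reports) || length(reports) == 0L) {
    ms_abort("reports must be a non-empty list", "msgroupr_structure_error")
  }
  if (inherits(reports, "group_report")) reports <- list(reports)
  formats <- match.arg(formats, c("tsv", "xlsx", "json"), several.ok = TRUE)
  if (!dir.exists(out_dir)) dir.create(out_dir, recursive = TRUE)
  ids <- vapply(reports, function(r) as.integer(attr(r, "group_id")),
                integer(1))
  targets <- character()
  if ("tsv" %in% formats) {
    targets <- c(targets, file.path(out_dir, sprintf("group_%d.txt", ids)))
  }
  if ("xlsx" %in% formats) targets <- c(targets,
                                        file.path(out_dir, "groups.xlsx"))
  if ("json" %in% formats) targets <- c(targets,
                                        file.path(out_dir, "reports.json"))
  existing <- targets[file.exists(targets)]
  if (length(existing) > 0L && !force) {
    ms_abort(sprintf("output exists (use force = TRUE): %s",
                     paste(basename(existing), collapse = ", ")),
             "msgroupr_io_error")
  }
  written <- character()
  for (i in seq_along(reports)) {
    rep <- sanitize_report(reports[[i]])
    if ("tsv" %in% formats) {
      p <- file.path(out_dir, sprintf("group_%d.txt", ids[i]))
      write_utf8(paste(rep$term_label, rep$value, sep = "\t"), p)
      written <- c(written, p)
    }
    reports[[i]] <- rep
  }
  if ("xlsx" %in% formats) {
    p <- file.path(out_dir, "groups.xlsx")
    write_reports_xlsx(reports, p)
    written <- c(written, p)
  }
  if ("json" %in% formats) {
    p <- file.path(out_dir, "reports.json")
    rep_json <- vapply(seq_along(reports), function(i) {
      rows <- paste0(
        "      {\"Term\": ",
        vapply(reports[[i]]$term_label, json_escape_string, character(1)),
        ", \"Value\": ",
        vapply(reports[[i]]$value, json_escape_string, character(1)), "}")
      fns <- attr(reports[[i]], "file_names")
      paste0(
        "{\n    \"GroupId\": ", ids[i], ",\n    \"FileNames\": [",
        paste(vapply(as.character(fns %||% character()), json_escape_string,
                     character(1)), collapse = ", "),
        "],\n    \"Rows\": [\n",
        paste(rows, collapse = ",\n"), "\n    ]\n  }")
    }, character(1))
    write_utf8(paste0("[\n  ", paste(rep_json, collapse = ",\n  "), "\n]"),
               p)
    written <- c(written, p)
  }
  invisible(written)
}

# Replace tabs in values (they would corrupt the two-column layout).
sanitize_report <- function(rep) {
  has_tab <- grepl("\t", rep$value, fixed = TRUE) |
    grepl("\t", rep$term_label, fixed = TRUE)
  if (any(has_tab)) {
    warning(sprintf("%d report value(s) contained tab characters; replaced by spaces",
                    sum(has_tab)), call. = FALSE)
    rep$value <- gsub("\t", " ", rep$value, fixed = TRUE)
    rep$term_label <- gsub("\t", " ", rep$term_label, fixed = TRUE)
  }
  rep
}

#' Re-import a group report written as tab-delimited text
#'
#' Inverse of the TSV branch of [save_all_groups()] (modulo the
#' documented tab substitution).
#'
#' @param path path to a `group_<id>.txt` file.
#' @return data frame with columns `term_label`, `value`.
#' @export
read_group_table <- function(path) {
  lines <- read_utf8(path)
  parts <- strsplit(lines, "\t", fixed = TRUE)
  bad <- which(vapply(parts, length, integer(1)) != 2L)
  if (length(bad) > 0L) {
    ms_abort(sprintf("line %d of %s is not two tab-separated columns",
                     bad[1], path), "msgroupr_validation_error")
  }
  data.frame(term_label = vapply(parts, `[[`, character(1), 1),
             value = vapply(parts, `[[`, character(1), 2),
             stringsAsFactors = FALSE)
}

## ---- minimal xlsx writer --------------------------------------------------
##
## A workbook is a zip of XML parts; reports are small two-column tables,
## so inline strings and a single bold header style suffice.  Content,
## not cosmetics.

xml_escape <- function(s) {
  s <- gsub("&", "&amp;", s, fixed = TRUE)
  s <- gsub("<", "&lt;", s, fixed = TRUE)
  gsub(">", "&gt;", s, fixed = TRUE)
}

xlsx_sheet_xml <- function(df, header) {
  cell <- function(row, col, text, style) {
    ref <- paste0(LETTERS[col], row)
    sprintf('<c r="%s" s="%d" t="inlineStr"><is><t xml:space="preserve">%s</t></is></c>',
            ref, style, xml_escape(enc2utf8(text)))
  }
  rows <- character()
  rows <- c(rows, paste0('<row r="1">',
                         paste(vapply(seq_along(header), function(j) {
                           cell(1L, j, header[j], 1L)
                         }, character(1)), collapse = ""), "</row>"))
  for (i in seq_len(nrow(df))) {
    rows <- c(rows, paste0(sprintf('<row r="%d">', i + 1L),
                           paste(vapply(seq_len(ncol(df)), function(j) {
                             cell(i + 1L, j, as.character(df[i, j]), 0L)
                           }, character(1)), collapse = ""), "</row>"))
  }
  paste0('<?xml version="1.0" encoding="UTF-8" standalone="yes"?>\n',
         '<worksheet xmlns="http://schemas.openxmlformats.org/spreadsheetml/2006/main">',
         "<sheetData>", paste(rows, collapse = ""), "</sheetData></worksheet>")
}

write_reports_xlsx <- function(reports, path) {
  ids <- vapply(reports, function(r) as.integer(attr(r, "group_id")),
                integer(1))
  sheets <- lapply(reports, function(r) {
    df <- data.frame(r$term_label, r$value, stringsAsFactors = FALSE)
    names(df) <- c("term", "value")
    df
  })
  sheet_names <- sprintf("group_%d", ids)
  files_df <- do.call(rbind, lapply(seq_along(reports), function(i) {
    fns <- attr(reports[[i]], "file_names")
    if (is.null(fns) || length(fns) == 0L) return(NULL)
    data.frame(file_name = fns, group_id = ids[i], stringsAsFactors = FALSE)
  }))
  if (is.null(files_df)) {
    files_df <- data.frame(file_name = character(), group_id = integer())
  }
  sheets <- c(sheets, list(files_df))
  sheet_names <- c(sheet_names, "files")
  headers <- c(lapply(ids, function(...) c("term", "value")),
               list(c("file_name", "group_id")))

  tmp <- tempfile("xlsx_")
  dir.create(file.path(tmp, "_rels"), recursive = TRUE)
  dir.create(file.path(tmp, "xl", "_rels"), recursive = TRUE)
  dir.create(file.path(tmp, "xl", "worksheets"), recursive = TRUE)
  n <- length(sheets)
  sheet_overrides <- paste(sprintf(
    '<Override PartName="/xl/worksheets/sheet%d.xml" ContentType="application/vnd.openxmlformats-officedocument.spreadsheetml.worksheet+xml"/>',
    seq_len(n)), collapse = "")
  write_utf8(paste0(
    '<?xml version="1.0" encoding="UTF-8" standalone="yes"?>\n',
    '<Types xmlns="http://schemas.openxmlformats.org/package/2006/content-types">',
    '<Default Extension="rels" ContentType="application/vnd.openxmlformats-package.relationships+xml"/>',
    '<Default Extension="xml" ContentType="application/xml"/>',
    '<Override PartName="/xl/workbook.xml" ContentType="application/vnd.openxmlformats-officedocument.spreadsheetml.sheet.main+xml"/>',
    '<Override PartName="/xl/styles.xml" ContentType="application/vnd.openxmlformats-officedocument.spreadsheetml.styles+xml"/>',
    sheet_overrides, "</Types>"),
    file.path(tmp, "[Content_Types].xml"))
  write_utf8(paste0(
    '<?xml version="1.0" encoding="UTF-8" standalone="yes"?>\n',
    '<Relationships xmlns="http://schemas.openxmlformats.org/package/2006/relationships">',
    '<Relationship Id="rId1" Type="http://schemas.openxmlformats.org/officeDocument/2006/relationships/officeDocument" Target="xl/workbook.xml"/>',
    "</Relationships>"),
    file.path(tmp, "_rels", ".rels"))
  sheet_entries <- paste(sprintf(
    '<sheet name="%s" sheetId="%d" r:id="rId%d"/>',
    xml_escape(sheet_names), seq_len(n), seq_len(n)), collapse = "")
  write_utf8(paste0(
    '<?xml version="1.0" encoding="UTF-8" standalone="yes"?>\n',
    '<workbook xmlns="http://schemas.openxmlformats.org/spreadsheetml/2006/main" ',
    'xmlns:r="http://schemas.openxmlformats.org/officeDocument/2006/relationships">',
    "<sheets>", sheet_entries, "</sheets></workbook>"),
    file.path(tmp, "xl", "workbook.xml"))
  rels <- paste(sprintf(
    '<Relationship Id="rId%d" Type="http://schemas.openxmlformats.org/officeDocument/2006/relationships/worksheet" Target="worksheets/sheet%d.xml"/>',
    seq_len(n), seq_len(n)), collapse = "")
  rels <- paste0(rels, sprintf(
    '<Relationship Id="rId%d" Type="http://schemas.openxmlformats.org/officeDocument/2006/relationships/styles" Target="styles.xml"/>',
    n + 1L))
  write_utf8(paste0(
    '<?xml version="1.0" encoding="UTF-8" standalone="yes"?>\n',
    '<Relationships xmlns="http://schemas.openxmlformats.org/package/2006/relationships">',
    rels, "</Relationships>"),
    file.path(tmp, "xl", "_rels", "workbook.xml.rels"))
  write_utf8(paste0(
    '<?xml version="1.0" encoding="UTF-8" standalone="yes"?>\n',
    '<styleSheet xmlns="http://schemas.openxmlformats.org/spreadsheetml/2006/main">',
    '<fonts count="2"><font><sz val="11"/><name val="Calibri"/></font>',
    '<font><b/><sz val="11"/><name val="Calibri"/></font></fonts>',
    '<fills count="1"><fill><patternFill patternType="none"/></fill></fills>',
    '<borders count="1"><border/></borders>',
    '<cellStyleXfs count="1"><xf/></cellStyleXfs>',
    '<cellXfs count="2"><xf fontId="0"/><xf fontId="1" applyFont="1"/></cellXfs>',
    "</styleSheet>"),
    file.path(tmp, "xl", "styles.xml"))
  for (i in seq_len(n)) {
    write_utf8(xlsx_sheet_xml(sheets[[i]], headers[[i]]),
               file.path(tmp, "xl", "worksheets",
                         sprintf("sheet%d.xml", i)))
  }
  if (file.exists(path)) unlink(path)
  target <- file.path(normalizePath(dirname(path)), basename(path))
  zip::zip(target, files = c("[Content_Types].xml", "_rels", "xl"),
           root = tmp, recurse = TRUE, include_directories = FALSE,
           mode = "mirror")
  unlink(tmp, recursive = TRUE)
  invisible(path)
}
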