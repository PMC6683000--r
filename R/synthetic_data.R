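## Seeded generator of synthetic acquisition-metadata collections.
##
## Emulates what a core facility sees: hundreds of per-file metadata
## records deriving from a small number of underlying instrument-method
## templates, with file-specific header fields (name, date, sample
## information) varying per file and, optionally, injected parameter
## drift.  Drift persists from its event index onward (a step change --
## the scenario in which an instrument setting is altered mid-series and
## stays altered); a point glitch can be modelled by a pair of events.
##
## Bundled templates approximate a Q Exactive class mass spectrometer
## ("Q Exactive - Orbitrap_MS") coupled to an EASY-nLC class LC
## ("Thermo EASY-nLC") in name and rough parameter vocabulary; all
## values are invented.

#' Bundled template identifiers
#' @return character vector of available template ids.
#' @export
template_ids <- function() sprintf("qex_nlc_%d", 1:6)

# Variant-specific settings; each variant differs from every other in at
# least the collision energy, so any subset of templates yields pairwise
# distinct parameter trees.
template_variant <- function(k) {
  stopifnot(k >= 1L, k <= 6L)
  list(
    nce = c(27, 25, 28, 30, 26, 32)[k],
    ms1_resolution = c(70000, 70000, 140000, 70000, 35000, 70000)[k],
    top_n = c(10L, 10L, 10L, 15L, 12L, 20L)[k],
    gradient_mid_b = c(38, 35, 38, 40, 38, 38)[k],
    gradient_end = c(60, 90, 60, 120, 60, 45)[k]
  )
}

ms_template_instrument <- function(k) {
  v <- template_variant(k)
  instrument_metadata(
    model = "Q Exactive - Orbitrap_MS",
    module_type = "MS",
    parameters = list(
      Tune = list(
        "Spray voltage (kV)" = 2.1,
        "Capillary temperature (C)" = 275,
        "S-lens RF level" = 50.0
      ),
      Method = list(
        Polarity = "positive",
        "Full MS" = list(
          Resolution = v$ms1_resolution,
          "AGC target" = 3e6,
          "Maximum injection time (ms)" = 20,
          "Scan range (m/z)" = "300 to 1750",
          Microscans = 1L
        ),
        "dd-MS2" = list(
          Resolution = 17500,
          "AGC target" = 1e5,
          "Maximum injection time (ms)" = 60,
          "Isolation window (m/z)" = 1.6,
          "Normalized collision energy" = v$nce,
          TopN = v$top_n,
          "Dynamic exclusion (s)" = 20.0
        )
      ),
      Software = list(
        "Tune version" = "2.9.0.2926"
      )
    )
  )
}

lc_template_method_text <- function(k) {
  v <- template_variant(k)
  gp <- structure(list(
    steps = data.frame(
      time_min = c(0, 5, v$gradient_end, v$gradient_end + 5),
      duration_min = c(5, v$gradient_end - 5, 5, 5),
      flow_nl_min = c(300, 300, 300, 300),
      percent_b = c(5, v$gradient_mid_b, 95, 95)
    ),
    sample_volume_ul = 2.0,
    column_equilibration_ul = 4.0,
    unparsed = character()
  ), class = "gradient_program")
  render_lc_method(gp)
}

lc_template_instrument <- function(k, parse_method = FALSE) {
  text <- lc_template_method_text(k)
  params <- list(
    Properties = list(
      "Column length (cm)" = 50,
      "Column inner diameter (um)" = 75,
      "Mobile phase A" = "0.1% formic acid in water",
      "Mobile phase B" = "0.1% formic acid in 80% acetonitrile"
    )
  )
  inst <- instrument_metadata(model = "Thermo EASY-nLC",
                              module_type = "LC",
                              method_text = if (parse_method) NULL else text,
                              parameters = params)
  if (parse_method) {
    # gradient pre-parsed into the parameter tree (the representation
    # used when the record must also be expressible as mzML, which has
    # no method-string slot)
    gp <- parse_lc_method(text)
    inst$parameters[["Gradient"]] <- gradient_to_tree(gp)
    for (kk in names(gradient_extras(gp))) {
      inst$parameters[[kk]] <- gradient_extras(gp)[[kk]]
    }
  }
  inst
}

# Full template: list of instruments for a given template id.
build_template <- function(template_id, parse_method = FALSE) {
  k <- match(template_id, template_ids())
  if (is.na(k)) {
    ms_abort(sprintf("unknown template id '%s'; available: %s", template_id,
                     paste(template_ids(), collapse = ", ")),
             "msgroupr_structure_error")
  }
  list(lc_template_instrument(k, parse_method = parse_method),
       ms_template_instrument(k))
}

#' Specify a synthetic collection
#'
#' @param n_files number of acquisition files to emulate.
#' @param templates named positive numeric vector: template ids (see
#'   [template_ids()]) with sampling weights.
#' @param drift_events list of `list(file_index =, path =, value =)`:
#'   from `file_index` (1-based) onward, the leaf at `path` (slash-joined
#'   path into the merged parameter tree, first segment the instrument
#'   model) is replaced by `value`.  The replacement must differ from
#'   the template value.
#' @param seed integer seed; the emitted corpus is byte-identical for a
#'   given spec.
#' @param emit_formats subset of `c("json", "mzML")`; with `"mzML"`
#'   included, every record is emitted in each requested format and LC
#'   methods are pre-parsed into parameter trees for all formats (mzML
#'   has no method-string slot).
#' @return a `generator_spec`.
#' @export
generator_spec <- function(n_files, templates = c(qex_nlc_1 = 1),
                           drift_events = list(), seed = 1L,
                           emit_formats = "json") {
  if (!is.numeric(n_files) || n_files < 1L) {
    ms_abort("n_files must be a positive integer", "msgroupr_structure_error")
  }
  if (is.null(names(templates)) || any(templates <= 0)) {
    ms_abort("templates must be a named vector of positive weights",
             "msgroupr_structure_error")
  }
  for (id in names(templates)) {
    if (!id %in% template_ids()) {
      ms_abort(sprintf("unknown template id '%s'", id),
               "msgroupr_structure_error")
    }
  }
  emit_formats <- match.arg(emit_formats, c("json", "mzML"),
                            several.ok = TRUE)
  seen <- character()
  for (ev in drift_events) {
    if (!is.numeric(ev$file_index) || ev$file_index < 1L ||
        ev$file_index > n_files) {
      ms_abort("drift event file_index out of range",
               "msgroupr_structure_error")
    }
    key <- paste(ev$file_index, ev$path, sep = "\r")
    if (key %in% seen) {
      ms_abort(sprintf("conflicting drift events at index %d, path '%s'",
                       ev$file_index, ev$path), "msgroupr_structure_error")
    }
    seen <- c(seen, key)
  }
  structure(list(n_files = as.integer(n_files), templates = templates,
                 drift_events = drift_events, seed = as.integer(seed),
                 emit_formats = emit_formats),
            class = "generator_spec")
}

# Apply a drift event to a list of instruments.  The first path segment
# selects the instrument by model; the rest addresses its parameter tree.
apply_drift <- function(instruments, ev) {
  keys <- split_path(ev$path)
  if (length(keys) < 2L) {
    ms_abort(sprintf("drift path '%s' must address a parameter below an instrument",
                     ev$path), "msgroupr_structure_error")
  }
  hit <- FALSE
  for (i in seq_along(instruments)) {
    if (instruments[[i]]$model == keys[1]) {
      cur <- tree_get(instruments[[i]]$parameters, keys[-1],
                      missing = quote(missing))
      if (identical(cur, quote(missing))) {
        ms_abort(sprintf("drift path '%s' does not exist in the template",
                         ev$path), "msgroupr_structure_error")
      }
      if (identical(render_scalar(cur), render_scalar(ev$value))) {
        ms_abort(sprintf("drift value at '%s' equals the template value",
                         ev$path), "msgroupr_structure_error")
      }
      instruments[[i]]$parameters <-
        tree_set(instruments[[i]]$parameters, keys[-1], ev$value)
      hit <- TRUE
      break
    }
  }
  if (!hit) {
    ms_abort(sprintf("drift path '%s': no instrument '%s' in template",
                     ev$path, keys[1]), "msgroupr_structure_error")
  }
  instruments
}

#' Generate a synthetic metadata collection
#'
#' Writes `n_files` records (in each requested format) under `out_dir`
#' and returns the exact expected parameter-group partition as ground
#' truth, computed from the generating process itself: two files belong
#' to the same expected group iff they derive from the same template
#' with the same set of active drift events.
#'
#' @param spec a [generator_spec()].
#' @param out_dir output directory (created if needed).
#' @return list with `manifest` (a `collection_manifest`), `groups`
#'   (list of sorted file-name vectors, the ground-truth partition,
#'   ordered by first file name) and `spec`.
#' @export
generate_collection <- function(spec, out_dir) {
  if (!inherits(spec, "generator_spec")) {
    ms_abort("spec must be a generator_spec", "msgroupr_structure_error")
  }
  if (!dir.exists(out_dir)) dir.create(out_dir, recursive = TRUE)
  parse_method <- "mzML" %in% spec$emit_formats
  with_seed(spec$seed, function() {
    tpl_ids <- names(spec$templates)
    assignment <- if (length(tpl_ids) == 1L) {
      rep(tpl_ids, spec$n_files)
    } else {
      sample(tpl_ids, spec$n_files, replace = TRUE,
             prob = spec$templates / sum(spec$templates))
    }
    # ensure every template occurs at least once so K templates really
    # yield K groups
    if (length(tpl_ids) <= spec$n_files) {
      assignment[seq_along(tpl_ids)] <- tpl_ids
    }
    base_date <- as.POSIXct("2019-01-07 09:00:00", tz = "UTC")
    offsets <- cumsum(round(stats::runif(spec$n_files, 35, 180)))
    vials <- sprintf("%s%d", sample(LETTERS[1:8], spec$n_files, TRUE),
                     sample(1:12, spec$n_files, TRUE))
    sample_ids <- sprintf("S-%05d", sample(1:99999, spec$n_files))
    signatures <- character(spec$n_files)
    stems <- sprintf("run_%04d", seq_len(spec$n_files))
    written <- character()
    for (i in seq_len(spec$n_files)) {
      instruments <- build_template(assignment[i],
                                    parse_method = parse_method)
      active <- Filter(function(ev) ev$file_index <= i, spec$drift_events)
      for (ev in active) instruments <- apply_drift(instruments, ev)
      signatures[i] <- paste(
        assignment[i],
        paste(sort(vapply(active, function(ev) {
          paste(ev$file_index, ev$path, sep = "\r")
        }, character(1))), collapse = "\n"),
        sep = "\r\r")
      meta <- file_metadata(
        file_name = stems[i],
        acquired_date = format(base_date + offsets[i] * 60,
                               "%Y-%m-%dT%H:%M:%SZ"),
        sample_info = list("Sample id" = sample_ids[i], "Vial" = vials[i],
                           "Comment" = sprintf("injection %d", i)),
        instruments = instruments
      )
      if ("json" %in% spec$emit_formats) {
        fn <- paste0(stems[i], ".json")
        m <- meta
        m$file_name <- fn
        write_native_json(m, file.path(out_dir, fn))
        written <- c(written, fn)
      }
      if ("mzML" %in% spec$emit_formats) {
        fn <- paste0(stems[i], ".mzML")
        m <- meta
        m$file_name <- fn
        write_synthetic_mzml(m, file.path(out_dir, fn))
        written <- c(written, fn)
      }
    }
    # ground-truth partition over all emitted file names (a record
    # emitted in both formats contributes both names to its group)
    exts <- ifelse(spec$emit_formats == "json", ".json", ".mzML")
    per_file_name <- as.vector(t(outer(stems, exts, paste0)))
    per_file_sig <- rep(signatures, each = length(exts))
    groups <- lapply(unique(per_file_sig), function(s) {
      sort(per_file_name[per_file_sig == s], method = "radix")
    })
    groups <- groups[order(vapply(groups, `[[`, character(1), 1),
                           method = "radix")]
    list(manifest = scan_collection(out_dir), groups = groups, spec = spec)
  })
}

## ---- synthetic mzML emission ---------------------------------------------

# Minimal valid mzML 1.1 carrying only header metadata: sample, two
# instrument configurations (parameters as userParams with path-style
# names), an empty spectrum list.  Synthetic by construction; never a
# stand-in for vendor output.
write_synthetic_mzml <- function(meta, path) {
  esc <- function(s) {
    s <- xml_escape(s)
    gsub('"', "&quot;", s, fixed = TRUE)
  }
  param_lines <- function(tree, prefix = character(), indent = "        ") {
    out <- character()
    for (k in names(tree)) {
      v <- tree[[k]]
      if (is.list(v)) {
        out <- c(out, param_lines(v, c(prefix, k), indent))
      } else {
        out <- c(out, sprintf('%s<userParam name="%s" value="%s"/>',
                              indent, esc(join_path(c(prefix, k))),
                              esc(render_scalar(v))))
      }
    }
    out
  }
  cfgs <- character()
  for (i in seq_along(meta$instruments)) {
    inst <- meta$instruments[[i]]
    if (!is.null(inst$method_text)) {
      ms_abort("mzML emission requires pre-parsed LC methods (no method-string slot)",
               "msgroupr_structure_error")
    }
    cfgs <- c(cfgs,
      sprintf('      <instrumentConfiguration id="IC%d">', i),
      sprintf('        <userParam name="instrument model" value="%s"/>',
              esc(inst$model)),
      param_lines(inst$parameters),
      "      </instrumentConfiguration>")
  }
  sample_params <- vapply(names(meta$sample_info), function(k) {
    sprintf('      <userParam name="%s" value="%s"/>', esc(k),
            esc(meta$sample_info[[k]]))
  }, character(1))
  lines <- c(
    '<?xml version="1.0" encoding="utf-8"?>',
    '<mzML xmlns="http://psi.hupo.org/ms/mzml" version="1.1.0">',
    '  <cvList count="1">',
    '    <cv id="MS" fullName="Proteomics Standards Initiative Mass Spectrometry Ontology" URI="https://raw.githubusercontent.com/HUPO-PSI/psi-ms-CV/master/psi-ms.obo"/>',
    "  </cvList>",
    "  <fileDescription>",
    "    <fileContent/>",
    "  </fileDescription>",
    '  <sampleList count="1">',
    '    <sample id="SMP1" name="synthetic sample">',
    sample_params,
    "    </sample>",
    "  </sampleList>",
    '  <softwareList count="1">',
    '    <software id="SW1" version="0"/>',
    "  </softwareList>",
    sprintf('  <instrumentConfigurationList count="%d">',
            length(meta$instruments)),
    cfgs,
    "  </instrumentConfigurationList>",
    '  <dataProcessingList count="1">',
    '    <dataProcessing id="DP1">',
    '      <processingMethod order="0" softwareRef="SW1"/>',
    "    </dataProcessing>",
    "  </dataProcessingList>",
    sprintf('  <run id="R1" defaultInstrumentConfigurationRef="IC1"%s>',
            if (is.null(meta$acquired_date)) ""
            else sprintf(' startTimeStamp="%s"', esc(meta$acquired_date))),
    '    <spectrumList count="0" defaultDataProcessingRef="DP1"/>',
    "  </run>",
    "</mzML>")
  write_utf8(lines, path)
}
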