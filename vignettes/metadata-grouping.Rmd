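---
title: "Grouping mass-spectrometry acquisition metadata: model and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Grouping mass-spectrometry acquisition metadata: model and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(msgroupr)
```

## The problem

Proteomics and metabolomics experiments routinely produce hundreds of
acquisition files per study, each carrying the instrument settings it was
acquired with. Reporting guidelines (MIAPE, journal-specific requirements)
and repository submissions ask for those settings, but copying them from
individual files is tedious and error-prone — in practice metadata for a
whole data set is often taken from a single file, which hides *parameter
drift*: a setting that changed partway through a long acquisition series.

`msgroupr` addresses this by reducing a collection of per-file metadata
records to the **minimal set of parameter groups**: a partition of the
files such that two files share a group exactly when all their relevant
instrument settings agree. One group is the ideal outcome; more than one
group is itself a finding, and the pairwise group diff shows which
settings moved.

## Data model

Every instrument's settings are carried as a *parameter tree*: an ordered
mapping from string keys to scalar values (string, number, boolean, null)
or sub-trees. The tree abstracts over instrument-class specific layouts —
a tune file section, a method section, LC properties — without the package
needing to know any of them.

A *per-file record* (`file_metadata()`) is a fixed header — file name,
acquisition timestamp, sample information — plus an ordered list of
instrument modules (`instrument_metadata()`), each with a model name, a
module class (MS/LC/OTHER), an optional verbatim method string, and a
parameter tree.

## Grouping by content hash

Grouping proceeds in three steps per file:

1. **Strip file-specific fields.** `strip_file_specific()` merges all
   instruments' parameter trees into one tree keyed by instrument model
   and drops the header fields (file name, date, sample information) —
   exactly the fields that legitimately differ between technical
   replicates of one method. The exclusion is user-extensible
   (`exclude_paths`) because instrument logs can embed per-run values
   (e.g. tune-file paths, timestamps) that no fixed list can anticipate.
   The module-class tag is treated as a classification, not an acquisition
   parameter, and does not participate in hashing; the model name itself
   participates through an injected `"Instrument model"` leaf.
2. **Canonical serialization.** `canonical_serialize()` renders the tree
   as compact JSON with keys NFC-normalized and sorted by Unicode code
   point at every level, and scalars rendered by a fixed rule: integers as
   plain decimal text, decimals by the shortest digit string that
   round-trips through binary floating point, booleans as `true`/`false`,
   null as `null`. Two consequences are deliberate: insertion order never
   matters, and the integer `300` hashes identically to the double
   `300.0` (required for consistency with mzML, whose parameter values
   are untyped text). Strings are compared byte-wise after NFC
   normalization with **no case folding** — `"Full MS"` and `"full ms"`
   plausibly denote different vendor labels, and guessing would be worse
   than splitting a group.
3. **Hashing.** `content_hash()` takes the SHA-256 of those bytes. At any
   realistic collection size the collision risk is negligible, and the
   test suite asserts, over tens of thousands of generated tree pairs,
   that hash equality and deep structural equality coincide in both
   directions.

Groups are numbered by first occurrence in lexicographic file-name order
and member lists are sorted, so the output is identical across input
orderings, platforms and worker counts. Duplicate sibling keys anywhere in
an input document are a hard error rather than last-wins: silently losing
a parameter would defeat the tool's purpose. Files that fail to read are
excluded from grouping but always listed in the `Failed` section of the
grouped JSON — one corrupt file must not abort a 300-file report, and
silent omission is unacceptable.

Grouping is strict: `35.0` and `35.000001` minutes are different
settings. Tolerance-based grouping is out of scope by design; it would
turn a reproducible partition into a threshold choice.

## Input formats

Two readers produce per-file records:

* **Native JSON dialect** (`read_native_json()` / `write_native_json()`):
  an open per-file document — `FileName`, `AcquiredDate`, `SampleInfo`,
  `Instruments` with nested `Parameters` — validated structurally with
  JSON-pointer error paths. The schema is shipped under
  `inst/extdata/schemas/`. Writing is deterministic, so a document
  round-trips bit-identically through read–write.
* **mzML headers** (`read_mzml_metadata()`): only the header sections of
  an mzML 1.1 document are read (`indexedmzML` wrappers accepted);
  spectra are never touched. Each `instrumentConfiguration` becomes one
  instrument; `cvParam`/`userParam` entries become leaves keyed by term
  name with the CV accession kept as a `"<name>@accession"` sibling, so
  reports stay human-readable without losing term identity. Because
  mzML's parameter model is flat, a `userParam` name containing `/` is
  interpreted as a tree path; and because mzML values are untyped strings,
  they are re-typed by syntax (integer/decimal/boolean patterns). mzML has
  no slot for vendor method strings or status logs; records that must be
  expressible in both formats therefore carry the LC gradient as
  parameters rather than as method text.

A decimal leaf's original source text is not retained separately: numbers
re-render by the shortest round-trip rule, which makes
serialize–parse–serialize idempotent and is the property canonicalization
actually needs.

## LC method parsing

EASY-nLC class instruments store their gradient program inside a method
string. The vendor's exact formatting is not publicly documented, so the
package defines an explicit, testable line dialect:

```
Gradient:
  <time_min> / <duration_min> / <flow_nl_min> / <percent_B>
  ...
Sample pickup: <v> µl
Equilibration: <v> µl
```

`parse_lc_method()` enforces the physics of the program — times strictly
increasing from 0, %B in [0, 100], positive flow — and rejects
comma-decimal numbers outright (a silently misread `5,5` is a 10× error;
rejection is cheaper). Lines outside the dialect are never dropped: they
ride along verbatim in an `unparsed` remainder so they still participate
in grouping. A parser registry keyed by instrument model is the extension
point for real vendor dialects. `attach_gradient()` folds the parsed
program into the parameter tree (`Gradient/00`, `Gradient/01`, … with
zero-padded keys) so a single changed %B step splits a group; if a method
fails to parse the instrument is left unchanged with a warning, and the
verbatim method string still participates in hashing as a leaf.

## Reporting

`flatten_group()` turns a shared tree into a two-column path/value table
(depth-first, sorted keys). The separator is `/`, with literal `/` and
`\` in keys backslash-escaped, so flattening is lossless for every tree
and `unflatten_table()` inverts it exactly.

A *term-matching table* defines a reporting guideline: rows of
(origin key, instrument, term label, source path, display order,
required). The bundled `miape` and `jpr` registries are re-derived from
the MIAPE-MS guideline vocabulary and are deliberately not claimed to be
byte-compatible with any other tool's tables; user TSV files can extend
or override them row by row. `match_terms()` resolves each term by exact
path first, then by path-suffix match — one row can cover layout variants
across instrument classes — and an ambiguous suffix (several paths,
conflicting values) is an error listing the candidates rather than a
silent pick. Required terms with no match appear as `"(not recorded)"`:
publication tables must show gaps explicitly. Optional terms with no
match are omitted, which is what "optional" means for a gradient field
that a given instrument class does not expose.

`save_all_groups()` writes per-group tab-delimited text (UTF-8, LF,
deterministic bytes; tabs inside values become spaces with a warning),
a spreadsheet workbook with one sheet per group plus a file/group index
sheet (content only — a bold header row is the entire styling budget),
and/or a JSON rendering. File names use the stable group id
(`group_1.txt`), which is human-citable in a manuscript.

## The synthetic-data generator

`generate_collection()` emulates the realistic shape of a core-facility
collection: many files deriving from a small number of instrument-method
templates, with per-file header fields varying and optional injected
drift. Six bundled templates approximate a Q Exactive class instrument
coupled to an EASY-nLC in naming and parameter vocabulary; every value is
invented. Each template differs from every other in at least the
normalized collision energy, so any subset yields pairwise distinct
trees; when several templates are requested, each is forced to occur at
least once so the expected group count is exact.

Drift persists from its (1-based) `file_index` onward — a step change,
the scenario in which a setting is altered mid-series and never reset; a
point glitch is a pair of events. The generator validates that a drift
value actually differs from what it replaces, and returns the expected
partition computed from the generating process itself (template identity
plus active drift set), *not* from the package's hashing — this
independence is what makes the generator/grouper agreement a real test.
Everything is reproducible: the same seed yields a byte-identical corpus.

What the generator does **not** emulate: vendor tune-file statistics,
status-log readbacks, real EASY-nLC method formatting, or mixed-vendor
collections. Tests passing on synthetic corpora therefore demonstrate the
correctness of the reduction machinery, not coverage of every vendor
layout quirk; the term registry and parser registry are the adaptation
points for real data.

## Command line and configuration

`exec/msgroupr` exposes `group`, `report`, `diff` and `simulate`
subcommands over the same functions (`msgroupr_main()`). Config files are
YAML with one key per flag; explicit flags win. `--jobs` parallelizes
per-file ingestion only — the partition step is a deterministic reduce,
so output bytes are identical across worker counts (the workbook is
exempt from byte identity only because zip archives embed timestamps;
its content is compared instead).

## Problem sizes and numerical choices

The shipped test suite exercises corpora up to 500 files against an
O(N²) all-pairs deep-equality oracle and about 10⁴ random tree pairs for
the hash/equality equivalence property; both complete in well under a
minute on a single core, which is also the scale at which the package is
expected to run interactively. Degenerate inputs are defined, not
accidental: a record with no instruments strips to the empty tree (and
groups with other empty records); an empty input collection is an
explicit error, never an empty success.
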