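---
title: "Storing multi-omic layers in single-file stacks: design and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Storing multi-omic layers in single-file stacks: design and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(omistack)
```

## The problem

A multi-omic study produces several tabular datasets of very different
shapes: a small cohort table (samples as rows), wide feature matrices
(metabolite abundances, gene counts, microbial taxa), and very long
variant tables parsed from VCF. During analysis these are stored,
re-read, annotated, extended row- and column-wise, and joined —
constantly. General matrix containers handle the reading well but not
mixed column types, transactional safety, or incremental extension;
client–server databases handle those but sacrifice portability.
`omistack` targets the middle ground: every layer of a study lives in
**one** embedded single-file SQL database (the *stack*), with a small,
fixed API for the repetitive operations, so the user never writes SQL
and the whole study is distributed by copying one file.

## Two engines, one contract

Storage goes through an engine-agnostic contract
(`create_table`/`append_rows`/`add_columns`/`read_table`/`read_columns`/
`read_where`/`drop_table`/`list_tables`/`table_schema`) with two
implementations on the SQLite file format, chosen for its ubiquity,
ACID transactions and true single-file storage:

* the **rowstore** maps each layer to one row-oriented SQL table — the
  layout that favours frequent small transactions;
* the **columnstore** decomposes each layer into one physical
  single-column table per logical column plus a schema registry. A
  column scan then touches only that column's storage and a column
  addition writes a fresh physical table instead of rewriting rows —
  the access pattern that makes column-oriented engines fast on omic
  matrices.

Both engines therefore present genuinely different physical layouts and
performance profiles behind identical semantics. The equivalence is not
assumed: the test suite replays randomized operation scripts
(store/extend/annotate/query/drop) on both engines and requires
value-identical reads and catalogues, and the round-trip property suite
runs every generated table through both.

### Types, order, and NULLs

Columns have one of three kinds — `integer` (stored as 64-bit SQL
integers), `real` (IEEE doubles, so values round-trip without precision
change), `text` (variable-length strings) — recorded in a registry so
reads restore exact R types regardless of SQLite's dynamic typing.
Missing values in any kind are SQL `NULL`. Integer values widen into
real columns and whole-valued doubles narrow into integer columns; any
lossy coercion (text into a numeric column, fractional into integer)
raises *before* a write, and every `append_rows` call is a single
transaction, so a rejected chunk changes the observable row count by
zero.

SQL tables are unordered, but positional column extension requires a
stable row order. Both engines guarantee it with the implicit monotone
insertion-order rowid: rows are never deleted in place (a layer is
dropped whole), so `ORDER BY rowid` *is* insertion order. In the
columnstore, appends write all column tables in the same transaction
and order, which keeps rowids aligned across a layer's physical
columns.

Identifiers are quoted everywhere, so feature IDs with dots and dashes
(`HMDB-0001.v2`) are legal column names; names opening with an
underscore are reserved for the internal catalogue tables and rejected.

### The catalogue

Layer metadata (name, one tag string, description) lives in a reserved
table `_layers_meta` inside the same database file — keeping the stack
a single portable file. Store and drop update table and catalogue
together; the consistency invariant `set(tables) == set(catalogue)` is
asserted by tests after random operation scripts. A tag is one string
per layer (sufficient for grouping, e.g. `"metabolomics"` across blood
and urine layers); richer many-tag schemes were deliberately left out.

Row extension aligns by column **name** (append semantics; a reordered
data.frame is fine), while column extension aligns **positionally**
with strict length equality — mirroring SQL's INSERT vs ALTER-ADD
semantics. `join_layers()` is a convenience inner equi-join, reduced
left-to-right with duplicate non-key names suffixed `.k` by the
right-hand layer's position; anything fancier belongs in the caller's
data-frame tooling.

## The VCF layer

VCF files are ingested streaming: the header is parsed first (so a
malformed header fails before any write), then data lines are read in
chunks — 100,000 lines by default — each chunk appended in its own
transaction. The layer content is a pure function of the file content,
not of the chunk size, which the tests check down to `chunk_size = 1`.
An ingest interrupted by a malformed line keeps the chunks already
committed and reports the offending line number.

Fixed columns are stored as raw text except `pos` (integer, 1-based as
in the standard; no interval conversion anywhere), one text column per
sample holds the full sample field (`"0|1:0.98"`), and INFO/FORMAT are
never expanded into typed columns: queries here are by position and
sample, and raw storage buys byte-fidelity — tab-joining a stored row
reproduces the input line exactly, which is the property the tests
assert. Contig names are stored verbatim; `"chr1"` and `"1"` are
different contigs. gzip input is detected from the two magic bytes,
not the filename. The `##` meta-header is preserved in the layer
description (truncated at 65,000 characters — beyond any realistic
header — rather than kept in a second table, preserving the
one-table-per-layer model), so a layer can be re-exported as VCF text.

`run_query_batch()` executes read-only position queries with forked
workers, each opening its own connection (single-writer,
many-reader is the stack's concurrency contract; parallel batches must
not run against a concurrent writer). Results are returned in query
order and are asserted identical to sequential execution; per-query
failures are returned as condition objects without aborting the batch.

## What the synthetic generator emulates

The generator reproduces the shape of a 100-sample multi-omic study
and is the fixture source for the entire test suite:

* `cohort`: sample IDs `S001…`, gender uniform over F/M (no
  distribution is specified for gender in the study design the
  generator emulates, so uniform is the documented choice), integer
  ages uniform on [20, 50], BMI uniform on [20, 40] rounded to exactly
  2 decimals;
* feature matrices (features as rows, samples as columns — the
  orientation that favours column scans): uniform on [0, 1000], with
  4-decimal reals for metabolite abundances and integers for RNA-seq
  and microbiome counts;
* placeholder feature IDs (`HMDB-SYN-000001`, `ENSG-SYN-000001`,
  `SPEC-SYN-000001`): deterministic stand-ins for real catalogue
  identifiers, which can be supplied as plain ID vectors instead —
  nothing is ever downloaded;
* synthetic VCF: per contig, positions run contiguously from 100,000;
  REF/ALT uniform distinct single bases; QUAL `"."`, FILTER `"PASS"`;
  genotypes uniform over the phased set `0|0, 0|1, 1|0, 1|1` (imputed
  cohort data are typically phased; an unphased option is provided);
  INFO carries two representative uniform-real metrics, a
  variant-quality-like `QD` on [0, 100] and an imputation-accuracy-like
  `R2` on [0, 1], standing in for caller/imputation pipeline metrics.

Every generator is a pure function of its spec and seed.

What the generator does **not** emulate: linkage structure or realistic
allele frequencies, correlated features, batch effects, missingness
patterns, or single-cell sparse matrices (excluded deliberately —
sparse single-cell storage is well served elsewhere and would duplicate
it). Passing tests therefore demonstrate the *management* contract —
typed round-trips, ordering, transactional behaviour, query
correctness — on realistically shaped data, not statistical properties
of real cohorts.

## Benchmark harness and the scaling regression

`run_benchmark()` times store / retrieve / column-extension / row-query
cells across payload sizes and engines, with payloads deterministic per
cell and identical across engines. Size is the payload's in-memory
footprint in MB; disk size is deliberately not used. Chunked VCF
ingestion is excluded from the scaling grid because its runtime is
dominated by per-chunk disk transactions rather than payload size.
Absolute runtimes are never asserted anywhere — they are
hardware-bound; the harness exists to *summarise* scaling.

The summary statistic is least squares through the origin,
$\hat\beta = \sum x_i y_i / \sum x_i^2$: runtime grows from zero with
data size, so the no-intercept model is the natural one-parameter
summary (reported as ms/MB). The standard error uses an $n-1$
denominator — the model estimates a single parameter — and the 95%
interval uses the t quantile on $n-1$ df. Since no reference formula
was fixed for the interval, a simulation is the arbiter: over 1,000
replicates of $y = \beta x + \varepsilon$ the interval covers the true
slope at 0.95 (±0.02 asserted). Raw repeat timings all enter the fit;
they are not averaged per size point first, which would discard
replicate variance.

Desk scales used by the default suite: property tables up to ~120 rows
× 10 columns (200 of them per engine), a 10,000-line VCF for chunk
invariance, 297-query parallel batches on a 400-variant layer, and
sub-MB benchmark payloads. Full study-scale sizes (millions of variant
rows) remain reachable through the same API by configuration.

## Numerical and degenerate-input choices

* Real values are stored as IEEE doubles; round-trips are exact at full
  precision, not merely 15 significant digits.
* Empty tables (0 rows) round-trip with full schema and types; 0-row
  appends and 0-column extensions are identities.
* Filters use SQL `IN` semantics: `NULL` never matches, and the value
  set must be non-empty (an empty set is an error, not an empty
  result, to catch caller bugs).
* `read_where`/`select_rows` preserve stored order; set-membership
  queries on `pos` compare integers, never strings.
* Tag queries sort names in C-locale (radix) order for
  locale-independent determinism.

## Known limitations

Single writer at a time (no cross-process write locking); no secondary
indexes (retrieval on the rowstore could be tuned with one at the cost
of extension speed — left to the user's own SQL if needed); no schema
migration or layer versioning; no server mode, and both engines scale
vertically only. The columnstore pays a per-column transaction overhead
on very small chunked appends — visible at `chunk_size = 1` — which is
the mirror image of its advantage on column scans.
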