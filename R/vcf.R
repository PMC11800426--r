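# VCF ingestion and querying. Data lines are stored verbatim: the nine
# fixed columns (POS as integer, the rest as text) plus one text column per
# sample, so tab-joining a stored row reproduces the input line
# byte-for-byte. INFO and FORMAT are deliberately kept as raw text —
# variant queries here are by position and sample, never by INFO key — and
# contig names are never normalised ("chr1" and "1" stay distinct).

VCF_FIXED_COLS <- c("chrom", "pos", "id", "ref", "alt", "qual", "filter", "info", "format")
VCF_HEADER_COLS <- c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER", "INFO", "FORMAT")
VCF_DESC_MAX <- 65000L  # header meta-lines kept in the layer description are truncated here

# gzip is detected from the two magic bytes, not the file extension
open_vcf_text <- function(path) {
  if (!file.exists(path)) omi_io_error(sprintf("no such file: %s", path))
  rb <- file(path, "rb")
  magic <- readBin(rb, "raw", n = 2L)
  close(rb)
  gz <- length(magic) == 2L && magic[1] == as.raw(0x1f) && magic[2] == as.raw(0x8b)
  if (gz) gzfile(path, "rt") else file(path, "rt")
}

# Reads meta-lines up to and including the #CHROM line; errors on a
# malformed header before anything is written.
parse_vcf_header <- function(con) {
  meta <- character(0)
  n_lines <- 0L
  repeat {
    line <- readLines(con, n = 1L)
    if (length(line) == 0L) {
      omi_parse_error("malformed VCF: no #CHROM header line found")
    }
    n_lines <- n_lines + 1L
    if (startsWith(line, "##")) {
      meta <- c(meta, line)
    } else if (startsWith(line, "#CHROM")) {
      fields <- strsplit(line, "\t", fixed = TRUE)[[1]]
      if (length(fields) < 9L || !identical(fields[1:9], VCF_HEADER_COLS)) {
        omi_parse_error("malformed VCF: #CHROM line does not carry the nine fixed columns")
      }
      return(list(meta = meta, samples = fields[-(1:9)], header_lines = n_lines))
    } else {
      omi_parse_error(sprintf("malformed VCF: unexpected line before #CHROM: '%s'",
                              substr(line, 1, 60)))
    }
  }
}

vcf_chunk_to_table <- function(lines, n_samples, sample_ids, first_line_no) {
  fields <- strsplit(lines, "\t", fixed = TRUE)
  lens <- lengths(fields)
  want <- 9L + n_samples
  if (any(lens != want)) {
    bad <- which(lens != want)[1]
    omi_ingest_error(sprintf(
      "malformed VCF data line %d: %d fields (expected %d)",
      first_line_no + bad - 1L, lens[bad], want))
  }
  m <- matrix(unlist(fields, use.names = FALSE), nrow = length(lines), byrow = TRUE)
  pos <- suppressWarnings(as.integer(m[, 2]))
  if (anyNA(pos)) {
    bad <- which(is.na(pos))[1]
    omi_ingest_error(sprintf("malformed VCF data line %d: non-integer POS '%s'",
                             first_line_no + bad - 1L, m[bad, 2]))
  }
  cols <- c(list(m[, 1]), list(pos), lapply(3:ncol(m), function(j) m[, j]))
  names(cols) <- c(VCF_FIXED_COLS, sample_ids)
  as.data.frame(cols, stringsAsFactors = FALSE, check.names = FALSE, optional = TRUE)
}

#' Ingest a VCF file into a layer, streaming in chunks
#'
#' The file (plain or gzip; detected by content, not extension) is read in
#' chunks of `chunk_size` data lines, each appended in its own transaction,
#' so the whole file never resides in memory and an interrupted ingestion
#' retains the chunks already committed. The resulting layer has the nine
#' fixed VCF columns (`chrom`, `pos` as integer, `id`, `ref`, `alt`,
#' `qual`, `filter`, `info`, `format`, all others text) plus one text
#' column per sample, named by the sample IDs of the `#CHROM` line. The
#' `##` meta-header is preserved in the layer description (truncated at
#' 65,000 characters).
#'
#' @param stack an `omi_stack`.
#' @param path VCF file, plain or gzip-compressed.
#' @param name layer name to create.
#' @param chunk_size positive number of data lines per transaction
#'   (default 100,000).
#' @param if_exists `"fail"` or `"replace"`.
#' @return total number of data lines stored (with attribute `chunks`,
#'   the number of transactions used).
#' @export
ingest_vcf <- function(stack, path, name, chunk_size = 100000L,
                       if_exists = c("fail", "replace")) {
  if_exists <- match.arg(if_exists)
  if (!is.numeric(chunk_size) || length(chunk_size) != 1L || chunk_size < 1) {
    omi_config_error("chunk_size must be a positive integer")
  }
  chunk_size <- as.integer(chunk_size)
  con <- open_vcf_text(path)
  on.exit(close(con), add = TRUE)
  hdr <- parse_vcf_header(con)
  kinds <- stats::setNames(
    c("text", "integer", rep("text", 7L + length(hdr$samples))),
    c(VCF_FIXED_COLS, hdr$samples))
  check_schema(kinds)
  if (nrow(meta_row(stack, name)) > 0L && if_exists == "fail") {
    omi_duplicate_error(sprintf("layer '%s' already exists", name))
  }
  create_table(stack$handle, name, kinds, if_exists = if_exists)
  desc <- paste(hdr$meta, collapse = "\n")
  if (nchar(desc) > VCF_DESC_MAX) desc <- substr(desc, 1L, VCF_DESC_MAX)
  DBI::dbExecute(stack$handle$con,
    "INSERT INTO \"_layers_meta\" (name, tag, description) VALUES (?, '', ?)
     ON CONFLICT(name) DO UPDATE SET description = excluded.description",
    params = list(name, desc))
  total <- 0L
  chunks <- 0L
  line_no <- hdr$header_lines
  repeat {
    lines <- readLines(con, n = chunk_size)
    if (length(lines) == 0L) break
    tbl <- vcf_chunk_to_table(lines, length(hdr$samples), hdr$samples, line_no + 1L)
    append_rows(stack$handle, name, tbl)
    total <- total + nrow(tbl)
    chunks <- chunks + 1L
    line_no <- line_no + length(lines)
  }
  structure(total, chunks = chunks)
}

vcf_sample_ids <- function(stack, name) {
  sch <- table_schema(stack$handle, name)
  cols <- names(sch$kinds)
  if (length(cols) < 9L || !identical(cols[1:9], VCF_FIXED_COLS)) {
    omi_schema_error(sprintf("layer '%s' is not a VCF layer", name))
  }
  cols[-(1:9)]
}

#' Extract the stored variant fields of one sample
#'
#' Returns the single sample column (every stored variant's field for that
#' sample, e.g. `"0|1"`), in stored row order.
#'
#' @inheritParams ingest_vcf
#' @param sample_id one of the layer's sample column names.
#' @export
sample_genotype_column <- function(stack, name, sample_id) {
  assert_layer(stack, name)
  samples <- vcf_sample_ids(stack, name)
  if (!sample_id %in% samples) {
    omi_not_found_error(sprintf(
      "no sample '%s' in layer '%s'; available: %s",
      sample_id, name, paste(samples, collapse = ", ")))
  }
  load_column(stack, name, sample_id)
}

#' Query a VCF layer by contig and position set
#'
#' Returns the rows whose contig equals `chrom` and whose 1-based position
#' is a member of `positions`, projected to `columns`, in stored row order.
#'
#' @inheritParams ingest_vcf
#' @param chrom contig name, matched verbatim.
#' @param positions non-empty set of integer positions (>= 1).
#' @param columns columns to return.
#' @export
position_query <- function(stack, name, chrom, positions, columns) {
  assert_layer(stack, name)
  if (length(positions) == 0L) omi_query_error("position set must be non-empty")
  if (!is.numeric(positions) || anyNA(positions) || any(positions < 1) ||
      any(positions != trunc(positions))) {
    omi_query_error("positions must be integers >= 1")
  }
  sch <- table_schema(stack$handle, name)
  missing <- setdiff(columns, names(sch$kinds))
  if (length(missing)) {
    omi_not_found_error(sprintf("column(s) not in layer '%s': %s",
                                name, paste(missing, collapse = ", ")))
  }
  hits <- select_rows(stack, name, "pos", as.integer(positions))
  hits <- hits[hits$chrom == chrom, , drop = FALSE]
  rownames(hits) <- NULL
  hits[, columns, drop = FALSE]
}

#' Run a batch of position queries, optionally in parallel
#'
#' Executes read-only position queries with `workers` forked readers (each
#' worker opens its own connection to the stack file; a batch must not run
#' concurrently with a writer). Results are returned in query order and
#' are identical to sequential execution; a query that fails contributes
#' its error condition to the result list without aborting the batch.
#'
#' @inheritParams ingest_vcf
#' @param queries list of `list(chrom =, positions =, columns =)` queries.
#' @param workers number of parallel readers (>= 1).
#' @return list of data.frames (or error conditions), one per query.
#' @export
run_query_batch <- function(stack, queries, workers = 1L) {
  if (!is.numeric(workers) || workers < 1) {
    omi_config_error("workers must be a positive integer")
  }
  path <- stack$path
  engine <- stack$engine
  run_one <- function(i) {
    q <- queries[[i]]
    tryCatch({
      st <- create_stack(path, engine)
      on.exit(close_stack(st), add = TRUE)
      position_query(st, q$layer, q$chrom, q$positions, q$columns)
    }, error = function(e) e)
  }
  idx <- seq_along(queries)
  if (workers == 1L) {
    lapply(idx, run_one)
  } else {
    parallel::mclapply(idx, run_one, mc.cores = as.integer(workers))
  }
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Derive a new column of a VCF layer from an existing one
#'
#' Reads `source_column`, applies a registered pure transform (default
#' `"identity"`, a plain copy), and appends the result as a new column
#' aligned to the stored row order.
#'
#' @inheritParams ingest_vcf
#' @param source_column existing column to read.
#' @param new_name name for the new column (must be unused); defaults to
#'   `<source_column>_<transform>`.
#' @param transform `"identity"` or a pure function of one vector.
#' @export
add_variant_column <- function(stack, name, source_column,
                               new_name = NULL, transform = "identity") {
  assert_layer(stack, name)
  fn <- if (is.function(transform)) {
    transform
  } else {
    switch(as.character(transform),
      identity = identity,
      omi_config_error(sprintf("unknown transform '%s'", transform)))
  }
  tag <- if (is.function(transform)) "derived" else as.character(transform)
  if (is.null(new_name)) new_name <- paste0(source_column, "_", tag)
  src <- load_column(stack, name, source_column)[[1]]
  new <- stats::setNames(
    as.data.frame(list(fn(src)), stringsAsFactors = FALSE, optional = TRUE),
    new_name)
  extend_layer_columns(stack, name, new)
  invisible(stack)
}

#' Re-export a VCF layer as VCF text
#'
#' Writes the preserved `##` meta-header (from the layer description), a
#' reconstructed `#CHROM` line, and every stored row tab-joined; gzip
#' output when `path` ends in `.gz`.
#'
#' @inheritParams ingest_vcf
#' @param path output file.
#' @return invisibly, the number of data lines written.
#' @export
export_layer_vcf <- function(stack, name, path) {
  info <- layer_info(stack, name)
  samples <- vcf_sample_ids(stack, name)
  df <- load_layer(stack, name)
  chrom_line <- paste(c(VCF_HEADER_COLS, samples), collapse = "\t")
  body <- if (nrow(df)) do.call(paste, c(lapply(df, as.character), sep = "\t")) else character(0)
  con <- if (grepl("\\.gz$", path)) gzfile(path, "wt") else file(path, "wt")
  on.exit(close(con), add = TRUE)
  header <- if (nzchar(info$description)) strsplit(info$description, "\n", fixed = TRUE)[[1]] else character(0)
  writeLines(c(header, chrom_line, body), con)
  invisible(length(body))
}
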