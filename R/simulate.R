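# Synthetic multi-omic data generator. Emulates a 100-sample cohort with
# five tabular layers plus a synthetic VCF: every value is drawn from a
# uniform distribution on a stated closed interval, at a stated decimal
# precision, and every generator is deterministic given its seed.

sample_id_labels <- function(n) sprintf("S%03d", seq_len(n))

check_n <- function(n, what = "n_samples") {
  if (!is.numeric(n) || length(n) != 1L || is.na(n) || n < 0 || n != trunc(n)) {
    omi_spec_error(sprintf("%s must be a non-negative integer", what))
  }
  as.integer(n)
}

#' Simulate cohort characteristics
#'
#' One row per sample with sample ID (`"S001"`, ...), gender (uniform over
#' `"F"`/`"M"`; the source data give no distribution, so uniform is
#' assumed), integer age uniform on \[20, 50\], and BMI uniform on
#' \[20, 40\] rounded to exactly 2 decimals.
#'
#' @param n_samples number of samples (default 100).
#' @param age_range closed integer interval for age.
#' @param bmi_range closed real interval for BMI.
#' @param seed RNG seed; the output is a pure function of the spec + seed.
#' @return data.frame with columns `sample_id` (text), `gender` (text),
#'   `age` (integer), `bmi` (real).
#' @export
simulate_cohort <- function(n_samples = 100, age_range = c(20L, 50L),
                            bmi_range = c(20, 40), seed = 1L) {
  n <- check_n(n_samples)
  withr::with_seed(seed, {
    data.frame(
      sample_id = sample_id_labels(n),
      gender = sample(c("F", "M"), n, replace = TRUE),
      age = sample(seq.int(age_range[1], age_range[2]), n, replace = TRUE),
      bmi = round(stats::runif(n, bmi_range[1], bmi_range[2]), 2),
      stringsAsFactors = FALSE
    )
  })
}

#' Simulate a feature-by-sample omic matrix
#'
#' Features as rows, samples as columns (the orientation that favours
#' column scans): first column `feature_id`, then one column per sample.
#' Real values are uniform on `value_range` rounded to `decimals` places
#' (metabolite abundances: 4 decimals on \[0, 1000\]); integer values are
#' uniform integers on `value_range` (RNA-seq counts, microbiome counts:
#' \[0, 1000\]).
#'
#' @param feature_ids unique character feature identifiers (one row each).
#' @param n_samples number of sample columns.
#' @param value_kind `"real"` or `"integer"`.
#' @param value_range closed interval for the values.
#' @param decimals decimal places kept for real values.
#' @param seed RNG seed.
#' @export
simulate_feature_matrix <- function(feature_ids, n_samples = 100,
                                    value_kind = c("real", "integer"),
                                    value_range = c(0, 1000), decimals = 4L,
                                    seed = 1L) {
  value_kind <- match.arg(value_kind)
  n <- check_n(n_samples)
  if (anyDuplicated(feature_ids)) omi_spec_error("feature_ids must be unique")
  if (value_kind == "real" && (length(decimals) != 1L || decimals < 0)) {
    omi_spec_error("decimals must be >= 0 for real values")
  }
  p <- length(feature_ids)
  withr::with_seed(seed, {
    draw <- function() {
      if (value_kind == "real") {
        round(stats::runif(p, value_range[1], value_range[2]), decimals)
      } else {
        sample(seq.int(value_range[1], value_range[2]), p, replace = TRUE)
      }
    }
    cols <- c(list(feature_id = as.character(feature_ids)),
              stats::setNames(replicate(n, draw(), simplify = FALSE),
                              sample_id_labels(n)))
    as.data.frame(cols, stringsAsFactors = FALSE, check.names = FALSE, optional = TRUE)
  })
}

#' Deterministic placeholder feature identifiers
#'
#' Stands in for real catalogue identifiers (metabolite, gene, or
#' microbial-species IDs) when no ID list is supplied: unique,
#' kind-prefixed, stable across calls. Real ID lists can be passed to
#' [simulate_feature_matrix()] directly.
#'
#' @param kind `"metabolite"`, `"gene"` or `"species"`.
#' @param count number of IDs (>= 0).
#' @export
placeholder_feature_ids <- function(kind = c("metabolite", "gene", "species"), count) {
  kind <- match.arg(kind)
  count <- check_n(count, "count")
  if (count == 0L) return(character(0))
  prefix <- switch(kind, metabolite = "HMDB-SYN-", gene = "ENSG-SYN-", species = "SPEC-SYN-")
  sprintf("%s%06d", prefix, seq_len(count))
}

#' Write a synthetic VCF file
#'
#' Per contig, exactly `per_chrom_counts[[contig]]` data lines with
#' positions `start_pos, start_pos + 1, ...` (a contiguous unit-incremented
#' run; default start 100,000). REF and ALT are uniform single bases from
#' A/C/G/T with REF != ALT; QUAL is `"."` and FILTER `"PASS"`; INFO
#' carries two uniform-real placeholder metrics of the kind a variant
#' caller and an imputation service report (`QD` on \[0, 100\], `R2` on
#' \[0, 1\]); sample fields are genotypes drawn uniformly from the phased
#' set `0|0, 0|1, 1|0, 1|1` (or the unphased `/` set).
#'
#' @param per_chrom_counts named non-negative integer vector: data lines
#'   per contig, written in the order given.
#' @param n_samples number of sample columns (`"S001"`, ...).
#' @param path output file; gzip-compressed when `compress = TRUE`.
#' @param start_pos first position on every contig (default 100,000).
#' @param seed RNG seed.
#' @param compress write gzip output.
#' @param phased use `|` genotype separators (default) or `/`.
#' @return invisibly, the named per-contig line counts written.
#' @export
simulate_vcf <- function(per_chrom_counts, n_samples, path,
                         start_pos = 100000L, seed = 1L,
                         compress = FALSE, phased = TRUE) {
  n <- check_n(n_samples)
  if (is.null(names(per_chrom_counts)) || any(!nzchar(names(per_chrom_counts)))) {
    omi_spec_error("per_chrom_counts must be a named vector (contig -> count)")
  }
  if (any(per_chrom_counts < 0) || any(per_chrom_counts != trunc(per_chrom_counts))) {
    omi_spec_error("per_chrom_counts must be non-negative integers")
  }
  con <- tryCatch(
    if (compress) gzfile(path, "wt") else file(path, "wt"),
    error = function(e) omi_io_error(sprintf("cannot write '%s': %s", path,
                                             conditionMessage(e))),
    warning = function(w) omi_io_error(sprintf("cannot write '%s': %s", path,
                                               conditionMessage(w))))
  on.exit(close(con), add = TRUE)
  sep <- if (phased) "|" else "/"
  gts <- paste0(rep(0:1, each = 2), sep, rep(0:1, times = 2))
  writeLines(c(
    "##fileformat=VCFv4.2",
    "##INFO=<ID=QD,Number=1,Type=Float,Description=\"Simulated variant-quality metric\">",
    "##INFO=<ID=R2,Number=1,Type=Float,Description=\"Simulated imputation-accuracy metric\">",
    "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">",
    paste(c(VCF_HEADER_COLS, sample_id_labels(n)), collapse = "\t")
  ), con)
  bases <- c("A", "C", "G", "T")
  counts <- stats::setNames(as.integer(per_chrom_counts), names(per_chrom_counts))
  withr::with_seed(seed, {
    for (contig in names(counts)) {
      k <- counts[[contig]]
      done <- 0L
      while (done < k) {
        m <- min(200000L, k - done)  # bound the in-memory block
        pos <- seq.int(start_pos + done, length.out = m)
        ref <- sample(bases, m, replace = TRUE)
        alt_off <- sample.int(3L, m, replace = TRUE)
        alt <- bases[((match(ref, bases) - 1L + alt_off) %% 4L) + 1L]
        info <- sprintf("QD=%.2f;R2=%.4f", stats::runif(m, 0, 100), stats::runif(m, 0, 1))
        gt <- matrix(sample(gts, m * n, replace = TRUE), nrow = m)
        line <- paste(contig, pos, ".", ref, alt, ".", "PASS", info, "GT", sep = "\t")
        if (n > 0L) {
          line <- paste(line, do.call(paste, c(asplit(gt, 2), sep = "\t")), sep = "\t")
        }
        writeLines(line, con)
        done <- done + m
      }
    }
  })
  invisible(counts)
}

#' Build a demonstration stack with all six layers
#'
#' Creates a stack holding the five tabular layers (`cohort`,
#' `blood_metas`, `urine_metas`, `rnaseq`, `microbiome`) and an ingested
#' synthetic `vcf` layer, at a configurable (by default small) scale, with
#' the metabolite layers tagged `"metabolomics"`. Used by the
#' documentation and tests.
#'
#' @param path database file for the stack.
#' @param engine `"columnstore"` (default) or `"rowstore"`.
#' @param seed RNG seed driving every layer.
#' @param n_samples samples per layer.
#' @param n_features features per omic matrix layer.
#' @param vcf_counts named per-contig variant counts for the VCF layer.
#' @return the open `omi_stack`.
#' @export
build_demo_stack <- function(path, engine = c("columnstore", "rowstore"),
                             seed = 1L, n_samples = 100, n_features = 50,
                             vcf_counts = c(chr1 = 300L, chr2 = 200L)) {
  engine <- match.arg(engine)
  stack <- create_stack(path, engine)
  store_layer(stack, "cohort", simulate_cohort(n_samples, seed = seed))
  store_layer(stack, "blood_metas", simulate_feature_matrix(
    placeholder_feature_ids("metabolite", n_features), n_samples,
    value_kind = "real", decimals = 4L, seed = seed + 1L))
  store_layer(stack, "urine_metas", simulate_feature_matrix(
    placeholder_feature_ids("metabolite", n_features), n_samples,
    value_kind = "real", decimals = 4L, seed = seed + 2L))
  store_layer(stack, "rnaseq", simulate_feature_matrix(
    placeholder_feature_ids("gene", n_features), n_samples,
    value_kind = "integer", seed = seed + 3L))
  store_layer(stack, "microbiome", simulate_feature_matrix(
    placeholder_feature_ids("species", n_features), n_samples,
    value_kind = "integer", seed = seed + 4L))
  annotate_layer(stack, "blood_metas", tag = "metabolomics")
  annotate_layer(stack, "urine_metas", tag = "metabolomics")
  vcf_path <- tempfile(fileext = ".vcf.gz")
  simulate_vcf(vcf_counts, n_samples, vcf_path, seed = seed + 5L, compress = TRUE)
  ingest_vcf(stack, vcf_path, "vcf")
  unlink(vcf_path)
  stack
}
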