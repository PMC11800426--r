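# Benchmark harness: times store/retrieve/extend/query operations across
# payload sizes and engines and summarises scaling with a least-squares
# regression through the origin (runtime grows from zero with data size,
# so the no-intercept model is the natural summary).

#' Regression through the origin with a 95% confidence interval
#'
#' Fits `y = b x` by least squares: `b = sum(x*y) / sum(x^2)`, with
#' standard error `sqrt((sum((y - b x)^2) / (n - 1)) / sum(x^2))` — the
#' model estimates a single parameter, so the residual variance uses
#' `n - 1` degrees of freedom — and a two-sided 95% CI from the t
#' distribution on `n - 1` df.
#'
#' @param x predictor (e.g. payload size in MB); all values must be > 0.
#' @param y response (e.g. runtime in seconds), same length as `x`.
#' @return an `omi_slope` object: list with `slope`, `se`, `ci_low`,
#'   `ci_high`, `df`, `n`.
#' @examples
#' fit_origin_regression(c(1, 2, 3), c(2, 4, 6))$slope  # exactly 2
#' @export
fit_origin_regression <- function(x, y) {
  if (length(x) != length(y)) omi_bench_error("x and y must have equal length")
  n <- length(x)
  if (n < 2L) omi_bench_error("need at least 2 observations")
  if (anyNA(x) || anyNA(y)) omi_bench_error("x and y must not contain NA")
  if (any(x <= 0)) omi_bench_error("all x must be > 0")
  sxx <- sum(x * x)
  b <- sum(x * y) / sxx
  rss <- sum((y - b * x)^2)
  se <- sqrt((rss / (n - 1)) / sxx)
  tq <- stats::qt(0.975, df = n - 1)
  structure(
    list(slope = b, se = se, ci_low = b - tq * se, ci_high = b + tq * se,
         df = n - 1L, n = n),
    class = "omi_slope")
}

#' @export
print.omi_slope <- function(x, ...) {
  cat(sprintf("slope %.6g  (95%% CI %.6g to %.6g, df = %d, n = %d)\n",
              x$slope, x$ci_low, x$ci_high, x$df, x$n))
  invisible(x)
}

bench_payload <- function(size_mb, n_samples, seed) {
  # one feature row costs ~ 8 bytes per numeric sample cell; size the
  # feature count so the in-memory footprint approximates size_mb MiB
  n_features <- max(10L, as.integer(ceiling(size_mb * 2^20 / (n_samples * 8))))
  simulate_feature_matrix(placeholder_feature_ids("gene", n_features),
                          n_samples, value_kind = "real", decimals = 4L,
                          seed = seed)
}

payload_mb <- function(data) as.numeric(utils::object.size(data)) / 2^20

time_s <- function(expr) {
  t0 <- proc.time()[["elapsed"]]
  force(expr)
  proc.time()[["elapsed"]] - t0
}

#' Time storage/retrieval/extension operations across sizes and engines
#'
#' For each engine x size x operation x repeat, builds a deterministic
#' synthetic payload (identical across engines for the same cell),
#' performs the operation against a fresh single-file stack, and records
#' the payload's in-memory footprint (MiB, reported as MB) and the elapsed
#' runtime in seconds. Operations: `store` (store the layer), `retrieve`
#' (load it back whole), `extend_col` (append one derived column),
#' `row_query` (select a fixed fraction of rows by key). A failing cell is
#' recorded with `NA` runtime and the run continues. Chunked VCF ingestion
#' is deliberately not part of this grid: its runtime is dominated by
#' per-chunk disk transactions, not payload size, so it would distort the
#' scaling regression.
#'
#' @param sizes_mb payload sizes to target, in MB.
#' @param operations subset of `c("store","retrieve","extend_col","row_query")`.
#' @param engines engines to benchmark.
#' @param repeats timings per cell.
#' @param n_samples sample columns in the synthetic payloads.
#' @param seed seed for the payload generators.
#' @param dir directory for the scratch database files.
#' @return data.frame of benchmark records (one row per timing).
#' @export
run_benchmark <- function(sizes_mb, operations = c("store", "retrieve", "extend_col", "row_query"),
                          engines = c("rowstore", "columnstore"),
                          repeats = 1L, n_samples = 100L, seed = 1L,
                          dir = tempdir()) {
  if (length(sizes_mb) == 0L) omi_bench_error("sizes_mb must be non-empty")
  operations <- match.arg(operations, several.ok = TRUE)
  records <- list()
  for (size in sizes_mb) {
    payload <- bench_payload(size, n_samples, seed + round(size * 1000))
    mb <- payload_mb(payload)
    extra <- stats::setNames(
      data.frame(x = payload[[2]] * 2, stringsAsFactors = FALSE), "derived")
    keys <- payload$feature_id[seq_len(max(1L, nrow(payload) %/% 10L))]
    for (engine in engines) {
      for (op in operations) {
        for (r in seq_len(repeats)) {
          db <- tempfile(tmpdir = dir, fileext = ".db")
          rec <- tryCatch({
            st <- create_stack(db, engine)
            rt <- switch(op,
              store = time_s(store_layer(st, "bench", payload)),
              retrieve = { store_layer(st, "bench", payload)
                           time_s(load_layer(st, "bench")) },
              extend_col = { store_layer(st, "bench", payload)
                             time_s(extend_layer_columns(st, "bench", extra)) },
              row_query = { store_layer(st, "bench", payload)
                            time_s(select_rows(st, "bench", "feature_id", keys)) })
            close_stack(st)
            data.frame(engine = engine, operation = op, size_mb = mb,
                       runtime_s = rt, rep = r, error = NA_character_,
                       stringsAsFactors = FALSE)
          }, error = function(e) {
            data.frame(engine = engine, operation = op, size_mb = mb,
                       runtime_s = NA_real_, rep = r,
                       error = conditionMessage(e), stringsAsFactors = FALSE)
          })
          unlink(db)
          records[[length(records) + 1L]] <- rec
        }
      }
    }
  }
  do.call(rbind, c(records, list(make.row.names = FALSE)))
}

#' Summarise benchmark records with per-engine scaling slopes
#'
#' Fits the no-intercept regression of runtime on payload size for every
#' engine x operation with at least two successful timings and reports the
#' slope in ms/MB with its 95% CI, alongside the raw records. Repeats are
#' not averaged before fitting: every raw timing enters the regression.
#'
#' @param records data.frame from [run_benchmark()].
#' @return an `omi_bench_report`: list with `summary` (data.frame of
#'   slopes) and `records`.
#' @export
bench_report <- function(records) {
  if (!is.data.frame(records) || nrow(records) == 0L) {
    omi_bench_error("no benchmark records")
  }
  ok <- records[!is.na(records$runtime_s), , drop = FALSE]
  groups <- unique(ok[, c("engine", "operation")])
  rows <- lapply(seq_len(nrow(groups)), function(i) {
    g <- ok[ok$engine == groups$engine[i] & ok$operation == groups$operation[i], ]
    if (nrow(g) < 2L) return(NULL)
    fit <- fit_origin_regression(g$size_mb, g$runtime_s)
    data.frame(engine = groups$engine[i], operation = groups$operation[i],
               slope_ms_per_mb = fit$slope * 1000,
               ci_low_ms = fit$ci_low * 1000, ci_high_ms = fit$ci_high * 1000,
               df = fit$df, n = fit$n, stringsAsFactors = FALSE)
  })
  structure(list(summary = do.call(rbind, c(rows, list(make.row.names = FALSE))),
                 records = records),
            class = "omi_bench_report")
}

#' @export
print.omi_bench_report <- function(x, ...) {
  cat("scaling of runtime with payload size (regression through the origin)\n")
  if (is.null(x$summary)) {
    cat("  (not enough successful timings to fit)\n")
  } else {
    for (i in seq_len(nrow(x$summary))) {
      s <- x$summary[i, ]
      cat(sprintf("  %-12s %-10s %8.2f ms/MB  (95%% CI %.2f to %.2f, n = %d)\n",
                  s$engine, s$operation, s$slope_ms_per_mb, s$ci_low_ms,
                  s$ci_high_ms, s$n))
    }
  }
  cat(sprintf("raw records: %d\n", nrow(x$records)))
  invisible(x)
}
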