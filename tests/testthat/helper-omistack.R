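ENGINES <- c("rowstore", "columnstore")

new_stack <- function(engine = "columnstore") {
  create_stack(tempfile(fileext = ".db"), engine)
}

# Property generator: rectangular table with 1..max_cols columns of random
# kinds, optional NAs, and field-realistic column names (dots and dashes,
# like gene/metabolite IDs).
random_typed_table <- function(seed, max_rows = 40L, max_cols = 6L, na_prob = 0.1) {
  withr::with_seed(seed, {
    n <- sample(0:max_rows, 1L)
    k <- sample(1:max_cols, 1L)
    kinds <- sample(c("integer", "real", "text"), k, replace = TRUE)
    nm <- paste0(sample(c("col", "gene.x", "HMDB-syn", "v"), k, replace = TRUE),
                 "_", seq_len(k))
    cols <- lapply(kinds, function(kind) {
      v <- switch(kind,
        integer = sample.int(1000L, n, replace = TRUE),
        real = round(stats::runif(n, -500, 500), 4),
        text = paste0("t", sample.int(500L, n, replace = TRUE), recycle0 = TRUE))
      v[stats::runif(n) < na_prob] <- NA
      v
    })
    names(cols) <- nm
    as.data.frame(cols, stringsAsFactors = FALSE, check.names = FALSE, optional = TRUE)
  })
}

strip_rn <- function(df) { rownames(df) <- NULL; df }

# brute-force oracles, kept independent of the storage path
oracle_filter <- function(df, column, values) {
  strip_rn(df[!is.na(df[[column]]) & df[[column]] %in% values, , drop = FALSE])
}

oracle_nested_join <- function(a, b, on) {
  rows <- list()
  bn <- setdiff(names(b), on)
  out_names <- c(names(a), ifelse(bn %in% names(a), paste0(bn, ".2"), bn))
  for (i in seq_len(nrow(a))) {
    for (j in seq_len(nrow(b))) {
      if (!is.na(a[[on]][i]) && !is.na(b[[on]][j]) && a[[on]][i] == b[[on]][j]) {
        rows[[length(rows) + 1L]] <- c(as.list(a[i, , drop = FALSE]),
                                       as.list(b[j, bn, drop = FALSE]))
      }
    }
  }
  if (!length(rows)) {
    out <- cbind(a[0, , drop = FALSE], b[0, bn, drop = FALSE])
    names(out) <- out_names
    return(strip_rn(out))
  }
  out <- do.call(rbind, lapply(rows, function(r)
    as.data.frame(r, stringsAsFactors = FALSE, check.names = FALSE, optional = TRUE)))
  names(out) <- out_names
  strip_rn(out)
}

# raw tab-split parse of a VCF file (plain or gz), independent of ingest_vcf
oracle_parse_vcf <- function(path) {
  lines <- readLines(if (grepl("\\.gz$", path)) gzfile(path) else file(path))
  body <- lines[!startsWith(lines, "#")]
  hdr <- lines[startsWith(lines, "#CHROM")]
  cols <- strsplit(hdr, "\t", fixed = TRUE)[[1]]
  m <- do.call(rbind, strsplit(body, "\t", fixed = TRUE))
  list(columns = cols, matrix = m, meta = lines[startsWith(lines, "##")])
}

# a randomized stack operation script; replaying it on any engine must give
# the same observable state (used by the cross-engine equivalence tests)
replay_ops <- function(stack, seed, n_ops = 30L) {
  tables <- list()
  withr::with_seed(seed, {
    op_seeds <- sample.int(1e6, n_ops)
  })
  for (i in seq_len(n_ops)) {
    withr::with_seed(op_seeds[i], {
      existing <- names(tables)
      op <- sample(c("store", "extend_rows", "extend_cols", "annotate", "drop"), 1L,
                   prob = c(0.35, 0.2, 0.15, 0.2, 0.1))
      if (op == "store" || length(existing) == 0L) {
        nm <- paste0("layer", sample.int(8L, 1L))
        df <- random_typed_table(op_seeds[i] + 1L)
        if (nm %in% existing) {
          store_layer(stack, nm, df, if_exists = "replace")
        } else {
          store_layer(stack, nm, df)
        }
        tables[[nm]] <- df
      } else {
        nm <- sample(existing, 1L)
        if (op == "extend_rows") {
          idx <- if (nrow(tables[[nm]]) == 0L) integer(0)
                 else sample.int(nrow(tables[[nm]]), sample(0:5, 1L), replace = TRUE)
          add <- strip_rn(tables[[nm]][idx, , drop = FALSE])
          perm <- sample(seq_along(tables[[nm]]))
          extend_layer_rows(stack, nm, add[, perm, drop = FALSE])
          tables[[nm]] <- strip_rn(rbind(tables[[nm]], add))
        } else if (op == "extend_cols") {
          newc <- stats::setNames(
            data.frame(round(stats::runif(nrow(tables[[nm]])), 3)),
            paste0("extra_", i))
          extend_layer_columns(stack, nm, newc)
          tables[[nm]] <- cbind(tables[[nm]], newc)
        } else if (op == "annotate") {
          annotate_layer(stack, nm, tag = sample(c("omics", "qc", "raw"), 1L))
        } else {
          drop_layer(stack, nm)
          tables[[nm]] <- NULL
        }
      }
    })
  }
  tables
}

# full observable state of a stack: catalogue + every layer's contents
stack_state <- function(stack) {
  cat_ <- list_layers(stack)
  layers <- lapply(cat_$name, function(n) load_layer(stack, n))
  names(layers) <- cat_$name
  list(catalogue = cat_, layers = layers)
}
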