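# Engine contract: identical observable behaviour on the row-oriented and
# column-oriented layouts.

test_that("store handles open, persist across reopen, and reject unknown engines", {
  for (eng in ENGINES) {
    path <- tempfile(fileext = ".db")
    h <- open_store(path, eng)
    create_table(h, "t", c(a = "integer", b = "text"))
    append_rows(h, "t", data.frame(a = 1:2, b = c("x", "y"), stringsAsFactors = FALSE))
    close_store(h)
    h2 <- open_store(path, eng)
    expect_identical(list_tables(h2), "t")
    expect_identical(read_table(h2, "t")$b, c("x", "y"))
    close_store(h2)
  }
  expect_error(open_store(tempfile(), "graphstore"), class = "omi_config_error")
  expect_error(open_store(file.path(tempfile(), "nodir", "x.db"), "rowstore"),
               class = "omi_storage_error")
})

test_that("create_table enforces schema invariants and replace semantics", {
  for (eng in ENGINES) {
    h <- open_store(tempfile(fileext = ".db"), eng)
    kinds <- c(sample_id = "text", gender = "text", age = "integer", bmi = "real")
    create_table(h, "cohort", kinds)
    sch <- table_schema(h, "cohort")
    expect_identical(sch$kinds, kinds)
    expect_identical(sch$row_count, 0L)

    expect_error(create_table(h, "cohort", kinds), class = "omi_duplicate_error")
    append_rows(h, "cohort", data.frame(sample_id = "S001", gender = "F",
                                        age = 30L, bmi = 22.5, stringsAsFactors = FALSE))
    create_table(h, "cohort", kinds, if_exists = "replace")
    expect_identical(table_schema(h, "cohort")$row_count, 0L)

    expect_error(create_table(h, "_meta", kinds), class = "omi_naming_error")
    expect_error(create_table(h, "bad", c(a = "integer", A = "text")),
                 class = "omi_schema_error")
    expect_error(create_table(h, "bad", c(a = "blob")), class = "omi_schema_error")
    close_store(h)
  }
})

test_that("round-trip preserves values, order, kinds and nulls on both engines", {
  for (eng in ENGINES) {
    h <- open_store(tempfile(fileext = ".db"), eng)
    for (seed in 1:15) {
      df <- random_typed_table(seed)
      nm <- paste0("t", seed)
      create_table(h, nm, table_kinds(df))
      expect_identical(append_rows(h, nm, df), nrow(df))
      expect_identical(read_table(h, nm), df)
    }
    close_store(h)
  }
})

test_that("doubles survive storage without precision loss", {
  vals <- c(pi, exp(1), 1/3, 123456789.123456789, .Machine$double.xmin, -1e300)
  for (eng in ENGINES) {
    h <- open_store(tempfile(fileext = ".db"), eng)
    create_table(h, "t", c(x = "real"))
    append_rows(h, "t", data.frame(x = vals))
    expect_identical(read_table(h, "t")$x, vals)
    close_store(h)
  }
})

test_that("append is all-or-nothing: a rejected chunk leaves the row count unchanged", {
  for (eng in ENGINES) {
    h <- open_store(tempfile(fileext = ".db"), eng)
    create_table(h, "t", c(a = "integer", b = "text"))
    append_rows(h, "t", data.frame(a = 1:3, b = c("x", "y", "z"), stringsAsFactors = FALSE))
    before <- read_table(h, "t")
    expect_error(
      append_rows(h, "t", data.frame(a = c("10", "oops"), b = c("p", "q"),
                                     stringsAsFactors = FALSE)),
      class = "omi_schema_error")
    expect_identical(read_table(h, "t"), before)
    expect_error(
      append_rows(h, "t", data.frame(b = c("p"), a = 1L, stringsAsFactors = FALSE)[, c("b", "a")]),
      class = "omi_schema_error")
    expect_identical(read_table(h, "t"), before)
    expect_identical(append_rows(h, "t", before[0, ]), 0L)
    expect_identical(table_schema(h, "t")$row_count, 3L)
    close_store(h)
  }
})

test_that("add_columns aligns positionally and equals one-shot construction", {
  for (eng in ENGINES) {
    for (seed in 1:5) {
      df <- random_typed_table(seed, max_rows = 30L, max_cols = 4L)
      extra <- data.frame(added_r = round(stats::runif(nrow(df)), 3),
                          added_t = paste0("v", seq_len(nrow(df))),
                          stringsAsFactors = FALSE)
      h1 <- open_store(tempfile(fileext = ".db"), eng)
      create_table(h1, "t", table_kinds(df)); append_rows(h1, "t", df)
      add_columns(h1, "t", extra)
      # oracle: the table built whole in one shot
      whole <- cbind(df, extra)
      h2 <- open_store(tempfile(fileext = ".db"), eng)
      create_table(h2, "t", table_kinds(whole)); append_rows(h2, "t", whole)
      expect_identical(read_table(h1, "t"), read_table(h2, "t"))
      close_store(h1); close_store(h2)
    }
  }
})

test_that("add_columns rejects misaligned or colliding columns, leaving the table intact", {
  for (eng in ENGINES) {
    h <- open_store(tempfile(fileext = ".db"), eng)
    df <- data.frame(a = 1:4, stringsAsFactors = FALSE)
    create_table(h, "t", table_kinds(df)); append_rows(h, "t", df)
    expect_error(add_columns(h, "t", data.frame(b = 1:3)), class = "omi_alignment_error")
    expect_error(add_columns(h, "t", data.frame(a = 1:4)), class = "omi_schema_error")
    expect_identical(read_table(h, "t"), df)
    # zero columns is the identity
    add_columns(h, "t", df[, 0])
    expect_identical(read_table(h, "t"), df)
    close_store(h)
  }
})

test_that("read_columns projects in requested order; unknown columns are named", {
  for (eng in ENGINES) {
    h <- open_store(tempfile(fileext = ".db"), eng)
    df <- data.frame(a = 1:3, b = c("x", "y", "z"), c = c(0.1, 0.2, 0.3),
                     stringsAsFactors = FALSE)
    create_table(h, "t", table_kinds(df)); append_rows(h, "t", df)
    expect_identical(read_columns(h, "t", c("c", "a")), df[, c("c", "a")])
    expect_identical(read_columns(h, "t", names(df)), df)
    err <- tryCatch(read_columns(h, "t", c("a", "nope")), error = identity)
    expect_s3_class(err, "omi_not_found_error")
    expect_match(conditionMessage(err), "nope")
    close_store(h)
  }
})

test_that("read_where matches a brute-force scan filter on random tables", {
  for (eng in ENGINES) {
    h <- open_store(tempfile(fileext = ".db"), eng)
    for (seed in 21:32) {
      df <- random_typed_table(seed, max_rows = 60L)
      nm <- paste0("t", seed)
      create_table(h, nm, table_kinds(df)); append_rows(h, nm, df)
      col <- withr::with_seed(seed, sample(names(df), 1L))
      pool <- df[[col]][!is.na(df[[col]])]
      vals <- if (length(pool)) withr::with_seed(seed + 1L, sample(pool, min(5L, length(pool)))) else NULL
      if (is.null(vals)) next
      expect_identical(read_where(h, nm, col, vals), oracle_filter(df, col, vals))
    }
    # no matches: 0-row table with full schema
    df <- data.frame(a = 1:3, b = c("x", "y", "z"), stringsAsFactors = FALSE)
    create_table(h, "t0", table_kinds(df)); append_rows(h, "t0", df)
    expect_identical(read_where(h, "t0", "a", 99L), df[0, ])
    expect_error(read_where(h, "t0", "a", integer(0)), class = "omi_query_error")
    expect_error(read_where(h, "t0", "a", "notanint"), class = "omi_query_error")
    close_store(h)
  }
})

test_that("list/drop/table_schema keep the table inventory consistent", {
  for (eng in ENGINES) {
    h <- open_store(tempfile(fileext = ".db"), eng)
    df <- data.frame(x = 1:2)
    for (nm in c("alpha", "beta", "gamma")) {
      create_table(h, nm, table_kinds(df)); append_rows(h, nm, df)
    }
    expect_identical(list_tables(h), c("alpha", "beta", "gamma"))
    expect_true(drop_table(h, "beta"))
    expect_identical(list_tables(h), c("alpha", "gamma"))
    expect_false(drop_table(h, "beta"))
    expect_error(table_schema(h, "beta"), class = "omi_not_found_error")
    expect_identical(table_schema(h, "alpha")$row_count, nrow(read_table(h, "alpha")))
    close_store(h)
  }
})

test_that("identical operation sequences give value-identical reads across engines", {
  for (seed in c(7L, 99L)) {
    states <- lapply(ENGINES, function(eng) {
      h <- open_store(tempfile(fileext = ".db"), eng)
      for (s in 1:6) {
        df <- random_typed_table(seed + s)
        create_table(h, paste0("t", s), table_kinds(df))
        append_rows(h, paste0("t", s), df)
      }
      drop_table(h, "t3")
      out <- list(tables = list_tables(h),
                  reads = lapply(list_tables(h), function(n) read_table(h, n)))
      close_store(h)
      out
    })
    expect_identical(states[[1]], states[[2]])
  }
})
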