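test_that("stack creation defaults to the column-oriented engine and reopens intact", {
  path <- tempfile(fileext = ".db")
  s <- create_stack(path)
  expect_identical(s$engine, "columnstore")
  s2 <- create_stack(tempfile(fileext = ".db"), "rowstore")
  expect_identical(s2$engine, "rowstore")
  close_stack(s2)

  store_layer(s, "cohort", simulate_cohort(n_samples = 10, seed = 1))
  annotate_layer(s, "cohort", tag = "pheno", description = "cohort characteristics")
  before <- stack_state(s)
  close_stack(s)
  reopened <- create_stack(path)
  expect_identical(stack_state(reopened), before)
  close_stack(reopened)
})

test_that("storing the five tabular study layers catalogues all of them", {
  for (eng in ENGINES) {
    s <- new_stack(eng)
    nms <- c("cohort", "blood_metas", "urine_metas", "rnaseq", "microbiome")
    store_layer(s, "cohort", simulate_cohort(n_samples = 8, seed = 1))
    ids <- placeholder_feature_ids("metabolite", 5)
    for (nm in nms[-1]) {
      store_layer(s, nm, simulate_feature_matrix(ids, 8, seed = match(nm, nms)))
    }
    expect_setequal(list_layers(s)$name, nms)
    expect_error(store_layer(s, "cohort", simulate_cohort(5, seed = 2)),
                 class = "omi_duplicate_error")
    # replace leaves a single entry with the new contents
    store_layer(s, "cohort", simulate_cohort(n_samples = 3, seed = 9), if_exists = "replace")
    expect_identical(layer_info(s, "cohort")$row_count, 3L)
    expect_identical(sum(list_layers(s)$name == "cohort"), 1L)
    close_stack(s)
  }
})

test_that("stored layers round-trip exactly", {
  for (eng in ENGINES) {
    s <- new_stack(eng)
    for (seed in 41:46) {
      df <- random_typed_table(seed)
      nm <- paste0("l", seed)
      store_layer(s, nm, df)
      expect_identical(load_layer(s, nm), df)
    }
    close_stack(s)
  }
})

test_that("tags group layers and tag queries equal a catalogue scan", {
  s <- new_stack()
  store_layer(s, "blood_metas", data.frame(feature_id = "m1", S001 = 0.5))
  store_layer(s, "urine_metas", data.frame(feature_id = "m1", S001 = 0.7))
  store_layer(s, "rnaseq", data.frame(feature_id = "g1", S001 = 10L))
  annotate_layer(s, "blood_metas", tag = "metabolomics")
  annotate_layer(s, "urine_metas", tag = "metabolomics")
  expect_identical(layers_with_tag(s, "metabolomics"), c("blood_metas", "urine_metas"))
  expect_identical(layers_with_tag(s, "unknown"), character(0))
  # idempotent
  annotate_layer(s, "blood_metas", tag = "metabolomics")
  expect_identical(layers_with_tag(s, "metabolomics"), c("blood_metas", "urine_metas"))
  # oracle: linear scan of the catalogue
  cat_ <- list_layers(s)
  expect_identical(layers_with_tag(s, "metabolomics"),
                   sort(cat_$name[cat_$tag == "metabolomics"], method = "radix"))
  expect_error(annotate_layer(s, "missing", tag = "x"), class = "omi_not_found_error")
  close_stack(s)
})

test_that("layer_info reports schema, counts and annotation without loading data", {
  s <- new_stack()
  df <- simulate_feature_matrix(placeholder_feature_ids("gene", 7), 4, seed = 3)
  store_layer(s, "rnaseq", df, description = "synthetic bulk counts")
  info <- layer_info(s, "rnaseq")
  expect_identical(info$row_count, 7L)
  expect_identical(info$row_count, nrow(load_layer(s, "rnaseq")))
  expect_identical(info$description, "synthetic bulk counts")
  expect_identical(names(info$kinds), names(df))
  drop_layer(s, "rnaseq")
  expect_error(layer_info(s, "rnaseq"), class = "omi_not_found_error")
  close_stack(s)
})

test_that("row extension aligns by name and equals one-shot storage", {
  for (eng in ENGINES) {
    for (seed in c(11L, 12L)) {
      df <- random_typed_table(seed, max_rows = 50L)
      if (nrow(df) < 2L) df <- rbind(df, df, df)
      cut <- max(1L, nrow(df) %/% 3L)
      a <- strip_rn(df[seq_len(cut), , drop = FALSE])
      b <- strip_rn(df[-seq_len(cut), , drop = FALSE])
      s1 <- new_stack(eng)
      store_layer(s1, "t", a)
      extend_layer_rows(s1, "t", b[, rev(names(b)), drop = FALSE])  # reordered columns
      s2 <- new_stack(eng)
      store_layer(s2, "t", df)
      expect_identical(load_layer(s1, "t"), load_layer(s2, "t"))
      # zero-row extension is the identity
      extend_layer_rows(s1, "t", df[0, , drop = FALSE])
      expect_identical(load_layer(s1, "t"), df)
      expect_error(extend_layer_rows(s1, "t", data.frame(unrelated = 1)),
                   class = "omi_schema_error")
      close_stack(s1); close_stack(s2)
    }
  }
})

test_that("select_rows and load_column delegate with identical contracts", {
  s <- new_stack()
  df <- simulate_cohort(n_samples = 30, seed = 5)
  store_layer(s, "cohort", df)
  expect_identical(load_column(s, "cohort", "age"), df[, "age", drop = FALSE])
  got <- select_rows(s, "cohort", "gender", "F")
  expect_identical(got, oracle_filter(df, "gender", "F"))
  close_stack(s)
})

test_that("drop_layer removes table and catalogue entry atomically", {
  s <- new_stack()
  store_layer(s, "a", data.frame(x = 1:2))
  store_layer(s, "b", data.frame(x = 1:2))
  annotate_layer(s, "a", tag = "t")
  drop_layer(s, "a")
  expect_identical(layers_with_tag(s, "t"), character(0))
  expect_error(layer_info(s, "a"), class = "omi_not_found_error")
  # catalogue and physical tables enumerate identically
  expect_setequal(list_layers(s)$name, list_tables(s$handle))
  expect_error(drop_layer(s, "a"), class = "omi_not_found_error")
  close_stack(s)
})

test_that("join_layers matches the nested-loop oracle and handles self-joins", {
  s <- new_stack()
  cohort <- data.frame(sample_id = c("S1", "S2", "S3", "S4"),
                       age = c(31L, 44L, 28L, 39L), stringsAsFactors = FALSE)
  metas <- data.frame(sample_id = c("S2", "S3", "S5"),
                      hmdb1 = c(0.5, 1.25, 9.0), age = c(1L, 2L, 3L),
                      stringsAsFactors = FALSE)
  store_layer(s, "cohort", cohort)
  store_layer(s, "metas", metas)
  got <- join_layers(s, c("cohort", "metas"), on = "sample_id")
  expect_identical(got, oracle_nested_join(cohort, metas, "sample_id"))
  # join with itself on a unique key preserves the row count
  self <- join_layers(s, c("cohort", "cohort"), on = "sample_id")
  expect_identical(nrow(self), nrow(cohort))
  err <- tryCatch(join_layers(s, c("cohort", "metas"), on = "hmdb1"), error = identity)
  expect_s3_class(err, "omi_join_error")
  expect_match(conditionMessage(err), "cohort")
  expect_error(join_layers(s, "cohort", on = "sample_id"), class = "omi_join_error")
  close_stack(s)
})

test_that("catalogue and physical tables stay consistent through random op scripts", {
  for (eng in ENGINES) {
    s <- new_stack(eng)
    expected <- replay_ops(s, seed = 314L, n_ops = 25L)
    expect_setequal(list_layers(s)$name, list_tables(s$handle))
    expect_setequal(list_layers(s)$name, names(expected))
    for (nm in names(expected)) {
      expect_identical(load_layer(s, nm), strip_rn(expected[[nm]]), label = nm)
    }
    close_stack(s)
  }
})

test_that("a randomized operation script replays identically on both engines", {
  states <- lapply(ENGINES, function(eng) {
    s <- new_stack(eng)
    replay_ops(s, seed = 2718L, n_ops = 30L)
    st <- stack_state(s)
    close_stack(s)
    st
  })
  expect_identical(states[[1]], states[[2]])
})
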