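#' Create or open a stack of omic layers
#'
#' A stack is one single-file database holding any number of omic layers
#' (tabular datasets) together with a metadata catalogue (per-layer name,
#' tag, description) kept in a reserved table inside the same file, so a
#' whole multi-omic study travels as one portable file.
#'
#' The column-oriented engine is used when none is specified; it is the
#' better default for omic matrices, where retrieval is dominated by
#' whole-column scans (samples as columns, features as rows). Choose the
#' row-oriented engine for workloads of frequent small transactions.
#'
#' @param path database file; created if absent, reopened (with its
#'   catalogue intact) if present.
#' @param engine `"columnstore"` (default) or `"rowstore"`.
#' @return an `omi_stack` object.
#' @examples
#' s <- create_stack(tempfile(fileext = ".db"))
#' store_layer(s, "cohort", simulate_cohort(n_samples = 10, seed = 1))
#' layer_info(s, "cohort")$row_count
#' close_stack(s)
#' @export
create_stack <- function(path, engine = c("columnstore", "rowstore")) {
  handle <- open_store(path, engine)
  DBI::dbExecute(handle$con, paste(
    "CREATE TABLE IF NOT EXISTS \"_layers_meta\"",
    "(name TEXT PRIMARY KEY, tag TEXT NOT NULL DEFAULT '',",
    " description TEXT NOT NULL DEFAULT '')"))
  structure(list(handle = handle, path = path, engine = handle$engine),
            class = "omi_stack")
}

#' Close a stack's database connection
#' @param stack an `omi_stack`.
#' @export
close_stack <- function(stack) close_store(stack$handle)

#' @export
print.omi_stack <- function(x, ...) {
  cat(sprintf("<omi_stack> %s [%s]\n", x$path, x$engine))
  cat("layers:", paste(stack_catalogue(x)$name, collapse = ", "), "\n")
  invisible(x)
}

stack_catalogue <- function(stack) {
  DBI::dbGetQuery(stack$handle$con,
    "SELECT name, tag, description FROM \"_layers_meta\" ORDER BY name")
}

meta_row <- function(stack, name) {
  DBI::dbGetQuery(stack$handle$con,
    "SELECT name, tag, description FROM \"_layers_meta\" WHERE name = ?",
    params = list(name))
}

assert_layer <- function(stack, name) {
  if (nrow(meta_row(stack, name)) == 0L) {
    omi_not_found_error(sprintf("no layer named '%s'", name))
  }
  invisible(name)
}

#' Store a data.frame as a named layer
#'
#' Creates the table, inserts the rows, and registers the layer in the
#' catalogue with empty tag/description — all-or-nothing: a failure at any
#' step leaves neither table nor catalogue entry behind.
#'
#' @param stack an `omi_stack`.
#' @param name layer name (unique within the stack).
#' @param data data.frame with integer, real (double) and/or text
#'   (character) columns; missing values allowed.
#' @param if_exists `"fail"` (default) or `"replace"`.
#' @param description optional free-text description stored in the catalogue.
#' @return invisibly, the stack.
#' @export
store_layer <- function(stack, name, data, if_exists = c("fail", "replace"),
                        description = "") {
  if_exists <- match.arg(if_exists)
  check_typed_table(data, allow_zero_cols = FALSE)
  if (nrow(meta_row(stack, name)) > 0L && if_exists == "fail") {
    omi_duplicate_error(sprintf("layer '%s' already exists", name))
  }
  kinds <- vapply(data, column_kind, character(1))
  created <- FALSE
  tryCatch({
    create_table(stack$handle, name, kinds, if_exists = if_exists)
    created <- TRUE
    append_rows(stack$handle, name, data)
    DBI::dbExecute(stack$handle$con,
      "INSERT INTO \"_layers_meta\" (name, tag, description) VALUES (?, '', ?)
       ON CONFLICT(name) DO UPDATE SET description = excluded.description",
      params = list(name, description))
  }, error = function(e) {
    if (created) {
      try(drop_table(stack$handle, name), silent = TRUE)
      try(DBI::dbExecute(stack$handle$con,
        "DELETE FROM \"_layers_meta\" WHERE name = ?", params = list(name)),
        silent = TRUE)
    }
    stop(e)
  })
  invisible(stack)
}

#' Annotate a layer with a tag and/or description
#'
#' Tags group layers (e.g. tag both blood and urine metabolite layers
#' `"metabolomics"`); only the fields supplied are updated, and repeating
#' the same annotation is a no-op.
#'
#' @inheritParams store_layer
#' @param tag,description new values; `NULL` leaves the field unchanged.
#' @export
annotate_layer <- function(stack, name, tag = NULL, description = NULL) {
  assert_layer(stack, name)
  if (!is.null(tag)) {
    DBI::dbExecute(stack$handle$con,
      "UPDATE \"_layers_meta\" SET tag = ? WHERE name = ?",
      params = list(as.character(tag), name))
  }
  if (!is.null(description)) {
    DBI::dbExecute(stack$handle$con,
      "UPDATE \"_layers_meta\" SET description = ? WHERE name = ?",
      params = list(as.character(description), name))
  }
  invisible(stack)
}

#' Names of layers carrying a given tag
#'
#' @inheritParams store_layer
#' @param tag tag to look up.
#' @return lexicographically sorted character vector (possibly empty).
#' @export
layers_with_tag <- function(stack, tag) {
  cat_ <- stack_catalogue(stack)
  sort(cat_$name[cat_$tag == tag], method = "radix")
}

#' Schema, row count and annotation of a layer, without loading its values
#'
#' @inheritParams store_layer
#' @return list with `name`, `kinds`, `row_count`, `tag`, `description`.
#' @export
layer_info <- function(stack, name) {
  assert_layer(stack, name)
  sch <- table_schema(stack$handle, name)
  m <- meta_row(stack, name)
  list(name = name, kinds = sch$kinds, row_count = sch$row_count,
       tag = m$tag, description = m$description)
}

#' All layer names and annotations
#' @inheritParams store_layer
#' @return data.frame with columns name, tag, description.
#' @export
list_layers <- function(stack) stack_catalogue(stack)

#' Load a stored layer (whole, by columns, or by row values)
#'
#' `load_layer()` returns the full layer; `load_column()` a projection of
#' one or more columns; `select_rows()` the rows whose value in `column`
#' is among `values`. All preserve stored row order and declared types.
#'
#' @inheritParams store_layer
#' @param columns character vector of column names.
#' @param column single column name to filter on.
#' @param values non-empty set of values to match.
#' @export
load_layer <- function(stack, name) {
  assert_layer(stack, name)
  read_table(stack$handle, name)
}

#' @rdname load_layer
#' @export
load_column <- function(stack, name, columns) {
  assert_layer(stack, name)
  read_columns(stack$handle, name, columns)
}

#' @rdname load_layer
#' @export
select_rows <- function(stack, name, column, values) {
  assert_layer(stack, name)
  read_where(stack$handle, name, column, values)
}

#' Extend a layer row-wise
#'
#' Appends new rows. Alignment is by column NAME (a reordered data.frame
#' with the same columns is accepted); extending with `a` then `b` is
#' equivalent to having stored `rbind(a, b)` at once.
#'
#' @inheritParams store_layer
#' @export
extend_layer_rows <- function(stack, name, data) {
  assert_layer(stack, name)
  check_typed_table(data)
  sch <- table_schema(stack$handle, name)
  if (!setequal(names(data), names(sch$kinds))) {
    omi_append_error(sprintf(
      "layer '%s' has columns (%s); got (%s)", name,
      paste(names(sch$kinds), collapse = ","), paste(names(data), collapse = ",")))
  }
  append_rows(stack$handle, name, data[, names(sch$kinds), drop = FALSE])
  invisible(stack)
}

#' Extend a layer column-wise
#'
#' Adds new columns, aligned POSITIONALLY to the stored row order; the new
#' columns must have exactly one value per stored row.
#'
#' @inheritParams store_layer
#' @export
extend_layer_columns <- function(stack, name, data) {
  assert_layer(stack, name)
  add_columns(stack$handle, name, data)
  invisible(stack)
}

#' Remove a layer and its catalogue entry
#' @inheritParams store_layer
#' @export
drop_layer <- function(stack, name) {
  assert_layer(stack, name)
  DBI::dbWithTransaction(stack$handle$con, {
    DBI::dbExecute(stack$handle$con,
      "DELETE FROM \"_layers_meta\" WHERE name = ?", params = list(name))
  })
  drop_table(stack$handle, name)
  invisible(stack)
}

#' Inner-join layers on a shared column
#'
#' Convenience wrapper: loads each named layer and reduces them
#' left-to-right with an inner equi-join on `on`; the join column appears
#' once, and a non-key column name occurring in several layers is
#' disambiguated with a deterministic `.k` suffix (k = 2, 3, ... position
#' of the right-hand layer in `names`).
#'
#' @inheritParams store_layer
#' @param names two or more layer names.
#' @param on join column, present in every named layer.
#' @export
join_layers <- function(stack, names, on) {
  if (length(names) < 2L) omi_join_error("need at least two layers to join")
  for (n in names) {
    assert_layer(stack, n)
    sch <- table_schema(stack$handle, n)
    if (!on %in% names(sch$kinds)) {
      omi_join_error(sprintf("layer '%s' has no column '%s'", n, on))
    }
  }
  out <- load_layer(stack, names[1])
  for (k in seq_along(names)[-1]) {
    out <- dplyr::inner_join(out, load_layer(stack, names[k]),
                             by = on, suffix = c("", paste0(".", k)),
                             relationship = "many-to-many")
  }
  out
}
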