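#' Open a single-file storage engine
#'
#' A store is one embedded SQLite-format database file holding any number of
#' tables. Two physical layouts ("engines") implement the same contract:
#'
#' * `rowstore` — each table is one row-oriented SQL table; favours frequent
#'   small transactions.
#' * `columnstore` — each logical table is decomposed into one physical
#'   table per column (plus a schema registry); whole-column scans touch
#'   only the requested columns' storage, the layout a column-oriented
#'   engine uses.
#'
#' Every operation behaves identically on both engines; only the physical
#' layout (and hence the performance profile) differs. The store is opened
#' for a single writer at a time; concurrent readers are supported.
#'
#' @param path path of the database file; created if absent. The parent
#'   directory must exist.
#' @param engine `"rowstore"` or `"columnstore"`.
#' @return a store handle (also a `DBIConnection` wrapper) to pass to the
#'   table operations.
#' @seealso [create_stack()] for the layer-level user API.
#' @export
open_store <- function(path, engine = c("columnstore", "rowstore")) {
  if (length(engine) == 1L && !engine %in% c("columnstore", "rowstore")) {
    omi_config_error(sprintf(
      "unknown engine '%s' (expected 'rowstore' or 'columnstore')", engine))
  }
  engine <- match.arg(engine)
  if (!dir.exists(dirname(path))) {
    omi_storage_error(sprintf("parent directory of '%s' does not exist", path))
  }
  con <- tryCatch(
    DBI::dbConnect(RSQLite::SQLite(), path, bigint = "integer"),
    error = function(e) omi_storage_error(sprintf("cannot open store '%s': %s",
                                                  path, conditionMessage(e)))
  )
  h <- structure(
    list(con = con, path = path, engine = engine),
    class = c(paste0("omistack_", engine), "omi_store")
  )
  init_store(h)
  h
}

#' Close a store handle
#' @param handle a store handle from [open_store()].
#' @export
close_store <- function(handle) {
  DBI::dbDisconnect(handle$con)
  invisible(NULL)
}

sql_type <- function(kind) switch(kind, integer = "INTEGER", real = "REAL", text = "TEXT")

qid <- function(handle, name) DBI::dbQuoteIdentifier(handle$con, name)

# --- engine-dispatched table contract ---------------------------------------

init_store <- function(handle) UseMethod("init_store")

#' Create a table with a typed schema
#'
#' @param handle store handle.
#' @param name table name; names starting with `_` are reserved for the
#'   internal catalogue and rejected.
#' @param kinds named character vector of column kinds (`integer`, `real`,
#'   `text`) in column order.
#' @param if_exists `"fail"` (default) or `"replace"`.
#' @return invisibly, the handle.
#' @export
create_table <- function(handle, name, kinds, if_exists = c("fail", "replace")) {
  if_exists <- match.arg(if_exists)
  check_identifier(name, "table name")
  check_schema(kinds)
  if (table_exists(handle, name)) {
    if (if_exists == "fail") {
      omi_duplicate_error(sprintf("table '%s' already exists", name))
    }
    drop_table(handle, name)
  }
  log_debug("create_table %s (%s) [%s]", name, paste(kinds, collapse = ","), handle$engine)
  engine_create(handle, name, kinds)
  invisible(handle)
}

#' Append rows to a table in a single transaction
#'
#' All rows are appended or none. The incoming data.frame must have the
#' stored column names in the stored order; integer values widen into real
#' columns, whole-valued doubles narrow into integer columns, anything lossy
#' raises before any write.
#'
#' @inheritParams create_table
#' @param data data.frame conforming to the stored schema.
#' @return number of rows appended.
#' @export
append_rows <- function(handle, name, data) {
  sch <- table_schema(handle, name)
  data <- conform_to_schema(data, sch$kinds)
  if (nrow(data) == 0L) return(0L)
  log_debug("append_rows %s +%d rows [%s]", name, nrow(data), handle$engine)
  engine_append(handle, name, data)
  nrow(data)
}

#' Add new columns to an existing table (positional alignment)
#'
#' The new columns must have exactly as many values as the table has rows;
#' values are aligned to the stored row order.
#'
#' @inheritParams append_rows
#' @return invisibly, the handle.
#' @export
add_columns <- function(handle, name, data) {
  check_typed_table(data)
  if (ncol(data) == 0L) return(invisible(handle))
  sch <- table_schema(handle, name)
  if (nrow(data) != sch$row_count) {
    omi_alignment_error(sprintf(
      "table '%s' has %d rows but new columns have %d values",
      name, sch$row_count, nrow(data)))
  }
  clash <- intersect(tolower(names(data)), tolower(names(sch$kinds)))
  if (length(clash)) {
    omi_schema_error(sprintf("column(s) already present in '%s': %s",
                             name, paste(clash, collapse = ", ")))
  }
  for (n in names(data)) check_identifier(n, "column name")
  log_debug("add_columns %s +%d cols [%s]", name, ncol(data), handle$engine)
  engine_add_columns(handle, name, data)
  invisible(handle)
}

#' Read a whole table
#'
#' Rows come back in insertion order and columns in schema order, with the
#' declared kinds.
#'
#' @inheritParams create_table
#' @export
read_table <- function(handle, name) {
  sch <- table_schema(handle, name)
  engine_read(handle, name, names(sch$kinds), sch$kinds)
}

#' Read a projection of columns
#' @inheritParams create_table
#' @param columns character vector of column names; returned in the
#'   requested order.
#' @export
read_columns <- function(handle, name, columns) {
  sch <- table_schema(handle, name)
  missing <- setdiff(columns, names(sch$kinds))
  if (length(missing)) {
    omi_not_found_error(sprintf("column(s) not in table '%s': %s",
                                name, paste(missing, collapse = ", ")))
  }
  engine_read(handle, name, columns, sch$kinds[columns])
}

#' Read the rows whose value in one column belongs to a set
#'
#' Returns exactly the rows with `column` value in `values`, in stored row
#' order, with the full schema.
#'
#' @inheritParams create_table
#' @param column column to filter on.
#' @param values non-empty vector of values, kind-compatible with `column`.
#' @export
read_where <- function(handle, name, column, values) {
  sch <- table_schema(handle, name)
  if (!column %in% names(sch$kinds)) {
    omi_not_found_error(sprintf("column '%s' not in table '%s'", column, name))
  }
  if (length(values) == 0L) {
    omi_query_error("value set must be non-empty")
  }
  values <- tryCatch(
    coerce_column(values, sch$kinds[[column]], column),
    omi_error = function(e) omi_query_error(sprintf(
      "values are not kind-compatible with column '%s' (%s)", column, sch$kinds[[column]]))
  )
  engine_read_where(handle, name, column, unique(values), sch$kinds)
}

#' Drop a table if it exists
#' @inheritParams create_table
#' @return invisibly, TRUE if a table was dropped, FALSE if absent.
#' @export
drop_table <- function(handle, name) {
  if (!table_exists(handle, name)) return(invisible(FALSE))
  log_debug("drop_table %s [%s]", name, handle$engine)
  engine_drop(handle, name)
  invisible(TRUE)
}

#' List user tables (internal catalogue tables are hidden)
#' @inheritParams create_table
#' @export
list_tables <- function(handle) UseMethod("list_tables")

#' Schema and row count of a table
#' @inheritParams create_table
#' @return list with `kinds` (named character vector) and `row_count`.
#' @export
table_schema <- function(handle, name) {
  sch <- engine_schema(handle, name)
  if (is.null(sch)) {
    omi_not_found_error(sprintf("no table named '%s'", name))
  }
  sch
}

table_exists <- function(handle, name) !is.null(engine_schema(handle, name))

engine_create      <- function(handle, name, kinds) UseMethod("engine_create")
engine_append      <- function(handle, name, data) UseMethod("engine_append")
engine_add_columns <- function(handle, name, data) UseMethod("engine_add_columns")
engine_read        <- function(handle, name, columns, kinds) UseMethod("engine_read")
engine_read_where  <- function(handle, name, column, values, kinds) UseMethod("engine_read_where")
engine_drop        <- function(handle, name) UseMethod("engine_drop")
engine_schema      <- function(handle, name) UseMethod("engine_schema")

# shared: coerce a freshly read data.frame to declared kinds
apply_kinds <- function(df, kinds) {
  stopifnot(identical(names(df), names(kinds)))
  for (i in seq_along(df)) df[[i]] <- coerce_column(df[[i]], kinds[[i]], names(df)[i])
  df
}

# shared: run an IN-set query in chunks to stay under the bound-parameter
# limit; fn(chunk_values) must return a data.frame carrying a `.rid` column.
chunked_in <- function(values, chunk = 500L, fn) {
  idx <- split(values, ceiling(seq_along(values) / chunk))
  parts <- lapply(idx, fn)
  out <- do.call(rbind, c(parts, list(make.row.names = FALSE)))
  out[order(out$.rid), , drop = FALSE]
}
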