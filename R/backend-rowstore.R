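# Row-oriented engine: one physical SQL table per logical table, plus a
# schema registry (_rs_schema) that records declared kinds so reads can
# restore exact column types regardless of SQLite's dynamic typing.
# Insertion order is materialised by the implicit monotone rowid: rows are
# never deleted, so ORDER BY _rowid_ is the stored row order.

#' @exportS3Method omistack::init_store
init_store.omistack_rowstore <- function(handle) {
  DBI::dbExecute(handle$con, paste(
    "CREATE TABLE IF NOT EXISTS \"_rs_schema\"",
    "(tbl TEXT NOT NULL, pos INTEGER NOT NULL, col TEXT NOT NULL, kind TEXT NOT NULL)"
  ))
  invisible(handle)
}

rs_registry <- function(handle, name) {
  DBI::dbGetQuery(handle$con,
    "SELECT pos, col, kind FROM \"_rs_schema\" WHERE tbl = ? ORDER BY pos",
    params = list(name))
}

#' @exportS3Method omistack::engine_schema
engine_schema.omistack_rowstore <- function(handle, name) {
  reg <- rs_registry(handle, name)
  if (nrow(reg) == 0L) return(NULL)
  kinds <- stats::setNames(reg$kind, reg$col)
  n <- DBI::dbGetQuery(handle$con,
    sprintf("SELECT count(*) AS n FROM %s", qid(handle, name)))$n
  list(kinds = kinds, row_count = as.integer(n))
}

#' @exportS3Method omistack::engine_create
engine_create.omistack_rowstore <- function(handle, name, kinds) {
  cols <- paste(
    vapply(names(kinds), function(n) paste(qid(handle, n), sql_type(kinds[[n]])), character(1)),
    collapse = ", ")
  DBI::dbWithTransaction(handle$con, {
    DBI::dbExecute(handle$con, sprintf("CREATE TABLE %s (%s)", qid(handle, name), cols))
    for (i in seq_along(kinds)) {
      DBI::dbExecute(handle$con,
        "INSERT INTO \"_rs_schema\" (tbl, pos, col, kind) VALUES (?, ?, ?, ?)",
        params = list(name, i, names(kinds)[i], kinds[[i]]))
    }
  })
  invisible(handle)
}

#' @exportS3Method omistack::engine_append
engine_append.omistack_rowstore <- function(handle, name, data) {
  DBI::dbWithTransaction(handle$con, {
    DBI::dbAppendTable(handle$con, name, data)
  })
  invisible(handle)
}

#' @exportS3Method omistack::engine_add_columns
engine_add_columns.omistack_rowstore <- function(handle, name, data) {
  kinds <- vapply(data, column_kind, character(1))
  pos0 <- max(rs_registry(handle, name)$pos)
  rids <- DBI::dbGetQuery(handle$con,
    sprintf("SELECT _rowid_ AS rid FROM %s ORDER BY _rowid_", qid(handle, name)))$rid
  DBI::dbWithTransaction(handle$con, {
    for (i in seq_along(data)) {
      cn <- names(data)[i]
      DBI::dbExecute(handle$con, sprintf("ALTER TABLE %s ADD COLUMN %s %s",
        qid(handle, name), qid(handle, cn), sql_type(kinds[[i]])))
      if (length(rids)) {
        DBI::dbExecute(handle$con,
          sprintf("UPDATE %s SET %s = ? WHERE _rowid_ = ?", qid(handle, name), qid(handle, cn)),
          params = list(data[[i]], rids))
      }
      DBI::dbExecute(handle$con,
        "INSERT INTO \"_rs_schema\" (tbl, pos, col, kind) VALUES (?, ?, ?, ?)",
        params = list(name, pos0 + i, cn, kinds[[i]]))
    }
  })
  invisible(handle)
}

#' @exportS3Method omistack::engine_read
engine_read.omistack_rowstore <- function(handle, name, columns, kinds) {
  sel <- paste(vapply(columns, function(c) as.character(qid(handle, c)), character(1)),
               collapse = ", ")
  df <- DBI::dbGetQuery(handle$con,
    sprintf("SELECT %s FROM %s ORDER BY _rowid_", sel, qid(handle, name)))
  names(df) <- columns  # dbGetQuery may mangle unusual identifiers
  apply_kinds(df, kinds)
}

#' @exportS3Method omistack::engine_read_where
engine_read_where.omistack_rowstore <- function(handle, name, column, values, kinds) {
  sel <- paste(vapply(names(kinds), function(c) as.character(qid(handle, c)), character(1)),
               collapse = ", ")
  df <- chunked_in(values, fn = function(v) {
    ph <- paste(rep("?", length(v)), collapse = ", ")
    DBI::dbGetQuery(handle$con,
      sprintf("SELECT _rowid_ AS \".rid\", %s FROM %s WHERE %s IN (%s) ORDER BY _rowid_",
              sel, qid(handle, name), qid(handle, column), ph),
      params = as.list(v))
  })
  df <- df[, setdiff(names(df), ".rid"), drop = FALSE]
  names(df) <- names(kinds)
  apply_kinds(df, kinds)
}

#' @exportS3Method omistack::engine_drop
engine_drop.omistack_rowstore <- function(handle, name) {
  DBI::dbWithTransaction(handle$con, {
    DBI::dbExecute(handle$con, sprintf("DROP TABLE %s", qid(handle, name)))
    DBI::dbExecute(handle$con, "DELETE FROM \"_rs_schema\" WHERE tbl = ?", params = list(name))
  })
  invisible(handle)
}

#' @exportS3Method omistack::list_tables
list_tables.omistack_rowstore <- function(handle) {
  DBI::dbGetQuery(handle$con,
    "SELECT DISTINCT tbl FROM \"_rs_schema\" ORDER BY tbl")$tbl
}
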