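# Column-oriented engine: each logical table is decomposed into one
# physical single-column table per logical column ("_cv_<id>", id assigned
# by the registry), so scans of a column touch only that column's storage
# and new columns are written without rewriting existing data. Row k of a
# logical table is rowid k of every physical column table: appends insert
# into all column tables in the same transaction and rows are never
# deleted, which keeps the rowids aligned and monotone in insertion order.

#' @exportS3Method omistack::init_store
init_store.omistack_columnstore <- function(handle) {
  DBI::dbExecute(handle$con, paste(
    "CREATE TABLE IF NOT EXISTS \"_cs_tables\"",
    "(tbl TEXT PRIMARY KEY, nrows INTEGER NOT NULL)"))
  DBI::dbExecute(handle$con, paste(
    "CREATE TABLE IF NOT EXISTS \"_cs_cols\"",
    "(id INTEGER PRIMARY KEY AUTOINCREMENT, tbl TEXT NOT NULL,",
    " pos INTEGER NOT NULL, col TEXT NOT NULL, kind TEXT NOT NULL)"))
  invisible(handle)
}

cs_cols <- function(handle, name) {
  DBI::dbGetQuery(handle$con,
    "SELECT id, pos, col, kind FROM \"_cs_cols\" WHERE tbl = ? ORDER BY pos",
    params = list(name))
}

cs_phys <- function(id) sprintf("_cv_%d", id)

#' @exportS3Method omistack::engine_schema
engine_schema.omistack_columnstore <- function(handle, name) {
  t <- DBI::dbGetQuery(handle$con,
    "SELECT nrows FROM \"_cs_tables\" WHERE tbl = ?", params = list(name))
  if (nrow(t) == 0L) return(NULL)
  reg <- cs_cols(handle, name)
  list(kinds = stats::setNames(reg$kind, reg$col), row_count = as.integer(t$nrows))
}

#' @exportS3Method omistack::engine_create
engine_create.omistack_columnstore <- function(handle, name, kinds) {
  DBI::dbWithTransaction(handle$con, {
    DBI::dbExecute(handle$con, "INSERT INTO \"_cs_tables\" (tbl, nrows) VALUES (?, 0)",
                   params = list(name))
    for (i in seq_along(kinds)) {
      DBI::dbExecute(handle$con,
        "INSERT INTO \"_cs_cols\" (tbl, pos, col, kind) VALUES (?, ?, ?, ?)",
        params = list(name, i, names(kinds)[i], kinds[[i]]))
      id <- DBI::dbGetQuery(handle$con, "SELECT last_insert_rowid() AS id")$id
      DBI::dbExecute(handle$con, sprintf("CREATE TABLE %s (v %s)",
        qid(handle, cs_phys(id)), sql_type(kinds[[i]])))
    }
  })
  invisible(handle)
}

#' @exportS3Method omistack::engine_append
engine_append.omistack_columnstore <- function(handle, name, data) {
  reg <- cs_cols(handle, name)
  DBI::dbWithTransaction(handle$con, {
    for (i in seq_len(nrow(reg))) {
      DBI::dbExecute(handle$con,
        sprintf("INSERT INTO %s (v) VALUES (?)", qid(handle, cs_phys(reg$id[i]))),
        params = list(data[[reg$col[i]]]))
    }
    DBI::dbExecute(handle$con,
      "UPDATE \"_cs_tables\" SET nrows = nrows + ? WHERE tbl = ?",
      params = list(nrow(data), name))
  })
  invisible(handle)
}

#' @exportS3Method omistack::engine_add_columns
engine_add_columns.omistack_columnstore <- function(handle, name, data) {
  kinds <- vapply(data, column_kind, character(1))
  pos0 <- max(cs_cols(handle, name)$pos)
  DBI::dbWithTransaction(handle$con, {
    for (i in seq_along(data)) {
      DBI::dbExecute(handle$con,
        "INSERT INTO \"_cs_cols\" (tbl, pos, col, kind) VALUES (?, ?, ?, ?)",
        params = list(name, pos0 + i, names(data)[i], kinds[[i]]))
      id <- DBI::dbGetQuery(handle$con, "SELECT last_insert_rowid() AS id")$id
      DBI::dbExecute(handle$con, sprintf("CREATE TABLE %s (v %s)",
        qid(handle, cs_phys(id)), sql_type(kinds[[i]])))
      if (nrow(data)) {
        DBI::dbExecute(handle$con,
          sprintf("INSERT INTO %s (v) VALUES (?)", qid(handle, cs_phys(id))),
          params = list(data[[i]]))
      }
    }
  })
  invisible(handle)
}

#' @exportS3Method omistack::engine_read
engine_read.omistack_columnstore <- function(handle, name, columns, kinds) {
  reg <- cs_cols(handle, name)
  out <- lapply(columns, function(cn) {
    id <- reg$id[reg$col == cn]
    DBI::dbGetQuery(handle$con,
      sprintf("SELECT v FROM %s ORDER BY _rowid_", qid(handle, cs_phys(id))))$v
  })
  names(out) <- columns
  df <- as.data.frame(out, stringsAsFactors = FALSE, check.names = FALSE, optional = TRUE)
  if (length(out) && length(out[[1]]) == 0L) df <- empty_typed_table(kinds)
  apply_kinds(df, kinds)
}

#' @exportS3Method omistack::engine_read_where
engine_read_where.omistack_columnstore <- function(handle, name, column, values, kinds) {
  reg <- cs_cols(handle, name)
  fid <- reg$id[reg$col == column]
  rids <- chunked_in(values, fn = function(v) {
    ph <- paste(rep("?", length(v)), collapse = ", ")
    DBI::dbGetQuery(handle$con,
      sprintf("SELECT _rowid_ AS \".rid\" FROM %s WHERE v IN (%s)",
              qid(handle, cs_phys(fid)), ph),
      params = as.list(v))
  })$`.rid`
  if (length(rids) == 0L) return(empty_typed_table(kinds))
  # materialise the matching row ids once, then join each column against them
  DBI::dbExecute(handle$con, "CREATE TEMP TABLE IF NOT EXISTS \"_rid_filter\" (rid INTEGER PRIMARY KEY)")
  DBI::dbExecute(handle$con, "DELETE FROM \"_rid_filter\"")
  DBI::dbExecute(handle$con, "INSERT INTO \"_rid_filter\" (rid) VALUES (?)",
                 params = list(rids))
  out <- lapply(names(kinds), function(cn) {
    id <- reg$id[reg$col == cn]
    DBI::dbGetQuery(handle$con, sprintf(
      "SELECT t.v FROM %s t JOIN \"_rid_filter\" f ON t._rowid_ = f.rid ORDER BY t._rowid_",
      qid(handle, cs_phys(id))))$v
  })
  names(out) <- names(kinds)
  df <- as.data.frame(out, stringsAsFactors = FALSE, check.names = FALSE, optional = TRUE)
  apply_kinds(df, kinds)
}

#' @exportS3Method omistack::engine_drop
engine_drop.omistack_columnstore <- function(handle, name) {
  reg <- cs_cols(handle, name)
  DBI::dbWithTransaction(handle$con, {
    for (id in reg$id) {
      DBI::dbExecute(handle$con, sprintf("DROP TABLE %s", qid(handle, cs_phys(id))))
    }
    DBI::dbExecute(handle$con, "DELETE FROM \"_cs_cols\" WHERE tbl = ?", params = list(name))
    DBI::dbExecute(handle$con, "DELETE FROM \"_cs_tables\" WHERE tbl = ?", params = list(name))
  })
  invisible(handle)
}

#' @exportS3Method omistack::list_tables
list_tables.omistack_columnstore <- function(handle) {
  DBI::dbGetQuery(handle$con, "SELECT tbl FROM \"_cs_tables\" ORDER BY tbl")$tbl
}
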