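#' Column kinds understood by the storage engines
#'
#' Layers are plain data.frames whose columns belong to one of three kinds:
#' `integer` (R integer), `real` (R double), and `text` (R character).
#' Missing values are allowed in every kind and are stored as SQL NULL.
#'
#' @param x an R vector.
#' @return the kind string for `x`.
#' @keywords internal
column_kind <- function(x) {
  if (is.integer(x)) return("integer")
  if (is.double(x))  return("real")
  if (is.character(x)) return("text")
  # an all-NA logical column carries no type information; treat as text-null
  if (is.logical(x) && all(is.na(x))) return("text")
  omi_schema_error(sprintf("unsupported column type '%s'", class(x)[1]))
}

KINDS <- c("integer", "real", "text")

#' Ordered kind vector (the schema) of a data.frame
#'
#' @param data a data.frame with columns of kind integer, real or text.
#' @return named character vector of kinds, in column order.
#' @export
table_kinds <- function(data) {
  check_typed_table(data)
  vapply(data, column_kind, character(1))
}

# Validate the rectangular typed-table contract: a data.frame, >=1 column
# unless allow_empty, unique names after case-folding, supported types.
check_typed_table <- function(data, allow_zero_cols = TRUE) {
  if (!is.data.frame(data)) {
    omi_schema_error("layer data must be a data.frame")
  }
  if (!allow_zero_cols && ncol(data) == 0L) {
    omi_schema_error("layer data must have at least one column")
  }
  nm <- names(data)
  if (ncol(data) > 0L) {
    if (is.null(nm) || any(!nzchar(nm))) {
      omi_schema_error("all columns must be named")
    }
    folded <- tolower(nm)
    if (anyDuplicated(folded)) {
      omi_schema_error(sprintf(
        "duplicate column names after case-folding: %s",
        paste(unique(nm[duplicated(folded)]), collapse = ", ")
      ))
    }
    for (i in seq_along(data)) column_kind(data[[i]])
  }
  invisible(data)
}

check_schema <- function(kinds) {
  if (length(kinds) < 1L) omi_schema_error("schema must have at least one column")
  nm <- names(kinds)
  if (is.null(nm) || any(!nzchar(nm))) omi_schema_error("schema columns must be named")
  if (anyDuplicated(tolower(nm))) omi_schema_error("schema column names must be unique (case-insensitive)")
  bad <- setdiff(unique(kinds), KINDS)
  if (length(bad)) {
    omi_schema_error(sprintf("unknown column kind(s): %s", paste(bad, collapse = ", ")))
  }
  for (n in nm) check_identifier(n, what = "column name")
  invisible(kinds)
}

# Identifiers are quoted everywhere, so dots/dashes in gene or metabolite IDs
# are fine; we only reject what quoting cannot make safe plus the reserved
# underscore prefix used by the internal catalogue tables.
check_identifier <- function(name, what = "name", allow_reserved = FALSE) {
  if (length(name) != 1L || is.na(name) || !nzchar(name)) {
    omi_naming_error(sprintf("%s must be a non-empty string", what))
  }
  if (grepl('["`\\\\]|[[:cntrl:]]', name)) {
    omi_naming_error(sprintf("%s '%s' contains characters that cannot be stored safely", what, name))
  }
  if (!allow_reserved && startsWith(name, "_")) {
    omi_naming_error(sprintf("%s '%s' is reserved (leading underscore)", what, name))
  }
  invisible(name)
}

# 0-row data.frame with the given kinds.
empty_typed_table <- function(kinds) {
  cols <- lapply(unname(kinds), function(k) {
    switch(k, integer = integer(0), real = double(0), text = character(0))
  })
  names(cols) <- names(kinds)
  as.data.frame(cols, stringsAsFactors = FALSE, check.names = FALSE, optional = TRUE)
}

# Coerce a column read back from SQL (or supplied by a user) to its declared
# kind, erroring on lossy coercions (text into a numeric column, fractional
# values into an integer column).
coerce_column <- function(x, kind, col = "<column>") {
  if (is.logical(x) && all(is.na(x))) {
    x <- switch(kind, integer = as.integer(x), real = as.double(x), text = as.character(x))
    return(x)
  }
  ok <- switch(kind,
    integer = {
      if (is.integer(x)) TRUE
      else if (is.double(x) && all(is.na(x) | (is.finite(x) & x == trunc(x)))) {
        x <- as.integer(x); TRUE
      } else FALSE
    },
    real = {
      if (is.double(x)) TRUE
      else if (is.integer(x)) { x <- as.double(x); TRUE }
      else FALSE
    },
    text = {
      if (is.character(x)) TRUE else FALSE
    }
  )
  if (!ok) {
    omi_append_error(sprintf(
      "column '%s': cannot coerce %s values to kind '%s' without loss",
      col, class(x)[1], kind
    ))
  }
  x
}

# Check an incoming data.frame against a stored schema (same names, same
# order) and coerce compatible kinds; any failure raises before a write.
conform_to_schema <- function(data, kinds) {
  check_typed_table(data)
  if (!identical(names(data), names(kinds))) {
    omi_append_error(sprintf(
      "column names/order mismatch: stored (%s) vs supplied (%s)",
      paste(names(kinds), collapse = ","), paste(names(data), collapse = ",")
    ))
  }
  for (i in seq_along(data)) {
    data[[i]] <- coerce_column(data[[i]], kinds[[i]], names(data)[i])
  }
  data
}
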