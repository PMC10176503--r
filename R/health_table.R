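#' @keywords internal
"_PACKAGE"

# Canonical missing marker: R's NA. It is out-of-band, so the literal string
# "NA" remains representable as a category label; serialisation writes NA as
# "NA" (see export_dataset).

#' Construct a health table
#'
#' A `health_table` is the package's container for a rectangular
#' patient-by-variable dataset: one row per record, one column per variable,
#' a designated record-identifier column, and per-variable metadata
#' (see [variable_meta()]). Cells hold numbers, category labels, free text,
#' or the canonical missing marker (`NA`).
#'
#' @param data data.frame; one row per record. Columns may be character or
#'   numeric. Must contain `id_column`.
#' @param id_column name of the record-identifier column. Its values must be
#'   unique and non-missing.
#' @param meta optional named list of [variable_meta()] entries, one per
#'   column. Missing entries are initialised with an unset type.
#' @return an object of class `health_table`.
#' @export
health_table <- function(data, id_column, meta = NULL) {
  if (!is.data.frame(data)) stop("`data` must be a data.frame", call. = FALSE)
  if (!id_column %in% names(data)) {
    stop(sprintf("id column '%s' not found in data", id_column), call. = FALSE)
  }
  ids <- as.character(data[[id_column]])
  if (anyNA(ids)) stop("record identifiers must not be missing", call. = FALSE)
  dup <- unique(ids[duplicated(ids)])
  if (length(dup)) {
    stop(sprintf("duplicate record identifier(s): %s",
                 paste(dup, collapse = ", ")), call. = FALSE)
  }
  data[[id_column]] <- ids
  rownames(data) <- NULL
  if (is.null(meta)) meta <- list()
  for (v in names(data)) {
    if (is.null(meta[[v]])) {
      meta[[v]] <- variable_meta(
        name = v,
        vtype = if (v == id_column) "identifier" else NA_character_
      )
    }
  }
  meta <- meta[names(data)]
  structure(
    list(data = data, id_column = id_column, meta = meta),
    class = "health_table"
  )
}

#' Variable metadata entry
#'
#' Describes one variable's semantic characteristics: its type, the data
#' modality it belongs to (e.g. "clinical pathology"), the ordered levels if
#' ordinal, and whether the assignment was inferred or user-reviewed.
#'
#' @param name variable name.
#' @param vtype one of `"continuous"`, `"integer"`, `"ordinal"`,
#'   `"nominal_binary"`, `"nominal_multi"`, `"free_text"`, `"identifier"`,
#'   or `NA` (unset).
#' @param modality free-text modality label.
#' @param ordinal_levels character vector of ordered levels; required iff
#'   `vtype == "ordinal"`; must be non-empty and duplicate-free.
#' @param source `"inferred"` or `"user"`.
#' @return a list of class `variable_meta`.
#' @export
variable_meta <- function(name, vtype = NA_character_, modality = NA_character_,
                          ordinal_levels = NULL, source = "inferred") {
  ok <- c("continuous", "integer", "ordinal", "nominal_binary",
          "nominal_multi", "free_text", "identifier")
  if (!is.na(vtype) && !vtype %in% ok) {
    stop(sprintf("unknown variable type '%s'", vtype), call. = FALSE)
  }
  if (identical(vtype, "ordinal")) {
    if (is.null(ordinal_levels) || !length(ordinal_levels)) {
      stop(sprintf("ordinal variable '%s' requires non-empty ordinal_levels",
                   name), call. = FALSE)
    }
    if (anyDuplicated(ordinal_levels)) {
      stop(sprintf("ordinal_levels for '%s' contain duplicates", name),
           call. = FALSE)
    }
    ordinal_levels <- as.character(ordinal_levels)
  } else {
    ordinal_levels <- NULL
  }
  structure(
    list(name = name, vtype = vtype, modality = modality,
         ordinal_levels = ordinal_levels, source = source),
    class = "variable_meta"
  )
}

#' Variable names of a health table
#'
#' @param x a `health_table`.
#' @param include_id include the record-identifier column? Default `FALSE`:
#'   analysis operations act on the non-identifier variables.
#' @return character vector of variable names.
#' @export
variables <- function(x, include_id = FALSE) {
  stopifnot(inherits(x, "health_table"))
  v <- names(x$data)
  if (!include_id) v <- setdiff(v, x$id_column)
  v
}

#' Record identifiers of a health table
#' @param x a `health_table`.
#' @return character vector of record ids, in row order.
#' @export
record_ids <- function(x) {
  stopifnot(inherits(x, "health_table"))
  x$data[[x$id_column]]
}

#' Extract the values of one variable
#' @param x a `health_table`.
#' @param variable variable name.
#' @return the column vector (character or numeric), `NA` marking missing.
#' @export
ht_values <- function(x, variable) {
  stopifnot(inherits(x, "health_table"))
  if (!variable %in% names(x$data)) {
    stop(sprintf("variable '%s' not found", variable), call. = FALSE)
  }
  x$data[[variable]]
}

ht_set <- function(x, variable, values, meta = NULL) {
  x$data[[variable]] <- values
  if (!is.null(meta)) {
    x$meta[[variable]] <- meta
  } else if (is.null(x$meta[[variable]])) {
    x$meta[[variable]] <- variable_meta(variable)
  }
  x$meta <- x$meta[names(x$data)]
  x
}

ht_drop <- function(x, vars) {
  keep <- setdiff(names(x$data), setdiff(vars, x$id_column))
  x$data <- x$data[, keep, drop = FALSE]
  x$meta <- x$meta[keep]
  x
}

#' @export
dim.health_table <- function(x) dim(x$data)

#' @export
as.data.frame.health_table <- function(x, ...) x$data

#' @export
print.health_table <- function(x, ...) {
  nv <- length(variables(x))
  cat(sprintf("<health_table> %d records x %d variables (id: %s)\n",
              nrow(x$data), nv, x$id_column))
  typed <- vapply(x$meta[variables(x)],
                  function(m) !is.na(m$vtype), logical(1))
  cat(sprintf("  typed variables: %d / %d\n", sum(typed), nv))
  invisible(x)
}

#' @export
summary.health_table <- function(object, ...) {
  vt <- vapply(object$meta[variables(object)],
               function(m) if (is.na(m$vtype)) "unset" else m$vtype,
               character(1))
  comp <- vapply(variables(object), function(v) {
    mean(!is.na(object$data[[v]]))
  }, numeric(1))
  out <- data.frame(
    variable = variables(object),
    vtype = unname(vt),
    completeness = unname(comp),
    stringsAsFactors = FALSE
  )
  rownames(out) <- NULL
  out
}

#' Import a delimited dataset as a health table
#'
#' Reads an RFC-4180 CSV or TSV file (UTF-8, header row, one record per row)
#' into a [health_table()]. All cells are kept as raw strings except exact
#' occurrences of `na_token`, which become the canonical missing marker.
#' Variable metadata is initialised with unset types; see
#' [infer_variable_types()].
#'
#' @param path file path.
#' @param format `"csv"` or `"tsv"`.
#' @param id_column name of the record-identifier column.
#' @param na_token string read as missing (default `"NA"`).
#' @return a `health_table`.
#' @export
import_dataset <- function(path, format = c("csv", "tsv"), id_column,
                           na_token = "NA") {
  format <- match.arg(format)
  sep <- if (format == "csv") "," else "\t"
  df <- utils::read.table(
    path, header = TRUE, sep = sep, quote = "\"",
    colClasses = "character", na.strings = na_token,
    check.names = FALSE, comment.char = "", stringsAsFactors = FALSE,
    encoding = "UTF-8"
  )
  if (!id_column %in% names(df)) {
    stop(sprintf("id column '%s' not present in %s", id_column, path),
         call. = FALSE)
  }
  health_table(df, id_column)
}

#' Export a health table to delimited text
#'
#' Writes the table back out as CSV or TSV; the canonical missing marker is
#' serialised as `"NA"`. Together with [import_dataset()] this round-trips
#' cells and missing markers exactly (provided no category label is the
#' literal string `"NA"`).
#'
#' @param x a `health_table`.
#' @param path output file path.
#' @param format `"csv"` or `"tsv"`.
#' @return `path`, invisibly.
#' @export
export_dataset <- function(x, path, format = c("csv", "tsv")) {
  stopifnot(inherits(x, "health_table"))
  format <- match.arg(format)
  sep <- if (format == "csv") "," else "\t"
  utils::write.table(
    x$data, path, sep = sep, na = "NA", row.names = FALSE,
    col.names = TRUE, qmethod = "double", fileEncoding = "UTF-8"
  )
  invisible(path)
}

# numeric parse helper: returns numeric vector with NA where unparseable
parse_num <- function(x) {
  if (is.numeric(x)) return(x)
  suppressWarnings(as.numeric(x))
}

# TRUE iff every non-missing value parses as a number
all_numeric_values <- function(x) {
  v <- x[!is.na(x)]
  if (!length(v)) return(TRUE)
  !anyNA(parse_num(v))
}
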