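# Semantic characterisation: automatic variable typing plus mandatory user
# review. Ordinal types are never inferred automatically because the level
# order is domain knowledge only the user holds.

#' Infer variable types heuristically
#'
#' Assigns a provisional type to every non-identifier variable:
#' all values parse as numbers -> `continuous` (or `integer` when all values
#' are whole numbers); at most two distinct non-missing values ->
#' `nominal_binary`; mean whitespace-token count per non-missing cell above
#' `freetext_token_threshold` -> `free_text`; otherwise `nominal_multi`
#' (variables with more than `max_levels_nominal` levels are still reported
#' as `nominal_multi` and left to user review). Ordinal types are never
#' inferred. Inference is deterministic given the thresholds.
#'
#' @param table a [health_table()].
#' @param max_levels_nominal level count above which a categorical variable
#'   is worth a review warning (default 10).
#' @param freetext_token_threshold mean tokens per cell above which a
#'   variable is typed as free text (default 3).
#' @return named list of [variable_meta()] entries (`source = "inferred"`),
#'   one per variable including the identifier.
#' @export
infer_variable_types <- function(table, max_levels_nominal = 10,
                                 freetext_token_threshold = 3) {
  stopifnot(inherits(table, "health_table"))
  if (nrow(table$data) == 0 || length(variables(table)) == 0) {
    stop("cannot infer types for an empty table", call. = FALSE)
  }
  meta <- list()
  for (v in names(table$data)) {
    if (v == table$id_column) {
      meta[[v]] <- variable_meta(v, "identifier", source = "inferred")
      next
    }
    vals <- table$data[[v]]
    obs <- vals[!is.na(vals)]
    obs <- as.character(obs)
    vtype <- if (length(obs) && all_numeric_values(obs)) {
      num <- parse_num(obs)
      if (all(num == trunc(num))) "integer" else "continuous"
    } else if (length(unique(obs)) <= 2) {
      "nominal_binary"
    } else {
      ntok <- lengths(strsplit(trimws(obs), "[[:space:]]+"))
      if (mean(ntok) > freetext_token_threshold) "free_text" else "nominal_multi"
    }
    m <- variable_meta(v, vtype, source = "inferred")
    if (vtype == "nominal_multi" &&
        length(unique(obs)) > max_levels_nominal) {
      m$review_note <- sprintf("%d levels exceeds max_levels_nominal = %d",
                               length(unique(obs)), max_levels_nominal)
    }
    meta[[v]] <- m
  }
  meta
}

#' Apply user review to inferred variable metadata
#'
#' Replaces inferred metadata fields with user-supplied overrides and marks
#' those entries `source = "user"`. Overrides may change `vtype`, `modality`
#' and `ordinal_levels`. When `table` is supplied, ordinal overrides are
#' validated: the declared levels must cover every observed non-missing
#' label.
#'
#' @param meta named list of [variable_meta()], as returned by
#'   [infer_variable_types()].
#' @param overrides named list: variable -> list of fields to replace
#'   (`vtype`, `modality`, `ordinal_levels`).
#' @param table optional [health_table()] used to validate ordinal level
#'   coverage.
#' @return the reviewed metadata list.
#' @export
apply_user_review <- function(meta, overrides, table = NULL) {
  if (!length(overrides)) return(meta)
  unknown <- setdiff(names(overrides), names(meta))
  if (length(unknown)) {
    stop(sprintf("override(s) for unknown variable(s): %s",
                 paste(unknown, collapse = ", ")), call. = FALSE)
  }
  for (v in names(overrides)) {
    o <- overrides[[v]]
    m <- meta[[v]]
    vtype <- if (!is.null(o$vtype)) o$vtype else m$vtype
    levels <- if (!is.null(o$ordinal_levels)) as.character(o$ordinal_levels)
              else m$ordinal_levels
    modality <- if (!is.null(o$modality)) o$modality else m$modality
    m2 <- variable_meta(v, vtype, modality = modality,
                        ordinal_levels = levels, source = "user")
    if (identical(vtype, "ordinal") && !is.null(table)) {
      obs <- table$data[[v]]
      obs <- unique(as.character(obs[!is.na(obs)]))
      uncovered <- setdiff(obs, m2$ordinal_levels)
      if (length(uncovered)) {
        stop(sprintf(
          "ordinal levels for '%s' omit observed label(s): %s",
          v, paste(sort(uncovered), collapse = ", ")), call. = FALSE)
      }
    }
    meta[[v]] <- m2
  }
  meta
}

#' Set the variable metadata of a health table
#'
#' @param table a [health_table()].
#' @param meta named list of [variable_meta()] covering every variable.
#' @return the table with metadata attached.
#' @export
set_variable_meta <- function(table, meta) {
  stopifnot(inherits(table, "health_table"))
  missing <- setdiff(names(table$data), names(meta))
  if (length(missing)) {
    stop(sprintf("metadata missing for variable(s): %s",
                 paste(missing, collapse = ", ")), call. = FALSE)
  }
  table$meta <- meta[names(table$data)]
  table
}
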