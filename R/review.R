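# Quality review: tracking and summarising the effect of QC operations on
# the dataset (what changed, for whom, and by how much).

# canonical cell representation for comparison: numbers formatted to 12
# significant digits so float noise never counts as a substitution
canon_cell <- function(x) {
  out <- as.character(x)
  num <- parse_num(x)
  isnum <- !is.na(num)
  out[isnum] <- formatC(num[isnum], digits = 12, format = "g")
  out
}

#' Comparative tally of value combinations before and after a change
#'
#' Counts the unique combinations of values taken by the chosen variables
#' in the before and after tables, aligning combination counts side by
#' side. Missing values appear as the label `<MISSING>`.
#'
#' @param before,after [health_table()] objects sharing record ids.
#' @param variables character vector of variables to tally (must be
#'   present in at least one of the tables; non-empty).
#' @return data.frame with one column per variable plus `before_n` and
#'   `after_n`.
#' @export
count_compare <- function(before, after, variables) {
  stopifnot(inherits(before, "health_table"),
            inherits(after, "health_table"))
  if (!length(variables)) {
    stop("`variables` must be non-empty", call. = FALSE)
  }
  absent <- variables[!(variables %in% names(before$data) |
                          variables %in% names(after$data))]
  if (length(absent)) {
    stop(sprintf("variable(s) absent from both tables: %s",
                 paste(absent, collapse = ", ")), call. = FALSE)
  }
  combo <- function(tab) {
    cols <- lapply(variables, function(v) {
      if (v %in% names(tab$data)) {
        x <- as.character(tab$data[[v]])
        ifelse(is.na(x), "<MISSING>", x)
      } else rep("<ABSENT>", nrow(tab$data))
    })
    key <- do.call(paste, c(cols, sep = "\x1f"))
    table(key)
  }
  tb <- combo(before)
  ta <- combo(after)
  keys <- sort(unique(c(names(tb), names(ta))))
  parts <- do.call(rbind, strsplit(keys, "\x1f", fixed = TRUE))
  out <- as.data.frame(parts, stringsAsFactors = FALSE)
  names(out) <- variables
  out$before_n <- as.integer(ifelse(keys %in% names(tb), tb[keys], 0))
  out$after_n <- as.integer(ifelse(keys %in% names(ta), ta[keys], 0))
  rownames(out) <- NULL
  out
}

#' Track cell-level modifications between two dataset versions
#'
#' Classifies every cell shared between the two tables (intersection of
#' record ids and of variable names) as `unchanged`, `substitution` (both
#' values present but different), `removal` (value became missing) or
#' `addition` (missing value became present). Numeric values are compared
#' after canonical formatting to 12 significant digits. Per record, the
#' four kinds partition the compared cells, so their percentages sum
#' to 100.
#'
#' @param before,after [health_table()] objects with overlapping record
#'   ids.
#' @return list with `modifications` (data.frame record_id / variable /
#'   before / after / kind for every non-unchanged cell) and `per_record`
#'   (data.frame of percentages per kind, one row per shared record).
#' @export
track_modifications <- function(before, after) {
  stopifnot(inherits(before, "health_table"),
            inherits(after, "health_table"))
  ids <- intersect(record_ids(before), record_ids(after))
  if (!length(ids)) {
    stop("before and after tables share no record ids", call. = FALSE)
  }
  vars <- intersect(variables(before), variables(after))
  ib <- match(ids, record_ids(before))
  ia <- match(ids, record_ids(after))
  n <- length(ids)
  counts <- matrix(0L, n, 4,
                   dimnames = list(ids, c("unchanged", "substitution",
                                          "removal", "addition")))
  mods <- list()
  for (v in vars) {
    b <- canon_cell(before$data[[v]])[ib]
    a <- canon_cell(after$data[[v]])[ia]
    kind <- ifelse(is.na(b) & is.na(a), "unchanged",
            ifelse(is.na(b), "addition",
            ifelse(is.na(a), "removal",
            ifelse(b == a, "unchanged", "substitution"))))
    for (k in colnames(counts)) counts[, k] <- counts[, k] + (kind == k)
    chg <- kind != "unchanged"
    if (any(chg)) {
      mods[[length(mods) + 1L]] <- data.frame(
        record_id = ids[chg], variable = v,
        before = b[chg], after = a[chg], kind = kind[chg],
        stringsAsFactors = FALSE
      )
    }
  }
  total <- length(vars)
  per_record <- data.frame(
    record_id = ids,
    100 * counts / max(total, 1),
    check.names = FALSE, stringsAsFactors = FALSE
  )
  rownames(per_record) <- NULL
  mods_df <- if (length(mods)) do.call(rbind, mods) else
    data.frame(record_id = character(0), variable = character(0),
               before = character(0), after = character(0),
               kind = character(0), stringsAsFactors = FALSE)
  rownames(mods_df) <- NULL
  list(modifications = mods_df, per_record = per_record,
       n_compared_cells = n * total)
}

#' Compare variable completeness before and after QC
#'
#' @param before,after [health_table()] objects.
#' @param threshold completeness threshold reported on (default 0.95).
#' @return list with the two per-variable completeness vectors, the mean
#'   delta (after minus before), and counts of variables above the
#'   threshold in each table.
#' @export
compare_completeness <- function(before, after, threshold = 0.95) {
  cb <- assess_completeness(before)$variable_completeness
  ca <- assess_completeness(after)$variable_completeness
  list(
    before = cb,
    after = ca,
    mean_delta = mean(ca) - mean(cb),
    n_above_threshold_before = sum(cb > threshold),
    n_above_threshold_after = sum(ca > threshold),
    threshold = threshold
  )
}

#' Variables added and removed between two dataset versions
#'
#' Names are compared literally; a renamed variable appears in both lists.
#'
#' @param before,after [health_table()] objects.
#' @return list with `added` and `removed` character vectors.
#' @export
variable_diff <- function(before, after) {
  vb <- variables(before)
  va <- variables(after)
  list(added = sort(setdiff(va, vb)), removed = sort(setdiff(vb, va)))
}

#' Write a combined quality report in markdown
#'
#' Summarises completeness, zero-entropy variables, inconsistency
#' findings, cell-level modifications and the variable diff into a single
#' human-readable report.
#'
#' @param before,after [health_table()] objects (as imported and after
#'   QC).
#' @param path output markdown file path.
#' @param inconsistencies optional data.frame from
#'   [identify_inconsistency()].
#' @param zero_entropy optional character vector of flagged variables.
#' @param threshold completeness threshold (default 0.95).
#' @return `path`, invisibly.
#' @export
write_quality_report <- function(before, after, path,
                                 inconsistencies = NULL,
                                 zero_entropy = NULL, threshold = 0.95) {
  cc <- compare_completeness(before, after, threshold)
  tm <- track_modifications(before, after)
  vd <- variable_diff(before, after)
  kinds <- c("substitution", "removal", "addition")
  kind_totals <- vapply(kinds, function(k)
    sum(tm$modifications$kind == k), integer(1))
  md <- c(
    "# Data quality report", "",
    "## Completeness", "",
    sprintf("- Mean variable completeness before: %.1f%%",
            100 * mean(cc$before)),
    sprintf("- Mean variable completeness after: %.1f%%",
            100 * mean(cc$after)),
    sprintf("- Mean change: %+.2f percentage points", 100 * cc$mean_delta),
    sprintf("- Variables above %.0f%% complete: %d before, %d after",
            100 * threshold, cc$n_above_threshold_before,
            cc$n_above_threshold_after), "",
    "## Zero-entropy variables", "",
    if (length(zero_entropy)) paste0("- ", zero_entropy) else "- none", "",
    "## Internal consistency", "",
    if (!is.null(inconsistencies)) {
      sprintf("- %d inconsistent (record, rule) pair(s) found",
              nrow(inconsistencies))
    } else "- no rules applied", "",
    "## Modifications", "",
    sprintf("- Compared cells: %d", tm$n_compared_cells),
    sprintf("- %s: %d", names(kind_totals), kind_totals), "",
    "## Variable diff", "",
    sprintf("- Added (%d): %s", length(vd$added),
            if (length(vd$added)) paste(vd$added, collapse = ", ")
            else "none"),
    sprintf("- Removed (%d): %s", length(vd$removed),
            if (length(vd$removed)) paste(vd$removed, collapse = ", ")
            else "none")
  )
  writeLines(md, path)
  invisible(path)
}
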