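# Semantic enrichment: dataset variables are attached to an ontology DAG
# (child -> parent is_a edges), variable sets sharing common ancestors are
# discovered, each set is labelled by its most informative common ancestor
# (MICA), and row-wise aggregations of each set are appended as
# meta-variables after zero-entropy filtering.

#' Load an ontology from a child-parent edge table
#'
#' Reads CSV columns `child`, `parent` (entity ids) into a directed
#' ontology graph. Multiple roots are allowed (a forest); self-loops and
#' cycles are errors.
#'
#' @param path CSV file path, or a data.frame with `child` and `parent`
#'   columns.
#' @param labels optional CSV path or data.frame with columns `id`,
#'   `label` giving human-readable node labels.
#' @return an `igraph` object with vertex attributes `kind`
#'   (`"ontology"`) and `label`.
#' @export
load_ontology_edges <- function(path, labels = NULL) {
  edges <- if (is.data.frame(path)) path else {
    utils::read.csv(path, colClasses = "character", check.names = FALSE)
  }
  if (!all(c("child", "parent") %in% names(edges))) {
    stop("ontology edge table requires columns 'child' and 'parent'",
         call. = FALSE)
  }
  edges$child <- as.character(edges$child)
  edges$parent <- as.character(edges$parent)
  self <- edges$child == edges$parent
  if (any(self)) {
    stop(sprintf("self-loop edge(s): %s",
                 paste(unique(edges$child[self]), collapse = ", ")),
         call. = FALSE)
  }
  g <- igraph::graph_from_data_frame(
    edges[, c("child", "parent")], directed = TRUE
  )
  if (!igraph::is_dag(g)) {
    comp <- igraph::components(g, mode = "strong")
    cyc <- names(comp$membership)[comp$membership ==
                                    which(comp$csize > 1)[1]]
    stop(sprintf("ontology contains a cycle through: %s",
                 paste(sort(cyc), collapse = " -> ")), call. = FALSE)
  }
  igraph::V(g)$kind <- "ontology"
  lab <- igraph::V(g)$name
  if (!is.null(labels)) {
    ldf <- if (is.data.frame(labels)) labels else {
      utils::read.csv(labels, colClasses = "character", check.names = FALSE)
    }
    idx <- match(igraph::V(g)$name, ldf$id)
    lab[!is.na(idx)] <- ldf$label[idx[!is.na(idx)]]
  }
  igraph::V(g)$label <- lab
  g
}

#' Attach dataset variables to an ontology graph
#'
#' Adds one node per mapped variable (`kind = "variable"`) with a mapping
#' edge to each ontology entity it maps to, forming the ontology:variable
#' network. Variables mapped to several entities get several edges.
#' Dataset variables absent from the mapping are simply not part of the
#' network (e.g. negative-finding indicators that have no ontology
#' equivalent).
#'
#' @param graph ontology graph from [load_ontology_edges()].
#' @param mappings CSV path or data.frame with columns `variable`,
#'   `entity_id` (long form; multiple rows per variable allowed).
#' @return the augmented `igraph` object.
#' @export
attach_variable_mappings <- function(graph, mappings) {
  mdf <- if (is.data.frame(mappings)) mappings else {
    utils::read.csv(mappings, colClasses = "character", check.names = FALSE)
  }
  if (!all(c("variable", "entity_id") %in% names(mdf))) {
    stop("mapping table requires columns 'variable' and 'entity_id'",
         call. = FALSE)
  }
  onto <- igraph::V(graph)$name[igraph::V(graph)$kind == "ontology"]
  unknown <- setdiff(unique(mdf$entity_id), onto)
  if (length(unknown)) {
    stop(sprintf("mapping(s) to unknown ontology entit(ies): %s",
                 paste(sort(unknown), collapse = ", ")), call. = FALSE)
  }
  vars <- unique(mdf$variable)
  clash <- intersect(vars, igraph::V(graph)$name)
  if (length(clash)) {
    stop(sprintf("variable name(s) collide with ontology ids: %s",
                 paste(clash, collapse = ", ")), call. = FALSE)
  }
  graph <- igraph::add_vertices(graph, length(vars), name = vars,
                                kind = "variable", label = vars)
  graph <- igraph::add_edges(
    graph, as.vector(rbind(mdf$variable, mdf$entity_id))
  )
  graph
}

ontology_nodes <- function(graph) {
  igraph::V(graph)$name[igraph::V(graph)$kind == "ontology"]
}

variable_nodes <- function(graph) {
  igraph::V(graph)$name[igraph::V(graph)$kind == "variable"]
}

# depth = longest root-to-node path in nodes (roots have depth 1), over the
# ontology subgraph only; computed by DP over a topological order
node_depths <- function(graph) {
  og <- igraph::induced_subgraph(
    graph, igraph::V(graph)[igraph::V(graph)$kind == "ontology"]
  )
  ord <- igraph::topo_sort(og, mode = "in")  # parents before children
  depth <- stats::setNames(rep(1L, igraph::vcount(og)),
                           igraph::V(og)$name)
  for (v in ord) {
    parents <- igraph::neighbors(og, v, mode = "out")
    if (length(parents)) {
      depth[igraph::V(og)$name[v]] <-
        1L + max(depth[igraph::V(og)$name[parents]])
    }
  }
  depth
}

#' Node information content of an ontology
#'
#' Quantifies each ontology node's specificity from its depth and its
#' relative number of descendants:
#' \deqn{IC(c) = k\left(1 - \frac{\ln(hypo(c)+1)}{\ln N}\right) +
#'   (1-k)\frac{\ln(depth(c))}{\ln(depth_{max})}}
#' where `hypo(c)` is the number of ontology descendants of `c` (variable
#' nodes excluded), `N` the number of ontology nodes, `depth(c)` the
#' longest root-to-node path length in nodes (roots have depth 1), and
#' `depth_max` the maximum depth. Roots have IC 0; a childless node at
#' maximum depth has IC 1. A single-node ontology has IC 0.
#'
#' @param graph ontology(:variable) graph.
#' @param k weight of the descendants term, in \[0, 1\] (default 0.5).
#' @return named numeric vector of IC values in \[0, 1\], plus attributes
#'   `depth` and `hypo`.
#' @export
node_information_content <- function(graph, k = 0.5) {
  if (!is.numeric(k) || k < 0 || k > 1) {
    stop("k must lie in [0, 1]", call. = FALSE)
  }
  onto <- ontology_nodes(graph)
  n_onto <- length(onto)
  if (!n_onto) stop("ontology is empty", call. = FALSE)
  depth <- node_depths(graph)
  depth_max <- max(depth)
  hypo <- vapply(onto, function(v) {
    desc <- igraph::subcomponent(graph, v, mode = "in")
    sum(igraph::V(graph)$kind[desc] == "ontology") - 1L
  }, numeric(1))
  term_hypo <- if (n_onto > 1) 1 - log(hypo + 1) / log(n_onto) else
    rep(0, n_onto)
  term_depth <- if (depth_max > 1) log(depth[onto]) / log(depth_max) else
    rep(0, n_onto)
  ic <- k * term_hypo + (1 - k) * term_depth
  ic <- stats::setNames(pmin(pmax(ic, 0), 1), onto)
  attr(ic, "depth") <- depth
  attr(ic, "hypo") <- stats::setNames(hypo, onto)
  ic
}

# variable-descendant set per ontology node: variables mapped to the node
# itself or to any of its ontology descendants
variable_descendant_sets <- function(graph) {
  onto <- ontology_nodes(graph)
  vars <- variable_nodes(graph)
  out <- vector("list", length(onto))
  names(out) <- onto
  for (v in onto) {
    desc <- igraph::subcomponent(graph, v, mode = "in")
    nm <- igraph::V(graph)$name[desc]
    out[[v]] <- sort(intersect(nm, vars))
  }
  out
}

#' Identify variable sets and their most informative common ancestors
#'
#' For each ontology node the set of variables among its descendants is
#' computed; sets with at least two variables are retained and ontology
#' nodes carrying the identical variable set are grouped as that set's
#' common ancestors. Each set is labelled by its MICA: the common ancestor
#' with maximal information content (ties broken by greater depth, then
#' lexicographically smaller id).
#'
#' @param graph ontology:variable graph from [attach_variable_mappings()].
#' @param node_ic output of [node_information_content()].
#' @return list of `variable_set` objects: `variables`,
#'   `common_ancestors`, `mica`, `mica_label`, `mica_ic`. Ordered by
#'   decreasing set size then MICA id.
#' @export
identify_variable_sets <- function(graph, node_ic) {
  if (length(variable_nodes(graph)) < 2) {
    stop("at least two mapped variables are required", call. = FALSE)
  }
  depth <- attr(node_ic, "depth")
  vsets <- variable_descendant_sets(graph)
  vsets <- vsets[lengths(vsets) >= 2]
  if (!length(vsets)) return(list())
  keys <- vapply(vsets, paste, character(1), collapse = "\x1f")
  groups <- split(names(vsets), keys)
  labels <- stats::setNames(igraph::V(graph)$label, igraph::V(graph)$name)
  out <- lapply(groups, function(anc) {
    ic <- node_ic[anc]
    best <- anc[order(-ic, -depth[anc], anc)][1]
    structure(
      list(variables = vsets[[best]],
           common_ancestors = sort(anc),
           mica = best,
           mica_label = unname(labels[best]),
           mica_ic = unname(node_ic[best])),
      class = "variable_set"
    )
  })
  names(out) <- NULL
  ord <- order(-vapply(out, function(s) length(s$variables), numeric(1)),
               vapply(out, function(s) s$mica, character(1)))
  out[ord]
}

#' @export
print.variable_set <- function(x, ...) {
  cat(sprintf("<variable_set> MICA '%s' (%s, IC = %.4f): %s\n",
              x$mica_label, x$mica, x$mica_ic,
              paste(x$variables, collapse = ", ")))
  invisible(x)
}

agg_functions <- list(
  SUM = function(v) sum(v),
  MIN = function(v) min(v),
  MAX = function(v) max(v),
  AVG = function(v) mean(v),
  MULT = function(v) prod(v)
)

meta_variable_name <- function(label, agg, existing) {
  base <- paste0("MV_", sanitise_label(label), "_", agg)
  nm <- base
  i <- 1L
  while (nm %in% existing) {
    i <- i + 1L
    nm <- paste0(base, "_", i)
  }
  nm
}

#' Aggregate a variable set into meta-variable candidates
#'
#' Produces the five row-wise aggregations (sum, minimum, maximum,
#' average, product) of the set's constituent variables, skipping missing
#' values; a record with all constituents missing gets a missing value.
#' With `normalise = TRUE` each constituent is min-max normalised first
#' (recommended when constituents have differing magnitudes); constant
#' constituents cannot be normalised and are used as-is with a warning.
#'
#' @param table a [health_table()].
#' @param set a `variable_set` (or a list with `variables` and
#'   `mica_label`).
#' @param normalise apply min-max normalisation per constituent first?
#' @param existing_names names already taken (for collision suffixes).
#' @return named list of five numeric candidate vectors, named
#'   `MV_<mica_label>_<AGG>`.
#' @export
aggregate_set <- function(table, set, normalise = TRUE,
                          existing_names = character(0)) {
  stopifnot(inherits(table, "health_table"))
  vars <- set$variables
  cols <- lapply(vars, function(v) {
    x <- ht_values(table, v)
    num <- parse_num(x)
    if (any(is.na(num) & !is.na(x))) {
      stop(sprintf("constituent variable '%s' is not numeric", v),
           call. = FALSE)
    }
    num
  })
  if (normalise) {
    cols <- lapply(seq_along(cols), function(i) {
      obs <- cols[[i]][!is.na(cols[[i]])]
      if (length(unique(obs)) < 2) {
        warning(sprintf("constituent '%s' is constant; left unnormalised",
                        vars[i]), call. = FALSE)
        cols[[i]]
      } else {
        min_max_normalise(cols[[i]], name = vars[i])
      }
    })
  }
  mat <- do.call(cbind, cols)
  out <- list()
  for (agg in names(agg_functions)) {
    f <- agg_functions[[agg]]
    vals <- apply(mat, 1, function(row) {
      v <- row[!is.na(row)]
      if (!length(v)) NA_real_ else f(v)
    })
    nm <- meta_variable_name(set$mica_label, agg,
                             c(existing_names, names(out)))
    out[[nm]] <- as.numeric(vals)
  }
  out
}

# zero entropy at declared tolerance: <= 1 distinct non-missing value after
# rounding to 12 decimals
is_zero_entropy_values <- function(x) {
  v <- x[!is.na(x)]
  length(unique(round(v, 12))) <= 1
}

#' Semantic enrichment of a numeric health table
#'
#' Runs the full enrichment workflow: node information content, variable
#' set discovery, per-set aggregation into five meta-variable candidates,
#' zero-entropy filtering, and appending of the surviving meta-variables.
#' The report records set/candidate counts, per-set MICA labels and ICs,
#' and a redundancy audit: the symmetric uncertainty of every appended
#' meta-variable with each of its constituents.
#'
#' @param table a [health_table()] whose mapped variables are numeric.
#' @param graph ontology:variable graph from [attach_variable_mappings()].
#' @param k IC weighting passed to [node_information_content()].
#' @param normalise min-max normalise constituents before aggregation?
#' @return list with `table` (meta-variables appended) and `report`
#'   (class `enrichment_report`).
#' @export
semantic_enrichment <- function(table, graph, k = 0.5, normalise = TRUE) {
  stopifnot(inherits(table, "health_table"))
  ic <- node_information_content(graph, k = k)
  sets <- identify_variable_sets(graph, ic)
  sets <- Filter(function(s) all(s$variables %in% names(table$data)), sets)
  n_sets <- length(sets)
  set_df <- data.frame(
    mica = vapply(sets, function(s) s$mica, character(1)),
    mica_label = vapply(sets, function(s) s$mica_label, character(1)),
    mica_ic = vapply(sets, function(s) s$mica_ic, numeric(1)),
    n_variables = vapply(sets, function(s) length(s$variables), integer(1)),
    variables = vapply(sets, function(s)
      paste(s$variables, collapse = ";"), character(1)),
    stringsAsFactors = FALSE
  )
  n_candidates <- 0L
  n_dropped <- 0L
  appended <- character(0)
  audit <- list()
  for (s in sets) {
    cands <- aggregate_set(table, s, normalise = normalise,
                           existing_names = c(names(table$data), appended))
    n_candidates <- n_candidates + length(cands)
    for (nm in names(cands)) {
      vals <- cands[[nm]]
      if (is_zero_entropy_values(vals)) {
        n_dropped <- n_dropped + 1L
        next
      }
      table <- ht_set(table, nm, vals,
                      meta = variable_meta(nm, "continuous",
                                           source = "user"))
      appended <- c(appended, nm)
      for (v in s$variables) {
        audit[[length(audit) + 1L]] <- data.frame(
          meta_variable = nm, constituent = v,
          su = symmetric_uncertainty(round(vals, 12),
                                     ht_values(table, v)),
          stringsAsFactors = FALSE
        )
      }
    }
  }
  audit_df <- if (length(audit)) do.call(rbind, audit) else
    data.frame(meta_variable = character(0), constituent = character(0),
               su = numeric(0), stringsAsFactors = FALSE)
  report <- structure(
    list(n_sets = n_sets,
         n_candidates = n_candidates,
         n_dropped = n_dropped,
         n_appended = length(appended),
         sets = set_df,
         meta_variables = appended,
         redundancy = audit_df),
    class = "enrichment_report"
  )
  list(table = table, report = report)
}

#' @export
print.enrichment_report <- function(x, ...) {
  cat("<enrichment_report>\n")
  cat(sprintf("  variable sets: %d\n", x$n_sets))
  cat(sprintf("  candidates: %d; zero-entropy dropped: %d; appended: %d\n",
              x$n_candidates, x$n_dropped, x$n_appended))
  if (nrow(x$redundancy)) {
    cat(sprintf("  mean redundancy (SU) with constituents: %.3f\n",
                mean(x$redundancy$su)))
    cat(sprintf("  fully redundant meta-variable/constituent pairs: %d\n",
                sum(x$redundancy$su >= 1 - 1e-9)))
  }
  invisible(x)
}

#' Write an enrichment report to CSV and markdown
#'
#' @param report an `enrichment_report`.
#' @param dir output directory (created if absent).
#' @return the directory, invisibly.
#' @export
write_enrichment_report <- function(report, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  utils::write.csv(report$sets, file.path(dir, "variable_sets.csv"),
                   row.names = FALSE)
  utils::write.csv(report$redundancy,
                   file.path(dir, "redundancy_audit.csv"),
                   row.names = FALSE)
  md <- c(
    "# Semantic enrichment report", "",
    sprintf("- Variable sets: %d", report$n_sets),
    sprintf("- Meta-variable candidates: %d", report$n_candidates),
    sprintf("- Dropped (zero entropy): %d", report$n_dropped),
    sprintf("- Appended: %d", report$n_appended), "",
    if (nrow(report$redundancy)) {
      c(sprintf("- Mean redundancy (SU) with constituents: %.3f",
                mean(report$redundancy$su)),
        sprintf("- Mean nonredundancy: %.1f%%",
                100 * (1 - mean(report$redundancy$su))))
    } else character(0)
  )
  writeLines(md, file.path(dir, "enrichment_report.md"))
  invisible(dir)
}
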