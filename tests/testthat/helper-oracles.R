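# Independent brute-force oracles used to validate the package's
# information-theoretic and graph computations. These deliberately avoid
# the package's own code paths (explicit frequency tables, naive
# reachability) so agreement is evidence, not tautology.

# entropy from an explicitly built frequency table
oracle_entropy <- function(x) {
  v <- as.character(x[!is.na(x)])
  if (length(v) == 0) return(0)
  counts <- numeric(0)
  for (val in v) {
    counts[val] <- if (val %in% names(counts)) counts[val] + 1 else 1
  }
  h <- 0
  for (c_i in counts) {
    p <- c_i / length(v)
    h <- h - p * log2(p)
  }
  h
}

# mutual information from an explicitly built joint frequency table
oracle_mi <- function(x, y) {
  keep <- !is.na(x) & !is.na(y)
  xv <- as.character(x[keep]); yv <- as.character(y[keep])
  n <- length(xv)
  joint <- list()
  for (i in seq_len(n)) {
    key <- paste0(xv[i], "||", yv[i])
    joint[[key]] <- if (is.null(joint[[key]])) 1 else joint[[key]] + 1
  }
  margx <- list(); margy <- list()
  for (i in seq_len(n)) {
    margx[[xv[i]]] <- if (is.null(margx[[xv[i]]])) 1 else margx[[xv[i]]] + 1
    margy[[yv[i]]] <- if (is.null(margy[[yv[i]]])) 1 else margy[[yv[i]]] + 1
  }
  mi <- 0
  for (key in names(joint)) {
    parts <- strsplit(key, "||", fixed = TRUE)[[1]]
    pxy <- joint[[key]] / n
    px <- margx[[parts[1]]] / n
    py <- margy[[parts[2]]] / n
    mi <- mi + pxy * log2(pxy / (px * py))
  }
  mi
}

# is `x` recoverable from `m` by a deterministic map on the observed pairs?
oracle_recoverable <- function(x, m) {
  keep <- !is.na(x) & !is.na(m)
  x <- as.character(x[keep]); m <- as.character(m[keep])
  for (mv in unique(m)) {
    if (length(unique(x[m == mv])) > 1) return(FALSE)
  }
  TRUE
}

# naive DAG helpers working directly on an edge data.frame (child, parent)
oracle_descendants <- function(edges, node) {
  # nodes from which `node` is reachable following child->parent edges
  desc <- character(0)
  frontier <- edges$child[edges$parent == node]
  while (length(frontier)) {
    new <- setdiff(frontier, desc)
    desc <- c(desc, new)
    frontier <- unique(edges$child[edges$parent %in% new])
  }
  unique(desc)
}

oracle_depth <- function(edges, node) {
  parents <- edges$parent[edges$child == node]
  if (!length(parents)) return(1)
  1 + max(vapply(parents, function(p) oracle_depth(edges, p), numeric(1)))
}

# brute-force node IC on an ontology edge table (no variables)
oracle_node_ic <- function(edges, k = 0.5) {
  nodes <- sort(unique(c(edges$child, edges$parent)))
  n <- length(nodes)
  depths <- vapply(nodes, function(v) oracle_depth(edges, v), numeric(1))
  dmax <- max(depths)
  ic <- vapply(seq_along(nodes), function(i) {
    hypo <- length(oracle_descendants(edges, nodes[i]))
    t1 <- if (n > 1) 1 - log(hypo + 1) / log(n) else 0
    t2 <- if (dmax > 1) log(depths[i]) / log(dmax) else 0
    k * t1 + (1 - k) * t2
  }, numeric(1))
  stats::setNames(ic, nodes)
}

# brute-force variable-set discovery: enumerate every ontology node's
# variable-descendant set, keep sets of size >= 2, and pick the max-IC
# representative per distinct set (ties: depth, then id)
oracle_variable_sets <- function(edges, mappings, k = 0.5) {
  nodes <- sort(unique(c(edges$child, edges$parent)))
  ic <- oracle_node_ic(edges, k)
  depths <- vapply(nodes, function(v) oracle_depth(edges, v), numeric(1))
  vsets <- lapply(nodes, function(v) {
    ents <- c(v, oracle_descendants(edges, v))
    sort(unique(mappings$variable[mappings$entity_id %in% ents]))
  })
  names(vsets) <- nodes
  vsets <- vsets[lengths(vsets) >= 2]
  if (!length(vsets)) return(list())
  keys <- vapply(vsets, paste, character(1), collapse = "|")
  out <- lapply(unique(keys), function(kk) {
    anc <- names(vsets)[keys == kk]
    best <- anc[order(-ic[anc], -depths[anc], anc)][1]
    list(variables = vsets[[best]], common_ancestors = sort(anc),
         mica = best, mica_ic = unname(ic[best]))
  })
  ord <- order(vapply(out, function(s) s$mica, character(1)))
  out[ord]
}

# small convenience: build a health_table from a data.frame with ids r1..rn
make_ht <- function(df, id = NULL) {
  if (is.null(id)) {
    df <- cbind(data.frame(rid = paste0("r", seq_len(nrow(df))),
                           stringsAsFactors = FALSE), df)
    id <- "rid"
  }
  health_table(df, id)
}

# all vectors of length n over an alphabet, as a list
enumerate_vectors <- function(n, alphabet) {
  grids <- rep(list(alphabet), n)
  g <- do.call(expand.grid, c(grids, stringsAsFactors = FALSE))
  lapply(seq_len(nrow(g)), function(i) as.character(unlist(g[i, ])))
}
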