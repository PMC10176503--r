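toy_graph <- function() {
  toy <- generate_toy_ontology("tree", 5, 2)
  g <- load_ontology_edges(toy$edges, labels = toy$labels)
  attach_variable_mappings(g, toy$mappings)
}

test_that("ontology loading validates structure", {
  toy <- generate_toy_ontology("tree", 5, 2)
  g <- load_ontology_edges(toy$edges)
  expect_equal(igraph::vcount(g), 5)
  expect_equal(igraph::ecount(g), 4)
  # self-loop
  expect_error(load_ontology_edges(
    data.frame(child = "A", parent = "A")), "self-loop")
  # cycle
  expect_error(load_ontology_edges(
    data.frame(child = c("A", "B", "C"), parent = c("B", "C", "A"))),
    "cycle")
  # two-root forest is accepted; roots identifiable by having no parents
  forest <- data.frame(child = c("A", "B"), parent = c("R1", "R2"))
  gf <- load_ontology_edges(forest)
  roots <- igraph::V(gf)$name[igraph::degree(gf, mode = "out") == 0]
  expect_setequal(roots, c("R1", "R2"))
})

test_that("variable mappings attach as variable nodes", {
  g <- toy_graph()
  expect_setequal(igraph::V(g)$name[igraph::V(g)$kind == "variable"],
                  c("v1", "v2"))
  # multi-entity mapping: one node, two edges
  toy <- generate_toy_ontology("tree", 5, 1)
  g2 <- load_ontology_edges(toy$edges)
  g2 <- attach_variable_mappings(
    g2, data.frame(variable = c("v1", "v1"), entity_id = c("C", "D")))
  expect_equal(sum(igraph::V(g2)$kind == "variable"), 1)
  expect_equal(igraph::ecount(g2), 4 + 2)
  expect_error(attach_variable_mappings(
    g2, data.frame(variable = "v9", entity_id = "X999")), "X999")
})

test_that("node IC anchors: root 0, deep childless leaf 1, toy node value", {
  g <- toy_graph()
  ic <- node_information_content(g, k = 0.5)
  expect_equal(unname(ic["R"]), 0)
  expect_equal(unname(ic["C"]), 1)  # depth 3 of 3, no descendants
  expect_equal(unname(ic["A"]), 0.4742, tolerance = 1e-4)
  expect_true(all(ic >= 0 & ic <= 1))
  expect_error(node_information_content(g, k = 1.5), "\\[0, 1\\]")
})

test_that("node IC matches the brute-force formula on random ontologies", {
  for (seed in 1:15) {
    toy <- generate_toy_ontology("dag", n_nodes = sample(5:30, 1),
                                 n_variables = 2, seed = seed)
    g <- load_ontology_edges(toy$edges)
    ic <- node_information_content(g, k = 0.5)
    want <- oracle_node_ic(toy$edges, k = 0.5)
    expect_equal(ic[sort(names(want))], want[sort(names(want))],
                 tolerance = 1e-12, ignore_attr = TRUE)
  }
})

test_that("IC is non-increasing from child to parent on trees", {
  for (seed in 1:5) {
    toy <- generate_toy_ontology("tree", n_nodes = 20, n_variables = 2,
                                 seed = seed)
    g <- load_ontology_edges(toy$edges)
    ic <- node_information_content(g)
    for (i in seq_len(nrow(toy$edges))) {
      expect_gte(ic[toy$edges$child[i]], ic[toy$edges$parent[i]])
    }
  }
})

test_that("variable-set discovery finds the toy set with MICA A", {
  g <- toy_graph()
  ic <- node_information_content(g)
  sets <- identify_variable_sets(g, ic)
  expect_length(sets, 1)
  expect_equal(sets[[1]]$variables, c("v1", "v2"))
  expect_setequal(sets[[1]]$common_ancestors, c("A", "R"))
  expect_equal(sets[[1]]$mica, "A")
})

test_that("nested comorbidity topology yields two sets with a deeper MICA", {
  hd <- ontology_heart_disease()
  g <- load_ontology_edges(hd$edges, labels = hd$labels)
  g <- attach_variable_mappings(g, hd$mappings)
  ic <- node_information_content(g)
  sets <- identify_variable_sets(g, ic)
  expect_length(sets, 2)
  big <- sets[[which(vapply(sets, function(s) length(s$variables), 0L) == 5)]]
  small <- sets[[which(vapply(sets, function(s) length(s$variables), 0L) == 2)]]
  expect_equal(big$mica_label, "heart disease")
  expect_setequal(big$variables, c("mi", "ihd", "af", "hf", "vd"))
  expect_equal(small$mica_label, "ischaemic heart disease")
  expect_setequal(small$variables, c("mi", "ihd"))
  # the nested MICA is deeper and more informative than the outer one
  depth <- attr(ic, "depth")
  expect_gt(depth[small$mica], depth[big$mica])
  expect_gt(small$mica_ic, big$mica_ic)
})

test_that("set discovery equals brute-force enumeration on random DAGs", {
  for (seed in 1:25) {
    n_nodes <- sample(6:40, 1)
    n_vars <- sample(2:10, 1)
    toy <- generate_toy_ontology("dag", n_nodes, n_vars, seed = seed,
                                 map_to = "any")
    g <- load_ontology_edges(toy$edges)
    g <- attach_variable_mappings(g, toy$mappings)
    ic <- node_information_content(g)
    got <- identify_variable_sets(g, ic)
    want <- oracle_variable_sets(toy$edges, toy$mappings)
    got <- got[order(vapply(got, function(s) s$mica, character(1)))]
    expect_equal(length(got), length(want))
    for (i in seq_along(got)) {
      expect_equal(got[[i]]$variables, want[[i]]$variables)
      expect_equal(got[[i]]$common_ancestors, want[[i]]$common_ancestors)
      expect_equal(got[[i]]$mica, want[[i]]$mica)
      expect_equal(got[[i]]$mica_ic, want[[i]]$mica_ic, tolerance = 1e-12)
    }
  }
})

test_that("no shared ancestry yields no variable sets", {
  forest <- data.frame(child = c("A", "B"), parent = c("R1", "R2"))
  g <- load_ontology_edges(forest)
  g <- attach_variable_mappings(
    g, data.frame(variable = c("v1", "v2"), entity_id = c("A", "B")))
  ic <- node_information_content(g)
  expect_length(identify_variable_sets(g, ic), 0)
})

test_that("aggregation skips missing values and handles all-missing rows", {
  df <- data.frame(
    x1 = c("0", "0.5", "1"),
    x2 = c("1", NA, "0"),
    stringsAsFactors = FALSE
  )
  ht <- make_ht(df)
  set <- list(variables = c("x1", "x2"), mica_label = "toy")
  cands <- aggregate_set(ht, set, normalise = FALSE)
  expect_equal(unname(cands[["MV_toy_SUM"]]), c(1, 0.5, 1))
  expect_equal(unname(cands[["MV_toy_MIN"]]), c(0, 0.5, 0))
  expect_equal(unname(cands[["MV_toy_MAX"]]), c(1, 0.5, 1))
  expect_equal(unname(cands[["MV_toy_AVG"]]), c(0.5, 0.5, 0.5))
  expect_equal(unname(cands[["MV_toy_MULT"]]), c(0, 0.5, 0))
  # all-missing record
  df2 <- data.frame(x1 = c("1", NA), x2 = c("2", NA),
                    stringsAsFactors = FALSE)
  cands2 <- aggregate_set(make_ht(df2),
                          list(variables = c("x1", "x2"),
                               mica_label = "toy"),
                          normalise = FALSE)
  expect_true(all(vapply(cands2, function(v) is.na(v[2]), logical(1))))
  # non-numeric constituent errors
  bad <- make_ht(data.frame(x1 = c("a", "b"), x2 = c("1", "2"),
                            stringsAsFactors = FALSE))
  expect_error(aggregate_set(bad, list(variables = c("x1", "x2"),
                                       mica_label = "t")),
               "not numeric")
})

test_that("normalised aggregations respect their ranges", {
  set.seed(12)
  df <- data.frame(
    a = as.character(runif(40, 0, 10)),
    b = as.character(runif(40, 100, 500)),
    c = as.character(runif(40, -5, 5)),
    stringsAsFactors = FALSE
  )
  df$a[sample(40, 6)] <- NA
  ht <- make_ht(df)
  cands <- aggregate_set(ht, list(variables = c("a", "b", "c"),
                                  mica_label = "s"), normalise = TRUE)
  for (agg in c("MIN", "MAX", "AVG", "MULT")) {
    v <- cands[[paste0("MV_s_", agg)]]
    expect_true(all(v >= 0 & v <= 1, na.rm = TRUE))
  }
  s <- cands[["MV_s_SUM"]]
  expect_true(all(s >= 0 & s <= 3, na.rm = TRUE))
})

test_that("enrichment filters zero-entropy candidates and audits redundancy", {
  wx <- worked_example_heart_disease()
  g <- load_ontology_edges(wx$edges, labels = wx$labels)
  g <- attach_variable_mappings(g, wx$mappings)
  res <- semantic_enrichment(wx$table, g, normalise = TRUE)
  r <- res$report
  expect_equal(r$n_sets, wx$expected$counts$n_sets)
  expect_equal(r$n_candidates, wx$expected$counts$n_candidates)
  expect_equal(r$n_dropped, wx$expected$counts$n_dropped)
  expect_equal(r$n_appended, wx$expected$counts$n_appended)
  expect_equal(r$n_candidates - r$n_dropped, r$n_appended)
  expect_equal(r$n_candidates, 5 * r$n_sets)
  for (nm in setdiff(names(wx$expected), "counts")) {
    expect_equal(as.numeric(ht_values(res$table, nm)), wx$expected[[nm]],
                 tolerance = 1e-12)
  }
  # every appended meta-variable has nonzero entropy
  for (nm in r$meta_variables) {
    expect_gt(entropy(round(ht_values(res$table, nm), 12)), 0)
  }
  # redundancy audit covers every (meta-variable, constituent) pair
  expect_equal(nrow(r$redundancy), 2 * 5 + 5 * 2)
  expect_true(all(r$redundancy$su >= 0 & r$redundancy$su <= 1))
})

test_that("binary two-variable sets can be fully redundant with a constituent", {
  # one constituent almost constant: aggregations collapse onto the other
  df <- data.frame(
    bisoprolol = c("0", "0", "0", "0", "1", "0"),
    betablocker = c("0", "1", "0", "1", "1", "0"),
    stringsAsFactors = FALSE
  )
  ht <- make_ht(df)
  edges <- data.frame(child = c("c_bb_therapy"), parent = "c_therapy")
  mappings <- data.frame(variable = c("bisoprolol", "betablocker"),
                         entity_id = "c_bb_therapy")
  g <- load_ontology_edges(edges)
  g <- attach_variable_mappings(g, mappings)
  res <- semantic_enrichment(ht, g, normalise = FALSE)
  su <- res$report$redundancy
  expect_true(any(su$su >= 1 - 1e-9))
})

test_that("meta-variable completeness is at least each constituent's", {
  set.seed(31)
  for (rep in 1:5) {
    n <- 50
    df <- data.frame(
      a = as.character(round(runif(n), 3)),
      b = as.character(round(runif(n), 3)),
      c = as.character(round(runif(n), 3)),
      stringsAsFactors = FALSE
    )
    for (v in names(df)) df[[v]][runif(n) < 0.3] <- NA
    ht <- make_ht(df)
    cands <- aggregate_set(ht, list(variables = names(df),
                                    mica_label = "m"), normalise = FALSE)
    const_comp <- vapply(names(df), function(v)
      mean(!is.na(ht_values(ht, v))), numeric(1))
    for (v in cands) {
      expect_gte(mean(!is.na(v)), max(const_comp))
    }
  }
})

test_that("meta-variable names sanitise labels and avoid collisions", {
  df <- data.frame(x1 = c("1", "0"), x2 = c("0", "1"),
                   stringsAsFactors = FALSE)
  ht <- make_ht(df)
  set <- list(variables = c("x1", "x2"), mica_label = "heart disease")
  cands <- aggregate_set(ht, set, normalise = FALSE)
  expect_true("MV_heart_disease_SUM" %in% names(cands))
  cands2 <- aggregate_set(ht, set, normalise = FALSE,
                          existing_names = names(cands))
  expect_true("MV_heart_disease_SUM_2" %in% names(cands2))
})
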