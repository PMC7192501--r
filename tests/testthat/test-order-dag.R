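manual_orders <- function(ordered = NULL, equal = NULL, ids = NULL) {
  rows <- list()
  if (!is.null(ordered)) {
    rows[[1]] <- tibble::tibble(from = ordered[, 1], to = ordered[, 2],
                                relation = "ordered", method = "manual",
                                z_min = NA_real_, z_max = NA_real_)
  }
  if (!is.null(equal)) {
    rows[[2]] <- tibble::tibble(from = equal[, 1], to = equal[, 2],
                                relation = "equal", method = "manual",
                                z_min = 1, z_max = 1)
  }
  fluxorder:::new_ordered_pair_set(dplyr::bind_rows(rows),
                                   reaction_ids = ids)
}

test_that("transitive reduction removes exactly the implied edges", {
  ops <- manual_orders(ordered = cbind(c("a", "b", "a"), c("b", "c", "c")))
  dag <- build_order_dag(ops)
  edges <- igraph::as_data_frame(dag$graph)
  expect_setequal(paste(edges$from, edges$to), c("a b", "b c"))
  expect_equal(unname(dag$nodes$level[match(c("a", "b", "c"),
                                            dag$nodes$node)]), 0:2)
})

test_that("re-reducing a reduced DAG is a no-op", {
  set.seed(4)
  for (rep in 1:5) {
    # random DAG on 8 nodes via a random triangular adjacency
    A <- matrix(rbinom(64, 1, 0.35), 8, 8)
    A[lower.tri(A, diag = TRUE)] <- 0
    g <- igraph::graph_from_adjacency_matrix(A)
    r1 <- fluxorder:::transitive_reduction(g)
    r2 <- fluxorder:::transitive_reduction(r1)
    expect_identical(igraph::as_adjacency_matrix(r1, sparse = FALSE),
                     igraph::as_adjacency_matrix(r2, sparse = FALSE))
  }
})

test_that("always-equal pairs collapse into a single node without self-edges", {
  ops <- manual_orders(equal = cbind("a", "b"), ids = c("a", "b"))
  dag <- build_order_dag(ops)
  expect_equal(nrow(dag$nodes), 1)
  expect_equal(igraph::ecount(dag$graph), 0)
  expect_setequal(dag$nodes$members[[1]], c("a", "b"))
  # a full chain of equalities collapses transitively
  ch <- build_order_dag(cached_orders("chain"))
  expect_equal(nrow(ch$nodes), 1)
  expect_equal(sort(ch$nodes$members[[1]]), c("R1", "R2", "R3"))
})

test_that("a cycle in the input relation is reported as an error", {
  ops <- manual_orders(ordered = cbind(c("a", "b"), c("b", "a")))
  expect_error(build_order_dag(ops), "cycle")
})

test_that("levels are the longest shortest path from any root", {
  g <- igraph::graph_from_data_frame(
    data.frame(from = c("a", "b", "a", "c", "e", "f"),
               to = c("b", "d", "c", "e", "d", "d")))
  lev <- assign_levels(g)
  # d: shortest path from root a has 2 edges, from root f one edge -> max 2
  expect_equal(lev[["d"]], 2)
  expect_equal(lev[["a"]], 0)
  expect_equal(lev[["f"]], 0)
  expect_equal(lev[["e"]], 2)
  # an isolated node is its own root
  g2 <- igraph::add_vertices(g, 1, name = "iso")
  expect_equal(assign_levels(g2)[["iso"]], 0)
})

test_that("the branch DAG has the uptake as its only root", {
  dag <- build_order_dag(cached_orders("branch"))
  roots <- dag$nodes$node[dag$nodes$level == 0]
  expect_equal(roots, "E1")
  hist <- level_histogram(dag)
  expect_equal(sum(hist$n_nodes), nrow(dag$nodes))
  expect_equal(sum(hist$n_reactions), 5)
  # level-0 nodes are exactly the in-degree-0 nodes
  indeg <- igraph::degree(dag$graph, mode = "in")
  expect_setequal(names(indeg)[indeg == 0], roots)
})

test_that("level partition defaults to first/middle/last by level index", {
  g <- cached_fixture("growth")
  gm <- apply_medium(g, medium_config("EX_glc", carbon_uptake_max = 18,
                                      biomass_fraction = 0.95))
  ops <- suppressWarnings(find_flux_ordered_pairs(gm, n_samples = 100,
                                                  seed = 1))
  dag <- build_order_dag(ops)
  part <- level_partition(dag)
  expect_setequal(unlist(part), dag$nodes$node)
  expect_true(all(dag$nodes$level[dag$nodes$node %in% part$first] == 0))
  expect_true(all(dag$nodes$level[dag$nodes$node %in% part$middle] == 1))
  expect_true(all(dag$nodes$level[dag$nodes$node %in% part$last] >= 2))
})

test_that("condition overlap computes Jaccard distances from the formula", {
  a <- manual_orders(ordered = cbind(c("a", "a", "b"), c("b", "c", "c")))
  b_same <- a
  ov <- condition_overlap(list(x = a, y = b_same))
  expect_equal(ov$pairwise$jaccard_distance, 0)
  expect_equal(ov$n_shared, 3)
  disj <- manual_orders(ordered = cbind(c("p", "q"), c("q", "r")))
  ov2 <- condition_overlap(list(x = a, y = disj))
  expect_equal(ov2$pairwise$jaccard_distance, 1)
  expect_equal(ov2$n_shared, 0)
  # |A| = 3, |B| = 2, one shared pair: 1 - 1/4
  b_part <- manual_orders(ordered = cbind(c("a", "z"), c("b", "w")))
  ov3 <- condition_overlap(list(x = a, y = b_part))
  expect_equal(ov3$pairwise$jaccard_distance, 0.75)
  expect_equal(ov3$per_condition$n_exclusive, c(2, 1))
})

test_that("biomass ancestors form the expected subgraph", {
  g <- cached_fixture("growth")
  ops <- cached_orders("growth")
  dag <- build_order_dag(ops)
  anc <- biomass_ancestor_subgraph(dag, "BIOMASS")
  expect_equal(unique(unlist(anc$nodes$members)), "EX_glc")
  # excluding the only ancestor empties the subgraph
  anc2 <- biomass_ancestor_subgraph(dag, "BIOMASS", exclude = "EX_glc")
  expect_equal(nrow(anc2$nodes), 0)
  # a biomass reaction at the root has no ancestors
  ops_root <- manual_orders(ordered = cbind("BIOMASS", "x"))
  anc3 <- biomass_ancestor_subgraph(build_order_dag(ops_root), "BIOMASS")
  expect_equal(nrow(anc3$nodes), 0)
  expect_error(biomass_ancestor_subgraph(dag, "nope"), "not in the DAG")
})

test_that("essential reactions equal the exhaustive knockout oracle", {
  g <- cached_fixture("growth")
  ess <- find_essential_reactions(g)
  expect_setequal(ess, c("EX_glc", "R_c", "R_e", "BIOMASS", "EX_bm"))
  # oracle: per-reaction knockout evaluated over enumerated vertices
  wt <- solve_fba(g, "BIOMASS", "max")$optimum
  oracle <- vapply(reaction_ids(g), function(r) {
    m2 <- g
    m2$reactions$lb[m2$reactions$id == r] <- 0
    m2$reactions$ub[m2$reactions$id == r] <- 0
    V <- polytope_vertices(m2)
    nrow(V) == 0 || max(V[, "BIOMASS"]) < 1e-6 * wt
  }, logical(1))
  expect_setequal(ess, reaction_ids(g)[oracle])
  # redundant parallel routes are individually dispensable
  expect_false("R_a" %in% ess)
  expect_false("R_b" %in% ess)
})

test_that("every biomass ancestor is essential; the report counts hold", {
  g <- cached_fixture("growth")
  dag <- build_order_dag(cached_orders("growth"))
  anc <- biomass_ancestor_subgraph(dag, "BIOMASS")
  ess <- find_essential_reactions(g)
  rep <- essentiality_order_report(ess, anc)
  expect_length(rep$violations, 0)
  expect_equal(rep$n_ordered_and_essential, 1)
  expect_equal(rep$n_essential_not_ordered, 4)
  # an empty ancestor DAG puts every essential reaction in the second count
  empty <- biomass_ancestor_subgraph(dag, "BIOMASS", exclude = "EX_glc")
  rep2 <- essentiality_order_report(ess, empty)
  expect_equal(rep2$n_ordered_and_essential, 0)
  expect_equal(rep2$n_essential_not_ordered, length(ess))
})

test_that("DAG exports carry level and membership attributes", {
  dag <- build_order_dag(cached_orders("branch"))
  gml <- withr::local_tempfile(fileext = ".graphml")
  export_dag(dag, gml, "graphml")
  txt <- readLines(gml)
  expect_true(any(grepl("level", txt)))
  back <- igraph::read_graph(gml, format = "graphml")
  expect_equal(sort(igraph::V(back)$name), sort(dag$nodes$node))
  expect_setequal(igraph::V(back)$level1, dag$nodes$level + 1)
  dot <- withr::local_tempfile(fileext = ".dot")
  export_dag(dag, dot, "dot")
  expect_true(any(grepl("->", readLines(dot))))
})
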