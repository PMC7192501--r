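test_that("GPR gene extraction handles operators, parentheses, duplicates", {
  expect_setequal(gpr_genes("(b0001 and b0002) or b0003"),
                  c("b0001", "b0002", "b0003"))
  expect_equal(gpr_genes("g1 OR g1"), "g1")
  expect_length(gpr_genes(""), 0)
  expect_length(gpr_genes(NA_character_), 0)
})

test_that("gene data pool through GPRs into per-reaction multisets", {
  m <- cached_fixture("branch")
  m$reactions$gpr <- c("", "g1 or g2", "g2", "", "g_absent")
  tbl <- tibble::tibble(gene_id = c("g1", "g1", "g2"), value = c(1, 2, 3))
  prof <- map_data_to_reactions(m, tbl, "transcript")
  expect_setequal(prof$reaction_id, c("R1", "R2"))
  expect_setequal(prof$values[[match("R1", prof$reaction_id)]], c(1, 2, 3))
  expect_equal(prof$values[[match("R2", prof$reaction_id)]], 3)
  # reactions with no GPR or no covered gene are absent
  expect_false("E1" %in% prof$reaction_id)
  expect_false("E3" %in% prof$reaction_id)
  # duplicated genes in a rule count once
  m$reactions$gpr[2] <- "g1 or g1 or g2"
  prof2 <- map_data_to_reactions(m, tbl)
  expect_setequal(prof2$values[[match("R1", prof2$reaction_id)]], c(1, 2, 3))
  expect_error(
    map_data_to_reactions(m, tibble::tibble(gene_id = "zz", value = 1)),
    "no overlap")
})

test_that("mean difference equals the double-sum definition", {
  expect_equal(mean_difference(c(2, 4), c(1, 3)), 1)
  expect_equal(mean_difference(c(1, 2), c(1, 2)), 0)
  expect_equal(mean_difference(5, c(2, 2, 2)), 3)
  expect_error(mean_difference(numeric(0), 1), "nonempty")
  set.seed(8)
  for (rep in 1:20) {
    d_i <- rnorm(sample(1:6, 1))
    d_j <- rnorm(sample(1:6, 1))
    double_sum <- sum(outer(d_i, d_j, "-")) / (length(d_i) * length(d_j))
    expect_equal(mean_difference(d_i, d_j), double_sum)
  }
})

test_that("noiseless synthetic omics give perfect concordance", {
  pl <- cached_fixture("paperlike")
  ops <- cached_orders("paperlike")
  so <- synthetic_omics(pl, noise_sd = 0, seed = 5)
  prof <- map_data_to_reactions(so$model, so$gene_data, "transcript")
  res <- concordance(ops, prof, n_perm = 99, seed = 3)
  expect_equal(res$f_pos, 1)
  expect_gte(res$p_value, 1 / 100)   # permutation floor
  expect_lte(res$p_value, 1)
  # reaction-granularity route agrees
  rprof <- reaction_data_profile(so$reaction_data, "flux")
  expect_equal(concordance(ops, rprof, n_perm = 99, seed = 3)$f_pos, 1)
})

test_that("identical data multisets give zero strict-positive fraction", {
  ops <- cached_orders("branch")
  prof <- reaction_data_profile(
    tibble::tibble(reaction_id = reaction_ids(cached_fixture("branch")),
                   value = 7),
    "flux")
  res <- concordance(ops, prof, n_perm = 49, seed = 1)
  expect_equal(res$f_pos, 0)
  expect_equal(res$p_value, 1)
})

test_that("concordance requires covered pairs and nonempty profiles", {
  ops <- cached_orders("branch")
  prof <- reaction_data_profile(
    tibble::tibble(reaction_id = c("zz", "ww"), value = 1:2))
  expect_error(concordance(ops, prof), "no ordered pair")
})

test_that("permutation p-values are deterministic given the seed", {
  pl <- cached_fixture("paperlike")
  ops <- cached_orders("paperlike")
  so <- synthetic_omics(pl, noise_sd = 2, seed = 5)
  prof <- map_data_to_reactions(so$model, so$gene_data)
  a <- concordance(ops, prof, n_perm = 99, seed = 7)
  b <- concordance(ops, prof, n_perm = 99, seed = 7)
  expect_equal(a$p_value, b$p_value)
  expect_equal(a$f_pos, b$f_pos)
})

test_that("cost percentile subsets keep pairs with both members costed high", {
  ops <- cached_orders("paperlike")
  ids <- attr(ops, "reaction_ids")
  costs <- reaction_data_profile(
    tibble::tibble(reaction_id = ids, value = seq_along(ids)), "cost")
  expect_identical(cost_percentile_subset(ops, costs, 0), ops)
  p70 <- cost_percentile_subset(ops, costs, 70)
  thr <- stats::quantile(seq_along(ids), 0.7, names = FALSE)
  keep <- ids[seq_along(ids) >= thr]
  expect_true(all(p70$from %in% keep))
  expect_true(all(p70$to %in% keep))
  # a pair with an uncosted member is dropped from nonzero percentiles
  costs2 <- reaction_data_profile(
    tibble::tibble(reaction_id = setdiff(ids, "E1"), value = 1), "cost")
  expect_false("E1" %in% cost_percentile_subset(ops, costs2, 50)$from)
  expect_error(cost_percentile_subset(ops, costs, 100), "percentile")
  expect_error(cost_percentile_subset(ops, costs, -5), "percentile")
})

fake_dag <- function(sizes = c(35, 35, 35)) {
  nodes <- tibble::tibble(
    node = c("n0", "n1", "n2"),
    members = list(paste0("rA", seq_len(sizes[1])),
                   paste0("rB", seq_len(sizes[2])),
                   paste0("rC", seq_len(sizes[3]))),
    level = 0:2)
  g <- igraph::graph_from_data_frame(
    data.frame(from = c("n0", "n1"), to = c("n1", "n2")))
  structure(list(graph = g, nodes = nodes, condition = NA_character_),
            class = "order_dag")
}

fake_model_for <- function(dag) {
  rxns <- unlist(dag$nodes$members)
  list(reactions = tibble::tibble(id = rxns, gpr = paste0("gene_", rxns)))
}

test_that("regulatory level analysis detects enriched early levels", {
  dag <- fake_dag()
  model <- fake_model_for(dag)
  genes <- paste0("gene_", unlist(dag$nodes$members))
  withr::with_seed(21, {
    counts <- c(rpois(35, 12), rpois(35, 6), rpois(35, 2))
  })
  reg <- tibble::tibble(gene_id = genes, n_interactions = counts)
  # ties in the Poisson counts: the tie-corrected normal approximation warns
  res <- suppressWarnings(regulatory_level_analysis(dag, reg, model))
  expect_equal(nrow(res$tests), 3)
  p <- stats::setNames(res$tests$p_value, res$tests$comparison)
  expect_lt(p[["first_vs_last"]], 0.05)
  expect_lt(p[["first_vs_middle"]], 0.05)
  expect_lt(p[["middle_vs_last"]], 0.05)
})

test_that("identical level distributions give non-significant tests", {
  dag <- fake_dag()
  model <- fake_model_for(dag)
  genes <- paste0("gene_", unlist(dag$nodes$members))
  # literally the same count multiset in every subset: the one-sided
  # Mann-Whitney statistic sits at its null center
  reg <- tibble::tibble(gene_id = genes,
                        n_interactions = rep(rep(c(1, 3, 5, 7, 9), 7), 3))
  res <- suppressWarnings(regulatory_level_analysis(dag, reg, model))
  expect_true(all(res$tests$p_value > 0.4))
})

test_that("single-gene subsets fall back to an exact test", {
  dag <- fake_dag(sizes = c(1, 1, 1))
  model <- fake_model_for(dag)
  reg <- tibble::tibble(gene_id = paste0("gene_", unlist(dag$nodes$members)),
                        n_interactions = c(9, 5, 1))
  res <- regulatory_level_analysis(dag, reg, model)
  expect_true(all(is.finite(res$tests$p_value)))
  expect_true(all(res$tests$p_value > 0 & res$tests$p_value <= 1))
})

test_that("empty subsets are skipped with a warning", {
  dag <- fake_dag()
  dag$nodes <- dag$nodes[1:2, ]   # no "last" levels
  model <- fake_model_for(dag)
  reg <- tibble::tibble(gene_id = paste0("gene_",
                                         unlist(dag$nodes$members)),
                        n_interactions = seq_len(70))
  w <- capture_warnings(res <- regulatory_level_analysis(dag, reg, model))
  expect_true(any(grepl("skipped", w)))
  expect_equal(nrow(res$tests), 1)
})

test_that("tidiers summarize concordance results and DAGs", {
  pl <- cached_fixture("paperlike")
  ops <- cached_orders("paperlike")
  so <- synthetic_omics(pl, noise_sd = 0, seed = 5)
  prof <- map_data_to_reactions(so$model, so$gene_data, "transcript")
  res <- concordance(ops, prof, n_perm = 49, seed = 3)
  td <- generics::tidy(res)
  expect_s3_class(td, "tbl_df")
  expect_named(td, c("from", "to", "delta"))
  gl <- generics::glance(res)
  expect_equal(gl$f_pos, res$f_pos)
  dag <- build_order_dag(ops)
  expect_equal(sum(generics::tidy(dag)$n_reactions),
               length(attr(ops, "reaction_ids")))
  expect_s3_class(ggplot2::autoplot(dag), "ggplot")
  expect_s3_class(ggplot2::autoplot(res), "ggplot")
})
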