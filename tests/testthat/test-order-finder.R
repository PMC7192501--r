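test_that("flux samples satisfy steady state and bounds", {
  for (nm in c("branch", "growth")) {
    m <- cached_fixture(nm)
    s <- sample_flux_space(m, 50, seed = 7)
    expect_equal(nrow(s), 50)
    expect_lt(max(abs(as.matrix(m$S) %*% t(s))), 1e-6)
    expect_true(all(t(s) >= m$reactions$lb - 1e-6))
    expect_true(all(t(s) <= m$reactions$ub + 1e-6))
  }
  # conservation on the chain: uptake equals export in every sample
  ch <- cached_fixture("chain")
  s <- sample_flux_space(ch, 30, seed = 1)
  expect_equal(s[, "R1"], s[, "R3"], tolerance = 1e-8)
})

test_that("sampling is deterministic for a fixed seed", {
  m <- cached_fixture("branch")
  expect_identical(sample_flux_space(m, 20, seed = 5),
                   sample_flux_space(m, 20, seed = 5))
})

test_that("a zero-volume flux space warns and returns the feasible point", {
  m <- cached_fixture("chain")
  m$reactions$lb <- rep(5, 3)
  m$reactions$ub <- rep(5, 3)
  expect_warning(s <- sample_flux_space(m, 4, seed = 1), "zero volume")
  expect_equal(unclass(s), matrix(5, 4, 3, dimnames = list(NULL, reaction_ids(m))),
               ignore_attr = TRUE)
})

test_that("candidate prefilter keeps exactly the sample-consistent pairs", {
  ch <- cached_fixture("chain")
  cands <- candidate_pairs(sample_flux_space(ch, 50, seed = 1))
  # all fluxes equal in every sample: both directions of every pair survive
  expect_equal(nrow(cands), 6)
  br <- cached_fixture("branch")
  cands <- candidate_pairs(sample_flux_space(br, 300, seed = 1))
  key <- paste(cands$from, cands$to)
  expect_true("E1 R1" %in% key)
  expect_false("R1 E1" %in% key)   # sampled counterexample eliminates it
  # empty sample: vacuous truth, all n(n-1) directed pairs are candidates
  empty <- sample_flux_space(br, 0)
  expect_equal(nrow(candidate_pairs(empty)), 20)
})

test_that("one sampled violation eliminates a direction in both directions", {
  s <- structure(
    matrix(c(1, 2,
             2, 1), nrow = 2, byrow = TRUE,
           dimnames = list(NULL, c("a", "b"))),
    class = c("flux_sample", "matrix", "array"))
  expect_equal(nrow(candidate_pairs(s)), 0)
})

test_that("fully coupled candidates are resolved from alpha without LPs", {
  sc <- canonicalize_model(make_scaled_chain())
  coup <- coupling_table(sc)
  expect_equal(coup$class[coup$i == "R2" & coup$j == "R3"], "full")
  cands <- tibble::tibble(from = c("R3", "R2", "R1"),
                          to = c("R2", "R3", "R3"))
  rf <- remove_fully_coupled(cands, coup)
  expect_equal(rf$resolution[1], "ordered")     # alpha = 2 in this direction
  expect_equal(rf$resolution[2], "unordered")   # alpha = 1/2
  # R1 vs R3 is also fully coupled (alpha 1/2); an uncoupled pair stays NA
  par <- cached_fixture("parallel")
  rf2 <- remove_fully_coupled(tibble::tibble(from = "U1", to = "U2"),
                              coupling_table(par))
  expect_true(is.na(rf2$resolution[1]))
})

test_that("ordered-pair sets equal the oracles on the named fixtures", {
  for (nm in c("chain", "branch", "diamond", "parallel", "growth",
               "paperlike")) {
    ops <- cached_orders(nm)
    m <- cached_fixture(nm)
    expect_identical(canon_pairs(ops), canon_pairs(oracle_order_set(m, "lp")),
                     info = nm)
  }
  # the branch fixture in detail: the uptake dominates both branches
  ops <- cached_orders("branch")
  ord <- ops[ops$relation == "ordered", ]
  expect_setequal(paste(ord$from, ord$to),
                  c("E1 R1", "E1 R2", "E1 E2", "E1 E3"))
})

test_that("the chain collapses entirely: no ordered pairs, all equal", {
  ops <- cached_orders("chain")
  expect_equal(sum(ops$relation == "ordered"), 0)
  expect_equal(sum(ops$relation == "equal"), 3)
})

test_that("the final set is seed-independent (exactness of the prefilter)", {
  for (nm in c("branch", "paperlike")) {
    m <- cached_fixture(nm)
    coup <- coupling_table(m)
    sets <- lapply(c(1, 42, 1234), function(s) {
      suppressWarnings(find_flux_ordered_pairs(m, n_samples = 150, seed = s,
                                               coupling = coup))
    })
    expect_identical(canon_pairs(sets[[1]]), canon_pairs(sets[[2]]))
    expect_identical(canon_pairs(sets[[1]]), canon_pairs(sets[[3]]))
  }
  # and independent of the sample size, including no prefilter at all
  m <- cached_fixture("diamond")
  a <- suppressWarnings(find_flux_ordered_pairs(m, n_samples = 0, seed = 1))
  b <- suppressWarnings(find_flux_ordered_pairs(m, n_samples = 300, seed = 9))
  expect_identical(canon_pairs(a), canon_pairs(b))
})

test_that("tightening the biomass bound only grows the order relation", {
  g <- cached_fixture("growth")
  ops_lo <- suppressWarnings(find_flux_ordered_pairs(
    g, cfg = medium_config("EX_glc", carbon_uptake_max = 18,
                           biomass_fraction = 0.925),
    n_samples = 200, seed = 1))
  ops_hi <- suppressWarnings(find_flux_ordered_pairs(
    g, cfg = medium_config("EX_glc", carbon_uptake_max = 18,
                           biomass_fraction = 1),
    n_samples = 200, seed = 1))
  lo_keys <- paste(ops_lo$from[ops_lo$relation == "ordered"],
                   ops_lo$to[ops_lo$relation == "ordered"])
  hi_all <- c(paste(ops_hi$from, ops_hi$to),
              paste(ops_hi$to, ops_hi$from)[ops_hi$relation == "equal"])
  expect_true(all(lo_keys %in% hi_all))
})

test_that("ordered-pair TSV round-trips with a reproducibility manifest", {
  ops <- cached_orders("branch")
  path <- withr::local_tempfile(fileext = ".tsv")
  write_ordered_pairs(ops, path)
  expect_true(file.exists(paste0(path, ".manifest.json")))
  manifest <- jsonlite::fromJSON(paste0(path, ".manifest.json"))
  expect_equal(manifest$seed, attr(ops, "seed"))
  expect_match(manifest$model_hash, "^[0-9a-f]+$")
  back <- read_ordered_pairs(path)
  expect_identical(canon_pairs(back), canon_pairs(ops))
})
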