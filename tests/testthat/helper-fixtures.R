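# Shared helpers: canonical keys for set comparisons, a lazily filled cache of
# fixture models and their ordered-pair sets, and small bespoke networks.

`%||%` <- function(x, y) if (is.null(x)) y else x

canon_pairs <- function(df) {
  df <- as.data.frame(df)[, c("from", "to", "relation")]
  df <- df[order(df$relation, df$from, df$to), ]
  paste(df$from, df$to, df$relation, collapse = ";")
}

.fixture_cache <- new.env(parent = emptyenv())

cached_fixture <- function(name, ...) {
  key <- paste0("model_", name)
  if (is.null(.fixture_cache[[key]])) {
    .fixture_cache[[key]] <- make_fixture(name, ...)
  }
  .fixture_cache[[key]]
}

cached_orders <- function(name, n_samples = 200, seed = 1) {
  key <- paste0("orders_", name, "_", seed)
  if (is.null(.fixture_cache[[key]])) {
    .fixture_cache[[key]] <- suppressWarnings(
      find_flux_ordered_pairs(cached_fixture(name),
                              n_samples = n_samples, seed = seed))
  }
  .fixture_cache[[key]]
}

# linear chain with a 2:1 stoichiometric step: v_R3 = 2 v_R1 (full, alpha 2)
make_scaled_chain <- function() {
  S <- matrix(c(1, -1, 0,
                0, 2, -1), nrow = 2, byrow = TRUE,
              dimnames = list(c("M1", "M2"), c("R1", "R2", "R3")))
  metabolic_model(
    S,
    tibble::tibble(id = c("R1", "R2", "R3"), lb = 0, ub = c(10, 10, 20)),
    tibble::tibble(id = c("M1", "M2")))
}

# dead-end network: R2 produces a metabolite no reaction consumes
make_deadend <- function() {
  S <- matrix(c(1, -1, -1, 0,
                0, 0, 1, 0,
                0, 0, 0, 0), nrow = 3, byrow = TRUE,
              dimnames = list(c("A", "DEAD", "X"),
                              c("U", "E", "R2", "ISO")))
  S["X", "ISO"] <- 0   # ISO: no stoichiometry at all is invalid; give it one
  S["A", "ISO"] <- -1
  S["X", "ISO"] <- 1
  metabolic_model(
    S,
    tibble::tibble(id = colnames(S), lb = 0, ub = 10),
    tibble::tibble(id = rownames(S)))
}

# blocked-reaction oracle: per-reaction flux maximum over enumerated vertices
vertex_blocked <- function(model, tol = 1e-9) {
  V <- polytope_vertices(model)
  if (nrow(V) == 0) return(model$reactions$id)
  vmax <- apply(V, 2, max)
  model$reactions$id[vmax <= tol]
}
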