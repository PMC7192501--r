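# Deterministic toy networks with known order/coupling structure, plus a
# seeded random-network generator. These are first-class test beds: every
# other module is validated against them and against the brute-force oracles.

#' Construct a named fixture network
#'
#' Available fixtures:
#' * `"chain"` — linear uptake-conversion-export pathway of `n` reactions;
#'   all pairs fully coupled with `alpha = 1`.
#' * `"branch"` — one uptake splitting into two independent export branches;
#'   the uptake is flux-ordered above each branch, the branches are mutually
#'   unordered.
#' * `"diamond"` — two branches reconverging before export.
#' * `"parallel"` — two disconnected chains; cross-pairs are uncoupled and
#'   unordered.
#' * `"growth"` — biomass pseudo-reaction with partially redundant precursor
#'   routes, an essential single-route precursor, and a low-flux cofactor
#'   route ordered below biomass.
#' * `"paperlike"` — a 9-reaction, 5-metabolite branched network structurally
#'   analogous to the toy networks used to illustrate flux-order hierarchies
#'   (synthetic; not transcribed from any published figure).
#' * `"random"` — seeded random network over `n_mets` metabolites and
#'   `n_rxns` reactions, built around a guaranteed uptake-to-export spine.
#'
#' @param name fixture name.
#' @param n chain length (chain fixture).
#' @param n_mets,n_rxns,seed random-fixture parameters.
#' @param canonicalize return the canonical (irreversible, unblocked) form.
#' @return A `metabolic_model`.
#' @export
make_fixture <- function(name = c("chain", "branch", "diamond", "parallel",
                                  "growth", "paperlike", "random"),
                         n = 3, n_mets = 8, n_rxns = 12, seed = 1L,
                         canonicalize = TRUE) {
  name <- match.arg(name)
  model <- switch(name,
                  chain = fixture_chain(n),
                  branch = fixture_branch(),
                  diamond = fixture_diamond(),
                  parallel = fixture_parallel(),
                  growth = fixture_growth(),
                  paperlike = fixture_paperlike(),
                  random = fixture_random(n_mets, n_rxns, seed))
  if (canonicalize) model <- canonicalize_model(model)
  model
}

build_fixture <- function(mets, rxn_list, biomass_id = NA_character_,
                          atpm_id = NA_character_) {
  ids <- vapply(rxn_list, `[[`, character(1), "id")
  S <- matrix(0, length(mets), length(ids),
              dimnames = list(mets, ids))
  for (k in seq_along(rxn_list)) {
    sto <- rxn_list[[k]]$sto
    S[names(sto), k] <- sto
  }
  rxns <- tibble::tibble(
    id = ids,
    lb = vapply(rxn_list, function(r) r$lb %||% 0, numeric(1)),
    ub = vapply(rxn_list, function(r) r$ub %||% 10, numeric(1)),
    gpr = vapply(rxn_list, function(r) r$gpr %||% paste0("g_", r$id),
                 character(1)),
    subsystem = vapply(rxn_list, function(r) r$subsystem %||% "",
                       character(1)))
  metabolic_model(S, rxns, tibble::tibble(id = mets),
                  biomass_id = biomass_id, atpm_id = atpm_id)
}

fixture_chain <- function(n = 3) {
  stopifnot(n >= 2)
  mets <- paste0("M", seq_len(n - 1))
  rxns <- vector("list", n)
  rxns[[1]] <- list(id = "R1", sto = c(M1 = 1))
  if (n > 2) {
    for (k in 2:(n - 1)) {
      sto <- stats::setNames(c(-1, 1), c(paste0("M", k - 1), paste0("M", k)))
      rxns[[k]] <- list(id = paste0("R", k), sto = sto)
    }
  }
  rxns[[n]] <- list(id = paste0("R", n),
                    sto = stats::setNames(-1, paste0("M", n - 1)))
  build_fixture(mets, rxns)
}

fixture_branch <- function() {
  build_fixture(
    c("A", "B", "C"),
    list(
      list(id = "E1", sto = c(A = 1)),
      list(id = "R1", sto = c(A = -1, B = 1)),
      list(id = "R2", sto = c(A = -1, C = 1)),
      list(id = "E2", sto = c(B = -1)),
      list(id = "E3", sto = c(C = -1))))
}

fixture_diamond <- function() {
  build_fixture(
    c("A", "B", "C", "D"),
    list(
      list(id = "E1", sto = c(A = 1)),
      list(id = "R1", sto = c(A = -1, B = 1)),
      list(id = "R2", sto = c(A = -1, C = 1)),
      list(id = "R3", sto = c(B = -1, D = 1)),
      list(id = "R4", sto = c(C = -1, D = 1)),
      list(id = "E2", sto = c(D = -1))))
}

fixture_parallel <- function() {
  build_fixture(
    c("X", "Y"),
    list(
      list(id = "U1", sto = c(X = 1)),
      list(id = "V1", sto = c(X = -1)),
      list(id = "U2", sto = c(Y = 1)),
      list(id = "V2", sto = c(Y = -1))))
}

# Growth network: glucose-like substrate G feeds precursor P through two
# redundant routes (R_a capacity-limited, R_b), precursor Q through the sole
# route R_c, and cofactor E through R_e (2 E per G; biomass uses 0.5 E per
# unit). Biomass: P + Q + 0.5 E -> BM, exported by EX_bm. Consequences used
# in tests: v_EX_glc = 2.25 v_bio (full coupling, alpha = 2.25), R_c and
# EX_bm are fully coupled 1:1 with biomass, R_e runs at 0.25 v_bio (ordered
# below biomass), and R_a/R_b are individually dispensable.
fixture_growth <- function() {
  build_fixture(
    c("G", "P", "Q", "E", "BM"),
    list(
      list(id = "EX_glc", sto = c(G = 1), ub = 10, gpr = ""),
      list(id = "R_a", sto = c(G = -1, P = 1), ub = 3, gpr = "gA"),
      list(id = "R_b", sto = c(G = -1, P = 1), ub = 10, gpr = "gB"),
      list(id = "R_c", sto = c(G = -1, Q = 1), ub = 10,
           gpr = "gC1 or gC2"),
      list(id = "R_e", sto = c(G = -1, E = 2), ub = 10, gpr = "gE"),
      list(id = "BIOMASS", sto = c(P = -1, Q = -1, E = -0.5, BM = 1),
           ub = 10, gpr = ""),
      list(id = "EX_bm", sto = c(BM = -1), ub = 10, gpr = "")),
    biomass_id = "BIOMASS")
}

# 9 reactions, 5 metabolites; two uptakes, a 2:1 stoichiometric step and a
# secondary branch give a non-trivial poset with full (alpha != 1),
# directional and uncoupled pairs.
fixture_paperlike <- function() {
  build_fixture(
    c("A", "B", "C", "D", "E"),
    list(
      list(id = "E1", sto = c(A = 1), gpr = "g1"),
      list(id = "E4", sto = c(C = 1), gpr = "g2"),
      list(id = "R1", sto = c(A = -1, B = 1), gpr = "g3a and g3b"),
      list(id = "R2", sto = c(A = -1, C = 1), gpr = "g4a or g4b"),
      list(id = "R3", sto = c(B = -1, D = 2), gpr = "g5"),
      list(id = "R4", sto = c(C = -1, D = 1), gpr = "g6"),
      list(id = "R5", sto = c(C = -1, E = 1), gpr = "g7"),
      list(id = "E2", sto = c(D = -1), gpr = "g8"),
      list(id = "E3", sto = c(E = -1), gpr = "g9")))
}

fixture_random <- function(n_mets = 8, n_rxns = 12, seed = 1L) {
  stopifnot(n_rxns >= n_mets + 2)
  withr::with_seed(seed, {
    mets <- paste0("M", seq_len(n_mets))
    rxns <- list()
    # spine: uptake -> M1 -> ... -> Mn -> export guarantees feasibility
    rxns[[1]] <- list(id = "U1", sto = c(M1 = 1))
    for (k in seq_len(n_mets - 1)) {
      sto <- stats::setNames(c(-1, 1), c(mets[k], mets[k + 1]))
      rxns[[length(rxns) + 1L]] <- list(id = paste0("S", k), sto = sto)
    }
    rxns[[length(rxns) + 1L]] <-
      list(id = "X1", sto = stats::setNames(-1, mets[n_mets]))
    # random extra reactions: exchanges or internal 1-2 substrate/product
    extra <- n_rxns - length(rxns)
    for (k in seq_len(extra)) {
      kind <- sample(c("uptake", "export", "internal"), 1,
                     prob = c(0.2, 0.2, 0.6))
      sto <- switch(kind,
        uptake = stats::setNames(sample(1:2, 1), sample(mets, 1)),
        export = stats::setNames(-sample(1:2, 1), sample(mets, 1)),
        internal = {
          subs <- sample(mets, sample(1:2, 1))
          prods <- sample(setdiff(mets, subs), sample(1:2, 1))
          stats::setNames(c(-sample(1:2, length(subs), replace = TRUE),
                            sample(1:2, length(prods), replace = TRUE)),
                          c(subs, prods))
        })
      rxns[[length(rxns) + 1L]] <- list(id = paste0("R", k), sto = sto)
    }
    build_fixture(mets, rxns)
  })
}
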