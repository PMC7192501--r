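#' Classify the flux-coupling relation of one reaction pair
#'
#' Flux coupling classes for an unordered pair `{i, j}`:
#' * `full` — the ratio `v_i / v_j` is a constant `alpha` in every steady
#'   state;
#' * `partial` — the two activities force each other (`v_i > 0` iff
#'   `v_j > 0`) but the ratio varies;
#' * `directional_ij` / `directional_ji` — only one implication holds; the
#'   first index is the leader: `directional_ij` means j active forces i
#'   active, so i sits above j in the coupling hierarchy;
#' * `uncoupled` — neither implication holds.
#'
#' Activity implications are decided by explicit LPs (maximum of one flux
#' with the other fixed to zero), which is exact on the polytope; ratio
#' extrema come from the Charnes-Cooper programs.
#'
#' @param model a canonical `metabolic_model`.
#' @param i,j distinct reaction ids.
#' @param eps ratio tolerance used to call a constant ratio.
#' @param tol activity tolerance on fluxes.
#' @param unconstrained_biomass drop the biomass lower bound (installed by
#'   [apply_medium()]) for the coupling analysis.
#' @return One-row tibble: `i`, `j`, `class`, `ratio_low`, `ratio_high`,
#'   `alpha` (`NA` unless full).
#' @export
classify_coupling <- function(model, i, j, eps = 1e-6, tol = 1e-6,
                              unconstrained_biomass = FALSE) {
  if (unconstrained_biomass && !is.na(model$biomass_id)) {
    model$reactions$lb[rxn_index(model, model$biomass_id)] <- 0
  }
  run_j_wo_i <- can_run_without(model, target = j, off = i, tol = tol)
  run_i_wo_j <- can_run_without(model, target = i, off = j, tol = tol)
  rb <- flux_ratio_bounds(model, i, j)
  z_lo <- rb$z_min
  z_hi <- rb$z_max
  cls <- if (!run_j_wo_i && !run_i_wo_j) {
    if (!is.na(z_lo) && !is.na(z_hi) &&
        abs(z_hi - z_lo) <= eps * max(1, abs(z_hi))) "full" else "partial"
  } else if (!run_j_wo_i) {
    "directional_ij"
  } else if (!run_i_wo_j) {
    "directional_ji"
  } else {
    "uncoupled"
  }
  tibble::tibble(
    i = i, j = j, class = cls,
    ratio_low = z_lo, ratio_high = z_hi,
    alpha = if (cls == "full") (z_lo + z_hi) / 2 else NA_real_)
}

# can `target` carry flux while `off` is fixed to zero?
can_run_without <- function(model, target, off, tol = 1e-6) {
  obj <- numeric(n_reactions(model))
  obj[rxn_index(model, target)] <- 1
  res <- lp_over_polytope(model, obj, maximize = TRUE,
                          extra_fixed = stats::setNames(0, off))
  if (res$status == "infeasible") return(FALSE)   # `off` can never be off
  if (res$status != "optimal") {
    stop("activity LP failed (", res$status, ") for ", target,
         " without ", off, call. = FALSE)
  }
  res$value > tol
}

#' Flux-coupling table over all reaction pairs
#'
#' Classifies every unordered pair of a canonical model (one row per pair;
#' classes are stored once with the `directional_*` suffix carrying the
#' orientation).
#'
#' @inheritParams classify_coupling
#' @return A `coupling_table` tibble: `i`, `j`, `class`, `ratio_low`,
#'   `ratio_high`, `alpha`.
#' @export
coupling_table <- function(model, eps = 1e-6, tol = 1e-6,
                           unconstrained_biomass = FALSE) {
  ids <- model$reactions$id
  n <- length(ids)
  rows <- list()
  if (n >= 2) {
    for (a in seq_len(n - 1)) {
      for (b in seq((a + 1), n)) {
        rows[[length(rows) + 1L]] <-
          classify_coupling(model, ids[a], ids[b], eps = eps, tol = tol,
                            unconstrained_biomass = unconstrained_biomass)
      }
    }
  }
  out <- if (length(rows)) dplyr::bind_rows(rows) else {
    tibble::tibble(i = character(), j = character(), class = character(),
                   ratio_low = numeric(), ratio_high = numeric(),
                   alpha = numeric())
  }
  structure(out, class = c("coupling_table", class(tibble::tibble())),
            condition = model$condition)
}

#' Overlap between flux-ordered and flux-coupled pairs
#'
#' Conditional probabilities between the ordered-pair set O and the coupling
#' classes: C (any coupling), D (directional), P (partial), F (full).
#' `Pr(X|O)` is the fraction of ordered pairs whose unordered pair belongs to
#' class X; `Pr(O|X)` is the fraction of class-X pairs having an ordered
#' orientation in O. Fully coupled pairs with `alpha != 1` count as ordered
#' (their orientation is implied by alpha); always-equal pairs do not.
#'
#' @param orders an `ordered_pair_set`.
#' @param coupling a `coupling_table` on the same model/condition.
#' @return One-row tibble with `pr_C_given_O`, `pr_D_given_O`,
#'   `pr_P_given_O`, `pr_F_given_O`, `pr_O_given_C`, `pr_O_given_D`,
#'   `pr_O_given_P` and the underlying counts `n_ordered`, `n_coupled`.
#' @export
order_coupling_overlap <- function(orders, coupling) {
  ord <- orders[orders$relation == "ordered", , drop = FALSE]
  okey <- unique(paste(pmin(ord$from, ord$to), pmax(ord$from, ord$to)))
  ckey <- paste(pmin(coupling$i, coupling$j), pmax(coupling$i, coupling$j))
  classes <- list(
    C = ckey[coupling$class != "uncoupled"],
    D = ckey[coupling$class %in% c("directional_ij", "directional_ji")],
    P = ckey[coupling$class == "partial"],
    F = ckey[coupling$class == "full"])
  n_ord <- length(okey)
  if (n_ord == 0) {
    warning("empty ordered-pair set: conditional probabilities undefined",
            call. = FALSE)
  }
  pr_given_O <- vapply(classes, function(k) {
    if (n_ord == 0) NaN else length(intersect(okey, k)) / n_ord
  }, numeric(1))
  pr_O_given <- vapply(classes[c("C", "D", "P")], function(k) {
    if (length(k) == 0) NaN else length(intersect(k, okey)) / length(k)
  }, numeric(1))
  tibble::tibble(
    pr_C_given_O = pr_given_O[["C"]],
    pr_D_given_O = pr_given_O[["D"]],
    pr_P_given_O = pr_given_O[["P"]],
    pr_F_given_O = pr_given_O[["F"]],
    pr_O_given_C = pr_O_given[["C"]],
    pr_O_given_D = pr_O_given[["D"]],
    pr_O_given_P = pr_O_given[["P"]],
    n_ordered = n_ord,
    n_coupled = length(classes$C))
}

#' Write a coupling table as TSV
#'
#' @param coupling a `coupling_table`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_coupling_table <- function(coupling, path) {
  utils::write.table(as.data.frame(coupling), path, sep = "\t",
                     quote = FALSE, row.names = FALSE)
  invisible(path)
}
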