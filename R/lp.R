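#' @importFrom rlang %||%
NULL

# Internal LP interface in boot::simplex-style form:
# min/max obj'x subject to A1 x <= b1, A2 x >= b2, A3 x = b3, x >= 0.
# Inequalities are closed with slack/surplus variables and handed to the
# package's bounded-variable simplex (R/simplex.R).
lp_solve <- function(obj, A1 = NULL, b1 = NULL, A2 = NULL, b2 = NULL,
                     A3 = NULL, b3 = NULL, maximize = FALSE) {
  n <- length(obj)
  as_mat <- function(A) if (is.null(A)) NULL else matrix(A, ncol = n)
  A1 <- as_mat(A1); A2 <- as_mat(A2); A3 <- as_mat(A3)
  m1 <- NROW(A1); m2 <- NROW(A2); m3 <- NROW(A3)
  A <- rbind(
    if (m1) cbind(A1, diag(m1), matrix(0, m1, m2)),
    if (m2) cbind(A2, matrix(0, m2, m1), -diag(m2)),
    if (m3) cbind(A3, matrix(0, m3, m1 + m2)))
  b <- c(b1, b2, b3)
  ntot <- n + m1 + m2
  res <- simplex_bounded(c(obj, rep(0, m1 + m2)), A, b,
                         lo = rep(0, ntot), hi = rep(Inf, ntot),
                         maximize = maximize)
  list(status = res$status,
       value = res$value,
       x = if (res$status == "optimal") res$x[seq_len(n)] else NULL)
}

# min/max c'v over {S v = 0, lb <= v <= ub}; bounds are native to the
# bounded-variable simplex, no shifting needed.
lp_over_polytope <- function(model, obj, maximize = FALSE,
                             extra_fixed = NULL) {
  S <- as.matrix(model$S)
  lb <- model$reactions$lb
  ub <- model$reactions$ub
  if (!is.null(extra_fixed)) {
    idx <- rxn_index(model, names(extra_fixed))
    lb[idx] <- extra_fixed
    ub[idx] <- extra_fixed
  }
  if (any(lb > ub + 1e-12)) {
    return(list(status = "infeasible", value = NA_real_, v = NULL))
  }
  res <- simplex_bounded(obj, S, rep(0, nrow(S)), lo = lb, hi = ub,
                         maximize = maximize)
  if (res$status != "optimal") {
    return(list(status = res$status, value = NA_real_, v = NULL))
  }
  list(status = "optimal",
       value = res$value,
       v = stats::setNames(res$x, model$reactions$id))
}

#' Flux balance analysis
#'
#' Maximizes or minimizes the flux of a single reaction over the steady-state
#' polytope `{v : S v = 0, lb <= v <= ub}`.
#'
#' @param model a `metabolic_model` with finite bounds.
#' @param objective reaction id to optimize.
#' @param sense `"max"` or `"min"`.
#' @return A list with `optimum` (scalar flux, mmol/gDW/h) and `fluxes`
#'   (named flux vector attaining it).
#' @export
solve_fba <- function(model, objective, sense = c("max", "min")) {
  sense <- match.arg(sense)
  j <- rxn_index(model, objective)
  obj <- numeric(n_reactions(model))
  obj[j] <- 1
  res <- lp_over_polytope(model, obj, maximize = sense == "max")
  if (res$status != "optimal") {
    stop("FBA ", sense, " of '", objective, "' failed: LP status ",
         res$status, call. = FALSE)
  }
  list(optimum = res$value, fluxes = res$v)
}

#' Extrema of a flux ratio via the Charnes-Cooper transformation
#'
#' Computes the minimum and maximum of `v_i / v_j` over all steady states with
#' `v_j > 0`. The linear-fractional program is rewritten as a linear program in
#' `w = v / v_j` and `t = 1 / v_j`:
#' minimize/maximize `w_i` subject to `S w = 0`, `w_j = 1`,
#' `t * lb <= w <= t * ub`, `0 <= t <= t_cap`.
#' The cap on `t` keeps the maximization bounded when the true ratio supremum
#' is infinite (the reported `z_max` is then the cap-induced maximum).
#'
#' @param model a canonical (irreversible, finite-bound) `metabolic_model`.
#' @param i,j distinct reaction ids; the ratio is `v_i / v_j`.
#' @param t_cap upper bound on the homogenization variable `t = 1/v_j`.
#' @return A list of class `ratio_bounds`: `z_min`, `z_max`, `status_min`,
#'   `status_max`, and the pair ids. When the `w_j = 1` system is infeasible
#'   (`v_j` identically zero, which cannot occur after blocked-reaction
#'   removal) both statuses are `"infeasible"` and the bounds are `NA`.
#' @export
flux_ratio_bounds <- function(model, i, j, t_cap = 1e6) {
  if (identical(i, j)) stop("i and j must be distinct reactions", call. = FALSE)
  ii <- rxn_index(model, i)
  jj <- rxn_index(model, j)
  S <- as.matrix(model$S)
  lb <- model$reactions$lb
  ub <- model$reactions$ub
  if (any(lb < 0)) {
    stop("flux_ratio_bounds requires an irreversible model (lb >= 0)",
         call. = FALSE)
  }
  if (any(!is.finite(ub))) {
    stop("flux_ratio_bounds requires finite upper bounds (cap them first)",
         call. = FALSE)
  }
  n <- ncol(S)
  # variables y = (w_1..w_n, t), all >= 0; pinned fluxes (lb = ub) become
  # equality rows w_k = lb_k * t rather than a degenerate <=/>= pair
  pinned <- which(ub - lb <= 1e-12)
  ranged <- setdiff(seq_len(n), pinned)
  obj <- c(as.numeric(seq_len(n) == ii), 0)
  A3 <- rbind(cbind(S, 0),
              c(as.numeric(seq_len(n) == jj), 0),
              if (length(pinned)) {
                cbind(diag(n)[pinned, , drop = FALSE], -lb[pinned])
              })
  b3 <- c(rep(0, nrow(S)), 1, rep(0, length(pinned)))
  A1 <- rbind(cbind(diag(n)[ranged, , drop = FALSE], -ub[ranged]),
              c(rep(0, n), 1))                        # w <= t*ub, t <= cap
  b1 <- c(rep(0, length(ranged)), t_cap)
  pos_lb <- ranged[lb[ranged] > 0]
  A2 <- if (length(pos_lb)) {
    cbind(diag(n)[pos_lb, , drop = FALSE], -lb[pos_lb]) # w >= t*lb
  } else NULL
  b2 <- if (length(pos_lb)) rep(0, length(pos_lb)) else NULL
  lo <- lp_solve(obj, A1, b1, A2, b2, A3, b3, maximize = FALSE)
  hi <- lp_solve(obj, A1, b1, A2, b2, A3, b3, maximize = TRUE)
  structure(
    list(i = i, j = j,
         z_min = lo$value, z_max = hi$value,
         status_min = lo$status, status_max = hi$status),
    class = "ratio_bounds"
  )
}

#' @export
print.ratio_bounds <- function(x, ...) {
  cat("<ratio_bounds> v_", x$i, " / v_", x$j, " in [",
      format(x$z_min), ", ", format(x$z_max), "] (",
      x$status_min, "/", x$status_max, ")\n", sep = "")
  invisible(x)
}

#' Decide the order relation of a pair from its ratio bounds
#'
#' A pair (i, j) is flux-ordered (`v_i >= v_j` in every steady state, and not
#' always equal) iff `z_min >= 1` and `z_max > 1`; it is always-equal iff both
#' extrema equal 1. Comparisons carry a tolerance `eps` on ratio space.
#'
#' @param bounds a `ratio_bounds` object from [flux_ratio_bounds()].
#' @param eps tolerance on the ratio scale (default `1e-6`; double-precision
#'   LP duality gaps on genome-scale models exceed `1e-9`).
#' @return One of `"ordered"`, `"equal"`, `"unordered"`, or `"undetermined"`
#'   when either LP failed to solve.
#' @export
is_ordered <- function(bounds, eps = 1e-6) {
  if (bounds$status_min == "infeasible" && bounds$status_max == "infeasible") {
    # v_j == 0 over the whole polytope; treated as unordered and logged
    return("unordered")
  }
  if (bounds$status_min != "optimal" || bounds$status_max != "optimal") {
    return("undetermined")
  }
  if (abs(bounds$z_min - 1) <= eps && abs(bounds$z_max - 1) <= eps) {
    return("equal")
  }
  if (bounds$z_min >= 1 - eps && bounds$z_max > 1 + eps) {
    return("ordered")
  }
  "unordered"
}
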