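# Independent brute-force oracles for the order and coupling relations.
# These deliberately avoid the Charnes-Cooper route used by the main path:
# the difference-LP oracle extremizes v_i - v_j directly, and the vertex
# oracle evaluates the decision over the enumerated vertices of the flux
# polytope (a linear functional attains its extrema at vertices).

#' Enumerate the vertices of the flux polytope
#'
#' Vertices of `{v : S v = 0, lb <= v <= ub}` via active-bound-set
#' enumeration: with `d = n - rank(S)` degrees of freedom, every vertex fixes
#' at least `d` variables at a bound; all `choose(n, d) * 2^d` assignments
#' are solved and filtered for feasibility and uniqueness. Intended for
#' oracle use on small networks only.
#'
#' @param model a `metabolic_model` with finite bounds.
#' @param tol feasibility/dedup tolerance.
#' @param max_combos guard on the enumeration size; exceeding it is an error
#'   directing to the LP oracle mode.
#' @return Numeric matrix, rows = vertices, columns = reactions.
#' @export
polytope_vertices <- function(model, tol = 1e-9, max_combos = 2e5) {
  S <- as.matrix(model$S)
  n <- ncol(S)
  lb <- model$reactions$lb
  ub <- model$reactions$ub
  r <- qr(S)$rank
  d <- n - r
  if (d == 0) {
    qs <- qr(S)
    v <- qr.coef(qs, rep(0, nrow(S)))
    v[is.na(v)] <- 0
    ok <- all(v >= lb - tol) && all(v <= ub + tol)
    out <- if (ok) matrix(v, 1, n) else matrix(numeric(0), 0, n)
    colnames(out) <- model$reactions$id
    return(out)
  }
  n_combos <- choose(n, d) * 2^d
  if (n_combos > max_combos) {
    stop("vertex enumeration would need ", format(n_combos),
         " active-set candidates; use the LP oracle mode for this model",
         call. = FALSE)
  }
  subsets <- utils::combn(n, d)
  verts <- list()
  bound_grid <- as.matrix(expand.grid(rep(list(c(0, 1)), d)))
  for (s in seq_len(ncol(subsets))) {
    fix <- subsets[, s]
    free <- setdiff(seq_len(n), fix)
    qf <- qr(S[, free, drop = FALSE])
    if (qf$rank < length(free)) next  # non-unique solution: not a vertex
    # all 2^d lb/ub assignments at once
    vals <- t(bound_grid) * ub[fix] + t(1 - bound_grid) * lb[fix]  # d x 2^d
    rhs <- -S[, fix, drop = FALSE] %*% vals
    x <- qr.coef(qf, rhs)
    fitted <- S[, free, drop = FALSE] %*% x
    resid <- colSums(abs(fitted - rhs))
    for (g in seq_len(ncol(vals))) {
      if (resid[g] > 1e-7) next
      v <- numeric(n)
      v[fix] <- vals[, g]
      v[free] <- x[, g]
      if (all(v >= lb - 1e-7) && all(v <= ub + 1e-7)) {
        verts[[length(verts) + 1L]] <- pmin(pmax(v, lb), ub)
      }
    }
  }
  if (length(verts) == 0) {
    out <- matrix(numeric(0), 0, n)
  } else {
    out <- do.call(rbind, verts)
    out <- out[!duplicated(round(out, 7)), , drop = FALSE]
  }
  colnames(out) <- model$reactions$id
  out
}

#' Brute-force oracle for the order relation of one pair
#'
#' @param model a canonical `metabolic_model`.
#' @param i,j distinct reaction ids.
#' @param mode `"lp"` extremizes `v_i - v_j` over the polytope with two
#'   difference LPs; `"vertex"` evaluates the same decision over enumerated
#'   polytope vertices.
#' @param tol flux tolerance.
#' @param vertices optional precomputed vertex matrix (vertex mode).
#' @return `"ordered"`, `"equal"`, or `"unordered"`.
#' @export
oracle_order <- function(model, i, j, mode = c("lp", "vertex"), tol = 1e-6,
                         vertices = NULL) {
  mode <- match.arg(mode)
  if (mode == "lp") {
    obj <- numeric(n_reactions(model))
    obj[rxn_index(model, i)] <- 1
    obj[rxn_index(model, j)] <- -1
    lo <- lp_over_polytope(model, obj, maximize = FALSE)
    hi <- lp_over_polytope(model, obj, maximize = TRUE)
    if (lo$status != "optimal" || hi$status != "optimal") {
      stop("difference-LP oracle failed: ", lo$status, "/", hi$status,
           call. = FALSE)
    }
    dmin <- lo$value
    dmax <- hi$value
  } else {
    V <- vertices %||% polytope_vertices(model)
    if (nrow(V) == 0) stop("empty polytope", call. = FALSE)
    diffs <- V[, i] - V[, j]
    dmin <- min(diffs)
    dmax <- max(diffs)
  }
  if (dmin >= -tol && dmax > tol) return("ordered")
  if (abs(dmin) <= tol && abs(dmax) <= tol) return("equal")
  "unordered"
}

#' Brute-force oracle for the coupling class of one pair
#'
#' Classifies from enumerated polytope vertices: activity implications from
#' vertex activity patterns (a face extremum is attained at a vertex), full
#' coupling from a constant `v_i = alpha * v_j` across all vertices.
#'
#' @inheritParams oracle_order
#' @return One-row tibble with `i`, `j`, `class`, `alpha`.
#' @export
oracle_coupling <- function(model, i, j, tol = 1e-6, vertices = NULL) {
  V <- vertices %||% polytope_vertices(model)
  if (nrow(V) == 0) stop("empty polytope", call. = FALSE)
  vi <- V[, i]
  vj <- V[, j]
  act_i <- vi > tol
  act_j <- vj > tol
  run_j_wo_i <- any(act_j & !act_i)
  run_i_wo_j <- any(act_i & !act_j)
  alpha <- NA_real_
  cls <- if (!run_j_wo_i && !run_i_wo_j) {
    act <- act_i | act_j
    if (any(act)) {
      a <- vi[act][1] / vj[act][1]
      if (all(abs(vi - a * vj) <= tol * max(1, a))) {
        alpha <- a
        "full"
      } else "partial"
    } else "full"  # both identically zero cannot occur post-canonicalization
  } else if (!run_j_wo_i) {
    "directional_ij"
  } else if (!run_i_wo_j) {
    "directional_ji"
  } else {
    "uncoupled"
  }
  tibble::tibble(i = i, j = j, class = cls, alpha = alpha)
}

#' All ordered pairs by brute force
#'
#' Runs [oracle_order()] over every directed pair; the reference result the
#' main path ([find_flux_ordered_pairs()]) must reproduce exactly.
#'
#' @inheritParams oracle_order
#' @return Tibble `from`, `to`, `relation` with ordered pairs (both
#'   orientations of equal pairs reduced to one lexicographic `"equal"` row).
#' @export
oracle_order_set <- function(model, mode = c("lp", "vertex"), tol = 1e-6) {
  mode <- match.arg(mode)
  ids <- model$reactions$id
  V <- if (mode == "vertex") polytope_vertices(model) else NULL
  rows <- list()
  for (a in ids) {
    for (b in ids) {
      if (a == b) next
      cls <- oracle_order(model, a, b, mode = mode, tol = tol, vertices = V)
      if (cls == "ordered") {
        rows[[length(rows) + 1L]] <-
          tibble::tibble(from = a, to = b, relation = "ordered")
      } else if (cls == "equal" && a < b) {
        rows[[length(rows) + 1L]] <-
          tibble::tibble(from = a, to = b, relation = "equal")
      }
    }
  }
  if (length(rows)) dplyr::bind_rows(rows) else {
    tibble::tibble(from = character(), to = character(),
                   relation = character())
  }
}
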