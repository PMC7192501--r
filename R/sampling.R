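#' Sample the steady-state flux polytope
#'
#' Draws approximately uniform flux vectors from
#' `{v : S v = 0, lb <= v <= ub}` with a hit-and-run random walk in the null
#' space of `S`, started from an interior (Chebyshev-like) point. Samples are
#' used only as a prefilter: a sampled violation of `v_i >= v_j` is a proof
#' that the pair is not ordered, so sampling never affects the exactness of
#' the final ordered-pair set.
#'
#' @param model a canonical `metabolic_model`.
#' @param n_samples number of flux vectors to return.
#' @param seed integer seed; the sample is deterministic for a fixed seed.
#' @param burnin,thin walk length controls.
#' @param tol feasibility tolerance each returned row must satisfy.
#' @return A `flux_sample`: numeric matrix (rows = samples, columns =
#'   reactions, mmol/gDW/h) with attributes `sampler` and `seed`.
#' @export
sample_flux_space <- function(model, n_samples, seed = 1L,
                              burnin = 100L, thin = 5L, tol = 1e-6) {
  n <- n_reactions(model)
  ids <- model$reactions$id
  empty <- matrix(numeric(0), nrow = 0, ncol = n,
                  dimnames = list(NULL, ids))
  if (n_samples == 0) {
    return(structure(empty, class = c("flux_sample", "matrix", "array"),
                     sampler = "hit_and_run", seed = seed))
  }
  lb <- model$reactions$lb
  ub <- model$reactions$ub
  width <- ub - lb
  fixed <- which(width <= 1e-12)
  S <- as.matrix(model$S)
  # directions must not move variables pinned by their bounds
  S_dir <- rbind(S, diag(n)[fixed, , drop = FALSE])
  N <- MASS::Null(t(S_dir))
  center <- interior_point(model)
  if (is.null(center)) {
    stop("model is infeasible: cannot sample an empty flux space",
         call. = FALSE)
  }
  draws <- withr::with_seed(seed, {
    if (ncol(N) == 0 || attr(center, "radius") <= 1e-9) {
      warning("flux space has zero volume; returning the feasible point ",
              "repeated", call. = FALSE)
      matrix(rep(center, each = n_samples), nrow = n_samples,
             dimnames = list(NULL, ids))
    } else {
      hit_and_run(center, N, lb, ub, n_samples, burnin, thin)
    }
  })
  colnames(draws) <- ids
  resid <- max(abs(S %*% t(draws)))
  if (resid > tol) {
    stop("sampled flux vectors violate S v = 0 beyond tolerance (",
         format(resid), ")", call. = FALSE)
  }
  structure(draws, class = c("flux_sample", "matrix", "array"),
            sampler = "hit_and_run", seed = seed)
}

# Chebyshev-style interior point: maximize a common slack s pushed against
# both bounds of every non-fixed variable. Fixed (lb = ub) variables are
# substituted out of the program.
interior_point <- function(model) {
  S <- as.matrix(model$S)
  n <- ncol(S)
  lb <- model$reactions$lb
  ub <- model$reactions$ub
  width <- ub - lb
  free <- which(width > 1e-12)
  b3 <- as.numeric(-S %*% lb)
  if (length(free) == 0) {
    if (max(abs(b3)) > 1e-9) return(NULL)
    return(structure(stats::setNames(lb, model$reactions$id), radius = 0))
  }
  nf <- length(free)
  s_max <- max(width[free]) / 2
  # variables (x_free = v_free - lb_free, s) >= 0
  obj <- c(rep(0, nf), 1)
  A3 <- cbind(S[, free, drop = FALSE], 0)
  A1 <- rbind(cbind(diag(nf), 1),                       # v + s <= ub
              c(rep(0, nf), 1))
  b1 <- c(width[free], s_max)
  A2 <- cbind(diag(nf), -1)                             # v - s >= lb
  b2 <- rep(0, nf)
  res <- lp_solve(obj, A1, b1, A2, b2, A3, b3, maximize = TRUE)
  if (res$status != "optimal") return(NULL)
  v <- lb
  v[free] <- res$x[seq_len(nf)] + lb[free]
  structure(stats::setNames(v, model$reactions$id),
            radius = res$x[nf + 1])
}

hit_and_run <- function(x0, N, lb, ub, n_samples, burnin, thin) {
  n <- length(x0)
  k <- ncol(N)
  out <- matrix(NA_real_, n_samples, n)
  x <- as.numeric(x0)
  total <- burnin + n_samples * thin
  kept <- 0L
  for (step in seq_len(total)) {
    d <- as.numeric(N %*% stats::rnorm(k))
    nd <- sqrt(sum(d^2))
    if (nd < 1e-12) next
    d <- d / nd
    # segment {x + t d} within bounds
    t_lo <- -Inf
    t_hi <- Inf
    mv <- abs(d) > 1e-12
    if (any(mv)) {
      r1 <- (lb[mv] - x[mv]) / d[mv]
      r2 <- (ub[mv] - x[mv]) / d[mv]
      t_lo <- max(pmin(r1, r2))
      t_hi <- min(pmax(r1, r2))
    }
    if (!is.finite(t_lo) || !is.finite(t_hi) || t_hi <= t_lo) next
    x <- x + stats::runif(1, t_lo, t_hi) * d
    x <- pmin(pmax(x, lb), ub)
    if (step > burnin && (step - burnin) %% thin == 0) {
      kept <- kept + 1L
      out[kept, ] <- x
      if (kept == n_samples) break
    }
  }
  if (kept < n_samples) {
    out[(kept + 1):n_samples, ] <- matrix(rep(x, n_samples - kept),
                                          ncol = n, byrow = TRUE)
  }
  out
}
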