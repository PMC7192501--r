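# Bounded-variable two-phase revised simplex.
#
# Solves   min (or max)  c'x   s.t.  A x = b,  lo <= x <= hi
# with lo finite, hi possibly +Inf, by the textbook two-phase method with
# Bland's anticycling rule. Written for the small, dense, highly degenerate
# programs of constraint-based modelling (many zero right-hand sides from
# S v = 0); correctness and determinism matter far more than speed at these
# sizes (tens of variables). The basis system is re-solved from scratch at
# every iteration, trading flops for numerical hygiene.

simplex_bounded <- function(cost, A, b, lo, hi, maximize = FALSE,
                            tol = 1e-9, feas_tol = 1e-7, max_iter = NULL) {
  A <- as.matrix(A)
  m <- nrow(A)
  n <- ncol(A)
  stopifnot(length(cost) == n, length(b) == m,
            length(lo) == n, length(hi) == n, all(is.finite(lo)))
  if (any(lo > hi + tol)) {
    return(list(status = "infeasible", value = NA_real_, x = NULL))
  }
  sense <- if (maximize) -1 else 1
  # phase 1: artificial variables close the residual of a bound-feasible start
  x <- ifelse(is.finite(hi) & (abs(hi) < abs(lo)), hi, lo)
  at_upper <- is.finite(hi) & (abs(hi) < abs(lo))
  r <- as.numeric(b - A %*% x)
  sgn <- ifelse(r >= 0, 1, -1)
  Aall <- cbind(A, diag(sgn, m))
  nall <- n + m
  lo_all <- c(lo, rep(0, m))
  hi_all <- c(hi, rep(Inf, m))
  state <- c(ifelse(at_upper, 2L, 1L), rep(0L, m))  # 0 basic, 1 at lo, 2 at hi
  basis <- n + seq_len(m)
  x_all <- c(x, abs(r))

  run_phase <- function(obj, basis, state, x_all, hi_all, max_iter) {
    for (it in seq_len(max_iter)) {
      Bmat <- Aall[, basis, drop = FALSE]
      qB <- qr(Bmat)
      x_nb <- ifelse(state > 0L, x_all, 0)   # nonbasic vars at their bounds
      xB <- tryCatch(
        solve(qB, as.numeric(b - Aall %*% x_nb)),
        error = function(e) NULL)
      if (is.null(xB)) {
        return(list(status = "singular", basis = basis, state = state,
                    x_all = x_all))
      }
      x_all[basis] <- xB
      y <- tryCatch(solve(t(Bmat), obj[basis]), error = function(e) NULL)
      if (is.null(y)) {
        return(list(status = "singular", basis = basis, state = state,
                    x_all = x_all))
      }
      d <- obj - as.numeric(crossprod(Aall, y))
      movable <- state > 0L & (hi_all - lo_all > tol)
      enter_lo <- movable & state == 1L & d < -tol
      enter_hi <- movable & state == 2L & d > tol
      cand <- which(enter_lo | enter_hi)
      if (length(cand) == 0) {
        return(list(status = "optimal", basis = basis, state = state,
                    x_all = x_all,
                    value = sum(obj[basis] * xB) +
                      sum(obj[state > 0L] * x_all[state > 0L])))
      }
      j <- min(cand)                       # Bland: smallest entering index
      w <- solve(qB, Aall[, j])
      dir <- if (state[j] == 1L) 1 else -1 # increase from lo / decrease from hi
      # ratio test: basic variables hitting a bound, plus j's own range
      step <- hi_all[j] - lo_all[j]
      leave <- 0L                          # 0 => bound flip of j itself
      leave_to <- 0L
      for (k in seq_len(m)) {
        wk <- dir * w[k]
        bi <- basis[k]
        if (wk > tol) {                    # x_bi decreases towards lo
          s <- (x_all[bi] - lo_all[bi]) / wk
          if (s < step - tol || (s < step + tol && leave > 0L &&
                                 bi < basis[leave])) {
            step <- max(s, 0)
            leave <- k
            leave_to <- 1L
          }
        } else if (wk < -tol && is.finite(hi_all[bi])) {
          s <- (hi_all[bi] - x_all[bi]) / (-wk)
          if (s < step - tol || (s < step + tol && leave > 0L &&
                                 bi < basis[leave])) {
            step <- max(s, 0)
            leave <- k
            leave_to <- 2L
          }
        }
      }
      if (!is.finite(step)) {
        return(list(status = "unbounded", basis = basis, state = state,
                    x_all = x_all))
      }
      x_all[j] <- x_all[j] + dir * step
      x_all[basis] <- x_all[basis] - dir * step * w
      if (leave == 0L) {
        state[j] <- if (state[j] == 1L) 2L else 1L   # bound flip
      } else {
        out <- basis[leave]
        state[out] <- leave_to
        x_all[out] <- if (leave_to == 1L) lo_all[out] else hi_all[out]
        basis[leave] <- j
        state[j] <- 0L
      }
    }
    list(status = "iteration_limit", basis = basis, state = state,
         x_all = x_all)
  }

  max_iter <- max_iter %||% (200L + 50L * nall)
  obj1 <- c(rep(0, n), rep(1, m))
  ph1 <- run_phase(obj1, basis, state, x_all, hi_all, max_iter)
  if (ph1$status != "optimal") {
    return(list(status = ph1$status, value = NA_real_, x = NULL))
  }
  if (sum(ph1$x_all[n + seq_len(m)]) > feas_tol) {
    return(list(status = "infeasible", value = NA_real_, x = NULL))
  }
  # pin artificials to zero for phase 2 (basic-at-zero artificials are
  # harmless: their bounds forbid any movement)
  hi_all[n + seq_len(m)] <- 0
  obj2 <- c(sense * cost, rep(0, m))
  ph2 <- run_phase(obj2, ph1$basis, ph1$state, ph1$x_all, hi_all, max_iter)
  if (ph2$status != "optimal") {
    return(list(status = ph2$status, value = NA_real_, x = NULL))
  }
  x <- ph2$x_all[seq_len(n)]
  list(status = "optimal", value = sum(cost * x), x = x)
}
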