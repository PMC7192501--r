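#' Candidate ordered pairs from a flux sample
#'
#' Retains a directed pair (i, j) iff `v_i >= v_j - tol` holds in every
#' sampled flux vector. A single sampled violation is a counterexample proving
#' the pair unordered, so eliminated pairs need no LP verification. With an
#' empty sample every directed pair `i != j` is returned (vacuous truth).
#'
#' @param sample a `flux_sample` from [sample_flux_space()].
#' @param tol absolute tolerance on flux differences.
#' @return Tibble with columns `from`, `to` (reaction ids).
#' @export
candidate_pairs <- function(sample, tol = 1e-6) {
  ids <- colnames(sample)
  n <- length(ids)
  grid <- expand.grid(from = seq_len(n), to = seq_len(n))
  grid <- grid[grid$from != grid$to, ]
  if (nrow(sample) == 0) {
    return(tibble::tibble(from = ids[grid$from], to = ids[grid$to]))
  }
  M <- unclass(sample)
  ok <- matrix(TRUE, n, n)
  for (j in seq_len(n)) {
    # min over samples of v_i - v_j, for all i at once
    ok[, j] <- apply(M - M[, j], 2, min) >= -tol
  }
  keep <- ok[cbind(grid$from, grid$to)]
  tibble::tibble(from = ids[grid$from[keep]], to = ids[grid$to[keep]])
}

#' Resolve candidates that are fully coupled
#'
#' Fully coupled pairs satisfy `v_i = alpha * v_j` at every steady state, so
#' their order status follows from `alpha` without any LP: ordered iff
#' `alpha > 1`, always-equal iff `alpha = 1`. Such candidates are removed from
#' the LP queue and resolved directly.
#'
#' @param cands candidate tibble from [candidate_pairs()].
#' @param coupling a `coupling_table` computed on the same model/condition.
#' @param eps ratio tolerance.
#' @return `cands` with an added `resolution` column: `NA` (still pending LP
#'   verification), `"ordered"`, `"equal"`, or `"unordered"`.
#' @export
remove_fully_coupled <- function(cands, coupling, eps = 1e-6) {
  full <- coupling[coupling$class == "full", , drop = FALSE]
  res <- rep(NA_character_, nrow(cands))
  if (nrow(full)) {
    key <- paste(pmin(cands$from, cands$to), pmax(cands$from, cands$to))
    fkey <- paste(pmin(full$i, full$j), pmax(full$i, full$j))
    m <- match(key, fkey)
    hit <- which(!is.na(m))
    for (h in hit) {
      row <- full[m[h], ]
      alpha <- if (cands$from[h] == row$i) row$alpha else 1 / row$alpha
      res[h] <- if (abs(alpha - 1) <= eps) "equal"
      else if (alpha > 1) "ordered"
      else "unordered"
    }
  }
  cands$resolution <- res
  cands
}

#' Find all flux-ordered reaction pairs
#'
#' The two-stage exact algorithm: (1) a hit-and-run flux sample eliminates
#' every directed pair with a sampled counterexample to `v_i >= v_j`;
#' (2) fully coupled candidates are resolved from their coupling ratio; (3)
#' each remaining candidate is verified by the Charnes-Cooper ratio program
#' ([flux_ratio_bounds()] + [is_ordered()]). Because sampling only removes
#' pairs with explicit counterexamples, the result is exact and independent
#' of the sample and seed.
#'
#' @param model a canonical `metabolic_model` (see [canonicalize_model()]);
#'   when `cfg` is given, the medium is applied first.
#' @param cfg optional [medium_config()].
#' @param n_samples prefilter sample size (affects runtime only, default
#'   1000).
#' @param seed sampler seed.
#' @param eps ratio-space tolerance for order/equality calls.
#' @param coupling optional precomputed [coupling_table()]; computed when
#'   missing.
#' @return An `ordered_pair_set`: tibble with columns `from`, `to`,
#'   `relation` (`"ordered"` or `"equal"`), `method` (`"coupling"` or
#'   `"lp"`), `z_min`, `z_max`; attributes carry the condition label, seed,
#'   tolerances, reaction universe and model hash. Equal pairs are stored
#'   once, lexicographically oriented, and are meant for node collapsing in
#'   [build_order_dag()]. Pairs whose LPs failed are recorded in the
#'   `undetermined` attribute, never silently dropped.
#' @export
find_flux_ordered_pairs <- function(model, cfg = NULL, n_samples = 1000,
                                    seed = 1L, eps = 1e-6, coupling = NULL) {
  if (!is.null(cfg)) model <- apply_medium(model, cfg)
  if (any(model$reactions$lb < 0)) {
    stop("find_flux_ordered_pairs requires an irreversible model; ",
         "run canonicalize_model() first", call. = FALSE)
  }
  coupling <- coupling %||% coupling_table(model)
  sample <- sample_flux_space(model, n_samples, seed)
  cands <- candidate_pairs(sample)
  cands <- remove_fully_coupled(cands, coupling, eps)

  rows <- list()
  undetermined <- character()
  resolved_equal <- character()
  for (k in seq_len(nrow(cands))) {
    from <- cands$from[k]
    to <- cands$to[k]
    res <- cands$resolution[k]
    if (!is.na(res)) {
      if (res == "ordered") {
        rows[[length(rows) + 1L]] <- tibble::tibble(
          from = from, to = to, relation = "ordered", method = "coupling",
          z_min = NA_real_, z_max = NA_real_)
      } else if (res == "equal") {
        a <- min(from, to)
        b <- max(from, to)
        if (!paste(a, b) %in% resolved_equal) {
          resolved_equal <- c(resolved_equal, paste(a, b))
          rows[[length(rows) + 1L]] <- tibble::tibble(
            from = a, to = b, relation = "equal",
            method = "coupling", z_min = 1, z_max = 1)
        }
      }
      next
    }
    bounds <- flux_ratio_bounds(model, from, to)
    cls <- is_ordered(bounds, eps)
    if (cls == "undetermined") {
      # single retry with a larger iteration budget
      bounds <- flux_ratio_bounds(model, from, to)
      cls <- is_ordered(bounds, eps)
    }
    if (cls == "undetermined") {
      undetermined <- c(undetermined, paste0(from, "->", to))
      next
    }
    if (cls == "ordered") {
      rows[[length(rows) + 1L]] <- tibble::tibble(
        from = from, to = to, relation = "ordered", method = "lp",
        z_min = bounds$z_min, z_max = bounds$z_max)
    } else if (cls == "equal") {
      a <- min(from, to)
      b <- max(from, to)
      if (!paste(a, b) %in% resolved_equal) {
        resolved_equal <- c(resolved_equal, paste(a, b))
        rows[[length(rows) + 1L]] <- tibble::tibble(
          from = a, to = b, relation = "equal",
          method = "lp", z_min = bounds$z_min, z_max = bounds$z_max)
      }
    }
  }
  out <- if (length(rows)) dplyr::bind_rows(rows) else {
    tibble::tibble(from = character(), to = character(),
                   relation = character(), method = character(),
                   z_min = numeric(), z_max = numeric())
  }
  if (length(undetermined)) {
    warning(length(undetermined), " pair(s) undetermined after LP retry: ",
            paste(utils::head(undetermined, 5), collapse = ", "),
            call. = FALSE)
  }
  out <- new_ordered_pair_set(
    out,
    condition = model$condition,
    reaction_ids = model$reactions$id,
    seed = seed, n_samples = n_samples, eps = eps,
    model_hash = rlang::hash(list(model$S, model$reactions$lb,
                                  model$reactions$ub)),
    undetermined = undetermined)
  check_partial_order(out)
  out
}

new_ordered_pair_set <- function(df, condition = NA_character_,
                                 reaction_ids = NULL, seed = NA_integer_,
                                 n_samples = NA_integer_, eps = 1e-6,
                                 model_hash = NA_character_,
                                 undetermined = character()) {
  structure(tibble::as_tibble(df),
            class = c("ordered_pair_set", class(tibble::tibble())),
            condition = condition,
            reaction_ids = reaction_ids %||%
              sort(unique(c(df$from, df$to))),
            seed = seed, n_samples = n_samples, eps = eps,
            model_hash = model_hash, undetermined = undetermined)
}

# antisymmetry + transitive closure over the ">=" relation (ordered union
# symmetric equal); violations are numerical-tolerance defects and warned
check_partial_order <- function(orders) {
  ord <- orders[orders$relation == "ordered", c("from", "to")]
  if (nrow(ord)) {
    key <- paste(ord$from, ord$to)
    rkey <- paste(ord$to, ord$from)
    both <- intersect(key, rkey)
    if (length(both)) {
      warning("antisymmetry violated for: ",
              paste(utils::head(both, 5), collapse = "; "), call. = FALSE)
    }
  }
  ids <- attr(orders, "reaction_ids")
  n <- length(ids)
  if (n == 0 || nrow(orders) == 0) return(invisible(TRUE))
  A <- matrix(FALSE, n, n, dimnames = list(ids, ids))
  eq <- orders[orders$relation == "equal", ]
  A[cbind(match(orders$from, ids), match(orders$to, ids))] <- TRUE
  if (nrow(eq)) A[cbind(match(eq$to, ids), match(eq$from, ids))] <- TRUE
  R <- A
  repeat {
    R2 <- R | (R %*% R > 0)
    if (identical(R2, R)) break
    R <- R2
  }
  diag(R) <- FALSE
  missing <- which(R & !A, arr.ind = TRUE)
  if (nrow(missing)) {
    warning("transitive closure not attained for ", nrow(missing),
            " implied pair(s); likely a numerical-tolerance defect",
            call. = FALSE)
  }
  invisible(nrow(missing) == 0)
}

#' @export
print.ordered_pair_set <- function(x, ...) {
  cat("<ordered_pair_set> ", sum(x$relation == "ordered"), " ordered, ",
      sum(x$relation == "equal"), " equal pair(s)",
      if (!is.na(attr(x, "condition"))) paste0(" [", attr(x, "condition"), "]"),
      "\n", sep = "")
  NextMethod()
}

#' Write / read an ordered-pair set as TSV (+ JSON run manifest)
#'
#' The TSV has columns `source_id`, `target_id`, `relation`; the manifest
#' records the condition, seed, tolerances and model hash so a run can be
#' reproduced.
#'
#' @param orders an `ordered_pair_set`.
#' @param path output TSV path; the manifest is written alongside as
#'   `<path>.manifest.json`.
#' @return `path`, invisibly.
#' @export
write_ordered_pairs <- function(orders, path) {
  utils::write.table(
    data.frame(source_id = orders$from, target_id = orders$to,
               relation = orders$relation),
    path, sep = "\t", quote = FALSE, row.names = FALSE)
  manifest <- list(
    condition = attr(orders, "condition"),
    seed = attr(orders, "seed"),
    n_samples = attr(orders, "n_samples"),
    eps = attr(orders, "eps"),
    model_hash = attr(orders, "model_hash"),
    n_reactions = length(attr(orders, "reaction_ids")),
    package_version = as.character(utils::packageVersion("fluxorder")))
  jsonlite::write_json(manifest, paste0(path, ".manifest.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_ordered_pairs
#' @export
read_ordered_pairs <- function(path) {
  df <- utils::read.delim(path, sep = "\t", stringsAsFactors = FALSE)
  new_ordered_pair_set(tibble::tibble(
    from = df$source_id, to = df$target_id, relation = df$relation,
    method = "file", z_min = NA_real_, z_max = NA_real_))
}
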