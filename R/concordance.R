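#' Genes of a GPR rule
#'
#' Extracts the set of gene identifiers appearing anywhere in a boolean
#' gene-protein-reaction rule (duplicates count once).
#'
#' @param gpr GPR string, e.g. `"(b0001 and b0002) or b0003"`.
#' @return Character vector of gene ids (empty for an empty rule).
#' @export
gpr_genes <- function(gpr) {
  if (is.na(gpr) || !nzchar(trimws(gpr))) return(character(0))
  tokens <- strsplit(gsub("[()]", " ", gpr), "\\s+")[[1]]
  tokens <- tokens[nzchar(tokens)]
  unique(tokens[!tolower(tokens) %in% c("and", "or")])
}

#' Map gene-level data onto reactions through GPR rules
#'
#' For each reaction, pools the data values of every gene appearing anywhere
#' in its GPR (across replicates/conditions present in the table), producing
#' one multiset of values per covered reaction. Reactions with no covered
#' gene are absent from the profile.
#'
#' @param model a `metabolic_model` with GPR annotations.
#' @param gene_table data frame with columns `gene_id` and `value` (extra
#'   columns such as `condition` or `replicate` are ignored; all rows pool).
#' @param data_type free-form label (e.g. `"transcript"`, `"protein"`).
#' @return A `reaction_data_profile` tibble (`reaction_id`, `genes` and
#'   `values` list-columns, `mean`) with gene granularity; the per-gene
#'   value multisets ride along as an attribute for permutation analysis.
#' @export
map_data_to_reactions <- function(model, gene_table, data_type = "value") {
  stopifnot(all(c("gene_id", "value") %in% names(gene_table)))
  model_genes <- unique(unlist(lapply(model$reactions$gpr, gpr_genes)))
  covered <- intersect(model_genes, unique(gene_table$gene_id))
  if (length(covered) == 0) {
    stop("no overlap between data gene ids (e.g. ",
         paste(utils::head(unique(gene_table$gene_id), 3), collapse = ", "),
         ") and model GPR gene ids (e.g. ",
         paste(utils::head(model_genes, 3), collapse = ", "), ")",
         call. = FALSE)
  }
  gene_values <- split(gene_table$value[gene_table$gene_id %in% covered],
                       gene_table$gene_id[gene_table$gene_id %in% covered])
  rows <- purrr::map2(model$reactions$id, model$reactions$gpr,
                      function(id, gpr) {
    genes <- intersect(gpr_genes(gpr), covered)
    if (length(genes) == 0) return(NULL)
    vals <- unlist(gene_values[genes], use.names = FALSE)
    tibble::tibble(reaction_id = id, genes = list(genes),
                   values = list(vals), mean = mean(vals))
  })
  out <- dplyr::bind_rows(rows)
  if (nrow(out) == 0) {
    stop("no reaction is covered by the supplied gene data", call. = FALSE)
  }
  structure(out,
            class = c("reaction_data_profile", class(tibble::tibble())),
            granularity = "gene", data_type = data_type,
            gene_values = gene_values)
}

#' Reaction-granularity data profile
#'
#' For data measured (or defined) per reaction — fluxes, k_cat values,
#' enzyme costs — rather than per gene.
#'
#' @param reaction_table data frame with columns `reaction_id`, `value`;
#'   multiple rows per reaction form its value multiset.
#' @param data_type free-form label.
#' @return A `reaction_data_profile` with reaction granularity.
#' @export
reaction_data_profile <- function(reaction_table, data_type = "value") {
  stopifnot(all(c("reaction_id", "value") %in% names(reaction_table)))
  vals <- split(reaction_table$value, reaction_table$reaction_id)
  out <- tibble::tibble(
    reaction_id = names(vals),
    genes = list(character(0)),
    values = unname(vals),
    mean = vapply(vals, mean, numeric(1)))
  structure(out,
            class = c("reaction_data_profile", class(tibble::tibble())),
            granularity = "reaction", data_type = data_type,
            gene_values = NULL)
}

#' Mean pairwise difference between two value multisets
#'
#' `delta_ij = (1/(n m)) * sum_p sum_q (d_ip - d_jq)`, which collapses to
#' `mean(D_i) - mean(D_j)`.
#'
#' @param d_i,d_j nonempty numeric vectors.
#' @return Scalar mean difference.
#' @export
mean_difference <- function(d_i, d_j) {
  if (length(d_i) == 0 || length(d_j) == 0) {
    stop("mean_difference requires nonempty multisets", call. = FALSE)
  }
  mean(d_i) - mean(d_j)
}

#' Concordance of a data profile with the flux order relation
#'
#' For every ordered pair with data on both sides, computes the mean data
#' difference `delta_ij`; the fraction of strictly positive differences
#' `f_pos` quantifies how well the data respect the predicted ordering
#' (strict positivity guards against pairs whose enzymes share the same
#' gene set, which would match trivially with `delta = 0`). Significance
#' comes from a permutation null: data values are randomly reassigned at the
#' profile's granularity (per gene for transcript/protein, per reaction for
#' flux/k_cat), drawn with replacement from the pool of all available
#' values with multiset sizes preserved, and `f_pos` is recomputed each
#' round; the empirical p-value is `(r + 1) / (n_perm + 1)` with `r` the
#' number of rounds reaching at least the observed `f_pos`.
#'
#' @param orders an `ordered_pair_set`.
#' @param profile a `reaction_data_profile`.
#' @param n_perm number of permutation rounds (default 10000).
#' @param seed permutation seed.
#' @return A `concordance_result`: list with `delta` (tibble `from`, `to`,
#'   `delta`), `f_pos`, `n_pairs`, `p_value`, `n_perm`, `seed`,
#'   `data_type`, `granularity`.
#' @export
concordance <- function(orders, profile, n_perm = 10000, seed = 1L) {
  ord <- orders[orders$relation == "ordered", , drop = FALSE]
  covered <- ord$from %in% profile$reaction_id &
    ord$to %in% profile$reaction_id
  ord <- ord[covered, , drop = FALSE]
  if (nrow(ord) == 0) {
    stop("no ordered pair has data on both sides", call. = FALSE)
  }
  mu <- stats::setNames(profile$mean, profile$reaction_id)
  delta <- mu[ord$from] - mu[ord$to]
  f_pos <- mean(delta > 0)
  granularity <- attr(profile, "granularity")
  perm_fpos <- withr::with_seed(seed, {
    if (granularity == "gene") {
      gene_values <- attr(profile, "gene_values")
      pool <- unlist(gene_values, use.names = FALSE)
      sizes <- lengths(gene_values)
      gene_ids <- names(gene_values)
      rxn_gene_idx <- lapply(profile$genes, match, table = gene_ids)
      rxn_sizes <- lapply(rxn_gene_idx, function(ix) sizes[ix])
      from_i <- match(ord$from, profile$reaction_id)
      to_i <- match(ord$to, profile$reaction_id)
      vapply(seq_len(n_perm), function(rep) {
        draw_sums <- vapply(sizes, function(s) {
          sum(pool[sample.int(length(pool), s, replace = TRUE)])
        }, numeric(1))
        gmean_num <- draw_sums
        rmean <- vapply(seq_along(rxn_gene_idx), function(k) {
          ix <- rxn_gene_idx[[k]]
          sum(gmean_num[ix]) / sum(sizes[ix])
        }, numeric(1))
        mean(rmean[from_i] - rmean[to_i] > 0)
      }, numeric(1))
    } else {
      pool <- unlist(profile$values, use.names = FALSE)
      sizes <- lengths(profile$values)
      from_i <- match(ord$from, profile$reaction_id)
      to_i <- match(ord$to, profile$reaction_id)
      vapply(seq_len(n_perm), function(rep) {
        rmean <- vapply(sizes, function(s) {
          mean(pool[sample.int(length(pool), s, replace = TRUE)])
        }, numeric(1))
        mean(rmean[from_i] - rmean[to_i] > 0)
      }, numeric(1))
    }
  })
  r <- sum(perm_fpos >= f_pos - 1e-12)
  structure(
    list(delta = tibble::tibble(from = ord$from, to = ord$to,
                                delta = unname(delta)),
         f_pos = f_pos,
         n_pairs = nrow(ord),
         p_value = (r + 1) / (n_perm + 1),
         n_perm = n_perm,
         seed = seed,
         data_type = attr(profile, "data_type"),
         granularity = granularity),
    class = "concordance_result")
}

#' @export
print.concordance_result <- function(x, ...) {
  cat("<concordance_result> ", x$data_type, ": f_pos = ",
      format(x$f_pos, digits = 4), " over ", x$n_pairs,
      " ordered pair(s); permutation p = ", format(x$p_value, digits = 3),
      " (", x$n_perm, " rounds)\n", sep = "")
  invisible(x)
}

#' Restrict an ordered-pair set to high-cost enzymes
#'
#' Keeps the ordered pairs in which both reactions carry an enzyme cost at
#' least as large as the given percentile of the distribution of all
#' employed costs (linear-interpolation percentile on the per-reaction mean
#' cost). `percentile = 0` is the identity. Pairs with an uncosted reaction
#' are dropped from any nonzero-percentile subset.
#'
#' @param orders an `ordered_pair_set`.
#' @param costs a `reaction_data_profile` of enzyme costs at reaction
#'   granularity (mol carbon per mol protein).
#' @param percentile percentile in `[0, 100)`, e.g. 0, 70, 80, 85.
#' @return The filtered `ordered_pair_set` (attributes preserved).
#' @export
cost_percentile_subset <- function(orders, costs, percentile) {
  if (!is.numeric(percentile) || percentile < 0 || percentile >= 100) {
    stop("percentile must lie in [0, 100)", call. = FALSE)
  }
  if (percentile == 0) return(orders)
  thr <- stats::quantile(costs$mean, probs = percentile / 100,
                         names = FALSE, type = 7)
  costed <- costs$reaction_id[costs$mean >= thr]
  keep <- orders$from %in% costed & orders$to %in% costed
  out <- orders[keep, , drop = FALSE]
  attributes(out) <- utils::modifyList(
    attributes(orders), list(row.names = attr(out, "row.names")))
  out
}

#' Regulatory interactions across DAG level subsets
#'
#' Pools the total number of regulatory interactions (activating plus
#' inhibitory) of the genes catalysing the reactions of each level subset
#' (first / middle / last) and runs one-sided Mann-Whitney U tests for
#' larger counts in earlier subsets: first vs middle, first vs last, middle
#' vs last.
#'
#' @param dag an `order_dag`.
#' @param reg_counts data frame with columns `gene_id`, `n_interactions`.
#' @param model the `metabolic_model` supplying GPR rules.
#' @param partition a [level_partition()]; defaults to the standard
#'   first/middle/last split.
#' @return List with `distributions` (tibble: subset, gene_id,
#'   n_interactions) and `tests` (tibble: comparison, p_value, n_a, n_b;
#'   comparisons with an empty subset are skipped with a warning).
#' @export
regulatory_level_analysis <- function(dag, reg_counts, model,
                                      partition = level_partition(dag)) {
  stopifnot(all(c("gene_id", "n_interactions") %in% names(reg_counts)))
  gpr_of <- stats::setNames(model$reactions$gpr, model$reactions$id)
  subset_counts <- lapply(partition, function(nodes) {
    rxns <- unique(unlist(dag$nodes$members[dag$nodes$node %in% nodes]))
    genes <- unique(unlist(lapply(gpr_of[intersect(rxns, names(gpr_of))],
                                  gpr_genes)))
    hit <- reg_counts$gene_id %in% genes
    tibble::tibble(gene_id = reg_counts$gene_id[hit],
                   n_interactions = reg_counts$n_interactions[hit])
  })
  distributions <- dplyr::bind_rows(subset_counts, .id = "subset")
  combos <- list(c("first", "middle"), c("first", "last"),
                 c("middle", "last"))
  tests <- purrr::map(combos, function(cmp) {
    a <- subset_counts[[cmp[1]]]$n_interactions
    b <- subset_counts[[cmp[2]]]$n_interactions
    if (length(a) == 0 || length(b) == 0) {
      warning("empty subset in comparison ", cmp[1], " vs ", cmp[2],
              "; skipped", call. = FALSE)
      return(NULL)
    }
    p <- stats::wilcox.test(a, b, alternative = "greater",
                            exact = NULL)$p.value
    tibble::tibble(comparison = paste(cmp, collapse = "_vs_"),
                   p_value = p, n_a = length(a), n_b = length(b))
  })
  list(distributions = distributions, tests = dplyr::bind_rows(tests))
}
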