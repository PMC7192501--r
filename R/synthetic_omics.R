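#' Generate synthetic omics tables consistent with a flux state
#'
#' Draws one steady-state flux vector (the "truth"), assigns every gene the
#' mean truth of the reactions it catalyses plus Gaussian noise, and emits
#' tables in the concordance input format. With `noise_sd = 0`, data follow
#' the flux order relation exactly wherever the sampled fluxes differ
#' strictly; with large noise the data are uninformative and concordance
#' approaches the null. Reactions without a GPR receive a synthetic
#' single-gene rule `g_<reaction_id>` so every reaction is covered.
#'
#' @param model a canonical `metabolic_model`.
#' @param noise_sd standard deviation of the additive Gaussian noise, on the
#'   flux scale (mmol/gDW/h).
#' @param seed integer seed; tables are identical for a fixed seed.
#' @param n_replicates noisy replicates per gene.
#' @return List with `gene_data` (tibble: gene_id, condition, replicate,
#'   value), `reaction_data` (tibble: reaction_id, value — the noiseless
#'   truth), `truth` (named flux vector), and `model` (with synthetic GPRs
#'   filled in).
#' @export
synthetic_omics <- function(model, noise_sd = 0, seed = 1L,
                            n_replicates = 3) {
  empty <- !nzchar(trimws(model$reactions$gpr))
  model$reactions$gpr[empty] <- paste0("g_", model$reactions$id[empty])
  truth <- sample_flux_space(model, 1, seed = seed)[1, ]
  rxn_genes <- lapply(model$reactions$gpr, gpr_genes)
  gene_rxns <- split(
    rep(model$reactions$id, lengths(rxn_genes)),
    unlist(rxn_genes))
  gene_truth <- vapply(gene_rxns, function(r) mean(truth[r]), numeric(1))
  gene_data <- withr::with_seed(seed + 1L, {
    tidyr::crossing(gene_id = names(gene_truth),
                    replicate = seq_len(n_replicates)) |>
      dplyr::mutate(
        condition = "synthetic",
        value = gene_truth[.data$gene_id] +
          stats::rnorm(dplyr::n(), sd = noise_sd)) |>
      dplyr::select("gene_id", "condition", "replicate", "value")
  })
  reaction_data <- tibble::tibble(reaction_id = model$reactions$id,
                                  value = unname(truth))
  list(gene_data = gene_data, reaction_data = reaction_data,
       truth = truth, model = model)
}
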