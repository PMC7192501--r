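#' Construct a constraint-based metabolic model
#'
#' A `metabolic_model` couples a (sparse) stoichiometric matrix `S` with
#' per-reaction flux bounds, gene-protein-reaction (GPR) rules and pathway
#' annotations. Rows of `S` are metabolites, columns are reactions; entry
#' `s_ij < 0` marks metabolite i as a substrate of reaction j, `s_ij > 0` as a
#' product. Steady states are the polytope `{v : S v = 0, lb <= v <= ub}`
#' (fluxes in mmol/gDW/h).
#'
#' @param S numeric matrix or `Matrix::sparseMatrix`, metabolites x reactions.
#' @param reactions data frame with columns `id`, `lb`, `ub` and optionally
#'   `name`, `gpr`, `subsystem`, `macrosystem`.
#' @param metabolites data frame with column `id` and optionally `name`,
#'   `compartment`, `boundary` (logical boundary-condition flag).
#' @param biomass_id,atpm_id reaction ids of the biomass pseudo-reaction and of
#'   the non-growth-associated ATP maintenance reaction, or `NA` when absent
#'   (toy models).
#' @param exchanges optional character vector of reaction ids annotated as
#'   exchange reactions; when present it takes precedence over structural
#'   exchange detection.
#' @param condition free-form label of the simulated condition.
#'
#' @return An object of class `metabolic_model`.
#' @export
metabolic_model <- function(S, reactions, metabolites,
                            biomass_id = NA_character_,
                            atpm_id = NA_character_,
                            exchanges = NULL,
                            condition = NA_character_) {
  S <- methods::as(methods::as(Matrix::Matrix(S, sparse = TRUE), "generalMatrix"), "CsparseMatrix")
  reactions <- tibble::as_tibble(reactions)
  metabolites <- tibble::as_tibble(metabolites)
  for (col in c("name", "gpr", "subsystem", "macrosystem")) {
    if (!col %in% names(reactions)) reactions[[col]] <- ""
  }
  reactions$gpr[is.na(reactions$gpr)] <- ""
  reactions$subsystem[is.na(reactions$subsystem)] <- ""
  if (!"boundary" %in% names(metabolites)) metabolites$boundary <- FALSE
  if (!"name" %in% names(metabolites)) metabolites$name <- ""
  if (!"compartment" %in% names(metabolites)) metabolites$compartment <- ""
  dimnames(S) <- list(metabolites$id, reactions$id)
  model <- structure(
    list(
      S = S,
      reactions = reactions,
      metabolites = metabolites,
      biomass_id = biomass_id,
      atpm_id = atpm_id,
      exchanges = exchanges,
      condition = condition
    ),
    class = "metabolic_model"
  )
  validate_metabolic_model(model)
}

validate_metabolic_model <- function(model) {
  S <- model$S
  rxn <- model$reactions
  met <- model$metabolites
  if (nrow(rxn) != ncol(S)) {
    stop("number of reactions (", nrow(rxn), ") does not match ncol(S) (",
         ncol(S), ")", call. = FALSE)
  }
  if (nrow(met) != nrow(S)) {
    stop("number of metabolites (", nrow(met), ") does not match nrow(S) (",
         nrow(S), ")", call. = FALSE)
  }
  if (anyDuplicated(rxn$id)) {
    stop("duplicated reaction ids: ",
         paste(unique(rxn$id[duplicated(rxn$id)]), collapse = ", "),
         call. = FALSE)
  }
  if (anyDuplicated(met$id)) {
    stop("duplicated metabolite ids", call. = FALSE)
  }
  if (any(rxn$lb > rxn$ub + 1e-12)) {
    bad <- rxn$id[rxn$lb > rxn$ub + 1e-12]
    stop("lower bound exceeds upper bound for: ",
         paste(bad, collapse = ", "), call. = FALSE)
  }
  if (!is.na(model$biomass_id) && !model$biomass_id %in% rxn$id) {
    stop("biomass_id '", model$biomass_id, "' is not a model reaction",
         call. = FALSE)
  }
  model
}

#' @export
print.metabolic_model <- function(x, ...) {
  cat("<metabolic_model> ", n_metabolites(x), " metabolites x ",
      n_reactions(x), " reactions\n", sep = "")
  irr <- all(x$reactions$lb >= 0)
  cat("  bounds: [", format(min(x$reactions$lb)), ", ",
      format(max(x$reactions$ub)), "]",
      if (irr) " (irreversible form)" else " (has reversible reactions)",
      "\n", sep = "")
  if (!is.na(x$biomass_id)) cat("  biomass: ", x$biomass_id, "\n", sep = "")
  if (!is.na(x$condition)) cat("  condition: ", x$condition, "\n", sep = "")
  invisible(x)
}

#' @rdname metabolic_model
#' @param model a `metabolic_model`.
#' @export
n_reactions <- function(model) ncol(model$S)

#' @rdname metabolic_model
#' @export
n_metabolites <- function(model) nrow(model$S)

#' @rdname metabolic_model
#' @export
reaction_ids <- function(model) model$reactions$id

rxn_index <- function(model, id) {
  idx <- match(id, model$reactions$id)
  if (anyNA(idx)) {
    stop("unknown reaction id(s): ", paste(id[is.na(idx)], collapse = ", "),
         call. = FALSE)
  }
  idx
}

#' Identify exchange reactions
#'
#' A reaction is treated as an exchange if it is listed in the model's exchange
#' annotation; absent an annotation, a structural rule is used: after dropping
#' rows of boundary metabolites, the column has nonzero entries of one sign
#' only (a pure source or pure sink of mass).
#'
#' @param model a `metabolic_model`.
#' @return Character vector of exchange reaction ids.
#' @export
find_exchanges <- function(model) {
  if (!is.null(model$exchanges)) {
    return(intersect(model$exchanges, model$reactions$id))
  }
  keep <- !model$metabolites$boundary
  S <- model$S[keep, , drop = FALSE]
  is_ex <- vapply(seq_len(ncol(S)), function(j) {
    col <- S[, j]
    nz <- col[col != 0]
    length(nz) > 0 && (all(nz > 0) || all(nz < 0))
  }, logical(1))
  model$reactions$id[is_ex]
}

#' Remove reactions from a model
#'
#' Drops the given reactions (columns of `S`) and any metabolites left
#' without participating reactions.
#'
#' @param model a `metabolic_model`.
#' @param ids reaction ids to remove.
#' @param drop_orphans drop metabolites no longer used by any reaction.
#' @return The reduced `metabolic_model`.
#' @export
remove_reactions <- function(model, ids, drop_orphans = TRUE) {
  if (length(ids) == 0) return(model)
  keep <- !model$reactions$id %in% ids
  model$S <- model$S[, keep, drop = FALSE]
  model$reactions <- model$reactions[keep, , drop = FALSE]
  if (!is.na(model$biomass_id) && !model$biomass_id %in% model$reactions$id) {
    model$biomass_id <- NA_character_
  }
  if (!is.na(model$atpm_id) && !model$atpm_id %in% model$reactions$id) {
    model$atpm_id <- NA_character_
  }
  if (!is.null(model$exchanges)) {
    model$exchanges <- intersect(model$exchanges, model$reactions$id)
  }
  if (drop_orphans) {
    used <- Matrix::rowSums(abs(model$S)) > 0
    model$S <- model$S[used, , drop = FALSE]
    model$metabolites <- model$metabolites[used, , drop = FALSE]
  }
  validate_metabolic_model(model)
}
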