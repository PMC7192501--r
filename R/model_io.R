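#' Read a metabolic model from SBML or COBRA-JSON
#'
#' Parses a genome-scale or toy model into a [metabolic_model()]. Original
#' (possibly negative) bounds, GPR rules and subsystem annotations are
#' preserved verbatim; infinite or missing bounds are capped at
#' `+/- bound_cap` so all downstream linear programs stay bounded.
#'
#' @param path path to the model file.
#' @param format `"sbml"` (Level 3 core + fbc) or `"json"` (COBRA-JSON);
#'   guessed from the file extension by default.
#' @param bound_cap cap applied to infinite bounds (mmol/gDW/h).
#' @return A `metabolic_model` (not yet canonicalized; see
#'   [canonicalize_model()]).
#' @export
read_model <- function(path, format = c("auto", "sbml", "json"),
                       bound_cap = 1000) {
  format <- match.arg(format)
  if (format == "auto") {
    format <- if (grepl("\\.json$", path, ignore.case = TRUE)) "json" else "sbml"
  }
  model <- switch(format,
                  json = read_cobra_json(path),
                  sbml = read_sbml(path))
  model$reactions$lb <- pmax(model$reactions$lb, -bound_cap)
  model$reactions$ub <- pmin(model$reactions$ub, bound_cap)
  validate_metabolic_model(model)
}

read_cobra_json <- function(path) {
  doc <- tryCatch(jsonlite::fromJSON(path, simplifyVector = FALSE),
                  error = function(e) {
                    stop("cannot parse COBRA-JSON '", path, "': ",
                         conditionMessage(e), call. = FALSE)
                  })
  if (is.null(doc$reactions) || is.null(doc$metabolites)) {
    stop("COBRA-JSON '", path,
         "' lacks a reactions or metabolites list", call. = FALSE)
  }
  mets <- tibble::tibble(
    id = vapply(doc$metabolites, function(m) m$id, character(1)),
    name = vapply(doc$metabolites, function(m) m$name %||% "", character(1)),
    compartment = vapply(doc$metabolites,
                         function(m) as.character(m$compartment %||% ""),
                         character(1)),
    boundary = vapply(doc$metabolites,
                      function(m) isTRUE(m$boundary_condition), logical(1))
  )
  rxns <- tibble::tibble(
    id = vapply(doc$reactions, function(r) r$id, character(1)),
    name = vapply(doc$reactions, function(r) r$name %||% "", character(1)),
    lb = vapply(doc$reactions, function(r) as.numeric(r$lower_bound %||% 0),
                numeric(1)),
    ub = vapply(doc$reactions, function(r) as.numeric(r$upper_bound %||% 0),
                numeric(1)),
    gpr = vapply(doc$reactions, function(r) r$gene_reaction_rule %||% "",
                 character(1)),
    subsystem = vapply(doc$reactions, function(r) r$subsystem %||% "",
                       character(1))
  )
  trip <- list()
  for (j in seq_along(doc$reactions)) {
    st <- doc$reactions[[j]]$metabolites
    if (length(st) == 0) {
      stop("reaction '", rxns$id[j], "' has no reactants and no products",
           call. = FALSE)
    }
    i <- match(names(st), mets$id)
    if (anyNA(i)) {
      stop("reaction '", rxns$id[j], "' references unknown metabolite(s): ",
           paste(names(st)[is.na(i)], collapse = ", "), call. = FALSE)
    }
    trip[[j]] <- cbind(i, j, as.numeric(unlist(st)))
  }
  trip <- do.call(rbind, trip)
  S <- Matrix::sparseMatrix(i = trip[, 1], j = trip[, 2], x = trip[, 3],
                            dims = c(nrow(mets), nrow(rxns)))
  metabolic_model(S, rxns, mets)
}

read_sbml <- function(path) {
  doc <- tryCatch(xml2::read_xml(path),
                  error = function(e) {
                    stop("cannot parse SBML '", path, "': ",
                         conditionMessage(e), call. = FALSE)
                  })
  xml2::xml_ns_strip(doc)
  sp_nodes <- xml2::xml_find_all(doc, ".//listOfSpecies/species")
  rx_nodes <- xml2::xml_find_all(doc, ".//listOfReactions/reaction")
  if (length(rx_nodes) == 0) {
    stop("SBML '", path, "' contains no reactions", call. = FALSE)
  }
  par_nodes <- xml2::xml_find_all(doc, ".//listOfParameters/parameter")
  params <- stats::setNames(
    as.numeric(xml2::xml_attr(par_nodes, "value")),
    xml2::xml_attr(par_nodes, "id"))
  gp_nodes <- xml2::xml_find_all(
    doc, ".//*[local-name()='listOfGeneProducts']/*[local-name()='geneProduct']")
  gp_label <- stats::setNames(
    dplyr::coalesce(xml2::xml_attr(gp_nodes, "label"),
                    xml2::xml_attr(gp_nodes, "id")),
    xml2::xml_attr(gp_nodes, "id"))

  mets <- tibble::tibble(
    id = xml2::xml_attr(sp_nodes, "id"),
    name = xml2::xml_attr(sp_nodes, "name") %|NA|% "",
    compartment = xml2::xml_attr(sp_nodes, "compartment") %|NA|% "",
    boundary = xml2::xml_attr(sp_nodes, "boundaryCondition") %in%
      c("true", "1")
  )

  n_rx <- length(rx_nodes)
  rxns <- tibble::tibble(
    id = xml2::xml_attr(rx_nodes, "id"),
    name = xml2::xml_attr(rx_nodes, "name") %|NA|% "",
    lb = NA_real_, ub = NA_real_,
    gpr = "", subsystem = ""
  )
  trip <- list()
  for (j in seq_len(n_rx)) {
    node <- rx_nodes[[j]]
    reac <- xml2::xml_find_all(node, "./listOfReactants/speciesReference")
    prod <- xml2::xml_find_all(node, "./listOfProducts/speciesReference")
    if (length(reac) + length(prod) == 0) {
      stop("reaction '", rxns$id[j], "' has no reactants and no products",
           call. = FALSE)
    }
    sto <- function(nodes, sign) {
      if (length(nodes) == 0) return(NULL)
      sp <- xml2::xml_attr(nodes, "species")
      coef <- as.numeric(xml2::xml_attr(nodes, "stoichiometry"))
      coef[is.na(coef)] <- 1
      i <- match(sp, mets$id)
      if (anyNA(i)) {
        stop("reaction '", rxns$id[j], "' references unknown species: ",
             paste(sp[is.na(i)], collapse = ", "), call. = FALSE)
      }
      cbind(i, j, sign * coef)
    }
    trip[[j]] <- rbind(sto(reac, -1), sto(prod, 1))

    rev <- xml2::xml_attr(node, "reversible") %in% c("true", "1", NA)
    lb_ref <- xml2::xml_attr(node, "lowerFluxBound")
    ub_ref <- xml2::xml_attr(node, "upperFluxBound")
    rxns$lb[j] <- if (!is.na(lb_ref) && lb_ref %in% names(params)) {
      params[[lb_ref]]
    } else if (rev) -Inf else 0
    rxns$ub[j] <- if (!is.na(ub_ref) && ub_ref %in% names(params)) {
      params[[ub_ref]]
    } else Inf

    gpa <- xml2::xml_find_first(
      node, "./*[local-name()='geneProductAssociation']")
    if (!inherits(gpa, "xml_missing")) {
      rxns$gpr[j] <- sbml_gpr_string(xml2::xml_children(gpa)[[1]], gp_label)
    }
    notes <- xml2::xml_find_first(node, "./notes")
    if (!inherits(notes, "xml_missing")) {
      txt <- xml2::xml_text(notes)
      m <- regmatches(txt, regexpr("SUBSYSTEM:\\s*[^\n<]+", txt))
      if (length(m)) rxns$subsystem[j] <- trimws(sub("SUBSYSTEM:\\s*", "", m))
    }
  }
  trip <- do.call(rbind, trip)
  # collapse duplicated (metabolite, reaction) entries additively
  S <- Matrix::sparseMatrix(i = trip[, 1], j = trip[, 2], x = trip[, 3],
                            dims = c(nrow(mets), n_rx))
  metabolic_model(S, rxns, mets)
}

sbml_gpr_string <- function(node, gp_label) {
  nm <- xml2::xml_name(node)
  if (nm == "geneProductRef") {
    ref <- xml2::xml_attr(node, "geneProduct")
    return(gp_label[[ref]] %||% ref)
  }
  parts <- vapply(xml2::xml_children(node), sbml_gpr_string,
                  character(1), gp_label = gp_label)
  paste0("(", paste(parts, collapse = paste0(" ", nm, " ")), ")")
}

`%|NA|%` <- function(x, y) ifelse(is.na(x), y, x)

#' Serialize a model to COBRA-JSON
#'
#' @param model a `metabolic_model`.
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_model_json <- function(model, path) {
  rxns <- purrr::pmap(model$reactions, function(id, name, lb, ub, gpr,
                                                subsystem, ...) {
    j <- match(id, model$reactions$id)
    col <- model$S[, j]
    nz <- which(col != 0)
    list(id = id, name = name,
         metabolites = as.list(stats::setNames(as.numeric(col[nz]),
                                               model$metabolites$id[nz])),
         lower_bound = lb, upper_bound = ub,
         gene_reaction_rule = gpr, subsystem = subsystem)
  })
  mets <- purrr::pmap(model$metabolites, function(id, name, compartment,
                                                  boundary, ...) {
    list(id = id, name = name, compartment = compartment,
         boundary_condition = boundary)
  })
  genes <- unique(unlist(lapply(model$reactions$gpr, gpr_genes)))
  doc <- list(metabolites = mets, reactions = rxns,
              genes = lapply(genes, function(g) list(id = g, name = g)),
              id = "fluxorder_model")
  jsonlite::write_json(doc, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(path)
}

#' Split reversible reactions into forward and backward copies
#'
#' Every reaction with a negative lower bound is replaced by a forward copy
#' with bounds `[0, ub]` and a reverse copy (negated stoichiometric column,
#' id suffixed `"_reverse"`) with bounds `[0, -lb]`. GPR and subsystem
#' annotations are copied to both. A reaction with `ub <= 0` yields only the
#' reverse copy. After splitting, all fluxes are non-negative.
#'
#' @param model a `metabolic_model`.
#' @return The irreversible `metabolic_model`.
#' @export
split_reversible <- function(model) {
  rev_idx <- which(model$reactions$lb < 0)
  if (length(rev_idx) == 0) return(model)
  S <- model$S
  rxns <- model$reactions
  keep_fwd <- setdiff(seq_len(nrow(rxns)), rev_idx[rxns$ub[rev_idx] <= 0])
  bwd <- rxns[rev_idx, , drop = FALSE]
  bwd$id <- paste0(bwd$id, "_reverse")
  bwd$ub <- -bwd$lb
  bwd$lb <- 0
  fwd <- rxns[keep_fwd, , drop = FALSE]
  fwd$lb <- pmax(fwd$lb, 0)
  new_S <- cbind(S[, keep_fwd, drop = FALSE], -S[, rev_idx, drop = FALSE])
  new_rxns <- dplyr::bind_rows(fwd, bwd)
  exch <- model$exchanges
  if (!is.null(exch)) {
    exch <- union(intersect(exch, new_rxns$id),
                  paste0(intersect(exch, rxns$id[rev_idx]), "_reverse"))
  }
  metabolic_model(new_S, new_rxns, model$metabolites,
                  biomass_id = model$biomass_id, atpm_id = model$atpm_id,
                  exchanges = exch, condition = model$condition)
}

#' Find blocked reactions
#'
#' A reaction is blocked when its maximum achievable flux over
#' `{S v = 0, lb <= v <= ub}` is at most `tol`; blocked reactions cannot carry
#' flux at steady state and are removed during canonicalization. The search
#' is objective-independent: one flux maximization per still-undecided
#' reaction, with every strictly positive flux in each solution marking its
#' reaction unblocked.
#'
#' @param model an irreversible `metabolic_model`.
#' @param tol tolerance on the LP optimum (default `1e-9`).
#' @return Character vector of blocked reaction ids.
#' @export
find_blocked_reactions <- function(model, tol = 1e-9) {
  if (any(model$reactions$lb < 0)) {
    stop("find_blocked_reactions expects an irreversible model", call. = FALSE)
  }
  n <- n_reactions(model)
  undecided <- rep(TRUE, n)
  blocked <- rep(FALSE, n)
  for (j in seq_len(n)) {
    if (!undecided[j]) next
    obj <- numeric(n)
    obj[j] <- 1
    res <- lp_over_polytope(model, obj, maximize = TRUE)
    if (res$status == "infeasible") {
      stop("model is infeasible: no steady-state flux vector satisfies the bounds",
           call. = FALSE)
    }
    if (res$status != "optimal") {
      stop("blocked-reaction LP failed with status ", res$status, call. = FALSE)
    }
    if (res$value <= tol) {
      blocked[j] <- TRUE
      undecided[j] <- FALSE
    } else {
      undecided[res$v > tol] <- FALSE
    }
  }
  model$reactions$id[blocked]
}

#' Canonicalize a model to irreversible, unblocked form
#'
#' Caps infinite bounds, splits reversible reactions, removes zero-width
#' (`lb = ub = 0`) reactions, and removes blocked reactions. All downstream
#' pair analyses require this form.
#'
#' @param model a `metabolic_model`.
#' @param bound_cap cap for infinite bounds (mmol/gDW/h).
#' @param tol blocked-reaction tolerance.
#' @return The canonical `metabolic_model`.
#' @export
canonicalize_model <- function(model, bound_cap = 1000, tol = 1e-9) {
  model$reactions$lb <- pmax(model$reactions$lb, -bound_cap)
  model$reactions$ub <- pmin(model$reactions$ub, bound_cap)
  model <- split_reversible(model)
  zero <- model$reactions$id[model$reactions$lb == 0 & model$reactions$ub == 0]
  model <- remove_reactions(model, zero)
  model <- remove_reactions(model, find_blocked_reactions(model, tol))
  model
}

#' Growth-medium configuration
#'
#' Describes a minimal medium with a single carbon source: all exchange
#' imports are closed except the carbon source (capped at
#' `carbon_uptake_max`) and the `open_exchanges` (oxygen and inorganic
#' compounds), the biomass flux is bounded below by `biomass_fraction` of its
#' FBA optimum under the medium, and the ATP maintenance reaction keeps a
#' minimum flux of `atpm_min`.
#'
#' @param carbon_source exchange reaction id of the sole carbon source.
#' @param carbon_uptake_max maximum carbon import rate (default 20
#'   mmol/gDW/h).
#' @param open_exchanges exchange ids left unconstrained.
#' @param biomass_fraction required fraction `alpha_b` of the optimal biomass
#'   rate, in `[0, 1]` (default 0.95).
#' @param atpm_min minimum ATP maintenance flux (default 3.15 mmol/gDW/h).
#' @return A `medium_config` list.
#' @export
medium_config <- function(carbon_source, carbon_uptake_max = 20,
                          open_exchanges = character(),
                          biomass_fraction = 0.95, atpm_min = 3.15) {
  stopifnot(is.character(carbon_source), length(carbon_source) == 1)
  if (!is.numeric(carbon_uptake_max) || carbon_uptake_max <= 0) {
    stop("carbon_uptake_max must be positive", call. = FALSE)
  }
  if (biomass_fraction < 0 || biomass_fraction > 1) {
    stop("biomass_fraction must lie in [0, 1]", call. = FALSE)
  }
  structure(list(carbon_source = carbon_source,
                 carbon_uptake_max = carbon_uptake_max,
                 open_exchanges = open_exchanges,
                 biomass_fraction = biomass_fraction,
                 atpm_min = atpm_min),
            class = "medium_config")
}

#' Apply a growth-medium configuration
#'
#' Closes all import exchanges except the carbon source and the configured
#' open exchanges, sets the carbon import cap, installs the ATP maintenance
#' minimum, fixes the biomass lower bound at `biomass_fraction` times the FBA
#' optimum under the medium, and removes reactions newly blocked by the
#' medium. Idempotent for a fixed configuration.
#'
#' @param model a canonical `metabolic_model`.
#' @param cfg a [medium_config()].
#' @param tol blocked-reaction tolerance for the post-medium cleanup.
#' @return The constrained `metabolic_model`, with its `condition` field set
#'   to `"<carbon_source>@<biomass_fraction>"`.
#' @export
apply_medium <- function(model, cfg, tol = 1e-9) {
  stopifnot(inherits(cfg, "medium_config"))
  if (cfg$biomass_fraction > 0 && is.na(model$biomass_id)) {
    stop("biomass_fraction > 0 requires a model biomass_id", call. = FALSE)
  }
  exch <- find_exchanges(model)
  # imports in irreversible form: exchange columns producing mass (all
  # nonzero entries positive over non-boundary metabolites)
  keep <- !model$metabolites$boundary
  is_import <- vapply(exch, function(id) {
    col <- model$S[keep, rxn_index(model, id)]
    nz <- col[col != 0]
    length(nz) > 0 && all(nz > 0)
  }, logical(1))
  imports <- exch[is_import]
  closed <- setdiff(imports, c(cfg$carbon_source, cfg$open_exchanges))
  idx <- rxn_index(model, closed)
  model$reactions$ub[idx] <- 0
  model$reactions$lb[idx] <- 0
  if (cfg$carbon_source %in% model$reactions$id) {
    model$reactions$ub[rxn_index(model, cfg$carbon_source)] <-
      cfg$carbon_uptake_max
  } else {
    stop("carbon source '", cfg$carbon_source, "' is not a model reaction",
         call. = FALSE)
  }
  if (!is.na(model$atpm_id)) {
    model$reactions$lb[rxn_index(model, model$atpm_id)] <- cfg$atpm_min
  }
  if (!is.na(model$biomass_id)) {
    bidx <- rxn_index(model, model$biomass_id)
    model$reactions$lb[bidx] <- 0
    opt <- solve_fba(model, model$biomass_id, "max")$optimum
    if (opt <= tol && cfg$biomass_fraction > 0) {
      stop("no growth on this medium: biomass optimum is 0 with carbon source '",
           cfg$carbon_source, "'", call. = FALSE)
    }
    model$reactions$lb[bidx] <- cfg$biomass_fraction * opt
  }
  model <- remove_reactions(model, find_blocked_reactions(model, tol))
  model$condition <- paste0(cfg$carbon_source, "@", cfg$biomass_fraction)
  model
}

#' Default subsystem-to-macrosystem mapping
#'
#' Eight macrosystem categories (amino acid, carbohydrate, energy and
#' maintenance, cell wall, cofactor and vitamin, lipid, nucleotide metabolism,
#' and transport) keyed by subsystem name. Shipped as an editable TSV in
#' `inst/extdata/macrosystem_map.tsv`; pass your own table to
#' [assign_macrosystems()] to override.
#'
#' @return Tibble with columns `subsystem`, `macrosystem`.
#' @export
macrosystem_map <- function() {
  path <- system.file("extdata", "macrosystem_map.tsv", package = "fluxorder")
  tibble::as_tibble(utils::read.delim(path, sep = "\t",
                                      stringsAsFactors = FALSE))
}

#' Assign macrosystem labels to reactions
#'
#' @param model a `metabolic_model` with subsystem annotations.
#' @param map data frame with columns `subsystem`, `macrosystem`; defaults to
#'   the shipped mapping. Unmapped subsystems map to `"other"`.
#' @return The model with its `macrosystem` reaction column filled in.
#' @export
assign_macrosystems <- function(model, map = macrosystem_map()) {
  i <- match(model$reactions$subsystem, map$subsystem)
  model$reactions$macrosystem <- ifelse(is.na(i), "other", map$macrosystem[i])
  model
}
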