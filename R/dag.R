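#' Build the flux order DAG
#'
#' Collapses groups of always-equal reactions (fully coupled with
#' `alpha = 1`, extended transitively) into single nodes, draws one edge per
#' ordered group pair, and applies the transitive reduction, yielding the
#' Hasse diagram of the flux-order poset. Hierarchy levels (longest shortest
#' path from any root) are assigned to every node.
#'
#' @param orders an `ordered_pair_set` (its `"equal"` rows define the
#'   collapsed groups unless `equal_groups` is supplied).
#' @param equal_groups optional list of character vectors partitioning
#'   reactions into equal-flux groups.
#' @return An `order_dag`: list with `graph` (igraph), `nodes` (tibble:
#'   `node`, `members` list-column, `level`), and `condition`.
#' @export
build_order_dag <- function(orders, equal_groups = NULL) {
  ids <- attr(orders, "reaction_ids") %||%
    sort(unique(c(orders$from, orders$to)))
  if (is.null(equal_groups)) {
    eq <- orders[orders$relation == "equal", , drop = FALSE]
    g_eq <- igraph::graph_from_data_frame(
      eq[, c("from", "to")], directed = FALSE,
      vertices = data.frame(name = ids))
    comp <- igraph::components(g_eq)
    equal_groups <- split(ids, comp$membership[ids])
  }
  label_of <- stats::setNames(
    rep(vapply(equal_groups, function(g) min(g), character(1)),
        lengths(equal_groups)),
    unlist(equal_groups))
  missing <- setdiff(ids, names(label_of))
  label_of[missing] <- missing
  ord <- orders[orders$relation == "ordered", , drop = FALSE]
  edges <- unique(data.frame(from = unname(label_of[ord$from]),
                             to = unname(label_of[ord$to])))
  edges <- edges[edges$from != edges$to, , drop = FALSE]
  labels <- sort(unique(unname(label_of[ids])))
  g <- igraph::graph_from_data_frame(edges, directed = TRUE,
                                     vertices = data.frame(name = labels))
  if (!igraph::is_dag(g)) {
    comp <- igraph::components(g, mode = "strong")
    cyc <- names(comp$membership)[comp$membership %in%
                                    which(comp$csize > 1)]
    stop("order relation contains a cycle (numerical artifact) among: ",
         paste(cyc, collapse = ", "), call. = FALSE)
  }
  g <- transitive_reduction(g)
  members <- split(names(label_of), unname(label_of))
  nodes <- tibble::tibble(
    node = labels,
    members = unname(members[labels]))
  dag <- structure(list(graph = g, nodes = nodes,
                        condition = attr(orders, "condition")),
                   class = "order_dag")
  dag$nodes$level <- unname(assign_levels(dag)[labels])
  dag
}

# unique for DAGs: drop every edge implied by a path of length >= 2
transitive_reduction <- function(g) {
  A <- as.matrix(igraph::as_adjacency_matrix(g)) > 0
  if (!any(A)) return(g)
  R <- A
  repeat {
    R2 <- R | (R %*% R > 0)
    if (identical(R2, R)) break
    R <- R2
  }
  implied <- (A %*% R) > 0      # length >= 2 paths
  keep <- A & !implied
  igraph::graph_from_adjacency_matrix(keep * 1, mode = "directed")
}

#' Hierarchy levels of an order DAG
#'
#' The level of a node is the longest shortest path (in edges) from any root
#' (in-degree-0 node) that reaches it; roots themselves, including isolated
#' nodes, have level 0.
#'
#' @param dag an `order_dag` (or an igraph DAG).
#' @return Named integer vector of levels.
#' @export
assign_levels <- function(dag) {
  g <- if (inherits(dag, "order_dag")) dag$graph else dag
  roots <- igraph::V(g)[igraph::degree(g, mode = "in") == 0]
  if (length(roots) == 0) {
    return(stats::setNames(integer(0), character(0)))
  }
  d <- igraph::distances(g, v = roots, mode = "out")
  lev <- apply(d, 2, function(col) {
    col <- col[is.finite(col)]
    if (length(col) == 0) 0L else as.integer(max(col))
  })
  stats::setNames(as.integer(lev), igraph::V(g)$name)
}

#' @export
print.order_dag <- function(x, ...) {
  cat("<order_dag> ", nrow(x$nodes), " node(s), ",
      igraph::ecount(x$graph), " edge(s), ",
      max(x$nodes$level) + 1, " level(s)",
      if (!is.na(x$condition %||% NA)) paste0(" [", x$condition, "]"),
      "\n", sep = "")
  invisible(x)
}

#' Level histogram of an order DAG
#'
#' @param dag an `order_dag`.
#' @return Tibble with `level`, `n_nodes`, `n_reactions` (levels reported
#'   0-based; add one for 1-based labelling).
#' @export
level_histogram <- function(dag) {
  dag$nodes |>
    dplyr::mutate(n_rxn = lengths(.data$members)) |>
    dplyr::group_by(.data$level) |>
    dplyr::summarise(n_nodes = dplyr::n(),
                     n_reactions = sum(.data$n_rxn), .groups = "drop") |>
    dplyr::arrange(.data$level)
}

#' Partition DAG levels into first / middle / last subsets
#'
#' Default partition: first = level 0 nodes, middle = level 1, last = all
#' remaining levels (chosen so each subset holds a comparable number of
#' reactions, since the lowest levels dominate the node count).
#'
#' @param dag an `order_dag`.
#' @param first_levels,middle_levels level indices of the first and middle
#'   subsets; everything else is "last".
#' @return A `level_partition`: list of node-label vectors `first`,
#'   `middle`, `last` (disjoint, covering).
#' @export
level_partition <- function(dag, first_levels = 0, middle_levels = 1) {
  lev <- dag$nodes$level
  structure(list(
    first = dag$nodes$node[lev %in% first_levels],
    middle = dag$nodes$node[lev %in% middle_levels],
    last = dag$nodes$node[!lev %in% c(first_levels, middle_levels)]),
    class = "level_partition")
}

#' Compare ordered-pair sets across conditions
#'
#' @param sets named list of `ordered_pair_set` objects (>= 2 conditions).
#' @return List with `n_shared` (pairs ordered in every condition),
#'   `per_condition` (tibble: condition, n_pairs, n_exclusive,
#'   frac_exclusive) and `pairwise` (tibble with Jaccard distances
#'   `1 - |A n B| / |A u B|`).
#' @export
condition_overlap <- function(sets) {
  stopifnot(length(sets) >= 2)
  labels <- names(sets) %||% paste0("condition_", seq_along(sets))
  keys <- lapply(sets, function(s) {
    s <- s[s$relation == "ordered", , drop = FALSE]
    unique(paste(s$from, s$to))
  })
  shared <- Reduce(intersect, keys)
  per <- tibble::tibble(
    condition = labels,
    n_pairs = lengths(keys),
    n_exclusive = vapply(seq_along(keys), function(k) {
      length(setdiff(keys[[k]], unique(unlist(keys[-k]))))
    }, integer(1)))
  per$frac_exclusive <- ifelse(per$n_pairs > 0,
                               per$n_exclusive / per$n_pairs, NaN)
  combos <- utils::combn(seq_along(keys), 2)
  pairwise <- tibble::tibble(
    a = labels[combos[1, ]],
    b = labels[combos[2, ]],
    jaccard_distance = apply(combos, 2, function(ab) {
      u <- union(keys[[ab[1]]], keys[[ab[2]]])
      if (length(u) == 0) return(0)
      1 - length(intersect(keys[[ab[1]]], keys[[ab[2]]])) / length(u)
    }))
  list(n_shared = length(shared), per_condition = per, pairwise = pairwise)
}

#' Ancestors of the biomass reaction in the order DAG
#'
#' Induced subgraph on all DAG ancestors of the node containing the biomass
#' reaction: the reactions carrying at least the biomass flux in every steady
#' state. The ATP maintenance reaction is excluded by default when the
#' ancestor relation is an artifact of its forced minimum flux.
#'
#' @param dag an `order_dag`.
#' @param biomass_id biomass reaction id.
#' @param exclude reaction ids removed from the subgraph (e.g. ATPM).
#' @return An `order_dag` restricted to the ancestors (levels recomputed
#'   within the subgraph); its `biomass_node` field names the collapsed node
#'   that contains the biomass reaction.
#' @export
biomass_ancestor_subgraph <- function(dag, biomass_id, exclude = character()) {
  hit <- vapply(dag$nodes$members, function(m) biomass_id %in% m, logical(1))
  if (!any(hit)) {
    stop("biomass reaction '", biomass_id, "' is not in the DAG",
         call. = FALSE)
  }
  bnode <- dag$nodes$node[hit]
  anc <- setdiff(
    names(igraph::subcomponent(dag$graph, bnode, mode = "in")), bnode)
  nodes <- dag$nodes[dag$nodes$node %in% anc, , drop = FALSE]
  nodes$members <- lapply(nodes$members, setdiff, y = exclude)
  nodes <- nodes[lengths(nodes$members) > 0, , drop = FALSE]
  g <- igraph::induced_subgraph(dag$graph, nodes$node)
  sub <- structure(list(graph = g, nodes = nodes,
                        condition = dag$condition, biomass_node = bnode),
                   class = "order_dag")
  lev <- assign_levels(sub)
  sub$nodes$level <- if (nrow(nodes)) unname(lev[nodes$node]) else integer(0)
  sub
}

#' Essential reactions by single-knockout FBA
#'
#' A reaction is essential when forcing its flux to zero drops the maximum
#' biomass flux below `growth_tol` (or makes the model infeasible). Any
#' biomass lower bound installed by [apply_medium()] is relaxed during the
#' knockouts, so essentiality reflects the ability to grow at all rather
#' than to grow near-optimally.
#'
#' @param model a canonical `metabolic_model` with a biomass reaction.
#' @param growth_tol absolute growth threshold; defaults to `1e-6` times the
#'   wild-type optimum.
#' @return Character vector of essential reaction ids.
#' @export
find_essential_reactions <- function(model, growth_tol = NULL) {
  if (is.na(model$biomass_id)) {
    stop("model has no biomass_id", call. = FALSE)
  }
  bidx <- rxn_index(model, model$biomass_id)
  model$reactions$lb[bidx] <- 0
  wt <- solve_fba(model, model$biomass_id, "max")$optimum
  growth_tol <- growth_tol %||% (1e-6 * wt)
  obj <- numeric(n_reactions(model))
  obj[bidx] <- 1
  essential <- vapply(model$reactions$id, function(r) {
    res <- lp_over_polytope(model, obj, maximize = TRUE,
                            extra_fixed = stats::setNames(0, r))
    res$status == "infeasible" ||
      (res$status == "optimal" && res$value < growth_tol)
  }, logical(1))
  model$reactions$id[essential]
}

#' Essentiality versus the biomass-ancestor subgraph
#'
#' Every reaction flux-ordered above the biomass reaction must be essential
#' (its inactivity would impose a zero upper bound on biomass); the report
#' counts the overlap and flags any violation of that implication as a
#' defect.
#'
#' @param essential character vector from [find_essential_reactions()].
#' @param ancestors `order_dag` from [biomass_ancestor_subgraph()].
#' @return List with `n_ordered_and_essential`, `n_essential_not_ordered`,
#'   `ancestor_reactions`, and `violations` (ancestors that are not
#'   essential; empty in a correct analysis).
#' @export
essentiality_order_report <- function(essential, ancestors) {
  anc <- unique(unlist(ancestors$nodes$members))
  violations <- setdiff(anc, essential)
  if (length(violations)) {
    warning("biomass ancestors not essential (defect): ",
            paste(violations, collapse = ", "), call. = FALSE)
  }
  list(
    n_ordered_and_essential = length(intersect(anc, essential)),
    n_essential_not_ordered = length(setdiff(essential, anc)),
    ancestor_reactions = anc,
    violations = violations)
}

#' Export an order DAG to GraphML or DOT
#'
#' Nodes carry `level`, `members` (comma-separated) and `n_reactions`
#' attributes; `level1` carries the 1-based level labelling.
#'
#' @param dag an `order_dag`.
#' @param path output file.
#' @param format `"graphml"` or `"dot"`.
#' @return `path`, invisibly.
#' @export
export_dag <- function(dag, path, format = c("graphml", "dot")) {
  format <- match.arg(format)
  g <- dag$graph
  ord <- match(igraph::V(g)$name, dag$nodes$node)
  igraph::V(g)$level <- dag$nodes$level[ord]
  igraph::V(g)$level1 <- dag$nodes$level[ord] + 1L
  igraph::V(g)$members <- vapply(dag$nodes$members[ord], paste,
                                 character(1), collapse = ",")
  igraph::V(g)$n_reactions <- lengths(dag$nodes$members[ord])
  igraph::write_graph(g, path, format = format)
  invisible(path)
}
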