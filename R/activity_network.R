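# Phase 1-2: heterogeneous taxonomy-activity(-compound) networks and hub
# ranking.  Networks are undirected igraph objects with vertex attributes
# `name` (unique id) and `node_type` in {family, genus, species, activity,
# compound, target, gene}, and an edge attribute `relation`.

species_node <- function(genus, species) paste(genus, species)

hetero_graph <- function(nodes, edges) {
  # nodes: data.frame(name, node_type); edges: data.frame(from, to, relation)
  nodes <- nodes[!duplicated(nodes$name), ]
  edges <- edges[edges$from != edges$to, , drop = FALSE]
  key <- ifelse(edges$from < edges$to, paste(edges$from, edges$to),
                paste(edges$to, edges$from))
  edges <- edges[!duplicated(key), , drop = FALSE]
  igraph::graph_from_data_frame(edges, directed = FALSE, vertices = nodes)
}

#' Build the taxonomy-activity network
#'
#' One node per family, genus, species and activity class (activity nodes
#' are shared network-wide), optionally per compound.  Edges: family-genus,
#' genus-species, species-activity (one per evidenced class) and
#' species-compound when `include_compounds`.
#'
#' @param plants Plant tibble (see [read_plant_table()]).
#' @param include_compounds Add compound nodes and containment edges.
#' @return Undirected igraph with `node_type` vertex attribute.
#' @export
build_taxonomy_activity_network <- function(plants, include_compounds = FALSE) {
  sp <- species_node(plants$genus, plants$species)
  nodes <- rbind(
    data.frame(name = unique(plants$family), node_type = "family"),
    data.frame(name = unique(plants$genus), node_type = "genus"),
    data.frame(name = unique(sp), node_type = "species")
  )
  edges <- rbind(
    data.frame(from = plants$family, to = plants$genus, relation = "taxonomy"),
    data.frame(from = plants$genus, to = sp, relation = "taxonomy")
  )
  acts <- unique(unlist(plants$activities))
  if (length(acts) > 0) {
    nodes <- rbind(nodes, data.frame(name = acts, node_type = "activity"))
    has <- lengths(plants$activities) > 0
    edges <- rbind(edges, data.frame(
      from = rep(sp[has], lengths(plants$activities[has])),
      to = unlist(plants$activities[has]),
      relation = "activity"
    ))
  }
  if (include_compounds) {
    cmp <- unique(unlist(plants$compound_ids))
    if (length(cmp) > 0) {
      nodes <- rbind(nodes, data.frame(name = cmp, node_type = "compound"))
      hasc <- lengths(plants$compound_ids) > 0
      edges <- rbind(edges, data.frame(
        from = rep(sp[hasc], lengths(plants$compound_ids[hasc])),
        to = unlist(plants$compound_ids[hasc]),
        relation = "contains"
      ))
    }
  }
  hetero_graph(nodes, edges)
}

#' Maximal-clique-count (MCC) hub scores
#'
#' `mcc(v)` is the sum over maximal cliques containing `v` of
#' `(|C| - 1)!`; on triangle-free graphs every maximal clique is an edge and
#' MCC reduces to degree.
#'
#' @param graph igraph object.
#' @return Named numeric vector of scores.
#' @export
mcc_scores <- function(graph) {
  scores <- stats::setNames(numeric(igraph::vcount(graph)),
                            igraph::V(graph)$name)
  for (cl in igraph::max_cliques(graph)) {
    scores[cl$name] <- scores[cl$name] + factorial(length(cl) - 1)
  }
  scores
}

#' Rank hub nodes
#'
#' Orders nodes by a connectivity score, descending, ties broken
#' lexicographically by node id.
#'
#' @param network igraph object.
#' @param metric `"degree"` (default) or `"mcc"`.
#' @param top_k Number of nodes returned; `Inf` for all.
#' @param node_types Optional filter on the `node_type` attribute.
#' @return Tibble with `node`, `node_type`, `metric`, `value`.
#' @export
rank_hubs <- function(network, metric = c("degree", "mcc"), top_k = 10,
                      node_types = NULL) {
  metric <- match.arg(metric)
  if (top_k <= 0) stop("top_k must be positive")
  if (igraph::vcount(network) == 0) stop("network is empty")
  value <- switch(metric,
    degree = igraph::degree(network),
    mcc = mcc_scores(network)
  )
  tab <- tibble::tibble(
    node = igraph::V(network)$name,
    node_type = igraph::V(network)$node_type %||%
      rep(NA_character_, igraph::vcount(network)),
    metric = metric,
    value = as.numeric(value)
  )
  if (!is.null(node_types)) tab <- tab[tab$node_type %in% node_types, ]
  tab <- tab[order(-tab$value, tab$node), ]
  utils::head(tab, top_k)
}

#' Plants with multi-class activity evidence
#'
#' @param plants Plant tibble.
#' @param min_classes Minimum number of evidenced activity classes (1..4).
#' @return Plant tibble rows with `n_classes`, sorted by descending class
#'   count then species name.
#' @export
multi_effect_plants <- function(plants, min_classes) {
  stopifnot(min_classes >= 1, min_classes <= length(ACTIVITY_CLASSES))
  n_classes <- lengths(plants$activities)
  keep <- plants[n_classes >= min_classes, ]
  keep$n_classes <- n_classes[n_classes >= min_classes]
  keep[order(-keep$n_classes, species_node(keep$genus, keep$species)), ]
}

#' Rank evidence-gap plants
#'
#' Plants without any evidenced activity, scored by the connectivity of
#' their species node in the plant-compound-activity subnetwork restricted
#' to compounds with reported activities (the plants most likely to carry
#' unrecognised multi-effect potential).
#'
#' @param plants Plant tibble.
#' @param compounds Compound tibble with `known_activities` populated.
#' @param metric Hub metric, `"degree"` or `"mcc"`.
#' @return Tibble of evidence-free plants with `score`, descending (ties by
#'   species name).
#' @export
evidence_gap_ranking <- function(plants, compounds,
                                 metric = c("degree", "mcc")) {
  metric <- match.arg(metric)
  active <- compounds[lengths(compounds$known_activities) > 0, ]
  sp <- species_node(plants$genus, plants$species)
  nodes <- data.frame(name = unique(sp), node_type = "species")
  edges <- data.frame(from = character(0), to = character(0),
                      relation = character(0))
  if (nrow(active) > 0) {
    nodes <- rbind(nodes, data.frame(name = active$compound_id,
                                     node_type = "compound"))
    link <- lapply(seq_len(nrow(plants)), function(i) {
      hit <- intersect(plants$compound_ids[[i]], active$compound_id)
      if (length(hit) == 0) return(NULL)
      data.frame(from = sp[i], to = hit, relation = "contains")
    })
    edges <- rbind(edges, do.call(rbind, link))
    acts <- unique(unlist(active$known_activities))
    if (length(acts) > 0) {
      nodes <- rbind(nodes, data.frame(name = acts, node_type = "activity"))
      edges <- rbind(edges, data.frame(
        from = rep(active$compound_id, lengths(active$known_activities)),
        to = unlist(active$known_activities),
        relation = "activity"
      ))
    }
  }
  g <- hetero_graph(nodes, edges)
  score <- switch(metric, degree = igraph::degree(g), mcc = mcc_scores(g))
  gap <- plants[!plants$has_evidence, ]
  gap$score <- as.numeric(score[species_node(gap$genus, gap$species)])
  gap[order(-gap$score, species_node(gap$genus, gap$species)), ]
}
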