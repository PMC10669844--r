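# Phase 6: the four-criterion candidate cascade and the
# compound-target-pathway structural network.

#' Four-criterion candidate cascade
#'
#' Keeps, in the printed order: (1) drug-like compounds (`qed >` threshold),
#' (2) compounds structurally similar to the reference panel
#' (`reference_similar` flag, see [reference_cluster_members()]), (3)
#' compounds with bioassay-reported target genes, (4) compounds lacking any
#' reported activity in the four classes (the screen hunts unrecognised
#' potential).  The gates are pure filters, so membership is
#' order-independent; the per-stage counts follow this order.
#'
#' @param compounds Compound tibble carrying `qed`, logical
#'   `reference_similar`, `targets` and `known_activities`.
#' @param qed_threshold Strict QED cut-off (default 0.5).
#' @return List with `survivors` (tibble) and `stages` (tibble: `stage`,
#'   `criterion`, `n_in`, `n_out`, `n_excluded`).
#' @export
candidate_cascade <- function(compounds, qed_threshold = 0.5) {
  needed <- c("qed", "reference_similar", "targets", "known_activities")
  missing <- setdiff(needed, names(compounds))
  if (length(missing) > 0) {
    stop("compounds lack cascade column(s): ", paste(missing, collapse = ", "))
  }
  criteria <- list(
    drug_like = function(x) x$qed > qed_threshold,
    reference_similar = function(x) x$reference_similar,
    has_targets = function(x) lengths(x$targets) > 0,
    no_known_activity = function(x) lengths(x$known_activities) == 0
  )
  cur <- compounds
  stages <- vector("list", length(criteria))
  for (i in seq_along(criteria)) {
    n_in <- nrow(cur)
    keep <- if (n_in > 0) criteria[[i]](cur) else logical(0)
    cur <- cur[keep, ]
    stages[[i]] <- tibble::tibble(
      stage = i, criterion = names(criteria)[i],
      n_in = n_in, n_out = nrow(cur), n_excluded = n_in - nrow(cur)
    )
  }
  list(survivors = cur, stages = dplyr::bind_rows(stages))
}

#' Build the compound-target-pathway structural network
#'
#' Nodes: plant species containing at least one of the given compounds, the
#' compounds, their target genes, and pathway genes.  Edges: plant-compound
#' (containment), compound-target (bioassay), and target-gene when the
#' target and the gene are members of the same pathway set (identity match
#' on gene symbol).
#'
#' @param plants Plant tibble.
#' @param compounds Compound tibble (typically cascade survivors).
#' @param pathways `pathway_db` gene sets.
#' @param gene_layer `"connected"` (default) includes only pathway genes
#'   sharing a set with some target; `"all"` includes every gene of every
#'   loaded pathway as a node.
#' @return Undirected igraph with `node_type` in
#'   {species, compound, target, gene} and edge attribute `relation`.
#' @export
build_structural_network <- function(plants, compounds, pathways,
                                     gene_layer = c("connected", "all")) {
  gene_layer <- match.arg(gene_layer)
  targets <- unique(unlist(compounds$targets))
  path_genes <- unique(unlist(pathways))
  sp <- species_node(plants$genus, plants$species)

  pc <- lapply(seq_len(nrow(plants)), function(i) {
    hit <- intersect(plants$compound_ids[[i]], compounds$compound_id)
    if (length(hit) == 0) return(NULL)
    data.frame(from = sp[i], to = hit, relation = "contains")
  })
  pc <- do.call(rbind, pc)
  ct <- if (length(targets) > 0) {
    data.frame(from = rep(compounds$compound_id, lengths(compounds$targets)),
               to = unlist(compounds$targets), relation = "targets")
  } else NULL
  tg <- NULL
  for (set in pathways) {
    t_in <- intersect(targets, set)
    if (length(t_in) > 0) {
      partners <- setdiff(set, character(0))
      pairs <- expand.grid(from = t_in, to = partners,
                           stringsAsFactors = FALSE)
      pairs <- pairs[pairs$from != pairs$to, ]
      if (nrow(pairs) > 0) {
        pairs$relation <- "pathway_comember"
        tg <- rbind(tg, pairs)
      }
    }
  }
  edges <- rbind(pc, ct, tg)
  if (is.null(edges)) edges <- data.frame(from = character(0),
                                          to = character(0),
                                          relation = character(0))
  gene_nodes <- if (gene_layer == "all") path_genes else {
    unique(c(tg$from, tg$to))
  }
  gene_nodes <- setdiff(gene_nodes, targets)
  node_df <- function(names, type) {
    data.frame(name = names, node_type = rep(type, length(names)))
  }
  nodes <- rbind(
    node_df(unique(if (!is.null(pc)) pc$from else character(0)), "species"),
    node_df(compounds$compound_id, "compound"),
    node_df(targets, "target"),
    node_df(gene_nodes, "gene")
  )
  hetero_graph(nodes, edges)
}

#' Rank candidate plants in the structural network
#'
#' Eligible plants lack activity evidence of their own and contain at least
#' one of the given compounds whose targets reach the pathway-gene layer;
#' they are ranked by the hub score of their species node.  (The screen
#' proposes plants whose potential is unrecognised, so evidenced plants are
#' never candidates.)  Also returns the Cytohubba-style induced subnetwork of the
#' `top_k` highest-scoring nodes of any type.
#'
#' @param network Structural network from [build_structural_network()].
#' @param plants Plant tibble.
#' @param compounds Compound tibble used to build the network.
#' @param pathways `pathway_db` used to build the network.
#' @param top_k Subnetwork size (default 10).
#' @param metric Hub metric, `"degree"` or `"mcc"`.
#' @return List with `plants` (ranked tibble with `score`) and `subnetwork`
#'   (igraph of the `top_k` hub nodes).
#' @export
candidate_plants <- function(network, plants, compounds, pathways,
                             top_k = 10, metric = c("degree", "mcc")) {
  metric <- match.arg(metric)
  path_genes <- unique(unlist(pathways))
  reaches <- vapply(seq_len(nrow(compounds)), function(i) {
    length(intersect(compounds$targets[[i]], path_genes)) > 0
  }, logical(1))
  good <- compounds$compound_id[reaches]
  eligible <- !plants$has_evidence & vapply(plants$compound_ids, function(ids) {
    length(intersect(ids, good)) > 0
  }, logical(1))
  cand <- plants[eligible, ]
  score <- switch(metric, degree = igraph::degree(network),
                  mcc = mcc_scores(network))
  sp <- species_node(cand$genus, cand$species)
  cand$score <- as.numeric(score[sp])
  cand$score[is.na(cand$score)] <- 0
  cand <- cand[order(-cand$score, species_node(cand$genus, cand$species)), ]
  hubs <- rank_hubs(network, metric, top_k)
  sub <- igraph::induced_subgraph(network,
                                  igraph::V(network)$name %in% hubs$node)
  list(plants = cand, subnetwork = sub)
}

#' Candidate-plant report table
#'
#' Per candidate plant: taxonomy, the number of its surviving compounds with
#' reported targets, and the number of those targets that interact with the
#' network's pathway-gene layer.
#'
#' @param candidates Ranked candidate tibble from [candidate_plants()].
#' @param compounds Compound tibble used to build the network.
#' @param pathways `pathway_db` used to build the network.
#' @return Tibble: `family`, `genus`, `species`, `n_compounds_with_targets`,
#'   `n_interacting_targets`.  Plants with no surviving compound are absent.
#' @export
candidate_report <- function(candidates, compounds, pathways) {
  path_genes <- unique(unlist(pathways))
  rows <- lapply(seq_len(nrow(candidates)), function(i) {
    ids <- intersect(candidates$compound_ids[[i]], compounds$compound_id)
    sub <- compounds[compounds$compound_id %in% ids, ]
    with_t <- lengths(sub$targets) > 0
    if (!any(with_t)) return(NULL)
    interacting <- intersect(unique(unlist(sub$targets)), path_genes)
    tibble::tibble(
      family = candidates$family[i], genus = candidates$genus[i],
      species = candidates$species[i],
      n_compounds_with_targets = sum(with_t),
      n_interacting_targets = length(interacting)
    )
  })
  dplyr::bind_rows(rows)
}
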