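# Phase 6b: pathway enrichment of candidate target genes.  Two routes:
# hypergeometric over-representation, and a topology-aware XD-score based on
# random-walk-with-restart proximity.

#' Hypergeometric over-representation test
#'
#' For each pathway, the upper-tail probability `P(X >= k)` of observing `k`
#' query genes in the pathway under hypergeometric sampling of `n` query
#' genes from a universe of `N` background genes containing `K` pathway
#' genes.  Benjamini-Hochberg adjusted q-values are reported beside the raw
#' p-values; selection in the screen follows raw `p < 0.05`.
#'
#' @param query Character vector of query gene symbols (subset of
#'   `background`).
#' @param pathway_db `pathway_db` from [read_gmt()] (or named list of sets).
#' @param background Character vector: the gene universe of the network.
#' @return Tibble sorted by raw p (ties: pathway id): `pathway_id`, `name`,
#'   `k`, `K`, `n`, `N`, `p`, `q`.  Pathways with no gene in the background
#'   are skipped with a warning.
#' @export
hypergeom_enrich <- function(query, pathway_db, background) {
  background <- unique(toupper(background))
  query <- unique(toupper(query))
  if (length(query) == 0) stop("query gene set is empty")
  out <- setdiff(query, background)
  if (length(out) > 0) {
    stop("query gene(s) not in background: ", paste(out, collapse = ", "))
  }
  nm <- attr(pathway_db, "pathway_names")
  if (is.null(nm)) nm <- stats::setNames(names(pathway_db), names(pathway_db))
  N <- length(background)
  n <- length(query)
  rows <- lapply(names(pathway_db), function(id) {
    Kset <- intersect(unique(toupper(pathway_db[[id]])), background)
    if (length(Kset) == 0) {
      warning("pathway ", id, " has no gene in the background; skipped")
      return(NULL)
    }
    k <- length(intersect(query, Kset))
    K <- length(Kset)
    p <- stats::phyper(k - 1, K, N - K, n, lower.tail = FALSE)
    tibble::tibble(pathway_id = id, name = unname(nm[id]), k = k, K = K,
                   n = n, N = N, p = p)
  })
  tab <- dplyr::bind_rows(rows)
  if (nrow(tab) == 0) return(tab)
  tab$q <- stats::p.adjust(tab$p, method = "BH")
  tab[order(tab$p, tab$pathway_id), ]
}

#' Random walk with restart
#'
#' Iterates the mass-conserving propagation
#' `p <- r * e_S + (1 - r) * M p`, where `M` is the degree-normalised
#' (column-stochastic) adjacency of the undirected network and `e_S` is
#' uniform on the seed set, until the L1 change falls below `tol`.  The
#' fixed point solves `(I - (1 - r) M) p = r e_S`.
#'
#' @param network igraph object (undirected).
#' @param seeds Character vector of seed node names (must intersect the
#'   network).
#' @param r Restart probability in (0, 1), default 0.7.
#' @param tol L1 convergence tolerance.
#' @param max_iter Iteration cap.
#' @return List with `p` (named steady-state probabilities, summing to 1),
#'   `r`, `seeds`, `iterations`.
#' @export
rwr <- function(network, seeds, r = 0.7, tol = 1e-10, max_iter = 1e5) {
  stopifnot(r > 0, r < 1)
  nodes <- igraph::V(network)$name
  seeds <- intersect(seeds, nodes)
  if (length(seeds) == 0) stop("seed set is disjoint from the network")
  A <- igraph::as_adjacency_matrix(network, sparse = FALSE)
  deg <- colSums(A)
  e <- stats::setNames(numeric(length(nodes)), nodes)
  e[seeds] <- 1 / length(seeds)
  # dangling nodes restart immediately: their column of M is e_S
  p <- e
  scaled <- numeric(length(p))
  for (it in seq_len(max_iter)) {
    scaled[] <- 0
    scaled[deg > 0] <- p[deg > 0] / deg[deg > 0]
    spread <- as.numeric(A %*% scaled)
    dangling <- sum(p[deg == 0])
    p_new <- r * e + (1 - r) * (spread + dangling * e)
    if (sum(abs(p_new - p)) < tol) {
      p <- p_new
      break
    }
    p <- p_new
  }
  names(p) <- nodes
  list(p = p, r = r, seeds = seeds, iterations = it)
}

#' XD-score of a pathway
#'
#' Mean random-walk proximity of the pathway's in-network genes minus the
#' network-wide mean proximity; positive values mean the pathway sits closer
#' to the query than an average node.
#'
#' @param rwr_state Result of [rwr()].
#' @param pathway_genes Character vector of gene symbols.
#' @return Scalar XD-score.
#' @export
xd_score <- function(rwr_state, pathway_genes) {
  p <- rwr_state$p
  inside <- intersect(names(p), unique(pathway_genes))
  if (length(inside) == 0) {
    stop("pathway has no gene in the network; XD-score undefined")
  }
  mean(p[inside]) - mean(p)
}

#' Enrichment with XD revision
#'
#' Runs the hypergeometric test, then revises each tested pathway with the
#' XD-score of its genes under a random walk restarted at the query set on
#' the given network.  Ranking: raw p, then -XD, then pathway id.
#'
#' @inheritParams hypergeom_enrich
#' @param network igraph whose gene nodes carry the walk (background is its
#'   intersection with `background`).
#' @param r Restart probability.
#' @param alpha Significance gate on raw p (reported as `significant`).
#' @return [hypergeom_enrich()] tibble with `xd` and `significant` columns.
#' @export
enrich_with_xd <- function(query, pathway_db, background, network, r = 0.7,
                           alpha = 0.05) {
  tab <- hypergeom_enrich(query, pathway_db, background)
  if (nrow(tab) == 0) return(tab)
  state <- rwr(network, query, r = r)
  tab$xd <- vapply(tab$pathway_id, function(id) {
    genes <- intersect(unique(toupper(pathway_db[[id]])), names(state$p))
    if (length(genes) == 0) NA_real_ else xd_score(state, genes)
  }, numeric(1))
  tab$significant <- tab$p < alpha
  tab[order(tab$p, -tab$xd, tab$pathway_id), ]
}
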