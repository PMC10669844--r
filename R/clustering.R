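# Clustering of compounds on 1 - Tanimoto distances: Ward tree with a WSS
# profile for the elbow rule, k-means corroboration, and silhouette/Dunn
# validity.  The distance-induced within-cluster dispersion
#   WSS(labels) = sum over clusters of sum of pairwise d^2 / (2 n_c)
# coincides with the usual sum of squared deviations from centroids when d
# is Euclidean.

#' Within-cluster dispersion from a distance matrix
#'
#' @param distances Symmetric distance matrix (or `dist`).
#' @param labels Integer cluster labels aligned with the matrix rows.
#' @return Scalar WSS.
#' @export
wss_from_distances <- function(distances, labels) {
  d <- as.matrix(distances)
  stopifnot(nrow(d) == length(labels))
  total <- 0
  for (cl in unique(labels)) {
    idx <- which(labels == cl)
    if (length(idx) > 1) {
      sub <- d[idx, idx, drop = FALSE]
      total <- total + sum(sub^2) / (2 * length(idx))
    }
  }
  total
}

#' Ward clustering with a WSS profile
#'
#' Agglomerative Ward linkage in the Ward.D2 convention (squared distances
#' in the Lance-Williams update) via [stats::hclust()], plus the
#' within-cluster dispersion of every cut `K' = 1..K_max` for the elbow
#' rule.
#'
#' @param distances Symmetric distance matrix or `dist` object.
#' @param K_max Largest cut evaluated; must be `< n`.
#' @return Object of class `ward_solution`: list with `tree` (hclust),
#'   `wss_profile` (numeric, named `1..K_max`) and `n`.
#' @export
ward_cluster <- function(distances, K_max) {
  d <- stats::as.dist(distances)
  n <- attr(d, "Size")
  if (K_max >= n) stop("K_max must be smaller than the number of items")
  if (K_max < 1) stop("K_max must be at least 1")
  tree <- stats::hclust(d, method = "ward.D2")
  dm <- as.matrix(d)
  cuts <- stats::cutree(tree, k = seq_len(K_max))
  wss <- vapply(seq_len(K_max), function(k) {
    wss_from_distances(dm, cuts[, k])
  }, numeric(1))
  names(wss) <- seq_len(K_max)
  structure(list(tree = tree, wss_profile = wss, n = n),
            class = "ward_solution")
}

#' Cut a Ward tree into K clusters
#' @param solution `ward_solution` from [ward_cluster()].
#' @param K Number of clusters.
#' @return Integer labels `1..K` (named by item when the input was named).
#' @export
ward_cut <- function(solution, K) {
  stats::cutree(solution$tree, k = K)
}

#' Elbow rule for the number of clusters
#'
#' Selects the interior `K` maximising the discrete second difference
#' `WSS(K-1) - 2 WSS(K) + WSS(K+1)` of the dispersion profile (the sharpest
#' bend).  Ties break to the smallest `K`; a flat (all-equal) profile gives
#' `K = 1`.
#'
#' @param wss_profile Numeric WSS values for `K' = 1..K_max`
#'   (`K_max >= 3`).
#' @return Selected integer `K`.
#' @export
elbow_select <- function(wss_profile) {
  w <- as.numeric(wss_profile)
  if (length(w) < 3) stop("WSS profile must cover at least K' = 1..3")
  if (all(w == w[1])) return(1L)
  interior <- 2:(length(w) - 1)
  curvature <- w[interior - 1] - 2 * w[interior] + w[interior + 1]
  interior[which.max(curvature)]
}

#' k-means on binary fingerprint coordinates
#'
#' Lloyd iterations (via [stats::kmeans()]) on the raw 0/1 bit matrix, where
#' squared Euclidean distance equals Hamming distance.  Centers are seeded
#' with k-means++ over the distinct rows; the best of `n_init` restarts by
#' total within-cluster sum of squares is returned.  Fully reproducible
#' given `seed` and leaves the global RNG untouched.
#'
#' @param fingerprints List of fingerprints or a numeric matrix (rows =
#'   items).
#' @param K Number of clusters, `1 <= K <= n` distinct rows.
#' @param seed Integer seed.
#' @param n_init Number of k-means++ restarts.
#' @return List with `labels` (integer, named by item), `K`, `wss` (total
#'   within-cluster sum of squares), `centers` and `method = "kmeans"`.
#' @export
kmeans_binary <- function(fingerprints, K, seed, n_init = 10) {
  x <- if (is.matrix(fingerprints)) fingerprints else fp_matrix(fingerprints)
  n <- nrow(x)
  if (K > n) stop("K must not exceed the number of items")
  if (K < 1) stop("K must be at least 1")
  uniq <- unique(x)
  if (K > nrow(uniq)) {
    stop("K exceeds the number of distinct points (", nrow(uniq), ")")
  }
  best <- NULL
  with_local_seed(seed, {
    for (rep in seq_len(n_init)) {
      centers <- kmeanspp_init(uniq, K)
      fit <- stats::kmeans(x, centers = centers, iter.max = 100,
                           algorithm = "Lloyd")
      if (is.null(best) || fit$tot.withinss < best$tot.withinss) best <- fit
    }
  })
  labels <- as.integer(best$cluster)
  names(labels) <- rownames(x)
  list(labels = labels, K = K, wss = best$tot.withinss,
       centers = best$centers, method = "kmeans")
}

# k-means++ seeding: first center uniform, then points with probability
# proportional to their squared distance to the nearest chosen center.
kmeanspp_init <- function(x, K) {
  n <- nrow(x)
  chosen <- integer(K)
  chosen[1] <- sample.int(n, 1)
  if (K > 1) {
    d2 <- rowSums(sweep(x, 2, x[chosen[1], ], `-`)^2)
    for (j in 2:K) {
      d2[chosen[seq_len(j - 1)]] <- 0
      prob <- if (sum(d2) > 0) d2 / sum(d2) else {
        p <- rep(1, n); p[chosen[seq_len(j - 1)]] <- 0; p / sum(p)
      }
      chosen[j] <- sample.int(n, 1, prob = prob)
      dj <- rowSums(sweep(x, 2, x[chosen[j], ], `-`)^2)
      d2 <- pmin(d2, dj)
    }
  }
  x[chosen, , drop = FALSE]
}

#' Silhouette widths
#'
#' Per-item silhouette `s(i) = (b(i) - a(i)) / max(a(i), b(i))` with `a(i)`
#' the mean intra-cluster distance (self excluded) and `b(i)` the smallest
#' mean distance to another cluster.  Members of singleton clusters take
#' `s(i) = 0` by convention.
#'
#' @param distances Symmetric distance matrix or `dist`.
#' @param labels Cluster labels (at least two clusters).
#' @return List with `widths` (tibble: `item`, `cluster`, `a`, `b`, `s`) and
#'   `mean_silhouette`.
#' @export
silhouette_index <- function(distances, labels) {
  d <- as.matrix(distances)
  n <- nrow(d)
  stopifnot(length(labels) == n)
  cls <- unique(labels)
  if (length(cls) < 2) stop("silhouette needs at least 2 clusters")
  a <- b <- s <- numeric(n)
  for (i in seq_len(n)) {
    own <- which(labels == labels[i])
    if (length(own) == 1) {
      a[i] <- 0; b[i] <- 0; s[i] <- 0
      next
    }
    others <- setdiff(own, i)
    a[i] <- sum(d[i, others]) / length(others)
    b[i] <- min(vapply(setdiff(cls, labels[i]), function(cl) {
      idx <- which(labels == cl)
      sum(d[i, idx]) / length(idx)
    }, numeric(1)))
    s[i] <- (b[i] - a[i]) / max(a[i], b[i])
  }
  items <- if (!is.null(rownames(d))) rownames(d) else as.character(seq_len(n))
  list(
    widths = tibble::tibble(item = items, cluster = labels, a = a, b = b,
                            s = s),
    mean_silhouette = mean(s)
  )
}

#' Dunn index
#'
#' Minimum between-cluster (single-link) distance divided by the maximum
#' within-cluster diameter.  When every cluster is a singleton the diameter
#' is zero and the index is `Inf`.
#'
#' @inheritParams silhouette_index
#' @return Scalar Dunn index (`>= 0`, possibly `Inf`).
#' @export
dunn_index <- function(distances, labels) {
  d <- as.matrix(distances)
  cls <- unique(labels)
  if (length(cls) < 2) stop("Dunn index needs at least 2 clusters")
  diam <- max(vapply(cls, function(cl) {
    idx <- which(labels == cl)
    if (length(idx) < 2) 0 else max(d[idx, idx])
  }, numeric(1)))
  inter <- min(vapply(seq_along(cls)[-1], function(j) {
    min(vapply(seq_len(j - 1), function(i) {
      min(d[labels == cls[j], labels == cls[i], drop = FALSE])
    }, numeric(1)))
  }, numeric(1)))
  if (diam == 0) return(Inf)
  inter / diam
}

#' Phytochemicals co-clustered with reference compounds
#'
#' Given a clustering of a joint set of phytochemicals and reference drugs,
#' returns the non-reference compounds sharing a cluster with at least one
#' reference (the candidates with structural similarity to the panel), plus
#' the per-reference membership lists.
#'
#' @param labels Cluster labels aligned with `compounds` rows.
#' @param compounds Compound tibble with `compound_id` and `is_reference`.
#' @return List with `selected` (tibble subset of `compounds`) and
#'   `per_reference` (named list: reference id -> co-clustered non-reference
#'   ids).  Warns and returns empty when no reference is present.
#' @export
reference_cluster_members <- function(labels, compounds) {
  stopifnot(length(labels) == nrow(compounds))
  refs <- which(compounds$is_reference)
  if (length(refs) == 0) {
    warning("no reference compounds in the clustered set")
    return(list(selected = compounds[0, ], per_reference = list()))
  }
  ref_clusters <- unique(labels[refs])
  sel <- !compounds$is_reference & labels %in% ref_clusters
  per_ref <- lapply(refs, function(r) {
    compounds$compound_id[!compounds$is_reference & labels == labels[r]]
  })
  names(per_ref) <- compounds$compound_id[refs]
  list(selected = compounds[sel, ], per_reference = per_ref)
}

#' Cluster a reference-drug descriptor panel
#'
#' Standardises the numeric descriptor columns (zero mean, unit variance;
#' constant columns are dropped with a warning), clusters the drugs on
#' Euclidean distances with a Ward tree, cross-checks with seeded k-means,
#' and reports the "top cluster" as the Ward cluster containing the most
#' anchor compounds.
#'
#' @param panel Data frame of reference drugs: an id column `compound_id`
#'   plus numeric descriptor columns.
#' @param K Number of clusters.
#' @param seed Integer seed for the k-means cross-check.
#' @param anchors Character vector of anchor `compound_id`s designating the
#'   cluster of interest (`NULL` = no top cluster reported).
#' @return List with `labels`, `kmeans_labels`, `top_cluster` (ids or
#'   `NULL`), `tree` and `heat_order` (dendrogram leaf order).
#' @export
descriptor_panel_cluster <- function(panel, K, seed = 1L, anchors = NULL) {
  stopifnot("compound_id" %in% names(panel))
  num <- panel[, vapply(panel, is.numeric, logical(1)), drop = FALSE]
  const <- vapply(num, function(x) stats::sd(x) == 0, logical(1))
  if (any(const)) {
    warning("dropping constant descriptor column(s): ",
            paste(names(num)[const], collapse = ", "))
    num <- num[, !const, drop = FALSE]
  }
  x <- scale(as.matrix(num))
  rownames(x) <- panel$compound_id
  d <- stats::dist(x)
  tree <- stats::hclust(d, method = "ward.D2")
  labels <- stats::cutree(tree, k = K)
  km <- kmeans_binary(x, K, seed = seed)
  top <- NULL
  if (!is.null(anchors)) {
    hit <- labels[names(labels) %in% anchors]
    if (length(hit) == 0) stop("no anchor compound found in the panel")
    top_label <- as.integer(names(which.max(table(hit))))
    top <- names(labels)[labels == top_label]
  }
  list(labels = labels, kmeans_labels = km$labels, top_cluster = top,
       tree = tree, heat_order = tree$order)
}
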