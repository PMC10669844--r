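test_that("tanimoto matches hand-counted cases and conventions", {
  f1 <- make_fp(c(1, 3, 5, 7), 16)
  f2 <- make_fp(c(3, 5, 8), 16)
  expect_equal(tanimoto(f1, f2), 2 / 5)  # a=4, b=3, c=2
  expect_equal(tanimoto(f1, f1), 1)
  expect_equal(tanimoto(f1, make_fp(c(2, 4), 16)), 0)
  zero <- fingerprint(integer(16))
  expect_equal(tanimoto(zero, zero), 1)
  expect_equal(tanimoto(zero, f1), 0)
  expect_error(tanimoto(f1, fingerprint(integer(8))), "mismatch")
})

test_that("similarity matrix equals the brute-force double loop exactly", {
  withr::with_seed(19, {
    fps <- lapply(1:40, function(i) fingerprint(as.integer(runif(256) < 0.12)))
    names(fps) <- paste0("c", 1:40)
    s <- similarity_matrix(fps)
    expect_identical(s, t(s))
    expect_true(all(diag(s) == 1))
    for (i in 1:40) for (j in 1:40) {
      expect_identical(s[i, j], oracle_tanimoto(as.integer(fps[[i]]),
                                                as.integer(fps[[j]])))
    }
    d <- tanimoto_distance(s)
    expect_true(all(diag(d) == 0))
    expect_equal(d, 1 - s, ignore_attr = TRUE, tolerance = 1e-15)
  })
})

blob_distances <- function() {
  # 6 points, 3 planted pairs: within-pair distance 0.05, between 0.9
  d <- matrix(0.9, 6, 6)
  diag(d) <- 0
  for (p in list(c(1, 2), c(3, 4), c(5, 6))) d[p[1], p[2]] <- d[p[2], p[1]] <- 0.05
  dimnames(d) <- list(letters[1:6], letters[1:6])
  d
}

test_that("Ward tree recovers planted blobs and its WSS profile is monotone", {
  d <- blob_distances()
  sol <- ward_cluster(d, K_max = 5)
  labels <- ward_cut(sol, 3)
  expect_equal(ari(labels, rep(1:3, each = 2)), 1)
  expect_true(all(diff(sol$wss_profile) <= 1e-12))
  expect_error(ward_cluster(d, 6), "K_max")

  # identical duplicated points: the 2-cut has exactly zero dispersion
  d0 <- matrix(1, 4, 4); d0[1, 2] <- d0[2, 1] <- 0; d0[3, 4] <- d0[4, 3] <- 0
  diag(d0) <- 0
  sol0 <- ward_cluster(d0, 3)
  expect_equal(unname(sol0$wss_profile["2"]), 0)

  withr::with_seed(23, {
    for (i in 1:5) {
      x <- matrix(runif(40), 10)
      dr <- as.matrix(dist(x))
      expect_true(all(diff(ward_cluster(dr, 8)$wss_profile) <= 1e-12))
    }
  })
})

test_that("the elbow rule picks the largest second difference", {
  expect_equal(elbow_select(c(100, 10, 9, 8)), 2)
  expect_equal(elbow_select(c(0, 0, 0, 0)), 1)
  expect_equal(elbow_select(c(5, 5, 5)), 1)
  expect_error(elbow_select(c(3, 1)), "at least")
  # tie between K=2 and K=3 resolves to the smaller K
  expect_equal(elbow_select(c(10, 6, 4, 3, 2.5)), 2)
})

test_that("k-means on bits is seeded, reproducible, and corroborates Ward", {
  withr::with_seed(29, {
    proto <- lapply(1:3, function(k) as.integer(runif(128) < 0.15))
    fps <- lapply(1:24, function(i) fingerprint(proto[[(i - 1) %% 3 + 1]]))
    names(fps) <- paste0("c", 1:24)
  })
  truth <- rep(1:3, 8)
  km1 <- kmeans_binary(fps, 3, seed = 99)
  km2 <- kmeans_binary(fps, 3, seed = 99)
  expect_identical(km1$labels, km2$labels)
  expect_equal(ari(km1$labels, truth), 1)
  expect_equal(km1$wss, 0)  # clean prototypes: zero dispersion at K=3

  ward <- ward_cut(ward_cluster(tanimoto_distance(fps), 5), 3)
  expect_equal(ari(km1$labels, ward), 1)

  expect_error(kmeans_binary(fps, 25, seed = 1), "exceed")
  # K = n needs n distinct points; with 3 distinct rows K=3 is the max
  expect_error(kmeans_binary(fps, 4, seed = 1), "distinct")

  distinct <- lapply(1:6, function(i) make_fp(i, 32))
  names(distinct) <- paste0("d", 1:6)
  expect_equal(kmeans_binary(distinct, 6, seed = 1)$wss, 0)
})

test_that("silhouette equals its brute-force definition on small fixtures", {
  d <- blob_distances()
  labels <- rep(1:3, each = 2)
  sil <- silhouette_index(d, labels)
  expect_equal(sil$widths$s, oracle_silhouette(d, labels), tolerance = 1e-15)
  # perfectly separated duplicate pairs: a = 0.05, b = 0.9
  expect_true(all(sil$widths$s > 0.9))

  dup <- matrix(1, 4, 4); diag(dup) <- 0
  dup[1, 2] <- dup[2, 1] <- 0; dup[3, 4] <- dup[4, 3] <- 0
  s2 <- silhouette_index(dup, c(1, 1, 2, 2))
  expect_equal(s2$widths$s, rep(1, 4))

  s3 <- silhouette_index(d, c(1, 1, 1, 1, 1, 2))
  expect_equal(s3$widths$s[6], 0)  # singleton convention

  expect_error(silhouette_index(d, rep(1, 6)), "2 clusters")

  withr::with_seed(37, {
    for (i in 1:10) {
      n <- sample(5:12, 1)
      x <- matrix(runif(2 * n), n)
      dm <- as.matrix(dist(x))
      lb <- random_labels(n, sample(2:4, 1))
      got <- silhouette_index(dm, lb)
      expect_equal(got$widths$s, oracle_silhouette(dm, lb), tolerance = 1e-12)
      if (requireNamespace("cluster", quietly = TRUE)) {
        ref <- cluster::silhouette(lb, dmatrix = dm)
        expect_equal(sort(got$widths$s), sort(ref[, "sil_width"]),
                     tolerance = 1e-12)
      }
    }
  })
})

test_that("Dunn index matches direct quotients and edge conventions", {
  d <- matrix(0.9, 4, 4); diag(d) <- 0
  d[1, 2] <- d[2, 1] <- 0.1; d[3, 4] <- d[4, 3] <- 0.1
  expect_equal(dunn_index(d, c(1, 1, 2, 2)), 9)

  dup <- matrix(1, 4, 4); diag(dup) <- 0
  dup[1, 3] <- dup[3, 1] <- 0  # duplicates split across clusters
  expect_equal(dunn_index(dup, c(1, 1, 2, 2)), 0)

  singletons <- as.matrix(dist(matrix(1:3, 3)))
  expect_equal(dunn_index(singletons, 1:3), Inf)
  expect_error(dunn_index(d, rep(1, 4)), "2 clusters")

  withr::with_seed(41, {
    for (i in 1:10) {
      n <- sample(6:12, 1)
      dm <- as.matrix(dist(matrix(runif(2 * n), n)))
      lb <- random_labels(n, 3)
      expect_equal(dunn_index(dm, lb), oracle_dunn(dm, lb),
                   tolerance = 1e-12)
    }
  })
})

test_that("reference-cluster selection returns exactly the co-clustered set", {
  d <- generate_dataset(synth_config(seed = 43, bitflip_prob = 0.02))
  comp <- d$compounds
  proto <- d$truth$prototype[comp$compound_id]
  labels <- ward_cut(
    ward_cluster(tanimoto_distance(
      stats::setNames(comp$fingerprint, comp$compound_id)), 5), 3)
  sel <- reference_cluster_members(labels, comp)
  # references all come from prototype 1: selection = prototype-1 phytochemicals
  expect_setequal(sel$selected$compound_id,
                  comp$compound_id[!comp$is_reference & proto == 1])
  expect_true(all(lengths(sel$per_reference) ==
                    nrow(sel$selected)))

  # references isolated in their own cluster select nothing
  iso <- tibble::tibble(
    compound_id = c("a", "b", "r"),
    is_reference = c(FALSE, FALSE, TRUE)
  )
  got <- reference_cluster_members(c(1, 1, 2), iso)
  expect_equal(nrow(got$selected), 0)
  expect_equal(got$per_reference$r, character(0))

  none <- iso; none$is_reference <- FALSE
  expect_warning(res <- reference_cluster_members(c(1, 1, 2), none),
                 "no reference")
  expect_equal(nrow(res$selected), 0)
})

test_that("descriptor-panel clustering recovers blobs and anchors the top cluster", {
  withr::with_seed(47, {
    centers <- matrix(c(0, 0, 8, 8, -8, 8), 3, byrow = TRUE)
    panel <- tibble::tibble(
      compound_id = paste0("drug", 1:18),
      d1 = rep(centers[, 1], each = 6) + rnorm(18, sd = 0.3),
      d2 = rep(centers[, 2], each = 6) + rnorm(18, sd = 0.3),
      flat = 1
    )
  })
  expect_warning(sol <- descriptor_panel_cluster(panel, 3, seed = 7,
                                                 anchors = c("drug1", "drug2")),
                 "constant")
  truth <- rep(1:3, each = 6)
  expect_equal(ari(sol$labels, truth), 1)
  expect_equal(ari(sol$kmeans_labels, truth), 1)
  expect_setequal(sol$top_cluster, paste0("drug", 1:6))

  dup <- panel[c(1, 1, 7, 7), ]
  dup$compound_id <- paste0("x", 1:4)
  sdup <- suppressWarnings(descriptor_panel_cluster(dup, 2, seed = 1))
  expect_equal(unname(sdup$labels[1]), unname(sdup$labels[2]))
  expect_equal(unname(sdup$labels[3]), unname(sdup$labels[4]))
})
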