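test_that("classical MDS inverts Euclidean RDMs up to rigid motion", {
  # collinear points embed in 1-D with exact distances
  line <- euclidean_rdm(matrix(c(0, 3, 7, 11), 4, 1))
  emb1 <- classical_mds(line, k = 1)
  expect_equal(rdm_values(euclidean_rdm(emb1$coords)), rdm_values(line),
               tolerance = 1e-8, ignore_attr = TRUE)

  set.seed(2)
  pts <- matrix(rnorm(20), 10, 2)
  emb <- classical_mds(euclidean_rdm(pts), k = 2)
  expect_lt(procrustes_error(pts, emb$coords), 1e-6)
  expect_equal(rdm_values(euclidean_rdm(emb$coords)),
               rdm_values(euclidean_rdm(pts)), tolerance = 1e-8,
               ignore_attr = TRUE)

  # requesting more dimensions than positive eigenvalues warns
  expect_warning(classical_mds(line, k = 3), "truncated")
})

test_that("PCA variance fractions match an SVD oracle", {
  # points on a line in 3-D: first component carries everything
  t <- seq(-2, 2, length.out = 15)
  line3 <- cbind(t, 2 * t, -t) + 0
  p <- pca_variance(line3)
  expect_equal(p$variance_fraction[1], 1, tolerance = 1e-12)

  set.seed(3)
  x <- matrix(rnorm(40 * 3), 40, 3)
  p2 <- pca_variance(x)
  sv <- svd(scale(x, scale = FALSE))$d
  expect_equal(p2$variance_fraction, sv^2 / sum(sv^2), tolerance = 1e-12)
  expect_equal(sum(p2$variance_fraction), 1, tolerance = 1e-12)

  # large isotropic cloud: fractions near 1/k
  set.seed(4)
  iso <- matrix(rnorm(4000 * 4), ncol = 4)
  expect_equal(pca_variance(iso)$variance_fraction, rep(0.25, 4),
               tolerance = 0.05)

  expect_error(pca_variance(matrix(1, 5, 2)), "zero-variance")
})

test_that("silhouette selection finds well-separated blob counts", {
  set.seed(5)
  blobs <- rbind(matrix(rnorm(20, 0, 0.3), 10, 2),
                 matrix(rnorm(20, 8, 0.3), 10, 2))
  sol <- silhouette_select_k(blobs, k_range = 2:8, n_restarts = 25,
                             seed = 1)
  expect_equal(sol$best_k, 2)
  expect_gt(sol$mean_silhouette, 0.8)

  gt <- make_ground_truth(n_items = 28, n_clusters = 6, seed = 4)
  sol6 <- silhouette_select_k(gt$latent_coords, seed = 2)
  expect_equal(sol6$best_k, 6)
  expect_gte(adjusted_rand(sol6$labels, gt$cluster_labels), 0.9)

  expect_identical(
    glance(silhouette_select_k(blobs, k_range = 2:4, n_restarts = 5,
                               seed = 9)),
    glance(silhouette_select_k(blobs, k_range = 2:4, n_restarts = 5,
                               seed = 9)))
  expect_error(silhouette_select_k(blobs, k_range = 2:25), "k_range")
})

test_that("hierarchical clustering reproduces known merge structure", {
  # two tight pairs far apart merge pairs first
  pts <- rbind(c(0, 0), c(0.1, 0), c(10, 0), c(10.1, 0))
  r <- euclidean_rdm(pts, items = c("a1", "a2", "b1", "b2"))
  hc <- hierarchical_cluster(r, "average")
  first_two <- list(sort(-hc$merge[1, ]), sort(-hc$merge[2, ]))
  expect_setequal(first_two, list(1:2, 3:4))

  # ultrametric input is reproduced exactly by the cophenetic distances
  ultra <- matrix(c(0, 1, 4, 4,
                    1, 0, 4, 4,
                    4, 4, 0, 2,
                    4, 4, 2, 0), 4, 4)
  ru <- rdm(ultra, items = letters[1:4])
  hcu <- hierarchical_cluster(ru, "average")
  expect_equal(as.matrix(stats::cophenetic(hcu))[letters[1:4], letters[1:4]],
               ultra, tolerance = 1e-12, ignore_attr = TRUE)

  # average-linkage heights match a brute-force agglomeration on 6 items
  r6 <- random_rdm(6, seed = 7)
  hc6 <- hierarchical_cluster(r6, "average")
  d <- rdm_values(r6)
  groups <- as.list(seq_len(6))
  heights <- numeric(0)
  while (length(groups) > 1) {
    best <- c(Inf, 0, 0)
    for (i in seq_along(groups)) {
      for (j in seq_along(groups)) {
        if (j <= i) next
        h <- mean(d[groups[[i]], groups[[j]]])
        if (h < best[1]) best <- c(h, i, j)
      }
    }
    heights <- c(heights, best[1])
    groups[[best[2]]] <- c(groups[[best[2]]], groups[[best[3]]])
    groups[[best[3]]] <- NULL
  }
  expect_equal(hc6$height, heights, tolerance = 1e-10)

  # newick export parses back to the same topology
  nwk <- dendrogram_newick(hc6)
  expect_match(nwk, "^\\(")
  tr <- ape::read.tree(text = nwk)
  expect_setequal(tr$tip.label, rdm_items(r6))
})

test_that("peak-ROI geometry identifies the planted model", {
  surf <- make_toy_surface(2, n_regions = 1, region_size = 30, seed = 8)
  gt <- make_ground_truth(seed = 9)
  semantic <- normalize_rdm(squared_euclidean_rdm(gt$latent_coords))
  other <- random_sq_rdm(28, seed = 10,
                         items = rdm_items(semantic))
  models <- model_set(semantic = semantic, other = other)
  ds <- plant_brain_patterns(surf, models,
                             region_weights = list("1" = c(semantic = 1)),
                             n_subjects = 6, n_runs = 2, noise_sd = 0.2,
                             seed = 11)
  sl <- build_searchlights(surf, 10)
  maps <- standard_rsa_map(ds, semantic, sl)
  tmap <- group_t_map(maps, "fisher")

  roi <- roi_geometry(ds, tmap, models, roi_size = 20)
  expect_true(roi$peak_vertex %in% which(surf$region_map == 1))
  mc <- roi$model_correlations
  expect_equal(mc$model[which.max(mc$mean_tau)], "semantic")
  expect_true(mc$reject[mc$model == "semantic"])
  # display RDM is on the 0-100 rank scale
  expect_equal(max(rdm_values(roi$group_rdm)), 100)
  expect_s3_class(roi$mds, "embedding")
  expect_s3_class(roi$dendrogram, "hclust")

  # bit-for-bit reproducible given identical inputs
  roi2 <- roi_geometry(ds, tmap, models, roi_size = 20)
  expect_identical(roi$model_correlations, roi2$model_correlations)
})

test_that("tidiers and autoplot methods return well-formed objects", {
  r <- random_rdm(6, seed = 12)
  expect_named(tidy(r), c("item_i", "item_j", "value"))
  expect_s3_class(ggplot2::autoplot(r), "ggplot")

  emb <- classical_mds(r, k = 2)
  expect_named(tidy(emb), c("item", "dim1", "dim2"))
  expect_s3_class(ggplot2::autoplot(emb), "ggplot")

  gt <- make_ground_truth(n_items = 12, n_clusters = 3, seed = 13)
  sol <- silhouette_select_k(gt$latent_coords, k_range = 2:5,
                             n_restarts = 10, seed = 1)
  expect_named(tidy(sol), c("item", "cluster", "silhouette"))
  expect_s3_class(ggplot2::autoplot(sol), "ggplot")
})

test_that("K recovery degrades as planted separation shrinks", {
  rate_at <- function(sep) {
    mean(vapply(1:20, function(s) {
      gt <- make_ground_truth(n_items = 24, n_clusters = 6,
                              cluster_spread = max(sep, 3),
                              min_separation = sep, seed = 600 + s)
      silhouette_select_k(gt$latent_coords, k_range = 2:8,
                          n_restarts = 50, seed = s)$best_k == 6
    }, logical(1)))
  }
  rates <- vapply(c(1.5, 4, 7), rate_at, numeric(1))
  # monotone within Monte-Carlo wiggle, clearly increasing overall
  expect_true(all(diff(rates) >= -0.1))
  expect_gt(rates[3] - rates[1], 0.3)
})
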