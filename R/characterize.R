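#' Classical (Torgerson) multidimensional scaling of an RDM
#'
#' Double-centers the squared dissimilarities, eigendecomposes, and returns
#' the top-`k` coordinates scaled by the square roots of the eigenvalues.
#' Variance-explained fractions are computed over the positive eigenvalues;
#' negative-eigenvalue mass (non-Euclidean residual) is reported separately.
#' If fewer than `k` positive eigenvalues exist, the embedding is truncated
#' with a warning.
#'
#' @param x an `rdm`
#' @param k requested dimensionality
#' @return an `embedding`: list with `items`, `coords` (n x <= k),
#'   `eigenvalues`, `variance_explained`, `negative_mass`
#' @export
classical_mds <- function(x, k = 2) {
  stopifnot(inherits(x, "rdm"))
  n <- length(x$items)
  stop_if(k >= n, "k must be smaller than the number of items")
  d2 <- rdm_values(x)^2
  j <- diag(n) - 1 / n
  g <- -0.5 * j %*% d2 %*% j
  e <- eigen((g + t(g)) / 2, symmetric = TRUE)
  pos <- e$values > max(e$values, 0) * 1e-12
  n_pos <- sum(pos)
  if (n_pos < k) {
    warning(sprintf("only %d positive eigenvalue(s); embedding truncated %s",
                    n_pos, "below requested k"), call. = FALSE)
  }
  kk <- min(k, n_pos)
  coords <- if (kk > 0) {
    e$vectors[, seq_len(kk), drop = FALSE] %*%
      diag(sqrt(e$values[seq_len(kk)]), kk)
  } else matrix(0, n, 0)
  rownames(coords) <- x$items
  pos_sum <- sum(e$values[pos])
  structure(list(
    items = x$items, coords = coords, eigenvalues = e$values,
    variance_explained = if (pos_sum > 0) e$values[seq_len(kk)] / pos_sum
                         else numeric(kk),
    negative_mass = sum(abs(e$values[e$values < 0])) /
      max(sum(abs(e$values)), .Machine$double.eps)
  ), class = "embedding")
}

#' @export
print.embedding <- function(x, ...) {
  cat(sprintf("<embedding> %d items in %d dim; var explained: %s\n",
              length(x$items), ncol(x$coords),
              paste(sprintf("%.1f%%", 100 * x$variance_explained),
                    collapse = ", ")))
  invisible(x)
}

#' Tidy an embedding into an item x coordinate tibble
#' @param x an `embedding`
#' @param ... unused
#' @method tidy embedding
#' @export
tidy.embedding <- function(x, ...) {
  out <- tibble(item = x$items)
  for (d in seq_len(ncol(x$coords)))
    out[[paste0("dim", d)]] <- x$coords[, d]
  out
}

#' Scatter plot of the first two embedding dimensions
#' @param object an `embedding`
#' @param labels draw item labels
#' @param cluster_labels optional item -> cluster assignment for coloring
#' @param ... unused
#' @method autoplot embedding
#' @export
autoplot.embedding <- function(object, labels = TRUE, cluster_labels = NULL,
                               ...) {
  stop_if(ncol(object$coords) < 2, "need at least a 2-D embedding to plot")
  df <- tidy(object)
  if (!is.null(cluster_labels))
    df$cluster <- factor(cluster_labels[df$item])
  p <- ggplot2::ggplot(df, ggplot2::aes(.data$dim1, .data$dim2)) +
    ggplot2::theme_minimal() +
    ggplot2::labs(x = "component 1", y = "component 2")
  p <- if (!is.null(cluster_labels))
    p + ggplot2::geom_point(ggplot2::aes(color = .data$cluster), size = 2)
  else p + ggplot2::geom_point(size = 2)
  if (labels)
    p <- p + ggplot2::geom_text(ggplot2::aes(label = .data$item),
                                vjust = -0.6, size = 3)
  p
}

#' PCA variance decomposition of item coordinates
#'
#' Centered covariance eigendecomposition of an item x coordinate matrix
#' (e.g. MDS coordinates of a group RDM). Variance fractions sum to 1 over
#' all components.
#'
#' @param coords items x dimensions matrix, or an `embedding`
#' @return list with `loadings`, `scores`, `sdev`,
#'   `variance_fraction`
#' @export
pca_variance <- function(coords) {
  if (inherits(coords, "embedding")) coords <- coords$coords
  stopifnot(is.matrix(coords))
  stop_if(nrow(coords) < 2, "need at least 2 items")
  stop_if(all(apply(coords, 2, sd) == 0), "zero-variance input")
  p <- stats::prcomp(coords, center = TRUE, scale. = FALSE)
  list(loadings = p$rotation, scores = p$x, sdev = p$sdev,
       variance_fraction = p$sdev^2 / sum(p$sdev^2))
}

# k-means++ seeding: first center uniform, later centers with probability
# proportional to squared distance to the nearest chosen center.
kmeanspp_centers <- function(coords, k) {
  n <- nrow(coords)
  centers <- numeric(k)
  centers[1] <- sample.int(n, 1)
  d2 <- rowSums((coords - matrix(coords[centers[1], ], n, ncol(coords),
                                 byrow = TRUE))^2)
  if (k < 2) return(coords[centers[1], , drop = FALSE])
  for (i in 2:k) {
    probs <- d2 / sum(d2)
    if (all(d2 == 0)) probs <- rep(1 / n, n)
    centers[i] <- sample.int(n, 1, prob = probs)
    nd <- rowSums((coords - matrix(coords[centers[i], ], n, ncol(coords),
                                   byrow = TRUE))^2)
    d2 <- pmin(d2, nd)
  }
  coords[centers, , drop = FALSE]
}

#' Silhouette-guided k-means clustering
#'
#' For each candidate `k`, runs `n_restarts` k-means fits (Lloyd's
#' algorithm with k-means++ seeding) and keeps the lowest-inertia fit; each
#' `k` is scored by the mean silhouette width of its best fit, and the `k`
#' with the maximal mean silhouette is selected. Singleton clusters get
#' silhouette 0 by convention. Deterministic for a fixed seed.
#'
#' @param coords items x dimensions matrix (or an `embedding`)
#' @param k_range candidate cluster counts, within `[2, n - 1]`
#' @param n_restarts k-means restarts per k
#' @param seed RNG seed
#' @return a `cluster_solution`: list with `best_k`, `labels`,
#'   `silhouette` (per item), `mean_silhouette`, `inertia`,
#'   `silhouette_curve` (tibble k, mean_silhouette), `seed`
#' @export
silhouette_select_k <- function(coords, k_range = 2:10, n_restarts = 100,
                                seed = 1) {
  if (inherits(coords, "embedding")) coords <- coords$coords
  stopifnot(is.matrix(coords))
  n <- nrow(coords)
  stop_if(min(k_range) < 2 || max(k_range) > n - 1,
          "k_range must lie within [2, n - 1]")
  dmat <- as.matrix(stats::dist(coords))
  with_seed(seed, {
    fits <- lapply(k_range, function(k) {
      best <- NULL
      for (r in seq_len(n_restarts)) {
        init <- kmeanspp_centers(coords, k)
        fit <- tryCatch(
          suppressWarnings(stats::kmeans(coords, centers = init,
                                         iter.max = 50,
                                         algorithm = "Lloyd")),
          error = function(e) NULL)
        if (is.null(fit) || any(fit$size == 0)) next
        if (is.null(best) || fit$tot.withinss < best$tot.withinss) best <- fit
      }
      stop_if(is.null(best), "k-means failed for every restart at k = %d", k)
      sil <- cluster::silhouette(best$cluster, dmatrix = dmat)
      sil_width <- if (is.matrix(sil)) sil[, "sil_width"] else rep(0, n)
      sil_width[is.na(sil_width)] <- 0
      list(k = k, fit = best, sil = sil_width,
           mean_sil = mean(sil_width))
    })
    curve <- tibble(k = k_range,
                    mean_silhouette = vapply(fits, `[[`, numeric(1),
                                             "mean_sil"))
    best_i <- which.max(curve$mean_silhouette)
    best <- fits[[best_i]]
    structure(list(
      best_k = best$k,
      labels = setNames(best$fit$cluster,
                        rownames(coords) %||% seq_len(n)),
      silhouette = best$sil,
      mean_silhouette = best$mean_sil,
      inertia = best$fit$tot.withinss,
      silhouette_curve = curve,
      seed = seed
    ), class = "cluster_solution")
  })
}

#' @export
print.cluster_solution <- function(x, ...) {
  cat(sprintf("<cluster_solution> best k = %d (mean silhouette %.3f)\n",
              x$best_k, x$mean_silhouette))
  invisible(x)
}

#' Tidy a cluster solution into an item table
#' @param x a `cluster_solution`
#' @param ... unused
#' @method tidy cluster_solution
#' @export
tidy.cluster_solution <- function(x, ...) {
  tibble(item = names(x$labels), cluster = unname(x$labels),
         silhouette = x$silhouette)
}

#' One-row summary of a cluster solution
#' @param x a `cluster_solution`
#' @param ... unused
#' @method glance cluster_solution
#' @export
glance.cluster_solution <- function(x, ...) {
  tibble(best_k = x$best_k, mean_silhouette = x$mean_silhouette,
         inertia = x$inertia)
}

#' Silhouette curve plot
#' @param object a `cluster_solution`
#' @param ... unused
#' @method autoplot cluster_solution
#' @export
autoplot.cluster_solution <- function(object, ...) {
  ggplot2::ggplot(object$silhouette_curve,
                  ggplot2::aes(.data$k, .data$mean_silhouette)) +
    ggplot2::geom_line() + ggplot2::geom_point() +
    ggplot2::geom_vline(xintercept = object$best_k, linetype = 2) +
    ggplot2::labs(x = "number of clusters k",
                  y = "mean silhouette width") +
    ggplot2::theme_minimal()
}

#' Agglomerative hierarchical clustering of an RDM
#'
#' [stats::hclust()] on the dissimilarities with the chosen linkage
#' (average by default, the conventional choice for correlation-like
#' dissimilarities). The dendrogram can be exported as a Newick string.
#'
#' @param x an `rdm`
#' @param linkage `"average"`, `"complete"` or `"ward"` (ward.D2)
#' @return an `hclust` object with item labels
#' @export
hierarchical_cluster <- function(x, linkage = c("average", "complete",
                                                "ward")) {
  linkage <- match.arg(linkage)
  stopifnot(inherits(x, "rdm"))
  stop_if(length(x$items) < 2, "need at least 2 items")
  method <- if (linkage == "ward") "ward.D2" else linkage
  d <- stats::as.dist(rdm_values(x))
  stats::hclust(d, method = method)
}

#' Export a dendrogram as a Newick string
#' @param hc an `hclust` object
#' @return Newick string (with branch lengths)
#' @export
dendrogram_newick <- function(hc) {
  ape::write.tree(ape::as.phylo(hc))
}

#' Adjusted Rand index between two labelings
#'
#' Permutation-invariant agreement between cluster assignments; 1 for
#' identical partitions, ~0 for chance.
#'
#' @param a,b integer label vectors of equal length
#' @return adjusted Rand index
#' @export
adjusted_rand <- function(a, b) {
  stop_if(length(a) != length(b), "labelings differ in length")
  tab <- table(a, b)
  comb2 <- function(x) x * (x - 1) / 2
  sum_ij <- sum(comb2(tab))
  sum_a <- sum(comb2(rowSums(tab)))
  sum_b <- sum(comb2(colSums(tab)))
  n <- length(a)
  expected <- sum_a * sum_b / comb2(n)
  max_index <- (sum_a + sum_b) / 2
  if (max_index == expected) return(1)
  (sum_ij - expected) / (max_index - expected)
}

#' Representational geometry of the peak ROI
#'
#' Reproduces the post-hoc ROI workflow: the ROI is the searchlight of
#' `roi_size` vertices centered on the argmax vertex of a group stat map
#' (ties broken toward the lowest vertex index). Per subject, a neural RDM
#' is computed from the ROI with the standard-RSA recipe and correlated
#' (Kendall tau-a) with every model; the per-model correlations are tested
#' against zero with one-tailed t-tests, BH-FDR corrected. The group-mean
#' neural RDM is rank-rescaled to 0-100 for display and characterized by
#' classical MDS and hierarchical clustering.
#'
#' @param dataset a `beta_dataset`
#' @param stat_map tibble with `vertex` and a statistic column `t` (or
#'   `value`) defined on the dataset's surface
#' @param models a [model_set()]
#' @param roi_size vertices in the ROI
#' @param mds_k dimensions of the display embedding
#' @return an `roi_report`: list with `peak_vertex`, `roi_vertices`,
#'   `model_correlations` (tibble: model, mean_tau, t, p, p_adj, reject),
#'   `group_rdm` (rank-rescaled), `mds` (embedding), `dendrogram` (hclust)
#' @export
roi_geometry <- function(dataset, stat_map, models, roi_size = 100,
                         mds_k = 2) {
  surface <- dataset$surface
  stat_col <- if ("t" %in% names(stat_map)) "t" else "value"
  vals <- stat_map[[stat_col]]
  stop_if(nrow(stat_map) != nrow(surface$vertices),
          "stat map does not cover the surface")
  peak <- stat_map$vertex[which.max(vals)]  # which.max = lowest index on ties
  roi <- searchlight_members(surface$adjacency, surface$vertices, peak,
                             roi_size)
  subj_rdms <- lapply(dataset$betas, neural_rdm, members = roi,
                      mode = "standard")
  taus <- vapply(names(models$models), function(mn) {
    vapply(subj_rdms, function(nr)
      rdm_correlation(nr, models$models[[mn]], "kendall_tau_a"),
      numeric(1))
  }, numeric(length(subj_rdms)))
  n <- nrow(taus)
  tt <- apply(taus, 2, function(v) {
    s <- sd(v)
    tval <- if (s > 0) mean(v) / (s / sqrt(n)) else
      ifelse(mean(v) == 0, 0, sign(mean(v)) * 1e12)
    c(mean(v), tval, stats::pt(tval, n - 1, lower.tail = FALSE))
  })
  fdr <- fdr_bh(tt[3, ])
  model_correlations <- tibble(
    model = colnames(taus), mean_tau = tt[1, ], t = tt[2, ],
    p = tt[3, ], p_adj = fdr$p_adj, reject = fdr$reject)

  mean_vals <- Reduce(`+`, lapply(subj_rdms, rdm_values)) / length(subj_rdms)
  group_rdm <- rdm(mean_vals, items = dataset$items,
                   meta = list(source = "roi_group_mean"))
  structure(list(
    peak_vertex = peak, roi_vertices = roi,
    model_correlations = model_correlations,
    group_rdm = rank_rescale_rdm(group_rdm),
    mds = classical_mds(group_rdm, k = mds_k),
    dendrogram = hierarchical_cluster(group_rdm)
  ), class = "roi_report")
}

#' @export
print.roi_report <- function(x, ...) {
  cat(sprintf("<roi_report> peak vertex %d, %d ROI vertices; best model: %s\n",
              x$peak_vertex, length(x$roi_vertices),
              x$model_correlations$model[
                which.max(x$model_correlations$mean_tau)]))
  invisible(x)
}

#' Tidy the model-correlation table of an ROI report
#' @param x an `roi_report`
#' @param ... unused
#' @method tidy roi_report
#' @export
tidy.roi_report <- function(x, ...) x$model_correlations
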