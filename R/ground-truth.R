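#' Planted semantic ground truth
#'
#' Generates a latent item configuration with a known cluster structure:
#' `n_clusters` centers drawn from an isotropic normal with sd
#' `cluster_spread`, items scattered around their centers with sd
#' `within_spread`. Centers are redrawn until every pair is at least
#' `min_separation * within_spread` apart, so the planted clusters are
#' genuinely distinct rather than merged by chance. The true RDM is the
#' max-normalized Euclidean distance matrix of the latent coordinates. The
#' default geometry — 28 items in 6 clusters — emulates the semantic
#' structure a multi-arrangement cohort is expected to produce; the
#' separation ratio controls how recoverable that structure is.
#'
#' @param n_items number of items (conditions)
#' @param n_clusters number of planted clusters
#' @param cluster_spread sd of cluster centers (arbitrary latent units)
#' @param within_spread sd of items around their center
#' @param dim latent dimensionality
#' @param min_separation minimum pairwise center distance, in units of
#'   `within_spread` (rejection-sampled; set 0 to disable)
#' @param seed RNG seed
#' @return a `ground_truth`: list with `n_items`, `latent_coords`,
#'   `cluster_labels`, `true_rdm`
#' @export
make_ground_truth <- function(n_items = 28, n_clusters = 6,
                              cluster_spread = 7, within_spread = 1,
                              dim = 2, min_separation = 7, seed = 1) {
  stop_if(n_clusters > n_items, "n_clusters cannot exceed n_items")
  stop_if(n_clusters < 1, "need at least one cluster")
  stop_if(cluster_spread <= 0 || within_spread < 0, "spreads must be positive")
  with_seed(seed, {
    draw_centers <- function() matrix(rnorm(n_clusters * dim,
                                            sd = cluster_spread),
                                      n_clusters, dim)
    centers <- draw_centers()
    if (n_clusters > 1 && min_separation > 0) {
      for (try in 1:1000) {
        if (min(stats::dist(centers)) >=
            min_separation * within_spread) break
        centers <- draw_centers()
      }
      stop_if(min(stats::dist(centers)) < min_separation * within_spread,
              paste0("could not separate %d cluster centers by %.1f x ",
                     "within_spread; increase cluster_spread"),
              n_clusters, min_separation)
    }
    # near-balanced assignment: planted clusters differ in size by at most
    # one item (a size-1 "cluster" would not be a planted structure)
    labels <- sample(rep_len(seq_len(n_clusters), n_items))
    coords <- centers[labels, , drop = FALSE] +
      matrix(rnorm(n_items * dim, sd = within_spread), n_items, dim)
    items <- sprintf("action%02d", seq_len(n_items))
    rownames(coords) <- items
    true_rdm <- normalize_rdm(euclidean_rdm(coords, items = items,
                                            meta = list(task = "ground_truth")))
    structure(
      list(n_items = n_items, latent_coords = coords,
           cluster_labels = setNames(labels, items), true_rdm = true_rdm),
      class = "ground_truth"
    )
  })
}

#' @export
print.ground_truth <- function(x, ...) {
  cat(sprintf("<ground_truth> %d items, %d clusters, dim %d\n",
              x$n_items, max(x$cluster_labels), ncol(x$latent_coords)))
  invisible(x)
}

# Exact Euclidean embedding of a target squared-distance matrix.
# Returns an n x p pattern matrix whose squared Euclidean RDM equals `d`
# (entries interpreted as squared distances). Errors if `d` is not
# embeddable (double-centered Gram matrix not PSD within tolerance).
embed_squared_distances <- function(d, tol = 1e-8) {
  n <- nrow(d)
  j <- diag(n) - 1 / n
  g <- -0.5 * j %*% d %*% j
  e <- eigen((g + t(g)) / 2, symmetric = TRUE)
  lam <- e$values
  stop_if(min(lam) < -tol * max(abs(lam), 1),
          paste0("dissimilarities are not embeddable as squared Euclidean ",
                 "distances (min eigenvalue %.3g)"), min(lam))
  keep <- lam > tol * max(abs(lam), 1)
  if (!any(keep)) return(matrix(0, n, 1))
  e$vectors[, keep, drop = FALSE] %*% diag(sqrt(lam[keep]), sum(keep))
}

#' Plant model geometries into a toy brain
#'
#' Builds a per-subject beta dataset on a toy surface in which selected
#' regions carry activation-pattern geometries that are exact linear
#' mixtures of model RDMs. For each region, every model k with weight
#' `w_k > 0` contributes a disjoint block of features (vertices) holding an
#' exact Euclidean embedding of `w_k * modelRDM_k` (entries read as squared
#' distances). Because squared Euclidean distances add over disjoint feature
#' blocks, the region's noiseless squared-Euclidean RDM equals
#' `sum_k w_k * modelRDM_k` exactly — the oracle for the whole
#' regression-RSA stack. The block patterns are then spread over all of the
#' region's vertices by a random orthonormal rotation, which preserves
#' every pairwise distance exactly while avoiding signal concentrated in a
#' few vertices. Background vertices and all noise are i.i.d. Gaussian,
#' drawn independently per subject and run.
#'
#' @param surface a [make_toy_surface()] with `region_map` labels
#' @param model_set a [model_set()] of predictor RDMs
#' @param region_weights named list: region id (as character) -> named
#'   numeric vector of model weights
#' @param n_subjects number of subjects
#' @param n_runs runs per subject
#' @param noise_sd sd of additive Gaussian noise on every beta
#' @param seed RNG seed
#' @return a `beta_dataset`: list with `betas` (list over subjects of
#'   run x condition x vertex arrays), `items`, `surface`, `region_weights`
#' @export
plant_brain_patterns <- function(surface, model_set, region_weights,
                                 n_subjects = 20, n_runs = 2,
                                 noise_sd = 0, seed = 1) {
  stopifnot(inherits(surface, "toy_surface"))
  items <- model_set$items
  n_cond <- length(items)
  m <- nrow(surface$vertices)

  betas <- with_seed(seed, {
  # region template patterns (shared across subjects and runs)
  templates <- matrix(0, n_cond, m)
  for (rid in names(region_weights)) {
    w <- region_weights[[rid]]
    stop_if(is.null(names(w)) || !all(names(w) %in% names(model_set$models)),
            "region %s: weights must be named after models in the set", rid)
    stop_if(any(w < 0), "region %s: weights must be >= 0", rid)
    verts <- which(surface$region_map == as.integer(rid))
    stop_if(length(verts) == 0, "region %s not present on surface", rid)
    blocks <- lapply(names(w)[w > 0], function(mn) {
      d <- w[[mn]] * rdm_values(model_set$models[[mn]])
      embed_squared_distances(d)
    })
    need <- sum(vapply(blocks, ncol, integer(1)))
    stop_if(need > length(verts),
            "region %s has %d vertices but needs %d feature columns",
            rid, length(verts), need)
    if (need > 0) {
      pat <- do.call(cbind, blocks)
      # distance-preserving rotation onto the full region width
      q <- qr.Q(qr(matrix(rnorm(length(verts) * need), length(verts), need)))
      templates[, verts] <- pat %*% t(q)
    }
  }

  lapply(seq_len(n_subjects), function(s) {
    arr <- array(0, dim = c(n_runs, n_cond, m),
                 dimnames = list(NULL, items, NULL))
    for (r in seq_len(n_runs)) {
      arr[r, , ] <- templates +
        matrix(rnorm(n_cond * m, sd = noise_sd), n_cond, m)
    }
    arr
  })
  })

  structure(
    list(betas = betas, items = items, surface = surface,
         region_weights = region_weights, noise_sd = noise_sd),
    class = "beta_dataset"
  )
}

#' @export
print.beta_dataset <- function(x, ...) {
  d <- dim(x$betas[[1]])
  cat(sprintf(
    "<beta_dataset> %d subjects, %d runs x %d conditions x %d vertices\n",
    length(x$betas), d[1], d[2], d[3]))
  invisible(x)
}
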