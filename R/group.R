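#' Group t-map across subject maps
#'
#' Per-vertex one-sample t-test of the subject maps against zero, after an
#' optional Fisher transform (used for correlation maps; coefficients from
#' regression RSA are tested untransformed). Vertices where any subject is
#' `NA` are masked. Zero-variance vertices (all subjects identical) are
#' guarded: they get a large finite t with the correct sign rather than
#' `Inf`.
#'
#' @param subject_maps subjects x vertices matrix (see [maps_to_matrix()])
#'   or a long tibble with `subject`, `vertex`, `value`
#' @param transform `"fisher"` or `"none"`
#' @return tibble with `vertex`, `mean`, `t`, `df`, `n`, `masked`
#' @export
group_t_map <- function(subject_maps, transform = c("fisher", "none")) {
  transform <- match.arg(transform)
  x <- prepare_group_matrix(subject_maps, transform)
  n <- nrow(x)
  stop_if(n < 3, "need at least 3 subjects")
  masked <- apply(x, 2, anyNA)
  mu <- colMeans(x)
  s <- apply(x, 2, sd)
  tval <- ifelse(s > 0, mu / (s / sqrt(n)),
                 ifelse(mu == 0, 0, sign(mu) * 1e12))
  tibble(vertex = as.integer(colnames(x) %||% seq_len(ncol(x))),
         mean = unname(ifelse(masked, NA_real_, mu)),
         t = unname(ifelse(masked, NA_real_, tval)),
         df = n - 1L, n = n, masked = unname(masked))
}

# Accepts long tibble or matrix; applies the transform with an |r| < 1
# clamp so noiseless planted maps (r exactly 1) stay finite.
prepare_group_matrix <- function(subject_maps, transform) {
  x <- if (is.matrix(subject_maps)) subject_maps else
    maps_to_matrix(subject_maps)
  if (transform == "fisher") {
    x <- atanh(pmin(pmax(x, -1 + 1e-12), 1 - 1e-12))
  }
  x
}

# Edge-connected components of a vertex subset. Returns a list of integer
# vectors (vertex indices).
connected_components <- function(adjacency, vertices) {
  if (length(vertices) == 0) return(list())
  inset <- logical(length(adjacency))
  inset[vertices] <- TRUE
  seen <- logical(length(adjacency))
  comps <- list()
  for (v in vertices) {
    if (seen[v]) next
    comp <- integer(0)
    frontier <- v
    seen[v] <- TRUE
    while (length(frontier)) {
      comp <- c(comp, frontier)
      nxt <- unique(unlist(adjacency[frontier]))
      nxt <- nxt[inset[nxt] & !seen[nxt]]
      seen[nxt] <- TRUE
      frontier <- nxt
    }
    comps[[length(comps) + 1]] <- sort(comp)
  }
  comps
}

# Max cluster mass over suprathreshold vertices of a t vector (0 if none).
max_cluster_mass <- function(tvec, t_cut, adjacency) {
  supra <- which(tvec > t_cut)
  if (!length(supra)) return(0)
  comps <- connected_components(adjacency, supra)
  max(vapply(comps, function(cc) sum(tvec[cc]), numeric(1)))
}

#' Cluster-based Monte-Carlo permutation correction on a surface
#'
#' Family-wise-error correction for one-tailed group maps: vertices whose
#' uncorrected one-tailed p is below `p0` are formed into edge-connected
#' clusters; each cluster's mass (sum of t, the max-sum statistic) is
#' compared to a null distribution of maximum cluster masses obtained by
#' randomly sign-flipping each subject's (transformed) map and recomputing
#' the t-map (`n_perm` iterations). Corrected p-values use the add-one rule
#' `(1 + #{null >= observed}) / (1 + n_perm)`, so they are never zero, with
#' ties counted conservatively. Corrected p is converted to a one-tailed
#' normal z; clusters with `z > z_thresh` are significant, and the z-map is
#' nonzero only at their member vertices.
#'
#' @param subject_maps subjects x vertices matrix or long tibble
#' @param surface a `toy_surface` providing the adjacency
#' @param n_perm permutation iterations (default 5000)
#' @param p0 initial (cluster-forming) one-tailed p threshold
#' @param z_thresh significance threshold on the corrected-p z score
#'   (1.65, one-tailed)
#' @param transform `"fisher"` or `"none"` applied before all statistics
#' @param seed RNG seed for the sign flips (required for reproducibility)
#' @return a `group_result`: list with `t_map` (tibble), `z_map` (tibble),
#'   `clusters` (tibble: cluster, n_vertices, peak_vertex, mass, p_corr,
#'   z, significant), `null_max_mass`, and the parameters used
#' @export
cluster_permutation <- function(subject_maps, surface, n_perm = 5000,
                                p0 = 0.001, z_thresh = 1.65,
                                transform = c("fisher", "none"), seed = 1) {
  transform <- match.arg(transform)
  stopifnot(inherits(surface, "toy_surface"))
  x <- prepare_group_matrix(subject_maps, transform)
  n <- nrow(x)
  m <- ncol(x)
  stop_if(m != nrow(surface$vertices),
          "maps have %d vertices but the surface has %d", m,
          nrow(surface$vertices))
  if (n < 8) warning("fewer than 8 subjects: permutation null is coarse",
                     call. = FALSE)
  if (n_perm < 100) warning("n_perm < 100 gives a very coarse null",
                            call. = FALSE)
  masked <- apply(x, 2, anyNA)
  xw <- x
  xw[, masked] <- 0

  df <- n - 1
  t_cut <- qt(1 - p0, df)
  sumsq <- colSums(xw^2)

  t_from_signs <- function(signs) {
    mu <- as.vector(signs %*% xw) / n
    ss <- pmax(sumsq - n * mu^2, 0)
    s <- sqrt(ss / df)
    ifelse(s > 0, mu / (s / sqrt(n)), ifelse(mu == 0, 0, sign(mu) * 1e12))
  }

  t_obs <- t_from_signs(matrix(1, 1, n))
  t_obs[masked] <- -Inf
  supra <- which(t_obs > t_cut)
  comps <- connected_components(surface$adjacency, supra)

  null_max <- with_seed(seed, {
    signs <- matrix(sample(c(-1, 1), n_perm * n, replace = TRUE), n_perm, n)
    mu <- (signs %*% xw) / n
    ss <- pmax(matrix(sumsq, n_perm, m, byrow = TRUE) - n * mu^2, 0)
    tmat <- mu / (sqrt(ss / df) / sqrt(n))
    tmat[!is.finite(tmat)] <- 0
    tmat[, masked] <- -Inf
    apply(tmat, 1, max_cluster_mass, t_cut = t_cut,
          adjacency = surface$adjacency)
  })

  clusters <- if (length(comps)) {
    dplyr::bind_rows(lapply(seq_along(comps), function(i) {
      cc <- comps[[i]]
      mass <- sum(t_obs[cc])
      p_corr <- (1 + sum(null_max >= mass)) / (1 + n_perm)
      tibble(cluster = i, n_vertices = length(cc),
             peak_vertex = cc[which.max(t_obs[cc])], mass = mass,
             p_corr = p_corr, z = qnorm(1 - p_corr),
             significant = qnorm(1 - p_corr) > z_thresh,
             members = list(cc))
    }))
  } else {
    tibble(cluster = integer(), n_vertices = integer(),
           peak_vertex = integer(), mass = numeric(), p_corr = numeric(),
           z = numeric(), significant = logical(), members = list())
  }

  z_map <- numeric(m)
  for (i in seq_len(nrow(clusters))) {
    if (clusters$significant[i])
      z_map[clusters$members[[i]]] <- clusters$z[i]
  }

  structure(list(
    t_map = tibble(vertex = seq_len(m),
                   t = ifelse(masked, NA_real_, t_obs)),
    z_map = tibble(vertex = seq_len(m), z = z_map),
    clusters = clusters,
    null_max_mass = null_max,
    params = list(n_perm = n_perm, p0 = p0, z_thresh = z_thresh,
                  transform = transform, seed = seed, n_subjects = n)
  ), class = "group_result")
}

#' @export
print.group_result <- function(x, ...) {
  cat(sprintf("<group_result> %d subject(s), %d cluster(s), %d significant\n",
              x$params$n_subjects, nrow(x$clusters),
              sum(x$clusters$significant)))
  invisible(x)
}

#' Tidy the cluster table of a group result
#' @param x a `group_result`
#' @param ... unused
#' @method tidy group_result
#' @export
tidy.group_result <- function(x, ...) {
  dplyr::select(x$clusters, -"members")
}

#' One-row summary of a group result
#' @param x a `group_result`
#' @param ... unused
#' @method glance group_result
#' @export
glance.group_result <- function(x, ...) {
  tibble(n_subjects = x$params$n_subjects, n_perm = x$params$n_perm,
         n_clusters = nrow(x$clusters),
         n_significant = sum(x$clusters$significant),
         min_p_corr = if (nrow(x$clusters)) min(x$clusters$p_corr) else NA)
}

#' Benjamini-Hochberg FDR correction
#'
#' Step-up adjusted p-values (via [stats::p.adjust()]) and the rejection
#' mask at level `q`.
#'
#' @param pvalues numeric vector in `[0, 1]`
#' @param q FDR level
#' @return tibble with `p`, `p_adj`, `reject`
#' @export
fdr_bh <- function(pvalues, q = 0.05) {
  stop_if(any(pvalues < 0 | pvalues > 1), "p-values must be in [0, 1]")
  adj <- stats::p.adjust(pvalues, method = "BH")
  tibble(p = pvalues, p_adj = adj, reject = adj <= q)
}

#' Write a cluster table as TSV
#' @param result a `group_result`
#' @param path output path
#' @export
write_cluster_table <- function(result, path) {
  utils::write.table(tidy(result), path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}
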