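#' Simulation studies validating the inference stack
#'
#' Three self-contained simulation studies exercise the pipeline end to end
#' under known ground truth. They are part of the package surface (not just
#' test code) so the same study definitions back the test suite, the
#' acceptance script and the vignette.
#'
#' `recovery_study()` plants a semantic geometry into one compact region of
#' a toy cortical mesh, simulates a 20-subject cohort at a beta noise level
#' calibrated to give per-subject searchlight-map correlations around
#' 0.1-0.3, runs the standard searchlight RSA and the cluster-based
#' permutation correction, and scores spatial recovery: the Dice overlap
#' between the significant vertices and the planted region, and the number
#' of false-positive clusters (significant clusters disjoint from the
#' region). Anatomy, ground truth and cohort noise are redrawn each
#' replicate.
#'
#' @param n_replicates number of simulated studies
#' @param n_subjects subjects per study
#' @param n_runs runs per subject
#' @param noise_sd beta noise sd (default calibrated as above)
#' @param mesh_subdivisions icosphere subdivisions
#' @param region_size planted-region vertices
#' @param searchlight_features searchlight size on the toy mesh
#' @param n_perm permutation iterations
#' @param seed master seed; replicate r uses streams derived from it
#' @return `recovery_study()`: tibble with `replicate`, `dice`,
#'   `false_positive_clusters`, `mean_subject_r` (mean per-subject map
#'   correlation over region-interior searchlights)
#' @export
recovery_study <- function(n_replicates = 20, n_subjects = 20, n_runs = 2,
                           noise_sd = 0.15, mesh_subdivisions = 2,
                           region_size = 50, searchlight_features = 5,
                           n_perm = 1000, seed = 1) {
  rows <- lapply(seq_len(n_replicates), function(s) {
    base <- derive_seed(seed, sprintf("recovery%03d", s))
    gt <- make_ground_truth(seed = base)
    surface <- make_toy_surface(mesh_subdivisions, n_regions = 1,
                                region_size = region_size, seed = base + 1)
    semantic <- normalize_rdm(squared_euclidean_rdm(gt$latent_coords))
    models <- model_set(semantic = semantic)
    sl <- build_searchlights(surface, searchlight_features)
    ds <- plant_brain_patterns(surface, models,
                               region_weights = list("1" = c(semantic = 1)),
                               n_subjects = n_subjects, n_runs = n_runs,
                               noise_sd = noise_sd, seed = base + 2)
    maps <- standard_rsa_map(ds, semantic, sl)
    gr <- cluster_permutation(maps, surface, n_perm = n_perm,
                              seed = base + 3)
    region <- which(surface$region_map == 1)
    sig <- gr$clusters[gr$clusters$significant, ]
    sig_vertices <- unlist(sig$members)
    fp <- sum(vapply(sig$members, function(mm)
      length(intersect(mm, region)) == 0, logical(1)))
    interior <- region[vapply(region, function(v)
      all(sl$members[[v]] %in% region), logical(1))]
    mm <- maps_to_matrix(maps)
    tibble(
      replicate = s,
      dice = 2 * length(intersect(sig_vertices, region)) /
        (length(sig_vertices) + length(region)),
      false_positive_clusters = fp,
      mean_subject_r = mean(mm[, as.character(interior), drop = FALSE])
    )
  })
  dplyr::bind_rows(rows)
}

#' @rdname recovery_study
#'
#' @details
#' `fwer_study()` estimates the family-wise error rate of the cluster
#' permutation correction under the global null: pure-noise subject maps on
#' a small mesh, many simulated cohorts; the FWER is the fraction of
#' cohorts reporting any significant cluster, which should sit near the
#' nominal 0.05.
#'
#' @param n_cohorts number of null cohorts
#' @return `fwer_study()`: tibble with `cohort`, `any_significant`
#' @export
fwer_study <- function(n_cohorts = 200, n_subjects = 12,
                       mesh_subdivisions = 1, n_perm = 500, seed = 1) {
  surface <- make_toy_surface(mesh_subdivisions,
                              seed = derive_seed(seed, "fwer_mesh"))
  m <- nrow(surface$vertices)
  rows <- lapply(seq_len(n_cohorts), function(s) {
    base <- derive_seed(seed, sprintf("fwer%04d", s))
    x <- with_seed(base, matrix(rnorm(n_subjects * m), n_subjects, m,
                                dimnames = list(NULL, seq_len(m))))
    gr <- cluster_permutation(x, surface, n_perm = n_perm,
                              transform = "none", seed = base + 1)
    tibble(cohort = s, any_significant = any(gr$clusters$significant))
  })
  dplyr::bind_rows(rows)
}

#' @rdname recovery_study
#'
#' @details
#' `k_recovery_study()` checks that silhouette-guided k-means recovers the
#' planted number of clusters from high-separation latent configurations
#' (the default ground-truth geometry: 28 items, 6 clusters, center
#' separation at least 5 within-cluster sds).
#'
#' @param n_clusters planted cluster count
#' @return `k_recovery_study()`: tibble with `replicate`, `selected_k`,
#'   `adjusted_rand`
#' @export
k_recovery_study <- function(n_replicates = 50, n_clusters = 6, seed = 1) {
  rows <- lapply(seq_len(n_replicates), function(s) {
    base <- derive_seed(seed, sprintf("krec%03d", s))
    gt <- make_ground_truth(n_clusters = n_clusters, seed = base)
    sol <- silhouette_select_k(gt$latent_coords, seed = base + 1)
    tibble(replicate = s, selected_k = sol$best_k,
           adjusted_rand = adjusted_rand(sol$labels, gt$cluster_labels))
  })
  dplyr::bind_rows(rows)
}
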