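#' Pipeline configuration
#'
#' A single serializable list driving [run_pipeline()]: every stochastic
#' stage has an explicit seed, and all design parameters are recorded.
#' Unknown keys are rejected, so configs round-trip through YAML without
#' silent drift.
#'
#' @param seed master seed; per-stage seeds are derived from it
#'   deterministically and can be overridden individually
#' @param n_subjects simulated cohort size
#' @param n_items number of action conditions
#' @param n_clusters planted semantic clusters
#' @param arrangement_trials trials per simulated arrangement session
#' @param arrangement_noise_sd arranger placement noise (normalized RDM
#'   units)
#' @param mesh_subdivisions icosphere subdivisions of the toy surface
#' @param region_size vertices per planted region
#' @param searchlight_features vertices per searchlight
#' @param n_runs simulated runs per subject
#' @param beta_noise_sd sd of beta noise in the planted dataset
#' @param n_perm permutation iterations for cluster correction
#' @param p0 cluster-forming threshold
#' @param k_range candidate cluster counts for silhouette selection
#' @param out_dir run directory for artifacts
#' @return a `pipeline_config` list
#' @export
pipeline_config <- function(seed = 1, n_subjects = 12, n_items = 28,
                            n_clusters = 6, arrangement_trials = 10,
                            arrangement_noise_sd = 0.45,
                            mesh_subdivisions = 2, region_size = 40,
                            searchlight_features = 30, n_runs = 2,
                            beta_noise_sd = 1, n_perm = 1000, p0 = 0.001,
                            k_range = 2:10, out_dir = tempfile("rsarun")) {
  cfg <- list(seed = seed, n_subjects = n_subjects, n_items = n_items,
              n_clusters = n_clusters,
              arrangement_trials = arrangement_trials,
              arrangement_noise_sd = arrangement_noise_sd,
              mesh_subdivisions = mesh_subdivisions,
              region_size = region_size,
              searchlight_features = searchlight_features,
              n_runs = n_runs, beta_noise_sd = beta_noise_sd,
              n_perm = n_perm, p0 = p0, k_range = k_range,
              out_dir = out_dir)
  structure(cfg, class = "pipeline_config")
}

pipeline_config_keys <- function() names(unclass(pipeline_config()))

#' @rdname pipeline_config
#' @param config a `pipeline_config`
#' @param path YAML file
#' @export
write_pipeline_config <- function(config, path) {
  obj <- unclass(config)
  obj$k_range <- as.integer(obj$k_range)
  yaml::write_yaml(obj, path)
  invisible(path)
}

#' @rdname pipeline_config
#' @export
read_pipeline_config <- function(path) {
  obj <- yaml::read_yaml(path)
  known <- pipeline_config_keys()
  unknown <- setdiff(names(obj), known)
  stop_if(length(unknown) > 0, "unknown config key(s): %s",
          paste(unknown, collapse = ", "))
  do.call(pipeline_config, obj)
}

#' @rdname pipeline_config
#' @param x a `pipeline_config`
#' @param ... unused
#' @export
print.pipeline_config <- function(x, ...) {
  cat("<pipeline_config>\n")
  for (k in names(unclass(x)))
    cat(sprintf("  %s: %s\n", k, paste(x[[k]], collapse = " ")))
  invisible(x)
}

#' Run the full synthetic pipeline
#'
#' Chains every stage end to end on synthetic data: generate the planted
#' semantic ground truth, simulate an arrangement cohort and aggregate it
#' into subject and group RDMs, assemble a predictor model set (semantic,
#' movement, people), plant the semantic geometry into a region of a toy
#' surface, run searchlight standard and regression RSA, correct the group
#' map by cluster permutation, and characterize the recovered geometry
#' (silhouette-selected k-means, MDS, peak-ROI report). All artifacts are
#' written under `config$out_dir` as plain-text files plus a JSON manifest;
#' rerunning with the same config reproduces them bit-for-bit.
#'
#' @param config a [pipeline_config()]
#' @return list with all stage outputs (invisible components documented in
#'   the manifest)
#' @export
run_pipeline <- function(config = pipeline_config()) {
  cfg <- config
  dir.create(cfg$out_dir, showWarnings = FALSE, recursive = TRUE)
  seeds <- lapply(setNames(nm = c("truth", "arrange", "mesh", "plant",
                                  "perm", "cluster")),
                  function(st) derive_seed(cfg$seed, st))

  # stage 1: ground truths (semantic structure + an uncorrelated movement
  # structure used as a second predictor)
  truth <- make_ground_truth(n_items = cfg$n_items,
                             n_clusters = cfg$n_clusters,
                             seed = seeds$truth)
  movement_truth <- make_ground_truth(n_items = cfg$n_items, n_clusters = 4,
                                      seed = seeds$truth + 1)

  # stage 2: arrangement cohort -> subject RDMs -> group semantic RDM
  sessions <- lapply(seq_len(cfg$n_subjects), function(s)
    simulate_arranger(truth$true_rdm, noise_sd = cfg$arrangement_noise_sd,
                      n_trials = cfg$arrangement_trials,
                      subject = sprintf("sub%02d", s),
                      seed = seeds$arrange + s))
  subject_rdms <- lapply(sessions, aggregate_session)
  names(subject_rdms) <- sprintf("sub%02d", seq_len(cfg$n_subjects))
  group_vals <- Reduce(`+`, lapply(subject_rdms, rdm_values)) /
    length(subject_rdms)
  semantic_rdm <- normalize_rdm(rdm(group_vals, items = truth$true_rdm$items,
                                    meta = list(task = "semantic")))

  # stage 3: model set; the planted region mixes the semantic model only
  items <- rdm_items(semantic_rdm)
  people <- binary_feature_rdm(
    setNames(rep(c(0, 1), length.out = cfg$n_items), items))
  planted_semantic <- normalize_rdm(squared_euclidean_rdm(
    truth$latent_coords, items = items))
  movement <- normalize_rdm(squared_euclidean_rdm(
    movement_truth$latent_coords, items = items))
  models <- model_set(semantic = planted_semantic, movement = movement,
                      people = people)

  # stage 4: toy brain + searchlight RSA
  surface <- make_toy_surface(cfg$mesh_subdivisions, n_regions = 1,
                              region_size = cfg$region_size,
                              seed = seeds$mesh)
  dataset <- plant_brain_patterns(surface, models,
                                  region_weights = list("1" = c(semantic = 1)),
                                  n_subjects = cfg$n_subjects,
                                  n_runs = cfg$n_runs,
                                  noise_sd = cfg$beta_noise_sd,
                                  seed = seeds$plant)
  searchlights <- build_searchlights(surface, cfg$searchlight_features)
  std_maps <- standard_rsa_map(dataset, models$models$semantic, searchlights)
  reg_maps <- regression_rsa_map(dataset, models, searchlights)

  # stage 5: group inference on the standard semantic map
  result <- cluster_permutation(std_maps, surface, n_perm = cfg$n_perm,
                                p0 = cfg$p0, seed = seeds$perm)

  # stage 6: characterization
  emb <- classical_mds(semantic_rdm, k = min(3, cfg$n_items - 1))
  clust <- silhouette_select_k(emb$coords, k_range = cfg$k_range,
                               seed = seeds$cluster)
  roi <- roi_geometry(dataset, result$t_map, models,
                      roi_size = cfg$searchlight_features)

  # artifacts
  write_rdm(semantic_rdm, file.path(cfg$out_dir, "semantic_group_rdm.tsv"))
  write_stat_map(std_maps, file.path(cfg$out_dir, "standard_rsa_maps.tsv"))
  write_stat_map(reg_maps, file.path(cfg$out_dir, "regression_rsa_maps.tsv"))
  write_cluster_table(result, file.path(cfg$out_dir, "clusters.tsv"))
  utils::write.table(tidy(clust), file.path(cfg$out_dir, "clustering.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  writeLines(dendrogram_newick(roi$dendrogram),
             file.path(cfg$out_dir, "roi_dendrogram.nwk"))
  manifest <- list(
    package_version = as.character(utils::packageVersion("actionrsa")),
    config = unclass(cfg), seeds = seeds,
    artifacts = list.files(cfg$out_dir))
  jsonlite::write_json(manifest, file.path(cfg$out_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)

  invisible(list(truth = truth, sessions = sessions,
                 subject_rdms = subject_rdms, semantic_rdm = semantic_rdm,
                 models = models, surface = surface, dataset = dataset,
                 searchlights = searchlights, standard_maps = std_maps,
                 regression_maps = reg_maps, group_result = result,
                 embedding = emb, clustering = clust, roi = roi,
                 out_dir = cfg$out_dir))
}

#' Validate pipeline input files against their format contracts
#'
#' Checks every path against the contract implied by its extension/name:
#' RDM TSVs must parse and satisfy the RDM invariants, events TSVs must
#' have the BIDS-style column set with numeric onsets, session JSONs must
#' reconstruct a valid arrangement session. Violations are collected, not
#' thrown.
#'
#' @param paths character vector of files
#' @return tibble with `file`, `ok`, `message`
#' @export
validate_inputs <- function(paths) {
  rows <- lapply(paths, function(p) {
    msg <- tryCatch({
      if (!file.exists(p)) stop("file not found")
      if (grepl("events\\.tsv$", p)) {
        ev <- utils::read.table(p, sep = "\t", header = TRUE,
                                na.strings = "n/a")
        need <- c("onset", "duration", "trial_type")
        miss <- setdiff(need, names(ev))
        if (length(miss)) stop("missing column(s): ",
                               paste(miss, collapse = ", "))
        if (!is.numeric(ev$onset) || anyNA(ev$onset))
          stop("non-numeric onset at line ",
               which(is.na(suppressWarnings(as.numeric(ev$onset))))[1] + 1)
        if (is.unsorted(ev$onset)) stop("onsets are not sorted")
      } else if (grepl("\\.json$", p)) {
        obj <- jsonlite::read_json(p)
        if (!is.null(obj$trials)) invisible(read_session_json(p))
      } else if (grepl("\\.tsv$", p)) {
        invisible(read_rdm(p))
      } else {
        stop("unknown file type")
      }
      NA_character_
    }, error = function(e) conditionMessage(e))
    tibble(file = p, ok = is.na(msg),
           message = ifelse(is.na(msg), "", msg))
  })
  dplyr::bind_rows(rows)
}
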