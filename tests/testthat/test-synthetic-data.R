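test_that("ground truth plants separated, near-balanced clusters", {
  gt <- make_ground_truth(n_items = 28, n_clusters = 6, seed = 1)
  expect_equal(gt$n_items, 28)
  expect_true(all(table(gt$cluster_labels) %in% 4:5))
  expect_equal(rdm_values(gt$true_rdm),
               rdm_values(normalize_rdm(euclidean_rdm(gt$latent_coords))),
               tolerance = 1e-12, ignore_attr = TRUE)

  # limit case: vanishing within-cluster spread gives near-zero
  # within-cluster distances and large between-cluster distances
  tight <- make_ground_truth(n_items = 24, n_clusters = 6,
                             within_spread = 1e-9, seed = 2)
  d <- rdm_values(tight$true_rdm)
  same <- outer(tight$cluster_labels, tight$cluster_labels, "==")
  expect_lt(max(d[same]), 1e-6)
  expect_gt(min(d[!same]), 0.01)

  expect_identical(make_ground_truth(seed = 9)$latent_coords,
                   make_ground_truth(seed = 9)$latent_coords)
  expect_error(make_ground_truth(n_items = 4, n_clusters = 6), "exceed")
})

test_that("icosphere meshes have the expected combinatorics", {
  for (s in 1:3) {
    surf <- make_toy_surface(s)
    expect_equal(nrow(surf$vertices), 10 * 4^s + 2)
    expect_equal(nrow(surf$faces), 20 * 4^s)
    expect_equal(euler_characteristic(surf), 2)
  }
  # all vertices on the unit sphere
  surf <- make_toy_surface(2)
  expect_equal(unname(sqrt(rowSums(surf$vertices^2))), rep(1, 162),
               tolerance = 1e-12)
})

test_that("painted regions are edge-connected and sized as requested", {
  surf <- make_toy_surface(2, n_regions = 3, region_size = 20, seed = 5)
  expect_equal(sort(unique(surf$region_map)), 0:3)
  for (rid in 1:3) {
    verts <- which(surf$region_map == rid)
    expect_length(verts, 20)
    # BFS within the region must reach every member
    seen <- verts[1]
    repeat {
      nxt <- setdiff(intersect(unique(unlist(surf$adjacency[seen])), verts),
                     seen)
      if (!length(nxt)) break
      seen <- c(seen, nxt)
    }
    expect_setequal(seen, verts)
  }
  expect_error(make_toy_surface(1, n_regions = 3, region_size = 20),
               "cannot place")
})

test_that("trial sequences satisfy every design constraint", {
  cfg <- design_config()
  ev <- generate_trial_sequence(cfg, seed = 1)

  per_run <- dplyr::count(ev, run, trial_type) |>
    tidyr::pivot_wider(names_from = "trial_type", values_from = "n")
  expect_true(all(per_run$exp == 56))
  expect_true(all(per_run$null == 18))
  expect_true(all(per_run$catch == 7))

  # runs 1-6: each action x exemplar combination exactly once
  first_half <- ev[ev$run <= 6 & ev$trial_type == "exp", ]
  expect_equal(nrow(first_half), 336)
  expect_equal(nrow(dplyr::distinct(first_half, action, exemplar)), 336)
  second_half <- ev[ev$run > 6 & ev$trial_type == "exp", ]
  expect_equal(nrow(dplyr::distinct(second_half, action, exemplar)), 336)

  # each action presented 24 times as experimental trial over the session
  expect_true(all(table(ev$action[ev$trial_type == "exp"]) == 24))

  # catch trials repeat the previous trial's action with another exemplar
  for (r in unique(ev$run)) {
    stim <- ev[ev$run == r & ev$trial_type != "null", ]
    idx <- which(stim$trial_type == "catch")
    expect_true(all(idx > 1))
    expect_equal(stim$action[idx], stim$action[idx - 1])
    expect_true(all(stim$exemplar[idx] != stim$exemplar[idx - 1]))
    # no consecutive repeats among experimental trials
    exp_only <- stim$action[stim$trial_type == "exp"]
    expect_true(all(exp_only[-1] != exp_only[-length(exp_only)]))
    # quasi-balance: the two exemplars of each action differ in actor
    # and scene within the run
    by_act <- split(stim[stim$trial_type == "exp", ],
                    stim$action[stim$trial_type == "exp"])
    for (ba in by_act) {
      expect_setequal(ba$actor, 1:2)
      expect_setequal(ba$scene, c("A", "B"))
    }
  }

  # catch actions sampled without replacement within each 4-run block
  catch <- ev[ev$trial_type == "catch", ]
  for (block in list(1:4, 5:8, 9:12)) {
    acts <- catch$action[catch$run %in% block]
    expect_equal(anyDuplicated(acts), 0)
    expect_length(acts, 28)
  }

  expect_identical(generate_trial_sequence(cfg, seed = 3),
                   generate_trial_sequence(cfg, seed = 3))
})

test_that("trial-sequence constraints hold across many seeds", {
  cfg <- design_config()
  for (s in c(2, 17, 401)) {
    ev <- generate_trial_sequence(cfg, seed = s)
    expect_equal(sum(ev$trial_type == "exp"), 672)
    stim <- ev[ev$trial_type != "null", ]
    for (r in unique(stim$run)) {
      a <- stim[stim$run == r, ]
      idx <- which(a$trial_type == "catch")
      expect_equal(a$action[idx], a$action[idx - 1])
    }
  }
})

test_that("events TSV export is BIDS-shaped and validates", {
  ev <- generate_trial_sequence(design_config(), seed = 2)
  dir <- withr::local_tempdir()
  paths <- write_events_tsv(ev, dir)
  expect_length(paths, 12)
  rep <- validate_inputs(paths)
  expect_true(all(rep$ok))
})

test_that("simulated time series round-trip through the GLM", {
  cfg <- design_config(n_runs = 4, n_actions = 6, n_exemplars = 4,
                      n_null_per_run = 4, n_catch_per_run = 2,
                      volumes_per_run = 45)
  ev <- generate_trial_sequence(cfg, seed = 4)
  labels <- sprintf("action%02d", 1:6)
  set.seed(1)
  betas <- lapply(1:4, function(r) {
    b <- matrix(rnorm(6 * 5), 6, 5)
    rownames(b) <- labels
    b
  })
  ts <- simulate_timeseries(betas, ev, cfg, noise_sd = 0, seed = 1)

  for (r in 1:2) {
    est <- glm_betas(ts[[r]], ev[ev$run == r, ], cfg,
                     condition_labels = labels)
    expect_equal(est, betas[[r]], tolerance = 1e-8)
  }

  # zero betas, zero noise: flat series
  zb <- lapply(betas, function(b) b * 0)
  flat <- simulate_timeseries(zb, ev, cfg, noise_sd = 0, seed = 1)
  expect_equal(max(abs(flat[[1]])), 0)

  # linearity: doubling betas doubles the noiseless series
  db <- lapply(betas, function(b) b * 2)
  ts2 <- simulate_timeseries(db, ev, cfg, noise_sd = 0, seed = 1)
  expect_equal(ts2[[1]][, ], 2 * ts[[1]][, ], tolerance = 1e-12)
})

test_that("synthetic image families are deterministic and jitter-controlled", {
  imgs0 <- make_synthetic_images(n_actions = 3, n_exemplars = 3,
                                 jitter = 0, seed = 2)
  expect_equal(imgs0[[1]][[1]], imgs0[[1]][[2]])
  expect_false(isTRUE(all.equal(imgs0[[1]][[1]], imgs0[[2]][[1]])))

  again <- make_synthetic_images(n_actions = 3, n_exemplars = 3,
                                 jitter = 0, seed = 2)
  expect_identical(imgs0, again)

  jit <- make_synthetic_images(n_actions = 2, n_exemplars = 2,
                               jitter = 0.05, seed = 3)
  expect_false(isTRUE(all.equal(jit[[1]][[1]], jit[[1]][[2]])))
  expect_error(make_synthetic_images(size = c(32, 32)), "64")
})

test_that("luminance equalization hits the target mean", {
  const <- matrix(100, 70, 70)
  out <- normalize_luminance(list(const), target_mean = 115.8)
  expect_equal(mean(out$images[[1]]), 115.8, tolerance = 0.5)
  expect_equal(out$images[[1]][1, 1], 115.8, tolerance = 0.5)

  # already at target: unchanged
  at <- matrix(115.8, 70, 70)
  expect_equal(normalize_luminance(list(at))$images[[1]], at)

  # a stack of random images ends with across-image sd of means below 0.5
  set.seed(6)
  stack <- lapply(1:12, function(i)
    pmin(pmax(matrix(rnorm(70 * 70, mean = runif(1, 60, 180), sd = 30),
                     70, 70), 0), 255))
  res <- normalize_luminance(stack)
  expect_lt(sd(res$report$mean), 0.5)

  # unattainable target warns and reports
  dark <- matrix(c(0, 255), 64, 64)
  expect_warning(normalize_luminance(list(dark), target_mean = 300),
                 "unattainable")
})

test_that("planted brain patterns realize exact model-RDM mixtures", {
  surf <- make_toy_surface(2, n_regions = 1, region_size = 30, seed = 3)
  a <- random_sq_rdm(10, seed = 1)
  b <- random_sq_rdm(10, seed = 2)
  models <- model_set(a = a, b = b)
  ds <- plant_brain_patterns(surf, models,
                             region_weights = list("1" = c(a = 2, b = 3)),
                             n_subjects = 1, n_runs = 1, noise_sd = 0,
                             seed = 4)
  verts <- which(surf$region_map == 1)
  nr <- neural_rdm(ds$betas[[1]], verts, mode = "standard",
                   normalize = "none")
  expect_equal(rdm_values(nr), 2 * rdm_values(a) + 3 * rdm_values(b),
               tolerance = 1e-10, ignore_attr = TRUE)

  # single model, unit weight: correlation 1 after normalization
  ds1 <- plant_brain_patterns(surf, model_set(a = a),
                              region_weights = list("1" = c(a = 1)),
                              n_subjects = 1, n_runs = 2, noise_sd = 0,
                              seed = 5)
  nr1 <- neural_rdm(ds1$betas[[1]], verts, mode = "standard")
  expect_equal(rdm_correlation(nr1, a), 1, tolerance = 1e-10)

  # region too small to host the blocks errors out
  tiny <- make_toy_surface(1, n_regions = 1, region_size = 3, seed = 1)
  big <- random_sq_rdm(12, dim = 6, seed = 3)
  expect_error(
    plant_brain_patterns(tiny, model_set(m = big),
                         region_weights = list("1" = c(m = 1)),
                         n_subjects = 1, noise_sd = 0),
    "vertices but needs")
})
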