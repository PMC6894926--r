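test_that("searchlight construction matches a geodesic-ring oracle", {
  surf <- make_toy_surface(1)   # 42 vertices
  sl <- build_searchlights(surf, 7)
  expect_true(all(sl$n_members == 7))
  expect_true(all(vapply(seq_len(nrow(sl)), function(i)
    sl$center[i] %in% sl$members[[i]], logical(1))))

  # oracle: grow hop rings by brute force; members must consist of all
  # complete rings plus a subset of the first partial ring
  for (center in c(1, 10, 37)) {
    members <- sl$members[[center]]
    ring <- center; seen <- center; hops <- list(center)
    while (length(seen) < 42) {
      nxt <- setdiff(unique(unlist(surf$adjacency[ring])), seen)
      hops[[length(hops) + 1]] <- sort(nxt)
      seen <- c(seen, nxt); ring <- nxt
    }
    acc <- c()
    for (h in hops) {
      if (length(acc) + length(h) <= 7) {
        acc <- c(acc, h)
      } else {
        partial <- setdiff(members, acc)
        expect_true(all(partial %in% h))
        break
      }
    }
    expect_true(all(acc %in% members))
  }

  # single-feature searchlights are their own centers
  solo <- build_searchlights(surf, 1)
  expect_equal(unlist(solo$members), solo$center)
})

test_that("every searchlight on a subdivision-3 icosphere has 100 members", {
  surf <- make_toy_surface(3)
  sl <- build_searchlights(surf, 100)
  expect_equal(nrow(sl), 642)
  expect_true(all(sl$n_members == 100))
  expect_true(all(sl$complete))
})

test_that("neural RDMs honor the mode-specific normalizations", {
  surf <- make_toy_surface(1, n_regions = 1, region_size = 12, seed = 2)
  a <- random_sq_rdm(8, seed = 3)
  ds <- plant_brain_patterns(surf, model_set(a = a),
                             region_weights = list("1" = c(a = 1)),
                             n_subjects = 1, n_runs = 2, noise_sd = 0,
                             seed = 1)
  verts <- which(surf$region_map == 1)

  std <- neural_rdm(ds$betas[[1]], verts, "standard")
  expect_equal(max(rdm_values(std)), 1)
  expect_equal(rdm_correlation(std, a), 1, tolerance = 1e-9)

  # identical patterns across conditions: degenerate, flagged
  flat <- ds$betas[[1]]
  for (k in seq_len(dim(flat)[2])) flat[, k, ] <- flat[, 1, ]
  deg <- neural_rdm(flat, verts, "standard")
  expect_true(isTRUE(deg$meta$degenerate))

  # permutation equivariance: permuting conditions permutes the RDM
  perm <- c(3, 1, 2, 8, 5, 4, 7, 6)
  permuted <- ds$betas[[1]][, perm, , drop = FALSE]
  rp <- neural_rdm(permuted, verts, "standard")
  expect_equal(rdm_values(rp), rdm_values(std)[perm, perm],
               tolerance = 1e-12, ignore_attr = TRUE)

  # regression mode z-scores: each condition pattern has unit variance
  reg <- neural_rdm(ds$betas[[1]], verts, "regression", normalize = "none")
  expect_s3_class(reg, "rdm")
})

test_that("standard RSA maps equal looped RDM correlations", {
  surf <- make_toy_surface(1, n_regions = 1, region_size = 10, seed = 4)
  a <- random_sq_rdm(8, seed = 5)
  ds <- plant_brain_patterns(surf, model_set(a = a),
                             region_weights = list("1" = c(a = 1)),
                             n_subjects = 2, n_runs = 2, noise_sd = 0.3,
                             seed = 6)
  sl <- build_searchlights(surf, 6)
  maps <- standard_rsa_map(ds, a, sl)
  expect_equal(nrow(maps), 2 * 42)

  for (v in c(2, 20)) {
    nr <- neural_rdm(ds$betas[[1]], sl$members[[v]], "standard")
    expect_equal(maps$value[maps$subject == "sub01" & maps$vertex == v],
                 rdm_correlation(nr, normalize_rdm(a)), tolerance = 1e-12)
  }

  # noiseless planted geometry: exactly 1 over the full region (the
  # mixture is exact there); sub-searchlights inside the region see a
  # rotated partial projection and stay close to 1
  ds0 <- plant_brain_patterns(surf, model_set(a = a),
                              region_weights = list("1" = c(a = 1)),
                              n_subjects = 1, n_runs = 1, noise_sd = 0,
                              seed = 7)
  region <- which(surf$region_map == 1)
  m_roi <- standard_rsa_map(ds0, a, roi_searchlight(region))
  expect_equal(m_roi$value, 1, tolerance = 1e-9)
  m0 <- standard_rsa_map(ds0, a, sl)
  inner <- region[vapply(region, function(v)
    all(sl$members[[v]] %in% region), logical(1))]
  expect_true(all(m0$value[m0$vertex %in% inner] > 0.9))

  # pure-noise data: map mean near 0 once averaged over subjects (a
  # single subject map is one correlated noise draw and can sit far off)
  noise_ds <- plant_brain_patterns(surf, model_set(a = a),
                                   region_weights = list(),
                                   n_subjects = 10, n_runs = 2,
                                   noise_sd = 1, seed = 8)
  mn <- standard_rsa_map(noise_ds, a, build_searchlights(surf, 20))
  expect_lt(abs(mean(mn$value)), 0.1)
})

test_that("regression RSA recovers planted mixture weights", {
  surf <- make_toy_surface(1, n_regions = 1, region_size = 14, seed = 9)
  a <- random_sq_rdm(10, seed = 11)
  b <- random_sq_rdm(10, seed = 12)
  ds <- plant_brain_patterns(surf, model_set(a = a, b = b),
                             region_weights = list("1" = c(a = 2, b = 3)),
                             n_subjects = 1, n_runs = 1, noise_sd = 0,
                             seed = 13)
  verts <- which(surf$region_map == 1)
  sl <- roi_searchlight(verts)
  center <- sl$center
  maps <- regression_rsa_map(ds, model_set(a = a, b = b), sl,
                             normalize_images = FALSE,
                             normalize_features = FALSE,
                             normalize = "none")
  ca <- maps$beta[maps$vertex == center & maps$model == "a"]
  cb <- maps$beta[maps$vertex == center & maps$model == "b"]
  expect_equal(c(ca, cb), c(2, 3), tolerance = 1e-6)

  # adding an orthogonal irrelevant model leaves coefficients unchanged
  set.seed(14)
  x <- cbind(rdm_vectorize(a)$value, rdm_vectorize(b)$value, 1)
  raw <- rnorm(45)
  resid <- raw - x %*% qr.coef(qr(x), raw)
  extra <- rdm_devectorize(as.vector(resid - min(resid) + 0.05),
                           rdm_items(a))
  maps3 <- regression_rsa_map(ds, model_set(a = a, b = b, extra = extra),
                              sl, normalize_images = FALSE,
                              normalize_features = FALSE,
                              normalize = "none")
  ca3 <- maps3$beta[maps3$vertex == center & maps3$model == "a"]
  # same up to the rescaling that max-normalization of `extra` cannot touch
  expect_equal(ca3, ca, tolerance = 1e-6)

  # a perfectly collinear model set is rejected up front
  expect_error(
    regression_rsa_map(ds, model_set(a = a, acopy = a), sl),
    "collinear")
})

test_that("standard and regression RSA agree for a single noiseless model", {
  surf <- make_toy_surface(1, n_regions = 1, region_size = 12, seed = 15)
  a <- random_sq_rdm(8, seed = 16)
  ds <- plant_brain_patterns(surf, model_set(a = a),
                             region_weights = list("1" = c(a = 1)),
                             n_subjects = 1, n_runs = 1, noise_sd = 0,
                             seed = 17)
  verts <- which(surf$region_map == 1)
  sl <- roi_searchlight(verts)
  std <- standard_rsa_map(ds, a, sl)
  reg <- regression_rsa_map(ds, model_set(a = a), sl,
                            normalize_images = FALSE,
                            normalize_features = FALSE)
  expect_true(all(std$value > 0.999))
  expect_equal(reg$beta, 1, tolerance = 1e-6)
})
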