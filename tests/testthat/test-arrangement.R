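test_that("trial distances are scaled by the trial maximum", {
  two <- list(items = c("a", "b"), coords = rbind(c(0, 0), c(100, 0)))
  expect_equal(rdm_values(trial_distances(two))["a", "b"], 1)

  tri <- list(items = c("a", "b", "c"),
              coords = rbind(c(0, 0), c(1, 0), c(0.5, sqrt(3) / 2)))
  expect_equal(rdm_vectorize(trial_distances(tri))$value, rep(1, 3),
               tolerance = 1e-12)

  set.seed(2)
  coords <- matrix(runif(12), 6, 2)
  td <- trial_distances(list(items = letters[1:6], coords = coords))
  brute <- sqrt(brute_sq_euclid(coords))
  expect_equal(rdm_values(td), brute / max(brute), tolerance = 1e-12,
               ignore_attr = TRUE)

  expect_error(trial_distances(list(items = "a",
                                    coords = matrix(0, 1, 2))), "2 items")
})

test_that("session aggregation averages co-occurring pairs and normalizes", {
  items <- letters[1:5]
  ar <- arena(radius = 10)
  set.seed(3)
  coords <- matrix(rnorm(10), 5, 2)
  t1 <- list(items = items, coords = coords)
  sess1 <- arrangement_session("s1", "semantic", list(t1), ar, items)
  agg1 <- aggregate_session(sess1)
  expect_equal(rdm_values(agg1), rdm_values(normalize_rdm(
    trial_distances(t1))), tolerance = 1e-12, ignore_attr = TRUE)

  # duplicated identical trial changes nothing (averaging idempotence)
  sess2 <- arrangement_session("s1", "semantic", list(t1, t1), ar, items)
  expect_equal(rdm_values(aggregate_session(sess2)), rdm_values(agg1),
               tolerance = 1e-12)

  # global rescaling of all coordinates leaves the aggregate unchanged
  t_scaled <- list(items = items, coords = coords * 0.35)
  sess3 <- arrangement_session("s1", "semantic", list(t_scaled), ar, items)
  expect_equal(rdm_values(aggregate_session(sess3)), rdm_values(agg1),
               tolerance = 1e-12)

  expect_error(
    arrangement_session("s1", "semantic",
                        list(list(items = items[1:3],
                                  coords = coords[1:3, ])), ar, items),
    "trial 1")
})

test_that("adaptive subset selection lifts the weakest pairs", {
  n <- 8
  ev <- matrix(1, n, n); diag(ev) <- 0
  # uniform evidence: deterministic tie-break gives the first items
  sub <- select_next_subset(ev, min_items = 3, max_items = 3)
  expect_equal(sub, 1:3)

  # a zero-evidence pair is always included
  ev2 <- ev; ev2[4, 7] <- ev2[7, 4] <- 0
  expect_true(all(c(4, 7) %in% select_next_subset(ev2, max_items = 4)))

  # over a simulated session, the minimum pair evidence grows
  truth <- random_rdm(12, seed = 5)
  sess <- simulate_arranger(truth, noise_sd = 0, n_trials = 9, seed = 2)
  n_items <- length(truth$items)
  evid <- matrix(0, n_items, n_items)
  mins <- numeric(length(sess$trials))
  for (t in seq_along(sess$trials)) {
    idx <- match(sess$trials[[t]]$items, truth$items)
    evid[idx, idx] <- evid[idx, idx] + n_items / length(idx)
    diag(evid) <- 0
    mins[t] <- min(evid[upper.tri(evid)])
  }
  expect_true(all(diff(mins) >= 0))
  expect_gt(mins[length(mins)], mins[1])
})

test_that("simulated arrangers recover 2-D structure at zero noise", {
  set.seed(9)
  pts <- matrix(rnorm(28 * 2), 28, 2)
  truth <- normalize_rdm(euclidean_rdm(pts,
                                       items = sprintf("a%02d", 1:28)))
  sess <- simulate_arranger(truth, noise_sd = 0, n_trials = 6, seed = 3)
  # default per-trial-max scaling carries a small subset-scale bias
  agg <- aggregate_session(sess)
  expect_gte(rdm_correlation(agg, truth), 0.95)
  # the iterative rescaling mode removes it
  agg_it <- aggregate_session(sess, method = "iterative_rescale")
  expect_gte(rdm_correlation(agg_it, truth), 0.99)

  expect_identical(
    simulate_arranger(truth, noise_sd = 0.2, n_trials = 4, seed = 7)$trials,
    simulate_arranger(truth, noise_sd = 0.2, n_trials = 4, seed = 7)$trials)
})

test_that("recovery degrades monotonically with arranger noise", {
  set.seed(12)
  pts <- matrix(rnorm(20 * 2), 20, 2)
  truth <- normalize_rdm(euclidean_rdm(pts, items = sprintf("a%02d", 1:20)))
  grid <- c(0, 0.2, 0.8, 3)
  rec <- vapply(grid, function(ns) {
    mean(vapply(1:6, function(s) {
      agg <- aggregate_session(
        simulate_arranger(truth, noise_sd = ns, n_trials = 5,
                          seed = 50 + s))
      rdm_correlation(agg, truth)
    }, numeric(1)))
  }, numeric(1))
  # allow small Monte-Carlo wiggle but require the overall decreasing trend
  expect_true(all(diff(rec) < 0.05))
  expect_gt(rec[1] - rec[length(rec)], 0.3)
})

test_that("leave-one-subject-out reliability behaves at the extremes", {
  base <- random_rdm(10, seed = 21)
  cohort <- lapply(1:5, function(i) base)
  res <- loso_reliability(cohort, n_perm = 200, seed = 1)
  expect_equal(res$per_subject$r, rep(1, 5), tolerance = 1e-12)
  expect_equal(res$mean_r, 1)

  # independent random cohorts: mean r near 0, few FDR rejections
  null_cohort <- lapply(1:8, function(i) random_rdm(10, seed = 100 + i))
  nres <- loso_reliability(null_cohort, n_perm = 200, seed = 2)
  expect_lt(abs(nres$mean_r), 0.25)
  expect_lt(mean(nres$per_subject$p_adj <= 0.05), 0.3)

  expect_error(loso_reliability(cohort[1:2]), "3 subjects")
})

test_that("cosine agreement matches a brute-force pairwise loop", {
  cohort <- lapply(1:4, function(i) random_rdm(7, seed = 30 + i))
  res <- cosine_agreement(cohort)
  items <- rdm_items(cohort[[1]])
  for (i in c(1, 4, 7)) {
    vals <- c()
    for (s1 in 1:3) {
      for (s2 in (s1 + 1):4) {
        a <- rdm_values(cohort[[s1]])[i, -i]
        b <- rdm_values(cohort[[s2]])[i, -i]
        vals <- c(vals, 1 - sum(a * b) / sqrt(sum(a^2) * sum(b^2)))
      }
    }
    expect_equal(res$mean_cosine_distance[i], mean(vals), tolerance = 1e-12)
  }

  # identical cohorts agree perfectly; sign-orthogonal rows disagree fully
  same <- cosine_agreement(list(cohort[[1]], cohort[[1]]))
  expect_equal(same$mean_cosine_distance, rep(0, 7), tolerance = 1e-12)
})

test_that("consistency filtering keeps items within one sd in every table", {
  items <- sprintf("a%02d", 1:10)
  flat <- tibble::tibble(item = items, mean_cosine_distance = rep(0.2, 10))
  keep_all <- select_consistent_items(list(t1 = flat, t2 = flat))
  expect_true(all(keep_all$keep))

  spiky <- flat
  spiky$mean_cosine_distance[4] <- 0.9
  res <- select_consistent_items(list(t1 = flat, t2 = spiky))
  expect_false(res$keep[4])
  expect_true(all(res$keep[-4]))
})

test_that("arrangement sessions round-trip through JSON", {
  truth <- random_rdm(8, seed = 41)
  sess <- simulate_arranger(truth, noise_sd = 0.1, n_trials = 4, seed = 5)
  path <- withr::local_tempfile(fileext = ".json")
  write_session_json(sess, path)
  back <- read_session_json(path)
  expect_identical(back$items, sess$items)
  expect_equal(length(back$trials), length(sess$trials))
  expect_equal(back$trials[[2]]$coords, unname(sess$trials[[2]]$coords),
               tolerance = 1e-12, ignore_attr = TRUE)
})
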