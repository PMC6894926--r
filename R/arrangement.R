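#' Multi-arrangement sessions
#'
#' In the multi-arrangement (inverse MDS) task, participants drag item
#' images inside a circular arena so that on-screen distance expresses
#' dissimilarity. Trial 1 shows every item; each later trial shows an
#' adaptively chosen subset (>= 3 items). An `arrangement_session` stores
#' the ordered trials (item subset + 2D coordinates) together with the
#' arena geometry.
#'
#' @param radius arena radius in screen units
#' @param center arena center, length-2
#' @return `arena()`: an `arena` list
#' @export
arena <- function(radius = 1, center = c(0, 0)) {
  stop_if(radius <= 0, "arena radius must be positive")
  structure(list(radius = radius, center = center), class = "arena")
}

#' @rdname arena
#' @param subject subject identifier
#' @param task task label (e.g. `semantic`, `body`, `scene`, `movement`,
#'   `object`)
#' @param trials list of trials, each a list with `items` (character) and
#'   `coords` (items x 2 matrix)
#' @param arena_obj an [arena()]
#' @param items the full item list; trial 1 must contain exactly these
#' @export
arrangement_session <- function(subject, task, trials, arena_obj, items) {
  stop_if(length(trials) < 1, "a session needs at least one trial")
  t1 <- trials[[1]]
  stop_if(!setequal(t1$items, items),
          "trial 1 must contain every item exactly once")
  for (i in seq_along(trials)) {
    tr <- trials[[i]]
    stop_if(!all(tr$items %in% items),
            "trial %d contains unknown items", i)
    stop_if(i > 1 && length(tr$items) < 3,
            "adaptive trial %d has fewer than 3 items", i)
    stop_if(nrow(tr$coords) != length(tr$items),
            "trial %d: coords/items mismatch", i)
    d <- sqrt(colSums((t(tr$coords) - arena_obj$center)^2))
    stop_if(any(d > arena_obj$radius * (1 + 1e-6)),
            "trial %d: items placed outside the arena", i)
  }
  structure(list(subject = subject, task = task, trials = trials,
                 arena = arena_obj, items = items),
            class = "arrangement_session")
}

#' @export
print.arrangement_session <- function(x, ...) {
  cat(sprintf("<arrangement_session> subject %s, task %s: %d trials, %d items\n",
              x$subject, x$task, length(x$trials), length(x$items)))
  invisible(x)
}

#' Scaled on-screen distances for one arrangement trial
#'
#' Euclidean screen distances between the trial's items, divided by the
#' trial's maximum pair distance. The per-trial scaling removes the
#' arbitrary screen area a subset occupies before distances are averaged
#' across trials. Coincident (stacked) items are allowed and yield 0.
#'
#' @param trial a list with `items` and `coords`
#' @return a partial `rdm` over the trial's items
#' @export
trial_distances <- function(trial) {
  stop_if(length(trial$items) < 2, "a trial needs at least 2 items")
  d <- euclidean_rdm(trial$coords, items = trial$items)
  mx <- max(rdm_values(d))
  stop_if(mx <= 0, "all items stacked on one point: distances undefined")
  rdm(rdm_values(d) / mx, items = trial$items,
      meta = list(scaled = "per_trial_max"))
}

#' Aggregate an arrangement session into a subject RDM
#'
#' With `method = "per_trial_max"` (default), each trial's distances are
#' scaled by that trial's maximum and the per-pair mean over co-occurring
#' trials is taken. Because small subsets are drawn with a scale of their
#' own, this mixes slightly different scales across pairs; it is simple,
#' robust, and adequate for noisy observers. `method =
#' "iterative_rescale"` removes that bias: starting from the per-trial-max
#' estimate, each trial is rescaled by the least-squares factor aligning it
#' with the current estimate and the estimate is re-averaged until
#' convergence, in the spirit of iterative evidence-weighted dissimilarity
#' estimation; with a noiseless 2-D arranger it reproduces the true RDM
#' essentially exactly. The result is max-normalized either way. Because
#' trial 1 contains every item, every pair co-occurs at least once; a
#' missing pair therefore signals corrupt input and is an error.
#' `meta$pair_counts` records how many trials informed each pair.
#'
#' @param session an [arrangement_session()]
#' @param method `"per_trial_max"` or `"iterative_rescale"`
#' @param max_iter iterations for the rescaling mode
#' @return an `rdm` over the session's items
#' @export
aggregate_session <- function(session,
                              method = c("per_trial_max",
                                         "iterative_rescale"),
                              max_iter = 20) {
  method <- match.arg(method)
  items <- session$items
  n <- length(items)
  trials <- lapply(session$trials, function(tr) {
    td <- trial_distances(tr)
    list(idx = match(td$items, items), d = rdm_values(td))
  })
  average <- function(trs) {
    sums <- matrix(0, n, n); counts <- matrix(0L, n, n)
    for (tr in trs) {
      sums[tr$idx, tr$idx] <- sums[tr$idx, tr$idx] + tr$d
      counts[tr$idx, tr$idx] <- counts[tr$idx, tr$idx] + 1L
    }
    diag(counts) <- 1L
    list(mean = sums / pmax(counts, 1L), counts = counts)
  }
  first <- average(trials)
  miss <- first$counts == 0
  stop_if(any(miss),
          "pair(s) never co-placed (corrupt session): %s",
          paste(utils::head(apply(which(miss, arr.ind = TRUE), 1, function(r)
            paste(items[r], collapse = "/")), 5), collapse = ", "))
  est <- first$mean
  if (method == "iterative_rescale") {
    for (it in seq_len(max_iter)) {
      rescaled <- lapply(trials, function(tr) {
        ref <- est[tr$idx, tr$idx]
        s <- sum(tr$d * ref) / max(sum(tr$d^2), .Machine$double.eps)
        list(idx = tr$idx, d = tr$d * s)
      })
      new_est <- average(rescaled)$mean
      mx <- max(new_est)
      if (mx > 0) new_est <- new_est / mx
      if (max(abs(new_est - est / max(est))) < 1e-10) {
        est <- new_est
        break
      }
      est <- new_est
    }
  }
  mean_rdm <- rdm(est, items = items,
                  meta = list(subject = session$subject, task = session$task,
                              aggregation = method))
  out <- normalize_rdm(mean_rdm)
  out$meta$pair_counts <- first$counts
  out
}

#' Pick the next adaptive item subset ("lift the weakest" rule)
#'
#' Seeds the subset with the pair of lowest accumulated evidence, then
#' greedily adds the item whose pairs with the current subset cover the
#' largest evidence deficit (evidence short of the current maximum), until
#' `max_items` is reached or the marginal gain drops to `gain_threshold`.
#' All ties break by item order, so the rule is deterministic.
#'
#' @param evidence symmetric non-negative matrix of per-pair evidence
#' @param min_items minimum subset size (>= 3)
#' @param max_items maximum subset size
#' @param gain_threshold stop growing when the best marginal gain is <= this
#' @return integer vector of item indices
#' @export
select_next_subset <- function(evidence, min_items = 3,
                               max_items = nrow(evidence),
                               gain_threshold = 0) {
  stop_if(min_items < 3, "min_items must be >= 3")
  n <- nrow(evidence)
  stop_if(max_items < min_items || max_items > n,
          "max_items must be in [min_items, n]")
  e <- evidence
  diag(e) <- Inf
  # weakest pair, ties by row-major upper-triangle order
  ut <- which(upper.tri(e), arr.ind = TRUE)
  ut <- ut[order(ut[, 1], ut[, 2]), , drop = FALSE]
  vals <- e[ut]
  best <- ut[which.min(vals), ]
  subset <- sort(as.integer(best))
  emax <- max(evidence[upper.tri(evidence)])
  while (length(subset) < max_items) {
    cand <- setdiff(seq_len(n), subset)
    gain <- vapply(cand, function(cc)
      sum(pmax(0, emax - evidence[cc, subset])), numeric(1))
    pick <- cand[which.max(gain)]
    if (length(subset) >= min_items && max(gain) <= gain_threshold) break
    subset <- sort(c(subset, pick))
  }
  subset
}

# Evidence contributed by one trial: each co-occurring pair gains
# n_total / n_subset, so smaller subsets (larger, better-resolved on-screen
# distances) contribute more evidence per pair.
evidence_increment <- function(n_total, n_subset) n_total / n_subset

#' Simulate a multi-arrangement participant
#'
#' Each trial, the simulated subject "arranges" the shown items by placing
#' them at a 2D metric-MDS embedding of the noise-perturbed true
#' sub-dissimilarity matrix, rescaled to fill the arena. Trial 1 shows all
#' items; later trials use [select_next_subset()] on the accumulated
#' evidence. With zero noise and a 2D latent structure the session's
#' aggregate recovers the true RDM up to scale.
#'
#' @param true_rdm the subject's latent dissimilarity structure
#' @param noise_sd sd of Gaussian noise added to each dissimilarity before
#'   embedding (on the normalized RDM scale). The default 0.45 is calibrated
#'   so that a simulated 28-item cohort reproduces the inter-observer
#'   reliability typical of multi-arrangement semantic judgments (mean
#'   leave-one-subject-out r around 0.6)
#' @param arena_obj an [arena()]
#' @param n_trials total number of trials (including trial 1)
#' @param subject,task labels stored in the session
#' @param min_items,max_items subset-size bounds for the adaptive rule
#' @param seed RNG seed
#' @return an [arrangement_session()]
#' @export
simulate_arranger <- function(true_rdm, noise_sd = 0.45, arena_obj = arena(),
                              n_trials = 8, subject = "sim01",
                              task = "semantic", min_items = 3,
                              max_items = NULL, seed = 1) {
  stopifnot(inherits(true_rdm, "rdm"))
  items <- rdm_items(true_rdm)
  n <- length(items)
  max_items <- max_items %||% max(min_items, ceiling(n / 2))
  with_seed(seed, {
    evidence <- matrix(0, n, n)
    trials <- vector("list", n_trials)
    for (t in seq_len(n_trials)) {
      idx <- if (t == 1) seq_len(n) else
        select_next_subset(evidence, min_items, max_items)
      sub <- rdm_values(true_rdm)[idx, idx, drop = FALSE]
      if (noise_sd > 0) {
        pert <- matrix(0, length(idx), length(idx))
        pert[upper.tri(pert)] <- rnorm(sum(upper.tri(pert)), sd = noise_sd)
        sub <- pmax(sub + pert + t(pert), 0)
        diag(sub) <- 0
      }
      coords <- embed_in_arena(sub, arena_obj)
      trials[[t]] <- list(items = items[idx], coords = coords)
      evidence[idx, idx] <- evidence[idx, idx] +
        evidence_increment(n, length(idx))
      diag(evidence) <- 0
    }
    arrangement_session(subject, task, trials, arena_obj, items)
  })
}

# 2D metric MDS of a dissimilarity matrix, rescaled to fill the arena.
embed_in_arena <- function(d, arena_obj) {
  n <- nrow(d)
  xy <- suppressWarnings(stats::cmdscale(stats::as.dist(d), k = 2))
  if (ncol(xy) < 2) xy <- cbind(xy, 0)
  if (any(!is.finite(xy))) xy[!is.finite(xy)] <- 0
  xy <- sweep(xy, 2, colMeans(xy))
  r <- sqrt(rowSums(xy^2))
  if (max(r) > 0) xy <- xy / max(r) * arena_obj$radius * 0.95
  sweep(xy, 2, arena_obj$center, "+")
}

#' Leave-one-subject-out reliability of a cohort of RDMs
#'
#' Each subject's RDM is Pearson-correlated with the mean RDM of all other
#' subjects. One-sided p-values come from a permutation null in which the
#' subject's item labels are shuffled (respecting the RDM structure) and
#' the correlation recomputed; permutation is used because RDM entries are
#' not independent. P-values are Benjamini-Hochberg adjusted across
#' subjects.
#'
#' @param subject_rdms named list of `rdm` objects over identical items
#' @param n_perm number of item-label permutations per subject
#' @param seed RNG seed for the permutations
#' @return list with `per_subject` (tibble: subject, r, p, p_adj) and
#'   `mean_r`
#' @export
loso_reliability <- function(subject_rdms, n_perm = 10000, seed = 1) {
  stop_if(length(subject_rdms) < 3, "need at least 3 subjects")
  items <- rdm_items(subject_rdms[[1]])
  for (s in subject_rdms)
    stop_if(!identical(rdm_items(s), items),
            "subjects have mismatching item sets")
  n_sub <- length(subject_rdms)
  mats <- lapply(subject_rdms, rdm_values)
  vecs <- vapply(mats, ut_vec, numeric(length(ut_vec(mats[[1]]))))
  subj_names <- names(subject_rdms) %||% sprintf("sub%02d", seq_len(n_sub))

  with_seed(seed, {
    rows <- lapply(seq_len(n_sub), function(s) {
      others <- rowMeans(vecs[, -s, drop = FALSE])
      obs <- cor(vecs[, s], others)
      null <- vapply(seq_len(n_perm), function(p) {
        perm <- sample(length(items))
        cor(ut_vec(mats[[s]][perm, perm]), others)
      }, numeric(1))
      tibble(subject = subj_names[s], r = obs,
             p = (1 + sum(null >= obs)) / (1 + n_perm))
    })
    tab <- dplyr::bind_rows(rows)
    tab$p_adj <- stats::p.adjust(tab$p, method = "BH")
    list(per_subject = tab, mean_r = mean(tab$r))
  })
}

#' Per-item inter-observer agreement (cosine distance)
#'
#' For each item, its RDM row (dissimilarities to every other item) is
#' compared between every pair of subjects via the cosine distance
#' `1 - cos(angle)`; the per-item score is the mean over all subject pairs.
#' 0 means all subjects agree on the item's geometry; 1 means orthogonal
#' profiles.
#'
#' @param subject_rdms list of `rdm` objects over identical items
#' @return tibble with `item`, `mean_cosine_distance`
#' @export
cosine_agreement <- function(subject_rdms) {
  stop_if(length(subject_rdms) < 2, "need at least 2 subjects")
  items <- rdm_items(subject_rdms[[1]])
  n <- length(items)
  mats <- lapply(subject_rdms, rdm_values)
  scores <- vapply(seq_len(n), function(i) {
    rows <- lapply(mats, function(m) m[i, -i])
    for (r in rows) stop_if(all(r == 0),
                            "item %s has a zero dissimilarity row", items[i])
    pairs <- utils::combn(length(rows), 2)
    mean(apply(pairs, 2, function(pr) {
      a <- rows[[pr[1]]]; b <- rows[[pr[2]]]
      1 - sum(a * b) / (sqrt(sum(a^2)) * sqrt(sum(b^2)))
    }))
  }, numeric(1))
  tibble(item = items, mean_cosine_distance = scores)
}

#' Keep items that are consistently arranged across tasks and stimulus sets
#'
#' An item is kept if, in every agreement table, its score is within
#' `sd_rule` standard deviations above that table's mean. Used to filter a
#' candidate item set down to those arranged consistently across observers.
#'
#' @param agreement_tables named list of tibbles from [cosine_agreement()]
#'   (one per task x stimulus set), all covering the same items
#' @param sd_rule the SD multiplier of the keep threshold
#' @return tibble with `item`, `keep`, `worst_margin` (most negative slack
#'   across tables; negative = over threshold somewhere)
#' @export
select_consistent_items <- function(agreement_tables, sd_rule = 1) {
  stop_if(length(agreement_tables) < 1, "need at least one table")
  items <- agreement_tables[[1]]$item
  margins <- vapply(agreement_tables, function(tab) {
    stop_if(!setequal(tab$item, items), "tables cover different items")
    tab <- tab[match(items, tab$item), ]
    thr <- mean(tab$mean_cosine_distance) +
      sd_rule * sd(tab$mean_cosine_distance)
    thr - tab$mean_cosine_distance
  }, numeric(length(items)))
  margins <- matrix(margins, nrow = length(items))
  worst <- apply(margins, 1, min)
  out <- tibble(item = items, keep = worst >= 0, worst_margin = worst)
  if (!any(out$keep))
    warning("no item satisfies the consistency rule in every table",
            call. = FALSE)
  out
}

#' Serialize an arrangement session to JSON / read it back
#' @param session an [arrangement_session()]
#' @param path JSON file path
#' @export
write_session_json <- function(session, path) {
  obj <- list(
    subject = session$subject, task = session$task,
    items = session$items,
    arena = list(radius = session$arena$radius,
                 center = session$arena$center),
    trials = lapply(session$trials, function(tr)
      list(items = tr$items, x = tr$coords[, 1], y = tr$coords[, 2]))
  )
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_session_json
#' @export
read_session_json <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  trials <- lapply(seq_len(nrow(obj$trials)), function(i) {
    list(items = unlist(obj$trials$items[[i]]),
         coords = cbind(unlist(obj$trials$x[[i]]),
                        unlist(obj$trials$y[[i]])))
  })
  arrangement_session(obj$subject, obj$task, trials,
                      arena(obj$arena$radius, unlist(obj$arena$center)),
                      unlist(obj$items))
}
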