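#' Canonical double-gamma hemodynamic response function
#'
#' The standard two-gamma parameterization: a positive lobe with response
#' delay `peak` (gamma shape, unit rate), an undershoot with delay
#' `undershoot`, and undershoot amplitude `1/ratio` of the peak.
#'
#' @param t time points in seconds (>= 0)
#' @param peak response delay of the positive lobe (s)
#' @param undershoot response delay of the undershoot (s)
#' @param ratio peak-to-undershoot amplitude ratio
#' @return HRF values at `t`, scaled so the kernel maxes at 1
#' @export
hrf_double_gamma <- function(t, peak = 6, undershoot = 16, ratio = 6) {
  stopifnot(all(t >= 0))
  a1 <- peak; a2 <- undershoot
  h <- stats::dgamma(t, shape = a1, rate = 1) -
    stats::dgamma(t, shape = a2, rate = 1) / ratio
  h / max(h)
}

# Convolve per-condition boxcars with the HRF on a fine grid and sample at
# the volume acquisition times. Returns volumes x n_regressors matrix.
convolved_design <- function(onsets, durations, cond_index, n_cond,
                             n_volumes, tr_s, hrf_params = list(), dt = 0.1) {
  run_dur <- n_volumes * tr_s
  hrf_len_s <- 32
  stop_if(hrf_len_s >= run_dur, "HRF kernel longer than the run")
  grid_n <- ceiling(run_dur / dt)
  kern <- do.call(hrf_double_gamma,
                  c(list(t = seq(0, hrf_len_s, by = dt)), hrf_params))
  x <- matrix(0, n_volumes, n_cond)
  sample_idx <- round(seq(0, by = tr_s, length.out = n_volumes) / dt) + 1
  for (k in seq_len(n_cond)) {
    sel <- which(cond_index == k)
    if (!length(sel)) next
    box <- numeric(grid_n)
    for (i in sel) {
      stop_if(onsets[i] + durations[i] > run_dur,
              "trial at %.1f s falls outside the run", onsets[i])
      a <- floor(onsets[i] / dt) + 1
      b <- min(grid_n, ceiling((onsets[i] + durations[i]) / dt))
      box[a:b] <- 1
    }
    conv <- stats::convolve(box, rev(kern), type = "open")[seq_len(grid_n)]
    x[, k] <- conv[sample_idx]
  }
  x
}

#' Simulate fMRI-like vertex time series from planted betas
#'
#' For each run, the series is `design %*% betas + noise` where the design
#' holds one HRF-convolved boxcar regressor per condition (catch trials get
#' their own regressor) and the noise is AR(1) Gaussian, independent per
#' vertex. Zero noise and zero betas give a flat series; the generator is
#' linear in the betas, so [glm_betas()] recovers planted values exactly in
#' the noiseless case.
#'
#' @param betas_per_run list over runs of condition x vertex beta matrices
#'   (rownames = condition labels)
#' @param trial_sequence tibble from [generate_trial_sequence()]
#' @param config a [design_config()]
#' @param hrf_params list passed to [hrf_double_gamma()]
#' @param noise_sd innovation sd of the AR(1) noise
#' @param ar_coef AR(1) coefficient
#' @param seed RNG seed
#' @return list over runs of volumes x vertex matrices, with the per-run
#'   design attached as attribute `design`
#' @export
simulate_timeseries <- function(betas_per_run, trial_sequence,
                                config = design_config(), hrf_params = list(),
                                noise_sd = 0, ar_coef = 0.3, seed = 1) {
  runs <- sort(unique(trial_sequence$run))
  stop_if(length(betas_per_run) != length(runs),
          "need one beta matrix per run (%d runs, %d matrices)",
          length(runs), length(betas_per_run))
  with_seed(seed, lapply(seq_along(runs), function(ri) {
    ev <- trial_sequence[trial_sequence$run == runs[ri] &
                           trial_sequence$trial_type != "null", ]
    betas <- betas_per_run[[ri]]
    labels <- rownames(betas)
    stop_if(is.null(labels), "beta matrices need condition rownames")
    cond <- ifelse(ev$trial_type == "catch", "catch",
                   sprintf("action%02d", ev$action))
    all_cond <- c(labels, "catch")
    x <- convolved_design(ev$onset, ev$duration,
                          match(cond, all_cond), length(all_cond),
                          config$volumes_per_run, config$tr_s, hrf_params)
    n_vert <- ncol(betas)
    signal <- x[, seq_along(labels), drop = FALSE] %*% betas
    noise <- 0
    if (noise_sd > 0) {
      noise <- vapply(seq_len(n_vert), function(v) {
        as.numeric(stats::arima.sim(list(ar = ar_coef),
                                    n = config$volumes_per_run,
                                    sd = noise_sd))
      }, numeric(config$volumes_per_run))
    }
    out <- signal + noise
    attr(out, "design") <- x
    attr(out, "condition_labels") <- all_cond
    out
  }))
}

#' Estimate condition betas from a run's time series by OLS
#'
#' Fits `[condition regressors | catch regressor | nuisance | intercept]`
#' by ordinary least squares and returns the condition betas only. The
#' design is rebuilt from the event table exactly as in
#' [simulate_timeseries()], so noiseless simulated data round-trips to the
#' planted betas.
#'
#' @param timeseries volumes x vertex matrix for one run
#' @param events event tibble rows for that run
#' @param config a [design_config()]
#' @param condition_labels character vector of condition names (order of the
#'   returned betas)
#' @param nuisance optional volumes x k matrix of nuisance regressors
#' @param hrf_params list passed to [hrf_double_gamma()]
#' @return condition x vertex matrix of betas
#' @export
glm_betas <- function(timeseries, events, config = design_config(),
                      condition_labels = NULL, nuisance = NULL,
                      hrf_params = list()) {
  ev <- events[events$trial_type != "null", ]
  if (is.null(condition_labels)) {
    condition_labels <- sprintf("action%02d",
                                sort(unique(ev$action[!is.na(ev$action)])))
  }
  cond <- ifelse(ev$trial_type == "catch", "catch",
                 sprintf("action%02d", ev$action))
  all_cond <- condition_labels
  if (any(cond == "catch")) all_cond <- c(all_cond, "catch")
  x <- convolved_design(ev$onset, ev$duration, match(cond, all_cond),
                        length(all_cond), nrow(timeseries), config$tr_s,
                        hrf_params)
  x <- cbind(x, nuisance, 1)
  qrx <- qr(x)
  if (qrx$rank < ncol(x)) {
    dropped <- setdiff(seq_len(ncol(x)), qrx$pivot[seq_len(qrx$rank)])
    stop_if(TRUE, "rank-deficient design matrix; collinear column(s): %s",
            paste(dropped, collapse = ", "))
  }
  b <- qr.coef(qrx, timeseries)
  out <- b[seq_along(condition_labels), , drop = FALSE]
  rownames(out) <- condition_labels
  out
}
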