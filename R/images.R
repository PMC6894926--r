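#' Synthetic grayscale action-image families
#'
#' Stands in for the photographic stimulus set: each "action" is a
#' parametric texture family — an oriented sinusoidal grating windowed by a
#' Gaussian blob, with family-specific orientation, spatial frequency, blob
#' position and size — and exemplars are jittered instances of the family.
#' At zero jitter all exemplars of an action are identical; at low jitter
#' families remain separable by C1 features while exemplars vary, mimicking
#' the exemplar variability of real photographs.
#'
#' @param n_actions number of image families
#' @param n_exemplars exemplars per family
#' @param size `c(height, width)` in pixels (>= 64 x 64)
#' @param jitter relative jitter of family parameters across exemplars
#'   (0 = identical exemplars)
#' @param contrast grating contrast in intensity units
#' @param seed RNG seed
#' @return list over actions of lists of `height x width` matrices in
#'   `[0, 255]`
#' @export
make_synthetic_images <- function(n_actions = 28, n_exemplars = 12,
                                  size = c(96, 128), jitter = 0.05,
                                  contrast = 60, seed = 1) {
  stop_if(size[1] < 64 || size[2] < 64, "images must be at least 64 x 64")
  h <- size[1]; w <- size[2]
  with_seed(seed, {
    # family parameters spread over orientation x frequency x position
    fam <- tibble(
      theta = runif(n_actions, 0, pi),
      freq = runif(n_actions, 0.06, 0.18),          # cycles per pixel
      cx = runif(n_actions, 0.3, 0.7) * w,
      cy = runif(n_actions, 0.3, 0.7) * h,
      sigma = runif(n_actions, 0.12, 0.22) * min(h, w),
      phase = runif(n_actions, 0, 2 * pi)
    )
    xs <- matrix(rep(seq_len(w), each = h), h, w)
    ys <- matrix(rep(seq_len(h), times = w), h, w)
    lapply(seq_len(n_actions), function(a) {
      p <- fam[a, ]
      lapply(seq_len(n_exemplars), function(e) {
        th <- p$theta + rnorm(1, sd = jitter * pi / 4)
        fr <- p$freq * exp(rnorm(1, sd = jitter))
        cx <- p$cx + rnorm(1, sd = jitter * w / 4)
        cy <- p$cy + rnorm(1, sd = jitter * h / 4)
        sg <- p$sigma * exp(rnorm(1, sd = jitter))
        ph <- p$phase + rnorm(1, sd = jitter * pi)
        u <- cos(th) * (xs - cx) + sin(th) * (ys - cy)
        env <- exp(-(((xs - cx)^2 + (ys - cy)^2) / (2 * sg^2)))
        img <- 128 + contrast * env * sin(2 * pi * fr * u + ph)
        pmin(pmax(img, 0), 255)
      })
    })
  })
}

#' Equalize mean luminance across grayscale images
#'
#' Shifts every image additively so its mean intensity hits `target_mean`,
#' then clips to `[0, 255]`. Clipping pulls the realized mean back off
#' target, so the shift is iterated until the mean is within `tol` or the
#' target is unattainable (saturated image), which is reported with a
#' warning. This mirrors the luminance-equalization step applied to the
#' photographic stimuli, whose equalized set had mean 115.80 across images
#' with sd 0.4723.
#'
#' @param images list of matrices in `[0, 255]` (or a nested
#'   action -> exemplar list, which is flattened and re-nested)
#' @param target_mean target mean intensity
#' @param tol acceptable |mean - target|
#' @param max_iter shift-and-clip iterations
#' @return list with `images` (same shape as input), and a tibble `report`
#'   (per image: achieved mean, clipped fraction, attained flag)
#' @export
normalize_luminance <- function(images, target_mean = 115.8, tol = 0.5,
                                max_iter = 25) {
  nested <- is.list(images[[1]])
  flat <- if (nested) unlist(images, recursive = FALSE) else images
  out <- vector("list", length(flat))
  rep_rows <- vector("list", length(flat))
  for (i in seq_along(flat)) {
    img <- flat[[i]]
    stop_if(min(img) < 0 || max(img) > 255, "image %d outside [0, 255]", i)
    for (it in seq_len(max_iter)) {
      delta <- target_mean - mean(img)
      if (abs(delta) <= tol) break
      img <- pmin(pmax(img + delta, 0), 255)
    }
    achieved <- mean(img)
    attained <- abs(achieved - target_mean) <= tol
    if (!attained)
      warning(sprintf(
        "image %d: target mean %.2f unattainable (achieved %.2f)",
        i, target_mean, achieved), call. = FALSE)
    out[[i]] <- img
    rep_rows[[i]] <- tibble(
      image = i, mean = achieved,
      clipped_fraction = mean(img <= 0 | img >= 255),
      attained = attained)
  }
  if (nested) {
    sizes <- lengths(images)
    out <- split(out, rep(seq_along(images), sizes))
    names(out) <- names(images)
  }
  list(images = out, report = dplyr::bind_rows(rep_rows))
}

#' Write a grayscale image as plain-text PGM (P2)
#' @param img matrix in `[0, 255]`
#' @param path output path
#' @export
write_pgm <- function(img, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c("P2", sprintf("%d %d", ncol(img), nrow(img)), "255"), con)
  apply(round(img), 1, function(row)
    writeLines(paste(row, collapse = " "), con))
  invisible(path)
}

#' @rdname write_pgm
#' @export
read_pgm <- function(path) {
  txt <- scan(path, what = character(), quiet = TRUE, comment.char = "#")
  stop_if(txt[1] != "P2", "only plain-text (P2) PGM supported")
  w <- as.integer(txt[2]); h <- as.integer(txt[3])
  vals <- as.numeric(txt[-(1:4)])
  stop_if(length(vals) != w * h, "truncated PGM: expected %d values, got %d",
          w * h, length(vals))
  matrix(vals, nrow = h, ncol = w, byrow = TRUE)
}
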