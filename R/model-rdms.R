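#' Rating-derived model RDMs
#'
#' Converts Likert-style judgment scores into dissimilarities: per subject,
#' entry (i, j) is `|score_i - score_j|`, max-normalized; the group RDM is
#' the mean of the per-subject normalized RDMs, renormalized (so every
#' subject contributes with equal weight). This is how the sociality,
#' transitivity and observer-distance models are built (sociality and
#' transitivity on a 1-7 scale; distance on an ordinal 1-3 scale treated
#' the same way).
#'
#' @param ratings subjects x items numeric matrix (colnames = item labels),
#'   or a long tibble with columns `subject`, `item`, `score`
#' @param bounds allowed score range, e.g. `c(1, 7)`
#' @return list with `group` (an `rdm`) and `per_subject` (list of `rdm`)
#' @export
rating_rdm <- function(ratings, bounds = c(1, 7)) {
  if (is.data.frame(ratings)) {
    wide <- tidyr::pivot_wider(ratings, id_cols = "subject",
                               names_from = "item", values_from = "score")
    m <- as.matrix(wide[, -1])
    rownames(m) <- wide$subject
    ratings <- m
  }
  stop_if(nrow(ratings) < 1, "need at least one subject")
  stop_if(anyNA(ratings), "missing ratings are not allowed after validation")
  bad <- which(ratings < bounds[1] | ratings > bounds[2], arr.ind = TRUE)
  stop_if(nrow(bad) > 0,
          "out-of-bounds score (subject %s, item %s)",
          rownames(ratings)[bad[1, 1]] %||% bad[1, 1],
          colnames(ratings)[bad[1, 2]] %||% bad[1, 2])
  items <- colnames(ratings) %||% paste0("item", seq_len(ncol(ratings)))
  per_subject <- lapply(seq_len(nrow(ratings)), function(s) {
    d <- abs(outer(ratings[s, ], ratings[s, ], "-"))
    r <- rdm(d, items = items,
             meta = list(source = "rating",
                         subject = rownames(ratings)[s] %||% s))
    tryCatch(normalize_rdm(r), error = function(e)
      stop(sprintf("subject %s rated all items identically: %s",
                   rownames(ratings)[s] %||% s, conditionMessage(e)),
           call. = FALSE))
  })
  avg <- Reduce(`+`, lapply(per_subject, rdm_values)) / length(per_subject)
  group <- normalize_rdm(rdm(avg, items = items,
                             meta = list(source = "rating_group")))
  list(group = group, per_subject = per_subject)
}

#' Binary-feature model RDM
#'
#' Items with the same label get dissimilarity 0, items with different
#' labels get 1 — equivalently `|a - b|` for 0/1 codes. Used for the
#' one-vs-two-people control model.
#'
#' @param labels named 0/1 vector (names = item labels)
#' @return an `rdm`
#' @export
binary_feature_rdm <- function(labels) {
  stop_if(!all(labels %in% c(0, 1)), "labels must be 0 or 1")
  items <- names(labels) %||% paste0("item", seq_along(labels))
  d <- abs(outer(as.numeric(labels), as.numeric(labels), "-"))
  out <- rdm(d, items = items, meta = list(source = "binary_feature"))
  if (max(d) == 0) out$meta$degenerate <- TRUE
  out
}

#' HMAX C1 configuration
#'
#' A reduced, desk-scale version of the standard C1 parameter table: 4
#' orientations and 2 scale bands (Gabor sizes 7/9 and 11/13 pixels, pooling
#' neighborhoods 8 and 10 with 50% overlap), applied to images resized (by
#' the caller) to about 128 x 96. Larger published parameter tables can be
#' supplied through the same structure.
#'
#' @param n_orientations number of Gabor orientations
#' @param bands list of bands, each `list(sizes = c(s1, s2), pool = p)`
#' @param lambda_ratio Gabor wavelength as a fraction of filter size
#' @param gamma Gabor aspect ratio
#' @return a `c1_params` list
#' @export
c1_params <- function(n_orientations = 4,
                      bands = list(list(sizes = c(7, 9), pool = 8),
                                   list(sizes = c(11, 13), pool = 10)),
                      lambda_ratio = 0.8, gamma = 0.3) {
  stop_if(n_orientations < 1, "need at least one orientation")
  stop_if(length(bands) < 1, "need at least one band")
  for (b in bands) stop_if(b$pool < 2, "pooling size must exceed stride")
  structure(list(n_orientations = n_orientations, bands = bands,
                 lambda_ratio = lambda_ratio, gamma = gamma),
            class = "c1_params")
}

# Zero-mean, unit-norm Gabor filter of a given odd size and orientation.
gabor_filter <- function(size, theta, lambda_ratio = 0.8, gamma = 0.3) {
  half <- (size - 1) / 2
  xs <- matrix(rep(-half:half, each = size), size, size)
  ys <- matrix(rep(-half:half, times = size), size, size)
  x0 <- xs * cos(theta) + ys * sin(theta)
  y0 <- -xs * sin(theta) + ys * cos(theta)
  sigma <- 0.0036 * size^2 + 0.35 * size + 0.18
  lambda <- size * lambda_ratio
  g <- exp(-(x0^2 + gamma^2 * y0^2) / (2 * sigma^2)) *
    cos(2 * pi * x0 / lambda)
  g <- g - mean(g)
  g / sqrt(sum(g^2))
}

# Valid 2D cross-correlation of image with kernel (no padding).
conv2_valid <- function(img, kern) {
  kh <- nrow(kern); kw <- ncol(kern)
  oh <- nrow(img) - kh + 1; ow <- ncol(img) - kw + 1
  out <- matrix(0, oh, ow)
  for (i in seq_len(kh)) {
    for (j in seq_len(kw)) {
      out <- out + kern[i, j] * img[i:(i + oh - 1), j:(j + ow - 1)]
    }
  }
  out
}

# Max-pool a map over pool x pool cells with 50% overlap, padding the
# border cells with -Inf-free truncation.
max_pool <- function(m, pool) {
  step <- max(1, floor(pool / 2))
  rs <- seq(1, max(1, nrow(m) - 1), by = step)
  cs <- seq(1, max(1, ncol(m) - 1), by = step)
  out <- matrix(0, length(rs), length(cs))
  for (a in seq_along(rs)) {
    for (b in seq_along(cs)) {
      r2 <- min(nrow(m), rs[a] + pool - 1)
      c2 <- min(ncol(m), cs[b] + pool - 1)
      out[a, b] <- max(m[rs[a]:r2, cs[b]:c2])
    }
  }
  out
}

#' C1 features of a grayscale image
#'
#' The second layer of the HMAX hierarchy. S1: the image is filtered with
#' zero-mean, unit-norm Gabors at every configured orientation and size;
#' responses are half-wave rectified by absolute value. C1: within each
#' band, responses are taken as the maximum over the band's two filter
#' sizes, then max-pooled over local `pool x pool` neighborhoods with 50%
#' overlap. The pooled maps are flattened band-by-band, orientation-by-
#' orientation into one feature vector. Because the filters are zero-mean,
#' C1 is exactly invariant to adding a constant to the image.
#'
#' @param image numeric matrix (grayscale)
#' @param params a [c1_params()]
#' @return numeric feature vector; attribute `layout` is a tibble with one
#'   row per (band, orientation) block giving its length, documenting the
#'   flattening order
#' @export
c1_features <- function(image, params = c1_params()) {
  stopifnot(is.matrix(image), is.numeric(image))
  max_size <- max(unlist(lapply(params$bands, `[[`, "sizes")))
  stop_if(nrow(image) < max_size || ncol(image) < max_size,
          "image (%d x %d) smaller than the largest filter (%d)",
          nrow(image), ncol(image), max_size)
  thetas <- (seq_len(params$n_orientations) - 1) * pi / params$n_orientations
  feats <- list()
  layout <- list()
  for (bi in seq_along(params$bands)) {
    b <- params$bands[[bi]]
    for (ti in seq_along(thetas)) {
      th <- thetas[ti]
      # S1: abs response at each of the band's scales, cropped to the
      # smaller response map so the scale max is well-defined
      resp <- lapply(b$sizes, function(sz)
        abs(conv2_valid(image, gabor_filter(sz, th, params$lambda_ratio,
                                            params$gamma))))
      oh <- min(vapply(resp, nrow, integer(1)))
      ow <- min(vapply(resp, ncol, integer(1)))
      crop <- function(m) {
        ro <- floor((nrow(m) - oh) / 2); co <- floor((ncol(m) - ow) / 2)
        m[(ro + 1):(ro + oh), (co + 1):(co + ow), drop = FALSE]
      }
      scale_max <- Reduce(pmax, lapply(resp, crop))
      pooled <- as.vector(max_pool(scale_max, b$pool))
      feats[[length(feats) + 1]] <- pooled
      layout[[length(layout) + 1]] <-
        tibble(band = bi, orientation_deg = th * 180 / pi,
               length = length(pooled))
    }
  }
  out <- unlist(feats)
  attr(out, "layout") <- dplyr::bind_rows(layout)
  out
}

#' HMAX-C1 model RDM from exemplar images
#'
#' Each action's exemplar images are reduced to C1 feature vectors and
#' averaged into one vector per action; the RDM entry is `1 - Pearson`
#' between action vectors (squared Euclidean available as an option), then
#' max-normalized. This is the low-level visual control model.
#'
#' @param action_images named list: action -> list of grayscale matrices
#' @param params a [c1_params()]
#' @param metric `"one_minus_pearson"` or `"squared_euclidean"`
#' @return an `rdm` over the actions
#' @export
hmax_rdm <- function(action_images, params = c1_params(),
                     metric = c("one_minus_pearson", "squared_euclidean")) {
  metric <- match.arg(metric)
  items <- names(action_images) %||%
    sprintf("action%02d", seq_along(action_images))
  vecs <- lapply(action_images, function(imgs) {
    fv <- vapply(imgs, c1_features, params = params,
                 numeric(length(c1_features(imgs[[1]], params))))
    rowMeans(matrix(fv, ncol = length(imgs)))
  })
  mat <- do.call(rbind, vecs)
  rownames(mat) <- items
  if (metric == "one_minus_pearson") {
    for (i in seq_len(nrow(mat)))
      stop_if(sd(mat[i, ]) == 0,
              "action %s has a zero-variance C1 vector (degenerate image)",
              items[i])
    d <- 1 - cor(t(mat))
    d[d < 0] <- 0
    out <- rdm(d, items = items, meta = list(source = "hmax_c1",
                                             metric = metric))
  } else {
    out <- squared_euclidean_rdm(mat, items = items,
                                 meta = list(source = "hmax_c1"))
  }
  normalize_rdm(out)
}

#' Named, ordered collection of predictor RDMs
#'
#' The predictor set for multiple-regression RSA. All members must share
#' the same items in the same order; each is max-normalized on entry. The
#' canonical ten-model order is semantic, body, scene, movement, object,
#' sociality, transitivity, distance, people, hmax_c1; any subset or other
#' named collection is allowed.
#'
#' @param ... named `rdm` objects, or a single named list of them
#' @return a `model_set`
#' @export
model_set <- function(...) {
  models <- list(...)
  if (length(models) == 1 && is.list(models[[1]]) &&
      !inherits(models[[1]], "rdm")) models <- models[[1]]
  stop_if(length(models) < 1, "need at least one model")
  stop_if(is.null(names(models)) || any(names(models) == ""),
          "every model must be named")
  stop_if(anyDuplicated(names(models)) > 0, "model names must be unique")
  items <- rdm_items(models[[1]])
  models <- lapply(models, function(m) {
    stopifnot(inherits(m, "rdm"))
    stop_if(!identical(rdm_items(m), items),
            "all models must share the same items in the same order")
    if (!identical(m$meta$normalized, "max")) m <- normalize_rdm(m)
    m
  })
  structure(list(models = models, items = items), class = "model_set")
}

#' @export
print.model_set <- function(x, ...) {
  cat(sprintf("<model_set> %d models over %d items: %s\n",
              length(x$models), length(x$items),
              paste(names(x$models), collapse = ", ")))
  invisible(x)
}

#' @export
length.model_set <- function(x) length(x$models)

# Model vectors as a pairs x models matrix.
model_matrix <- function(models) {
  vapply(models$models, ut_vec, numeric(length(ut_vec(models$models[[1]]))))
}

#' Pairwise correlations between model RDMs
#'
#' @param models a [model_set()]
#' @param method correlation type (see [rdm_correlation()])
#' @return symmetric model x model correlation matrix with unit diagonal
#' @export
model_intercorrelation <- function(models, method = "pearson") {
  stop_if(length(models) < 2, "need at least 2 models")
  nm <- names(models$models)
  out <- diag(length(nm))
  dimnames(out) <- list(nm, nm)
  for (i in seq_along(nm)) {
    for (j in seq_along(nm)) {
      if (j > i) {
        out[i, j] <- out[j, i] <-
          rdm_correlation(models$models[[i]], models$models[[j]], method)
      }
    }
  }
  out
}

#' Variance inflation factors of a model set
#'
#' Each model's pair vector is regressed (with intercept) on all other
#' models' vectors; `VIF_i = 1 / (1 - R^2_i)`. Perfectly collinear
#' predictors get `Inf`, not an error, so the diagnostic can still be
#' reported.
#'
#' @param models a [model_set()]
#' @return tibble with `model`, `r_squared`, `vif`
#' @export
vif <- function(models) {
  stop_if(length(models) < 2, "need at least 2 models")
  x <- model_matrix(models)
  stop_if(nrow(x) <= ncol(x),
          "need more item pairs than models (%d pairs, %d models)",
          nrow(x), ncol(x))
  rows <- lapply(seq_len(ncol(x)), function(i) {
    fit <- stats::lm.fit(cbind(1, x[, -i, drop = FALSE]), x[, i])
    ssr <- sum(fit$residuals^2)
    sst <- sum((x[, i] - mean(x[, i]))^2)
    r2 <- if (sst == 0) 1 else 1 - ssr / sst
    tibble(model = colnames(x)[i], r_squared = r2,
           vif = if (r2 >= 1 - 1e-12) Inf else 1 / (1 - r2))
  })
  dplyr::bind_rows(rows)
}
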