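#' Neural RDM of a vertex neighborhood
#'
#' Computes the squared-Euclidean RDM of the condition patterns restricted
#' to a set of member vertices, with the normalizations used by the two RSA
#' variants:
#'
#' * `standard`: betas averaged across runs, squared-Euclidean RDM,
#'   max-normalized.
#' * `regression`: each vertex is z-scored across conditions within run
#'   ("across images", removing univariate amplitude differences), runs are
#'   averaged, then each condition's member-vertex pattern is z-scored
#'   ("across features", removing pattern-norm differences), and the
#'   squared-Euclidean RDM is computed.
#'
#' Both z-scoring steps and the final max-normalization are individually
#' toggleable: planted-mixture oracles require the raw additive RDM, so
#' validation code runs with them off.
#'
#' @param betas run x condition x vertex array (dimnames on conditions)
#' @param members integer vertex indices of the searchlight
#' @param mode `"standard"` or `"regression"`
#' @param normalize_images z-score vertices across conditions within run
#'   (default on in regression mode)
#' @param normalize_features z-score condition patterns across members
#'   (default on in regression mode)
#' @param normalize `"max"` or `"none"` final RDM scaling
#' @return an `rdm` over the conditions; `meta$degenerate` flags an all-zero
#'   RDM, `meta$dropped_vertices` counts zero-variance vertices removed by
#'   z-scoring
#' @export
neural_rdm <- function(betas, members, mode = c("standard", "regression"),
                       normalize_images = NULL, normalize_features = NULL,
                       normalize = c("max", "none")) {
  mode <- match.arg(mode)
  normalize <- match.arg(normalize)
  normalize_images <- normalize_images %||% (mode == "regression")
  normalize_features <- normalize_features %||% (mode == "regression")
  stopifnot(length(dim(betas)) == 3)
  items <- dimnames(betas)[[2]]
  n_runs <- dim(betas)[1]
  sub <- betas[, , members, drop = FALSE]
  dropped <- 0L

  if (normalize_images) {
    for (r in seq_len(n_runs)) {
      m <- sub[r, , ]
      sds <- apply(m, 2, sd)
      zero <- sds == 0
      if (any(zero)) {
        dropped <- dropped + sum(zero)
        sds[zero] <- 1
      }
      sub[r, , ] <- scale(m, center = TRUE, scale = sds)
      if (any(zero)) sub[r, , zero] <- 0
    }
  }
  avg <- colMeans(sub)  # average over the run dimension
  if (normalize_features) {
    avg <- t(scale(t(avg)))
    bad <- apply(avg, 1, function(x) any(!is.finite(x)))
    if (any(bad)) avg[bad, ] <- 0
  }
  rownames(avg) <- items
  out <- squared_euclidean_rdm(avg, items = items,
                               meta = list(mode = mode))
  if (dropped > 0) {
    out$meta$dropped_vertices <- dropped
    warning(sprintf("%d zero-variance vertex/run combinations zeroed %s",
                    dropped, "during z-scoring"), call. = FALSE)
  }
  if (max(rdm_values(out)) == 0) {
    out$meta$degenerate <- TRUE
    return(out)
  }
  if (normalize == "max") out <- normalize_rdm(out)
  out
}

# Pairs x searchlights matrix of neural RDM vectors for one subject.
# Returns NA columns for degenerate searchlights.
neural_rdm_vectors <- function(betas, searchlights, mode, ...) {
  n_pairs <- choose(dim(betas)[2], 2)
  vapply(searchlights$members, function(mem) {
    r <- neural_rdm(betas, mem, mode = mode, ...)
    if (isTRUE(r$meta$degenerate)) return(rep(NA_real_, n_pairs))
    ut_vec(r)
  }, numeric(n_pairs))
}

#' Searchlight standard RSA: one model, one correlation map per subject
#'
#' At every searchlight, the neural RDM (standard normalization) is
#' correlated with the model RDM and the coefficient is written to the
#' center vertex. Degenerate (zero-variance) searchlights get `NA`.
#'
#' @param dataset a `beta_dataset` (see [plant_brain_patterns()])
#' @param model an `rdm` over the dataset's conditions
#' @param searchlights tibble from [build_searchlights()]
#' @param method correlation type, Pearson by default (the maps are Fisher
#'   transformed downstream)
#' @return tibble with `subject`, `vertex`, `value`
#' @export
standard_rsa_map <- function(dataset, model, searchlights,
                             method = "pearson") {
  stopifnot(inherits(model, "rdm"))
  stop_if(!identical(rdm_items(model), dataset$items),
          "model items do not match dataset conditions")
  mv <- ut_vec(model)
  rows <- lapply(seq_along(dataset$betas), function(s) {
    y <- neural_rdm_vectors(dataset$betas[[s]], searchlights, "standard")
    vals <- apply(y, 2, function(col) {
      if (anyNA(col) || sd(col) == 0) return(NA_real_)
      if (method == "pearson") cor(col, mv)
      else if (method == "spearman") cor(col, mv, method = "spearman")
      else kendall_tau_a(col, mv)
    })
    tibble(subject = sprintf("sub%02d", s),
           vertex = searchlights$center, value = vals)
  })
  dplyr::bind_rows(rows)
}

#' Searchlight multiple-regression RSA
#'
#' At every searchlight, the neural RDM vector (regression normalization)
#' is regressed by OLS on all model RDM vectors plus an intercept; each
#' model's coefficient is written to its own map at the center vertex. An
#' intercept is always included because max-normalized distance vectors
#' have a nonzero mean. Predictors are not standardized by default, so
#' coefficients live on the normalized-RDM scale and are comparable across
#' searchlights; `standardize = TRUE` z-scores the predictors first. A
#' perfectly collinear model set is rejected before the searchlight loop.
#'
#' @param dataset a `beta_dataset`
#' @param models a [model_set()] over the dataset's conditions
#' @param searchlights tibble from [build_searchlights()]
#' @param standardize z-score predictor vectors before regressing
#' @param ... normalization toggles passed to [neural_rdm()]
#' @return tibble with `subject`, `vertex`, `model`, `beta`
#' @export
regression_rsa_map <- function(dataset, models, searchlights,
                               standardize = FALSE, ...) {
  stop_if(!identical(models$items, dataset$items),
          "model items do not match dataset conditions")
  x <- model_matrix(models)
  stop_if(nrow(x) <= ncol(x) + 1,
          "need more item pairs than models + intercept")
  if (length(models) >= 2) {
    v <- vif(models)
    stop_if(any(is.infinite(v$vif)),
            "model set is perfectly collinear (%s); cannot regress",
            paste(v$model[is.infinite(v$vif)], collapse = ", "))
  }
  if (standardize) x <- scale(x)
  xmat <- cbind(intercept = 1, x)
  qrx <- qr(xmat)
  rows <- lapply(seq_along(dataset$betas), function(s) {
    y <- neural_rdm_vectors(dataset$betas[[s]], searchlights, "regression",
                            ...)
    coefs <- qr.coef(qrx, y)   # (models+1) x searchlights, NA columns kept
    tidyr::expand_grid(model = names(models$models),
                       vertex = searchlights$center) |>
      dplyr::mutate(subject = sprintf("sub%02d", s),
                    beta = as.vector(t(coefs[-1, , drop = FALSE]))) |>
      dplyr::select("subject", "vertex", "model", "beta")
  })
  dplyr::bind_rows(rows)
}

#' Build a one-row searchlight table for a fixed vertex set
#'
#' Runs the searchlight machinery over a single region of interest: the
#' returned tibble plugs into [standard_rsa_map()] / [regression_rsa_map()]
#' so ROI analyses share the exact searchlight code path. The planted-RDM
#' mixtures of [plant_brain_patterns()] are exact over a full region, so
#' this is also how the regression-recovery oracle is evaluated.
#'
#' @param vertices integer vertex indices of the ROI
#' @param center center vertex to which results are assigned (defaults to
#'   the first)
#' @return tibble with the [build_searchlights()] columns
#' @export
roi_searchlight <- function(vertices, center = vertices[1]) {
  stop_if(length(vertices) < 1, "empty ROI")
  tibble(center = as.integer(center),
         members = list(as.integer(vertices)),
         n_members = length(vertices), complete = TRUE)
}

#' Reshape a long subject-map tibble into a subjects x vertices matrix
#'
#' @param maps tibble with `subject`, `vertex`, `value` (or `beta`)
#' @param value name of the value column
#' @return numeric matrix, rownames = subjects, colnames = vertices
#' @export
maps_to_matrix <- function(maps, value = "value") {
  wide <- tidyr::pivot_wider(maps, id_cols = "subject",
                             names_from = "vertex", values_from = value)
  m <- as.matrix(wide[, -1])
  rownames(m) <- wide$subject
  m
}

#' Write a per-vertex stat map as TSV
#' @param map tibble with at least `vertex` and a value column
#' @param path output path
#' @export
write_stat_map <- function(map, path) {
  utils::write.table(map, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
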