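#' Representational dissimilarity matrices
#'
#' An `rdm` is a square, symmetric, non-negative dissimilarity matrix with a
#' zero diagonal and named rows/columns (the condition labels). It is the
#' common currency of the whole pipeline: behavioral arrangement estimates,
#' rating differences, image-feature distances and neural pattern distances
#' are all expressed as RDMs before they are compared.
#'
#' `rdm()` validates a plain matrix and stamps the class. Near-symmetric
#' input (relative asymmetry below `tol`) is symmetrized as `(M + t(M))/2`;
#' anything worse is rejected. `meta` carries provenance (task, subject,
#' normalization applied) and travels with the object.
#'
#' @param values square numeric matrix of dissimilarities
#' @param items character vector of condition labels; defaults to the
#'   dimnames of `values` or `item1..itemN`
#' @param meta named list of provenance tags
#' @param tol relative tolerance for the symmetry check
#' @param allow_na allow missing entries (pre-aggregation RDMs only); the
#'   missingness is flagged in `meta$has_missing`
#' @return an object of class `rdm`
#' @examples
#' m <- matrix(c(0, 1, 2, 1, 0, 3, 2, 3, 0), 3, 3)
#' r <- rdm(m, items = c("a", "b", "c"))
#' rdm_values(r)["a", "c"]
#' @export
rdm <- function(values, items = NULL, meta = list(), tol = 1e-8,
                allow_na = FALSE) {
  stop_if(!is.matrix(values) || !is.numeric(values),
          "an RDM must be a numeric matrix")
  n <- nrow(values)
  stop_if(ncol(values) != n, "an RDM must be square (got %d x %d)",
          n, ncol(values))
  if (is.null(items)) items <- rownames(values) %||% paste0("item", seq_len(n))
  stop_if(length(items) != n, "need %d item labels, got %d", n, length(items))
  stop_if(anyDuplicated(items) > 0, "item labels must be unique")

  miss <- is.na(values)
  if (any(miss)) {
    stop_if(!allow_na, "RDM contains missing entries; use allow_na = TRUE %s",
            "only for pre-aggregation RDMs")
    stop_if(!identical(miss, t(miss)), "missingness mask must be symmetric")
    meta$has_missing <- TRUE
  }
  stop_if(any(!is.finite(values[!miss])), "RDM entries must be finite")
  stop_if(any(values[!miss] < 0), "RDM entries must be non-negative")

  scale <- max(abs(values), na.rm = TRUE)
  asym <- max(abs(values - t(values)), na.rm = TRUE)
  stop_if(scale > 0 && asym > tol * scale,
          "matrix is asymmetric beyond tolerance (max |M - t(M)| = %.3g)", asym)
  values <- (values + t(values)) / 2
  stop_if(any(abs(diag(values)) > tol * max(scale, 1)),
          "RDM diagonal must be zero")
  diag(values) <- 0

  dimnames(values) <- list(items, items)
  structure(list(values = values, items = as.character(items), meta = meta),
            class = "rdm")
}

#' @rdname rdm
#' @param x an `rdm` object
#' @export
rdm_values <- function(x) {
  stopifnot(inherits(x, "rdm"))
  x$values
}

#' @rdname rdm
#' @export
rdm_items <- function(x) {
  stopifnot(inherits(x, "rdm"))
  x$items
}

#' @export
print.rdm <- function(x, ...) {
  n <- length(x$items)
  v <- rdm_vectorize(x)$value
  cat(sprintf("<rdm> %d items, %d pairs; range [%.4g, %.4g]\n",
              n, length(v), min(v), max(v)))
  if (length(x$meta))
    cat("  meta:", paste(names(x$meta), unlist(lapply(x$meta, format)),
                         sep = "=", collapse = ", "), "\n")
  invisible(x)
}

#' @export
dim.rdm <- function(x) dim(x$values)

#' @export
as.matrix.rdm <- function(x, ...) x$values

#' Vectorize an RDM / rebuild an RDM from its pair vector
#'
#' The upper triangle (excluding the diagonal) in column-pair order
#' `(1,2), (1,3), (2,3), (1,4), ...` is the canonical vector form used for
#' all RDM correlations and regressions. `rdm_vectorize()` returns a tibble
#' with the pair index so the mapping is explicit; `rdm_devectorize()` is its
#' exact inverse.
#'
#' @param x an `rdm`
#' @return `rdm_vectorize()`: tibble with columns `item_i`, `item_j`, `value`;
#'   `rdm_devectorize()`: an `rdm`
#' @export
rdm_vectorize <- function(x) {
  stopifnot(inherits(x, "rdm"))
  v <- x$values
  ut <- upper.tri(v)
  idx <- which(ut, arr.ind = TRUE)
  tibble(
    item_i = x$items[idx[, "row"]],
    item_j = x$items[idx[, "col"]],
    value = v[ut]
  )
}

#' @rdname rdm_vectorize
#' @param values numeric vector of length `n(n-1)/2` in upper-triangle order
#' @param items condition labels
#' @param meta provenance list
#' @export
rdm_devectorize <- function(values, items, meta = list()) {
  n <- length(items)
  stop_if(length(values) != n * (n - 1) / 2,
          "need %d pair values for %d items, got %d",
          n * (n - 1) / 2, n, length(values))
  m <- matrix(0, n, n)
  m[upper.tri(m)] <- values
  m <- m + t(m)
  rdm(m, items = items, meta = meta, allow_na = anyNA(values))
}

# Plain numeric upper-triangle vector (internal fast path).
ut_vec <- function(x) {
  v <- if (inherits(x, "rdm")) x$values else x
  v[upper.tri(v)]
}

#' Pairwise squared Euclidean distance RDM from activation patterns
#'
#' Distance between conditions i and j is `sum_f (x_if - x_jf)^2` over
#' features. The squared Euclidean distance is the metric used for neural
#' RDMs throughout because it sums linearly over disjoint feature blocks,
#' which is the property that licenses multiple-regression RSA: the RDM of a
#' pattern made of independent model-specific blocks is exactly the sum of
#' the block RDMs.
#'
#' @param patterns numeric matrix, conditions x features; rownames become the
#'   item labels
#' @param items optional condition labels
#' @param meta provenance list
#' @return an `rdm`
#' @export
squared_euclidean_rdm <- function(patterns, items = NULL, meta = list()) {
  stopifnot(is.matrix(patterns), is.numeric(patterns))
  stop_if(nrow(patterns) < 2, "need at least 2 conditions")
  if (any(!is.finite(patterns))) {
    bad <- unique(which(!is.finite(patterns), arr.ind = TRUE)[, "col"])
    stop_if(TRUE, "non-finite values in feature column(s): %s",
            paste(utils::head(bad, 10), collapse = ", "))
  }
  g <- tcrossprod(patterns)
  sq <- diag(g)
  d <- outer(sq, sq, "+") - 2 * g
  d[d < 0] <- 0  # numerical guard
  items <- items %||% rownames(patterns)
  rdm(d, items = items, meta = c(meta, list(metric = "squared_euclidean")))
}

#' Euclidean distance RDM from point coordinates
#'
#' @param points numeric matrix, items x dimensions
#' @inheritParams squared_euclidean_rdm
#' @return an `rdm`
#' @export
euclidean_rdm <- function(points, items = NULL, meta = list()) {
  if (is.vector(points)) points <- matrix(points, ncol = 1)
  stopifnot(is.numeric(points))
  points <- as.matrix(points)
  stop_if(ncol(points) < 1, "need at least one coordinate dimension")
  sq <- squared_euclidean_rdm(points, items = items)
  v <- sqrt(sq$values)
  rdm(v, items = sq$items, meta = c(meta, list(metric = "euclidean")))
}

#' Max-normalize an RDM
#'
#' Divides every entry by the maximum off-diagonal entry so the largest
#' dissimilarity equals 1. This is the scale convention applied to every
#' behavioral and model RDM before comparison; it preserves the ordering of
#' entries. An all-zero RDM has no scale and is rejected explicitly.
#'
#' @param x an `rdm`
#' @return an `rdm` with max entry 1 and `meta$normalized = "max"`
#' @export
normalize_rdm <- function(x) {
  stopifnot(inherits(x, "rdm"))
  mx <- max(x$values, na.rm = TRUE)
  stop_if(mx <= 0, "degenerate RDM: all dissimilarities are zero, %s",
          "cannot max-normalize")
  meta <- x$meta
  meta$normalized <- "max"
  rdm(x$values / mx, items = x$items, meta = meta,
      allow_na = isTRUE(meta$has_missing))
}

# Kendall's tau-a: (concordant - discordant) / (n(n-1)/2). Unlike tau-b it
# does not rescale for ties, which is the conservative choice when a model
# RDM predicts tied dissimilarities.
kendall_tau_a <- function(x, y) {
  n <- length(x)
  dx <- sign(outer(x, x, "-"))
  dy <- sign(outer(y, y, "-"))
  s <- sum((dx * dy)[upper.tri(dx)])
  s / (n * (n - 1) / 2)
}

#' Correlate two RDMs
#'
#' Correlation is computed on the upper-triangle pair vectors only, so the
#' structural zero diagonal never inflates agreement. `kendall_tau_a` uses
#' the tau-a denominator `P(P-1)/2` over the `P` pairs, the convention for
#' comparing a neural RDM against model RDMs with tied predictions.
#'
#' @param a,b `rdm` objects over the same items in the same order
#' @param method one of `"pearson"`, `"spearman"`, `"kendall_tau_a"`
#' @return a single correlation in `[-1, 1]`
#' @export
rdm_correlation <- function(a, b, method = c("pearson", "spearman",
                                             "kendall_tau_a")) {
  method <- match.arg(method)
  stopifnot(inherits(a, "rdm"), inherits(b, "rdm"))
  if (!identical(a$items, b$items)) {
    diff <- union(setdiff(a$items, b$items), setdiff(b$items, a$items))
    stop_if(TRUE, "RDMs have different items%s",
            if (length(diff)) paste0(": ", paste(diff, collapse = ", "))
            else " (same labels, different order)")
  }
  stop_if(length(a$items) < 3, "need at least 3 items to correlate RDMs")
  va <- ut_vec(a); vb <- ut_vec(b)
  stop_if(sd(va) == 0 || sd(vb) == 0,
          "zero-variance RDM vector: correlation undefined")
  switch(method,
    pearson = cor(va, vb, method = "pearson"),
    spearman = cor(va, vb, method = "spearman"),
    kendall_tau_a = kendall_tau_a(va, vb)
  )
}

#' Fisher z-transform of a correlation coefficient
#'
#' `atanh(r)`, the variance-stabilizing transform applied to per-subject
#' correlation maps before group t-tests.
#'
#' @param r correlation(s), `|r| < 1`
#' @return z score(s)
#' @export
fisher_z <- function(r) {
  stop_if(any(!is.finite(r)) || any(abs(r) >= 1),
          "fisher_z requires finite |r| < 1")
  atanh(r)
}

#' Rank-transform an RDM and rescale to 0-100
#'
#' Display convention for group-average neural RDMs: off-diagonal entries are
#' replaced by their average ranks, linearly mapped onto `[0, 100]`. All-tied
#' input maps to a constant 50.
#'
#' @param x an `rdm`
#' @return an `rdm` on the 0-100 rank scale
#' @export
rank_rescale_rdm <- function(x) {
  stopifnot(inherits(x, "rdm"))
  stop_if(length(x$items) < 2, "need at least 2 items")
  v <- ut_vec(x)
  r <- rank(v, ties.method = "average")
  out <- if (length(v) == 1 || max(r) == min(r)) {
    rep(50, length(v))
  } else {
    (r - min(r)) / (max(r) - min(r)) * 100
  }
  meta <- x$meta
  meta$normalized <- "rank_0_100"
  rdm_devectorize(out, items = x$items, meta = meta)
}

#' Read / write RDMs as TSV with a JSON meta sidecar
#'
#' The on-disk format is a plain TSV matrix with item labels as the header
#' row and first column, plus `<path>.json` holding the `meta` list. The
#' reader re-validates all RDM invariants.
#'
#' @param x an `rdm`
#' @param path TSV file path
#' @return `write_rdm()` the path invisibly; `read_rdm()` an `rdm`
#' @export
write_rdm <- function(x, path) {
  stopifnot(inherits(x, "rdm"))
  df <- data.frame(item = x$items, x$values, check.names = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  jsonlite::write_json(x$meta, paste0(path, ".json"), auto_unbox = TRUE,
                       digits = NA)
  invisible(path)
}

#' @rdname write_rdm
#' @export
read_rdm <- function(path) {
  df <- utils::read.table(path, sep = "\t", header = TRUE, check.names = FALSE)
  items <- as.character(df[[1]])
  m <- as.matrix(df[, -1, drop = FALSE])
  stop_if(!identical(colnames(m), items),
          "RDM file header does not match its item column")
  meta <- list()
  side <- paste0(path, ".json")
  if (file.exists(side)) meta <- jsonlite::read_json(side, simplifyVector = TRUE)
  rdm(m, items = items, meta = as.list(meta),
      allow_na = isTRUE(meta$has_missing))
}

#' Tidy an RDM into a long pair tibble
#'
#' @param x an `rdm`
#' @param ... unused
#' @return tibble with `item_i`, `item_j`, `value`
#' @method tidy rdm
#' @export
tidy.rdm <- function(x, ...) rdm_vectorize(x)

#' Heatmap of an RDM
#'
#' @param object an `rdm`
#' @param rank_rescale display the 0-100 rank-rescaled values instead of raw
#'   dissimilarities
#' @param ... unused
#' @return a ggplot
#' @method autoplot rdm
#' @export
autoplot.rdm <- function(object, rank_rescale = FALSE, ...) {
  if (rank_rescale) object <- rank_rescale_rdm(object)
  m <- object$values
  df <- tibble(
    item_i = factor(rep(object$items, times = ncol(m)), levels = object$items),
    item_j = factor(rep(object$items, each = nrow(m)),
                    levels = rev(object$items)),
    value = as.vector(m)
  )
  ggplot2::ggplot(df, ggplot2::aes(.data$item_i, .data$item_j,
                                   fill = .data$value)) +
    ggplot2::geom_tile() +
    ggplot2::scale_fill_viridis_c(name = "dissimilarity") +
    ggplot2::labs(x = NULL, y = NULL) +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 90,
                                                       vjust = 0.5, hjust = 1))
}
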