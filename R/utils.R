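#' @importFrom rlang %||% .data abort warn
#' @importFrom stats cor sd var qt qnorm pnorm rnorm runif setNames
#' @importFrom tibble tibble as_tibble
#' @keywords internal
"_PACKAGE"

#' @importFrom generics tidy glance
#' @importFrom ggplot2 autoplot
#' @export
generics::tidy

#' @export
generics::glance

#' @export
ggplot2::autoplot

# Internal assertion helper: stop with a formatted message.
stop_if <- function(cond, ..., call. = FALSE) {
  if (isTRUE(cond)) stop(sprintf(...), call. = call.)
  invisible(TRUE)
}

# Deterministic child seed derived from a master seed and a stage label.
# Keeps every stage's RNG stream independent while staying below 2^31.
derive_seed <- function(seed, label) {
  stopifnot(is.numeric(seed), length(seed) == 1)
  h <- sum(utf8ToInt(label) * seq_along(utf8ToInt(label)))
  as.integer((as.double(seed) * 48271 + h) %% 2147483587L) + 1L
}

# Evaluate expr with a local RNG state seeded by `seed` (NULL = leave RNG alone).
with_seed <- function(seed, expr) {
  if (is.null(seed)) return(expr)
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(rm(".Random.seed", envir = globalenv()), add = TRUE)
  }
  set.seed(seed)
  expr
}
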