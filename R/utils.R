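#' @keywords internal
"_PACKAGE"

## numerical guards shared across modules

# clamp a probability-scale quantity into the open unit interval
clamp_unit <- function(x, eps = 1e-6) {
  pmin(pmax(x, eps), 1 - eps)
}

clamp_corr <- function(r) {
  pmin(pmax(r, -1), 1)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

is_number <- function(x) {
  is.numeric(x) && length(x) == 1L && is.finite(x)
}

stopf <- function(fmt, ...) stop(sprintf(fmt, ...), call. = FALSE)
warnf <- function(fmt, ...) warning(sprintf(fmt, ...), call. = FALSE)

#' Gauss-Hermite quadrature nodes and weights
#'
#' Nodes and weights for the physicists' Gauss-Hermite rule, computed by
#' Golub-Welsch eigendecomposition of the Jacobi matrix. Used to turn the
#' discrete-support expectations of the product-moment approximations into
#' integrals for Gaussian predictors.
#'
#' @param k number of nodes.
#' @return list with `nodes` and `weights` (weights sum to `sqrt(pi)`).
#' @examples
#' gh <- gauss_hermite(16)
#' sum(gh$weights) / sqrt(pi) # 1
#' @export
gauss_hermite <- function(k = 64L) {
  k <- as.integer(k)
  stopifnot(k >= 1L)
  cached <- .gh_cache[[as.character(k)]]
  if (!is.null(cached)) return(cached)
  if (k == 1L) {
    return(.gh_cache[["1"]] <- list(nodes = 0, weights = sqrt(pi)))
  }
  off <- sqrt(seq_len(k - 1L) / 2)
  J <- matrix(0, k, k)
  J[cbind(seq_len(k - 1L), seq_len(k - 1L) + 1L)] <- off
  J[cbind(seq_len(k - 1L) + 1L, seq_len(k - 1L))] <- off
  e <- eigen(J, symmetric = TRUE)
  ord <- order(e$values)
  .gh_cache[[as.character(k)]] <-
    list(nodes = e$values[ord],
         weights = sqrt(pi) * e$vectors[1L, ord]^2)
}

# quadrature rules are deterministic; cache by node count
.gh_cache <- new.env(parent = emptyenv())

# expectation of fun(X) for X ~ N(mu, sd^2) by Gauss-Hermite quadrature;
# fun must be vectorized
gh_expect <- function(fun, mu, sd, gh = gauss_hermite(64L)) {
  x <- mu + sqrt(2) * sd * gh$nodes
  sum(gh$weights * fun(x)) / sqrt(pi)
}
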