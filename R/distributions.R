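#' Marginal predictor distributions
#'
#' The product-moment approximations take expectations of conditional means
#' and variances over each predictor's assumed marginal law `f_j`. Four
#' kinds are supported:
#'
#' * `dist_genotype(maf)` — minor allele count under Hardy-Weinberg
#'   equilibrium, binomial(2, maf) on support \{0, 1, 2\};
#' * `dist_bernoulli(p)` — a binary covariate or phenotype;
#' * `dist_gaussian(mu, sigma)` — a continuous variable, expectations taken
#'   by Gauss-Hermite quadrature;
#' * `dist_degenerate(value)` — a constant column (e.g. an intercept);
#'   contributes nothing to the expectations and is excluded from the
#'   per-predictor variance median.
#'
#' @param maf minor allele frequency, in (0, 0.5].
#' @param p success probability, in (0, 1).
#' @param mu,sigma Gaussian mean and standard deviation (`sigma > 0`).
#' @param value the constant value of a degenerate column.
#' @return an object of class `pcss_dist` with fields `kind`, the
#'   distribution parameters, and for discrete kinds a `support` vector.
#' @examples
#' d <- dist_genotype(0.3)
#' dist_mass(d, 0:2)        # HWE proportions (1-p)^2, 2p(1-p), p^2 on counts
#' dist_moments(d)          # mean 2p, variance 2p(1-p)
#' @name pcss_dist
NULL

new_pcss_dist <- function(kind, params, support = NULL) {
  structure(list(kind = kind, params = params, support = support),
            class = "pcss_dist")
}

#' @rdname pcss_dist
#' @export
dist_genotype <- function(maf) {
  # allele frequencies above 0.5 are tolerated so that empirically
  # estimated frequencies (sample mean / 2) can be attached directly
  if (!is_number(maf) || maf <= 0 || maf >= 1) {
    stopf("genotype allele frequency must lie in (0, 1), got %s",
          format(maf))
  }
  new_pcss_dist("genotype_hwe", list(maf = maf), support = c(0, 1, 2))
}

#' @rdname pcss_dist
#' @export
dist_bernoulli <- function(p) {
  if (!is_number(p) || p <= 0 || p >= 1) {
    stopf("Bernoulli p must lie in (0, 1), got %s", format(p))
  }
  new_pcss_dist("bernoulli", list(p = p), support = c(0, 1))
}

#' @rdname pcss_dist
#' @export
dist_gaussian <- function(mu, sigma) {
  if (!is_number(mu) || !is_number(sigma) || sigma <= 0) {
    stopf("Gaussian distribution needs finite mu and sigma > 0")
  }
  new_pcss_dist("gaussian", list(mu = mu, sigma = sigma))
}

#' @rdname pcss_dist
#' @export
dist_degenerate <- function(value = 1) {
  new_pcss_dist("degenerate", list(value = value), support = value)
}

#' @export
print.pcss_dist <- function(x, ...) {
  cat(sprintf("<pcss_dist %s(%s)>\n", x$kind,
              paste(sprintf("%s=%g", names(x$params), unlist(x$params)),
                    collapse = ", ")))
  invisible(x)
}

#' Probability mass/density of a predictor distribution
#'
#' @param dist a [pcss_dist] object.
#' @param x values at which to evaluate `f_j(x)`.
#' @return numeric vector of masses (discrete kinds) or densities (Gaussian).
#' @export
dist_mass <- function(dist, x) {
  stopifnot(inherits(dist, "pcss_dist"))
  switch(dist$kind,
    genotype_hwe = stats::dbinom(x, size = 2, prob = dist$params$maf),
    bernoulli    = stats::dbinom(x, size = 1, prob = dist$params$p),
    gaussian     = stats::dnorm(x, dist$params$mu, dist$params$sigma),
    degenerate   = as.numeric(x == dist$params$value),
    stopf("unknown distribution kind '%s'", dist$kind))
}

#' Population mean and variance of a predictor distribution
#'
#' @param dist a [pcss_dist] object.
#' @return named numeric vector `c(mean, variance)`.
#' @export
dist_moments <- function(dist) {
  stopifnot(inherits(dist, "pcss_dist"))
  switch(dist$kind,
    genotype_hwe = {
      p <- dist$params$maf
      c(mean = 2 * p, variance = 2 * p * (1 - p))
    },
    bernoulli = {
      p <- dist$params$p
      c(mean = p, variance = p * (1 - p))
    },
    gaussian = c(mean = dist$params$mu, variance = dist$params$sigma^2),
    degenerate = c(mean = dist$params$value, variance = 0))
}

# expectation of a vectorized function under the distribution; discrete
# kinds sum over the support, the Gaussian kind uses GH quadrature
dist_expect <- function(dist, fun, gh = NULL) {
  if (dist$kind == "gaussian") {
    gh_expect(fun, dist$params$mu, dist$params$sigma,
              gh = gh %||% gauss_hermite(64L))
  } else {
    s <- dist$support
    sum(dist_mass(dist, s) * fun(s))
  }
}

dist_is_degenerate <- function(dist) {
  is.null(dist) || dist$kind == "degenerate"
}

# default distributional assumption for a phenotype acting as the
# conditioning variable inside the recursion (its PCSS mean/variance are
# known): Gaussian for continuous, Bernoulli for binary
default_phenotype_dist <- function(vtype, mean, variance) {
  if (identical(vtype, "binary")) {
    dist_bernoulli(clamp_unit(mean))
  } else if (variance > 0) {
    dist_gaussian(mean, sqrt(variance))
  } else {
    dist_degenerate(mean)
  }
}
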