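#' Conditional mean line of a phenotype given a predictor
#'
#' From summary statistics alone, the conditional mean of a phenotype `y`
#' at predictor value `x` is approximated by the simple-regression line
#' `g(y|x) = a + b x` with `b = s_{x,y}/s_x^2` and `a = ybar - b xbar`.
#' For binary phenotypes every estimated mean is subsequently restricted to
#' the open unit interval `(eps, 1 - eps)`.
#'
#' @param y_mean,x_mean means of phenotype and predictor.
#' @param x_var predictor sample variance; when 0 the line degenerates to
#'   the constant `ybar` (`b = 0`).
#' @param cov_xy sample covariance of predictor and phenotype.
#' @param binary is the phenotype binary (activates clamping on
#'   evaluation)?
#' @param eps clamp constant for binary means.
#' @return object of class `conditional_moments` with fields `a`, `b`,
#'   `is_binary`, `eps`; evaluate with [eval_conditional_mean()].
#' @export
conditional_mean <- function(y_mean, x_mean, x_var, cov_xy,
                             binary = FALSE, eps = 1e-6) {
  b <- if (x_var > 0) cov_xy / x_var else 0
  structure(list(a = y_mean - b * x_mean, b = b,
                 is_binary = isTRUE(binary), eps = eps),
            class = "conditional_moments")
}

#' @rdname conditional_mean
#' @param cm a `conditional_moments` object.
#' @param x predictor values (vectorized).
#' @export
eval_conditional_mean <- function(cm, x) {
  g <- cm$a + cm$b * x
  if (cm$is_binary) clamp_unit(g, cm$eps) else g
}

#' Conditional variance of a phenotype given a predictor
#'
#' Continuous phenotypes: the homoscedastic residual variance of the
#' conditional-mean line, `(n - 1)(s_y^2 - b s_{x,y})/(n - 2)`, constant in
#' `x` and floored at 0. Binary phenotypes: the Bernoulli variance of the
#' clamped conditional mean, `g(y|x)(1 - g(y|x))`, which varies with `x` —
#' evaluate it at specific `x` by passing them.
#'
#' @param cm [conditional_mean()] output for this phenotype/predictor pair.
#' @param y_var phenotype sample variance.
#' @param cov_xy predictor/phenotype sample covariance.
#' @param n sample size (`> 2`).
#' @param x predictor values at which to evaluate (required for binary
#'   phenotypes; ignored for continuous ones).
#' @return numeric: a single constant for continuous phenotypes, a vector
#'   along `x` for binary ones.
#' @export
conditional_variance <- function(cm, y_var, cov_xy, n, x = NULL) {
  if (cm$is_binary) {
    if (is.null(x)) stopf("binary conditional variance needs evaluation points x")
    g <- eval_conditional_mean(cm, x)
    g * (1 - g)
  } else {
    if (n <= 2) stopf("conditional variance needs n > 2")
    max(0, (n - 1) * (y_var - cm$b * cov_xy) / (n - 2))
  }
}

#' Sample partial correlation of two phenotypes given a predictor
#'
#' `(r12 - r_x1 r_x2) / sqrt((1 - r_x1^2)(1 - r_x2^2))`, returning 0 when
#' either predictor/phenotype correlation is 1 in magnitude, and clamped to
#' `[-1, 1]`. Under a joint linear relationship the expected conditional
#' correlation equals the partial correlation, which is why it stands in
#' for the conditional correlation at every predictor value.
#'
#' @param r12 marginal correlation of the two phenotypes.
#' @param r_x1,r_x2 correlations of the predictor with each phenotype.
#' @return partial correlation in `[-1, 1]`.
#' @examples
#' partial_correlation(0.5, 0.6, 0.5) # 0.2886751
#' partial_correlation(0.5, 1, 0.2)   # 0
#' @export
partial_correlation <- function(r12, r_x1, r_x2) {
  stopifnot(abs(r12) <= 1 + 1e-12, abs(r_x1) <= 1 + 1e-12,
            abs(r_x2) <= 1 + 1e-12)
  d1 <- 1 - r_x1^2
  d2 <- 1 - r_x2^2
  if (d1 <= 0 || d2 <= 0) return(0)
  clamp_corr((r12 - r_x1 * r_x2) / sqrt(d1 * d2))
}

#' Conditional covariance of two phenotypes given a predictor
#'
#' `h(y1, y2 | x) = r_partial * sqrt(h(y1|x) h(y2|x))`: the partial
#' correlation scaled by the conditional standard deviations.
#'
#' @param h1,h2 conditional variances at the evaluation points (scalars or
#'   vectors; recycled).
#' @param r_partial output of [partial_correlation()].
#' @return conditional covariance values.
#' @export
conditional_covariance <- function(h1, h2, r_partial) {
  r_partial * sqrt(pmax(h1, 0) * pmax(h2, 0))
}

#' Conditional mean of a phenotype product
#'
#' `g(w|x) = g(y1|x) g(y2|x) + h(y1, y2|x)`.
#'
#' @param g1,g2 conditional means of the two phenotypes at `x`.
#' @param h12 conditional covariance at `x`.
#' @return conditional product mean values.
#' @export
conditional_product_mean <- function(g1, g2, h12) {
  g1 * g2 + h12
}

#' Conditional variance of a phenotype product
#'
#' Default: the normal-theory variance of a product of two jointly
#' Gaussian variables with means `g1, g2`, variances `h1, h2` and
#' covariance `h12`:
#' `g1^2 h2 + g2^2 h1 + h1 h2 + 2 g1 g2 h12 + h12^2`.
#' `strict_printed = TRUE` switches to the alternative grouping
#' `h1 h2 + g1 h2 + g2 h1 + g_w h12` (conditional means entering linearly),
#' kept only for comparison; it is dimensionally inconsistent and is not
#' used anywhere by default. Results are floored at 0.
#'
#' @param g1,g2 conditional means at `x`.
#' @param h1,h2 conditional variances at `x`.
#' @param h12 conditional covariance at `x`.
#' @param strict_printed use the linear-in-means grouping (see Details).
#' @return conditional product variance values (`>= 0`).
#' @export
conditional_product_variance <- function(g1, g2, h1, h2, h12,
                                         strict_printed = FALSE) {
  v <- if (strict_printed) {
    gw <- conditional_product_mean(g1, g2, h12)
    h1 * h2 + g1 * h2 + g2 * h1 + gw * h12
  } else {
    g1^2 * h2 + g2^2 * h1 + h1 * h2 + 2 * g1 * g2 * h12 + h12^2
  }
  pmax(v, 0)
}

#' Sample mean of a phenotype product
#'
#' `wbar = ybar1 ybar2 + s12 (n - 1)/n`. This is an exact sample identity
#' (not an approximation): the mean of the elementwise product equals the
#' product of means plus the population-denominator covariance.
#'
#' @param mean1,mean2 phenotype means.
#' @param s12 phenotype sample covariance (`n - 1` denominator).
#' @param n sample size.
#' @return the product mean.
#' @examples
#' y1 <- c(1, 2, 3); y2 <- c(2, 2, 4)
#' product_mean(mean(y1), mean(y2), cov(y1, y2), 3) # = mean(y1 * y2) = 6
#' @export
product_mean <- function(mean1, mean2, s12, n) {
  mean1 * mean2 + s12 * (n - 1) / n
}

#' Covariance of a predictor with a phenotype product
#'
#' `s_{x,w} ~ E_f[(x - xbar) g(w|x)]`: the expectation of the centered
#' predictor times the conditional product mean, under the predictor's
#' assumed marginal law. Discrete predictors sum over their support;
#' Gaussian predictors swap the sum for a Gauss-Hermite integral.
#' Intercept-like (degenerate) predictors return 0.
#'
#' @param gw vectorized function giving `g(w|x)`.
#' @param dist the predictor's [pcss_dist].
#' @param x_mean the predictor's sample mean `xbar`.
#' @param gh Gauss-Hermite rule (Gaussian predictors only).
#' @return approximated sample covariance.
#' @export
cov_predictor_product <- function(gw, dist, x_mean, gh = NULL) {
  if (is.null(dist)) stopf("predictor has no marginal distribution")
  if (dist_is_degenerate(dist)) return(0)
  dist_expect(dist, function(x) (x - x_mean) * gw(x), gh = gh)
}

#' Sample variance of a phenotype product (one predictor's estimate)
#'
#' Law-of-total-variance grouping of the within/between decomposition over
#' the predictor's assumed law: for discrete support,
#' `[sum_x ((n f(x) - 1) h(w|x) + n f(x) (g(w|x) - wbar)^2)] / (n - 1)`;
#' for Gaussian predictors the sum-to-integral swap gives
#' `E[h(w|x)] + n/(n-1) E[(g(w|x) - wbar)^2]`. Floored at 0. The
#' model-level estimate takes the median of these across eligible
#' predictors (see [product_moments()]); binary products instead use the
#' exact Bernoulli form `wbar (1 - wbar) n/(n - 1)`.
#'
#' @param gw,hw vectorized functions giving `g(w|x)` and `h(w|x)`.
#' @param dist the predictor's [pcss_dist].
#' @param w_mean the product mean from [product_mean()].
#' @param n sample size.
#' @param gh Gauss-Hermite rule (Gaussian predictors only).
#' @return variance estimate (`>= 0`).
#' @export
product_variance_one <- function(gw, hw, dist, w_mean, n, gh = NULL) {
  if (dist_is_degenerate(dist)) {
    stopf("degenerate predictors do not contribute a variance estimate")
  }
  v <- if (dist$kind == "gaussian") {
    dist_expect(dist, hw, gh = gh) +
      n / (n - 1) * dist_expect(dist, function(x) (gw(x) - w_mean)^2,
                                gh = gh)
  } else {
    s <- dist$support
    f <- dist_mass(dist, s)
    sum((n * f - 1) * hw(s) + n * f * (gw(s) - w_mean)^2) / (n - 1)
  }
  max(v, 0)
}

#' Variance of a binary phenotype product
#'
#' Exact Bernoulli sample variance implied by the product mean:
#' `wbar (1 - wbar) n / (n - 1)`.
#'
#' @param w_mean product mean (clamped to the open unit interval upstream).
#' @param n sample size.
#' @return the variance.
#' @export
binary_product_variance <- function(w_mean, n) {
  w_mean * (1 - w_mean) * n / (n - 1)
}

# ---------------------------------------------------------------------------
# pair engine: full approximated moments of w = y1 * y2 given raw stats.
#
# y1, y2: list(mean, var, cov = named vector over predictor names,
#              binary = flag)
# s12:    sample covariance of y1 and y2
# preds:  named list; each element list(mean, var, dist, use_for_variance)
# binary_pair: both phenotypes binary -> Bernoulli conditional variances,
#              clamped means, exact Bernoulli product variance
#
# Returns list(mean, variance, cov_with (named), per_predictor_variance).
pair_product_moments <- function(y1, y2, s12, preds, n,
                                 binary_pair = FALSE, eps = 1e-6,
                                 gh = NULL, strict_printed = FALSE) {
  wbar <- product_mean(y1$mean, y2$mean, s12, n)
  if (binary_pair) wbar <- clamp_unit(wbar, eps)

  pn <- names(preds)
  cov_w <- stats::setNames(numeric(length(preds)), pn)
  var_est <- stats::setNames(rep(NA_real_, length(preds)), pn)

  v1 <- y1$var
  v2 <- y2$var
  r12 <- if (v1 > 0 && v2 > 0) {
    max(-1, min(1, s12 / sqrt(v1 * v2)))
  } else 0

  for (j in seq_along(preds)) {
    pr <- preds[[j]]
    if (dist_is_degenerate(pr$dist) || !(pr$var > 0)) {
      # intercept-like: covariance with the product is 0, no variance vote
      if (!dist_is_degenerate(pr$dist) && !(pr$var > 0)) {
        warnf("predictor '%s' has zero variance; treated as intercept-like",
              pn[j])
      }
      next
    }
    c1 <- y1$cov[[pn[j]]]
    c2 <- y2$cov[[pn[j]]]
    b1 <- c1 / pr$var
    b2 <- c2 / pr$var
    a1 <- y1$mean - b1 * pr$mean
    a2 <- y2$mean - b2 * pr$mean

    rx1 <- if (v1 > 0) max(-1, min(1, c1 / sqrt(pr$var * v1))) else 0
    rx2 <- if (v2 > 0) max(-1, min(1, c2 / sqrt(pr$var * v2))) else 0
    d1 <- 1 - rx1^2
    d2 <- 1 - rx2^2
    rp <- if (d1 <= 0 || d2 <= 0) 0 else
      max(-1, min(1, (r12 - rx1 * rx2) / sqrt(d1 * d2)))

    if (pr$dist$kind == "gaussian") {
      rule <- gh %||% gauss_hermite(64L)
      x <- pr$dist$params$mu + sqrt(2) * pr$dist$params$sigma * rule$nodes
      wt <- rule$weights / sqrt(pi)
      discrete <- FALSE
    } else {
      x <- pr$dist$support
      wt <- dist_mass(pr$dist, x)
      discrete <- TRUE
    }

    g1 <- a1 + b1 * x
    g2 <- a2 + b2 * x
    if (binary_pair) {
      g1 <- clamp_unit(g1, eps)
      g2 <- clamp_unit(g2, eps)
      h1 <- g1 * (1 - g1)
      h2 <- g2 * (1 - g2)
    } else {
      h1 <- max(0, (n - 1) * (v1 - b1 * c1) / (n - 2))
      h2 <- max(0, (n - 1) * (v2 - b2 * c2) / (n - 2))
    }
    h12 <- conditional_covariance(h1, h2, rp)
    gw <- conditional_product_mean(g1, g2, h12)
    if (binary_pair) gw <- clamp_unit(gw, eps)

    cov_w[j] <- sum(wt * (x - pr$mean) * gw)

    if (!binary_pair && isTRUE(pr$use_for_variance)) {
      hw <- conditional_product_variance(g1, g2, h1, h2, h12,
                                         strict_printed = strict_printed)
      var_est[j] <- if (discrete) {
        max(0, sum((n * wt - 1) * hw + n * wt * (gw - wbar)^2) / (n - 1))
      } else {
        max(0, sum(wt * hw) + n / (n - 1) * sum(wt * (gw - wbar)^2))
      }
    }
  }

  variance <- if (binary_pair) {
    binary_product_variance(wbar, n)
  } else {
    est <- var_est[!is.na(var_est)]
    if (length(est) == 1L) {
      est
    } else if (length(est)) {
      stats::median(est)
    } else {
      # no eligible predictor: unconditional normal-theory product variance
      y1$mean^2 * v2 + y2$mean^2 * v1 + v1 * v2 +
        2 * y1$mean * y2$mean * s12 + s12^2
    }
  }

  list(mean = wbar, variance = max(variance, 0), cov_with = cov_w,
       per_predictor_variance = var_est)
}

new_product_moments <- function(mean, variance, cov_with, label,
                                order_trace = NULL,
                                per_predictor_variance = NULL) {
  structure(list(mean = mean, variance = variance, cov_with = cov_with,
                 label = label, order_trace = order_trace,
                 per_predictor_variance = per_predictor_variance),
            class = "product_moments")
}

#' @export
print.product_moments <- function(x, digits = 6, ...) {
  cat(sprintf("<product_moments '%s'>\n  mean %.6g, variance %.6g\n",
              x$label, x$mean, x$variance))
  cat("  cov with:",
      paste(sprintf("%s=%.4g", names(x$cov_with), x$cov_with),
            collapse = ", "), "\n")
  if (!is.null(x$order_trace) && length(x$order_trace) > 1L) {
    cat(sprintf("  aggregated over %d multiplication orderings\n",
                length(x$order_trace)))
  }
  invisible(x)
}
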