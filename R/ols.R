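#' Reconstruct X'X from summary statistics
#'
#' For a design matrix `X` with column means `xbar` and sample covariance
#' `S(X)` (denominator `n - 1`), the cross-product matrix is the exact
#' identity `X'X = (n - 1) S(X) + n xbar xbar'`. No approximation is
#' involved.
#'
#' @param pcss a [pcss_set].
#' @param design character vector of design-column names (may include the
#'   intercept variable).
#' @return the `p x p` cross-product matrix with dimnames.
#' @examples
#' ipd <- cbind(x = c(0, 1, 2, 1))
#' ps <- pcss_set(4, colMeans(ipd), cov(ipd),
#'                list(pcss_variable("x", "predictor", "genotype",
#'                                   dist_genotype(0.5))))
#' reconstruct_xtx(ps, c("(Intercept)", "x"))
#' @export
reconstruct_xtx <- function(pcss, design) {
  stopifnot(inherits(pcss, "pcss_set"))
  i <- pcss_index(pcss, design)
  n <- pcss$n
  S <- pcss$covariance[i, i, drop = FALSE]
  xbar <- pcss$means[i]
  (n - 1) * S + n * tcrossprod(xbar)
}

#' Reconstruct X'w from summary statistics
#'
#' Exact identity `X'w = (n - 1) s_{w,x} + n wbar xbar` linking the
#' cross-product of the design with a response `w` to the response/design
#' covariances, the response mean, and the column means.
#'
#' @param cov_xw numeric vector of sample covariances between `w` and each
#'   design column.
#' @param w_mean mean of the response.
#' @param x_means design column means (same length as `cov_xw`).
#' @param n sample size.
#' @return numeric vector `X'w`.
#' @export
reconstruct_xtw <- function(cov_xw, w_mean, x_means, n) {
  if (length(cov_xw) != length(x_means)) {
    stopf("cov_xw (%d) and x_means (%d) lengths differ",
          length(cov_xw), length(x_means))
  }
  (n - 1) * cov_xw + n * w_mean * x_means
}

#' Fitted linear model reconstructed from summary statistics
#'
#' Given a response described only by its mean, variance, and covariance
#' with each design column (either a phenotype already in the PCSS set, or
#' the approximated moments of a phenotype product from
#' [product_moments()]), reconstructs the ordinary-least-squares fit:
#' `bhat = (X'X)^{-1} X'w`, `w'w = (n - 1) s_w^2 + n wbar^2`,
#' `sigma2 = (w'w - bhat' X'w)/(n - p)`, `Var(bhat) = sigma2 (X'X)^{-1}`.
#' When fed the exact sample moments of an IPD dataset this reproduces a
#' direct least-squares fit on that data to machine precision; with
#' approximated product moments it inherits their approximation error.
#'
#' Two-sided p-values use the t distribution with `n - p` degrees of
#' freedom. A numerically non-positive `sigma2` (possible because product
#' moments are approximations) is floored at `1e-12` with a warning and all
#' p-values then report 1. An `X'X` with condition number above
#' `condition_cap` fails loudly, naming the collinear columns.
#'
#' @param pcss a [pcss_set].
#' @param response a phenotype name present in `pcss`, or a
#'   [product_moments] object.
#' @param design character vector of design-column names; the PCSS
#'   intercept variable is prepended when `intercept = TRUE` and not
#'   already listed.
#' @param intercept include the intercept column (default `TRUE`).
#' @param condition_cap maximum allowed condition number of `X'X`.
#' @return an object of class `pcss_lm`: list with `beta`, `se`, `tstat`,
#'   `pvalue` (named vectors), `sigma2`, `df`, `n`, `p`, `response`.
#' @examples
#' ipd <- data.frame(g = c(0, 1, 2, 1, 0, 2), y = c(0.9, 2.1, 3.2, 1.8, 1.1, 2.9))
#' ps <- pcss_set(6, colMeans(ipd), cov(ipd),
#'                list(pcss_variable("g", "predictor", "genotype",
#'                                   dist_genotype(0.4)),
#'                     pcss_variable("y", "phenotype")))
#' fit <- ols_from_pcss(ps, "y", "g")
#' all.equal(unname(fit$beta), unname(coef(lm(y ~ g, ipd))))
#' @export
ols_from_pcss <- function(pcss, response, design, intercept = TRUE,
                          condition_cap = 1e10) {
  stopifnot(inherits(pcss, "pcss_set"))
  int_nm <- pcss_intercept_name(pcss)
  if (intercept) {
    if (is.null(int_nm)) stopf("pcss has no intercept variable")
    design <- union(int_nm, design)
  }
  p <- length(design)
  n <- pcss$n
  if (n <= p) stopf("n (%d) must exceed the number of design columns (%d)",
                    n, p)

  xtx <- reconstruct_xtx(pcss, design)

  if (inherits(response, "product_moments")) {
    w_mean <- response$mean
    w_var <- response$variance
    cov_xw <- response$cov_with[design]
    if (!is.null(int_nm) && int_nm %in% design) {
      cov_xw[match(int_nm, design)] <- 0
    }
    if (anyNA(cov_xw)) {
      stopf("product moments lack covariances for: %s",
            paste(design[is.na(cov_xw)], collapse = ", "))
    }
    resp_label <- response$label %||% "product"
  } else {
    j <- pcss_index(pcss, response)
    w_mean <- unname(pcss$means[j])
    w_var <- pcss$covariance[j, j]
    cov_xw <- pcss$covariance[j, pcss_index(pcss, design)]
    resp_label <- response
  }

  kap <- kappa(xtx, exact = TRUE)
  if (!is.finite(kap) || kap > condition_cap) {
    qr_ <- qr(xtx)
    bad <- design[qr_$pivot[seq.int(qr_$rank + 1L, length.out =
                                      p - qr_$rank)]]
    stopf("X'X is ill-conditioned (kappa = %.3g > %.3g); collinear column(s): %s",
          kap, condition_cap,
          if (length(bad)) paste(bad, collapse = ", ") else "<none isolated>")
  }

  xtw <- reconstruct_xtw(cov_xw, w_mean, pcss$means[design], n)
  beta <- drop(solve(xtx, xtw))
  wtw <- (n - 1) * w_var + n * w_mean^2
  sigma2 <- (wtw - sum(beta * xtw)) / (n - p)

  floored <- FALSE
  # <= 0 up to the rounding noise of the w'w - beta'X'w cancellation
  if (!is.finite(sigma2) ||
      sigma2 <= 1e-10 * max(1, abs(wtw)) / (n - p)) {
    warnf("residual variance %.3g <= 0 (approximated moments); floored at 1e-12, p-values report 1",
          sigma2)
    sigma2 <- 1e-12
    floored <- TRUE
  }

  vb <- sigma2 * diag(solve(xtx))
  se <- sqrt(pmax(vb, 0))
  tstat <- ifelse(se > 0, beta / se, NA_real_)
  pvalue <- 2 * stats::pt(-abs(tstat), df = n - p)
  pvalue[is.na(tstat)] <- 1
  if (floored) pvalue[] <- 1

  names(beta) <- names(se) <- names(tstat) <- names(pvalue) <- design
  structure(list(beta = beta, se = se, tstat = tstat, pvalue = pvalue,
                 sigma2 = sigma2, df = n - p, n = n, p = p,
                 sigma2_floored = floored, response = resp_label),
            class = "pcss_lm")
}

#' @export
print.pcss_lm <- function(x, digits = 4, ...) {
  cat(sprintf("Linear model for '%s' reconstructed from PCSS (n = %d, df = %d)\n",
              x$response, x$n, x$df))
  tab <- data.frame(Estimate = x$beta, `Std. Error` = x$se,
                    `t value` = x$tstat, `Pr(>|t|)` = x$pvalue,
                    check.names = FALSE)
  stats::printCoefmat(as.matrix(tab), digits = digits, ...)
  cat(sprintf("Residual variance: %.*g\n", digits, x$sigma2))
  invisible(x)
}

#' @export
coef.pcss_lm <- function(object, ...) object$beta
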