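# fixtures are built in code; no data files

# PCSS from an IPD matrix: predictors get empirical distribution descriptors
pcss_from_ipd <- function(dat, phenotypes, binary_phenos = FALSE,
                          genotype_cols = character(0)) {
  dat <- as.matrix(dat)
  n <- nrow(dat)
  means <- colMeans(dat)
  cv <- stats::cov(dat)
  vars <- lapply(colnames(dat), function(nm) {
    if (nm %in% phenotypes) {
      pcss_variable(nm, "phenotype",
                    if (binary_phenos) "binary" else "continuous")
    } else if (nm %in% genotype_cols) {
      pcss_variable(nm, "predictor", "genotype",
                    dist_genotype(min(max(means[nm] / 2, 1e-6), 1 - 1e-6)))
    } else if (all(dat[, nm] %in% c(0, 1))) {
      pcss_variable(nm, "predictor", "binary",
                    dist_bernoulli(min(max(means[nm], 1e-6), 1 - 1e-6)))
    } else {
      pcss_variable(nm, "predictor", "continuous",
                    dist_gaussian(means[nm], sqrt(cv[nm, nm])))
    }
  })
  pcss_set(n, means, cv, vars)
}

# random toy IPD: genotype + up to 2 continuous covariates + phenotypes
random_toy_ipd <- function(n = NULL, n_pred = NULL, n_pheno = 1L,
                           binary_phenos = FALSE) {
  n <- n %||% sample(20:200, 1)
  n_pred <- n_pred %||% sample(1:3, 1)
  g <- rbinom(n, 2, runif(1, 0.15, 0.5))
  if (length(unique(g)) == 1L) g[1:2] <- c(0L, 1L)
  X <- cbind(g = g)
  if (n_pred >= 2) X <- cbind(X, c1 = rnorm(n, 1, 2))
  if (n_pred >= 3) X <- cbind(X, c2 = rnorm(n))
  Y <- sapply(seq_len(n_pheno), function(k) {
    eta <- runif(1, 0.5, 2) + X %*% runif(n_pred, -0.3, 0.5)
    if (binary_phenos) rbinom(n, 1, plogis(drop(eta) - 1))
    else drop(eta) + rnorm(n, 0, runif(1, 0.5, 1.5))
  })
  colnames(Y) <- paste0("y", seq_len(n_pheno))
  list(X = X, Y = Y, n = n)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# bare product_moments container for feeding ols_from_pcss in tests
new_pm_for_test <- function(mean, variance, cov_with) {
  prodpcss:::new_product_moments(mean, variance, cov_with, label = "test")
}

# direct least-squares oracle via the textbook normal equations
direct_ols <- function(X, w) {
  X <- cbind(`(Intercept)` = 1, X)
  n <- nrow(X); p <- ncol(X)
  xtx <- crossprod(X)
  beta <- drop(solve(xtx, crossprod(X, w)))
  res <- drop(w - X %*% beta)
  sigma2 <- sum(res^2) / (n - p)
  se <- sqrt(sigma2 * diag(solve(xtx)))
  tstat <- beta / se
  list(beta = beta, se = se, tstat = tstat,
       pvalue = 2 * pt(-abs(tstat), n - p), sigma2 = sigma2)
}

# correlated binary toy dataset with genotype association
random_binary_toy <- function(n = 4000, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  g <- rbinom(n, 2, runif(1, 0.2, 0.5))
  b <- runif(2, -0.4, 0.6)
  y1 <- rbinom(n, 1, plogis(runif(1, -1, 0.5) + b[1] * g))
  y2 <- rbinom(n, 1, plogis(runif(1, -1, 0.5) + b[2] * g + 0.7 * y1))
  cbind(g = g, y1 = y1, y2 = y2)
}
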