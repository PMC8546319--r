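#' Simulation study configuration
#'
#' Describes one of the two simulation designs used to validate the
#' summary-statistic approximation against individual-level fits.
#'
#' `sim_config("null_type1")` draws, per replicate, a sample size, a MAF,
#' and phenotype marginals/correlations from the stated ranges, simulates a
#' genotype *independent* of the phenotypes, and is used to measure the
#' empirical Type I error of the summary-statistic test. The default
#' ranges are: `n ~ U{500..2000}`, `MAF ~ U(0.1, 0.5)`; continuous
#' phenotypes `mu ~ U(0.5, 3)`, `sigma ~ U(0.5, 2)`, `rho ~ U(0.1, 0.7)`;
#' binary phenotypes `mu ~ U(0.2, 0.8)`, `rho ~ U(0, 0.5)` subject to
#' Frechet feasibility (infeasible draws are resampled).
#'
#' `sim_config("factorial")` fixes a parameter setting (factor levels of a
#' 2^k design are laid over it by [run_comparison_experiment()]): genotype
#' at HWE, a binary covariate drawn from a logistic model of the genotype
#' (`x2 ~ Bernoulli(logit^-1(alpha2 x1))`), optionally a continuous
#' covariate with mean 0, variance 1 and correlation `alpha3` with the
#' genotype, and phenotypes from `u(y_k) = beta_k0 + sum_j x_j beta_kj +
#' e_k` with multivariate-normal errors (`u` identity for continuous
#' phenotypes, the logit of the success probability for binary ones).
#'
#' @param study `"null_type1"` or `"factorial"`.
#' @param m number of phenotypes.
#' @param phenotype_type `"continuous"` or `"binary"`.
#' @param n_range,maf_range,mu_range,sigma_range,rho_range sampling ranges
#'   for the null study (sigma ignored for binary phenotypes).
#' @param n,maf fixed values for the factorial study.
#' @param alpha2 logistic coefficient of the genotype in the binary
#'   covariate model.
#' @param alpha3 genotype/continuous-covariate correlation; `NULL` omits
#'   the continuous covariate.
#' @param beta `m x (p + 1)` coefficient matrix (intercept, then one
#'   column per predictor in order genotype, binary covariate, continuous
#'   covariate) for the factorial phenotype model.
#' @param sigma,rho error scales (length m) and correlation (scalar or
#'   m x m matrix) of the factorial phenotype errors.
#' @param replicates number of simulated datasets.
#' @param alphas significance thresholds at which rejection is tallied.
#' @param seed master seed; spawns one sub-seed per replicate.
#' @return object of class `sim_config`.
#' @export
sim_config <- function(study = c("null_type1", "factorial"),
                       m = 2L,
                       phenotype_type = c("continuous", "binary"),
                       n_range = c(500L, 2000L),
                       maf_range = c(0.1, 0.5),
                       mu_range = NULL,
                       sigma_range = c(0.5, 2),
                       rho_range = NULL,
                       n = 1000L, maf = 0.3,
                       alpha2 = 0.3, alpha3 = NULL,
                       beta = NULL, sigma = NULL, rho = NULL,
                       replicates = 1000L,
                       alphas = c(5e-2, 1e-3, 1e-5, 1e-6),
                       seed = 1L) {
  study <- match.arg(study)
  phenotype_type <- match.arg(phenotype_type)
  if (is.null(mu_range)) {
    mu_range <- if (phenotype_type == "continuous") c(0.5, 3) else c(0.2, 0.8)
  }
  if (is.null(rho_range)) {
    rho_range <- if (phenotype_type == "continuous") c(0.1, 0.7) else c(0, 0.5)
  }
  m <- as.integer(m)
  stopifnot(m >= 2L)
  if (study == "factorial") {
    p <- 2L + as.integer(!is.null(alpha3))
    if (is.null(beta)) beta <- matrix(0, m, p + 1L)
    beta <- as.matrix(beta)
    if (nrow(beta) != m || ncol(beta) != p + 1L) {
      stopf("beta must be %d x %d (intercept + %d predictors)", m, p + 1L, p)
    }
    if (is.null(sigma)) sigma <- rep(1, m)
    if (is.null(rho)) rho <- 0.3
    if (!is.matrix(rho)) {
      rho <- matrix(rho, m, m) + diag(1 - rho, m)
    }
  }
  structure(list(study = study, m = m, phenotype_type = phenotype_type,
                 n_range = n_range, maf_range = maf_range,
                 mu_range = mu_range, sigma_range = sigma_range,
                 rho_range = rho_range,
                 n = as.integer(n), maf = maf, alpha2 = alpha2,
                 alpha3 = alpha3, beta = beta, sigma = sigma, rho = rho,
                 replicates = as.integer(replicates), alphas = alphas,
                 seed = as.integer(seed)),
            class = "sim_config")
}

# --- correlated Bernoulli machinery (Gaussian copula) ----------------------

gauss_legendre <- function(k = 64L) {
  i <- seq_len(k - 1L)
  b <- i / sqrt(4 * i^2 - 1)
  J <- matrix(0, k, k)
  J[cbind(i, i + 1L)] <- b
  J[cbind(i + 1L, i)] <- b
  e <- eigen(J, symmetric = TRUE)
  ord <- order(e$values)
  # nodes on [0, 1]
  list(nodes = (e$values[ord] + 1) / 2, weights = e$vectors[1L, ord]^2)
}

.gl_cache <- new.env(parent = emptyenv())
gl_rule <- function(k = 64L) {
  key <- as.character(k)
  if (is.null(.gl_cache[[key]])) .gl_cache[[key]] <- gauss_legendre(k)
  .gl_cache[[key]]
}

# P(Z1 <= z1, Z2 <= z2) for standard bivariate normal with correlation r,
# by Gauss-Legendre quadrature of the probit representation
bvn_lower_prob <- function(z1, z2, r) {
  if (abs(r) >= 1) {
    return(if (r >= 1) stats::pnorm(min(z1, z2)) else
             max(0, stats::pnorm(z1) + stats::pnorm(z2) - 1))
  }
  gl <- gl_rule()
  p1 <- stats::pnorm(z1)
  qn <- stats::qnorm(gl$nodes * p1)
  p1 * sum(gl$weights * stats::pnorm((z2 - r * qn) / sqrt(1 - r^2)))
}

# latent Gaussian correlation reproducing a target Pearson correlation
# between Bernoulli(p1) and Bernoulli(p2); NA if infeasible
latent_bernoulli_corr <- function(p1, p2, rho, tol = 1e-6) {
  if (rho == 0) return(0)
  z1 <- stats::qnorm(p1)
  z2 <- stats::qnorm(p2)
  s <- sqrt(p1 * (1 - p1) * p2 * (1 - p2))
  target <- p1 * p2 + rho * s       # required P(Y1 = 1, Y2 = 1)
  f <- function(r) bvn_lower_prob(z1, z2, r) - target
  lo <- -0.9999
  hi <- 0.9999
  if (f(hi) < 0 || f(lo) > 0) return(NA_real_)
  stats::uniroot(f, c(lo, hi), tol = tol)$root
}

# draw n correlated Bernoulli vectors via a Gaussian copula with pairwise
# calibrated latent correlations; margins mu (length m), target Pearson
# correlations rho (m x m)
rbernoulli_correlated <- function(n, mu, rho_mat) {
  m <- length(mu)
  lat <- diag(m)
  for (k in seq_len(m - 1L)) {
    for (l in (k + 1L):m) {
      r <- latent_bernoulli_corr(mu[k], mu[l], rho_mat[k, l])
      if (is.na(r)) return(NULL)
      lat[k, l] <- lat[l, k] <- r
    }
  }
  ch <- tryCatch(chol(lat), error = function(e) NULL)
  if (is.null(ch)) return(NULL)
  z <- matrix(stats::rnorm(n * m), n, m) %*% ch
  y <- matrix(0L, n, m)
  for (k in seq_len(m)) y[, k] <- as.integer(z[, k] <= stats::qnorm(mu[k]))
  y
}

# random correlation matrix with off-diagonals drawn from rho_range,
# redrawn until positive definite
draw_corr_matrix <- function(m, rho_range, max_tries = 200L) {
  for (i in seq_len(max_tries)) {
    R <- diag(m)
    R[upper.tri(R)] <- stats::runif(m * (m - 1) / 2, rho_range[1],
                                    rho_range[2])
    R[lower.tri(R)] <- t(R)[lower.tri(R)]
    # a 2x2 correlation matrix with |rho| < 1 is always positive definite
    if (m <= 2L) {
      if (abs(R[1, 2]) < 1) return(R)
      next
    }
    if (min(eigen(R, symmetric = TRUE, only.values = TRUE)$values) > 1e-8) {
      return(R)
    }
  }
  stopf("could not draw a positive-definite correlation matrix")
}

#' Simulate a null dataset (genotype independent of phenotypes)
#'
#' Per the Type-I-error design: the genotype is binomial(2, MAF) and
#' carries no association with any phenotype. Continuous phenotypes are
#' multivariate normal with the drawn means, scales, and correlations;
#' binary phenotypes are correlated Bernoulli variables generated through a
#' Gaussian copula whose latent correlation is calibrated to the target
#' Pearson correlation (infeasible targets are resampled). Simulation
#' parameters are drawn from the config's ranges on each call; seed the
#' R RNG beforehand for reproducibility.
#'
#' @param config a [sim_config] with `study = "null_type1"`.
#' @return an `ipd_dataset`: list with genotype/covariate matrix `X`,
#'   phenotype matrix `Y`, and the drawn `params`.
#' @export
simulate_null_dataset <- function(config) {
  stopifnot(inherits(config, "sim_config"),
            config$study == "null_type1")
  m <- config$m
  n <- sample.int(config$n_range[2] - config$n_range[1] + 1L, 1L) +
    config$n_range[1] - 1L
  maf <- stats::runif(1, config$maf_range[1], config$maf_range[2])
  g <- stats::rbinom(n, 2L, maf)

  mu <- stats::runif(m, config$mu_range[1], config$mu_range[2])
  if (config$phenotype_type == "continuous") {
    sd_ <- stats::runif(m, config$sigma_range[1], config$sigma_range[2])
    R <- draw_corr_matrix(m, config$rho_range)
    Y <- matrix(stats::rnorm(n * m), n, m) %*% chol(R)
    Y <- sweep(sweep(Y, 2, sd_, `*`), 2, mu, `+`)
    params <- list(n = n, maf = maf, mu = mu, sigma = sd_, rho = R)
  } else {
    repeat {
      R <- draw_corr_matrix(m, config$rho_range)
      Y <- rbernoulli_correlated(n, mu, R)
      if (!is.null(Y)) break
    }
    params <- list(n = n, maf = maf, mu = mu, rho = R)
  }
  colnames(Y) <- paste0("y", seq_len(m))
  structure(list(X = cbind(g = g), Y = Y, params = params,
                 phenotype_type = config$phenotype_type),
            class = "ipd_dataset")
}

#' Simulate a factorial-design dataset
#'
#' Genotype at HWE; binary covariate from a logistic model of the
#' genotype; optional continuous covariate correlated `alpha3` with the
#' genotype (mean 0, variance 1); phenotypes from the linear (or
#' logistic-link) model with multivariate-normal errors.
#'
#' @param config a [sim_config] with `study = "factorial"`.
#' @return an `ipd_dataset`.
#' @export
simulate_factorial_dataset <- function(config) {
  stopifnot(inherits(config, "sim_config"), config$study == "factorial")
  n <- config$n
  m <- config$m
  maf <- config$maf
  g <- stats::rbinom(n, 2L, maf)
  x2 <- stats::rbinom(n, 1L, stats::plogis(config$alpha2 * g))
  X <- cbind(g = g, x2 = x2)
  if (!is.null(config$alpha3)) {
    a3 <- config$alpha3
    gv <- 2 * maf * (1 - maf)
    x3 <- a3 * (g - 2 * maf) / sqrt(gv) +
      stats::rnorm(n, 0, sqrt(max(0, 1 - a3^2)))
    X <- cbind(X, x3 = x3)
  }
  Sig <- config$sigma %o% config$sigma * config$rho
  E <- matrix(stats::rnorm(n * m), n, m) %*% chol(Sig)
  eta <- cbind(1, X) %*% t(config$beta) + E
  Y <- if (config$phenotype_type == "continuous") {
    eta
  } else {
    matrix(stats::rbinom(n * m, 1L, stats::plogis(eta)), n, m)
  }
  colnames(Y) <- paste0("y", seq_len(m))
  structure(list(X = X, Y = Y,
                 params = list(n = n, maf = maf, alpha2 = config$alpha2,
                               alpha3 = config$alpha3, beta = config$beta,
                               sigma = config$sigma, rho = config$rho),
                 phenotype_type = config$phenotype_type),
            class = "ipd_dataset")
}

#' Exact summary statistics of a simulated dataset
#'
#' Computes the sample means and `n - 1` covariances of every column of an
#' individual-level dataset and attaches the generating marginal
#' distribution descriptors: the genotype's HWE law at the true MAF,
#' Bernoulli/Gaussian descriptors (from sample moments) for covariates.
#' Feeding the result to [ols_from_pcss()] with a phenotype response
#' reproduces the direct least-squares fit on the data exactly.
#'
#' @param ipd an `ipd_dataset`.
#' @return a [pcss_set] (with intercept variable appended).
#' @export
exact_pcss_from_ipd <- function(ipd) {
  stopifnot(inherits(ipd, "ipd_dataset"))
  dat <- cbind(ipd$X, ipd$Y)
  n <- nrow(dat)
  means <- colMeans(dat)
  covm <- stats::cov(dat)
  ptype <- if (identical(ipd$phenotype_type, "binary")) "binary"
           else "continuous"
  vars <- vector("list", ncol(dat))
  for (j in seq_len(ncol(dat))) {
    nm <- colnames(dat)[j]
    if (nm %in% colnames(ipd$Y)) {
      vars[[j]] <- pcss_variable(nm, "phenotype", ptype)
    } else if (nm == "g") {
      # the attached allele frequency is the sample frequency, as published
      # by PCSS repositories: the assumed law's mean must match the sample
      # mean or constant terms of g(w|x) leak into the covariance
      # expectation and inflate its sampling noise
      vars[[j]] <- pcss_variable(nm, "predictor", "genotype",
                                 dist_genotype(
                                   min(max(means[j] / 2, 1e-6), 1 - 1e-6)))
    } else if (all(dat[, j] %in% c(0, 1))) {
      p <- clamp_unit(means[j])
      vars[[j]] <- pcss_variable(nm, "predictor", "binary",
                                 dist_bernoulli(p))
    } else {
      vars[[j]] <- pcss_variable(nm, "predictor", "continuous",
                                 dist_gaussian(means[j],
                                               sqrt(covm[j, j])))
    }
  }
  pcss_set(n = n, means = means, covariance = covm, variables = vars)
}

#' Direct individual-level oracle fit
#'
#' Forms the literal elementwise product (or logical combination) of the
#' phenotypes and fits ordinary least squares on the individual-level
#' data; for binary combinations a covariate-adjusted logistic regression
#' can be fit instead. This is the oracle the summary-statistic
#' approximation is judged against.
#'
#' @param ipd an `ipd_dataset`.
#' @param phenotypes phenotype column names to combine (default: all).
#' @param op `"product"`, `"and"`, or `"or"`.
#' @param design predictor column names (default: all columns of `X`).
#' @param logistic fit logistic instead of linear regression (binary
#'   combinations only).
#' @return a `pcss_lm`-shaped fit (coefficients, SEs, t/z statistics,
#'   two-sided p-values).
#' @export
ipd_oracle_fit <- function(ipd, phenotypes = colnames(ipd$Y),
                           op = c("product", "and", "or"),
                           design = colnames(ipd$X), logistic = FALSE) {
  stopifnot(inherits(ipd, "ipd_dataset"))
  op <- match.arg(op)
  Y <- ipd$Y[, phenotypes, drop = FALSE]
  w <- switch(op,
    product = apply(Y, 1, prod),
    and = as.numeric(rowSums(Y == 1) == ncol(Y)),
    or = as.numeric(rowSums(Y == 1) > 0))
  X <- cbind(`(Intercept)` = 1, ipd$X[, design, drop = FALSE])
  n <- nrow(X)
  p <- ncol(X)
  if (logistic) {
    fit <- stats::glm.fit(X, w, family = stats::binomial())
    sm <- glm_wald_summary(fit, X)
    return(structure(list(beta = sm$beta, se = sm$se, tstat = sm$z,
                          pvalue = sm$p, sigma2 = NA_real_, df = n - p,
                          n = n, p = p, sigma2_floored = FALSE,
                          response = paste0("logit[", paste(phenotypes,
                            collapse = switch(op, product = "*", and = "&",
                                              or = "|")), "]")),
                     class = "pcss_lm"))
  }
  fit <- stats::lm.fit(X, w)
  res <- fit$residuals
  sigma2 <- sum(res^2) / (n - p)
  XtXinv <- chol2inv(fit$qr$qr[seq_len(p), seq_len(p), drop = FALSE])
  # undo pivoting
  piv <- fit$qr$pivot
  XtXinv <- XtXinv[order(piv), order(piv), drop = FALSE]
  se <- sqrt(sigma2 * diag(XtXinv))
  beta <- fit$coefficients[colnames(X)]
  tstat <- beta / se
  pvalue <- 2 * stats::pt(-abs(tstat), df = n - p)
  names(se) <- names(tstat) <- names(pvalue) <- colnames(X)
  structure(list(beta = beta, se = se, tstat = tstat, pvalue = pvalue,
                 sigma2 = sigma2, df = n - p, n = n, p = p,
                 sigma2_floored = FALSE,
                 response = paste(phenotypes, collapse =
                   switch(op, product = "*", and = "&", or = "|"))),
            class = "pcss_lm")
}

# Wald summaries for a glm.fit object
glm_wald_summary <- function(fit, X) {
  p <- ncol(X)
  Rmat <- fit$qr$qr[seq_len(p), seq_len(p), drop = FALSE]
  covm <- chol2inv(Rmat)
  piv <- fit$qr$pivot
  covm <- covm[order(piv), order(piv), drop = FALSE]
  se <- sqrt(diag(covm))
  beta <- fit$coefficients
  z <- beta / se
  list(beta = beta, se = stats::setNames(se, names(beta)),
       z = z, p = 2 * stats::pnorm(-abs(z)))
}

# per-replicate sub-seeds below 2^31, derived from the master seed
spawn_seeds <- function(master, k) {
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed",
                                                      globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
  set.seed(master)
  sample.int(.Machine$integer.max, k)
}

#' Empirical Type I error of the summary-statistic product test
#'
#' Runs the null simulation study: per replicate, draws parameters from the
#' config ranges, simulates a dataset with the genotype independent of all
#' phenotypes, computes exact summary statistics, fits the
#' summary-statistic product model of all phenotypes on genotype +
#' intercept, and records the genotype's two-sided p-value. Reports the
#' empirical rejection rate at each threshold with Wilson 95%
#' Monte-Carlo confidence intervals.
#'
#' @param config a [sim_config] with `study = "null_type1"`.
#' @param progress print a progress message every this many replicates
#'   (0 = silent).
#' @return a `data.frame` (class `type1_result`) with columns `alpha`,
#'   `rejections`, `used`, `rate`, `mc_se`, `ci_lo`, `ci_hi`; the vector
#'   of p-values is attached as attribute `pvalues`.
#' @export
run_type1_experiment <- function(config, progress = 0L) {
  stopifnot(inherits(config, "sim_config"), config$study == "null_type1")
  reps <- config$replicates
  seeds <- spawn_seeds(config$seed, reps)
  pvals <- rep(NA_real_, reps)
  phen <- paste0("y", seq_len(config$m))
  for (i in seq_len(reps)) {
    set.seed(seeds[i])
    pvals[i] <- tryCatch({
      ipd <- simulate_null_dataset(config)
      ps <- exact_pcss_from_ipd(ipd)
      fit <- suppressWarnings(product_model(ps, phen, design = "g"))
      fit$pvalue[["g"]]
    }, error = function(e) NA_real_)
    if (progress > 0L && i %% progress == 0L) {
      message(sprintf("  type1 replicate %d/%d", i, reps))
    }
  }
  used <- sum(!is.na(pvals))
  out <- do.call(rbind, lapply(config$alphas, function(a) {
    x <- sum(pvals < a, na.rm = TRUE)
    ci <- wilson_ci(x, used)
    data.frame(alpha = a, rejections = x, used = used, rate = x / used,
               mc_se = sqrt(a * (1 - a) / used),
               ci_lo = ci[1], ci_hi = ci[2])
  }))
  attr(out, "pvalues") <- pvals
  attr(out, "config") <- config
  class(out) <- c("type1_result", class(out))
  out
}

wilson_ci <- function(x, n, conf = 0.95) {
  z <- stats::qnorm(1 - (1 - conf) / 2)
  ph <- x / n
  den <- 1 + z^2 / n
  ctr <- (ph + z^2 / (2 * n)) / den
  hw <- z * sqrt(ph * (1 - ph) / n + z^2 / (4 * n^2)) / den
  c(max(0, ctr - hw), min(1, ctr + hw))
}

#' Factorial comparison of summary-statistic and individual-level fits
#'
#' Runs a 2^k factorial study: for every combination of the supplied
#' two-level factors, simulates `replicates` datasets, fits the genotype
#' model for the phenotype product both from exact summary statistics and
#' directly on the individual-level data, and summarizes the genotype
#' coefficient's estimation error (bias and MSE of the slope, its standard
#' error, and the absolute t statistic) plus test-decision disagreement
#' rates across significance thresholds. For binary phenotypes a
#' logistic-regression oracle can be compared as well.
#'
#' @param config a [sim_config] with `study = "factorial"` holding the
#'   base parameter setting.
#' @param factors named list of length-2 vectors; names must be
#'   `sim_config` fields (`n`, `maf`, `alpha2`, `alpha3`) or `beta_snp`
#'   (the genotype effect on the first phenotype). Defaults to a 2^3
#'   design over `n`, `maf`, and `beta_snp`.
#' @param replicates simulated datasets per cell.
#' @param alphas significance thresholds for the decision comparison.
#' @param logistic_oracle also fit the logistic oracle (binary phenotypes).
#' @param progress print progress per cell.
#' @return list of class `comparison_result` with elements `cells`
#'   (per-cell error summaries), `overall` (aggregated bias/MSE and the
#'   mean IPD slope), and `decisions` (per-alpha disagreement rates:
#'   overall, reject-given-IPD-fail, fail-given-IPD-reject, and against
#'   the logistic oracle when requested).
#' @export
run_comparison_experiment <- function(config,
                                      factors = list(
                                        n = c(500L, 1500L),
                                        maf = c(0.1, 0.4),
                                        beta_snp = c(0, 0.3)),
                                      replicates = 1000L,
                                      alphas = 10^-(1:8),
                                      logistic_oracle =
                                        config$phenotype_type == "binary",
                                      progress = FALSE) {
  stopifnot(inherits(config, "sim_config"), config$study == "factorial")
  grid <- expand.grid(factors, KEEP.OUT.ATTRS = FALSE)
  seeds <- spawn_seeds(config$seed, nrow(grid))
  phen <- paste0("y", seq_len(config$m))
  op <- if (config$phenotype_type == "binary") "and" else "product"

  cell_rows <- vector("list", nrow(grid))
  dec <- vector("list", nrow(grid))
  for (ci in seq_len(nrow(grid))) {
    cfg <- config
    for (f in names(factors)) {
      if (f == "beta_snp") cfg$beta[1, 2] <- grid[ci, f]
      else cfg[[f]] <- grid[ci, f]
    }
    set.seed(seeds[ci])
    res <- matrix(NA_real_, replicates, 9,
                  dimnames = list(NULL, c("b_p", "se_p", "t_p", "p_p",
                                          "b_i", "se_i", "t_i", "p_i",
                                          "p_log")))
    for (r in seq_len(replicates)) {
      ok <- tryCatch({
        ipd <- simulate_factorial_dataset(cfg)
        ps <- exact_pcss_from_ipd(ipd)
        pf <- suppressWarnings(
          if (op == "and") and_model(ps, phen, design = colnames(ipd$X))
          else product_model(ps, phen, design = colnames(ipd$X)))
        of <- ipd_oracle_fit(ipd, phen, op = op)
        res[r, 1:8] <- c(pf$beta[["g"]], pf$se[["g"]],
                         abs(pf$tstat[["g"]]), pf$pvalue[["g"]],
                         of$beta[["g"]], of$se[["g"]],
                         abs(of$tstat[["g"]]), of$pvalue[["g"]])
        if (logistic_oracle) {
          lf <- ipd_oracle_fit(ipd, phen, op = op, logistic = TRUE)
          res[r, 9] <- lf$pvalue[["g"]]
        }
        TRUE
      }, error = function(e) FALSE)
    }
    res <- res[stats::complete.cases(res[, 1:8]), , drop = FALSE]
    cell_rows[[ci]] <- data.frame(
      grid[ci, , drop = FALSE],
      used = nrow(res),
      ipd_mean_beta = mean(res[, "b_i"]),
      bias_beta = mean(res[, "b_p"] - res[, "b_i"]),
      mse_beta = mean((res[, "b_p"] - res[, "b_i"])^2),
      bias_se = mean(res[, "se_p"] - res[, "se_i"]),
      mse_se = mean((res[, "se_p"] - res[, "se_i"])^2),
      bias_t = mean(res[, "t_p"] - res[, "t_i"]),
      mse_t = mean((res[, "t_p"] - res[, "t_i"])^2),
      row.names = NULL)
    dec[[ci]] <- res
    if (progress) message(sprintf("  cell %d/%d done", ci, nrow(grid)))
  }

  cells <- do.call(rbind, cell_rows)
  all_res <- do.call(rbind, dec)
  decisions <- do.call(rbind, lapply(alphas, function(a) {
    rp <- all_res[, "p_p"] < a
    ri <- all_res[, "p_i"] < a
    row <- data.frame(
      alpha = a,
      disagree = mean(rp != ri),
      pcss_reject_given_ipd_fail = if (any(!ri)) mean(rp[!ri]) else NA,
      pcss_fail_given_ipd_reject = if (any(ri)) mean(!rp[ri]) else NA)
    if (logistic_oracle) {
      rl <- all_res[, "p_log"] < a
      row$disagree_logistic <- mean(rp != rl, na.rm = TRUE)
    }
    row
  }))
  overall <- data.frame(
    used = nrow(all_res),
    ipd_mean_beta = mean(all_res[, "b_i"]),
    ipd_mean_abs_beta = mean(abs(all_res[, "b_i"])),
    bias_beta = mean(all_res[, "b_p"] - all_res[, "b_i"]),
    mse_beta = mean((all_res[, "b_p"] - all_res[, "b_i"])^2),
    bias_se = mean(all_res[, "se_p"] - all_res[, "se_i"]),
    mse_se = mean((all_res[, "se_p"] - all_res[, "se_i"])^2),
    bias_t = mean(all_res[, "t_p"] - all_res[, "t_i"]),
    mse_t = mean((all_res[, "t_p"] - all_res[, "t_i"])^2))
  structure(list(cells = cells, overall = overall, decisions = decisions,
                 config = config, factors = factors,
                 replicates = replicates),
            class = "comparison_result")
}

#' @export
print.comparison_result <- function(x, ...) {
  cat(sprintf("Factorial comparison: %d cells x %d replicates\n",
              nrow(x$cells), x$replicates))
  cat("Overall errors (summary-statistic fit minus individual-level fit):\n")
  print(x$overall, ...)
  cat("Decision disagreement rates:\n")
  print(x$decisions, ...)
  invisible(x)
}
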