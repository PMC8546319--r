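# recursion, permutation medians, and logical combinations

test_that("combination_spec validates its inputs", {
  sp <- combination_spec(c("a", "b", "c"), "product")
  expect_s3_class(sp, "combination_spec")
  expect_error(combination_spec("a"), "at least 2")
  expect_error(combination_spec(c("a", "a")), "duplicate")
})

test_that("ordering enumeration is m!/2 unique up to the first pair", {
  o3 <- prodpcss:::orderings_up_to_first_pair(3)
  expect_length(o3, 3)
  o4 <- prodpcss:::orderings_up_to_first_pair(4)
  expect_length(o4, 12)
  expect_true(all(vapply(o4, function(p) p[1] < p[2], logical(1))))
})

test_that("three-way product with a near-constant factor collapses to the pair model", {
  set.seed(61)
  n <- 2000
  g <- rbinom(n, 2, 0.3)
  z <- matrix(rnorm(2 * n), n, 2) %*% chol(matrix(c(1, .4, .4, 1), 2))
  y1 <- 1.5 + 0.2 * g + z[, 1]
  y2 <- 2.0 + 0.1 * g + z[, 2]
  y3 <- 1 + rnorm(n, 0, 1e-4)   # essentially the constant 1
  dat <- cbind(g = g, y1 = y1, y2 = y2, y3 = y3)
  ps <- pcss_from_ipd(dat, c("y1", "y2", "y3"), genotype_cols = "g")
  f3 <- product_model(ps, c("y1", "y2", "y3"), "g")
  f2 <- product_model(ps, c("y1", "y2"), "g")
  expect_equal(f3$beta[["g"]], f2$beta[["g"]], tolerance = 0.02)
  expect_equal(f3$beta[["(Intercept)"]], f2$beta[["(Intercept)"]],
               tolerance = 0.02)
})

test_that("permutation-median moments ignore the input ordering", {
  set.seed(62)
  toy <- random_toy_ipd(n = 500, n_pred = 2, n_pheno = 3)
  ps <- pcss_from_ipd(cbind(toy$X, toy$Y), c("y1", "y2", "y3"),
                      genotype_cols = "g")
  pa <- product_moments(ps, c("y1", "y2", "y3"), "g")
  pb <- product_moments(ps, c("y3", "y1", "y2"), "g")
  expect_equal(pa$mean, pb$mean, tolerance = 1e-12)
  expect_equal(pa$variance, pb$variance, tolerance = 1e-12)
  expect_equal(pa$cov_with, pb$cov_with, tolerance = 1e-12)
})

test_that("three-phenotype recursion tracks the individual-level product fit", {
  set.seed(63)
  n <- 5e4
  g <- rbinom(n, 2, 0.3)
  R <- matrix(0.3, 3, 3) + diag(0.7, 3)
  z <- matrix(rnorm(3 * n), n, 3) %*% chol(R)
  Y <- sweep(z * 0.8, 2, c(1.5, 2, 1.8), `+`) +
    g %o% c(0.15, 0.1, 0)
  colnames(Y) <- paste0("y", 1:3)
  dat <- cbind(g = g, Y)
  ps <- pcss_from_ipd(dat, colnames(Y), genotype_cols = "g")
  fp <- product_model(ps, colnames(Y), "g")
  w <- Y[, 1] * Y[, 2] * Y[, 3]
  oracle <- direct_ols(cbind(g = g), w)
  expect_equal(fp$beta[["g"]], oracle$beta[["g"]], tolerance = 0.05)
  expect_equal(fp$se[["g"]], oracle$se[["g"]], tolerance = 0.05)
})

test_that("m above the cap refuses with guidance and force overrides", {
  set.seed(64)
  toy <- random_toy_ipd(n = 300, n_pred = 1, n_pheno = 7)
  ps <- pcss_from_ipd(cbind(toy$X, toy$Y), paste0("y", 1:7),
                      genotype_cols = "g")
  expect_error(product_moments(ps, paste0("y", 1:7)), "cap")
  # with a tiny cap, force overrides with a warning
  expect_warning(
    pm <- product_moments(ps, paste0("y", 1:3), m_cap = 2L, force = TRUE),
    "cautiously")
  expect_s3_class(pm, "product_moments")
})

test_that("complement_stats flips means and predictor covariances only", {
  y1 <- c(0, 1, 1, 0, 1); y2 <- c(1, 1, 0, 0, 0); x <- c(0, 1, 2, 1, 0)
  dat <- cbind(x = x, y1 = y1, y2 = y2)
  ps <- pcss_from_ipd(dat, c("y1", "y2"), binary_phenos = TRUE,
                      genotype_cols = "x")
  cp <- complement_stats(ps, c("y1", "y2"))
  expect_equal(cp$means[["y1"]], 1 - mean(y1))
  expect_equal(cp$covariance["x", "y1"], cov(x, 1 - y1))
  expect_equal(cp$covariance["y1", "y2"], cov(1 - y1, 1 - y2))
  expect_equal(cp$covariance["y1", "y2"], cov(y1, y2))
  expect_equal(cp$covariance["y1", "y1"], var(y1))
  # involution
  cc <- complement_stats(cp, c("y1", "y2"))
  expect_equal(cc$means, ps$means)
  expect_equal(cc$covariance, ps$covariance)
  # single-phenotype complement flips its covariance with the other one
  c1 <- complement_stats(ps, "y1")
  expect_equal(c1$covariance["y1", "y2"], -cov(y1, y2))
  expect_error(complement_stats(pcss_from_ipd(dat, "y1",
                                              binary_phenos = FALSE), "y1"),
               "not binary")
})

test_that("De Morgan consistency holds exactly at the moment level", {
  set.seed(65)
  for (i in 1:10) {
    dat <- random_binary_toy(n = 1500)
    ps <- pcss_from_ipd(dat, c("y1", "y2"), binary_phenos = TRUE,
                        genotype_cols = "g")
    or_m <- prodpcss:::or_moments(ps, c("y1", "y2"), "g")
    and_comp <- product_moments(complement_stats(ps, c("y1", "y2")),
                                c("y1", "y2"), "g")
    expect_equal(or_m$mean, 1 - and_comp$mean, tolerance = 1e-12)
    expect_equal(or_m$variance, and_comp$variance, tolerance = 1e-12)
    expect_equal(or_m$cov_with, -and_comp$cov_with, tolerance = 1e-12)

    # coefficient identity: beta_or = e_intercept - beta_and(complements)
    f_or <- or_model(ps, c("y1", "y2"), "g")
    f_andc <- and_model(complement_stats(ps, c("y1", "y2")),
                        c("y1", "y2"), "g")
    e_int <- c(`(Intercept)` = 1, g = 0)
    expect_equal(f_or$beta, e_int - f_andc$beta, tolerance = 1e-10)
  }
})

test_that("and/or identity and absorbing elements", {
  set.seed(66)
  n <- 3000
  g <- rbinom(n, 2, 0.3)
  y1 <- rbinom(n, 1, plogis(-0.3 + 0.3 * g))
  # y2 nearly always 0: OR reduces to y1 alone
  y0 <- rbinom(n, 1, 0.002)
  dat <- cbind(g = g, y1 = y1, y2 = y0)
  ps <- pcss_from_ipd(dat, c("y1", "y2"), binary_phenos = TRUE,
                      genotype_cols = "g")
  f_or <- or_model(ps, c("y1", "y2"), "g")
  f_y1 <- ols_from_pcss(ps, "y1", "g")
  expect_equal(f_or$beta[["g"]], f_y1$beta[["g"]], tolerance = 0.02)

  # y2 nearly always 1: AND reduces to y1 alone
  dat2 <- cbind(g = g, y1 = y1, y2 = 1 - y0)
  ps2 <- pcss_from_ipd(dat2, c("y1", "y2"), binary_phenos = TRUE,
                       genotype_cols = "g")
  f_and <- and_model(ps2, c("y1", "y2"), "g")
  f_y1b <- ols_from_pcss(ps2, "y1", "g")
  expect_equal(f_and$beta[["g"]], f_y1b$beta[["g"]], tolerance = 0.05)

  # logical operators demand binary phenotypes
  toyc <- random_toy_ipd(n = 100, n_pred = 1, n_pheno = 2)
  psc <- pcss_from_ipd(cbind(toyc$X, toyc$Y), c("y1", "y2"),
                       genotype_cols = "g")
  expect_error(and_model(psc, c("y1", "y2")), "binary")
  expect_error(or_model(psc, c("y1", "y2")), "binary")
})

test_that("fitted intercept-only combination means stay in [0, 1]", {
  set.seed(67)
  for (i in 1:5) {
    dat <- random_binary_toy(n = 800)
    ps <- pcss_from_ipd(dat, c("y1", "y2"), binary_phenos = TRUE,
                        genotype_cols = "g")
    f_and <- and_model(ps, c("y1", "y2"), character(0))
    f_or <- or_model(ps, c("y1", "y2"), character(0))
    expect_gte(f_and$beta[["(Intercept)"]], 0)
    expect_lte(f_and$beta[["(Intercept)"]], 1)
    expect_gte(f_or$beta[["(Intercept)"]], 0)
    expect_lte(f_or$beta[["(Intercept)"]], 1)
  }
})

test_that("median over terms and median over coefficients roughly agree", {
  set.seed(68)
  n <- 2e4
  g <- rbinom(n, 2, 0.35)
  R <- matrix(0.35, 3, 3) + diag(0.65, 3)
  z <- matrix(rnorm(3 * n), n, 3) %*% chol(R)
  Y <- sweep(0.7 * z, 2, c(1.2, 1.8, 2.4), `+`) + g %o% c(0.1, 0.05, 0.08)
  colnames(Y) <- paste0("y", 1:3)
  ps <- pcss_from_ipd(cbind(g = g, Y), colnames(Y), genotype_cols = "g")
  fit_terms <- product_model(ps, colnames(Y), "g")

  # alternative aggregation: median of final coefficients across orderings
  ords <- prodpcss:::orderings_up_to_first_pair(3)
  betas <- vapply(ords, function(o) {
    r <- prodpcss:::product_moments_one_order(
      ps, colnames(Y)[o], "g", binary_product = FALSE, eps = 1e-6,
      gh = gauss_hermite(64L), strict_printed = FALSE)
    pm <- new_pm_for_test(r$mean, r$variance,
                          c(r$cov_with, `(Intercept)` = 0))
    ols_from_pcss(ps, pm, "g")$beta[["g"]]
  }, numeric(1))
  expect_equal(fit_terms$beta[["g"]], median(betas), tolerance = 0.05)
})
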