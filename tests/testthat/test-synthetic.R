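# synthetic data generation, exact PCSS extraction, and oracle fits

test_that("null datasets are reproducible and respect their margins", {
  cfg <- sim_config("null_type1", m = 2, replicates = 1, seed = 1)
  set.seed(99); d1 <- simulate_null_dataset(cfg)
  set.seed(99); d2 <- simulate_null_dataset(cfg)
  expect_identical(d1, d2)
  expect_true(all(d1$X[, "g"] %in% 0:2))
  expect_gte(d1$params$n, cfg$n_range[1])
  expect_lte(d1$params$n, cfg$n_range[2])

  # genotype frequencies close to HWE proportions at large n
  cfg_big <- sim_config("null_type1", m = 2, n_range = c(1e5L, 1e5L),
                        maf_range = c(0.3, 0.3))
  set.seed(100)
  d <- simulate_null_dataset(cfg_big)
  emp <- tabulate(d$X[, "g"] + 1L, 3) / 1e5
  expect_equal(emp, c(0.49, 0.42, 0.09), tolerance = 0.02)

  # continuous phenotype correlation near its target
  cfg_rho <- sim_config("null_type1", m = 2, n_range = c(1e5L, 1e5L),
                        rho_range = c(0.4, 0.4))
  set.seed(101)
  dr <- simulate_null_dataset(cfg_rho)
  expect_equal(cor(dr$Y)[1, 2], 0.4, tolerance = 0.02)
  expect_equal(mean(dr$Y[, 1]), dr$params$mu[1], tolerance = 0.05)

  # binary phenotypes: Bernoulli margins and copula-calibrated correlation
  cfg_b <- sim_config("null_type1", m = 2, phenotype_type = "binary",
                      n_range = c(1e5L, 1e5L), mu_range = c(0.35, 0.35),
                      rho_range = c(0.3, 0.3))
  set.seed(102)
  db <- simulate_null_dataset(cfg_b)
  expect_true(all(db$Y %in% 0:1))
  expect_equal(mean(db$Y[, 1]), 0.35, tolerance = 0.02)
  expect_equal(cor(db$Y)[1, 2], 0.3, tolerance = 0.03)
})

test_that("factorial datasets follow the generating model", {
  cfg <- default_factorial_config(m = 2, seed = 3)
  cfg$n <- 1e5L; cfg$maf <- 0.3
  cfg$beta[1, 2] <- 0.3
  set.seed(103)
  d <- simulate_factorial_dataset(cfg)
  # continuous covariate: mean 0, variance 1, correlation alpha3 with SNP
  expect_equal(mean(d$X[, "x3"]), 0, tolerance = 0.02)
  expect_equal(var(d$X[, "x3"]), 1, tolerance = 0.02)
  expect_equal(cor(d$X[, "g"], d$X[, "x3"]), cfg$alpha3, tolerance = 0.02)
  # binary covariate follows its logistic model in the genotype
  p_by_g <- tapply(d$X[, "x2"], d$X[, "g"], mean)
  expect_equal(as.numeric(p_by_g), plogis(cfg$alpha2 * (0:2)),
               tolerance = 0.02)
  # phenotype marginal moments match the linear-model algebra
  eta_mean <- cfg$beta[1, 1] + cfg$beta[1, 2] * 2 * cfg$maf +
    cfg$beta[1, 3] * mean(plogis(cfg$alpha2 * d$X[, "g"])) +
    cfg$beta[1, 4] * 0
  expect_equal(mean(d$Y[, 1]), eta_mean, tolerance = 0.02)

  # with all predictor effects zeroed the phenotypes decouple from the SNP
  # (covariate paths x2, x3 would otherwise carry an indirect association)
  cfg0 <- default_factorial_config(m = 2, seed = 4)
  cfg0$n <- 1e5L
  cfg0$beta[, -1] <- 0
  set.seed(104)
  d0 <- simulate_factorial_dataset(cfg0)
  expect_lt(abs(cor(d0$X[, "g"], d0$Y[, 1])), 0.02)
})

test_that("exact PCSS round-trips through the OLS reconstruction", {
  set.seed(105)
  cfg <- default_factorial_config(m = 2, seed = 5)
  cfg$n <- 800L
  ipd <- simulate_factorial_dataset(cfg)
  ps <- exact_pcss_from_ipd(ipd)
  expect_s3_class(ps, "pcss_set")
  # PSD covariance (Gram structure)
  ev <- eigen(ps$covariance, symmetric = TRUE, only.values = TRUE)$values
  expect_gte(min(ev), -1e-8)
  fit <- ols_from_pcss(ps, "y1", colnames(ipd$X))
  oracle <- direct_ols(ipd$X, ipd$Y[, 1])
  expect_equal(unname(fit$beta), unname(oracle$beta), tolerance = 1e-8)
  expect_equal(unname(fit$se), unname(oracle$se), tolerance = 1e-8)

  # constant column: zero variance recorded
  ipd2 <- ipd
  ipd2$Y[, 2] <- 3
  ps2 <- exact_pcss_from_ipd(ipd2)
  expect_equal(ps2$covariance["y2", "y2"], 0)
})

test_that("the IPD oracle agrees with textbook normal equations", {
  X <- cbind(g = c(0, 1, 2, 1, 0), x2 = c(1, 0, 1, 1, 0))
  Y <- cbind(y1 = c(1.2, 2.3, 3.1, 2.0, 0.9),
             y2 = c(0.5, 1.0, 1.8, 1.1, 0.7))
  ipd <- structure(list(X = X, Y = Y, params = list(maf = 0.4),
                        phenotype_type = "continuous"),
                   class = "ipd_dataset")
  fit <- ipd_oracle_fit(ipd, c("y1", "y2"), op = "product")
  oracle <- direct_ols(X, Y[, 1] * Y[, 2])
  expect_equal(unname(fit$beta), unname(oracle$beta), tolerance = 1e-10)
  expect_equal(unname(fit$se), unname(oracle$se), tolerance = 1e-10)
  expect_equal(unname(fit$pvalue), unname(oracle$pvalue),
               tolerance = 1e-10)

  # product of a phenotype with itself is regression on its square
  fit_sq <- ipd_oracle_fit(ipd, c("y1", "y1"), op = "product")
  oracle_sq <- direct_ols(X, Y[, 1]^2)
  expect_equal(unname(fit_sq$beta), unname(oracle_sq$beta),
               tolerance = 1e-10)
})

test_that("logistic and linear oracles agree on sign for separated data", {
  set.seed(106)
  n <- 4000
  g <- rbinom(n, 2, 0.4)
  y1 <- rbinom(n, 1, plogis(-1 + 0.8 * g))
  y2 <- rbinom(n, 1, plogis(-0.5 + 0.6 * g))
  ipd <- structure(list(X = cbind(g = g), Y = cbind(y1 = y1, y2 = y2),
                        params = list(maf = 0.4),
                        phenotype_type = "binary"),
                   class = "ipd_dataset")
  lin <- ipd_oracle_fit(ipd, op = "and")
  log_ <- ipd_oracle_fit(ipd, op = "and", logistic = TRUE)
  expect_equal(sign(lin$beta[["g"]]), sign(log_$beta[["g"]]))
  expect_lt(log_$pvalue[["g"]], 1e-4)
  # logistic Wald summaries match glm()
  gf <- glm(I(y1 & y2) ~ g, family = binomial())
  expect_equal(unname(log_$beta), unname(coef(gf)), tolerance = 1e-6)
  expect_equal(unname(log_$se), unname(summary(gf)$coefficients[, 2]),
               tolerance = 1e-6)
})

test_that("type-1 experiment tables are deterministic and monotone", {
  cfg <- sim_config("null_type1", m = 2, replicates = 150, seed = 11,
                    alphas = c(0.05, 0.01, 0.001))
  r1 <- run_type1_experiment(cfg)
  r2 <- run_type1_experiment(cfg)
  expect_equal(as.data.frame(r1), as.data.frame(r2))
  expect_true(all(diff(r1$rejections) <= 0))
  expect_true(all(r1$ci_lo <= r1$rate & r1$rate <= r1$ci_hi))
  expect_equal(r1$used[1], 150)
})

test_that("feeding exact product moments isolates approximation error", {
  # when the PCSS model receives the realized product's exact moments the
  # reconstruction equals the IPD fit identically
  set.seed(107)
  cfg <- default_factorial_config(m = 2, seed = 7)
  cfg$n <- 600L
  ipd <- simulate_factorial_dataset(cfg)
  ps <- exact_pcss_from_ipd(ipd)
  w <- ipd$Y[, 1] * ipd$Y[, 2]
  pm <- new_pm_for_test(mean(w), var(w),
                        c(cov(w, ipd$X)[1, ], `(Intercept)` = 0))
  fit <- ols_from_pcss(ps, pm, colnames(ipd$X))
  oracle <- ipd_oracle_fit(ipd, op = "product")
  expect_equal(unname(fit$beta), unname(oracle$beta), tolerance = 1e-10)
  expect_equal(unname(fit$se), unname(oracle$se), tolerance = 1e-10)
})

test_that("comparison experiment runs and reports coherent summaries", {
  cfg <- default_factorial_config(m = 2, seed = 13)
  cr <- run_comparison_experiment(cfg,
                                  factors = list(maf = c(0.15, 0.4),
                                                 beta_snp = c(0, 0.3)),
                                  replicates = 40,
                                  alphas = c(1e-1, 1e-3))
  expect_equal(nrow(cr$cells), 4)
  expect_true(all(cr$cells$used > 0))
  expect_equal(nrow(cr$decisions), 2)
  expect_true(all(cr$decisions$disagree >= 0 & cr$decisions$disagree <= 1))
  # null cells: mean SNP coefficient near zero
  null_cells <- cr$cells[cr$cells$beta_snp == 0, ]
  expect_lt(max(abs(null_cells$ipd_mean_beta)), 0.1)
})
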