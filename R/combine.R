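#' Specification of a phenotype combination
#'
#' @param phenotypes ordered character vector of phenotype names (m >= 2).
#' @param op `"product"` (Hadamard product), `"and"` (conjunction of binary
#'   phenotypes), or `"or"` (disjunction of binary phenotypes).
#' @param design predictor names for the downstream model; `NULL` means all
#'   predictor-role variables of the PCSS set.
#' @param intercept include an intercept column.
#' @return object of class `combination_spec`.
#' @export
combination_spec <- function(phenotypes, op = c("product", "and", "or"),
                             design = NULL, intercept = TRUE) {
  op <- match.arg(op)
  phenotypes <- as.character(phenotypes)
  if (length(phenotypes) < 2L) stopf("a combination needs at least 2 phenotypes")
  if (anyDuplicated(phenotypes)) stopf("duplicate phenotype names")
  structure(list(phenotypes = phenotypes, op = op, design = design,
                 intercept = isTRUE(intercept)),
            class = "combination_spec")
}

#' @export
print.combination_spec <- function(x, ...) {
  sep <- switch(x$op, product = " * ", and = " & ", or = " | ")
  cat(sprintf("<combination_spec: %s>\n", paste(x$phenotypes, collapse = sep)))
  invisible(x)
}

# all permutations of 1..m, canonicalized so the first element index is
# smaller than the second (orderings unique up to the first two factors:
# m!/2 of them)
orderings_up_to_first_pair <- function(m) {
  perm <- function(v) {
    if (length(v) <= 1L) return(list(v))
    out <- list()
    for (i in seq_along(v)) {
      for (rest in perm(v[-i])) out[[length(out) + 1L]] <- c(v[i], rest)
    }
    out
  }
  ps <- perm(seq_len(m))
  Filter(function(p) p[1] < p[2], ps)
}

resolve_design <- function(pcss, design) {
  roles <- pcss_roles(pcss)
  if (is.null(design)) {
    names(which(roles == "predictor"))
  } else {
    i <- pcss_index(pcss, design)
    if (any(roles[i] == "phenotype")) {
      stopf("design names a phenotype: %s",
            paste(design[roles[i] == "phenotype"], collapse = ", "))
    }
    setdiff(design, names(which(roles == "intercept")))
  }
}

pred_entry <- function(pcss, name, use_for_variance) {
  v <- pcss$variables[[name]]
  m <- pcss$means[[name]]
  s2 <- pcss$covariance[name, name]
  dist <- v$distribution
  if (is.null(dist)) {
    dist <- default_phenotype_dist(v$vtype, m, s2)
  }
  list(mean = m, var = s2, dist = dist, use_for_variance = use_for_variance)
}

pheno_stats <- function(pcss, name, covnames) {
  list(mean = pcss$means[[name]],
       var = pcss$covariance[name, name],
       cov = stats::setNames(pcss$covariance[name, covnames], covnames),
       binary = identical(pcss$variables[[name]]$vtype, "binary"))
}

#' Approximated moments of a product of phenotypes
#'
#' Computes the mean, variance, and per-predictor covariances of the
#' elementwise product of `m >= 2` phenotypes from summary statistics
#' alone. For `m = 2` this is the direct conditional-moment approximation;
#' for `m > 2` the method is applied recursively (extend the running
#' product one phenotype at a time, re-expressing each needed
#' product/phenotype covariance as a predictor/product covariance with the
#' conditioning phenotype given its assumed marginal law). Because the
#' recursion depends on multiplication order, all `m!/2` orderings unique
#' up to the first two factors are evaluated and the median of each scalar
#' summary (mean, variance, each predictor covariance) across orderings is
#' taken.
#'
#' Intermediate partial products are treated as continuous even when the
#' factors are binary; the Bernoulli-specific estimators apply to the
#' two-binary base case and to the final overall mean/variance of an
#' all-binary product.
#'
#' @param pcss a [pcss_set].
#' @param phenotypes character vector of phenotype names (m >= 2).
#' @param design predictor names whose covariances with the product are
#'   needed; `NULL` means all predictor-role variables.
#' @param eps clamp constant for binary means.
#' @param gh_nodes Gauss-Hermite node count for Gaussian predictors.
#' @param strict_printed use the linear-in-means conditional product
#'   variance (comparison only; see [conditional_product_variance()]).
#' @param m_cap refuse products of more than this many phenotypes unless
#'   `force = TRUE` (approximation error compounds; combinations of five or
#'   more phenotypes warrant caution).
#' @param force override `m_cap` with a warning.
#' @return a `product_moments` object.
#' @export
product_moments <- function(pcss, phenotypes, design = NULL, eps = 1e-6,
                            gh_nodes = 64L, strict_printed = FALSE,
                            m_cap = 6L, force = FALSE) {
  stopifnot(inherits(pcss, "pcss_set"))
  m <- length(phenotypes)
  if (m < 2L) stopf("need at least two phenotypes")
  roles <- pcss_roles(pcss)[pcss_index(pcss, phenotypes)]
  if (any(roles != "phenotype")) {
    stopf("not phenotypes: %s", paste(phenotypes[roles != "phenotype"],
                                      collapse = ", "))
  }
  if (m > m_cap) {
    if (!force) {
      stopf(paste0("product of %d phenotypes exceeds the cap of %d; ",
                   "approximation error compounds with m and results for ",
                   "m >= 5 warrant caution. Pass force = TRUE to override."),
            m, m_cap)
    }
    warnf("product of %d phenotypes: use results cautiously", m)
  }
  design <- resolve_design(pcss, design)
  gh <- gauss_hermite(gh_nodes)

  all_binary <- all(vapply(phenotypes, function(p) {
    identical(pcss$variables[[p]]$vtype, "binary")
  }, logical(1)))

  ords <- orderings_up_to_first_pair(m)
  runs <- lapply(ords, function(ord) {
    product_moments_one_order(pcss, phenotypes[ord], design,
                              binary_product = all_binary, eps = eps,
                              gh = gh, strict_printed = strict_printed)
  })

  if (length(runs) == 1L) {
    w_mean <- runs[[1]]$mean
    w_var <- runs[[1]]$variance
    cov_w <- runs[[1]]$cov_with
  } else {
    # median of each scalar term across multiplication orderings
    agg <- function(get) {
      stats::median(vapply(runs, get, numeric(1)))
    }
    w_mean <- agg(function(r) r$mean)
    w_var <- agg(function(r) r$variance)
    cov_w <- vapply(design, function(j) {
      agg(function(r) r$cov_with[[j]])
    }, numeric(1))
  }
  int_nm <- pcss_intercept_name(pcss)
  if (!is.null(int_nm)) cov_w[int_nm] <- 0

  pm <- new_product_moments(
    mean = w_mean,
    variance = w_var,
    cov_with = cov_w,
    label = paste(phenotypes, collapse = "*"),
    order_trace = lapply(ords, function(o) phenotypes[o]),
    per_predictor_variance = runs[[1]]$per_predictor_variance)

  # implied predictor/product correlations must stay in [-1, 1]
  for (j in design) {
    sx2 <- pcss$covariance[j, j]
    if (sx2 > 0 && pm$variance > 0) {
      r <- pm$cov_with[[j]] / sqrt(sx2 * pm$variance)
      if (abs(r) > 1) {
        warnf("implied correlation of '%s' with %s is %.3f; clamped",
              j, pm$label, r)
        pm$cov_with[[j]] <- sign(r) * sqrt(sx2 * pm$variance)
      }
    }
  }
  pm
}

# one multiplication ordering of the recursion
product_moments_one_order <- function(pcss, phenos, design, binary_product,
                                      eps, gh, strict_printed) {
  m <- length(phenos)
  n <- pcss$n
  preds_design <- lapply(design, function(j) pred_entry(pcss, j, TRUE))
  names(preds_design) <- design

  binary_pair <- binary_product && m == 2L

  # running product state: mean, var, covariances with design predictors
  # and with the phenotypes not yet multiplied in
  cur <- pheno_stats(pcss, phenos[1], c(design, phenos[-1]))
  cur$binary <- FALSE

  for (l in 2:m) {
    yl <- pheno_stats(pcss, phenos[l], c(design, phenos[-seq_len(l)]))
    s12 <- cur$cov[[phenos[l]]]
    remaining <- if (l < m) phenos[(l + 1):m] else character(0)
    preds_rem <- lapply(remaining, function(r) pred_entry(pcss, r, FALSE))
    names(preds_rem) <- remaining
    preds <- c(preds_design, preds_rem)

    y1 <- list(mean = cur$mean, var = cur$var,
               cov = cur$cov[c(design, remaining)], binary = cur$binary)
    y2 <- list(mean = yl$mean, var = yl$var,
               cov = yl$cov[c(design, remaining)], binary = yl$binary)

    res <- pair_product_moments(y1, y2, s12, preds, n,
                                binary_pair = binary_pair && l == m,
                                eps = eps, gh = gh,
                                strict_printed = strict_printed)
    cur <- list(mean = res$mean, var = res$variance, cov = res$cov_with,
                binary = FALSE)
  }

  if (binary_product && m > 2L) {
    # the full product of binary phenotypes is itself binary
    cur$mean <- clamp_unit(cur$mean, eps)
    cur$var <- binary_product_variance(cur$mean, n)
  }

  list(mean = cur$mean, variance = cur$var,
       cov_with = cur$cov[design],
       per_predictor_variance = attr(cur, "per_predictor_variance"))
}

#' Complement binary phenotypes in a PCSS set
#'
#' Replaces each named binary phenotype `y` by `1 - y` ("not y") at the
#' summary-statistic level: means map to `1 - mean`, covariances with any
#' non-complemented variable flip sign, covariances among complemented
#' phenotypes and all variances are preserved. Applying the operation twice
#' is the identity.
#'
#' @param pcss a [pcss_set].
#' @param phenotypes names of the binary phenotypes to complement.
#' @return a new [pcss_set].
#' @export
complement_stats <- function(pcss, phenotypes) {
  stopifnot(inherits(pcss, "pcss_set"))
  i <- pcss_index(pcss, phenotypes)
  for (k in i) {
    v <- pcss$variables[[k]]
    if (!identical(v$vtype, "binary")) {
      stopf("'%s' is not binary; complement undefined", v$name)
    }
    pcss$means[k] <- 1 - pcss$means[k]
    pcss$covariance[k, ] <- -pcss$covariance[k, ]
    pcss$covariance[, k] <- -pcss$covariance[, k]
    # the double flip above restored the diagonal; fix covariances among
    # already-complemented phenotypes is automatic (two sign flips)
    if (!is.null(v$distribution) && v$distribution$kind == "bernoulli") {
      pcss$variables[[k]]$distribution <-
        dist_bernoulli(1 - v$distribution$params$p)
    }
  }
  validate_pcss_set(pcss)
  pcss
}

#' Regression models for products and logical combinations of phenotypes
#'
#' `product_model()` fits the covariate-adjusted linear model for the
#' Hadamard product of phenotypes from summary statistics: the product's
#' moments are approximated with [product_moments()] and the fit is
#' reconstructed with [ols_from_pcss()]. `and_model()` is the same fit for
#' the conjunction of binary phenotypes (their product). `or_model()` fits
#' the disjunction by complementing the phenotypes with
#' [complement_stats()], approximating the product of the complements, and
#' mapping the moments back (`wbar = 1 - wbar'`, predictor covariances
#' negated, variance preserved).
#'
#' @param pcss a [pcss_set].
#' @param phenotypes character vector of phenotype names (m >= 2); `and` /
#'   `or` require all of them binary.
#' @param design predictor names; `NULL` means all predictor-role
#'   variables.
#' @param intercept include the intercept column.
#' @param ... passed to [product_moments()] (`eps`, `gh_nodes`, `m_cap`,
#'   `force`, `strict_printed`).
#' @return a `pcss_lm` fit (see [ols_from_pcss()]).
#' @export
product_model <- function(pcss, phenotypes, design = NULL,
                          intercept = TRUE, ...) {
  design <- resolve_design(pcss, design)
  pm <- product_moments(pcss, phenotypes, design, ...)
  ols_from_pcss(pcss, pm, design, intercept = intercept)
}

check_all_binary <- function(pcss, phenotypes, op) {
  bad <- phenotypes[!vapply(phenotypes, function(p) {
    identical(pcss$variables[[p]]$vtype, "binary")
  }, logical(1))]
  if (length(bad)) {
    stopf("'%s' requires binary phenotypes; not binary: %s", op,
          paste(bad, collapse = ", "))
  }
}

#' @rdname product_model
#' @export
and_model <- function(pcss, phenotypes, design = NULL, intercept = TRUE,
                      ...) {
  check_all_binary(pcss, phenotypes, "and")
  product_model(pcss, phenotypes, design, intercept = intercept, ...)
}

#' @rdname product_model
#' @export
or_model <- function(pcss, phenotypes, design = NULL, intercept = TRUE,
                     ...) {
  check_all_binary(pcss, phenotypes, "or")
  pm <- or_moments(pcss, phenotypes, design, ...)
  design <- resolve_design(pcss, design)
  ols_from_pcss(pcss, pm, design, intercept = intercept)
}

# moments of the disjunction: 1 - prod(1 - y_k)
or_moments <- function(pcss, phenotypes, design = NULL, ...) {
  design <- resolve_design(pcss, design)
  comp <- complement_stats(pcss, phenotypes)
  pmc <- product_moments(comp, phenotypes, design, ...)
  new_product_moments(
    mean = 1 - pmc$mean,
    variance = pmc$variance,
    cov_with = -pmc$cov_with,
    label = paste(phenotypes, collapse = "|"),
    order_trace = pmc$order_trace)
}
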