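#' Genotype moments under Hardy-Weinberg equilibrium
#'
#' A biallelic minor allele count at HWE follows binomial(2, MAF), so its
#' mean is `2 maf` and its variance `2 maf (1 - maf)`. These population
#' moments stand in for missing genotype summary statistics; no
#' finite-sample correction is applied.
#'
#' @param maf minor allele frequency, in (0, 0.5].
#' @return named numeric vector `c(mean, variance)`.
#' @examples
#' hwe_moments(0.2) # mean 0.4, variance 0.32
#' @export
hwe_moments <- function(maf) {
  if (!is_number(maf) || maf <= 0 || maf > 0.5) {
    stopf("MAF must lie in (0, 0.5], got %s", format(maf))
  }
  c(mean = 2 * maf, variance = 2 * maf * (1 - maf))
}

#' Covariance of a genotype with a trait from its single-marker slope
#'
#' In the simple regression of a trait on a genotype the slope is
#' `b = s_{x,y} / s_x^2`, so the missing covariance is recovered as
#' `s_{x,y} = b * s_x^2`: the marginal slope multiplied by the genotype
#' variance.
#'
#' @param slope single-marker regression slope (trait on genotype).
#' @param genotype_variance genotype variance (e.g. from [hwe_moments()]).
#' @return the implied sample covariance.
#' @export
cov_from_marginal_slope <- function(slope, genotype_variance) {
  if (any(genotype_variance <= 0)) stopf("genotype variance must be > 0")
  slope * genotype_variance
}

#' Phenotype correlation from Z-statistic correlation at null markers
#'
#' The correlation of two traits can be approximated by the Pearson
#' correlation of their per-marker association Z statistics across markers
#' associated with neither trait. Markers are filtered to those with both
#' `|z|` below `assoc_threshold`; at least `min_markers` must survive.
#'
#' @param z1,z2 aligned numeric vectors of per-marker Z statistics for the
#'   two traits.
#' @param assoc_threshold drop markers with either `|z|` at or above this
#'   (default 2).
#' @param min_markers minimum surviving marker count (default 30).
#' @return estimated phenotype correlation, clamped to `[-1, 1]`.
#' @export
pheno_corr_from_z <- function(z1, z2, assoc_threshold = 2,
                              min_markers = 30L) {
  if (length(z1) != length(z2)) stopf("z vectors must be aligned")
  keep <- is.finite(z1) & is.finite(z2) &
    abs(z1) < assoc_threshold & abs(z2) < assoc_threshold
  if (sum(keep) < min_markers) {
    stopf("only %d markers survive the |z| < %g filter (need >= %d)",
          sum(keep), assoc_threshold, min_markers)
  }
  clamp_corr(stats::cor(z1[keep], z2[keep]))
}

#' Assemble a per-marker PCSS set from GWAS summary rows
#'
#' Combines a phenotype-block PCSS set (phenotype and covariate means and
#' covariances, typically shared across markers) with one marker's summary
#' row (MAF plus per-trait single-marker slopes) into a full [pcss_set]
#' for model fitting: the genotype's mean and variance come from
#' [hwe_moments()] and its covariance with each trait from
#' [cov_from_marginal_slope()]. User-supplied values take precedence over
#' derived ones; a missing slope for a modeled trait is an error. The
#' provenance of every derived cell is recorded.
#'
#' @param base a [pcss_set] over phenotypes and covariates (no genotype).
#' @param snp marker identifier (becomes the genotype variable name).
#' @param maf marker minor allele frequency.
#' @param slopes named numeric vector of single-marker slopes, one per
#'   base variable the genotype's covariance is needed with; variables
#'   without a slope get covariance `NA` and cannot enter a design.
#' @param n sample size for the assembled set (defaults to `base$n`).
#' @return list with `pcss` (the assembled [pcss_set]) and `provenance`
#'   (character vector describing each derived quantity).
#' @export
assemble_marker_pcss <- function(base, snp, maf, slopes, n = NULL) {
  stopifnot(inherits(base, "pcss_set"))
  n <- n %||% base$n
  hm <- hwe_moments(maf)
  prov <- c(sprintf("%s mean/variance derived from HWE with MAF %.4g",
                    snp, maf))
  base_names <- setdiff(names(base$means), pcss_intercept_name(base))
  cv <- stats::setNames(rep(0, length(base_names)), base_names)
  for (v in names(slopes)) {
    if (!v %in% base_names) stopf("slope given for unknown variable '%s'", v)
    cv[v] <- cov_from_marginal_slope(slopes[[v]], hm[["variance"]])
    prov <- c(prov, sprintf("cov(%s, %s) derived from slope %.4g", snp, v,
                            slopes[[v]]))
  }
  no_slope <- setdiff(base_names, names(slopes))
  if (length(no_slope)) {
    prov <- c(prov, sprintf("cov(%s, %s) assumed 0 (no slope provided)",
                            snp, paste(no_slope, collapse = "/")))
  }

  nm <- c(snp, names(base$means))
  means <- c(stats::setNames(hm[["mean"]], snp), base$means)
  k <- length(nm)
  covm <- matrix(0, k, k, dimnames = list(nm, nm))
  covm[names(base$means), names(base$means)] <- base$covariance
  covm[snp, snp] <- hm[["variance"]]
  covm[snp, base_names] <- cv
  covm[base_names, snp] <- cv

  vars <- c(list(pcss_variable(snp, "predictor", "genotype",
                               dist_genotype(maf))),
            unname(base$variables))
  ps <- pcss_set(n = n, means = means, covariance = covm, variables = vars,
                 intercept = is.null(pcss_intercept_name(base)))
  list(pcss = ps, provenance = prov)
}
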