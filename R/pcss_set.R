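#' Variable metadata for a summary-statistic set
#'
#' Describes one column of the (unobserved) subject-level data matrix: its
#' name, its role in downstream models, its type, and — for predictors that
#' enter the product-moment expectations — an assumed marginal distribution.
#'
#' @param name variable identifier.
#' @param role one of `"predictor"`, `"phenotype"`, `"intercept"`.
#' @param vtype one of `"continuous"`, `"binary"`, `"genotype"`.
#' @param distribution optional [pcss_dist]; phenotypes need none.
#' @return an object of class `pcss_variable`.
#' @export
pcss_variable <- function(name,
                          role = c("predictor", "phenotype", "intercept"),
                          vtype = c("continuous", "binary", "genotype"),
                          distribution = NULL) {
  role <- match.arg(role)
  vtype <- match.arg(vtype)
  stopifnot(is.character(name), length(name) == 1L, nzchar(name))
  if (!is.null(distribution) && !inherits(distribution, "pcss_dist")) {
    stopf("distribution for '%s' must be a pcss_dist", name)
  }
  if (role == "intercept" && is.null(distribution)) {
    distribution <- dist_degenerate(1)
  }
  structure(list(name = name, role = role, vtype = vtype,
                 distribution = distribution),
            class = "pcss_variable")
}

#' Pre-computed summary statistics (PCSS) set
#'
#' The complete information assumed available in place of individual
#' participant data: the sample size `n`, per-variable means, and the joint
#' sample variance-covariance matrix (denominator `n - 1`) over all
#' predictors and phenotypes, plus per-variable metadata. Everything the
#' package fits is computed from an object of this class.
#'
#' @param n positive integer sample size.
#' @param means named numeric vector of per-variable means.
#' @param covariance symmetric matrix with dimnames matching `means`;
#'   sample covariances with the `n - 1` denominator.
#' @param variables list of [pcss_variable] in the same order as `means`.
#' @param intercept if `TRUE`, append an intercept variable named
#'   `"(Intercept)"` (mean 1, all covariances 0) unless one is present.
#' @return an object of class `pcss_set`.
#' @examples
#' ipd <- cbind(g = c(0, 1, 2, 1), y = c(1, 2, 3, 2))
#' ps <- pcss_set(
#'   n = 4,
#'   means = colMeans(ipd),
#'   covariance = cov(ipd),
#'   variables = list(
#'     pcss_variable("g", "predictor", "genotype", dist_genotype(0.5)),
#'     pcss_variable("y", "phenotype", "continuous")
#'   )
#' )
#' ps
#' @export
pcss_set <- function(n, means, covariance, variables, intercept = TRUE) {
  if (!is_number(n) || n < 2 || n != round(n)) {
    stopf("n must be an integer sample size >= 2")
  }
  n <- as.integer(n)
  means <- as.numeric(means)
  covariance <- as.matrix(covariance)
  if (!all(vapply(variables, inherits, logical(1), "pcss_variable"))) {
    stopf("variables must be a list of pcss_variable objects")
  }
  nm <- vapply(variables, `[[`, character(1), "name")
  if (anyDuplicated(nm)) stopf("duplicate variable names")
  if (length(means) != length(nm) || any(dim(covariance) != length(nm))) {
    stopf("means (%d), covariance (%dx%d) and variables (%d) disagree",
          length(means), nrow(covariance), ncol(covariance), length(nm))
  }
  if (intercept && !any(vapply(variables, `[[`, character(1), "role") ==
                          "intercept")) {
    variables <- c(variables, list(
      pcss_variable("(Intercept)", "intercept", "continuous",
                    dist_degenerate(1))))
    means <- c(means, 1)
    covariance <- if (length(nm)) rbind(cbind(covariance, 0), 0)
                  else matrix(0, 1, 1)
    nm <- c(nm, "(Intercept)")
  }
  dimnames(covariance) <- list(nm, nm)
  names(means) <- nm
  obj <- structure(list(n = n, means = means, covariance = covariance,
                        variables = stats::setNames(variables, nm)),
                   class = "pcss_set")
  validate_pcss_set(obj)
  obj
}

validate_pcss_set <- function(x, tol = 1e-8) {
  cv <- x$covariance
  if (max(abs(cv - t(cv))) > tol * max(1, max(abs(cv)))) {
    stopf("covariance matrix is not symmetric")
  }
  if (any(diag(cv) < -tol)) stopf("negative variance on the diagonal")
  sd <- sqrt(pmax(diag(cv), 0))
  pos <- sd > 0
  if (any(pos)) {
    cr <- cv[pos, pos, drop = FALSE] / tcrossprod(sd[pos])
    if (max(abs(cr)) > 1 + tol) {
      stopf("implied correlations exceed 1 in magnitude (max %.6g)",
            max(abs(cr)))
    }
  }
  roles <- vapply(x$variables, `[[`, character(1), "role")
  ic <- which(roles == "intercept")
  if (length(ic) > 1L) stopf("at most one intercept variable is allowed")
  if (length(ic) == 1L) {
    if (abs(x$means[ic] - 1) > tol) stopf("intercept mean must be 1")
    if (any(abs(cv[ic, ]) > tol)) stopf("intercept covariances must be 0")
  }
  invisible(x)
}

#' @export
print.pcss_set <- function(x, ...) {
  roles <- vapply(x$variables, `[[`, character(1), "role")
  cat(sprintf("<pcss_set: n = %d, %d variables (%d predictors, %d phenotypes%s)>\n",
              x$n, length(x$means), sum(roles == "predictor"),
              sum(roles == "phenotype"),
              if (any(roles == "intercept")) ", intercept" else ""))
  df <- data.frame(
    role = roles,
    vtype = vapply(x$variables, `[[`, character(1), "vtype"),
    mean = x$means,
    variance = diag(x$covariance))
  print(df, ...)
  invisible(x)
}

#' Variable roles and the intercept name of a PCSS set
#'
#' Accessors: `pcss_roles` returns the named character vector of variable
#' roles; `pcss_intercept_name` returns the intercept variable's name, or
#' `NULL` when the set has none.
#'
#' @param pcss a [pcss_set].
#' @return see Description.
#' @export
pcss_roles <- function(pcss) {
  vapply(pcss$variables, `[[`, character(1), "role")
}

#' @rdname pcss_roles
#' @export
pcss_intercept_name <- function(pcss) {
  nm <- names(which(pcss_roles(pcss) == "intercept"))
  if (length(nm)) nm else NULL
}

pcss_index <- function(pcss, names) {
  i <- match(names, names(pcss$means))
  if (anyNA(i)) {
    stopf("unknown variable(s): %s",
          paste(names[is.na(i)], collapse = ", "))
  }
  i
}

#' Read / write a PCSS set as tab-separated text
#'
#' Two files define a set: a means file with columns
#' `variable, role, vtype, mean, dist_kind, dist_params` (`dist_params`
#' comma-separated, empty when no distribution is attached) and a covariance
#' file holding the square matrix with variable names as header row and
#' first column. `write_pcss` emits the same dialect, so write-then-read is
#' an exact round trip.
#'
#' @param means_file,cov_file paths to the two TSV files.
#' @param pcss a [pcss_set].
#' @return `read_pcss` returns a [pcss_set]; `write_pcss` returns the paths
#'   invisibly.
#' @export
read_pcss <- function(means_file, cov_file) {
  mt <- utils::read.delim(means_file, stringsAsFactors = FALSE,
                          colClasses = c(dist_params = "character"))
  need <- c("variable", "role", "vtype", "mean", "dist_kind", "dist_params")
  if (!all(need %in% names(mt))) {
    stopf("means file must have columns: %s", paste(need, collapse = ", "))
  }
  if (!"n" %in% names(mt)) stopf("means file must carry an 'n' column")
  n <- unique(mt$n)
  if (length(n) != 1L) stopf("inconsistent n in means file")
  vars <- lapply(seq_len(nrow(mt)), function(i) {
    d <- parse_dist(mt$dist_kind[i], mt$dist_params[i])
    pcss_variable(mt$variable[i], mt$role[i], mt$vtype[i], d)
  })
  cm <- as.matrix(utils::read.delim(cov_file, row.names = 1,
                                    check.names = FALSE))
  cm <- cm[mt$variable, mt$variable, drop = FALSE]
  pcss_set(n = n, means = stats::setNames(mt$mean, mt$variable),
           covariance = cm, variables = vars, intercept = FALSE)
}

parse_dist <- function(kind, params) {
  if (is.na(kind) || !nzchar(kind) || kind == "none") return(NULL)
  p <- as.numeric(strsplit(params, ",", fixed = TRUE)[[1]])
  switch(kind,
    genotype_hwe = dist_genotype(p[1]),
    bernoulli    = dist_bernoulli(p[1]),
    gaussian     = dist_gaussian(p[1], p[2]),
    degenerate   = dist_degenerate(p[1]),
    stopf("unknown dist_kind '%s'", kind))
}

#' @rdname read_pcss
#' @export
write_pcss <- function(pcss, means_file, cov_file) {
  stopifnot(inherits(pcss, "pcss_set"))
  kinds <- vapply(pcss$variables, function(v) {
    if (is.null(v$distribution)) "none" else v$distribution$kind
  }, character(1))
  params <- vapply(pcss$variables, function(v) {
    if (is.null(v$distribution)) "" else
      paste(format(unlist(v$distribution$params), digits = 17,
                   trim = TRUE), collapse = ",")
  }, character(1))
  mt <- data.frame(
    variable = names(pcss$means),
    role = pcss_roles(pcss),
    vtype = vapply(pcss$variables, `[[`, character(1), "vtype"),
    mean = format(pcss$means, digits = 17, trim = TRUE),
    dist_kind = kinds,
    dist_params = params,
    n = pcss$n)
  utils::write.table(mt, means_file, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  cm <- format(pcss$covariance, digits = 17, trim = TRUE)
  utils::write.table(cm, cov_file, sep = "\t", quote = FALSE,
                     col.names = NA)
  invisible(c(means_file, cov_file))
}
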