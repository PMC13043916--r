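#' Phylogenetic linear mixed model on individual-level data
#'
#' Fits `y = X beta + u + e` by maximum likelihood, where `u` is a
#' species-level random effect with covariance `sigma2_phylo * C` (`C` the
#' phylogenetic covariance) and `e` is i.i.d. within-individual noise with
#' variance `sigma2_resid`. This is the individual-level allometric regression:
#' the fixed effects can include the body-size covariate, sex and family
#' contrasts and their two-way interactions. The variance ratio
#' `sigma2_phylo / sigma2_resid` is profiled by one-dimensional ML; beta and
#' the residual variance have closed forms given the ratio. ML (not REML) is
#' used throughout so AIC is comparable across fixed-effect structures.
#'
#' Species present in the data but absent from the tree are an error, never
#' silently dropped.
#'
#' @param formula Fixed-effects formula on columns of `data` (see
#'   [allometry_formulas()] for the standard presets).
#' @param data Individual-level `"trait_table"` (log10 columns added if
#'   absent).
#' @param tree A `"phylo"` object covering all species.
#' @param species_col Name of the species column.
#' @return Object of class `"pglmm"` with `print`, `summary`, `coef`,
#'   `logLik` and `AIC` support.
#' @export
fit_pglmm <- function(formula, data, tree, species_col = "species") {
  if (inherits(data, "trait_table") && !isTRUE(attr(data, "log10")))
    data <- log10_traits(data)
  sp <- as.character(data[[species_col]])
  usp <- sort(unique(sp))
  if (length(usp) < 2) stop("need at least 2 species")
  missing <- setdiff(usp, tree$tip.label)
  if (length(missing))
    stop("species not on tree (refusing to drop them): ",
         paste(missing, collapse = ", "))
  C <- phylo_vcv(prune_phylogeny(tree, usp))[usp, usp]

  mf <- stats::model.frame(formula, data)
  y <- stats::model.response(mf)
  X <- stats::model.matrix(attr(mf, "terms"), mf)
  n <- length(y)
  Z <- matrix(0, n, length(usp))
  Z[cbind(seq_len(n), match(sp, usp))] <- 1
  M <- Z %*% C %*% t(Z)  # n x n species-level phylogenetic kernel

  prof_at <- function(theta) {
    R <- theta * M
    diag(R) <- diag(R) + 1
    .gls_profile(X, y, R)
  }
  obj <- function(ltheta) prof_at(exp(ltheta))$loglik
  opt <- stats::optimize(obj, c(-15, 10), maximum = TRUE, tol = 1e-7)
  # the no-phylogeny boundary theta = 0 is a valid optimum; check it explicitly
  prof0 <- .gls_profile(X, y, diag(n))
  if (prof0$loglik >= opt$objective) {
    theta <- 0; prof <- prof0
  } else {
    theta <- exp(opt$maximum); prof <- prof_at(theta)
  }

  beta <- drop(prof$beta); names(beta) <- colnames(X)
  p <- ncol(X)
  k <- p + 2L  # sigma2_phylo, sigma2_resid
  sigma2_resid <- prof$sigma2
  sigma2_phylo <- theta * sigma2_resid
  se <- sqrt(diag(prof$sigma2 * n / (n - p) * prof$XtX_inv))
  names(se) <- names(beta)
  zval <- beta / se
  pval <- 2 * stats::pnorm(-abs(zval))  # normal approximation, flagged

  out <- list(
    coefficients = beta, se = se, zval = zval, pval = pval,
    sigma2_phylo = sigma2_phylo, sigma2_resid = sigma2_resid,
    loglik = prof$loglik, aic = -2 * prof$loglik + 2 * k,
    k = k, n_obs = n, n_species = length(usp),
    residuals = drop(y - X %*% beta), species = sp,
    terms = attr(mf, "terms"), call = match.call()
  )
  class(out) <- "pglmm"
  out
}

#' Standard fixed-effect presets for the allometric mixed model
#'
#' The model set compared by AIC: global allometry, additive and interactive
#' sex effects, and family effects. Three-way interactions are deliberately
#' not offered.
#'
#' @return Named list of formulas.
#' @export
allometry_formulas <- function() {
  list(
    wing            = log10_eye ~ log10_wing,
    wing_sex        = log10_eye ~ log10_wing + sex,
    wing_x_sex      = log10_eye ~ log10_wing * sex,
    wing_family     = log10_eye ~ log10_wing + family,
    wing_family_sex = log10_eye ~ log10_wing + family + sex
  )
}

#' @export
print.pglmm <- function(x, ...) {
  cat("Phylogenetic linear mixed model (ML)\n")
  cat("n_obs =", x$n_obs, " n_species =", x$n_species,
      " logLik =", format(x$loglik, digits = 6),
      " AIC =", format(x$aic, digits = 6), "\n")
  cat("sigma2_phylo =", signif(x$sigma2_phylo, 4),
      " sigma2_resid =", signif(x$sigma2_resid, 4), "\nFixed effects:\n")
  print(signif(x$coefficients, 5))
  invisible(x)
}

#' @export
summary.pglmm <- function(object, ...) {
  tab <- cbind(Estimate = object$coefficients, `Std. Error` = object$se,
               `z value` = object$zval, `Pr(>|z|)` = object$pval)
  structure(list(fit = object, coefficients = tab), class = "summary.pglmm")
}

#' @export
print.summary.pglmm <- function(x, ...) {
  print(x$fit)
  cat("\nCoefficient table (normal approximation, approximate p-values):\n")
  stats::printCoefmat(x$coefficients, P.values = TRUE, has.Pvalue = TRUE)
  invisible(x)
}

#' @export
coef.pglmm <- function(object, ...) object$coefficients

#' @export
logLik.pglmm <- function(object, ...) {
  structure(object$loglik, df = object$k, nobs = object$n_obs,
            class = "logLik")
}

#' @export
nobs.pglmm <- function(object, ...) object$n_obs

#' @export
residuals.pglmm <- function(object, ...) object$residuals
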