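# Profiled generalized least squares under a fixed correlation matrix R:
# beta and sigma2 have closed forms; the log-likelihood is the exact MVN
# log-density at the optimum (all normalization constants included, so AIC is
# comparable across correlation structures).
.gls_profile <- function(X, y, R) {
  L <- tryCatch(chol(R), error = function(e)
    stop("singular covariance structure: ", conditionMessage(e), call. = FALSE))
  Xs <- backsolve(L, X, transpose = TRUE)
  ys <- backsolve(L, y, transpose = TRUE)
  qrX <- qr(Xs)
  if (qrX$rank < ncol(X))
    stop("non-identifiable design: collinear columns ",
         paste(colnames(X)[qrX$pivot[(qrX$rank + 1):ncol(X)]], collapse = ", "))
  beta <- qr.coef(qrX, ys)
  fitted_s <- Xs %*% beta
  rss <- sum((ys - fitted_s)^2)
  n <- length(y)
  s2 <- rss / n
  logdet <- 2 * sum(log(diag(L)))
  ll <- -0.5 * n * log(2 * pi) - 0.5 * n * log(s2) - 0.5 * logdet - n / 2
  XtX_inv <- chol2inv(qr.R(qrX))
  list(beta = beta, sigma2 = s2, loglik = ll, rss = rss, XtX_inv = XtX_inv)
}

#' Phylogenetic generalized least squares on species means
#'
#' Fits `formula` by maximum likelihood with the residual covariance following
#' the phylogeny under a chosen correlation structure. Free structure
#' parameters (Pagel's lambda, or the OU attraction alpha) are profiled by ML;
#' the regression coefficients and the Brownian rate have closed forms given
#' the structure. Fixing `lambda = 0` (or `structure = "white"`) gives the
#' ordinary non-phylogenetic regression, so fits are directly comparable by
#' AIC across structures.
#'
#' @param formula Model formula on columns of `data`.
#' @param data Data frame of species-level values; species identified by the
#'   `species` column (or row names).
#' @param tree A `"phylo"` object covering all species in `data`; alternatively
#'   supply `vcv` directly.
#' @param vcv Optional precomputed phylogenetic covariance (labeled).
#' @param structure `"BM"`, `"lambda"`, `"OU"` or `"white"`.
#' @param lambda Fix Pagel's lambda instead of profiling it.
#' @param alpha Fix the OU attraction instead of profiling it.
#' @param mean_noise Optional named vector of known per-species sampling
#'   variances of the response (e.g. from [species_mean_noise()]), added to
#'   the diagonal of the residual covariance. With it, the Brownian rate (and
#'   lambda, if free) are optimized numerically instead of profiled in closed
#'   form; supported for the BM, lambda and white structures.
#' @return An object of class `"pgls"` with `print`, `summary`, `coef`,
#'   `logLik`, `AIC`, `residuals`, `fitted`, `predict` and `vcov` methods.
#'   Residuals are raw response-scale residuals `y - X beta`, keyed by species.
#' @export
fit_pgls <- function(formula, data, tree = NULL, vcv = NULL,
                     structure = c("BM", "lambda", "OU", "white"),
                     lambda = NULL, alpha = NULL, mean_noise = NULL) {
  structure <- match.arg(structure)
  sp <- if ("species" %in% names(data)) as.character(data$species)
        else rownames(data)
  if (anyDuplicated(sp)) stop("duplicate species in data")
  if (structure != "white") {
    if (is.null(vcv)) {
      if (is.null(tree)) stop("supply `tree` or `vcv`")
      missing <- setdiff(sp, tree$tip.label)
      if (length(missing))
        stop("species not on tree: ", paste(missing, collapse = ", "))
      vcv <- phylo_vcv(prune_phylogeny(tree, sp))
    }
    if (!all(sp %in% rownames(vcv)))
      stop("species missing from covariance: ",
           paste(setdiff(sp, rownames(vcv)), collapse = ", "))
    C <- vcv[sp, sp]
  } else {
    C <- diag(length(sp)); dimnames(C) <- list(sp, sp)
  }

  mf <- stats::model.frame(formula, data)
  y <- stats::model.response(mf)
  X <- stats::model.matrix(attr(mf, "terms"), mf)
  n <- length(y)
  if (n < ncol(X) + 1) stop("too few species for the design")

  if (!is.null(mean_noise))
    return(.fit_pgls_noise(X, y, C, sp, structure, lambda, mean_noise,
                           attr(mf, "terms"), match.call()))

  free_par <- 0L
  par_hat <- NULL
  if (structure == "BM" || structure == "white") {
    R <- C
    prof <- .gls_profile(X, y, R)
  } else if (structure == "lambda") {
    obj <- function(l) .gls_profile(X, y, vcv_transform(C, "lambda",
                                                        lambda = l))$loglik
    if (is.null(lambda)) {
      opt <- stats::optimize(obj, c(0, 1), maximum = TRUE, tol = 1e-8)
      # compare against the boundaries, which optimize() never visits exactly
      cand <- c(opt$maximum, 0, 1)
      lls <- c(opt$objective, obj(0), obj(1))
      lambda <- cand[which.max(lls)]
      free_par <- 1L
    } else if (lambda < 0 || lambda > 1) stop("lambda must be in [0, 1]")
    par_hat <- c(lambda = lambda)
    R <- vcv_transform(C, "lambda", lambda = lambda)
    prof <- .gls_profile(X, y, R)
  } else { # OU
    h <- max(diag(C))
    lo <- log(1e-8 / h); hi <- log(50 / h)
    obj <- function(la) .gls_profile(X, y, vcv_transform(C, "OU",
                                                         alpha = exp(la)))$loglik
    if (is.null(alpha)) {
      opt <- stats::optimize(obj, c(lo, hi), maximum = TRUE, tol = 1e-8)
      alpha <- exp(opt$maximum)
      free_par <- 1L
    } else if (alpha <= 0) stop("alpha must be > 0")
    par_hat <- c(alpha = alpha)
    R <- vcv_transform(C, "OU", alpha = alpha)
    prof <- .gls_profile(X, y, R)
  }

  beta <- drop(prof$beta); names(beta) <- colnames(X)
  p <- ncol(X)
  k <- p + 1L + free_par
  s2_unb <- prof$rss / (n - p)
  se <- sqrt(diag(s2_unb * prof$XtX_inv))
  names(se) <- names(beta)
  tval <- beta / se
  pval <- 2 * stats::pt(-abs(tval), df = n - k)
  fitted <- drop(X %*% beta); names(fitted) <- sp
  res <- y - fitted; names(res) <- sp

  out <- list(
    coefficients = beta, se = se, tval = tval, pval = pval,
    structure = list(kind = structure, params = par_hat,
                     sigma2 = prof$sigma2, profiled = free_par > 0),
    loglik = prof$loglik, aic = -2 * prof$loglik + 2 * k,
    k = k, n = n, residuals = res, fitted = fitted, y = y,
    species = sp, terms = attr(mf, "terms"), call = match.call(),
    vcov = prof$sigma2 * n / (n - p) * prof$XtX_inv
  )
  dimnames(out$vcov) <- list(names(beta), names(beta))
  class(out) <- "pgls"
  out
}

#' @export
print.pgls <- function(x, ...) {
  cat("Phylogenetic GLS (ML), structure:", x$structure$kind)
  if (!is.null(x$structure$params))
    cat(" (", paste(names(x$structure$params), "=",
                    signif(x$structure$params, 4), collapse = ", "),
        if (x$structure$profiled) ", profiled" else ", fixed", ")", sep = "")
  cat("\nn =", x$n, " logLik =", format(x$loglik, digits = 6),
      " AIC =", format(x$aic, digits = 6), "\nCoefficients:\n")
  print(signif(x$coefficients, 5))
  invisible(x)
}

#' @export
summary.pgls <- function(object, ...) {
  tab <- cbind(Estimate = object$coefficients, `Std. Error` = object$se,
               `t value` = object$tval, `Pr(>|t|)` = object$pval)
  structure(list(fit = object, coefficients = tab), class = "summary.pgls")
}

#' @export
print.summary.pgls <- function(x, ...) {
  print(x$fit)
  cat("\nCoefficient table (Wald t, df = n - k, approximate):\n")
  stats::printCoefmat(x$coefficients, P.values = TRUE, has.Pvalue = TRUE)
  invisible(x)
}

#' @export
coef.pgls <- function(object, ...) object$coefficients

#' @export
logLik.pgls <- function(object, ...) {
  structure(object$loglik, df = object$k, nobs = object$n, class = "logLik")
}

#' @export
nobs.pgls <- function(object, ...) object$n

#' @export
residuals.pgls <- function(object, ...) object$residuals

#' @export
fitted.pgls <- function(object, ...) object$fitted

#' @export
vcov.pgls <- function(object, ...) object$vcov

#' @export
predict.pgls <- function(object, newdata = NULL, ...) {
  if (is.null(newdata)) return(object$fitted)
  tt <- stats::delete.response(object$terms)
  X <- stats::model.matrix(tt, stats::model.frame(tt, newdata))
  drop(X %*% object$coefficients)
}

#' Relative trait size as PGLS residuals
#'
#' Raw response-scale residuals from a Brownian-motion PGLS, keyed by species.
#' These are the "relative eye size" values used downstream when a body-size
#' covariate cannot enter the model directly (signal estimation, trait-
#' evolution model fits, multi-rate models).
#'
#' @param fit A `"pgls"` fit (BM structure expected).
#' @return Named numeric vector of residuals.
#' @export
residuals_relative_size <- function(fit) {
  stopifnot(inherits(fit, "pgls"))
  if (fit$structure$kind != "BM")
    warning("relative size is conventionally taken from the BM fit; this fit ",
            "uses ", fit$structure$kind)
  fit$residuals
}

#' Likelihood-ratio test between nested ML fits
#'
#' @param full,reduced Fits with `logLik` methods, fitted by ML on identical
#'   data, `reduced` nested in `full`.
#' @param df Degrees of freedom; defaults to the difference in parameter
#'   counts.
#' @return List with `statistic`, `df`, `p.value`.
#' @export
lrt <- function(full, reduced, df = NULL) {
  llf <- as.numeric(stats::logLik(full))
  llr <- as.numeric(stats::logLik(reduced))
  if (llf - llr < -1e-6)
    stop("nesting violated: full model has lower log-likelihood (",
         format(llf), " < ", format(llr), ")")
  stat <- max(0, 2 * (llf - llr))
  if (is.null(df))
    df <- attr(stats::logLik(full), "df") - attr(stats::logLik(reduced), "df")
  if (is.null(df) || is.na(df) || df < 1) df <- 1
  list(statistic = stat, df = df,
       p.value = stats::pchisq(stat, df = df, lower.tail = FALSE))
}

#' Likelihood-based partition of variation attributable to phylogeny
#'
#' Partial R-squared comparing a phylogenetic fit to the same-formula
#' non-phylogenetic fit: `R2 = 1 - exp(-(2/n) (logLik_full - logLik_reduced))`,
#' clipped to \[0, 1\]. Both fits must be ML fits on identical data.
#'
#' @param full Phylogenetic fit (`"pgls"` or `"pglmm"`).
#' @param reduced Non-phylogenetic fit with the same fixed effects (`"pgls"`
#'   with white structure, `"pglmm"` on a star tree, or an `lm`/`glm` fit).
#' @return List of class `"r2_partition"`: `r2`, `loglik_full`,
#'   `loglik_reduced`, `n`, `flavor = "R2_lik"`.
#' @export
r2_phylo <- function(full, reduced) {
  llf <- as.numeric(stats::logLik(full))
  llr <- as.numeric(stats::logLik(reduced))
  n <- stats::nobs(full)
  if (n != stats::nobs(reduced)) stop("fits are not on identical data")
  if (llr - llf > 1e-6)
    stop("nesting violated: reduced fit has higher log-likelihood")
  r2 <- 1 - exp(-(2 / n) * max(0, llf - llr))
  out <- list(r2 = min(max(r2, 0), 1), loglik_full = llf, loglik_reduced = llr,
              n = n, flavor = "R2_lik")
  class(out) <- "r2_partition"
  out
}

#' @export
print.r2_partition <- function(x, ...) {
  cat("Phylogeny R2 partition (", x$flavor, "): ",
      sprintf("%.3f", x$r2), "\n", sep = "")
  cat("logLik full = ", format(x$loglik_full, digits = 6),
      ", reduced = ", format(x$loglik_reduced, digits = 6),
      ", n = ", x$n, "\n", sep = "")
  invisible(x)
}

# ML GLS when the residual covariance carries a known diagonal noise term:
# V = sigma2 * R(lambda) + diag(noise). beta keeps its closed form given V;
# sigma2 (and lambda) are optimized numerically.
.gls_fixedV <- function(X, y, V) {
  L <- tryCatch(chol(V), error = function(e) NULL)
  if (is.null(L)) return(NULL)
  Xs <- backsolve(L, X, transpose = TRUE)
  ys <- backsolve(L, y, transpose = TRUE)
  qrX <- qr(Xs)
  beta <- qr.coef(qrX, ys)
  rss <- sum((ys - Xs %*% beta)^2)
  n <- length(y)
  ll <- -0.5 * n * log(2 * pi) - sum(log(diag(L))) - 0.5 * rss
  list(beta = beta, loglik = ll, XtX_inv = chol2inv(qr.R(qrX)))
}

.fit_pgls_noise <- function(X, y, C, sp, structure, lambda, mean_noise,
                            terms, call) {
  if (!structure %in% c("BM", "lambda", "white"))
    stop("mean_noise is supported for the BM, lambda and white structures")
  if (is.null(names(mean_noise)) || !all(sp %in% names(mean_noise)))
    stop("mean_noise must be named by species and cover all species")
  D <- mean_noise[sp]
  if (any(D < 0)) stop("mean_noise must be nonnegative")
  n <- length(y); p <- ncol(X)

  Vof <- function(s2, l) {
    V <- if (structure == "white") diag(s2, n)
         else s2 * vcv_transform(C, "lambda", lambda = l)
    diag(V) <- diag(V) + D
    V
  }
  s2_init <- .gls_profile(X, y, if (structure == "white") diag(n) else C)$sigma2
  free_lambda <- structure == "lambda" && is.null(lambda)
  if (free_lambda) {
    obj <- function(par) {
      f <- .gls_fixedV(X, y, Vof(exp(par[1]), stats::plogis(par[2])))
      if (is.null(f)) 1e10 else -f$loglik
    }
    op <- stats::optim(c(log(s2_init), stats::qlogis(0.9)), obj,
                       control = list(reltol = 1e-12, maxit = 2000))
    s2 <- exp(op$par[1]); lambda <- stats::plogis(op$par[2])
    free_par <- 1L
  } else {
    if (is.null(lambda) || structure != "lambda")
      lambda <- if (structure == "BM") 1 else 0
    obj <- function(ls2) {
      f <- .gls_fixedV(X, y, Vof(exp(ls2), lambda))
      if (is.null(f)) 1e10 else -f$loglik
    }
    op <- stats::optimize(obj, c(-25, 10))
    s2 <- exp(op$minimum)
    free_par <- 0L
  }
  fit <- .gls_fixedV(X, y, Vof(s2, lambda))
  beta <- drop(fit$beta); names(beta) <- colnames(X)
  k <- p + 1L + free_par
  se <- sqrt(diag(fit$XtX_inv)); names(se) <- names(beta)
  tval <- beta / se
  pval <- 2 * stats::pt(-abs(tval), df = n - k)
  fitted <- drop(X %*% beta); names(fitted) <- sp
  res <- y - fitted; names(res) <- sp
  par_hat <- if (structure != "white") c(lambda = lambda) else NULL
  out <- list(coefficients = beta, se = se, tval = tval, pval = pval,
              structure = list(kind = structure, params = par_hat,
                               sigma2 = s2, profiled = free_par > 0,
                               mean_noise = TRUE),
              loglik = fit$loglik, aic = -2 * fit$loglik + 2 * k,
              k = k, n = n, residuals = res, fitted = fitted, y = y,
              species = sp, terms = terms, call = call, vcov = fit$XtX_inv)
  dimnames(out$vcov) <- list(names(beta), names(beta))
  class(out) <- "pgls"
  out
}
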