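# Identifiability check at an interior shape-parameter optimum: the
# log-likelihood in (z0, log sigma2, shape) must have vanishing gradient and
# a negative-definite Hessian (central differences). Flat shape directions
# mark the model unidentified on these data.
.evo_identified <- function(y, C, shape_vcv, shape_hat,
                            grad_tol = 1e-3, eig_tol = 1e-6) {
  n <- length(y)
  prof <- .gls_profile(matrix(1, n, 1), y, shape_vcv(shape_hat))
  x0 <- c(drop(prof$beta), log(prof$sigma2), shape_hat)
  ll <- function(p) {
    V <- exp(p[2]) * shape_vcv(p[3])
    L <- tryCatch(chol(V), error = function(e) NULL)
    if (is.null(L)) return(-Inf)
    r <- y - p[1]
    -0.5 * (n * log(2 * pi) + 2 * sum(log(diag(L))) +
              sum(backsolve(L, r, transpose = TRUE)^2))
  }
  h <- 1e-4 * pmax(1, abs(x0))
  g <- vapply(1:3, function(i) {
    e <- rep(0, 3); e[i] <- h[i]
    (ll(x0 + e) - ll(x0 - e)) / (2 * h[i])
  }, 0)
  if (!all(is.finite(g)) || sqrt(sum(g^2)) > grad_tol) return(FALSE)
  H <- matrix(0, 3, 3)
  for (i in 1:3) for (j in i:3) {
    ei <- ej <- rep(0, 3); ei[i] <- h[i]; ej[j] <- h[j]
    H[i, j] <- H[j, i] <- (ll(x0 + ei + ej) - ll(x0 + ei - ej) -
                             ll(x0 - ei + ej) + ll(x0 - ei - ej)) /
      (4 * h[i] * h[j])
  }
  if (!all(is.finite(H))) return(FALSE)
  max(eigen(H, symmetric = TRUE, only.values = TRUE)$values) < -eig_tol
}

# align a named trait vector to tree tips, with errors on mismatch
.align_trait <- function(trait, tree) {
  if (is.null(names(trait))) stop("trait must be named by tip labels")
  missing <- setdiff(tree$tip.label, names(trait))
  if (length(missing))
    stop("trait missing for tips: ", paste(missing, collapse = ", "))
  trait[tree$tip.label]
}

#' Pagel's lambda phylogenetic signal
#'
#' Maximum-likelihood estimate of Pagel's lambda for a continuous trait: the
#' multiplier on the off-diagonal of the phylogenetic covariance that best
#' explains the data under a multivariate-normal model with free mean and
#' rate (both profiled analytically). lambda = 0 means no effect of shared
#' ancestry, lambda = 1 is consistent with Brownian motion. The likelihood is
#' maximized by Brent search on \[0, 1\] and a grid profile is returned for
#' plotting; significance against lambda = 0 comes from a 1-df likelihood
#' ratio test.
#'
#' @param trait Named numeric vector keyed by tip labels.
#' @param tree A `"phylo"` object with >= 4 tips.
#' @param grid_n Number of grid points in the exported likelihood profile.
#' @return Object of class `"signal_lambda"`: `lambda`, `loglik`,
#'   `loglik_lambda0`, `p_vs_zero`, `profile` (data frame).
#' @export
pagel_lambda <- function(trait, tree, grid_n = 101) {
  if (length(tree$tip.label) < 4) stop("need at least 4 species")
  y <- .align_trait(trait, tree)
  if (stats::var(y) == 0) stop("trait is constant; lambda is undefined")
  C <- phylo_vcv(tree)
  X <- matrix(1, length(y), 1)
  ll_at <- function(l) .gls_profile(X, y, vcv_transform(C, "lambda",
                                                        lambda = l))$loglik
  opt <- stats::optimize(ll_at, c(0, 1), maximum = TRUE, tol = 1e-8)
  cand <- c(opt$maximum, 0, 1)
  lls <- c(opt$objective, ll_at(0), ll_at(1))
  i <- which.max(lls)
  lambda_hat <- cand[i]; ll_hat <- lls[i]
  grid <- seq(0, 1, length.out = grid_n)
  prof <- data.frame(lambda = grid, loglik = vapply(grid, ll_at, 0))
  ll0 <- lls[2]
  stat <- max(0, 2 * (ll_hat - ll0))
  out <- list(lambda = lambda_hat, loglik = ll_hat, loglik_lambda0 = ll0,
              p_vs_zero = stats::pchisq(stat, 1, lower.tail = FALSE),
              profile = prof, n = length(y))
  class(out) <- "signal_lambda"
  out
}

#' @export
print.signal_lambda <- function(x, ...) {
  cat("Pagel's lambda = ", sprintf("%.4f", x$lambda),
      " (logLik ", format(x$loglik, digits = 6),
      ", LRT vs lambda = 0: p = ", format.pval(x$p_vs_zero, digits = 3),
      ", n = ", x$n, ")\n", sep = "")
  invisible(x)
}

#' Fit a homogeneous-rate continuous-trait evolution model
#'
#' Exact ML fits of the five standard single-rate models by direct
#' construction of the implied multivariate-normal mean and covariance:
#' Brownian motion (BM), Ornstein-Uhlenbeck (OU, attraction `alpha` optimized
#' within `alpha_bounds`), early burst (EB, decay `r_eb` optimized within
#' `r_bounds`), BM with a directional trend (mean changes linearly with
#' root-to-tip depth; identifiable only on non-ultrametric trees), and
#' non-phylogenetic white noise. The ancestral state and rate are profiled
#' analytically; one-dimensional shape parameters are optimized by Brent
#' search. Small-sample AICc is reported for model comparison.
#'
#' @param trait Named numeric vector keyed by tip labels.
#' @param tree A `"phylo"` object.
#' @param model One of `"BM"`, `"OU"`, `"EB"`, `"trend"`, `"white"`.
#' @param alpha_bounds,r_bounds Search bounds for OU/EB shape parameters, as
#'   multiples of 1/tree height (defaults `c(1e-8, 50)` and `c(-10, 0)`).
#' Convergence is declared when the optimizer finishes away from its search
#' bounds, the numerical gradient of the log-likelihood vanishes at the
#' optimum, and the Hessian is negative definite; boundary or flat optima are
#' flagged non-converged and excluded from Akaike weights (shape parameters
#' of the richer models are frequently unidentifiable on small trees, so low
#' convergence of OU/EB/trend is expected behavior, not an error).
#'
#' @return Object of class `"evofit"`: `model`, `params`, `loglik`, `k`,
#'   `aic`, `aicc`, `converged`, `n`.
#' @export
fit_continuous <- function(trait, tree,
                           model = c("BM", "OU", "EB", "trend", "white"),
                           alpha_bounds = c(1e-8, 50), r_bounds = c(-10, 0)) {
  model <- match.arg(model)
  y <- .align_trait(trait, tree)
  n <- length(y)
  C <- phylo_vcv(tree)
  h <- max(diag(C))
  X1 <- matrix(1, n, 1)
  converged <- TRUE
  boundary <- FALSE

  if (model == "BM") {
    prof <- .gls_profile(X1, y, C)
    params <- c(z0 = drop(prof$beta), sigma2 = prof$sigma2)
    k <- 2L; ll <- prof$loglik
  } else if (model == "white") {
    prof <- .gls_profile(X1, y, diag(n))
    params <- c(z0 = drop(prof$beta), sigma2 = prof$sigma2)
    k <- 2L; ll <- prof$loglik
  } else if (model == "OU") {
    lo <- log(alpha_bounds[1] / h); hi <- log(alpha_bounds[2] / h)
    f <- function(la) .gls_profile(X1, y, vcv_transform(C, "OU",
                                                        alpha = exp(la)))$loglik
    opt <- stats::optimize(f, c(lo, hi), maximum = TRUE, tol = 1e-8)
    alpha <- exp(opt$maximum)
    boundary <- opt$maximum > hi - 1e-4 || opt$maximum < lo + 1e-4
    prof <- .gls_profile(X1, y, vcv_transform(C, "OU", alpha = alpha))
    params <- c(z0 = drop(prof$beta), sigma2 = prof$sigma2, alpha = alpha)
    k <- 3L; ll <- prof$loglik
    converged <- !boundary &&
      .evo_identified(y, C, function(p)
        vcv_transform(C, "OU", alpha = exp(p), sigma2 = 1), log(alpha))
  } else if (model == "EB") {
    lo <- r_bounds[1] / h
    f <- function(r) .gls_profile(X1, y, vcv_transform(C, "EB",
                                                       r_eb = r))$loglik
    opt <- stats::optimize(f, c(lo, 0), maximum = TRUE, tol = 1e-10)
    # r = 0 (the BM boundary) is a legal optimum optimize() cannot land on
    r_eb <- if (f(0) >= opt$objective) 0 else opt$maximum
    boundary <- r_eb == 0 || r_eb < lo * (1 - 1e-4)
    prof <- .gls_profile(X1, y, vcv_transform(C, "EB", r_eb = r_eb))
    params <- c(z0 = drop(prof$beta), sigma2 = prof$sigma2, r_eb = r_eb)
    k <- 3L; ll <- prof$loglik
    converged <- !boundary &&
      .evo_identified(y, C, function(p)
        vcv_transform(C, "EB", r_eb = p), r_eb)
  } else { # trend
    depth <- diag(C)
    if (stats::sd(depth) < 1e-8 * h) {
      # ultrametric: the trend coefficient is collinear with the intercept
      out <- list(model = model, params = c(z0 = NA, sigma2 = NA, mu = NA),
                  loglik = NA_real_, k = 3L, aic = NA_real_, aicc = NA_real_,
                  converged = FALSE, boundary = FALSE, n = n,
                  note = "trend unidentifiable on an ultrametric tree")
      class(out) <- "evofit"
      return(out)
    }
    X <- cbind(1, depth)
    prof <- .gls_profile(X, y, C)
    params <- c(z0 = prof$beta[1], sigma2 = prof$sigma2, mu = prof$beta[2])
    k <- 3L; ll <- prof$loglik
  }

  aic <- -2 * ll + 2 * k
  aicc <- if (n - k - 1 > 0) aic + 2 * k * (k + 1) / (n - k - 1) else NA_real_
  out <- list(model = model, params = params, loglik = ll, k = k, aic = aic,
              aicc = aicc, converged = converged, boundary = boundary, n = n)
  class(out) <- "evofit"
  out
}

#' @export
print.evofit <- function(x, ...) {
  cat("Trait-evolution model: ", x$model,
      if (!x$converged) " (NOT converged)" else "",
      "\n  logLik = ", format(x$loglik, digits = 6),
      "  AICc = ", format(x$aicc, digits = 6),
      "\n  params: ", paste(names(x$params), "=", signif(x$params, 4),
                            collapse = ", "), "\n", sep = "")
  invisible(x)
}

#' @export
logLik.evofit <- function(object, ...) {
  structure(object$loglik, df = object$k, nobs = object$n, class = "logLik")
}

#' Akaike weights from AICc values
#'
#' `w_i = exp(-Delta_i/2) / sum_j exp(-Delta_j/2)` with `Delta` the AICc
#' differences from the best model. Non-converged fits are excluded.
#'
#' @param fits List of `"evofit"` objects, or a named numeric vector of AICc
#'   values.
#' @return Named numeric weights summing to 1.
#' @export
aicc_weights <- function(fits) {
  if (is.numeric(fits)) {
    aicc <- fits
  } else {
    ok <- vapply(fits, function(f) isTRUE(f$converged), TRUE)
    fits <- fits[ok]
    aicc <- vapply(fits, function(f) f$aicc, 0)
    names(aicc) <- vapply(fits, function(f) f$model, "")
  }
  if (length(aicc) == 0) stop("no converged fits to weight")
  d <- aicc - min(aicc)
  w <- exp(-d / 2)
  w / sum(w)
}

#' Fit the full homogeneous-rate model set
#'
#' Convenience wrapper fitting BM, OU, EB, trend and white-noise models and
#' tabulating AICc and Akaike weights (non-converged fits are kept in the
#' table, flagged, and excluded from the weights).
#'
#' @inheritParams fit_continuous
#' @param models Character vector of model ids.
#' @return Object of class `"evofit_set"`: `fits` (list) and `table`
#'   (data frame).
#' @export
fit_evo_models <- function(trait, tree,
                           models = c("BM", "OU", "EB", "trend", "white")) {
  fits <- lapply(models, function(m) fit_continuous(trait, tree, m))
  names(fits) <- models
  conv <- vapply(fits, function(f) isTRUE(f$converged), TRUE)
  w <- rep(NA_real_, length(fits)); names(w) <- models
  if (any(conv)) w[names(aicc_weights(fits[conv]))] <- aicc_weights(fits[conv])
  tab <- data.frame(
    model = models,
    loglik = vapply(fits, function(f) f$loglik, 0),
    k = vapply(fits, function(f) f$k, 0L),
    aicc = vapply(fits, function(f) f$aicc, 0),
    weight = w,
    converged = conv,
    row.names = NULL
  )
  structure(list(fits = fits, table = tab[order(tab$aicc), ]),
            class = "evofit_set")
}

#' @export
print.evofit_set <- function(x, ...) {
  cat("Homogeneous-rate trait-evolution model comparison (AICc):\n")
  print(x$table, digits = 5, row.names = FALSE)
  invisible(x)
}

#' Sensitivity of an analysis to phylogenetic uncertainty
#'
#' Replicates an analysis across a posterior set of trees sharing the same tip
#' set: either Pagel's lambda (`what = "lambda"`, returning the per-tree
#' estimate with its median and 95% interval) or homogeneous-rate model
#' selection (`what = "model"`, returning the per-tree AICc-best model and the
#' modal choice).
#'
#' @param trait Named numeric vector keyed by tip labels.
#' @param trees A `"multiPhylo"` (or list) of trees with identical tip sets.
#' @param what `"lambda"` or `"model"`.
#' @return List with `per_tree` (data frame) and `summary`.
#' @export
posterior_sensitivity <- function(trait, trees, what = c("lambda", "model")) {
  what <- match.arg(what)
  tips <- sort(trees[[1]]$tip.label)
  for (i in seq_along(trees)) {
    if (!identical(sort(trees[[i]]$tip.label), tips))
      stop("tree ", i, " has a different tip set")
  }
  if (what == "lambda") {
    est <- vapply(seq_along(trees),
                  function(i) pagel_lambda(trait, trees[[i]])$lambda, 0)
    per_tree <- data.frame(tree = seq_along(trees), lambda = est)
    summ <- c(median = stats::median(est),
              q2.5 = unname(stats::quantile(est, 0.025)),
              q97.5 = unname(stats::quantile(est, 0.975)))
  } else {
    est <- vapply(seq_along(trees), function(i) {
      ms <- fit_evo_models(trait, trees[[i]])
      ms$table$model[which.max(ms$table$weight)]
    }, "")
    per_tree <- data.frame(tree = seq_along(trees), best_model = est)
    tally <- sort(table(est), decreasing = TRUE)
    summ <- list(modal_model = names(tally)[1], tally = tally)
  }
  list(what = what, per_tree = per_tree, summary = summ)
}
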