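test_that("identity covariance reduces PGLS to ordinary least squares", {
  set.seed(1)
  d <- data.frame(species = paste0("s", 1:12), y = rnorm(12), x = rnorm(12))
  f <- fit_pgls(y ~ x, d, structure = "white")
  ols <- lm(y ~ x, d)
  expect_equal(unname(coef(f)), unname(coef(ols)), tolerance = 1e-10)
  expect_equal(f$loglik, as.numeric(logLik(ols)), tolerance = 1e-8)
  expect_equal(sum(residuals(f)), 0, tolerance = 1e-10)
})

test_that("PGLS matches the dense closed-form GLS oracle", {
  # small trees, several fixed structures: coefficients and log-likelihood
  # agree with (X' V^-1 X)^-1 X' V^-1 y and the exact MVN density
  for (seed in 1:3) {
    tr <- quick_tree(5, seed)
    set.seed(seed + 50)
    d <- data.frame(species = tr$tip.label,
                    y = sim_bm_trait(tr) + rnorm(5, 0, 0.2),
                    x = rnorm(5))
    C <- phylo_vcv(tr)
    X <- cbind(1, d$x)
    for (lam in c(1, 0.6)) {
      f <- fit_pgls(y ~ x, d, tr, structure = "lambda", lambda = lam)
      o <- dense_gls(X, d$y, vcv_transform(C, "lambda", lambda = lam))
      expect_equal(unname(coef(f)), unname(o$beta), tolerance = 1e-8)
      expect_equal(f$loglik, o$loglik, tolerance = 1e-8)
    }
    f_bm <- fit_pgls(y ~ x, d, tr, structure = "BM")
    o_bm <- dense_gls(X, d$y, C)
    expect_equal(unname(coef(f_bm)), unname(o_bm$beta), tolerance = 1e-8)
    expect_equal(f_bm$loglik, o_bm$loglik, tolerance = 1e-8)
  }
})

test_that("BM PGLS agrees with nlme::gls under corBrownian", {
  skip_if_not_installed("nlme")
  tr <- quick_tree(25, 4)
  set.seed(11)
  d <- data.frame(species = tr$tip.label, y = sim_bm_trait(tr),
                  x = rnorm(25))
  f <- fit_pgls(y ~ x, d, tr, structure = "BM")
  g <- nlme::gls(y ~ x, data = d, method = "ML",
                 correlation = ape::corBrownian(phy = tr, form = ~species))
  expect_equal(unname(coef(f)), unname(coef(g)), tolerance = 1e-6)
  expect_equal(f$loglik, as.numeric(logLik(g)), tolerance = 1e-6)
})

test_that("profiled lambda agrees with nlme::gls under corPagel", {
  skip_if_not_installed("nlme")
  tr <- quick_tree(30, 6)
  set.seed(12)
  d <- data.frame(species = tr$tip.label,
                  y = sim_bm_trait(tr) + rnorm(30, 0, 0.4),
                  x = rnorm(30))
  f <- fit_pgls(y ~ x, d, tr, structure = "lambda")
  g <- nlme::gls(y ~ x, data = d, method = "ML",
                 correlation = ape::corPagel(0.5, phy = tr, form = ~species))
  expect_equal(unname(f$structure$params["lambda"]),
               unname(coef(g$modelStruct$corStruct, unconstrained = FALSE)),
               tolerance = 0.02)
  expect_equal(f$loglik, as.numeric(logLik(g)), tolerance = 1e-4)
})

test_that("likelihood-ratio test follows the chi-squared calibration", {
  mk <- function(ll, k) structure(list(loglik = ll, k = k, n = 10),
                                  class = "pgls")
  expect_equal(lrt(mk(-5, 3), mk(-5, 2))$p.value, 1)
  p <- lrt(mk(-5 + 3.84 / 2, 3), mk(-5, 2), df = 1)$p.value
  expect_equal(p, pchisq(3.84, 1, lower.tail = FALSE), tolerance = 1e-12)
  expect_equal(p, 0.05, tolerance = 0.001)
  expect_error(lrt(mk(-6, 3), mk(-5, 2)), "nesting")
})

test_that("BM-vs-lambda LRT is valid (not anticonservative) under BM truth", {
  # under the null, lambda sits on its boundary (lambda = 1), so the LRT
  # statistic is a 0 / chi2(1) mixture: p-values should reject at no more
  # than the nominal rate
  set.seed(3)
  rej <- replicate(100, {
    tr <- quick_tree(30, sample.int(1e6, 1))
    d <- data.frame(species = tr$tip.label, y = sim_bm_trait(tr))
    f1 <- fit_pgls(y ~ 1, d, tr, structure = "lambda")
    f0 <- fit_pgls(y ~ 1, d, tr, structure = "BM")
    lrt(f1, f0, df = 1)$p.value < 0.05
  })
  expect_lte(mean(rej), 0.08)  # nominal 5% plus Monte Carlo slack
})

test_that("residuals are raw, linear, and keyed by species", {
  tr <- toy_tree()
  d <- data.frame(species = tr$tip.label, x = c(1, 2, 3))
  d$y <- 2 + 0.5 * d$x
  f <- suppressWarnings(fit_pgls(y ~ x, d, tr, structure = "BM"))
  expect_equal(unname(residuals_relative_size(f)), rep(0, 3),
               tolerance = 1e-10)

  d2 <- d; d2$y[2] <- d2$y[2] + 0.1
  f2 <- suppressWarnings(fit_pgls(y ~ x, d2, tr, structure = "BM"))
  delta <- residuals(f2) - residuals(f)
  # shifting one species' response moves the fit, but the residual change
  # plus fitted change at that species is exactly +0.1
  expect_equal(unname(delta["B"] + (fitted(f2) - fitted(f))["B"]), 0.1,
               tolerance = 1e-10)
})

test_that("phylogeny R2 partition follows the likelihood formula", {
  mk <- function(ll, n) structure(list(loglik = ll, k = 3, n_obs = n),
                                  class = "pglmm")
  expect_equal(r2_phylo(mk(-10, 40), mk(-10, 40))$r2, 0)
  expect_equal(r2_phylo(mk(0, 40), mk(-20, 40))$r2, 1 - exp(-1))
  expect_error(r2_phylo(mk(-10, 40), mk(-5, 40)), "nesting")
})

test_that("standardizing predictors maps coefficients by the affine rule", {
  tr <- quick_tree(20, 9)
  set.seed(21)
  d <- data.frame(species = tr$tip.label, y = sim_bm_trait(tr), x = rnorm(20))
  f_raw <- fit_pgls(y ~ x, d, tr, structure = "BM")
  d$xz <- (d$x - mean(d$x)) / sd(d$x)
  f_std <- fit_pgls(y ~ xz, d, tr, structure = "BM")
  expect_equal(unname(coef(f_std)["xz"]), unname(coef(f_raw)["x"]) * sd(d$x),
               tolerance = 1e-8)
  expect_equal(f_std$loglik, f_raw$loglik, tolerance = 1e-8)
})

test_that("measurement-error PGLS reduces to plain PGLS at zero noise", {
  tr <- quick_tree(15, 2)
  set.seed(31)
  d <- data.frame(species = tr$tip.label, y = sim_bm_trait(tr), x = rnorm(15))
  noise0 <- setNames(rep(0, 15), tr$tip.label)
  f0 <- fit_pgls(y ~ x, d, tr, structure = "BM", mean_noise = noise0)
  f <- fit_pgls(y ~ x, d, tr, structure = "BM")
  expect_equal(coef(f0), coef(f), tolerance = 1e-5)
  expect_equal(f0$loglik, f$loglik, tolerance = 1e-5)
  # positive noise shrinks the apparent Brownian rate
  noisy <- fit_pgls(y ~ x, d, tr, structure = "BM",
                    mean_noise = setNames(rep(0.5, 15), tr$tip.label))
  expect_lt(noisy$structure$sigma2, f$structure$sigma2)
  expect_error(fit_pgls(y ~ x, d, tr, structure = "OU", mean_noise = noise0),
               "supported")
})
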