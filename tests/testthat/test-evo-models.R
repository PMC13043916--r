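test_that("every model's likelihood matches a dense MVN oracle on 5 taxa", {
  dense_mvn_ll <- function(y, mu, V) {
    n <- length(y)
    -0.5 * (n * log(2 * pi) + as.numeric(determinant(V)$modulus) +
              drop(t(y - mu) %*% solve(V, y - mu)))
  }
  tr <- quick_tree(5, 8)
  tr$edge.length[1] <- tr$edge.length[1] + 0.3  # make it non-ultrametric
  set.seed(5)
  y <- sim_bm_trait(tr)
  C <- phylo_vcv(tr)
  for (m in c("BM", "OU", "EB", "trend", "white")) {
    f <- fit_continuous(y, tr, m)
    p <- f$params
    V <- switch(m,
      BM = p["sigma2"] * C,
      white = diag(p["sigma2"], 5),
      OU = vcv_transform(C, "OU", alpha = p["alpha"], sigma2 = p["sigma2"]),
      EB = vcv_transform(C, "EB", r_eb = p["r_eb"], sigma2 = p["sigma2"]),
      trend = p["sigma2"] * C)
    mu <- if (m == "trend") p["z0"] + p["mu"] * diag(C) else rep(p["z0"], 5)
    expect_equal(f$loglik, dense_mvn_ll(y, mu, V), tolerance = 1e-8,
                 label = paste("loglik", m))
  }
})

test_that("early burst with zero decay equals Brownian motion", {
  tr <- quick_tree(20, 2)
  set.seed(9)
  y <- sim_bm_trait(tr)
  f_bm <- fit_continuous(y, tr, "BM")
  f_eb <- fit_continuous(y, tr, "EB")
  # on BM data the EB optimum collapses to the boundary r_eb = 0
  expect_gte(f_eb$loglik, f_bm$loglik - 1e-6)
  expect_lte(f_eb$loglik, f_bm$loglik + 0.2)
})

test_that("the trend model is unidentifiable on ultrametric trees only", {
  tr <- quick_tree(10, 3)  # rphylo trees are ultrametric
  set.seed(10)
  y <- sim_bm_trait(tr)
  f <- fit_continuous(y, tr, "trend")
  expect_false(f$converged)
  expect_true(is.na(f$aicc))

  tr2 <- tr
  tr2$edge.length <- tr2$edge.length * runif(length(tr2$edge.length), 0.5, 2)
  f2 <- fit_continuous(sim_bm_trait(tr2), tr2, "trend")
  expect_true(f2$converged)
  expect_true(is.finite(f2$params["mu"]))
})

test_that("rate recovery: BM sigma2 estimates center on the truth", {
  set.seed(14)
  s2 <- replicate(60, {
    tr <- quick_tree(59, sample.int(1e6, 1))
    fit_continuous(sim_bm_trait(tr, 1), tr, "BM")$params["sigma2"]
  })
  expect_gt(mean(s2), 0.8)
  expect_lt(mean(s2), 1.2)
})

test_that("AICc weights follow the closed-form ratios", {
  expect_equal(unname(aicc_weights(c(a = 10, b = 10))), c(0.5, 0.5))
  w <- aicc_weights(c(a = 10, b = 12))
  expect_equal(unname(w[2] / w[1]), exp(-1), tolerance = 1e-12)
  w20 <- aicc_weights(c(a = 0, b = 20))
  expect_lt(w20[2], 1e-4)
  expect_equal(sum(aicc_weights(c(1, 3, 7, 2))), 1, tolerance = 1e-9)
  expect_error(aicc_weights(numeric(0)), "no converged")
})

test_that("AICc includes the small-sample correction term", {
  tr <- quick_tree(25, 4)
  set.seed(15)
  f <- fit_continuous(sim_bm_trait(tr), tr, "BM")
  expect_equal(f$aicc, f$aic + 2 * 2 * 3 / (25 - 2 - 1))
})

test_that("lambda estimate is invariant to affine trait transforms", {
  tr <- quick_tree(40, 6)
  set.seed(16)
  y <- sim_bm_trait(tr) + rnorm(40, 0, 0.3)
  l1 <- pagel_lambda(y, tr)
  l2 <- pagel_lambda(5 - 3 * y, tr)
  expect_equal(l1$lambda, l2$lambda, tolerance = 1e-5)
  expect_equal(which.max(l1$profile$loglik), which.max(l2$profile$loglik))
  expect_error(pagel_lambda(setNames(rep(1, 40), tr$tip.label), tr),
               "constant")
})

test_that("lambda agrees with the phytools reference implementation", {
  skip_if_not_installed("phytools")
  tr <- quick_tree(40, 7)
  set.seed(17)
  y <- sim_bm_trait(tr) + rnorm(40, 0, 0.5)
  ours <- pagel_lambda(y, tr)
  ref <- phytools::phylosig(tr, y, method = "lambda")
  expect_equal(ours$lambda, ref$lambda, tolerance = 1e-3)
  expect_equal(ours$loglik, ref$logL, tolerance = 1e-4)
})

test_that("model-set wrapper tabulates weights and flags non-convergence", {
  tr <- quick_tree(30, 5)
  set.seed(18)
  ms <- fit_evo_models(sim_bm_trait(tr), tr)
  expect_setequal(ms$table$model, c("BM", "OU", "EB", "trend", "white"))
  expect_false(ms$table$converged[ms$table$model == "trend"])
  conv_w <- ms$table$weight[ms$table$converged]
  expect_equal(sum(conv_w), 1, tolerance = 1e-9)
})

test_that("posterior-tree sensitivity is deterministic and validates tips", {
  cfg <- sim_config(seed = 6, n_species = 20, n_posterior_trees = 10)
  tr <- simulate_tree(cfg)
  set.seed(19)
  y <- sim_bm_trait(tr, 0.01)
  same <- rep(c(tr), 10); class(same) <- "multiPhylo"
  ps <- posterior_sensitivity(y, same, "lambda")
  expect_equal(unname(diff(range(ps$per_tree$lambda))), 0)

  jit <- simulate_posterior_trees(tr, cfg)
  ps2 <- posterior_sensitivity(y, jit, "lambda")
  expect_lt(ps2$summary["q97.5"] - ps2$summary["q2.5"], 0.2)

  bad <- jit
  bad[[4]] <- prune_phylogeny(tr, tr$tip.label[1:10])
  expect_error(posterior_sensitivity(y, bad, "lambda"), "tree 4")

  ps3 <- posterior_sensitivity(y, jit[1:5], "model")
  expect_equal(ps3$summary$modal_model, "BM")
})
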