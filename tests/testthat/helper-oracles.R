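# small fixed trees and independent oracles used across the suite

toy_newick <- "((A:1,B:1):1,C:2);"
toy_tree <- function() read_phylogeny(text = toy_newick)

quick_tree <- function(n, seed = 1) {
  set.seed(seed)
  ape::rphylo(n, birth = 1, death = 0)
}

# brute-force phylogenetic covariance: shared path length from root,
# computed from pairwise node distances (independent of ape::vcv.phylo)
brute_vcv <- function(tree) {
  n <- length(tree$tip.label)
  root <- n + 1L
  d <- ape::dist.nodes(tree)
  C <- matrix(0, n, n, dimnames = list(tree$tip.label, tree$tip.label))
  for (i in seq_len(n)) for (j in seq_len(n))
    C[i, j] <- (d[root, i] + d[root, j] - d[i, j]) / 2
  C
}

# dense closed-form GLS: beta = (X' V^-1 X)^-1 X' V^-1 y, sigma2 profiled,
# exact MVN log-likelihood
dense_gls <- function(X, y, V) {
  Vi <- solve(V)
  B <- solve(t(X) %*% Vi %*% X, t(X) %*% Vi %*% y)
  r <- y - X %*% B
  n <- length(y)
  s2 <- drop(t(r) %*% Vi %*% r) / n
  ll <- -0.5 * (n * log(2 * pi) + n * log(s2) +
                  as.numeric(determinant(V)$modulus) + n)
  list(beta = drop(B), sigma2 = s2, loglik = ll)
}

# one Brownian trait on a tree
sim_bm_trait <- function(tree, sigma2 = 1) {
  C <- ape::vcv.phylo(tree)
  stats::setNames(drop(t(chol(C)) %*% stats::rnorm(nrow(C))) * sqrt(sigma2),
                  tree$tip.label)
}

# minimal individual-level trait table for loader tests
write_trait_csv <- function(df, path = tempfile(fileext = ".csv")) {
  utils::write.csv(df, path, row.names = FALSE)
  path
}
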