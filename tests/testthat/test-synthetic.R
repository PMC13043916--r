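test_that("the generated tree has the advertised combinatorics", {
  cfg <- sim_config(seed = 11)
  tr <- simulate_tree(cfg)
  expect_equal(length(tr$tip.label), 59)
  expect_equal(tr$Nnode, 58)                       # fully bifurcating
  expect_equal(max(eyescale:::node_depths(tr)[1:59]), 1, tolerance = 1e-10)
  # the designated clade is monophyletic: the MRCA of its tips spans exactly them
  shifted <- attr(tr, "shifted_clade")
  mrca <- ape::getMRCA(tr, shifted)
  expect_setequal(ape::extract.clade(tr, mrca)$tip.label, shifted)
  fam <- attr(tr, "families")
  expect_equal(sort(unique(names(fam))), sort(tr$tip.label))
  expect_setequal(names(fam)[fam == "Hesperiidae"], shifted)
})

test_that("the same seed reproduces the tree byte for byte", {
  cfg <- sim_config(seed = 12)
  expect_identical(ape::write.tree(simulate_tree(cfg)),
                   ape::write.tree(simulate_tree(cfg)))
})

test_that("degenerate noise collapses individuals onto the species value", {
  cfg <- sim_config(seed = 13, n_species = 10, sigma2_resid = 1e-12,
                    sigma2_ind = 0, sex_offset = 0)
  tt <- simulate_traits(simulate_tree(cfg), cfg)
  spread <- tapply(log10(tt$eye_area), tt$species, function(v) diff(range(v)))
  expect_lt(max(spread), 1e-4)
})

test_that("individual counts follow the configured range or exact total", {
  cfg <- sim_config(seed = 14)
  tt <- simulate_traits(simulate_tree(cfg), cfg)
  n_i <- table(tt$species)
  expect_true(all(n_i >= 4 & n_i <= 8))
  cfg2 <- sim_config(seed = 14, n_total = 443)
  tt2 <- simulate_traits(simulate_tree(cfg2), cfg2)
  expect_equal(nrow(tt2), 443)
})

test_that("the shifted clade carries excess residual variance", {
  hits <- logical(6)
  for (i in seq_along(hits)) {
    cfg <- sim_config(seed = 800 + i)
    tr <- simulate_tree(cfg)
    tt <- simulate_traits(tr, cfg)
    truth <- attr(tt, "truth")
    dev <- truth$phylo_deviation
    hits[i] <- var(dev[truth$in_shifted_clade]) > var(dev[!truth$in_shifted_clade])
  }
  expect_gte(mean(hits), 0.8)
})

test_that("posterior trees jitter branch lengths but not the tip set", {
  cfg <- sim_config(seed = 15, n_species = 20, n_posterior_trees = 500,
                    bl_jitter = 0.1)
  tr <- simulate_tree(cfg)
  post <- simulate_posterior_trees(tr, cfg)
  expect_length(post, 500)
  expect_true(all(vapply(post, function(t)
    setequal(t$tip.label, tr$tip.label), TRUE)))
  # mean root-to-tip depth over tips and trees; each path's expected jitter
  # factor is exp(bl_jitter^2 / 2) ~ 1.005
  depths <- vapply(post, function(t)
    mean(eyescale:::node_depths(t)[1:20]), 0)
  expect_lt(abs(mean(depths) - mean(eyescale:::node_depths(tr)[1:20])), 0.05)

  cfg0 <- sim_config(seed = 15, n_species = 20, n_posterior_trees = 5,
                     bl_jitter = 0)
  post0 <- simulate_posterior_trees(tr, cfg0)
  expect_identical(ape::write.tree(post0[[1]]), ape::write.tree(post0[[5]]))
})

test_that("a full fixture bundle is deterministic and loads cleanly", {
  cfg <- sim_config(seed = 16, n_species = 15, n_posterior_trees = 5,
                    n_transects = 4, segments_per_transect = 4,
                    raster_dim = c(60, 60))
  d1 <- file.path(tempdir(), "fix1"); d2 <- file.path(tempdir(), "fix2")
  p1 <- simulate_dataset(cfg, d1)
  p2 <- simulate_dataset(cfg, d2)
  for (nm in names(p1))
    expect_identical(readLines(p1[[nm]]), readLines(p2[[nm]]),
                     label = paste("file", nm))

  tr <- read_phylogeny(p1$tree)
  expect_equal(length(tr$tip.label), 15)
  tt <- load_traits(p1$traits)
  expect_equal(nrow(attr(tt, "dropped")), 0)
  expect_length(read_posterior_trees(p1$posterior), 5)
  ras <- read_ascii_grid(p1$raster)
  expect_equal(dim(ras$values), c(60, 60))
  segs <- load_segments(p1$segments)
  expect_length(segs, 16)
  occ <- load_occurrences(p1$occurrences)
  expect_true(all(occ$species %in% tr$tip.label))
  expect_equal(length(setdiff(tr$tip.label, occ$species)), 2)  # withheld pair
})

test_that("two species with identical occurrences get identical medians", {
  hab <- data.frame(transect_id = "T", segment_id = c("a", "b", "c"),
                    cover = c(15, 55, 75), n_cells = 3, excluded = FALSE)
  occ <- expand.grid(segment_id = c("a", "b"), species = c("s1", "s2"))
  occ$transect_id <- "T"; occ$abundance <- 1
  sh <- species_habitat(occ, hab)
  expect_equal(sh$median_cover[1], sh$median_cover[2])
})
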