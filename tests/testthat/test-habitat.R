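test_that("coverage-fraction weighting matches hand arithmetic", {
  wc <- weighted_cover(c(0.25, 0.75), c(20, 80))
  expect_equal(wc$weighted_mean, 65)
  # a cell below the exclusion threshold drops out of both sums
  wc2 <- weighted_cover(c(0.25, 0.75, 0.001), c(20, 80, 0))
  expect_equal(wc2$weighted_mean, 65)
  expect_equal(wc2$keep, c(TRUE, TRUE, FALSE))
  # missing covers are excluded
  wc3 <- weighted_cover(c(0.5, 0.5), c(NA, 30))
  expect_equal(wc3$weighted_mean, 30)
  expect_true(is.na(weighted_cover(0.001, 50)$weighted_mean))
})

test_that("a uniform raster gives the uniform value for any geometry", {
  ras <- cover_raster(matrix(40, 30, 30), cell_size = 10)
  for (coords in list(rbind(c(50, 50), c(150, 150)),
                      rbind(c(30, 200), c(120, 200), c(120, 90)))) {
    sh <- segment_coverage(transect_segment("T", "S", coords), ras)
    expect_equal(sh$weighted_mean_cover, 40)
    expect_gt(sh$n_cells_used, 0)
  }
})

test_that("coverage fractions sum to buffered area over cell area", {
  ras <- cover_raster(matrix(50, 40, 40), cell_size = 10)
  seg <- transect_segment("T", "S", rbind(c(100, 120), c(250, 190)))
  sh <- segment_coverage(seg, ras, min_fraction = 0)
  len <- sqrt(150^2 + 70^2)
  capsule_area <- 2 * 10 * len + pi * 10^2
  expect_equal(sum(sh$fractions$fraction), capsule_area / 100,
               tolerance = 0.01 * capsule_area / 100)
  # weighted mean is convex in the contributing covers
  expect_gte(sh$weighted_mean_cover, min(sh$fractions$cover))
  expect_lte(sh$weighted_mean_cover, max(sh$fractions$cover))
})

test_that("segments outside the raster are flagged and excluded", {
  ras <- cover_raster(matrix(50, 10, 10), cell_size = 10)
  seg <- transect_segment("T", "S", rbind(c(500, 500), c(600, 600)))
  expect_warning(sh <- segment_coverage(seg, ras), "outside")
  expect_true(sh$excluded)
})

test_that("ascii grid rasters round-trip including missing cells", {
  m <- matrix(runif(30, 0, 100), 5, 6)
  m[2, 3] <- NA
  ras <- cover_raster(m, x0 = 100, y0 = 200, cell_size = 10)
  f <- tempfile(fileext = ".asc")
  write_ascii_grid(ras, f)
  back <- read_ascii_grid(f)
  expect_equal(back$values, ras$values, tolerance = 1e-10)
  expect_equal(back$x0, 100)
  expect_equal(back$cell_size, 10)
  expect_error(cover_raster(matrix(150, 2, 2)), "0, 100")
})

test_that("species habitat is presence-based with an empirical median", {
  hab <- data.frame(transect_id = "T1", segment_id = c("a", "b", "c"),
                    cover = c(10, 20, 90), n_cells = 5, excluded = FALSE)
  occ <- data.frame(transect_id = "T1",
                    segment_id = c("a", "b", "c", "a", "a"),
                    species = c("x", "x", "x", "y", "y"),
                    abundance = c(1, 5, 2, 3, 7))
  sh <- species_habitat(occ, hab)
  expect_equal(sh$median_cover[sh$species == "x"], 20)
  # duplicated (species, segment) rows do not change the distribution
  expect_equal(sh$median_cover[sh$species == "y"], 10)
  expect_equal(sh$n_segments[sh$species == "y"], 1)

  # a species only on unresolvable segments is excluded with a message
  occ2 <- rbind(occ, data.frame(transect_id = "T9", segment_id = "zz",
                                species = "ghost", abundance = 1))
  expect_message(sh2 <- species_habitat(occ2, hab), "ghost")
  expect_false("ghost" %in% sh2$species)
})

test_that("community-weighted means follow the abundance weighting", {
  expect_equal(community_weighted_mean(5, 3.3), 3.3)
  expect_equal(community_weighted_mean(c(3, 1), c(1, 2)), 1.25)
  expect_equal(community_weighted_mean(c(2, 2, 2), c(1, 2, 6)), 3)
  expect_error(community_weighted_mean(c(0, 0), c(1, 2)), "zero")
  tr <- c(0.2, 0.9, 0.5)
  ab <- c(4, 1, 7)
  cwm <- community_weighted_mean(ab, tr)
  expect_gte(cwm, min(tr)); expect_lte(cwm, max(tr))
})

test_that("cwm table joins traits by species and skips empty segments", {
  occ <- data.frame(transect_id = "T1", segment_id = c("a", "a", "b"),
                    species = c("x", "y", "zz"), abundance = c(3, 1, 2))
  traits <- c(x = 1, y = 2)
  tab <- cwm_table(occ, traits)
  expect_equal(nrow(tab), 1)  # segment b has no species with traits
  expect_equal(tab$cwm, 1.25)
})

test_that("cwm regression returns exact OLS results", {
  cover <- c(10, 30, 50, 70)
  cwm <- 0.2 - 0.001 * cover
  # lm warns about the numerically perfect fit; the exactness is the point
  r <- suppressWarnings(cwm_regression(cwm, cover))
  expect_equal(r$slope, -0.001, tolerance = 1e-12)
  expect_equal(r$r.squared, 1)
  expect_equal(suppressWarnings(cwm_regression(rep(0.5, 4), cover))$slope, 0,
               tolerance = 1e-12)
  expect_error(cwm_regression(cwm, rep(1, 4)), "constant")
  expect_error(cwm_regression(cwm[1:2], cover[1:2]), "3 segments")
})

test_that("habitat PGLS wires species, habitat and tree together", {
  cfg <- sim_config(seed = 31)
  tr <- simulate_tree(cfg)
  tt <- simulate_traits(tr, cfg)
  mon <- simulate_monitoring(tr, tt, cfg)
  seg <- segments_coverage(mon$segments, mon$raster, supersample = 4)
  sph <- species_habitat(mon$occurrences, seg)
  ms <- species_means(tt)
  f <- habitat_pgls(ms, sph, tr)
  expect_s3_class(f, "pgls")
  expect_true("cover_z" %in% names(coef(f)))
  expect_equal(f$n, 57)  # two species withheld from monitoring
  f_abs <- habitat_pgls(ms, sph, tr, include_wing = FALSE)
  expect_false("wing_z" %in% names(coef(f_abs)))
  f_nym <- habitat_pgls(ms, sph, tr, families = "Nymphalidae")
  expect_lt(f_nym$n, f$n)
  expect_error(habitat_pgls(ms, sph, tr, families = "NoSuchFamily"),
               "fewer than 4")
})

test_that("a forest specialist's median sits above the landscape median", {
  hits <- logical(5)
  for (i in 1:5) {
    cfg <- sim_config(seed = 700 + i, n_species = 20)
    tr <- simulate_tree(cfg)
    tt <- simulate_traits(tr, cfg)
    truth <- attr(tt, "truth")
    # force one monitored species to a high-cover optimum
    truth$habitat_optimum[1] <- 90
    attr(tt, "truth") <- truth
    mon <- simulate_monitoring(tr, tt, cfg)
    if (truth$species[1] %in% mon$withheld) { hits[i] <- NA; next }
    seg <- segments_coverage(mon$segments, mon$raster, supersample = 4)
    sph <- species_habitat(mon$occurrences, seg)
    med <- sph$median_cover[sph$species == truth$species[1]]
    hits[i] <- length(med) == 1 && med > median(seg$cover, na.rm = TRUE)
  }
  expect_gte(mean(hits, na.rm = TRUE), 0.8)
})
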