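#' Configuration for the synthetic-data generator
#'
#' Defaults emulate the empirical study conditions: 59 species, 4-8 scanned
#' individuals per species in two sexes (or an exact total via `n_total`),
#' log10-log10 allometry with slope 0.55, a +0.11 male eye-size offset on the
#' log10 scale, strong species-level phylogenetic variance, one monophyletic
#' clade (the skipper-family analogue) with a 10x Brownian rate, 500-tree
#' posterior sets with 10% branch-length jitter, and transect monitoring with
#' a tunable trait-habitat coupling whose default (0) reproduces the
#' no-association finding.
#'
#' @param seed Integer seed; all generators derive their streams from it.
#' @param n_species Number of species (tips).
#' @param n_per_species Range (length-2) of individuals per species.
#' @param n_total Optional exact total number of individuals, spread as evenly
#'   as possible across species (overrides `n_per_species`).
#' @param allometric_slope,intercept Allometry on the log10-log10 scale.
#' @param sex_offset Added to male log10 eye size.
#' @param sigma2_phylo Brownian variance of the species-level eye-size
#'   deviation (per unit tree height).
#' @param sigma2_resid Within-species measurement/residual variance of log10
#'   eye size.
#' @param sigma2_ind Variance of individual body-size deviations (log10
#'   scale); an individual's eye scales allometrically with its own size, so
#'   this variation is shared between wing and eye.
#' @param sigma2_wing Brownian variance of log10 forewing length.
#' @param wing_mean Root state of log10 forewing length.
#' @param shifted_clade_size Target tip count of the elevated-rate clade.
#' @param rate_multiplier Brownian rate multiplier inside the shifted clade.
#' @param n_families Number of monophyletic family labels.
#' @param habitat_effect Coupling between species habitat optimum and eye
#'   size (0 = none).
#' @param assoc_strength Strength of the species-habitat association in the
#'   occurrence model (0 = species occur independently of cover).
#' @param n_transects,segments_per_transect,segment_length_m Monitoring
#'   design.
#' @param raster_dim,cell_size,smooth_cells Cover-raster extent (rows,
#'   cols), cell size in meters, and Gaussian smoothing radius in cells.
#' @param n_posterior_trees,bl_jitter Posterior tree set size and relative
#'   log-normal branch-length jitter.
#' @return List of class `"sim_config"`.
#' @export
sim_config <- function(seed = 1, n_species = 59, n_per_species = c(4, 8),
                       n_total = NULL, allometric_slope = 0.55,
                       intercept = -0.2, sex_offset = 0.11,
                       sigma2_phylo = 0.01, sigma2_resid = 0.0025,
                       sigma2_ind = 0.002, sigma2_wing = 0.03,
                       wing_mean = 1.3,
                       shifted_clade_size = 8, rate_multiplier = 10,
                       n_families = 6, habitat_effect = 0,
                       assoc_strength = 8, n_transects = 30,
                       segments_per_transect = 10, segment_length_m = 50,
                       raster_dim = c(150, 150), cell_size = 10,
                       smooth_cells = 8, n_posterior_trees = 500,
                       bl_jitter = 0.1) {
  stopifnot(n_species >= 4, sigma2_phylo > 0, sigma2_resid > 0,
            sigma2_ind >= 0, sigma2_wing > 0, rate_multiplier > 0,
            bl_jitter >= 0)
  cfg <- as.list(environment())
  class(cfg) <- "sim_config"
  cfg
}

# family names in decreasing assignment priority; the shifted clade is always
# the skipper analogue
.family_names <- c("Hesperiidae", "Nymphalidae", "Lycaenidae", "Pieridae",
                   "Papilionidae", "Riodinidae", "Satyridae", "Zygaenidae")

#' Simulate a pure-birth phylogeny with family structure
#'
#' Generates a fully bifurcating ultrametric tree, rescales its depth to 1,
#' partitions the tips into monophyletic family groups, and designates the
#' group closest to `shifted_clade_size` tips as the elevated-rate clade
#' (family label "Hesperiidae"). The family map and the shifted clade's tips
#' are attached as attributes `"families"` and `"shifted_clade"`.
#'
#' @param config A `"sim_config"`.
#' @return A `"phylo"` object with `n_species` tips named `sp001`, ...
#' @export
simulate_tree <- function(config) {
  set.seed(config$seed)
  n <- config$n_species
  tr <- ape::rphylo(n, birth = 1, death = 0)
  tr$tip.label <- sprintf("sp%03d", seq_len(n))
  depth <- max(node_depths(tr)[seq_len(n)])
  tr$edge.length <- tr$edge.length / depth

  # partition tips into monophyletic groups by repeatedly splitting the
  # largest clade at its root
  desc <- descendant_tips(tr)
  root <- n + 1L
  kids <- function(v) tr$edge[tr$edge[, 1] == v, 2]
  groups <- as.list(kids(root))
  while (length(groups) < config$n_families) {
    sizes <- vapply(groups, function(v) length(desc[[v]]), 0L)
    splittable <- which(sizes > 1)
    if (!length(splittable)) break
    g <- splittable[which.max(sizes[splittable])]
    groups <- c(groups[-g], as.list(kids(groups[[g]])))
  }
  sizes <- vapply(groups, function(v) length(desc[[v]]), 0L)
  # the rate-shifted family emulates an old, distinct clade (long stem
  # branch, like the skippers' deep split): among groups of workable size,
  # take the one with the longest stem
  stems <- vapply(groups, function(v)
    tr$edge.length[match(v, tr$edge[, 2])], 0)
  workable <- sizes >= 4 & sizes <= max(config$shifted_clade_size * 2 + 1,
                                        ceiling(n / 3))
  shifted_i <- if (any(workable)) which(workable)[which.max(stems[workable])]
               else which.min(abs(sizes - config$shifted_clade_size))
  ord <- c(shifted_i, setdiff(order(sizes, decreasing = TRUE), shifted_i))
  fam <- character(n)
  for (k in seq_along(ord))
    fam[desc[[groups[[ord[k]]]]]] <- .family_names[min(k,
                                                       length(.family_names))]
  names(fam) <- tr$tip.label
  attr(tr, "families") <- fam
  attr(tr, "shifted_clade") <- tr$tip.label[desc[[groups[[shifted_i]]]]]
  attr(tr, "shifted_node") <- groups[[shifted_i]]
  tr
}

# Brownian draw on a tree: MVN(0, sigma2 * C) via Cholesky
.rbm <- function(C, sigma2) {
  drop(t(chol(C)) %*% stats::rnorm(nrow(C))) * sqrt(sigma2)
}

#' Simulate individual-level trait measurements
#'
#' Species log10 forewing length evolves by Brownian motion on the tree;
#' species log10 eye size is `intercept + slope * wing + u`, where `u` is a
#' Brownian deviation whose rate is multiplied inside the shifted clade.
#' Each individual deviates from its species size by `s ~ N(0, sigma2_ind)`,
#' shared allometrically between wing (`+ s`) and eye (`+ slope * s`), and
#' adds the sex offset (males) plus i.i.d. measurement noise on eye size. Each species also receives a habitat optimum (percent
#' cover); a nonzero `habitat_effect` adds `habitat_effect * z(optimum)` to
#' species eye size, coupling trait and habitat.
#'
#' @param tree Tree from [simulate_tree()].
#' @param config A `"sim_config"`.
#' @return A `"trait_table"` data frame (linear scale, as measured); the
#'   species-level ground truth is attached as attribute `"truth"`.
#' @export
simulate_traits <- function(tree, config) {
  set.seed(config$seed + 1000L)
  n <- config$n_species
  C <- phylo_vcv(tree)
  fam <- attr(tree, "families")
  shifted <- attr(tree, "shifted_clade")

  wing <- config$wing_mean + .rbm(C, config$sigma2_wing)

  # eye-size deviation: BM with branch lengths multiplied inside the clade
  tr2 <- tree
  A <- edge_incidence(tree)
  inclade <- colSums(A[shifted, , drop = FALSE]) == colSums(A)
  tr2$edge.length[inclade] <- tr2$edge.length[inclade] * config$rate_multiplier
  u <- .rbm(ape::vcv.phylo(tr2)[tree$tip.label, tree$tip.label],
            config$sigma2_phylo)

  optimum <- stats::runif(n, 5, 95)
  names(optimum) <- tree$tip.label
  eye <- config$intercept + config$allometric_slope * wing + u
  if (config$habitat_effect != 0)
    eye <- eye + config$habitat_effect *
      (optimum - mean(optimum)) / stats::sd(optimum)

  if (!is.null(config$n_total)) {
    base <- config$n_total %/% n
    extra <- config$n_total %% n
    n_ind <- rep(base, n) + (seq_len(n) <= extra)
  } else {
    n_ind <- sample(seq(config$n_per_species[1], config$n_per_species[2]),
                    n, replace = TRUE)
  }

  rows <- lapply(seq_len(n), function(i) {
    ni <- n_ind[i]
    sex <- rep(c("male", "female"), length.out = ni)
    s <- stats::rnorm(ni, 0, sqrt(config$sigma2_ind))
    log_eye <- eye[i] + config$allometric_slope * s +
      config$sex_offset * (sex == "male") +
      stats::rnorm(ni, 0, sqrt(config$sigma2_resid))
    log_wing <- wing[i] + s
    data.frame(individual_id = sprintf("%s_%02d", tree$tip.label[i],
                                       seq_len(ni)),
               species = tree$tip.label[i], sex = sex,
               family = unname(fam[i]),
               eye_area = 10^log_eye, forewing_length = 10^log_wing,
               stringsAsFactors = FALSE)
  })
  tab <- do.call(rbind, rows)
  rownames(tab) <- NULL
  attr(tab, "log10") <- FALSE
  attr(tab, "truth") <- data.frame(
    species = tree$tip.label, family = unname(fam),
    log10_wing = unname(wing), log10_eye = unname(eye),
    phylo_deviation = unname(u), habitat_optimum = unname(optimum),
    in_shifted_clade = tree$tip.label %in% shifted,
    stringsAsFactors = FALSE)
  class(tab) <- c("trait_table", "data.frame")
  tab
}

#' Simulate a posterior tree set
#'
#' Fixed topology; every branch length multiplied by an independent
#' log-normal(0, `bl_jitter`) factor, emulating dating uncertainty.
#'
#' @param tree Reference tree.
#' @param config A `"sim_config"`.
#' @return A `"multiPhylo"` of `n_posterior_trees` trees.
#' @export
simulate_posterior_trees <- function(tree, config) {
  set.seed(config$seed + 2000L)
  m <- length(tree$edge.length)
  trees <- lapply(seq_len(config$n_posterior_trees), function(i) {
    t2 <- tree
    t2$edge.length <- t2$edge.length *
      exp(stats::rnorm(m, 0, config$bl_jitter))
    t2
  })
  class(trees) <- "multiPhylo"
  trees
}

# Gaussian-smoothed white-noise field rescaled to [0, 100]
.smooth_field <- function(nr, nc, radius) {
  z <- matrix(stats::rnorm(nr * nc), nr, nc)
  k <- stats::dnorm(seq(-3 * radius, 3 * radius), 0, radius)
  k <- k / sum(k)
  pad <- length(k) %/% 2
  smooth1 <- function(m) {
    # reflect-pad rows then convolve each column
    n1 <- nrow(m)
    mp <- rbind(m[pad:1, , drop = FALSE], m, m[n1:(n1 - pad + 1), ,
                                               drop = FALSE])
    apply(mp, 2, function(col) stats::filter(col, k, sides = 2))[
      pad + seq_len(n1), , drop = FALSE]
  }
  z <- smooth1(z)
  z <- t(smooth1(t(z)))
  z <- 100 * (z - min(z)) / (max(z) - min(z))
  pmin(pmax(z, 0), 100)  # guard against floating-point overshoot
}

#' Simulate monitoring data: cover raster, transects, occurrences
#'
#' The tree-cover raster is spatially autocorrelated smoothed noise on
#' \[0, 100\]. Straight transects are placed across the landscape and divided
#' into fixed-length segments. Each species occurs on a segment with a
#' logistic probability declining in the mismatch between the segment's cover
#' and the species' habitat optimum (strength `assoc_strength`; 0 makes
#' occupancy habitat-blind), with Poisson abundance given presence. Two
#' species are withheld from the output, emulating monitoring schemes that
#' never record some of the studied species.
#'
#' @param tree Tree from [simulate_tree()].
#' @param traits Trait table from [simulate_traits()] (for the habitat
#'   optima).
#' @param config A `"sim_config"`.
#' @return List: `raster` (`"cover_raster"`), `segments` (list of
#'   `"transect_segment"`), `occurrences` (data frame), `truth` (species
#'   optima and true segment covers), `withheld` (species labels).
#' @export
simulate_monitoring <- function(tree, traits, config) {
  set.seed(config$seed + 3000L)
  nr <- config$raster_dim[1]; nc <- config$raster_dim[2]
  cs <- config$cell_size
  ras <- cover_raster(.smooth_field(nr, nc, config$smooth_cells),
                      x0 = 0, y0 = 0, cell_size = cs)

  xmax <- nc * cs; ymax <- nr * cs
  tr_len <- config$segments_per_transect * config$segment_length_m
  segs <- list()
  seg_cover_true <- c()
  for (t in seq_len(config$n_transects)) {
    repeat {
      x <- stats::runif(1, 0.05 * xmax, 0.95 * xmax)
      y <- stats::runif(1, 0.05 * ymax, 0.95 * ymax)
      ang <- stats::runif(1, 0, 2 * pi)
      xe <- x + tr_len * cos(ang); ye <- y + tr_len * sin(ang)
      if (xe > 0 && xe < xmax && ye > 0 && ye < ymax) break
    }
    for (s in seq_len(config$segments_per_transect)) {
      f0 <- (s - 1) / config$segments_per_transect
      f1 <- s / config$segments_per_transect
      p0 <- c(x + f0 * (xe - x), y + f0 * (ye - y))
      p1 <- c(x + f1 * (xe - x), y + f1 * (ye - y))
      seg <- transect_segment(sprintf("T%02d", t), sprintf("S%02d", s),
                              rbind(p0, p1))
      segs <- c(segs, list(seg))
      # true habitat of the segment: cover at sampled points along the line
      fr <- seq(0, 1, length.out = 11)
      px <- p0[1] + fr * (p1[1] - p0[1]); py <- p0[2] + fr * (p1[2] - p0[2])
      i <- pmin(nr, pmax(1, floor(py / cs) + 1))
      j <- pmin(nc, pmax(1, floor(px / cs) + 1))
      seg_cover_true <- c(seg_cover_true, mean(ras$values[cbind(i, j)]))
    }
  }

  truth_sp <- attr(traits, "truth")
  opt <- truth_sp$habitat_optimum
  names(opt) <- truth_sp$species
  withheld <- sample(truth_sp$species, 2)
  active <- setdiff(truth_sp$species, withheld)

  occ <- list()
  for (k in seq_along(segs)) {
    cover <- seg_cover_true[k]
    p <- stats::plogis(2 - config$assoc_strength * abs(cover - opt[active]) /
                         100)
    pres <- stats::runif(length(active)) < p
    if (!any(pres)) next
    occ[[length(occ) + 1]] <- data.frame(
      transect_id = segs[[k]]$transect_id, segment_id = segs[[k]]$segment_id,
      species = active[pres],
      abundance = stats::rpois(sum(pres), 3) + 1,
      stringsAsFactors = FALSE)
  }
  occurrences <- do.call(rbind, occ)
  rownames(occurrences) <- NULL

  list(raster = ras, segments = segs, occurrences = occurrences,
       truth = list(optima = opt, segment_cover = seg_cover_true),
       withheld = withheld)
}

#' Write a complete synthetic input bundle to disk
#'
#' Emits exactly the formats the loaders read: `tree.nwk`, `traits.csv`,
#' `posterior_trees.nwk` (one tree per line), `raster.asc`, `segments.csv`,
#' `occurrences.csv`. Byte-identical across runs with the same configuration.
#'
#' @param config A `"sim_config"`.
#' @param dir Output directory (created if needed).
#' @return Named list of file paths, invisibly; the simulated objects as the
#'   `"objects"` attribute.
#' @export
simulate_dataset <- function(config, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  tree <- simulate_tree(config)
  traits <- simulate_traits(tree, config)
  post <- simulate_posterior_trees(tree, config)
  mon <- simulate_monitoring(tree, traits, config)

  paths <- list(tree = file.path(dir, "tree.nwk"),
                traits = file.path(dir, "traits.csv"),
                posterior = file.path(dir, "posterior_trees.nwk"),
                raster = file.path(dir, "raster.asc"),
                segments = file.path(dir, "segments.csv"),
                occurrences = file.path(dir, "occurrences.csv"))
  write_phylogeny(tree, paths$tree)
  utils::write.csv(as.data.frame(traits), paths$traits, row.names = FALSE)
  write_phylogeny(post, paths$posterior)
  write_ascii_grid(mon$raster, paths$raster)
  seg_df <- do.call(rbind, lapply(mon$segments, function(s)
    data.frame(transect_id = s$transect_id, segment_id = s$segment_id,
               vertex = seq_len(nrow(s$coords)),
               x = s$coords[, 1], y = s$coords[, 2])))
  utils::write.csv(seg_df, paths$segments, row.names = FALSE)
  utils::write.csv(mon$occurrences, paths$occurrences, row.names = FALSE)
  attr(paths, "objects") <- list(tree = tree, traits = traits,
                                 posterior = post, monitoring = mon)
  invisible(paths)
}
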