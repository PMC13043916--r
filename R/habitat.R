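# --- raster ------------------------------------------------------------------

#' Create a tree-cover raster grid
#'
#' A regular grid of percent tree cover. `values[i, j]` is the cell whose
#' lower-left corner is at `(x0 + (j-1)*cell_size, y0 + (i-1)*cell_size)`,
#' i.e. row index increases with y (note this is flipped relative to the
#' top-down row order of the ESRI ASCII file format; the readers/writers
#' handle the flip).
#'
#' @param values Numeric matrix in \[0, 100\] (NA = missing).
#' @param x0,y0 Coordinates of the grid's lower-left corner, in meters.
#' @param cell_size Cell edge length in meters, > 0.
#' @return Object of class `"cover_raster"`.
#' @export
cover_raster <- function(values, x0 = 0, y0 = 0, cell_size = 10) {
  stopifnot(is.matrix(values), cell_size > 0)
  v <- values[is.finite(values)]
  if (length(v) && (min(v) < 0 || max(v) > 100))
    stop("cover values must be in [0, 100] or missing")
  structure(list(values = values, x0 = x0, y0 = y0, cell_size = cell_size),
            class = "cover_raster")
}

#' Read an ESRI ASCII grid raster
#'
#' @param path File with an `ncols/nrows/xllcorner/yllcorner/cellsize/
#'   NODATA_value` header followed by the matrix (rows top-down).
#' @return A `"cover_raster"`.
#' @export
read_ascii_grid <- function(path) {
  lines <- readLines(path)
  hdr <- list()
  i <- 1
  while (grepl("^[A-Za-z]", lines[i])) {
    kv <- strsplit(trimws(lines[i]), "\\s+")[[1]]
    hdr[[tolower(kv[1])]] <- as.numeric(kv[2])
    i <- i + 1
  }
  need <- c("ncols", "nrows", "xllcorner", "yllcorner", "cellsize")
  miss <- setdiff(need, names(hdr))
  if (length(miss)) stop("ASCII grid header missing: ",
                         paste(miss, collapse = ", "))
  vals <- scan(text = paste(lines[i:length(lines)], collapse = "\n"),
               quiet = TRUE)
  if (length(vals) != hdr$ncols * hdr$nrows)
    stop("ASCII grid has ", length(vals), " values, expected ",
         hdr$ncols * hdr$nrows)
  m <- matrix(vals, nrow = hdr$nrows, ncol = hdr$ncols, byrow = TRUE)
  if (!is.null(hdr$nodata_value)) m[m == hdr$nodata_value] <- NA
  m <- m[rev(seq_len(nrow(m))), , drop = FALSE]  # file is top-down
  cover_raster(m, hdr$xllcorner, hdr$yllcorner, hdr$cellsize)
}

#' Write a raster as an ESRI ASCII grid
#'
#' @param raster A `"cover_raster"`.
#' @param path Output file.
#' @param nodata Value written for missing cells.
#' @export
write_ascii_grid <- function(raster, path, nodata = -9999) {
  m <- raster$values
  m[!is.finite(m)] <- nodata
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c(paste("ncols", ncol(m)), paste("nrows", nrow(m)),
               paste("xllcorner", raster$x0), paste("yllcorner", raster$y0),
               paste("cellsize", raster$cell_size),
               paste("NODATA_value", nodata)), con)
  utils::write.table(m[rev(seq_len(nrow(m))), , drop = FALSE], con,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}

# --- transect segments -------------------------------------------------------

#' Construct a transect segment
#'
#' @param transect_id,segment_id Identifiers.
#' @param coords Two-column matrix of (x, y) polyline vertices in meters,
#'   at least 2 rows with positive total length.
#' @param buffer_m Buffer half-width in meters (10 m on each side of the
#'   transect by default).
#' @return Object of class `"transect_segment"`.
#' @export
transect_segment <- function(transect_id, segment_id, coords, buffer_m = 10) {
  coords <- as.matrix(coords)
  stopifnot(ncol(coords) == 2, nrow(coords) >= 2, buffer_m > 0)
  len <- sum(sqrt(rowSums(diff(coords)^2)))
  if (len <= 0) stop("segment has zero length")
  structure(list(transect_id = as.character(transect_id),
                 segment_id = as.character(segment_id),
                 coords = coords, buffer_m = buffer_m, length = len),
            class = "transect_segment")
}

#' Load transect segments from CSV
#'
#' Expected columns: `transect_id`, `segment_id`, `vertex`, `x`, `y`; vertices
#' are ordered within each segment.
#'
#' @param path CSV path.
#' @param buffer_m Buffer half-width applied to every segment.
#' @return List of `"transect_segment"` objects.
#' @export
load_segments <- function(path, buffer_m = 10) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  req <- c("transect_id", "segment_id", "vertex", "x", "y")
  miss <- setdiff(req, names(df))
  if (length(miss)) stop("missing columns: ", paste(miss, collapse = ", "))
  key <- paste(df$transect_id, df$segment_id, sep = "\r")
  lapply(split(df, factor(key, levels = unique(key))), function(d) {
    d <- d[order(d$vertex), ]
    transect_segment(d$transect_id[1], d$segment_id[1],
                     cbind(d$x, d$y), buffer_m)
  })
}

#' Coverage-fraction-weighted mean cover
#'
#' The weighting kernel of [segment_coverage()]: drops cells whose coverage
#' fraction is below `min_fraction`, then returns `sum(f v) / sum(f)` over
#' the retained cells (missing covers excluded).
#'
#' @param fractions Coverage fractions in (0, 1\].
#' @param covers Cell cover values (% in \[0, 100\], NA = missing).
#' @param min_fraction Exclusion threshold (default 0.002).
#' @return List: `weighted_mean` (NA if nothing retained), `keep` (logical).
#' @export
weighted_cover <- function(fractions, covers, min_fraction = 0.002) {
  stopifnot(length(fractions) == length(covers))
  keep <- fractions >= min_fraction & is.finite(covers)
  wm <- if (any(keep)) {
    sum(fractions[keep] * covers[keep]) / sum(fractions[keep])
  } else NA_real_
  list(weighted_mean = wm, keep = keep)
}

# squared distance from points (px, py) to segment (x1,y1)-(x2,y2), vectorized
.dist2_to_seg <- function(px, py, x1, y1, x2, y2) {
  dx <- x2 - x1; dy <- y2 - y1
  L2 <- dx * dx + dy * dy
  t <- if (L2 == 0) 0 else pmin(1, pmax(0, ((px - x1) * dx + (py - y1) * dy) / L2))
  (px - (x1 + t * dx))^2 + (py - (y1 + t * dy))^2
}

#' Coverage-fraction-weighted tree cover of one segment
#'
#' Buffers the segment's polyline by `buffer_m` on each side (a capsule with
#' rounded end caps), computes the fraction of each raster cell's area inside
#' the buffer by supersampling the cell at `supersample^2` points, drops cells
#' with fraction below `min_fraction` (default 0.002) and missing cells, and
#' returns the coverage-fraction-weighted mean cover
#' `sum(f_i v_i) / sum(f_i)`.
#'
#' @param segment A `"transect_segment"`.
#' @param raster A `"cover_raster"`.
#' @param min_fraction Exclusion threshold on the coverage fraction.
#' @param supersample Subsampling resolution per cell edge (32 gives < 0.1%
#'   area error; reduce for large simulation sweeps).
#' @return List of class `"segment_habitat"`: `transect_id`, `segment_id`,
#'   `weighted_mean_cover`, `n_cells_used`, `fractions` (data frame),
#'   `excluded` flag (TRUE if no cell was retained).
#' @export
segment_coverage <- function(segment, raster, min_fraction = 0.002,
                             supersample = 32) {
  cs <- raster$cell_size
  v <- raster$values
  xy <- segment$coords
  b <- segment$buffer_m

  # candidate cells: bounding box of the buffered polyline
  jmin <- max(1L, floor((min(xy[, 1]) - b - raster$x0) / cs) + 1L)
  jmax <- min(ncol(v), ceiling((max(xy[, 1]) + b - raster$x0) / cs))
  imin <- max(1L, floor((min(xy[, 2]) - b - raster$y0) / cs) + 1L)
  imax <- min(nrow(v), ceiling((max(xy[, 2]) + b - raster$y0) / cs))
  if (jmin > jmax || imin > imax) {
    warning("segment ", segment$segment_id, " lies outside the raster")
    return(structure(list(transect_id = segment$transect_id,
                          segment_id = segment$segment_id,
                          weighted_mean_cover = NA_real_, n_cells_used = 0L,
                          fractions = NULL, excluded = TRUE),
                     class = "segment_habitat"))
  }
  cells <- expand.grid(i = imin:imax, j = jmin:jmax)

  # supersample each candidate cell at the centers of an s x s subgrid
  s <- supersample
  off <- (seq_len(s) - 0.5) / s * cs
  sub <- expand.grid(ox = off, oy = off)
  n1 <- nrow(xy) - 1L
  b2 <- b * b
  frac <- vapply(seq_len(nrow(cells)), function(k) {
    cx <- raster$x0 + (cells$j[k] - 1) * cs
    cy <- raster$y0 + (cells$i[k] - 1) * cs
    px <- cx + sub$ox; py <- cy + sub$oy
    inside <- rep(FALSE, length(px))
    for (e in seq_len(n1)) {
      inside <- inside | .dist2_to_seg(px, py, xy[e, 1], xy[e, 2],
                                       xy[e + 1, 1], xy[e + 1, 2]) <= b2
      if (all(inside)) break
    }
    mean(inside)
  }, 0)

  val <- v[cbind(cells$i, cells$j)]
  wc <- weighted_cover(frac, val, min_fraction)
  keep <- wc$keep
  if (!any(keep)) {
    return(structure(list(transect_id = segment$transect_id,
                          segment_id = segment$segment_id,
                          weighted_mean_cover = NA_real_, n_cells_used = 0L,
                          fractions = NULL, excluded = TRUE),
                     class = "segment_habitat"))
  }
  f <- frac[keep]; vv <- val[keep]
  structure(list(transect_id = segment$transect_id,
                 segment_id = segment$segment_id,
                 weighted_mean_cover = wc$weighted_mean,
                 n_cells_used = sum(keep),
                 fractions = data.frame(i = cells$i[keep], j = cells$j[keep],
                                        fraction = f, cover = vv),
                 excluded = FALSE),
            class = "segment_habitat")
}

#' Weighted cover for a list of segments
#'
#' @inheritParams segment_coverage
#' @param segments List of `"transect_segment"` objects.
#' @return Data frame: `transect_id`, `segment_id`, `cover`, `n_cells`,
#'   `excluded`.
#' @export
segments_coverage <- function(segments, raster, min_fraction = 0.002,
                              supersample = 32) {
  rows <- lapply(segments, function(s) {
    h <- segment_coverage(s, raster, min_fraction, supersample)
    data.frame(transect_id = h$transect_id, segment_id = h$segment_id,
               cover = h$weighted_mean_cover, n_cells = h$n_cells_used,
               excluded = h$excluded, stringsAsFactors = FALSE)
  })
  do.call(rbind, c(rows, list(make.row.names = FALSE)))
}

# --- species habitat and community-weighted means ----------------------------

#' Load per-segment species occurrence records
#'
#' Expected columns: `transect_id`, `segment_id`, `species`, `abundance`
#' (mean count across years, >= 0).
#'
#' @param path CSV path.
#' @return Validated data frame.
#' @export
load_occurrences <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  req <- c("transect_id", "segment_id", "species", "abundance")
  miss <- setdiff(req, names(df))
  if (length(miss)) stop("missing columns: ", paste(miss, collapse = ", "))
  if (any(!is.finite(df$abundance) | df$abundance < 0))
    stop("abundance must be finite and >= 0")
  df
}

#' Species habitat distributions and medians
#'
#' Every species recorded on a segment is assigned that segment's weighted
#' tree cover (presence-based: one value per segment regardless of
#' abundance). The species' habitat statistic is the median of its segment
#' values. Species with no resolvable segment are excluded with a message.
#'
#' @param occurrences Occurrence data frame (see [load_occurrences()]).
#' @param habitats Segment habitat data frame from [segments_coverage()].
#' @return Data frame: `species`, `n_segments`, `median_cover`; the per-
#'   species segment values are kept in the `"segment_values"` attribute.
#' @export
species_habitat <- function(occurrences, habitats) {
  hab <- habitats[!habitats$excluded & is.finite(habitats$cover), ]
  key <- function(d) paste(d$transect_id, d$segment_id, sep = "\r")
  occ <- occurrences[!duplicated(cbind(occurrences$species,
                                       key(occurrences))), ]
  occ$cover <- hab$cover[match(key(occ), key(hab))]
  unresolved <- unique(occ$species[is.na(occ$cover)])
  occ <- occ[!is.na(occ$cover), ]
  lost <- setdiff(unresolved, occ$species)
  if (length(lost))
    message("species with no resolvable segment excluded: ",
            paste(lost, collapse = ", "))
  vals <- split(occ$cover, occ$species)
  sp <- sort(names(vals))
  out <- data.frame(species = sp,
                    n_segments = vapply(vals[sp], length, 0L),
                    median_cover = vapply(vals[sp], stats::median, 0),
                    row.names = NULL, stringsAsFactors = FALSE)
  attr(out, "segment_values") <- vals[sp]
  out
}

#' Community-weighted mean of a trait at one sampling unit
#'
#' Abundance-weighted average of trait values of the species recorded:
#' `sum(a_s t_s) / sum(a_s)`.
#'
#' @param abundance Nonnegative weights, not all zero.
#' @param trait Trait values, same length.
#' @return The weighted mean.
#' @export
community_weighted_mean <- function(abundance, trait) {
  stopifnot(length(abundance) == length(trait))
  ok <- is.finite(trait) & is.finite(abundance)
  abundance <- abundance[ok]; trait <- trait[ok]
  if (length(trait) == 0) stop("no species with trait values")
  if (any(abundance < 0)) stop("abundances must be >= 0")
  if (sum(abundance) == 0) stop("all abundances are zero")
  sum(abundance * trait) / sum(abundance)
}

#' Community-weighted means for every segment
#'
#' @param occurrences Occurrence data frame.
#' @param traits Named numeric vector of species trait values.
#' @return Data frame: `transect_id`, `segment_id`, `cwm`, `n_species`.
#' @export
cwm_table <- function(occurrences, traits) {
  key <- paste(occurrences$transect_id, occurrences$segment_id, sep = "\r")
  rows <- lapply(split(occurrences, factor(key, levels = unique(key))),
                 function(d) {
    t <- traits[d$species]
    ok <- is.finite(t) & d$abundance > 0
    if (!any(ok)) return(NULL)
    data.frame(transect_id = d$transect_id[1], segment_id = d$segment_id[1],
               cwm = sum(d$abundance[ok] * t[ok]) / sum(d$abundance[ok]),
               n_species = sum(ok), stringsAsFactors = FALSE)
  })
  do.call(rbind, c(rows, list(make.row.names = FALSE)))
}

#' PGLS of eye size on habitat
#'
#' Species-averaged eye size regressed on median tree cover density, with the
#' body-size covariate optionally included; covariate and predictor are
#' standardized (mean 0, SD 1) before fitting. Supports family subsets (e.g.
#' Nymphalidae only).
#'
#' @param means Species means data frame (from [species_means()]).
#' @param habitat Species habitat data frame (from [species_habitat()]).
#' @param tree A `"phylo"` object.
#' @param include_wing Include the forewing-length covariate (`FALSE` tests
#'   absolute eye size).
#' @param families Optional character vector restricting the species set.
#' @param structure Correlation structure passed to [fit_pgls()]. The default
#'   (Pagel's lambda) absorbs the non-phylogenetic part of the species-mean
#'   variation; pure-BM errors are badly anticonservative when species means
#'   carry sampling noise.
#' @param measurement_error Add the known sampling variance of each species
#'   mean (from [species_mean_noise()]) to the residual diagonal. Requires the
#'   `var_within_eye` column produced by [species_means()].
#' @return A `"pgls"` fit; the habitat coefficient is named `cover_z`.
#' @export
habitat_pgls <- function(means, habitat, tree, include_wing = TRUE,
                         families = NULL, structure = "lambda",
                         measurement_error = TRUE) {
  d <- merge(means, habitat[, c("species", "median_cover")], by = "species")
  if (!is.null(families)) d <- d[d$family %in% families, ]
  if (nrow(d) < 4) stop("fewer than 4 species in the intersection")
  zscore <- function(x) (x - mean(x)) / stats::sd(x)
  d$cover_z <- zscore(d$median_cover)
  fm <- if (include_wing) {
    d$wing_z <- zscore(d$mean_log10_wing)
    mean_log10_eye ~ wing_z + cover_z
  } else mean_log10_eye ~ cover_z
  noise <- if (measurement_error && "var_within_eye" %in% names(d))
    species_mean_noise(d) else NULL
  fit_pgls(fm, d, tree = tree, structure = structure, mean_noise = noise)
}

#' Linear regression of community-weighted means on segment habitat
#'
#' @param cwm Per-segment community-weighted means.
#' @param cover Per-segment weighted tree cover (same order).
#' @return List: `slope`, `se`, `p.value`, `ci` (95%), `r.squared`, `n`.
#' @export
cwm_regression <- function(cwm, cover) {
  ok <- is.finite(cwm) & is.finite(cover)
  cwm <- cwm[ok]; cover <- cover[ok]
  if (length(cwm) < 3) stop("need at least 3 segments")
  if (stats::var(cover) == 0) stop("constant habitat covariate")
  fit <- stats::lm(cwm ~ cover)
  sm <- summary(fit)
  ci <- stats::confint(fit)["cover", ]
  list(slope = unname(coef(fit)["cover"]),
       se = sm$coefficients["cover", "Std. Error"],
       p.value = sm$coefficients["cover", "Pr(>|t|)"],
       ci = unname(ci), r.squared = sm$r.squared, n = length(cwm))
}
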