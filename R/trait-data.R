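#' Load an individual-level trait table
#'
#' Reads a CSV of individual measurements (one row per scanned specimen) and
#' validates it: measurements must be strictly positive, species and sex must
#' be present. Invalid rows are dropped and the reasons recorded in the
#' `"dropped"` attribute; nothing is dropped silently.
#'
#' Required columns: `individual_id`, `species`, `sex` (`male`/`female`),
#' `family`, `eye_area` (mm^2), `forewing_length` (mm). An optional
#' `forewing_area` column is carried through.
#'
#' @param path CSV file path.
#' @return A `data.frame` of class `"trait_table"` with a `"dropped"`
#'   attribute (data frame of rejected rows and reasons).
#' @export
load_traits <- function(path) {
  raw <- utils::read.csv(path, stringsAsFactors = FALSE)
  req <- c("individual_id", "species", "sex", "family",
           "eye_area", "forewing_length")
  miss <- setdiff(req, names(raw))
  if (length(miss))
    stop("missing required columns: ", paste(miss, collapse = ", "))
  if (nrow(raw) == 0) stop("no records in ", path)

  reason <- rep(NA_character_, nrow(raw))
  bad <- function(cond, why) {
    cond[is.na(cond)] <- TRUE
    reason[cond & is.na(reason)] <<- why
  }
  bad(!is.finite(raw$eye_area) | raw$eye_area <= 0, "nonpositive eye_area")
  bad(!is.finite(raw$forewing_length) | raw$forewing_length <= 0,
      "nonpositive forewing_length")
  bad(is.na(raw$species) | raw$species == "", "missing species")
  bad(!raw$sex %in% c("male", "female"), "invalid sex")

  dropped <- cbind(raw[!is.na(reason), , drop = FALSE],
                   reason = reason[!is.na(reason)])
  tab <- raw[is.na(reason), , drop = FALSE]
  if (nrow(tab) == 0) stop("no valid records after validation")
  if (nrow(dropped) > 0)
    message(nrow(dropped), " row(s) dropped during validation")
  rownames(tab) <- NULL
  attr(tab, "dropped") <- dropped
  attr(tab, "log10") <- FALSE
  class(tab) <- c("trait_table", "data.frame")
  tab
}

#' Add log10-transformed trait columns
#'
#' All comparative analyses run on log10-transformed traits. The transform is
#' guarded so it can only be applied once per table.
#'
#' @param tab A `"trait_table"`.
#' @return The table with `log10_eye` and `log10_wing` columns.
#' @export
log10_traits <- function(tab) {
  if (isTRUE(attr(tab, "log10")))
    stop("traits are already log10 transformed; refusing to transform twice")
  tab$log10_eye <- log10(tab$eye_area)
  tab$log10_wing <- log10(tab$forewing_length)
  attr(tab, "log10") <- TRUE
  tab
}

#' Species-averaged traits
#'
#' Arithmetic means of the log10-transformed individual values per species
#' (sexes pooled, no reweighting of unbalanced sampling), returned in
#' deterministic label order.
#'
#' @param tab A `"trait_table"` (log10 columns added if absent).
#' @return A data frame with `species`, `mean_log10_eye`, `mean_log10_wing`,
#'   `n_individuals`, `family`.
#' @export
species_means <- function(tab) {
  if (!isTRUE(attr(tab, "log10"))) tab <- log10_traits(tab)
  sp <- sort(unique(tab$species))
  idx <- split(seq_len(nrow(tab)), tab$species)[sp]
  out <- data.frame(
    species = sp,
    mean_log10_eye = vapply(idx, function(i) mean(tab$log10_eye[i]), 0),
    mean_log10_wing = vapply(idx, function(i) mean(tab$log10_wing[i]), 0),
    n_individuals = vapply(idx, length, 0L),
    var_within_eye = vapply(idx, function(i)
      if (length(i) > 1) stats::var(tab$log10_eye[i]) else NA_real_, 0),
    family = vapply(idx, function(i) tab$family[i][1L], ""),
    row.names = NULL, stringsAsFactors = FALSE
  )
  out
}

#' Sampling variance of each species mean
#'
#' Per-species variance of the mean log10 eye size, `s2_pooled / n`, using
#' the pooled within-species variance (per-species variances at n of 4-8 are
#' too noisy to use individually). This is the known "measurement error"
#' diagonal for measurement-error-aware PGLS.
#'
#' @param means Output of [species_means()].
#' @return Named numeric vector keyed by species.
#' @export
species_mean_noise <- function(means) {
  w <- means$n_individuals - 1L
  ok <- !is.na(means$var_within_eye) & w > 0
  if (!any(ok)) return(stats::setNames(rep(0, nrow(means)), means$species))
  pooled <- sum(w[ok] * means$var_within_eye[ok]) / sum(w[ok])
  stats::setNames(pooled / means$n_individuals, means$species)
}

#' Repeatability of paired measurements
#'
#' R-squared from a simple linear regression of the repeated measurement on
#' the original one, i.e. the squared Pearson correlation. Used to check that
#' manual eye and wing measurements are reproducible.
#'
#' @param x,y Paired measurement vectors, length >= 3.
#' @return R-squared in \[0, 1\].
#' @export
repeatability_r2 <- function(x, y) {
  stopifnot(length(x) == length(y))
  ok <- is.finite(x) & is.finite(y)
  x <- x[ok]; y <- y[ok]
  if (length(x) < 3) stop("need at least 3 complete pairs")
  if (stats::var(x) == 0) stop("zero variance in x; repeatability undefined")
  if (stats::var(y) == 0) return(0)
  unname(stats::cor(x, y)^2)
}
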