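# Polar coordinates of occupied grids about the lattice centre.
# Angle convention: atan2(d_row, d_col) mapped to [0, 2*pi).
polar_living <- function(state) {
  living <- living_counts(state)
  idx <- which(living > 0L)
  if (!length(idx)) return(NULL)
  L <- nrow(living)
  ctr <- (L + 1L) %/% 2L
  r <- ((idx - 1L) %% L) + 1L
  cc <- ((idx - 1L) %/% L) + 1L
  dr <- r - ctr
  dc <- cc - ctr
  ang <- atan2(dr, dc) %% (2 * pi)
  list(radius = sqrt(dr^2 + dc^2), angle = ang, n = living[idx])
}

#' Phenotype counts and fractions
#'
#' @param state A [world_state()].
#' @return A one-row tibble with counts `n_prolif`, `n_invasive`,
#'   `n_necrotic`, `n_total` and fractions `frac_prolif`, `frac_invasive`,
#'   `frac_necrotic` (summing to 1 when any cell exists).
#' @export
phenotype_counts <- function(state) {
  np <- sum(state$n_prolif)
  ni <- sum(state$n_invasive)
  nn <- sum(state$n_necrotic)
  tot <- np + ni + nn
  tibble::tibble(
    n_prolif = np, n_invasive = ni, n_necrotic = nn, n_total = tot,
    frac_prolif = if (tot > 0) np / tot else NA_real_,
    frac_invasive = if (tot > 0) ni / tot else NA_real_,
    frac_necrotic = if (tot > 0) nn / tot else NA_real_
  )
}

#' Angular front profile of the living-cell colony
#'
#' Divides the circle into `n_bins` equal angular bins about the lattice
#' centre (the founder's grid) and records, per bin, the maximum radial
#' distance of any grid containing a living cell. Bins with no living
#' cell are excluded (not interpolated).
#'
#' @param state A [world_state()] with at least one living cell.
#' @param n_bins Number of angular bins (default 360).
#' @return A tibble with columns `bin` (1-based index), `angle` (bin
#'   centre, radians) and `front_radius` (grid units), one row per
#'   non-empty bin; the total bin count is kept in the `n_bins` attribute.
#' @export
front_profile <- function(state, n_bins = 360L) {
  pol <- polar_living(state)
  if (is.null(pol)) stop("no living cells: front undefined", call. = FALSE)
  width <- 2 * pi / n_bins
  bin <- pmin(floor(pol$angle / width), n_bins - 1L) + 1L
  rmax <- tapply(pol$radius, bin, max)
  out <- tibble::tibble(
    bin = as.integer(names(rmax)),
    angle = (as.integer(names(rmax)) - 0.5) * width,
    front_radius = as.numeric(rmax)
  )
  attr(out, "n_bins") <- as.integer(n_bins)
  out
}

#' Global surface roughness of the front
#'
#' The population standard deviation of the per-bin front radii,
#' \eqn{R = \sqrt{(1/N_r)\sum_i (r_i - \langle r\rangle)^2}}, over the
#' non-empty angular bins.
#'
#' @param profile A [front_profile()] with at least 2 non-empty bins.
#' @return Roughness in grid units.
#' @export
surface_roughness <- function(profile) {
  rr <- profile$front_radius
  if (length(rr) < 2) stop("need >= 2 non-empty bins for roughness",
                           call. = FALSE)
  sqrt(mean((rr - mean(rr))^2))
}

#' Mean front radius
#'
#' @param profile A [front_profile()] with at least 1 non-empty bin.
#' @return Arithmetic mean of the per-bin front radii, grid units.
#' @export
mean_front_radius <- function(profile) {
  if (nrow(profile) < 1) stop("empty front profile", call. = FALSE)
  mean(profile$front_radius)
}

#' Ordinary-least-squares slope of a time series
#'
#' Fits `y ~ t` by OLS after discarding points with `t < burn_in` and
#' returns the slope. Used for the radial growth velocity (on the mean
#' front radius) and the roughness velocity (on the roughness series).
#'
#' @param t,y Numeric vectors of equal length.
#' @param burn_in Points with `t < burn_in` are discarded (default 0).
#' @return The OLS slope, with the fit's `r.squared` attached as an
#'   attribute.
#' @examples
#' fit_slope(0:10, 2 * (0:10))  # 2
#' @export
fit_slope <- function(t, y, burn_in = 0) {
  keep <- t >= burn_in & is.finite(y)
  t <- t[keep]
  y <- y[keep]
  if (length(t) < 2) stop("need >= 2 points after burn-in for a slope fit",
                          call. = FALSE)
  fit <- stats::lm(y ~ t)
  slope <- unname(stats::coef(fit)[2])
  if (is.na(slope)) slope <- 0
  ss_tot <- sum((y - mean(y))^2)
  attr(slope, "r.squared") <- if (ss_tot > 0) {
    1 - sum(stats::residuals(fit)^2) / ss_tot
  } else {
    NaN
  }
  slope
}

#' Power-law exponent of a time series
#'
#' OLS slope of `log(y)` versus `log(t)` over the points with
#' `t >= burn_in`, `t > 0` and `y > 0`; the kinetic-roughening exponent
#' when applied to the roughness series.
#'
#' @inheritParams fit_slope
#' @return The log--log slope with `r.squared` attached.
#' @export
fit_loglog_exponent <- function(t, y, burn_in = 0) {
  keep <- t >= burn_in & t > 0 & is.finite(y) & y > 0
  fit_slope(log(t[keep]), log(y[keep]))
}

#' Per-sector radial distribution function of living cells
#'
#' The lattice is divided into four quadrant sectors about the centre,
#' sector `k` covering angles `[(k-1)*pi/2, k*pi/2)`. Within a sector the
#' RDF is the probability density of the radial distance of its living
#' cells: `g(r) = n(r) / (N_s * dr)` where `n(r)` counts living cells
#' with radius in `[r, r + dr)` and `N_s` is the sector's living-cell
#' total, so `sum(g) * dr = 1`.
#'
#' @param state A [world_state()].
#' @param sector Sector index 1--4, or `NULL` for all four at once.
#' @param bin_width Radial bin width `dr` in grids (default 2).
#' @return A tibble with columns `sector`, `r_lo`, `r_mid`, `g`.
#' @export
radial_distribution <- function(state, sector = NULL, bin_width = 2) {
  pol <- polar_living(state)
  if (is.null(pol)) stop("no living cells: RDF undefined", call. = FALSE)
  sectors <- if (is.null(sector)) 1:4 else as.integer(sector)
  stopifnot(all(sectors %in% 1:4))
  out <- lapply(sectors, function(s) {
    inside <- pol$angle >= (s - 1) * pi / 2 & pol$angle < s * pi / 2
    w <- pol$n[inside]
    if (sum(w) == 0) stop("sector ", s, " contains no living cells",
                          call. = FALSE)
    rad <- pol$radius[inside]
    b <- floor(rad / bin_width)
    cnt <- tapply(w, b, sum)
    lo <- as.numeric(names(cnt)) * bin_width
    tibble::tibble(
      sector = s, r_lo = lo, r_mid = lo + bin_width / 2,
      g = as.numeric(cnt) / (sum(w) * bin_width)
    )
  })
  dplyr::bind_rows(out)
}

#' Summary record of one simulation step
#'
#' @param state A [world_state()].
#' @param config A [sim_config()] (angular bin count is taken from it).
#' @return A one-row tibble: `t`, phenotype counts and fractions,
#'   `mean_front_radius` and `roughness` (NA where undefined, e.g. fewer
#'   than two occupied angular bins).
#' @export
record_state <- function(state, config) {
  pc <- phenotype_counts(state)
  mfr <- NA_real_
  rough <- NA_real_
  if (sum(state$n_prolif) + sum(state$n_invasive) > 0) {
    prof <- front_profile(state, config$n_angular_bins)
    mfr <- mean_front_radius(prof)
    if (nrow(prof) >= 2) rough <- surface_roughness(prof)
  }
  dplyr::bind_cols(tibble::tibble(t = state$t), pc,
                   tibble::tibble(mean_front_radius = mfr, roughness = rough))
}

#' Growth and roughness velocities of a simulation
#'
#' Convenience fits over a [run_simulation()] result: the radial growth
#' velocity `v` (OLS slope of the mean front radius), the roughness
#' velocity `v_r` (slope of the roughness series) and the roughening
#' exponent (log--log slope of roughness vs time), all after the
#' configured burn-in.
#'
#' @param sim A `tumor_sim` object.
#' @param burn_in Burn-in override (default: the run's configured value).
#' @return A one-row tibble: `v`, `r2_front`, `v_r`, `r2_rough`,
#'   `rough_exponent`.
#' @export
growth_velocities <- function(sim, burn_in = NULL) {
  if (is.null(burn_in)) burn_in <- sim$config$burn_in
  rec <- sim$records
  v <- fit_slope(rec$t, rec$mean_front_radius, burn_in)
  vr <- fit_slope(rec$t, rec$roughness, burn_in)
  ex <- tryCatch(fit_loglog_exponent(rec$t, rec$roughness, burn_in),
                 error = function(e) NA_real_)
  r2_front <- attr(v, "r.squared") %||% NA_real_
  r2_rough <- attr(vr, "r.squared") %||% NA_real_
  tibble::tibble(
    v = as.numeric(v), r2_front = r2_front,
    v_r = as.numeric(vr), r2_rough = r2_rough,
    rough_exponent = as.numeric(ex)
  )
}
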