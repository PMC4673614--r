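#' Simulation configuration
#'
#' Collects every model constant, the lattice geometry, numerics settings
#' and the RNG seed. Units: the grid spacing is 1 lattice unit and the cell
#' cycle tau is 1 time unit; all rates are expressed in these units.
#'
#' @param L Lattice side length in grids. Must be odd so a unique central
#'   grid exists. Default 401.
#' @param t_max Run length in cell cycles tau. Default 200.
#' @param D Nutrient diffusion coefficient, grid^2 per tau.
#' @param k Nutrient consumption rate per living cell, 1 per tau.
#' @param phi_c Necrosis threshold on the nutrient concentration, in (0, 1).
#'   Living cells in a grid with nutrient strictly below `phi_c` die.
#' @param theta_p,theta_i Shape parameters of the proliferation and invasion
#'   base probabilities (per-cell nutrient scale); must be > 0.
#' @param gamma ECM degradation per living cell per tau.
#' @param payoff A [payoff_matrix()].
#' @param n_sub Number of explicit diffusion substeps per tau; the substep
#'   is `dt = 1/n_sub` and must satisfy `D * dt <= 1/4`.
#' @param degrade_neighbors If `TRUE` (default) a living cell degrades the
#'   ECM in its own grid and its 8 Moore neighbours, each by `gamma` per
#'   tau. If `FALSE`, only its own grid (literal mode; with a continuous
#'   initial ECM field the colony then cannot expand -- see the vignette).
#' @param payoff_aggregation How neighbour payoffs are aggregated: `"mean"`
#'   (default; divide by the number of living interaction partners) or
#'   `"sum"`.
#' @param consumption_form Nutrient sink form: `"proportional"` (default,
#'   `-k * N_T * phi`) or `"constant"` (`-k * N_T`, clamped at 0).
#' @param n_angular_bins Angular bins for the front profile (default 360).
#' @param rdf_bin_width Radial bin width in grids for the radial
#'   distribution function (default 2).
#' @param burn_in Cell cycles discarded before velocity fits (default 30).
#' @param snapshot_times Times (tau) at which [run_simulation()] keeps full
#'   lattice snapshots.
#' @param seed Integer RNG seed.
#' @return An object of class `sim_config` (a named list).
#' @seealso [validate_config()], [fixture_preset()]
#' @examples
#' cfg <- sim_config(L = 61, t_max = 30, seed = 1)
#' validate_config(cfg)
#' @export
sim_config <- function(L = 401L,
                       t_max = 200L,
                       D = 1.0,
                       k = 0.3,
                       phi_c = 0.25,
                       theta_p = 0.3,
                       theta_i = 0.3,
                       gamma = 0.4,
                       payoff = standard_payoffs(0.1, 0.1),
                       n_sub = 8L,
                       degrade_neighbors = TRUE,
                       payoff_aggregation = c("mean", "sum"),
                       consumption_form = c("proportional", "constant"),
                       n_angular_bins = 360L,
                       rdf_bin_width = 2,
                       burn_in = 30,
                       snapshot_times = c(50L, 100L, 150L, 200L),
                       seed = 1L) {
  cfg <- list(
    L = as.integer(L), t_max = as.integer(t_max),
    D = D, k = k, phi_c = phi_c,
    theta_p = theta_p, theta_i = theta_i, gamma = gamma,
    payoff = payoff, n_sub = as.integer(n_sub),
    degrade_neighbors = isTRUE(degrade_neighbors),
    payoff_aggregation = match.arg(payoff_aggregation),
    consumption_form = match.arg(consumption_form),
    n_angular_bins = as.integer(n_angular_bins),
    rdf_bin_width = rdf_bin_width,
    burn_in = burn_in,
    snapshot_times = as.integer(snapshot_times),
    seed = as.integer(seed)
  )
  structure(cfg, class = "sim_config")
}

#' Validate a simulation configuration
#'
#' Checks every structural invariant of a [sim_config()] and reports all
#' violations rather than stopping at the first.
#'
#' @param config A [sim_config()].
#' @return A character vector of violation messages, empty when the
#'   configuration is valid. Each message names the offending field.
#' @examples
#' validate_config(sim_config())              # character(0)
#' validate_config(sim_config(L = 400))       # parity violation
#' @export
validate_config <- function(config) {
  v <- character(0)
  add <- function(msg) v <<- c(v, msg)
  if (!is.numeric(config$L) || length(config$L) != 1 || config$L < 3) {
    add("L must be a single integer >= 3")
  } else if (config$L %% 2 == 0) {
    add("L must be odd")
  }
  if (config$t_max < 0) add("t_max must be >= 0")
  if (!is.numeric(config$D) || config$D < 0) add("D must be >= 0")
  if (!is.numeric(config$k) || config$k < 0) add("k must be >= 0")
  if (!is.numeric(config$gamma) || config$gamma < 0) add("gamma must be >= 0")
  if (!is.numeric(config$phi_c) || config$phi_c <= 0 || config$phi_c >= 1) {
    add("phi_c must lie strictly between 0 and 1")
  }
  if (config$theta_p <= 0) add("theta_p must be > 0")
  if (config$theta_i <= 0) add("theta_i must be > 0")
  if (config$n_sub < 1) add("n_sub must be >= 1")
  if (config$n_sub >= 1 && config$D * (1 / config$n_sub) > 0.25 + 1e-12) {
    add("stability D*dt <= 1/4 violated: reduce D or increase n_sub")
  }
  if (!inherits(config$payoff, "payoff_matrix")) {
    add("payoff must be a payoff_matrix")
  }
  if (config$n_angular_bins < 1) add("n_angular_bins must be >= 1")
  if (config$rdf_bin_width <= 0) add("rdf_bin_width must be > 0")
  if (config$burn_in < 0) add("burn_in must be >= 0")
  v
}

assert_valid_config <- function(config) {
  v <- validate_config(config)
  if (length(v)) {
    stop("invalid simulation configuration:\n  ",
         paste(v, collapse = "\n  "), call. = FALSE)
  }
  invisible(config)
}

#' Named configuration presets
#'
#' Ready-made configurations used throughout the documentation and tests:
#' \describe{
#'   \item{`smoke`}{Tiny, fast run: `L = 61`, `t_max = 30`.}
#'   \item{`fig2_default`}{The full reference run: `L = 401`,
#'     `t_max = 200`, payoffs `alpha_pp = beta_ii = 0.1`.}
#'   \item{`calibration`}{The reference run on an `L = 201` lattice for
#'     faster replicated experiments; otherwise identical to
#'     `fig2_default`.}
#' }
#'
#' @param name Preset name.
#' @param seed Optional seed override.
#' @return A [sim_config()].
#' @examples
#' fixture_preset("smoke")
#' @export
fixture_preset <- function(name = c("smoke", "fig2_default", "calibration"),
                           seed = 1L) {
  if (length(name) != 1 || !name %in% c("smoke", "fig2_default", "calibration")) {
    stop("unknown preset: ", paste(name, collapse = ", "), call. = FALSE)
  }
  cfg <- switch(name,
    smoke = sim_config(L = 61L, t_max = 30L, burn_in = 5,
                       snapshot_times = c(10L, 20L, 30L)),
    fig2_default = sim_config(L = 401L, t_max = 200L),
    calibration = sim_config(L = 201L, t_max = 200L)
  )
  cfg$seed <- as.integer(seed)
  cfg
}

#' @export
print.sim_config <- function(x, ...) {
  cat("<sim_config>\n")
  cat(sprintf("  lattice %d x %d, t_max %d tau, seed %d\n",
              x$L, x$L, x$t_max, x$seed))
  cat(sprintf("  nutrient: D = %g, k = %g (%s sink), n_sub = %d, phi_c = %g\n",
              x$D, x$k, x$consumption_form, x$n_sub, x$phi_c))
  cat(sprintf("  ECM: gamma = %g (%s)\n", x$gamma,
              if (x$degrade_neighbors) "Moore footprint" else "own grid only"))
  cat(sprintf("  fates: theta_p = %g, theta_i = %g, %s, %s\n",
              x$theta_p, x$theta_i, format(x$payoff), x$payoff_aggregation))
  invisible(x)
}
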