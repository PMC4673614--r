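#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Growth curves of a simulation
#'
#' Two-panel view of a run: phenotype counts over time (log scale) and
#' phenotype fractions over time.
#'
#' @param object A `tumor_sim`.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.tumor_sim <- function(object, ...) {
  long <- tidyr::pivot_longer(
    object$records,
    cols = c("n_prolif", "n_invasive", "n_necrotic", "n_total"),
    names_to = "phenotype", values_to = "count"
  )
  ggplot2::ggplot(long, ggplot2::aes(.data$t, .data$count,
                                     colour = .data$phenotype)) +
    ggplot2::geom_line() +
    ggplot2::scale_y_continuous(trans = "log1p") +
    ggplot2::labs(x = "t (cell cycles)", y = "cells",
                  title = "Tumor growth by phenotype") +
    ggplot2::theme_minimal()
}

#' Phenotype fraction curves
#'
#' @param sim A `tumor_sim`.
#' @return A ggplot object.
#' @export
plot_fractions <- function(sim) {
  long <- tidyr::pivot_longer(
    sim$records,
    cols = c("frac_prolif", "frac_invasive", "frac_necrotic"),
    names_to = "phenotype", values_to = "fraction"
  )
  ggplot2::ggplot(long, ggplot2::aes(.data$t, .data$fraction,
                                     colour = .data$phenotype)) +
    ggplot2::geom_line() +
    ggplot2::labs(x = "t (cell cycles)", y = "fraction of all cells") +
    ggplot2::theme_minimal()
}

#' Lattice snapshot of living cells
#'
#' @param state A [world_state()].
#' @param what `"living"`, `"necrotic"`, `"phi"` or `"rho_ecm"`.
#' @return A ggplot raster of the chosen field.
#' @export
plot_lattice <- function(state, what = c("living", "necrotic", "phi", "rho_ecm")) {
  what <- match.arg(what)
  m <- switch(what,
    living = living_counts(state),
    necrotic = state$n_necrotic,
    phi = state$phi,
    rho_ecm = state$rho_ecm
  )
  df <- tibble::tibble(
    row = rep(seq_len(nrow(m)), ncol(m)),
    col = rep(seq_len(ncol(m)), each = nrow(m)),
    value = as.vector(m)
  )
  ggplot2::ggplot(df, ggplot2::aes(.data$col, .data$row, fill = .data$value)) +
    ggplot2::geom_raster() +
    ggplot2::coord_equal() +
    ggplot2::labs(title = sprintf("%s at t = %d", what, state$t)) +
    ggplot2::theme_void()
}

#' Sector radial distribution functions
#'
#' @param rdf A tibble from [radial_distribution()].
#' @return A ggplot object, one line per sector.
#' @export
plot_rdf <- function(rdf) {
  ggplot2::ggplot(rdf, ggplot2::aes(.data$r_mid, .data$g,
                                    colour = factor(.data$sector))) +
    ggplot2::geom_line() +
    ggplot2::labs(x = "r (grids)", y = "g(r)", colour = "sector") +
    ggplot2::theme_minimal()
}

#' Aggregated sweep surfaces
#'
#' Tile maps of the mean growth velocity and mean roughness velocity over
#' the `(alpha_pp, beta_ii)` payoff grid.
#'
#' @param object A `tumor_sweep`.
#' @param which `"v"` or `"v_r"`.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.tumor_sweep <- function(object, which = c("v_r", "v"), ...) {
  which <- match.arg(which)
  agg <- summarize_sweep(object)
  agg$z <- if (which == "v") agg$v_mean else agg$v_r_mean
  ggplot2::ggplot(agg, ggplot2::aes(.data$beta_ii, .data$alpha_pp,
                                    fill = .data$z)) +
    ggplot2::geom_tile() +
    ggplot2::labs(x = expression(beta[ii]), y = expression(alpha[pp]),
                  fill = if (which == "v") "<v>" else "<v_r>") +
    ggplot2::theme_minimal()
}
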