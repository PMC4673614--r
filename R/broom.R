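#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' Tidy the per-step records of a simulation
#'
#' @param x A `tumor_sim` from [run_simulation()].
#' @param ... Unused.
#' @return The records tibble, one row per recorded cell cycle.
#' @export
tidy.tumor_sim <- function(x, ...) x$records

#' One-row summary of a simulation
#'
#' @param x A `tumor_sim`.
#' @param ... Unused.
#' @return A one-row tibble: steps recorded, final counts and fractions,
#'   fitted growth velocity `v`, roughness velocity `v_r`, roughening
#'   exponent, front-fit R^2 and the halt reason.
#' @export
glance.tumor_sim <- function(x, ...) {
  last <- x$records[nrow(x$records), ]
  gv <- tryCatch(growth_velocities(x), error = function(e) {
    tibble::tibble(v = NA_real_, r2_front = NA_real_, v_r = NA_real_,
                   r2_rough = NA_real_, rough_exponent = NA_real_)
  })
  dplyr::bind_cols(
    tibble::tibble(n_steps = nrow(x$records), t_final = last$t,
                   n_total = last$n_total,
                   frac_necrotic = last$frac_necrotic,
                   frac_invasive = last$frac_invasive),
    gv,
    tibble::tibble(halt_reason = x$halt_reason)
  )
}

#' Tidy the per-trial rows of a payoff sweep
#'
#' @param x A `tumor_sweep` from [run_sweep()].
#' @param ... Unused.
#' @return The per-trial results tibble.
#' @export
tidy.tumor_sweep <- function(x, ...) x$results

#' Per-grid-point summary of a payoff sweep
#'
#' @param x A `tumor_sweep`.
#' @param ... Unused.
#' @return The aggregated tibble of [summarize_sweep()].
#' @export
glance.tumor_sweep <- function(x, ...) summarize_sweep(x)
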