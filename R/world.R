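#' Lattice world state
#'
#' The full state of a simulation at one instant: per-grid counts of
#' proliferative, invasive and necrotic cells, the nutrient field `phi`
#' (in \[0, 1\]) and the ECM density field `rho_ecm` (in \[0, 1\]), plus the
#' current time `t` in cell cycles. Grids can host many cells; occupancy
#' and ECM are exclusive (an occupied grid always has `rho_ecm = 0`).
#'
#' `world_state()` builds an empty state, which is convenient for
#' constructing fixtures; [initialize_world()] builds the seeded starting
#' state of a simulation.
#'
#' @param L Odd lattice side length.
#' @param phi Scalar or `L x L` matrix of initial nutrient values.
#' @param rho_ecm Scalar or `L x L` matrix of initial ECM density.
#' @return An object of class `world_state`: a list with elements `t`,
#'   `n_prolif`, `n_invasive`, `n_necrotic` (integer matrices), `phi`,
#'   `rho_ecm` (double matrices).
#' @examples
#' w <- world_state(9)
#' w$n_prolif[5, 5] <- 1L
#' @export
world_state <- function(L, phi = 1, rho_ecm = 0) {
  L <- as.integer(L)
  zero <- matrix(0L, L, L)
  as_field <- function(x) {
    if (is.matrix(x)) {
      stopifnot(nrow(x) == L, ncol(x) == L)
      x
    } else {
      matrix(as.numeric(x), L, L)
    }
  }
  structure(list(
    t = 0L,
    n_prolif = zero, n_invasive = zero, n_necrotic = zero,
    phi = as_field(phi), rho_ecm = as_field(rho_ecm)
  ), class = "world_state")
}

#' Initialize the simulation world
#'
#' Seeds the global RNG from `config$seed`, draws the initial ECM and
#' nutrient fields i.i.d. uniform on \[0, 1\] per grid (ECM first, then
#' nutrient), fixes the nutrient at 1 on the four boundary rows/columns
#' (the surrounding vasculature), clears the ECM of the central grid and
#' places a single proliferative founder cell there.
#'
#' @param config A valid [sim_config()].
#' @return A [world_state()] at `t = 0` with exactly one living cell at
#'   the central grid `((L+1)/2, (L+1)/2)`.
#' @examples
#' w <- initialize_world(sim_config(L = 61, seed = 7))
#' sum(w$n_prolif)  # 1
#' @export
initialize_world <- function(config) {
  assert_valid_config(config)
  set.seed(config$seed)
  L <- config$L
  rho <- matrix(stats::runif(L * L), L, L)
  phi <- matrix(stats::runif(L * L), L, L)
  phi[c(1L, L), ] <- 1
  phi[, c(1L, L)] <- 1
  ctr <- (L + 1L) %/% 2L
  rho[ctr, ctr] <- 0
  w <- world_state(L, phi = phi, rho_ecm = rho)
  w$n_prolif[ctr, ctr] <- 1L
  w
}

#' Per-grid living-cell counts
#' @param state A [world_state()].
#' @return Integer matrix `n_prolif + n_invasive`.
#' @export
living_counts <- function(state) state$n_prolif + state$n_invasive

#' Per-grid total counts (living plus necrotic)
#' @param state A [world_state()].
#' @return Integer matrix of total cells per grid.
#' @export
total_counts <- function(state) {
  state$n_prolif + state$n_invasive + state$n_necrotic
}

# Index of the central grid (founder position), 1-based.
center_index <- function(state) (nrow(state$phi) + 1L) %/% 2L

#' @export
print.world_state <- function(x, ...) {
  L <- nrow(x$phi)
  cat(sprintf("<world_state> %d x %d lattice at t = %d tau\n", L, L, x$t))
  cat(sprintf("  cells: %d proliferative, %d invasive, %d necrotic\n",
              sum(x$n_prolif), sum(x$n_invasive), sum(x$n_necrotic)))
  cat(sprintf("  phi in [%.3f, %.3f], rho_ecm in [%.3f, %.3f]\n",
              min(x$phi), max(x$phi), min(x$rho_ecm), max(x$rho_ecm)))
  invisible(x)
}
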