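# Five-point Laplacian with unit grid spacing; boundary rows/cols left 0
# (they are reset to the vascular value by the caller).
laplacian5 <- function(m) {
  L <- nrow(m)
  out <- matrix(0, L, ncol(m))
  i <- 2:(L - 1)
  j <- 2:(ncol(m) - 1)
  out[i, j] <- m[i - 1, j] + m[i + 1, j] + m[i, j - 1] + m[i, j + 1] - 4 * m[i, j]
  out
}

#' One explicit diffusion--consumption substep
#'
#' Advances the nutrient field by one explicit Euler substep of the
#' reaction--diffusion equation on the lattice: interior grids are updated
#' by `phi <- phi + dt * (D * lap(phi) - sink)` with the 5-point Laplacian
#' at unit spacing, where the sink is `k * N_T * phi` (proportional form,
#' default) or `k * N_T` (constant form). The four boundary rows/columns
#' are then reset to 1 (the surrounding vessels hold the nutrient fixed)
#' and the result is clamped to \[0, 1\].
#'
#' @param phi `L x L` nutrient matrix in \[0, 1\].
#' @param living_total `L x L` matrix of living-cell counts `N_T`.
#' @param D Diffusion coefficient; `D * dt` must be `<= 1/4`.
#' @param k Per-cell consumption rate.
#' @param dt Substep length in tau.
#' @param consumption_form `"proportional"` or `"constant"`.
#' @return The updated nutrient matrix.
#' @examples
#' phi <- matrix(1, 5, 5)
#' nt <- matrix(0L, 5, 5)
#' identical(diffusion_substep(phi, nt, D = 1, k = 0.1, dt = 0.125), phi)
#' @export
diffusion_substep <- function(phi, living_total, D, k, dt,
                              consumption_form = c("proportional", "constant")) {
  consumption_form <- match.arg(consumption_form)
  if (!is.matrix(phi) || !is.matrix(living_total) ||
      !all(dim(phi) == dim(living_total))) {
    stop("phi and living_total must be matrices of equal dimension",
         call. = FALSE)
  }
  if (D * dt > 0.25 + 1e-12) {
    stop("explicit scheme unstable: D*dt must be <= 1/4", call. = FALSE)
  }
  sink <- if (consumption_form == "proportional") {
    k * living_total * phi
  } else {
    k * living_total
  }
  out <- phi + dt * (D * laplacian5(phi) - sink)
  out[out < 0] <- 0
  out[out > 1] <- 1
  L <- nrow(out)
  out[c(1L, L), ] <- 1
  out[, c(1L, ncol(out))] <- 1
  out
}

#' Renew the nutrient field for one cell cycle
#'
#' Applies [diffusion_substep()] `n_sub` times with the living-cell counts
#' frozen at their current values, i.e. integrates the nutrient equation
#' over one cell cycle tau with substep `dt = 1/n_sub`.
#'
#' @param state A [world_state()] (only `phi` and the living counts are
#'   used).
#' @param D,k,consumption_form As in [diffusion_substep()].
#' @param n_sub Number of substeps per tau (>= 1).
#' @return The renewed nutrient matrix.
#' @export
update_nutrient_field <- function(state, D, k, n_sub,
                                  consumption_form = c("proportional", "constant")) {
  consumption_form <- match.arg(consumption_form)
  n_sub <- as.integer(n_sub)
  if (n_sub < 1) stop("n_sub must be >= 1", call. = FALSE)
  dt <- 1 / n_sub
  if (D * dt > 0.25 + 1e-12) {
    stop("explicit scheme unstable: D/n_sub must be <= 1/4", call. = FALSE)
  }
  phi <- state$phi
  nt <- living_counts(state)
  for (s in seq_len(n_sub)) {
    phi <- diffusion_substep(phi, nt, D, k, dt, consumption_form)
  }
  phi
}
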