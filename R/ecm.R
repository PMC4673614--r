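# 3x3 (Moore + centre) neighbourhood sum via a zero-padded shift stack.
conv3 <- function(m) {
  L <- nrow(m)
  W <- ncol(m)
  p <- matrix(0, L + 2L, W + 2L)
  p[2:(L + 1L), 2:(W + 1L)] <- m
  out <- matrix(0, L, W)
  for (dr in 0:2) {
    for (dc in 0:2) {
      out <- out + p[dr + seq_len(L), dc + seq_len(W)]
    }
  }
  out
}

#' Degrade the extracellular matrix
#'
#' Each living cell lowers the ECM density by `gamma` per cell cycle. With
#' `degrade_neighbors = TRUE` (the default) a cell degrades its own grid
#' and each of its 8 Moore neighbours by `gamma`; with `FALSE` only its own
#' grid (the literal single-grid mode, under which a colony seeded into a
#' continuous ECM field cannot expand). The result is clamped at exactly 0
#' so that the placement predicate is well defined in floating point.
#'
#' @param rho `L x L` ECM density matrix in \[0, 1\].
#' @param living_total `L x L` matrix of living-cell counts.
#' @param gamma Degradation per living cell per tau (>= 0).
#' @param degrade_neighbors Moore-footprint switch (default `TRUE`).
#' @return The degraded ECM matrix (element-wise `<=` the input, `>= 0`).
#' @examples
#' rho <- matrix(0.5, 3, 3)
#' nt <- matrix(0L, 3, 3); nt[2, 2] <- 2L
#' degrade_ecm(rho, nt, gamma = 0.1, degrade_neighbors = FALSE)[2, 2]  # 0.3
#' @export
degrade_ecm <- function(rho, living_total, gamma, degrade_neighbors = TRUE) {
  if (!is.matrix(rho) || !is.matrix(living_total) ||
      !all(dim(rho) == dim(living_total))) {
    stop("rho and living_total must be matrices of equal dimension",
         call. = FALSE)
  }
  if (gamma < 0) stop("gamma must be >= 0", call. = FALSE)
  dec <- if (degrade_neighbors) conv3(living_total) else living_total
  out <- rho - gamma * dec
  out[out < 0] <- 0
  out
}

#' Placement eligibility
#'
#' A tumour cell (daughter or migrant) may only enter a grid whose ECM
#' density is exactly 0. Degradation clamps to exact zero, so strict
#' equality is the intended test.
#'
#' @param rho ECM density matrix.
#' @return Logical matrix, `TRUE` where placement is allowed.
#' @export
placement_eligible <- function(rho) rho == 0
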