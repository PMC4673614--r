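#' Phenotype-phenotype payoff matrix
#'
#' Signed per-encounter rewards that shift a living cell's fate
#' probabilities. Rows are the focal cell's candidate behaviour
#' (proliferate / invade), columns the phenotype of the partner cell it
#' encounters in its interaction neighbourhood:
#' `a_pp` and `a_pi` perturb the proliferative probability on meeting a
#' proliferative or an invasive neighbour; `b_ip` and `b_ii` perturb the
#' invasive probability likewise.
#'
#' Entries are signed: a negative entry inhibits the behaviour, a positive
#' one enhances it. See [standard_payoffs()] for the conventional
#' parameterisation in terms of an inhibition magnitude between
#' proliferative cells and an enhancement between invasive cells.
#'
#' @param a_pp,a_pi,b_ip,b_ii Finite signed reals (defaults 0).
#' @return An object of class `payoff_matrix`.
#' @examples
#' payoff_matrix(a_pp = -0.1, b_ii = 0.1)
#' @export
payoff_matrix <- function(a_pp = 0, a_pi = 0, b_ip = 0, b_ii = 0) {
  vals <- c(a_pp = a_pp, a_pi = a_pi, b_ip = b_ip, b_ii = b_ii)
  if (!all(is.finite(vals))) {
    stop("payoff entries must be finite reals", call. = FALSE)
  }
  structure(as.list(vals), class = "payoff_matrix")
}

#' Conventional payoff parameterisation
#'
#' The model is usually discussed in terms of two non-negative magnitudes:
#' `alpha_pp`, the inhibition between two proliferative cells (stored as
#' `a_pp = -alpha_pp`), and `beta_ii`, the enhancement between two invasive
#' cells (stored as `b_ii = +beta_ii`). The cross terms `alpha_pi` and
#' `beta_ip` have no conventional sign and are stored as given (default 0).
#'
#' @param alpha_pp Inhibition magnitude between proliferative cells (>= 0).
#' @param beta_ii Enhancement magnitude between invasive cells (>= 0).
#' @param alpha_pi,beta_ip Signed cross-phenotype rewards (default 0).
#' @return A [payoff_matrix()].
#' @examples
#' standard_payoffs(alpha_pp = 0.1, beta_ii = 0.1)
#' @export
standard_payoffs <- function(alpha_pp = 0.1, beta_ii = 0.1,
                             alpha_pi = 0, beta_ip = 0) {
  if (alpha_pp < 0 || beta_ii < 0) {
    stop("alpha_pp and beta_ii are magnitudes and must be >= 0", call. = FALSE)
  }
  payoff_matrix(a_pp = -alpha_pp, a_pi = alpha_pi, b_ip = beta_ip, b_ii = beta_ii)
}

#' @export
print.payoff_matrix <- function(x, ...) {
  m <- matrix(c(x$a_pp, x$a_pi, x$b_ip, x$b_ii), 2, 2, byrow = TRUE,
              dimnames = list(c("proliferate", "invade"),
                              c("vs proliferative", "vs invasive")))
  cat("<payoff_matrix>\n")
  print(m)
  invisible(x)
}

#' @export
format.payoff_matrix <- function(x, ...) {
  sprintf("payoff(a_pp=%g, a_pi=%g, b_ip=%g, b_ii=%g)",
          x$a_pp, x$a_pi, x$b_ip, x$b_ii)
}
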