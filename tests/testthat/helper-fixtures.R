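# Small-world config used across unit tests: quiet, fast, valid.
tiny_config <- function(L = 9L, t_max = 5L, ...) {
  cfg <- sim_config(L = L, t_max = t_max, snapshot_times = integer(0), seed = 1L)
  over <- list(...)
  for (nm in names(over)) cfg[[nm]] <- over[[nm]]
  cfg
}

# State with living cells on an (approximate) circle of the given radius.
ring_state <- function(radius, L = 2L * ceiling(radius) + 21L) {
  st <- world_state(L)
  ctr <- (L + 1L) %/% 2L
  for (th in seq(0, 2 * pi, length.out = 720)) {
    r0 <- ctr + round(radius * sin(th))
    c0 <- ctr + round(radius * cos(th))
    st$n_prolif[r0, c0] <- 1L
  }
  st
}

# Two-level synthetic front profile: half the bins at r_lo, half at r_hi.
two_level_profile <- function(r_lo = 8, r_hi = 12, n_bins = 360L) {
  width <- 2 * pi / n_bins
  tibble::tibble(
    bin = seq_len(n_bins),
    angle = (seq_len(n_bins) - 0.5) * width,
    front_radius = rep(c(r_lo, r_hi), each = n_bins / 2)
  )
}
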