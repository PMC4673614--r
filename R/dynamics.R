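#' Necrosis below the nutrient threshold
#'
#' Every grid whose nutrient concentration is strictly below `phi_c` has
#' all of its living cells (both phenotypes) moved into the necrotic
#' count. Necrosis is absorbing: necrotic cells never change state, never
#' move and never interact.
#'
#' @param state A [world_state()] whose `phi` has been renewed for this
#'   cycle.
#' @param phi_c Necrosis threshold in (0, 1); the comparison is strict, a
#'   grid at exactly `phi_c` survives.
#' @return The updated [world_state()].
#' @export
apply_necrosis <- function(state, phi_c) {
  living <- living_counts(state)
  m <- (state$phi < phi_c) & (living > 0L)
  if (any(m)) {
    state$n_necrotic[m] <- state$n_necrotic[m] + living[m]
    state$n_prolif[m] <- 0L
    state$n_invasive[m] <- 0L
  }
  state
}

#' Game payoff increments from the interaction neighbourhood
#'
#' Aggregates the payoff-matrix rewards a focal living cell collects from
#' its living interaction partners: the other living cells in its own grid
#' plus all living cells in the 8 Moore-neighbour grids, with phenotypes
#' taken from the previous round. Necrotic cells do not interact.
#'
#' With `aggregation = "mean"` (default) the summed rewards are divided by
#' the number of partners (0 if there are none), which keeps the
#' increments bounded as local density grows; `"sum"` returns the raw
#' totals.
#'
#' @param n_prolif_nbhd,n_invasive_nbhd Non-negative partner counts by
#'   phenotype (vectorised).
#' @param payoff A [payoff_matrix()].
#' @param aggregation `"mean"` or `"sum"`.
#' @return A [tibble::tibble()] with columns `delta_p` (increment to the
#'   proliferative probability) and `delta_i` (increment to the invasive
#'   probability).
#' @examples
#' game_increments(3, 1, payoff_matrix(a_pp = -0.1, b_ii = 0.1))
#' @export
game_increments <- function(n_prolif_nbhd, n_invasive_nbhd, payoff,
                            aggregation = c("mean", "sum")) {
  aggregation <- match.arg(aggregation)
  if (any(n_prolif_nbhd < 0) || any(n_invasive_nbhd < 0)) {
    stop("neighbourhood counts must be non-negative", call. = FALSE)
  }
  dp <- payoff$a_pp * n_prolif_nbhd + payoff$a_pi * n_invasive_nbhd
  di <- payoff$b_ip * n_prolif_nbhd + payoff$b_ii * n_invasive_nbhd
  if (aggregation == "mean") {
    den <- n_prolif_nbhd + n_invasive_nbhd
    pos <- den > 0
    dp <- ifelse(pos, dp / pmax(den, 1), 0)
    di <- ifelse(pos, di / pmax(den, 1), 0)
  }
  tibble::tibble(delta_p = dp, delta_i = di)
}

#' Proliferative and invasive probabilities
#'
#' Base fate probabilities as functions of the per-cell nutrient supply
#' `phi / N_T`, shifted by the aggregated game increment and clamped to
#' \[0, 1\]:
#' \deqn{P_p = 1 - \exp\{-(\phi/(N_T\,\theta_p))^2\} + \Delta_p,\qquad
#'       P_i = \exp\{-(\phi/(N_T\,\theta_i))^2\} + \Delta_i.}
#' Division becomes more likely with more nutrient per cell (sigmoidal in
#' `phi`, suppressed by crowding); migration is the mirror image, favoured
#' when the local supply is poor.
#'
#' @param phi Local nutrient concentration in \[0, 1\] (vectorised).
#' @param n_t Living cells in the focal grid, including the focal cell
#'   (>= 1).
#' @param theta_p,theta_i Shape parameters (> 0), the per-cell nutrient
#'   scale at which the exponential term reaches `1/e`.
#' @param delta_p,delta_i Signed game increments (default 0).
#' @return Numeric vector of probabilities in \[0, 1\].
#' @examples
#' proliferation_probability(0.3, 1, theta_p = 0.3)  # 1 - exp(-1)
#' invasion_probability(0.3, 1, theta_i = 0.3)       # exp(-1)
#' @export
proliferation_probability <- function(phi, n_t, theta_p, delta_p = 0) {
  if (any(theta_p <= 0)) stop("theta_p must be > 0", call. = FALSE)
  if (any(n_t < 1)) stop("n_t must be >= 1 (the focal cell counts itself)",
                         call. = FALSE)
  base <- 1 - exp(-(phi / (n_t * theta_p))^2)
  pmin(pmax(base + delta_p, 0), 1)
}

#' @rdname proliferation_probability
#' @export
invasion_probability <- function(phi, n_t, theta_i, delta_i = 0) {
  if (any(theta_i <= 0)) stop("theta_i must be > 0", call. = FALSE)
  if (any(n_t < 1)) stop("n_t must be >= 1 (the focal cell counts itself)",
                         call. = FALSE)
  base <- exp(-(phi / (n_t * theta_i))^2)
  pmin(pmax(base + delta_i, 0), 1)
}

#' Normalised fate probabilities
#'
#' Normalises the raw proliferative and invasive probabilities so they sum
#' to 1. If both raw values are exactly 0 the cell holds (no division, no
#' movement this cycle): the normalisation is undefined at 0/0 and the
#' hold flag records it.
#'
#' @param p_prolif_raw,p_invade_raw Raw (clamped) probabilities in \[0, 1\].
#' @return A list with elements `p_prolif`, `p_invade` (summing to 1
#'   unless holding), `hold` (logical) and `normalized = TRUE`.
#' @export
fate_probabilities <- function(p_prolif_raw, p_invade_raw) {
  stopifnot(length(p_prolif_raw) == 1, length(p_invade_raw) == 1)
  if (p_prolif_raw < 0 || p_invade_raw < 0 ||
      p_prolif_raw > 1 || p_invade_raw > 1) {
    stop("raw probabilities must lie in [0, 1]", call. = FALSE)
  }
  s <- p_prolif_raw + p_invade_raw
  if (s == 0) {
    list(p_prolif = 0, p_invade = 0, hold = TRUE, normalized = TRUE)
  } else {
    list(p_prolif = p_prolif_raw / s, p_invade = p_invade_raw / s,
         hold = FALSE, normalized = TRUE)
  }
}

#' Draw phenotype fates for the cells of one grid
#'
#' Each of `n_cells` living cells is independently assigned the
#' proliferative fate with probability `p$p_prolif`, otherwise the
#' invasive fate. When the probabilities carry the hold flag (both raw
#' values were 0) no cell acts this cycle.
#'
#' @param p Normalised probabilities from [fate_probabilities()].
#' @param n_cells Number of cells to assign (>= 0).
#' @return Named integer vector `c(n_prolif_fated, n_invade_fated)`
#'   summing to `n_cells`, or to 0 when holding.
#' @export
draw_fates <- function(p, n_cells) {
  n_cells <- as.integer(n_cells)
  stopifnot(n_cells >= 0)
  if (isTRUE(p$hold)) {
    return(c(n_prolif_fated = 0L, n_invade_fated = 0L))
  }
  nd <- stats::rbinom(1L, n_cells, p$p_prolif)
  c(n_prolif_fated = nd, n_invade_fated = n_cells - nd)
}

#' Select a destination grid among candidates
#'
#' The lexicographic placement rule: a daughter or migrant prefers the
#' candidate grid with the minimum total cell count (necrotic cells
#' included), then the highest nutrient concentration, and finally picks
#' uniformly at random among remaining ties.
#'
#' @param candidates A data frame with columns `site` (any identifier),
#'   `count` (total cells, necrotic included) and `phi` (nutrient), one
#'   row per candidate; must be non-empty.
#' @return The `site` entry of the selected row.
#' @examples
#' choose_site(data.frame(site = c("a", "b"), count = c(2, 5),
#'                        phi = c(0.1, 0.9)))  # "a"
#' @export
choose_site <- function(candidates) {
  if (is.null(candidates) || nrow(candidates) == 0) {
    stop("no candidate sites", call. = FALSE)
  }
  keep <- which(candidates$count == min(candidates$count))
  keep <- keep[candidates$phi[keep] == max(candidates$phi[keep])]
  pick <- keep[sample.int(length(keep), 1L)]
  if (is.list(candidates$site)) candidates$site[[pick]] else candidates$site[pick]
}

moore_dr <- c(-1L, -1L, -1L, 0L, 0L, 1L, 1L, 1L)
moore_dc <- c(-1L, 0L, 1L, -1L, 1L, -1L, 0L, 1L)

# Candidate table for single-event placement ops (tests and reference use).
site_candidates <- function(state, site, include_self) {
  L <- nrow(state$phi)
  tc <- total_counts(state)
  rows <- site[1] + moore_dr
  cols <- site[2] + moore_dc
  ok <- rows >= 1L & rows <= L & cols >= 1L & cols <= L
  rows <- rows[ok]; cols <- cols[ok]
  el <- state$rho_ecm[cbind(rows, cols)] == 0
  rows <- rows[el]; cols <- cols[el]
  if (include_self) {
    rows <- c(site[1], rows)
    cols <- c(site[2], cols)
  }
  if (length(rows) == 0) return(NULL)
  data.frame(
    site = I(lapply(seq_along(rows), function(i) c(rows[i], cols[i]))),
    count = tc[cbind(rows, cols)],
    phi = state$phi[cbind(rows, cols)]
  )
}

#' Place a daughter cell
#'
#' One division event at `site`: the candidate set is the current grid
#' plus every Moore neighbour with `rho_ecm = 0`; [choose_site()] picks
#' the destination and one new proliferative cell is added there. The
#' parent stays in place, so the current grid is always a valid fallback.
#'
#' @param state A [world_state()].
#' @param site Integer `c(row, col)` of the dividing cell's grid.
#' @return A list with the updated `state` and the chosen `target`
#'   (`c(row, col)`).
#' @export
place_offspring <- function(state, site) {
  cand <- site_candidates(state, site, include_self = TRUE)
  target <- choose_site(cand)
  state$n_prolif[target[1], target[2]] <- state$n_prolif[target[1], target[2]] + 1L
  list(state = state, target = target)
}

#' Move an invasive cell
#'
#' One migration event at `site`: the candidate set is the Moore
#' neighbours with `rho_ecm = 0` (the current grid is excluded). If no
#' neighbour is eligible the cell has to stay in its grid. Cell count is
#' conserved.
#'
#' @param state A [world_state()] with at least one invasive cell at
#'   `site`.
#' @param site Integer `c(row, col)`.
#' @return A list with the updated `state`, the `target` (`c(row, col)`,
#'   equal to `site` when staying) and `moved` (logical).
#' @export
move_invader <- function(state, site) {
  if (state$n_invasive[site[1], site[2]] < 1L) {
    stop("no invasive cell at the given site", call. = FALSE)
  }
  cand <- site_candidates(state, site, include_self = FALSE)
  if (is.null(cand)) {
    return(list(state = state, target = site, moved = FALSE))
  }
  target <- choose_site(cand)
  state$n_invasive[site[1], site[2]] <- state$n_invasive[site[1], site[2]] - 1L
  state$n_invasive[target[1], target[2]] <- state$n_invasive[target[1], target[2]] + 1L
  list(state = state, target = target, moved = TRUE)
}

# Vectorised lexicographic selection over a candidate matrix.
# cnt/phm/el are n x m matrices (Inf / -Inf / FALSE where ineligible);
# nev gives the number of events per row. Returns expanded per-event
# (row, col) pairs plus the rows with no candidate at all.
select_targets <- function(cnt, phm, el, nev) {
  n <- nrow(cnt)
  m <- ncol(cnt)
  bestc <- cnt[, 1]
  for (j in seq_len(m)[-1]) bestc <- pmin(bestc, cnt[, j])
  ph2 <- phm
  ph2[!(el & cnt == bestc)] <- -Inf
  bestp <- ph2[, 1]
  for (j in seq_len(m)[-1]) bestp <- pmax(bestp, ph2[, j])
  tie <- el & cnt == bestc & phm == bestp
  ntie <- rowSums(tie)
  rows <- integer(0); cols <- integer(0)
  single <- which(ntie == 1L & nev > 0L)
  if (length(single)) {
    mc <- max.col(tie, ties.method = "first")
    rows <- rep.int(single, nev[single])
    cols <- rep.int(mc[single], nev[single])
  }
  multi <- which(ntie > 1L & nev > 0L)
  for (i in multi) {
    tc <- which(tie[i, ])
    pick <- tc[sample.int(length(tc), nev[i], replace = TRUE)]
    rows <- c(rows, rep.int(i, nev[i]))
    cols <- c(cols, pick)
  }
  list(rows = rows, cols = cols, none = which(ntie == 0L & nev > 0L))
}

#' Advance the world by one cell cycle
#'
#' One synchronous update, in order: ECM degradation by all living cells;
#' nutrient renewal over `n_sub` substeps with the living counts frozen;
#' necrosis where the renewed nutrient falls below `phi_c`; fate
#' computation for every surviving cell from last-round phenotypes and
#' start-of-step counts; and synchronous application of all divisions and
#' migrations into a staged next state. Placement comparisons (counts,
#' nutrient, ECM eligibility) all use the start-of-step values, so
#' multiple arrivals at one grid within a step are possible. Fate draws
#' are consumed in row-major grid order (proliferative-class cells first,
#' then invasive-class), followed by placement draws in the same order.
#'
#' @param state A [world_state()].
#' @param config A valid [sim_config()].
#' @return The successor [world_state()] with `t` advanced by one tau.
#' @export
step_world <- function(state, config) {
  L <- nrow(state$phi)
  P <- state$n_prolif
  I <- state$n_invasive
  Nec <- state$n_necrotic
  living <- P + I

  rho <- degrade_ecm(state$rho_ecm, living, config$gamma, config$degrade_neighbors)
  phi <- update_nutrient_field(state, config$D, config$k, config$n_sub,
                               config$consumption_form)

  necm <- (phi < config$phi_c) & (living > 0L)
  if (any(necm)) {
    Nec[necm] <- Nec[necm] + living[necm]
    P[necm] <- 0L
    I[necm] <- 0L
    living <- P + I
  }

  out <- structure(list(t = state$t + 1L, n_prolif = P, n_invasive = I,
                        n_necrotic = Nec, phi = phi, rho_ecm = rho),
                   class = "world_state")

  idx <- which(living > 0L)
  if (length(idx) == 0L) return(out)

  r <- ((idx - 1L) %% L) + 1L
  cc <- ((idx - 1L) %/% L) + 1L
  ord <- order((r - 1L) * L + cc)  # row-major draw order
  idx <- idx[ord]; r <- r[ord]; cc <- cc[ord]

  P9 <- conv3(P)
  I9 <- conv3(I)
  nt <- living[idx]
  ph <- phi[idx]
  n <- length(idx)

  class_fates <- function(size, own_prolif) {
    div <- integer(n); mig <- integer(n); held <- integer(n)
    h <- which(size > 0L)
    if (!length(h)) return(list(div = div, mig = mig, held = held))
    nP <- P9[idx[h]] - if (own_prolif) 1L else 0L
    nI <- I9[idx[h]] - if (own_prolif) 0L else 1L
    gi <- game_increments(nP, nI, config$payoff, config$payoff_aggregation)
    Pp <- proliferation_probability(ph[h], nt[h], config$theta_p, gi$delta_p)
    Pi <- invasion_probability(ph[h], nt[h], config$theta_i, gi$delta_i)
    hold <- Pp == 0 & Pi == 0
    act <- which(!hold)
    if (length(act)) {
      d <- stats::rbinom(length(act), size[h][act],
                         Pp[act] / (Pp[act] + Pi[act]))
      div[h[act]] <- d
      mig[h[act]] <- size[h][act] - d
    }
    hh <- h[hold]
    held[hh] <- size[hh]
    list(div = div, mig = mig, held = held)
  }

  fP <- class_fates(P[idx], TRUE)
  fI <- class_fates(I[idx], FALSE)
  divs <- fP$div + fI$div
  migs <- fP$mig + fI$mig
  stayP <- divs + fP$held    # dividing cells keep their grid as proliferative
  stayI <- fI$held

  total0 <- P + I + Nec
  eligM <- rho == 0

  cand_info <- function(e, include_self) {
    ne <- length(e)
    m <- if (include_self) 9L else 8L
    cnt <- matrix(Inf, ne, m)
    phm <- matrix(-Inf, ne, m)
    el <- matrix(FALSE, ne, m)
    lin <- matrix(NA_integer_, ne, m)
    for (j in 1:8) {
      tr <- r[e] + moore_dr[j]
      tc <- cc[e] + moore_dc[j]
      ok <- tr >= 1L & tr <= L & tc >= 1L & tc <= L
      lj <- tr + (tc - 1L) * L
      ej <- ok
      ej[ok] <- eligM[lj[ok]]
      cnt[ej, j] <- total0[lj[ej]]
      phm[ej, j] <- phi[lj[ej]]
      el[, j] <- ej
      lin[ok, j] <- lj[ok]
    }
    if (include_self) {
      lin[, 9L] <- idx[e]
      el[, 9L] <- TRUE
      cnt[, 9L] <- total0[idx[e]]
      phm[, 9L] <- phi[idx[e]]
    }
    list(cnt = cnt, phm = phm, el = el, lin = lin)
  }

  add_arrivals <- function(mat, tlin) {
    if (!length(tlin)) return(mat)
    ag <- rowsum(rep.int(1L, length(tlin)), tlin)
    at <- as.integer(rownames(ag))
    mat[at] <- mat[at] + as.integer(ag)
    mat
  }

  P2 <- matrix(0L, L, L)
  I2 <- matrix(0L, L, L)
  P2[idx] <- stayP
  I2[idx] <- stayI

  de <- which(divs > 0L)
  if (length(de)) {
    ci <- cand_info(de, include_self = TRUE)
    sel <- select_targets(ci$cnt, ci$phm, ci$el, divs[de])
    P2 <- add_arrivals(P2, ci$lin[cbind(sel$rows, sel$cols)])
  }

  me <- which(migs > 0L)
  if (length(me)) {
    ci <- cand_info(me, include_self = FALSE)
    sel <- select_targets(ci$cnt, ci$phm, ci$el, migs[me])
    I2 <- add_arrivals(I2, ci$lin[cbind(sel$rows, sel$cols)])
    if (length(sel$none)) {
      stuck <- me[sel$none]
      I2[idx[stuck]] <- I2[idx[stuck]] + migs[stuck]
    }
  }

  out$n_prolif <- P2
  out$n_invasive <- I2
  out
}

ring_occupied <- function(state) {
  tc <- total_counts(state)
  L <- nrow(tc)
  any(tc[1L, ] > 0L) || any(tc[L, ] > 0L) ||
    any(tc[, 1L] > 0L) || any(tc[, L] > 0L)
}

#' Run a full simulation
#'
#' Initialises the world from `config` (seeding the RNG), then iterates
#' [step_world()] until `t_max` cell cycles have elapsed or the tumour
#' touches the lattice boundary, recording the summary metrics of
#' [record_state()] at every step (including `t = 0`) and keeping full
#' lattice snapshots at `config$snapshot_times`.
#'
#' @param config A valid [sim_config()].
#' @param keep_snapshots Keep full lattice snapshots at the configured
#'   times (default `TRUE`).
#' @param progress Print a progress line every 25 cycles.
#' @return An object of class `tumor_sim`: a list with `config`,
#'   `final_state`, `records` (a tibble, one row per recorded step),
#'   `snapshots` (named list of [world_state()]s), `halted_early` and
#'   `halt_reason` (`"edge_contact"` or `"t_max"`).
#' @examples
#' \donttest{
#' sim <- run_simulation(fixture_preset("smoke", seed = 1))
#' glance(sim)
#' }
#' @export
run_simulation <- function(config, keep_snapshots = TRUE, progress = FALSE) {
  assert_valid_config(config)
  state <- initialize_world(config)
  records <- vector("list", config$t_max + 1L)
  records[[1L]] <- record_state(state, config)
  snaps <- list()
  halted <- FALSE
  for (t in seq_len(config$t_max)) {
    state <- step_world(state, config)
    records[[t + 1L]] <- record_state(state, config)
    if (keep_snapshots && state$t %in% config$snapshot_times) {
      snaps[[as.character(state$t)]] <- state
    }
    if (progress && t %% 25L == 0L) {
      message(sprintf("t = %d tau: %d cells", t, sum(total_counts(state))))
    }
    if (ring_occupied(state)) {
      halted <- TRUE
      break
    }
  }
  structure(list(
    config = config,
    final_state = state,
    records = dplyr::bind_rows(records[!vapply(records, is.null, logical(1))]),
    snapshots = snaps,
    halted_early = halted,
    halt_reason = if (halted) "edge_contact" else "t_max"
  ), class = "tumor_sim")
}

#' @export
print.tumor_sim <- function(x, ...) {
  cat(sprintf("<tumor_sim> %d recorded steps (halt: %s)\n",
              nrow(x$records), x$halt_reason))
  print(utils::tail(x$records, 3))
  invisible(x)
}
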