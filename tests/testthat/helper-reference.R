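# Literal per-agent reference implementation of one synchronous cell cycle.
# Written independently of the package's vectorised engine: explicit agent
# lists, double-loop stencils and per-agent draws. Used only to check that
# the count-based engine agrees in distribution on small lattices.

ref_laplacian <- function(m) {
  L <- nrow(m)
  out <- matrix(0, L, L)
  for (i in 2:(L - 1)) {
    for (j in 2:(L - 1)) {
      out[i, j] <- m[i - 1, j] + m[i + 1, j] + m[i, j - 1] + m[i, j + 1] -
        4 * m[i, j]
    }
  }
  out
}

ref_step <- function(state, cfg) {
  L <- nrow(state$phi)
  living <- state$n_prolif + state$n_invasive

  # agents, grid by grid in row-major order
  agents <- list()
  for (i in seq_len(L)) {
    for (j in seq_len(L)) {
      if (state$n_prolif[i, j] > 0) {
        for (a in seq_len(state$n_prolif[i, j])) {
          agents[[length(agents) + 1L]] <- list(r = i, c = j, phen = "P")
        }
      }
      if (state$n_invasive[i, j] > 0) {
        for (a in seq_len(state$n_invasive[i, j])) {
          agents[[length(agents) + 1L]] <- list(r = i, c = j, phen = "I")
        }
      }
    }
  }

  # ECM degradation, agent by agent
  rho <- state$rho_ecm
  for (ag in agents) {
    for (dr in -1:1) {
      for (dc in -1:1) {
        if (!cfg$degrade_neighbors && !(dr == 0 && dc == 0)) next
        rr <- ag$r + dr; cc <- ag$c + dc
        if (rr >= 1 && rr <= L && cc >= 1 && cc <= L) {
          rho[rr, cc] <- max(rho[rr, cc] - cfg$gamma, 0)
        }
      }
    }
  }

  # nutrient substeps with frozen counts
  phi <- state$phi
  dt <- 1 / cfg$n_sub
  for (s in seq_len(cfg$n_sub)) {
    sink <- if (cfg$consumption_form == "proportional") {
      cfg$k * living * phi
    } else {
      cfg$k * living
    }
    phi <- phi + dt * (cfg$D * ref_laplacian(phi) - sink)
    phi[phi < 0] <- 0
    phi[phi > 1] <- 1
    phi[c(1, L), ] <- 1
    phi[, c(1, L)] <- 1
  }

  # necrosis
  nec <- state$n_necrotic
  alive <- list()
  for (ag in agents) {
    if (phi[ag$r, ag$c] < cfg$phi_c) {
      nec[ag$r, ag$c] <- nec[ag$r, ag$c] + 1L
    } else {
      alive[[length(alive) + 1L]] <- ag
    }
  }

  # start-of-step count matrices (post-necrosis)
  P0 <- matrix(0L, L, L); I0 <- matrix(0L, L, L)
  for (ag in alive) {
    if (ag$phen == "P") P0[ag$r, ag$c] <- P0[ag$r, ag$c] + 1L
    else I0[ag$r, ag$c] <- I0[ag$r, ag$c] + 1L
  }
  tot0 <- P0 + I0 + nec

  ref_pick <- function(r0, c0, include_self) {
    cand <- NULL
    if (include_self) cand <- rbind(cand, c(r0, c0))
    for (dr in -1:1) for (dc in -1:1) {
      if (dr == 0 && dc == 0) next
      rr <- r0 + dr; cc <- c0 + dc
      if (rr >= 1 && rr <= L && cc >= 1 && cc <= L && rho[rr, cc] == 0) {
        cand <- rbind(cand, c(rr, cc))
      }
    }
    if (is.null(cand)) return(NULL)
    cnt <- apply(cand, 1, function(x) tot0[x[1], x[2]])
    cand <- cand[cnt == min(cnt), , drop = FALSE]
    ph <- apply(cand, 1, function(x) phi[x[1], x[2]])
    cand <- cand[ph == max(ph), , drop = FALSE]
    cand[sample.int(nrow(cand), 1L), ]
  }

  P1 <- matrix(0L, L, L); I1 <- matrix(0L, L, L)
  for (ag in alive) {
    nP <- 0L; nI <- 0L
    for (dr in -1:1) for (dc in -1:1) {
      rr <- ag$r + dr; cc <- ag$c + dc
      if (rr >= 1 && rr <= L && cc >= 1 && cc <= L) {
        nP <- nP + P0[rr, cc]; nI <- nI + I0[rr, cc]
      }
    }
    if (ag$phen == "P") nP <- nP - 1L else nI <- nI - 1L
    dp <- cfg$payoff$a_pp * nP + cfg$payoff$a_pi * nI
    di <- cfg$payoff$b_ip * nP + cfg$payoff$b_ii * nI
    if (cfg$payoff_aggregation == "mean" && (nP + nI) > 0) {
      dp <- dp / (nP + nI); di <- di / (nP + nI)
    }
    nt <- P0[ag$r, ag$c] + I0[ag$r, ag$c]
    pp <- min(max(1 - exp(-(phi[ag$r, ag$c] / (nt * cfg$theta_p))^2) + dp, 0), 1)
    pi_ <- min(max(exp(-(phi[ag$r, ag$c] / (nt * cfg$theta_i))^2) + di, 0), 1)
    if (pp == 0 && pi_ == 0) {
      # hold: keep previous phenotype in place
      if (ag$phen == "P") P1[ag$r, ag$c] <- P1[ag$r, ag$c] + 1L
      else I1[ag$r, ag$c] <- I1[ag$r, ag$c] + 1L
    } else if (stats::runif(1) < pp / (pp + pi_)) {
      # divide: parent stays proliferative, daughter placed
      P1[ag$r, ag$c] <- P1[ag$r, ag$c] + 1L
      tgt <- ref_pick(ag$r, ag$c, include_self = TRUE)
      P1[tgt[1], tgt[2]] <- P1[tgt[1], tgt[2]] + 1L
    } else {
      # migrate as invasive; stay if no eligible neighbour
      tgt <- ref_pick(ag$r, ag$c, include_self = FALSE)
      if (is.null(tgt)) tgt <- c(ag$r, ag$c)
      I1[tgt[1], tgt[2]] <- I1[tgt[1], tgt[2]] + 1L
    }
  }

  structure(list(t = state$t + 1L, n_prolif = P1, n_invasive = I1,
                 n_necrotic = nec, phi = phi, rho_ecm = rho),
            class = "world_state")
}

# Deterministic 9x9 fixture shared by the equivalence tests: mixed
# phenotypes, a nutrient gradient and a partially cleared ECM field.
ref_fixture <- function() {
  L <- 9L
  phi <- matrix(rep(seq(0.3, 1, length.out = L), each = L), L, L)
  rho <- matrix(0.6, L, L)
  rho[3:7, 3:7] <- 0
  rho[2, 5] <- 0
  st <- world_state(L, phi = phi, rho_ecm = rho)
  st$n_prolif[5, 5] <- 2L
  st$n_invasive[5, 4] <- 1L
  st$n_prolif[6, 6] <- 1L
  st
}
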