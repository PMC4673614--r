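#' Payoff sweep specification
#'
#' Describes a grid of payoff magnitudes (`alpha_pp` inhibition values by
#' `beta_ii` enhancement values) with `n_trials` independent replicate
#' runs per grid point, all sharing one base configuration. Trial seeds
#' are derived deterministically from the base seed and the grid indices,
#' so no seed is reused across grid points or trials.
#'
#' @param alpha_pp_values,beta_ii_values Non-empty vectors of magnitudes
#'   (>= 0). Defaults cover 0 to 1 in steps of 0.1.
#' @param n_trials Replicates per grid point (default 10).
#' @param base_config Base [sim_config()]; its payoff entry is replaced at
#'   each grid point and its seed acts as the sweep's base seed.
#' @return An object of class `sweep_spec`.
#' @export
sweep_spec <- function(alpha_pp_values = seq(0, 1, by = 0.1),
                       beta_ii_values = seq(0, 1, by = 0.1),
                       n_trials = 10L,
                       base_config = fixture_preset("calibration")) {
  stopifnot(length(alpha_pp_values) >= 1, length(beta_ii_values) >= 1,
            all(alpha_pp_values >= 0), all(beta_ii_values >= 0),
            n_trials >= 1)
  structure(list(
    alpha_pp_values = as.numeric(alpha_pp_values),
    beta_ii_values = as.numeric(beta_ii_values),
    n_trials = as.integer(n_trials),
    base_config = base_config
  ), class = "sweep_spec")
}

# Deterministic trial seed: unique per (base seed, grid point, trial) for
# any realistic sweep size, and always below 2^31.
trial_seed <- function(base_seed, ia, ib, trial, n_beta, n_trials) {
  offset <- ((ia - 1) * n_beta + (ib - 1)) * n_trials + (trial - 1)
  as.integer((base_seed + 104729 * (offset + 1)) %% 2147483647L)
}

#' Run a payoff sweep
#'
#' Runs every `(alpha_pp, beta_ii, trial)` combination of a
#' [sweep_spec()], fitting the radial growth velocity `v` and the
#' roughness velocity `v_r` for each run (on the post-burn-in window; runs
#' that touch the lattice edge before `t_max` are fit on the available
#' window and flagged `halted_early`).
#'
#' If `out_csv` is given, rows are appended to it as they complete and any
#' combinations already present in the file are skipped, so an
#' interrupted sweep can be resumed and yields the same final table.
#'
#' @param spec A [sweep_spec()].
#' @param out_csv Optional CSV path for incremental results / resume.
#' @param progress Print one line per completed run.
#' @return An object of class `tumor_sweep`: list with `results` (tibble
#'   of `alpha_pp, beta_ii, trial, seed, v, v_r, halted_early`) and
#'   `spec`.
#' @export
run_sweep <- function(spec, out_csv = NULL, progress = FALSE) {
  stopifnot(inherits(spec, "sweep_spec"))
  done <- NULL
  if (!is.null(out_csv) && file.exists(out_csv)) {
    done <- readr::read_csv(out_csv, show_col_types = FALSE)
  }
  grid <- expand.grid(
    trial = seq_len(spec$n_trials),
    ib = seq_along(spec$beta_ii_values),
    ia = seq_along(spec$alpha_pp_values)
  )
  rows <- vector("list", nrow(grid))
  for (g in seq_len(nrow(grid))) {
    ia <- grid$ia[g]; ib <- grid$ib[g]; trial <- grid$trial[g]
    a <- spec$alpha_pp_values[ia]
    b <- spec$beta_ii_values[ib]
    if (!is.null(done) &&
        any(abs(done$alpha_pp - a) < 1e-12 & abs(done$beta_ii - b) < 1e-12 &
            done$trial == trial)) {
      hit <- done[abs(done$alpha_pp - a) < 1e-12 &
                  abs(done$beta_ii - b) < 1e-12 & done$trial == trial, ]
      rows[[g]] <- tibble::as_tibble(hit[1, ])
      next
    }
    cfg <- spec$base_config
    cfg$payoff <- standard_payoffs(alpha_pp = a, beta_ii = b)
    cfg$seed <- trial_seed(spec$base_config$seed, ia, ib, trial,
                           length(spec$beta_ii_values), spec$n_trials)
    sim <- run_simulation(cfg, keep_snapshots = FALSE)
    gv <- tryCatch(growth_velocities(sim), error = function(e) {
      tibble::tibble(v = NA_real_, r2_front = NA_real_, v_r = NA_real_,
                     r2_rough = NA_real_, rough_exponent = NA_real_)
    })
    row <- tibble::tibble(
      alpha_pp = a, beta_ii = b, trial = trial, seed = cfg$seed,
      v = gv$v, v_r = gv$v_r, halted_early = sim$halted_early
    )
    rows[[g]] <- row
    if (!is.null(out_csv)) {
      readr::write_csv(row, out_csv, append = file.exists(out_csv))
    }
    if (progress) {
      message(sprintf("alpha_pp=%.2f beta_ii=%.2f trial %d: v=%.3f v_r=%.4f",
                      a, b, trial, row$v, row$v_r))
    }
  }
  res <- dplyr::bind_rows(rows)
  res <- dplyr::arrange(res, .data$alpha_pp, .data$beta_ii, .data$trial)
  structure(list(results = res, spec = spec), class = "tumor_sweep")
}

#' Aggregate a sweep over trials
#'
#' @param sweep A `tumor_sweep` (or its results tibble).
#' @return A tibble with one row per `(alpha_pp, beta_ii)` grid point:
#'   mean velocities `v_mean`, `v_r_mean`, their standard deviations and
#'   the trial count.
#' @export
summarize_sweep <- function(sweep) {
  res <- if (inherits(sweep, "tumor_sweep")) sweep$results else sweep
  dplyr::summarise(
    dplyr::group_by(res, .data$alpha_pp, .data$beta_ii),
    v_mean = mean(.data$v), v_sd = stats::sd(.data$v),
    v_r_mean = mean(.data$v_r), v_r_sd = stats::sd(.data$v_r),
    n_trials = dplyr::n(),
    .groups = "drop"
  )
}

#' @export
print.tumor_sweep <- function(x, ...) {
  cat(sprintf("<tumor_sweep> %d runs over a %d x %d payoff grid\n",
              nrow(x$results), length(x$spec$alpha_pp_values),
              length(x$spec$beta_ii_values)))
  print(summarize_sweep(x))
  invisible(x)
}
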