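config_scalar_keys <- c(
  "L", "t_max", "D", "k", "phi_c", "theta_p", "theta_i", "gamma", "n_sub",
  "degrade_neighbors", "payoff_aggregation", "consumption_form",
  "n_angular_bins", "rdf_bin_width", "burn_in", "snapshot_times", "seed"
)
payoff_keys <- c("a_pp", "a_pi", "b_ip", "b_ii",
                 "alpha_pp", "beta_ii", "alpha_pi", "beta_ip")

#' Read a simulation configuration from YAML
#'
#' The canonical configuration dialect is YAML. Every [sim_config()] field
#' is addressable by its name; the payoff matrix lives under a `payoff`
#' mapping given either as raw signed entries (`a_pp`, `a_pi`, `b_ip`,
#' `b_ii`) or in the conventional magnitudes (`alpha_pp`, `beta_ii`,
#' `alpha_pi`, `beta_ip`, see [standard_payoffs()]). Unknown keys are
#' rejected.
#'
#' @param path Path to a YAML file.
#' @return A validated [sim_config()].
#' @export
read_sim_config <- function(path) {
  raw <- yaml::read_yaml(path)
  if (is.null(raw)) raw <- list()
  unknown <- setdiff(names(raw), c(config_scalar_keys, "payoff"))
  if (length(unknown)) {
    stop("unknown configuration key(s): ", paste(unknown, collapse = ", "),
         call. = FALSE)
  }
  args <- raw[intersect(names(raw), config_scalar_keys)]
  if (!is.null(raw$payoff)) {
    pk <- raw$payoff
    bad <- setdiff(names(pk), payoff_keys)
    if (length(bad)) {
      stop("unknown payoff key(s): ", paste(bad, collapse = ", "),
           call. = FALSE)
    }
    args$payoff <- if (any(c("alpha_pp", "beta_ii") %in% names(pk))) {
      do.call(standard_payoffs, pk)
    } else {
      do.call(payoff_matrix, pk)
    }
  }
  cfg <- do.call(sim_config, args)
  assert_valid_config(cfg)
  cfg
}

#' Write a simulation configuration to YAML
#'
#' @param config A [sim_config()].
#' @param path Output path.
#' @return `path`, invisibly. Round-trips through [read_sim_config()].
#' @export
write_sim_config <- function(config, path) {
  lst <- unclass(config)
  lst$payoff <- unclass(lst$payoff)
  yaml::write_yaml(lst, path)
  invisible(path)
}

#' Snapshot persistence
#'
#' Stores the five lattice fields and the time stamp of a [world_state()]
#' in R's compressed serialisation container (`.rds`, gzip). The
#' round-trip is lossless.
#'
#' @param state A [world_state()].
#' @param path Output path (conventionally `snapshot_t<t>.rds`).
#' @return `path`, invisibly.
#' @export
write_snapshot <- function(state, path) {
  saveRDS(unclass(state), path, compress = "gzip")
  invisible(path)
}

#' @rdname write_snapshot
#' @export
read_snapshot <- function(path) {
  structure(readRDS(path), class = "world_state")
}

#' Write the per-step time series to CSV
#'
#' One row per recorded cell cycle with the columns of [record_state()].
#'
#' @param sim A `tumor_sim` object (or its `records` tibble).
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_timeseries_csv <- function(sim, path) {
  rec <- if (inherits(sim, "tumor_sim")) sim$records else sim
  readr::write_csv(rec, path)
  invisible(path)
}

#' Write per-sector radial distribution functions to CSV
#'
#' @param rdf A tibble from [radial_distribution()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_rdf_csv <- function(rdf, path) {
  readr::write_csv(rdf, path)
  invisible(path)
}

# Plain-text run manifest: enough to reproduce the run exactly.
write_manifest <- function(config, path, halt_reason = NA_character_) {
  lst <- unclass(config)
  lst$payoff <- unclass(lst$payoff)
  jsonlite::write_json(
    list(package = "tumorgame",
         version = as.character(utils::packageVersion("tumorgame")),
         config = lst,
         halt_reason = halt_reason),
    path, auto_unbox = TRUE, pretty = TRUE, digits = NA
  )
  invisible(path)
}
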