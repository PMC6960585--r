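# Experiment orchestration: one-axis parameter sweeps (stiffness, density,
# short-chain length) at desk scale, aggregated into a tidy results table
# and an optional on-disk manifest.

#' Parameter sweep over runs
#'
#' Builds, runs and analyses one system per (value, seed) combination,
#' varying a single `system` field of the base configuration (e.g.
#' `"kb_long"`, `"rho"`, `"n_short"`). Each run reports the long-species
#' mean radial distance, orientation order, and — when the trajectory
#' permits — the tangential/radial velocity ratio. Density sweeps
#' automatically receive a critical-density estimate from the seed-averaged
#' velocity ratios.
#'
#' @param base_config raw config list or path (see [validate_config()]).
#' @param axis name of the `system` field to vary.
#' @param values values of the axis (non-empty).
#' @param seeds one run per seed per value.
#' @param delta_t displacement interval for the velocity decomposition;
#'   defaults to the trajectory sampling interval.
#' @param out_dir optional directory: aggregated CSV, per-run trajectories
#'   and a JSON manifest are written there.
#' @return A list of class `sweep_result`: `results` (one row per run),
#'   `summary` (seed-averaged per value), `critical_density` (rho sweeps
#'   only), `manifest_path` (if written).
#' @export
sweep_parameter <- function(base_config, axis, values, seeds = 1L, delta_t = NULL,
                  out_dir = NULL) {
  if (is.character(base_config) && length(base_config) == 1) {
    base_config <- yaml::read_yaml(base_config)
  }
  if (!length(values)) abort("sweep needs a non-empty list of values")
  probe <- validate_config(base_config)
  if (!axis %in% names(base_config$system) &&
    !axis %in% names(probe$system)) {
    abort(sprintf("unknown sweep axis '%s' (not a system field)", axis))
  }
  if (!is.null(out_dir) && !dir.exists(out_dir)) {
    dir.create(out_dir, recursive = TRUE)
  }

  grid <- tidyr::expand_grid(value = values, seed = as.integer(seeds))
  outputs <- list()
  results <- purrr::pmap_dfr(grid, function(value, seed) {
    raw <- base_config
    raw$system[[axis]] <- value
    raw$system$seed <- seed
    raw$schedule$seed <- seed
    cfg <- validate_config(raw)
    state <- place_chains(cfg$topology, cfg$confinement, cfg$forcefield,
      seed = seed
    )
    traj <- run_md(state, cfg$forcefield, cfg$schedule)
    ratio <- NA_real_
    if (n_frames(traj) >= 3) {
      dt_use <- delta_t %||% traj$sampling_interval
      vd <- tryCatch(
        velocity_decomposition(traj, "long", delta_t = dt_use),
        error = function(e) NULL
      )
      if (!is.null(vd)) ratio <- vd$ratio
    }
    if (!is.null(out_dir)) {
      tag <- sprintf("%s_%s_seed%d", axis, format(value), seed)
      tp <- file.path(out_dir, paste0(tag, ".dump"))
      write_trajectory(traj, tp, "lammps_dump")
      outputs[[tag]] <<- list(
        path = tp,
        parameters = list(axis = axis, value = value, seed = seed)
      )
    }
    tibble::tibble(
      axis = axis, value = value, seed = seed,
      mean_r_long = mean_radial_distance(traj, "long"),
      p2 = orientation_order(traj, "long"),
      velocity_ratio = ratio,
      mean_temperature = traj$metadata$mean_temperature
    )
  })

  summary <- results |>
    dplyr::group_by(.data$value) |>
    dplyr::summarise(
      mean_r_long = mean(.data$mean_r_long),
      p2 = mean(.data$p2),
      velocity_ratio = mean(.data$velocity_ratio),
      .groups = "drop"
    )

  rho_star <- NULL
  if (identical(axis, "rho") && nrow(summary) >= 3 &&
    all(is.finite(summary$velocity_ratio))) {
    rho_star <- critical_density(
      data.frame(rho = summary$value, ratio = summary$velocity_ratio)
    )
  }

  manifest_path <- NULL
  if (!is.null(out_dir)) {
    csv <- file.path(out_dir, sprintf("sweep_%s.csv", axis))
    readr::write_csv(results, csv)
    outputs$aggregate <- list(
      path = csv,
      parameters = list(axis = axis, values = values, seeds = seeds)
    )
    if (!is.null(rho_star)) {
      outputs$critical_density <- list(path = NULL, value = rho_star,
        parameters = list(axis = "rho")
      )
    }
    manifest_path <- file.path(out_dir, sprintf("sweep_%s_manifest.json", axis))
    write_manifest(base_config, outputs, manifest_path)
  }

  structure(
    list(
      results = results, summary = summary, critical_density = rho_star,
      manifest_path = manifest_path
    ),
    class = "sweep_result"
  )
}

#' @export
print.sweep_result <- function(x, ...) {
  cat(sprintf(
    "<sweep_result> %d runs over %s\n", nrow(x$results), x$results$axis[1]
  ))
  print(x$summary)
  if (!is.null(x$critical_density)) {
    cat(sprintf("critical density rho* = %.3f\n", x$critical_density))
  }
  invisible(x)
}

#' @export
tidy.sweep_result <- function(x, ...) x$results

#' @export
glance.sweep_result <- function(x, ...) {
  tibble::tibble(
    axis = x$results$axis[1],
    n_runs = nrow(x$results),
    n_values = dplyr::n_distinct(x$results$value),
    critical_density = x$critical_density %||% NA_real_
  )
}
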