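# NVT/NVE integration.  Velocity Verlet with a single Nose-Hoover variable;
# annealing ladders and production sampling orchestrated here, the inner
# loop in compiled code.

# Nose-Hoover coupling mass: damping period of 100 timesteps.
nh_mass <- function(n, tstar, dt) 3 * n * tstar * (100 * dt)^2

#' Instantaneous kinetic temperature
#'
#' `T = sum(m v^2) / (3N - 3)` — three degrees of freedom removed for the
#' zeroed total momentum (reduced units, k_B = m = 1).
#'
#' @param state a [system_state()].
#' @return Reduced temperature.
#' @export
instantaneous_temperature <- function(state) {
  n <- nrow(state$velocities)
  if (n < 2) abort("temperature needs at least 2 monomers")
  sum(state$velocities^2) / (3 * n - 3)
}

#' Advance a state by one (or a few) integration steps
#'
#' One velocity-Verlet update per step; with `thermostat = "on"` a single
#' Nose-Hoover variable couples the system to the target temperature, with
#' `"off"` the update is symplectic NVE.
#'
#' @param state a [system_state()].
#' @param ff force-field parameters.
#' @param dt timestep in tau0 (0.006 recommended; larger risks FENE
#'   overstretch).
#' @param thermostat `"on"` or `"off"`.
#' @param n_steps number of consecutive steps to take.
#' @param tstar thermostat target temperature.
#' @return The advanced [system_state()].
#' @export
md_step <- function(state, ff = forcefield_params(), dt = 0.006,
                    thermostat = c("off", "on"), n_steps = 1L, tstar = 1.0) {
  thermostat <- match.arg(thermostat)
  al <- angle_list(state$topology)
  n <- nrow(state$positions)
  res <- run_md_cpp(
    state$positions, state$velocities,
    bond_list(state$topology) - 1L, al$triplets - 1L, al$k,
    unclass(ff), conf_cpp(state$confinement),
    dt = dt, nsteps = as.integer(n_steps), sample_every = 0L,
    thermostat = thermostat == "on", tstar = tstar,
    q = nh_mass(n, tstar, dt), xi0 = 0,
    record_velocities = FALSE, temp_every = 0L
  )
  system_state(res$positions, res$velocities, state$topology,
    state$confinement,
    time = state$time + n_steps * dt
  )
}

#' Run an MD simulation
#'
#' Executes the schedule against an initial state: optional reheat-annealing
#' stages (a temperature ladder that shakes the system out of locally trapped
#' configurations), an equilibration stretch at the target temperature, then
#' production with frames sampled every `sample_interval` steps. The
#' thermostat variable carries over between stages. On the final frame the
#' ring topology is re-verified: any pair whose linking number differs from
#' zero aborts the run (a chain crossing occurred, i.e. the timestep was too
#' large).
#'
#' Run metadata (resolved schedule, seed, achieved temperature, topology
#' check) is embedded in the returned trajectory.
#'
#' @param initial a builder-validated [system_state()].
#' @param ff force-field parameters.
#' @param schedule a [run_schedule()].
#' @param record_velocities keep per-frame velocities (needed by the velocity
#'   decomposition observable).
#' @param check_topology verify ring linking numbers on the final frame.
#' @return A [trajectory()] of the production frames.
#' @export
run_md <- function(initial, ff = forcefield_params(), schedule = run_schedule(),
                   record_velocities = TRUE, check_topology = TRUE) {
  stopifnot(inherits(initial, "system_state"), inherits(schedule, "run_schedule"))
  dt <- schedule$timestep
  n <- nrow(initial$positions)
  al <- angle_list(initial$topology)
  bonds0 <- bond_list(initial$topology) - 1L
  conf <- conf_cpp(initial$confinement)
  ffl <- unclass(ff)
  xi <- 0
  pos <- initial$positions
  vel <- initial$velocities
  t0 <- initial$time

  stage <- function(nsteps, tstar, sample_every = 0L, record = FALSE) {
    if (nsteps < 1) {
      return(NULL)
    }
    res <- run_md_cpp(
      pos, vel, bonds0, al$triplets - 1L, al$k, ffl, conf,
      dt = dt, nsteps = as.integer(nsteps), sample_every = as.integer(sample_every),
      thermostat = TRUE, tstar = tstar, q = nh_mass(n, tstar, dt), xi0 = xi,
      record_velocities = record, temp_every = 10L
    )
    pos <<- res$positions
    vel <<- res$velocities
    xi <<- res$xi
    res
  }

  if (!is.null(schedule$anneal)) {
    for (s in seq_len(nrow(schedule$anneal))) {
      stage(round(schedule$anneal$duration[s] / dt), schedule$anneal$tstar[s])
    }
  }
  eq_steps <- round(schedule$equilibration_time / dt)
  stage(eq_steps, schedule$tstar)

  prod_steps <- round(schedule$production_time / dt)
  temps <- numeric()
  energy <- NULL
  frames <- list()
  vel_frames <- NULL
  frame_step <- integer()
  if (prod_steps >= 1) {
    res <- stage(prod_steps, schedule$tstar,
      sample_every = schedule$sample_interval, record = record_velocities
    )
    frames <- res$frames
    if (record_velocities) vel_frames <- res$frame_velocities
    frame_step <- res$frame_step
    temps <- res$temperature
    energy <- res$energy
  }

  final <- system_state(pos, vel, initial$topology, initial$confinement)
  topo <- NULL
  if (check_topology) {
    topo <- verify_topology(final)
    if (!topo$ok) {
      abort(paste(
        "ring topology violated during the run (chain crossing):",
        sum(topo$pairs$flagged), "linked pair(s); reduce the timestep"
      ))
    }
  }

  t_prod0 <- t0 +
    (if (!is.null(schedule$anneal)) sum(schedule$anneal$duration) else 0) +
    eq_steps * dt
  times <- t_prod0 + frame_step * dt
  trajectory_from_frames(
    frames, times, initial$topology, initial$confinement, vel_frames,
    metadata = list(
      schedule = schedule,
      forcefield = unclass(ff),
      seed = schedule$seed,
      mean_temperature = if (length(temps)) mean(temps) else NA_real_,
      energy_samples = energy,
      final_state = final,
      topology_check = topo
    )
  )
}

#' Equilibration check from the long-species radial drift
#'
#' Fits a line to the second half of the per-frame mean radial distance of
#' the long species; the system is considered equilibrated when the slope is
#' consistent with zero at the given confidence level.
#'
#' @param traj a sphere-mode [trajectory()].
#' @param species which species' monomers to track.
#' @param level confidence level of the slope test.
#' @return A one-row tibble: `slope`, `conf_lo`, `conf_hi`, `equilibrated`.
#' @export
check_equilibration <- function(traj, species = "long", level = 0.95) {
  at <- atom_table(traj$topology)
  sel <- at$atom[at$species == species]
  nf <- n_frames(traj)
  if (nf < 6) abort("too few frames for an equilibration check")
  rmean <- vapply(seq_len(nf), function(i) {
    mean(sqrt(rowSums(traj$positions[sel, , i, drop = FALSE]^2)))
  }, numeric(1))
  half <- seq.int(ceiling(nf / 2), nf)
  fit <- stats::lm(r ~ t, data = data.frame(t = traj$times[half], r = rmean[half]))
  ci <- stats::confint(fit, "t", level = level)
  tibble::tibble(
    slope = unname(stats::coef(fit)["t"]),
    conf_lo = ci[1], conf_hi = ci[2],
    equilibrated = ci[1] <= 0 && ci[2] >= 0
  )
}

#' @export
glance.trajectory <- function(x, ...) {
  tibble::tibble(
    n_frames = n_frames(x),
    n_monomers = dim(x$positions)[1],
    n_chains = nrow(x$topology),
    confinement = x$confinement$shape,
    sampling_interval = x$sampling_interval,
    mean_temperature = x$metadata$mean_temperature %||% NA_real_,
    topology_ok = if (!is.null(x$metadata$topology_check)) {
      x$metadata$topology_check$ok
    } else {
      NA
    }
  )
}

#' Per-frame summary of a trajectory
#'
#' One row per frame and species with the mean monomer radial distance and
#' the mean chain-COM radial distance (sphere mode; radial columns are `NA`
#' in periodic mode).
#'
#' @param x a [trajectory()].
#' @param ... unused.
#' @return A tibble.
#' @export
tidy.trajectory <- function(x, ...) {
  at <- atom_table(x$topology)
  sphere <- x$confinement$shape == "sphere"
  purrr::map_dfr(seq_len(n_frames(x)), function(i) {
    pos <- x$positions[, , i]
    purrr::map_dfr(unique(at$species), function(sp) {
      sel <- at$atom[at$species == sp]
      tibble::tibble(
        frame = i, time = x$times[i], species = sp,
        mean_r = if (sphere) mean(sqrt(rowSums(pos[sel, , drop = FALSE]^2))) else NA_real_,
        mean_r_com = if (sphere) {
          coms <- chain_coms(pos, x$topology, species = sp)
          mean(sqrt(rowSums(coms^2)))
        } else {
          NA_real_
        }
      )
    })
  })
}
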