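# Builder: initial states with guaranteed topology.  Rings start as rigid
# planar polygons (unknotted by construction), rejection-placed so that no
# two chains approach below `min_separation` and no ring pair is
# concatenated; a short capped-repulsion ramp then relaxes residual strain
# before the full WCA potential takes over.

#' Number of short chains implied by a target density
#'
#' The mixture density is defined as monomer count over cavity volume,
#' `rho = (M_long N_long + M_short N_short) / V`. Given the long-species
#' composition this solves for the short-chain count, rounded down; the
#' achieved density is therefore at most the requested one.
#'
#' @param rho target number density (monomers / sigma^3).
#' @param confinement a confinement object (its volume sets `V`).
#' @param m_long,n_long long-chain count and length.
#' @param n_short short-chain length.
#' @return Integer chain count (>= 1).
#' @examples
#' count_short_chains(0.4, confinement_sphere(20), 10, 50, 10) # 1290
#' @export
count_short_chains <- function(rho, confinement, m_long, n_long, n_short) {
  if (rho <= 0) abort("rho must be positive")
  v <- confinement_volume(confinement)
  m <- floor((rho * v - m_long * n_long) / n_short)
  if (m < 1) {
    abort(sprintf(
      "infeasible composition: rho V = %.1f leaves no room for short chains after %d long monomers",
      rho * v, m_long * n_long
    ))
  }
  as.integer(m)
}

#' Build an initial state of unlinked chains
#'
#' Places every chain of `topology` into the confinement: rings as planar
#' regular polygons and linear chains as straight rods, at random positions
#' and orientations, rejection-sampled so that (i) all monomers respect the
#' wall margin, (ii) no two monomers of different chains are closer than
#' `min_separation`, and (iii) no ring pair is concatenated (checked by Gauss
#' linking number during placement). A 500-step ramp of a capped soft
#' repulsion under the Nose-Hoover thermostat then pushes residual contacts
#' apart before the full WCA potential applies. Velocities are drawn from the
#' Maxwell-Boltzmann distribution at `tstar` with the total momentum zeroed.
#'
#' Placement is deterministic given `seed`.
#'
#' @param topology a [topology()]; chains are placed in table order (place
#'   the large rings first — the default ordering of
#'   [binary_mixture_topology()]).
#' @param confinement sphere or periodic box.
#' @param ff force-field parameters.
#' @param seed integer seed.
#' @param bond_length initial bond length of the rigid polygons/rods.
#' @param min_separation smallest allowed inter-chain monomer distance at
#'   placement (the rigid-unit rejection sampling needs a little slack at
#'   the paper-scale densities); the push-off then separates chains to at
#'   least `pushoff_target`.
#' @param pushoff_target inter-chain distance the push-off must achieve.
#' @param pushoff_steps length of the soft-repulsion ramp (0 skips it).
#' @param tstar temperature of the initial Maxwell-Boltzmann velocities.
#' @param max_attempts placement attempts per chain before giving up.
#' @return A [system_state()] passing [check_state()] with all ring pairs
#'   unlinked.
#' @export
place_chains <- function(topology, confinement, ff = forcefield_params(),
                         seed = 1L, bond_length = 0.97,
                         min_separation = 0.75, pushoff_target = 0.9,
                         pushoff_steps = 500L,
                         tstar = 1.0, max_attempts = 200000L) {
  stopifnot(inherits(topology, "topology"), inherits(confinement, "confinement"))
  # coarse feasibility: monomer excluded volume vs cavity volume
  n <- sum(topology$n_monomers)
  v <- confinement_volume(confinement)
  if (n * pi / 6 * ff$lj_sigma^3 > 0.55 * v) {
    abort(sprintf(
      "infeasible density: %d monomers of excluded volume %.2f in volume %.2f",
      n, n * pi / 6 * ff$lj_sigma^3, v
    ))
  }
  pos <- place_chains_cpp(
    n_mon = topology$n_monomers,
    is_ring = topology$kind == "ring",
    bond_length = bond_length,
    conf_ = conf_cpp(confinement),
    min_sep = min_separation,
    wall_margin = ff$lj_sigma,
    seed = as.integer(seed),
    max_attempts = as.integer(max_attempts)
  )

  # Maxwell-Boltzmann velocities, total momentum zeroed (R RNG, seeded)
  vel <- withr::with_seed(as.integer(seed), {
    matrix(rnorm(3 * n, sd = sqrt(tstar)), n, 3)
  })
  vel <- sweep(vel, 2, colMeans(vel))

  state <- system_state(pos, vel, topology, confinement)

  if (pushoff_steps > 0) {
    state <- pushoff(state, ff,
      steps = as.integer(pushoff_steps),
      target_separation = pushoff_target, tstar = tstar
    )
  }
  state
}

#' @rdname place_chains
#' @export
place_rings_in_sphere <- function(topology, confinement = confinement_sphere(),
                                  ff = forcefield_params(), seed = 1L, ...) {
  if (confinement$shape != "sphere") abort("confinement must be a sphere")
  place_chains(topology, confinement, ff, seed, ...)
}

# Soft push-off: capped repulsion A(t) ramped 0 -> a_max over `steps`
# thermostatted steps, then verified against the full WCA overlap criterion.
pushoff <- function(state, ff, steps = 500L, a_max = 30,
                    target_separation = 0.9, tstar = 1.0, dt = 0.001) {
  al <- angle_list(state$topology)
  n <- nrow(state$positions)
  res <- run_md_cpp(
    state$positions, state$velocities,
    bond_list(state$topology) - 1L, al$triplets - 1L, al$k,
    unclass(ff), conf_cpp(state$confinement),
    dt = dt, nsteps = steps, sample_every = 0L,
    thermostat = TRUE, tstar = tstar, q = nh_mass(n, tstar, dt), xi0 = 0,
    pair_style = 1L, soft_a0 = 0, soft_a1 = a_max,
    record_velocities = FALSE, temp_every = 0L
  )
  out <- system_state(
    res$positions, res$velocities, state$topology, state$confinement,
    time = state$time
  )
  # settle onto the full WCA surface at a conservative timestep
  out <- md_step(out, ff, dt = dt, thermostat = "on", n_steps = 200L,
    tstar = tstar
  )
  at <- atom_table(state$topology)
  sep <- min_separation_cpp(out$positions, at$chain, conf_cpp(out$confinement))
  if (is.finite(sep$min_interchain) && sep$min_interchain < target_separation) {
    # one more ramp round at full strength resolves rare stubborn contacts
    res <- run_md_cpp(
      out$positions, out$velocities,
      bond_list(state$topology) - 1L, al$triplets - 1L, al$k,
      unclass(ff), conf_cpp(state$confinement),
      dt = dt, nsteps = steps, sample_every = 0L,
      thermostat = TRUE, tstar = tstar, q = nh_mass(n, tstar, dt), xi0 = 0,
      pair_style = 1L, soft_a0 = a_max, soft_a1 = 2 * a_max,
      record_velocities = FALSE, temp_every = 0L
    )
    out <- system_state(
      res$positions, res$velocities, state$topology, state$confinement
    )
    out <- md_step(out, ff, dt = dt, thermostat = "on", n_steps = 200L,
      tstar = tstar
    )
  }
  out
}

#' Gauss linking number of two closed polylines
#'
#' The discrete Gauss double integral, evaluated exactly segment pair by
#' segment pair through the solid angle of the connecting quadrilateral, so
#' the result is an integer (up to floating-point noise) for any
#' discretisation: 0 for unlinked rings, +-1 for a Hopf link.
#'
#' @param ring_a,ring_b `n x 3` vertex matrices of closed polylines (the
#'   closing segment from the last vertex back to the first is implicit).
#' @return The raw (unrounded) linking number.
#' @examples
#' rings <- hopf_pair()
#' linking_number(rings[[1]], rings[[2]]) # +-1
#' @export
linking_number <- function(ring_a, ring_b) {
  ring_a <- as.matrix(ring_a)
  ring_b <- as.matrix(ring_b)
  if (identical(dim(ring_a), dim(ring_b)) && isTRUE(all(ring_a == ring_b))) {
    abort("a ring cannot be paired with itself")
  }
  if (nrow(ring_a) < 3 || nrow(ring_b) < 3) {
    abort("closed polylines need at least 3 segments")
  }
  linking_number_cpp(ring_a, ring_b)
}

#' Verify that all ring pairs of a state are unlinked
#'
#' Evaluates the Gauss linking number for every pair of ring chains (pairs
#' whose bounding spheres are disjoint are unlinked by geometry and reported
#' as exact zeros) and flags any pair whose rounded linking number is nonzero
#' or whose raw value sits further than `tol` from an integer.
#'
#' @param state a [system_state()].
#' @param tol residual tolerance on |raw - rounded|.
#' @return A list of class `topology_report`: `pairs` (tibble with columns
#'   `chain_i`, `chain_j`, `lk_raw`, `lk`, `flagged`), `max_residual`, and
#'   `ok` (no flagged pair).
#' @export
verify_topology <- function(state, tol = 0.05) {
  sl <- chain_slices(state$topology)
  rings <- sl[sl$kind == "ring", ]
  if (nrow(rings) < 2) {
    return(structure(
      list(
        pairs = tibble::tibble(
          chain_i = integer(), chain_j = integer(),
          lk_raw = numeric(), lk = integer(), flagged = logical()
        ),
        max_residual = 0, ok = TRUE
      ),
      class = "topology_report"
    ))
  }
  lk <- pairwise_linking_cpp(state$positions, rings$start - 1L, rings$n)
  idx <- which(upper.tri(lk), arr.ind = TRUE)
  raw <- lk[idx]
  rounded <- round(raw)
  pairs <- tibble::tibble(
    chain_i = rings$chain[idx[, 1]],
    chain_j = rings$chain[idx[, 2]],
    lk_raw = raw,
    lk = as.integer(rounded),
    flagged = rounded != 0 | abs(raw - rounded) > tol
  )
  structure(
    list(
      pairs = pairs,
      max_residual = if (nrow(pairs)) max(abs(raw - rounded)) else 0,
      ok = !any(pairs$flagged)
    ),
    class = "topology_report"
  )
}

#' @export
print.topology_report <- function(x, ...) {
  cat(sprintf(
    "<topology_report> %d ring pairs, max residual %.2g, %s\n",
    nrow(x$pairs), x$max_residual,
    if (x$ok) "all unlinked" else sprintf("%d pair(s) FLAGGED", sum(x$pairs$flagged))
  ))
  invisible(x)
}

#' Build the system described by a configuration
#'
#' Convenience wrapper: [validate_config()] then [place_chains()].
#'
#' @param config raw config (path or list).
#' @param ... passed to [place_chains()].
#' @return A list with `state` and the resolved `config`.
#' @export
build_system <- function(config, ...) {
  cfg <- validate_config(config)
  state <- place_chains(cfg$topology, cfg$confinement, cfg$forcefield,
    seed = cfg$schedule$seed, ...
  )
  list(state = state, config = cfg)
}
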