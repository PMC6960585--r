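# Synthetic fixtures: idealised configurations and trajectories with known
# geometric or statistical structure, so each analysis stage can be tested
# against closed-form expectations instead of long simulations.  Every
# fixture is deterministic given its seed.  Fixtures deliberately ignore
# excluded volume unless stated; hopf_pair deliberately violates the
# unlinked-topology invariant (it exists to test the detector).

#' Perfect rigid ring
#'
#' A regular n-gon of the given bond length (circumradius
#' `b / (2 sin(pi/n))`) in the plane through `center` perpendicular to
#' `normal`. The default bond length is the nominal monomer diameter
#' (1 sigma), for which the N = 50 ring has gyration radius 7.963.
#'
#' @param n number of monomers (>= 3).
#' @param bond_length edge length of the polygon.
#' @param center 3-vector.
#' @param normal plane normal (normalised internally).
#' @param phase in-plane rotation angle (radians).
#' @return An `n x 3` coordinate matrix.
#' @export
perfect_rigid_ring <- function(n, bond_length = 1, center = c(0, 0, 0),
                               normal = c(0, 0, 1), phase = 0) {
  if (n < 3) abort("a ring needs at least 3 monomers")
  w <- normal / sqrt(sum(normal^2))
  a <- if (abs(w[1]) > 0.9) c(0, 1, 0) else c(1, 0, 0)
  u <- c(
    w[2] * a[3] - w[3] * a[2],
    w[3] * a[1] - w[1] * a[3],
    w[1] * a[2] - w[2] * a[1]
  )
  u <- u / sqrt(sum(u^2))
  v <- c(
    w[2] * u[3] - w[3] * u[2],
    w[3] * u[1] - w[1] * u[3],
    w[1] * u[2] - w[2] * u[1]
  )
  rc <- bond_length / (2 * sin(pi / n))
  ang <- phase + 2 * pi * (seq_len(n) - 1) / n
  t(vapply(
    ang, function(a) center + rc * cos(a) * u + rc * sin(a) * v,
    numeric(3)
  ))
}

# minimal one-species ring topology for fixture states
ring_ensemble_topology <- function(m, n, bending_k = 100, species = "long") {
  topology(tibble::tibble(
    kind = "ring", n_monomers = rep(n, m),
    bending_k = bending_k, species = species
  ))
}

#' Wall-attached ring shell
#'
#' `m` perfect rigid rings whose monomers all sit at radial distance
#' `reach`, with normals radial and azimuthal placement random: the
#' idealised fully segregated configuration. Every chain COM then sits at
#' `sqrt(reach^2 - Rc^2)` — 17.25 for N = 50 rings at reach 19.
#'
#' @param m number of rings.
#' @param n monomers per ring.
#' @param reach radial distance of every monomer (must exceed the ring
#'   circumradius).
#' @param seed integer seed for the random directions.
#' @param bond_length polygon edge.
#' @param sphere_radius cavity radius of the returned state (default
#'   `reach + 1`, the wall-exclusion geometry).
#' @return A [system_state()] with orientation order exactly 1.
#' @export
wall_attached_ensemble <- function(m, n, reach, seed = 1L, bond_length = 1,
                                   sphere_radius = reach + 1) {
  rc <- bond_length / (2 * sin(pi / n))
  if (rc >= reach) {
    abort(sprintf(
      "infeasible geometry: circumradius %.3f >= reach %.3f", rc, reach
    ))
  }
  com_dist <- sqrt(reach^2 - rc^2)
  pos <- withr::with_seed(as.integer(seed), {
    do.call(rbind, lapply(seq_len(m), function(i) {
      w <- rnorm(3)
      w <- w / sqrt(sum(w^2))
      perfect_rigid_ring(n, bond_length,
        center = com_dist * w, normal = w,
        phase = stats::runif(1, 0, 2 * pi)
      )
    }))
  })
  system_state(pos, NULL, ring_ensemble_topology(m, n),
    confinement_sphere(sphere_radius)
  )
}

#' Isotropic ring ensemble
#'
#' `m` rigid rings with centres uniform in the sphere (kept a circumradius
#' plus one sigma clear of the wall) and isotropic normals: the null model
#' with orientation order 0. Excluded volume between rings is deliberately
#' ignored — this is a statistical fixture, not a physical state.
#'
#' @param m,n ring count and length.
#' @param sphere_radius cavity radius.
#' @param seed integer seed.
#' @param bond_length polygon edge.
#' @return A [system_state()].
#' @export
isotropic_ring_ensemble <- function(m, n, sphere_radius = 20, seed = 1L,
                                    bond_length = 1) {
  rc <- bond_length / (2 * sin(pi / n))
  rmax <- sphere_radius - 1 - rc
  if (rmax <= 0) abort("sphere too small for rings of this circumradius")
  pos <- withr::with_seed(as.integer(seed), {
    do.call(rbind, lapply(seq_len(m), function(i) {
      repeat {
        c0 <- stats::runif(3, -rmax, rmax)
        if (sum(c0^2) <= rmax^2) break
      }
      w <- rnorm(3)
      w <- w / sqrt(sum(w^2))
      perfect_rigid_ring(n, bond_length,
        center = c0, normal = w,
        phase = stats::runif(1, 0, 2 * pi)
      )
    }))
  })
  system_state(pos, NULL, ring_ensemble_topology(m, n),
    confinement_sphere(sphere_radius)
  )
}

#' Hopf-linked ring pair
#'
#' A unit circle in the xy-plane at the origin and a unit circle in the
#' xz-plane centred at (1, 0, 0): linking number +-1. The canonical positive
#' control for the topology detector (it fails [verify_topology()] by
#' design).
#'
#' @param n_segments vertices per circle.
#' @return A list of two `n x 3` matrices.
#' @export
hopf_pair <- function(n_segments = 100) {
  t <- 2 * pi * (seq_len(n_segments) - 1) / n_segments
  a <- cbind(cos(t), sin(t), 0)
  b <- cbind(1 + cos(t), 0, sin(t))
  list(a, b)
}

#' Boltzmann sampler of a radial potential
#'
#' Rejection-samples points in a sphere from the density proportional to
#' `exp(-U(r)) * 4 pi r^2`: the exact equilibrium distribution whose PMF is
#' `U(r)` up to a constant. The round trip through [pmf()] must therefore
#' recover `U` — the oracle for the free-energy machinery.
#'
#' @param potential a function `U(r)` in k_B T (may return `Inf` for hard
#'   exclusions), or a data frame with columns `r`, `u` interpolated
#'   linearly.
#' @param sphere_radius sampling range.
#' @param n_samples number of points.
#' @param seed integer seed.
#' @return An `n_samples x 3` matrix with attribute `radius`.
#' @export
boltzmann_radial_sampler <- function(potential, sphere_radius, n_samples,
                                     seed = 1L) {
  ufun <- if (is.function(potential)) {
    potential
  } else {
    tab <- tibble::as_tibble(potential)
    if (!all(c("r", "u") %in% names(tab))) {
      abort("tabulated potential needs columns 'r' and 'u'")
    }
    function(r) stats::approx(tab$r, tab$u, xout = r, rule = 2)$y
  }
  grid <- seq(1e-6, sphere_radius, length.out = 4096)
  fmax <- max(exp(-ufun(grid)) * grid^2, na.rm = TRUE)
  if (!is.finite(fmax) || fmax <= 0) abort("potential admits no samples")
  withr::with_seed(as.integer(seed), {
    out <- matrix(NA_real_, n_samples, 3)
    got <- 0L
    while (got < n_samples) {
      m <- max(1024L, 2L * (n_samples - got))
      r <- stats::runif(m, 0, sphere_radius)
      keep <- stats::runif(m, 0, fmax) < exp(-ufun(r)) * r^2
      r <- r[keep]
      if (!length(r)) next
      take <- seq_len(min(length(r), n_samples - got))
      r <- r[take]
      z <- stats::runif(length(r), -1, 1)
      phi <- stats::runif(length(r), 0, 2 * pi)
      s <- sqrt(1 - z^2)
      out[got + seq_along(r), ] <- cbind(
        r * s * cos(phi), r * s * sin(phi), r * z
      )
      got <- got + length(r)
    }
    attr(out, "radius") <- sphere_radius
    out
  })
}

#' Tangentially sliding ring trajectory
#'
#' A rigid wall-attached ring whose centre of mass moves on its sphere of
#' constant radius at constant angular speed, the normal locked radial: pure
#' tangential kinematics, so the velocity decomposition must give
#' `V_par -> 0` and a diverging ratio. Zero angular speed gives
#' `V_perp = V_par = 0`.
#'
#' @param n_frames number of frames.
#' @param delta_t frame spacing in tau0.
#' @param sphere_radius cavity radius.
#' @param n monomers per ring.
#' @param reach monomer radial distance (default `sphere_radius - 1`).
#' @param angular_speed COM angular speed in rad/tau0.
#' @param bond_length polygon edge.
#' @return A single-ring [trajectory()].
#' @export
tangential_slide_trajectory <- function(n_frames, delta_t, sphere_radius,
                                        n = 50, reach = sphere_radius - 1,
                                        angular_speed = 0.005,
                                        bond_length = 1) {
  rc <- bond_length / (2 * sin(pi / n))
  if (rc >= reach) abort("ring circumradius exceeds the requested reach")
  com_dist <- sqrt(reach^2 - rc^2)
  top <- ring_ensemble_topology(1, n)
  frames <- lapply(seq_len(n_frames) - 1, function(k) {
    ang <- angular_speed * k * delta_t
    w <- c(cos(ang), sin(ang), 0)
    perfect_rigid_ring(n, bond_length, center = com_dist * w, normal = w)
  })
  trajectory_from_frames(
    frames,
    times = (seq_len(n_frames) - 1) * delta_t,
    topology = top,
    confinement = confinement_sphere(sphere_radius)
  )
}
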