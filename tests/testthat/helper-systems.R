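# Shared miniature systems for the unit tests.

ff_default <- forcefield_params()

# a single rigid ring state far from the wall
single_ring_state <- function(n = 50, kb = 50, bond = 1, radius = 20) {
  top <- topology(tibble::tibble(
    kind = "ring", n_monomers = n, bending_k = kb, species = "long"
  ))
  system_state(perfect_rigid_ring(n, bond), NULL, top,
    confinement_sphere(radius)
  )
}

# two small rings placed in a small sphere, relaxed
two_ring_state <- function(seed = 3, radius = 6) {
  top <- binary_mixture_topology(1, 12, 50, 1, 6, 20)
  place_chains(top, confinement_sphere(radius), ff_default,
    seed = seed, pushoff_steps = 200
  )
}

# thermalised velocities for a state (deterministic)
with_mb_velocities <- function(state, tstar = 1, seed = 11) {
  n <- nrow(state$positions)
  state$velocities <- withr::with_seed(seed, matrix(rnorm(3 * n, sd = sqrt(tstar)), n, 3))
  state$velocities <- sweep(state$velocities, 2, colMeans(state$velocities))
  state
}

# rings whose normals are tangential to the radius vector (P2 = -0.5 fixture)
tangential_ring_ensemble <- function(m, n = 10, r0 = 10, radius = 20, seed = 5) {
  pos <- withr::with_seed(seed, {
    do.call(rbind, lapply(seq_len(m), function(i) {
      w <- rnorm(3)
      w <- w / sqrt(sum(w^2))
      a <- rnorm(3)
      u <- a - sum(a * w) * w
      u <- u / sqrt(sum(u^2))
      perfect_rigid_ring(n, 1, center = r0 * w, normal = u)
    }))
  })
  top <- topology(tibble::tibble(
    kind = "ring", n_monomers = rep(n, m), bending_k = 100, species = "long"
  ))
  system_state(pos, NULL, top, confinement_sphere(radius))
}

# uniform point cloud in a ball wrapped as a single-chain state
uniform_ball_state <- function(n_pts, radius, seed = 1) {
  pts <- boltzmann_radial_sampler(function(r) rep(0, length(r)), radius,
    n_pts,
    seed = seed
  )
  top <- topology(tibble::tibble(
    kind = "linear", n_monomers = n_pts, bending_k = 0, species = "long"
  ))
  system_state(pts, NULL, top, confinement_sphere(radius))
}

total_e <- function(state, ff = ff_default) {
  total_energy(state, ff)$total + 0.5 * sum(state$velocities^2)
}
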