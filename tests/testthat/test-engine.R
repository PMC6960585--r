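test_that("kinetic temperature follows its quadratic definition", {
  st <- single_ring_state(10, 0)
  st$velocities <- matrix(0, 10, 3)
  expect_equal(instantaneous_temperature(st), 0)
  st2 <- with_mb_velocities(st, tstar = 1, seed = 2)
  st3 <- st2
  st3$velocities <- 2 * st2$velocities
  expect_equal(
    instantaneous_temperature(st3),
    4 * instantaneous_temperature(st2)
  )
  # large Maxwell-Boltzmann sample concentrates at the target
  big <- system_state(
    matrix(withr::with_seed(1, runif(3e4, -5, 5)), 1e4, 3), NULL,
    topology(tibble::tibble(
      kind = "linear", n_monomers = 1e4, bending_k = 0, species = "long"
    )),
    confinement_sphere(10)
  )
  big <- with_mb_velocities(big, tstar = 1, seed = 3)
  expect_equal(instantaneous_temperature(big), 1, tolerance = 0.02)
})

test_that("a free particle moves ballistically under NVE", {
  top <- topology(tibble::tibble(
    kind = "linear", n_monomers = 2, bending_k = 0, species = "long"
  ))
  # bond at the exact FENE+WCA minimum: zero force, both monomers drift
  fnet <- function(r) {
    -30 * r / (1 - (r / 1.5)^2) + 24 * (2 / r^13 - 1 / r^7)
  }
  req <- uniroot(fnet, c(0.9, 1.1), tol = 1e-14)$root
  st <- system_state(rbind(c(0, 0, 0), c(req, 0, 0)),
    rbind(c(0.3, 0.1, 0), c(0.3, 0.1, 0)),
    top, confinement_sphere(50)
  )
  st2 <- md_step(st, ff_default, dt = 0.006, thermostat = "off")
  expect_lt(max(abs(st2$positions[1, ] - c(0.3, 0.1, 0) * 0.006)), 1e-8)
  expect_equal(st2$time, 0.006)
})

test_that("NVE conserves energy and periodic momentum", {
  st <- single_ring_state(50, 50, bond = 0.97)
  st <- with_mb_velocities(st, tstar = 1, seed = 7)
  st <- md_step(st, ff_default, 0.006, "off", n_steps = 2000) # settle transient
  e0 <- total_e(st)
  st2 <- md_step(st, ff_default, 0.006, "off", n_steps = 1e4)
  expect_lt(abs(total_e(st2) - e0) / abs(e0), 1e-4)
  # periodic bulk: total momentum conserved to accumulation error
  top <- binary_mixture_topology(1, 10, 50, 4, 5, 50)
  stb <- place_chains(top, confinement_box(6), ff_default, seed = 4)
  p0 <- colSums(stb$velocities)
  stb2 <- md_step(stb, ff_default, 0.006, "off", n_steps = 5000)
  expect_equal(colSums(stb2$velocities), p0, tolerance = 1e-9)
})

test_that("the Nose-Hoover thermostat recovers the target temperature", {
  st <- two_ring_state(seed = 13)
  al <- ringmix:::angle_list(st$topology)
  res <- ringmix:::run_md_cpp(
    st$positions, st$velocities,
    ringmix:::bond_list(st$topology) - 1L, al$triplets - 1L, al$k,
    unclass(ff_default), ringmix:::conf_cpp(st$confinement),
    dt = 0.006, nsteps = 1e5, sample_every = 0L,
    thermostat = TRUE, tstar = 1, q = ringmix:::nh_mass(18, 1, 0.006),
    xi0 = 0, temp_every = 10L
  )
  expect_equal(mean(res$temperature), 1, tolerance = 0.02)
  # equipartition: per-component velocity variance ~ T within 3 SE
  v <- res$velocities
  expect_equal(mean(v^2), 1, tolerance = 0.3)
})

test_that("run_md samples frames, embeds metadata and preserves topology", {
  st <- two_ring_state(seed = 3)
  sch <- run_schedule(
    timestep = 0.006, equilibration_time = 6, production_time = 60,
    sample_interval = 1000, seed = 3
  )
  traj <- run_md(st, ff_default, sch)
  expect_equal(n_frames(traj), 10)
  expect_equal(traj$sampling_interval, 6, tolerance = 1e-9)
  expect_true(traj$metadata$topology_check$ok)
  expect_equal(traj$metadata$seed, 3L)
  for (i in c(1, n_frames(traj))) {
    expect_silent(check_state(frame_state(traj, i)))
  }
  # determinism: same initial state, same schedule -> identical frames
  traj2 <- run_md(st, ff_default, sch)
  expect_identical(traj$positions, traj2$positions)
})

test_that("zero-duration production yields an empty but valid trajectory", {
  st <- two_ring_state(seed = 3)
  sch <- run_schedule(production_time = 0, seed = 1)
  traj <- run_md(st, ff_default, sch)
  expect_equal(n_frames(traj), 0)
  expect_true(traj$metadata$topology_check$ok)
  expect_s3_class(traj, "trajectory")
})

test_that("bulk periodic runs carry no wall energy", {
  top <- binary_mixture_topology(1, 10, 50, 4, 5, 50)
  st <- place_chains(top, confinement_box(6), ff_default, seed = 4)
  sch <- run_schedule(
    timestep = 0.006, production_time = 30, sample_interval = 500, seed = 4
  )
  traj <- run_md(st, ff_default, sch)
  expect_gt(n_frames(traj), 0)
  expect_true(all(traj$metadata$energy_samples[, "wall"] == 0))
})

test_that("annealing ladder runs and lands at the target ensemble", {
  st <- two_ring_state(seed = 5)
  sch <- run_schedule(
    timestep = 0.006,
    anneal = tibble::tibble(tstar = c(2, 1.5), duration = c(12, 12)),
    equilibration_time = 12, production_time = 30, sample_interval = 500,
    seed = 5
  )
  traj <- run_md(st, ff_default, sch)
  expect_gt(n_frames(traj), 0)
  expect_equal(traj$metadata$mean_temperature, 1, tolerance = 0.15)
})

test_that("equilibration check detects a plateau", {
  # synthetic trajectory: monomer radii constant after an initial drift
  st <- single_ring_state(10, 0, radius = 20)
  nf <- 40
  frames <- lapply(seq_len(nf), function(i) {
    shift <- if (i < 10) (10 - i) * 0.3 else 0
    sweep(st$positions, 2, c(shift, 0, 0), "+")
  })
  traj <- ringmix:::trajectory_from_frames(
    frames, seq_len(nf), st$topology, st$confinement
  )
  chk <- check_equilibration(traj, "long")
  expect_true(chk$equilibrated)
})
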