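test_that("default configuration resolves to the reference composition", {
  cfg <- validate_config(default_config())
  expect_equal(cfg$system$m_short, 1290L) # floor((0.4 V - 500)/10), V = (4/3) pi 20^3
  expect_equal(nrow(cfg$topology), 10 + 1290)
  expect_equal(sum(cfg$topology$n_monomers), 500 + 12900)
  expect_lte(cfg$system$rho_achieved, 0.4)
  expect_equal(cfg$forcefield$fene_k, 30)
  expect_equal(cfg$schedule$timestep, 0.006)
})

test_that("config validation rejects bad parameters and warns above rho 0.6", {
  expect_error(
    validate_config(list(system = list(
      rho = 0.4, m_long = 10, n_long = 50, n_short = 10
    ), forcefield = list(fene_r0 = 0.5))),
    "fene_r0"
  )
  expect_error(validate_config(list(system = list(rho = -1))), "positive")
  expect_error(validate_config(list(system = list(rho = 0.4))), "missing")
  expect_warning(
    validate_config(default_config(rho = 0.7)),
    "0.6"
  )
})

test_that("config round-trips through serialize -> validate to identity", {
  raw <- default_config(rho = 0.3, kb_long = 25, seed = 42L)
  raw$schedule <- list(
    timestep = 0.005, equilibration_time = 10, production_time = 20,
    sample_interval = 100, seed = 42L,
    anneal = list(tstar = c(2, 1), duration = c(5, 5))
  )
  cfg1 <- validate_config(raw)
  cfg2 <- validate_config(serialize_config(cfg1))
  expect_equal(cfg2$topology, cfg1$topology)
  expect_equal(unclass(cfg2$forcefield), unclass(cfg1$forcefield))
  expect_equal(cfg2$schedule, cfg1$schedule)
  expect_equal(cfg2$system, cfg1$system)
  # and through a YAML file
  f <- withr::local_tempfile(fileext = ".yaml")
  serialize_config(cfg1, f)
  cfg3 <- validate_config(f)
  expect_equal(cfg3$system, cfg1$system)
})

test_that("topology validates chain kinds, lengths and species", {
  expect_error(topology(tibble::tibble(
    kind = "ring", n_monomers = 2, bending_k = 0, species = "long"
  )), "at least 3")
  expect_error(topology(tibble::tibble(
    kind = "circle", n_monomers = 5, bending_k = 0, species = "long"
  )), "ring")
  top <- binary_mixture_topology(2, 20, 50, 3, 5, kb_short = 50)
  expect_equal(nrow(top), 5)
  expect_equal(bond_lengths_count <- nrow(ringmix:::bond_list(top)), 2 * 20 + 3 * 5)
  al <- ringmix:::angle_list(top)
  expect_equal(nrow(al$triplets), 2 * 20 + 3 * 5) # rings: one angle per monomer
  lin <- binary_mixture_topology(1, 10, 0, 1, 5, long_kind = "linear")
  expect_equal(nrow(ringmix:::bond_list(lin)), 9 + 5)
  expect_equal(nrow(ringmix:::angle_list(lin)$triplets), 8 + 5)
})

test_that("state invariants catch overstretched bonds and escaped monomers", {
  st <- single_ring_state(10, 0, bond = 1, radius = 20)
  expect_silent(check_state(st))
  bad <- st
  bad$positions[1, ] <- bad$positions[1, ] * 3.5 # stretches its two bonds
  expect_error(check_state(bad), "bond")
  out <- st
  out$positions <- sweep(out$positions, 2, c(19.5, 0, 0), "+") # whole ring out
  expect_error(check_state(out), "accessible")
})

test_that("trajectory enforces uniform frame spacing and exposes frames", {
  st <- single_ring_state(5, 0)
  pos <- array(st$positions, dim = c(5, 3, 3))
  expect_error(
    trajectory(pos, c(0, 1, 3), st$topology, st$confinement),
    "constant spacing"
  )
  tr <- trajectory(pos, c(0, 1, 2), st$topology, st$confinement)
  expect_equal(n_frames(tr), 3)
  expect_equal(tr$sampling_interval, 1)
  f2 <- frame_state(tr, 2)
  expect_equal(f2$positions, st$positions)
  expect_equal(f2$time, 1)
})

test_that("count_short_chains follows the density bookkeeping", {
  sph <- confinement_sphere(20)
  expect_equal(count_short_chains(0.4, sph, 10, 50, 10), 1290L)
  expect_equal(count_short_chains(0.1, sph, 10, 50, 10), 285L)
  # rho V exactly equal to the long-monomer budget leaves no room
  rho0 <- 500 / confinement_volume(sph)
  expect_error(count_short_chains(rho0, sph, 10, 50, 10), "infeasible")
  expect_error(count_short_chains(0, sph, 10, 50, 10), "positive")
})
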