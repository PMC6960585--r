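test_that("linking number is 0 for separated rings and +-1 for a Hopf link", {
  t <- 2 * pi * (0:99) / 100
  c1 <- cbind(cos(t), sin(t), 0)
  c2 <- cbind(cos(t), sin(t), 5) # parallel plane, 5 sigma away
  expect_lt(abs(linking_number(c1, c2)), 0.05)
  h <- hopf_pair(100)
  expect_equal(abs(linking_number(h[[1]], h[[2]])), 1, tolerance = 1e-9)
  expect_error(linking_number(c1, c1), "itself")
  degen <- rbind(c(0, 0, 0), c(0, 0, 0), c(1, 0, 0))
  expect_error(linking_number(degen, c2), "degenerate")
})

test_that("linking number is invariant under rigid motion and refinement", {
  h <- hopf_pair(100)
  lk0 <- linking_number(h[[1]], h[[2]])
  # rigid rotation + translation of both rings together
  th <- 0.7
  rot <- rbind(
    c(cos(th), -sin(th), 0), c(sin(th), cos(th), 0), c(0, 0, 1)
  )
  move <- function(m) sweep(m %*% t(rot), 2, c(3, -2, 7), "+")
  expect_equal(linking_number(move(h[[1]]), move(h[[2]])), lk0, tolerance = 1e-9)
  # refinement at 2x and 4x segment counts
  for (nseg in c(200, 400)) {
    hf <- hopf_pair(nseg)
    expect_equal(linking_number(hf[[1]], hf[[2]]), lk0, tolerance = 1e-9)
  }
})

test_that("builder output is deterministic and satisfies all invariants", {
  st1 <- two_ring_state(seed = 3)
  st2 <- two_ring_state(seed = 3)
  expect_identical(st1$positions, st2$positions)
  expect_identical(st1$velocities, st2$velocities)
  st3 <- two_ring_state(seed = 4)
  expect_false(isTRUE(all.equal(st1$positions, st3$positions)))
  expect_silent(check_state(st1))
  expect_equal(nrow(st1$positions), 12 + 6)
  expect_true(all(sqrt(rowSums(st1$positions^2)) <= 6 - 1 + 0.1))
  rep <- verify_topology(st1)
  expect_true(rep$ok)
  expect_equal(rep$pairs$lk, 0L)
})

test_that("planar polygon initialisation carries no intra-ring WCA overlap", {
  # bond length >= 0.9 sigma: adjacent pairs are inside the WCA cutoff but
  # below ~1 kBT; non-adjacent polygon vertices sit beyond the cutoff
  st <- single_ring_state(12, 0, bond = 0.97, radius = 20)
  e <- total_energy(st, ff_default)
  expect_lt(e$pair, 12 * wca_energy(0.97, ff_default) + 1e-9)
  nonadj <- as.matrix(dist(st$positions))
  nonadj <- nonadj[abs(row(nonadj) - col(nonadj)) %in% 2:10]
  expect_true(all(nonadj > ff_default$lj_cutoff))
})

test_that("builder handles the full reference composition", {
  cfg <- validate_config(default_config(kb_long = 50))
  st <- place_chains(cfg$topology, cfg$confinement, cfg$forcefield, seed = 1)
  expect_silent(check_state(st))
  expect_equal(nrow(st$positions), 13400)
  rep <- verify_topology(st)
  expect_true(rep$ok)
  # Maxwell-Boltzmann start: near T* = 1 (the push-off settle leaves mild
  # excess heat that the run equilibration removes)
  expect_equal(instantaneous_temperature(st), 1, tolerance = 0.2)
  # the velocities themselves are exact Maxwell-Boltzmann draws
  raw <- place_chains(cfg$topology, cfg$confinement, cfg$forcefield,
    seed = 1, pushoff_steps = 0
  )
  expect_equal(instantaneous_temperature(raw), 1, tolerance = 0.02)
  expect_equal(colSums(raw$velocities), c(0, 0, 0), tolerance = 1e-9)
})

test_that("infeasible densities fail with an explicit placement error", {
  top <- binary_mixture_topology(2, 20, 0, 300, 10, 0)
  expect_error(
    place_chains(top, confinement_sphere(4), ff_default, seed = 1),
    "infeasible|placement failed"
  )
})

test_that("verify_topology flags an injected Hopf pair and skips single rings", {
  h <- hopf_pair(60)
  top <- topology(tibble::tibble(
    kind = "ring", n_monomers = c(60, 60), bending_k = 0, species = "long"
  ))
  st <- system_state(rbind(h[[1]], h[[2]]), NULL, top, confinement_sphere(10))
  rep <- verify_topology(st)
  expect_false(rep$ok)
  expect_equal(abs(rep$pairs$lk), 1L)
  one <- single_ring_state(10, 0)
  rep1 <- verify_topology(one)
  expect_true(rep1$ok)
  expect_equal(nrow(rep1$pairs), 0)
})

test_that("linear chains are placed as rods and bonded correctly", {
  top <- binary_mixture_topology(2, 10, 50, 2, 5, long_kind = "linear")
  st <- place_chains(top, confinement_sphere(8), ff_default,
    seed = 2, pushoff_steps = 0
  )
  bl <- ringmix:::bond_lengths(st)
  expect_equal(bl, rep(0.97, length(bl)), tolerance = 1e-10)
  # rod: first chain end-to-end distance = 9 bonds
  ee <- sqrt(sum((st$positions[10, ] - st$positions[1, ])^2))
  expect_equal(ee, 9 * 0.97, tolerance = 1e-10)
})
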