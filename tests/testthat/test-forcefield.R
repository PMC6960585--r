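test_that("potential terms reproduce hand-evaluated values", {
  ff <- ff_default
  expect_equal(fene_energy(0, ff), 0)
  expect_equal(fene_energy(0.97, ff), 18.28, tolerance = 0.01 / 18.28)
  expect_error(fene_energy(1.5, ff), "overstretch")
  expect_equal(wca_energy(2^(1 / 6), ff), 0)
  expect_equal(wca_energy(1, ff), 1)
  expect_equal(wca_energy(2, ff), 0)
  expect_error(wca_energy(0, ff), "singular")
  expect_equal(bending_energy(pi, 75), 0)
  expect_equal(bending_energy(pi / 2, 50), 50)
  # rigid 50-ring at kb = 50: 50 * 50 * (1 - cos(2 pi / 50))
  st <- single_ring_state(50, 50)
  expect_equal(total_energy(st, ff)$bending, 19.71, tolerance = 0.01 / 19.71)
})

test_that("smooth wall excludes monomers beyond R - sigma", {
  ff <- ff_default
  conf <- confinement_sphere(20)
  expect_equal(wall_energy(c(20 - 2^(1 / 6), 0, 0), conf, ff), 0)
  expect_equal(wall_energy(c(19, 0, 0), conf, ff), 1) # gap = sigma
  expect_equal(wall_energy(c(10, 0, 0), conf, ff), 0)
  expect_gt(wall_energy(c(19.5, 0, 0), conf, ff), 100)
  expect_error(wall_energy(c(20.5, 0, 0), conf, ff), "escaped")
})

test_that("particulate wall approximates the smooth wall near contact", {
  ff <- ff_default
  conf <- confinement_sphere(8, wall_style = "particulate")
  st <- single_ring_state(10, 0, radius = 8)
  st$confinement <- conf
  e <- total_energy(st, ff)
  expect_equal(e$wall, 0) # ring far from wall
  # a monomer one sigma off the shell feels kBT-scale repulsion
  expect_gt(wall_energy(c(7, 0, 0), conf, ff), 0.05)
  expect_lt(wall_energy(c(7, 0, 0), conf, ff), 20)
  expect_equal(wall_energy(c(3, 0, 0), conf, ff), 0)
  # whole ring translated near the shell: positive finite wall term
  st$positions <- sweep(st$positions, 2, c(0, 0, 6.9), "+")
  e2 <- total_energy(st, ff)
  expect_gt(e2$wall, 0)
  expect_true(is.finite(e2$wall))
})

test_that("energy breakdown composes and totals exactly", {
  ff <- ff_default
  # straight trimer at bond length 2^(1/6): pure FENE, no pair, no bending
  top <- topology(tibble::tibble(
    kind = "linear", n_monomers = 3, bending_k = 30, species = "long"
  ))
  b <- 2^(1 / 6)
  st <- system_state(
    rbind(c(0, 0, 0), c(b, 0, 0), c(2 * b, 0, 0)), NULL,
    top, confinement_sphere(20)
  )
  e <- total_energy(st, ff)
  expect_equal(e$fene, 2 * fene_energy(b, ff))
  expect_equal(e$pair, 0)
  expect_equal(e$bending, 0)
  expect_equal(e$total, e$fene + e$pair + e$bending + e$wall)
  # bonded dimer gets FENE plus WCA
  top2 <- topology(tibble::tibble(
    kind = "linear", n_monomers = 2, bending_k = 0, species = "long"
  ))
  st2 <- system_state(rbind(c(0, 0, 0), c(0.97, 0, 0)), NULL, top2,
    confinement_sphere(20)
  )
  e2 <- total_energy(st2, ff)
  expect_equal(e2$total, fene_energy(0.97, ff) + wca_energy(0.97, ff))
})

test_that("analytic forces match central-difference gradients to 1e-6", {
  ff <- ff_default
  st <- two_ring_state(seed = 5)
  f <- forces(st, ff)
  h <- 1e-6
  idx <- withr::with_seed(1, sample(nrow(st$positions), 8))
  for (i in idx) {
    for (k in 1:3) {
      sp <- st
      sp$positions[i, k] <- sp$positions[i, k] + h
      sm <- st
      sm$positions[i, k] <- sm$positions[i, k] - h
      num <- -(total_energy(sp, ff)$total - total_energy(sm, ff)$total) / (2 * h)
      expect_equal(f[i, k], num, tolerance = 1e-6)
    }
  }
})

test_that("pair forces vanish at the WCA minimum and for straight trimers", {
  ff <- ff_default
  # two parallel vertical dimers: the inter-chain 1-3 pair sits exactly at
  # the WCA minimum (the cutoff), so it exerts no horizontal force
  top2 <- topology(tibble::tibble(
    kind = "linear", n_monomers = c(2, 2), bending_k = 0, species = "long"
  ))
  b <- 2^(1 / 6)
  st <- system_state(
    rbind(c(0, 0, 0), c(0, 0, 1.1), c(b, 0, 0), c(b, 0, 1.1)), NULL,
    top2, confinement_sphere(20)
  )
  f <- forces(st, ff)
  expect_equal(f[1, 1], 0, tolerance = 1e-12)
  # straight trimer: zero bending force on every monomer
  top3 <- topology(tibble::tibble(
    kind = "linear", n_monomers = 3, bending_k = 80, species = "long"
  ))
  st3 <- system_state(
    rbind(c(0, 0, 0), c(1.2, 0, 0), c(2.4, 0, 0)), NULL, top3,
    confinement_sphere(20)
  )
  f3 <- forces(st3, ff_default)
  expect_equal(f3[, 2:3], matrix(0, 3, 2), tolerance = 1e-12)
})

test_that("cell-list pair evaluation equals brute force", {
  st <- two_ring_state(seed = 7) # 18 monomers
  expect_equal(forces(st, ff_default, use_cells = TRUE),
    forces(st, ff_default, use_cells = FALSE),
    tolerance = 1e-12
  )
  top <- binary_mixture_topology(2, 20, 50, 30, 5, 50) # 190 monomers
  st2 <- place_chains(top, confinement_sphere(6), ff_default,
    seed = 2, pushoff_steps = 100
  )
  expect_equal(forces(st2, ff_default, use_cells = TRUE),
    forces(st2, ff_default, use_cells = FALSE),
    tolerance = 1e-12
  )
  e1 <- total_energy(st2, ff_default, use_cells = TRUE)
  e2 <- total_energy(st2, ff_default, use_cells = FALSE)
  expect_equal(e1$total, e2$total, tolerance = 1e-12)
})

test_that("forces obey Newton's third law", {
  # periodic box: no wall, total force must vanish
  top <- binary_mixture_topology(2, 10, 50, 4, 5, 50)
  st <- place_chains(top, confinement_box(6), ff_default,
    seed = 9, pushoff_steps = 100
  )
  f <- forces(st, ff_default)
  expect_equal(colSums(f), c(0, 0, 0), tolerance = 1e-10)
})

test_that("energies are invariant under global rotation about the centre", {
  st <- two_ring_state(seed = 11)
  e0 <- total_energy(st, ff_default)
  th <- 1.1
  rot <- rbind(
    c(cos(th), -sin(th), 0), c(sin(th), cos(th), 0), c(0, 0, 1)
  )
  st2 <- st
  st2$positions <- st$positions %*% t(rot)
  e1 <- total_energy(st2, ff_default)
  expect_equal(e1$total, e0$total, tolerance = 1e-9)
  expect_equal(e1$wall, e0$wall, tolerance = 1e-9)
})
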