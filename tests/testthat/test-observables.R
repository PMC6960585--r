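test_that("ring normal follows orientation and tolerates puckering", {
  ring <- perfect_rigid_ring(50, 1, normal = c(0, 0, 1))
  expect_equal(ring_normal(ring), c(0, 0, 1), tolerance = 1e-12)
  expect_equal(ring_normal(ring[50:1, ]), c(0, 0, -1), tolerance = 1e-12)
  puck <- ring
  puck[, 3] <- puck[, 3] + withr::with_seed(2, rnorm(50, sd = 0.01))
  ang <- acos(min(1, sum(ring_normal(puck) * c(0, 0, 1))))
  expect_lt(ang, 1 * pi / 180)
  collinear <- cbind(seq_len(4), 0, 0)
  expect_error(ring_normal(collinear), "degenerate")
})

test_that("gyration radius matches closed-form polygon geometry", {
  circ <- cbind(5 * cos(2 * pi * (1:50) / 50), 5 * sin(2 * pi * (1:50) / 50), 0)
  expect_equal(gyration_radius(circ), 5, tolerance = 1e-12)
  expect_equal(gyration_radius(perfect_rigid_ring(50, 1)),
    1 / (2 * sin(pi / 50)),
    tolerance = 1e-12
  )
  expect_equal(gyration_radius(matrix(c(1, 2, 3), 1, 3)), 0)
})

test_that("orientation order hits its exact bounds on the three fixtures", {
  wa <- wall_attached_ensemble(10, 50, 19, seed = 2)
  expect_equal(orientation_order(wa), 1.0, tolerance = 1e-10)
  tang <- tangential_ring_ensemble(50, 10, r0 = 10)
  expect_equal(orientation_order(tang), -0.5, tolerance = 1e-10)
  iso <- isotropic_ring_ensemble(10000, 10, 20, seed = 3)
  expect_equal(orientation_order(iso), 0, tolerance = 0.015)
})

test_that("orientation order stays within the quadratic-form bounds", {
  for (seed in 1:5) {
    iso <- isotropic_ring_ensemble(50, 8, 15, seed = seed)
    p2 <- orientation_order(iso)
    expect_gte(p2, -0.5)
    expect_lte(p2, 1)
  }
})

test_that("density profile is flat for uniform samples and localises shells", {
  st <- uniform_ball_state(2e6, 10, seed = 4)
  prof <- radial_density_profile(st, "all", bin_width = 1)
  inner <- prof$r_lo < 2
  expect_equal(prof$value[!inner], rep(1, sum(!inner)), tolerance = 0.02)
  expect_equal(prof$value[inner], rep(1, sum(inner)), tolerance = 0.1)
  # conservation: counts integrate back to the sample size
  expect_equal(sum(prof$count), 2e6)
  rho_sp <- 2e6 / confinement_volume(st$confinement)
  expect_equal(
    sum(prof$density * 4 / 3 * pi * (prof$r_hi^3 - prof$r_lo^3)), 2e6,
    tolerance = 1e-9
  )
  expect_equal(rho_sp * sum(prof$value * 4 / 3 * pi * (prof$r_hi^3 - prof$r_lo^3)),
    2e6,
    tolerance = 1e-9
  )
  # localisation: everything in shell [18, 19] of an R = 20 sphere
  wa <- wall_attached_ensemble(20, 10, 18.5, seed = 1)
  pw <- radial_density_profile(wa, "long", bin_width = 1)
  expect_true(all(pw$count[pw$r_lo != 18] == 0))
  expect_gt(pw$value[pw$r_lo == 18], 1)
})

test_that("wall-attached rings put the density maximum in the outermost bin", {
  wa <- wall_attached_ensemble(30, 50, 18.9, seed = 6)
  prof <- radial_density_profile(wa, "long", bin_width = 0.25)
  populated <- which(prof$count > 0)
  expect_equal(which.max(prof$value), max(populated))
})

test_that("mean radial distance matches geometry and the uniform-ball moment", {
  wa <- wall_attached_ensemble(12, 50, 18.5, seed = 3)
  expect_equal(mean_radial_distance(wa, "long", "monomer"), 18.5,
    tolerance = 1e-9
  )
  rc_exp <- sqrt(19^2 - (1 / (2 * sin(pi / 50)))^2)
  wa19 <- wall_attached_ensemble(12, 50, 19, seed = 3)
  expect_equal(mean_radial_distance(wa19, "long", "chain_com"), rc_exp,
    tolerance = 1e-9
  )
  st <- uniform_ball_state(5e5, 8, seed = 5)
  expect_equal(mean_radial_distance(st, "all", "monomer"), 0.75 * 8,
    tolerance = 0.01
  )
})

test_that("velocity decomposition resolves normal and oblique displacements", {
  # two frames: ring displaced exactly along its own normal
  ring0 <- perfect_rigid_ring(10, 1, center = c(5, 0, 0), normal = c(1, 0, 0))
  ring1 <- sweep(ring0, 2, c(0.5, 0, 0), "+")
  top <- topology(tibble::tibble(
    kind = "ring", n_monomers = 10, bending_k = 100, species = "long"
  ))
  tr <- ringmix:::trajectory_from_frames(
    list(ring0, ring1), c(0, 10), top, confinement_sphere(20)
  )
  vd <- velocity_decomposition(tr, "long", delta_t = 10)
  expect_equal(vd$v_perp, 0, tolerance = 1e-10)
  expect_equal(vd$ratio, 0, tolerance = 1e-10)
  expect_equal(vd$v_par, 0.05, tolerance = 1e-10)
  # 45-degree displacement: ratio exactly 1
  ring45 <- sweep(ring0, 2, c(0.3, 0.3, 0), "+")
  tr45 <- ringmix:::trajectory_from_frames(
    list(ring0, ring45), c(0, 10), top, confinement_sphere(20)
  )
  vd45 <- velocity_decomposition(tr45, "long", delta_t = 10)
  expect_equal(vd45$ratio, 1, tolerance = 1e-10)
  # delta_t must divide into the sampling grid
  expect_error(
    velocity_decomposition(tr, "long", delta_t = 7),
    "integer multiple"
  )
})

test_that("tangentially sliding rings give a dominant perpendicular component", {
  tr <- tangential_slide_trajectory(30, 10, 20, n = 50, angular_speed = 0.001)
  vd <- velocity_decomposition(tr, "long", delta_t = 10)
  expect_gt(vd$ratio, 50)
  # radial-reference variant coincides for wall-attached rings
  vdr <- velocity_decomposition(tr, "long", delta_t = 10, beta_ref = "radial")
  expect_equal(vdr$ratio, vd$ratio, tolerance = 1e-6)
  still <- tangential_slide_trajectory(5, 10, 20, n = 10, angular_speed = 0)
  expect_warning(
    vd0 <- velocity_decomposition(still, "long", delta_t = 10),
    "zero"
  )
  expect_equal(vd0$v_perp, 0)
  expect_equal(vd0$v_par, 0)
})

test_that("critical density interpolates the velocity-ratio peak", {
  # exact parabola peaked at 0.35
  rho <- c(0.25, 0.3, 0.35, 0.4, 0.5)
  ratio <- 3 - 40 * (rho - 0.35)^2
  expect_equal(critical_density(data.frame(rho = rho, ratio = ratio)), 0.35,
    tolerance = 1e-6
  )
  est <- critical_density(data.frame(
    rho = c(0.1, 0.3, 0.5),
    ratio = c(0.5, 2.0, 0.8)
  ))
  expect_gt(est, 0.1)
  expect_lt(est, 0.5)
  expect_warning(
    b <- critical_density(data.frame(rho = 1:4 / 10, ratio = 1:4)),
    "boundary"
  )
  expect_equal(b, 0.4)
  expect_error(critical_density(data.frame(rho = c(.1, .2), ratio = c(1, 2))), "3")
})

test_that("pmf is flat for uniform sampling and recovers a known potential", {
  u0 <- boltzmann_radial_sampler(function(r) rep(0, length(r)), 10, 1e6,
    seed = 6
  )
  flat <- pmf(u0, bin_width = 0.5)
  # the innermost-bin anchor is itself sampling-limited; flatness is about
  # the spread of the well-sampled bins around their common level
  ok <- flat$count > 5000
  v <- flat$value[ok]
  expect_lt(max(abs(v - mean(v))), 0.05)
  # linear ramp potential: round trip within 0.1 kBT RMS
  ramp <- function(r) 0.3 * r
  pts <- boltzmann_radial_sampler(ramp, 10, 1e6, seed = 7)
  prof <- pmf(pts, bin_width = 0.25)
  ok <- prof$count > 0
  resid <- prof$value[ok] - ramp(prof$r_mid[ok])
  # potentials are defined up to a constant: align by count-weighted mean,
  # then require count-weighted RMS recovery within 0.1 kBT
  w <- prof$count[ok]
  resid <- resid - sum(w * resid) / sum(w)
  expect_lt(sqrt(sum(w * resid^2) / sum(w)), 0.1)
})

test_that("pmf handles degenerate and empty histograms", {
  pts <- matrix(rep(c(5, 0, 0), each = 7), 7, 3)
  prof <- pmf(pts, bin_width = 0.5, r_max = 10)
  filled <- prof$count > 0
  expect_equal(sum(filled), 1)
  expect_equal(prof$value[filled], 0)
  expect_true(all(is.na(prof$value[!filled])))
  expect_false(any(is.infinite(prof$value), na.rm = TRUE))
})

test_that("hard exclusions never produce samples below the cut", {
  u <- function(r) ifelse(r < 3, Inf, 0)
  pts <- boltzmann_radial_sampler(u, 8, 2e4, seed = 8)
  expect_gte(min(sqrt(rowSums(pts^2))), 3)
})

test_that("energy/entropy decomposition vanishes for identical rigid rings", {
  # confined and bulk chains all rigid planar rings: identical bending energy
  # everywhere, so dU == 0 in every populated bin and T dS == -dF exactly
  wa <- wall_attached_ensemble(10, 20, 8.5, seed = 2, sphere_radius = 10)
  wa$topology$bending_k <- 50
  conf_tr <- ringmix:::as_trajectory(wa)
  bulk_pos <- do.call(rbind, lapply(1:10, function(i) {
    perfect_rigid_ring(20, 1, center = c(3 * (i - 1), 0, 0))
  }))
  bulk <- system_state(
    bulk_pos, NULL,
    topology(tibble::tibble(
      kind = "ring", n_monomers = rep(20, 10),
      bending_k = 50, species = "long"
    )),
    confinement_box(30)
  )
  bulk_tr <- ringmix:::as_trajectory(bulk)
  dec <- energy_entropy_decomposition(conf_tr, bulk_tr, "long", bin_width = 0.5)
  pop <- dec$count > 0
  expect_equal(dec$delta_u_bending[pop], rep(0, sum(pop)), tolerance = 1e-9)
  expect_equal(dec$t_delta_s[pop], dec$delta_u_bending[pop] - dec$delta_f[pop])
  expect_error(
    energy_entropy_decomposition(conf_tr, conf_tr),
    "periodic"
  )
})

test_that("crumpled bulk rings make the wall-attached bending cost negative", {
  # confined fixture: planar rings (minimum bending); bulk fixture: the same
  # rings puckered -> higher bending energy, so dU(outer bin) < 0
  wa <- wall_attached_ensemble(10, 20, 8.5, seed = 2, sphere_radius = 10)
  wa$topology$bending_k <- 50
  crumple <- function(ring, seed) {
    ring + withr::with_seed(seed, matrix(rnorm(length(ring), sd = 0.1), nrow(ring), 3))
  }
  bulk_pos <- do.call(rbind, lapply(1:10, function(i) {
    crumple(perfect_rigid_ring(20, 1, center = c(3 * (i - 1), 0, 0)), i)
  }))
  bulk <- system_state(
    bulk_pos, NULL,
    topology(tibble::tibble(
      kind = "ring", n_monomers = rep(20, 10),
      bending_k = 50, species = "long"
    )),
    confinement_box(30)
  )
  dec <- energy_entropy_decomposition(
    ringmix:::as_trajectory(wa), ringmix:::as_trajectory(bulk), "long",
    bin_width = 0.5
  )
  outer <- max(which(dec$count > 0))
  expect_lt(dec$delta_u_bending[outer], 0)
})

test_that("observables are invariant under global rotation of every frame", {
  st <- two_ring_state(seed = 17)
  tr <- run_md(st, ff_default, run_schedule(
    timestep = 0.006, production_time = 30, sample_interval = 500, seed = 1
  ))
  th <- 0.9
  rot <- rbind(c(1, 0, 0), c(0, cos(th), -sin(th)), c(0, sin(th), cos(th)))
  tr2 <- tr
  for (f in seq_len(n_frames(tr))) {
    tr2$positions[, , f] <- tr$positions[, , f] %*% t(rot)
  }
  expect_equal(orientation_order(tr2, "long"), orientation_order(tr, "long"),
    tolerance = 1e-9
  )
  expect_equal(
    mean_radial_distance(tr2, "long"), mean_radial_distance(tr, "long"),
    tolerance = 1e-9
  )
  p1 <- radial_density_profile(tr, "long", 0.5)
  p2 <- radial_density_profile(tr2, "long", 0.5)
  expect_equal(p2$value, p1$value, tolerance = 1e-9)
  v1 <- velocity_decomposition(tr, "long", delta_t = tr$sampling_interval)
  v2 <- velocity_decomposition(tr2, "long", delta_t = tr$sampling_interval)
  expect_equal(v2$ratio, v1$ratio, tolerance = 1e-9)
})

test_that("profile tooling: tidy, autoplot and CSV round trip", {
  wa <- wall_attached_ensemble(10, 20, 8.5, seed = 2, sphere_radius = 10)
  prof <- radial_density_profile(wa, "long", 0.5)
  td <- tidy(prof)
  expect_s3_class(td, "tbl_df")
  gg <- autoplot(prof)
  expect_s3_class(gg, "ggplot")
  f <- withr::local_tempfile(fileext = ".csv")
  write_profile_csv(prof, f)
  back <- read_profile_csv(f)
  expect_equal(back$value, prof$value)
  expect_equal(attr(back, "normalization"), "shell_density")
})
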