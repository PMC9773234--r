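test_that("particle generation produces the requested packing", {
  bed <- generate_particles(3, seed = 1)
  expect_equal(bed$n, 3 * 20 * 20)
  expect_true(all(bed$diameter >= 0.95 & bed$diameter <= 1.05))
  expect_true(all(bed$pos[, 3] > bed$floor_height))
  # no pair overlaps at generation (check a deterministic subsample)
  idx <- seq(1, bed$n, by = 7)
  p <- bed$pos[idx, ]; d <- bed$diameter[idx]
  dx <- abs(outer(p[, 1], p[, 1], "-")); dx <- pmin(dx, bed$box[1] - dx)
  dy <- abs(outer(p[, 2], p[, 2], "-")); dy <- pmin(dy, bed$box[2] - dy)
  dz <- outer(p[, 3], p[, 3], "-")
  dist <- sqrt(dx^2 + dy^2 + dz^2)
  rsum <- outer(d, d, "+") / 2
  diag(dist) <- Inf
  expect_true(all(dist > rsum))
  # determinism and dispersion limits
  expect_identical(generate_particles(1, box = c(4, 4, 8), seed = 3)$pos,
                   generate_particles(1, box = c(4, 4, 8), seed = 3)$pos)
  mono <- generate_particles(1, dispersion = 0, box = c(4, 4, 8), seed = 2)
  expect_equal(mono$n, 16)
  expect_true(all(mono$diameter == 1))
  expect_error(generate_particles(1, dispersion = 0.5), "dispersion")
})

test_that("hysteretic contact force switches stiffness with approach direction", {
  law <- contact_law()
  expect_equal(law$restitution, sqrt(5e3 / 5e4))
  # no overlap -> zero
  expect_equal(contact_force(c(0, 0, 0), c(2, 0, 0), 1, 1), c(0, 0, 0))
  # overlapping pair at rest is on the separating (unloading) branch
  f <- contact_force(c(0, 0, 0), c(0.9, 0, 0), 1, 1)
  expect_equal(f, c(-5e3 * 1 * 0.1, 0, 0))
  # approaching pair uses the stiff loading branch
  f2 <- contact_force(c(0, 0, 0), c(0.9, 0, 0), 1, 1,
                      vel_i = c(1, 0, 0), vel_j = c(0, 0, 0))
  expect_equal(f2, c(-5e4 * 1 * 0.1, 0, 0))
  # stiffness scales with the pair mean diameter
  f3 <- contact_force(c(0, 0, 0), c(0.7, 0, 0), 1, 0.5)
  expect_equal(f3[1], -5e3 * 0.75 * 0.05)
  expect_error(contact_force(c(0, 0, 0), c(0, 0, 0), 1, 1), "degenerate")
})

test_that("Gear integrator is exact on free fall and accurate on oscillations", {
  dt <- 5e-5
  grav <- function(s) matrix(rep(c(0, 0, -1), each = nrow(s$pos)), ncol = 3)
  st <- gear_state(matrix(c(0, 0, 10), 1, 3), forces_fn = grav)
  for (i in 1:10000) st <- gear_step(st, grav, dt)
  expect_lt(abs(st$pos[1, 3] - (10 - (10000 * dt)^2 / 2)), 1e-10)
  # zero force, zero velocity: state unchanged
  null_f <- function(s) 0 * s$pos
  st0 <- gear_state(matrix(c(1, 2, 3), 1, 3), forces_fn = null_f)
  expect_equal(gear_step(st0, null_f, dt)$pos, st0$pos)
  # harmonic oscillator: position after 10 periods within 0.1%
  hook <- function(s) -s$pos
  st <- gear_state(matrix(c(1, 0, 0), 1, 3), forces_fn = hook)
  n <- ceiling(10 * 2 * pi / dt)
  for (i in seq_len(n)) st <- gear_step(st, hook, dt)
  expect_lt(abs(st$pos[1, 1] - cos(n * dt)), 1e-3)
  expect_error(gear_step(st, function(s) s$pos * NaN, dt), "non-finite")
})

test_that("two-body drop tests reproduce the Walton-Braun restitution", {
  # rebound/impact speed ratio from the rebound apex: e = sqrt(rise / fall)
  for (seed in 1) {
    fx <- make_fixture("two_particle_collision", seed = seed)
    sc <- granulocell:::bed_scene(fx$bed)
    z0 <- fx$bed$pos[2, 3]
    zc <- fx$bed$pos[1, 3] + 1          # contact height (monodisperse)
    apex <- -Inf; rising <- FALSE
    for (seg in 1:400) {
      out <- granulocell:::cpp_run_phase(sc, granulocell:::phase_params(
        phase = 3L, dt = 5e-5, max_steps = 100))
      sc$pos <- out$pos; sc$vel <- out$vel; sc$hd <- out$hd
      if (out$vel[2, 3] > 1e-6) rising <- TRUE
      if (rising) apex <- max(apex, out$pos[2, 3])
      if (rising && out$vel[2, 3] < -1e-6) break
    }
    e <- sqrt((apex - zc) / (z0 - zc))
    expect_lt(abs(e - sqrt(0.1)) / sqrt(0.1), 0.05)
  }
})

test_that("a small bed settles to rest and stays put", {
  fx <- make_fixture("mini_bed_4x4", seed = 2)
  e_start <- sum(fx$bed$diameter^3 * fx$bed$pos[, 3])  # potential energy
  bed <- settle_bed(fx$bed)
  expect_true(bed$relaxed)
  expect_lt(bed$final_ke, 2e-3)
  expect_lt(bed_kinetic_energy(bed), 2e-3)
  expect_true(all(bed$pos[, 3] > bed$floor_height))
  expect_true(all(bed$pos[, 1] >= 0 & bed$pos[, 1] < bed$box[1]))
  expect_equal(bed$n, 16)  # periodic wrapping conserves particles
  # settled single layer sits within a particle diameter of the wall
  expect_lt(bed_height(bed), 1.3)
  # inelastic settling dissipates energy
  e_end <- sum(bed$diameter^3 * bed$pos[, 3]) +
    sum(0.5 * bed$diameter^3 * rowSums(bed$vel^2))
  expect_lt(e_end, e_start)
  # overlaps at rest below 1% of the smaller diameter
  p <- bed$pos; d <- bed$diameter
  dx <- abs(outer(p[, 1], p[, 1], "-")); dx <- pmin(dx, bed$box[1] - dx)
  dy <- abs(outer(p[, 2], p[, 2], "-")); dy <- pmin(dy, bed$box[2] - dy)
  dist <- sqrt(dx^2 + dy^2 + outer(p[, 3], p[, 3], "-")^2)
  ov <- outer(d, d, "+") / 2 - dist
  diag(ov) <- -Inf
  expect_lt(max(ov / min(d)), 0.01)
  # idempotence: an already-relaxed bed converges immediately
  again <- settle_bed(bed)
  expect_true(again$relaxed)
  expect_lte(again$settle_steps, 2200)
  # determinism: the same seed settles to the identical packing
  bed2 <- settle_bed(make_fixture("mini_bed_4x4", seed = 2)$bed)
  expect_identical(bed$pos, bed2$pos)
})
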