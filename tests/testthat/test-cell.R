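test_that("hexagonal template reproduces the size calibration", {
  tm <- cell_template(1)
  expect_equal(nrow(tm$xy), 43)
  expect_equal(as.vector(table(tm$layer)), c(1, 6, 12, 24))
  expect_equal(tm$element_diameter, 1 / 3)
  # enclosing diameter of the 7-element core is L_i; fully spread it is 2 L_i
  expect_equal(enclosing_diameter(tm$xy[tm$layer <= 1, ], 1 / 3), 1,
               tolerance = 1e-12)
  expect_equal(enclosing_diameter(tm$xy, 1 / 3), 2, tolerance = 1e-12)
  # six-fold symmetry of the first shell
  r1 <- sqrt(rowSums(tm$xy[2:7, ]^2))
  expect_equal(r1, rep(1 / 3, 6))
  ang <- sort(atan2(tm$xy[2:7, 2], tm$xy[2:7, 1]))
  expect_equal(diff(ang), rep(pi / 3, 5))
  # scale invariance: template scales linearly with L_i
  tm2 <- cell_template(2.5)
  expect_equal(tm2$xy, 2.5 * tm$xy)
})

test_that("a dropped cell lands at first contact with impact velocity", {
  fx <- make_fixture("three_particle_pocket")
  cell <- init_cell(1, fx$drop_position, fx$bed, seed = 5)
  expect_equal(sum(cell$active), 7)
  expect_equal(sum(cell$layer == 0), 1)
  # active elements keep the rigid hexagon while falling
  act <- cell$pos[cell$active, ]
  expect_equal(enclosing_diameter(act, cell$diameter, cell$pos[1, ]), 1,
               tolerance = 1e-9)
  # first contact: minimal element-particle gap is zero
  gaps <- sapply(which(cell$active), function(e) {
    min(sqrt(colSums((t(fx$bed$pos) - cell$pos[e, ])^2)) -
          (fx$bed$diameter + cell$diameter) / 2)
  })
  expect_equal(min(gaps), 0, tolerance = 1e-9)
  expect_lt(cell$vel[1, 3], 0)  # arrives falling
  expect_error(init_cell(1, c(99, 0), fx$bed), "outside")
})

test_that("stretching activates shells 7 -> 19 -> 43 and respects terminals", {
  fx <- make_fixture("three_particle_pocket")
  cell <- init_cell(1, fx$drop_position, fx$bed, seed = 5)
  expect_error(add_layer(cell), "unbonded")
  cell <- bind_on_contact(cell, fx$bed)
  expect_gt(nrow(cell$bonds), 0)
  c19 <- add_layer(cell)
  expect_equal(sum(c19$active), 19)
  expect_true(all(c19$mass_scale[c19$active] == 1))
  expect_false(any(c19$tethers[, 1] %in% which(c19$active)))
  c43 <- add_layer(c19)
  expect_equal(sum(c43$active), 43)
  expect_error(add_layer(c43), "three shells")
  # terminal parents spawn nothing
  cterm <- c19
  cterm$terminal[cterm$layer == 2] <- TRUE
  expect_equal(sum(add_layer(cterm)$active), 19)
})

test_that("structural springs are linear viscoelastic force pairs", {
  sp <- list(L0 = 1, k = 6.25, c = 6.25e-2)
  # at natural length with no relative motion: no force
  f0 <- structural_force(sp, c(0, 0, 0), c(1, 0, 0))
  expect_equal(f0, rbind(c(0, 0, 0), c(0, 0, 0)))
  # static stretch of 0.01 at k = 6.25 transmits 0.0625
  f1 <- structural_force(sp, c(0, 0, 0), c(1.01, 0, 0))
  expect_equal(f1[1, ], c(6.25 * 0.01, 0, 0))
  expect_equal(colSums(f1), c(0, 0, 0))  # momentum conservation
  # damping resists relative separation velocity
  f2 <- structural_force(sp, c(0, 0, 0), c(1, 0, 0),
                         vel_i = c(0, 0, 0), vel_j = c(0.1, 0, 0))
  expect_equal(f2[1, 1], 6.25e-2 * 0.1)
  expect_error(structural_force(sp, c(0, 0, 0), c(0, 0, 0)), "degenerate")
})

test_that("contraction shrinks natural lengths on schedule", {
  fx <- make_fixture("flat_rigid_plane")
  cell <- init_cell(1, fx$drop_position, fx$bed, seed = 2)
  res <- relax_layer(cell, fx$bed, on_fail = "warn", max_steps = 5e4)
  cell <- res$cell
  # scalar rate: natural lengths hit zero after ceiling(L0/(rate dt)) steps
  rate <- 0.5; dt <- 5e-5
  expected_steps <- ceiling(max(cell$springs[, 3]) / (rate * dt))
  res <- contract(cell, fx$bed, shrink_rate = rate, dt = dt, max_dwell = 0)
  expect_equal(res$info$steps, expected_steps)
  expect_true(all(res$cell$springs[, 3] == 0))
  # a free cell on the bare wall contracts toward its center
  d0 <- enclosing_diameter(cell$pos[cell$active, ], cell$diameter,
                           cell$pos[1, ])
  d1 <- enclosing_diameter(res$cell$pos[res$cell$active, ], cell$diameter,
                           res$cell$pos[1, ])
  expect_lt(d1, d0)
})

test_that("a fully frozen cell does not move during contraction", {
  fx <- make_fixture("three_particle_pocket")
  cell <- init_cell(1, fx$drop_position, fx$bed, seed = 5)
  cell <- bind_on_contact(cell, fx$bed)
  cell$fixed[cell$active] <- TRUE
  p0 <- cell$pos
  res <- contract(cell, fx$bed, n_steps = 5e3)
  expect_lt(max(abs(res$cell$pos[cell$active, ] - p0[cell$active, ])), 1e-6)
})

test_that("structural damping attenuates two-element oscillations", {
  # two elements connected by one spring, stretched and released: the
  # vibration amplitude must decay markedly over a few periods
  dt <- 5e-5
  sp <- list(L0 = 1 / 3, k = 6.25, c = 6.25e-2)
  m <- (1 / 3)^3
  f <- function(s) {
    fp <- structural_force(sp, s$pos[1, ], s$pos[2, ],
                           s$vel[1, ], s$vel[2, ])
    rbind(fp[1, ], fp[2, ])
  }
  x0 <- 0.1  # initial stretch
  st <- gear_state(rbind(c(0, 0, 0), c(1 / 3 + x0, 0, 0)),
                   mass = c(m, m), forces_fn = f)
  omega <- sqrt(2 * sp$k / m)  # relative-coordinate frequency
  n_per <- ceiling(2 * pi / omega / dt)
  peak <- function(st, n) {
    mx <- 0
    for (i in seq_len(n)) {
      st <- gear_step(st, f, dt)
      mx <- max(mx, abs(st$pos[2, 1] - st$pos[1, 1] - sp$L0))
    }
    list(st = st, mx = mx)
  }
  first <- peak(st, n_per)
  later <- first
  for (k in 1:8) later <- peak(later$st, n_per)
  expect_lt(later$mx, 0.5 * first$mx)
})
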