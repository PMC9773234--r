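test_that("binding-spring constants satisfy the maximum-displacement identity", {
  for (L_i in c(0.5, 1, 2)) {
    ad <- adhesion_params(L_i)
    # full maximum force at a stretch of 0.0025% of L_i, exactly
    expect_equal(ad$k_b * 2.5e-5 * L_i, ad$F_max)
    expect_equal(ad$max_spring_displacement / L_i, 2.5e-5)
    # saturation displacement far below the detachment threshold
    expect_lt(ad$max_spring_displacement,
              ad$detachment_fraction * L_i)
    expect_equal(ad$reinforcement_threshold, (82 / 32 * L_i)^3)
    expect_equal(ad$c_b, ad$F_max / (1.25e-2 * L_i))
  }
})

test_that("binding is instantaneous, one bond per element, no duplicates", {
  fx <- make_fixture("three_particle_pocket")
  cell <- init_cell(1, fx$drop_position, fx$bed, seed = 5)
  cell <- bind_on_contact(cell, fx$bed)
  expect_gt(nrow(cell$bonds), 0)
  expect_false(any(duplicated(cell$bonds$element)))
  # rebinding creates nothing new while contacts are unchanged
  again <- bind_on_contact(cell, fx$bed)
  expect_equal(nrow(again$bonds), nrow(cell$bonds))
  # after relaxation the draped cell holds >= 3 bonds in the pocket
  res <- relax_layer(cell, fx$bed, on_fail = "warn", max_steps = 5e4)
  expect_gte(nrow(res$cell$bonds), 3)
  # terminal elements do not re-engage
  term <- res$cell
  term$bonds <- term$bonds[0, ]
  term$terminal[term$active] <- TRUE
  expect_equal(nrow(bind_on_contact(term, fx$bed)$bonds), 0)
})

test_that("bond force is linear with the calibrated saturation point", {
  L_i <- 1
  ad <- adhesion_params(L_i)
  bond <- list(rest = 0.6, k = ad$k_b, c = ad$c_b, state = "engaged")
  # zero extension, no motion: no force
  expect_equal(bond_force(bond, c(0, 0, 0), c(0.6, 0, 0)),
               rbind(c(0, 0, 0), c(0, 0, 0)))
  # at the saturation stretch the elastic force equals F_max
  x <- 2.5e-5 * L_i
  f <- bond_force(bond, c(0, 0, 0), c(0.6 + x, 0, 0))
  expect_equal(f[1, 1], ad$F_max, tolerance = 1e-9)
  # linearity: half the stretch, half the force
  f2 <- bond_force(bond, c(0, 0, 0), c(0.6 + x / 2, 0, 0))
  expect_equal(f2[1, 1], ad$F_max / 2, tolerance = 1e-9)
  expect_equal(f[1, ] + f[2, ], c(0, 0, 0))
  bond$state <- "broken"
  expect_error(bond_force(bond, c(0, 0, 0), c(1, 0, 0)), "broken")
})

test_that("reinforcement freezes both bodies at the force threshold", {
  fx <- make_fixture("three_particle_pocket")
  bed <- fx$bed; bed$mobile <- rep(TRUE, bed$n)
  cell <- init_cell(1, fx$drop_position, bed, seed = 5)
  cell <- bind_on_contact(cell, bed)
  b1 <- cell$bonds[1, ]
  # stretch the first bond just past / just below the threshold
  over <- cell
  dirv <- bed$pos[b1$particle, ] - cell$pos[b1$element, ]
  dirv <- dirv / sqrt(sum(dirv^2))
  over$pos[b1$element, ] <- over$pos[b1$element, ] -
    dirv * 1.01 * over$adhesion$F_max / b1$k
  res <- check_reinforcement(over, bed)
  expect_equal(res$cell$bonds$state[1], "reinforced")
  expect_true(res$cell$fixed[b1$element])
  expect_false(res$bed$mobile[b1$particle])
  under <- cell
  under$pos[b1$element, ] <- under$pos[b1$element, ] -
    dirv * 0.99 * under$adhesion$F_max / b1$k
  res2 <- check_reinforcement(under, bed)
  expect_equal(res2$cell$bonds$state[1], "engaged")
  expect_true(all(res2$bed$mobile))
})

test_that("detachment trips at 4% of the cell diameter and marks terminals", {
  fx <- make_fixture("three_particle_pocket")
  cell <- init_cell(1, fx$drop_position, fx$bed, seed = 5)
  cell <- bind_on_contact(cell, fx$bed)
  b1 <- cell$bonds[1, ]
  thr <- cell$adhesion$detachment_fraction * cell$L_i
  ctr <- cell$pos[cell$center, ]
  inward <- function(cell, e, dist) {
    u <- ctr - cell$pos[e, ]; u <- u / sqrt(sum(u^2))
    cell$pos[e, ] <- cell$pos[e, ] + u * dist
    cell
  }
  broken <- check_detachment(inward(cell, b1$element, 1.01 * thr))
  expect_false(b1$element %in% broken$bonds$element)
  expect_true(broken$terminal[b1$element])
  held <- check_detachment(inward(cell, b1$element, 0.99 * thr))
  expect_true(b1$element %in% held$bonds$element)
  expect_false(held$terminal[b1$element])
  # reinforced bonds are immune: the state machine is absorbing
  rf <- inward(cell, b1$element, 2 * thr)
  rf$bonds$state[1] <- "reinforced"
  expect_equal(check_detachment(rf)$bonds$state[1], "reinforced")
})

test_that("an element anchored to an immobile particle reinforces, never breaks", {
  # two-body oracle: contraction pulls the bonded element sideways; the
  # particle cannot move, so the bond force climbs to the threshold long
  # before the element has moved 4% of L_i
  tb <- two_body_scene(particle_mobile = FALSE, k_s = 30 * 6.25)
  out <- run_two_body(tb, n_steps = 4e4)
  ev <- out$events
  expect_true(any(ev[, 3] == 1))   # reinforced
  expect_false(any(ev[, 3] == 2))  # never broken
  expect_equal(out$bonds[1, 6], 1)
  # both bodies frozen afterwards
  expect_equal(out$mobile[1:2], c(0L, 0L))
})

test_that("a light mobile particle is dragged along until the bond breaks", {
  tb <- two_body_scene(particle_mobile = TRUE)
  out <- run_two_body(tb, n_steps = 4e4)
  ev <- out$events
  expect_true(any(ev[, 3] == 2))   # detached
  expect_false(any(ev[, 3] == 1))
  expect_equal(out$bonds[1, 6], 2)
  expect_equal(out$terminal[2], 1L)
  # the element was free to move away (dragging, not resisting): it ends well
  # above its starting height, and the bond broke at a force far below the
  # reinforcement threshold
  expect_gt(out$pos[2, 3], 2.2)
  expect_lt(max(out$events[out$events[, 3] == 2, 4]),
            0.5 * tb$adhesion$F_max)
})

test_that("heavier particles shift the two-body fate toward reinforcement", {
  # the central competition: at fixed maximum force, increasing the particle
  # weight weakly increases the number of reinforced (vs broken) bonds
  fate <- sapply(c(1, 2, 40), function(r) {
    tb <- two_body_scene(particle_mobile = TRUE, rel_density = r,
                         k_s = 30 * 6.25)
    out <- run_two_body(tb, n_steps = 4e4)
    if (any(out$events[, 3] == 1)) 1 else if (any(out$events[, 3] == 2)) -1 else 0
  })
  expect_true(all(diff(fate) >= 0))
  expect_lt(fate[1], 1)   # light particle does not reinforce
  expect_equal(fate[3], 1)  # near-immobile particle reinforces
})
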