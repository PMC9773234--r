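test_that("drop positions form a uniform grid over the cross-section", {
  g <- drop_positions(16, c(20, 20, 20))
  expect_equal(nrow(g), 16)
  expect_equal(sort(unique(g[, 1])), (1:4 - 0.5) / 4 * 20)
  expect_equal(sort(unique(g[, 2])), (1:4 - 0.5) / 4 * 20)
  expect_equal(nrow(drop_positions(5, c(10, 10, 10))), 5)
})

test_that("union-of-spheres volumes match analytic references", {
  v1 <- union_volume(matrix(c(0, 0, 0), 1, 3), 1, n_points = 2^15, seed = 1)
  expect_equal(v1, 4 / 3 * pi, tolerance = 0.01)
  # two disjoint spheres have twice the volume; ratio of one to two is 0.5
  two <- rbind(c(0, 0, 0), c(5, 0, 0))
  v2 <- union_volume(two, 1, n_points = 2^15, seed = 1)
  expect_equal(v2 / (2 * v1), 1, tolerance = 0.01)
  # coincident spheres collapse to a single sphere volume
  vc <- union_volume(rbind(c(0, 0, 0), c(0, 0, 0)), 1, seed = 2)
  expect_equal(vc, 4 / 3 * pi, tolerance = 0.01)
  # determinism for a fixed seed
  expect_identical(union_volume(two, 1, seed = 3), union_volume(two, 1, seed = 3))
  expect_error(union_volume(matrix(numeric(0), 0, 3), 1), "empty")
})

test_that("volume ratio compares final to reference cells", {
  fx <- make_fixture("three_particle_pocket")
  cell <- init_cell(1, fx$drop_position, fx$bed, seed = 4)
  expect_equal(volume_ratio(cell, cell), 1)
  # all elements collapsed onto one point: a single element volume remains
  collapsed <- cell
  collapsed$active <- rep(TRUE, 43)
  collapsed$pos <- matrix(rep(cell$pos[1, ], each = 43), 43, 3)
  ref <- cell
  ref$active <- rep(TRUE, 43)
  tmpl <- cell_template(1)
  ref$pos <- cbind(tmpl$xy + 2, 2)
  vr <- volume_ratio(collapsed, ref)
  v_one <- union_volume(cell$pos[1, , drop = FALSE], cell$diameter / 2)
  v_ref <- union_volume(ref$pos, cell$diameter / 2)
  expect_equal(vr, v_one / v_ref, tolerance = 0.02)
  expect_lt(vr, 0.1)
})

test_that("a toy sweep does the bookkeeping and is reproducible", {
  # 2 ratios x 2 drop positions x 1 bed on a miniature single-layer bed
  sw <- suppressWarnings(
    run_sweep(ratios = c(0.4, 0.8), densities = 1, layers = 1,
              n_positions = 2, n_beds = 1, master_seed = 11,
              box = c(4, 4, 8), contraction_steps = 4e3,
              relax_max_steps = 1.5e4))
  expect_s3_class(sw, "granulo_sweep")
  expect_equal(nrow(sw), 4)
  expect_true(all(sw$volume_ratio > 0 & sw$volume_ratio <= 1))
  agg <- aggregate_sweep(sw)
  expect_equal(nrow(agg), 2)
  expect_equal(agg$n, c(2, 2))
  # determinism: identical config + seeds give identical records
  cfg <- scenario_config(aspect_ratio = 0.4, bed_layers = 1, box = c(4, 4, 8),
                         n_drop_positions = 2, contraction_steps = 4e3,
                         relax_max_steps = 1.5e4, master_seed = 11)
  bed <- settle_bed(generate_particles(1, box = c(4, 4, 8), seed = 1))
  r1 <- suppressWarnings(run_scenario(cfg, bed_seed = 1, drop_index = 1, bed = bed))
  r2 <- suppressWarnings(run_scenario(cfg, bed_seed = 1, drop_index = 1, bed = bed))
  expect_identical(r1$volume_ratio, r2$volume_ratio)
  expect_identical(r1$n_broken, r2$n_broken)
  expect_identical(r1$volume_ratio, sw$volume_ratio[sw$aspect_ratio == 0.4 &
                                                      sw$drop_index == 1])
  # tidy/glance/plot accessors
  expect_s3_class(tidy(sw), "tbl_df")
  expect_s3_class(glance(sw), "tbl_df")
  expect_s3_class(plot_fate_curve(sw), "ggplot")
  expect_s3_class(ggplot2::autoplot(sw), "ggplot")
})

test_that("aggregate of constant samples has zero standard error", {
  sw <- data.frame(aspect_ratio = 1, relative_density = 1, bed_layers = 3,
                   volume_ratio = rep(0.7, 5))
  agg <- aggregate_sweep(sw)
  expect_equal(agg$mean_ratio, 0.7)
  expect_equal(agg$sem, 0)
  expect_equal(agg$n, 5)
})

test_that("localized bed dynamics do not change a scenario's fate", {
  # enlarging the mobile region around the drop site leaves the volume ratio
  # essentially unchanged: disturbances are short-ranged
  bed <- settled_bed(1, seed = 1)  # single layer keeps this quick
  base <- toy_config(0.8)
  wide <- toy_config(0.8, mobility_radius = Inf)
  r1 <- suppressWarnings(run_scenario(base, bed_seed = 1, drop_index = 2,
                                      bed = bed))
  r2 <- suppressWarnings(run_scenario(wide, bed_seed = 1, drop_index = 2,
                                      bed = bed))
  expect_lt(abs(r1$volume_ratio - r2$volume_ratio), 0.1)
})

test_that("conclusions are insensitive to the structural stiffness scale", {
  # an order of magnitude in k_s up or down leaves the sintered fate intact
  fx <- make_fixture("three_particle_pocket")
  vr <- sapply(c(0.1, 1, 10), function(fac) {
    cell <- init_cell(1, fx$drop_position, fx$bed, seed = 3)
    cell$springs[, 5] <- cell$springs[, 5] * fac
    cell$springs[, 6] <- cell$springs[, 6] * fac
    cell <- bind_on_contact(cell, fx$bed)
    res <- relax_layer(cell, fx$bed, on_fail = "warn", max_steps = 5e4)
    res <- contract(res$cell, fx$bed, n_steps = 2e4)
    res <- relax_layer(res$cell, fx$bed, on_fail = "warn", max_steps = 5e4)
    ref <- init_cell(1, fx$drop_position, fx$bed, seed = 3)
    volume_ratio(res$cell, ref)
  })
  # immobile anchors hold the cell near its spread size in all cases
  expect_true(all(vr > 0.6))
})
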