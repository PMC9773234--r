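# Internal marshalling between R-level objects (granulo_bed, granulo_cell)
# and the flat scene lists consumed by the compiled core.

BOND_STATE <- c(engaged = 0, reinforced = 1, broken = 2)

phase_params <- function(phase, dt = 5e-5, yu = 5e4, yl = 5e3, g = 1,
                         skin = 0.5, max_steps = 1e5, check_every = 200,
                         ke_threshold = 2e-3, ke_cap = 0.1, arm_steps = 2000,
                         watch = integer(0), watch_tol = numeric(0),
                         shrink = numeric(0), detach_dist = 0.04,
                         f_threshold = Inf, adhesion = FALSE, drag = 0,
                         v_still = 1e-3,
                         bind = FALSE, bond_rate = 500) {
  list(phase = as.integer(phase), dt = dt, yu = yu, yl = yl, g = g,
       skin = skin, max_steps = as.double(max_steps),
       check_every = as.integer(check_every), ke_threshold = ke_threshold,
       ke_cap = ke_cap,
       arm_steps = as.double(arm_steps), watch = as.integer(watch),
       watch_tol = as.double(watch_tol), shrink = as.double(shrink),
       detach_dist = detach_dist, f_threshold = f_threshold,
       adhesion = adhesion, drag = drag, v_still = v_still,
       bind = bind, bond_rate = bond_rate)
}

empty_springs <- function() matrix(numeric(0), 0, 5)
empty_tethers <- function() matrix(numeric(0), 0, 6)
empty_bonds_m <- function() matrix(numeric(0), 0, 7)

bed_masses <- function(bed) {
  f <- density_weight_factor(bed$rel_density)
  w <- bed$diameter^3 * f
  w[!is.finite(w)] <- 0    # sintered particles never move; weight unused
  list(mass = pmax(w, 1e-12), weight = w)
}

bed_scene <- function(bed) {
  mw <- bed_masses(bed)
  n <- bed$n
  list(pos = bed$pos, vel = bed$vel, hd = bed$hd, diam = bed$diameter,
       mass = mw$mass, weight = mw$weight,
       mobile = as.integer(bed$mobile), incontact = rep(1L, n),
       kind = rep(0L, n), terminal = rep(0L, n),
       box = bed$box, floor = bed$floor_height,
       springs = empty_springs(), tethers = empty_tethers(),
       center = 0L, bonds = empty_bonds_m())
}

# combined bed + cell scene; elements are appended after the particles
scene_build <- function(bed, cell) {
  np <- bed$n
  ne <- nrow(cell$pos)
  mw <- bed_masses(bed)
  d_e <- cell$diameter
  m_e <- d_e^3 * cell$mass_scale
  elem_mobile <- as.integer(!cell$fixed)
  springs <- cell$springs
  sc_springs <- if (nrow(springs) > 0)
    cbind(springs[, 1] + np, springs[, 2] + np, springs[, 3],
          springs[, 5], springs[, 6])
  else empty_springs()
  teth <- cell$tethers
  sc_teth <- if (nrow(teth) > 0)
    cbind(teth[, 1] + np, teth[, 2:4, drop = FALSE],
          teth[, 5], teth[, 6])
  else empty_tethers()
  b <- cell$bonds
  live <- b$state != "broken"
  sc_bonds <- if (any(live))
    cbind(b$element[live] + np, b$particle[live], b$dx[live],
          b$dy[live], b$dz[live], BOND_STATE[b$state[live]],
          b$bind_dist[live])
  else empty_bonds_m()
  # spare capacity for bonds formed on contact during the phase
  n_spare <- sum(cell$active & !cell$terminal &
                   !(seq_len(ne) %in% b$element[live]))
  if (n_spare > 0)
    sc_bonds <- rbind(sc_bonds,
                      matrix(rep(c(0, 0, 0, 0, 0, -1, 0), n_spare),
                             ncol = 7, byrow = TRUE))
  list(pos = rbind(bed$pos, cell$pos),
       vel = rbind(bed$vel, cell$vel),
       hd = rbind(bed$hd, cell$hd),
       diam = c(bed$diameter, rep(d_e, ne)),
       mass = c(mw$mass, m_e), weight = c(mw$weight, m_e),
       mobile = c(as.integer(bed$mobile), elem_mobile),
       incontact = c(rep(1L, np), as.integer(cell$active)),
       kind = c(rep(0L, np), rep(1L, ne)),
       terminal = c(rep(0L, np), as.integer(cell$terminal)),
       box = bed$box, floor = bed$floor_height,
       springs = sc_springs, tethers = sc_teth,
       center = np + cell$center, bonds = sc_bonds,
       np = np, ne = ne, live_bonds = which(live))
}

# write the phase result back into the bed and cell objects
scene_apply <- function(bed, cell, scene, out, step_offset = 0) {
  np <- scene$np
  ip <- seq_len(np); ie <- np + seq_len(scene$ne)
  bed$pos <- out$pos[ip, , drop = FALSE]
  bed$vel <- out$vel[ip, , drop = FALSE]
  bed$hd <- out$hd[ip, , drop = FALSE]
  bed$mobile <- out$mobile[ip] == 1L
  cell$pos <- out$pos[ie, , drop = FALSE]
  cell$vel <- out$vel[ie, , drop = FALSE]
  cell$hd <- out$hd[ie, , drop = FALSE]
  cell$terminal <- out$terminal[ie] == 1L
  cell$fixed <- cell$active & (out$mobile[ie] == 0L)
  if (nrow(cell$springs) > 0)
    cell$springs[, 3] <- out$springs[, 3]
  bm <- out$bonds
  ev <- out$events
  if (nrow(ev) > 0)
    cell$events <- rbind(cell$events, data.frame(
      step = ev[, 1] + step_offset,
      element = bm[ev[, 2], 1] - np,
      particle = bm[ev[, 2], 2],
      event = c("bind", "reinforce", "break")[ev[, 3] + 1],
      force = ev[, 4]))
  # live bond table rebuilt from the phase output (broken bonds are dropped
  # from the live set but kept in the event log)
  keep <- bm[, 6] %in% c(0, 1)
  ad <- cell$adhesion
  cell$bonds <- if (any(keep)) data.frame(
    element = as.integer(bm[keep, 1] - np), particle = as.integer(bm[keep, 2]),
    dx = bm[keep, 3], dy = bm[keep, 4], dz = bm[keep, 5],
    rest = sqrt(bm[keep, 3]^2 + bm[keep, 4]^2 + bm[keep, 5]^2),
    k = ad$k_b, c = ad$c_b,
    state = names(BOND_STATE)[match(bm[keep, 6], BOND_STATE)],
    bind_dist = bm[keep, 7])
  else empty_bonds()
  list(bed = bed, cell = cell)
}

run_cell_phase <- function(bed, cell, params, step_offset = 0) {
  scene <- scene_build(bed, cell)
  out <- cpp_run_phase(scene, params)
  res <- scene_apply(bed, cell, scene, out, step_offset)
  res$info <- list(steps = out$steps, converged = out$converged,
                   max_watch_force = out$max_watch_force)
  res
}
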