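# shared, lazily computed heavy objects (settled beds, sweeps); everything is
# generated in code at test time and memoized for the session
.scene_cache <- new.env(parent = emptyenv())

cached <- function(key, expr) {
  if (is.null(.scene_cache[[key]])) .scene_cache[[key]] <- force(expr)
  .scene_cache[[key]]
}

# bed cache shared with run_sweep (keys "bed_<layers>_<seed>")
shared_bed_cache <- function() {
  if (is.null(.scene_cache$beds))
    .scene_cache$beds <- new.env(parent = emptyenv())
  .scene_cache$beds
}

settled_bed <- function(layers = 3, seed = 1) {
  cache <- shared_bed_cache()
  key <- sprintf("bed_%d_%d", layers, seed)
  if (is.null(cache[[key]]))
    cache[[key]] <- settle_bed(generate_particles(layers, seed = seed))
  cache[[key]]
}

# study-condition sweep at reduced replication (4 drop positions x 2 beds)
fate_sweep <- function() {
  cached("fate_sweep", suppressWarnings(
    run_sweep(ratios = c(0.5, 1, 2), densities = c(1, 2, Inf), layers = 3,
              n_positions = 4, n_beds = 2, master_seed = 20260101,
              bed_cache = shared_bed_cache())))
}

fate_sweep_5layer <- function() {
  cached("fate_sweep5", suppressWarnings(
    run_sweep(ratios = 2, densities = 1, layers = 5,
              n_positions = 4, n_beds = 2, master_seed = 20260101,
              bed_cache = shared_bed_cache())))
}

# tiny scenario configuration for fast protocol/bookkeeping tests
toy_config <- function(ratio = 0.5, ...) {
  scenario_config(aspect_ratio = ratio, bed_layers = 1, box = c(4, 4, 8),
                  n_drop_positions = 4, n_bed_configs = 1,
                  contraction_steps = 5e3, relax_max_steps = 2e4,
                  master_seed = 7, ...)
}

# minimal hand-built scene for two-body adhesion oracles: one microparticle,
# one bonded element, and a frozen anchor element connected to the bonded one
# by a structural spring whose natural length shrinks (the contraction drive).
# Returns positions so that the element sits on top of the particle.
two_body_scene <- function(particle_mobile = TRUE, rel_density = 1,
                           L_i = 1, k_s = 6.25 * L_i^2) {
  d_e <- L_i / 3
  ad <- adhesion_params(L_i)
  zp <- 1.5                          # particle resting on the bottom wall
  ze <- zp + 0.5 + d_e / 2           # element touching the particle top
  # anchor directly above: contraction pulls the element axially off the
  # particle, so the bond is loaded without pendulum swing
  anchor <- c(5, 5, ze + 1.5 * L_i)
  pos <- rbind(c(5, 5, zp), c(5, 5, ze), anchor)
  wfac <- granulocell:::density_weight_factor(rel_density)
  list(
    scene = list(
      pos = pos, vel = matrix(0, 3, 3),
      hd = matrix(c(0, 0, 0, 0, 0, 0, rep(0, 21)), 3, 9),
      diam = c(1, d_e, d_e),
      mass = c(max(wfac, 1), d_e^3, d_e^3),
      weight = c(wfac, d_e^3, d_e^3),
      mobile = c(as.integer(particle_mobile), 1L, 0L),
      incontact = c(1L, 1L, 0L),
      kind = c(0L, 1L, 1L),
      terminal = c(0L, 0L, 0L),
      box = c(10, 10, 10), floor = 1,
      springs = cbind(2, 3, 1.5 * L_i, k_s, 6.25e-2 * L_i^2),
      tethers = granulocell:::empty_tethers(),
      center = 3L,
      # bond columns: element, particle, relative vector at binding (the
      # particle sits directly below the element), state, bind distance
      bonds = cbind(2, 1, 0, 0, -(0.5 + d_e / 2), 0, 1.5 * L_i)),
    adhesion = ad, L_i = L_i)
}

run_two_body <- function(tb, n_steps = 4e4, shrink_frac = 1) {
  L0 <- tb$scene$springs[1, 3]
  granulocell:::cpp_run_phase(tb$scene, granulocell:::phase_params(
    phase = 3L, dt = 5e-5, max_steps = n_steps,
    shrink = shrink_frac * L0 / (n_steps * 5e-5),
    detach_dist = tb$adhesion$detachment_fraction * tb$L_i,
    f_threshold = tb$adhesion$reinforcement_threshold,
    adhesion = TRUE, check_every = 500L))
}
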