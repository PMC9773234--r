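#' Hysteretic (Walton-Braun) normal contact law
#'
#' Linear spring contact with a stiffer constant while two spheres approach
#' than while they separate, giving inelastic collisions with restitution
#' coefficient `sqrt(Y_l/Y_u)` independent of impact speed. Stiffnesses are
#' per unit diameter: the force constant for a particle pair is
#' `Y * mean(diameters)`, for a wall contact `Y * diameter`.
#'
#' @param Y_u loading (approach) stiffness per unit diameter. Default 5e4.
#' @param Y_l unloading (separation) stiffness per unit diameter. Default 5e3.
#' @return object of class `granulo_contact_law` with the implied
#'   `restitution` coefficient.
#' @export
contact_law <- function(Y_u = 5e4, Y_l = 5e3) {
  stopifnot(Y_u > Y_l, Y_l > 0)
  structure(list(Y_u = Y_u, Y_l = Y_l, restitution = sqrt(Y_l / Y_u)),
            class = "granulo_contact_law")
}

#' Contact force between two spheres
#'
#' Returns the force on sphere `i` from its overlap with sphere `j` under the
#' hysteretic law: zero without overlap, else `Y * overlap` along the
#' center-to-center direction away from `j`, with `Y = Y_u` while the pair
#' approaches and `Y_l` while it separates.
#'
#' @param pos_i,pos_j centers (length-3).
#' @param diam_i,diam_j diameters.
#' @param vel_i,vel_j velocities (length-3).
#' @param law a [contact_law()].
#' @return force 3-vector on sphere `i`.
#' @export
contact_force <- function(pos_i, pos_j, diam_i, diam_j,
                          vel_i = c(0, 0, 0), vel_j = c(0, 0, 0),
                          law = contact_law()) {
  dr <- pos_j - pos_i
  d2 <- sum(dr^2)
  rsum <- (diam_i + diam_j) / 2
  if (d2 >= rsum^2) return(c(0, 0, 0))
  if (d2 < 1e-24) stop("degenerate geometry: coincident centers")
  r <- sqrt(d2)
  approaching <- sum((vel_j - vel_i) * dr) < 0  # d|r_ij|/dt < 0
  Y <- (if (approaching) law$Y_u else law$Y_l) * (diam_i + diam_j) / 2
  -Y * (rsum - r) * dr / r
}

# Gear 5-value corrector coefficients (second order equations,
# velocity-dependent forces); shared with the compiled core.
gear_alpha <- c(19 / 90, 3 / 4, 1, 1 / 2, 1 / 12)

#' One step of the 4th-order Gear predictor-corrector
#'
#' Reference R implementation of the integrator used by the compiled core,
#' operating on an explicit state list. Useful for small oracle problems
#' (free fall, harmonic oscillator); the production loops run in C++ with the
#' same coefficients.
#'
#' @param state list with `pos`, `vel`, `acc`, `der3`, `der4` (n x 3 matrices),
#'   `mass` (length n) and optional `mobile` (logical n).
#' @param forces_fn function of `state` returning an n x 3 force matrix.
#' @param dt time step (default 5e-5, the bed-settling step).
#' @return the advanced state.
#' @export
gear_step <- function(state, forces_fn, dt = 5e-5) {
  stopifnot(dt > 0)
  mob <- if (is.null(state$mobile)) rep(TRUE, nrow(state$pos)) else state$mobile
  # scaled variables r_k = dt^k/k! d^k r/dt^k
  r0 <- state$pos; r1 <- state$vel * dt; r2 <- state$acc * dt^2 / 2
  r3 <- state$der3 * dt^3 / 6; r4 <- state$der4 * dt^4 / 24
  p0 <- r0 + r1 + r2 + r3 + r4
  p1 <- r1 + 2 * r2 + 3 * r3 + 4 * r4
  p2 <- r2 + 3 * r3 + 6 * r4
  p3 <- r3 + 4 * r4
  s <- state
  s$pos[mob, ] <- p0[mob, ]; s$vel[mob, ] <- p1[mob, ] / dt
  s$acc[mob, ] <- 2 * p2[mob, ] / dt^2; s$der3[mob, ] <- 6 * p3[mob, ] / dt^3
  f <- forces_fn(s)
  if (any(!is.finite(f[mob, ])))
    stop("non-finite forces in gear_step")
  a <- gear_alpha
  r2new <- f / state$mass * dt^2 / 2
  corr <- r2new - p2
  out <- state
  out$pos[mob, ] <- (p0 + a[1] * corr)[mob, ]
  out$vel[mob, ] <- ((p1 + a[2] * corr) / dt)[mob, ]
  out$acc[mob, ] <- (2 * r2new / dt^2)[mob, ]
  out$der3[mob, ] <- (6 * (p3 + a[4] * corr) / dt^3)[mob, ]
  out$der4[mob, ] <- (24 * (r4 + a[5] * corr) / dt^4)[mob, ]
  out
}

#' Blank integrator state
#'
#' @param pos n x 3 positions.
#' @param vel n x 3 velocities.
#' @param mass length-n masses.
#' @param mobile logical length-n.
#' @param forces_fn optional force function used to initialize the
#'   acceleration at t = 0 (recommended: a cold start with zero stored
#'   acceleration leaves a permanent O(a dt) velocity offset).
#' @return a state list for [gear_step()].
#' @export
gear_state <- function(pos, vel = 0 * pos, mass = rep(1, nrow(pos)),
                       mobile = rep(TRUE, nrow(pos)), forces_fn = NULL) {
  z <- matrix(0, nrow(pos), 3)
  st <- list(pos = pos, vel = vel, acc = z, der3 = z, der4 = z,
             mass = mass, mobile = mobile)
  if (!is.null(forces_fn)) st$acc <- forces_fn(st) / mass
  st
}

#' Generate an unsettled polydisperse microsphere bed
#'
#' Draws particle diameters i.i.d. uniform on
#' `[1 - dispersion, 1 + dispersion] * d_mean` and places the particles
#' uniformly at random, without overlap, in a periodic (x, y) box above the
#' bottom wall. The particle count is what a settled bed of `n_target_layers`
#' particle heights needs: `n_target_layers * floor(Lx/d) * floor(Ly/d)`.
#'
#' @param n_target_layers settled bed height in particle diameters (1, 3 or 5
#'   in the study design).
#' @param d_mean mean particle diameter (1 in dimensionless units).
#' @param dispersion half-width of the relative size dispersion (default 0.05).
#' @param box box dimensions `(Lx, Ly, Lz)`, default `(20, 20, 20) * d_mean`.
#' @param seed integer seed; the same seed reproduces the same bed exactly.
#' @param floor_height height of the bottom wall (particle centers stay above
#'   it; default `1 * d_mean`).
#' @return an unsettled `granulo_bed`.
#' @export
generate_particles <- function(n_target_layers = 3, d_mean = 1,
                               dispersion = 0.05, box = c(20, 20, 20) * d_mean,
                               seed = 1, floor_height = 1 * d_mean) {
  stopifnot(dispersion >= 0, dispersion <= 0.2, all(box > 2 * d_mean),
            n_target_layers >= 1)
  n <- n_target_layers * floor(box[1] / d_mean) * floor(box[2] / d_mean)
  with_seed(seed, {
    diam <- runif(n, (1 - dispersion) * d_mean, (1 + dispersion) * d_mean)
    pos <- matrix(NA_real_, n, 3)
    for (i in seq_len(n)) {
      placed <- FALSE
      for (try in seq_len(5000)) {
        p <- c(runif(1, 0, box[1]), runif(1, 0, box[2]),
               runif(1, floor_height + diam[i] / 2, box[3]))
        if (i == 1) { pos[i, ] <- p; placed <- TRUE; break }
        prev <- pos[seq_len(i - 1), , drop = FALSE]
        dx <- abs(prev[, 1] - p[1]); dx <- pmin(dx, box[1] - dx)
        dy <- abs(prev[, 2] - p[2]); dy <- pmin(dy, box[2] - dy)
        dz <- prev[, 3] - p[3]
        rsum <- (diam[seq_len(i - 1)] + diam[i]) / 2
        if (all(dx^2 + dy^2 + dz^2 > rsum^2)) { pos[i, ] <- p; placed <- TRUE; break }
      }
      if (!placed)
        stop("placement error: could not place particle ", i,
             " without overlap; box too small for the requested count")
    }
    new_bed(pos, diam, box, floor_height, d_mean, dispersion,
            n_target_layers, seed)
  })
}

new_bed <- function(pos, diam, box, floor_height, d_mean, dispersion,
                    target_layers, seed) {
  n <- nrow(pos)
  hd <- matrix(0, n, 9)
  hd[, 3] <- -1  # free bodies start in gravitational free fall (g = 1)
  structure(list(
    pos = pos, vel = matrix(0, n, 3), hd = hd,
    diameter = diam, rel_density = rep(1, n), mobile = rep(TRUE, n),
    box = box, floor_height = floor_height, d_mean = d_mean,
    dispersion = dispersion, target_layers = target_layers,
    relaxed = FALSE, seed = seed, n = n), class = "granulo_bed")
}

#' @export
print.granulo_bed <- function(x, ...) {
  cat(sprintf("<granulo_bed> %d particles, box %s, %s\n", x$n,
              paste(signif(x$box, 3), collapse = " x "),
              if (x$relaxed) "relaxed" else "unsettled"))
  invisible(x)
}

#' @export
as.data.frame.granulo_bed <- function(x, ...) {
  data.frame(x = x$pos[, 1], y = x$pos[, 2], z = x$pos[, 3],
             diameter = x$diameter, rel_density = x$rel_density,
             mobile = x$mobile)
}

# dimensionless effective (buoyant) weight multiplier for relative density r:
# rho_particle = r * rho_polystyrene, so the contrast scales as
# (1.07 r - 1)/0.07 relative to the polystyrene baseline
density_weight_factor <- function(rel_density,
                                  particle_density = 1070,
                                  fluid_density = 1000) {
  ifelse(is.infinite(rel_density), Inf,
         (rel_density * particle_density - fluid_density) /
           (particle_density - fluid_density))
}

#' Height of the bed above the bottom wall
#'
#' @param bed a `granulo_bed`.
#' @return max particle center height minus the floor height.
#' @export
bed_height <- function(bed) max(bed$pos[, 3]) - bed$floor_height

#' Settle a bed under gravity to a loose random packing
#'
#' Integrates the particles (4th-order Gear, hysteretic contacts, periodic
#' x/y, bottom wall) until the average kinetic energy per particle falls below
#' `ke_threshold`. Collisions are inelastic, so kinetic and potential energy
#' drain until the packing is at rest.
#'
#' @param bed a `granulo_bed` from [generate_particles()].
#' @param law a [contact_law()].
#' @param dt time step (default 5e-5).
#' @param ke_threshold relaxation criterion on the mean kinetic energy per
#'   particle (default 2e-3).
#' @param max_steps step budget; exceeding it raises a relaxation-failure
#'   error reporting the final kinetic energy.
#' @param check_every interval (steps) between convergence checks.
#' @return the settled bed with `relaxed = TRUE`.
#' @export
settle_bed <- function(bed, law = contact_law(), dt = 5e-5,
                       ke_threshold = 2e-3, max_steps = 3e6,
                       check_every = 200) {
  stopifnot(inherits(bed, "granulo_bed"), dt > 0)
  scene <- bed_scene(bed)
  out <- cpp_run_phase(scene, phase_params(
    phase = 0L, dt = dt, yu = law$Y_u, yl = law$Y_l,
    max_steps = max_steps, check_every = check_every,
    ke_threshold = ke_threshold))
  if (!out$converged)
    stop(sprintf(
      "relaxation failure: bed not settled after %g steps (KE/particle = %.3g)",
      out$steps, out$ke_avg))
  bed$pos <- out$pos; bed$vel <- out$vel; bed$hd <- out$hd
  bed$relaxed <- TRUE
  bed$settle_steps <- out$steps
  bed$final_ke <- out$ke_avg
  bed
}

#' Average kinetic energy per particle
#'
#' @param bed a `granulo_bed`.
#' @return mean of `m v^2 / 2` over particles, dimensionless.
#' @export
bed_kinetic_energy <- function(bed) {
  m <- bed$diameter^3 * density_weight_factor(bed$rel_density)
  m[!bed$mobile] <- 0  # immobile (sintered) particles do not move
  mean(ifelse(bed$mobile, 0.5 * m * rowSums(bed$vel^2), 0))
}
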