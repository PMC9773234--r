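#' Hexagonal three-shell cell template
#'
#' Element positions for the full spread cell in its local plane. The cell
#' starts as seven elements (a center and a hexagon) whose smallest enclosing
#' circle has diameter `L_i`; two further shells of 12 and 24 elements bring it
#' to 43 elements with enclosing diameter `L_f = 2 L_i`. Shell radii are
#' linearly interpolated between those two calibration points; each peripheral
#' element spawns two children at half its angular spacing.
#'
#' @param L_i initial cell diameter (dimensionless, in particle diameters).
#' @return list with `xy` (43 x 2 local coordinates), `layer` (0 = center,
#'   1..3 = shells), `parent` (spawning element index, NA for the first 7),
#'   `element_diameter` (`L_i/3`) and `springs0` (the 12 initial springs).
#' @export
cell_template <- function(L_i) {
  stopifnot(L_i > 0)
  d_e <- L_i / 3
  # enclosing-circle calibration: 2*(r1 + d_e/2) = L_i, 2*(r3 + d_e/2) = 2*L_i
  r1 <- L_i / 3
  r3 <- 5 * L_i / 6
  r2 <- (r1 + r3) / 2
  a1 <- (0:5) * pi / 3
  a2 <- rep(a1, each = 2) + rep(c(-1, 1) * pi / 12, 6)
  a3 <- rep(a2, each = 2) + rep(c(-1, 1) * pi / 24, 12)
  xy <- rbind(c(0, 0),
              cbind(r1 * cos(a1), r1 * sin(a1)),
              cbind(r2 * cos(a2), r2 * sin(a2)),
              cbind(r3 * cos(a3), r3 * sin(a3)))
  layer <- c(0L, rep(1L, 6), rep(2L, 12), rep(3L, 24))
  parent <- c(NA_integer_, rep(NA_integer_, 6),
              1L + rep(1:6, each = 2),        # shell 2 children of shell 1
              7L + rep(1:12, each = 2))       # shell 3 children of shell 2
  # initial springs: center-hexagon spokes and the hexagon ring
  ring1 <- 2:7
  springs0 <- rbind(cbind(1L, ring1),
                    cbind(ring1, c(ring1[-1], ring1[1])))
  list(xy = xy, layer = layer, parent = parent,
       element_diameter = d_e, springs0 = springs0,
       ring_angle = c(0, a1, a2, a3))
}

#' Diameter of the smallest enclosing circle of a set of elements
#'
#' Computed in the cell plane (x, y) about the element centroid axis: twice
#' the largest center distance from the cell center plus one element diameter,
#' matching the definition used to calibrate `L_i` and `L_f`.
#'
#' @param pos n x 2 or n x 3 element centers.
#' @param element_diameter common element diameter.
#' @param center optional center point (defaults to the first row).
#' @return the enclosing diameter.
#' @export
enclosing_diameter <- function(pos, element_diameter, center = pos[1, ]) {
  d <- sweep(pos[, 1:2, drop = FALSE], 2, center[1:2])
  2 * max(sqrt(rowSums(d^2))) + element_diameter
}

new_cell <- function(L_i, tmpl, pos, active, seed) {
  ne <- nrow(pos)
  k_s <- 6.25 * L_i^2
  c_s <- 6.25e-2 * L_i^2
  cell <- structure(list(
    L_i = L_i, L_f = 2 * L_i, diameter = tmpl$element_diameter,
    pos = pos, vel = matrix(0, ne, 3), hd = matrix(0, ne, 9),
    layer = tmpl$layer, parent = tmpl$parent, center = 1L,
    active = active, terminal = rep(FALSE, ne), fixed = rep(FALSE, ne),
    mass_scale = ifelse(active, 1, 1e-3),
    k_s = k_s, c_s = c_s,
    template_offsets = NULL, springs = NULL, tethers = NULL,
    adhesion = adhesion_params(L_i),
    bonds = empty_bonds(), events = empty_events(), seed = seed),
    class = "granulo_cell")
  cell
}

empty_bonds <- function() {
  data.frame(element = integer(0), particle = integer(0), dx = numeric(0),
             dy = numeric(0), dz = numeric(0), rest = numeric(0),
             k = numeric(0), c = numeric(0), state = character(0),
             bind_dist = numeric(0))
}
empty_events <- function() {
  data.frame(step = numeric(0), element = integer(0), particle = integer(0),
             event = character(0), force = numeric(0))
}

#' @export
print.granulo_cell <- function(x, ...) {
  cat(sprintf(
    "<granulo_cell> L_i = %.3g, %d/%d elements active, %d bonds (%d reinforced)\n",
    x$L_i, sum(x$active), length(x$active), nrow(x$bonds),
    sum(x$bonds$state == "reinforced")))
  invisible(x)
}

# spring rows: i, j, L0 (current), L0_init, k, c
make_springs <- function(pairs, pos, k, c) {
  L0 <- sqrt(rowSums((pos[pairs[, 1], , drop = FALSE] -
                        pos[pairs[, 2], , drop = FALSE])^2))
  cbind(i = pairs[, 1], j = pairs[, 2], L0 = L0, L0_init = L0, k = k, c = c)
}

#' Initialize a cell above a settled bed
#'
#' Builds the seven-element cell (full template precomputed; outer shells
#' inactive with mass reduced by 1e3 and tethered to their template sites) at
#' the drop position, rotated by a seeded random angle, and lets it fall
#' freely onto the bed. Free fall of the rigid template is integrated exactly:
#' the cell is advanced to the first element--microparticle (or floor) contact
#' with the corresponding impact velocity.
#'
#' @param L_i initial cell diameter in particle diameters.
#' @param drop_position length-2 (x, y) position inside the box.
#' @param bed a settled `granulo_bed`.
#' @param seed integer seed (in-plane orientation of the template).
#' @return a `granulo_cell` in first contact with the bed (no bonds yet; see
#'   [bind_on_contact()]).
#' @export
init_cell <- function(L_i, drop_position, bed, seed = 1) {
  stopifnot(L_i > 0)
  if (drop_position[1] < 0 || drop_position[1] > bed$box[1] ||
      drop_position[2] < 0 || drop_position[2] > bed$box[2])
    stop("drop position outside the box")
  tmpl <- cell_template(L_i)
  theta <- with_seed(seed, runif(1, 0, 2 * pi))
  rot <- matrix(c(cos(theta), sin(theta), -sin(theta), cos(theta)), 2, 2)
  off <- cbind(tmpl$xy %*% rot, 0)
  d_e <- tmpl$element_diameter
  z0 <- if (bed$n > 0) max(bed$pos[, 3] + bed$diameter / 2) + d_e / 2 + 0.5 * d_e
        else bed$floor_height + d_e / 2 + 2 * d_e
  pos <- cbind(drop_position[1] + off[, 1], drop_position[2] + off[, 2], z0)
  active <- tmpl$layer <= 1
  cell <- new_cell(L_i, tmpl, pos, active, seed)
  cell$template_offsets <- off
  cell$springs <- make_springs(tmpl$springs0, pos, cell$k_s, cell$c_s)
  inact <- which(!active)
  # fictitious tethers: translation-following anchors at the template sites,
  # stiffness k_s scaled with the 1e-3 mass reduction, critically damped
  k_t <- cell$k_s * 1e-3
  m_in <- d_e^3 * 1e-3
  cell$tethers <- cbind(i = inact,
                        off[inact, 1], off[inact, 2], off[inact, 3],
                        k = k_t, c = 2 * sqrt(k_t * m_in))
  drop_cell(cell, bed)
}

# exact rigid free fall to first contact: every active element accelerates
# identically (gravity only; springs at natural length, tethers co-moving), so
# the touchdown distance is pure geometry
drop_cell <- function(cell, bed) {
  act <- which(cell$active)
  r_e <- cell$diameter / 2
  drop <- Inf
  for (e in act) {
    p <- cell$pos[e, ]
    # floor touchdown
    drop <- min(drop, p[3] - r_e - bed$floor_height)
    if (bed$n == 0) next
    dx <- abs(bed$pos[, 1] - p[1]); dx <- pmin(dx, bed$box[1] - dx)
    dy <- abs(bed$pos[, 2] - p[2]); dy <- pmin(dy, bed$box[2] - dy)
    rsum <- (bed$diameter + cell$diameter) / 2
    h2 <- dx^2 + dy^2
    hit <- h2 < rsum^2
    if (any(hit)) {
      dz <- (p[3] - bed$pos[hit, 3]) - sqrt(rsum[hit]^2 - h2[hit])
      drop <- min(drop, dz[dz > -1e-9])
    }
  }
  if (!is.finite(drop)) stop("cell cannot reach the bed")
  drop <- max(drop, 0)
  cell$pos[, 3] <- cell$pos[, 3] - drop
  cell$vel[, 3] <- -sqrt(2 * drop)   # g = 1
  cell$hd[, 3] <- -1                 # gravitational acceleration
  cell
}

#' Activate the next shell of elements
#'
#' Stretching half-cycle: the next shell's elements are switched from their
#' tethered, mass-reduced standby state to full mass at their current
#' positions; each is connected by structural springs to its spawning
#' (parent) element and to its activated ring neighbors, with natural lengths
#' taken from the template. Terminal parents (whose adhesion broke) spawn
#' nothing: the cell has stopped spreading in those directions.
#'
#' @param cell a bonded `granulo_cell`.
#' @return the cell with the new shell active (unchanged if every parent is
#'   terminal).
#' @export
add_layer <- function(cell) {
  outer <- max(cell$layer[cell$active])
  if (outer >= 3) stop("cell already has three shells")
  if (nrow(cell$bonds) == 0)
    stop("unbonded cell: spreading requires at least one bond")
  nxt <- outer + 1L
  cand <- which(cell$layer == nxt & !cell$terminal[cell$parent])
  if (length(cand) == 0) return(cell)
  cell$active[cand] <- TRUE
  cell$mass_scale[cand] <- 1
  keep <- !(cell$tethers[, 1] %in% cand)
  cell$tethers <- cell$tethers[keep, , drop = FALSE]
  tmpl <- cell_template(cell$L_i)
  # parent spokes
  pairs <- cbind(cand, cell$parent[cand])
  # ring adjacency: consecutive activated neighbors in template angular order
  ring <- which(cell$layer == nxt)
  ring <- ring[order(tmpl$ring_angle[ring])]
  nr <- length(ring)
  adj <- cbind(ring, ring[c(2:nr, 1)])
  adj <- adj[adj[, 1] %in% cand & adj[, 2] %in% cand, , drop = FALSE]
  pairs <- rbind(pairs, adj)
  # natural lengths from the template geometry, not the draped positions
  tpos <- cbind(tmpl$xy, 0)
  cell$springs <- rbind(cell$springs,
                        make_springs(pairs, tpos, cell$k_s, cell$c_s))
  cell
}

#' Relax the cell (and mobile bed) to mechanical equilibrium
#'
#' Integrates until the largest net force on any active, unfrozen element
#' falls below the tolerance. Newly contacting element--particle pairs are
#' bound afterwards, so the bond set is current when the next half-cycle
#' starts.
#'
#' @param cell,bed the cell and settled bed.
#' @param dt time step.
#' @param force_tolerance absolute force tolerance; default `NULL` means
#'   2 percent of an active element's buoyant weight.
#' @param max_steps step budget.
#' @param on_fail `"error"` (default) or `"warn"` when the budget is exhausted
#'   before convergence.
#' @param drag weak global viscous drag rate (per unit time, x mass) used to
#'   seek the equilibrium faster; it vanishes at the converged state and does
#'   not change it.
#' @return list with updated `cell`, `bed` and an `info` list (steps taken,
#'   residual force).
#' @export
relax_layer <- function(cell, bed, dt = 5e-5, force_tolerance = NULL,
                        max_steps = 1.5e5, on_fail = c("error", "warn"),
                        drag = 2) {
  on_fail <- match.arg(on_fail)
  watch <- which(cell$active)
  tol <- if (is.null(force_tolerance)) 0.02 * cell$diameter^3
         else force_tolerance
  res <- run_cell_phase(bed, cell, phase_params(
    phase = 2L, dt = dt, max_steps = max_steps,
    watch = watch + bed$n, watch_tol = rep(tol, length(watch)),
    check_every = 100L, drag = drag))
  if (!res$info$converged) {
    msg <- sprintf(
      "cell relaxation did not converge in %g steps (max net force %.3g > %.3g)",
      res$info$steps, res$info$max_watch_force, tol)
    if (on_fail == "error") stop(msg) else warning(msg)
  }
  res$cell <- bind_on_contact(res$cell, res$bed)
  res
}

#' Contraction half-cycle
#'
#' Shrinks the natural length of every structural spring at a steady rate
#' while integrating the dynamics; the adhesion state machine (reinforcement
#' above the force threshold, detachment beyond the contraction-distance
#' threshold) runs every step. With `shrink_rate = NULL` (default) each
#' spring's rate is set so all natural lengths reach zero together after
#' `n_steps`; a scalar `shrink_rate` applies one absolute rate to all springs
#' and runs for `ceiling(max(L0)/(shrink_rate * dt))` steps. After the shrink
#' schedule the phase dwells (tension persists once natural lengths are zero)
#' until the adhesion cascade stops: segments of `dwell_steps` steps are run
#' until one passes without a binding event, up to `max_dwell` extra steps, so
#' the outcome is the quasi-static fixed point rather than an artifact of the
#' schedule length.
#'
#' @param cell,bed the cell and bed.
#' @param shrink_rate optional scalar natural-length shrink rate (length per
#'   time).
#' @param dt time step.
#' @param n_steps contraction duration in steps (default 1e5).
#' @param dwell_steps,max_dwell post-schedule dwell segment length and budget.
#' @return list with updated `cell`, `bed`, `info`.
#' @export
contract <- function(cell, bed, shrink_rate = NULL, dt = 5e-5,
                     n_steps = 1e5, dwell_steps = 2e4, max_dwell = 4e5) {
  # bindings are recalculated before each cycle: the detachment clock runs
  # from the relaxed state at the start of this contraction, not from the
  # moment of first touch
  if (nrow(cell$bonds) > 0) {
    b <- cell$bonds
    dre <- bed$pos[b$particle, , drop = FALSE] - cell$pos[b$element, , drop = FALSE]
    for (d in 1:2) dre[, d] <- dre[, d] - bed$box[d] * round(dre[, d] / bed$box[d])
    cell$bonds$dx <- dre[, 1]; cell$bonds$dy <- dre[, 2]; cell$bonds$dz <- dre[, 3]
    cell$bonds$rest <- sqrt(rowSums(dre^2))
    dc <- cell$pos[b$element, , drop = FALSE] -
      matrix(cell$pos[cell$center, ], nrow(b), 3, byrow = TRUE)
    for (d in 1:2) dc[, d] <- dc[, d] - bed$box[d] * round(dc[, d] / bed$box[d])
    cell$bonds$bind_dist <- sqrt(rowSums(dc^2))
  }
  L0 <- cell$springs[, 3]
  if (is.null(shrink_rate)) {
    rates <- L0 / (n_steps * dt)
  } else {
    stopifnot(shrink_rate > 0)
    rates <- rep(shrink_rate, length(L0))
    n_steps <- if (length(L0) > 0) ceiling(max(L0) / (shrink_rate * dt)) else 0
  }
  if (n_steps == 0) return(list(cell = cell, bed = bed, info = list(steps = 0)))
  ad <- cell$adhesion
  pars <- phase_params(
    phase = 3L, dt = dt, max_steps = n_steps, shrink = rates,
    watch = which(cell$active) + bed$n,
    watch_tol = numeric(sum(cell$active)),
    detach_dist = ad$detachment_fraction * cell$L_i,
    f_threshold = ad$reinforcement_threshold,
    adhesion = TRUE, check_every = 500L)
  res <- run_cell_phase(bed, cell, pars)
  steps <- res$info$steps
  n_events <- nrow(res$cell$events)
  pars$shrink <- numeric(0)
  pars$max_steps <- dwell_steps
  while (steps < n_steps + max_dwell) {
    before <- nrow(res$cell$events)
    res <- run_cell_phase(res$bed, res$cell, pars, step_offset = steps)
    steps <- steps + res$info$steps
    if (nrow(res$cell$events) == before) break  # cascade has stopped
  }
  res$info$steps <- steps
  res
}

#' Viscoelastic structural spring force
#'
#' Force pair for one spring: elastic restoring force on the extension from
#' the (possibly contracted) natural length plus damping on the relative
#' velocity along the spring axis. Equal and opposite on the two elements.
#'
#' @param spring list or named vector with `L0`, `k`, `c`.
#' @param pos_i,pos_j,vel_i,vel_j endpoint states (length-3).
#' @return 2 x 3 matrix: force on `i` (row 1) and on `j` (row 2).
#' @export
structural_force <- function(spring, pos_i, pos_j,
                             vel_i = c(0, 0, 0), vel_j = c(0, 0, 0)) {
  dr <- pos_j - pos_i
  L <- sqrt(sum(dr^2))
  if (L < 1e-12) stop("degenerate geometry: coincident spring endpoints")
  nv <- dr / L
  ext <- L - spring[["L0"]]
  vrel <- sum((vel_j - vel_i) * nv)
  fmag <- spring[["k"]] * ext + spring[["c"]] * vrel
  rbind(fmag * nv, -fmag * nv)
}
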