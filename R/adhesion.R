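#' Adhesion parameters for a cell of initial diameter L_i
#'
#' The three binding/unbinding mechanisms are parameterized by the maximum
#' cell force `F_max` (the buoyant weight of a baseline sphere of diameter
#' `(82/32) L_i`; about 200 pN for a 32 um cell): binding springs have elastic
#' constant `F_max / (2.5e-5 L_i)` -- so the spring transmits the full maximum
#' force at a stretch of 0.0025 percent of `L_i`, far below the detachment
#' threshold -- and damping constant `F_max / (1.25e-2 L_i)`; reinforcement
#' triggers when a binding spring's elastic force reaches `F_max`; detachment
#' triggers when a bonded element has moved toward the cell center by more
#' than 4 percent of the initial cell diameter (the distance a cell
#' contracting at 110 nm/s covers within the 2-4 s integrin engagement
#' lifetime) since the bindings were last recalculated. The experimental integrin
#' engagement lifetime (2-4 s) and contraction speed (110 nm/s) are carried
#' for reference only: their product is folded into the 4 percent distance
#' threshold, so no wall-clock mapping enters the model.
#'
#' @param L_i initial cell diameter (dimensionless).
#' @param detachment_fraction fractional contraction threshold (default 0.04).
#' @return object of class `granulo_adhesion`.
#' @export
adhesion_params <- function(L_i, detachment_fraction = 0.04) {
  F_max <- max_cell_force_dimless(L_i)
  p <- list(F_max = F_max,
            k_b = F_max / (2.5e-5 * L_i),
            c_b = F_max / (1.25e-2 * L_i),
            reinforcement_threshold = F_max,
            detachment_fraction = detachment_fraction,
            max_spring_displacement = 2.5e-5 * L_i,
            engagement_lifetime = c(2, 4),       # seconds, informational
            contraction_velocity = 110e-9)       # m/s, informational
  # the binding spring must saturate before the unbinding threshold
  stopifnot(p$max_spring_displacement < detachment_fraction * L_i)
  class(p) <- "granulo_adhesion"
  p
}

#' Instantaneous integrin binding on contact
#'
#' Creates an engaged bond for every unbonded, non-terminal active element
#' that overlaps a microparticle: one binding spring per element, to the
#' particle with the deepest overlap (at most one bond per element--particle
#' pair; several elements may share a particle). Terminal elements --
#' directions where adhesion already failed -- do not re-engage. The bond
#' records the center-to-center rest length and the element's current distance
#' to the center element, the reference for the detachment criterion.
#'
#' @param cell a `granulo_cell`.
#' @param bed a `granulo_bed`.
#' @return the cell with an updated bond table.
#' @export
bind_on_contact <- function(cell, bed) {
  if (bed$n == 0) return(cell)
  act <- setdiff(which(cell$active & !cell$terminal), cell$bonds$element)
  if (length(act) == 0) return(cell)
  ad <- cell$adhesion
  ctr <- cell$pos[cell$center, ]
  # candidate contacts: all overlapping (element, particle) pairs
  cand <- list()
  for (e in act) {
    p <- cell$pos[e, ]
    dx <- bed$pos[, 1] - p[1]; dx <- dx - bed$box[1] * round(dx / bed$box[1])
    dy <- bed$pos[, 2] - p[2]; dy <- dy - bed$box[2] * round(dy / bed$box[2])
    dz <- bed$pos[, 3] - p[3]
    rsum <- (bed$diameter + cell$diameter) / 2
    d2 <- dx^2 + dy^2 + dz^2
    hit <- which(d2 <= rsum^2)
    if (length(hit) > 0)
      cand[[length(cand) + 1L]] <- data.frame(
        element = e, particle = hit, dx = dx[hit], dy = dy[hit], dz = dz[hit],
        overlap = rsum[hit] - sqrt(d2[hit]))
  }
  if (length(cand) == 0) return(cell)
  cand <- do.call(rbind, cand)
  # one binding spring per element, to its deepest-overlap particle
  cand <- cand[order(-cand$overlap), ]
  new <- list()
  for (i in seq_len(nrow(cand))) {
    e <- cand$element[i]; pp <- cand$particle[i]
    if (e %in% vapply(new, function(x) x$element, 1L)) next
    dc <- cell$pos[e, ] - ctr
    dc[1] <- dc[1] - bed$box[1] * round(dc[1] / bed$box[1])
    dc[2] <- dc[2] - bed$box[2] * round(dc[2] / bed$box[2])
    new[[length(new) + 1L]] <- data.frame(
      element = e, particle = pp,
      dx = cand$dx[i], dy = cand$dy[i], dz = cand$dz[i],
      rest = sqrt(cand$dx[i]^2 + cand$dy[i]^2 + cand$dz[i]^2),
      k = ad$k_b, c = ad$c_b, state = "engaged",
      bind_dist = sqrt(sum(dc^2)))
  }
  add <- do.call(rbind, new)
  if (!is.null(add)) cell$bonds <- rbind(cell$bonds, add)
  cell
}

#' Binding-spring force
#'
#' Viscoelastic force pair transmitted by one engaged (or reinforced) bond.
#'
#' @param bond one row of a cell's bond table (list-like with `rest`, `k`,
#'   `c`, `state`).
#' @param pos_e,pos_p element and particle centers.
#' @param vel_e,vel_p velocities.
#' @return 2 x 3 matrix: force on the element (row 1) and particle (row 2).
#' @export
bond_force <- function(bond, pos_e, pos_p,
                       vel_e = c(0, 0, 0), vel_p = c(0, 0, 0)) {
  if (bond[["state"]] == "broken") stop("bond is broken")
  structural_force(list(L0 = bond[["rest"]], k = bond[["k"]], c = bond[["c"]]),
                   pos_e, pos_p, vel_e, vel_p)
}

#' Talin-like adhesion reinforcement
#'
#' An engaged bond whose elastic force reaches the threshold (the maximum cell
#' force) is reinforced instantaneously: the bond becomes permanent and both
#' the element and the bonded microparticle are frozen in place.
#'
#' @param cell,bed cell and bed.
#' @param threshold force threshold (defaults to the cell's `F_max`).
#' @return list with updated `cell` and `bed`.
#' @export
check_reinforcement <- function(cell, bed,
                                threshold = cell$adhesion$reinforcement_threshold) {
  b <- cell$bonds
  eng <- which(b$state == "engaged")
  for (i in eng) {
    dr <- bed$pos[b$particle[i], ] - cell$pos[b$element[i], ]
    dr[1] <- dr[1] - bed$box[1] * round(dr[1] / bed$box[1])
    dr[2] <- dr[2] - bed$box[2] * round(dr[2] / bed$box[2])
    # elastic force of the anchor-to-anchor spring: stiffness times the
    # displacement of the relative position from its at-binding value
    fel <- b$k[i] * sqrt(sum((dr - c(b$dx[i], b$dy[i], b$dz[i]))^2))
    if (fel >= threshold) {
      cell$bonds$state[i] <- "reinforced"
      e <- b$element[i]; p <- b$particle[i]
      cell$fixed[e] <- TRUE
      cell$vel[e, ] <- 0; cell$hd[e, ] <- 0
      bed$mobile[p] <- FALSE
      bed$vel[p, ] <- 0; bed$hd[p, ] <- 0
      cell$events <- rbind(cell$events, data.frame(
        step = NA_real_, element = e, particle = p,
        event = "reinforce", force = fel))
    }
  }
  list(cell = cell, bed = bed)
}

#' Contraction-distance detachment
#'
#' An engaged bond breaks once its element has moved toward the cell center
#' by more than `detachment_fraction * L_i` from its distance at binding
#' time; the element is marked terminal and the cell stops spreading in that
#' direction. Reinforced bonds never break.
#'
#' @param cell a `granulo_cell`.
#' @param box optional box for the periodic center distance (defaults to no
#'   wrapping).
#' @return the cell with broken bonds removed and terminals marked.
#' @export
check_detachment <- function(cell, box = NULL) {
  b <- cell$bonds
  frac <- cell$adhesion$detachment_fraction
  ctr <- cell$pos[cell$center, ]
  drop <- logical(nrow(b))
  for (i in which(b$state == "engaged")) {
    e <- b$element[i]
    if (e == cell$center || b$bind_dist[i] <= 0) next
    dc <- cell$pos[e, ] - ctr
    if (!is.null(box)) {
      dc[1] <- dc[1] - box[1] * round(dc[1] / box[1])
      dc[2] <- dc[2] - box[2] * round(dc[2] / box[2])
    }
    if (sqrt(sum(dc^2)) < b$bind_dist[i] - frac * cell$L_i) {
      drop[i] <- TRUE
      cell$terminal[e] <- TRUE
      cell$events <- rbind(cell$events, data.frame(
        step = NA_real_, element = e, particle = b$particle[i],
        event = "break", force = NA_real_))
    }
  }
  cell$bonds <- b[!drop, , drop = FALSE]
  cell
}
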