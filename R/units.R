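#' Unit system for dimensionless <-> experimental conversions
#'
#' The simulation is dimensionless: lengths are measured in mean microparticle
#' diameters, the gravitational acceleration is `gravity_dimless` (1 by
#' default), and forces in buoyant weights of a mean-diameter baseline
#' (polystyrene-in-water) particle. A `unit_system` fixes the physical scale:
#' the length unit (mean particle diameter in meters), the baseline
#' particle--fluid density contrast, and physical gravity. The time unit is
#' derived as `sqrt(length_unit * gravity_dimless / gravity_phys)` so that the
#' dimensionless gravitational acceleration equals `gravity_dimless`.
#'
#' @param length_unit meters per dimensionless length (mean microparticle
#'   diameter). Default 32 um, the estimated initial diameter of a human
#'   adipose-derived stem cell, i.e. an aspect ratio of 1.
#' @param particle_density baseline particle density in kg m^-3 (polystyrene,
#'   1070).
#' @param fluid_density suspending fluid density in kg m^-3 (water, 1000).
#' @param gravity_phys physical gravitational acceleration, m s^-2.
#' @param gravity_dimless dimensionless gravitational acceleration (default 1).
#' @return an object of class `granulo_units` with derived `time_unit`,
#'   `mass_unit` (effective, buoyancy-reduced mass of a mean-diameter baseline
#'   particle) and `force_unit` (its buoyant weight).
#' @examples
#' us <- unit_system()
#' to_dimensionless(82e-6, "length", us)   # 82 um in particle diameters
#' @export
unit_system <- function(length_unit = 32e-6, particle_density = 1070,
                        fluid_density = 1000, gravity_phys = 9.81,
                        gravity_dimless = 1) {
  stopifnot(length_unit > 0, gravity_phys > 0, gravity_dimless > 0,
            particle_density >= 0, fluid_density >= 0,
            particle_density > fluid_density)
  eff <- particle_density - fluid_density
  time_unit <- sqrt(length_unit * gravity_dimless / gravity_phys)
  mass_unit <- pi / 6 * length_unit^3 * eff
  us <- list(length_unit = length_unit,
             particle_density = particle_density,
             fluid_density = fluid_density,
             effective_density_unit = eff,
             gravity_phys = gravity_phys,
             gravity_dimless = gravity_dimless,
             time_unit = time_unit,
             mass_unit = mass_unit,
             force_unit = mass_unit * gravity_phys / gravity_dimless)
  class(us) <- "granulo_units"
  us
}

#' @export
print.granulo_units <- function(x, ...) {
  cat("<granulo_units>\n")
  cat(sprintf("  length unit: %.4g m   time unit: %.4g s\n",
              x$length_unit, x$time_unit))
  cat(sprintf("  density contrast: %.4g kg/m^3   force unit: %.4g N\n",
              x$effective_density_unit, x$force_unit))
  invisible(x)
}

#' Buoyant weight of a sphere
#'
#' Gravitational force on a submerged sphere minus the displaced-fluid force:
#' `(pi/6) d^3 (rho_p - rho_f) g`. This is the force a cell must exert to lift
#' a microparticle out of the packing, and the basis of the maximum-cell-force
#' calibration (a 82 um polystyrene sphere in water weighs about 200 pN).
#'
#' @param diameter sphere diameter (m). May be a vector.
#' @param particle_density sphere density (kg m^-3).
#' @param fluid_density fluid density (kg m^-3).
#' @param g gravitational acceleration (m s^-2).
#' @return force in newtons; negative when the sphere is lighter than the
#'   fluid.
#' @examples
#' buoyant_weight(82e-6, 1070, 1000) / 1e-12  # about 200 pN
#' @export
buoyant_weight <- function(diameter, particle_density, fluid_density,
                           g = 9.81) {
  if (any(diameter < 0)) stop("diameter must be non-negative")
  if (any(particle_density < 0) || any(fluid_density < 0))
    stop("densities must be non-negative")
  pi / 6 * diameter^3 * (particle_density - fluid_density) * g
}

#' Maximum force a cell can exert
#'
#' Calibrated from the observation that a cell of diameter 32 um exerts at most
#' about 200 pN, the buoyant weight of an 82 um polystyrene sphere in water:
#' the maximum force for a cell of initial diameter `L_i` is the buoyant weight
#' of a baseline-density sphere of diameter `(82/32) L_i`, hence it scales with
#' the cube of the cell size.
#'
#' @param L_i initial cell diameter, in meters (or any length unit; the result
#'   is then in the corresponding force unit given the densities in `units`).
#' @param units a [unit_system()] supplying the baseline densities and gravity.
#' @return maximum cell force in newtons (for `L_i` in meters).
#' @examples
#' max_cell_force(32e-6) / 1e-12  # about 200 pN
#' @export
max_cell_force <- function(L_i, units = unit_system()) {
  if (any(L_i <= 0)) stop("L_i must be positive")
  buoyant_weight(82 / 32 * L_i, units$particle_density, units$fluid_density,
                 units$gravity_phys)
}

# dimensionless maximum cell force for a cell of diameter L_i (in particle
# diameters): buoyant weights cancel to a pure cube
max_cell_force_dimless <- function(L_i) (82 / 32 * L_i)^3

unit_for_kind <- function(quantity_kind, units) {
  switch(quantity_kind,
         length = units$length_unit,
         time = units$time_unit,
         mass = units$mass_unit,
         force = units$force_unit,
         velocity = units$length_unit / units$time_unit,
         energy = units$force_unit * units$length_unit,
         stop("unknown quantity_kind: ", quantity_kind))
}

#' Convert between physical and dimensionless quantities
#'
#' @param value numeric value(s).
#' @param quantity_kind one of `"length"`, `"time"`, `"mass"`, `"force"`,
#'   `"velocity"`, `"energy"`.
#' @param units a [unit_system()].
#' @return converted value(s); `to_physical(to_dimensionless(x))` is the
#'   identity.
#' @export
to_dimensionless <- function(value, quantity_kind, units = unit_system()) {
  value / unit_for_kind(quantity_kind, units)
}

#' @rdname to_dimensionless
#' @export
to_physical <- function(value, quantity_kind, units = unit_system()) {
  value * unit_for_kind(quantity_kind, units)
}
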