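#' Default simulation parameters
#'
#' Full parameter set with the model's published defaults: time step 5e-5,
#' contact stiffnesses 5e4/5e3 per diameter, kinetic-energy relaxation
#' threshold 2e-3, (20 d)^3 box with 5 percent size dispersion, structural
#' springs 6.25 L_i^2 with damping 6.25e-2 L_i^2, and the 4 percent
#' detachment threshold.
#'
#' @return nested list with sections `units`, `bed`, `cell`, `adhesion`,
#'   `sweep`.
#' @export
default_config <- function() {
  list(
    units = list(length_unit = 32e-6, particle_density = 1070,
                 fluid_density = 1000, gravity_phys = 9.81),
    bed = list(box = c(20, 20, 20), d_mean = 1, dispersion = 0.05,
               target_layers = 3, Y_u = 5e4, Y_l = 5e3, dt = 5e-5,
               ke_threshold = 2e-3, floor_height = 1, max_steps = 3e6),
    cell = list(aspect_ratio = 1, contraction_steps = 1e5,
                relax_max_steps = 2e5, force_tolerance = NULL,
                mobility_radius = NULL),
    adhesion = list(detachment_fraction = 0.04),
    sweep = list(ratios = c(0.5, 1, 2), densities = 1, layers = 3,
                 n_positions = 16, n_beds = 10, master_seed = 1))
}

config_ranges <- list(
  bed.dispersion = c(0, 0.2), bed.dt = c(1e-9, 1e-2),
  bed.ke_threshold = c(0, Inf), bed.target_layers = c(1, 10),
  adhesion.detachment_fraction = c(0, 0.5),
  cell.aspect_ratio = c(0.01, 100))

#' Load (and validate) a configuration file
#'
#' YAML file with sections `units`, `bed`, `cell`, `adhesion`, `sweep`;
#' omitted keys take the published defaults, unknown keys and out-of-range
#' values raise a validation error naming the offending keys.
#'
#' @param path file path.
#' @return validated nested parameter list.
#' @export
load_config <- function(path) {
  user <- if (is.null(path)) list() else yaml::read_yaml(path)
  validate_config(user)
}

validate_config <- function(user) {
  base <- default_config()
  bad <- character(0)
  for (sec in names(user)) {
    if (!sec %in% names(base)) { bad <- c(bad, sec); next }
    for (key in names(user[[sec]]))
      if (!key %in% names(base[[sec]])) bad <- c(bad, paste(sec, key, sep = "."))
  }
  if (length(bad) > 0)
    stop("unknown configuration keys: ", paste(bad, collapse = ", "))
  cfg <- base
  for (sec in names(user))
    cfg[[sec]] <- modifyList(cfg[[sec]], user[[sec]], keep.null = TRUE)
  oor <- character(0)
  for (key in names(config_ranges)) {
    parts <- strsplit(key, ".", fixed = TRUE)[[1]]
    val <- cfg[[parts[1]]][[parts[2]]]
    rng <- config_ranges[[key]]
    if (!is.null(val) && (any(val < rng[1]) || any(val > rng[2])))
      oor <- c(oor, key)
  }
  if (cfg$bed$dt <= 0) oor <- c(oor, "bed.dt")
  if (length(oor) > 0)
    stop("configuration values out of range: ", paste(unique(oor), collapse = ", "))
  cfg
}

#' Save a configuration file
#'
#' @param config nested parameter list (as from [load_config()]).
#' @param path output path.
#' @export
save_config <- function(config, path) {
  yaml::write_yaml(config, path)
  invisible(path)
}

#' Write a particle/element snapshot as extended XYZ
#'
#' One record per body: species (`P` microparticle / `E` cell element),
#' position, diameter, layer index (-1 for particles), relative density and
#' mobility flag; the comment line carries the box as a `Lattice` entry.
#' Values are written with full double precision and read back exactly.
#'
#' @param bed a `granulo_bed` (or `NULL`).
#' @param path output path.
#' @param cell optional `granulo_cell` appended to the record.
#' @param append append as an additional frame.
#' @export
write_xyz <- function(bed, path, cell = NULL, append = FALSE) {
  rows <- character(0)
  box <- if (!is.null(bed)) bed$box else c(0, 0, 0)
  if (!is.null(bed) && bed$n > 0)
    rows <- sprintf("P %.17g %.17g %.17g %.17g %d %.17g %d",
                    bed$pos[, 1], bed$pos[, 2], bed$pos[, 3], bed$diameter,
                    -1L, ifelse(is.finite(bed$rel_density), bed$rel_density, -1),
                    as.integer(bed$mobile))
  if (!is.null(cell))
    rows <- c(rows, sprintf("E %.17g %.17g %.17g %.17g %d %.17g %d",
                            cell$pos[, 1], cell$pos[, 2], cell$pos[, 3],
                            rep(cell$diameter, nrow(cell$pos)), cell$layer,
                            1, as.integer(cell$active)))
  hdr <- c(length(rows), sprintf(
    'Lattice="%.17g 0 0 0 %.17g 0 0 0 %.17g" Properties=species:S:1:pos:R:3:diameter:R:1:layer:I:1:rel_density:R:1:flag:I:1',
    box[1], box[2], box[3]))
  con <- file(path, if (append) "a" else "w")
  writeLines(c(hdr, rows), con)
  close(con)
  invisible(path)
}

#' Read an extended-XYZ snapshot
#'
#' @param path file written by [write_xyz()].
#' @return list with a `bodies` data frame (species, position, diameter,
#'   layer, rel_density, flag) and the `box`.
#' @export
read_xyz <- function(path) {
  lines <- readLines(path)
  n <- as.integer(lines[1])
  box <- as.numeric(strsplit(sub('.*Lattice="([^"]*)".*', "\\1", lines[2]),
                             " +")[[1]])[c(1, 5, 9)]
  if (n == 0)
    return(list(bodies = data.frame(), box = box))
  f <- strsplit(lines[2 + seq_len(n)], " +")
  m <- do.call(rbind, f)
  list(bodies = data.frame(
    species = m[, 1],
    x = as.numeric(m[, 2]), y = as.numeric(m[, 3]), z = as.numeric(m[, 4]),
    diameter = as.numeric(m[, 5]), layer = as.integer(m[, 6]),
    rel_density = as.numeric(m[, 7]), flag = as.integer(m[, 8])),
    box = box)
}

#' Write a legacy-VTK point snapshot
#'
#' ASCII VTK PolyData points with the diameter as point data, for quick
#' visualization in ParaView-like tools.
#'
#' @param bed a `granulo_bed`.
#' @param path output path.
#' @param cell optional cell appended.
#' @export
write_vtk <- function(bed, path, cell = NULL) {
  pos <- bed$pos; diam <- bed$diameter
  if (!is.null(cell)) {
    pos <- rbind(pos, cell$pos)
    diam <- c(diam, rep(cell$diameter, nrow(cell$pos)))
  }
  n <- nrow(pos)
  con <- file(path, "w")
  writeLines(c("# vtk DataFile Version 3.0", "granulocell snapshot", "ASCII",
               "DATASET POLYDATA", sprintf("POINTS %d double", n),
               sprintf("%.17g %.17g %.17g", pos[, 1], pos[, 2], pos[, 3]),
               sprintf("POINT_DATA %d", n), "SCALARS diameter double 1",
               "LOOKUP_TABLE default", sprintf("%.17g", diam)), con)
  close(con)
  invisible(path)
}

#' Small deterministic test scenes
#'
#' Prefabricated fixtures used by the test suite and examples:
#' `two_particle_collision` (a mobile particle falling onto a fixed one, for
#' restitution measurements), `three_particle_pocket` (three mutually touching
#' immobile spheres forming a binding pocket), `flat_rigid_plane` (an empty
#' box: the bottom wall only) and `mini_bed_4x4` (an unsettled 16-particle
#' single-layer bed).
#'
#' @param name fixture name.
#' @param seed integer seed.
#' @return a list with a `granulo_bed` (`$bed`) plus fixture-specific extras.
#' @export
make_fixture <- function(name = c("two_particle_collision",
                                  "three_particle_pocket",
                                  "flat_rigid_plane", "mini_bed_4x4"),
                         seed = 1) {
  name <- match.arg(name)
  switch(name,
    two_particle_collision = {
      h <- with_seed(seed, runif(1, 1.5, 2.5))
      bed <- new_bed(pos = rbind(c(2, 2, 2), c(2, 2, 2 + h)),
                     diam = c(1, 1), box = c(4, 4, 10), floor_height = 0.5,
                     d_mean = 1, dispersion = 0, target_layers = 1, seed = seed)
      bed$mobile <- c(FALSE, TRUE)
      list(bed = bed, drop_height = h)
    },
    three_particle_pocket = {
      ctr <- c(2, 2)
      ang <- pi / 2 + (0:2) * 2 * pi / 3
      pos <- cbind(ctr[1] + cos(ang) / sqrt(3), ctr[2] + sin(ang) / sqrt(3), 2)
      bed <- new_bed(pos = pos, diam = rep(1, 3), box = c(4, 4, 10),
                     floor_height = 0.5, d_mean = 1, dispersion = 0,
                     target_layers = 1, seed = seed)
      bed$mobile <- rep(FALSE, 3)
      bed$relaxed <- TRUE
      list(bed = bed, drop_position = ctr)
    },
    flat_rigid_plane = {
      bed <- new_bed(pos = matrix(numeric(0), 0, 3), diam = numeric(0),
                     box = c(6, 6, 10), floor_height = 1, d_mean = 1,
                     dispersion = 0, target_layers = 0, seed = seed)
      bed$relaxed <- TRUE
      list(bed = bed, drop_position = c(3, 3))
    },
    mini_bed_4x4 = {
      list(bed = generate_particles(1, 1, 0.05, box = c(4, 4, 8), seed = seed,
                                    floor_height = 1))
    })
}

#' Run manifest
#'
#' Records everything needed to reproduce a sweep bit-for-bit: the full
#' parameter set, the resolved per-sample seed tree, the package version and a
#' timestamp.
#'
#' @param config nested parameter list (see [default_config()]).
#' @param path optional JSON output path.
#' @return the manifest list (invisibly if written).
#' @export
run_manifest <- function(config = default_config(), path = NULL) {
  sw <- config$sweep
  seeds <- expand.grid(bed = seq_len(sw$n_beds), drop = seq_len(sw$n_positions))
  seeds$seed <- mapply(function(b, d) derive_seed(sw$master_seed, b, d),
                       seeds$bed, seeds$drop)
  man <- list(package = "granulocell",
              version = as.character(utils::packageVersion("granulocell")),
              timestamp = format(Sys.time(), tz = "UTC"),
              config = config, sample_seeds = seeds)
  if (!is.null(path)) {
    jsonlite::write_json(man, path, auto_unbox = TRUE, digits = NA,
                         pretty = TRUE)
    return(invisible(man))
  }
  man
}
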