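#' Scenario configuration
#'
#' Collects the parameters of one simulated condition. The study design
#' crosses the cell--microparticle aspect ratio `L_i/d` with the particle
#' relative density (1 = polystyrene, 2 = glass, `Inf` = sintered/immobile)
#' and the bed layer count, with `n_drop_positions * n_bed_configs` replicates
#' per condition (16 x 10 = 160 in the full design).
#'
#' @param aspect_ratio cell-to-particle size ratio `L_i/d`.
#' @param relative_density particle density relative to polystyrene; `Inf`
#'   makes every particle immobile (sintered limit).
#' @param bed_layers settled bed height in particle diameters (1, 3 or 5).
#' @param n_drop_positions drop positions per bed, laid out on a uniform grid
#'   over the periodic cross-section (default 16, a 4 x 4 grid).
#' @param n_bed_configs independently settled beds (default 10).
#' @param master_seed root of the deterministic seed tree.
#' @param dt integration time step.
#' @param contraction_steps steps per contraction half-cycle (all natural
#'   lengths reach zero together at the end).
#' @param relax_max_steps step budget per relaxation half-cycle.
#' @param force_tolerance relaxation tolerance (`NULL` = 2 percent of an
#'   element weight).
#' @param box bed box dimensions.
#' @param dispersion particle size dispersion.
#' @param mobility_radius horizontal radius around the drop site within which
#'   bed particles stay dynamic during the cell phases (default
#'   `L_f/2 + 2`); farther particles are held static. Use `Inf` to integrate
#'   the whole bed.
#' @param ke_threshold bed settling criterion.
#' @param law a [contact_law()].
#' @return a `granulo_config` list.
#' @export
scenario_config <- function(aspect_ratio, relative_density = 1,
                            bed_layers = 3, n_drop_positions = 16,
                            n_bed_configs = 10, master_seed = 1,
                            dt = 5e-5, contraction_steps = 1e5,
                            relax_max_steps = 8e4, force_tolerance = NULL,
                            box = c(20, 20, 20), dispersion = 0.05,
                            mobility_radius = NULL, ke_threshold = 2e-3,
                            law = contact_law()) {
  stopifnot(aspect_ratio > 0, relative_density >= 1, bed_layers >= 1)
  structure(list(aspect_ratio = aspect_ratio,
                 relative_density = relative_density,
                 bed_layers = bed_layers,
                 n_drop_positions = n_drop_positions,
                 n_bed_configs = n_bed_configs,
                 master_seed = master_seed, dt = dt,
                 contraction_steps = contraction_steps,
                 relax_max_steps = relax_max_steps,
                 force_tolerance = force_tolerance,
                 box = box, dispersion = dispersion,
                 mobility_radius = mobility_radius %||% (aspect_ratio + 2),
                 ke_threshold = ke_threshold, law = law),
            class = "granulo_config")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Drop-position grid
#'
#' Near-square uniform grid of `n` positions over the periodic box
#' cross-section.
#'
#' @param n number of positions.
#' @param box box dimensions.
#' @return n x 2 matrix of (x, y) positions.
#' @export
drop_positions <- function(n, box = c(20, 20, 20)) {
  nx <- ceiling(sqrt(n))
  ny <- ceiling(n / nx)
  g <- expand.grid(i = seq_len(nx), j = seq_len(ny))[seq_len(n), ]
  cbind(x = (g$i - 0.5) / nx * box[1], y = (g$j - 0.5) / ny * box[2])
}

# settle (or fetch) the baseline bed for a seed, then apply the density
# variant: masses rescale after settling, which leaves the packing unchanged
prepare_bed <- function(config, bed_seed, cache = NULL) {
  key <- sprintf("bed_%d_%d", config$bed_layers, bed_seed)
  bed <- if (!is.null(cache) && !is.null(cache[[key]])) cache[[key]]
  else {
    b <- generate_particles(config$bed_layers, 1, config$dispersion,
                            config$box, seed = bed_seed)
    b <- settle_bed(b, config$law, config$dt, config$ke_threshold)
    if (!is.null(cache)) cache[[key]] <- b
    b
  }
  # settled packing is the initial condition: quench residual motion
  bed$vel[] <- 0; bed$hd[] <- 0
  bed$rel_density <- rep(config$relative_density, bed$n)
  if (is.infinite(config$relative_density)) bed$mobile <- rep(FALSE, bed$n)
  bed
}

# hold particles far from the drop site static for this scenario; the cell's
# force paths are local and settled beds damp disturbances within a few
# diameters
apply_mobility_mask <- function(bed, drop_xy, radius) {
  if (is.infinite(radius)) return(bed)
  dx <- abs(bed$pos[, 1] - drop_xy[1]); dx <- pmin(dx, bed$box[1] - dx)
  dy <- abs(bed$pos[, 2] - drop_xy[2]); dy <- pmin(dy, bed$box[2] - dy)
  bed$mobile <- bed$mobile & (dx^2 + dy^2 < radius^2)
  bed
}

#' Run one cell-on-bed scenario
#'
#' Full protocol for one sample: settle (or reuse) the bed, apply the density
#' variant, drop the cell at the chosen grid position, then repeat
#' rebind / stretch (activate shell + relax) / contract until three shells are
#' done or every spreading direction is terminal, with a final relaxation.
#' The volume ratio compares the final cell to a reference replay of the same
#' scenario with contraction disabled (the no-contraction upper bound).
#'
#' @param config a [scenario_config()].
#' @param bed_seed integer seed of the bed configuration (or a pre-settled
#'   `granulo_bed` via `bed`).
#' @param drop_index 1-based index into the drop-position grid.
#' @param bed optional pre-settled baseline bed (overrides `bed_seed`
#'   settling).
#' @param bed_cache optional environment used to memoize settled beds.
#' @param contraction_enabled internal; `FALSE` runs the no-contraction
#'   reference replay.
#' @return one-row data frame with the volume ratio, bond statistics and
#'   seeds; the final and reference cells are attached as attributes
#'   `cell_final` and `cell_reference`.
#' @export
run_scenario <- function(config, bed_seed = 1, drop_index = 1, bed = NULL,
                         bed_cache = NULL, contraction_enabled = TRUE) {
  stopifnot(inherits(config, "granulo_config"))
  bed0 <- if (is.null(bed)) prepare_bed(config, bed_seed, bed_cache)
  else {
    b <- bed
    b$vel[] <- 0; b$hd[] <- 0
    b$rel_density <- rep(config$relative_density, b$n)
    if (is.infinite(config$relative_density)) b$mobile <- rep(FALSE, b$n)
    b
  }
  grid <- drop_positions(config$n_drop_positions, config$box)
  stopifnot(drop_index >= 1, drop_index <= nrow(grid))
  xy <- grid[drop_index, ]
  seed <- derive_seed(config$master_seed, bed_seed, drop_index)
  run1 <- function(contracting) {
    bed <- apply_mobility_mask(bed0, xy, config$mobility_radius)
    cell <- init_cell(config$aspect_ratio, xy, bed, seed = seed)
    cell <- bind_on_contact(cell, bed)
    res <- relax_layer(cell, bed, config$dt, config$force_tolerance,
                       config$relax_max_steps, on_fail = "warn")
    cell <- res$cell; bed <- res$bed
    steps <- res$info$steps
    for (shell in 2:3) {
      if (nrow(cell$bonds) == 0) break
      n_active_before <- sum(cell$active)
      cell <- add_layer(cell)
      if (sum(cell$active) == n_active_before) break  # all terminal
      res <- relax_layer(cell, bed, config$dt, config$force_tolerance,
                         config$relax_max_steps, on_fail = "warn")
      cell <- res$cell; bed <- res$bed; steps <- steps + res$info$steps
      if (contracting) {
        res <- contract(cell, bed, dt = config$dt,
                        n_steps = config$contraction_steps)
        cell <- res$cell; bed <- res$bed; steps <- steps + res$info$steps
      }
    }
    res <- relax_layer(cell, bed, config$dt, config$force_tolerance,
                       config$relax_max_steps, on_fail = "warn")
    res$steps_total <- steps + res$info$steps
    res
  }
  fin <- run1(contraction_enabled)
  ref <- run1(FALSE)
  vr <- volume_ratio(fin$cell, ref$cell, seed = seed)
  out <- data.frame(
    aspect_ratio = config$aspect_ratio,
    relative_density = config$relative_density,
    bed_layers = config$bed_layers,
    bed_seed = bed_seed, drop_index = drop_index, seed = seed,
    volume_ratio = vr,
    n_bonds = nrow(fin$cell$bonds),
    n_reinforced = sum(fin$cell$bonds$state == "reinforced"),
    n_broken = sum(fin$cell$events$event == "break"),
    n_active = sum(fin$cell$active),
    steps = fin$steps_total)
  attr(out, "cell_final") <- fin$cell
  attr(out, "cell_reference") <- ref$cell
  attr(out, "bed_final") <- fin$bed
  out
}

# Halton low-discrepancy sequence with a seeded Cranley-Patterson rotation
halton_points <- function(n, bases = c(2, 3, 5), seed = 1) {
  radical_inverse <- function(i, b) {
    f <- 1; r <- 0
    while (any(i > 0)) {
      f <- f / b
      r <- r + f * (i %% b)
      i <- i %/% b
    }
    r
  }
  idx <- seq_len(n)
  pts <- sapply(bases, function(b) radical_inverse(idx, b))
  shift <- with_seed(seed, runif(length(bases)))
  (pts + matrix(shift, n, length(bases), byrow = TRUE)) %% 1
}

#' Union-of-spheres volume
#'
#' Quasi-random (Halton) estimate of the volume of a union of spheres, the
#' cell-volume measure behind the fate statistic.
#'
#' @param centers n x 3 sphere centers.
#' @param radii common radius or length-n radii.
#' @param n_points sample size (default 2^15, relative error well under 1
#'   percent for cell-like geometries).
#' @param seed seed of the quasi-random rotation.
#' @return estimated volume.
#' @export
union_volume <- function(centers, radii, n_points = 2^15, seed = 1) {
  centers <- matrix(centers, ncol = 3)
  n <- nrow(centers)
  if (n == 0) stop("empty sphere set")
  radii <- rep_len(radii, n)
  lo <- apply(centers - radii, 2, min)
  hi <- apply(centers + radii, 2, max)
  vol_box <- prod(hi - lo)
  pts <- halton_points(n_points, seed = seed)
  pts <- sweep(sweep(pts, 2, hi - lo, "*"), 2, lo, "+")
  inside <- rep(FALSE, n_points)
  for (i in seq_len(n)) {
    d2 <- (pts[, 1] - centers[i, 1])^2 + (pts[, 2] - centers[i, 2])^2 +
      (pts[, 3] - centers[i, 3])^2
    inside <- inside | (d2 < radii[i]^2)
  }
  mean(inside) * vol_box
}

#' Cell-fate volume ratio
#'
#' Ratio of the union-of-spheres volume of the final cell's active elements to
#' that of the reference cell advanced through the same spreading schedule
#' with contraction disabled. Near its minimum when the cell contracts
#' completely, 1 when it spreads to the no-contraction bound.
#'
#' @param cell_final,cell_reference `granulo_cell` objects.
#' @param n_points,seed passed to [union_volume()].
#' @return a fraction in (0, 1].
#' @export
volume_ratio <- function(cell_final, cell_reference, n_points = 2^15,
                         seed = 1) {
  if (sum(cell_final$active) == 0 || sum(cell_reference$active) == 0)
    stop("empty cell")
  v_fin <- union_volume(cell_final$pos[cell_final$active, , drop = FALSE],
                        cell_final$diameter / 2, n_points, seed)
  v_ref <- union_volume(cell_reference$pos[cell_reference$active, , drop = FALSE],
                        cell_reference$diameter / 2, n_points, seed)
  min(v_fin / v_ref, 1)
}

#' Sweep aspect ratios, densities and layer counts
#'
#' Runs every (ratio x density x layers x bed x drop position) combination
#' with per-sample seeds derived from the master seed. Beds are settled once
#' per (layers, seed) and reused across ratios and densities. Failed samples
#' are dropped with a warning.
#'
#' @param ratios aspect ratios `L_i/d` to sweep.
#' @param densities relative densities (1, 2, `Inf`).
#' @param layers bed layer counts.
#' @param n_positions,n_beds replicate structure (defaults 16 x 10; scale down
#'   for quick runs).
#' @param master_seed seed-tree root.
#' @param out_dir optional directory for per-sample and aggregate CSVs.
#' @param bed_cache environment memoizing settled beds (reused across calls).
#' @param ... further arguments to [scenario_config()].
#' @return a `granulo_sweep` data frame of per-sample records.
#' @export
run_sweep <- function(ratios, densities = 1, layers = 3, n_positions = 16,
                      n_beds = 10, master_seed = 1, out_dir = NULL,
                      bed_cache = NULL, ...) {
  cache <- bed_cache %||% new.env(parent = emptyenv())
  rows <- list()
  failures <- 0L
  for (ly in layers) for (r in ratios) for (dens in densities) {
    config <- scenario_config(aspect_ratio = r, relative_density = dens,
                              bed_layers = ly, n_drop_positions = n_positions,
                              n_bed_configs = n_beds,
                              master_seed = master_seed, ...)
    for (bs in seq_len(n_beds)) for (di in seq_len(n_positions)) {
      rec <- tryCatch(
        run_scenario(config, bed_seed = bs, drop_index = di,
                     bed_cache = cache),
        error = function(e) {
          warning(sprintf("sample failed (ratio %.3g, density %.3g, bed %d, drop %d): %s",
                          r, dens, bs, di, conditionMessage(e)))
          NULL
        })
      if (is.null(rec)) failures <- failures + 1L else {
        attributes(rec)[c("cell_final", "cell_reference", "bed_final")] <- NULL
        rows[[length(rows) + 1L]] <- rec
      }
    }
  }
  out <- do.call(rbind, rows)
  class(out) <- c("granulo_sweep", class(out))
  attr(out, "master_seed") <- master_seed
  attr(out, "failures") <- failures
  if (!is.null(out_dir)) {
    dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
    write.csv(as.data.frame(out), file.path(out_dir, "samples.csv"),
              row.names = FALSE)
    write.csv(aggregate_sweep(out), file.path(out_dir, "aggregate.csv"),
              row.names = FALSE)
  }
  out
}

#' Aggregate a sweep: mean volume ratio and standard error per condition
#'
#' @param sweep a `granulo_sweep`.
#' @return data frame with `mean_ratio`, `sem` (standard error, n = samples in
#'   the condition) and `n` per (aspect ratio, density, layers).
#' @export
aggregate_sweep <- function(sweep) {
  df <- as.data.frame(sweep)
  agg <- do.call(rbind, lapply(
    split(df, df[c("aspect_ratio", "relative_density", "bed_layers")],
          drop = TRUE),
    function(g) data.frame(
      aspect_ratio = g$aspect_ratio[1],
      relative_density = g$relative_density[1],
      bed_layers = g$bed_layers[1],
      mean_ratio = mean(g$volume_ratio),
      sem = if (nrow(g) > 1) sd(g$volume_ratio) / sqrt(nrow(g)) else 0,
      n = nrow(g))))
  rownames(agg) <- NULL
  agg[order(agg$bed_layers, agg$relative_density, agg$aspect_ratio), ]
}

#' @exportS3Method generics::tidy
tidy.granulo_sweep <- function(x, ...) {
  tibble::as_tibble(as.data.frame(x))
}

#' @exportS3Method generics::glance
glance.granulo_sweep <- function(x, ...) {
  tibble::as_tibble(aggregate_sweep(x))
}

#' Fate curve: mean volume ratio versus aspect ratio
#'
#' @param sweep a `granulo_sweep` (or its [aggregate_sweep()] output).
#' @param color_by `"relative_density"` or `"bed_layers"`.
#' @return a ggplot object.
#' @export
plot_fate_curve <- function(sweep, color_by = "relative_density") {
  agg <- if (inherits(sweep, "granulo_sweep")) aggregate_sweep(sweep)
         else as.data.frame(sweep)
  agg$group <- factor(agg[[color_by]])
  ggplot2::ggplot(agg, ggplot2::aes(x = .data$aspect_ratio,
                                    y = .data$mean_ratio,
                                    color = .data$group,
                                    group = .data$group)) +
    ggplot2::geom_line() +
    ggplot2::geom_point() +
    ggplot2::geom_errorbar(ggplot2::aes(ymin = .data$mean_ratio - .data$sem,
                                        ymax = .data$mean_ratio + .data$sem),
                           width = 0.03) +
    ggplot2::scale_x_log10() +
    ggplot2::labs(x = expression(L[i] / d), y = "volume ratio",
                  color = color_by) +
    ggplot2::theme_minimal()
}

#' @exportS3Method ggplot2::autoplot
autoplot.granulo_sweep <- function(object, ...) plot_fate_curve(object, ...)
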