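#' Write cell fields as a legacy-VTK structured grid
#'
#' Writes named scalar fields (and optionally the cell-centred velocity) on
#' the mesh as an ASCII legacy VTK `STRUCTURED_POINTS` dataset, readable by
#' ParaView and friends.
#'
#' @param fields Named list of `nx x ny` matrices.
#' @param mesh The mesh.
#' @param path Output file path (`.vtk`).
#' @param velocity Optional list with `uc`, `vc` matrices (m/s) written as
#'   a vector field.
#' @return `path`, invisibly.
#' @export
write_vtk <- function(fields, mesh, path, velocity = NULL) {
  nx <- mesh$nx; ny <- mesh$ny
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c("# vtk DataFile Version 3.0",
               "clotsim fields", "ASCII",
               "DATASET STRUCTURED_POINTS",
               sprintf("DIMENSIONS %d %d 1", nx, ny),
               sprintf("ORIGIN %g %g 0", mesh$dx / 2, mesh$dy / 2),
               sprintf("SPACING %g %g 1", mesh$dx, mesh$dy),
               sprintf("POINT_DATA %d", nx * ny)), con)
  for (nm in names(fields)) {
    writeLines(c(sprintf("SCALARS %s double 1", nm),
                 "LOOKUP_TABLE default"), con)
    writeLines(format(as.numeric(fields[[nm]]), digits = 9, trim = TRUE,
                      scientific = TRUE), con)
  }
  if (!is.null(velocity)) {
    writeLines("VECTORS velocity double", con)
    writeLines(paste(format(as.numeric(velocity$uc), digits = 9,
                            scientific = TRUE),
                     format(as.numeric(velocity$vc), digits = 9,
                            scientific = TRUE), "0"), con)
  }
  invisible(path)
}

#' Write kinetics time series as tidy CSV
#'
#' @param kinetics Either one kinetics data frame or a named list of them
#'   (one per condition).
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_kinetics_csv <- function(kinetics, path) {
  if (is.data.frame(kinetics)) kinetics <- list(run = kinetics)
  rows <- lapply(names(kinetics), function(nm) {
    k <- kinetics[[nm]]
    out <- utils::stack(k, select = setdiff(names(k), "time_s"))
    data.frame(condition = nm, time_s = rep(k$time_s, ncol(k) - 1),
               species = out$ind, value = out$values,
               stringsAsFactors = FALSE)
  })
  utils::write.csv(do.call(rbind, rows), path, row.names = FALSE)
  invisible(path)
}

#' Write/read deposition profiles in the tidy CSV schema
#'
#' Columns: condition, donor, repetition, time_s, x_um, value.
#'
#' @param profiles List of [deposition_profile()]s.
#' @param path CSV path.
#' @return `path` (write) / list of profiles (read).
#' @export
write_profiles_csv <- function(profiles, path) {
  rows <- lapply(profiles, function(p)
    data.frame(condition = p$condition, donor = p$donor,
               repetition = p$repetition, time_s = p$time_s, x_um = p$x,
               value = p$value, stringsAsFactors = FALSE))
  utils::write.csv(do.call(rbind, rows), path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_profiles_csv
#' @export
read_profiles_csv <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("condition", "donor", "repetition", "time_s", "x_um", "value")
  if (!all(need %in% names(df)))
    stop("profile CSV must have columns ", paste(need, collapse = ", "))
  key <- interaction(df$condition, df$donor, df$repetition, df$time_s,
                     drop = TRUE)
  lapply(split(df, key), function(g)
    deposition_profile(g$x_um, g$value, donor = g$donor[1],
                       repetition = g$repetition[1],
                       condition = g$condition[1], time_s = g$time_s[1]))
}

#' Write a region contour as CSV (x, y vertices)
#'
#' @param region A `region_contour`.
#' @param path CSV path.
#' @return `path`, invisibly.
#' @export
write_contour_csv <- function(region, path) {
  utils::write.csv(as.data.frame(as_polyline(region)), path,
                   row.names = FALSE)
  invisible(path)
}

#' Read a simulation configuration from a YAML run-config file
#'
#' Recognised blocks: `geometry` (length, height, width, surface_center,
#' surface_length, tf_density), `fluid` (density, viscosity, wall_shear),
#' `numerics` (dx, dy, dt, flow_interval, t_end, sample_interval,
#' snapshot_times), plus top-level `condition` and `seed`. Anything omitted
#' keeps the package default.
#'
#' @param path YAML file path.
#' @return A [simulation_config()].
#' @export
read_run_config <- function(path) {
  cfg <- yaml::read_yaml(path)
  geom <- if (!is.null(cfg$geometry)) do.call(channel_geometry, cfg$geometry)
  fl <- if (!is.null(cfg$fluid)) do.call(fluid_properties, cfg$fluid)
        else fluid_properties()
  args <- c(list(condition = cfg$condition %||% "long_hi", geometry = geom,
                 fluid = fl, seed = cfg$seed %||% 1),
            cfg$numerics)
  do.call(simulation_config, args)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
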