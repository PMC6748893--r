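# connected components of a logical cell mask (4-connectivity), plain BFS
.largest_component <- function(mask) {
  nx <- nrow(mask); ny <- ncol(mask)
  lab <- matrix(0L, nx, ny)
  cur <- 0L
  idx <- which(mask)
  for (start in idx) {
    if (lab[start] != 0L) next
    cur <- cur + 1L
    queue <- start
    lab[start] <- cur
    while (length(queue)) {
      c0 <- queue[length(queue)]; queue <- queue[-length(queue)]
      i <- (c0 - 1L) %% nx + 1L; j <- (c0 - 1L) %/% nx + 1L
      for (nb in c(if (i > 1) c0 - 1L, if (i < nx) c0 + 1L,
                   if (j > 1) c0 - nx, if (j < ny) c0 + nx)) {
        if (mask[nb] && lab[nb] == 0L) {
          lab[nb] <- cur
          queue <- c(queue, nb)
        }
      }
    }
  }
  if (cur == 0L) return(mask & FALSE)
  sizes <- tabulate(lab[lab > 0L], cur)
  lab == which.max(sizes)
}

# region contour from a column-height profile (wall-anchored region)
.region_from_heights <- function(x, h, dx) {
  nz <- which(h > 0)
  if (!length(nz)) {
    return(structure(list(x = x, h = h, dx = dx, height = 0, length = 0,
                          area = 0, empty = TRUE), class = "region_contour"))
  }
  structure(list(x = x, h = h, dx = dx,
                 height = max(h),
                 length = (max(nz) - min(nz) + 1) * dx,
                 area = sum(h) * dx,
                 empty = FALSE),
            class = "region_contour")
}

#' Region contour from a wall-anchored column-height profile
#'
#' Builds a [region_contour] directly from a deposition-profile-style height
#' function (e.g. a measured, averaged platelet deposition profile), for use
#' as a measured clot shell in [embed_core_in_shell()] and
#' [flow_through_measured_shape()].
#'
#' @param x Column-centre coordinates (um), uniformly spaced.
#' @param h Heights (um), one per column, `>= 0`.
#' @return A `region_contour`.
#' @export
region_from_profile <- function(x, h) {
  stopifnot(length(x) == length(h), all(h >= 0), length(x) >= 2)
  dx <- diff(x)
  if (max(abs(dx - dx[1])) > 1e-9 * dx[1]) stop("x must be uniformly spaced")
  .region_from_heights(x, h, dx[1])
}

# contour from a thresholded field: largest connected superlevel component,
# summarised as its column-wise top envelope (clots are wall-anchored)
.contour_from_field <- function(field, mesh, level) {
  mask <- .largest_component(field >= level)
  h <- rep(0, mesh$nx)
  if (any(mask)) {
    for (i in seq_len(mesh$nx)) {
      jj <- which(mask[i, ])
      if (length(jj)) h[i] <- max(jj) * mesh$dy
    }
  }
  out <- .region_from_heights(mesh$xc, h, mesh$dx)
  out$mask <- mask
  out
}

#' Extract the fibrin-rich clot core
#'
#' The core is the largest connected component of the fibrin superlevel set
#' at the given concentration threshold (1 nM by default), summarised as a
#' wall-anchored contour.
#'
#' @param fibrin `nx x ny` fibrin field (nM).
#' @param mesh The mesh the field lives on.
#' @param threshold Fibrin level defining the core boundary (nM).
#' @return A `region_contour` (empty when the field never reaches the
#'   threshold).
#' @export
extract_core <- function(fibrin, mesh, threshold = 1) {
  stopifnot(is.matrix(fibrin), all(dim(fibrin) == c(mesh$nx, mesh$ny)))
  .contour_from_field(fibrin, mesh, threshold)
}

#' Extract the platelet-rich clot shell
#'
#' The shell is the largest connected component of the bound-platelet
#' superlevel set at `threshold * phi_max` (5% of the packing cap by
#' default; a fixed threshold makes the boundary reproducible).
#'
#' @param bound `nx x ny` bound-platelet volume fraction field.
#' @param mesh The mesh.
#' @param threshold Fraction of `phi_max` defining the boundary.
#' @param phi_max Packing cap.
#' @return A `region_contour`.
#' @export
extract_shell <- function(bound, mesh, threshold = 0.05, phi_max = 0.6) {
  stopifnot(is.matrix(bound), all(dim(bound) == c(mesh$nx, mesh$ny)))
  .contour_from_field(bound, mesh, threshold * phi_max)
}

#' @exportS3Method
print.region_contour <- function(x, ...) {
  if (x$empty) cat("Empty region contour\n")
  else cat(sprintf("Region contour: peak height %.1f um, length %.0f um, area %.0f um^2\n",
                   x$height, x$length, x$area))
  invisible(x)
}

#' Closed polyline of a region contour
#'
#' @param region A `region_contour`.
#' @return Two-column matrix (x, y in um) of the closed boundary polyline,
#'   anchored on the bottom wall; areas computed from it by the shoelace
#'   formula equal the region area.
#' @export
as_polyline <- function(region) {
  stopifnot(inherits(region, "region_contour"))
  if (region$empty) return(matrix(numeric(0), 0, 2,
                                  dimnames = list(NULL, c("x", "y"))))
  nz <- which(region$h > 0)
  i0 <- min(nz); i1 <- max(nz)
  d2 <- region$dx / 2
  xs <- c(region$x[i0] - d2)
  ys <- c(0)
  for (i in i0:i1) {
    xs <- c(xs, region$x[i] - d2, region$x[i] + d2)
    ys <- c(ys, region$h[i], region$h[i])
  }
  xs <- c(xs, region$x[i1] + d2)
  ys <- c(ys, 0)
  cbind(x = xs, y = ys)
}

#' Clot occlusivity
#'
#' Ratio of the peak clot height to the channel height.
#'
#' @param contour A `region_contour`.
#' @param channel_height Channel height (um).
#' @return Fraction in `[0, 1]`.
#' @examples
#' occlusivity(region_from_profile(0:10, c(0, rep(18, 9), 0)), 60)  # 0.3
#' @export
occlusivity <- function(contour, channel_height) {
  stopifnot(inherits(contour, "region_contour"), channel_height > 0)
  if (contour$empty) return(0)
  if (contour$height > channel_height)
    stop("contour height exceeds the channel height")
  contour$height / channel_height
}

#' Pair a clot core and shell with their resistances
#'
#' @param core,shell `region_contour`s; the core must nest inside the
#'   shell.
#' @param k_core,k_shell Spatially averaged viscous resistances (1/m^2),
#'   `k_core >= k_shell >= 0`.
#' @param clip If `TRUE`, clip the core height profile to the shell instead
#'   of rejecting a core that pokes out by a cell or two (useful when both
#'   contours come from thresholded simulation fields, where the fibrin
#'   fringe can exceed the shell threshold in boundary cells).
#' @return Object of class `core_shell_pair`.
#' @export
core_shell_pair <- function(core, shell, k_core = 0, k_shell = 0,
                            clip = FALSE) {
  stopifnot(inherits(core, "region_contour"), inherits(shell, "region_contour"))
  if (k_shell < 0 || k_core < k_shell)
    stop("need k_core >= k_shell >= 0")
  if (clip && !core$empty && !shell$empty) {
    hs <- stats::approx(shell$x, shell$h, xout = core$x, yleft = 0,
                        yright = 0)$y
    core <- .region_from_heights(core$x, pmin(core$h, hs), core$dx)
  }
  if (!core$empty && !.nested(core, shell))
    stop("core must lie inside the shell")
  structure(list(core = core, shell = shell, k_core = k_core,
                 k_shell = k_shell), class = "core_shell_pair")
}

# core nested in shell: core height profile under shell profile (interpolated)
.nested <- function(core, shell, tol = 1e-9) {
  if (core$empty) return(TRUE)
  if (shell$empty) return(FALSE)
  hs <- stats::approx(shell$x, shell$h, xout = core$x, yleft = 0,
                      yright = 0)$y
  all(core$h <= hs + tol)
}

# centre of a region = midpoint of its non-zero footprint
.region_center <- function(region) {
  nz <- which(region$h > 0)
  (region$x[min(nz)] + region$x[max(nz)]) / 2
}

#' Embed a rescaled simulated core inside a measured shell
#'
#' The simulated core is rescaled so that the embedded core-to-shell ratios
#' of height and length equal those of the simulation, and positioned so the
#' core centre keeps its simulated offset relative to the shell centre
#' (relative to shell length). The embedded core is clipped to the measured
#' shell so the nesting invariant always holds.
#'
#' @param sim A [core_shell_pair()] from a coupled simulation.
#' @param measured_shell A `region_contour` from measured (or synthetic)
#'   deposition profiles.
#' @return A `core_shell_pair` with the measured shell and the embedded
#'   core, carrying over `k_core`, `k_shell`.
#' @examples
#' # sim ratios 0.5 (height) and 0.6 (length) on a 15 x 120 um shell give
#' # an embedded core of 7.5 x 72 um
#' @export
embed_core_in_shell <- function(sim, measured_shell) {
  stopifnot(inherits(sim, "core_shell_pair"),
            inherits(measured_shell, "region_contour"))
  if (sim$core$empty || measured_shell$empty) {
    empty <- .region_from_heights(measured_shell$x,
                                  rep(0, length(measured_shell$x)),
                                  measured_shell$dx)
    return(core_shell_pair(empty, measured_shell, sim$k_core, sim$k_shell))
  }
  rh <- sim$core$height / sim$shell$height
  rl <- sim$core$length / sim$shell$length
  off_rel <- (.region_center(sim$core) - .region_center(sim$shell)) /
    sim$shell$length
  H <- measured_shell$height * rh
  L <- measured_shell$length * rl
  cx <- .region_center(measured_shell) + off_rel * measured_shell$length
  # rescale the simulated core height profile onto the measured grid;
  # normalise by the centre-to-centre span on both sides so a sampled
  # indicator keeps exact footprint lengths (no one-cell interpolation bleed)
  c0 <- .region_center(sim$core)
  den_s <- max(sim$core$length - sim$core$dx, sim$core$dx)
  den_t <- max(L - measured_shell$dx, measured_shell$dx)
  rel <- (measured_shell$x - cx) / den_t        # [-0.5, 0.5] inside the core
  hshape <- stats::approx(x = (sim$core$x - c0) / den_s,
                          y = sim$core$h / sim$core$height,
                          xout = rel, yleft = 0, yright = 0)$y
  hshape[abs(rel) > 0.5 + 1e-9] <- 0
  h <- H * hshape
  hs <- measured_shell$h
  h <- pmin(h, hs)                               # enforce nesting
  core <- .region_from_heights(measured_shell$x, h, measured_shell$dx)
  core_shell_pair(core, measured_shell, sim$k_core, sim$k_shell)
}

# logical cell mask of a region on a mesh (cells whose centres lie under
# the contour height profile)
.region_mask <- function(region, mesh) {
  if (!is.null(region$mask) &&
      all(dim(region$mask) == c(mesh$nx, mesh$ny))) return(region$mask)
  h <- stats::approx(region$x, region$h, xout = mesh$xc, yleft = 0,
                     yright = 0)$y
  outer(seq_len(mesh$nx), seq_len(mesh$ny),
        function(i, j) mesh$yc[j] < h[i])
}

#' Spatially averaged resistance over a region
#'
#' Area-weighted mean of the Brinkman coefficient over cells whose centres
#' lie inside the region (equal-area cells, so the arithmetic mean).
#'
#' @param resistance `nx x ny` resistance matrix (1/m^2).
#' @param region A `region_contour`.
#' @param mesh The mesh.
#' @param exclude Optional `region_contour` whose cells are excluded (e.g.
#'   the core when averaging over the shell annulus).
#' @return Mean resistance (1/m^2).
#' @export
region_mean_resistance <- function(resistance, region, mesh, exclude = NULL) {
  stopifnot(inherits(region, "region_contour"))
  if (region$empty) stop("cannot average over an empty region")
  mask <- .region_mask(region, mesh)
  if (!is.null(exclude)) mask <- mask & !.region_mask(exclude, mesh)
  if (!any(mask)) stop("region contains no cells on this mesh")
  mean(resistance[mask])
}

#' Blood flow through a measured clot shape
#'
#' Builds a piecewise-constant resistance field (`k_core` inside the
#' embedded core, `k_shell` in the shell annulus, zero outside) from a
#' measured shell and a core/shell pair, solves the Stokes-Brinkman flow,
#' and summarises the intraclot velocity structure.
#'
#' @param measured_shell A `region_contour` (the measured platelet
#'   deposition domain).
#' @param pair A [core_shell_pair()] carrying the simulated core/shell
#'   ratios and averaged resistances.
#' @param mesh,fluid Mesh and [fluid_properties()] for the flow solve.
#' @return List with `flow` (a `flow_state`), `pair` (the embedded pair),
#'   `resistance`, and `metrics`: intraclot mean/max axial velocity (m/s),
#'   `sd_horizontal` (SD of axial velocity along x at mid-clot relative
#'   height), `sd_vertical` (SD along y at the clot centre), lumen mean
#'   velocity, `low_velocity_extent`/`low_velocity_range` (footprint, um,
#'   of columns slower than 10% of the clot-free flow below half the shell
#'   peak), and the shell half-peak footprint `shell_fwhm` plus full
#'   support `shell_extent` for comparison.
#' @export
flow_through_measured_shape <- function(measured_shell, pair, mesh, fluid) {
  emb <- embed_core_in_shell(pair, measured_shell)
  shell_mask <- .region_mask(emb$shell, mesh)
  core_mask <- .region_mask(emb$core, mesh) & shell_mask
  k <- matrix(0, mesh$nx, mesh$ny)
  k[shell_mask] <- emb$k_shell
  k[core_mask] <- emb$k_core
  flow <- solve_flow(mesh, fluid, k)
  uc <- flow$uc
  lumen_mean <- mean(uc[!shell_mask])
  if (!any(shell_mask)) stop("measured shell contains no cells")
  # vertical profile at the clot centre column
  ic <- which.min(abs(mesh$xc - .region_center(emb$shell)))
  jj <- which(shell_mask[ic, ])
  sd_vert <- stats::sd(uc[ic, jj])
  # horizontal profile at mid relative height within the clot
  cols <- which(apply(shell_mask, 1, any))
  uh <- vapply(cols, function(i) {
    j <- which(shell_mask[i, ])
    jmid <- j[max(1L, ceiling(length(j) / 2))]
    uc[i, jmid]
  }, 0)
  sd_horiz <- stats::sd(uh)
  # low-velocity region: cells slower than 10% of the lumen mean, ignoring
  # the first row above the wall (the no-slip layer is slow in any
  # channel); its x-footprint is compared against the shell's half-peak
  # (FWHM) footprint
  slow_cells <- uc < 0.1 * lumen_mean
  slow <- apply(slow_cells[, -c(1, mesh$ny), drop = FALSE], 1, any)
  lv_extent <- if (any(slow)) (max(which(slow)) - min(which(slow)) + 1) * mesh$dx else 0
  lv_range <- if (any(slow)) range(mesh$xc[slow]) else c(NA_real_, NA_real_)
  hs <- stats::approx(emb$shell$x, emb$shell$h, xout = mesh$xc, yleft = 0,
                      yright = 0)$y
  fwhm_cols <- which(hs >= emb$shell$height / 2)
  shell_fwhm <- (max(fwhm_cols) - min(fwhm_cols) + 1) * mesh$dx
  list(flow = flow, pair = emb, resistance = k,
       metrics = list(
         intraclot_mean = mean(uc[shell_mask]),
         intraclot_max = max(uc[shell_mask]),
         lumen_mean = lumen_mean,
         sd_horizontal = sd_horiz,
         sd_vertical = sd_vert,
         low_velocity_extent = lv_extent,
         low_velocity_range = lv_range,
         shell_fwhm = shell_fwhm,
         shell_extent = emb$shell$length))
}
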