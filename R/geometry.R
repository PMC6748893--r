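#' Channel geometry with a thrombogenic surface patch
#'
#' Describes the 2-D microfluidic channel cross-section used throughout the
#' package: flow runs along `x` from the inlet at 0 to the outlet at `length`,
#' `y` runs from the bottom wall (0) to the top wall at `height`. A
#' thrombogenic patch (collagen + tissue factor) of length `surface_length`
#' sits on the bottom wall centred at `surface_center`. The out-of-plane
#' width `width` is only used to convert fluxes between 2-D and device units.
#'
#' @param length Domain length along the flow direction (um). Default 600.
#' @param height Channel height (um). Default 60.
#' @param width Out-of-plane channel width (um). Default 250.
#' @param surface_center Centre of the thrombogenic patch (um). Default 300.
#' @param surface_length Length of the thrombogenic patch (um), canonically
#'   20 ("short") or 100 ("long").
#' @param tf_density Tissue-factor surface density (molecules/um^2),
#'   canonically 0.1 ("low") or 2 ("high").
#' @return An object of class `channel_geometry`.
#' @examples
#' channel_geometry(surface_length = 100, tf_density = 2)
#' @export
channel_geometry <- function(length = 600, height = 60, width = 250,
                             surface_center = 300, surface_length = 20,
                             tf_density = 0.1) {
  stopifnot(is.numeric(length), length > 0,
            is.numeric(height), height > 0,
            is.numeric(width), width > 0,
            is.numeric(surface_length), surface_length > 0)
  if (!is.numeric(tf_density) || tf_density < 0)
    stop("tf_density must be a non-negative surface density (molecules/um^2)")
  lo <- surface_center - surface_length / 2
  hi <- surface_center + surface_length / 2
  if (lo <= 0 || hi >= length)
    stop("thrombogenic surface [", lo, ", ", hi,
         "] um must lie strictly inside the bottom wall (0, ", length, ")")
  structure(list(length = length, height = height, width = width,
                 surface_center = surface_center,
                 surface_length = surface_length,
                 tf_density = tf_density),
            class = "channel_geometry")
}

#' @exportS3Method
print.channel_geometry <- function(x, ...) {
  cat(sprintf("Channel %g x %g um (width %g um), thrombogenic surface %g um @ %g um, TF %g /um^2\n",
              x$length, x$height, x$width, x$surface_length,
              x$surface_center, x$tf_density))
  invisible(x)
}

#' Build a uniform structured mesh over the channel
#'
#' Cell-centred uniform Cartesian mesh. Cell ownership is half-open
#' `[x, x + dx)`; a bottom-wall face belongs to the thrombogenic patch when
#' its centre falls inside the patch interval, so every bottom face is either
#' plain wall or thrombogenic, never both.
#'
#' @param geometry A [channel_geometry()].
#' @param dx,dy Cell sizes (um); must divide the domain lengths.
#' @return An object of class `channel_mesh` with fields `nx`, `ny`, `dx`,
#'   `dy`, cell-centre coordinates `xc`, `yc` (um), logical vector `thromb`
#'   marking thrombogenic bottom-wall faces, and the geometry.
#' @examples
#' m <- build_mesh(channel_geometry(), dx = 2, dy = 2)
#' sum(m$thromb)  # 10 faces for a 20-um surface at dx = 2
#' @export
build_mesh <- function(geometry, dx = 2, dy = 2) {
  stopifnot(inherits(geometry, "channel_geometry"))
  if (!is.numeric(dx) || !is.numeric(dy) || dx <= 0 || dy <= 0)
    stop("dx and dy must be positive cell sizes (um)")
  if (geometry$surface_length < dx)
    stop("thrombogenic surface (", geometry$surface_length,
         " um) is shorter than one cell; use dx <= ",
         geometry$surface_length, " um")
  nx <- round(geometry$length / dx)
  ny <- round(geometry$height / dy)
  if (abs(nx * dx - geometry$length) > 1e-9 * geometry$length ||
      abs(ny * dy - geometry$height) > 1e-9 * geometry$height)
    stop("dx, dy must tile the domain exactly (", geometry$length,
         " x ", geometry$height, " um)")
  xc <- (seq_len(nx) - 0.5) * dx
  yc <- (seq_len(ny) - 0.5) * dy
  lo <- geometry$surface_center - geometry$surface_length / 2
  hi <- geometry$surface_center + geometry$surface_length / 2
  thromb <- xc >= lo & xc < hi
  structure(list(geom = geometry, nx = nx, ny = ny, dx = dx, dy = dy,
                 xc = xc, yc = yc, thromb = thromb),
            class = "channel_mesh")
}

#' @exportS3Method
print.channel_mesh <- function(x, ...) {
  cat(sprintf("Structured mesh %d x %d cells (dx = %g, dy = %g um), %d thrombogenic faces\n",
              x$nx, x$ny, x$dx, x$dy, sum(x$thromb)))
  invisible(x)
}

#' Convert a tissue-factor surface density to molar units
#'
#' @param tf_density Surface density in molecules/um^2.
#' @return Molar surface density in mol/m^2
#'   (`density * 1e12 / N_A`, with Avogadro's number `N_A`).
#' @examples
#' surface_site_density(2)    # ~3.32e-12 mol/m^2
#' surface_site_density(0.1)  # ~1.66e-13 mol/m^2
#' @export
surface_site_density <- function(tf_density) {
  if (!is.numeric(tf_density) || any(tf_density < 0))
    stop("tf_density must be non-negative")
  tf_density * 1e12 / 6.02214076e23
}

# canonical experimental conditions: short/long surface x low/high TF
#' The four canonical experimental conditions
#'
#' Short (20 um) or long (100 um) thrombogenic surface crossed with low
#' (0.1 /um^2) or high (2 /um^2) TF surface density.
#'
#' @return A data frame with columns `condition`, `surface_length`,
#'   `tf_density`.
#' @export
canonical_conditions <- function() {
  data.frame(
    condition = c("short_lo", "short_hi", "long_lo", "long_hi"),
    surface_length = c(20, 20, 100, 100),
    tf_density = c(0.1, 2, 0.1, 2),
    stringsAsFactors = FALSE
  )
}
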