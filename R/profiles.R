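#' A single platelet deposition profile
#'
#' Width-averaged platelet signal (height-equivalent um, or intensity in
#' a.u.) versus the channel length coordinate, for one clotting event at one
#' time point.
#'
#' @param x Length coordinate (um), strictly increasing, uniformly spaced.
#' @param value Non-negative signal, same length as `x`.
#' @param donor,repetition,condition,time_s Metadata.
#' @return Object of class `deposition_profile`.
#' @export
deposition_profile <- function(x, value, donor = NA, repetition = NA,
                               condition = NA, time_s = NA) {
  stopifnot(length(x) == length(value), length(x) >= 3)
  dx <- diff(x)
  if (any(dx <= 0)) stop("x must be strictly increasing")
  if (max(abs(dx - dx[1])) > 1e-6 * dx[1]) stop("x must be uniformly spaced")
  if (any(value < 0)) stop("profile values must be non-negative")
  structure(list(x = x, value = value, donor = donor,
                 repetition = repetition, condition = condition,
                 time_s = time_s),
            class = "deposition_profile")
}

#' Detect the edges of the platelet accumulation region
#'
#' Finds the outermost crossings of `level * max(value)` (linearly
#' interpolated between grid points); the profile centre is their midpoint.
#'
#' @param profile A [deposition_profile()] (or list with `x`, `value`).
#' @param level Fraction of the maximum defining "substantial" accumulation.
#' @return List with `x_up`, `x_down`, `center` (um).
#' @export
detect_edges <- function(profile, level = 0.1) {
  x <- profile$x; v <- profile$value
  if (max(v) <= 0) stop("no accumulation: all-zero profile")
  thr <- level * max(v)
  above <- v >= thr
  if (!any(above)) stop("no accumulation above the edge level")
  i0 <- min(which(above)); i1 <- max(which(above))
  x_up <- if (i0 == 1) x[1] else {
    # linear interpolation of the upward crossing
    x[i0 - 1] + (thr - v[i0 - 1]) / (v[i0] - v[i0 - 1]) * (x[i0] - x[i0 - 1])
  }
  x_down <- if (i1 == length(x)) x[length(x)] else {
    x[i1] + (v[i1] - thr) / (v[i1] - v[i1 + 1]) * (x[i1 + 1] - x[i1])
  }
  list(x_up = x_up, x_down = x_down, center = (x_up + x_down) / 2)
}

#' Align deposition profiles to a common centre
#'
#' Shifts every profile so its edge-midpoint centre sits at `center`
#' (300 um by convention), resamples onto the common grid by linear
#' interpolation with zero fill outside the recorded range. Profiles whose
#' edges cannot be detected are excluded with a logged reason.
#'
#' @param profiles List of [deposition_profile()]s.
#' @param center Target centre coordinate (um).
#' @param grid Common grid (um). Default 0..600 um at 1-um spacing.
#' @param level Edge-detection level.
#' @return Object of class `profile_ensemble`: `x` (grid), `values`
#'   (n x length(grid) matrix), `meta` (data frame with donor, repetition,
#'   condition, time_s, shift applied), `failed` (list of reasons).
#' @export
align_profiles <- function(profiles, center = 300, grid = seq(0, 600, by = 1),
                           level = 0.1) {
  stopifnot(length(profiles) >= 1)
  vals <- list(); meta <- list(); failed <- list()
  for (k in seq_along(profiles)) {
    p <- profiles[[k]]
    ed <- tryCatch(detect_edges(p, level), error = function(e) e)
    if (inherits(ed, "error")) {
      failed[[length(failed) + 1L]] <- list(index = k,
                                            reason = conditionMessage(ed))
      next
    }
    shift <- center - ed$center
    v <- stats::approx(p$x + shift, p$value, xout = grid, yleft = 0,
                       yright = 0, rule = 1)$y
    v[is.na(v)] <- 0
    vals[[length(vals) + 1L]] <- v
    meta[[length(meta) + 1L]] <- data.frame(
      donor = p$donor, repetition = p$repetition, condition = p$condition,
      time_s = p$time_s, shift = shift, stringsAsFactors = FALSE)
  }
  if (!length(vals)) stop("no profile could be aligned")
  structure(list(x = grid, values = do.call(rbind, vals),
                 meta = do.call(rbind, meta), center = center,
                 failed = failed),
            class = "profile_ensemble")
}

#' @exportS3Method
print.profile_ensemble <- function(x, ...) {
  cat(sprintf("Profile ensemble: %d profiles on [%g, %g] um, centred at %g um (%d failed)\n",
              nrow(x$values), min(x$x), max(x$x), x$center, length(x$failed)))
  invisible(x)
}

#' Filter out profiles with spurious platelet accumulation
#'
#' Two translation-invariant rules, both logged per rejection:
#' (1) outside-fraction -- the integrated signal outside the detected main
#' accumulation region exceeds `max_outside_fraction` of the total;
#' (2) twin peaks -- a secondary local maximum above `peak_ratio` of the
#' main peak lies more than `peak_separation` um away.
#'
#' @param profiles List of [deposition_profile()]s.
#' @param max_outside_fraction Maximal tolerated outside-signal fraction.
#' @param peak_ratio Secondary/main peak ratio that triggers rejection.
#' @param peak_separation Minimal peak separation (um) for the twin-peak
#'   rule.
#' @param level Edge-detection level for the main region.
#' @return List with `kept`, `rejected` (lists of profiles) and `reasons`
#'   (character per rejected profile).
#' @export
filter_spurious <- function(profiles, max_outside_fraction = 0.2,
                            peak_ratio = 0.5, peak_separation = 100,
                            level = 0.1) {
  kept <- list(); rejected <- list(); reasons <- character(0)
  for (p in profiles) {
    v <- p$value; x <- p$x
    if (max(v) <= 0) { kept[[length(kept) + 1L]] <- p; next }
    ed <- detect_edges(p, level)
    inside <- x >= ed$x_up & x <= ed$x_down
    out_frac <- sum(v[!inside]) / sum(v)
    # local maxima above the twin-peak ratio, away from the global peak
    imax <- which.max(v)
    is_peak <- c(FALSE, diff(sign(diff(v))) < 0, FALSE) & v > peak_ratio * v[imax]
    twin <- any(is_peak & abs(x - x[imax]) > peak_separation)
    if (out_frac > max_outside_fraction || twin) {
      rejected[[length(rejected) + 1L]] <- p
      reasons <- c(reasons, paste0(
        if (out_frac > max_outside_fraction)
          sprintf("outside fraction %.2f > %.2f", out_frac,
                  max_outside_fraction),
        if (out_frac > max_outside_fraction && twin) "; ",
        if (twin) "secondary peak beyond separation limit"))
    } else kept[[length(kept) + 1L]] <- p
  }
  list(kept = kept, rejected = rejected, reasons = reasons)
}

#' Pointwise mean and standard deviation of an aligned ensemble
#'
#' @param ensemble A [align_profiles()] result.
#' @return List with `x`, `mean`, `sd` (NA with a flag when n = 1), `n`.
#' @export
ensemble_stats <- function(ensemble) {
  stopifnot(inherits(ensemble, "profile_ensemble"))
  n <- nrow(ensemble$values)
  m <- colMeans(ensemble$values)
  s <- if (n >= 2) apply(ensemble$values, 2, stats::sd) else rep(NA_real_,
                                                                 ncol(ensemble$values))
  list(x = ensemble$x, mean = m, sd = s, n = n, sd_defined = n >= 2)
}
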