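#' Platelet model parameters
#'
#' Four functional platelet phenotypes are tracked: mobile x {resting,
#' activated} as number densities (platelets/uL) and bound x {resting,
#' activated} as immobile volume fractions. Mobile platelets adhere to the
#' collagen/TF surface and aggregate onto existing bound platelets, saturating
#' as the packing cap is approached; thrombin activates platelets with
#' first-order Hill kinetics and collagen contact activates surface-bound
#' platelets.
#'
#' @param inlet_count Inlet mobile platelet density (platelets/uL).
#' @param activated_fraction Fraction of inlet platelets already activated.
#' @param volume Single-platelet volume (m^3). Default 11 fL.
#' @param phi_max Packing cap for bound volume fraction.
#' @param adhesion_rate Base first-order capture rate onto the thrombogenic
#'   surface (1/s), before calibration.
#' @param aggregation_rate Base capture rate onto clot-adjacent cells (1/s).
#' @param adhesion_multiplier Single calibration knob scaling both capture
#'   rates; 4 is the post-calibration value (the only tuned parameter).
#' @param resting_efficiency Relative capture efficiency of resting vs
#'   activated mobile platelets.
#' @param phi_aggregation Bound-activated fraction a neighbour cell needs
#'   before it seeds aggregation.
#' @param k_act Saturating thrombin-driven activation rate (1/s).
#' @param ec50 Thrombin concentration of half-maximal activation (nM).
#' @param hill Hill exponent of the activation law.
#' @param k_contact Collagen contact activation rate of surface-bound
#'   resting platelets (1/s).
#' @param D_brownian Brownian platelet diffusivity (m^2/s).
#' @param d_platelet,d_fiber Effective grain diameters (m) of packed
#'   platelets and fibrin fibres in the Kozeny-Carman resistance law.
#' @param nu_fibrin Fibrin volume fraction per nM of fibrin (1.5e-4 per
#'   1000 nM).
#' @return List of class `platelet_params`.
#' @export
platelet_params <- function(inlet_count = 2.5e5, activated_fraction = 0.005,
                            volume = 1.1e-17, phi_max = 0.6,
                            adhesion_rate = 0.065, aggregation_rate = 0.065,
                            adhesion_multiplier = 4,
                            resting_efficiency = 0.3,
                            phi_aggregation = 0.01,
                            k_act = 0.5, ec50 = 1, hill = 1,
                            k_contact = 0.065, D_brownian = 1e-13,
                            d_platelet = 2e-6, d_fiber = 1e-7,
                            nu_fibrin = 1.5e-7) {
  structure(as.list(environment()), class = "platelet_params")
}

#' Initialise platelet phenotype fields
#'
#' @param mesh A [build_mesh()] mesh.
#' @param params A [platelet_params()].
#' @return List of class `platelet_state`: `mobile_resting`,
#'   `mobile_activated` (platelets/uL), `bound_resting`, `bound_activated`
#'   (volume fraction), all `nx x ny`.
#' @export
platelet_state <- function(mesh, params = platelet_params()) {
  z <- matrix(0, mesh$nx, mesh$ny)
  structure(list(
    mobile_resting = matrix(params$inlet_count * (1 - params$activated_fraction),
                            mesh$nx, mesh$ny),
    mobile_activated = matrix(params$inlet_count * params$activated_fraction,
                              mesh$nx, mesh$ny),
    bound_resting = z, bound_activated = z),
    class = "platelet_state")
}

#' Near-wall platelet margination model
#'
#' Red-cell collisions expel platelets toward the walls. The model is a
#' conserved enhancement profile: platelet density in a near-wall layer of
#' thickness `delta` at either wall is `peak` times the bulk density, with
#' the bulk depleted so that every vertical column conserves its platelet
#' count.
#'
#' @param mesh A [build_mesh()] mesh.
#' @param peak Near-wall/bulk enhancement ratio. Default 3.
#' @param delta Boundary-layer thickness (um). Default 5.
#' @return List of class `margination_model` with the per-row enhancement
#'   vector `E` (length `ny`), normalised so `sum(E) == ny`.
#' @export
margination_model <- function(mesh, peak = 3, delta = 5) {
  stopifnot(peak >= 1, delta > 0)
  y <- mesh$yc; h <- mesh$geom$height
  raw <- ifelse(y < delta | y > h - delta, peak, 1)
  E <- raw * length(raw) / sum(raw)   # discrete conservation: sum(E) = ny
  structure(list(E = E, peak = peak, delta = delta), class = "margination_model")
}

#' Redistribute mobile platelets toward the walls
#'
#' Multiplicative reweighting of each vertical column by the enhancement
#' profile, rescaled so the column total is exactly conserved. With a flat
#' profile (`E == 1`) this is the identity.
#'
#' @param field `nx x ny` mobile platelet density matrix.
#' @param model A [margination_model()].
#' @return Redistributed matrix of the same shape.
#' @export
margination_redistribution <- function(field, model) {
  stopifnot(inherits(model, "margination_model"))
  w <- sweep(field, 2, model$E, `*`)
  tot <- rowSums(field); wtot <- rowSums(w)
  scale <- ifelse(wtot > 0, tot / wtot, 1)
  w * scale
}

#' Thrombin-driven and contact activation of platelets
#'
#' Resting platelets (mobile and bound) convert to their activated
#' counterparts at rate `k_act * T^n / (ec50^n + T^n)` in local thrombin `T`.
#' Bound resting platelets in contact with an activating surface -- the
#' collagen faces, or a cell whose neighbourhood already holds activated
#' bound platelets (contact-dependent activation on the clot surface) --
#' additionally convert at the fixed contact rate, so deposition can
#' propagate even before the thrombin burst. Platelet count is conserved
#' (pure conversion).
#'
#' @param state A [platelet_state()].
#' @param thrombin `nx x ny` thrombin field (nM).
#' @param mesh Mesh (for the collagen faces).
#' @param dt Time step (s).
#' @param params A [platelet_params()].
#' @return Updated `platelet_state`.
#' @export
activation_step <- function(state, thrombin, mesh, dt, params = platelet_params()) {
  stopifnot(all(thrombin >= 0), dt > 0)
  Tn <- thrombin^params$hill
  rate <- params$k_act * Tn / (params$ec50^params$hill + Tn)
  f <- 1 - exp(-rate * dt)   # exact exponential conversion for frozen rate
  conv_m <- state$mobile_resting * f
  state$mobile_resting <- state$mobile_resting - conv_m
  state$mobile_activated <- state$mobile_activated + conv_m
  fb <- f
  contact <- .clot_contact(state$bound_activated, mesh,
                           params$phi_aggregation)
  contact[mesh$thromb, 1] <- TRUE
  fb[contact] <- 1 - (1 - fb[contact]) * exp(-params$k_contact * dt)
  conv_b <- state$bound_resting * fb
  state$bound_resting <- state$bound_resting - conv_b
  state$bound_activated <- state$bound_activated + conv_b
  state
}

# cells whose own or 4-neighbour bound-activated fraction exceeds phi_agg
.clot_contact <- function(ba, mesh, phi_agg) {
  nx <- mesh$nx; ny <- mesh$ny
  seed <- ba > phi_agg
  nb <- seed
  nb[-1, ] <- nb[-1, ] | seed[-nx, ]
  nb[-nx, ] <- nb[-nx, ] | seed[-1, ]
  nb[, -1] <- nb[, -1] | seed[, -ny]
  nb[, -ny] <- nb[, -ny] | seed[, -1]
  nb
}

#' Adhesion to the thrombogenic surface and aggregation onto the clot
#'
#' First-order capture of mobile platelets in capture-competent cells:
#' cells over a thrombogenic face (adhesion) and cells with a neighbouring
#' (or own) bound-activated fraction above `phi_aggregation` (aggregation).
#' Capture converts mobile number density to bound volume fraction through
#' the single-platelet volume and saturates with the factor
#' `(1 - phi/phi_max)`. Resting platelets are captured at reduced
#' efficiency. The step sub-divides `dt` so the packing cap is never
#' overshot.
#'
#' @param state A [platelet_state()].
#' @param mesh Mesh.
#' @param dt Time step (s).
#' @param params A [platelet_params()].
#' @return Updated `platelet_state`.
#' @export
adhesion_aggregation_step <- function(state, mesh, dt, params = platelet_params()) {
  stopifnot(dt > 0)
  nx <- mesh$nx; ny <- mesh$ny
  mult <- params$adhesion_multiplier
  nb <- .clot_contact(state$bound_activated, mesh, params$phi_aggregation)
  rate <- matrix(0, nx, ny)
  rate[nb] <- params$aggregation_rate * mult
  rate[mesh$thromb, 1] <- rate[mesh$thromb, 1] + params$adhesion_rate * mult
  if (all(rate == 0)) return(state)

  # platelets/uL -> volume fraction per captured platelet
  cap_vol <- params$volume * 1e9   # (plt/uL * m^3) -> vol fraction: 1/uL = 1e9/m^3
  nsub <- max(1L, ceiling(dt * max(rate) / 0.2))
  h <- dt / nsub
  for (s in seq_len(nsub)) {
    phi <- state$bound_resting + state$bound_activated
    sat <- pmax(1 - phi / params$phi_max, 0)
    fa <- 1 - exp(-rate * sat * h)
    fr <- 1 - exp(-rate * sat * params$resting_efficiency * h)
    da <- state$mobile_activated * fa
    dr <- state$mobile_resting * fr
    # cap at phi_max
    room <- pmax(params$phi_max - phi, 0)
    dphi <- (da + dr) * cap_vol
    over <- dphi > room
    if (any(over)) {
      sc <- ifelse(over, room / pmax(dphi, .Machine$double.xmin), 1)
      da <- da * sc; dr <- dr * sc
    }
    state$mobile_activated <- state$mobile_activated - da
    state$mobile_resting <- state$mobile_resting - dr
    state$bound_activated <- state$bound_activated + da * cap_vol
    state$bound_resting <- state$bound_resting + dr * cap_vol
  }
  state
}

#' Kozeny-Carman viscous resistance of the platelet/fibrin composite
#'
#' The Brinkman coefficient (inverse permeability) of each cell is the sum
#' of a packed-platelet and a fibrin-fibre Kozeny-Carman term,
#' `k(phi; d) = 180 phi^2 / ((1 - phi)^3 d^2)`, with the fibrin volume
#' fraction obtained from the fibrin concentration via `nu_fibrin`.
#'
#' @param state A [platelet_state()].
#' @param fibrin `nx x ny` fibrin field (nM), or `NULL`.
#' @param params A [platelet_params()].
#' @return `nx x ny` resistance matrix (1/m^2).
#' @examples
#' kz <- function(phi, d) 180 * phi^2 / ((1 - phi)^3 * d^2)
#' kz(0.3, 2e-6)   # ~1.18e13 1/m^2
#' @export
resistance_from_composition <- function(state, fibrin = NULL,
                                        params = platelet_params()) {
  phi_b <- state$bound_resting + state$bound_activated
  if (any(phi_b >= 1)) stop("bound platelet fraction >= 1: upstream invariant breached")
  kz <- function(phi, d) 180 * phi^2 / ((1 - phi)^3 * d^2)
  k <- kz(phi_b, params$d_platelet)
  if (!is.null(fibrin)) {
    phi_f <- pmin(fibrin * params$nu_fibrin, 0.99)
    if (any(phi_f < 0)) stop("negative fibrin concentration")
    k <- k + kz(phi_f, params$d_fiber)
  }
  k
}
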