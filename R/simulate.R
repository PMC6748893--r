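#' Configuration for a coupled clot-growth simulation
#'
#' Bundles geometry, fluid, network, platelet and numerical settings for
#' [simulate_clot_growth()]. A `condition` name from
#' [canonical_conditions()] sets the thrombogenic surface length and TF
#' density; otherwise pass a full [channel_geometry()].
#'
#' @param condition One of `"short_lo"`, `"short_hi"`, `"long_lo"`,
#'   `"long_hi"`, or `NULL` when `geometry` is given.
#' @param geometry Optional [channel_geometry()] overriding `condition`.
#' @param dx,dy Cell size (um). Default 2 (desk-scale mesh).
#' @param dt Transport/platelet coupling step (s). Default 0.5.
#' @param flow_interval Simulated seconds between flow re-solves; the
#'   Brinkman resistance evolves on tens of seconds, so the quasi-steady
#'   flow field is refreshed on that scale. Default 10.
#' @param t_end End time (s). Default 450 (the measurement horizon).
#' @param sample_interval Kinetics sampling cadence (s). Default 50,
#'   mirroring the fluorescence measurement cadence.
#' @param snapshot_times Times (s) at which full fields are stored.
#' @param seed RNG seed stored with the run (the core solver is
#'   deterministic; the seed makes downstream stochastic post-processing
#'   reproducible).
#' @param fluid,network,platelet,surface Component parameter objects.
#' @param hematocrit Red-cell volume fraction for shear-enhanced diffusion.
#' @param D_protein Brownian diffusivity of the plasma proteins (m^2/s).
#' @param gate_phi_ref Bound-platelet fraction giving full procoagulant
#'   surface availability for the gated reactions.
#' @param gate_leak Residual relative rate of gated reactions in
#'   platelet-free plasma.
#' @return List of class `simulation_config`.
#' @export
simulation_config <- function(condition = "long_hi", geometry = NULL,
                              dx = 2, dy = 2, dt = 0.5, flow_interval = 10,
                              t_end = 450, sample_interval = 50,
                              snapshot_times = 400, seed = 1,
                              fluid = fluid_properties(),
                              network = coagulation_network(),
                              platelet = platelet_params(),
                              surface = surface_params(),
                              hematocrit = 0.4, D_protein = 5e-11,
                              gate_phi_ref = 0.05, gate_leak = 0) {
  if (is.null(geometry)) {
    cc <- canonical_conditions()
    if (!condition %in% cc$condition)
      stop("condition must be one of ", paste(cc$condition, collapse = ", "),
           " or supply a geometry")
    row <- cc[cc$condition == condition, ]
    geometry <- channel_geometry(surface_length = row$surface_length,
                                 tf_density = row$tf_density)
  } else if (is.null(condition)) condition <- "custom"
  stopifnot(t_end > 0, dt > 0, sample_interval > 0)
  if (any(snapshot_times > t_end))
    stop("snapshot_times must lie within the simulated horizon")
  structure(list(condition = condition, geometry = geometry, dx = dx,
                 dy = dy, dt = dt, flow_interval = flow_interval,
                 t_end = t_end, sample_interval = sample_interval,
                 snapshot_times = snapshot_times, seed = seed, fluid = fluid,
                 network = network, platelet = platelet, surface = surface,
                 hematocrit = hematocrit, D_protein = D_protein,
                 gate_phi_ref = gate_phi_ref, gate_leak = gate_leak),
            class = "simulation_config")
}

#' Simulate clot growth on the thrombogenic surface
#'
#' Orchestrates the coupled time loop: (1) Kozeny-Carman resistance from the
#' current platelet/fibrin composition, (2) quasi-steady Stokes-Brinkman
#' flow re-solve, (3) shear-dependent effective diffusivities, (4) species
#' reaction-convection-diffusion transport with thrombogenic-surface fluxes,
#' (5) platelet transport, margination, activation, adhesion and
#' aggregation. Domain-integrated platelet, thrombin and fibrin kinetics are
#' sampled on the measurement cadence and full fields are stored at the
#' snapshot times.
#'
#' @param config A [simulation_config()].
#' @param verbose Print progress every flow re-solve.
#' @return Object of class `clot_sim`: `kinetics` (data frame: time_s,
#'   platelet, thrombin, fibrin; platelet as bound-platelet area um^2,
#'   thrombin/fibrin as domain integrals nM um^2), `snapshots` (list per
#'   snapshot time with bound/fibrin/thrombin/resistance fields and the flow
#'   state), final `fields`, `platelets`, `surface`, `mesh`, `config`.
#' @export
simulate_clot_growth <- function(config, verbose = FALSE) {
  stopifnot(inherits(config, "simulation_config"))
  set.seed(config$seed)
  mesh <- build_mesh(config$geometry, config$dx, config$dy)
  net <- config$network
  pp <- config$platelet
  fields <- init_species_fields(mesh, net)
  surf <- surface_state(mesh)
  plt <- platelet_state(mesh, pp)
  marg <- margination_model(mesh)
  cell_area <- mesh$dx * mesh$dy   # um^2

  nsteps <- round(config$t_end / config$dt)
  sample_every <- max(1L, round(config$sample_interval / config$dt))
  flow_every <- max(1L, round(config$flow_interval / config$dt))

  kin <- data.frame(time_s = numeric(0), platelet = numeric(0),
                    thrombin = numeric(0), fibrin = numeric(0))
  take_sample <- function(t) {
    data.frame(time_s = t,
               platelet = sum(plt$bound_resting + plt$bound_activated) * cell_area,
               thrombin = sum(fields$FIIa) * cell_area,
               fibrin = sum(fields$fibrin) * cell_area)
  }
  kin <- rbind(kin, take_sample(0))
  snapshots <- list()
  flow <- NULL; Dfield <- NULL; Dplt <- NULL

  stage <- "init"
  wrap <- function(expr, name, t) {
    stage <<- name
    tryCatch(expr, error = function(e)
      stop(sprintf("stage '%s' failed at t = %g s: %s", name, t,
                   conditionMessage(e)), call. = FALSE))
  }

  for (step in seq_len(nsteps)) {
    t <- step * config$dt
    if ((step - 1L) %% flow_every == 0L) {
      kres <- wrap(resistance_from_composition(plt, fields$fibrin, pp),
                   "resistance", t)
      flow <- wrap(solve_flow(mesh, config$fluid, kres), "flow", t)
      shear <- wrap(shear_field(flow), "shear", t)
      Dfield <- effective_diffusivity(config$D_protein, shear,
                                      config$hematocrit)
      Dplt <- effective_diffusivity(pp$D_brownian, shear, config$hematocrit)
      if (verbose)
        message(sprintf("t = %5.1f s  phi_max = %.3f  thrombin tot = %.3g",
                        t, max(plt$bound_resting + plt$bound_activated),
                        sum(fields$FIIa) * cell_area))
    }
    phi <- plt$bound_resting + plt$bound_activated
    gate <- config$gate_leak +
      (1 - config$gate_leak) * pmin(phi / config$gate_phi_ref, 1)
    st <- wrap(advance_transport(fields, flow, config$dt,
                                 diffusivity = Dfield, inlet = net$baselines,
                                 network = net, gate = gate, surface = surf,
                                 surf_params = config$surface),
               "species_transport", t)
    fields <- st$fields; surf <- st$surface

    dxm <- mesh$dx * 1e-6; dym <- mesh$dy * 1e-6
    for (sp in c("mobile_resting", "mobile_activated")) {
      cin <- if (sp == "mobile_resting")
        pp$inlet_count * (1 - pp$activated_fraction)
      else pp$inlet_count * pp$activated_fraction
      plt[[sp]] <- wrap(cs_adi_step(plt[[sp]], flow$u, flow$v, Dplt,
                                    config$dt, dxm, dym, cin, 0L),
                        "platelet_transport", t)
    }
    plt$mobile_resting <- margination_redistribution(plt$mobile_resting, marg)
    plt$mobile_activated <- margination_redistribution(plt$mobile_activated, marg)
    plt <- wrap(activation_step(plt, fields$FIIa, mesh, config$dt, pp),
                "platelet_activation", t)
    plt <- wrap(adhesion_aggregation_step(plt, mesh, config$dt, pp),
                "platelet_adhesion", t)

    if (step %% sample_every == 0L) kin <- rbind(kin, take_sample(t))
    hit <- abs(config$snapshot_times - t) < config$dt / 2
    if (any(hit)) {
      kres <- resistance_from_composition(plt, fields$fibrin, pp)
      snapshots[[as.character(config$snapshot_times[hit][1])]] <- list(
        time_s = t,
        bound = plt$bound_resting + plt$bound_activated,
        bound_activated = plt$bound_activated,
        fibrin = fields$fibrin, thrombin = fields$FIIa,
        resistance = kres, flow = solve_flow(mesh, config$fluid, kres))
    }
  }
  structure(list(kinetics = kin, snapshots = snapshots, fields = fields,
                 platelets = plt, surface = surf, mesh = mesh, flow = flow,
                 config = config),
            class = "clot_sim")
}

#' @exportS3Method
print.clot_sim <- function(x, ...) {
  kk <- x$kinetics[nrow(x$kinetics), ]
  cat(sprintf("Clot-growth simulation [%s]: %g s on %d x %d cells\n",
              x$config$condition, kk$time_s, x$mesh$nx, x$mesh$ny))
  cat(sprintf("  final totals: platelet %.3g um^2, thrombin %.3g nM um^2, fibrin %.3g nM um^2\n",
              kk$platelet, kk$thrombin, kk$fibrin))
  invisible(x)
}

#' @exportS3Method
summary.clot_sim <- function(object, ...) {
  out <- list(condition = object$config$condition,
              kinetics = object$kinetics)
  if (length(object$snapshots)) {
    sn <- object$snapshots[[1]]
    shell <- extract_shell(sn$bound, object$mesh,
                           phi_max = object$config$platelet$phi_max)
    core <- extract_core(sn$fibrin, object$mesh)
    out$shell_height <- shell$height
    out$core_height <- core$height
    out$occlusivity <- occlusivity(shell, object$mesh$geom$height)
  }
  class(out) <- "summary.clot_sim"
  out
}

#' @exportS3Method
print.summary.clot_sim <- function(x, ...) {
  cat("Condition:", x$condition, "\n")
  if (!is.null(x$shell_height))
    cat(sprintf("Shell peak height %.1f um (occlusivity %.2f), core peak height %.1f um\n",
                x$shell_height, x$occlusivity, x$core_height))
  print(x$kinetics, row.names = FALSE)
  invisible(x)
}

#' @exportS3Method
plot.clot_sim <- function(x, which = c("kinetics", "fields"), ...) {
  which <- match.arg(which)
  if (which == "kinetics") {
    k <- x$kinetics
    op <- graphics::par(mfrow = c(1, 3), mar = c(4, 4, 2, 1))
    on.exit(graphics::par(op))
    for (an in c("platelet", "thrombin", "fibrin")) {
      graphics::plot(k$time_s, k[[an]], type = "b", xlab = "time (s)",
                     ylab = an, main = an)
    }
  } else {
    if (!length(x$snapshots)) stop("no snapshots stored")
    sn <- x$snapshots[[1]]
    op <- graphics::par(mfrow = c(2, 1), mar = c(4, 4, 2, 1))
    on.exit(graphics::par(op))
    graphics::image(x$mesh$xc, x$mesh$yc, sn$bound, xlab = "x (um)",
                    ylab = "y (um)", main = "bound platelet fraction")
    graphics::image(x$mesh$xc, x$mesh$yc, sn$fibrin, xlab = "x (um)",
                    ylab = "y (um)", main = "fibrin (nM)")
  }
  invisible(x)
}

#' Normalise kinetics families to their cross-condition maximum
#'
#' Model outputs are in absolute units while fluorescence data are in
#' arbitrary units; both are made comparable by dividing each analyte's
#' family of time courses by the family maximum, so the normalised family
#' peaks at 1.
#'
#' @param kinetics_list Named list (one entry per condition) of kinetics
#'   data frames as produced by [simulate_clot_growth()] (columns `time_s`
#'   and one per analyte).
#' @param analytes Analyte columns to normalise.
#' @return List of the same shape with normalised analyte columns.
#' @export
normalize_kinetics <- function(kinetics_list,
                               analytes = c("platelet", "thrombin", "fibrin")) {
  stopifnot(length(kinetics_list) > 0)
  for (an in analytes) {
    mx <- max(vapply(kinetics_list, function(k) max(k[[an]]), 0))
    if (mx <= 0) stop("all-zero series for analyte ", an,
                      ": nothing to normalize")
    for (nm in names(kinetics_list))
      kinetics_list[[nm]][[an]] <- kinetics_list[[nm]][[an]] / mx
  }
  kinetics_list
}

#' Synergy fold-change between the combined and single-factor conditions
#'
#' Ratio of the domain-integrated analyte at time `t` between the combined
#' long-surface/high-TF condition and the short/low reference, together with
#' the two single-factor ratios (length only, density only).
#'
#' @param outputs Named list with elements `short_lo`, `short_hi`,
#'   `long_lo`, `long_hi`: either `clot_sim` objects or kinetics data
#'   frames.
#' @param analyte One of `"platelet"`, `"thrombin"`, `"fibrin"`.
#' @param t Time (s) at which to compare.
#' @return List with `fold` (combined/reference), `length_fold`,
#'   `density_fold`, and `infinite` flag when the reference is zero.
#' @export
synergy_ratio <- function(outputs, analyte = "thrombin", t = 450) {
  need <- c("short_lo", "short_hi", "long_lo", "long_hi")
  if (!all(need %in% names(outputs)))
    stop("outputs must contain all four canonical conditions")
  val <- function(o) {
    k <- if (inherits(o, "clot_sim")) o$kinetics else o
    i <- which.min(abs(k$time_s - t))
    if (abs(k$time_s[i] - t) > 1e-6)
      warning("no sample exactly at t = ", t, "; using t = ", k$time_s[i])
    k[[analyte]][i]
  }
  ref <- val(outputs$short_lo)
  inf <- ref == 0
  dv <- function(a) if (inf) Inf else a / ref
  list(fold = dv(val(outputs$long_hi)),
       length_fold = dv(val(outputs$long_lo)),
       density_fold = dv(val(outputs$short_hi)),
       infinite = inf)
}
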