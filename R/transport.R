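#' Surface reaction parameters for the thrombogenic patch
#'
#' Tissue factor patterned on the collagen strip captures plasma FVIIa to
#' form the extrinsic tenase TF:FVIIa, which activates FIX and FX in the
#' adjacent fluid; the TFPI:FXa complex shuts TF:FVIIa down by forming a
#' quaternary dead-end complex. Units: surface species mol/m^2, bulk nM.
#'
#' @param kon_tf TF + FVIIa association rate (1/(nM s)).
#' @param kcat_ix,km_ix Turnover (1/s) and Michaelis constant (nM) for FIX
#'   activation by TF:FVIIa.
#' @param kcat_x,km_x Same for FX activation.
#' @param k_tfpi TFPI:FXa + TF:FVIIa quenching rate (1/(nM s)).
#' @return List of class `surface_params`.
#' @export
surface_params <- function(kon_tf = 2.3e-2, kcat_ix = 1.0, km_ix = 243,
                           kcat_x = 6.0, km_x = 450, k_tfpi = 0.32) {
  structure(list(kon_tf = kon_tf, kcat_ix = kcat_ix, km_ix = km_ix,
                 kcat_x = kcat_x, km_x = km_x, k_tfpi = k_tfpi),
            class = "surface_params")
}

#' Initialise the thrombogenic surface state
#'
#' @param mesh A [build_mesh()] mesh.
#' @return List of class `surface_state` with per-thrombogenic-face vectors
#'   `TF` (free sites, mol/m^2), `TFVIIa` (active extrinsic tenase) and
#'   `dead` (TFPI-quenched complex), plus the face indices `ix`.
#' @export
surface_state <- function(mesh) {
  stopifnot(inherits(mesh, "channel_mesh"))
  ix <- which(mesh$thromb)
  s0 <- surface_site_density(mesh$geom$tf_density)
  structure(list(ix = ix, TF = rep(s0, length(ix)),
                 TFVIIa = rep(0, length(ix)), dead = rep(0, length(ix))),
            class = "surface_state")
}

#' Boundary reaction fluxes at the thrombogenic surface
#'
#' Instantaneous rates for the surface species and the bulk fluxes they
#' inject into (or draw from) the wall-adjacent cells. TF:FVIIa formation
#' consumes free TF sites (bounded by the patterned density); activation of
#' FIX/FX follows Michaelis-Menten kinetics in the near-wall substrate
#' concentration; TFPI:FXa irreversibly quenches TF:FVIIa.
#'
#' @param surface A [surface_state()].
#' @param conc_wall Named list/data frame of near-wall concentrations (nM)
#'   with elements `FVII`, `FVIIa`, `FIX`, `FX`, `TFPI_FXa`, each a vector
#'   over the thrombogenic faces.
#' @param params A [surface_params()].
#' @return List with `surface` (d/dt of TF, TFVIIa, dead in mol/m^2/s) and
#'   `bulk` (mol/m^2/s fluxes, positive into the fluid, for FVII, FVIIa,
#'   FIX, FIXa, FX, FXa, TFPI_FXa).
#' @export
surface_reaction_flux <- function(surface, conc_wall, params = surface_params()) {
  stopifnot(inherits(surface, "surface_state"))
  # TF captures both FVIIa and zymogen FVII; surface-bound FVII is
  # autoactivated by neighbouring TF:FVIIa fast compared to the capture
  # step, so both channels feed the active complex
  r_bind7 <- params$kon_tf * conc_wall$FVII * surface$TF
  r_bind <- params$kon_tf * conc_wall$FVIIa * surface$TF
  r_ix <- params$kcat_ix * surface$TFVIIa * conc_wall$FIX /
    (params$km_ix + conc_wall$FIX)
  r_x <- params$kcat_x * surface$TFVIIa * conc_wall$FX /
    (params$km_x + conc_wall$FX)
  r_q <- params$k_tfpi * conc_wall$TFPI_FXa * surface$TFVIIa
  list(surface = list(TF = -(r_bind + r_bind7),
                      TFVIIa = r_bind + r_bind7 - r_q, dead = r_q),
       bulk = list(FVII = -r_bind7, FVIIa = -r_bind, FIX = -r_ix,
                   FIXa = r_ix, FX = -r_x, FXa = r_x, TFPI_FXa = -r_q))
}

# advance surface state + wall cells over dt with explicit substeps
.surface_substep <- function(surface, fields, mesh, dt, params, nsub = 5L) {
  ix <- surface$ix
  if (!length(ix)) return(list(surface = surface, fields = fields))
  dy_m <- mesh$dy * 1e-6
  to_nM <- 1e6 / dy_m   # mol/m^2/s -> nM/s in the wall cell
  h <- dt / nsub
  for (s in seq_len(nsub)) {
    cw <- list(FVII = fields$FVII[ix, 1], FVIIa = fields$FVIIa[ix, 1],
               FIX = fields$FIX[ix, 1], FX = fields$FX[ix, 1],
               TFPI_FXa = fields$TFPI_FXa[ix, 1])
    fl <- surface_reaction_flux(surface, cw, params)
    # amounts over the sub-step, clamped so neither surface sites nor
    # near-wall substrate can be overdrawn
    bind_a <- pmin(-fl$bulk$FVIIa * h, cw$FVIIa / to_nM)   # mol/m^2
    bind_7 <- pmin(-fl$bulk$FVII * h, cw$FVII / to_nM)
    tot <- bind_a + bind_7
    over <- tot > surface$TF
    if (any(over)) {
      sc <- ifelse(over, surface$TF / pmax(tot, .Machine$double.xmin), 1)
      bind_a <- bind_a * sc; bind_7 <- bind_7 * sc
    }
    bind <- bind_a + bind_7
    quench <- pmin(fl$surface$dead * h, surface$TFVIIa + bind,
                   cw$TFPI_FXa / to_nM)
    a_ix <- pmin(fl$bulk$FIXa * h, cw$FIX / to_nM)
    a_x <- pmin(fl$bulk$FXa * h, cw$FX / to_nM)
    surface$TF <- surface$TF - bind
    surface$TFVIIa <- surface$TFVIIa + bind - quench
    surface$dead <- surface$dead + quench
    fields$FVII[ix, 1] <- fields$FVII[ix, 1] - bind_7 * to_nM
    fields$FVIIa[ix, 1] <- fields$FVIIa[ix, 1] - bind_a * to_nM
    fields$TFPI_FXa[ix, 1] <- fields$TFPI_FXa[ix, 1] - quench * to_nM
    fields$FIX[ix, 1] <- fields$FIX[ix, 1] - a_ix * to_nM
    fields$FIXa[ix, 1] <- fields$FIXa[ix, 1] + a_ix * to_nM
    fields$FX[ix, 1] <- fields$FX[ix, 1] - a_x * to_nM
    fields$FXa[ix, 1] <- fields$FXa[ix, 1] + a_x * to_nM
  }
  list(surface = surface, fields = fields)
}

#' Advance species fields by convection, diffusion and reactions
#'
#' One coupling step of the reaction-convection-diffusion system. Each
#' transported species is advanced with an unconditionally stable
#' implicit-upwind ADI (finite-volume) sweep, then thrombogenic-surface
#' boundary fluxes are applied, then the bulk reaction network is integrated
#' per cell with adaptive Heun sub-steps. Inlet cells hold plasma baselines
#' (Dirichlet), the outlet is zero-gradient, walls are zero-flux. Fibrin is
#' polymerised in place and is not transported.
#'
#' @param fields Named list of `nx x ny` concentration matrices (nM).
#' @param flow A [solve_flow()] state, or `NULL` for a quiescent fluid.
#' @param dt Time step (s).
#' @param diffusivity Named list (or single value) of diffusivities per
#'   species: scalar m^2/s or an `nx x ny` matrix (e.g. shear-enhanced).
#' @param mesh Mesh; taken from `flow` if omitted.
#' @param inlet Named vector of inlet Dirichlet values (nM); species missing
#'   from it get a zero-concentration inlet. Ignored for a closed domain.
#' @param closed If `TRUE`, all boundaries are zero-flux (closed box).
#' @param network Optional [coagulation_network()] to react after transport.
#' @param gate Per-cell multiplier (`nx x ny` matrix or scalar, default 1)
#'   for platelet-surface-gated reactions.
#' @param surface Optional [surface_state()]; when given, surface boundary
#'   reactions are applied and the updated state is returned.
#' @param surf_params A [surface_params()].
#' @param immobile Character vector of species not transported.
#' @param react_safety Relative local-error tolerance per reaction sub-step
#'   (embedded Euler/Heun estimate).
#' @return List with updated `fields` and (if applicable) `surface`.
#' @export
advance_transport <- function(fields, flow, dt, diffusivity, mesh = NULL,
                              inlet = NULL, closed = FALSE, network = NULL,
                              gate = 1, surface = NULL,
                              surf_params = surface_params(),
                              immobile = "fibrin", react_safety = 1e-4) {
  if (is.null(mesh)) {
    if (is.null(flow)) stop("need a mesh when flow is NULL")
    mesh <- flow$mesh
  }
  stopifnot(dt > 0)
  nx <- mesh$nx; ny <- mesh$ny
  dx <- mesh$dx * 1e-6; dy <- mesh$dy * 1e-6
  if (is.null(flow)) {
    u <- matrix(0, nx + 1L, ny); v <- matrix(0, nx, ny + 1L)
  } else {
    u <- flow$u; v <- flow$v
  }
  Dof <- function(sp) {
    D <- if (is.list(diffusivity)) diffusivity[[sp]] else diffusivity
    if (is.null(D)) stop("no diffusivity for species ", sp)
    if (is.matrix(D)) D else matrix(D, nx, ny)
  }
  for (sp in names(fields)) {
    if (sp %in% immobile) next
    cin <- if (closed) 0 else if (!is.null(inlet) && sp %in% names(inlet))
      inlet[[sp]] else 0
    fields[[sp]] <- cs_adi_step(fields[[sp]], u, v, Dof(sp), dt, dx, dy,
                                cin, as.integer(closed))
    if (any(!is.finite(fields[[sp]])))
      stop("transport produced non-finite values in species ", sp)
  }
  if (!is.null(surface)) {
    st <- .surface_substep(surface, fields, mesh, dt, surf_params)
    surface <- st$surface; fields <- st$fields
  }
  if (!is.null(network)) {
    conc <- vapply(network$species, function(sp) {
      m <- fields[[sp]]
      if (is.null(m)) stop("fields is missing network species ", sp)
      as.numeric(m)
    }, numeric(nx * ny))
    cp <- .network_compiled(network)
    g <- if (is.matrix(gate)) as.numeric(gate) else rep(gate, nx * ny)
    out <- cs_react(conc, cp$rtype, cp$ia, cp$ib, cp$k1, cp$k2, cp$stoich,
                    cp$gated, g, dt, react_safety, 100000L)
    if (any(!is.finite(out)))
      stop("reaction integration produced non-finite concentrations")
    for (s in seq_along(network$species))
      fields[[network$species[s]]] <- matrix(out[, s], nx, ny)
  }
  list(fields = fields, surface = surface)
}

#' Initialise species fields at plasma baselines
#'
#' @param mesh A [build_mesh()] mesh.
#' @param network A [coagulation_network()].
#' @return Named list of `nx x ny` matrices (nM).
#' @export
init_species_fields <- function(mesh, network = coagulation_network()) {
  lapply(as.list(network$baselines), function(b)
    matrix(b, mesh$nx, mesh$ny))
}
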