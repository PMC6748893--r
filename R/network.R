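#' Default tissue-factor-pathway coagulation network
#'
#' A mass-action / Michaelis-Menten reaction table for the extrinsic
#' (TF-initiated) pathway, restricted to the nine plasma proteins tracked by
#' the simulator -- factors II, V, VII, VIII, IX, X, fibrinogen and TFPI,
#' plus their activated forms and the tenase (FIXa:FVIIIa), prothrombinase
#' (FXa:FVa) and TFPI:FXa complexes. Tissue factor itself lives on the
#' thrombogenic surface and is handled by [surface_reaction_flux()]. The
#' contact (FXII) pathway is absent: the experiments this model represents
#' inhibit it with corn trypsin inhibitor. Rate constants are
#' literature-scale defaults in nM and s units (Hockin-Mann lineage) and are
#' plain data, so any entry can be overridden.
#'
#' Complex-assembly reactions and fibrin polymerisation are flagged `gated`:
#' in the coupled simulation their rates are scaled by a local
#' platelet-surface availability factor (procoagulant membrane is supplied by
#' deposited platelets), which localises thrombin amplification and fibrin to
#' the growing clot.
#'
#' @return An object of class `coagulation_network`: list with `species`,
#'   `reactions` (data frame: name, type, a, b, k1, k2, gated), `stoich`
#'   (reactions x species matrix), and `baselines` (named nM vector for an
#'   average healthy subject).
#' @export
coagulation_network <- function() {
  species <- c("FVII", "FVIIa", "FIX", "FIXa", "FX", "FXa",
               "FVIII", "FVIIIa", "tenase", "FV", "FVa", "prothrombinase",
               "FII", "FIIa", "fibrinogen", "fibrin", "TFPI", "TFPI_FXa")
  baselines <- c(FVII = 10, FVIIa = 0.1, FIX = 90, FIXa = 0, FX = 170,
                 FXa = 0, FVIII = 0.7, FVIIIa = 0, tenase = 0, FV = 20,
                 FVa = 0, prothrombinase = 0, FII = 1400, FIIa = 0,
                 fibrinogen = 9000, fibrin = 0, TFPI = 2.5, TFPI_FXa = 0)

  rx <- function(name, type, a, b, k1, k2, gated, ...) {
    ch <- list(...) # named stoichiometry changes
    list(name = name, type = type, a = a, b = b, k1 = k1, k2 = k2,
         gated = gated, changes = ch)
  }
  reactions <- list(
    rx("xa_activates_vii",   "ma2", "FXa",  "FVII",  1.3e-2, 0, FALSE,
       FVII = -1, FVIIa = 1),
    rx("iia_activates_vii",  "ma2", "FIIa", "FVII",  2.3e-5, 0, FALSE,
       FVII = -1, FVIIa = 1),
    rx("tenase_assembly",    "ma2", "FIXa", "FVIIIa", 1e-2, 0, TRUE,
       FIXa = -1, FVIIIa = -1, tenase = 1),
    rx("tenase_dissoc",      "ma1", "tenase", NA,    5e-3,  0, FALSE,
       tenase = -1, FIXa = 1, FVIIIa = 1),
    rx("tenase_activates_x", "mm", "tenase", "FX",   20,   160, FALSE,
       FX = -1, FXa = 1),
    rx("iia_activates_viii", "ma2", "FIIa", "FVIII", 2e-2,  0, FALSE,
       FVIII = -1, FVIIIa = 1),
    rx("iia_activates_v",    "ma2", "FIIa", "FV",    2e-2,  0, FALSE,
       FV = -1, FVa = 1),
    rx("prothrombinase_assembly", "ma2", "FXa", "FVa", 1e-1, 0, TRUE,
       FXa = -1, FVa = -1, prothrombinase = 1),
    rx("prothrombinase_dissoc",   "ma1", "prothrombinase", NA, 1e-2, 0, FALSE,
       prothrombinase = -1, FXa = 1, FVa = 1),
    rx("prothrombinase_activates_ii", "mm", "prothrombinase", "FII", 30, 300,
       FALSE, FII = -1, FIIa = 1),
    rx("xa_activates_ii",    "ma2", "FXa", "FII",  7.5e-6, 0, FALSE,
       FII = -1, FIIa = 1),
    rx("iia_cleaves_fibrinogen", "mm", "FIIa", "fibrinogen", 59, 3160, TRUE,
       fibrinogen = -1, fibrin = 1),
    rx("tfpi_binds_xa",      "ma2", "TFPI", "FXa",  9e-4,  0, FALSE,
       TFPI = -1, FXa = -1, TFPI_FXa = 1),
    rx("tfpi_xa_dissoc",     "ma1", "TFPI_FXa", NA, 3.6e-4, 0, FALSE,
       TFPI_FXa = -1, TFPI = 1, FXa = 1)
  )
  nr <- length(reactions)
  stoich <- matrix(0, nr, length(species),
                   dimnames = list(vapply(reactions, `[[`, "", "name"),
                                   species))
  tab <- data.frame(
    name = vapply(reactions, `[[`, "", "name"),
    type = vapply(reactions, `[[`, "", "type"),
    a = vapply(reactions, `[[`, "", "a"),
    b = vapply(reactions, function(r) as.character(r$b), ""),
    k1 = vapply(reactions, `[[`, 0, "k1"),
    k2 = vapply(reactions, `[[`, 0, "k2"),
    gated = vapply(reactions, `[[`, TRUE, "gated"),
    stringsAsFactors = FALSE
  )
  for (r in seq_len(nr)) {
    ch <- reactions[[r]]$changes
    bad <- setdiff(names(ch), species)
    if (length(bad)) stop("unknown species in reaction table: ",
                          paste(bad, collapse = ", "))
    stoich[r, names(ch)] <- unlist(ch)
  }
  bad <- setdiff(stats::na.omit(c(tab$a, tab$b[tab$b != "NA"])), species)
  if (length(bad)) stop("unknown species in reaction table: ",
                        paste(bad, collapse = ", "))
  structure(list(species = species, reactions = tab, stoich = stoich,
                 baselines = baselines),
            class = "coagulation_network")
}

#' @exportS3Method
print.coagulation_network <- function(x, ...) {
  cat(sprintf("Coagulation network: %d species, %d reactions (%d platelet-surface gated)\n",
              length(x$species), nrow(x$reactions), sum(x$reactions$gated)))
  invisible(x)
}

#' Net reaction rates for a set of local concentrations
#'
#' Reference (pure R) evaluation of the reaction table: mass-action and
#' Michaelis-Menten laws, returning the net production rate of every species.
#' This is the rate function integrated (per cell, with adaptive
#' sub-stepping) inside [advance_transport()]; it is exposed so that the
#' network can be checked against independent stiff-ODE integrations.
#'
#' @param network A [coagulation_network()].
#' @param conc Named numeric vector of concentrations (nM) covering all
#'   species of the network.
#' @param gate Multiplier in `[0, 1]` applied to platelet-surface-gated
#'   reactions (1 = fully available procoagulant surface).
#' @return Named vector of net rates (nM/s).
#' @export
reaction_rates <- function(network, conc, gate = 1) {
  stopifnot(inherits(network, "coagulation_network"))
  if (!all(network$species %in% names(conc)))
    stop("conc must name every network species")
  if (any(conc < 0)) stop("concentrations must be non-negative")
  x <- conc[network$species]
  tab <- network$reactions
  rates <- numeric(nrow(tab))
  for (r in seq_len(nrow(tab))) {
    rates[r] <- switch(tab$type[r],
      ma1 = tab$k1[r] * x[[tab$a[r]]],
      ma2 = tab$k1[r] * x[[tab$a[r]]] * x[[tab$b[r]]],
      mm  = tab$k1[r] * x[[tab$a[r]]] * x[[tab$b[r]]] /
              (tab$k2[r] + x[[tab$b[r]]]),
      stop("unknown rate law type: ", tab$type[r]))
    if (tab$gated[r]) rates[r] <- rates[r] * gate
  }
  drop(rates %*% network$stoich)
}

# integer-index form of the table for the C++ integrator
.network_compiled <- function(network) {
  tab <- network$reactions
  typecode <- c(ma1 = 0L, ma2 = 1L, mm = 2L)
  list(rtype = typecode[tab$type],
       ia = match(tab$a, network$species) - 1L,
       ib = ifelse(is.na(match(tab$b, network$species)), 0L,
                   match(tab$b, network$species) - 1L),
       k1 = tab$k1, k2 = tab$k2,
       stoich = network$stoich,
       gated = as.integer(tab$gated))
}

#' Shear-enhanced effective diffusivity
#'
#' Red blood cells are not modelled explicitly; their effect on the lateral
#' transport of platelets and proteins enters through a shear-dependent
#' augmentation of the Brownian diffusivity:
#' `D_eff = D_b + k_sh * a_rbc^2 * shear * H * (1 - H)^0.8`,
#' with red-cell radius `a_rbc`, hematocrit `H` and a dimensionless
#' coefficient `k_sh`.
#'
#' @param D_brownian Brownian diffusivity (m^2/s).
#' @param shear Local shear rate (1/s); scalar or matrix.
#' @param hematocrit Red-cell volume fraction in `[0, 1)`. Default 0.4.
#' @param k_sh Enhancement coefficient. Default 0.15.
#' @param a_rbc Red-cell radius (m). Default 2.75e-6.
#' @return Effective diffusivity, same shape as `shear` (m^2/s).
#' @examples
#' effective_diffusivity(5e-11, 1000)  # ~3.5e-10 m^2/s at H = 0.4
#' @export
effective_diffusivity <- function(D_brownian, shear, hematocrit = 0.4,
                                  k_sh = 0.15, a_rbc = 2.75e-6) {
  stopifnot(D_brownian >= 0, all(shear >= 0),
            hematocrit >= 0, hematocrit < 1)
  D_brownian + k_sh * a_rbc^2 * shear * hematocrit * (1 - hematocrit)^0.8
}
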