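# Parameter sets for the biochemical, transport, and energetics models.
# Defaults are the standard maize (NADP-ME) parameterization at 25 C.

#' Kinetic parameters of the C4 biochemical model
#'
#' Enzyme capacities, Michaelis constants, hydration kinetics, respiration,
#' and compartment pH values. Area-based capacities (`V_cmax`, `V_pmax`,
#' `R_d`) are converted to volumetric rates with [volumetric_scaling()].
#'
#' Units follow field conventions: Rubisco constants `K_mC`/`K_mO` are in
#' ubar/mbar of gas-equivalent partial pressure; dissolved-species constants
#' are mol m-3. `k1` (CO2 hydration, s-1), `k2` (dehydration, s-1) and the
#' H2CO3 acid dissociation constant `K_a` (mol l-1) parameterize spontaneous
#' interconversion; `K_eq` (mol m-3, with [H+] expressed in mol m-3) is the
#' carbonic-anhydrase equilibrium constant.
#'
#' @param ... named overrides of any default.
#' @return object of class `kinetic_params`.
#' @export
kinetic_params <- function(...) {
  p <- list(
    V_cmax = 78.5,        # umol m-2 s-1, Rubisco carboxylation capacity
    V_pmax = 183,         # umol m-2 s-1, PEPC capacity
    K_mC = 485,           # ubar
    K_mO = 146,           # mbar
    S_CO = 2862,          # dimensionless Rubisco specificity
    K_h = 2e-2,           # mol m-3, PEPC bicarbonate constant
    V_CAmax = 2.1e11,     # umol m-3 s-1 (2.1e5 mol m-3 s-1; the mol-scale
                          # value is required for CA to sustain measured C4
                          # fluxes -- see the methods vignette)
    K_CO2 = 2.8,          # mol m-3, CA hydration MM constant
    K_HCO3 = 34,          # mol m-3, CA dehydration MM constant
    K_eq = 5.6e-4,        # mol m-3, CA equilibrium constant ([H+] in mol m-3)
    k1 = 3.9e-2,          # s-1, spontaneous CO2 hydration
    k2 = 23,              # s-1, spontaneous dehydration
    K_a = 0.2,            # mol l-1, H2CO3 acid dissociation constant
    R_d = 1.70,           # umol m-2 s-1, day respiration
    pH_cytosol = 7.5,
    pH_stroma = 7.8,
    pH_vascular = 7.0,
    pH_vacuole = 4.0
  )
  p <- utils::modifyList(p, list(...))
  stopifnot(all(vapply(p, is.numeric, TRUE)))
  if (any(unlist(p[c("V_cmax", "V_pmax", "K_mC", "K_mO", "S_CO", "K_h",
                     "V_CAmax", "K_CO2", "K_HCO3", "K_eq", "k1", "k2",
                     "K_a")]) <= 0)) {
    stop("kinetic constants must be positive")
  }
  p$gamma_star <- 0.5 / p$S_CO
  structure(p, class = "kinetic_params")
}

#' Proton concentration (mol m-3) for a pH
#'
#' pH is defined on the mol/l scale; the result is expressed in mol m-3 as
#' used by the hydration rate laws.
#' @param pH compartment pH.
#' @return mol m-3.
#' @export
proton_concentration <- function(pH) 10^(-pH) * 1e3

#' Transport parameters for CO2, HCO3- and O2
#'
#' Diffusivities per phase, membrane permeabilities, wall/plasmodesmata
#' geometry and porosities, relative viscosity, and ambient conditions.
#'
#' @param ... named overrides of any default.
#' @return object of class `transport_params`.
#' @export
transport_params <- function(...) {
  p <- list(
    eta = 2,                        # relative viscosity of cell media
    D_co2_liquid = 1.89e-9,         # m2 s-1 (divided by eta in cell media)
    D_co2_gas = 1.57e-5,            # m2 s-1, IAS
    D_o2_liquid = 1.97e-9,
    D_o2_gas = 2.10e-5,
    D_hco3_liquid = 1.17e-9,
    P_co2_bs_membrane = 3.5e-3,     # m s-1, BS plasma membrane
    P_co2_chloroplast = 1.75e-3,    # m s-1, chloroplast envelope
    P_co2_m_membrane = 1.6e-2,      # m s-1, mesophyll plasma membrane
    P_o2_chloroplast = 1.25e-2,
    P_o2_membrane = 2.5e-2,         # plasma membranes (M and BS)
    t_wall_m = 0.188e-6,            # m
    t_wall_bs = 0.161e-6,
    t_plasmodesma = 0.354e-6,
    zeta_wall_m = 0.5,
    zeta_wall_bs = 0.1,
    zeta_plasmodesmata = 3e-2,      # fraction of M-BS interface
    ambient_co2 = 380,              # umol mol-1
    ambient_o2 = 210,               # mmol mol-1
    g_s = 0.2                       # mol m-2 s-1, stomatal conductance target
  )
  p <- utils::modifyList(p, list(...))
  if (p$eta < 1) stop("relative viscosity eta must be >= 1")
  if (any(unlist(p[grep("^D_", names(p))]) <= 0)) stop("diffusivities must be positive")
  z <- unlist(p[grep("^zeta", names(p))])
  if (any(z <= 0 | z > 1)) stop("porosities must lie in (0, 1]")
  structure(p, class = "transport_params")
}

#' Energetics parameters (electron transport and ATP production)
#'
#' Limiting-light efficiencies of the two photosystems, convexity, Q-cycle
#' fraction, protons per ATP, the ATP allocation fraction to the C4 cycle,
#' the fluorescence calibration factor, the per-class fractions of absorbed
#' light driving linear electron transport, and the light-saturated electron
#' transport capacities.
#'
#' @param ... named overrides of any default.
#' @return object of class `energetics_params`.
#' @export
energetics_params <- function(...) {
  p <- list(
    phi1_LL = 0.94,     # mol mol-1, PSI limiting-light efficiency
    phi2_LL = 0.83,     # mol mol-1, PSII limiting-light efficiency
    theta = 0.97,       # convexity of the non-rectangular hyperbola
    fQ = 1,             # fraction of electron flux through the Q cycle
    h = 4,              # H+ per ATP
    x = 0.40,           # fraction of ATP allocated to the C4 cycle
    s_prime = 0.325,    # lumped fluorescence calibration factor
    u_M = 0.89,         # fraction of absorbed light driving LET, mesophyll
    u_BS = 0.28,        # fraction of absorbed light driving LET, bundle sheath
    jmax_M = 138.43,    # umol m-2 s-1
    jmax_BS = 64.01     # umol m-2 s-1
  )
  p <- utils::modifyList(p, list(...))
  fr <- unlist(p[c("u_M", "u_BS", "x", "fQ")])
  if (any(fr < 0 | fr > 1)) stop("fractions must lie in [0, 1]")
  if (p$theta <= 0 || p$theta > 1) stop("theta must lie in (0, 1]")
  if (p$h <= 0) stop("h must be positive")
  structure(p, class = "energetics_params")
}
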