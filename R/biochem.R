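# Volumetric rate laws of the C4 biochemical model: Rubisco and PEPC
# carboxylation, enzymatic (CA) and spontaneous CO2 hydration, respiration,
# photorespiration, the decarboxylation source, and area <-> volume scaling.
#
# All rate functions return umol m-3 s-1 and are vectorized over
# concentration fields. Dissolved concentrations are mol m-3 (liquid phase);
# Rubisco Michaelis constants are applied on the gas-equivalent
# partial-pressure scale (ubar CO2 / mbar O2) via the Henry coefficients.

#' Gross volumetric Rubisco carboxylation rate
#'
#' Minimum of the enzyme-limited rate and the ATP-limited
#' (electron-transport) rate. The ATP branch caps carboxylation at one third
#' of the C3-cycle ATP supply (3 ATP per CO2 fixed), attenuated by
#' photorespiratory competition through `7 gamma* [O2]`.
#'
#' @param C dissolved CO2, mol m-3 (liquid); vectorized.
#' @param O dissolved O2, mol m-3 (liquid); vectorized.
#' @param V_cmax_star volumetric Rubisco capacity, umol m-3 s-1.
#' @param j_atp_c3_star volumetric C3-cycle ATP supply, umol m-3 s-1.
#' @param params a [kinetic_params()] object.
#' @return carboxylation rate, umol m-3 s-1.
#' @export
rubisco_rate <- function(C, O, V_cmax_star, j_atp_c3_star,
                         params = kinetic_params()) {
  if (any(C < 0) || any(O < 0)) stop("negative concentrations")
  k <- physical_constants()
  C_ubar <- liquid_to_ppm(C, k$henry_co2)          # ubar
  O_ubar <- liquid_to_ppm(O, k$henry_o2)           # ubar ( = mbar * 1000 )
  enz <- C_ubar * V_cmax_star /
    (C_ubar + params$K_mC * (1 + O_ubar / (params$K_mO * 1e3)))
  atp <- C_ubar * (j_atp_c3_star / 3) /
    (C_ubar + 7 * params$gamma_star * O_ubar)
  out <- pmin(enz, atp)
  out[C_ubar == 0] <- 0
  out
}

#' Volumetric PEP carboxylation rate
#'
#' Minimum of the bicarbonate-saturated enzyme rate and the C4-cycle
#' ATP-limited rate (2 ATP per PEP regenerated). Applies in mesophyll
#' cytosol only.
#'
#' @param HCO3 bicarbonate, mol m-3; vectorized.
#' @param V_pmax_star volumetric PEPC capacity, umol m-3 s-1.
#' @param j_atp_c4_star volumetric C4-cycle ATP supply, umol m-3 s-1.
#' @param K_h PEPC bicarbonate Michaelis constant, mol m-3.
#' @return PEP carboxylation rate, umol m-3 s-1.
#' @export
pepc_rate <- function(HCO3, V_pmax_star, j_atp_c4_star, K_h = 2e-2) {
  if (any(HCO3 < 0)) stop("negative concentrations")
  pmin(HCO3 * V_pmax_star / (HCO3 + K_h), j_atp_c4_star / 2)
}

#' Net enzymatic CO2 hydration rate (carbonic anhydrase)
#'
#' `B_CA = V_CAmax ([CO2] - [HCO3][H+]/K_eq) /
#'   (K_CO2 + (K_CO2/K_HCO3) [HCO3] + [CO2])`. Positive values hydrate CO2 to
#' bicarbonate. Mesophyll cytosol only (bundle sheath cells of maize carry
#' little carbonic anhydrase).
#'
#' @param C dissolved CO2, mol m-3; vectorized.
#' @param HCO3 bicarbonate, mol m-3; vectorized.
#' @param H proton concentration, mol m-3 (see [proton_concentration()]).
#' @param params a [kinetic_params()] object.
#' @return net hydration rate, umol m-3 s-1.
#' @export
ca_hydration <- function(C, HCO3, H, params = kinetic_params()) {
  params$V_CAmax * (C - HCO3 * H / params$K_eq) /
    (params$K_CO2 + params$K_CO2 / params$K_HCO3 * HCO3 + C)
}

#' Net spontaneous (non-enzymatic) CO2 hydration rate
#'
#' `B_NCA = k1 [CO2] - k2 [HCO3][H+]/K_a`, valid everywhere in the liquid
#' phase. `[H+]` and `K_a` enter as a ratio, evaluated on the mol m-3 scale.
#'
#' @inheritParams ca_hydration
#' @return net hydration rate, umol m-3 s-1.
#' @export
spontaneous_hydration <- function(C, HCO3, H, params = kinetic_params()) {
  Ka <- params$K_a * 1e3   # mol l-1 -> mol m-3
  (params$k1 * C - params$k2 * HCO3 * H / Ka) * 1e6
}

#' Uniform volumetric respiration rate and per-class bookkeeping
#'
#' Respiratory CO2 release occurs in the epidermis, the cytosol of mesophyll
#' and bundle-sheath cells, and the vascular bundle, at a single volumetric
#' rate `R* = R_d / (d f_resp)` chosen so that the volume integral over all
#' respiring tissue equals the leaf-level day respiration `R_d` exactly.
#'
#' @param R_d day respiration, umol m-2 s-1.
#' @param anatomy an [anatomical_stats()] result (uses `f_resp`, class
#'   volume fractions, and `d`).
#' @param d leaf tissue thickness (m); defaults to `anatomy$d`.
#' @return list with `R_star` (umol m-3 s-1, uniform over respiring
#'   classes), `R_M` (mesophyll-cytosol respiration per leaf area,
#'   umol m-2 s-1), and `per_class` area-based rates.
#' @export
respiration_rates <- function(R_d, anatomy, d = anatomy$d) {
  f_resp <- anatomy$f_resp
  if (R_d == 0 || f_resp == 0) {
    return(list(R_star = 0, R_M = 0, per_class = c(
      EPIDERMIS = 0, M_CYTOSOL = 0, BS_CYTOSOL = 0, VASCULAR = 0
    )))
  }
  R_star <- R_d / (d * f_resp)
  fr <- anatomy$volume_fraction
  per_class <- R_d / f_resp * c(
    EPIDERMIS = unname(fr["EPIDERMIS"]),
    M_CYTOSOL = unname(fr["M_CYTOSOL"]),
    BS_CYTOSOL = unname(fr["BS_CYTOSOL"]),
    VASCULAR = unname(fr["VASCULAR"])
  )
  list(R_star = R_star, R_M = unname(per_class["M_CYTOSOL"]),
       per_class = per_class)
}

#' Photorespiratory CO2 release and O2 consumption rates
#'
#' Oxygenation runs at `2 gamma* [O2]/[CO2]` relative to carboxylation.
#' Each oxygenation releases 0.5 CO2 (in the bundle-sheath cytosol, where
#' glycine decarboxylation is located) and consumes 1.5 O2 (1 by Rubisco
#' plus 0.5 by glycolate oxidase), deposited in the bundle-sheath
#' chloroplast. Both returned rates are uniform over their compartments.
#'
#' @param Vc Rubisco carboxylation rates on bundle-sheath chloroplast voxels,
#'   umol m-3 s-1.
#' @param O,C dissolved O2 and CO2 on the same voxels, mol m-3.
#' @param gamma_star Rubisco compensation factor `0.5 / S_CO`.
#' @param voxel_volume voxel volume, m3.
#' @param V_bs_cytosol,V_bs_chloroplast compartment volumes, m3.
#' @return list with `r_co2` (uniform in BS cytosol) and `r_o2` (uniform in
#'   BS chloroplast), umol m-3 s-1.
#' @export
photorespiration_rates <- function(Vc, O, C, gamma_star, voxel_volume,
                                   V_bs_cytosol, V_bs_chloroplast) {
  # gamma* is defined on the gas-equivalent (partial-pressure) scale, so
  # the O/C ratio is taken between gas-equivalent mixing ratios
  k <- physical_constants()
  O_gas <- O / k$henry_o2
  C_gas <- C / k$henry_co2
  ox <- Vc * gamma_star * ifelse(C_gas > 0, O_gas / C_gas, 0)
  total <- sum(ox) * voxel_volume           # umol s-1 (per unit leaf area off)
  list(
    r_co2 = total / V_bs_cytosol,
    r_o2 = 3 * total / V_bs_chloroplast
  )
}

#' Decarboxylation source of CO2 in bundle-sheath chloroplasts
#'
#' C4-acid decarboxylation proceeds at the whole-leaf rate of PEP
#' carboxylation, released uniformly over the bundle-sheath chloroplast
#' volume: `Vbar_p* = integral(Vp*) / V_BS,chloroplast`.
#'
#' @param Vp PEP carboxylation rates on mesophyll-cytosol voxels,
#'   umol m-3 s-1.
#' @param voxel_volume voxel volume, m3.
#' @param V_bs_chloroplast bundle-sheath chloroplast volume, m3.
#' @return uniform volumetric release rate, umol m-3 s-1.
#' @export
decarboxylation_source <- function(Vp, voxel_volume, V_bs_chloroplast) {
  sum(Vp) * voxel_volume / V_bs_chloroplast
}

#' Convert a leaf-area rate to a volumetric rate
#'
#' `Q* = Q / (d f_i)` where `f_i` is the tissue volume fraction of the
#' compartment in which the rate applies.
#'
#' @param Q rate per leaf area, umol m-2 s-1.
#' @param d leaf tissue thickness, m.
#' @param f_i compartment volume fraction of the tissue.
#' @return volumetric rate, umol m-3 s-1.
#' @export
volumetric_scaling <- function(Q, d, f_i) {
  stopifnot(d > 0, all(f_i > 0))
  Q / (d * f_i)
}

#' Oxygen evolution from linear electron transport
#'
#' One O2 per four electrons: `E*_O2 = j*/4`.
#' @param j_star volumetric LET rate, umol m-3 s-1; vectorized.
#' @return O2 evolution rate, umol m-3 s-1.
#' @export
oxygen_evolution <- function(j_star) j_star / 4
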