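# Electron-transport partitioning (linear vs cyclic), potential LET rates,
# ATP/NADPH production, fluorescence calibration and jmax fitting.
#
# Cell classes are indexed i in {M, BS} (mesophyll / bundle sheath
# chloroplasts). Quantities per unit leaf area are umol m-2 s-1; volumetric
# quantities (suffix *) are umol m-3 s-1.

#' Fraction of cyclic electron transport from the LET light fraction
#'
#' Under limiting light the rates of linear and cyclic electron transport are
#' both proportional to the absorbed irradiance, which therefore cancels:
#' `fCET = phi1 (1 - u) / (phi1 (1 - u) + u phi2 / (1 + phi2/phi1))`, where
#' `u` is the fraction of absorbed light driving linear electron transport.
#'
#' @param u fraction of absorbed light allocated to LET, in `[0, 1]`;
#'   vectorized.
#' @param params an [energetics_params()] object.
#' @return fraction of cyclic electron transport in `[0, 1]`.
#' @export
cet_fraction <- function(u, params = energetics_params()) {
  stopifnot(all(u >= 0 & u <= 1))
  p1 <- params$phi1_LL
  p2 <- params$phi2_LL
  cet <- p1 * (1 - u)
  let <- p2 / (1 + p2 / p1) * u
  out <- cet / (cet + let)
  out[u == 1] <- 0
  out[u == 0] <- 1
  out
}

#' Photochemical efficiency of linear electron transport under limiting light
#'
#' `alpha2_LL = phi2 (1 - fCET) / (phi2/phi1 + (1 - fCET))`, on the basis of
#' light absorbed by both photosystems when cyclic transport runs in
#' parallel.
#'
#' @param fCET fraction of cyclic electron transport; vectorized.
#' @param params an [energetics_params()] object.
#' @return efficiency in mol electrons per mol absorbed photons.
#' @export
alpha2_ll <- function(fCET, params = energetics_params()) {
  stopifnot(all(fCET >= 0 & fCET <= 1))
  p1 <- params$phi1_LL
  p2 <- params$phi2_LL
  p2 * (1 - fCET) / (p2 / p1 + (1 - fCET))
}

#' Potential rate of linear electron transport (non-rectangular hyperbola)
#'
#' Smaller root of `theta j^2 - (alpha I + jmax) j + alpha I jmax = 0`.
#' Works identically for volumetric (umol m-3 s-1) and area-based
#' (umol m-2 s-1) arguments as long as `I_abs` and `jmax` share units.
#' `theta = 0` falls back to the Blackman limit `min(alpha I, jmax)`.
#'
#' @param I_abs absorbed irradiance (photon basis); vectorized.
#' @param alpha2 limiting-light efficiency from [alpha2_ll()].
#' @param jmax light-saturated electron transport rate, `> 0`.
#' @param theta convexity in `[0, 1]`.
#' @return LET rate, bounded by `min(alpha2 * I_abs, jmax)`.
#' @export
potential_let_rate <- function(I_abs, alpha2, jmax, theta = 0.97) {
  stopifnot(all(jmax > 0), theta >= 0, theta <= 1)
  aI <- alpha2 * I_abs
  if (theta == 0) {
    return(pmin(aI, jmax))
  }
  b <- aI + jmax
  disc <- pmax(b^2 - 4 * theta * aI * jmax, 0)
  (b - sqrt(disc)) / (2 * theta)
}

#' ATP production multiplier for a given CET fraction
#'
#' `(2 + fQ - fCET) / (h (1 - fCET))`: mol ATP per mol LET electrons when a
#' fraction `fCET` of photosystem-I turnover is cyclic.
#'
#' @param fCET fraction of cyclic electron transport, `< 1`.
#' @param params an [energetics_params()] object.
#' @return dimensionless multiplier.
#' @export
atp_multiplier <- function(fCET, params = energetics_params()) {
  if (any(fCET >= 1)) stop("fCET = 1: ATP production is singular (no LET)")
  (2 + params$fQ - fCET) / (params$h * (1 - fCET))
}

# Integrate a volumetric field (umol m-3 s-1) to a leaf-area rate
# (umol m-2 s-1). `values` are the field samples on voxels of volume
# `voxel_volume` (m3); `S_leaf` is the projected leaf area (m2).
integrate_per_area <- function(values, voxel_volume, S_leaf) {
  sum(values) * voxel_volume / S_leaf
}

#' ATP production per leaf area for one cell class
#'
#' @param j_star volumetric LET rates (umol m-3 s-1) on the class's
#'   chloroplast voxels, or a single area-based rate if `voxel_volume` is
#'   `NULL`.
#' @param fCET fraction of cyclic electron transport for the class.
#' @param params an [energetics_params()] object.
#' @param S_leaf projected leaf area (m2); required with `voxel_volume`.
#' @param voxel_volume voxel volume (m3) if `j_star` is a field.
#' @param class_name used in the error message when `fCET = 1`.
#' @return ATP production in umol m-2 s-1.
#' @export
atp_production <- function(j_star, fCET, params = energetics_params(),
                           S_leaf = NULL, voxel_volume = NULL,
                           class_name = "chloroplast") {
  if (fCET >= 1) {
    stop(sprintf("fCET = 1 in %s: ATP production is singular", class_name))
  }
  j_area <- if (is.null(voxel_volume)) {
    sum(j_star)
  } else {
    integrate_per_area(j_star, voxel_volume, S_leaf)
  }
  atp_multiplier(fCET, params) * j_area
}

#' NADPH production per leaf area for one cell class
#'
#' 0.5 mol NADPH per mol electrons through linear transport.
#' @inheritParams atp_production
#' @return NADPH production in umol m-2 s-1.
#' @export
nadph_production <- function(j_star, S_leaf = NULL, voxel_volume = NULL) {
  j_area <- if (is.null(voxel_volume)) {
    sum(j_star)
  } else {
    integrate_per_area(j_star, voxel_volume, S_leaf)
  }
  0.5 * j_area
}

#' Bundle-sheath fractions of ATP and NADPH production
#'
#' @param jATP_M,jATP_BS ATP production per class (umol m-2 s-1).
#' @param jNADPH_M,jNADPH_BS NADPH production per class.
#' @return list with `fATP_BS` and `fNADPH_BS`.
#' @export
bundle_fractions <- function(jATP_M, jATP_BS, jNADPH_M = NULL, jNADPH_BS = NULL) {
  out <- list(fATP_BS = jATP_BS / (jATP_M + jATP_BS))
  if (!is.null(jNADPH_M)) {
    out$fNADPH_BS <- jNADPH_BS / (jNADPH_M + jNADPH_BS)
  }
  out
}

#' Chlorophyll-fluorescence record
#'
#' @param I_inc incident irradiance (umol m-2 s-1).
#' @param Fs steady-state relative fluorescence yield.
#' @param Fm_prime light-adapted maximum relative fluorescence yield.
#' @return object of class `fluorescence_record`.
#' @export
fluorescence_record <- function(I_inc, Fs, Fm_prime) {
  stopifnot(I_inc >= 0, Fs >= 0, Fm_prime >= Fs)
  structure(list(I_inc = I_inc, Fs = Fs, Fm_prime = Fm_prime),
            class = "fluorescence_record")
}

#' Whole-leaf ATP production inferred from chlorophyll fluorescence
#'
#' `jATP_CF = s' I_inc (Fm' - Fs)/Fm' / (1 - x)`, with the lumped calibration
#' factor `s'` and the C4 ATP allocation fraction `x`.
#'
#' @param rec a [fluorescence_record()].
#' @param params an [energetics_params()] object.
#' @return ATP production in umol m-2 s-1.
#' @export
atp_from_fluorescence <- function(rec, params = energetics_params()) {
  if (rec$Fm_prime == 0) stop("Fm_prime = 0: fluorescence yield undefined")
  dF <- (rec$Fm_prime - rec$Fs) / rec$Fm_prime
  params$s_prime * rec$I_inc * dF / (1 - params$x)
}

#' Leaf-level ATP light response from class absorbances
#'
#' Area-based two-class model used for jmax fitting and light-response
#' summaries: per class, the absorbed irradiance is `absorbance_i * I_inc`,
#' LET follows the non-rectangular hyperbola, and ATP production applies the
#' class's CET multiplier.
#'
#' @param I_inc incident irradiance(s), umol m-2 s-1; vectorized.
#' @param absorbance_M,absorbance_BS fraction of incident photons absorbed by
#'   each chloroplast class.
#' @param params an [energetics_params()] object (uses `u_M`, `u_BS`,
#'   `jmax_M`, `jmax_BS`, `theta`).
#' @param jmax_M,jmax_BS optional overrides of the capacities in `params`.
#' @return data.frame with `I_inc`, `j_M`, `j_BS`, `jATP_M`, `jATP_BS`,
#'   `jATP`, `jNADPH_M`, `jNADPH_BS`.
#' @export
atp_light_response <- function(I_inc, absorbance_M, absorbance_BS,
                               params = energetics_params(),
                               jmax_M = params$jmax_M,
                               jmax_BS = params$jmax_BS) {
  fC_M <- cet_fraction(params$u_M, params)
  fC_BS <- cet_fraction(params$u_BS, params)
  a2_M <- alpha2_ll(fC_M, params)
  a2_BS <- alpha2_ll(fC_BS, params)
  j_M <- potential_let_rate(absorbance_M * I_inc, a2_M, jmax_M, params$theta)
  j_BS <- potential_let_rate(absorbance_BS * I_inc, a2_BS, jmax_BS, params$theta)
  jATP_M <- atp_multiplier(fC_M, params) * j_M
  jATP_BS <- atp_multiplier(fC_BS, params) * j_BS
  data.frame(
    I_inc = I_inc, j_M = j_M, j_BS = j_BS,
    jATP_M = jATP_M, jATP_BS = jATP_BS, jATP = jATP_M + jATP_BS,
    jNADPH_M = 0.5 * j_M, jNADPH_BS = 0.5 * j_BS
  )
}

#' Fit light-saturated electron transport capacities from fluorescence data
#'
#' Minimizes the squared difference between modelled whole-leaf ATP
#' production ([atp_light_response()]) and the fluorescence-derived rates
#' ([atp_from_fluorescence()]) over `jmax_M`, with `jmax_BS` tied to `jmax_M`
#' through the constraint that capacities scale as the product of the
#' limiting-light LET efficiency and the absorbed irradiance per class:
#' `jmax_BS / jmax_M = alpha2_BS * absorbance_BS / (alpha2_M * absorbance_M)`.
#'
#' @param records list of [fluorescence_record()] objects (at least 4,
#'   spanning more than one irradiance).
#' @param absorbance_M,absorbance_BS chloroplast-class absorbances.
#' @param params an [energetics_params()] object.
#' @param interval search interval for `jmax_M` (umol m-2 s-1).
#' @return list with `jmax_M`, `jmax_BS`, `ratio`, `sse`.
#' @export
fit_jmax <- function(records, absorbance_M, absorbance_BS,
                     params = energetics_params(), interval = c(1, 2000)) {
  if (length(records) < 4) stop("need at least 4 fluorescence records")
  I <- vapply(records, function(r) r$I_inc, 0)
  if (length(unique(I)) < 2) {
    stop("ill-posed fit: all records share one irradiance")
  }
  jCF <- vapply(records, atp_from_fluorescence, 0, params = params)
  a2_M <- alpha2_ll(cet_fraction(params$u_M, params), params)
  a2_BS <- alpha2_ll(cet_fraction(params$u_BS, params), params)
  ratio <- (a2_BS * absorbance_BS) / (a2_M * absorbance_M)
  sse <- function(jm) {
    mod <- atp_light_response(I, absorbance_M, absorbance_BS, params,
                              jmax_M = jm, jmax_BS = ratio * jm)
    sum((mod$jATP - jCF)^2)
  }
  opt <- stats::optimize(sse, interval = interval, tol = 1e-8)
  if (opt$minimum > 0.999 * interval[2]) {
    stop("jmax fit did not converge inside the search interval")
  }
  list(jmax_M = opt$minimum, jmax_BS = ratio * opt$minimum,
       ratio = ratio, sse = opt$objective)
}

#' Allocate total ATP production between the C3 and C4 cycles
#'
#' A fraction `x` of total ATP drives the C4 cycle (PEP regeneration in
#' mesophyll cytosol); the remainder drives the C3 cycle in bundle-sheath
#' chloroplasts. Volumetric densities spread each allocation uniformly over
#' the receiving compartment volume per leaf area (`d * f_i`).
#'
#' @param jATP total ATP production, umol m-2 s-1.
#' @param params an [energetics_params()] object (uses `x`).
#' @param d leaf tissue thickness (m).
#' @param f_bs_chloroplast,f_m_cytosol tissue volume fractions of the
#'   receiving compartments.
#' @return list with `jATP_C3`, `jATP_C4` (umol m-2 s-1) and
#'   `j_star_ATP_C3`, `j_star_ATP_C4` (umol m-3 s-1).
#' @export
allocate_atp <- function(jATP, params = energetics_params(), d = NULL,
                         f_bs_chloroplast = NULL, f_m_cytosol = NULL) {
  x <- params$x
  out <- list(jATP_C3 = (1 - x) * jATP, jATP_C4 = x * jATP)
  if (!is.null(d)) {
    out$j_star_ATP_C3 <- volumetric_scaling(out$jATP_C3, d, f_bs_chloroplast)
    out$j_star_ATP_C4 <- volumetric_scaling(out$jATP_C4, d, f_m_cytosol)
  }
  out
}

#' Full per-voxel energetics state from a light solution
#'
#' Converts the absorbed-photon field into volumetric absorbed irradiance on
#' the chloroplast voxels, evaluates the non-rectangular hyperbola voxelwise
#' against the volumetric electron-transport capacity of each cell class,
#' and integrates to leaf-area ATP and NADPH production, bundle-sheath
#' fractions, and the C3/C4 ATP allocation densities used by the transport
#' solver.
#'
#' @param vol a [label_volume()].
#' @param field an `absorption_field` (normally the spectrally combined
#'   one from [run_light_model()]).
#' @param light an [incident_light()].
#' @param params an [energetics_params()] object.
#' @param stats optional precomputed [anatomical_stats()].
#' @return object of class `energetics_state`: per-class `fCET`, `alpha2`,
#'   `j` (area-based LET), `jATP`, `jNADPH`; totals and bundle-sheath
#'   fractions; `j_let_density` (3D array, umol m-3 s-1); scalar allocation
#'   densities `j_star_ATP_C3`, `j_star_ATP_C4`.
#' @export
energetics_state <- function(vol, field, light, params = energetics_params(),
                             stats = NULL) {
  if (is.null(stats)) stats <- anatomical_stats(vol)
  irr <- absorbed_irradiance_density(field, light, vol)
  d_leaf <- stats$d
  h <- vol$voxel_pitch_um * 1e-6
  L <- kranz_labels()
  i_mch <- vol$labels == L["M_CHLOROPLAST"]
  i_bsch <- vol$labels == L["BS_CHLOROPLAST"]
  f_mch <- stats$chloroplast_volume_m / d_leaf
  f_bsch <- stats$chloroplast_volume_bs / d_leaf

  fC_M <- cet_fraction(params$u_M, params)
  fC_BS <- cet_fraction(params$u_BS, params)
  a2_M <- alpha2_ll(fC_M, params)
  a2_BS <- alpha2_ll(fC_BS, params)
  jmax_M_star <- volumetric_scaling(params$jmax_M, d_leaf, f_mch)
  jmax_BS_star <- volumetric_scaling(params$jmax_BS, d_leaf, f_bsch)

  j_density <- array(0, dim = dim(vol$labels))
  j_density[i_mch] <- potential_let_rate(irr$density[i_mch], a2_M,
                                         jmax_M_star, params$theta)
  j_density[i_bsch] <- potential_let_rate(irr$density[i_bsch], a2_BS,
                                          jmax_BS_star, params$theta)
  voxel_volume <- h^3
  j_M <- integrate_per_area(j_density[i_mch], voxel_volume, stats$S_leaf)
  j_BS <- integrate_per_area(j_density[i_bsch], voxel_volume, stats$S_leaf)
  jATP_M <- atp_multiplier(fC_M, params) * j_M
  jATP_BS <- atp_multiplier(fC_BS, params) * j_BS
  jATP <- jATP_M + jATP_BS
  jNADPH_M <- 0.5 * j_M
  jNADPH_BS <- 0.5 * j_BS
  fr <- bundle_fractions(jATP_M, jATP_BS, jNADPH_M, jNADPH_BS)
  alloc <- allocate_atp(jATP, params, d = d_leaf,
                        f_bs_chloroplast = f_bsch,
                        f_m_cytosol = stats$volume_fraction["M_CYTOSOL"])
  structure(list(
    fCET_M = fC_M, fCET_BS = fC_BS, alpha2_M = a2_M, alpha2_BS = a2_BS,
    j_M = j_M, j_BS = j_BS, jATP_M = jATP_M, jATP_BS = jATP_BS, jATP = jATP,
    jNADPH_M = jNADPH_M, jNADPH_BS = jNADPH_BS,
    jNADPH = jNADPH_M + jNADPH_BS,
    fATP_BS = fr$fATP_BS, fNADPH_BS = fr$fNADPH_BS,
    I_abs_M = irr$I_abs_M, I_abs_BS = irr$I_abs_BS,
    absorbance_M = irr$absorbance_M, absorbance_BS = irr$absorbance_BS,
    absorbance_total = irr$absorbance_total,
    j_let_density = j_density,
    jATP_C3 = alloc$jATP_C3, jATP_C4 = alloc$jATP_C4,
    j_star_ATP_C3 = unname(alloc$j_star_ATP_C3),
    j_star_ATP_C4 = unname(alloc$j_star_ATP_C4),
    I_inc = light$I_inc
  ), class = "energetics_state")
}

#' Choose LET light fractions that balance an ATP:NADPH demand ratio
#'
#' Optional balancing solver (off by default in the pipeline): picks `u` for
#' one cell class so that the produced ATP:NADPH ratio at limiting light
#' matches a stated demand stoichiometry. The demand ratios are an assumption
#' of this solver, not part of the core model.
#'
#' @param target_ratio desired ATP:NADPH production ratio.
#' @param params an [energetics_params()] object.
#' @return the balancing `u` in (0, 1).
#' @export
balance_let_fraction <- function(target_ratio, params = energetics_params()) {
  f <- function(u) {
    fc <- cet_fraction(u, params)
    atp_multiplier(fc, params) / 0.5 - target_ratio
  }
  stats::uniroot(f, c(1e-6, 1 - 1e-6), tol = 1e-10)$root
}
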