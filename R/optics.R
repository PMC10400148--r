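# Per-tissue optical properties and Monte Carlo light propagation on the
# voxel grid. The spectral basis is two wavelengths, 470 nm (blue) and
# 665 nm (red), combined with fixed weights (default 10% blue / 90% red).

.wavelengths <- c(470, 665)

#' Default per-tissue optical properties
#'
#' Absorption coefficient `mua` (m-1), scattering coefficient `mus` (m-1),
#' Henyey-Greenstein anisotropy `g`, and refractive index `n` for every
#' label class at 470 and 665 nm. Gas-phase classes (air, stomatal pores,
#' airspace) are transparent with n = 1; all hydrated tissue shares a single
#' refractive index (default 1.36) so internal Fresnel events occur only at
#' gas-liquid faces. Epidermis, vacuole, and cytosol absorb weakly
#' (100 m-1); chloroplast absorption is set from leaf chlorophyll content
#' with [chlorophyll_absorption()]. Cell walls are not explicit: their
#' scattering is lumped into the chloroplast scattering coefficient, a
#' calibration knob (default 2e5 m-1 with g = 0.90).
#'
#' @param mua_tissue background absorption of epidermis/vacuole/cytosol, m-1.
#' @param mus_cell scattering of non-chloroplast cell media, m-1.
#' @param mus_chloroplast chloroplast (plus lumped wall) scattering, m-1.
#' @param g_cell,g_chloroplast anisotropy factors.
#' @param n_tissue refractive index of hydrated tissue.
#' @return object of class `optical_properties`: per wavelength, a data.frame
#'   with one row per label.
#' @export
optical_properties <- function(mua_tissue = 100, mus_cell = 1e3,
                               mus_chloroplast = 2e5, g_cell = 0.90,
                               g_chloroplast = 0.90, n_tissue = 1.36) {
  L <- kranz_labels()
  base <- data.frame(
    label = unname(L), class = names(L),
    mua = mua_tissue, mus = mus_cell, g = g_cell, n = n_tissue
  )
  gas <- base$class %in% c("AIR", "STOMATAL_PORE", "IAS")
  base$mua[gas] <- 0; base$mus[gas] <- 0; base$g[gas] <- 0; base$n[gas] <- 1
  vac <- base$class %in% c("M_VACUOLE", "BS_VACUOLE")
  base$mus[vac] <- 100
  chl <- base$class %in% c("M_CHLOROPLAST", "BS_CHLOROPLAST")
  base$mus[chl] <- mus_chloroplast
  base$g[chl] <- g_chloroplast
  props <- stats::setNames(lapply(.wavelengths, function(w) base),
                           as.character(.wavelengths))
  structure(props, class = "optical_properties")
}

#' Set chloroplast absorption coefficients from leaf chlorophyll content
#'
#' Distributes the leaf chlorophyll between mesophyll and bundle-sheath
#' chloroplasts (fraction `f_chl_bs` to the bundle sheath) and converts each
#' class's areal chlorophyll to a homogeneous volumetric absorption
#' coefficient: `mua = chl_class * specific_abs(lambda) / (chloroplast
#' volume per leaf area)`.
#'
#' @param props an [optical_properties()] object.
#' @param vol a [label_volume()] (supplies chloroplast volumes per leaf
#'   area).
#' @param chl_leaf leaf chlorophyll content, umol m-2 (default 539).
#' @param f_chl_bs fraction of chlorophyll in the bundle sheath (default
#'   0.5).
#' @param specific_abs named vector of in-vivo chlorophyll specific
#'   absorption coefficients (m2 umol-1) per wavelength.
#' @return updated `optical_properties`.
#' @export
chlorophyll_absorption <- function(props, vol, chl_leaf = 539,
                                   f_chl_bs = 0.5,
                                   specific_abs = c("470" = 0.00653,
                                                    "665" = 0.00466)) {
  stopifnot(chl_leaf > 0, f_chl_bs >= 0, f_chl_bs <= 1)
  stats_ <- anatomical_stats(vol)
  v_m <- stats_$chloroplast_volume_m     # m3 m-2
  v_bs <- stats_$chloroplast_volume_bs
  chl_m <- (1 - f_chl_bs) * chl_leaf
  chl_bs <- f_chl_bs * chl_leaf
  if ((chl_m > 0 && v_m == 0) || (chl_bs > 0 && v_bs == 0)) {
    stop("nonzero chlorophyll assigned to a class with zero chloroplast volume")
  }
  for (w in names(props)) {
    sa <- specific_abs[[w]]
    if (is.null(sa)) stop("no specific absorption for wavelength ", w)
    i_m <- props[[w]]$class == "M_CHLOROPLAST"
    i_bs <- props[[w]]$class == "BS_CHLOROPLAST"
    props[[w]]$mua[i_m] <- if (v_m > 0) chl_m * sa / v_m else 0
    props[[w]]$mua[i_bs] <- if (v_bs > 0) chl_bs * sa / v_bs else 0
  }
  attr(props, "chlorophyll") <- c(M = chl_m, BS = chl_bs)
  props
}

#' Incident light description
#'
#' @param I_inc incident photon flux, umol m-2 s-1.
#' @param spectral_weights named fractions per wavelength (must sum to 1).
#' @return object of class `incident_light`.
#' @export
incident_light <- function(I_inc,
                           spectral_weights = c("470" = 0.10, "665" = 0.90)) {
  if (abs(sum(spectral_weights) - 1) > 1e-9) {
    stop("spectral weights must sum to 1")
  }
  structure(list(I_inc = I_inc, spectral_weights = spectral_weights),
            class = "incident_light")
}

#' Monte Carlo photon transport through a label volume
#'
#' Photons are launched uniformly over the adaxial face at normal incidence;
#' free paths are sampled from the local extinction coefficient, absorption
#' is deposited by the albedo-weight method, scattering follows
#' Henyey-Greenstein, refractive-index steps apply Fresnel
#' reflection/refraction, lateral boundaries are periodic, and photons below
#' weight 1e-4 undergo Russian roulette.
#'
#' @param vol a [label_volume()].
#' @param props an [optical_properties()] object.
#' @param lambda wavelength, one of 470 or 665.
#' @param n_photons number of photon packets (>= 1e4).
#' @param seed integer random seed.
#' @return object of class `absorption_field`: `frac_absorbed` (3D array,
#'   fraction of incident photons absorbed per voxel), `budget` (named:
#'   R, T, A, lateral_loss), `n_photons`, `rng_seed`, `lambda`,
#'   `voxel_pitch_um`.
#' @export
run_photon_transport <- function(vol, props, lambda = 665,
                                 n_photons = 1e5, seed = 1) {
  stopifnot(inherits(vol, "label_volume"))
  if (n_photons < 1e4) stop("n_photons must be at least 1e4")
  tab <- props[[as.character(lambda)]]
  if (is.null(tab)) stop("no optical properties for wavelength ", lambda)
  present <- unique(as.integer(vol$labels))
  vals <- unlist(tab[match(present, tab$label), c("mua", "mus", "g", "n")])
  if (any(!is.finite(vals))) {
    stop("non-finite optical properties for a label present in the volume")
  }
  d <- dim(vol$labels)
  mua <- mus <- g <- nref <- numeric(11)
  mua[tab$label + 1] <- tab$mua
  mus[tab$label + 1] <- tab$mus
  g[tab$label + 1] <- tab$g
  nref[tab$label + 1] <- tab$n
  res <- photon_mc_cpp(as.integer(vol$labels), d, mua, mus, g, nref,
                       vol$voxel_pitch_um * 1e-6, as.integer(n_photons),
                       as.double(seed))
  structure(list(
    frac_absorbed = array(res$frac_absorbed, dim = d),
    budget = c(R = res$R, T = res$T, A = res$A, lateral_loss = res$lost),
    n_photons = n_photons, rng_seed = seed, lambda = lambda,
    voxel_pitch_um = vol$voxel_pitch_um
  ), class = "absorption_field")
}

#' Combine per-wavelength absorption fields
#'
#' Voxelwise convex combination of absorbed fractions and budgets.
#'
#' @param fields named list of [run_photon_transport()] results, keyed by
#'   wavelength.
#' @param weights named weights summing to 1.
#' @return combined `absorption_field` (lambda = "combined").
#' @export
combine_wavelengths <- function(fields, weights = c("470" = 0.10,
                                                    "665" = 0.90)) {
  weights <- weights[names(weights) %in% names(fields)]
  if (abs(sum(weights) - 1) > 1e-9) stop("weights must sum to 1")
  dims <- lapply(fields, function(f) dim(f$frac_absorbed))
  if (length(unique(lapply(dims, paste, collapse = "x"))) != 1) {
    stop("absorption fields are on mismatched grids")
  }
  acc <- array(0, dim = dims[[1]])
  budget <- c(R = 0, T = 0, A = 0, lateral_loss = 0)
  for (w in names(weights)) {
    acc <- acc + weights[[w]] * fields[[w]]$frac_absorbed
    budget <- budget + weights[[w]] * fields[[w]]$budget
  }
  structure(list(
    frac_absorbed = acc, budget = budget,
    n_photons = fields[[1]]$n_photons, rng_seed = fields[[1]]$rng_seed,
    lambda = "combined", voxel_pitch_um = fields[[1]]$voxel_pitch_um
  ), class = "absorption_field")
}

#' Absorbed-photon fraction per depth layer
#'
#' @param field an `absorption_field`.
#' @param vol optional [label_volume()] to restrict the profile to one
#'   label class.
#' @param class_name optional class name (e.g. "BS_CHLOROPLAST").
#' @return data.frame with `z` (layer index) and `absorbed` (fraction of
#'   incident photons absorbed in the layer).
#' @export
depth_absorption_profile <- function(field, vol = NULL, class_name = NULL) {
  fa <- field$frac_absorbed
  if (!is.null(class_name)) {
    if (is.null(vol)) stop("a label volume is needed to restrict by class")
    fa <- fa * (vol$labels == .L(class_name))
  }
  data.frame(z = seq_len(dim(fa)[3]), absorbed = apply(fa, 3, sum))
}

#' Absorbed irradiance density and per-class absorbed irradiance
#'
#' Converts the absorbed-photon fractions into a volumetric photon
#' absorption rate `I*_abs = I_inc * frac_absorbed * S_leaf / voxel volume`
#' (umol m-3 s-1) and integrates it per chloroplast class back to leaf-area
#' rates (umol m-2 s-1).
#'
#' @param field an `absorption_field`.
#' @param light an [incident_light()].
#' @param vol the [label_volume()] the field was computed on.
#' @return list with `density` (3D array, umol m-3 s-1), `I_abs_M`,
#'   `I_abs_BS` (umol m-2 s-1), `absorbance_M`, `absorbance_BS`
#'   (chloroplast-class absorbances), `absorbance_total`.
#' @export
absorbed_irradiance_density <- function(field, light, vol) {
  h <- vol$voxel_pitch_um * 1e-6
  d <- dim(vol$labels)
  S_leaf <- d[1] * d[2] * h^2
  voxel_volume <- h^3
  density <- light$I_inc * field$frac_absorbed * S_leaf / voxel_volume
  abs_m <- sum(field$frac_absorbed[vol$labels == .L("M_CHLOROPLAST")])
  abs_bs <- sum(field$frac_absorbed[vol$labels == .L("BS_CHLOROPLAST")])
  list(
    density = density,
    I_abs_M = light$I_inc * abs_m,
    I_abs_BS = light$I_inc * abs_bs,
    absorbance_M = abs_m,
    absorbance_BS = abs_bs,
    absorbance_total = unname(field$budget["A"])
  )
}

#' One-call light solution: both wavelengths plus spectral combination
#'
#' @param vol a [label_volume()].
#' @param props an [optical_properties()] object (run
#'   [chlorophyll_absorption()] first).
#' @param n_photons photon packets per wavelength.
#' @param seed integer seed (the 470 nm run uses `seed + 1`).
#' @param weights spectral weights.
#' @return combined `absorption_field`.
#' @export
run_light_model <- function(vol, props, n_photons = 1e5, seed = 1,
                            weights = c("470" = 0.10, "665" = 0.90)) {
  fields <- list(
    "470" = run_photon_transport(vol, props, 470, n_photons, seed + 1),
    "665" = run_photon_transport(vol, props, 665, n_photons, seed)
  )
  combine_wavelengths(fields, weights)
}
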