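# End-to-end orchestration: scenario comparisons, A-Ci and light response
# curves, the 2D-slice comparison mode, the 0-D well-mixed oracle, and
# tabular reporting.

#' Experiment configuration
#'
#' @param geometry a [geometry_params()] object, or a [label_volume()] to
#'   use directly.
#' @param scenario one of "default", "aggregative", "avoidance".
#' @param Ca_grid ambient CO2 grid for A-Ci sweeps, umol mol-1.
#' @param I_grid irradiance grid for light-response sweeps, umol m-2 s-1.
#' @param I_inc irradiance for single runs, umol m-2 s-1.
#' @param ambient_co2,ambient_o2 conditions for single runs (umol mol-1,
#'   mmol mol-1).
#' @param n_photons Monte Carlo photon packets per wavelength.
#' @param seed integer seed for all stochastic stages.
#' @param g_s stomatal conductance target, mol m-2 s-1.
#' @param transport,kinetics,energetics parameter objects.
#' @param optics an [optical_properties()] object (chloroplast absorption is
#'   filled in per geometry).
#' @param damping,tol,maxit solver settings.
#' @param outdir output directory for [report()].
#' @return object of class `experiment_config`.
#' @export
experiment_config <- function(geometry = geometry_params(),
                              scenario = "default",
                              Ca_grid = c(100, 250, 380, 700),
                              I_grid = c(200, 500, 1000, 1500, 2000),
                              I_inc = 1500,
                              ambient_co2 = 380, ambient_o2 = 210,
                              n_photons = 1e5, seed = 1, g_s = 0.2,
                              transport = transport_params(),
                              kinetics = kinetic_params(),
                              energetics = energetics_params(),
                              optics = optical_properties(),
                              damping = 0.5, tol = 3e-5, maxit = 400,
                              outdir = NULL) {
  scenario <- match.arg(scenario, c("default", "aggregative", "avoidance"))
  if (length(Ca_grid) == 0 || length(I_grid) == 0) {
    stop("environment grids must be non-empty")
  }
  cfg <- as.list(environment())
  cfg$transport <- utils::modifyList(transport,
                                     list(ambient_co2 = ambient_co2,
                                          ambient_o2 = ambient_o2,
                                          g_s = g_s))
  structure(cfg, class = "experiment_config")
}

# resolve the configured geometry + scenario into a label volume
.scenario_volume <- function(cfg) {
  vol <- if (inherits(cfg$geometry, "label_volume")) {
    cfg$geometry
  } else {
    generate_kranz_geometry(cfg$geometry)
  }
  switch(cfg$scenario,
         default = vol,
         aggregative = apply_aggregative_movement(vol),
         avoidance = apply_avoidance_movement(vol))
}

#' Run the full pipeline once for a configuration
#'
#' Geometry (with the configured chloroplast-movement scenario), chlorophyll
#' assignment, Monte Carlo light transport at both wavelengths, energetics,
#' stomatal calibration, and the coupled reaction-diffusion solve.
#'
#' @param cfg an [experiment_config()].
#' @param light_field optionally reuse a precomputed absorption field.
#' @param pore_scale optionally reuse a calibrated pore scale.
#' @return a [solve_steady_state()] result with the `energetics_state` and
#'   scenario metadata attached.
#' @export
run_pipeline <- function(cfg = experiment_config(), light_field = NULL,
                         pore_scale = NULL) {
  vol <- .scenario_volume(cfg)
  props <- chlorophyll_absorption(cfg$optics, vol)
  if (is.null(light_field)) {
    light_field <- run_light_model(vol, props, cfg$n_photons, cfg$seed)
  }
  en <- energetics_state(vol, light_field, incident_light(cfg$I_inc),
                         cfg$energetics)
  if (is.null(pore_scale)) {
    pore_scale <- calibrate_stomatal_diffusivity(vol, cfg$transport)$pore_scale
  }
  res <- solve_steady_state(vol, en, cfg$transport, cfg$kinetics,
                            pore_scale = pore_scale, damping = cfg$damping,
                            tol = cfg$tol, maxit = cfg$maxit)
  res$scenario <- cfg$scenario
  res$light_budget <- light_field$budget
  res$vol <- vol
  res$light_field <- light_field
  res
}

#' Compare the chloroplast-arrangement scenarios end to end
#'
#' Runs the default, aggregative, and avoidance arrangements through the
#' full pipeline under identical conditions and seeds, and tabulates light
#' absorbance (total, per chloroplast class, bundle-sheath:mesophyll ratio),
#' transmittance, electron-transport partitioning, ATP/NADPH bundle-sheath
#' fractions, net photosynthesis, and leakiness.
#'
#' @param cfg an [experiment_config()] (its `scenario` field is ignored).
#' @return data.frame with one row per scenario.
#' @export
run_scenario_comparison <- function(cfg = experiment_config()) {
  rows <- lapply(c("default", "aggregative", "avoidance"), function(sc) {
    cfg$scenario <- sc
    res <- tryCatch(run_pipeline(cfg), error = function(e) {
      stop(sprintf("scenario '%s': %s", sc, conditionMessage(e)))
    })
    en <- res$energy
    data.frame(
      scenario = sc,
      absorbance_total = res$light_budget[["A"]],
      absorbance_chloroplast = en$absorbance_M + en$absorbance_BS,
      transmittance = res$light_budget[["T"]],
      reflectance = res$light_budget[["R"]],
      absorbance_bs_to_m = en$absorbance_BS / en$absorbance_M,
      fCET_M = en$fCET_M, fCET_BS = en$fCET_BS,
      jATP = en$jATP, fATP_BS = en$fATP_BS, fNADPH_BS = en$fNADPH_BS,
      A_n = res$A_n, Phi = res$Phi, C_c = res$C_c
    )
  })
  do.call(rbind, rows)
}

#' Net-photosynthesis response to ambient CO2 (A-Ci curve)
#'
#' Sweeps the ambient CO2 grid at fixed irradiance, re-using one Monte
#' Carlo light solution (light does not depend on CO2) and one stomatal
#' calibration across the grid.
#'
#' @param cfg an [experiment_config()].
#' @return data.frame (`CurveResult`) with one row per grid point: `Ca`,
#'   `C_i`, `A_n`, `Phi`, `C_c`, `jATP`, `fATP_BS`, `scenario`.
#' @export
run_aci_curve <- function(cfg = experiment_config()) {
  if (length(cfg$Ca_grid) == 0) stop("empty Ca grid")
  vol <- .scenario_volume(cfg)
  props <- chlorophyll_absorption(cfg$optics, vol)
  lf <- run_light_model(vol, props, cfg$n_photons, cfg$seed)
  en <- energetics_state(vol, lf, incident_light(cfg$I_inc), cfg$energetics)
  cal <- calibrate_stomatal_diffusivity(vol, cfg$transport)
  rows <- lapply(sort(cfg$Ca_grid), function(ca) {
    tp <- utils::modifyList(cfg$transport, list(ambient_co2 = ca))
    class(tp) <- class(cfg$transport)
    res <- solve_steady_state(vol, en, tp, cfg$kinetics,
                              pore_scale = cal$pore_scale,
                              damping = cfg$damping, tol = cfg$tol,
                              maxit = cfg$maxit)
    data.frame(Ca = ca, C_i = res$C_i, A_n = res$A_n, Phi = res$Phi,
               C_c = res$C_c, jATP = en$jATP, fATP_BS = en$fATP_BS,
               scenario = cfg$scenario)
  })
  do.call(rbind, rows)
}

#' Net-photosynthesis response to irradiance (light curve)
#'
#' Sweeps the irradiance grid at fixed ambient CO2; each irradiance re-uses
#' the same absorbed-photon fractions (the Monte Carlo solution scales
#' linearly with incident flux) and one stomatal calibration.
#'
#' @param cfg an [experiment_config()].
#' @return data.frame with one row per irradiance.
#' @export
run_light_curve <- function(cfg = experiment_config()) {
  if (length(cfg$I_grid) == 0) stop("empty irradiance grid")
  vol <- .scenario_volume(cfg)
  props <- chlorophyll_absorption(cfg$optics, vol)
  lf <- run_light_model(vol, props, cfg$n_photons, cfg$seed)
  cal <- calibrate_stomatal_diffusivity(vol, cfg$transport)
  rows <- lapply(sort(cfg$I_grid), function(ii) {
    en <- energetics_state(vol, lf, incident_light(ii), cfg$energetics)
    res <- solve_steady_state(vol, en, cfg$transport, cfg$kinetics,
                              pore_scale = cal$pore_scale,
                              damping = cfg$damping, tol = cfg$tol,
                              maxit = cfg$maxit)
    data.frame(I_inc = ii, C_i = res$C_i, A_n = res$A_n, Phi = res$Phi,
               C_c = res$C_c, jATP = en$jATP, fATP_BS = en$fATP_BS,
               scenario = cfg$scenario)
  })
  do.call(rbind, rows)
}

#' 2D cross-section comparison mode
#'
#' Extracts single anatomical cross-sections (x-z planes at the given
#' positions along the vein axis), holds the airspace at the mean
#' intercellular CO2/O2 of a full 3D solution (2D slices cannot resolve the
#' airspace network), re-uses the 3D light solution restricted to the slice,
#' and solves the in-plane reaction-diffusion system per slice.
#'
#' @param cfg an [experiment_config()].
#' @param slice_y integer positions along y (defaults to quartile slices).
#' @param result3d optionally a precomputed 3D [run_pipeline()] result.
#' @param eta relative viscosity for the slice solve (1 mimics pure-water
#'   diffusivities; 2 is the default biological medium).
#' @return list with `slices` (data.frame of per-slice A_n and C_c) and
#'   `result3d`.
#' @export
run_2d_slice_mode <- function(cfg = experiment_config(), slice_y = NULL,
                              result3d = NULL, eta = cfg$transport$eta) {
  if (is.null(result3d)) result3d <- run_pipeline(cfg)
  vol <- result3d$vol
  d <- dim(vol$labels)
  if (is.null(slice_y)) slice_y <- round(d[2] * c(0.25, 0.5, 0.75))
  if (any(slice_y < 1 | slice_y > d[2])) stop("invalid slice position")
  L <- kranz_labels()
  mean_ias_co2 <- mean(result3d$co2[vol$labels == L["IAS"]])
  mean_ias_o2 <- mean(result3d$o2[vol$labels == L["IAS"]])
  tp <- utils::modifyList(cfg$transport, list(eta = eta))
  class(tp) <- class(cfg$transport)
  rows <- lapply(slice_y, function(j) {
    labs <- vol$labels[, j, , drop = FALSE]
    ids <- vol$cell_instance_ids[, j, , drop = FALSE]
    vol2 <- label_volume(array(labs, dim = c(d[1], 1L, d[3])),
                         vol$voxel_pitch_um,
                         cell_instance_ids = array(ids, dim = c(d[1], 1L, d[3])))
    # slice energetics: restrict the 3D LET/ATP fields to the slice
    en <- result3d$energy
    en2 <- en
    en2$j_let_density <- array(en$j_let_density[, j, , drop = FALSE],
                               dim = c(d[1], 1L, d[3]))
    res <- solve_steady_state(
      vol2, en2, tp, cfg$kinetics, pore_scale = result3d$pore_scale,
      damping = cfg$damping, tol = cfg$tol, maxit = cfg$maxit,
      fix_gas_at = c(co2 = mean_ias_co2, o2 = mean_ias_o2)
    )
    data.frame(slice_y = j, A_n = res$A_n, C_c = res$C_c, Phi = res$Phi)
  })
  list(slices = do.call(rbind, rows), result3d = result3d)
}

#' Algebraic well-mixed (0-D) model of the C4 leaf
#'
#' Independent compartment model used as an oracle for the 3D solver: one
#' well-mixed mesophyll-cytosol compartment (CA and spontaneous hydration,
#' PEPC, respiration), one bundle-sheath compartment (decarboxylation,
#' Rubisco, photorespiration, respiration), a single
#' mesophyll-bundle-sheath plasmodesmatal conductance, and a stomatal
#' conductance to ambient. Solved by damped fixed-point iteration on the
#' four unknown concentrations.
#'
#' @param anatomy an [anatomical_stats()] result.
#' @param energy an [energetics_state()].
#' @param tp a [transport_params()] object.
#' @param kp a [kinetic_params()] object.
#' @param g_s stomatal conductance, mol m-2 s-1 (default `tp$g_s`).
#' @param conductance_scale multiplier applied to the lumped stomatal and
#'   plasmodesmatal conductances (use the same factor as a scaled 3D run).
#' @param maxit,tol fixed-point controls.
#' @return list with `A_n`, `Vp`, `L`, `Phi`, `C_M`, `C_BS`, `HCO3_M`,
#'   `O_BS` and convergence info.
#' @export
well_mixed_oracle <- function(anatomy, energy, tp = transport_params(),
                              kp = kinetic_params(), g_s = tp$g_s,
                              conductance_scale = 1, maxit = 5000,
                              tol = 1e-10) {
  k <- physical_constants()
  d <- anatomy$d
  f <- anatomy$volume_fraction
  v_mcy <- d * f[["M_CYTOSOL"]]          # m3 per m2 leaf
  v_bsch <- d * f[["BS_CHLOROPLAST"]]
  v_bscy <- d * f[["BS_CYTOSOL"]]
  Vcmax_star <- volumetric_scaling(kp$V_cmax, d, f[["BS_CHLOROPLAST"]])
  Vpmax_star <- volumetric_scaling(kp$V_pmax, d, f[["M_CYTOSOL"]])
  resp <- respiration_rates(kp$R_d, anatomy)
  H_cy <- proton_concentration(kp$pH_cytosol)

  # lumped conductances in liquid-equivalent units (m s-1 per leaf area)
  g_sto <- g_s / (k$c_total * k$henry_co2) * conductance_scale
  Dliq <- tp$D_co2_liquid / tp$eta
  P_pd <- Dliq * tp$zeta_plasmodesmata / tp$t_plasmodesma
  g_pd <- P_pd * anatomy$S_BS * conductance_scale
  Dliq_o <- tp$D_o2_liquid / tp$eta
  P_pd_o <- Dliq_o * tp$zeta_plasmodesmata / tp$t_plasmodesma
  g_pd_o <- P_pd_o * anatomy$S_BS * conductance_scale
  g_sto_o <- g_s * (tp$D_o2_gas / tp$D_co2_gas) /
    (k$c_total * k$henry_o2) * conductance_scale

  C_amb <- ppm_to_liquid(tp$ambient_co2, k$henry_co2)
  O_amb <- ppm_to_liquid(tp$ambient_o2 * 1e3, k$henry_o2)
  j_c3_star <- energy$j_star_ATP_C3
  j_c4_star <- energy$j_star_ATP_C4
  E_bs <- energy$j_BS / 4                 # umol m-2 s-1 O2 evolution in BS

  C_M <- C_amb; B_M <- kp$K_eq * C_M / H_cy
  C_BS <- 3 * C_amb; O_BS <- O_amb
  u <- 1e-6
  damp <- 0.2
  conv <- FALSE
  for (it in seq_len(maxit)) {
    # bicarbonate balance at the current C_M: hydration supply = PEPC draw
    fB <- function(B) {
      (ca_hydration(C_M, B, H_cy, kp) +
         spontaneous_hydration(C_M, B, H_cy, kp)) * v_mcy -
        pepc_rate(B, Vpmax_star, j_c4_star, kp$K_h) * v_mcy
    }
    B_hi <- 1e3
    B_M <- if (fB(0) <= 0) 0 else
      stats::uniroot(fB, c(0, B_hi), tol = 1e-12)$root
    hyd <- (ca_hydration(C_M, B_M, H_cy, kp) +
              spontaneous_hydration(C_M, B_M, H_cy, kp)) * v_mcy
    Vp <- pepc_rate(B_M, Vpmax_star, j_c4_star, kp$K_h) * v_mcy
    Vc <- rubisco_rate(C_BS, O_BS, Vcmax_star, j_c3_star, kp) * v_bsch
    ox <- Vc * kp$gamma_star *
      ifelse(C_BS > 0, (O_BS / k$henry_o2) / (C_BS / k$henry_co2), 0)
    R_M_area <- resp$per_class[["M_CYTOSOL"]]
    R_BS_area <- resp$per_class[["BS_CYTOSOL"]]

    # fixed-point updates (flux balances solved for each unknown)
    C_M_new <- (g_sto * C_amb + g_pd * C_BS +
                  (R_M_area - hyd) * u) / (g_sto + g_pd)
    C_BS_new <- C_M + (Vp - Vc + ox + R_BS_area) * u / g_pd
    O_BS_new <- O_amb + (E_bs - 3 * ox - R_BS_area) * u / g_pd_o

    delta <- max(abs(C_M_new - C_M), abs(C_BS_new - C_BS),
                 abs(O_BS_new - O_BS)) / max(C_amb, 1e-12)
    C_M <- C_M + damp * (C_M_new - C_M)
    C_BS <- max(C_BS + damp * (C_BS_new - C_BS), 1e-9)
    O_BS <- max(O_BS + damp * (O_BS_new - O_BS), 1e-9)
    if (delta < tol) { conv <- TRUE; break }
  }
  Vp <- pepc_rate(B_M, Vpmax_star, j_c4_star, kp$K_h) * v_mcy
  Vc <- rubisco_rate(C_BS, O_BS, Vcmax_star, j_c3_star, kp) * v_bsch
  ox <- Vc * kp$gamma_star * (O_BS / k$henry_o2) / (C_BS / k$henry_co2)
  A_n <- Vc - ox - kp$R_d
  lk <- if (Vp > 0) leakiness(Vp, A_n, resp$per_class[["M_CYTOSOL"]]) else
    list(L = NA, Phi = NA)
  list(A_n = A_n, Vp = Vp, Vc = Vc, L = lk$L, Phi = lk$Phi,
       C_M = C_M, C_BS = C_BS, HCO3_M = B_M, O_BS = O_BS,
       C_c = liquid_to_ppm(C_BS), converged = conv, iterations = it)
}

#' Write experiment tables to disk
#'
#' Deterministic file naming; every table carries the configuration hash,
#' seed, and package version as comment headers. Re-running with the same
#' configuration produces byte-identical files.
#'
#' @param results named list of data.frames.
#' @param outdir output directory (created if missing).
#' @param cfg the [experiment_config()] used (for the header).
#' @return character vector of files written, invisibly.
#' @export
report <- function(results, outdir, cfg = NULL) {
  if (!is.list(results) || is.null(names(results)) ||
      any(names(results) == "")) {
    stop("malformed results: expected a named list of data.frames")
  }
  if (!dir.exists(outdir)) dir.create(outdir, recursive = TRUE)
  ver <- as.character(utils::packageVersion("kranzsim"))
  hash <- if (!is.null(cfg)) {
    keep <- !vapply(cfg, is.function, TRUE)
    digestable <- utils::capture.output(utils::str(cfg[keep], digits.d = 12))
    sprintf("%08x", sum(utf8ToInt(paste(digestable, collapse = "")) *
                          seq_along(utf8ToInt(paste(digestable, collapse = "")))) %% .Machine$integer.max)
  } else "none"
  seed <- if (!is.null(cfg)) cfg$seed else NA
  files <- character(0)
  for (nm in names(results)) {
    path <- file.path(outdir, paste0(nm, ".csv"))
    con <- file(path, "w")
    writeLines(sprintf("# kranzsim %s | config %s | seed %s", ver, hash,
                       as.character(seed)), con)
    utils::write.csv(results[[nm]], con, row.names = FALSE)
    close(con)
    files <- c(files, path)
  }
  invisible(files)
}
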