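# Procedural 3D Kranz-anatomy label volumes: generation, chloroplast-movement
# transforms, anatomical statistics, and TIFF/VTK input-output.
#
# Axes: x is lateral (across veins), y runs along the vein axis, z is leaf
# depth from the adaxial (upper) to the abaxial (lower) surface. Voxel i has
# its center at (i - 0.5) voxel units from the domain origin.

#' Label vocabulary of a Kranz tissue volume
#'
#' @return named integer vector mapping tissue-class names to label codes.
#' @export
kranz_labels <- function() {
  c(AIR = 0L, EPIDERMIS = 1L, STOMATAL_PORE = 2L, IAS = 3L,
    M_CYTOSOL = 4L, M_VACUOLE = 5L, M_CHLOROPLAST = 6L,
    BS_CYTOSOL = 7L, BS_VACUOLE = 8L, BS_CHLOROPLAST = 9L, VASCULAR = 10L)
}

.L <- function(name) unname(kranz_labels()[name])

# label groups used throughout
.mesophyll_labels <- function() .L(c("M_CYTOSOL", "M_VACUOLE", "M_CHLOROPLAST"))
.bs_labels <- function() .L(c("BS_CYTOSOL", "BS_VACUOLE", "BS_CHLOROPLAST"))
.gas_labels <- function() .L(c("AIR", "STOMATAL_PORE", "IAS"))
.liquid_labels <- function() setdiff(unname(kranz_labels()), .gas_labels())

#' Parameters of the synthetic Kranz-anatomy generator
#'
#' Defaults describe one concentric vein / bundle-sheath / mesophyll unit of
#' a maize-type (NADP-ME) leaf on a desk-scale grid (64 x 32 x 84 voxels at
#' 2 um pitch, one air layer above and below the tissue; the tissue is
#' statistically homogeneous along the vein axis, so a half-length vein
#' segment carries the same anatomy statistics at half the cost). The default
#' composition fractions are calibrated so the generated anatomy matches
#' measured maize tissue statistics: intercellular airspace near 22% of
#' tissue volume, exposed mesophyll surface near 12 m2 per m2 leaf,
#' chloroplast volumes near 13 (mesophyll) and 15 (bundle sheath) um3 per
#' um2 of leaf. Interveinal mesophyll cells (those beyond one cell diameter
#' from the sheath) are smaller and chloroplast-enriched relative to
#' perivein cells, reproducing the reported covariance between cell position
#' and plastid content.
#'
#' @param voxel_pitch_um voxel edge length, um.
#' @param grid_dims integer triple (nx, ny, nz).
#' @param leaf_thickness_um nominal tissue thickness, um.
#' @param vein_count number of vein units across the x extent (>= 1).
#' @param vein_spacing_um lateral spacing between vein axes, um.
#' @param vascular_radius_um,bundle_sheath_radius_um cylinder radii, um.
#' @param mesophyll_cell_radius_um nominal mesophyll cell radius, um.
#' @param epidermis_thickness_um per-face epidermis thickness, um.
#' @param vacuole_volume_fraction mesophyll vacuole fraction of cell volume.
#' @param vacuole_volume_fraction_bs bundle-sheath vacuole fraction.
#' @param chloroplast_volume_fraction_m mesophyll (perivein) chloroplast
#'   fraction of cell volume.
#' @param chloroplast_volume_fraction_bs bundle-sheath chloroplast fraction.
#' @param interveinal_chloroplast_fraction,interveinal_vacuole_fraction
#'   composition of interveinal mesophyll cells.
#' @param interveinal_radius_factor radius multiplier for interveinal cells.
#' @param cell_spacing_factor center-to-center spacing as a multiple of the
#'   cell diameter.
#' @param ring_penetration_factor radial position of the first (contact)
#'   shell of mesophyll cells as `r_bs + factor * r_m`; smaller values press
#'   the cells deeper into the sheath surface, widening the plasmodesmatal
#'   contact caps.
#' @param polar_gap_deg angular half-width (degrees from vertical) of the
#'   sheath's polar sectors where perivein cells are lifted off the sheath
#'   surface instead of touching it (cells arch over the vein; the
#'   plasmodesmatal contacts sit on the flanks).
#' @param polar_lift_factor lift of polar-sector cells off the sheath, as a
#'   fraction of the cell radius.
#' @param jitter_vox uniform positional jitter of cell centers, voxels.
#' @param stomatal_pore_radius_um stomatal pore radius, um.
#' @param stomata_per_face stomata on the adaxial face.
#' @param stomatal_ratio abaxial:adaxial stomatal count ratio.
#' @param rng_seed integer seed controlling all random placement.
#' @return object of class `geometry_params`.
#' @export
geometry_params <- function(voxel_pitch_um = 2,
                            grid_dims = c(64L, 32L, 84L),
                            leaf_thickness_um = 164,
                            vein_count = 1,
                            vein_spacing_um = 128,
                            vascular_radius_um = 10,
                            bundle_sheath_radius_um = 34.9,
                            mesophyll_cell_radius_um = 9.3,
                            epidermis_thickness_um = 18,
                            vacuole_volume_fraction = 0.60,
                            vacuole_volume_fraction_bs = 0.20,
                            chloroplast_volume_fraction_m = 0.19,
                            chloroplast_volume_fraction_bs = 0.548,
                            interveinal_chloroplast_fraction = 0.36,
                            interveinal_vacuole_fraction = 0.50,
                            interveinal_radius_factor = 0.95,
                            cell_spacing_factor = 0.87,
                            ring_penetration_factor = 0.5,
                            polar_gap_deg = 25,
                            polar_lift_factor = 1.0,
                            jitter_vox = 0.5,
                            stomatal_pore_radius_um = 3,
                            stomata_per_face = 2,
                            stomatal_ratio = 1.0,
                            rng_seed = 1L) {
  p <- as.list(environment())
  lens <- unlist(p[c("voxel_pitch_um", "leaf_thickness_um", "vein_spacing_um",
                     "vascular_radius_um", "bundle_sheath_radius_um",
                     "mesophyll_cell_radius_um", "epidermis_thickness_um",
                     "stomatal_pore_radius_um")])
  if (any(lens <= 0)) stop("all lengths must be positive")
  fr <- unlist(p[c("vacuole_volume_fraction", "vacuole_volume_fraction_bs",
                   "chloroplast_volume_fraction_m",
                   "chloroplast_volume_fraction_bs",
                   "interveinal_chloroplast_fraction",
                   "interveinal_vacuole_fraction")])
  if (any(fr <= 0 | fr >= 1)) stop("volume fractions must lie in (0, 1)")
  if (p$vacuole_volume_fraction + p$chloroplast_volume_fraction_m >= 1 ||
      p$interveinal_vacuole_fraction + p$interveinal_chloroplast_fraction >= 1 ||
      p$vacuole_volume_fraction_bs + p$chloroplast_volume_fraction_bs >= 1) {
    stop("vacuole + chloroplast fractions must leave room for cytosol")
  }
  if (length(grid_dims) != 3 || any(grid_dims < 4)) {
    stop("grid_dims must be three integers >= 4")
  }
  p$grid_dims <- as.integer(grid_dims)
  if (leaf_thickness_um > grid_dims[3] * voxel_pitch_um) {
    stop("leaf thickness exceeds the grid depth")
  }
  structure(p, class = "geometry_params")
}

#' Construct and validate a label volume
#'
#' @param labels 3D integer array of tissue-class codes (see
#'   [kranz_labels()]).
#' @param voxel_pitch_um voxel edge length, um.
#' @param cell_instance_ids optional 3D integer array of mesophyll cell ids
#'   (0 outside mesophyll cells).
#' @param cells optional data.frame of per-cell metadata.
#' @param params the [geometry_params()] that produced the volume, if any.
#' @return object of class `label_volume`.
#' @export
label_volume <- function(labels, voxel_pitch_um, cell_instance_ids = NULL,
                         cells = NULL, params = NULL) {
  stopifnot(length(dim(labels)) == 3, voxel_pitch_um > 0)
  bad <- setdiff(unique(as.integer(labels)), unname(kranz_labels()))
  if (length(bad) > 0) {
    stop("unknown label code(s): ", paste(bad, collapse = ", "))
  }
  structure(list(labels = labels, voxel_pitch_um = voxel_pitch_um,
                 cell_instance_ids = cell_instance_ids, cells = cells,
                 params = params),
            class = "label_volume")
}

#' @export
print.label_volume <- function(x, ...) {
  d <- dim(x$labels)
  cat(sprintf("<label_volume> %d x %d x %d voxels at %.3g um\n",
              d[1], d[2], d[3], x$voxel_pitch_um))
  tab <- table(factor(as.integer(x$labels), levels = unname(kranz_labels()),
                      labels = names(kranz_labels())))
  print(tab)
  invisible(x)
}

# rasterize a sphere into currently-IAS voxels; returns global linear indices
.claim_sphere <- function(labels, center, radius) {
  d <- dim(labels)
  ix <- max(1L, ceiling(center[1] - radius + 0.5)):min(d[1], floor(center[1] + radius + 0.5))
  iy <- max(1L, ceiling(center[2] - radius + 0.5)):min(d[2], floor(center[2] + radius + 0.5))
  iz <- max(1L, ceiling(center[3] - radius + 0.5)):min(d[3], floor(center[3] + radius + 0.5))
  if (!length(ix) || !length(iy) || !length(iz)) return(integer(0))
  dx2 <- (ix - 0.5 - center[1])^2
  dy2 <- (iy - 0.5 - center[2])^2
  dz2 <- (iz - 0.5 - center[3])^2
  inside <- outer(outer(dx2, dy2, "+"), dz2, "+") <= radius^2
  sub <- which(inside, arr.ind = TRUE)
  if (!nrow(sub)) return(integer(0))
  gi <- ix[sub[, 1]] + d[1] * (iy[sub[, 2]] - 1L + d[2] * (iz[sub[, 3]] - 1L))
  gi[labels[gi] == .L("IAS")]
}

# voxel center coordinates for global linear indices
.voxel_coords <- function(idx, dims) {
  i <- (idx - 1L) %% dims[1] + 1L
  j <- ((idx - 1L) %/% dims[1]) %% dims[2] + 1L
  k <- (idx - 1L) %/% (dims[1] * dims[2]) + 1L
  cbind(i - 0.5, j - 0.5, k - 0.5)
}

#' Generate a synthetic 3D Kranz-anatomy label volume
#'
#' Builds one (or several) concentric vein / bundle-sheath / mesophyll units:
#' a vascular cylinder along y wrapped by a bundle-sheath annulus whose
#' outermost layer is a centrifugal chloroplast sheet, surrounded by
#' spherical mesophyll cells (central vacuole, parietal chloroplast patches,
#' cytosol) packed between epidermis slabs, with intercellular airspace in
#' the gaps and stomatal pores piercing both epidermes. Deterministic for a
#' fixed `rng_seed`.
#'
#' @param params a [geometry_params()] object.
#' @return a [label_volume()] with `cell_instance_ids` and per-cell metadata
#'   (including the interveinal classification).
#' @export
generate_kranz_geometry <- function(params = geometry_params()) {
  stopifnot(inherits(params, "geometry_params"))
  if (params$vein_count < 1) {
    stop("sizing error: vein_count must be >= 1 to host a Kranz unit")
  }
  h <- params$voxel_pitch_um
  d <- params$grid_dims
  nx <- d[1]; ny <- d[2]; nz <- d[3]
  L <- kranz_labels()

  ne <- max(1L, round(params$epidermis_thickness_um / h))
  if (nz < 2 * ne + 6) stop("sizing error: grid too shallow for the epidermis")
  z_top_plane <- 1 + ne          # plane below the adaxial epidermis
  z_bot_plane <- nz - 1 - ne     # plane above the abaxial epidermis
  int_lo <- z_top_plane + 1L     # first interior layer
  int_hi <- z_bot_plane          # last interior layer

  r_v <- params$vascular_radius_um / h
  r_bs <- params$bundle_sheath_radius_um / h
  r_m <- params$mesophyll_cell_radius_um / h
  zc <- nz / 2
  if (2 * r_bs + 2 > nx / params$vein_count ||
      2 * r_bs + 2 > (int_hi - int_lo + 1)) {
    stop("sizing error: grid too small to host one vein unit")
  }
  vein_x <- nx / 2 + (seq_len(params$vein_count) - (params$vein_count + 1) / 2) *
    params$vein_spacing_um / h

  # --- y-invariant template: air, epidermis, IAS, vein cylinder rings -----
  tmpl <- matrix(L["IAS"], nx, nz)
  tmpl[, c(1L, nz)] <- L["AIR"]
  tmpl[, c(2:(1 + ne), (nz - ne):(nz - 1))] <- L["EPIDERMIS"]
  xs <- seq_len(nx) - 0.5
  zs <- seq_len(nz) - 0.5
  area_bs <- pi * (r_bs^2 - r_v^2)
  r_chl_in <- sqrt(r_bs^2 - params$chloroplast_volume_fraction_bs * area_bs / pi)
  r_vac_out <- sqrt(r_v^2 + params$vacuole_volume_fraction_bs * area_bs / pi)
  for (vx in vein_x) {
    R2 <- outer((xs - vx)^2, (zs - zc)^2, "+")
    interior_cols <- matrix(rep(seq_len(nz) >= int_lo & seq_len(nz) <= int_hi,
                                each = nx), nx, nz)
    tmpl[R2 <= r_bs^2 & interior_cols] <- L["BS_CHLOROPLAST"]
    tmpl[R2 <= r_chl_in^2 & interior_cols] <- L["BS_CYTOSOL"]
    tmpl[R2 <= r_vac_out^2 & interior_cols] <- L["BS_VACUOLE"]
    tmpl[R2 <= r_v^2 & interior_cols] <- L["VASCULAR"]
  }
  labels <- aperm(array(tmpl, dim = c(nx, nz, ny)), c(1, 3, 2))

  # --- stomatal pores ------------------------------------------------------
  n_ad <- params$stomata_per_face
  n_ab <- max(1L, round(params$stomata_per_face * params$stomatal_ratio))
  pore_xy <- function(n, offset) {
    tt <- (seq_len(n) - 0.5) / n
    cbind(x = nx * tt, y = ny * ((tt + offset) %% 1))
  }
  pores <- rbind(
    cbind(pore_xy(n_ad, 0.25), face = 1),
    cbind(pore_xy(n_ab, 0.75), face = 2)
  )
  r_p <- params$stomatal_pore_radius_um / h
  cx <- seq_len(nx) - 0.5
  cy <- seq_len(ny) - 0.5
  for (s in seq_len(nrow(pores))) {
    mask <- outer((cx - pores[s, "x"])^2, (cy - pores[s, "y"])^2, "+") <= r_p^2
    kr <- if (pores[s, "face"] == 1) 2:(1 + ne) else (nz - ne):(nz - 1)
    for (k in kr) {
      slab <- labels[, , k]
      slab[mask & slab == L["EPIDERMIS"]] <- L["STOMATAL_PORE"]
      labels[, , k] <- slab
    }
  }

  # --- mesophyll cell centers ---------------------------------------------
  old_seed <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  on.exit({
    if (!is.null(old_seed)) assign(".Random.seed", old_seed, globalenv())
  }, add = TRUE)
  set.seed(params$rng_seed)

  spacing <- params$cell_spacing_factor * 2 * r_m
  jit <- function(n) stats::runif(n, -params$jitter_vox, params$jitter_vox)
  y_rows <- seq(spacing / 2, ny, by = spacing)
  z_lo_c <- z_top_plane + 0.7 * r_m
  z_hi_c <- z_bot_plane - 0.7 * r_m
  iv_threshold <- r_bs + 2 * r_m

  centers <- NULL
  add_cells <- function(cent, interveinal) {
    if (is.null(cent) || nrow(cent) == 0) return(invisible())
    cent <- cbind(cent, interveinal = interveinal)
    centers <<- rbind(centers, cent)
    invisible()
  }
  for (vx in vein_x) {
    # first shell: ring of cells in contact with the sheath, except within
    # the polar sectors (the sheath's top and bottom shoulders carry the
    # plasmodesmatal contacts; directly above and below the sheath the cells
    # are lifted off the surface, mimicking cells arching over the vein)
    rho1 <- r_bs + params$ring_penetration_factor * r_m
    polar_gap <- params$polar_gap_deg * pi / 180
    n_ang <- max(8L, round(2 * pi * rho1 / spacing))
    for (m in seq_along(y_rows)) {
      ang <- 2 * pi * ((seq_len(n_ang) - 1) + 0.5 * (m %% 2)) / n_ang
      polar <- abs(sin(ang)) > cos(polar_gap)
      lift <- ifelse(polar, params$polar_lift_factor * r_m, 0)
      cent <- cbind(vx + rho1 * cos(ang) + jit(n_ang),
                    y_rows[m] + jit(n_ang),
                    zc + (rho1 + lift) * sin(ang) + jit(n_ang))
      keep <- cent[, 3] >= z_lo_c & cent[, 3] <= z_hi_c
      add_cells(cent[keep, , drop = FALSE], FALSE)
    }
    # second shell: diagonal arcs between the first shell and the epidermis,
    # restricted to stay perivein and inside the interior slab
    rho2 <- rho1 + spacing
    n_ang2 <- max(8L, round(2 * pi * rho2 / spacing))
    for (m in seq_along(y_rows)) {
      ang <- 2 * pi * ((seq_len(n_ang2) - 1) + 0.5 * ((m + 1) %% 2)) / n_ang2
      cent <- cbind(vx + rho2 * cos(ang) + jit(n_ang2),
                    y_rows[m] + jit(n_ang2),
                    zc + rho2 * sin(ang) + jit(n_ang2))
      keep <- cent[, 3] >= z_lo_c & cent[, 3] <= z_hi_c &
        abs(cent[, 1] - vx) < iv_threshold - 0.2 * r_m
      add_cells(cent[keep, , drop = FALSE], FALSE)
    }
  }
  # interveinal columns: lateral bands beyond one cell diameter from the
  # sheath (domain edges for a single vein, midpoints between veins)
  r_iv <- r_m * params$interveinal_radius_factor
  band_x <- unique(c(
    if (params$vein_count > 1) {
      (vein_x[-1] + vein_x[-length(vein_x)]) / 2
    },
    min(vein_x) - (iv_threshold + 0.7 * r_m),
    max(vein_x) + (iv_threshold + 0.7 * r_m)
  ))
  band_x <- band_x[band_x > 0.2 * r_m & band_x < nx - 0.2 * r_m]
  spacing_iv <- params$cell_spacing_factor * 2 * r_iv
  z_rows_iv <- zc + (seq(-floor((z_hi_c - zc) / spacing_iv),
                         floor((z_hi_c - zc) / spacing_iv)) +
                       0.5) * spacing_iv
  z_rows_iv <- z_rows_iv[z_rows_iv >= z_lo_c & z_rows_iv <= z_hi_c]
  for (bx in band_x) {
    for (m in seq_along(y_rows)) {
      cent <- cbind(bx + jit(length(z_rows_iv)),
                    y_rows[m] + jit(length(z_rows_iv)),
                    z_rows_iv + jit(length(z_rows_iv)))
      add_cells(cent, TRUE)
    }
  }

  # --- claim voxels and assign intracellular composition -------------------
  cellid <- array(0L, dim = d)
  cells <- list()
  next_id <- 0L
  for (ci in seq_len(nrow(centers))) {
    interveinal <- centers[ci, "interveinal"] > 0
    radius <- if (interveinal) r_iv else r_m
    ctr <- centers[ci, 1:3]
    vox <- .claim_sphere(labels, ctr, radius)
    if (length(vox) < 0.3 * 4 / 3 * pi * radius^3) next
    next_id <- next_id + 1L
    cellid[vox] <- next_id
    f_vac <- if (interveinal) params$interveinal_vacuole_fraction else params$vacuole_volume_fraction
    f_chl <- if (interveinal) params$interveinal_chloroplast_fraction else params$chloroplast_volume_fraction_m
    co <- .voxel_coords(vox, d)
    off <- sweep(co, 2, ctr)
    dist <- sqrt(rowSums(off^2))
    n <- length(vox)
    n_vac <- round(f_vac * n)
    n_chl <- round(f_chl * n)
    ord <- order(dist, vox)
    vac <- ord[seq_len(n_vac)]
    rest <- ord[-seq_len(n_vac)]
    # parietal chloroplast patches: outermost voxels nearest a few random
    # surface directions
    ndir <- 4L
    dirs <- matrix(stats::rnorm(3 * ndir), ndir, 3)
    dirs <- dirs / sqrt(rowSums(dirs^2))
    udir <- off[rest, , drop = FALSE] / pmax(dist[rest], 1e-9)
    bonus <- apply(udir %*% t(dirs), 1, max)
    score <- dist[rest] + 1.2 * radius * bonus
    chl <- rest[order(-score, vox[rest])][seq_len(min(n_chl, length(rest)))]
    lab_cell <- rep(.L("M_CYTOSOL"), n)
    lab_cell[vac] <- .L("M_VACUOLE")
    lab_cell[chl] <- .L("M_CHLOROPLAST")
    labels[vox] <- lab_cell
    cells[[next_id]] <- data.frame(
      id = next_id, x = ctr[1], y = ctr[2], z = ctr[3], radius = radius,
      interveinal = interveinal, n_voxels = n
    )
  }
  cells <- do.call(rbind, cells)

  # keep the stomatal mouths open: the voxel layers just inside each pore
  # must remain airspace
  for (s in seq_len(nrow(pores))) {
    mask <- outer((cx - pores[s, "x"])^2, (cy - pores[s, "y"])^2, "+") <= (r_p + 1)^2
    kr <- if (pores[s, "face"] == 1) int_lo + 0:1 else int_hi - 0:1
    for (k in kr) {
      slab <- labels[, , k]
      ids <- cellid[, , k]
      sel <- mask & (slab %in% .mesophyll_labels())
      slab[sel] <- L["IAS"]
      ids[sel] <- 0L
      labels[, , k] <- slab
      cellid[, , k] <- ids
    }
  }

  label_volume(labels, h, cell_instance_ids = cellid, cells = cells,
               params = params)
}

# count faces between voxels whose labels fall in set_a and set_b
.count_faces <- function(labels, set_a, set_b) {
  d <- dim(labels)
  total <- 0
  pairs <- function(a, b) {
    sum((a %in% set_a & b %in% set_b) | (a %in% set_b & b %in% set_a))
  }
  total <- total + pairs(labels[-d[1], , ], labels[-1, , ])
  total <- total + pairs(labels[, -d[2], ], labels[, -1, ])
  total <- total + pairs(labels[, , -d[3]], labels[, , -1])
  total
}

# shift a 3D array by one voxel along an axis with edge replication
.shift3 <- function(a, axis, by) {
  d <- dim(a)
  idx <- pmin(pmax(seq_len(d[axis]) + by, 1L), d[axis])
  switch(axis, a[idx, , , drop = FALSE], a[, idx, , drop = FALSE],
         a[, , idx, drop = FALSE])
}

# 3x3x3 box smoothing (separable)
.box_smooth <- function(a) {
  for (ax in 1:3) {
    a <- (.shift3(a, ax, -1L) + a + .shift3(a, ax, 1L)) / 3
  }
  a
}

# Surface area (in face units of h^2) of the interface between set_a and
# set_b, estimated by weighting each exposed face with the local surface
# normal: a planar patch with unit normal n produces |nx|+|ny|+|nz| faces
# per unit area, so each face contributes 1/(|nx|+|ny|+|nz|). Normals come
# from the gradient of the box-smoothed indicator of set_a; this removes the
# systematic 3/2 (sphere) / 4:pi (cylinder) overestimate of raw counting.
.surface_area_faces <- function(labels, set_a, set_b) {
  d <- dim(labels)
  m <- array(as.numeric(array(as.integer(labels) %in% set_a, dim = d)), dim = d)
  s <- .box_smooth(.box_smooth(m))
  gx <- (.shift3(s, 1, 1L) - .shift3(s, 1, -1L))
  gy <- (.shift3(s, 2, 1L) - .shift3(s, 2, -1L))
  gz <- (.shift3(s, 3, 1L) - .shift3(s, 3, -1L))
  gn <- abs(gx) + abs(gy) + abs(gz)
  gmag <- sqrt(gx^2 + gy^2 + gz^2)
  w <- ifelse(gn > 1e-9, gmag / gn, 2 / 3)
  inA <- array(as.integer(labels) %in% set_a, dim = d)
  inB <- array(as.integer(labels) %in% set_b, dim = d)
  total <- 0
  face_w <- function(a_ia, a_ib, b_ia, b_ib, wa, wb) {
    hit <- (a_ia & b_ib) | (a_ib & b_ia)
    sum(((wa + wb) / 2)[hit])
  }
  total <- total + face_w(inA[-d[1], , ], inB[-d[1], , ], inA[-1, , ],
                          inB[-1, , ], w[-d[1], , ], w[-1, , ])
  total <- total + face_w(inA[, -d[2], ], inB[, -d[2], ], inA[, -1, ],
                          inB[, -1, ], w[, -d[2], ], w[, -1, ])
  total <- total + face_w(inA[, , -d[3]], inB[, , -d[3]], inA[, , -1],
                          inB[, , -1], w[, , -d[3]], w[, , -1])
  total
}

#' Anatomical statistics of a label volume
#'
#' Volume fractions by voxel counting over tissue (air excluded); exposed
#' surfaces by normal-weighted face counting (raw face counting
#' overestimates smooth surfaces, by 3/2 for spheres and 4/pi for
#' axis-aligned cylinders; weighting each face by the local surface normal
#' removes the bias for both); chloroplast volumes per projected leaf area;
#' the interveinal mesophyll fraction; and the respiring-volume fraction
#' `f_resp`.
#'
#' @param vol a [label_volume()].
#' @param surface_correction `NULL` (default) for the normal-weighted
#'   estimator, or a numeric multiplier applied to raw face counts (e.g.
#'   2/3 for the fixed smooth-sphere correction, 1 for raw counting).
#' @return object of class `anatomy_stats`: a list with `volume_fraction`
#'   (named, over tissue), `S_M`, `S_BS` (m2 m-2), `sv_mesophyll`,
#'   `sv_bundle_sheath` (m2 m-3), `chloroplast_volume_m`,
#'   `chloroplast_volume_bs` (m3 m-2), `interveinal_mesophyll_fraction`,
#'   `f_resp`, `S_leaf` (m2), `d` (m), `voxel_volume` (m3).
#' @export
anatomical_stats <- function(vol, surface_correction = NULL) {
  stopifnot(inherits(vol, "label_volume"))
  labs <- vol$labels
  d <- dim(labs)
  h <- vol$voxel_pitch_um * 1e-6
  L <- kranz_labels()
  lab_int <- as.integer(labs)
  counts <- tabulate(lab_int + 1L, nbins = 11L)
  names(counts) <- names(L)
  n_tissue <- sum(counts) - counts["AIR"]
  vf <- if (n_tissue > 0) counts / n_tissue else counts * 0
  vf["AIR"] <- NA_real_
  S_leaf <- d[1] * d[2] * h^2
  area_of <- if (is.null(surface_correction)) {
    function(set_a, set_b) .surface_area_faces(labs, set_a, set_b) * h^2
  } else {
    function(set_a, set_b) {
      .count_faces(labs, set_a, set_b) * surface_correction * h^2
    }
  }

  m_set <- .mesophyll_labels()
  bs_set <- .bs_labels()
  S_M <- area_of(m_set, .L("IAS")) / S_leaf
  S_BS <- area_of(bs_set,
                  c(m_set, .L(c("IAS", "EPIDERMIS", "STOMATAL_PORE")))) /
    S_leaf
  surf_m <- area_of(m_set, setdiff(unname(L), m_set))
  surf_bs <- area_of(bs_set, setdiff(unname(L), bs_set))
  vol_m <- sum(counts[c("M_CYTOSOL", "M_VACUOLE", "M_CHLOROPLAST")]) * h^3
  vol_bs <- sum(counts[c("BS_CYTOSOL", "BS_VACUOLE", "BS_CHLOROPLAST")]) * h^3

  iv_frac <- NA_real_
  if (!is.null(vol$cells) && !is.null(vol$cell_instance_ids) &&
      nrow(vol$cells) > 0) {
    per_cell <- tabulate(vol$cell_instance_ids[vol$cell_instance_ids > 0],
                         nbins = max(vol$cells$id))
    iv_frac <- sum(per_cell[vol$cells$id[vol$cells$interveinal]]) /
      max(sum(per_cell), 1)
  }

  n_z_tissue <- sum(apply(labs != L["AIR"], 3, any))
  structure(list(
    volume_fraction = vf,
    S_M = S_M,
    S_BS = S_BS,
    sv_mesophyll = if (vol_m > 0) surf_m / vol_m else 0,
    sv_bundle_sheath = if (vol_bs > 0) surf_bs / vol_bs else 0,
    chloroplast_volume_m = counts["M_CHLOROPLAST"] * h^3 / S_leaf,
    chloroplast_volume_bs = counts["BS_CHLOROPLAST"] * h^3 / S_leaf,
    interveinal_mesophyll_fraction = iv_frac,
    f_resp = sum(vf[c("VASCULAR", "EPIDERMIS", "M_CYTOSOL", "BS_CYTOSOL")]),
    S_leaf = S_leaf,
    d = n_z_tissue * h,
    voxel_volume = h^3,
    counts = counts
  ), class = "anatomy_stats")
}

#' @export
print.anatomy_stats <- function(x, ...) {
  cat("<anatomy_stats>\n")
  cat(sprintf("  S_M  = %.2f m2/m2, S_BS = %.2f m2/m2, d = %.1f um\n",
              x$S_M, x$S_BS, x$d * 1e6))
  cat(sprintf("  IAS fraction = %.1f%%, f_resp = %.3f\n",
              100 * x$volume_fraction["IAS"], x$f_resp))
  cat(sprintf("  chloroplast volume per leaf area: M %.1f, BS %.1f um3/um2\n",
              1e6 * x$chloroplast_volume_m, 1e6 * x$chloroplast_volume_bs))
  invisible(x)
}

# relocate the chloroplasts of the given mesophyll cells into the cell shell
# nearest the mesophyll-bundle sheath contact surface (the plasmodesmatal
# zones), conserving every class count per cell exactly
.relocate_chloroplasts <- function(vol, ids) {
  labs <- vol$labels
  d <- dim(labs)
  cid <- vol$cell_instance_ids
  # seed voxels: mesophyll voxels sharing a face with the bundle sheath
  lab_arr <- array(as.integer(labs), dim = d)
  in_m <- array(lab_arr %in% .mesophyll_labels(), dim = d)
  in_bs <- array(lab_arr %in% .bs_labels(), dim = d)
  adj <- array(FALSE, dim = d)
  for (ax in 1:3) {
    adj <- adj | (in_m & .shift3(in_bs, ax, 1L)) |
      (in_m & .shift3(in_bs, ax, -1L))
  }
  seeded <- lab_arr
  seeded[adj] <- 11L  # sentinel label marking the contact surface
  dist <- bfs_distance_cpp(as.vector(seeded), d, 11L)
  sel <- which(cid > 0 & array(cid %in% ids, dim = d))
  by_cell <- split(sel, cid[sel])
  moved <- 0L
  for (vox in by_cell) {
    cur <- labs[vox]
    q <- sum(cur == .L("M_CHLOROPLAST"))
    if (q == 0) next
    rank <- order(dist[vox], vox)
    new_chl <- vox[rank[seq_len(q)]]
    old_chl <- vox[cur == .L("M_CHLOROPLAST")]
    freed <- setdiff(old_chl, new_chl)
    taken <- setdiff(new_chl, old_chl)
    n_vac_taken <- sum(labs[taken] == .L("M_VACUOLE"))
    labs[taken] <- .L("M_CHLOROPLAST")
    if (length(freed)) {
      co <- .voxel_coords(freed, d)
      ctr <- colMeans(.voxel_coords(vox, d))
      dd <- sqrt(rowSums(sweep(co, 2, ctr)^2))
      ordf <- order(dd, freed)
      vac_new <- freed[ordf[seq_len(min(n_vac_taken, length(freed)))]]
      cyt_new <- setdiff(freed, vac_new)
      labs[vac_new] <- .L("M_VACUOLE")
      labs[cyt_new] <- .L("M_CYTOSOL")
    }
    moved <- moved + q
  }
  out <- vol
  out$labels <- labs
  attr(out, "moved_chloroplast_voxels") <- moved
  out
}

#' Aggregative chloroplast movement
#'
#' Relocates the chloroplasts of every mesophyll cell into the shell of the
#' cell nearest the bundle sheath (the construction dilates the
#' bundle-sheath domain through the tissue, intersects it with each cell,
#' and fills the intersection to the cell's chloroplast quota). Per-cell
#' chloroplast volume and every non-chloroplast class count are conserved
#' exactly; bundle-sheath chloroplasts are unaffected.
#'
#' @param vol a [label_volume()] with `cell_instance_ids`.
#' @param tolerance allowed relative change of per-cell chloroplast volume
#'   (the construction conserves counts exactly; the check guards custom
#'   volumes).
#' @return transformed [label_volume()] with attribute
#'   `moved_chloroplast_voxels`.
#' @export
apply_aggregative_movement <- function(vol, tolerance = 0.1) {
  stopifnot(inherits(vol, "label_volume"))
  if (is.null(vol$cell_instance_ids)) {
    stop("cell_instance_ids required to identify mesophyll cells")
  }
  before <- sum(vol$labels == .L("M_CHLOROPLAST"))
  ids <- sort(unique(vol$cell_instance_ids[vol$cell_instance_ids > 0]))
  out <- .relocate_chloroplasts(vol, ids)
  after <- sum(out$labels == .L("M_CHLOROPLAST"))
  if (before > 0 && abs(after / before - 1) > tolerance) {
    stop("chloroplast volume conservation failed beyond tolerance")
  }
  attr(out, "scenario") <- "aggregative"
  out
}

#' Interveinal mesophyll cells of a volume
#'
#' A mesophyll cell is interveinal when the lateral distance from its
#' centroid to the nearest vein axis exceeds the bundle-sheath outer radius
#' plus one mesophyll cell diameter.
#'
#' @param vol a [label_volume()] produced by [generate_kranz_geometry()].
#' @return data.frame of interveinal cell metadata.
#' @export
interveinal_cells <- function(vol) {
  if (is.null(vol$cells)) stop("volume carries no cell metadata")
  p <- vol$params
  if (!is.null(p)) {
    h <- p$voxel_pitch_um
    nx <- p$grid_dims[1]
    vein_x <- nx / 2 + (seq_len(p$vein_count) - (p$vein_count + 1) / 2) *
      p$vein_spacing_um / h
    thr <- (p$bundle_sheath_radius_um + 2 * p$mesophyll_cell_radius_um) / h
    lat <- vapply(vol$cells$x, function(x) min(abs(x - vein_x)), 0)
    vol$cells[lat > thr, , drop = FALSE]
  } else {
    vol$cells[vol$cells$interveinal, , drop = FALSE]
  }
}

#' Avoidance chloroplast movement
#'
#' Applies the same shell construction as [apply_aggregative_movement()] but
#' only to interveinal mesophyll cells (those lying between veins); all
#' other labels are unchanged.
#'
#' @inheritParams apply_aggregative_movement
#' @return transformed [label_volume()] with attributes
#'   `moved_chloroplast_voxels` and `scenario`.
#' @export
apply_avoidance_movement <- function(vol, tolerance = 0.1) {
  stopifnot(inherits(vol, "label_volume"))
  if (is.null(vol$cell_instance_ids)) {
    stop("cell_instance_ids required to identify mesophyll cells")
  }
  iv <- interveinal_cells(vol)
  if (nrow(iv) == 0) stop("no interveinal mesophyll cells found")
  before <- sum(vol$labels == .L("M_CHLOROPLAST"))
  out <- .relocate_chloroplasts(vol, iv$id)
  after <- sum(out$labels == .L("M_CHLOROPLAST"))
  if (before > 0 && abs(after / before - 1) > tolerance) {
    stop("chloroplast volume conservation failed beyond tolerance")
  }
  attr(out, "scenario") <- "avoidance"
  out
}

#' Write a label volume as a multi-page TIFF with a JSON sidecar
#'
#' One 8-bit page per z-slice; cell instance ids, when present, go to a
#' 16-bit companion stack. The sidecar records the voxel pitch, dimensions
#' and label vocabulary so the round trip is lossless.
#'
#' @param vol a [label_volume()].
#' @param path output TIFF path; the sidecar replaces the extension with
#'   `.json`.
#' @return `path`, invisibly.
#' @export
write_label_volume <- function(vol, path) {
  stopifnot(inherits(vol, "label_volume"))
  d <- dim(vol$labels)
  pages <- lapply(seq_len(d[3]), function(k) vol$labels[, , k] / 255)
  tiff::writeTIFF(pages, path, bits.per.sample = 8L)
  sidecar <- sub("\\.tiff?$", ".json", path)
  if (sidecar == path) sidecar <- paste0(path, ".json")
  meta <- list(voxel_pitch_um = vol$voxel_pitch_um, dims = d,
               labels = as.list(kranz_labels()),
               has_cell_ids = !is.null(vol$cell_instance_ids))
  if (meta$has_cell_ids) {
    idpath <- sub("\\.tiff?$", "_cells.tif", path)
    if (idpath == path) idpath <- paste0(path, "_cells.tif")
    idpages <- lapply(seq_len(d[3]),
                      function(k) vol$cell_instance_ids[, , k] / 65535)
    tiff::writeTIFF(idpages, idpath, bits.per.sample = 16L)
    meta$cell_id_file <- basename(idpath)
  }
  if (!is.null(vol$cells)) meta$cells <- vol$cells
  jsonlite::write_json(meta, sidecar, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Read a label volume written by [write_label_volume()]
#'
#' @param path TIFF path.
#' @return a [label_volume()].
#' @export
read_label_volume <- function(path) {
  sidecar <- sub("\\.tiff?$", ".json", path)
  if (sidecar == path) sidecar <- paste0(path, ".json")
  if (!file.exists(sidecar)) stop("missing JSON sidecar: ", sidecar)
  meta <- jsonlite::read_json(sidecar, simplifyVector = TRUE)
  pages <- tiff::readTIFF(path, all = TRUE, as.is = TRUE)
  d <- c(dim(pages[[1]]), length(pages))
  labels <- array(0L, dim = d)
  for (k in seq_along(pages)) labels[, , k] <- pages[[k]]
  bad <- setdiff(unique(as.integer(labels)), unlist(meta$labels))
  if (length(bad) > 0) {
    stop("label(s) outside vocabulary: ", paste(bad, collapse = ", "))
  }
  cid <- NULL
  if (isTRUE(meta$has_cell_ids)) {
    idpath <- file.path(dirname(path), meta$cell_id_file)
    idpages <- tiff::readTIFF(idpath, all = TRUE, as.is = TRUE)
    cid <- array(0L, dim = d)
    for (k in seq_along(idpages)) cid[, , k] <- idpages[[k]]
  }
  cells <- if (!is.null(meta$cells)) as.data.frame(meta$cells) else NULL
  label_volume(labels, meta$voxel_pitch_um, cell_instance_ids = cid,
               cells = cells)
}

#' Export a 3D scalar field or label volume as a legacy-VTK image
#'
#' ASCII STRUCTURED_POINTS file readable by ParaView, for visualization.
#'
#' @param x a [label_volume()] or a 3D numeric array.
#' @param path output file path.
#' @param spacing voxel pitch in um (taken from `x` when it is a volume).
#' @param name the scalar array name.
#' @return `path`, invisibly.
#' @export
write_vtk_image <- function(x, path, spacing = NULL, name = "field") {
  if (inherits(x, "label_volume")) {
    spacing <- x$voxel_pitch_um
    arr <- x$labels
    name <- "label"
  } else {
    arr <- x
    if (is.null(spacing)) spacing <- 1
  }
  d <- dim(arr)
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c("# vtk DataFile Version 3.0", "kranzsim field", "ASCII",
               "DATASET STRUCTURED_POINTS",
               sprintf("DIMENSIONS %d %d %d", d[1], d[2], d[3]),
               "ORIGIN 0 0 0",
               sprintf("SPACING %g %g %g", spacing, spacing, spacing),
               sprintf("POINT_DATA %d", prod(d)),
               sprintf("SCALARS %s float 1", name),
               "LOOKUP_TABLE default"), con)
  writeLines(format(as.vector(arr), trim = TRUE), con)
  invisible(path)
}

#' Flag intercellular-airspace regions not connected to any stoma
#'
#' Orphan airspace pockets cannot exchange gas with the atmosphere (a known
#' hazard of 2D slices); the transport solver still handles them, but a
#' warning with the region count is emitted here.
#'
#' @param vol a [label_volume()].
#' @return integer count of orphan IAS regions, invisibly; warns when > 0.
#' @export
check_ias_connectivity <- function(vol) {
  labs <- vol$labels
  d <- dim(labs)
  gas <- array(as.integer(labs) %in% .gas_labels(), dim = d)
  comp <- connected_components_cpp(as.vector(gas), d)
  comp <- array(comp, dim = d)
  air_comps <- unique(comp[labs == .L("AIR")])
  ias_comps <- unique(comp[labs == .L("IAS")])
  orphans <- setdiff(ias_comps, air_comps)
  if (length(orphans) > 0) {
    warning(sprintf("%d IAS region(s) not connected to any stoma",
                    length(orphans)))
  }
  invisible(length(orphans))
}
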