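test_that("generation is deterministic for a fixed seed", {
  p <- small_geometry_params()
  a <- generate_kranz_geometry(p)
  b <- generate_kranz_geometry(p)
  expect_identical(a$labels, b$labels)
  expect_identical(a$cell_instance_ids, b$cell_instance_ids)
  c2 <- generate_kranz_geometry(small_geometry_params(rng_seed = 99L))
  expect_false(identical(a$labels, c2$labels))
})

test_that("invalid parameters raise sizing errors", {
  expect_error(geometry_params(vein_count = 0) |> generate_kranz_geometry(),
               "sizing")
  expect_error(generate_kranz_geometry(
    geometry_params(grid_dims = c(16L, 16L, 84L))), "sizing")
  expect_error(geometry_params(vacuole_volume_fraction = 1.2))
  expect_error(geometry_params(mesophyll_cell_radius_um = -1))
  expect_error(geometry_params(chloroplast_volume_fraction_bs = 0.9))
})

test_that("every voxel carries a known label and a stoma connects air to IAS", {
  vol <- small_volume()
  expect_true(all(as.integer(vol$labels) %in% unname(kranz_labels())))
  L <- kranz_labels()
  expect_gt(sum(vol$labels == L["STOMATAL_PORE"]), 0)
  # gas phase connected from the outside air into the airspace
  d <- dim(vol$labels)
  gas <- as.integer(vol$labels) %in% L[c("AIR", "STOMATAL_PORE", "IAS")]
  comp <- array(kranzsim:::connected_components_cpp(gas, d), dim = d)
  air_comp <- unique(comp[vol$labels == L["AIR"]])
  ias_comp <- unique(comp[vol$labels == L["IAS"]])
  expect_true(length(intersect(air_comp, ias_comp)) > 0)
})

test_that("bundle-sheath chloroplasts form the centrifugal (outer) layer", {
  vol <- small_volume()
  L <- kranz_labels()
  d <- dim(vol$labels)
  idx <- which(vol$labels == L["BS_CHLOROPLAST"])
  i <- (idx - 1) %% d[1] + 1
  k <- (idx - 1) %/% (d[1] * d[2]) + 1
  r_chl <- sqrt((i - 0.5 - d[1] / 2)^2 + (k - 0.5 - d[3] / 2)^2)
  idx2 <- which(vol$labels == L["BS_VACUOLE"])
  i2 <- (idx2 - 1) %% d[1] + 1
  k2 <- (idx2 - 1) %/% (d[1] * d[2]) + 1
  r_vac <- sqrt((i2 - 0.5 - d[1] / 2)^2 + (k2 - 0.5 - d[3] / 2)^2)
  expect_gt(mean(r_chl), mean(r_vac))
})

test_that("anatomical statistics behave on degenerate volumes", {
  L <- kranz_labels()
  allias <- label_volume(array(L[["IAS"]], dim = c(8, 8, 8)), 2)
  st <- anatomical_stats(allias)
  expect_equal(st$S_M, 0)
  expect_equal(unname(st$volume_fraction["IAS"]), 1)
  expect_equal(st$f_resp, 0)
})

test_that("surface estimator is unbiased for sphere and cylinder phantoms", {
  L <- kranz_labels()
  d <- c(44L, 44L, 44L)
  co <- (1:44) - 0.5
  h <- 2e-6
  # sphere, radius 10 voxels
  a <- array(L[["IAS"]], dim = d)
  R2 <- outer(outer((co - 22)^2, (co - 22)^2, "+"), (co - 22)^2, "+")
  a[R2 <= 100] <- L[["M_CYTOSOL"]]
  sph <- label_volume(a, 2)
  st <- anatomical_stats(sph)
  area <- st$S_M * st$S_leaf   # all mesophyll surface faces IAS here
  expect_equal(area, 4 * pi * (10 * h)^2, tolerance = 0.03)
  # axis-aligned cylinder, radius 10 voxels
  a <- array(L[["IAS"]], dim = d)
  m <- outer((co - 22)^2, (co - 22)^2, "+") <= 100
  for (k in 1:44) { s <- a[, , k]; s[m] <- L[["M_CYTOSOL"]]; a[, , k] <- s }
  cyl <- label_volume(a, 2)
  stc <- anatomical_stats(cyl)
  # lateral surface only (caps touch the domain boundary)
  expect_equal(stc$S_M * stc$S_leaf, 2 * pi * (10 * h) * (44 * h),
               tolerance = 0.03)
  # the fixed 2/3 correction overestimates the cylinder (sanity contrast)
  st_fixed <- anatomical_stats(cyl, surface_correction = 2 / 3)
  expect_gt(abs(st_fixed$S_M / stc$S_M - 1), 0.05)
})

test_that("reference anatomy reproduces the measured maize statistics", {
  st <- anatomical_stats(reference_volume())
  expect_equal(100 * unname(st$volume_fraction["IAS"]), 22.3,
               tolerance = 0.15)
  expect_equal(st$S_M, 12, tolerance = 0.15)
  expect_equal(st$S_BS, 1.9, tolerance = 0.15)
  expect_equal(1e6 * unname(st$chloroplast_volume_m), 13, tolerance = 0.15)
  expect_equal(1e6 * unname(st$chloroplast_volume_bs), 15, tolerance = 0.15)
})

test_that("aggregative movement conserves every class and targets the sheath", {
  vol <- small_volume()
  agg <- apply_aggregative_movement(vol)
  t0 <- table(factor(as.integer(vol$labels), levels = 0:10))
  t1 <- table(factor(as.integer(agg$labels), levels = 0:10))
  expect_equal(as.integer(t1), as.integer(t0))   # exact, every class
  L <- kranz_labels()
  expect_identical(which(agg$labels == L["BS_CHLOROPLAST"]),
                   which(vol$labels == L["BS_CHLOROPLAST"]))
  # chloroplasts end up nearer the sheath than before
  dist <- array(kranzsim:::bfs_distance_cpp(as.integer(vol$labels),
                                            dim(vol$labels),
                                            kranzsim:::.bs_labels()),
                dim = dim(vol$labels))
  expect_lt(mean(dist[agg$labels == L["M_CHLOROPLAST"]]),
            mean(dist[vol$labels == L["M_CHLOROPLAST"]]))
})

test_that("avoidance movement touches only interveinal cells", {
  vol <- small_volume()
  avd <- apply_avoidance_movement(vol)
  iv <- interveinal_cells(vol)
  expect_gt(nrow(iv), 0)
  changed <- which(avd$labels != vol$labels)
  ids_changed <- unique(vol$cell_instance_ids[changed])
  expect_true(all(ids_changed %in% iv$id))
  t0 <- table(factor(as.integer(vol$labels), levels = 0:10))
  t1 <- table(factor(as.integer(avd$labels), levels = 0:10))
  expect_equal(as.integer(t1), as.integer(t0))
})

test_that("a volume without mesophyll chloroplasts is left unchanged", {
  vol <- small_volume()
  L <- kranz_labels()
  vol2 <- vol
  vol2$labels[vol2$labels == L["M_CHLOROPLAST"]] <- L[["M_CYTOSOL"]]
  agg <- apply_aggregative_movement(vol2)
  expect_identical(agg$labels, vol2$labels)
})

test_that("TIFF round trip is lossless and validates labels", {
  vol <- small_volume()
  tmp <- file.path(tempdir(), "vol_test.tif")
  write_label_volume(vol, tmp)
  back <- read_label_volume(tmp)
  expect_identical(back$labels, array(as.integer(vol$labels),
                                      dim = dim(vol$labels)))
  expect_identical(back$cell_instance_ids,
                   array(as.integer(vol$cell_instance_ids),
                         dim = dim(vol$labels)))
  expect_equal(back$voxel_pitch_um, vol$voxel_pitch_um)
  # page count equals nz
  pages <- tiff::readTIFF(tmp, all = TRUE)
  expect_equal(length(pages), dim(vol$labels)[3])
  # corrupt a label beyond the vocabulary
  bad <- vol$labels / 255
  bad[1, 1, 1] <- 200 / 255
  tiff::writeTIFF(lapply(seq_len(dim(bad)[3]), function(k) bad[, , k]),
                  tmp, bits.per.sample = 8L)
  expect_error(read_label_volume(tmp), "vocabulary")
  unlink(c(tmp, sub("\\.tif$", ".json", tmp),
           sub("\\.tif$", "_cells.tif", tmp)))
})

test_that("VTK export writes a well-formed header", {
  vol <- small_volume()
  tmp <- file.path(tempdir(), "vol_test.vtk")
  write_vtk_image(vol, tmp)
  head <- readLines(tmp, n = 10)
  expect_match(head[1], "vtk DataFile")
  d <- dim(vol$labels)
  expect_match(head[5], sprintf("DIMENSIONS %d %d %d", d[1], d[2], d[3]))
  unlink(tmp)
})
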