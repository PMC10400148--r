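# Transport tests run on the coarse "small" geometry for speed; the
# desk-scale reference geometry is exercised in the acceptance suite.

test_that("uniform gas medium gives the textbook face conductance", {
  L <- kranz_labels()
  vol <- label_volume(array(L[["IAS"]], dim = c(4, 4, 4)), 2)
  sys <- assemble_system(vol, species = "co2")
  k <- physical_constants()
  h <- 2e-6
  g_expect <- h^2 * (1.57e-5 / k$henry_co2) / h
  expect_equal(sys$co2$gx[1, 1, 1], g_expect, tolerance = 1e-12)
  expect_equal(sys$co2$gz[2, 3, 2], g_expect, tolerance = 1e-12)
  expect_equal(sys$co2$gx[4, 1, 1], 0)  # boundary slot unused
})

test_that("serial membrane resistance matches the 1D resistor network", {
  # column: 10 mesophyll-cytosol voxels over 10 bundle-sheath-cytosol voxels;
  # flux between the ends must equal the closed-form serial conductance
  L <- kranz_labels()
  nz <- 20
  labs <- array(L[["M_CYTOSOL"]], dim = c(1, 1, nz))
  labs[, , 11:20] <- L[["BS_CYTOSOL"]]
  ids <- array(1L, dim = dim(labs))
  vol <- label_volume(labs, 2, cell_instance_ids = ids)
  tp <- transport_params()
  sys <- assemble_system(vol, tp, species = "co2")
  d <- dim(labs)
  fixed <- array(FALSE, dim = d); fixed[, , c(1, nz)] <- TRUE
  fv <- array(0, dim = d); fv[, , 1] <- 1
  r <- kranzsim:::cg_solve_cpp(d, as.numeric(sys$co2$gx),
                               as.numeric(sys$co2$gy), as.numeric(sys$co2$gz),
                               numeric(prod(d)), numeric(prod(d)),
                               as.logical(fixed), as.numeric(fv),
                               as.numeric(fv), 1e-14, 10000)
  x <- array(r$x, dim = d)
  flux <- sys$co2$gz[1, 1, 1] * (x[1, 1, 1] - x[1, 1, 2])
  h <- 2e-6
  Dliq <- tp$D_co2_liquid / tp$eta
  R_pd <- tp$t_plasmodesma / (Dliq * tp$zeta_plasmodesmata)
  # 19 plain half-pairs plus the plasmodesmatal interface in the middle
  R_total <- 19 * h / Dliq + R_pd
  expect_equal(flux, h^2 * 1 / R_total, tolerance = 1e-8)
})

test_that("zero sources with a uniform boundary give the constant field", {
  vol <- small_volume()
  en <- .zero_energetics(vol)
  res <- solve_steady_state(vol, en,
                            kp = kinetic_params(R_d = 1e-12, k1 = 1e-12),
                            pore_scale = 1, maxit = 60)
  amb <- ppm_to_liquid(380)
  expect_equal(max(abs(res$co2 - amb)) / amb, 0, tolerance = 1e-4)
  expect_equal(res$A_n, 0, tolerance = 1e-3)
})

test_that("a dark leaf respires at exactly R_d", {
  vol <- small_volume()
  en <- .zero_energetics(vol)
  res <- solve_steady_state(vol, en, pore_scale = NULL, maxit = 120)
  # respiration integrates to R_d by construction, so A_n = -R_d
  expect_equal(res$A_n, -1.70, tolerance = 0.01)
  expect_lt(max(res$mass_balance), 1e-6)
  expect_true(res$converged)
})

test_that("stomatal calibration hits the target and is monotone", {
  vol <- small_volume()
  tp <- transport_params()
  cal <- calibrate_stomatal_diffusivity(vol, tp, g_s_target = 0.2)
  expect_equal(cal$g_s_achieved, 0.2, tolerance = 0.01)
  cal2 <- calibrate_stomatal_diffusivity(vol, tp, g_s_target = 0.4)
  expect_equal(cal2$g_s_achieved, 0.4, tolerance = 0.01)
  expect_gt(cal2$pore_scale, cal$pore_scale)
  expect_error(calibrate_stomatal_diffusivity(vol, tp, g_s_target = 1e6),
               "unreachable")
})

test_that("the lit small leaf concentrates CO2 in the bundle sheath", {
  res <- .small_lit_run()
  expect_true(res$converged)
  expect_gt(res$A_n, 5)
  expect_gt(res$C_c, res$C_i)           # the CCM at work
  expect_lt(res$C_i, 380)               # stomatal drawdown
  expect_lt(max(res$mass_balance), 1e-6)
  expect_gt(res$Phi, 0)
  expect_lt(res$Phi, 1)
  # bundle-sheath O2 rises above ambient behind the suberized wall
  k <- physical_constants()
  expect_gt(res$O_bs_chl, ppm_to_liquid(210e3, k$henry_o2))
})

test_that("net photosynthesis equals the negative source integral", {
  res <- .small_lit_run()
  expect_lt(res$mass_balance[["co2"]], 1e-6)
  expect_equal(net_photosynthesis(res), res$A_n)
})

test_that("leakiness arithmetic and edge cases", {
  lk <- leakiness(60, 40, 1)
  expect_equal(lk$L, 19)
  expect_equal(lk$Phi, 19 / 60, tolerance = 1e-12)
  expect_equal(leakiness(50, 49, 1)$Phi, 0)
  expect_equal(leakiness(50, -1, 1)$Phi, 1)
  expect_error(leakiness(0, 10, 1), "undefined")
})

test_that("sparse matrix view agrees with the matrix-free kernel", {
  L <- kranz_labels()
  labs <- array(L[["M_CYTOSOL"]], dim = c(4, 3, 5))
  labs[, , 1] <- L[["IAS"]]
  vol <- label_volume(labs, 2,
                      cell_instance_ids = array(1L, dim = dim(labs)))
  sys <- assemble_system(vol, species = "co2")
  n <- prod(dim(labs))
  A <- species_matrix(sys, "co2", diag_extra = rep(1e-15, n))
  set.seed(8)
  x <- runif(n)
  y_mat <- as.numeric(A %*% x)
  r <- kranzsim:::cg_solve_cpp(dim(labs), as.numeric(sys$co2$gx),
                               as.numeric(sys$co2$gy), as.numeric(sys$co2$gz),
                               rep(1e-15, n), y_mat,
                               rep(FALSE, n), numeric(n), numeric(n),
                               1e-13, 5000)
  expect_equal(as.numeric(r$x), x, tolerance = 1e-8)
})

test_that("the coupled two-species kernel matches a dense reference solve", {
  set.seed(1)
  d <- c(5L, 4L, 6L); n <- prod(d)
  mk <- function() { g <- array(runif(n, 0.5, 2) * 1e-14, dim = d)
    g[d[1], , ] <- 0; g }
  mky <- function() { g <- array(runif(n, 0.5, 2) * 1e-14, dim = d)
    g[, d[2], ] <- 0; g }
  mkz <- function() { g <- array(runif(n, 0.5, 2) * 1e-14, dim = d)
    g[, , d[3]] <- 0; g }
  gxC <- mk(); gyC <- mky(); gzC <- mkz()
  gxB <- mk(); gyB <- mky(); gzB <- mkz()
  aV <- runif(n, 0, 5e-13); dV <- runif(n, 0, 5e-13)
  dCC <- aV + runif(n, 0, 1e-15); dBB <- dV + runif(n, 0, 1e-15)
  dCB <- -dV; dBC <- -aV
  fixedC <- rep(FALSE, n); fixedC[1:6] <- TRUE
  fixedB <- rep(FALSE, n); fixedB[1:4] <- TRUE
  fxC <- runif(n) * fixedC; fxB <- runif(n) * fixedB
  rhsC <- rnorm(n) * 1e-15; rhsB <- rnorm(n) * 1e-15
  res <- kranzsim:::coupled_solve_cpp(d, gxC, gyC, gzC, gxB, gyB, gzB,
    dCC, dCB, dBC, dBB, rhsC, rhsB, fixedC, fixedB, fxC, fxB,
    numeric(n), numeric(n), 1e-13, 10000)
  lap <- function(gx, gy, gz) {
    A <- matrix(0, n, n)
    idx <- array(seq_len(n), dim = d)
    add <- function(A, g, from, to) {
      gv <- as.numeric(g)[as.vector(from)]
      fr <- as.vector(from); to2 <- as.vector(to)
      for (m in seq_along(gv)) {
        i <- fr[m]; j <- to2[m]
        A[i, j] <- A[i, j] - gv[m]; A[j, i] <- A[j, i] - gv[m]
        A[i, i] <- A[i, i] + gv[m]; A[j, j] <- A[j, j] + gv[m]
      }
      A
    }
    A <- add(A, gx, idx[-d[1], , ], idx[-1, , ])
    A <- add(A, gy, idx[, -d[2], ], idx[, -1, ])
    add(A, gz, idx[, , -d[3]], idx[, , -1])
  }
  either <- fixedC | fixedB
  dCB2 <- ifelse(either, 0, dCB); dBC2 <- ifelse(either, 0, dBC)
  M <- rbind(cbind(lap(gxC, gyC, gzC) + diag(as.numeric(dCC)),
                   diag(as.numeric(dCB2))),
             cbind(diag(as.numeric(dBC2)),
                   lap(gxB, gyB, gzB) + diag(as.numeric(dBB))))
  rhs <- c(rhsC, rhsB)
  fixed <- c(fixedC, fixedB); fx <- c(fxC, fxB)
  M[fixed, ] <- 0; M[cbind(which(fixed), which(fixed))] <- 1
  rhs[fixed] <- fx[fixed]
  sol <- solve(M, rhs)
  expect_equal(c(res$C, res$B), as.numeric(sol), tolerance = 1e-9)
})
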