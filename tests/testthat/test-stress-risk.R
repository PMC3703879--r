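test_that("principal stresses match closed forms and the eigen oracle", {
  expect_equal(unname(principalStresses(diag(c(3, 1, -2)))), c(3, 1, -2))
  ## pure shear tau in xy: (tau, 0, -tau)
  tau <- 5
  S <- matrix(0, 3, 3); S[1, 2] <- S[2, 1] <- tau
  expect_equal(unname(principalStresses(S)), c(tau, 0, -tau), tolerance = 1e-12)
  ## random symmetric tensors vs base eigen()
  set.seed(21)
  V <- matrix(rnorm(200 * 6, sd = 50), 200, 6)
  P <- principalStresses(V)
  for (i in seq_len(50)) {
    M <- matrix(c(V[i, 1], V[i, 4], V[i, 6],
                  V[i, 4], V[i, 2], V[i, 5],
                  V[i, 6], V[i, 5], V[i, 3]), 3, 3)
    expect_equal(unname(P[i, ]), sort(eigen(M, symmetric = TRUE,
                                            only.values = TRUE)$values,
                                      decreasing = TRUE), tolerance = 1e-9)
  }
  expect_error(principalStresses(matrix(c(1, 2, 3, 0, 1, 0, 0, 0, 1), 3, 3)),
               "symmetric")
})

test_that("sigmaC / sigmaT clamp at zero as defined", {
  ct <- sigmaCT(c(3, 1, -2))
  expect_equal(ct$sigma_C, -2)
  expect_equal(ct$sigma_T, 3)
  expect_equal(sigmaCT(c(5, 5, 5)), list(sigma_C = 0, sigma_T = 5))
  expect_equal(sigmaCT(c(-5, -5, -5)), list(sigma_C = -5, sigma_T = 0))
  ## whenever all principal stresses share a sign, sigmaT * (-sigmaC) = 0
  set.seed(4)
  for (i in 1:50) {
    s <- sort(rnorm(3), decreasing = TRUE)
    if (s[1] * s[3] > 0) {
      ct <- sigmaCT(s)
      expect_equal(ct$sigma_T * (-ct$sigma_C), 0)
    }
  }
})

test_that("the Von Mises stress has its invariance properties", {
  expect_equal(vonMises(diag(c(5, 0, 0))), 5)
  expect_equal(vonMises(diag(c(-7, -7, -7))), 0)
  tau <- 3
  S <- matrix(0, 3, 3); S[1, 2] <- S[2, 1] <- tau
  expect_equal(vonMises(S), sqrt(3) * tau, tolerance = 1e-12)
  ## hydrostatic shift invariance
  set.seed(5)
  v <- rnorm(6, sd = 10)
  v2 <- v; v2[1:3] <- v2[1:3] + 42
  expect_equal(vonMises(matrix(v, 1)), vonMises(matrix(v2, 1)),
               tolerance = 1e-9)
})

test_that("the overloading risk index matches the strength limits", {
  lim <- defaultStrengthLimits()
  expect_equal(lim$cortical@sigma_T0_MPa, 180)
  expect_equal(lim$cortical@sigma_C0_MPa, 115)
  expect_equal(lim$trabecular@sigma_T0_MPa, 5)
  expect_equal(riskIndex(-115, 0, lim$cortical), 1)
  expect_equal(riskIndex(0, 0, lim$cortical), 0)
  expect_equal(riskIndex(-2.5, 2.5, lim$trabecular), 1)
  expect_error(strengthLimits(-1, 5, "x"))
})

test_that("control regions have the stated thickness and equal thirds", {
  tiny <- tinySolve()
  reg <- tiny$regions
  expect_equal(reg@delta_mm, 0.25 * 3.6) # 0.9 mm
  ## the two split planes cut the trabecular span into equal thirds
  mem <- reg@membership
  z <- reg@pts[, 3]
  z_top <- max(z[mem >= 2])
  iface <- tiny$mesh@faceGroups$bone_implant_interface
  apex <- min(tiny$mesh@nodes[unique(as.vector(iface[, 1:3])), 3])
  z_bot <- min(apex, min(z[mem >= 2]))
  expect_equal(reg@split_z[1] - reg@split_z[2], (z_top - z_bot) / 3,
               tolerance = 1e-9)
  expect_equal(z_top - reg@split_z[1], (z_top - z_bot) / 3, tolerance = 1e-9)
  ## membership distances audited against a brute-force oracle on a sample
  set.seed(9)
  members <- which(mem > 0)
  take <- sample(members, 25)
  d_or <- oracleTriDistance(tiny$mesh@nodes, iface[, 1:3, drop = FALSE],
                            reg@pts[take, , drop = FALSE])
  ## the sampling oracle overestimates slightly; the C++ distance is exact
  expect_true(all(reg@dist[take] <= d_or + 1e-9))
  expect_true(all(abs(reg@dist[take] - d_or) < 0.05))
  expect_true(all(reg@dist[take] <= reg@delta_mm + 1e-9))
})

test_that("region statistics aggregate pointwise, volume-weighted", {
  ## hand-built two-point control region
  sig <- matrix(0, 2, 24)
  sig[1, c(1, 7, 13, 19)] <- 1   # sigma_xx = 1 at all 4 points of elem 1
  sig[2, c(1, 7, 13, 19)] <- 3
  st <- new("StressField", sigma = sig, wdet = matrix(0.25, 2, 4),
            pts = matrix(0, 2, 12), regionTag = c("cortical", "cortical"),
            quadrature = "tet10-4pt")
  reg <- new("ControlRegions", delta_mm = 1,
             membership = rep(1L, 8), split_z = c(NA_real_, NA_real_),
             weights = rep(0.25, 8), dist = rep(0, 8), pts = matrix(0, 8, 3))
  rep <- regionStats(st, reg)
  tb <- rep@table
  expect_equal(tb$mean[tb$measure == "sigma_T"], 2)
  expect_equal(tb$peak[tb$measure == "sigma_T"], 3)
  expect_equal(tb$mean[tb$measure == "sigma_vm"], 2)
  ## uniform field: mean equals peak
  sigu <- matrix(rep(c(2, 0, 0, 0, 0, 0), 4), 2, 24, byrow = TRUE)
  stu <- new("StressField", sigma = rbind(sigu[1, ], sigu[1, ]),
             wdet = matrix(0.25, 2, 4), pts = matrix(0, 2, 12),
             regionTag = c("cortical", "cortical"), quadrature = "tet10-4pt")
  tbu <- regionStats(stu, reg)@table
  expect_equal(tbu$mean, tbu$peak, tolerance = 1e-12)
  ## empty regions are flagged, not silently zero
  regE <- reg; regE@membership <- rep(0L, 8)
  expect_true("cortical" %in% regionStats(st, regE)@empty_regions)
})

test_that("pointwise-R aggregation dominates R of aggregated stresses", {
  set.seed(12)
  lim <- defaultStrengthLimits()$cortical
  for (k in 1:20) {
    n <- 30
    sC <- -abs(rnorm(n, sd = 40))
    sT <- abs(rnorm(n, sd = 40))
    Rmean <- mean(riskIndex(sC, sT, lim))
    Ragg <- riskIndex(mean(sC), mean(sT), lim)
    expect_gte(Rmean, Ragg - 1e-12)
  }
})

test_that("the risk field scales linearly with the load", {
  sc1 <- tinyScenario()
  sc2 <- tinyScenario()
  sc2@load <- loadCase(F_lateral_N = 200, F_vertical_N = 500)
  r1 <- solveScenario(sc1, hi_ratio = 0.12, h0_ratio = 0.12, n_theta = 12,
                      domain_radius_mm = 3.4)
  r2 <- solveScenario(sc2, hi_ratio = 0.12, h0_ratio = 0.12, n_theta = 12,
                      domain_radius_mm = 3.4)
  t1 <- r1$report@table
  t2 <- r2$report@table
  sel <- t1$measure == "R"
  expect_equal(t2$peak[sel], 2 * t1$peak[sel], tolerance = 1e-6)
  expect_equal(t2$mean[sel], 2 * t1$mean[sel], tolerance = 1e-6)
})
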