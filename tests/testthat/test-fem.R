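test_that("default materials carry the reference elastic constants", {
  m <- defaultMaterials()
  expect_equal(m$cortical@E_MPa, 13700)
  expect_equal(m$cortical@nu, 0.30)
  expect_equal(m$trabecular@E_MPa, 500)
  expect_equal(m$implant@E_MPa, 114000)
  expect_equal(m$implant@nu, 0.34)
  expect_error(materialModel(-1, 0.3, "x"))
  expect_error(materialModel(100, 0.5, "x"))
})

test_that("the default load case is the 68-degree functional load", {
  lc <- loadCase()
  expect_equal(sqrt(lc@F_lateral_N^2 + lc@F_vertical_N^2), 269.258,
               tolerance = 1e-5)
  expect_equal(atan(lc@F_vertical_N / lc@F_lateral_N) * 180 / pi, 68.2,
               tolerance = 1e-3)
  expect_equal(lc@application_height_mm, 7)
})

test_that("single-element stiffness matches an independent quadrature oracle", {
  set.seed(3)
  corners <- rbind(c(0, 0, 0), c(1.1, 0, 0), c(0.2, 0.9, 0), c(0.1, 0.2, 1.3))
  mids <- rbind((corners[1, ] + corners[2, ]) / 2, (corners[2, ] + corners[3, ]) / 2,
                (corners[1, ] + corners[3, ]) / 2, (corners[1, ] + corners[4, ]) / 2,
                (corners[2, ] + corners[4, ]) / 2, (corners[3, ] + corners[4, ]) / 2)
  nodes <- rbind(corners, mids)
  elems <- matrix(1:10, 1, 10)
  tr <- osseoFEM:::tet10_assemble(nodes, elems, 1, 0)
  K <- matrix(0, 30, 30)
  for (i in seq_along(tr$i)) {
    K[tr$i[i], tr$j[i]] <- K[tr$i[i], tr$j[i]] + tr$x[i]
    if (tr$i[i] != tr$j[i])
      K[tr$j[i], tr$i[i]] <- K[tr$j[i], tr$i[i]] + tr$x[i]
  }
  Kref <- oracleTet10Stiffness(corners, 1, 0)
  expect_equal(K, Kref, tolerance = 1e-6)
  ## rigid translation has zero strain energy
  for (d in 1:3) {
    u <- rep(0, 30); u[seq(d, 30, by = 3)] <- 1
    expect_lt(abs(t(u) %*% K %*% u), 1e-10)
  }
  ## linearity in E
  tr2 <- osseoFEM:::tet10_assemble(nodes, elems, 2, 0)
  expect_equal(tr2$x, 2 * tr$x, tolerance = 1e-12)
})

test_that("the patch test is exact to machine precision", {
  mb <- meshBox(1, 1, 1, h = 0.3)
  mats <- list(domain = materialModel(100, 0.3, "domain"))
  sys <- assembleSystem(mb, mats)
  A <- matrix(c(1e-3, 2e-4, -1e-4, 2e-4, -5e-4, 3e-4, -1e-4, 3e-4, 4e-4), 3, 3)
  uex <- mb@nodes %*% A
  bnodes <- sort(unique(as.vector(do.call(rbind, mb@faceGroups))))
  bd <- as.integer(sort(c(3 * (bnodes - 1) + 1, 3 * (bnodes - 1) + 2,
                          3 * (bnodes - 1) + 3)))
  sys <- constrainSystem(sys, bd, f = numeric(3 * nNodes(mb)))
  u <- solveSystem(sys, u_fixed = as.numeric(t(uex))[bd])
  expect_lt(max(abs(u@u - uex)), 1e-12)
  ## stresses constant across all Gauss points
  st <- stressAtGauss(mb, mats, u)
  for (c in 1:6) {
    vals <- st@sigma[, c(c, c + 6, c + 12, c + 18)]
    expect_lt(diff(range(vals)), 1e-10)
  }
})

test_that("constitutive identities hold at Gauss points", {
  mb <- meshBox(1, 1, 1, h = 0.5)
  E <- 200; nu <- 0.25
  mats <- list(domain = materialModel(E, nu, "domain"))
  ## uniaxial strain with nu = 0: sigma_xx = E*e
  mats0 <- list(domain = materialModel(E, 0, "domain"))
  e <- 1e-3
  u <- cbind(e * mb@nodes[, 1], 0, 0)
  st <- stressAtGauss(mb, mats0, u)
  expect_equal(unname(st@sigma[1, 1]), E * e, tolerance = 1e-10)
  expect_lt(max(abs(st@sigma[, 2:6])), 1e-10)
  ## pure shear: sigma_xy = G * gamma
  g <- 2e-3
  u2 <- cbind(g * mb@nodes[, 2], 0, 0)
  st2 <- stressAtGauss(mb, mats, u2)
  G <- E / (2 * (1 + nu))
  expect_equal(unname(st2@sigma[1, 4]), G * g, tolerance = 1e-10)
})

test_that("a uniaxial bar recovers the closed-form tip displacement", {
  L <- 4; A <- 1; F <- 10; E <- 1000
  mb <- meshBox(L, 1, 1, h = 0.5)
  mats <- list(domain = materialModel(E, 0, "domain"))
  sys <- assembleSystem(mb, mats)
  f <- numeric(3 * nNodes(mb))
  xm <- mb@faceGroups$xmax
  Af <- osseoFEM:::.faceCornerAreas(mb@nodes, xm)
  ids <- as.vector(xm[, 4:6])
  acc <- tapply(rep(F / sum(Af) * Af / 3, 3), ids, sum)
  f[3 * (as.integer(names(acc)) - 1) + 1] <- as.numeric(acc)
  fixN <- sort(unique(as.vector(mb@faceGroups$xmin)))
  sys <- constrainSystem(sys, sort(c(3 * (fixN - 1) + 1, 3 * (fixN - 1) + 2,
                                     3 * (fixN - 1) + 3)), f)
  u <- solveSystem(sys)
  tip <- max(u@u[abs(mb@nodes[, 1] - L) < 1e-9, 1])
  expect_equal(tip, F * L / (E * A), tolerance = 5e-3)
  ## global equilibrium: reactions balance the applied load
  expect_equal(unname(reactionForces(sys, u)), c(-F, 0, 0), tolerance = 1e-6)
  ## energy consistency
  expect_equal(strainEnergy(sys, u), externalWork(sys, u), tolerance = 1e-8)
})

test_that("the Lame cylinder converges to the closed form", {
  l1 <- lameCase(3, 12, 1)
  l2 <- lameCase(6, 24, 2)
  e1 <- rmsRel(l1$w, l1$stt - l1$stt_ex, l1$stt_ex)
  e2 <- rmsRel(l2$w, l2$stt - l2$stt_ex, l2$stt_ex)
  expect_lt(e2, 0.02)  # within 2% at the second refinement
  expect_lt(rmsRel(l2$w, l2$srr - l2$srr_ex, l2$stt_ex), 0.02)
  ## roughly O(h^2) decay of the L2 stress error (allow a generous margin)
  expect_gt(e1 / e2, 2.5)
})

test_that("scenario loads and supports are statically consistent", {
  tiny <- tinySolve()
  sc <- tinyScenario()
  sys <- applyBCsAndLoad(assembleSystem(tiny$mesh, sc@materials), sc@load)
  ## half-domain: half the 100/250 N load is applied
  expect_equal(sum(sys@f[seq(1, length(sys@f), by = 3)]), 50, tolerance = 1e-10)
  expect_equal(sum(sys@f[seq(3, length(sys@f), by = 3)]), -125, tolerance = 1e-10)
  expect_equal(sum(sys@f[seq(2, length(sys@f), by = 3)]), 0, tolerance = 1e-10)
  r <- reactionForces(sys, tiny$u)
  expect_equal(unname(r[1]), -50, tolerance = 1e-5)
  expect_equal(unname(r[3]), 125, tolerance = 1e-5)
  ## displacements vanish on the fixed support
  cuts <- sort(unique(as.vector(tiny$mesh@faceGroups$coronal_cuts)))
  expect_lt(max(abs(tiny$u@u[cuts, ])), 1e-14)
  ## zero load gives the zero solution
  sys0 <- sys; sys0@f <- numeric(length(sys@f))
  u0 <- solveSystem(sys0)
  expect_lt(max(abs(u0@u)), 1e-12)
  ## missing constraints are refused
  expect_error(solveSystem(assembleSystem(tiny$mesh, sc@materials)), "singular")
})
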