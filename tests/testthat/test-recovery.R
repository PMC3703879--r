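test_that("recovery reproduces constant and linear stress states", {
  mb <- meshBox(1, 1, 1, h = 0.34)
  mats <- list(domain = materialModel(100, 0.3, "domain"))
  ## constant field: recovered equals raw exactly
  u <- cbind(1e-3 * mb@nodes[, 1], 0, 0)
  st <- stressAtGauss(mb, mats, u)
  rec <- recoverStress(mb, mats, st, mode = "average")
  nod <- rec@nodal[[1]]
  expect_equal(max(abs(nod[, 1] - st@sigma[1, 1])), 0, tolerance = 1e-10)
  ## linear-in-x stress: SPR is exact at every node, including boundaries
  uq <- cbind(1e-3 * mb@nodes[, 1]^2, 0, 0) # sigma_xx linear in x
  stq <- stressAtGauss(mb, mats, uq)
  recq <- recoverStress(mb, mats, stq, mode = "spr")
  mats0 <- mats
  E <- 100; nu <- 0.3
  lam <- E * nu / ((1 + nu) * (1 - 2 * nu)); mu <- E / (2 * (1 + nu))
  want <- (lam + 2 * mu) * 2e-3 * mb@nodes[, 1]
  bnd <- sort(unique(as.vector(do.call(rbind, mb@faceGroups))))
  interior <- setdiff(seq_len(nNodes(mb)), bnd)
  expect_equal(unname(recq@nodal[[1]][interior, 1]), unname(want[interior]),
               tolerance = 1e-8)
})

test_that("recovery never averages across material interfaces", {
  ## two-material bar: stiff left half, soft right half (grid chosen so a
  ## node plane lies exactly on the material interface x = 1)
  mb <- meshBox(2, 1, 1, h = 0.25)
  cen <- (mb@nodes[mb@elems[, 1], 1] + mb@nodes[mb@elems[, 2], 1] +
          mb@nodes[mb@elems[, 3], 1] + mb@nodes[mb@elems[, 4], 1]) / 4
  mesh <- mb
  mesh@regionTag <- ifelse(cen < 1, "stiff", "soft")
  mats <- list(stiff = materialModel(1000, 0.0, "stiff"),
               soft = materialModel(100, 0.0, "soft"))
  ## uniform strain -> stress jumps by the modulus ratio at the interface
  u <- cbind(1e-3 * mesh@nodes[, 1], 0, 0)
  st <- stressAtGauss(mesh, mats, u)
  rec <- recoverStress(mesh, mats, st)
  expect_length(rec@nodal, 2)
  iface <- which(abs(mesh@nodes[, 1] - 1) < 1e-9)
  g_st <- which(vapply(names(rec@nodal), function(g) startsWith(g, "1000"), TRUE))
  v_st <- rec@nodal[[g_st]][iface, 1]
  v_so <- rec@nodal[[-g_st + 3]][iface, 1]
  expect_equal(unname(v_st), rep(1, length(iface)), tolerance = 1e-9)
  expect_equal(unname(v_so), rep(0.1, length(iface)), tolerance = 1e-9)
})

test_that("the energy error norm is zero for an exactly recovered field", {
  mb <- meshBox(1, 1, 1, h = 0.34)
  mats <- list(domain = materialModel(100, 0.3, "domain"))
  u <- cbind(1e-3 * mb@nodes[, 1], 0, 0)
  st <- stressAtGauss(mb, mats, u)
  rec <- recoverStress(mb, mats, st)
  expect_lt(as.numeric(energyErrorNorm(mb, mats, st, rec)), 1e-8)
})

test_that("the ZZ estimate tracks the true error on the Lame benchmark", {
  l1 <- lameCase(3, 12, 1, mode = "spr")
  l2 <- lameCase(6, 24, 2, mode = "spr")
  ## estimated error decreases monotonically under refinement
  expect_lt(l2$energy_pct, l1$energy_pct)
  ## estimate within a factor 2 of the true energy-norm error
  trueErr <- function(l) {
    mats <- l$mats
    E <- mats$domain@E_MPa; nu <- mats$domain@nu
    ## plane-strain exact field also has sigma_zz = nu*(srr+stt)
    err2 <- (l$srr - l$srr_ex)^2 + (l$stt - l$stt_ex)^2
    ref2 <- l$srr_ex^2 + l$stt_ex^2
    100 * sqrt(sum(l$w * err2) / sum(l$w * ref2))
  }
  t2 <- trueErr(l2)
  expect_gt(l2$energy_pct / t2, 0.5)
  expect_lt(l2$energy_pct / t2, 2)
})

test_that("displacement error norms behave as a relative L2 metric", {
  tiny <- tinySolve()
  u <- tiny$u
  ## identical fields -> 0
  expect_equal(displacementErrorNorm(u, u), 0, tolerance = 1e-8)
  ## uniform scaling: u_coarse = (1+e) u_fine -> 100 e percent
  e <- 0.02
  uc <- u; uc@u <- (1 + e) * u@u
  expect_equal(displacementErrorNorm(uc, u), 100 * e, tolerance = 1e-6)
})

test_that("displacement norms decrease along a fixed-geometry refinement", {
  ## bar benchmark sequence with exact geometry at every level
  sols <- lapply(c(0.5, 0.34, 0.25), function(h) {
    mb <- meshBox(2, 1, 1, h = h)
    mats <- list(domain = materialModel(1000, 0.3, "domain"))
    sys <- assembleSystem(mb, mats)
    f <- numeric(3 * nNodes(mb))
    xm <- mb@faceGroups$xmax
    A <- osseoFEM:::.faceCornerAreas(mb@nodes, xm)
    ids <- as.vector(xm[, 4:6])
    acc <- tapply(rep(10 / sum(A) * A / 3, 3), ids, sum)
    f[3 * (as.integer(names(acc)) - 1) + 1] <- as.numeric(acc)
    ## clamped end: a genuinely 3D stress state near the support
    fixN <- sort(unique(as.vector(mb@faceGroups$xmin)))
    sys <- constrainSystem(sys, sort(c(3 * (fixN - 1) + 1, 3 * (fixN - 1) + 2,
                                       3 * (fixN - 1) + 3)), f)
    solveSystem(sys)
  })
  d12 <- displacementErrorNorm(sols[[1]], sols[[2]])
  d23 <- displacementErrorNorm(sols[[2]], sols[[3]])
  expect_lt(d23, d12)
})

test_that("convergeMesh honours its acceptance semantics", {
  solid <- buildScenarioSolid(tinyScenario())
  ## permissive thresholds: the first mesh is certified by the second
  cv <- convergeMesh(solid, schedule = c(0.14, 0.1), energy_max_pct = 100,
                     disp_max_pct = 100, h0_ratio = 0.14, n_theta = 12,
                     domain_radius_mm = 3.4)
  expect_true(cv$report@converged)
  expect_equal(cv$report@level, 1)
  expect_equal(nrow(cv$history), 2)
  ## a schedule of length 1 cannot certify and says so
  cv1 <- convergeMesh(solid, schedule = 0.14, energy_max_pct = 100,
                      disp_max_pct = 100, h0_ratio = 0.14, n_theta = 12,
                      domain_radius_mm = 3.4)
  expect_false(cv1$report@converged)
  expect_true(is.na(cv1$report@displacement_error_norm_pct))
})
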