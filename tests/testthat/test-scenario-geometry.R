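test_that("thread and milling specs enforce their physical constraints", {
  th <- threadSpec("T0_30_sawtooth", "ST")
  expect_equal(th@free_thickness_mm, 0.33)
  expect_equal(th@depth_secondary_mm, th@depth_primary_mm)
  th2 <- threadSpec("T10_30_trapezoid", "DT")
  expect_equal(th2@free_thickness_mm, 0.25)
  expect_equal(th2@depth_secondary_mm, 0.19)
  expect_equal(th2@lower_flank_angle_deg, 100)
  expect_error(implantSpec("x", 3.6, 9, abutment_connection_diameter_mm = 3.7),
               "platform switching")
  expect_error(millingSpec("LM")@width_mm < millingSpec("SM")@width_mm, NA)
  expect_true(millingSpec("LM")@width_mm > millingSpec("SM")@width_mm)
  expect_true(millingSpec("LM")@depth_mm > millingSpec("SM")@depth_mm)
})

test_that("the implant catalogue matches the design-study labelling", {
  cat11 <- implantCatalogue()
  expect_length(cat11, 11)
  expect_equal(cat11[["A"]]@D_mm, 3.5)
  expect_equal(cat11[["A"]]@L_mm, 11)
  expect_equal(cat11[["A"]]@milling@kind, "none")
  expect_equal(cat11[["8"]]@D_mm, 3.6)
  expect_equal(cat11[["8"]]@L_mm, 9)
  expect_equal(cat11[["8"]]@thread@profile_kind, "T10_30_trapezoid")
  expect_equal(cat11[["8"]]@thread@truncation, "DT")
  expect_equal(cat11[["8"]]@milling@kind, "SM")
  ## every entry is platform-switched
  for (sp in cat11)
    expect_lt(sp@abutment_connection_diameter_mm, sp@D_mm)
  ## single-factor pairs used by the comparative studies
  expect_equal(cat11[["1"]]@thread@profile_kind, "T0_30_sawtooth")
  expect_equal(cat11[["2"]]@thread@profile_kind, "T10_30_trapezoid")
  expect_equal(cat11[["2"]]@L_mm, cat11[["1"]]@L_mm)
  expect_equal(cat11[["3"]]@D_mm, 4.3)
})

test_that("implant solids realize the thread profile and scale with D", {
  solid8 <- buildImplantSolid(implantCatalogue()[["8"]])
  zb <- seq(0, 9, by = 0.002)
  a <- solid8@radiusFun(0, zb)
  expect_equal(max(a), 1.8, tolerance = 1e-9) # D3.6 -> max outer radius
  ## alternating fin depths 0.38 / 0.19 for DT: crest radii alternate
  crest <- a > 1.8 - 1e-6
  runs <- rle(crest)
  expect_gt(sum(runs$values), 3) # several full-depth fins present
  ## troughs reach the core radius
  core <- 1.8 - 0.38
  expect_lt(min(a[zb > 1 & zb < 7]), core + 0.05)
  ## second-start fins stop at depth 0.19 below the crest
  mids <- a[a > core + 0.17 & a < core + 0.21]
  expect_gt(length(mids), 0)

  ## degenerate thread: a smooth cylinder of diameter D
  th0 <- threadSpec("T0_30_sawtooth", "ST", depth_primary_mm = 0)
  smooth <- buildImplantSolid(implantSpec("s", 3.6, 9, th0, millingSpec("none")))
  zz <- seq(0.5, 7, by = 0.01)
  expect_equal(max(abs(smooth@radiusFun(0, zz) - 1.8)), 0, tolerance = 1e-12)

  ## volume strictly increases with D at fixed L and thread
  v36 <- implantVolume(buildImplantSolid(
    implantSpec("a", 3.6, 9, threadSpec("T10_30_trapezoid", "DT"), millingSpec("none"))))
  v43 <- implantVolume(buildImplantSolid(
    implantSpec("b", 4.3, 9, threadSpec("T10_30_trapezoid", "DT"), millingSpec("none"))))
  expect_gt(v43, v36)

  ## truncating one start (DT) cuts its thread crests down to 0.19 mm, so
  ## the DT solid carries strictly less material than ST (equivalently, the
  ## truncation removes extra volume from the full-depth thread)
  vST <- implantVolume(buildImplantSolid(
    implantSpec("c", 3.6, 9, threadSpec("T10_30_trapezoid", "ST"), millingSpec("none"))))
  vDT <- implantVolume(buildImplantSolid(
    implantSpec("d", 3.6, 9, threadSpec("T10_30_trapezoid", "DT"), millingSpec("none"))))
  expect_gt(vST, vDT)

  ## self-intersecting profile is refused with a named constraint
  bad <- threadSpec("T10_30_trapezoid", "ST", depth_primary_mm = 2)
  expect_error(buildImplantSolid(implantSpec("e", 3.6, 9, bad)),
               "self-intersecting")
})

test_that("helical and annular thread modes agree on bulk metrics", {
  sp <- implantCatalogue()[["8"]]
  va <- implantVolume(buildImplantSolid(sp, "annular_rings"))
  vh <- implantVolume(buildImplantSolid(sp, "helical"))
  expect_equal(va, vh, tolerance = 0.05)
  hel <- buildImplantSolid(sp, "helical")
  ## helix: fin position advances with theta
  z <- seq(1, 3, by = 0.001)
  a0 <- hel@radiusFun(rep(0, length(z)), z)
  a1 <- hel@radiusFun(rep(pi / 2, length(z)), z)
  expect_gt(max(abs(a0 - a1)), 0.1)
})

test_that("the bone segment has the stated shell thickness and partitions", {
  bone <- buildBoneSegment(boneSegmentSpec())
  ## vertical probes through the crest plate, away from side plates/fillets
  for (x in c(-1, 0, 1)) {
    zz <- seq(-0.01, -4, by = -0.005)
    tis <- bone@tissueFun(rep(x, length(zz)), rep(0, length(zz)), zz)
    depth <- -zz[max(which(tis == "cortical" & zz > -3))]
    expect_equal(depth, 2, tolerance = 0.05)
  }
  ## buccolingual probe at mid height: side shell thickness ~2 along normal
  xx <- seq(4.74, 0, by = -0.005) # halfwidth at z = -7 is ~4.75
  tis <- bone@tissueFun(xx, rep(0, length(xx)), rep(-7, length(xx)))
  t_side <- (xx[1] - xx[min(which(tis == "trabecular"))])
  expect_equal(t_side, 2, tolerance = 0.1)
  ## analytic partition: cortical + trabecular = total prism volume
  spec <- boneSegmentSpec()
  A_tot <- (spec@crest_width_mm + spec@crest_width_mm + 3) / 2 *
    spec@crest_height_mm
  expect_equal(bone@cortical_volume_mm3 + bone@trabecular_volume_mm3,
               A_tot * spec@mesiodistal_length_mm, tolerance = 1e-9)
  ## limiting case: very thick shell still leaves a core
  thick <- buildBoneSegment(boneSegmentSpec(cortical_thickness_mm = 3.9))
  expect_gt(thick@trabecular_volume_mm3, 0)
  expect_error(boneSegmentSpec(cortical_thickness_mm = 4.1),
               "half the crest width")
})

test_that("placement and morphology compose into a consistent scenario solid", {
  sc <- tinyScenario("P1")
  solid <- buildScenarioSolid(sc)
  expect_equal(solid@platform_z, -1)
  expect_equal(solid@apex_z, -6.5)
  ## platform depth recovered by probing along the axis region:
  ## just above the platform (inside the soft-tissue gap region) there is
  ## abutment at small radius; just below the platform there is implant
  expect_equal(unname(solid@regionAtFun(0.3, 0, -1.01)), "implant")
  expect_equal(unname(solid@regionAtFun(0.3, 0, -0.99)), "abutment")
  ## crater depth: P0 with 50% loss on 2 mm cortical gives a 1 mm crater
  sc0 <- tinyScenario("P0", crestalMorphology("bone_loss", 0.5))
  s0 <- buildScenarioSolid(sc0)
  expect_equal(s0@crater_depth_mm, 1)
  expect_equal(s0@crestZFun(1.8), -1)          # at the implant wall
  expect_equal(s0@crestZFun(2.8), 0)           # 45 deg wall closes 1 mm out
  expect_equal(s0@crestZFun(2.3), -0.5, tolerance = 1e-12)
  ## pristine P0: bone flush with the platform
  sp <- buildScenarioSolid(tinyScenario("P0", crestalMorphology("pristine")))
  expect_equal(unname(sp@regionAtFun(2.5, 0, -0.05)), "cortical")
  ## error cases
  expect_error(buildScenarioSolid(
    scenarioSpec(implantCatalogue()[["A"]], "P1",
                 bone = boneSegmentSpec(crest_height_mm = 11))),
    "apex exits")
  expect_error(buildScenarioSolid(
    tinyScenario("P0", crestalMorphology("apposition"))), "subcrestal")
  expect_error(buildScenarioSolid(
    tinyScenario("P1", crestalMorphology("bone_loss", 0.2))), "crater")
})

test_that("scenario regions partition space with no overlaps", {
  solid <- buildScenarioSolid(tinyScenario("P1"))
  set.seed(7)
  n <- 4000
  x <- runif(n, -4, 4); y <- runif(n, -4, 4); z <- runif(n, -13, 6)
  tags <- solid@regionAtFun(x, y, z)
  expect_true(all(tags %in% c("implant", "abutment", "cortical",
                              "trabecular", "void")))
  ## determinism of the geometry
  tags2 <- solid@regionAtFun(x, y, z)
  expect_identical(tags, tags2)
  ## titanium points lie within the column envelope
  ti <- tags %in% c("implant", "abutment")
  r <- sqrt(x^2 + y^2)
  expect_true(all(r[ti] <= solid@columnEnvelopeFun(z[ti]) + 1e-9))
})
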