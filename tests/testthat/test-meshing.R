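test_that("size fields follow the stated ratios", {
  sf <- makeSizeField(3.6)
  expect_equal(sf@h0_mm, 0.36)
  expect_equal(sf@hi_mm, 0.036)
  expect_equal(makeSizeField(4.3)@h0_mm, 0.43)
  uni <- makeSizeField(3.6, 0.1, 0.1)
  expect_equal(uni@h0_mm, uni@hi_mm)
  expect_error(makeSizeField(3.6, 0.01, 0.1))
})

test_that("the calibration cube meets the mean-edge target", {
  mb <- meshBox(1, 1, 1, h = 0.25)
  L <- osseoFEM:::.edgeStats(mb@nodes, mb@elems[, 1:4, drop = FALSE])
  expect_lt(abs(mean(L) - 0.25) / 0.25, 0.25)
  expect_gt(min(mb@quality), 0.2)
})

test_that("meshes are conforming with positive volumes and clean interfaces", {
  tiny <- tinySolve()
  mesh <- tiny$mesh
  ## positive volumes everywhere
  expect_true(all(osseoFEM:::tet10_volumes(mesh@nodes, mesh@elems) > 0))
  ## conformity: every interior corner face is shared by exactly two elements
  el <- mesh@elems
  cf <- rbind(c(1, 2, 3), c(1, 2, 4), c(1, 3, 4), c(2, 3, 4))
  faces <- rbind(el[, cf[1, ]], el[, cf[2, ]], el[, cf[3, ]], el[, cf[4, ]])
  a <- pmin(faces[, 1], faces[, 2], faces[, 3])
  c_ <- pmax(faces[, 1], faces[, 2], faces[, 3])
  b <- rowSums(faces) - a - c_
  key <- paste(a, b, c_)
  cnt <- table(table(key))
  expect_true(all(names(cnt) %in% c("1", "2")))
  ## every bone-implant interface face borders one titanium and one bone side
  iface <- mesh@faceGroups$bone_implant_interface
  expect_gt(nrow(iface), 0)
  keyI <- paste(pmin(iface[, 1], iface[, 2], iface[, 3]),
                iface[, 1] + iface[, 2] + iface[, 3] -
                  pmin(iface[, 1], iface[, 2], iface[, 3]) -
                  pmax(iface[, 1], iface[, 2], iface[, 3]),
                pmax(iface[, 1], iface[, 2], iface[, 3]))
  felem <- rep(seq_len(nrow(el)), 4)
  hit <- key %in% keyI
  tags <- mesh@regionTag[felem[hit]]
  byface <- split(tags, key[hit])
  expect_true(all(vapply(byface, function(tt)
    sum(tt %in% c("implant", "abutment")) == 1 &&
      sum(tt %in% c("cortical", "trabecular")) == 1, TRUE)))
})

test_that("halving hi at least doubles the peri-implant element count", {
  sc <- tinyScenario()
  solid <- buildScenarioSolid(sc)
  count_shell <- function(hr) {
    mesh <- meshScenario(solid, makeSizeField(3.6, 0.12, hr), n_theta = 12,
                         domain_radius_mm = 3.4)
    cen <- (mesh@nodes[mesh@elems[, 1], ] + mesh@nodes[mesh@elems[, 2], ] +
            mesh@nodes[mesh@elems[, 3], ] + mesh@nodes[mesh@elems[, 4], ]) / 4
    r <- sqrt(cen[, 1]^2 + cen[, 2]^2)
    bone <- mesh@regionTag %in% c("cortical", "trabecular")
    sum(bone & r < 1.8 + 0.9 & cen[, 3] < -0.5 & cen[, 3] > -6.5)
  }
  expect_gte(count_shell(0.06) / count_shell(0.12), 2)
})

test_that("meshing is deterministic and the quality gate rejects bad meshes", {
  sc <- tinyScenario()
  solid <- buildScenarioSolid(sc)
  m1 <- meshScenario(solid, makeSizeField(3.6, 0.12, 0.12), n_theta = 12,
                     domain_radius_mm = 3.4)
  m2 <- meshScenario(solid, makeSizeField(3.6, 0.12, 0.12), n_theta = 12,
                     domain_radius_mm = 3.4)
  expect_identical(m1@nodes, m2@nodes)
  expect_identical(m1@elems, m2@elems)
  expect_identical(m1@regionTag, m2@regionTag)
  expect_error(meshScenario(solid, makeSizeField(3.6, 0.12, 0.12),
                            n_theta = 12, domain_radius_mm = 3.4,
                            quality_floor = 0.9), "quality floor")
})

test_that("the tube mesh resolves its face groups", {
  tb <- meshTube(1, 2, 0.5, nr = 3, ntheta = 12, nz = 1)
  expect_gt(nrow(tb@faceGroups$inner), 0)
  expect_gt(nrow(tb@faceGroups$outer), 0)
  r_in <- sqrt(tb@nodes[tb@faceGroups$inner[, 1:3], 1]^2 +
               tb@nodes[tb@faceGroups$inner[, 1:3], 2]^2)
  expect_true(all(abs(r_in - 1) < 1e-9))
})
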