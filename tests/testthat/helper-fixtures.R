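## Shared fixtures and independent oracles.  Heavy objects are computed once
## per test run and cached in this environment.

.fix <- new.env(parent = emptyenv())

tinyImplant <- function(thread = threadSpec("T10_30_trapezoid", "DT"),
                        milling = millingSpec("none")) {
  implantSpec("T", 3.6, 5.5, thread, milling)
}

tinyScenario <- function(placement = "P1", morphology = NULL) {
  scenarioSpec(tinyImplant(), placement, morphology)
}

## coarse but complete scenario pipeline (mesh + solve + stress + regions)
tinySolve <- function() {
  if (is.null(.fix$tiny)) {
    .fix$tiny <- solveScenario(tinyScenario(), hi_ratio = 0.12,
                               h0_ratio = 0.12, n_theta = 12,
                               domain_radius_mm = 3.4, keep_fields = TRUE)
  }
  .fix$tiny
}

## Lame thick-walled cylinder benchmark: internal pressure, plane strain.
## Returns Gauss-point radial/hoop stresses, exact values and ZZ error norms.
lameCase <- function(nr, ntheta, nz, mode = "average") {
  key <- paste("lame", nr, ntheta, nz, mode, sep = "_")
  if (!is.null(.fix[[key]])) return(.fix[[key]])
  a <- 1; b <- 2; p <- 10; E <- 1000; nu <- 0.3
  mesh <- meshTube(a, b, height = 0.5, nr = nr, ntheta = ntheta, nz = nz)
  mats <- list(domain = materialModel(E, nu, "domain"))
  sys <- assembleSystem(mesh, mats)
  nd <- mesh@nodes
  f <- numeric(3 * nNodes(mesh))
  inner <- mesh@faceGroups$inner
  A <- osseoFEM:::.faceCornerAreas(nd, inner)
  for (d in 1:2) {
    ids <- as.vector(inner[, 4:6])
    r <- sqrt(nd[ids, 1]^2 + nd[ids, 2]^2)
    v <- p * nd[ids, d] / r * rep(A / 3, 3)
    acc <- tapply(v, ids, sum)
    ii <- as.integer(names(acc))
    f[3 * (ii - 1) + d] <- f[3 * (ii - 1) + d] + as.numeric(acc)
  }
  tol <- 1e-9
  fix <- c(3 * (which(abs(nd[, 3]) < tol | abs(nd[, 3] - 0.5) < tol) - 1) + 3,
           3 * (which(abs(nd[, 2]) < tol) - 1) + 2,
           3 * (which(abs(nd[, 1]) < tol) - 1) + 1)
  sys <- constrainSystem(sys, fix, f)
  u <- solveSystem(sys)
  st <- stressAtGauss(mesh, mats, u)
  pts <- rbind(st@pts[, 1:3], st@pts[, 4:6], st@pts[, 7:9], st@pts[, 10:12])
  sig <- rbind(st@sigma[, 1:6], st@sigma[, 7:12], st@sigma[, 13:18],
               st@sigma[, 19:24])
  w <- c(st@wdet[, 1], st@wdet[, 2], st@wdet[, 3], st@wdet[, 4])
  r <- sqrt(pts[, 1]^2 + pts[, 2]^2)
  th <- atan2(pts[, 2], pts[, 1])
  c2 <- cos(th)^2; s2 <- sin(th)^2; sc <- sin(th) * cos(th)
  srr <- sig[, 1] * c2 + sig[, 2] * s2 + 2 * sig[, 4] * sc
  stt <- sig[, 1] * s2 + sig[, 2] * c2 - 2 * sig[, 4] * sc
  k <- p * a^2 / (b^2 - a^2)
  rec <- recoverStress(mesh, mats, st, mode = mode)
  en <- energyErrorNorm(mesh, mats, st, rec)
  out <- list(mesh = mesh, mats = mats, sys = sys, u = u, st = st, w = w,
              srr = srr, stt = stt,
              srr_ex = k * (1 - b^2 / r^2), stt_ex = k * (1 + b^2 / r^2),
              energy_pct = as.numeric(en))
  .fix[[key]] <- out
  out
}

## relative volume-weighted RMS error
rmsRel <- function(w, err, ref) sqrt(sum(w * err^2) / sum(w * ref^2))

## ---- independent oracles ---------------------------------------------------

## Exact quadratic quadrature on a tetrahedron: vertices weighted -1/20,
## edge midpoints 1/5 (times the volume).  Shape gradients by central
## finite differences of the tet10 shape functions -- fully independent of
## the compiled assembly path.
oracleTet10Stiffness <- function(corners, E, nu) {
  A <- rbind(1, t(corners)) # barycentric: A %*% L = (1, x)
  baryAt <- function(x) solve(A, c(1, x))
  shapeAt <- function(x) {
    L <- baryAt(x)
    c(L[1] * (2 * L[1] - 1), L[2] * (2 * L[2] - 1), L[3] * (2 * L[3] - 1),
      L[4] * (2 * L[4] - 1), 4 * L[1] * L[2], 4 * L[2] * L[3],
      4 * L[1] * L[3], 4 * L[1] * L[4], 4 * L[2] * L[4], 4 * L[3] * L[4])
  }
  gradAt <- function(x, h = 1e-6) {
    g <- matrix(0, 10, 3)
    for (d in 1:3) {
      e <- numeric(3); e[d] <- h
      g[, d] <- (shapeAt(x + e) - shapeAt(x - e)) / (2 * h)
    }
    g
  }
  Dm <- matrix(0, 6, 6)
  lam <- E * nu / ((1 + nu) * (1 - 2 * nu)); mu <- E / (2 * (1 + nu))
  Dm[1:3, 1:3] <- lam; diag(Dm)[1:3] <- lam + 2 * mu
  diag(Dm)[4:6] <- mu
  Bof <- function(g) {
    B <- matrix(0, 6, 30)
    for (i in 1:10) {
      B[1, 3 * i - 2] <- g[i, 1]; B[2, 3 * i - 1] <- g[i, 2]
      B[3, 3 * i] <- g[i, 3]
      B[4, 3 * i - 2] <- g[i, 2]; B[4, 3 * i - 1] <- g[i, 1]
      B[5, 3 * i - 1] <- g[i, 3]; B[5, 3 * i] <- g[i, 2]
      B[6, 3 * i - 2] <- g[i, 3]; B[6, 3 * i] <- g[i, 1]
    }
    B
  }
  V <- abs(det(cbind(corners[2, ] - corners[1, ], corners[3, ] - corners[1, ],
                     corners[4, ] - corners[1, ]))) / 6
  pts <- rbind(corners,
               (corners[1, ] + corners[2, ]) / 2, (corners[2, ] + corners[3, ]) / 2,
               (corners[1, ] + corners[3, ]) / 2, (corners[1, ] + corners[4, ]) / 2,
               (corners[2, ] + corners[4, ]) / 2, (corners[3, ] + corners[4, ]) / 2)
  wts <- c(rep(-1 / 20, 4), rep(1 / 5, 6)) * V
  K <- matrix(0, 30, 30)
  for (q in 1:10) {
    B <- Bof(gradAt(pts[q, ]))
    K <- K + wts[q] * t(B) %*% Dm %*% B
  }
  K
}

## brute-force point-to-triangle-soup distance (dense, O(n*m))
oracleTriDistance <- function(verts, tris, pts) {
  d1 <- function(p, a, b, c) {
    ## closest point by constrained minimization over barycentric samples +
    ## edge projections (dense sampling; adequate as a slow oracle)
    uv <- expand.grid(u = seq(0, 1, length.out = 21), v = seq(0, 1, length.out = 21))
    uv <- uv[uv$u + uv$v <= 1, ]
    q <- t(sapply(seq_len(nrow(uv)), function(i)
      a + uv$u[i] * (b - a) + uv$v[i] * (c - a)))
    min(sqrt(rowSums((q - matrix(p, nrow(q), 3, byrow = TRUE))^2)))
  }
  out <- numeric(nrow(pts))
  for (i in seq_len(nrow(pts))) {
    best <- Inf
    for (t in seq_len(nrow(tris))) {
      a <- verts[tris[t, 1], ]; b <- verts[tris[t, 2], ]; c <- verts[tris[t, 3], ]
      ## cheap lower bound prune
      cen <- (a + b + c) / 3
      if (sqrt(sum((cen - pts[i, ])^2)) - max(sqrt(sum((a - cen)^2)),
                                              sqrt(sum((b - cen)^2)),
                                              sqrt(sum((c - cen)^2))) > best) next
      best <- min(best, d1(pts[i, ], a, b, c))
    }
    out[i] <- best
  }
  out
}
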