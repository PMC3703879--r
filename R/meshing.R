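#' @include classes.R
NULL

## Graded quadratic tetrahedral meshing.
##
## Scenario meshes are built as mapped extrusions: a polar ring template
## (centre fan + graded rings) is extruded along the implant axis, node radii
## are fitted to the implant/abutment interface radius a(theta, z) so the
## bone-implant interface is a body-fitted node surface, prisms are split
## into tetrahedra with a global-min-vertex diagonal rule (guaranteeing a
## conforming mesh) and elements are tagged by region.  Mid-edge nodes sit at
## straight-edge midpoints (subparametric geometry).

#' Two-zone mesh-size field
#'
#' @slot h0_mm target mean size away from the bone-implant interface
#' @slot hi_mm target mean size in the peri-implant zone
#' @slot transition_mm blending span from hi to h0
#' @export
setClass("SizeField", representation(
  h0_mm = "numeric", hi_mm = "numeric", transition_mm = "numeric"
), validity = function(object) {
  if (object@hi_mm <= 0 || object@hi_mm > object@h0_mm)
    return("0 < hi_mm <= h0_mm required")
  TRUE
})

#' Build a size field from the implant diameter
#'
#' Mean mesh sizes are specified relative to the implant diameter:
#' \code{h0 = h0_ratio * D} away from the interface and
#' \code{hi = hi_ratio * D} close to the peri-implant region.
#'
#' @param D_mm implant diameter
#' @param h0_ratio far-field size ratio (default 0.1)
#' @param hi_ratio near-interface size ratio (default 0.01)
#' @param transition_mm blending distance; defaults to 1.2x the control
#'   volume thickness (0.3 D), which keeps the whole control volume inside
#'   the fine zone at desk-scale cost
#' @return a \code{SizeField}
#' @examples
#' sf <- makeSizeField(3.6)
#' c(sf@h0_mm, sf@hi_mm)  # 0.36, 0.036
#' @export
makeSizeField <- function(D_mm, h0_ratio = 0.1, hi_ratio = 0.01,
                          transition_mm = 0.3 * D_mm) {
  obj <- new("SizeField", h0_mm = h0_ratio * D_mm, hi_mm = hi_ratio * D_mm,
             transition_mm = transition_mm)
  validObject(obj)
  obj
}

#' Quadratic tetrahedral mesh
#'
#' 10-node tetrahedra with VTK local ordering (corners 1-4, then mid-edge
#' nodes on edges (1,2),(2,3),(1,3),(1,4),(2,4),(3,4)).
#'
#' @slot nodes numeric matrix n x 3 of coordinates (mm)
#' @slot elems integer matrix m x 10 of node indices
#' @slot regionTag character vector, per-element region
#' @slot faceGroups named list of 6-column node-index matrices (3 corners +
#'   3 mid-edge nodes) for boundary/interface facet sets
#' @slot quality per-element normalized shape quality (1 = regular tet)
#' @slot info list of mesher metadata (size field, counts, edge statistics)
#' @export
setClass("Tet10Mesh", representation(
  nodes = "matrix", elems = "matrix", regionTag = "character",
  faceGroups = "list", quality = "numeric", info = "list"))

#' @describeIn Tet10Mesh number of nodes
#' @param mesh a \code{Tet10Mesh}
#' @export
nNodes <- function(mesh) nrow(mesh@nodes)

#' @describeIn Tet10Mesh number of elements
#' @export
nElements <- function(mesh) nrow(mesh@elems)

#' @describeIn Tet10Mesh node coordinate matrix
#' @export
meshNodes <- function(mesh) mesh@nodes

#' @describeIn Tet10Mesh element connectivity matrix
#' @export
meshElements <- function(mesh) mesh@elems

#' @describeIn Tet10Mesh per-element region tags
#' @export
regionTags <- function(mesh) mesh@regionTag

#' @describeIn Tet10Mesh named boundary/interface facet sets
#' @export
faceGroups <- function(mesh) mesh@faceGroups

setMethod("show", "Tet10Mesh", function(object) {
  cat(sprintf("Tet10Mesh: %d nodes, %d elements\n", nNodes(object), nElements(object)))
  tb <- table(object@regionTag)
  cat("  regions:", paste(sprintf("%s=%d", names(tb), tb), collapse = ", "), "\n")
  cat("  face groups:", paste(sprintf("%s=%d", names(object@faceGroups),
                                      vapply(object@faceGroups, nrow, 1L)),
                              collapse = ", "), "\n")
  cat(sprintf("  quality: min %.3f, median %.3f\n", min(object@quality),
              stats::median(object@quality)))
})

## ---- internal helpers ------------------------------------------------------

## Dompierre-style prism -> 3 tets split; diagonals pass through the smallest
## global vertex id of each quad face, so neighbouring prisms always agree.
.splitPrisms <- function(P) {
  m <- nrow(P)
  pos <- rep(1L, m)
  cur <- P[, 1]
  for (j in 2:6) {
    sel <- P[, j] < cur
    pos[sel] <- j
    cur[sel] <- P[sel, j]
  }
  rotTab <- rbind(
    c(1, 2, 3, 4, 5, 6), c(2, 3, 1, 5, 6, 4), c(3, 1, 2, 6, 4, 5),
    c(4, 6, 5, 1, 3, 2), c(5, 4, 6, 2, 1, 3), c(6, 5, 4, 3, 2, 1))
  RM <- rotTab[pos, , drop = FALSE]
  Q <- matrix(P[cbind(rep(seq_len(m), 6), as.vector(RM))], m, 6)
  c1 <- pmin(Q[, 2], Q[, 6]) < pmin(Q[, 3], Q[, 5])
  tets <- matrix(0L, 3 * m, 4)
  i1 <- which(c1); i2 <- which(!c1)
  if (length(i1)) {
    tets[3 * i1 - 2, ] <- cbind(Q[i1, 1], Q[i1, 2], Q[i1, 3], Q[i1, 6])
    tets[3 * i1 - 1, ] <- cbind(Q[i1, 1], Q[i1, 2], Q[i1, 6], Q[i1, 5])
    tets[3 * i1, ] <- cbind(Q[i1, 1], Q[i1, 5], Q[i1, 6], Q[i1, 4])
  }
  if (length(i2)) {
    tets[3 * i2 - 2, ] <- cbind(Q[i2, 1], Q[i2, 2], Q[i2, 3], Q[i2, 5])
    tets[3 * i2 - 1, ] <- cbind(Q[i2, 1], Q[i2, 5], Q[i2, 3], Q[i2, 6])
    tets[3 * i2, ] <- cbind(Q[i2, 1], Q[i2, 5], Q[i2, 6], Q[i2, 4])
  }
  tets
}

## signed volume * 6 of corner tets, vectorized
.signedVol6 <- function(nodes, tets) {
  p1 <- nodes[tets[, 1], , drop = FALSE]
  a <- nodes[tets[, 2], , drop = FALSE] - p1
  b <- nodes[tets[, 3], , drop = FALSE] - p1
  c <- nodes[tets[, 4], , drop = FALSE] - p1
  a[, 1] * (b[, 2] * c[, 3] - b[, 3] * c[, 2]) -
    a[, 2] * (b[, 1] * c[, 3] - b[, 3] * c[, 1]) +
    a[, 3] * (b[, 1] * c[, 2] - b[, 2] * c[, 1])
}

.fixOrientation <- function(nodes, tets) {
  v <- .signedVol6(nodes, tets)
  bad <- v < 0
  if (any(bad)) tets[bad, c(3, 4)] <- tets[bad, c(4, 3)]
  if (any(abs(.signedVol6(nodes, tets)) < 1e-14))
    stop("degenerate tetrahedra produced by the mesher")
  tets
}

## add mid-edge nodes; returns list(nodes, elems10)
.toTet10 <- function(nodes, tets) {
  edgesLocal <- rbind(c(1, 2), c(2, 3), c(1, 3), c(1, 4), c(2, 4), c(3, 4))
  m <- nrow(tets)
  ea <- eb <- matrix(0L, m, 6)
  for (k in 1:6) {
    a <- tets[, edgesLocal[k, 1]]
    b <- tets[, edgesLocal[k, 2]]
    ea[, k] <- pmin(a, b)
    eb[, k] <- pmax(a, b)
  }
  keyBase <- nrow(nodes) + 1
  key <- as.numeric(ea) * keyBase + as.numeric(eb)
  uk <- unique(key)
  idx <- match(key, uk)
  ua <- as.integer(uk %/% keyBase)
  ub <- as.integer(uk %% keyBase)
  mids <- (nodes[ua, , drop = FALSE] + nodes[ub, , drop = FALSE]) / 2
  midIds <- as.integer(nrow(nodes) + seq_along(uk))
  elems10 <- cbind(tets, matrix(midIds[idx], m, 6))
  storage.mode(elems10) <- "integer"
  list(nodes = rbind(nodes, mids), elems = elems10,
       edgeKeyBase = keyBase)
}

## boundary + interface facet extraction with mid-edge completion
.buildFaceGroups <- function(nodes, elems, regionTag, classifyBoundary) {
  m <- nrow(elems)
  cf <- rbind(c(1, 2, 3), c(1, 2, 4), c(1, 3, 4), c(2, 3, 4))
  faces <- rbind(elems[, cf[1, ]], elems[, cf[2, ]], elems[, cf[3, ]], elems[, cf[4, ]])
  felem <- rep(seq_len(m), 4)
  ## sorted triple key without apply()
  a <- pmin(faces[, 1], faces[, 2], faces[, 3])
  c_ <- pmax(faces[, 1], faces[, 2], faces[, 3])
  b <- faces[, 1] + faces[, 2] + faces[, 3] - a - c_
  nb <- nrow(nodes) + 1
  key <- (as.numeric(a) * nb + b) * nb + c_
  ord <- order(key)
  key_s <- key[ord]
  first <- !duplicated(key_s)
  grp <- cumsum(first)
  cnt <- tabulate(grp)
  ## boundary faces: unique keys
  bidx <- ord[first & cnt[grp] == 1]
  ## interface: pairs with differing region classes
  titan <- regionTag %in% c("implant", "abutment")
  dup2 <- which(first & cnt[grp] == 2)
  e1 <- felem[ord[dup2]]
  e2 <- felem[ord[dup2 + 1]]
  iface <- titan[e1] != titan[e2]
  fint <- ord[dup2][iface]

  midLookup <- function(fidx) {
    ## complete corner triples with mid-edge nodes from the owning element
    out <- matrix(0L, length(fidx), 6)
    if (!length(fidx)) return(out)
    el <- felem[fidx]
    tri <- faces[fidx, , drop = FALSE]
    edgesLocal <- rbind(c(1, 2), c(2, 3), c(1, 3), c(1, 4), c(2, 4), c(3, 4))
    for (r in seq_along(fidx)) {
      e10 <- elems[el[r], ]
      loc <- match(tri[r, ], e10[1:4])
      pairs <- rbind(sort(loc[c(1, 2)]), sort(loc[c(2, 3)]), sort(loc[c(1, 3)]))
      mid <- integer(3)
      for (k in 1:3) {
        ei <- which(edgesLocal[, 1] == pairs[k, 1] & edgesLocal[, 2] == pairs[k, 2])
        mid[k] <- e10[4 + ei]
      }
      out[r, ] <- c(tri[r, ], mid)
    }
    out
  }

  bfaces <- midLookup(bidx)
  groups <- classifyBoundary(nodes, bfaces)
  groups$bone_implant_interface <- midLookup(fint)
  groups
}

.edgeStats <- function(nodes, elems) {
  edgesLocal <- rbind(c(1, 2), c(2, 3), c(1, 3), c(1, 4), c(2, 4), c(3, 4))
  L <- matrix(0, nrow(elems), 6)
  for (k in 1:6) {
    d <- nodes[elems[, edgesLocal[k, 1]], , drop = FALSE] -
      nodes[elems[, edgesLocal[k, 2]], , drop = FALSE]
    L[, k] <- sqrt(rowSums(d^2))
  }
  L
}

.assembleTet10Mesh <- function(nodes, tets, tags, classifyBoundary, info,
                               quality_floor) {
  keep <- tags != "void"
  tets <- tets[keep, , drop = FALSE]
  tags <- tags[keep]
  ## drop orphan nodes
  used <- sort(unique(as.vector(tets)))
  remap <- integer(nrow(nodes))
  remap[used] <- seq_along(used)
  nodes <- nodes[used, , drop = FALSE]
  tets <- matrix(remap[tets], nrow(tets), 4)
  tets <- .fixOrientation(nodes, tets)
  q <- as.numeric(tet_quality(nodes, tets))
  if (min(q) < quality_floor)
    stop(sprintf("mesh rejected: %d elements below the quality floor %.3g (min %.3g)",
                 sum(q < quality_floor), quality_floor, min(q)))
  t10 <- .toTet10(nodes, tets)
  fg <- .buildFaceGroups(t10$nodes, t10$elems, tags, classifyBoundary)
  info$edge_mean <- mean(.edgeStats(t10$nodes, t10$elems[, 1:4, drop = FALSE]))
  new("Tet10Mesh", nodes = t10$nodes, elems = t10$elems, regionTag = tags,
      faceGroups = fg, quality = q, info = info)
}

## ---- scenario mesher -------------------------------------------------------

#' Mesh a scenario solid with graded quadratic tetrahedra
#'
#' Builds a body-fitted, graded mesh of the peri-implant subdomain: a
#' cylinder of radius \code{domain_radius_mm} around the implant axis spanning
#' the full section height plus the abutment.  Radial and axial spacing equal
#' \code{size@hi_mm} near the bone-implant interface and coarsen geometrically
#' to \code{size@h0_mm} beyond the transition distance; the angular resolution
#' follows the interface circumference at a fixed anisotropy factor.  Element
#' regions are tagged \code{implant}, \code{abutment}, \code{cortical} or
#' \code{trabecular}; elements above the (possibly cratered) crest surface
#' are removed.  Meshing is fully deterministic.
#'
#' @param solid a \code{\link{buildScenarioSolid}} result
#' @param size a \code{\link{makeSizeField}}
#' @param seed unused (kept for interface stability; the mesher is
#'   deterministic)
#' @param domain_radius_mm radius of the solved subdomain; the default
#'   (half the crest width + 1.25 mm) encloses the buccal/lingual cortical
#'   plates with margin, so their outer surfaces remain free and only the
#'   mesiodistal sectors of the cylinder carry the remote fixed support
#' @param n_theta angular node count (multiple of 4); default derived from
#'   the interface circumference at anisotropy ~2.5
#' @param growth radial/axial geometric coarsening ratio
#' @param axial_factor axial spacing in the fine zone as a multiple of hi
#' @param quality_floor minimum admissible element quality; meshes below it
#'   are rejected with an error
#' @param symmetry_half model only the y >= 0 half of the domain (default):
#'   geometry and load are mirror-symmetric about the buccolingual (xz)
#'   plane (the helical milling groove, a minor feature, is symmetrized),
#'   and \code{\link{applyBCsAndLoad}} imposes the symmetry condition and
#'   halves the applied load accordingly
#' @return a \code{\link{Tet10Mesh}}
#' @export
meshScenario <- function(solid, size, seed = 1L,
                         domain_radius_mm = solid@bone@spec@crest_width_mm / 2 + 1.25,
                         n_theta = NULL, growth = 1.7, axial_factor = 2,
                         quality_floor = 0.005, symmetry_half = TRUE) {
  hi <- size@hi_mm
  h0 <- size@h0_mm
  spec <- solid@scenario@implant
  R <- spec@D_mm / 2
  H <- solid@bone@spec@crest_height_mm
  Rd <- domain_radius_mm
  if (is.null(n_theta)) {
    n_theta <- round(2 * pi * R / (3.5 * hi) / 4) * 4
    n_theta <- max(12L, min(48L, as.integer(n_theta)))
  }
  stopifnot(n_theta %% 4 == 0)

  ## --- axial layers ---------------------------------------------------------
  ## cap the axial spacing at half the thread fin spacing so the thread
  ## profile never aliases, whatever the radial size
  fin_sp <- spec@thread@effective_pitch_mm / spec@thread@n_starts
  hz <- max(hi, min(hi * axial_factor, fin_sp / 2))
  ## the crestal band (cortical plate + upper trabecular margin) carries the
  ## reported peaks and the thread-profile detail: resolve the inter-fin free
  ## gap there (half the crest free thickness), coarser hz below
  hz_band <- max(hi, min(hz, spec@thread@free_thickness_mm / 2))
  tcort0 <- solid@bone@spec@cortical_thickness_mm
  band_lo <- max(solid@apex_z, -(tcort0 + 1))
  fine_lo <- max(-H + 1e-9, solid@apex_z - min(1, size@transition_mm / 2))
  zf1 <- seq(0, band_lo, by = -hz_band)
  nfine <- max(2L, ceiling((band_lo - fine_lo) / hz))
  zf2 <- seq(band_lo, fine_lo, length.out = nfine + 1)
  zf <- sort(unique(c(zf1, zf2)), decreasing = TRUE)
  ## snap layers onto geometric/material horizons: the platform level, the
  ## cortical-trabecular boundary, the floor-plate top and the implant apex,
  ## so region tagging produces clean (non-jagged) interfaces
  tcort <- tcort0
  forced <- c(solid@platform_z, -tcort, solid@apex_z, -(H - tcort))
  if (solid@crater_depth_mm > 0) forced <- c(forced, -solid@crater_depth_mm)
  forced <- forced[forced < -1e-9 & forced > fine_lo + 1e-9]
  for (pz in forced) {
    if (min(abs(zf - pz)) > 1e-9) {
      drop <- which.min(abs(zf - pz))
      if (drop > 1 && drop < length(zf)) zf[drop] <- pz else zf <- c(zf, pz)
    }
  }
  zf <- sort(unique(zf), decreasing = TRUE)
  ## coarsen below the fine zone to the floor
  zb <- numeric(0)
  z <- fine_lo
  step <- hz
  while (z > -H + 1e-9) {
    step <- min(step * growth, h0 * 2)
    z <- max(z - step, -H)
    zb <- c(zb, z)
  }
  if (length(zb) >= 2 && (zb[length(zb) - 1] - (-H)) < 0.4 * step)
    zb <- zb[-(length(zb) - 1)]
  floor_top <- -(H - tcort)
  if (floor_top < fine_lo && length(zb) > 1) {
    drop <- which.min(abs(zb - floor_top))
    if (abs(zb[drop] - floor_top) > 1e-9 && drop < length(zb))
      zb[drop] <- floor_top
  }
  ## coarsen above the crest along the abutment
  za <- numeric(0)
  z <- 0
  step <- hz
  while (z < solid@top_z - 1e-9) {
    step <- min(step * growth, 1.2)
    if (solid@top_z - z < 1.6 * step) step <- solid@top_z - z
    z <- min(z + step, solid@top_z)
    za <- c(za, z)
  }
  zlev <- sort(unique(c(za, zf, zb)), decreasing = TRUE)
  nl <- length(zlev)

  ## --- radial template ------------------------------------------------------
  J_in <- max(3L, min(10L, as.integer(ceiling(R / (2.5 * hi)))))
  offs <- numeric(0)
  s <- 0
  step <- hi
  repeat {
    ## hi inside the transition band, geometric growth to h0 beyond it and
    ## to 2 h0 in the far support region (outside any reporting zone)
    if (s >= size@transition_mm) {
      cap <- if (s < 2 * size@transition_mm) h0 else 2 * h0
      step <- min(step * growth, cap)
    }
    s <- s + step
    if (s >= Rd - R) break
    offs <- c(offs, s)
  }
  ## last ring lands exactly on the domain boundary; drop any ring that
  ## would leave a sliver shell against it
  offs <- offs[offs < (Rd - R) - 0.4 * step]
  offs <- c(offs, Rd - R)
  n_out <- length(offs)
  nring <- J_in + n_out
  ## angular nodes: full circle (periodic) or half plane (0..pi inclusive)
  if (symmetry_half) {
    nth_nodes <- n_theta %/% 2L + 1L
    theta <- (seq_len(nth_nodes) - 1) / (n_theta %/% 2L) * pi
  } else {
    nth_nodes <- n_theta
    theta <- (seq_len(n_theta) - 1) / n_theta * 2 * pi
  }
  npl <- 1L + nring * nth_nodes
  ct <- cos(theta); st <- sin(theta)

  ## node coordinates, layer by layer
  nnode <- nl * npl
  nodes <- matrix(0, nnode, 3)
  u_far <- offs / offs[n_out]
  for (l in seq_len(nl)) {
    zl <- zlev[l]
    aa <- solid@columnRadiusFun(theta, rep(zl, nth_nodes))
    a0 <- solid@columnEnvelopeFun(zl)
    base <- (l - 1) * npl
    nodes[base + 1, ] <- c(0, 0, zl)
    rmat <- matrix(0, nring, nth_nodes)
    for (j in seq_len(J_in)) rmat[j, ] <- aa * j / J_in
    for (i in seq_len(n_out)) {
      raw <- aa + offs[i]
      fitted <- (1 - u_far[i]) * raw + u_far[i] * (R + offs[i])
      rmat[J_in + i, ] <- fitted
    }
    idx <- base + 1 + seq_len(nring * nth_nodes)
    rv <- as.vector(t(rmat)) # ring-major, theta fastest
    thv <- rep(ct, nring)
    shv <- rep(st, nring)
    nodes[idx, 1] <- rv * thv
    nodes[idx, 2] <- rv * shv
    nodes[idx, 3] <- zl
  }

  ## --- 2D template triangles (local per-layer indices) ----------------------
  nsect <- if (symmetry_half) nth_nodes - 1L else n_theta
  ringIdx <- function(j, k) {
    kk <- if (symmetry_half) k else ((k - 1L) %% n_theta) + 1L
    1L + (j - 1L) * nth_nodes + kk
  }
  k <- seq_len(nsect)
  fan <- cbind(1L, ringIdx(1L, k), ringIdx(1L, k + 1L))
  quads <- NULL
  for (j in seq_len(nring - 1L)) {
    A <- ringIdx(j, k); B <- ringIdx(j, k + 1L)
    C <- ringIdx(j + 1L, k); D <- ringIdx(j + 1L, k + 1L)
    quads <- rbind(quads, cbind(A, C, D), cbind(A, D, B))
  }
  T2 <- rbind(fan, quads)

  ## --- prisms over layer pairs, split to tets -------------------------------
  ntri <- nrow(T2)
  prisms <- matrix(0L, (nl - 1L) * ntri, 6)
  for (l in seq_len(nl - 1L)) {
    lo <- (l - 1L) * npl # zlev is decreasing: layer l is above layer l+1
    hi_ <- l * npl
    rows <- (l - 1L) * ntri + seq_len(ntri)
    prisms[rows, ] <- cbind(T2 + hi_, T2 + lo) # bottom below, top above
  }
  tets <- .splitPrisms(prisms)

  ## --- region tagging -------------------------------------------------------
  cx <- (nodes[tets[, 1], 1] + nodes[tets[, 2], 1] + nodes[tets[, 3], 1] + nodes[tets[, 4], 1]) / 4
  cy <- (nodes[tets[, 1], 2] + nodes[tets[, 2], 2] + nodes[tets[, 3], 2] + nodes[tets[, 4], 2]) / 4
  cz <- (nodes[tets[, 1], 3] + nodes[tets[, 2], 3] + nodes[tets[, 3], 3] + nodes[tets[, 4], 3]) / 4
  tags <- solid@regionAtFun(cx, cy, cz)
  ## clip to the cylindrical subdomain
  tags[sqrt(cx^2 + cy^2) > Rd + 1e-9] <- "void"

  tol <- 1e-6
  classify <- function(nd, bf) {
    if (!nrow(bf)) {
      return(list(coronal_cuts = bf, load_patch = bf, symmetry_plane = bf,
                  free_surface = bf))
    }
    r1 <- sqrt(nd[bf[, 1], 1]^2 + nd[bf[, 1], 2]^2)
    r2 <- sqrt(nd[bf[, 2], 1]^2 + nd[bf[, 2], 2]^2)
    r3 <- sqrt(nd[bf[, 3], 1]^2 + nd[bf[, 3], 2]^2)
    z1 <- nd[bf[, 1], 3]; z2 <- nd[bf[, 2], 3]; z3 <- nd[bf[, 3], 3]
    sym <- rep(FALSE, nrow(bf))
    if (symmetry_half) {
      ally <- abs(nd[bf[, 1], 2]) < tol & abs(nd[bf[, 2], 2]) < tol &
        abs(nd[bf[, 3], 2]) < tol
      sym <- ally
    }
    lateral <- abs(r1 - Rd) < 1e-4 & abs(r2 - Rd) < 1e-4 & abs(r3 - Rd) < 1e-4
    bottom <- abs(z1 + H) < tol & abs(z2 + H) < tol & abs(z3 + H) < tol
    top <- abs(z1 - solid@top_z) < tol & abs(z2 - solid@top_z) < tol &
      abs(z3 - solid@top_z) < tol
    cuts <- (lateral | bottom) & !top & !sym
    list(coronal_cuts = bf[cuts, , drop = FALSE],
         load_patch = bf[top & !sym, , drop = FALSE],
         symmetry_plane = bf[sym, , drop = FALSE],
         free_surface = bf[!cuts & !top & !sym, , drop = FALSE])
  }

  info <- list(size = size, n_theta = n_theta, J_in = J_in, n_out = n_out,
               n_layers = nl, domain_radius_mm = Rd,
               scenario_label = spec@label, seed = seed,
               symmetry_half = symmetry_half)
  .assembleTet10Mesh(nodes, tets, tags, classify, info, quality_floor)
}

## ---- benchmark meshes ------------------------------------------------------

#' Structured tet10 mesh of a box
#'
#' Benchmark/calibration mesh: a box split into cubes, prisms and then
#' tetrahedra with the same conforming diagonal rule as the scenario mesher.
#' Face groups are the six sides (\code{xmin}, \code{xmax}, ..., \code{zmax}).
#'
#' @param lx,ly,lz box edge lengths
#' @param h target edge length (isotropic)
#' @param region region tag for all elements
#' @return a \code{\link{Tet10Mesh}}
#' @export
meshBox <- function(lx = 1, ly = 1, lz = 1, h = 0.25, region = "domain") {
  ## tets from cube splitting mix axis edges with face/body diagonals (mean
  ## edge ~1.26x the grid step), so the grid step is calibrated accordingly
  nx <- max(1L, round(1.25 * lx / h)); ny <- max(1L, round(1.25 * ly / h))
  nz <- max(1L, round(1.25 * lz / h))
  xs <- seq(0, lx, length.out = nx + 1)
  ys <- seq(0, ly, length.out = ny + 1)
  zs <- seq(0, lz, length.out = nz + 1)
  nid <- function(i, j, l) ((l - 1L) * (ny + 1L) + (j - 1L)) * (nx + 1L) + i
  nodes <- as.matrix(expand.grid(x = xs, y = ys, z = zs))
  colnames(nodes) <- NULL
  ij <- expand.grid(i = seq_len(nx), j = seq_len(ny))
  ## split each xy cell into two triangles (consistent diagonal)
  A <- nid(ij$i, ij$j, 1L); B <- nid(ij$i + 1L, ij$j, 1L)
  C <- nid(ij$i, ij$j + 1L, 1L); D <- nid(ij$i + 1L, ij$j + 1L, 1L)
  T2 <- rbind(cbind(A, B, D), cbind(A, D, C))
  npl <- (nx + 1L) * (ny + 1L)
  prisms <- NULL
  for (l in seq_len(nz)) {
    lo <- (l - 1L) * npl; up <- l * npl
    prisms <- rbind(prisms, cbind(T2 + lo, T2 + up))
  }
  tets <- .splitPrisms(prisms)
  tags <- rep(region, nrow(tets))
  tol <- 1e-9
  classify <- function(nd, bf) {
    co <- function(d, v) abs(nd[bf[, 1], d] - v) < tol & abs(nd[bf[, 2], d] - v) < tol &
      abs(nd[bf[, 3], d] - v) < tol
    list(xmin = bf[co(1, 0), , drop = FALSE], xmax = bf[co(1, lx), , drop = FALSE],
         ymin = bf[co(2, 0), , drop = FALSE], ymax = bf[co(2, ly), , drop = FALSE],
         zmin = bf[co(3, 0), , drop = FALSE], zmax = bf[co(3, lz), , drop = FALSE])
  }
  .assembleTet10Mesh(nodes, tets, tags, classify,
                     list(kind = "box", h = h), 0.01)
}

#' Structured tet10 mesh of a hollow cylinder
#'
#' Benchmark mesh for the thick-walled (Lame) cylinder problem.  Face groups:
#' \code{inner}, \code{outer}, \code{zmin}, \code{zmax}.
#'
#' @param r_in,r_out inner and outer radii
#' @param height axial extent
#' @param nr,ntheta,nz radial/angular/axial divisions (\code{ntheta} a
#'   multiple of 4)
#' @param region region tag
#' @return a \code{\link{Tet10Mesh}}
#' @export
meshTube <- function(r_in, r_out, height, nr = 4, ntheta = 16, nz = 2,
                     region = "domain") {
  stopifnot(ntheta %% 4 == 0, r_in > 0, r_out > r_in)
  rs <- seq(r_in, r_out, length.out = nr + 1)
  theta <- (seq_len(ntheta) - 1) / ntheta * 2 * pi
  zs <- seq(0, height, length.out = nz + 1)
  npl <- (nr + 1L) * ntheta
  nodes <- matrix(0, npl * (nz + 1L), 3)
  for (l in seq_len(nz + 1L)) {
    idx <- (l - 1L) * npl + seq_len(npl)
    rv <- rep(rs, each = ntheta)
    tv <- rep(theta, nr + 1L)
    nodes[idx, ] <- cbind(rv * cos(tv), rv * sin(tv), zs[l])
  }
  rid <- function(j, k) (j - 1L) * ntheta + ((k - 1L) %% ntheta) + 1L
  k <- seq_len(ntheta)
  T2 <- NULL
  for (j in seq_len(nr)) {
    A <- rid(j, k); B <- rid(j, k + 1L); C <- rid(j + 1L, k); D <- rid(j + 1L, k + 1L)
    T2 <- rbind(T2, cbind(A, C, D), cbind(A, D, B))
  }
  prisms <- NULL
  for (l in seq_len(nz)) {
    lo <- (l - 1L) * npl; up <- l * npl
    prisms <- rbind(prisms, cbind(T2 + lo, T2 + up))
  }
  tets <- .splitPrisms(prisms)
  tags <- rep(region, nrow(tets))
  tol <- 1e-7
  classify <- function(nd, bf) {
    rr <- function(i) sqrt(nd[bf[, i], 1]^2 + nd[bf[, i], 2]^2)
    r1 <- rr(1); r2 <- rr(2); r3 <- rr(3)
    z1 <- nd[bf[, 1], 3]; z2 <- nd[bf[, 2], 3]; z3 <- nd[bf[, 3], 3]
    inner <- abs(r1 - r_in) < tol & abs(r2 - r_in) < tol & abs(r3 - r_in) < tol
    outer <- abs(r1 - r_out) < tol & abs(r2 - r_out) < tol & abs(r3 - r_out) < tol
    zmin <- abs(z1) < tol & abs(z2) < tol & abs(z3) < tol
    zmax <- abs(z1 - height) < tol & abs(z2 - height) < tol & abs(z3 - height) < tol
    list(inner = bf[inner, , drop = FALSE], outer = bf[outer, , drop = FALSE],
         zmin = bf[zmin & !inner & !outer, , drop = FALSE],
         zmax = bf[zmax & !inner & !outer, , drop = FALSE])
  }
  .assembleTet10Mesh(nodes, tets, tags, classify,
                     list(kind = "tube"), 0.01)
}
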