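#' @include meshing.R
NULL

## Linear isotropic elasticity on Tet10Mesh: assembly, boundary conditions,
## direct sparse solution and Gauss-point stress evaluation.

#' Assembled finite-element system
#'
#' @slot K symmetric sparse stiffness matrix (3 dof per node)
#' @slot mesh the \code{\link{Tet10Mesh}}
#' @slot E_elem,nu_elem per-element material parameters
#' @slot f global load vector
#' @slot fixed_dofs integer vector of constrained dofs (homogeneous)
#' @export
setClass("FESystem", representation(
  K = "ANY", mesh = "Tet10Mesh", E_elem = "numeric", nu_elem = "numeric",
  f = "numeric", fixed_dofs = "integer"))

#' Displacement solution
#'
#' @slot u numeric matrix n x 3 of nodal displacements (mm)
#' @slot mesh the mesh the field lives on
#' @slot residual relative residual of the linear solve
#' @export
setClass("DisplacementField", representation(
  u = "matrix", mesh = "Tet10Mesh", residual = "numeric"))

#' Gauss-point stress field
#'
#' Symmetric stress tensors in Voigt order (xx, yy, zz, xy, yz, xz) at the
#' four-point quadrature rule of every element.
#'
#' @slot sigma m x 24 matrix (4 Gauss points x 6 components)
#' @slot wdet m x 4 integration weights (quadrature weight x |J|)
#' @slot pts m x 12 physical Gauss point coordinates
#' @slot regionTag per-element region tags (copied from the mesh)
#' @slot quadrature rule identifier
#' @export
setClass("StressField", representation(
  sigma = "matrix", wdet = "matrix", pts = "matrix", regionTag = "character",
  quadrature = "character"))

.materialVectors <- function(mesh, materials) {
  tags <- unique(mesh@regionTag)
  miss <- setdiff(tags, names(materials))
  if (length(miss))
    stop("materials missing for region(s): ", paste(miss, collapse = ", "))
  E <- vapply(materials, function(m) m@E_MPa, 1)[mesh@regionTag]
  nu <- vapply(materials, function(m) m@nu, 1)[mesh@regionTag]
  list(E = unname(E), nu = unname(nu))
}

#' Assemble the global stiffness matrix
#'
#' Pure displacement formulation, 4-point quadrature per tet10 element.
#' The unconstrained matrix is symmetric positive-semidefinite with the
#' 6-dimensional rigid-body null space.
#'
#' @param mesh a \code{\link{Tet10Mesh}}
#' @param materials named list of \code{\link{materialModel}} covering all
#'   region tags in the mesh
#' @return an \code{FESystem} (no loads or constraints yet)
#' @export
assembleSystem <- function(mesh, materials) {
  mv <- .materialVectors(mesh, materials)
  tr <- tet10_assemble(mesh@nodes, mesh@elems, mv$E, mv$nu)
  ndof <- 3L * nrow(mesh@nodes)
  K <- Matrix::sparseMatrix(i = tr$i, j = tr$j, x = tr$x,
                            dims = c(ndof, ndof), symmetric = TRUE)
  new("FESystem", K = K, mesh = mesh, E_elem = mv$E, nu_elem = mv$nu,
      f = numeric(ndof), fixed_dofs = integer(0))
}

.faceCornerAreas <- function(nodes, faces) {
  a <- nodes[faces[, 1], , drop = FALSE]
  b <- nodes[faces[, 2], , drop = FALSE]
  c <- nodes[faces[, 3], , drop = FALSE]
  u <- b - a; v <- c - a
  cx <- u[, 2] * v[, 3] - u[, 3] * v[, 2]
  cy <- u[, 3] * v[, 1] - u[, 1] * v[, 3]
  cz <- u[, 1] * v[, 2] - u[, 2] * v[, 1]
  0.5 * sqrt(cx^2 + cy^2 + cz^2)
}

#' Apply boundary conditions and the functional load
#'
#' Fixes all displacement dofs on the \code{coronal_cuts} face group and
#' applies a uniform traction over the load patch on the abutment top,
#' statically equivalent to (F_lateral, 0, -F_vertical) through the implant
#' axis.  Consistent quadratic nodal forces are used (for a uniform traction
#' on straight 6-node triangles the whole force goes to the mid-edge nodes,
#' one third of t*A each).  For symmetric half-domain meshes the y
#' displacement is fixed on the symmetry plane and half the load is applied.
#'
#' @param sys an \code{\link{assembleSystem}} result
#' @param load a \code{\link{loadCase}}
#' @return the \code{FESystem} with \code{f} and \code{fixed_dofs} set
#' @export
applyBCsAndLoad <- function(sys, load) {
  mesh <- sys@mesh
  cuts <- mesh@faceGroups$coronal_cuts
  patch <- mesh@faceGroups$load_patch
  if (is.null(cuts) || !nrow(cuts)) stop("empty coronal_cuts face group")
  if (is.null(patch) || !nrow(patch)) stop("empty load_patch face group")
  ## restrict the patch to the requested radius around the axis
  cen <- (mesh@nodes[patch[, 1], 1:2, drop = FALSE] +
          mesh@nodes[patch[, 2], 1:2, drop = FALSE] +
          mesh@nodes[patch[, 3], 1:2, drop = FALSE]) / 3
  rad <- sqrt(rowSums(cen^2))
  sel <- rad <= load@patch_radius_mm + 1e-9
  if (!any(sel)) sel <- rep(TRUE, nrow(patch))
  patch <- patch[sel, , drop = FALSE]
  A <- .faceCornerAreas(mesh@nodes, patch)
  Atot <- sum(A)
  Fvec <- c(load@F_lateral_N, 0, -load@F_vertical_N)
  half <- isTRUE(mesh@info$symmetry_half)
  if (half) Fvec <- Fvec / 2
  f <- numeric(3L * nrow(mesh@nodes))
  for (d in 1:3) {
    idx <- as.vector(patch[, 4:6])
    w <- rep(Fvec[d] / Atot * A / 3, 3)
    acc <- tapply(w, idx, sum)
    ids <- as.integer(names(acc))
    f[3 * (ids - 1) + d] <- f[3 * (ids - 1) + d] + as.numeric(acc)
  }
  fixedNodes <- sort(unique(as.vector(cuts)))
  fixed <- c(3 * (fixedNodes - 1) + 1, 3 * (fixedNodes - 1) + 2,
             3 * (fixedNodes - 1) + 3)
  if (half && !is.null(mesh@faceGroups$symmetry_plane) &&
      nrow(mesh@faceGroups$symmetry_plane)) {
    symNodes <- sort(unique(as.vector(mesh@faceGroups$symmetry_plane)))
    fixed <- c(fixed, 3 * (symNodes - 1) + 2) # u_y = 0 on the plane
  }
  sys@f <- f
  sys@fixed_dofs <- as.integer(sort(unique(fixed)))
  sys
}

#' Fix arbitrary dofs (homogeneous constraints)
#'
#' Low-level alternative to \code{\link{applyBCsAndLoad}} for benchmark
#' problems: constrain the listed dofs to the given values and/or set a
#' custom load vector.
#'
#' @param sys an \code{FESystem}
#' @param fixed_dofs integer dof indices (dof = 3*(node-1)+component)
#' @param f optional load vector
#' @return the updated \code{FESystem}
#' @export
constrainSystem <- function(sys, fixed_dofs, f = NULL) {
  sys@fixed_dofs <- as.integer(sort(unique(fixed_dofs)))
  if (!is.null(f)) sys@f <- f
  sys
}

#' Solve the constrained linear system
#'
#' Direct sparse Cholesky factorization (deterministic).  Supports
#' inhomogeneous constraints via \code{u_fixed}.
#'
#' @param sys an \code{FESystem} with constraints applied
#' @param u_fixed values for the fixed dofs (default 0)
#' @return a \code{\link{DisplacementField}}
#' @export
solveSystem <- function(sys, u_fixed = NULL) {
  ndof <- length(sys@f)
  if (!length(sys@fixed_dofs))
    stop("system is singular: no constraints applied (rigid-body modes)")
  free <- setdiff(seq_len(ndof), sys@fixed_dofs)
  K <- sys@K
  rhs <- sys@f[free]
  ufix <- if (is.null(u_fixed)) numeric(length(sys@fixed_dofs)) else u_fixed
  if (any(ufix != 0))
    rhs <- rhs - as.numeric(K[free, sys@fixed_dofs, drop = FALSE] %*% ufix)
  Kff <- K[free, free, drop = FALSE]
  ch <- Matrix::Cholesky(Matrix::forceSymmetric(Kff), LDL = FALSE, super = TRUE)
  uf <- as.numeric(Matrix::solve(ch, rhs, system = "A"))
  u <- numeric(ndof)
  u[free] <- uf
  u[sys@fixed_dofs] <- ufix
  res <- sqrt(sum((as.numeric(Kff %*% uf) - rhs)^2))
  den <- sqrt(sum(rhs^2))
  rel <- if (den > 0) res / den else res
  if (is.finite(rel) && den > 0 && rel > 1e-8)
    warning("large relative residual: ", format(rel))
  new("DisplacementField", u = matrix(u, ncol = 3, byrow = TRUE),
      mesh = sys@mesh, residual = rel)
}

#' Evaluate stresses at element Gauss points
#'
#' sigma = C : eps(u) with the isotropic elasticity tensor of each element's
#' region, at the 4-point rule.
#'
#' @param mesh a \code{\link{Tet10Mesh}}
#' @param materials material map (as in \code{\link{assembleSystem}})
#' @param u a \code{\link{DisplacementField}} (or displacement matrix)
#' @return a \code{\link{StressField}}
#' @export
stressAtGauss <- function(mesh, materials, u) {
  if (is(u, "DisplacementField")) u <- u@u
  mv <- .materialVectors(mesh, materials)
  res <- tet10_stress(mesh@nodes, mesh@elems, mv$E, mv$nu,
                      as.numeric(t(u)))
  new("StressField", sigma = res$sigma, wdet = res$wdet, pts = res$pts,
      regionTag = mesh@regionTag, quadrature = "tet10-4pt")
}

#' Reaction forces on the constrained dofs
#'
#' @param sys the solved \code{FESystem}
#' @param u the \code{\link{DisplacementField}}
#' @return 3-vector of total reaction force (N)
#' @export
reactionForces <- function(sys, u) {
  if (is(u, "DisplacementField")) u <- u@u
  r <- as.numeric(sys@K %*% as.numeric(t(u))) - sys@f
  rf <- r[sys@fixed_dofs]
  comp <- (sys@fixed_dofs - 1) %% 3 + 1
  vapply(1:3, function(d) sum(rf[comp == d]), 1)
}

#' Strain energy of a solution
#' @param sys the \code{FESystem}
#' @param u the \code{\link{DisplacementField}}
#' @return elastic strain energy (N mm)
#' @export
strainEnergy <- function(sys, u) {
  if (is(u, "DisplacementField")) u <- u@u
  uv <- as.numeric(t(u))
  0.5 * sum(uv * as.numeric(sys@K %*% uv))
}

#' External work of the applied loads
#' @param sys the \code{FESystem}
#' @param u the \code{\link{DisplacementField}}
#' @return work (N mm); equals the strain energy for a linear problem
#' @export
externalWork <- function(sys, u) {
  if (is(u, "DisplacementField")) u <- u@u
  0.5 * sum(sys@f * as.numeric(t(u)))
}
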