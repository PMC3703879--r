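#' @include fem.R
NULL

## Zienkiewicz-Zhu stress recovery, error norms and mesh-convergence driver.

#' Recovered (nodal) stress field
#'
#' Nodal stress tensors recovered per material region: no averaging is
#' performed across material interfaces (stress is discontinuous there), so
#' interface nodes carry one value per adjacent region.
#'
#' @slot nodal named list (one entry per material group) of n x 6 matrices,
#'   NA at nodes not touching the group
#' @slot groups named list: element index vector per material group
#' @slot mode \code{"average"} or \code{"spr"}
#' @export
setClass("RecoveredStress", representation(
  nodal = "list", groups = "list", mode = "character"))

#' Convergence / error report
#'
#' @slot energy_error_norm_pct global relative energy-norm error estimate (%)
#' @slot displacement_error_norm_pct relative L2 displacement change between
#'   successive refinements (%); NA for the first mesh of a schedule
#' @slot per_region data.frame with the per-region energy-error breakdown
#' @slot converged logical
#' @slot level index of the accepted mesh in the schedule
#' @slot schedule the hi/D schedule walked
#' @export
setClass("ErrorReport", representation(
  energy_error_norm_pct = "numeric", displacement_error_norm_pct = "numeric",
  per_region = "data.frame", converged = "logical", level = "numeric",
  schedule = "numeric"))

setMethod("show", "ErrorReport", function(object) {
  cat(sprintf("ErrorReport: energy %.2f%%, displacement %s%%, converged: %s\n",
              object@energy_error_norm_pct,
              ifelse(is.na(object@displacement_error_norm_pct), "NA",
                     sprintf("%.3f", object@displacement_error_norm_pct)),
              object@converged))
})

## material groups: elements sharing identical (E, nu)
.materialGroups <- function(mesh, materials) {
  mv <- .materialVectors(mesh, materials)
  key <- paste0(mv$E, "/", mv$nu)
  split(seq_len(nElements(mesh)), key)
}

#' Recover nodal stresses (Zienkiewicz-Zhu)
#'
#' \code{mode = "average"} uses volume-weighted averaging of element-mean
#' stresses over each nodal patch; \code{mode = "spr"} fits a linear
#' polynomial to the Gauss values of the nodal patch (superconvergent patch
#' recovery), exact for fields linear in the coordinates.  Both operate
#' region-by-region so no information crosses the bone-implant or
#' cortical-trabecular interfaces.
#'
#' @param mesh the \code{\link{Tet10Mesh}}
#' @param materials material map (defines the recovery regions)
#' @param stress a \code{\link{stressAtGauss}} result
#' @param mode recovery mode
#' @return a \code{\link{RecoveredStress}}
#' @export
recoverStress <- function(mesh, materials, stress, mode = c("average", "spr")) {
  mode <- match.arg(mode)
  groups <- .materialGroups(mesh, materials)
  n <- nNodes(mesh)
  nodal <- lapply(groups, function(eidx) {
    el <- mesh@elems[eidx, , drop = FALSE]
    used <- sort(unique(as.vector(el)))
    if (!length(setdiff(seq_len(n), used)) || TRUE) {
      ## build a compact submesh for recovery
      remap <- integer(n)
      remap[used] <- seq_along(used)
      sub <- matrix(remap[el], nrow(el), 10)
      avg <- tet10_recover_avg(mesh@nodes[used, , drop = FALSE], sub,
                               stress@sigma[eidx, , drop = FALSE])
      if (mode == "spr") {
        avg <- tet10_recover_spr(mesh@nodes[used, , drop = FALSE], sub,
                                 stress@sigma[eidx, , drop = FALSE],
                                 stress@pts[eidx, , drop = FALSE], avg)
      }
      out <- matrix(NA_real_, n, 6)
      out[used, ] <- avg
      out
    }
  })
  new("RecoveredStress", nodal = nodal, groups = groups, mode = mode)
}


#' Evaluate a recovered stress field at the element Gauss points
#'
#' Interpolates the region-wise nodal recovered tensors back to the 4-point
#' quadrature of every element, yielding a smoothed Gauss stress table in the
#' same layout as \code{\link{stressAtGauss}} (useful for reporting
#' statistics the way contour postprocessors do, from nodal-averaged data).
#'
#' @param mesh the \code{\link{Tet10Mesh}}
#' @param stress the raw \code{\link{stressAtGauss}} result (supplies
#'   weights, points and layout)
#' @param rec a \code{\link{recoverStress}} result
#' @return a \code{\link{StressField}} with smoothed \code{sigma}
#' @export
recoveredAtGauss <- function(mesh, stress, rec) {
  sig <- stress@sigma
  out <- sig
  for (g in names(rec@groups)) {
    eidx <- rec@groups[[g]]
    snod <- rec@nodal[[g]]
    snod[is.na(snod)] <- 0
    sub <- mesh@elems[eidx, , drop = FALSE]
    a <- 0.5854101966249685; b <- 0.1381966011250105
    for (gp in 1:4) {
      L <- rep(b, 4); L[gp] <- a
      N <- c(L[1] * (2 * L[1] - 1), L[2] * (2 * L[2] - 1),
             L[3] * (2 * L[3] - 1), L[4] * (2 * L[4] - 1),
             4 * L[1] * L[2], 4 * L[2] * L[3], 4 * L[1] * L[3],
             4 * L[1] * L[4], 4 * L[2] * L[4], 4 * L[3] * L[4])
      acc <- 0
      for (i in 1:10) acc <- acc + N[i] * snod[sub[, i], , drop = FALSE]
      out[eidx, (6 * gp - 5):(6 * gp)] <- acc
    }
  }
  new("StressField", sigma = out, wdet = stress@wdet, pts = stress@pts,
      regionTag = stress@regionTag, quadrature = stress@quadrature)
}

#' Global relative energy error norm (percent)
#'
#' The classic recovery-based estimate: the energy norm of the difference
#' between the recovered and the raw Gauss stress fields, normalized by the
#' total (recovered + error) energy:
#' 100 * sqrt( E_err / (U_star + E_err) ).
#'
#' @param mesh the mesh
#' @param materials material map
#' @param raw \code{\link{stressAtGauss}} result
#' @param rec \code{\link{recoverStress}} result
#' @return percentage; the per-region breakdown is attached as attribute
#'   \code{"per_region"}
#' @export
energyErrorNorm <- function(mesh, materials, raw, rec) {
  mv <- .materialVectors(mesh, materials)
  tot_err <- 0; tot_u <- 0
  rows <- list()
  for (g in names(rec@groups)) {
    eidx <- rec@groups[[g]]
    snod <- rec@nodal[[g]]
    snod[is.na(snod)] <- 0 # untouched nodes are never interpolated
    ints <- tet10_zz_integrals(mesh@nodes, mesh@elems[eidx, , drop = FALSE],
                               mv$E[eidx], mv$nu[eidx],
                               raw@sigma[eidx, , drop = FALSE], snod)
    err <- sum(ints[, 1]); ust <- sum(ints[, 2])
    tot_err <- tot_err + err; tot_u <- tot_u + ust
    rows[[g]] <- data.frame(group = g, err_energy = err, star_energy = ust,
                            pct = 100 * sqrt(err / max(err + ust, 1e-300)))
  }
  if (tot_u + tot_err <= 0) stop("zero strain energy: no load applied")
  out <- 100 * sqrt(tot_err / (tot_u + tot_err))
  attr(out, "per_region") <- do.call(rbind, rows)
  out
}

#' Relative displacement error norm between successive meshes (percent)
#'
#' 100 * ||u_fine - P u_coarse||_L2 / ||u_fine||_L2, with P the interpolation
#' of the coarse solution onto the fine mesh, both norms integrated with the
#' fine mesh quadrature.
#'
#' @param u_coarse,u_fine \code{\link{DisplacementField}} objects from two
#'   refinement levels of the same geometry
#' @return percentage
#' @export
displacementErrorNorm <- function(u_coarse, u_fine) {
  fm <- u_fine@mesh
  stress_pts <- tet10_stress(fm@nodes, fm@elems, rep(1, nElements(fm)),
                             rep(0, nElements(fm)),
                             as.numeric(t(u_fine@u)))
  pts <- stress_pts$pts
  wdet <- stress_pts$wdet
  ## fine solution at its own Gauss points via shape interpolation
  gw <- c(0.5854101966249685, 0.1381966011250105)
  uf <- .valuesAtGauss(fm, u_fine@u)
  ## coarse solution interpolated at the fine Gauss points
  qpts <- rbind(pts[, 1:3, drop = FALSE], pts[, 4:6, drop = FALSE],
                pts[, 7:9, drop = FALSE], pts[, 10:12, drop = FALSE])
  itp <- tet10_interp(u_coarse@mesh@nodes, u_coarse@mesh@elems, u_coarse@u,
                      qpts, 1e-8)
  found <- itp$found
  if (mean(found) < 0.99)
    warning(sprintf("%.1f%% of fine Gauss points not located in the coarse mesh",
                    100 * mean(!found)))
  w <- c(wdet[, 1], wdet[, 2], wdet[, 3], wdet[, 4])
  d2 <- rowSums((uf - itp$values)^2)
  n2 <- rowSums(uf^2)
  d2[!found] <- 0; n2[!found] <- 0
  den <- sum(w * n2)
  if (den <= 0) stop("zero fine-solution norm")
  100 * sqrt(sum(w * d2) / den)
}

## nodal field values at the 4 Gauss points of every element, stacked by
## Gauss point (4m x q)
.valuesAtGauss <- function(mesh, vals) {
  a <- 0.5854101966249685; b <- 0.1381966011250105
  Nmat <- sapply(1:4, function(g) {
    L <- rep(b, 4); L[g] <- a
    c(L[1] * (2 * L[1] - 1), L[2] * (2 * L[2] - 1), L[3] * (2 * L[3] - 1),
      L[4] * (2 * L[4] - 1), 4 * L[1] * L[2], 4 * L[2] * L[3], 4 * L[1] * L[3],
      4 * L[1] * L[4], 4 * L[2] * L[4], 4 * L[3] * L[4])
  })
  out <- NULL
  for (g in 1:4) {
    acc <- 0
    for (i in 1:10) acc <- acc + Nmat[i, g] * vals[mesh@elems[, i], , drop = FALSE]
    out <- rbind(out, acc)
  }
  out
}

#' Walk a mesh-refinement schedule until the error norms pass
#'
#' Meshes and solves the scenario for each hi/D ratio in the schedule, in
#' order.  A mesh is certified when its recovery-based energy error norm is
#' below \code{energy_max_pct} and the relative displacement change to its
#' next refinement is below \code{disp_max_pct}; the first certified mesh is
#' returned.  If none certifies, the finest mesh is returned with
#' \code{converged = FALSE} (a schedule of length 1 can never certify the
#' displacement norm and is returned with honest flags).
#'
#' @param solid a \code{\link{buildScenarioSolid}} result
#' @param schedule decreasing vector of hi/D ratios
#'   (default \code{c(0.1, 0.05, 0.025)})
#' @param energy_max_pct energy error norm threshold (default 5)
#' @param disp_max_pct displacement error norm threshold (default 0.5)
#' @param h0_ratio far-field size ratio
#' @param recovery_mode passed to \code{\link{recoverStress}}
#' @param ... further arguments to \code{\link{meshScenario}}
#' @return list with elements \code{mesh}, \code{u}, \code{stress},
#'   \code{report} (an \code{\link{ErrorReport}}) and \code{history}
#'   (data.frame of all levels walked)
#' @export
convergeMesh <- function(solid, schedule = c(0.1, 0.05, 0.025),
                         energy_max_pct = 5, disp_max_pct = 0.5,
                         h0_ratio = 0.1, recovery_mode = "spr", ...) {
  stopifnot(all(diff(schedule) < 0))
  materials <- solid@scenario@materials
  D <- solid@scenario@implant@D_mm
  hist <- NULL
  levels <- list()
  solveLevel <- function(r) {
    size <- makeSizeField(D, h0_ratio, r)
    mesh <- meshScenario(solid, size, ...)
    sys <- applyBCsAndLoad(assembleSystem(mesh, materials),
                           solid@scenario@load)
    u <- solveSystem(sys)
    stress <- stressAtGauss(mesh, materials, u)
    rec <- recoverStress(mesh, materials, stress, mode = recovery_mode)
    en <- as.numeric(energyErrorNorm(mesh, materials, stress, rec))
    list(mesh = mesh, u = u, stress = stress, energy = en)
  }
  accepted <- NULL
  for (k in seq_along(schedule)) {
    levels[[k]] <- solveLevel(schedule[k])
    dn <- if (k >= 2) displacementErrorNorm(levels[[k - 1]]$u, levels[[k]]$u)
          else NA_real_
    hist <- rbind(hist, data.frame(level = k, hi_ratio = schedule[k],
                                   n_nodes = nNodes(levels[[k]]$mesh),
                                   n_elems = nElements(levels[[k]]$mesh),
                                   energy_pct = levels[[k]]$energy,
                                   disp_to_next_pct = NA_real_))
    if (k >= 2) hist$disp_to_next_pct[k - 1] <- dn
    if (k >= 2 && levels[[k - 1]]$energy <= energy_max_pct &&
        dn <= disp_max_pct) {
      accepted <- list(idx = k - 1, disp = dn, converged = TRUE)
      break
    }
  }
  if (is.null(accepted)) {
    k <- length(levels)
    dn <- if (k >= 2) hist$disp_to_next_pct[k - 1] else NA_real_
    accepted <- list(idx = k, disp = dn, converged = FALSE)
  }
  acc <- levels[[accepted$idx]]
  rep <- new("ErrorReport",
             energy_error_norm_pct = acc$energy,
             displacement_error_norm_pct = accepted$disp,
             per_region = data.frame(),
             converged = accepted$converged,
             level = accepted$idx, schedule = schedule)
  list(mesh = acc$mesh, u = acc$u, stress = acc$stress,
       report = rep, history = hist)
}
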