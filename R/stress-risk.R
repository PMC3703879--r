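#' @include fem.R
NULL

## Principal-stress measures, the overloading risk index and the
## peri-implant control-volume statistics.

#' Tissue strength limits
#'
#' Admissible stress levels in pure traction and compression used by the
#' overloading risk index: cortical bone 180 / 115 MPa, trabecular bone
#' 5 / 5 MPa.
#'
#' @slot sigma_T0_MPa admissible traction
#' @slot sigma_C0_MPa admissible compression
#' @slot tissue tissue tag
#' @export
setClass("StrengthLimits", representation(
  sigma_T0_MPa = "numeric", sigma_C0_MPa = "numeric", tissue = "character"
), validity = function(object) {
  if (object@sigma_T0_MPa <= 0 || object@sigma_C0_MPa <= 0)
    return("strength limits must be positive")
  TRUE
})

#' Construct StrengthLimits
#' @param sigma_T0_MPa admissible traction (MPa)
#' @param sigma_C0_MPa admissible compression (MPa)
#' @param tissue tissue tag
#' @return a \code{StrengthLimits}
#' @export
strengthLimits <- function(sigma_T0_MPa, sigma_C0_MPa, tissue) {
  obj <- new("StrengthLimits", sigma_T0_MPa = sigma_T0_MPa,
             sigma_C0_MPa = sigma_C0_MPa, tissue = tissue)
  validObject(obj)
  obj
}

#' Default bone strength limits
#' @return named list with \code{cortical} and \code{trabecular} entries
#' @examples defaultStrengthLimits()$cortical@sigma_C0_MPa  # 115
#' @export
defaultStrengthLimits <- function() {
  list(cortical = strengthLimits(180, 115, "cortical"),
       trabecular = strengthLimits(5, 5, "trabecular"))
}

#' Principal stresses of symmetric stress tensors
#'
#' Accepts a single symmetric 3x3 matrix or an m x 6 Voigt matrix
#' (xx, yy, zz, xy, yz, xz) and returns eigenvalues sorted descending.
#' Uses the closed-form trigonometric solution for the symmetric 3x3
#' eigenproblem, vectorized over rows.
#'
#' @param tensor symmetric 3x3 matrix or m x 6 Voigt matrix
#' @return numeric vector (sigma1, sigma2, sigma3) or m x 3 matrix, descending
#' @examples
#' principalStresses(diag(c(3, 1, -2)))
#' @export
principalStresses <- function(tensor) {
  single <- is.matrix(tensor) && nrow(tensor) == 3 && ncol(tensor) == 3
  if (single) {
    if (max(abs(tensor - t(tensor))) > 1e-8 * max(1, max(abs(tensor))))
      stop("stress tensor must be symmetric")
    v <- c(tensor[1, 1], tensor[2, 2], tensor[3, 3],
           tensor[1, 2], tensor[2, 3], tensor[1, 3])
    tensor <- matrix(v, 1, 6)
  }
  xx <- tensor[, 1]; yy <- tensor[, 2]; zz <- tensor[, 3]
  xy <- tensor[, 4]; yz <- tensor[, 5]; xz <- tensor[, 6]
  q <- (xx + yy + zz) / 3
  p2 <- (xx - q)^2 + (yy - q)^2 + (zz - q)^2 + 2 * (xy^2 + yz^2 + xz^2)
  p <- sqrt(pmax(p2 / 6, 0))
  ## det of (A - qI)/p, guarded for the hydrostatic case
  ps <- ifelse(p > 0, p, 1)
  bxx <- (xx - q) / ps; byy <- (yy - q) / ps; bzz <- (zz - q) / ps
  bxy <- xy / ps; byz <- yz / ps; bxz <- xz / ps
  detB <- bxx * (byy * bzz - byz^2) - bxy * (bxy * bzz - byz * bxz) +
    bxz * (bxy * byz - byy * bxz)
  r <- pmin(pmax(detB / 2, -1), 1)
  phi <- acos(r) / 3
  e1 <- q + 2 * p * cos(phi)
  e3 <- q + 2 * p * cos(phi + 2 * pi / 3)
  e2 <- 3 * q - e1 - e3
  out <- cbind(e1, e2, e3)
  hyd <- p == 0
  if (any(hyd)) out[hyd, ] <- cbind(q, q, q)[hyd, ]
  colnames(out) <- c("sigma1", "sigma2", "sigma3")
  if (single) out[1, ] else out
}

#' Maximum compressive / tensile principal stress measures
#'
#' sigmaC = min(sigma1, sigma2, sigma3, 0) and
#' sigmaT = max(sigma1, sigma2, sigma3, 0): the local maximum compressive
#' stress (always <= 0) and maximum tensile stress (always >= 0).
#'
#' @param prin vector (sigma1, sigma2, sigma3) or m x 3 matrix
#' @return list with \code{sigma_C} and \code{sigma_T}
#' @examples
#' sigmaCT(c(3, 1, -2))  # sigma_C = -2, sigma_T = 3
#' @export
sigmaCT <- function(prin) {
  if (is.null(dim(prin))) prin <- matrix(prin, 1)
  sC <- pmin(prin[, 1], prin[, 2], prin[, 3], 0)
  sT <- pmax(prin[, 1], prin[, 2], prin[, 3], 0)
  list(sigma_C = unname(sC), sigma_T = unname(sT))
}

#' Von Mises equivalent stress
#'
#' @param tensor symmetric 3x3 matrix or m x 6 Voigt matrix
#' @return scalar or vector, >= 0, invariant to hydrostatic shifts
#' @examples
#' vonMises(diag(c(5, 0, 0)))  # = 5
#' @export
vonMises <- function(tensor) {
  single <- is.matrix(tensor) && nrow(tensor) == 3 && ncol(tensor) == 3
  if (single) {
    v <- c(tensor[1, 1], tensor[2, 2], tensor[3, 3],
           tensor[1, 2], tensor[2, 3], tensor[1, 3])
    tensor <- matrix(v, 1, 6)
  }
  out <- sqrt(pmax(0,
    0.5 * ((tensor[, 1] - tensor[, 2])^2 + (tensor[, 2] - tensor[, 3])^2 +
           (tensor[, 3] - tensor[, 1])^2) +
    3 * (tensor[, 4]^2 + tensor[, 5]^2 + tensor[, 6]^2)))
  if (single) out[1] else out
}

#' Overloading risk index
#'
#' R = |sigmaC| / sigmaC0 + sigmaT / sigmaT0.  R > 1 flags a locally
#' critical bone state with respect to overloading.
#'
#' @param sigma_C maximum compressive stress (<= 0), MPa
#' @param sigma_T maximum tensile stress (>= 0), MPa
#' @param limits a \code{\link{strengthLimits}}
#' @return risk index, >= 0
#' @examples
#' riskIndex(-115, 0, defaultStrengthLimits()$cortical)  # = 1
#' @export
riskIndex <- function(sigma_C, sigma_T, limits) {
  if (limits@sigma_T0_MPa <= 0 || limits@sigma_C0_MPa <= 0)
    stop("strength limits must be positive")
  abs(sigma_C) / limits@sigma_C0_MPa + sigma_T / limits@sigma_T0_MPa
}

#' Peri-implant control regions
#'
#' @slot delta_mm control layer thickness (0.25 D)
#' @slot membership integer per Gauss point: 0 outside, 1 cortical (Omega_c),
#'   2/3/4 trabecular crest/intermediate/apex thirds
#' @slot split_z the two axial plane levels separating the trabecular thirds
#' @slot weights quadrature weights of the Gauss points
#' @slot dist distance of each Gauss point to the implant surface (NA for
#'   titanium points)
#' @slot pts Gauss point coordinates
#' @export
setClass("ControlRegions", representation(
  delta_mm = "numeric", membership = "integer", split_z = "numeric",
  weights = "numeric", dist = "numeric", pts = "matrix"))

.regionNames <- c("cortical", "trabecular_crest", "trabecular_mid",
                  "trabecular_apex")

#' Build the peri-implant control regions
#'
#' The control volume is the bone layer within delta = delta_ratio * D of the
#' implant surface (measured as exact point-to-triangle distance against the
#' triangulated bone-implant interface).  Cortical member points form
#' Omega_c; trabecular member points are split by two planes orthogonal to
#' the implant axis into three subregions of equal axial length spanning the
#' trabecular contact span (most coronal trabecular member point down to the
#' implant apex).
#'
#' @param mesh the \code{\link{Tet10Mesh}}
#' @param stress a \code{\link{stressAtGauss}} result (supplies the Gauss
#'   points and weights)
#' @param D_mm implant diameter
#' @param delta_ratio layer thickness ratio (default 0.25)
#' @return a \code{\link{ControlRegions}}
#' @export
buildControlRegions <- function(mesh, stress, D_mm, delta_ratio = 0.25) {
  delta <- delta_ratio * D_mm
  m <- nElements(mesh)
  pts <- rbind(stress@pts[, 1:3, drop = FALSE], stress@pts[, 4:6, drop = FALSE],
               stress@pts[, 7:9, drop = FALSE], stress@pts[, 10:12, drop = FALSE])
  w <- c(stress@wdet[, 1], stress@wdet[, 2], stress@wdet[, 3], stress@wdet[, 4])
  tag <- rep(mesh@regionTag, 4)
  iface <- mesh@faceGroups$bone_implant_interface
  if (is.null(iface) || !nrow(iface))
    stop("mesh has no bone_implant_interface face group")
  bone <- tag %in% c("cortical", "trabecular")
  dist <- rep(NA_real_, length(tag))
  dist[bone] <- min_tri_distance(mesh@nodes, iface[, 1:3, drop = FALSE],
                                 pts[bone, , drop = FALSE])
  member <- bone & !is.na(dist) & dist <= delta
  membership <- integer(length(tag))
  membership[member & tag == "cortical"] <- 1L
  trab <- member & tag == "trabecular"
  split_z <- c(NA_real_, NA_real_)
  if (any(trab)) {
    z <- pts[, 3]
    z_top <- max(z[trab])
    apex_z <- min(mesh@nodes[unique(as.vector(iface[, 1:3])), 3])
    z_bot <- min(apex_z, min(z[trab]))
    split_z <- c(z_top - (z_top - z_bot) / 3, z_top - 2 * (z_top - z_bot) / 3)
    membership[trab & z > split_z[1]] <- 2L
    membership[trab & z <= split_z[1] & z > split_z[2]] <- 3L
    membership[trab & z <= split_z[2]] <- 4L
  }
  new("ControlRegions", delta_mm = delta, membership = membership,
      split_z = split_z, weights = w, dist = dist, pts = pts)
}

#' Per-region stress report
#'
#' @slot table data.frame: region x measure with volume-weighted mean, peak
#'   and point count
#' @slot delta_mm control layer thickness used
#' @slot empty_regions names of control regions without member points
#' @export
setClass("RegionReport", representation(
  table = "data.frame", delta_mm = "numeric", empty_regions = "character"))

setMethod("show", "RegionReport", function(object) {
  cat("RegionReport (delta =", object@delta_mm, "mm)\n")
  print(object@table, digits = 4)
  if (length(object@empty_regions))
    cat("empty regions:", paste(object@empty_regions, collapse = ", "), "\n")
})

#' Mean / peak stress measures over the control regions
#'
#' Computes the Von Mises stress, the principal-stress measures sigmaT and
#' |sigmaC| and the pointwise overloading risk index R at every member Gauss
#' point, then aggregates per control region: volume-weighted mean
#' (quadrature weight x Jacobian) and peak (extremum over member points).
#' R is computed pointwise before aggregation, with the cortical limits in
#' Omega_c and the trabecular limits in the trabecular subregions.
#'
#' @param stress a \code{\link{stressAtGauss}} result
#' @param regions a \code{\link{buildControlRegions}} result
#' @param limits named list of \code{\link{strengthLimits}} (default
#'   \code{\link{defaultStrengthLimits}})
#' @param mean_mode \code{"volume"} (weighted) or \code{"plain"}
#' @return a \code{\link{RegionReport}}
#' @export
regionStats <- function(stress, regions, limits = defaultStrengthLimits(),
                        mean_mode = c("volume", "plain")) {
  mean_mode <- match.arg(mean_mode)
  sig <- rbind(stress@sigma[, 1:6, drop = FALSE], stress@sigma[, 7:12, drop = FALSE],
               stress@sigma[, 13:18, drop = FALSE], stress@sigma[, 19:24, drop = FALSE])
  mem <- regions@membership
  sel <- mem > 0L
  rows <- list()
  empty <- character(0)
  prin <- principalStresses(sig[sel, , drop = FALSE])
  ct <- sigmaCT(prin)
  vm <- vonMises(sig[sel, , drop = FALSE])
  msel <- mem[sel]
  wsel <- regions@weights[sel]
  for (ri in 1:4) {
    nm <- .regionNames[ri]
    pick <- msel == ri
    if (!any(pick)) {
      empty <- c(empty, nm)
      next
    }
    lim <- if (ri == 1) limits$cortical else limits$trabecular
    vals <- list(sigma_vm = vm[pick],
                 sigma_T = ct$sigma_T[pick],
                 abs_sigma_C = abs(ct$sigma_C[pick]),
                 R = riskIndex(ct$sigma_C[pick], ct$sigma_T[pick], lim))
    w <- wsel[pick]
    for (msr in names(vals)) {
      v <- vals[[msr]]
      mn <- if (mean_mode == "volume") sum(w * v) / sum(w) else mean(v)
      rows[[paste(nm, msr)]] <- data.frame(
        region = nm, measure = msr, mean = mn, peak = max(v),
        n_points = sum(pick))
    }
  }
  tab <- if (length(rows)) do.call(rbind, rows) else
    data.frame(region = character(), measure = character(), mean = numeric(),
               peak = numeric(), n_points = integer())
  rownames(tab) <- NULL
  new("RegionReport", table = tab, delta_mm = regions@delta_mm,
      empty_regions = empty)
}

#' Extract one statistic from a RegionReport
#'
#' @param report a \code{\link{RegionReport}}
#' @param measure one of \code{"sigma_vm"}, \code{"sigma_T"},
#'   \code{"abs_sigma_C"}, \code{"R"}
#' @param region \code{"cortical"}, \code{"trabecular_crest"},
#'   \code{"trabecular_mid"}, \code{"trabecular_apex"} or
#'   \code{"trabecular"} (union: peak = max of the thirds, mean =
#'   weighted by point count)
#' @param statistic \code{"mean"} or \code{"peak"}
#' @return numeric value
#' @export
reportValue <- function(report, measure, region, statistic = c("peak", "mean")) {
  statistic <- match.arg(statistic)
  tb <- report@table
  if (region == "trabecular") {
    sub <- tb[tb$measure == measure & grepl("^trabecular", tb$region), ]
    if (!nrow(sub)) return(NA_real_)
    if (statistic == "peak") return(max(sub$peak))
    return(sum(sub$mean * sub$n_points) / sum(sub$n_points))
  }
  sub <- tb[tb$measure == measure & tb$region == region, ]
  if (!nrow(sub)) return(NA_real_)
  sub[[statistic]]
}
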