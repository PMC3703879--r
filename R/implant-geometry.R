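#' @include classes.R
NULL

## Parametric implant/abutment geometry.
##
## The implant body is described by its outer radius a(theta, zb) as a
## function of the angular coordinate and of the depth zb below the platform
## (zb in [0, L]).  Because the radius function is single-valued the solid is
## watertight by construction; the mesher fits a node surface to it exactly.

#' Parametric implant solid
#'
#' @slot spec the generating \code{\link{implantSpec}}
#' @slot thread_mode \code{"annular_rings"} (circumferential fins with the
#'   exact 2D thread profile) or \code{"helical"} (true two-start helix)
#' @slot radiusFun function(theta, zb) -> outer radius, vectorized
#' @slot envelopeFun function(zb) -> smooth outer envelope radius (threads at
#'   full height, no milling), used by the mesher for ring placement
#' @export
setClass("ImplantSolid", representation(
  spec = "ImplantSpec", thread_mode = "character",
  radiusFun = "function", envelopeFun = "function"))

## trapezoid fin height at axial offset `off` from the fin centre
finHeight <- function(off, w_root, depth, tan_up, tan_low) {
  up <- (off + w_root / 2) / tan_up
  low <- if (tan_low > 1e-12) (w_root / 2 - off) / tan_low else Inf
  h <- pmin(depth, up, low)
  pmax(h, 0)
}

#' Build a watertight parametric implant solid
#'
#' The thread is realized either as circumferential annular fins at axial
#' spacing pitch/n_starts with depths alternating between the two starts
#' (\code{"annular_rings"}, the default: it preserves flank angles, crest
#' free thickness and per-start depths exactly and meshes robustly), or as a
#' true two-start helical sweep.  A lead-in bevel is modelled as a 45-degree
#' chamfer from the abutment connection diameter to the platform diameter,
#' and the apex is closed with a spherical cap.
#'
#' @param spec an \code{\link{implantSpec}}
#' @param thread_mode \code{"annular_rings"} or \code{"helical"}
#' @return an \code{ImplantSolid}
#' @examples
#' sol <- buildImplantSolid(implantCatalogue()[["8"]])
#' max(sol@radiusFun(0, seq(0, 9, by = 0.01)))  # = D/2 = 1.8
#' @export
buildImplantSolid <- function(spec, thread_mode = c("annular_rings", "helical")) {
  thread_mode <- match.arg(thread_mode)
  th <- spec@thread
  R <- spec@D_mm / 2
  L <- spec@L_mm
  d1 <- th@depth_primary_mm
  d2 <- th@depth_secondary_mm
  if (d1 >= R)
    stop("self-intersecting thread profile: depth_primary_mm (", d1,
         ") must be smaller than the implant radius D/2 (", R, ")")
  spacing <- th@effective_pitch_mm / th@n_starts
  w_root <- spacing - th@free_thickness_mm
  if (w_root <= 0)
    stop("free_thickness_mm must be smaller than pitch/n_starts")
  tan_up <- tan((th@upper_flank_angle_deg - 90) * pi / 180)
  tan_low <- tan((th@lower_flank_angle_deg - 90) * pi / 180)
  if (w_root - d1 * (tan_up + tan_low) <= 0)
    stop("self-intersecting thread profile: flank angles leave no crest ",
         "thickness at depth ", d1)
  r_ab <- spec@abutment_connection_diameter_mm / 2
  t_ch <- if (spec@has_lead_in_bevel) min(0.3, R - r_ab) else min(0.15, R - r_ab)
  collar_h <- min(0.4, L / 4)
  R_core <- R - d1
  cap_z0 <- L - R_core # apex spherical-cap start
  mill <- spec@milling
  has_thread <- d1 > 0

  ## smooth envelope: chamfer -> full radius -> apex cap
  envelopeFun <- function(zb) {
    a <- rep(R, length(zb))
    ch <- zb < t_ch
    a[ch] <- r_ab + (R - r_ab) * pmax(0, zb[ch]) / t_ch
    cz <- zb > cap_z0
    a[cz] <- pmin(a[cz], sqrt(pmax(0, R_core^2 - (zb[cz] - cap_z0)^2)) +
                    (R - R_core) * pmax(0, 1 - (zb[cz] - cap_z0) / R_core))
    a[zb > L] <- 0
    pmax(a, 0)
  }

  radiusFun <- function(theta, zb) {
    n <- max(length(theta), length(zb))
    theta <- rep_len(theta, n)
    zb <- rep_len(zb, n)
    a <- rep(R, n)
    ## chamfer / collar
    ch <- zb < t_ch
    a[ch] <- r_ab + (R - r_ab) * pmax(0, zb[ch]) / t_ch
    ## threaded span: core + fins
    thr <- zb >= collar_h & zb <= L & has_thread
    if (any(thr)) {
      zt <- zb[thr]
      h <- numeric(length(zt))
      if (thread_mode == "annular_rings") {
        z0 <- collar_h + w_root / 2
        k <- floor((zt - z0) / spacing + 0.5)
        for (dk in c(-1, 0, 1)) {
          kk <- k + dk
          keep <- kk >= 0
          dep <- ifelse(kk %% 2 == 0, d1, d2)
          off <- zt - (z0 + kk * spacing)
          hh <- finHeight(off, w_root, dep, tan_up, tan_low)
          hh[!keep] <- 0
          h <- pmax(h, hh)
        }
      } else {
        tt <- theta[thr] / (2 * pi)
        for (s in 0:1) {
          dep <- if (s == 0) d1 else d2
          zc0 <- collar_h + w_root / 2 + tt * th@effective_pitch_mm +
            s * spacing
          j <- floor((zt - zc0) / th@effective_pitch_mm + 0.5)
          for (dj in c(-1, 0, 1)) {
            off <- zt - (zc0 + (j + dj) * th@effective_pitch_mm)
            keep <- (j + dj) >= 0
            hh <- finHeight(off, w_root, dep, tan_up, tan_low)
            hh[!keep] <- 0
            h <- pmax(h, hh)
          }
        }
      }
      a[thr] <- R_core + h
    }
    if (!has_thread) a[zb >= collar_h & zb <= L] <- R_core + 0
    ## milling groove (helix, pitch = threaded length); ground flutes fade
    ## out toward the collar, so the cut reaches full depth only below the
    ## coronal quarter of the threaded span
    if (mill@kind != "none") {
      span <- zb >= collar_h & zb <= cap_z0
      if (any(span)) {
        pitch_m <- L
        u <- (zb[span] - collar_h) - theta[span] / (2 * pi) * pitch_m
        u <- u %% pitch_m
        dmin <- pmin(u, pitch_m - u)
        whalf <- mill@width_mm / 2
        fade <- pmin(1, (zb[span] - collar_h) / (0.25 * (L - collar_h)))
        cut <- fade * mill@depth_mm * pmax(0, 1 - (dmin / whalf)^2)
        a[span] <- pmax(a[span] - cut, 0.25 * R)
      }
    }
    ## apex cap bounds everything
    cz <- zb > cap_z0
    if (any(cz)) {
      cap <- sqrt(pmax(0, R_core^2 - (zb[cz] - cap_z0)^2))
      a[cz] <- pmin(a[cz], pmax(cap, 0))
    }
    a[zb > L | zb < 0] <- 0
    pmax(a, 0)
  }

  new("ImplantSolid", spec = spec, thread_mode = thread_mode,
      radiusFun = radiusFun, envelopeFun = envelopeFun)
}

#' Volume of an implant solid
#'
#' Numerical volume by the disc method, pi * int a(z)^2 dz, averaging over
#' the angular coordinate when the radius is theta-dependent (helical thread
#' or milling groove).
#'
#' @param solid an \code{\link{buildImplantSolid}} result
#' @param nz axial quadrature resolution
#' @param ntheta angular resolution
#' @return volume in mm^3
#' @export
implantVolume <- function(solid, nz = 4000, ntheta = 32) {
  L <- solid@spec@L_mm
  zb <- seq(0, L, length.out = nz)
  dz <- zb[2] - zb[1]
  needTheta <- solid@thread_mode == "helical" || solid@spec@milling@kind != "none"
  if (needTheta) {
    theta <- (seq_len(ntheta) - 1) / ntheta * 2 * pi
    a2 <- rowMeans(vapply(theta, function(t) solid@radiusFun(rep(t, nz), zb)^2,
                          numeric(nz)))
  } else {
    a2 <- solid@radiusFun(0, zb)^2
  }
  pi * sum(a2) * dz
}
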