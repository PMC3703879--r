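#' @include classes.R
#' @include implant-geometry.R
NULL

## Synthetic premolar bone segment and scenario composition.
##
## Coordinates: z = 0 at the outer (pristine) crestal bone surface, z negative
## into bone; x buccolingual, y mesiodistal.  The implant axis is the z axis
## at the segment mid-span.

#' Synthetic bone segment solid
#'
#' Analytic two-region solid: a cortical shell of constant normal thickness
#' around a trabecular core, open at the two mesiodistal cut faces.
#'
#' @slot spec the generating \code{\link{boneSegmentSpec}}
#' @slot halfWidthFun function(z) -> buccolingual half width of the section
#' @slot tissueFun function(x, y, z) -> "cortical", "trabecular" or "outside"
#' @slot cortical_volume_mm3 analytic cortical volume
#' @slot trabecular_volume_mm3 analytic trabecular volume
#' @export
setClass("BoneSolid", representation(
  spec = "BoneSegmentSpec", halfWidthFun = "function", tissueFun = "function",
  cortical_volume_mm3 = "numeric", trabecular_volume_mm3 = "numeric"))

#' Build the cortical/trabecular bone segment pair
#'
#' The cross-section is an isosceles trapezoid with the stated crest width at
#' the top, widening by a fixed flare toward the floor (or a rectangle), and
#' the cortical shell has the stated constant thickness measured along the
#' surface normal on the crest, floor and buccal/lingual faces.
#'
#' @param spec a \code{\link{boneSegmentSpec}}
#' @param flare_mm total widening of the section from crest to floor for the
#'   trapezoid section (default 3)
#' @param corner_fillet_mm radius of the rounded interior transition where
#'   two cortical plates meet (the corticalization of real bone is graded;
#'   a sharp interior L-corner would also be a spurious bi-material stress
#'   singularity)
#' @return a \code{BoneSolid} (conforming cortical/trabecular partition)
#' @examples
#' b <- buildBoneSegment(boneSegmentSpec())
#' b@tissueFun(0, 0, -1)   # inside the crestal cortical plate
#' b@tissueFun(0, 0, -5)   # trabecular core
#' @export
buildBoneSegment <- function(spec, flare_mm = 3, corner_fillet_mm = 1) {
  H <- spec@crest_height_mm
  t <- spec@cortical_thickness_mm
  wt <- spec@crest_width_mm / 2
  flare <- if (spec@cross_section_kind == "trapezoid") flare_mm / 2 else 0
  Ly <- spec@mesiodistal_length_mm
  slope <- flare / H # d(halfwidth)/d(depth)
  cosphi <- 1 / sqrt(1 + slope^2)

  halfWidthFun <- function(z) wt + slope * pmax(0, -z)

  tissueFun <- function(x, y, z) {
    n <- max(length(x), length(y), length(z))
    x <- rep_len(x, n); y <- rep_len(y, n); z <- rep_len(z, n)
    W <- halfWidthFun(z)
    inside <- z <= 0 & z >= -H & abs(x) <= W & abs(y) <= Ly / 2
    side <- (W - abs(x)) * cosphi
    dtop <- -z
    dbot <- z + H
    cort <- dtop <= t | dbot <= t | side <= t
    ## rounded interior corners where two plates meet
    rf <- corner_fillet_mm
    cort <- cort |
      sqrt(pmax(0, dtop - t)^2 + pmax(0, side - t)^2) <= rf |
      sqrt(pmax(0, dbot - t)^2 + pmax(0, side - t)^2) <= rf
    out <- ifelse(!inside, "outside", ifelse(cort, "cortical", "trabecular"))
    out
  }

  ## analytic volumes (prism; shell open at the y cut faces).  The inner
  ## trapezoid spans depths t .. H - t with halfwidth W(z) - t/cosphi; the
  ## four rounded interior corners each trade a quarter-disc of trabecular
  ## core for cortical fillet (right-angle approximation; the sides are
  ## inclined by only ~6 degrees)
  A_total <- (wt + (wt + flare)) * H # 2 * mean halfwidth * H
  Wa <- wt + slope * t - t / cosphi
  Wb <- wt + slope * (H - t) - t / cosphi
  A_fillet <- pi * corner_fillet_mm^2
  A_in <- (Wa + Wb) * (H - 2 * t) - A_fillet
  new("BoneSolid", spec = spec, halfWidthFun = halfWidthFun,
      tissueFun = tissueFun,
      cortical_volume_mm3 = (A_total - A_in) * Ly,
      trabecular_volume_mm3 = A_in * Ly)
}

#' Placed, morphology-adjusted scenario solid
#'
#' Combines bone, implant, placement depth and crestal morphology into a
#' single region-tagged solid: the implant is carved into the bone with full
#' interfacial contact (complete osseointegration), subcrestal placements are
#' covered by crestal bone up to the outer surface (horizontal apposition over
#' the platform ledge), and crestal placements may carry an axisymmetric
#' conical resorption crater around the neck.
#'
#' @slot scenario the generating \code{\link{scenarioSpec}}
#' @slot implant the \code{\link{buildImplantSolid}} result
#' @slot bone the \code{\link{buildBoneSegment}} result
#' @slot platform_z z level of the implant platform (= -depth)
#' @slot apex_z z level of the implant apex
#' @slot top_z z level of the load application surface
#' @slot crater_depth_mm crater depth carved below the crest
#' @slot columnRadiusFun function(theta, z) -> interface radius of the
#'   implant/abutment column (continued as a thin core below the apex)
#' @slot columnEnvelopeFun function(z) -> smooth envelope of the column
#' @slot crestZFun function(r) -> z of the (possibly cratered) crest surface
#' @slot regionAtFun function(x, y, z) -> region tag or "void"
#' @export
setClass("ScenarioSolid", representation(
  scenario = "ScenarioSpec", implant = "ImplantSolid", bone = "BoneSolid",
  platform_z = "numeric", apex_z = "numeric", top_z = "numeric",
  crater_depth_mm = "numeric",
  columnRadiusFun = "function", columnEnvelopeFun = "function",
  crestZFun = "function", regionAtFun = "function"))

#' Place an implant in the bone segment and apply the crestal morphology
#'
#' @param bone a \code{\link{buildBoneSegment}} result
#' @param implant a \code{\link{buildImplantSolid}} result
#' @param placement a \code{\link{placementSpec}}
#' @param morph a \code{\link{crestalMorphology}}
#' @param scenario optionally, the full \code{\link{scenarioSpec}} (used to
#'   carry the load case; a default one is built otherwise)
#' @param core_radius_mm radius of the internal column continued below the
#'   implant apex (mesh construction aid, tagged as bone); defaults to the
#'   thread core radius so the mapped ring spacing stays uniform
#' @param abutment_gap_mm radial width of the soft-tissue gap separating the
#'   abutment lateral surface from crestal bone above the platform (the
#'   implant-abutment junction is not osseointegrated); bone covers the
#'   platform ledge itself.  The gap widens coronally with slope
#'   \code{gap_flare} so the apposition bone meets the shoulder smoothly
#' @param gap_flare radial widening of the gap per mm of height above the
#'   platform
#' @return a \code{ScenarioSolid}
#' @export
applyPlacementAndMorphology <- function(bone, implant, placement, morph,
                                        scenario = NULL, core_radius_mm = NULL,
                                        abutment_gap_mm = 0.2, gap_flare = 0.7) {
  spec <- implant@spec
  p <- placement@depth_mm
  H <- bone@spec@crest_height_mm
  t <- bone@spec@cortical_thickness_mm
  if (p + spec@L_mm > H)
    stop("implant apex exits the cortical floor: depth + L = ", p + spec@L_mm,
         " exceeds segment height ", H)
  if (placement@depth_code == "P0" && morph@kind == "apposition")
    stop("apposition morphology is only meaningful for subcrestal placements")
  if (placement@depth_code != "P0" && morph@kind == "bone_loss")
    stop("bone-loss crater overlaps the apposition region for subcrestal placements")
  if (is.null(scenario))
    scenario <- scenarioSpec(spec, placement, morph, bone@spec)

  d_c <- morph@bone_loss_fraction * t
  R <- spec@D_mm / 2
  if (is.null(core_radius_mm))
    core_radius_mm <- max(0.25 * R, R - spec@thread@depth_primary_mm)
  r_ab <- spec@abutment_connection_diameter_mm / 2
  tanw <- tan(morph@crater_wall_angle_deg * pi / 180)
  platform_z <- -p
  apex_z <- -p - spec@L_mm
  top_z <- scenario@load@application_height_mm

  crestZFun <- function(r) {
    if (d_c <= 0) return(rep(0, length(r)))
    pmin(0, -d_c + pmax(0, r - R) * tanw)
  }

  columnRadiusFun <- function(theta, z) {
    n <- max(length(theta), length(z))
    theta <- rep_len(theta, n); z <- rep_len(z, n)
    a <- rep(core_radius_mm, n)
    ab <- z > platform_z
    a[ab] <- r_ab
    im <- z <= platform_z & z >= apex_z
    a[im] <- pmax(implant@radiusFun(theta[im], -(z[im] + p)), core_radius_mm)
    a
  }
  columnEnvelopeFun <- function(z) {
    a <- rep(core_radius_mm, length(z))
    ab <- z > platform_z
    a[ab] <- r_ab
    im <- z <= platform_z & z >= apex_z
    a[im] <- pmax(implant@envelopeFun(-(z[im] + p)), core_radius_mm)
    a
  }

  regionAtFun <- function(x, y, z) {
    n <- max(length(x), length(y), length(z))
    x <- rep_len(x, n); y <- rep_len(y, n); z <- rep_len(z, n)
    r <- sqrt(x^2 + y^2)
    theta <- atan2(y, x)
    out <- rep("void", n)
    ## titanium
    ab <- z > platform_z & z <= top_z & r <= r_ab
    out[ab] <- "abutment"
    im <- z <= platform_z & z >= apex_z &
      r <= implant@radiusFun(theta, -(z + p))
    out[im] <- "implant"
    ## bone (a flared soft-tissue gap separates bone from the abutment wall)
    gap <- z > platform_z & z <= 0 &
      r <= r_ab + abutment_gap_mm + gap_flare * (z - platform_z)
    cand <- out == "void" & !gap & z <= crestZFun(r)
    if (any(cand)) {
      tis <- bone@tissueFun(x[cand], y[cand], z[cand])
      out[cand][tis != "outside"] <- tis[tis != "outside"]
    }
    out
  }

  new("ScenarioSolid", scenario = scenario, implant = implant, bone = bone,
      platform_z = platform_z, apex_z = apex_z, top_z = top_z,
      crater_depth_mm = d_c,
      columnRadiusFun = columnRadiusFun, columnEnvelopeFun = columnEnvelopeFun,
      crestZFun = crestZFun, regionAtFun = regionAtFun)
}

#' Build the scenario solid straight from a ScenarioSpec
#'
#' @param scenario a \code{\link{scenarioSpec}}
#' @param thread_mode thread representation passed to
#'   \code{\link{buildImplantSolid}}
#' @return a \code{ScenarioSolid}
#' @export
buildScenarioSolid <- function(scenario, thread_mode = "annular_rings") {
  bone <- buildBoneSegment(scenario@bone)
  implant <- buildImplantSolid(scenario@implant, thread_mode)
  applyPlacementAndMorphology(bone, implant, scenario@placement,
                              scenario@morphology, scenario = scenario)
}
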