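#' @include osseoFEM-package.R
NULL

## ---------------------------------------------------------------------------
## Specification classes: implants, bone, placement, morphology, load,
## materials and full scenarios.  All dimensions in mm, forces in N,
## moduli/stresses in MPa.
## ---------------------------------------------------------------------------

#' Thread specification
#'
#' Describes a two-start thread pattern.  \code{T0_30_sawtooth} is a saw-tooth
#' profile whose upper flank is angled 120 degrees from the implant axis (30
#' degrees from the horizontal) with an axially flat lower flank;
#' \code{T10_30_trapezoid} is a trapezoid profile with flanks at 120 and 100
#' degrees from the axis.  \code{truncation} \code{"ST"} gives both starts the
#' same maximum depth, \code{"DT"} halves the depth of the second start.
#'
#' @slot profile_kind character, \code{"T0_30_sawtooth"} or
#'   \code{"T10_30_trapezoid"}
#' @slot upper_flank_angle_deg angle of the coronal flank from the implant axis
#' @slot lower_flank_angle_deg angle of the apical flank from the implant axis
#' @slot free_thickness_mm free axial distance between consecutive thread
#'   crests at the internal diameter
#' @slot n_starts number of thread starts (always 2)
#' @slot effective_pitch_mm axial advance per full turn of one start
#' @slot truncation \code{"ST"} (same truncation) or \code{"DT"} (different)
#' @slot depth_primary_mm maximum depth of the first start
#' @slot depth_secondary_mm maximum depth of the second start
#' @export
setClass("ThreadSpec", representation(
  profile_kind = "character",
  upper_flank_angle_deg = "numeric",
  lower_flank_angle_deg = "numeric",
  free_thickness_mm = "numeric",
  n_starts = "numeric",
  effective_pitch_mm = "numeric",
  truncation = "character",
  depth_primary_mm = "numeric",
  depth_secondary_mm = "numeric"
), validity = function(object) {
  msg <- character()
  if (!object@profile_kind %in% c("T0_30_sawtooth", "T10_30_trapezoid"))
    msg <- c(msg, "unknown profile_kind")
  if (!object@truncation %in% c("ST", "DT"))
    msg <- c(msg, "truncation must be 'ST' or 'DT'")
  if (object@n_starts != 2) msg <- c(msg, "n_starts must be 2")
  if (object@effective_pitch_mm <= 0) msg <- c(msg, "effective_pitch_mm must be > 0")
  if (object@depth_secondary_mm < 0 ||
      object@depth_secondary_mm > object@depth_primary_mm + 1e-12)
    msg <- c(msg, "0 <= depth_secondary_mm <= depth_primary_mm required")
  if (object@depth_primary_mm > 0 && object@depth_secondary_mm <= 0)
    msg <- c(msg, "depth_secondary_mm must be > 0 unless the thread is degenerate")
  if (object@truncation == "ST" &&
      abs(object@depth_secondary_mm - object@depth_primary_mm) > 1e-12)
    msg <- c(msg, "ST requires equal thread depths for both starts")
  if (length(msg)) msg else TRUE
})

#' Construct a ThreadSpec
#'
#' @param profile_kind thread profile, \code{"T0_30_sawtooth"} or
#'   \code{"T10_30_trapezoid"}
#' @param truncation \code{"ST"} or \code{"DT"}
#' @param depth_primary_mm maximum thread depth of the first start
#' @param effective_pitch_mm axial advance per turn
#' @return a \code{ThreadSpec}
#' @examples
#' threadSpec("T10_30_trapezoid", "DT")
#' @export
threadSpec <- function(profile_kind = c("T0_30_sawtooth", "T10_30_trapezoid"),
                       truncation = c("ST", "DT"),
                       depth_primary_mm = 0.38,
                       effective_pitch_mm = 1.2) {
  profile_kind <- match.arg(profile_kind)
  truncation <- match.arg(truncation)
  saw <- profile_kind == "T0_30_sawtooth"
  obj <- new("ThreadSpec",
    profile_kind = profile_kind,
    upper_flank_angle_deg = 120,
    lower_flank_angle_deg = if (saw) 90 else 100,
    free_thickness_mm = if (saw) 0.33 else 0.25,
    n_starts = 2,
    effective_pitch_mm = effective_pitch_mm,
    truncation = truncation,
    depth_primary_mm = depth_primary_mm,
    depth_secondary_mm = if (truncation == "ST") depth_primary_mm else depth_primary_mm / 2)
  validObject(obj)
  obj
}

#' Helical milling specification
#'
#' A single helical groove along the implant body whose pitch equals the
#' implant threaded length.  \code{"SM"} (small) and \code{"LM"} (large)
#' differ in the width and depth of the cut.
#'
#' @slot kind \code{"none"}, \code{"SM"} or \code{"LM"}
#' @slot width_mm groove width
#' @slot depth_mm groove depth
#' @slot pitch_mm helix pitch (filled in from the implant threaded length)
#' @export
setClass("MillingSpec", representation(
  kind = "character", width_mm = "numeric", depth_mm = "numeric",
  pitch_mm = "numeric"
), validity = function(object) {
  msg <- character()
  if (!object@kind %in% c("none", "SM", "LM")) msg <- c(msg, "unknown milling kind")
  if (object@kind == "none" && (object@width_mm != 0 || object@depth_mm != 0))
    msg <- c(msg, "milling 'none' must have zero width and depth")
  if (length(msg)) msg else TRUE
})

#' Construct a MillingSpec
#' @param kind \code{"none"}, \code{"SM"} or \code{"LM"}
#' @return a \code{MillingSpec}; large-milling dimensions strictly exceed the
#'   small-milling ones
#' @export
millingSpec <- function(kind = c("none", "SM", "LM")) {
  kind <- match.arg(kind)
  dims <- switch(kind,
    none = c(0, 0),
    SM = c(0.3, 0.15),
    LM = c(0.6, 0.3))
  new("MillingSpec", kind = kind, width_mm = dims[1], depth_mm = dims[2],
      pitch_mm = NA_real_)
}

#' Implant specification
#'
#' One threaded implant plus its platform-switched abutment.  The abutment
#' connection diameter is strictly narrower than the implant collar; the
#' abutment height is derived so the load application point sits 7 mm above
#' the outer bone surface regardless of in-bone positioning depth.
#'
#' @slot label catalogue identifier ("1".."10", "A")
#' @slot D_mm outer implant diameter
#' @slot L_mm in-bone (threaded) length
#' @slot thread a \code{\link{threadSpec}}
#' @slot milling a \code{\link{millingSpec}}
#' @slot has_lead_in_bevel logical, internal lead-in bevel at the platform
#' @slot abutment_connection_diameter_mm abutment diameter at the platform
#' @export
setClass("ImplantSpec", representation(
  label = "character", D_mm = "numeric", L_mm = "numeric",
  thread = "ThreadSpec", milling = "MillingSpec",
  has_lead_in_bevel = "logical",
  abutment_connection_diameter_mm = "numeric"
), validity = function(object) {
  msg <- character()
  if (object@D_mm < 3 || object@D_mm > 6) msg <- c(msg, "D_mm must be in [3, 6]")
  if (object@L_mm < 4 || object@L_mm > 14) msg <- c(msg, "L_mm must be in [4, 14]")
  if (object@abutment_connection_diameter_mm >= object@D_mm)
    msg <- c(msg, "platform switching requires abutment connection < D")
  if (length(msg)) msg else TRUE
})

#' Construct an ImplantSpec
#'
#' @param label catalogue identifier
#' @param D_mm outer diameter (3--6 mm)
#' @param L_mm threaded in-bone length (4--14 mm)
#' @param thread a \code{\link{threadSpec}}
#' @param milling a \code{\link{millingSpec}}
#' @param has_lead_in_bevel lead-in bevel flag
#' @param abutment_connection_diameter_mm platform-switch connection diameter;
#'   default 0.75 D
#' @return an \code{ImplantSpec}
#' @examples
#' implantSpec("8", 3.6, 9, threadSpec("T10_30_trapezoid", "DT"), millingSpec("SM"))
#' @export
implantSpec <- function(label, D_mm, L_mm, thread = threadSpec(), milling = millingSpec(),
                        has_lead_in_bevel = TRUE,
                        abutment_connection_diameter_mm = 0.75 * D_mm) {
  milling@pitch_mm <- L_mm
  obj <- new("ImplantSpec", label = as.character(label), D_mm = D_mm, L_mm = L_mm,
             thread = thread, milling = milling,
             has_lead_in_bevel = has_lead_in_bevel,
             abutment_connection_diameter_mm = abutment_connection_diameter_mm)
  validObject(obj)
  obj
}

#' Synthetic bone segment specification
#'
#' An idealized premolar bone segment: a trapezoid-prism cross-section
#' (narrow at the crest, wider toward the floor) spanning 40 mm mesiodistally,
#' with a cortical shell of given mean thickness around a trabecular core.
#' The shell is open at the two mesiodistal (coronal-cut) faces.
#'
#' @slot mesiodistal_length_mm segment span along y
#' @slot cortical_thickness_mm mean cortical shell thickness
#' @slot crest_width_mm buccolingual width at the crest
#' @slot crest_height_mm apico-coronal height of the section
#' @slot cross_section_kind \code{"trapezoid"} or \code{"rectangle"}
#' @export
setClass("BoneSegmentSpec", representation(
  mesiodistal_length_mm = "numeric", cortical_thickness_mm = "numeric",
  crest_width_mm = "numeric", crest_height_mm = "numeric",
  cross_section_kind = "character"
), validity = function(object) {
  msg <- character()
  if (object@cortical_thickness_mm <= 0) msg <- c(msg, "cortical thickness must be > 0")
  if (object@cortical_thickness_mm >= object@crest_width_mm / 2)
    msg <- c(msg, "cortical shell thickness must be < half the crest width")
  if (!object@cross_section_kind %in% c("trapezoid", "rectangle"))
    msg <- c(msg, "cross_section_kind must be 'trapezoid' or 'rectangle'")
  if (length(msg)) msg else TRUE
})

#' Construct a BoneSegmentSpec
#' @param mesiodistal_length_mm segment span (default 40)
#' @param cortical_thickness_mm shell thickness (default 2)
#' @param crest_width_mm buccolingual crest width (default 8)
#' @param crest_height_mm section height (default 14)
#' @param cross_section_kind idealized section shape
#' @return a \code{BoneSegmentSpec}
#' @export
boneSegmentSpec <- function(mesiodistal_length_mm = 40, cortical_thickness_mm = 2,
                            crest_width_mm = 8, crest_height_mm = 14,
                            cross_section_kind = c("trapezoid", "rectangle")) {
  obj <- new("BoneSegmentSpec",
             mesiodistal_length_mm = mesiodistal_length_mm,
             cortical_thickness_mm = cortical_thickness_mm,
             crest_width_mm = crest_width_mm, crest_height_mm = crest_height_mm,
             cross_section_kind = match.arg(cross_section_kind))
  validObject(obj)
  obj
}

#' In-bone positioning specification
#'
#' P0 places the implant platform at the outer bone surface, P05 and P1 are
#' subcrestal placements 0.5 and 1 mm deep.
#'
#' @slot depth_code "P0", "P05" or "P1"
#' @slot depth_mm platform depth below the outer bone surface
#' @export
setClass("PlacementSpec", representation(
  depth_code = "character", depth_mm = "numeric"
), validity = function(object) {
  want <- c(P0 = 0, P05 = 0.5, P1 = 1)
  if (!object@depth_code %in% names(want)) return("depth_code must be P0, P05 or P1")
  if (abs(object@depth_mm - want[[object@depth_code]]) > 1e-12)
    return("depth_mm inconsistent with depth_code")
  TRUE
})

#' Construct a PlacementSpec
#' @param depth_code "P0", "P05" or "P1"
#' @return a \code{PlacementSpec} with the matching depth
#' @examples placementSpec("P05")@depth_mm
#' @export
placementSpec <- function(depth_code = c("P1", "P05", "P0")) {
  depth_code <- match.arg(depth_code)
  new("PlacementSpec", depth_code = depth_code,
      depth_mm = c(P0 = 0, P05 = 0.5, P1 = 1)[[depth_code]])
}

#' Post-healing crestal bone morphology
#'
#' Subcrestal placements develop a horizontal bone apposition covering the
#' implant platform (about 0.25 mm mean thickness); crestal placements are
#' modelled with a marginal bone-loss crater around the implant neck, an
#' axisymmetric cone whose depth is a fraction of the cortical thickness.
#'
#' @slot kind "apposition", "bone_loss" or "pristine"
#' @slot apposition_thickness_mm mean apposition thickness on the platform
#' @slot bone_loss_fraction crater depth as a fraction of cortical thickness
#' @slot crater_wall_angle_deg slope of the crater wall from the horizontal
#' @export
setClass("CrestalMorphology", representation(
  kind = "character", apposition_thickness_mm = "numeric",
  bone_loss_fraction = "numeric", crater_wall_angle_deg = "numeric"
), validity = function(object) {
  msg <- character()
  if (!object@kind %in% c("apposition", "bone_loss", "pristine"))
    msg <- c(msg, "unknown morphology kind")
  if (object@bone_loss_fraction < 0 || object@bone_loss_fraction > 0.5)
    msg <- c(msg, "bone_loss_fraction must be in [0, 0.5]")
  if (object@kind != "bone_loss" && object@bone_loss_fraction != 0)
    msg <- c(msg, "only bone_loss morphologies may have a crater")
  if (length(msg)) msg else TRUE
})

#' Construct a CrestalMorphology
#' @param kind morphology kind
#' @param bone_loss_fraction crater depth fraction (bone_loss only)
#' @param apposition_thickness_mm apposition thickness (subcrestal)
#' @param crater_wall_angle_deg crater wall slope
#' @return a \code{CrestalMorphology}
#' @export
crestalMorphology <- function(kind = c("apposition", "bone_loss", "pristine"),
                              bone_loss_fraction = 0,
                              apposition_thickness_mm = 0.25,
                              crater_wall_angle_deg = 45) {
  kind <- match.arg(kind)
  if (kind == "bone_loss" && bone_loss_fraction == 0) kind <- "pristine"
  obj <- new("CrestalMorphology", kind = kind,
             apposition_thickness_mm = apposition_thickness_mm,
             bone_loss_fraction = if (kind == "bone_loss") bone_loss_fraction else 0,
             crater_wall_angle_deg = crater_wall_angle_deg)
  validObject(obj)
  obj
}

#' Static functional load case
#'
#' The default is a 100 N buccolingual (x) plus 250 N intrusive (-z) force,
#' i.e. a resultant of about 269 N angled about 68 degrees to the occlusal
#' plane, applied on the abutment top 7 mm above the outer bone surface with
#' no eccentricity relative to the implant axis.
#'
#' @slot F_lateral_N buccolingual force component
#' @slot F_vertical_N intrusive (downward) force component
#' @slot application_height_mm height of the load point above the bone surface
#' @slot patch_radius_mm radius of the traction patch standing in for the
#'   point load
#' @export
setClass("LoadCase", representation(
  F_lateral_N = "numeric", F_vertical_N = "numeric",
  application_height_mm = "numeric", patch_radius_mm = "numeric"
))

#' Construct a LoadCase
#' @param F_lateral_N lateral (x) force, N
#' @param F_vertical_N intrusive (-z) force magnitude, N
#' @param application_height_mm load point height above the bone surface
#' @param patch_radius_mm traction patch radius on the abutment top
#' @return a \code{LoadCase}
#' @export
loadCase <- function(F_lateral_N = 100, F_vertical_N = 250,
                     application_height_mm = 7, patch_radius_mm = 0.5) {
  new("LoadCase", F_lateral_N = F_lateral_N, F_vertical_N = F_vertical_N,
      application_height_mm = application_height_mm,
      patch_radius_mm = patch_radius_mm)
}

#' Linear isotropic material model
#' @slot E_MPa Young's modulus, MPa
#' @slot nu Poisson's ratio
#' @slot region region tag this material applies to
#' @export
setClass("MaterialModel", representation(
  E_MPa = "numeric", nu = "numeric", region = "character"
), validity = function(object) {
  if (object@E_MPa <= 0) return("E must be > 0")
  if (object@nu < 0 || object@nu >= 0.5) return("nu must be in [0, 0.5)")
  TRUE
})

#' Construct a MaterialModel
#' @param E_MPa Young's modulus in MPa
#' @param nu Poisson's ratio
#' @param region region tag
#' @return a \code{MaterialModel}
#' @export
materialModel <- function(E_MPa, nu, region) {
  obj <- new("MaterialModel", E_MPa = E_MPa, nu = nu, region = region)
  validObject(obj)
  obj
}

#' Default material map
#'
#' Titanium alloy (Ti6Al4V) for implant and abutment (E = 114 GPa, nu = 0.34),
#' type-II quality bone: cortical E = 13.7 GPa, trabecular E = 0.5 GPa, both
#' with nu = 0.30.
#'
#' @return named list of \code{\link{materialModel}} objects keyed by region
#' @examples defaultMaterials()$cortical@E_MPa
#' @export
defaultMaterials <- function() {
  list(
    implant = materialModel(114000, 0.34, "implant"),
    abutment = materialModel(114000, 0.34, "abutment"),
    cortical = materialModel(13700, 0.30, "cortical"),
    trabecular = materialModel(500, 0.30, "trabecular"))
}

#' Full analysis scenario
#'
#' Bundles one implant, the bone segment, its placement depth, the crestal
#' morphology, the load case and the material map: everything needed for one
#' finite-element run.
#'
#' @slot implant an \code{\link{implantSpec}}
#' @slot bone a \code{\link{boneSegmentSpec}}
#' @slot placement a \code{\link{placementSpec}}
#' @slot morphology a \code{\link{crestalMorphology}}
#' @slot load a \code{\link{loadCase}}
#' @slot materials named list of \code{\link{materialModel}}
#' @export
setClass("ScenarioSpec", representation(
  implant = "ImplantSpec", bone = "BoneSegmentSpec",
  placement = "PlacementSpec", morphology = "CrestalMorphology",
  load = "LoadCase", materials = "list"
))

#' Construct a ScenarioSpec
#'
#' Subcrestal placements (P05, P1) default to the apposition morphology;
#' crestal placement (P0) defaults to a 10 percent cortical bone-loss crater,
#' matching the convention used for the positioning comparisons.
#'
#' @param implant an \code{\link{implantSpec}}
#' @param placement a \code{\link{placementSpec}} or depth code string
#' @param morphology a \code{\link{crestalMorphology}}; default depends on the
#'   placement as described above
#' @param bone a \code{\link{boneSegmentSpec}}
#' @param load a \code{\link{loadCase}}
#' @param materials named material list covering all region tags
#' @return a \code{ScenarioSpec}
#' @examples
#' sc <- scenarioSpec(implantCatalogue()[["8"]], "P1")
#' sc@morphology@kind
#' @export
scenarioSpec <- function(implant, placement = "P1", morphology = NULL,
                         bone = boneSegmentSpec(), load = loadCase(),
                         materials = defaultMaterials()) {
  if (is.character(placement)) placement <- placementSpec(placement)
  if (is.null(morphology)) {
    morphology <- if (placement@depth_code == "P0")
      crestalMorphology("bone_loss", bone_loss_fraction = 0.1)
    else crestalMorphology("apposition")
  }
  new("ScenarioSpec", implant = implant, bone = bone, placement = placement,
      morphology = morphology, load = load, materials = materials)
}

setMethod("show", "ScenarioSpec", function(object) {
  i <- object@implant
  cat(sprintf("ScenarioSpec: implant %s (D%.1f-L%.1f-%s-%s-%s) at %s, %s\n",
              i@label, i@D_mm, i@L_mm,
              if (i@thread@profile_kind == "T0_30_sawtooth") "T0/30" else "T10/30",
              i@thread@truncation, i@milling@kind,
              object@placement@depth_code, object@morphology@kind))
  if (object@morphology@kind == "bone_loss")
    cat(sprintf("  crater: %.0f%% of cortical thickness\n",
                100 * object@morphology@bone_loss_fraction))
  cat(sprintf("  load: %g N lateral + %g N intrusive at +%g mm\n",
              object@load@F_lateral_N, object@load@F_vertical_N,
              object@load@application_height_mm))
})

setMethod("show", "ImplantSpec", function(object) {
  cat(sprintf("ImplantSpec %s: D = %.1f mm, L = %.1f mm, %s, %s, milling %s\n",
              object@label, object@D_mm, object@L_mm,
              object@thread@profile_kind, object@thread@truncation,
              object@milling@kind))
})
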