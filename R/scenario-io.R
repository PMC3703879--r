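#' @include classes.R
NULL

## Scenario serialization to/from YAML configuration files.

.threadToList <- function(t) list(
  profile_kind = t@profile_kind, truncation = t@truncation,
  depth_primary_mm = t@depth_primary_mm,
  effective_pitch_mm = t@effective_pitch_mm)

.implantToList <- function(i) list(
  label = i@label, D_mm = i@D_mm, L_mm = i@L_mm,
  thread = .threadToList(i@thread),
  milling = i@milling@kind,
  has_lead_in_bevel = i@has_lead_in_bevel,
  abutment_connection_diameter_mm = i@abutment_connection_diameter_mm)

#' Serialize a scenario to a YAML configuration file
#'
#' The file captures the full scenario (implant, bone, placement, morphology,
#' load, materials) with fixed key names; \code{\link{readScenarioYaml}}
#' reconstructs an identical \code{\link{scenarioSpec}}.
#'
#' @param scenario a \code{\link{scenarioSpec}}
#' @param path output file
#' @return the path, invisibly
#' @export
writeScenarioYaml <- function(scenario, path) {
  b <- scenario@bone; p <- scenario@placement; m <- scenario@morphology
  l <- scenario@load
  cfg <- list(
    implant = .implantToList(scenario@implant),
    bone = list(mesiodistal_length_mm = b@mesiodistal_length_mm,
                cortical_thickness_mm = b@cortical_thickness_mm,
                crest_width_mm = b@crest_width_mm,
                crest_height_mm = b@crest_height_mm,
                cross_section_kind = b@cross_section_kind),
    placement = p@depth_code,
    morphology = list(kind = m@kind,
                      apposition_thickness_mm = m@apposition_thickness_mm,
                      bone_loss_fraction = m@bone_loss_fraction,
                      crater_wall_angle_deg = m@crater_wall_angle_deg),
    load = list(F_lateral_N = l@F_lateral_N, F_vertical_N = l@F_vertical_N,
                application_height_mm = l@application_height_mm,
                patch_radius_mm = l@patch_radius_mm),
    materials = lapply(scenario@materials, function(mm)
      list(E_MPa = mm@E_MPa, nu = mm@nu, region = mm@region)))
  yaml::write_yaml(cfg, path, precision = 15)
  invisible(path)
}

#' Read a scenario from a YAML configuration file
#'
#' @param path file written by \code{\link{writeScenarioYaml}}
#' @return a \code{\link{scenarioSpec}}
#' @export
readScenarioYaml <- function(path) {
  cfg <- yaml::read_yaml(path)
  ic <- cfg$implant
  thread <- threadSpec(ic$thread$profile_kind, ic$thread$truncation,
                       depth_primary_mm = ic$thread$depth_primary_mm,
                       effective_pitch_mm = ic$thread$effective_pitch_mm)
  implant <- implantSpec(ic$label, ic$D_mm, ic$L_mm, thread,
                         millingSpec(ic$milling),
                         has_lead_in_bevel = ic$has_lead_in_bevel,
                         abutment_connection_diameter_mm =
                           ic$abutment_connection_diameter_mm)
  bone <- boneSegmentSpec(cfg$bone$mesiodistal_length_mm,
                          cfg$bone$cortical_thickness_mm,
                          cfg$bone$crest_width_mm, cfg$bone$crest_height_mm,
                          cfg$bone$cross_section_kind)
  morph <- crestalMorphology(cfg$morphology$kind,
                             cfg$morphology$bone_loss_fraction,
                             cfg$morphology$apposition_thickness_mm,
                             cfg$morphology$crater_wall_angle_deg)
  load <- loadCase(cfg$load$F_lateral_N, cfg$load$F_vertical_N,
                   cfg$load$application_height_mm, cfg$load$patch_radius_mm)
  mats <- lapply(cfg$materials, function(mm)
    materialModel(mm$E_MPa, mm$nu, mm$region))
  scenarioSpec(implant, cfg$placement, morph, bone, load, mats)
}
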