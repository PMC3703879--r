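#' @include stress-risk.R
#' @include recovery.R
NULL

## Study orchestration: one-scenario pipeline, multi-scenario sweeps and the
## comparative percent-change statements.

#' Result container for comparative studies
#'
#' @slot reports named list of \code{\link{RegionReport}} per scenario
#' @slot table long-format data.frame (scenario, region, measure, mean, peak,
#'   n_points)
#' @slot meta per-scenario mesh/solver metadata
#' @slot comparisons derived percent-change table (possibly empty)
#' @slot failures named list of error messages for failed scenarios
#' @export
setClass("StudyResult", representation(
  reports = "list", table = "data.frame", meta = "data.frame",
  comparisons = "data.frame", failures = "list"))

setMethod("show", "StudyResult", function(object) {
  cat(sprintf("StudyResult: %d scenarios solved, %d failed\n",
              length(object@reports), length(object@failures)))
  if (nrow(object@meta)) print(object@meta, digits = 4)
})

#' Solve one scenario end to end
#'
#' Builds the scenario solid, meshes it at the requested size field, solves
#' the elasticity problem and returns the control-volume stress report plus
#' solver/mesh diagnostics.
#'
#' @param scenario a \code{\link{scenarioSpec}}
#' @param hi_ratio peri-implant mesh size ratio hi/D
#' @param h0_ratio far-field mesh size ratio h0/D
#' @param thread_mode thread representation
#' @param stress_field \code{"recovered"} (default) evaluates the region
#'   statistics on the region-wise nodal-recovered stress field interpolated
#'   back to the Gauss points, mirroring how contour postprocessors report
#'   nodal-averaged results and damping single-point mesh noise;
#'   \code{"raw"} uses the raw Gauss stresses
#' @param estimate_error also compute the recovery-based energy error norm
#' @param keep_fields keep the displacement/stress fields in the result
#' @param ... further arguments to \code{\link{meshScenario}}
#' @return list with \code{report} (\code{\link{RegionReport}}),
#'   \code{meta} (one-row data.frame) and optionally \code{u}, \code{stress},
#'   \code{mesh}
#' @export
solveScenario <- function(scenario, hi_ratio = 0.05, h0_ratio = 0.1,
                          thread_mode = "annular_rings",
                          stress_field = c("recovered", "raw"),
                          estimate_error = FALSE, keep_fields = FALSE, ...) {
  stress_field <- match.arg(stress_field)
  solid <- buildScenarioSolid(scenario, thread_mode)
  D <- scenario@implant@D_mm
  size <- makeSizeField(D, h0_ratio, hi_ratio)
  mesh <- meshScenario(solid, size, ...)
  sys <- applyBCsAndLoad(assembleSystem(mesh, scenario@materials),
                         scenario@load)
  u <- solveSystem(sys)
  stress <- stressAtGauss(mesh, scenario@materials, u)
  regions <- buildControlRegions(mesh, stress, D)
  en <- NA_real_
  rec <- NULL
  if (stress_field == "recovered" || estimate_error)
    rec <- recoverStress(mesh, scenario@materials, stress)
  stat_field <- if (stress_field == "recovered")
    recoveredAtGauss(mesh, stress, rec) else stress
  report <- regionStats(stat_field, regions)
  if (estimate_error)
    en <- as.numeric(energyErrorNorm(mesh, scenario@materials, stress, rec))
  meta <- data.frame(
    implant = scenario@implant@label,
    placement = scenario@placement@depth_code,
    morphology = scenario@morphology@kind,
    bone_loss = scenario@morphology@bone_loss_fraction,
    n_nodes = nNodes(mesh), n_elems = nElements(mesh),
    energy_pct = en,
    max_R = max(report@table$peak[report@table$measure == "R"]),
    residual = u@residual)
  out <- list(report = report, meta = meta)
  if (keep_fields) out <- c(out, list(mesh = mesh, u = u, stress = stress,
                                      regions = regions))
  out
}

#' Run a set of scenarios as one study
#'
#' Each scenario is solved independently; failures are recorded and the run
#' continues.  Fully deterministic for fixed inputs.
#'
#' @param scenarios named list of \code{\link{scenarioSpec}} objects
#' @param ... arguments forwarded to \code{\link{solveScenario}}
#' @return a \code{\link{StudyResult}}
#' @export
runStudy <- function(scenarios, ...) {
  if (is.null(names(scenarios)) || any(names(scenarios) == ""))
    names(scenarios) <- as.character(seq_along(scenarios))
  reports <- list()
  metas <- list()
  failures <- list()
  tabs <- list()
  for (id in names(scenarios)) {
    res <- tryCatch(solveScenario(scenarios[[id]], ...),
                    error = function(e) e)
    if (inherits(res, "error")) {
      failures[[id]] <- conditionMessage(res)
      next
    }
    reports[[id]] <- res$report
    metas[[id]] <- cbind(scenario = id, res$meta)
    tabs[[id]] <- cbind(scenario = id, res$report@table)
    rm(res)
    gc(FALSE) # keep the factorization memory of successive solves bounded
  }
  new("StudyResult", reports = reports,
      table = if (length(tabs)) do.call(rbind, tabs) else data.frame(),
      meta = if (length(metas)) do.call(rbind, metas) else data.frame(),
      comparisons = data.frame(), failures = failures)
}

#' Percent change of a stress statistic between two scenarios
#'
#' 100 * (a - b) / a with scenario \code{ref} as reference a: a positive
#' value is a reduction going from \code{ref} to \code{other}.
#'
#' @param study a \code{\link{StudyResult}} (or two RegionReports via
#'   \code{ref}/\code{other})
#' @param ref,other scenario ids (or \code{\link{RegionReport}} objects when
#'   \code{study} is NULL)
#' @param measure,region,statistic as in \code{\link{reportValue}}
#' @return percentage
#' @examples
#' # a = 100, b = 73 -> 27% reduction
#' @export
percentChange <- function(study, ref, other, measure, region,
                          statistic = "peak") {
  if (is.null(study)) {
    a <- reportValue(ref, measure, region, statistic)
    b <- reportValue(other, measure, region, statistic)
  } else {
    a <- reportValue(study@reports[[ref]], measure, region, statistic)
    b <- reportValue(study@reports[[other]], measure, region, statistic)
  }
  if (is.na(a) || a == 0) stop("reference value is zero or undefined")
  100 * (a - b) / a
}

#' Marginal bone-loss sweep at crestal placement
#'
#' Runs the crestal (P0) scenario for the given implant across a set of
#' crater depths and tabulates the percent increase of every region/measure
#' statistic relative to the pristine (0 percent) case.
#'
#' @param implant an \code{\link{implantSpec}}
#' @param fractions bone-loss fractions of cortical thickness
#' @param bone a \code{\link{boneSegmentSpec}}
#' @param ... forwarded to \code{\link{runStudy}}
#' @return a \code{\link{StudyResult}} whose \code{comparisons} table holds
#'   the percent increases vs the 0 case
#' @export
boneLossSweep <- function(implant, fractions = c(0, 0.1, 0.25, 0.5),
                          bone = boneSegmentSpec(), ...) {
  stopifnot(0 %in% fractions)
  scen <- lapply(fractions, function(f) {
    morph <- if (f > 0) crestalMorphology("bone_loss", bone_loss_fraction = f)
             else crestalMorphology("pristine")
    scenarioSpec(implant, "P0", morph, bone = bone)
  })
  names(scen) <- sprintf("loss%02.0f", 100 * fractions)
  study <- runStudy(scen, ...)
  ref <- study@reports[["loss00"]]
  comp <- list()
  if (!is.null(ref)) {
    for (id in setdiff(names(study@reports), "loss00")) {
      rp <- study@reports[[id]]
      for (i in seq_len(nrow(rp@table))) {
        row <- rp@table[i, ]
        r0 <- ref@table[ref@table$region == row$region &
                          ref@table$measure == row$measure, ]
        if (!nrow(r0)) next
        comp[[paste(id, row$region, row$measure)]] <- data.frame(
          scenario = id, reference = "loss00",
          region = row$region, measure = row$measure,
          pct_increase_peak = 100 * (row$peak - r0$peak) / r0$peak,
          pct_increase_mean = 100 * (row$mean - r0$mean) / r0$mean)
      }
    }
  }
  study@comparisons <- if (length(comp)) do.call(rbind, comp) else data.frame()
  rownames(study@comparisons) <- NULL
  study
}

#' Write study outputs as CSV
#'
#' Writes \code{region_report.csv}, \code{comparisons.csv} (if any) and
#' \code{study_meta.csv} into \code{dir}; byte-identical across reruns with
#' identical inputs.
#'
#' @param study a \code{\link{StudyResult}}
#' @param dir output directory (created if missing)
#' @return invisibly, the paths written
#' @export
writeStudyCsv <- function(study, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  paths <- character(0)
  p <- file.path(dir, "region_report.csv")
  write.csv(study@table, p, row.names = FALSE)
  paths <- c(paths, p)
  if (nrow(study@comparisons)) {
    p <- file.path(dir, "comparisons.csv")
    write.csv(study@comparisons, p, row.names = FALSE)
    paths <- c(paths, p)
  }
  p <- file.path(dir, "study_meta.csv")
  write.csv(study@meta, p, row.names = FALSE)
  paths <- c(paths, p)
  invisible(paths)
}
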