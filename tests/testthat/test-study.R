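test_that("percent changes use the first-named scenario as reference", {
  mk <- function(v) {
    tb <- data.frame(region = "cortical", measure = "abs_sigma_C",
                     mean = v / 2, peak = v, n_points = 10L)
    new("RegionReport", table = tb, delta_mm = 0.9, empty_regions = character())
  }
  expect_equal(percentChange(NULL, mk(100), mk(73), "abs_sigma_C",
                             "cortical", "peak"), 27)
  expect_equal(percentChange(NULL, mk(50), mk(50), "abs_sigma_C",
                             "cortical", "peak"), 0)
  ## antisymmetry identity: change(a->b) = -change(b->a) * a/b
  a <- 80; b <- 64
  ab <- percentChange(NULL, mk(a), mk(b), "abs_sigma_C", "cortical", "peak")
  ba <- percentChange(NULL, mk(b), mk(a), "abs_sigma_C", "cortical", "peak")
  expect_equal(ab, -ba * b / a, tolerance = 1e-12)
  expect_error(percentChange(NULL, mk(0), mk(1), "abs_sigma_C",
                             "cortical", "peak"), "zero")
})

test_that("runStudy keeps going past failures and conserves scenarios", {
  good <- tinyScenario()
  bad <- scenarioSpec(implantCatalogue()[["A"]], "P1",
                      bone = boneSegmentSpec(crest_height_mm = 11))
  study <- runStudy(list(ok = good, broken = bad), hi_ratio = 0.12, h0_ratio = 0.12,
                    n_theta = 12, domain_radius_mm = 3.4)
  expect_length(study@reports, 1)
  expect_length(study@failures, 1)
  expect_match(study@failures$broken, "apex")
  ## conservation: reports + failures = scenarios requested
  expect_equal(length(study@reports) + length(study@failures), 2)
  ## every region has all four measures with peak >= mean >= 0
  tb <- study@table
  expect_equal(sort(unique(tb$measure)),
               sort(c("sigma_vm", "sigma_T", "abs_sigma_C", "R")))
  expect_true(all(tb$peak >= tb$mean - 1e-12))
  expect_true(all(tb$mean >= 0))
})

test_that("studies rerun byte-identically", {
  run <- function(dir) {
    study <- runStudy(list(s = tinyScenario()), hi_ratio = 0.12, h0_ratio = 0.12,
                      n_theta = 12, domain_radius_mm = 3.4)
    writeStudyCsv(study, dir)
  }
  d1 <- file.path(tempdir(), "study_a")
  d2 <- file.path(tempdir(), "study_b")
  run(d1); run(d2)
  for (f in c("region_report.csv", "study_meta.csv")) {
    expect_identical(readBin(file.path(d1, f), "raw", 1e6),
                     readBin(file.path(d2, f), "raw", 1e6))
  }
})

test_that("the bone-loss sweep tabulates increases against the pristine case", {
  sw <- boneLossSweep(tinyImplant(), fractions = c(0, 0.5),
                      hi_ratio = 0.12, h0_ratio = 0.12, n_theta = 12,
                      domain_radius_mm = 3.4)
  expect_length(sw@reports, 2)
  cmp <- sw@comparisons
  expect_true(all(cmp$reference == "loss00"))
  ## one row per (scenario, region, measure)
  expect_equal(nrow(cmp), nrow(sw@reports[["loss50"]]@table))
  ## cortical Von Mises stresses increase with cratering
  expect_gt(cmp$pct_increase_peak[cmp$region == "cortical" &
                                    cmp$measure == "sigma_vm"], 0)
})
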