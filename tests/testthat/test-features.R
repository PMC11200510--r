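# Zonal histogram statistics and per-case feature records.

test_that("constant zones give degenerate-but-defined statistics", {
  s <- zoneStatistics(rep(7, 20))
  expect_equal(unname(s[c("mean", "median", "p10", "p90")]), rep(7, 4))
  expect_identical(unname(s["skewness"]), 0)
  expect_identical(unname(s["kurtosis"]), 0)
  expect_true(isTRUE(attr(s, "degenerate")))
})

test_that("percentiles follow the linear-interpolation convention", {
  s <- zoneStatistics(1:100, c("p10", "p90"))
  expect_equal(unname(s["p10"]), 10.9)
  expect_equal(unname(s["p90"]), 90.1)
})

test_that("moment statistics match their definitions", {
  expect_equal(unname(zoneStatistics(c(-1, 0, 1), "skewness")), 0)
  set.seed(31)
  x <- rnorm(5000)
  s <- zoneStatistics(x, c("skewness", "kurtosis"))
  # population-moment definitions (cross-checked against e1071 type 1)
  expect_equal(unname(s["skewness"]), e1071::skewness(x, type = 1),
               tolerance = 1e-12)
  expect_equal(unname(s["kurtosis"]), e1071::kurtosis(x, type = 1) + 3,
               tolerance = 1e-12)
  # permutation invariance
  expect_equal(zoneStatistics(x), zoneStatistics(sample(x)), tolerance = 1e-12)
  # adding voxels at the mean leaves the mean unchanged
  expect_equal(unname(zoneStatistics(c(x, rep(mean(x), 50)), "mean")),
               mean(x), tolerance = 1e-12)
})

test_that("feature records have the promised combinatorics and names", {
  case <- buildPhantom(tinySpec(noiseSigma = 0), "PCa", caseSeed = 41L)
  maps <- case@truth

  adcRec <- extractFeatures(maps, case@masks,
                            featureSpec(parameters = "ADC",
                                        zones = c("CZ", "PZ")))
  expect_length(adcRec, 12L)   # 1 parameter x 6 statistics x 2 zones

  both <- extractFeatures(maps, case@masks, modalityFeatureSpec("CZ+PZ"))
  expect_length(both, 36L)
  czRec <- extractFeatures(maps, case@masks, modalityFeatureSpec("CZ"))
  pzRec <- extractFeatures(maps, case@masks, modalityFeatureSpec("PZ"))
  expect_identical(both, c(czRec, pzRec))   # concatenation contract
  expect_true(all(grepl("^(cz|pz)_(f|D|Dstar)_", names(both))))

  lat <- extractFeatures(maps, case@masks, modalityFeatureSpec("ADC"))
  expect_length(lat, 24L)      # laterality doubles the ADC record
  expect_true(any(grepl("_left_", names(lat))) &&
              any(grepl("_right_", names(lat))))
})

test_that("a lesion lowers the host zone's mean diffusion coefficient", {
  spec <- tinySpec(noiseSigma = 0)
  pca <- buildPhantom(spec, "PCa", caseSeed = 50L)
  bph <- buildPhantom(spec, "BPH", caseSeed = 50L)   # same geometry, benign lesion
  hostZone <- if (any(pca@masks@pz & pca@masks@lesion)) "pz" else "cz"
  zmask <- slot(pca@masks, hostZone)
  expect_lt(mean(pca@truth@d[zmask]), mean(bph@truth@d[zmask]))
})

test_that("deterministic records and loud failures on starved zones", {
  case <- buildPhantom(tinySpec(), "BPH", caseSeed = 61L)
  maps <- case@truth
  r1 <- extractFeatures(maps, case@masks, modalityFeatureSpec("CZ+PZ"))
  r2 <- extractFeatures(maps, case@masks, modalityFeatureSpec("CZ+PZ"))
  expect_identical(r1, r2)

  starved <- maps
  starved@status[case@masks@cz] <- "max-iter"
  expect_error(extractFeatures(starved, case@masks, modalityFeatureSpec("CZ"),
                               caseId = "case_x"),
               "case_x.*CZ")
})

test_that("cohort feature tables validate and carry one labelled row per case", {
  cohort <- generateCohort(tinySpec(seed = 71L))
  truthMaps <- lapply(cohort, function(cs) cs@truth)
  tab <- cohortFeatureTable(cohort, truthMaps, modalityFeatureSpec("CZ+PZ"))
  expect_identical(nrow(tab), 6L)
  expect_identical(ncol(tab), 38L)   # case_id + 36 features + label
  expect_silent(checkFeatureTable(tab))
  expect_setequal(tab$label, c("PCa", "BPH"))
})
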