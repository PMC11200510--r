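# Phantom generation: tissue sampling, geometry, noise model, cohorts.

test_that("zero-variance tissue distributions return the means exactly", {
  tc <- ivimcad:::tissueClass("PCa-lesion",
    s0 = c(1100, 0, 600, 1500), f = c(0.18, 0, 0.05, 0.35),
    d = c(0.8e-3, 0, 0.4e-3, 1.2e-3), dstar = c(15e-3, 0, 5e-3, 30e-3))
  p <- sampleTissueParams(tc)
  expect_identical(c(p@s0, p@f, p@d, p@dstar), c(1100, 0.18, 0.8e-3, 15e-3))
})

test_that("every tissue draw satisfies the parameter invariants", {
  set.seed(4)
  for (tc in defaultTissueClasses()) {
    draws <- sampleTissueParams(tc, n = 500)
    expect_true(all(draws[, "f"] >= 0 & draws[, "f"] <= 1))
    expect_true(all(draws[, "d"] > 0))
    expect_true(all(draws[, "d"] <= draws[, "dstar"]))
    expect_true(all(draws[, "s0"] > 0))
    d <- tc@dist
    expect_true(all(draws >= matrix(d$lo, 500, 4, byrow = TRUE) - 1e-12))
    expect_true(all(draws <= matrix(d$hi, 500, 4, byrow = TRUE) + 1e-12))
  }
})

test_that("tumour tissue samples lower D than benign peripheral zone", {
  set.seed(12)
  classes <- defaultTissueClasses()
  dPca <- mean(sampleTissueParams(classes[["PCa-lesion"]], 1000)[, "d"])
  dPz <- mean(sampleTissueParams(classes[["benign-PZ"]], 1000)[, "d"])
  expect_lt(dPca, dPz)
})

test_that("phantom geometry obeys the mask contracts", {
  case <- buildPhantom(tinySpec(), "PCa", caseSeed = 3L)
  m <- case@masks
  expect_identical(sum(m@cz & m@pz), 0L)
  expect_true(all(m@prostate[m@cz | m@pz]))
  expect_true(all(m@cz[m@lesion] | m@pz[m@lesion]))   # lesion inside a zone
  expect_gt(sum(m@lesion), 0)
  expect_identical(dim(dwiData(case@dwi))[4], 9L)
})

test_that("noiseless phantom signal equals truth S0 at b = 0 and decays in b", {
  spec <- tinySpec(noiseSigma = 0)
  case <- buildPhantom(spec, "BPH", caseSeed = 6L)
  arr <- dwiData(case@dwi)
  inP <- case@masks@prostate
  b0 <- arr[, , , 1]
  expect_equal(b0[inP], case@truth@s0[inP], tolerance = 1e-12)
  for (j in 2:dim(arr)[4])
    expect_true(all(arr[, , , j][inP] < arr[, , , j - 1][inP]))
})

test_that("oversized lesions are rejected", {
  expect_error(buildPhantom(tinySpec(lesionRadius = 30), "PCa", caseSeed = 1L),
               "lesion radius")
})

test_that("Rician noise matches its closed-form moments", {
  set.seed(77)
  n <- 1e5
  # signal 0: Rayleigh mean sigma * sqrt(pi/2)
  r0 <- addRicianNoise(rep(0, n), 10)
  expect_lt(abs(mean(r0) / (10 * sqrt(pi / 2)) - 1), 0.01)
  expect_true(all(r0 >= 0))
  # high SNR: mean approx sqrt(s^2 + 2 sigma^2)
  r1 <- addRicianNoise(rep(1000, n), 10)
  expect_lt(abs(mean(r1) / sqrt(1000^2 + 2 * 10^2) - 1), 0.005)
  # sigma 0 is the identity; negative sigma rejected
  x <- runif(10)
  expect_identical(addRicianNoise(x, 0), x)
  expect_error(addRicianNoise(x, -1), "sigma")
})

test_that("cohorts have the specified composition and unique ids", {
  spec <- tinySpec(seed = 19L)
  cohort <- generateCohort(spec)
  labels <- vapply(cohort, function(cs) cs@label, "")
  ids <- vapply(cohort, function(cs) cs@caseId, "")
  expect_identical(sum(labels == "PCa"), 3L)
  expect_identical(sum(labels == "BPH"), 3L)
  expect_false(anyDuplicated(ids) > 0)

  solo <- generateCohort(phantomSpec(cohortSize = 1L, nPositive = 0L,
                                     gridShape = c(24L, 24L, 2L),
                                     lesionRadius = 2, seed = 5L))
  expect_identical(vapply(solo, function(cs) cs@label, ""), "BPH")
})

test_that("identical specs generate identical cohorts", {
  spec <- tinySpec(seed = 42L)
  a <- generateCohort(spec)
  b <- generateCohort(spec)
  expect_identical(vapply(a, function(cs) cs@label, ""),
                   vapply(b, function(cs) cs@label, ""))
  expect_identical(dwiData(a[[1]]@dwi), dwiData(b[[1]]@dwi))
  expect_identical(a[[1]]@truth@d, b[[1]]@truth@d)
})
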