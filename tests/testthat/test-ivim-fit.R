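# The bounded Levenberg-Marquardt fitter and the voxel-wise map driver.

test_that("noiseless curves are recovered to well under 0.1% relative", {
  b <- defaultBValues()
  truth <- c(1000, 0.15, 0.9e-3, 12e-3)
  fr <- fitIvimCurve(curveFromVector(truth, b))
  expect_identical(fr@status, "converged")
  fitted <- c(fr@params@s0, fr@params@f, fr@params@d, fr@params@dstar)
  expect_true(all(abs(fitted / truth - 1) < 1e-3))
  expect_lt(fr@ssr, 1e-12)
})

test_that("the mono-exponential limit (f = 0) is identified", {
  b <- defaultBValues()
  cur <- signalCurve(b, 1000 * exp(-b * 1.3e-3))
  fr <- fitIvimCurve(cur)
  expect_lt(fr@params@f, 0.01)
  expect_lt(abs(fr@params@d - 1.3e-3) / 1.3e-3, 0.01)
  # ADC consistency: for f = 0 data ADC equals the generating D
  expect_equal(adcFromCurve(cur, 1400), 1.3e-3, tolerance = 1e-9)
})

test_that("accepted LM steps never increase the SSR from initialization", {
  set.seed(5)
  b <- defaultBValues()
  cfg <- fitConfig()
  for (i in 1:20) {
    p <- randomIvimParams(1)
    noisy <- addRicianNoise(ivimSignal(ivimParams(p[1], p[2], p[3], p[4]), b),
                            p[1] / 20)
    ini <- ivimcad:::segmentedInit(matrix(noisy, 1), b, cfg)
    initSSR <- ivimSSR(signalCurve(b, noisy),
                       c(ini$init[1, 1], ini$init[1, 2], ini$init[1, 3],
                         max(ini$init[1, 4], ini$init[1, 3])))
    fr <- fitIvimCurve(signalCurve(b, noisy), cfg)
    expect_lte(fr@ssr, initSSR + 1e-9)
  }
})

test_that("fitted SSR matches the independent reference fitter on noisy curves", {
  set.seed(9)
  b <- defaultBValues()
  for (i in 1:15) {
    p <- randomIvimParams(1)
    y <- addRicianNoise(ivimSignal(ivimParams(p[1], p[2], p[3], p[4]), b),
                        p[1] / 30)
    mine <- fitIvimCurve(signalCurve(b, y))
    ref <- nlsLmFit(y, b)
    refSSR <- ivimSSR(signalCurve(b, y),
                      c(ref[1], min(max(ref[2], 0), 1),
                        min(ref[3], ref[4]), max(ref[3], ref[4])))
    expect_lte(mine@ssr, refSSR * 1.001 + 1e-12)
  }
})

test_that("capping the fitted b-range at 700 still identifies noiseless curves", {
  b <- defaultBValues()
  truth <- c(1000, 0.15, 0.9e-3, 12e-3)
  fr <- fitIvimCurve(curveFromVector(truth, b), fitConfig(maxB = 700))
  fitted <- c(fr@params@s0, fr@params@f, fr@params@d, fr@params@dstar)
  expect_true(all(abs(fitted / truth - 1) < 1e-3))
  expect_error(fitIvimCurve(curveFromVector(truth, b), fitConfig(maxB = 150)),
               "fewer than 4")
})

test_that("degenerate and pathological curves are flagged, never fatal", {
  b <- defaultBValues()
  allZero <- signalCurve(b, rep(0, length(b)))
  expect_identical(fitIvimCurve(allZero)@status, "degenerate-input")
  spike <- signalCurve(b, c(rep(0, 8), 50))
  expect_true(fitIvimCurve(spike)@status %in%
                c("converged", "max-iter", "degenerate-input"))
})

test_that("a single-voxel mask reduces the volume fit to the curve fit", {
  spec <- tinySpec(noiseSigma = 10)
  case <- buildPhantom(spec, "PCa", caseSeed = 21L)
  mask <- array(FALSE, dim = spec@gridShape)
  vox <- which(case@masks@cz, arr.ind = TRUE)[1, ]
  mask[vox[1], vox[2], vox[3]] <- TRUE
  maps <- fitIvimVolume(case@dwi, mask, smoothSigma = 0)
  fr <- fitIvimCurve(voxelCurve(case@dwi, vox[1], vox[2], vox[3]))
  expect_equal(maps@f[vox[1], vox[2], vox[3]], fr@params@f, tolerance = 1e-12)
  expect_equal(maps@d[vox[1], vox[2], vox[3]], fr@params@d, tolerance = 1e-12)
  expect_identical(maps@status[vox[1], vox[2], vox[3]], fr@status)
  expect_true(all(is.na(maps@s0[!mask])))
})

test_that("a noiseless phantom's maps reproduce the truth maps", {
  spec <- tinySpec(noiseSigma = 0)
  case <- buildPhantom(spec, "BPH", caseSeed = 33L)
  maps <- fitIvimVolume(case@dwi, case@masks@prostate, smoothSigma = 0)
  conv <- maps@status == "converged"
  expect_gt(mean(conv[case@masks@prostate]), 0.99)
  for (pn in c("f", "D", "Dstar")) {
    est <- parameterMap(maps, pn)[conv]
    tru <- parameterMap(case@truth, pn)[conv]
    expect_lt(max(abs(est / tru - 1)), 1e-3)
  }
  # noiseless ADC map (unsmoothed) agrees with the analytic truth ADC
  expect_lt(max(abs(maps@adc[conv] - case@truth@adc[conv])), 1e-9)
})

test_that("mask-restricted smoothing preserves a constant ADC field", {
  spec <- tinySpec(noiseSigma = 0)
  case <- buildPhantom(spec, "PCa", caseSeed = 8L)
  mask <- case@masks@prostate
  const <- array(NA_real_, dim = dim(mask))
  const[mask] <- 1.234e-3
  sm <- ivimcad:::smoothAdcInPlane(const, mask, sigma = 1)
  expect_equal(sm[mask], const[mask], tolerance = 1e-12)
  expect_true(all(is.na(sm[!mask])))
})

test_that("an empty mask yields empty maps with a warning", {
  spec <- tinySpec(noiseSigma = 0)
  case <- buildPhantom(spec, "PCa", caseSeed = 2L)
  empty <- array(FALSE, dim = spec@gridShape)
  expect_warning(maps <- fitIvimVolume(case@dwi, empty), "empty mask")
  expect_true(all(maps@status == "not-fitted"))
  expect_true(all(is.na(maps@d)))
})
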