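# The bi-exponential forward model, its objective, and the ADC closed form.

test_that("forward model returns S0 at b = 0 and decays monotonically", {
  set.seed(1)
  P <- randomIvimParams(25)
  for (i in seq_len(nrow(P))) {
    p <- ivimParams(P[i, 1], P[i, 2], P[i, 3], P[i, 4])
    expect_equal(ivimSignal(p, 0), P[[i, 1]], tolerance = 1e-15)
    s <- ivimSignal(p, defaultBValues())
    expect_true(all(diff(s) < 0))   # strictly decreasing for D > 0
    expect_true(all(s > 0))
  }
})

test_that("forward model reduces to mono-exponential at f = 0 and matches a frozen value", {
  expect_equal(ivimSignal(ivimParams(1000, 0, 1e-3, 1e-3), 1000),
               1000 * exp(-1))
  # independent high-precision evaluation of the model at these inputs
  expect_equal(ivimSignal(ivimParams(1000, 0.1, 1.0e-3, 10e-3), 500),
               546.5513884, tolerance = 1e-8)
})

test_that("invalid parameters are rejected", {
  expect_error(ivimParams(0, 0.1, 1e-3, 1e-2), "S0")
  expect_error(ivimParams(1000, 1.2, 1e-3, 1e-2), "f")
  expect_error(ivimParams(1000, 0.1, 2e-2, 1e-2), "D\\*")
  expect_error(ivimSignal(ivimParams(1000, 0.1, 1e-3, 1e-2), -5), "b")
})

test_that("residuals and SSR satisfy their algebraic identities", {
  p <- ivimParams(1000, 0.1, 1.0e-3, 10e-3)
  b <- defaultBValues()
  exact <- signalCurve(b, ivimSignal(p, b))
  expect_equal(ivimResiduals(exact, p), rep(0, length(b)))
  expect_equal(ivimSSR(exact, p), 0)

  # constant offset c at every one of N points -> SSR = N * c^2
  cOff <- 3.5
  shifted <- signalCurve(b, ivimSignal(p, b) + cOff)
  expect_equal(ivimSSR(shifted, p), length(b) * cOff^2)

  # +1 on the b = 0 point only -> SSR = 1 (direct summation)
  bump <- ivimSignal(p, b); bump[1] <- bump[1] + 1
  expect_equal(ivimSSR(signalCurve(b, bump), p), 1)
})

test_that("log-linear mono-exponential fit recovers exact and flat curves", {
  b <- defaultBValues()
  cur <- signalCurve(b, 800 * exp(-b * 1.2e-3))
  fit <- monoExpFit(cur, bMin = 0)
  expect_equal(fit$d, 1.2e-3, tolerance = 1e-12)
  expect_equal(fit$logIntercept, log(800), tolerance = 1e-12)

  flat <- signalCurve(b, rep(500, length(b)))
  expect_equal(monoExpFit(flat, bMin = 0)$d, 0)
})

test_that("high-b log-linear fit approximates D for bi-exponential data", {
  b <- defaultBValues()
  cur <- curveFromVector(c(1000, 0.1, 1e-3, 10e-3), b)
  fit <- monoExpFit(cur, bMin = 200)
  # brute-force minimization of the same log-linear objective as the oracle
  sel <- b >= 200
  obj <- function(th) sum((log(cur@intensities[sel]) - th[1] + th[2] * b[sel])^2)
  brute <- optim(c(log(1000), 1e-3), obj, control = list(reltol = 1e-14))
  expect_equal(fit$d, brute$par[2], tolerance = 1e-4)
  expect_lt(abs(fit$d - 1e-3) / 1e-3, 0.05)
})

test_that("log-linear fit flags degenerate input and excludes non-positive points", {
  b <- defaultBValues()
  one <- signalCurve(b, c(rep(0, 8), 10))
  expect_warning(out <- monoExpFit(one, bMin = 0), "non-positive")
  expect_identical(out$status, "degenerate-input")
  expect_identical(out$nExcluded, 8L)
})

test_that("ADC closed form inverts the mono-exponential generator", {
  b <- defaultBValues()
  expect_equal(adcFromCurve(signalCurve(b, rep(900, length(b))), 700), 0)
  cur <- signalCurve(c(0, 100, 500, 1000), c(1000, 933, 717, 500))
  expect_equal(adcFromCurve(cur, 1000), log(2) / 1000, tolerance = 1e-9)
  mono <- signalCurve(b, 1200 * exp(-b * 1.1e-3))
  for (bt in b[-1])
    expect_equal(adcFromCurve(mono, bt), 1.1e-3, tolerance = 1e-12)
  zero <- signalCurve(b, rep(0, length(b)))
  expect_identical(attr(adcFromCurve(zero, 700), "status"), "degenerate-input")
})
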