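# ITC one-site fitting, KD fold changes, Tm calling and screening.

test_that("dilution correction and normalization drop the first point", {
  # X0 * v = 1 umol per injection; heats in ucal
  s <- titrationSeries(injectionVolumes = c(1e-5, 1e-5),
                       rawHeats = c(-10, -9), cellConc = 1e-5,
                       syringeConc = 0.1, dilutionHeats = -1)
  norm <- correctAndNormalize(s)
  expect_identical(norm$use, c(FALSE, TRUE))
  # (-9 - (-1)) ucal / 1 umol = -8 ucal/umol = -0.008 kcal/mol
  expect_equal(norm$ndh[2L], -0.008)
  expect_error(titrationSeries(c(1e-5, 1e-5), c(-10, -9), 1e-5, 0.1,
                               dilutionHeats = c(-1, -1, -1)))
  zero <- titrationSeries(c(1e-5, 1e-5), c(0, 0), 1e-5, 0.1,
                          dilutionHeats = 0)
  expect_equal(correctAndNormalize(zero)$ndh, c(0, 0))
  nodil <- titrationSeries(c(1e-5, 1e-5), c(-10, -9), 1e-5, 0.1)
  expect_warning(out <- correctAndNormalize(nodil), "dilution")
  expect_true(attr(out, "uncorrected"))
})

test_that("noiseless titrations are recovered essentially exactly", {
  cfg <- assayConfig(trueKd = 2.6e-6, trueDh = -10, trueN = 1)
  fit <- fitOneSite(simulateItc(cfg))
  expect_true(isConverged(fit))
  expect_lt(abs(kd(fit) - 2.6e-6) / 2.6e-6, 0.01)
  expect_lt(abs(stoichiometry(fit) - 1), 0.01)
  expect_lt(abs(deltaH(fit) + 10) / 10, 0.01)
})

test_that("the high-c limit gives a sharp step with n recovered", {
  # c = n*M0/kd = 1000: step at molar ratio n
  cfg <- assayConfig(trueKd = 1e-8, cellConc = 1e-5, syringeConc = 1.5e-4,
                     trueN = 0.8)
  s <- simulateItc(cfg)
  norm <- suppressWarnings(correctAndNormalize(s))
  before <- norm$ndh[norm$molar_ratio < 0.7]
  after <- norm$ndh[norm$molar_ratio > 0.95]
  expect_lt(max(abs(after)), 0.05 * max(abs(before)))  # sharp saturation
  fit <- fitOneSite(s)
  expect_lt(abs(stoichiometry(fit) - 0.8) / 0.8, 0.02)
})

test_that("flat and zero-enthalpy series are called no-binding", {
  cfg <- assayConfig(trueDh = 0)
  fit <- fitOneSite(simulateItc(cfg))
  expect_false(isConverged(fit))
  expect_identical(fit@status, "no-binding")
  expect_error(fitOneSite(titrationSeries(rep(1e-5, 3), rep(0, 3), 1e-5,
                                          1e-4, dilutionHeats = 0)),
               "at least 5")
})

test_that("fold reductions reproduce ratios and are scale invariant", {
  expect_identical(foldReduction(151e-6, 2.6e-6)@rounded, 58L)
  expect_identical(foldReduction(2.6e-6, 2.6e-6)@rounded, 1L)
  expect_identical(foldReduction(209e-6, 2.6e-6)@rounded, 80L)
  set.seed(51)
  for (i in 1:20) {
    x <- runif(1, 1e-7, 1e-3); y <- runif(1, 1e-7, 1e-3); a <- runif(1, 0.1, 10)
    expect_equal(foldReduction(a * x, a * y)@ratio,
                 foldReduction(x, y)@ratio)
    expect_equal(foldReduction(x, x)@ratio, 1)
  }
  # round half away from zero matches the printed integers
  expect_identical(foldReduction(2.5, 1)@rounded, 3L)
  expect_error(foldReduction(-1e-6, 2.6e-6), "positive")
})

test_that("noiseless melt curves are called to within a grid step", {
  for (tm0 in c(40, 55, 70.25)) {
    curve <- simulateMelt(assayConfig(trueTm = tm0))
    call <- callTm(curve)
    expect_true(call@transition)
    expect_lt(abs(tmValue(call) - tm0), 0.5)
  }
})

test_that("drifting or flat curves give no transition", {
  tt <- seq(23, 85, 0.5)
  expect_false(callTm(meltCurve(tt, 10 + 0.3 * tt))@transition)
  expect_false(callTm(simulateMelt(assayConfig(meltAmplitude = 0,
                                               noiseSd = 0.001),
                                   seed = 5))@transition)
})

test_that("Tm calls are invariant under affine fluorescence transforms", {
  m <- simulateMelt(assayConfig(noiseSd = 0.02), seed = 6)
  a <- callTm(m)
  b <- callTm(meltCurve(m@temperatures, 7 * m@fluorescence + 123))
  expect_equal(tmValue(a), tmValue(b), tolerance = 1e-9)
  expect_identical(a@transition, b@transition)
})

test_that("the strict 2-degree screening rule classifies shifts", {
  expect_true(screenDeltaTm(57.1, 55.0))
  expect_false(screenDeltaTm(56.9, 55.0))
  expect_false(screenDeltaTm(57.0, 55.0))   # strict inequality
  expect_false(screenDeltaTm(53.0, 55.0))   # decreases never significant
  expect_error(screenDeltaTm(NA_real_, 55))
})
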