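# Instrument simulator: envelope, Beer-Lambert transmittance, noise model.

test_that("instrument timing arithmetic: duty cycle, scan duration, pulse count", {
  cfg <- instrumentConfig("transmission")
  expect_equal(dutyCycle(cfg), 0.05)
  expect_equal(scanDuration(cfg), 1)
  expect_identical(pulsesPerScan(cfg), 100000L)
  expect_equal(nominalSpacing(cfg, 390L), 275 / 390)
  expect_error(instrumentConfig("transmission", pulseWidthNs = 2e7),
               "duty cycle")
})

test_that("emission envelope is normalised, usable across the range, and deterministic", {
  cfg <- smallConfig()
  wn <- scanWavenumbers(cfg)
  env <- emissionEnvelope(wn, cfg)
  expect_equal(emissionEnvelope(1060, cfg), 1)   # exact at the gain centre
  expect_equal(max(env), 1, tolerance = 1e-5)    # grid point nearest centre
  expect_gt(env[1], 0.1)                  # 1200 cm-1 edge
  expect_gt(env[length(env)], 0.1)        # 925 cm-1 edge
  expect_identical(env, emissionEnvelope(wn, cfg))
  expect_error(emissionEnvelope(1500, cfg), "scan range")
})

test_that("blank transmittance is the water background alone and ratioed absorbance vanishes", {
  cfg <- smallConfig()
  wn <- c(950, 1050, 1150)
  Tblank <- sampleTransmittance(numeric(0), wn, cfg)
  expect_equal(Tblank, 10^(-waterAbsorptivity(wn, cfg) *
                             samplePathLength(wn, cfg)))
  Tzero <- sampleTransmittance(c(glucose = 0, albumin = 0), wn, cfg)
  expect_equal(-log10(Tzero / Tblank), rep(0, 3))
})

test_that("analyte absorbance is Beer-Lambert linear in concentration", {
  cfg <- smallConfig()
  wn <- seq(930, 1195, by = 5)
  A1 <- -log10(sampleTransmittance(c(glucose = 200), wn, cfg) /
               sampleTransmittance(numeric(0), wn, cfg))
  A2 <- -log10(sampleTransmittance(c(glucose = 400), wn, cfg) /
               sampleTransmittance(numeric(0), wn, cfg))
  expect_equal(A2, 2 * A1, tolerance = 1e-12)
  # additivity across analytes
  Au <- -log10(sampleTransmittance(c(urea = 150), wn, cfg) /
               sampleTransmittance(numeric(0), wn, cfg))
  Amix <- -log10(sampleTransmittance(c(glucose = 200, urea = 150), wn, cfg) /
                 sampleTransmittance(numeric(0), wn, cfg))
  expect_equal(Amix, A1 + Au, tolerance = 1e-12)
  expect_error(sampleTransmittance(c(glucose = -1), wn, cfg),
               "non-negative")
})

test_that("transmission vs ATR analyte absorbance ratio is ~7 at mid-band", {
  cfgT <- smallConfig("transmission")
  cfgA <- smallConfig("ATR")
  wn <- 1080
  aT <- -log10(sampleTransmittance(c(glucose = 400), wn, cfgT) /
               sampleTransmittance(numeric(0), wn, cfgT))
  aA <- -log10(sampleTransmittance(c(glucose = 400), wn, cfgA) /
               sampleTransmittance(numeric(0), wn, cfgA))
  expect_gt(aT / aA, 6)
  expect_lt(aT / aA, 8)
  # the ratio is exactly the path-length ratio under Beer-Lambert
  expect_equal(aT / aA,
               165 / interactionLength(cfgA@prism, wn), tolerance = 1e-9)
})

test_that("noiseless simulation yields identical scans equal to the injected signal", {
  cfg <- smallNoiselessConfig()
  scans <- simulateMeasurement(c(lactate = 60), cfg, nScans = 3, seed = 1)
  expect_length(scans, 3L)
  expect_identical(scans[[1]]@intensities, scans[[2]]@intensities)
  expect_identical(scans[[2]]@intensities, scans[[3]]@intensities)
  wn <- scanWavenumbers(cfg)
  expect_equal(scans[[1]]@intensities,
               emissionEnvelope(wn, cfg) *
                 sampleTransmittance(c(lactate = 60), wn, cfg),
               tolerance = 1e-14)
  expect_identical(length(scans[[1]]@intensities), pulsesPerScan(cfg))
})

test_that("simulation is reproducible under a seed and respects metadata", {
  cfg <- smallConfig()
  a <- simulateMeasurement(c(glucose = 100), cfg, nScans = 2, seed = 5,
                           sampleId = "S3", seriesId = 2L, dayId = 1L)
  b <- simulateMeasurement(c(glucose = 100), cfg, nScans = 2, seed = 5,
                           sampleId = "S3", seriesId = 2L, dayId = 1L)
  expect_identical(a[[1]]@intensities, b[[1]]@intensities)
  expect_identical(a[[2]]@intensities, b[[2]]@intensities)
  expect_identical(a[[1]]@sampleId, "S3")
  expect_identical(a[[1]]@seriesId, 2L)
  expect_false(identical(a[[1]]@intensities, a[[2]]@intensities))
})

test_that("a background/sample pair shares the series but differs in content", {
  cfg <- smallNoiselessConfig()
  pair <- simulateSamplePair(c(glucose = 400), cfg, nScans = 2, seed = 2)
  expect_true(pair$background[[1]]@isBackground)
  expect_false(pair$sample[[1]]@isBackground)
  expect_gt(mean(pair$background[[1]]@intensities),
            mean(pair$sample[[1]]@intensities))  # absorption removes light
})

test_that("relative noise in ratioed absorbance grows below 970 cm-1 in transmission but not in ATR", {
  mkreps <- function(setup) {
    cfg <- smallConfig(setup, perPulseRsd = 0, scanOffsetSd = 0,
                       scanShiftSd = 0, seriesDriftSd = 0,
                       detectorNoiseSd = 2e-4)
    lapply(1:20, function(i)
      absorbanceFromPair(simulateSamplePair(c(glucose = 200), cfg,
                                            nScans = 2),
                         binSize = 5L))
  }
  sdWindow <- function(reps, lo, hi) {
    wn <- wavenumbers(reps[[1]])
    m <- sapply(reps, spectrumValues)
    mean(apply(m[wn >= lo & wn <= hi, ], 1, sd))
  }
  set.seed(8)
  repsT <- mkreps("transmission")
  repsA <- mkreps("ATR")
  lowT <- sdWindow(repsT, 930, 960); midT <- sdWindow(repsT, 1050, 1150)
  lowA <- sdWindow(repsA, 930, 960); midA <- sdWindow(repsA, 1050, 1150)
  expect_gt(lowT / midT, 3)             # strong amplification at the edge
  expect_gt(lowT / midT, 2 * lowA / midA)  # much weaker in ATR (short path)
})
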