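# Pulse binning, scan averaging, chi-squared alignment, absorbance, RSD.

mkScan <- function(intensities, wnHi = 1200, wnLo = 925) {
  P <- length(intensities)
  new("ScanRecord", intensities = intensities,
      wavenumbers = wnHi - (seq_len(P) - 0.5) * (wnHi - wnLo) / P,
      sampleId = "S1", seriesId = 1L, dayId = 1L, isBackground = FALSE)
}

test_that("binning a constant pulse train returns the constant, on an ascending axis", {
  sc <- mkScan(rep(2.5, 1000))
  sp <- binPulses(sc, binSize = 10L)
  expect_identical(nPoints(sp), 100L)
  expect_equal(spectrumValues(sp), rep(2.5, 100))
  expect_true(all(diff(wavenumbers(sp)) > 0))
  expect_equal(nPoints(binPulses(sc, 10L, 80L)), 80L)
  expect_error(binPulses(sc, 2000L), "fewer pulses")
  expect_error(binPulses(sc, 10L, 150L), "complete bins")
})

test_that("default binning yields a 390-point spectrum spanning the scan at ~0.7 cm-1 spacing", {
  cfg <- instrumentConfig("transmission", perPulseRsd = 0, scanOffsetSd = 0,
                          scanShiftSd = 0, detectorNoiseSd = 0)
  sc <- simulateMeasurement(numeric(0), cfg, nScans = 1, seed = 1)[[1]]
  sp <- binPulses(sc, 255L)
  expect_identical(nPoints(sp), 390L)
  expect_equal(mean(diff(wavenumbers(sp))), 255 * 275 / 100000,
               tolerance = 1e-9)
  expect_equal(mean(diff(wavenumbers(sp))), 0.7, tolerance = 0.01)
  expect_gt(max(wavenumbers(sp)), 1199)
  expect_lt(min(wavenumbers(sp)), 932.5)
})

test_that("binning reduces i.i.d. pulse noise by sqrt(binSize)", {
  set.seed(31)
  sigma <- 0.05
  reps <- replicate(400, {
    sc <- mkScan(1 + rnorm(400, 0, sigma))
    spectrumValues(binPulses(sc, 16L))
  })
  sdBin <- mean(apply(reps, 1, sd))
  expect_equal(sdBin, sigma / sqrt(16), tolerance = 0.05)
})

test_that("scan averaging is the point-wise mean and checks its inputs", {
  sp <- bumpySpectrum()
  avg <- averageScans(list(sp, sp, sp))
  expect_equal(spectrumValues(avg), spectrumValues(sp))
  expect_identical(avg@metadata$nAveraged, 3L)
  set.seed(7)
  noisy <- lapply(1:10, function(i)
    Spectrum(wavenumbers(sp), spectrumValues(sp) + rnorm(nPoints(sp), 0, 0.01)))
  expect_lt(sd(spectrumValues(averageScans(noisy)) - spectrumValues(sp)),
            2 * 0.01 / sqrt(10))
  expect_error(averageScans(list()), "empty")
  other <- Spectrum(wavenumbers(sp) + 1, spectrumValues(sp))
  expect_error(averageScans(list(sp, other)), "identical grids")
})

test_that("alignment recovers the identity, pure shifts, and pure offsets exactly", {
  ref <- bumpySpectrum()
  id <- alignScan(ref, ref, maxShift = 5L)
  expect_identical(id$solution@binShift, 0L)
  expect_equal(id$solution@intensityOffset, 0)
  expect_equal(id$solution@chiSquared, 0)
  # displacing the values two bins toward higher indices is recovered as -2
  sh <- alignScan(ref, displaceValues(ref, 2), maxShift = 5L)
  expect_identical(sh$solution@binShift, -2L)
  off <- alignScan(ref, Spectrum(wavenumbers(ref),
                                 spectrumValues(ref) + 0.01))
  expect_identical(off$solution@binShift, 0L)
  expect_equal(off$solution@intensityOffset, -0.01, tolerance = 1e-12)
  expect_equal(spectrumValues(off$aligned), spectrumValues(ref),
               tolerance = 1e-12)
})

test_that("alignment recovery holds over shift x offset combinations, and within 1 bin under noise", {
  ref <- bumpySpectrum()
  for (k in -3:3) for (o in c(0, -0.01, 0.01)) {
    tgt <- displaceValues(ref, k)
    tgt <- Spectrum(wavenumbers(tgt), spectrumValues(tgt) + o)
    sol <- alignScan(ref, tgt, maxShift = 4L)$solution
    expect_identical(sol@binShift, -as.integer(k))
    expect_equal(sol@intensityOffset, -o, tolerance = 1e-10)
  }
  set.seed(12)
  for (k in c(-2, 0, 2)) {
    tgt <- displaceValues(ref, k)
    tgt <- Spectrum(wavenumbers(tgt),
                    spectrumValues(tgt) + rnorm(nPoints(ref), 0, 0.002))
    sol <- alignScan(ref, tgt, maxShift = 4L)$solution
    expect_lte(abs(sol@binShift + k), 1L)
  }
})

test_that("alignment refuses too-short overlaps and breaks ties toward zero shift", {
  shorty <- Spectrum(1:8, rnorm(8))
  expect_error(alignScan(shorty, shorty, maxShift = 2L), "10 points")
  flat <- Spectrum(seq(925, 1200, length.out = 50), rep(1, 50))
  sol <- alignScan(flat, flat, maxShift = 5L)$solution
  expect_identical(sol@binShift, 0L)   # all shifts tie at chi-squared 0
})

test_that("absorbance follows the decade law and flags non-positive intensities", {
  wn <- seq(1000, 1100, length.out = 50)
  i0 <- Spectrum(wn, rep(0.8, 50))
  expect_equal(spectrumValues(computeAbsorbance(i0, i0)), rep(0, 50))
  i1 <- Spectrum(wn, rep(0.008, 50))
  expect_equal(spectrumValues(computeAbsorbance(i1, i0)), rep(2, 50))
  neg <- Spectrum(wn, c(-1, rep(0.5, 49)))
  expect_error(
    expect_error(computeAbsorbance(neg, i0), "1000"),
    NA)
  expect_error(computeAbsorbance(Spectrum(wn + 1, rep(1, 50)), i0),
               "identical grids")
})

test_that("replicate RSD matches the hand-computed two-replicate case", {
  wn <- seq(1000, 1100, length.out = 20)
  a <- Spectrum(wn, rep(1, 20)); b <- Spectrum(wn, rep(3, 20))
  expect_equal(characteriseRsd(list(a, b), c(1000, 1100)), sqrt(2) / 2,
               tolerance = 1e-12)
  expect_equal(characteriseRsd(list(a, a), c(1000, 1100)), 0)
  expect_error(characteriseRsd(list(a), c(1000, 1100)), "2 replicates")
  expect_error(characteriseRsd(list(a, b), c(2000, 2100)), "outside")
})

test_that("sigma_A = RSD / ln(10): 0.07% intensity noise is 0.0003 AU", {
  expect_equal(absorbanceNoiseFromRsd(0.0007), 0.0007 / log(10))
  expect_equal(absorbanceNoiseFromRsd(0.0007), 3.0e-4, tolerance = 0.02)
})

test_that("the noiseless chain reproduces the injected Beer-Lambert profile and is exactly linear", {
  cfg <- smallNoiselessConfig()
  conc <- c(glucose = 400, lactate = 45)
  a1 <- absorbanceFromPair(simulateSamplePair(conc, cfg, nScans = 2,
                                              seed = 1), binSize = 5L)
  wn <- wavenumbers(a1)
  injected <- -log10(sampleTransmittance(conc, wn, cfg) /
                     sampleTransmittance(numeric(0), wn, cfg))
  # binning smooths over 5 pulses; agreement is to well below the noise floor
  expect_lt(max(abs(spectrumValues(a1) - injected)), 1e-4)
  # two-fold linearity of the full chain; the only departure is the
  # within-bin quadrature of the Beer-Lambert exponential (~1e-6 AU)
  a2 <- absorbanceFromPair(simulateSamplePair(conc * 2, cfg, nScans = 2,
                                              seed = 1), binSize = 5L)
  expect_lt(max(abs(spectrumValues(a2) - 2 * spectrumValues(a1))), 1e-5)
})

test_that("processing a shifted-scan measurement realigns it onto the background grid", {
  cfg <- smallConfig(perPulseRsd = 0, scanOffsetSd = 0, detectorNoiseSd = 0,
                     seriesDriftSd = 0, scanShiftSd = 1.2)
  conc <- c(glucose = 600)
  set.seed(23)
  ab <- absorbanceFromPair(simulateSamplePair(conc, cfg, nScans = 5),
                           binSize = 5L)
  wn <- wavenumbers(ab)
  injected <- -log10(sampleTransmittance(conc, wn, cfg) /
                     sampleTransmittance(numeric(0), wn, cfg))
  # away from the padded edges the aligned chain matches the injected bands
  mid <- wn > 975 & wn < 1190
  expect_lt(max(abs(spectrumValues(ab)[mid] - injected[mid])), 5e-3)
})
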