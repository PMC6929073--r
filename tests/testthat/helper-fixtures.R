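# Shared fixtures: a reduced-scale instrument (2000 pulses per scan, 5-pulse
# bins) keeps the unit tests fast while preserving the full processing chain;
# the full 100,000-pulse instrument is exercised in the acceptance suite.

paperPrism <- function(nSample = 1.33) {
  PrismGeometry(topFacetLength = 24, topFacetWidth = 6, height = 2.4,
                facetAngle = 45, nPrism = 2.2, nSample = nSample)
}

noNoise <- list(perPulseRsd = 0, scanOffsetSd = 0, scanShiftSd = 0,
                detectorNoiseSd = 0, seriesDriftSd = 0)

# 2 kHz repetition -> 2000 pulses/scan; 5-pulse bins -> 400 bins, 390 kept
smallConfig <- function(setupType = "transmission", ...) {
  args <- list(setupType = setupType, repetitionRateKHz = 2, binSize = 5L,
               ...)
  do.call(instrumentConfig, args)
}

smallNoiselessConfig <- function(setupType = "transmission", ...) {
  do.call(smallConfig, c(list(setupType = setupType), noNoise, list(...)))
}

# a smooth structured spectrum used by the alignment tests
bumpySpectrum <- function(n = 390) {
  wn <- seq(925, 1200, length.out = n)
  v <- 1 + 0.5 * exp(-(wn - 1050)^2 / 500) - 0.3 * exp(-(wn - 1150)^2 / 200)
  Spectrum(wn, v, kind = "intensity")
}

# displace a spectrum's values by k bins toward higher indices (edge-padded)
displaceValues <- function(spec, k) {
  v <- spectrumValues(spec)
  n <- length(v)
  idx <- pmin(pmax(seq_len(n) - k, 1L), n)
  Spectrum(wavenumbers(spec), v[idx], kind = spec@kind)
}

# noiseless Beer-Lambert feature matrix for nSamples random mixtures:
# rows = samples, columns = wavenumber points; returns X, Y and the grid
linearMixtures <- function(nSamples, seed = 1, pathUm = 165,
                           wn = seq(925, 1200, length.out = 120)) {
  set.seed(seed)
  rg <- concentrationRanges()
  Y <- sapply(seq_len(nrow(rg)), function(i) runif(nSamples, 0, rg$max[i]))
  colnames(Y) <- rg$analyte
  cfg <- instrumentConfig("transmission")
  M <- sapply(rg$analyte, function(a) {
    -log10(sampleTransmittance(setNames(1, a), wn, cfg)) +
      log10(sampleTransmittance(setNames(0, a), wn, cfg))
  })
  list(X = Y %*% t(M), Y = Y, wn = wn)
}
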