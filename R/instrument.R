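# Pulse-resolved simulation of the tuneable pulsed-QCL spectrometer in the
# ATR and transmission configurations.  One intensity value is stored per
# laser pulse (no intra-pulse waveform).

#' Mid-infrared band library of the four analytes
#'
#' Gaussian absorption-band parameters used by the simulator, one table per
#' analyte with columns `center` (cm-1), `fwhm` (cm-1) and `peak`
#' (AU dL / (mg um) - absorbance per unit concentration and unit path
#' length, base-10).  Lactate carries its two bands at 1040 and 1124 cm-1
#' and urea its small band near 1160 cm-1; glucose is modelled with four
#' bands at 1036/1080/1110/1152 cm-1 and albumin as two broad weak bands
#' across 1050-1170 cm-1, positions from standard mid-infrared solution
#' spectra.  Amplitudes are synthetic, calibrated so that 800 mg/dL glucose
#' over a 165 um path gives a peak absorbance near 0.1 AU; they are not fits
#' to any measured spectrum.
#'
#' @return named list of data.frames (glucose, albumin, urea, lactate).
#' @export
analyteBands <- function() {
  list(
    glucose = data.frame(
      center = c(1036, 1080, 1110, 1152),
      fwhm   = c(30, 28, 30, 26),
      peak   = 7.6e-7 * c(1.00, 0.90, 0.65, 0.35)),
    albumin = data.frame(
      center = c(1075, 1160),
      fwhm   = c(90, 70),
      peak   = 2.6e-7 * c(1.00, 0.70)),
    urea = data.frame(
      center = 1160,
      fwhm   = 24,
      peak   = 8.0e-7),
    lactate = data.frame(
      center = c(1040, 1124),
      fwhm   = c(26, 28),
      peak   = 1.2e-6 * c(1.00, 0.85))
  )
}

#' Construct an InstrumentConfig
#'
#' Defaults describe the simulated study instrument: 500 ns pulses at
#' 100 kHz (5% duty cycle), a 1200 to 925 cm-1 scan at 275 cm-1/s (1 s and
#' 100,000 pulses per scan), a 165 um transmission gap or the standard ZnS
#' ATR prism, 3.54% pulse-to-pulse intensity noise, 0.1% per-scan offsets,
#' 1-bin wavenumber jitter, and a weak additive detector noise floor.
#'
#' @param setupType `"transmission"` or `"ATR"`.
#' @param pulseWidthNs,repetitionRateKHz,scanRange,tuningSpeed timing
#'   parameters, see [InstrumentConfig-class].
#' @param perPulseRsd,scanOffsetSd,scanShiftSd,detectorNoiseSd,seriesDriftSd
#'   noise parameters, see [InstrumentConfig-class].
#' @param transmissionPath transmission gap, um.
#' @param prism [PrismGeometry-class] for the ATR configuration.
#' @param effectiveDepthFactor sampling-depth multiplier, see
#'   [penetrationDepth()].
#' @param binSize pulses per spectral bin (acquisition convention).
#' @param bands analyte band library, see [analyteBands()].
#' @param water water-background model: baseline absorptivity (AU/um), added
#'   absorptivity below the edge, edge position (cm-1), edge width (cm-1).
#' @param envelope emission envelope centre and Gaussian width, cm-1.
#' @return an [InstrumentConfig-class].
#' @examples
#' cfg <- instrumentConfig("transmission")
#' dutyCycle(cfg)      # 0.05
#' pulsesPerScan(cfg)  # 100000
#' @export
instrumentConfig <- function(setupType = c("transmission", "ATR"),
                             pulseWidthNs = 500,
                             repetitionRateKHz = 100,
                             scanRange = c(1200, 925),
                             tuningSpeed = 275,
                             perPulseRsd = 0.0354,
                             scanOffsetSd = 0.001,
                             scanShiftSd = 1,
                             detectorNoiseSd = 2e-4,
                             seriesDriftSd = 5e-4,
                             transmissionPath = 165,
                             prism = PrismGeometry(),
                             effectiveDepthFactor = 2.62,
                             binSize = 255L,
                             bands = analyteBands(),
                             water = c(base = 0.004, step = 0.010,
                                       edge = 960, width = 10),
                             envelope = c(center = 1060, width = 120)) {
  setupType <- match.arg(setupType)
  new("InstrumentConfig",
      pulseWidthNs = pulseWidthNs, repetitionRateKHz = repetitionRateKHz,
      scanRange = as.numeric(scanRange), tuningSpeed = tuningSpeed,
      perPulseRsd = perPulseRsd, scanOffsetSd = scanOffsetSd,
      scanShiftSd = scanShiftSd, detectorNoiseSd = detectorNoiseSd,
      seriesDriftSd = seriesDriftSd, setupType = setupType,
      transmissionPath = transmissionPath, prism = prism,
      effectiveDepthFactor = effectiveDepthFactor,
      binSize = as.integer(binSize), bands = bands,
      water = as.numeric(water), envelope = as.numeric(envelope))
}

#' Nominal per-pulse wavenumber axis of one scan
#'
#' Wavenumbers descend from `scanRange[1]` to `scanRange[2]` as the laser
#' tunes; pulse i sits at the centre of its tuning interval.
#'
#' @param config an [InstrumentConfig-class].
#' @return numeric vector, one wavenumber (cm-1) per pulse, descending.
#' @export
scanWavenumbers <- function(config) {
  P <- pulsesPerScan(config)
  step <- (config@scanRange[1] - config@scanRange[2]) / P
  config@scanRange[1] - (seq_len(P) - 0.5) * step
}

#' Laser emission envelope
#'
#' Smooth positive gain profile of the laser over the scan range, a Gaussian
#' in wavenumber normalised to 1 at its maximum within the range.
#'
#' @param wavenumber wavenumber(s), cm-1; must lie within the scan range.
#' @param config an [InstrumentConfig-class].
#' @return relative intensity in (0, 1].
#' @export
emissionEnvelope <- function(wavenumber, config) {
  lo <- config@scanRange[2]; hi <- config@scanRange[1]
  if (any(wavenumber < lo - 1e-9) || any(wavenumber > hi + 1e-9))
    stop("wavenumber outside the scan range [", lo, ", ", hi, "] cm-1")
  ctr <- config@envelope[1]; w <- config@envelope[2]
  g <- function(v) exp(-(v - ctr)^2 / (2 * w^2))
  g(wavenumber) / g(min(max(ctr, lo), hi))
}

#' Water background absorptivity
#'
#' Base-10 absorbance of the aqueous matrix per um of path length,
#' modelled as a flat baseline plus a logistic rise below the water
#' absorption edge (strong libration/bending-wing absorption at low
#' wavenumbers), which amplifies relative noise below ~970 cm-1 at long
#' path lengths.
#'
#' @inheritParams emissionEnvelope
#' @return absorptivity, AU/um.
#' @export
waterAbsorptivity <- function(wavenumber, config) {
  w <- config@water
  w[1] + w[2] / (1 + exp((wavenumber - w[3]) / w[4]))
}

# summed analyte absorptivity eps(v) * c for a named concentration vector,
# AU per um of path length
.analyteAbsorptivity <- function(concentrations, wavenumber, config) {
  eps <- numeric(length(wavenumber))
  for (a in names(concentrations)) {
    c_a <- concentrations[[a]]
    if (c_a == 0) next
    bands <- config@bands[[a]]
    if (is.null(bands))
      stop("no band definition for analyte '", a, "'")
    for (b in seq_len(nrow(bands))) {
      sig2 <- bands$fwhm[b]^2 / (8 * log(2))
      eps <- eps + c_a * bands$peak[b] *
        exp(-(wavenumber - bands$center[b])^2 / (2 * sig2))
    }
  }
  eps
}

#' Per-wavenumber sample path length
#'
#' The effective absorption path length of the configuration: the fixed
#' fiber-gap for transmission, or the wavelength-dependent evanescent
#' interaction length (sampling-facet reflections times effective sampling
#' depth) for ATR.
#'
#' @inheritParams emissionEnvelope
#' @return path length(s), um.
#' @export
samplePathLength <- function(wavenumber, config) {
  if (config@setupType == "transmission")
    rep(config@transmissionPath, length(wavenumber))
  else
    interactionLength(config@prism, wavenumber,
                      config@effectiveDepthFactor)
}

#' Sample transmittance under the Beer-Lambert model
#'
#' `T = 10^-( (sum_a eps_a(v) c_a + a_water(v)) * L(v) )` with `L` the
#' configuration path length ([samplePathLength()]).  The water term is
#' shared by sample and background measurements and cancels in the ratioed
#' absorbance; the analyte term is linear in every concentration.
#'
#' @param concentrations named numeric vector of analyte concentrations,
#'   mg/dL (names must match the band library); missing analytes count as 0.
#' @inheritParams emissionEnvelope
#' @return transmittance fraction(s) in (0, 1].
#' @export
sampleTransmittance <- function(concentrations, wavenumber, config) {
  concentrations <- concentrations[!is.na(concentrations)]
  if (any(concentrations < 0)) stop("concentrations must be non-negative")
  A <- (.analyteAbsorptivity(as.list(concentrations), wavenumber, config) +
        waterAbsorptivity(wavenumber, config)) *
       samplePathLength(wavenumber, config)
  10^(-A)
}

#' Simulate one pulse-resolved measurement
#'
#' Generates `nScans` raw scans of one sample: per pulse,
#' `I = envelope x transmittance x (1 + pulse noise) x (1 + scan offset)
#' + detector noise`, where the pulse noise is i.i.d. with sd `perPulseRsd`,
#' the multiplicative offset is drawn once per scan with sd `scanOffsetSd`,
#' and each scan's wavenumber registration is jittered by an integer number
#' of spectral bins (`binSize` pulses) drawn from `round(N(0, scanShiftSd))`
#' - the imperfection the chi-squared alignment corrects.  `seriesDrift`
#' applies a fixed multiplicative factor `(1 + drift)` to the whole
#' measurement, modelling slow source drift between a sample measurement
#' and its background within one series.
#'
#' @param concentrations named concentration vector, mg/dL; use zeros (or
#'   an empty vector) with `isBackground = TRUE` for a blank water
#'   background.
#' @param config an [InstrumentConfig-class].
#' @param nScans number of scans in the measurement.
#' @param sampleId,seriesId,dayId metadata labels.
#' @param isBackground background flag stored in the records.
#' @param seriesDrift multiplicative drift applied to this measurement.
#' @param seed optional integer seed (local to this call); when `NULL` the
#'   current RNG stream is used, which is how the study pipeline chains all
#'   stochastic stages off a single master seed.
#' @return list of [ScanRecord-class] objects, one per scan.
#' @export
simulateMeasurement <- function(concentrations, config, nScans = 10,
                                sampleId = "S1", seriesId = 1L, dayId = 1L,
                                isBackground = FALSE, seriesDrift = 0,
                                seed = NULL) {
  if (nScans < 1) stop("nScans must be >= 1")
  .withSeed(seed, {
    axis <- scanWavenumbers(config)
    P <- length(axis)
    base <- emissionEnvelope(axis, config) *
      sampleTransmittance(concentrations, axis, config) * (1 + seriesDrift)
    shiftQ <- config@binSize
    scans <- vector("list", nScans)
    for (s in seq_len(nScans)) {
      k <- as.integer(round(rnorm(1, 0, config@scanShiftSd))) * shiftQ
      if (k == 0L) sig <- base
      else {
        idx <- pmin(pmax(seq_len(P) - k, 1L), P)  # edge padding
        sig <- base[idx]
      }
      inten <- sig * (1 + rnorm(P, 0, config@perPulseRsd)) *
        (1 + rnorm(1, 0, config@scanOffsetSd)) +
        rnorm(P, 0, config@detectorNoiseSd)
      scans[[s]] <- new("ScanRecord",
                        intensities = inten, wavenumbers = axis,
                        sampleId = as.character(sampleId),
                        seriesId = as.integer(seriesId),
                        dayId = as.integer(dayId),
                        isBackground = isBackground)
    }
    scans
  })
}

#' Simulate a background/sample measurement pair
#'
#' A background (blank water) measurement followed by the sample
#' measurement, as acquired for each designed sample; the series drift
#' applies to the sample measurement only (it models the source drifting
#' between the two acquisitions).
#'
#' @inheritParams simulateMeasurement
#' @return list with elements `background` and `sample`, each a list of
#'   [ScanRecord-class] objects.
#' @export
simulateSamplePair <- function(concentrations, config, nScans = 10,
                               sampleId = "S1", seriesId = 1L, dayId = 1L,
                               seriesDrift = 0, seed = NULL) {
  .withSeed(seed, {
    bg <- simulateMeasurement(numeric(0), config, nScans,
                              sampleId = sampleId, seriesId = seriesId,
                              dayId = dayId, isBackground = TRUE)
    sm <- simulateMeasurement(concentrations, config, nScans,
                              sampleId = sampleId, seriesId = seriesId,
                              dayId = dayId, isBackground = FALSE,
                              seriesDrift = seriesDrift)
    list(background = bg, sample = sm)
  })
}
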