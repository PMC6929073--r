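#' @import methods
#' @importFrom stats rnorm sd predict coef lm setNames
#' @importFrom utils head
NULL

# ---------------------------------------------------------------------------
# PrismGeometry
# ---------------------------------------------------------------------------

#' Trapezoidal ATR prism geometry
#'
#' Describes a trapezoidal attenuated-total-reflection (ATR) prism in the
#' vertical cross-section used for 2-D ray tracing: a long top (sampling)
#' facet, a parallel shorter bottom facet, and two slanted coupling facets at
#' `facetAngle` degrees from the horizontal.  Refractive indices are treated
#' as dispersionless scalars (prism material and sample medium).
#'
#' @slot topFacetLength length of the top (sampling) facet, mm.
#' @slot topFacetWidth width of the top facet, mm (not used by the 2-D trace,
#'   kept for completeness).
#' @slot height prism height, mm; the top and bottom facets are this far
#'   apart.
#' @slot facetAngle angle of the slanted coupling facets from the horizontal,
#'   degrees; 45 for the standard parallelogram-style coupling.
#' @slot nPrism refractive index of the prism material (e.g. 2.2 for ZnS
#'   around 10 um).
#' @slot nSample refractive index of the sample medium on the top facet
#'   (e.g. 1.3 for water in the mid-infrared).
#'
#' @seealso [PrismGeometry()], [tracePrism()], [penetrationDepth()]
#' @exportClass PrismGeometry
setClass("PrismGeometry",
  slots = c(
    topFacetLength = "numeric",
    topFacetWidth  = "numeric",
    height         = "numeric",
    facetAngle     = "numeric",
    nPrism         = "numeric",
    nSample        = "numeric"
  )
)

setValidity("PrismGeometry", function(object) {
  msg <- character()
  if (length(object@height) != 1L || !is.finite(object@height) ||
      object@height <= 0)
    msg <- c(msg, "height must be a single positive number")
  if (length(object@facetAngle) != 1L || !is.finite(object@facetAngle) ||
      object@facetAngle <= 0 || object@facetAngle >= 90)
    msg <- c(msg, "facetAngle must lie strictly between 0 and 90 degrees")
  if (!(object@nPrism > object@nSample && object@nSample > 0))
    msg <- c(msg, "refractive indices must satisfy nPrism > nSample > 0")
  if (length(msg) == 0L) {
    bottom <- object@topFacetLength -
      2 * object@height / tan(object@facetAngle * pi / 180)
    # a degenerate triangle (bottom == 0) is allowed; a crossed shape is not
    if (bottom < -1e-9)
      msg <- c(msg, "bottom facet length (topFacetLength - 2*height/tan(facetAngle)) must be >= 0")
  }
  if (length(msg)) msg else TRUE
})

#' Construct a PrismGeometry
#'
#' Defaults describe a 24 x 6 mm ZnS trapezoid of height 2.4 mm with
#' 45-degree coupling facets, immersed in water on the sampling side.
#'
#' @param topFacetLength top (sampling) facet length, mm.
#' @param topFacetWidth top facet width, mm.
#' @param height prism height, mm.
#' @param facetAngle coupling-facet angle from horizontal, degrees.
#' @param nPrism refractive index of the prism.
#' @param nSample refractive index of the sample medium.
#' @return a [PrismGeometry-class] object.
#' @examples
#' pg <- PrismGeometry()
#' bottomFacetLength(pg)
#' @export
PrismGeometry <- function(topFacetLength = 24, topFacetWidth = 6,
                          height = 2.4, facetAngle = 45,
                          nPrism = 2.2, nSample = 1.3) {
  new("PrismGeometry",
      topFacetLength = as.numeric(topFacetLength),
      topFacetWidth  = as.numeric(topFacetWidth),
      height         = as.numeric(height),
      facetAngle     = as.numeric(facetAngle),
      nPrism         = as.numeric(nPrism),
      nSample        = as.numeric(nSample))
}

#' @describeIn PrismGeometry length of the bottom facet, mm.
#' @param object,x a `PrismGeometry`.
#' @export
bottomFacetLength <- function(x) {
  stopifnot(is(x, "PrismGeometry"))
  max(0, x@topFacetLength - 2 * x@height / tan(x@facetAngle * pi / 180))
}

#' @describeIn PrismGeometry critical angle for total internal reflection at
#'   the sampling facet, degrees.
#' @export
criticalAngle <- function(x) {
  stopifnot(is(x, "PrismGeometry"))
  asin(x@nSample / x@nPrism) * 180 / pi
}

setMethod("show", "PrismGeometry", function(object) {
  cat("PrismGeometry: ",
      object@topFacetLength, " x ", object@topFacetWidth,
      " mm top facet, height ", object@height, " mm, ",
      object@facetAngle, " deg facets\n", sep = "")
  cat("  n(prism) = ", object@nPrism, ", n(sample) = ", object@nSample,
      ", critical angle = ", format(criticalAngle(object), digits = 4),
      " deg\n", sep = "")
})

# ---------------------------------------------------------------------------
# RayTraceResult
# ---------------------------------------------------------------------------

#' Result of a 2-D prism ray trace
#'
#' @slot totalReflections total number of internal reflections of the central
#'   ray between the top and bottom facets.
#' @slot topFacetReflections reflections on the top (sampling) facet.
#' @slot bottomFacetReflections reflections on the bottom facet.
#' @slot propagationLength summed in-prism segment length of the central ray,
#'   mm.
#' @slot maxRadialPathDifference largest absolute path-length difference of
#'   the traced marginal rays versus the central ray, mm (0 when the beam is
#'   collimated and has zero width).
#' @slot path matrix of the central-ray vertex coordinates (x, y in mm), one
#'   row per vertex from entry to exit point.
#' @seealso [tracePrism()]
#' @exportClass RayTraceResult
setClass("RayTraceResult",
  slots = c(
    totalReflections        = "integer",
    topFacetReflections     = "integer",
    bottomFacetReflections  = "integer",
    propagationLength       = "numeric",
    maxRadialPathDifference = "numeric",
    path                    = "matrix"
  )
)

setValidity("RayTraceResult", function(object) {
  msg <- character()
  if (object@totalReflections !=
      object@topFacetReflections + object@bottomFacetReflections)
    msg <- c(msg, "totalReflections must equal top + bottom reflections")
  if (any(c(object@totalReflections, object@topFacetReflections,
            object@bottomFacetReflections) < 0L))
    msg <- c(msg, "reflection counts must be non-negative")
  if (object@propagationLength < 0)
    msg <- c(msg, "propagationLength must be non-negative")
  if (length(msg)) msg else TRUE
})

#' @describeIn RayTraceResult total internal reflection count.
#' @param object,x a `RayTraceResult`.
#' @export
totalReflections <- function(x) x@totalReflections

#' @describeIn RayTraceResult sampling-facet reflection count.
#' @export
topFacetReflections <- function(x) x@topFacetReflections

#' @describeIn RayTraceResult in-prism propagation length, mm.
#' @export
propagationLength <- function(x) x@propagationLength

setMethod("show", "RayTraceResult", function(object) {
  cat("RayTraceResult: ", object@totalReflections, " reflections (",
      object@topFacetReflections, " top / ",
      object@bottomFacetReflections, " bottom)\n", sep = "")
  cat("  propagation length ", format(object@propagationLength, digits = 5),
      " mm; max marginal-ray path difference ",
      format(object@maxRadialPathDifference, digits = 4), " mm\n", sep = "")
})

# ---------------------------------------------------------------------------
# InstrumentConfig
# ---------------------------------------------------------------------------

#' Pulsed-QCL spectrometer configuration
#'
#' All timing, noise, optics, and band-library parameters of the simulated
#' instrument.  The laser scans from `scanRange[1]` down to `scanRange[2]`
#' (descending wavenumber) at `tuningSpeed`; the pulse train is emitted at
#' `repetitionRateKHz` so that pulses-per-scan = repetition rate x scan
#' duration.
#'
#' @slot pulseWidthNs laser pulse width, ns.
#' @slot repetitionRateKHz pulse repetition rate, kHz.
#' @slot scanRange numeric length-2, scan limits in cm-1 (high, low).
#' @slot tuningSpeed scan tuning speed, cm-1/s.
#' @slot perPulseRsd relative standard deviation of the multiplicative
#'   pulse-to-pulse intensity noise (fraction).
#' @slot scanOffsetSd sd of the multiplicative per-scan intensity offset
#'   (fraction), drawn once per scan.
#' @slot scanShiftSd sd of the integer spectral-bin jitter of the wavenumber
#'   registration, in spectral bins of `binSize` pulses.
#' @slot detectorNoiseSd sd of the additive detector noise, in units of the
#'   (unit-normalised) emission envelope.
#' @slot seriesDriftSd sd of the slow multiplicative drift between a sample
#'   measurement and its background within one measurement series (fraction);
#'   drawn once per series by the study pipeline.
#' @slot setupType `"transmission"` or `"ATR"`.
#' @slot transmissionPath sample path length of the transmission gap, um.
#' @slot prism the [PrismGeometry-class] used when `setupType == "ATR"`.
#' @slot effectiveDepthFactor multiplier converting the Harrick penetration
#'   depth into an effective sampling depth (see [penetrationDepth()]).
#' @slot binSize pulses per spectral bin; the acquisition convention used
#'   both for the wavenumber-jitter quantum and for downstream binning.
#' @slot bands named list of per-analyte band tables (see [analyteBands()]).
#' @slot water numeric length-4: baseline absorptivity (AU/um), added
#'   absorptivity below the water edge (AU/um), edge position (cm-1), and
#'   edge width (cm-1) of the water background model.
#' @slot envelope numeric length-2: centre (cm-1) and Gaussian width (cm-1)
#'   of the laser emission envelope.
#' @seealso [instrumentConfig()]
#' @exportClass InstrumentConfig
setClass("InstrumentConfig",
  slots = c(
    pulseWidthNs        = "numeric",
    repetitionRateKHz   = "numeric",
    scanRange           = "numeric",
    tuningSpeed         = "numeric",
    perPulseRsd         = "numeric",
    scanOffsetSd        = "numeric",
    scanShiftSd         = "numeric",
    detectorNoiseSd     = "numeric",
    seriesDriftSd       = "numeric",
    setupType           = "character",
    transmissionPath    = "numeric",
    prism               = "PrismGeometry",
    effectiveDepthFactor = "numeric",
    binSize             = "integer",
    bands               = "list",
    water               = "numeric",
    envelope            = "numeric"
  )
)

setValidity("InstrumentConfig", function(object) {
  msg <- character()
  dc <- object@pulseWidthNs * 1e-9 * object@repetitionRateKHz * 1e3
  if (!is.finite(dc) || dc <= 0 || dc > 1)
    msg <- c(msg, "duty cycle (pulseWidthNs * repetitionRateKHz) must lie in (0, 1]")
  if (length(object@scanRange) != 2L || diff(object@scanRange) >= 0)
    msg <- c(msg, "scanRange must be c(high, low) with high > low (cm-1)")
  if (object@tuningSpeed <= 0)
    msg <- c(msg, "tuningSpeed must be positive")
  if (!object@setupType %in% c("transmission", "ATR"))
    msg <- c(msg, "setupType must be 'transmission' or 'ATR'")
  if (object@transmissionPath <= 0)
    msg <- c(msg, "transmissionPath must be positive (um)")
  if (any(c(object@perPulseRsd, object@scanOffsetSd, object@scanShiftSd,
            object@detectorNoiseSd, object@seriesDriftSd) < 0))
    msg <- c(msg, "noise standard deviations must be non-negative")
  if (object@binSize < 1L)
    msg <- c(msg, "binSize must be >= 1")
  if (length(msg)) msg else TRUE
})

#' @describeIn instrumentConfig laser duty cycle (fraction of time on).
#' @export
dutyCycle <- function(config) {
  config@pulseWidthNs * 1e-9 * config@repetitionRateKHz * 1e3
}

#' @describeIn instrumentConfig duration of one scan, s.
#' @export
scanDuration <- function(config) {
  (config@scanRange[1] - config@scanRange[2]) / config@tuningSpeed
}

#' @describeIn instrumentConfig number of laser pulses per scan.
#' @export
pulsesPerScan <- function(config) {
  as.integer(round(config@repetitionRateKHz * 1e3 * scanDuration(config)))
}

#' @describeIn instrumentConfig nominal wavenumber spacing of an
#'   `nPoints`-point spectrum over the scan range, cm-1.
#' @param nPoints number of spectral points.
#' @export
nominalSpacing <- function(config, nPoints = 390L) {
  (config@scanRange[1] - config@scanRange[2]) / nPoints
}

setMethod("show", "InstrumentConfig", function(object) {
  cat("InstrumentConfig [", object@setupType, "]\n", sep = "")
  cat("  scan ", object@scanRange[1], " -> ", object@scanRange[2],
      " cm-1 at ", object@tuningSpeed, " cm-1/s (",
      format(scanDuration(object), digits = 3), " s, ",
      pulsesPerScan(object), " pulses)\n", sep = "")
  cat("  pulse ", object@pulseWidthNs, " ns @ ", object@repetitionRateKHz,
      " kHz (duty cycle ", format(100 * dutyCycle(object), digits = 3),
      "%)\n", sep = "")
  cat("  noise: per-pulse RSD ", format(100 * object@perPulseRsd, digits = 3),
      "%, scan offset ", format(100 * object@scanOffsetSd, digits = 3),
      "%, shift sd ", object@scanShiftSd, " bins, detector ",
      object@detectorNoiseSd, "\n", sep = "")
  if (object@setupType == "transmission")
    cat("  path length ", object@transmissionPath, " um\n", sep = "")
  else
    cat("  ATR prism with effective depth factor ",
        object@effectiveDepthFactor, "\n", sep = "")
})

# ---------------------------------------------------------------------------
# ScanRecord
# ---------------------------------------------------------------------------

#' One raw pulse-resolved scan
#'
#' Detector intensity per laser pulse over one wavelength scan, together with
#' the nominal (unshifted) wavenumber of each pulse and the measurement
#' metadata.  Wavenumbers descend over the scan (the laser tunes from high to
#' low wavenumber).
#'
#' @slot intensities detector intensity per pulse (arbitrary detector units).
#' @slot wavenumbers nominal wavenumber per pulse, cm-1, strictly decreasing.
#' @slot sampleId,seriesId,dayId measurement identifiers.
#' @slot isBackground whether the scan belongs to a background (blank water)
#'   measurement.
#' @exportClass ScanRecord
setClass("ScanRecord",
  slots = c(
    intensities  = "numeric",
    wavenumbers  = "numeric",
    sampleId     = "character",
    seriesId     = "integer",
    dayId        = "integer",
    isBackground = "logical"
  )
)

setValidity("ScanRecord", function(object) {
  msg <- character()
  if (length(object@intensities) != length(object@wavenumbers))
    msg <- c(msg, "intensities and wavenumbers must have equal length")
  if (is.unsorted(-object@wavenumbers, strictly = TRUE))
    msg <- c(msg, "wavenumbers must be strictly decreasing over the scan")
  if (length(msg)) msg else TRUE
})

setMethod("show", "ScanRecord", function(object) {
  cat("ScanRecord: ", length(object@intensities), " pulses, ",
      format(object@wavenumbers[1], digits = 6), " -> ",
      format(object@wavenumbers[length(object@wavenumbers)], digits = 6),
      " cm-1\n", sep = "")
  cat("  sample ", object@sampleId, ", series ", object@seriesId,
      ", day ", object@dayId,
      if (object@isBackground) " (background)" else "", "\n", sep = "")
})

# ---------------------------------------------------------------------------
# Spectrum
# ---------------------------------------------------------------------------

#' A binned spectrum
#'
#' Wavenumber axis (stored ascending regardless of the descending scan
#' direction) plus intensity or absorbance values and free-form metadata.
#'
#' @slot wavenumbers strictly increasing wavenumber grid, cm-1.
#' @slot values intensity (detector units) or absorbance (AU) per point.
#' @slot kind `"intensity"` or `"absorbance"`.
#' @slot metadata named list (sample, series, day, setup, number of scans
#'   averaged, ...).
#' @exportClass Spectrum
setClass("Spectrum",
  slots = c(
    wavenumbers = "numeric",
    values      = "numeric",
    kind        = "character",
    metadata    = "list"
  )
)

setValidity("Spectrum", function(object) {
  msg <- character()
  if (length(object@wavenumbers) != length(object@values))
    msg <- c(msg, "wavenumbers and values must have equal length")
  if (is.unsorted(object@wavenumbers, strictly = TRUE))
    msg <- c(msg, "wavenumbers must be strictly increasing")
  if (any(!is.finite(object@values)))
    msg <- c(msg, "values must all be finite")
  if (!object@kind %in% c("intensity", "absorbance"))
    msg <- c(msg, "kind must be 'intensity' or 'absorbance'")
  if (length(msg)) msg else TRUE
})

#' Construct a Spectrum
#' @param wavenumbers ascending wavenumber grid, cm-1.
#' @param values intensity or absorbance values.
#' @param kind `"intensity"` or `"absorbance"`.
#' @param metadata named list of metadata.
#' @return a [Spectrum-class] object.
#' @export
Spectrum <- function(wavenumbers, values, kind = "intensity",
                     metadata = list()) {
  new("Spectrum", wavenumbers = as.numeric(wavenumbers),
      values = as.numeric(values), kind = kind, metadata = metadata)
}

#' @describeIn Spectrum the wavenumber axis, cm-1.
#' @param x a `Spectrum`.
#' @export
wavenumbers <- function(x) x@wavenumbers

#' @describeIn Spectrum the intensity/absorbance values.
#' @export
spectrumValues <- function(x) x@values

#' @describeIn Spectrum number of spectral points.
#' @export
nPoints <- function(x) length(x@values)

setMethod("show", "Spectrum", function(object) {
  cat("Spectrum (", object@kind, "): ", length(object@values), " points, ",
      format(min(object@wavenumbers), digits = 6), " - ",
      format(max(object@wavenumbers), digits = 6), " cm-1\n", sep = "")
  if (length(object@metadata))
    cat("  metadata: ", paste(names(object@metadata), collapse = ", "),
        "\n", sep = "")
})

# ---------------------------------------------------------------------------
# AlignmentSolution
# ---------------------------------------------------------------------------

#' Chi-squared alignment solution
#'
#' @slot binShift integer bin shift applied to the target spectrum.
#' @slot intensityOffset additive intensity offset (same units as the
#'   spectrum values).
#' @slot chiSquared residual sum of squares over the overlap at the optimum.
#' @seealso [alignScan()]
#' @exportClass AlignmentSolution
setClass("AlignmentSolution",
  slots = c(binShift = "integer", intensityOffset = "numeric",
            chiSquared = "numeric")
)

setValidity("AlignmentSolution", function(object) {
  if (object@chiSquared < 0) "chiSquared must be non-negative" else TRUE
})

setMethod("show", "AlignmentSolution", function(object) {
  cat("AlignmentSolution: shift ", object@binShift, " bins, offset ",
      format(object@intensityOffset, digits = 5), ", chi-squared ",
      format(object@chiSquared, digits = 5), "\n", sep = "")
})

# ---------------------------------------------------------------------------
# SampleDesign
# ---------------------------------------------------------------------------

#' Mixture-design sample set
#'
#' Concentration matrix (mg/dL) of the designed calibration samples plus the
#' Scheffe model terms and the achieved A-optimality criterion.
#'
#' @slot concentrations N x q matrix of analyte concentrations, mg/dL, with
#'   analyte column names.
#' @slot modelTerms character vector describing the Scheffe model terms used
#'   by the optimiser (pseudo-component space).
#' @slot aCriterion achieved A-criterion, trace((X'X)^-1), of the design
#'   model matrix.
#' @slot ranges data.frame with columns `analyte`, `min`, `max` (mg/dL).
#' @seealso [aOptimalDesign()]
#' @exportClass SampleDesign
setClass("SampleDesign",
  slots = c(
    concentrations = "matrix",
    modelTerms     = "character",
    aCriterion     = "numeric",
    ranges         = "data.frame"
  )
)

setValidity("SampleDesign", function(object) {
  msg <- character()
  cc <- object@concentrations
  rg <- object@ranges
  if (!all(colnames(cc) %in% rg$analyte))
    msg <- c(msg, "every concentration column needs a matching range row")
  else {
    for (a in colnames(cc)) {
      r <- rg[rg$analyte == a, ]
      if (any(cc[, a] < r$min - 1e-9) || any(cc[, a] > r$max + 1e-9))
        msg <- c(msg, paste0("concentrations of ", a, " outside its range"))
    }
  }
  if (anyDuplicated(as.data.frame(cc)))
    msg <- c(msg, "design rows must be unique")
  if (!is.finite(object@aCriterion) || object@aCriterion <= 0)
    msg <- c(msg, "aCriterion must be positive and finite")
  if (length(msg)) msg else TRUE
})

#' @describeIn aOptimalDesign concentration matrix (mg/dL) of a design.
#' @param design a [SampleDesign-class].
#' @export
designConcentrations <- function(design) design@concentrations

#' @describeIn aOptimalDesign achieved A-criterion of a design.
#' @export
aCriterion <- function(design) design@aCriterion

setMethod("show", "SampleDesign", function(object) {
  cat("SampleDesign: ", nrow(object@concentrations), " samples x ",
      ncol(object@concentrations), " analytes (",
      paste(colnames(object@concentrations), collapse = ", "), ")\n",
      sep = "")
  cat("  ", length(object@modelTerms),
      " Scheffe model terms, A-criterion ",
      format(object@aCriterion, digits = 5), "\n", sep = "")
})

# ---------------------------------------------------------------------------
# PLSModel
# ---------------------------------------------------------------------------

#' Fitted NIPALS partial least-squares model
#'
#' @slot weights X-weight matrix W (p x k).
#' @slot loadings X-loading matrix P (p x k).
#' @slot yLoadings Y-loading matrix Q (m x k).
#' @slot scores training score matrix T (n x k).
#' @slot xMeans,yMeans training column means of X and Y.
#' @slot nLV number of latent variables requested.
#' @slot achievedLV number of latent variables actually extracted (may be
#'   lower than `nLV` when X becomes rank-deficient).
#' @seealso [plsFit()]
#' @exportClass PLSModel
setClass("PLSModel",
  slots = c(
    weights   = "matrix",
    loadings  = "matrix",
    yLoadings = "matrix",
    scores    = "matrix",
    xMeans    = "numeric",
    yMeans    = "numeric",
    nLV       = "integer",
    achievedLV = "integer"
  )
)

setMethod("show", "PLSModel", function(object) {
  cat("PLSModel: ", object@achievedLV, " latent variable(s) over ",
      length(object@xMeans), " features, ",
      ncol(object@yLoadings), " response(s)\n", sep = "")
})

# ---------------------------------------------------------------------------
# CVResult
# ---------------------------------------------------------------------------

#' Cross-validation result
#'
#' Per-analyte RMSECV and R-squared for each candidate number of latent
#' variables under one cross-validation scheme, with the fold assignment and
#' the pooled held-out predictions at the RMSECV-minimising latent-variable
#' count.
#'
#' @slot scheme `"LOOCV"`, `"L5OCV"` or `"LDOCV"`.
#' @slot perLV data.frame with columns `analyte`, `nLV`, `rmsecv`, `r2`.
#' @slot best data.frame with one row per analyte: the RMSECV-minimising
#'   latent-variable count and its RMSECV / R-squared.
#' @slot folds integer fold id per measurement.
#' @slot predictions matrix (measurements x analytes) of pooled held-out
#'   predictions at the per-analyte best latent-variable count, mg/dL.
#' @slot reference matrix of reference concentrations, mg/dL.
#' @seealso [crossValidate()]
#' @exportClass CVResult
setClass("CVResult",
  slots = c(
    scheme      = "character",
    perLV       = "data.frame",
    best        = "data.frame",
    folds       = "integer",
    predictions = "matrix",
    reference   = "matrix"
  )
)

setValidity("CVResult", function(object) {
  msg <- character()
  if (nrow(object@perLV) && any(object@perLV$rmsecv < 0))
    msg <- c(msg, "rmsecv must be non-negative")
  if (nrow(object@perLV) && any(object@perLV$r2 > 1 + 1e-12))
    msg <- c(msg, "r2 cannot exceed 1")
  if (length(msg)) msg else TRUE
})

#' @describeIn crossValidate per-latent-variable RMSECV/R2 table.
#' @param result a [CVResult-class].
#' @export
cvTable <- function(result) result@perLV

#' @describeIn crossValidate best (RMSECV-minimising) row per analyte.
#' @export
cvBest <- function(result) result@best

#' @describeIn crossValidate pooled held-out predictions at the best
#'   latent-variable count.
#' @export
cvPredictions <- function(result) result@predictions

setMethod("show", "CVResult", function(object) {
  cat("CVResult [", object@scheme, "]: ",
      length(unique(object@folds)), " folds, ",
      length(object@folds), " measurements\n", sep = "")
  print(object@best, row.names = FALSE, digits = 4)
})
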