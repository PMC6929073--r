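# Raw scans -> aligned absorbance spectra: pulse binning, chi-squared
# alignment, scan averaging, absorbance ratioing and noise characterisation.

#' Bin laser pulses into a spectrum
#'
#' Averages consecutive non-overlapping blocks of `binSize` pulses; the
#' wavenumber of each point is the mean wavenumber of its block.  The
#' output is truncated to the first `nPoints` complete bins of the scan
#' (the defaults reduce a 100,000-pulse scan to 390 points; the final edge
#' bins are dropped).  The axis is stored ascending; the descending scan
#' direction is recorded in the metadata.
#'
#' @param scan a [ScanRecord-class].
#' @param binSize pulses per bin.
#' @param nPoints number of spectral points kept; defaults to
#'   `floor(pulses / binSize)` capped at 390.
#' @return a [Spectrum-class] of kind `"intensity"`.
#' @export
binPulses <- function(scan, binSize = 255L, nPoints = NULL) {
  stopifnot(is(scan, "ScanRecord"))
  P <- length(scan@intensities)
  if (P < binSize) stop("scan has fewer pulses (", P, ") than binSize")
  nBins <- P %/% binSize
  if (is.null(nPoints)) nPoints <- min(nBins, 390L)
  if (nPoints > nBins)
    stop("nPoints (", nPoints, ") exceeds the ", nBins, " complete bins")
  # block means over the first nPoints complete bins (column-major view)
  vals <- .colMeans(scan@intensities, binSize, nPoints)
  wns  <- .colMeans(scan@wavenumbers, binSize, nPoints)
  Spectrum(rev(wns), rev(vals), kind = "intensity",
           metadata = list(sampleId = scan@sampleId,
                           seriesId = scan@seriesId,
                           dayId = scan@dayId,
                           isBackground = scan@isBackground,
                           scanDirection = "descending",
                           binSize = as.integer(binSize)))
}

.sameGrid <- function(a, b, tol = 1e-8) {
  length(a@wavenumbers) == length(b@wavenumbers) &&
    max(abs(a@wavenumbers - b@wavenumbers)) < tol
}

#' Average spectra point-wise
#'
#' @param spectra list of [Spectrum-class] objects on identical grids.
#' @return a [Spectrum-class]; the metadata records `nAveraged`.
#' @export
averageScans <- function(spectra) {
  if (length(spectra) == 0L) stop("cannot average an empty set of spectra")
  ref <- spectra[[1]]
  for (s in spectra[-1])
    if (!.sameGrid(ref, s)) stop("spectra are not on identical grids")
  vals <- rowMeans(vapply(spectra, function(s) s@values,
                          numeric(length(ref@values))))
  md <- ref@metadata
  md$nAveraged <- length(spectra)
  Spectrum(ref@wavenumbers, vals, kind = ref@kind, metadata = md)
}

#' Align a spectrum to a reference by chi-squared minimisation
#'
#' Grid search over integer bin shifts in `[-maxShift, maxShift]`; for each
#' shift the optimal additive intensity offset has the closed form of the
#' mean residual over the overlap, and the (shift, offset) pair minimising
#' `sum((ref - shifted(target) - offset)^2)` is returned.  Ties are broken
#' toward the smaller absolute shift.  The aligned spectrum places
#' `target[i - shift]` at grid point `i` (edge gaps are filled with the
#' nearest target value); when `applyOffset = FALSE` the offset is still
#' estimated inside the fit but not applied - used when aligning a sample
#' measurement to its background, where an additive correction would
#' subtract genuine absorbance signal.
#'
#' @param reference,target [Spectrum-class] objects on grids with equal
#'   spacing.
#' @param maxShift search half-width, bins.
#' @param applyOffset whether the fitted offset is applied to the aligned
#'   values.
#' @param window optional length-2 wavenumber window (cm-1); when given,
#'   the chi-squared fit is restricted to reference grid points inside it
#'   (the aligned spectrum still covers the full grid).  Restricting the
#'   fit to a region where both spectra share their structure (e.g. a
#'   solvent feature) keeps the shift estimate unbiased when the spectra
#'   differ elsewhere.
#' @return list with elements `solution` (an [AlignmentSolution-class]) and
#'   `aligned` (a [Spectrum-class]).
#' @export
alignScan <- function(reference, target, maxShift = 5L,
                      applyOffset = TRUE, window = NULL) {
  stopifnot(is(reference, "Spectrum"), is(target, "Spectrum"))
  if (maxShift < 0) stop("maxShift must be >= 0")
  n <- length(reference@values)
  dr <- diff(reference@wavenumbers); dt <- diff(target@wavenumbers)
  if (length(dr) && (abs(mean(dr) - mean(dt)) > 1e-6 * mean(dr)))
    stop("reference and target must share the grid spacing")
  inWindow <- if (is.null(window)) rep(TRUE, n)
              else reference@wavenumbers >= min(window) &
                   reference@wavenumbers <= max(window)
  shifts <- seq.int(-maxShift, maxShift)
  shifts <- shifts[order(abs(shifts), shifts)]   # ties -> smaller |shift|
  best <- NULL
  for (b in shifts) {
    i <- seq.int(max(1L, 1L + b), min(n, n + b))   # ref indices
    i <- i[inWindow[i]]
    j <- i - b                                     # target indices
    if (length(i) < 10L) next
    resid <- reference@values[i] - target@values[j]
    off <- mean(resid)
    chi2 <- sum((resid - off)^2)
    if (is.null(best) || chi2 < best$chi2)
      best <- list(shift = b, offset = off, chi2 = chi2)
  }
  if (is.null(best))
    stop("alignment overlap shorter than 10 points; reduce maxShift")
  j <- pmin(pmax(seq_len(n) - best$shift, 1L), n)
  vals <- target@values[j] + if (applyOffset) best$offset else 0
  sol <- new("AlignmentSolution", binShift = as.integer(best$shift),
             intensityOffset = best$offset, chiSquared = best$chi2)
  list(solution = sol,
       aligned = Spectrum(reference@wavenumbers, vals, kind = target@kind,
                          metadata = target@metadata))
}

#' Absorbance from sample and background spectra
#'
#' `A = -log10(I / I0)` point-wise, on aligned identical grids.
#'
#' @param sample,background intensity [Spectrum-class] objects.
#' @return an absorbance [Spectrum-class] (AU).
#' @export
computeAbsorbance <- function(sample, background) {
  stopifnot(is(sample, "Spectrum"), is(background, "Spectrum"))
  if (!.sameGrid(sample, background))
    stop("sample and background must be on identical grids")
  bad <- which(sample@values <= 0 | background@values <= 0)
  if (length(bad))
    stop("non-positive intensity at ",
         format(sample@wavenumbers[bad[1]], digits = 6),
         " cm-1: cannot form absorbance")
  md <- sample@metadata
  md$ratioed <- TRUE
  Spectrum(sample@wavenumbers, -log10(sample@values / background@values),
           kind = "absorbance", metadata = md)
}

#' Relative standard deviation across replicate spectra
#'
#' Per-point sd/mean across replicates, averaged over a wavenumber window.
#'
#' @param spectra list of replicate [Spectrum-class] objects (or a numeric
#'   matrix, points x replicates, with a `wavenumbers` attribute supplied
#'   via `wn`).
#' @param window length-2 wavenumber window, cm-1.
#' @param wn wavenumber axis when `spectra` is a matrix.
#' @return mean RSD over the window (fraction).
#' @export
characteriseRsd <- function(spectra, window = c(1000, 1200), wn = NULL) {
  if (is.list(spectra)) {
    if (length(spectra) < 2L) stop("need at least 2 replicates")
    wn <- spectra[[1]]@wavenumbers
    m <- vapply(spectra, function(s) s@values, numeric(length(wn)))
  } else {
    m <- as.matrix(spectra)
    if (is.null(wn)) stop("supply the wavenumber axis via wn")
    if (ncol(m) < 2L) stop("need at least 2 replicates")
  }
  window <- sort(window)
  sel <- wn >= window[1] & wn <= window[2]
  if (!any(sel)) stop("window [", window[1], ", ", window[2],
                      "] cm-1 lies outside the spectral grid")
  mu <- rowMeans(m[sel, , drop = FALSE])
  sdv <- apply(m[sel, , drop = FALSE], 1, sd)
  mean(sdv / mu)
}

#' Absorbance noise equivalent of an intensity RSD
#'
#' For small relative intensity noise, `sigma_A = RSD / ln(10)`; e.g. an
#' RSD of 0.07% corresponds to about 0.0003 absorbance units.
#'
#' @param rsd relative standard deviation (fraction).
#' @return absorbance standard deviation, AU.
#' @export
absorbanceNoiseFromRsd <- function(rsd) rsd / log(10)

#' Process one raw measurement to an averaged intensity spectrum
#'
#' Bins every scan, aligns scans 2..n to the first scan (shift + additive
#' offset), and averages.
#'
#' @param scans list of [ScanRecord-class] objects (one measurement).
#' @param binSize,nPoints see [binPulses()].
#' @param maxShift alignment search half-width, bins.
#' @return an intensity [Spectrum-class].
#' @export
processMeasurement <- function(scans, binSize = 255L, nPoints = NULL,
                               maxShift = 5L) {
  ref <- binPulses(scans[[1]], binSize = binSize, nPoints = nPoints)
  np <- length(ref@values)
  spectra <- c(list(ref), lapply(scans[-1], function(sc) {
    # scans share the measurement's wavenumber grid; bin intensities only
    vals <- .colMeans(sc@intensities, binSize, np)
    Spectrum(ref@wavenumbers, rev(vals), kind = "intensity",
             metadata = ref@metadata)
  }))
  aligned <- c(spectra[1], lapply(spectra[-1], function(s)
    alignScan(ref, s, maxShift = maxShift, applyOffset = TRUE)$aligned))
  averageScans(aligned)
}

#' Absorbance spectrum of a background/sample measurement pair
#'
#' Processes both measurements ([processMeasurement()]) and aligns the
#' sample average to the background average before ratioing them into
#' absorbance.  This inter-measurement alignment is performed on the
#' log10-intensity spectra over `alignWindow`, by default the water-edge
#' region below 1000 cm-1 where none of the analytes absorb: there the
#' sample and background share their structure (the steep solvent edge),
#' so the chi-squared shift estimate is not biased by the absorption bands
#' (a fit over the full range systematically trades a spurious shift
#' against its free offset when the sample absorbs).  Only the recovered
#' shift is applied; the fitted log-offset (a multiplicative gain) is left
#' in place so the absorbance signal is preserved exactly.
#'
#' When a `reference` background spectrum is supplied, the processed
#' background is first registered onto it (shift only, full-range
#' intensity fit -- two backgrounds share their structure), and the sample
#' follows its background.  Anchoring every measurement of a study to one
#' common reference removes the measurement-to-measurement registration
#' jitter that otherwise makes band positions wander between spectra --
#' the "offset between measurements" the alignment procedure exists to
#' correct.
#'
#' @param pair list with elements `background` and `sample`, as from
#'   [simulateSamplePair()].
#' @param alignWindow wavenumber window (cm-1) used for the
#'   sample-to-background shift estimate.
#' @param reference optional processed background [Spectrum-class] serving
#'   as the study-wide registration anchor.
#' @inheritParams processMeasurement
#' @return an absorbance [Spectrum-class]; its metadata carries the
#'   processed (and, if applicable, re-registered) background under
#'   `$background`, so the first measurement of a study can seed the
#'   reference for the rest.
#' @export
absorbanceFromPair <- function(pair, binSize = 255L, nPoints = NULL,
                               maxShift = 5L, alignWindow = c(925, 1000),
                               reference = NULL) {
  bg <- processMeasurement(pair$background, binSize, nPoints, maxShift)
  sm <- processMeasurement(pair$sample, binSize, nPoints, maxShift)
  if (!is.null(reference))
    bg <- alignScan(reference, bg, maxShift = maxShift,
                    applyOffset = FALSE)$aligned
  if (any(sm@values <= 0) || any(bg@values <= 0)) {
    bad <- which(sm@values <= 0 | bg@values <= 0)
    stop("non-positive intensity at ",
         format(sm@wavenumbers[bad[1]], digits = 6),
         " cm-1: cannot form absorbance")
  }
  lbg <- Spectrum(bg@wavenumbers, log10(bg@values), kind = "intensity",
                  metadata = bg@metadata)
  lsm <- Spectrum(sm@wavenumbers, log10(sm@values), kind = "intensity",
                  metadata = sm@metadata)
  al <- alignScan(lbg, lsm, maxShift = maxShift, applyOffset = FALSE,
                  window = alignWindow)
  md <- sm@metadata
  md$ratioed <- TRUE
  md$pairShift <- al$solution@binShift
  md$background <- bg
  Spectrum(bg@wavenumbers, -(al$aligned@values - lbg@values),
           kind = "absorbance", metadata = md)
}
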