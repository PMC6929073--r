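# End-to-end study orchestration: design -> simulate -> process -> quantify
# for both setups, mirroring the study layout of 25 designed samples
# measured in 4 series (2 series on each of 2 days) in each configuration.

#' Study configuration
#'
#' Bundles everything [runStudy()] needs: the design parameters, the two
#' instrument configurations, the series/day layout, the processing
#' parameters and the cross-validation settings.  Any instrument parameter
#' can be overridden for both setups at once via `...` (passed to
#' [instrumentConfig()]).
#'
#' @param nSamples number of designed samples.
#' @param ranges analyte concentration ranges, see [concentrationRanges()].
#' @param nSeries number of measurement series per setup.
#' @param dayOfSeries day id of each series.
#' @param nScans scans per measurement.
#' @param setups which configurations to run.
#' @param binSize,nPoints,maxShift processing parameters, see
#'   [processMeasurement()].
#' @param schemes cross-validation schemes to evaluate.
#' @param nLV latent-variable counts to evaluate.
#' @param window,polyorder,standardize preprocessing, see
#'   [preprocessSpectra()].
#' @param gridLevels,nRestarts design optimiser settings, see
#'   [aOptimalDesign()].
#' @param ... overrides forwarded to [instrumentConfig()] for both setups.
#' @return a named list of class `"studyConfig"`.
#' @export
studyConfig <- function(nSamples = 25, ranges = concentrationRanges(),
                        nSeries = 4, dayOfSeries = c(1, 1, 2, 2),
                        nScans = 10,
                        setups = c("transmission", "ATR"),
                        binSize = 255L, nPoints = 390L, maxShift = 5L,
                        schemes = c("LOOCV", "L5OCV", "LDOCV"),
                        nLV = 1:8, window = 9L, polyorder = 2L,
                        standardize = TRUE,
                        gridLevels = 4, nRestarts = 20, ...) {
  stopifnot(length(dayOfSeries) == nSeries)
  cfg <- list(nSamples = nSamples, ranges = ranges, nSeries = nSeries,
              dayOfSeries = as.integer(dayOfSeries), nScans = nScans,
              setups = match.arg(setups, several.ok = TRUE),
              binSize = as.integer(binSize), nPoints = as.integer(nPoints),
              maxShift = as.integer(maxShift), schemes = schemes,
              nLV = nLV, window = as.integer(window),
              polyorder = as.integer(polyorder),
              standardize = standardize, gridLevels = gridLevels,
              nRestarts = nRestarts, instrument = list(...))
  # the acquisition shift quantum follows the processing bin unless the
  # caller pins it explicitly
  if (is.null(cfg$instrument$binSize))
    cfg$instrument$binSize <- as.integer(binSize)
  class(cfg) <- c("studyConfig", "list")
  cfg
}

#' Assemble absorbance spectra into a SummarizedExperiment
#'
#' Rows are spectral points (wavenumber in the row data), columns are
#' measurements; the assay is named `"absorbance"` and the column data
#' carries the sample / series / day identifiers and the reference
#' concentrations.
#'
#' @param spectra list of absorbance [Spectrum-class] objects on a common
#'   grid.
#' @param colData data.frame of per-measurement metadata (one row per
#'   spectrum).
#' @return a [SummarizedExperiment::SummarizedExperiment] with an
#'   `"analytes"` attribute naming the concentration columns.
#' @importFrom SummarizedExperiment SummarizedExperiment assay colData
#' @importFrom S4Vectors DataFrame
#' @export
spectraSet <- function(spectra, colData) {
  stopifnot(length(spectra) == nrow(colData))
  wn <- spectra[[1]]@wavenumbers
  m <- vapply(spectra, function(s) {
    if (!.sameGrid(spectra[[1]], s))
      stop("spectra are not on a common grid")
    s@values
  }, numeric(length(wn)))
  rownames(m) <- format(wn, digits = 7)
  se <- SummarizedExperiment(
    assays = list(absorbance = m),
    rowData = DataFrame(wavenumber = wn),
    colData = DataFrame(colData))
  attr(se, "analytes") <- intersect(colnames(colData),
                                    c("glucose", "albumin", "urea",
                                      "lactate"))
  se
}

#' Run the full synthetic study
#'
#' Generates the A-optimal design, simulates every background/sample
#' measurement pair for each series and setup, processes the raw scans into
#' aligned absorbance spectra, and cross-validates PLS1 concentration
#' predictions under every requested scheme.  All randomness is chained off
#' the single `seed`, so the result (including the written JSON) is
#' reproducible bit-for-bit.
#'
#' @param config a [studyConfig()].
#' @param seed integer master seed.
#' @param verbose print stage progress to stderr.
#' @return a list of class `"studyResult"` with elements
#'   \describe{
#'     \item{design}{the [SampleDesign-class]}
#'     \item{spectra}{named list of [spectraSet()] objects, one per setup}
#'     \item{cv}{nested list `setup -> scheme ->` [CVResult-class]}
#'     \item{manifest}{seeds, configuration and package version}
#'   }
#' @examples
#' \donttest{
#' res <- runStudy(studyConfig(nSamples = 25), seed = 7)
#' cvBest(res$cv$transmission$L5OCV)
#' }
#' @export
runStudy <- function(config = studyConfig(), seed = 1, verbose = FALSE) {
  stopifnot(inherits(config, "studyConfig"))
  .withSeed(seed, {
    design <- aOptimalDesign(config$ranges, config$nSamples,
                             gridLevels = config$gridLevels,
                             seed = NULL, nRestarts = config$nRestarts)
    conc <- designConcentrations(design)
    spectraSets <- list()
    cv <- list()
    for (setup in config$setups) {
      if (verbose) message("simulating ", setup, " setup")
      icfg <- do.call(instrumentConfig,
                      c(list(setupType = setup), config$instrument))
      specs <- list()
      meta <- list()
      refBg <- NULL     # study-wide registration anchor (first background)
      for (series in seq_len(config$nSeries)) {
        drift <- rnorm(1, 0, icfg@seriesDriftSd)
        day <- config$dayOfSeries[series]
        for (i in seq_len(nrow(conc))) {
          pair <- simulateSamplePair(conc[i, ], icfg,
                                     nScans = config$nScans,
                                     sampleId = rownames(conc)[i],
                                     seriesId = series, dayId = day,
                                     seriesDrift = drift)
          ab <- absorbanceFromPair(pair, binSize = config$binSize,
                                   nPoints = config$nPoints,
                                   maxShift = config$maxShift,
                                   reference = refBg)
          if (is.null(refBg)) refBg <- ab@metadata$background
          specs[[length(specs) + 1L]] <- ab
          meta[[length(meta) + 1L]] <- data.frame(
            sampleId = rownames(conc)[i], seriesId = series, dayId = day,
            setup = setup, as.data.frame(t(conc[i, ])))
        }
      }
      se <- spectraSet(specs, do.call(rbind, meta))
      spectraSets[[setup]] <- se
      cv[[setup]] <- lapply(setNames(config$schemes, config$schemes),
                            function(sch)
        crossValidate(se, scheme = sch, nLV = config$nLV,
                      window = config$window,
                      polyorder = config$polyorder,
                      standardize = config$standardize,
                      edgeExclude = config$maxShift + 1L))
    }
    res <- list(design = design, spectra = spectraSets, cv = cv,
                manifest = list(seed = seed, config = config,
                                version = as.character(
                                  utils::packageVersion("qclspec"))))
    class(res) <- c("studyResult", "list")
    res
  })
}

#' Flat summary table of a study's cross-validation results
#'
#' One row per setup / scheme / analyte with the RMSECV-minimising
#' latent-variable count - the layout of a multi-scheme prediction-error
#' table.
#'
#' @param result a `"studyResult"` from [runStudy()].
#' @return data.frame with columns `setup`, `scheme`, `analyte`, `nLV`,
#'   `rmsecv`, `r2`.
#' @export
studySummary <- function(result) {
  out <- list()
  for (setup in names(result$cv))
    for (sch in names(result$cv[[setup]])) {
      b <- cvBest(result$cv[[setup]][[sch]])
      out[[length(out) + 1L]] <- data.frame(setup = setup, scheme = sch,
                                            b, row.names = NULL)
    }
  do.call(rbind, out)
}

# ---------------------------------------------------------------------------
# plain-text I/O
# ---------------------------------------------------------------------------

#' Read / write a design as CSV
#'
#' Columns: `sample_id` then one column per analyte (mg/dL).
#'
#' @param design a [SampleDesign-class].
#' @param path CSV file path.
#' @return `readDesignCSV` returns the concentration matrix.
#' @export
writeDesignCSV <- function(design, path) {
  cc <- designConcentrations(design)
  df <- data.frame(sample_id = rownames(cc), cc, row.names = NULL)
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname writeDesignCSV
#' @export
readDesignCSV <- function(path) {
  df <- utils::read.csv(path)
  m <- as.matrix(df[, -1, drop = FALSE])
  rownames(m) <- df[[1]]
  m
}

#' Read / write a prism geometry as JSON
#'
#' @param geometry a [PrismGeometry-class].
#' @param path JSON file path.
#' @return `readPrismJSON` returns a [PrismGeometry-class].
#' @export
writePrismJSON <- function(geometry, path) {
  jsonlite::write_json(list(
    topFacetLength = geometry@topFacetLength,
    topFacetWidth = geometry@topFacetWidth,
    height = geometry@height, facetAngle = geometry@facetAngle,
    nPrism = geometry@nPrism, nSample = geometry@nSample),
    path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname writePrismJSON
#' @export
readPrismJSON <- function(path) {
  x <- jsonlite::read_json(path, simplifyVector = TRUE)
  do.call(PrismGeometry, x)
}

#' Write spectra and study results to plain-text files
#'
#' Writes `design.csv`, one `spectra_<setup>.csv` per setup (wavenumber
#' column followed by one absorbance column per measurement), and
#' `results.json` with the cross-validation tables and the manifest.  All
#' artifacts are deterministic for a given seed.
#'
#' @param result a `"studyResult"` from [runStudy()].
#' @param dir output directory (created if needed).
#' @return invisibly, the paths written.
#' @export
writeStudyResults <- function(result, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  paths <- character()
  p <- file.path(dir, "design.csv")
  writeDesignCSV(result$design, p); paths <- c(paths, p)
  for (setup in names(result$spectra)) {
    se <- result$spectra[[setup]]
    df <- data.frame(
      wavenumber = SummarizedExperiment::rowData(se)$wavenumber,
      SummarizedExperiment::assay(se), check.names = FALSE)
    p <- file.path(dir, paste0("spectra_", setup, ".csv"))
    utils::write.csv(df, p, row.names = FALSE, quote = FALSE)
    paths <- c(paths, p)
  }
  cvOut <- lapply(result$cv, function(bySetup)
    lapply(bySetup, function(r)
      list(best = cvBest(r), perLV = cvTable(r))))
  p <- file.path(dir, "results.json")
  jsonlite::write_json(list(cv = cvOut,
                            manifest = result$manifest[c("seed", "version")],
                            summary = studySummary(result)),
                       p, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  paths <- c(paths, p)
  invisible(paths)
}
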