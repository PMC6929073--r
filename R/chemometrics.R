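# Preprocessing, NIPALS partial least-squares regression, and the three
# cross-validation schemes (LOOCV, L5OCV, LDOCV) with RMSECV / R-squared.

#' Savitzky-Golay smoothing plus standardisation
#'
#' Applies per-spectrum Savitzky-Golay smoothing (via
#' [signal::sgolayfilt()]) and then per-feature centring/scaling.  When
#' `stats` is `NULL` the centring and scaling statistics are computed from
#' `X` (a training set); pass the returned `stats` to transform held-out
#' spectra with training statistics only, avoiding leakage across
#' cross-validation folds.  Features with (near-)zero training variance are
#' centred but not scaled.
#'
#' @param X numeric matrix, one spectrum per row.
#' @param window Savitzky-Golay window width (odd), points.
#' @param polyorder Savitzky-Golay polynomial order (< window).
#' @param standardize centre and scale features.
#' @param stats list with elements `center` and `scale` from a previous
#'   call, or `NULL` to fit them on `X`.
#' @return list with the transformed matrix `X` and the `stats` used.
#' @importFrom signal sgolayfilt
#' @export
preprocessSpectra <- function(X, window = 9L, polyorder = 2L,
                              standardize = TRUE, stats = NULL) {
  X <- as.matrix(X)
  if (window %% 2L != 1L || window <= polyorder)
    stop("window must be odd and greater than polyorder")
  if (window >= ncol(X))
    stop("Savitzky-Golay window (", window, ") must be shorter than the ",
         "spectrum (", ncol(X), " points)")
  Xs <- t(apply(X, 1, sgolayfilt, p = polyorder, n = window))
  if (!standardize)
    return(list(X = Xs, stats = NULL))
  if (is.null(stats)) {
    ctr <- colMeans(Xs)
    scl <- apply(Xs, 2, sd)
    scl[!is.finite(scl) | scl < 1e-12] <- 1
    stats <- list(center = ctr, scale = scl)
  }
  Xs <- sweep(sweep(Xs, 2, stats$center, `-`), 2, stats$scale, `/`)
  list(X = Xs, stats = stats)
}

#' Fit a partial least-squares model (NIPALS)
#'
#' Sequential NIPALS extraction of latent variables maximising the
#' covariance between X-scores and the response(s).  Deterministic (no
#' random initialisation); supports a single response (PLS1, closed-form
#' weights per component) or multiple responses (PLS2, inner NIPALS
#' iteration).  Extraction stops early with a warning when the deflated X
#' carries no variance (rank reached); the number actually extracted is
#' recorded in `achievedLV`.
#'
#' @param X feature matrix (n x p).
#' @param Y response matrix or vector (n x m), e.g. concentrations in
#'   mg/dL.
#' @param nLV number of latent variables, in
#'   `[1, min(nrow(X) - 1, ncol(X))]`.
#' @return a [PLSModel-class].
#' @examples
#' X <- matrix(rnorm(60), 12, 5)
#' y <- X %*% c(1, -1, 0, 2, 0)
#' m <- plsFit(X, y, 3)
#' @export
plsFit <- function(X, Y, nLV) {
  X <- as.matrix(X); Y <- as.matrix(Y)
  if (nrow(X) != nrow(Y)) stop("X and Y must have the same number of rows")
  kmax <- min(nrow(X) - 1L, ncol(X))
  if (nLV < 1L || nLV > kmax)
    stop("nLV must lie in [1, ", kmax, "]")
  xm <- colMeans(X); ym <- colMeans(Y)
  E <- sweep(X, 2, xm); F <- sweep(Y, 2, ym)
  p <- ncol(X); m <- ncol(Y)
  W <- matrix(0, p, nLV); P <- matrix(0, p, nLV)
  Q <- matrix(0, m, nLV); Tm <- matrix(0, nrow(X), nLV)
  k <- 0L
  tolX <- 1e-12 * max(1, sum(E^2))
  for (a in seq_len(nLV)) {
    if (sum(E^2) <= tolX) {
      warning("X exhausted after ", k, " latent variables (rank reached)")
      break
    }
    if (m == 1L) {
      w <- crossprod(E, F)[, 1]
    } else {
      u <- F[, which.max(colSums(F^2))]
      w <- crossprod(E, u)[, 1]
      for (it in 1:500) {
        w <- w / sqrt(sum(w^2))
        tt <- E %*% w
        q <- crossprod(F, tt)[, 1] / sum(tt^2)
        u_new <- F %*% q / sum(q^2)
        if (sum((u_new - u)^2) < 1e-14 * max(sum(u^2), 1e-300)) break
        u <- u_new
        w <- crossprod(E, u)[, 1]
      }
    }
    nw <- sqrt(sum(w^2))
    if (nw < 1e-14) {
      warning("no covariance left after ", k, " latent variables")
      break
    }
    w <- w / nw
    tt <- E %*% w
    tt2 <- sum(tt^2)
    if (tt2 < 1e-28) {
      warning("degenerate score after ", k, " latent variables")
      break
    }
    pp <- crossprod(E, tt)[, 1] / tt2
    qq <- crossprod(F, tt)[, 1] / tt2
    E <- E - tt %*% t(pp)
    F <- F - tt %*% t(qq)
    k <- a
    W[, a] <- w; P[, a] <- pp; Q[, a] <- qq; Tm[, a] <- tt
  }
  if (k == 0L) stop("could not extract any latent variable")
  rownames(Q) <- colnames(Y)
  new("PLSModel",
      weights = W[, seq_len(k), drop = FALSE],
      loadings = P[, seq_len(k), drop = FALSE],
      yLoadings = Q[, seq_len(k), drop = FALSE],
      scores = Tm[, seq_len(k), drop = FALSE],
      xMeans = xm, yMeans = ym,
      nLV = as.integer(nLV), achievedLV = k)
}

#' Regression coefficients of a PLS model
#'
#' `B = W (P'W)^-1 Q'` using the first `nLV` latent variables.
#'
#' @param model a [PLSModel-class].
#' @param nLV number of latent variables to use (default: all achieved).
#' @return p x m coefficient matrix (centred scale).
#' @export
plsCoefficients <- function(model, nLV = model@achievedLV) {
  if (nLV < 1L || nLV > model@achievedLV)
    stop("nLV must lie in [1, ", model@achievedLV, "]")
  idx <- seq_len(nLV)
  W <- model@weights[, idx, drop = FALSE]
  P <- model@loadings[, idx, drop = FALSE]
  Q <- model@yLoadings[, idx, drop = FALSE]
  W %*% solve(crossprod(P, W)) %*% t(Q)
}

#' Predict from a PLS model
#'
#' @param object a [PLSModel-class].
#' @param newdata feature matrix (n x p).
#' @param nLV number of latent variables to use (default: all achieved).
#' @param ... unused.
#' @return n x m matrix of predicted responses.
#' @export
setMethod("predict", "PLSModel", function(object, newdata,
                                          nLV = object@achievedLV, ...) {
  B <- plsCoefficients(object, nLV)
  sweep(sweep(as.matrix(newdata), 2, object@xMeans) %*% B, 2,
        object@yMeans, `+`)
})

#' Root-mean-square error
#' @param pred,ref numeric vectors of equal length.
#' @return RMSE in the units of the inputs (mg/dL for concentrations).
#' @export
rmse <- function(pred, ref) {
  stopifnot(length(pred) == length(ref))
  sqrt(mean((pred - ref)^2))
}

#' Coefficient of determination
#'
#' `R^2 = 1 - SS_res / SS_tot` about the reference mean.
#'
#' @param pred,ref numeric vectors of equal length >= 2.
#' @return R-squared (dimensionless, <= 1).
#' @export
rsq <- function(pred, ref) {
  stopifnot(length(pred) == length(ref), length(ref) >= 2)
  sstot <- sum((ref - mean(ref))^2)
  if (sstot <= 0) stop("reference values have zero variance: R2 undefined")
  1 - sum((pred - ref)^2) / sstot
}

#' Cross-validation fold assignment
#'
#' LOOCV: one measurement per fold.  L5OCV: blocks of five consecutive
#' samples in design order within each series.  LDOCV: one fold per
#' measurement series.
#'
#' @param sampleId integer/character sample identifier per measurement.
#' @param seriesId integer series identifier per measurement.
#' @param scheme `"LOOCV"`, `"L5OCV"` or `"LDOCV"`.
#' @param blockSize block size for L5OCV.
#' @return integer fold id per measurement.
#' @export
cvFolds <- function(sampleId, seriesId,
                    scheme = c("LOOCV", "L5OCV", "LDOCV"),
                    blockSize = 5L) {
  scheme <- match.arg(scheme)
  n <- length(sampleId)
  if (scheme == "LOOCV") return(seq_len(n))
  if (scheme == "LDOCV") {
    sid <- as.integer(factor(seriesId))
    if (length(unique(sid)) < 2L)
      stop("LDOCV requires at least 2 distinct measurement series")
    return(sid)
  }
  # L5OCV: consecutive blocks of blockSize samples within each series
  folds <- integer(n)
  next_id <- 1L
  for (s in unique(seriesId)) {
    i <- which(seriesId == s)
    i <- i[order(sampleId[i])]
    blocks <- ceiling(seq_along(i) / blockSize)
    folds[i] <- next_id - 1L + blocks
    next_id <- next_id + max(blocks)
  }
  folds
}

#' Cross-validated PLS concentration prediction
#'
#' Runs the full preprocessing + PLS1 chain under one of the three
#' cross-validation schemes.  Savitzky-Golay smoothing is per-spectrum;
#' the centring/scaling statistics are refit on each training fold and
#' applied to its held-out measurements (no leakage).  One PLS1 model per
#' analyte is fitted per fold at the maximum requested latent-variable
#' count and evaluated at every count in `nLV`; RMSECV and R-squared are
#' computed on the pooled held-out predictions.
#'
#' @param X spectra matrix (measurements x points) or a
#'   `SummarizedExperiment` from [spectraSet()] (in which case `Y`,
#'   `sampleId` and `seriesId` are taken from its column data).
#' @param Y concentration matrix (measurements x analytes), mg/dL.
#' @param sampleId,seriesId per-measurement identifiers.
#' @param scheme cross-validation scheme, see [cvFolds()].
#' @param nLV latent-variable counts to evaluate.
#' @param window,polyorder,standardize see [preprocessSpectra()].
#' @param edgeExclude number of spectral points dropped from each end of
#'   the feature matrix before regression.  Bins within the alignment
#'   search half-width of the spectrum edges can be edge-padded when
#'   shifts are applied, so the study pipeline excludes them; 0 keeps all
#'   features.
#' @return a [CVResult-class].
#' @export
crossValidate <- function(X, Y = NULL, sampleId = NULL, seriesId = NULL,
                          scheme = c("LOOCV", "L5OCV", "LDOCV"),
                          nLV = 1:8, window = 9L, polyorder = 2L,
                          standardize = TRUE, edgeExclude = 0L) {
  scheme <- match.arg(scheme)
  if (is(X, "SummarizedExperiment")) {
    se <- X
    cd <- as.data.frame(SummarizedExperiment::colData(se))
    analytes <- attr(se, "analytes")
    if (is.null(analytes))
      analytes <- intersect(colnames(cd), concentrationRanges()$analyte)
    Y <- as.matrix(cd[, analytes, drop = FALSE])
    sampleId <- cd$sampleId
    seriesId <- cd$seriesId
    X <- t(SummarizedExperiment::assay(se))
  }
  X <- as.matrix(X); Y <- as.matrix(Y)
  if (edgeExclude > 0L) {
    if (2L * edgeExclude >= ncol(X) - 1L)
      stop("edgeExclude removes every feature")
    X <- X[, (1L + edgeExclude):(ncol(X) - edgeExclude), drop = FALSE]
  }
  if (is.null(colnames(Y))) colnames(Y) <- paste0("y", seq_len(ncol(Y)))
  n <- nrow(X)
  stopifnot(nrow(Y) == n, length(sampleId) == n, length(seriesId) == n)
  folds <- cvFolds(sampleId, seriesId, scheme)
  kmax <- max(nLV)

  analytes <- colnames(Y)
  pred <- array(NA_real_, c(n, length(analytes), length(nLV)),
                dimnames = list(NULL, analytes, paste0("LV", nLV)))
  for (f in unique(folds)) {
    test <- folds == f
    train <- !test
    tr <- preprocessSpectra(X[train, , drop = FALSE], window, polyorder,
                            standardize)
    te <- preprocessSpectra(X[test, , drop = FALSE], window, polyorder,
                            standardize, stats = tr$stats)
    for (a in analytes) {
      fit <- suppressWarnings(
        plsFit(tr$X, Y[train, a], min(kmax, nrow(tr$X) - 1L, ncol(tr$X))))
      for (ki in seq_along(nLV)) {
        k <- min(nLV[ki], fit@achievedLV)
        pred[test, a, ki] <- predict(fit, te$X, nLV = k)[, 1]
      }
    }
  }

  perLV <- do.call(rbind, lapply(analytes, function(a) {
    do.call(rbind, lapply(seq_along(nLV), function(ki) {
      data.frame(analyte = a, nLV = nLV[ki],
                 rmsecv = rmse(pred[, a, ki], Y[, a]),
                 r2 = rsq(pred[, a, ki], Y[, a]))
    }))
  }))
  best <- do.call(rbind, lapply(analytes, function(a) {
    sub <- perLV[perLV$analyte == a, ]
    sub[which.min(sub$rmsecv), ]
  }))
  bestPred <- vapply(seq_along(analytes), function(ai) {
    ki <- which(nLV == best$nLV[ai])
    pred[, analytes[ai], ki]
  }, numeric(n))
  colnames(bestPred) <- analytes

  new("CVResult", scheme = scheme, perLV = perLV, best = best,
      folds = as.integer(folds), predictions = bestPred,
      reference = Y)
}
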