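# Preprocessing, NIPALS PLS, RMSE/R2 and the cross-validation schemes.

test_that("Savitzky-Golay smoothing leaves low-degree polynomials unchanged away from the edges", {
  x <- seq(0, 1, length.out = 60)
  poly <- 2 - 3 * x + 0.5 * x^2
  out <- preprocessSpectra(rbind(poly), window = 9L, polyorder = 2L,
                           standardize = FALSE)$X[1, ]
  interior <- 5:56
  expect_equal(out[interior], poly[interior], tolerance = 1e-10)
  expect_error(preprocessSpectra(rbind(poly), window = 8L), "odd")
  expect_error(preprocessSpectra(rbind(poly), window = 61L), "shorter")
})

test_that("standardisation gives zero-mean unit-variance training features and reuses training stats", {
  set.seed(5)
  X <- matrix(rnorm(200, mean = 3), 10, 20)
  tr <- preprocessSpectra(X, standardize = TRUE)
  expect_equal(colMeans(tr$X), rep(0, 20), tolerance = 1e-12)
  expect_equal(apply(tr$X, 2, sd), rep(1, 20), tolerance = 1e-12)
  Xnew <- matrix(rnorm(40, mean = 5), 2, 20)
  held <- preprocessSpectra(Xnew, standardize = TRUE, stats = tr$stats)$X
  self <- preprocessSpectra(Xnew, standardize = TRUE)$X
  expect_gt(max(abs(held - self)), 0.1)   # training stats matter
  # constant feature: centred, not scaled
  Xc <- cbind(X, 7)
  expect_true(all(is.finite(preprocessSpectra(Xc)$X)))
})

test_that("a response carried by a single orthogonal channel is captured by one latent variable", {
  set.seed(11)
  # centred orthonormal channels: the weight vector collapses onto the
  # informative channel and a single component fits exactly
  X <- qr.Q(qr(scale(matrix(rnorm(25 * 12), 25, 12), scale = FALSE)))
  y <- 3 * X[, 4]
  fit <- plsFit(X, y, 1)
  expect_lt(rmse(predict(fit, X)[, 1], y), 1e-10)
})

test_that("PLS with full rank reproduces ordinary least squares", {
  set.seed(21)
  X <- matrix(rnorm(12 * 5), 12, 5)
  y <- rnorm(12)
  fit <- plsFit(X, y, 5)
  ols <- lm(y ~ X)
  expect_equal(predict(fit, X)[, 1], unname(fitted(ols)),
               tolerance = 1e-8)
  Xnew <- matrix(rnorm(3 * 5), 3, 5)
  expect_equal(predict(fit, Xnew)[, 1],
               unname(cbind(1, Xnew) %*% coef(ols))[, 1], tolerance = 1e-8)
})

test_that("four latent variables recover noiseless four-analyte Beer-Lambert mixtures", {
  mix <- linearMixtures(30, seed = 3)
  fit <- plsFit(mix$X, mix$Y, 4)
  pred <- predict(fit, mix$X)
  rg <- concentrationRanges()
  for (a in rg$analyte) {
    expect_lt(rmse(pred[, a], mix$Y[, a]),
              1e-6 * rg$max[rg$analyte == a])
  }
})

test_that("NIPALS agrees with an independent PLS implementation", {
  suppressMessages(requireNamespace("mixOmics", quietly = TRUE))
  set.seed(17)
  X <- matrix(rnorm(20 * 8), 20, 8,
              dimnames = list(NULL, paste0("v", 1:8)))
  y <- X %*% rnorm(8) + rnorm(20, 0, 0.1)
  ours <- plsFit(X, y, 3)
  theirs <- mixOmics::pls(X, y, ncomp = 3, mode = "regression",
                          scale = FALSE)
  predTheirs <- predict(theirs, X)$predict[, 1, 3]
  expect_equal(predict(ours, X, nLV = 3)[, 1], unname(predTheirs),
               tolerance = 1e-6)
})

test_that("rank-deficient feature matrices stop early with a warning and record achieved LVs", {
  set.seed(9)
  base <- matrix(rnorm(20 * 2), 20, 2)
  X <- cbind(base, base %*% matrix(rnorm(4), 2, 2))  # rank 2, 4 columns
  y <- rnorm(20)
  expect_warning(fit <- plsFit(X, y, 4), "latent variables")
  expect_lt(fit@achievedLV, 4L)
  expect_error(plsFit(X, y, 25), "nLV")
})

test_that("rmse and r2 match hand calculations and guard degenerate input", {
  expect_equal(rmse(c(1, 2, 3), c(1, 2, 4)), sqrt(1 / 3))
  expect_equal(rmse(1:4, 1:4), 0)
  expect_equal(rsq(1:4, 1:4), 1)
  ref <- c(2, 4, 6, 8)
  expect_equal(rsq(rep(mean(ref), 4), ref), 0)
  expect_error(rsq(c(1, 2), c(3, 3)), "zero variance")
})

test_that("fold construction matches the three schemes", {
  sampleId <- rep(1:25, times = 2)
  seriesId <- rep(1:2, each = 25)
  expect_length(unique(cvFolds(sampleId, seriesId, "LOOCV")), 50L)
  l5 <- cvFolds(sampleId, seriesId, "L5OCV")
  expect_length(unique(l5), 10L)
  expect_true(all(table(l5) == 5))
  # blocks never straddle series
  expect_true(all(vapply(split(seriesId, l5),
                         function(s) length(unique(s)) == 1L, logical(1))))
  ld <- cvFolds(sampleId, seriesId, "LDOCV")
  expect_length(unique(ld), 2L)
  expect_error(cvFolds(1:10, rep(1, 10), "LDOCV"), "at least 2")
})

test_that("a perfectly linear dataset cross-validates to ~zero RMSECV and R2 = 1 under every scheme", {
  mix <- linearMixtures(25, seed = 8)
  X2 <- rbind(mix$X, mix$X)            # two identical series
  Y2 <- rbind(mix$Y, mix$Y)
  sampleId <- rep(1:25, 2); seriesId <- rep(1:2, each = 25)
  for (sch in c("LOOCV", "L5OCV", "LDOCV")) {
    cv <- crossValidate(X2, Y2, sampleId, seriesId, scheme = sch,
                        nLV = 4, window = 9L)
    b <- cvBest(cv)
    expect_lt(max(b$rmsecv / c(800, 6000, 200, 90)), 1e-6)
    expect_gt(min(b$r2), 1 - 1e-10)
  }
})

test_that("RMSECV is scale-equivariant in the concentrations", {
  mix <- linearMixtures(25, seed = 13)
  set.seed(14)
  Xn <- mix$X + matrix(rnorm(length(mix$X), 0, 1e-4), nrow(mix$X))
  sampleId <- 1:25; seriesId <- rep(1, 25)
  cv1 <- crossValidate(Xn, mix$Y, sampleId, seriesId, scheme = "LOOCV",
                       nLV = 4)
  cv10 <- crossValidate(Xn, 10 * mix$Y, sampleId, seriesId,
                        scheme = "LOOCV", nLV = 4)
  expect_equal(cvBest(cv10)$rmsecv, 10 * cvBest(cv1)$rmsecv,
               tolerance = 1e-10)
})

test_that("a series-level offset degrades LDOCV more than LOOCV", {
  mix <- linearMixtures(25, seed = 19)
  nWn <- ncol(mix$X)
  set.seed(20)
  baseline <- outer(c(-0.02, 0.01, 0.02, -0.01), rep(1, nWn))  # per series
  X4 <- do.call(rbind, lapply(1:4, function(s) {
    mix$X + baseline[rep(s, 25), ] +
      matrix(rnorm(length(mix$X), 0, 2e-4), 25)
  }))
  Y4 <- do.call(rbind, replicate(4, mix$Y, simplify = FALSE))
  sampleId <- rep(1:25, 4); seriesId <- rep(1:4, each = 25)
  loo <- crossValidate(X4, Y4, sampleId, seriesId, scheme = "LOOCV",
                       nLV = 1:5)
  ldo <- crossValidate(X4, Y4, sampleId, seriesId, scheme = "LDOCV",
                       nLV = 1:5)
  g <- function(cv) cvBest(cv)$rmsecv[cvBest(cv)$analyte == "glucose"]
  expect_gte(g(ldo), g(loo))
})

test_that("interferents at random concentrations keep glucose prediction linear with slope ~1", {
  mix <- linearMixtures(50, seed = 23)
  sampleId <- 1:50; seriesId <- rep(1:2, each = 25)
  cv <- crossValidate(mix$X, mix$Y, sampleId, seriesId, scheme = "L5OCV",
                      nLV = 4)
  pred <- cvPredictions(cv)[, "glucose"]
  slope <- coef(lm(pred ~ mix$Y[, "glucose"]))[2]
  expect_gt(slope, 0.95)
  expect_lt(slope, 1.05)
})
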