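# A-optimal mixture design for the calibration sample set.
#
# The four analytes are mapped to Scheffe pseudo-components by scaling each
# concentration with its range; a fifth closing component (the aqueous
# diluent) makes the compositions sum to one, as the canonical Scheffe
# polynomial requires.  A Fedorov single-point exchange over a simplex
# lattice candidate set minimises the A-criterion trace((X'X)^-1).

# run a block of code with a locally-seeded RNG, restoring the caller's state
.withSeed <- function(seed, code) {
  if (is.null(seed)) return(force(code))
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(suppressWarnings(
      rm(".Random.seed", envir = globalenv())), add = TRUE)
  }
  set.seed(seed)
  force(code)
}

#' Default analyte concentration ranges
#'
#' The calibration design space of the four-analyte aqueous system:
#' glucose 0-800, albumin 0-6000, urea 0-200 and lactate 0-90 mg/dL.
#'
#' @return data.frame with columns `analyte`, `min`, `max` (mg/dL).
#' @export
concentrationRanges <- function() {
  data.frame(
    analyte = c("glucose", "albumin", "urea", "lactate"),
    min = c(0, 0, 0, 0),
    max = c(800, 6000, 200, 90)
  )
}

#' Scheffe quadratic model terms
#'
#' Terms of the canonical quadratic Scheffe mixture polynomial in `q`
#' components: the `q` linear terms plus the `q(q-1)/2` two-way cross
#' products.  The canonical form has no intercept and no pure quadratic
#' terms (both are absorbed by the mixture constraint sum(x) = 1).
#'
#' @param nComponents number of mixture components, >= 2.
#' @return character vector of term labels (`"x1"`, ..., `"x1:x2"`, ...).
#' @examples
#' scheffeQuadraticTerms(3)  # 6 terms
#' @export
scheffeQuadraticTerms <- function(nComponents) {
  if (nComponents < 2) stop("a mixture needs at least 2 components")
  q <- as.integer(nComponents)
  lin <- paste0("x", seq_len(q))
  idx <- which(upper.tri(matrix(0, q, q)), arr.ind = TRUE)
  idx <- idx[order(idx[, 1], idx[, 2]), , drop = FALSE]
  cross <- paste0("x", idx[, 1], ":x", idx[, 2])
  c(lin, cross)
}

#' Scheffe quadratic model matrix
#'
#' Expands an n x q matrix of mixture compositions into the canonical
#' quadratic Scheffe model matrix (linear + cross terms, no intercept).
#'
#' @param x matrix of compositions (rows sum to 1).
#' @return n x (q + q(q-1)/2) model matrix.
#' @export
scheffeModelMatrix <- function(x) {
  x <- as.matrix(x)
  q <- ncol(x)
  if (q < 2) stop("a mixture needs at least 2 components")
  idx <- which(upper.tri(matrix(0, q, q)), arr.ind = TRUE)
  idx <- idx[order(idx[, 1], idx[, 2]), , drop = FALSE]
  cross <- x[, idx[, 1], drop = FALSE] * x[, idx[, 2], drop = FALSE]
  out <- cbind(x, cross)
  colnames(out) <- scheffeQuadraticTerms(q)
  out
}

#' Simplex-lattice candidate compositions
#'
#' All compositions of `q` components on the \{q, m\} simplex lattice, i.e.
#' every composition whose coordinates are multiples of `1/m`.  Rows are
#' returned in canonical lexicographic order so that the design search is
#' invariant to how candidates were generated.
#'
#' @param q number of components.
#' @param m lattice degree.
#' @return matrix of compositions, rows summing to 1.
#' @export
simplexLattice <- function(q, m) {
  stopifnot(q >= 2, m >= 1)
  grid <- do.call(expand.grid, rep(list(0:m), q - 1))
  keep <- rowSums(grid) <= m
  x <- cbind(as.matrix(grid[keep, , drop = FALSE]),
             m - rowSums(grid[keep, , drop = FALSE])) / m
  colnames(x) <- paste0("x", seq_len(q))
  rownames(x) <- NULL
  x[do.call(order, as.data.frame(x)), , drop = FALSE]
}

# A-criterion of a design model matrix; Inf when singular
.aCrit <- function(Fd) {
  M <- crossprod(Fd)
  tryCatch(sum(diag(solve(M))), error = function(e) Inf)
}

#' A-optimal mixture design by Fedorov exchange
#'
#' Generates `nSamples` calibration mixtures over the analyte concentration
#' ranges using the canonical quadratic Scheffe model and A-optimality.
#' Each analyte is scaled to a pseudo-component `x_i = c_i / max_i`, and a
#' closing diluent component `x_q = 1 - sum(x_i)` completes the simplex.
#' A Fedorov single-point exchange, started from random full-rank subsets of
#' a simplex-lattice candidate grid and repeated over `nRestarts` restarts,
#' minimises `trace((X'X)^-1)` of the Scheffe model matrix.  Exchange steps
#' only ever accept strict improvements, so the criterion descends
#' monotonically; the whole procedure is deterministic given `seed`.
#'
#' @param ranges data.frame with columns `analyte`, `min`, `max`, as from
#'   [concentrationRanges()].
#' @param nSamples number of design points (>= number of model terms).
#' @param gridLevels simplex-lattice degree of the candidate grid.
#' @param seed integer seed for the random restarts.
#' @param nRestarts number of random restarts of the exchange.
#' @return a [SampleDesign-class]; concentrations are mapped back to mg/dL
#'   and are exactly representable on the candidate grid.
#' @examples
#' des <- aOptimalDesign(nSamples = 25, seed = 1)
#' head(designConcentrations(des))
#' @export
aOptimalDesign <- function(ranges = concentrationRanges(), nSamples = 25,
                           gridLevels = 4, seed = NULL, nRestarts = 20) {
  if (any(ranges$max <= ranges$min))
    stop("degenerate concentration ranges (max <= min): ",
         "the design would be rank-deficient")
  q <- nrow(ranges) + 1L                    # analytes + closing diluent
  terms <- scheffeQuadraticTerms(q)
  p <- length(terms)
  if (nSamples < p)
    stop("nSamples (", nSamples, ") must be at least the number of model ",
         "terms (", p, "): the design would be singular")
  cand <- simplexLattice(q, gridLevels)
  if (nSamples > nrow(cand))
    stop("candidate grid has only ", nrow(cand), " points; increase ",
         "gridLevels")
  Fc <- scheffeModelMatrix(cand)

  .withSeed(seed, {
    bestCrit <- Inf
    bestIdx <- NULL
    for (rs in seq_len(nRestarts)) {
      # random full-rank start (bounded retries)
      idx <- NULL
      for (try in 1:50) {
        cand_idx <- sample(nrow(cand), nSamples)
        if (is.finite(.aCrit(Fc[cand_idx, , drop = FALSE]))) {
          idx <- sort(cand_idx); break
        }
      }
      if (is.null(idx)) next
      crit <- .aCrit(Fc[idx, , drop = FALSE])
      repeat {
        improved <- FALSE
        outPool <- setdiff(seq_len(nrow(cand)), idx)
        bestSwap <- NULL; bestSwapCrit <- crit
        for (i in seq_along(idx)) {
          for (j in outPool) {
            trial <- idx; trial[i] <- j
            cr <- .aCrit(Fc[trial, , drop = FALSE])
            if (cr < bestSwapCrit - 1e-12) {
              bestSwapCrit <- cr; bestSwap <- c(i, j)
            }
          }
        }
        if (!is.null(bestSwap)) {
          idx[bestSwap[1]] <- bestSwap[2]
          crit <- bestSwapCrit
          improved <- TRUE
        }
        if (!improved) break
      }
      if (crit < bestCrit) { bestCrit <- crit; bestIdx <- sort(idx) }
    }
    if (is.null(bestIdx) || !is.finite(bestCrit))
      stop("Fedorov exchange failed to reach a full-rank design after ",
           nRestarts, " restarts")

    x <- cand[bestIdx, , drop = FALSE]
    conc <- sweep(x[, seq_len(q - 1L), drop = FALSE], 2,
                  ranges$max - ranges$min, `*`)
    conc <- sweep(conc, 2, ranges$min, `+`)
    colnames(conc) <- ranges$analyte
    rownames(conc) <- paste0("S", seq_len(nSamples))
    new("SampleDesign",
        concentrations = conc,
        modelTerms     = terms,
        aCriterion     = bestCrit,
        ranges         = ranges)
  })
}

#' Evenly spaced single-analyte dilution series
#'
#' Plain linear spacing helper for single-analyte characterisation samples
#' (e.g. ten glucose-in-water solutions spanning 0-810 mg/dL); this is not
#' part of the optimal-design machinery.
#'
#' @param n number of samples.
#' @param max top concentration, mg/dL.
#' @param analyte analyte name.
#' @return matrix with one concentration column.
#' @export
dilutionSeries <- function(n = 10, max = 810, analyte = "glucose") {
  conc <- matrix(seq(0, max, length.out = n), ncol = 1,
                 dimnames = list(paste0("D", seq_len(n)), analyte))
  conc
}
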