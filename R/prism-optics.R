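# 2-D geometric optics of the trapezoidal ATR prism.
#
# Coordinate frame: bottom facet on y = 0, top (sampling) facet on
# y = height; the top facet spans x in [0, topFacetLength]; the slanted
# coupling facets connect (0, h)->(b0, 0) on the left (entry) and
# (L - b0, 0)->(L, h) on the right (exit), with b0 = h / tan(facetAngle).

.prismFacets <- function(geometry) {
  L <- geometry@topFacetLength
  h <- geometry@height
  b0 <- h / tan(geometry@facetAngle * pi / 180)
  list(
    top    = rbind(c(0, h), c(L, h)),
    bottom = rbind(c(b0, 0), c(L - b0, 0)),
    entry  = rbind(c(0, h), c(b0, 0)),
    exit   = rbind(c(L - b0, 0), c(L, h))
  )
}

# intersection of ray p + t*v (t > tol) with segment a->b; NA when none
.raySegment <- function(p, v, seg, tol = 1e-9) {
  a <- seg[1, ]; b <- seg[2, ]
  d <- b - a
  den <- v[1] * d[2] - v[2] * d[1]
  if (abs(den) < 1e-14) return(NA_real_)
  t <- ((a[1] - p[1]) * d[2] - (a[2] - p[2]) * d[1]) / den
  u <- ((a[1] - p[1]) * v[2] - (a[2] - p[2]) * v[1]) / den
  if (t <= tol || u < -1e-9 || u > 1 + 1e-9) return(NA_real_)
  t
}

# trace one ray from entry point p0 with unit direction v0; returns a list
# with counts, length, and vertex path, or stops on loss of confinement
.traceRay <- function(geometry, p0, v0, maxBounce = 100000L) {
  facets <- .prismFacets(geometry)
  critical <- asin(geometry@nSample / geometry@nPrism)
  p <- p0; v <- v0 / sqrt(sum(v0^2))
  top <- 0L; bottom <- 0L; len <- 0
  path <- list(p)
  for (i in seq_len(maxBounce)) {
    ts <- vapply(facets, function(s) .raySegment(p, v, s), numeric(1))
    if (all(is.na(ts)))
      stop("ray trace failed: ray left the prism without reaching the exit ",
           "facet (entry point ", paste(format(p0, digits = 4),
           collapse = ", "), ")")
    hit <- names(which.min(ts))
    # prefer the exit facet on a (corner) tie
    if (!is.na(ts["exit"]) && ts["exit"] <= min(ts, na.rm = TRUE) + 1e-9)
      hit <- "exit"
    tmin <- ts[[hit]]
    p <- p + tmin * v
    len <- len + tmin
    path[[length(path) + 1L]] <- p
    if (hit == "exit") {
      return(list(top = top, bottom = bottom, length = len,
                  path = do.call(rbind, path)))
    }
    if (hit == "entry")
      stop("ray trace failed: ray returned to the entry facet")
    # top/bottom reflection; check total internal reflection on the
    # sampling (top) facet against the sample medium
    incidence <- acos(min(1, abs(v[2])))  # angle from the facet normal
    if (hit == "top" && incidence <= critical + 1e-12)
      stop(sprintf(paste0("total internal reflection lost on the sampling ",
           "facet: incidence %.2f deg <= critical angle %.2f deg"),
           incidence * 180 / pi, critical * 180 / pi))
    if (hit == "top") top <- top + 1L else bottom <- bottom + 1L
    v[2] <- -v[2]
  }
  stop("ray trace failed: bounce limit exceeded")
}

#' Trace the beam through a trapezoidal ATR prism
#'
#' Traces the central ray (entering at the midpoint of the entry facet at
#' normal incidence, so that it propagates unrefracted at the facet angle)
#' as specular 2-D bounces between the top and bottom facets until it leaves
#' through the exit facet.  With `numericalAperture > 0` and/or a non-zero
#' `beamDiameter`, eight marginal rays are traced in addition - the
#' combinations of entry offsets \{-r, 0, +r\} along the entry facet and
#' internal divergence angles \{-a, 0, +a\} with
#' `a = asin(numericalAperture / nPrism)` - and the largest path-length
#' difference against the central ray is reported.
#'
#' @param geometry a [PrismGeometry-class].
#' @param beamDiameter beam diameter at the entry facet, um.
#' @param numericalAperture numerical aperture of the delivery fiber
#'   (dimensionless, in \[0, 1)); the in-prism divergence half-angle is
#'   `asin(NA / nPrism)`.
#' @return a [RayTraceResult-class].
#' @details Reflections on the sampling (top) facet are checked against the
#'   critical angle `asin(nSample/nPrism)`; losing total internal reflection
#'   raises an error.  The reflection pattern is independent of the entry
#'   offset along the 45-degree facet (all normally-incident entry rays
#'   strike the top facet at the same abscissa), so only the short entry and
#'   exit segments of the propagation length depend on it.
#' @examples
#' res <- tracePrism(PrismGeometry())
#' totalReflections(res)   # 9
#' propagationLength(res)  # ~30.5 mm
#' @export
tracePrism <- function(geometry, beamDiameter = 0, numericalAperture = 0) {
  stopifnot(is(geometry, "PrismGeometry"))
  validObject(geometry)
  if (numericalAperture < 0 || numericalAperture >= 1)
    stop("numericalAperture must lie in [0, 1)")
  if (beamDiameter < 0) stop("beamDiameter must be non-negative (um)")

  facets <- .prismFacets(geometry)
  entry <- facets$entry
  mid <- (entry[1, ] + entry[2, ]) / 2
  edir <- entry[2, ] - entry[1, ]
  edir <- edir / sqrt(sum(edir^2))           # along the entry facet
  normal <- c(-edir[2], edir[1])             # inward normal
  if (normal[1] < 0) normal <- -normal

  central <- .traceRay(geometry, mid, normal)

  maxDiff <- 0
  if (numericalAperture > 0 || beamDiameter > 0) {
    r <- beamDiameter / 2 / 1000             # um -> mm
    alpha <- asin(numericalAperture / geometry@nPrism)
    offs <- unique(c(-r, 0, r))
    angs <- unique(c(-alpha, 0, alpha))
    rot <- function(v, a) c(cos(a) * v[1] - sin(a) * v[2],
                            sin(a) * v[1] + cos(a) * v[2])
    for (o in offs) for (a in angs) {
      if (o == 0 && a == 0) next
      res <- .traceRay(geometry, mid + o * edir, rot(normal, a))
      maxDiff <- max(maxDiff, abs(res$length - central$length))
    }
  }

  new("RayTraceResult",
      totalReflections        = central$top + central$bottom,
      topFacetReflections     = central$top,
      bottomFacetReflections  = central$bottom,
      propagationLength       = central$length,
      maxRadialPathDifference = maxDiff,
      path                    = central$path)
}

#' Evanescent-field penetration depth and interaction length
#'
#' Computes the Harrick penetration depth of the evanescent field at the
#' sampling facet,
#' `d_p = lambda / (2 pi n1 sqrt(sin^2(theta) - (n2/n1)^2))`,
#' with `lambda = 1e4 / wavenumber` um and `theta` the incidence angle at the
#' sampling facet (equal to the coupling-facet angle for a normally-incident
#' entry beam).  The effective sampling depth is
#' `effectiveDepthFactor * d_p` - the conventional allowance for the fact
#' that absorbing material beyond one 1/e decay length still contributes to
#' the attenuated reflection - and the per-wavenumber interaction length is
#' the sampling depth times the number of sampling-facet reflections.
#'
#' @param geometry a [PrismGeometry-class].
#' @param wavenumber wavenumber(s), cm-1 (vectorised).
#' @param effectiveDepthFactor sampling-depth multiplier on the Harrick
#'   depth; the default 2.62 places the sampling depth in the 4-5.4 um range
#'   over 1200-925 cm-1 for a 45-degree ZnS/water interface.
#' @param topReflections number of sampling-facet reflections; by default
#'   taken from the central-ray trace of `geometry`.
#' @return a data.frame with columns `wavenumber` (cm-1), `wavelength` (um),
#'   `penetrationDepth`, `samplingDepth` and `interactionLength` (all um).
#' @examples
#' penetrationDepth(PrismGeometry(), c(1200, 1000, 925))
#' @export
penetrationDepth <- function(geometry, wavenumber,
                             effectiveDepthFactor = 2.62,
                             topReflections = NULL) {
  stopifnot(is(geometry, "PrismGeometry"))
  validObject(geometry)
  if (any(wavenumber <= 0)) stop("wavenumber must be positive (cm-1)")
  theta <- geometry@facetAngle * pi / 180
  ratio <- geometry@nSample / geometry@nPrism
  disc <- sin(theta)^2 - ratio^2
  if (disc <= 0)
    stop(sprintf(paste0("incidence angle %.2f deg does not exceed the ",
         "critical angle %.2f deg: no evanescent confinement"),
         geometry@facetAngle, asin(ratio) * 180 / pi))
  if (is.null(topReflections))
    topReflections <- topFacetReflections(tracePrism(geometry))
  lambda <- 1e4 / wavenumber
  dp <- lambda / (2 * pi * geometry@nPrism * sqrt(disc))
  sdep <- effectiveDepthFactor * dp
  data.frame(
    wavenumber        = wavenumber,
    wavelength        = lambda,
    penetrationDepth  = dp,
    samplingDepth     = sdep,
    interactionLength = topReflections * sdep
  )
}

#' Effective ATR interaction length
#'
#' Convenience wrapper around [penetrationDepth()] returning only the
#' interaction length (um) for a vector of wavenumbers.
#'
#' @inheritParams penetrationDepth
#' @return numeric vector of interaction lengths, um.
#' @export
interactionLength <- function(geometry, wavenumber,
                              effectiveDepthFactor = 2.62,
                              topReflections = NULL) {
  penetrationDepth(geometry, wavenumber, effectiveDepthFactor,
                   topReflections)$interactionLength
}
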