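# Thermal-shift assay analysis: melting-temperature calls from the
# first derivative of the fluorescence trace, and the >2 degC screening
# rule for ligand-induced stabilization.

#' Construct a melt curve
#'
#' @param temperatures Strictly increasing temperatures, degrees C.
#' @param fluorescence Fluorescence readings, same length.
#' @return A [MeltCurve].
#' @export
meltCurve <- function(temperatures, fluorescence) {
  new("MeltCurve", temperatures = as.numeric(temperatures),
      fluorescence = as.numeric(fluorescence))
}

#' Call the melting temperature from a melt curve
#'
#' Smooths the fluorescence with a centered moving average, takes the
#' first derivative by central differences, and reports the temperature
#' of the derivative maximum over the interior of the scan (the first
#' and last `smoothingWindow` points are excluded as edge artefacts),
#' refined by a three-point parabolic interpolation around the peak.
#' A transition is only called when the peak rises above
#' `noiseFactor` times the median absolute derivative; flat or purely
#' drifting curves are reported as "no transition" (`tm = NA`).  The
#' call is invariant under affine transforms of the fluorescence
#' (`F -> aF + b`, `a > 0`).
#'
#' @param curve A [MeltCurve].
#' @param smoothingWindow Odd moving-average window length (default 7).
#' @param noiseFactor Peak-over-median threshold (default 3).
#' @return A [TmCall].
#' @export
callTm <- function(curve, smoothingWindow = 7L, noiseFactor = 3) {
  stopifnot(is(curve, "MeltCurve"))
  if (smoothingWindow %% 2L != 1L || smoothingWindow < 3L)
    stop("smoothingWindow must be an odd integer >= 3")
  tt <- curve@temperatures
  ff <- curve@fluorescence
  n <- length(tt)
  sm <- as.numeric(stats::filter(ff, rep(1 / smoothingWindow,
                                         smoothingWindow), sides = 2L))
  # edges keep the raw trace so the derivative is defined everywhere
  sm[is.na(sm)] <- ff[is.na(sm)]
  d <- numeric(n)
  d[2:(n - 1L)] <- (sm[3:n] - sm[1:(n - 2L)]) / (tt[3:n] - tt[1:(n - 2L)])
  d[1L] <- d[2L]; d[n] <- d[n - 1L]
  interior <- (smoothingWindow + 1L):(n - smoothingWindow)
  if (length(interior) < 3L) stop("curve too short for the chosen window")
  pk <- interior[which.max(d[interior])]
  floorLevel <- noiseFactor * stats::median(abs(d[interior]))
  if (!is.finite(d[pk]) || d[pk] <= floorLevel || d[pk] <= 0)
    return(new("TmCall", tm = NA_real_, peakHeight = d[pk],
               noiseFloor = floorLevel, transition = FALSE))
  tm <- tt[pk]
  if (pk > 1L && pk < n) {
    y1 <- d[pk - 1L]; y2 <- d[pk]; y3 <- d[pk + 1L]
    denom <- y1 - 2 * y2 + y3
    if (is.finite(denom) && abs(denom) > .Machine$double.eps) {
      shift <- 0.5 * (y1 - y3) / denom
      if (abs(shift) <= 1)
        tm <- tt[pk] + shift * (tt[pk + 1L] - tt[pk])
    }
  }
  new("TmCall", tm = tm, peakHeight = d[pk], noiseFloor = floorLevel,
      transition = TRUE)
}

#' Screen a ligand-induced thermal shift
#'
#' A ligand is flagged significant when it raises the melting midpoint
#' by strictly more than `threshold` degrees over the apo protein;
#' decreases are never significant.
#'
#' @param tmLigand,tmApo Melting temperatures (degrees C) of the
#'   ligand-bound and apo samples.
#' @param threshold Shift threshold in degrees C (default 2).
#' @return Logical.
#' @examples
#' screenDeltaTm(57.1, 55.0)  # TRUE
#' screenDeltaTm(56.9, 55.0)  # FALSE
#' @export
screenDeltaTm <- function(tmLigand, tmApo, threshold = 2.0) {
  if (is.na(tmLigand) || is.na(tmApo))
    stop("both melting temperatures must be called before screening")
  (tmLigand - tmApo) > threshold
}
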