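# Peak characterization: intensity-weighted m/z centroid, resolution-
# derived m/z extent, and apex/valley extents in mobility and retention
# time from Savitzky-Golay smoothed 1-D profiles.

#' Intensity-weighted m/z centroid of a point set
#'
#' @param points data.frame with `mz` and `intensity` columns.
#' @return sum(mz * I) / sum(I).
#' @export
mzCentroid <- function(points) {
  if (nrow(points) == 0 || sum(points$intensity) <= 0)
    tdStop("mz centroid of an empty or zero-intensity point set",
           "degenerateInput")
  sum(points$mz * points$intensity) / sum(points$intensity)
}

#' Resolution-derived m/z extent around a centroid
#'
#' The peak width follows from the instrument's resolving power:
#' FWHM = centroid / resolution, sigma = FWHM / (2 sqrt(2 ln 2)), and the
#' extent is three standard deviations either side of the centroid.
#'
#' @param centroid peak centroid m/z (Th).
#' @param resolution resolving power (default 40,000).
#' @return numeric `c(mz_lo, mz_hi)` = centroid -/+ 3 sigma.
#' @export
mzExtent <- function(centroid, resolution = 40000) {
  stopifnot(centroid > 0, resolution > 0)
  s <- mzPeakSigma(centroid, resolution)
  c(centroid - 3 * s, centroid + 3 * s)
}

# Local maxima of a series: s[i] >= both neighbours with at least one
# strict inequality; plateau ties resolve to the first index. Endpoints
# qualify when they exceed their single neighbour.
localMaxima <- function(s) {
  n <- length(s)
  if (n == 1) return(1L)
  left <- c(Inf, s[-n]); right <- c(s[-1], Inf)
  idx <- which((s >= left & s > right) | (s > left & s >= right))
  if (s[1] > s[2]) idx <- union(1L, idx)
  if (s[n] > s[n - 1]) idx <- union(idx, n)
  sort(idx)
}

localMinima <- function(s) localMaxima(-s)

#' Flatten points to one axis and find the peak apex and valleys
#'
#' Points within `half_window` of `midpoint` are grouped by axis position
#' (mobility scan index, or frame retention time) and their intensities
#' summed; missing grid positions are filled with zero. A Savitzky-Golay
#' filter smooths the series, candidate apexes are local maxima above
#' `min_peak_frac` of the series maximum, and — when several apexes are
#' found — the one closest to the midpoint is chosen. The nearest local
#' minimum on either side of the apex is the valley bounding the peak's
#' extent; the window edge is used when no interior valley exists. An
#' apex on the window edge is flagged (`@edgeApex`) as low confidence.
#'
#' @param points data.frame of raw points (`scan`, `rt`, `intensity`).
#' @param axis `"mobility"` (flatten to scans) or `"rt"` (to frame RTs).
#' @param midpoint window center (scan index or RT seconds).
#' @param half_window half-width of the window, in axis units.
#' @param grid optional full set of axis positions inside the window
#'   (e.g. all frame RTs); defaults to integer scans for mobility and to
#'   the positions observed in `points` for RT.
#' @param savgol_window,savgol_order Savitzky-Golay filter length (odd)
#'   and polynomial order; the window shrinks to the largest odd number
#'   not exceeding the series length.
#' @param min_peak_frac local maxima below this fraction of the series
#'   maximum are not apex candidates (noise suppression).
#' @return a [PeakProfile-class].
#' @export
profileExtent <- function(points, axis = c("mobility", "rt"), midpoint,
                          half_window, grid = NULL,
                          savgol_window = 11L, savgol_order = 3L,
                          min_peak_frac = 0.05) {
  axis <- match.arg(axis)
  pos <- if (axis == "mobility") points$scan else points$rt
  inWin <- abs(pos - midpoint) <= half_window
  pos <- pos[inWin]
  inten <- points$intensity[inWin]
  if (length(unique(pos)) < 3)
    tdStop("fewer than 3 distinct axis positions in the window",
           "degeneratePeak")
  if (is.null(grid)) {
    grid <- if (axis == "mobility")
      seq(floor(midpoint - half_window), ceiling(midpoint + half_window))
    else sort(unique(pos))
  } else {
    grid <- sort(grid[abs(grid - midpoint) <= half_window])
  }
  raw <- numeric(length(grid))
  at <- match(pos, grid)
  keep <- !is.na(at)
  sums <- rowsum(inten[keep], at[keep])
  raw[as.integer(rownames(sums))] <- sums[, 1]
  n <- length(raw)
  w <- min(savgol_window, if (n %% 2 == 1) n else n - 1)
  if (w %% 2 == 0) w <- w - 1
  smoothed <- if (w >= savgol_order + 2)
    pmax(0, as.numeric(signal::sgolayfilt(raw, p = savgol_order, n = w)))
  else raw
  maxima <- localMaxima(smoothed)
  maxima <- maxima[smoothed[maxima] >= min_peak_frac * max(smoothed)]
  if (length(maxima) == 0) maxima <- which.max(smoothed)
  apexIdx <- maxima[order(abs(grid[maxima] - midpoint), grid[maxima])][1]
  minima <- localMinima(smoothed)
  lo <- minima[minima < apexIdx]
  hi <- minima[minima > apexIdx]
  vLo <- if (length(lo) > 0) max(lo) else 1L
  vHi <- if (length(hi) > 0) min(hi) else n
  new("PeakProfile", axis = axis, positions = grid, raw = raw,
      smoothed = smoothed, apex = grid[apexIdx], valleyLo = grid[vLo],
      valleyHi = grid[vHi],
      edgeApex = apexIdx == 1L || apexIdx == n)
}

#' Trim retention-time gaps around the main peak
#'
#' Starting from the frame nearest the profile's RT apex, frames are kept
#' while consecutive retained frames are at most `max_gap` seconds apart;
#' disconnected leading or trailing points (superfluous edges) are
#' dropped. The retained frame RTs therefore form a single chain
#' containing the apex with no gap above `max_gap`.
#'
#' @param points data.frame of raw points with an `rt` column.
#' @param profile the RT-axis [PeakProfile-class] (supplies the apex).
#' @param max_gap largest allowed frame-to-frame gap (default 1 s).
#' @return the retained subset of `points`.
#' @export
trimRtGaps <- function(points, profile, max_gap = 1.0) {
  stopifnot(is(profile, "PeakProfile"))
  if (nrow(points) == 0) return(points)
  rts <- sort(unique(points$rt))
  a <- which.min(abs(rts - profile@apex))
  lo <- a
  while (lo > 1 && rts[lo] - rts[lo - 1] <= max_gap) lo <- lo - 1
  hi <- a
  while (hi < length(rts) && rts[hi + 1] - rts[hi] <= max_gap) hi <- hi + 1
  points[points$rt >= rts[lo] & points$rt <= rts[hi], , drop = FALSE]
}
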