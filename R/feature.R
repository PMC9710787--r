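# Feature building: expand the characterized peak to the isotopic-envelope
# region, simplify to a 2-D spectrum by intensity descent, deconvolve
# charge and monoisotopic m/z against the averagine model, validate against
# the seeding voxel, and compute feature intensity and alignment
# coefficients.

#' Expand a peak's bounds to the full isotopic-envelope region
#'
#' The lower m/z edge is extended by 0.6 Th (one isotope for charge 2
#' plus margin — the seeding peak may be the base peak rather than the
#' monoisotopic peak) and the upper edge by 3 Th (up to six isotopes for
#' charge 2 plus margin). Scan and RT bounds are unchanged. Single-call
#' contract: the expansion is not idempotent.
#'
#' @param bounds list with at least `mz_lo` and `mz_hi`.
#' @param down,up extensions in Th.
#' @return `bounds` with the m/z edges moved.
#' @export
expandRegion <- function(bounds, down = 0.6, up = 3.0) {
  stopifnot(bounds$mz_lo < bounds$mz_hi)
  bounds$mz_lo <- bounds$mz_lo - down
  bounds$mz_hi <- bounds$mz_hi + up
  bounds
}

#' Simplify a 3-D point region to a 2-D spectrum by intensity descent
#'
#' Iteratively takes the most intense remaining point (ties broken by
#' lower m/z), groups all remaining points within the 3-sigma
#' resolution-derived m/z extent around it, emits one peak at the group's
#' intensity-weighted centroid with the summed intensity, removes the
#' group, and repeats until no points remain. Total intensity is
#' conserved exactly.
#'
#' @param points data.frame with `mz` and `intensity`.
#' @param resolution resolving power for the grouping window.
#' @return data.frame `(mz, intensity)` with strictly increasing m/z.
#' @export
intensityDescent <- function(points, resolution = 40000) {
  if (nrow(points) == 0)
    return(data.frame(mz = numeric(0), intensity = numeric(0)))
  ord <- order(points$mz)
  mz <- points$mz[ord]
  inten <- points$intensity[ord]
  alive <- rep(TRUE, length(mz))
  out_mz <- numeric(0); out_i <- numeric(0)
  while (any(alive)) {
    ai <- which(alive)
    seed <- ai[which.max(inten[ai])]  # which.max: first (lowest m/z) on ties
    halfw <- 3 * mzPeakSigma(mz[seed], resolution)
    grp <- ai[mz[ai] >= mz[seed] - halfw & mz[ai] <= mz[seed] + halfw]
    tot <- sum(inten[grp])
    out_mz <- c(out_mz, sum(mz[grp] * inten[grp]) / tot)
    out_i <- c(out_i, tot)
    alive[grp] <- FALSE
  }
  o <- order(out_mz)
  data.frame(mz = out_mz[o], intensity = out_i[o])
}

#' Resolve isotopic envelopes in a 2-D spectrum
#'
#' For every peak as a candidate monoisotopic peak and every charge in
#' `charge_range`, peaks are assembled at the expected spacings of
#' 1.003355/z Th (nearest peak within `match_ppm`, walking upward until
#' the first missing isotope). Candidates with at least `min_isotopes`
#' peaks are scored against the averagine prediction at the implied
#' neutral mass:
#' score = sum over matched peaks of sqrt(intensity) * w_mz * w_height,
#' where w_mz = 1 - |spacing error| / tolerance and w_height =
#' max(0, 1 - |observed fraction - predicted fraction|). Envelopes below
#' `score_threshold` are dropped; survivors are returned in descending
#' score order. An emitted envelope only ever references peaks present in
#' the input spectrum.
#'
#' @param spectrum data.frame `(mz, intensity)` as from
#'   [intensityDescent()].
#' @param charge_range integer charges to consider (default 1:4).
#' @param min_isotopes minimum envelope length (default 3).
#' @param match_ppm isotope m/z matching tolerance (default 10 ppm).
#' @param score_threshold minimum deconvolution score (default 20).
#' @param max_isotopes longest envelope assembled.
#' @return list of envelopes; each is a list with `mono_mz`, `charge`,
#'   `peaks` (data.frame mz, intensity), `score`, `base_peak_index`,
#'   `peak_rows` (row indices into `spectrum`).
#' @export
deconvolveSpectrum <- function(spectrum, charge_range = 1:4,
                               min_isotopes = 3L, match_ppm = 10,
                               score_threshold = 20, max_isotopes = 10L) {
  if (nrow(spectrum) == 0) return(list())
  envs <- list()
  seen <- character(0)
  for (seed in seq_len(nrow(spectrum))) {
    mono <- spectrum$mz[seed]
    for (z in charge_range) {
      rows <- seed
      k <- 1L
      while (length(rows) < max_isotopes) {
        expect <- mono + k * .ISOTOPE_DELTA / z
        tol <- match_ppm * 1e-6 * expect
        d <- abs(spectrum$mz - expect)
        hit <- which(d <= tol)
        if (length(hit) == 0) break
        rows <- c(rows, hit[which.min(d[hit])])
        k <- k + 1L
      }
      if (length(rows) < min_isotopes) next
      key <- paste(z, paste(rows, collapse = ","))
      if (key %in% seen) next
      seen <- c(seen, key)
      obs <- spectrum$intensity[rows]
      neutral <- mono * z - z * .PROTON_MASS
      if (neutral <= 0) next
      pred <- averagineEnvelope(neutral, length(rows))
      obs_frac <- obs / sum(obs)
      spacing_err <- abs(ppmError(
        spectrum$mz[rows],
        mono + (seq_along(rows) - 1) * .ISOTOPE_DELTA / z))
      w_mz <- pmax(0, 1 - spacing_err / match_ppm)
      w_h <- pmax(0, 1 - abs(obs_frac - pred))
      score <- sum(sqrt(obs) * w_mz * w_h)
      if (score <= score_threshold) next
      envs[[length(envs) + 1]] <- list(
        mono_mz = mono, charge = as.integer(z),
        peaks = data.frame(mz = spectrum$mz[rows], intensity = obs),
        score = score, base_peak_index = which.max(obs),
        peak_rows = rows)
    }
  }
  if (length(envs) == 0) return(envs)
  envs[order(-vapply(envs, `[[`, 0, "score"))]
}

#' Accept or reject an envelope against the seeding voxel
#'
#' A deconvolved envelope is accepted only when its monoisotopic peak or
#' its base peak matches the voxel's m/z centroid within tolerance —
#' this ensures the feature is actually formed from the voxel's peak.
#'
#' @param envelope an envelope from [deconvolveSpectrum()].
#' @param voxel_centroid_mz the seeding voxel's intensity-weighted
#'   centroid (Th).
#' @param tolerance_ppm matching tolerance (default 10 ppm of the
#'   centroid).
#' @return TRUE or FALSE.
#' @export
validateCandidate <- function(envelope, voxel_centroid_mz,
                              tolerance_ppm = 10) {
  stopifnot(nrow(envelope$peaks) >= 1)
  tol <- tolerance_ppm * 1e-6 * voxel_centroid_mz
  base_mz <- envelope$peaks$mz[envelope$base_peak_index]
  abs(envelope$mono_mz - voxel_centroid_mz) <= tol ||
    abs(base_mz - voxel_centroid_mz) <= tol
}

#' Feature intensity from the frames around the RT apex
#'
#' For each isotopic peak, the intensity is the mean over the three
#' frames nearest the RT apex (inclusive of the apex frame) of that
#' frame's maximum point intensity within the peak's 3-sigma m/z extent;
#' a frame with no point in the extent contributes zero. The feature
#' intensity is the sum over the first three isotopic peaks (fewer when
#' the envelope is shorter). A saturation-correction hook is applied per
#' point before the maximum is taken; the default is the identity (no
#' correction) — detector-specific models can be plugged in.
#'
#' @param envelope an envelope from [deconvolveSpectrum()].
#' @param points data.frame of the feature region's raw points.
#' @param rt_apex the feature's RT apex (seconds).
#' @param resolution resolving power for the per-isotope m/z extents.
#' @param saturation per-point intensity correction function.
#' @param n_frames,n_peaks number of frames averaged and isotopes summed.
#' @return feature intensity in counts.
#' @export
featureIntensity <- function(envelope, points, rt_apex,
                             resolution = 40000, saturation = identity,
                             n_frames = 3L, n_peaks = 3L) {
  if (nrow(points) == 0 || nrow(envelope$peaks) == 0)
    tdStop("no points near the RT apex", "degenerateInput")
  rts <- sort(unique(points$rt))
  frames <- rts[order(abs(rts - rt_apex))][seq_len(min(n_frames, length(rts)))]
  corrected <- saturation(points$intensity)
  total <- 0
  for (i in seq_len(min(n_peaks, nrow(envelope$peaks)))) {
    ext <- mzExtent(envelope$peaks$mz[i], resolution)
    per_frame <- vapply(frames, function(f) {
      sel <- points$rt == f & points$mz >= ext[1] & points$mz <= ext[2]
      if (any(sel)) max(corrected[sel]) else 0
    }, 0)
    total <- total + mean(per_frame)
  }
  total
}

#' Coelution and mobility alignment coefficients
#'
#' Each isotope's intensity profile over frames (retention time) and over
#' scans (mobility) is built on the common grid of the feature region;
#' the coefficients are the mean cosine similarity between each higher
#' isotope's profile and the monoisotopic profile, in RT and in mobility
#' respectively. Isotopes with an all-zero profile are excluded from the
#' mean. Values lie in [-1, 1] (non-negative in practice, intensities
#' being non-negative).
#'
#' @param envelope an envelope from [deconvolveSpectrum()].
#' @param points data.frame of the feature region's raw points.
#' @param resolution resolving power for the per-isotope m/z extents.
#' @return named numeric `c(coelution, mobility)`.
#' @export
alignmentCoefficients <- function(envelope, points, resolution = 40000) {
  if (nrow(envelope$peaks) < 2)
    tdStop("alignment needs an envelope with >= 2 isotopes", "degenerateInput")
  rt_grid <- sort(unique(points$rt))
  scan_grid <- sort(unique(points$scan))
  profiles <- lapply(seq_len(nrow(envelope$peaks)), function(i) {
    ext <- mzExtent(envelope$peaks$mz[i], resolution)
    sel <- points$mz >= ext[1] & points$mz <= ext[2]
    rt_prof <- numeric(length(rt_grid))
    sc_prof <- numeric(length(scan_grid))
    if (any(sel)) {
      s <- rowsum(points$intensity[sel], match(points$rt[sel], rt_grid))
      rt_prof[as.integer(rownames(s))] <- s[, 1]
      s <- rowsum(points$intensity[sel], match(points$scan[sel], scan_grid))
      sc_prof[as.integer(rownames(s))] <- s[, 1]
    }
    list(rt = rt_prof, scan = sc_prof)
  })
  ref <- profiles[[1]]
  co <- mob <- numeric(0)
  for (i in seq_along(profiles)[-1]) {
    s <- cosineSimilarity(ref$rt, profiles[[i]]$rt)
    if (!is.na(s)) co <- c(co, s)
    s <- cosineSimilarity(ref$scan, profiles[[i]]$scan)
    if (!is.na(s)) mob <- c(mob, s)
  }
  if (length(co) == 0 || length(mob) == 0)
    tdStop("all higher isotopes have zero profiles", "degenerateInput")
  c(coelution = mean(co), mobility = mean(mob))
}
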