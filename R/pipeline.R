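# End-to-end detection workflow: voxel ranking -> per-band queue
# consumption -> peak profiling -> region expansion -> intensity descent
# -> deconvolution -> validation -> intensity/alignment -> retirement ->
# classification -> de-duplication. Plus the isolation-window filter.

#' Detector configuration
#'
#' All tunable parameters of the detection pipeline with their defaults.
#' `min_voxel_intensity` has no instrument-independent default — it is
#' the depth-versus-runtime knob (lower values process more voxels and
#' detect more, mostly lower-intensity, features) and must be chosen for
#' the data at hand.
#'
#' @param min_voxel_intensity stopping threshold on mean voxel intensity
#'   (counts); required.
#' @param voxel_mz_width,voxel_scan_span,voxel_rt_span voxel grid
#'   dimensions (0.1 Th, 10 scans, 5 s).
#' @param band_width m/z band width for worker scheduling (10 Th).
#' @param resolution instrument resolving power (40,000).
#' @param mobility_half_window half-window for mobility profiling
#'   (40 scans = twice the mean mobility peak width).
#' @param rt_half_window half-window for RT profiling (13.2 s = twice the
#'   mean base RT peak width of 6.6 s).
#' @param savgol_window,savgol_order Savitzky-Golay smoothing parameters.
#' @param rt_max_gap largest frame gap kept around the RT peak (1 s).
#' @param expand_down,expand_up m/z region expansion (0.6 / 3.0 Th).
#' @param charge_min,charge_max deconvolution charge search range (1-4).
#' @param min_isotopes minimum envelope length (3).
#' @param score_threshold minimum deconvolution score (20).
#' @param match_ppm isotope-spacing match tolerance (10 ppm).
#' @param validate_ppm mono-or-base centroid match tolerance (10 ppm).
#' @param identifiability_threshold classifier filter threshold (0.2).
#' @param dedup_ppm,dedup_scans,dedup_rt de-duplication tolerances
#'   (10 ppm, 20 scans, 5 s).
#' @param saturation per-point saturation-correction hook (identity by
#'   default; plug in a detector model as `function(intensity) ...`).
#' @param worker_count number of band workers the schedule is split
#'   across; results are identical for any value (bands are independent
#'   and the post-pass de-duplication resolves cross-band duplicates).
#' @param seed RNG seed carried into classifier training when used.
#' @param verbose emit per-stage progress messages.
#' @return a classed config list.
#' @export
detectorConfig <- function(min_voxel_intensity,
                           voxel_mz_width = 0.1, voxel_scan_span = 10L,
                           voxel_rt_span = 5.0, band_width = 10,
                           resolution = 40000,
                           mobility_half_window = 40,
                           rt_half_window = 13.2,
                           savgol_window = 11L, savgol_order = 3L,
                           rt_max_gap = 1.0,
                           expand_down = 0.6, expand_up = 3.0,
                           charge_min = 1L, charge_max = 4L,
                           min_isotopes = 3L, score_threshold = 20,
                           match_ppm = 10, validate_ppm = 10,
                           identifiability_threshold = 0.2,
                           dedup_ppm = 10, dedup_scans = 20, dedup_rt = 5,
                           saturation = identity,
                           worker_count = 1L, seed = 1L,
                           verbose = FALSE) {
  if (missing(min_voxel_intensity))
    tdStop("min_voxel_intensity is required", "configError")
  cfg <- as.list(environment())
  structure(cfg, class = "timsDetectorConfig")
}

# Fast region query against a cloud pre-sorted by m/z.
makeRegionQuery <- function(points) {
  ord <- order(points$mz)
  mzs <- points$mz[ord]
  function(mz_lo, mz_hi, scan_lo = -Inf, scan_hi = Inf,
           rt_lo = -Inf, rt_hi = Inf) {
    i <- findInterval(c(mz_lo, mz_hi), mzs)
    lo <- if (i[1] > 0 && mzs[i[1]] >= mz_lo) i[1] else i[1] + 1
    if (lo > i[2]) return(integer(0))
    rows <- ord[lo:i[2]]
    rows[points$scan[rows] >= scan_lo & points$scan[rows] <= scan_hi &
           points$rt[rows] >= rt_lo & points$rt[rows] <= rt_hi]
  }
}

# Process a single voxel; returns a one-row feature data.frame with a
# point-refs attribute, or NULL when the voxel yields no feature.
processVoxel <- function(vox, pts, query, frame_rt, scanInvK0, cfg) {
  vpts_idx <- query(vox$mz_lo, vox$mz_hi, vox$scan_lo, vox$scan_hi,
                    vox$rt_lo, vox$rt_hi)
  if (length(vpts_idx) == 0) return(NULL)
  vpts <- pts[vpts_idx, ]
  centroid <- mzCentroid(vpts)
  ext <- mzExtent(centroid, cfg$resolution)
  scan_mid <- (vox$scan_lo + vox$scan_hi) / 2
  rt_mid <- (vox$rt_lo + vox$rt_hi) / 2
  mob_idx <- query(ext[1], ext[2], scan_mid - cfg$mobility_half_window,
                   scan_mid + cfg$mobility_half_window,
                   vox$rt_lo, vox$rt_hi)
  mob <- profileExtent(pts[mob_idx, ], "mobility", midpoint = scan_mid,
                       half_window = cfg$mobility_half_window,
                       savgol_window = cfg$savgol_window,
                       savgol_order = cfg$savgol_order)
  rt_idx <- query(ext[1], ext[2], mob@valleyLo, mob@valleyHi,
                  rt_mid - cfg$rt_half_window, rt_mid + cfg$rt_half_window)
  rtp <- profileExtent(pts[rt_idx, ], "rt", midpoint = rt_mid,
                       half_window = cfg$rt_half_window, grid = frame_rt,
                       savgol_window = cfg$savgol_window,
                       savgol_order = cfg$savgol_order)
  rt_pts <- pts[rt_idx, ]
  rt_pts <- rt_pts[rt_pts$rt >= rtp@valleyLo & rt_pts$rt <= rtp@valleyHi, ]
  rt_pts <- trimRtGaps(rt_pts, rtp, cfg$rt_max_gap)
  if (nrow(rt_pts) == 0) return(NULL)
  bounds <- list(mz_lo = ext[1], mz_hi = ext[2],
                 scan_lo = mob@valleyLo, scan_hi = mob@valleyHi,
                 rt_lo = min(rt_pts$rt), rt_hi = max(rt_pts$rt))
  bounds <- expandRegion(bounds, cfg$expand_down, cfg$expand_up)
  region_idx <- query(bounds$mz_lo, bounds$mz_hi, bounds$scan_lo,
                      bounds$scan_hi, bounds$rt_lo, bounds$rt_hi)
  region <- pts[region_idx, ]
  spectrum <- intensityDescent(region, cfg$resolution)
  envs <- deconvolveSpectrum(spectrum,
                             charge_range = cfg$charge_min:cfg$charge_max,
                             min_isotopes = cfg$min_isotopes,
                             match_ppm = cfg$match_ppm,
                             score_threshold = cfg$score_threshold)
  env <- NULL
  for (e in envs) {
    if (validateCandidate(e, centroid, cfg$validate_ppm)) { env <- e; break }
  }
  if (is.null(env)) return(NULL)
  # points belonging to the envelope's isotopic peaks, for intensity,
  # alignment and voxel retirement
  fsel <- rep(FALSE, nrow(region))
  for (i in seq_len(nrow(env$peaks))) {
    pe <- mzExtent(env$peaks$mz[i], cfg$resolution)
    fsel <- fsel | (region$mz >= pe[1] & region$mz <= pe[2])
  }
  fpts <- region[fsel, ]
  inten <- featureIntensity(env, fpts, rtp@apex,
                            resolution = cfg$resolution,
                            saturation = cfg$saturation)
  coef <- tryCatch(alignmentCoefficients(env, fpts, cfg$resolution),
                   timsDescentError = function(e)
                     c(coelution = NA_real_, mobility = NA_real_))
  feat <- data.frame(
    mono_mz = env$mono_mz, charge = env$charge, intensity = inten,
    rt_apex = rtp@apex, rt_lo = bounds$rt_lo, rt_hi = bounds$rt_hi,
    scan_apex = mob@apex, scan_lo = mob@valleyLo, scan_hi = mob@valleyHi,
    num_isotopes = nrow(env$peaks), deconvolution_score = env$score,
    coelution_coefficient = coef[["coelution"]],
    mobility_coefficient = coef[["mobility"]],
    identifiability_score = NA_real_,
    inv_k0_apex = scanInvK0(mob@apex))
  attr(feat, "pointRefs") <- region_idx[fsel]
  feat
}

#' Detect precursor features in a point cloud
#'
#' Runs the full detection workflow: the cloud is voxelized and ranked,
#' voxels are consumed per m/z band in descending mean-intensity order,
#' each seeding voxel is profiled (m/z centroid and 3-sigma extent,
#' mobility and RT apex/valley extents, RT gap trimming), expanded to the
#' isotopic-envelope region, simplified to a 2-D spectrum by intensity
#' descent and deconvolved; validated envelopes become features with
#' intensity (sum of the first three isotopes around the RT apex) and
#' alignment coefficients, and voxels dominated by an accepted feature
#' are retired. If a trained classifier is supplied, features are scored
#' and filtered at the identifiability threshold; finally nearby
#' duplicate detections are removed. Deterministic for a fixed config;
#' `worker_count` only partitions the band schedule and does not change
#' the result.
#'
#' @param cloud a [PointCloud-class].
#' @param config a [detectorConfig()].
#' @param classifier optional trained classifier; when NULL, features are
#'   left unscored and the identifiability filter is skipped.
#' @return a [FeatureSet-class]; per-stage counts are attached as
#'   `attr(x, "counts")`.
#' @export
detectFeatures <- function(cloud, config, classifier = NULL) {
  stopifnot(is(cloud, "PointCloud"), is(config, "timsDetectorConfig"))
  pts <- ionData(cloud)
  counts <- list(points = nrow(pts))
  if (nrow(pts) == 0) return(FeatureSet())
  index <- buildVoxelIndex(cloud, config$min_voxel_intensity,
                           mz_width = config$voxel_mz_width,
                           scan_span = config$voxel_scan_span,
                           rt_span = config$voxel_rt_span)
  bands <- partitionBands(index, config$band_width)
  query <- makeRegionQuery(pts)
  frame_rt <- unname(frameTimes(cloud))
  # scan -> 1/K0 lookup from the observed readings (per-frame maps are
  # assumed consistent across frames, as on the instrument)
  sc <- sort(unique(pts$scan))
  k0 <- vapply(split(pts$inv_k0, match(pts$scan, sc)), stats::median, 0)
  scanInvK0 <- function(scan) {
    if (length(sc) == 1) return(k0[[1]])
    stats::approx(sc, k0, xout = scan, rule = 2)$y
  }
  feats <- list()
  nproc <- 0L; nskip <- 0L
  # Bands are assigned to workers round-robin and each worker's bands are
  # processed in turn. Bands are fully independent (they schedule voxels;
  # feature building reads the global cloud, and retirement only affects
  # the band's own queue), and the output is canonically sorted, so the
  # schedule split cannot change the result.
  workers <- split(seq_along(bands),
                   (seq_along(bands) - 1L) %% max(1L, config$worker_count))
  for (wk in workers) {
    for (band_ids in bands[wk]) {
      repeat {
        vox <- nextVoxel(index, band_ids)
        if (is.null(vox)) break
        nproc <- nproc + 1L
        feat <- tryCatch(
          processVoxel(vox, pts, query, frame_rt, scanInvK0, config),
          timsDescentError = function(e) NULL)
        if (is.null(feat)) { nskip <- nskip + 1L; next }
        feats[[length(feats) + 1]] <- feat
        retireVoxels(index, attr(feat, "pointRefs"), ids = band_ids)
      }
    }
  }
  counts$voxels_processed <- nproc
  counts$voxels_skipped <- nskip
  counts$features_raw <- length(feats)
  fs <- if (length(feats) == 0) FeatureSet() else {
    f <- do.call(rbind, feats)
    FeatureSet(f[order(f$mono_mz, f$rt_apex, f$scan_apex,
                       f$charge), , drop = FALSE])
  }
  if (!is.null(classifier)) {
    fs <- classifyAndFilter(fs, classifier,
                            config$identifiability_threshold)
    counts$features_classified <- length(fs)
  }
  fs <- deduplicateFeatures(fs, config$dedup_ppm, config$dedup_scans,
                            config$dedup_rt)
  counts$features_final <- length(fs)
  if (isTRUE(config$verbose))
    message(sprintf(
      "processed %d voxels (%d yielded no feature); %d raw -> %d final features",
      nproc, nskip, counts$features_raw, counts$features_final))
  attr(fs, "counts") <- counts
  fs
}

#' Filter features by isolation-window membership
#'
#' Retains features whose monoisotopic-peak apex — (mono m/z, scan apex,
#' RT apex) — lies inside at least one isolation window (closed bounds
#' on every axis).
#'
#' @param features a [FeatureSet-class].
#' @param windows data.frame of windows with columns `mz_lo`, `mz_hi`,
#'   `scan_lo`, `scan_hi`, `rt_lo`, `rt_hi` (see
#'   [readIsolationWindows()]).
#' @return the filtered [FeatureSet-class].
#' @export
filterByWindows <- function(features, windows) {
  stopifnot(is(features, "FeatureSet"))
  f <- featureTable(features)
  if (nrow(f) == 0 || nrow(windows) == 0)
    return(FeatureSet(f[integer(0), , drop = FALSE]))
  inside <- rep(FALSE, nrow(f))
  for (w in seq_len(nrow(windows))) {
    inside <- inside |
      (f$mono_mz >= windows$mz_lo[w] & f$mono_mz <= windows$mz_hi[w] &
         f$scan_apex >= windows$scan_lo[w] &
         f$scan_apex <= windows$scan_hi[w] &
         f$rt_apex >= windows$rt_lo[w] & f$rt_apex <= windows$rt_hi[w])
  }
  FeatureSet(f[inside, , drop = FALSE])
}
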