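# Voxel work queue: fixed-size 3-D bins over (m/z, scan, rt), ranked by
# mean point intensity and consumed in descending order until the mean
# intensity falls below the configured stopping threshold.

#' Build the ranked voxel index of a point cloud
#'
#' Partitions the cloud into voxels of fixed dimensions (0.1 Th in m/z,
#' 10 scans in mobility, 5 s in retention time by default), half-open bins
#' anchored at coordinate 0. Every point is assigned to exactly one voxel.
#' Non-empty voxels are ranked in descending order of mean point
#' intensity, ties broken by (mz_bin, scan_bin, rt_bin); voxels whose
#' mean intensity is below `min_voxel_intensity` are excluded from the
#' work queue (but retained in the table for neighbourhood reads). The
#' stopping threshold is deliberately config-required: it is the
#' depth-versus-runtime knob of the detector.
#'
#' @param cloud a [PointCloud-class].
#' @param min_voxel_intensity stopping threshold on mean voxel intensity
#'   (counts).
#' @param mz_width,scan_span,rt_span voxel dimensions.
#' @return a [VoxelIndex-class].
#' @export
buildVoxelIndex <- function(cloud, min_voxel_intensity,
                            mz_width = 0.1, scan_span = 10L, rt_span = 5.0) {
  stopifnot(is(cloud, "PointCloud"))
  if (missing(min_voxel_intensity) || !is.numeric(min_voxel_intensity))
    tdStop("min_voxel_intensity is required (no instrument-independent default)",
           "configError")
  p <- ionData(cloud)
  mzb <- binIndex(p$mz, mz_width)
  scb <- p$scan %/% as.integer(scan_span)
  rtb <- binIndex(p$rt, rt_span)
  key <- paste(mzb, scb, rtb)
  grp <- match(key, unique(key))
  if (nrow(p) == 0) {
    vox <- data.frame(mz_bin = integer(0), scan_bin = integer(0),
                      rt_bin = integer(0), mz_lo = numeric(0),
                      mz_hi = numeric(0), scan_lo = integer(0),
                      scan_hi = integer(0), rt_lo = numeric(0),
                      rt_hi = numeric(0), n_points = integer(0),
                      total_intensity = numeric(0),
                      mean_intensity = numeric(0), queued = logical(0))
    q <- new.env(parent = emptyenv()); q$state <- integer(0)
    return(new("VoxelIndex", voxels = vox, pointVoxel = integer(0),
               minVoxelIntensity = min_voxel_intensity,
               grid = list(mz_width = mz_width,
                           scan_span = as.integer(scan_span),
                           rt_span = rt_span), queue = q))
  }
  first <- !duplicated(grp)
  n <- tabulate(grp)
  tot <- as.numeric(rowsum(p$intensity, grp))
  vox <- data.frame(
    mz_bin = mzb[first], scan_bin = scb[first], rt_bin = rtb[first],
    n_points = n, total_intensity = tot, mean_intensity = tot / n)
  ord <- order(-vox$mean_intensity, vox$mz_bin, vox$scan_bin, vox$rt_bin)
  vox <- vox[ord, ]
  rownames(vox) <- NULL
  vox$mz_lo <- vox$mz_bin * mz_width
  vox$mz_hi <- (vox$mz_bin + 1) * mz_width
  vox$scan_lo <- vox$scan_bin * as.integer(scan_span)
  vox$scan_hi <- (vox$scan_bin + 1L) * as.integer(scan_span) - 1L
  vox$rt_lo <- vox$rt_bin * rt_span
  vox$rt_hi <- (vox$rt_bin + 1) * rt_span
  vox$queued <- vox$mean_intensity >= min_voxel_intensity
  vox <- vox[, c("mz_bin", "scan_bin", "rt_bin", "mz_lo", "mz_hi",
                 "scan_lo", "scan_hi", "rt_lo", "rt_hi", "n_points",
                 "total_intensity", "mean_intensity", "queued")]
  # map each point's original group id to its rank position
  rankOfGroup <- integer(nrow(vox)); rankOfGroup[ord] <- seq_len(nrow(vox))
  pointVoxel <- rankOfGroup[grp]
  q <- new.env(parent = emptyenv())
  q$state <- integer(nrow(vox))  # 0 pending, 1 processed, 2 retired
  q$pointIntensity <- p$intensity  # used by retireVoxels
  new("VoxelIndex", voxels = vox, pointVoxel = as.integer(pointVoxel),
      minVoxelIntensity = min_voxel_intensity,
      grid = list(mz_width = mz_width, scan_span = as.integer(scan_span),
                  rt_span = rt_span),
      queue = q)
}

#' Partition the voxel index into m/z bands
#'
#' Bands of `band_width` Th through retention time and mobility are the
#' unit of worker parallelism: each worker processes the voxels of one
#' band. Bands are disjoint and cover the m/z range; within a band the
#' global descending mean-intensity order is preserved. Bands schedule
#' voxels only — feature building always reads the full point cloud, so a
#' feature whose envelope crosses a band edge is unaffected.
#'
#' @param index a [VoxelIndex-class].
#' @param band_width band width in Th (default 10).
#' @return named list mapping band id (floor(mz / band_width)) to the
#'   integer voxel ids of the band, in ranking order.
#' @export
partitionBands <- function(index, band_width = 10) {
  stopifnot(is(index, "VoxelIndex"))
  if (band_width <= 0) tdStop("band_width must be > 0", "configError")
  v <- index@voxels
  if (nrow(v) == 0) return(list())
  band <- floor(v$mz_lo / band_width + 1e-9)
  ids <- split(seq_len(nrow(v)), band)
  ids[order(as.numeric(names(ids)))]
}

#' @rdname nextVoxel
#' @export
setMethod("nextVoxel", "VoxelIndex", function(index, ids = NULL) {
  v <- index@voxels
  st <- index@queue$state
  if (is.null(ids)) ids <- seq_len(nrow(v))
  cand <- ids[st[ids] == 0L & v$queued[ids] &
                v$mean_intensity[ids] >= index@minVoxelIntensity]
  if (length(cand) == 0) return(NULL)
  id <- cand[1]  # ids are in ranking order
  index@queue$state[id] <- 1L
  out <- v[id, , drop = FALSE]
  out$voxel_id <- id
  out
})

#' @rdname retireVoxels
#' @export
setMethod("retireVoxels", "VoxelIndex", function(index, pointRefs,
                                                 fraction = 0.8,
                                                 ids = NULL) {
  if (length(pointRefs) == 0) return(integer(0))
  pv <- index@pointVoxel[pointRefs]
  contrib <- rowsum(index@queue$pointIntensity[pointRefs], pv)
  vid <- as.integer(rownames(contrib))
  share <- contrib[, 1] / index@voxels$total_intensity[vid]
  retired <- vid[share > fraction]
  if (!is.null(ids)) retired <- intersect(retired, ids)
  index@queue$state[retired] <- 2L
  retired
})
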