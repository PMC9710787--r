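# Accessors and show methods for the core classes.

#' @rdname ionData
#' @export
setMethod("ionData", "PointCloud", function(x) x@points)

#' @describeIn PointCloud number of points.
#' @param x a PointCloud.
#' @export
setMethod("length", "PointCloud", function(x) nrow(x@points))

#' @rdname frameTimes
#' @export
setMethod("frameTimes", "PointCloud", function(x) {
  fr <- unique(x@points[, c("frame_id", "rt")])
  fr <- fr[order(fr$frame_id), ]
  stats::setNames(fr$rt, fr$frame_id)
})

setMethod("show", "PointCloud", function(object) {
  p <- object@points
  cat("PointCloud with", nrow(p), "points in", length(unique(p$frame_id)),
      "frames\n")
  if (nrow(p) > 0) {
    cat(sprintf("  m/z:  %.4f - %.4f Th\n", min(p$mz), max(p$mz)))
    cat(sprintf("  scan: %d - %d\n", min(p$scan), max(p$scan)))
    cat(sprintf("  rt:   %.2f - %.2f s\n", min(p$rt), max(p$rt)))
    cat(sprintf("  total intensity: %.4g\n", sum(p$intensity)))
  }
})

#' @rdname featureTable
#' @export
setMethod("featureTable", "FeatureSet", function(x) x@features)

#' @describeIn FeatureSet number of features.
#' @param x a FeatureSet.
#' @export
setMethod("length", "FeatureSet", function(x) nrow(x@features))

setMethod("show", "FeatureSet", function(object) {
  f <- object@features
  cat("FeatureSet with", nrow(f), "features\n")
  if (nrow(f) > 0) {
    cat("  charge states:",
        paste(sprintf("%d+ (%d)", sort(unique(f$charge)),
                      tabulate(factor(f$charge))[order(unique(f$charge))]),
              collapse = ", "), "\n")
    cat(sprintf("  m/z: %.4f - %.4f Th; rt: %.1f - %.1f s\n",
                min(f$mono_mz), max(f$mono_mz),
                min(f$rt_apex), max(f$rt_apex)))
    nsc <- sum(!is.na(f$identifiability_score))
    cat("  identifiability scored:", nsc, "of", nrow(f), "\n")
  }
})

#' @rdname voxelTable
#' @export
setMethod("voxelTable", "VoxelIndex", function(x) {
  v <- x@voxels
  v$state <- c("pending", "processed", "retired")[x@queue$state + 1L]
  v
})

setMethod("show", "VoxelIndex", function(object) {
  v <- object@voxels
  st <- object@queue$state
  cat("VoxelIndex with", nrow(v), "non-empty voxels (",
      sum(v$queued), "queued )\n")
  cat(sprintf("  grid: %.2g Th x %d scans x %.3g s; min voxel intensity %.4g\n",
              object@grid$mz_width, object@grid$scan_span,
              object@grid$rt_span, object@minVoxelIntensity))
  cat("  pending:", sum(st == 0L & v$queued), " processed:", sum(st == 1L),
      " retired:", sum(st == 2L), "\n")
})

setMethod("show", "PeakProfile", function(object) {
  cat(sprintf("PeakProfile (%s): %d positions, apex %.3f in [%.3f, %.3f]%s\n",
              object@axis, length(object@positions), object@apex,
              object@valleyLo, object@valleyHi,
              if (object@edgeApex) " [edge apex]" else ""))
})
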