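#' @import methods
NULL

.POINT_COLUMNS <- c("frame_id", "rt", "scan", "inv_k0", "mz", "intensity")

.FEATURE_COLUMNS <- c(
  "mono_mz", "charge", "intensity",
  "rt_apex", "rt_lo", "rt_hi",
  "scan_apex", "scan_lo", "scan_hi",
  "num_isotopes", "deconvolution_score",
  "coelution_coefficient", "mobility_coefficient",
  "identifiability_score", "inv_k0_apex"
)

#' PointCloud: a 4-D MS1 ion point cloud
#'
#' One row per detector reading: MS1 frame id, retention time (seconds),
#' mobility scan index, 1/K0 mobility value, m/z (Th) and intensity (counts).
#' Rows are stored sorted by frame, scan and m/z. Within one frame the
#' 1/K0 value decreases with increasing scan index (the timsTOF convention:
#' lower scan, higher 1/K0).
#'
#' @slot points a data.frame with columns `frame_id`, `rt`, `scan`,
#'   `inv_k0`, `mz`, `intensity`.
#' @seealso [PointCloud()], [readPointCloud()], [ionData()]
#' @export
setClass("PointCloud", representation(points = "data.frame"))

setValidity("PointCloud", function(object) {
  p <- object@points
  miss <- setdiff(.POINT_COLUMNS, names(p))
  if (length(miss) > 0)
    return(paste0("missing column(s): ", paste(miss, collapse = ", ")))
  for (col in .POINT_COLUMNS)
    if (!is.numeric(p[[col]]))
      return(paste0("column '", col, "' must be numeric"))
  if (nrow(p) == 0) return(TRUE)
  if (any(p$intensity < 0)) return("intensity must be >= 0")
  if (any(p$mz <= 0)) return("mz must be > 0")
  if (any(p$rt < 0)) return("rt must be >= 0")
  if (any(p$scan < 0)) return("scan must be >= 0")
  fr <- unique(p[, c("frame_id", "rt")])
  if (anyDuplicated(fr$frame_id))
    return("a frame_id maps to more than one rt")
  fr <- fr[order(fr$frame_id), ]
  if (is.unsorted(fr$rt, strictly = TRUE))
    return("frame_id -> rt mapping must be strictly increasing")
  TRUE
})

#' Construct a PointCloud
#'
#' @param points data.frame (or coercible) with the six point columns.
#' @return a validated [PointCloud-class] object with canonically ordered
#'   rows.
#' @export
PointCloud <- function(points) {
  points <- as.data.frame(points)
  miss <- setdiff(.POINT_COLUMNS, names(points))
  if (length(miss) > 0)
    tdStop(paste0("point table is missing column(s): ",
                  paste(miss, collapse = ", ")), "schemaError")
  points <- points[, .POINT_COLUMNS, drop = FALSE]
  points$frame_id <- as.integer(points$frame_id)
  points$scan <- as.integer(points$scan)
  ord <- order(points$frame_id, points$scan, points$mz)
  points <- points[ord, , drop = FALSE]
  rownames(points) <- NULL
  new("PointCloud", points = points)
}

#' FeatureSet: a table of detected precursor features
#'
#' One row per detected feature with its monoisotopic m/z, charge state,
#' intensity (sum of the first three isotopic peak intensities), apex and
#' extent in retention time and mobility, number of isotopes, deconvolution
#' score, coelution and mobility alignment coefficients, identifiability
#' score (NA until classified) and the 1/K0 value at the mobility apex.
#'
#' @slot features a data.frame with the columns listed above.
#' @seealso [FeatureSet()], [featureTable()], [writeFeatureTable()]
#' @export
setClass("FeatureSet", representation(features = "data.frame"))

setValidity("FeatureSet", function(object) {
  f <- object@features
  miss <- setdiff(.FEATURE_COLUMNS, names(f))
  if (length(miss) > 0)
    return(paste0("missing column(s): ", paste(miss, collapse = ", ")))
  if (nrow(f) == 0) return(TRUE)
  if (any(f$charge < 1)) return("charge must be >= 1")
  if (any(f$num_isotopes < 1)) return("num_isotopes must be >= 1")
  if (any(f$intensity < 0)) return("intensity must be >= 0")
  if (any(f$rt_lo > f$rt_apex | f$rt_apex > f$rt_hi))
    return("rt_lo <= rt_apex <= rt_hi violated")
  if (any(f$scan_lo > f$scan_apex | f$scan_apex > f$scan_hi))
    return("scan_lo <= scan_apex <= scan_hi violated")
  sc <- f$identifiability_score
  if (any(!is.na(sc) & (sc < 0 | sc > 1)))
    return("identifiability_score must be in [0, 1]")
  TRUE
})

#' Construct a FeatureSet
#'
#' @param features data.frame of feature rows; the `identifiability_score`
#'   and `inv_k0_apex` columns are added (as NA) when absent.
#' @return a validated [FeatureSet-class].
#' @export
FeatureSet <- function(features = emptyFeatureTable()) {
  features <- as.data.frame(features)
  if (is.null(features$identifiability_score))
    features$identifiability_score <- NA_real_
  if (is.null(features$inv_k0_apex))
    features$inv_k0_apex <- NA_real_
  miss <- setdiff(.FEATURE_COLUMNS, names(features))
  if (length(miss) > 0)
    tdStop(paste0("feature table is missing column(s): ",
                  paste(miss, collapse = ", ")), "schemaError")
  features <- features[, .FEATURE_COLUMNS, drop = FALSE]
  features$charge <- as.integer(features$charge)
  features$num_isotopes <- as.integer(features$num_isotopes)
  rownames(features) <- NULL
  new("FeatureSet", features = features)
}

emptyFeatureTable <- function() {
  f <- data.frame(
    mono_mz = numeric(0), charge = integer(0), intensity = numeric(0),
    rt_apex = numeric(0), rt_lo = numeric(0), rt_hi = numeric(0),
    scan_apex = numeric(0), scan_lo = numeric(0), scan_hi = numeric(0),
    num_isotopes = integer(0), deconvolution_score = numeric(0),
    coelution_coefficient = numeric(0), mobility_coefficient = numeric(0),
    identifiability_score = numeric(0), inv_k0_apex = numeric(0)
  )
  f
}

#' PeakProfile: a 1-D intensity profile with apex and valleys
#'
#' A voxel's candidate peak flattened to one axis (mobility scans or
#' retention time): per-position summed raw intensities, the
#' Savitzky-Golay smoothed series, the apex chosen nearest the window
#' midpoint, and the valleys on either side that bound the peak's extent.
#'
#' @slot axis `"mobility"` or `"rt"`.
#' @slot positions ordered axis coordinates (scan indices or frame RTs).
#' @slot raw per-position summed intensities.
#' @slot smoothed smoothed series (same length as `raw`).
#' @slot apex axis coordinate of the selected apex.
#' @slot valleyLo,valleyHi axis coordinates bounding the peak.
#' @slot edgeApex TRUE when the apex sits on the window edge
#'   (low-confidence peak).
#' @export
setClass("PeakProfile", representation(
  axis = "character", positions = "numeric", raw = "numeric",
  smoothed = "numeric", apex = "numeric", valleyLo = "numeric",
  valleyHi = "numeric", edgeApex = "logical"
))

setValidity("PeakProfile", function(object) {
  if (length(object@smoothed) != length(object@raw))
    return("smoothed series must have the same length as the raw series")
  if (object@valleyLo > object@apex || object@apex > object@valleyHi)
    return("valleyLo <= apex <= valleyHi violated")
  TRUE
})

#' VoxelIndex: the ranked voxel work queue over a point cloud
#'
#' The point cloud partitioned into fixed-size voxels (0.1 Th by 10 scans
#' by 5 s by default), anchored at coordinate 0 on each axis and ranked in
#' descending order of mean point intensity (ties broken by voxel key).
#' Voxels whose mean intensity is below `minVoxelIntensity` are excluded
#' from the queue but retained for neighbourhood reads. Queue state
#' (pending / processed / retired) lives in an environment so that
#' [nextVoxel()] and [retireVoxels()] update it in place.
#'
#' @slot voxels data.frame of voxels in ranking order (row = voxel id).
#' @slot pointVoxel integer voxel id per point of the indexed cloud.
#' @slot minVoxelIntensity the stopping threshold (mean voxel intensity).
#' @slot grid list of bin widths (`mz_width`, `scan_span`, `rt_span`).
#' @slot queue environment holding the `state` vector.
#' @export
setClass("VoxelIndex", representation(
  voxels = "data.frame", pointVoxel = "integer",
  minVoxelIntensity = "numeric", grid = "list", queue = "environment"
))

setValidity("VoxelIndex", function(object) {
  v <- object@voxels
  need <- c("mz_bin", "scan_bin", "rt_bin", "mz_lo", "mz_hi", "scan_lo",
            "scan_hi", "rt_lo", "rt_hi", "n_points", "total_intensity",
            "mean_intensity", "queued")
  miss <- setdiff(need, names(v))
  if (length(miss) > 0)
    return(paste0("missing voxel column(s): ", paste(miss, collapse = ", ")))
  if (nrow(v) > 0) {
    if (any(abs(v$mean_intensity - v$total_intensity / v$n_points) > 1e-9 *
            pmax(1, v$mean_intensity)))
      return("mean_intensity != total_intensity / n_points")
    q <- which(v$queued)
    if (is.unsorted(-v$mean_intensity[q]))
      return("queued voxels are not in descending mean-intensity order")
  }
  if (length(object@queue$state) != nrow(v))
    return("queue state length does not match voxel count")
  TRUE
})
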