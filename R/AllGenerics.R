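#' Extract the ion table of a PointCloud
#'
#' @param x a [PointCloud-class].
#' @return data.frame with one row per detector reading.
#' @export
setGeneric("ionData", function(x) standardGeneric("ionData"))

#' Extract the feature table of a FeatureSet
#'
#' @param x a [FeatureSet-class].
#' @return data.frame with one row per detected feature.
#' @export
setGeneric("featureTable", function(x) standardGeneric("featureTable"))

#' Extract the voxel table of a VoxelIndex
#'
#' @param x a [VoxelIndex-class].
#' @return data.frame of voxels in ranking order, with the current queue
#'   state appended as a `state` column.
#' @export
setGeneric("voxelTable", function(x) standardGeneric("voxelTable"))

#' Frame id to retention time mapping of a PointCloud
#'
#' @param x a [PointCloud-class].
#' @return named numeric vector of retention times (seconds), names are
#'   frame ids, strictly increasing.
#' @export
setGeneric("frameTimes", function(x) standardGeneric("frameTimes"))

#' Pop the next voxel from the work queue
#'
#' Returns the highest-ranked pending voxel whose mean intensity is at or
#' above the index's stopping threshold, marks it processed, or returns
#' NULL when the queue (or the supplied subset) is exhausted.
#'
#' @param index a [VoxelIndex-class].
#' @param ids optional integer vector of voxel ids restricting the queue
#'   (e.g. one m/z band); ranking order within the subset is preserved.
#' @return one-row data.frame for the voxel (with its id in `voxel_id`),
#'   or NULL when exhausted.
#' @export
setGeneric("nextVoxel", function(index, ids = NULL) standardGeneric("nextVoxel"))

#' Retire voxels consumed by an accepted feature
#'
#' A voxel is retired when strictly more than 80% of its total intensity
#' is contributed by the feature's isotopic-peak points; retired voxels
#' are never returned by [nextVoxel()] again.
#'
#' @param index a [VoxelIndex-class].
#' @param pointRefs integer row indices (into the indexed cloud's point
#'   table) of the feature's isotopic-peak points.
#' @param fraction retirement fraction (default 0.8; strict inequality).
#' @param ids optional voxel ids eligible for retirement (used to keep
#'   retirement band-local so the worker schedule cannot change results).
#' @return integer vector of retired voxel ids (possibly empty).
#' @export
setGeneric("retireVoxels", function(index, pointRefs, fraction = 0.8,
                                    ids = NULL)
  standardGeneric("retireVoxels"))
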