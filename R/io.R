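# Tabular readers and writers: the point-cloud CSV is the package's native
# input (conversion from vendor raw formats is external); the feature table
# is its native output.

#' Read a 4-D point cloud from delimited text
#'
#' Expects a header row `frame_id,rt,scan,inv_k0,mz,intensity`. Rows whose
#' cells cannot be parsed as numbers, or which violate the point invariants
#' (intensity >= 0, mz > 0, rt >= 0, scan >= 0), are rejected. With
#' `strict = TRUE` (default) the first malformed cell raises a parse error
#' naming the row; with `strict = FALSE` malformed rows are dropped with a
#' warning listing the row numbers, so that accepted + rejected always
#' equals the input row count.
#'
#' @param path path to a delimited text file.
#' @param sep field separator (default comma).
#' @param strict stop on the first malformed row (default) instead of
#'   rejecting and continuing.
#' @return a [PointCloud-class]; the number of rejected rows is available
#'   as `attr(x, "rejected")`.
#' @export
readPointCloud <- function(path, sep = ",", strict = TRUE) {
  if (!file.exists(path))
    tdStop(paste0("file not found: ", path), "ioError")
  raw <- data.table::fread(path, sep = sep, colClasses = "character",
                           data.table = FALSE, showProgress = FALSE)
  miss <- setdiff(.POINT_COLUMNS, names(raw))
  if (length(miss) > 0)
    tdStop(paste0("point table is missing column(s): ",
                  paste(miss, collapse = ", ")), "schemaError")
  raw <- raw[, .POINT_COLUMNS, drop = FALSE]
  num <- suppressWarnings(
    as.data.frame(lapply(raw, as.numeric), col.names = .POINT_COLUMNS))
  badParse <- rowSums(is.na(num)) > 0
  if (any(badParse) && strict) {
    row <- which(badParse)[1]
    col <- .POINT_COLUMNS[which(is.na(num[row, ]))[1]]
    tdStop(sprintf("non-numeric value in column '%s' at data row %d", col, row),
           "parseError")
  }
  badRange <- !badParse & (num$intensity < 0 | num$mz <= 0 |
                             num$rt < 0 | num$scan < 0)
  bad <- badParse | badRange
  if (any(bad)) {
    warning(sprintf("rejected %d of %d rows (%s malformed, %s out of range): rows %s",
                    sum(bad), nrow(num), sum(badParse), sum(badRange),
                    paste(utils::head(which(bad), 20), collapse = ", ")))
  }
  cloud <- PointCloud(num[!bad, , drop = FALSE])
  attr(cloud, "rejected") <- sum(bad)
  cloud
}

#' Write a point cloud to delimited text
#'
#' @param cloud a [PointCloud-class].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
writePointCloud <- function(cloud, path) {
  stopifnot(is(cloud, "PointCloud"))
  data.table::fwrite(ionData(cloud), path, sep = ",")
  invisible(path)
}

#' Write a feature table to delimited text
#'
#' One row per feature; column order is stable
#' (`mono_mz,charge,intensity,rt_apex,rt_lo,rt_hi,scan_apex,scan_lo,
#' scan_hi,num_isotopes,deconvolution_score,coelution_coefficient,
#' mobility_coefficient,identifiability_score,inv_k0_apex`). An empty set
#' writes a header-only file. Numeric values keep full precision, so a
#' write/read round trip preserves m/z to better than 1e-6 Th.
#'
#' @param features a [FeatureSet-class].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
writeFeatureTable <- function(features, path) {
  stopifnot(is(features, "FeatureSet"))
  ok <- tryCatch({
    data.table::fwrite(featureTable(features), path, sep = ",")
    TRUE
  }, error = function(e) e)
  if (!isTRUE(ok))
    tdStop(paste0("cannot write feature table to '", path, "': ",
                  conditionMessage(ok)), "ioError")
  invisible(path)
}

#' Read a feature table written by [writeFeatureTable()]
#'
#' @param path path to the delimited feature table.
#' @return a [FeatureSet-class].
#' @export
readFeatureTable <- function(path) {
  if (!file.exists(path))
    tdStop(paste0("file not found: ", path), "ioError")
  f <- data.table::fread(path, sep = ",", data.table = FALSE,
                         showProgress = FALSE)
  if (nrow(f) == 0) return(FeatureSet())
  FeatureSet(f)
}

#' Read isolation windows from delimited text
#'
#' Expects the header `mz_lo,mz_hi,scan_lo,scan_hi,rt_lo,rt_hi`.
#'
#' @param path path to the windows file.
#' @return data.frame of isolation windows.
#' @export
readIsolationWindows <- function(path) {
  need <- c("mz_lo", "mz_hi", "scan_lo", "scan_hi", "rt_lo", "rt_hi")
  w <- data.table::fread(path, sep = ",", data.table = FALSE,
                         showProgress = FALSE)
  miss <- setdiff(need, names(w))
  if (length(miss) > 0)
    tdStop(paste0("windows table is missing column(s): ",
                  paste(miss, collapse = ", ")), "schemaError")
  if (any(w$mz_lo > w$mz_hi | w$scan_lo > w$scan_hi | w$rt_lo > w$rt_hi))
    tdStop("isolation window bounds must be ordered", "schemaError")
  w[, need, drop = FALSE]
}
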