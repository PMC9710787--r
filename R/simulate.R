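# Synthetic point-cloud generator. Plants peptide precursor features with
# known ground truth on the instrument's discrete frame/scan grid so every
# downstream stage can be validated without instrument data.
#
# Each planted feature is a series of isotopic peaks spaced 1.003355/z Th
# apart, with averagine-predicted peak height ratios, Gaussian marginal
# profiles in m/z, mobility (scans) and retention time, and Poisson
# sampling jitter on the grid-node intensities. Typical geometry follows
# reported feature dimensions on this instrument class: envelopes about
# 2 +/- 0.3 Th wide in m/z, base widths of 44 +/- 14 scans in mobility and
# 6.6 +/- 2.4 s in retention time (sigma = base width / 4).

.TRUTH_COLUMNS <- c("feature_id", "mono_mz", "charge", "total_intensity",
                    "rt_apex", "rt_sigma", "scan_apex", "scan_sigma",
                    "mz_sigma", "n_isotopes", "envelope_fractions")

#' Noise specification for the synthetic generator
#'
#' Noise points are uniform in position (m/z continuous, scan and frame on
#' the acquisition grid) with exponentially distributed intensities — the
#' simplest ambient-noise model that exercises voxel ranking and the
#' minimum-voxel-intensity stopping rule. The defaults describe a
#' de-noised point cloud (vendor de-noising is assumed upstream).
#'
#' @param density expected noise points per (Th x scan x second) of
#'   extent volume.
#' @param mean_intensity mean of the exponential intensity distribution
#'   (counts); drawn intensities are rounded up to at least 1 count.
#' @param saturation_limit detector saturation ceiling in counts, or NULL
#'   for none; applied to all generated points.
#' @return a classed list.
#' @export
noiseSpec <- function(density = 1e-3, mean_intensity = 30,
                      saturation_limit = NULL) {
  if (density < 0) tdStop("noise density must be >= 0", "domainError")
  if (mean_intensity <= 0)
    tdStop("mean_intensity must be > 0", "domainError")
  structure(list(density = density, mean_intensity = mean_intensity,
                 saturation_limit = saturation_limit),
            class = "timsNoiseSpec")
}

#' Draw a random set of ground-truth features
#'
#' Samples `n` planted features with monoisotopic m/z uniform over
#' `mz_range`, charges from `charge_range`, total intensities log-uniform
#' over `intensity_range` (the default spans 100x), and apexes uniform
#' over `rt_window` / `scan_window`. Peak widths follow the typical
#' feature geometry (base widths 6.6 +/- 2.4 s and 44 +/- 14 scans,
#' sigma = width / 4); the m/z peak sigma matches a resolving power of
#' 40,000. Apexes are rejection-sampled so that no two features fall
#' within `min_separation` on all three axes at once. Isotope counts and
#' envelope fractions come from [averagineEnvelope()] at the implied
#' neutral mass.
#'
#' @param n number of features.
#' @param seed RNG seed.
#' @param mz_range,charge_range,intensity_range,rt_window,scan_window
#'   sampling ranges.
#' @param rt_width,scan_width mean and sd of the base widths (4 sigma).
#' @param resolution instrument resolving power for the m/z peak width.
#' @param min_separation named vector `c(mz=, scan=, rt=)`; two features
#'   closer than all three components at once are resampled.
#' @return data.frame of ground-truth features; `envelope_fractions` is a
#'   semicolon-separated string of per-isotope relative abundances
#'   summing to 1.
#' @export
syntheticFeatures <- function(n = 50L, seed = 1L,
                              mz_range = c(450, 550),
                              charge_range = 2:4,
                              intensity_range = c(1e5, 1e7),
                              rt_window = c(30, 270),
                              scan_window = c(100, 500),
                              rt_width = c(mean = 6.6, sd = 2.4),
                              scan_width = c(mean = 44, sd = 14),
                              resolution = 40000,
                              min_separation = c(mz = 1.5, scan = 30, rt = 10)) {
  set.seed(seed)
  out <- vector("list", n)
  placed <- data.frame(mz = numeric(0), scan = numeric(0), rt = numeric(0))
  for (i in seq_len(n)) {
    for (try in 1:1000) {
      mono <- stats::runif(1, mz_range[1], mz_range[2])
      scan <- round(stats::runif(1, scan_window[1], scan_window[2]))
      rt <- stats::runif(1, rt_window[1], rt_window[2])
      clash <- abs(placed$mz - mono) < min_separation[["mz"]] &
        abs(placed$scan - scan) < min_separation[["scan"]] &
        abs(placed$rt - rt) < min_separation[["rt"]]
      if (!any(clash)) break
    }
    placed <- rbind(placed, data.frame(mz = mono, scan = scan, rt = rt))
    z <- if (length(charge_range) == 1) charge_range else sample(charge_range, 1)
    total <- 10^stats::runif(1, log10(intensity_range[1]),
                             log10(intensity_range[2]))
    rt_sigma <- max(0.8, stats::rnorm(1, rt_width[["mean"]],
                                      rt_width[["sd"]])) / 4
    scan_sigma <- max(8, stats::rnorm(1, scan_width[["mean"]],
                                      scan_width[["sd"]])) / 4
    neutral <- mono * z - z * .PROTON_MASS
    full <- averagineEnvelope(neutral, 8L)
    n_iso <- max(3L, min(6L, sum(full >= 0.01)))
    frac <- averagineEnvelope(neutral, n_iso)
    out[[i]] <- data.frame(
      feature_id = i, mono_mz = mono, charge = z, total_intensity = total,
      rt_apex = rt, rt_sigma = rt_sigma, scan_apex = scan,
      scan_sigma = scan_sigma, mz_sigma = mzPeakSigma(mono, resolution),
      n_isotopes = n_iso,
      envelope_fractions = paste(sprintf("%.8f", frac / sum(frac)),
                                 collapse = ";"))
  }
  do.call(rbind, out)
}

truthFractions <- function(truth_row) {
  f <- as.numeric(strsplit(truth_row$envelope_fractions, ";")[[1]])
  f / sum(f)
}

validateTruths <- function(truths) {
  miss <- setdiff(.TRUTH_COLUMNS, names(truths))
  if (length(miss) > 0)
    tdStop(paste0("truth table is missing column(s): ",
                  paste(miss, collapse = ", ")), "schemaError")
  for (i in seq_len(nrow(truths))) {
    f <- truthFractions(truths[i, ])
    if (length(f) < 2 || any(f < 0) || abs(sum(f) - 1) > 1e-9)
      tdStop("envelope_fractions must be >= 2 non-negative values summing to 1",
             "validationError")
  }
  pos <- c("mono_mz", "charge", "total_intensity", "rt_sigma", "scan_sigma",
           "mz_sigma")
  for (col in pos)
    if (any(truths[[col]] <= 0))
      tdStop(paste0("truth column '", col, "' must be positive"),
             "validationError")
  invisible(TRUE)
}

#' Generate a synthetic point cloud with planted features
#'
#' Lays down the acquisition grid (frames every `frame_period` seconds
#' over `rt_range`; integer scans over `scan_range`; 1/K0 mapped affinely
#' and decreasing in scan), then for every ground-truth feature samples
#' grid-node intensities from the product-Gaussian profile scaled so the
#' expected summed intensity equals `total_intensity`, applies Poisson
#' jitter, and draws each point's m/z from a Gaussian around its isotope
#' center (isotope spacing 1.003355/charge Th, heights proportional to the
#' envelope fractions). Noise points are added per the [noiseSpec()] and
#' all intensities are clipped at the saturation limit when one is set.
#'
#' @param truths ground-truth feature table (see [syntheticFeatures()]).
#' @param noise a [noiseSpec()].
#' @param mz_range,scan_range,rt_range extent of the generated cloud;
#'   every truth must lie inside it.
#' @param frame_period MS1 frame period in seconds (default 0.5).
#' @param inv_k0_range 1/K0 at the highest and lowest scan index
#'   (decreasing in scan).
#' @param seed RNG seed; the same seed reproduces the cloud bit for bit.
#' @param min_expected grid nodes with expected intensity below this are
#'   not sampled (keeps the cloud sparse, as on the instrument).
#' @return list with elements `cloud` (a [PointCloud-class]) and `truth`
#'   (the manifest: the input truths plus generation parameters in
#'   attributes).
#' @export
simulateCloud <- function(truths, noise = noiseSpec(),
                          mz_range = c(440, 560),
                          scan_range = c(0L, 600L),
                          rt_range = c(0, 300),
                          frame_period = 0.5,
                          inv_k0_range = c(0.6, 1.6),
                          seed = 1L, min_expected = 0.25) {
  if (nrow(truths) > 0) {
    validateTruths(truths)
    hi_mz <- truths$mono_mz +
      (truths$n_isotopes - 1) * .ISOTOPE_DELTA / truths$charge
    if (any(truths$mono_mz - 4 * truths$mz_sigma < mz_range[1]) ||
        any(hi_mz + 4 * truths$mz_sigma > mz_range[2]) ||
        any(truths$scan_apex < scan_range[1]) ||
        any(truths$scan_apex > scan_range[2]) ||
        any(truths$rt_apex < rt_range[1]) ||
        any(truths$rt_apex > rt_range[2]))
      tdStop("a ground-truth feature lies outside the extent",
             "validationError")
  }
  set.seed(seed)
  frame_rt <- seq(rt_range[1], rt_range[2], by = frame_period)
  frame_id <- seq_along(frame_rt)
  scans <- seq(scan_range[1], scan_range[2])
  invK0 <- function(scan) {
    inv_k0_range[2] - (scan - scan_range[1]) /
      max(1, diff(scan_range)) * diff(inv_k0_range)
  }
  pieces <- list()
  for (i in seq_len(nrow(truths))) {
    tr <- truths[i, ]
    frac <- truthFractions(tr)
    g_rt <- exp(-0.5 * ((frame_rt - tr$rt_apex) / tr$rt_sigma)^2)
    g_sc <- exp(-0.5 * ((scans - tr$scan_apex) / tr$scan_sigma)^2)
    amp <- tr$total_intensity / (sum(g_rt) * sum(g_sc))
    fi <- which(g_rt > 1e-4)
    si <- which(g_sc > 1e-4)
    if (length(fi) == 0 || length(si) == 0) next
    node <- expand.grid(f = fi, s = si)
    base <- amp * g_rt[node$f] * g_sc[node$s]
    for (j in seq_len(tr$n_isotopes)) {
      expect <- base * frac[j]
      keep <- expect >= min_expected
      if (!any(keep)) next
      inten <- stats::rpois(sum(keep), expect[keep])
      nz <- inten > 0
      if (!any(nz)) next
      center <- tr$mono_mz + (j - 1) * .ISOTOPE_DELTA / tr$charge
      kf <- node$f[keep][nz]; ks <- node$s[keep][nz]
      pieces[[length(pieces) + 1]] <- data.frame(
        frame_id = frame_id[kf], rt = frame_rt[kf],
        scan = scans[ks], inv_k0 = invK0(scans[ks]),
        mz = stats::rnorm(sum(nz), center, tr$mz_sigma),
        intensity = as.numeric(inten[nz]))
    }
  }
  volume <- diff(mz_range) * diff(range(scans)) * diff(rt_range)
  n_noise <- stats::rpois(1, noise$density * volume)
  if (n_noise > 0) {
    nsc <- sample(scans, n_noise, replace = TRUE)
    nfr <- sample(frame_id, n_noise, replace = TRUE)
    pieces[[length(pieces) + 1]] <- data.frame(
      frame_id = nfr, rt = frame_rt[nfr], scan = nsc, inv_k0 = invK0(nsc),
      mz = stats::runif(n_noise, mz_range[1], mz_range[2]),
      intensity = pmax(1, ceiling(stats::rexp(n_noise,
                                              1 / noise$mean_intensity))))
  }
  pts <- if (length(pieces) > 0) do.call(rbind, pieces) else
    data.frame(frame_id = integer(0), rt = numeric(0), scan = integer(0),
               inv_k0 = numeric(0), mz = numeric(0), intensity = numeric(0))
  if (!is.null(noise$saturation_limit))
    pts$intensity <- pmin(pts$intensity, noise$saturation_limit)
  truth <- truths
  attr(truth, "params") <- list(
    seed = seed, frame_period = frame_period, mz_range = mz_range,
    scan_range = scan_range, rt_range = rt_range,
    inv_k0_range = inv_k0_range, noise_density = noise$density,
    noise_mean_intensity = noise$mean_intensity,
    saturation_limit = noise$saturation_limit)
  list(cloud = PointCloud(pts), truth = truth)
}

#' The standard synthetic benchmark
#'
#' Convenience wrapper planting `n_features` features (charges 2-4,
#' intensities spanning 100x, typical geometry) in the default extent
#' with the default noise, used throughout the test suite as the
#' end-to-end recovery benchmark.
#'
#' @param seed RNG seed (drives both feature placement and sampling).
#' @param n_features number of planted features.
#' @param noise a [noiseSpec()].
#' @return as [simulateCloud()].
#' @export
simulateBenchmark <- function(seed = 1L, n_features = 50L,
                              noise = noiseSpec()) {
  truths <- syntheticFeatures(n = n_features, seed = seed)
  simulateCloud(truths, noise = noise, seed = seed + 1L)
}

#' Write / read a ground-truth manifest
#'
#' The manifest is delimited text, one row per planted feature, with the
#' generation parameters in a `key=value` sidecar file (`<path>.params`).
#'
#' @param truth manifest as returned by [simulateCloud()].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
writeGroundTruth <- function(truth, path) {
  data.table::fwrite(as.data.frame(truth)[, .TRUTH_COLUMNS], path, sep = ",")
  p <- attr(truth, "params")
  if (!is.null(p)) {
    keys <- vapply(p, function(v)
      if (is.null(v)) "" else paste(format(v, scientific = FALSE),
                                    collapse = " "), "")
    writeLines(paste0(names(p), "=", keys), paste0(path, ".params"))
  }
  invisible(path)
}

#' @rdname writeGroundTruth
#' @export
readGroundTruth <- function(path) {
  data.table::fread(path, sep = ",", data.table = FALSE,
                    showProgress = FALSE)
}
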