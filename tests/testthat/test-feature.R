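test_that("region expansion moves only the m/z edges, by 0.6 and 3 Th", {
  b <- list(mz_lo = 500.00, mz_hi = 500.05, scan_lo = 10L, scan_hi = 60L,
            rt_lo = 100, rt_hi = 110)
  e <- expandRegion(b)
  expect_equal(c(e$mz_lo, e$mz_hi), c(499.40, 503.05))
  expect_identical(e[c("scan_lo", "scan_hi", "rt_lo", "rt_hi")],
                   b[c("scan_lo", "scan_hi", "rt_lo", "rt_hi")])
  # not idempotent: guarded by the single-call contract
  e2 <- expandRegion(e)
  expect_false(isTRUE(all.equal(e, e2)))
})

test_that("intensity descent groups close points and keeps distant ones", {
  p <- makePoints(mz = c(500.000, 500.001), intensity = c(10, 5))
  sp <- intensityDescent(p)
  expect_equal(nrow(sp), 1L)
  expect_equal(sp$intensity, 15)
  expect_equal(sp$mz, (500.000 * 10 + 500.001 * 5) / 15)

  p <- makePoints(mz = c(500, 505), intensity = c(10, 5))
  sp <- intensityDescent(p)
  expect_equal(nrow(sp), 2L)
  expect_true(!is.unsorted(sp$mz, strictly = TRUE))
})

test_that("intensity descent conserves total intensity on random inputs", {
  for (s in 1:20) {
    set.seed(s)
    p <- makePoints(mz = runif(100, 500, 501), intensity = runif(100, 1, 50))
    sp <- intensityDescent(p)
    expect_equal(sum(sp$intensity), sum(p$intensity), tolerance = 1e-12)
    expect_true(!is.unsorted(sp$mz, strictly = TRUE))
  }
})

test_that("a clean charge-2 envelope deconvolves to its mono and charge", {
  sp <- makeEnvelopeSpectrum(mono_mz = 500, charge = 2L, n_isotopes = 4L)
  envs <- deconvolveSpectrum(sp)
  expect_gt(length(envs), 0)
  best <- envs[[1]]
  expect_equal(best$charge, 2L)
  expect_lt(abs(ppmError(best$mono_mz, 500)), 5)
  expect_equal(nrow(best$peaks), 4L)
})

test_that("a single peak cannot form an envelope", {
  sp <- data.frame(mz = 500, intensity = 1000)
  expect_length(deconvolveSpectrum(sp, min_isotopes = 2), 0)
})

test_that("envelope detection is translation-consistent in m/z", {
  sp <- makeEnvelopeSpectrum(mono_mz = 450, charge = 2L, n_isotopes = 4L)
  sp2 <- sp; sp2$mz <- sp2$mz + 100
  b1 <- deconvolveSpectrum(sp)[[1]]
  b2 <- deconvolveSpectrum(sp2)[[1]]
  expect_equal(b2$charge, b1$charge)
  expect_equal(b2$mono_mz, b1$mono_mz + 100, tolerance = 1e-9)
})

test_that("emitted envelopes only reference peaks present in the spectrum", {
  for (s in 1:10) {
    set.seed(s)
    sp <- rbind(makeEnvelopeSpectrum(mono_mz = 400 + 50 * runif(1),
                                     charge = sample(1:3, 1)),
                data.frame(mz = runif(5, 400, 460),
                           intensity = runif(5, 100, 1000)))
    sp <- sp[order(sp$mz), ]
    for (e in deconvolveSpectrum(sp))
      expect_true(all(e$peaks$mz %in% sp$mz))
  }
})

test_that("candidate validation accepts mono OR base peak at the centroid", {
  env <- list(mono_mz = 500,
              peaks = data.frame(mz = c(500, 500.5017),
                                 intensity = c(100, 150)),
              base_peak_index = 2L)
  expect_true(validateCandidate(env, 500))            # mono exact
  expect_true(validateCandidate(env, 500.5017))       # base matches, mono not
  off <- 500 * (1 + 50e-6)
  expect_false(validateCandidate(env, off, tolerance_ppm = 10))
})

# Points whose per-frame maxima in each isotope window equal the given
# per-isotope values, across three frames at 0.5 s spacing.
isotopePoints <- function(values, mono = 500, charge = 2L,
                          rts = c(99.5, 100, 100.5)) {
  rows <- list()
  for (i in seq_along(values)) {
    mzc <- mono + (i - 1) * 1.003355 / charge
    for (r in rts)
      rows[[length(rows) + 1]] <- makePoints(
        mz = c(mzc, mzc + 1e-4), intensity = c(values[i], values[i] / 2),
        rt = r, scan = 300L, frame_id = match(r, rts))
  }
  do.call(rbind, rows)
}

test_that("feature intensity sums the first three isotopes at the apex", {
  env <- list(mono_mz = 500, charge = 2L,
              peaks = data.frame(mz = 500 + (0:3) * 1.003355 / 2,
                                 intensity = c(100, 60, 30, 10)),
              base_peak_index = 1L)
  pts <- isotopePoints(c(100, 60, 30, 10))
  expect_equal(featureIntensity(env, pts, rt_apex = 100), 190)

  env2 <- env; env2$peaks <- env$peaks[1:2, ]
  pts2 <- isotopePoints(c(100, 60))
  expect_equal(featureIntensity(env2, pts2, rt_apex = 100), 160)
})

test_that("feature intensity is linear under the identity saturation hook", {
  env <- list(mono_mz = 500, charge = 2L,
              peaks = data.frame(mz = 500 + (0:2) * 1.003355 / 2,
                                 intensity = c(100, 60, 30)),
              base_peak_index = 1L)
  pts <- isotopePoints(c(100, 60, 30))
  base <- featureIntensity(env, pts, rt_apex = 100)
  doubled <- pts; doubled$intensity <- doubled$intensity * 2
  expect_equal(featureIntensity(env, doubled, rt_apex = 100), 2 * base)
  # a custom hook is applied per point before the maximum
  expect_equal(featureIntensity(env, pts, rt_apex = 100,
                                saturation = function(x) x * 10),
               10 * base)
  expect_error(featureIntensity(env, pts[0, ], rt_apex = 100),
               class = "degenerateInput")
})

test_that("alignment coefficients are cosine similarities to isotope 0", {
  # identical profiles across isotopes -> both coefficients 1
  pts <- isotopePoints(c(100, 60, 30))
  env <- list(mono_mz = 500, charge = 2L,
              peaks = data.frame(mz = 500 + (0:2) * 1.003355 / 2,
                                 intensity = c(100, 60, 30)),
              base_peak_index = 1L)
  co <- alignmentCoefficients(env, pts)
  expect_equal(unname(co), c(1, 1), tolerance = 1e-9)

  # disjoint support -> 0
  a <- makePoints(mz = 500, intensity = 10, rt = c(10, 10.5),
                  scan = c(100L, 100L), frame_id = c(1L, 2L))
  b <- makePoints(mz = 500.5017, intensity = 10, rt = c(12, 12.5),
                  scan = c(200L, 200L), frame_id = c(5L, 6L))
  env2 <- list(mono_mz = 500, charge = 2L,
               peaks = data.frame(mz = c(500, 500.5017),
                                  intensity = c(20, 20)),
               base_peak_index = 1L)
  co2 <- alignmentCoefficients(env2, rbind(a, b))
  expect_equal(unname(co2), c(0, 0))
})

test_that("alignment matches a brute-force cosine computation", {
  for (s in 1:10) {
    set.seed(s)
    rts <- seq(10, 14, 0.5)
    pts <- do.call(rbind, lapply(0:2, function(i) {
      makePoints(mz = 500 + i * 0.50168 + rnorm(length(rts), 0, 1e-4),
                 intensity = runif(length(rts), 1, 100), rt = rts,
                 scan = sample(290:310, length(rts), TRUE),
                 frame_id = seq_along(rts))
    }))
    env <- list(mono_mz = 500, charge = 2L,
                peaks = data.frame(mz = 500 + (0:2) * 0.50168,
                                   intensity = c(3, 2, 1)),
                base_peak_index = 1L)
    co <- alignmentCoefficients(env, pts)
    # oracle: direct dot / (|a||b|) on per-frame and per-scan sums
    prof <- function(i, axis) {
      half <- 3 * (env$peaks$mz[i + 1] / 40000) / (2 * sqrt(2 * log(2)))
      sel <- abs(pts$mz - env$peaks$mz[i + 1]) <= half
      grid <- sort(unique(pts[[axis]]))
      vapply(grid, function(g) sum(pts$intensity[sel & pts[[axis]] == g]), 0)
    }
    cosv <- function(a, b) sum(a * b) / sqrt(sum(a^2) * sum(b^2))
    expect_equal(co[["coelution"]],
                 mean(c(cosv(prof(0, "rt"), prof(1, "rt")),
                        cosv(prof(0, "rt"), prof(2, "rt")))),
                 tolerance = 1e-9)
    expect_equal(co[["mobility"]],
                 mean(c(cosv(prof(0, "scan"), prof(1, "scan")),
                        cosv(prof(0, "scan"), prof(2, "scan")))),
                 tolerance = 1e-9)
  }
})
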