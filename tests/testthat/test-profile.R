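test_that("mz centroid is the intensity-weighted mean", {
  expect_equal(mzCentroid(makePoints(c(100.0, 100.2), c(1, 1))), 100.1)
  expect_equal(mzCentroid(makePoints(c(100.0, 100.4), c(3, 1))), 100.1)
  for (s in 1:20) {
    set.seed(s)
    p <- makePoints(runif(30, 400, 600), runif(30, 1, 100))
    expect_equal(mzCentroid(p),
                 sum(p$mz * p$intensity) / sum(p$intensity),
                 tolerance = 1e-12)
  }
  expect_error(mzCentroid(makePoints(numeric(0), numeric(0))),
               class = "degenerateInput")
})

test_that("mz extent follows FWHM = m/R with a 3 sigma half-width", {
  ext <- mzExtent(800, 40000)
  half <- (800 / 40000) / (2 * sqrt(2 * log(2))) * 3  # 0.025480 Th
  expect_equal(ext, c(800 - half, 800 + half), tolerance = 1e-12)
  expect_equal(half, 0.02548, tolerance = 1e-4)
  # doubling the resolution halves the extent; always symmetric
  expect_equal(diff(mzExtent(800, 80000)), diff(ext) / 2)
  expect_equal(mean(mzExtent(512.3, 40000)), 512.3)
})

gaussSeries <- function(center, sigma, scans, height = 1000) {
  makePoints(mz = 500, intensity = height * exp(-0.5 * ((scans - center) / sigma)^2),
             scan = scans)
}

test_that("a symmetric noiseless peak yields its center as apex", {
  pts <- gaussSeries(300, 10, 260:340)
  prof <- profileExtent(pts, "mobility", midpoint = 300, half_window = 40)
  expect_equal(prof@apex, 300)
  expect_equal(c(prof@valleyLo, prof@valleyHi), c(260, 340))
  expect_false(prof@edgeApex)
})

test_that("with multiple apexes the one nearest the midpoint wins", {
  pts <- rbind(gaussSeries(290, 5, 260:340, 1000),
               gaussSeries(320, 5, 260:340, 1000))
  prof <- profileExtent(pts, "mobility", midpoint = 300, half_window = 40)
  expect_equal(prof@apex, 290)
  # the interior minimum between the modes bounds the left peak
  expect_gt(prof@valleyHi, 290)
  expect_lt(prof@valleyHi, 320)
  # oracle: brute-force minimum of the smoothed series between the modes
  between <- prof@positions > 290 & prof@positions < 320
  expect_equal(prof@valleyHi,
               prof@positions[between][which.min(prof@smoothed[between])])
})

test_that("flattening conserves the windowed intensity", {
  set.seed(4)
  pts <- makePoints(mz = 500, intensity = runif(200, 1, 50),
                    scan = sample(280:320, 200, TRUE))
  prof <- profileExtent(pts, "mobility", midpoint = 300, half_window = 40)
  expect_equal(sum(prof@raw), sum(pts$intensity))
})

test_that("profiling is translation-equivariant along its axis", {
  pts <- gaussSeries(300, 8, 265:335)
  p1 <- profileExtent(pts, "mobility", midpoint = 300, half_window = 40)
  shifted <- pts; shifted$scan <- shifted$scan + 57L
  p2 <- profileExtent(shifted, "mobility", midpoint = 357, half_window = 40)
  expect_equal(p2@apex, p1@apex + 57)
  expect_equal(p2@valleyLo, p1@valleyLo + 57)
  expect_equal(p2@valleyHi, p1@valleyHi + 57)
})

test_that("too few distinct positions is a degenerate-peak error", {
  pts <- makePoints(mz = 500, intensity = c(10, 20), scan = c(300L, 301L))
  expect_error(profileExtent(pts, "mobility", midpoint = 300,
                             half_window = 40),
               class = "degeneratePeak")
})

test_that("RT gap trimming drops disconnected stray frames only", {
  rts <- c(seq(10, 12, 0.5), 15)
  pts <- makePoints(mz = 500, intensity = c(5, 20, 40, 20, 5, 7),
                    rt = rts, frame_id = seq_along(rts))
  prof <- profileExtent(pts, "rt", midpoint = 11, half_window = 13.2)
  trimmed <- trimRtGaps(pts, prof, max_gap = 1.0)
  expect_setequal(trimmed$rt, seq(10, 12, 0.5))  # 15 s stray removed

  contiguous <- pts[pts$rt <= 12, ]
  expect_identical(trimRtGaps(contiguous, prof), contiguous)
})

test_that("trimming never splits the retained chain around the apex", {
  for (s in 1:20) {
    set.seed(s)
    rts <- sort(sample(seq(0, 30, 0.5), 25))
    pts <- makePoints(mz = 500, intensity = runif(25, 1, 100), rt = rts,
                      frame_id = seq_along(rts))
    prof <- new("PeakProfile", axis = "rt", positions = rts,
                raw = pts$intensity, smoothed = pts$intensity,
                apex = rts[13], valleyLo = min(rts), valleyHi = max(rts),
                edgeApex = FALSE)
    kept <- sort(unique(trimRtGaps(pts, prof)$rt))
    expect_true(all(diff(kept) <= 1.0))
    expect_true(rts[13] %in% kept)
  }
})
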