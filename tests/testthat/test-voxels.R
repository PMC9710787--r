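cloudFromPoints <- function(...) PointCloud(makePoints(...))

test_that("points either side of a 0.1 Th boundary land in different bins", {
  cloud <- cloudFromPoints(mz = c(100.05, 100.15), intensity = c(1, 1))
  idx <- buildVoxelIndex(cloud, min_voxel_intensity = 0)
  expect_equal(nrow(voxelTable(idx)), 2L)
  expect_setequal(voxelTable(idx)$mz_bin, c(1000L, 1001L))
})

test_that("a single point's voxel mean is its intensity", {
  cloud <- cloudFromPoints(mz = 500.05, intensity = 500)
  idx <- buildVoxelIndex(cloud, min_voxel_intensity = 0)
  expect_equal(voxelTable(idx)$mean_intensity, 500)
})

test_that("voxel totals conserve the cloud's intensity exactly", {
  set.seed(99)
  cloud <- cloudFromPoints(mz = runif(1000, 400, 600),
                           intensity = rexp(1000, 1 / 50),
                           scan = sample(0:500, 1000, TRUE),
                           rt = round(runif(1000, 0, 100), 1))
  idx <- buildVoxelIndex(cloud, min_voxel_intensity = 0)
  expect_equal(sum(voxelTable(idx)$total_intensity),
               sum(ionData(cloud)$intensity))
  # every point assigned to exactly one voxel
  expect_equal(length(idx@pointVoxel), length(cloud))
  expect_true(all(idx@pointVoxel >= 1 &
                    idx@pointVoxel <= nrow(voxelTable(idx))))
})

test_that("bands are a disjoint cover with 10 Th width", {
  cloud <- cloudFromPoints(mz = c(105, 115), intensity = c(1, 1))
  idx <- buildVoxelIndex(cloud, min_voxel_intensity = 0)
  bands <- partitionBands(idx)
  expect_identical(names(bands), c("10", "11"))

  set.seed(7)
  cloud <- cloudFromPoints(mz = runif(500, 400, 600),
                           intensity = runif(500, 1, 100),
                           scan = sample(0:300, 500, TRUE))
  idx <- buildVoxelIndex(cloud, min_voxel_intensity = 0)
  bands <- partitionBands(idx)
  allIds <- sort(unlist(bands, use.names = FALSE))
  expect_identical(allIds, seq_len(nrow(voxelTable(idx))))

  emptyIdx <- buildVoxelIndex(PointCloud(makePoints(numeric(0), numeric(0))),
                              min_voxel_intensity = 0)
  expect_identical(partitionBands(emptyIdx), list())
})

test_that("the queue yields voxels in descending mean order above threshold", {
  # three voxels with means 900, 700, 300 in separate mz bins
  cloud <- cloudFromPoints(mz = c(500.05, 500.95, 501.85),
                           intensity = c(900, 700, 300))
  idx <- buildVoxelIndex(cloud, min_voxel_intensity = 500)
  v1 <- nextVoxel(idx); v2 <- nextVoxel(idx)
  expect_equal(v1$mean_intensity, 900)
  expect_equal(v2$mean_intensity, 700)
  expect_null(nextVoxel(idx))
})

test_that("yielded means are non-increasing on random clouds", {
  for (s in 1:5) {
    set.seed(s)
    cloud <- cloudFromPoints(mz = runif(400, 450, 470),
                             intensity = rexp(400, 1 / 100),
                             scan = sample(0:100, 400, TRUE))
    idx <- buildVoxelIndex(cloud, min_voxel_intensity = 10)
    means <- numeric(0)
    repeat {
      v <- nextVoxel(idx)
      if (is.null(v)) break
      means <- c(means, v$mean_intensity)
    }
    expect_false(is.unsorted(-means))
  }
})

test_that("retirement needs strictly more than 80% of voxel intensity", {
  # one voxel, total 1000, from points of 850 + 150
  cloud <- cloudFromPoints(mz = c(500.01, 500.02), intensity = c(850, 150))
  idx <- buildVoxelIndex(cloud, min_voxel_intensity = 0)
  expect_equal(retireVoxels(idx, which(ionData(cloud)$intensity == 850)), 1L)
  expect_null(nextVoxel(idx))  # retired voxels never yielded

  cloud <- cloudFromPoints(mz = c(500.01, 500.02), intensity = c(800, 200))
  idx <- buildVoxelIndex(cloud, min_voxel_intensity = 0)
  expect_length(retireVoxels(idx, which(ionData(cloud)$intensity == 800)), 0)
  expect_false(is.null(nextVoxel(idx)))  # kept: 80% is not > 80%
})

test_that("retirement is monotone and idempotent", {
  set.seed(12)
  cloud <- cloudFromPoints(mz = runif(200, 500, 500.5),
                           intensity = runif(200, 1, 100))
  idx1 <- buildVoxelIndex(cloud, min_voxel_intensity = 0)
  idx2 <- buildVoxelIndex(cloud, min_voxel_intensity = 0)
  refs <- sample(200, 120)
  more <- union(refs, sample(200, 60))
  r1 <- retireVoxels(idx1, refs)
  r2 <- retireVoxels(idx2, more)
  expect_true(all(r1 %in% r2))           # monotone in the point set
  expect_setequal(retireVoxels(idx1, refs), r1)  # idempotent
})

test_that("no voxel is processed twice", {
  cloud <- cloudFromPoints(mz = c(500.05, 500.95), intensity = c(10, 20))
  idx <- buildVoxelIndex(cloud, min_voxel_intensity = 0)
  ids <- c(nextVoxel(idx)$voxel_id, nextVoxel(idx)$voxel_id)
  expect_null(nextVoxel(idx))
  expect_equal(anyDuplicated(ids), 0L)
})
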