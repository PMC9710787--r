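trainedTinyModel <- local({
  model <- NULL
  function() {
    if (is.null(model)) {
      d <- syntheticLabelledFeatures(n = 400, seed = 31)
      model <<- trainClassifier(
        buildClassifier(classifierConfig(seed = 8, epochs = 30)), d)$model
    }
    model
  }
})

test_that("classification filters below threshold and preserves order", {
  feats <- FeatureSet(rbind(
    makeFeature(mono_mz = 450, coelution_coefficient = 0.95),
    makeFeature(mono_mz = 470, coelution_coefficient = 0.05),
    makeFeature(mono_mz = 490, coelution_coefficient = 0.90)))
  model <- trainedTinyModel()
  all_kept <- classifyAndFilter(feats, model, threshold = 0)
  expect_equal(length(all_kept), 3L)
  expect_true(all(!is.na(featureTable(all_kept)$identifiability_score)))
  expect_equal(featureTable(all_kept)$mono_mz, c(450, 470, 490))

  none <- classifyAndFilter(feats, model, threshold = 1)
  expect_equal(length(none), 0L)

  # retained set equals a brute-force filter by score
  scored <- featureTable(all_kept)
  kept <- classifyAndFilter(feats, model, threshold = 0.2)
  expect_equal(featureTable(kept)$mono_mz,
               scored$mono_mz[scored$identifiability_score >= 0.2])
})

test_that("missing classifier inputs are a validation error", {
  f <- featureTable(FeatureSet(makeFeature()))
  f$coelution_coefficient <- NULL
  expect_error(predictIdentifiability(trainedTinyModel(), f),
               class = "validationError")
})

test_that("dedup keeps the highest-scoring member of a duplicate group", {
  f <- FeatureSet(rbind(
    makeFeature(mono_mz = 500.000, rt_apex = 100, scan_apex = 300,
                identifiability_score = 0.9),
    makeFeature(mono_mz = 500.0025, rt_apex = 102, scan_apex = 303,
                identifiability_score = 0.4)))   # 5 ppm / 2 s / 3 scans
  kept <- deduplicateFeatures(f)
  expect_equal(length(kept), 1L)
  expect_equal(featureTable(kept)$identifiability_score, 0.9)

  far <- FeatureSet(rbind(
    makeFeature(mono_mz = 500.000, identifiability_score = 0.9),
    makeFeature(mono_mz = 500.025, identifiability_score = 0.4)))  # 50 ppm
  expect_equal(length(deduplicateFeatures(far)), 2L)
})

test_that("dedup is idempotent and leaves no close pair", {
  for (s in 1:10) {
    set.seed(s)
    n <- 30
    f <- FeatureSet(do.call(rbind, lapply(seq_len(n), function(i)
      makeFeature(mono_mz = 500 + sample(0:5, 1) * 0.002,
                  rt_apex = 100 + runif(1, 0, 12),
                  scan_apex = 300 + sample(-30:30, 1),
                  identifiability_score = runif(1)))))
    d1 <- deduplicateFeatures(f)
    d2 <- deduplicateFeatures(d1)
    expect_identical(featureTable(d2), featureTable(d1))
    ft <- featureTable(d1)
    if (nrow(ft) >= 2) {
      for (i in 1:(nrow(ft) - 1)) for (j in (i + 1):nrow(ft)) {
        close_all <- abs(ppmError(ft$mono_mz[j], ft$mono_mz[i])) <= 10 &&
          abs(ft$scan_apex[i] - ft$scan_apex[j]) <= 20 &&
          abs(ft$rt_apex[i] - ft$rt_apex[j]) <= 5
        expect_false(close_all)
      }
    }
    # survivors keep all their attributes unchanged
    orig <- featureTable(f)
    for (r in seq_len(nrow(ft)))
      expect_true(any(apply(orig, 1, function(x)
        isTRUE(all.equal(as.numeric(x), as.numeric(ft[r, ]))))))
  }
})

test_that("identical feature sets match completely, disjoint not at all", {
  f <- FeatureSet(rbind(makeFeature(mono_mz = 500, inv_k0_apex = 1.0),
                        makeFeature(mono_mz = 520, rt_apex = 150,
                                    inv_k0_apex = 1.1)))
  m <- matchFeatureSets(f, f)
  expect_equal(nrow(m$pairs), 2L)
  expect_length(m$unmatched_a, 0)
  expect_length(m$unmatched_b, 0)

  g <- FeatureSet(makeFeature(mono_mz = 900, inv_k0_apex = 1.0))
  m2 <- matchFeatureSets(f, g)
  expect_equal(nrow(m2$pairs), 0L)
  expect_length(m2$unmatched_a, 2)
})

test_that("greedy matching is within 1 of the exhaustive optimum", {
  for (s in 1:30) {
    set.seed(s)
    na <- sample(2:8, 1); nb <- sample(2:8, 1)
    a <- do.call(rbind, lapply(seq_len(na), function(i)
      makeFeature(mono_mz = 500 + sample(0:4, 1) * 0.004,
                  rt_apex = 100 + runif(1, 0, 15),
                  inv_k0_apex = 1 + runif(1, 0, 0.12))))
    b <- do.call(rbind, lapply(seq_len(nb), function(i)
      makeFeature(mono_mz = 500 + sample(0:4, 1) * 0.004,
                  rt_apex = 100 + runif(1, 0, 15),
                  inv_k0_apex = 1 + runif(1, 0, 0.12))))
    m <- matchFeatureSets(FeatureSet(a), FeatureSet(b))
    ok <- outer(seq_len(na), seq_len(nb), Vectorize(function(i, j) {
      abs(ppmError(b$mono_mz[j], a$mono_mz[i])) <= 25 &&
        abs(a$rt_apex[i] - b$rt_apex[j]) <= 5 &&
        abs(a$inv_k0_apex[i] - b$inv_k0_apex[j]) <= 0.05
    }))
    expect_gte(nrow(m$pairs), optimalMatchCount(ok) - 1L)
    expect_lte(nrow(m$pairs), optimalMatchCount(ok))
    expect_equal(anyDuplicated(m$pairs$a_row), 0L)
    expect_equal(anyDuplicated(m$pairs$b_row), 0L)
  }
})
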