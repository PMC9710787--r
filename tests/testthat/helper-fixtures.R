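# Shared fixtures and independent oracles for the suite. Everything is
# generated in code; nothing is read from disk.

# Minimal well-formed point table.
makePoints <- function(mz, intensity, scan = 0L, rt = 0, frame_id = NULL,
                       inv_k0 = NULL) {
  n <- if (length(mz) == 0) 0L else
    max(length(mz), length(intensity), length(scan), length(rt))
  rt <- rep_len(rt, n)
  if (is.null(frame_id)) frame_id <- match(rt, sort(unique(rt)))
  if (is.null(inv_k0)) inv_k0 <- 1.6 - rep_len(scan, n) / 1000
  data.frame(frame_id = rep_len(frame_id, n), rt = rt,
             scan = rep_len(as.integer(scan), n),
             inv_k0 = rep_len(inv_k0, n), mz = rep_len(mz, n),
             intensity = rep_len(intensity, n))
}

# A fully populated feature row for post-processing tests.
makeFeature <- function(mono_mz = 500, charge = 2L, intensity = 1000,
                        rt_apex = 100, scan_apex = 300,
                        num_isotopes = 4L, deconvolution_score = 50,
                        coelution_coefficient = 0.9,
                        mobility_coefficient = 0.9,
                        identifiability_score = NA_real_,
                        inv_k0_apex = 1.0) {
  data.frame(
    mono_mz = mono_mz, charge = charge, intensity = intensity,
    rt_apex = rt_apex, rt_lo = rt_apex - 3, rt_hi = rt_apex + 3,
    scan_apex = scan_apex, scan_lo = scan_apex - 20,
    scan_hi = scan_apex + 20, num_isotopes = num_isotopes,
    deconvolution_score = deconvolution_score,
    coelution_coefficient = coelution_coefficient,
    mobility_coefficient = mobility_coefficient,
    identifiability_score = identifiability_score,
    inv_k0_apex = inv_k0_apex)
}

# One explicit ground-truth row (values chosen, not sampled).
makeTruth <- function(feature_id = 1L, mono_mz = 500, charge = 2L,
                      total_intensity = 2e6, rt_apex = 100,
                      rt_sigma = 1.65, scan_apex = 300, scan_sigma = 11,
                      mz_sigma = NULL, n_isotopes = 4L) {
  if (is.null(mz_sigma)) mz_sigma <- (mono_mz / 40000) / 2.35482
  neutral <- mono_mz * charge - charge * 1.00727646688
  frac <- averagineEnvelope(neutral, n_isotopes)
  data.frame(feature_id = feature_id, mono_mz = mono_mz, charge = charge,
             total_intensity = total_intensity, rt_apex = rt_apex,
             rt_sigma = rt_sigma, scan_apex = scan_apex,
             scan_sigma = scan_sigma, mz_sigma = mz_sigma,
             n_isotopes = n_isotopes,
             envelope_fractions = paste(sprintf("%.8f", frac / sum(frac)),
                                        collapse = ";"))
}

# Noiseless 2-D spectrum of an averagine envelope (closed form).
makeEnvelopeSpectrum <- function(mono_mz = 500, charge = 2L,
                                 n_isotopes = 4L, total = 1e4) {
  neutral <- mono_mz * charge - charge * 1.00727646688
  frac <- averagineEnvelope(neutral, n_isotopes)
  data.frame(mz = mono_mz + (seq_len(n_isotopes) - 1) * 1.003355 / charge,
             intensity = total * frac)
}

# Brute-force maximum bipartite matching (exhaustive, n <= 8): the oracle
# for the greedy matcher.
optimalMatchCount <- function(ok) {
  # ok: logical matrix a x b of admissible pairs
  best <- 0L
  recurse <- function(a, usedB, count) {
    if (count + (nrow(ok) - a + 1) <= best) return()
    if (a > nrow(ok)) { best <<- max(best, count); return() }
    recurse(a + 1L, usedB, count)  # leave a unmatched
    for (b in which(ok[a, ] & !usedB)) {
      usedB2 <- usedB; usedB2[b] <- TRUE
      recurse(a + 1L, usedB2, count + 1L)
    }
  }
  if (nrow(ok) == 0 || ncol(ok) == 0) return(0L)
  recurse(1L, logical(ncol(ok)), 0L)
  best
}

# Cache the standard benchmark so several tests can share one run.
.benchCache <- new.env(parent = emptyenv())
benchmarkRun <- function() {
  if (is.null(.benchCache$run)) {
    sim <- simulateBenchmark(seed = 1)
    cfg <- detectorConfig(min_voxel_intensity = 50)
    fs <- detectFeatures(sim$cloud, cfg)
    .benchCache$run <- list(sim = sim, features = fs,
                            match = matchToTruth(fs, sim$truth))
  }
  .benchCache$run
}
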