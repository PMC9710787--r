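# Post-detection processing: identifiability filtering, de-duplication of
# nearby detections, and feature-set matching.

#' Score features and filter at the identifiability threshold
#'
#' Annotates every feature with the classifier's identifiability score
#' and removes those scoring below the threshold (0.2 by default — low
#' enough to drop only the features least likely to be identified).
#' Feature order and all other attributes are preserved.
#'
#' @param features a [FeatureSet-class].
#' @param model a trained classifier (see [trainClassifier()]).
#' @param threshold removal threshold on the score (default 0.2).
#' @return a [FeatureSet-class] of the scored survivors.
#' @export
classifyAndFilter <- function(features, model, threshold = 0.2) {
  stopifnot(is(features, "FeatureSet"))
  f <- featureTable(features)
  if (nrow(f) == 0) return(features)
  f$identifiability_score <- predictIdentifiability(model, f)
  FeatureSet(f[f$identifiability_score >= threshold, , drop = FALSE])
}

# Pairs of features within all three tolerances (mono m/z in ppm, scan
# apex, rt apex); n is expected to be moderate, pruned by an m/z sort.
closePairs <- function(f, tol_ppm, tol_scans, tol_rt) {
  n <- nrow(f)
  if (n < 2) return(matrix(integer(0), ncol = 2))
  ord <- order(f$mono_mz)
  out <- list()
  for (a in seq_len(n - 1)) {
    i <- ord[a]
    for (b in (a + 1):n) {
      j <- ord[b]
      if (f$mono_mz[j] - f$mono_mz[i] > tol_ppm * 1e-6 * f$mono_mz[i]) break
      if (abs(f$scan_apex[i] - f$scan_apex[j]) <= tol_scans &&
          abs(f$rt_apex[i] - f$rt_apex[j]) <= tol_rt)
        out[[length(out) + 1]] <- c(i, j)
    }
  }
  if (length(out) == 0) return(matrix(integer(0), ncol = 2))
  do.call(rbind, out)
}

#' De-duplicate nearby detections
#'
#' Features within 10 ppm in monoisotopic m/z, 20 scans in mobility and
#' 5 seconds in retention time of one another are considered duplicate
#' detections. Duplicate groups are the single-linkage connected
#' components of the "within tolerance" relation; from each group only
#' the member with the highest identifiability score is kept (falling
#' back to the deconvolution score when features are unscored; ties go to
#' higher intensity, then lower m/z). The result contains no pair within
#' all three tolerances.
#'
#' @param features a [FeatureSet-class].
#' @param tol_ppm,tol_scans,tol_rt the three tolerances.
#' @return the de-duplicated [FeatureSet-class].
#' @export
deduplicateFeatures <- function(features, tol_ppm = 10, tol_scans = 20,
                                tol_rt = 5) {
  stopifnot(is(features, "FeatureSet"))
  f <- featureTable(features)
  if (nrow(f) < 2) return(features)
  prs <- closePairs(f, tol_ppm, tol_scans, tol_rt)
  if (nrow(prs) == 0) return(features)
  g <- igraph::graph_from_data_frame(
    data.frame(from = prs[, 1], to = prs[, 2]), directed = FALSE,
    vertices = data.frame(name = seq_len(nrow(f))))
  member <- igraph::components(g)$membership[as.character(seq_len(nrow(f)))]
  score <- ifelse(is.na(f$identifiability_score),
                  f$deconvolution_score, f$identifiability_score)
  keep <- vapply(split(seq_len(nrow(f)), member), function(rows) {
    rows[order(-score[rows], -f$intensity[rows], f$mono_mz[rows])][1]
  }, 0L)
  FeatureSet(f[sort(keep), , drop = FALSE])
}

#' Match two feature sets by apex proximity
#'
#' Two features (one from each set) are candidate matches when their
#' apexes are within `tol_ppm` in m/z, `tol_rt` seconds in retention time
#' and `tol_inv_k0` in 1/K0. Matching is greedy nearest-neighbour in ppm
#' distance; each feature is matched at most once. (Greedy matching can
#' differ from the optimal bipartite assignment by at most a small margin
#' on pathological inputs; on well-separated features they coincide.)
#'
#' @param a,b [FeatureSet-class] objects (or feature data.frames) whose
#'   features carry `mono_mz`, `rt_apex` and `inv_k0_apex`.
#' @param tol_ppm,tol_rt,tol_inv_k0 matching tolerances (defaults 25 ppm,
#'   5 s, 0.05 1/K0).
#' @return list with `pairs` (data.frame `a_row`, `b_row`, `ppm`,
#'   `d_rt`, `d_inv_k0`), `unmatched_a` and `unmatched_b` (row indices).
#' @export
matchFeatureSets <- function(a, b, tol_ppm = 25, tol_rt = 5,
                             tol_inv_k0 = 0.05) {
  fa <- if (is(a, "FeatureSet")) featureTable(a) else as.data.frame(a)
  fb <- if (is(b, "FeatureSet")) featureTable(b) else as.data.frame(b)
  cand <- list()
  for (i in seq_len(nrow(fa))) {
    ppm <- abs(ppmError(fb$mono_mz, fa$mono_mz[i]))
    d_rt <- abs(fb$rt_apex - fa$rt_apex[i])
    d_k0 <- abs(fb$inv_k0_apex - fa$inv_k0_apex[i])
    hit <- which(ppm <= tol_ppm & d_rt <= tol_rt & d_k0 <= tol_inv_k0)
    if (length(hit) > 0)
      cand[[length(cand) + 1]] <- data.frame(
        a_row = i, b_row = hit, ppm = ppm[hit], d_rt = d_rt[hit],
        d_inv_k0 = d_k0[hit])
  }
  pairs <- data.frame(a_row = integer(0), b_row = integer(0),
                      ppm = numeric(0), d_rt = numeric(0),
                      d_inv_k0 = numeric(0))
  if (length(cand) > 0) {
    cand <- do.call(rbind, cand)
    cand <- cand[order(cand$ppm, cand$d_rt), ]
    usedA <- logical(nrow(fa)); usedB <- logical(nrow(fb))
    for (r in seq_len(nrow(cand))) {
      i <- cand$a_row[r]; j <- cand$b_row[r]
      if (!usedA[i] && !usedB[j]) {
        usedA[i] <- TRUE; usedB[j] <- TRUE
        pairs <- rbind(pairs, cand[r, ])
      }
    }
  }
  rownames(pairs) <- NULL
  list(pairs = pairs,
       unmatched_a = setdiff(seq_len(nrow(fa)), pairs$a_row),
       unmatched_b = setdiff(seq_len(nrow(fb)), pairs$b_row))
}

#' Match detected features to a ground-truth manifest
#'
#' Greedy nearest-neighbour (in ppm) matching of detected features to
#' planted ground-truth features, within `tol_ppm` on monoisotopic m/z,
#' `tol_scans` on the mobility apex and `tol_rt` seconds on the RT apex.
#' Used to measure recovery on synthetic data.
#'
#' @param features a [FeatureSet-class].
#' @param truth a ground-truth manifest (see [simulateCloud()]).
#' @param tol_ppm,tol_scans,tol_rt matching tolerances.
#' @return list with `pairs` (data.frame `feature_row`, `truth_row`,
#'   `ppm`, `charge_ok`), `recovered` (fraction of truths matched),
#'   `unmatched_truth` rows.
#' @export
matchToTruth <- function(features, truth, tol_ppm = 10, tol_scans = 20,
                         tol_rt = 5) {
  f <- featureTable(features)
  cand <- list()
  for (i in seq_len(nrow(truth))) {
    ppm <- abs(ppmError(f$mono_mz, truth$mono_mz[i]))
    hit <- which(ppm <= tol_ppm &
                   abs(f$scan_apex - truth$scan_apex[i]) <= tol_scans &
                   abs(f$rt_apex - truth$rt_apex[i]) <= tol_rt)
    if (length(hit) > 0)
      cand[[length(cand) + 1]] <- data.frame(truth_row = i,
                                             feature_row = hit,
                                             ppm = ppm[hit])
  }
  pairs <- data.frame(truth_row = integer(0), feature_row = integer(0),
                      ppm = numeric(0))
  if (length(cand) > 0) {
    cand <- do.call(rbind, cand)
    cand <- cand[order(cand$ppm), ]
    uT <- logical(nrow(truth)); uF <- logical(nrow(f))
    for (r in seq_len(nrow(cand))) {
      i <- cand$truth_row[r]; j <- cand$feature_row[r]
      if (!uT[i] && !uF[j]) {
        uT[i] <- TRUE; uF[j] <- TRUE
        pairs <- rbind(pairs, cand[r, ])
      }
    }
  }
  rownames(pairs) <- NULL
  pairs$charge_ok <- f$charge[pairs$feature_row] ==
    truth$charge[pairs$truth_row]
  list(pairs = pairs,
       recovered = if (nrow(truth) == 0) NA_real_ else
         nrow(pairs) / nrow(truth),
       unmatched_truth = setdiff(seq_len(nrow(truth)), pairs$truth_row))
}
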