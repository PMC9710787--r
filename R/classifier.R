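# Identifiability classifier: a small feed-forward network predicting
# whether a detected feature is likely to be identified from its MS2
# spectra, from four MS1-only attributes (deconvolution score, coelution
# coefficient, mobility coefficient, number of isotopes).
#
# Architecture: 4 inputs -> n_hidden dense layers, 200 units wide, each
# with batch normalisation and 40% dropout, ReLU activations -> one
# sigmoid output. Trained with Adam on binary cross-entropy. The network
# is implemented directly in R (matrix algebra via BLAS) so training is
# fully seeded and reproducible.

.CLASSIFIER_INPUTS <- c("deconvolution_score", "coelution_coefficient",
                        "mobility_coefficient", "num_isotopes")

#' Classifier configuration
#'
#' Defaults mirror the detector's training regime: dense layers 200 units
#' wide with batch normalisation and 40% dropout on each, trained for
#' 4000 epochs with batch size 512 on an 80/10/10 train/validation/test
#' split. The number of hidden layers is not architecture-critical;
#' 3 is the default. Small synthetic tasks converge in far fewer epochs
#' (pass `epochs` explicitly).
#'
#' @param n_hidden number of hidden dense layers.
#' @param hidden_width units per hidden layer.
#' @param dropout dropout rate in [0, 1).
#' @param epochs,batch_size training regime.
#' @param split train/validation/test fractions, summing to 1.
#' @param learning_rate Adam step size.
#' @param seed RNG seed for initialization, splitting and shuffling.
#' @return a classed config list.
#' @export
classifierConfig <- function(n_hidden = 3L, hidden_width = 200L,
                             dropout = 0.4, epochs = 4000L,
                             batch_size = 512L, split = c(0.8, 0.1, 0.1),
                             learning_rate = 1e-3, seed = 1L) {
  if (abs(sum(split) - 1) > 1e-9)
    tdStop("split fractions must sum to 1", "configError")
  if (dropout < 0 || dropout >= 1)
    tdStop("dropout must be in [0, 1)", "configError")
  if (n_hidden < 1 || hidden_width < 1)
    tdStop("invalid network dimensions", "configError")
  structure(list(n_hidden = as.integer(n_hidden),
                 hidden_width = as.integer(hidden_width),
                 dropout = dropout, epochs = as.integer(epochs),
                 batch_size = as.integer(batch_size), split = split,
                 learning_rate = learning_rate, seed = as.integer(seed),
                 input_names = .CLASSIFIER_INPUTS),
            class = "timsClassifierConfig")
}

#' Build an (untrained) identifiability classifier
#'
#' Weights are He-initialized under the config seed; batch-norm scales
#' start at 1, shifts at 0.
#'
#' @param config a [classifierConfig()].
#' @return a classed model list.
#' @export
buildClassifier <- function(config = classifierConfig()) {
  set.seed(config$seed)
  sizes <- c(length(config$input_names),
             rep(config$hidden_width, config$n_hidden))
  layers <- vector("list", config$n_hidden)
  for (l in seq_len(config$n_hidden)) {
    fan_in <- sizes[l]; fan_out <- sizes[l + 1]
    layers[[l]] <- list(
      W = matrix(stats::rnorm(fan_in * fan_out, 0, sqrt(2 / fan_in)),
                 fan_in, fan_out),
      b = numeric(fan_out),
      gamma = rep(1, fan_out), beta = numeric(fan_out),
      run_mean = numeric(fan_out), run_var = rep(1, fan_out))
  }
  out <- list(
    W = matrix(stats::rnorm(config$hidden_width, 0,
                            sqrt(2 / config$hidden_width)),
               config$hidden_width, 1),
    b = 0)
  structure(list(layers = layers, out = out, config = config,
                 center = NULL, scale = NULL, trained = FALSE),
            class = "timsClassifier")
}

#' Number of learnable parameters of a classifier
#'
#' Counts dense weights and biases plus the batch-norm scale and shift of
#' each hidden layer (running statistics are not learnable).
#'
#' @param model a classifier from [buildClassifier()].
#' @return integer parameter count.
#' @export
nParams <- function(model) {
  n <- 0L
  for (l in model$layers)
    n <- n + length(l$W) + length(l$b) + length(l$gamma) + length(l$beta)
  n + length(model$out$W) + length(model$out$b)
}

.BN_EPS <- 1e-5

forwardPass <- function(model, X, training = FALSE) {
  cfg <- model$config
  cache <- list()
  A <- X
  for (l in seq_along(model$layers)) {
    ly <- model$layers[[l]]
    Z <- sweep(A %*% ly$W, 2, ly$b, `+`)
    if (training) {
      mu <- colMeans(Z)
      vr <- colMeans(sweep(Z, 2, mu)^2)
    } else {
      mu <- ly$run_mean; vr <- ly$run_var
    }
    Zc <- sweep(Z, 2, mu)
    inv_sd <- 1 / sqrt(vr + .BN_EPS)
    Xhat <- sweep(Zc, 2, inv_sd, `*`)
    Y <- sweep(sweep(Xhat, 2, ly$gamma, `*`), 2, ly$beta, `+`)
    H <- pmax(Y, 0)
    if (training && cfg$dropout > 0) {
      mask <- matrix(stats::rbinom(length(H), 1, 1 - cfg$dropout),
                     nrow(H), ncol(H)) / (1 - cfg$dropout)
      Hd <- H * mask
    } else {
      mask <- NULL; Hd <- H
    }
    cache[[l]] <- list(A = A, Z = Z, mu = mu, vr = vr, Zc = Zc,
                       inv_sd = inv_sd, Xhat = Xhat, Y = Y, H = H,
                       mask = mask)
    A <- Hd
  }
  logit <- as.numeric(A %*% model$out$W + model$out$b)
  p <- 1 / (1 + exp(-logit))
  list(p = p, A = A, cache = cache)
}

# Backpropagation through dense + batchnorm + relu + dropout layers;
# returns gradients in the same shape as the parameters.
backwardPass <- function(model, fw, y) {
  m <- length(y)
  grads <- list(layers = vector("list", length(model$layers)), out = NULL)
  dlogit <- (fw$p - y) / m                     # dBCE/dlogit through sigmoid
  grads$out <- list(W = crossprod(fw$A, dlogit),
                    b = sum(dlogit))
  dA <- tcrossprod(matrix(dlogit, ncol = 1), model$out$W)
  for (l in rev(seq_along(model$layers))) {
    cc <- fw$cache[[l]]
    ly <- model$layers[[l]]
    if (!is.null(cc$mask)) dA <- dA * cc$mask
    dY <- dA * (cc$Y > 0)                      # ReLU gate
    dgamma <- colSums(dY * cc$Xhat)
    dbeta <- colSums(dY)
    dXhat <- sweep(dY, 2, ly$gamma, `*`)
    mB <- nrow(dY)
    # batch-norm backward (standard closed form)
    dZ <- sweep(dXhat -
                  matrix(colMeans(dXhat), mB, ncol(dXhat), byrow = TRUE) -
                  sweep(cc$Xhat, 2, colMeans(dXhat * cc$Xhat), `*`),
                2, cc$inv_sd, `*`)
    grads$layers[[l]] <- list(W = crossprod(cc$A, dZ), b = colSums(dZ),
                              gamma = dgamma, beta = dbeta)
    dA <- tcrossprod(dZ, ly$W)
  }
  grads
}

adamInit <- function(model) {
  zero <- function(x) {
    lapply(x, function(p) if (is.matrix(p)) p * 0 else p * 0)
  }
  list(layers = lapply(model$layers, function(l)
    list(m = zero(l[c("W", "b", "gamma", "beta")]),
         v = zero(l[c("W", "b", "gamma", "beta")]))),
    out = list(m = zero(model$out), v = zero(model$out)), t = 0L)
}

adamStep <- function(p, g, st, lr, b1 = 0.9, b2 = 0.999, eps = 1e-8, t) {
  st$m <- b1 * st$m + (1 - b1) * g
  st$v <- b2 * st$v + (1 - b2) * g^2
  mhat <- st$m / (1 - b1^t)
  vhat <- st$v / (1 - b2^t)
  list(p = p - lr * mhat / (sqrt(vhat) + eps), st = st)
}

#' Train the identifiability classifier
#'
#' Splits the labelled data into train/validation/test per the config
#' (seeded), standardizes the four inputs with statistics fitted on the
#' training split only, and trains with Adam on binary cross-entropy for
#' the configured number of epochs, shuffling each epoch. Batch-norm
#' running statistics (momentum 0.9) are used at inference.
#'
#' @param model a classifier from [buildClassifier()].
#' @param data data.frame with the four input columns and a `label`
#'   column (0/1, or the strings "identified"/"not_identified").
#' @param epochs optional override of the configured epoch count.
#' @return list with `model` (trained), `test_accuracy`,
#'   `val_accuracy`, and the per-epoch training-loss `history`.
#' @export
trainClassifier <- function(model, data, epochs = NULL) {
  cfg <- model$config
  if (!is.null(epochs)) cfg$epochs <- as.integer(epochs)
  y <- data$label
  if (is.character(y) || is.factor(y))
    y <- as.integer(as.character(y) == "identified")
  y <- as.numeric(y)
  if (length(unique(y)) < 2)
    tdStop("training data must contain both labels", "trainingError")
  if (nrow(data) < 50)
    tdStop("need at least 50 labelled features", "trainingError")
  X <- as.matrix(data[, cfg$input_names])
  if (any(!is.finite(X))) tdStop("non-finite classifier input", "trainingError")
  set.seed(cfg$seed)
  n <- nrow(X)
  idx <- sample(n)
  n_tr <- floor(cfg$split[1] * n)
  n_va <- floor(cfg$split[2] * n)
  tr <- idx[seq_len(n_tr)]
  va <- idx[n_tr + seq_len(n_va)]
  te <- idx[(n_tr + n_va + 1):n]
  center <- colMeans(X[tr, , drop = FALSE])
  scale <- apply(X[tr, , drop = FALSE], 2, stats::sd)
  scale[scale == 0] <- 1
  Xs <- sweep(sweep(X, 2, center), 2, scale, `/`)
  model$center <- center; model$scale <- scale
  st <- adamInit(model)
  history <- numeric(cfg$epochs)
  momentum <- 0.9
  for (ep in seq_len(cfg$epochs)) {
    ord <- sample(tr)
    batches <- split(ord, ceiling(seq_along(ord) / cfg$batch_size))
    ep_loss <- 0
    for (bt in batches) {
      Xb <- Xs[bt, , drop = FALSE]
      yb <- y[bt]
      fw <- forwardPass(model, Xb, training = TRUE)
      eps <- 1e-12
      ep_loss <- ep_loss - sum(yb * log(fw$p + eps) +
                                 (1 - yb) * log(1 - fw$p + eps))
      gr <- backwardPass(model, fw, yb)
      st$t <- st$t + 1L
      for (l in seq_along(model$layers)) {
        for (nm in c("W", "b", "gamma", "beta")) {
          up <- adamStep(model$layers[[l]][[nm]], gr$layers[[l]][[nm]],
                         list(m = st$layers[[l]]$m[[nm]],
                              v = st$layers[[l]]$v[[nm]]),
                         cfg$learning_rate, t = st$t)
          model$layers[[l]][[nm]] <- up$p
          st$layers[[l]]$m[[nm]] <- up$st$m
          st$layers[[l]]$v[[nm]] <- up$st$v
        }
        cc <- fw$cache[[l]]
        model$layers[[l]]$run_mean <-
          momentum * model$layers[[l]]$run_mean + (1 - momentum) * cc$mu
        model$layers[[l]]$run_var <-
          momentum * model$layers[[l]]$run_var + (1 - momentum) * cc$vr
      }
      for (nm in c("W", "b")) {
        up <- adamStep(model$out[[nm]], gr$out[[nm]],
                       list(m = st$out$m[[nm]], v = st$out$v[[nm]]),
                       cfg$learning_rate, t = st$t)
        model$out[[nm]] <- up$p
        st$out$m[[nm]] <- up$st$m
        st$out$v[[nm]] <- up$st$v
      }
    }
    history[ep] <- ep_loss / length(tr)
  }
  model$trained <- TRUE
  acc <- function(rows) {
    if (length(rows) == 0) return(NA_real_)
    p <- forwardPass(model, Xs[rows, , drop = FALSE])$p
    mean((p >= 0.5) == (y[rows] == 1))
  }
  list(model = model, test_accuracy = acc(te), val_accuracy = acc(va),
       history = history)
}

#' Predict identifiability scores for features
#'
#' @param model a trained classifier.
#' @param features a [FeatureSet-class] or data.frame with the four input
#'   columns.
#' @return numeric scores in [0, 1].
#' @export
predictIdentifiability <- function(model, features) {
  if (!isTRUE(model$trained))
    tdStop("classifier has not been trained", "validationError")
  f <- if (is(features, "FeatureSet")) featureTable(features) else features
  miss <- setdiff(model$config$input_names, names(f))
  if (length(miss) > 0)
    tdStop(paste0("features are missing classifier input(s): ",
                  paste(miss, collapse = ", ")), "validationError")
  X <- as.matrix(f[, model$config$input_names])
  if (any(!is.finite(X)))
    tdStop("non-finite classifier input attribute", "validationError")
  if (nrow(X) == 0) return(numeric(0))
  Xs <- sweep(sweep(X, 2, model$center), 2, model$scale, `/`)
  forwardPass(model, Xs)$p
}

#' Generate a synthetic labelled feature set
#'
#' Draws the four classifier inputs from plausible ranges and labels each
#' row by thresholding the coelution coefficient — a linearly separable
#' task a threshold rule solves perfectly, so a trained network should
#' approach perfect held-out accuracy. The default threshold 0.5 gives
#' balanced classes (for null-model checks with permuted labels, where
#' chance accuracy is then 0.5).
#'
#' @param n number of rows.
#' @param seed RNG seed.
#' @param rule_threshold label = 1 iff coelution coefficient exceeds this.
#' @return data.frame with the four input columns and `label` (0/1).
#' @export
syntheticLabelledFeatures <- function(n = 2000L, seed = 1L,
                                      rule_threshold = 0.5) {
  set.seed(seed)
  d <- data.frame(
    deconvolution_score = stats::runif(n, 0, 500),
    coelution_coefficient = stats::runif(n),
    mobility_coefficient = stats::runif(n),
    num_isotopes = sample(3:8, n, replace = TRUE))
  d$label <- as.integer(d$coelution_coefficient > rule_threshold)
  d
}

#' Write / read labelled training data
#'
#' Delimited text with header `deconvolution_score,coelution_coefficient,
#' mobility_coefficient,num_isotopes,label`.
#'
#' @param data data.frame of labelled features.
#' @param path file path.
#' @return `path` (write) or the data.frame (read).
#' @export
writeLabelledFeatures <- function(data, path) {
  need <- c(.CLASSIFIER_INPUTS, "label")
  data.table::fwrite(data[, need], path, sep = ",")
  invisible(path)
}

#' @rdname writeLabelledFeatures
#' @export
readLabelledFeatures <- function(path) {
  d <- data.table::fread(path, sep = ",", data.table = FALSE,
                         showProgress = FALSE)
  miss <- setdiff(c(.CLASSIFIER_INPUTS, "label"), names(d))
  if (length(miss) > 0)
    tdStop(paste0("labelled data is missing column(s): ",
                  paste(miss, collapse = ", ")), "schemaError")
  d
}
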