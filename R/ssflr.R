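# Semi-supervised factored logistic regression ("predictive pattern
# decomposition"): a linear bottleneck autoencoder and a 4-class softmax
# classifier share one latent component space and are trained jointly by
# minibatch RMSProp. The compound objective is
#
#   lambda * crossEntropy + (1 - lambda) * meanSquaredReconstruction
#     + l1 * sum|W| + l2 * sum W^2 + ortho * sum_{i != j} Cov(h)_ij^2
#
# over the three weight matrices (biases unpenalized). The encoder and
# decoder are linear with untied weights, making the model a supervised
# generalization of PCA/ICA-style matrix factorization; with lambda = 1 it
# collapses to multinomial logistic regression through a rank-k bottleneck,
# with lambda = 0 and no penalties to a least-squares autoencoder whose
# optimum is the rank-k PCA reconstruction.

#' Configuration for semi-supervised factored logistic regression
#'
#' Stated hyperparameters of the emulated analysis: `lambda = 0.5` (equally
#' weighted composite), RMSProp with learning rate 1e-4, decay `rho = 0.9`,
#' damping `epsilon = 1e-6`, at most 500 epochs and gradient clipping;
#' Gaussian initialization scaled by `gain = 0.004`, biases zero; `k = 10`
#' components. Penalty coefficients, the clipping threshold and the batch
#' size are not stated; they default to `l1 = l2 = 0.001`, `ortho = 0.1`,
#' `clipNorm = 5` and `batchSize = 100`. The Elastic-Net defaults are kept
#' small because RMSProp normalizes per coordinate: a constant L1
#' subgradient comparable to the data gradients freezes training entirely.
#'
#' @param nComponents latent dimensionality k.
#' @param lambda classification weight in `[0, 1]`.
#' @param l1,l2,ortho penalty coefficients (>= 0).
#' @param learningRate,rho,epsilon RMSProp step size, decay and damping.
#' @param maxEpochs training epoch cap.
#' @param clipNorm global gradient-norm clipping threshold.
#' @param gain scale of the Gaussian weight initialization.
#' @param batchSize minibatch size (capped at the sample count).
#' @param orthoTarget `"latent"` (off-diagonal latent covariance, default) or
#'   `"spatial"` (off-diagonal Gram matrix of decoder rows).
#' @param seed RNG seed for initialization and batch shuffling.
#' @return an [SSFLRConfig-class].
#' @export
ssflrConfig <- function(nComponents = 10L, lambda = 0.5, l1 = 0.001,
                        l2 = 0.001, ortho = 0.1, learningRate = 1e-4,
                        rho = 0.9,
                        epsilon = 1e-6, maxEpochs = 500L, clipNorm = 5.0,
                        gain = 0.004, batchSize = 100L,
                        orthoTarget = c("latent", "spatial"), seed = 1L) {
  new("SSFLRConfig", nComponents = as.integer(nComponents), lambda = lambda,
      l1 = l1, l2 = l2, ortho = ortho, learningRate = learningRate,
      rho = rho, epsilon = epsilon, maxEpochs = as.integer(maxEpochs),
      clipNorm = clipNorm, gain = gain, batchSize = as.integer(batchSize),
      orthoTarget = match.arg(orthoTarget), seed = as.integer(seed))
}

#' Initialize an SSFLR model
#'
#' All weight matrices are drawn from `gain * N(0, 1)`; all biases start at
#' exactly zero. Deterministic given `config@seed`.
#'
#' @param config an [SSFLRConfig-class].
#' @param nVoxels feature dimensionality (must be >= k).
#' @return an [SSFLRModel-class] with empty training history.
#' @export
initializeModel <- function(config, nVoxels) {
  k <- config@nComponents
  if (k > nVoxels) stop("nComponents must not exceed nVoxels")
  set.seed(stageSeed(config@seed, "ssflr_init"))
  g <- config@gain
  new("SSFLRModel",
      Wenc = matrix(g * stats::rnorm(nVoxels * k), nVoxels, k),
      benc = numeric(k),
      Wdec = matrix(g * stats::rnorm(k * nVoxels), k, nVoxels),
      bdec = numeric(nVoxels),
      Wcls = matrix(g * stats::rnorm(k * 4L), k, 4L),
      bcls = numeric(4L),
      history = emptyHistory(), config = config)
}

emptyHistory <- function() {
  data.frame(epoch = integer(), total = numeric(), reconstruction = numeric(),
             classification = numeric(), l1_term = numeric(),
             l2_term = numeric(), ortho_term = numeric())
}

modelParams <- function(model)
  list(Wenc = model@Wenc, benc = model@benc, Wdec = model@Wdec,
       bdec = model@bdec, Wcls = model@Wcls, bcls = model@bcls)

setParams <- function(model, params) {
  model@Wenc <- params$Wenc; model@benc <- params$benc
  model@Wdec <- params$Wdec; model@bdec <- params$bdec
  model@Wcls <- params$Wcls; model@bcls <- params$bcls
  model
}

softmaxRows <- function(z) {
  z <- z - apply(z, 1, max)
  e <- exp(z)
  e / rowSums(e)
}

#' Compound SSFLR objective and analytic gradients
#'
#' Evaluates the loss breakdown on a batch: mean squared reconstruction error
#' of the linear autoencoder, mean 4-class cross-entropy of the softmax
#' read-out, L1/L2 penalties over the three weight matrices, and the
#' orthogonality penalty on the off-diagonal latent covariance (or decoder
#' Gram matrix). Gradients for every parameter are computed analytically;
#' they are verified against central finite differences in the test suite.
#'
#' @param params named list (Wenc, benc, Wdec, bdec, Wcls, bcls), e.g. from
#'   an [SSFLRModel-class] or [initializeModel()].
#' @param x batch feature matrix (rows are maps; standardized).
#' @param y per-row condition labels in noun/verb/object/implied_action.
#' @param config an [SSFLRConfig-class].
#' @return list with `loss` (named list: total, reconstruction,
#'   classification, l1_term, l2_term, ortho_term) and `grads` (named list
#'   matching `params`).
#' @export
ssflrObjective <- function(params, x, y, config) {
  if (any(!is.finite(x))) stop("non-finite values in the input batch")
  n <- nrow(x); v <- ncol(x); k <- ncol(params$Wenc)
  lam <- config@lambda
  Y <- matrix(0, n, 4L)
  ci <- match(as.character(y), CONDITIONS)
  if (anyNA(ci)) stop("labels must be one of: ", paste(CONDITIONS, collapse = ", "))
  Y[cbind(seq_len(n), ci)] <- 1

  h <- x %*% params$Wenc + matrix(params$benc, n, k, byrow = TRUE)

  # reconstruction: mean over all n * v entries
  E <- h %*% params$Wdec + matrix(params$bdec, n, v, byrow = TRUE) - x
  recon <- mean(E^2)

  # classification: mean cross-entropy
  Z <- h %*% params$Wcls + matrix(params$bcls, n, 4L, byrow = TRUE)
  P <- softmaxRows(Z)
  cls <- -mean(log(pmax(P[cbind(seq_len(n), ci)], 1e-300)))

  l1t <- config@l1 * (sum(abs(params$Wenc)) + sum(abs(params$Wdec)) +
                        sum(abs(params$Wcls)))
  l2t <- config@l2 * (sum(params$Wenc^2) + sum(params$Wdec^2) +
                        sum(params$Wcls^2))

  if (config@orthoTarget == "latent") {
    hc <- sweep(h, 2, colMeans(h))
    Cv <- crossprod(hc) / n
    D <- Cv; diag(D) <- 0
    orthot <- config@ortho * sum(D^2)
  } else {
    G <- tcrossprod(params$Wdec)
    D <- G; diag(D) <- 0
    orthot <- config@ortho * sum(D^2)
  }

  total <- lam * cls + (1 - lam) * recon + l1t + l2t + orthot

  # ---- gradients ----
  dE <- (2 / (n * v)) * E                       # d recon / d (h Wdec + bdec)
  gWdec <- crossprod(h, dE) * (1 - lam)
  gbdec <- colSums(dE) * (1 - lam)
  dh <- (1 - lam) * (dE %*% t(params$Wdec))

  dZ <- (P - Y) / n                             # d cls / d logits
  gWcls <- crossprod(h, dZ) * lam
  gbcls <- colSums(dZ) * lam
  dh <- dh + lam * (dZ %*% t(params$Wcls))

  if (config@orthoTarget == "latent" && config@ortho > 0) {
    # f = sum_{i != j} C_ij^2, C = hc' hc / n  =>  df/dhc = (4/n) hc D
    dh <- dh + config@ortho * (4 / n) * (hc %*% D)
  }

  gWenc <- crossprod(x, dh)
  gbenc <- colSums(dh)

  addPen <- function(g, W)
    g + config@l1 * sign(W) + 2 * config@l2 * W
  gWenc <- addPen(gWenc, params$Wenc)
  gWdecP <- addPen(gWdec, params$Wdec)
  if (config@orthoTarget == "spatial" && config@ortho > 0)
    gWdecP <- gWdecP + config@ortho * 4 * (D %*% params$Wdec)
  gWcls <- addPen(gWcls, params$Wcls)

  list(loss = list(total = total, reconstruction = recon,
                   classification = cls, l1_term = l1t, l2_term = l2t,
                   ortho_term = orthot),
       grads = list(Wenc = gWenc, benc = gbenc, Wdec = gWdecP, bdec = gbdec,
                    Wcls = gWcls, bcls = gbcls))
}

#' One RMSProp update
#'
#' Applies global gradient-norm clipping at `config@clipNorm`, then the
#' RMSProp recursion `a <- rho a + (1 - rho) g^2`,
#' `theta <- theta - lr g / (sqrt(a) + epsilon)` coordinate-wise.
#'
#' @param params,grads named lists of parameters and matching gradients.
#' @param state accumulator list (same shapes; `NULL` initializes to zero).
#' @param config an [SSFLRConfig-class].
#' @return list with updated `params` and `state`.
#' @export
rmspropStep <- function(params, grads, state, config) {
  if (is.null(state))
    state <- lapply(params, function(p) p * 0)
  gnorm <- sqrt(sum(vapply(grads, function(g) sum(g^2), 0)))
  if (is.finite(config@clipNorm) && config@clipNorm > 0 &&
      gnorm > config@clipNorm)
    grads <- lapply(grads, function(g) g * (config@clipNorm / gnorm))
  for (nm in names(params)) {
    g <- grads[[nm]]
    state[[nm]] <- config@rho * state[[nm]] + (1 - config@rho) * g^2
    params[[nm]] <- params[[nm]] -
      config@learningRate * g / (sqrt(state[[nm]]) + config@epsilon)
  }
  list(params = params, state = state)
}

#' Fit semi-supervised factored logistic regression
#'
#' Trains the composite autoencoder + classifier by minibatch RMSProp for up
#' to `maxEpochs` epochs (batch order reshuffled per epoch under the config
#' seed), recording the loss breakdown per epoch. Returns the fitted model
#' and a [ComponentReport-class]: the k decoder rows z-scored over voxels as
#' component maps, and the 4 x k per-condition contribution matrix (see
#' [componentContributions()]).
#'
#' @param x an [ActivityDataset-class] (labels taken from its conditions) or
#'   a numeric maps x voxels matrix.
#' @param y condition labels when `x` is a matrix; ignored otherwise.
#' @param config an [SSFLRConfig-class].
#' @param standardize standardize columns (training statistics) before
#'   fitting; disable if `x` is already standardized.
#' @param verbose print the loss every 50 epochs.
#' @return list with `model` ([SSFLRModel-class]) and `report`
#'   ([ComponentReport-class]).
#' @export
fitSSFLR <- function(x, y = NULL, config = ssflrConfig(), standardize = TRUE,
                     verbose = FALSE) {
  if (is(x, "ActivityDataset")) {
    y <- conditionLabels(x)
    x <- featureMatrix(x)
  }
  if (is.null(y)) stop("labels y are required when x is a matrix")
  if (length(unique(y)) < 4L)
    stop("all four conditions must be present")
  if (standardize) x <- standardizeTrainTest(x)$train

  n <- nrow(x)
  model <- initializeModel(config, ncol(x))
  params <- modelParams(model)
  state <- NULL
  bs <- min(config@batchSize, n)
  hist <- emptyHistory()

  set.seed(stageSeed(config@seed, "ssflr_train"))
  for (epoch in seq_len(config@maxEpochs)) {
    ord <- sample.int(n)
    starts <- seq(1L, n, by = bs)
    sums <- c(total = 0, reconstruction = 0, classification = 0,
              l1_term = 0, l2_term = 0, ortho_term = 0)
    wsum <- 0
    for (s in starts) {
      idx <- ord[s:min(s + bs - 1L, n)]
      ob <- ssflrObjective(params, x[idx, , drop = FALSE], y[idx], config)
      if (!is.finite(ob$loss$total))
        stop("SSFLR training diverged (non-finite loss) at epoch ", epoch,
             "; lower the learning rate or tighten clipNorm")
      up <- rmspropStep(params, ob$grads, state, config)
      params <- up$params; state <- up$state
      w <- length(idx)
      sums <- sums + w * unlist(ob$loss)
      wsum <- wsum + w
    }
    hist <- rbind(hist, data.frame(epoch = epoch, t(sums / wsum)))
    if (verbose && epoch %% 50L == 0L)
      message(sprintf("epoch %d: total %.5g", epoch, sums[["total"]] / wsum))
  }
  model <- setParams(model, params)
  model@history <- hist
  validObject(model)

  report <- ComponentReport(model, x)
  list(model = model, report = report)
}

# z-score decoder rows over voxels; constant rows become zero.
ComponentReport <- function(model, x) {
  W <- model@Wdec
  mu <- rowMeans(W)
  sdv <- apply(W, 1, stats::sd)
  maps <- (W - mu) / ifelse(sdv > 0, sdv, 1)
  maps[sdv == 0, ] <- 0
  rownames(maps) <- sprintf("component_%02d", seq_len(nrow(maps)))
  new("ComponentReport", componentMaps = maps,
      contributions = componentContributions(model, x),
      conditionOrder = CONDITIONS)
}

#' Per-condition contributions of each latent component
#'
#' The contribution of component j to condition c is the classifier weight
#' `Wcls[j, c]` scaled by the standard deviation of the latent activation
#' `h_j` over the given data, making contributions comparable across
#' components. Signs are reported as fitted; per-component sign conventions
#' are arbitrary (flipping a component's decoder row, classifier row and
#' latent jointly leaves all predictions unchanged).
#'
#' @param model a fitted [SSFLRModel-class].
#' @param x an [ActivityDataset-class] or standardized maps x voxels matrix
#'   on which to measure latent variation.
#' @param standardize standardize a raw matrix first.
#' @return 4 x k matrix with condition rows (noun, verb, object,
#'   implied_action).
#' @export
componentContributions <- function(model, x, standardize = FALSE) {
  if (is(x, "ActivityDataset")) x <- featureMatrix(x)
  if (standardize) x <- standardizeTrainTest(x)$train
  if (nrow(model@history) == 0L)
    warning("model has no training history; contributions reflect the initialization")
  h <- x %*% model@Wenc + matrix(model@benc, nrow(x), ncol(model@Wenc),
                                 byrow = TRUE)
  sdh <- apply(h, 2, stats::sd)
  contrib <- t(model@Wcls * sdh)
  dimnames(contrib) <- list(CONDITIONS,
                            sprintf("component_%02d", seq_len(ncol(contrib))))
  contrib
}

#' Predict condition classes or probabilities from an SSFLR model
#'
#' @param object an [SSFLRModel-class].
#' @param newdata standardized maps x voxels matrix.
#' @param type `"class"` or `"prob"`.
#' @return character labels or an n x 4 probability matrix.
#' @export
setMethod("predict", "SSFLRModel", function(object, newdata,
                                            type = c("class", "prob")) {
  type <- match.arg(type)
  h <- newdata %*% object@Wenc +
    matrix(object@benc, nrow(newdata), ncol(object@Wenc), byrow = TRUE)
  P <- softmaxRows(h %*% object@Wcls +
                     matrix(object@bcls, nrow(newdata), 4L, byrow = TRUE))
  colnames(P) <- CONDITIONS
  if (type == "prob") P else CONDITIONS[max.col(P, ties.method = "first")]
})

#' Export component maps as NIfTI volumes plus a contribution table
#'
#' Writes one z-valued volume per component (zeros outside the mask) and a
#' tab-separated 4 x k contribution table with condition rows.
#'
#' @param report a [ComponentReport-class] whose maps live on the mask's
#'   voxels.
#' @param mask a [MaskVolume-class] with `nVoxelsIn` equal to the map length.
#' @param outdir output directory (created if needed).
#' @return character vector of written file paths, invisibly.
#' @export
exportComponentMaps <- function(report, mask, outdir) {
  if (ncol(report@componentMaps) != nVoxelsIn(mask))
    stop("component map length does not match mask voxel count")
  dir.create(outdir, recursive = TRUE, showWarnings = FALSE)
  k <- nrow(report@componentMaps)
  paths <- character(k)
  grid <- mask@grid
  for (j in seq_len(k)) {
    vol <- insertFeatures(report@componentMaps[j, ], mask)
    paths[j] <- file.path(outdir, sprintf("component_%02d.nii.gz", j))
    writeVolume(grid, vol, paths[j])
  }
  tsv <- file.path(outdir, "contributions.tsv")
  utils::write.table(
    data.frame(condition = rownames(report@contributions),
               report@contributions, check.names = FALSE),
    tsv, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(c(paths, tsv))
}
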