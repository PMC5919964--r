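# Cross-modal generalization: train the linear classifier on word-modality
# maps (verb vs noun), test it on picture-modality maps (implied action vs
# plain object), with train-fitted standardization, optional recursive
# feature elimination, and exact binomial significance. Plus the three
# stability perturbations (leave-one-subject-out jackknife, subject
# bootstrap, split-half).

#' Cross-modal classifier generalization
#'
#' Trains verb-vs-noun on the word-modality maps and scores the
#' action/non-action predictions on the picture-modality maps (implied
#' actions count as action, plain objects as non-action). Features are
#' standardized with training statistics only; when RFE is enabled, the
#' retained set with the best grouped cross-validated training accuracy is
#' used for the final classifier. Accuracy is reported with its one-sided
#' exact binomial p-value against chance 0.5.
#'
#' @param train word-modality [ActivityDataset-class] (noun/verb maps).
#' @param test picture-modality [ActivityDataset-class]
#'   (object/implied-action maps).
#' @param useRFE run recursive feature elimination on the training data.
#' @param halving,floorSize,nSteps,nFolds RFE settings, see [rfeSelect()].
#' @param C,loss classifier settings, see [fitLinearClassifier()].
#' @param sided binomial test sidedness, see [binomialSignificance()].
#' @param byTrial aggregate map-level predictions to one prediction per trial
#'   by majority vote (mean decision score breaks ties). Off by default: the
#'   emulated analysis scores each of the 2400 test maps.
#' @param standardize apply [standardizeTrainTest()] first (disable only if
#'   the matrices are already standardized).
#' @param seed seed for the cross-validation fold assignment inside RFE.
#' @return a [DecodingResult-class].
#' @export
crossModalGeneralize <- function(train, test, useRFE = TRUE, halving = 0.5,
                                 floorSize = 16L, nSteps = NULL, C = 1,
                                 loss = "squared_hinge",
                                 sided = c("one", "two"), byTrial = FALSE,
                                 standardize = TRUE, nFolds = 5L, seed = 1L) {
  sided <- match.arg(sided)
  if (!all(modalityLabels(train) == "word"))
    stop("training set must contain word-modality (noun/verb) maps only")
  if (!all(modalityLabels(test) == "picture"))
    stop("test set must contain picture-modality (object/implied_action) maps only")

  Xtr <- featureMatrix(train)
  Xte <- featureMatrix(test)
  ytr <- factor(conditionLabels(train), levels = c("noun", "verb"))
  if (standardize) {
    std <- standardizeTrainTest(Xtr, Xte)
    Xtr <- std$train; Xte <- std$test
  }

  rfe <- NULL
  sel <- rep(TRUE, ncol(Xtr))
  if (useRFE) {
    rfe <- rfeSelect(Xtr, ytr, groups = subjectIds(train), halving = halving,
                     floorSize = floorSize, nSteps = nSteps, C = C,
                     loss = loss, nFolds = nFolds, seed = seed)
    sel <- rfe@retained[[rfe@bestStep]]
  }

  clf <- fitLinearClassifier(Xtr[, sel, drop = FALSE], ytr, C = C, loss = loss)
  # verb-side (positive) scores map to "action", noun-side to "non_action"
  scores <- predict(clf, Xte[, sel, drop = FALSE], type = "score")
  predBinary <- ifelse(scores > 0, "action", "non_action")
  truthBinary <- binaryLabels(test)

  if (byTrial) {
    tr <- trialIds(test)
    agg <- tapply(seq_along(scores), tr, function(i) {
      votes <- sum(predBinary[i] == "action") - sum(predBinary[i] != "action")
      if (votes != 0) (if (votes > 0) "action" else "non_action")
      else if (mean(scores[i]) > 0) "action" else "non_action"
    })
    truthAgg <- tapply(truthBinary, tr, function(z) z[1])
    nCorrect <- sum(unlist(agg) == unlist(truthAgg))
    nTotal <- length(agg)
  } else {
    nCorrect <- sum(predBinary == truthBinary)
    nTotal <- length(truthBinary)
  }

  new("DecodingResult", nCorrect = as.integer(nCorrect),
      nTotal = as.integer(nTotal), accuracy = nCorrect / nTotal,
      pValue = binomialSignificance(nCorrect, nTotal, 0.5, sided),
      chance = 0.5, selectedFeatures = sel, rfe = rfe)
}

# Concatenate map subsets into a fresh dataset, relabelling subjects/trials so
# bootstrap duplicates act as distinct pseudo-subjects.
bindSubjectCopies <- function(ds, chosen) {
  keepIdx <- lapply(seq_along(chosen), function(i) {
    which(subjectIds(ds) == chosen[i])
  })
  idx <- unlist(keepIdx)
  copy <- rep(seq_along(chosen), vapply(keepIdx, length, 1L))
  ActivityDataset(featureMatrix(ds)[idx, , drop = FALSE],
    condition = conditionLabels(ds)[idx],
    subject = sprintf("%s_b%02d", subjectIds(ds)[idx], copy),
    trial = sprintf("%s_b%02d", trialIds(ds)[idx], copy),
    grid = S4Vectors::metadata(ds)$grid)
}

#' Stability of cross-modal decoding under resampling perturbations
#'
#' Reruns the full cross-modal analysis under one of three perturbation
#' schemes: `"jackknife"` leaves one subject out per iteration (one iteration
#' per subject), `"bootstrap"` resamples subjects with replacement (default
#' 100 replications), `"split_half"` trains on a random half of the training
#' trials against the full test set (default 100 iterations). Each iteration
#' records out-of-sample accuracy and binomial p; the summary reports mean
#' and sd of both.
#'
#' @param ds an [ActivityDataset-class] with both modalities.
#' @param scheme `"jackknife"`, `"bootstrap"` or `"split_half"`.
#' @param nIterations iteration count; defaults to the subject count for the
#'   jackknife and 100 otherwise.
#' @param seed seed controlling all resampling.
#' @param ... further arguments to [crossModalGeneralize()] (e.g. `useRFE`).
#' @return a [PerturbationSummary-class].
#' @export
perturbationSuite <- function(ds, scheme = c("jackknife", "bootstrap",
                                             "split_half"),
                              nIterations = NULL, seed = 1L, ...) {
  scheme <- match.arg(scheme)
  subj <- unique(subjectIds(ds))
  if (scheme %in% c("jackknife", "bootstrap") && length(subj) < 4L)
    stop("jackknife/bootstrap need at least 4 subjects")
  nIterations <- as.integer(nIterations %||%
    (if (scheme == "jackknife") length(subj) else 100L))

  accs <- numeric(nIterations)
  ps <- numeric(nIterations)
  for (it in seq_len(nIterations)) {
    itSeed <- stageSeed(seed, paste0(scheme, "_", it))
    dsIt <- switch(scheme,
      jackknife = ds[, subjectIds(ds) != subj[((it - 1L) %% length(subj)) + 1L]],
      bootstrap = {
        set.seed(itSeed)
        bindSubjectCopies(ds, sample(subj, length(subj), replace = TRUE))
      },
      split_half = ds)
    parts <- splitByModality(dsIt)
    if (scheme == "split_half") {
      set.seed(itSeed)
      trTrials <- unique(trialIds(parts$train))
      half <- sample(trTrials, floor(length(trTrials) / 2))
      parts$train <- parts$train[, trialIds(parts$train) %in% half]
    }
    res <- crossModalGeneralize(parts$train, parts$test, seed = itSeed, ...)
    accs[it] <- res@accuracy
    ps[it] <- res@pValue
  }
  new("PerturbationSummary", scheme = scheme, nIterations = nIterations,
      accuracies = accs, pValues = ps, meanAccuracy = mean(accs),
      sdAccuracy = stats::sd(accs), meanP = mean(ps), sdP = stats::sd(ps))
}
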