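# Recursive feature elimination: refit the linear classifier, rank voxels by
# absolute weight, keep the top half, repeat. Selection uses training data
# only; the step finally used for prediction is chosen by grouped
# cross-validated training accuracy, since no explicit stopping criterion is
# stated for "the optimal number of predictive voxels".

# Grouped k-fold cross-validated accuracy of the linear classifier.
cvAccuracy <- function(x, y, groups, nFolds = 5L, C = 1,
                       loss = "squared_hinge", seed = 1L) {
  n <- nrow(x)
  set.seed(seed)
  foldOf <- integer(n)
  if (is.null(groups)) {
    foldOf <- sample(rep_len(seq_len(nFolds), n))
  } else {
    g <- unique(groups)
    gf <- sample(rep_len(seq_len(min(nFolds, length(g))), length(g)))
    foldOf <- gf[match(groups, g)]
  }
  acc <- 0L
  for (f in unique(foldOf)) {
    tr <- foldOf != f
    if (length(unique(y[tr])) < 2L) next
    clf <- fitLinearClassifier(x[tr, , drop = FALSE], y[tr], C = C,
                               loss = loss)
    acc <- acc + sum(predict(clf, x[!tr, , drop = FALSE]) ==
                       as.character(y[!tr]))
  }
  acc / n
}

#' Recursive feature elimination on training data
#'
#' Starting from all features, repeatedly refits the linear classifier on the
#' retained set, ranks features by absolute weight (ties broken by lower
#' feature index) and keeps the top `floor(n * halving)`. The path runs until
#' the retained count would drop below `floorSize`, or for exactly `nSteps`
#' eliminations when given. Each step also records a grouped cross-validated
#' training accuracy; `bestStep` marks the best-scoring step. Selection never
#' sees test data.
#'
#' @param x training feature matrix.
#' @param y binary training labels.
#' @param groups optional grouping (subject IDs) for the cross-validation
#'   folds, so maps of one subject never straddle a fold boundary.
#' @param halving retained fraction per step, in (0, 1); default 0.5.
#' @param floorSize stop before going below this many features (default 16).
#' @param nSteps run exactly this many elimination steps instead of using
#'   `floorSize`.
#' @param C,loss classifier settings, see [fitLinearClassifier()].
#' @param nFolds,seed cross-validation folds and fold-assignment seed.
#' @return an [RFETrace-class] with strictly decreasing, nested retain-sets.
#' @export
rfeSelect <- function(x, y, groups = NULL, halving = 0.5, floorSize = 16L,
                      nSteps = NULL, C = 1, loss = "squared_hinge",
                      nFolds = 5L, seed = 1L) {
  x <- as.matrix(x)
  p <- ncol(x)
  if (p < 2L) stop("need at least 2 features for elimination")
  if (halving <= 0 || halving >= 1) stop("halving must lie in (0, 1)")
  y <- factor(y)

  retained <- rep(TRUE, p)
  sizes <- p
  masks <- list(retained)
  scores <- cvAccuracy(x, y, groups, nFolds, C, loss, seed)
  step <- 0L
  repeat {
    cur <- sum(retained)
    nxt <- floor(cur * halving)
    if (is.null(nSteps)) {
      if (nxt < floorSize || nxt < 1L || nxt >= cur) break
    } else {
      if (step >= nSteps || nxt < 1L || nxt >= cur) break
    }
    clf <- fitLinearClassifier(x[, retained, drop = FALSE], y, C = C,
                               loss = loss)
    idx <- which(retained)
    keepLocal <- order(-abs(clf@weights), seq_along(idx))[seq_len(nxt)]
    retained <- rep(FALSE, p)
    retained[idx[keepLocal]] <- TRUE
    step <- step + 1L
    sizes <- c(sizes, nxt)
    masks <- c(masks, list(retained))
    scores <- c(scores,
                cvAccuracy(x[, retained, drop = FALSE], y, groups, nFolds, C,
                           loss, seed))
  }
  new("RFETrace", sizes = as.integer(sizes), retained = masks,
      scores = scores, bestStep = which.max(scores))
}
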