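# Linear support-vector classifier and the exact binomial test used to judge
# out-of-sample decoding accuracy. No SVM solver ships with the installed R
# stack, so the L2-regularized (squared-)hinge objective is minimized directly
# with L-BFGS and analytic gradients; the fit is deterministic (zero init, no
# stochasticity).

#' Fit a linear support-vector classifier
#'
#' Minimizes `0.5 * ||w||^2 + C * sum_i loss(1 - y_i (x_i w + b))` with
#' squared-hinge loss (smooth; the default) or hinge loss. The decision
#' function is `sign(x w + b)`: positive scores predict `levels(y)[2]`.
#'
#' @param x numeric feature matrix (rows are maps).
#' @param y binary labels (factor or character); both classes must occur.
#' @param C regularization constant (default 1).
#' @param loss `"squared_hinge"` or `"hinge"`.
#' @param maxit L-BFGS iteration cap.
#' @return a [LinearClassifier-class].
#' @export
fitLinearClassifier <- function(x, y, C = 1, loss = c("squared_hinge", "hinge"),
                                maxit = 300L) {
  loss <- match.arg(loss)
  x <- as.matrix(x)
  if (anyNA(x) || anyNA(y)) stop("missing values are not allowed")
  y <- factor(y)
  if (nlevels(y) != 2L)
    stop("y must contain exactly two classes (got ", nlevels(y), ")")
  yn <- ifelse(as.integer(y) == 2L, 1, -1)
  p <- ncol(x)

  fn <- function(theta) {
    w <- theta[seq_len(p)]; b <- theta[p + 1L]
    m <- 1 - yn * (drop(x %*% w) + b)
    act <- pmax(m, 0)
    pen <- if (loss == "squared_hinge") sum(act^2) else sum(act)
    0.5 * sum(w^2) + C * pen
  }
  gr <- function(theta) {
    w <- theta[seq_len(p)]; b <- theta[p + 1L]
    m <- 1 - yn * (drop(x %*% w) + b)
    act <- m > 0
    coefv <- if (loss == "squared_hinge") 2 * m * act else as.numeric(act)
    gw <- w - C * drop(crossprod(x, yn * coefv))
    gb <- -C * sum(yn * coefv)
    c(gw, gb)
  }
  fit <- stats::optim(numeric(p + 1L), fn, gr, method = "L-BFGS-B",
                      control = list(maxit = maxit, factr = 1e7))
  new("LinearClassifier", weights = fit$par[seq_len(p)],
      bias = fit$par[p + 1L], levels = levels(y), loss = loss, cost = C)
}

#' Predict from a linear classifier
#'
#' @param object a [LinearClassifier-class].
#' @param newdata feature matrix with the training column count.
#' @param type `"class"` for labels, `"score"` for the decision values.
#' @return character vector of labels, or numeric scores.
#' @export
setMethod("predict", "LinearClassifier", function(object, newdata,
                                                  type = c("class", "score")) {
  type <- match.arg(type)
  newdata <- as.matrix(newdata)
  if (ncol(newdata) != length(object@weights))
    stop("newdata has ", ncol(newdata), " features; classifier expects ",
         length(object@weights))
  s <- drop(newdata %*% object@weights) + object@bias
  if (type == "score") s else ifelse(s > 0, object@levels[2], object@levels[1])
})

#' Exact binomial significance of a decoding accuracy
#'
#' One-sided exact tail probability `P(X >= nCorrect)` for
#' `X ~ Binomial(nTotal, chance)`, computed by direct log-space summation of
#' the binomial probability mass (numerically stable for thousands of
#' trials). The one-sided test matches the directional hypothesis that
#' decoding exceeds chance; `sided = "two"` doubles the smaller tail (capped
#' at 1).
#'
#' @param nCorrect,nTotal correct predictions out of total predictions.
#' @param chance chance success probability, strictly inside (0, 1).
#' @param sided `"one"` (default) or `"two"`.
#' @return the p-value.
#' @examples
#' binomialSignificance(1292, 2400)   # the worked example: ~9.3e-5
#' @export
binomialSignificance <- function(nCorrect, nTotal, chance = 0.5,
                                 sided = c("one", "two")) {
  sided <- match.arg(sided)
  if (chance <= 0 || chance >= 1) stop("chance must lie strictly in (0, 1)")
  if (nCorrect < 0 || nCorrect > nTotal)
    stop("nCorrect must lie in [0, nTotal]")
  upper <- exp(logSumExp(stats::dbinom(nCorrect:nTotal, nTotal, chance,
                                       log = TRUE)))
  upper <- min(1, upper)
  if (sided == "one") return(upper)
  lower <- exp(logSumExp(stats::dbinom(0:nCorrect, nTotal, chance,
                                       log = TRUE)))
  min(1, 2 * min(upper, lower))
}
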