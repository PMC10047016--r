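#' Fit a penalized linear discriminant analysis
#'
#' Fisher's linear discriminant with a ridge-penalized within-class scatter,
#' suited to many highly correlated predictors such as adjacent radial
#' histogram bands: the discriminant direction is
#' `w = (S_w + penalty * I)^-1 (mu_pos - mu_neg)`, where `S_w` is the pooled
#' within-class covariance. The decision threshold on the projected score is
#' the midpoint of the projected class means shifted by the log prior odds,
#' so class imbalance moves the cut toward the rarer class. Higher score
#' means positive class.
#'
#' @param X numeric matrix, cases in rows
#' @param y binary labels (0/1, logical, or 2-level factor; the second level
#'   / 1 / TRUE is the positive class)
#' @param penalty non-negative ridge penalty on the within-class covariance
#' @param feature_set tag recorded on the model
#' @return object of class `plda`: `direction`, `class_means` (2 x p),
#'   `threshold`, `penalty`, `priors`, `feature_set`
#' @export
fit_plda <- function(X, y, penalty = 0, feature_set = "features") {
  X <- as.matrix(X)
  y <- to_binary(y)
  if (penalty < 0) stop("penalty must be >= 0", call. = FALSE)
  n1 <- sum(y == 1L); n0 <- sum(y == 0L)
  if (n1 < 2L || n0 < 2L)
    stop("need at least 2 cases per class", call. = FALSE)
  if (!all(is.finite(X))) stop("non-finite feature values", call. = FALSE)

  mu1 <- colMeans(X[y == 1L, , drop = FALSE])
  mu0 <- colMeans(X[y == 0L, , drop = FALSE])
  c1 <- sweep(X[y == 1L, , drop = FALSE], 2, mu1)
  c0 <- sweep(X[y == 0L, , drop = FALSE], 2, mu0)
  sw <- (crossprod(c1) + crossprod(c0)) / (n1 + n0 - 2)

  p <- ncol(X)
  w <- tryCatch(
    solve(sw + penalty * diag(p), mu1 - mu0),
    error = function(e)
      stop("within-class scatter is singular (p >= n or collinear ",
           "features); use a positive penalty", call. = FALSE))
  if (!all(is.finite(w)) || all(w == 0))
    stop("degenerate discriminant direction", call. = FALSE)

  m1 <- sum(w * mu1); m0 <- sum(w * mu0)
  threshold <- (m1 + m0) / 2 - log(n1 / n0)
  structure(list(direction = w,
                 class_means = rbind(negative = mu0, positive = mu1),
                 threshold = threshold, penalty = penalty,
                 priors = c(negative = n0, positive = n1) / (n0 + n1),
                 feature_set = feature_set),
            class = "plda")
}

#' Predict from a fitted PLDA model
#'
#' @param object a `plda` model
#' @param newdata feature matrix with the model's feature dimension
#' @param ... unused
#' @return list with `score` (continuous discriminant score `w . x`) and
#'   `label` (integer 0/1; scores exactly at the threshold go to the
#'   negative class)
#' @export
predict.plda <- function(object, newdata, ...) {
  newdata <- as.matrix(newdata)
  if (ncol(newdata) != length(object$direction))
    stop("feature dimension ", ncol(newdata), " does not match model (",
         length(object$direction), ")", call. = FALSE)
  score <- as.vector(newdata %*% object$direction)
  list(score = score, label = as.integer(score > object$threshold))
}

#' @rdname predict.plda
#' @param model a `plda` model
#' @param X feature matrix
#' @export
predict_plda <- function(model, X) predict.plda(model, X)

# coerce labels to integer 0/1 with 1 = positive class
to_binary <- function(y) {
  if (is.factor(y)) {
    if (nlevels(y) != 2L) stop("labels must have 2 levels", call. = FALSE)
    as.integer(y == levels(y)[2])
  } else if (is.logical(y)) {
    as.integer(y)
  } else {
    y <- as.integer(y)
    if (!all(y %in% c(0L, 1L)))
      stop("labels must be binary 0/1", call. = FALSE)
    y
  }
}
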