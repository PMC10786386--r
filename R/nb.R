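#' Bernoulli naive Bayes with Laplace smoothing
#'
#' Fits the classifier used by the referral prediction model: binary
#' features, class priors equal to training class frequencies, and
#' per-feature Bernoulli probabilities smoothed as
#' `P(x = 1 | class) = (count + alpha) / (n_class + 2 alpha)` with
#' `alpha = 1` by default, so no probability is ever exactly 0 or 1.
#' Prediction maximizes the posterior computed in log space; an exact
#' posterior tie is broken conservatively toward class 0 (no referral).
#'
#' @param x Binary (0/1) feature matrix, one row per observation.
#' @param y Binary labels (0/1 vector) with both classes present.
#' @param alpha Laplace smoothing parameter (default 1).
#' @return An object of class `bernoulli_nb` with elements `log_prior`,
#'   `prob1` (feature x class matrix of smoothed P(x = 1 | class)),
#'   `classes` and `alpha`.
#' @examples
#' x <- matrix(c(1, 1, 0, 0, 1), ncol = 1)
#' y <- c(1, 1, 0, 0, 0)
#' fit <- fit_bernoulli_nb(x, y)
#' fit$prob1  # P(x=1|y=1) = 3/4, P(x=1|y=0) = 2/5
#' predict(fit, matrix(1, 1, 1))
#' @export
fit_bernoulli_nb <- function(x, y, alpha = 1) {
  x <- as.matrix(x)
  y <- as.integer(y)
  stopifnot(length(y) == nrow(x), all(y %in% c(0L, 1L)),
            all(x %in% c(0, 1)), alpha > 0)
  if (length(unique(y)) < 2) {
    stop("training data contain a single class; oversample the minority ",
         "class before fitting")
  }
  n0 <- sum(y == 0L)
  n1 <- sum(y == 1L)
  count1 <- colSums(x[y == 1L, , drop = FALSE])
  count0 <- colSums(x[y == 0L, , drop = FALSE])
  prob1 <- cbind(`0` = (count0 + alpha) / (n0 + 2 * alpha),
                 `1` = (count1 + alpha) / (n1 + 2 * alpha))
  rownames(prob1) <- colnames(x)
  structure(list(
    log_prior = c(`0` = log(n0 / length(y)), `1` = log(n1 / length(y))),
    prob1 = prob1,
    classes = c(0L, 1L),
    alpha = alpha,
    n_features = ncol(x)
  ), class = "bernoulli_nb")
}

# Decision margin log P(1|x) - log P(0|x) up to normalization; class 1 is
# predicted iff the margin is strictly positive (ties go to class 0).
nb_margin <- function(object, x) {
  x <- as.matrix(x)
  w <- (log(object$prob1[, "1"]) - log(1 - object$prob1[, "1"])) -
       (log(object$prob1[, "0"]) - log(1 - object$prob1[, "0"]))
  b <- sum(log(1 - object$prob1[, "1"]) - log(1 - object$prob1[, "0"])) +
    object$log_prior[["1"]] - object$log_prior[["0"]]
  drop(x %*% w) + b
}

#' @param object A `bernoulli_nb` fit.
#' @param newdata Binary feature matrix with the training column layout.
#' @param type `"class"` for 0/1 predictions, `"posterior"` for class
#'   probabilities.
#' @param ... Unused.
#' @rdname fit_bernoulli_nb
#' @export
predict.bernoulli_nb <- function(object, newdata,
                                 type = c("class", "posterior"), ...) {
  type <- match.arg(type)
  newdata <- as.matrix(newdata)
  stopifnot(ncol(newdata) == object$n_features)
  margin <- nb_margin(object, newdata)
  if (type == "class") {
    return(as.integer(margin > 0))
  }
  p1 <- 1 / (1 + exp(-margin))
  cbind(`0` = 1 - p1, `1` = p1)
}

#' @export
print.bernoulli_nb <- function(x, ...) {
  cat("Bernoulli naive Bayes:", x$n_features, "features, priors",
      sprintf("P(0)=%.3f P(1)=%.3f", exp(x$log_prior[["0"]]),
              exp(x$log_prior[["1"]])),
      sprintf("(Laplace alpha = %g)\n", x$alpha))
  invisible(x)
}

#' Balanced accuracy
#'
#' The mean of sensitivity and specificity,
#' `score = (TP/(TP+FN) + TN/(TN+FP)) / 2`, suitable for highly imbalanced
#' labels; predicting the majority class everywhere scores 0.5. Undefined
#' (an error) when the true labels contain a single class.
#'
#' @param predictions,labels Binary (0/1) vectors of equal length.
#' @return A scalar in [0, 1].
#' @export
balanced_accuracy <- function(predictions, labels) {
  predictions <- as.integer(predictions)
  labels <- as.integer(labels)
  stopifnot(length(predictions) == length(labels))
  if (length(unique(labels)) < 2) {
    stop("balanced accuracy is undefined when labels contain a single class")
  }
  pos <- labels == 1L
  (mean(predictions[pos] == 1L) + mean(predictions[!pos] == 0L)) / 2
}
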