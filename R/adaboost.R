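# AdaBoost.M1 with classification-tree base learners.

#' AdaBoost.M1 classifier on recursive-partitioning trees
#'
#' Classic discrete AdaBoost for a binary response: at each round a weighted
#' classification tree is fitted, its weighted training error `e` determines
#' the learner weight `log((1 - e) / e)`, and misclassified observations are
#' upweighted.  Rounds with error >= 0.5 terminate the boosting; a perfect
#' round is kept with a capped weight.
#'
#' @param formula Model formula with a 0/1 (or two-level factor) response.
#' @param data Training data.
#' @param n_iter Number of boosting rounds (default 10).
#' @param control An [rpart::rpart.control()] for the base trees.
#' @return An object of class `cs_adaboost` with a [predict.cs_adaboost()]
#'   method.
#' @export
cs_adaboost <- function(formula, data, n_iter = 10,
                        control = rpart::rpart.control(maxdepth = 5,
                                                       cp = 0.01, xval = 0)) {
  mf <- stats::model.frame(formula, data, na.action = stats::na.omit)
  y <- factor(mf[[1]])
  if (nlevels(y) != 2) stop("binary response required", call. = FALSE)
  n <- nrow(mf)
  w <- rep(1 / n, n)
  trees <- list()
  alphas <- numeric()
  for (m in seq_len(n_iter)) {
    dat <- mf
    dat$.boost_w <- w
    fit <- rpart::rpart(formula, data = dat, weights = .boost_w,
                        method = "class", control = control)
    pred <- stats::predict(fit, mf, type = "class")
    mis <- pred != y
    err <- sum(w[mis])
    if (err >= 0.5) break
    err <- max(err, 1e-10)
    a <- log((1 - err) / err)
    trees[[length(trees) + 1]] <- fit
    alphas <- c(alphas, a)
    if (sum(mis) == 0) break
    w <- w * exp(a * mis)
    w <- w / sum(w)
  }
  if (length(trees) == 0) {
    # degenerate: fall back to the majority class
    trees <- list(NULL)
    alphas <- 1
  }
  structure(list(trees = trees, alphas = alphas, levels = levels(y),
                 majority = levels(y)[which.max(table(y))],
                 formula = formula),
            class = "cs_adaboost")
}

#' Predict method for AdaBoost.M1 fits
#' @param object A `cs_adaboost` fit.
#' @param newdata Data frame of predictors.
#' @param ... Unused.
#' @return Factor of predicted classes with the training levels.
#' @export
predict.cs_adaboost <- function(object, newdata, ...) {
  lv <- object$levels
  if (is.null(object$trees[[1]])) {
    return(factor(rep(object$majority, nrow(newdata)), levels = lv))
  }
  score <- rep(0, nrow(newdata))
  for (m in seq_along(object$trees)) {
    p <- stats::predict(object$trees[[m]], newdata, type = "class")
    score <- score + object$alphas[m] * ifelse(p == lv[2], 1, -1)
  }
  factor(ifelse(score >= 0, lv[2], lv[1]), levels = lv)
}
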