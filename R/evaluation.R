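# Repeated-holdout classifier evaluation: stratified splits, five
# classifiers, confusion counting, and the averaged performance measures.

#' Stratified train/test split
#'
#' Random split preserving the class proportions within rounding; the
#' per-class training count is clamped so both classes appear on both sides
#' (requires at least two records per class).  Deterministic given the seed.
#'
#' @param cohort Data frame with a 0/1 `y` column.
#' @param train_fraction Fraction of each class assigned to training
#'   (default 0.7).
#' @param seed Integer seed.
#' @return List with integer index vectors `train` and `test`.
#' @export
holdout_split <- function(cohort, train_fraction = 0.7, seed = 1) {
  if (train_fraction <= 0 || train_fraction >= 1) {
    stop("train_fraction must be in (0, 1)", call. = FALSE)
  }
  y <- cohort$y
  classes <- sort(unique(y))
  if (length(classes) < 2) {
    stop("cohort must contain both classes", call. = FALSE)
  }
  set.seed(seed)
  train <- integer()
  for (cl in classes) {
    idx <- which(y == cl)
    if (length(idx) < 2) {
      stop("class ", cl, " has fewer than 2 records; cannot stratify",
           call. = FALSE)
    }
    k <- round(train_fraction * length(idx))
    k <- min(max(k, 1), length(idx) - 1)
    train <- c(train, sample(idx, k))
  }
  train <- sort(train)
  list(train = train, test = setdiff(seq_len(nrow(cohort)), train))
}

#' Fit a named classifier and predict test labels
#'
#' The five classifiers and their configurations: naive Bayes (no Laplace
#' smoothing, missing values passed through), random forest (500 trees,
#' complete-case training), logistic regression (logit link, probability
#' threshold 0.5), AdaBoost.M1 with 10 rounds of classification trees, and a
#' polynomial-kernel support vector machine (cost 100, unscaled inputs).
#'
#' @param classifier One of `"nb"`, `"rf"`, `"lr"`, `"adaboost"`, `"svm"`.
#' @param train,test Data frames with the feature columns and a 0/1 `y`.
#' @param features Feature columns to use.
#' @param config Optional overrides: `ntree`, `n_iter`, `cost`, `kernel`,
#'   `threshold`.
#' @return Integer vector of 0/1 predictions for `test` (NA where a test
#'   record could not be scored).
#' @export
fit_predict <- function(classifier = c("nb", "rf", "lr", "adaboost", "svm"),
                        train, test, features, config = list()) {
  classifier <- match.arg(classifier)
  if (length(features) == 0) stop("empty feature set", call. = FALSE)
  fml <- stats::as.formula(paste("y ~", paste(features, collapse = " + ")))
  tr <- train[c("y", features)]
  tr$y <- factor(tr$y, levels = c(0, 1))
  te <- test[features]
  n_te <- nrow(test)
  cc <- stats::complete.cases(te)
  pred <- rep(NA_integer_, n_te)
  as01 <- function(f) as.integer(as.character(f))
  if (classifier == "nb") {
    fit <- e1071::naiveBayes(fml, data = tr, laplace = 0,
                             na.action = stats::na.pass)
    pred <- as01(stats::predict(fit, test))
  } else if (classifier == "rf") {
    ntree <- config$ntree %||% 500
    fit <- randomForest::randomForest(fml, data = tr, ntree = ntree,
                                      na.action = stats::na.omit)
    pred[cc] <- as01(stats::predict(fit, test[cc, , drop = FALSE]))
  } else if (classifier == "lr") {
    fit <- suppressWarnings(
      stats::glm(fml, family = stats::binomial("logit"),
                 data = tr[stats::complete.cases(tr), , drop = FALSE],
                 control = stats::glm.control(maxit = 50)))
    thr <- config$threshold %||% 0.5
    p <- suppressWarnings(
      stats::predict(fit, newdata = test[cc, , drop = FALSE],
                     type = "response"))
    pred[cc] <- as.integer(p > thr)
  } else if (classifier == "adaboost") {
    n_iter <- config$n_iter %||% 10
    fit <- cs_adaboost(fml, data = tr[stats::complete.cases(tr), ,
                                      drop = FALSE], n_iter = n_iter)
    pred[cc] <- as01(stats::predict(fit, test[cc, , drop = FALSE]))
  } else if (classifier == "svm") {
    fit <- e1071::svm(fml, data = tr[stats::complete.cases(tr), ,
                                     drop = FALSE],
                      type = "C-classification",
                      kernel = config$kernel %||% "polynomial",
                      cost = config$cost %||% 100, scale = FALSE,
                      na.action = stats::na.omit)
    pred[cc] <- as01(stats::predict(fit, test[cc, , drop = FALSE]))
  }
  pred
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Confusion counts for binary predictions
#'
#' Orientation: class 0 is negative, class 1 positive; `tn` counts class-0
#' records predicted 0, `fp` class-0 predicted 1, `fn` class-1 predicted 0,
#' `tp` class-1 predicted 1.  Predictions of `NA` are dropped from the counts
#' (with the dropped number recorded in the `n_dropped` attribute).
#'
#' @param predicted,truth Equal-length 0/1 vectors.
#' @return Named integer vector of class `cs_confusion`
#'   (`tn`, `fp`, `fn`, `tp`).
#' @export
confusion <- function(predicted, truth) {
  if (length(predicted) != length(truth)) {
    stop("predicted and truth must have equal length", call. = FALSE)
  }
  keep <- !is.na(predicted) & !is.na(truth)
  p <- predicted[keep]; tr <- truth[keep]
  out <- c(tn = sum(tr == 0 & p == 0), fp = sum(tr == 0 & p == 1),
           fn = sum(tr == 1 & p == 0), tp = sum(tr == 1 & p == 1))
  structure(as.integer(out), names = names(out), class = "cs_confusion",
            n_dropped = sum(!keep))
}

#' Aggregate confusion counts over holdout iterations
#'
#' Accuracy is `(tn + tp) / total * 100` per iteration, averaged with its
#' standard deviation over the `J - 1` denominator (a single iteration yields
#' `NA`, never 0).  Average sensitivity `ASe = mean(tp / (tp + fn)) * 100`,
#' specificity `ASp = mean(tn / (tn + fp)) * 100`, and positive predictive
#' value `ATPP = mean(tp / (tp + fp)) * 100` skip iterations whose denominator
#' is zero (the affected count is reported, never averaged in as 0).
#'
#' @param counts A list of `cs_confusion` vectors (or a 4-column matrix with
#'   columns tn, fp, fn, tp).
#' @return List with `mu_accuracy`, `sigma_accuracy`, `ase`, `asp`, `atpp`
#'   (percent), `n_undefined` (per measure), and the per-iteration matrix.
#' @export
aggregate_confusion <- function(counts) {
  m <- if (is.matrix(counts)) counts else do.call(rbind, counts)
  colnames(m) <- c("tn", "fp", "fn", "tp")
  if (nrow(m) == 0) stop("no iterations to aggregate", call. = FALSE)
  total <- rowSums(m)
  acc <- (m[, "tn"] + m[, "tp"]) / total * 100
  rate <- function(num, den) {
    r <- ifelse(den > 0, num / den * 100, NA_real_)
    list(mean = if (all(is.na(r))) NA_real_ else mean(r, na.rm = TRUE),
         undefined = sum(is.na(r)))
  }
  se <- rate(m[, "tp"], m[, "tp"] + m[, "fn"])
  sp <- rate(m[, "tn"], m[, "tn"] + m[, "fp"])
  pp <- rate(m[, "tp"], m[, "tp"] + m[, "fp"])
  list(mu_accuracy = mean(acc),
       sigma_accuracy = if (nrow(m) > 1) stats::sd(acc) else NA_real_,
       ase = se$mean, asp = sp$mean, atpp = pp$mean,
       n_undefined = c(sensitivity = se$undefined,
                       specificity = sp$undefined, tpp = pp$undefined),
       per_iteration = m, accuracy = acc)
}

#' Run a multiple-holdout classification experiment
#'
#' Optionally performs feature selection once on the full cohort (matching
#' the convention of fixed per-model variable lists), then repeats a
#' stratified holdout split, fits the classifier on the training part, and
#' accumulates confusion counts over the iterations.  With `nested = TRUE`
#' the selection is re-run inside every iteration on the training part only,
#' for leakage-sensitivity analysis.
#'
#' @param cohort A `cs_cohort` (indicators are attached if absent).
#' @param classifier One of `"nb"`, `"rf"`, `"lr"`, `"adaboost"`, `"svm"`.
#' @param features Explicit feature columns; alternatively give `scenario`
#'   (and optionally `criterion`) to derive them.
#' @param scenario 1 or 2, used when `features` is NULL.
#' @param criterion Optional selection criterion name for [cs_select()].
#' @param iterations Number of holdout repetitions (default 100).
#' @param train_fraction Training fraction per split (default 0.7).
#' @param seed Master seed; the whole experiment is reproducible from it.
#' @param nested Re-select features inside each iteration.
#' @param config Classifier configuration overrides (see [fit_predict()]).
#' @return Object of class `cs_holdout`.
#' @export
run_experiment <- function(cohort, classifier, features = NULL,
                           scenario = NULL, criterion = NULL,
                           iterations = 100, train_fraction = 0.7, seed = 1,
                           nested = FALSE, config = list()) {
  if (!all(cs_indicator_names() %in% names(cohort)) &&
      all(c("sbp", "dbp", "hr") %in% names(cohort))) {
    cohort <- add_indicators(cohort)
  }
  if (is.null(features)) {
    if (is.null(scenario)) stop("give either features or scenario",
                                call. = FALSE)
    features <- scenario_features(cohort, scenario)
  }
  selection <- NULL
  if (!is.null(criterion) && !nested) {
    selection <- cs_select(cohort, features, criterion)
    features <- selection$kept
  }
  set.seed(seed)
  iter_seeds <- sample.int(.Machine$integer.max - 1, iterations)
  counts <- matrix(0L, iterations, 4,
                   dimnames = list(NULL, c("tn", "fp", "fn", "tp")))
  for (j in seq_len(iterations)) {
    sp <- holdout_split(cohort, train_fraction, seed = iter_seeds[j])
    train <- as.data.frame(cohort)[sp$train, , drop = FALSE]
    test <- as.data.frame(cohort)[sp$test, , drop = FALSE]
    feats_j <- features
    if (nested && !is.null(criterion)) {
      feats_j <- cs_select(train, features, criterion)$kept
    }
    set.seed(iter_seeds[j])
    pred <- fit_predict(classifier, train, test, feats_j, config)
    counts[j, ] <- confusion(pred, test$y)
  }
  agg <- aggregate_confusion(counts)
  structure(c(agg, list(config = list(classifier = classifier,
                                      features = features,
                                      scenario = scenario,
                                      criterion = criterion,
                                      iterations = iterations,
                                      train_fraction = train_fraction,
                                      seed = seed, nested = nested),
                        selection = selection)),
            class = "cs_holdout")
}

#' @export
print.cs_holdout <- function(x, ...) {
  cfg <- x$config
  cat("Multiple holdout:", cfg$classifier, "-", cfg$iterations,
      "iterations, train fraction", cfg$train_fraction, "\n")
  cat(sprintf("  Accuracy: %.2f (%s)\n", x$mu_accuracy,
              if (is.na(x$sigma_accuracy)) "NA"
              else sprintf("%.2f", x$sigma_accuracy)))
  fmt <- function(v) if (is.na(v)) "NA" else sprintf("%.2f", v)
  cat("  ASe:", fmt(x$ase), " ASp:", fmt(x$asp), " ATPP:", fmt(x$atpp), "\n")
  if (any(x$n_undefined > 0)) {
    cat("  Undefined iterations skipped:",
        paste(names(x$n_undefined), x$n_undefined, collapse = ", "), "\n")
  }
  invisible(x)
}

#' @export
summary.cs_holdout <- function(object, ...) {
  print(object)
  cat("  Features:", paste(object$config$features, collapse = ", "), "\n")
  invisible(object)
}
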