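test_that("holdout split stratifies and is seed-deterministic", {
  co <- data.frame(y = rep(c(0L, 1L), each = 50))
  sp <- holdout_split(co, 0.7, seed = 14)
  expect_identical(length(sp$train), 70L)
  expect_identical(length(sp$test), 30L)
  expect_identical(sum(co$y[sp$train]), 35L)
  expect_identical(sum(co$y[sp$test]), 15L)
  sp2 <- holdout_split(co, 0.7, seed = 14)
  expect_identical(sp, sp2)
  expect_false(identical(sp, holdout_split(co, 0.7, seed = 15)))
  expect_error(holdout_split(data.frame(y = rep(1L, 10)), 0.7, 1),
               "both classes")
  expect_error(holdout_split(co, 1.2, 1), "train_fraction")
})

test_that("confusion counts follow the class-0-negative orientation", {
  expect_identical(unclass(confusion(c(0, 1, 0, 1), c(0, 1, 0, 1)))[1:4],
                   c(tn = 2L, fp = 0L, fn = 0L, tp = 2L))
  expect_identical(unclass(confusion(c(1, 0, 1, 0), c(0, 1, 0, 1)))[1:4],
                   c(tn = 0L, fp = 2L, fn = 2L, tp = 0L))
  expect_identical(unclass(confusion(c(1, 1, 0, 0), c(0, 1, 0, 1)))[1:4],
                   c(tn = 1L, fp = 1L, fn = 1L, tp = 1L))
  expect_error(confusion(c(0, 1), c(0, 1, 1)), "equal length")
  # NA predictions are dropped, not counted
  cf <- confusion(c(0, NA, 1), c(0, 1, 1))
  expect_identical(sum(cf), 2L)
  expect_identical(attr(cf, "n_dropped"), 1L)
})

test_that("aggregation reproduces the hand-computed performance measures", {
  one <- aggregate_confusion(matrix(c(50, 5, 5, 40), 1,
                                    dimnames = list(NULL,
                                                    c("tn", "fp", "fn", "tp"))))
  expect_equal(one$mu_accuracy, 90)
  expect_equal(one$ase, 40 / 45 * 100)
  expect_equal(one$asp, 50 / 55 * 100)
  expect_equal(one$atpp, 40 / 45 * 100)
  expect_true(is.na(one$sigma_accuracy))  # a single iteration has no SD

  same <- aggregate_confusion(matrix(rep(c(50, 5, 5, 40), each = 5), 5))
  expect_equal(same$sigma_accuracy, 0)

  # accuracies 80 and 90: mean 85, SD with the (J-1) denominator
  two <- aggregate_confusion(rbind(c(40, 10, 10, 40), c(45, 5, 5, 45)))
  expect_equal(two$mu_accuracy, 85)
  expect_equal(two$sigma_accuracy, sqrt((25 + 25) / 1))
  expect_equal(two$sigma_accuracy, 7.0711, tolerance = 1e-4)
})

test_that("zero-denominator iterations contribute missingness, not zeros", {
  m <- rbind(c(10, 0, 0, 0),    # no positives in test: sensitivity undefined
             c(5, 0, 1, 4))
  agg <- aggregate_confusion(m)
  expect_equal(agg$ase, 80)               # only the defined iteration
  expect_identical(agg$n_undefined[["sensitivity"]], 1L)
  expect_identical(agg$n_undefined[["tpp"]], 1L)
  all_undef <- aggregate_confusion(rbind(c(10, 0, 0, 0)))
  expect_true(is.na(all_undef$ase))
})

test_that("every classifier separates a linearly separable cohort", {
  co <- make_separable_cohort(n = 200, seed = 2)
  for (clf in c("nb", "rf", "lr", "adaboost", "svm")) {
    res <- run_experiment(co, clf, features = c("f1", "f2"),
                          iterations = 10, seed = 4)
    expect_gte(res$mu_accuracy, 90)
  }
})

test_that("classifiers sit at chance on label-independent features", {
  co <- make_null_cohort(n = 1000, p_pos = 0.5, seed = 6)
  for (clf in c("lr", "nb")) {
    res <- run_experiment(co, clf, features = c("f1", "f2"),
                          iterations = 10, seed = 8)
    expect_gte(res$mu_accuracy, 45)
    expect_lte(res$mu_accuracy, 55)
  }
})

test_that("logistic regression on a constant feature predicts the majority", {
  train <- data.frame(c1 = rep(1, 100), y = rep(c(0L, 1L), c(60, 40)))
  test <- data.frame(c1 = rep(1, 10), y = rep(0L, 10))
  pred <- fit_predict("lr", train, test, "c1")
  expect_identical(pred, rep(0L, 10))
  train$y <- rep(c(0L, 1L), c(40, 60))
  expect_identical(fit_predict("lr", train, test, "c1"), rep(1L, 10))
  expect_error(fit_predict("lr", train, test, character()), "empty feature")
})

test_that("experiments are bit-reproducible from the master seed", {
  co <- make_separable_cohort(n = 120, seed = 3)
  r1 <- run_experiment(co, "rf", features = c("f1", "f2"), iterations = 5,
                       seed = 99, config = list(ntree = 50))
  r2 <- run_experiment(co, "rf", features = c("f1", "f2"), iterations = 5,
                       seed = 99, config = list(ntree = 50))
  expect_identical(r1$per_iteration, r2$per_iteration)
  expect_identical(r1$mu_accuracy, r2$mu_accuracy)
  # accuracy identity per iteration
  m <- r1$per_iteration
  expect_equal(r1$accuracy, (m[, "tn"] + m[, "tp"]) / rowSums(m) * 100)
})

test_that("selection-integrated experiments record their provenance", {
  set.seed(64)
  co <- make_separable_cohort(n = 160, seed = 12)
  co$junk <- rnorm(nrow(co))
  res <- run_experiment(co, "lr", features = c("f1", "f2", "junk"),
                        criterion = "anova", iterations = 5, seed = 21)
  expect_s3_class(res, "cs_holdout")
  expect_true(all(res$config$features %in% c("f1", "f2", "junk")))
  expect_false("junk" %in% res$config$features)
  expect_identical(res$config$iterations, 5)
  out <- capture.output(print(res))
  expect_match(out[1], "lr")
  nested <- run_experiment(co, "lr", features = c("f1", "f2", "junk"),
                           criterion = "anova", iterations = 3, seed = 21,
                           nested = TRUE)
  expect_s3_class(nested, "cs_holdout")
})

test_that("boosted trees upweight hard points and beat a single stump", {
  set.seed(17)
  n <- 400
  x1 <- runif(n); x2 <- runif(n)
  y <- as.integer((x1 > 0.5) != (x2 > 0.5))   # XOR: stumps fail, trees win
  d <- data.frame(x1 = x1, x2 = x2, y = factor(y))
  fit <- cs_adaboost(y ~ x1 + x2, d, n_iter = 10)
  acc <- mean(predict(fit, d) == d$y)
  expect_gt(acc, 0.9)
  stump <- cs_adaboost(y ~ x1 + x2, d, n_iter = 1,
                       control = rpart::rpart.control(maxdepth = 1, cp = 0,
                                                      xval = 0))
  expect_gt(acc, mean(predict(stump, d) == d$y))
})
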