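test_that("scenario presets enumerate the agreed feature sets", {
  co <- generate_cohort(cohort_preset("cleveland"))
  f1 <- scenario_features(co, 1)
  expect_identical(length(f1), 10L)
  expect_setequal(f1, c("age", "gender", "htn", cs_indicator_names()))

  # scenario 2: all non-response, non-identifier columns plus indicators
  d <- as.data.frame(matrix(rnorm(20 * 19), 20,
                            dimnames = list(NULL, paste0("V", 1:19))))
  d$y <- rep(c(0L, 1L), 10)
  f2 <- scenario_features(as_cohort(d), 2)
  expect_identical(length(f2), 19L + 7L)

  no_htn <- as_cohort(data.frame(age = 1:4, gender = c(0, 1, 0, 1),
                                 y = c(0L, 1L, 0L, 1L)))
  expect_error(scenario_features(no_htn, 1), "V3")
  expect_error(scenario_features(co, 3), "scenario")
})

test_that("information gain matches hand-enumerated entropies", {
  y <- c(0L, 0L, 1L, 1L)
  co <- data.frame(f = c("a", "a", "a", "b"), g = c("p", "p", "q", "q"),
                   y = y)
  res <- info_gain_rank(co, c("f", "g"))
  # H(Y) = 1 bit; H(Y|f) = 3/4 * H(1/3, 2/3) = 0.75 * 0.918296
  gain_f <- 1 - 0.75 * (-(1 / 3) * log2(1 / 3) - (2 / 3) * log2(2 / 3))
  expect_equal(res$trace$statistic[res$trace$feature == "f"], gain_f,
               tolerance = 1e-10)
  # g reproduces y exactly: gain equals H(Y)
  expect_equal(res$trace$statistic[res$trace$feature == "g"], 1)
  expect_identical(res$kept[1], "g")
})

test_that("information gain is near zero for independent features", {
  set.seed(8)
  co <- data.frame(noise = rnorm(1e4), y = rep(c(0L, 1L), 5e3))
  res <- info_gain_rank(co, "noise")
  g <- res$trace$statistic
  expect_gte(g, 0)
  expect_lt(g, 0.01)
})

test_that("VIF filter removes exact and near collinearity only", {
  set.seed(21)
  n <- 200
  x1 <- rnorm(n); x2 <- rnorm(n)
  ortho <- data.frame(x1 = x1, x2 = x2, y = rep(0:1, n / 2))
  expect_identical(vif_filter(ortho, c("x1", "x2"))$kept, c("x1", "x2"))

  dup <- ortho; dup$x3 <- dup$x1
  res <- vif_filter(dup, c("x1", "x2", "x3"))
  expect_identical(length(res$kept), 2L)
  expect_true("x2" %in% res$kept)
  expect_identical(res$trace$statistic[1], Inf)

  trio <- ortho; trio$x3 <- trio$x1 + trio$x2 + rnorm(n, sd = 0.01)
  res2 <- vif_filter(trio, c("x1", "x2", "x3"))
  expect_identical(length(res2$kept), 2L)
  # independent check of the terminal VIFs via car on the survivors
  fit <- lm(reformulate(res2$kept, response = "y"), data = trio)
  expect_true(all(car::vif(fit) <= 10))
})

test_that("VIF filter terminates with all reported VIFs under the threshold", {
  set.seed(77)
  n <- 150
  base <- matrix(rnorm(n * 3), n)
  X <- data.frame(a = base[, 1], b = base[, 2], c = base[, 3],
                  d = base[, 1] + 0.1 * rnorm(n),
                  e = base[, 2] - base[, 3] + 0.1 * rnorm(n))
  X$y <- rep(0:1, length.out = n)
  feats <- c("a", "b", "c", "d", "e")
  res <- vif_filter(X, feats)
  expect_lte(nrow(res$trace), length(feats))
  fit <- lm(reformulate(res$kept, response = "y"), data = X)
  expect_true(all(car::vif(fit) <= 10))
  # deterministic: same call, same answer
  expect_identical(res$kept, vif_filter(X, feats)$kept)
})

test_that("ANOVA screening keeps strong effects and drops constants", {
  set.seed(12)
  n <- 200
  co <- data.frame(y = rep(0:1, n / 2))
  co$strong <- co$y + rnorm(n, sd = 0.1)
  co$flat <- rep(3, n)
  res <- anova_select(co, c("strong", "flat"))
  expect_identical(res$kept, "strong")
  expect_match(res$trace$action[res$trace$feature == "flat"],
               "zero variance")
})

test_that("ANOVA type-I rate on independent features is near alpha", {
  set.seed(99)
  kept <- logical(1000)
  y <- rep(0:1, 50)
  for (r in 1:1000) {
    co <- data.frame(y = y, x = rnorm(100))
    kept[r] <- length(anova_select(co, "x")$kept) == 1
  }
  expect_gte(mean(kept), 0.03)
  expect_lte(mean(kept), 0.07)
})

test_that("backward AIC keeps the informative feature and prunes noise", {
  set.seed(303)
  n <- 500
  x <- rnorm(n)
  y <- rbinom(n, 1, plogis(2 * x))
  co <- data.frame(y = y, x = x,
                   n1 = rnorm(n), n2 = rnorm(n), n3 = rnorm(n),
                   n4 = rnorm(n), n5 = rnorm(n))
  res <- aic_stepwise(co, c("x", paste0("n", 1:5)))
  expect_true("x" %in% res$kept)
  expect_gte(5 - sum(paste0("n", 1:5) %in% res$kept), 3)
  expect_true(all(diff(res$trace$statistic) <= 0))  # AIC never increases
})

test_that("AIC stepwise reaches the closed-form null model on pure noise", {
  set.seed(41)
  co <- data.frame(y = rep(0:1, 50), z = rnorm(100))
  res <- aic_stepwise(co, "z")
  if (length(res$kept) == 0) {
    # final AIC is the Bernoulli null: 2 * 100 * log(2) + 2
    expect_equal(tail(res$trace$statistic, 1), 2 * 100 * log(2) + 2,
                 tolerance = 1e-4)
  }
  expect_identical(aic_stepwise(co, character())$kept, character())
})

test_that("composite criteria chain stages in order", {
  set.seed(55)
  n <- 300
  co <- data.frame(y = rbinom(n, 1, 0.5))
  co$a <- co$y + rnorm(n, sd = 0.3)
  co$b <- -co$y + rnorm(n, sd = 0.3)
  plain <- cs_select(co, c("a", "b"), "anova")
  combo <- cs_select(co, c("a", "b"), "anova+vif")
  expect_setequal(combo$kept, plain$kept)  # orthogonal: VIF is a no-op

  # a duplicated informative column survives ANOVA but falls to VIF,
  # and the trace shows the ANOVA phase strictly before the VIF phase
  dup <- co; dup$a2 <- dup$a
  res <- cs_select(dup, c("a", "a2", "b"), "anova+vif")
  expect_false(all(c("a", "a2") %in% res$kept))
  expect_true("b" %in% res$kept)
  expect_identical(unique(res$trace$phase), c("anova", "vif"))

  res2 <- cs_select(dup, c("a", "a2", "b"), "aic+vif")
  expect_false(all(c("a", "a2") %in% res2$kept))
  expect_identical(unique(res2$trace$phase)[1], "aic")
})
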