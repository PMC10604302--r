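# Feature-selection criteria: scenario presets, information gain, iterative
# VIF filtering, per-feature ANOVA screening, stepwise AIC on the logistic
# model, and their compositions.

new_selection <- function(criterion, kept, trace) {
  structure(list(criterion = criterion, kept = kept, trace = trace),
            class = "cs_selection")
}

#' @export
print.cs_selection <- function(x, ...) {
  cat("Selection by", x$criterion, "- kept", length(x$kept), "feature(s):\n")
  cat(" ", paste(x$kept, collapse = ", "), "\n")
  if (nrow(x$trace) > 0) {
    cat("Trace:\n")
    print.data.frame(x$trace, row.names = FALSE)
  }
  invisible(x)
}

#' Scenario feature presets
#'
#' Scenario 1 is the low-acquisition-cost set: age (V3), gender (V4), and
#' hypertension history (V11) plus the seven indicators - exactly 10
#' features.  Scenario 2 uses every registered variable except the response
#' and identifiers, plus the seven indicators.
#'
#' @param cohort A `cs_cohort` whose registry resolves the named codes.
#' @param scenario 1 or 2.
#' @return Character vector of column names.
#' @export
scenario_features <- function(cohort, scenario) {
  reg <- attr(cohort, "registry")
  if (is.null(reg)) stop("cohort has no variable registry", call. = FALSE)
  resolve <- function(code) {
    i <- match(code, reg$code)
    if (is.na(i)) {
      stop("registry error: code ", code, " not resolvable in this cohort",
           call. = FALSE)
    }
    reg$column[i]
  }
  if (scenario == 1) {
    covs <- vapply(c("V3", "V4", "V11"), resolve, character(1))
    feats <- c(unname(covs), cs_indicator_names())
  } else if (scenario == 2) {
    keep <- !(reg$role %in% c("identifier", "response"))
    feats <- unique(c(reg$column[keep & reg$role != "indicator"],
                      cs_indicator_names()))
  } else {
    stop("scenario must be 1 or 2", call. = FALSE)
  }
  missing_ind <- setdiff(feats, names(cohort))
  if (length(missing_ind) > 0 &&
      all(missing_ind %in% cs_indicator_names())) {
    # indicators not yet attached; still part of the scenario contract
    feats
  } else if (length(missing_ind) > 0) {
    stop("registry error: column(s) absent from cohort: ",
         paste(missing_ind, collapse = ", "), call. = FALSE)
  }
  feats
}

shannon_entropy <- function(x) {
  p <- table(x)
  p <- p[p > 0] / sum(p)
  -sum(p * log2(p))
}

# equal-frequency binning for continuous features; ties grouped
discretize_ef <- function(x, bins = 10) {
  ux <- unique(x[!is.na(x)])
  if (length(ux) <= bins) return(as.character(x))
  br <- unique(stats::quantile(x, probs = seq(0, 1, length.out = bins + 1),
                               na.rm = TRUE, type = 7))
  as.character(cut(x, breaks = br, include.lowest = TRUE))
}

#' Information-gain ranking of features
#'
#' Shannon-entropy gain of the binary response given each feature,
#' `gain(f) = H(Y) - H(Y | f)` in bits, with continuous features discretised
#' by equal-frequency binning.  Features are returned in descending gain
#' order, ties broken alphabetically.  Missing feature values form their own
#' bin.
#'
#' @param cohort Data frame with a 0/1 `y` column.
#' @param features Candidate feature columns.
#' @param bins Number of equal-frequency bins for continuous features.
#' @param top_k Optional retention cutoff; by default all ranked features are
#'   kept (the ranking, not an absolute threshold, is what downstream
#'   consumers use).
#' @return A `cs_selection`; the trace holds the per-feature gain.
#' @export
info_gain_rank <- function(cohort, features, bins = 10, top_k = NULL) {
  y <- cohort$y
  hy <- shannon_entropy(y)
  if (hy == 0) warning("constant response: all gains are 0", call. = FALSE)
  gain <- vapply(features, function(f) {
    fx <- cohort[[f]]
    fx <- if (is.numeric(fx)) discretize_ef(fx, bins) else as.character(fx)
    fx[is.na(fx)] <- "(missing)"
    tab <- table(fx)
    hcond <- sum(vapply(names(tab), function(lv) {
      w <- tab[[lv]] / length(fx)
      w * shannon_entropy(y[fx == lv])
    }, numeric(1)))
    hy - hcond
  }, numeric(1))
  ord <- order(-gain, features)
  ranked <- features[ord]
  kept <- if (is.null(top_k)) ranked else utils::head(ranked, top_k)
  new_selection("InfoGain", kept,
                data.frame(step = seq_along(ranked), feature = ranked,
                           statistic = unname(gain[ord]), action = "ranked"))
}

# VIF of each column of a numeric design matrix (auxiliary regressions with
# intercept); exact collinearity gives Inf
column_vifs <- function(X) {
  p <- ncol(X)
  vapply(seq_len(p), function(j) {
    xj <- X[, j]
    others <- cbind(1, X[, -j, drop = FALSE])
    fit <- stats::lm.fit(others, xj)
    ssr <- sum(fit$residuals^2)
    sst <- sum((xj - mean(xj))^2)
    if (sst == 0) return(Inf)
    r2 <- 1 - ssr / sst
    if (r2 >= 1 - 1e-12) Inf else 1 / (1 - r2)
  }, numeric(1))
}

#' Iterative variance-inflation-factor filter
#'
#' Builds a numeric design matrix (one-hot encoding categorical features),
#' computes the VIF `1 / (1 - R^2)` of every column, and repeatedly removes
#' the single feature owning the highest-VIF column while any VIF exceeds the
#' threshold.  Exactly collinear columns have infinite VIF and are removed
#' first.  A categorical feature is removed as a whole if any of its encoded
#' columns exceeds the threshold.
#'
#' @param cohort Data frame holding the features.
#' @param features Candidate feature columns.
#' @param threshold VIF threshold; values above 10 conventionally indicate
#'   strong multicollinearity.
#' @return A `cs_selection`; the trace records each removal with its VIF.
#' @export
vif_filter <- function(cohort, features, threshold = 10) {
  kept <- features
  trace <- data.frame(step = integer(), feature = character(),
                      statistic = numeric(), action = character())
  step <- 0
  repeat {
    if (length(kept) < 2) break
    d <- cohort[kept]
    cc <- stats::complete.cases(d)
    d2 <- as.data.frame(lapply(d[cc, , drop = FALSE], function(x)
      if (is.character(x)) factor(x) else x))
    mm <- stats::model.matrix(~ ., data = d2)
    asgn <- attr(mm, "assign")
    labs <- attr(stats::terms(~ ., data = d2), "term.labels")
    X <- mm[, asgn > 0, drop = FALSE]
    owner <- labs[asgn[asgn > 0]]
    # drop all-constant columns (no variance => VIF undefined, not inflating)
    keep_col <- apply(X, 2, function(x) stats::sd(x) > 0)
    X <- X[, keep_col, drop = FALSE]
    owner <- owner[keep_col]
    if (ncol(X) < 2) break
    v <- column_vifs(X)
    if (max(v) <= threshold) break
    worst <- owner[which.max(v)]
    step <- step + 1
    trace <- rbind(trace, data.frame(step = step, feature = worst,
                                     statistic = max(v),
                                     action = "removed (VIF > threshold)"))
    kept <- setdiff(kept, worst)
  }
  new_selection("VIF", kept, trace)
}

#' Per-feature ANOVA screening against the binary response
#'
#' One-way ANOVA of each numeric feature on the two response groups (for a
#' binary response this is the two-sample equal-variance F test); features
#' with `p < alpha` are kept.  Categorical features are screened with a
#' chi-squared test of association.  Zero-variance features are excluded with
#' a trace note.
#'
#' @param cohort Data frame with a 0/1 `y` column.
#' @param features Candidate feature columns.
#' @param alpha Significance level (default 0.05).
#' @return A `cs_selection`; the trace holds each p-value and action.
#' @export
anova_select <- function(cohort, features, alpha = 0.05) {
  y <- factor(cohort$y)
  rows <- lapply(features, function(f) {
    x <- cohort[[f]]
    if (is.numeric(x)) {
      ok <- !is.na(x) & !is.na(y)
      if (stats::sd(x[ok]) == 0) {
        return(data.frame(feature = f, statistic = NA_real_,
                          action = "excluded (zero variance)"))
      }
      p <- stats::anova(stats::lm(x[ok] ~ y[ok]))$`Pr(>F)`[1]
    } else {
      p <- suppressWarnings(stats::chisq.test(table(x, y))$p.value)
    }
    data.frame(feature = f, statistic = p,
               action = if (!is.na(p) && p < alpha) "kept" else "dropped")
  })
  trace <- do.call(rbind, rows)
  trace$step <- seq_len(nrow(trace))
  kept <- trace$feature[trace$action == "kept"]
  new_selection("ANOVA", kept,
                trace[, c("step", "feature", "statistic", "action")])
}

#' Backward stepwise selection by AIC on the logistic model
#'
#' Starts from the full logistic regression (logit link) on complete cases
#' and removes single terms while a removal lowers
#' `AIC = -2 loglik + 2 (k + 1)`.  Quasi-separated fits are tolerated via an
#' iteration cap rather than penalisation, keeping the AIC comparable to the
#' unpenalised likelihood.
#'
#' @param cohort Data frame with a 0/1 `y` column.
#' @param features Candidate feature columns; an empty set returns an empty
#'   selection.
#' @param direction `"backward"` (default) or `"forward"`.
#' @return A `cs_selection`; the trace logs the AIC after each step.
#' @export
aic_stepwise <- function(cohort, features, direction = "backward") {
  if (length(features) == 0) {
    return(new_selection("AIC", character(),
                         data.frame(step = integer(), feature = character(),
                                    statistic = numeric(),
                                    action = character())))
  }
  d <- cohort[c("y", features)]
  d <- d[stats::complete.cases(d), , drop = FALSE]
  ctrl <- stats::glm.control(maxit = 50)
  full <- suppressWarnings(
    stats::glm(y ~ ., family = stats::binomial("logit"), data = d,
               control = ctrl))
  null <- suppressWarnings(
    stats::glm(y ~ 1, family = stats::binomial("logit"), data = d,
               control = ctrl))
  fit <- suppressWarnings(
    if (direction == "backward") {
      stats::step(full, direction = "backward", trace = 0)
    } else {
      stats::step(null, direction = "forward",
                  scope = list(lower = null, upper = full), trace = 0)
    })
  # term labels equal the column names (factors keep their name as one term)
  kept <- intersect(features, attr(stats::terms(fit), "term.labels"))
  an <- fit$anova
  trace <- if (is.null(an)) {
    data.frame(step = 1L, feature = "(full model)", statistic = stats::AIC(fit),
               action = "no beneficial removal")
  } else {
    data.frame(step = seq_len(nrow(an)),
               feature = trimws(as.character(an$Step)),
               statistic = an$AIC, action = "AIC step")
  }
  new_selection("AIC", kept, trace)
}

#' Apply a named selection criterion or composition
#'
#' The six named criteria are `infogain`, `vif`, `anova`, `anova+vif`, `aic`,
#' and `aic+vif`.  The composite criteria apply the first stage to the full
#' candidate set and the VIF filter to its survivors, with a concatenated
#' trace (a `phase` column records the stage).
#'
#' @param cohort Data frame with a 0/1 `y` column.
#' @param features Candidate feature columns.
#' @param criterion Criterion name (case-insensitive).
#' @param ... Passed to the underlying criterion functions.
#' @return A `cs_selection`.
#' @export
cs_select <- function(cohort, features,
                      criterion = c("infogain", "vif", "anova", "anova+vif",
                                    "aic", "aic+vif"), ...) {
  criterion <- match.arg(tolower(criterion), c("infogain", "vif", "anova",
                                               "anova+vif", "aic", "aic+vif"))
  chain <- strsplit(criterion, "+", fixed = TRUE)[[1]]
  stage <- function(name, feats) {
    switch(name,
           infogain = info_gain_rank(cohort, feats, ...),
           vif = vif_filter(cohort, feats, ...),
           anova = anova_select(cohort, feats, ...),
           aic = aic_stepwise(cohort, feats, ...))
  }
  with_phase <- function(name, tr) {
    if (nrow(tr) == 0) {
      data.frame(phase = character(), step = integer(),
                 feature = character(), statistic = numeric(),
                 action = character())
    } else {
      cbind(phase = name, tr)
    }
  }
  res <- stage(chain[1], features)
  trace <- with_phase(chain[1], res$trace)
  for (name in chain[-1]) {
    res2 <- stage(name, res$kept)
    trace <- rbind(trace, with_phase(name, res2$trace))
    res <- res2
  }
  new_selection(criterion, res$kept, trace)
}
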