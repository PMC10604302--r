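# Cohort container and readers for the UCI heart-disease file dialects.

#' Standard registry for the 76-attribute UCI heart-disease files
#'
#' The raw files carry 76 attributes per record: 75 numeric fields coded
#' V1..V75 (V3 age, V4 sex, V10 resting systolic pressure, V11 hypertension
#' history, V33 resting heart rate, V37 resting diastolic pressure, V40
#' exercise-induced ST depression, V58 the multi-level disease diagnosis,
#' V61 distance from the left anterior descending artery, ...) followed by a
#' name placeholder that terminates the record.
#'
#' @return A data frame with columns `code`, `column`, `description`, `type`,
#'   `role` (one of `identifier`, `response`, `vital`, `covariate`).
#' @export
uci_registry <- function() {
  nm <- c("id", "ccf", "age", "sex", "painloc", "painexer", "relrest",
          "pncaden", "cp", "trestbps", "htn", "chol", "smoke", "cigs",
          "years", "fbs", "dm", "famhist", "restecg", "ekgmo", "ekgday",
          "ekgyr", "dig", "prop", "nitr", "pro", "diuretic", "proto",
          "thaldur", "thaltime", "met", "thalach", "thalrest", "tpeakbps",
          "tpeakbpd", "dummy", "trestbpd", "exang", "xhypo", "oldpeak",
          "slope", "rldv5", "rldv5e", "ca", "restckm", "exerckm", "restef",
          "restwm", "exeref", "exerwm", "thal", "thalsev", "thalpul",
          "earlobe", "cmo", "cday", "cyr", "num", "lmt", "ladprox",
          "laddist", "diag", "cxmain", "ramus", "om1", "om2", "rcaprox",
          "rcadist", "lvx1", "lvx2", "lvx3", "lvx4", "lvf", "cathef", "junk")
  role <- rep("covariate", 75)
  role[1:2] <- "identifier"
  role[58] <- "response"
  role[c(10, 37, 33)] <- "vital"
  data.frame(code = paste0("V", 1:75), column = nm,
             description = nm, type = "numeric", role = role)
}

#' Dichotomise the multi-level disease diagnosis
#'
#' The raw diagnosis field ranges over 0 (no disease) to 4 (increasing
#' severity); the binary label maps 0 to 0 and 1-4 to 1.  Idempotent on
#' already-binary input.
#'
#' @param x Numeric vector; `NA` propagates.
#' @return Integer vector of 0/1 labels.
#' @export
dichotomize_disease <- function(x) {
  ifelse(is.na(x), NA_integer_, as.integer(x > 0))
}

#' Build a cohort from a data frame
#'
#' A cohort is a data frame of subject records with vitals columns
#' (`sbp`, `dbp`, `hr`), a binary response `y`, optional covariates, and a
#' variable registry mapping codes (V1..V75, indicator names) to columns.
#'
#' @param data Data frame with at least a `y` column of 0/1 labels.
#' @param registry Optional registry data frame (`code`, `column`,
#'   `description`, `type`, `role`); built from the columns when `NULL`.
#' @param provenance Free-text source tag.
#' @return A `cs_cohort` object (a classed data frame).
#' @export
as_cohort <- function(data, registry = NULL, provenance = "unknown") {
  if (!"y" %in% names(data)) {
    stop("cohort requires a binary response column 'y'", call. = FALSE)
  }
  yv <- data$y[!is.na(data$y)]
  if (!all(yv %in% c(0, 1))) {
    stop("response 'y' must be coded 0/1", call. = FALSE)
  }
  if (is.null(registry)) {
    cols <- setdiff(names(data), "y")
    registry <- data.frame(code = cols, column = cols, description = cols,
                           type = vapply(data[cols], function(x)
                             if (is.numeric(x)) "numeric" else "categorical",
                             character(1)),
                           role = ifelse(cols %in% c("sbp", "dbp", "hr"),
                                         "vital",
                                         ifelse(cols == "id", "identifier",
                                                "covariate")))
  }
  missing_cols <- setdiff(registry$column, names(data))
  registry <- registry[!(registry$column %in% missing_cols), , drop = FALSE]
  structure(data, registry = registry, provenance = provenance,
            class = c("cs_cohort", "data.frame"))
}

#' @export
print.cs_cohort <- function(x, ...) {
  cat("Cohort:", nrow(x), "subjects (", sum(x$y == 1, na.rm = TRUE),
      "with disease ), source:", attr(x, "provenance"), "\n")
  cat("Columns:", paste(utils::head(names(x), 12), collapse = ", "),
      if (ncol(x) > 12) "..." else "", "\n")
  invisible(x)
}

#' Read a raw 76-attribute UCI heart-disease file
#'
#' The raw dialect is a stream of whitespace-separated tokens in which one
#' subject spans several physical lines: 75 numeric attribute values followed
#' by the literal terminator token `name`.  The sentinel `-9` is mapped to
#' missing and the V58 diagnosis is dichotomised into `y`.
#'
#' @param path Path to the raw file.
#' @param registry Attribute registry, by default [uci_registry()].
#' @param vitals_map Named character vector locating the vitals among the
#'   V-codes; the default uses resting systolic pressure (V10), resting
#'   diastolic pressure (V37), and resting heart rate (V33).
#' @return A `cs_cohort` with V-code columns, vitals columns, and `y`.
#' @export
read_uci_raw <- function(path, registry = uci_registry(),
                         vitals_map = c(sbp = "V10", dbp = "V37", hr = "V33")) {
  tokens <- scan(path, what = character(), quiet = TRUE)
  if (length(tokens) == 0) stop("empty file: ", path, call. = FALSE)
  ends <- which(tokens == "name")
  if (length(ends) == 0) {
    stop("no record terminator token 'name' found in ", path, call. = FALSE)
  }
  starts <- c(1, utils::head(ends, -1) + 1)
  n_attr <- 75
  rec <- vector("list", length(ends))
  for (i in seq_along(ends)) {
    body <- tokens[starts[i]:(ends[i] - 1)]
    if (length(body) != n_attr) {
      stop("parse error at record ", i, ": expected ", n_attr,
           " attribute values before 'name', found ", length(body),
           call. = FALSE)
    }
    v <- suppressWarnings(as.numeric(body))
    if (anyNA(v)) {
      stop("parse error at record ", i, ": non-numeric attribute token",
           call. = FALSE)
    }
    rec[[i]] <- v
  }
  m <- do.call(rbind, rec)
  m[m == -9] <- NA
  d <- as.data.frame(m)
  names(d) <- registry$code
  d$y <- dichotomize_disease(d$V58)
  d$sbp <- d[[vitals_map[["sbp"]]]]
  d$dbp <- d[[vitals_map[["dbp"]]]]
  d$hr <- d[[vitals_map[["hr"]]]]
  reg <- rbind(registry,
               data.frame(code = c("sbp", "dbp", "hr"),
                          column = c("sbp", "dbp", "hr"),
                          description = paste("vital from",
                                              vitals_map[c("sbp", "dbp", "hr")]),
                          type = "numeric", role = "vital"))
  as_cohort(d, registry = reg, provenance = path)
}

#' Read a cohort from a delimited file with header
#'
#' @param path CSV path.
#' @param column_map Named list mapping the canonical columns (`sbp`, `dbp`,
#'   `hr`, `y`, optionally `id`) to header names in the file.
#' @param provenance Source tag; defaults to the path.
#' @return A `cs_cohort`; extra unmapped columns are retained and registered.
#' @export
read_cohort_csv <- function(path,
                            column_map = list(sbp = "sbp", dbp = "dbp",
                                              hr = "hr", y = "y"),
                            provenance = path) {
  d <- utils::read.csv(path, stringsAsFactors = FALSE)
  wanted <- unlist(column_map)
  absent <- setdiff(wanted, names(d))
  if (length(absent) > 0) {
    stop("schema error: mapped column(s) absent from ", path, ": ",
         paste(absent, collapse = ", "), call. = FALSE)
  }
  for (canon in names(column_map)) {
    from <- column_map[[canon]]
    if (!identical(from, canon)) {
      d[[canon]] <- d[[from]]
      d[[from]] <- NULL
    }
  }
  as_cohort(d, provenance = provenance)
}

#' Write a cohort as CSV (missing values as empty fields)
#' @param cohort A `cs_cohort`.
#' @param path Output path.
#' @export
write_cohort_csv <- function(cohort, path) {
  utils::write.csv(as.data.frame(cohort), path, row.names = FALSE, na = "")
  invisible(path)
}

#' Cleaning policy for cohort records
#'
#' @param require_vitals Drop records whose vitals are missing or violate
#'   `SBP > DBP > 0`, `HR > 0`.
#' @param required Character vector of additional columns that must be
#'   non-missing.
#' @param zero_as_missing Columns in which a literal 0 is a missing-value
#'   sentinel (pressures and heart rate by default; 0 is a legal code in other
#'   UCI fields).
#' @return A list of class `cs_policy`.
#' @export
cohort_policy <- function(require_vitals = TRUE, required = character(),
                          zero_as_missing = c("sbp", "dbp", "hr")) {
  structure(list(require_vitals = require_vitals, required = required,
                 zero_as_missing = zero_as_missing), class = "cs_policy")
}

#' Filter a cohort by a cleaning policy
#'
#' Pure filtration: retained records are never altered beyond the sentinel
#' recoding of zeros to missing in the named fields.  An exclusion report
#' (per-rule counts) is attached as the `exclusions` attribute.
#'
#' @param cohort A `cs_cohort`.
#' @param policy A [cohort_policy()].
#' @return The filtered cohort; an empty result is legal.
#' @export
clean_cohort <- function(cohort, policy = cohort_policy()) {
  reg <- attr(cohort, "registry")
  prov <- attr(cohort, "provenance")
  for (f in intersect(policy$zero_as_missing, names(cohort))) {
    cohort[[f]][!is.na(cohort[[f]]) & cohort[[f]] == 0] <- NA
  }
  drop <- rep(FALSE, nrow(cohort))
  report <- c()
  if (policy$require_vitals && all(c("sbp", "dbp", "hr") %in% names(cohort))) {
    bad <- !valid_vitals(cohort$sbp, cohort$dbp, cohort$hr)
    report["invalid_vitals"] <- sum(bad & !drop)
    drop <- drop | bad
  }
  for (col in policy$required) {
    if (!col %in% names(cohort)) {
      stop("policy requires unknown column: ", col, call. = FALSE)
    }
    bad <- is.na(cohort[[col]])
    report[paste0("missing_", col)] <- sum(bad & !drop)
    drop <- drop | bad
  }
  out <- cohort[!drop, , drop = FALSE]
  out <- as_cohort(as.data.frame(out), registry = reg, provenance = prov)
  attr(out, "exclusions") <- as.list(report)
  out
}

#' Published reference group statistics for the UCI heart-disease subsets
#'
#' Per-indicator group means, medians, standard deviations and
#' Wilcoxon-Mann-Whitney p-values for the non-cardiac (0) and cardiac (1)
#' groups of the Cleveland, Hungarian, Long Beach and Switzerland subsets, as
#' reported in the original study of these indicators.  Shipped as a plain-text
#' table so the consistency measure can be recomputed from published summary
#' statistics without the raw data.
#'
#' @return Data frame with columns `dataset`, `n`, `indicator`, `mu0`, `mu1`,
#'   `m0`, `m1`, `s0`, `s1`, `p_wmw`.
#' @export
reference_group_stats <- function() {
  path <- system.file("extdata", "reference_group_stats.csv",
                      package = "cardioCS", mustWork = TRUE)
  utils::read.csv(path, stringsAsFactors = FALSE)
}
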