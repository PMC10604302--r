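# Fixtures built in code: random valid vitals, separable / null feature
# cohorts, and a writer for the raw 76-attribute file dialect.

random_vitals <- function(n, seed = 1) {
  set.seed(seed)
  dbp <- runif(n, 50, 110)
  pp <- runif(n, 16, 80)
  data.frame(sbp = dbp + pp, dbp = dbp, hr = runif(n, 45, 140))
}

# two numeric features, labels determined by the sign of their sum with a
# margin, so the classes are linearly separable
make_separable_cohort <- function(n = 300, seed = 1, margin = 0.5) {
  set.seed(seed)
  x1 <- numeric(0); x2 <- numeric(0)
  while (length(x1) < n) {
    a <- rnorm(3 * n); b <- rnorm(3 * n)
    keep <- abs(a + b) > margin
    x1 <- c(x1, a[keep]); x2 <- c(x2, b[keep])
  }
  x1 <- x1[1:n]; x2 <- x2[1:n]
  as_cohort(data.frame(f1 = x1, f2 = x2, y = as.integer(x1 + x2 > 0)),
            provenance = "separable fixture")
}

# labels independent of the features
make_null_cohort <- function(n = 400, p_pos = 0.5, seed = 1, k = 2) {
  set.seed(seed)
  d <- as.data.frame(matrix(rnorm(n * k), n,
                            dimnames = list(NULL, paste0("f", 1:k))))
  d$y <- as.integer(runif(n) < p_pos)
  if (length(unique(d$y)) < 2) d$y[1:2] <- c(0L, 1L)
  as_cohort(d, provenance = "null fixture")
}

# write records in the raw UCI dialect: 75 numeric tokens then 'name',
# wrapped over several physical lines
write_uci_fixture <- function(path, records) {
  lines <- unlist(lapply(records, function(r) {
    toks <- c(format(r, trim = TRUE, scientific = FALSE), "name")
    split(toks, ceiling(seq_along(toks) / 8)) |>
      vapply(paste, character(1), collapse = " ")
  }))
  writeLines(lines, path)
  path
}

# a full 75-value record with chosen vitals and disease level
uci_record <- function(sbp = 130, dbp = 85, hr = 72, disease = 0,
                       age = 54, sex = 1) {
  r <- rep(0, 75)
  r[3] <- age; r[4] <- sex
  r[10] <- sbp; r[37] <- dbp; r[33] <- hr
  r[58] <- disease
  r
}
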