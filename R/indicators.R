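# Hemodynamic indicators derived from cuff vitals (SBP, DBP, HR).
#
# The underlying model treats diastolic run-off as a first-order exponential
# pressure decay P(t) = SBP * exp(-t / RC), where RC is the product of
# peripheral resistance and arterial compliance (only the product is
# identifiable).  Requiring the decay to reach DBP after exactly one beat
# period pins RC = 1 / (HR * log(SBP/DBP)), and averaging P(t) over the beat
# gives the logarithmic-mean MAP.  The ejection-time fraction alpha comes from
# a triangular approximation of the pressure wave.

#' Unit conventions for the indicator formulas
#'
#' The indicator formulas are unit-sensitive and the conventions below are
#' pinned so that typical resting vitals give values on the scales reported
#' for the UCI heart-disease subsets: heart rate enters `RC` in beats per
#' minute (RC around 0.03), the beat period enters `alpha` in milliseconds
#' (alpha around 0.002-0.005), and the harmony measure uses the squared rate
#' factor `(1000 * HR / 60)^2` (HM roughly 30-200).
#'
#' @param rc_hr_unit Heart-rate unit in the RC formula, `"per_min"` (default)
#'   or `"per_sec"`.
#' @param alpha_tau_unit Beat-period unit in the alpha formula, `"ms"`
#'   (default) or `"s"`.
#' @param hm_rate_scale Multiplier applied to HR (in beats/min) before squaring
#'   in the harmony measure; default `1000/60`.
#' @return A list of class `cs_conventions`.
#' @export
cs_conventions <- function(rc_hr_unit = c("per_min", "per_sec"),
                           alpha_tau_unit = c("ms", "s"),
                           hm_rate_scale = 1000 / 60) {
  structure(list(rc_hr_unit = match.arg(rc_hr_unit),
                 alpha_tau_unit = match.arg(alpha_tau_unit),
                 hm_rate_scale = hm_rate_scale),
            class = "cs_conventions")
}

# TRUE where a (sbp, dbp[, hr]) triple is admissible for the indicator math
valid_vitals <- function(sbp, dbp, hr = NULL) {
  ok <- !is.na(sbp) & !is.na(dbp) & sbp > dbp & dbp > 0
  if (!is.null(hr)) ok <- ok & !is.na(hr) & hr > 0
  ok
}

stop_if_invalid <- function(ok, what) {
  if (!all(ok)) {
    stop("undefined input for ", what, ": requires SBP > DBP > 0",
         " (and HR > 0 where used); offending index ",
         which(!ok)[1], call. = FALSE)
  }
}

#' Mean arterial pressure (logarithmic mean of SBP and DBP)
#'
#' Time-average of the exponential pressure decay over one beat, which has the
#' closed form `(SBP - DBP) / (log(SBP) - log(DBP))`.  Natural logarithms are
#' forced by the exponential decay model.
#'
#' @param sbp,dbp Systolic and diastolic pressure in mmHg (vectorised).
#' @return MAP in mmHg.  Errors on invalid inputs (`sbp <= dbp` or
#'   non-positive values); use [cs_indicators()] for a missing-value-tolerant
#'   interface.
#' @examples
#' cs_map(120, 80)   # 40 / log(1.5)
#' @export
cs_map <- function(sbp, dbp) {
  stop_if_invalid(valid_vitals(sbp, dbp), "MAP")
  (sbp - dbp) / (log(sbp) - log(dbp))
}

#' Resistance-compliance product of the pressure-decay model
#'
#' Time constant of the exponential diastolic decay, fixed by requiring the
#' pressure to fall from SBP to DBP over one beat period:
#' `RC = 1 / (HR * log(SBP / DBP))`.
#'
#' @inheritParams cs_map
#' @param hr Heart rate in beats per minute.
#' @param conventions A [cs_conventions()] object.
#' @return RC in the time unit implied by the HR convention (minutes for the
#'   default beats/min).
#' @export
cs_rc <- function(sbp, dbp, hr, conventions = cs_conventions()) {
  stop_if_invalid(valid_vitals(sbp, dbp, hr), "RC")
  hr <- if (conventions$rc_hr_unit == "per_sec") hr / 60 else hr
  1 / (hr * log(sbp / dbp))
}

#' Pulsatile blood pressure index
#'
#' Pulse pressure normalised by diastolic pressure, `(SBP - DBP) / DBP`.
#'
#' @inheritParams cs_map
#' @return Dimensionless index, positive for valid vitals.
#' @export
cs_pbpi <- function(sbp, dbp) {
  stop_if_invalid(valid_vitals(sbp, dbp), "PBPI")
  (sbp - dbp) / dbp
}

#' Pulsatile index over the resistance-compliance product
#'
#' `PBPI / RC`, linear in heart rate at fixed pressures.
#'
#' @inheritParams cs_rc
#' @export
cs_pbpirc <- function(sbp, dbp, hr, conventions = cs_conventions()) {
  cs_pbpi(sbp, dbp) / cs_rc(sbp, dbp, hr, conventions)
}

#' Harmony measure
#'
#' A Kepler-law-inspired ratio of the squared beat frequency to the cubed gap
#' between SBP and the (logarithmic-mean) MAP:
#' `HM = (1000 * HR / 60)^2 / (SBP - MAP)^3`.  The MAP entering the formula is
#' the logarithmic-mean MAP of [cs_map()], not the arithmetic mean of the
#' triangular-wave model.
#'
#' @inheritParams cs_rc
#' @return Model units; strictly increasing in HR at fixed pressures and
#'   strictly decreasing in pulse pressure at fixed HR.
#' @export
cs_hm <- function(sbp, dbp, hr, conventions = cs_conventions()) {
  stop_if_invalid(valid_vitals(sbp, dbp, hr), "HM")
  (conventions$hm_rate_scale * hr)^2 / (sbp - cs_map(sbp, dbp))^3
}

#' Ejection-time fraction of the cardiac cycle
#'
#' Under a triangular pressure-wave model with equal ascent and descent slopes,
#' the ejection fraction of the beat period satisfies
#' `alpha * (1 - alpha) * tau^2 = (SBP - DBP)^2` with `tau = 60000 / HR`
#' milliseconds; the physiological solution is the smaller root
#' `alpha = 1/2 - sqrt(tau^2 - 4 * (SBP - DBP)^2) / (2 * tau)`.
#'
#' Computed in the cancellation-free form
#' `x / (2 * (1 + sqrt(1 - x)))` with `x = (2 * (SBP - DBP) / tau)^2`, which is
#' algebraically identical but accurate for the small alphas typical of
#' resting vitals.  A negative discriminant (pulse pressure exceeding half the
#' beat period) yields `NA` with a warning rather than a clamped 0.5, so that
#' group statistics are not silently biased.
#'
#' @inheritParams cs_rc
#' @return Fraction in (0, 0.5]; `NA` where the discriminant is negative.
#' @export
cs_alpha <- function(sbp, dbp, hr, conventions = cs_conventions()) {
  stop_if_invalid(valid_vitals(sbp, dbp, hr), "alpha")
  tau <- beat_period(hr, conventions)
  x <- (2 * (sbp - dbp) / tau)^2
  out <- rep(NA_real_, length(x))
  ok <- x <= 1
  if (any(!ok)) {
    warning(sum(!ok), " record(s) with pulse pressure exceeding half the ",
            "beat period: alpha undefined, set to NA", call. = FALSE)
  }
  out[ok] <- x[ok] / (2 * (1 + sqrt(1 - x[ok])))
  out
}

beat_period <- function(hr, conventions = cs_conventions()) {
  if (conventions$alpha_tau_unit == "ms") 60000 / hr else 60 / hr
}

#' Negative-log transform of the ejection-time fraction
#'
#' `alpha2 = -log(alpha)`, a strictly decreasing transform of alpha, hence
#' `median(alpha2) = -log(median(alpha))` on any sample.
#'
#' @param alpha Ejection-time fraction in (0, 0.5]; `NA` propagates.
#' @export
cs_alpha2 <- function(alpha) {
  bad <- !is.na(alpha) & (alpha <= 0 | alpha > 0.5)
  if (any(bad)) {
    stop("alpha outside (0, 0.5]: alpha2 undefined", call. = FALSE)
  }
  -log(alpha)
}

#' Exponential pressure-decay model
#'
#' `P(t) = SBP * exp(-t / RC)` with RC from [cs_rc()].  With the default
#' conventions RC is in minutes, so `t` is in minutes as well; at `t = 1/HR`
#' (one beat period) the decay reaches DBP exactly.
#'
#' @inheritParams cs_rc
#' @param t Time since the systolic peak, in the RC time unit; `t >= 0`.
#' @return Pressure in mmHg.
#' @examples
#' pressure_decay(120, 80, 70, 0)       # SBP
#' pressure_decay(120, 80, 70, 1 / 70)  # DBP after one beat
#' @export
pressure_decay <- function(sbp, dbp, hr, t, conventions = cs_conventions()) {
  stop_if_invalid(valid_vitals(sbp, dbp, hr), "pressure decay")
  if (any(t < 0)) stop("t must be non-negative", call. = FALSE)
  sbp * exp(-t / cs_rc(sbp, dbp, hr, conventions))
}

#' Compute all seven indicators, tolerating invalid records
#'
#' Vectorised, missing-value-tolerant front end to the indicator formulas:
#' records failing the validity contract (`SBP > DBP > 0`, `HR > 0`, all
#' non-missing) get `NA` in every indicator; a negative alpha discriminant
#' gives `NA` in `ALPHA`/`ALPHA2` only.  Never errors on a bad record.
#'
#' @param sbp,dbp,hr Vitals vectors, or `sbp` may be a `cs_cohort` /
#'   data frame with `sbp`, `dbp`, `hr` columns.
#' @param conventions A [cs_conventions()] object.
#' @return A data frame with columns `ALPHA`, `ALPHA2`, `HM`, `MAP`, `PBPI`,
#'   `PBPIRC`, `RC` and an attribute `n_invalid` (count of records with
#'   invalid vitals).
#' @examples
#' cs_indicators(c(120, 0), c(80, 0), c(70, 0))  # second row all NA
#' @export
cs_indicators <- function(sbp, dbp = NULL, hr = NULL,
                          conventions = cs_conventions()) {
  if (is.data.frame(sbp)) {
    d <- sbp
    stopifnot(all(c("sbp", "dbp", "hr") %in% names(d)))
    sbp <- d$sbp; dbp <- d$dbp; hr <- d$hr
  }
  n <- length(sbp)
  stopifnot(length(dbp) == n, length(hr) == n)
  ok <- valid_vitals(sbp, dbp, hr)
  out <- data.frame(ALPHA = rep(NA_real_, n), ALPHA2 = NA_real_,
                    HM = NA_real_, MAP = NA_real_, PBPI = NA_real_,
                    PBPIRC = NA_real_, RC = NA_real_)
  if (any(ok)) {
    s <- sbp[ok]; d <- dbp[ok]; h <- hr[ok]
    out$MAP[ok] <- cs_map(s, d)
    out$RC[ok] <- cs_rc(s, d, h, conventions)
    out$PBPI[ok] <- cs_pbpi(s, d)
    out$PBPIRC[ok] <- out$PBPI[ok] / out$RC[ok]
    out$HM[ok] <- cs_hm(s, d, h, conventions)
    a <- suppressWarnings(cs_alpha(s, d, h, conventions))
    out$ALPHA[ok] <- a
    out$ALPHA2[ok] <- ifelse(is.na(a), NA_real_, -log(a))
  }
  attr(out, "n_invalid") <- sum(!ok)
  out
}

#' Fixed reporting order of the indicators
#' @return Character vector `ALPHA, ALPHA2, HM, MAP, PBPI, PBPIRC, RC`.
#' @export
cs_indicator_names <- function() {
  c("ALPHA", "ALPHA2", "HM", "MAP", "PBPI", "PBPIRC", "RC")
}

#' Attach indicator columns to a cohort
#'
#' Computes the seven indicators from the cohort's vitals columns and appends
#' (or refreshes) them as columns, extending the variable registry.
#'
#' @param cohort A `cs_cohort` (see [as_cohort()]).
#' @param conventions A [cs_conventions()] object.
#' @return The cohort with indicator columns added.
#' @export
add_indicators <- function(cohort, conventions = cs_conventions()) {
  ind <- cs_indicators(cohort$sbp, cohort$dbp, cohort$hr, conventions)
  for (nm in names(ind)) cohort[[nm]] <- ind[[nm]]
  reg <- attr(cohort, "registry")
  if (!is.null(reg)) {
    add <- !(cs_indicator_names() %in% reg$column)
    if (any(add)) {
      reg <- rbind(reg, data.frame(
        code = cs_indicator_names()[add],
        column = cs_indicator_names()[add],
        description = c("ejection-time fraction", "-log ejection fraction",
                        "harmony measure", "mean arterial pressure",
                        "pulsatile blood pressure index", "PBPI / RC",
                        "resistance-compliance product")[add],
        type = "numeric", role = "indicator"))
      attr(cohort, "registry") <- reg
    }
  }
  cohort
}
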