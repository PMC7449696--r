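# Competitive-fitness (selection-coefficient) estimation from labeled vs
# spike-in event counts over recovery. Under constant exponential growth the
# log of the count ratio, normalized to its initial mixing fraction, is
# linear in time with slope r_labeled - r_ref; only the early, linear
# portion of the series is fitted.

#' Construct a growth series
#'
#' @param time timepoints in minutes.
#' @param n_labeled,n_spike gated, BV421-filtered event counts of the
#'   labeled (stressed) and unlabeled spike-in reference populations.
#' @return a `growth_series` data frame.
#' @export
growth_series <- function(time, n_labeled, n_spike) {
  stopifnot(length(time) == length(n_labeled),
            length(time) == length(n_spike),
            all(n_labeled >= 0), all(n_spike >= 0))
  out <- data.frame(time = time, n_labeled = n_labeled, n_spike = n_spike)
  out <- out[order(out$time), , drop = FALSE]
  rownames(out) <- NULL
  class(out) <- c("growth_series", "data.frame")
  out
}

#' Log count-ratio series
#'
#' Computes \eqn{y(t) = \ln\left[\frac{n_{lab}(t)}{n_{spk}(t)} \cdot
#' \frac{n_{spk}(0)}{n_{lab}(0)}\right]}, so that `y(0) = 0` and the slope
#' of `y` against `t` is the growth-rate difference. Timepoints with a zero
#' count in either population are dropped (no pseudocounts) and the dropped
#' times are reported via an attribute.
#'
#' @param series a `growth_series` (first row is the t = 0 reference).
#' @return data frame with columns `time`, `log_ratio`;
#'   `attr(, "dropped_times")` lists timepoints removed for zero counts.
#' @export
log_ratio_series <- function(series) {
  stopifnot(is.data.frame(series),
            all(c("time", "n_labeled", "n_spike") %in% names(series)))
  s <- series[order(series$time), , drop = FALSE]
  if (s$n_labeled[1] <= 0 || s$n_spike[1] <= 0) {
    stop("initial counts must be positive to define the mixing fraction")
  }
  mix0 <- s$n_labeled[1] / s$n_spike[1]
  ok <- s$n_labeled > 0 & s$n_spike > 0
  dropped <- s$time[!ok]
  s <- s[ok, , drop = FALSE]
  if (nrow(s) < 3) {
    stop("fewer than 3 timepoints with positive counts in both populations")
  }
  out <- data.frame(time = s$time,
                    log_ratio = log((s$n_labeled / s$n_spike) / mix0))
  attr(out, "dropped_times") <- dropped
  out
}

#' Fit the growth-rate difference (selection coefficient)
#'
#' Ordinary least-squares slope of the log count ratio against time,
#' restricted to the linear early-recovery window: timepoints strictly less
#' than `window` minutes (100 min for untreated stress series, 160 min when
#' ionophore treatment delays induction and growth resumption). The
#' intercept is left free. A curvature warning is raised when the windowed
#' fit's residual spread is much smaller than the full series', indicating
#' the excluded tail departs from linearity.
#'
#' @param pairs data frame with `time` and `log_ratio` (see
#'   [log_ratio_series()]).
#' @param window upper time bound in minutes (points with `time < window`
#'   are fitted); `Inf` fits everything.
#' @param check_curvature compare windowed vs full-series fit and warn on
#'   strong curvature (default TRUE when the window excludes points).
#' @return a `fitness_estimate` with `slope` (1/min), `se`, `window`, `n`,
#'   `corrections` (empty), `components`.
#' @export
fit_growth_difference <- function(pairs, window = Inf,
                                  check_curvature = TRUE) {
  stopifnot(all(c("time", "log_ratio") %in% names(pairs)), window > 0)
  inside <- pairs$time < window
  sub <- pairs[inside, , drop = FALSE]
  if (nrow(sub) < 3) {
    stop("window leaves fewer than 3 points; cannot fit a slope")
  }
  fit <- lm(log_ratio ~ time, data = sub)
  slope <- unname(coef(fit)[["time"]])
  # direct OLS standard error (avoids summary.lm's perfect-fit warning on
  # noiseless closed-form series)
  res <- residuals(fit)
  sxx <- sum((sub$time - mean(sub$time))^2)
  se <- sqrt(sum(res^2) / (nrow(sub) - 2) / sxx)
  if (check_curvature && any(!inside) && nrow(pairs) >= 4) {
    full <- lm(log_ratio ~ time, data = pairs)
    rms_w <- sqrt(mean(residuals(fit)^2))
    rms_f <- sqrt(mean(residuals(full)^2))
    if (is.finite(rms_w) && rms_f > 5 * (rms_w + 1e-12)) {
      warning("series is strongly curved outside the fitting window; ",
              "exponential-growth assumption holds only within it")
    }
  }
  structure(
    list(slope = slope, se = se, window = window, n = nrow(sub),
         corrections = character(0),
         components = c(raw = slope)),
    class = "fitness_estimate"
  )
}

#' @export
print.fitness_estimate <- function(x, ...) {
  cat("Relative growth rate (selection coefficient)\n")
  cat(sprintf("  slope = %.5g /min  (SE %.2g, n = %d, window < %s min)\n",
              x$slope, x$se, x$n,
              if (is.infinite(x$window)) "Inf" else format(x$window)))
  if (length(x$corrections)) {
    cat("  corrections applied:", paste(x$corrections, collapse = ", "), "\n")
    cat("  components:",
        paste(sprintf("%s = %.5g", names(x$components), x$components),
              collapse = ", "), "\n")
  }
  invisible(x)
}

#' Apply mock and mix-in corrections to a fitness estimate
#'
#' Two controls isolate the treatment effect: a mix-in control (both
#' populations handled identically, no treatment) measures the pure strain
#' effect of carrying the fluorescent label, and a mock control (labeled
#' population put through the pH-manipulation handling at room temperature,
#' no heat) measures handling plus strain. Rates add in exponential growth,
#' so corrections are subtractive in rate space:
#' corrected = raw - mixin - (mock - mixin) = raw - mock.
#' All three estimates must share the same fitting window. Component slopes
#' are retained for reporting; the standard error is propagated in
#' quadrature.
#'
#' @param raw,mock,mixin `fitness_estimate`s from the treated series and the
#'   two control series.
#' @return a corrected `fitness_estimate`.
#' @export
apply_corrections <- function(raw, mock, mixin) {
  stopifnot(inherits(raw, "fitness_estimate"),
            inherits(mock, "fitness_estimate"),
            inherits(mixin, "fitness_estimate"))
  if (!isTRUE(all.equal(raw$window, mock$window)) ||
      !isTRUE(all.equal(raw$window, mixin$window))) {
    stop("raw, mock and mix-in estimates must use the same fitting window")
  }
  corrected <- raw$slope - mixin$slope - (mock$slope - mixin$slope)
  structure(
    list(slope = corrected,
         se = sqrt(raw$se^2 + mock$se^2),
         window = raw$window, n = raw$n,
         corrections = c("mock", "mixin"),
         components = c(raw = raw$slope, mock = mock$slope,
                        mixin = mixin$slope)),
    class = "fitness_estimate"
  )
}

#' Growth rate relative to the fully arrested bound
#'
#' Re-expresses a labeled-vs-reference slope as a difference from the
#' theoretical minimum for completely arrested cells: an arrested population
#' has absolute rate 0, hence relative slope `-r_ref`, which maps to 0 on
#' this scale; a population matching the reference's growth maps to `r_ref`
#' (e.g. ln(2)/70 per minute for a 70-minute doubling time).
#'
#' @param est a `fitness_estimate` (slope = r_labeled - r_ref).
#' @param r_ref absolute growth rate of the spike-in reference (1/min),
#'   must be > 0.
#' @return slope relative to arrest, i.e. the labeled population's absolute
#'   growth rate, in 1/min.
#' @export
relative_to_arrest <- function(est, r_ref) {
  stopifnot(inherits(est, "fitness_estimate"))
  if (!is.numeric(r_ref) || length(r_ref) != 1 || r_ref <= 0) {
    stop("r_ref must be a single positive rate (1/min)")
  }
  est$slope + r_ref
}
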