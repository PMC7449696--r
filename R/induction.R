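# Ssa4-mCherry induction kinetics: fold-change curves relative to an
# unstressed baseline, constrained sigmoid fits in the log domain, midpoint
# induction delays, and sliding-window smoothing of continuous-time traces.

# median red fluorescence normalized to forward scatter
red_per_fsc <- function(events, method = c("per_cell", "ratio_of_medians")) {
  method <- match.arg(method)
  if (method == "per_cell") {
    median(events$ch_red / events$fsc_area, na.rm = TRUE)
  } else {
    median(events$ch_red, na.rm = TRUE) / median(events$fsc_area, na.rm = TRUE)
  }
}

#' Induction fold-change curve
#'
#' Per timepoint, the median over cells of red fluorescence as a ratio to
#' forward scatter, divided by the same statistic in a within-experiment
#' unstressed baseline; the curve is anchored at 1 for unstressed cells.
#'
#' @param timecourse event table with a `timepoint` column; should already
#'   be gated, BV421-filtered and restricted to labeled cells.
#' @param baseline event table of unstressed cells from the same experiment.
#' @param method `"per_cell"` (median of per-cell `ch_red/fsc_area`, the
#'   default) or `"ratio_of_medians"`; the two agree for scale-family
#'   distributions.
#' @param min_cells warn when a timepoint has fewer cells than this
#'   (default 1000).
#' @return an `induction_curve` data frame with columns `time`,
#'   `fold_change`, `n_cells`.
#' @export
fold_change_curve <- function(timecourse, baseline,
                              method = c("per_cell", "ratio_of_medians"),
                              min_cells = 1000) {
  method <- match.arg(method)
  stopifnot(is.data.frame(timecourse), "timepoint" %in% names(timecourse))
  base_stat <- red_per_fsc(baseline, method)
  if (!is.finite(base_stat) || base_stat <= 0) {
    stop("baseline red/FSC statistic is not positive; cannot normalize")
  }
  times <- sort(unique(timecourse$timepoint))
  rows <- lapply(times, function(t) {
    ev <- timecourse[timecourse$timepoint == t, , drop = FALSE]
    data.frame(time = t,
               fold_change = red_per_fsc(ev, method) / base_stat,
               n_cells = nrow(ev))
  })
  out <- do.call(rbind, rows)
  if (any(out$n_cells < min_cells)) {
    warning(sum(out$n_cells < min_cells),
            " timepoint(s) below the minimum of ", min_cells, " cells")
  }
  class(out) <- c("induction_curve", "data.frame")
  out
}

#' Fit the constrained induction sigmoid
#'
#' Least-squares fit, on log-transformed fold change, of
#' \deqn{\mathrm{fold\ change}(t) = \frac{a}{1 + e^{-b (t - c)}} + d}
#' with the baseline constrained to `d >= 1` (fold change of unstressed
#' cells cannot fall below 1 by construction). Bounded Levenberg-Marquardt
#' with deterministic multi-start over rate and midpoint heuristics; the
#' lowest log-domain RSS wins. A curve with fitted amplitude below
#' `a_floor` is flagged `no_induction`.
#'
#' @param curve an `induction_curve` (or data frame with `time` and
#'   `fold_change`).
#' @param a_floor amplitude below which the fit is flagged as no induction
#'   (default 0.1).
#' @param epsilon fold-change values at or below 0 are floored here before
#'   the log transform (count reported via attribute).
#' @return an `induction_fit` with elements `a`, `b`, `c`, `d`, `rss`
#'   (log domain), `converged`, `no_induction`, `n_floored`.
#' @export
fit_induction <- function(curve, a_floor = 0.1, epsilon = 1e-6) {
  stopifnot(all(c("time", "fold_change") %in% names(curve)))
  t <- curve$time
  y <- curve$fold_change
  keep <- is.finite(t) & is.finite(y)
  t <- t[keep]; y <- y[keep]
  if (length(t) < 5) stop("need >= 5 timepoints to fit the induction sigmoid")
  n_floored <- sum(y <= 0)
  y <- pmax(y, epsilon)
  ly <- log(y)
  span <- diff(range(t))

  # an exactly flat curve carries no kinetic information: report zero
  # amplitude, flagged, rather than letting the optimizer chase a ridge
  if (diff(range(ly)) < 1e-10) {
    d_flat <- max(exp(mean(ly)), 1)
    return(structure(
      list(a = 0, b = 0, c = NA_real_, d = d_flat,
           rss = sum((ly - log(d_flat))^2), converged = TRUE,
           no_induction = TRUE, n_floored = n_floored, n_points = length(t)),
      class = "induction_fit"))
  }

  amp0 <- max(max(y) - min(y), 1e-3)
  # midpoint heuristic: first time the curve crosses half its rise
  half <- min(y) + (max(y) - min(y)) / 2
  c0 <- t[which.min(abs(y - half))]
  starts <- expand.grid(b = c(0.02, 0.05, 0.15), c = unique(c(c0, median(t))))
  lower <- c(a = 0, b = 1e-4, c = min(t) - span, d = 1)
  upper <- c(a = 50 * max(amp0, 1), b = 5, c = max(t) + span, d = max(max(y), 1) + 1)
  obj <- function(p) sum((ly - log(ratio_sigmoid(t, p[1], p[2], p[3], p[4])))^2)

  fits <- lapply(seq_len(nrow(starts)), function(i) {
    st <- list(a = amp0, b = starts$b[i], c = starts$c[i], d = 1)
    tryCatch({
      fit <- minpack.lm::nlsLM(
        ly ~ log(a / (1 + exp(-b * (tt - c))) + d),
        data = data.frame(tt = t, ly = ly),
        start = st, lower = lower, upper = upper,
        control = minpack.lm::nls.lm.control(maxiter = 500, ftol = 1e-14,
                                             ptol = 1e-14)
      )
      p <- coef(fit)
      list(par = p, rss = obj(p))
    }, error = function(e) NULL)
  })
  fits <- Filter(Negate(is.null), fits)
  if (length(fits) == 0) stop("induction fit failed to converge from all starts")
  best <- fits[[which.min(vapply(fits, `[[`, numeric(1), "rss"))]]
  p <- best$par
  structure(
    list(a = p[["a"]], b = p[["b"]], c = p[["c"]], d = p[["d"]],
         rss = best$rss, converged = TRUE,
         no_induction = p[["a"]] < a_floor,
         n_floored = n_floored, n_points = length(t)),
    class = "induction_fit"
  )
}

#' @export
print.induction_fit <- function(x, ...) {
  cat("Induction sigmoid fit (log-domain least squares, d >= 1)\n")
  cat(sprintf("  amplitude a = %.4g   rate b = %.4g /min\n", x$a, x$b))
  cat(sprintf("  midpoint  c = %.4g min   baseline d = %.4g\n", x$c, x$d))
  cat(sprintf("  RSS(log) = %.4g over %d timepoints%s\n", x$rss, x$n_points,
              if (x$no_induction) "  [flagged: no induction]" else ""))
  invisible(x)
}

#' Induction delay (sigmoid midpoint)
#'
#' The delay between stress and half-maximal chaperone induction is read off
#' as the fitted midpoint `c`. Fits flagged as showing no induction return
#' `NA` (a delay is meaningless for a flat curve).
#'
#' @param fit an `induction_fit`.
#' @return midpoint in minutes, or `NA`.
#' @export
induction_delay <- function(fit) {
  stopifnot(inherits(fit, "induction_fit"))
  if (isTRUE(fit$no_induction) || !isTRUE(fit$converged)) return(NA_real_)
  fit$c
}

#' Centered sliding-window average
#'
#' Smooths a continuous-time series with a centered moving average; at the
#' edges the window is truncated to the available data. Note that centered
#' smoothing lets a sharp change bleed into earlier times (e.g. an apparent
#' pre-shock pH drift when smoothing across the shock onset); this is a
#' property of the window, not of the data.
#'
#' @param time numeric times (any order; output follows input order).
#' @param value values to smooth.
#' @param window full window width in time units (events with
#'   `|t - t_i| <= window/2` are averaged), or if `count = TRUE`, an odd
#'   number of samples.
#' @param count interpret `window` as a sample count instead of a time span.
#' @return numeric vector of smoothed values, same length as the input.
#' @export
sliding_window <- function(time, value, window, count = FALSE) {
  stopifnot(length(time) == length(value), window > 0)
  ord <- order(time)
  t_s <- time[ord]; v_s <- value[ord]
  n <- length(t_s)
  out_s <- numeric(n)
  if (count) {
    k <- as.integer(window)
    half <- (k - 1) %/% 2
    cs <- cumsum(c(0, v_s))
    lo <- pmax(seq_len(n) - half, 1)
    hi <- pmin(seq_len(n) + half, n)
    out_s <- (cs[hi + 1] - cs[lo]) / (hi - lo + 1)
  } else {
    half <- window / 2
    # first index with t >= t_i - half; last index with t <= t_i + half
    lo <- findInterval(t_s - half, t_s, left.open = TRUE) + 1
    hi <- findInterval(t_s + half, t_s)
    cs <- cumsum(c(0, v_s))
    out_s <- (cs[hi + 1] - cs[lo]) / (hi - lo + 1)
  }
  out <- numeric(n)
  out[ord] <- out_s
  out
}
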