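#' Four-parameter logistic describing the pHluorin excitation ratio
#'
#' The background-corrected 405:488 excitation ratio of pHluorin as a
#' function of pH is modelled as
#' \deqn{R(pH) = \frac{a}{1 + e^{-b (pH - c)}} + d}
#' with `a` the ratio span, `b` the steepness (1/pH), `c` the midpoint (pH
#' units) and `d` the ratio offset.
#'
#' @param ph numeric vector of pH values.
#' @param a,b,c,d sigmoid parameters.
#' @return numeric vector of predicted ratios.
#' @export
ratio_sigmoid <- function(ph, a, b, c, d) {
  a / (1 + exp(-b * (ph - c))) + d
}

#' Subtract channel autofluorescence background from pHluorin channels
#'
#' Background is measured as the median autofluorescence of unlabeled
#' (wild-type) cells in the matching matrix (growth media or calibration
#' buffer). Both pHluorin channels are shifted; events driven non-positive
#' in either channel are flagged and excluded from ratio computation (their
#' `ratio405_488` is `NA`) rather than clamped.
#'
#' @param events an event table (data frame with at least `ch405`, `ch488`).
#' @param background named numeric vector with elements `ch405` and `ch488`:
#'   median autofluorescence to subtract, in channel units.
#' @return the event table with corrected `ch405`, `ch488`, a
#'   `ratio405_488` column, and a logical `ratio_ok` column. The number of
#'   excluded events is available as `attr(x, "n_excluded_background")`.
#' @export
subtract_background <- function(events, background) {
  stopifnot(is.data.frame(events))
  if (is.null(background) || !all(c("ch405", "ch488") %in% names(background))) {
    stop("background must be a named vector with 'ch405' and 'ch488' ",
         "(median autofluorescence of unlabeled cells in the matching matrix)")
  }
  events$ch405 <- events$ch405 - background[["ch405"]]
  events$ch488 <- events$ch488 - background[["ch488"]]
  ok <- is.finite(events$ch405) & is.finite(events$ch488) &
    events$ch405 > 0 & events$ch488 > 0
  events$ratio405_488 <- ifelse(ok, events$ch405 / events$ch488, NA_real_)
  events$ratio_ok <- ok
  attr(events, "n_excluded_background") <- sum(!ok)
  events
}

#' Per-buffer median calibration points
#'
#' Reduces a list of background-corrected calibration event tables (one per
#' buffer pH) to one `(buffer_ph, ratio)` point each, taking the median of
#' the per-event 405:488 ratio.
#'
#' @param event_tables list of event tables with a `ratio405_488` column and
#'   a `buffer_ph` column (constant within each table).
#' @return data frame with columns `buffer_ph`, `ratio`, `n_events`.
#' @export
calibration_points <- function(event_tables) {
  stopifnot(is.list(event_tables), length(event_tables) >= 1)
  rows <- lapply(event_tables, function(tab) {
    r <- tab$ratio405_488
    r <- r[is.finite(r)]
    data.frame(buffer_ph = tab$buffer_ph[1],
               ratio = median(r),
               n_events = length(r))
  })
  out <- do.call(rbind, rows)
  out[order(out$buffer_ph), , drop = FALSE]
}

# least-squares objective for the calibration sigmoid
.calib_rss <- function(par, ph, ratio) {
  sum((ratio - ratio_sigmoid(ph, par[1], par[2], par[3], par[4]))^2)
}

#' Fit the pHluorin calibration sigmoid
#'
#' Least-squares fit of the four-parameter logistic to per-buffer median
#' ratios. The fit uses bounded Levenberg-Marquardt with four deterministic
#' initializations (midpoint/quartile heuristics, both sign conventions for
#' the steepness); the candidate with the smallest residual sum of squares
#' wins, ties broken by smallest `|b|`. The sign convention `a > 0` is
#' enforced through the reflection symmetry
#' `(a, b, c, d) -> (-a, -b, c, a + d)` of the logistic.
#'
#' @param points data frame with columns `buffer_ph` and `ratio` (one point
#'   per buffer), e.g. from [calibration_points()].
#' @param min_ratio_range refuse to fit when the ratio range across points is
#'   below this floor (non-sigmoidal data). Default 0.05.
#' @param background optional numeric vector `c(ch405=, ch488=)` recording
#'   the background that was subtracted upstream (stored, not applied).
#' @return an object of class `calibration_fit` with elements `a`, `b`, `c`,
#'   `d`, `r_min`, `r_max`, `pka_eff`, `rss`, `n_points`, `ph_range`,
#'   `background`.
#' @export
fit_calibration <- function(points, min_ratio_range = 0.05, background = NULL) {
  stopifnot(is.data.frame(points), all(c("buffer_ph", "ratio") %in% names(points)))
  points <- points[is.finite(points$ratio) & is.finite(points$buffer_ph), ]
  if (nrow(points) < 5) {
    stop("under-determined calibration: need >= 5 buffer points, got ",
         nrow(points))
  }
  if (diff(range(points$buffer_ph)) < 2) {
    stop("calibration buffers must span at least 2 pH units")
  }
  if (diff(range(points$ratio)) < min_ratio_range) {
    stop("non-sigmoidal calibration data: ratio range ",
         signif(diff(range(points$ratio)), 3), " is below the floor ",
         min_ratio_range)
  }
  ph <- points$buffer_ph
  ratio <- points$ratio

  span <- diff(range(ratio))
  d0 <- min(ratio)
  mid_ratio <- d0 + span / 2
  c0 <- ph[which.min(abs(ratio - mid_ratio))]
  # slope heuristic from the inner quartile rise: logistic max slope = a*b/4
  b_quart <- abs(diff(quantile(ratio, c(0.25, 0.75), names = FALSE))) /
    max(diff(quantile(ph, c(0.25, 0.75), names = FALSE)), 0.5) * 4 / span
  starts <- list(
    c(a = span, b = max(b_quart, 0.2), c = c0, d = d0),
    c(a = span, b = 1, c = median(ph), d = d0),
    c(a = span, b = -max(b_quart, 0.2), c = c0, d = max(ratio) - span),
    c(a = span, b = -1, c = median(ph), d = max(ratio) - span)
  )

  lower <- c(a = span * 0.05, b = -50, c = min(ph) - 2, d = min(ratio) - span)
  upper <- c(a = span * 20, b = 50, c = max(ph) + 2, d = max(ratio))
  fits <- lapply(starts, function(st) {
    tryCatch({
      fit <- minpack.lm::nlsLM(
        ratio ~ a / (1 + exp(-b * (ph - c))) + d,
        data = data.frame(ph = ph, ratio = ratio),
        start = as.list(st), lower = lower, upper = upper,
        control = minpack.lm::nls.lm.control(maxiter = 500, ftol = 1e-14,
                                             ptol = 1e-14)
      )
      p <- coef(fit)
      list(par = p, rss = .calib_rss(p, ph, ratio))
    }, error = function(e) NULL)
  })
  fits <- Filter(Negate(is.null), fits)
  if (length(fits) == 0) {
    stop("calibration optimizer failed to converge from all starts")
  }
  rss <- vapply(fits, `[[`, numeric(1), "rss")
  absb <- vapply(fits, function(f) abs(f$par[["b"]]), numeric(1))
  best <- fits[[order(rss, absb)[1]]]
  par <- best$par
  # normalize to the a > 0 convention via reflection symmetry
  if (par[["a"]] < 0) {
    par <- c(a = -par[["a"]], b = -par[["b"]], c = par[["c"]],
             d = par[["a"]] + par[["d"]])
  }
  fit <- structure(
    list(a = par[["a"]], b = par[["b"]], c = par[["c"]], d = par[["d"]],
         r_min = min(par[["d"]], par[["a"]] + par[["d"]]),
         r_max = max(par[["d"]], par[["a"]] + par[["d"]]),
         rss = best$rss, n_points = nrow(points),
         ph_range = range(ph),
         background = background),
    class = "calibration_fit"
  )
  fit$pka_eff <- effective_pka(fit)
  fit
}

#' @export
print.calibration_fit <- function(x, ...) {
  cat("pHluorin calibration fit (4-parameter logistic)\n")
  cat(sprintf("  a = %.5g  b = %.5g /pH  c = %.5g  d = %.5g\n",
              x$a, x$b, x$c, x$d))
  cat(sprintf("  ratio asymptotes: [%.5g, %.5g]\n", x$r_min, x$r_max))
  cat(sprintf("  effective pKa = %.4f\n", x$pka_eff))
  cat(sprintf("  RSS = %.4g over %d buffer points (pH %.2f-%.2f)\n",
              x$rss, x$n_points, x$ph_range[1], x$ph_range[2]))
  invisible(x)
}

#' Effective pKa of the biosensor from a calibration fit
#'
#' The effective pKa is the pH at which the ratio lies midway between its
#' asymptotic extremes, i.e. the root of
#' \deqn{\log\frac{R - R_{max}}{R_{min} - R} = 0,}
#' located numerically on the fitted curve. For the four-parameter logistic
#' this root coincides with the midpoint parameter `c`; the numerical route
#' is kept so the definition, not the parameterization, is what is computed.
#'
#' @param fit a `calibration_fit`.
#' @return the effective pKa in pH units.
#' @export
effective_pka <- function(fit) {
  stopifnot(inherits(fit, "calibration_fit"))
  f <- function(ph) {
    r <- ratio_sigmoid(ph, fit$a, fit$b, fit$c, fit$d)
    log((r - fit$r_max) / (fit$r_min - r))
  }
  # the midpoint is bracketed well inside the logistic's dynamic range
  half_width <- 20 / abs(fit$b)
  uniroot(f, interval = c(fit$c - half_width, fit$c + half_width),
          tol = 1e-12)$root
}

#' Convert 405:488 ratios to intracellular pH
#'
#' Inverts the calibration sigmoid:
#' \deqn{pH = c - \frac{1}{b} \ln\left(\frac{a}{R - d} - 1\right).}
#' Ratios outside the open interval `(r_min, r_max)` cannot be inverted and
#' become missing values (never clamped), with the out-of-range count
#' attached as an attribute.
#'
#' @param fit a `calibration_fit`.
#' @param ratio numeric vector of background-corrected 405:488 ratios.
#' @return numeric vector of pH values, `NA` where the ratio is out of
#'   range; `attr(, "n_out_of_range")` counts the flagged events.
#' @export
ratio_to_ph <- function(fit, ratio) {
  stopifnot(inherits(fit, "calibration_fit"))
  inside <- is.finite(ratio) & ratio > fit$r_min & ratio < fit$r_max
  ph <- rep(NA_real_, length(ratio))
  ph[inside] <- fit$c - log(fit$a / (ratio[inside] - fit$d) - 1) / fit$b
  attr(ph, "n_out_of_range") <- sum(!inside & !is.na(ratio))
  ph
}

#' Attach per-cell pH to an event table
#'
#' Applies [ratio_to_ph()] to the `ratio405_488` column.
#'
#' @param events event table with a `ratio405_488` column (see
#'   [subtract_background()]).
#' @param fit a `calibration_fit`.
#' @return the event table with a `ph` column.
#' @export
add_ph <- function(events, fit) {
  stopifnot(is.data.frame(events), "ratio405_488" %in% names(events))
  ph <- ratio_to_ph(fit, events$ratio405_488)
  events$ph <- as.numeric(ph)
  attr(events, "n_ph_out_of_range") <- attr(ph, "n_out_of_range")
  events
}

#' Serialize / read a calibration fit as plain text
#'
#' A versioned key-value text format so a per-experiment calibration can be
#' stored next to its event files and passed explicitly to conversion steps.
#'
#' @param fit a `calibration_fit`.
#' @param path file path.
#' @return `write_calibration` returns `path` invisibly; `read_calibration`
#'   returns a `calibration_fit`.
#' @export
write_calibration <- function(fit, path) {
  stopifnot(inherits(fit, "calibration_fit"))
  bg <- fit$background
  lines <- c(
    "phshock_calibration_v1",
    sprintf("a\t%.17g", fit$a), sprintf("b\t%.17g", fit$b),
    sprintf("c\t%.17g", fit$c), sprintf("d\t%.17g", fit$d),
    sprintf("rss\t%.17g", fit$rss),
    sprintf("n_points\t%d", fit$n_points),
    sprintf("ph_min\t%.17g", fit$ph_range[1]),
    sprintf("ph_max\t%.17g", fit$ph_range[2]),
    sprintf("background_405\t%.17g", if (is.null(bg)) NA_real_ else bg[["ch405"]]),
    sprintf("background_488\t%.17g", if (is.null(bg)) NA_real_ else bg[["ch488"]])
  )
  writeLines(lines, path)
  invisible(path)
}

#' @rdname write_calibration
#' @export
read_calibration <- function(path) {
  lines <- readLines(path)
  if (lines[1] != "phshock_calibration_v1") {
    stop("not a phshock calibration file: ", path)
  }
  kv <- strsplit(lines[-1], "\t", fixed = TRUE)
  vals <- setNames(as.numeric(vapply(kv, `[`, character(1), 2)),
                   vapply(kv, `[`, character(1), 1))
  bg <- c(ch405 = vals[["background_405"]], ch488 = vals[["background_488"]])
  if (all(is.na(bg))) bg <- NULL
  fit <- structure(
    list(a = vals[["a"]], b = vals[["b"]], c = vals[["c"]], d = vals[["d"]],
         r_min = min(vals[["d"]], vals[["a"]] + vals[["d"]]),
         r_max = max(vals[["d"]], vals[["a"]] + vals[["d"]]),
         rss = vals[["rss"]], n_points = as.integer(vals[["n_points"]]),
         ph_range = c(vals[["ph_min"]], vals[["ph_max"]]),
         background = bg),
    class = "calibration_fit"
  )
  fit$pka_eff <- effective_pka(fit)
  fit
}
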