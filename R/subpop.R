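# Two-component Gaussian-mixture classification with a posterior cutoff:
# used both for Ssa4 expression level (high vs low, fitted on log fold
# change) and for budding state from FSC pulse width (linear scale), plus
# resting-pH-range fractions and rank-based pH comparisons between classes.

# log-likelihood of a 1-D two-component Gaussian mixture
.mix_loglik <- function(x, mu, sigma, w) {
  sum(log(w[1] * dnorm(x, mu[1], sigma[1]) +
            w[2] * dnorm(x, mu[2], sigma[2])))
}

# one EM run from a hard split of the data
.mix_em <- function(x, assign_high, sigma_floor, max_iter = 500, tol = 1e-10) {
  n <- length(x)
  groups <- list(x[!assign_high], x[assign_high])
  if (any(vapply(groups, length, integer(1)) < 2)) return(NULL)
  mu <- vapply(groups, mean, numeric(1))
  sigma <- pmax(vapply(groups, sd, numeric(1)), sigma_floor)
  w <- vapply(groups, length, integer(1)) / n
  ll_old <- -Inf
  converged <- FALSE
  for (iter in seq_len(max_iter)) {
    d1 <- w[1] * dnorm(x, mu[1], sigma[1])
    d2 <- w[2] * dnorm(x, mu[2], sigma[2])
    tot <- d1 + d2
    tot[tot == 0] <- .Machine$double.xmin
    g2 <- d2 / tot
    g1 <- 1 - g2
    w <- c(mean(g1), mean(g2))
    mu <- c(sum(g1 * x) / sum(g1), sum(g2 * x) / sum(g2))
    sigma <- pmax(c(sqrt(sum(g1 * (x - mu[1])^2) / sum(g1)),
                    sqrt(sum(g2 * (x - mu[2])^2) / sum(g2))),
                  sigma_floor)
    ll <- .mix_loglik(x, mu, sigma, w)
    if (is.finite(ll) && abs(ll - ll_old) < tol * (abs(ll_old) + 1)) {
      converged <- TRUE
      ll_old <- ll
      break
    }
    ll_old <- ll
  }
  list(mu = mu, sigma = sigma, w = w, loglik = ll_old, converged = converged)
}

#' Fit a two-component Gaussian mixture
#'
#' EM fit of a two-component univariate Gaussian mixture, with deterministic
#' initialization: three hard splits of the data (at the median and at the
#' 25th and 75th percentiles) each seed one EM run, and the run with the
#' best log-likelihood wins (ties broken by larger component separation).
#' Components are ordered by mean. A floor of `1e-6` times the data range on
#' the component standard deviations prevents the likelihood from diverging
#' on degenerate clusters. Fits whose component means are closer than one
#' pooled standard deviation are flagged `poorly_separated`.
#'
#' @param x numeric values (at least 50 finite values).
#' @param domain `"linear"` to fit the raw values or `"log"` to fit
#'   `log(x)` (multiplicative signals such as fluorescence); the returned
#'   parameters are in the fitted domain.
#' @return a `mixture_fit` with `means`, `sds`, `weights` (component 1 has
#'   the lower mean), `loglik`, `converged`, `poorly_separated`, `domain`,
#'   `n`.
#' @export
fit_two_component <- function(x, domain = c("linear", "log")) {
  domain <- match.arg(domain)
  x <- x[is.finite(x)]
  if (domain == "log") {
    if (any(x <= 0)) {
      n_drop <- sum(x <= 0)
      x <- x[x > 0]
      warning(n_drop, " non-positive value(s) dropped before log transform")
    }
    x <- log(x)
  }
  if (length(x) < 50) stop("need >= 50 finite values to fit a mixture, got ",
                           length(x))
  rng <- diff(range(x))
  sigma_floor <- max(1e-6 * rng, .Machine$double.eps)
  runs <- lapply(c(0.5, 0.25, 0.75), function(q) {
    .mix_em(x, x > quantile(x, q, names = FALSE), sigma_floor)
  })
  runs <- Filter(Negate(is.null), runs)
  if (length(runs) == 0) stop("mixture EM failed: degenerate data")
  ll <- vapply(runs, `[[`, numeric(1), "loglik")
  sep <- vapply(runs, function(r) abs(diff(r$mu)), numeric(1))
  best <- runs[[order(-ll, -sep)[1]]]
  ord <- order(best$mu)
  mu <- best$mu[ord]; sigma <- best$sigma[ord]; w <- best$w[ord]
  pooled <- sqrt(w[1] * sigma[1]^2 + w[2] * sigma[2]^2)
  # separation check: means at least one pooled sd apart AND the fitted
  # mixture density has a genuine dip between the component means (i.e. the
  # fit is actually bimodal, not a two-piece description of one mode)
  has_dip <- FALSE
  if (mu[2] > mu[1]) {
    grid <- seq(mu[1], mu[2], length.out = 201)
    dens <- w[1] * dnorm(grid, mu[1], sigma[1]) +
      w[2] * dnorm(grid, mu[2], sigma[2])
    i_min <- which.min(dens)
    has_dip <- i_min > 1 && i_min < length(grid)
  }
  structure(
    list(means = mu, sds = sigma, weights = w,
         loglik = best$loglik, converged = best$converged,
         poorly_separated = abs(diff(mu)) < pooled || !has_dip,
         domain = domain, n = length(x)),
    class = "mixture_fit"
  )
}

#' @export
print.mixture_fit <- function(x, ...) {
  cat(sprintf("Two-component Gaussian mixture (%s domain, n = %d)\n",
              x$domain, x$n))
  cat(sprintf("  comp 1: mean %.4g  sd %.4g  weight %.3f\n",
              x$means[1], x$sds[1], x$weights[1]))
  cat(sprintf("  comp 2: mean %.4g  sd %.4g  weight %.3f\n",
              x$means[2], x$sds[2], x$weights[2]))
  cat(sprintf("  logLik %.4g%s%s\n", x$loglik,
              if (!x$converged) "  [not converged]" else "",
              if (x$poorly_separated) "  [poorly separated]" else ""))
  invisible(x)
}

#' Posterior probability of the upper component
#'
#' @param fit a `mixture_fit`.
#' @param x values on the original scale (log-transformed internally when
#'   the fit used the log domain).
#' @return posterior probability that each value belongs to the component
#'   with the larger mean.
#' @export
posterior_high <- function(fit, x) {
  stopifnot(inherits(fit, "mixture_fit"))
  if (fit$domain == "log") x <- log(x)
  d1 <- fit$weights[1] * dnorm(x, fit$means[1], fit$sds[1])
  d2 <- fit$weights[2] * dnorm(x, fit$means[2], fit$sds[2])
  tot <- d1 + d2
  out <- ifelse(tot > 0, d2 / tot, NA_real_)
  # far tails where both densities underflow: decide by distance in sds
  und <- !is.finite(out) | is.na(out)
  if (any(und & is.finite(x))) {
    z1 <- abs(x - fit$means[1]) / fit$sds[1]
    z2 <- abs(x - fit$means[2]) / fit$sds[2]
    out[und & is.finite(x)] <- as.numeric(z2 < z1)[und & is.finite(x)]
  }
  out
}

#' Classify values with a posterior cutoff
#'
#' A value is assigned to a component only when its posterior probability
#' for that component reaches the cutoff; everything else is `"ambiguous"`
#' and must be excluded from downstream class statistics.
#'
#' @param fit a `mixture_fit`.
#' @param x values on the original scale.
#' @param cutoff posterior cutoff, must exceed 0.5 (default 0.90, the
#'   confidence used for both expression and budding classification).
#' @param labels two labels for the lower and upper component, e.g.
#'   `c("low", "high")` or `c("unbudded", "budded")`.
#' @return character vector of labels (`labels[1]`, `labels[2]` or
#'   `"ambiguous"`); the posterior is attached as `attr(, "posterior_high")`.
#' @export
classify_mixture <- function(fit, x, cutoff = 0.90,
                             labels = c("low", "high")) {
  if (!is.numeric(cutoff) || cutoff <= 0.5 || cutoff >= 1) {
    stop("posterior cutoff must lie in (0.5, 1); labels are ill-defined otherwise")
  }
  stopifnot(length(labels) == 2)
  p2 <- posterior_high(fit, x)
  lab <- ifelse(is.na(p2), NA_character_,
                ifelse(p2 >= cutoff, labels[2],
                       ifelse(1 - p2 >= cutoff, labels[1], "ambiguous")))
  attr(lab, "posterior_high") <- p2
  lab
}

#' Budded fraction over time
#'
#' Fraction of budded cells among non-ambiguous cells per timepoint, plus
#' the mean fraction over a stated summary window of the recovery (default
#' 90-120 min, the interval used to summarize cell-cycle reentry).
#'
#' @param time per-cell timepoints (minutes).
#' @param labels per-cell budding labels
#'   (`"budded"` / `"unbudded"` / `"ambiguous"`).
#' @param window `c(lo, hi)` minutes for the summary mean.
#' @return a `budded_fraction` data frame with columns `time`, `fraction`,
#'   `n_classified`; the windowed mean in `attr(, "window_mean")` and the
#'   window itself in `attr(, "window")`.
#' @export
budded_fraction <- function(time, labels, window = c(90, 120)) {
  stopifnot(length(time) == length(labels), length(window) == 2,
            window[1] < window[2])
  times <- sort(unique(time))
  rows <- lapply(times, function(t) {
    lab <- labels[time == t]
    lab <- lab[!is.na(lab) & lab != "ambiguous"]
    data.frame(time = t,
               fraction = if (length(lab) == 0) NA_real_
                          else mean(lab == "budded"),
               n_classified = length(lab))
  })
  out <- do.call(rbind, rows)
  inside <- out$time >= window[1] & out$time <= window[2] &
    is.finite(out$fraction)
  attr(out, "window_mean") <- if (any(inside)) mean(out$fraction[inside])
                              else NA_real_
  attr(out, "window") <- window
  class(out) <- c("budded_fraction", "data.frame")
  out
}

#' Fraction of cells inside the resting pH range
#'
#' @param ph per-cell pH values (missing values are ignored).
#' @param range `c(lower, upper)` resting pH range; the default
#'   `c(7.3, 7.8)` brackets the unstressed resting pH of about 7.5 and is a
#'   configuration choice, not a measured bound.
#' @return proportion of non-missing pH values within the closed range.
#' @export
fraction_in_range <- function(ph, range = c(7.3, 7.8)) {
  stopifnot(length(range) == 2, range[1] < range[2])
  ph <- ph[!is.na(ph)]
  if (length(ph) == 0) stop("all pH values are missing")
  mean(ph >= range[1] & ph <= range[2])
}

#' Compare intracellular pH between two cell classes
#'
#' Two-sided Mann-Whitney U (Wilcoxon rank-sum) test: exact when both
#' groups are small (n <= 12) and untied, normal approximation with tie and
#' continuity correction otherwise. Two identical constant groups — where
#' the tie-corrected variance vanishes — return p = 1.
#'
#' @param a,b numeric values for the two classes (each n >= 3).
#' @return list with `statistic` (U for the first group), `p.value`,
#'   `method`.
#' @export
compare_class_ph <- function(a, b) {
  a <- a[is.finite(a)]; b <- b[is.finite(b)]
  if (length(a) < 3 || length(b) < 3) {
    stop("both groups need n >= 3 finite values")
  }
  if (length(unique(c(a, b))) == 1) {
    return(list(statistic = length(a) * length(b) / 2, p.value = 1,
                method = "Mann-Whitney U (degenerate: all values tied)"))
  }
  ties <- anyDuplicated(c(a, b)) > 0
  use_exact <- !ties && length(a) <= 12 && length(b) <= 12
  wt <- suppressWarnings(
    wilcox.test(a, b, alternative = "two.sided", exact = use_exact,
                correct = TRUE)
  )
  list(statistic = unname(wt$statistic), p.value = wt$p.value,
       method = wt$method)
}
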