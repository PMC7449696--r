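# Two-component mixture fitting, posterior-cutoff classification, budded
# fractions, resting-range fractions, and the rank-sum comparison.

test_that("a well-separated known mixture is recovered accurately", {
  set.seed(2)
  x <- c(rnorm(1000, 0, 0.5), rnorm(1000, 5, 0.5))
  fit <- fit_two_component(x)
  expect_equal(fit$means, c(0, 5), tolerance = 0.05, ignore_attr = TRUE)
  expect_equal(fit$weights, c(0.5, 0.5), tolerance = 0.02, ignore_attr = TRUE)
  expect_false(fit$poorly_separated)
  expect_true(fit$converged)
})

test_that("mixture EM agrees with an independent implementation (mclust)", {
  withr::local_package("mclust")
  set.seed(3)
  x <- c(rnorm(700, 1, 0.6), rnorm(1300, 4, 0.9))
  fit <- fit_two_component(x)
  mc <- Mclust(x, G = 2, modelNames = "V", verbose = FALSE)
  expect_equal(sort(fit$means), sort(as.numeric(mc$parameters$mean)),
               tolerance = 0.05)
  expect_gte(fit$loglik, mc$loglik - 0.1)
})

test_that("single-mode data are flagged poorly separated", {
  set.seed(4)
  fit <- fit_two_component(rnorm(1000))
  expect_true(fit$poorly_separated)
  # and a clearly bimodal sample is not
  set.seed(4)
  fit2 <- fit_two_component(c(rnorm(500, 0, 0.5), rnorm(500, 3, 0.5)))
  expect_false(fit2$poorly_separated)
})

test_that("two-point data hit the sigma floor with equal weights", {
  x <- rep(c(0, 5), each = 50)
  fit <- fit_two_component(x)
  expect_equal(fit$means, c(0, 5), tolerance = 1e-6, ignore_attr = TRUE)
  expect_equal(fit$weights, c(0.5, 0.5), tolerance = 1e-6, ignore_attr = TRUE)
  expect_equal(fit$sds, rep(5e-6, 2), tolerance = 1e-9, ignore_attr = TRUE)
  expect_error(fit_two_component(rnorm(40)), ">= 50")
})

test_that("posterior is monotone in x for equal-variance components", {
  set.seed(5)
  x <- c(rnorm(500, 0, 1), rnorm(500, 4, 1))
  fit <- fit_two_component(x)
  grid <- seq(-3, 7, length.out = 200)
  post <- posterior_high(fit, grid)
  expect_true(all(diff(post) >= -1e-12))
})

test_that("classification honors the posterior cutoff exactly", {
  set.seed(6)
  x <- c(rnorm(2000, 0, 0.5), rnorm(2000, 4, 0.5))
  truth <- rep(c("low", "high"), each = 2000)
  fit <- fit_two_component(x)
  lab <- classify_mixture(fit, x, cutoff = 0.90)
  post <- attr(lab, "posterior_high")
  assigned <- lab != "ambiguous"
  expect_true(all(pmax(post, 1 - post)[assigned] >= 0.90))
  expect_gte(mean(lab[assigned] == truth[assigned]), 0.99)
  # a stricter cutoff can only enlarge the ambiguous band
  lab999 <- classify_mixture(fit, x, cutoff = 0.999)
  expect_gte(sum(lab999 == "ambiguous"), sum(lab == "ambiguous"))
  expect_error(classify_mixture(fit, x, cutoff = 0.5), "cutoff")
})

test_that("the equal-posterior point of a symmetric fit is ambiguous", {
  fit <- structure(list(means = c(0, 4), sds = c(1, 1), weights = c(0.5, 0.5),
                        loglik = 0, converged = TRUE, poorly_separated = FALSE,
                        domain = "linear", n = 100),
                   class = "mixture_fit")
  lab <- classify_mixture(fit, 2, cutoff = 0.9)
  expect_equal(as.character(lab), "ambiguous")
  expect_equal(attr(lab, "posterior_high"), 0.5, tolerance = 1e-12)
})

test_that("log-domain fitting classifies multiplicative expression data", {
  set.seed(7)
  x <- c(150 * exp(rnorm(1000, 0, 0.25)),
         150 * exp(rnorm(1000, 8 * 0.25, 0.25)))
  fit <- fit_two_component(x, domain = "log")
  lab <- classify_mixture(fit, x, 0.90, labels = c("low", "high"))
  truth <- rep(c("low", "high"), each = 1000)
  ok <- lab != "ambiguous"
  expect_gte(mean(lab[ok] == truth[ok]), 0.99)
  expect_lte(mean(lab == "ambiguous"), 0.02)
})

test_that("budded fraction reproduces constructed labels and window summary", {
  time <- rep(c(0, 60, 120), each = 100)
  labels <- c(rep(c("budded", "unbudded"), c(30, 70)),
              rep(c("budded", "unbudded"), c(50, 50)),
              rep(c("budded", "unbudded", "ambiguous"), c(40, 40, 20)))
  bf <- budded_fraction(time, labels, window = c(90, 120))
  expect_equal(bf$fraction, c(0.30, 0.50, 0.50))
  expect_equal(bf$n_classified, c(100, 100, 80))
  expect_equal(attr(bf, "window_mean"), 0.50)
  # all-ambiguous timepoint yields a missing fraction
  bf2 <- budded_fraction(c(0, 0), c("ambiguous", "ambiguous"))
  expect_true(is.na(bf2$fraction))
})

test_that("a simulated budding hump peaks at the planted time", {
  ev <- simulate_recovery(timepoints = seq(0, 240, 30), n_events = 3000,
                          spike_frac = 0, bv421_bright_frac = 0, seed = 8)
  labs <- rep(NA_character_, nrow(ev))
  for (t in unique(ev$timepoint)) {
    idx <- ev$timepoint == t
    fit <- fit_two_component(ev$fsc_width[idx])
    labs[idx] <- classify_mixture(fit, ev$fsc_width[idx], 0.90,
                                  labels = c("unbudded", "budded"))
  }
  bf <- budded_fraction(ev$timepoint, labs)
  peak <- bf$time[which.max(sliding_window(bf$time, bf$fraction, 61))]
  expect_lte(abs(peak - 120), 30)  # within one timepoint of the planted peak
})

test_that("resting-range fraction matches the normal CDF closed form", {
  expect_equal(fraction_in_range(c(7.4, 7.5, 7.6), c(7.3, 7.8)), 1)
  expect_equal(fraction_in_range(c(6, 9), c(7.3, 7.8)), 0)
  set.seed(9)
  ph <- rnorm(20000, 7.5, 0.1)
  expected <- pnorm(2) - pnorm(-2)   # +/- 2 sd
  expect_equal(fraction_in_range(ph, c(7.3, 7.7)), expected,
               tolerance = 0.01)
  expect_error(fraction_in_range(c(NA_real_, NA_real_)), "missing")
})

test_that("rank-sum p for {1,2,3} vs {4,5,6} matches exhaustive enumeration", {
  # oracle: all C(6,3) = 20 assignments of ranks to group A under the null
  ranks <- combn(6, 3)
  u_stats <- apply(ranks, 2, function(r) sum(r) - 3 * 4 / 2)
  observed_u <- 0   # A = {1,2,3} holds the three smallest ranks
  p_oracle <- mean(pmin(u_stats, 9 - u_stats) <= min(observed_u, 9 - observed_u)) # nolint
  res <- compare_class_ph(c(1, 2, 3), c(4, 5, 6))
  expect_equal(res$p.value, 0.1)
  expect_equal(p_oracle, 0.1)
  expect_equal(res$statistic, 0)
})

test_that("rank-sum degenerate and power behaviors", {
  expect_equal(compare_class_ph(c(2, 2, 2), c(2, 2, 2))$p.value, 1)
  set.seed(9)
  a <- rnorm(200, 0, 1)
  b <- rnorm(200, 1, 1)
  expect_lt(compare_class_ph(a, b)$p.value, 1e-6)
  expect_error(compare_class_ph(c(1, 2), c(3, 4, 5)), "n >= 3")
})

test_that("high-expression class shows the higher pH when recovery gates expression", {
  ev <- simulate_recovery(timepoints = c(120), n_events = 5000,
                          p_recovered = 0.6, p_high_given_recovered = 0.8,
                          red_sep_sd = 8, spike_frac = 0, bv421_bright_frac = 0,
                          seed = 10)
  fit <- fit_two_component(ev$ch_red, domain = "log")
  lab <- classify_mixture(fit, ev$ch_red, 0.90)
  ok <- lab != "ambiguous"
  expect_gte(mean(lab[ok] == ev$true_expr[ok]), 0.99)
  res <- compare_class_ph(ev$true_ph[lab == "high"], ev$true_ph[lab == "low"])
  expect_lt(res$p.value, 0.01)
  expect_gt(median(ev$true_ph[lab == "high"]),
            median(ev$true_ph[lab == "low"]))
})
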