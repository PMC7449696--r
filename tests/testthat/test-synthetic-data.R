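# Generators must be deterministic under a fixed seed and agree with their
# generating formulas exactly when noise is disabled.

test_that("all four generators are byte-deterministic under a fixed seed", {
  regs <- make_test_regulons(n_null = 2)
  twice <- function(f) list(f(), f())
  pairs <- list(
    twice(function() simulate_calibration(n_events = 200, seed = 11)),
    twice(function() simulate_recovery(timepoints = c(0, 60, 120),
                                       n_events = 300, seed = 11)),
    twice(function() simulate_competition(-0.004, 0, depth = 500, seed = 11)),
    twice(function() simulate_expression(regs[1:2],
                                         acid_effects = c("Hsf1" = 4, "Msn2/4" = 1),
                                         n_genes = 500, seed = 11))
  )
  for (p in pairs) expect_identical(p[[1]], p[[2]])
})

test_that("generators do not disturb the caller's RNG stream", {
  set.seed(99)
  before <- .Random.seed
  invisible(simulate_competition(-0.004, 0, depth = 100, seed = 3))
  expect_identical(.Random.seed, before)
})

test_that("noise-free calibration events reproduce the sigmoid exactly", {
  truth <- c(a = 2, b = 1.5, c = 7, d = 0.3)
  bg <- c(ch405 = 20, ch488 = 50)
  tabs <- simulate_calibration(n_events = 50, calib = truth, background = bg,
                               cv = 0, seed = 1)
  for (tab in tabs) {
    corrected <- subtract_background(tab, bg)
    expected <- ratio_sigmoid(tab$buffer_ph[1], truth["a"], truth["b"],
                              truth["c"], truth["d"])
    expect_equal(median(corrected$ratio405_488), unname(expected),
                 tolerance = 1e-12)
  }
})

test_that("noisy calibration medians stay within 1% of the sigmoid", {
  truth <- c(a = 2, b = 1.5, c = 7, d = 0.3)
  tabs <- simulate_calibration(n_events = 5000, calib = truth, cv = 0.05,
                               seed = 1)
  pts <- calibration_points(lapply(tabs, subtract_background,
                                   background = c(ch405 = 0, ch488 = 0)))
  expected <- ratio_sigmoid(pts$buffer_ph, truth["a"], truth["b"],
                            truth["c"], truth["d"])
  expect_true(all(abs(pts$ratio / expected - 1) < 0.01))
})

test_that("calibration input validation catches bad grids", {
  expect_error(simulate_calibration(buffer_ph = numeric(0)), "empty")
  expect_error(simulate_calibration(buffer_ph = c(5, 4.5)), "increasing")
  expect_error(simulate_calibration(buffer_ph = c(3, 5, 7)), "4, 9")
  # single event per buffer is valid but under-determines the downstream fit
  tabs <- simulate_calibration(n_events = 1, buffer_ph = c(5, 6, 7), seed = 1)
  expect_true(all(vapply(tabs, nrow, integer(1)) == 1L))
})

test_that("recovery generator ties expression class to pH recovery", {
  ev <- simulate_recovery(timepoints = c(0, 120, 240), n_events = 2000,
                          seed = 4)
  expect_true(all(ev$true_recovered[ev$true_expr == "high"]))
  expect_true(all(is.na(ev$true_ph[ev$true_strain == "spike"])))
})

test_that("degenerate recovery config yields single-mode channels", {
  ev <- simulate_recovery(timepoints = c(0, 60), n_events = 2000,
                          p_recovered = 0, p_high_given_recovered = 0,
                          p_budded = 0, spike_frac = 0, bv421_bright_frac = 0,
                          seed = 5)
  expect_true(all(ev$true_expr == "low"))
  expect_true(all(ev$true_budded == "unbudded"))
  # red channel is a single lognormal: log-sd near the configured CV
  expect_lt(sd(log(ev$ch_red)), 0.3)
  expect_equal(sd(ev$fsc_width), 4, tolerance = 0.1)
})

test_that("spike fraction 0.5 gives a near 1:1 labeled:spike event ratio", {
  ev <- simulate_recovery(timepoints = c(0, 60), n_events = 10000,
                          spike_frac = 0.5, seed = 6)
  frac <- mean(ev$true_strain == "spike")
  expect_equal(frac, 0.5, tolerance = 3 * sqrt(0.25 / nrow(ev)) / 0.5)
})

test_that("recovery rejects malformed class proportions", {
  expect_error(simulate_recovery(p_recovered = 1.2), "probabilities")
  expect_error(simulate_recovery(spike_frac = 0.7, bv421_bright_frac = 0.5),
               "sum")
  expect_error(simulate_recovery(timepoints = c(60, 0)), "increasing")
})

test_that("noiseless competition series is exactly log-linear", {
  gs <- simulate_competition(-0.004, 0, timepoints = seq(0, 200, 40),
                             depth = Inf)
  lr <- log_ratio_series(gs)
  expect_equal(lr$log_ratio, -0.004 * lr$time, tolerance = 1e-12)
  # equal rates: flat
  gs0 <- simulate_competition(0.01, 0.01, timepoints = seq(0, 200, 40),
                              depth = Inf)
  expect_equal(log_ratio_series(gs0)$log_ratio, rep(0, 6), tolerance = 1e-12)
  expect_error(simulate_competition(-0.004, 0, depth = -5), "depth")
  expect_error(simulate_competition(-0.004, 0, timepoints = 0), "2 timepoints")
})

test_that("sampled competition slope is within the stated sampling bound", {
  gs <- simulate_competition(-0.004, 0, timepoints = seq(0, 200, 40),
                             depth = 10000, seed = 7)
  est <- fit_growth_difference(log_ratio_series(gs))
  expect_lt(abs(est$slope - (-0.004)), 5e-4)
})

test_that("expression simulation: exact folds without noise, tpm closure with", {
  regs <- list(Hsf1 = paste0("gene", 1:40))
  sim <- simulate_expression(regs, acid_effects = c(Hsf1 = 4),
                             n_genes = 500, cv = 0, renormalize = FALSE,
                             seed = 2)
  mat <- combine_replicates(sim$tpm, sim$samples)
  acid <- acidification_fold_change(mat, "shock_allowed", "shock_prevented",
                                    pseudo = 0)
  expect_equal(unname(acid[paste0("gene", 1:40)]), rep(4, 40),
               tolerance = 1e-12)
  expect_equal(unname(acid[paste0("gene", 41:500)]), rep(1, 460),
               tolerance = 1e-12)
  # with renormalization every column is tpm
  sim2 <- simulate_expression(regs, acid_effects = c(Hsf1 = 4),
                              n_genes = 500, cv = 0.2, seed = 2)
  expect_equal(unname(colSums(sim2$tpm)), rep(1e6, ncol(sim2$tpm)),
               tolerance = 1e-6 / 1e6)
  expect_error(simulate_expression(regs, acid_effects = c(Hsf1 = 4),
                                   n_genes = 0), "empty")
  expect_error(simulate_expression(list(A = "gene1", B = "gene1"),
                                   acid_effects = c(A = 2, B = 2),
                                   n_genes = 10), "disjoint")
})

test_that("with all effects at 1 the conditions are exchangeable up to noise", {
  sim <- simulate_expression(list(), acid_effects = numeric(0),
                             n_genes = 800, cv = 0.1, seed = 3)
  mat <- combine_replicates(sim$tpm, sim$samples)
  acid <- acidification_fold_change(mat, "shock_allowed", "shock_prevented",
                                    pseudo = 0)
  expect_equal(median(acid), 1, tolerance = 0.02)
  hs <- induction_fold_change(mat, "shock_allowed", "mock_allowed", pseudo = 0)
  expect_equal(median(hs), 1, tolerance = 0.02)
})
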