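# Shared fixtures and independent oracles, all built in code at test time.

# exact calibration points on the four-parameter logistic
make_calib_points <- function(a = 2, b = 1.5, c = 7, d = 0.3,
                              ph = seq(4.5, 8.5, by = 0.5),
                              noise_sd = 0, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  ratio <- ratio_sigmoid(ph, a, b, c, d)
  if (noise_sd > 0) ratio <- ratio + rnorm(length(ph), 0, noise_sd)
  data.frame(buffer_ph = ph, ratio = ratio)
}

# independent oracle: dense two-stage 4-D grid search minimizing the
# calibration RSS (coarse pass, then refinement around the coarse optimum)
grid_search_calib_rss <- function(points, n_coarse = 13, n_fine = 13,
                                  n_rounds = 4) {
  ph <- points$buffer_ph
  ratio <- points$ratio
  rss_of <- function(a, b, c, d) {
    sum((ratio - ratio_sigmoid(ph, a, b, c, d))^2)
  }
  span <- diff(range(ratio))
  ranges <- list(a = c(span * 0.5, span * 1.5),
                 b = c(0.3, 4),
                 c = range(ph),
                 d = c(min(ratio) - span / 2, min(ratio) + span / 2))
  best <- NULL
  for (round in seq_len(n_rounds)) {
    n <- if (round == 1) n_coarse else n_fine
    grids <- lapply(ranges, function(r) seq(r[1], r[2], length.out = n))
    g <- expand.grid(grids)
    rss <- mapply(rss_of, g$a, g$b, g$c, g$d)
    i <- which.min(rss)
    best <- list(par = unlist(g[i, ]), rss = rss[i])
    # shrink each range around the incumbent
    ranges <- lapply(names(ranges), function(nm) {
      w <- diff(ranges[[nm]]) / (n - 1)
      best$par[[nm]] + c(-2, 2) * w
    })
    names(ranges) <- c("a", "b", "c", "d")
  }
  best
}

# independent oracle for the induction fit: grid search on log-domain RSS
# with the d >= 1 constraint
grid_search_induction_rss <- function(time, fold, n = 13, n_rounds = 4) {
  ly <- log(fold)
  rss_of <- function(a, b, c, d) {
    sum((ly - log(ratio_sigmoid(time, a, b, c, d)))^2)
  }
  span <- max(fold) - min(fold)
  ranges <- list(a = c(span * 0.5, span * 1.5),
                 b = c(0.01, 0.3),
                 c = range(time),
                 d = c(1, max(1, min(fold)) + 1))
  best <- NULL
  for (round in seq_len(n_rounds)) {
    grids <- lapply(ranges, function(r) seq(r[1], r[2], length.out = n))
    g <- expand.grid(grids)
    rss <- mapply(rss_of, g$a, g$b, g$c, g$d)
    i <- which.min(rss)
    best <- list(par = unlist(g[i, ]), rss = rss[i])
    ranges <- lapply(names(ranges), function(nm) {
      w <- diff(ranges[[nm]]) / (n - 1)
      lo <- best$par[[nm]] - 2 * w
      hi <- best$par[[nm]] + 2 * w
      if (nm == "d") lo <- max(lo, 1)   # keep the constraint
      if (nm %in% c("a", "b")) lo <- max(lo, 1e-6)
      c(lo, hi)
    })
    names(ranges) <- c("a", "b", "c", "d")
  }
  best
}

# a small disjoint regulon universe for expression simulations:
# one Hsf1-style set, one Msn2/4-style set, and `n_null` null sets
make_test_regulons <- function(n_hsf1 = 40, n_msn = 40, n_null = 20,
                               null_size = 15) {
  stopifnot(n_hsf1 + n_msn + n_null * null_size <= 2000)
  idx <- 1
  take <- function(k) {
    out <- paste0("gene", seq(idx, idx + k - 1))
    idx <<- idx + k
    out
  }
  sets <- c(list(take(n_hsf1), take(n_msn)),
            replicate(n_null, take(null_size), simplify = FALSE))
  names(sets) <- c("Hsf1", "Msn2/4", paste0("TF", seq_len(n_null)))
  sets
}

# gated + filtered labeled cells from a recovery simulation
prepare_labeled <- function(events, background = c(ch405 = 0, ch488 = 0)) {
  events <- subtract_background(events, background)
  ref <- events[events$timepoint == min(events$timepoint), , drop = FALSE]
  events <- gate_scatter(events, ref)
  events <- exclude_bv421(events, default_bv421_threshold(ref))
  cells <- events[events$gate == "cell" & events$bv421 == "ok", , drop = FALSE]
  cells <- split_strains(cells)
  cells[cells$strain == "labeled", , drop = FALSE]
}
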