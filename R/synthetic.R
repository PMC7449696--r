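# Synthetic generators for every pipeline input type, each with known
# ground truth. Noise is multiplicative lognormal per channel (flow data are
# positive and right-skewed); a coefficient of variation of 0 switches noise
# off exactly, so closed-form checks hold to machine precision.

# Run code under a seed, restoring the caller's RNG state afterwards.
local_seed <- function(seed, code) {
  has_old <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has_old) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (has_old) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  force(code)
}

# sdlog of a lognormal with unit median and the given coefficient of variation
cv_to_sdlog <- function(cv) {
  stopifnot(all(cv >= 0))
  sqrt(log(1 + cv^2))
}

# multiplicative noise factor with median exactly 1 (zero CV => exactly 1)
lognoise <- function(n, cv) {
  if (cv == 0) return(rep(1, n))
  exp(rnorm(n, mean = 0, sd = cv_to_sdlog(cv)))
}

#' Simulate pHluorin calibration-buffer event sets
#'
#' One event table per buffer pH. Cells are equilibrated in buffer so their
#' intracellular pH equals the buffer pH; the noise-free median 405:488
#' ratio at buffer pH x equals the calibration sigmoid evaluated at x, plus
#' the configured channel backgrounds.
#'
#' @param buffer_ph strictly increasing pH grid, within \[4, 9\]. Default
#'   0.5-unit steps from pH 4.5 to 8.5.
#' @param n_events events per buffer.
#' @param calib named vector `c(a=, b=, c=, d=)` of true sigmoid parameters.
#' @param background named vector `c(ch405=, ch488=)` of additive channel
#'   autofluorescence.
#' @param cv per-channel lognormal coefficient of variation (0 = noise off).
#' @param base488 median 488-channel intensity of labeled cells.
#' @param seed integer seed; identical `(arguments, seed)` give identical
#'   output.
#' @return list of event tables (data frames), one per buffer, each with
#'   channel columns and a `buffer_ph` metadata column; the generating
#'   parameters are attached as `attr(, "truth")`.
#' @export
simulate_calibration <- function(buffer_ph = seq(4.5, 8.5, by = 0.5),
                                 n_events = 10000,
                                 calib = c(a = 2, b = 1.5, c = 7, d = 0.3),
                                 background = c(ch405 = 0, ch488 = 0),
                                 cv = 0.05, base488 = 2000, seed = 1) {
  if (length(buffer_ph) == 0) stop("empty buffer pH grid")
  if (any(diff(buffer_ph) <= 0)) stop("buffer pH grid must be strictly increasing")
  if (any(buffer_ph < 4 | buffer_ph > 9)) stop("buffer grid must lie within [4, 9]")
  stopifnot(n_events >= 1, cv >= 0)
  local_seed(seed, {
    tabs <- lapply(buffer_ph, function(x) {
      r_true <- ratio_sigmoid(x, calib[["a"]], calib[["b"]], calib[["c"]],
                              calib[["d"]])
      ch488 <- base488 * lognoise(n_events, cv)
      ch405 <- r_true * ch488 * lognoise(n_events, cv)
      data.frame(
        sample_id = sprintf("calib_pH%.1f", x),
        buffer_ph = x,
        fsc_area = 5e4 * lognoise(n_events, cv),
        fsc_width = rnorm(n_events, 60, 5),
        ssc = 3e4 * lognoise(n_events, cv),
        ch405 = ch405 + background[["ch405"]],
        ch488 = ch488 + background[["ch488"]],
        ch_red = 100 * lognoise(n_events, cv),
        ch_bv421 = 50 * lognoise(n_events, cv)
      )
    })
    names(tabs) <- sprintf("pH%.1f", buffer_ph)
    attr(tabs, "truth") <- list(calib = calib, background = background,
                                cv = cv, seed = seed)
    tabs
  })
}

#' Simulate a stress-recovery flow-cytometry time course
#'
#' Emulates recovery after a 42 C heat shock: per cell, intracellular pH is
#' drawn from a class-dependent distribution (pH-recovered vs not), red
#' (Ssa4-mCherry) fluorescence from a two-component lognormal tied to the
#' expression class (high expressors occur only among pH-recovered cells),
#' and forward-scatter pulse width from a two-component Gaussian tied to
#' budding state. A configurable fraction of events are BV421-bright
#' artifacts and a fraction are unlabeled spike-in reference cells. All
#' ground-truth labels are retained as `true_*` columns.
#'
#' @param timepoints sorted recovery times in minutes.
#' @param n_events events per timepoint (default 10000, matching typical
#'   acquisition depth).
#' @param calib true calibration parameters used to map pH to the 405:488
#'   ratio.
#' @param fold_profile function of time giving the population induction fold
#'   change of high-expressing cells (default: sigmoid with amplitude 9,
#'   rate 0.05/min, midpoint 120 min, baseline 1).
#' @param p_recovered,p_high_given_recovered,p_budded probabilities per
#'   timepoint: each a function of time (minutes) or a vector matching
#'   `timepoints`. High expression occurs only among pH-recovered cells.
#' @param spike_frac fraction of events that are unlabeled spike-in cells.
#' @param bv421_bright_frac fraction of BV421-bright artifact events.
#' @param ph_recovered,ph_unrecovered `c(mean, sd)` of intracellular pH for
#'   the recovered and non-recovered classes.
#' @param red_base median red fluorescence of low expressors;
#'   `red_sep_sd`, if non-`NULL`, overrides `fold_profile` and places the
#'   high component exactly that many log-domain standard deviations above
#'   the low one.
#' @param cv lognormal CV for intensity channels; `red_cv` for the red
#'   channel (sets the mixture's log-sd); `ratio_cv` for the 405:488
#'   excitation ratio, which is far less noisy than the absolute channels
#'   because the ratio cancels per-cell expression level.
#' @param fscw_unbudded,fscw_budded `c(mean, sd)` of FSC pulse width per
#'   budding class.
#' @param base488 median 488 intensity of labeled cells; spike-in cells sit
#'   at autofluorescence (`spike488`).
#' @param bv421_threshold_factor bright events are this many times the
#'   baseline BV421 median.
#' @param seed integer seed.
#' @return a single time-indexed event table (data frame) with channel,
#'   metadata and `true_*` truth columns; generator parameters in
#'   `attr(, "truth")`.
#' @export
simulate_recovery <- function(timepoints = seq(0, 240, by = 30),
                              n_events = 10000,
                              calib = c(a = 2, b = 1.5, c = 7, d = 0.3),
                              fold_profile = function(t)
                                ratio_sigmoid(t, 9, 0.05, 120, 1),
                              p_recovered = function(t) stats::plogis((t - 45) / 20),
                              p_high_given_recovered = function(t)
                                stats::plogis((t - 90) / 25),
                              p_budded = function(t)
                                0.12 + 0.45 * exp(-((t - 120) / 45)^2),
                              spike_frac = 0.1,
                              bv421_bright_frac = 0.05,
                              ph_recovered = c(7.45, 0.08),
                              ph_unrecovered = c(6.8, 0.12),
                              red_base = 150, red_sep_sd = NULL,
                              cv = 0.25, red_cv = 0.25, ratio_cv = 0.05,
                              fscw_unbudded = c(60, 4), fscw_budded = c(85, 4),
                              base488 = 2000, spike488 = 25,
                              bv421_threshold_factor = 20,
                              seed = 1) {
  if (is.unsorted(timepoints, strictly = TRUE)) {
    stop("timepoints must be strictly increasing")
  }
  as_prob_fun <- function(p, what) {
    if (is.function(p)) {
      v <- p(timepoints)
    } else {
      if (length(p) == 1) p <- rep(p, length(timepoints))
      v <- p
    }
    if (length(v) != length(timepoints) || any(v < 0 | v > 1)) {
      stop(what, " must give probabilities in [0, 1], one per timepoint")
    }
    v
  }
  pr <- as_prob_fun(p_recovered, "p_recovered")
  phigh <- as_prob_fun(p_high_given_recovered, "p_high_given_recovered")
  pbud <- as_prob_fun(p_budded, "p_budded")
  if (spike_frac < 0 || bv421_bright_frac < 0 ||
      spike_frac + bv421_bright_frac > 1) {
    stop("spike and BV421-bright fractions must be >= 0 and sum to <= 1")
  }
  sdlog_red <- cv_to_sdlog(red_cv)
  local_seed(seed, {
    tabs <- lapply(seq_along(timepoints), function(i) {
      t <- timepoints[i]
      n <- n_events
      spike <- runif(n) < spike_frac
      recovered <- !spike & (runif(n) < pr[i])
      high <- recovered & (runif(n) < phigh[i])
      budded <- runif(n) < pbud[i]
      bright <- runif(n) < bv421_bright_frac

      ph_true <- ifelse(recovered,
                        rnorm(n, ph_recovered[1], ph_recovered[2]),
                        rnorm(n, ph_unrecovered[1], ph_unrecovered[2]))
      ph_true[spike] <- NA_real_

      high_mult <- if (is.null(red_sep_sd)) {
        max(fold_profile(t), 1)
      } else {
        exp(red_sep_sd * sdlog_red)
      }
      expr_fold <- ifelse(high, high_mult, 1)
      ch_red <- red_base * expr_fold * lognoise(n, red_cv)
      ch_red[spike] <- 0.2 * red_base * lognoise(sum(spike), red_cv)

      ch488 <- base488 * lognoise(n, cv)
      ch488[spike] <- spike488 * lognoise(sum(spike), cv)
      ratio_true <- ratio_sigmoid(ph_true, calib[["a"]], calib[["b"]],
                                  calib[["c"]], calib[["d"]])
      ch405 <- ratio_true * ch488 * lognoise(n, ratio_cv)
      ch405[spike] <- spike488 * lognoise(sum(spike), cv)

      fscw <- ifelse(budded,
                     rnorm(n, fscw_budded[1], fscw_budded[2]),
                     rnorm(n, fscw_unbudded[1], fscw_unbudded[2]))
      bv421 <- 50 * lognoise(n, cv)
      bv421[bright] <- 50 * bv421_threshold_factor * lognoise(sum(bright), cv)

      data.frame(
        sample_id = sprintf("recovery_t%03d", t),
        timepoint = t,
        condition = "recovery",
        fsc_area = 5e4 * lognoise(n, cv),
        fsc_width = fscw,
        ssc = 3e4 * lognoise(n, cv),
        ch405 = ch405, ch488 = ch488, ch_red = ch_red, ch_bv421 = bv421,
        true_ph = ph_true,
        true_expr = ifelse(high, "high", "low"),
        true_budded = ifelse(budded, "budded", "unbudded"),
        true_strain = ifelse(spike, "spike", "labeled"),
        true_recovered = recovered,
        true_bv421_bright = bright,
        true_fold = expr_fold
      )
    })
    out <- do.call(rbind, tabs)
    rownames(out) <- NULL
    attr(out, "truth") <- list(
      calib = calib, timepoints = timepoints,
      p_recovered = pr, p_high_given_recovered = phigh, p_budded = pbud,
      spike_frac = spike_frac, bv421_bright_frac = bv421_bright_frac,
      red_base = red_base, red_sep_sd = red_sep_sd, red_cv = red_cv,
      cv = cv, seed = seed
    )
    out
  })
}

#' Simulate a competitive growth (spike-in) count series
#'
#' Labeled and reference populations grow exponentially at rates
#' `r_labeled` and `r_ref` (1/min); at each timepoint, `depth` events are
#' drawn and split binomially according to the current expected population
#' ratio. `depth = Inf` disables sampling noise and returns the expected
#' (real-valued) counts, for closed-form checks.
#'
#' @param r_labeled,r_ref instantaneous growth rates (1/min).
#' @param mix0 initial mixing fraction n_labeled(0) / n_spike(0).
#' @param timepoints sampling times in minutes (at least 2, the first taken
#'   as t = 0 reference).
#' @param depth events acquired per timepoint (>= 1, or `Inf`).
#' @param seed integer seed.
#' @return a `growth_series` data frame with columns `time`, `n_labeled`,
#'   `n_spike`; truth in `attr(, "truth")`.
#' @export
simulate_competition <- function(r_labeled, r_ref, mix0 = 1,
                                 timepoints = seq(0, 200, by = 40),
                                 depth = 10000, seed = 1) {
  if (length(timepoints) < 2) stop("need at least 2 timepoints")
  if (!(is.infinite(depth) || depth >= 1)) stop("depth must be >= 1 (or Inf)")
  stopifnot(is.finite(r_labeled), is.finite(r_ref), mix0 > 0)
  frac <- mix0 * exp(r_labeled * timepoints) /
    (mix0 * exp(r_labeled * timepoints) + exp(r_ref * timepoints))
  out <- local_seed(seed, {
    if (is.infinite(depth)) {
      n_lab <- 10000 * frac
      n_spk <- 10000 * (1 - frac)
    } else {
      n_lab <- rbinom(length(timepoints), size = depth, prob = frac)
      n_spk <- depth - n_lab
    }
    data.frame(time = timepoints, n_labeled = n_lab, n_spike = n_spk)
  })
  class(out) <- c("growth_series", "data.frame")
  attr(out, "truth") <- list(r_labeled = r_labeled, r_ref = r_ref,
                             delta_r = r_labeled - r_ref, mix0 = mix0,
                             depth = depth, seed = seed)
  out
}

#' Simulate a regulon-structured expression matrix (tpm)
#'
#' Generates gene-by-sample transcript abundances for a two-factor design:
#' temperature (heat shock vs mock) crossed with acidification (allowed vs
#' prevented), with replicates. Heat shock multiplies a gene's basal
#' abundance by its heat-shock fold; the acidification fold is applied only
#' to genes in designated regulons, and only in the shock-with-acidification
#' condition. Values are lognormal around their expected abundance and each
#' sample column is renormalized to transcripts per million (sum 1e6).
#'
#' @param regulons named list of gene-id character vectors (disjoint after
#'   any exclusions; checked).
#' @param acid_effects named numeric vector (same names as `regulons`):
#'   acidification fold change per regulon; genes outside any regulon get 1.
#' @param hs_effects heat-shock fold per regulon (default 8 for every
#'   regulon); background genes get 1.
#' @param n_genes total genes in the universe (regulon members included).
#' @param cv lognormal noise CV on abundances (0 = noise off).
#' @param n_reps replicates per condition.
#' @param basal_meanlog,basal_sdlog log-normal distribution of basal
#'   abundances across genes.
#' @param renormalize renormalize columns to sum 1e6 (tpm). Disable only for
#'   closed-form checks on raw abundances.
#' @param seed integer seed.
#' @return list with `tpm` (gene x sample matrix), `samples` (metadata data
#'   frame: `sample`, `temperature`, `acidification`, `replicate`), and
#'   `truth` (per-gene true folds and regulon membership).
#' @export
simulate_expression <- function(regulons,
                                acid_effects,
                                hs_effects = NULL,
                                n_genes = 2000, cv = 0.2, n_reps = 2,
                                basal_meanlog = log(50), basal_sdlog = 1,
                                renormalize = TRUE, seed = 1) {
  if (n_genes < 1) stop("empty gene universe")
  stopifnot(is.list(regulons), length(regulons) == 0 ||
              !is.null(names(regulons)))
  members <- unlist(regulons, use.names = FALSE)
  if (anyDuplicated(members)) {
    stop("regulons must be disjoint (apply exclusions first)")
  }
  if (length(regulons) > 0) {
    stopifnot(all(names(regulons) %in% names(acid_effects)))
    if (any(acid_effects <= 0)) stop("acidification effects must be > 0")
  }
  if (is.null(hs_effects)) {
    hs_effects <- setNames(rep(8, length(regulons)), names(regulons))
  }
  genes <- paste0("gene", seq_len(n_genes))
  if (length(members) > n_genes) stop("more regulon members than genes")
  # regulon member ids must exist in the universe
  if (length(members) > 0 && !all(members %in% genes)) {
    stop("regulon gene ids must be within gene1..gene<n_genes>")
  }
  gene_regulon <- setNames(rep(NA_character_, n_genes), genes)
  for (rg in names(regulons)) gene_regulon[regulons[[rg]]] <- rg

  acid_fold <- ifelse(is.na(gene_regulon), 1,
                      acid_effects[gene_regulon])
  hs_fold <- ifelse(is.na(gene_regulon), 1, hs_effects[gene_regulon])

  conditions <- expand.grid(temperature = c("mock", "shock"),
                            acidification = c("prevented", "allowed"),
                            replicate = seq_len(n_reps),
                            stringsAsFactors = FALSE)
  local_seed(seed, {
    basal <- exp(rnorm(n_genes, basal_meanlog, basal_sdlog))
    cols <- lapply(seq_len(nrow(conditions)), function(j) {
      shock <- conditions$temperature[j] == "shock"
      acid <- conditions$acidification[j] == "allowed"
      mu <- basal *
        (if (shock) hs_fold else 1) *
        (if (shock && acid) acid_fold else 1)
      mu * lognoise(n_genes, cv)
    })
    tpm <- do.call(cbind, cols)
    rownames(tpm) <- genes
    colnames(tpm) <- sprintf("%s_%s_rep%d", conditions$temperature,
                             conditions$acidification, conditions$replicate)
    if (renormalize) {
      tpm <- sweep(tpm, 2, colSums(tpm), "/") * 1e6
    }
    samples <- data.frame(sample = colnames(tpm),
                          temperature = conditions$temperature,
                          acidification = conditions$acidification,
                          replicate = conditions$replicate)
    truth <- list(gene_regulon = gene_regulon, acid_fold = acid_fold,
                  hs_fold = hs_fold, basal = basal, cv = cv, seed = seed)
    list(tpm = tpm, samples = samples, truth = truth)
  })
}
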