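# Deterministic re-implementation of the study's event-selection logic:
# scatter gating on unstressed reference cells, computational exclusion of
# BV421-bright artifact events, and splitting labeled cells from unlabeled
# spike-in reference cells on the 488 (FITC) channel.

#' Scatter gate for intact cells
#'
#' Replaces a manual forward/side-scatter polygon with a deterministic
#' quantile gate: events are kept when both FSC-A and SSC fall inside the
#' central region of the unstressed reference distribution. Per axis, the
#' central `1 - (1 - coverage)/2` span is used, so at most `1 - coverage` of
#' reference events fall outside the joint gate.
#'
#' @param events event table to gate.
#' @param reference event table of unstressed cells used to place the gate.
#' @param coverage target joint coverage of the reference (default 0.98).
#' @return `events` with a `gate` column (`"cell"` / `"debris"`); kept and
#'   dropped counts in `attr(, "gate_counts")`.
#' @export
gate_scatter <- function(events, reference, coverage = 0.98) {
  stopifnot(is.data.frame(events))
  if (is.null(reference) || nrow(reference) == 0) {
    stop("empty reference: unstressed cells are required to place the scatter gate")
  }
  stopifnot(coverage > 0, coverage < 1)
  tail_per_axis <- (1 - coverage) / 4   # two axes, two tails each
  lims <- lapply(c("fsc_area", "ssc"), function(ch) {
    quantile(reference[[ch]], c(tail_per_axis, 1 - tail_per_axis),
             names = FALSE, na.rm = TRUE)
  })
  inside <- events$fsc_area >= lims[[1]][1] & events$fsc_area <= lims[[1]][2] &
    events$ssc >= lims[[2]][1] & events$ssc <= lims[[2]][2]
  events$gate <- ifelse(inside, "cell", "debris")
  attr(events, "gate_counts") <- c(cell = sum(inside), debris = sum(!inside))
  attr(events, "gate_limits") <- list(fsc_area = lims[[1]], ssc = lims[[2]])
  events
}

#' Default BV421 artifact threshold from an unstressed control
#'
#' The study excluded a handling-dependent BV421-bright subpopulation by
#' threshold gating but did not record the threshold; by default it is
#' placed at the 99.9th percentile of the unstressed control's BV421 signal.
#'
#' @param reference event table of unstressed control cells.
#' @param p percentile (default 0.999).
#' @return threshold in channel units.
#' @export
default_bv421_threshold <- function(reference, p = 0.999) {
  quantile(reference$ch_bv421, p, names = FALSE, na.rm = TRUE)
}

#' Exclude BV421-bright artifact events
#'
#' Events above the threshold are labeled `"bright"` and must be dropped
#' from downstream statistics; the bright fraction is reported (the study
#' observed 5-50% depending on handling).
#'
#' @param events event table (gated or not).
#' @param threshold BV421 channel threshold, must be > 0.
#' @return `events` with a `bv421` column (`"ok"` / `"bright"`); the bright
#'   fraction in `attr(, "bv421_bright_fraction")`.
#' @export
exclude_bv421 <- function(events, threshold) {
  if (!is.numeric(threshold) || length(threshold) != 1 || threshold <= 0) {
    stop("BV421 threshold must be a single positive number")
  }
  bright <- events$ch_bv421 > threshold
  events$bv421 <- ifelse(bright, "bright", "ok")
  attr(events, "bv421_bright_fraction") <- mean(bright)
  events
}

#' Split labeled cells from unlabeled spike-in reference cells
#'
#' Spike-in wild-type cells carry no pHluorin and are dim in the 488 (FITC)
#' channel; labeled cells are bright. The partition is a threshold on
#' `ch488`, with an optional symmetric ambiguity margin in log units around
#' it. When no threshold is given, one is derived deterministically as the
#' midpoint (in log space) between the two component means of a
#' two-component Gaussian mixture fitted to `log(ch488)`; if the two modes
#' are poorly separated a warning is raised and the partition is still
#' produced.
#'
#' @param events event table (should be scatter-gated and BV421-filtered).
#' @param threshold 488-channel threshold; `NULL` to derive from the data.
#' @param margin half-width of the ambiguous band in log-488 units
#'   (default 0: hard split).
#' @return `events` with a `strain` column
#'   (`"labeled"` / `"spike"` / `"ambiguous"`); counts per side in
#'   `attr(, "strain_counts")`, threshold used in `attr(, "fitc_threshold")`.
#' @export
split_strains <- function(events, threshold = NULL, margin = 0) {
  stopifnot(is.data.frame(events), margin >= 0)
  x <- events$ch488
  pos <- x[is.finite(x) & x > 0]
  if (is.null(threshold)) {
    if (length(pos) < 50) stop("too few events to derive a 488 threshold")
    fit <- fit_two_component(pos, domain = "log")
    if (fit$poorly_separated) {
      warning("ch488 appears unimodal; strain split may be unreliable")
    }
    threshold <- exp(mean(c(fit$means[1], fit$means[2])))
  }
  lx <- log(pmax(x, .Machine$double.xmin))
  lthr <- log(threshold)
  strain <- ifelse(lx > lthr + margin, "labeled",
                   ifelse(lx < lthr - margin, "spike", "ambiguous"))
  events$strain <- strain
  attr(events, "strain_counts") <- c(labeled = sum(strain == "labeled"),
                                     spike = sum(strain == "spike"),
                                     ambiguous = sum(strain == "ambiguous"))
  attr(events, "fitc_threshold") <- threshold
  events
}
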