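# End-to-end orchestration: simulate (or load) -> calibrate -> gate ->
# per-cell pH -> induction kinetics -> subpopulations (recovery pipeline),
# and simulate/load -> fold changes -> regulon scores (regulon pipeline).
# Runs are reproducible: the seed and a hash of the configuration are
# recorded in a manifest, outputs are written deterministically (no
# timestamps), and re-running an unchanged config overwrites outputs
# byte-identically.

# md5 of the deparsed configuration, for the manifest; the output directory
# is not part of the analysis identity, so identical analyses written to
# different places produce identical manifests
config_hash <- function(config) {
  tmp <- tempfile()
  on.exit(unlink(tmp))
  writeLines(deparse(config[setdiff(names(config), "out_dir")]), tmp)
  unname(tools::md5sum(tmp))
}

write_manifest <- function(path, stage, config, extra = list()) {
  lines <- c(
    sprintf("pipeline\t%s", stage),
    sprintf("package_version\t%s",
            as.character(utils::packageVersion("phshock"))),
    sprintf("seed\t%d", config$seed),
    sprintf("config_md5\t%s", config_hash(config))
  )
  for (nm in names(extra)) {
    lines <- c(lines, sprintf("%s\t%s", nm, format(extra[[nm]])))
  }
  writeLines(lines, path)
  invisible(path)
}

stage_error <- function(stage, sample_id, e) {
  stop(sprintf("[stage %s | sample %s] %s", stage, sample_id,
               conditionMessage(e)), call. = FALSE)
}

.require_field <- function(config, field) {
  if (is.null(config[[field]])) {
    stop("config validation: missing required field '", field, "'",
         call. = FALSE)
  }
  config[[field]]
}

#' Run the stress-recovery analysis pipeline
#'
#' Composes the single-cell analyses end to end: per-experiment pHluorin
#' calibration, background subtraction, scatter gating against the
#' unstressed (t = 0) reference, BV421 artifact exclusion, strain
#' splitting, per-cell pH conversion, induction fold-change curve and
#' sigmoid fit, two-component classification of expression and budding
#' state, resting-pH-range fractions and the budded-fraction time course.
#'
#' @param config a list with fields:
#'   \describe{
#'     \item{seed}{integer; drives every stochastic step (required).}
#'     \item{out_dir}{output directory (required; created).}
#'     \item{calibration}{either a list of per-buffer event tables, or a
#'       list of arguments for [simulate_calibration()]; alternatively
#'       supply `calibration_fit` (a `calibration_fit` object or a file
#'       written by [write_calibration()]). One of the two is required.}
#'     \item{recovery}{either a time-indexed event table or a list of
#'       arguments for [simulate_recovery()] (required).}
#'     \item{background}{`c(ch405=, ch488=)` autofluorescence medians
#'       (default `c(0, 0)`).}
#'     \item{bv421_threshold}{numeric, or `NULL` to derive from the t = 0
#'       sample's 99.9th percentile.}
#'     \item{cutoff}{posterior cutoff for class assignment (default 0.90).}
#'     \item{resting_range}{`c(lower, upper)` resting pH range (default
#'       `c(7.3, 7.8)`, an assumption recorded in the outputs).}
#'     \item{summary_window}{minutes, for the budded-fraction summary
#'       (default `c(90, 120)`).}
#'   }
#' @return (invisibly) a result bundle: list with `calibration`, `events`
#'   (labeled cells with pH and class labels), `induction_curve`,
#'   `induction_fit`, `induction_delay`, `range_fractions`,
#'   `budded_fractions`, `exclusions`, `out_dir`.
#' @export
run_recovery_pipeline <- function(config) {
  seed <- .require_field(config, "seed")
  out_dir <- .require_field(config, "out_dir")
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  background <- config$background %||% c(ch405 = 0, ch488 = 0)
  cutoff <- config$cutoff %||% 0.90
  resting_range <- config$resting_range %||% c(7.3, 7.8)
  summary_window <- config$summary_window %||% c(90, 120)

  # --- calibration -------------------------------------------------------
  fit <- NULL
  if (!is.null(config$calibration_fit)) {
    fit <- config$calibration_fit
    if (is.character(fit)) fit <- read_calibration(fit)
  } else if (!is.null(config$calibration)) {
    cal <- config$calibration
    tabs <- if (is.data.frame(cal[[1]])) cal
            else do.call(simulate_calibration,
                         c(cal, list(seed = seed + 1000L)))
    tabs <- lapply(tabs, subtract_background, background = background)
    fit <- tryCatch(fit_calibration(calibration_points(tabs),
                                    background = background),
                    error = function(e) stage_error("calibrate", "buffers", e))
  } else {
    stop("config validation: missing required field 'calibration' ",
         "(or 'calibration_fit')", call. = FALSE)
  }

  # --- events ------------------------------------------------------------
  rec <- .require_field(config, "recovery")
  events <- if (is.data.frame(rec)) rec
            else do.call(simulate_recovery, c(rec, list(seed = seed)))

  events <- subtract_background(events, background)
  n_bg_excluded <- attr(events, "n_excluded_background")
  reference <- events[events$timepoint == min(events$timepoint), , drop = FALSE]
  events <- tryCatch(gate_scatter(events, reference),
                     error = function(e) stage_error("gate_scatter", "all", e))
  thr <- config$bv421_threshold %||% default_bv421_threshold(reference)
  events <- exclude_bv421(events, thr)
  bv421_frac <- attr(events, "bv421_bright_fraction")
  cells <- events[events$gate == "cell" & events$bv421 == "ok", , drop = FALSE]
  cells <- tryCatch(split_strains(cells, threshold = config$fitc_threshold),
                    error = function(e) stage_error("split_strains", "all", e))
  labeled <- cells[cells$strain == "labeled", , drop = FALSE]

  # --- per-cell pH and induction curve -----------------------------------
  labeled <- add_ph(labeled, fit)
  baseline <- labeled[labeled$timepoint == min(labeled$timepoint), , drop = FALSE]
  curve <- tryCatch(
    fold_change_curve(labeled, baseline, min_cells = config$min_cells %||% 1000),
    error = function(e) stage_error("fold_change_curve", "labeled", e))
  ind_fit <- if (nrow(curve) >= 5) fit_induction(curve) else NULL
  delay <- if (!is.null(ind_fit)) induction_delay(ind_fit) else NA_real_

  # --- subpopulations ----------------------------------------------------
  timepoints <- sort(unique(labeled$timepoint))
  labeled$expr_class <- NA_character_
  labeled$bud_class <- NA_character_
  for (t in timepoints) {
    idx <- which(labeled$timepoint == t)
    if (length(idx) >= 50) {
      red <- labeled$ch_red[idx] / labeled$fsc_area[idx]
      mf <- fit_two_component(red, domain = "log")
      labeled$expr_class[idx] <-
        classify_mixture(mf, red, cutoff, c("low", "high"))
      bf <- fit_two_component(labeled$fsc_width[idx], domain = "linear")
      labeled$bud_class[idx] <-
        classify_mixture(bf, labeled$fsc_width[idx], cutoff,
                         c("unbudded", "budded"))
    }
  }
  budded <- budded_fraction(labeled$timepoint, labeled$bud_class,
                            window = summary_window)
  range_frac <- do.call(rbind, lapply(timepoints, function(t) {
    ph <- labeled$ph[labeled$timepoint == t]
    data.frame(time = t,
               fraction_in_resting_range =
                 if (all(is.na(ph))) NA_real_
                 else fraction_in_range(ph, resting_range),
               n_ph = sum(!is.na(ph)))
  }))

  # --- outputs -----------------------------------------------------------
  write_calibration(fit, file.path(out_dir, "calibration.txt"))
  write_events(labeled, file.path(out_dir, "events_labeled.csv"))
  utils::write.table(format(curve, digits = 15),
                     file.path(out_dir, "induction_curve.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  utils::write.table(format(range_frac, digits = 15),
                     file.path(out_dir, "range_fractions.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  utils::write.table(format(as.data.frame(budded), digits = 15),
                     file.path(out_dir, "budded_fractions.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  exclusions <- c(
    background_nonpositive = n_bg_excluded,
    debris = sum(events$gate == "debris"),
    bv421_bright = sum(events$bv421 == "bright"),
    ambiguous_strain = sum(cells$strain == "ambiguous"),
    ph_out_of_range = attr(labeled, "n_ph_out_of_range") %||% 0L,
    ambiguous_expr = sum(labeled$expr_class == "ambiguous", na.rm = TRUE),
    ambiguous_bud = sum(labeled$bud_class == "ambiguous", na.rm = TRUE)
  )
  if (!is.null(ind_fit)) {
    utils::write.table(
      data.frame(parameter = c("a", "b", "c", "d", "rss"),
                 value = sprintf("%.17g", c(ind_fit$a, ind_fit$b, ind_fit$c,
                                            ind_fit$d, ind_fit$rss))),
      file.path(out_dir, "induction_fit.tsv"),
      sep = "\t", quote = FALSE, row.names = FALSE)
  }
  write_manifest(
    file.path(out_dir, "manifest.txt"), "recovery", config,
    extra = c(as.list(exclusions),
              list(resting_range = paste(resting_range, collapse = "-"),
                   resting_range_note = "assumed_not_measured",
                   bv421_threshold = sprintf("%.17g", thr),
                   induction_delay_min = sprintf("%.17g", delay)))
  )
  invisible(list(calibration = fit, events = labeled,
                 induction_curve = curve, induction_fit = ind_fit,
                 induction_delay = delay, range_fractions = range_frac,
                 budded_fractions = budded, exclusions = exclusions,
                 out_dir = out_dir))
}

#' Run the regulon pH-sensitivity pipeline
#'
#' Composes the transcriptomic analyses: replicate averaging, per-gene
#' heat-shock and acidification fold changes, regulon exclusion and size
#' rules, per-regulon summaries and rank tests against the background, with
#' Benjamini-Hochberg adjustment across regulons.
#'
#' @param config a list with fields:
#'   \describe{
#'     \item{seed}{integer (required).}
#'     \item{out_dir}{output directory (required).}
#'     \item{expression}{either a list `list(tpm=, samples=)` or a list of
#'       arguments for [simulate_expression()] (required).}
#'     \item{regulons}{named list of gene-id vectors, or a GMT file path
#'       (required).}
#'     \item{pseudo}{pseudocount in tpm (default 1).}
#'     \item{min_size}{minimum regulon size (default 4).}
#'     \item{core_regulons}{names excluded from all other regulons
#'       (default `c("Hsf1", "Msn2/4")`).}
#'   }
#' @return (invisibly) list with `scores` (a `regulon_scores` data frame),
#'   `hs_fc`, `acid_fc`, `out_dir`.
#' @export
run_regulon_pipeline <- function(config) {
  seed <- .require_field(config, "seed")
  out_dir <- .require_field(config, "out_dir")
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  regulons <- .require_field(config, "regulons")
  if (is.character(regulons)) regulons <- read_gmt(regulons)
  if (length(regulons) == 0) stop("empty gene-set input", call. = FALSE)
  pseudo <- config$pseudo %||% 1
  min_size <- config$min_size %||% 4
  core <- config$core_regulons %||% c("Hsf1", "Msn2/4")

  expr <- .require_field(config, "expression")
  if (!is.null(expr$tpm)) {
    tpm <- expr$tpm
    samples <- expr$samples
  } else {
    sim <- do.call(simulate_expression, c(expr, list(seed = seed)))
    tpm <- sim$tpm
    samples <- sim$samples
  }
  mat <- combine_replicates(tpm, samples)
  hs_fc <- tryCatch(
    induction_fold_change(mat, "shock_allowed", "mock_allowed", pseudo),
    error = function(e) stage_error("induction_fold_change", "conditions", e))
  acid_fc <- tryCatch(
    acidification_fold_change(mat, "shock_allowed", "shock_prevented", pseudo),
    error = function(e) stage_error("acidification_fold_change", "conditions", e))
  regs <- apply_regulon_exclusions(regulons, core = core, min_size = min_size)
  scores <- score_regulons(hs_fc, acid_fc, regs, min_size = min_size)
  utils::write.table(
    format(as.data.frame(scores), digits = 15),
    file.path(out_dir, "regulon_scores.tsv"),
    sep = "\t", quote = FALSE, row.names = FALSE)
  write_manifest(file.path(out_dir, "manifest.txt"), "regulon", config,
                 extra = list(n_regulons_scored = nrow(scores),
                              n_regulons_dropped =
                                length(attr(scores, "dropped")) +
                                length(attr(regs, "dropped"))))
  invisible(list(scores = scores, hs_fc = hs_fc, acid_fc = acid_fc,
                 out_dir = out_dir))
}

`%||%` <- function(a, b) if (is.null(a)) b else a
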