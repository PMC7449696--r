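# Regulon-level pH-sensitivity scoring from transcripts-per-million tables:
# replicate averaging, per-gene induction and acidification fold changes,
# regulon filtering/exclusion rules, summaries with ECDFs, and rank tests
# against the non-regulon background.

#' Average replicates into condition-level columns
#'
#' @param tpm gene x sample numeric matrix.
#' @param samples data frame with columns `sample` (matching `colnames(tpm)`)
#'   and `condition` (or columns `temperature` and `acidification`, combined
#'   into one condition label).
#' @return gene x condition matrix of per-gene mean tpm across replicates.
#' @export
combine_replicates <- function(tpm, samples) {
  stopifnot(is.matrix(tpm), is.data.frame(samples),
            "sample" %in% names(samples))
  if (!"condition" %in% names(samples)) {
    if (!all(c("temperature", "acidification") %in% names(samples))) {
      stop("samples need a 'condition' column or 'temperature' + 'acidification'")
    }
    samples$condition <- paste(samples$temperature, samples$acidification,
                               sep = "_")
  }
  missing <- setdiff(samples$sample, colnames(tpm))
  if (length(missing)) {
    stop("samples absent from the matrix: ", paste(missing, collapse = ", "))
  }
  conds <- unique(samples$condition)
  out <- vapply(conds, function(cd) {
    cols <- samples$sample[samples$condition == cd]
    rowMeans(tpm[, cols, drop = FALSE])
  }, numeric(nrow(tpm)))
  rownames(out) <- rownames(tpm)
  out
}

#' Per-gene induction fold change (stressed vs unstressed)
#'
#' @param mat gene x condition matrix (see [combine_replicates()]).
#' @param stressed,unstressed condition column names.
#' @param pseudo pseudocount in tpm added to both conditions to stabilize
#'   low-abundance genes (default 1; 0 gives raw ratios).
#' @return named numeric vector of per-gene fold changes.
#' @export
induction_fold_change <- function(mat, stressed, unstressed, pseudo = 1) {
  for (cd in c(stressed, unstressed)) {
    if (!cd %in% colnames(mat)) stop("condition not in matrix: ", cd)
  }
  stopifnot(pseudo >= 0)
  (mat[, stressed] + pseudo) / (mat[, unstressed] + pseudo)
}

#' Per-gene acidification fold change
#'
#' Ratio of transcript abundance after heat shock with intracellular
#' acidification to abundance after heat shock with acidification
#' prevented. Values above 1 mark genes preferentially induced in acidified
#' cells. Both conditions must come from the same translation state; when a
#' `samples`-style annotation is supplied the translation states are
#' checked.
#'
#' @param mat gene x condition matrix.
#' @param acid,noacid condition column names (shock with / without
#'   acidification).
#' @param pseudo pseudocount in tpm (default 1).
#' @param translation optional named character vector mapping condition
#'   names to translation states; mismatched states raise an error.
#' @return named numeric vector of per-gene ratios.
#' @export
acidification_fold_change <- function(mat, acid, noacid, pseudo = 1,
                                      translation = NULL) {
  if (!is.null(translation)) {
    if (!all(c(acid, noacid) %in% names(translation))) {
      stop("translation states missing for the requested conditions")
    }
    if (translation[[acid]] != translation[[noacid]]) {
      stop("acidification ratios must compare conditions with the same ",
           "translation state (got '", translation[[acid]], "' vs '",
           translation[[noacid]], "')")
    }
  }
  induction_fold_change(mat, acid, noacid, pseudo)
}

#' Apply regulon exclusion and size rules
#'
#' Genes under control of the core stress factors (Hsf1, Msn2/4) are removed
#' from every other regulon, and regulons below the minimum size are
#' dropped.
#'
#' @param regulons named list of gene-id vectors.
#' @param core names (within `regulons`) of the core regulons whose members
#'   are excluded from all others; default `c("Hsf1", "Msn2/4")`,
#'   intersected with the available names.
#' @param min_size minimum regulon size after exclusion (default 4).
#' @return filtered named list; dropped regulons recorded in
#'   `attr(, "dropped")`.
#' @export
apply_regulon_exclusions <- function(regulons, core = c("Hsf1", "Msn2/4"),
                                     min_size = 4) {
  stopifnot(is.list(regulons), !is.null(names(regulons)))
  core <- intersect(core, names(regulons))
  core_genes <- unique(unlist(regulons[core], use.names = FALSE))
  out <- lapply(names(regulons), function(nm) {
    if (nm %in% core) regulons[[nm]]
    else setdiff(regulons[[nm]], core_genes)
  })
  names(out) <- names(regulons)
  sizes <- lengths(out)
  dropped <- names(out)[sizes < min_size]
  out <- out[sizes >= min_size]
  attr(out, "dropped") <- dropped
  out
}

#' Score regulons for heat-shock induction and pH sensitivity
#'
#' Per regulon: the mean log2 heat-shock fold change, the median
#' acidification fold change, and the empirical CDF of acidification fold
#' changes over member genes. Regulons smaller than `min_size` are dropped
#' with a logged reason (exclusion rules should already have been applied,
#' see [apply_regulon_exclusions()]).
#'
#' @param hs_fc named per-gene heat-shock fold changes (ratio scale).
#' @param acid_fc named per-gene acidification fold changes (ratio scale).
#' @param regulons named list of gene-id vectors.
#' @param min_size minimum genes with finite statistics per regulon
#'   (default 4).
#' @return a `regulon_scores` data frame with columns `regulon`, `n_genes`,
#'   `mean_log2_hs_fc`, `median_acid_fc`, `p_vs_background`,
#'   `p_adj`; per-regulon ECDFs in `attr(, "ecdf")` (named list of sorted
#'   member ratios); dropped regulons in `attr(, "dropped")`.
#' @export
score_regulons <- function(hs_fc, acid_fc, regulons, min_size = 4) {
  stopifnot(is.list(regulons))
  if (length(regulons) == 0) stop("empty regulon list")
  genes <- intersect(names(hs_fc), names(acid_fc))
  member_all <- unique(unlist(regulons, use.names = FALSE))
  background_genes <- setdiff(genes, member_all)
  rows <- list(); ecdfs <- list(); dropped <- character(0)
  for (nm in names(regulons)) {
    members <- intersect(regulons[[nm]], genes)
    acid <- acid_fc[members]
    hs <- hs_fc[members]
    ok <- is.finite(acid) & is.finite(hs)
    if (sum(ok) < min_size) {
      dropped <- c(dropped, nm)
      next
    }
    acid <- acid[ok]; hs <- hs[ok]
    p <- if (length(background_genes) >= 4 && length(acid) >= 4) {
      test_regulon_vs_background(acid, acid_fc[background_genes])$p.value
    } else NA_real_
    rows[[nm]] <- data.frame(
      regulon = nm, n_genes = sum(ok),
      mean_log2_hs_fc = mean(log2(hs)),
      median_acid_fc = median(acid),
      p_vs_background = p
    )
    ecdfs[[nm]] <- sort(acid)
  }
  if (length(rows) == 0) stop("no regulon met the minimum size of ", min_size)
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out$p_adj <- p.adjust(out$p_vs_background, method = "BH")
  attr(out, "ecdf") <- ecdfs
  attr(out, "dropped") <- dropped
  class(out) <- c("regulon_scores", "data.frame")
  out
}

#' Rank test of a regulon's pH sensitivity against background genes
#'
#' Two-sided Mann-Whitney U test on log acidification ratios of regulon
#' members versus background genes (all scored genes outside the core
#' Hsf1/Msn2-4 regulons). Shares the rank-test implementation of
#' [compare_class_ph()]. The two groups must be disjoint.
#'
#' @param regulon_ratios acidification fold changes of member genes
#'   (n >= 4), named by gene when overlap checking is wanted.
#' @param background_ratios fold changes of background genes (n >= 4).
#' @return list with `statistic`, `p.value`, `method`.
#' @export
test_regulon_vs_background <- function(regulon_ratios, background_ratios) {
  if (length(regulon_ratios) < 4 || length(background_ratios) < 4) {
    stop("regulon and background each need n >= 4 genes")
  }
  if (!is.null(names(regulon_ratios)) && !is.null(names(background_ratios))) {
    ov <- intersect(names(regulon_ratios), names(background_ratios))
    if (length(ov)) {
      stop("regulon and background overlap: ",
           paste(head(ov, 5), collapse = ", "))
    }
  }
  compare_class_ph(log(regulon_ratios), log(background_ratios))
}
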