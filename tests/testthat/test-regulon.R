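# Regulon-level pH-sensitivity scoring from tpm tables.

test_that("replicate averaging is exact and validates conditions", {
  tpm <- cbind(a_rep1 = c(2, 10), a_rep2 = c(4, 30), b_rep1 = c(1, 1))
  rownames(tpm) <- c("g1", "g2")
  samples <- data.frame(sample = colnames(tpm),
                        condition = c("a", "a", "b"))
  out <- combine_replicates(tpm, samples)
  expect_equal(out[, "a"], c(g1 = 3, g2 = 20))
  expect_equal(out[, "b"], c(g1 = 1, g2 = 1))
  expect_error(combine_replicates(tpm, data.frame(sample = "zzz",
                                                  condition = "a")),
               "absent")
})

test_that("replicate means concentrate as CV/sqrt(n_reps)", {
  sim <- simulate_expression(list(), numeric(0), n_genes = 1000, cv = 0.2,
                             n_reps = 2, renormalize = FALSE, seed = 4)
  mat <- combine_replicates(sim$tpm, sim$samples)
  rel_err <- abs(mat[, "mock_allowed"] / sim$truth$basal - 1)
  expect_lt(mean(rel_err), 0.2 / sqrt(2) * 1.2)
})

test_that("fold changes follow the pseudocount arithmetic exactly", {
  mat <- cbind(stress = c(10, 0, 5), rest = c(1, 1, 5))
  rownames(mat) <- paste0("g", 1:3)
  expect_equal(unname(induction_fold_change(mat, "stress", "rest", pseudo = 0)),
               c(10, 0, 1))
  expect_equal(unname(induction_fold_change(mat, "stress", "rest", pseudo = 1)),
               c(11 / 2, 1 / 2, 1))
  expect_error(induction_fold_change(mat, "nope", "rest"), "nope")
  # acidification ratios refuse mismatched translation states
  expect_error(
    acidification_fold_change(mat, "stress", "rest",
                              translation = c(stress = "active",
                                              rest = "cycloheximide")),
    "translation")
})

test_that("renormalization shifts ratios compositionally but medians stay informative", {
  regs <- list(Hsf1 = paste0("gene", 1:25))   # 5% of a 500-gene transcriptome
  sim <- simulate_expression(regs, acid_effects = c(Hsf1 = 4),
                             hs_effects = c(Hsf1 = 1),
                             n_genes = 500, cv = 0, basal_sdlog = 0,
                             renormalize = TRUE, seed = 5)
  mat <- combine_replicates(sim$tpm, sim$samples)
  acid <- acidification_fold_change(mat, "shock_allowed", "shock_prevented",
                                    pseudo = 0)
  members <- paste0("gene", 1:25)
  others <- setdiff(names(acid), members)
  # members slightly below the planted 4, non-members slightly below 1
  expect_true(all(acid[members] < 4 & acid[members] > 3))
  expect_true(all(acid[others] < 1 & acid[others] > 0.8))
  expect_equal(unname(median(acid[members]) / median(acid[others])), 4,
               tolerance = 1e-9)
})

test_that("exclusion rule removes core-regulon genes and small regulons", {
  regs <- list("Hsf1" = c("g1", "g2", "g3", "g4", "g5"),
               "Msn2/4" = c("g6", "g7", "g8", "g9"),
               "TF1" = c("g1", "g6", "g10", "g11", "g12", "g13"),
               "TF2" = c("g2", "g3", "g14"))
  out <- apply_regulon_exclusions(regs)
  expect_false(any(c("g1", "g6") %in% out$TF1))
  expect_equal(out$TF1, c("g10", "g11", "g12", "g13"))
  expect_false("TF2" %in% names(out))     # 1 gene left < 4
  expect_equal(attr(out, "dropped"), "TF2")
  core_members <- unlist(out[c("Hsf1", "Msn2/4")])
  for (nm in setdiff(names(out), c("Hsf1", "Msn2/4"))) {
    expect_length(intersect(out[[nm]], core_members), 0)
  }
})

test_that("regulon scores report size, medians and drop small sets", {
  genes <- paste0("g", 1:100)
  hs <- setNames(rep(2, 100), genes)
  acid <- setNames(rep(1, 100), genes)
  acid[c("g1", "g2", "g3")] <- c(2, 4, 8)
  scores <- score_regulons(hs, acid,
                           list(big = paste0("g", 1:6),
                                small = paste0("g", 7:9)),
                           min_size = 4)
  expect_equal(attr(scores, "dropped"), "small")
  expect_equal(scores$n_genes, 6)
  expect_equal(scores$median_acid_fc, median(c(2, 4, 8, 1, 1, 1)))
  expect_equal(scores$mean_log2_hs_fc, 1)
  expect_error(score_regulons(hs, acid, list()), "empty")
  # {2,4,8} medians to 4
  s2 <- score_regulons(hs, acid, list(trio = c("g1", "g2", "g3"),
                                      rest = paste0("g", 4:20)),
                       min_size = 3)
  expect_equal(s2$median_acid_fc[s2$regulon == "trio"], 4)
})

test_that("planted acidification effects rank and test as designed", {
  regs <- make_test_regulons(n_null = 10)
  effects <- setNames(c(4, 1, rep(1, 10)), names(regs))
  sim <- simulate_expression(regs, acid_effects = effects, n_genes = 2000,
                             cv = 0.2, seed = 3)
  mat <- combine_replicates(sim$tpm, sim$samples)
  hs <- induction_fold_change(mat, "shock_allowed", "mock_allowed")
  acid <- acidification_fold_change(mat, "shock_allowed", "shock_prevented")
  scores <- score_regulons(hs, acid, apply_regulon_exclusions(regs))
  expect_equal(scores$regulon[which.max(scores$median_acid_fc)], "Hsf1")
  expect_lt(scores$p_vs_background[scores$regulon == "Hsf1"], 1e-6)
  # monotone in the planted effect (noise-free)
  meds <- vapply(c(1, 2, 4, 8), function(eff) {
    s <- simulate_expression(regs[1], acid_effects = c(Hsf1 = eff),
                             n_genes = 500, cv = 0, seed = 1)
    m <- combine_replicates(s$tpm, s$samples)
    a <- acidification_fold_change(m, "shock_allowed", "shock_prevented")
    median(a[regs$Hsf1])
  }, numeric(1))
  expect_true(all(diff(meds) > 0))
})

test_that("regulon-vs-background test rejects overlap and tiny groups", {
  acid <- setNames(runif(50, 0.5, 2), paste0("g", 1:50))
  expect_error(test_regulon_vs_background(acid[1:10], acid[5:50]), "overlap")
  expect_error(test_regulon_vs_background(acid[1:3], acid[4:50]), "n >= 4")
  # identical distributions: no signal
  set.seed(8)
  p <- test_regulon_vs_background(setNames(exp(rnorm(40)), paste0("a", 1:40)),
                                  setNames(exp(rnorm(400)), paste0("b", 1:400)))
  expect_gt(p$p.value, 0.01)
})

test_that("GMT and tpm round-trips preserve structure", {
  sets <- list(Hsf1 = c("g1", "g2", "g3"), TF1 = c("g4", "g5", "g6"))
  path <- withr::local_tempfile()
  write_gmt(sets, path)
  expect_equal(read_gmt(path), sets, ignore_attr = TRUE)
  sim <- simulate_expression(list(), numeric(0), n_genes = 50, seed = 1)
  tpath <- withr::local_tempfile()
  write_tpm(sim$tpm, tpath)
  back <- read_tpm(tpath)
  expect_equal(back, sim$tpm, tolerance = 1e-12)
  expect_error(read_gmt(withr::local_tempfile(lines = character(0))), "empty")
})
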