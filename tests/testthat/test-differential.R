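test_that("within-group shuffling preserves group multisets and determinism", {
  v <- c(10, 20, 30, 40, 50, 60, 70)
  g <- factor(c("a", "a", "a", "b", "b", "b", "c")) # c has one member
  s1 <- shuffle_within_group(v, g, seed = 42)
  s2 <- shuffle_within_group(v, g, seed = 42)
  expect_identical(s1, s2)
  expect_identical(s1[7], v[7]) # singleton group fixed
  for (lev in levels(g)) {
    expect_setequal(s1[g == lev], v[g == lev])
  }
  # different seeds give a different permutation with high probability
  many <- vapply(1:20, function(s) {
    any(shuffle_within_group(1:10, factor(rep("a", 10)), seed = s) != 1:10)
  }, logical(1))
  expect_true(any(many))
})

test_that("estimate group test recovers exact and null effects", {
  cond <- factor(rep(c("control", "case"), each = 15),
                 levels = c("control", "case"))
  exact <- as.numeric(cond == "case")
  res <- suppressWarnings(estimate_group_test(exact, cond)) # perfect fit
  expect_equal(res$effect, 1, tolerance = 1e-10)
  expect_lt(res$p_value, 1e-10)

  # null: p-values approximately uniform over replications
  set.seed(7)
  ps <- vapply(1:200, function(i) {
    estimate_group_test(rnorm(30), cond)$p_value
  }, numeric(1))
  expect_gt(ks.test(ps, "punif")$p.value, 0.01)

  # sign check on a simulated neuronal-loss study
  comp <- draw_compositions(40, condition_shift = c(-1.2, 0, 0, 0, 0),
                            seed = 8)
  neu <- comp[comp$cell_type == "neuron" & comp$tissue_sample == "TS1", ]
  res2 <- estimate_group_test(neu$p_nuclear,
                              factor(neu$condition,
                                     levels = c("control", "case")))
  expect_lt(res2$effect, 0)
  expect_lt(res2$p_value, 0.01)
})

test_that("stepwise selection finds the single truly shifted cell type", {
  hits <- 0
  clean <- 0
  for (s in 1:50) {
    set.seed(100 + s)
    n <- 60
    cond <- factor(rep(c("control", "case"), each = n / 2),
                   levels = c("control", "case"))
    est <- matrix(rnorm(n * 5), n, 5,
                  dimnames = list(sprintf("s%02d", 1:n), cell_types()))
    est[, "neuron"] <- est[, "neuron"] - 1.2 * (cond == "case")
    sel <- stepwise_cell_association(est, cond)
    if ("neuron" %in% sel$cell_type) hits <- hits + 1
    if (nrow(sel) == 0 || all(sel$cell_type == "neuron")) clean <- clean + 1
  }
  expect_gte(hits / 50, 0.9)
  # false inclusions happen at the usual stepwise baseline; just record
  expect_gte(clean, 10)
})

test_that("stepwise selection recovers a three-cell-type sign pattern", {
  set.seed(9)
  n <- 80
  cond <- factor(rep(c("control", "case"), each = n / 2),
                 levels = c("control", "case"))
  est <- matrix(rnorm(n * 5, 0, 0.6), n, 5,
                dimnames = list(sprintf("s%02d", 1:n), cell_types()))
  est[, "neuron"] <- est[, "neuron"] - 1.5 * (cond == "case")
  est[, "microglia"] <- est[, "microglia"] - 1.0 * (cond == "case")
  est[, "oligodendrocyte"] <- est[, "oligodendrocyte"] + 1.0 * (cond == "case")
  sel <- stepwise_cell_association(est, cond)
  expect_true(all(c("neuron", "microglia", "oligodendrocyte") %in%
                    sel$cell_type))
  expect_identical(sel$sign[sel$cell_type == "neuron"], -1)
  expect_identical(sel$sign[sel$cell_type == "microglia"], -1)
  expect_identical(sel$sign[sel$cell_type == "oligodendrocyte"], 1)
})

test_that("model specs build the intended adjustments", {
  cond <- factor(rep(c("control", "case"), each = 6),
                 levels = c("control", "case"))
  est <- runif(12)
  spec <- model_spec(cond, cell_adjustment = adjustment_ordered(est))
  expect_s3_class(spec, "model_spec")
  expect_error(model_spec(factor(rep("a", 5))))
  expect_error(adjustment_continuous(data.frame(x = c(-1, 1)),
                                     transform = "log"))
})

test_that("shuffled adjustment behaves like no adjustment under confounding", {
  panel <- build_reference_panel(seed = 31)
  comp <- draw_compositions(100, condition_shift = c(-1.2, 0, 0, 0, 0),
                            seed = 32)
  sim <- simulate_study(comp, panel, da_fraction = 0.05, seed = 33)
  meta <- sim$bundle$sample_meta
  ts1 <- meta$sample_id[meta$tissue_sample == "TS1"]
  rip1 <- sim$bundle$rip_counts[, ts1]
  m1 <- meta[match(ts1, meta$sample_id), ]
  nuis <- data.frame(age_band = m1$age_band, sex = m1$sex)
  cond <- factor(m1$condition, levels = c("control", "case"))
  mn <- msp(sim$bundle$rip_counts, panel$peak_markers)[ts1, "neuron"]
  wn <- composition_matrix(comp, "nuclear", ts1)

  da_none <- fit_adjusted_da(rip1, model_spec(cond, nuis, adjustment_none()))
  da_shuf <- fit_adjusted_da(rip1, model_spec(cond, nuis,
                                              adjustment_shuffled(mn, 99)))
  expect_gt(cor(da_none$log2fc, da_shuf$log2fc), 0.95)

  # exact true-proportion adjustment removes composition-driven hits
  da_true <- fit_adjusted_da(rip1, model_spec(cond, nuis,
    adjustment_continuous(as.data.frame(wn), transform = "log")))
  sig <- da_true$feature_id[da_true$fdr < 0.05]
  marker_peaks <- unlist(panel$peak_markers)
  expect_lt(mean(sig %in% marker_peaks), 0.1)
  # and keeps genuine condition effects detectable
  truth <- sim$truth$da_truth
  expect_gt(mean(truth$feature_id[truth$is_da] %in% sig), 0.8)
})
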