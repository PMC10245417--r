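test_that("cpm_log2 matches hand computation and flags empty libraries", {
  m <- matrix(c(10, 0, 90, 100, 50, 850), nrow = 3,
              dimnames = list(c("a", "b", "c"), c("s1", "s2")))
  got <- cpm_log2(m)
  expect_equal(got["a", "s1"], log2(10 / 100 * 1e6 + 1))
  expect_equal(got["b", "s1"], 0)
  expect_equal(got["c", "s2"], log2(850 / 1000 * 1e6 + 1))

  single <- matrix(10, 1, 3, dimnames = list("g", c("x", "y", "z")))
  expect_equal(unname(cpm_log2(single)[1, 1]), log2(1e6 + 1))

  bad <- matrix(c(1, 0, 0, 0), 2, dimnames = list(c("a", "b"), c("s1", "s2")))
  expect_error(cpm_log2(bad), "s2")
})

test_that("first PC score matches a dense eigendecomposition oracle", {
  set.seed(12)
  x <- matrix(rnorm(200), 10, 20,
              dimnames = list(paste0("f", 1:10), paste0("s", 1:20)))
  score <- first_pc_score(x)
  xs <- t(scale(t(x)))
  ev <- eigen(xs %*% t(xs))$vectors[, 1]
  oracle <- as.numeric(t(xs) %*% ev)
  # equal up to overall sign
  expect_equal(abs(cor(score, oracle)), 1, tolerance = 1e-10)
  expect_equal(sort(abs(unname(score))), sort(abs(oracle)), tolerance = 1e-8)
  # orientation: high score = high mean marker signal
  expect_gt(cor(score, colMeans(xs)), 0)
})

test_that("first PC score handles rank-1 structure and degenerate inputs", {
  base <- seq(1, 5, length.out = 8)
  x <- rbind(a = base, b = 2 * base + 3, c = -base + 10)
  colnames(x) <- paste0("s", 1:8)
  s <- first_pc_score(x)
  expect_equal(abs(cor(s, base)), 1, tolerance = 1e-10)

  # zero-variance features are dropped, too few features error
  x2 <- rbind(flat = rep(1, 8), ok = base)
  colnames(x2) <- paste0("s", 1:8)
  expect_error(suppressMessages(first_pc_score(x2)),
               class = "cellwise_insufficient_marker_error")
})

test_that("profile estimates span [0,1], permute with samples, ignore feature duplication", {
  panel <- tiny_panel()
  comp <- draw_compositions(15, seed = 2)
  sim <- simulate_study(comp, panel, seed = 3)
  est <- mgp(sim$bundle$expression, panel$expr_markers)
  expect_true(all(apply(est, 2, min) == 0))
  expect_true(all(apply(est, 2, max) == 1))

  # determinism
  est2 <- mgp(sim$bundle$expression, panel$expr_markers)
  expect_identical(unclass(est), unclass(est2))

  # permutation equivariance
  perm <- sample(ncol(sim$bundle$expression))
  estp <- mgp(sim$bundle$expression[, perm], panel$expr_markers)
  expect_equal(unclass(estp), unclass(est)[rownames(estp), ],
               tolerance = 1e-10, ignore_attr = TRUE)

  # duplicating every feature row leaves the rescaled PC score unchanged
  x <- cpm_log2(sim$bundle$expression)[panel$expr_markers$neuron, ]
  s1 <- rescale01(first_pc_score(x))
  dup <- rbind(x, `rownames<-`(x, paste0(rownames(x), "_dup")))
  s2 <- rescale01(first_pc_score(dup))
  expect_equal(s2, s1, tolerance = 1e-8, ignore_attr = TRUE)
})

test_that("MGP endpoints follow pure-mixture fractions", {
  panel <- tiny_panel()
  props <- matrix(0, 5, 5, dimnames = list(NULL, cell_types()))
  props[, "neuron"] <- c(0, 0.25, 0.5, 0.75, 1)
  props[, "astrocyte"] <- 1 - props[, "neuron"]
  comp <- manual_composition(props)
  sim <- simulate_study(comp, panel, lib_sizes = rep(1e7, 5),
                        dispersion = 0, seed = 4)
  est <- mgp(sim$bundle$expression, panel$expr_markers["neuron"])
  expect_equal(unname(est[1, "neuron"]), 0)
  expect_equal(unname(est[5, "neuron"]), 1)
  expect_true(all(diff(est[, "neuron"]) > 0))
})

test_that("WGBS MSP rises monotonically with the true fraction and flips under complementation", {
  panel <- tiny_panel()
  props <- matrix(0, 8, 5, dimnames = list(NULL, cell_types()))
  props[, "neuron"] <- seq(0.05, 0.75, length.out = 8)
  props[, "oligodendrocyte"] <- 1 - props[, "neuron"]
  comp <- manual_composition(props)
  sim <- simulate_study(comp, panel, beta_noise_sd = 0, missing_rate = 0,
                        coverage_mean = 50, seed = 5)
  beta <- sim$bundle$methylation_beta
  # only neuron and oligodendrocyte marks are informative in this mixture
  marks <- panel$meth_markers[panel$meth_markers$cell_type %in%
                                c("neuron", "oligodendrocyte"), ]
  est <- wgbs_msp(beta, marks)
  expect_equal(unname(cor(est[, "neuron"], props[, "neuron"],
                          method = "spearman")), 1)

  flipped <- wgbs_msp(1 - beta, marks)
  expect_equal(unname(flipped[, "neuron"]), unname(1 - est[, "neuron"]),
               tolerance = 1e-8)
})

test_that("WGBS MSP imputes missing entries with site medians", {
  panel <- tiny_panel()
  comp <- draw_compositions(10, seed = 6)
  sim <- simulate_study(comp, panel, missing_rate = 0.15, seed = 7)
  est <- suppressMessages(
    wgbs_msp(sim$bundle$methylation_beta, panel$meth_markers,
             sim$bundle$methylation_coverage))
  expect_false(anyNA(est))
  expect_true(all(est >= 0 & est <= 1))
})

test_that("reference-based NNLS recovers mixing proportions exactly when identifiable", {
  panel <- tiny_panel()
  sig <- panel$expression
  # pure signature column
  bulk1 <- matrix(sig[, "astrocyte"], ncol = 1,
                  dimnames = list(rownames(sig), "pure"))
  p1 <- reference_proportions(bulk1, sig, input = "linear")
  expect_equal(unname(p1["pure", "astrocyte"]), 1, tolerance = 1e-8)

  # 50/50 mix
  bulk2 <- matrix(0.5 * sig[, "neuron"] + 0.5 * sig[, "microglia"], ncol = 1,
                  dimnames = list(rownames(sig), "mix"))
  p2 <- reference_proportions(bulk2, sig, input = "linear")
  expect_equal(unname(p2["mix", c("neuron", "microglia")]), c(0.5, 0.5),
               tolerance = 1e-8)

  # random simplex mixes of all five columns
  set.seed(8)
  w <- t(apply(matrix(rgamma(5 * 6, 2), 6), 1, function(x) x / sum(x)))
  bulk3 <- sig %*% t(w)
  colnames(bulk3) <- paste0("m", 1:6)
  p3 <- reference_proportions(bulk3, sig, input = "linear")
  expect_lt(max(abs(unclass(p3) - w)), 1e-6)
  expect_equal(unname(rowSums(p3)), rep(1, 6), tolerance = 1e-12)

  # rank-deficient signature
  sig2 <- sig
  sig2[, 2] <- sig2[, 1]
  expect_error(reference_proportions(bulk1, sig2, input = "linear"),
               class = "cellwise_rank_error")
})

test_that("ordered-factor conversion bins by quantile, monotonically", {
  lev <- to_ordered_factor(0:9)
  expect_identical(as.integer(lev), rep(1:5, each = 2))
  expect_true(is.ordered(lev))

  expect_true(all(to_ordered_factor(rep(3.2, 7)) == 1))

  set.seed(9)
  x <- rnorm(50)
  l <- as.integer(to_ordered_factor(x))
  o <- order(x)
  expect_true(all(diff(l[o]) >= 0))
  # equal scores always share a level
  y <- c(1, 1, 1, 2, 2, 3, 4, 5, 6, 7)
  ly <- as.integer(to_ordered_factor(y))
  expect_true(length(unique(ly[y == 1])) == 1)
})

test_that("profile methods track the tissue fraction their modality measures", {
  panel <- tiny_panel()
  comp <- draw_compositions(40, seed = 13)
  sim <- simulate_study(comp, panel, seed = 14)
  ww <- composition_matrix(comp, "whole")
  wn <- composition_matrix(comp, "nuclear")
  e_mgp <- mgp(sim$bundle$expression, panel$expr_markers)
  e_msp <- msp(sim$bundle$rip_counts, panel$peak_markers)
  e_wgbs <- wgbs_msp(sim$bundle$methylation_beta, panel$meth_markers,
                     sim$bundle$methylation_coverage)
  k <- "neuron"
  expect_gt(cor(e_mgp[, k], ww[, k]), cor(e_mgp[, k], wn[, k]))
  expect_gt(cor(e_msp[, k], wn[, k]), cor(e_msp[, k], ww[, k]))
  expect_gt(cor(e_wgbs[, k], wn[, k]), cor(e_wgbs[, k], ww[, k]))
})
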