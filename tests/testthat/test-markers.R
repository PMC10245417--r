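test_that("NB differential test handles null and exact-ratio features", {
  n <- 8
  grp <- factor(rep(c("a", "b"), each = n / 2))
  # balance libraries so the exact 4x feature is not distorted by the offset
  cnt <- rbind(
    flat = rep(500L, n),
    up4 = c(rep(100L, n / 2), rep(400L, n / 2)),
    down4 = c(rep(400L, n / 2), rep(100L, n / 2)),
    other = rep(1000L, n))
  colnames(cnt) <- paste0("s", 1:n)
  da <- call_differential(cnt, grp)
  expect_s3_class(da, "da_result")
  expect_equal(da$log2fc[da$feature_id == "flat"], 0, tolerance = 1e-8)
  expect_gt(da$p_value[da$feature_id == "flat"], 0.99)
  expect_equal(da$log2fc[da$feature_id == "up4"], 2, tolerance = 1e-6)
  expect_equal(da$log2fc[da$feature_id == "down4"], -2, tolerance = 1e-6)
  expect_equal(da$mean_count[da$feature_id == "up4"], 250)
  # BH never lowers a p-value
  expect_true(all(da$fdr >= da$p_value - 1e-12))
})

test_that("confounded and constant covariates are caught", {
  n <- 8
  grp <- factor(rep(c("a", "b"), each = n / 2))
  cnt <- matrix(rpois(5 * n, 100), 5, n,
                dimnames = list(paste0("f", 1:5), paste0("s", 1:n)))
  cnt <- matrix(as.integer(cnt), 5, n, dimnames = dimnames(cnt))
  # covariate collinear with group
  expect_error(
    call_differential(cnt, grp,
                      covariates = data.frame(x = as.numeric(grp))),
    class = "cellwise_singular_design_error")
  # constant covariate: dropped with a warning, inference unchanged
  plain <- call_differential(cnt, grp)
  expect_warning(
    with_const <- call_differential(cnt, grp,
                                    covariates = data.frame(c0 = 1)),
    "constant")
  expect_equal(with_const$p_value, plain$p_value, tolerance = 1e-10)
  expect_equal(with_const$log2fc, plain$log2fc, tolerance = 1e-10)
})

test_that("DAR filtering applies both thresholds strictly", {
  da <- data.frame(
    feature_id = paste0("f", 1:5),
    log2fc = log2(abs(c(2, 5, -6, 10, -3))) * sign(c(2, 5, -6, 10, -3)),
    mean_count = c(2000, 2000, 500, 1500, 3000),
    p_value = rep(0.001, 5), fdr = rep(0.01, 5))
  class(da) <- c("da_result", "data.frame")
  kept <- filter_dars(da)
  expect_identical(kept$up, c("f2", "f4"))
  expect_identical(kept$down, character(0))

  edge <- data.frame(feature_id = c("at4", "m999", "at1000"),
                     log2fc = c(2, 3, 3),
                     mean_count = c(2000, 999, 1000),
                     p_value = 1e-4, fdr = 1e-3)
  class(edge) <- c("da_result", "data.frame")
  kept2 <- filter_dars(edge)
  expect_identical(kept2$up, character(0)) # all boundaries are strict
})

test_that("peak annotation respects half-open windows and strand", {
  genes <- data.frame(
    gene_id = c("gplus", "gminus"),
    chrom = "chr1", strand = c("+", "-"),
    tss = c(10000L, 40000L), utr5_end = c(10300L, 39700L))
  peaks <- data.frame(
    peak_id = c("inside", "at_boundary", "upstream_minus", "nowhere"),
    chrom = "chr1",
    start = c(10050L, 4900L, 41000L, 20000L),
    end = c(10200L, 5000L, 41500L, 20500L))
  map <- annotate_peaks(peaks, genes)
  # window of gplus is [5000, 10300): a peak ending exactly at 5000 misses
  expect_true("inside" %in% map$peak_id)
  expect_false("at_boundary" %in% map$peak_id)
  # minus-strand window is [39700, 45000): 41000-41500 is inside
  expect_identical(map$gene_id[map$peak_id == "upstream_minus"], "gminus")
  expect_false("nowhere" %in% map$peak_id)
})

test_that("peak annotation matches the brute-force oracle on random instances", {
  set.seed(77)
  for (rep in 1:5) {
    peaks <- random_intervals(60, "p")
    genes <- data.frame(
      gene_id = sprintf("g%03d", 1:25),
      chrom = sample(paste0("chr", 1:3), 25, replace = TRUE),
      strand = sample(c("+", "-"), 25, replace = TRUE),
      tss = t0 <- sample.int(50000L, 25, replace = TRUE),
      stringsAsFactors = FALSE)
    genes$utr5_end <- ifelse(genes$strand == "+", genes$tss + 400L,
                             pmax(genes$tss - 400L, 0L))
    got <- annotate_peaks(peaks, genes)
    want <- bf_annotate(peaks, genes)
    key <- function(d) sort(paste(d$peak_id, d$gene_id))
    expect_identical(key(got), key(want))
  }
})

test_that("marker-site assignment follows exclusivity and sign concordance", {
  markers <- list(neuron = c("gN1", "gN2"), astrocyte = "gA1",
                  oligodendrocyte = "gO1")
  map <- data.frame(
    peak_id = c("d1", "d2", "d2", "d3", "d4", "d5", "d6", "d7"),
    gene_id = c("gN1", "gN1", "gA1", "gA1", "gA1", "gO1", "gX", "gN2"))
  dars <- list(up = c("d1", "d2", "d4", "d6", "d7"), down = c("d3", "d5"))
  ms <- assign_marker_sites(dars, map, markers)
  expect_identical(ms$neuron, c("d1", "d7"))        # concordant neuron-up
  expect_identical(ms$astrocyte, "d3")              # concordant glia-up
  expect_identical(ms$oligodendrocyte, "d5")
  all_assigned <- unlist(ms)
  expect_false("d2" %in% all_assigned)  # ambiguous across cell types
  expect_false("d4" %in% all_assigned)  # astro marker but neuron-up
  expect_false("d6" %in% all_assigned)  # touches a non-marker gene
  expect_identical(anyDuplicated(all_assigned), 0L)

  expect_error(assign_marker_sites(dars, map,
                                   list(neuron = "g1", astrocyte = "g1")))
})

test_that("marker derivation on simulated sorted data recovers planted markers", {
  panel <- tiny_panel(seed = 5)
  sorted <- simulate_sorted_chip(panel, seed = 6)
  da <- call_differential(sorted$counts, sorted$group)
  ms <- assign_marker_sites(filter_dars(da),
                            annotate_peaks(panel$peaks, panel$genes),
                            panel$expr_markers)
  truth <- panel$peak_markers
  recovered <- mean(unlist(truth) %in% unlist(ms))
  wrong <- sum(vapply(names(ms),
                      function(k) sum(!(ms[[k]] %in% truth[[k]])), numeric(1)))
  expect_gte(recovered, 0.9)
  expect_identical(wrong, 0)
  expect_identical(anyDuplicated(unlist(ms)), 0L)
})

test_that("methylation mark filtering drops multi-assigned and low-coverage sites", {
  marks <- data.frame(site_id = c("s1", "s2", "s2", "s3", "s4"),
                      cell_type = c("neuron", "neuron", "astrocyte",
                                    "oligodendrocyte", "microglia"))
  cov <- matrix(20L, 4, 10, dimnames = list(paste0("s", 1:4), paste0("x", 1:10)))
  cov["s3", 1:2] <- 5L   # low in exactly 20% -> retained (strict 'more than')
  cov["s4", 1:3] <- 5L   # low in 30% -> dropped
  out <- filter_methylation_marks(marks, cov)
  expect_setequal(out$site_id, c("s1", "s3"))
})
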