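#' Simulate a linked multi-omic bulk-tissue study with known composition
#'
#' Mixes the cell-type reference signals of a panel according to
#' ground-truth proportions and adds sampling noise, producing an omics
#' bundle of expression counts (whole-tissue proportions, which include
#' the neuropil component), H3K27ac reads-in-peaks counts (nuclear
#' proportions) and methylation beta/coverage tables (nuclear
#' proportions), plus sample metadata with nuisance covariates. Counts are
#' negative binomial around `lib_size * sum_k p_k * signal_k(feature)`
#' (Poisson when `dispersion = 0`); bulk methylation beta is the convex
#' combination of cell-type betas plus bounded Gaussian noise; coverage is
#' Poisson and beta is missing exactly where coverage is zero (extra
#' missingness at `missing_rate` zeroes the coverage too). A fraction of
#' non-marker peaks can carry genuine condition effects that multiply the
#' case means, giving a known differential-acetylation truth.
#'
#' Randomness is consumed in a fixed order from `seed`: library sizes (if
#' defaulted), age/sex covariates, differential-peak selection and signs,
#' expression counts, reads-in-peaks counts, methylation noise, coverage,
#' extra missingness.
#'
#' @param composition A `true_composition` table from
#'   [draw_compositions()].
#' @param panel A [build_reference_panel()] object covering all three
#'   modalities.
#' @param lib_sizes Per-sample library sizes (named or in sample order);
#'   `NULL` draws log-normal sizes around `2e6`. Used for expression and
#'   reads-in-peaks alike.
#' @param dispersion Negative binomial dispersion (variance
#'   `mu + dispersion * mu^2`); 0 gives Poisson counts.
#' @param coverage_mean Mean Poisson sequencing coverage per methylation
#'   site.
#' @param missing_rate Extra fraction of methylation entries set missing.
#' @param da_fraction Fraction of all peaks flagged with a true condition
#'   effect; flagged peaks are drawn from non-marker peaks so marker peaks
#'   carry composition signal only.
#' @param da_log2fc Absolute log2 effect of flagged peaks in cases; the
#'   sign of each flagged peak is random.
#' @param beta_noise_sd SD of the bounded methylation noise.
#' @param seed Integer seed.
#'
#' @return A list with `bundle` (class `omics_bundle`: `expression`,
#'   `rip_counts`, `methylation_beta`, `methylation_coverage`, `peaks`,
#'   `sample_meta`) and `truth` (class `simulation_truth`: `composition`,
#'   `da_truth`, `panel`).
#' @export
simulate_study <- function(composition, panel,
                           lib_sizes = NULL,
                           dispersion = 0.05,
                           coverage_mean = 30,
                           missing_rate = 0.05,
                           da_fraction = 0,
                           da_log2fc = 0.8,
                           beta_noise_sd = 0.02,
                           seed = 1L) {
  stopifnot(inherits(panel, "reference_panel"))
  if (!inherits(composition, "true_composition")) {
    cw_stop("composition must come from draw_compositions()")
  }
  samples <- unique(composition$sample_id)
  n <- length(samples)
  W_nuc <- composition_matrix(composition, "nuclear", samples)
  W_whole <- composition_matrix(composition, "whole", samples)
  if (anyNA(W_nuc) || anyNA(W_whole)) {
    cw_stop("composition does not cover every sample x cell type",
            class = "cellwise_dimension_error")
  }
  meta1 <- composition[!duplicated(composition$sample_id),
                       c("sample_id", "individual_id", "tissue_sample",
                         "condition")]
  rownames(meta1) <- NULL

  set.seed(as.integer(seed))
  # stream 1: library sizes
  if (is.null(lib_sizes)) {
    lib_sizes <- 2e6 * exp(rnorm(n, 0, 0.2))
  } else if (!is.null(names(lib_sizes))) {
    lib_sizes <- lib_sizes[samples]
  }
  if (length(lib_sizes) != n || any(lib_sizes <= 0)) {
    cw_stop("lib_sizes must be positive, one per sample",
            class = "cellwise_dimension_error")
  }

  # stream 2: nuisance covariates, assigned per individual
  ind <- unique(meta1$individual_id)
  age_ind <- sample(1:5, length(ind), replace = TRUE)
  sex_ind <- sample(c("F", "M"), length(ind), replace = TRUE)
  meta <- meta1
  meta$age_band <- factor(age_ind[match(meta$individual_id, ind)],
                          levels = 1:5, ordered = TRUE)
  meta$sex <- factor(sex_ind[match(meta$individual_id, ind)])

  # stream 3: differential-acetylation truth on non-marker peaks
  peak_ids <- panel$peaks$peak_id
  marker_peaks <- unlist(panel$peak_markers, use.names = FALSE)
  n_da <- round(da_fraction * length(peak_ids))
  da_truth <- data.frame(feature_id = peak_ids,
                         is_da = FALSE, effect_log2fc = 0,
                         stringsAsFactors = FALSE)
  if (n_da > 0) {
    candidates <- setdiff(peak_ids, marker_peaks)
    if (n_da > length(candidates)) {
      cw_stop("da_fraction exceeds the available non-marker peaks",
              class = "cellwise_parameter_error")
    }
    flagged <- sample(candidates, n_da)
    signs <- sample(c(-1, 1), n_da, replace = TRUE)
    i <- match(flagged, da_truth$feature_id)
    da_truth$is_da[i] <- TRUE
    da_truth$effect_log2fc[i] <- signs * da_log2fc
  }

  draw_counts <- function(mu) {
    m <- matrix(0L, nrow(mu), ncol(mu), dimnames = dimnames(mu))
    if (dispersion <= 0) {
      m[] <- rpois(length(mu), lambda = mu)
    } else {
      m[] <- rnbinom(length(mu), mu = mu, size = 1 / dispersion)
    }
    m
  }

  # stream 4: expression (whole-tissue proportions)
  mu_expr <- panel$expression %*% t(W_whole)
  mu_expr <- sweep(mu_expr, 2, lib_sizes, "*")
  expression <- draw_counts(mu_expr)

  # stream 5: reads in peaks (nuclear proportions) with case effects
  mu_rip <- panel$h3k27ac %*% t(W_nuc)
  mu_rip <- sweep(mu_rip, 2, lib_sizes, "*")
  is_case <- meta$condition[match(samples, meta$sample_id)] == "case"
  if (any(da_truth$is_da) && any(is_case)) {
    fc <- 2^da_truth$effect_log2fc
    mu_rip[, is_case] <- mu_rip[, is_case] * fc
  }
  rip_counts <- draw_counts(mu_rip)

  # streams 6-8: methylation beta, coverage, missingness
  beta <- panel$methylation %*% t(W_nuc)
  beta <- beta + matrix(rnorm(length(beta), 0, beta_noise_sd),
                        nrow(beta), ncol(beta))
  beta <- pmin(pmax(beta, 0), 1)
  coverage <- matrix(rpois(length(beta), coverage_mean),
                     nrow(beta), ncol(beta), dimnames = dimnames(beta))
  if (missing_rate > 0) {
    drop <- matrix(runif(length(beta)) < missing_rate,
                   nrow(beta), ncol(beta))
    coverage[drop] <- 0L
  }
  beta[coverage == 0] <- NA_real_

  bundle <- structure(list(
    expression = expression,
    rip_counts = rip_counts,
    methylation_beta = beta,
    methylation_coverage = coverage,
    peaks = panel$peaks,
    sample_meta = meta
  ), class = "omics_bundle")
  truth <- structure(list(
    composition = composition,
    da_truth = da_truth,
    panel = panel
  ), class = "simulation_truth")
  list(bundle = bundle, truth = truth)
}

#' Simulate sorted-nuclei H3K27ac ChIP-seq reference samples
#'
#' Generates reads-in-peaks counts for NeuN+ (pure neuronal) and NeuN-
#' (glial mixture) sorted populations from the panel's H3K27ac signals —
#' the input from which differential acetylated regions, and hence marker
#' sites, are derived.
#'
#' @param panel A [build_reference_panel()] object.
#' @param n_per_group Samples per sorted population.
#' @param lib_size Mean library size (log-normal across samples).
#' @param dispersion Negative binomial dispersion.
#' @param glia_mix Composition of the NeuN- fraction over the four
#'   non-neuronal types (astrocyte, microglia, oligodendrocyte,
#'   endothelial); oligodendrocytes and astrocytes dominate.
#' @param seed Integer seed.
#' @return List with `counts` (peaks x samples) and `group` (factor with
#'   levels `glia`, `neuron`; `neuron` is the second level, so positive
#'   log2 fold changes mean neuron-hyperacetylated).
#' @export
simulate_sorted_chip <- function(panel, n_per_group = 5,
                                 lib_size = 3e7, dispersion = 0.05,
                                 glia_mix = c(astrocyte = 0.35,
                                              microglia = 0.10,
                                              oligodendrocyte = 0.45,
                                              endothelial = 0.10),
                                 seed = 1L) {
  stopifnot(inherits(panel, "reference_panel"), n_per_group >= 2)
  ct <- cell_types()
  glia_mix <- glia_mix / sum(glia_mix)
  set.seed(as.integer(seed))
  w <- matrix(0, 2 * n_per_group, length(ct), dimnames = list(NULL, ct))
  w[seq_len(n_per_group), names(glia_mix)] <-
    matrix(glia_mix, n_per_group, length(glia_mix), byrow = TRUE)
  w[(n_per_group + 1):(2 * n_per_group), "neuron"] <- 1
  libs <- lib_size * exp(rnorm(2 * n_per_group, 0, 0.2))
  mu <- sweep(panel$h3k27ac %*% t(w), 2, libs, "*")
  counts <- matrix(0L, nrow(mu), ncol(mu))
  if (dispersion <= 0) {
    counts[] <- rpois(length(mu), mu)
  } else {
    counts[] <- rnbinom(length(mu), mu = mu, size = 1 / dispersion)
  }
  dimnames(counts) <- list(panel$peaks$peak_id,
                           c(sprintf("glia_%02d", seq_len(n_per_group)),
                             sprintf("neuron_%02d", seq_len(n_per_group))))
  list(counts = counts,
       group = factor(rep(c("glia", "neuron"), each = n_per_group),
                      levels = c("glia", "neuron")))
}
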