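#' Counts-per-million log2 transform
#'
#' Scales every sample column to one million total counts and returns
#' `log2(CPM + 1)`.
#'
#' @param counts Features x samples matrix with positive column sums.
#' @return Transformed matrix of the same shape.
#' @export
cpm_log2 <- function(counts) {
  check_matrix(counts, "counts")
  libs <- colSums(counts)
  if (any(libs <= 0)) {
    cw_stop("zero-library sample(s): ",
            paste(colnames(counts)[libs <= 0], collapse = ", "))
  }
  log2(sweep(counts, 2, libs / 1e6, "/") + 1)
}

#' Per-sample score on the first principal component of marker features
#'
#' Centers (and, by default, unit-scales) each marker feature across
#' samples and projects the samples on the first right singular
#' direction. The sign of the component is oriented so the score
#' correlates positively with the across-feature mean of the scaled
#' marker signal — high score means high marker signal — with ties broken
#' toward a positive first-loading sum. Zero-variance features are
#' dropped with a log record.
#'
#' @param x Marker features x samples matrix (>= 2 usable features,
#'   >= 3 samples).
#' @param scale_features Unit-scale features before the decomposition.
#' @return Named numeric vector of per-sample scores; the number of
#'   features used is attached as attribute `n_features`.
#' @export
first_pc_score <- function(x, scale_features = TRUE) {
  check_matrix(x, "x")
  if (ncol(x) < 3) cw_stop("need >= 3 samples")
  v <- apply(x, 1, var)
  if (any(v == 0)) {
    cw_log("dropping ", sum(v == 0), " zero-variance feature(s)")
    x <- x[v > 0, , drop = FALSE]
  }
  if (nrow(x) < 2) {
    cw_stop("fewer than 2 usable marker features",
            class = "cellwise_insufficient_marker_error")
  }
  xs <- t(scale(t(x), center = TRUE, scale = scale_features))
  pc <- prcomp(t(xs), center = FALSE, scale. = FALSE)
  score <- pc$x[, 1]
  marker_mean <- colMeans(xs)
  r <- suppressWarnings(cor(score, marker_mean))
  if (is.na(r) || r == 0) {
    if (sum(pc$rotation[, 1]) < 0) score <- -score
  } else if (r < 0) {
    score <- -score
  }
  names(score) <- colnames(x)
  attr(score, "n_features") <- nrow(x)
  score
}

# shared profile-score driver for MGP / MSP
profile_scores <- function(transformed, markers, method, scale_features) {
  scores <- list()
  for (k in names(markers)) {
    feats <- intersect(markers[[k]], rownames(transformed))
    if (length(feats) < 2) {
      warning("skipping ", k, ": fewer than 2 marker features present")
      next
    }
    s <- tryCatch(
      first_pc_score(transformed[feats, , drop = FALSE], scale_features),
      cellwise_insufficient_marker_error = function(e) NULL)
    if (is.null(s)) {
      warning("skipping ", k, ": insufficient usable markers")
      next
    }
    scores[[k]] <- rescale01(s)
  }
  if (!length(scores)) {
    cw_stop("no cell type had enough markers",
            class = "cellwise_empty_result_error")
  }
  m <- do.call(cbind, scores)
  rownames(m) <- colnames(transformed)
  structure(m, method = method, class = c("estimate_matrix", class(m)))
}

#' Marker gene profiles (MGP) from bulk expression counts
#'
#' Per cell type: `log2(CPM + 1)` transform, subset to the type's marker
#' genes, first-principal-component score across samples, rescaled to
#' span exactly \[0, 1\]. Cell types with fewer than two usable markers
#' are skipped with a warning.
#'
#' @param expression Genes x samples count matrix.
#' @param markers Named list, cell type -> marker gene ids.
#' @param scale_features Unit-scale marker features before PCA.
#' @return Samples x cell types `estimate_matrix` (attribute
#'   `method = "MGP"`).
#' @export
mgp <- function(expression, markers, scale_features = TRUE) {
  profile_scores(cpm_log2(expression), markers, "MGP", scale_features)
}

#' Marker site profiles (MSP) from H3K27ac reads-in-peaks counts
#'
#' The reads-in-peaks analogue of [mgp()]: `log2(CPM + 1)` transform of
#' the peak counts, then a first-principal-component score over each cell
#' type's marker sites, rescaled to \[0, 1\].
#'
#' @param rip_counts Peaks x samples count matrix.
#' @param marker_sites Named list, cell type -> marker peak ids (e.g.
#'   from [assign_marker_sites()]).
#' @param scale_features Unit-scale marker features before PCA.
#' @return Samples x cell types `estimate_matrix` (attribute
#'   `method = "MSP"`).
#' @export
msp <- function(rip_counts, marker_sites, scale_features = TRUE) {
  profile_scores(cpm_log2(rip_counts), marker_sites, "MSP", scale_features)
}

#' Methylation-based marker site profiles (WGBS MSP)
#'
#' Per cell type: subset the beta matrix to that type's marks (after
#' dropping multi-assigned and poorly covered sites when coverage is
#' supplied), impute missing entries with the across-sample median of the
#' site, compute the first-principal-component score with feature
#' scaling, rescale to \[0, 1\], and return `1 - rescaled` — marker sites
#' are hypomethylated in their cell type, so low methylation means high
#' abundance. Sites missing in every sample are dropped with a log
#' record.
#'
#' @param methylation_beta Sites x samples beta matrix (missing allowed).
#' @param marks `data.frame` with `site_id` and `cell_type`.
#' @param methylation_coverage Optional coverage matrix; when given,
#'   marks are first passed through [filter_methylation_marks()].
#' @param min_cov,max_low_frac Coverage filter settings.
#' @return Samples x cell types `estimate_matrix` (attribute
#'   `method = "WGBS_MSP"`).
#' @export
wgbs_msp <- function(methylation_beta, marks, methylation_coverage = NULL,
                     min_cov = 10, max_low_frac = 0.2) {
  check_matrix(methylation_beta, "methylation_beta")
  if (!is.null(methylation_coverage)) {
    marks <- filter_methylation_marks(marks, methylation_coverage,
                                      min_cov, max_low_frac)
  }
  scores <- list()
  for (k in unique(marks$cell_type)) {
    sites <- intersect(marks$site_id[marks$cell_type == k],
                       rownames(methylation_beta))
    b <- methylation_beta[sites, , drop = FALSE]
    all_missing <- rowSums(!is.na(b)) == 0
    if (any(all_missing)) {
      cw_log("dropping ", sum(all_missing), " ", k,
             " site(s) missing in all samples")
      b <- b[!all_missing, , drop = FALSE]
    }
    if (nrow(b) < 2) {
      warning("skipping ", k, ": fewer than 2 usable methylation marks")
      next
    }
    med <- apply(b, 1, median, na.rm = TRUE)
    for (i in seq_len(nrow(b))) b[i, is.na(b[i, ])] <- med[i]
    s <- tryCatch(first_pc_score(b, scale_features = TRUE),
                  cellwise_insufficient_marker_error = function(e) NULL)
    if (is.null(s)) {
      warning("skipping ", k, ": insufficient usable methylation marks")
      next
    }
    scores[[k]] <- 1 - rescale01(s)
  }
  if (!length(scores)) {
    cw_stop("no cell type had enough methylation marks",
            class = "cellwise_empty_result_error")
  }
  m <- do.call(cbind, scores)
  rownames(m) <- colnames(methylation_beta)
  structure(m, method = "WGBS_MSP", class = c("estimate_matrix", class(m)))
}

#' Reference-based proportions by constrained least squares
#'
#' Deconvolves each bulk sample against a linear-scale signature matrix
#' by nonnegative least squares, renormalizing the solution to the
#' simplex. Counts are converted to linear CPM first (set
#' `input = "linear"` if the matrix is already on a linear relative
#' scale).
#'
#' @param bulk Features x samples matrix (counts by default).
#' @param signature Features x cell types reference matrix; must have
#'   full column rank on the shared features.
#' @param input `"counts"` or `"linear"`.
#' @return Samples x cell types `estimate_matrix` of simplex proportions
#'   (attribute `method = "REF"`).
#' @export
reference_proportions <- function(bulk, signature,
                                  input = c("counts", "linear")) {
  input <- match.arg(input)
  check_matrix(bulk, "bulk")
  feats <- intersect(rownames(bulk), rownames(signature))
  if (length(feats) < ncol(signature)) {
    cw_stop("too few shared features for the signature")
  }
  S <- as.matrix(signature[feats, , drop = FALSE])
  if (qr(S)$rank < ncol(S)) {
    cw_stop("signature matrix is rank deficient",
            class = "cellwise_rank_error")
  }
  B <- bulk[feats, , drop = FALSE]
  if (input == "counts") {
    B <- sweep(B, 2, colSums(bulk) / 1e6, "/")
  }
  # scale signature columns to unit sum so coefficients read as proportions
  S <- sweep(S, 2, colSums(S), "/")
  props <- t(apply(B, 2, function(y) {
    sol <- pracma::lsqnonneg(S, y)$x
    if (sum(sol) <= 0) {
      cw_stop("nonnegative least squares returned an all-zero solution")
    }
    sol / sum(sol)
  }))
  dimnames(props) <- list(colnames(bulk), colnames(signature))
  structure(props, method = "REF", simplex = TRUE,
            class = c("estimate_matrix", class(props)))
}

#' Discretize continuous scores into ordered quantile levels
#'
#' Quantile-based binning into `n_levels` ordered levels. Equal scores
#' always share a level (so the map is monotone); with heavy ties the
#' effective number of distinct levels may be smaller. Equal-width
#' binning over the observed range is available as an alternative.
#'
#' @param scores Numeric vector.
#' @param n_levels Number of ordered levels.
#' @param method `"quantile"` (default) or `"width"`.
#' @return Ordered factor with levels `1 < 2 < ... < n_levels`.
#' @export
to_ordered_factor <- function(scores, n_levels = 5,
                              method = c("quantile", "width")) {
  method <- match.arg(method)
  stopifnot(n_levels >= 2, is.numeric(scores))
  if (method == "quantile") {
    brk <- unique(quantile(scores, probs = seq(0, 1, length.out = n_levels + 1),
                           names = FALSE, na.rm = TRUE))
  } else {
    brk <- unique(seq(min(scores), max(scores), length.out = n_levels + 1))
  }
  if (length(brk) < 2) {
    lev <- rep(1L, length(scores))
  } else {
    lev <- cut(scores, breaks = brk, labels = FALSE, include.lowest = TRUE)
  }
  factor(lev, levels = seq_len(n_levels), ordered = TRUE)
}
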