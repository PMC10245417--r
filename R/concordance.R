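#' Pairwise Pearson correlations between estimate sets
#'
#' For every pair of estimate matrices and every cell type they share,
#' computes the Pearson correlation across the samples present in both
#' (after removing `exclude_samples`, e.g. individuals sequenced twice
#' that would inflate agreement).
#'
#' @param estimates Named list of `estimate_matrix` objects (samples x
#'   cell types).
#' @param exclude_samples Sample ids removed before correlating.
#' @return `data.frame` with `method_a`, `method_b`, `cell_type`, `r`,
#'   `n`; one row per unordered method pair and shared cell type.
#' @export
estimate_correlations <- function(estimates, exclude_samples = character()) {
  stopifnot(is.list(estimates), length(estimates) >= 2,
            !is.null(names(estimates)))
  nm <- names(estimates)
  out <- list()
  for (a in seq_along(nm)) {
    for (b in seq_along(nm)) {
      if (b <= a) next
      ea <- estimates[[a]]
      eb <- estimates[[b]]
      shared <- setdiff(intersect(rownames(ea), rownames(eb)),
                        exclude_samples)
      if (length(shared) < 3) {
        cw_stop("fewer than 3 shared samples between ", nm[a], " and ", nm[b],
                class = "cellwise_insufficient_overlap_error")
      }
      for (k in intersect(colnames(ea), colnames(eb))) {
        out[[length(out) + 1]] <- data.frame(
          method_a = nm[a], method_b = nm[b], cell_type = k,
          r = cor(ea[shared, k], eb[shared, k]),
          n = length(shared), stringsAsFactors = FALSE)
      }
    }
  }
  do.call(rbind, out)
}

#' Hierarchically cluster estimate columns by correlation
#'
#' Computes the Pearson correlation matrix of the supplied estimate
#' columns, converts it to the distance `1 - r`, and clusters with
#' average linkage (configurable). The leaf order is deterministic given
#' the column order: ties merge lower column indices first.
#'
#' @param all_estimates Samples x estimate-columns numeric matrix (>= 3
#'   columns, e.g. method x cell-type columns from several estimators).
#' @param linkage Agglomeration method passed to [stats::hclust()].
#' @return List with `hclust` (the merge tree), `correlation` (the
#'   correlation matrix), `order` and `labels`.
#' @export
correlation_cluster <- function(all_estimates, linkage = "average") {
  check_matrix(all_estimates, "all_estimates")
  if (ncol(all_estimates) < 3) cw_stop("need >= 3 estimate columns")
  const <- apply(all_estimates, 2, var) == 0
  if (any(const)) {
    cw_stop("constant estimate column(s): ",
            paste(colnames(all_estimates)[const], collapse = ", "))
  }
  r <- cor(all_estimates)
  hc <- hclust(as.dist(1 - r), method = linkage)
  list(hclust = hc, correlation = r, order = hc$order,
       labels = hc$labels[hc$order])
}

#' Associate covariates and estimates with principal components
#'
#' Runs PCA on the (optionally standardized) feature matrix and, for
#' each of the first `n_pcs` components, fits one linear model of the PC
#' scores on all supplied variables jointly, reporting the p-value of
#' every variable's coefficient (categorical variables are expanded to
#' indicator columns). Collinear columns are dropped with a warning and
#' recorded in the output.
#'
#' @param data Features x samples matrix.
#' @param variables `data.frame` of covariates/estimates, rows aligned
#'   with the samples.
#' @param n_pcs Number of leading components to test.
#' @param standardize Scale features to unit variance before PCA.
#' @return List with `p_values` (variables x PCs matrix),
#'   `var_explained` (per-PC fraction), `scores` (samples x PCs) and
#'   `dropped` (collinear columns removed).
#' @export
pc_covariate_association <- function(data, variables, n_pcs = 5,
                                     standardize = TRUE) {
  check_matrix(data, "data")
  stopifnot(nrow(variables) == ncol(data))
  v <- apply(data, 1, var)
  x <- data[v > 0, , drop = FALSE]
  xs <- t(scale(t(x), center = TRUE, scale = standardize))
  pc <- prcomp(t(xs), center = FALSE)
  n_pcs <- min(n_pcs, ncol(pc$x))
  scores <- pc$x[, seq_len(n_pcs), drop = FALSE]
  varexp <- pc$sdev^2 / sum(pc$sdev^2)

  X <- model.matrix(~ ., data = as.data.frame(variables))
  X <- X[, -1, drop = FALSE] # intercept added back by lm
  qrX <- qr(cbind(1, X))
  dropped <- character()
  if (qrX$rank < ncol(X) + 1) {
    bad <- qrX$pivot[(qrX$rank + 1):(ncol(X) + 1)] - 1
    bad <- bad[bad > 0]
    dropped <- colnames(X)[bad]
    warning("dropping collinear variable column(s): ",
            paste(dropped, collapse = ", "))
    X <- X[, setdiff(colnames(X), dropped), drop = FALSE]
  }
  pmat <- matrix(NA_real_, ncol(X), n_pcs,
                 dimnames = list(colnames(X), colnames(scores)))
  dat <- as.data.frame(X, check.names = FALSE)
  for (j in seq_len(n_pcs)) {
    fit <- lm(scores[, j] ~ ., data = dat)
    # lm mangles column names through make.names; align positionally
    cf <- summary(fit)$coefficients[-1, , drop = FALSE]
    pmat[seq_len(nrow(cf)), j] <- cf[, 4]
  }
  list(p_values = pmat, var_explained = varexp[seq_len(n_pcs)],
       scores = scores, dropped = dropped)
}
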