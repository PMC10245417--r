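#' Negative-binomial differential test between two groups of count samples
#'
#' Per-feature Wald test on the group coefficient of a log-link negative
#' binomial GLM with library-size offset. The dispersion of each feature
#' is estimated by method of moments from the Pearson residuals of a
#' Poisson fit (`phi = sum((y - mu)^2 - mu) / sum(mu^2)`, floored at
#' 1e-8), then held fixed for the NB fit. Reported are the log2 fold
#' change of group level 2 vs level 1, the raw mean count, the Wald
#' p-value and Benjamini-Hochberg FDR.
#'
#' Constant covariate columns are dropped with a warning; a design in
#' which the group is collinear with covariates raises a singular-design
#' error naming the offending columns.
#'
#' @param counts Nonnegative integer matrix, features x samples.
#' @param group Two-level factor over samples; the test contrasts level 2
#'   vs level 1.
#' @param covariates Optional data.frame of nuisance covariates (numeric,
#'   factor or ordered factor), rows aligned with samples.
#' @param offset `"libsize"` (default, log column totals) or `"none"`.
#' @return `data.frame` (class `da_result`) with `feature_id`, `log2fc`,
#'   `mean_count`, `p_value`, `fdr`; the realized design matrix is
#'   attached as attribute `design`.
#' @export
call_differential <- function(counts, group, covariates = NULL,
                              offset = c("libsize", "none")) {
  offset <- match.arg(offset)
  check_matrix(counts, "counts")
  if (!is_count_matrix(counts)) {
    cw_stop("counts must be nonnegative integers")
  }
  group <- as.factor(group)
  if (nlevels(group) != 2 || any(table(group) < 2)) {
    cw_stop("group must have two levels with >= 2 samples each")
  }
  X <- build_design(group, covariates)
  o <- if (offset == "libsize") log(colSums(counts)) else rep(0, ncol(counts))
  if (any(!is.finite(o))) cw_stop("zero-library sample in counts")

  res <- nb_wald_fit(counts, X, o, test_col = attr(X, "group_col"))
  out <- data.frame(feature_id = rownames(counts),
                    log2fc = res$log2fc,
                    mean_count = rowMeans(counts),
                    p_value = res$p,
                    fdr = p.adjust(res$p, "BH"),
                    stringsAsFactors = FALSE)
  rownames(out) <- NULL
  class(out) <- c("da_result", "data.frame")
  attr(out, "design") <- X
  out
}

# design matrix with the group indicator last; drops constant covariates,
# errors on collinearity naming the aliased columns
build_design <- function(group, covariates) {
  df <- data.frame(row.names = seq_along(group))
  if (!is.null(covariates)) {
    covariates <- as.data.frame(covariates)
    keep <- vapply(covariates, function(v) length(unique(v)) > 1, logical(1))
    if (any(!keep)) {
      warning("dropping constant covariate(s): ",
              paste(names(covariates)[!keep], collapse = ", "))
      covariates <- covariates[, keep, drop = FALSE]
    }
    if (ncol(covariates)) df <- cbind(df, covariates)
  }
  df$.group <- group
  X <- model.matrix(~ ., data = df)
  qrX <- qr(X)
  if (qrX$rank < ncol(X)) {
    aliased <- colnames(X)[qrX$pivot[(qrX$rank + 1):ncol(X)]]
    cw_stop("singular design; aliased columns: ",
            paste(aliased, collapse = ", "),
            class = "cellwise_singular_design_error")
  }
  attr(X, "group_col") <- grep("^\\.group", colnames(X))
  X
}

# per-feature NB Wald machinery shared by the DA entry points.
# dispersion: method of moments on Poisson-fit residuals with a residual-df
# correction (without it phi is biased low by (n - p)/n and the test runs
# anticonservative); reference distribution: t with n - p df rather than
# normal, the usual small-sample guard for Wald tests with estimated
# dispersion.
nb_wald_fit <- function(counts, X, o, test_col) {
  nfeat <- nrow(counts)
  n <- ncol(counts)
  pdim <- ncol(X)
  dfres <- max(n - pdim, 1)
  log2fc <- numeric(nfeat)
  p <- rep(1, nfeat)
  for (i in seq_len(nfeat)) {
    y <- counts[i, ]
    if (all(y == 0)) next
    fit0 <- tryCatch(
      suppressWarnings(glm.fit(X, y, family = poisson(), offset = o)),
      error = function(e) NULL)
    if (is.null(fit0)) next
    mu <- pmax(fit0$fitted.values, 1e-8)
    phi <- max((sum((y - mu)^2) * n / dfres - sum(mu)) / sum(mu^2), 1e-8)
    fam <- MASS::negative.binomial(theta = 1 / phi)
    fit <- tryCatch(
      suppressWarnings(glm.fit(X, y, family = fam, offset = o,
                               start = fit0$coefficients)),
      error = function(e) NULL)
    if (is.null(fit) || !fit$converged) fit <- fit0
    b <- fit$coefficients[test_col]
    R <- qr.R(fit$qr)
    se <- tryCatch(sqrt(diag(chol2inv(R))[test_col]), error = function(e) NA)
    log2fc[i] <- b / log(2)
    if (is.finite(se) && se > 0) {
      p[i] <- 2 * stats::pt(-abs(b / se), df = dfres)
    }
  }
  list(log2fc = log2fc, p = p)
}

#' Select differential acetylated regions by effect size and abundance
#'
#' Keeps features with absolute fold change strictly above `fc_fold` and
#' mean count strictly above `min_mean` (both inequalities strict), split
#' by the sign of the fold change.
#'
#' @param da A `da_result` from [call_differential()].
#' @param fc_fold Fold-change threshold on the natural (not log) scale.
#' @param min_mean Mean-count threshold.
#' @return List with `up` (group-2-up feature ids) and `down`.
#' @export
filter_dars <- function(da, fc_fold = 4, min_mean = 1000) {
  stopifnot(inherits(da, "da_result") || is.data.frame(da))
  lcut <- log2(fc_fold)
  ok <- da$mean_count > min_mean
  list(up = da$feature_id[ok & da$log2fc > lcut],
       down = da$feature_id[ok & da$log2fc < -lcut])
}

#' Annotate peaks to genes via promoter-proximal windows
#'
#' A peak is assigned to every gene whose window — from `upstream` bases
#' upstream of the TSS to the end of the 5'UTR, reflected on the minus
#' strand — it overlaps by at least one base. Coordinates are 0-based
#' half-open throughout; window starts pushed below zero are clamped to 0
#' with a log record. With `strand_aware = FALSE` the window spans the
#' gene's TSS-to-5'UTR extent plus `upstream` on both sides.
#'
#' @param peaks `data.frame` with `peak_id`, `chrom`, `start`, `end`
#'   (0-based half-open) or a named `GRanges`.
#' @param genes `data.frame` with `gene_id`, `chrom`, `strand`, `tss`,
#'   `utr5_end` (0-based).
#' @param upstream Window extension upstream of the TSS, in bases.
#' @param strand_aware Reflect the window on minus-strand genes.
#' @return `data.frame` with `peak_id`, `gene_id` (many-to-many); peaks
#'   with no overlapping window are absent.
#' @export
annotate_peaks <- function(peaks, genes, upstream = 5000L,
                           strand_aware = TRUE) {
  if (inherits(peaks, "GRanges")) {
    peaks <- data.frame(peak_id = names(peaks),
                        chrom = as.character(GenomicRanges::seqnames(peaks)),
                        start = GenomicRanges::start(peaks) - 1L,
                        end = GenomicRanges::end(peaks),
                        stringsAsFactors = FALSE)
  }
  stopifnot(all(c("gene_id", "chrom", "strand", "tss", "utr5_end") %in%
                  names(genes)))
  if (strand_aware) {
    ws <- ifelse(genes$strand == "+", genes$tss - upstream, genes$utr5_end)
    we <- ifelse(genes$strand == "+", genes$utr5_end, genes$tss + upstream)
  } else {
    lo <- pmin(genes$tss, genes$utr5_end)
    hi <- pmax(genes$tss, genes$utr5_end)
    ws <- lo - upstream
    we <- hi + upstream
  }
  if (any(ws < 0)) {
    cw_log("clamping ", sum(ws < 0), " gene window(s) at coordinate 0")
    ws <- pmax(ws, 0)
  }
  win <- GenomicRanges::GRanges(genes$chrom,
                                IRanges::IRanges(ws + 1L, we))
  pk <- intervals_to_granges(peaks)
  hits <- GenomicRanges::findOverlaps(pk, win, minoverlap = 1L)
  data.frame(peak_id = peaks$peak_id[S4Vectors::queryHits(hits)],
             gene_id = genes$gene_id[S4Vectors::subjectHits(hits)],
             stringsAsFactors = FALSE)
}

#' Reassign differential acetylated regions to specific cell types
#'
#' A DAR becomes a marker site of cell type K iff every gene it is
#' annotated to is an expression marker of K and its direction is
#' concordant: neuronal types require neuron-up DARs, non-neuronal types
#' require glia-up (neuron-down) DARs. DARs touching markers of more than
#' one cell type, any non-marker gene, or no gene at all are dropped, so
#' the resulting marker sets are mutually exclusive.
#'
#' @param dar_ids List with `up` (neuron-hyperacetylated peak ids) and
#'   `down` (glia-hyperacetylated), as from [filter_dars()] of a
#'   glia-vs-neuron contrast with neuron as level 2.
#' @param peak_gene_map `data.frame` `peak_id`/`gene_id` from
#'   [annotate_peaks()].
#' @param expression_markers Named list, cell type -> marker gene ids;
#'   must be mutually exclusive.
#' @param neuronal_types Cell types whose markers require neuron-up DARs.
#' @return Named list, cell type -> marker peak ids (h3k27ac modality).
#' @export
assign_marker_sites <- function(dar_ids, peak_gene_map, expression_markers,
                                neuronal_types = "neuron") {
  all_marker_genes <- unlist(expression_markers, use.names = FALSE)
  if (anyDuplicated(all_marker_genes)) {
    cw_stop("expression_markers must be mutually exclusive across cell types")
  }
  gene_type <- rep(names(expression_markers),
                   lengths(expression_markers))
  names(gene_type) <- all_marker_genes

  out <- setNames(vector("list", length(expression_markers)),
                  names(expression_markers))
  for (dir in c("up", "down")) {
    for (peak in dar_ids[[dir]]) {
      genes <- peak_gene_map$gene_id[peak_gene_map$peak_id == peak]
      if (length(genes) == 0) next
      types <- gene_type[genes]
      if (anyNA(types)) next            # touches a non-marker gene
      types <- unique(unname(types))
      if (length(types) != 1) next      # ambiguous across cell types
      k <- types
      concordant <- if (k %in% neuronal_types) dir == "up" else dir == "down"
      if (!concordant) next
      out[[k]] <- c(out[[k]], peak)
    }
  }
  out
}

#' Filter cell-assigned methylation marks by assignment and coverage
#'
#' Drops sites assigned to more than one cell type and sites whose
#' coverage falls below `min_cov` in strictly more than `max_low_frac` of
#' the samples.
#'
#' @param marks `data.frame` with `site_id` and `cell_type`.
#' @param coverage Sites x samples coverage matrix (rownames are site
#'   ids; sites absent from it are treated as uncovered everywhere).
#' @param min_cov Minimum acceptable per-sample coverage.
#' @param max_low_frac Maximum tolerated fraction of low-coverage samples
#'   (strict: a site low in exactly this fraction is retained).
#' @return The filtered `marks` table.
#' @export
filter_methylation_marks <- function(marks, coverage, min_cov = 10,
                                     max_low_frac = 0.2) {
  stopifnot(all(c("site_id", "cell_type") %in% names(marks)))
  multi <- unique(marks$site_id[duplicated(marks$site_id)])
  keep <- !(marks$site_id %in% multi)
  idx <- match(marks$site_id, rownames(coverage))
  low_frac <- rep(1, nrow(marks))
  has <- !is.na(idx)
  if (any(has)) {
    low_frac[has] <- rowMeans(coverage[idx[has], , drop = FALSE] < min_cov)
  }
  marks[keep & low_frac <= max_low_frac, , drop = FALSE]
}
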