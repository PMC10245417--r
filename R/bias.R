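#' Classify significant case-control peaks by a cell-type reference contrast
#'
#' Takes a case-control differential result and a reference differential
#' result contrasting two cell populations (e.g. neurons vs glia, with
#' positive log2 fold change meaning up in the first population). Among
#' the FDR-significant case peaks of each direction (hypo- and
#' hyperacetylated in cases), reports how many fall in each reference
#' class: up in population 1 (`cell1_up`), up in population 2
#' (`cell2_up`), or not reference-specific. Reference specificity
#' requires adjusted p below `fdr_cut` and, when `require_lfc` is given,
#' absolute log2 fold change strictly above it. Under composition
#' confounding (e.g. neuronal loss in cases) most hypo-in-case peaks are
#' expected in the `cell1_up` class.
#'
#' @param case_da `da_result` of the case-control contrast.
#' @param reference_da `da_result` of the cell-population contrast on
#'   shared peak ids.
#' @param fdr_cut FDR threshold for both results.
#' @param require_lfc Reference absolute log2 fold-change requirement.
#' @param cell_labels Length-2 labels for the reference populations
#'   (population 1 = positive reference log2 fold change).
#' @return `data.frame` (class `overlap_summary`) with `direction`,
#'   `region_class`, `count`, `fraction`, `denominator`; fractions within
#'   a direction sum to 1, and are `NA` when the direction has no
#'   significant peaks.
#' @export
classify_by_reference_da <- function(case_da, reference_da, fdr_cut = 0.05,
                                     require_lfc = 3,
                                     cell_labels = c("neuron", "glia")) {
  shared <- intersect(case_da$feature_id, reference_da$feature_id)
  if (length(shared) == 0) cw_stop("no shared peak ids")
  ca <- case_da[match(shared, case_da$feature_id), ]
  re <- reference_da[match(shared, reference_da$feature_id), ]
  specific <- re$fdr < fdr_cut &
    (if (is.null(require_lfc)) TRUE else abs(re$log2fc) > require_lfc)
  ref_class <- ifelse(!specific, "not_specific",
                      ifelse(re$log2fc > 0,
                             paste0(cell_labels[1], "_up"),
                             paste0(cell_labels[2], "_up")))
  classes <- c(paste0(cell_labels[1], "_up"),
               paste0(cell_labels[2], "_up"), "not_specific")
  out <- list()
  for (dir in c("hypo_in_case", "hyper_in_case")) {
    sig <- ca$fdr < fdr_cut &
      (if (dir == "hypo_in_case") ca$log2fc < 0 else ca$log2fc > 0)
    denom <- sum(sig)
    for (cl in classes) {
      cnt <- sum(sig & ref_class == cl)
      out[[length(out) + 1]] <- data.frame(
        direction = dir, region_class = cl, count = cnt,
        fraction = if (denom > 0) cnt / denom else NA_real_,
        denominator = denom, stringsAsFactors = FALSE)
    }
  }
  res <- do.call(rbind, out)
  class(res) <- c("overlap_summary", "data.frame")
  res
}

#' Uniquely label peaks by overlap with cell-type-specific region sets
#'
#' A peak receives cell type K's label iff it overlaps at least
#' `min_overlap` positions of K's region set and of no other set; peaks
#' overlapping several sets are `ambiguous`, peaks overlapping none are
#' `none`. Multiple overlaps within one set count once. Coordinates are
#' 0-based half-open.
#'
#' @param peaks `data.frame` (`peak_id`, `chrom`, `start`, `end`) or
#'   named `GRanges`.
#' @param region_sets Named list of region sets (same formats), one per
#'   cell type.
#' @param min_overlap Minimum overlapping positions.
#' @return Named character vector: peak id -> cell-type label,
#'   `"ambiguous"` or `"none"`.
#' @export
overlap_with_region_sets <- function(peaks, region_sets, min_overlap = 1L) {
  as_gr <- function(x) {
    if (inherits(x, "GRanges")) return(x)
    intervals_to_granges(x)
  }
  pk <- as_gr(peaks)
  if (is.null(names(pk))) cw_stop("peaks must carry ids")
  labels <- setNames(rep("none", length(pk)), names(pk))
  hit_count <- setNames(integer(length(pk)), names(pk))
  for (k in names(region_sets)) {
    hits <- GenomicRanges::findOverlaps(pk, as_gr(region_sets[[k]]),
                                        minoverlap = min_overlap)
    touched <- unique(S4Vectors::queryHits(hits))
    labels[touched][labels[touched] == "none"] <- k
    hit_count[touched] <- hit_count[touched] + 1L
  }
  labels[hit_count > 1] <- "ambiguous"
  labels
}

#' Correlation between case-control and cell-type reference effect sizes
#'
#' Pearson correlation between the two log2 fold-change vectors over
#' shared peaks, on all peaks or restricted to case-significant ones.
#' A strong negative correlation with a neuron-vs-glia reference is the
#' signature of unadjusted composition confounding.
#'
#' @param case_da,reference_da `da_result` tables with shared peak ids.
#' @param subset `"all"` or `"significant"` (case FDR < `fdr_cut`).
#' @param fdr_cut Significance cut for the `"significant"` subset.
#' @return One-row `data.frame`: `subset`, `r`, `n`; `r` is `NA` when
#'   fewer than 3 peaks remain or a vector is constant.
#' @export
effect_size_correlation <- function(case_da, reference_da,
                                    subset = c("all", "significant"),
                                    fdr_cut = 0.05) {
  subset <- match.arg(subset)
  shared <- intersect(case_da$feature_id, reference_da$feature_id)
  ca <- case_da[match(shared, case_da$feature_id), ]
  re <- reference_da[match(shared, reference_da$feature_id), ]
  keep <- if (subset == "significant") ca$fdr < fdr_cut else rep(TRUE, nrow(ca))
  x <- ca$log2fc[keep]
  y <- re$log2fc[keep]
  r <- if (length(x) < 3 || var(x) == 0 || var(y) == 0) NA_real_ else cor(x, y)
  data.frame(subset = subset, r = r, n = length(x),
             stringsAsFactors = FALSE)
}

#' Directional overlap of significant peaks with a focal cell type's regions
#'
#' Among FDR-significant case-control peaks that carry any unique
#' cell-type region label, reports per direction (hypo/hyper in cases)
#' the count and fraction labelled with `focal_type`. The denominator is
#' the number of significant peaks in that direction with a unique label
#' (ambiguous and unlabelled peaks are excluded).
#'
#' @param case_da `da_result` of the case-control contrast.
#' @param labels Peak labels from [overlap_with_region_sets()].
#' @param focal_type Cell-type label of interest.
#' @param fdr_cut Significance threshold.
#' @return `data.frame` with `direction`, `count`, `fraction`,
#'   `denominator`; fraction is `NA` for an empty denominator.
#' @export
direction_vs_annotation <- function(case_da, labels, focal_type = "neuron",
                                    fdr_cut = 0.05) {
  lab <- labels[match(case_da$feature_id, names(labels))]
  unique_lab <- !is.na(lab) & !(lab %in% c("none", "ambiguous"))
  out <- list()
  for (dir in c("hypo_in_case", "hyper_in_case")) {
    sig <- case_da$fdr < fdr_cut &
      (if (dir == "hypo_in_case") case_da$log2fc < 0 else case_da$log2fc > 0)
    denom <- sum(sig & unique_lab)
    cnt <- sum(sig & unique_lab & lab == focal_type)
    out[[length(out) + 1]] <- data.frame(
      direction = dir, count = cnt,
      fraction = if (denom > 0) cnt / denom else NA_real_,
      denominator = denom, stringsAsFactors = FALSE)
  }
  do.call(rbind, out)
}
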