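#' Build a synthetic cell-type reference panel for three omics modalities
#'
#' Constructs the per-cell-type mean signals the simulator mixes:
#' expression signal per gene, H3K27ac signal per peak, and methylation
#' beta per CpG site, for the five brain cell types, together with gene
#' models and peak coordinates on synthetic chromosomes. Marker features
#' are built in by construction: a marker gene/peak carries at least
#' `marker_fold` times the maximum signal of the other cell types, and a
#' marker methylation site is hypomethylated in its cell type (beta 0.1
#' vs 0.85 elsewhere, a difference well above the 0.5 neuron-glia
#' separation required of methylation marks). Marker peaks are placed
#' inside the promoter-proximal window of marker genes of the same cell
#' type so that peak annotation recovers the expression-marker link;
#' background peaks are intergenic.
#'
#' @param n_genes Total genes (markers included).
#' @param n_peaks Total H3K27ac peaks.
#' @param n_meth_sites Total methylation sites.
#' @param expr_markers_per_type Marker genes per cell type.
#' @param peak_markers Named integer vector of marker peaks per cell type;
#'   neuron-specific peaks dominate H3K27ac landscapes, so the default
#'   gives neurons the largest share. Every marker peak is hosted by a
#'   marker gene of the same type, so values must not exceed
#'   `expr_markers_per_type`.
#' @param meth_markers_per_type Marker methylation sites per cell type.
#' @param marker_fold Minimum fold by which a marker feature's signal in
#'   its cell type exceeds the maximum across the other types.
#' @param background_sd Log-scale SD of mild cross-cell-type variation of
#'   non-marker features.
#' @param marker_offtarget Multiplier applied to a marker feature's signal
#'   in the non-marked cell types (markers are near-silent off target).
#' @param seed Integer seed.
#'
#' @return A `reference_panel` list: `genes` (gene models, 0-based
#'   coordinates), `expression` and `h3k27ac` (feature x cell-type signal
#'   matrices, each cell-type column normalized to unit total so signals
#'   read as expected counts at unit library size), `methylation` (site x
#'   cell-type beta), `peaks` (0-based half-open intervals),
#'   `expr_markers` / `peak_markers` / `meth_markers` (cell type ->
#'   feature ids), and `params`.
#' @export
build_reference_panel <- function(n_genes = 500,
                                  n_peaks = 600,
                                  n_meth_sites = 150,
                                  expr_markers_per_type = 80,
                                  peak_markers = c(neuron = 80, astrocyte = 30,
                                                   microglia = 30,
                                                   oligodendrocyte = 30,
                                                   endothelial = 30),
                                  meth_markers_per_type = 20,
                                  marker_fold = 8,
                                  background_sd = 0.1,
                                  marker_offtarget = 0.1,
                                  seed = 1L) {
  ct <- cell_types()
  stopifnot(marker_fold > 1, n_genes > length(ct) * expr_markers_per_type)
  peak_markers <- peak_markers[ct]
  if (any(is.na(peak_markers)) || any(peak_markers > expr_markers_per_type)) {
    cw_stop("peak_markers must name every cell type and not exceed ",
            "expr_markers_per_type", class = "cellwise_parameter_error")
  }
  if (n_peaks <= sum(peak_markers)) {
    cw_stop("n_peaks must exceed the total marker peak count",
            class = "cellwise_parameter_error")
  }
  set.seed(as.integer(seed))

  ## --- gene models on synthetic chromosomes -------------------------------
  gene_id <- sprintf("gene%04d", seq_len(n_genes))
  chrom <- paste0("chr", (seq_len(n_genes) - 1) %% 5 + 1)
  idx_on_chrom <- ceiling(seq_len(n_genes) / 5)
  tss <- idx_on_chrom * 20000L
  strand <- rep_len(c("+", "-"), n_genes)
  utr5_end <- ifelse(strand == "+", tss + 300L, tss - 300L)
  genes <- data.frame(gene_id, chrom, strand, tss, utr5_end,
                      stringsAsFactors = FALSE)

  # first 5 * expr_markers_per_type genes are the marker genes
  marker_type <- rep(ct, each = expr_markers_per_type)
  expr_markers <- split(gene_id[seq_along(marker_type)], marker_type)[ct]

  ## --- expression signal --------------------------------------------------
  offtarget <- marker_offtarget
  signal_matrix <- function(ids, marker_sets) {
    n <- length(ids)
    base <- exp(rnorm(n, 0, 1))
    m <- base * matrix(exp(rnorm(n * length(ct), 0, background_sd)),
                       n, length(ct))
    dimnames(m) <- list(ids, ct)
    for (k in ct) {
      mk <- marker_sets[[k]]
      if (length(mk) == 0) next
      i <- match(mk, ids)
      others <- setdiff(ct, k)
      # cell-type-specific enhancers/genes are close to silent outside
      # their cell type, not merely somewhat lower
      m[i, others] <- m[i, others] * offtarget
      top <- apply(m[i, others, drop = FALSE], 1, max)
      # enrichment spans 2x-30x the guaranteed floor: curated markers of
      # rare cell types are typically tens-to-hundreds-fold specific,
      # which is what keeps them callable from sorted-population bulk
      m[i, k] <- top * marker_fold * runif(length(i), 2, 30)
    }
    sweep(m, 2, colSums(m), "/") # unit library size per cell type
  }
  expression <- signal_matrix(gene_id, expr_markers)

  ## --- peaks: markers inside marker-gene promoter windows, rest intergenic
  peak_rows <- list()
  peak_markers_ids <- setNames(vector("list", length(ct)), ct)
  pk <- 0L
  for (k in ct) {
    host <- genes[match(expr_markers[[k]][seq_len(peak_markers[[k]])],
                        genes$gene_id), ]
    for (j in seq_len(nrow(host))) {
      pk <- pk + 1L
      id <- sprintf("peak%04d", pk)
      if (host$strand[j] == "+") {
        s <- host$tss[j] + 50L
      } else {
        s <- host$tss[j] - 550L
      }
      peak_rows[[pk]] <- data.frame(peak_id = id, chrom = host$chrom[j],
                                    start = s, end = s + 500L,
                                    stringsAsFactors = FALSE)
      peak_markers_ids[[k]] <- c(peak_markers_ids[[k]], id)
    }
  }
  n_bg <- n_peaks - pk
  # intergenic slots: offsets past the promoter window, before the next gene
  slot <- 0L
  gslot <- 0L
  for (b in seq_len(n_bg)) {
    pk <- pk + 1L
    gslot <- gslot + 1L
    if (gslot > n_genes) {
      gslot <- 1L
      slot <- slot + 1L
    }
    g <- genes[gslot, ]
    s <- g$tss + 8000L + slot * 1000L
    peak_rows[[pk]] <- data.frame(peak_id = sprintf("peak%04d", pk),
                                  chrom = g$chrom, start = s, end = s + 500L,
                                  stringsAsFactors = FALSE)
  }
  peaks <- do.call(rbind, peak_rows)
  h3k27ac <- signal_matrix(peaks$peak_id, peak_markers_ids)

  ## --- methylation --------------------------------------------------------
  site_id <- sprintf("cpg%04d", seq_len(n_meth_sites))
  n_mk <- meth_markers_per_type * length(ct)
  stopifnot(n_meth_sites > n_mk)
  meth_type <- rep(ct, each = meth_markers_per_type)
  meth_markers <- data.frame(site_id = site_id[seq_len(n_mk)],
                             cell_type = meth_type,
                             stringsAsFactors = FALSE)
  beta <- matrix(NA_real_, n_meth_sites, length(ct),
                 dimnames = list(site_id, ct))
  beta[seq_len(n_mk), ] <- 0.85
  for (r in seq_len(n_mk)) beta[r, meth_type[r]] <- 0.10
  bg <- runif(n_meth_sites - n_mk, 0.3, 0.8)
  beta[(n_mk + 1):n_meth_sites, ] <-
    pmin(pmax(bg + matrix(rnorm((n_meth_sites - n_mk) * length(ct), 0, 0.03),
                          ncol = length(ct)), 0), 1)

  structure(list(
    genes = genes,
    expression = expression,
    expr_markers = expr_markers,
    peaks = peaks,
    h3k27ac = h3k27ac,
    peak_markers = peak_markers_ids,
    methylation = beta,
    meth_markers = meth_markers,
    params = list(n_genes = n_genes, n_peaks = n_peaks,
                  n_meth_sites = n_meth_sites,
                  expr_markers_per_type = expr_markers_per_type,
                  peak_markers = peak_markers,
                  meth_markers_per_type = meth_markers_per_type,
                  marker_fold = marker_fold, background_sd = background_sd,
                  marker_offtarget = marker_offtarget, seed = seed)
  ), class = "reference_panel")
}

#' Cell-type-specific genomic region sets derived from a panel
#'
#' Returns, per cell type, the intervals of that type's marker peaks
#' extended by `flank` on both sides — the synthetic analogue of
#' cell-type-specific enhancer/promoter region sets used to audit
#' differential results for composition bias.
#'
#' @param panel A [build_reference_panel()] object.
#' @param flank Bases added on each side of a marker peak.
#' @return Named list of `GRanges`, one per cell type.
#' @export
panel_region_sets <- function(panel, flank = 200L) {
  stopifnot(inherits(panel, "reference_panel"))
  lapply(panel$peak_markers, function(ids) {
    df <- panel$peaks[match(ids, panel$peaks$peak_id), ]
    df$start <- pmax(df$start - flank, 0L)
    df$end <- df$end + flank
    intervals_to_granges(df)
  })
}

#' Flatten a reference panel to a long feature table
#'
#' One row per modality, feature and cell type, with the mean signal and
#' a marker flag — the serialization format for panel truth tables.
#'
#' @param panel A [build_reference_panel()] object.
#' @return `data.frame` with columns `modality`, `feature_id`,
#'   `cell_type`, `signal`, `is_marker`.
#' @export
as_panel_table <- function(panel) {
  stopifnot(inherits(panel, "reference_panel"))
  ct <- cell_types()
  flat <- function(m, modality, markers) {
    marker_of <- rep(NA_character_, nrow(m))
    if (is.data.frame(markers)) {
      marker_of[match(markers$site_id, rownames(m))] <- markers$cell_type
    } else {
      for (k in names(markers)) marker_of[match(markers[[k]], rownames(m))] <- k
    }
    do.call(rbind, lapply(ct, function(k) {
      data.frame(modality = modality, feature_id = rownames(m), cell_type = k,
                 signal = m[, k],
                 is_marker = !is.na(marker_of) & marker_of == k,
                 stringsAsFactors = FALSE, row.names = NULL)
    }))
  }
  rbind(
    flat(panel$expression, "expression", panel$expr_markers),
    flat(panel$h3k27ac, "h3k27ac", panel$peak_markers),
    flat(panel$methylation, "methylation", panel$meth_markers)
  )
}
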