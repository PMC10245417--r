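# shared fixtures: everything is generated in code at test time

# a small but complete reference panel for fast module tests
tiny_panel <- function(seed = 1L) {
  build_reference_panel(
    n_genes = 120, n_peaks = 150, n_meth_sites = 60,
    expr_markers_per_type = 12,
    peak_markers = c(neuron = 8, astrocyte = 6, microglia = 6,
                     oligodendrocyte = 6, endothelial = 6),
    meth_markers_per_type = 8,
    seed = seed)
}

# hand-built composition table (bypasses the Dirichlet draw) so tests can
# pin exact proportions; `props` is samples x 5 cell types, rows sum to 1
manual_composition <- function(props, p_whole = props) {
  ct <- cell_types()
  stopifnot(ncol(props) == length(ct))
  n <- nrow(props)
  ids <- sprintf("s%02d", seq_len(n))
  out <- do.call(rbind, lapply(seq_len(n), function(i) {
    data.frame(sample_id = ids[i], individual_id = ids[i],
               tissue_sample = "TS1", condition = "control",
               cell_type = ct, p_nuclear = props[i, ],
               p_whole = p_whole[i, ], stringsAsFactors = FALSE)
  }))
  rownames(out) <- NULL
  class(out) <- c("true_composition", "data.frame")
  out
}

# brute-force interval overlap oracle on 0-based half-open intervals
bf_overlap <- function(s1, e1, s2, e2, min_overlap = 1L) {
  ov <- pmin(e1, e2) - pmax(s1, s2)
  ov >= min_overlap
}

# brute-force peak -> gene annotation oracle (strand-aware windows)
bf_annotate <- function(peaks, genes, upstream = 5000L) {
  hits <- list()
  for (i in seq_len(nrow(peaks))) {
    for (j in seq_len(nrow(genes))) {
      if (peaks$chrom[i] != genes$chrom[j]) next
      if (genes$strand[j] == "+") {
        ws <- max(genes$tss[j] - upstream, 0)
        we <- genes$utr5_end[j]
      } else {
        ws <- max(genes$utr5_end[j], 0)
        we <- genes$tss[j] + upstream
      }
      if (bf_overlap(peaks$start[i], peaks$end[i], ws, we)) {
        hits[[length(hits) + 1]] <- data.frame(
          peak_id = peaks$peak_id[i], gene_id = genes$gene_id[j],
          stringsAsFactors = FALSE)
      }
    }
  }
  if (!length(hits)) {
    return(data.frame(peak_id = character(), gene_id = character()))
  }
  do.call(rbind, hits)
}

# random interval instance on a handful of chromosomes
random_intervals <- function(n, prefix, width_max = 800L) {
  data.frame(
    peak_id = sprintf("%s%03d", prefix, seq_len(n)),
    chrom = sample(paste0("chr", 1:3), n, replace = TRUE),
    start = s <- sample.int(50000L, n, replace = TRUE),
    end = s + sample.int(width_max, n, replace = TRUE),
    stringsAsFactors = FALSE)
}
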