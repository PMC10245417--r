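#' Draw ground-truth cell compositions for a two-tissue-sample study design
#'
#' Generates per-individual cell-type proportions for two adjacent tissue
#' samples (TS1 and TS2) of each individual, in both their nuclear and
#' whole-tissue variants. TS1 proportions are Dirichlet draws; a case-only
#' shift on the log-ratio scale models disease-driven composition change
#' (e.g. neuronal loss); TS2 is TS1 perturbed by Gaussian noise on the
#' centered log-ratio scale, modelling dissection-level variation between
#' neighbouring samples. Whole-tissue proportions add a neuropil weight to
#' the neuron coordinate and renormalize: neuropil (dendrites, axons,
#' synapses) contributes neuron-attributed signal to whole-tissue
#' modalities but is invisible to nuclear modalities. The neuropil weight
#' varies mostly between individuals (log-normal), with a smaller
#' sample-level component, so adjacent samples of one individual share
#' their neuropil character.
#'
#' Randomness is consumed in a fixed stream order from a single seed:
#' (1) TS1 Dirichlet gammas per individual, (2) TS2 centered-log-ratio
#' noise, (3) individual-level neuropil weights, (4) sample-level neuropil
#' multipliers. Results are reproducible given `seed`.
#'
#' @param n_individuals Number of individuals; each contributes samples
#'   TS1 and TS2.
#' @param alpha Dirichlet concentration, one positive value per cell type
#'   (order of [cell_types()]). The default puts neurons and
#'   oligodendrocytes as the dominant classes, with a total concentration
#'   giving interindividual variability in line with immunohistochemistry
#'   (roughly 15 percent CV for neurons, 50 percent for the rare types).
#' @param adjacency_sd Standard deviation of the centered-log-ratio noise
#'   between adjacent tissue samples; 0 makes TS2 identical to TS1.
#' @param neuropil_weight Mean extra neuron-attributed signal mass in
#'   whole-tissue modalities; 0 makes whole-tissue equal nuclear.
#' @param neuropil_sd Log-scale SD of the individual-level neuropil weight.
#' @param neuropil_sample_sd Log-scale SD of the sample-level neuropil
#'   multiplier (TS1 vs TS2 of one individual).
#' @param condition_shift Per-cell-type shift applied on the log-ratio
#'   scale to case individuals only (e.g. `c(-0.7, 0, 0, 0, 0)` for severe
#'   neuronal loss).
#' @param case_fraction Fraction of individuals labelled `case`; assignment
#'   is deterministic (alternating) so group sizes are balanced.
#' @param seed Integer seed.
#'
#' @return A `data.frame` (class `true_composition`) with one row per
#'   sample and cell type: `sample_id`, `individual_id`, `tissue_sample`,
#'   `condition`, `cell_type`, `p_nuclear`, `p_whole`. Per sample both
#'   proportion vectors sum to 1.
#' @export
draw_compositions <- function(n_individuals,
                              alpha = c(neuron = 24, astrocyte = 12, microglia = 3,
                                        oligodendrocyte = 12, endothelial = 3),
                              adjacency_sd = 0.3,
                              neuropil_weight = 1.0,
                              neuropil_sd = 0.5,
                              neuropil_sample_sd = 0.15,
                              condition_shift = c(0, 0, 0, 0, 0),
                              case_fraction = 0.5,
                              seed = 1L) {
  ct <- cell_types()
  if (length(alpha) != length(ct) || any(!is.finite(alpha)) || any(alpha <= 0)) {
    cw_stop("alpha must be ", length(ct), " strictly positive values",
            class = "cellwise_parameter_error")
  }
  if (length(condition_shift) != length(ct)) {
    cw_stop("condition_shift must have one value per cell type",
            class = "cellwise_parameter_error")
  }
  stopifnot(n_individuals >= 1, adjacency_sd >= 0, neuropil_weight >= 0)

  set.seed(as.integer(seed))
  condition <- rep_len(c("control", "case"), n_individuals)
  n_case <- round(case_fraction * n_individuals)
  condition <- c(rep("control", n_individuals - n_case), rep("case", n_case))

  # stream 1: TS1 Dirichlet draws (with case shift on the log-ratio scale)
  p1 <- t(vapply(seq_len(n_individuals), function(i) {
    p <- rdirichlet1(alpha)
    if (condition[i] == "case" && any(condition_shift != 0)) {
      p <- clr_inv(clr(p) + condition_shift)
    }
    p
  }, numeric(length(ct))))

  # stream 2: TS2 = TS1 + clr noise
  p2 <- t(vapply(seq_len(n_individuals), function(i) {
    if (adjacency_sd == 0) return(p1[i, ])
    clr_inv(clr(p1[i, ]) + rnorm(length(ct), 0, adjacency_sd))
  }, numeric(length(ct))))

  # streams 3-4: neuropil weights (individual level, then sample level)
  w_ind <- neuropil_weight *
    exp(rnorm(n_individuals, -neuropil_sd^2 / 2, neuropil_sd))
  w_samp <- matrix(
    exp(rnorm(2 * n_individuals, -neuropil_sample_sd^2 / 2, neuropil_sample_sd)),
    nrow = n_individuals
  )

  add_neuropil <- function(p, w) {
    q <- p
    q[1] <- q[1] + w # neuron coordinate
    q / sum(q)
  }

  rows <- lapply(seq_len(n_individuals), function(i) {
    id <- sprintf("ind%03d", i)
    do.call(rbind, lapply(1:2, function(ts) {
      p <- if (ts == 1) p1[i, ] else p2[i, ]
      w <- w_ind[i] * w_samp[i, ts]
      pw <- add_neuropil(p, w)
      data.frame(
        sample_id = paste0(id, "_TS", ts),
        individual_id = id,
        tissue_sample = paste0("TS", ts),
        condition = condition[i],
        cell_type = ct,
        p_nuclear = p,
        p_whole = pw,
        stringsAsFactors = FALSE
      )
    }))
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  class(out) <- c("true_composition", "data.frame")
  out
}

#' Reshape a composition table to a samples x cell-types matrix
#'
#' @param comp A `true_composition` table from [draw_compositions()].
#' @param which `"nuclear"` or `"whole"`: which proportion variant.
#' @param samples Optional sample ids to keep (in that order).
#' @return Numeric matrix, samples in rows, cell types in columns.
#' @export
composition_matrix <- function(comp, which = c("nuclear", "whole"),
                               samples = NULL) {
  which <- match.arg(which)
  col <- if (which == "nuclear") "p_nuclear" else "p_whole"
  ids <- unique(comp$sample_id)
  if (!is.null(samples)) ids <- samples
  ct <- cell_types()
  m <- matrix(NA_real_, length(ids), length(ct),
              dimnames = list(ids, ct))
  for (k in ct) {
    sub <- comp[comp$cell_type == k, ]
    m[, k] <- sub[[col]][match(ids, sub$sample_id)]
  }
  m
}
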