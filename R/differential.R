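#' Specify a case-control differential model with a cell-composition adjustment
#'
#' Bundles the condition factor, nuisance covariates and one of four
#' cell-composition adjustment strategies into a model specification for
#' [fit_adjusted_da()]:
#' \describe{
#'   \item{none}{no composition term — [adjustment_none()].}
#'   \item{ordered_factor}{one estimate discretized into five ordered
#'     levels, the classic single-estimate adjustment —
#'     [adjustment_ordered()].}
#'   \item{continuous}{one or more estimates entered as continuous
#'     covariates — [adjustment_continuous()].}
#'   \item{shuffled}{the ordered-factor adjustment after permuting the
#'     estimate within condition groups, a negative control that keeps
#'     the covariate's marginal distribution but destroys its link to the
#'     samples — [adjustment_shuffled()].}
#' }
#'
#' @param condition Two-level factor (level 2 is the case group).
#' @param nuisance Optional data.frame of nuisance covariates; age bands
#'   should be ordered factors (orthogonal polynomial contrasts).
#' @param cell_adjustment One of the `adjustment_*()` objects.
#' @return A `model_spec` list.
#' @export
model_spec <- function(condition, nuisance = NULL,
                       cell_adjustment = adjustment_none()) {
  condition <- as.factor(condition)
  stopifnot(nlevels(condition) == 2,
            inherits(cell_adjustment, "cell_adjustment"))
  structure(list(condition = condition, nuisance = nuisance,
                 cell_adjustment = cell_adjustment),
            class = "model_spec")
}

#' @rdname model_spec
#' @export
adjustment_none <- function() {
  structure(list(type = "none"), class = "cell_adjustment")
}

#' @rdname model_spec
#' @param estimate Per-sample numeric estimate (e.g. one MSP column).
#' @param n_levels Levels of the ordered factor.
#' @export
adjustment_ordered <- function(estimate, n_levels = 5) {
  structure(list(type = "ordered_factor", estimate = estimate,
                 n_levels = n_levels), class = "cell_adjustment")
}

#' @rdname model_spec
#' @param estimates Data frame or matrix of per-sample estimates entered
#'   as continuous covariates.
#' @param transform `"identity"` or `"log"`; the log scale is the natural
#'   choice when the covariates are true proportions entering a log-link
#'   count model.
#' @export
adjustment_continuous <- function(estimates,
                                  transform = c("identity", "log")) {
  transform <- match.arg(transform)
  estimates <- as.data.frame(estimates)
  if (transform == "log") {
    if (any(estimates <= 0)) cw_stop("log transform needs positive estimates")
    estimates[] <- lapply(estimates, log)
  }
  structure(list(type = "continuous", estimates = estimates),
            class = "cell_adjustment")
}

#' @rdname model_spec
#' @param seed Seed for the within-group permutation.
#' @export
adjustment_shuffled <- function(estimate, seed = 1L, n_levels = 5) {
  structure(list(type = "shuffled", estimate = estimate, seed = seed,
                 n_levels = n_levels), class = "cell_adjustment")
}

#' Permute values within the levels of a grouping factor
#'
#' Applies an independent uniform random permutation inside each group
#' level, so the multiset of values per group is preserved but their
#' assignment to samples is destroyed. Deterministic given `seed`.
#'
#' @param values Per-sample numeric vector.
#' @param group Factor over the same samples.
#' @param seed Integer seed.
#' @return Permuted vector of the same length.
#' @export
shuffle_within_group <- function(values, group, seed = 1L) {
  stopifnot(length(values) == length(group))
  group <- as.factor(group)
  set.seed(as.integer(seed))
  out <- values
  for (lev in levels(group)) {
    idx <- which(group == lev)
    if (length(idx) > 1) out[idx] <- values[idx][sample(length(idx))]
  }
  out
}

#' Case-control differential acetylation under a composition adjustment
#'
#' Builds the covariate table implied by a [model_spec()] (nuisance
#' covariates plus the chosen cell adjustment) and tests the condition
#' coefficient per peak with the negative binomial engine of
#' [call_differential()]. The realized design matrix is attached to the
#' result for audit.
#'
#' @param counts Peaks x samples count matrix.
#' @param spec A [model_spec()].
#' @return A `da_result` (see [call_differential()]); log2 fold changes
#'   are case vs control.
#' @export
fit_adjusted_da <- function(counts, spec) {
  stopifnot(inherits(spec, "model_spec"))
  adj <- spec$cell_adjustment
  covariates <- spec$nuisance
  extra <- switch(adj$type,
    none = NULL,
    ordered_factor = data.frame(
      cell_of = to_ordered_factor(adj$estimate, adj$n_levels)),
    shuffled = data.frame(
      cell_of = to_ordered_factor(
        shuffle_within_group(adj$estimate, spec$condition, adj$seed),
        adj$n_levels)),
    continuous = as.data.frame(adj$estimates)
  )
  if (!is.null(extra)) {
    covariates <- if (is.null(covariates)) extra else cbind(covariates, extra)
  }
  call_differential(counts, spec$condition, covariates)
}

#' Group difference in a cell-composition estimate
#'
#' Ordinary linear model of the estimate on condition plus nuisance
#' covariates; reports the condition effect (level 2 vs level 1) with a
#' 95 percent confidence interval and p-value.
#'
#' @param estimate Per-sample numeric scores.
#' @param condition Two-level factor.
#' @param nuisance Optional covariate data.frame.
#' @return One-row `data.frame`: `effect`, `ci_low`, `ci_high`,
#'   `p_value`, `n`.
#' @export
estimate_group_test <- function(estimate, condition, nuisance = NULL) {
  condition <- as.factor(condition)
  stopifnot(nlevels(condition) == 2)
  dat <- data.frame(.y = estimate, .cond = condition)
  if (!is.null(nuisance)) dat <- cbind(dat, as.data.frame(nuisance))
  fit <- lm(.y ~ ., data = dat)
  if (any(is.na(coef(fit)))) {
    cw_stop("singular design in estimate_group_test",
            class = "cellwise_singular_design_error")
  }
  term <- grep("^\\.cond", names(coef(fit)), value = TRUE)
  ci <- confint(fit)[term, ]
  data.frame(effect = unname(coef(fit)[term]),
             ci_low = ci[1], ci_high = ci[2],
             p_value = summary(fit)$coefficients[term, 4],
             n = length(estimate), row.names = NULL)
}

#' Stepwise selection of cell types independently associated with disease
#'
#' Cell-type estimates are collinear, so single-estimate tests cannot
#' tell which types change independently with the condition. This fits a
#' linear model of the condition indicator on all cell estimates plus
#' nuisance covariates and runs bidirectional stepwise selection by AIC
#' (nuisance terms are kept in the lower scope and never dropped).
#'
#' @param estimates `estimate_matrix` or samples x cell types data.
#' @param condition Two-level factor; coded 0/1 with level 2 as 1.
#' @param nuisance Optional covariate data.frame.
#' @param direction Passed to [stats::step()].
#' @return `data.frame` of retained cell types with `coefficient`,
#'   `sign` and `p_value` from the final model; zero rows when nothing
#'   is retained.
#' @export
stepwise_cell_association <- function(estimates, condition, nuisance = NULL,
                                      direction = "both") {
  est <- as.data.frame(unclass(estimates))
  stopifnot(ncol(est) >= 2)
  condition <- as.factor(condition)
  y <- as.numeric(condition == levels(condition)[2])
  cellcols <- colnames(est)
  dat <- cbind(data.frame(.y = y), est)
  lower_terms <- "1"
  if (!is.null(nuisance)) {
    nuisance <- as.data.frame(nuisance)
    dat <- cbind(dat, nuisance)
    lower_terms <- paste(colnames(nuisance), collapse = " + ")
  }
  full <- lm(.y ~ ., data = dat)
  lower <- as.formula(paste(".y ~", lower_terms))
  sel <- step(full, scope = list(lower = lower, upper = formula(full)),
              direction = direction, trace = 0)
  cf <- summary(sel)$coefficients
  kept <- intersect(rownames(cf), cellcols)
  data.frame(cell_type = kept,
             coefficient = cf[kept, 1],
             sign = sign(cf[kept, 1]),
             p_value = cf[kept, 4],
             row.names = NULL, stringsAsFactors = FALSE)
}
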