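# Dual-luciferase reporter (SLAP) normalization and statistics, and
# nuclear/cytoplasmic intensity-ratio summaries.
#
# A well's raw readout is a Renilla/firefly luminescence ratio; all
# ratios are scaled so that the control condition averages exactly one
# normalized luciferase unit (NLU).  Standard errors are sample SD
# (n - 1 denominator) over sqrt(n); significance uses the two-tailed
# Welch (unequal-variance) t-test.

#' Normalize luciferase wells to control NLU
#'
#' `NLU_i = (renilla_i / firefly_i) / mean(renilla/firefly over control
#' wells)`, so the control condition has mean NLU 1 by construction.
#'
#' @param wells Data frame with columns `condition`, `replicate`,
#'   `renilla_rlu`, `firefly_rlu` (both readings strictly positive).
#' @param control Condition label of the background/control samples.
#' @return `wells` with an added `nlu` column (attribute `control`).
#' @export
normalize_slap <- function(wells, control) {
  need <- c("condition", "replicate", "renilla_rlu", "firefly_rlu")
  if (!all(need %in% names(wells)))
    stopf("wells table missing column(s): %s",
          paste(setdiff(need, names(wells)), collapse = ", "))
  if (any(!is.finite(wells$firefly_rlu)) || any(wells$firefly_rlu <= 0))
    stopf("firefly readings must be strictly positive")
  if (any(!is.finite(wells$renilla_rlu)) || any(wells$renilla_rlu <= 0))
    stopf("renilla readings must be strictly positive")
  ctrl <- wells$condition == control
  if (!any(ctrl))
    stopf("control condition '%s' not present in wells table", control)
  ratio <- wells$renilla_rlu / wells$firefly_rlu
  wells$nlu <- ratio / mean(ratio[ctrl])
  attr(wells, "control") <- control
  wells
}

#' Summarize NLU values for one condition
#'
#' @param nlus Numeric NLU values for the condition.
#' @param condition Condition label.
#' @return A `slap_summary`: `condition`, `n`, `mean_nlu`, `se_nlu`
#'   (sample SD over sqrt(n); defined as 0 with a warning for a single
#'   replicate).
#' @export
slap_summary <- function(nlus, condition = "condition") {
  n <- length(nlus)
  if (n == 0L) stopf("no NLU values for '%s'", condition)
  se <- if (n == 1L) {
    warnf("single replicate for '%s': SE reported as 0", condition)
    0
  } else sd(nlus) / sqrt(n)
  structure(list(condition = condition, n = n, mean_nlu = mean(nlus),
                 se_nlu = se),
            class = "slap_summary")
}

#' @export
print.slap_summary <- function(x, ...) {
  cat(sprintf("%s: %.4g +/- %.3g NLU (n = %d, SE)\n",
              x$condition, x$mean_nlu, x$se_nlu, x$n))
  invisible(x)
}

#' Welch two-sample t-test
#'
#' Two-tailed t-test assuming unequal variances (Welch-Satterthwaite
#' degrees of freedom).  Both groups constant is an error: the statistic
#' is undefined.
#'
#' @param a,b Numeric vectors, each with at least two values.
#' @return A list with `t`, `df`, `p`.
#' @export
welch_t_test <- function(a, b) {
  if (length(a) < 2L || length(b) < 2L)
    stopf("each group needs at least 2 values")
  if (stats::var(a) == 0 && stats::var(b) == 0)
    stopf("both groups have zero variance: Welch statistic undefined")
  r <- t.test(a, b, var.equal = FALSE, alternative = "two.sided")
  list(t = unname(r$statistic), df = unname(r$parameter), p = r$p.value)
}

#' Ordinary least-squares dose-response line
#'
#' Regresses response (e.g. NLU) on a dose/abundance predictor and
#' reports slope, intercept and the coefficient of determination
#' `r_squared = 1 - SSR/SST`.  A constant response (`SST = 0`) is
#' reported as `r_squared = 0` with a degeneracy flag rather than an
#' undefined value; a constant predictor is an error.
#'
#' @param x Predictor values (non-constant, length >= 2).
#' @param y Response values.
#' @return A `dose_response` list: `slope`, `intercept`, `r_squared`,
#'   `degenerate`.
#' @export
linear_dose_response <- function(x, y) {
  if (length(x) != length(y)) stopf("x and y lengths differ")
  if (length(x) < 2L) stopf("need at least 2 points")
  if (sd(x) == 0) stopf("constant predictor: slope undefined")
  fit <- lm(y ~ x)
  sst <- sum((y - mean(y))^2)
  degenerate <- sst == 0
  if (degenerate)
    warnf("constant response: r_squared reported as 0 (degenerate)")
  r2 <- if (degenerate) 0 else 1 - sum(resid(fit)^2) / sst
  structure(list(slope = unname(coef(fit)[2]),
                 intercept = unname(coef(fit)[1]),
                 r_squared = r2, degenerate = degenerate),
            class = "dose_response")
}

#' @export
print.dose_response <- function(x, ...) {
  cat(sprintf("dose-response: slope %.4g, intercept %.4g, R^2 = %.4f%s\n",
              x$slope, x$intercept, x$r_squared,
              if (x$degenerate) " (degenerate)" else ""))
  invisible(x)
}

#' Percent stimulation of one condition over another
#'
#' `100 * (test - base) / base` on mean NLUs; e.g. a test mean of 1.5
#' over a base mean of 1.0 is a +50 percent stimulatory effect.
#'
#' @param test,base [slap_summary()] objects (or bare numeric means).
#' @return Percent change (positive = stimulation).
#' @export
stimulation_effect <- function(test, base) {
  m <- function(s) if (inherits(s, "slap_summary")) s$mean_nlu else s
  tb <- m(test); bb <- m(base)
  if (bb == 0) stopf("base mean NLU is zero: percent change undefined")
  100 * (tb - bb) / bb
}

#' Nuclear/cytoplasmic intensity ratio over cells
#'
#' Each cell is measured with three boxes in the nucleus and three in the
#' cytoplasm; the per-cell nuclear ratio is the mean nuclear intensity
#' over the mean cytoplasmic intensity (ratio of means -- robust to a
#' single dim box; `method = "mean_of_ratios"` averages the three paired
#' box ratios instead).  Summaries with fewer than 30 cells carry a
#' warning.
#'
#' @param cells Data frame with columns `cell_id`, `nuc1..nuc3`,
#'   `cyt1..cyt3` (intensities >= 0) and optionally `channel`.
#' @param method `"ratio_of_means"` (default) or `"mean_of_ratios"`.
#' @return A `ratio_summary`: `n_cells`, `mean_ratio`, `se_ratio`, and
#'   the per-cell `ratios`.
#' @export
nuclear_cyto_ratio <- function(cells,
                               method = c("ratio_of_means",
                                          "mean_of_ratios")) {
  method <- match.arg(method)
  nuc_cols <- c("nuc1", "nuc2", "nuc3")
  cyt_cols <- c("cyt1", "cyt2", "cyt3")
  need <- c("cell_id", nuc_cols, cyt_cols)
  if (!all(need %in% names(cells)))
    stopf("cell-box table missing column(s): %s",
          paste(setdiff(need, names(cells)), collapse = ", "))
  nuc <- as.matrix(cells[nuc_cols]); cyt <- as.matrix(cells[cyt_cols])
  if (any(nuc < 0) || any(cyt < 0)) stopf("box intensities must be >= 0")
  cyt_mean <- rowMeans(cyt)
  if (any(cyt_mean <= 0))
    stopf("cell '%s' has non-positive mean cytoplasmic intensity",
          cells$cell_id[which(cyt_mean <= 0)[1]])
  ratios <- switch(method,
                   ratio_of_means = rowMeans(nuc) / cyt_mean,
                   mean_of_ratios = rowMeans(nuc / cyt))
  n <- length(ratios)
  if (n < 30L) warnf("fewer than 30 cells (n = %d)", n)
  se <- if (n == 1L) 0 else sd(ratios) / sqrt(n)
  structure(list(n_cells = n, mean_ratio = mean(ratios), se_ratio = se,
                 ratios = ratios, method = method),
            class = "ratio_summary")
}

#' @export
print.ratio_summary <- function(x, ...) {
  cat(sprintf("nuclear/cytoplasmic ratio: %.4g +/- %.3g (n = %d cells, SE)\n",
              x$mean_ratio, x$se_ratio, x$n_cells))
  invisible(x)
}

#' Read a luciferase wells table
#'
#' @param path TSV with columns `condition`, `replicate`, `renilla_rlu`,
#'   `firefly_rlu`.
#' @return The wells data frame.
#' @export
read_wells_table <- function(path) {
  if (!file.exists(path)) stopf("wells table not found: %s", path)
  read.delim(path, stringsAsFactors = FALSE)
}

#' Read a cell-box intensity table
#'
#' @param path TSV with columns `cell_id`, `channel`, `nuc1..nuc3`,
#'   `cyt1..cyt3`.
#' @return The cell-box data frame.
#' @export
read_cell_boxes <- function(path) {
  if (!file.exists(path)) stopf("cell-box table not found: %s", path)
  read.delim(path, stringsAsFactors = FALSE)
}
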