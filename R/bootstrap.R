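# Design-aware stratified bootstrap percentile confidence intervals.

#' Bootstrap plan
#'
#' @param B number of replicates (default 999; 99 is a fast mode for
#'   smoke-level checks).
#' @param level confidence level in (0, 1).
#' @param seed integer seed for the resampling stream.
#' @return object of class `bootstrap_plan`.
#' @export
bootstrap_plan <- function(B = 999, level = 0.95, seed = 1L) {
  stopifnot(B >= 1, level > 0, level < 1)
  structure(list(B = as.integer(B), level = level, seed = as.integer(seed)),
            class = "bootstrap_plan")
}

# subset a cch_sample keeping its design attributes
resample_cch <- function(sample, idx) {
  out <- as.data.frame(sample)[idx, , drop = FALSE]
  rownames(out) <- NULL
  class(out) <- class(sample)
  for (a in c("alphas", "scheme", "endpoint", "biomarkers"))
    attr(out, a) <- attr(sample, a)
  out
}

#' Stratified bootstrap percentile confidence interval
#'
#' Resamples subjects with replacement independently within each
#' case-status x design-stratum cell (preserving cell sizes — the minimal
#' scheme consistent with the case-cohort design), recomputes the design
#' weights on each replicate, re-evaluates the statistic (which should
#' refit its models, so e.g. z-transform moments are recomputed and their
#' uncertainty propagates), and takes the empirical percentile interval
#' (type-7 quantiles). Replicates where the statistic fails are dropped
#' and counted; more than 5% failures is an error.
#'
#' @param statistic function taking a `cch_sample` and returning a single
#'   number.
#' @param sample the original weighted `cch_sample`.
#' @param plan a [bootstrap_plan()].
#' @return list of class `cch_boot`: `estimate`, `ci_low`, `ci_high`,
#'   `replicates`, `n_failed`, `level`.
#' @export
bootstrap_ci <- function(statistic, sample, plan = bootstrap_plan()) {
  est <- statistic(sample)
  if (!is.finite(est)) stop("statistic is not finite on the original sample")
  cells <- interaction(sample$is_case, sample$stratum, drop = TRUE)
  cell_rows <- split(seq_len(nrow(sample)), cells)
  set.seed(plan$seed)
  reps <- numeric(plan$B)
  failed <- 0L
  for (b in seq_len(plan$B)) {
    idx <- unlist(lapply(cell_rows, function(r)
      r[sample.int(length(r), length(r), replace = TRUE)]), use.names = FALSE)
    rs <- compute_weights(resample_cch(sample, idx))
    val <- tryCatch(statistic(rs), error = function(e) NA_real_)
    if (!is.finite(val)) { failed <- failed + 1L; val <- NA_real_ }
    reps[b] <- val
  }
  ok <- reps[is.finite(reps)]
  if (!length(ok)) stop("all bootstrap replicates failed")
  if (failed > 0.05 * plan$B)
    stop("more than 5% of bootstrap replicates failed (", failed,
         " of ", plan$B, ")")
  alpha <- 1 - plan$level
  ci <- stats::quantile(ok, c(alpha / 2, 1 - alpha / 2), type = 7, names = FALSE)
  structure(list(estimate = est, ci_low = ci[1], ci_high = ci[2],
                 replicates = ok, n_failed = failed, level = plan$level),
            class = "cch_boot")
}

#' @export
print.cch_boot <- function(x, ...) {
  cat(format(x$estimate, digits = 4), " (",
      format(100 * x$level), "% CI ", format(x$ci_low, digits = 4), " to ",
      format(x$ci_high, digits = 4), "; B = ", length(x$replicates),
      if (x$n_failed) paste0(", ", x$n_failed, " failed") else "", ")\n",
      sep = "")
  invisible(x)
}
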