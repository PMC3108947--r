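# Stratified subcohort sampling, design weights, and weighted descriptive
# statistics for the case-cohort design.

#' Stratified case-cohort sampling design
#'
#' Strata are the survey-by-sex cells; each has a sampling fraction
#' `alpha` in (0, 1]. `scheme` picks the weighting used when fitting the
#' Cox model: "prentice" (subcohort weight 1; cases outside the subcohort
#' enter only their own risk set) or "barlow" (subcohort weighted by
#' 1/alpha; case weight drops to 1 at the event).
#'
#' @param fraction either a single fraction applied to every stratum or a
#'   named vector keyed by "survey.sex" stratum labels (e.g. "S1.male").
#' @param scheme "prentice" (default) or "barlow".
#' @param seed integer seed controlling the subcohort draw.
#' @return object of class `sampling_design`.
#' @export
sampling_design <- function(fraction = 0.134,
                            scheme = c("prentice", "barlow"),
                            seed = 1L) {
  scheme <- match.arg(scheme)
  if (any(fraction <= 0) || any(fraction > 1))
    stop("sampling fractions must be in (0, 1]")
  structure(list(fraction = fraction, scheme = scheme, seed = as.integer(seed)),
            class = "sampling_design")
}

stratum_labels <- function(cohort) {
  interaction(cohort$survey, cohort$sex, drop = FALSE, sep = ".")
}

prevalent_column <- function(cohort, endpoint) {
  cand <- paste0("prevalent_", endpoint)
  if (cand %in% names(cohort)) return(cand)
  if (endpoint == "coronary" && "prevalent_mi" %in% names(cohort)) return("prevalent_mi")
  NULL
}

#' Draw a stratified case-cohort sample
#'
#' Subjects with the prevalent condition for the endpoint are excluded,
#' then a simple random sample without replacement of size
#' `round(alpha_s * N_s)` is drawn within each survey-by-sex stratum, and
#' all incident cases for the endpoint are appended. The random keys used
#' for sampling are assigned to the full cohort from `design$seed`, so the
#' subcohort is shared across endpoints with identical exclusions (the
#' study draws one subcohort used for both outcomes).
#'
#' @param cohort a cohort table.
#' @param design a [sampling_design()].
#' @param endpoint endpoint label, e.g. "diabetes" or "coronary".
#' @return data.frame of class `cch_sample` with flags `in_subcohort`,
#'   `is_case`, the `stratum` label, the endpoint's `time`/`status`, and
#'   design weights (column `weight`). Attributes: `alphas`, `scheme`,
#'   `endpoint`.
#' @export
draw_subcohort <- function(cohort, design, endpoint) {
  tcol <- paste0("time_", endpoint); scol <- paste0("status_", endpoint)
  if (!all(c(tcol, scol) %in% names(cohort)))
    stop("endpoint columns not found: ", tcol, ", ", scol)
  strata_all <- stratum_labels(cohort)
  set.seed(design$seed)
  key <- stats::runif(nrow(cohort))

  pcol <- prevalent_column(cohort, endpoint)
  eligible <- if (is.null(pcol)) rep(TRUE, nrow(cohort)) else cohort[[pcol]] == 0

  levs <- levels(strata_all)
  frac <- design$fraction
  alphas <- if (length(frac) == 1) stats::setNames(rep(frac, length(levs)), levs) else frac
  missing_strata <- setdiff(levs[tabulate(strata_all[eligible], length(levs)) > 0], names(alphas))
  if (length(missing_strata))
    stop("no sampling fraction for strata: ", paste(missing_strata, collapse = ", "))

  in_sub <- rep(FALSE, nrow(cohort))
  for (s in levs) {
    idx <- which(eligible & strata_all == s)
    if (!length(idx)) next
    m <- round(alphas[[s]] * length(idx))
    if (m < 1) stop("stratum ", s, ": alpha * N = ",
                    alphas[[s]] * length(idx), " < 1")
    take <- idx[order(key[idx])[seq_len(m)]]
    in_sub[take] <- TRUE
  }
  is_case <- eligible & cohort[[scol]] == 1
  keep <- which(in_sub | is_case)

  smp <- as.data.frame(cohort)[keep, , drop = FALSE]
  rownames(smp) <- NULL
  smp$stratum <- as.character(strata_all[keep])
  smp$in_subcohort <- as.integer(in_sub[keep])
  smp$is_case <- as.integer(is_case[keep])
  smp$time <- smp[[tcol]]
  smp$status <- smp[[scol]]
  class(smp) <- c("cch_sample", "data.frame")
  attr(smp, "alphas") <- alphas
  attr(smp, "scheme") <- design$scheme
  attr(smp, "endpoint") <- endpoint
  attr(smp, "biomarkers") <- attr(cohort, "biomarkers")
  compute_weights(smp)
}

#' Attach design weights to a case-cohort sample
#'
#' The `weight` column holds the cohort-representative analysis weights
#' (Horvitz-Thompson): cases are always in the sample, so every case
#' carries weight 1, while subcohort non-cases carry the inverse sampling
#' fraction of their survey-by-sex stratum. These weights drive the
#' weighted Kaplan-Meier, descriptive statistics and the discrimination
#' measures. The Cox fitter builds its own risk-set weights from the
#' stored scheme ("prentice"/"barlow"); with every fraction equal to 1 all
#' weights are 1 under either scheme.
#'
#' @param sample a `cch_sample`.
#' @param scheme optional override of the stored weighting scheme.
#' @return the sample with the `weight` column (re)computed.
#' @export
compute_weights <- function(sample, scheme = NULL) {
  if (!is.null(scheme)) {
    if (!scheme %in% c("prentice", "barlow")) stop("unknown scheme: ", scheme)
    attr(sample, "scheme") <- scheme
  }
  alphas <- attr(sample, "alphas")
  a <- alphas[sample$stratum]
  sample$weight <- ifelse(sample$is_case == 1, 1, 1 / a)
  sample
}

# survey-style linearized variance of a weighted mean, stratified, no FPC
weighted_mean_se <- function(x, w, stratum) {
  mu <- sum(w * x) / sum(w)
  z <- w * (x - mu) / sum(w)
  v <- 0
  for (s in unique(stratum)) {
    zs <- z[stratum == s]
    ns <- length(zs)
    if (ns > 1) v <- v + ns / (ns - 1) * sum((zs - mean(zs))^2)
  }
  c(mean = mu, se = sqrt(v))
}

#' Weighted descriptive statistics by case status
#'
#' Design-weighted means with survey-sampling (linearized, stratified)
#' standard errors, separately for cases and non-cases. Variables flagged
#' log-scale are summarized on the log scale and back-transformed: the
#' point estimate is the geometric mean and the `se` column the antilog of
#' the SE of the log mean.
#'
#' @param sample a weighted `cch_sample`.
#' @param variables character vector of numeric column names.
#' @param log_scale character subset of `variables` summarized
#'   geometrically (all values must be positive).
#' @return data.frame with columns `variable`, `group`, `estimate`, `se`,
#'   `scale`.
#' @export
weighted_descriptives <- function(sample, variables, log_scale = character(0)) {
  if (!"weight" %in% names(sample)) stop("weights not computed")
  out <- list()
  for (v in variables) {
    x <- sample[[v]]
    if (!is.numeric(x)) stop("variable not numeric: ", v)
    use_log <- v %in% log_scale
    if (use_log && any(x <= 0))
      stop("nonpositive values in log-scale variable: ", v)
    for (g in c(0, 1)) {
      i <- sample$is_case == g
      if (!any(i)) next
      xs <- if (use_log) log(x[i]) else x[i]
      ms <- weighted_mean_se(xs, sample$weight[i], sample$stratum[i])
      out[[length(out) + 1]] <- data.frame(
        variable = v, group = if (g == 1) "case" else "noncase",
        estimate = if (use_log) exp(ms["mean"]) else ms["mean"],
        se = if (use_log) exp(ms["se"]) else ms["se"],
        scale = if (use_log) "geometric" else "arithmetic",
        stringsAsFactors = FALSE, row.names = NULL)
    }
  }
  do.call(rbind, out)
}

#' Spearman rank correlation matrix of the biomarker panel
#'
#' Computed on the randomly sampled subcohort (design-representative),
#' with average ranks for ties. Constant columns yield NA (undefined), not
#' zero.
#'
#' @param sample a `cch_sample` (restricted internally to the subcohort) or
#'   any data.frame.
#' @param biomarkers column names; defaults to the sample's biomarker set.
#' @return symmetric matrix of rank correlations with unit diagonal.
#' @export
spearman_matrix <- function(sample, biomarkers = attr(sample, "biomarkers")) {
  if (is.null(biomarkers)) stop("no biomarker columns specified")
  df <- sample
  if ("in_subcohort" %in% names(df)) df <- df[df$in_subcohort == 1, , drop = FALSE]
  if (nrow(df) < 3) stop("need at least 3 subjects")
  m <- suppressWarnings(stats::cor(as.matrix(df[, biomarkers, drop = FALSE]),
                                   method = "spearman"))
  constant <- vapply(df[, biomarkers, drop = FALSE],
                     function(x) stats::sd(x) == 0, logical(1))
  diag(m)[!constant] <- 1
  m
}
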