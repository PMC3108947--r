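# Synthetic cohort generator: correlated log-normal biomarker panel,
# cardiometabolic covariates, and two Weibull proportional-hazards endpoints
# (incident diabetes, incident coronary events) under staggered entry with
# administrative censoring.

#' Default biomarker panel specification
#'
#' Thirteen inflammation-related serum biomarkers modelled as log-normal
#' marginals: acute-phase protein (CRP), cytokines (IL-6, IL-18, TGF-beta1,
#' MIF), chemokines (MCP-1, IL-8, IP-10, RANTES), adipokines (adiponectin,
#' leptin) and soluble adhesion molecules (sE-selectin, sICAM-1).
#' `log_mean`/`log_sd` are the mean and SD of the log concentration.
#'
#' @return data.frame with columns `name`, `log_mean`, `log_sd`.
#' @export
default_biomarker_spec <- function() {
  data.frame(
    name = c("crp", "il6", "il18", "mif", "mcp1", "il8", "ip10",
             "adiponectin", "leptin", "rantes", "tgfb1", "eselectin", "icam1"),
    log_mean = c(log(1.2), log(1.8), log(180), log(1.5), log(130), log(5),
                 log(100), log(8), log(8), log(30), log(15), log(40), log(250)),
    log_sd = c(1.00, 0.70, 0.45, 0.80, 0.50, 0.60, 0.50,
               0.55, 0.90, 0.60, 0.50, 0.50, 0.35),
    stringsAsFactors = FALSE
  )
}

#' Default biomarker log-scale correlation matrix
#'
#' Mild positive exchangeable dependence (0.20) with stronger pairs for
#' markers sharing biology (CRP/IL-6, IL-6/IL-8, MCP-1/IP-10,
#' sE-selectin/sICAM-1, CRP/leptin) and a weak negative
#' adiponectin--leptin correlation. Positive definite by construction.
#'
#' @param names biomarker names (order defines rows/columns).
#' @return symmetric positive-definite correlation matrix.
#' @export
default_biomarker_corr <- function(names = default_biomarker_spec()$name) {
  p <- length(names)
  m <- matrix(0.20, p, p, dimnames = list(names, names))
  # adiponectin is only weakly correlated with the inflammatory markers
  if ("adiponectin" %in% names) {
    m["adiponectin", ] <- m[, "adiponectin"] <- 0.05
  }
  set_pair <- function(a, b, r) {
    if (all(c(a, b) %in% names)) {
      m[a, b] <<- r
      m[b, a] <<- r
    }
  }
  set_pair("crp", "il6", 0.45)
  set_pair("crp", "leptin", 0.35)
  set_pair("il6", "il8", 0.35)
  set_pair("mcp1", "ip10", 0.30)
  set_pair("eselectin", "icam1", 0.40)
  set_pair("adiponectin", "leptin", -0.15)
  diag(m) <- 1
  m
}

#' Default cardiometabolic covariate distributions
#'
#' Continuous: BMI (kg/m^2), systolic blood pressure (mmHg), total/HDL
#' cholesterol ratio (log-normal). Categorical: smoking (never/former/
#' current), alcohol consumption (none/moderate/high), physical activity
#' (low/high), parental history of diabetes and of myocardial infarction
#' (no/yes/unknown). Prevalence flags used for per-endpoint exclusion.
#'
#' @return named list of distribution parameters.
#' @export
default_covariate_spec <- function() {
  list(
    bmi = list(mean = 26.5, sd = 4.0),
    sbp = list(mean = 132, sd = 17),
    tchdl = list(log_mean = log(4.2), log_sd = 0.28),
    smoking = c(never = 0.45, former = 0.28, current = 0.27),
    alcohol = c(none = 0.30, moderate = 0.50, high = 0.20),
    phys_act = c(low = 0.55, high = 0.45),
    parental_diabetes = c(no = 0.65, yes = 0.20, unknown = 0.15),
    parental_mi = c(no = 0.60, yes = 0.20, unknown = 0.20),
    prevalent_diabetes = 0.05,
    prevalent_mi = 0.03
  )
}

#' Default endpoint hazard specifications
#'
#' Each endpoint has a Weibull baseline hazard (shape; scale calibrated at
#' simulation time so the latent 10-year cumulative incidence matches
#' `target_cuminc`) and a named vector of log hazard ratios per standardized
#' covariate / log dummy contrast. Standardized hazard ratios span the
#' 0.33--1.7 range typical of single inflammation-related biomarkers, with
#' adiponectin protective.
#'
#' @return named list with elements `diabetes` and `coronary`.
#' @export
default_endpoint_spec <- function() {
  list(
    diabetes = list(
      shape = 1.6,
      scale = NULL,           # calibrated to target_cuminc at simulation time
      target_cuminc = 0.10,
      cuminc_horizon = 10,
      loghr = c(
        age = log(1.7), sex_male = 0.30,
        bmi = log(1.5), sbp = log(1.2), tchdl = log(1.3),
        smoking_former = 0.10, smoking_current = 0.25,
        alcohol_moderate = 0.00, alcohol_high = 0.15,
        phys_act_high = -0.15,
        parental_diabetes_yes = 0.50, parental_diabetes_unknown = 0.10,
        crp = 0.10, il6 = 0.10, il18 = 0.18,
        adiponectin = -1.00, leptin = 0.26,
        eselectin = 0.30, icam1 = 0.15
      )
    ),
    coronary = list(
      shape = 1.8,
      scale = NULL,
      target_cuminc = 0.07,
      cuminc_horizon = 10,
      loghr = c(
        age = log(1.7) + 0.17, sex_male = 0.60,
        bmi = 0.15, sbp = 0.30, tchdl = 0.35,
        smoking_former = 0.10, smoking_current = 0.45,
        alcohol_high = 0.10,
        phys_act_high = -0.10,
        parental_mi_yes = 0.35, parental_mi_unknown = 0.05,
        prevalent_diabetes_yes = 0.60,
        crp = 0.10, il6 = log(1.23),
        eselectin = 0.15, icam1 = log(1.31)
      )
    )
  )
}

#' Simulation configuration
#'
#' Bundles and validates every ingredient of the synthetic cohort: sample
#' size, survey strata, demographics, the biomarker panel (log-normal
#' marginals with a log-scale correlation matrix), cardiometabolic
#' covariates, the two endpoint hazard models (Weibull baseline,
#' proportional-hazards effects, shared log-normal frailty linking the two
#' endpoints), and the censoring mechanism (administrative horizon, uniform
#' entry stagger, exponential loss to follow-up).
#'
#' @param n_subjects cohort size.
#' @param n_surveys number of survey strata (labelled S1, S2, ...).
#' @param sex_ratio proportion male, in (0, 1).
#' @param age_range numeric `c(min, max)` in years.
#' @param biomarker_spec data.frame `name`, `log_mean`, `log_sd`.
#' @param biomarker_corr symmetric positive-definite correlation matrix on
#'   the log scale, dimension matching `biomarker_spec`.
#' @param covariate_spec list as [default_covariate_spec()].
#' @param endpoint_spec list as [default_endpoint_spec()].
#' @param frailty_sd SD of the shared normal frailty added to both linear
#'   predictors (induces between-endpoint dependence); 0 disables it.
#' @param censoring_spec list: `horizon` (administrative censoring, years),
#'   `entry_window` (uniform entry stagger, years), `dropout_rate`
#'   (exponential loss-to-follow-up rate per year; 0 disables).
#' @param adiposity_loadings named loadings of a latent adiposity factor on
#'   log biomarkers (variance-preserving mixing; also drives BMI).
#' @param seed integer seed; the whole cohort is reproducible from it.
#' @return object of class `sim_config`.
#' @export
sim_config <- function(n_subjects = 13427L,
                       n_surveys = 3L,
                       sex_ratio = 0.5,
                       age_range = c(25, 74),
                       biomarker_spec = default_biomarker_spec(),
                       biomarker_corr = default_biomarker_corr(biomarker_spec$name),
                       covariate_spec = default_covariate_spec(),
                       endpoint_spec = default_endpoint_spec(),
                       frailty_sd = 0.3,
                       censoring_spec = list(horizon = 18.2, entry_window = 10,
                                             dropout_rate = 0.034),
                       adiposity_loadings = c(leptin = 0.5, crp = 0.3,
                                              adiponectin = -0.35, eselectin = 0.2),
                       seed = 1L) {
  stopifnot(n_subjects >= 1, n_surveys >= 1,
            sex_ratio > 0, sex_ratio < 1,
            length(age_range) == 2, age_range[1] < age_range[2],
            is.data.frame(biomarker_spec),
            all(c("name", "log_mean", "log_sd") %in% names(biomarker_spec)))
  check_corr(biomarker_corr, nrow(biomarker_spec))
  if (is.null(censoring_spec$dropout_rate)) censoring_spec$dropout_rate <- 0
  if (censoring_spec$horizon <= 0) stop("censoring horizon must be > 0")
  for (ep in names(endpoint_spec)) {
    es <- endpoint_spec[[ep]]
    if (es$shape <= 0) stop("Weibull shape must be > 0 (endpoint ", ep, ")")
    if (!is.null(es$scale) && es$scale <= 0)
      stop("Weibull scale must be > 0 (endpoint ", ep, ")")
    if (!all(is.finite(es$loghr)))
      stop("non-finite log hazard ratio in endpoint ", ep)
  }
  structure(list(
    n_subjects = as.integer(n_subjects), n_surveys = as.integer(n_surveys),
    sex_ratio = sex_ratio, age_range = age_range,
    biomarker_spec = biomarker_spec, biomarker_corr = biomarker_corr,
    covariate_spec = covariate_spec, endpoint_spec = endpoint_spec,
    frailty_sd = frailty_sd, censoring_spec = censoring_spec,
    adiposity_loadings = adiposity_loadings,
    seed = as.integer(seed)
  ), class = "sim_config")
}

check_corr <- function(corr, p) {
  if (!is.matrix(corr) || nrow(corr) != p || ncol(corr) != p)
    stop("correlation matrix must be ", p, "x", p)
  if (max(abs(corr - t(corr))) > 1e-10)
    stop("correlation matrix must be symmetric")
  if (max(abs(diag(corr) - 1)) > 1e-10)
    stop("correlation matrix must have unit diagonal")
  ev <- eigen(corr, symmetric = TRUE, only.values = TRUE)$values
  if (min(ev) <= 1e-12)
    stop("correlation matrix is not positive definite: smallest eigenvalue ",
         format(min(ev), digits = 6))
  invisible(TRUE)
}

# correlated standard-normal draws via Cholesky
rmvn_std <- function(n, corr) {
  z <- matrix(stats::rnorm(n * nrow(corr)), n, nrow(corr))
  z %*% chol(corr)
}

#' Draw a correlated log-normal biomarker matrix
#'
#' Multivariate normal on the log scale (given correlation matrix),
#' exponentiated to concentrations. Spearman correlations of the output
#' equal those of the log-scale draws because ranks are invariant to the
#' exponential map.
#'
#' @param n number of subjects.
#' @param spec data.frame `name`, `log_mean`, `log_sd`.
#' @param corr log-scale correlation matrix.
#' @param seed optional integer seed.
#' @return numeric matrix, one column per biomarker.
#' @export
simulate_biomarkers <- function(n, spec = default_biomarker_spec(),
                                corr = default_biomarker_corr(spec$name),
                                seed = NULL) {
  stopifnot(n >= 1)
  check_corr(corr, nrow(spec))
  if (!is.null(seed)) set.seed(seed)
  z <- rmvn_std(n, corr)
  x <- exp(sweep(sweep(z, 2, spec$log_sd, "*"), 2, spec$log_mean, "+"))
  colnames(x) <- spec$name
  x
}

#' Draw latent event times from a Weibull proportional-hazards model
#'
#' Inverse-transform sampling: `T = scale * (-log(U) / exp(lp))^(1/shape)`,
#' so the hazard is the Weibull baseline multiplied by `exp(lp)` — the
#' data-generating model is exactly proportional hazards.
#'
#' @param lp per-subject linear predictor (finite).
#' @param shape,scale Weibull baseline parameters (> 0), scale in years.
#' @param seed optional integer seed.
#' @return vector of latent event times in years.
#' @export
simulate_event_times <- function(lp, shape, scale, seed = NULL) {
  if (!all(is.finite(lp))) stop("non-finite linear predictor")
  stopifnot(shape > 0, scale > 0)
  if (!is.null(seed)) set.seed(seed)
  u <- stats::runif(length(lp))
  scale * (-log(u) / exp(lp))^(1 / shape)
}

# theoretical mean/sd of a log-normal(mu, sigma) variable
lnorm_moments <- function(mu, sigma) {
  m <- exp(mu + sigma^2 / 2)
  list(mean = m, sd = m * sqrt(exp(sigma^2) - 1))
}

# solve the Weibull scale so that mean 10-year latent cumulative incidence
# over the realized linear predictors hits the target
calibrate_scale <- function(shape, elp, target, horizon) {
  f <- function(log_s) mean(1 - exp(-(horizon / exp(log_s))^shape * elp)) - target
  exp(stats::uniroot(f, c(log(0.5), log(5000)), tol = 1e-10)$root)
}

canonical_levels <- function() {
  list(sex = c("female", "male"),
       smoking = c("never", "former", "current"),
       alcohol = c("none", "moderate", "high"),
       phys_act = c("low", "high"),
       parental_diabetes = c("no", "yes", "unknown"),
       parental_mi = c("no", "yes", "unknown"))
}

rcat <- function(n, probs) {
  factor(sample(names(probs), n, replace = TRUE, prob = probs),
         levels = names(probs))
}

#' Simulate a complete synthetic cohort
#'
#' Assembles demographics, cardiometabolic covariates, the correlated
#' log-normal biomarker panel (coupled to BMI through a latent adiposity
#' factor with variance-preserving loadings), and two proportional-hazards
#' endpoints sharing covariate effects and a common frailty. Observed time
#' is the minimum of the latent event time and the censoring time
#' (administrative horizon minus uniform entry stagger, and exponential
#' loss to follow-up); status indicates the event was observed. Fully
#' deterministic given `config$seed`.
#'
#' @param config a [sim_config()] object.
#' @return `data.frame` of class `cch_cohort` with one row per subject and
#'   columns `id`, `survey`, `sex`, `age`, covariates, biomarkers, and per
#'   endpoint `time_<endpoint>`, `status_<endpoint>`. The generating truth
#'   (calibrated scales, log-HR vectors) is attached as attribute `truth`.
#' @export
simulate_cohort <- function(config = sim_config()) {
  stopifnot(inherits(config, "sim_config"))
  set.seed(config$seed)
  n <- config$n_subjects
  cs <- config$covariate_spec

  survey <- factor(sample(paste0("S", seq_len(config$n_surveys)), n, replace = TRUE),
                   levels = paste0("S", seq_len(config$n_surveys)))
  sex <- factor(ifelse(stats::runif(n) < config$sex_ratio, "male", "female"),
                levels = canonical_levels()$sex)
  age <- stats::runif(n, config$age_range[1], config$age_range[2])

  z_adip <- stats::rnorm(n)
  # BMI driven by the adiposity factor; marginal sd preserved
  bmi <- cs$bmi$mean + cs$bmi$sd * (0.7 * z_adip + sqrt(1 - 0.7^2) * stats::rnorm(n))
  bmi <- pmax(bmi, 16)
  sbp <- cs$sbp$mean + 0.4 * (age - mean(config$age_range)) +
    cs$sbp$sd * (0.2 * z_adip + sqrt(1 - 0.2^2) * stats::rnorm(n))
  tchdl <- exp(cs$tchdl$log_mean + cs$tchdl$log_sd * stats::rnorm(n))

  smoking <- rcat(n, cs$smoking)
  alcohol <- rcat(n, cs$alcohol)
  phys_act <- rcat(n, cs$phys_act)
  parental_diabetes <- rcat(n, cs$parental_diabetes)
  parental_mi <- rcat(n, cs$parental_mi)
  prevalent_diabetes <- as.integer(stats::runif(n) < cs$prevalent_diabetes)
  prevalent_mi <- as.integer(stats::runif(n) < cs$prevalent_mi)

  # biomarkers: correlated normals mixed with the adiposity factor so that
  # marginal log-sd is preserved: u = sqrt(1 - lambda^2) z + lambda z_adip
  bs <- config$biomarker_spec
  z <- rmvn_std(n, config$biomarker_corr)
  lambda <- rep(0, nrow(bs))
  names(lambda) <- bs$name
  common <- intersect(names(config$adiposity_loadings), bs$name)
  lambda[common] <- config$adiposity_loadings[common]
  u <- sweep(z, 2, sqrt(1 - lambda^2), "*") + outer(z_adip, lambda)
  biom <- exp(sweep(sweep(u, 2, bs$log_sd, "*"), 2, bs$log_mean, "+"))
  colnames(biom) <- bs$name

  # standardized covariate values on theoretical moments (the truth scale)
  std <- list(
    age = (age - mean(config$age_range)) / (diff(config$age_range) / sqrt(12)),
    sex_male = as.numeric(sex == "male"),
    bmi = (bmi - cs$bmi$mean) / cs$bmi$sd,
    sbp = (sbp - cs$sbp$mean) / sqrt((0.4 * diff(config$age_range) / sqrt(12))^2 + cs$sbp$sd^2),
    tchdl = (tchdl - lnorm_moments(cs$tchdl$log_mean, cs$tchdl$log_sd)$mean) /
      lnorm_moments(cs$tchdl$log_mean, cs$tchdl$log_sd)$sd,
    smoking_former = as.numeric(smoking == "former"),
    smoking_current = as.numeric(smoking == "current"),
    alcohol_moderate = as.numeric(alcohol == "moderate"),
    alcohol_high = as.numeric(alcohol == "high"),
    phys_act_high = as.numeric(phys_act == "high"),
    parental_diabetes_yes = as.numeric(parental_diabetes == "yes"),
    parental_diabetes_unknown = as.numeric(parental_diabetes == "unknown"),
    parental_mi_yes = as.numeric(parental_mi == "yes"),
    parental_mi_unknown = as.numeric(parental_mi == "unknown"),
    prevalent_diabetes_yes = as.numeric(prevalent_diabetes == 1)
  )
  for (j in seq_len(nrow(bs))) {
    mom <- lnorm_moments(bs$log_mean[j], bs$log_sd[j])
    std[[bs$name[j]]] <- (biom[, j] - mom$mean) / mom$sd
  }

  frailty <- if (config$frailty_sd > 0) stats::rnorm(n, 0, config$frailty_sd) else rep(0, n)

  # censoring shared by both endpoints (one follow-up process per subject)
  cens <- config$censoring_spec
  entry <- stats::runif(n, 0, cens$entry_window)
  cadmin <- cens$horizon - entry
  cdrop <- if (cens$dropout_rate > 0) stats::rexp(n, cens$dropout_rate) else rep(Inf, n)
  ctime <- pmax(pmin(cadmin, cdrop), 0.05)

  out <- data.frame(id = seq_len(n), survey = survey, sex = sex, age = age,
                    bmi = bmi, sbp = sbp, tchdl = tchdl,
                    smoking = smoking, alcohol = alcohol, phys_act = phys_act,
                    parental_diabetes = parental_diabetes, parental_mi = parental_mi,
                    prevalent_diabetes = prevalent_diabetes, prevalent_mi = prevalent_mi,
                    stringsAsFactors = FALSE)
  out <- cbind(out, as.data.frame(biom))

  truth <- list(seed = config$seed, endpoints = list())
  for (ep in names(config$endpoint_spec)) {
    es <- config$endpoint_spec[[ep]]
    lhr <- es$loghr
    missing_terms <- setdiff(names(lhr), names(std))
    if (length(missing_terms))
      stop("unknown covariate term(s) in endpoint ", ep, ": ",
           paste(missing_terms, collapse = ", "))
    lp <- frailty
    for (term in names(lhr)) lp <- lp + lhr[[term]] * std[[term]]
    scale <- es$scale
    if (is.null(scale))
      scale <- calibrate_scale(es$shape, exp(lp), es$target_cuminc,
                               if (is.null(es$cuminc_horizon)) 10 else es$cuminc_horizon)
    latent <- simulate_event_times(lp, es$shape, scale)
    out[[paste0("time_", ep)]] <- pmin(latent, ctime)
    out[[paste0("status_", ep)]] <- as.integer(latent <= ctime)
    truth$endpoints[[ep]] <- list(shape = es$shape, scale = scale,
                                  loghr = lhr, lp = lp)
  }
  class(out) <- c("cch_cohort", "data.frame")
  attr(out, "endpoints") <- names(config$endpoint_spec)
  attr(out, "biomarkers") <- bs$name
  attr(out, "truth") <- truth
  out
}
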