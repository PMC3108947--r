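# End-to-end orchestration: simulate or load a cohort, draw the
# case-cohort sample per endpoint, fit the model registry (basic,
# biomarker-panel, cardiometabolic, combined, per-biomarker and
# significant-subset models), compute the four accuracy measures with
# optional design-aware bootstrap CIs, and write tables, a JSON summary
# and a run log.

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Default model registry for one endpoint
#'
#' The basic adjustment is age, sex and survey. The cardiometabolic set
#' adds BMI, systolic blood pressure, total/HDL-cholesterol ratio,
#' smoking, alcohol, physical activity and — endpoint-specifically —
#' parental diabetes (diabetes endpoint) or parental myocardial
#' infarction plus prevalent diabetes (coronary endpoint). Registry
#' entries: `model_a` (basic), `model_b` (a + all biomarkers), `model_c`
#' (a + cardiometabolic), `model_d` (c + all biomarkers), and per
#' biomarker `model1_<bm>` (a + biomarker) and `model2_<bm>`
#' (c + biomarker). Biomarkers are z-transformed.
#'
#' @param endpoint "diabetes" or "coronary" (any label; the two known ones
#'   pick their covariate sets).
#' @param biomarkers biomarker column names.
#' @param cardio optional override of the cardiometabolic covariate list.
#' @return list with `base`, `cardio` and the named `specs` list.
#' @export
default_model_registry <- function(endpoint, biomarkers, cardio = NULL) {
  base <- c("age", "sex", "survey")
  if (is.null(cardio)) {
    cardio <- c("bmi", "sbp", "tchdl", "smoking", "alcohol", "phys_act")
    cardio <- c(cardio, if (endpoint == "coronary")
      c("parental_mi", "prevalent_diabetes") else "parental_diabetes")
  }
  specs <- list(
    model_a = model_spec("model_a", base, endpoint = endpoint),
    model_b = model_spec("model_b", c(base, biomarkers), z_terms = biomarkers,
                         endpoint = endpoint),
    model_c = model_spec("model_c", c(base, cardio), endpoint = endpoint),
    model_d = model_spec("model_d", c(base, cardio, biomarkers),
                         z_terms = biomarkers, endpoint = endpoint)
  )
  for (bm in biomarkers) {
    specs[[paste0("model1_", bm)]] <-
      model_spec(paste0("model1_", bm), c(base, bm), z_terms = bm,
                 endpoint = endpoint)
    specs[[paste0("model2_", bm)]] <-
      model_spec(paste0("model2_", bm), c(base, cardio, bm), z_terms = bm,
                 endpoint = endpoint)
  }
  list(base = base, cardio = cardio, specs = specs)
}

# bootstrap statistic factories: refit both models on the replicate
make_delta_auc_stat <- function(spec_new, spec_old, tau) {
  function(s) {
    f1 <- cch_cox(s, spec_new); f0 <- cch_cox(s, spec_old)
    ip <- ipcw_weights(s$time, s$status, tau, weights = s$weight)
    delta_auc(predict(f1, s, tau = tau), predict(f0, s, tau = tau),
              s$time, s$status, s$weight, tau, ip)
  }
}

make_idi_stat <- function(spec_new, spec_old, tau) {
  function(s) {
    f1 <- cch_cox(s, spec_new); f0 <- cch_cox(s, spec_old)
    ip <- ipcw_weights(s$time, s$status, tau, weights = s$weight)
    as.numeric(idi(predict(f1, s, tau = tau), predict(f0, s, tau = tau),
                   s$time, s$status, s$weight, tau, ip))
  }
}

analyse_endpoint <- function(cohort, design, endpoint, biomarkers, tau, cats,
                             boot, boot_comparisons, cardio = NULL,
                             verbose = TRUE) {
  say <- function(...) if (verbose) message("[", endpoint, "] ", ...)
  smp <- draw_subcohort(cohort, design, endpoint)
  say("sample: ", nrow(smp), " subjects (", sum(smp$is_case), " cases, ",
      sum(smp$in_subcohort), " subcohort)")
  reg <- default_model_registry(endpoint, biomarkers, cardio = cardio)
  fits <- lapply(reg$specs, function(sp) cch_cox(smp, sp))

  # significant subset: biomarkers with robust-Wald p < 0.05 for their own
  # coefficient in the cardiometabolic-adjusted single-biomarker model
  pvals <- vapply(biomarkers, function(bm) {
    hr <- hazard_ratios(fits[[paste0("model2_", bm)]])
    hr$p[hr$term == bm]
  }, numeric(1))
  subset_bm <- biomarkers[pvals < 0.05]
  say("significant biomarkers (model 2): ",
      if (length(subset_bm)) paste(subset_bm, collapse = ", ") else "none")
  if (length(subset_bm)) {
    fits$model_sig1 <- cch_cox(smp, model_spec(
      "model_sig1", c(reg$base, subset_bm), z_terms = subset_bm,
      endpoint = endpoint))
    fits$model_sig2 <- cch_cox(smp, model_spec(
      "model_sig2", c(reg$base, reg$cardio, subset_bm), z_terms = subset_bm,
      endpoint = endpoint))
  }

  # adjustment set 1: baseline age/sex/survey
  fits1 <- c(list(none = fits$model_a),
             stats::setNames(fits[paste0("model1_", biomarkers)], biomarkers),
             list(all13 = fits$model_b))
  if (length(subset_bm)) fits1$subset <- fits$model_sig1
  eval1 <- evaluate_models(smp, fits1, baseline = "none", tau = tau, cats = cats)

  # adjustment set 2: baseline adds cardiometabolic risk factors
  fits2 <- c(list(none = fits$model_c),
             stats::setNames(fits[paste0("model2_", biomarkers)], biomarkers),
             list(all13 = fits$model_d))
  if (length(subset_bm)) fits2$subset <- fits$model_sig2
  eval2 <- evaluate_models(smp, fits2, baseline = "none", tau = tau, cats = cats)

  # model c vs model a on the same weighting (the basic-vs-cardiometabolic
  # comparison quoted alongside the main tables)
  eval_ca <- evaluate_models(smp, list(none = fits$model_a, cardio = fits$model_c),
                             baseline = "none", tau = tau, cats = cats)

  s1 <- eval1$summary; s2 <- eval2$summary
  table_auc <- data.frame(
    biomarker = s1$model,
    auc1 = s1$auc, delta_auc1 = s1$delta_auc,
    auc2 = s2$auc[match(s1$model, s2$model)],
    delta_auc2 = s2$delta_auc[match(s1$model, s2$model)],
    stringsAsFactors = FALSE)
  table_accuracy <- data.frame(
    biomarker = s1$model,
    delta_aic1 = s1$delta_aic, idi1 = s1$idi, nri1 = s1$nri,
    delta_aic2 = s2$delta_aic[match(s1$model, s2$model)],
    idi2 = s2$idi[match(s1$model, s2$model)],
    nri2 = s2$nri[match(s1$model, s2$model)],
    stringsAsFactors = FALSE)

  boot_results <- list()
  if (!is.null(boot)) {
    comps <- list()
    if ("panel" %in% boot_comparisons) {
      comps[["delta_auc1_all13"]] <- make_delta_auc_stat(
        reg$specs$model_b, reg$specs$model_a, tau)
      comps[["delta_auc2_all13"]] <- make_delta_auc_stat(
        reg$specs$model_d, reg$specs$model_c, tau)
      comps[["idi2_all13"]] <- make_idi_stat(
        reg$specs$model_d, reg$specs$model_c, tau)
    }
    if ("all" %in% boot_comparisons) {
      for (bm in biomarkers) {
        comps[[paste0("delta_auc1_", bm)]] <- make_delta_auc_stat(
          reg$specs[[paste0("model1_", bm)]], reg$specs$model_a, tau)
        comps[[paste0("delta_auc2_", bm)]] <- make_delta_auc_stat(
          reg$specs[[paste0("model2_", bm)]], reg$specs$model_c, tau)
      }
    }
    for (nm in names(comps)) {
      say("bootstrap: ", nm, " (B = ", boot$B, ")")
      boot_results[[nm]] <- bootstrap_ci(comps[[nm]], smp, boot)
    }
  }

  list(endpoint = endpoint, sample = smp, registry = reg, fits = fits,
       eval1 = eval1, eval2 = eval2, eval_cardio_vs_basic = eval_ca,
       significant = subset_bm, table_auc = table_auc,
       table_accuracy = table_accuracy, boot = boot_results)
}

#' Run the full two-endpoint case-cohort analysis
#'
#' Simulates (or takes) a cohort, and for each endpoint draws the
#' stratified case-cohort sample, fits the whole model registry, computes
#' AUC(tau)/delta-AUC/IDI/NRI/delta-AIC for every biomarker and for the
#' full and significant-subset panels under both adjustment sets, and
#' optionally bootstrap percentile CIs for the panel comparisons. If
#' `outdir` is given, writes per-endpoint CSV tables, a JSON summary and
#' a plain-text run log.
#'
#' @param cohort a cohort table; if NULL, simulated from `config`.
#' @param config [sim_config()] used when `cohort` is NULL.
#' @param design a [sampling_design()].
#' @param endpoints endpoint labels (default: those in the cohort).
#' @param biomarkers biomarker columns (default: the cohort's panel).
#' @param tau risk horizon in years.
#' @param cats [nri_categories()] for the NRI.
#' @param boot optional [bootstrap_plan()]; NULL skips CIs.
#' @param boot_comparisons "panel" (full-panel comparisons only) and/or
#'   "all" (every per-biomarker delta-AUC).
#' @param cardio optional override of the cardiometabolic covariate list
#'   (used by the covariate-substitution sensitivity analysis).
#' @param outdir optional output directory.
#' @param verbose print progress messages.
#' @return object of class `cch_analysis`.
#' @export
run_full_analysis <- function(cohort = NULL, config = sim_config(),
                              design = sampling_design(),
                              endpoints = NULL, biomarkers = NULL,
                              tau = 10, cats = nri_categories(),
                              boot = NULL, boot_comparisons = "panel",
                              cardio = NULL, outdir = NULL, verbose = TRUE) {
  t0 <- Sys.time()
  if (is.null(cohort)) cohort <- simulate_cohort(config)
  endpoints <- endpoints %||% attr(cohort, "endpoints") %||%
    sub("^time_", "", grep("^time_", names(cohort), value = TRUE))
  biomarkers <- biomarkers %||% attr(cohort, "biomarkers")
  if (is.null(biomarkers)) stop("no biomarker columns identified")
  missing_bm <- setdiff(biomarkers, names(cohort))
  if (length(missing_bm))
    stop("biomarkers not in cohort: ", paste(missing_bm, collapse = ", "))

  results <- list()
  for (ep in endpoints) {
    results[[ep]] <- tryCatch(
      analyse_endpoint(cohort, design, ep, biomarkers, tau, cats,
                       boot, boot_comparisons, cardio = cardio,
                       verbose = verbose),
      error = function(e) stop("endpoint '", ep, "' failed: ",
                               conditionMessage(e), call. = FALSE))
  }
  out <- structure(list(endpoints = results, cohort = cohort, design = design,
                        biomarkers = biomarkers, tau = tau, cats = cats,
                        elapsed = as.numeric(difftime(Sys.time(), t0,
                                                      units = "secs"))),
                   class = "cch_analysis")
  if (!is.null(outdir)) write_analysis(out, outdir)
  out
}

# serialize tables, JSON summary and run log
write_analysis <- function(analysis, outdir) {
  dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
  summary_list <- list()
  for (ep in names(analysis$endpoints)) {
    res <- analysis$endpoints[[ep]]
    utils::write.csv(res$table_auc,
                     file.path(outdir, paste0("table_auc_", ep, ".csv")),
                     row.names = FALSE)
    utils::write.csv(res$table_accuracy,
                     file.path(outdir, paste0("table_accuracy_", ep, ".csv")),
                     row.names = FALSE)
    summary_list[[ep]] <- list(
      n_sample = nrow(res$sample),
      n_cases = sum(res$sample$is_case),
      n_subcohort = sum(res$sample$in_subcohort),
      significant_biomarkers = res$significant,
      auc = stats::setNames(res$table_auc$auc1, res$table_auc$biomarker),
      auc_adjusted = stats::setNames(res$table_auc$auc2,
                                     res$table_auc$biomarker),
      boot = lapply(res$boot, function(b)
        list(estimate = b$estimate, ci = c(b$ci_low, b$ci_high)))
    )
  }
  jsonlite::write_json(summary_list, file.path(outdir, "summary.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  log_lines <- c(
    paste0("run completed: ", format(Sys.time())),
    paste0("R version: ", R.version.string),
    paste0("cchpredict version: ",
           as.character(utils::packageVersion("cchpredict"))),
    paste0("design seed: ", analysis$design$seed,
           "; scheme: ", analysis$design$scheme),
    paste0("tau: ", analysis$tau, " years"),
    paste0("elapsed: ", round(analysis$elapsed, 1), " s"))
  writeLines(log_lines, file.path(outdir, "run.log"))
  invisible(outdir)
}

#' @export
print.cch_analysis <- function(x, ...) {
  cat("Case-cohort prediction analysis (tau =", x$tau, "years)\n")
  for (ep in names(x$endpoints)) {
    res <- x$endpoints[[ep]]
    cat("\nEndpoint:", ep, "-", sum(res$sample$is_case), "cases\n")
    rows <- res$table_auc$biomarker %in% c("none", "all13", "subset")
    print(res$table_auc[rows, ], digits = 3, row.names = FALSE)
  }
  invisible(x)
}

#' Sensitivity analyses around a base run
#'
#' Re-runs the pipeline (i) excluding a named list of biomarkers (e.g. the
#' four multiplex-assay markers), (ii) re-scoring the NRI under alternative
#' category grids on the already-computed predictions, and (iii)
#' substituting covariates in the cardiometabolic list (e.g. waist
#' circumference for BMI), and reports deltas against the base run's panel
#' AUCs.
#'
#' @param base a `cch_analysis` from [run_full_analysis()].
#' @param exclude_biomarkers biomarker names to drop (empty = no-op rerun).
#' @param alt_cats list of alternative [nri_categories()] grids.
#' @param substitute named character vector, e.g. `c(bmi = "waist")`.
#' @param verbose print progress.
#' @return list of class `cch_sensitivity` with elements `exclusion`
#'   (variant analysis + `deltas` data.frame), `nri_grids`, and
#'   `substitution` (or NULL where not requested).
#' @export
sensitivity_suite <- function(base, exclude_biomarkers = character(0),
                              alt_cats = list(nri_categories(c(0.02, 0.05, 0.10)),
                                              nri_categories(c(0.05, 0.10, 0.20))),
                              substitute = NULL, verbose = FALSE) {
  stopifnot(inherits(base, "cch_analysis"))
  out <- list()

  unknown <- setdiff(exclude_biomarkers, base$biomarkers)
  if (length(unknown)) stop("unknown biomarker name(s): ",
                            paste(unknown, collapse = ", "))
  keep <- setdiff(base$biomarkers, exclude_biomarkers)
  variant <- run_full_analysis(cohort = base$cohort, design = base$design,
                               endpoints = names(base$endpoints),
                               biomarkers = keep, tau = base$tau,
                               cats = base$cats, boot = NULL,
                               verbose = verbose)
  deltas <- list()
  for (ep in names(base$endpoints)) {
    b <- base$endpoints[[ep]]$table_auc
    v <- variant$endpoints[[ep]]$table_auc
    for (row in c("none", "all13")) {
      deltas[[length(deltas) + 1]] <- data.frame(
        endpoint = ep, model = row,
        auc1_base = b$auc1[b$biomarker == row],
        auc1_variant = v$auc1[v$biomarker == row],
        auc2_base = b$auc2[b$biomarker == row],
        auc2_variant = v$auc2[v$biomarker == row],
        stringsAsFactors = FALSE)
    }
  }
  out$exclusion <- list(excluded = exclude_biomarkers, analysis = variant,
                        deltas = do.call(rbind, deltas))

  # NRI under alternative grids, on the stored predictions (no refit)
  grid_rows <- list()
  for (ep in names(base$endpoints)) {
    res <- base$endpoints[[ep]]
    smp <- res$sample
    ip <- ipcw_weights(smp$time, smp$status, base$tau, weights = smp$weight)
    for (ev_name in c("eval1", "eval2")) {
      ev <- res[[ev_name]]
      if (!"all13" %in% colnames(ev$predictions)) next
      for (g in c(list(base$cats), alt_cats)) {
        nr <- nri(ev$predictions[, "all13"], ev$predictions[, "none"],
                  smp$time, smp$status, smp$weight, base$tau,
                  cats = g, ipcw = ip)
        grid_rows[[length(grid_rows) + 1]] <- data.frame(
          endpoint = ep, adjustment = ev_name,
          cuts = paste(as.numeric(g), collapse = "/"),
          nri = nr$nri, nri_case = nr$nri_case, nri_control = nr$nri_control,
          stringsAsFactors = FALSE)
      }
    }
  }
  out$nri_grids <- do.call(rbind, grid_rows)

  if (!is.null(substitute)) {
    for (i in seq_along(substitute)) {
      if (!substitute[[i]] %in% names(base$cohort))
        stop("substitution column not in cohort: ", substitute[[i]])
    }
    sub_analysis <- list()
    for (ep in names(base$endpoints)) {
      cardio <- base$endpoints[[ep]]$registry$cardio
      for (nm in names(substitute)) cardio[cardio == nm] <- substitute[[nm]]
      sub_analysis[[ep]] <- run_full_analysis(
        cohort = base$cohort, design = base$design, endpoints = ep,
        biomarkers = base$biomarkers, tau = base$tau, cats = base$cats,
        boot = NULL, cardio = cardio, verbose = verbose)$endpoints[[ep]]
    }
    out$substitution <- list(map = substitute, endpoints = sub_analysis)
  }
  class(out) <- "cch_sensitivity"
  out
}
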