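# Experiment orchestration: baselines -> GA -> bullseye report ->
# probability shifts -> (both modes) agreement + stability, with all
# artifacts written as JSON/CSV alongside a run log.

log_line <- function(con, fmt, ...) {
  msg <- sprintf(fmt, ...)
  if (!is.null(con)) writeLines(msg, con)
  message(msg)
}

#' Run a full specification-optimization experiment
#'
#' Given a cohort (loaded from CSV or generated synthetically), fits both
#' single-level baselines, runs the GA under the requested specification
#' mode(s), evaluates each best solution with the bullseye subgroup report
#' and predicted-probability shifts, and - when both modes are run -
#' summarizes the agreement between the two selections and the stability of
#' each hall of fame. All randomness flows from `config$rng_seed` (GA,
#' generator) and `config$fold_seed` (CV folds); identical configurations
#' produce identical artifacts.
#'
#' @param cohort an `ed_cohort`, or `NULL` to simulate one.
#' @param synthetic a [synthetic_config()] used when `cohort` is `NULL`.
#' @param modes specification modes to search: subset of
#'   `c("flattened", "hierarchical")`.
#' @param config a [ga_config()]; its `mode` field is overridden per run.
#' @param out_dir output directory for artifacts (`run_<mode>.json`,
#'   `bullseye_<mode>.csv`, `shifts_<mode>.csv`, `stability_<mode>.csv`,
#'   `agreement.json`, `log.txt`); `NULL` writes nothing.
#' @param bin_width probability-shift histogram bin width.
#' @param truth optional `ground_truth` (attached recovery metrics when the
#'   cohort is synthetic).
#' @return An `experiment_result` list: per-mode `runs` (each with the
#'   `ga_result`, `cv_result`s, `bullseye_report`, shifts and stability),
#'   the shared baselines, and `agreement` when both modes ran.
#' @export
run_experiment <- function(cohort = NULL, synthetic = NULL,
                           modes = c("flattened", "hierarchical"),
                           config = ga_config(), out_dir = NULL,
                           bin_width = 0.01, truth = NULL) {
  modes <- match.arg(modes, c("flattened", "hierarchical"),
                     several.ok = TRUE)
  if (is.null(cohort) == is.null(synthetic)) {
    stop_evospec("provide exactly one input source: cohort or synthetic",
                 "evospec_validation_error")
  }
  logcon <- NULL
  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    logcon <- file(file.path(out_dir, "log.txt"), open = "wt")
    on.exit(close(logcon), add = TRUE)
  }
  if (is.null(cohort)) {
    sim <- generate_cohort(synthetic)
    cohort <- sim$cohort
    truth <- sim$truth
    log_line(logcon, "simulated cohort: %d visits, %d complaints, seed %d",
             nrow(cohort$records), n_complaints(cohort$hierarchy),
             synthetic$seed)
  }
  log_line(logcon, "seeds: rng_seed=%d fold_seed=%d",
           config$rng_seed, config$fold_seed)

  baselines <- list(
    complaints_only = cv_fitness(cohort, mode = "complaints_only",
                                 k = config$k_folds,
                                 fold_seed = config$fold_seed,
                                 ridge = config$ridge),
    categories_only = cv_fitness(cohort, mode = "categories_only",
                                 k = config$k_folds,
                                 fold_seed = config$fold_seed,
                                 ridge = config$ridge)
  )
  log_line(logcon, "baseline AUC: complaints_only=%.4f categories_only=%.4f",
           baselines$complaints_only$auc, baselines$categories_only$auc)

  runs <- list()
  for (mode in modes) {
    cfg <- config
    cfg$mode <- mode
    ga <- evolve(cohort, cfg)
    for (g in seq_len(nrow(ga$history))) {
      log_line(logcon, "[%s] generation %d: best=%.6f mean=%.6f", mode,
               ga$history$generation[g], ga$history$best[g],
               ga$history$mean[g])
    }
    ga_cv <- cv_fitness(cohort, ga$best_mask, mode, k = cfg$k_folds,
                        fold_seed = cfg$fold_seed, ridge = cfg$ridge)
    report <- bullseye_report(cohort, ga_cv, baselines$complaints_only,
                              baselines$categories_only, ga$best_mask)
    shifts <- lapply(baselines, function(b) {
      probability_shifts(ga_cv, b, report$subgroup, bin_width = bin_width)
    })
    stability <- selection_stability(ga)
    recovery <- if (!is.null(truth)) recovery_metrics(ga, truth)
    runs[[mode]] <- list(ga = ga, cv = ga_cv, bullseye = report,
                         shifts = shifts, stability = stability,
                         recovery = recovery)
    log_line(logcon, "[%s] best CV-AUC %.4f, %d/%d complaints selected",
             mode, ga$best_fitness, sum(ga$best_mask),
             length(ga$best_mask))

    if (!is.null(out_dir)) {
      jsonlite::write_json(
        list(config = unclass(cfg),
             best_mask = mask_key(ga$best_mask),
             best_fitness = ga$best_fitness,
             history = ga$history,
             hall_of_fame = list(
               masks = apply(ga$hall_of_fame$masks, 1L, mask_key),
               fitness = ga$hall_of_fame$fitness),
             evaluations = ga$evaluations),
        file.path(out_dir, paste0("run_", mode, ".json")),
        auto_unbox = TRUE, digits = NA)
      write.csv(report$cells,
                file.path(out_dir, paste0("bullseye_", mode, ".csv")),
                row.names = FALSE)
      shift_df <- do.call(rbind, lapply(names(shifts), function(b) {
        cbind(baseline = b, shifts[[b]]$histogram)
      }))
      write.csv(shift_df[shift_df$count > 0, ],
                file.path(out_dir, paste0("shifts_", mode, ".csv")),
                row.names = FALSE)
      write.csv(
        data.frame(complaint = cohort$hierarchy$complaints,
                   inclusion_fraction = stability$inclusion_fraction,
                   inconsistent = stability$inconsistent),
        file.path(out_dir, paste0("stability_", mode, ".csv")),
        row.names = FALSE)
    }
  }

  agreement <- NULL
  if (all(c("flattened", "hierarchical") %in% names(runs))) {
    agreement <- mask_agreement(runs$flattened$ga$best_mask,
                                runs$hierarchical$ga$best_mask)
    log_line(logcon,
             "agreement: jointly selected %.1f%% + jointly excluded %.1f%% = %.1f%%",
             agreement$jointly_selected_pct, agreement$jointly_excluded_pct,
             agreement$total_agreement_pct)
    if (!is.null(out_dir)) {
      jsonlite::write_json(unclass(agreement),
                           file.path(out_dir, "agreement.json"),
                           auto_unbox = TRUE, digits = NA)
    }
  }

  structure(list(runs = runs, baselines = baselines, agreement = agreement,
                 truth = truth, config = config),
            class = "experiment_result")
}

#' @export
print.experiment_result <- function(x, ...) {
  cat("specification-optimization experiment\n")
  cat(sprintf("  baseline AUC: complaints_only %.4f, categories_only %.4f\n",
              x$baselines$complaints_only$auc,
              x$baselines$categories_only$auc))
  for (mode in names(x$runs)) {
    r <- x$runs[[mode]]
    cat(sprintf("  %s GA: best CV-AUC %.4f (%d/%d complaints selected)\n",
                mode, r$ga$best_fitness, sum(r$ga$best_mask),
                length(r$ga$best_mask)))
  }
  if (!is.null(x$agreement)) {
    cat(sprintf("  mode agreement: %.1f%%\n",
                x$agreement$total_agreement_pct))
  }
  invisible(x)
}
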