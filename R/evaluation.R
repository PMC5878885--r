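# Model evaluation: bullseye subgroup partition, DeLong tests for correlated
# AUCs, predicted-probability shifts, and flattened-vs-hierarchical agreement
# and stability summaries.

#' Bullseye partition of a cohort induced by a specification mask
#'
#' * `inner`: the record's own complaint is selected (directly affected);
#' * `middle`: the complaint is unselected but a sibling complaint in the
#'   same category is selected, so the composition of the record's category
#'   is altered (indirectly affected);
#' * `outer`: no complaint in the record's category is selected.
#'
#' @param cohort an `ed_cohort`.
#' @param mask specification mask aligned with the cohort's hierarchy.
#' @return Character vector (`"inner"`/`"middle"`/`"outer"`), one per record.
#' @export
partition_bullseye <- function(cohort, mask) {
  ctx <- design_context(cohort)
  mask <- check_mask(mask, length(ctx$hierarchy$complaints))
  cat_has_sel <- tapply(mask, ctx$category_of, max)
  cat_hit <- as.logical(cat_has_sel[ctx$category_code])
  own_sel <- mask[ctx$complaint_code] == 1L
  ifelse(own_sel, "inner", ifelse(cat_hit, "middle", "outer"))
}

# Per-observation placement components of the Mann-Whitney AUC, via
# mid-ranks: v10[i] is the fraction of negatives scored below positive i
# (ties 1/2), v01[j] the fraction of positives scored above negative j.
delong_placements <- function(scores, labels) {
  pos <- labels == 1L
  m <- sum(pos)
  n <- sum(!pos)
  if (m == 0L || n == 0L) {
    stop_evospec("DeLong components undefined: both classes required",
                 "evospec_degenerate_error")
  }
  r_all <- rank(scores, ties.method = "average")
  v10 <- (r_all[pos] - rank(scores[pos], ties.method = "average")) / n
  v01 <- 1 - (r_all[!pos] - rank(scores[!pos], ties.method = "average")) / m
  list(v10 = v10, v01 = v01, auc = mean(v10), m = m, n = n)
}

#' DeLong test for the difference between two correlated AUCs
#'
#' Nonparametric comparison of two score vectors for the same observations,
#' using the per-observation placement components of each AUC to estimate
#' the variance of the paired difference; `z = (auc_a - auc_b) / sqrt(var)`
#' with a two-sided normal p-value.
#'
#' @param probs_a,probs_b aligned score (probability) vectors for the same
#'   observations.
#' @param labels binary 0/1 outcome vector.
#' @return List with `auc_a`, `auc_b`, `var_diff`, `z`, `p`.
#' @export
delong_compare <- function(probs_a, probs_b, labels) {
  if (length(probs_a) != length(probs_b) ||
      length(probs_a) != length(labels)) {
    stop_evospec("probs_a, probs_b and labels must be aligned",
                 "evospec_validation_error")
  }
  labels <- as.integer(labels)
  ca <- delong_placements(probs_a, labels)
  cb <- delong_placements(probs_b, labels)
  s10 <- cov(cbind(ca$v10, cb$v10))
  s01 <- cov(cbind(ca$v01, cb$v01))
  var_diff <- (s10[1, 1] + s10[2, 2] - 2 * s10[1, 2]) / ca$m +
    (s01[1, 1] + s01[2, 2] - 2 * s01[1, 2]) / ca$n
  d <- ca$auc - cb$auc
  if (var_diff <= 0) {
    if (isTRUE(all.equal(d, 0))) {
      z <- 0
    } else {
      stop_evospec(
        "zero DeLong variance with unequal AUCs: degenerate comparison",
        "evospec_degenerate_error")
    }
  } else {
    z <- d / sqrt(var_diff)
  }
  list(auc_a = ca$auc, auc_b = cb$auc, var_diff = max(var_diff, 0),
       z = z, p = 2 * pnorm(-abs(z)))
}

significance_stars <- function(p) {
  if (is.na(p)) return("")
  if (p < 0.001) "***" else if (p < 0.01) "**" else if (p < 0.05) "*" else ""
}

#' Bullseye evaluation of the GA model against both baselines
#'
#' Computes the AUC of the GA model and of the two single-level baselines
#' within each bullseye subgroup and overall (subgroup AUCs use the pooled
#' out-of-fold probabilities restricted to that subgroup), with paired
#' DeLong comparisons of the GA model against each baseline in every cell.
#' A subgroup containing a single outcome class gets `NA` AUCs for that cell
#' rather than an imputed value.
#'
#' @param cohort an `ed_cohort`.
#' @param ga_cv `cv_result` of the GA-selected model.
#' @param baseline_complaints_cv `cv_result` of the complaints-only baseline.
#' @param baseline_categories_cv `cv_result` of the categories-only baseline.
#' @param mask the GA mask that defines the subgroups.
#' @return A `bullseye_report`: `subgroup` per record, a `cells` data frame
#'   (region x model AUC, sizes, DeLong z/p and significance stars for GA vs
#'   each baseline).
#' @export
bullseye_report <- function(cohort, ga_cv, baseline_complaints_cv,
                            baseline_categories_cv, mask) {
  cvs <- list(ga = ga_cv, complaints_only = baseline_complaints_cv,
              categories_only = baseline_categories_cv)
  folds <- lapply(cvs, function(cv) cv$fold_assignment)
  if (!all(vapply(folds, identical, logical(1), folds[[1]]))) {
    stop_evospec("all models must share one fold assignment",
                 "evospec_validation_error")
  }
  subgroup <- partition_bullseye(cohort, mask)
  y <- cohort$records$outcome
  regions <- list(inner = subgroup == "inner", middle = subgroup == "middle",
                  outer = subgroup == "outer",
                  overall = rep(TRUE, length(subgroup)))
  cells <- do.call(rbind, lapply(names(regions), function(rg) {
    sel <- regions[[rg]]
    ys <- y[sel]
    defined <- sum(sel) > 0L && length(unique(ys)) == 2L
    aucs <- vapply(cvs, function(cv) {
      if (defined) auc(cv$oof_probabilities[sel], ys) else NA_real_
    }, numeric(1))
    cmp <- lapply(cvs[c("complaints_only", "categories_only")], function(cv) {
      if (!defined) return(list(z = NA_real_, p = NA_real_))
      delong_compare(cvs$ga$oof_probabilities[sel],
                     cv$oof_probabilities[sel], ys)
    })
    data.frame(
      region = rg, n = sum(sel), events = sum(ys),
      auc_ga = aucs[["ga"]],
      auc_complaints_only = aucs[["complaints_only"]],
      auc_categories_only = aucs[["categories_only"]],
      z_vs_complaints = cmp$complaints_only$z,
      p_vs_complaints = cmp$complaints_only$p,
      stars_vs_complaints = significance_stars(cmp$complaints_only$p),
      z_vs_categories = cmp$categories_only$z,
      p_vs_categories = cmp$categories_only$p,
      stars_vs_categories = significance_stars(cmp$categories_only$p),
      stringsAsFactors = FALSE
    )
  }))
  rownames(cells) <- NULL
  structure(list(subgroup = subgroup, cells = cells, mask = mask),
            class = "bullseye_report")
}

#' @export
print.bullseye_report <- function(x, ...) {
  cat("bullseye evaluation (GA vs baselines)\n")
  print(x$cells[, c("region", "n", "events", "auc_ga",
                    "auc_complaints_only", "auc_categories_only",
                    "stars_vs_complaints", "stars_vs_categories")],
        row.names = FALSE, digits = 4)
  invisible(x)
}

#' Per-subgroup histogram of predicted-probability shifts
#'
#' Differences `ga probability - baseline probability` per record, binned
#' with a fixed width over `[-1, 1]`; counts are reported per subgroup (and
#' are typically displayed on a logarithmic count scale).
#'
#' @param ga_cv,baseline_cv aligned `cv_result`s.
#' @param subgroups subgroup label per record (from [partition_bullseye()]).
#' @param bin_width histogram bin width (default 0.01).
#' @return List with `differences` and a `histogram` data frame
#'   (subgroup, bin_lower, bin_upper, count).
#' @export
probability_shifts <- function(ga_cv, baseline_cv, subgroups,
                               bin_width = 0.01) {
  d <- ga_cv$oof_probabilities - baseline_cv$oof_probabilities
  if (length(d) != length(subgroups)) {
    stop_evospec("subgroups must align with the probability vectors",
                 "evospec_validation_error")
  }
  breaks <- seq(-1, 1, by = bin_width)
  if (breaks[length(breaks)] < 1) breaks <- c(breaks, 1)
  nbins <- length(breaks) - 1L
  hist_df <- do.call(rbind, lapply(unique(subgroups), function(sg) {
    # half-open bins [lower, upper), last bin closed at 1
    bin <- findInterval(d[subgroups == sg], breaks, rightmost.closed = TRUE)
    bin <- pmin(pmax(bin, 1L), nbins)
    counts <- tabulate(bin, nbins = nbins)
    data.frame(subgroup = sg,
               bin_lower = breaks[-length(breaks)],
               bin_upper = breaks[-1],
               count = counts, stringsAsFactors = FALSE)
  }))
  list(differences = d, histogram = hist_df)
}

#' Agreement between the flattened and hierarchical selections
#'
#' Counts each of the `n` complaints once: jointly selected (both masks 1),
#' jointly excluded (both 0), and disagreement (the remainder), reported as
#' percentages of `n` that total 100.
#'
#' @param mask_flattened,mask_hierarchical equal-length binary masks.
#' @return An `agreement_summary`: `jointly_selected_pct`,
#'   `jointly_excluded_pct`, `disagreement_pct`, `total_agreement_pct`, `n`.
#' @export
mask_agreement <- function(mask_flattened, mask_hierarchical) {
  if (length(mask_flattened) != length(mask_hierarchical)) {
    stop_evospec("masks must have equal length", "evospec_validation_error")
  }
  a <- as.integer(mask_flattened)
  b <- as.integer(mask_hierarchical)
  n <- length(a)
  sel <- sum(a == 1L & b == 1L)
  exc <- sum(a == 0L & b == 0L)
  structure(
    list(jointly_selected_pct = 100 * sel / n,
         jointly_excluded_pct = 100 * exc / n,
         disagreement_pct = 100 * (n - sel - exc) / n,
         total_agreement_pct = 100 * (sel + exc) / n,
         n = n),
    class = "agreement_summary"
  )
}

#' @export
print.agreement_summary <- function(x, ...) {
  cat(sprintf(paste0(
    "mask agreement over %d complaints:\n",
    "  jointly selected %.1f%% + jointly excluded %.1f%% = %.1f%% agreement",
    " (%.1f%% disagreement)\n"),
    x$n, x$jointly_selected_pct, x$jointly_excluded_pct,
    x$total_agreement_pct, x$disagreement_pct))
  invisible(x)
}

#' Selection stability across the top candidate masks of a run
#'
#' For each complaint, the fraction of the top-M masks that select it. A
#' complaint is *inconsistent* when that fraction is strictly between 0 and
#' 1 (e.g. one included in 19 of 20 top candidates has fraction 0.95 and
#' counts as inconsistent, though it leans strongly toward inclusion).
#'
#' @param hall_of_fame a `ga_result`, its `hall_of_fame` element, or a mask
#'   matrix with at least two rows.
#' @return List with `inclusion_fraction` (per complaint),
#'   `inconsistent` (logical per complaint) and
#'   `inconsistent_fraction` (share of complaints inconsistent).
#' @export
selection_stability <- function(hall_of_fame) {
  masks <- hall_of_fame
  if (inherits(masks, "ga_result")) masks <- masks$hall_of_fame
  if (is.list(masks) && !is.null(masks$masks)) masks <- masks$masks
  masks <- as.matrix(masks)
  if (nrow(masks) < 2L) {
    stop_evospec("stability needs at least 2 masks",
                 "evospec_validation_error")
  }
  frac <- colMeans(masks)
  inconsistent <- frac > 0 & frac < 1
  list(inclusion_fraction = frac, inconsistent = inconsistent,
       inconsistent_fraction = mean(inconsistent))
}
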