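# Synthetic ED cohort generator with known ground truth: a two-level
# complaint hierarchy, the standard triage predictor blocks, a rare binary
# critical-care outcome driven by a logistic model with category-level and
# complaint-level effects, and long-tailed complaint frequencies.

# Marginal category distributions used for the non-complaint predictors.
# Chosen once to look like an adult ED population: a front-loaded age
# pyramid, ~30% ambulance arrivals, vitals concentrated in the normal range
# with thin abnormal tails.
SYNTH_STATIC_PROBS <- list(
  age_band = c(0.22, 0.18, 0.16, 0.14, 0.12, 0.09, 0.06, 0.03),
  gender = c(0.53, 0.47),
  arrival_mode = c(0.30, 0.70),
  temperature = c(0.01, 0.05, 0.80, 0.10, 0.04),
  pulse = c(0.01, 0.05, 0.74, 0.06, 0.07, 0.04, 0.03),
  respiratory_rate = c(0.02, 0.06, 0.70, 0.17, 0.05),
  blood_pressure = c(0.03, 0.05, 0.78, 0.10, 0.04),
  oxygen_saturation = c(0.03, 0.07, 0.90)
)

#' Configuration for the synthetic ED cohort generator
#'
#' Defaults define the package's reference simulation: 5 categories of 8
#' complaints each (n = 40), 50,000 visits, 8 informative complaints with
#' log-odds effects of +/- 1, category effects drawn from N(0, 0.5), a 3%
#' critical-outcome prevalence, power-law complaint frequencies (exponent
#' 1.2) emulating the long tail of real chief-complaint distributions, and
#' 5% vital-sign missingness.
#'
#' @param n_patients number of visits.
#' @param n_categories number of complaint categories.
#' @param complaints_per_category integer (or min/max pair) of complaints in
#'   each category.
#' @param informative_complaint_count number of complaints with a true
#'   specific effect (the set `S`).
#' @param specific_effect absolute log-odds effect of an informative
#'   complaint; half of `S` receives `+specific_effect`, half `-`.
#' @param category_effect_sd SD of the N(0, sd) category-level log-odds
#'   effects.
#' @param demo_effect_sd SD of the N(0, sd) per-level demographic/vital
#'   log-odds effects.
#' @param target_prevalence outcome prevalence the intercept is calibrated
#'   to (default 0.03).
#' @param freq_exponent power-law exponent of the complaint frequency
#'   distribution.
#' @param missing_rate probability each vital sign is missing.
#' @param seed RNG seed; the generator is fully seed-reproducible.
#' @return A `synthetic_config` list.
#' @export
synthetic_config <- function(n_patients = 50000L, n_categories = 5L,
                             complaints_per_category = 8L,
                             informative_complaint_count = 8L,
                             specific_effect = 1.0,
                             category_effect_sd = 0.5,
                             demo_effect_sd = 0.3,
                             target_prevalence = 0.03,
                             freq_exponent = 1.2,
                             missing_rate = 0.05,
                             seed = 1L) {
  cfg <- list(n_patients = as.integer(n_patients),
              n_categories = as.integer(n_categories),
              complaints_per_category =
                as.integer(rep_len(complaints_per_category, 2L)),
              informative_complaint_count =
                as.integer(informative_complaint_count),
              specific_effect = specific_effect,
              category_effect_sd = category_effect_sd,
              demo_effect_sd = demo_effect_sd,
              target_prevalence = target_prevalence,
              freq_exponent = freq_exponent,
              missing_rate = missing_rate,
              seed = as.integer(seed))
  if (cfg$target_prevalence <= 0 || cfg$target_prevalence >= 1) {
    stop_evospec("target_prevalence must be in (0, 1)",
                 "evospec_validation_error")
  }
  if (cfg$n_patients < 1L || cfg$n_categories < 1L ||
      any(cfg$complaints_per_category < 1L)) {
    stop_evospec("counts must be positive", "evospec_validation_error")
  }
  structure(cfg, class = "synthetic_config")
}

# Calibrate the intercept so that the mean event probability over the
# realized linear predictors equals the target prevalence.
calibrate_intercept <- function(lp, target) {
  f <- function(b0) mean(plogis(b0 + lp)) - target
  lo <- -30
  hi <- 10
  if (f(lo) > 0 || f(hi) < 0) {
    stop_evospec(
      "target prevalence unreachable given the configured effects",
      "evospec_calibration_error")
  }
  uniroot(f, c(lo, hi), tol = 1e-10)$root
}

#' Generate a synthetic ED cohort with known ground truth
#'
#' Complaints are assigned from a power-law frequency distribution over the
#' hierarchy; demographics and vitals are drawn categorically with the
#' configured missingness; the binary outcome is drawn from
#' `logit(p) = intercept + static effects + category effect +
#' specific effect * 1[complaint in S]`, with the intercept calibrated by
#' root finding so the expected prevalence matches the target. Informative
#' complaints are sampled from mid-frequency ranks (between roughly the
#' 25th and 75th frequency percentiles) so that recovering them is neither
#' trivial nor hopeless, and half of them raise risk while half lower it.
#'
#' @param config a [synthetic_config()].
#' @return List with `cohort` (an `ed_cohort`) and `truth` (a `ground_truth`
#'   list: informative set `S` with signed effects, category and
#'   per-level static effects, calibrated intercept, config echo).
#' @export
generate_cohort <- function(config = synthetic_config()) {
  stopifnot(inherits(config, "synthetic_config"))
  with_seed(config$seed, {
    # hierarchy
    sizes <- if (config$complaints_per_category[1] ==
                 config$complaints_per_category[2]) {
      rep(config$complaints_per_category[1], config$n_categories)
    } else {
      sample(seq(config$complaints_per_category[1],
                 config$complaints_per_category[2]),
             config$n_categories, replace = TRUE)
    }
    categories <- sprintf("category_%02d", seq_len(config$n_categories))
    parent <- unlist(lapply(seq_len(config$n_categories), function(ci) {
      stats::setNames(rep(categories[ci], sizes[ci]),
                      sprintf("complaint_%02d_%02d", ci, seq_len(sizes[ci])))
    }))
    hierarchy <- complaint_hierarchy(parent)
    n <- n_complaints(hierarchy)
    if (config$informative_complaint_count > n) {
      stop_evospec("informative_complaint_count exceeds total complaints",
                   "evospec_validation_error")
    }

    # power-law complaint frequencies; ranks assigned randomly to complaints
    ranks <- sample.int(n)
    freq <- ranks^(-config$freq_exponent)
    freq <- freq / sum(freq)

    # informative set from mid-frequency complaints: under a power law,
    # log-frequency is linear in log-rank, so the middle of the frequency
    # scale is the middle half of the log-rank range - neither the
    # ubiquitous head (trivial to recover) nor the sparse tail (too few
    # events for any effect to be identifiable)
    mid <- which(ranks >= max(2, ceiling(n^0.25)) & ranks <= floor(n^0.75))
    pool <- if (length(mid) >= config$informative_complaint_count) {
      mid
    } else {
      order(ranks)  # fall back to all, most frequent first
    }
    s_idx <- sort(sample(pool, config$informative_complaint_count))
    delta <- numeric(n)
    if (length(s_idx)) {
      signs <- rep(c(1, -1), length.out = length(s_idx))
      delta[s_idx] <- config$specific_effect * sample(signs)
    }

    gamma <- rnorm(config$n_categories, 0, config$category_effect_sd)
    static_effects <- lapply(names(SYNTH_STATIC_PROBS), function(block) {
      lv <- predictor_levels(block)
      eff <- rnorm(length(lv), 0, config$demo_effect_sd)
      eff[1] <- 0  # first level is the anchor
      stats::setNames(eff, lv)
    })
    names(static_effects) <- names(SYNTH_STATIC_PROBS)
    # missing vitals carry no effect contribution
    for (v in VITAL_NAMES) static_effects[[v]]["missing"] <- 0

    n_pat <- config$n_patients
    complaint_code <- sample.int(n, n_pat, replace = TRUE, prob = freq)
    category_code <- match(unname(hierarchy$parent[hierarchy$complaints]),
                           hierarchy$categories)[complaint_code]

    records <- data.frame(row.names = seq_len(n_pat))
    lp <- numeric(n_pat)
    for (block in names(SYNTH_STATIC_PROBS)) {
      lv <- predictor_levels(block)
      probs <- SYNTH_STATIC_PROBS[[block]]
      if (block %in% VITAL_NAMES) {
        probs <- c(probs * (1 - config$missing_rate), config$missing_rate)
      }
      code <- sample.int(length(lv), n_pat, replace = TRUE, prob = probs)
      records[[block]] <- lv[code]
      lp <- lp + static_effects[[block]][code]
    }
    lp <- lp + gamma[category_code] + delta[complaint_code]

    intercept <- calibrate_intercept(lp, config$target_prevalence)
    prob <- plogis(intercept + lp)
    outcome <- rbinom(n_pat, 1L, prob)
    if (length(unique(outcome)) < 2L) {
      stop_evospec(
        "degenerate draw: cohort has a single outcome class; increase n",
        "evospec_calibration_error")
    }
    records$complaint <- hierarchy$complaints[complaint_code]
    records$outcome <- outcome

    truth <- structure(
      list(informative = stats::setNames(delta[s_idx],
                                         hierarchy$complaints[s_idx]),
           informative_mask = as.integer(seq_len(n) %in% s_idx),
           category_effects = stats::setNames(gamma, categories),
           static_effects = static_effects,
           intercept = intercept,
           complaint_frequencies = stats::setNames(freq,
                                                   hierarchy$complaints),
           config = config),
      class = "ground_truth")

    list(cohort = new_cohort(records, hierarchy), truth = truth)
  })
}

#' Sensitivity and specificity of a recovered complaint selection
#'
#' Compares a selection mask (or the best mask of a `ga_result`) with the
#' generator's informative set `S`: sensitivity is the fraction of `S`
#' selected, specificity the fraction of non-informative complaints
#' excluded.
#'
#' @param ga_result a `ga_result`, or a binary mask.
#' @param truth the `ground_truth` returned by [generate_cohort()].
#' @return List with `sensitivity` and `specificity`.
#' @export
recovery_metrics <- function(ga_result, truth) {
  mask <- if (inherits(ga_result, "ga_result")) {
    ga_result$best_mask
  } else {
    as.integer(ga_result)
  }
  s <- truth$informative_mask
  if (length(mask) != length(s)) {
    stop_evospec("mask length does not match the truth's hierarchy",
                 "evospec_validation_error")
  }
  n_s <- sum(s == 1L)
  n_sc <- sum(s == 0L)
  list(
    sensitivity = if (n_s > 0L) sum(mask == 1L & s == 1L) / n_s else NA_real_,
    specificity = if (n_sc > 0L) sum(mask == 0L & s == 0L) / n_sc else NA_real_
  )
}
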