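# Shared fixtures, built in code.

# Three-category hierarchy used throughout the structural tests; mirrors the
# canonical abdominal-pain example.
abdominal_hierarchy <- function() {
  complaint_hierarchy(c(
    "abdominal cramping" = "abdominal pain",
    "abdominal mass"     = "abdominal pain",
    "abdominal swelling" = "abdominal pain",
    "headache"           = "neurological",
    "dizziness"          = "neurological",
    "cough"              = "respiratory"
  ))
}

# Deterministic hand-rolled record block: cycles through all predictor
# levels so every block is exercised; outcome from a fixed pattern.
make_records <- function(n, hierarchy, outcome = NULL,
                         complaints = NULL, seed = 1) {
  withr::with_seed(seed, {
    cplts <- hierarchy$complaints
    data.frame(
      age_band = sample(predictor_levels("age_band"), n, replace = TRUE),
      gender = sample(predictor_levels("gender"), n, replace = TRUE),
      arrival_mode = sample(predictor_levels("arrival_mode"), n,
                            replace = TRUE),
      temperature = sample(predictor_levels("temperature"), n,
                           replace = TRUE),
      pulse = sample(predictor_levels("pulse"), n, replace = TRUE),
      respiratory_rate = sample(predictor_levels("respiratory_rate"), n,
                                replace = TRUE),
      blood_pressure = sample(predictor_levels("blood_pressure"), n,
                              replace = TRUE),
      oxygen_saturation = sample(predictor_levels("oxygen_saturation"), n,
                                 replace = TRUE),
      complaint = if (is.null(complaints)) {
        sample(cplts, n, replace = TRUE)
      } else {
        rep_len(complaints, n)
      },
      outcome = if (is.null(outcome)) {
        rep_len(c(1L, 0L, 0L, 0L), n)
      } else {
        rep_len(outcome, n)
      },
      stringsAsFactors = FALSE
    )
  })
}

small_cohort <- function(n = 60, seed = 1) {
  h <- abdominal_hierarchy()
  new_cohort(make_records(n, h, seed = seed), h)
}

# Small synthetic cohort presets for search / fitness tests.
tiny_sim <- function(n_patients = 4000, seed = 5, ...) {
  generate_cohort(synthetic_config(
    n_patients = n_patients, n_categories = 2, complaints_per_category = 5,
    informative_complaint_count = 3, specific_effect = 1.2,
    target_prevalence = 0.08, seed = seed, ...))
}

# Brute-force all-pairs AUC oracle (ties count 1/2).
auc_bruteforce <- function(scores, labels) {
  pos <- scores[labels == 1]
  neg <- scores[labels == 0]
  total <- 0
  for (p in pos) total <- total + sum(p > neg) + 0.5 * sum(p == neg)
  total / (length(pos) * length(neg))
}
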