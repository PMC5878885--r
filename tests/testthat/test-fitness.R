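test_that("logistic slope matches the closed-form log odds ratio", {
  # saturated 2x2: exposed 30/100 events, unexposed 10/100 events
  values <- matrix(rep(c(1L, 0L), each = 100), ncol = 1,
                   dimnames = list(NULL, "exposed"))
  outcome <- c(rep(1L, 30), rep(0L, 70), rep(1L, 10), rep(0L, 90))
  fit <- fit_logistic(list(values = values, outcome = outcome), ridge = 0)
  expect_equal(unname(fit$coefficients["exposed"]),
               log((30 * 90) / (70 * 10)), tolerance = 1e-7)
  expect_equal(unname(fit$coefficients["(Intercept)"]),
               qlogis(0.10), tolerance = 1e-7)
})

test_that("intercept-only fit returns the logit of prevalence", {
  values <- matrix(integer(0), nrow = 20, ncol = 0)
  outcome <- rep(c(1L, 0L, 0L, 0L), 5)
  fit <- fit_logistic(list(values = values, outcome = outcome), ridge = 0)
  expect_equal(unname(fit$coefficients), qlogis(0.25), tolerance = 1e-8)
})

test_that("a predictor independent of the outcome gets slope zero", {
  values <- matrix(rep(c(1L, 0L), each = 50), ncol = 1,
                   dimnames = list(NULL, "x"))
  outcome <- rep(c(rep(1L, 10), rep(0L, 40)), 2)  # identical event rates
  fit <- fit_logistic(list(values = values, outcome = outcome), ridge = 0)
  expect_equal(unname(fit$coefficients["x"]), 0, tolerance = 1e-7)
})

test_that("IRLS agrees with glm on a multi-column indicator design", {
  co <- small_cohort(400, seed = 9)
  d <- build_design(co, NULL, "categories_only", drop_reference = TRUE)
  fit <- fit_logistic(d, ridge = 0)
  g <- suppressWarnings(
    glm.fit(cbind(1, d$values), d$outcome, family = binomial()))
  expect_lt(max(abs(fit$coefficients - g$coefficients)), 1e-6)
  # predictions agree too
  p <- predict(fit, d)
  expect_lt(max(abs(p - g$fitted.values)), 1e-7)
})

test_that("complete separation errors at ridge zero but fits with ridge", {
  values <- matrix(c(rep(1L, 10), rep(0L, 10)), ncol = 1,
                   dimnames = list(NULL, "sep"))
  outcome <- c(rep(1L, 10), rep(0L, 10))
  expect_error(fit_logistic(list(values = values, outcome = outcome),
                            ridge = 0),
               class = "evospec_convergence_error")
  fit <- fit_logistic(list(values = values, outcome = outcome), ridge = 0.01)
  expect_true(fit$converged)
})

test_that("auc implements the Mann-Whitney estimator with ties at 1/2", {
  expect_equal(auc(c(0.9, 0.8, 0.3, 0.2), c(1, 0, 1, 0)), 0.75)
  expect_equal(auc(c(5, 6, 1, 2), c(1, 1, 0, 0)), 1)
  expect_equal(auc(rep(0.3, 10), rep_len(c(1, 0), 10)), 0.5)
  expect_error(auc(1:4, rep(1, 4)), class = "evospec_degenerate_error")
  expect_error(auc(1:4, c(1, 0, 1)), class = "evospec_validation_error")
})

test_that("auc matches the brute-force pair counter on tied fixtures", {
  withr::with_seed(42, {
    for (i in 1:100) {
      n <- sample(5:150, 1)
      scores <- round(runif(n), sample(1:2, 1))  # coarse grid forces ties
      labels <- rbinom(n, 1, 0.4)
      if (length(unique(labels)) < 2) labels[1:2] <- c(0, 1)
      expect_identical(auc(scores, labels), auc_bruteforce(scores, labels))
    }
  })
})

test_that("auc is invariant under increasing transforms and flips sign", {
  withr::with_seed(7, {
    scores <- runif(60)
    labels <- rbinom(60, 1, 0.5)
    expect_equal(auc(plogis(3 * scores - 1), labels), auc(scores, labels))
    expect_equal(auc(-scores, labels), 1 - auc(scores, labels))
  })
})

test_that("cv_fitness is deterministic and mode-consistent at the zero mask", {
  sim <- tiny_sim(2500)
  co <- sim$cohort
  zero <- rep(0L, n_complaints(co$hierarchy))
  a <- cv_fitness(co, zero, "flattened", fold_seed = 3)
  b <- cv_fitness(co, zero, "flattened", fold_seed = 3)
  expect_identical(a, b)
  h <- cv_fitness(co, zero, "hierarchical", fold_seed = 3)
  expect_identical(a$oof_probabilities, h$oof_probabilities)
  expect_identical(a$auc, h$auc)
  # exactly one out-of-fold probability per record, all in (0, 1)
  expect_length(a$oof_probabilities, nrow(co$records))
  expect_true(all(a$oof_probabilities > 0 & a$oof_probabilities < 1))
  expect_identical(sort(unique(a$fold_assignment)), 1:5)
})

test_that("cv_fitness matches an independent glm-based CV oracle", {
  co <- small_cohort(300, seed = 21)
  mask <- as.integer(co$hierarchy$complaints %in%
                       c("headache", "abdominal mass"))
  cv <- cv_fitness(co, mask, "hierarchical", k = 5, fold_seed = 7)

  # oracle: refit every fold with glm on the exported dense design
  d <- build_design(co, mask, "hierarchical", drop_reference = TRUE)
  folds <- cv$fold_assignment
  oof <- numeric(nrow(d$values))
  X <- cbind(1, d$values)
  for (f in 1:5) {
    test <- folds == f
    g <- suppressWarnings(glm.fit(X[!test, , drop = FALSE],
                                  d$outcome[!test], family = binomial()))
    eta <- X[test, , drop = FALSE] %*% g$coefficients
    oof[test] <- plogis(as.vector(eta))
  }
  expect_lt(max(abs(cv$oof_probabilities - oof)), 1e-4)
  expect_equal(cv$auc, auc(oof, d$outcome), tolerance = 1e-8)
})

test_that("pooled and averaged CV summaries are both available", {
  sim <- tiny_sim(2500)
  cv_p <- cv_fitness(sim$cohort, sim$truth$informative_mask, "flattened",
                     fold_seed = 5, summary = "pooled")
  cv_a <- cv_fitness(sim$cohort, sim$truth$informative_mask, "flattened",
                     fold_seed = 5, summary = "averaged")
  expect_equal(cv_a$auc, mean(cv_a$auc_by_fold))
  expect_equal(cv_p$auc, cv_p$auc_pooled)
  expect_identical(cv_p$oof_probabilities, cv_a$oof_probabilities)
})

test_that("stratification requires k records of each class", {
  h <- abdominal_hierarchy()
  rec <- make_records(30, h, outcome = c(1L, rep(0L, 9)))  # 3 events
  co <- new_cohort(rec, h)
  expect_error(cv_fitness(co, rep(0L, 6), "flattened", k = 5),
               class = "evospec_stratification_error")
})

test_that("cv_as_df exports one row per record", {
  sim <- tiny_sim(2500)
  cv <- cv_fitness(sim$cohort, sim$truth$informative_mask, "flattened")
  df <- cv_as_df(cv, sim$cohort$records$outcome)
  expect_identical(nrow(df), nrow(sim$cohort$records))
  expect_named(df, c("record", "fold", "oof_probability", "outcome"))
})
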