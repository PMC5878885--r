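test_that("bullseye partition separates direct, sibling and untouched records", {
  h <- abdominal_hierarchy()
  rec <- make_records(9, h, complaints = c("abdominal cramping",
                                           "abdominal mass", "headache"))
  co <- new_cohort(rec, h)
  mask <- as.integer(h$complaints == "abdominal cramping")
  sg <- partition_bullseye(co, mask)
  expect_identical(sg[co$records$complaint == "abdominal cramping"][1],
                   "inner")
  expect_identical(sg[co$records$complaint == "abdominal mass"][1], "middle")
  expect_identical(sg[co$records$complaint == "headache"][1], "outer")

  expect_true(all(partition_bullseye(co, rep(0L, 6)) == "outer"))
  expect_true(all(partition_bullseye(co, rep(1L, 6)) == "inner"))
})

test_that("bullseye partition sizes follow the mask arithmetic", {
  co <- small_cohort(200, seed = 13)
  h <- co$hierarchy
  withr::with_seed(3, {
    for (i in 1:10) {
      mask <- rbinom(6, 1, 0.5)
      sg <- partition_bullseye(co, mask)
      expect_identical(sum(sg == "inner"),
                       sum(co$records$complaint %in% h$complaints[mask == 1]))
      hit_cats <- unique(unname(h$parent[h$complaints[mask == 1]]))
      expect_identical(sum(sg != "outer"),
                       sum(h$parent[co$records$complaint] %in% hit_cats))
    }
  })
})

test_that("DeLong self-comparison and antisymmetry are exact", {
  withr::with_seed(5, {
    labels <- rbinom(80, 1, 0.3)
    labels[1:2] <- c(0, 1)
    pa <- plogis(rnorm(80))
    pb <- plogis(0.6 * qlogis(pa) + 0.4 * rnorm(80))
    self <- delong_compare(pa, pa, labels)
    expect_identical(self$z, 0)
    expect_identical(self$p, 1)
    d1 <- delong_compare(pa, pb, labels)
    d2 <- delong_compare(pb, pa, labels)
    expect_equal(d1$z, -d2$z)
    expect_equal(d1$p, d2$p)
    expect_equal(d1$auc_a, auc(pa, labels))
    expect_equal(d1$auc_b, auc(pb, labels))
    expect_error(delong_compare(pa, pb, rep(1, 80)),
                 class = "evospec_degenerate_error")
  })
})

test_that("DeLong agrees with the pROC reference implementation", {
  skip_if_not_installed("pROC")
  withr::with_seed(11, {
    for (i in 1:5) {
      labels <- rbinom(120, 1, 0.35)
      labels[1:2] <- c(0, 1)
      x <- rnorm(120) + labels
      pa <- plogis(x + rnorm(120, sd = 0.5))
      pb <- plogis(x + rnorm(120, sd = 1.0))
      ours <- delong_compare(pa, pb, labels)
      ref <- pROC::roc.test(
        pROC::roc(labels, pa, quiet = TRUE, direction = "<"),
        pROC::roc(labels, pb, quiet = TRUE, direction = "<"),
        method = "delong", paired = TRUE)
      expect_equal(unname(ours$z), unname(ref$statistic), tolerance = 1e-8)
      expect_equal(ours$p, ref$p.value, tolerance = 1e-8)
    }
  })
})

test_that("bullseye report handles self-comparison and empty subgroups", {
  sim <- tiny_sim(3000, seed = 8)
  co <- sim$cohort
  mask <- sim$truth$informative_mask
  cv <- cv_fitness(co, mask, "flattened", fold_seed = 5)
  b1 <- cv_fitness(co, mode = "complaints_only", fold_seed = 5)
  b2 <- cv_fitness(co, mode = "categories_only", fold_seed = 5)

  # GA compared against itself in all cells: p = 1 everywhere defined
  rep_self <- bullseye_report(co, cv, cv, cv, mask)
  defined <- !is.na(rep_self$cells$p_vs_complaints)
  expect_true(all(rep_self$cells$p_vs_complaints[defined] == 1))

  # zero mask: inner and middle are empty, outer equals overall
  zero <- rep(0L, n_complaints(co$hierarchy))
  cv0 <- cv_fitness(co, zero, "flattened", fold_seed = 5)
  rep0 <- bullseye_report(co, cv0, b1, b2, zero)
  cells <- rep0$cells
  expect_identical(cells$n[cells$region == "inner"], 0L)
  expect_identical(cells$n[cells$region == "middle"], 0L)
  expect_true(is.na(cells$auc_ga[cells$region == "inner"]))
  expect_equal(cells$auc_ga[cells$region == "outer"],
               cells$auc_ga[cells$region == "overall"])

  # a proper report carries significance stars per comparison
  full <- bullseye_report(co, cv, b1, b2, mask)
  expect_setequal(full$cells$region, c("inner", "middle", "outer", "overall"))
  expect_true(all(full$cells$stars_vs_categories %in%
                    c("", "*", "**", "***")))

  # all models must share the fold assignment
  b1_other <- cv_fitness(co, mode = "complaints_only", fold_seed = 99)
  expect_error(bullseye_report(co, cv, b1_other, b2, mask),
               class = "evospec_validation_error")
})

test_that("probability shifts are bounded, conserved and zero for self", {
  sim <- tiny_sim(3000, seed = 8)
  co <- sim$cohort
  mask <- sim$truth$informative_mask
  cv <- cv_fitness(co, mask, "hierarchical", fold_seed = 5)
  b2 <- cv_fitness(co, mode = "categories_only", fold_seed = 5)
  sg <- partition_bullseye(co, mask)

  self <- probability_shifts(cv, cv, sg)
  expect_true(all(self$differences == 0))

  sh <- probability_shifts(cv, b2, sg, bin_width = 0.02)
  expect_true(all(sh$differences >= -1 & sh$differences <= 1))
  counts <- tapply(sh$histogram$count, sh$histogram$subgroup, sum)
  expect_identical(as.integer(counts[names(table(sg))]),
                   as.integer(table(sg)))
})

test_that("mask agreement percentages follow the confusion arithmetic", {
  m <- rep_len(c(1L, 1L, 0L, 0L, 0L), 100)  # 40% ones
  a <- mask_agreement(m, m)
  expect_equal(a$jointly_selected_pct, 40)
  expect_equal(a$jointly_excluded_pct, 60)
  expect_equal(a$disagreement_pct, 0)

  b <- mask_agreement(m, 1L - m)
  expect_equal(b$disagreement_pct, 100)

  withr::with_seed(2, {
    for (i in 1:10) {
      x <- rbinom(64, 1, 0.5)
      y <- rbinom(64, 1, 0.5)
      s <- mask_agreement(x, y)
      expect_equal(s$jointly_selected_pct + s$jointly_excluded_pct +
                     s$disagreement_pct, 100)
    }
  })
  expect_error(mask_agreement(m, m[-1]), class = "evospec_validation_error")
})

test_that("selection stability flags partially included complaints", {
  masks <- matrix(rep(c(1L, 0L, 1L, 0L), each = 20), nrow = 20)
  st <- selection_stability(masks)
  expect_equal(st$inconsistent_fraction, 0)

  masks[1, 2] <- 1L          # complaint 2 appears in 1 of 20
  masks[2:20, 4] <- 1L       # complaint 4 appears in 19 of 20
  st <- selection_stability(masks)
  expect_equal(unname(st$inclusion_fraction[4]), 0.95)
  expect_true(st$inconsistent[4])
  expect_true(st$inconsistent[2])
  expect_false(st$inconsistent[1])
  expect_equal(st$inconsistent_fraction, 0.5)

  expect_error(selection_stability(masks[1, , drop = FALSE]),
               class = "evospec_validation_error")
})
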