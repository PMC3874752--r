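test_that("LVEDP dichotomization uses a strict > 12 boundary", {
  expect_identical(dichotomize_lvedp(12), "normal")
  expect_identical(dichotomize_lvedp(12.1), "elevated")
  expect_identical(dichotomize_lvedp(c(22, 9)), c("elevated", "normal"))
  expect_identical(dichotomize_lvedp(NA_real_), NA_character_)
  expect_error(dichotomize_lvedp(-3), class = "laphase_validation_error")
})

test_that("empirical AUC reproduces pair-count values", {
  expect_identical(empirical_auc(c(1, 2, 3, 4), c(F, F, T, T), "ge")$auc, 1)
  expect_identical(empirical_auc(c(1, 3, 2, 4), c(F, F, T, T), "ge")$auc, 0.75)
  tied <- empirical_auc(rep(5, 8), rep(c(TRUE, FALSE), 4), "ge")
  expect_identical(tied$auc, 0.5)
  expect_identical(tied$p, 1)
  expect_error(empirical_auc(1:4, rep(TRUE, 4), "ge"),
               class = "laphase_validation_error")
})

test_that("AUC matches the brute-force oracle on random tied instances", {
  set.seed(23)
  for (rep in 1:200) {
    m <- sample(1:8, 1)
    n <- sample(1:8, 1)
    labels <- c(rep(TRUE, m), rep(FALSE, n))
    scores <- sample(1:4, m + n, replace = TRUE)  # heavy ties
    dir <- sample(c("ge", "le"), 1)
    expect_identical(empirical_auc(scores, labels, dir)$auc,
                     oracle_auc(scores, labels, dir))
  }
})

test_that("AUC is invariant under strictly monotone score transforms", {
  set.seed(29)
  labels <- rep(c(TRUE, FALSE), c(10, 15))
  scores <- rnorm(25)
  a0 <- empirical_auc(scores, labels, "ge")$auc
  expect_identical(empirical_auc(exp(scores), labels, "ge")$auc, a0)
  expect_identical(empirical_auc(3 * scores + 100, labels, "ge")$auc, a0)
})

test_that("DeLong p behaves at the extremes", {
  sep <- empirical_auc(c(1, 2, 9, 10), c(F, F, T, T), "ge")
  expect_identical(sep$p, 0)  # zero placement variance at AUC 1
  mid <- empirical_auc(c(1, 2, 1, 2), c(T, F, F, T), "ge")
  expect_true(mid$p >= 0 && mid$p <= 1)
})

test_that("Youden cutoff maximizes J with specificity-leaning ties", {
  # perfect separation: midpoint rule, sens = spec = 1
  oc <- optimal_cutoff(c(1, 2, 3, 4), c(F, F, T, T), "ge")
  expect_identical(oc$cutoff, 2.5)
  expect_identical(oc$sensitivity, 1)
  expect_identical(oc$specificity, 1)
  # (neg 1,3 | pos 2,4): J = 0.5 at both ends; tie goes to higher specificity
  oc2 <- optimal_cutoff(c(1, 3, 2, 4), c(F, F, T, T), "ge")
  expect_identical(oc2$youden, 0.5)
  expect_identical(oc2$cutoff, 3.5)
  expect_identical(oc2$specificity, 1)
  expect_identical(oc2$sensitivity, 0.5)
  # degenerate: indistinguishable scores
  oc3 <- optimal_cutoff(rep(2, 6), rep(c(TRUE, FALSE), 3), "ge")
  expect_true(is.na(oc3$cutoff))
})

test_that("Youden cutoff lies on the ROC and dominates every threshold", {
  set.seed(31)
  scores <- round(rnorm(40), 1)
  labels <- scores + rnorm(40) > 0.3
  if (sum(labels) > 0 && sum(!labels) > 0) {
    oc <- optimal_cutoff(scores, labels, "ge")
    u <- sort(unique(scores))
    cands <- (u[-1] + u[-length(u)]) / 2
    js <- vapply(cands, function(c0) {
      called <- scores >= c0
      mean(called[labels]) + mean(!called[!labels]) - 1
    }, numeric(1))
    expect_equal(oc$youden, max(js))
    called <- scores >= oc$cutoff
    expect_equal(oc$sensitivity, mean(called[labels]))
    expect_equal(oc$specificity, mean(!called[!labels]))
  }
})

test_that("direction bookkeeping: volumes >=, fractions <=", {
  co <- sample_cohort(cohort_config(n_patients = 300, seed = 37))
  ef <- emptying_fractions(data.frame(lav_max = co$true_lav_max,
                                      lav_ac = co$true_lav_ac,
                                      lav_min = co$true_lav_min))
  d <- cbind(co, ef)
  d$lav_min <- co$true_lav_min
  rep <- diagnostic_report(d, co$group, indices = c("lav_min", "laef_total"))
  expect_identical(rep$direction[rep$index == "lav_min"], "ge")
  expect_identical(rep$direction[rep$index == "laef_total"], "le")
  expect_true(all(rep$auc > 0.5))
})

test_that("group comparison matches the closed-form pooled t", {
  x <- c(5.1, 6.3, 4.8, 7.2, 5.9)
  y <- c(3.9, 4.4, 5.0, 3.1)
  gc <- group_compare(c(x, y), rep(c("elevated", "normal"), c(5, 4)))
  expect_equal(gc$mean_elevated, mean(x))
  expect_equal(gc$sd_normal, sd(y))
  expect_equal(gc$p_value, oracle_t_p(x, y), tolerance = 1e-12)
  # identical groups: no difference
  gc0 <- group_compare(rep(c(1, 2, 3), 2), rep(c("elevated", "normal"), 3))
  expect_equal(gc0$mean_elevated, gc0$mean_normal)
  expect_equal(gc0$p_value, 1, tolerance = 1e-8)
  # near-complete separation
  gc1 <- group_compare(c(rnorm(4, 0, 1e-4), rnorm(4, 1, 1e-4)),
                       rep(c("normal", "elevated"), c(4, 4)))
  expect_lt(gc1$p_value, 1e-3)
  expect_error(group_compare(1:3, c("elevated", "normal", "normal")),
               class = "laphase_validation_error")
})

test_that("pearson_r reproduces exact and brute-force correlations", {
  x <- c(1, 2, 3, 4, 5)
  expect_equal(pearson_r(x, 2 * x + 1)$r, 1)
  expect_equal(pearson_r(x, -x)$r, -1)
  y <- c(2.2, 1.9, 3.8, 3.1, 5.5)
  r_oracle <- sum((x - mean(x)) * (y - mean(y))) /
    sqrt(sum((x - mean(x))^2) * sum((y - mean(y))^2))
  expect_equal(pearson_r(x, y)$r, r_oracle, tolerance = 1e-12)
  expect_error(pearson_r(x, rep(1, 5)), class = "laphase_validation_error")
  expect_error(pearson_r(1:2, 2:3), class = "laphase_validation_error")
})

test_that("fisher_exact matches enumeration landmarks", {
  expect_equal(fisher_exact(matrix(c(5, 0, 0, 5), 2)), 2 / choose(10, 5),
               tolerance = 1e-12)
  expect_equal(fisher_exact(matrix(c(2, 2, 2, 2), 2)), 1)
  expect_equal(fisher_exact(matrix(c(0, 0, 3, 4), 2, byrow = TRUE)), 1)
  expect_error(fisher_exact(matrix(c(-1, 2, 3, 4), 2)),
               class = "laphase_validation_error")
})

test_that("diagnostic and group tables carry all six indices", {
  co <- sample_cohort(cohort_config(n_patients = 120, seed = 41))
  ef <- emptying_fractions(data.frame(lav_max = co$true_lav_max,
                                      lav_ac = co$true_lav_ac,
                                      lav_min = co$true_lav_min))
  d <- data.frame(lav_min = co$true_lav_min, lav_ac = co$true_lav_ac,
                  lav_max = co$true_lav_max, ef, lvedp_mmhg = co$lvedp_mmhg)
  t3 <- diagnostic_report(d, co$group)
  expect_equal(nrow(t3), 6)
  expect_true(all(t3$auc >= 0 & t3$auc <= 1))
  expect_true(all(t3$n_pos + t3$n_neg == nrow(co)))
  t2 <- group_table(d, co$group)
  expect_equal(nrow(t2), 7)  # six indices + LVEDP
  expect_true(all(t2$n_elevated + t2$n_normal == nrow(co)))
})
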