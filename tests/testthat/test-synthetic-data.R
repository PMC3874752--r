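test_that("degenerate configurations are rejected", {
  expect_error(cohort_config(prevalence_elevated = 1.2), class = "laphase_config_error")
  expect_error(cohort_config(prevalence_elevated = -0.1), class = "laphase_config_error")
  gp <- default_group_params()
  gp$elevated$lav_min[2] <- -5
  expect_error(cohort_config(group_params = gp), class = "laphase_config_error")
  expect_error(cohort_config(n_frames_range = c(10, 30)), class = "laphase_config_error")
  expect_error(cohort_config(n_frames_range = c(20, 40)), class = "laphase_config_error")
  expect_error(cohort_config(noise_sd_rel = -0.1), class = "laphase_config_error")
  expect_error(cohort_config(n_patients = 0), class = "laphase_config_error")
})

test_that("group sizes, LVEDP truncation and dichotomy consistency hold", {
  co <- sample_cohort(cohort_config(n_patients = 41, prevalence_elevated = 14 / 41,
                                    seed = 1))
  expect_equal(sum(co$group == "elevated"), 14)
  expect_equal(sum(co$group == "normal"), 27)
  expect_true(all(co$lvedp_mmhg[co$group == "elevated"] > 12))
  expect_true(all(co$lvedp_mmhg[co$group == "normal"] <= 12))
  expect_true(all(co$lvedp_mmhg > 0))
  # label derived from LVEDP agrees with the generating group everywhere
  expect_identical(dichotomize_lvedp(co$lvedp_mmhg), co$group)
  # strict phasic ordering after generation
  expect_true(all(co$true_lav_min < co$true_lav_ac))
  expect_true(all(co$true_lav_ac < co$true_lav_max))
  # frame counts and landmark ordering
  expect_true(all(co$n_frames >= 20 & co$n_frames <= 30))
  expect_true(all(co$mv_open_frame < co$ac_onset_frame))
  expect_true(all(co$ac_onset_frame < co$mv_close_frame))
  expect_true(all(co$mv_close_frame == co$n_frames - 1))
})

test_that("prevalence 0 gives an all-normal cohort", {
  co <- sample_cohort(cohort_config(n_patients = 10, prevalence_elevated = 0,
                                    seed = 2))
  expect_true(all(co$group == "normal"))
  expect_true(all(co$lvedp_mmhg <= 12))
})

test_that("zero-variance group parameters collapse to the configured means", {
  gp <- default_group_params()
  for (g in names(gp)) for (f in names(gp[[g]])) gp[[g]][[f]][2] <- 0
  co <- sample_cohort(cohort_config(n_patients = 50, group_params = gp, seed = 3))
  e <- co[co$group == "elevated", ]
  n <- co[co$group == "normal", ]
  expect_true(all(e$true_lav_min == 35 & e$true_lav_ac == 48 & e$true_lav_max == 56))
  expect_true(all(e$lvedp_mmhg == 22))
  expect_true(all(n$true_lav_min == 22 & n$true_lav_ac == 37 & n$true_lav_max == 44))
  expect_true(all(n$lvedp_mmhg == 9))
})

test_that("sampling is deterministic under a fixed seed and seed-sensitive", {
  cfg <- cohort_config(n_patients = 100, seed = 11)
  expect_identical(sample_cohort(cfg), sample_cohort(cfg))
  expect_false(identical(sample_cohort(cfg),
                         sample_cohort(cohort_config(n_patients = 100, seed = 12))))
})

test_that("sample means recover configured group means within 3 SE at n = 1e4", {
  co <- sample_cohort(cohort_config(n_patients = 10000, seed = 7))
  gp <- default_group_params()
  for (g in c("elevated", "normal")) {
    sub <- co[co$group == g, ]
    for (ix in c("lav_min", "lav_ac", "lav_max")) {
      target <- gp[[g]][[ix]][1]
      se <- gp[[g]][[ix]][2] / sqrt(nrow(sub))
      expect_lt(abs(mean(sub[[paste0("true_", ix)]]) - target), 3 * se,
                label = sprintf("|mean - %g| for %s/%s", target, g, ix))
    }
  }
})

test_that("curves hit their landmarks exactly and stay within the envelope", {
  np <- noiseless_patients(200, seed = 21)
  for (i in seq_len(nrow(np$cohort))) {
    p <- np$cohort[i, ]
    cv <- np$curves[[i]]
    expect_equal(length(cv$times), length(cv$volumes))
    expect_gte(cv$n_frames, 20)
    expect_true(all(diff(cv$times) > 0))
    expect_true(all(cv$volumes > 0))
    # landmark values by construction
    expect_identical(cv$volumes[1], p$true_lav_min)
    expect_identical(cv$volumes[p$mv_open_frame + 1], p$true_lav_max)
    expect_identical(cv$volumes[p$ac_onset_frame + 1], p$true_lav_ac)
    expect_identical(cv$volumes[p$mv_close_frame + 1], p$true_lav_min)
    # envelope: never above lav_max nor below lav_min at any frame
    expect_true(all(cv$volumes <= p$true_lav_max))
    expect_true(all(cv$volumes >= p$true_lav_min))
  }
})

test_that("landmark values are invariant to sampling density", {
  p <- noiseless_patients(1, seed = 5)$cohort[1, ]
  for (n in c(20, 25, 30)) {
    cv <- build_curve(p, n_frames = n)
    expect_identical(max(cv$volumes), p$true_lav_max)
    expect_identical(min(cv$volumes), p$true_lav_min)
    expect_identical(cv$volumes[cv$event_frames$ac_onset + 1], p$true_lav_ac)
  }
  expect_error(build_curve(p, n_frames = 12), class = "laphase_validation_error")
})

test_that("biplane projection inverts exactly at zero noise", {
  np <- noiseless_patients(5, seed = 31)
  for (i in 1:5) {
    p <- np$cohort[i, ]
    cv <- np$curves[[i]]
    bp <- project_biplane(cv, p$bsa_m2, noise_sd_rel = 0)
    expect_true(all(bp$a1_cm2 > 0 & bp$a2_cm2 > 0 & bp$l_cm > 0))
    rc <- curve_from_biplane(bp, p$bsa_m2)
    expect_equal(rc$volumes, cv$volumes, tolerance = 1e-12)
    # distinct observers are identical when there is no noise
    bp2 <- project_biplane(cv, p$bsa_m2, noise_sd_rel = 0, observer_id = "obs2")
    expect_identical(bp$a1_cm2, bp2$a1_cm2)
  }
  expect_error(
    project_biplane(np$curves[[1]], np$cohort$bsa_m2[1],
                    shape_params = list(aspect = -1, l_scale = 1.4)),
    class = "laphase_validation_error"
  )
})

test_that("round-trip relative error under noise matches error propagation", {
  # V-hat = 0.85 a1 a2 / l with 3% multiplicative noise on each quantity:
  # to first order the relative volume error has SD sqrt(3) * 0.03.
  np <- noiseless_patients(5, seed = 41)
  rel <- c()
  set.seed(99)
  for (r in 1:80) {
    i <- ((r - 1) %% 5) + 1
    p <- np$cohort[i, ]
    cv <- np$curves[[i]]
    bp <- project_biplane(cv, p$bsa_m2, noise_sd_rel = 0.03)
    rc <- curve_from_biplane(bp, p$bsa_m2)
    rel <- c(rel, (rc$volumes - cv$volumes) / cv$volumes)
  }
  expect_gt(length(rel), 1500)
  expect_lt(abs(sd(rel) - sqrt(3) * 0.03), 0.006)
  expect_lt(abs(mean(rel)), 0.005)
})
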