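test_that("norm pool generation is deterministic and respects its curves", {
  flat <- data.frame(percentile = c(1, 99), a = 0, b = 0, c = 7)
  spec <- norm_pool_spec(n_records = 500, curves = flat, noise_sd = 0,
                         seed = 5)
  pool <- generate_norm_pool(spec)
  expect_equal(pool$psych, rep(7, 500))
  expect_true(all(pool$age_months >= 120 & pool$age_months <= 240))
  expect_identical(generate_norm_pool(spec), pool)

  # crossing generator curves are rejected at spec time
  crossing <- data.frame(percentile = c(10, 90), a = c(0, 0),
                         b = c(0, -0.01), c = c(7, 8))
  expect_error(norm_pool_spec(curves = crossing), "cross")
  expect_error(norm_pool_spec(noise_sd = -1), "noise_sd")
})

test_that("the default curve family declines with age, fastest at the bottom", {
  curves <- default_norm_curves(anchors = c(10, 25, 50, 75, 90))
  val <- function(p, age) {
    r <- curves[curves$percentile == p, ]
    r$a * age^2 + r$b * age + r$c
  }
  for (p in curves$percentile) {
    expect_gt(val(p, 120), val(p, 180))
    expect_gt(val(p, 180), val(p, 240))
  }
  # lower percentiles decline more over the decade
  declines <- vapply(curves$percentile,
                     function(p) val(p, 120) - val(p, 240), numeric(1))
  expect_true(all(diff(declines) < 0))
  # and percentile order is preserved at every age (non-crossing family)
  for (age in c(120, 180, 240)) {
    vals <- vapply(curves$percentile, val, numeric(1), age = age)
    expect_true(all(diff(vals) > 0))
  }
})

test_that("trial generation respects structure, attrition and determinism", {
  tab <- cached_norm_table()
  spec <- trial_spec(n_schools = 2, classes_per_school = 2,
                     students_per_class = 10,
                     retention_posttest = 1, retention_followup = 1,
                     seed = 21)
  tr <- generate_trial(spec, tab)
  expect_equal(sum(tr$wave == "pretest"), 40L)
  expect_equal(nrow(tr), 120L)
  expect_equal(length(unique(tr$classroom_id)), 4L)
  expect_identical(generate_trial(spec, tab), tr)
  expect_true(all(tr$alcohol %in% 0:1))
  expect_true(all(tr$age_months >= 120 & tr$age_months <= 240))

  # student-wise retention 0.5 at posttest: binomial 3-sigma band
  spec2 <- trial_spec(n_schools = 4, classes_per_school = 5,
                      students_per_class = 30,
                      retention_posttest = 0.5, retention_followup = 0.5,
                      school_attrition_share = 0, seed = 8)
  tr2 <- generate_trial(spec2, tab)
  n <- 600
  n_post <- sum(tr2$wave == "posttest")
  expect_lt(abs(n_post - n * 0.5), 3 * sqrt(n * 0.25))

  # school-wise attrition drops whole schools
  spec3 <- trial_spec(n_schools = 30, classes_per_school = 1,
                      students_per_class = 10,
                      retention_posttest = 0.3, retention_followup = 0.3,
                      school_attrition_share = 1, seed = 9)
  tr3 <- generate_trial(spec3, tab)
  post_sizes <- table(tr3$school_id[tr3$wave == "posttest"])
  expect_true(all(post_sizes == 10))  # surviving schools keep all students

  # a configuration whose waves exit the table is rejected
  expect_error(generate_trial(trial_spec(pretest_age_mean = 235), tab),
               "range")
})

test_that("item responses hit the alpha target and track the psych score", {
  tab <- cached_norm_table()
  set.seed(631)
  psych <- eval_norm(tab, sample(tab$percentiles, 4000, TRUE),
                     sample(125:135, 4000, TRUE))

  # near-perfect reliability: items equal the (grid-valued) psych score
  grid_psych <- round(psych)
  bat0 <- default_battery()
  m1 <- item_responses_from_psych(grid_psych, bat0, reliability = 0.999,
                                  seed = 1)
  coded1 <- vapply(seq_len(13),
                   function(j) code_item(m1[, j], bat0$items[[j]]),
                   numeric(length(grid_psych)))
  expect_true(all(coded1 == grid_psych))

  # target alpha 0.681: empirical alpha of the coded battery within 0.05
  bat <- default_battery()
  m <- item_responses_from_psych(psych, bat, reliability = 0.681, seed = 2)
  coded <- vapply(seq_len(13), function(j) code_item(m[, j], bat$items[[j]]),
                  numeric(length(psych)))
  expect_lt(abs(cronbach_alpha(coded) - 0.681), 0.05)

  # rescored psych correlates strongly with the generating score
  m9 <- item_responses_from_psych(psych, bat, reliability = 0.9, seed = 3)
  coded9 <- vapply(seq_len(13), function(j) code_item(m9[, j], bat$items[[j]]),
                   numeric(length(psych)))
  expect_gt(cor(rowMeans(coded9), psych), 0.9)

  expect_error(item_responses_from_psych(rep(5, 10), reliability = 0.5),
               "variance")
  expect_error(item_responses_from_psych(psych, reliability = 1.2),
               "reliability")
})

test_that("the pipeline recovers generating structure end to end", {
  tab <- cached_norm_table()
  spec <- trial_spec(n_schools = 20, classes_per_school = 4,
                     students_per_class = 50,
                     retention_posttest = 1, retention_followup = 1,
                     noise_preset = "norms-like", seed = 77)
  tr <- score_surveys(generate_trial(spec, tab))

  # calibration on the pretests recovers the generating alcohol slope
  rep <- fit_behavior_weights(tr[tr$wave == "pretest", ], "alcohol")
  expect_true(rep$converged)
  expect_lt(abs(rep$weights$b_psych - (-2.421)), 3 * rep$se["b_psych"])

  # matched percentiles track latent percentiles
  m <- match_cohort(tab, reference_weights()["alcohol"], tr)
  truth <- attr(tr, "truth")
  v <- m$virtual[m$virtual$wave == "pretest", ]
  expect_gt(cor(v$matched_percentile,
                truth$latent_percentile[match(v$student_id,
                                              truth$student_id)]), 0.7)
})

test_that("a programmed protective effect moves outcomes in the right direction", {
  tab <- cached_norm_table()
  spec <- trial_spec(n_schools = 12, classes_per_school = 4,
                     students_per_class = 25,
                     program_psych_shift = 0.3,
                     program_logodds_multiplier = 1.4,
                     retention_posttest = 1, retention_followup = 1,
                     seed = 5)
  tr <- score_surveys(generate_trial(spec, tab))
  m <- match_cohort(tab, reference_weights()["alcohol"], tr)
  cells <- outcome_cells(tr, m$virtual)
  res <- compare(cells[cells$condition == "treatment", ],
                 cells[cells$condition == "virtual_control", ],
                 "student", "alcohol", "followup")
  # deterred onset: treatment below the virtual-control estimate, d > 0
  expect_lt(res$mean_treatment, res$mean_control)
  expect_gt(res$cohens_d, 0)
})
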