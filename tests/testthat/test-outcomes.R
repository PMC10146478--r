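make_cells <- function(unit, condition, behavior, wave, value,
                       classroom = "c1", school = "s1") {
  data.frame(unit_id = unit, condition = condition, behavior = behavior,
             wave = wave, value = value, classroom_id = classroom,
             school_id = school, stringsAsFactors = FALSE)
}

test_that("aggregation takes unweighted means within clusters", {
  cells <- make_cells(paste0("u", 1:4), "treatment", "alcohol", "pretest",
                      c(0, 0, 1, 1))
  cls <- aggregate_cells(cells, "class")
  expect_equal(cls$value, 0.5)
  expect_equal(cls$unit_id, "c1")

  zero <- make_cells(paste0("u", 1:3), "treatment", "alcohol", "pretest",
                     c(0, 0, 0))
  expect_equal(aggregate_cells(zero, "class")$value, 0)

  # two classes of unequal size: student-weighted school mean vs mean of
  # class means differ; hand computation on a 2-class fixture
  two <- rbind(
    make_cells(paste0("a", 1:4), "treatment", "alcohol", "pretest",
               c(1, 1, 1, 1), classroom = "cA"),
    make_cells("b1", "treatment", "alcohol", "pretest", 0, classroom = "cB"))
  sw <- aggregate_cells(two, "school", weighting = "student")
  cm <- aggregate_cells(two, "school", weighting = "class_mean")
  expect_equal(sw$value, 4 / 5)   # mean over the school's five students
  expect_equal(cm$value, 1 / 2)   # mean of class means (1 and 0)

  # grand-mean conservation: student grand mean equals the class-size
  # weighted mean of class values
  cls2 <- aggregate_cells(two, "class")
  sizes <- c(cA = 4, cB = 1)
  expect_equal(sum(cls2$value * sizes[cls2$unit_id]) / sum(sizes),
               mean(two$value), ignore_attr = TRUE)
})

test_that("welch comparison matches textbook arithmetic and sign convention", {
  tr <- make_cells(paste0("t", 1:5), "treatment", "alcohol", "posttest",
                   c(0, 0, 1, 0, 0))
  vc <- make_cells(paste0("t", 1:5), "virtual_control", "alcohol", "posttest",
                   c(0, 1, 1, 1, 0))
  res <- compare(tr, vc, "student", "alcohol", "posttest")

  # hand-computed Welch statistics: means .2/.6, variances .2/.3
  se <- sqrt(0.2 / 5 + 0.3 / 5)
  t_hand <- (0.6 - 0.2) / se
  df_hand <- (0.1)^2 / ((0.2 / 5)^2 / 4 + (0.3 / 5)^2 / 4)
  expect_equal(res$t_stat, t_hand, tolerance = 1e-12)
  expect_equal(res$df, df_hand, tolerance = 1e-12)
  expect_equal(res$p_value, 2 * pt(-t_hand, df_hand), tolerance = 1e-12)
  # pooled-sd Cohen's d, control minus treatment: (0.6-0.2)/0.5
  expect_equal(res$cohens_d, 0.8, tolerance = 1e-12)
  expect_gt(res$cohens_d, 0)  # control mean exceeds treatment -> positive d

  # identical collections: t = 0, d = 0
  same <- compare(tr, tr, "student", "alcohol", "posttest")
  expect_equal(same$t_stat, 0)
  expect_equal(same$cohens_d, 0)
  expect_false(same$degenerate)

  # zero variance with unequal means is flagged degenerate
  t0 <- make_cells(paste0("t", 1:4), "treatment", "alcohol", "posttest",
                   rep(0, 4))
  c1 <- make_cells(paste0("t", 1:4), "virtual_control", "alcohol", "posttest",
                   rep(1, 4))
  deg <- compare(t0, c1, "student", "alcohol", "posttest")
  expect_true(deg$degenerate)

  expect_error(compare(tr[1, ], vc, "student", "alcohol", "posttest"),
               "2 units")
})

test_that("subgroup z-tests follow two-proportion arithmetic and pairing", {
  # identical prevalences: z = 0, not significant
  n <- 700
  mk_pair <- function(p_flag, p_ctrl) {
    surveys <- data.frame(student_id = paste0("s", 1:n), wave = "posttest",
                          gender = "male", hispanic = 0, race = "white",
                          alcohol = c(rep(1, round(p_flag * n)),
                                      rep(0, n - round(p_flag * n))))
    virtual <- data.frame(student_id = paste0("s", 1:n), wave = "posttest",
                          p_alcohol = p_ctrl)
    list(surveys = surveys, virtual = virtual)
  }
  eqd <- mk_pair(0.04, 0.04)
  r0 <- subgroup_compare(eqd$surveys, eqd$virtual, "boys", "alcohol",
                         "posttest")
  expect_equal(r0$z_stat, 0)
  expect_false(r0$significant_at_95)
  expect_equal(r0$n_treatment, r0$n_control)

  # 0.8% vs 4.0% at n = 700 per side: significant at the 95% level
  d <- mk_pair(0.008, 0.040)
  r1 <- subgroup_compare(d$surveys, d$virtual, "boys", "alcohol", "posttest")
  pbar <- (mean(d$surveys$alcohol) + 0.040) / 2
  z_hand <- (0.040 - mean(d$surveys$alcohol)) /
    sqrt(pbar * (1 - pbar) * 2 / n)
  expect_equal(r1$z_stat, z_hand, tolerance = 1e-12)
  expect_true(r1$significant_at_95)

  # girls subgroup is empty here
  expect_error(subgroup_compare(d$surveys, d$virtual, "girls", "alcohol",
                                "posttest"), "girls")

  # boys + girls partition all gendered cases
  set.seed(33)
  d$surveys$gender <- sample(c("male", "female"), n, TRUE)
  rb <- subgroup_compare(d$surveys, d$virtual, "boys", "alcohol", "posttest")
  rg <- subgroup_compare(d$surveys, d$virtual, "girls", "alcohol", "posttest")
  expect_equal(rb$n_treatment + rg$n_treatment, n)
})

test_that("dichotomization flags strict increases only", {
  mk <- function(unit, wave, value) {
    make_cells(unit, "treatment", "alcohol", wave, value)
  }
  cells <- rbind(
    mk("u1", "pretest", 0),    mk("u1", "followup", 1),
    mk("u2", "pretest", 0.02), mk("u2", "followup", 0.02),
    mk("u3", "pretest", 0.10), mk("u3", "followup", 0.04),
    mk("u4", "pretest", 0),    mk("u4", "followup", 0),
    mk("u5", "pretest", 0.01), mk("u5", "followup", 0.05),
    mk("u6", "pretest", 1),    mk("u6", "followup", 0))
  d <- dichotomize_increase(cells, "followup")
  expect_equal(d$increase[match(paste0("u", 1:6), d$unit_id)],
               c(1L, 0L, 0L, 0L, 1L, 0L))

  # a unit missing the baseline wave is omitted
  cells2 <- rbind(cells, mk("u7", "followup", 1))
  expect_false("u7" %in% dichotomize_increase(cells2, "followup")$unit_id)
})
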