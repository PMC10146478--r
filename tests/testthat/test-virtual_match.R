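test_that("matching returns the nearest percentile with a lower tie-break", {
  tab <- make_value_table(c(10, 50, 90), 130:132,
                          rbind(c(7, 7, 7), c(8, 8, 8), c(9, 9, 9)))
  # exact hit
  expect_equal(match_percentile(tab, 130, 8), 50)
  # nearest neighbor
  expect_equal(match_percentile(tab, 131, 8.2), 50)
  expect_equal(match_percentile(tab, 131, 8.8), 90)
  # equidistant between two adjacent percentiles: the lower one wins
  expect_equal(match_percentile(tab, 132, 7.5), 10)
  expect_equal(match_percentile(tab, 132, 8.5), 50)

  expect_error(match_percentile(tab, 129, 8), "below")
  expect_warning(match_percentile(tab, 133, 8), "clamped")
  expect_error(match_percentile(tab, 130, 11), "psych")
})

test_that("matching agrees exactly with exhaustive nearest-neighbor search", {
  set.seed(217)
  for (i in 1:200) {
    n_pct <- sample(2:10, 1)
    pcts <- sort(sample(seq(1, 99, by = 0.5), n_pct))
    ages <- 120:124
    vals <- matrix(sort(runif(n_pct * length(ages), 0, 10)),
                   n_pct, length(ages))
    tab <- norm_table(pcts, ages, vals)
    age <- sample(ages, 1)
    psych <- runif(1, 0, 10)
    # independent oracle: scan every percentile, keep the first minimum
    dist <- abs(eval_norm(tab, pcts, rep(age, n_pct)) - psych)
    oracle <- pcts[which(dist == min(dist))[1]]
    expect_identical(match_percentile(tab, age, psych), oracle)
  }
})

test_that("virtual cases reproduce the pegged worked-example probabilities", {
  tab <- worked_example_table()
  w <- reference_weights()["alcohol"]
  case <- data.frame(student_id = "X", wave = c("pretest", "posttest", "followup"),
                     age_months = c(127, 129, 137),
                     psych = c(8.97, NA, NA))
  vc <- build_virtual_case(tab, w, case)
  expect_equal(vc$matched_percentile, rep(41, 3))
  expect_equal(vc$psych, c(8.97, 8.93, 8.73))
  # pretest/posttest/follow-up drinking probabilities: 1.20%, 1.58%, 4.61%
  expect_equal(vc$p_alcohol, c(0.01204830, 0.01581352, 0.04608047),
               tolerance = 1e-6)
  expect_equal(round(100 * vc$p_alcohol, 1), c(1.2, 1.6, 4.6))
})

test_that("pegging is constant and independent of later-wave self-reports", {
  tab <- cached_norm_table()
  w <- reference_weights()["alcohol"]
  case <- data.frame(student_id = "s1", wave = c("pretest", "posttest", "followup"),
                     age_months = c(128, 130, 138),
                     psych = c(8.5, 9.9, 2.2), alcohol = c(0, 1, 1))
  vc <- build_virtual_case(tab, w, case)
  # one percentile for all waves, one row per wave with a recorded age
  expect_equal(length(unique(vc$matched_percentile)), 1L)
  expect_equal(nrow(vc), 3L)

  # perturbing posttest/follow-up psych and behaviors changes nothing
  case2 <- case
  case2$psych[2:3] <- c(1.1, 7.7)
  case2$alcohol <- c(0, 0, 0)
  expect_equal(build_virtual_case(tab, w, case2), vc)

  # a wave without a recorded age is absent from the virtual case
  case3 <- case
  case3$age_months[3] <- NA
  expect_equal(build_virtual_case(tab, w, case3)$wave,
               c("pretest", "posttest"))

  # constant table + all-zero weights: probability 1/2 everywhere
  flat <- constant_table(7)
  w0 <- list(alcohol = behavior_weights("alcohol", 0, 0, 0))
  vc0 <- build_virtual_case(flat, w0, case)
  expect_equal(vc0$p_alcohol, rep(0.5, 3))
})

test_that("cohort matching excludes ineligible cases with logged reasons", {
  tab <- cached_norm_table()
  w <- reference_weights()["alcohol"]
  mk <- function(id, age, psych) {
    data.frame(student_id = id, wave = "pretest", age_months = age,
               psych = psych, classroom_id = "c1", school_id = "s1")
  }
  surveys <- rbind(mk("a", 125, 8.1), mk("b", 118, 8.2), mk("c", 131, 9.0),
                   mk("d", 127, NA), mk("e", 140, 6.5))
  m <- match_cohort(tab, w, surveys)
  expect_equal(sort(unique(m$virtual$student_id)), c("a", "c", "e"))
  expect_equal(m$exclusions$reason[m$exclusions$student_id == "b"],
               "age_below_range")
  expect_equal(m$exclusions$reason[m$exclusions$student_id == "d"],
               "missing_pretest_psych")

  # a student with no pretest row is excluded too
  s2 <- rbind(surveys, data.frame(student_id = "f", wave = "posttest",
                                  age_months = 133, psych = 8,
                                  classroom_id = "c1", school_id = "s1"))
  m2 <- match_cohort(tab, w, s2)
  expect_equal(m2$exclusions$reason[m2$exclusions$student_id == "f"],
               "missing_pretest")

  # determinism: the same inputs give identical output
  expect_identical(match_cohort(tab, w, surveys), m)

  # empty eligible set is an error
  expect_error(match_cohort(tab, w, mk("z", 117, 8)), "eligible")
})

test_that("matched percentiles recover latent percentiles as noise shrinks", {
  tab <- cached_norm_table()
  set.seed(515)
  n <- 400
  latent <- sample(tab$percentiles, n, replace = TRUE)
  age <- sample(125:135, n, replace = TRUE)
  truth <- eval_norm(tab, latent, age)
  err <- vapply(c(0.5, 0.05), function(noise) {
    obs <- pmin(pmax(truth + rnorm(n, 0, noise), 0), 10)
    matched <- match_percentile(tab, age, obs)
    mean(abs(matched - latent))
  }, numeric(1))
  expect_lt(err[2], err[1])
  expect_lt(err[2], 5)  # low noise pins matches near the latent percentile
})
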