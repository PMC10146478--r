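# Synthetic-data generators: a normative pool with age-declining percentile
# structure, and nested longitudinal trial cohorts (schools > classrooms >
# students) with demographics, 30-day behaviors, survey items and attrition.
# Everything is deterministic given the spec seed.

#' Default generating percentile curves
#'
#' A non-crossing family of quadratic-in-age psych curves used to simulate
#' normative pools: with q = percentile/100 and s = (age - 120)/120,
#' psych(q, age) = base(q) - d(q) (0.7 s + 0.3 s^2), where
#' base(q) = 6.5 + 3.4 q^0.35 (psych level at age 120) and
#' d(q) = 5.5 (1 - q)^1.2 (total decade decline). Scores decline with age at
#' every percentile and decline fastest at low percentiles; the family is
#' non-crossing because base is increasing and d decreasing in q. Returned
#' as exact quadratic coefficients per percentile anchor
#' (psych = a age^2 + b age + c).
#'
#' @param anchors Percentile anchors (default 0.5 to 99.5 by 0.5).
#' @return Data frame `percentile`, `a`, `b`, `c`.
#' @export
default_norm_curves <- function(anchors = seq(0.5, 99.5, by = 0.5)) {
  q <- anchors / 100
  d <- 5.5 * (1 - q)^1.2
  base <- 6.5 + 3.4 * q^0.35
  # expand base - d*(0.7 s + 0.3 s^2), s = (age-120)/120, in powers of age
  data.frame(percentile = anchors,
             a = -d / 48000,
             b = -d / 1200,
             c = base + 0.4 * d)
}

.eval_curves <- function(curves, age) {
  # anchors x ages matrix of curve values
  outer(seq_len(nrow(curves)), seq_along(age), function(i, j) {
    curves$a[i] * age[j]^2 + curves$b[i] * age[j] + curves$c[i]
  })
}

#' Specify a synthetic normative pool
#'
#' @param n_records Number of survey records to draw.
#' @param age_range Age coverage in months (default 120--240).
#' @param curves Generating percentile curves (data frame `percentile`,
#'   `a`, `b`, `c`); default [default_norm_curves()]. Must be non-crossing
#'   over the age range.
#' @param noise_sd Within-percentile noise standard deviation (>= 0).
#' @param seed RNG seed.
#' @return An object of class `"norm_pool_spec"`.
#' @export
norm_pool_spec <- function(n_records = 50000, age_range = c(120L, 240L),
                           curves = default_norm_curves(), noise_sd = 0.25,
                           seed = 1L) {
  if (noise_sd < 0) stop("noise_sd must be >= 0", call. = FALSE)
  if (n_records < 1) stop("n_records must be positive", call. = FALSE)
  ages <- seq.int(age_range[1], age_range[2])
  vals <- .eval_curves(curves[order(curves$percentile), , drop = FALSE], ages)
  if (any(apply(vals, 2, function(col) any(diff(col) < -1e-9))))
    stop("generating percentile curves cross within the age range",
         call. = FALSE)
  structure(list(n_records = as.integer(n_records),
                 age_range = as.integer(age_range),
                 curves = curves[order(curves$percentile), , drop = FALSE],
                 noise_sd = noise_sd, seed = as.integer(seed)),
            class = "norm_pool_spec")
}

# psych value of the generating family at (latent percentile, age), linearly
# interpolated between anchors; latent outside the anchor span is clamped.
.curve_value <- function(curves, latent_pct, age) {
  anchors <- curves$percentile
  u <- clamp(latent_pct, min(anchors), max(anchors))
  i <- findInterval(u, anchors, all.inside = TRUE)
  w <- (u - anchors[i]) / (anchors[i + 1] - anchors[i])
  v_lo <- curves$a[i] * age^2 + curves$b[i] * age + curves$c[i]
  v_hi <- curves$a[i + 1] * age^2 + curves$b[i + 1] * age + curves$c[i + 1]
  (1 - w) * v_lo + w * v_hi
}

#' Generate a synthetic normative pool
#'
#' Draws records with ages uniform over the spec's range and latent
#' percentiles uniform on (0, 100); each record's psych score is the
#' generating curve value at its latent percentile plus Gaussian noise,
#' clamped to `[0, 10]`.
#'
#' @param spec A [norm_pool_spec()].
#' @return Data frame `record_id`, `age_months`, `psych`; the latent
#'   percentiles are attached as attribute `"latent_percentile"` and the
#'   seed as `"seed"`.
#' @export
generate_norm_pool <- function(spec) {
  stopifnot(inherits(spec, "norm_pool_spec"))
  with_seed(spec$seed, {
    n <- spec$n_records
    age <- sample(seq.int(spec$age_range[1], spec$age_range[2]), n,
                  replace = TRUE)
    u <- stats::runif(n, 0, 100)
    psych <- .curve_value(spec$curves, u, age) +
      stats::rnorm(n, 0, spec$noise_sd)
    pool <- data.frame(record_id = sprintf("N%06d", seq_len(n)),
                       age_months = age, psych = clamp(psych, 0, 10))
    attr(pool, "latent_percentile") <- u
    attr(pool, "seed") <- spec$seed
    pool
  })
}

#' Default generating weights for the four 30-day behaviors
#'
#' The three published reference behaviors use the packaged reference
#' weights; cigarette smoking uses a synthetic near-zero-prevalence set
#' (about 0.05% at typical fifth-grade psych scores), reproducing the regime
#' in which the calibration prevalence guard trips.
#'
#' @return Named list of [behavior_weights()] for alcohol, drunkenness,
#'   cigarette and vaping.
#' @export
default_true_weights <- function() {
  w <- reference_weights()
  w$cigarette <- behavior_weights("cigarette", -2.0, -0.65, 0)
  w[c("alcohol", "drunkenness", "cigarette", "vaping")]
}

#' Specify a synthetic nested trial cohort
#'
#' Defaults emulate a two-cohort fifth-grade school trial: pretest at mean
#' age 130 months (about 10.8 years, sd 4), posttest ~2 months and follow-up
#' ~10 months later; 48.5% boys, 14.9% Hispanic, 59.4% White; whole-school
#' attrition dominating student-level attrition, with retention 33.5% at
#' posttest and 24.3% at follow-up. Psych measurement noise is parameterized
#' as the item battery's target reliability: the `"study-like"` preset uses
#' alpha 0.681, the `"norms-like"` preset 0.90 (the low-noise regime the
#' matching methodology assumes).
#'
#' @param n_schools,classes_per_school,students_per_class Cohort structure.
#' @param pretest_age_mean,pretest_age_sd Pretest age distribution (months).
#' @param posttest_offset,followup_offset Wave offsets in months.
#' @param p_male,p_hispanic,p_white Demographic mix.
#' @param true_weights Named list of generating [behavior_weights()];
#'   default [default_true_weights()].
#' @param trait_noise_sd Within-percentile scatter of each student's
#'   realized psych around the normative curve (default 0.25, matching the
#'   default normative-pool noise); behaviors and item responses are both
#'   keyed to the realized value.
#' @param program_psych_shift Additive protective shift on the psych
#'   trajectory after pretest (0 = null).
#' @param program_logodds_multiplier Multiplier on the behavior log-odds
#'   after pretest (1 = null; > 1 makes the typically negative log-odds more
#'   negative, i.e. protective).
#' @param retention_posttest,retention_followup Overall retention targets.
#' @param school_attrition_share Share of attrition carried by whole-school
#'   dropout (default 0.7; the remainder is independent student dropout).
#' @param noise_preset `"study-like"` (reliability 0.681) or `"norms-like"`
#'   (0.90); overridden by an explicit `reliability`.
#' @param reliability Optional explicit Cronbach-alpha target for the
#'   generated item battery.
#' @param latent_dist `"uniform"` latent percentiles, or `"top_heavy"` (13%
#'   mass at the top percentile, ~70% below the 60th) matching the skewed
#'   percentile distributions real cohorts show.
#' @param battery Item battery used to emit raw item responses.
#' @param seed RNG seed.
#' @return An object of class `"trial_spec"`.
#' @export
trial_spec <- function(n_schools = 20, classes_per_school = 4,
                       students_per_class = 25,
                       pretest_age_mean = 130, pretest_age_sd = 4,
                       posttest_offset = 2, followup_offset = 10,
                       p_male = 0.485, p_hispanic = 0.149, p_white = 0.594,
                       trait_noise_sd = 0.25,
                       true_weights = default_true_weights(),
                       program_psych_shift = 0,
                       program_logodds_multiplier = 1,
                       retention_posttest = 0.335,
                       retention_followup = 0.243,
                       school_attrition_share = 0.7,
                       noise_preset = c("study-like", "norms-like"),
                       reliability = NULL,
                       latent_dist = c("uniform", "top_heavy"),
                       battery = default_battery(),
                       seed = 1L) {
  noise_preset <- match.arg(noise_preset)
  latent_dist <- match.arg(latent_dist)
  props <- c(p_male, p_hispanic, p_white, retention_posttest,
             retention_followup, school_attrition_share)
  if (any(props < 0 | props > 1))
    stop("proportions must lie in [0, 1]", call. = FALSE)
  if (any(c(n_schools, classes_per_school, students_per_class) < 1))
    stop("cohort counts must be positive", call. = FALSE)
  if (is.null(reliability))
    reliability <- if (noise_preset == "study-like") 0.681 else 0.90
  structure(list(
    n_schools = as.integer(n_schools),
    classes_per_school = as.integer(classes_per_school),
    students_per_class = as.integer(students_per_class),
    pretest_age_mean = pretest_age_mean, pretest_age_sd = pretest_age_sd,
    posttest_offset = posttest_offset, followup_offset = followup_offset,
    p_male = p_male, p_hispanic = p_hispanic, p_white = p_white,
    trait_noise_sd = trait_noise_sd, true_weights = true_weights,
    program_psych_shift = program_psych_shift,
    program_logodds_multiplier = program_logodds_multiplier,
    retention_posttest = retention_posttest,
    retention_followup = retention_followup,
    school_attrition_share = school_attrition_share,
    noise_preset = noise_preset, reliability = reliability,
    latent_dist = latent_dist, battery = battery, seed = as.integer(seed)
  ), class = "trial_spec")
}

#' Generate raw item responses consistent with a psych score
#'
#' Each item is the student's psych score plus independent Gaussian noise,
#' rounded to the item's response levels and clamped to `[0, 10]`. The noise
#' scale is solved in closed form from the Cronbach-alpha target: with k
#' items and between-student psych variance V, alpha implies a mean
#' inter-item correlation r = alpha / (k - alpha (k - 1)) and a per-item
#' noise variance V (1 - r) / r, from which the rounding variance (1/12 on
#' the 0--10 integer grid) is subtracted.
#'
#' @param psych Vector of psych scores in `[0, 10]`.
#' @param battery An [item_battery()].
#' @param reliability Target alpha in (0, 1).
#' @param psych_var Between-student psych variance; default the sample
#'   variance of `psych` (must be positive).
#' @param seed Optional RNG seed.
#' @return Integer matrix, students x items, with item-id column names.
#' @export
item_responses_from_psych <- function(psych, battery = default_battery(),
                                      reliability = 0.681, psych_var = NULL,
                                      seed = NULL) {
  if (any(psych < 0 | psych > 10, na.rm = TRUE))
    stop("psych must lie in [0, 10]", call. = FALSE)
  if (reliability <= 0 || reliability >= 1)
    stop("reliability target must lie in (0, 1)", call. = FALSE)
  k <- length(battery$items)
  if (is.null(psych_var)) psych_var <- stats::var(psych)
  if (!is.finite(psych_var) || psych_var <= 0)
    stop("between-student psych variance must be positive; supply psych_var",
         call. = FALSE)
  r_bar <- reliability / (k - reliability * (k - 1))
  if (r_bar <= 0 || r_bar >= 1)
    stop("reliability target infeasible for this battery size", call. = FALSE)
  noise_var <- max(psych_var * (1 - r_bar) / r_bar - 1 / 12, 0)
  with_seed(seed, {
    n <- length(psych)
    m <- matrix(NA_integer_, n, k,
                dimnames = list(NULL, battery_item_ids(battery)))
    for (j in seq_len(k)) {
      spec_j <- battery$items[[j]]
      lev <- spec_j$n_response_levels - 1L
      coded <- clamp(psych + stats::rnorm(n, 0, sqrt(noise_var)), 0, 10)
      coded_lev <- as.integer(round(coded / 10 * lev))
      # invert the coding map so the emitted raw response codes back to the
      # intended value (reverse-ordered items run most-desirable-first)
      m[, j] <- if (spec_j$desirable_high) coded_lev else lev - coded_lev
    }
    m
  })
}

.draw_latent <- function(n, dist) {
  if (dist == "uniform") return(stats::runif(n, 0, 100))
  # top_heavy: 13% at the top ranking, 70% uniform below the 60th pct,
  # the remainder uniform between the 60th and the top
  grp <- stats::runif(n)
  u <- numeric(n)
  top <- grp < 0.13
  low <- grp >= 0.13 & grp < 0.83
  u[top] <- 99.5
  u[low] <- stats::runif(sum(low), 0.5, 60)
  u[!top & !low] <- stats::runif(sum(!top & !low), 60, 99.5)
  u
}

#' Generate a synthetic nested trial cohort
#'
#' Draws a school > classroom > student hierarchy with one latent normative
#' percentile per student. Each wave's realized psych is the normative-table
#' value at that percentile and the wave's age, plus within-percentile trait
#' scatter (plus the programmed protective shift after pretest); raw item
#' responses are emitted around the realized psych at the spec's reliability
#' target; 30-day behavior flags are Bernoulli draws under the true weights
#' at the realized psych and age (with the programmed log-odds multiplier
#' after pretest); attrition removes whole schools plus independent students
#' at posttest and follow-up.
#'
#' @param spec A [trial_spec()].
#' @param table A [norm_table()] covering the wave ages.
#' @return Long data frame in the pipeline's survey input format: one row
#'   per retained student x wave, with `student_id`, `classroom_id`,
#'   `school_id`, `wave`, `age_months`, demographics (`gender`, `hispanic`,
#'   `race`), the battery's raw item columns, and the four behavior flag
#'   columns. The latent truth (percentile and true psych per wave) is
#'   attached as attribute `"truth"`, the seed as `"seed"`.
#' @export
generate_trial <- function(spec, table) {
  stopifnot(inherits(spec, "trial_spec"), inherits(table, "norm_table"))
  if (spec$pretest_age_mean < min(table$ages) ||
      spec$pretest_age_mean + spec$followup_offset > max(table$ages))
    stop("wave ages fall outside the normative table's range", call. = FALSE)
  with_seed(spec$seed, {
    n <- spec$n_schools * spec$classes_per_school * spec$students_per_class
    school <- rep(sprintf("S%03d", seq_len(spec$n_schools)),
                  each = spec$classes_per_school * spec$students_per_class)
    class_in_school <- rep(rep(seq_len(spec$classes_per_school),
                               each = spec$students_per_class),
                           times = spec$n_schools)
    classroom <- sprintf("%s_C%02d", school, class_in_school)
    student <- sprintf("%s_T%03d", classroom,
                       rep(seq_len(spec$students_per_class),
                           times = spec$n_schools * spec$classes_per_school))

    gender <- ifelse(stats::runif(n) < spec$p_male, "male", "female")
    hispanic <- as.integer(stats::runif(n) < spec$p_hispanic)
    race <- ifelse(stats::runif(n) < spec$p_white, "white",
                   ifelse(stats::runif(n) < 0.426, "black", "other"))
    u <- .draw_latent(n, spec$latent_dist)

    age_pre <- clamp(round(stats::rnorm(n, spec$pretest_age_mean,
                                        spec$pretest_age_sd)),
                     min(table$ages), max(table$ages))
    ages <- cbind(pretest = age_pre,
                  posttest = clamp(age_pre + spec$posttest_offset,
                                   min(table$ages), max(table$ages)),
                  followup = clamp(age_pre + spec$followup_offset,
                                   min(table$ages), max(table$ages)))

    # table value at the latent percentile, interpolated between grid rows
    table_value <- function(lat, age) {
      ai <- .age_index(table, age)
      g <- table$percentiles
      lu <- clamp(lat, min(g), max(g))
      i <- findInterval(lu, g, all.inside = TRUE)
      w <- (lu - g[i]) / (g[i + 1] - g[i])
      (1 - w) * table$values[cbind(i, ai)] + w * table$values[cbind(i + 1, ai)]
    }

    waves <- c("pretest", "posttest", "followup")
    true_psych <- sapply(waves, function(wv) {
      p <- table_value(u, ages[, wv]) +
        stats::rnorm(n, 0, spec$trait_noise_sd)
      if (wv != "pretest") p <- p + spec$program_psych_shift
      clamp(p, 0, 10)
    })

    # retention: whole-school survival times independent student survival
    r_school <- function(r) r^spec$school_attrition_share
    r_student <- function(r) r^(1 - spec$school_attrition_share)
    keep_wave <- function(r) {
      school_up <- stats::runif(spec$n_schools) < r_school(r)
      names(school_up) <- sprintf("S%03d", seq_len(spec$n_schools))
      school_up[school] & (stats::runif(n) < r_student(r))
    }
    retained <- cbind(pretest = rep(TRUE, n),
                      posttest = keep_wave(spec$retention_posttest),
                      followup = keep_wave(spec$retention_followup))

    psych_var <- stats::var(true_psych[, "pretest"])
    rows <- list()
    for (wv in waves) {
      k <- retained[, wv]
      if (!any(k)) next
      tp <- true_psych[k, wv]
      aw <- ages[k, wv]
      items <- item_responses_from_psych(tp, spec$battery,
                                         reliability = spec$reliability,
                                         psych_var = psych_var)
      d <- data.frame(student_id = student[k], classroom_id = classroom[k],
                      school_id = school[k], wave = wv, age_months = aw,
                      gender = gender[k], hispanic = hispanic[k],
                      race = race[k], stringsAsFactors = FALSE)
      d <- cbind(d, as.data.frame(items))
      for (b in names(spec$true_weights)) {
        w <- spec$true_weights[[b]]
        t_lin <- w$b_intercept + w$b_psych * tp + w$b_psych_age * (tp * aw)
        if (wv != "pretest") t_lin <- t_lin * spec$program_logodds_multiplier
        d[[b]] <- stats::rbinom(sum(k), 1, stats::plogis(t_lin))
      }
      rows[[wv]] <- d
    }
    out <- do.call(rbind, rows)
    out <- out[order(out$student_id, match(out$wave, waves)), , drop = FALSE]
    rownames(out) <- NULL
    truth <- data.frame(student_id = student, latent_percentile = u,
                        true_psych_pretest = true_psych[, "pretest"],
                        true_psych_posttest = true_psych[, "posttest"],
                        true_psych_followup = true_psych[, "followup"],
                        stringsAsFactors = FALSE)
    attr(out, "truth") <- truth
    attr(out, "seed") <- spec$seed
    out
  })
}

#' Write / read a survey table as delimited text
#'
#' Standard comma-separated survey format, one row per student x wave, with
#' missing values as empty fields. Generated tables embed their seed in a
#' leading `#`-comment header line.
#'
#' @param surveys Survey data frame (e.g. from [generate_trial()]).
#' @param path CSV path.
#' @param seed Seed recorded in the header; default the table's `"seed"`
#'   attribute, if any.
#' @return `path` invisibly; the reader returns the data frame.
#' @export
write_surveys <- function(surveys, path, seed = attr(surveys, "seed")) {
  con <- file(path, "w")
  on.exit(close(con))
  if (!is.null(seed)) writeLines(sprintf("# seed: %d", as.integer(seed)), con)
  utils::write.csv(surveys, con, row.names = FALSE, na = "")
  invisible(path)
}

#' @rdname write_surveys
#' @export
read_surveys <- function(path) {
  if (!file.exists(path))
    stop("survey file not found: ", path, call. = FALSE)
  utils::read.csv(path, comment.char = "#", na.strings = c("NA", ""),
                  stringsAsFactors = FALSE)
}
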