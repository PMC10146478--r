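# Virtual-controls matching: peg each treatment case to the normative
# percentile whose curve best matches the case's pretest age and psych score,
# then read the virtual case's psych scores and use probabilities off the
# table at the treatment case's later-wave ages. Later-wave self-reports are
# never consulted.

# Resolve an age against the table: below-range ages are an exclusion
# (normative pools contain no one younger); above-range ages are clamped to
# the table maximum with a warning.
.resolve_age <- function(table, age_months) {
  age <- as.integer(age_months)
  if (any(age < min(table$ages), na.rm = TRUE))
    stop("age below the table's range", call. = FALSE)
  hi <- !is.na(age) & age > max(table$ages)
  if (any(hi)) {
    warning(sprintf("%d age(s) above %d months clamped to the table maximum",
                    sum(hi), max(table$ages)), call. = FALSE)
    age[hi] <- max(table$ages)
  }
  age
}

#' Match a pretest case to its nearest normative percentile
#'
#' Returns the grid percentile whose table psych score at `age_months` is
#' closest (absolute difference) to the observed `psych`. Ties are broken
#' toward the lower percentile -- the conservative direction, since a lower
#' percentile means a lower psych score and hence higher estimated risk.
#'
#' @param table A [norm_table()].
#' @param age_months Pretest age in months (inside the table's range; above
#'   the maximum is clamped with a warning, below the minimum is an error).
#' @param psych Observed pretest psych score in `[0, 10]`.
#' @return The matched grid percentile (scalar, or vector if inputs are
#'   vectors of equal length).
#' @export
match_percentile <- function(table, age_months, psych) {
  stopifnot(inherits(table, "norm_table"))
  if (any(psych < 0 | psych > 10, na.rm = TRUE))
    stop("psych must lie in [0, 10]", call. = FALSE)
  age <- .resolve_age(table, age_months)
  n <- max(length(age), length(psych))
  age <- rep_len(age, n); psych <- rep_len(psych, n)
  ai <- .age_index(table, age)
  idx <- vapply(seq_len(n), function(i) {
    which.min(abs(table$values[, ai[i]] - psych[i]))  # first min = lower pct
  }, integer(1))
  table$percentiles[idx]
}

#' Build the virtual-control case for one treatment case
#'
#' The matched percentile is determined from the pretest wave only and held
#' constant at every later wave ("pegging"). At each wave where the
#' treatment case has a recorded age, the virtual case's psych score is the
#' table value at the pegged percentile and that age, and its behavior
#' probabilities come from the calibrated logistic weights at that psych and
#' age. The treatment case's posttest/follow-up psych scores and behavior
#' self-reports are never used.
#'
#' @param table A [norm_table()].
#' @param weights Named list of [behavior_weights()] (one per calibrated
#'   behavior).
#' @param case Data frame of one student's waves with columns `wave`,
#'   `age_months`, `psych` (pretest psych required), and optionally
#'   `student_id`, demographics and cluster ids, which are inherited.
#' @param pretest_wave Name of the pretest wave (default `"pretest"`).
#' @return Data frame, one row per wave with a recorded age: inherited ids,
#'   `wave`, `matched_percentile`, `age_months`, `psych` (virtual), and one
#'   `p_<behavior>` column per calibrated behavior.
#' @export
build_virtual_case <- function(table, weights, case,
                               pretest_wave = "pretest") {
  stopifnot(is.data.frame(case))
  if (!length(weights)) stop("no calibrated behavior weights", call. = FALSE)
  pre <- case[case$wave == pretest_wave, , drop = FALSE]
  if (nrow(pre) != 1 || is.na(pre$psych) || is.na(pre$age_months))
    stop("pretest wave with age and psych score is required", call. = FALSE)
  pct <- match_percentile(table, pre$age_months, pre$psych)
  waves <- case[!is.na(case$age_months), , drop = FALSE]
  age <- .resolve_age(table, waves$age_months)
  vpsych <- eval_norm(table, rep(pct, nrow(waves)), age)
  carry <- intersect(c("student_id", "classroom_id", "school_id",
                       "gender", "hispanic", "race"), names(waves))
  out <- cbind(waves[, carry, drop = FALSE],
               data.frame(wave = waves$wave, matched_percentile = pct,
                          age_months = waves$age_months, psych = vpsych))
  for (b in names(weights))
    out[[paste0("p_", b)]] <- probability_of_use(weights[[b]], vpsych, age)
  rownames(out) <- NULL
  out
}

#' Match a whole treatment cohort to virtual controls
#'
#' Vectorized cohort form of [build_virtual_case()]: one virtual case per
#' eligible treatment case, plus an exclusion log. A case is excluded when it
#' has no pretest row (`missing_pretest`), a missing pretest psych score
#' (`missing_pretest_psych`), or a pretest age below the table's range
#' (`age_below_range`).
#'
#' @param table A [norm_table()].
#' @param weights Named list of [behavior_weights()].
#' @param surveys Long survey data frame (one row per student x wave) with
#'   columns `student_id`, `wave`, `age_months`, `psych`, and optionally
#'   demographics/cluster ids to inherit.
#' @param pretest_wave Name of the pretest wave.
#' @return List with `virtual` (data frame as in [build_virtual_case()], all
#'   students), and `exclusions` (data frame `student_id`, `reason`).
#' @export
match_cohort <- function(table, weights, surveys, pretest_wave = "pretest") {
  stopifnot(inherits(table, "norm_table"))
  if (!length(weights)) stop("no calibrated behavior weights", call. = FALSE)
  pre <- surveys[surveys$wave == pretest_wave, , drop = FALSE]
  pre <- pre[!duplicated(pre$student_id), , drop = FALSE]
  all_ids <- unique(surveys$student_id)
  excl <- data.frame(student_id = character(0), reason = character(0))
  add_excl <- function(ids, reason) {
    if (length(ids))
      rbind(excl, data.frame(student_id = as.character(ids), reason = reason))
    else excl
  }
  excl <- add_excl(setdiff(all_ids, pre$student_id), "missing_pretest")
  no_psych <- is.na(pre$psych)
  excl <- add_excl(pre$student_id[no_psych], "missing_pretest_psych")
  pre <- pre[!no_psych, , drop = FALSE]
  no_age <- is.na(pre$age_months)
  excl <- add_excl(pre$student_id[no_age], "missing_pretest_age")
  pre <- pre[!no_age, , drop = FALSE]
  young <- pre$age_months < min(table$ages)
  excl <- add_excl(pre$student_id[young], "age_below_range")
  pre <- pre[!young, , drop = FALSE]
  if (!nrow(pre)) stop("no eligible treatment cases to match", call. = FALSE)

  pct <- match_percentile(table, pre$age_months, pre$psych)
  names(pct) <- pre$student_id

  rows <- surveys[surveys$student_id %in% pre$student_id &
                    !is.na(surveys$age_months), , drop = FALSE]
  age <- .resolve_age(table, rows$age_months)
  row_pct <- unname(pct[as.character(rows$student_id)])
  vpsych <- eval_norm(table, row_pct, age)
  carry <- intersect(c("student_id", "classroom_id", "school_id",
                       "gender", "hispanic", "race"), names(rows))
  virtual <- cbind(rows[, carry, drop = FALSE],
                   data.frame(wave = rows$wave, matched_percentile = row_pct,
                              age_months = rows$age_months, psych = vpsych))
  for (b in names(weights))
    virtual[[paste0("p_", b)]] <- probability_of_use(weights[[b]], vpsych, age)
  rownames(virtual) <- NULL
  list(virtual = virtual, exclusions = excl)
}

#' Write virtual cases / exclusion log as text
#'
#' Virtual cases go to CSV (one row per case x wave); exclusions go to a
#' plain-text log, one line per excluded case with a machine-readable reason
#' code.
#'
#' @param matched Result of [match_cohort()].
#' @param cases_path CSV path for the virtual cases.
#' @param exclusions_path Path for the exclusion log.
#' @return `cases_path`, invisibly.
#' @export
write_virtual_cases <- function(matched, cases_path, exclusions_path = NULL) {
  utils::write.csv(matched$virtual, cases_path, row.names = FALSE)
  if (!is.null(exclusions_path)) {
    lines <- sprintf("%s\t%s", matched$exclusions$student_id,
                     matched$exclusions$reason)
    writeLines(lines, exclusions_path)
  }
  invisible(cases_path)
}
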