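# Outcome comparison: treatment self-reports (0/1) against virtual-control
# probability estimates, at the student level and aggregated to classrooms
# and schools, plus demographic subgroup z-tests. The mixed-scale contrast
# (observed flags vs model probabilities) is the method's design: both sides
# estimate a 30-day prevalence.

#' Build paired student-level outcome cells
#'
#' One cell per student x condition x behavior x wave. Treatment cells carry
#' the 0/1 self-report; virtual-control cells carry the model probability.
#' Pairing restricts both sides to students with a non-missing self-report
#' for that behavior and wave, so treatment and control sides are always the
#' same students (equal n by construction).
#'
#' @param surveys Scored survey data frame (long, with behavior flag columns
#'   and cluster ids).
#' @param virtual The `virtual` data frame from [match_cohort()].
#' @param behaviors Behaviors to include; default those with `p_<behavior>`
#'   columns in `virtual`.
#' @return Data frame with columns `unit_id`, `condition`, `behavior`,
#'   `wave`, `value`, `classroom_id`, `school_id`.
#' @export
outcome_cells <- function(surveys, virtual, behaviors = NULL) {
  if (is.null(behaviors))
    behaviors <- sub("^p_", "", grep("^p_", names(virtual), value = TRUE))
  if (!length(behaviors)) stop("no calibrated behaviors found", call. = FALSE)
  key <- function(d) paste(d$student_id, d$wave, sep = "\r")
  vkey <- key(virtual)
  out <- lapply(behaviors, function(b) {
    flag <- surveys[[b]]
    keep <- !is.na(flag) & key(surveys) %in% vkey
    tr <- surveys[keep, , drop = FALSE]
    vc <- virtual[match(key(tr), vkey), , drop = FALSE]
    rbind(
      data.frame(unit_id = as.character(tr$student_id), condition = "treatment",
                 behavior = b, wave = tr$wave, value = as.numeric(flag[keep]),
                 classroom_id = tr$classroom_id, school_id = tr$school_id,
                 stringsAsFactors = FALSE),
      data.frame(unit_id = as.character(vc$student_id),
                 condition = "virtual_control",
                 behavior = b, wave = vc$wave,
                 value = vc[[paste0("p_", b)]],
                 classroom_id = vc$classroom_id, school_id = vc$school_id,
                 stringsAsFactors = FALSE)
    )
  })
  out <- do.call(rbind, out)
  rownames(out) <- NULL
  out
}

#' Aggregate student cells to classroom or school level
#'
#' One cell per cluster x condition x behavior x wave; the cell value is the
#' unweighted mean over member students with non-missing values. For schools
#' the default is the mean over all the school's students
#' (student-weighted); `weighting = "class_mean"` instead averages the
#' school's classroom means, which differs when class sizes are unequal.
#'
#' @param cells Student-level cells from [outcome_cells()].
#' @param level `"class"` or `"school"`.
#' @param weighting School aggregation rule: `"student"` (default) or
#'   `"class_mean"`.
#' @return Aggregated cells data frame (`unit_id` is the cluster id).
#' @export
aggregate_cells <- function(cells, level = c("class", "school"),
                            weighting = c("student", "class_mean")) {
  level <- match.arg(level)
  weighting <- match.arg(weighting)
  cells <- cells[!is.na(cells$value), , drop = FALSE]
  if (level == "school" && weighting == "class_mean")
    cells <- aggregate_cells(cells, "class")
  id_col <- if (level == "class") "classroom_id" else "school_id"
  if (any(is.na(cells[[id_col]])))
    stop("cluster ids are required on all cells", call. = FALSE)
  by <- list(unit_id = cells[[id_col]], condition = cells$condition,
             behavior = cells$behavior, wave = cells$wave)
  # classrooms are nested in schools; keep the school id on class cells so
  # they can be aggregated once more
  if (level == "class") by$school_id <- cells$school_id
  agg <- stats::aggregate(cells["value"], by = by, FUN = mean)
  agg$unit_id <- as.character(agg$unit_id)
  agg
}

# Welch two-sample comparison with the degenerate-variance guard.
.welch <- function(treat_values, control_values) {
  n1 <- length(treat_values); n2 <- length(control_values)
  if (n1 < 2 || n2 < 2)
    stop("at least 2 units per condition are required", call. = FALSE)
  m1 <- mean(treat_values); m2 <- mean(control_values)
  v1 <- stats::var(treat_values); v2 <- stats::var(control_values)
  degenerate <- FALSE
  if (v1 == 0 && v2 == 0) {
    if (m1 == m2) {
      t_stat <- 0; df <- n1 + n2 - 2; p <- 1
    } else {
      degenerate <- TRUE; t_stat <- NA_real_; df <- NA_real_; p <- NA_real_
    }
  } else {
    ht <- stats::t.test(control_values, treat_values)  # control - treatment
    t_stat <- unname(ht$statistic); df <- unname(ht$parameter)
    p <- ht$p.value
  }
  pooled <- sqrt(((n1 - 1) * v1 + (n2 - 1) * v2) / (n1 + n2 - 2))
  d <- if (pooled > 0) (m2 - m1) / pooled else if (m1 == m2) 0 else NA_real_
  list(mean_treatment = m1, mean_control = m2, t_stat = t_stat, df = df,
       p_value = p, cohens_d = d, n_treatment = n1, n_control = n2,
       degenerate = degenerate)
}

#' Compare treatment against virtual controls for one contrast
#'
#' Welch (unequal-variance) two-sample t-test with Welch--Satterthwaite
#' degrees of freedom, two-sided, plus Cohen's d computed with the pooled
#' standard deviation and oriented control minus treatment: positive d means
#' the virtual-control estimate exceeds the treatment prevalence (the
#' protective-effect direction). Zero variance in both groups with equal
#' means yields t = 0, d = 0; unequal means with zero variance is flagged
#' degenerate.
#'
#' @param treatment_cells,control_cells Cell data frames (student-level or
#'   aggregated) for the two conditions; filtered to `behavior` and `wave`.
#' @param level Label recorded in the result (`"student"`, `"class"`,
#'   `"school"`).
#' @param behavior,wave Contrast selectors.
#' @return An object of class `"comparison_result"`.
#' @export
compare <- function(treatment_cells, control_cells, level, behavior, wave) {
  pick <- function(cells) {
    v <- cells$value[cells$behavior == behavior & cells$wave == wave]
    v[!is.na(v)]
  }
  w <- .welch(pick(treatment_cells), pick(control_cells))
  structure(c(list(level = level, behavior = behavior, wave = wave), w),
            class = "comparison_result")
}

#' @export
print.comparison_result <- function(x, ...) {
  cat(sprintf("%s / %s / %s: treatment %.2f%% vs control %.2f%% (t = %.3f, df = %.0f, p = %.3g, d = %.3f)%s\n",
              x$level, x$behavior, x$wave, 100 * x$mean_treatment,
              100 * x$mean_control, x$t_stat, x$df, x$p_value, x$cohens_d,
              if (isTRUE(x$degenerate)) " [degenerate]" else ""))
  invisible(x)
}

#' Full comparison table across levels, behaviors and waves
#'
#' Convenience driver producing one row per level x behavior x wave, in the
#' shape of a published outcome table: prevalences, t, df, p and Cohen's d.
#'
#' @param cells Student-level cells from [outcome_cells()].
#' @param levels Levels to report.
#' @param weighting School aggregation rule, see [aggregate_cells()].
#' @return Data frame of comparison rows.
#' @export
compare_all <- function(cells, levels = c("student", "class", "school"),
                        weighting = "student") {
  combos <- unique(cells[, c("behavior", "wave")])
  rows <- list()
  for (lev in levels) {
    lev_cells <- switch(lev,
      student = cells,
      class = aggregate_cells(cells, "class"),
      school = aggregate_cells(cells, "school", weighting))
    tr <- lev_cells[lev_cells$condition == "treatment", , drop = FALSE]
    vc <- lev_cells[lev_cells$condition == "virtual_control", , drop = FALSE]
    for (i in seq_len(nrow(combos))) {
      # a contrast can be unavailable at an aggregate level (e.g. a single
      # surviving school); report it as an NA row rather than aborting
      res <- tryCatch(compare(tr, vc, lev, combos$behavior[i], combos$wave[i]),
                      error = function(e) NULL)
      rows[[length(rows) + 1]] <- if (is.null(res)) data.frame(
        level = lev, behavior = combos$behavior[i], wave = combos$wave[i],
        pct_treatment = NA_real_, pct_control = NA_real_,
        t = NA_real_, df = NA_real_, p = NA_real_, d = NA_real_,
        n_treatment = NA_integer_, n_control = NA_integer_,
        degenerate = NA) else data.frame(
        level = lev, behavior = res$behavior, wave = res$wave,
        pct_treatment = 100 * res$mean_treatment,
        pct_control = 100 * res$mean_control,
        t = res$t_stat, df = res$df, p = res$p_value, d = res$cohens_d,
        n_treatment = res$n_treatment, n_control = res$n_control,
        degenerate = res$degenerate)
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

.subgroup_filter <- function(d, subgroup) {
  switch(subgroup,
    boys = !is.na(d$gender) & d$gender == "male",
    girls = !is.na(d$gender) & d$gender == "female",
    hispanic = !is.na(d$hispanic) & d$hispanic == 1,
    non_hispanic = !is.na(d$hispanic) & d$hispanic == 0,
    white = !is.na(d$race) & d$race == "white",
    non_white = !is.na(d$race) & d$race != "white",
    stop("unknown subgroup: ", subgroup, call. = FALSE))
}

#' Demographic subgroup comparison by two-proportion z-test
#'
#' Virtual cases inherit the gender and race/ethnicity of their matched
#' treatment case, so each subgroup contrast compares a treatment subgroup
#' with its own matched virtual controls (equal n by construction). The
#' treatment prevalence is compared with the mean virtual-control
#' probability by the standard pooled two-proportion z statistic, two-sided,
#' flagged significant at the 95% confidence level by default.
#'
#' @param surveys Scored survey data frame with demographics and behavior
#'   flags.
#' @param virtual The `virtual` data frame from [match_cohort()].
#' @param subgroup One of `"boys"`, `"girls"`, `"hispanic"`,
#'   `"non_hispanic"`, `"white"`, `"non_white"`.
#' @param behavior,wave Contrast selectors.
#' @param alpha Significance level (default 0.05).
#' @return An object of class `"subgroup_result"`: subgroup, behavior, wave,
#'   both prevalences, z, p, `significant_at_95`, n per side.
#' @export
subgroup_compare <- function(surveys, virtual, subgroup, behavior, wave,
                             alpha = 0.05) {
  flag <- surveys[[behavior]]
  keep <- surveys$wave == wave & !is.na(flag) & .subgroup_filter(surveys, subgroup)
  tr <- surveys[keep, , drop = FALSE]
  if (!nrow(tr))
    stop("subgroup '", subgroup, "' is empty for this contrast", call. = FALSE)
  vkey <- paste(virtual$student_id, virtual$wave, sep = "\r")
  vc <- virtual[match(paste(tr$student_id, wave, sep = "\r"), vkey), ,
                drop = FALSE]
  ok <- !is.na(vc$student_id)
  tr <- tr[ok, , drop = FALSE]; vc <- vc[ok, , drop = FALSE]
  if (!nrow(tr))
    stop("subgroup '", subgroup, "' has no matched virtual cases", call. = FALSE)
  n <- nrow(tr)
  p1 <- mean(as.numeric(tr[[behavior]]))
  p2 <- mean(vc[[paste0("p_", behavior)]])
  pbar <- (p1 + p2) / 2
  se <- sqrt(pbar * (1 - pbar) * (2 / n))
  z <- if (se > 0) (p2 - p1) / se else 0
  p_value <- 2 * stats::pnorm(-abs(z))
  structure(list(subgroup = subgroup, behavior = behavior, wave = wave,
                 prevalence_treatment = p1, prevalence_control = p2,
                 z_stat = z, p_value = p_value,
                 significant_at_95 = p_value < alpha,
                 n_treatment = n, n_control = n),
            class = "subgroup_result")
}

#' Subgroup table across all six subgroups
#'
#' @param surveys,virtual As in [subgroup_compare()].
#' @param behaviors Behaviors to test; default those calibrated in `virtual`.
#' @param waves Test waves (default posttest and follow-up).
#' @param alpha Significance level.
#' @return Data frame, one row per subgroup x behavior x wave.
#' @export
subgroup_table <- function(surveys, virtual, behaviors = NULL,
                           waves = c("posttest", "followup"), alpha = 0.05) {
  if (is.null(behaviors))
    behaviors <- sub("^p_", "", grep("^p_", names(virtual), value = TRUE))
  subgroups <- c("boys", "girls", "hispanic", "non_hispanic", "white",
                 "non_white")
  rows <- list()
  for (sg in subgroups) for (b in behaviors) for (w in waves) {
    res <- tryCatch(subgroup_compare(surveys, virtual, sg, b, w, alpha = alpha),
                    error = function(e) NULL)  # empty subgroup at this wave
    rows[[length(rows) + 1]] <- if (is.null(res)) data.frame(
      subgroup = sg, behavior = b, wave = w,
      pct_treatment = NA_real_, pct_control = NA_real_,
      z = NA_real_, p = NA_real_, significant_at_95 = NA, n = NA_integer_)
    else data.frame(
      subgroup = sg, behavior = b, wave = w,
      pct_treatment = 100 * res$prevalence_treatment,
      pct_control = 100 * res$prevalence_control,
      z = res$z_stat, p = res$p_value,
      significant_at_95 = res$significant_at_95, n = res$n_treatment)
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Dichotomize pre-to-later change as an increase flag
#'
#' For each unit x condition x behavior with both waves present, emits 1
#' when the later-wave value strictly exceeds the pretest value, else 0
#' (ties are no increase). The resulting table is analysis-ready for
#' external multi-level modelling; model fitting itself is out of this
#' package's scope.
#'
#' @param cells Cells (any level) covering both waves.
#' @param to_wave Later wave (`"posttest"` or `"followup"`).
#' @param from_wave Baseline wave (default `"pretest"`).
#' @return Data frame `unit_id`, `condition`, `behavior`, `from_wave`,
#'   `to_wave`, `increase` (0/1). Units missing either wave are omitted.
#' @export
dichotomize_increase <- function(cells, to_wave, from_wave = "pretest") {
  pre <- cells[cells$wave == from_wave & !is.na(cells$value), , drop = FALSE]
  post <- cells[cells$wave == to_wave & !is.na(cells$value), , drop = FALSE]
  key <- function(d) paste(d$unit_id, d$condition, d$behavior, sep = "\r")
  idx <- match(key(post), key(pre))
  ok <- !is.na(idx)
  post <- post[ok, , drop = FALSE]
  prev <- pre$value[idx[ok]]
  data.frame(unit_id = post$unit_id, condition = post$condition,
             behavior = post$behavior, from_wave = from_wave,
             to_wave = to_wave,
             increase = as.integer(post$value > prev),
             stringsAsFactors = FALSE)
}
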