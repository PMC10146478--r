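#' Define a psychosocial survey item
#'
#' An item specification records how one survey prompt is coded onto the
#' 0--10 theoretically-desirable scale: the construct it measures, the number
#' of ordered response levels, and whether the raw response order already runs
#' from least to most desirable.
#'
#' @param item_id Unique item identifier (character).
#' @param construct One of `"belief_consequences"`, `"intention_avoid"`,
#'   `"normative_belief"`, `"refusal_ease"`.
#' @param n_response_levels Number of ordered response levels (>= 2).
#' @param desirable_high If `TRUE`, the highest raw level is the most
#'   theoretically desirable and maps to 10; if `FALSE` the order is reversed
#'   before coding (e.g. "How many people your age get drunk?" where "none"
#'   is the first level and the most desirable).
#' @return An object of class `"item_spec"`.
#' @seealso [default_battery()], [code_item()]
#' @export
item_spec <- function(item_id, construct, n_response_levels = 11L,
                      desirable_high = TRUE) {
  construct <- match.arg(construct, c("belief_consequences", "intention_avoid",
                                      "normative_belief", "refusal_ease"))
  n_response_levels <- as.integer(n_response_levels)
  if (is.na(n_response_levels) || n_response_levels < 2L)
    stop("n_response_levels must be an integer >= 2", call. = FALSE)
  structure(
    list(item_id = as.character(item_id), construct = construct,
         n_response_levels = n_response_levels,
         desirable_high = isTRUE(desirable_high)),
    class = "item_spec"
  )
}

#' Assemble an ordered battery of survey items
#'
#' @param items List of [item_spec()] objects with unique ids.
#' @param min_items_required Minimum number of non-missing items needed for a
#'   psych score to be computed (default 7, a majority of the 13-item default
#'   battery).
#' @return An object of class `"item_battery"`.
#' @export
item_battery <- function(items, min_items_required = 7L) {
  if (!length(items) || !all(vapply(items, inherits, TRUE, "item_spec")))
    stop("items must be a non-empty list of item_spec objects", call. = FALSE)
  ids <- vapply(items, `[[`, character(1), "item_id")
  if (anyDuplicated(ids))
    stop("duplicate item_id in battery: ", ids[duplicated(ids)][1], call. = FALSE)
  min_items_required <- as.integer(min_items_required)
  if (is.na(min_items_required) || min_items_required < 1L ||
      min_items_required > length(items))
    stop("min_items_required must be between 1 and the number of items",
         call. = FALSE)
  structure(list(items = items, min_items_required = min_items_required),
            class = "item_battery")
}

#' @export
print.item_battery <- function(x, ...) {
  cons <- table(vapply(x$items, `[[`, character(1), "construct"))
  cat(sprintf("Item battery: %d items (%s); min required: %d\n",
              length(x$items),
              paste(sprintf("%s=%d", names(cons), cons), collapse = ", "),
              x$min_items_required))
  invisible(x)
}

#' Item ids of a battery, in order
#' @param battery An `"item_battery"`.
#' @return Character vector of item ids.
#' @export
battery_item_ids <- function(battery) {
  vapply(battery$items, `[[`, character(1), "item_id")
}

#' The default 13-item psychosocial battery
#'
#' Three beliefs about consequences of use, three intentions to avoid use,
#' four normative beliefs about peer prevalence/acceptability, and three
#' refusal-ease items. All items use 11 ordered response levels so coded
#' values fall on the 0--10 integer grid; the normative-belief prevalence
#' items are reverse-ordered (the first level, "none", is most desirable).
#'
#' @param min_items_required Passed to [item_battery()].
#' @return An `"item_battery"` of 13 items.
#' @export
default_battery <- function(min_items_required = 7L) {
  it <- function(id, con, high = TRUE) item_spec(id, con, 11L, high)
  item_battery(list(
    it("belief_smoke_harm",      "belief_consequences"),
    it("belief_alcohol_harm",    "belief_consequences"),
    it("belief_drug_harm",       "belief_consequences"),
    it("intent_avoid_alcohol",   "intention_avoid"),
    it("intent_avoid_cigarette", "intention_avoid"),
    it("intent_avoid_marijuana", "intention_avoid"),
    it("norm_peer_drink",        "normative_belief", high = FALSE),
    it("norm_peer_smoke",        "normative_belief", high = FALSE),
    it("norm_peer_drunk",        "normative_belief", high = FALSE),
    it("norm_accept_use",        "normative_belief", high = FALSE),
    it("refuse_alcohol",         "refusal_ease"),
    it("refuse_cigarette",       "refusal_ease"),
    it("refuse_marijuana",       "refusal_ease")
  ), min_items_required = min_items_required)
}

#' Read an item battery from a JSON configuration file
#'
#' The file holds an array of objects with fields `item_id`, `construct`,
#' `n_response_levels`, `desirable_high`, and optionally a top-level object
#' with `items` plus `min_items_required`.
#'
#' @param path Path to a JSON battery definition.
#' @return An `"item_battery"`.
#' @export
read_battery <- function(path) {
  j <- jsonlite::read_json(path, simplifyVector = FALSE)
  min_req <- 7L
  items_json <- j
  if (!is.null(j$items)) {
    items_json <- j$items
    min_req <- as.integer(j$min_items_required %||% 7L)
  }
  items <- lapply(items_json, function(x) {
    item_spec(x$item_id, x$construct,
              x$n_response_levels %||% 11L,
              x$desirable_high %||% TRUE)
  })
  item_battery(items, min_items_required = min_req)
}

#' Code a raw item response onto the 0--10 desirable scale
#'
#' Ordered response levels `0 .. n_response_levels - 1` are mapped linearly
#' onto `[0, 10]`: the most desirable level codes to exactly 10 and the least
#' desirable to exactly 0, reversing the raw order when `desirable_high` is
#' `FALSE`. Missing responses pass through as `NA`.
#'
#' @param raw_response Integer raw level(s), `0 <= raw < n_response_levels`.
#' @param spec An [item_spec()].
#' @return Numeric coded value(s) in `[0, 10]`.
#' @export
code_item <- function(raw_response, spec) {
  stopifnot(inherits(spec, "item_spec"))
  n <- spec$n_response_levels
  r <- as.numeric(raw_response)
  bad <- !is.na(r) & (r < 0 | r > n - 1 | r != floor(r))
  if (any(bad))
    stop(sprintf("item '%s': raw response %s outside levels 0..%d",
                 spec$item_id, paste(r[bad][1]), n - 1), call. = FALSE)
  lev <- if (spec$desirable_high) r else (n - 1) - r
  lev / (n - 1) * 10
}

#' Combine coded items into a psych score
#'
#' The psych score is the arithmetic mean of the student's present coded item
#' values. When fewer than `min_items_required` items are present the score
#' is flagged missing (`NA`), never coerced to zero.
#'
#' @param coded_items Numeric vector of coded values aligned with the
#'   battery's items; `NA` marks a missing response.
#' @param battery An [item_battery()].
#' @return An object of class `"psych_score"`: list with `value` (in
#'   `[0, 10]` or `NA`) and `n_items_used`.
#' @export
compute_psych_score <- function(coded_items, battery) {
  stopifnot(inherits(battery, "item_battery"))
  if (length(coded_items) != length(battery$items))
    stop("coded_items does not align with the battery (length mismatch)",
         call. = FALSE)
  present <- !is.na(coded_items)
  vals <- coded_items[present]
  if (any(vals < 0 | vals > 10))
    stop("coded item values must lie in [0, 10]", call. = FALSE)
  n_used <- sum(present)
  value <- if (n_used >= battery$min_items_required) mean(vals) else NA_real_
  structure(list(value = value, n_items_used = n_used), class = "psych_score")
}

#' Score a survey table: code items and append psych scores
#'
#' Data-frame interface over [code_item()] and [compute_psych_score()]: each
#' battery item id must be a column of raw responses; two columns are
#' appended, `psych` and `n_items_used`.
#'
#' @param surveys Data frame with one row per student x wave and one column
#'   per battery item id holding raw responses (NA = missing).
#' @param battery An [item_battery()]; default [default_battery()].
#' @return `surveys` with `psych` and `n_items_used` columns appended.
#' @export
score_surveys <- function(surveys, battery = default_battery()) {
  ids <- battery_item_ids(battery)
  missing_cols <- setdiff(ids, names(surveys))
  if (length(missing_cols))
    stop("survey table lacks item columns: ",
         paste(missing_cols, collapse = ", "), call. = FALSE)
  coded <- vapply(seq_along(ids), function(i) {
    code_item(surveys[[ids[i]]], battery$items[[i]])
  }, numeric(nrow(surveys)))
  coded <- matrix(coded, nrow = nrow(surveys))
  n_used <- rowSums(!is.na(coded))
  psych <- rowMeans(coded, na.rm = TRUE)
  psych[n_used < battery$min_items_required] <- NA_real_
  psych[n_used == 0] <- NA_real_
  surveys$psych <- psych
  surveys$n_items_used <- as.integer(n_used)
  surveys
}

#' Cronbach's alpha of an item matrix
#'
#' Standard internal-consistency coefficient
#' \eqn{\alpha = k/(k-1)\,(1 - \sum_i s_i^2 / s_T^2)} where \eqn{s_i^2} are
#' item variances and \eqn{s_T^2} the variance of the total score, computed
#' over complete records.
#'
#' @param item_matrix Numeric matrix or data frame, records x items.
#' @return Alpha (scalar).
#' @export
cronbach_alpha <- function(item_matrix) {
  m <- as.matrix(item_matrix)
  if (ncol(m) < 2) stop("alpha requires at least 2 items", call. = FALSE)
  m <- m[stats::complete.cases(m), , drop = FALSE]
  if (nrow(m) < 3) stop("alpha requires at least 3 complete records", call. = FALSE)
  k <- ncol(m)
  total_var <- stats::var(rowSums(m))
  if (!is.finite(total_var) || total_var <= .Machine$double.eps)
    stop("total-score variance is zero; alpha is undefined", call. = FALSE)
  k / (k - 1) * (1 - sum(apply(m, 2, stats::var)) / total_var)
}
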