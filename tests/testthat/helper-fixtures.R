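# Shared fixtures built in code. The full-grid normative table is expensive
# enough (198 quadratic fits on a 60k-record pool) that it is built once per
# test run and cached.

.fixture_cache <- new.env(parent = emptyenv())

# 198-percentile x 121-age table fitted to a synthetic normative pool
cached_norm_table <- function() {
  if (is.null(.fixture_cache$norm_table)) {
    pool <- generate_norm_pool(norm_pool_spec(n_records = 60000, seed = 11))
    .fixture_cache$norm_table <- build_norm_table(pool)
  }
  .fixture_cache$norm_table
}

# tiny norm table with explicit values; one row per percentile
make_value_table <- function(percentiles, ages, values) {
  if (!is.matrix(values))
    values <- matrix(values, nrow = length(percentiles), byrow = TRUE)
  norm_table(percentiles, ages, values)
}

# constant-valued table across the grid
constant_table <- function(value = 7, percentiles = c(10, 50, 90),
                           ages = 120:150) {
  norm_table(percentiles, ages,
             matrix(value, length(percentiles), length(ages)))
}

# worked-example fixture: the pegged percentile (41) carries the published
# psych values 8.97 @ 127 mo, 8.93 @ 129 mo, 8.73 @ 137 mo
worked_example_table <- function() {
  make_value_table(
    percentiles = c(40, 41, 42),
    ages = c(127, 129, 137),
    values = rbind(c(8.87, 8.83, 8.63),
                   c(8.97, 8.93, 8.73),
                   c(9.07, 9.03, 8.83))
  )
}

# minimal long survey data frame for matching/outcome tests
make_surveys <- function(students, waves_per_student) {
  do.call(rbind, lapply(seq_along(students), function(i) {
    w <- waves_per_student[[i]]
    cbind(data.frame(student_id = students[i], stringsAsFactors = FALSE), w)
  }))
}
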