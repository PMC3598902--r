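#' @importFrom rlang %||% abort warn inform .data
#' @importFrom dplyr mutate filter select arrange group_by summarise ungroup
#'   left_join inner_join bind_rows n distinct count across all_of
#' @importFrom tibble tibble as_tibble is_tibble
#' @importFrom purrr map map2 pmap map_int map_dbl
#' @importFrom stats rbeta rbinom rgamma rnorm rpois runif setNames
NULL

# Table-style percentage: 100 * num / den, round half away from zero to one
# decimal. base::round() rounds half to even, which would turn e.g. 57.45
# into 57.4; printed yield tables use commercial rounding.
percent_1dp <- function(num, den) {
  ifelse(den > 0, round_half_up(100 * num / den, 1), NA_real_)
}

round_half_up <- function(x, digits = 0) {
  f <- 10^digits
  sign(x) * floor(abs(x) * f + 0.5) / f
}

stopifnot_scalar_count <- function(x, name) {
  if (!is.numeric(x) || length(x) != 1L || is.na(x) || x < 0 || x != floor(x)) {
    abort(sprintf("`%s` must be a single non-negative integer, got %s",
                  name, deparse(substitute(x))))
  }
}

assert_columns <- function(df, cols, what) {
  missing <- setdiff(cols, names(df))
  if (length(missing)) {
    abort(sprintf("%s is missing column(s): %s", what,
                  paste(missing, collapse = ", ")))
  }
  invisible(df)
}

# Set a seed only when the caller supplies one; NULL means "continue the
# current RNG stream", which is how simulate_experiment() threads a single
# seeded generator through all stages.
maybe_seed <- function(seed) {
  if (!is.null(seed)) {
    if (!is.numeric(seed) || length(seed) != 1L || is.na(seed)) {
      abort("`seed` must be a single number or NULL")
    }
    set.seed(as.integer(seed))
  }
  invisible(NULL)
}
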