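## Internal helpers shared across modules.

# 365-day synthetic calendar (no leap days); month m covers
# month_start[m] .. month_start[m] + month_len[m] - 1 of the year.
month_len <- c(31L, 28L, 31L, 30L, 31L, 30L, 31L, 31L, 30L, 31L, 30L, 31L)
month_start <- cumsum(c(1L, month_len[-12]))

#' Map day-of-year (1-365) to calendar month under the synthetic calendar
#' @param doy integer vector in 1..365
#' @return integer month 1..12
#' @keywords internal
doy_to_month <- function(doy) {
  stopifnot(all(doy >= 1L & doy <= 365L))
  findInterval(doy, month_start)
}

#' Derive a reproducible child seed from a global seed and a stage label
#'
#' Every stochastic stage of the pipeline draws its own seed from the global
#' seed and its stage name, so changing one stage's draws never perturbs
#' another's. The result is kept below 2^31 - 1.
#'
#' @param seed integer global seed
#' @param stage character stage label
#' @return integer seed
#' @export
child_seed <- function(seed, stage) {
  stopifnot(is.numeric(seed), length(seed) == 1, is.character(stage))
  h <- sum(utf8ToInt(stage) * seq_along(utf8ToInt(stage)))
  as.integer((abs(seed) * 48271 + h * 16807) %% 2147483563)
}

#' Standardize a numeric vector to mean 0 and standard deviation 1
#'
#' @param x numeric vector with at least two distinct values
#' @return numeric vector with mean 0 and sd 1
#' @examples
#' standardize(c(1, 2, 3))
#' @export
standardize <- function(x) {
  if (!is.numeric(x)) abort("`x` must be numeric.")
  s <- sd(x)
  if (!is.finite(s) || s == 0) {
    abort("Cannot standardize a vector with zero variance.")
  }
  (x - mean(x)) / s
}

## stop with a consistent class so tests can assert on failures
ra_abort <- function(msg, class = "reefadapt_error") {
  abort(msg, class = class)
}

## check that a data frame carries required columns
check_cols <- function(df, cols, what = deparse(substitute(df))) {
  missing <- setdiff(cols, names(df))
  if (length(missing) > 0) {
    ra_abort(paste0(
      what, " is missing required column(s): ",
      paste(missing, collapse = ", ")
    ))
  }
  invisible(df)
}
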