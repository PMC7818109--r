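#' Convert a period probability to a per-cycle probability
#'
#' Splits a cumulative probability observed over `n_cycles` equal cycles into
#' the per-cycle probability under a constant hazard, i.e. the `p_c` solving
#' `1 - (1 - p_c)^n = p_period`. This is the conversion used to turn a
#' 12-month admission proportion (e.g. 9/29 = 0.31) into a monthly admission
#' probability (0.03).
#'
#' @param p_period Probability over the whole period, in `[0, 1)`.
#' @param n_cycles Number of cycles the period spans (positive integer).
#' @return Per-cycle probability in `[0, 1)`.
#' @examples
#' period_prob_to_cycle_prob(9 / 29, 12) # ~0.0305, prints as 0.03
#' @export
period_prob_to_cycle_prob <- function(p_period, n_cycles) {
  stopifnot(is.numeric(p_period), is.numeric(n_cycles))
  if (any(n_cycles < 1) || any(n_cycles != floor(n_cycles))) {
    stop("n_cycles must be a positive integer", call. = FALSE)
  }
  if (any(p_period < 0) || any(p_period >= 1)) {
    stop("p_period must lie in [0, 1): a period probability of 1 implies an infinite hazard",
         call. = FALSE)
  }
  1 - (1 - p_period)^(1 / n_cycles)
}

#' Convert a per-cycle probability to a period probability
#'
#' Inverse of [period_prob_to_cycle_prob()]: `1 - (1 - p_cycle)^n`.
#'
#' @param p_cycle Per-cycle probability in `[0, 1]`.
#' @param n_cycles Number of cycles (positive integer).
#' @return Cumulative probability over `n_cycles` cycles.
#' @export
cycle_prob_to_period_prob <- function(p_cycle, n_cycles) {
  stopifnot(is.numeric(p_cycle), is.numeric(n_cycles))
  if (any(n_cycles < 1) || any(n_cycles != floor(n_cycles))) {
    stop("n_cycles must be a positive integer", call. = FALSE)
  }
  if (any(p_cycle < 0) || any(p_cycle > 1)) {
    stop("p_cycle must lie in [0, 1]", call. = FALSE)
  }
  1 - (1 - p_cycle)^n_cycles
}

#' Probability to hazard rate
#'
#' Actuarial identity `r = -log(1 - p)` for a probability over one period.
#'
#' @param p Probability per period, in `[0, 1)`.
#' @return Hazard rate per period (non-negative).
#' @export
prob_to_rate <- function(p) {
  stopifnot(is.numeric(p))
  if (any(p < 0) || any(p >= 1)) {
    stop("p must lie in [0, 1)", call. = FALSE)
  }
  -log(1 - p)
}

#' Hazard rate to probability
#'
#' Inverse of [prob_to_rate()]: `p = 1 - exp(-r)`.
#'
#' @param r Hazard rate per period (non-negative).
#' @return Probability per period.
#' @export
rate_to_prob <- function(r) {
  stopifnot(is.numeric(r))
  if (any(r < 0)) stop("rate must be non-negative", call. = FALSE)
  1 - exp(-r)
}

#' Discount factor at a time point
#'
#' Compound annual discounting evaluated at a (possibly fractional) number of
#' months since model start: `(1 + annual_rate)^(-t_months / 12)`. Exact at
#' annual boundaries and standard in health-economic guidelines.
#'
#' @param annual_rate Annual discount rate (fraction, e.g. 0.05).
#' @param t_months Months since model start (non-negative, may be fractional).
#' @return Dimensionless factor in `(0, 1]`; 1 at `t_months = 0`.
#' @examples
#' discount_factor(0.05, 12) # 1/1.05
#' @export
discount_factor <- function(annual_rate, t_months) {
  stopifnot(is.numeric(annual_rate), is.numeric(t_months))
  if (any(annual_rate < 0)) stop("annual_rate must be non-negative", call. = FALSE)
  if (any(t_months < 0)) stop("t_months must be non-negative", call. = FALSE)
  (1 + annual_rate)^(-t_months / 12)
}
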