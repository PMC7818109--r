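#' A 2x2 events/non-events by arm table
#'
#' @param events Named integer vector of event counts, one per arm (names are
#'   the arm labels, e.g. `c(sc = 9, intervention = 2)`).
#' @param n Named integer vector of arm sizes, matching `events`.
#' @return A `two_by_two` object.
#' @export
two_by_two <- function(events, n) {
  if (length(events) != 2L || length(n) != 2L) {
    stop("exactly two arms required", call. = FALSE)
  }
  if (is.null(names(events))) names(events) <- c("a", "b")
  if (is.null(names(n))) names(n) <- names(events)
  if (!identical(sort(names(events)), sort(names(n)))) {
    stop("arm names of events and n must match", call. = FALSE)
  }
  n <- n[names(events)]
  if (any(events < 0) || any(n < 0) || any(events > n) ||
      any(events != floor(events)) || any(n != floor(n))) {
    stop("counts must be non-negative integers with events <= n", call. = FALSE)
  }
  if (sum(n) == 0L) stop("at least one margin must be positive", call. = FALSE)
  structure(list(events = as.integer(events), n = as.integer(n),
                 arms = names(events)),
            class = "two_by_two")
}

#' Fisher's exact test for a 2x2 table
#'
#' Conditions on both margins, using the hypergeometric distribution of the
#' first arm's event count. The one-sided p-value is the tail probability in
#' the direction of the observed deviation from its conditional expectation;
#' the two-sided p-value follows the point-probability rule (the sum of the
#' probabilities of all tables no more probable than the observed one).
#'
#' @param table A [two_by_two()].
#' @param sidedness "one" or "two".
#' @return The p-value.
#' @export
fishers_exact <- function(table, sidedness = c("two", "one")) {
  stopifnot(inherits(table, "two_by_two"))
  sidedness <- match.arg(sidedness)
  x <- table$events[1]
  n1 <- table$n[1]
  n2 <- table$n[2]
  k <- sum(table$events)
  if (n1 == 0L || n2 == 0L) stop("both arms must be non-empty", call. = FALSE)
  support <- max(0L, k - n2):min(n1, k)
  dens <- stats::dhyper(support, n1, n2, k)
  if (sidedness == "one") {
    expected <- k * n1 / (n1 + n2)
    if (x <= expected) {
      sum(dens[support <= x])
    } else {
      sum(dens[support >= x])
    }
  } else {
    d_obs <- stats::dhyper(x, n1, n2, k)
    sum(dens[dens <= d_obs * (1 + 1e-7)])
  }
}

#' Pearson chi-square test for a 2x2 table
#'
#' Thin wrapper around [stats::chisq.test()] (df = 1), refusing tables with a
#' zero expected cell, for which Fisher's exact test is appropriate.
#'
#' @param table A [two_by_two()].
#' @param continuity_correction Apply the Yates continuity correction?
#' @return List with `statistic` and `p_value`.
#' @export
chi_square_test <- function(table, continuity_correction = FALSE) {
  stopifnot(inherits(table, "two_by_two"))
  m <- rbind(events = table$events, non_events = table$n - table$events)
  if (any(outer(rowSums(m), colSums(m)) / sum(m) == 0)) {
    stop("zero expected cell count: use fishers_exact() instead", call. = FALSE)
  }
  res <- suppressWarnings(stats::chisq.test(m, correct = continuity_correction))
  list(statistic = unname(res$statistic), p_value = res$p.value)
}

#' Two-sample t test
#'
#' Wrapper around [stats::t.test()] with explicit pooled-variance or Welch
#' degrees of freedom, two-sided.
#'
#' @param x,y Numeric samples for the two arms (at least 2 observations each).
#' @param variant "welch" (default) or "pooled".
#' @return List with `t`, `df`, `p_value`.
#' @export
two_sample_t <- function(x, y, variant = c("welch", "pooled")) {
  variant <- match.arg(variant)
  if (length(x) < 2L || length(y) < 2L) {
    stop("need at least 2 observations per arm", call. = FALSE)
  }
  if (stats::var(x) == 0 && stats::var(y) == 0) {
    if (mean(x) == mean(y)) {
      return(list(t = 0, df = length(x) + length(y) - 2, p_value = 1))
    }
    stop("zero variance in both arms with unequal means: t undefined", call. = FALSE)
  }
  res <- stats::t.test(x, y, var.equal = (variant == "pooled"))
  list(t = unname(res$statistic), df = unname(res$parameter),
       p_value = res$p.value)
}

#' Summarise admissions as cumulative proportions and monthly probabilities
#'
#' Converts each arm's event proportion over an observation window into a
#' per-month probability under a constant hazard (e.g. 9/29 over 12 months
#' gives 0.31 cumulative, 0.03 per month).
#'
#' @param table A [two_by_two()] of admissions by arm.
#' @param months Length of the observation window in months (default 12).
#' @return List with named vectors `cumulative_proportion` and
#'   `monthly_probability`.
#' @export
admission_summary <- function(table, months = 12L) {
  stopifnot(inherits(table, "two_by_two"))
  if (any(table$n == 0L)) stop("arm sizes must be positive", call. = FALSE)
  prop <- table$events / table$n
  monthly <- vapply(prop, function(p) {
    if (p >= 1) stop("all-events arm: cumulative proportion of 1 has no finite hazard",
                     call. = FALSE)
    period_prob_to_cycle_prob(p, months)
  }, numeric(1))
  names(prop) <- names(monthly) <- table$arms
  list(cumulative_proportion = prop, monthly_probability = monthly)
}
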