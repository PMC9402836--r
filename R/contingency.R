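#' Build a 2x2 events/non-events contingency table
#'
#' Group 1 is the exposed (first) group and group 2 the reference, matching
#' the column order of a published outcome table: `events_g1` of `n_g1`
#' patients with the event versus `events_g2` of `n_g2`.
#'
#' @param events_g1,n_g1 Event count and group size of group 1.
#' @param events_g2,n_g2 Event count and group size of group 2.
#' @param labels Optional length-2 character vector naming the groups.
#' @return An object of class `contingency_2x2`.
#' @examples
#' contingency_2x2(20, 205, 16, 124) # stable patients, GP vs cardiologist
#' @export
contingency_2x2 <- function(events_g1, n_g1, events_g2, n_g2,
                            labels = c("group1", "group2")) {
  cells <- c(events_g1 = events_g1, n_g1 = n_g1, events_g2 = events_g2, n_g2 = n_g2)
  if (any(!is.finite(cells)) || any(cells < 0) || any(cells != round(cells))) {
    abort("All cells must be non-negative integers")
  }
  if (events_g1 > n_g1 || events_g2 > n_g2) {
    abort("Event counts cannot exceed group sizes")
  }
  structure(list(events_g1 = as.integer(events_g1), n_g1 = as.integer(n_g1),
                 events_g2 = as.integer(events_g2), n_g2 = as.integer(n_g2),
                 labels = labels),
            class = "contingency_2x2")
}

#' @export
print.contingency_2x2 <- function(x, ...) {
  cat(sprintf("2x2 table: %s %d/%d (%.1f%%) vs %s %d/%d (%.1f%%)\n",
              x$labels[1], x$events_g1, x$n_g1, 100 * x$events_g1 / x$n_g1,
              x$labels[2], x$events_g2, x$n_g2, 100 * x$events_g2 / x$n_g2))
  invisible(x)
}

#' Pool two 2x2 tables cellwise
#'
#' Adds event counts and group sizes; used to derive an overall comparison
#' (for example, all high-score versus all low-score patients) from
#' per-care-setting tables that share the same event definition.
#'
#' @param t_a,t_b `contingency_2x2` objects.
#' @return A `contingency_2x2` with cellwise sums; labels from `t_a`.
#' @export
pool_tables <- function(t_a, t_b) {
  stopifnot(inherits(t_a, "contingency_2x2"), inherits(t_b, "contingency_2x2"))
  contingency_2x2(t_a$events_g1 + t_b$events_g1, t_a$n_g1 + t_b$n_g1,
                  t_a$events_g2 + t_b$events_g2, t_a$n_g2 + t_b$n_g2,
                  labels = t_a$labels)
}

#' Odds ratio with Woolf confidence interval and Wald test
#'
#' Computes the cross-product odds ratio OR = (a d)/(b c) on the
#' events/non-events table (a = events in group 1, b = non-events in group
#' 1, c and d likewise in group 2), a Woolf confidence interval
#' exp(ln OR +/- z * sqrt(1/a + 1/b + 1/c + 1/d)) and a two-sided Wald
#' p-value on the log odds ratio. When any cell is zero the estimate is
#' undefined and reported as such (`estimate_defined = FALSE`, missing OR
#' and CI) unless `zero_cells = "haldane"`, which adds 0.5 to every cell
#' (Haldane--Anscombe) before estimating.
#'
#' @param ct A [contingency_2x2()].
#' @param alpha_level Two-sided significance level for the CI, in (0, 1).
#' @param zero_cells `"undefined"` (default) or `"haldane"`.
#' @return A one-row tibble: `events_g1`, `n_g1`, `events_g2`, `n_g2`,
#'   `odds_ratio`, `ci_low`, `ci_high`, `log_or_se`, `p_value`, `method`,
#'   `estimate_defined`.
#' @examples
#' odds_ratio_estimate(contingency_2x2(90, 308, 36, 329))
#' @export
odds_ratio_estimate <- function(ct, alpha_level = 0.05,
                                zero_cells = c("undefined", "haldane")) {
  stopifnot(inherits(ct, "contingency_2x2"))
  zero_cells <- match.arg(zero_cells)
  if (ct$n_g1 < 1 || ct$n_g2 < 1) abort("Both group sizes must be at least 1")
  if (!is.numeric(alpha_level) || length(alpha_level) != 1 ||
      alpha_level <= 0 || alpha_level >= 1) {
    abort("`alpha_level` must be a single number strictly between 0 and 1")
  }

  a <- ct$events_g1; b <- ct$n_g1 - ct$events_g1
  c_ <- ct$events_g2; d <- ct$n_g2 - ct$events_g2

  base <- tibble::tibble(
    events_g1 = ct$events_g1, n_g1 = ct$n_g1,
    events_g2 = ct$events_g2, n_g2 = ct$n_g2
  )

  if (any(c(a, b, c_, d) == 0)) {
    if (zero_cells == "undefined") {
      return(dplyr::mutate(base,
        odds_ratio = NA_real_, ci_low = NA_real_, ci_high = NA_real_,
        log_or_se = NA_real_, p_value = NA_real_,
        method = "woolf_wald", estimate_defined = FALSE))
    }
    a <- a + 0.5; b <- b + 0.5; c_ <- c_ + 0.5; d <- d + 0.5
  }

  or <- (a * d) / (b * c_)
  se <- sqrt(1 / a + 1 / b + 1 / c_ + 1 / d)
  z <- qnorm(1 - alpha_level / 2)
  wald <- log(or) / se

  dplyr::mutate(base,
    odds_ratio = or,
    ci_low = exp(log(or) - z * se),
    ci_high = exp(log(or) + z * se),
    log_or_se = se,
    p_value = 2 * pnorm(-abs(wald)),
    method = if (zero_cells == "haldane" && any(c(ct$events_g1, ct$n_g1 - ct$events_g1,
                                                  ct$events_g2, ct$n_g2 - ct$events_g2) == 0))
      "woolf_wald_haldane" else "woolf_wald",
    estimate_defined = TRUE)
}
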