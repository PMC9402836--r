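#' Logistic regression by iteratively reweighted least squares
#'
#' Maximum-likelihood logistic regression fit with IRLS, used for
#' covariate-adjusted odds ratios (age, sex, COPD, diabetes in the
#' instrument's validation design). Convergence is declared when the change
#' in deviance falls below `tol`; complete or quasi-complete separation is
#' detected by a diverging coefficient norm or fitted probabilities pinned
#' to 0/1 and reported as `converged = FALSE` with `separation = TRUE`
#' rather than as spuriously huge finite estimates.
#'
#' @param y Binary outcome vector (0/1 or logical).
#' @param x Numeric model matrix including the intercept column.
#' @param max_iter Maximum IRLS iterations.
#' @param tol Convergence tolerance on the deviance change.
#' @return An object of class `mishf_logit` with elements `coefficients`,
#'   `standard_errors`, `converged`, `iterations`, `separation`, `deviance`,
#'   `n`. Use [tidy()] / [glance()] for tibble summaries.
#' @examples
#' ct <- contingency_2x2(90, 308, 36, 329)
#' y <- c(rep(1, 90), rep(0, 308 - 90), rep(1, 36), rep(0, 329 - 36))
#' x <- cbind(intercept = 1, high_score = rep(c(1, 0), c(308, 329)))
#' exp(coef(fit_logistic(y, x))["high_score"]) # equals the cross-product OR
#' @export
fit_logistic <- function(y, x, max_iter = 100, tol = 1e-8) {
  y <- as.numeric(y)
  if (length(y) == 0) abort("Empty input: `y` has length 0")
  if (!all(y %in% c(0, 1))) abort("`y` must be binary (0/1)")
  x <- as.matrix(x)
  if (!is.numeric(x)) abort("`x` must be a numeric matrix")
  if (nrow(x) != length(y)) abort("`x` must have one row per element of `y`")
  if (is.null(colnames(x))) colnames(x) <- paste0("x", seq_len(ncol(x)))

  qrx <- qr(x)
  if (qrx$rank < ncol(x)) {
    dropped <- colnames(x)[qrx$pivot[(qrx$rank + 1):ncol(x)]]
    abort(paste0("Model matrix is rank deficient; collinear column(s): ",
                 paste(dropped, collapse = ", ")))
  }

  p <- ncol(x)
  beta <- rep(0, p)
  dev_old <- Inf
  converged <- FALSE
  separation <- FALSE
  iter <- 0

  for (iter in seq_len(max_iter)) {
    eta <- drop(x %*% beta)
    mu <- plogis(eta)
    w <- pmax(mu * (1 - mu), 1e-10)
    z <- eta + (y - mu) / w
    xtw <- t(x * w)
    beta <- drop(solve(xtw %*% x, xtw %*% z))
    mu_new <- plogis(drop(x %*% beta))
    dev <- -2 * sum(y * log(pmax(mu_new, 1e-300)) +
                    (1 - y) * log(pmax(1 - mu_new, 1e-300)))
    if (sqrt(sum(beta^2)) > 1e4 || all(mu_new < 1e-8 | mu_new > 1 - 1e-8)) {
      separation <- TRUE
      break
    }
    if (abs(dev_old - dev) < tol) {
      converged <- TRUE
      dev_old <- dev
      break
    }
    dev_old <- dev
  }

  eta <- drop(x %*% beta)
  mu <- plogis(eta)
  w <- pmax(mu * (1 - mu), 1e-10)
  info <- t(x * w) %*% x
  se <- tryCatch(sqrt(diag(solve(info))), error = function(e) rep(NA_real_, p))

  structure(list(
    coefficients = stats::setNames(beta, colnames(x)),
    standard_errors = stats::setNames(se, colnames(x)),
    converged = converged,
    separation = separation,
    iterations = iter,
    deviance = if (is.finite(dev_old)) dev_old else NA_real_,
    n = length(y),
    df_residual = length(y) - p
  ), class = "mishf_logit")
}

#' @export
coef.mishf_logit <- function(object, ...) object$coefficients

#' @export
print.mishf_logit <- function(x, ...) {
  cat(sprintf("Logistic fit (IRLS): n = %d, %s in %d iteration(s)\n",
              x$n,
              if (x$converged) "converged" else if (x$separation) "separation detected" else "not converged",
              x$iterations))
  print(tidy(x))
  invisible(x)
}

#' Tidy a logistic fit
#'
#' @param x A `mishf_logit` object.
#' @param exponentiate Report odds-ratio scale estimates and CI.
#' @param conf.level Confidence level for the Wald interval.
#' @param ... Unused.
#' @return A tibble with one row per coefficient: `term`, `estimate`,
#'   `std.error`, `statistic`, `p.value`, `conf.low`, `conf.high`.
#' @export
tidy.mishf_logit <- function(x, exponentiate = FALSE, conf.level = 0.95, ...) {
  z <- qnorm(1 - (1 - conf.level) / 2)
  out <- tibble::tibble(
    term = names(x$coefficients),
    estimate = unname(x$coefficients),
    std.error = unname(x$standard_errors),
    statistic = unname(x$coefficients / x$standard_errors),
    p.value = 2 * pnorm(-abs(unname(x$coefficients / x$standard_errors))),
    conf.low = unname(x$coefficients) - z * unname(x$standard_errors),
    conf.high = unname(x$coefficients) + z * unname(x$standard_errors)
  )
  if (exponentiate) {
    out <- dplyr::mutate(out,
      estimate = exp(.data$estimate),
      conf.low = exp(.data$conf.low),
      conf.high = exp(.data$conf.high))
  }
  out
}

#' @rdname tidy.mishf_logit
#' @return `glance()` returns a one-row tibble: `deviance`, `iterations`,
#'   `converged`, `separation`, `nobs`, `df.residual`.
#' @export
glance.mishf_logit <- function(x, ...) {
  tibble::tibble(
    deviance = x$deviance, iterations = x$iterations,
    converged = x$converged, separation = x$separation,
    nobs = x$n, df.residual = x$df_residual
  )
}
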