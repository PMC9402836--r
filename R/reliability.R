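#' Cohen's kappa for two raters
#'
#' Chance-corrected agreement between two raters assigning the same
#' categorical label (here: the stable/unstable referral class) to the same
#' subjects: kappa = (p_o - p_e) / (1 - p_e), with observed agreement p_o
#' and expected agreement p_e from the marginal label frequencies of each
#' rater. When p_e = 1 (both raters constant on the same label) kappa is
#' undefined and reported as such.
#'
#' @param pairs Data frame with one row per subject.
#' @param rater1,rater2 Names of the two label columns (default
#'   `rater1_class` / `rater2_class`).
#' @return One-row tibble: `kappa`, `p_observed`, `p_expected`, `n_subjects`,
#'   `defined`.
#' @examples
#' pairs <- tibble::tibble(rater1_class = c("stable", "unstable", "stable"),
#'                         rater2_class = c("stable", "unstable", "stable"))
#' cohen_kappa(pairs)
#' @export
cohen_kappa <- function(pairs, rater1 = "rater1_class", rater2 = "rater2_class") {
  stopifnot(is.data.frame(pairs))
  if (!all(c(rater1, rater2) %in% names(pairs))) {
    abort(paste0("Columns not found: ", paste(setdiff(c(rater1, rater2), names(pairs)), collapse = ", ")))
  }
  r1 <- as.character(pairs[[rater1]])
  r2 <- as.character(pairs[[rater2]])
  if (length(r1) != length(r2)) abort("Rater vectors must have equal length")
  if (length(r1) < 1) abort("At least one subject is required")
  if (any(is.na(r1)) || any(is.na(r2))) abort("Missing labels are not allowed")

  labels <- sort(unique(c(r1, r2)))
  n <- length(r1)
  p_o <- mean(r1 == r2)
  p1 <- table(factor(r1, levels = labels)) / n
  p2 <- table(factor(r2, levels = labels)) / n
  p_e <- sum(as.numeric(p1) * as.numeric(p2))

  defined <- (1 - p_e) > .Machine$double.eps^0.5
  tibble::tibble(
    kappa = if (defined) (p_o - p_e) / (1 - p_e) else NA_real_,
    p_observed = p_o, p_expected = p_e,
    n_subjects = n, defined = defined
  )
}

#' Intraclass correlation for absolute agreement, ICC(2,1)
#'
#' Single-rater intraclass correlation from the two-way random-effects
#' mean-squares decomposition (subjects and raters both random), in the
#' absolute-agreement form: systematic differences between raters count as
#' disagreement. The consistency form, which ignores a constant rater shift,
#' is available with `type = "consistency"`.
#'
#' With n subjects, k raters, between-subject mean square MSR, between-rater
#' mean square MSC and residual mean square MSE:
#' agreement ICC = (MSR - MSE) / (MSR + (k-1) MSE + (k/n)(MSC - MSE));
#' consistency ICC = (MSR - MSE) / (MSR + (k-1) MSE).
#'
#' @param scores Data frame or matrix, one row per subject, one column per
#'   rater, numeric, no missing cells.
#' @param type `"agreement"` (default) or `"consistency"`.
#' @return One-row tibble: `icc`, `type`, `n_subjects`, `n_raters`,
#'   `ms_subjects`, `ms_raters`, `ms_error`, `defined` (`FALSE` when the
#'   matrix is constant, i.e. no between-subject variance to apportion).
#' @export
icc_agreement <- function(scores, type = c("agreement", "consistency")) {
  type <- match.arg(type)
  m <- as.matrix(scores)
  if ("subject_id" %in% colnames(m)) abort("`scores` must contain rater columns only")
  storage.mode(m) <- "double"
  n <- nrow(m); k <- ncol(m)
  if (n < 2 || k < 2) abort("At least 2 subjects and 2 raters are required")
  if (any(is.na(m))) abort("Missing cells are not allowed")

  grand <- mean(m)
  row_means <- rowMeans(m)
  col_means <- colMeans(m)
  ss_rows <- k * sum((row_means - grand)^2)
  ss_cols <- n * sum((col_means - grand)^2)
  ss_total <- sum((m - grand)^2)
  ss_err <- ss_total - ss_rows - ss_cols

  msr <- ss_rows / (n - 1)
  msc <- ss_cols / (k - 1)
  mse <- ss_err / ((n - 1) * (k - 1))

  denom <- if (type == "agreement") {
    msr + (k - 1) * mse + (k / n) * (msc - mse)
  } else {
    msr + (k - 1) * mse
  }
  defined <- abs(denom) > .Machine$double.eps^0.5
  tibble::tibble(
    icc = if (defined) (msr - mse) / denom else NA_real_,
    type = type, n_subjects = n, n_raters = k,
    ms_subjects = msr, ms_raters = msc, ms_error = mse,
    defined = defined
  )
}

#' Cronbach's alpha internal-consistency coefficient
#'
#' alpha = K/(K-1) * (1 - sum of item variances / variance of the total
#' score), with sample variances (denominator n-1) throughout. Operates by
#' default on the per-item point values; `mode = "binary"` first reduces
#' each item to fired/not-fired.
#'
#' @param items Data frame or matrix, one row per subject, one column per
#'   item, non-negative numeric.
#' @param mode `"points"` (default) or `"binary"`.
#' @return One-row tibble: `alpha`, `mode`, `n_items`, `n_subjects`,
#'   `defined` (`FALSE` when the total score has zero variance).
#' @export
cronbach_alpha <- function(items, mode = c("points", "binary")) {
  mode <- match.arg(mode)
  m <- as.matrix(items)
  storage.mode(m) <- "double"
  if (nrow(m) < 2 || ncol(m) < 2) abort("At least 2 subjects and 2 items are required")
  if (any(is.na(m))) abort("Missing cells are not allowed")
  if (mode == "binary") m <- (m > 0) * 1

  k <- ncol(m)
  item_vars <- apply(m, 2, var)
  total_var <- var(rowSums(m))
  defined <- total_var > .Machine$double.eps^0.5
  tibble::tibble(
    alpha = if (defined) k / (k - 1) * (1 - sum(item_vars) / total_var) else NA_real_,
    mode = mode, n_items = k, n_subjects = nrow(m),
    defined = defined
  )
}

#' Combined reliability report for dual-rater data
#'
#' Convenience wrapper producing the three reliability statistics used to
#' evaluate the instrument: Cohen's kappa on the stable/unstable class,
#' ICC(2,1) on exact totals, and (when an item matrix is supplied)
#' Cronbach's alpha on item points.
#'
#' @param pairs Data frame with `rater1_total`, `rater2_total`,
#'   `rater1_class`, `rater2_class`.
#' @param item_matrix Optional subjects x items matrix for alpha.
#' @return A tibble with columns `statistic`, `estimate`, `n_subjects`,
#'   `defined`.
#' @export
reliability_report <- function(pairs, item_matrix = NULL) {
  kap <- cohen_kappa(pairs)
  icc <- icc_agreement(pairs[c("rater1_total", "rater2_total")])
  out <- tibble::tibble(
    statistic = c("cohen_kappa", "icc_2_1_agreement"),
    estimate = c(kap$kappa, icc$icc),
    n_subjects = c(kap$n_subjects, icc$n_subjects),
    defined = c(kap$defined, icc$defined)
  )
  if (!is.null(item_matrix)) {
    al <- cronbach_alpha(item_matrix)
    out <- dplyr::bind_rows(out, tibble::tibble(
      statistic = "cronbach_alpha", estimate = al$alpha,
      n_subjects = al$n_subjects, defined = al$defined))
  }
  out
}
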