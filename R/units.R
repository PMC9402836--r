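#' Unit conversions for instrument thresholds
#'
#' The instrument states its NT-proBNP cut-off in both pmol/l and pg/ml
#' (400 pmol/l = 3383 pg/ml, i.e. 8.4575 pg/ml per pmol/l) and its
#' haemoglobin cut-off in both mmol/l and g/dl (6.5 mmol/l = 10.5 g/dl).
#' These linear conversions are fixed from those printed equivalences so the
#' engine and its thresholds agree exactly at the cut-offs.
#'
#' @param value Non-negative numeric vector.
#' @param to Target unit.
#' @return Numeric vector in the target unit.
#' @examples
#' convert_ntprobnp(3383, to = "pmol_l") # 400
#' convert_haemoglobin(6.5, to = "g_dl") # 10.5
#' @export
convert_ntprobnp <- function(value, to = c("pmol_l", "pg_ml")) {
  to <- match.arg(to)
  check_nonnegative(value, "value")
  factor <- 3383 / 400 # pg/ml per pmol/l
  if (to == "pmol_l") value / factor else value * factor
}

#' @rdname convert_ntprobnp
#' @export
convert_haemoglobin <- function(value, to = c("mmol_l", "g_dl")) {
  to <- match.arg(to)
  check_nonnegative(value, "value")
  factor <- 10.5 / 6.5 # g/dl per mmol/l
  if (to == "mmol_l") value / factor else value * factor
}

check_nonnegative <- function(x, name) {
  if (!is.numeric(x) || any(is.na(x)) || any(x < 0)) {
    abort(paste0("`", name, "` must be non-negative and non-missing"))
  }
  invisible(x)
}
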