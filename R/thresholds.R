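#' Scoring thresholds for the MIS-HF instrument
#'
#' All numeric cut-offs used by the scoring engine live in one auditable
#' record. Defaults are the published values of the instrument's scoring
#' list: blood-pressure limits of 90/50 mm Hg (symptomatic hypotension) and
#' 140/85 mm Hg (hypertension), heart-rate limits of 75/min in sinus rhythm
#' and 100/min in atrial fibrillation, NT-proBNP limits of a >25% rise and a
#' 400 pmol/l level, potassium 3.5--5.0 mmol/l, sodium 135--145 mmol/l,
#' creatinine 220 umol/l or a >25% rise or GFR < 30 ml/min, haemoglobin
#' 6.5 mmol/l, an admission history of at least one heart-failure admission
#' in 6 months or two in 12 months, and the stability threshold (total
#' score of `stable_max` or less is classed stable).
#'
#' @param ... Named overrides of individual cut-offs (see Details for names).
#' @return A named list of class `mishf_thresholds`.
#' @examples
#' cfg <- mishf_thresholds()
#' cfg$ntprobnp_high
#' strict <- mishf_thresholds(bp_high_systolic = 130)
#' @export
mishf_thresholds <- function(...) {
  defaults <- list(
    bp_low_systolic     = 90,
    bp_low_diastolic    = 50,
    bp_high_systolic    = 140,
    bp_high_diastolic   = 85,
    sinus_rate_high     = 75,
    af_rate_high        = 100,
    ntprobnp_rise_pct   = 25,
    ntprobnp_high       = 400,
    potassium_low       = 3.5,
    potassium_high      = 5.0,
    sodium_low          = 135,
    sodium_high         = 145,
    creatinine_high     = 220,
    creatinine_rise_pct = 25,
    gfr_low             = 30,
    haemoglobin_low     = 6.5,
    admissions_6mo_min  = 1,
    admissions_12mo_min = 2,
    stable_max          = 2
  )
  overrides <- list(...)
  if (length(overrides)) {
    unknown <- setdiff(names(overrides), names(defaults))
    if (length(unknown)) {
      abort(paste0("Unknown threshold name(s): ", paste(unknown, collapse = ", ")))
    }
    defaults[names(overrides)] <- overrides
  }
  validate_thresholds(structure(defaults, class = "mishf_thresholds"))
}

validate_thresholds <- function(x) {
  num <- vapply(x, function(v) is.numeric(v) && length(v) == 1 && is.finite(v), logical(1))
  if (!all(num)) {
    abort(paste0("Thresholds must be finite numeric scalars; offending: ",
                 paste(names(x)[!num], collapse = ", ")))
  }
  neg <- vapply(x, function(v) v < 0, logical(1))
  if (any(neg)) {
    abort(paste0("Thresholds must be non-negative; offending: ",
                 paste(names(x)[neg], collapse = ", ")))
  }
  if (x$potassium_low >= x$potassium_high) abort("potassium_low must be below potassium_high")
  if (x$sodium_low >= x$sodium_high) abort("sodium_low must be below sodium_high")
  if (x$bp_low_systolic >= x$bp_high_systolic) abort("bp_low_systolic must be below bp_high_systolic")
  x
}

#' @export
print.mishf_thresholds <- function(x, ...) {
  cat("MIS-HF scoring thresholds\n")
  for (nm in names(x)) cat(sprintf("  %-20s %g\n", nm, x[[nm]]))
  invisible(x)
}

#' Read or write a threshold configuration file
#'
#' The on-disk format is YAML key-value pairs, one per cut-off; keys are the
#' names accepted by [mishf_thresholds()]. Unknown keys are rejected so a
#' mistyped cut-off cannot silently fall back to its default.
#'
#' @param path File path.
#' @return `read_thresholds()` returns a `mishf_thresholds` record;
#'   `write_thresholds()` returns `path` invisibly.
#' @export
read_thresholds <- function(path) {
  if (!file.exists(path)) abort(paste0("Threshold file not found: ", path))
  vals <- yaml::read_yaml(path)
  if (!is.list(vals) || is.null(names(vals))) {
    abort("Threshold file must contain named key-value pairs")
  }
  do.call(mishf_thresholds, vals)
}

#' @rdname read_thresholds
#' @param thresholds A `mishf_thresholds` record.
#' @export
write_thresholds <- function(thresholds, path) {
  stopifnot(inherits(thresholds, "mishf_thresholds"))
  yaml::write_yaml(unclass(thresholds), path)
  invisible(path)
}

# Order-independent digest of an effective configuration, for run manifests.
config_digest <- function(cfg) {
  cfg <- cfg[order(names(cfg))]
  json <- jsonlite::toJSON(cfg, auto_unbox = TRUE, digits = NA)
  fnv1a64(as.character(json))
}

# Polynomial rolling hash over the UTF-8 bytes, reduced mod 2^48 so every
# intermediate stays exactly representable in a double.
fnv1a64 <- function(s) {
  bytes <- as.integer(charToRaw(enc2utf8(s)))
  h <- 1469598103
  for (b in bytes) h <- (h * 31 + b) %% 2^48
  sprintf("%06x%06x", as.integer(h %/% 2^24), as.integer(h %% 2^24))
}
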