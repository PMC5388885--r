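#' Fit a power-law or exponential decay curve
#'
#' Least-squares fit on the log-linearized form: for the power model
#' `y = a * x^b`, `ln y` is regressed on `ln x`; for the exponential model
#' `y = a * exp(b * x)`, `ln y` is regressed on `x`. Used to summarize how
#' the perceived species-unique fraction declines as a reference database
#' grows.
#'
#' @param xs,ys Positive numeric vectors of equal length (at least 3).
#' @param model `"power"` or `"exponential"`.
#' @return An object of class `decay_fit` with fields `model`, `a`, `b`,
#'   `r_squared` and the underlying `lm` fit.
#' @export
fit_decay_curve <- function(xs, ys, model = c("power", "exponential")) {
  model <- match.arg(model)
  if (length(xs) != length(ys) || length(xs) < 3) {
    abort("xs and ys must have equal length >= 3")
  }
  if (any(ys <= 0) || (model == "power" && any(xs <= 0))) {
    abort("decay fitting requires positive values (log-linearized fit)")
  }
  df <- data.frame(x = xs, y = ys)
  fit <- if (model == "power") {
    stats::lm(log(y) ~ log(x), data = df)
  } else {
    stats::lm(log(y) ~ x, data = df)
  }
  # R^2 on the log scale, computed directly: summary.lm warns on exact data
  rss <- sum(stats::residuals(fit)^2)
  tss <- sum((log(ys) - mean(log(ys)))^2)
  structure(list(
    model = model,
    a = unname(exp(stats::coef(fit)[1])),
    b = unname(stats::coef(fit)[2]),
    r_squared = if (tss < .Machine$double.eps) 1 else 1 - rss / tss,
    fit = fit
  ), class = "decay_fit")
}

#' @export
print.decay_fit <- function(x, ...) {
  form <- if (x$model == "power") "y = %.4g * x^%.4g"
          else "y = %.4g * exp(%.4g * x)"
  cat(sprintf(paste0("<decay_fit> ", form, "  (R2 = %.4f)\n"),
              x$a, x$b, x$r_squared))
  invisible(x)
}

#' @export
tidy.decay_fit <- function(x, ...) {
  tibble(term = c("a", "b"), estimate = c(x$a, x$b))
}

#' @export
glance.decay_fit <- function(x, ...) {
  tibble(model = x$model, a = x$a, b = x$b, r_squared = x$r_squared)
}

#' @export
predict.decay_fit <- function(object, newdata, ...) {
  x <- if (is.data.frame(newdata)) newdata$x else newdata
  if (object$model == "power") object$a * x^object$b
  else object$a * exp(object$b * x)
}

#' Shared overlap of aligned sequence intervals
#'
#' Length of the region covered by every interval — the effective number of
#' comparable bases in an alignment of variable-length reference barcodes.
#'
#' @param intervals Data frame with numeric columns `start` and `end`
#'   (half-open, `end > start`), one row per sequence.
#' @return Integer number of shared bases (0 when the intersection is
#'   empty).
#' @export
shared_overlap <- function(intervals) {
  if (nrow(intervals) == 0) abort("shared_overlap requires >= 1 interval")
  if (any(intervals$end <= intervals$start)) {
    abort("intervals must satisfy end > start")
  }
  as.integer(max(0, min(intervals$end) - max(intervals$start)))
}

#' Filter barcode records by minimum length
#'
#' Removes records whose sequence is shorter than `min_len` and reports the
#' percentage removed — the cost of a read-length filter applied to a
#' reference database.
#'
#' @param records Tibble of barcode records.
#' @param min_len Minimum sequence length to keep.
#' @return The kept records, with attribute `pct_removed` (percentage of
#'   input records removed; 0 for empty input).
#' @export
filter_by_length <- function(records, min_len) {
  if (min_len < 0) abort("min_len must be >= 0")
  keep <- nchar(records$sequence) >= min_len
  out <- records[keep, , drop = FALSE]
  attr(out, "pct_removed") <-
    if (nrow(records) == 0) 0 else 100 * sum(!keep) / nrow(records)
  out
}

#' Project years to reference-database completion
#'
#' Arithmetic of database growth: given the number of species already
#' carrying both core barcodes, the total number of species, and the years
#' elapsed, computes current percent coverage, the accumulation rate per
#' annum, and a lower bound on the years remaining at that rate.
#'
#' @param n_both_barcodes Species with both core barcodes recorded.
#' @param n_total_species Total species to cover.
#' @param years_elapsed Years over which `n_both_barcodes` accumulated.
#' @return One-row tibble: `coverage_pct` (rounded to the nearest integer),
#'   `rate_per_annum` (rounded), `years_remaining` (integer part of the
#'   quotient; the true requirement exceeds this bound).
#' @export
coverage_projection <- function(n_both_barcodes, n_total_species,
                                years_elapsed) {
  if (n_total_species <= 0 || years_elapsed <= 0) {
    abort("n_total_species and years_elapsed must be positive")
  }
  rate <- round(n_both_barcodes / years_elapsed)
  if (rate == 0) abort("accumulation rate rounds to zero; projection undefined")
  tibble(
    coverage_pct = round(100 * n_both_barcodes / n_total_species),
    rate_per_annum = rate,
    years_remaining = (n_total_species - n_both_barcodes) %/% rate
  )
}
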