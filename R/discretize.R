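#' Conversion rule from quantitative copy numbers to three-state calls
#'
#' Two modes are provided:
#'
#' * `"threshold"` (default): values in `[lower, upper]` (1.5–2.5 by
#'   default, boundaries inclusive) are called `normal`; values below
#'   `lower` are `deletion`; values above `upper` are `amplification`.
#'   Every finite non-negative value maps to exactly one category.
#' * `"vendor_band"`: the platform vendor's integer-rounding guideline —
#'   a value within `band_halfwidth` (0.4 by default, boundary inclusive)
#'   of its nearest integer maps to that integer (<= 1 copy: `deletion`,
#'   2: `normal`, >= 3: `amplification`); values farther from any integer
#'   are *excluded* from categorical analysis. Rounding of exact halves is
#'   away from zero, so e.g. 2.5 rounds to 3 (and, at the default 0.4 band,
#'   is excluded since it sits 0.5 from that integer).
#'
#' @param mode `"threshold"` or `"vendor_band"`.
#' @param lower,upper Normal-range boundaries in copies per diploid genome
#'   (threshold mode).
#' @param band_halfwidth Half-width of the accepted band around each
#'   integer (vendor mode); must lie in (0, 0.5).
#' @return A list of class `conversion_rule`.
#' @export
#' @examples
#' conversion_rule()
#' conversion_rule("vendor_band")
conversion_rule <- function(mode = c("threshold", "vendor_band"),
                            lower = 1.5, upper = 2.5,
                            band_halfwidth = 0.4) {
  mode <- match.arg(mode)
  if (!is.numeric(lower) || !is.numeric(upper) || lower >= upper) {
    abort("conversion_rule: need lower < upper.")
  }
  if (!is.numeric(band_halfwidth) ||
      band_halfwidth <= 0 || band_halfwidth >= 0.5) {
    abort("conversion_rule: band_halfwidth must lie in (0, 0.5).")
  }
  structure(
    list(mode = mode, lower = lower, upper = upper,
         band_halfwidth = band_halfwidth),
    class = "conversion_rule"
  )
}

#' @export
print.conversion_rule <- function(x, ...) {
  if (x$mode == "threshold") {
    cat(sprintf("<conversion_rule> threshold: normal in [%g, %g]\n",
                x$lower, x$upper))
  } else {
    cat(sprintf("<conversion_rule> vendor_band: +/-%g around integers\n",
                x$band_halfwidth))
  }
  invisible(x)
}

# round-half-away-from-zero; inputs are non-negative copy numbers
round_half_away <- function(v) floor(v + 0.5)

#' Discretize quantitative copy numbers into three-state calls
#'
#' Applies a [conversion_rule()] to a vector of copy numbers. In vendor-band
#' mode, values outside every accepted band are excluded and returned as
#' `NA`; threshold mode is total and never excludes.
#'
#' @param v Numeric vector of non-negative, finite copy numbers.
#' @param rule A [conversion_rule()]; threshold mode by default.
#' @return Ordered factor with levels `deletion < normal < amplification`,
#'   `NA` marking vendor-mode exclusions.
#' @export
#' @examples
#' discretize_value(c(0, 1.49, 1.5, 2.5, 2.51))
#' discretize_value(c(1.45, 2.0, 2.45), conversion_rule("vendor_band"))
discretize_value <- function(v, rule = conversion_rule()) {
  stopifnot(inherits(rule, "conversion_rule"))
  if (!is.numeric(v)) abort("discretize_value: v must be numeric.")
  if (any(!is.finite(v) | v < 0)) {
    abort("discretize_value: copy numbers must be finite and >= 0.")
  }
  lev <- cn_categories()
  if (rule$mode == "threshold") {
    out <- ifelse(v < rule$lower, "deletion",
                  ifelse(v > rule$upper, "amplification", "normal"))
  } else {
    nearest <- round_half_away(v)
    inside <- abs(v - nearest) <= rule$band_halfwidth
    out <- ifelse(!inside, NA_character_,
                  ifelse(nearest <= 1, "deletion",
                         ifelse(nearest == 2, "normal", "amplification")))
  }
  factor(out, levels = lev, ordered = TRUE)
}

#' Discretize every quantitative measurement in a dataset
#'
#' Replaces quantitative measurements by categorical calls under the given
#' [conversion_rule()]; categorical measurements pass through unchanged.
#' In vendor-band mode, excluded values are dropped from the output (missing
#' data is row absence). A per-method conversion log is attached as the
#' `"conversion_log"` attribute.
#'
#' @param ds A [cnv_dataset()] or coercible data frame.
#' @param rule A [conversion_rule()].
#' @return A [cnv_dataset()] in which every method is categorical, with
#'   attribute `conversion_log`: a tibble of per-method counts
#'   (`n_converted`, `n_excluded`).
#' @export
discretize_dataset <- function(ds, rule = conversion_rule()) {
  ds <- as_cnv_dataset(ds)
  tbl <- as_tibble(ds)
  quant <- tbl$value_kind == "quantitative"
  new_call <- tbl$call
  if (any(quant)) {
    new_call[quant] <- discretize_value(tbl$value[quant], rule)
  }
  log <- dplyr::summarise(
    dplyr::group_by(tbl[quant, c("method_id", "value")], .data$method_id),
    n_converted = sum(!is.na(discretize_value(.data$value, rule))),
    n_excluded = sum(is.na(discretize_value(.data$value, rule))),
    .groups = "drop"
  )
  tbl$call <- new_call
  tbl$value <- NA_real_
  tbl$value_kind <- "categorical"
  tbl <- tbl[!is.na(tbl$call), ]
  out <- cnv_dataset(tbl)
  attr(out, "conversion_log") <- log
  out
}
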