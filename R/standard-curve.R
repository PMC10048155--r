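#' Amplification efficiency from a dilution-series standard curve
#'
#' Least-squares fit of Cq on log10(template amount). For a valid curve the
#' slope is negative and the amplification efficiency is
#' `E = 10^(-1/slope)` (fold/cycle), with percent efficiency
#' `(E - 1) * 100`. A perfect two-fold dilution series stepping one cycle
#' per dilution gives slope `-1/log10(2) = -3.3219`, E = 2 and 100%
#' efficiency. End points may be dropped explicitly (never silently) to
#' restrict the fit to the linear range.
#'
#' @param amounts template quantities per reaction (> 0; any consistent unit)
#' @param cq_obs observed Cq per dilution point
#' @param gene_id optional label carried into the result
#' @param drop_low,drop_high number of points (0-2) to drop from the
#'   low-/high-amount end of the series before fitting
#' @return object of class `efficiency_curve`: list with `gene_id`,
#'   `amounts`, `cq_obs` (after dropping), `slope` (cycles per log10),
#'   `intercept`, `r_squared`, `E`, `percent_e`, `valid` (slope < 0)
#' @export
fit_standard_curve <- function(amounts, cq_obs, gene_id = NA_character_,
                               drop_low = 0, drop_high = 0) {
  stopifnot(length(amounts) == length(cq_obs))
  if (any(!is.finite(amounts) | amounts <= 0))
    stop("template amounts must be finite and > 0", call. = FALSE)
  if (drop_low < 0 || drop_low > 2 || drop_high < 0 || drop_high > 2)
    stop("at most two points may be dropped from either end", call. = FALSE)
  ord <- order(amounts)
  amounts <- amounts[ord]; cq_obs <- cq_obs[ord]
  n <- length(amounts)
  keep <- seq_len(n)
  if (drop_low > 0) keep <- setdiff(keep, seq_len(drop_low))
  if (drop_high > 0) keep <- setdiff(keep, n - seq_len(drop_high) + 1)
  amounts <- amounts[keep]; cq_obs <- cq_obs[keep]
  if (length(amounts) < 3)
    stop("standard curve needs >= 3 points after dropping", call. = FALSE)
  if (length(amounts) < 5)
    warning("fewer than 5 dilution points; efficiency estimate is fragile",
            call. = FALSE)
  fit <- stats::lm(cq_obs ~ log10(amounts))
  slope <- unname(stats::coef(fit)[2])
  r2 <- suppressWarnings(summary(fit)$r.squared)  # exact data is legitimate
  valid <- is.finite(slope) && slope < 0
  if (!valid) {
    warning("non-negative standard-curve slope; curve flagged invalid and E not reported",
            call. = FALSE)
    E <- NA_real_; pct <- NA_real_
  } else {
    E <- 10^(-1 / slope)
    pct <- (E - 1) * 100
  }
  structure(list(gene_id = gene_id, amounts = amounts, cq_obs = cq_obs,
                 slope = slope,
                 intercept = unname(stats::coef(fit)[1]),
                 r_squared = r2, E = E, percent_e = pct, valid = valid),
            class = "efficiency_curve")
}

#' @export
print.efficiency_curve <- function(x, ...) {
  cat(sprintf(
    "standard curve%s: slope %.4f, R^2 %.4f, E %.4f (%.2f%%)%s\n",
    if (is.na(x$gene_id)) "" else paste0(" [", x$gene_id, "]"),
    x$slope, x$r_squared, x$E, x$percent_e,
    if (x$valid) "" else "  ** INVALID (slope >= 0) **"))
  invisible(x)
}

#' Convert between efficiency and standard-curve slope
#'
#' `slope_from_efficiency(E) = -1/log10(E)`, the inverse of
#' `E = 10^(-1/slope)`.
#' @param E amplification efficiency, fold/cycle (> 1)
#' @return slope in cycles per log10(amount)
#' @export
slope_from_efficiency <- function(E) {
  stopifnot(all(E > 1))
  -1 / log10(E)
}
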