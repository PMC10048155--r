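#' Efficiency-corrected relative quantities from Cq values
#'
#' Converts a Cq table to relative quantities
#' `rq[g, s] = E_g ^ (calibrator_Cq_g - Cq[g, s])`, the efficiency-corrected
#' expression level relative to a per-gene calibrator. The classic calibrator
#' is the sample with the gene's minimum Cq (highest expression), which makes
#' `max(rq) = 1` per gene; the control-condition mean Cq is offered for
#' quantification workflows where the control fold should be 1. Any positive
#' rescaling of the calibrator leaves log-ratio statistics (geNorm M, V) and
#' fold changes unchanged.
#'
#' @param x a [cq_table()] (technical replicates are collapsed first if a
#'   grouping is present)
#' @param calibrator `"min"` (default) or `"control_mean"`
#' @param control control condition label, required for
#'   `calibrator = "control_mean"`
#' @return an object of class `rq_matrix`: list with `rq` (genes x samples
#'   matrix, all > 0), `efficiency`, `condition`, `calibrator`
#' @export
to_relative_quantities <- function(x, calibrator = c("min", "control_mean"),
                                   control = NULL) {
  stopifnot(inherits(x, "cq_table"))
  calibrator <- match.arg(calibrator)
  x <- collapse_tech_reps(x)
  if (any(x$efficiency <= 1))
    stop("amplification efficiencies must be > 1 fold/cycle", call. = FALSE)
  cal <- switch(calibrator,
    min = apply(x$cq, 1, min),
    control_mean = {
      if (is.null(control) || !control %in% x$condition)
        stop("`control` must name a condition present in the table",
             call. = FALSE)
      rowMeans(x$cq[, names(x$condition)[x$condition == control],
                    drop = FALSE])
    })
  rq <- x$efficiency ^ (cal - x$cq)   # recycles per-gene E down columns
  structure(list(rq = rq, efficiency = x$efficiency,
                 condition = x$condition, calibrator = calibrator),
            class = "rq_matrix")
}

#' @export
print.rq_matrix <- function(x, ...) {
  cat(sprintf("rq_matrix: %d genes x %d samples (calibrator: %s)\n",
              nrow(x$rq), ncol(x$rq), x$calibrator))
  invisible(x)
}
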