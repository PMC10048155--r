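#' Efficiency-corrected single reference-gene expression ratio
#'
#' The classic single-RG ratio: `E_t^dcq_t / E_r^dcq_r`, where each dcq is
#' the mean control Cq minus the mean treated Cq for the target (t) and the
#' reference (r) gene, and each E is the gene's amplification efficiency.
#'
#' @param e_target,e_ref amplification efficiencies (fold/cycle, > 1)
#' @param dcq_target,dcq_ref mean Cq(control) - mean Cq(treated), cycles
#' @return the expression ratio (fold change), dimensionless
#' @references Pfaffl (2001) Nucleic Acids Res 29:e45
#' @export
pfaffl_ratio <- function(e_target, dcq_target, e_ref, dcq_ref) {
  if (e_target <= 1 || e_ref <= 1)
    stop("efficiencies must be > 1 fold/cycle", call. = FALSE)
  (e_target ^ dcq_target) / (e_ref ^ dcq_ref)
}

#' Multi reference-gene normalized relative quantities and fold change
#'
#' Per sample, each gene's relative quantity is
#' `RQ_g(s) = E_g^(mean control Cq of g - Cq[g, s])` (so the control
#' condition averages to RQ ~ 1); the target's normalized relative quantity
#' is its RQ divided by the geometric mean of the RQ of the reference-gene
#' set. The fold change of each treated condition versus control is the
#' ratio of mean NRQs, with a two-tailed t-test on the per-replicate NRQs.
#' With a single reference gene and `fold_mean = "geometric"` the fold
#' reduces exactly to [pfaffl_ratio()] on the mean delta-Cqs.
#'
#' @param x a [cq_table()]; technical replicates are collapsed first
#' @param target target gene id (must not be in `rg_set`)
#' @param rg_set character vector of reference-gene ids (non-empty)
#' @param control control condition label
#' @param fold_mean `"arithmetic"` (default; ratio of arithmetic mean NRQs)
#'   or `"geometric"` (ratio of geometric mean NRQs)
#' @param test_scale run the t-test on `"linear"` (default) or `"log2"` NRQs
#' @param var_equal `FALSE` (default) Welch, `TRUE` pooled-variance Student
#' @return object of class `quant_result`: list with `target`, `rg_set`,
#'   `nrq` (named per-sample vector), `rq` (genes x samples matrix), and
#'   `table` (data.frame: `condition`, `fold`, `p`; control row fold = 1)
#' @export
multi_rg_nrq <- function(x, target, rg_set, control,
                         fold_mean = c("arithmetic", "geometric"),
                         test_scale = c("linear", "log2"),
                         var_equal = FALSE) {
  stopifnot(inherits(x, "cq_table"))
  fold_mean <- match.arg(fold_mean)
  test_scale <- match.arg(test_scale)
  if (length(rg_set) == 0) stop("`rg_set` must be non-empty", call. = FALSE)
  if (target %in% rg_set)
    stop("target gene must not be part of the reference-gene set",
         call. = FALSE)
  x <- collapse_tech_reps(x)
  missing_g <- setdiff(c(target, rg_set), gene_ids(x))
  if (length(missing_g) > 0)
    stop(sprintf("gene(s) not in table: %s",
                 paste(missing_g, collapse = ", ")), call. = FALSE)
  if (!control %in% x$condition)
    stop(sprintf("control condition '%s' not present", control),
         call. = FALSE)
  rqm <- to_relative_quantities(x, calibrator = "control_mean",
                                control = control)
  rg_rq <- rqm$rq[rg_set, , drop = FALSE]
  nf <- exp(colMeans(log(rg_rq)))        # geometric mean of RG quantities
  nrq <- rqm$rq[target, ] / nf
  conds <- unique(unname(x$condition))
  ctrl_nrq <- nrq[x$condition == control]
  if (length(ctrl_nrq) == 0) stop("empty control condition", call. = FALSE)
  tab <- do.call(rbind, lapply(conds, function(cc) {
    v <- nrq[x$condition == cc]
    if (length(v) == 0) stop("empty condition", call. = FALSE)
    ft <- fold_change_test(ctrl_nrq, v, var_equal = var_equal,
                           scale = test_scale, fold_mean = fold_mean)
    data.frame(condition = cc, n = length(v), fold = ft[["fold"]],
               p = ft[["p"]], stringsAsFactors = FALSE)
  }))
  rownames(tab) <- NULL
  structure(list(target = target, rg_set = rg_set, control = control,
                 nrq = nrq, rq = rqm$rq[c(target, rg_set), , drop = FALSE],
                 condition = x$condition, table = tab,
                 fold_mean = fold_mean),
            class = "quant_result")
}

#' @export
print.quant_result <- function(x, ...) {
  cat(sprintf("relative expression of %s normalized by {%s} (control: %s)\n",
              x$target, paste(x$rg_set, collapse = ", "), x$control))
  print(x$table, row.names = FALSE, digits = 4)
  invisible(x)
}

#' Fold change and two-tailed t-test between NRQ arms
#'
#' @param nrq_control,nrq_treated per-replicate normalized relative
#'   quantities (> 0, >= 2 per arm for a p-value)
#' @param var_equal `FALSE` (default) Welch, `TRUE` pooled-variance Student
#' @param scale t-test on `"linear"` (default) or `"log2"` NRQs
#' @param fold_mean `"arithmetic"` (default) or `"geometric"` mean ratio
#' @return named numeric vector `c(fold = , p = )`. Identical arms give
#'   p = 1; distinct means with zero variance in both arms give p = 0 with a
#'   warning (degenerate separation).
#' @export
fold_change_test <- function(nrq_control, nrq_treated, var_equal = FALSE,
                             scale = c("linear", "log2"),
                             fold_mean = c("arithmetic", "geometric")) {
  scale <- match.arg(scale)
  fold_mean <- match.arg(fold_mean)
  stopifnot(all(nrq_control > 0), all(nrq_treated > 0))
  fold <- switch(fold_mean,
                 arithmetic = mean(nrq_treated) / mean(nrq_control),
                 geometric = exp(mean(log(nrq_treated)) -
                                   mean(log(nrq_control))))
  if (length(nrq_control) < 2 || length(nrq_treated) < 2)
    return(c(fold = fold, p = NA_real_))
  a <- if (scale == "log2") log2(nrq_treated) else nrq_treated
  b <- if (scale == "log2") log2(nrq_control) else nrq_control
  if (stats::sd(a) == 0 && stats::sd(b) == 0 &&
        !isTRUE(all.equal(mean(a), mean(b))))
    warning("zero within-arm variance with distinct means; p = 0 limit",
            call. = FALSE)
  p <- .two_tailed_t(a, b, var_equal)
  c(fold = fold, p = p)
}

#' Fig-4-style quantification over targets and reference-gene sets
#'
#' Convenience wrapper running [multi_rg_nrq()] for every combination of
#' target gene and reference-gene set (single genes or geometric-mean
#' combinations).
#'
#' @param x a [cq_table()]
#' @param targets character vector of target gene ids
#' @param rg_sets list of character vectors (each one reference-gene set)
#' @param control control condition label
#' @param ... passed to [multi_rg_nrq()]
#' @return data.frame: `target`, `rg_set` (comma-joined), `condition`,
#'   `fold`, `p`
#' @export
quantify_targets <- function(x, targets, rg_sets, control, ...) {
  if (!is.list(rg_sets)) rg_sets <- list(rg_sets)
  out <- do.call(rbind, lapply(targets, function(tg) {
    do.call(rbind, lapply(rg_sets, function(rgs) {
      q <- multi_rg_nrq(x, tg, rgs, control, ...)
      cbind(target = tg, rg_set = paste(rgs, collapse = ","),
            q$table[, c("condition", "fold", "p")])
    }))
  }))
  rownames(out) <- NULL
  out
}
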