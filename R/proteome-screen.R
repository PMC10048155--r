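#' One-way ANOVA across conditions, per protein
#'
#' Fixed-effects one-way analysis of variance of relative abundance on
#' condition, run independently for every protein. A protein whose values
#' are all identical (zero between- and within-group variance) is reported
#' as F = 0, p = 1; zero residual variance with a real group effect gives
#' F = Inf, p = 0.
#'
#' @param tab an [abundance_table()] with >= 2 conditions and >= 2 replicates
#'   per condition
#' @return data.frame with columns `protein_id`, `f`, `p`
#' @export
anova_per_protein <- function(tab) {
  stopifnot(inherits(tab, "abundance_table"))
  g <- factor(unname(tab$condition))
  if (nlevels(g) < 2)
    stop("ANOVA needs at least 2 conditions", call. = FALSE)
  n_per <- table(g)
  if (any(n_per < 2))
    stop(sprintf("condition '%s' has fewer than 2 replicates",
                 names(n_per)[which(n_per < 2)[1]]), call. = FALSE)
  m <- tab$abundance
  # sums of squares directly; equivalent to anova(lm(y ~ g)) per protein but
  # vectorized over the (possibly thousands of) proteins
  grand <- rowMeans(m)
  sst <- rowSums((m - grand)^2)
  gm <- .condition_means(m, tab$condition)
  counts <- as.numeric(n_per[colnames(gm)])
  ssb <- rowSums(sweep((gm - grand)^2, 2, counts, `*`))
  sse <- sst - ssb
  df1 <- nlevels(g) - 1
  df2 <- ncol(m) - nlevels(g)
  f <- (ssb / df1) / (sse / df2)
  p <- stats::pf(f, df1, df2, lower.tail = FALSE)
  # degenerate cases
  flat <- sst < .Machine$double.eps * pmax(1, grand^2) * ncol(m)
  f[flat] <- 0; p[flat] <- 1
  sep <- !flat & sse <= 0
  f[sep] <- Inf; p[sep] <- 0
  data.frame(protein_id = rownames(m), f = unname(f), p = unname(p),
             stringsAsFactors = FALSE)
}

#' Rank proteins by the absolute difference of condition means
#'
#' The candidate screen: for every protein the absolute difference between
#' the mean abundances of a designated condition pair (typically the
#' progenitor/control vs the most variable derived condition) is computed and
#' proteins are ranked ascending — the smallest difference marks the most
#' promising reference-gene candidate. All remaining pairwise mean
#' differences and the per-protein one-way ANOVA p-value are attached.
#'
#' @param tab an [abundance_table()]
#' @param control,treated condition labels of the primary pair
#' @return data.frame of class `screen_rows` sorted ascending by
#'   `diff_primary` (ties broken by protein accession): columns `rank`,
#'   `protein_id`, one `mean_<condition>` per condition, `diff_primary`,
#'   one `diff_<a>_<b>` per remaining pair, `anova_p`.
#' @export
rank_by_mean_difference <- function(tab, control, treated) {
  stopifnot(inherits(tab, "abundance_table"))
  conds <- unique(unname(tab$condition))
  for (cc in c(control, treated))
    if (!cc %in% conds)
      stop(sprintf("unknown condition label '%s'", cc), call. = FALSE)
  gm <- .condition_means(tab$abundance, tab$condition)
  out <- data.frame(protein_id = rownames(gm), stringsAsFactors = FALSE)
  for (cc in conds) out[[paste0("mean_", cc)]] <- gm[, cc]
  out$diff_primary <- abs(gm[, control] - gm[, treated])
  pairs <- utils::combn(conds, 2, simplify = FALSE)
  for (pr in pairs) {
    if (setequal(pr, c(control, treated))) next
    out[[paste0("diff_", pr[1], "_", pr[2])]] <- abs(gm[, pr[1]] - gm[, pr[2]])
  }
  out$anova_p <- anova_per_protein(tab)$p
  ord <- order(out$diff_primary, out$protein_id)
  out <- out[ord, , drop = FALSE]
  out <- cbind(rank = seq_len(nrow(out)), out)
  rownames(out) <- NULL
  class(out) <- c("screen_rows", "data.frame")
  out
}

#' Filter the top-ranked candidates by ANOVA p-value
#'
#' Keeps, among the `top_n` best-ranked rows of the screen, those whose
#' one-way ANOVA p-value exceeds `p_min` — i.e. proteins with no detectable
#' abundance difference across conditions. Rank order is preserved.
#'
#' @param rows output of [rank_by_mean_difference()]
#' @param top_n how many top-ranked rows to consider (clamped to the table
#'   size with a warning)
#' @param p_min candidates must have `anova_p > p_min` (strict)
#' @return the retained subset of `rows`, in rank order
#' @export
select_candidates <- function(rows, top_n = 25, p_min = 0.05) {
  stopifnot(is.data.frame(rows), all(c("rank", "anova_p") %in% names(rows)))
  if (top_n < 1) stop("`top_n` must be >= 1", call. = FALSE)
  if (p_min < 0 || p_min >= 1) stop("`p_min` must be in [0, 1)", call. = FALSE)
  if (top_n > nrow(rows)) {
    warning(sprintf("top_n = %d exceeds table size %d; clamped", top_n,
                    nrow(rows)), call. = FALSE)
    top_n <- nrow(rows)
  }
  head_rows <- rows[order(rows$rank), , drop = FALSE][seq_len(top_n), ,
                                                      drop = FALSE]
  out <- head_rows[head_rows$anova_p > p_min, , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Protein fold change relative to the control-condition mean
#'
#' For each protein every replicate abundance is divided by the mean
#' abundance of the control condition; these per-replicate ratios are
#' averaged within each condition and reported as fold change, with a
#' two-tailed t-test of the condition's ratios against the control's ratios.
#' By construction the control condition has fold = 1 exactly.
#'
#' @param tab an [abundance_table()]
#' @param control control condition label (>= 2 replicates)
#' @param var_equal `FALSE` (default) for Welch's t-test, `TRUE` for the
#'   pooled-variance Student test
#' @return data.frame with columns `protein_id`, `condition`, `fold`, `p`
#' @export
protein_fold_change <- function(tab, control, var_equal = FALSE) {
  stopifnot(inherits(tab, "abundance_table"))
  conds <- unique(unname(tab$condition))
  if (!control %in% conds)
    stop(sprintf("unknown control condition '%s'", control), call. = FALSE)
  ctrl_cols <- names(tab$condition)[tab$condition == control]
  if (length(ctrl_cols) < 2)
    stop("control condition needs >= 2 replicates", call. = FALSE)
  m <- tab$abundance
  ctrl_mean <- rowMeans(m[, ctrl_cols, drop = FALSE])
  if (any(ctrl_mean == 0))
    stop(sprintf("control-condition mean abundance is 0 for protein '%s'",
                 rownames(m)[which(ctrl_mean == 0)[1]]), call. = FALSE)
  ratios <- m / ctrl_mean
  res <- lapply(conds, function(cc) {
    cols <- names(tab$condition)[tab$condition == cc]
    r <- ratios[, cols, drop = FALSE]
    r0 <- ratios[, ctrl_cols, drop = FALSE]
    p <- vapply(seq_len(nrow(m)), function(i)
      .two_tailed_t(r[i, ], r0[i, ], var_equal), numeric(1))
    data.frame(protein_id = rownames(m), condition = cc,
               fold = rowMeans(r), p = p, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, res)
  rownames(out) <- NULL
  out
}

# two-tailed t-test p-value robust to the zero-variance degeneracies the
# simulators and trivial fixtures produce
.two_tailed_t <- function(x, y, var_equal = FALSE) {
  if (identical(unname(as.numeric(x)), unname(as.numeric(y)))) return(1)
  if (stats::sd(x) == 0 && stats::sd(y) == 0)
    return(if (isTRUE(all.equal(mean(x), mean(y)))) 1 else 0)
  tryCatch(stats::t.test(x, y, var.equal = var_equal)$p.value,
           error = function(e) {
             if (isTRUE(all.equal(mean(x), mean(y)))) 1 else 0
           })
}
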