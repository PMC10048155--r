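#' BestKeeper descriptive statistics and index correlation
#'
#' For each candidate gene: the standard deviation and coefficient of
#' variation of its raw Cq values across samples, and the Pearson correlation
#' (with two-sided p-value) between the gene's Cq and the BestKeeper index —
#' the per-sample geometric mean of the Cq values of all candidates. Genes
#' with Cq SD >= 1 cycle are flagged unsuitable. The full gene-by-gene
#' pairwise correlation matrix is also returned. Genes are ranked by
#' descending index correlation (undefined correlations rank last, ties by
#' gene id).
#'
#' @param x a [cq_table()]; technical replicates are collapsed first
#' @return object of class `bestkeeper`: list with `stats` (data.frame:
#'   `gene_id`, `sd`, `cv`, `r`, `p`, `suitable`, `rank`), `index`
#'   (per-sample geometric-mean Cq), `pairwise_r` (gene x gene matrix)
#' @references Pfaffl et al. (2004) Biotechnol Lett 26:509-515
#' @export
bestkeeper <- function(x) {
  stopifnot(inherits(x, "cq_table"))
  x <- collapse_tech_reps(x)
  m <- x$cq
  if (ncol(m) < 3) stop("BestKeeper needs >= 3 samples", call. = FALSE)
  sds <- apply(m, 1, stats::sd)
  cvs <- 100 * sds / rowMeans(m)
  index <- exp(colMeans(log(m)))
  rp <- t(vapply(seq_len(nrow(m)), function(i) {
    if (sds[i] == 0 || stats::sd(index) == 0) return(c(NA_real_, NA_real_))
    ct <- stats::cor.test(m[i, ], index)
    c(unname(ct$estimate), ct$p.value)
  }, numeric(2)))
  pw <- suppressWarnings(stats::cor(t(m)))
  genes <- rownames(m)
  stats_df <- data.frame(gene_id = genes, sd = unname(sds), cv = unname(cvs),
                         r = rp[, 1], p = rp[, 2],
                         suitable = unname(sds) < 1,
                         stringsAsFactors = FALSE)
  stats_df$rank <- .rank_metric(-stats_df$r, genes)
  structure(list(stats = stats_df, index = index, pairwise_r = pw),
            class = "bestkeeper")
}

#' @export
print.bestkeeper <- function(x, ...) {
  cat("BestKeeper stability statistics\n")
  print(x$stats[order(x$stats$rank), ], row.names = FALSE, digits = 3)
  invisible(x)
}

# average ranks on a metric (lower = better), NA always last, with a
# deterministic display order tie-broken by gene id
.rank_metric <- function(metric, ids) {
  r <- rank(metric, ties.method = "average", na.last = "keep")
  n_ok <- sum(!is.na(metric))
  if (anyNA(r)) r[is.na(r)] <- n_ok + rank(ids[is.na(r)])
  unname(r)
}

# deterministic ordering: metric ascending, gene id breaks exact ties
.order_metric <- function(metric, ids) order(metric, ids, na.last = TRUE)
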