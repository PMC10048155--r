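#' Comparative delta-Ct stability ranking
#'
#' For every gene pair (j, k) the per-sample difference
#' `dCq_s = Cq[j, s] - Cq[k, s]` is formed and its standard deviation across
#' samples computed; a pair of stably (or co-) expressed genes keeps a
#' constant offset and a small SD. Each gene is scored by the mean of these
#' pair SDs over all its partners and ranked ascending.
#'
#' @param x a [cq_table()]; technical replicates are collapsed first
#' @return object of class `delta_ct`: list with `stats` (data.frame:
#'   `gene_id`, `mean_sd`, `rank`) and `pair_sd` (gene x gene matrix of pair
#'   SDs, zero diagonal)
#' @references Silver et al. (2006) BMC Mol Biol 7:33
#' @export
delta_ct_method <- function(x) {
  stopifnot(inherits(x, "cq_table"))
  x <- collapse_tech_reps(x)
  m <- x$cq
  if (nrow(m) < 2) stop("delta-Ct needs >= 2 genes", call. = FALSE)
  genes <- rownames(m)
  k <- nrow(m)
  pair_sd <- matrix(0, k, k, dimnames = list(genes, genes))
  for (j in seq_len(k - 1)) {
    for (l in (j + 1):k) {
      s <- stats::sd(m[j, ] - m[l, ])
      pair_sd[j, l] <- s
      pair_sd[l, j] <- s
    }
  }
  mean_sd <- rowSums(pair_sd) / (k - 1)
  stats_df <- data.frame(gene_id = genes, mean_sd = unname(mean_sd),
                         stringsAsFactors = FALSE)
  stats_df$rank <- .rank_metric(stats_df$mean_sd, genes)
  structure(list(stats = stats_df, pair_sd = pair_sd), class = "delta_ct")
}

#' @export
print.delta_ct <- function(x, ...) {
  cat("comparative delta-Ct stability (mean pairwise SD, cycles)\n")
  print(x$stats[order(x$stats$rank), ], row.names = FALSE, digits = 3)
  invisible(x)
}
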