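#' Geometric-mean consensus of per-algorithm ranks
#'
#' Combines the stability rankings of several algorithms into one consensus
#' by the unweighted geometric mean of each gene's ranks (the aggregation
#' rule popularized by comprehensive ranking tools). Ties within an
#' algorithm are expected to carry average ranks. The consensus value is
#' rounded to two decimals for reporting; the final order is ascending, with
#' exact ties broken by gene id.
#'
#' @param ranks a named list (or data.frame / matrix with genes in rows) of
#'   per-algorithm rank vectors, each named by gene id; every algorithm must
#'   rank the same gene set
#' @return data.frame: `gene_id`, one `rank_<algorithm>` column per input,
#'   `geomean` (2-decimal), `consensus_rank`, ordered by consensus
#' @export
consensus_rank <- function(ranks) {
  if (is.data.frame(ranks) || is.matrix(ranks)) {
    ranks <- as.matrix(ranks)
    ranks <- stats::setNames(lapply(seq_len(ncol(ranks)), function(j)
      stats::setNames(ranks[, j], rownames(ranks))), colnames(ranks))
  }
  stopifnot(is.list(ranks), length(ranks) >= 1)
  if (is.null(names(ranks)) || any(names(ranks) == ""))
    names(ranks) <- paste0("alg", seq_along(ranks))
  genes <- sort(names(ranks[[1]]))
  for (a in names(ranks)) {
    if (is.null(names(ranks[[a]])) ||
          !setequal(names(ranks[[a]]), genes))
      stop(sprintf("algorithm '%s' does not rank the same gene set", a),
           call. = FALSE)
    if (any(!is.finite(ranks[[a]])))
      stop(sprintf("algorithm '%s' has non-finite ranks", a), call. = FALSE)
  }
  rm_ <- sapply(ranks, function(r) r[genes])
  if (is.null(dim(rm_))) rm_ <- matrix(rm_, nrow = 1,
                                       dimnames = list(genes, names(ranks)))
  gm <- exp(rowMeans(log(rm_)))
  out <- data.frame(gene_id = genes, stringsAsFactors = FALSE)
  for (a in names(ranks)) out[[paste0("rank_", a)]] <- rm_[, a]
  out$geomean <- round(gm, 2)
  out <- out[.order_metric(gm, genes), , drop = FALSE]
  out$consensus_rank <- seq_len(nrow(out))
  rownames(out) <- NULL
  out
}

#' Full stability report across all algorithms
#'
#' Runs BestKeeper, NormFinder, geNorm and the comparative delta-Ct method on
#' one Cq table and combines their rankings into the geometric-mean
#' consensus, together with the standard suitability flags (BestKeeper Cq
#' SD < 1 cycle; geNorm M < 1) and the geNorm pairwise-variation series.
#'
#' @param x a [cq_table()]
#' @param v_cutoff geNorm pairwise-variation cutoff (default 0.15)
#' @param grouped use conditions as NormFinder subgroups (default `TRUE`)
#' @return object of class `stability_report`: list with `table` (one row
#'   per gene: per-algorithm metrics, ranks, consensus geometric mean,
#'   suitability flags), the four fitted objects, and the V series
#' @export
stability_report <- function(x, v_cutoff = 0.15, grouped = TRUE) {
  stopifnot(inherits(x, "cq_table"))
  x <- collapse_tech_reps(x)
  bk <- bestkeeper(x)
  nf <- normfinder(x, grouped = grouped)
  gn <- genorm(to_relative_quantities(x), v_cutoff = v_cutoff)
  dc <- delta_ct_method(x)
  genes <- gene_ids(x)
  ranks <- list(
    bestkeeper = stats::setNames(bk$stats$rank, bk$stats$gene_id),
    normfinder = stats::setNames(nf$stats$rank, nf$stats$gene_id),
    genorm = stats::setNames(gn$stats$rank, gn$stats$gene_id),
    deltact = stats::setNames(dc$stats$rank, dc$stats$gene_id))
  cons <- consensus_rank(ranks)
  tab <- data.frame(gene_id = genes, stringsAsFactors = FALSE)
  tab$bestkeeper_sd <- bk$stats$sd[match(genes, bk$stats$gene_id)]
  tab$bestkeeper_cv <- bk$stats$cv[match(genes, bk$stats$gene_id)]
  tab$bestkeeper_r <- bk$stats$r[match(genes, bk$stats$gene_id)]
  tab$bestkeeper_p <- bk$stats$p[match(genes, bk$stats$gene_id)]
  tab$normfinder_rho <- nf$stats$rho[match(genes, nf$stats$gene_id)]
  tab$normfinder_se <- nf$stats$se[match(genes, nf$stats$gene_id)]
  tab$genorm_m <- gn$stats$m[match(genes, gn$stats$gene_id)]
  tab$deltact_mean_sd <- dc$stats$mean_sd[match(genes, dc$stats$gene_id)]
  for (a in names(ranks)) tab[[paste0("rank_", a)]] <- unname(ranks[[a]][genes])
  tab$consensus_geomean <- cons$geomean[match(genes, cons$gene_id)]
  tab$consensus_rank <- cons$consensus_rank[match(genes, cons$gene_id)]
  tab$sd_suitable <- tab$bestkeeper_sd < 1
  tab$m_suitable <- tab$genorm_m < 1
  tab <- tab[order(tab$consensus_rank), , drop = FALSE]
  rownames(tab) <- NULL
  structure(list(table = tab, bestkeeper = bk, normfinder = nf, genorm = gn,
                 delta_ct = dc, v = gn$v, recommended_n = gn$recommended_n),
            class = "stability_report")
}

#' @export
print.stability_report <- function(x, ...) {
  cat("Reference-gene stability report (consensus order)\n")
  cols <- c("gene_id", "bestkeeper_r", "normfinder_rho", "genorm_m",
            "deltact_mean_sd", "consensus_geomean", "consensus_rank")
  print(x$table[, cols], row.names = FALSE, digits = 3)
  cat(sprintf("\ngeNorm V series: %s\nrecommended number of RGs: %s\n",
              paste(sprintf("%s=%.3f", names(x$v), x$v), collapse = ", "),
              if (is.na(x$recommended_n)) "none" else x$recommended_n))
  invisible(x)
}
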