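#' geNorm expression stability M and pairwise variation V
#'
#' The M value of gene *j* is the mean, over every other candidate *k*, of
#' the standard deviation across samples of `log2(rq_j / rq_k)`; a low M
#' marks a gene whose expression ratio with the other candidates is constant.
#' Genes are ranked directly by their full-panel M (the convention of
#' comprehensive ranking tools, which report a distinct M for every gene
#' including the top pair, and the one that uses all partner information).
#' The classic stepwise-exclusion trajectory is also computed and returned:
#' the gene with the highest M is removed and M recomputed on the remainder
#' until two genes are left; the final pair is unresolvable by the exclusion
#' procedure itself and is ordered by the three-gene-step M.
#'
#' Normalization factors `NF_n` (per-sample geometric mean of the rq of the
#' n most stable genes) give the pairwise variation
#' `V_{n/n+1} = sd(log2(NF_n / NF_{n+1}))`; the smallest n with V below the
#' cutoff (default 0.15) is the recommended number of reference genes.
#'
#' @param rq an `rq_matrix` from [to_relative_quantities()] (or a
#'   [cq_table()], converted with the min-Cq calibrator)
#' @param v_cutoff pairwise-variation cutoff, default 0.15
#' @return object of class `genorm`: list with `stats` (data.frame:
#'   `gene_id`, `m` (full-panel), `m_step` (M at the exclusion step),
#'   `rank` (by full-panel M, ties by gene id), `rank_stepwise`),
#'   `exclusion_order` (first removed ... ), `final_pair`, `v` (named vector
#'   `V2/3`, `V3/4`, ...), `v_cutoff`, `recommended_n` (`NA` when no V falls
#'   below the cutoff)
#' @references Vandesompele et al. (2002) Genome Biol 3:research0034
#' @export
genorm <- function(rq, v_cutoff = 0.15) {
  if (inherits(rq, "cq_table")) rq <- to_relative_quantities(rq)
  stopifnot(inherits(rq, "rq_matrix"))
  m <- rq$rq
  if (any(m <= 0)) stop("relative quantities must be > 0", call. = FALSE)
  if (nrow(m) < 3) stop("geNorm needs >= 3 genes", call. = FALSE)
  if (ncol(m) < 2) stop("geNorm needs >= 2 samples", call. = FALSE)
  lg <- log2(m)
  genes <- rownames(m)

  m_full <- genorm_m(lg)
  # stepwise exclusion (highest M removed; exact ties resolved by removing
  # the lexicographically later gene id, for deterministic output)
  keep <- genes
  excluded <- character(0)
  m_step <- stats::setNames(numeric(length(genes)), genes)
  m3 <- NULL
  while (length(keep) > 2) {
    mk <- genorm_m(lg[keep, , drop = FALSE])
    if (length(keep) == 3) m3 <- mk
    worst <- keep[order(-mk, keep, method = "radix",
                        decreasing = c(FALSE, TRUE))][1]
    m_step[worst] <- mk[worst]
    excluded <- c(excluded, worst)
    keep <- setdiff(keep, worst)
  }
  m2 <- genorm_m(lg[keep, , drop = FALSE])
  m_step[keep] <- m2
  # final pair of the exclusion path, ordered by the 3-gene-step M
  pair <- keep[.order_metric(m3[keep], keep)]
  step_order <- c(pair, rev(excluded))
  rank_step <- stats::setNames(seq_along(step_order), step_order)[genes]

  rank_order <- genes[.order_metric(m_full, genes)]
  rank <- stats::setNames(seq_along(rank_order), rank_order)[genes]

  stats_df <- data.frame(gene_id = genes, m = unname(m_full),
                         m_step = unname(m_step[genes]),
                         rank = unname(rank),
                         rank_stepwise = unname(rank_step),
                         stringsAsFactors = FALSE)

  nf <- .genorm_nf(m, rank_order)
  nmax <- length(genes)
  v <- stats::setNames(numeric(nmax - 2),
                       paste0("V", 2:(nmax - 1), "/", 3:nmax))
  for (n in 2:(nmax - 1))
    v[n - 1] <- stats::sd(log2(nf[, n] / nf[, n + 1]))
  below <- which(v < v_cutoff)
  recommended_n <- if (length(below) > 0) unname(below[1]) + 1L
                   else NA_integer_

  structure(list(stats = stats_df, exclusion_order = excluded,
                 final_pair = pair, v = v, v_cutoff = v_cutoff,
                 recommended_n = recommended_n),
            class = "genorm")
}

#' geNorm M values for a log2 relative-quantity matrix
#'
#' Lower-level worker: mean over partners of the SD across samples of the
#' pairwise log-ratios. Exported for property checks against brute-force
#' recomputation.
#'
#' @param lg log2 relative quantities, genes x samples
#' @return named numeric vector of M values
#' @export
genorm_m <- function(lg) {
  k <- nrow(lg)
  stopifnot(k >= 2)
  m <- stats::setNames(numeric(k), rownames(lg))
  for (j in seq_len(k)) {
    partners <- setdiff(seq_len(k), j)
    m[j] <- mean(vapply(partners, function(p)
      stats::sd(lg[j, ] - lg[p, ]), numeric(1)))
  }
  m
}

# per-sample normalization factors NF_n for n = 1..N in stability order
.genorm_nf <- function(rq, order_ids) {
  sapply(seq_along(order_ids), function(n)
    exp(colMeans(log(rq[order_ids[seq_len(n)], , drop = FALSE]))))
}

#' @export
print.genorm <- function(x, ...) {
  cat("geNorm expression stability\n")
  print(x$stats[order(x$stats$rank), ], row.names = FALSE, digits = 3)
  cat("\npairwise variation:\n")
  print(round(x$v, 3))
  cat(sprintf("recommended number of reference genes (V < %.2f): %s\n",
              x$v_cutoff,
              if (is.na(x$recommended_n)) "none" else x$recommended_n))
  invisible(x)
}
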