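#' NormFinder model-based stability estimation
#'
#' Variance-decomposition estimator of candidate reference-gene stability on
#' the log2 scale. Relative quantities are log2-transformed and
#' sample-centered across genes (removing per-sample loading); for each gene
#' and sample group the model separates an intergroup deviation (systematic
#' condition-dependent shift) from the intragroup variance (random
#' within-group scatter). Intragroup variance is modelled as group-shared
#' per gene and pooled across groups (essential at the few-replicates-per-
#' group design sizes this package targets), bias-corrected for the sample
#' centering; the intergroup variance component is estimated by the method
#' of moments, and each group deviation is shrunk toward zero by its
#' sampling-variance weight. The stability value combines the magnitude of
#' the shrunken intergroup deviation with the intragroup standard error;
#' lower is more stable. With no grouping (or one group) the estimator
#' reduces to the corrected intragroup standard deviation.
#'
#' @param x a [cq_table()]; technical replicates are collapsed first
#' @param grouped use the sample-to-condition map as subgroups (default
#'   `TRUE` when >= 2 conditions each with >= 2 samples)
#' @return object of class `normfinder`: list with `stats` (data.frame:
#'   `gene_id`, `rho` (stability value), `se`, `rank`), `intergroup`
#'   (genes x groups matrix of shrunken deviations), `intragroup_var`
#'   (genes x groups matrix)
#' @references Andersen, Jensen & Orntoft (2004) Cancer Res 64:5245-5250
#' @export
normfinder <- function(x, grouped = TRUE) {
  stopifnot(inherits(x, "cq_table"))
  x <- collapse_tech_reps(x)
  if (nrow(x$cq) < 2) stop("NormFinder needs >= 2 genes", call. = FALSE)
  y <- log2(to_relative_quantities(x)$rq)
  genes <- rownames(y)
  k <- nrow(y)
  z <- sweep(y, 2, colMeans(y))          # sample-centered log quantities
  groups <- unname(x$condition)
  gl <- unique(groups)
  if (grouped && length(gl) >= 2) {
    n_per <- table(factor(groups, levels = gl))
    if (any(n_per < 2))
      stop(sprintf("group '%s' has a single sample; >= 2 required per group",
                   names(n_per)[which(n_per < 2)[1]]), call. = FALSE)
    G <- length(gl)
    zbar <- sapply(gl, function(g)
      rowMeans(z[, groups == g, drop = FALSE]))
    # pooled within-group variance per gene (group-shared), then corrected
    # for the across-gene sample centering
    ss <- sapply(gl, function(g) {
      zg <- z[, groups == g, drop = FALSE]
      rowSums((zg - rowMeans(zg))^2)
    })
    s2_pooled <- rowSums(ss) / sum(as.numeric(n_per) - 1)
    sig2_vec <- .correct_centered_var(s2_pooled, k)
    sig2 <- matrix(sig2_vec, nrow = k, ncol = G,
                   dimnames = list(genes, gl))
    d <- zbar - rowMeans(zbar)           # intergroup deviations, sum_g = 0
    n_g <- matrix(as.numeric(n_per[gl]), nrow = k, ncol = G, byrow = TRUE)
    # sampling variance of each d_ig: on the *centered* scale (uncorrected
    # pooled variance), because the across-gene centering noise shared by a
    # group propagates into every gene's group mean
    sv <- matrix(s2_pooled, nrow = k, ncol = G) / n_g
    # variance of true intergroup deviations, pooled over all genes (the
    # candidates are modelled as draws from one intergroup distribution)
    gamma2 <- max(0, sum(d^2) / (k * (G - 1)) - mean(sv))
    shrink <- gamma2 / (gamma2 + sv)     # empirical-Bayes weight, 0 when
    shrink[!is.finite(shrink)] <- 0      # gamma2 = sv = 0
    d_tilde <- d * shrink
    # per-gene variability term: SE of a group mean from the gene's own
    # corrected variance (floored to keep strict ordering when the
    # correction hits zero)
    own2 <- pmax(sig2_vec, 1e-3 * s2_pooled + 1e-12)
    own_se <- sqrt(matrix(own2, nrow = k, ncol = G) / n_g)
    rho_g <- abs(d_tilde) + own_se
    rho <- rowMeans(rho_g)
    se <- apply(rho_g, 1, stats::sd) / sqrt(G)
  } else {
    if (ncol(z) < 2) stop("NormFinder needs >= 2 samples", call. = FALSE)
    sig2 <- .correct_centered_var(apply(z, 1, stats::var), k)
    rho <- sqrt(sig2)
    se <- rho / sqrt(2 * (ncol(z) - 1))  # delta-method SE of an SD
    d_tilde <- matrix(0, k, 1, dimnames = list(genes, "all"))
    sig2 <- matrix(sig2, ncol = 1, dimnames = list(genes, "all"))
  }
  stats_df <- data.frame(gene_id = genes, rho = unname(rho),
                         se = unname(se), stringsAsFactors = FALSE)
  stats_df$rank <- .rank_metric(stats_df$rho, genes)
  out <- list(stats = stats_df,
              intergroup = if (exists("d_tilde")) d_tilde else NULL,
              intragroup_var = sig2)
  class(out) <- "normfinder"
  out
}

# unbiased intragroup variances after centering each sample across k genes:
# E[s2_i] = sigma2_i (1 - 2/k) + mean-term; invert the linear system.
# k = 2 leaves the system singular, so raw variances are returned.
.correct_centered_var <- function(s2, k) {
  if (k < 3) return(pmax(s2, 0))
  S_hat <- sum(s2) * k / (k - 1)
  pmax(k * (s2 - S_hat / k^2) / (k - 2), 0)
}

#' @export
print.normfinder <- function(x, ...) {
  cat("NormFinder stability values (lower = more stable)\n")
  print(x$stats[order(x$stats$rank), ], row.names = FALSE, digits = 3)
  invisible(x)
}
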