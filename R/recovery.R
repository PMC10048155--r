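#' Truth designed for ground-truth recovery of the most stable gene
#'
#' A seven-candidate panel in which one gene (`STABLE1`) has strictly the
#' smallest injected total variation: technical SD 0.1 cycles, no
#' biological noise of its own, no condition effect. The six competitors
#' carry technical SDs spanning 0.40-0.50 cycles (the top of the observed
#' per-gene range) plus 0.12 cycles of biological noise, and are likewise
#' effect-free, so the discrimination task is purely noise-driven. A shared
#' loading SD of 0.5 cycles gives every gene the common per-replicate
#' signal that normalization (and index-correlation scoring) exists to
#' exploit. A target gene (`TARGET1`, technical SD 0.37) carries a 6-fold
#' adipogenic effect for fold-recovery scoring.
#'
#' @param target_effect true ADM fold effect of the target gene
#' @return a [sim_truth()]
#' @seealso [recovery_experiment()]
#' @export
recovery_truth <- function(target_effect = 6) {
  genes <- data.frame(
    gene_id = c("STABLE1", paste0("VAR", 1:6), "TARGET1"),
    base_cq = c(22, 24.5, 23.7, 20.8, 17.8, 16.2, 21.2, 26.8),
    tech_sd = c(0.1, seq(0.40, 0.50, length.out = 6), 0.37),
    bio_sd = c(0, rep(0.12, 6), 0.1),
    efficiency = c(2, 1.883, 2.0992, 2.0161, 1.9098, 2.0942, 1.8365,
                   2.0398),
    effect_ADM = c(rep(1, 7), target_effect),
    effect_OM  = c(rep(1, 7), 1),
    stringsAsFactors = FALSE)
  sim_truth(genes, conditions = c("SM", "ADM", "OM"), load_sd = 0.5)
}

#' Seeded recovery experiment across the four stability algorithms
#'
#' Repeatedly simulates the study design (default: 3 conditions x 3
#' biological x 3 technical replicates), runs BestKeeper, NormFinder, geNorm
#' and the comparative delta-Ct method on the candidate reference genes, and
#' scores how often each algorithm ranks the gene with the smallest injected
#' total variation first. Also records how often the geNorm
#' pairwise-variation rule recommends two reference genes (sufficient here,
#' since truly stable candidates exist), and the estimated fold change of
#' the target gene normalized by the three effect-free candidates.
#'
#' @param n_seeds number of simulated replicates of the experiment
#' @param truth a [sim_truth()]; genes with a condition effect of 2-fold or
#'   more are treated as targets, the rest as reference candidates
#' @param bio_reps,tech_reps design size per condition
#' @param seed base seed; replicate i uses substreams keyed on `seed + i`
#' @param treated condition whose target fold is scored (default `"ADM"`)
#' @return object of class `recovery_summary`: list with `top1` (named
#'   fraction per algorithm), `recommended_n_match` (fraction of seeds with
#'   geNorm recommended n == 2), `folds` (per-seed estimated target folds),
#'   `true_fold`, `fold_median`, `n_seeds`
#' @export
recovery_experiment <- function(n_seeds = 200, truth = recovery_truth(),
                                bio_reps = 3, tech_reps = 3, seed = 1,
                                treated = "ADM") {
  stopifnot(inherits(truth, "sim_truth"))
  lfc <- abs(log2(truth$effect))
  is_target <- apply(lfc >= 1, 1, any)   # >= 2-fold somewhere = target
  rg_candidates <- rownames(truth$effect)[!is_target]
  targets <- rownames(truth$effect)[is_target]
  # injected total variation: technical (after averaging), biological and
  # systematic condition-shift components, in cycles
  g <- truth$genes
  shift <- -log(truth$effect[g$gene_id, , drop = FALSE]) /
    log(g$efficiency)
  eff_var <- apply(shift, 1, function(s) mean((s - mean(s))^2))
  tot <- sqrt(g$tech_sd^2 / tech_reps + g$bio_sd^2 + eff_var)
  names(tot) <- g$gene_id
  stable <- rg_candidates[which.min(tot[rg_candidates])]
  if (sum(tot[rg_candidates] == tot[stable]) > 1)
    stop("truth must designate a strictly most stable candidate",
         call. = FALSE)
  effect_free <- intersect(rg_candidates, truth_reference_genes(truth))
  rg_set <- effect_free[order(tot[effect_free])][1:3]
  if (anyNA(rg_set))
    stop("need >= 3 effect-free reference candidates for quantification",
         call. = FALSE)
  algs <- c("bestkeeper", "normfinder", "genorm", "deltact")
  hits <- matrix(FALSE, n_seeds, length(algs),
                 dimnames = list(NULL, algs))
  rec_n <- integer(n_seeds)
  folds <- rep(NA_real_, n_seeds * max(1, length(targets)))
  dim(folds) <- c(n_seeds, max(1, length(targets)))
  for (i in seq_len(n_seeds)) {
    tab <- simulate_cq(truth, bio_reps = bio_reps, tech_reps = tech_reps,
                       seed = seed + i)
    tab <- collapse_tech_reps(tab)
    rg_tab <- subset_genes(tab, rg_candidates)
    bk <- bestkeeper(rg_tab)
    nf <- normfinder(rg_tab)
    gn <- genorm(to_relative_quantities(rg_tab))
    dc <- delta_ct_method(rg_tab)
    rank_of <- function(st) st$rank[match(stable, st$gene_id)]
    hits[i, ] <- c(rank_of(bk$stats) == 1, rank_of(nf$stats) == 1,
                   rank_of(gn$stats) == 1, rank_of(dc$stats) == 1)
    rec_n[i] <- gn$recommended_n
    for (j in seq_along(targets)) {
      q <- multi_rg_nrq(tab, targets[j], rg_set, truth$control)
      folds[i, j] <- q$table$fold[q$table$condition == treated]
    }
  }
  true_fold <- if (length(targets) > 0)
    truth$effect[targets[1], treated] else NA_real_
  structure(list(
    top1 = colMeans(hits),
    recommended_n_match = mean(!is.na(rec_n) & rec_n == 2),
    folds = folds[, 1],
    true_fold = true_fold,
    fold_median = stats::median(folds[, 1]),
    stable_gene = stable, rg_set = rg_set, n_seeds = n_seeds),
    class = "recovery_summary")
}

#' @export
print.recovery_summary <- function(x, ...) {
  cat(sprintf("recovery over %d seeds (stable gene: %s)\n", x$n_seeds,
              x$stable_gene))
  cat("fraction ranked #1:\n")
  print(round(x$top1, 3))
  cat(sprintf("geNorm recommended n == 2: %.3f\n", x$recommended_n_match))
  if (!is.na(x$true_fold))
    cat(sprintf("target fold: true %.2f, median estimate %.3f\n",
                x$true_fold, x$fold_median))
  invisible(x)
}

#' Subset a Cq table to a set of genes
#' @param x a `cq_table`
#' @param genes gene ids to keep (order preserved as given)
#' @return a `cq_table`
#' @export
subset_genes <- function(x, genes) {
  stopifnot(inherits(x, "cq_table"))
  missing_g <- setdiff(genes, gene_ids(x))
  if (length(missing_g) > 0)
    stop(sprintf("gene(s) not in table: %s",
                 paste(missing_g, collapse = ", ")), call. = FALSE)
  .cq_table(x$cq[genes, , drop = FALSE], x$condition,
            x$efficiency[genes], x$tech_rep_group, warn = FALSE)
}
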