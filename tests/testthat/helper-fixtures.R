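# deterministic toy tables used across the suite

# small complete Cq table: 4 genes x 6 samples, 2 conditions, E varied
toy_cq <- function() {
  m <- rbind(
    RGA = c(20.1, 20.0, 19.9, 20.2, 20.0, 19.8),
    RGB = c(22.3, 22.1, 22.2, 22.4, 22.0, 22.2),
    RGC = c(18.0, 18.4, 17.8, 18.2, 18.1, 18.3),
    TGT = c(25.0, 25.2, 24.9, 23.1, 23.0, 23.2))
  colnames(m) <- paste0("s", 1:6)
  suppressWarnings(   # one candidate runs over 100% efficiency by design
    cq_table(m,
             conditions = setNames(rep(c("CTRL", "TRT"), each = 3),
                                   colnames(m)),
             efficiencies = c(RGA = 2, RGB = 1.9, RGC = 2.05, TGT = 1.95)))
}

# genes x samples matrix of uniform Cq noise around per-gene baselines
random_cq <- function(n_genes, n_samples, seed, conditions = NULL,
                      efficiencies = NULL) {
  set.seed(seed)
  m <- matrix(runif(n_genes * n_samples, 18, 26), n_genes, n_samples,
              dimnames = list(paste0("g", seq_len(n_genes)),
                              paste0("s", seq_len(n_samples))))
  if (is.null(conditions))
    conditions <- setNames(sort(rep(c("A", "B", "C"),
                                    length.out = n_samples)),
                           colnames(m))
  if (is.null(efficiencies))
    efficiencies <- setNames(runif(n_genes, 1.85, 2.1), rownames(m))
  suppressWarnings(cq_table(m, conditions, efficiencies))
}

# brute-force delta-Ct oracle: enumerate all ordered pairs explicitly
oracle_delta_ct <- function(m) {
  genes <- rownames(m)
  out <- setNames(numeric(length(genes)), genes)
  for (g in genes) {
    sds <- c()
    for (h in setdiff(genes, g))
      sds <- c(sds, sd(m[g, ] - m[h, ]))
    out[g] <- mean(sds)
  }
  out
}

# brute-force geNorm oracle on a relative-quantity matrix
oracle_genorm_m <- function(rq) {
  lg <- log2(rq)
  genes <- rownames(rq)
  out <- setNames(numeric(length(genes)), genes)
  for (g in genes) {
    vals <- c()
    for (h in setdiff(genes, g))
      vals <- c(vals, sd(lg[g, ] - lg[h, ]))
    out[g] <- mean(vals)
  }
  out
}

table4_ranks <- function() {
  df <- eadmsc_rank_table()
  lapply(setNames(c("bestkeeper", "normfinder", "genorm", "deltact"),
                  c("bestkeeper", "normfinder", "genorm", "deltact")),
         function(a) setNames(df[[a]], df$gene))
}
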