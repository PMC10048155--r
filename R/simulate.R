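#' Ground-truth parameters for synthetic Cq data
#'
#' Describes the generative model for a qPCR experiment: per gene a baseline
#' Cq, a map of true condition fold effects (control = 1), a biological
#' between-replicate noise SD, a technical (well-to-well) noise SD and an
#' amplification efficiency; plus a shared per-replicate loading SD
#' (`load_sd`) that shifts every gene of a biological replicate by the same
#' amount, emulating variation in RNA input / RT yield — the artifact that
#' reference-gene normalization exists to remove.
#'
#' @param genes data.frame with columns `gene_id`, `base_cq`, `bio_sd`,
#'   `tech_sd`, `efficiency`, plus one `effect_<condition>` column per
#'   non-control condition (fold change; missing columns default to 1)
#' @param conditions condition labels; the first is the control
#' @param load_sd shared per-biological-replicate loading SD in cycles
#' @return object of class `sim_truth`
#' @seealso [simulate_cq()], [eadmsc_truth()], [recovery_truth()]
#' @export
sim_truth <- function(genes, conditions = c("SM", "ADM", "OM"),
                      load_sd = 0.2) {
  stopifnot(is.data.frame(genes),
            all(c("gene_id", "base_cq", "bio_sd", "tech_sd",
                  "efficiency") %in% names(genes)))
  if (any(genes$bio_sd < 0) || any(genes$tech_sd < 0) || load_sd < 0)
    stop("noise SDs must be >= 0", call. = FALSE)
  if (any(genes$efficiency <= 1))
    stop("efficiencies must be > 1", call. = FALSE)
  eff <- matrix(1, nrow(genes), length(conditions),
                dimnames = list(genes$gene_id, conditions))
  for (cc in conditions[-1]) {
    col <- paste0("effect_", cc)
    if (col %in% names(genes)) eff[, cc] <- genes[[col]]
  }
  if (any(eff <= 0)) stop("fold effects must be > 0", call. = FALSE)
  structure(list(genes = genes, conditions = conditions,
                 control = conditions[1], effect = eff, load_sd = load_sd),
            class = "sim_truth")
}

#' Simulate a Cq table from known ground truth
#'
#' The generative model, on the Cq scale, for gene g in well (condition c,
#' biological replicate r, technical replicate t):
#' \deqn{Cq = base_g - log(effect_{g,c}) / log(E_g) + L_{c,r} + b_{g,c,r} +
#'   \epsilon_{g,c,r,t}}
#' where `L ~ N(0, load_sd^2)` is shared by all genes of a replicate,
#' `b ~ N(0, bio_sd_g^2)` is the gene's biological noise and
#' `\epsilon ~ N(0, tech_sd_g^2)` the technical noise. A true f-fold effect
#' with efficiency E lowers Cq by `log(f)/log(E)` cycles, so the implied
#' efficiency-corrected expression ratio is exactly f in expectation.
#'
#' Randomness is drawn from per-(gene, condition, replicate) substreams
#' keyed on the global seed, so the same seed reproduces the same table
#' regardless of generation order, and the caller's RNG state is left
#' untouched.
#'
#' @param truth a [sim_truth()]
#' @param bio_reps,tech_reps biological / technical replicates per condition
#' @param seed integer seed driving all substreams
#' @return a [cq_table()] with sample ids `<cond>_<rep>_t<tech>` and, when
#'   `tech_reps > 1`, a `tech_rep_group` mapping wells to `<cond>_<rep>`
#' @export
simulate_cq <- function(truth, bio_reps = 3, tech_reps = 3, seed = 1) {
  stopifnot(inherits(truth, "sim_truth"))
  if (bio_reps < 1 || tech_reps < 1)
    stop("design needs >= 1 biological and technical replicate",
         call. = FALSE)
  g <- truth$genes
  conds <- truth$conditions
  wells <- expand.grid(tech = seq_len(tech_reps), rep = seq_len(bio_reps),
                       cond = conds, stringsAsFactors = FALSE)
  sample_id <- sprintf("%s_%d_t%d", wells$cond, wells$rep, wells$tech)
  bio_id <- sprintf("%s_%d", wells$cond, wells$rep)
  m <- matrix(NA_real_, nrow(g), nrow(wells),
              dimnames = list(g$gene_id, sample_id))
  for (cc in conds) {
    for (r in seq_len(bio_reps)) {
      L <- .stream_norm(seed, paste("load", cc, r), 1, truth$load_sd)
      cols <- which(wells$cond == cc & wells$rep == r)
      for (i in seq_len(nrow(g))) {
        b <- .stream_norm(seed, paste("bio", g$gene_id[i], cc, r), 1,
                          g$bio_sd[i])
        eps <- .stream_norm(seed, paste("tech", g$gene_id[i], cc, r),
                            tech_reps, g$tech_sd[i])
        shift <- log(truth$effect[g$gene_id[i], cc]) / log(g$efficiency[i])
        m[i, cols] <- g$base_cq[i] - shift + L + b + eps
      }
    }
  }
  .cq_table(m,
            stats::setNames(wells$cond, sample_id),
            stats::setNames(g$efficiency, g$gene_id),
            if (tech_reps > 1) stats::setNames(bio_id, sample_id) else NULL,
            warn = FALSE)
}

# deterministic Normal substream: a small integer hash of (seed, key) seeds
# an isolated RNG draw; the caller's .Random.seed is preserved
.stream_norm <- function(seed, key, n, sd) {
  if (sd == 0) return(rep(0, n))
  old <- .save_rng()
  on.exit(.restore_rng(old))
  set.seed(.hash31(seed, key))
  stats::runif(7)                 # decorrelate from the seeding itself
  stats::rnorm(n, 0, sd)
}

.stream_lnorm <- function(seed, key, n, sdlog) {
  if (sdlog == 0) return(rep(1, n))
  old <- .save_rng()
  on.exit(.restore_rng(old))
  set.seed(.hash31(seed, key))
  stats::runif(7)
  stats::rlnorm(n, 0, sdlog)
}

# polynomial string hash with a final multiplicative avalanche, so that
# near-identical keys land on well-separated 31-bit seeds
.hash31 <- function(seed, key) {
  h <- as.double(seed %% 2147483647L)
  for (ch in utf8ToInt(key)) h <- (h * 131 + ch) %% 2147483647
  h <- (h * 48271) %% 2147483647   # Lehmer step 1
  h <- (h * 48271) %% 2147483647   # Lehmer step 2
  as.integer(h)
}

.save_rng <- function() {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    get(".Random.seed", envir = globalenv())
  else NULL
}

.restore_rng <- function(old) {
  if (is.null(old)) {
    if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  } else assign(".Random.seed", old, envir = globalenv())
}

#' Ground truth for synthetic protein abundance data
#'
#' @param proteins data.frame with columns `protein_id`, `base`, `cv`
#'   (replicate coefficient of variation on the natural scale), plus
#'   `effect_<condition>` fold columns (default 1)
#' @param conditions condition labels, first is control
#' @return object of class `sim_abundance_truth`
#' @export
sim_abundance_truth <- function(proteins, conditions = c("SM", "ADM", "OM")) {
  stopifnot(is.data.frame(proteins),
            all(c("protein_id", "base", "cv") %in% names(proteins)))
  if (any(proteins$base <= 0)) stop("base abundances must be > 0",
                                    call. = FALSE)
  if (any(proteins$cv < 0)) stop("CV must be >= 0", call. = FALSE)
  eff <- matrix(1, nrow(proteins), length(conditions),
                dimnames = list(proteins$protein_id, conditions))
  for (cc in conditions[-1]) {
    col <- paste0("effect_", cc)
    if (col %in% names(proteins)) eff[, cc] <- proteins[[col]]
  }
  structure(list(proteins = proteins, conditions = conditions,
                 control = conditions[1], effect = eff),
            class = "sim_abundance_truth")
}

#' Simulate a protein abundance table
#'
#' Log-normal replicate noise around `base * effect` condition means: the
#' multiplicative noise has median 1 and coefficient of variation `cv`
#' (sdlog = sqrt(log(1 + cv^2))). `cv = 0` returns the condition means
#' exactly.
#'
#' @param truth a [sim_abundance_truth()]
#' @param reps biological replicates per condition
#' @param seed integer seed
#' @return an [abundance_table()] with sample ids `<cond>_<rep>`
#' @export
simulate_abundance <- function(truth, reps = 3, seed = 1) {
  stopifnot(inherits(truth, "sim_abundance_truth"))
  if (reps < 1) stop("design needs >= 1 replicate", call. = FALSE)
  p <- truth$proteins
  conds <- truth$conditions
  grid <- expand.grid(rep = seq_len(reps), cond = conds,
                      stringsAsFactors = FALSE)
  sample_id <- sprintf("%s_%d", grid$cond, grid$rep)
  m <- matrix(NA_real_, nrow(p), nrow(grid),
              dimnames = list(p$protein_id, sample_id))
  for (i in seq_len(nrow(p))) {
    sdlog <- sqrt(log(1 + p$cv[i]^2))
    for (j in seq_len(nrow(grid))) {
      noise <- .stream_lnorm(seed, paste("ab", p$protein_id[i],
                                         grid$cond[j], grid$rep[j]), 1,
                             sdlog)
      m[i, j] <- p$base[i] * truth$effect[p$protein_id[i], grid$cond[j]] *
        noise
    }
  }
  abundance_table(m, stats::setNames(grid$cond, sample_id))
}

#' Packaged equine ADSC differentiation preset
#'
#' Ground truth emulating the candidate panel of an equine adipose-derived
#' stem cell differentiation experiment: seven reference-gene candidates
#' (PPP6R1, EHD3, CCDC97, EPHA2, GAPDH, ACTB, B2M) plus two targets (FABP5,
#' RUNX2), under standard (SM, control), adipogenic (ADM) and osteogenic
#' (OM) media. Baseline Cq (16-27 cycles), technical SDs (0.04-0.37) and
#' efficiencies (1.84-2.09 fold/cycle) follow the panel's published primer
#' characterization; the targets carry adipogenic/osteogenic induction
#' effects in the observed fold window (FABP5 ~6x ADM / ~5.5x OM, RUNX2
#' ~2x ADM / none in OM); reference candidates have no condition effect.
#'
#' @param bio_sd biological between-replicate SD applied to every gene
#' @param load_sd shared per-replicate loading SD
#' @return a [sim_truth()]
#' @export
eadmsc_truth <- function(bio_sd = 0.1, load_sd = 0.2) {
  genes <- data.frame(
    gene_id = c("PPP6R1", "EHD3", "CCDC97", "EPHA2", "GAPDH", "ACTB",
                "B2M", "FABP5", "RUNX2"),
    base_cq = c(24.50, 24.51, 23.67, 20.84, 17.84, 16.19, 21.19, 26.75,
                23.89),
    tech_sd = c(0.20, 0.08, 0.04, 0.14, 0.23, 0.35, 0.24, 0.37, 0.14),
    efficiency = c(1.883, 2.074, 2.0992, 2.0161, 1.9098, 2.0942, 1.8365,
                   2.0398, 1.902),
    effect_ADM = c(1, 1, 1, 1, 1, 1, 1, 6, 2),
    effect_OM = c(1, 1, 1, 1, 1, 1, 1, 5.5, 1),
    stringsAsFactors = FALSE)
  genes$bio_sd <- bio_sd
  sim_truth(genes, conditions = c("SM", "ADM", "OM"), load_sd = load_sd)
}

#' Reference genes vs target genes of a truth object
#' @param truth a `sim_truth`
#' @return character vector of gene ids with no condition effect (candidate
#'   reference genes) or with an effect (targets)
#' @export
truth_reference_genes <- function(truth) {
  stopifnot(inherits(truth, "sim_truth"))
  rownames(truth$effect)[apply(truth$effect == 1, 1, all)]
}

#' @rdname truth_reference_genes
#' @export
truth_target_genes <- function(truth) {
  stopifnot(inherits(truth, "sim_truth"))
  setdiff(rownames(truth$effect), truth_reference_genes(truth))
}
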