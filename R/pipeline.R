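#' End-to-end pipeline: screen, stability, quantification
#'
#' Orchestrates the three analysis stages in order — proteome candidate
#' screen, reference-gene stability report, target quantification — writing
#' `screen.tsv`, `stability.tsv` (+ `.json`), `vseries.tsv`, `quantify.tsv`
#' and a `run.json` provenance record (package version, seed, configuration
#' hash, input checksums, timestamp) to the output directory. Outputs are
#' deterministic: the same inputs and configuration yield byte-identical
#' tables.
#'
#' @param config a list (see Details) or path to a JSON file with fields:
#'   `cq`, `samples`, `efficiencies` (paths, or `cq_table` under `cq_table`),
#'   `abundance`, `abundance_samples` (paths, optional),
#'   `control` (condition label, required), `pair` (two conditions for the
#'   screen, default control + first other), `top_n` (25), `p_min` (0.05),
#'   `v_cutoff` (0.15), `targets`, `rg_sets` (list of character vectors),
#'   `out_dir` (required), `seed` (0)
#' @return object of class `pipeline_run`: list with `config`, `screen`,
#'   `stability`, `quantify`, `files`
#' @export
run_pipeline <- function(config) {
  if (is.character(config) && length(config) == 1)
    config <- jsonlite::read_json(config, simplifyVector = TRUE)
  stopifnot(is.list(config))
  defaults <- list(top_n = 25, p_min = 0.05, v_cutoff = 0.15, seed = 0)
  for (k in names(defaults))
    if (is.null(config[[k]])) config[[k]] <- defaults[[k]]
  if (is.null(config$out_dir)) stop("config needs `out_dir`", call. = FALSE)
  if (is.null(config$control)) stop("config needs `control`", call. = FALSE)
  if (config$p_min < 0 || config$p_min >= 1 || config$top_n < 1 ||
        config$v_cutoff <= 0)
    stop("invalid thresholds in config", call. = FALSE)
  dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)

  # --- validate inputs before any computation ---
  cq_tab <- NULL
  if (!is.null(config$cq_table)) cq_tab <- config$cq_table
  else if (!is.null(config$cq))
    cq_tab <- read_cq_table(config$cq, config$samples, config$efficiencies)
  ab_tab <- NULL
  if (!is.null(config$abundance_table)) ab_tab <- config$abundance_table
  else if (!is.null(config$abundance))
    ab_tab <- read_abundance_table(config$abundance,
                                   config$abundance_samples)
  if (is.null(cq_tab) && is.null(ab_tab))
    stop("config provides neither Cq nor abundance input", call. = FALSE)
  for (tab in list(cq_tab, ab_tab))
    if (!is.null(tab) && !config$control %in% tab$condition)
      stop(sprintf("control condition '%s' absent from input",
                   config$control), call. = FALSE)

  files <- character(0)
  screen <- NULL
  if (!is.null(ab_tab)) {
    pair <- config$pair
    if (is.null(pair)) {
      others <- setdiff(unique(unname(ab_tab$condition)), config$control)
      pair <- c(config$control, others[1])
    }
    rows <- rank_by_mean_difference(ab_tab, pair[1], pair[2])
    kept <- select_candidates(rows, config$top_n, config$p_min)
    screen <- list(rows = rows, candidates = kept)
    f <- file.path(config$out_dir, "screen.tsv")
    out <- rows
    num <- vapply(out, is.numeric, logical(1)) & names(out) != "rank"
    out[num] <- lapply(out[num], function(v) round(v, 3))
    out$selected <- out$protein_id %in% kept$protein_id
    .write_delim(out, f)
    files <- c(files, f)
  }

  stab <- NULL
  if (!is.null(cq_tab)) {
    cq_tab <- collapse_tech_reps(cq_tab)
    rg_candidates <- config$rg_candidates
    targets <- config$targets
    stab_tab <- if (!is.null(rg_candidates))
      subset_genes(cq_tab, rg_candidates) else cq_tab
    stab <- stability_report(stab_tab, v_cutoff = config$v_cutoff)
    f <- file.path(config$out_dir, "stability.tsv")
    files <- c(files, write_stability_report(stab, f),
               write_v_series(stab, file.path(config$out_dir,
                                              "vseries.tsv")))
    if (!is.null(targets)) {
      rg_sets <- config$rg_sets
      if (is.null(rg_sets))
        rg_sets <- list(stab$table$gene_id[seq_len(min(3,
                                                       nrow(stab$table)))])
      qt <- quantify_targets(cq_tab, targets, rg_sets, config$control)
      qt$fold <- round(qt$fold, 4)
      qt$p <- signif(qt$p, 4)
      fq <- file.path(config$out_dir, "quantify.tsv")
      .write_delim(qt, fq)
      files <- c(files, fq)
      quant <- qt
    } else quant <- NULL
  } else quant <- NULL

  prov <- list(
    tool = "qpcrstab",
    version = as.character(utils::packageVersion("qpcrstab")),
    seed = config$seed,
    config_hash = .fnv_hash(jsonlite::toJSON(
      config[setdiff(names(config), c("cq_table", "abundance_table"))],
      auto_unbox = TRUE)),
    inputs = .input_checksums(config),
    timestamp = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z"))
  fj <- file.path(config$out_dir, "run.json")
  jsonlite::write_json(prov, fj, auto_unbox = TRUE, pretty = TRUE)
  files <- c(files, fj)

  structure(list(config = config, screen = screen, stability = stab,
                 quantify = quant, files = files, provenance = prov),
            class = "pipeline_run")
}

#' @export
print.pipeline_run <- function(x, ...) {
  cat("pipeline run -> ", x$config$out_dir, "\n", sep = "")
  cat("files:", paste(basename(x$files), collapse = ", "), "\n")
  invisible(x)
}

# 32-bit FNV-1a over a string, reported as 8 hex digits
.fnv_hash <- function(s) {
  h <- 2166136261
  for (ch in utf8ToInt(as.character(s))) {
    h <- bitwXor(as.integer(h %% 2^31), ch)  # keep in integer range
    h <- (h * 16777619) %% 2^32
  }
  sprintf("%08x", as.integer(h %% 2^31))
}

.input_checksums <- function(config) {
  paths <- unlist(config[c("cq", "samples", "efficiencies", "abundance",
                           "abundance_samples")], use.names = TRUE)
  paths <- paths[!vapply(paths, is.null, logical(1))]
  if (length(paths) == 0) return(list())
  as.list(vapply(paths, function(p)
    if (file.exists(p)) unname(tools::md5sum(p)) else NA_character_,
    character(1)))
}
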