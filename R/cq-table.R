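#' Cq table: quantification cycles for genes across samples
#'
#' The central container of the package: a complete genes x samples matrix of
#' quantification-cycle (Cq) values together with a sample-to-condition map,
#' per-gene amplification efficiencies (fold increase of product per PCR
#' cycle, ideal 2.0), and an optional technical-replicate grouping. All
#' downstream stability and quantification functions consume this object.
#'
#' @param cq numeric matrix, genes in rows (rownames = gene ids), samples in
#'   columns (colnames = sample ids). Must be complete, finite, in (0, 60).
#' @param conditions named character vector mapping every sample id to a
#'   condition label.
#' @param efficiencies named numeric vector mapping gene id to amplification
#'   efficiency E (fold/cycle, 1 < E <= 2.2). Genes missing from the vector
#'   (or `NULL`) default to E = 2 with a warning.
#' @param tech_rep_group optional named character vector mapping every sample
#'   id to a biological-replicate id; technical replicates are averaged with
#'   [collapse_tech_reps()] before analysis.
#' @return an object of class `cq_table`: a list with elements `cq`,
#'   `condition`, `efficiency` and (possibly `NULL`) `tech_rep_group`.
#' @seealso [read_cq_table()], [collapse_tech_reps()],
#'   [to_relative_quantities()]
#' @export
cq_table <- function(cq, conditions, efficiencies = NULL,
                     tech_rep_group = NULL) {
  .cq_table(cq, conditions, efficiencies, tech_rep_group, warn = TRUE)
}

.cq_table <- function(cq, conditions, efficiencies, tech_rep_group,
                      warn = TRUE) {
  if (!is.matrix(cq) || !is.numeric(cq))
    stop("`cq` must be a numeric matrix (genes x samples)", call. = FALSE)
  if (is.null(rownames(cq)) || is.null(colnames(cq)))
    stop("`cq` must carry gene rownames and sample colnames", call. = FALSE)
  if (anyDuplicated(rownames(cq)))
    stop("duplicated gene ids in Cq matrix", call. = FALSE)
  if (anyDuplicated(colnames(cq)))
    stop("duplicated sample ids in Cq matrix", call. = FALSE)
  bad <- which(!is.finite(cq) | cq <= 0 | cq >= 60, arr.ind = TRUE)
  if (nrow(bad) > 0) {
    stop(sprintf(
      "invalid Cq value for gene '%s', sample '%s' (must be finite, in (0, 60))",
      rownames(cq)[bad[1, 1]], colnames(cq)[bad[1, 2]]), call. = FALSE)
  }
  samples <- colnames(cq)
  conditions <- .require_map(conditions, samples, "condition", "sample")
  genes <- rownames(cq)
  if (is.null(efficiencies)) {
    warning("no efficiencies supplied; defaulting all genes to E = 2.0 (100%)",
            call. = FALSE)
    efficiencies <- stats::setNames(rep(2, length(genes)), genes)
  } else {
    if (is.null(names(efficiencies)))
      stop("`efficiencies` must be named by gene id", call. = FALSE)
    missing_e <- setdiff(genes, names(efficiencies))
    if (length(missing_e) > 0) {
      warning(sprintf("no efficiency for gene(s) %s; defaulting to E = 2.0",
                      paste(missing_e, collapse = ", ")), call. = FALSE)
      efficiencies[missing_e] <- 2
    }
    efficiencies <- efficiencies[genes]
    if (any(!is.finite(efficiencies) | efficiencies <= 1 |
              efficiencies > 2.2)) {
      bad_g <- genes[which(!is.finite(efficiencies) | efficiencies <= 1 |
                             efficiencies > 2.2)[1]]
      stop(sprintf("efficiency for gene '%s' must be finite and in (1, 2.2]",
                   bad_g), call. = FALSE)
    }
    if (warn && any(efficiencies > 2))
      warning("efficiency > 2 (over 100%) accepted, not clamped",
              call. = FALSE)
  }
  if (!is.null(tech_rep_group))
    tech_rep_group <- .require_map(tech_rep_group, samples,
                                   "biological replicate", "sample")
  structure(list(cq = cq, condition = conditions,
                 efficiency = efficiencies,
                 tech_rep_group = tech_rep_group),
            class = "cq_table")
}

.require_map <- function(map, keys, what, keyname) {
  if (is.null(names(map)))
    stop(sprintf("%s map must be named by %s id", what, keyname),
         call. = FALSE)
  missing_k <- setdiff(keys, names(map))
  if (length(missing_k) > 0)
    stop(sprintf("no %s for %s(s): %s", what, keyname,
                 paste(missing_k, collapse = ", ")), call. = FALSE)
  stats::setNames(as.character(map[keys]), keys)
}

#' @export
print.cq_table <- function(x, ...) {
  cat(sprintf("cq_table: %d genes x %d samples, %d condition(s)%s\n",
              nrow(x$cq), ncol(x$cq), length(unique(x$condition)),
              if (is.null(x$tech_rep_group)) ""
              else sprintf(", %d biological replicate group(s)",
                           length(unique(x$tech_rep_group)))))
  cat("genes:", paste(rownames(x$cq), collapse = ", "), "\n")
  invisible(x)
}

#' @export
dim.cq_table <- function(x) dim(x$cq)

#' Gene and sample accessors
#' @param x a `cq_table` or `abundance_table`
#' @return character vector of ids
#' @export
gene_ids <- function(x) UseMethod("gene_ids")
#' @export
gene_ids.cq_table <- function(x) rownames(x$cq)
#' @rdname gene_ids
#' @export
sample_ids <- function(x) UseMethod("sample_ids")
#' @export
sample_ids.cq_table <- function(x) colnames(x$cq)

#' Average technical replicates to biological-replicate means
#'
#' Collapses the Cq matrix column-wise by the technical-replicate grouping:
#' every group of wells belonging to one biological replicate is replaced by
#' its per-gene mean Cq. Averaging is done on the Cq scale before any
#' stability or quantification computation. Samples within a group must share
#' one condition. The result is order-invariant: permuting input columns does
#' not change the collapsed table (columns are emitted in first-appearance
#' order of the group ids).
#'
#' @param x a `cq_table`. If `tech_rep_group` is `NULL` the table is returned
#'   unchanged.
#' @return a `cq_table` whose sample ids are the biological-replicate ids and
#'   whose `tech_rep_group` is `NULL`.
#' @export
collapse_tech_reps <- function(x) {
  stopifnot(inherits(x, "cq_table"))
  if (is.null(x$tech_rep_group)) return(x)
  grp <- x$tech_rep_group[colnames(x$cq)]
  groups <- unique(grp)  # first-appearance order
  cond <- character(length(groups))
  m <- matrix(NA_real_, nrow(x$cq), length(groups),
              dimnames = list(rownames(x$cq), groups))
  for (i in seq_along(groups)) {
    cols <- which(grp == groups[i])
    cc <- unique(x$condition[colnames(x$cq)[cols]])
    if (length(cc) != 1)
      stop(sprintf(
        "biological replicate '%s' spans multiple conditions: %s",
        groups[i], paste(cc, collapse = ", ")), call. = FALSE)
    cond[i] <- cc
    m[, i] <- rowMeans(x$cq[, cols, drop = FALSE])
  }
  .cq_table(m, stats::setNames(cond, groups), x$efficiency, NULL,
            warn = FALSE)
}

#' Read a Cq table and its sample sheet from delimited text
#'
#' @param path TSV/CSV file: first column gene id, remaining columns one per
#'   sample (header row of sample ids). Delimiter inferred from the file
#'   extension (`.csv` = comma, otherwise tab).
#' @param samples_path TSV/CSV sample sheet with columns `sample`,
#'   `condition` and optionally `bio_rep` (technical-replicate grouping).
#' @param efficiencies_path optional TSV/CSV with columns `gene`,
#'   `efficiency`. Values are fold/cycle (e.g. 1.883) unless
#'   `efficiency_percent = TRUE`, in which case percentages (e.g. 88.3) are
#'   converted via E = 1 + pct/100.
#' @param efficiency_percent logical; interpret the efficiency column as
#'   percent efficiency.
#' @param collapse average technical replicates when `bio_rep` is present
#'   (default `TRUE`).
#' @return a validated [cq_table()]
#' @export
read_cq_table <- function(path, samples_path, efficiencies_path = NULL,
                          efficiency_percent = FALSE, collapse = TRUE) {
  df <- .read_delim(path)
  if (ncol(df) < 2)
    stop("Cq table needs a gene column plus at least one sample column",
         call. = FALSE)
  genes <- as.character(df[[1]])
  m <- as.matrix(df[, -1, drop = FALSE])
  storage.mode(m) <- "double"
  rownames(m) <- genes
  bad <- which(is.na(m), arr.ind = TRUE)
  if (nrow(bad) > 0)
    stop(sprintf("missing or non-numeric Cq for gene '%s', sample '%s' in %s",
                 genes[bad[1, 1]], colnames(m)[bad[1, 2]], path),
         call. = FALSE)
  ss <- .read_delim(samples_path)
  .require_cols(ss, c("sample", "condition"), samples_path)
  unknown <- setdiff(as.character(ss$sample), colnames(m))
  if (length(unknown) > 0)
    stop(sprintf("sample sheet lists unknown sample(s): %s",
                 paste(unknown, collapse = ", ")), call. = FALSE)
  cond <- stats::setNames(as.character(ss$condition), as.character(ss$sample))
  trg <- NULL
  if ("bio_rep" %in% names(ss))
    trg <- stats::setNames(as.character(ss$bio_rep), as.character(ss$sample))
  eff <- NULL
  if (!is.null(efficiencies_path)) {
    ef <- .read_delim(efficiencies_path)
    .require_cols(ef, c("gene", "efficiency"), efficiencies_path)
    e <- as.numeric(ef$efficiency)
    if (efficiency_percent) e <- 1 + e / 100
    eff <- stats::setNames(e, as.character(ef$gene))
  }
  x <- cq_table(m, cond, eff, trg)
  if (collapse && !is.null(trg)) x <- collapse_tech_reps(x) else x
}

#' Write a Cq table (and companions) back to delimited text
#'
#' Round-trips with [read_cq_table()]: gene table, sample sheet and
#' efficiency table are written as TSV with UTF-8/LF and deterministic column
#' order.
#'
#' @param x a `cq_table`
#' @param path output path for the Cq matrix TSV
#' @param samples_path,efficiencies_path optional companion paths
#' @return invisibly, the vector of paths written
#' @export
write_cq_table <- function(x, path, samples_path = NULL,
                           efficiencies_path = NULL) {
  stopifnot(inherits(x, "cq_table"))
  df <- data.frame(gene = rownames(x$cq), x$cq, check.names = FALSE,
                   stringsAsFactors = FALSE)
  .write_delim(df, path)
  written <- path
  if (!is.null(samples_path)) {
    ss <- data.frame(sample = colnames(x$cq),
                     condition = unname(x$condition),
                     stringsAsFactors = FALSE)
    if (!is.null(x$tech_rep_group))
      ss$bio_rep <- unname(x$tech_rep_group[colnames(x$cq)])
    .write_delim(ss, samples_path)
    written <- c(written, samples_path)
  }
  if (!is.null(efficiencies_path)) {
    .write_delim(data.frame(gene = names(x$efficiency),
                            efficiency = unname(x$efficiency),
                            stringsAsFactors = FALSE), efficiencies_path)
    written <- c(written, efficiencies_path)
  }
  invisible(written)
}

.read_delim <- function(path) {
  if (!file.exists(path)) stop(sprintf("file not found: %s", path),
                               call. = FALSE)
  sep <- if (grepl("\\.csv$", path, ignore.case = TRUE)) "," else "\t"
  utils::read.table(path, header = TRUE, sep = sep, check.names = FALSE,
                    stringsAsFactors = FALSE, comment.char = "",
                    quote = "\"", na.strings = c("NA", ""))
}

.write_delim <- function(df, path) {
  sep <- if (grepl("\\.csv$", path, ignore.case = TRUE)) "," else "\t"
  con <- file(path, open = "wb")  # force LF on every platform
  on.exit(close(con))
  lines <- c(paste(names(df), collapse = sep),
             do.call(paste, c(lapply(df, function(col) {
               if (is.numeric(col)) format(col, digits = 15, trim = TRUE,
                                           scientific = FALSE)
               else as.character(col)
             }), sep = sep)))
  writeLines(lines, con, sep = "\n", useBytes = TRUE)
  invisible(path)
}

.require_cols <- function(df, cols, path) {
  missing_c <- setdiff(cols, names(df))
  if (length(missing_c) > 0)
    stop(sprintf("%s is missing column(s): %s", path,
                 paste(missing_c, collapse = ", ")), call. = FALSE)
  invisible(df)
}
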