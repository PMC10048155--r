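#' Protein relative-abundance table
#'
#' Proteins x samples matrix of relative abundance units (arbitrary scale,
#' non-negative), as produced by isobaric-label LC-MS reporter quantification,
#' with a sample-to-condition map. Input to the proteome candidate screen.
#'
#' @param abundance numeric matrix, proteins in rows (rownames = accessions),
#'   samples in columns. Values must be finite and >= 0.
#' @param conditions named character vector mapping sample id to condition.
#' @return an object of class `abundance_table` with elements `abundance` and
#'   `condition`.
#' @seealso [read_abundance_table()], [rank_by_mean_difference()]
#' @export
abundance_table <- function(abundance, conditions) {
  if (!is.matrix(abundance) || !is.numeric(abundance))
    stop("`abundance` must be a numeric matrix (proteins x samples)",
         call. = FALSE)
  if (is.null(rownames(abundance)) || is.null(colnames(abundance)))
    stop("`abundance` must carry protein rownames and sample colnames",
         call. = FALSE)
  bad <- which(!is.finite(abundance) | abundance < 0, arr.ind = TRUE)
  if (nrow(bad) > 0)
    stop(sprintf(
      "invalid abundance for protein '%s', sample '%s' (finite, >= 0 required)",
      rownames(abundance)[bad[1, 1]], colnames(abundance)[bad[1, 2]]),
      call. = FALSE)
  conditions <- .require_map(conditions, colnames(abundance),
                             "condition", "sample")
  structure(list(abundance = abundance, condition = conditions),
            class = "abundance_table")
}

#' @export
print.abundance_table <- function(x, ...) {
  cat(sprintf("abundance_table: %d proteins x %d samples, %d condition(s)\n",
              nrow(x$abundance), ncol(x$abundance),
              length(unique(x$condition))))
  invisible(x)
}

#' @export
dim.abundance_table <- function(x) dim(x$abundance)

#' @export
gene_ids.abundance_table <- function(x) rownames(x$abundance)

#' @export
sample_ids.abundance_table <- function(x) colnames(x$abundance)

#' Read a protein abundance table and sample sheet
#'
#' @param path TSV/CSV: first column protein accession, remaining columns one
#'   per sample.
#' @param samples_path TSV/CSV with columns `sample`, `condition`.
#' @return a validated [abundance_table()]
#' @export
read_abundance_table <- function(path, samples_path) {
  df <- .read_delim(path)
  if (ncol(df) < 2)
    stop("abundance table needs a protein column plus sample columns",
         call. = FALSE)
  prot <- as.character(df[[1]])
  m <- as.matrix(df[, -1, drop = FALSE])
  storage.mode(m) <- "double"
  rownames(m) <- prot
  bad <- which(is.na(m), arr.ind = TRUE)
  if (nrow(bad) > 0)
    stop(sprintf("missing or non-numeric abundance for protein '%s', sample '%s'",
                 prot[bad[1, 1]], colnames(m)[bad[1, 2]]), call. = FALSE)
  ss <- .read_delim(samples_path)
  .require_cols(ss, c("sample", "condition"), samples_path)
  unknown <- setdiff(as.character(ss$sample), colnames(m))
  if (length(unknown) > 0)
    stop(sprintf("sample sheet lists unknown sample(s): %s",
                 paste(unknown, collapse = ", ")), call. = FALSE)
  abundance_table(m, stats::setNames(as.character(ss$condition),
                                     as.character(ss$sample)))
}

#' Write an abundance table (and sample sheet) as TSV/CSV
#' @param x an `abundance_table`
#' @param path output path; `samples_path` optional companion sheet
#' @param samples_path optional sample-sheet path
#' @return invisibly, paths written
#' @export
write_abundance_table <- function(x, path, samples_path = NULL) {
  stopifnot(inherits(x, "abundance_table"))
  df <- data.frame(protein = rownames(x$abundance), x$abundance,
                   check.names = FALSE, stringsAsFactors = FALSE)
  .write_delim(df, path)
  written <- path
  if (!is.null(samples_path)) {
    .write_delim(data.frame(sample = colnames(x$abundance),
                            condition = unname(x$condition),
                            stringsAsFactors = FALSE), samples_path)
    written <- c(written, samples_path)
  }
  invisible(written)
}

# condition means of an abundance (or cq) matrix; columns = conditions
.condition_means <- function(m, cond) {
  conds <- unique(unname(cond))
  vapply(conds, function(cc) rowMeans(m[, names(cond)[cond == cc],
                                        drop = FALSE]),
         numeric(nrow(m))) |>
    matrix(nrow = nrow(m), dimnames = list(rownames(m), conds))
}
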