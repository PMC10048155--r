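#' Primer pair with transcript coordinates
#'
#' Holds a qPCR primer pair, its 1-based inclusive coordinates on the
#' transcript record, and the declared amplicon size for QC. The forward
#' start is the 5'-most product coordinate, the reverse end the 3'-most.
#'
#' @param gene_id gene symbol
#' @param forward_seq,reverse_seq primer sequences, A/C/G/T only (5' > 3')
#' @param forward_start,reverse_end 1-based inclusive product coordinates on
#'   the transcript; `forward_start < reverse_end` is required
#' @param declared_amplicon_bp declared product size in bp (optional, for QC)
#' @param annealing_temp_c annealing temperature in degrees C (optional)
#' @return an object of class `primer_pair`
#' @seealso [amplicon_length()], [read_primer_table()]
#' @export
primer_pair <- function(gene_id, forward_seq, reverse_seq, forward_start,
                        reverse_end, declared_amplicon_bp = NA_integer_,
                        annealing_temp_c = NA_real_) {
  for (s in c(forward = forward_seq, reverse = reverse_seq)) {
    if (!grepl("^[ACGT]+$", s))
      stop(sprintf("primer sequence for '%s' contains non-A/C/G/T characters",
                   gene_id), call. = FALSE)
  }
  forward_start <- as.integer(forward_start)
  reverse_end <- as.integer(reverse_end)
  if (is.na(forward_start) || is.na(reverse_end) ||
        forward_start < 1 || reverse_end < 1)
    stop("primer coordinates must be positive integers", call. = FALSE)
  if (reverse_end <= forward_start)
    stop(sprintf("'%s': reverse_end (%d) must exceed forward_start (%d)",
                 gene_id, reverse_end, forward_start), call. = FALSE)
  structure(list(gene_id = gene_id, forward_seq = forward_seq,
                 reverse_seq = reverse_seq, forward_start = forward_start,
                 reverse_end = reverse_end,
                 declared_amplicon_bp = as.integer(declared_amplicon_bp),
                 annealing_temp_c = annealing_temp_c),
            class = "primer_pair")
}

#' Amplicon length from primer coordinates
#'
#' With 1-based inclusive coordinates the product length is
#' `reverse_end - forward_start + 1`. When the pair declares an amplicon
#' size, a mismatch is flagged with a warning (the computed length is still
#' returned).
#'
#' @param p a [primer_pair()]
#' @return integer product length in bp, with attribute `matches_declared`
#'   (logical, `NA` when no size was declared)
#' @export
amplicon_length <- function(p) {
  stopifnot(inherits(p, "primer_pair"))
  len <- p$reverse_end - p$forward_start + 1L
  ok <- NA
  if (!is.na(p$declared_amplicon_bp)) {
    ok <- len == p$declared_amplicon_bp
    if (!ok)
      warning(sprintf(
        "'%s': computed amplicon %d bp differs from declared %d bp",
        p$gene_id, len, p$declared_amplicon_bp), call. = FALSE)
  }
  structure(len, matches_declared = ok)
}

#' Read a primer table and run amplicon QC
#'
#' @param path TSV/CSV with columns `gene`, `forward_seq`, `reverse_seq`,
#'   `forward_start`, `reverse_end` and optionally `declared_bp`,
#'   `annealing_temp_c`.
#' @return data.frame with one row per primer pair, the computed
#'   `amplicon_bp` and logical `matches_declared`; the `primer_pair` objects
#'   are attached as the `pairs` attribute.
#' @export
read_primer_table <- function(path) {
  df <- .read_delim(path)
  .require_cols(df, c("gene", "forward_seq", "reverse_seq",
                      "forward_start", "reverse_end"), path)
  if (!"declared_bp" %in% names(df)) df$declared_bp <- NA_integer_
  if (!"annealing_temp_c" %in% names(df)) df$annealing_temp_c <- NA_real_
  pairs <- lapply(seq_len(nrow(df)), function(i)
    primer_pair(df$gene[i], df$forward_seq[i], df$reverse_seq[i],
                df$forward_start[i], df$reverse_end[i], df$declared_bp[i],
                df$annealing_temp_c[i]))
  lens <- lapply(pairs, amplicon_length)
  out <- data.frame(gene = df$gene,
                    forward_start = as.integer(df$forward_start),
                    reverse_end = as.integer(df$reverse_end),
                    declared_bp = as.integer(df$declared_bp),
                    amplicon_bp = vapply(lens, as.integer, integer(1)),
                    matches_declared = vapply(lens, function(l)
                      attr(l, "matches_declared"), logical(1)),
                    stringsAsFactors = FALSE)
  attr(out, "pairs") <- pairs
  out
}
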