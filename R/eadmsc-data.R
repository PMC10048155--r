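#' Packaged equine ADSC candidate-panel data
#'
#' Small plain-text data shipped with the package, characterizing the
#' reference-gene candidate panel of an equine adipose-derived stem cell
#' (ADSC) differentiation experiment (standard / adipogenic / osteogenic
#' media; progenitor ADSCs vs derived adipocytes and osteoblasts):
#' `eadmsc_primer_table()` returns the nine primer pairs with transcript
#' coordinates and declared amplicon sizes; `eadmsc_rank_table()` returns
#' the per-algorithm stability ranks of the seven candidates together with
#' the published consensus values; `eadmsc_screen_rows()` returns the
#' 23-protein candidate screen (absolute differences of condition means, in
#' mean-relative-protein-abundance units, and one-way ANOVA p-values).
#'
#' @return a data.frame (see each function's description)
#' @name eadmsc_data
NULL

#' @rdname eadmsc_data
#' @export
eadmsc_primer_table <- function() {
  read_primer_table(system.file("extdata", "primers_eadmsc.tsv",
                                package = "qpcrstab", mustWork = TRUE))
}

#' @rdname eadmsc_data
#' @export
eadmsc_rank_table <- function() {
  .read_delim(system.file("extdata", "stability_ranks_eadmsc.tsv",
                          package = "qpcrstab", mustWork = TRUE))
}

#' @rdname eadmsc_data
#' @export
eadmsc_screen_rows <- function() {
  .read_delim(system.file("extdata", "proteome_screen_eadmsc.tsv",
                          package = "qpcrstab", mustWork = TRUE))
}

#' Synthetic abundance table reproducing the packaged screen differences
#'
#' Builds a 3-condition x 3-replicate protein abundance table whose
#' condition means reproduce, exactly, the packaged screen's absolute
#' differences of means (SM minus the tabulated ADSC-AD difference for AD,
#' and minus the ADSC-OB difference for OB), and whose within-condition
#' scatter is a fixed symmetric offset wide enough that one-way ANOVA finds
#' no condition effect (p near 1) for every tabulated protein. Optionally
#' two synthetic padding proteins with strong condition effects (ANOVA
#' p < 0.05) are interleaved into the ranking, emulating screen rows that
#' rank well by difference of means but fail the stability filter. The
#' replicate values are synthetic; only the differences of condition means
#' and the pass/fail side of the ANOVA filter are faithful to the packaged
#' screen.
#'
#' @param padding add the two sub-threshold padding proteins (default TRUE)
#' @return an [abundance_table()] with samples `SM_1..3`, `AD_1..3`,
#'   `OB_1..3`
#' @export
eadmsc_screen_table <- function(padding = TRUE) {
  rows <- eadmsc_screen_rows()
  n <- nrow(rows)
  ids <- rows$protein_id
  d1 <- rows$diff_adsc_ad
  d2 <- rows$diff_adsc_ob
  maxd <- pmax(d1, d2, 1)
  delta <- 40 * maxd                   # within-condition spread
  base <- 100 * maxd                   # keeps all values positive
  jitter <- c(-1, 0, 1)
  m <- matrix(NA_real_, n, 9)
  for (i in seq_len(n)) {
    means <- c(SM = base[i], AD = base[i] - d1[i], OB = base[i] - d2[i])
    m[i, ] <- rep(means, each = 3) + delta[i] * rep(jitter, 3)
  }
  if (padding) {
    # two effect-carrying proteins ranked inside the top 25 (diffs 5 and 9
    # MRPA units), zero replicate scatter: ANOVA p -> 0
    pad <- rbind(
      c(rep(1000, 3), rep(995, 3), rep(1600, 3)),
      c(rep(2000, 3), rep(1991, 3), rep(1300, 3)))
    m <- rbind(m, pad)
    ids <- c(ids, "SYNTH_PAD1", "SYNTH_PAD2")
  }
  rownames(m) <- ids
  colnames(m) <- paste(rep(c("SM", "AD", "OB"), each = 3), 1:3, sep = "_")
  abundance_table(m, stats::setNames(rep(c("SM", "AD", "OB"), each = 3),
                                     colnames(m)))
}
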