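#' Truncation geometry of a PTC within its ORF
#'
#' For a PTC at codon `k` (1-based) of an ORF of `L` amino-acid codons:
#' retained residues `k - 1`, position percent `100 (k-1) / L`, truncation
#' percent `100 (L - (k-1)) / L` (so a PTC at codon 1 removes 100% of the
#' protein), plus the spliced distance to the last exon-exon junction and
#' the NMD flag from [predict_nmd()].
#'
#' @param ptc one-row PTC call (needs `codon_index`; `dist_last_junction_nt`
#'   is recomputed from the transcript).
#' @param tx the matching `ptc_transcript`.
#' @param nmd_threshold_nt NMD rule threshold (default 50).
#' @return one-row data.frame: orf_codons, codon_index, retained_residues,
#'   position_pct, truncation_pct, dist_last_junction_nt, nmd.
#' @export
truncation_metrics <- function(ptc, tx, nmd_threshold_nt = 50L) {
  k <- ptc$codon_index
  L <- tx$orf_codons
  if (k < 1L || k > L) {
    stop(sprintf("codon index %d outside ORF of %d codons", k, L),
         call. = FALSE)
  }
  dist <- .dist_to_last_junction(tx, 3L * k)
  data.frame(
    orf_codons = L, codon_index = k, retained_residues = k - 1L,
    position_pct = 100 * (k - 1L) / L,
    truncation_pct = 100 * (L - (k - 1L)) / L,
    dist_last_junction_nt = dist,
    nmd = predict_nmd(ptc, tx, nmd_threshold_nt)
  )
}

#' Predict NMD susceptibility by the 50-nt last-junction rule
#'
#' A transcript with a premature stop is predicted to undergo
#' nonsense-mediated decay iff it has at least two exons and the PTC lies
#' strictly more than `rule_threshold_nt` nucleotides upstream (in spliced
#' mRNA coordinates, measured from the last base of the PTC codon) of the
#' final exon-exon junction. Single-exon transcripts are never flagged; a
#' PTC exactly at the threshold is not flagged (strict inequality).
#'
#' @param ptc one-row PTC call with `codon_index`.
#' @param tx the matching `ptc_transcript`.
#' @param rule_threshold_nt threshold in nucleotides (default 50).
#' @return logical.
#' @export
predict_nmd <- function(ptc, tx, rule_threshold_nt = 50L) {
  if (length(tx$exon_starts) < 2L) return(FALSE)
  dist <- .dist_to_last_junction(tx, 3L * ptc$codon_index)
  !is.na(dist) && dist > rule_threshold_nt
}

#' Annotate PTC calls with truncation and NMD metrics
#'
#' @param calls PTC call data.frame.
#' @param txdb a `ptc_txdb`.
#' @param nmd_threshold_nt NMD rule threshold (default 50).
#' @return `calls` with appended columns retained_residues, position_pct,
#'   truncation_pct, dist_last_junction_nt, nmd.
#' @export
annotate_consequences <- function(calls, txdb, nmd_threshold_nt = 50L) {
  if (nrow(calls) == 0L) return(calls)
  tx_by_id <- setNames(txdb$transcripts,
                       vapply(txdb$transcripts, `[[`, "", "tx_id"))
  mets <- lapply(seq_len(nrow(calls)), function(i) {
    truncation_metrics(calls[i, , drop = FALSE],
                       tx_by_id[[calls$tx_id[i]]], nmd_threshold_nt)
  })
  mets <- do.call(rbind, mets)
  calls$retained_residues <- mets$retained_residues
  calls$position_pct <- mets$position_pct
  calls$truncation_pct <- mets$truncation_pct
  calls$dist_last_junction_nt <- mets$dist_last_junction_nt
  calls$nmd <- mets$nmd
  calls
}

#' Summarize the truncation distribution
#'
#' Exact order statistics of truncation percentages: median, quartiles,
#' and the fraction of PTCs whose truncation exceeds each cutoff in
#' `over_pct`.
#'
#' @param truncation_pct numeric vector of truncation percentages.
#' @param over_pct cutoffs for exceedance fractions (default 20).
#' @return list with `median`, `q1`, `q3`, `n`, and `frac_over` (named
#'   vector).
#' @export
deletion_fraction_summary <- function(truncation_pct, over_pct = 20) {
  x <- truncation_pct[!is.na(truncation_pct)]
  if (length(x) == 0L) stop("no truncation values supplied", call. = FALSE)
  qs <- quantile(x, c(0.25, 0.5, 0.75), names = FALSE)
  frac <- vapply(over_pct, function(th) mean(x > th), numeric(1))
  names(frac) <- paste0("over_", over_pct)
  list(median = qs[2], q1 = qs[1], q3 = qs[3], n = length(x),
       frac_over = frac)
}
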