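#' Apply site-quality filters to variant records
#'
#' Retains a variant iff its total read depth, number of covered
#' individuals, and mean read-position fraction of variant alleles all
#' pass. The three filter semantics follow standard exome QC: depth >=
#' `min_depth`, covered individuals >= `min_covered_individuals`, and mean
#' read position within `read_pos_band` (variants clustered at read ends
#' are alignment-artifact prone). Thresholds are configurable; defaults are
#' conventional values. In strict mode a missing metric fails its filter;
#' in permissive mode it passes.
#'
#' @param variants data.frame with columns `depth`, `n_covered`,
#'   `mean_read_pos` (as from [load_variants()]).
#' @param min_depth minimum total site depth (reads).
#' @param min_covered_individuals minimum individuals with coverage; values
#'   in (0,1] are interpreted as a fraction of `n_samples`.
#' @param read_pos_band inclusive band `c(lo, hi)` for the mean
#'   read-position fraction.
#' @param n_samples total sample count (needed when
#'   `min_covered_individuals` is fractional).
#' @param strict if `TRUE` (default), missing metrics fail the filter.
#' @return list with `retained` (subset of `variants`), `retained_idx`,
#'   and `report` (data.frame of per-filter fail counts plus totals;
#'   retained + removed = input).
#' @export
apply_quality_filters <- function(variants, min_depth = 10,
                                  min_covered_individuals = 0.8,
                                  read_pos_band = c(0.1, 0.9),
                                  n_samples = NULL, strict = TRUE) {
  if (length(read_pos_band) != 2L || read_pos_band[1] > read_pos_band[2]) {
    stop("'read_pos_band' lower bound exceeds upper bound", call. = FALSE)
  }
  min_cov <- min_covered_individuals
  if (min_cov > 0 && min_cov <= 1) {
    if (is.null(n_samples)) {
      stop("fractional 'min_covered_individuals' needs 'n_samples'",
           call. = FALSE)
    }
    min_cov <- ceiling(min_cov * n_samples)
  }
  miss_pass <- !strict
  pass_or <- function(ok) ifelse(is.na(ok), miss_pass, ok)
  pass_depth <- pass_or(variants$depth >= min_depth)
  pass_cov <- pass_or(variants$n_covered >= min_cov)
  pass_rp <- pass_or(variants$mean_read_pos >= read_pos_band[1] &
                       variants$mean_read_pos <= read_pos_band[2])
  keep <- pass_depth & pass_cov & pass_rp
  report <- data.frame(
    filter = c("depth", "covered_individuals", "read_position",
               "retained", "removed", "input"),
    count = c(sum(!pass_depth), sum(!pass_cov), sum(!pass_rp),
              sum(keep), sum(!keep), nrow(variants))
  )
  list(retained = variants[keep, , drop = FALSE],
       retained_idx = which(keep), report = report)
}

#' Classify a single-nucleotide variant as a stop-gain (PTC)
#'
#' Substitutes the alt allele into the transcript's spliced CDS
#' (complemented for minus-strand transcripts) and reports a PTC call iff
#' the substitution converts an in-frame non-stop codon, upstream of the
#' native terminal stop, into TAA/TAG/TGA.
#'
#' @param variant one-row data.frame (or list) with `chrom`, `pos`, `ref`,
#'   `alt` (single nucleotides, genomic strand).
#' @param tx a `ptc_transcript`.
#' @param genome named character vector of chromosome sequences (used to
#'   verify the reference allele; `NULL` skips the check).
#' @return one-row data.frame (locus/gene/transcript, `codon_index` k
#'   1-based, `orf_codons` L, `ref_codon`, `alt_codon`,
#'   `dist_last_junction_nt` from the last base of the PTC codon to the
#'   final exon-exon junction, `NA` for single-exon transcripts), or
#'   `NULL` when the variant is not a stop-gain in this transcript.
#' @export
classify_stop_gain <- function(variant, tx, genome = NULL) {
  if (variant$chrom != tx$chrom) return(NULL)
  s <- genomic_to_spliced(tx, variant$pos)
  if (is.na(s)) return(NULL)  # outside CDS exons
  if (!is.null(genome)) {
    gbase <- substr(genome[[tx$chrom]], variant$pos, variant$pos)
    if (!identical(toupper(gbase), toupper(variant$ref))) {
      stop(sprintf(
        "reference mismatch at %s:%d (VCF ref %s, genome %s)",
        variant$chrom, variant$pos, variant$ref, gbase), call. = FALSE)
    }
  }
  ref_t <- if (tx$strand == "-") comp_base(variant$ref) else variant$ref
  alt_t <- if (tx$strand == "-") comp_base(variant$alt) else variant$alt
  cds_base <- substr(tx$cds_seq, s, s)
  if (!identical(toupper(cds_base), toupper(ref_t))) {
    stop(sprintf(
      "transcript/reference inconsistency for %s at CDS position %d",
      tx$tx_id, s), call. = FALSE)
  }
  k <- ((s - 1L) %/% 3L) + 1L
  off <- ((s - 1L) %% 3L) + 1L
  codon <- substr(tx$cds_seq, 3L * (k - 1L) + 1L, 3L * k)
  if (codon %in% STOP_CODONS) return(NULL)  # native stop: not premature
  if (k > tx$orf_codons) return(NULL)
  alt_codon <- codon
  substr(alt_codon, off, off) <- alt_t
  if (!alt_codon %in% STOP_CODONS) return(NULL)
  data.frame(
    locus_id = variant$locus_id %||% sprintf("%s_%d", variant$chrom,
                                             variant$pos),
    chrom = variant$chrom, pos = variant$pos,
    ref = variant$ref, alt = variant$alt,
    gene = tx$gene_id, tx_id = tx$tx_id, strand = tx$strand,
    codon_index = k, orf_codons = tx$orf_codons,
    ref_codon = codon, alt_codon = alt_codon,
    dist_last_junction_nt = .dist_to_last_junction(tx, 3L * k),
    stringsAsFactors = FALSE
  )
}

#' Classify all variants against a transcriptome
#'
#' Runs [classify_stop_gain()] for every variant x overlapping transcript
#' and binds the PTC calls.
#'
#' @param variants data.frame of variant records.
#' @param txdb a `ptc_txdb`.
#' @param check_reference verify VCF ref against the genome sequence.
#' @return data.frame of PTC calls (possibly 0 rows).
#' @export
classify_variants <- function(variants, txdb, check_reference = TRUE) {
  genome <- if (check_reference) txdb$genome else NULL
  calls <- list()
  for (tx in txdb$transcripts) {
    lo <- min(tx$exon_starts) + 1L
    hi <- max(tx$exon_ends)
    cand <- which(variants$chrom == tx$chrom & variants$pos >= lo &
                    variants$pos <= hi)
    for (i in cand) {
      call <- classify_stop_gain(variants[i, , drop = FALSE], tx, genome)
      if (!is.null(call)) calls[[length(calls) + 1L]] <- call
    }
  }
  if (length(calls) == 0L) {
    return(data.frame(locus_id = character(0), chrom = character(0),
                      pos = integer(0), ref = character(0),
                      alt = character(0), gene = character(0),
                      tx_id = character(0), strand = character(0),
                      codon_index = integer(0), orf_codons = integer(0),
                      ref_codon = character(0), alt_codon = character(0),
                      dist_last_junction_nt = integer(0),
                      stringsAsFactors = FALSE))
  }
  out <- do.call(rbind, calls)
  rownames(out) <- NULL
  out
}
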