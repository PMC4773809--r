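#' Transcript models
#'
#' A `ptc_transcript` is a light S3 container for one protein-coding
#' transcript: gene/transcript identifiers, chromosome, strand, exons as
#' 0-based half-open genomic intervals in genomic order, the spliced CDS
#' (mRNA sense, ATG..stop), and the ORF length in amino-acid codons
#' (`orf_codons`, excluding the terminal stop). The whole transcript is
#' treated as CDS (no UTRs).
#'
#' @param gene_id,tx_id identifiers.
#' @param chrom chromosome name.
#' @param strand "+" or "-".
#' @param exon_starts,exon_ends integer vectors, 0-based half-open, sorted
#'   in increasing genomic order, non-overlapping.
#' @param cds_seq spliced CDS sequence (mRNA sense strand).
#' @return object of class `ptc_transcript`.
#' @export
new_transcript <- function(gene_id, tx_id, chrom, strand,
                           exon_starts, exon_ends, cds_seq) {
  stopifnot(strand %in% c("+", "-"),
            length(exon_starts) == length(exon_ends),
            all(exon_ends > exon_starts),
            !is.unsorted(exon_starts, strictly = TRUE))
  widths <- exon_ends - exon_starts
  if (sum(widths) != nchar(cds_seq)) {
    stop("exon widths do not sum to spliced CDS length", call. = FALSE)
  }
  if (nchar(cds_seq) %% 3L != 0L) {
    stop("CDS length must be a multiple of 3", call. = FALSE)
  }
  codons <- split_codons(cds_seq)
  n <- length(codons)
  if (!codons[n] %in% STOP_CODONS) {
    stop("CDS must end with a stop codon", call. = FALSE)
  }
  if (any(codons[-n] %in% STOP_CODONS)) {
    stop("CDS contains an internal stop codon", call. = FALSE)
  }
  structure(list(
    gene_id = gene_id, tx_id = tx_id, chrom = chrom, strand = strand,
    exon_starts = as.integer(exon_starts), exon_ends = as.integer(exon_ends),
    cds_seq = cds_seq, orf_codons = n - 1L
  ), class = "ptc_transcript")
}

#' @export
print.ptc_transcript <- function(x, ...) {
  cat(sprintf("<ptc_transcript %s (%s) %s:%d-%d [%s] %d exons, ORF %d codons>\n",
              x$tx_id, x$gene_id, x$chrom, min(x$exon_starts),
              max(x$exon_ends), x$strand, length(x$exon_starts),
              x$orf_codons))
  invisible(x)
}

# Exon lengths in transcript (5'->3' mRNA) order.
.tx_exon_lengths <- function(tx) {
  w <- tx$exon_ends - tx$exon_starts
  if (tx$strand == "-") rev(w) else w
}

#' Map a genomic position to a spliced CDS position
#'
#' @param tx a `ptc_transcript`.
#' @param pos 1-based genomic position.
#' @return 1-based position in the spliced CDS (mRNA sense), or `NA` if the
#'   position falls outside the exons.
#' @export
genomic_to_spliced <- function(tx, pos) {
  g0 <- pos - 1L  # 0-based
  hit <- which(g0 >= tx$exon_starts & g0 < tx$exon_ends)
  if (length(hit) != 1L) return(NA_integer_)
  w <- tx$exon_ends - tx$exon_starts
  if (tx$strand == "+") {
    before <- if (hit > 1L) sum(w[seq_len(hit - 1L)]) else 0L
    as.integer(before + (g0 - tx$exon_starts[hit]) + 1L)
  } else {
    n <- length(w)
    # transcript order is reverse genomic order
    before <- if (hit < n) sum(w[seq.int(hit + 1L, n)]) else 0L
    as.integer(before + (tx$exon_ends[hit] - 1L - g0) + 1L)
  }
}

#' Map a spliced CDS position to a genomic position
#'
#' Inverse of [genomic_to_spliced()].
#'
#' @param tx a `ptc_transcript`.
#' @param s 1-based spliced CDS position.
#' @return 1-based genomic position.
#' @export
spliced_to_genomic <- function(tx, s) {
  stopifnot(s >= 1L, s <= nchar(tx$cds_seq))
  w <- tx$exon_ends - tx$exon_starts
  if (tx$strand == "+") {
    cum <- cumsum(w)
    hit <- which(s <= cum)[1L]
    before <- if (hit > 1L) cum[hit - 1L] else 0L
    as.integer(tx$exon_starts[hit] + (s - before - 1L) + 1L)
  } else {
    wr <- rev(w)  # transcript order
    cum <- cumsum(wr)
    hit_tx <- which(s <= cum)[1L]
    before <- if (hit_tx > 1L) cum[hit_tx - 1L] else 0L
    hit <- length(w) - hit_tx + 1L  # genomic index
    as.integer(tx$exon_ends[hit] - (s - before - 1L))
  }
}

#' Extract the spliced CDS of a transcript from a genome sequence
#'
#' Concatenates exon sequences in genomic order and reverse-complements for
#' minus-strand transcripts.
#'
#' @param tx a `ptc_transcript`.
#' @param genome named character vector (or `Biostrings::DNAStringSet`) of
#'   chromosome sequences.
#' @return spliced CDS string (mRNA sense).
#' @export
extract_cds <- function(tx, genome) {
  if (inherits(genome, "DNAStringSet")) {
    genome <- setNames(as.character(genome), names(genome))
  }
  chrom_seq <- genome[[tx$chrom]]
  pieces <- substring(chrom_seq, tx$exon_starts + 1L, tx$exon_ends)
  spliced <- paste(pieces, collapse = "")
  if (tx$strand == "-") revcomp(spliced) else spliced
}

#' Spliced distance from a CDS position to the last exon-exon junction
#'
#' @param tx a `ptc_transcript`.
#' @param s 1-based spliced CDS position.
#' @return junction position minus `s` in nucleotides (positive when `s`
#'   lies upstream of the last junction); `NA` for single-exon transcripts.
#' @keywords internal
.dist_to_last_junction <- function(tx, s) {
  w <- .tx_exon_lengths(tx)
  if (length(w) < 2L) return(NA_integer_)
  junction <- sum(w[-length(w)])  # spliced coordinate of last junction
  as.integer(junction - s)
}

#' Simulate protein-coding transcripts on a synthetic genome
#'
#' Generates `n_genes` transcripts on a single synthetic chromosome. Each
#' CDS starts with ATG, ends with a stop codon, has no internal stops, and
#' is split across a random number of exons; strands alternate so both are
#' represented. Coordinates follow BED conventions (0-based half-open).
#'
#' @param n_genes number of genes (one transcript each).
#' @param exons_per_gene integer interval `c(min, max)` of exon counts.
#' @param cds_codons integer interval `c(min, max)` of total CDS codons
#'   (including the terminal stop); minimum 10.
#' @param seed integer seed.
#' @param intron_range interval of intron lengths (nt).
#' @param intergenic length of spacer sequence between genes (nt).
#' @return a `ptc_txdb`: list with `transcripts` (list of
#'   `ptc_transcript`), `genome` (named character vector), `chrom`.
#' @export
simulate_transcripts <- function(n_genes, exons_per_gene = c(1L, 5L),
                                 cds_codons = c(100L, 400L), seed = 1L,
                                 intron_range = c(60L, 300L),
                                 intergenic = 200L) {
  .assert_count(n_genes, "n_genes")
  if (length(cds_codons) != 2L || cds_codons[1] > cds_codons[2]) {
    stop("'cds_codons' must be a well-ordered interval", call. = FALSE)
  }
  if (cds_codons[1] < 10L) {
    stop("'cds_codons' lower bound must be >= 10", call. = FALSE)
  }
  if (length(exons_per_gene) != 2L || exons_per_gene[1] > exons_per_gene[2] ||
      exons_per_gene[1] < 1L) {
    stop("'exons_per_gene' must be a well-ordered interval of counts",
         call. = FALSE)
  }
  set.seed(seed)
  sample1 <- function(v) v[sample.int(length(v), 1L)]  # safe for length 1
  sense <- setdiff(apply(expand.grid(DNA_BASES, DNA_BASES, DNA_BASES),
                         1L, paste, collapse = ""), STOP_CODONS)
  chrom <- "chrS"
  cursor <- 0L
  max_pieces <- (2L * exons_per_gene[2] + 1L) * n_genes + 1L
  seq_parts <- vector("list", max_pieces)  # pre-allocated pieces
  n_parts <- 0L
  add_part <- function(x) {
    n_parts <<- n_parts + 1L
    seq_parts[[n_parts]] <<- x
  }
  transcripts <- vector("list", n_genes)
  rand_dna <- function(n) {
    paste(sample(DNA_BASES, n, replace = TRUE), collapse = "")
  }
  for (g in seq_len(n_genes)) {
    add_part(rand_dna(intergenic))
    cursor <- cursor + intergenic
    n_codons <- sample1(seq.int(cds_codons[1], cds_codons[2]))
    cds <- paste0("ATG",
                  paste(sample(sense, n_codons - 2L, replace = TRUE),
                        collapse = ""),
                  sample1(STOP_CODONS))
    strand <- if (g %% 2L == 0L) "-" else "+"
    n_ex <- sample1(seq.int(exons_per_gene[1],
                            min(exons_per_gene[2], nchar(cds) %/% 3L)))
    # breakpoints in spliced coordinates; every exon >= 3 nt
    len <- nchar(cds)
    if (n_ex > 1L) {
      bps <- sort(sample(seq.int(3L, len - 3L), n_ex - 1L))
      while (any(diff(c(0L, bps, len)) < 3L)) {
        bps <- sort(sample(seq.int(3L, len - 3L), n_ex - 1L))
      }
    } else {
      bps <- integer(0)
    }
    starts_sp <- c(0L, bps)
    ends_sp <- c(bps, len)
    pieces <- substring(cds, starts_sp + 1L, ends_sp)  # transcript order
    genomic_pieces <- if (strand == "-") rev(revcomp(pieces)) else pieces
    ex_starts <- integer(length(pieces))
    ex_ends <- integer(length(pieces))
    for (i in seq_along(genomic_pieces)) {
      if (i > 1L) {
        ilen <- sample1(seq.int(intron_range[1], intron_range[2]))
        add_part(rand_dna(ilen))
        cursor <- cursor + ilen
      }
      ex_starts[i] <- cursor
      cursor <- cursor + nchar(genomic_pieces[i])
      ex_ends[i] <- cursor
      add_part(genomic_pieces[i])
    }
    transcripts[[g]] <- new_transcript(
      gene_id = sprintf("GENE%03d", g), tx_id = sprintf("TX%03d", g),
      chrom = chrom, strand = strand,
      exon_starts = ex_starts, exon_ends = ex_ends, cds_seq = cds
    )
  }
  add_part(rand_dna(intergenic))
  genome <- setNames(paste(unlist(seq_parts[seq_len(n_parts)]),
                           collapse = ""), chrom)
  structure(list(transcripts = transcripts, genome = genome, chrom = chrom),
            class = "ptc_txdb")
}

#' @export
print.ptc_txdb <- function(x, ...) {
  cat(sprintf("<ptc_txdb: %d transcripts on %s (%d nt)>\n",
              length(x$transcripts), x$chrom, nchar(x$genome[[1L]])))
  invisible(x)
}
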