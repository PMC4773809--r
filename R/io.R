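#' Write a synthetic dataset to standard file formats
#'
#' Emits a VCF 4.2 (GT genotypes; INFO keys `DP` = total read depth,
#' `NC` = individuals with coverage, `ARP` = mean read-position fraction of
#' variant alleles), a BED12 of transcripts (0-based half-open), the
#' reference FASTA, and panel / outgroup / archaic TSVs. The files
#' round-trip losslessly through [load_variants()], [read_transcripts()]
#' and the TSV readers.
#'
#' @param dataset a `ptc_dataset`.
#' @param txdb a `ptc_txdb` (optional; `NULL` skips BED/FASTA).
#' @param outgroup outgroup table data.frame (optional).
#' @param archaic archaic table data.frame (optional).
#' @param out_dir output directory (created if absent).
#' @return invisibly, a named character vector of the written paths.
#' @export
write_dataset <- function(dataset, txdb = NULL, outgroup = NULL,
                          archaic = NULL, out_dir) {
  stopifnot(inherits(dataset, "ptc_dataset"))
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  paths <- c(vcf = file.path(out_dir, "dataset.vcf"),
             panel = file.path(out_dir, "panel.tsv"))
  write_vcf(dataset, paths[["vcf"]])
  write.table(dataset$panel, paths[["panel"]], sep = "\t",
              quote = FALSE, row.names = FALSE)
  if (!is.null(txdb)) {
    paths[["bed"]] <- file.path(out_dir, "transcripts.bed")
    paths[["fasta"]] <- file.path(out_dir, "reference.fa")
    write_bed12(txdb, paths[["bed"]])
    Biostrings::writeXStringSet(
      Biostrings::DNAStringSet(txdb$genome), paths[["fasta"]])
  }
  if (!is.null(outgroup)) {
    paths[["outgroup"]] <- file.path(out_dir, "outgroup.tsv")
    write.table(outgroup, paths[["outgroup"]], sep = "\t",
                quote = FALSE, row.names = FALSE)
  }
  if (!is.null(archaic)) {
    paths[["archaic"]] <- file.path(out_dir, "archaic.tsv")
    write.table(archaic, paths[["archaic"]], sep = "\t",
                quote = FALSE, row.names = FALSE)
  }
  invisible(paths)
}

#' Write genotypes as VCF 4.2
#'
#' @param dataset a `ptc_dataset`.
#' @param path output path.
#' @return invisibly, `path`.
#' @export
write_vcf <- function(dataset, path) {
  loci <- dataset$loci
  geno <- dataset$genotypes
  gt <- matrix(c("0/0", "0/1", "1/1")[geno + 1L], nrow = nrow(geno))
  gt[is.na(geno)] <- "./."
  header <- c(
    "##fileformat=VCFv4.2",
    sprintf("##contig=<ID=%s>", unique(loci$chrom)),
    "##INFO=<ID=DP,Number=1,Type=Integer,Description=\"Total read depth at the site\">",
    "##INFO=<ID=NC,Number=1,Type=Integer,Description=\"Number of individuals with coverage at the site\">",
    "##INFO=<ID=ARP,Number=1,Type=Float,Description=\"Mean position fraction of variant alleles along a read\">",
    "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">",
    paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER", "INFO",
            "FORMAT", dataset$samples), collapse = "\t")
  )
  info <- sprintf("DP=%d;NC=%d;ARP=%g", loci$depth, loci$n_covered,
                  loci$mean_read_pos)
  body <- vapply(seq_len(nrow(loci)), function(i) {
    paste(c(loci$chrom[i], loci$pos[i], loci$locus_id[i], loci$ref[i],
            loci$alt[i], ".", "PASS", info[i], "GT", gt[, i]),
          collapse = "\t")
  }, character(1))
  writeLines(c(header, body), path)
  invisible(path)
}

#' Write transcripts as BED12
#'
#' @param txdb a `ptc_txdb`.
#' @param path output path.
#' @return invisibly, `path`.
#' @export
write_bed12 <- function(txdb, path) {
  lines <- vapply(txdb$transcripts, function(tx) {
    start <- min(tx$exon_starts)
    end <- max(tx$exon_ends)
    sizes <- tx$exon_ends - tx$exon_starts
    rel <- tx$exon_starts - start
    paste(tx$chrom, start, end, tx$tx_id, 0L, tx$strand, start, end,
          "0,0,0", length(sizes),
          paste0(paste(sizes, collapse = ","), ","),
          paste0(paste(rel, collapse = ","), ","),
          sep = "\t")
  }, character(1))
  writeLines(lines, path)
  invisible(path)
}

#' Read a population panel TSV
#'
#' Expects columns `sample_id`, `population`, `super_group` and validates
#' the many-to-one sample -> population -> super-group mapping.
#'
#' @param path panel TSV path.
#' @return data.frame with the three columns.
#' @export
read_panel <- function(path) {
  panel <- read.delim(path, stringsAsFactors = FALSE)
  need <- c("sample_id", "population", "super_group")
  if (!all(need %in% names(panel))) {
    stop("panel must have columns: ", paste(need, collapse = ", "),
         call. = FALSE)
  }
  if (anyDuplicated(panel$sample_id)) {
    stop("duplicate sample_id in panel", call. = FALSE)
  }
  pg <- unique(panel[, c("population", "super_group")])
  if (anyDuplicated(pg$population)) {
    stop("a population maps to more than one super_group", call. = FALSE)
  }
  panel
}

#' Load variants from a multi-sample VCF
#'
#' Reads a VCF (via \pkg{vcfR}), converts GT fields to alt-allele dosages,
#' splits multi-allelic sites into biallelic records (each alt evaluated
#' independently against ref), and attaches the site-quality INFO metrics.
#' Every VCF sample must be present in the panel.
#'
#' @param vcf_path VCF path.
#' @param panel_path panel TSV path (see [read_panel()]).
#' @param info_keys named character vector mapping the depth / coverage /
#'   read-position metrics to INFO keys.
#' @return list with `variants` (data.frame: locus_id, chrom, pos, ref,
#'   alt, depth, n_covered, mean_read_pos), `genotypes` (samples x records
#'   dosage matrix), `panel`, `samples`.
#' @export
load_variants <- function(vcf_path, panel_path,
                          info_keys = c(depth = "DP", covered = "NC",
                                        read_pos = "ARP")) {
  panel <- read_panel(panel_path)
  vcf <- vcfR::read.vcfR(vcf_path, verbose = FALSE)
  fix <- as.data.frame(vcfR::getFIX(vcf), stringsAsFactors = FALSE)
  gt_raw <- vcfR::extract.gt(vcf, element = "GT")
  samples <- colnames(gt_raw)
  missing_in_panel <- setdiff(samples, panel$sample_id)
  if (length(missing_in_panel) > 0) {
    stop("VCF sample(s) absent from panel: ",
         paste(missing_in_panel, collapse = ", "), call. = FALSE)
  }
  panel <- panel[match(samples, panel$sample_id), , drop = FALSE]
  rownames(panel) <- NULL

  info_get <- function(key, numeric = TRUE) {
    v <- vcfR::extract.info(vcf, element = key, as.numeric = numeric)
    if (is.null(v)) rep(NA_real_, nrow(fix)) else v
  }
  depth <- info_get(info_keys[["depth"]])
  covered <- info_get(info_keys[["covered"]])
  read_pos <- info_get(info_keys[["read_pos"]])

  rec <- list()
  dos <- list()
  for (i in seq_len(nrow(fix))) {
    alts <- strsplit(fix$ALT[i], ",", fixed = TRUE)[[1]]
    gts <- gt_raw[i, ]
    alleles <- strsplit(gts, "[/|]")
    for (j in seq_along(alts)) {
      dosage <- vapply(alleles, function(a) {
        if (length(a) == 0 || anyNA(a) || any(a == ".")) {
          return(NA_integer_)
        }
        sum(a == as.character(j))
      }, integer(1))
      rec[[length(rec) + 1L]] <- data.frame(
        locus_id = if (is.na(fix$ID[i]) || fix$ID[i] == ".")
          sprintf("%s_%s_%s", fix$CHROM[i], fix$POS[i], alts[j])
        else if (length(alts) > 1L) paste0(fix$ID[i], "_", alts[j])
        else fix$ID[i],
        chrom = fix$CHROM[i], pos = as.integer(fix$POS[i]),
        ref = fix$REF[i], alt = alts[j],
        depth = depth[i], n_covered = covered[i],
        mean_read_pos = read_pos[i], stringsAsFactors = FALSE)
      dos[[length(dos) + 1L]] <- dosage
    }
  }
  variants <- do.call(rbind, rec)
  rownames(variants) <- NULL
  genotypes <- do.call(cbind, dos)
  dimnames(genotypes) <- list(samples, variants$locus_id)
  list(variants = variants, genotypes = genotypes, panel = panel,
       samples = samples)
}

#' Read transcript models from BED12 + FASTA
#'
#' Parses BED12 via \pkg{rtracklayer}, extracts each transcript's spliced
#' CDS from the reference with [extract_cds()], and validates the ORF
#' (ATG start, single terminal stop).
#'
#' @param bed_path BED12 path.
#' @param fasta_path reference FASTA path.
#' @return a `ptc_txdb` (gene ids default to transcript names).
#' @export
read_transcripts <- function(bed_path, fasta_path) {
  gr <- rtracklayer::import(bed_path, format = "bed")
  genome_set <- Biostrings::readDNAStringSet(fasta_path)
  names(genome_set) <- sub("\\s.*$", "", names(genome_set))
  genome <- setNames(as.character(genome_set), names(genome_set))
  # extract the spliced sequence from a coordinate stub first, then let
  # new_transcript() validate widths/ORF against it
  txs <- lapply(seq_along(gr), function(i) {
    g <- gr[i]
    blocks <- IRanges::shift(gr$blocks[[i]],
                             IRanges::start(g) - 1L)
    starts0 <- IRanges::start(blocks) - 1L
    ends0 <- IRanges::end(blocks)
    tx_id <- g$name %||% sprintf("TX%03d", i)
    chrom <- as.character(GenomicRanges::seqnames(g))
    strand <- as.character(GenomicRanges::strand(g))
    stub <- structure(list(chrom = chrom, strand = strand,
                           exon_starts = starts0, exon_ends = ends0),
                      class = "ptc_transcript")
    cds <- extract_cds(stub, genome)
    new_transcript(gene_id = sub("^TX", "GENE", tx_id), tx_id = tx_id,
                   chrom = chrom, strand = strand,
                   exon_starts = starts0, exon_ends = ends0, cds_seq = cds)
  })
  structure(list(transcripts = txs, genome = genome,
                 chrom = names(genome)[1]), class = "ptc_txdb")
}

#' Read an outgroup allele TSV
#' @param path TSV with columns chrom, pos, ref, alt, chimp, gorilla,
#'   orangutan, human_ref ("." or empty = absent).
#' @return data.frame.
#' @export
read_outgroup_table <- function(path) {
  tab <- read.delim(path, stringsAsFactors = FALSE)
  need <- c("chrom", "pos", "chimp", "gorilla", "orangutan", "human_ref")
  if (!all(need %in% names(tab))) {
    stop("outgroup table must have columns: ", paste(need, collapse = ", "),
         call. = FALSE)
  }
  tab
}

#' Read an archaic allele TSV
#' @param path TSV with columns chrom, pos, alleles_neanderthal,
#'   alleles_denisovan ("." = no coverage).
#' @return data.frame.
#' @export
read_archaic_table <- function(path) {
  tab <- read.delim(path, stringsAsFactors = FALSE)
  need <- c("chrom", "pos", "alleles_neanderthal", "alleles_denisovan")
  if (!all(need %in% names(tab))) {
    stop("archaic table must have columns: ", paste(need, collapse = ", "),
         call. = FALSE)
  }
  tab
}
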