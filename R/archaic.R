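#' Virtual genotyping of PTC alleles against archaic genomes
#'
#' A PTC is "detected" in an archaic genome iff its derived allele is among
#' the alleles observed in that genome at the site; the union counts sites
#' detected in either Neanderthal or Denisovan. Sites with no archaic
#' coverage in a genome (entry ".", or absent from the table) are not
#' detectable there and are tallied separately.
#'
#' @param ptcs polarized PTC call data.frame (`chrom`, `pos`, `derived`).
#' @param archaic archaic allele table (columns chrom, pos,
#'   alleles_neanderthal, alleles_denisovan; comma-separated alleles,
#'   "." = no coverage).
#' @param denominator `"total"` (default; the full PTC set) or
#'   `"assayable"` (sites covered in at least one archaic genome).
#' @return list of class `archaic_overlap`: `n_total`, `n_assayable`,
#'   `detected_neanderthal`, `detected_denisovan`, `detected_union`,
#'   `fraction`, `denominator`, and per-site data.frame `detail`.
#' @export
overlap_fraction <- function(ptcs, archaic,
                             denominator = c("total", "assayable")) {
  denominator <- match.arg(denominator)
  key <- paste(archaic$chrom, archaic$pos)
  idx <- match(paste(ptcs$chrom, ptcs$pos), key)
  parse_alleles <- function(x) {
    if (is.na(x) || x == ".") return(NULL)  # no coverage
    toupper(strsplit(x, ",", fixed = TRUE)[[1]])
  }
  n <- nrow(ptcs)
  in_nea <- logical(n); in_den <- logical(n)
  cov_nea <- logical(n); cov_den <- logical(n)
  for (i in seq_len(n)) {
    if (is.na(idx[i])) next
    nea <- parse_alleles(archaic$alleles_neanderthal[idx[i]])
    den <- parse_alleles(archaic$alleles_denisovan[idx[i]])
    cov_nea[i] <- !is.null(nea)
    cov_den[i] <- !is.null(den)
    der <- toupper(ptcs$derived[i])
    in_nea[i] <- cov_nea[i] && der %in% nea
    in_den[i] <- cov_den[i] && der %in% den
  }
  assayable <- cov_nea | cov_den
  union_det <- in_nea | in_den
  denom_n <- if (denominator == "total") n else sum(assayable)
  fraction <- if (denom_n == 0) 0 else sum(union_det) / denom_n
  structure(list(
    n_total = n, n_assayable = sum(assayable),
    detected_neanderthal = sum(in_nea), detected_denisovan = sum(in_den),
    detected_union = sum(union_det), fraction = fraction,
    denominator = denominator,
    detail = data.frame(chrom = ptcs$chrom, pos = ptcs$pos,
                        derived = ptcs$derived, covered = assayable,
                        in_neanderthal = in_nea, in_denisovan = in_den,
                        detected = union_det, stringsAsFactors = FALSE)
  ), class = "archaic_overlap")
}

#' @export
print.archaic_overlap <- function(x, ...) {
  cat(sprintf(
    "Archaic overlap: %.1f%% (%d/%d, denominator = %s; Nea %d, Den %d)\n",
    100 * x$fraction, x$detected_union,
    if (x$denominator == "total") x$n_total else x$n_assayable,
    x$denominator, x$detected_neanderthal, x$detected_denisovan))
  invisible(x)
}
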