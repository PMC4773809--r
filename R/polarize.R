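#' Infer the ancestral allele at a site from primate outgroups
#'
#' Majority vote among the available outgroup alleles (chimpanzee, gorilla,
#' orangutan, human reference, equally weighted). At least
#' `min_informative` non-absent outgroups are required; ties, too few
#' informative genomes, or a consensus matching neither ref nor alt all
#' yield `"unresolved"` (a value, not an error — unresolved sites are
#' excluded downstream with a logged count).
#'
#' @param ref,alt the site's VCF alleles.
#' @param outgroup_alleles character vector of outgroup alleles; absent
#'   entries are `NA`, `""` or `"."`.
#' @param min_informative minimum informative outgroups (default 2).
#' @return the ancestral allele, or `"unresolved"`.
#' @export
infer_ancestral <- function(ref, alt, outgroup_alleles, min_informative = 2L) {
  og <- toupper(outgroup_alleles)
  og <- og[!is.na(og) & og != "" & og != "."]
  if (length(og) < min_informative) return("unresolved")
  tab <- sort(table(og), decreasing = TRUE)
  if (length(tab) > 1L && tab[1] == tab[2]) return("unresolved")
  consensus <- names(tab)[1]
  if (!consensus %in% c(toupper(ref), toupper(alt))) return("unresolved")
  consensus
}

#' Derived allele frequency (percent)
#'
#' `DAF = 100 * n_a / (n_A + n_a)` with `n_A` ancestral and `n_a` derived
#' allele counts; missing genotypes are excluded from both counts by the
#' callers that build the counts.
#'
#' @param n_A ancestral allele count.
#' @param n_a derived (mutated) allele count.
#' @return DAF in percent, in `[0, 100]`.
#' @export
compute_daf <- function(n_A, n_a) {
  if (any(n_A + n_a <= 0)) {
    stop("DAF undefined: no called alleles (n_A + n_a = 0)", call. = FALSE)
  }
  100 * n_a / (n_A + n_a)
}

#' Per-population ancestral/derived allele and genotype counts
#'
#' Orients dosages (alt-allele counts) by the ancestral assignment:
#' when the ancestral allele is the VCF ref, derived dosage = alt dosage;
#' when ancestral is the alt, genotype classes are swapped. Missing
#' genotypes reduce the denominators.
#'
#' @param dosages integer vector of alt-allele dosages (0/1/2, `NA`).
#' @param populations character vector parallel to `dosages`.
#' @param ancestral_is_ref logical: is the ancestral allele the VCF ref?
#' @return data.frame per population (plus a pooled `TOTAL` row):
#'   `n_AA`, `n_Aa`, `n_aa` (A = ancestral, a = derived), `n_A`, `n_a`,
#'   `n_missing`, `daf`.
#' @export
pop_allele_counts <- function(dosages, populations, ancestral_is_ref = TRUE) {
  stopifnot(length(dosages) == length(populations))
  der <- if (ancestral_is_ref) dosages else 2L - dosages
  pops <- unique(populations)
  rows <- lapply(pops, function(p) {
    d <- der[populations == p]
    miss <- sum(is.na(d))
    d <- d[!is.na(d)]
    cnt <- tabulate(d + 1L, nbins = 3L)  # dosage 0,1,2 of the derived allele
    data.frame(population = p, n_AA = cnt[1], n_Aa = cnt[2], n_aa = cnt[3],
               n_A = 2L * cnt[1] + cnt[2], n_a = cnt[2] + 2L * cnt[3],
               n_missing = miss, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  total <- data.frame(population = "TOTAL", n_AA = sum(out$n_AA),
                      n_Aa = sum(out$n_Aa), n_aa = sum(out$n_aa),
                      n_A = sum(out$n_A), n_a = sum(out$n_a),
                      n_missing = sum(out$n_missing),
                      stringsAsFactors = FALSE)
  out <- rbind(out, total)
  out$daf <- ifelse(out$n_A + out$n_a > 0,
                    100 * out$n_a / (out$n_A + out$n_a), NA_real_)
  out
}

#' Polarize PTC calls and compute per-population DAF
#'
#' Joins PTC calls with the outgroup table, infers ancestral alleles by
#' consensus, drops unresolved sites (count reported via attribute and a
#' message), and computes per-population and total derived allele
#' frequencies.
#'
#' @param calls PTC call data.frame (from [classify_variants()]).
#' @param genotypes samples x loci dosage matrix (columns named by
#'   locus_id).
#' @param panel panel data.frame.
#' @param outgroup outgroup table (columns chrom, pos, chimp, gorilla,
#'   orangutan, human_ref).
#' @param min_informative passed to [infer_ancestral()].
#' @return data.frame: the call columns plus `ancestral`, `derived`,
#'   `daf_total`, and one `daf_<population>` column per population;
#'   attribute `n_unresolved` counts excluded sites; attribute `counts` is
#'   a list of per-site [pop_allele_counts()] tables.
#' @export
polarize_calls <- function(calls, genotypes, panel, outgroup,
                           min_informative = 2L) {
  if (nrow(calls) == 0L) return(calls)
  key <- paste(outgroup$chrom, outgroup$pos)
  idx <- match(paste(calls$chrom, calls$pos), key)
  pops <- unique(panel$population)
  anc <- character(nrow(calls))
  for (i in seq_len(nrow(calls))) {
    if (is.na(idx[i])) {
      anc[i] <- "unresolved"
      next
    }
    og <- unlist(outgroup[idx[i], c("chimp", "gorilla", "orangutan",
                                    "human_ref")], use.names = FALSE)
    anc[i] <- infer_ancestral(calls$ref[i], calls$alt[i], og,
                              min_informative)
  }
  unresolved <- anc == "unresolved"
  if (any(unresolved)) {
    message(sum(unresolved), " site(s) with unresolved ancestral allele ",
            "excluded from DAF analysis")
  }
  out <- calls[!unresolved, , drop = FALSE]
  anc <- anc[!unresolved]
  out$ancestral <- anc
  out$derived <- ifelse(anc == out$ref, out$alt, out$ref)
  pop_of <- panel$population[match(rownames(genotypes), panel$sample_id)]
  counts_list <- vector("list", nrow(out))
  daf_pop <- matrix(NA_real_, nrow = nrow(out), ncol = length(pops),
                    dimnames = list(NULL, pops))
  daf_total <- numeric(nrow(out))
  for (i in seq_len(nrow(out))) {
    dos <- genotypes[, out$locus_id[i]]
    cnt <- pop_allele_counts(dos, pop_of,
                             ancestral_is_ref = anc[i] == out$ref[i])
    counts_list[[i]] <- cnt
    tot <- cnt[cnt$population == "TOTAL", ]
    daf_total[i] <- compute_daf(tot$n_A, tot$n_a)
    per <- cnt[cnt$population != "TOTAL", ]
    daf_pop[i, per$population] <- per$daf
  }
  out$daf_total <- daf_total
  for (p in pops) out[[paste0("daf_", p)]] <- daf_pop[, p]
  attr(out, "n_unresolved") <- sum(unresolved)
  attr(out, "counts") <- counts_list
  rownames(out) <- NULL
  out
}

#' Select PTCs above a total-DAF threshold
#'
#' Retains calls with pooled-cohort total DAF strictly greater than
#' `min_total_daf` (percent).
#'
#' @param ptcs polarized call data.frame with `daf_total`.
#' @param min_total_daf threshold in percent (default 1).
#' @return subset of `ptcs`.
#' @export
select_by_threshold <- function(ptcs, min_total_daf = 1) {
  ptcs[!is.na(ptcs$daf_total) & ptcs$daf_total > min_total_daf, ,
       drop = FALSE]
}

#' Aggregate variant DAFs to gene-level totals
#'
#' A gene's total DAF is the sum of its PTCs' total DAFs (and likewise per
#' population), so a gene whose individual PTCs each sit below a frequency
#' threshold can still pass at the gene level. Raw sums are returned; a
#' capped copy (at 100) is provided for reporting.
#'
#' @param ptcs polarized call data.frame (`gene`, `daf_total`, and
#'   `daf_<pop>` columns).
#' @return data.frame: gene, n_ptcs, daf_total (raw sum),
#'   daf_total_capped, plus summed `daf_<pop>` columns.
#' @export
aggregate_gene_daf <- function(ptcs) {
  stopifnot("gene" %in% names(ptcs))
  daf_cols <- grep("^daf_", names(ptcs), value = TRUE)
  genes <- unique(ptcs$gene)
  rows <- lapply(genes, function(g) {
    sub <- ptcs[ptcs$gene == g, , drop = FALSE]
    sums <- vapply(daf_cols, function(cl) sum(sub[[cl]], na.rm = TRUE),
                   numeric(1))
    cbind(data.frame(gene = g, n_ptcs = nrow(sub),
                     stringsAsFactors = FALSE),
          as.data.frame(as.list(sums)))
  })
  out <- do.call(rbind, rows)
  out$daf_total_capped <- pmin(out$daf_total, 100)
  rownames(out) <- NULL
  out
}
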