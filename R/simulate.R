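#' Simulation configuration
#'
#' Bundles and validates the parameters of the synthetic-data generator.
#' The defaults describe the study conditions the package is validated
#' under: a handful of populations with Balding-Nichols differentiation at
#' a target `F`, genotypes in Hardy-Weinberg equilibrium within each
#' population, and optional population grouping into super-groups
#' (continental-style structure).
#'
#' @param n_populations number of populations (K).
#' @param samples_per_population diploid individuals per population.
#' @param n_loci number of biallelic loci.
#' @param differentiation_F Balding-Nichols differentiation parameter,
#'   in `[0, 1)`; this is the quantity the Weir-Cockerham theta estimator
#'   targets.
#' @param ancestral_freq_range interval in (0,1) from which each locus's
#'   ancestral derived-allele frequency is drawn uniformly.
#' @param outgroup_concordance probability that an outgroup genome carries
#'   the true ancestral allele at a site.
#' @param archaic_carrier_fraction fraction of loci whose derived allele is
#'   present in at least one archaic genome.
#' @param n_groups number of super-groups populations are nested in.
#' @param group_F between-group Balding-Nichols differentiation (applied
#'   above the within-group `differentiation_F` when `n_groups > 1`).
#' @param missing_rate per-genotype missingness probability.
#' @param seed integer seed.
#' @return a validated list of class `sim_config`.
#' @export
sim_config <- function(n_populations = 4L, samples_per_population = 100L,
                       n_loci = 2000L, differentiation_F = 0.1,
                       ancestral_freq_range = c(0.01, 0.5),
                       outgroup_concordance = 1.0,
                       archaic_carrier_fraction = 0.25,
                       n_groups = 1L, group_F = 0,
                       missing_rate = 0, seed = 1L) {
  .assert_count(n_populations, "n_populations")
  .assert_count(samples_per_population, "samples_per_population")
  .assert_count(n_loci, "n_loci")
  .assert_proportion(differentiation_F, "differentiation_F", allow_one = FALSE)
  .assert_proportion(outgroup_concordance, "outgroup_concordance")
  .assert_proportion(archaic_carrier_fraction, "archaic_carrier_fraction")
  .assert_proportion(group_F, "group_F", allow_one = FALSE)
  .assert_proportion(missing_rate, "missing_rate")
  .assert_count(n_groups, "n_groups")
  if (length(ancestral_freq_range) != 2L ||
      ancestral_freq_range[1] >= ancestral_freq_range[2] ||
      ancestral_freq_range[1] <= 0 || ancestral_freq_range[2] >= 1) {
    stop("'ancestral_freq_range' must be a well-ordered interval in (0,1)",
         call. = FALSE)
  }
  if (n_groups > n_populations) {
    stop("'n_groups' cannot exceed 'n_populations'", call. = FALSE)
  }
  structure(list(
    n_populations = as.integer(n_populations),
    samples_per_population = as.integer(samples_per_population),
    n_loci = as.integer(n_loci),
    differentiation_F = differentiation_F,
    ancestral_freq_range = ancestral_freq_range,
    outgroup_concordance = outgroup_concordance,
    archaic_carrier_fraction = archaic_carrier_fraction,
    n_groups = as.integer(n_groups), group_F = group_F,
    missing_rate = missing_rate, seed = as.integer(seed)
  ), class = "sim_config")
}

# Balding-Nichols draw: population frequency around ancestral p at
# differentiation F. F = 0 degenerates to p exactly.
.bn_draw <- function(p, F) {
  if (F == 0) return(p)
  rbeta(length(p), p * (1 - F) / F, (1 - p) * (1 - F) / F)
}

#' Simulate population genotypes under the Balding-Nichols model
#'
#' For each locus an ancestral derived-allele frequency `p` is drawn
#' uniformly on `ancestral_freq_range`; each population's frequency is
#' drawn from `Beta(p(1-F)/F, (1-p)(1-F)/F)` (equal to `p` when `F = 0`),
#' and diploid genotypes are drawn as `Binomial(2, p_i)` per individual, so
#' genotypes are in Hardy-Weinberg equilibrium within populations. With
#' `n_groups > 1` a group-level frequency is first drawn at `group_F` and
#' population frequencies are nested within it, producing hierarchical
#' (continental-style) structure. True frequencies, the ancestral allele
#' and archaic carrier status are recorded in `$truth`.
#'
#' @param config a [sim_config()].
#' @return a `ptc_dataset`: list with `samples`, `panel` (data.frame:
#'   sample_id, population, super_group), `loci` (data.frame: locus_id,
#'   chrom, pos, ref, alt, depth, n_covered, mean_read_pos), `genotypes`
#'   (samples x loci integer matrix of derived-allele dosage, `NA` =
#'   missing) and `truth`.
#' @export
simulate_populations <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  set.seed(config$seed)
  K <- config$n_populations
  n <- config$samples_per_population
  L <- config$n_loci
  Fst <- config$differentiation_F

  pops <- sprintf("POP%02d", seq_len(K))
  group_of <- sprintf("GRP%d", ((seq_len(K) - 1L) %% config$n_groups) + 1L)
  samples <- as.vector(vapply(seq_len(K), function(k) {
    sprintf("%s_S%03d", pops[k], seq_len(n))
  }, character(n)))
  panel <- data.frame(
    sample_id = samples,
    population = rep(pops, each = n),
    super_group = rep(group_of, each = n),
    stringsAsFactors = FALSE
  )

  p_anc <- runif(L, config$ancestral_freq_range[1],
                 config$ancestral_freq_range[2])
  pop_freq <- matrix(NA_real_, nrow = K, ncol = L,
                     dimnames = list(pops, NULL))
  if (config$n_groups > 1L) {
    grp_freq <- matrix(NA_real_, nrow = config$n_groups, ncol = L)
    for (g in seq_len(config$n_groups)) {
      grp_freq[g, ] <- .bn_draw(p_anc, config$group_F)
    }
    for (k in seq_len(K)) {
      g <- ((k - 1L) %% config$n_groups) + 1L
      pop_freq[k, ] <- .bn_draw(grp_freq[g, ], Fst)
    }
  } else {
    for (k in seq_len(K)) pop_freq[k, ] <- .bn_draw(p_anc, Fst)
  }

  geno <- matrix(NA_integer_, nrow = K * n, ncol = L,
                 dimnames = list(samples, NULL))
  for (k in seq_len(K)) {
    rows <- seq.int((k - 1L) * n + 1L, k * n)
    geno[rows, ] <- matrix(rbinom(n * L, 2L, rep(pop_freq[k, ], each = n)),
                           nrow = n, ncol = L)
  }
  if (config$missing_rate > 0) {
    drop <- runif(length(geno)) < config$missing_rate
    geno[drop] <- NA_integer_
  }

  anc <- sample(DNA_BASES, L, replace = TRUE)
  der <- vapply(anc, function(b) sample(setdiff(DNA_BASES, b), 1L),
                character(1), USE.NAMES = FALSE)
  loci <- data.frame(
    locus_id = sprintf("L%05d", seq_len(L)),
    chrom = "chrS",
    pos = seq_len(L) * 10L,  # placeholders; inject_ptc_variants() remaps
    ref = anc, alt = der,
    depth = rpois(L, 60L) + 10L,
    n_covered = K * n,
    mean_read_pos = round(runif(L, 0.40, 0.60), 4),
    stringsAsFactors = FALSE
  )
  carrier <- rep(FALSE, L)
  n_car <- round(config$archaic_carrier_fraction * L)
  if (n_car > 0) carrier[sample.int(L, n_car)] <- TRUE

  structure(list(
    samples = samples, panel = panel, loci = loci, genotypes = geno,
    truth = list(ancestral = anc, derived = der, p_ancestral = p_anc,
                 pop_freq = pop_freq, archaic_carrier = carrier,
                 ptc_table = NULL),
    config = config
  ), class = "ptc_dataset")
}

#' @export
print.ptc_dataset <- function(x, ...) {
  cat(sprintf("<ptc_dataset: %d samples, %d populations, %d loci>\n",
              length(x$samples), length(unique(x$panel$population)),
              nrow(x$loci)))
  invisible(x)
}

# Enumerate single-nucleotide substitutions of codon `cod` (positions
# 1..3) that produce a stop codon. Returns data.frame(offset, from, to).
.stop_mutations <- function(cod) {
  out <- list()
  for (off in 1:3) {
    from <- substr(cod, off, off)
    for (to in setdiff(DNA_BASES, from)) {
      mut <- cod
      substr(mut, off, off) <- to
      if (mut %in% STOP_CODONS) {
        out[[length(out) + 1L]] <- data.frame(offset = off, from = from,
                                              to = to,
                                              stringsAsFactors = FALSE)
      }
    }
  }
  if (length(out) == 0L) return(NULL)
  do.call(rbind, out)
}

# Single-nucleotide substitutions of `cod` that do NOT produce a stop.
.nonstop_mutations <- function(cod) {
  out <- list()
  for (off in 1:3) {
    from <- substr(cod, off, off)
    for (to in setdiff(DNA_BASES, from)) {
      mut <- cod
      substr(mut, off, off) <- to
      if (!mut %in% STOP_CODONS) {
        out[[length(out) + 1L]] <- data.frame(offset = off, from = from,
                                              to = to,
                                              stringsAsFactors = FALSE)
      }
    }
  }
  do.call(rbind, out)
}

#' Place stop-gain and decoy variants on synthetic transcripts
#'
#' Maps the abstract loci of a simulated dataset onto genomic positions of
#' a synthetic transcriptome. A configurable fraction of loci become
#' genuine stop-gains (single substitutions converting an in-frame sense
#' codon, upstream of the native stop, into TAA/TAG/TGA); the rest become
#' decoy SNVs (synonymous/missense) so downstream classification has true
#' negatives. The dataset's `truth$ptc_table` records
#' (locus, transcript, codon index) for every injected PTC. Reference
#' alleles are taken as ancestral; the injected substitution is the derived
#' allele whose population frequencies were simulated.
#'
#' @param txdb a `ptc_txdb` from [simulate_transcripts()].
#' @param dataset a `ptc_dataset` from [simulate_populations()].
#' @param placement `"random"`, or an integer vector of codon indices
#'   (recycled over PTC loci) at which to place PTCs.
#' @param decoy_ratio decoys per PTC (default 1: half the loci are PTCs).
#' @param seed integer seed.
#' @return the updated `ptc_dataset` (loci remapped, `truth$ptc_table`
#'   filled).
#' @export
inject_ptc_variants <- function(txdb, dataset, placement = "random",
                                decoy_ratio = 1, seed = 1L) {
  stopifnot(inherits(txdb, "ptc_txdb"), inherits(dataset, "ptc_dataset"))
  set.seed(seed)
  L <- nrow(dataset$loci)
  n_ptc <- ceiling(L / (1 + decoy_ratio))
  is_ptc <- rep(FALSE, L)
  is_ptc[seq_len(n_ptc)] <- TRUE
  is_ptc <- sample(is_ptc)

  txs <- txdb$transcripts
  used_pos <- new.env(hash = TRUE)
  ptc_rows <- list()
  loci <- dataset$loci
  loci$gene <- NA_character_
  explicit <- is.numeric(placement)
  ptc_counter <- 0L

  for (i in seq_len(L)) {
    placed <- FALSE
    for (attempt in 1:200) {
      tx <- txs[[sample.int(length(txs), 1L)]]
      codons <- split_codons(tx$cds_seq)
      if (is_ptc[i]) {
        ptc_counter_try <- ptc_counter + 1L
        if (explicit) {
          k <- placement[((ptc_counter_try - 1L) %% length(placement)) + 1L]
          if (k < 1L || k > tx$orf_codons) next
        } else {
          k <- sample.int(tx$orf_codons, 1L)
        }
        muts <- .stop_mutations(codons[k])
        if (is.null(muts)) {
          if (explicit) {
            stop(sprintf("codon %d of %s (%s) is not mutable to a stop",
                         k, tx$tx_id, codons[k]), call. = FALSE)
          }
          next
        }
      } else {
        # decoys anywhere in the ORF, excluding the native stop codon and
        # excluding stop-creating changes
        k <- sample.int(tx$orf_codons, 1L)
        muts <- .nonstop_mutations(codons[k])
        if (k == 1L) {  # keep the start codon intact for decoys
          next
        }
      }
      m <- muts[sample.int(nrow(muts), 1L), ]
      s <- 3L * (k - 1L) + m$offset
      gpos <- spliced_to_genomic(tx, s)
      key <- as.character(gpos)
      if (!is.null(used_pos[[key]])) next
      used_pos[[key]] <- TRUE
      on_minus <- tx$strand == "-"
      ref <- if (on_minus) comp_base(m$from) else m$from
      alt <- if (on_minus) comp_base(m$to) else m$to
      loci$chrom[i] <- tx$chrom
      loci$pos[i] <- gpos
      loci$ref[i] <- ref
      loci$alt[i] <- alt
      loci$gene[i] <- tx$gene_id
      if (is_ptc[i]) {
        ptc_counter <- ptc_counter + 1L
        ptc_rows[[length(ptc_rows) + 1L]] <- data.frame(
          locus_id = loci$locus_id[i], tx_id = tx$tx_id,
          gene = tx$gene_id, codon_index = k, strand = tx$strand,
          pos = gpos, ref = ref, alt = alt, stringsAsFactors = FALSE)
      }
      placed <- TRUE
      break
    }
    if (!placed) {
      stop("failed to place variant; transcriptome too small for n_loci",
           call. = FALSE)
    }
  }
  ord <- order(loci$pos)
  perm <- ord  # keep loci sorted by position; permute genotype columns too
  dataset$loci <- loci[perm, , drop = FALSE]
  rownames(dataset$loci) <- NULL
  dataset$genotypes <- dataset$genotypes[, perm, drop = FALSE]
  dataset$truth$ancestral <- dataset$loci$ref
  dataset$truth$derived <- dataset$loci$alt
  dataset$truth$p_ancestral <- dataset$truth$p_ancestral[perm]
  dataset$truth$pop_freq <- dataset$truth$pop_freq[, perm, drop = FALSE]
  dataset$truth$archaic_carrier <- dataset$truth$archaic_carrier[perm]
  tt <- do.call(rbind, ptc_rows)
  dataset$truth$ptc_table <- tt[order(tt$pos), , drop = FALSE]
  rownames(dataset$truth$ptc_table) <- NULL
  dataset
}

#' Simulate a primate outgroup allele table
#'
#' Each outgroup genome (chimpanzee, gorilla, orangutan) carries the true
#' ancestral allele with probability `concordance`, otherwise the derived
#' allele. The human reference column reports the dataset's VCF ref allele.
#'
#' @param dataset a `ptc_dataset` with truth ancestral alleles.
#' @param concordance per-genome ancestral concordance probability.
#' @param seed integer seed.
#' @return data.frame: chrom, pos, ref, alt, chimp, gorilla, orangutan,
#'   human_ref.
#' @export
simulate_outgroup_alleles <- function(dataset, concordance = 1.0, seed = 1L) {
  stopifnot(inherits(dataset, "ptc_dataset"))
  .assert_proportion(concordance, "concordance")
  set.seed(seed)
  L <- nrow(dataset$loci)
  anc <- dataset$truth$ancestral
  der <- dataset$truth$derived
  draw <- function() ifelse(runif(L) < concordance, anc, der)
  data.frame(
    chrom = dataset$loci$chrom, pos = dataset$loci$pos,
    ref = dataset$loci$ref, alt = dataset$loci$alt,
    chimp = draw(), gorilla = draw(), orangutan = draw(),
    human_ref = dataset$loci$ref,
    stringsAsFactors = FALSE
  )
}

#' Simulate an archaic (Neanderthal/Denisovan) allele table
#'
#' At the truth-designated carrier loci the derived allele is present in at
#' least one archaic genome (Neanderthal, Denisovan, or both, at random);
#' elsewhere both genomes carry only the ancestral allele. `coverage_rate`
#' introduces no-coverage sites (written as ".").
#'
#' @param dataset a `ptc_dataset` (carrier status is taken from
#'   `truth$archaic_carrier`).
#' @param seed integer seed.
#' @param coverage_rate probability a genome has coverage at a site.
#' @return data.frame: chrom, pos, alleles_neanderthal, alleles_denisovan
#'   (comma-separated alleles; "." = no coverage).
#' @export
simulate_archaic_calls <- function(dataset, seed = 1L, coverage_rate = 1.0) {
  stopifnot(inherits(dataset, "ptc_dataset"))
  .assert_proportion(coverage_rate, "coverage_rate")
  set.seed(seed)
  L <- nrow(dataset$loci)
  anc <- dataset$truth$ancestral
  der <- dataset$truth$derived
  carrier <- dataset$truth$archaic_carrier
  which_genome <- sample(1:3, L, replace = TRUE)  # 1=nea, 2=den, 3=both
  nea <- ifelse(carrier & which_genome != 2L, paste(anc, der, sep = ","), anc)
  den <- ifelse(carrier & which_genome != 1L, paste(anc, der, sep = ","), anc)
  nea[runif(L) >= coverage_rate] <- "."
  den[runif(L) >= coverage_rate] <- "."
  # a carrier locus must stay detectable in at least one covered genome
  lost <- carrier & nea == "." & den == "."
  if (any(lost)) {
    nea[lost] <- paste(anc[lost], der[lost], sep = ",")
  }
  data.frame(
    chrom = dataset$loci$chrom, pos = dataset$loci$pos,
    alleles_neanderthal = nea, alleles_denisovan = den,
    stringsAsFactors = FALSE
  )
}
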