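test_that("sim_config validates its inputs", {
  expect_error(sim_config(n_populations = 0), "count")
  expect_error(sim_config(differentiation_F = 1), "proportion")
  expect_error(sim_config(ancestral_freq_range = c(0.5, 0.1)), "interval")
  expect_error(sim_config(n_groups = 5, n_populations = 3), "exceed")
})

test_that("Balding-Nichols generator matches its model", {
  # F = 0 degenerates: every population frequency equals the ancestral p
  cfg0 <- sim_config(n_populations = 3, samples_per_population = 10,
                     n_loci = 50, differentiation_F = 0, seed = 9)
  ds0 <- simulate_populations(cfg0)
  for (k in 1:3) {
    expect_equal(unname(ds0$truth$pop_freq[k, ]), ds0$truth$p_ancestral)
  }

  # seeded runs are byte-identical
  cfg <- sim_config(n_populations = 2, samples_per_population = 15,
                    n_loci = 40, differentiation_F = 0.2, seed = 123)
  expect_identical(simulate_populations(cfg), simulate_populations(cfg))

  # emitted genotype frequencies converge to truth p_i (n = 500, 3 SE)
  cfgn <- sim_config(n_populations = 1, samples_per_population = 500,
                     n_loci = 60, differentiation_F = 0.1, seed = 77)
  dsn <- simulate_populations(cfgn)
  phat <- colMeans(dsn$genotypes) / 2
  p <- dsn$truth$pop_freq[1, ]
  se <- sqrt(p * (1 - p) / (2 * 500))
  expect_true(all(abs(phat - p) <= 3 * se + 1e-12))

  # genotype matrix dimensions and dosage domain
  expect_equal(dim(dsn$genotypes), c(500, 60))
  expect_true(all(dsn$genotypes %in% 0:2))
})

test_that("missing-genotype injection respects the configured rate", {
  cfg <- sim_config(n_populations = 2, samples_per_population = 100,
                    n_loci = 100, missing_rate = 0.1, seed = 5)
  ds <- simulate_populations(cfg)
  rate <- mean(is.na(ds$genotypes))
  expect_gt(rate, 0.08)
  expect_lt(rate, 0.12)
})

test_that("simulated transcripts have valid ORFs on both strands", {
  txdb <- simulate_transcripts(20, exons_per_gene = c(1, 6),
                               cds_codons = c(20, 120), seed = 31)
  expect_length(txdb$transcripts, 20)
  strands <- vapply(txdb$transcripts, `[[`, "", "strand")
  expect_setequal(unique(strands), c("+", "-"))
  for (tx in txdb$transcripts) {
    # translation oracle: exactly one stop, at the end
    aa <- as.character(Biostrings::translate(Biostrings::DNAString(tx$cds_seq)))
    expect_identical(substr(aa, nchar(aa), nchar(aa)), "*")
    expect_equal(length(gregexpr("\\*", aa)[[1]]), 1L)
    expect_identical(substr(tx$cds_seq, 1, 3), "ATG")
    # exon boundaries consistent with spliced length
    expect_equal(sum(tx$exon_ends - tx$exon_starts), nchar(tx$cds_seq))
    # independent extraction oracle via Biostrings
    chr <- Biostrings::DNAString(txdb$genome[[tx$chrom]])
    pieces <- Biostrings::DNAStringSet(chr,
                                       start = tx$exon_starts + 1L,
                                       end = tx$exon_ends)
    spliced <- do.call(Biostrings::xscat, as.list(pieces))
    if (tx$strand == "-") {
      spliced <- Biostrings::reverseComplement(spliced)
    }
    expect_identical(as.character(spliced), tx$cds_seq)
  }
})

test_that("single-exon minimal transcript is 30 nt for 10 codons", {
  txdb <- simulate_transcripts(1, exons_per_gene = c(1, 1),
                               cds_codons = c(10, 10), seed = 2)
  tx <- txdb$transcripts[[1]]
  expect_equal(nchar(tx$cds_seq), 30)
  expect_length(tx$exon_starts, 1)
  expect_equal(tx$orf_codons, 9)
})

test_that("coordinate mapping round-trips on both strands", {
  txdb <- simulate_transcripts(6, exons_per_gene = c(2, 5),
                               cds_codons = c(20, 60), seed = 8)
  for (tx in txdb$transcripts) {
    for (s in c(1L, 2L, nchar(tx$cds_seq) %/% 2L, nchar(tx$cds_seq))) {
      g <- spliced_to_genomic(tx, s)
      expect_equal(genomic_to_spliced(tx, g), s)
    }
    # intronic position maps to NA
    if (length(tx$exon_starts) > 1) {
      intron_pos <- tx$exon_ends[1] + 1L  # first base after exon 1 (0-based end)
      expect_true(is.na(genomic_to_spliced(tx, intron_pos + 1L)) ||
                    intron_pos >= tx$exon_starts[2])
    }
  }
})

test_that("injected PTCs are genuine stop-gains and decoys are not", {
  run <- make_small_run(n_loci = 80, seed = 13)
  tt <- run$ds$truth$ptc_table
  expect_equal(nrow(tt), 40)  # decoy_ratio 1:1
  genome <- run$txdb$genome
  tx_by_id <- setNames(run$txdb$transcripts,
                       vapply(run$txdb$transcripts, `[[`, "", "tx_id"))
  for (i in seq_len(nrow(tt))) {
    tx <- tx_by_id[[tt$tx_id[i]]]
    call <- classify_stop_gain(
      list(chrom = tx$chrom, pos = tt$pos[i], ref = tt$ref[i],
           alt = tt$alt[i]), tx, genome)
    expect_false(is.null(call))
    expect_equal(call$codon_index, tt$codon_index[i])
  }
  # all loci have the simulated ancestral allele as VCF ref
  expect_identical(run$ds$truth$ancestral, run$ds$loci$ref)
})

test_that("explicit placement at codon 1 yields zero retained residues", {
  txdb <- simulate_transcripts(5, cds_codons = c(50, 80), seed = 3)
  cfg <- sim_config(n_populations = 2, samples_per_population = 5,
                    n_loci = 2, seed = 3)
  ds <- simulate_populations(cfg)
  # codon 1 is always ATG, which is >= 2 substitutions away from any stop,
  # so explicit placement there must raise a placement error
  expect_error(
    inject_ptc_variants(txdb, ds, placement = 1L, seed = 3),
    "not mutable")
})

test_that("outgroup and archaic simulators honor their rates", {
  run <- make_small_run(n_loci = 60, seed = 21, concordance = 1)
  # concordance 1: all outgroup genomes carry the ancestral allele
  expect_identical(run$og$chimp, run$ds$truth$ancestral)
  expect_identical(run$og$gorilla, run$ds$truth$ancestral)
  expect_identical(run$og$orangutan, run$ds$truth$ancestral)

  # carrier_fraction 0 -> archaic table never carries the derived allele
  run0 <- make_small_run(n_loci = 40, seed = 22, carrier_fraction = 0)
  der <- run0$ds$truth$derived
  has_der <- mapply(function(a, d) d %in% strsplit(a, ",")[[1]],
                    run0$ar$alleles_neanderthal, der) |
    mapply(function(a, d) d %in% strsplit(a, ",")[[1]],
           run0$ar$alleles_denisovan, der)
  expect_false(any(has_der))
})

test_that("write/read round trip preserves genotypes, panel and metrics", {
  run <- make_small_run(n_loci = 50, seed = 55)
  lv <- load_variants(run$paths[["vcf"]], run$paths[["panel"]])
  expect_identical(dimnames(lv$genotypes)[[1]], run$ds$samples)
  expect_equal(unname(lv$genotypes), unname(run$ds$genotypes))
  expect_identical(lv$variants$pos, run$ds$loci$pos)
  expect_identical(lv$variants$ref, run$ds$loci$ref)
  expect_identical(lv$variants$alt, run$ds$loci$alt)
  expect_equal(lv$variants$depth, run$ds$loci$depth)
  expect_equal(lv$variants$mean_read_pos, run$ds$loci$mean_read_pos)
  expect_identical(lv$panel$population, run$ds$panel$population)

  panel <- read_panel(run$paths[["panel"]])
  expect_equal(nrow(panel), 60)
  expect_length(unique(panel$population), 3)

  txdb2 <- read_transcripts(run$paths[["bed"]], run$paths[["fasta"]])
  for (i in seq_along(run$txdb$transcripts)) {
    expect_identical(txdb2$transcripts[[i]]$cds_seq,
                     run$txdb$transcripts[[i]]$cds_seq)
    expect_identical(txdb2$transcripts[[i]]$strand,
                     run$txdb$transcripts[[i]]$strand)
  }
})
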