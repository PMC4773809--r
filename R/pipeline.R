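#' Pipeline configuration
#'
#' Builds and validates the configuration driving [run_pipeline()]. Either
#' supply input paths (`vcf`, `bed`, `fasta`, `panel`, `outgroup`,
#' `archaic`) or set `simulate = TRUE` to generate inputs with the
#' synthetic-data module first.
#'
#' @param inputs named list of input paths (ignored when `simulate`).
#' @param simulate generate synthetic inputs in `out_dir/inputs`.
#' @param sim a [sim_config()] used when `simulate = TRUE`.
#' @param min_depth,min_covered_individuals,read_pos_band site-quality
#'   filter thresholds (see [apply_quality_filters()]).
#' @param daf_threshold total-DAF selection threshold in percent.
#' @param nmd_threshold_nt NMD rule threshold.
#' @param bootstrap_B,bootstrap_level bootstrap replicates / CI level for
#'   theta (B = 0 disables).
#' @param outlier_residual_threshold,outlier_percentile outlier rules.
#' @param archaic_denominator `"total"` or `"assayable"`.
#' @param genome_wide_ptc_rate reporting constant: the genome-wide average
#'   PTC allele frequency (percent) used as a reference line in reports.
#' @param seed integer seed.
#' @param out_dir output directory.
#' @return list of class `pipeline_config`.
#' @export
pipeline_config <- function(inputs = list(), simulate = FALSE,
                            sim = sim_config(),
                            min_depth = 10,
                            min_covered_individuals = 0.8,
                            read_pos_band = c(0.1, 0.9),
                            daf_threshold = 1,
                            nmd_threshold_nt = 50L,
                            bootstrap_B = 0L, bootstrap_level = 0.95,
                            outlier_residual_threshold = 2,
                            outlier_percentile = 0.95,
                            archaic_denominator = "total",
                            genome_wide_ptc_rate = 0.16,
                            seed = 1L, out_dir = tempfile("ptc_run_")) {
  if (!simulate) {
    need <- c("vcf", "bed", "fasta", "panel", "outgroup", "archaic")
    missing <- setdiff(need, names(inputs))
    if (length(missing) > 0) {
      stop("missing input path(s): ", paste(missing, collapse = ", "),
           call. = FALSE)
    }
  }
  structure(list(
    inputs = inputs, simulate = simulate, sim = sim,
    min_depth = min_depth,
    min_covered_individuals = min_covered_individuals,
    read_pos_band = read_pos_band, daf_threshold = daf_threshold,
    nmd_threshold_nt = nmd_threshold_nt,
    bootstrap_B = bootstrap_B, bootstrap_level = bootstrap_level,
    outlier_residual_threshold = outlier_residual_threshold,
    outlier_percentile = outlier_percentile,
    archaic_denominator = archaic_denominator,
    genome_wide_ptc_rate = genome_wide_ptc_rate,
    seed = as.integer(seed), out_dir = out_dir
  ), class = "pipeline_config")
}

#' Read a pipeline configuration from YAML
#'
#' Top-level keys mirror the arguments of [pipeline_config()]; the `sim`
#' block mirrors [sim_config()].
#'
#' @param path YAML file.
#' @return a `pipeline_config`.
#' @export
read_pipeline_config <- function(path) {
  y <- yaml::read_yaml(path)
  sim_args <- y$sim %||% list()
  y$sim <- NULL
  args <- y
  args$sim <- do.call(sim_config, sim_args)
  do.call(pipeline_config, args)
}

.write_tsv <- function(df, path) {
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  path
}

#' Run the full PTC analysis pipeline
#'
#' Stages, in order: (optional) simulate inputs; load + quality-filter
#' variants; classify stop-gains against transcript ORFs; polarize with
#' the outgroup table and compute DAFs; select by the DAF threshold;
#' annotate truncation/NMD; per-locus differentiation statistics and HWE;
#' outlier regression; structure (DAF matrix, PCA, HCA dendrogram, group
#' summaries); archaic overlap. Each stage writes a TSV under
#' `config$out_dir`; a JSON manifest records input checksums, seeds, stage
#' row counts and the package version. Deterministic given the config.
#'
#' @param config a `pipeline_config`.
#' @return invisibly, the manifest (list); side effect: files under
#'   `config$out_dir`.
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "pipeline_config"))
  out_dir <- config$out_dir
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  manifest <- list(version = as.character(packageVersion("ptcpopgen")),
                   seed = config$seed, stages = list())
  log_stage <- function(name, n) {
    manifest$stages[[name]] <<- n
    message(sprintf("[%s] %s: %s rows", format(Sys.time(), "%H:%M:%S"),
                    name, paste(n, collapse = "/")))
  }

  inputs <- config$inputs
  if (config$simulate) {
    sim <- config$sim
    txdb <- simulate_transcripts(
      n_genes = max(20L, ceiling(sim$n_loci / 40L)),
      seed = sim$seed)
    ds <- simulate_populations(sim)
    ds <- inject_ptc_variants(txdb, ds, seed = sim$seed)
    og <- simulate_outgroup_alleles(ds, sim$outgroup_concordance,
                                    seed = sim$seed)
    ar <- simulate_archaic_calls(ds, seed = sim$seed)
    inputs <- as.list(write_dataset(ds, txdb, og, ar,
                                    file.path(out_dir, "inputs")))
    log_stage("simulate", c(length(ds$samples), nrow(ds$loci)))
  }

  manifest$input_md5 <- vapply(inputs, function(p)
    unname(tools::md5sum(p)), character(1))

  loaded <- load_variants(inputs$vcf, inputs$panel)
  txdb <- read_transcripts(inputs$bed, inputs$fasta)
  outgroup <- read_outgroup_table(inputs$outgroup)
  archaic <- read_archaic_table(inputs$archaic)
  log_stage("load", nrow(loaded$variants))

  filt <- apply_quality_filters(
    loaded$variants, min_depth = config$min_depth,
    min_covered_individuals = config$min_covered_individuals,
    read_pos_band = config$read_pos_band,
    n_samples = length(loaded$samples))
  .write_tsv(filt$report, file.path(out_dir, "filter_report.tsv"))
  log_stage("filter", c(nrow(filt$retained),
                        nrow(loaded$variants) - nrow(filt$retained)))

  calls <- classify_variants(filt$retained, txdb)
  .write_tsv(calls, file.path(out_dir, "ptc_calls.tsv"))
  log_stage("classify", nrow(calls))

  geno <- loaded$genotypes[, calls$locus_id, drop = FALSE]
  ptcs <- polarize_calls(calls, geno, loaded$panel, outgroup)
  log_stage("polarize", c(nrow(ptcs), attr(ptcs, "n_unresolved")))

  selected <- select_by_threshold(ptcs, config$daf_threshold)
  log_stage("daf_threshold", nrow(selected))

  selected <- annotate_consequences(selected, txdb,
                                    config$nmd_threshold_nt)
  .write_tsv(selected, file.path(out_dir, "ptc_annotated.tsv"))
  log_stage("annotate", nrow(selected))

  gene_daf <- aggregate_gene_daf(selected)
  .write_tsv(gene_daf, file.path(out_dir, "gene_daf.tsv"))

  pop_of <- loaded$panel$population
  sel_geno <- loaded$genotypes[, selected$locus_id, drop = FALSE]
  # orient to derived dosage before differentiation/HWE
  flip <- selected$derived != selected$alt
  if (any(flip)) {
    sel_geno[, flip] <- 2L - sel_geno[, flip]
  }
  stats_tab <- differentiation_stats(
    sel_geno, pop_of, bootstrap_B = config$bootstrap_B,
    level = config$bootstrap_level, seed = config$seed)
  hwe_p <- vapply(seq_len(ncol(sel_geno)), function(j) {
    spec <- genotype_spectrum(sel_geno[, j], pop_of)
    tot <- spec["TOTAL", ]
    hwe_exact_test(tot[1], tot[2], tot[3])$p_value
  }, numeric(1))
  stats_tab$hwe_p <- hwe_p
  stats_tab$daf_total <- selected$daf_total
  .write_tsv(stats_tab, file.path(out_dir, "locus_stats.tsv"))
  log_stage("stats", nrow(stats_tab))

  outl <- regress_outliers(stats_tab$daf_total / 100, stats_tab$theta,
                           config$outlier_residual_threshold,
                           config$outlier_percentile)
  outl_tab <- data.frame(locus_id = stats_tab$locus_id,
                         theta = stats_tab$theta,
                         daf_total = stats_tab$daf_total,
                         std_residual = outl$std_residual,
                         outlier = outl$outlier,
                         above_percentile = outl$above_percentile)
  .write_tsv(outl_tab, file.path(out_dir, "outliers.tsv"))
  log_stage("outliers", sum(outl$outlier, na.rm = TRUE))

  m <- daf_matrix(selected, loaded$panel)
  structure_ok <- nrow(m) >= 2L && ncol(m) >= 2L
  if (structure_ok) {
    pca <- pca_structure(m)
    .write_tsv(data.frame(population = rownames(pca$scores),
                          pca$scores, check.names = FALSE),
               file.path(out_dir, "pca_scores.tsv"))
    hc <- hca_structure(m)
    write_dendrogram_newick(hc, file.path(out_dir, "dendrogram.nwk"))
    group_map <- setNames(loaded$panel$super_group,
                          loaded$panel$population)
    group_map <- group_map[!duplicated(names(group_map))]
    gs <- group_summaries(m, group_map)
    .write_tsv(gs, file.path(out_dir, "group_summaries.tsv"))
    log_stage("structure", nrow(m))
  }

  ov <- overlap_fraction(selected, archaic,
                         denominator = config$archaic_denominator)
  .write_tsv(ov$detail, file.path(out_dir, "archaic_overlap.tsv"))
  manifest$archaic_fraction <- ov$fraction
  log_stage("archaic", ov$detected_union)

  manifest$genome_wide_ptc_rate <- config$genome_wide_ptc_rate
  manifest$config <- config[setdiff(names(config), "inputs")]
  manifest$config$inputs <- inputs
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, force = TRUE,
                       pretty = TRUE)
  invisible(manifest)
}
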