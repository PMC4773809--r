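#' Differentiation outliers by regression residuals and percentiles
#'
#' Ordinary least squares of per-locus F_ST on a predictor (DAF or
#' heterozygosity). Loci with internally studentized (leverage-corrected)
#' residuals above +2 are flagged as outliers (one-sided: only unusually
#' high F_ST counts). An independent flag marks loci strictly above the
#' 95th percentile of raw F_ST (linear-interpolation percentile).
#'
#' @param x per-locus predictor values.
#' @param y per-locus F_ST values.
#' @param residual_threshold studentized-residual threshold (default +2).
#' @param percentile percentile for the raw-F_ST rule (default 0.95).
#' @return list of class `outlier_report`: `slope`, `intercept`,
#'   `residual_sd`, `std_residual` (NA where x or y missing),
#'   `outlier` (residual rule), `above_percentile`, `percentile_value`,
#'   `n_used`. With constant `x` the regression fields are `NA` and only
#'   percentile flags are computed.
#' @export
regress_outliers <- function(x, y, residual_threshold = 2,
                             percentile = 0.95) {
  stopifnot(length(x) == length(y))
  ok <- !is.na(x) & !is.na(y)
  n_ok <- sum(ok)
  pct_val <- quantile(y[!is.na(y)], percentile, names = FALSE)  # type 7
  above_pct <- !is.na(y) & y > pct_val
  std_res <- rep(NA_real_, length(y))
  if (n_ok >= 3L && sd(x[ok]) > 0) {
    fit <- lm(y[ok] ~ x[ok])
    res <- unname(resid(fit))
    res_sd <- sqrt(sum(res^2) / (n_ok - 2))
    # essentially perfect fit: residuals are numerical noise, no outliers
    if (res_sd <= 1e-10 * max(sd(y[ok]), mean(abs(y[ok])), .Machine$double.eps)) {
      std_res[ok] <- 0
    } else {
      std_res[ok] <- rstandard(fit)
    }
    slope <- unname(coef(fit)[2])
    intercept <- unname(coef(fit)[1])
  } else {
    if (n_ok >= 3L) warning("constant predictor: regression undefined")
    slope <- intercept <- res_sd <- NA_real_
  }
  structure(list(
    slope = slope, intercept = intercept, residual_sd = res_sd,
    std_residual = std_res,
    outlier = !is.na(std_res) & std_res > residual_threshold,
    above_percentile = above_pct, percentile_value = pct_val,
    n_used = n_ok), class = "outlier_report")
}

#' Population x variant DAF matrix
#'
#' @param ptcs polarized call data.frame with `daf_<population>` columns.
#' @param panel panel data.frame (defines row order by first appearance).
#' @return matrix populations x variants (percent DAF); unobserved entries
#'   are 0 with the mask recorded in attribute `missing_mask`.
#' @export
daf_matrix <- function(ptcs, panel) {
  pops <- unique(panel$population)
  cols <- paste0("daf_", pops)
  missing_cols <- setdiff(cols, names(ptcs))
  if (length(missing_cols) > 0) {
    stop("missing per-population DAF columns: ",
         paste(missing_cols, collapse = ", "), call. = FALSE)
  }
  m <- t(as.matrix(ptcs[, cols, drop = FALSE]))
  rownames(m) <- pops
  colnames(m) <- ptcs$locus_id
  mask <- is.na(m)
  m[mask] <- 0
  attr(m, "missing_mask") <- mask
  m
}

#' PCA of the population DAF matrix
#'
#' Principal components on the column-centered (not scaled: DAFs share
#' units) populations x variants matrix, populations as observations.
#'
#' @param m populations x variants matrix.
#' @return list: `scores` (populations x PCs), `loadings`,
#'   `variance_explained` (fractions, non-increasing).
#' @export
pca_structure <- function(m) {
  if (nrow(m) < 2L || ncol(m) < 2L) {
    stop("need >= 2 populations and >= 2 variants", call. = FALSE)
  }
  if (all(apply(m, 2, sd) == 0)) stop("degenerate (constant) matrix",
                                      call. = FALSE)
  pc <- prcomp(m, center = TRUE, scale. = FALSE)
  list(scores = pc$x, loadings = pc$rotation,
       variance_explained = pc$sdev^2 / sum(pc$sdev^2))
}

#' Hierarchical clustering of populations
#'
#' Average-linkage (UPGMA) clustering on Euclidean distances between
#' population DAF profiles.
#'
#' @param m populations x variants matrix.
#' @return an `hclust` object (leaves = populations).
#' @export
hca_structure <- function(m) {
  if (nrow(m) < 2L) stop("need >= 2 populations", call. = FALSE)
  hclust(dist(m, method = "euclidean"), method = "average")
}

#' Export a population dendrogram as Newick
#'
#' @param hc an `hclust` from [hca_structure()].
#' @param path output file.
#' @return invisibly, `path`.
#' @export
write_dendrogram_newick <- function(hc, path) {
  ape::write.tree(ape::as.phylo(hc), file = path)
  invisible(path)
}

#' Per-group distribution summaries of DAF
#'
#' Pools the per-variant DAFs of each group's populations and reports
#' exact order statistics (median, first and third quartiles).
#'
#' @param m populations x variants DAF matrix.
#' @param group_map named character vector population -> group.
#' @return data.frame: group, n_values, q1, median, q3. Empty groups are
#'   excluded with a warning.
#' @export
group_summaries <- function(m, group_map) {
  missing_pops <- setdiff(rownames(m), names(group_map))
  if (length(missing_pops) > 0) {
    stop("population(s) without group assignment: ",
         paste(missing_pops, collapse = ", "), call. = FALSE)
  }
  groups <- unique(unname(group_map[rownames(m)]))
  rows <- lapply(groups, function(g) {
    pops <- rownames(m)[group_map[rownames(m)] == g]
    vals <- as.vector(m[pops, , drop = FALSE])
    vals <- vals[!is.na(vals)]
    if (length(vals) == 0L) {
      warning("group '", g, "' has no values; excluded")
      return(NULL)
    }
    qs <- quantile(vals, c(0.25, 0.5, 0.75), names = FALSE)
    data.frame(group = g, n_values = length(vals), q1 = qs[1],
               median = qs[2], q3 = qs[3], stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Per-category, per-population total DAF
#'
#' Sums per-population gene DAFs over the member genes of each functional
#' category (olfaction, keratins, ...). Sums are intentionally uncapped and
#' may exceed 100%. Unmapped genes go to `"unclustered"`; a gene mapped to
#' a label outside `vocabulary` (when supplied) is an error.
#'
#' @param gene_daf data.frame from [aggregate_gene_daf()] (`gene`,
#'   `daf_total` and `daf_<pop>` columns).
#' @param category_map named character vector gene -> category.
#' @param vocabulary optional closed set of allowed category labels.
#' @return data.frame: category, n_genes, summed `daf_*` columns, with a
#'   `GRAND_TOTAL` row per population appended.
#' @export
category_daf <- function(gene_daf, category_map, vocabulary = NULL) {
  cat_of <- unname(category_map[gene_daf$gene])
  cat_of[is.na(cat_of)] <- "unclustered"
  if (!is.null(vocabulary)) {
    bad <- !cat_of %in% c(vocabulary, "unclustered")
    if (any(bad)) {
      stop("gene(s) mapped outside the category vocabulary: ",
           paste(gene_daf$gene[bad], collapse = ", "), call. = FALSE)
    }
  }
  daf_cols <- grep("^daf_", names(gene_daf), value = TRUE)
  daf_cols <- setdiff(daf_cols, "daf_total_capped")
  cats <- unique(cat_of)
  rows <- lapply(cats, function(cl) {
    sub <- gene_daf[cat_of == cl, , drop = FALSE]
    sums <- vapply(daf_cols, function(x) sum(sub[[x]], na.rm = TRUE),
                   numeric(1))
    cbind(data.frame(category = cl, n_genes = nrow(sub),
                     stringsAsFactors = FALSE),
          as.data.frame(as.list(sums)))
  })
  out <- do.call(rbind, rows)
  grand <- cbind(data.frame(category = "GRAND_TOTAL",
                            n_genes = nrow(gene_daf),
                            stringsAsFactors = FALSE),
                 as.data.frame(as.list(
                   vapply(daf_cols, function(x) sum(gene_daf[[x]],
                                                    na.rm = TRUE),
                          numeric(1)))))
  out <- rbind(out, grand)
  rownames(out) <- NULL
  out
}
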