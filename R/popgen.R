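#' Per-population genotype spectrum at a locus
#'
#' Counts ancestral homozygotes, heterozygotes and derived homozygotes per
#' population (missing genotypes excluded) and pools them.
#'
#' @param dosages integer vector of derived-allele dosages (0/1/2, `NA`).
#' @param populations character vector parallel to `dosages`.
#' @return matrix (populations + "TOTAL") x (n_AA, n_Aa, n_aa).
#' @export
genotype_spectrum <- function(dosages, populations) {
  pops <- unique(populations)
  m <- t(vapply(pops, function(p) {
    d <- dosages[populations == p]
    d <- d[!is.na(d)]
    tabulate(d + 1L, nbins = 3L)
  }, integer(3)))
  m <- rbind(m, colSums(m))
  dimnames(m) <- list(c(pops, "TOTAL"), c("n_AA", "n_Aa", "n_aa"))
  m
}

#' Exact test of Hardy-Weinberg equilibrium
#'
#' Conditional on the observed allele counts, enumerates all genotype
#' tables (heterozygote counts of matching parity), computes their exact
#' probabilities, and sums the probabilities of tables as probable or less
#' probable than the observed one (the standard biallelic exact HWE test).
#' Expected genotype frequencies `(p^2, 2pq, q^2)` are computed from the
#' observed allele frequencies.
#'
#' @param n_AA,n_Aa,n_aa observed genotype counts.
#' @return list of class `hwe_result`: observed counts, `p` (ancestral/
#'   first-allele frequency), `q`, `expected` frequencies, `expected_counts`,
#'   and `p_value`.
#' @export
hwe_exact_test <- function(n_AA, n_Aa, n_aa) {
  n <- n_AA + n_Aa + n_aa
  if (n < 1L) stop("no genotypes supplied", call. = FALSE)
  nA <- 2L * n_AA + n_Aa
  na <- 2L * n_aa + n_Aa
  p <- nA / (2 * n)
  q <- 1 - p
  expected <- c(AA = p^2, Aa = 2 * p * q, aa = q^2)

  rare <- min(nA, na)
  # heterozygote counts share the parity of the rare allele count
  hets <- seq.int(rare %% 2L, rare, by = 2L)
  logp <- vapply(hets, function(h) {
    hom_rare <- (rare - h) / 2
    hom_common <- n - h - hom_rare
    lfactorial(n) - lfactorial(hom_rare) - lfactorial(h) -
      lfactorial(hom_common) + h * log(2) +
      lfactorial(nA) + lfactorial(na) - lfactorial(2L * n)
  }, numeric(1))
  prob <- exp(logp - max(logp))
  prob <- prob / sum(prob)
  obs_prob <- prob[match(n_Aa, hets)]
  p_value <- min(1, sum(prob[prob <= obs_prob * (1 + 1e-7)]))
  structure(list(observed = c(AA = n_AA, Aa = n_Aa, aa = n_aa),
                 p = p, q = q, expected = expected,
                 expected_counts = expected * n, p_value = p_value),
            class = "hwe_result")
}

#' @export
print.hwe_result <- function(x, ...) {
  cat(sprintf("HWE exact test: obs (%d/%d/%d), q = %.4f, p-value = %.4g\n",
              x$observed[1], x$observed[2], x$observed[3], x$q, x$p_value))
  invisible(x)
}

# derived-allele frequency, observed-het fraction and sample size per
# population from a genotype-count matrix (rows pops, cols nAA,nAa,naa)
.counts_to_freq <- function(counts) {
  counts <- as.matrix(counts)
  n <- rowSums(counts)
  list(n = n,
       p = (counts[, 2] + 2 * counts[, 3]) / (2 * n),
       h = counts[, 2] / n)
}

#' Observed and expected heterozygosity per population
#'
#' `H_obs` is the heterozygote fraction; `H_exp` is the unbiased gene
#' diversity `(2n/(2n-1)) * 2 p q` (Nei's small-sample correction). The
#' pooled `H_exp` is computed the same way from pooled allele counts.
#'
#' @param counts matrix/data.frame, rows = populations, columns
#'   `n_AA`, `n_Aa`, `n_aa`. Populations with no genotyped individuals are
#'   dropped with a warning.
#' @return list with `per_pop` (data.frame: population, n, H_obs, H_exp)
#'   and `pooled_H_exp`.
#' @export
heterozygosity <- function(counts) {
  counts <- as.matrix(counts)
  n <- rowSums(counts)
  if (any(n == 0)) {
    warning("dropping population(s) with no genotyped individuals")
    counts <- counts[n > 0, , drop = FALSE]
    n <- n[n > 0]
  }
  f <- .counts_to_freq(counts)
  h_exp <- (2 * f$n / (2 * f$n - 1)) * 2 * f$p * (1 - f$p)
  pooled <- colSums(counts)
  np <- sum(pooled)
  pp <- (pooled[2] + 2 * pooled[3]) / (2 * np)
  pooled_h <- (2 * np / (2 * np - 1)) * 2 * pp * (1 - pp)
  list(per_pop = data.frame(
    population = rownames(counts) %||% as.character(seq_along(n)),
    n = f$n, H_obs = f$h, H_exp = h_exp, stringsAsFactors = FALSE),
    pooled_H_exp = unname(pooled_h))
}

#' Weir-Cockerham theta (F_ST) for one biallelic locus
#'
#' Moment estimator from the published diploid variance components:
#' `a` (among populations), `b` (among individuals within populations) and
#' `c` (within individuals); `theta = a / (a + b + c)`. Negative estimates
#' are reported as such (not truncated). Returns `NA` when the locus is
#' globally monomorphic (`a + b + c = 0`).
#'
#' @param counts matrix/data.frame, rows = populations (>= 2 with >= 1
#'   genotyped diploid), columns `n_AA`, `n_Aa`, `n_aa`.
#' @return list: `theta`, `a`, `b`, `c`.
#' @export
weir_cockerham_theta <- function(counts) {
  counts <- as.matrix(counts)
  counts <- counts[rowSums(counts) > 0, , drop = FALSE]
  r <- nrow(counts)
  if (r < 2L) stop("need >= 2 populations with data", call. = FALSE)
  f <- .counts_to_freq(counts)
  n <- f$n; p <- f$p; h <- f$h
  N <- sum(n)
  nbar <- N / r
  nc <- (N - sum(n^2) / N) / (r - 1)
  pbar <- sum(n * p) / N
  s2 <- sum(n * (p - pbar)^2) / ((r - 1) * nbar)
  hbar <- sum(n * h) / N
  a <- (nbar / nc) *
    (s2 - (1 / (nbar - 1)) *
       (pbar * (1 - pbar) - ((r - 1) / r) * s2 - hbar / 4))
  b <- (nbar / (nbar - 1)) *
    (pbar * (1 - pbar) - ((r - 1) / r) * s2 -
       ((2 * nbar - 1) / (4 * nbar)) * hbar)
  cc <- hbar / 2
  denom <- a + b + cc
  theta <- if (denom == 0) NA_real_ else a / denom
  list(theta = theta, a = a, b = b, c = cc)
}

#' Weir-Cockerham components for many loci at once
#'
#' Vectorized version of [weir_cockerham_theta()] over a dosage matrix.
#'
#' @param genotypes samples x loci matrix of derived-allele dosage.
#' @param populations population label per sample (rows).
#' @return data.frame per locus: a, b, c, theta (NA where globally
#'   monomorphic), plus `theta_global` attribute (ratio of summed
#'   components over loci, Weir & Cockerham's multi-locus combination).
#' @export
wc_theta_loci <- function(genotypes, populations) {
  pops <- unique(populations)
  r <- length(pops)
  L <- ncol(genotypes)
  n_mat <- matrix(0, r, L); p_mat <- matrix(0, r, L); h_mat <- matrix(0, r, L)
  for (k in seq_len(r)) {
    g <- genotypes[populations == pops[k], , drop = FALSE]
    n_k <- colSums(!is.na(g))
    n_mat[k, ] <- n_k
    p_mat[k, ] <- colSums(g, na.rm = TRUE) / (2 * n_k)
    h_mat[k, ] <- colSums(g == 1L, na.rm = TRUE) / n_k
  }
  N <- colSums(n_mat)
  nbar <- N / r
  nc <- (N - colSums(n_mat^2) / N) / (r - 1)
  pbar <- colSums(n_mat * p_mat) / N
  s2 <- colSums(n_mat * (p_mat - rep(pbar, each = r))^2) / ((r - 1) * nbar)
  hbar <- colSums(n_mat * h_mat) / N
  a <- (nbar / nc) *
    (s2 - (1 / (nbar - 1)) *
       (pbar * (1 - pbar) - ((r - 1) / r) * s2 - hbar / 4))
  b <- (nbar / (nbar - 1)) *
    (pbar * (1 - pbar) - ((r - 1) / r) * s2 -
       ((2 * nbar - 1) / (4 * nbar)) * hbar)
  cc <- hbar / 2
  denom <- a + b + cc
  theta <- ifelse(denom == 0, NA_real_, a / denom)
  out <- data.frame(a = a, b = b, c = cc, theta = theta)
  attr(out, "theta_global") <- sum(a[denom != 0]) / sum(denom[denom != 0])
  out
}

#' Nei G_ST, Hedrick's G'_ST and Jost's D for one biallelic locus
#'
#' With k populations: `G_ST = (H_T - H_S) / H_T`,
#' `G'_ST = G_ST (k - 1 + H_S) / ((k - 1)(1 - H_S))` (Hedrick) and
#' `D = (k/(k-1)) (H_T - H_S) / (1 - H_S)` (Jost). With
#' `corrected = TRUE` (default), `H_S` is the unweighted mean of
#' per-population unbiased gene diversities `(2n_i/(2n_i-1)) 2 p_i q_i`
#' and `H_T = 1 - pbar^2 - qbar^2 + H_S/(2 k ntilde)` with `pbar` the
#' unweighted mean frequency and `ntilde` the harmonic mean sample size
#' (Nei-Chesser-style small-sample correction). With `corrected = FALSE`
#' the plug-in forms `H_S = mean(2 p_i q_i)`, `H_T = 2 pbar qbar` are used,
#' for which the closed-form identities (identical populations give exactly
#' 0; fixed alternate alleles give exactly 1) hold.
#'
#' @param counts matrix/data.frame, rows = populations, columns
#'   `n_AA`, `n_Aa`, `n_aa`.
#' @param corrected use sample-size-corrected H_S/H_T (default `TRUE`).
#' @return list: `H_S`, `H_T`, `G_ST`, `Gp_ST`, `D`, `k`. Undefined values
#'   (`H_T = 0` for G_ST; `H_S = 1` for G'_ST/D) are `NA`.
#' @export
gst_family <- function(counts, corrected = TRUE) {
  counts <- as.matrix(counts)
  counts <- counts[rowSums(counts) > 0, , drop = FALSE]
  k <- nrow(counts)
  if (k < 2L) stop("need >= 2 populations with data", call. = FALSE)
  f <- .counts_to_freq(counts)
  p <- f$p; n <- f$n
  pbar <- mean(p)
  if (corrected) {
    ntilde <- k / sum(1 / n)
    hs_i <- (2 * n / (2 * n - 1)) * 2 * p * (1 - p)
    H_S <- mean(hs_i)
    H_T <- 1 - pbar^2 - (1 - pbar)^2 + H_S / (2 * k * ntilde)
  } else {
    H_S <- mean(2 * p * (1 - p))
    H_T <- 2 * pbar * (1 - pbar)
  }
  G_ST <- if (H_T == 0) NA_real_ else (H_T - H_S) / H_T
  if (H_S >= 1) {
    Gp_ST <- NA_real_
    D <- NA_real_
  } else {
    Gp_ST <- if (is.na(G_ST)) NA_real_ else
      G_ST * (k - 1 + H_S) / ((k - 1) * (1 - H_S))
    D <- (k / (k - 1)) * (H_T - H_S) / (1 - H_S)
  }
  list(H_S = H_S, H_T = H_T, G_ST = G_ST, Gp_ST = Gp_ST, D = D, k = k)
}

#' Per-locus differentiation statistics with optional bootstrap CIs
#'
#' Combines [weir_cockerham_theta()] and [gst_family()] per locus, with
#' percentile bootstrap confidence intervals for theta obtained by
#' resampling individuals with replacement within populations.
#'
#' @param genotypes samples x loci dosage matrix (loci in columns, named).
#' @param populations population label per sample.
#' @param bootstrap_B bootstrap replicates (0 disables; the paper-scale
#'   default elsewhere is 1000).
#' @param level CI level (default 0.95).
#' @param seed integer seed for the bootstrap.
#' @param corrected passed to [gst_family()].
#' @return data.frame per locus: locus_id, a, b, c, theta, H_S, H_T, G_ST,
#'   Gp_ST, D, and (if bootstrapped) theta_ci_lo / theta_ci_hi.
#' @export
differentiation_stats <- function(genotypes, populations, bootstrap_B = 0L,
                                  level = 0.95, seed = 1L,
                                  corrected = TRUE) {
  wc <- wc_theta_loci(genotypes, populations)
  pops <- unique(populations)
  L <- ncol(genotypes)
  gmat <- matrix(NA_real_, L, 5,
                 dimnames = list(NULL, c("H_S", "H_T", "G_ST", "Gp_ST", "D")))
  for (j in seq_len(L)) {
    spec <- genotype_spectrum(genotypes[, j], populations)
    g <- gst_family(spec[pops, , drop = FALSE], corrected = corrected)
    gmat[j, ] <- c(g$H_S, g$H_T, g$G_ST, g$Gp_ST, g$D)
  }
  out <- data.frame(
    locus_id = colnames(genotypes) %||% sprintf("L%05d", seq_len(L)),
    a = wc$a, b = wc$b, c = wc$c, theta = wc$theta,
    H_S = gmat[, "H_S"], H_T = gmat[, "H_T"], G_ST = gmat[, "G_ST"],
    Gp_ST = gmat[, "Gp_ST"], D = gmat[, "D"],
    stringsAsFactors = FALSE)
  if (bootstrap_B > 0L) {
    lo <- numeric(L); hi <- numeric(L)
    for (j in seq_len(L)) {
      ci <- bootstrap_ci(
        function(dos_by_pop) {
          spec <- t(vapply(dos_by_pop, function(d) {
            tabulate(d[!is.na(d)] + 1L, nbins = 3L)
          }, integer(3)))
          weir_cockerham_theta(spec)$theta
        },
        split(genotypes[, j], populations)[pops],
        B = bootstrap_B, level = level, seed = seed + j)
      lo[j] <- ci[1]; hi[j] <- ci[2]
    }
    out$theta_ci_lo <- lo
    out$theta_ci_hi <- hi
  }
  attr(out, "theta_global") <- attr(wc, "theta_global")
  out
}

#' Percentile bootstrap CI by resampling individuals within populations
#'
#' Resamples individuals with replacement within each population,
#' recomputes the statistic `B` times, and returns the percentile interval
#' at `level`. Seeded and reproducible. If the statistic is undefined
#' (`NA`) in more than half of the replicates the interval is reported as
#' missing with a diagnostic attribute.
#'
#' @param statistic function taking a list of per-population dosage
#'   vectors and returning one number.
#' @param pop_dosages named list of per-population dosage vectors.
#' @param B bootstrap replicates (default 1000).
#' @param level confidence level (default 0.95).
#' @param seed integer seed.
#' @return numeric `c(lo, hi)`; attributes `B_effective` (non-NA
#'   replicates) and, when missing, `reason`.
#' @export
bootstrap_ci <- function(statistic, pop_dosages, B = 1000L, level = 0.95,
                         seed = 1L) {
  stopifnot(B >= 1L)
  set.seed(seed)
  reps <- vapply(seq_len(B), function(b) {
    res <- lapply(pop_dosages, function(d) d[sample.int(length(d),
                                                        replace = TRUE)])
    as.numeric(statistic(res))
  }, numeric(1))
  ok <- !is.na(reps)
  if (mean(ok) < 0.5) {
    out <- c(NA_real_, NA_real_)
    attr(out, "B_effective") <- sum(ok)
    attr(out, "reason") <- "statistic undefined in > 50% of replicates"
    return(out)
  }
  alpha <- (1 - level) / 2
  out <- unname(quantile(reps[ok], c(alpha, 1 - alpha)))
  attr(out, "B_effective") <- sum(ok)
  out
}

#' Paired Wilcoxon signed-rank comparison of two DAF cohorts
#'
#' Two-sided signed-rank test on per-variant DAF pairs (e.g., the same
#' variants measured in two cohorts). For `n <= 16` informative (non-zero)
#' differences the exact permutation distribution of the positive-rank sum
#' is enumerated (handling tied ranks); larger samples use the normal
#' approximation with tie correction via [stats::wilcox.test()]. All pairs
#' tied gives p = 1 with a warning.
#'
#' @param x,y paired numeric vectors (e.g., DAF per variant in cohorts A
#'   and B).
#' @param exact_max largest n for exact enumeration (default 16).
#' @return list: `p_value`, `n_informative`, `method`.
#' @export
compare_cohort_daf <- function(x, y, exact_max = 16L) {
  stopifnot(length(x) == length(y))
  d <- x - y
  d <- d[!is.na(d)]
  d <- d[d != 0]
  n <- length(d)
  if (n == 0L) {
    warning("all pairs tied; p-value = 1")
    return(list(p_value = 1, n_informative = 0L, method = "degenerate"))
  }
  if (n <= exact_max) {
    rk <- rank(abs(d))
    W_obs <- sum(rk[d > 0])
    # enumerate all 2^n sign assignments of the ranked magnitudes
    signs <- as.matrix(expand.grid(rep(list(c(0, 1)), n)))
    W_all <- as.vector(signs %*% rk)
    p_le <- mean(W_all <= W_obs + 1e-9)
    p_ge <- mean(W_all >= W_obs - 1e-9)
    p <- min(1, 2 * min(p_le, p_ge))
    return(list(p_value = p, n_informative = n, method = "exact"))
  }
  wt <- suppressWarnings(wilcox.test(d, exact = FALSE, correct = TRUE))
  list(p_value = wt$p.value, n_informative = n,
       method = "normal_approximation")
}
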