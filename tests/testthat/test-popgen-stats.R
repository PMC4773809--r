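test_that("genotype spectrum counts and pools correctly", {
  dos <- c(0L, 0L, 1L, 2L, NA, 1L)
  pops <- c("A", "A", "A", "B", "B", "B")
  spec <- genotype_spectrum(dos, pops)
  expect_equal(unname(spec["A", ]), c(2L, 1L, 0L))
  expect_equal(unname(spec["B", ]), c(0L, 1L, 1L))
  expect_equal(unname(spec["TOTAL", ]), c(2L, 2L, 1L))
  # all missing -> all-zero counts
  spec0 <- genotype_spectrum(c(NA_integer_, NA_integer_), c("A", "A"))
  expect_equal(sum(spec0), 0)
})

test_that("HWE expected frequencies follow p^2, 2pq, q^2", {
  # q = 0.2 via counts (64, 32, 4) of n = 100
  h <- hwe_exact_test(64, 32, 4)
  expect_equal(h$q, 0.2)
  expect_equal(unname(h$expected), c(0.64, 0.32, 0.04))
  # perfect HWE at p = q = 0.5
  h2 <- hwe_exact_test(25, 50, 25)
  expect_gt(h2$p_value, 0.9)
  # grossly out of HWE: all homozygotes
  h3 <- hwe_exact_test(50, 0, 50)
  expect_lt(h3$p_value, 1e-10)
  expect_error(hwe_exact_test(0, 0, 0), "no genotypes")
})

test_that("HWE exact p-values agree with a permutation oracle", {
  set.seed(606)
  cases <- list(c(8, 4, 3), c(20, 5, 1), c(10, 10, 10), c(40, 8, 2))
  for (cs in cases) {
    ours <- hwe_exact_test(cs[1], cs[2], cs[3])$p_value
    # oracle: randomly pair the 2n alleles into genotypes, build the
    # empirical distribution of heterozygote counts conditional on the
    # allele counts, and sum probabilities of tables as or less probable
    n <- sum(cs)
    alleles <- rep(c(0L, 1L), c(2 * cs[1] + cs[2], 2 * cs[3] + cs[2]))
    B <- 20000
    hets <- vapply(seq_len(B), function(b) {
      a <- sample(alleles)
      sum(a[seq(1, 2 * n, 2)] != a[seq(2, 2 * n, 2)])
    }, integer(1))
    tab <- table(hets) / B
    p_obs <- tab[as.character(cs[2])]
    oracle <- sum(tab[tab <= p_obs + 1e-9])
    expect_lt(abs(ours - oracle), 0.02)
  }
})

test_that("HWE exact test is conservative under the null", {
  set.seed(99)
  n <- 200
  q <- runif(600, 0.05, 0.5)
  rej <- vapply(q, function(qi) {
    g <- rbinom(n, 2, qi)
    cnt <- tabulate(g + 1L, nbins = 3)
    hwe_exact_test(cnt[1], cnt[2], cnt[3])$p_value < 0.05
  }, logical(1))
  mc_se <- sqrt(0.05 * 0.95 / 600)
  expect_lte(mean(rej), 0.05 + 3 * mc_se)
})

test_that("heterozygosity estimators match direct computation", {
  # monomorphic population
  het0 <- heterozygosity(matrix(c(10, 0, 0), 1, dimnames = list("P", NULL)))
  expect_equal(het0$per_pop$H_obs, 0)
  expect_equal(het0$per_pop$H_exp, 0)
  # n = 1 heterozygote: small-sample correction gives H_exp = 1
  het1 <- heterozygosity(matrix(c(0, 1, 0), 1, dimnames = list("P", NULL)))
  expect_equal(het1$per_pop$H_obs, 1)
  expect_equal(het1$per_pop$H_exp, 1)
  # random fixtures against 1 - sum(p_i^2) with correction
  set.seed(12)
  for (r in 1:20) {
    cnt <- matrix(rpois(6, 20) + 1, 2)
    het <- heterozygosity(cnt)
    for (i in 1:2) {
      n <- sum(cnt[i, ])
      p <- (cnt[i, 2] + 2 * cnt[i, 3]) / (2 * n)
      direct <- (2 * n / (2 * n - 1)) * (1 - p^2 - (1 - p)^2)
      expect_equal(het$per_pop$H_exp[i], direct)
      expect_equal(het$per_pop$H_obs[i], cnt[i, 2] / n)
    }
  }
})

test_that("Weir-Cockerham theta matches an independent ANOVA oracle", {
  set.seed(71)
  for (r in 1:25) {
    sizes <- sample(3:40, sample(2:5, 1), replace = TRUE)
    dos_by_pop <- lapply(sizes, function(n) {
      p <- runif(1, 0.05, 0.95)
      rbinom(n, 2, p)
    })
    cnt <- dosage_to_counts(dos_by_pop)
    if (sum(cnt[, 2]) + sum(cnt[, 3]) == 0 || all(cnt[, 1] + cnt[, 2] == 0))
      next
    ours <- weir_cockerham_theta(cnt)
    oracle <- wc_theta_anova(dos_by_pop)
    if (is.na(ours$theta)) {
      expect_true(is.na(oracle) || !is.finite(oracle))
    } else {
      expect_equal(ours$theta, oracle, tolerance = 1e-12)
    }
  }
})

test_that("theta closed forms: fixed differences give 1, monomorphic NA", {
  # two pops fixed for alternate alleles, unequal sizes
  fixed <- rbind(c(5, 0, 0), c(0, 0, 9))
  wc <- weir_cockerham_theta(fixed)
  expect_equal(wc$theta, 1)
  expect_equal(wc$b, 0)
  expect_equal(wc$c, 0)
  # globally monomorphic -> undefined
  mono <- rbind(c(5, 0, 0), c(7, 0, 0))
  expect_true(is.na(weir_cockerham_theta(mono)$theta))
  expect_error(weir_cockerham_theta(rbind(c(5, 0, 0))), ">= 2 populations")
})

test_that("vectorized multi-locus theta equals the per-locus function", {
  set.seed(14)
  pops <- rep(c("P1", "P2", "P3"), times = c(12, 20, 9))
  geno <- vapply(1:30, function(j) {
    p <- runif(3, 0.1, 0.9)
    unlist(mapply(function(n, pi) rbinom(n, 2, pi), c(12, 20, 9), p,
                  SIMPLIFY = FALSE))
  }, integer(41))
  multi <- wc_theta_loci(geno, pops)
  for (j in c(1, 7, 30)) {
    single <- weir_cockerham_theta(
      dosage_to_counts(split(geno[, j], pops)[c("P1", "P2", "P3")]))
    expect_equal(multi$theta[j], single$theta, tolerance = 1e-12)
    expect_equal(multi$a[j], single$a, tolerance = 1e-12)
  }
  # missing genotypes are excluded, not counted as reference
  geno_na <- geno
  geno_na[1:3, 1] <- NA
  multi_na <- wc_theta_loci(geno_na, pops)
  single_na <- weir_cockerham_theta(
    dosage_to_counts(split(geno_na[, 1], pops)[c("P1", "P2", "P3")]))
  expect_equal(multi_na$theta[1], single_na$theta, tolerance = 1e-12)
})

test_that("G_ST family closed forms and hand-computed case", {
  # two pops fixed for different alleles (uncorrected and corrected)
  fixed <- rbind(c(5, 0, 0), c(0, 0, 5))
  for (corr in c(TRUE, FALSE)) {
    g <- gst_family(fixed, corrected = corr)
    expect_equal(g$H_S, 0)
    expect_equal(g$H_T, 0.5)
    expect_equal(g$G_ST, 1)
    expect_equal(g$Gp_ST, 1)
    expect_equal(g$D, 1)
  }
  # identical populations: plug-in forms give exactly zero
  same <- rbind(c(4, 4, 2), c(4, 4, 2))
  g0 <- gst_family(same, corrected = FALSE)
  expect_equal(g0$G_ST, 0)
  expect_equal(g0$Gp_ST, 0)
  expect_equal(g0$D, 0)

  # 3 pops with target freqs (0.2, 0.5, 0.8), n = 50 each;
  # direct evaluation of the closed forms (uncorrected) from the counts
  mk <- function(p, n = 50) {
    het <- round(n * 2 * p * (1 - p))
    hom_d <- round(n * p^2)
    c(n - het - hom_d, het, hom_d)
  }
  cnt <- rbind(mk(0.2), mk(0.5), mk(0.8))
  g3 <- gst_family(cnt, corrected = FALSE)
  p <- (cnt[, 2] + 2 * cnt[, 3]) / (2 * rowSums(cnt))
  HS <- mean(2 * p * (1 - p))
  HT <- 2 * mean(p) * (1 - mean(p))
  expect_equal(g3$H_S, HS)
  expect_equal(g3$H_T, HT)
  expect_equal(g3$G_ST, (HT - HS) / HT)
  expect_equal(g3$Gp_ST, ((HT - HS) / HT) * (3 - 1 + HS) / ((3 - 1) * (1 - HS)))
  expect_equal(g3$D, (3 / 2) * (HT - HS) / (1 - HS))
  # ordering on differentiated loci with H_S > 0: D, G'_ST >= G_ST
  expect_gte(g3$D, g3$G_ST)
  expect_gte(g3$Gp_ST, g3$G_ST)
})

test_that("differentiation statistics are invariant to population order", {
  set.seed(8)
  pops <- rep(c("P1", "P2", "P3"), each = 15)
  geno <- matrix(rbinom(45 * 10, 2, runif(10, 0.2, 0.8)[rep(1:10, each = 45)]),
                 45, 10)
  colnames(geno) <- sprintf("L%02d", 1:10)
  base <- differentiation_stats(geno, pops)
  perm <- sample(45)
  again <- differentiation_stats(geno[perm, , drop = FALSE], pops[perm])
  expect_equal(base$theta, again$theta, tolerance = 1e-12)
  expect_equal(base$G_ST, again$G_ST, tolerance = 1e-12)
  expect_equal(base$D, again$D, tolerance = 1e-12)
  # H_S <= H_T up to numerical tolerance on differentiated data
  expect_true(all(base$H_S <= base$H_T + 0.05))
})

test_that("bootstrap CIs are seeded, reproducible and sensible", {
  set.seed(3)
  dos <- list(P1 = rbinom(40, 2, 0.3), P2 = rbinom(40, 2, 0.7))
  stat <- function(dbp) weir_cockerham_theta(dosage_to_counts(dbp))$theta
  ci1 <- bootstrap_ci(stat, dos, B = 300, seed = 10)
  ci2 <- bootstrap_ci(stat, dos, B = 300, seed = 10)
  expect_identical(ci1, ci2)
  point <- stat(dos)
  expect_lte(ci1[1], point)
  expect_gte(ci1[2], point)
  # degenerate data: zero-width interval
  dege <- list(P1 = rep(1L, 10), P2 = rep(1L, 10))
  ci0 <- bootstrap_ci(function(dbp) mean(unlist(dbp)), dege, B = 50,
                      seed = 4)
  expect_equal(unname(ci0[1]), unname(ci0[2]))
  # mostly-undefined statistic -> missing interval with diagnostic
  ci_na <- bootstrap_ci(function(dbp) NA_real_, dege, B = 20, seed = 1)
  expect_true(all(is.na(ci_na)))
  expect_match(attr(ci_na, "reason"), "undefined")
})

test_that("paired signed-rank test matches exact enumeration", {
  # all-shifted pairs: one-sided extreme, two-sided p = 2/2^6
  x <- 1:6; y <- 2:7
  res <- compare_cohort_daf(x, y)
  expect_equal(res$p_value, 0.03125)
  expect_equal(res$method, "exact")
  # identical vectors -> all ties -> p = 1 with warning
  expect_warning(res_tie <- compare_cohort_daf(x, x), "tied")
  expect_equal(res_tie$p_value, 1)
  # random fixtures vs the combn-based oracle
  set.seed(20)
  for (r in 1:10) {
    n <- sample(5:12, 1)
    a <- rnorm(n); b <- rnorm(n)
    ours <- compare_cohort_daf(a, b)
    expect_equal(ours$p_value, wilcoxon_exact_oracle(a - b))
  }
  # large n falls back to the tie-corrected normal approximation
  set.seed(30)
  a <- rnorm(60); b <- a + rnorm(60, 0.05)
  res_big <- compare_cohort_daf(a, b)
  expect_equal(res_big$method, "normal_approximation")
  ref <- suppressWarnings(wilcox.test(a, b, paired = TRUE,
                                      exact = FALSE)$p.value)
  expect_equal(res_big$p_value, ref)
})
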