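test_that("site_pi equals the mean pairwise difference", {
  expect_equal(site_pi(2, 4), 2 / 3)   # 4 of the 6 allele pairs differ
  expect_equal(site_pi(0, 10), 0)
  expect_equal(site_pi(1, 2), 1)
  expect_error(site_pi(1, 1), "n_called")
})

test_that("windowed_pi divides by the window span and zeroes empty windows", {
  # one het pair of samples at a single site: n_alt=2, n_called=4 -> pi=2/3
  gm <- toy_gm(rbind(c(1L), c(1L)), pos = 5000L)
  w <- windowed_pi(gm, chrom_lengths = c(chr1 = 40000))
  expect_equal(w$pi_percent[1], 100 * (2 / 3) / 40000, tolerance = 1e-12)
  expect_equal(w$pi_percent[1], 0.001667, tolerance = 1e-3)
  # a window with no SNPs reports 0
  expect_true(all(w$pi_percent[w$n_snps == 0] == 0))
  # each SNP contributes to both windows containing it
  gm2 <- toy_gm(rbind(c(1L), c(1L)), pos = 25000L)
  w2 <- windowed_pi(gm2, chrom_lengths = c(chr1 = 60000))
  expect_equal(w2$n_snps[w2$start %in% c(1, 20001)], c(1L, 1L))
})

test_that("windowed_pi is invariant to sample order and ref/alt relabeling", {
  set.seed(5)
  calls <- matrix(sample(0:2, 60, replace = TRUE), 6, 10)
  gm <- toy_gm(calls)
  w1 <- windowed_pi(gm, chrom_lengths = c(chr1 = 10000))
  gm_perm <- gm_subset(gm, samples = sample(6))
  expect_equal(windowed_pi(gm_perm, chrom_lengths = c(chr1 = 10000))$pi_percent,
               w1$pi_percent)
  flip <- gm
  flip$calls[, 3] <- 2L - flip$calls[, 3]
  expect_equal(windowed_pi(flip, chrom_lengths = c(chr1 = 10000))$pi_percent,
               w1$pi_percent)
})

test_that("individual heterozygosity and F match a brute-force tally", {
  set.seed(7)
  calls <- matrix(sample(c(0:2, NA), 4 * 8, replace = TRUE, prob = c(.3, .3, .3, .1)), 4, 8)
  gm <- toy_gm(calls)
  het <- individual_het(gm)
  # oracle: explicit per-site loop
  p <- colSums(calls, na.rm = TRUE) / (2 * colSums(!is.na(calls)))
  n <- 2 * colSums(!is.na(calls))
  poly <- !is.na(p) & p > 0 & p < 1 & n >= 2
  for (s in 1:4) {
    S <- 0; O <- 0; E <- 0
    for (j in which(poly)) {
      if (is.na(calls[s, j])) next
      S <- S + 1
      if (calls[s, j] != 1L) O <- O + 1
      E <- E + 1 - 2 * p[j] * (1 - p[j]) * n[j] / (n[j] - 1)
    }
    expect_equal(het$S[s], S)
    expect_equal(het$O_hom[s], O)
    expect_equal(het$E_hom[s], E, tolerance = 1e-12)
    expect_equal(het$F[s], (O - E) / (S - E), tolerance = 1e-12)
  }
})

test_that("F is negative for a fully heterozygous sample and H_o bounds hold", {
  calls <- rbind(rep(1L, 6), rep(0L, 6), rep(2L, 6), c(0L, 1L, 2L, 0L, 1L, 2L))
  gm <- toy_gm(calls)
  het <- individual_het(gm)
  expect_equal(het$O_hom[1], 0)
  expect_lt(het$F[1], 0)
  expect_equal(het$H_o[1], 1)
  # fully homozygous sample has the maximal F of the dataset
  expect_equal(max(het$F), het$F[2], tolerance = 1e-12)
  expect_true(all(het$H_o >= 0 & het$H_o <= 1))
  expect_true(all(het$F <= 1 + 1e-12))
})

test_that("population expected heterozygosity uses the unbiased estimator", {
  # single site, p = 0.25 from 4 diploids: 2pq * n/(n-1) = 0.4286
  gm <- toy_gm(matrix(c(1L, 1L, 0L, 0L), 4, 1))
  expect_equal(population_he(gm), 2 * 0.25 * 0.75 * 8 / 7, tolerance = 1e-12)
  expect_equal(population_he(gm), 0.4286, tolerance = 1e-4)
  # monomorphic population -> missing
  gm0 <- toy_gm(matrix(0L, 4, 3))
  expect_true(is.na(population_he(gm0)))
  # p = 0.5 with many samples: exactly 0.5 * n/(n-1), approaching 0.5
  gmb <- toy_gm(matrix(rep(c(0L, 2L), 100), 200, 1))
  expect_equal(population_he(gmb), 0.5 * 400 / 399, tolerance = 1e-12)
  expect_equal(population_he(gmb), 0.5, tolerance = 0.01)
})

test_that("shared/private partition assigns SNPs to exact population subsets", {
  # 3 populations x 10 hand-assigned sites
  a <- rbind(c(1, 0, 1, 0, 1, 0, 0, 1, 1, 0), c(1, 0, 1, 0, 0, 0, 0, 1, 1, 0))
  b <- rbind(c(0, 1, 1, 0, 0, 0, 1, 1, 0, 0), c(0, 1, 1, 0, 0, 0, 1, 0, 0, 0))
  c_ <- rbind(c(0, 0, 0, 1, 0, 0, 1, 0, 1, 0), c(0, 0, 0, 1, 0, 0, 0, 0, 1, 0))
  gm <- toy_gm(rbind(a, b, c_))
  pm <- toy_pmap(gm, rep(c("A", "B", "C"), each = 2))
  sp <- shared_private_partition(gm, pm)
  # hand tally: site1 A only(poly in A: alleles 1&1? calls all 1 -> p=0.5 poly)
  # polymorphic means both alleles seen among calls within the population
  poly <- function(x) { cs <- colSums(x); cs > 0 & cs < 2 * nrow(x) }
  pa <- poly(a); pb <- poly(b); pc <- poly(c_)
  key <- sapply(1:10, function(j)
    paste(c("A", "B", "C")[c(pa[j], pb[j], pc[j])], collapse = "+"))
  expect_equal(sp$n_polymorphic, sum(key != ""))
  tab <- table(key[key != ""])
  for (k in names(tab))
    expect_equal(sp$partition$n[sp$partition$populations == k], unname(tab[k]))
  expect_equal(sum(sp$partition$n), sp$n_polymorphic)
})

test_that("method-of-moments F is centred at zero without inbreeding and tracks pedigree F", {
  set.seed(12)
  cfg <- sim_config(n_chromosomes = 4, chrom_length = 5e5, mutation_rate = 5e-7,
                    recombination_rate = 5e-8, n_ancestral = 60, burn_in = 120,
                    init = "equilibrium",
                    populations = list(list(name = "p", t_start = 0, N = 60,
                                            sample_size = 30)),
                    seed = 12)
  res <- simulate_wf(cfg)
  het <- individual_het(res$gm)
  se <- sd(het$F) / sqrt(nrow(het))
  expect_lt(abs(mean(het$F)), 3 * se + 1e-3)
  # sib-mated population: genetic F correlates with exact pedigree F.
  # Many short chromosomes give enough independent IBD blocks for the
  # genome-wide F estimate to resolve between-individual differences.
  cfg2 <- sim_config(n_chromosomes = 24, chrom_length = 4e5, mutation_rate = 8e-7,
                     recombination_rate = 5e-8, n_ancestral = 60, burn_in = 120,
                     init = "equilibrium",
                     populations = list(list(name = "p", t_start = 12, N = 60,
                                             sample_size = 30, sib_mating = 0.5)),
                     seed = 13)
  res2 <- simulate_wf(cfg2)
  het2 <- individual_het(res2$gm)
  pf <- res2$truth$ped_f[het2$sample]
  expect_gt(cor(het2$F, pf, method = "spearman"), 0.5)
})
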