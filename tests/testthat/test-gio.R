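test_that("read_vcf maps genotypes, missingness, phase and multi-allelic flags", {
  path <- write_toy_vcf(c(
    vcf_header(c("s1", "s2")),
    "chr1\t100\t.\tA\tC\t50\tPASS\tQD=5.0\tGT\t0/0\t0/1",
    "chr1\t200\t.\tG\tT\t50\tPASS\t.\tGT\t1/1\t./.",
    "chr1\t300\t.\tC\tA,T\t50\tPASS\t.\tGT\t0/1\t1/2",
    "chr1\t400\t.\tT\tG\t50\tPASS\tAA=G\tGT\t0/1\t1/1",
    "chr2\t100\t.\tA\tG\t50\tPASS\tAA=A\tGT\t0/0\t0/1"))
  gm <- read_vcf(path)
  expect_equal(dim(gm$calls), c(2L, 5L))
  # exactly one ./. among the biallelic records (the 1/2 genotype of the
  # multi-allelic record is uncodeable as a dosage and also missing)
  expect_equal(sum(is.na(gm$calls[, !gm$variants$multiallelic])), 1L)
  expect_equal(unname(gm$calls[1, 2]), 2L)          # 1/1 -> dosage 2
  expect_false(gm$phased)                           # "/" separators
  expect_equal(gm$variants$multiallelic, c(FALSE, FALSE, TRUE, FALSE, FALSE))
  expect_true(is.na(gm$calls[2, 3]))                # allele 2 cannot be coded
  expect_equal(gm$variants$ancestral, c("unknown", "unknown", "unknown", "alt", "ref"))
  expect_equal(gm$variants$QD, c(5, NA, NA, NA, NA))
})

test_that("read_vcf detects full phasing and reports malformed records", {
  path <- write_toy_vcf(c(
    vcf_header("s1"),
    "chr1\t100\t.\tA\tC\t50\tPASS\t.\tGT\t1|1",
    "chr1\t200\t.\tG\tT\t50\tPASS\t.\tGT\t0|1"))
  gm <- read_vcf(path)
  expect_true(gm$phased)
  expect_equal(unname(gm$calls[1, 1]), 2L)
  bad <- write_toy_vcf(c(
    vcf_header("s1"),
    "chr1\t100\t.\tA\tC\t50\tPASS\t.\tGT\tx/y"))
  expect_error(read_vcf(bad), "record")
})

test_that("hard filters remove on strict threshold violations, missing annotations pass", {
  gm <- toy_gm(matrix(1L, 2, 5),
               QD = c(1.5, 2.0, 5, 5, 5),
               QUAL = c(50, 50, 50, 50, 50),
               SOR = c(1, 1, NA, 3.0, 3.1),
               FS = c(0, 0, 0, 0, 0),
               MQ = c(60, 40.0, 60, 60, 60),
               MQRankSum = c(0, 0, 0, 0, 0),
               ReadPosRankSum = c(0, 0, 0, 0, 0))
  out <- apply_hard_filters(gm)
  # variant 1 fails QD<2.0; variant 2 sits exactly on QD=2.0 and MQ=40.0
  # (strict: retained); variant 3 has SOR missing (passes, logged);
  # variant 4 SOR=3.0 exactly (retained); variant 5 SOR=3.1 (removed)
  expect_equal(out$gm$variants$pos, gm$variants$pos[c(2, 3, 4)])
  expect_equal(out$report$n_removed, 2L)
  expect_equal(out$report$removed$n[out$report$removed$criterion == "QD"], 1L)
  expect_equal(out$report$removed$n[out$report$removed$criterion == "SOR"], 1L)
  expect_equal(unname(out$report$missing_annotation["SOR"]), 1L)
  expect_equal(out$report$n_input - out$report$n_removed, out$report$n_retained)
})

test_that("site filters: biallelic autosomal SNPs, call rate and MAC boundaries", {
  # 100 samples so a 49% call rate is expressible
  n <- 100
  calls <- matrix(0L, n, 5)
  calls[1, 1] <- 1L                  # MAC 1 -> removed
  calls[1:2, 2] <- 1L                # MAC 2 -> kept
  calls[, 3] <- c(rep(NA, 51), rep(1L, 49))   # 49% called -> removed
  calls[, 4] <- c(rep(NA, 50), rep(1L, 50))   # exactly 50% -> kept
  calls[1:10, 5] <- 2L               # on chrZ -> removed
  gm <- toy_gm(calls, chrom = c(rep("chr1", 4), "Z"), pos = c(1:4 * 1000, 1000))
  out <- filter_sites(gm, autosomes = "chr1")
  expect_equal(out$gm$variants$pos, c(2000L, 4000L))
  rep <- out$report$removed
  expect_equal(rep$n[rep$criterion == "mac"], 1L)
  expect_equal(rep$n[rep$criterion == "call_rate"], 1L)
  expect_equal(rep$n[rep$criterion == "not_autosomal"], 1L)
  # idempotence
  out2 <- filter_sites(out$gm, autosomes = "chr1")
  expect_equal(out2$gm$variants, out$gm$variants)
  expect_equal(out2$report$n_removed, 0L)
})

test_that("multi-allelic and non-SNP records are excluded by filter_sites, not read_vcf", {
  path <- write_toy_vcf(c(
    vcf_header(c("s1", "s2")),
    "chr1\t100\t.\tA\tC\t50\tPASS\t.\tGT\t0/1\t0/1",
    "chr1\t200\t.\tG\tT,A\t50\tPASS\t.\tGT\t0/1\t0/1",
    "chr1\t300\t.\tGA\tG\t50\tPASS\t.\tGT\t0/1\t0/1"))
  gm <- read_vcf(path)
  expect_equal(n_variants(gm), 3L)   # retained at read time
  out <- filter_sites(gm, autosomes = "chr1")
  expect_equal(out$gm$variants$pos, 100L)
  expect_equal(out$report$removed$n[out$report$removed$criterion == "not_biallelic_snp"], 2L)
})

test_that("allele counts tally called genotypes only", {
  gm <- toy_gm(rbind(c(1L, NA, 0L), c(2L, NA, NA)))
  ac <- allele_counts(gm)
  expect_equal(ac$n_alt, c(3L, 0L, 0L))
  expect_equal(ac$n_called, c(4L, 0L, 2L))
  # mixed-missing fixture vs hand tally on 4 samples x 6 sites
  set.seed(11)
  calls <- matrix(sample(c(0:2, NA), 24, replace = TRUE), 4, 6)
  gm2 <- toy_gm(calls)
  pm <- toy_pmap(gm2, c("a", "a", "b", "b"))
  ac2 <- allele_counts(gm2, pm, "a")
  hand_alt <- sapply(1:6, function(j) sum(calls[1:2, j], na.rm = TRUE))
  hand_n <- sapply(1:6, function(j) 2 * sum(!is.na(calls[1:2, j])))
  expect_equal(ac2$n_alt, hand_alt)
  expect_equal(ac2$n_called, hand_n)
  expect_error(allele_counts(gm2, pm, "nope"), "unknown population")
})

test_that("write_dataset round-trips calls, phase and ancestral annotation", {
  set.seed(3)
  cfg <- sim_config(n_chromosomes = 2, chrom_length = 1e5, mutation_rate = 2e-6,
                    recombination_rate = 1e-7, n_ancestral = 30, burn_in = 30,
                    populations = list(list(name = "p1", t_start = 0, N = 30,
                                            sample_size = 6)),
                    seed = 99)
  res <- simulate_wf(cfg)
  prefix <- tempfile()
  paths <- write_dataset(res$gm, res$pmap, prefix, hs = res$hs)
  gm2 <- read_vcf(paths[["vcf"]])
  expect_identical(gm2$calls, res$gm$calls)
  expect_identical(gm2$variants$pos, res$gm$variants$pos)
  expect_true(gm2$phased)
  # AA INFO emitted exactly for variants with known ancestral allele
  lines <- readLines(paths[["vcf"]])
  body <- lines[!startsWith(lines, "#")]
  expect_equal(sum(grepl("AA=", body)), sum(res$gm$variants$ancestral != "unknown"))
  pm2 <- read_popmap(paths[["popmap"]])
  expect_equal(nrow(pm2), length(res$gm$samples))
  hs2 <- read_haplotypes(paths[["vcf"]])
  expect_equal(unname(hs2$haps), unname(res$hs$haps))
})
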