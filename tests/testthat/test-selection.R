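test_that("EHH is 1 at the core, decays by group splitting, matches pair enumeration", {
  # 4 derived carriers splitting into two groups of 2 one marker to the right
  haps <- rbind(c(0, 1, 0, 0), c(0, 1, 0, 0), c(0, 1, 1, 0), c(0, 1, 1, 1),
                c(0, 0, 0, 0), c(0, 0, 1, 0))
  hs <- toy_hs(haps)
  cv <- ehh(hs, 2, "derived", ehh_floor = 0)
  expect_equal(cv$ehh[cv$side == "core"], 1)
  right <- cv[cv$side == "right", ]
  expect_equal(right$ehh[1], 2 / 6)   # two groups of 2 among C(4,2)=6 pairs
  # identical carriers stay at 1 everywhere
  hs2 <- toy_hs(rbind(c(1, 1, 1, 1), c(1, 1, 1, 1), c(0, 0, 0, 0), c(0, 0, 1, 0)))
  cv2 <- ehh(hs2, 2, "derived", ehh_floor = 0)
  expect_true(all(cv2$ehh == 1))
})

test_that("EHH equals exhaustive pair enumeration and is non-increasing", {
  set.seed(61)
  for (rep in 1:8) {
    nh <- 2 * sample(4:8, 1)
    m <- sample(10:30, 1)
    haps <- matrix(rbinom(nh * m, 1, runif(1, .2, .8)), nh, m)
    core <- sample(3:(m - 2), 1)
    for (allele in 0:1) {
      car <- which(haps[, core] == allele)
      if (length(car) < 2) next
      cv <- ehh(toy_hs(haps), core, if (allele == 1) "derived" else "ancestral",
                ehh_floor = 0)
      right <- cv[cv$side == "right", ]
      if (nrow(right)) {
        oracle <- ehh_oracle(haps, car, core, (core + 1):(core + nrow(right)))
        expect_equal(right$ehh, oracle, tolerance = 1e-12)
        expect_true(all(diff(right$ehh) <= 1e-12))
      }
      left <- cv[cv$side == "left", ]
      if (nrow(left)) {
        oracle <- rev(ehh_oracle(haps, car, core, (core - 1):(core - nrow(left))))
        expect_equal(left$ehh, oracle, tolerance = 1e-12)
      }
    }
  }
})

test_that("iHH integrates the curve: rectangle case and fine-grid quadrature oracle", {
  # EHH constant 1 over a 10 kb right flank, then a split at the last marker
  haps <- rbind(c(1, 1, 1, 1, 0), c(1, 1, 1, 1, 0),
                c(1, 1, 1, 1, 1), c(1, 1, 1, 1, 1),
                c(0, 1, 0, 0, 0), c(0, 0, 1, 0, 0))
  hs <- toy_hs(haps, pos = c(1000L, 3000L, 6000L, 11000L, 11100L))
  cv <- ehh(hs, 1, "derived", ehh_floor = 0.05)
  # carriers: 4 identical haplotypes over 10 kb, then two groups of 2 -> 1/3
  expect_equal(ihh(cv), 10000 + 0.5 * (1 + 1 / 3) * 100, tolerance = 1e-9)
  # random curves match a 1-bp Riemann sum of the linear interpolant
  set.seed(62)
  for (rep in 1:5) {
    nh <- 12; m <- 25
    haps <- matrix(rbinom(nh * m, 1, 0.5), nh, m)
    pos <- sort(sample.int(50000L, m))
    hs <- toy_hs(haps, pos = pos)
    core <- 12
    car <- which(haps[, core] == 1)
    if (length(car) < 2) next
    cv <- ehh(hs, core, "derived", ehh_floor = 0.05)
    val <- ihh(cv)
    riemann <- 0
    for (sd_ in c("left", "right")) {
      seg <- cv[cv$side == sd_, ]
      if (sd_ == "left") seg <- seg[rev(seq_len(nrow(seg))), ]
      pe <- 1; pp <- pos[core]
      for (i in seq_len(nrow(seg))) {
        if (seg$ehh[i] < 0.05) break
        xs <- seq(0, 1, length.out = max(2, abs(seg$pos[i] - pp) + 1))
        riemann <- riemann + mean(pe + xs * (seg$ehh[i] - pe)) * abs(seg$pos[i] - pp)
        pe <- seg$ehh[i]; pp <- seg$pos[i]
      }
    }
    expect_equal(val, riemann, tolerance = 1e-6)
  }
})

test_that("iHS is zero on mirror-image fixtures and standardisation is exact per bin", {
  # ancestral and derived carriers with mirror-image haplotype structure
  block <- rbind(c(0, 0, 0), c(0, 0, 1), c(1, 0, 0), c(1, 0, 1))
  haps <- rbind(cbind(block[, 1:2], 0, block[, 3]),
                cbind(block[, 1:2], 1, block[, 3]))
  hs <- toy_hs(haps, pos = c(1000L, 2000L, 3000L, 4000L))
  res <- popsweep:::ihs_ihh_cpp(matrix(as.raw(haps), nrow(haps)),
                                as.numeric(hs$variants$pos), 2L, 0.05, 0,
                                rep(TRUE, ncol(haps)))
  expect_equal(res[1, 1], res[1, 2], tolerance = 1e-12)   # iHH_A = iHH_D
  # standardized scores: mean 0, sd 1 within each frequency bin
  set.seed(63)
  sim <- simulate_wf(sim_config(n_chromosomes = 2, chrom_length = 4e5,
                                mutation_rate = 2e-6, recombination_rate = 2e-7,
                                n_ancestral = 40, burn_in = 120,
                                populations = list(list(name = "p", t_start = 0,
                                                        N = 40, sample_size = 20)),
                                seed = 64))
  tr <- ihs_scan(sim$hs)
  bin <- floor(tr$freq_derived / 0.025)
  for (b in unique(bin)) {
    v <- tr$std[bin == b & !is.na(tr$std)]
    if (length(v) >= 2) {
      expect_equal(mean(v), 0, tolerance = 1e-9)
      expect_equal(sd(v), 1, tolerance = 1e-9)
    }
  }
  # antisymmetry: relabeling ancestral/derived at the core negates raw iHS
  tr2 <- ihs_scan(hs_flip <- local({
    h <- sim$hs; h$haps <- 1L - h$haps; h
  }))
  common <- intersect(tr$id[!is.na(tr$raw)], tr2$id[!is.na(tr2$raw)])
  expect_equal(tr$raw[match(common, tr$id)], -tr2$raw[match(common, tr2$id)],
               tolerance = 1e-9)
})

test_that("XP-EHH is zero against itself and antisymmetric under population swap", {
  set.seed(65)
  sim <- simulate_wf(sim_config(n_chromosomes = 1, chrom_length = 3e5,
                                mutation_rate = 2e-6, recombination_rate = 2e-7,
                                n_ancestral = 30, burn_in = 90,
                                populations = list(
                                  list(name = "a", t_start = 30, N = 30, sample_size = 10),
                                  list(name = "b", t_start = 30, N = 30, sample_size = 10)),
                                seed = 66))
  tr_ab <- xpehh_scan(sim$hs, sim$pmap, "a", "b")
  tr_ba <- xpehh_scan(sim$hs, sim$pmap, "b", "a")
  expect_equal(tr_ab$raw, -tr_ba$raw, tolerance = 1e-12)
  # identical haplotype sets on both sides -> raw 0 at every SNP
  hsdup <- sim$hs
  rows_a <- popsweep:::hap_rows(hsdup, sim$pmap$sample[sim$pmap$population == "a"])
  pm_dup <- pop_map(c(paste0("c1_", 1:10), paste0("c2_", 1:10)), rep(c("c1", "c2"), each = 10))
  hs_dup <- haplo_set(rbind(hsdup$haps[rows_a, ], hsdup$haps[rows_a, ]),
                      hsdup$variants, pm_dup$sample)
  tr_same <- xpehh_scan(hs_dup, pm_dup, "c1", "c2")
  expect_true(all(abs(tr_same$raw) < 1e-12))
})

test_that("window scores average |std| and drop windows under the SNP minimum", {
  track <- data.frame(chrom = "chr1",
                      pos = c(seq(21000, 39000, by = 2000), seq(70100, 70500, by = 100)),
                      id = "x", freq_derived = 0.5,
                      raw = 1, std = rep(c(2, -2), length.out = 15))
  w <- window_scores(track, chrom_lengths = c(chr1 = 100000), min_snps = 10)
  expect_true(all(abs(w$score - 2) < 1e-12))
  # the cluster of 5 scored SNPs never reaches the 10-SNP window minimum
  expect_true(all(w$n_snps >= 10))
  expect_equal(w$start, c(1, 20001))
  # grid-translation property (away from chromosome edges): shifting all
  # positions by one step shifts the kept windows identically
  track2 <- track; track2$pos <- track2$pos + 20000
  w2 <- window_scores(track2, chrom_lengths = c(chr1 = 120000), min_snps = 10)
  expect_equal(w2$start, w$start + 20000)
  expect_equal(w2$score, w$score)
})

test_that("candidate calling uses the nearest-rank quantile with strict exceedance", {
  set.seed(67)
  w <- data.frame(chrom = "chr1", start = seq(1, by = 20000, length.out = 10000))
  w$end <- w$start + 39999; w$n_snps <- 20
  w$score <- sample(seq_len(10000))  # distinct values
  out <- call_candidates(w, top_fraction = 0.001)
  expect_equal(nrow(out$flagged), 10L)
  expect_equal(sort(out$flagged$score), 9991:10000)
  # brute-force sort-and-slice oracle
  expect_equal(out$threshold, sort(w$score)[9990])
  # degenerate: all equal -> none flagged, with a warning
  w$score <- 1
  expect_warning(out2 <- call_candidates(w, 0.001), "no window")
  expect_equal(nrow(out2$flagged), 0L)
})

test_that("adjacent flagged windows merge; separated ones stay apart", {
  fl <- data.frame(chrom = c("chr1", "chr1", "chr1"),
                   start = c(40001, 60001, 120001),
                   end = c(80000, 100000, 160000),
                   n_snps = 10, score = c(3, 4, 5))
  reg <- merge_regions(fl)
  expect_equal(nrow(reg), 2L)
  expect_equal(reg$start[1], 40001)
  expect_equal(reg$end[1], 100000)
  expect_equal(reg$max_score[1], 4)
  expect_equal(reg$n_windows, c(2L, 1L))
  # single window -> region identical to it
  reg1 <- merge_regions(fl[3, ])
  expect_equal(reg1$start, 120001)
  expect_equal(reg1$end, 160000)
})

test_that("regions are annotated with overlapping features or the nearest one", {
  regions <- data.frame(chrom = c("chr1", "chr1", "chr2"),
                        start = c(100, 5000, 200), end = c(200, 5100, 300),
                        n_windows = 1, max_score = 1, mean_score = 1,
                        frac_positive = NA)
  feats <- data.frame(chrom = c("chr1", "chr1", "chr2", "chr2"),
                      start = c(50, 6000, 400, 50), end = c(300, 6100, 450, 100),
                      label = c("geneA", "geneB", "geneC", "geneD"))
  ann <- annotate_regions(regions, feats)
  expect_equal(ann$features[1], "geneA")
  expect_false(ann$gene_void[1])
  expect_true(ann$gene_void[2])
  expect_equal(ann$features[2], "geneB")
  expect_equal(ann$nearest_distance[2], 900)
  # equidistant tie: both features reported
  expect_true(ann$gene_void[3])
  expect_equal(ann$nearest_distance[3], 100)
  expect_setequal(strsplit(ann$features[3], ",")[[1]], c("geneC", "geneD"))
})

test_that("BED and GFF3 features are normalised to 1-based inclusive coordinates", {
  bed <- tempfile(fileext = ".bed")
  writeLines(c("chr1\t99\t300\tgeneA", "chr1\t5999\t6100\tgeneB"), bed)
  fb <- read_features(bed)
  expect_equal(fb$start, c(100, 6000))
  expect_equal(fb$end, c(300, 6100))
  expect_equal(fb$label, c("geneA", "geneB"))
  gff <- tempfile(fileext = ".gff3")
  writeLines(c("##gff-version 3",
               "chr1\tsrc\tgene\t100\t300\t.\t+\t.\tID=g1;Name=geneA"), gff)
  fg <- read_features(gff)
  expect_equal(fg$start, 100)
  expect_equal(fg$end, 300)
  expect_equal(fg$label, "geneA")
})

test_that("iHS is elevated around an incomplete hard sweep", {
  hits <- logical(12)
  for (i in seq_along(hits)) {
    cfg <- sim_config(n_chromosomes = 3, chrom_length = 1e6, mutation_rate = 3e-7,
                      recombination_rate = 5e-8, n_ancestral = 80, burn_in = 160,
                      init = "equilibrium",
                      populations = list(list(
                        name = "p", t_start = 20, N = 80, sample_size = 40,
                        sweep = list(chrom = 2, pos = 5e5, s = 1, h = 0.5,
                                     start = 10, min_freq = 0.4))),
                      seed = 1000 + i)
    res <- simulate_wf(cfg)
    tr <- ihs_scan(res$hs)
    near <- tr$chrom == "chr2" & abs(tr$pos - res$truth$sweep$pos) <= 5e4 & !is.na(tr$std)
    hits[i] <- sum(near) > 0 &&
      mean(abs(tr$std[near])) > mean(abs(tr$std), na.rm = TRUE)
  }
  expect_gte(mean(hits), 0.75)
})

test_that("allele-agnostic EHH starts at 1 and refines over all haplotypes", {
  set.seed(68)
  haps <- matrix(rbinom(10 * 12, 1, 0.5), 10, 12)
  hs <- toy_hs(haps)
  cv <- ehh(hs, 6, "all", ehh_floor = 0)
  expect_equal(cv$ehh[cv$side == "core"], 1)
  right <- cv$ehh[cv$side == "right"]
  expect_true(all(diff(right) <= 1e-12))
  # first step right: partition of all 10 haplotypes by the allele at site 7
  k <- sum(haps[, 7])
  expect_equal(right[1], (choose(k, 2) + choose(10 - k, 2)) / choose(10, 2))
})
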