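# small in-code fixtures shared across tests

# genotype matrix from a plain integer matrix (samples x variants)
toy_gm <- function(calls, chrom = NULL, pos = NULL, phased = FALSE, ...) {
  calls <- as.matrix(calls)
  m <- ncol(calls)
  if (is.null(chrom)) chrom <- rep("chr1", m)
  if (is.null(pos)) pos <- seq_len(m) * 1000L
  vr <- data.frame(chrom = chrom, pos = pos,
                   ref = rep("A", m), alt = rep("C", m),
                   stringsAsFactors = FALSE)
  extra <- list(...)
  for (nm in names(extra)) vr[[nm]] <- extra[[nm]]
  geno_matrix(calls, vr, paste0("s", seq_len(nrow(calls))), phased = phased)
}

toy_pmap <- function(gm, populations) pop_map(gm$samples, populations)

# haplotype set from a 0/1 matrix (haplotypes x variants), ancestral = ref
toy_hs <- function(haps, chrom = NULL, pos = NULL) {
  haps <- as.matrix(haps)
  m <- ncol(haps)
  if (is.null(chrom)) chrom <- rep("chr1", m)
  if (is.null(pos)) pos <- seq_len(m) * 1000L
  vr <- data.frame(chrom = chrom, pos = pos, ref = rep("A", m), alt = rep("C", m),
                   ancestral = rep("ref", m), stringsAsFactors = FALSE)
  haplo_set(haps, vr, paste0("s", seq_len(nrow(haps) / 2)))
}

# write a small VCF by hand
write_toy_vcf <- function(lines, path = tempfile(fileext = ".vcf")) {
  writeLines(lines, path)
  path
}

vcf_header <- function(samples) {
  c("##fileformat=VCFv4.2",
    "##INFO=<ID=QD,Number=1,Type=Float,Description=\"qd\">",
    "##INFO=<ID=SOR,Number=1,Type=Float,Description=\"sor\">",
    "##INFO=<ID=AA,Number=1,Type=String,Description=\"ancestral\">",
    "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">",
    paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER", "INFO", "FORMAT",
            samples), collapse = "\t"))
}

# brute-force EHH by direct pair enumeration over allele strings
ehh_oracle <- function(haps, carriers, core, side_pos) {
  n <- length(carriers)
  idx_range <- function(j) if (j > core) (core + 1):j else j:(core - 1)
  vapply(side_pos, function(j) {
    same <- 0
    for (a in 1:(n - 1)) for (b in (a + 1):n) {
      ia <- carriers[a]; ib <- carriers[b]
      if (all(haps[ia, idx_range(j)] == haps[ib, idx_range(j)])) same <- same + 1
    }
    same / (n * (n - 1) / 2)
  }, 0)
}

# exhaustive Viterbi over the explicit trellis (<= 12 sites)
viterbi_oracle <- function(het, pos, p, params) {
  T_ <- length(het)
  states <- expand.grid(rep(list(0:1), T_))
  pi_auto <- params$t_in / (params$t_in + params$t_out)
  emis <- function(t, s) {
    h2 <- 2 * p[t] * (1 - p[t])
    phet <- if (s == 1) params$e_het else h2 * (1 - params$e_het) + params$e_het * (1 - h2)
    log(if (het[t] == 1) phet else 1 - phet)
  }
  best <- -Inf; best_path <- NULL
  for (r in seq_len(nrow(states))) {
    s <- as.integer(states[r, ])
    lp <- log(if (s[1] == 1) pi_auto else 1 - pi_auto) + emis(1, s[1])
    if (T_ > 1) for (t in 2:T_) {
      d <- pos[t] - pos[t - 1]
      p01 <- 1 - exp(-params$t_in * d)
      p10 <- 1 - exp(-params$t_out * d)
      tr <- if (s[t - 1] == 0) { if (s[t] == 1) p01 else 1 - p01 }
            else { if (s[t] == 0) p10 else 1 - p10 }
      lp <- lp + log(tr) + emis(t, s[t])
    }
    if (lp > best) { best <- lp; best_path <- s }
  }
  best_path
}

# step-by-step scalar transcription of the two-population variance components
wc_oracle <- function(n1, p1, h1, n2, p2, h2) {
  r <- 2
  nbar <- (n1 + n2) / r
  nc <- (r * nbar - (n1^2 / (r * nbar) + n2^2 / (r * nbar))) / (r - 1)
  pbar <- (n1 * p1 + n2 * p2) / (r * nbar)
  s2 <- (n1 * (p1 - pbar)^2 + n2 * (p2 - pbar)^2) / ((r - 1) * nbar)
  hbar <- (n1 * h1 + n2 * h2) / (r * nbar)
  a <- (nbar / nc) * (s2 - (pbar * (1 - pbar) - (r - 1) / r * s2 - hbar / 4) / (nbar - 1))
  b <- (nbar / (nbar - 1)) *
    (pbar * (1 - pbar) - (r - 1) / r * s2 - (2 * nbar - 1) / (4 * nbar) * hbar)
  c(a = a, b = b, c = hbar / 2)
}
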