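#' Weir-Cockerham variance components for a biallelic site (two populations)
#'
#' Computes the among-population (a), among-individual-within-population (b)
#' and within-individual (c) variance components from per-population sample
#' sizes (diploid individuals with calls), alt-allele frequencies and observed
#' heterozygote fractions. The site-level estimator is \code{a / (a + b + c)}.
#' All arguments are vectorised over sites.
#'
#' @param n1,n2 called diploid individuals per population.
#' @param p1,p2 alt-allele frequency per population.
#' @param h1,h2 observed heterozygote fraction per population.
#' @return data.frame with columns \code{a}, \code{b}, \code{c} and
#'   \code{informative} (FALSE where the site is monomorphic across both
#'   populations or a population has no calls; components are 0 there).
#' @export
wc_components <- function(n1, p1, h1, n2, p2, h2) {
  r <- 2
  nbar <- (n1 + n2) / r
  nc <- (r * nbar - (n1^2 + n2^2) / (r * nbar)) / (r - 1)
  pbar <- (n1 * p1 + n2 * p2) / (r * nbar)
  s2 <- (n1 * (p1 - pbar)^2 + n2 * (p2 - pbar)^2) / ((r - 1) * nbar)
  hbar <- (n1 * h1 + n2 * h2) / (r * nbar)
  a <- (nbar / nc) * (s2 - (1 / (nbar - 1)) * (pbar * (1 - pbar) - ((r - 1) / r) * s2 - hbar / 4))
  b <- (nbar / (nbar - 1)) * (pbar * (1 - pbar) - ((r - 1) / r) * s2 - ((2 * nbar - 1) / (4 * nbar)) * hbar)
  cc <- hbar / 2
  informative <- n1 >= 1 & n2 >= 1 & nbar > 1 & pbar > 0 & pbar < 1
  a[!informative] <- 0; b[!informative] <- 0; cc[!informative] <- 0
  data.frame(a = a, b = b, c = cc, informative = informative)
}

# per-site population summaries needed by the WC estimator
site_pop_stats <- function(gm, pmap, population) {
  idx <- pop_sample_idx(gm, pmap, population)
  calls <- gm$calls[idx, , drop = FALSE]
  n <- colSums(!is.na(calls))
  p <- ifelse(n > 0, colSums(calls, na.rm = TRUE) / (2 * n), 0)
  h <- ifelse(n > 0, colSums(calls == 1L, na.rm = TRUE) / n, 0)
  list(n = n, p = p, h = h)
}

#' Windowed Weir-Cockerham FST between two populations
#'
#' Window and genome-wide values are the "weighted" ratio of sums
#' \code{sum(a) / sum(a + b + c)} over informative sites; negative values are
#' reported as computed. Windows without informative sites get NA.
#'
#' @param gm a [geno_matrix()].
#' @param pmap a [pop_map()].
#' @param pop_a,pop_b population labels (each needs >= 2 diploids with calls).
#' @param chrom_lengths optional named chromosome lengths.
#' @param width,step window width and step in bp (default 40 kb / 20 kb).
#' @return list with \code{windows} (data.frame chrom, start, end, n_sites,
#'   fst_weighted) and \code{genome} (single ratio-of-sums value).
#' @export
windowed_fst <- function(gm, pmap, pop_a, pop_b, chrom_lengths = NULL,
                         width = 40000, step = 20000) {
  sa <- site_pop_stats(gm, pmap, pop_a)
  sb <- site_pop_stats(gm, pmap, pop_b)
  if (max(sa$n) < 2 || max(sb$n) < 2) stop("both populations need >= 2 diploids with calls")
  comp <- wc_components(sa$n, sa$p, sa$h, sb$n, sb$p, sb$h)
  num <- ifelse(comp$informative, comp$a, NA_real_)
  den <- ifelse(comp$informative, comp$a + comp$b + comp$c, NA_real_)
  lens <- infer_chrom_lengths(gm$variants, chrom_lengths)
  wa <- window_aggregate(gm$variants$chrom, gm$variants$pos, num, lens, width, step)
  wd <- window_aggregate(gm$variants$chrom, gm$variants$pos, den, lens, width, step)
  windows <- data.frame(chrom = wa$chrom, start = wa$start, end = wa$end,
                        n_sites = wa$n_defined,
                        fst_weighted = ifelse(wa$n_defined > 0, wa$sum / wd$sum, NA_real_),
                        stringsAsFactors = FALSE)
  genome <- sum(num, na.rm = TRUE) / sum(den, na.rm = TRUE)
  list(windows = windows, genome = genome)
}

#' Pairwise genome-wide weighted FST matrix
#'
#' @param gm a [geno_matrix()].
#' @param pmap a [pop_map()] with at least two populations.
#' @return symmetric matrix of genome-wide weighted FST, zero diagonal; pairs
#'   involving a population with fewer than 2 samples are NA.
#' @export
pairwise_fst <- function(gm, pmap) {
  pops <- unique(pop_labels_for(gm, pmap))
  if (length(pops) < 2) stop("need >= 2 populations")
  m <- matrix(0, length(pops), length(pops), dimnames = list(pops, pops))
  labs <- pop_labels_for(gm, pmap)
  for (i in seq_along(pops)) for (j in seq_len(i - 1)) {
    if (sum(labs == pops[i]) < 2 || sum(labs == pops[j]) < 2) {
      m[i, j] <- m[j, i] <- NA_real_
      next
    }
    sa <- site_pop_stats(gm, pmap, pops[i])
    sb <- site_pop_stats(gm, pmap, pops[j])
    comp <- wc_components(sa$n, sa$p, sa$h, sb$n, sb$p, sb$h)
    keep <- comp$informative
    m[i, j] <- m[j, i] <- sum(comp$a[keep]) / sum((comp$a + comp$b + comp$c)[keep])
  }
  m
}
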