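#' Pairwise linkage disequilibrium r-squared for two sites
#'
#' Haplotype mode (phased 0/1 vectors): \code{r2 = D^2 / (pA(1-pA) pB(1-pB))}
#' with \code{D = pAB - pA pB}. Genotype mode: squared Pearson correlation of
#' alt-dosage vectors over jointly called samples.
#'
#' @param a,b allele (haplotype mode) or dosage (genotype mode) vectors.
#' @param mode "haplotype" or "genotype".
#' @return r-squared, or NA if either site is monomorphic among the considered
#'   samples.
#' @export
pair_r2 <- function(a, b, mode = c("genotype", "haplotype")) {
  mode <- match.arg(mode)
  if (mode == "haplotype") {
    pa <- mean(a); pb <- mean(b)
    if (pa %in% c(0, 1) || pb %in% c(0, 1)) return(NA_real_)
    d <- mean(a * b) - pa * pb
    return(d^2 / (pa * (1 - pa) * pb * (1 - pb)))
  }
  ok <- !is.na(a) & !is.na(b)
  a <- a[ok]; b <- b[ok]
  if (length(a) < 2 || var(a) == 0 || var(b) == 0) return(NA_real_)
  cor(a, b)^2
}

# mean r2 between column blocks, accumulated into distance bins.
# X: samples x snps numeric matrix (dosages or haplotype alleles)
decay_accumulate <- function(X, pos, max_dist, bin_of, n_bins, block = 400L) {
  sums <- rep(0, n_bins)
  cnts <- rep(0L, n_bins)
  m <- ncol(X)
  has_na <- anyNA(X)
  i0 <- 1L
  while (i0 <= m) {
    i1 <- min(i0 + block - 1L, m)
    jmax <- i1
    while (jmax < m && pos[jmax + 1L] - pos[i1] <= max_dist) jmax <- jmax + 1L
    r <- if (has_na) suppressWarnings(cor(X[, i0:i1, drop = FALSE], X[, i0:jmax, drop = FALSE],
                                          use = "pairwise.complete.obs"))
         else suppressWarnings(cor(X[, i0:i1, drop = FALSE], X[, i0:jmax, drop = FALSE]))
    for (ii in seq_len(i1 - i0 + 1L)) {
      gi <- i0 + ii - 1L
      js <- which(pos[i0:jmax] - pos[gi] > 0 & pos[i0:jmax] - pos[gi] <= max_dist) + i0 - 1L
      if (!length(js)) next
      r2 <- r[ii, js - i0 + 1L]^2
      d <- pos[js] - pos[gi]
      ok <- !is.na(r2)
      if (!any(ok)) next
      bi <- bin_of(d[ok])
      agg <- rowsum(r2[ok], bi)
      idx <- as.integer(rownames(agg))
      sums[idx] <- sums[idx] + agg[, 1]
      cnts[idx] <- cnts[idx] + tabulate(bi, nbins = n_bins)[idx]
    }
    i0 <- i1 + 1L
  }
  list(sums = sums, cnts = cnts)
}

#' LD decay curve for one population
#'
#' Mean pairwise r-squared between all intra-chromosomal SNP pairs within
#' \code{max_dist}, reported at full resolution for distances up to 1 kb and
#' in 1 kb bins thereafter. Genotype-mode r-squared by default (no phasing
#' requirement); pass a [haplo_set()] with \code{mode = "haplotype"} for
#' haplotype r-squared.
#'
#' @param data a [geno_matrix()] or [haplo_set()].
#' @param pmap a [pop_map()]; NULL uses all samples.
#' @param population population label; NULL uses all samples.
#' @param max_dist maximum pair distance in bp (default 500 kb).
#' @param mode "genotype" (default) or "haplotype".
#' @return data.frame with \code{bin_start}, \code{bin_end}, \code{mean_r2},
#'   \code{n_pairs}; bins without pairs are dropped.
#' @export
ld_decay <- function(data, pmap = NULL, population = NULL, max_dist = 500000,
                     mode = c("genotype", "haplotype")) {
  mode <- match.arg(mode)
  if (inherits(data, "haplo_set")) {
    hs <- if (!is.null(population)) {
      keep <- pmap$sample[pmap$population == population]
      hs_subset(data, samples = intersect(data$samples, keep))
    } else data
    X <- if (mode == "haplotype") hs$haps else hs_to_gm(hs)$calls
    variants <- hs$variants
  } else {
    if (mode == "haplotype") stop("haplotype mode needs a haplo_set")
    gm <- if (!is.null(population)) gm_subset(data, samples = pop_sample_idx(data, pmap, population)) else data
    X <- gm$calls
    variants <- gm$variants
  }
  if (nrow(X) < (if (mode == "haplotype") 4 else 2)) stop("population too small for LD")
  # bins: 1..1000 at full bp resolution, then 1 kb windows (1000, 2000], ...
  n_fine <- 1000L
  n_coarse <- as.integer(ceiling(max_dist / 1000)) - 1L
  n_bins <- n_fine + n_coarse
  bin_of <- function(d) ifelse(d <= 1000, d, n_fine + ceiling(d / 1000) - 1L)
  sums <- rep(0, n_bins); cnts <- rep(0L, n_bins)
  X <- matrix(as.numeric(X), nrow(X))
  for (ch in unique(variants$chrom)) {
    sel <- which(variants$chrom == ch)
    if (length(sel) < 2) next
    Xc <- X[, sel, drop = FALSE]
    keep <- apply(Xc, 2, function(z) length(unique(z[!is.na(z)])) > 1)
    if (sum(keep) < 2) next
    acc <- decay_accumulate(Xc[, keep, drop = FALSE], variants$pos[sel][keep],
                            max_dist, bin_of, n_bins)
    sums <- sums + acc$sums
    cnts <- cnts + acc$cnts
  }
  bin_start <- c(seq_len(n_fine), 1000L + 1000L * (seq_len(n_coarse) - 1L) + 1L)
  bin_end <- c(seq_len(n_fine), 1000L + 1000L * seq_len(n_coarse))
  keep <- cnts > 0
  data.frame(bin_start = bin_start[keep], bin_end = bin_end[keep],
             mean_r2 = sums[keep] / cnts[keep], n_pairs = cnts[keep])
}

#' PLINK-style LD pruning (indep-pairwise)
#'
#' Greedy scan in position order: windows of \code{window} SNPs advanced by
#' \code{step} SNPs; within a window, for every pair of still-retained SNPs
#' with genotype-mode r-squared above \code{r2_max}, the later SNP (by
#' position) is removed. Deterministic.
#'
#' @param gm a [geno_matrix()].
#' @param window window size in SNPs (default 50).
#' @param step step size in SNPs (default 5).
#' @param r2_max r-squared threshold (default 0.2); pairs strictly above it
#'   are violations.
#' @return integer vector of retained variant indices (into
#'   \code{gm$variants}).
#' @export
ld_prune <- function(gm, window = 50, step = 5, r2_max = 0.2) {
  keep <- rep(TRUE, n_variants(gm))
  X <- matrix(as.numeric(gm$calls), nrow(gm$calls))
  for (ch in unique(gm$variants$chrom)) {
    sel <- which(gm$variants$chrom == ch)
    m <- length(sel)
    if (m < 2) next
    starts <- unique(c(seq(1L, max(1L, m - 1L), by = step)))
    for (s in starts) {
      e <- min(s + window - 1L, m)
      idx <- sel[s:e]
      idx <- idx[keep[idx]]
      if (length(idx) < 2) next
      r <- suppressWarnings(cor(X[, idx, drop = FALSE], use = "pairwise.complete.obs"))
      r2 <- r^2
      for (a in seq_len(length(idx) - 1L)) {
        if (!keep[idx[a]]) next
        for (b in seq((a + 1L), length(idx))) {
          if (!keep[idx[b]]) next
          v <- r2[a, b]
          if (!is.na(v) && v > r2_max) keep[idx[b]] <- FALSE
        }
      }
      if (e == m) break
    }
  }
  which(keep)
}
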