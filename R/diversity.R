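#' Per-site nucleotide diversity
#'
#' Mean pairwise difference per site among called allele copies:
#' \code{2 * n_alt * (n_called - n_alt) / (n_called * (n_called - 1))}.
#' Sites with fewer than two called allele copies must be excluded by the
#' caller.
#'
#' @param n_alt alt allele copies (vectorised).
#' @param n_called called allele copies.
#' @return numeric vector of per-site pi.
#' @export
site_pi <- function(n_alt, n_called) {
  if (any(n_called < 2)) stop("site_pi requires n_called >= 2 (caller must exclude)")
  2 * n_alt * (n_called - n_alt) / (n_called * (n_called - 1))
}

#' Windowed nucleotide diversity (percent)
#'
#' Per window: 100 * (sum of per-site pi over SNPs in the window) divided by
#' the window span in bp, so the denominator includes invariant positions.
#' Windows are 40 kb wide with a 20 kb step, anchored at position 1.
#'
#' @param gm a [geno_matrix()].
#' @param pmap a [pop_map()]; NULL uses all samples.
#' @param population population label; NULL uses all samples.
#' @param chrom_lengths named vector of chromosome lengths; inferred from the
#'   data when NULL.
#' @param width,step window width and step (bp).
#' @return data.frame with \code{chrom}, \code{start}, \code{end},
#'   \code{n_snps}, \code{pi_percent}.
#' @export
windowed_pi <- function(gm, pmap = NULL, population = NULL, chrom_lengths = NULL,
                        width = 40000, step = 20000) {
  ac <- allele_counts(gm, pmap, population)
  pi <- rep(0, nrow(ac))
  ok <- ac$n_called >= 2
  pi[ok] <- site_pi(ac$n_alt[ok], ac$n_called[ok])
  lens <- infer_chrom_lengths(gm$variants, chrom_lengths)
  agg <- window_aggregate(gm$variants$chrom, gm$variants$pos, pi, lens, width, step)
  data.frame(chrom = agg$chrom, start = agg$start, end = agg$end, n_snps = agg$n,
             pi_percent = 100 * agg$sum / (agg$end - agg$start + 1),
             stringsAsFactors = FALSE)
}

#' Individual heterozygosity and method-of-moments inbreeding
#'
#' For each sample, over sites that are polymorphic among the called genotypes
#' of the supplied matrix and called in that sample: \code{O_hom} observed
#' homozygous calls, \code{E_hom} the sum of per-site expected homozygosity
#' \code{1 - 2p(1-p) n/(n-1)} (p and n from all called genotypes at the site),
#' \code{H_o = 1 - O_hom/S} and \code{F = (O_hom - E_hom) / (S - E_hom)}.
#' To reproduce per-population estimates, subset the matrix to one population
#' first.
#'
#' @param gm a [geno_matrix()] with at least two samples.
#' @return data.frame with \code{sample}, \code{S}, \code{O_hom}, \code{E_hom},
#'   \code{H_o}, \code{F} (NA when \code{S - E_hom} is 0).
#' @export
individual_het <- function(gm) {
  if (length(gm$samples) < 2) stop("individual_het needs >= 2 samples")
  ac <- allele_counts(gm)
  p <- ifelse(ac$n_called > 0, ac$n_alt / ac$n_called, NA_real_)
  poly <- !is.na(p) & p > 0 & p < 1 & ac$n_called >= 2
  n <- ac$n_called
  ehom_site <- 1 - 2 * p * (1 - p) * n / (n - 1)
  calls <- gm$calls[, poly, drop = FALSE]
  eh <- ehom_site[poly]
  called <- !is.na(calls)
  S <- rowSums(called)
  O_hom <- rowSums(calls == 0L | calls == 2L, na.rm = TRUE)
  E_hom <- as.vector(called %*% eh)
  denom <- S - E_hom
  data.frame(sample = gm$samples, S = S, O_hom = O_hom, E_hom = E_hom,
             H_o = ifelse(S > 0, 1 - O_hom / S, NA_real_),
             F = ifelse(abs(denom) > .Machine$double.eps * S, (O_hom - E_hom) / denom, NA_real_),
             row.names = NULL, stringsAsFactors = FALSE)
}

#' Population expected heterozygosity
#'
#' Mean over sites polymorphic within the population of the unbiased
#' heterozygosity \code{2p(1-p) n/(n-1)}.
#'
#' @inheritParams windowed_pi
#' @return a single numeric value; NA if the population has no polymorphic
#'   sites.
#' @export
population_he <- function(gm, pmap = NULL, population = NULL) {
  ac <- allele_counts(gm, pmap, population)
  p <- ifelse(ac$n_called > 0, ac$n_alt / ac$n_called, NA_real_)
  poly <- !is.na(p) & p > 0 & p < 1 & ac$n_called >= 2
  if (!any(poly)) return(NA_real_)
  n <- ac$n_called[poly]
  mean(2 * p[poly] * (1 - p[poly]) * n / (n - 1))
}

#' Shared/private SNP partition across populations
#'
#' Each SNP is assigned to the exact subset of populations in which it is
#' polymorphic (both alleles observed among called genotypes). SNPs
#' polymorphic nowhere are excluded.
#'
#' @param gm a [geno_matrix()].
#' @param pmap a [pop_map()].
#' @return list with \code{partition} (data.frame: populations key, n),
#'   \code{private} (named vector: SNPs private to each population) and
#'   \code{n_polymorphic} (SNPs polymorphic in at least one population).
#' @export
shared_private_partition <- function(gm, pmap) {
  pops <- unique(pop_labels_for(gm, pmap))
  if (length(pops) < 2) stop("need >= 2 populations")
  polym <- sapply(pops, function(pp) {
    ac <- allele_counts(gm, pmap, pp)
    ac$n_alt > 0 & ac$n_alt < ac$n_called
  })
  anywhere <- rowSums(polym) > 0
  key <- apply(polym[anywhere, , drop = FALSE], 1, function(z) paste(pops[z], collapse = "+"))
  tab <- table(key)
  partition <- data.frame(populations = names(tab), n = as.integer(tab),
                          row.names = NULL, stringsAsFactors = FALSE)
  private <- setNames(integer(length(pops)), pops)
  hit <- match(pops, partition$populations)
  private[!is.na(hit)] <- partition$n[hit[!is.na(hit)]]
  list(partition = partition, private = private, n_polymorphic = sum(anywhere))
}
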