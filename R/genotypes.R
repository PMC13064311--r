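#' Construct a genotype matrix object
#'
#' The central data container: diploid calls coded as alt-allele dosage
#' (0, 1, 2 or \code{NA} for missing) for \code{n} samples at \code{m}
#' biallelic-or-flagged variants, plus per-variant metadata.
#'
#' @param calls integer matrix, samples x variants, values in \{0, 1, 2, NA\}.
#' @param variants data.frame with at least \code{chrom}, \code{pos},
#'   \code{ref}, \code{alt}; optional \code{id}, \code{multiallelic},
#'   \code{ancestral} ("ref", "alt" or "unknown") and INFO annotation columns
#'   (\code{QD}, \code{QUAL}, \code{SOR}, \code{FS}, \code{MQ},
#'   \code{MQRankSum}, \code{ReadPosRankSum}).
#' @param samples character vector of sample identifiers (one per row of
#'   \code{calls}).
#' @param phased logical flag; TRUE only if every genotype separator in the
#'   source was phased.
#' @return an object of class \code{geno_matrix}.
#' @export
geno_matrix <- function(calls, variants, samples, phased = FALSE) {
  calls <- as.matrix(calls)
  storage.mode(calls) <- "integer"
  stopifnot(is.data.frame(variants), nrow(variants) == ncol(calls),
            length(samples) == nrow(calls))
  if (is.null(variants$id))
    variants$id <- if (nrow(variants)) paste0(variants$chrom, "_", variants$pos) else character(0)
  if (is.null(variants$multiallelic)) variants$multiallelic <- rep(FALSE, nrow(variants))
  if (is.null(variants$ancestral)) variants$ancestral <- rep("unknown", nrow(variants))
  variants$chrom <- as.character(variants$chrom)
  variants$pos <- as.integer(variants$pos)
  if (any(variants$pos < 1L)) stop("variant positions must be >= 1")
  bad <- !variants$multiallelic & variants$ref == variants$alt
  if (any(bad)) stop("ref and alt allele identical at variant ", which(bad)[1])
  ord <- order(factor(variants$chrom, levels = unique(variants$chrom)), variants$pos)
  variants <- variants[ord, , drop = FALSE]
  calls <- calls[, ord, drop = FALSE]
  rownames(variants) <- NULL
  for (ch in unique(variants$chrom)) {
    p <- variants$pos[variants$chrom == ch]
    if (anyDuplicated(p)) stop("duplicate positions on chromosome ", ch)
  }
  rng <- calls[!is.na(calls)]
  if (length(rng) && (min(rng) < 0L || max(rng) > 2L))
    stop("calls must be alt-allele dosages in {0, 1, 2, NA}")
  dimnames(calls) <- list(samples, variants$id)
  structure(list(calls = calls, variants = variants,
                 samples = as.character(samples), phased = isTRUE(phased)),
            class = "geno_matrix")
}

#' @export
print.geno_matrix <- function(x, ...) {
  cat(sprintf("geno_matrix: %d samples x %d variants (%s), %d chromosome(s)\n",
              length(x$samples), nrow(x$variants),
              if (x$phased) "phased" else "unphased",
              length(unique(x$variants$chrom))))
  mis <- mean(is.na(x$calls))
  cat(sprintf("  missing calls: %.2f%%; multi-allelic flagged: %d\n",
              100 * mis, sum(x$variants$multiallelic)))
  invisible(x)
}

#' @export
dim.geno_matrix <- function(x) dim(x$calls)

#' Number of variants in a genotype matrix
#' @param gm a [geno_matrix()].
#' @return integer count.
#' @export
n_variants <- function(gm) nrow(gm$variants)

#' Subset a genotype matrix
#'
#' @param gm a \code{geno_matrix}.
#' @param samples sample names (or indices) to keep; NULL keeps all.
#' @param variants variant indices (logical or integer) to keep; NULL keeps all.
#' @return a \code{geno_matrix}.
#' @export
gm_subset <- function(gm, samples = NULL, variants = NULL) {
  calls <- gm$calls
  smp <- gm$samples
  if (!is.null(samples)) {
    if (is.character(samples)) {
      idx <- match(samples, gm$samples)
      if (anyNA(idx)) stop("unknown sample(s): ", paste(samples[is.na(idx)], collapse = ", "))
    } else idx <- samples
    calls <- calls[idx, , drop = FALSE]
    smp <- gm$samples[idx]
  }
  vr <- gm$variants
  if (!is.null(variants)) {
    calls <- calls[, variants, drop = FALSE]
    vr <- vr[variants, , drop = FALSE]
    rownames(vr) <- NULL
  }
  geno_matrix(calls, vr, smp, gm$phased)
}

#' Read a sample-to-population map
#'
#' Two-column TSV without header: sample, population.
#'
#' @param path file path.
#' @return a \code{pop_map} data.frame with columns \code{sample}, \code{population}.
#' @export
read_popmap <- function(path) {
  df <- read.table(path, sep = "\t", header = FALSE, stringsAsFactors = FALSE,
                   col.names = c("sample", "population"))
  pop_map(df$sample, df$population)
}

#' Construct a population map
#'
#' @param samples sample identifiers.
#' @param populations population label per sample (non-empty).
#' @return a \code{pop_map} data.frame.
#' @export
pop_map <- function(samples, populations) {
  if (length(samples) != length(populations)) stop("samples/populations length mismatch")
  if (anyDuplicated(samples)) stop("duplicated sample in population map")
  populations <- as.character(populations)
  if (any(is.na(populations) | populations == "")) stop("population labels must be non-empty")
  structure(data.frame(sample = as.character(samples), population = populations,
                       stringsAsFactors = FALSE),
            class = c("pop_map", "data.frame"))
}

# validate that every sample of gm is assigned; return vector of labels in gm order
pop_labels_for <- function(gm, pmap) {
  idx <- match(gm$samples, pmap$sample)
  if (anyNA(idx)) stop("population map misses sample(s): ",
                       paste(gm$samples[is.na(idx)][1:min(3, sum(is.na(idx)))], collapse = ", "))
  pmap$population[idx]
}

pop_sample_idx <- function(gm, pmap, population) {
  labs <- pop_labels_for(gm, pmap)
  if (!population %in% labs) stop("unknown population: ", population)
  which(labs == population)
}

#' Per-site allele counts within a population
#'
#' Counts are over called genotypes only.
#'
#' @param gm a \code{geno_matrix}.
#' @param pmap a \code{pop_map}; NULL counts over all samples.
#' @param population population label; NULL counts over all samples.
#' @return data.frame with per-site \code{n_alt} (alt allele copies) and
#'   \code{n_called} (called allele copies, 2 per called genotype).
#' @export
allele_counts <- function(gm, pmap = NULL, population = NULL) {
  if (!is.null(population)) {
    idx <- pop_sample_idx(gm, pmap, population)
    calls <- gm$calls[idx, , drop = FALSE]
  } else calls <- gm$calls
  n_alt <- colSums(calls, na.rm = TRUE)
  n_called <- 2L * colSums(!is.na(calls))
  data.frame(n_alt = as.integer(n_alt), n_called = as.integer(n_called))
}

#' Construct a phased haplotype set
#'
#' Haplotypes are rows (two consecutive rows per sample), alleles coded
#' 0 = ancestral, 1 = derived when the ancestral allele is known, otherwise
#' 0 = ref, 1 = alt with \code{ancestral == "unknown"} recorded per variant.
#'
#' @param haps integer 0/1 matrix, (2 x n_samples) x n_variants.
#' @param variants variant metadata data.frame (as in [geno_matrix()]).
#' @param samples sample identifiers; haplotype rows 2i-1, 2i belong to sample i.
#' @return an object of class \code{haplo_set}.
#' @export
haplo_set <- function(haps, variants, samples) {
  haps <- as.matrix(haps)
  storage.mode(haps) <- "integer"
  stopifnot(nrow(haps) == 2L * length(samples), ncol(haps) == nrow(variants))
  if (!all(haps %in% c(0L, 1L))) stop("haplotype alleles must be 0/1")
  if (is.null(variants$ancestral)) variants$ancestral <- "ref"
  ord <- order(factor(variants$chrom, levels = unique(variants$chrom)), variants$pos)
  haps <- haps[, ord, drop = FALSE]
  variants <- variants[ord, , drop = FALSE]
  rownames(variants) <- NULL
  structure(list(haps = haps, variants = variants, samples = as.character(samples),
                 sample_of_hap = rep(as.character(samples), each = 2L)),
            class = "haplo_set")
}

#' @export
print.haplo_set <- function(x, ...) {
  cat(sprintf("haplo_set: %d haplotypes (%d samples) x %d variants\n",
              nrow(x$haps), length(x$samples), ncol(x$haps)))
  invisible(x)
}

# genotype matrix implied by a haplotype set
hs_to_gm <- function(hs, phased = TRUE) {
  n <- length(hs$samples)
  calls <- hs$haps[seq(1, 2 * n, by = 2), , drop = FALSE] +
    hs$haps[seq(2, 2 * n, by = 2), , drop = FALSE]
  geno_matrix(calls, hs$variants, hs$samples, phased = phased)
}

hs_subset <- function(hs, samples = NULL, variants = NULL) {
  smp <- hs$samples
  haps <- hs$haps
  if (!is.null(samples)) {
    idx <- if (is.character(samples)) match(samples, hs$samples) else samples
    if (anyNA(idx)) stop("unknown sample(s) in haplo_set subset")
    rows <- as.vector(rbind(2L * idx - 1L, 2L * idx))
    haps <- haps[rows, , drop = FALSE]
    smp <- hs$samples[idx]
  }
  vr <- hs$variants
  if (!is.null(variants)) {
    haps <- haps[, variants, drop = FALSE]
    vr <- vr[variants, , drop = FALSE]
    rownames(vr) <- NULL
  }
  haplo_set(haps, vr, smp)
}
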