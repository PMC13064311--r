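#' Default ROH HMM parameters
#'
#' \code{e_het}: probability of observing a heterozygous call inside an
#' autozygous segment (genotyping error / mutation); \code{t_in}: per-bp rate
#' of entering the autozygous state; \code{t_out}: per-bp rate of leaving it.
#' The rate defaults put the expected autozygous segment length in the Mb
#' range.
#'
#' @return named list.
#' @export
roh_params <- function(e_het = 1e-3, t_in = 1e-8, t_out = 1e-7) {
  list(e_het = e_het, t_in = t_in, t_out = t_out)
}

# Viterbi path for one sample / chromosome (0 = normal, 1 = autozygous);
# exported via the compiled core, thin R wrapper kept for oracle tests
roh_decode <- function(het, pos, p, params = roh_params()) {
  stopifnot(length(het) == length(pos), length(p) == length(pos))
  roh_viterbi_cpp(as.integer(het), as.numeric(pos), as.numeric(p),
                  params$e_het, params$t_in, params$t_out)
}

#' Detect runs of homozygosity with a two-state HMM
#'
#' Viterbi decoding of a NORMAL/AUTOZYGOUS hidden state per sample and
#' chromosome. Emission probabilities use the alt-allele frequency within the
#' sample's own population; sites monomorphic in that population are
#' uninformative and excluded before decoding, and missing calls are skipped
#' (inter-marker distance accumulates across them). Segment coordinates are
#' the first and last SNP positions of each maximal autozygous run.
#'
#' @param gm a [geno_matrix()].
#' @param pmap a [pop_map()]; NULL treats all samples as one population.
#' @param params HMM parameters, see [roh_params()].
#' @param min_sites minimum called informative sites per chromosome to attempt
#'   decoding (default 10).
#' @return data.frame with \code{sample}, \code{chrom}, \code{start},
#'   \code{end}, \code{length} (bp, end - start + 1) and \code{n_snps}.
#' @export
detect_roh <- function(gm, pmap = NULL, params = roh_params(), min_sites = 10) {
  labs <- if (is.null(pmap)) rep("all", length(gm$samples)) else pop_labels_for(gm, pmap)
  out <- vector("list", 0)
  for (pp in unique(labs)) {
    idx <- which(labs == pp)
    sub <- gm_subset(gm, samples = idx)
    ac <- allele_counts(sub)
    p <- ifelse(ac$n_called > 0, ac$n_alt / ac$n_called, NA_real_)
    informative <- !is.na(p) & p > 0 & p < 1
    for (s in seq_along(idx)) {
      calls <- sub$calls[s, ]
      use0 <- informative & !is.na(calls)
      for (ch in unique(sub$variants$chrom)) {
        use <- use0 & sub$variants$chrom == ch
        if (sum(use) < min_sites) next
        pos <- sub$variants$pos[use]
        het <- as.integer(calls[use] == 1L)
        path <- roh_decode(het, pos, p[use], params)
        r <- rle(path)
        ends <- cumsum(r$lengths)
        starts <- ends - r$lengths + 1L
        auto <- which(r$values == 1L)
        if (!length(auto)) next
        out[[length(out) + 1]] <- data.frame(
          sample = sub$samples[s], chrom = ch,
          start = pos[starts[auto]], end = pos[ends[auto]],
          n_snps = r$lengths[auto], stringsAsFactors = FALSE)
      }
    }
  }
  if (!length(out))
    return(data.frame(sample = character(), chrom = character(), start = integer(),
                      end = integer(), length = integer(), n_snps = integer(),
                      stringsAsFactors = FALSE))
  seg <- do.call(rbind, out)
  seg$length <- seg$end - seg$start + 1L
  seg[, c("sample", "chrom", "start", "end", "length", "n_snps")]
}

#' Filter ROH segments by length and SNP count
#'
#' Keeps segments with \code{length >= min_len} AND \code{n_snps >= min_snps}
#' (inclusive bounds).
#'
#' @param segments data.frame from [detect_roh()].
#' @param min_len minimum segment length in bp (default 300 kb).
#' @param min_snps minimum SNPs per segment (default 10).
#' @return filtered data.frame.
#' @export
filter_roh <- function(segments, min_len = 300000, min_snps = 10) {
  segments[segments$length >= min_len & segments$n_snps >= min_snps, , drop = FALSE]
}

ROH_CLASS_BREAKS <- c(0.3, 1, 2, 4, 8, 10, 16, Inf)  # Mb
ROH_CLASS_LABELS <- c("0.3-1Mb", "1-2Mb", "2-4Mb", "4-8Mb", "8-10Mb", "10-16Mb", ">16Mb")

#' Per-population ROH summary with length classes
#'
#' Mean number of ROH segments per individual in the length classes
#' 0.3-1, 1-2, 2-4, 4-8, 8-10, 10-16 and >16 Mb, plus min/max/mean segment
#' length, total length, mean and SD of per-individual total length and mean
#' segment count. Per-individual means are taken over all individuals of a
#' population, including those without any segment.
#'
#' @param segments filtered ROH segments.
#' @param pmap a [pop_map()] listing every individual (zero-carriers count).
#' @return data.frame, one row per population.
#' @export
classify_roh <- function(segments, pmap) {
  pops <- unique(pmap$population)
  mb <- segments$length / 1e6
  cls <- cut(mb, ROH_CLASS_BREAKS, right = FALSE, labels = ROH_CLASS_LABELS)
  rows <- lapply(pops, function(pp) {
    ids <- pmap$sample[pmap$population == pp]
    seg <- segments[segments$sample %in% ids, , drop = FALSE]
    n_ind <- length(ids)
    cl <- cls[segments$sample %in% ids]
    class_means <- as.numeric(table(cl)) / n_ind
    per_ind <- setNames(rep(0, n_ind), ids)
    if (nrow(seg)) {
      tot <- tapply(seg$length, seg$sample, sum)
      per_ind[names(tot)] <- tot
    }
    data.frame(population = pp, n_individuals = n_ind,
               t(setNames(class_means, paste0("class_", seq_along(ROH_CLASS_LABELS)))),
               min_mb = if (nrow(seg)) min(seg$length) / 1e6 else NA_real_,
               max_mb = if (nrow(seg)) max(seg$length) / 1e6 else NA_real_,
               mean_mb = if (nrow(seg)) mean(seg$length) / 1e6 else NA_real_,
               total_mb = sum(per_ind) / 1e6,
               mean_total_mb = mean(per_ind) / 1e6,
               sd_total_mb = sd(per_ind) / 1e6,
               mean_n = nrow(seg) / n_ind,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  attr(out, "class_labels") <- ROH_CLASS_LABELS
  out
}

#' ROH-based inbreeding coefficient per sample
#'
#' \code{F_ROH} = total length of the sample's ROH segments divided by the
#' autosomal genome size (960.8 Mb in chicken by default).
#'
#' @param segments filtered ROH segments.
#' @param samples sample identifiers to report (zero-carriers get 0);
#'   defaults to the samples present in \code{segments}.
#' @param genome_size autosomal genome size in bp (default 960,800,000).
#' @return data.frame with \code{sample}, \code{total_bp}, \code{f_roh}.
#' @export
f_roh <- function(segments, samples = NULL, genome_size = 960800000) {
  stopifnot(genome_size > 0)
  if (is.null(samples)) samples <- unique(segments$sample)
  tot <- setNames(rep(0, length(samples)), samples)
  if (nrow(segments)) {
    agg <- tapply(segments$length, segments$sample, sum)
    agg <- agg[names(agg) %in% samples]
    tot[names(agg)] <- agg
  }
  data.frame(sample = samples, total_bp = as.numeric(tot),
             f_roh = as.numeric(tot) / genome_size,
             row.names = NULL, stringsAsFactors = FALSE)
}
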