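# Sliding-window grid: windows of `width` bp every `step` bp, anchored at
# position 1 of each chromosome, last window truncated at the chromosome end.
# With the default 40 kb / 20 kb design each position falls in up to two
# windows.

#' Sliding-window grid for a set of chromosomes
#'
#' @param chrom_lengths named numeric vector of chromosome lengths (bp).
#' @param width window width in bp (default 40000).
#' @param step step size in bp (default 20000).
#' @return data.frame with \code{chrom}, \code{start}, \code{end} (1-based
#'   inclusive).
#' @export
window_grid <- function(chrom_lengths, width = 40000, step = 20000) {
  stopifnot(!is.null(names(chrom_lengths)), width > 0, step > 0)
  out <- lapply(names(chrom_lengths), function(ch) {
    len <- chrom_lengths[[ch]]
    starts <- seq(1, len, by = step)
    data.frame(chrom = ch, start = starts, end = pmin(starts + width - 1, len),
               stringsAsFactors = FALSE)
  })
  do.call(rbind, out)
}

# chromosome lengths implied by the data unless supplied
infer_chrom_lengths <- function(variants, chrom_lengths = NULL) {
  if (!is.null(chrom_lengths)) return(chrom_lengths)
  tapply(variants$pos, factor(variants$chrom, levels = unique(variants$chrom)), max)
}

# aggregate a per-SNP statistic onto the window grid of one chromosome;
# every SNP contributes to every window containing its position.
# returns data.frame(start, end, n, sum, mean)
window_aggregate_chrom <- function(pos, value, chrom_len, width, step) {
  starts <- seq(1, chrom_len, by = step)
  n_win <- length(starts)
  kmin <- pmax(0, ceiling((pos - width) / step))
  kmax <- pmin(floor((pos - 1) / step), n_win - 1)
  reps <- pmax(0L, kmax - kmin + 1L)
  snp_i <- rep(seq_along(pos), reps)
  win_k <- unlist(lapply(seq_along(pos), function(i)
    if (reps[i] > 0) seq(kmin[i], kmax[i]) else integer()), use.names = FALSE)
  n <- tabulate(win_k + 1L, nbins = n_win)
  ok <- !is.na(value)
  sums <- rep(0, n_win)
  n_def <- integer(n_win)
  if (length(win_k)) {
    vv <- value[snp_i]
    def <- !is.na(vv)
    if (any(def)) {
      agg <- rowsum(vv[def], win_k[def] + 1L)
      sums[as.integer(rownames(agg))] <- agg[, 1]
      n_def <- tabulate((win_k + 1L)[def], nbins = n_win)
    }
  }
  data.frame(start = starts, end = pmin(starts + width - 1, chrom_len),
             n = n, n_defined = n_def, sum = sums,
             mean = ifelse(n_def > 0, sums / n_def, NA_real_))
}

window_aggregate <- function(chrom, pos, value, chrom_lengths, width, step) {
  out <- lapply(names(chrom_lengths), function(ch) {
    sel <- chrom == ch
    df <- window_aggregate_chrom(pos[sel], value[sel], chrom_lengths[[ch]], width, step)
    cbind(chrom = ch, df, stringsAsFactors = FALSE)
  })
  do.call(rbind, out)
}
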