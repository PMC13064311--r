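hs_raw <- function(hs) matrix(as.raw(hs$haps), nrow(hs$haps))

hap_rows <- function(hs, samples) {
  idx <- match(samples, hs$samples)
  if (anyNA(idx)) stop("unknown sample(s) in haplotype set")
  as.vector(rbind(2L * idx - 1L, 2L * idx))
}

#' Extended haplotype homozygosity around a core SNP
#'
#' EHH at marker distance x from the core is the probability that two randomly
#' chosen carrier haplotypes are identical over all markers between the core
#' (exclusive) and x (inclusive); it starts at 1 at the core and is
#' non-increasing outward. The curve is truncated at the first marker where
#' EHH drops below \code{ehh_floor} on each flank.
#'
#' @param hs a [haplo_set()] (one chromosome's worth of markers is used:
#'   the core's chromosome).
#' @param core_index variant index of the core SNP.
#' @param focal_allele "ancestral", "derived" (carriers of that core allele;
#'   needs known ancestral state) or "all" (every haplotype of the selected
#'   samples, allele-agnostic as used by XP-EHH).
#' @param samples restrict to these samples (default all).
#' @param ehh_floor truncation level (default 0.05).
#' @return object of class \code{ehh_curve}: data.frame with \code{pos},
#'   \code{ehh}, \code{side} ("left"/"core"/"right") plus attributes
#'   \code{core_pos}, \code{n_carriers}, \code{floor}.
#' @export
ehh <- function(hs, core_index, focal_allele = c("derived", "ancestral", "all"),
                samples = NULL, ehh_floor = 0.05) {
  focal_allele <- match.arg(focal_allele)
  ch <- hs$variants$chrom[core_index]
  on_ch <- which(hs$variants$chrom == ch)
  core <- match(core_index, on_ch)
  rows <- if (is.null(samples)) seq_len(nrow(hs$haps)) else hap_rows(hs, samples)
  if (focal_allele != "all") {
    if (hs$variants$ancestral[core_index] == "unknown")
      stop("ancestral state unknown at the core SNP")
    want <- if (focal_allele == "derived") 1L else 0L
    rows <- rows[hs$haps[rows, core_index] == want]
  }
  if (length(rows) < 2) stop("fewer than 2 carriers of the focal allele")
  hsub <- hs$haps[rows, on_ch, drop = FALSE]
  res <- ehh_core_cpp(matrix(as.raw(hsub), nrow(hsub)), seq_along(rows) - 1L,
                      core - 1L, ehh_floor)
  pos <- hs$variants$pos[on_ch]
  nl <- length(res$left_idx)
  nr <- length(res$right_idx)
  df <- rbind(
    data.frame(pos = rev(pos[res$left_idx + 1L]), ehh = rev(res$left_ehh),
               side = rep("left", nl)),
    data.frame(pos = pos[core], ehh = 1, side = "core"),
    data.frame(pos = pos[res$right_idx + 1L], ehh = res$right_ehh,
               side = rep("right", nr)))
  structure(df, class = c("ehh_curve", "data.frame"),
            core_pos = pos[core], n_carriers = length(rows), floor = ehh_floor)
}

#' Integrated EHH (area under the curve)
#'
#' Trapezoidal integral of EHH against physical position over both flanks,
#' each truncated where EHH falls below the curve's floor; flank
#' contributions are summed. Units: bp x EHH.
#'
#' @param curve an \code{ehh_curve} from [ehh()].
#' @return numeric iHH value.
#' @export
ihh <- function(curve) {
  floor_val <- attr(curve, "floor")
  core_pos <- attr(curve, "core_pos")
  total <- 0
  for (sd in c("left", "right")) {
    seg <- curve[curve$side == sd, , drop = FALSE]
    if (sd == "left") seg <- seg[rev(seq_len(nrow(seg))), , drop = FALSE]
    prev_e <- 1; prev_p <- core_pos
    for (i in seq_len(nrow(seg))) {
      if (seg$ehh[i] < floor_val) break
      total <- total + 0.5 * (seg$ehh[i] + prev_e) * abs(seg$pos[i] - prev_p)
      prev_e <- seg$ehh[i]; prev_p <- seg$pos[i]
    }
  }
  total
}

scan_chrom_split <- function(hs) split(seq_len(nrow(hs$variants)), hs$variants$chrom)

#' iHS scan within one population
#'
#' Per eligible core SNP (known ancestral state, minor allele frequency >=
#' \code{maf_min} among the population's haplotypes): raw iHS =
#' \code{ln(iHH_ancestral / iHH_derived)}, standardised within
#' derived-allele-frequency bins of width \code{freq_bin_width} (subtract bin
#' mean, divide by bin SD; bins with < 2 values give NA). SNPs where either
#' allele has iHH 0 or fewer than 2 carriers are skipped.
#'
#' @param hs a phased, ancestrally oriented [haplo_set()].
#' @param pmap a [pop_map()]; NULL uses all samples.
#' @param population population label; NULL uses all samples.
#' @param maf_min minor allele frequency floor (default 0.05).
#' @param freq_bin_width standardisation bin width (default 0.025).
#' @param ehh_floor EHH truncation (default 0.05).
#' @param max_gap truncate flanks at inter-marker gaps larger than this
#'   (bp; 0 disables, the default).
#' @return score track data.frame: \code{chrom}, \code{pos}, \code{id},
#'   \code{freq_derived}, \code{raw}, \code{std}; attribute
#'   \code{statistic = "iHS"}.
#' @export
ihs_scan <- function(hs, pmap = NULL, population = NULL, maf_min = 0.05,
                     freq_bin_width = 0.025, ehh_floor = 0.05, max_gap = 0) {
  if (!is.null(population)) {
    keep <- pmap$sample[pmap$population == population]
    hs <- hs_subset(hs, samples = intersect(hs$samples, keep))
  }
  nh <- nrow(hs$haps)
  if (nh < 4) stop("population too small for an iHS scan")
  freq <- colMeans(hs$haps)
  maf <- pmin(freq, 1 - freq)
  eligible <- hs$variants$ancestral != "unknown" & maf >= maf_min
  out <- vector("list", 0)
  for (idx in scan_chrom_split(hs)) {
    el <- which(eligible[idx])
    if (!length(el)) next
    hsub <- hs$haps[, idx, drop = FALSE]
    poly <- freq[idx] > 0 & freq[idx] < 1
    res <- ihs_ihh_cpp(matrix(as.raw(hsub), nh), as.numeric(hs$variants$pos[idx]),
                       el - 1L, ehh_floor, max_gap, poly)
    raw <- ifelse(is.na(res[, 1]) | is.na(res[, 2]) | res[, 1] <= 0 | res[, 2] <= 0,
                  NA_real_, log(res[, 1] / res[, 2]))
    out[[length(out) + 1]] <- data.frame(
      chrom = hs$variants$chrom[idx][el], pos = hs$variants$pos[idx][el],
      id = hs$variants$id[idx][el], freq_derived = freq[idx][el],
      raw = raw, stringsAsFactors = FALSE)
  }
  track <- do.call(rbind, out)
  if (is.null(track) || !nrow(track)) stop("no eligible core SNPs")
  bin <- pmin(floor(track$freq_derived / freq_bin_width),
              ceiling(1 / freq_bin_width) - 1)
  track$std <- NA_real_
  for (b in unique(bin)) {
    sel <- which(bin == b & !is.na(track$raw))
    if (length(sel) < 2) next
    s <- sd(track$raw[sel])
    if (s == 0) next
    track$std[sel] <- (track$raw[sel] - mean(track$raw[sel])) / s
  }
  attr(track, "statistic") <- "iHS"
  track
}

#' XP-EHH scan between two populations
#'
#' Per core SNP, allele-agnostic EHH is computed over all haplotypes within
#' each population; raw XP-EHH = \code{ln(iHH_A / iHH_B)}, standardised
#' genome-wide. Positive standardised scores indicate longer haplotypes
#' (a sweep) in \code{pop_a}, the first-named reference population.
#'
#' @param hs a phased [haplo_set()].
#' @param pmap a [pop_map()].
#' @param pop_a,pop_b population labels (>= 2 diploids each).
#' @param ehh_floor,max_gap as in [ihs_scan()].
#' @return score track data.frame as in [ihs_scan()], attribute
#'   \code{statistic = "XPEHH"}.
#' @export
xpehh_scan <- function(hs, pmap, pop_a, pop_b, ehh_floor = 0.05, max_gap = 0) {
  rows_a <- hap_rows(hs, intersect(hs$samples, pmap$sample[pmap$population == pop_a]))
  rows_b <- hap_rows(hs, intersect(hs$samples, pmap$sample[pmap$population == pop_b]))
  if (length(rows_a) < 4 || length(rows_b) < 4)
    stop("both populations need >= 2 diploids")
  out <- vector("list", 0)
  for (idx in scan_chrom_split(hs)) {
    hsub <- hs$haps[, idx, drop = FALSE]
    hraw <- matrix(as.raw(hsub), nrow(hsub))
    pos <- as.numeric(hs$variants$pos[idx])
    cores <- seq_along(idx) - 1L
    ca <- colSums(hsub[rows_a, , drop = FALSE])
    cb <- colSums(hsub[rows_b, , drop = FALSE])
    ia <- pop_ihh_cpp(hraw, pos, rows_a - 1L, cores, ehh_floor, max_gap,
                      ca > 0 & ca < length(rows_a))
    ib <- pop_ihh_cpp(hraw, pos, rows_b - 1L, cores, ehh_floor, max_gap,
                      cb > 0 & cb < length(rows_b))
    raw <- ifelse(ia <= 0 | ib <= 0, NA_real_, log(ia / ib))
    out[[length(out) + 1]] <- data.frame(
      chrom = hs$variants$chrom[idx], pos = hs$variants$pos[idx],
      id = hs$variants$id[idx], freq_derived = colMeans(hsub),
      raw = raw, stringsAsFactors = FALSE)
  }
  track <- do.call(rbind, out)
  ok <- !is.na(track$raw)
  mu <- mean(track$raw[ok]); s <- sd(track$raw[ok])
  track$std <- ifelse(ok & s > 0, (track$raw - mu) / s, NA_real_)
  attr(track, "statistic") <- "XPEHH"
  track
}

#' Windowed absolute score aggregation
#'
#' Mean of |standardised score| over scored SNPs in 40 kb windows with a 20 kb
#' step; windows with fewer than \code{min_snps} scored SNPs are dropped, not
#' zeroed.
#'
#' @param track a score track from [ihs_scan()] or [xpehh_scan()].
#' @param chrom_lengths optional named chromosome lengths.
#' @param width,step window width and step (bp).
#' @param min_snps minimum scored SNPs per window (default 10).
#' @return data.frame with \code{chrom}, \code{start}, \code{end},
#'   \code{n_snps}, \code{score} (mean |std|).
#' @export
window_scores <- function(track, chrom_lengths = NULL, width = 40000,
                          step = 20000, min_snps = 10) {
  if (!nrow(track)) stop("empty score track")
  lens <- infer_chrom_lengths(track[, c("chrom", "pos")], chrom_lengths)
  agg <- window_aggregate(track$chrom, track$pos, abs(track$std), lens, width, step)
  keep <- agg$n_defined >= min_snps
  data.frame(chrom = agg$chrom[keep], start = agg$start[keep], end = agg$end[keep],
             n_snps = agg$n_defined[keep], score = agg$mean[keep],
             stringsAsFactors = FALSE)
}

#' Empirical top-fraction outlier windows
#'
#' The threshold is the nearest-rank (1 - top_fraction) quantile of the window
#' scores; windows strictly above it are flagged.
#'
#' @param windows data.frame from [window_scores()].
#' @param top_fraction fraction to flag (default 0.001, i.e. the top 0.1\%).
#' @return list with \code{threshold} and \code{flagged} (subset of
#'   \code{windows}).
#' @export
call_candidates <- function(windows, top_fraction = 0.001) {
  w <- nrow(windows)
  if (w < 1 / top_fraction)
    warning("fewer than 1/top_fraction windows; the empirical quantile is coarse")
  v <- sort(windows$score)
  thr <- v[ceiling((1 - top_fraction) * w)]
  flagged <- windows[windows$score > thr, , drop = FALSE]
  if (!nrow(flagged)) warning("no window exceeds the empirical threshold")
  list(threshold = thr, flagged = flagged)
}

#' Merge flagged windows into sweep regions
#'
#' Windows whose intervals overlap or abut (gap of 0 bp) are unioned;
#' windows separated by at least one base remain separate regions.
#'
#' @param flagged flagged windows (from [call_candidates()]).
#' @param track optional score track used for the direction summary (fraction
#'   of scored SNPs in the region with positive raw score).
#' @return data.frame with \code{chrom}, \code{start}, \code{end},
#'   \code{n_windows}, \code{max_score}, \code{mean_score},
#'   \code{frac_positive} (NA without a track).
#' @export
merge_regions <- function(flagged, track = NULL) {
  if (!nrow(flagged))
    return(data.frame(chrom = character(), start = integer(), end = integer(),
                      n_windows = integer(), max_score = numeric(),
                      mean_score = numeric(), frac_positive = numeric()))
  flagged <- flagged[order(flagged$chrom, flagged$start), , drop = FALSE]
  out <- list()
  cur <- flagged[1, ]
  members <- cur$score
  flush <- function(cur, members) {
    fp <- NA_real_
    if (!is.null(track)) {
      sel <- track$chrom == cur$chrom & track$pos >= cur$start & track$pos <= cur$end &
        !is.na(track$std)
      if (any(sel)) fp <- mean(track$raw[sel] > 0)
    }
    data.frame(chrom = cur$chrom, start = cur$start, end = cur$end,
               n_windows = length(members), max_score = max(members),
               mean_score = mean(members), frac_positive = fp,
               stringsAsFactors = FALSE)
  }
  for (i in seq_len(nrow(flagged))[-1]) {
    w <- flagged[i, ]
    if (w$chrom == cur$chrom && w$start <= cur$end + 1) {
      cur$end <- max(cur$end, w$end)
      members <- c(members, w$score)
    } else {
      out[[length(out) + 1]] <- flush(cur, members)
      cur <- w
      members <- w$score
    }
  }
  out[[length(out) + 1]] <- flush(cur, members)
  do.call(rbind, out)
}

#' Read gene/QTL feature intervals from BED or GFF3
#'
#' BED (0-based half-open) and GFF3 (1-based inclusive) are both normalised to
#' 1-based inclusive coordinates.
#'
#' @param path file path; format guessed from the extension unless given.
#' @param format "auto", "bed" or "gff3".
#' @return data.frame with \code{chrom}, \code{start}, \code{end},
#'   \code{label}.
#' @export
read_features <- function(path, format = c("auto", "bed", "gff3")) {
  format <- match.arg(format)
  if (format == "auto")
    format <- if (grepl("\\.bed(\\.gz)?$", path, ignore.case = TRUE)) "bed" else "gff3"
  gr <- rtracklayer::import(path, format = if (format == "bed") "BED" else "GFF3")
  md <- as.data.frame(gr)
  label <- if (!is.null(md$Name)) as.character(md$Name)
           else if (!is.null(md$name)) as.character(md$name)
           else if (!is.null(md$ID)) as.character(md$ID)
           else paste0("feature_", seq_along(gr))
  label[is.na(label) | label == ""] <- paste0("feature_", which(is.na(label) | label == ""))
  data.frame(chrom = as.character(GenomicRanges::seqnames(gr)),
             start = GenomicRanges::start(gr), end = GenomicRanges::end(gr),
             label = label, stringsAsFactors = FALSE)
}

#' Annotate sweep regions with overlapping or nearest features
#'
#' Every feature overlapping a region is reported; a region without overlap is
#' flagged "gene void" and annotated with the nearest feature(s) by edge
#' distance (ties all reported).
#'
#' @param regions data.frame from [merge_regions()].
#' @param features data.frame from [read_features()] (or with the same
#'   columns), sorted or not.
#' @return \code{regions} with added columns \code{features}
#'   (comma-separated labels), \code{gene_void} and \code{nearest_distance}
#'   (NA when overlapping).
#' @export
annotate_regions <- function(regions, features) {
  if (!nrow(regions)) {
    regions$features <- character(0); regions$gene_void <- logical(0)
    regions$nearest_distance <- numeric(0)
    return(regions)
  }
  unknown <- setdiff(unique(features$chrom), unique(regions$chrom))
  if (length(unknown))
    warning("features on chromosome(s) absent from the regions: ",
            paste(head(unknown, 3), collapse = ", "))
  rg <- GenomicRanges::GRanges(regions$chrom, IRanges::IRanges(regions$start, regions$end))
  fg <- GenomicRanges::GRanges(features$chrom, IRanges::IRanges(features$start, features$end))
  ov <- GenomicRanges::findOverlaps(rg, fg)
  regions$features <- ""
  regions$gene_void <- TRUE
  regions$nearest_distance <- NA_real_
  if (length(ov)) {
    sp <- split(features$label[S4Vectors::subjectHits(ov)], S4Vectors::queryHits(ov))
    for (q in names(sp)) {
      qi <- as.integer(q)
      regions$features[qi] <- paste(unique(sp[[q]]), collapse = ",")
      regions$gene_void[qi] <- FALSE
    }
  }
  for (i in which(regions$gene_void)) {
    same <- which(features$chrom == regions$chrom[i])
    if (!length(same)) next
    d <- pmax(features$start[same] - regions$end[i], regions$start[i] - features$end[same], 0)
    dm <- min(d)
    regions$features[i] <- paste(unique(features$label[same][d == dm]), collapse = ",")
    regions$nearest_distance[i] <- dm
  }
  regions
}
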