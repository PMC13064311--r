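#' Per-population summary statistics
#'
#' Assembles the per-population table of a multi-population study: number of
#' SNPs polymorphic within the population, mean and SD of individual observed
#' heterozygosity and method-of-moments F (computed per population by
#' subsetting first), expected heterozygosity, mean and SD of F_ROH, and mean
#' and SD of windowed nucleotide diversity (percent). Means and SDs are over
#' individuals (or windows for pi), with the sample (n-1) SD.
#'
#' @param gm a filtered [geno_matrix()].
#' @param pmap a [pop_map()].
#' @param roh_segments filtered ROH segments (from [filter_roh()]); NULL skips
#'   the F_ROH columns.
#' @param genome_size autosomal genome size for F_ROH (bp).
#' @param chrom_lengths optional chromosome lengths for the pi windows.
#' @return data.frame, one row per population.
#' @export
population_summary <- function(gm, pmap, roh_segments = NULL,
                               genome_size = 960800000, chrom_lengths = NULL) {
  pops <- unique(pop_labels_for(gm, pmap))
  rows <- lapply(pops, function(pp) {
    idx <- pop_sample_idx(gm, pmap, pp)
    sub <- gm_subset(gm, samples = idx)
    ac <- allele_counts(sub)
    n_snp <- sum(ac$n_alt > 0 & ac$n_alt < ac$n_called)
    het <- individual_het(sub)
    pi <- windowed_pi(sub, chrom_lengths = chrom_lengths)
    fr <- if (!is.null(roh_segments))
      f_roh(roh_segments[roh_segments$sample %in% sub$samples, , drop = FALSE],
            samples = sub$samples, genome_size = genome_size)$f_roh
    else NA_real_
    data.frame(population = pp, n_individuals = length(idx), n_snp = n_snp,
               ho_mean = mean(het$H_o, na.rm = TRUE), ho_sd = sd(het$H_o),
               he = population_he(sub),
               f_mean = mean(het$F, na.rm = TRUE), f_sd = sd(het$F),
               froh_mean = mean(fr), froh_sd = sd(fr),
               pi_mean = mean(pi$pi_percent), pi_sd = sd(pi$pi_percent),
               stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}

#' ROH class table with internal arithmetic checks
#'
#' Emits the per-population ROH length-class table (see [classify_roh()]) and
#' verifies its internal identities: the class means sum to the mean segment
#' count; total length over individuals equals the mean per-individual total;
#' total length over (individuals x mean count) equals the mean segment
#' length; and mean F_ROH equals mean total length over the genome size.
#'
#' @param segments filtered ROH segments.
#' @param pmap a [pop_map()].
#' @param genome_size autosomal genome size in bp.
#' @return list with \code{table} (the class table, plus \code{froh_mean}) and
#'   \code{checks} (data.frame of identity checks, all exact before rounding).
#' @export
roh_table <- function(segments, pmap, genome_size = 960800000) {
  tab <- classify_roh(segments, pmap)
  tab$froh_mean <- tab$mean_total_mb * 1e6 / genome_size
  checks <- roh_table_checks(tab, genome_size = genome_size, tol = 1e-9)
  list(table = tab, checks = checks)
}

# identity checks on a (possibly transcribed, hence rounded) ROH class table
roh_table_checks <- function(tab, genome_size = 960800000, tol = 1e-9,
                             tol_sum = tol, tol_ratio = tol) {
  cls <- grep("^class_", names(tab), value = TRUE)
  out <- list()
  for (i in seq_len(nrow(tab))) {
    pp <- tab$population[i]
    add <- function(check, value, expected, tolerance)
      data.frame(population = pp, check = check, value = value,
                 expected = expected, tol = tolerance,
                 pass = is.finite(value) && is.finite(expected) &&
                   abs(value - expected) <= tolerance,
                 stringsAsFactors = FALSE)
    out[[length(out) + 1]] <- add("class_means_sum_to_mean_n",
                                  sum(unlist(tab[i, cls])), tab$mean_n[i], tol_sum)
    out[[length(out) + 1]] <- add("total_over_n_is_mean_total",
                                  tab$total_mb[i] / tab$n_individuals[i],
                                  tab$mean_total_mb[i], tol_ratio)
    out[[length(out) + 1]] <- add("mean_total_over_mean_n_is_mean_len",
                                  tab$mean_total_mb[i] / tab$mean_n[i],
                                  tab$mean_mb[i], tol_ratio)
    if (!is.null(tab$froh_mean))
      out[[length(out) + 1]] <- add("mean_total_over_genome_is_froh",
                                    tab$mean_total_mb[i] * 1e6 / genome_size,
                                    tab$froh_mean[i], tol_ratio)
  }
  do.call(rbind, out)
}

#' Arithmetic-consistency report over summary tables
#'
#' Evaluates the internal identities of a per-population ROH class table
#' (transcribed from a publication or produced by [roh_table()]): length-class
#' means summing to the mean segment count, total length / individuals
#' matching the mean per-individual total, mean total / mean count matching
#' the mean segment length, and mean total / genome size matching F_ROH.
#' For transcribed tables the tolerances default to the half-unit rounding of
#' the printed precision (2 decimals).
#'
#' @param tab a data.frame with the [classify_roh()] columns (class_1..class_7,
#'   total_mb, mean_total_mb, mean_mb, mean_n, n_individuals, optionally
#'   froh_mean).
#' @param genome_size autosomal genome size in bp (default 960.8 Mb).
#' @param printed_decimals printed precision of the transcribed values
#'   (default 2); NULL asserts exact identities.
#' @return data.frame of checks with a \code{pass} column.
#' @export
consistency_report <- function(tab, genome_size = 960800000, printed_decimals = 2) {
  if (is.null(printed_decimals))
    return(roh_table_checks(tab, genome_size, tol = 1e-9))
  half <- 0.5 * 10^-printed_decimals
  cls <- grep("^class_", names(tab), value = TRUE)
  roh_table_checks(tab, genome_size,
                   tol_sum = half * (length(cls) + 1),
                   tol_ratio = 2 * half)
}

#' Transcribed published ROH summary for six chicken populations
#'
#' The per-population ROH class table reported by a whole-genome resequencing
#' study of a dual-purpose chicken breed, its wild progenitor and four
#' commercial lines, as shipped in \code{inst/extdata}. Used by
#' [consistency_report()] to verify the table's internal arithmetic.
#'
#' @return data.frame in [classify_roh()] layout plus \code{froh_mean}.
#' @export
published_roh_table <- function() {
  path <- system.file("extdata", "chicken_roh_classes.tsv", package = "popsweep")
  read.table(path, header = TRUE, sep = "\t", stringsAsFactors = FALSE)
}
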