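#' Default hard-filter thresholds for SNPs
#'
#' The widely used GATK-style thresholds: a variant is removed when
#' QD < 2.0, QUAL < 30.0, SOR > 3.0, FS > 60.0, MQ < 40.0,
#' MQRankSum < -12.5 or ReadPosRankSum < -8.0. All inequalities are strict;
#' a variant sitting exactly on a threshold is retained.
#'
#' @return named list of thresholds.
#' @export
hard_filter_defaults <- function() {
  list(QD = 2.0, QUAL = 30.0, SOR = 3.0, FS = 60.0,
       MQ = 40.0, MQRankSum = -12.5, ReadPosRankSum = -8.0)
}

# direction of each criterion: "lt" removes values strictly below the
# threshold, "gt" removes values strictly above it
HARD_FILTER_DIR <- c(QD = "lt", QUAL = "lt", SOR = "gt", FS = "gt",
                     MQ = "lt", MQRankSum = "lt", ReadPosRankSum = "lt")

new_filter_report <- function(n_input, removed, missing = integer()) {
  stopifnot(sum(removed) <= n_input)
  structure(list(n_input = n_input, n_removed = sum(removed),
                 n_retained = n_input - sum(removed),
                 removed = data.frame(criterion = names(removed),
                                      n = as.integer(removed), row.names = NULL),
                 missing_annotation = missing),
            class = "filter_report")
}

#' @export
print.filter_report <- function(x, ...) {
  cat(sprintf("filter_report: %d in, %d removed, %d retained\n",
              x$n_input, x$n_removed, x$n_retained))
  for (i in seq_len(nrow(x$removed)))
    cat(sprintf("  %-18s %d\n", x$removed$criterion[i], x$removed$n[i]))
  if (length(x$missing_annotation))
    cat("  missing annotations:",
        paste(names(x$missing_annotation), x$missing_annotation, collapse = ", "), "\n")
  invisible(x)
}

#' Apply hard filters to variant annotations
#'
#' A variant is removed iff any *available* annotation violates its threshold;
#' absent annotations never trigger removal but are counted in the report's
#' missing-annotation log. Each removed variant is attributed to the first
#' violated criterion in the order QD, QUAL, SOR, FS, MQ, MQRankSum,
#' ReadPosRankSum.
#'
#' @param gm a [geno_matrix()] read with \code{want_info = TRUE}.
#' @param thresholds named list as in [hard_filter_defaults()].
#' @return list with elements \code{gm} (filtered) and \code{report}
#'   (a \code{filter_report}).
#' @export
apply_hard_filters <- function(gm, thresholds = hard_filter_defaults()) {
  vr <- gm$variants
  n <- nrow(vr)
  keys <- names(thresholds)
  unknown <- setdiff(keys, names(HARD_FILTER_DIR))
  if (length(unknown)) stop("unknown hard-filter criterion: ", unknown[1])
  fail_by <- rep(NA_character_, n)
  missing <- integer()
  for (k in keys) {
    val <- vr[[k]]
    if (is.null(val)) val <- rep(NA_real_, n)
    if (!is.numeric(val)) stop("non-numeric annotation column: ", k)
    missing[k] <- sum(is.na(val))
    viol <- if (HARD_FILTER_DIR[[k]] == "lt") val < thresholds[[k]] else val > thresholds[[k]]
    viol[is.na(viol)] <- FALSE
    fail_by[is.na(fail_by) & viol] <- k
  }
  removed <- vapply(keys, function(k) sum(fail_by == k, na.rm = TRUE), integer(1))
  keep <- is.na(fail_by)
  list(gm = gm_subset(gm, variants = keep),
       report = new_filter_report(n, removed, missing))
}

#' Site-level filtering: biallelic autosomal SNPs, call rate and MAC
#'
#' Retains variants that are biallelic single-nucleotide substitutions on one
#' of the listed autosomes, with a called-genotype fraction of at least
#' \code{min_call_rate} across all samples and a minor-allele copy count of at
#' least \code{min_mac} (both computed jointly over all samples). Criteria are
#' applied in the order multi-allelic/non-SNP, non-autosomal, call rate, MAC;
#' a removed variant is counted under the first criterion it fails.
#'
#' @param gm a [geno_matrix()].
#' @param autosomes character vector of autosome names (required).
#' @param min_call_rate minimum fraction of called genotypes (default 0.5).
#' @param min_mac minimum minor allele count in copies (default 2).
#' @return list with elements \code{gm} and \code{report}.
#' @export
filter_sites <- function(gm, autosomes, min_call_rate = 0.5, min_mac = 2) {
  if (missing(autosomes) || length(autosomes) == 0) stop("autosome list must be non-empty")
  vr <- gm$variants
  n <- nrow(vr)
  snp <- !vr$multiallelic & nchar(vr$ref) == 1L & nchar(vr$alt) == 1L &
    vr$ref %in% c("A", "C", "G", "T") & vr$alt %in% c("A", "C", "G", "T")
  auto <- vr$chrom %in% autosomes
  called <- colMeans(!is.na(gm$calls))
  ac <- allele_counts(gm)
  mac <- pmin(ac$n_alt, ac$n_called - ac$n_alt)
  fail_by <- rep(NA_character_, n)
  fail_by[!snp] <- "not_biallelic_snp"
  fail_by[is.na(fail_by) & !auto] <- "not_autosomal"
  fail_by[is.na(fail_by) & called < min_call_rate] <- "call_rate"
  fail_by[is.na(fail_by) & mac < min_mac] <- "mac"
  crit <- c("not_biallelic_snp", "not_autosomal", "call_rate", "mac")
  removed <- vapply(crit, function(k) sum(fail_by == k, na.rm = TRUE), integer(1))
  keep <- is.na(fail_by)
  if (!any(keep)) warning("no variants survive site filtering")
  list(gm = gm_subset(gm, variants = keep),
       report = new_filter_report(n, removed))
}
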