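INFO_KEYS <- c("QD", "SOR", "FS", "MQ", "MQRankSum", "ReadPosRankSum")

# parse a vector of GT strings (format field already stripped) to dosages
# returns list(dosage, phased_sep) ; alleles > 1 (non-primary alt) -> NA
parse_gt <- function(gt, line_of = NULL) {
  u <- unique(gt)
  dos <- rep(NA_integer_, length(u))
  phased <- rep(NA, length(u))
  ok <- rep(TRUE, length(u))
  for (i in seq_along(u)) {
    g <- u[i]
    if (is.na(g) || g == "." || g == "./." || g == ".|.") {
      phased[i] <- if (identical(g, ".|.")) TRUE else NA
      next
    }
    if (!grepl("^[0-9.]+[/|][0-9.]+$", g)) { ok[i] <- FALSE; next }
    phased[i] <- grepl("|", g, fixed = TRUE)
    al <- strsplit(g, "[/|]")[[1]]
    if (any(al == ".")) next
    al <- as.integer(al)
    if (any(al > 1L)) next  # involves a non-primary alt allele
    dos[i] <- sum(al)
  }
  if (any(!ok)) {
    bad <- which(!ok)[1]
    rec <- which(gt == u[bad])[1]
    where <- if (is.null(line_of)) rec else line_of[rec]
    stop("malformed genotype '", u[bad], "' at record ", where)
  }
  m <- match(gt, u)
  list(dosage = dos[m], phased = phased[m])
}

#' Read a multi-sample VCF into a genotype matrix
#'
#' Calls are coded as alt-allele dosage; \code{./.} becomes missing. The phase
#' flag is TRUE only if every genotype separator in the file is \code{|}.
#' Multi-allelic records are retained but flagged for later exclusion by
#' [filter_sites()]. With \code{want_info = TRUE} the INFO annotations used by
#' the hard filters (QD, SOR, FS, MQ, MQRankSum, ReadPosRankSum), the QUAL
#' column, and the ancestral-allele key AA are parsed into the variant table.
#'
#' @param path path to a VCF 4.x file (plain or gzipped).
#' @param want_info parse INFO annotations (default TRUE).
#' @return a [geno_matrix()].
#' @export
read_vcf <- function(path, want_info = TRUE) {
  if (!file.exists(path)) stop("no such file: ", path)
  v <- vcfR::read.vcfR(path, verbose = FALSE)
  fix <- v@fix
  if (nrow(fix) == 0) stop("VCF contains no records")
  fmt <- v@gt[, 1]
  if (any(!grepl("(^|:)GT(:|$)", fmt)))
    stop("record ", which(!grepl("(^|:)GT(:|$)", fmt))[1], " has no GT field")
  gt <- vcfR::extract.gt(v, element = "GT")
  pos <- suppressWarnings(as.integer(fix[, "POS"]))
  if (anyNA(pos)) stop("malformed POS at record ", which(is.na(pos))[1])
  n_rec <- nrow(fix)
  n_smp <- ncol(gt)
  calls <- matrix(NA_integer_, n_smp, n_rec)
  all_phased <- TRUE
  any_sep <- FALSE
  for (j in seq_len(n_rec)) {
    pg <- parse_gt(gt[j, ])
    calls[, j] <- pg$dosage
    sep <- pg$phased[!is.na(pg$phased)]
    if (length(sep)) { any_sep <- TRUE; all_phased <- all_phased && all(sep) }
  }
  variants <- data.frame(chrom = fix[, "CHROM"], pos = pos,
                         id = ifelse(is.na(fix[, "ID"]) | fix[, "ID"] == ".",
                                     paste0(fix[, "CHROM"], "_", pos), fix[, "ID"]),
                         ref = fix[, "REF"], alt = fix[, "ALT"],
                         multiallelic = grepl(",", fix[, "ALT"], fixed = TRUE),
                         stringsAsFactors = FALSE)
  aa <- extract_info_key(fix[, "INFO"], "AA", numeric = FALSE)
  variants$ancestral <- ifelse(is.na(aa), "unknown",
                               ifelse(aa == variants$ref, "ref",
                                      ifelse(aa == variants$alt, "alt", "unknown")))
  if (want_info) {
    variants$QUAL <- suppressWarnings(as.numeric(fix[, "QUAL"]))
    for (k in INFO_KEYS) variants[[k]] <- extract_info_key(fix[, "INFO"], k, numeric = TRUE)
  }
  geno_matrix(calls, variants, colnames(gt), phased = any_sep && all_phased)
}

extract_info_key <- function(info, key, numeric = TRUE) {
  pat <- paste0("(?:^|;)", key, "=([^;]*)")
  m <- regmatches(info, regexpr(pat, info, perl = TRUE))
  out <- rep(NA_character_, length(info))
  hit <- grepl(pat, info, perl = TRUE)
  out[hit] <- sub(pat, "\\1", m, perl = TRUE)
  if (!numeric) return(out)
  num <- suppressWarnings(as.numeric(out))
  bad <- hit & is.na(num)
  if (any(bad)) stop("non-numeric INFO annotation ", key, " at record ", which(bad)[1])
  num
}

#' Read a phased VCF into a haplotype set
#'
#' Every genotype must be phased and called. When the INFO key AA marks the
#' alternate allele as ancestral, the haplotype coding at that site is flipped
#' so that 0 is always the ancestral allele where the ancestral state is known.
#'
#' @param path path to a phased VCF.
#' @return a [haplo_set()].
#' @export
read_haplotypes <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path)
  v <- vcfR::read.vcfR(path, verbose = FALSE)
  gt <- vcfR::extract.gt(v, element = "GT")
  if (any(grepl("/", gt, fixed = TRUE)) || any(is.na(gt)) || any(grepl("\\.", gt)))
    stop("haplotype input must be fully phased and called (use phased VCF)")
  fix <- v@fix
  if (any(grepl(",", fix[, "ALT"], fixed = TRUE)))
    stop("haplotype input must be biallelic")
  n_rec <- nrow(fix)
  samples <- colnames(gt)
  a1 <- matrix(as.integer(substr(t(gt), 1L, 1L)), ncol = n_rec)
  a2 <- matrix(as.integer(substr(t(gt), 3L, 3L)), ncol = n_rec)
  haps <- matrix(0L, 2L * length(samples), n_rec)
  haps[seq(1, nrow(haps), 2), ] <- a1
  haps[seq(2, nrow(haps), 2), ] <- a2
  pos <- as.integer(fix[, "POS"])
  aa <- extract_info_key(fix[, "INFO"], "AA", numeric = FALSE)
  ancestral <- ifelse(is.na(aa), "unknown",
                      ifelse(aa == fix[, "REF"], "ref",
                             ifelse(aa == fix[, "ALT"], "alt", "unknown")))
  flip <- ancestral == "alt"
  if (any(flip)) haps[, flip] <- 1L - haps[, flip]
  variants <- data.frame(chrom = fix[, "CHROM"], pos = pos,
                         id = ifelse(is.na(fix[, "ID"]) | fix[, "ID"] == ".",
                                     paste0(fix[, "CHROM"], "_", pos), fix[, "ID"]),
                         ref = fix[, "REF"], alt = fix[, "ALT"],
                         ancestral = ancestral, stringsAsFactors = FALSE)
  haplo_set(haps, variants, samples)
}

#' Write a genotype dataset as VCF plus population map
#'
#' Emits \code{<prefix>.vcf} (phase preserved when haplotypes are supplied;
#' ancestral allele written as INFO key AA when known) and
#' \code{<prefix>.popmap.tsv} (sample TAB population). \code{read_vcf} applied
#' to the output reproduces the calls exactly.
#'
#' @param gm a [geno_matrix()].
#' @param pmap a [pop_map()] covering all samples.
#' @param out_prefix output path prefix.
#' @param hs optional [haplo_set()] carrying the phase of \code{gm}.
#' @return invisibly, the two file paths.
#' @export
write_dataset <- function(gm, pmap, out_prefix, hs = NULL) {
  if (n_variants(gm) == 0) stop("refusing to write an empty genotype matrix")
  pop_labels_for(gm, pmap)
  vr <- gm$variants
  sep <- if (gm$phased) "|" else "/"
  if (!is.null(hs)) {
    stopifnot(identical(hs$samples, gm$samples), ncol(hs$haps) == n_variants(gm))
    h1 <- hs$haps[seq(1, nrow(hs$haps), 2), , drop = FALSE]
    h2 <- hs$haps[seq(2, nrow(hs$haps), 2), , drop = FALSE]
    flip <- hs$variants$ancestral == "alt"  # haplo_set is ancestral-coded
    if (any(flip)) { h1[, flip] <- 1L - h1[, flip]; h2[, flip] <- 1L - h2[, flip] }
    gtm <- matrix(paste0(h1, sep, h2), nrow(h1), ncol(h1))
  } else {
    code <- c("0" = paste0(0, sep, 0), "1" = paste0(0, sep, 1), "2" = paste0(1, sep, 1))
    gtm <- matrix("./.", nrow(gm$calls), ncol(gm$calls))
    ok <- !is.na(gm$calls)
    gtm[ok] <- code[as.character(gm$calls[ok])]
  }
  info <- rep(".", nrow(vr))
  known <- vr$ancestral %in% c("ref", "alt")
  info[known] <- paste0("AA=", ifelse(vr$ancestral[known] == "ref", vr$ref[known], vr$alt[known]))
  qual <- if (!is.null(vr$QUAL)) ifelse(is.na(vr$QUAL), ".", format(vr$QUAL)) else "."
  lens <- tapply(vr$pos, vr$chrom, max)
  hdr <- c("##fileformat=VCFv4.2",
           "##source=popsweep",
           paste0("##contig=<ID=", names(lens), ",length=", as.integer(lens), ">"),
           "##INFO=<ID=AA,Number=1,Type=String,Description=\"Ancestral allele\">",
           "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">",
           paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER", "INFO", "FORMAT",
                   gm$samples), collapse = "\t"))
  body <- paste(vr$chrom, vr$pos, vr$id, vr$ref, vr$alt, qual, "PASS", info, "GT",
                sep = "\t")
  gt_cols <- apply(gtm, 2, paste, collapse = "\t")  # per variant
  vcf_path <- paste0(out_prefix, ".vcf")
  map_path <- paste0(out_prefix, ".popmap.tsv")
  con <- try(file(vcf_path, "w"), silent = TRUE)
  if (inherits(con, "try-error")) stop("cannot write to ", vcf_path)
  writeLines(c(hdr, paste(body, gt_cols, sep = "\t")), con)
  close(con)
  idx <- match(gm$samples, pmap$sample)
  write.table(data.frame(pmap$sample[idx], pmap$population[idx]),
              map_path, sep = "\t", quote = FALSE, row.names = FALSE, col.names = FALSE)
  invisible(c(vcf = vcf_path, popmap = map_path))
}
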