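#' Read a biallelic variant table from VCF
#'
#' Loads a VCF (via vcfR) into the simple in-memory variant table used by
#' the identity-by-state operations: one row per site, with chromosome,
#' 1-based position, and one genotype call column per sample coded 0
#' (hom-ref), 1 (het), 2 (hom-alt), NA (missing). Multiallelic sites are
#' dropped with a count. Contig lengths are taken from the VCF header when
#' present.
#'
#' @param path path to a VCF file (plain text or bgzipped).
#' @return list of class `variant_table`: `sites` data.frame (chrom, pos,
#'   one column per sample), `samples`, `contig_lengths` (named, possibly
#'   empty), `n_dropped_multiallelic`, `n_malformed`.
#' @export
read_variants <- function(path) {
  v <- vcfR::read.vcfR(path, verbose = FALSE)
  fix <- vcfR::getFIX(v)
  gt_raw <- vcfR::extract.gt(v, element = "GT")
  biallelic <- !grepl(",", fix[, "ALT"]) & nchar(fix[, "ALT"]) > 0
  code <- function(g) {
    g <- sub("\\|", "/", g)
    out <- rep(NA_real_, length(g))
    out[g %in% c("0/0")] <- 0
    out[g %in% c("0/1", "1/0")] <- 1
    out[g %in% c("1/1")] <- 2
    out
  }
  gt <- apply(gt_raw, 2, code)
  if (is.null(dim(gt))) gt <- matrix(gt, ncol = ncol(gt_raw),
                                     dimnames = list(NULL, colnames(gt_raw)))
  known <- gt_raw %in% c("0/0", "0/1", "1/0", "1/1", "0|0", "0|1", "1|0", "1|1",
                         "./.", ".", ".|.") | is.na(gt_raw)
  n_malformed <- sum(!known)
  sites <- data.frame(chrom = fix[, "CHROM"], pos = as.integer(fix[, "POS"]),
                      stringsAsFactors = FALSE)
  sites <- cbind(sites, as.data.frame(gt))
  sites <- sites[biallelic, , drop = FALSE]
  meta <- v@meta
  contigs <- grep("^##contig=", meta, value = TRUE)
  ids <- sub(".*ID=([^,>]+).*", "\\1", contigs)
  lens <- suppressWarnings(as.numeric(sub(".*length=([0-9]+).*", "\\1", contigs)))
  contig_lengths <- stats::setNames(lens, ids)
  contig_lengths <- contig_lengths[is.finite(contig_lengths)]
  structure(list(sites = sites, samples = colnames(gt_raw),
                 contig_lengths = contig_lengths,
                 n_dropped_multiallelic = sum(!biallelic),
                 n_malformed = n_malformed),
            class = "variant_table")
}

#' Construct a variant table from a data.frame
#'
#' @param sites data.frame with `chrom`, `pos` and one numeric genotype
#'   column per sample (0/1/2/NA coding).
#' @param contig_lengths optional named vector of chromosome lengths (bp).
#' @return A `variant_table`.
#' @export
variant_table <- function(sites, contig_lengths = numeric(0)) {
  stopifnot(all(c("chrom", "pos") %in% names(sites)))
  samples <- setdiff(names(sites), c("chrom", "pos"))
  for (ch in unique(sites$chrom)) {
    p <- sites$pos[sites$chrom == ch]
    if (any(diff(p) <= 0)) stop("positions must be strictly increasing within chromosome")
  }
  structure(list(sites = sites, samples = samples,
                 contig_lengths = contig_lengths,
                 n_dropped_multiallelic = 0L, n_malformed = 0L),
            class = "variant_table")
}

#' Filter variants on missingness and minor allele frequency
#'
#' Retains sites with a missing-call fraction strictly below `max_missing`
#' AND a minor allele frequency strictly above `min_maf` (both strict, to
#' mirror "<10% missing" and ">5% MAF" filter descriptions). MAF is
#' computed from allele counts over non-missing diploid calls.
#'
#' @param vt a `variant_table`.
#' @param max_missing maximum (exclusive) missing fraction.
#' @param min_maf minimum (exclusive) minor allele frequency.
#' @return Filtered `variant_table`; attribute `n_removed` records the
#'   count dropped.
#' @export
filter_variants <- function(vt, max_missing = 0.10, min_maf = 0.05) {
  g <- as.matrix(vt$sites[, vt$samples, drop = FALSE])
  n <- ncol(g)
  miss_frac <- rowMeans(is.na(g))
  nonmiss <- rowSums(!is.na(g))
  alt <- rowSums(g, na.rm = TRUE)
  af <- ifelse(nonmiss > 0, alt / (2 * nonmiss), NA_real_)
  maf <- pmin(af, 1 - af)
  keep <- miss_frac < max_missing & !is.na(maf) & maf > min_maf
  out <- vt
  out$sites <- vt$sites[keep, , drop = FALSE]
  attr(out, "n_removed") <- sum(!keep)
  out
}

#' Windowed identity-by-state similarity between two samples
#'
#' Tiles each chromosome with half-open bins [k*bin_size, (k+1)*bin_size)
#' on 0-based coordinates (VCF positions are 1-based and converted) and,
#' within each bin, counts sites where both samples have non-missing calls
#' and tallies those whose genotype calls are identical (identity by
#' state). With `mode = "allele"` sharing is scored 0/0.5/1 by shared
#' allele count instead of the exact-call match. Sites with a missing call
#' in either sample are excluded from `n_sites`. Terminal short bins are
#' kept; chromosome lengths come from the VCF contig headers when present,
#' else the maximum observed position.
#'
#' @param vt a `variant_table`.
#' @param sample_a,sample_b sample ids.
#' @param bin_size bin width in bp (default 5e6).
#' @param mode "call" (exact genotype-call match) or "allele"
#'   (allele-sharing fraction).
#' @return data.frame of class `bin_similarity`: `chrom`, `bin_start`
#'   (0-based incl.), `bin_end` (excl.), `n_sites`, `n_ibs`, `fraction`
#'   (NA for empty bins).
#' @export
bin_ibs <- function(vt, sample_a, sample_b, bin_size = 5e6,
                    mode = c("call", "allele")) {
  mode <- match.arg(mode)
  if (!sample_a %in% vt$samples) stop("unknown sample id: ", sample_a)
  if (!sample_b %in% vt$samples) stop("unknown sample id: ", sample_b)
  s <- vt$sites
  ga <- s[[sample_a]]; gb <- s[[sample_b]]
  out <- list()
  for (ch in unique(s$chrom)) {
    i <- s$chrom == ch
    len <- if (ch %in% names(vt$contig_lengths)) vt$contig_lengths[[ch]]
           else max(s$pos[i])
    nbins <- max(1L, ceiling(len / bin_size))
    starts <- (seq_len(nbins) - 1) * bin_size
    ends <- pmin(starts + bin_size, len)
    pos0 <- s$pos[i] - 1  # 0-based
    a <- ga[i]; b <- gb[i]
    use <- !is.na(a) & !is.na(b)
    bin_idx <- floor(pos0 / bin_size) + 1
    n_sites <- tabulate(bin_idx[use], nbins)
    score <- if (mode == "call") as.numeric(a == b)
             else 1 - abs(a - b) / 2
    n_ibs <- vapply(seq_len(nbins), function(kk)
      sum(score[use & bin_idx == kk]), numeric(1))
    out[[ch]] <- data.frame(chrom = ch, bin_start = starts, bin_end = ends,
                            n_sites = n_sites, n_ibs = n_ibs,
                            fraction = ifelse(n_sites > 0, n_ibs / n_sites, NA_real_),
                            stringsAsFactors = FALSE)
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  class(res) <- c("bin_similarity", "data.frame")
  res
}

#' Chromosome-level similarity summary
#'
#' Per chromosome: the percentage of non-empty bins with IBS fraction
#' above `hi` and below `lo`, plus the genome-wide total length of bins
#' above `hi`.
#'
#' @param bins a `bin_similarity` data.frame from [bin_ibs()].
#' @param hi,lo similarity thresholds (fractions; defaults 0.90 and 0.20).
#' @return list: `per_chromosome` data.frame (chrom, n_bins,
#'   n_nonempty, pct_above_hi, pct_below_lo), and `total_bp_above_hi`.
#' @export
chromosome_summary <- function(bins, hi = 0.90, lo = 0.20) {
  per <- do.call(rbind, lapply(split(bins, bins$chrom), function(d) {
    ne <- d[!is.na(d$fraction), , drop = FALSE]
    data.frame(chrom = d$chrom[1], n_bins = nrow(d), n_nonempty = nrow(ne),
               pct_above_hi = if (nrow(ne)) 100 * mean(ne$fraction > hi) else NA_real_,
               pct_below_lo = if (nrow(ne)) 100 * mean(ne$fraction < lo) else NA_real_,
               stringsAsFactors = FALSE)
  }))
  rownames(per) <- NULL
  hi_bins <- bins[!is.na(bins$fraction) & bins$fraction > hi, , drop = FALSE]
  list(per_chromosome = per,
       total_bp_above_hi = sum(hi_bins$bin_end - hi_bins$bin_start))
}

#' Write a bin-similarity table as BED-compatible TSV
#' @param bins a `bin_similarity` data.frame.
#' @param path output path.
#' @export
write_bin_table <- function(bins, path) {
  utils::write.table(bins, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
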