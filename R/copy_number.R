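# Copy-number estimation: locus depth relative to the average genome-wide
# depth, integer rounding, largest-remainder apportionment among haplotypes,
# and user-supplied assembly-QC flags.

#' Mapping-free average genome-wide depth
#'
#' Total read bases divided by total assembly length.
#'
#' @param reads Reads tibble (or character vector of read sequences).
#' @param assembly Assembly tibble (or character vector of contigs).
#' @return Mean depth (x).
#' @export
genome_mean_depth <- function(reads, assembly) {
  rseq <- if (is.character(reads)) reads else reads$seq
  aseq <- if (is.character(assembly)) assembly else assembly$seq
  glen <- sum(nchar(aseq))
  if (glen == 0) abort("assembly has zero length")
  sum(nchar(rseq)) / glen
}

#' Mean locus depth with flank trimming
#'
#' Mean per-position pileup depth over the locus, excluding `flank` bp at
#' each end where coverage decays because reads must overlap the locus.
#'
#' @param pileup Pileup matrix from [build_pileup()] (or a depth vector).
#' @param flank Bases trimmed at each end (default 50).
#' @return Mean depth (x). Errors when the locus has zero coverage.
#' @export
locus_depth <- function(pileup, flank = 50L) {
  depth <- if (is.matrix(pileup)) rowSums(pileup) else pileup
  L <- length(depth)
  if (sum(depth) == 0) abort("insufficient reads for fingerprint: zero locus coverage")
  idx <- if (L > 2 * flank) (flank + 1L):(L - flank) else seq_len(L)
  mean(depth[idx])
}

#' Total marker copy number from the depth ratio
#'
#' `max(1, round(locus_depth / genome_depth))` with half-up rounding: a locus
#' that was found always counts at least one copy.
#'
#' @param genome_depth Average genome-wide depth.
#' @param locus_depth Mean locus depth.
#' @return Integer copy number and the underlying ratio, as a list.
#' @export
estimate_total_copies <- function(genome_depth, locus_depth) {
  if (genome_depth <= 0 || locus_depth <= 0) {
    abort("depths must be positive for a copy-number estimate")
  }
  ratio <- locus_depth / genome_depth
  list(total_copies = max(1L, as.integer(floor(ratio + 0.5))), ratio = ratio)
}

#' Apportion total copies among haplotypes
#'
#' Largest-remainder apportionment proportional to read-support fractions,
#' with every haplotype receiving at least one copy. Ties are broken by
#' haplotype order.
#'
#' @param total Total copy number (integer, at least the haplotype count).
#' @param fractions Read-support fractions (must sum to 1).
#' @return Integer vector of per-haplotype copies summing to `total`.
#' @examples
#' apportion_copies(3, c(0.66, 0.34))  # 2 1
#' @export
apportion_copies <- function(total, fractions) {
  n <- length(fractions)
  if (abs(sum(fractions) - 1) > 1e-6) abort("fractions must sum to 1")
  if (total < n) {
    abort(sprintf(paste0("total copies (%d) below haplotype count (%d): ",
                         "sequencing depth may be insufficient to support ",
                         "all haplotypes"), total, n))
  }
  quota <- total * fractions
  base <- floor(quota)
  rem <- quota - base
  left <- total - sum(base)
  if (left > 0) {
    give <- order(-rem, seq_len(n))[seq_len(left)]
    base[give] <- base[give] + 1
  }
  # enforce the one-copy floor, taking from the largest allocations
  while (any(base == 0)) {
    z <- which(base == 0)[1]
    donor <- which.max(base)
    if (base[donor] <= 1) abort("cannot apportion: not enough copies")
    base[donor] <- base[donor] - 1
    base[z] <- base[z] + 1
  }
  as.integer(base)
}

#' Assembly-quality warning flags
#'
#' Thresholds follow the regimes under which copy numbers are known to be
#' overestimated: moderate (>5%) to high (>10%) contamination, heterogeneity
#' above 25%, and an elevated marker:genome G+C ratio above 0.85. Values come
#' from external QC tools and are optional.
#'
#' @param contamination_pct,heterogeneity_pct,gc_ratio Optional QC values.
#' @param thresholds Named list overriding the default cutoffs
#'   (`contamination_moderate`, `contamination_high`, `heterogeneity`, `gc`).
#' @return Character vector of warning flags (possibly empty).
#' @export
qc_flags <- function(contamination_pct = NULL, heterogeneity_pct = NULL,
                     gc_ratio = NULL,
                     thresholds = list(contamination_moderate = 5,
                                       contamination_high = 10,
                                       heterogeneity = 25, gc = 0.85)) {
  flags <- character()
  if (!is.null(contamination_pct)) {
    if (contamination_pct > thresholds$contamination_high) {
      flags <- c(flags, "contamination_high")
    } else if (contamination_pct > thresholds$contamination_moderate) {
      flags <- c(flags, "contamination_moderate")
    }
  }
  if (!is.null(heterogeneity_pct) && heterogeneity_pct > thresholds$heterogeneity) {
    flags <- c(flags, "heterogeneity_high")
  }
  if (!is.null(gc_ratio) && gc_ratio > thresholds$gc) {
    flags <- c(flags, "gc_bias")
  }
  flags
}
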