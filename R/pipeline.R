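# The end-to-end per-isolate stage: locus finding, read recruitment and
# alignment, variant calling, phasing, copy-number estimation, fingerprint
# construction.

#' Build a fingerprint for one isolate from assembly and reads
#'
#' Runs the full first stage: locates all marker loci with the seed, selects
#' the best-identity locus as the mapping reference (loci at or above
#' `paralog_identity` to it are copies of the same marker; lower-identity
#' loci act as mapping-quality competitors), recruits and aligns reads,
#' calls variants under the MQ >= 30 / base quality >= 20 filters, phases
#' them into at most two haplotypes (diploid model), estimates the total
#' copy number from the locus/genome depth ratio, and apportions copies
#' among haplotypes by read support.
#'
#' @param assembly Assembly tibble (from [read_fasta()]) or named character.
#' @param reads Reads tibble (from [read_fastq()]).
#' @param seed An [seed_target()] object (or a plain seed sequence).
#' @param min_identity Locus identity floor (default 0.75).
#' @param paralog_identity Loci below this identity to the selected locus are
#'   treated as paralogs/competitors rather than marker copies (default
#'   0.97, the documented floor for intragenomic marker identity).
#' @param min_mq,min_depth,min_af,min_alt_reads Variant-calling thresholds.
#' @param recruit_k,align_band Recruitment/alignment controls.
#' @param flank Flank trim (bp) for the locus-depth estimate.
#' @param phase_seed Seed for the phasing heuristic restarts.
#' @param contamination_pct,heterogeneity_pct,gc_ratio Optional external QC
#'   values for [qc_flags()].
#' @return An object of class `fq_main`: the fingerprint plus loci,
#'   variants, depth estimates and a processing log.
#' @export
fingerprint_genome <- function(assembly, reads, seed,
                               min_identity = 0.75, paralog_identity = 0.97,
                               min_mq = 30L, min_depth = 10L, min_af = 0.1,
                               min_alt_reads = 4L, recruit_k = 21L,
                               align_band = 8L, flank = 50L,
                               phase_seed = 42L,
                               contamination_pct = NULL,
                               heterogeneity_pct = NULL, gc_ratio = NULL,
                               member_id = "isolate") {
  if (is.character(seed)) seed <- seed_target(seed)
  loci <- find_target_loci(assembly, seed, min_identity = min_identity)
  best <- select_best_locus(loci)
  locus_seq <- best$seq
  # competitor loci: diverged paralogs, not copies of the same marker
  competitors <- character()
  if (nrow(loci) > 1) {
    others <- loci[!(loci$contig == best$contig & loci$start == best$start), ]
    for (i in seq_len(nrow(others))) {
      # copies of the same marker have near-identical lengths: a narrow band
      # suffices to separate >= 97% copies from diverged paralogs
      dd <- abs(nchar(others$seq[i]) - nchar(locus_seq)) + 48L
      r <- cpp_align_glocal(others$seq[i], locus_seq, dlo = -dd, dhi = dd,
                            local = TRUE)
      ident <- if (r$ok && r$columns > 0) r$matches / r$columns else 0
      if (ident < paralog_identity) {
        competitors <- c(competitors, others$seq[i])
      }
    }
  }
  rec <- recruit_reads(reads, locus_seq, k = recruit_k)
  aln <- align_recruited(rec, locus_seq, competitors = competitors,
                         k = recruit_k, band = align_band)
  if (nrow(aln) == 0) abort("insufficient reads for fingerprint: no read aligned")
  pile <- build_pileup(aln, min_mq = min_mq)
  variants <- call_variants(pile, locus_seq, aln, min_mq = min_mq,
                            min_depth = min_depth, min_af = min_af,
                            min_alt_reads = min_alt_reads)
  rvm <- read_variant_matrix(aln, variants, min_mq = min_mq)
  phasing <- phase_two_haplotypes(variants, rvm, seed = phase_seed)
  haps <- assemble_haplotypes(locus_seq, variants, phasing)
  gdepth <- genome_mean_depth(reads, assembly)
  ldepth <- locus_depth(pile, flank = flank)
  est <- estimate_total_copies(gdepth, ldepth)
  copies <- apportion_copies(est$total_copies, haps$fraction)
  flags <- qc_flags(contamination_pct, heterogeneity_pct, gc_ratio)
  fp <- build_fingerprint(member_id, haps$seq, copies)
  structure(list(
    fingerprint = fp, loci = loci, best_locus = best,
    variants = variants, phasing = phasing,
    genome_depth = gdepth, locus_mean_depth = ldepth,
    depth_ratio = est$ratio, total_copies = est$total_copies,
    qc_flags = flags,
    log = list(n_reads = nrow(reads), n_recruited = nrow(rec),
               n_aligned = nrow(aln),
               n_discarded = attr(aln, "n_unaligned"),
               n_competitor_loci = length(competitors))),
    class = "fq_main")
}

#' @export
print.fq_main <- function(x, ...) {
  cat(sprintf(
    "<fq_main> %s: %d haplotype(s) x %d total copies (depth ratio %.2f)\n",
    x$fingerprint$member_id, nrow(x$fingerprint$haplotypes),
    x$total_copies, x$depth_ratio))
  cat(sprintf("  reads: %d recruited, %d aligned, %d discarded; %d variant site(s)\n",
              x$log$n_recruited, x$log$n_aligned, x$log$n_discarded,
              nrow(x$variants)))
  if (length(x$qc_flags)) {
    cat("  QC flags:", paste(x$qc_flags, collapse = ", "), "\n")
  }
  invisible(x)
}

#' Per-isolate report row
#'
#' @param x An `fq_main` result.
#' @return One-row tibble: `member_id`, `total_copies`, `n_haplotypes`,
#'   per-haplotype copies (comma-joined), `genome_depth`, `locus_depth`,
#'   `qc_flags`.
#' @export
main_report <- function(x) {
  tibble(member_id = x$fingerprint$member_id,
         total_copies = x$total_copies,
         n_haplotypes = nrow(x$fingerprint$haplotypes),
         haplotype_copies = paste(x$fingerprint$haplotypes$copies,
                                  collapse = ","),
         genome_depth = x$genome_depth,
         locus_depth = x$locus_mean_depth,
         qc_flags = paste(x$qc_flags, collapse = ";"))
}
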