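# Locating the marker gene in an assembly: k-mer anchoring of the seed on
# both strands, banded glocal alignment of the seed against candidate
# windows, then length/identity filtering and greedy non-overlap resolution.

#' Describe the seed (query) marker gene
#'
#' @param seq The seed sequence (a single string), e.g. a full-length 16S
#'   rRNA gene.
#' @param id Identifier for reporting.
#' @param max_len_dev Maximum allowed deviation (bp, symmetric) between an
#'   extracted locus and the seed length. Default 300, accommodating natural
#'   variation in 16S rRNA gene length.
#' @return An object of class `fq_seed`.
#' @export
seed_target <- function(seq, id = "seed", max_len_dev = 300L) {
  seq <- normalize_seq(seq, "iupac", "seed")
  stopifnot(length(seq) == 1, nchar(seq) > 0, max_len_dev >= 0)
  structure(list(id = id, seq = seq, expected_len = nchar(seq),
                 max_len_dev = as.integer(max_len_dev)),
            class = "fq_seed")
}

#' @export
print.fq_seed <- function(x, ...) {
  cat(sprintf("<fq_seed> %s: %d bp (max length deviation %d bp)\n",
              x$id, x$expected_len, x$max_len_dev))
  invisible(x)
}

#' Find all marker-gene loci in an assembly
#'
#' Scans every contig on both strands for local matches to the seed, keeps
#' hits whose length is within `max_len_dev` of the seed length and whose
#' identity (matches / alignment columns, gaps counted as mismatches) is at
#' least `min_identity`, and resolves overlaps greedily by identity.
#'
#' @param assembly A tibble as returned by [read_fasta()], or a named
#'   character vector of contig sequences.
#' @param seed An [seed_target()] object.
#' @param min_identity Minimum identity to the seed (default 0.75; the length
#'   filter is the primary gate).
#' @param anchor_k Exact k-mer size used to anchor candidate windows.
#' @param anchor_stride Sample every `anchor_stride`-th seed k-mer as an
#'   anchor.
#' @return A tibble with columns `contig`, `start`, `end` (0-based half-open),
#'   `strand`, `seq` (forward-oriented with respect to the seed), `identity`,
#'   sorted by identity (descending), contig, start. Errors with
#'   "target absent or incomplete" when no locus passes both filters.
#' @export
find_target_loci <- function(assembly, seed, min_identity = 0.75,
                             anchor_k = 15L, anchor_stride = 25L) {
  stopifnot(inherits(seed, "fq_seed"), min_identity > 0, min_identity <= 1)
  asm <- as_seq_tbl(assembly)
  if (nrow(asm) == 0) abort("assembly is empty")
  L <- seed$expected_len
  dev <- seed$max_len_dev
  hits <- list()
  for (ci in seq_len(nrow(asm))) {
    contig <- asm$seq[ci]
    anch <- cpp_seed_anchors(contig, seed$seq, k = anchor_k,
                             stride = anchor_stride)
    if (nrow(anch) == 0) next
    for (st in c(1L, -1L)) {
      a <- anch[anch$strand == st, , drop = FALSE]
      if (nrow(a) == 0) next
      es <- sort(a$est_start)
      grp <- cumsum(c(1L, diff(es) > max(600L, dev)))
      for (g in split(es, grp)) {
        spread <- max(g) - min(g)
        band <- spread + 40L
        win_start <- max(0L, min(g) - dev - anchor_k)
        win_end <- min(nchar(contig), max(g) + L + dev + anchor_k)
        window <- substr(contig, win_start + 1L, win_end)
        if (st == 1L) {
          sub <- window
          exp_off <- min(g) - win_start
        } else {
          sub <- revcomp(window)
          exp_off <- (win_end - win_start) - (max(g) - win_start) - L
        }
        r <- cpp_align_glocal(seed$seq, sub,
                              dlo = exp_off - band, dhi = exp_off + band,
                              match = 1L, mismatch = -1L, gap = -2L,
                              local = TRUE)
        if (!r$ok || r$columns == 0) next
        if (st == 1L) {
          s0 <- win_start + r$sub_start
          e0 <- win_start + r$sub_end
          lseq <- substr(contig, s0 + 1L, e0)
        } else {
          wl <- win_end - win_start
          s0 <- win_start + (wl - r$sub_end)
          e0 <- win_start + (wl - r$sub_start)
          lseq <- substr(sub, r$sub_start + 1L, r$sub_end)
        }
        hits[[length(hits) + 1L]] <- tibble(
          contig = asm$id[ci], start = s0, end = e0,
          strand = if (st == 1L) "+" else "-",
          seq = lseq,
          identity = r$matches / r$columns,
          len = e0 - s0)
      }
    }
  }
  loci <- if (length(hits)) dplyr::bind_rows(hits) else
    tibble(contig = character(), start = integer(), end = integer(),
           strand = character(), seq = character(), identity = double(),
           len = integer())
  loci <- loci[abs(loci$len - L) <= dev & loci$identity >= min_identity, ]
  loci <- loci[order(-loci$identity, loci$contig, loci$start), ]
  # greedy non-overlap: discard hits overlapping an accepted hit by > 50%
  keep <- logical(nrow(loci))
  for (i in seq_len(nrow(loci))) {
    ok <- TRUE
    for (j in which(keep)) {
      if (loci$contig[i] != loci$contig[j]) next
      ov <- min(loci$end[i], loci$end[j]) - max(loci$start[i], loci$start[j])
      if (ov > 0.5 * (loci$end[i] - loci$start[i])) { ok <- FALSE; break }
    }
    keep[i] <- ok
  }
  loci <- loci[keep, setdiff(names(loci), "len")]
  if (nrow(loci) == 0) {
    abort("target absent or incomplete: no locus passed the length and identity filters")
  }
  loci
}

#' Select the best marker locus
#'
#' The hit with the highest identity to the seed; ties broken by contig id
#' (lexicographic), then smallest start.
#'
#' @param loci Tibble from [find_target_loci()].
#' @return A one-row tibble.
#' @export
select_best_locus <- function(loci) {
  if (is.null(loci) || nrow(loci) == 0) abort("no loci to select from")
  loci[order(-loci$identity, loci$contig, loci$start), ][1, ]
}

#' Read-free haplotypes straight from the assembly
#'
#' Fallback when no genomic reads are available: every passing locus is taken
#' at face value, deduplicated by exact sequence equality; the copy number is
#' the total locus count.
#'
#' @inheritParams find_target_loci
#' @return A list with `haplotypes` (tibble of `seq`, `multiplicity`) and
#'   `total_copies`.
#' @export
direct_haplotypes <- function(assembly, seed, min_identity = 0.75) {
  loci <- find_target_loci(assembly, seed, min_identity = min_identity)
  agg <- dplyr::count(loci, .data$seq, name = "multiplicity")
  agg <- agg[order(-agg$multiplicity, agg$seq), ]
  list(haplotypes = as_tibble(agg), total_copies = nrow(loci))
}

#' Report loci as BED6 (0-based half-open)
#'
#' @param loci Tibble from [find_target_loci()].
#' @param path Output path.
#' @param name Feature name prefix.
#' @return `path`, invisibly.
#' @export
write_loci_bed <- function(loci, path, name = "target") {
  df <- data.frame(loci$contig, loci$start, loci$end,
                   paste0(name, "_", seq_len(nrow(loci))),
                   round(1000 * loci$identity), loci$strand)
  write.table(df, path, sep = "\t", quote = FALSE,
              row.names = FALSE, col.names = FALSE)
  invisible(path)
}
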