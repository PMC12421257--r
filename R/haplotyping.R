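# Read recruitment, alignment to the selected marker locus, pileup-based
# variant calling with quality filters, and two-haplotype (diploid-model)
# phasing by minimum error correction.

#' Convert a Phred score to an error probability
#'
#' `10^(-q/10)`; Q30 corresponds to a 0.1% error rate.
#'
#' @param q Phred score(s), non-negative.
#' @return Error probabilities.
#' @examples
#' phred_to_error(30)  # 0.001
#' @export
phred_to_error <- function(q) {
  if (any(q < 0)) abort("Phred scores must be non-negative")
  10^(-q / 10)
}

#' Recruit reads that share k-mers with a locus
#'
#' Keeps reads sharing at least `min_shared` canonical `k`-mers with the
#' locus (either orientation); mates of recruited reads are included.
#'
#' @param reads Tibble from [read_fastq()] (columns `id`, `seq`, ...).
#' @param locus_seq Locus sequence (single string).
#' @param k Anchor k-mer size (default 21).
#' @param min_shared Minimum shared k-mers (default 2).
#' @return The recruited subset of `reads`.
#' @export
recruit_reads <- function(reads, locus_seq, k = 21L, min_shared = 2L) {
  if (nrow(reads) == 0) return(reads)
  shared <- cpp_shared_kmers(reads$seq, locus_seq, k)
  keep <- shared >= min_shared
  if (!is.null(reads$mate) && any(!is.na(reads$mate))) {
    base <- sub("/[12]$", "", reads$id)
    keep <- keep | base %in% base[keep]
  }
  reads[keep, ]
}

#' Align recruited reads to a locus
#'
#' Each read is anchored by exact k-mers in its best orientation, clipped to
#' the locus, and compared ungapped; reads with indel evidence fall back to a
#' banded glocal alignment. Mapping quality is `min(60, 4 * (S1 - S2))`
#' against the best-scoring competitor locus (e.g. a diverged paralog) and 60
#' when no competitor is supplied. Reads below `min_identity` are dropped and
#' counted.
#'
#' @param reads Recruited reads tibble (`id`, `seq`, `qual`).
#' @param locus_seq Locus sequence.
#' @param competitors Optional character vector of competitor locus sequences.
#' @param k Anchor k-mer size.
#' @param band Alignment band half-width for the indel fallback.
#' @param min_identity Drop alignments below this identity (default 0.8).
#' @return A tibble of alignments: `read_id`, `start` (0-based on locus),
#'   `strand`, `mq`, `score`, `identity`, `clipped`, `proj` (read projected
#'   onto locus coordinates, `-` for deletions), `qual` (projected quality
#'   string), `ins` (insertion tokens `pos:SEQ`). Attributes `n_unaligned`,
#'   `n_unanchored`, `n_low_identity` carry the log counts.
#' @export
align_recruited <- function(reads, locus_seq, competitors = character(),
                            k = 21L, band = 8L, min_identity = 0.8) {
  quals <- reads$qual %||% character()
  r <- cpp_align_reads(reads$seq, quals, locus_seq, k = k,
                       competitors = as.list(competitors), band = band,
                       min_identity = min_identity)
  out <- tibble(read_id = reads$id[r$read],
                start = r$start, strand = ifelse(r$strand > 0, "+", "-"),
                mq = r$mq, score = r$score, identity = r$identity,
                clipped = r$clipped, proj = r$proj, qual = r$qual,
                ins = r$ins)
  attr(out, "n_unaligned") <- r$n_unaligned
  attr(out, "n_unanchored") <- r$n_unanchored
  attr(out, "n_low_identity") <- r$n_low_identity
  attr(out, "locus_len") <- nchar(locus_seq)
  out
}

#' Build a pileup from locus-projected alignments
#'
#' Only alignments with `mq >= min_mq` contribute, and only base calls with
#' base quality `>= min_bq` (deletions are depth-counted without a base
#' quality).
#'
#' @param alignments Tibble from [align_recruited()].
#' @param locus_len Locus length (taken from the alignments attribute when
#'   omitted).
#' @param min_bq Base-quality floor (default 20).
#' @param min_mq Mapping-quality floor (default 30).
#' @return A matrix with one row per locus position and columns
#'   `A+,C+,G+,T+,del+,A-,C-,G-,T-,del-`.
#' @export
build_pileup <- function(alignments, locus_len = NULL, min_bq = 20L,
                         min_mq = 30L) {
  locus_len <- locus_len %||% attr(alignments, "locus_len")
  strand_i <- ifelse(alignments$strand == "+", 1L, -1L)
  m <- cpp_pileup(alignments$start, alignments$proj, alignments$qual,
                  strand_i, alignments$mq, locus_len,
                  min_bq = min_bq, min_mq = min_mq)
  colnames(m) <- c("A+", "C+", "G+", "T+", "del+",
                   "A-", "C-", "G-", "T-", "del-")
  m
}

pileup_depth <- function(pileup) rowSums(pileup)

# per-read allele observation at one locus position (0-based)
allele_at <- function(alignments, pos) {
  off <- pos - alignments$start
  len <- nchar(alignments$proj)
  covered <- off >= 0 & off < len
  out <- rep(NA_character_, nrow(alignments))
  out[covered] <- substr(alignments$proj[covered], off[covered] + 1L,
                         off[covered] + 1L)
  out
}

#' Call intragenomic variants from a pileup
#'
#' Emits positions where an alternate allele (substitution, deletion, or
#' insertion) reaches fraction `min_af` and count `min_alt_reads` at depth
#' `min_depth`, from a pileup restricted to alignments with mapping quality
#' at least `min_mq` and base quality at least 20. Strand-bias (Fisher
#' exact), mean mapping/base quality of supporting reads, and in-read
#' position bias (Wilcoxon rank) annotations are attached but not used to
#' hard-filter.
#'
#' @param pileup Matrix from [build_pileup()].
#' @param locus_seq Locus (reference) sequence.
#' @param alignments Alignments tibble, used for the annotations and for
#'   insertion calls; may be `NULL` to skip both.
#' @param min_mq,min_depth,min_af,min_alt_reads Filter thresholds.
#' @return A tibble with columns `pos` (0-based), `ref`, `alt` (a base, `-`
#'   for a single-base deletion, or `+SEQ` for an insertion before `pos`),
#'   `af`, `depth`, `alt_count`, `strand_bias_p`, `mean_mq`, `mean_bq`,
#'   `pos_bias_p`.
#' @export
call_variants <- function(pileup, locus_seq, alignments = NULL,
                          min_mq = 30L, min_depth = 10L, min_af = 0.1,
                          min_alt_reads = 4L) {
  L <- nrow(pileup)
  stopifnot(nchar(locus_seq) == L)
  ref <- strsplit(locus_seq, "")[[1]]
  bases <- c("A", "C", "G", "T", "-")
  fwd <- pileup[, 1:5, drop = FALSE]
  rev <- pileup[, 6:10, drop = FALSE]
  tot <- fwd + rev
  depth <- rowSums(tot)
  ref_idx <- match(ref, bases)
  ref_idx[is.na(ref_idx)] <- 5L  # ambiguity-code reference: treat as no-base
  ref_count <- tot[cbind(seq_len(L), ref_idx)]
  alt_tot <- tot
  alt_tot[cbind(seq_len(L), ref_idx)] <- -1L
  alt_idx <- max.col(alt_tot, ties.method = "first")
  alt_count <- tot[cbind(seq_len(L), alt_idx)]
  af <- ifelse(depth > 0, alt_count / depth, 0)
  sel <- which(depth >= min_depth & alt_count >= min_alt_reads &
                 af >= min_af & af < 1 & ref_count > 0)
  rows <- lapply(sel, function(p) {
    tibble(pos = p - 1L, ref = ref[p], alt = bases[alt_idx[p]],
           af = af[p], depth = as.integer(depth[p]),
           alt_count = as.integer(alt_count[p]),
           ref_fwd = fwd[p, ref_idx[p]], ref_rev = rev[p, ref_idx[p]],
           alt_fwd = fwd[p, alt_idx[p]], alt_rev = rev[p, alt_idx[p]])
  })
  out <- if (length(rows)) dplyr::bind_rows(rows) else
    tibble(pos = integer(), ref = character(), alt = character(),
           af = double(), depth = integer(), alt_count = integer(),
           ref_fwd = integer(), ref_rev = integer(),
           alt_fwd = integer(), alt_rev = integer())
  # insertion alleles, tallied from the alignment insertion tokens
  if (!is.null(alignments) && any(nzchar(alignments$ins))) {
    keep <- alignments$mq >= min_mq & nzchar(alignments$ins)
    toks <- unlist(strsplit(alignments$ins[keep], ","), use.names = FALSE)
    if (length(toks)) {
      tab <- table(toks)
      ipos <- as.integer(sub(":.*$", "", names(tab)))
      iseq <- sub("^[0-9]+:", "", names(tab))
      icount <- as.integer(tab)
      idepth <- depth[pmin(pmax(ipos + 1L, 1L), L)]
      iaf <- ifelse(idepth > 0, icount / idepth, 0)
      ok <- idepth >= min_depth & icount >= min_alt_reads & iaf >= min_af & iaf < 1
      if (any(ok)) {
        ins_rows <- tibble(pos = ipos[ok], ref = ref[pmin(ipos[ok] + 1L, L)],
                           alt = paste0("+", iseq[ok]), af = iaf[ok],
                           depth = as.integer(idepth[ok]),
                           alt_count = icount[ok],
                           ref_fwd = NA_integer_, ref_rev = NA_integer_,
                           alt_fwd = NA_integer_, alt_rev = NA_integer_)
        out <- dplyr::bind_rows(out, ins_rows)
      }
    }
  }
  out <- out[order(out$pos), ]
  annotate_variants(out, alignments, min_mq)
}

annotate_variants <- function(variants, alignments, min_mq = 30L) {
  n <- nrow(variants)
  variants$strand_bias_p <- rep(NA_real_, n)
  variants$mean_mq <- rep(NA_real_, n)
  variants$mean_bq <- rep(NA_real_, n)
  variants$pos_bias_p <- rep(NA_real_, n)
  if (n == 0 || is.null(alignments)) {
    return(variants[, c("pos", "ref", "alt", "af", "depth", "alt_count",
                        "strand_bias_p", "mean_mq", "mean_bq", "pos_bias_p")])
  }
  aln <- alignments[alignments$mq >= min_mq, ]
  for (i in seq_len(n)) {
    p <- variants$pos[i]
    alt <- variants$alt[i]
    if (startsWith(alt, "+")) {
      tok <- paste0(p, ":", substring(alt, 2))
      is_alt <- vapply(strsplit(aln$ins, ","), function(x) tok %in% x,
                       logical(1))
      obs <- allele_at(aln, p)
      is_ref <- !is.na(obs) & !is_alt
    } else {
      obs <- allele_at(aln, p)
      is_alt <- !is.na(obs) & obs == alt
      is_ref <- !is.na(obs) & obs == variants$ref[i]
    }
    if (!is.na(variants$alt_fwd[i])) {
      tb <- matrix(c(variants$ref_fwd[i], variants$ref_rev[i],
                     variants$alt_fwd[i], variants$alt_rev[i]), 2)
      variants$strand_bias_p[i] <- tryCatch(fisher.test(tb)$p.value,
                                            error = function(e) NA_real_)
    }
    sup <- which(is_alt)
    if (length(sup)) {
      variants$mean_mq[i] <- mean(aln$mq[sup])
      off <- p - aln$start[sup]
      bq <- utf8ToInt(paste0(substr(aln$qual[sup], off + 1L, off + 1L),
                             collapse = "")) - 33L
      variants$mean_bq[i] <- mean(bq)
      inpos_alt <- ifelse(aln$strand[sup] == "+", off,
                          nchar(aln$proj[sup]) - 1L - off)
      refw <- which(is_ref)
      offr <- p - aln$start[refw]
      inpos_ref <- ifelse(aln$strand[refw] == "+", offr,
                          nchar(aln$proj[refw]) - 1L - offr)
      if (length(inpos_ref) && length(inpos_alt)) {
        variants$pos_bias_p[i] <- tryCatch(
          suppressWarnings(wilcox.test(inpos_alt, inpos_ref)$p.value),
          error = function(e) NA_real_)
      }
    }
  }
  variants[, c("pos", "ref", "alt", "af", "depth", "alt_count",
               "strand_bias_p", "mean_mq", "mean_bq", "pos_bias_p")]
}

#' Per-read allele observations at the called variant sites
#'
#' @param alignments Alignments tibble.
#' @param variants Variants tibble from [call_variants()].
#' @param min_mq Mapping-quality floor.
#' @return Integer matrix, reads x variants: 0 = ref allele, 1 = alt allele,
#'   `NA` = not covered / third allele. Rows are named by read id.
#' @export
read_variant_matrix <- function(alignments, variants, min_mq = 30L) {
  aln <- alignments[alignments$mq >= min_mq, ]
  n <- nrow(aln); v <- nrow(variants)
  m <- matrix(NA_integer_, n, v, dimnames = list(aln$read_id, NULL))
  for (j in seq_len(v)) {
    p <- variants$pos[j]
    alt <- variants$alt[j]
    obs <- allele_at(aln, p)
    if (startsWith(alt, "+")) {
      tok <- paste0(p, ":", substring(alt, 2))
      has_ins <- vapply(strsplit(aln$ins, ","), function(x) tok %in% x,
                        logical(1))
      m[!is.na(obs), j] <- 0L
      m[has_ins, j] <- 1L
    } else {
      m[!is.na(obs) & obs == variants$ref[j], j] <- 0L
      m[!is.na(obs) & obs == alt, j] <- 1L
    }
  }
  m[rowSums(!is.na(m)) > 0, , drop = FALSE]
}

# MEC cost machinery on weighted allele patterns -----------------------------

# patterns: matrix p x v in {0,1,NA}; h: 0/1 vector. Under the diploid model
# the second haplotype is the complement of the first at every (het) site.
mec_cost_components <- function(patterns, weights) {
  A <- ifelse(is.na(patterns), 0L, patterns)
  M <- ifelse(is.na(patterns), 0L, 1L)
  nobs <- rowSums(M)
  list(A = A, M = M, nobs = nobs, w = weights)
}

mec_eval <- function(cmp, H) {
  # H: matrix (n_hyp x v) of 0/1 first-haplotype allele vectors
  # mismatches of pattern i vs h: M*A*(1-h) + M*(1-A)*h
  mis_h <- (cmp$M * cmp$A) %*% t(1 - H) + (cmp$M * (1 - cmp$A)) %*% t(H)
  mis_c <- cmp$nobs - mis_h  # vs complement haplotype
  colSums(pmin(mis_h, mis_c) * cmp$w)
}

#' Phase variants into two haplotypes by minimum error correction
#'
#' Under the diploid model the two haplotypes are complementary at every
#' variant site; the bipartition minimizing the weighted MEC cost is found by
#' exact enumeration for up to `max_exact` variants and by a seeded
#' local-search heuristic with random restarts beyond that.
#'
#' @param variants Variants tibble (its row count defines the site count).
#' @param read_matrix Matrix from [read_variant_matrix()].
#' @param max_exact Exact-enumeration ceiling (default 12).
#' @param restarts Random restarts for the heuristic (default 10).
#' @param seed Seed for the heuristic restarts (default 42).
#' @return A list with `h1`, `h2` (0/1 allele vectors; `h1` is the
#'   better-supported haplotype), `fractions` (read-support fractions,
#'   summing to 1, ordered as the haplotypes), `mec` (optimal cost) and
#'   `n_informative`. With zero variants, a single haplotype with fraction 1.
#' @export
phase_two_haplotypes <- function(variants, read_matrix, max_exact = 12L,
                                 restarts = 10L, seed = 42L) {
  v <- nrow(variants)
  if (v == 0) {
    return(list(h1 = integer(0), h2 = NULL, fractions = 1, mec = 0,
                n_informative = 0L))
  }
  rm <- read_matrix[rowSums(!is.na(read_matrix)) > 0, , drop = FALSE]
  if (nrow(rm) == 0) {
    return(list(h1 = rep(1L, v), h2 = rep(0L, v), fractions = c(0.5, 0.5),
                mec = 0, n_informative = 0L))
  }
  key <- apply(rm, 1, paste, collapse = ",")
  uniq <- !duplicated(key)
  patterns <- rm[uniq, , drop = FALSE]
  weights <- as.vector(table(key)[key[uniq]])
  cmp <- mec_cost_components(patterns, weights)
  if (v <= max_exact) {
    # enumerate with first allele fixed to 1 (complement symmetry)
    n_hyp <- 2^(v - 1)
    H <- cbind(1L, matrix(0L, n_hyp, v - 1))
    if (v > 1) {
      bits <- t(vapply(seq_len(n_hyp) - 1L,
                       function(x) as.integer(bitwAnd(bitwShiftR(x, 0:(v - 2)), 1L)),
                       integer(v - 1)))
      if (v == 2) bits <- matrix(bits, ncol = 1)
      H[, -1] <- bits
    }
    costs <- mec_eval(cmp, H)
    h1 <- H[which.min(costs), ]
    mec <- min(costs)
  } else {
    best <- NULL; mec <- Inf
    rng_state <- .save_rng(); on.exit(.restore_rng(rng_state))
    set.seed(seed)
    for (r in seq_len(restarts)) {
      h <- sample(0:1, v, replace = TRUE); h[1] <- 1L
      repeat {
        improved <- FALSE
        for (j in seq_len(v)) {
          h2 <- h; h2[j] <- 1L - h2[j]
          if (mec_eval(cmp, matrix(h2, 1)) < mec_eval(cmp, matrix(h, 1))) {
            h <- h2; improved <- TRUE
          }
        }
        if (!improved) break
      }
      c0 <- mec_eval(cmp, matrix(h, 1))
      if (c0 < mec) { mec <- c0; best <- h }
    }
    h1 <- best
  }
  h2 <- 1L - h1
  # read support: assign each pattern to the nearer haplotype, ties split
  mis_h <- as.vector((cmp$M * cmp$A) %*% (1 - h1) + (cmp$M * (1 - cmp$A)) %*% h1)
  mis_c <- cmp$nobs - mis_h
  w1 <- sum(cmp$w * ((mis_h < mis_c) + 0.5 * (mis_h == mis_c)))
  n_inf <- sum(cmp$w)
  f1 <- w1 / n_inf
  if (f1 < 0.5) {  # orient so the first haplotype is the better-supported one
    tmp <- h1; h1 <- h2; h2 <- tmp
    f1 <- 1 - f1
  }
  list(h1 = as.integer(h1), h2 = as.integer(h2),
       fractions = c(f1, 1 - f1), mec = as.numeric(mec),
       n_informative = as.integer(n_inf))
}

.save_rng <- function() {
  if (exists(".Random.seed", envir = globalenv())) {
    get(".Random.seed", envir = globalenv())
  } else NULL
}
.restore_rng <- function(state) {
  if (is.null(state)) {
    if (exists(".Random.seed", envir = globalenv())) {
      rm(".Random.seed", envir = globalenv())
    }
  } else assign(".Random.seed", state, envir = globalenv())
}

# apply allele edits (SNV / deletion / insertion) to a sequence; edits are
# applied right-to-left so positions stay valid
apply_alleles <- function(seq, pos, alt) {
  if (length(pos) == 0) return(seq)
  o <- order(pos, decreasing = TRUE)
  s <- seq
  for (i in o) {
    p <- pos[i] + 1L  # 1-based
    a <- alt[i]
    if (p < 1 || p > nchar(seq) + 1L) abort("allele position outside locus")
    if (startsWith(a, "+")) {
      s <- paste0(substr(s, 1, p - 1L), substring(a, 2), substring(s, p))
    } else if (a == "-") {
      s <- paste0(substr(s, 1, p - 1L), substring(s, p + 1L))
    } else {
      substr(s, p, p) <- a
    }
  }
  s
}

#' Assemble haplotype sequences from a phasing
#'
#' Applies each phased allele vector to the locus consensus; deletion and
#' insertion alleles are spliced; identical sequences are deduplicated (their
#' support fractions summed).
#'
#' @param locus_seq Locus consensus sequence.
#' @param variants Variants tibble.
#' @param phasing Result of [phase_two_haplotypes()].
#' @return A tibble with `seq` and `fraction`, ordered by descending
#'   fraction then sequence.
#' @export
assemble_haplotypes <- function(locus_seq, variants, phasing) {
  if (nrow(variants) == 0 || is.null(phasing$h2)) {
    return(tibble(seq = locus_seq, fraction = 1))
  }
  mk <- function(h) {
    sel <- h == 1L
    apply_alleles(locus_seq, variants$pos[sel], variants$alt[sel])
  }
  seqs <- c(mk(phasing$h1), mk(phasing$h2))
  out <- tibble(seq = seqs, fraction = phasing$fractions)
  out <- dplyr::summarise(dplyr::group_by(out, .data$seq),
                          fraction = sum(.data$fraction), .groups = "drop")
  out[order(-out$fraction, out$seq), ]
}
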