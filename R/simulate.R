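# Ground-truth simulator: genomes with embedded multi-copy marker variants,
# shotgun reads, synthetic communities and amplicon runs. Defaults mirror the
# data regimes the pipeline is built for (1-7 copies, 1-3 haplotypes, ~50x
# genomic coverage, 0.1% base error, 150 bp shotgun / 250 bp amplicon reads).

# primer-binding and terminal intervals of the bundled seed (0-based,
# half-open) that simulated mutations never touch: in real 16S rRNA genes
# these regions are conserved (that is why universal primers exist)
SEED_PROTECTED <- list(c(0L, 20L), c(340L, 357L), c(780L, 805L),
                       c(1170L, 1188L), c(1524L, 1544L))

#' Load the bundled synthetic seed marker gene
#'
#' A synthetic 1,544 bp 16S rRNA-like sequence with V3-V4 and V5-V7 primer
#' sites embedded at positions approximating the standard gene numbering. It
#' is generated, not a natural sequence.
#'
#' @return A single sequence string with attribute `protected` (intervals
#'   held conserved by the simulator).
#' @export
load_seed_marker <- function() {
  path <- system.file("extdata", "synthetic_16S_seed.fa",
                      package = "fingerquant")
  seq <- read_fasta(path)$seq[1]
  attr(seq, "protected") <- SEED_PROTECTED
  seq
}

#' The two standard primer pairs
#'
#' @param name `"V3V4"` or `"V5V7"`.
#' @return An [primer_pair()] object.
#' @export
standard_primers <- function(name = c("V3V4", "V5V7")) {
  name <- match.arg(name)
  switch(name,
         V3V4 = primer_pair("V3V4", "CCTACGGGNGGCWGCAG",
                            "GACTACHVGGGTATCTAATCC"),
         V5V7 = primer_pair("V5V7", "AACMGGATTAGATACCCKG",
                            "ACGTCATCCCCACCTTCC"))
}

#' Simulation configuration
#'
#' @param seed RNG seed.
#' @param genome_len Background genome length (bp). The default 25 kb is a
#'   desk-scale surrogate for a Mb-scale genome: copy-number estimation
#'   depends on the locus/genome depth ratio, which is length-invariant.
#' @param n_copies Marker copies embedded in the genome.
#' @param n_haplotypes Distinct haplotypes among the copies (at most
#'   `n_copies`).
#' @param n_variant_sites SNP sites distinguishing the haplotypes.
#' @param coverage Genome-wide shotgun coverage (x).
#' @param read_len Shotgun read length (bp).
#' @param base_error Per-base substitution error probability (0 to 0.1).
#' @param gene_divergence Divergence of the member's gene from the seed.
#' @param variant_region Interval (0-based) of the gene within which the
#'   variant window is placed; the default sits inside the V3-V4 amplicon.
#' @param variant_span Width of the contiguous window holding all variant
#'   sites, keeping them within read span (real intragenomic variation
#'   clusters in hypervariable loops).
#' @param paired Emit paired shotgun reads?
#' @param fragment_len,fragment_sd Fragment model for paired reads.
#' @return A `fq_sim_config` list.
#' @export
sim_config <- function(seed = 42L, genome_len = 25000L, n_copies = 4L,
                       n_haplotypes = 2L, n_variant_sites = 3L,
                       coverage = 50, read_len = 150L, base_error = 0.001,
                       gene_divergence = 0.02,
                       variant_region = c(400L, 700L), variant_span = 100L,
                       paired = FALSE, fragment_len = 450L,
                       fragment_sd = 50L) {
  stopifnot(n_haplotypes <= n_copies, n_haplotypes >= 1,
            base_error >= 0, base_error <= 0.1, genome_len > 0)
  structure(list(seed = as.integer(seed), genome_len = as.integer(genome_len),
                 n_copies = as.integer(n_copies),
                 n_haplotypes = as.integer(n_haplotypes),
                 n_variant_sites = as.integer(n_variant_sites),
                 coverage = coverage, read_len = as.integer(read_len),
                 base_error = base_error, gene_divergence = gene_divergence,
                 variant_region = as.integer(variant_region),
                 variant_span = as.integer(variant_span),
                 paired = paired, fragment_len = as.integer(fragment_len),
                 fragment_sd = as.integer(fragment_sd)),
            class = "fq_sim_config")
}

random_dna <- function(n, gc = 0.5) {
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE,
               prob = c((1 - gc) / 2, gc / 2, gc / 2, (1 - gc) / 2)),
        collapse = "")
}

# substitute the bases at `pos` (0-based) with random different bases
mutate_at <- function(seq, pos, alts = NULL) {
  if (length(pos) == 0) return(seq)
  ch <- strsplit(seq, "")[[1]]
  for (i in seq_along(pos)) {
    p <- pos[i] + 1L
    alt <- if (!is.null(alts)) alts[i] else
      sample(setdiff(c("A", "C", "G", "T"), ch[p]), 1)
    ch[p] <- alt
  }
  paste(ch, collapse = "")
}

positions_outside <- function(n, protected) {
  pos <- seq_len(n) - 1L
  for (iv in protected) pos <- pos[pos < iv[1] | pos >= iv[2]]
  pos
}

# per-read substitution errors at rate p; vectorized over the read set
inject_errors <- function(seqs, p) {
  if (p <= 0 || length(seqs) == 0) return(seqs)
  nerr <- rbinom(length(seqs), nchar(seqs), p)
  for (i in which(nerr > 0)) {
    ch <- strsplit(seqs[i], "")[[1]]
    at <- sample.int(length(ch), nerr[i])
    for (p1 in at) ch[p1] <- sample(setdiff(c("A", "C", "G", "T"), ch[p1]), 1)
    seqs[i] <- paste(ch, collapse = "")
  }
  seqs
}

revcomp_many <- function(x) {
  as.character(Biostrings::reverseComplement(Biostrings::DNAStringSet(x)))
}

qual_string <- function(base_error, len) {
  q <- if (base_error <= 0) 40L else
    min(40L, as.integer(round(-10 * log10(base_error))))
  strrep(intToUtf8(q + 33L), len)
}

#' Simulate one isolate: genome, shotgun reads and ground truth
#'
#' A random background genome receives `n_copies` embedded copies of a
#' seed-derived marker gene (the member's gene diverges from the seed by
#' `gene_divergence`), with `n_haplotypes` variants differing at
#' `n_variant_sites` SNPs clustered in a window of `variant_span` bp.
#' Shotgun reads are drawn uniformly with the stated per-base error and
#' constant Phred qualities consistent with it. Fully reproducible from
#' `cfg$seed`.
#'
#' @param cfg An [sim_config()] object.
#' @param seed_marker Seed gene sequence; defaults to the bundled synthetic
#'   seed. Protected intervals are taken from its `protected` attribute
#'   (terminal 20 bp only, for plain strings).
#' @return A list with `assembly` (tibble `id`, `seq`), `reads` (FASTQ-style
#'   tibble), `truth` (gene, haplotypes with copies, locus coordinates) and
#'   the config echo.
#' @export
simulate_isolate <- function(cfg, seed_marker = NULL) {
  stopifnot(inherits(cfg, "fq_sim_config"))
  if (is.null(seed_marker)) seed_marker <- load_seed_marker()
  protected <- attr(seed_marker, "protected") %||%
    list(c(0L, 20L), c(nchar(seed_marker) - 20L, nchar(seed_marker)))
  rng <- .save_rng(); on.exit(.restore_rng(rng))
  set.seed(cfg$seed)
  L <- nchar(seed_marker)
  G <- cfg$genome_len
  C <- cfg$n_copies; H <- cfg$n_haplotypes
  eligible <- positions_outside(L, protected)
  # the member's gene: seed diverged at a fixed fraction of eligible sites
  ndiv <- round(cfg$gene_divergence * L)
  gene <- mutate_at(as.character(seed_marker),
                    sort(sample(eligible, min(ndiv, length(eligible)))))
  # haplotype variants: SNPs clustered in a window inside variant_region
  haps <- gene
  sites <- integer(0)
  if (H > 1) {
    lo <- cfg$variant_region[1]
    hi <- cfg$variant_region[2] - cfg$variant_span
    wstart <- if (hi > lo) sample(lo:hi, 1) else lo
    wpos <- intersect(wstart:(wstart + cfg$variant_span - 1L), eligible)
    if (length(wpos) < cfg$n_variant_sites) {
      abort("variant window too small for the requested variant sites")
    }
    sites <- sort(sample(wpos, cfg$n_variant_sites))
    gch <- strsplit(gene, "")[[1]]
    for (h in 2:H) {
      alts <- vapply(sites + 1L, function(p) {
        sample(setdiff(c("A", "C", "G", "T"), gch[p]), 1)
      }, character(1))
      haps <- c(haps, mutate_at(gene, sites, alts))
    }
    if (anyDuplicated(haps)) abort("internal: duplicate simulated haplotypes")
  }
  copies_per_hap <- rep(C %/% H, H) + as.integer(seq_len(H) <= C %% H)
  hap_of_copy <- rep(seq_len(H), times = copies_per_hap)
  # non-overlapping placement via a random composition of the slack
  margin <- 10L
  slack <- G - C * L - (C + 1L) * margin
  if (slack < 0) abort("genome too short for the requested copy placements")
  gaps <- margin + as.vector(rmultinom(1, slack, rep(1, C + 1L)))
  starts <- cumsum(gaps[seq_len(C)] + c(0L, rep(L, C - 1L)))
  strands <- sample(c("+", "-"), C, replace = TRUE)
  # assemble the genome
  pieces <- character(2 * C + 1L)
  prev <- 0L
  for (i in seq_len(C)) {
    pieces[2 * i - 1L] <- random_dna(starts[i] - prev)
    emb <- haps[hap_of_copy[i]]
    pieces[2 * i] <- if (strands[i] == "+") emb else revcomp(emb)
    prev <- starts[i] + L
  }
  pieces[2 * C + 1L] <- random_dna(G - prev)
  genome <- paste(pieces, collapse = "")
  stopifnot(nchar(genome) == G)
  truth <- list(
    gene = gene,
    haplotypes = tibble(seq = haps, copies = copies_per_hap),
    variant_sites = sites,
    loci = tibble(copy = seq_len(C), start = starts, end = starts + L,
                  strand = strands, haplotype = hap_of_copy),
    total_copies = C)
  # shotgun reads
  rl <- cfg$read_len
  if (cfg$paired) {
    nfrag <- round(cfg$coverage * G / (2 * rl))
    flen <- pmax(2L * rl,
                 as.integer(round(stats::rnorm(nfrag, cfg$fragment_len,
                                               cfg$fragment_sd))))
    flen <- pmin(flen, G)
    fstart <- vapply(flen, function(fl) sample.int(G - fl + 1L, 1L) - 1L,
                     integer(1))
    frag <- substring(genome, fstart + 1L, fstart + flen)
    r1 <- substr(frag, 1L, rl)
    r2 <- revcomp_many(substr(frag, flen - rl + 1L, flen))
    seqs <- c(r1, r2)
    ids <- c(sprintf("frag_%06d/1", seq_len(nfrag)),
             sprintf("frag_%06d/2", seq_len(nfrag)))
    mate <- c(rep(1L, nfrag), rep(2L, nfrag))
  } else {
    nread <- round(cfg$coverage * G / rl)
    rstart <- sample.int(G - rl + 1L, nread, replace = TRUE) - 1L
    seqs <- substring(genome, rstart + 1L, rstart + rl)
    flip <- runif(nread) < 0.5
    seqs[flip] <- revcomp_many(seqs[flip])
    ids <- sprintf("read_%06d", seq_len(nread))
    mate <- rep(NA_integer_, nread)
  }
  seqs <- inject_errors(seqs, cfg$base_error)
  reads <- tibble(id = ids, seq = seqs,
                  qual = qual_string(cfg$base_error, rl), mate = mate)
  list(assembly = tibble(id = "genome", seq = genome, desc = ""),
       reads = reads, truth = truth, config = cfg)
}

#' Simulate a community of isolate fingerprints
#'
#' Members carry seed-derived genes (pairwise divergent), 1-2 haplotypes and
#' copy numbers drawn from `copy_range`. `n_isogenic_pairs` of the members
#' are near-isogenic: the pair differs by exactly one SNP in one haplotype,
#' placed inside the V3-V4 amplicon.
#'
#' @param n_members Community size.
#' @param seed RNG seed.
#' @param n_isogenic_pairs Number of near-isogenic pairs among the members.
#' @param copy_range Range of total copy numbers.
#' @param divergence Member-to-seed gene divergence.
#' @param seed_marker Optional seed override.
#' @return A list with `fingerprints` (full-length), `abundances` (named,
#'   summing to 1) and `pairs` (tibble of near-isogenic pair ids).
#' @export
simulate_community <- function(n_members = 20L, seed = 42L,
                               n_isogenic_pairs = 0L, copy_range = c(1L, 7L),
                               divergence = 0.03, seed_marker = NULL) {
  if (is.null(seed_marker)) seed_marker <- load_seed_marker()
  protected <- attr(seed_marker, "protected") %||% list()
  rng <- .save_rng(); on.exit(.restore_rng(rng))
  set.seed(seed)
  stopifnot(2L * n_isogenic_pairs <= n_members)
  L <- nchar(seed_marker)
  eligible <- positions_outside(L, protected)
  # V3-V4 interior positions for discriminating SNPs
  amp_inner <- intersect(eligible, 400:740)
  n_base <- n_members - n_isogenic_pairs
  fps <- list(); abund <- numeric(); pairs <- list()
  mk_gene <- function() {
    mutate_at(as.character(seed_marker),
              sort(sample(eligible, round(divergence * L))))
  }
  mid <- 0L
  for (b in seq_len(n_base)) {
    mid <- mid + 1L
    id <- sprintf("member_%02d", mid)
    gene <- mk_gene()
    # members founding a near-isogenic pair carry a single haplotype: a twin
    # SNP shadowed by a second haplotype that is locally identical to the
    # reference allele would make the pair statistically non-identifiable
    # (nested references), which is not the scenario being stated
    n_hap <- if (b <= n_isogenic_pairs) 1L else sample(1:2, 1)
    total <- sample(copy_range[1]:copy_range[2], 1)
    n_hap <- min(n_hap, total)
    haps <- gene
    if (n_hap == 2) {
      w <- sample(amp_inner, 3)
      haps <- c(haps, mutate_at(gene, sort(w)))
    }
    cps <- rep(total %/% n_hap, n_hap) + as.integer(seq_len(n_hap) <= total %% n_hap)
    fps[[id]] <- build_fingerprint(id, haps, cps)
    if (b <= n_isogenic_pairs) {
      # twin: same fingerprint except one SNP in the first haplotype
      mid <- mid + 1L
      tid <- sprintf("member_%02d", mid)
      snp <- sample(amp_inner, 1)
      twin1 <- mutate_at(haps[1], snp)
      fps[[tid]] <- build_fingerprint(tid, c(twin1, haps[-1]), cps)
      pairs[[length(pairs) + 1L]] <- tibble(a = id, b = tid, snp_pos = snp)
    }
  }
  ab <- stats::rexp(length(fps)) + 0.2
  ab <- ab / sum(ab)
  names(ab) <- names(fps)
  list(fingerprints = fps, abundances = ab,
       pairs = if (length(pairs)) dplyr::bind_rows(pairs) else
         tibble(a = character(), b = character(), snp_pos = integer()))
}

#' Simulate a paired-end amplicon sequencing run
#'
#' Reads are drawn from members proportionally to cell abundance times
#' amplicon copy number (mirroring amplicon biology); within a member the
#' haplotype is chosen proportionally to its copies. Mates read inward from
#' the two amplicon ends; substitution errors are injected at `base_error`.
#'
#' @param fps List of fingerprints. Full-length fingerprints are trimmed
#'   with `primers` first; an unamplifiable member raises an error naming it.
#' @param abundances Named true cell abundances (summing to 1).
#' @param primers Optional [primer_pair()] for trimming full-length input.
#' @param n_reads Number of read pairs.
#' @param read_len Read length (bp, default 250).
#' @param base_error Per-base error probability.
#' @param seed RNG seed.
#' @return A list with `reads1`, `reads2` (FASTQ-style tibbles), `truth`
#'   (read-to-member map), `amplicons` (the trimmed fingerprints) and
#'   `expected_read_share` (abundance x copies, normalized).
#' @export
simulate_amplicon_run <- function(fps, abundances, primers = NULL,
                                  n_reads = 10000L, read_len = 250L,
                                  base_error = 0.001, seed = 1L) {
  rng <- .save_rng(); on.exit(.restore_rng(rng))
  set.seed(seed)
  if (inherits(fps, "fq_fingerprint")) fps <- list(fps)
  names(fps) <- vapply(fps, function(f) f$member_id, character(1))
  if (!is.null(primers)) {
    fps <- lapply(fps, function(fp) {
      if (fp$region == "full") extract_amplicon(fp, primers) else fp
    })
  }
  stopifnot(setequal(names(fps), names(abundances)))
  members <- names(fps)
  copies <- vapply(fps, function(f) f$total_copies, numeric(1))
  w <- abundances[members] * copies
  w <- w / sum(w)
  empty <- tibble(id = character(), seq = character(), qual = character(),
                  mate = integer())
  if (n_reads == 0) {
    return(list(reads1 = empty, reads2 = empty,
                truth = tibble(read_id = character(), member_id = character()),
                amplicons = fps, expected_read_share = w))
  }
  counts <- as.vector(rmultinom(1, n_reads, w))
  s1 <- character(n_reads); s2 <- character(n_reads)
  memb <- character(n_reads)
  pos <- 0L
  for (mi in seq_along(members)) {
    cm <- counts[mi]
    if (cm == 0) next
    fp <- fps[[mi]]
    hi <- sample.int(nrow(fp$haplotypes), cm, replace = TRUE,
                     prob = fp$haplotypes$copies)
    amp <- fp$haplotypes$seq[hi]
    al <- nchar(amp)
    idx <- pos + seq_len(cm)
    s1[idx] <- substr(amp, 1L, pmin(read_len, al))
    s2[idx] <- revcomp_many(substr(amp, pmax(1L, al - read_len + 1L), al))
    memb[idx] <- members[mi]
    pos <- pos + cm
  }
  s1 <- inject_errors(s1, base_error)
  s2 <- inject_errors(s2, base_error)
  ids <- sprintf("amp_%06d", seq_len(n_reads))
  q1 <- qual_string(base_error, read_len)
  list(reads1 = tibble(id = paste0(ids, "/1"), seq = s1, qual = q1,
                       mate = 1L),
       reads2 = tibble(id = paste0(ids, "/2"), seq = s2, qual = q1,
                       mate = 2L),
       truth = tibble(read_id = ids, member_id = memb),
       amplicons = fps, expected_read_share = w)
}
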