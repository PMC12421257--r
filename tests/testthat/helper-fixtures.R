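# Shared fixtures: everything is generated in code, nothing is read from
# disk except the bundled synthetic seed marker.

fx_seed <- load_seed_marker()

# deterministic random DNA
rand_dna <- function(n, seed = 1) {
  withr::with_seed(seed, paste(sample(c("A", "C", "G", "T"), n,
                                      replace = TRUE), collapse = ""))
}

# embed sequences into a random background at given 0-based starts
embed_in_background <- function(inserts, starts, genome_len, seed = 1,
                                strands = NULL) {
  stopifnot(length(inserts) == length(starts))
  bg <- strsplit(rand_dna(genome_len, seed), "")[[1]]
  if (is.null(strands)) strands <- rep("+", length(inserts))
  for (i in seq_along(inserts)) {
    s <- if (strands[i] == "+") inserts[i] else revcomp(inserts[i])
    ch <- strsplit(s, "")[[1]]
    bg[(starts[i] + 1):(starts[i] + length(ch))] <- ch
  }
  paste(bg, collapse = "")
}

# substitute bases at 0-based positions (deterministic alts: A<->C, G<->T)
sub_at <- function(seq, pos) {
  ch <- strsplit(seq, "")[[1]]
  swap <- c(A = "C", C = "A", G = "T", T = "G")
  for (p in pos) ch[p + 1] <- swap[[ch[p + 1]]]
  paste(ch, collapse = "")
}

# simple fingerprint around literal haplotypes
fp_of <- function(id, seqs, copies, region = "full") {
  build_fingerprint(id, seqs, copies, region = region)
}

# brute-force alignment oracle: best-orientation identity (matches /
# alignment columns of a read-global Biostrings alignment) of every read
# against every reference (reads x refs matrix)
oracle_identity_matrix <- function(reads, refs) {
  fwd <- Biostrings::DNAStringSet(reads)
  rev <- Biostrings::reverseComplement(fwd)
  out <- matrix(0, length(reads), length(refs))
  for (k in seq_along(refs)) {
    pf <- Biostrings::pairwiseAlignment(fwd, refs[[k]], type = "global-local")
    pr <- Biostrings::pairwiseAlignment(rev, refs[[k]], type = "global-local")
    out[, k] <- pmax(Biostrings::nmatch(pf) / Biostrings::nchar(pf),
                     Biostrings::nmatch(pr) / Biostrings::nchar(pr))
  }
  out
}
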