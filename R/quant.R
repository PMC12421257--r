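# Quantification: canonical k-mer equivalence-class index over spacer-joined
# fingerprints, pseudoalignment with an identity-validation step, EM
# resolution of multi-compatible reads, and copy-number normalization.

#' Build the k-mer equivalence-class index
#'
#' Canonical k-mers (the lexicographic minimum of a k-mer and its reverse
#' complement) of every fingerprint are mapped to equivalence classes of
#' member sets; the N spacer between haplotypes breaks k-merization so no
#' k-mer spans a junction.
#'
#' @param fps List of fingerprints (all members must be unique).
#' @param k K-mer size (default 31).
#' @return An object of class `fq_index`.
#' @export
build_index <- function(fps, k = 31L) {
  if (inherits(fps, "fq_fingerprint")) fps <- list(fps)
  if (length(fps) == 0) abort("no fingerprints to index")
  members <- vapply(fps, function(f) f$member_id, character(1))
  if (anyDuplicated(members)) abort("duplicate member ids in fingerprints")
  joined <- vapply(fps, function(fp) {
    short <- nchar(fp$haplotypes$seq) < k
    if (any(short)) {
      warn(sprintf("%s: %d haplotype(s) shorter than k=%d skipped",
                   fp$member_id, sum(short), k))
    }
    paste(fp$haplotypes$seq[!short], collapse = strrep("N", k))
  }, character(1))
  if (any(!nzchar(joined))) {
    abort("a fingerprint has no haplotype of length >= k")
  }
  ptr <- cpp_build_index(members, joined, k)
  copies <- vapply(fps, function(f) f$total_copies, numeric(1))
  structure(list(ptr = ptr, k = as.integer(k), members = members,
                 copy_numbers = setNames(copies, members)),
            class = "fq_index")
}

#' @export
print.fq_index <- function(x, ...) {
  info <- cpp_index_info(x$ptr)
  cat(sprintf("<fq_index> k=%d, %d members, %s canonical k-mers, %d equivalence classes\n",
              x$k, length(x$members), format(info$n_kmers, big.mark = ","),
              length(info$classes)))
  invisible(x)
}

#' Equivalence classes of an index
#'
#' @param index An [build_index()] object.
#' @return A list of character vectors (member sets), one per class.
#' @export
index_classes <- function(index) {
  info <- cpp_index_info(index$ptr)
  lapply(info$classes, function(i) index$members[i])
}

#' Quality-window read trimming
#'
#' Truncates each read to the window `[trim_5p, trim_3p)` (0-based), the
#' low-quality-trim convention for 250 bp amplicon reads; the window is
#' clipped at the read end, reads shorter than `trim_5p` are dropped, and
#' reads shorter than `min_len` after trimming are dropped.
#'
#' @param reads Reads tibble (`id`, `seq`, and optionally `qual`).
#' @param trim_5p,trim_3p Window bounds (defaults 20 and 240).
#' @param min_len Minimum post-trim length (default 31, the index k).
#' @return The trimmed reads tibble.
#' @export
preprocess_reads <- function(reads, trim_5p = 20L, trim_3p = 240L,
                             min_len = 31L) {
  n <- nchar(reads$seq)
  keep <- n > trim_5p
  reads <- reads[keep, ]
  n <- n[keep]
  to <- pmin(trim_3p, n)
  reads$seq <- substr(reads$seq, trim_5p + 1L, to)
  if (!is.null(reads$qual)) reads$qual <- substr(reads$qual, trim_5p + 1L, to)
  reads[nchar(reads$seq) >= min_len, ]
}

#' Pseudoalign reads to the index
#'
#' Strict intersection over the equivalence classes of the read's k-mers
#' (k-mers absent from the index are skipped); when the intersection is
#' empty, members hit by at least `majority` of the matched k-mers are taken.
#' For pairs, the candidate set is the intersection of the mates' sets when
#' both map, else the mapped mate's set.
#'
#' @param index An [build_index()] object.
#' @param reads1 Character vector of (trimmed) read sequences, or a reads
#'   tibble.
#' @param reads2 Optional second mates.
#' @param majority Majority-vote fallback threshold (default 0.8).
#' @return A list of integer member-index vectors, one per read (empty =
#'   unassigned); member ids are in `index$members`.
#' @export
pseudoalign <- function(index, reads1, reads2 = NULL, majority = 0.8) {
  s1 <- if (is.character(reads1)) reads1 else reads1$seq
  s2 <- if (is.null(reads2)) character() else
    if (is.character(reads2)) reads2 else reads2$seq
  cpp_pseudoalign(index$ptr, s1, s2, majority = majority)
}

#' Validate candidates by alignment identity
#'
#' Each read is aligned (banded, anchored by shared k-mers) against every
#' candidate fingerprint; candidates with identity below `min_identity`
#' (default 0.95, the minimum mapping read identity score) are removed. For
#' pairs the identity is pooled over both mates.
#'
#' @param index An [build_index()] object.
#' @param reads1,reads2 Read sequences as in [pseudoalign()].
#' @param candidates List from [pseudoalign()].
#' @param min_identity Identity floor (default 0.95).
#' @param band Alignment band half-width.
#' @return A list with `candidates` (filtered member-index lists) and
#'   `identity` (parallel identity lists).
#' @export
validate_identity <- function(index, reads1, reads2 = NULL, candidates,
                              min_identity = 0.95, band = 8L) {
  s1 <- if (is.character(reads1)) reads1 else reads1$seq
  s2 <- if (is.null(reads2)) character() else
    if (is.character(reads2)) reads2 else reads2$seq
  cpp_validate_identity(index$ptr, s1, s2, candidates,
                        min_identity = min_identity, band = band)
}

#' EM resolution of multi-compatible reads
#'
#' Fits a categorical mixture over members: the E-step distributes each read
#' over its candidates proportionally to the member weights, the M-step
#' re-estimates the weights from the posteriors. Reads are grouped by
#' candidate set (equivalence classes), so the cost per iteration is
#' independent of read count. Exactly symmetric evidence stays at the
#' symmetric fixed point (uniform initialization, no randomness).
#'
#' @param assignments List of candidate member-index vectors (post
#'   validation); empty vectors are unassigned reads.
#' @param n_members Number of members in the index.
#' @param max_iter,tol Convergence controls (`max |delta theta| < tol`).
#' @return A list with `raw_counts` (expected reads per member),
#'   `theta` (mixture weights), `mapping_rate`, `n_assigned`, `n_reads`,
#'   `confidence` (per member, mean posterior over its compatible reads) and
#'   `loglik_trace`.
#' @export
em_quantify <- function(assignments, n_members, max_iter = 1000L,
                        tol = 1e-8) {
  n_reads <- length(assignments)
  nonempty <- lengths(assignments) > 0
  n_assigned <- sum(nonempty)
  if (n_assigned == 0) {
    return(list(raw_counts = rep(0, n_members), theta = rep(0, n_members),
                mapping_rate = 0, n_assigned = 0L, n_reads = n_reads,
                confidence = rep(NA_real_, n_members),
                loglik_trace = numeric()))
  }
  keys <- vapply(assignments[nonempty],
                 function(x) paste(sort(x), collapse = ","), character(1))
  tab <- table(keys)
  class_members <- lapply(strsplit(names(tab), ","), as.integer)
  cnt <- as.numeric(tab)
  C <- length(cnt)
  # class membership as a sparse pair list
  pair_class <- rep(seq_len(C), lengths(class_members))
  pair_member <- unlist(class_members)
  fclass <- factor(pair_class, levels = seq_len(C))
  theta <- rep(1 / n_members, n_members)
  ll_trace <- numeric()
  for (it in seq_len(max_iter)) {
    denom <- as.vector(tapply(theta[pair_member], fclass, sum))
    ll_trace <- c(ll_trace, sum(cnt * log(pmax(denom, 1e-300))))
    post <- theta[pair_member] / denom[pair_class]
    new_theta <- rep(0, n_members)
    agg <- tapply(cnt[pair_class] * post, pair_member, sum)
    new_theta[as.integer(names(agg))] <- as.vector(agg)
    new_theta <- new_theta / sum(new_theta)
    delta <- max(abs(new_theta - theta))
    theta <- new_theta
    if (delta < tol) break
  }
  denom <- as.vector(tapply(theta[pair_member], fclass, sum))
  post <- theta[pair_member] / pmax(denom[pair_class], 1e-300)
  raw <- rep(0, n_members)
  agg <- tapply(cnt[pair_class] * post, pair_member, sum)
  raw[as.integer(names(agg))] <- as.vector(agg)
  # confidence: mean posterior of a member over the reads compatible with it
  conf <- rep(NA_real_, n_members)
  wsum <- tapply(cnt[pair_class] * post, pair_member, sum)
  wn <- tapply(cnt[pair_class], pair_member, sum)
  conf[as.integer(names(wsum))] <- as.vector(wsum) / as.vector(wn)
  list(raw_counts = raw, theta = theta,
       mapping_rate = n_assigned / n_reads,
       n_assigned = as.integer(n_assigned), n_reads = as.integer(n_reads),
       confidence = conf, loglik_trace = ll_trace)
}

#' Copy-number normalization of raw counts
#'
#' `a_m = (raw_m / copies_m) / sum_j (raw_j / copies_j)`.
#'
#' @param raw_counts Named (or positional) raw counts.
#' @param copy_numbers Copies per member, aligned with `raw_counts`.
#' @return Relative abundances summing to 1 over detected members.
#' @export
copy_normalize <- function(raw_counts, copy_numbers) {
  if (!is.null(names(raw_counts)) && !is.null(names(copy_numbers))) {
    missing <- setdiff(names(raw_counts)[raw_counts > 0], names(copy_numbers))
    if (length(missing)) {
      abort(paste0("no copy number for counted member(s): ",
                   paste(missing, collapse = ", ")))
    }
    copy_numbers <- copy_numbers[names(raw_counts)]
  }
  if (any(is.na(copy_numbers)) || any(copy_numbers < 1)) {
    abort("copy numbers must be >= 1 for every counted member")
  }
  w <- raw_counts / copy_numbers
  tot <- sum(w)
  if (tot == 0) return(w)
  w / tot
}

#' Quantify a community from amplicon reads
#'
#' The full third stage: quality-window trimming, pseudoalignment,
#' identity validation, EM, and copy-number normalization.
#'
#' @param index An [build_index()] object.
#' @param reads1 Reads tibble or character vector.
#' @param reads2 Optional mates.
#' @param min_identity Minimum mapping read identity score (default 0.95).
#' @param majority Majority-vote fallback threshold.
#' @param trim Apply [preprocess_reads()] first? (default TRUE when `reads1`
#'   is a tibble with `qual`).
#' @param trim_5p,trim_3p Trim window (defaults 20/240).
#' @param copy_numbers Named copies per member; defaults to those stored in
#'   the index.
#' @return An object of class `fq_quant` with a tidy result table.
#' @export
quantify <- function(index, reads1, reads2 = NULL, min_identity = 0.95,
                     majority = 0.8, trim = NULL, trim_5p = 20L,
                     trim_3p = 240L, copy_numbers = NULL) {
  is_tbl <- !is.character(reads1)
  if (is.null(trim)) trim <- is_tbl && !is.null(reads1[["qual"]])
  if (trim) {
    r1 <- preprocess_reads(as_tibble(if (is_tbl) reads1 else tibble(id = seq_along(reads1), seq = reads1)),
                           trim_5p, trim_3p, min_len = index$k)
    if (!is.null(reads2)) {
      r2 <- preprocess_reads(as_tibble(reads2), trim_5p, trim_3p,
                             min_len = index$k)
      ids <- intersect(sub("/[12]$", "", r1$id), sub("/[12]$", "", r2$id))
      r1 <- r1[sub("/[12]$", "", r1$id) %in% ids, ]
      r2 <- r2[sub("/[12]$", "", r2$id) %in% ids, ]
      reads2 <- r2
    }
    reads1 <- r1
  }
  cand <- pseudoalign(index, reads1, reads2, majority = majority)
  val <- validate_identity(index, reads1, reads2, cand,
                           min_identity = min_identity)
  em <- em_quantify(val$candidates, length(index$members))
  raw <- setNames(em$raw_counts, index$members)
  copies <- copy_numbers %||% index$copy_numbers
  norm <- copy_normalize(raw, copies)
  tb <- tibble(member_id = index$members,
               raw_count = as.numeric(raw),
               copy_number = as.numeric(copies[index$members]),
               norm_abundance = as.numeric(norm),
               confidence = em$confidence)
  structure(list(table = tb, mapping_rate = em$mapping_rate,
                 n_reads = em$n_reads, n_assigned = em$n_assigned,
                 loglik_trace = em$loglik_trace,
                 min_identity = min_identity, k = index$k),
            class = "fq_quant")
}

#' @export
print.fq_quant <- function(x, ...) {
  cat(sprintf("<fq_quant> %d members, %d/%d reads assigned (mapping rate %.3f)\n",
              nrow(x$table), x$n_assigned, x$n_reads, x$mapping_rate))
  print(x$table, n = 10)
  invisible(x)
}

#' Write a quantification result as TSV
#'
#' @param x An `fq_quant` object.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_quant_tsv <- function(x, path) {
  write.table(x$table, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
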