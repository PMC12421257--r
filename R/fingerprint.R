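# Fingerprints: ordered haplotype sets with copy numbers, their FASTA
# serialization, and in-silico PCR trimming to amplicon regions with
# degenerate primers.

#' Build a per-isolate fingerprint
#'
#' Haplotypes with identical sequences are merged (copies summed); the result
#' is ordered by descending copies, then lexicographic sequence.
#'
#' @param member_id Isolate identifier.
#' @param haplotypes Character vector of haplotype sequences.
#' @param copies Integer copies per haplotype (each at least 1).
#' @param region Region tag: `"full"` or an amplicon name such as `"V3V4"`.
#' @return An object of class `fq_fingerprint`.
#' @export
build_fingerprint <- function(member_id, haplotypes, copies,
                              region = "full") {
  stopifnot(length(haplotypes) >= 1, length(haplotypes) == length(copies))
  if (any(copies < 1)) abort("every haplotype needs at least one copy")
  tb <- tibble(seq = haplotypes, copies = as.integer(copies))
  tb <- dplyr::summarise(dplyr::group_by(tb, .data$seq),
                         copies = sum(.data$copies), .groups = "drop")
  tb <- tb[order(-tb$copies, tb$seq), ]
  structure(list(member_id = member_id, haplotypes = tb,
                 total_copies = sum(tb$copies), region = region),
            class = "fq_fingerprint")
}

#' @export
print.fq_fingerprint <- function(x, ...) {
  cat(sprintf("<fq_fingerprint> %s [%s]: %d haplotype(s), %d total copies\n",
              x$member_id, x$region, nrow(x$haplotypes), x$total_copies))
  invisible(x)
}

#' Spacer-joined fingerprint sequence
#'
#' Haplotypes concatenated with a run of `spacer` N's between them, so that
#' no k-mer of size `<= spacer` spans a haplotype junction. Used as the
#' quantification-index sequence, never in FASTA output.
#'
#' @param fp A fingerprint.
#' @param spacer Spacer length (default 31, matching the index k).
#' @return A single string.
#' @export
fingerprint_serialize <- function(fp, spacer = 31L) {
  paste(fp$haplotypes$seq, collapse = strrep("N", spacer))
}

#' Define a degenerate primer pair
#'
#' `rev` is given 5'->3' on the opposite strand, as primers are ordered.
#'
#' @param name Amplicon name (e.g. `"V3V4"`).
#' @param fwd,rev IUPAC primer strings (length at least 10).
#' @param max_mismatches Mismatch allowance per primer site (default 2; no
#'   indels).
#' @return An object of class `fq_primer_pair`.
#' @examples
#' primer_pair("V3V4", "CCTACGGGNGGCWGCAG", "GACTACHVGGGTATCTAATCC")
#' @export
primer_pair <- function(name, fwd, rev, max_mismatches = 2L) {
  fwd <- normalize_seq(fwd, "iupac", "fwd primer")
  rev <- normalize_seq(rev, "iupac", "rev primer")
  if (nchar(fwd) < 10 || nchar(rev) < 10) abort("primers must be >= 10 bp")
  structure(list(name = name, fwd = fwd, rev = rev,
                 max_mismatches = as.integer(max_mismatches)),
            class = "fq_primer_pair")
}

# IUPAC-aware primer sites: start positions (0-based) and mismatch counts
primer_sites <- function(primer, seq, max_mismatches) {
  p <- Biostrings::DNAString(primer)
  s <- Biostrings::DNAString(seq)
  hits <- Biostrings::matchPattern(p, s, max.mismatch = max_mismatches,
                                   with.indels = FALSE, fixed = FALSE)
  if (length(hits) == 0) {
    return(tibble(start = integer(), mismatches = integer()))
  }
  st <- BiocGenerics::start(hits)
  mm <- Biostrings::neditStartingAt(p, s, starting.at = st,
                                    with.indels = FALSE, fixed = FALSE)
  tibble(start = st - 1L, mismatches = as.integer(mm))
}

#' Trim a full-length fingerprint to an amplicon region
#'
#' For each haplotype, finds the best forward-primer site and the best
#' reverse-primer site (as the reverse complement of `rev`) downstream, and
#' emits the region between the primers (primers excluded unless
#' `keep_primers`). Among valid site pairs the one with the fewest total
#' mismatches, then the longest amplicon, wins. Haplotypes whose amplicons
#' become identical are merged with copies summed; haplotypes lacking a
#' primer site are dropped with a warning.
#'
#' @param fp A full-length fingerprint.
#' @param primers An [primer_pair()] object.
#' @param keep_primers Include the primer sites in the amplicon?
#' @param min_len Minimum amplicon length between the primers (default 50).
#' @return An amplicon fingerprint tagged with the primer-pair name.
#' @export
extract_amplicon <- function(fp, primers, keep_primers = FALSE,
                             min_len = 50L) {
  stopifnot(inherits(fp, "fq_fingerprint"), inherits(primers, "fq_primer_pair"))
  rcrev <- revcomp(primers$rev)
  lf <- nchar(primers$fwd); lr <- nchar(rcrev)
  seqs <- character(); cps <- integer(); dropped <- character()
  for (i in seq_len(nrow(fp$haplotypes))) {
    hap <- fp$haplotypes$seq[i]
    fsite <- primer_sites(primers$fwd, hap, primers$max_mismatches)
    rsite <- primer_sites(rcrev, hap, primers$max_mismatches)
    best <- NULL
    for (a in seq_len(nrow(fsite))) {
      ins_start <- fsite$start[a] + lf
      ok <- rsite$start >= ins_start + min_len
      for (b in which(ok)) {
        cand <- list(mm = fsite$mismatches[a] + rsite$mismatches[b],
                     len = rsite$start[b] - ins_start,
                     fs = fsite$start[a], rs = rsite$start[b])
        if (is.null(best) || cand$mm < best$mm ||
            (cand$mm == best$mm && cand$len > best$len)) best <- cand
      }
    }
    if (is.null(best)) { dropped <- c(dropped, as.character(i)); next }
    amp <- if (keep_primers) {
      substr(hap, best$fs + 1L, best$rs + lr)
    } else {
      substr(hap, best$fs + lf + 1L, best$rs)
    }
    seqs <- c(seqs, amp); cps <- c(cps, fp$haplotypes$copies[i])
  }
  if (length(seqs) == 0) {
    abort(sprintf("amplicon not found for member %s", fp$member_id))
  }
  if (length(dropped)) {
    warn(sprintf("%s: haplotype(s) %s lack a %s primer site and were dropped",
                 fp$member_id, paste(dropped, collapse = ","), primers$name))
  }
  build_fingerprint(fp$member_id, seqs, cps, region = primers$name)
}

#' Trim a set of fingerprints to an amplicon region
#'
#' @param fps List of fingerprints.
#' @param primers An [primer_pair()] object.
#' @param on_missing `"error"` to fail on the first member without an
#'   amplicon, `"drop"` to drop such members with a warning.
#' @inheritParams extract_amplicon
#' @return A list of amplicon fingerprints.
#' @export
extract_amplicons <- function(fps, primers, keep_primers = FALSE,
                              min_len = 50L, on_missing = c("error", "drop")) {
  on_missing <- match.arg(on_missing)
  out <- list()
  for (fp in fps) {
    res <- tryCatch(extract_amplicon(fp, primers, keep_primers, min_len),
                    error = function(e) e)
    if (inherits(res, "error")) {
      if (on_missing == "error") stop(res)
      warn(conditionMessage(res))
    } else out[[fp$member_id]] <- res
  }
  out
}

#' Write fingerprints as FASTA
#'
#' One record per haplotype with header
#' `member_id|hap=i|copies=c|region=tag`. The N-spacer joined form is only
#' used internally for the quantification index, never in this file.
#'
#' @param fps A fingerprint or list of fingerprints.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_fingerprints <- function(fps, path) {
  if (inherits(fps, "fq_fingerprint")) fps <- list(fps)
  rows <- purrr::map_dfr(fps, function(fp) {
    tibble(id = sprintf("%s|hap=%d|copies=%d|region=%s", fp$member_id,
                        seq_len(nrow(fp$haplotypes)), fp$haplotypes$copies,
                        fp$region),
           seq = fp$haplotypes$seq, desc = "")
  })
  write_fasta(rows, path)
}

#' Read fingerprints from FASTA
#'
#' @param path Path written by [write_fingerprints()].
#' @return A named list of fingerprints.
#' @export
read_fingerprints <- function(path) {
  fa <- read_fasta(path)
  parts <- stringi::stri_match_first_regex(
    fa$id, "^(.+)\\|hap=(\\d+)\\|copies=(\\d+)\\|region=([^|]+)$")
  bad <- which(is.na(parts[, 1]))
  if (length(bad)) {
    abort(sprintf("malformed fingerprint header: '%s'", fa$id[bad[1]]))
  }
  df <- tibble(member_id = parts[, 2], seq = fa$seq,
               copies = as.integer(parts[, 4]), region = parts[, 5])
  out <- lapply(split(df, factor(df$member_id, levels = unique(df$member_id))),
                function(d) build_fingerprint(d$member_id[1], d$seq, d$copies,
                                              region = d$region[1]))
  out[unique(df$member_id)]
}

#' Copy-number sidecar table for a set of fingerprints
#'
#' @param fps List of fingerprints.
#' @return Tibble: `member_id`, `region`, `haplotype_index`, `copies`,
#'   `total_copies`.
#' @export
fingerprint_copies <- function(fps) {
  if (inherits(fps, "fq_fingerprint")) fps <- list(fps)
  purrr::map_dfr(fps, function(fp) {
    tibble(member_id = fp$member_id, region = fp$region,
           haplotype_index = seq_len(nrow(fp$haplotypes)),
           copies = fp$haplotypes$copies, total_copies = fp$total_copies)
  })
}
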