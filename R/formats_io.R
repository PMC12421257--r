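# Readers/writers for FASTA/FASTQ/abundance TSV and low-level sequence
# utilities. Parsing is delegated to Biostrings; this layer normalizes case,
# maps U to T, validates alphabets and presents everything as tibbles.

IUPAC_SETS <- list(
  A = "A", C = "C", G = "G", T = "T",
  M = c("A", "C"), R = c("A", "G"), W = c("A", "T"),
  S = c("C", "G"), Y = c("C", "T"), K = c("G", "T"),
  V = c("A", "C", "G"), H = c("A", "C", "T"),
  D = c("A", "G", "T"), B = c("C", "G", "T"),
  N = c("A", "C", "G", "T")
)
IUPAC_CHARS <- paste0(names(IUPAC_SETS), collapse = "")
# complement map (complement of each degeneracy set)
IUPAC_COMP <- "TGCAKYWSRMBDHVN"

normalize_seq <- function(seq, alphabet = c("iupac", "acgtn"), what = "sequence") {
  alphabet <- match.arg(alphabet)
  seq <- chartr("u", "t", toupper(seq))
  seq <- chartr("U", "T", seq)
  allowed <- if (alphabet == "iupac") IUPAC_CHARS else "ACGTN"
  bad <- stringi::stri_detect_regex(seq, paste0("[^", allowed, "]"))
  if (any(bad)) {
    abort(sprintf("%s %d contains characters outside {%s}",
                  what, which(bad)[1], allowed))
  }
  seq
}

#' Read a FASTA file
#'
#' Sequences are uppercased, `U` is mapped to `T`, and IUPAC ambiguity codes
#' are retained. Gzip input is detected transparently.
#'
#' @param path Path to a FASTA file (optionally gzipped).
#' @return A tibble with columns `id`, `seq`, `desc`, in file order.
#' @export
read_fasta <- function(path) {
  if (!file.exists(path)) abort(paste0("file not found: ", path))
  x <- tryCatch(Biostrings::readBStringSet(path, format = "fasta"),
                error = function(e) abort(paste0("malformed FASTA in ", path,
                                                 ": ", conditionMessage(e))))
  if (length(x) == 0) return(tibble(id = character(), seq = character(),
                                    desc = character()))
  hdr <- names(x)
  id <- sub("\\s.*$", "", hdr)
  desc <- ifelse(grepl("\\s", hdr), sub("^\\S+\\s+", "", hdr), "")
  seq <- as.character(x)
  empty <- !nzchar(seq)
  if (any(empty)) {
    abort(sprintf("empty sequence for record '%s' in %s", id[which(empty)[1]], path))
  }
  if (anyDuplicated(id)) {
    abort(sprintf("duplicate record id '%s' in %s", id[anyDuplicated(id)], path))
  }
  tibble(id = id, seq = normalize_seq(unname(seq), "iupac", "record"),
         desc = desc)
}

#' Write sequences as FASTA
#'
#' @param x A tibble with columns `id`, `seq` (and optionally `desc`), or a
#'   named character vector.
#' @param path Output path.
#' @param width Line-wrap width for sequences.
#' @return `path`, invisibly.
#' @export
write_fasta <- function(x, path, width = 70L) {
  x <- as_seq_tbl(x)
  hdr <- paste0(">", x$id, ifelse(nzchar(x$desc), paste0(" ", x$desc), ""))
  wrapped <- vapply(x$seq, function(s) {
    n <- nchar(s)
    paste0(substring(s, seq(1, n, width), pmin(seq(1, n, width) + width - 1L, n)),
           collapse = "\n")
  }, character(1))
  writeLines(paste0(hdr, "\n", wrapped), path)
  invisible(path)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# accept tibble(id, seq[, desc]) or named character
as_seq_tbl <- function(x) {
  if (is.character(x)) {
    ids <- names(x) %||% paste0("seq", seq_along(x))
    return(tibble(id = ids, seq = unname(x), desc = ""))
  }
  stopifnot(all(c("id", "seq") %in% names(x)))
  if (!"desc" %in% names(x)) x$desc <- ""
  as_tibble(x[c("id", "seq", "desc")])
}

#' Read a FASTQ file (Phred+33)
#'
#' Quality strings are decoded as `ord(char) - 33`. Inputs that look
#' Phred+64-encoded are rejected, as are reads containing characters outside
#' `{A,C,G,T,N}`.
#'
#' @param path Path to a FASTQ file (optionally gzipped).
#' @param mate Mate label for all reads in this file: 1, 2, or `NA` to infer
#'   from `/1`/`/2` id suffixes (default).
#' @return A tibble with columns `id`, `seq`, `qual` (raw quality string),
#'   `quals` (list of integer Phred scores) and `mate`.
#' @export
read_fastq <- function(path, mate = NA) {
  if (!file.exists(path)) abort(paste0("file not found: ", path))
  # strict 4-line-record parser (gzfile handles gzip by magic bytes and
  # plain text transparently); delegating to a lenient reader would let
  # sequence/quality length mismatches through silently
  con <- gzfile(path, "rt")
  on.exit(close(con))
  lines <- readLines(con)
  if (length(lines) == 0) {
    return(tibble(id = character(), seq = character(), qual = character(),
                  quals = list(), mate = integer()))
  }
  if (length(lines) %% 4 != 0) {
    abort(sprintf("malformed FASTQ in %s: %d lines is not a multiple of 4",
                  path, length(lines)))
  }
  hdr <- lines[seq(1, length(lines), 4)]
  seq <- lines[seq(2, length(lines), 4)]
  plus <- lines[seq(3, length(lines), 4)]
  qual <- lines[seq(4, length(lines), 4)]
  bad <- which(!startsWith(hdr, "@") | !startsWith(plus, "+"))
  if (length(bad)) {
    abort(sprintf("malformed FASTQ record %d (line %d) in %s", bad[1],
                  4L * (bad[1] - 1L) + 1L, path))
  }
  seq <- normalize_seq(seq, "acgtn", "read")
  if (any(nchar(qual) != nchar(seq))) {
    bad <- which(nchar(qual) != nchar(seq))[1]
    abort(sprintf("read %d: quality length differs from sequence length", bad))
  }
  quals <- lapply(qual, function(q) utf8ToInt(q) - 33L)
  qv <- unlist(quals, use.names = FALSE)
  if (length(qv) && min(qv) < 0) abort("quality characters below '!': not Phred+33")
  if (length(qv) && min(qv) >= 31 && max(qv) > 45) {
    abort("qualities look Phred+64-encoded; only Phred+33 input is supported")
  }
  id <- sub("\\s.*$", "", substring(hdr, 2))
  if (is.na(mate)) {
    m <- ifelse(grepl("/1$", id), 1L, ifelse(grepl("/2$", id), 2L, NA_integer_))
  } else m <- rep(as.integer(mate), length(id))
  tibble(id = id, seq = seq, qual = qual, quals = quals, mate = m)
}

#' Write reads as FASTQ (Phred+33)
#'
#' @param x A tibble with columns `id`, `seq`, `qual`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_fastq <- function(x, path) {
  stopifnot(all(c("id", "seq", "qual") %in% names(x)))
  writeLines(paste0("@", x$id, "\n", x$seq, "\n+\n", x$qual), path)
  invisible(path)
}

#' Reverse complement with IUPAC-aware complementation
#'
#' @param seq Character vector of DNA strings over the IUPAC alphabet.
#' @return Reverse complements, vectorized over `seq`.
#' @examples
#' revcomp("CCTACGGGNGGCWGCAG")
#' @export
revcomp <- function(seq) {
  seq <- normalize_seq(seq, "iupac")
  stringi::stri_reverse(chartr(IUPAC_CHARS, IUPAC_COMP, seq))
}

#' Does a concrete base fall in the degeneracy set of an IUPAC code?
#'
#' @param base A base in `{A,C,G,T}` (vectorized).
#' @param code An IUPAC code (vectorized, recycled against `base`).
#' @return Logical vector.
#' @examples
#' iupac_match("A", "W")  # TRUE
#' iupac_match("G", "H")  # FALSE
#' @export
iupac_match <- function(base, code) {
  base <- toupper(base); code <- toupper(code)
  if (!all(base %in% c("A", "C", "G", "T"))) {
    abort("base must be one of A, C, G, T")
  }
  if (!all(code %in% names(IUPAC_SETS))) {
    abort(sprintf("unknown IUPAC code: %s",
                  paste(setdiff(code, names(IUPAC_SETS)), collapse = ", ")))
  }
  mapply(function(b, k) b %in% IUPAC_SETS[[k]], base, code, USE.NAMES = FALSE)
}

#' Read an abundance table from TSV
#'
#' Rows are members, columns are samples; the first column must be
#' `member_id`.
#'
#' @param path Path to the TSV.
#' @param relative Is the table in relative-abundance form? If `TRUE`, each
#'   sample must sum to 1 within `1e-9`.
#' @return A numeric matrix (members x samples) with `relative` attribute.
#' @export
read_abundance_tsv <- function(path, relative = FALSE) {
  df <- read.delim(path, check.names = FALSE, stringsAsFactors = FALSE)
  if (names(df)[1] != "member_id") abort("first column must be 'member_id'")
  m <- as.matrix(df[, -1, drop = FALSE])
  rownames(m) <- df$member_id
  abundance_matrix(m, relative = relative)
}

#' Validate an abundance matrix
#'
#' @param m Numeric matrix, members as rows, samples as columns.
#' @param relative If `TRUE`, columns must each sum to 1 within `1e-9`.
#' @return `m` with a `relative` attribute.
#' @export
abundance_matrix <- function(m, relative = FALSE) {
  if (any(m < 0)) abort("abundance table contains negative entries")
  if (relative) {
    s <- colSums(m)
    if (any(abs(s - 1) > 1e-9)) {
      abort(sprintf("sample '%s' does not sum to 1 (got %.12f)",
                    colnames(m)[which(abs(s - 1) > 1e-9)[1]],
                    s[which(abs(s - 1) > 1e-9)[1]]))
    }
  }
  attr(m, "relative") <- relative
  m
}

#' Write an abundance table as TSV
#'
#' Values are written with 10 significant digits so that read/write
#' round-trips are value-identical at that precision.
#'
#' @param m Numeric matrix, members x samples.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_abundance_tsv <- function(m, path) {
  df <- data.frame(member_id = rownames(m),
                   apply(m, 2, function(x) formatC(x, digits = 10, format = "g")),
                   check.names = FALSE, stringsAsFactors = FALSE)
  colnames(df) <- c("member_id", colnames(m))
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Convert counts to relative abundances per sample
#'
#' @param m Numeric matrix, members x samples.
#' @return Matrix with each column scaled to sum to 1 (all-zero columns left
#'   at zero).
#' @export
as_relative <- function(m) {
  s <- colSums(m)
  s[s == 0] <- 1
  out <- sweep(m, 2, s, "/")
  abundance_matrix(out, relative = all(colSums(m) > 0))
}
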