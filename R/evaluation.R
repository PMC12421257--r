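# Evaluation layer: identity clustering of fingerprints, harmonization of an
# amplicon-derived composition against a metagenome-derived reference, the
# NRMSE deviation score, and presence/absence performance metrics.

# canonical serialization used for exact (threshold-1) clustering:
# haplotype sequences with their copies, in fingerprint order
fingerprint_key <- function(fp) {
  paste(paste0(fp$haplotypes$seq, "*", fp$haplotypes$copies), collapse = "|")
}

#' Cluster fingerprints by sequence identity
#'
#' At `threshold = 1` clusters are exact-equality groups of the serialized
#' fingerprint (haplotype sequences and copies). Below 1, greedy centroid
#' clustering: members are processed in order of decreasing length then
#' lexicographic id, joining the first centroid with global alignment
#' identity at least `threshold`, else founding a new cluster.
#'
#' @param fps List of fingerprints.
#' @param threshold Identity threshold in (0, 1] (default 1).
#' @return A tibble `member_id`, `cluster_id`, `centroid` (class
#'   `fq_clusters`).
#' @export
cluster_sequences <- function(fps, threshold = 1) {
  stopifnot(threshold > 0, threshold <= 1)
  members <- vapply(fps, function(f) f$member_id, character(1))
  if (threshold == 1) {
    keys <- vapply(fps, fingerprint_key, character(1))
    cid <- match(keys, unique(keys))
    centroid <- !duplicated(cid)
  } else {
    joined <- vapply(fps, function(f) paste(f$haplotypes$seq, collapse = ""),
                     character(1))
    ord <- order(-nchar(joined), members)
    cid <- integer(length(fps))
    centroid_seq <- character()
    centroid_of <- logical(length(fps))
    for (i in ord) {
      placed <- FALSE
      for (ci in seq_along(centroid_seq)) {
        pa <- Biostrings::pairwiseAlignment(joined[i], centroid_seq[ci],
                                            type = "global")
        ident <- Biostrings::nmatch(pa) / Biostrings::nchar(pa)
        if (ident >= threshold) { cid[i] <- ci; placed <- TRUE; break }
      }
      if (!placed) {
        centroid_seq <- c(centroid_seq, joined[i])
        cid[i] <- length(centroid_seq)
        centroid_of[i] <- TRUE
      }
    }
    centroid <- centroid_of
  }
  structure(tibble(member_id = members, cluster_id = cid,
                   centroid = centroid),
            class = c("fq_clusters", "tbl_df", "tbl", "data.frame"),
            threshold = threshold)
}

# sum member rows into cluster rows
collapse_clusters <- function(m, clusters) {
  missing <- setdiff(rownames(m), clusters$member_id)
  if (length(missing)) {
    abort(paste0("members without a cluster assignment: ",
                 paste(head(missing, 5), collapse = ", ")))
  }
  cid <- clusters$cluster_id[match(rownames(m), clusters$member_id)]
  out <- rowsum(m, group = cid)
  rownames(out) <- paste0("cluster_", rownames(out))
  out
}

#' Harmonize two compositions for comparison
#'
#' Member abundances are summed within clusters in both tables; taxa with
#' zero abundance in either table are removed from both (per sample by
#' default), and each sample is renormalized to sum to 1. With
#' `drop_absent = FALSE` absences are retained as zeros (the form required by
#' [presence_metrics()]).
#'
#' @param a Amplicon/fingerprint-derived abundance matrix (members x
#'   samples).
#' @param m Metagenome-derived reference matrix over the same samples.
#' @param clusters Optional `fq_clusters` table; when given, both tables are
#'   collapsed to clusters first.
#' @param drop_absent Drop taxa absent in either table?
#' @param drop_scope `"sample"` (default) drops per sample; `"global"` drops
#'   a taxon from all samples when its pooled abundance is zero in either
#'   table.
#' @param renormalize Rescale each sample to sum to 1 after dropping.
#' @return A list (class `fq_composition_pair`) with matrices `a`, `m`
#'   (dropped entries are `NA`) and the taxa/sample names.
#' @export
harmonize <- function(a, m, clusters = NULL, drop_absent = TRUE,
                      drop_scope = c("sample", "global"),
                      renormalize = TRUE) {
  drop_scope <- match.arg(drop_scope)
  if (!setequal(colnames(a), colnames(m))) {
    abort("the two tables must cover the same samples")
  }
  m <- m[, colnames(a), drop = FALSE]
  if (!is.null(clusters)) {
    a <- collapse_clusters(a, clusters)
    m <- collapse_clusters(m, clusters)
  }
  taxa <- union(rownames(a), rownames(m))
  pad <- function(x) {
    out <- matrix(0, length(taxa), ncol(x),
                  dimnames = list(taxa, colnames(x)))
    out[rownames(x), ] <- x
    out
  }
  a <- pad(a); m <- pad(m)
  if (drop_absent) {
    if (drop_scope == "sample") {
      drop <- a == 0 | m == 0
    } else {
      gone <- rowSums(a) == 0 | rowSums(m) == 0
      drop <- matrix(gone, nrow(a), ncol(a))
    }
    a[drop] <- NA; m[drop] <- NA
  }
  if (renormalize) {
    renorm <- function(x) {
      s <- colSums(x, na.rm = TRUE)
      s[s == 0] <- 1
      sweep(x, 2, s, "/")
    }
    a <- renorm(a); m <- renorm(m)
  }
  structure(list(a = a, m = m, taxa = taxa, samples = colnames(a)),
            class = "fq_composition_pair")
}

#' @export
print.fq_composition_pair <- function(x, ...) {
  cat(sprintf("<fq_composition_pair> %d taxa x %d samples (%d compared entries)\n",
              length(x$taxa), length(x$samples), sum(!is.na(x$a))))
  invisible(x)
}

#' Normalized root mean square error between two compositions
#'
#' Per sample, the mean over compared taxa of
#' `sqrt((a_i - m_i)^2) / ((a_i + m_i) / 2)`: the absolute deviation
#' normalized by the pairwise mean abundance. Each per-taxon term lies in
#' `[0, 2]`; the score is 0 iff the compositions agree exactly, and it is
#' symmetric in its arguments.
#'
#' @param pair An [harmonize()] result, or a numeric vector `a` (with `m`
#'   supplied).
#' @param m Optional reference vector when `pair` is a vector.
#' @return For a pair: a tibble `sample`, `K`, `nrmse`, with the across-sample
#'   mean in attribute `mean_nrmse`. For vectors: a single number.
#' @export
nrmse <- function(pair, m = NULL) {
  term <- function(a, m) abs(a - m) / ((a + m) / 2)
  if (is.numeric(pair)) {
    a <- pair
    stopifnot(length(a) == length(m))
    if (any(a + m == 0)) abort("taxa with zero total abundance must be dropped first")
    return(mean(term(a, m)))
  }
  stopifnot(inherits(pair, "fq_composition_pair"))
  out <- purrr::map_dfr(pair$samples, function(s) {
    a <- pair$a[, s]; mm <- pair$m[, s]
    keep <- !is.na(a) & !is.na(mm)
    a <- a[keep]; mm <- mm[keep]
    if (any(a + mm == 0)) {
      abort("internal error: zero-sum taxon reached nrmse; harmonize should have dropped it")
    }
    tibble(sample = s, K = length(a),
           nrmse = if (length(a)) mean(term(a, mm)) else NA_real_)
  })
  attr(out, "mean_nrmse") <- mean(out$nrmse, na.rm = TRUE)
  out
}

#' Presence/absence performance against a reference
#'
#' A taxon is present when its relative abundance reaches `threshold`
#' (default 0.005, i.e. 0.5%). With the metagenome-derived table as truth,
#' per-sample confusion tables give accuracy `(TP+TN)/N`, precision
#' `TP/(TP+FP)`, recall `TP/(TP+FN)` and specificity `TN/(TN+FP)`; ratios
#' with zero denominators are reported as `NA`, never as 0. The pair must
#' have been harmonized with `drop_absent = FALSE` so absences are retained
#' as zeros.
#'
#' @param pair An [harmonize()] result with zeros retained.
#' @param threshold Presence threshold on relative abundance.
#' @return Tibble `sample`, `TP`, `FP`, `FN`, `TN`, `accuracy`, `precision`,
#'   `recall`, `specificity`.
#' @export
presence_metrics <- function(pair, threshold = 0.005) {
  stopifnot(inherits(pair, "fq_composition_pair"))
  if (anyNA(pair$a)) {
    abort("presence_metrics needs a pair harmonized with drop_absent = FALSE")
  }
  rat <- function(num, den) ifelse(den > 0, num / den, NA_real_)
  purrr::map_dfr(pair$samples, function(s) {
    pa <- pair$a[, s] >= threshold
    pm <- pair$m[, s] >= threshold
    TP <- sum(pa & pm); FP <- sum(pa & !pm)
    FN <- sum(!pa & pm); TN <- sum(!pa & !pm)
    tibble(sample = s, TP = TP, FP = FP, FN = FN, TN = TN,
           accuracy = rat(TP + TN, TP + FP + FN + TN),
           precision = rat(TP, TP + FP),
           recall = rat(TP, TP + FN),
           specificity = rat(TN, TN + FP))
  })
}

#' Collapse an abundance table by a taxonomy map
#'
#' @param m Abundance matrix (members x samples).
#' @param map Named character vector: member id -> group label (e.g. genus).
#' @return Group-level abundance matrix.
#' @export
collapse_taxonomy <- function(m, map) {
  missing <- setdiff(rownames(m), names(map))
  if (length(missing)) {
    abort(paste0("members without a taxonomy mapping: ",
                 paste(missing, collapse = ", ")))
  }
  rowsum(m, group = unname(map[rownames(m)]))
}
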