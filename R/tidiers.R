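# broom-style tidiers and ggplot2 autoplot methods for the result objects.

#' Tidy a quantification result
#'
#' @param x An `fq_quant` object.
#' @param ... Unused.
#' @return The per-member result tibble.
#' @method tidy fq_quant
#' @export
tidy.fq_quant <- function(x, ...) x$table

#' One-row summary of a quantification result
#'
#' @param x An `fq_quant` object.
#' @param ... Unused.
#' @return Tibble: `n_members`, `n_detected`, `n_reads`, `n_assigned`,
#'   `mapping_rate`, `mean_confidence`.
#' @method glance fq_quant
#' @export
glance.fq_quant <- function(x, ...) {
  tibble(n_members = nrow(x$table),
         n_detected = sum(x$table$raw_count > 0),
         n_reads = x$n_reads, n_assigned = x$n_assigned,
         mapping_rate = x$mapping_rate,
         mean_confidence = mean(x$table$confidence, na.rm = TRUE))
}

#' Tidy a fingerprint-building result
#'
#' @param x An `fq_main` object.
#' @param ... Unused.
#' @return Tibble with one row per haplotype.
#' @method tidy fq_main
#' @export
tidy.fq_main <- function(x, ...) {
  tibble(member_id = x$fingerprint$member_id,
         haplotype = seq_len(nrow(x$fingerprint$haplotypes)),
         copies = x$fingerprint$haplotypes$copies,
         length = nchar(x$fingerprint$haplotypes$seq),
         seq = x$fingerprint$haplotypes$seq)
}

#' One-row summary of a fingerprint-building result
#'
#' @param x An `fq_main` object.
#' @param ... Unused.
#' @method glance fq_main
#' @export
glance.fq_main <- function(x, ...) {
  tibble(member_id = x$fingerprint$member_id,
         total_copies = x$total_copies,
         n_haplotypes = nrow(x$fingerprint$haplotypes),
         n_variants = nrow(x$variants),
         depth_ratio = x$depth_ratio,
         genome_depth = x$genome_depth,
         locus_depth = x$locus_mean_depth,
         n_qc_flags = length(x$qc_flags))
}

#' Tidy a fingerprint
#'
#' @param x An `fq_fingerprint`.
#' @param ... Unused.
#' @method tidy fq_fingerprint
#' @export
tidy.fq_fingerprint <- function(x, ...) {
  tibble(member_id = x$member_id, region = x$region,
         haplotype = seq_len(nrow(x$haplotypes)),
         copies = x$haplotypes$copies, seq = x$haplotypes$seq)
}

#' Abundance bar chart for a quantification result
#'
#' Raw read counts next to copy-number-normalized abundances, per member.
#'
#' @param object An `fq_quant` object.
#' @param ... Unused.
#' @return A ggplot.
#' @method autoplot fq_quant
#' @export
autoplot.fq_quant <- function(object, ...) {
  tb <- object$table
  tot <- sum(tb$raw_count)
  df <- dplyr::bind_rows(
    tibble(member_id = tb$member_id, value = if (tot > 0) tb$raw_count / tot else 0,
           what = "raw read share"),
    tibble(member_id = tb$member_id, value = tb$norm_abundance,
           what = "copy-normalized abundance"))
  ggplot2::ggplot(df, ggplot2::aes(x = .data$member_id, y = .data$value,
                                   fill = .data$what)) +
    ggplot2::geom_col(position = "dodge") +
    ggplot2::labs(x = NULL, y = "relative abundance", fill = NULL) +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 45, hjust = 1))
}

#' Scatter of the two compositions in a harmonized pair
#'
#' @param object An `fq_composition_pair`.
#' @param ... Unused.
#' @return A ggplot with one point per compared taxon x sample.
#' @method autoplot fq_composition_pair
#' @export
autoplot.fq_composition_pair <- function(object, ...) {
  df <- purrr::map_dfr(object$samples, function(s) {
    keep <- !is.na(object$a[, s])
    tibble(sample = s, taxon = object$taxa[keep],
           amplicon = object$a[keep, s], reference = object$m[keep, s])
  })
  ggplot2::ggplot(df, ggplot2::aes(x = .data$reference, y = .data$amplicon,
                                   colour = .data$sample)) +
    ggplot2::geom_abline(slope = 1, intercept = 0, linetype = 2,
                         colour = "grey60") +
    ggplot2::geom_point(alpha = 0.8) +
    ggplot2::labs(x = "reference abundance", y = "amplicon-derived abundance") +
    ggplot2::theme_minimal()
}
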