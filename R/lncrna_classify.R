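## Positional classification of surviving lncRNA candidates into
## antisense (opposite-strand gene overlap) and intergenic (no gene
## overlap) classes, plus cohort feature summaries.

#' Classify lncRNA candidates as antisense or intergenic
#'
#' A candidate is `antisense` iff its genomic span overlaps at least one
#' annotated gene span on the opposite strand (the most-overlapped gene is
#' recorded; ties broken by the lexicographically smaller gene id), and
#' `intergenic` otherwise. Candidates are expected to have already passed
#' the same-strand overlap filter; a same-strand overlap here is an error.
#'
#' @param candidates a `transcript_set` (or data.frame with `id`, `chrom`,
#'   `strand`, `start`, `end`).
#' @param annotation a `genome_annotation`.
#' @return the input with added columns `class` (`"antisense"` or
#'   `"intergenic"`) and `overlapped_gene_id` (NA for intergenic).
#' @export
classify_lncrnas <- function(candidates, annotation) {
  if (nrow(candidates) == 0L) {
    candidates$class <- character(0)
    candidates$overlapped_gene_id <- character(0)
    return(candidates)
  }
  if (any(overlaps_same_strand_all(candidates, annotation)))
    stop("candidate overlaps a gene on the same strand; ",
         "run apply_basic_filters() first")
  g <- annotation$genes
  cls <- rep("intergenic", nrow(candidates))
  ogene <- rep(NA_character_, nrow(candidates))
  for (i in seq_len(nrow(candidates))) {
    tr <- candidates[i, ]
    opp <- g$chrom == tr$chrom & g$strand != tr$strand &
      g$start <= tr$end & g$end >= tr$start
    if (any(opp)) {
      hit <- g[opp, , drop = FALSE]
      ov <- pmin(hit$end, tr$end) - pmax(hit$start, tr$start) + 1L
      best <- order(-ov, hit$gene_id)[1]
      cls[i] <- "antisense"
      ogene[i] <- hit$gene_id[best]
    }
  }
  candidates$class <- cls
  candidates$overlapped_gene_id <- ogene
  candidates
}

#' Summarize lncRNA cohort features by class
#'
#' Per class, reports the chromosome distribution, exon-count histogram,
#' transcript-length histogram (bins of `length_bin_width` nt starting at
#' 201), the median length, and the per-sample fraction of lncRNAs
#' expressed above an FPKM threshold.
#'
#' @param lncrnas classified lncRNA table from [classify_lncrnas()]; exon
#'   counts are taken from the `exons` list column when present, else 1.
#' @param fpkm FPKM matrix with lncRNA ids as row names.
#' @param length_bin_width width of the length bins in nt (default 200).
#' @param fpkm_threshold expression threshold (default 1).
#' @return named list (one element per class) of lists with components
#'   `n`, `chrom_proportions`, `exon_histogram`, `length_histogram`,
#'   `median_length`, `expressed_fraction`.
#' @export
summarize_features <- function(lncrnas, fpkm, length_bin_width = 200,
                               fpkm_threshold = 1) {
  if (nrow(lncrnas) == 0L) return(structure(list(), class = "lncrna_summary"))
  missing <- setdiff(lncrnas$id, rownames(fpkm))
  if (length(missing))
    stop("lncRNA ids missing from FPKM matrix: ",
         paste(missing, collapse = ", "))
  n_exons <- if ("exons" %in% names(lncrnas))
    vapply(lncrnas$exons, nrow, integer(1)) else rep(1L, nrow(lncrnas))
  out <- lapply(split(seq_len(nrow(lncrnas)), lncrnas$class), function(idx) {
    sub <- lncrnas[idx, , drop = FALSE]
    bin_idx <- pmax(0L, floor((sub$spliced_length - 201) /
                                length_bin_width)) + 1L
    bin_lab <- sprintf("%d-%d", (bin_idx - 1L) * length_bin_width + 201L -
                         ifelse(bin_idx == 1L, 1L, 0L),
                       bin_idx * length_bin_width + 200L)
    list(
      n = nrow(sub),
      chrom_proportions = proportions(table(sub$chrom)),
      exon_histogram = table(n_exons[idx]),
      length_histogram = table(factor(bin_lab, levels = unique(
        bin_lab[order(bin_idx)]))),
      median_length = median(sub$spliced_length),
      expressed_fraction = colMeans(
        fpkm[sub$id, , drop = FALSE] > fpkm_threshold))
  })
  structure(out, class = "lncrna_summary")
}

#' @export
print.lncrna_summary <- function(x, ...) {
  for (cls in names(x)) {
    cat(sprintf("%s: n=%d, median length %.0f nt\n",
                cls, x[[cls]]$n, x[[cls]]$median_length))
  }
  invisible(x)
}
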