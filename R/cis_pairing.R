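## Cis-regulation candidates: DE genes within an asymmetric genomic window
## of DE lncRNAs (10 kb on the lncRNA's 5' side, 100 kb on its 3' side),
## scored by expression correlation over all samples.

## signed geometry between one lncRNA and the genes on its chromosome:
## side is relative to the lncRNA's strand; distance is the nearest-
## boundary gap (gene start minus lncRNA end for a gene to the genomic
## right, etc.), 0 for overlapping spans (side then "downstream").
cis_geometry <- function(lnc, genes) {
  right <- genes$start > lnc$end
  left <- genes$end < lnc$start
  dist <- integer(nrow(genes))
  dist[right] <- genes$start[right] - lnc$end
  dist[left] <- lnc$start - genes$end[left]
  side <- rep("downstream", nrow(genes))  # overlap -> downstream, dist 0
  if (lnc$strand == "+") {
    side[left] <- "upstream"
  } else {
    side[right] <- "upstream"
  }
  data.frame(gene_id = genes$gene_id, side = side, distance = dist,
             stringsAsFactors = FALSE)
}

#' Find cis lncRNA-gene candidate pairs by genomic windows
#'
#' For each lncRNA, reports every gene on the same chromosome whose span's
#' nearest boundary lies within `window_up` on the lncRNA's 5' side or
#' `window_down` on its 3' side. Sides are defined by the lncRNA's strand
#' (for a minus-strand lncRNA, genomic left is downstream); boundaries are
#' inclusive, and overlapping spans get distance 0 on the downstream side.
#'
#' @param lncrnas data.frame with `id`, `chrom`, `strand`, `start`, `end`
#'   (e.g. DE lncRNAs from [classify_lncrnas()]).
#' @param genes data.frame with `gene_id`, `chrom`, `start`, `end`
#'   (e.g. the DE genes of a `genome_annotation`).
#' @param window_up 5'-side window in bp (default 10000).
#' @param window_down 3'-side window in bp (default 100000).
#' @return data.frame with columns `lncrna_id`, `gene_id`, `side`
#'   (`"upstream"`/`"downstream"`), `distance` (bp, >= 0).
#' @export
find_cis_candidates <- function(lncrnas, genes, window_up = 10000,
                                window_down = 100000) {
  out <- lapply(seq_len(nrow(lncrnas)), function(i) {
    lnc <- lncrnas[i, ]
    g <- genes[genes$chrom == lnc$chrom, , drop = FALSE]
    if (nrow(g) == 0L) return(NULL)
    geo <- cis_geometry(lnc, g)
    win <- ifelse(geo$side == "upstream", window_up, window_down)
    geo <- geo[geo$distance <= win, , drop = FALSE]
    if (nrow(geo) == 0L) return(NULL)
    cbind(lncrna_id = lnc$id, geo)
  })
  out <- do.call(rbind, out)
  if (is.null(out))
    out <- data.frame(lncrna_id = character(), gene_id = character(),
                      side = character(), distance = integer(),
                      stringsAsFactors = FALSE)
  rownames(out) <- NULL
  out
}

#' Score cis candidate pairs by expression correlation
#'
#' Adds the Pearson correlation of the two members' FPKM vectors over all
#' samples; a pair passes when `|r| >= r_min`. Constant expression vectors
#' leave `r` undefined (NA) and the pair failing, with a warning.
#'
#' @param candidates data.frame from [find_cis_candidates()].
#' @param fpkm FPKM matrix with both lncRNA and gene ids among row names.
#' @param r_min correlation threshold on `|r|` (default 0.8).
#' @return the candidates with columns `r` and `passes` added.
#' @export
score_cis_pairs <- function(candidates, fpkm, r_min = 0.8) {
  missing <- setdiff(unique(c(candidates$lncrna_id, candidates$gene_id)),
                     rownames(fpkm))
  if (length(missing))
    stop("features missing from FPKM matrix: ",
         paste(missing, collapse = ", "))
  r <- vapply(seq_len(nrow(candidates)), function(i) {
    x <- fpkm[candidates$lncrna_id[i], ]
    y <- fpkm[candidates$gene_id[i], ]
    if (sd(x) == 0 || sd(y) == 0) NA_real_ else cor(x, y)
  }, numeric(1))
  if (anyNA(r) && nrow(candidates) > 0)
    warning(sum(is.na(r)), " pair(s) with constant expression; ",
            "correlation undefined, pair fails")
  candidates$r <- r
  candidates$passes <- !is.na(r) & abs(r) >= r_min
  candidates
}
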