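## miRNA target prediction by ungapped complementarity scanning: the miRNA
## is aligned antiparallel to each target window, positions are classified
## as Watson-Crick match, G:U wobble, or mismatch, and a hit is accepted
## with at most `max_mismatch` mismatches (the "< 3 mismatches" rule) and
## at most `max_wobble` wobbles. T and U are interchangeable throughout.

canon_dna <- function(x) toupper(chartr("u", "t", tolower(x)))

WC_PARTNER <- c(A = "T", C = "G", G = "C", T = "A")

#' Count mismatches and G:U wobbles between a miRNA and a target window
#'
#' The miRNA (5'->3') is aligned antiparallel to the window (5'->3'):
#' miRNA position k pairs with window position `L - 1 - k`. A:U and G:C
#' are matches; G:U in either orientation is a wobble; everything else is
#' a mismatch.
#'
#' @param mirna_seq miRNA sequence, 5'->3' (RNA or DNA alphabet).
#' @param target_window target subsequence of the same length, 5'->3'.
#' @return list with `n_mismatch` and `n_wobble`.
#' @export
pair_positions <- function(mirna_seq, target_window) {
  m <- canon_dna(mirna_seq)
  w <- canon_dna(target_window)
  if (nchar(m) != nchar(w))
    stop("miRNA and target window must have equal length")
  mc <- strsplit(m, "", fixed = TRUE)[[1]]
  wc <- rev(strsplit(w, "", fixed = TRUE)[[1]])
  match_ <- wc == WC_PARTNER[mc]
  wobble <- (mc == "G" & wc == "T") | (mc == "T" & wc == "G")
  match_[is.na(match_)] <- FALSE
  list(n_mismatch = sum(!match_ & !wobble), n_wobble = sum(wobble))
}

#' Scan a target sequence for miRNA complementarity hits
#'
#' Evaluates every offset of the target; a hit is accepted when it has at
#' most `max_mismatch` mismatches and at most `max_wobble` G:U wobbles.
#' All hits (accepted or not, subject to `report_all`) are returned sorted
#' by (n_mismatch, n_wobble, offset); overlapping hits are all reported.
#'
#' @param mirna_id miRNA identifier.
#' @param mirna_seq miRNA sequence, 5'->3'.
#' @param target_id target identifier.
#' @param target_seq target sequence, 5'->3'.
#' @param max_mismatch maximal mismatches to accept (default 2,
#'   implementing "fewer than 3").
#' @param max_wobble maximal G:U wobbles to accept (default 4).
#' @param target_kind `"lncRNA"` or `"mRNA"` (annotation only).
#' @param report_all when FALSE (default) only accepted hits are returned.
#' @return data.frame with columns `mirna_id`, `mirna_family`, `target_id`,
#'   `target_kind`, `offset` (0-based on the target), `n_mismatch`,
#'   `n_wobble`, `accepted`.
#' @export
scan_target <- function(mirna_id, mirna_seq, target_id, target_seq,
                        max_mismatch = 2, max_wobble = 4,
                        target_kind = "lncRNA", report_all = FALSE) {
  m <- canon_dna(mirna_seq)
  t <- canon_dna(target_seq)
  lm <- nchar(m)
  lt <- nchar(t)
  empty <- data.frame(mirna_id = character(), mirna_family = character(),
                      target_id = character(), target_kind = character(),
                      offset = integer(), n_mismatch = integer(),
                      n_wobble = integer(), accepted = logical(),
                      stringsAsFactors = FALSE)
  if (lt < lm) return(empty)
  mc <- strsplit(m, "", fixed = TRUE)[[1]]
  tc <- strsplit(t, "", fixed = TRUE)[[1]]
  offsets <- 0:(lt - lm)
  ## window position pairing miRNA position k is offset + L - k (1-based)
  res <- vapply(offsets, function(off) {
    wc <- tc[(off + lm):(off + 1L)]
    match_ <- wc == WC_PARTNER[mc]
    match_[is.na(match_)] <- FALSE
    wob <- (mc == "G" & wc == "T") | (mc == "T" & wc == "G")
    c(sum(!match_ & !wob), sum(wob))
  }, numeric(2))
  hits <- data.frame(
    mirna_id = mirna_id, mirna_family = mirna_family(mirna_id),
    target_id = target_id, target_kind = target_kind,
    offset = offsets, n_mismatch = as.integer(res[1, ]),
    n_wobble = as.integer(res[2, ]), stringsAsFactors = FALSE)
  hits$accepted <- hits$n_mismatch <= max_mismatch &
    hits$n_wobble <= max_wobble
  if (!report_all) hits <- hits[hits$accepted, , drop = FALSE]
  hits <- hits[order(hits$n_mismatch, hits$n_wobble, hits$offset), ,
               drop = FALSE]
  rownames(hits) <- NULL
  hits
}

#' Scan many miRNAs against many targets
#'
#' @param mirnas named character vector of miRNA sequences.
#' @param targets named character vector of target sequences.
#' @param target_kind `"lncRNA"` or `"mRNA"`, recycled over targets.
#' @inheritParams scan_target
#' @return row-bound hit table (see [scan_target()]).
#' @export
scan_target_set <- function(mirnas, targets, max_mismatch = 2,
                            max_wobble = 4, target_kind = "lncRNA") {
  target_kind <- rep_len(target_kind, length(targets))
  out <- list()
  for (i in seq_along(mirnas)) {
    for (j in seq_along(targets)) {
      h <- scan_target(names(mirnas)[i], mirnas[[i]], names(targets)[j],
                       targets[[j]], max_mismatch, max_wobble,
                       target_kind[j])
      if (nrow(h)) out[[length(out) + 1L]] <- h
    }
  }
  if (!length(out))
    return(scan_target("m", "AAAAAA", "t", "A")[0, ])
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

#' Collapse a miRNA identifier to its family
#'
#' The family is the identifier prefix up to (and including) the first
#' digit run after "miR": `miR156a-5p -> miR156`. Identifiers without a
#' recognizable miR prefix are returned unchanged, which makes the
#' collapse idempotent.
#'
#' @param ids character vector of miRNA identifiers.
#' @return character vector of family names.
#' @export
mirna_family <- function(ids) {
  fam <- sub("^(.*?[mM][iI][rR][-]?[0-9]+).*$", "\\1", ids)
  ifelse(grepl("[mM][iI][rR][-]?[0-9]+", ids), fam, ids)
}

#' Degree histograms of accepted miRNA target hits
#'
#' @param hits hit table from [scan_target()]/[scan_target_set()].
#' @return list with three tables over accepted lncRNA hits:
#'   `lncrnas_per_mirna` (distinct lncRNA targets per miRNA),
#'   `mirnas_per_lncrna` (distinct miRNAs per lncRNA),
#'   `families_per_lncrna` (distinct miRNA families per lncRNA).
#' @export
degree_tables <- function(hits) {
  h <- hits[hits$accepted & hits$target_kind == "lncRNA", , drop = FALSE]
  uniq <- unique(h[, c("mirna_id", "mirna_family", "target_id")])
  list(
    lncrnas_per_mirna = table(tapply(uniq$target_id, uniq$mirna_id,
                                     function(x) length(unique(x)))),
    mirnas_per_lncrna = table(tapply(uniq$mirna_id, uniq$target_id,
                                     function(x) length(unique(x)))),
    families_per_lncrna = table(tapply(uniq$mirna_family, uniq$target_id,
                                       function(x) length(unique(x)))))
}

#' Build the lncRNA-miRNA-mRNA target network
#'
#' Union of the accepted edges of the lncRNA and mRNA hit tables, with
#' node kinds and degrees, in deterministic (sorted) node order.
#'
#' @param lncrna_hits hit table against lncRNA targets.
#' @param mrna_hits optional hit table against mRNA targets.
#' @return A `target_network`: list with `nodes` (data.frame: id, kind,
#'   degree) and `edges` (data.frame: source, relation, target). Export
#'   with [write_network()] on `$edges`.
#' @export
build_network <- function(lncrna_hits, mrna_hits = NULL) {
  h <- rbind(lncrna_hits, mrna_hits)
  h <- h[h$accepted, , drop = FALSE]
  edges <- unique(data.frame(source = h$mirna_id,
                             relation = rep("targets", nrow(h)),
                             target = h$target_id,
                             kind = h$target_kind,
                             stringsAsFactors = FALSE))
  edges <- edges[order(edges$source, edges$target), , drop = FALSE]
  node_ids <- sort(unique(c(edges$source, edges$target)))
  kind <- setNames(rep("miRNA", length(node_ids)), node_ids)
  kind[edges$target] <- edges$kind
  deg <- table(factor(c(edges$source, edges$target), levels = node_ids))
  nodes <- data.frame(id = node_ids, kind = unname(kind[node_ids]),
                      degree = as.integer(deg), stringsAsFactors = FALSE,
                      row.names = NULL)
  edges$kind <- NULL
  rownames(edges) <- NULL
  structure(list(nodes = nodes, edges = edges), class = "target_network")
}

#' @export
print.target_network <- function(x, ...) {
  cat(sprintf("target_network: %d nodes (%s), %d edges\n",
              nrow(x$nodes),
              paste(sprintf("%d %s", table(x$nodes$kind),
                            names(table(x$nodes$kind))), collapse = ", "),
              nrow(x$edges)))
  invisible(x)
}
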