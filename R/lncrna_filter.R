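## Basic filtering cascade reducing assembled transcripts to lncRNA
## candidates: recurrence across samples, same-strand overlap with coding
## genes, transcript length, read coverage, and longest-ORF length.

FILTER_ORDER <- c("recurrence", "same_strand_overlap", "length",
                  "coverage", "orf_length")

STOP_CODONS <- c("TAA", "TAG", "TGA")

#' Find the longest open reading frame on the sense strand
#'
#' Scans all three reading frames of the spliced sense sequence for
#' ATG-to-stop ORFs. The reported length is in nucleotides and includes the
#' stop codon; an ATG without a downstream in-frame stop is not counted as
#' an ORF. Ties across frames are broken by the smallest start offset.
#'
#' @param sequence nucleotide string over A/C/G/T/N (case-insensitive; U is
#'   accepted and treated as T).
#' @return A list (`orf_call`) with `found` (logical), `start` (0-based
#'   offset of the ATG), `end` (half-open end offset), `length`
#'   (nucleotides, 0 when not found) and `frame` (0-2, NA when not found).
#' @export
find_longest_orf <- function(sequence) {
  s <- toupper(chartr("u", "t", tolower(sequence)))
  if (!grepl("^[ACGTN]*$", s))
    stop("sequence contains non-IUPAC characters (allowed: A, C, G, T, N)")
  n <- nchar(s)
  best <- list(found = FALSE, start = NA_integer_, end = NA_integer_,
               length = 0L, frame = NA_integer_)
  if (n < 6L) return(structure(best, class = "orf_call"))
  ch <- strsplit(s, "", fixed = TRUE)[[1]]
  ## codon string starting at each position (last two positions invalid)
  cod <- paste0(ch[1:(n - 2)], ch[2:(n - 1)], ch[3:n])
  is_atg <- cod == "ATG"
  is_stop <- cod %in% STOP_CODONS
  for (f in 0:2) {
    pos <- seq.int(f + 1L, n - 2L, by = 3L)  # 1-based codon start positions
    cur <- NA_integer_
    for (p in pos) {
      if (is.na(cur)) {
        if (is_atg[p]) cur <- p
      } else if (is_stop[p]) {
        len <- p + 3L - cur
        if (len > best$length ||
            (len == best$length && (cur - 1L) < best$start)) {
          best <- list(found = TRUE, start = cur - 1L, end = cur - 1L + len,
                       length = len, frame = f)
        }
        cur <- NA_integer_
      }
    }
  }
  structure(best, class = "orf_call")
}

#' Does a transcript overlap a gene on the same strand?
#'
#' Span-level test: TRUE iff the transcript's genomic span shares at least
#' one base with at least one annotated gene span of identical strand.
#'
#' @param transcript list or one-row data.frame with `chrom`, `strand`,
#'   `start`, `end` (1-based inclusive).
#' @param annotation a `genome_annotation`.
#' @return logical flag.
#' @export
overlaps_same_strand <- function(transcript, annotation) {
  if (!transcript$chrom %in% annotation$chromosomes$name)
    stop("unknown chromosome: ", transcript$chrom)
  g <- annotation$genes
  any(g$chrom == transcript$chrom & g$strand == transcript$strand &
        g$start <= transcript$end & g$end >= transcript$start)
}

## vectorized same-strand overlap over a transcript_set via GenomicRanges
overlaps_same_strand_all <- function(transcripts, annotation) {
  unknown <- setdiff(unique(transcripts$chrom), annotation$chromosomes$name)
  if (length(unknown))
    stop("unknown chromosome(s): ", paste(unknown, collapse = ", "))
  g <- annotation$genes
  if (nrow(g) == 0L) return(rep(FALSE, nrow(transcripts)))
  tr_gr <- GenomicRanges::GRanges(transcripts$chrom,
    IRanges::IRanges(transcripts$start, transcripts$end),
    strand = transcripts$strand)
  g_gr <- GenomicRanges::GRanges(g$chrom, IRanges::IRanges(g$start, g$end),
                                 strand = g$strand)
  IRanges::overlapsAny(tr_gr, g_gr, ignore.strand = FALSE)
}

#' Apply the basic lncRNA filtering cascade
#'
#' A transcript is retained iff it was detected in at least `min_samples`
#' samples, does not overlap any coding gene on the same strand, is at
#' least `min_len` nt long, has read coverage of at least `min_cov`, and
#' its longest ORF is at most `max_orf` nt. Boundary values (length 200,
#' coverage 3, ORF 300 at the defaults) are retained; the discard rules are
#' strictly "< 200", "< 3" and "> 300". All filters are evaluated for every
#' transcript, so the retained set is independent of filter order;
#' `failed_filters` reports violations in the canonical cascade order
#' (recurrence, same_strand_overlap, length, coverage, orf_length).
#'
#' @param transcripts a `transcript_set` (see [read_transcripts()]).
#' @param annotation a `genome_annotation`.
#' @param min_len minimum spliced length in nt (default 200).
#' @param min_cov minimum assembler read coverage (default 3).
#' @param max_orf maximum longest-ORF length in nt (default 300).
#' @param min_samples minimum number of samples detected in (default 2).
#' @return data.frame with columns `id`, `retained`, `failed_filters`
#'   (comma-joined, "" when retained), `orf_start`, `orf_length`.
#' @export
apply_basic_filters <- function(transcripts, annotation, min_len = 200,
                                min_cov = 3, max_orf = 300,
                                min_samples = 2) {
  stopifnot(min_len > 0, min_cov > 0, max_orf > 0, min_samples > 0)
  if (anyDuplicated(transcripts$id))
    stop("duplicate transcript ids: ",
         paste(unique(transcripts$id[duplicated(transcripts$id)]),
               collapse = ", "))
  ov <- overlaps_same_strand_all(transcripts, annotation)
  orfs <- lapply(transcripts$sequence, find_longest_orf)
  orf_len <- vapply(orfs, `[[`, integer(1), "length")
  orf_start <- vapply(orfs, `[[`, integer(1), "start")

  fails <- cbind(
    recurrence = transcripts$samples_detected < min_samples,
    same_strand_overlap = ov,
    length = transcripts$spliced_length < min_len,
    coverage = transcripts$coverage < min_cov,
    orf_length = orf_len > max_orf)
  failed <- apply(fails, 1, function(row)
    paste(FILTER_ORDER[row[FILTER_ORDER]], collapse = ","))
  data.frame(id = transcripts$id,
             retained = !apply(fails, 1, any),
             failed_filters = failed,
             orf_start = orf_start,
             orf_length = orf_len,
             stringsAsFactors = FALSE)
}
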