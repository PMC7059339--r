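## I/O for every external format the pipeline touches, plus the coordinate
## conventions shared by all modules. Internally everything is 1-based and
## closed (the GFF/GRanges convention); BED is the single place where
## 0-based half-open coordinates appear, converted at the boundary.

#' Convert 1-based closed genomic coordinates to BED (0-based half-open)
#'
#' @param start,end integer vectors of 1-based inclusive coordinates.
#' @return A list with elements `start` and `end` in BED convention.
#' @export
genomic_to_bed <- function(start, end) {
  stopifnot(all(start >= 1L), all(end >= start))
  list(start = as.integer(start) - 1L, end = as.integer(end))
}

#' Convert BED (0-based half-open) coordinates back to 1-based closed
#'
#' @param start,end integer vectors in BED convention.
#' @return A list with elements `start` and `end`, 1-based inclusive.
#' @export
bed_to_genomic <- function(start, end) {
  stopifnot(all(start >= 0L), all(end > start))
  list(start = as.integer(start) + 1L, end = as.integer(end))
}

new_genome_annotation <- function(chromosomes, genes) {
  structure(list(chromosomes = chromosomes, genes = genes),
            class = "genome_annotation")
}

#' @export
print.genome_annotation <- function(x, ...) {
  cat(sprintf("genome_annotation: %d chromosome(s), %d gene(s)\n",
              nrow(x$chromosomes), nrow(x$genes)))
  invisible(x)
}

empty_genes_df <- function() {
  data.frame(gene_id = character(), chrom = character(),
             strand = character(), start = integer(), end = integer(),
             category = character(), stringsAsFactors = FALSE)
}

validate_annotation <- function(ann) {
  g <- ann$genes
  if (anyDuplicated(g$gene_id))
    stop("duplicate gene ids: ",
         paste(unique(g$gene_id[duplicated(g$gene_id)]), collapse = ", "))
  if (nrow(g) > 0) {
    if (!all(g$strand %in% c("+", "-")))
      stop("gene strand must be '+' or '-'")
    if (any(g$start < 1L) || any(g$end < g$start))
      stop("gene coordinates must satisfy 1 <= start <= end")
    len <- setNames(ann$chromosomes$length, ann$chromosomes$name)
    bad <- g$end > len[g$chrom]
    if (any(bad, na.rm = TRUE))
      stop("gene(s) extend beyond chromosome end: ",
           paste(g$gene_id[which(bad)], collapse = ", "))
  }
  ann
}

## Light structural pre-scan so malformed feature lines are reported with
## their line number before the real parser runs.
prescan_gff <- function(path) {
  lines <- readLines(path, warn = FALSE)
  feat <- which(!grepl("^\\s*(#|$)", lines))
  for (i in feat) {
    f <- strsplit(lines[i], "\t", fixed = TRUE)[[1]]
    if (length(f) < 8)
      stop(sprintf("%s line %d: expected >= 8 tab-separated fields", path, i))
    s <- suppressWarnings(as.integer(f[4]))
    e <- suppressWarnings(as.integer(f[5]))
    if (is.na(s) || is.na(e))
      stop(sprintf("%s line %d: non-numeric start/end", path, i))
    if (e < s)
      stop(sprintf("%s line %d: end (%d) < start (%d)", path, i, e, s))
  }
  length(feat)
}

guess_gff_format <- function(path) {
  if (grepl("\\.gtf$", path, ignore.case = TRUE)) "gtf" else "gff3"
}

#' Read a genome annotation from GFF3 or GTF
#'
#' Gene records are taken from `gene` features when present; otherwise gene
#' spans are derived as the union (including introns) of all features
#' sharing a `gene_id` attribute. The functional category is read from a
#' configurable attribute key, defaulting to `"mapman_bin"`; genes without
#' it are labelled `"unassigned"`.
#'
#' @param path GFF3 (`.gff`/`.gff3`) or GTF (`.gtf`) file.
#' @param category_attr attribute key holding the functional category.
#' @return A `genome_annotation`: a list with `chromosomes`
#'   (data.frame: name, length) and `genes` (data.frame: gene_id, chrom,
#'   strand, start, end, category), coordinates 1-based inclusive.
#' @export
read_annotation <- function(path, category_attr = "mapman_bin") {
  if (!file.exists(path)) stop("file not found: ", path)
  n_feat <- prescan_gff(path)
  if (n_feat == 0L) {
    return(new_genome_annotation(
      data.frame(name = character(), length = integer(),
                 stringsAsFactors = FALSE),
      empty_genes_df()))
  }
  gr <- rtracklayer::import(path, format = guess_gff_format(path))
  mc <- S4Vectors::mcols(gr)
  types <- as.character(mc$type)

  if (any(types == "gene")) {
    gg <- gr[types == "gene"]
    gmc <- S4Vectors::mcols(gg)
    ids <- if (!is.null(gmc$ID)) as.character(gmc$ID)
           else as.character(gmc$gene_id)
    cat_col <- if (category_attr %in% colnames(gmc))
      as.character(gmc[[category_attr]]) else rep(NA_character_, length(gg))
    genes <- data.frame(
      gene_id = ids,
      chrom = as.character(GenomicRanges::seqnames(gg)),
      strand = as.character(GenomicRanges::strand(gg)),
      start = GenomicRanges::start(gg),
      end = GenomicRanges::end(gg),
      category = ifelse(is.na(cat_col), "unassigned", cat_col),
      stringsAsFactors = FALSE)
  } else {
    if (is.null(mc$gene_id))
      stop("no 'gene' features and no gene_id attribute in ", path)
    keep <- !is.na(mc$gene_id)
    gg <- gr[keep]
    gid <- as.character(S4Vectors::mcols(gg)$gene_id)
    first <- !duplicated(gid)
    cat_col <- if (category_attr %in% colnames(mc))
      as.character(S4Vectors::mcols(gg)[[category_attr]])
    else rep(NA_character_, length(gg))
    genes <- data.frame(
      gene_id = gid[first],
      chrom = as.character(GenomicRanges::seqnames(gg))[first],
      strand = as.character(GenomicRanges::strand(gg))[first],
      start = as.integer(tapply(GenomicRanges::start(gg), gid, min)[gid[first]]),
      end = as.integer(tapply(GenomicRanges::end(gg), gid, max)[gid[first]]),
      category = ifelse(is.na(cat_col[first]), "unassigned", cat_col[first]),
      stringsAsFactors = FALSE)
  }
  rownames(genes) <- NULL
  if (nrow(genes) > 0 && !all(genes$strand %in% c("+", "-")))
    stop("gene strand must be '+' or '-' (got '",
         paste(setdiff(genes$strand, c("+", "-")), collapse = "','"), "')")

  sl <- GenomeInfoDb_seqlengths(gr)
  sl <- sl[!is.na(sl)]
  ## sequence-region directives take precedence over observed extents
  dir_lines <- grep("^##sequence-region", readLines(path, warn = FALSE),
                    value = TRUE)
  if (length(dir_lines)) {
    f <- strsplit(trimws(dir_lines), "\\s+")
    sl <- c(sl, setNames(
      vapply(f, function(x) as.integer(x[4]), integer(1)),
      vapply(f, function(x) x[2], character(1))))
    sl <- sl[!duplicated(names(sl))]
  }
  chroms <- unique(c(names(sl), genes$chrom))
  lens <- vapply(chroms, function(ch) {
    if (ch %in% names(sl) && !is.na(sl[[ch]])) as.integer(sl[[ch]])
    else max(genes$end[genes$chrom == ch], 0L)
  }, integer(1))
  ann <- new_genome_annotation(
    data.frame(name = chroms, length = lens, row.names = NULL,
               stringsAsFactors = FALSE),
    genes)
  validate_annotation(ann)
}

GenomeInfoDb_seqlengths <- function(gr) {
  sl <- GenomeInfoDb::seqlengths(gr)
  if (is.null(sl)) setNames(integer(0), character(0)) else sl
}

#' Write a genome annotation to GFF3
#'
#' Inverse of [read_annotation()]: one `gene` feature per record with the
#' category stored under `category_attr`.
#'
#' @param annotation a `genome_annotation`.
#' @param path output GFF3 path.
#' @param category_attr attribute key for the functional category.
#' @return `path`, invisibly.
#' @export
write_annotation <- function(annotation, path, category_attr = "mapman_bin") {
  g <- annotation$genes
  gr <- GenomicRanges::GRanges(
    seqnames = g$chrom,
    ranges = IRanges::IRanges(start = g$start, end = g$end),
    strand = g$strand)
  S4Vectors::mcols(gr)$type <- rep("gene", nrow(g))
  S4Vectors::mcols(gr)$ID <- g$gene_id
  S4Vectors::mcols(gr)[[category_attr]] <- g$category
  GenomeInfoDb::seqlevels(gr) <- annotation$chromosomes$name
  GenomeInfoDb::seqlengths(gr) <- as.integer(annotation$chromosomes$length)
  rtracklayer::export(gr, path, format = "gff3")
  ## rtracklayer does not emit sequence-region directives; add them so
  ## chromosome lengths survive the round trip
  lines <- readLines(path, warn = FALSE)
  region <- sprintf("##sequence-region %s 1 %d",
                    annotation$chromosomes$name,
                    as.integer(annotation$chromosomes$length))
  writeLines(c(lines[1], region, lines[-1]), path)
  invisible(path)
}

new_transcript_set <- function(df) {
  structure(df, class = c("transcript_set", "data.frame"))
}

#' Read assembled transcript models (GTF + FASTA + sidecar TSV)
#'
#' The GTF supplies exon structure, the FASTA the spliced sequences, and
#' the sidecar TSV the assembler attributes (`id`, `coverage`,
#' `samples_detected`) that standard GTF cannot carry.
#'
#' @param gtf_path GTF with `exon` features carrying `transcript_id`.
#' @param fasta_path FASTA of spliced transcript sequences (5'->3').
#' @param sidecar_path TSV with columns `id`, `coverage`, `samples_detected`.
#' @return A `transcript_set` data.frame with columns `id`, `chrom`,
#'   `strand`, `start`, `end`, `spliced_length`, `coverage`,
#'   `samples_detected`, `sequence` and a list column `exons` of two-column
#'   (start, end) matrices sorted along the genome.
#' @export
read_transcripts <- function(gtf_path, fasta_path, sidecar_path) {
  gr <- rtracklayer::import(gtf_path, format = "gtf")
  gr <- gr[as.character(S4Vectors::mcols(gr)$type) == "exon"]
  tid <- as.character(S4Vectors::mcols(gr)$transcript_id)
  ids <- unique(tid)

  seqs <- Biostrings::readDNAStringSet(fasta_path)
  names(seqs) <- sub("\\s.*$", "", names(seqs))
  side <- read.delim(sidecar_path, stringsAsFactors = FALSE)
  req <- c("id", "coverage", "samples_detected")
  if (!all(req %in% colnames(side)))
    stop("sidecar must have columns: ", paste(req, collapse = ", "))

  missing_fa <- setdiff(ids, names(seqs))
  missing_sc <- setdiff(ids, side$id)
  if (length(missing_fa) || length(missing_sc))
    stop("transcript ids missing from ",
         if (length(missing_fa)) paste0("FASTA: ",
           paste(missing_fa, collapse = ", ")) else "",
         if (length(missing_fa) && length(missing_sc)) "; " else "",
         if (length(missing_sc)) paste0("sidecar: ",
           paste(missing_sc, collapse = ", ")) else "")

  rows <- lapply(ids, function(id) {
    e <- gr[tid == id]
    o <- order(GenomicRanges::start(e))
    ex <- cbind(start = GenomicRanges::start(e)[o],
                end = GenomicRanges::end(e)[o])
    if (nrow(ex) > 1 && any(ex[-1, "start"] <= ex[-nrow(ex), "end"]))
      stop("overlapping exons in transcript ", id)
    sl <- sum(ex[, "end"] - ex[, "start"] + 1L)
    sq <- as.character(seqs[[id]])
    if (nchar(sq) != sl)
      stop(sprintf("transcript %s: sequence length %d != summed exon length %d",
                   id, nchar(sq), sl))
    sc <- side[match(id, side$id), ]
    list(id = id,
         chrom = as.character(GenomicRanges::seqnames(e))[1],
         strand = as.character(GenomicRanges::strand(e))[1],
         start = min(ex[, "start"]), end = max(ex[, "end"]),
         spliced_length = sl, coverage = as.numeric(sc$coverage),
         samples_detected = as.integer(sc$samples_detected),
         sequence = sq, exons = ex)
  })
  df <- data.frame(
    id = vapply(rows, `[[`, character(1), "id"),
    chrom = vapply(rows, `[[`, character(1), "chrom"),
    strand = vapply(rows, `[[`, character(1), "strand"),
    start = vapply(rows, `[[`, numeric(1), "start"),
    end = vapply(rows, `[[`, numeric(1), "end"),
    spliced_length = vapply(rows, `[[`, numeric(1), "spliced_length"),
    coverage = vapply(rows, `[[`, numeric(1), "coverage"),
    samples_detected = vapply(rows, `[[`, integer(1), "samples_detected"),
    sequence = vapply(rows, `[[`, character(1), "sequence"),
    stringsAsFactors = FALSE)
  df$exons <- lapply(rows, `[[`, "exons")
  new_transcript_set(df)
}

#' Write transcript models as GTF + FASTA + sidecar TSV
#'
#' Inverse of [read_transcripts()]; a round trip reproduces the input
#' models exactly.
#'
#' @param transcripts a `transcript_set`.
#' @param gtf_path,fasta_path,sidecar_path output paths.
#' @return `gtf_path`, invisibly.
#' @export
write_transcripts <- function(transcripts, gtf_path, fasta_path, sidecar_path) {
  ex_list <- transcripts$exons
  n_ex <- vapply(ex_list, nrow, integer(1))
  gr <- GenomicRanges::GRanges(
    seqnames = rep(transcripts$chrom, n_ex),
    ranges = IRanges::IRanges(
      start = unlist(lapply(ex_list, function(m) m[, "start"])),
      end = unlist(lapply(ex_list, function(m) m[, "end"]))),
    strand = rep(transcripts$strand, n_ex))
  S4Vectors::mcols(gr)$type <- "exon"
  S4Vectors::mcols(gr)$gene_id <- rep(transcripts$id, n_ex)
  S4Vectors::mcols(gr)$transcript_id <- rep(transcripts$id, n_ex)
  rtracklayer::export(gr, gtf_path, format = "gtf")
  Biostrings::writeXStringSet(
    Biostrings::DNAStringSet(setNames(transcripts$sequence, transcripts$id)),
    fasta_path)
  write.table(
    data.frame(id = transcripts$id, coverage = transcripts$coverage,
               samples_detected = transcripts$samples_detected),
    sidecar_path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(gtf_path)
}

#' Write features as BED6
#'
#' Converts from the internal 1-based closed convention to BED 0-based
#' half-open at this single boundary.
#'
#' @param x data.frame with columns `chrom`, `start`, `end`, `id`, `strand`
#'   (1-based inclusive coordinates), e.g. a `transcript_set` or classified
#'   lncRNA table.
#' @param path output BED path.
#' @return `path`, invisibly.
#' @export
write_bed <- function(x, path) {
  b <- genomic_to_bed(x$start, x$end)
  df <- data.frame(x$chrom, b$start, b$end, x$id, 0L, x$strand)
  write.table(df, path, sep = "\t", quote = FALSE,
              row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Read a BED6 file back into 1-based closed coordinates
#'
#' @param path BED6 file.
#' @return data.frame with columns `chrom`, `start`, `end`, `id`, `score`,
#'   `strand`, coordinates 1-based inclusive.
#' @export
read_bed <- function(path) {
  df <- read.delim(path, header = FALSE, stringsAsFactors = FALSE)
  g <- bed_to_genomic(df[[2]], df[[3]])
  data.frame(chrom = df[[1]], start = g$start, end = g$end,
             id = df[[4]], score = df[[5]], strand = df[[6]],
             stringsAsFactors = FALSE)
}

#' Write a network edge list as SIF
#'
#' @param edges data.frame with columns `source`, `relation`, `target`.
#' @param path output SIF path.
#' @return `path`, invisibly.
#' @export
write_network <- function(edges, path) {
  write.table(edges[, c("source", "relation", "target")], path,
              sep = "\t", quote = FALSE, row.names = FALSE,
              col.names = FALSE)
  invisible(path)
}

#' Read a SIF edge list
#'
#' @param path SIF file with rows `source<TAB>relation<TAB>target`.
#' @return data.frame with columns `source`, `relation`, `target`.
#' @export
read_network <- function(path) {
  df <- read.delim(path, header = FALSE, stringsAsFactors = FALSE)
  setNames(df[, 1:3], c("source", "relation", "target"))
}

#' Read a count matrix from TSV
#'
#' @param path TSV with a header row of sample ids and feature ids in the
#'   first column.
#' @return numeric matrix (features x samples) of non-negative integers.
#' @export
read_counts <- function(path) {
  df <- read.delim(path, row.names = 1, check.names = FALSE)
  m <- as.matrix(df)
  if (!is.numeric(m)) stop("counts must be numeric")
  if (any(m < 0)) stop("counts must be non-negative")
  if (any(m != round(m))) stop("counts must be integers")
  m
}

#' Write a count matrix to TSV
#'
#' @param counts numeric matrix with feature row names and sample column
#'   names.
#' @param path output TSV path.
#' @return `path`, invisibly.
#' @export
write_counts <- function(counts, path) {
  df <- data.frame(feature_id = rownames(counts), counts,
                   check.names = FALSE)
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
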