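## Planted transcript models on the synthetic genome: one mRNA per coding
## gene, antisense lncRNAs inside host genes on the opposite strand,
## intergenic lncRNAs (including deliberately placed cis partners of DE
## genes), and junk transcripts that each violate exactly one basic
## filter. Constructed sequences are spliced back into the genome so the
## emitted FASTA stays consistent with the transcript models.

extract_spliced <- function(chrom_seq, exons, strand) {
  pieces <- substring(chrom_seq, exons[, "start"], exons[, "end"])
  s <- paste(pieces, collapse = "")
  if (strand == "-") revcomp(s) else s
}

splice_into_genome <- function(chrom_seq, exons, strand, spliced) {
  genomic <- if (strand == "-") revcomp(spliced) else spliced
  widths <- exons[, "end"] - exons[, "start"] + 1L
  stopifnot(sum(widths) == nchar(genomic))
  off <- cumsum(c(0L, widths[-length(widths)]))
  for (i in seq_len(nrow(exons))) {
    substr(chrom_seq, exons[i, "start"], exons[i, "end"]) <-
      substr(genomic, off[i] + 1L, off[i] + widths[i])
  }
  chrom_seq
}

## split a spliced length into n exons (each >= 30 nt) plus introns,
## returning an exon matrix anchored at `start`
make_exons <- function(start, spliced_len, n_exons) {
  if (n_exons == 1L)
    return(cbind(start = start, end = start + spliced_len - 1L))
  min_ex <- 30L
  if (spliced_len < n_exons * min_ex) n_exons <- max(1L, spliced_len %/% min_ex)
  if (n_exons == 1L)
    return(cbind(start = start, end = start + spliced_len - 1L))
  cuts <- sort(sample(seq(min_ex, spliced_len - min_ex), n_exons - 1L))
  widths <- diff(c(0L, cuts, spliced_len))
  if (any(widths < min_ex)) {  # rare collision of cut points
    widths <- rep(spliced_len %/% n_exons, n_exons)
    widths[n_exons] <- spliced_len - sum(widths[-n_exons])
  }
  introns <- sample(40:120, n_exons - 1L, replace = TRUE)
  s <- integer(n_exons)
  e <- integer(n_exons)
  pos <- start
  for (i in seq_len(n_exons)) {
    s[i] <- pos
    e[i] <- pos + widths[i] - 1L
    pos <- e[i] + if (i < n_exons) introns[i] + 1L else 1L
  }
  cbind(start = s, end = e)
}

genomic_span <- function(exons) c(exons[1, "start"], exons[nrow(exons), "end"])

overlaps_any_interval <- function(start, end, intervals) {
  if (nrow(intervals) == 0L) return(FALSE)
  any(intervals$start <= end & intervals$end >= start)
}

lnc_length <- function(config) {
  max(210L, min(2000L, round(rlnorm(1, config$lncrna_meanlog,
                                    config$lncrna_sdlog))))
}

#' Generate planted transcripts and the ground-truth manifest
#'
#' Plants, per the configuration: one mRNA per coding gene (same strand,
#' full CDS); antisense lncRNAs strictly inside a host gene's span on the
#' opposite strand; intergenic lncRNAs overlapping no gene on either
#' strand, a subset of which is deliberately placed at a recorded distance
#' and side of a DE gene (the planted cis pairs, sharing that gene's
#' temporal archetype); and junk transcripts each violating exactly one
#' basic filter (length 150-199, coverage < 3, detected in 1 sample,
#' longest ORF > 300 nt, or same-strand gene overlap). All lncRNA
#' sequences are constructed or checked to carry no ORF longer than
#' 300 nt. Differential-expression status and archetypes for both genes
#' and lncRNAs are decided here and recorded in the ground truth.
#'
#' @param config a [simulation_config()].
#' @param genome a `synthetic_genome` from [generate_genome()].
#' @return list with `transcripts` (a `transcript_set`), `truth` (the
#'   ground-truth manifest) and `genome` (with constructed sequences
#'   spliced in and DE-gene categories biased towards their archetype's
#'   signature category).
#' @export
generate_transcripts <- function(config, genome) {
  stopifnot(inherits(config, "simulation_config"),
            inherits(genome, "synthetic_genome"))
  set.seed(stage_seed(config$seed, "transcripts"))
  ann <- genome$annotation
  seqs <- genome$sequences
  genes <- ann$genes
  L <- config$chromosome_length

  ## --- DE plan: which genes/lncRNAs are DE and with which archetype ---
  n_lnc <- config$n_antisense + config$n_intergenic
  n_de_gene <- min(nrow(genes),
                   round(config$de_fraction_coding * nrow(genes)))
  de_genes <- sort(sample(genes$gene_id, n_de_gene))
  arch_names <- rownames(config$archetype_multipliers)
  gene_arch <- setNames(sample(arch_names, n_de_gene, replace = TRUE),
                        de_genes)
  ## bias DE-gene categories towards the archetype signature category
  for (g in de_genes) {
    if (runif(1) < 0.8) {
      genes$category[genes$gene_id == g] <-
        ARCHETYPE_CATEGORY[[gene_arch[[g]]]]
    }
  }
  ann$genes <- genes

  occupied <- data.frame(start = genes$start, end = genes$end,
                         chrom = genes$chrom, stringsAsFactors = FALSE)
  claim <- function(chrom, start, end) {
    occupied[nrow(occupied) + 1L, ] <<- list(start, end, chrom)
  }
  is_free <- function(chrom, start, end) {
    if (start < 1L || end > L) return(FALSE)
    !overlaps_any_interval(start, end,
                           occupied[occupied$chrom == chrom, , drop = FALSE])
  }

  ## empirical enforcement model: coding = the CDS pool, noncoding =
  ## composition-random strings plus reverse-complemented CDSs (the same
  ## mixture a downstream scorer trains on); planted lncRNA ORFs are
  ## required to score noncoding under it
  gen_hex <- if (length(genome$cds)) {
    comp_train <- vapply(1:150, function(i) random_background(600),
                         character(1))
    train_hexamer_model(genome$cds,
                        orf_or_self(c(comp_train, revcomp(genome$cds))))
  } else generator_hexamer_model()
  rows <- list()
  add_row <- function(id, chrom, strand, exons, sequence, coverage,
                      samples_detected) {
    rows[[length(rows) + 1L]] <<- list(
      id = id, chrom = chrom, strand = strand, exons = exons,
      sequence = sequence, coverage = coverage,
      samples_detected = as.integer(samples_detected))
  }
  normal_cov <- function() 3 + rgamma(1, shape = 2, scale = 15)
  normal_samples <- function() sample(3:12, 1)

  ## --- mRNAs: one per gene, spanning the CDS on the same strand ---
  mrna_of_gene <- setNames(character(nrow(genes)), genes$gene_id)
  tcons_i <- 0L
  next_id <- function() {
    tcons_i <<- tcons_i + 1L
    sprintf("TCONS_%08d", tcons_i)
  }
  for (k in seq_len(nrow(genes))) {
    g <- genes[k, ]
    id <- next_id()
    mrna_of_gene[g$gene_id] <- id
    add_row(id, g$chrom, g$strand,
            cbind(start = g$start, end = g$end),
            genome$cds[[g$gene_id]], normal_cov(), normal_samples())
  }
  coding_ids <- vapply(rows, `[[`, character(1), "id")

  ## --- antisense lncRNAs: inside a host gene, opposite strand ---
  antisense_ids <- character(0)
  host_genes <- sample(genes$gene_id, config$n_antisense)
  for (g_id in host_genes) {
    g <- genes[genes$gene_id == g_id, ]
    strand <- if (g$strand == "+") "-" else "+"
    best <- NULL
    for (try in 1:60) {
      len <- min(lnc_length(config), g$end - g$start - 19L)
      if (try > 30) len <- min(len, 290L)  # short ORFs guaranteed
      start <- g$start + sample.int(g$end - g$start - len + 1L, 1) - 1L
      exons <- cbind(start = start, end = start + len - 1L)
      sq <- extract_spliced(seqs[[g$chrom]], exons, strand)
      if (find_longest_orf(sq)$length > 300L) next
      bias <- true_orf_bias(sq, gen_hex)
      if (is.null(best) || bias < best$bias)
        best <- list(exons = exons, sq = sq, bias = bias)
      if (bias <= NONCODING_BIAS_MARGIN) break
    }
    if (is.null(best)) stop("could not place antisense lncRNA in gene ", g_id)
    id <- next_id()
    antisense_ids <- c(antisense_ids, id)
    add_row(id, g$chrom, strand, best$exons, best$sq, normal_cov(),
            normal_samples())
  }

  ## --- intergenic lncRNAs; the first n_cis_pairs are planted near a DE
  ## gene at a recorded side and distance ---
  intergenic_ids <- character(0)
  cis_pairs <- list()
  lnc_arch <- character(0)

  place_intergenic <- function(target_gene = NULL) {
    for (try in 1:300) {
      len <- lnc_length(config)
      n_ex <- sample.int(5L, 1, prob = config$exon_count_probs)
      strand <- sample(c("+", "-"), 1)
      if (is.null(target_gene)) {
        chrom <- sample(ann$chromosomes$name, 1)
        start <- sample.int(L - 3L * len, 1)
        side <- NA_character_
        dist <- NA_integer_
      } else {
        g <- genes[genes$gene_id == target_gene, ]
        chrom <- g$chrom
        side <- sample(c("upstream", "downstream"), 1)
        win <- if (side == "upstream") config$window_up else
          config$window_down
        dist <- sample.int(min(win, L %/% 3), 1)
        ## invert the side geometry: where must the lncRNA sit so that
        ## the gene lies on that side of it?
        gene_left <- (strand == "+") == (side == "upstream")
        start <- if (gene_left) g$end + dist else NA
      }
      exons <- make_exons(if (!is.na(start)) start else 1L, len, n_ex)
      span <- genomic_span(exons)
      if (!is.null(target_gene) && !gene_left) {
        ## gene to the genomic right: lncRNA end must be at gs - dist
        g <- genes[genes$gene_id == target_gene, ]
        shift <- (g$start - dist) - span[2]
        exons[, "start"] <- exons[, "start"] + shift
        exons[, "end"] <- exons[, "end"] + shift
        span <- genomic_span(exons)
      }
      if (!is_free(chrom, span[1], span[2])) next
      sq <- random_noncoding(sum(exons[, "end"] - exons[, "start"] + 1L),
                             hex_model = gen_hex)
      id <- next_id()
      claim(chrom, span[1], span[2])
      seqs[[chrom]] <<- splice_into_genome(seqs[[chrom]], exons, strand, sq)
      add_row(id, chrom, strand, exons, sq, normal_cov(), normal_samples())
      return(list(id = id, side = side, distance = dist))
    }
    stop("could not place intergenic lncRNA; genome too dense")
  }

  n_cis <- min(config$n_cis_pairs, config$n_intergenic, length(de_genes))
  cis_gene_pool <- sample(de_genes, n_cis)
  for (g_id in cis_gene_pool) {
    p <- place_intergenic(target_gene = g_id)
    intergenic_ids <- c(intergenic_ids, p$id)
    cis_pairs[[length(cis_pairs) + 1L]] <- data.frame(
      lncrna_id = p$id, gene_id = g_id, side = p$side,
      distance = p$distance, stringsAsFactors = FALSE)
    lnc_arch[p$id] <- gene_arch[[g_id]]  # co-expressed with its partner
  }
  for (i in seq_len(config$n_intergenic - n_cis)) {
    p <- place_intergenic()
    intergenic_ids <- c(intergenic_ids, p$id)
  }

  ## --- remaining DE lncRNAs beyond the cis-planted ones ---
  lnc_ids <- c(antisense_ids, intergenic_ids)
  n_de_lnc <- round(config$de_fraction_lncrna * n_lnc)
  extra <- setdiff(lnc_ids, names(lnc_arch))
  n_extra <- max(0L, n_de_lnc - length(lnc_arch))
  if (n_extra > 0) {
    picked <- sample(extra, min(n_extra, length(extra)))
    lnc_arch[picked] <- sample(arch_names, length(picked), replace = TRUE)
  }

  ## --- junk transcripts: one named violation each ---
  junk <- list()
  junk_reasons <- rep_len(c("length", "coverage", "recurrence",
                            "orf_length", "same_strand_overlap"),
                          config$n_junk)
  for (reason in junk_reasons) {
    if (reason == "same_strand_overlap") {
      g <- genes[sample.int(nrow(genes), 1), ]
      len <- sample(220:290, 1)  # too short to host an ORF > 300 nt
      start <- g$start + sample.int(g$end - g$start - len + 1L, 1) - 1L
      exons <- cbind(start = start, end = start + len - 1L)
      sq <- extract_spliced(seqs[[g$chrom]], exons, g$strand)
      id <- next_id()
      add_row(id, g$chrom, g$strand, exons, sq, normal_cov(),
              normal_samples())
    } else {
      len <- switch(reason,
                    length = sample(150:199, 1),
                    orf_length = sample(420:600, 1),
                    sample(210:800, 1))
      repeat {
        chrom <- sample(ann$chromosomes$name, 1)
        start <- sample.int(L - len - 10L, 1)
        if (is_free(chrom, start, start + len - 1L)) break
      }
      exons <- cbind(start = start, end = start + len - 1L)
      strand <- sample(c("+", "-"), 1)
      sq <- if (reason == "orf_length") {
        ## a complete >300 nt ORF at the 5' end, noncoding tail after it
        n_cod <- sample(100:min(150L, (len - 6L) %/% 3L), 1)
        paste0(random_cds(n_cod),
               random_noncoding(len - 3L * n_cod - 6L, hex_model = gen_hex))
      } else random_noncoding(len, hex_model = gen_hex)
      id <- next_id()
      claim(chrom, start, start + len - 1L)
      seqs[[chrom]] <- splice_into_genome(seqs[[chrom]], exons, strand, sq)
      add_row(id, chrom, strand, exons, sq,
              if (reason == "coverage") runif(1, 0.3, 2.9) else normal_cov(),
              if (reason == "recurrence") 1L else normal_samples())
    }
    junk[[length(junk) + 1L]] <- data.frame(
      id = rows[[length(rows)]]$id, reason = reason,
      stringsAsFactors = FALSE)
  }

  ## --- assemble the transcript_set ---
  df <- data.frame(
    id = vapply(rows, `[[`, character(1), "id"),
    chrom = vapply(rows, `[[`, character(1), "chrom"),
    strand = vapply(rows, `[[`, character(1), "strand"),
    start = vapply(rows, function(r) genomic_span(r$exons)[1], numeric(1)),
    end = vapply(rows, function(r) genomic_span(r$exons)[2], numeric(1)),
    spliced_length = vapply(rows, function(r) nchar(r$sequence), numeric(1)),
    coverage = vapply(rows, `[[`, numeric(1), "coverage"),
    samples_detected = vapply(rows, `[[`, integer(1), "samples_detected"),
    sequence = vapply(rows, `[[`, character(1), "sequence"),
    stringsAsFactors = FALSE)
  df$exons <- lapply(rows, `[[`, "exons")
  transcripts <- new_transcript_set(df)

  genome$sequences <- seqs
  genome$annotation <- ann

  truth <- list(
    feature_ids = df$id,
    coding_ids = coding_ids,
    mrna_of_gene = mrna_of_gene,
    lncrnas = data.frame(
      id = lnc_ids,
      class = c(rep("antisense", length(antisense_ids)),
                rep("intergenic", length(intergenic_ids))),
      stringsAsFactors = FALSE),
    junk = do.call(rbind, junk),
    de = data.frame(
      feature_id = c(unname(mrna_of_gene[de_genes]), names(lnc_arch)),
      gene_id = c(de_genes, rep(NA_character_, length(lnc_arch))),
      kind = c(rep("coding", length(de_genes)),
               rep("lncrna", length(lnc_arch))),
      archetype = c(unname(gene_arch), unname(lnc_arch)),
      stringsAsFactors = FALSE),
    cis_pairs = if (length(cis_pairs)) do.call(rbind, cis_pairs) else
      data.frame(lncrna_id = character(), gene_id = character(),
                 side = character(), distance = integer(),
                 stringsAsFactors = FALSE),
    archetype_category = ARCHETYPE_CATEGORY)
  list(transcripts = transcripts, truth = truth, genome = genome)
}
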