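## Synthetic genome and annotation: coding genes with realistic codon
## usage implanted into random intergenic background, each gene carrying a
## functional category. All randomness is drawn from one stream keyed by
## (seed, stage name) so later stages never perturb earlier ones.

stage_seed <- function(seed, stage) {
  h <- sum(utf8ToInt(stage) * seq_len(nchar(stage)))
  as.integer((as.numeric(seed) * 48271 + h) %% 2147483629)
}

revcomp <- function(x) {
  vapply(x, function(s) {
    paste(rev(strsplit(chartr("ACGTacgt", "TGCAtgca", s), "",
                       fixed = TRUE)[[1]]), collapse = "")
  }, character(1), USE.NAMES = FALSE)
}

## Approximate dicot codon usage (relative weights per sense codon),
## strong enough to give coding sequences a realistic in-frame hexamer
## and codon-position signature.
CODON_USAGE <- c(
  TTT = 21.8, TTC = 20.7, TTA = 12.5, TTG = 20.9,
  CTT = 24.1, CTC = 16.1, CTA = 9.9,  CTG = 9.8,
  ATT = 21.5, ATC = 18.5, ATA = 12.6, ATG = 24.5,
  GTT = 27.2, GTC = 12.8, GTA = 9.9,  GTG = 17.4,
  TCT = 25.2, TCC = 11.2, TCA = 18.3, TCG = 9.3,
  CCT = 18.7, CCC = 5.3,  CCA = 16.1, CCG = 8.6,
  ACT = 17.5, ACC = 10.3, ACA = 15.7, ACG = 7.7,
  GCT = 28.3, GCC = 10.1, GCA = 17.5, GCG = 9.0,
  TAT = 14.6, TAC = 13.7, CAT = 13.8, CAC = 8.7,
  CAA = 19.4, CAG = 15.2, AAT = 22.3, AAC = 20.9,
  AAA = 30.8, AAG = 32.7, GAT = 36.6, GAC = 17.2,
  GAA = 34.3, GAG = 32.2, TGT = 10.5, TGC = 7.2,
  TGG = 12.5,
  CGT = 9.0,  CGC = 3.8,  CGA = 6.3,  CGG = 4.9,
  AGT = 13.9, AGC = 11.3, AGA = 19.0, AGG = 11.0,
  GGT = 22.2, GGC = 9.2,  GGA = 24.2, GGG = 10.2)

## Intergenic/noncoding base composition: AT-rich relative to coding
## sequence, as in real plant genomes (intergenic GC well below CDS GC).
## Constructed lncRNA sequence uses the same composition, so noncoding
## sequence follows the genome's noncoding hexamer model while CDSs carry
## the codon-usage signature.
BASE_FREQS <- c(A = 0.33, C = 0.17, G = 0.17, T = 0.33)

FUNCTIONAL_CATEGORIES <- c(
  "amino acid metabolism", "cell wall", "cell cycle",
  "hormone metabolism", "photosynthesis", "RNA transcription",
  "secondary metabolism", "transport", "abiotic stress",
  "protein folding")

## category each archetype's DE genes are enriched for
ARCHETYPE_CATEGORY <- c(
  M1 = "amino acid metabolism", M2 = "hormone metabolism",
  M3 = "abiotic stress", M4 = "RNA transcription",
  M5 = "photosynthesis", M6 = "cell cycle")

#' Simulation configuration for the synthetic salt-stress dataset
#'
#' Bundles and validates every knob of the generator. The defaults define
#' a desk-scale study: four chromosomes, 120 coding genes, 90 planted
#' lncRNAs (30 antisense, 60 intergenic), 15 junk transcripts (three per
#' basic filter), a 4 x 3 sample design over H0/H6/H12/H24, NB dispersion
#' 0.05, the canonical M1-M6 archetype multipliers, and the asymmetric
#' 10 kb / 100 kb cis windows.
#'
#' @param seed integer seed fixing all randomness end-to-end.
#' @param n_chromosomes,chromosome_length genome shape.
#' @param n_coding,n_antisense,n_intergenic,n_junk feature counts.
#' @param dispersion NB dispersion alpha shared across features.
#' @param archetype_multipliers 6 x 4 positive matrix over H0/H6/H12/H24.
#' @param size_factor_sd sd of log library-size factors across samples.
#' @param window_up,window_down cis windows in bp (5'/3' of the lncRNA).
#' @param mirna_length,n_mirnas miRNA pool shape.
#' @param sites_per_mirna,decoys_per_mirna planted true sites (at most 2
#'   mismatches) and decoy sites (at least 3) per miRNA.
#' @param n_cis_pairs planted cis lncRNA-gene pairs.
#' @param de_fraction_lncrna,de_fraction_coding fractions of features
#'   planted as differentially expressed.
#' @param exon_count_probs probabilities of 1-5 exons per lncRNA.
#' @param lncrna_meanlog,lncrna_sdlog log-normal lncRNA length law
#'   (median ~430 nt at the defaults).
#' @param baseline_meanlog,baseline_sdlog log-normal law of baseline
#'   normalized means.
#' @return validated `simulation_config` list.
#' @export
simulation_config <- function(seed = 1,
                              n_chromosomes = 4,
                              chromosome_length = 250000,
                              n_coding = 120,
                              n_antisense = 30,
                              n_intergenic = 60,
                              n_junk = 15,
                              dispersion = 0.05,
                              archetype_multipliers = salt_archetypes(),
                              size_factor_sd = 0.15,
                              window_up = 10000,
                              window_down = 100000,
                              mirna_length = 21,
                              n_mirnas = 15,
                              sites_per_mirna = 2,
                              decoys_per_mirna = 1,
                              n_cis_pairs = 8,
                              de_fraction_lncrna = 0.35,
                              de_fraction_coding = 0.5,
                              exon_count_probs = c(0.84, 0.10, 0.03,
                                                   0.01, 0.02),
                              lncrna_meanlog = log(430),
                              lncrna_sdlog = 0.45,
                              baseline_meanlog = log(150),
                              baseline_sdlog = 1) {
  cfg <- as.list(environment())
  stopifnot(cfg$n_chromosomes >= 1, cfg$chromosome_length > 0,
            cfg$n_coding >= 0, cfg$n_antisense >= 0,
            cfg$n_intergenic >= 0, cfg$n_junk >= 0,
            cfg$dispersion > 0,
            all(cfg$archetype_multipliers > 0),
            nrow(cfg$archetype_multipliers) == 6,
            ncol(cfg$archetype_multipliers) == 4,
            cfg$window_up > 0, cfg$window_down > 0,
            cfg$mirna_length >= 15,
            abs(sum(cfg$exon_count_probs) - 1) < 1e-8)
  if (cfg$n_antisense > cfg$n_coding)
    stop("n_antisense cannot exceed n_coding (one host gene each)")
  structure(cfg, class = "simulation_config")
}

random_background <- function(n) {
  paste(sample(names(BASE_FREQS), n, replace = TRUE, prob = BASE_FREQS),
        collapse = "")
}

## The generator's own (true-distribution) hexamer model: in-frame coding
## hexamers are codon pairs under the codon-usage law; noncoding hexamers
## are stop-free codon pairs under the base composition. A uniform mixing
## mass emulates the pseudocount shrinkage of estimated tables. Used to
## enforce, at construction time, that planted lncRNA ORFs follow the
## noncoding hexamer profile.
generator_hexamer_model <- function(mix = 0.15) {
  hx <- all_hexamers()
  sense <- names(CODON_USAGE)[!names(CODON_USAGE) %in% STOP_CODONS]
  pc <- CODON_USAGE[sense] / sum(CODON_USAGE[sense])
  comp <- vapply(sense, function(cod)
    prod(BASE_FREQS[strsplit(cod, "", fixed = TRUE)[[1]]]), numeric(1))
  pn <- comp / sum(comp)
  c1 <- substr(hx, 1, 3)
  c2 <- substr(hx, 4, 6)
  f_c <- ifelse(c1 %in% sense & c2 %in% sense,
                pc[c1] * pc[c2], 0)
  f_n <- ifelse(c1 %in% sense & c2 %in% sense,
                pn[c1] * pn[c2], 0)
  f_c <- (1 - mix) * f_c / sum(f_c) + mix / length(hx)
  f_n <- (1 - mix) * f_n / sum(f_n) + mix / length(hx)
  structure(list(coding = setNames(f_c, hx), noncoding = setNames(f_n, hx),
                 pseudocount = NA_real_),
            class = "hexamer_model")
}

## bias of the longest ORF under the generator's true model; sequences
## without an ORF score noncoding by convention
true_orf_bias <- function(sequence, model) {
  orf <- find_longest_orf(sequence)
  if (!orf$found) return(-Inf)
  hexamer_bias(substr(sequence, orf$start + 1L, orf$end), model)
}

random_cds <- function(n_codons) {
  sense <- names(CODON_USAGE)[!names(CODON_USAGE) %in% STOP_CODONS]
  w <- CODON_USAGE[sense]
  body <- sample(sense, n_codons, replace = TRUE, prob = w / sum(w))
  paste0("ATG", paste(body, collapse = ""),
         sample(STOP_CODONS, 1))
}

## Constructed lncRNA ORFs must score below this hexamer-bias margin
## under the generator's own tables: a clear noncoding profile that stays
## negative when the tables are re-estimated on finite training data.
NONCODING_BIAS_MARGIN <- -0.25

## random sequence constructed to score noncoding: no ORF longer than
## max_orf, and the longest ORF's hexamer profile follows the noncoding
## model (bias below the noncoding margin under the generator's tables).
## Offending ORFs are disrupted by writing an in-frame stop into them.
random_noncoding <- function(len, max_orf = 300,
                             hex_model = generator_hexamer_model()) {
  s <- random_background(len)
  repeat {
    orf <- find_longest_orf(s)
    if (!orf$found) return(s)
    ok_len <- orf$length <= max_orf
    ok_hex <- is.null(hex_model) ||
      hexamer_bias(substr(s, orf$start + 1L, orf$end), hex_model) <=
        NONCODING_BIAS_MARGIN
    if (ok_len && ok_hex) return(s)
    if (orf$length < 12L) {  # too short to disrupt internally: erase ATG
      substr(s, orf$start + 1L, orf$start + 3L) <- "TAA"
    } else {
      pos <- orf$start + 3 * sample(seq_len(orf$length %/% 3 - 2), 1) + 1
      substr(s, pos, pos + 2) <- "TAA"
    }
  }
}

#' Generate a synthetic genome with annotated coding genes
#'
#' Chromosomes are uniform-random background into which coding genes are
#' implanted without overlap: each gene is a CDS (ATG, codons drawn from a
#' dicot-like codon-usage table, one stop) on a random strand, so the
#' in-frame hexamer bias of real coding sequence is present. Each gene is
#' assigned one functional category.
#'
#' @param config a [simulation_config()].
#' @return A `synthetic_genome`: list with `sequences` (named character,
#'   one per chromosome), `annotation` (a `genome_annotation`) and `cds`
#'   (named character of coding sequences, 5'->3').
#' @export
generate_genome <- function(config) {
  stopifnot(inherits(config, "simulation_config"))
  set.seed(stage_seed(config$seed, "genome"))
  L <- config$chromosome_length
  n_chr <- config$n_chromosomes
  chrom_names <- sprintf("chr%02d", seq_len(n_chr))
  per_chr <- diff(floor(seq(0, config$n_coding, length.out = n_chr + 1)))

  min_gap <- 500L
  seqs <- character(n_chr)
  genes <- list()
  cds_all <- character(0)
  gi <- 0L
  for (ci in seq_len(n_chr)) {
    n_g <- per_chr[ci]
    chrom <- random_background(L)
    if (n_g > 0) {
      n_codons <- sample(100:300, n_g, replace = TRUE)
      lens <- 3L * n_codons + 6L
      free <- L - sum(lens) - (n_g + 1L) * min_gap
      if (free < 0)
        stop("genes cannot be placed without overlap; ",
             "increase chromosome_length or reduce n_coding")
      extra <- runif(n_g + 1L)
      extra <- floor(extra / sum(extra) * free)
      starts <- min_gap + cumsum(c(0L, lens[-n_g] + min_gap)) +
        cumsum(extra[-(n_g + 1L)]) + 1L
      for (k in seq_len(n_g)) {
        gi <- gi + 1L
        cds <- random_cds(n_codons[k])
        strand <- sample(c("+", "-"), 1)
        gseq <- if (strand == "+") cds else revcomp(cds)
        substr(chrom, starts[k], starts[k] + lens[k] - 1L) <- gseq
        id <- sprintf("Spsyn%02dG%04d", ci, k * 10L)
        genes[[gi]] <- data.frame(
          gene_id = id, chrom = chrom_names[ci], strand = strand,
          start = as.integer(starts[k]),
          end = as.integer(starts[k] + lens[k] - 1L),
          category = sample(FUNCTIONAL_CATEGORIES, 1),
          stringsAsFactors = FALSE)
        cds_all[id] <- cds
      }
    }
    seqs[ci] <- chrom
  }
  names(seqs) <- chrom_names
  ann <- new_genome_annotation(
    data.frame(name = chrom_names, length = rep(as.integer(L), n_chr),
               stringsAsFactors = FALSE),
    if (length(genes)) do.call(rbind, genes) else empty_genes_df())
  validate_annotation(ann)
  structure(list(sequences = seqs, annotation = ann, cds = cds_all),
            class = "synthetic_genome")
}
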