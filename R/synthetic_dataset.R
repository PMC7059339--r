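## Count simulation, miRNA planting, end-to-end dataset assembly and the
## independent ground-truth verification pass.

#' Simulate the NB count matrix over the salt time course
#'
#' Counts are drawn as `k_ij ~ NB(mean = s_j * q_i * m[a(i), c(j)],
#' dispersion alpha)`: `s_j` a per-sample library-size factor (log-normal,
#' geometric mean 1), `q_i` a log-normal per-feature baseline, and `m` the
#' archetype multiplier of feature i's archetype at sample j's condition
#' (1 for non-DE features at every condition). Twelve samples: H0/H6/H12/
#' H24 with three replicates each. True log2 fold changes per pairwise
#' comparison are recorded in the returned truth.
#'
#' @param config a [simulation_config()].
#' @param truth ground-truth manifest from [generate_transcripts()].
#' @return list with `counts` (features x 12 integer matrix),
#'   `conditions`, `size_factors`, and the updated `truth` (gains
#'   `log2fc`, a comparisons x features matrix, and `baselines`).
#' @export
generate_counts <- function(config, truth) {
  stopifnot(inherits(config, "simulation_config"))
  if (config$dispersion <= 0) stop("dispersion must be > 0")
  set.seed(stage_seed(config$seed, "counts"))
  ids <- truth$feature_ids
  n <- length(ids)
  conditions <- rep(CONDITIONS, each = 3)
  samples <- paste0(conditions, "_R", rep(1:3, times = 4))

  s <- exp(rnorm(12, 0, config$size_factor_sd))
  s <- s / exp(mean(log(s)))
  q <- pmax(5, rlnorm(n, config$baseline_meanlog, config$baseline_sdlog))

  mult <- matrix(1, nrow = n, ncol = 4,
                 dimnames = list(ids, CONDITIONS))
  arch <- setNames(truth$de$archetype, truth$de$feature_id)
  de_ids <- intersect(ids, names(arch))
  mult[de_ids, ] <- config$archetype_multipliers[arch[de_ids], ,
                                                 drop = FALSE]

  mu <- (q * mult[, conditions]) * rep(s, each = n)
  counts <- matrix(as.integer(rnbinom(n * 12, mu = mu,
                                      size = 1 / config$dispersion)),
                   nrow = n, dimnames = list(ids, samples))

  cmps <- c("H0_H6", "H0_H12", "H0_H24", "H6_H12", "H6_H24", "H12_H24")
  lfc <- vapply(cmps, function(cmp) {
    g <- parse_comparison(cmp)
    log2(mult[, g[2]] / mult[, g[1]])
  }, numeric(n))
  truth$log2fc <- t(lfc)
  truth$baselines <- setNames(q, ids)
  list(counts = counts, conditions = conditions, size_factors = s,
       truth = truth)
}

WOBBLE_PARTNER <- c(G = "T", T = "G")

## build a target window pairing with `mirna` with exactly n_mismatch
## mismatches and n_wobble G:U wobbles; NULL if the miRNA lacks enough
## G/T positions for the requested wobbles
build_site_window <- function(mirna, n_mismatch, n_wobble) {
  mc <- strsplit(canon_dna(mirna), "", fixed = TRUE)[[1]]
  L <- length(mc)
  wc <- rev(unname(WC_PARTNER[mc]))  # perfect antiparallel complement
  gu_ok <- which(mc %in% c("G", "T"))
  if (length(gu_ok) < n_wobble) return(NULL)
  wob_pos <- if (n_wobble > 0) sample(gu_ok, n_wobble) else integer(0)
  mm_pool <- setdiff(seq_len(L), wob_pos)
  mm_pos <- if (n_mismatch > 0) sample(mm_pool, n_mismatch) else integer(0)
  for (k in wob_pos) wc[L - k + 1L] <- WOBBLE_PARTNER[[mc[k]]]
  for (k in mm_pos) {
    banned <- c(WC_PARTNER[[mc[k]]],
                if (mc[k] %in% names(WOBBLE_PARTNER))
                  WOBBLE_PARTNER[[mc[k]]])
    wc[L - k + 1L] <- sample(setdiff(c("A", "C", "G", "T"), banned), 1)
  }
  paste(wc, collapse = "")
}

#' Generate miRNAs and plant complementary sites with known pairing counts
#'
#' Draws random mature miRNA sequences grouped into families
#' (`miR<number><letter>` naming), then implants target windows into
#' intergenic lncRNA (and some mRNA) transcript sequences. Each planted
#' site pairs with its miRNA with exactly the recorded number of
#' mismatches and G:U wobbles; true sites have at most 2 mismatches,
#' decoy sites at least 3. Sites on lncRNAs are only accepted where the
#' implant leaves no ORF longer than 300 nt. Modified sequences are
#' spliced back into the genome when it is supplied.
#'
#' @param config a [simulation_config()].
#' @param truth ground-truth manifest (gains `mirna_sites`).
#' @param transcripts the `transcript_set` (sequences are modified).
#' @param genome optional `synthetic_genome` to keep in sync.
#' @return list with `mirnas` (named character), `transcripts`, `truth`,
#'   `genome`.
#' @export
generate_mirnas <- function(config, truth, transcripts, genome = NULL) {
  stopifnot(inherits(config, "simulation_config"))
  set.seed(stage_seed(config$seed, "mirna"))
  n <- config$n_mirnas
  Lm <- config$mirna_length

  ## family structure: ~70% distinct families, extra members get letters
  n_fam <- max(1L, ceiling(n * 0.7))
  fam_nums <- sample(150:999, n_fam)
  fam_of <- sort(sample(seq_len(n_fam), n, replace = TRUE))
  names_out <- character(n)
  for (f in unique(fam_of)) {
    idx <- which(fam_of == f)
    suffix <- if (length(idx) == 1L) "" else letters[seq_along(idx)]
    names_out[idx] <- sprintf("miR%d%s", fam_nums[f], suffix)
  }
  mirnas <- vapply(seq_len(n), function(i) {
    repeat {
      s <- random_background(Lm)
      if (sum(strsplit(s, "")[[1]] %in% c("G", "T")) >= 6) return(s)
    }
  }, character(1))
  names(mirnas) <- names_out

  lnc_pool <- truth$lncrnas$id[truth$lncrnas$class == "intergenic"]
  de_lnc <- intersect(lnc_pool, truth$de$feature_id)
  if (length(de_lnc) >= 5) lnc_pool <- de_lnc
  ## mRNAs hosting an antisense lncRNA (or any other overlapping
  ## transcript) must stay untouched: editing them would silently change
  ## the overlapping transcript's genome-extracted sequence
  mrna_pool <- Filter(function(id) {
    i <- match(id, transcripts$id)
    !any(transcripts$chrom == transcripts$chrom[i] &
           transcripts$id != id &
           transcripts$start <= transcripts$end[i] &
           transcripts$end >= transcripts$start[i])
  }, truth$coding_ids)
  cds_seqs <- transcripts$sequence[match(truth$coding_ids, transcripts$id)]
  gen_hex <- if (length(cds_seqs)) {
    comp_train <- vapply(1:150, function(i) random_background(600),
                         character(1))
    train_hexamer_model(cds_seqs,
                        orf_or_self(c(comp_train, revcomp(cds_seqs))))
  } else generator_hexamer_model()
  planted_at <- list()  # per transcript: planted offsets to keep disjoint

  seq_of <- setNames(transcripts$sequence, transcripts$id)
  sites <- list()
  implant <- function(mirna_id, target_id, n_mm, n_wob, decoy) {
    win <- build_site_window(mirnas[[mirna_id]], n_mm, n_wob)
    if (is.null(win)) return(FALSE)
    sq <- seq_of[[target_id]]
    lt <- nchar(sq)
    if (lt < Lm + 2L) return(FALSE)
    is_lnc <- target_id %in% truth$lncrnas$id
    used <- planted_at[[target_id]]
    for (try in 1:40) {
      off <- sample.int(lt - Lm + 1L, 1) - 1L  # 0-based
      if (!is.null(used) &&
          any(abs(used - off) < Lm)) next
      cand <- sq
      substr(cand, off + 1L, off + Lm) <- win
      if (is_lnc && (find_longest_orf(cand)$length > 300L ||
                     true_orf_bias(cand, gen_hex) >
                       NONCODING_BIAS_MARGIN)) next
      seq_of[[target_id]] <<- cand
      planted_at[[target_id]] <<- c(used, off)
      sites[[length(sites) + 1L]] <<- data.frame(
        mirna_id = mirna_id, transcript_id = target_id, offset = off,
        n_mismatch = n_mm, n_wobble = n_wob, decoy = decoy,
        stringsAsFactors = FALSE)
      return(TRUE)
    }
    FALSE
  }

  for (mid in names(mirnas)) {
    for (k in seq_len(sample.int(config$sites_per_mirna, 1))) {
      implant(mid, sample(lnc_pool, 1), sample(0:2, 1), sample(0:2, 1),
              decoy = FALSE)
    }
    if (runif(1) < 0.4 && length(mrna_pool))
      implant(mid, sample(mrna_pool, 1), sample(0:2, 1), sample(0:2, 1),
              decoy = FALSE)
    for (k in seq_len(config$decoys_per_mirna)) {
      implant(mid, sample(lnc_pool, 1), sample(3:5, 1), sample(0:2, 1),
              decoy = TRUE)
    }
  }

  changed <- names(seq_of)[seq_of != transcripts$sequence]
  transcripts$sequence <- unname(seq_of[transcripts$id])
  if (!is.null(genome)) {
    for (id in changed) {
      i <- match(id, transcripts$id)
      ch <- transcripts$chrom[i]
      genome$sequences[[ch]] <- splice_into_genome(
        genome$sequences[[ch]], transcripts$exons[[i]],
        transcripts$strand[i], transcripts$sequence[i])
    }
  }
  truth$mirna_sites <- if (length(sites)) do.call(rbind, sites) else
    data.frame(mirna_id = character(), transcript_id = character(),
               offset = integer(), n_mismatch = integer(),
               n_wobble = integer(), decoy = logical(),
               stringsAsFactors = FALSE)
  list(mirnas = mirnas, transcripts = transcripts, truth = truth,
       genome = genome)
}

#' Simulate a complete synthetic salt-stress dataset
#'
#' Runs the full generator chain (genome, transcripts, counts, miRNAs) and
#' optionally writes every external file the pipeline consumes:
#' `genome.fa`, `genes.gff3`, `transcripts.gtf`, `transcripts.fa`,
#' `sidecar.tsv`, `counts.tsv`, `mirnas.fa`, `truth.json`.
#'
#' @param config a [simulation_config()].
#' @param out_dir optional output directory (created if missing).
#' @return A `salt_dataset`: list with `genome`, `annotation`,
#'   `transcripts`, `counts`, `conditions`, `size_factors`, `mirnas`,
#'   `truth`, `config`.
#' @export
simulate_dataset <- function(config = simulation_config(),
                             out_dir = NULL) {
  genome <- generate_genome(config)
  tr <- generate_transcripts(config, genome)
  cn <- generate_counts(config, tr$truth)
  mi <- generate_mirnas(config, cn$truth, tr$transcripts, tr$genome)
  ds <- structure(list(
    genome = mi$genome, annotation = mi$genome$annotation,
    transcripts = mi$transcripts, counts = cn$counts,
    conditions = cn$conditions, size_factors = cn$size_factors,
    mirnas = mi$mirnas, truth = mi$truth, config = config),
    class = "salt_dataset")
  if (!is.null(out_dir)) {
    dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
    p <- function(f) file.path(out_dir, f)
    Biostrings::writeXStringSet(
      Biostrings::DNAStringSet(ds$genome$sequences), p("genome.fa"))
    write_annotation(ds$annotation, p("genes.gff3"))
    write_transcripts(ds$transcripts, p("transcripts.gtf"),
                      p("transcripts.fa"), p("sidecar.tsv"))
    write_counts(ds$counts, p("counts.tsv"))
    Biostrings::writeXStringSet(
      Biostrings::DNAStringSet(ds$mirnas), p("mirnas.fa"))
    jsonlite::write_json(
      ds$truth[c("coding_ids", "lncrnas", "junk", "de", "cis_pairs",
                 "mirna_sites")],
      p("truth.json"), dataframe = "columns", auto_unbox = FALSE)
  }
  ds
}

#' @export
print.salt_dataset <- function(x, ...) {
  cat(sprintf(paste0(
    "salt_dataset: %d chromosomes, %d genes, %d transcripts ",
    "(%d lncRNA, %d junk), %d miRNAs, %d x %d counts\n"),
    nrow(x$annotation$chromosomes), nrow(x$annotation$genes),
    nrow(x$transcripts), nrow(x$truth$lncrnas), nrow(x$truth$junk),
    length(x$mirnas), nrow(x$counts), ncol(x$counts)))
  invisible(x)
}

#' Verify the internal consistency of a synthetic dataset
#'
#' Re-derives, from the emitted objects alone, everything the ground
#' truth claims: transcript sequences match the genome at their exons;
#' planted intergenic lncRNAs overlap no gene and antisense lncRNAs
#' overlap exactly their host on the opposite strand; no planted lncRNA
#' violates any basic filter while every junk transcript violates exactly
#' its recorded one; planted cis distances match the recorded geometry;
#' and every planted miRNA site pairs with exactly its recorded mismatch
#' and wobble counts.
#'
#' @param dataset a `salt_dataset` from [simulate_dataset()].
#' @return TRUE invisibly; inconsistencies raise an error.
#' @export
verify_ground_truth <- function(dataset) {
  tr <- dataset$transcripts
  genes <- dataset$annotation$genes
  truth <- dataset$truth
  fail <- function(...) stop("ground truth inconsistency: ", ...)

  ## genome/transcript consistency
  for (i in seq_len(nrow(tr))) {
    got <- extract_spliced(dataset$genome$sequences[[tr$chrom[i]]],
                           tr$exons[[i]], tr$strand[i])
    if (got != tr$sequence[i]) fail("sequence mismatch for ", tr$id[i])
  }
  if (any(tr$spliced_length != nchar(tr$sequence)))
    fail("spliced_length != sequence length")

  ## id sets disjoint
  sets <- list(truth$lncrnas$id, truth$coding_ids, truth$junk$id)
  if (anyDuplicated(unlist(sets))) fail("feature id sets overlap")

  overlap_rows <- function(i, same_strand) {
    which(genes$chrom == tr$chrom[i] &
            (if (same_strand) genes$strand == tr$strand[i]
             else genes$strand != tr$strand[i]) &
            genes$start <= tr$end[i] & genes$end >= tr$start[i])
  }
  for (j in seq_len(nrow(truth$lncrnas))) {
    i <- match(truth$lncrnas$id[j], tr$id)
    same <- overlap_rows(i, TRUE)
    opp <- overlap_rows(i, FALSE)
    if (truth$lncrnas$class[j] == "intergenic") {
      if (length(same) + length(opp) > 0)
        fail("intergenic lncRNA ", tr$id[i], " overlaps a gene")
    } else {
      if (length(same) > 0 || length(opp) != 1L)
        fail("antisense lncRNA ", tr$id[i],
             " does not overlap exactly one opposite-strand gene")
    }
    orf <- find_longest_orf(tr$sequence[i])
    if (orf$length > 300L) fail("lncRNA ", tr$id[i], " has ORF > 300 nt")
    if (tr$spliced_length[i] < 200L || tr$coverage[i] < 3 ||
        tr$samples_detected[i] < 2L)
      fail("lncRNA ", tr$id[i], " violates a basic filter")
  }
  for (j in seq_len(nrow(truth$junk))) {
    i <- match(truth$junk$id[j], tr$id)
    viol <- c(
      recurrence = tr$samples_detected[i] < 2L,
      same_strand_overlap = length(overlap_rows(i, TRUE)) > 0,
      length = tr$spliced_length[i] < 200L,
      coverage = tr$coverage[i] < 3,
      orf_length = find_longest_orf(tr$sequence[i])$length > 300L)
    if (sum(viol) != 1L || !viol[[truth$junk$reason[j]]])
      fail("junk ", tr$id[i], " violations: ",
           paste(names(viol)[viol], collapse = ","), " (expected ",
           truth$junk$reason[j], ")")
  }

  cp <- truth$cis_pairs
  for (j in seq_len(nrow(cp))) {
    i <- match(cp$lncrna_id[j], tr$id)
    g <- genes[genes$gene_id == cp$gene_id[j], ]
    geo <- cis_geometry(list(start = tr$start[i], end = tr$end[i],
                             strand = tr$strand[i]), g)
    if (geo$side != cp$side[j] || geo$distance != cp$distance[j])
      fail("cis pair ", cp$lncrna_id[j], "-", cp$gene_id[j],
           " geometry mismatch")
  }

  ms <- truth$mirna_sites
  seq_of <- setNames(tr$sequence, tr$id)
  Lm <- dataset$config$mirna_length
  for (j in seq_len(nrow(ms))) {
    win <- substr(seq_of[[ms$transcript_id[j]]], ms$offset[j] + 1L,
                  ms$offset[j] + Lm)
    pp <- pair_positions(dataset$mirnas[[ms$mirna_id[j]]], win)
    if (pp$n_mismatch != ms$n_mismatch[j] ||
        pp$n_wobble != ms$n_wobble[j])
      fail("miRNA site ", ms$mirna_id[j], "@", ms$transcript_id[j],
           " pairing counts mismatch")
  }

  if (any(dataset$counts < 0) || any(dataset$counts != round(dataset$counts)))
    fail("counts are not non-negative integers")
  invisible(TRUE)
}
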