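test_that("generation is a pure function of the configuration", {
  a <- simulate_dataset(small_config(5))
  b <- simulate_dataset(small_config(5))
  expect_identical(a$genome$sequences, b$genome$sequences)
  expect_identical(a$annotation$genes, b$annotation$genes)
  expect_identical(a$transcripts$sequence, b$transcripts$sequence)
  expect_identical(a$counts, b$counts)
  expect_identical(a$mirnas, b$mirnas)
  expect_identical(a$truth$mirna_sites, b$truth$mirna_sites)
  expect_identical(a$truth$cis_pairs, b$truth$cis_pairs)

  # a different seed changes the data
  c <- simulate_dataset(small_config(6))
  expect_false(identical(a$counts, c$counts))
})

test_that("the requested feature counts are generated", {
  ds <- small_dataset(1)
  cfg <- small_config(1)
  expect_equal(nrow(ds$annotation$genes), cfg$n_coding)
  expect_equal(sum(ds$truth$lncrnas$class == "antisense"),
               cfg$n_antisense)
  expect_equal(sum(ds$truth$lncrnas$class == "intergenic"),
               cfg$n_intergenic)
  expect_equal(nrow(ds$truth$junk), cfg$n_junk)
  expect_equal(length(ds$mirnas), cfg$n_mirnas)
  expect_equal(ncol(ds$counts), 12)
})

test_that("generated CDSs are in-frame, stop-free and complete", {
  ds <- small_dataset(1)
  stops <- c("TAA", "TAG", "TGA")
  for (cds in ds$genome$cds) {
    n <- nchar(cds)
    expect_equal(n %% 3, 0)
    expect_equal(substr(cds, 1, 3), "ATG")
    expect_true(substr(cds, n - 2, n) %in% stops)
    # no internal in-frame stop codon
    starts <- seq(4, n - 3, by = 3)
    codons <- substring(cds, starts, starts + 2)
    expect_false(any(codons %in% stops))
  }
  # base composition of the coding pool reflects the codon-usage law,
  # noncoding background is AT-rich
  gc_cds <- mean(strsplit(paste(ds$genome$cds, collapse = ""),
                          "")[[1]] %in% c("G", "C"))
  expect_gt(gc_cds, 0.38)
})

test_that("planted intergenic lncRNAs overlap no gene (interval oracle)", {
  ds <- small_dataset(2)
  g <- ds$annotation$genes
  tr <- ds$transcripts
  inter <- ds$truth$lncrnas$id[ds$truth$lncrnas$class == "intergenic"]
  for (id in inter) {
    i <- match(id, tr$id)
    hits <- sum(g$chrom == tr$chrom[i] & g$start <= tr$end[i] &
                  g$end >= tr$start[i])
    expect_equal(hits, 0)
  }
  anti <- ds$truth$lncrnas$id[ds$truth$lncrnas$class == "antisense"]
  for (id in anti) {
    i <- match(id, tr$id)
    opp <- sum(g$chrom == tr$chrom[i] & g$strand != tr$strand[i] &
                 g$start <= tr$end[i] & g$end >= tr$start[i])
    expect_equal(opp, 1)
  }
})

test_that("junk transcripts violate exactly their tagged filter", {
  ds <- small_dataset(3)
  tr <- ds$transcripts
  for (j in seq_len(nrow(ds$truth$junk))) {
    id <- ds$truth$junk$id[j]
    reason <- ds$truth$junk$reason[j]
    i <- match(id, tr$id)
    viol <- c(
      recurrence = tr$samples_detected[i] < 2,
      same_strand_overlap = any(
        ds$annotation$genes$chrom == tr$chrom[i] &
          ds$annotation$genes$strand == tr$strand[i] &
          ds$annotation$genes$start <= tr$end[i] &
          ds$annotation$genes$end >= tr$start[i]),
      length = tr$spliced_length[i] < 200,
      coverage = tr$coverage[i] < 3,
      orf_length = orf_oracle(tr$sequence[i])$length > 300)
    expect_equal(sum(viol), 1)
    expect_true(viol[[reason]])
  }
})

test_that("counts are NB with the planted mean structure", {
  ds <- small_dataset(1)
  expect_true(all(ds$counts >= 0))
  expect_true(all(ds$counts == round(ds$counts)))

  # M1 features: condition means ordered H0 < H6 < H12 < H24, averaged
  # over features (Monte-Carlo on the planted truth)
  cfg <- simulation_config(seed = 9, n_chromosomes = 1,
                           chromosome_length = 400000, n_coding = 40,
                           n_antisense = 10, n_intergenic = 40,
                           n_junk = 0, n_mirnas = 2,
                           de_fraction_lncrna = 1, de_fraction_coding = 1,
                           baseline_meanlog = log(1000),
                           baseline_sdlog = 0)
  ds9 <- simulate_dataset(cfg)
  m1 <- ds9$truth$de$feature_id[ds9$truth$de$archetype == "M1"]
  cm <- vapply(c("H0", "H6", "H12", "H24"), function(cd)
    mean(ds9$counts[m1, ds9$conditions == cd]), numeric(1))
  expect_true(all(diff(cm) > 0))

  # recorded log2 fold changes follow the multiplier table
  expect_equal(unname(ds9$truth$log2fc["H0_H24", m1]),
               rep(log2(8), length(m1)))
})

test_that("the NB sampler reaches the Poisson limit as alpha -> 0", {
  cfg <- simulation_config(seed = 12, n_chromosomes = 1,
                           chromosome_length = 150000, n_coding = 10,
                           n_antisense = 2, n_intergenic = 5, n_junk = 0,
                           n_mirnas = 2, dispersion = 1e-8,
                           de_fraction_lncrna = 0, de_fraction_coding = 0,
                           n_cis_pairs = 0, size_factor_sd = 0,
                           baseline_meanlog = log(1000),
                           baseline_sdlog = 0)
  genome <- generate_genome(cfg)
  tr <- generate_transcripts(cfg, genome)
  # replicate the feature list to reach 1e4 draws at mean 1000
  truth <- tr$truth
  truth$feature_ids <- paste0("f", 1:840)
  truth$de <- truth$de[0, ]
  cn <- generate_counts(cfg, truth)
  draws <- as.vector(cn$counts)  # 840 x 12 > 1e4 iid Poisson(1000)
  expect_gt(length(draws), 1e4)
  expect_lt(abs(var(draws) / mean(draws) - 1), 0.05)
  expect_lt(abs(mean(draws) / 1000 - 1), 0.05)
})

test_that("alpha <= 0 is rejected", {
  expect_error(simulation_config(dispersion = 0))
  expect_error(simulation_config(dispersion = -1))
})

test_that("planted miRNA sites recount exactly under the pairing oracle", {
  ds <- small_dataset(2)
  sites <- ds$truth$mirna_sites
  seqs <- setNames(ds$transcripts$sequence, ds$transcripts$id)
  Lm <- ds$config$mirna_length
  for (j in seq_len(nrow(sites))) {
    win <- substr(seqs[[sites$transcript_id[j]]], sites$offset[j] + 1,
                  sites$offset[j] + Lm)
    got <- pairing_oracle(ds$mirnas[[sites$mirna_id[j]]], win)
    expect_equal(got$n_mismatch, sites$n_mismatch[j])
    expect_equal(got$n_wobble, sites$n_wobble[j])
  }
  # a zero-mismatch zero-wobble site is the exact reverse complement
  perfect <- sites[sites$n_mismatch == 0 & sites$n_wobble == 0, ]
  for (j in seq_len(nrow(perfect))) {
    win <- substr(seqs[[perfect$transcript_id[j]]], perfect$offset[j] + 1,
                  perfect$offset[j] + Lm)
    expect_equal(win,
                 saltlnc:::revcomp(ds$mirnas[[perfect$mirna_id[j]]]))
  }
})

test_that("the emitted dataset passes the independent verification pass", {
  for (seed in 1:3) expect_true(verify_ground_truth(small_dataset(seed)))
})

test_that("written files reload into the same objects", {
  td <- tempfile()
  ds <- simulate_dataset(small_config(4), out_dir = td)
  expect_true(all(file.exists(file.path(td, c(
    "genome.fa", "genes.gff3", "transcripts.gtf", "transcripts.fa",
    "sidecar.tsv", "counts.tsv", "mirnas.fa", "truth.json")))))
  ann <- read_annotation(file.path(td, "genes.gff3"))
  expect_identical(ann$genes, ds$annotation$genes)
  expect_identical(read_counts(file.path(td, "counts.tsv")), ds$counts)
  truth <- jsonlite::read_json(file.path(td, "truth.json"),
                               simplifyVector = TRUE)
  expect_identical(truth$lncrnas$id, ds$truth$lncrnas$id)
  expect_identical(truth$junk$reason, ds$truth$junk$reason)
})
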