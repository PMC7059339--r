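test_that("the printed pair geometry is reproduced exactly", {
  # a gene whose span starts 59,575 bp past the 3' end of a plus-strand
  # lncRNA is a downstream candidate at exactly that distance under the
  # 10 kb / 100 kb windows
  lnc <- data.frame(id = "lnc1", chrom = "chr18", strand = "+",
                    start = 5000, end = 5400, stringsAsFactors = FALSE)
  genes <- gene_row("gene1", "chr18", "+", 5400 + 59575, 5400 + 61000)
  cand <- find_cis_candidates(lnc, genes)
  expect_equal(nrow(cand), 1)
  expect_equal(cand$side, "downstream")
  expect_equal(cand$distance, 59575)

  # one bp beyond the downstream window is excluded
  far <- gene_row("gene2", "chr18", "+", 5400 + 100001, 5400 + 102000)
  expect_equal(nrow(find_cis_candidates(lnc, far)), 0)
  at <- gene_row("gene3", "chr18", "+", 5400 + 100000, 5400 + 102000)
  expect_equal(find_cis_candidates(lnc, at)$distance, 100000)
})

test_that("sides follow the lncRNA strand and overlaps give distance 0", {
  genes <- gene_row("g", "chr1", "+", 20000, 21000)
  plus <- data.frame(id = "l", chrom = "chr1", strand = "+",
                     start = 25000, end = 25400, stringsAsFactors = FALSE)
  # gene on the genomic left of a plus-strand lncRNA -> upstream
  c1 <- find_cis_candidates(plus, genes)
  expect_equal(c1$side, "upstream")
  expect_equal(c1$distance, 25000 - 21000)
  # same geometry, minus strand -> downstream
  minus <- transform(plus, strand = "-")
  expect_equal(find_cis_candidates(minus, genes)$side, "downstream")

  # overlapping spans
  over <- data.frame(id = "l", chrom = "chr1", strand = "+",
                     start = 20500, end = 20900, stringsAsFactors = FALSE)
  c3 <- find_cis_candidates(over, genes)
  expect_equal(c3$distance, 0)
  expect_equal(c3$side, "downstream")
})

test_that("window scan equals the quadratic brute force", {
  set.seed(61)
  for (rep in 1:15) {
    nl <- sample(3:8, 1)
    ng <- sample(3:12, 1)
    lnc <- data.frame(id = paste0("l", 1:nl), chrom = "chr1",
                      strand = sample(c("+", "-"), nl, TRUE),
                      start = ls <- sample.int(3e5, nl),
                      end = ls + sample.int(2000, nl),
                      stringsAsFactors = FALSE)
    genes <- data.frame(gene_id = paste0("g", 1:ng), chrom = "chr1",
                        start = gs <- sample.int(3e5, ng),
                        end = gs + sample.int(5000, ng),
                        stringsAsFactors = FALSE)
    got <- find_cis_candidates(lnc, genes)
    key_got <- sort(paste(got$lncrna_id, got$gene_id, got$side,
                          got$distance))
    brute <- character(0)
    for (i in 1:nl) for (j in 1:ng) {
      if (genes$start[j] > lnc$end[i]) {        # gene right
        d <- genes$start[j] - lnc$end[i]
        side <- if (lnc$strand[i] == "+") "downstream" else "upstream"
      } else if (genes$end[j] < lnc$start[i]) { # gene left
        d <- lnc$start[i] - genes$end[j]
        side <- if (lnc$strand[i] == "+") "upstream" else "downstream"
      } else {
        d <- 0
        side <- "downstream"
      }
      win <- if (side == "upstream") 10000 else 100000
      if (d <= win)
        brute <- c(brute, paste(lnc$id[i], genes$gene_id[j], side, d))
    }
    expect_identical(key_got, sort(brute))
  }
})

test_that("mirroring coordinates and flipping strands preserves geometry", {
  set.seed(62)
  M <- 4e5
  for (rep in 1:10) {
    lnc <- data.frame(id = "l1", chrom = "chr1",
                      strand = sample(c("+", "-"), 1),
                      start = ls <- sample.int(2e5, 1),
                      end = ls + sample.int(1000, 1),
                      stringsAsFactors = FALSE)
    genes <- data.frame(gene_id = paste0("g", 1:5), chrom = "chr1",
                        start = gs <- sample.int(3e5, 5),
                        end = gs + sample.int(3000, 5),
                        stringsAsFactors = FALSE)
    a <- find_cis_candidates(lnc, genes)
    mirror <- function(s, e) list(start = M - e + 1, end = M - s + 1)
    ml <- mirror(lnc$start, lnc$end)
    lnc2 <- data.frame(id = "l1", chrom = "chr1",
                       strand = if (lnc$strand == "+") "-" else "+",
                       start = ml$start, end = ml$end,
                       stringsAsFactors = FALSE)
    mg <- mirror(genes$start, genes$end)
    genes2 <- data.frame(gene_id = genes$gene_id, chrom = "chr1",
                         start = mg$start, end = mg$end,
                         stringsAsFactors = FALSE)
    b <- find_cis_candidates(lnc2, genes2)
    expect_identical(
      sort(paste(a$gene_id, a$side, a$distance)),
      sort(paste(b$gene_id, b$side, b$distance)))
  }
})

test_that("widening a window never removes a candidate", {
  set.seed(63)
  lnc <- data.frame(id = paste0("l", 1:5), chrom = "chr1",
                    strand = sample(c("+", "-"), 5, TRUE),
                    start = ls <- sample.int(3e5, 5), end = ls + 500,
                    stringsAsFactors = FALSE)
  genes <- data.frame(gene_id = paste0("g", 1:10), chrom = "chr1",
                      start = gs <- sample.int(3e5, 10), end = gs + 800,
                      stringsAsFactors = FALSE)
  narrow <- find_cis_candidates(lnc, genes, 5000, 50000)
  wide <- find_cis_candidates(lnc, genes, 10000, 100000)
  expect_true(all(paste(narrow$lncrna_id, narrow$gene_id) %in%
                    paste(wide$lncrna_id, wide$gene_id)))
})

test_that("correlation scoring flags degenerate vectors", {
  fpkm <- rbind(l1 = 1:12, g1 = 1:12, g2 = rep(3, 12))
  cand <- data.frame(lncrna_id = c("l1", "l1"), gene_id = c("g1", "g2"),
                     side = "downstream", distance = c(10, 20),
                     stringsAsFactors = FALSE)
  expect_warning(sc <- score_cis_pairs(cand, fpkm), "constant")
  expect_equal(sc$r[1], 1)
  expect_true(sc$passes[1])
  expect_true(is.na(sc$r[2]))
  expect_false(sc$passes[2])
  expect_error(score_cis_pairs(
    data.frame(lncrna_id = "nope", gene_id = "g1", side = "d",
               distance = 1), fpkm), "missing")
})

test_that("planted cis pairs match the manifest and pass correlation", {
  for (seed in 1:3) {
    ds <- small_dataset(seed)
    truth <- ds$truth
    cp <- truth$cis_pairs
    de_lnc <- truth$de$feature_id[truth$de$kind == "lncrna"]
    lnc <- ds$transcripts[ds$transcripts$id %in% de_lnc, ]
    de_gene_ids <- truth$de$gene_id[truth$de$kind == "coding"]
    genes <- ds$annotation$genes[
      ds$annotation$genes$gene_id %in% de_gene_ids, ]
    cand <- find_cis_candidates(lnc, genes)
    m <- merge(cp, cand, by = c("lncrna_id", "gene_id"))
    expect_equal(nrow(m), nrow(cp))  # every planted pair is a candidate
    expect_identical(m$side.y, m$side.x)
    expect_equal(m$distance.y, m$distance.x)
  }
})
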