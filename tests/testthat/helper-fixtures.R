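# Shared fixtures: a reduced-size simulation for unit tests (the
# acceptance suite runs the full default configuration) plus small
# constructors used across files.

small_config <- function(seed) {
  simulation_config(seed = seed, n_chromosomes = 2,
                    chromosome_length = 120000, n_coding = 30,
                    n_antisense = 8, n_intergenic = 16, n_junk = 10,
                    n_mirnas = 6, n_cis_pairs = 4)
}

.ds_cache <- new.env(parent = emptyenv())

small_dataset <- function(seed) {
  key <- paste0("s", seed)
  if (is.null(.ds_cache[[key]]))
    .ds_cache[[key]] <- simulate_dataset(small_config(seed))
  .ds_cache[[key]]
}

full_dataset <- function(seed) {
  key <- paste0("f", seed)
  if (is.null(.ds_cache[[key]]))
    .ds_cache[[key]] <- simulate_dataset(simulation_config(seed = seed))
  .ds_cache[[key]]
}

# one-row transcript_set for filter/classification tests
make_tr <- function(id, chrom, strand, start, len, sequence,
                    coverage = 10, samples_detected = 5) {
  df <- data.frame(id = id, chrom = chrom, strand = strand,
                   start = start, end = start + len - 1,
                   spliced_length = len, coverage = coverage,
                   samples_detected = as.integer(samples_detected),
                   sequence = sequence, stringsAsFactors = FALSE)
  df$exons <- list(cbind(start = start, end = start + len - 1))
  structure(df, class = c("transcript_set", "data.frame"))
}

bind_tr <- function(...) {
  parts <- list(...)
  df <- do.call(rbind, lapply(parts, function(x) {
    x$exons <- NULL
    as.data.frame(x)
  }))
  df$exons <- do.call(c, lapply(parts, function(x) x$exons))
  structure(df, class = c("transcript_set", "data.frame"))
}

make_ann <- function(genes, chrom_len = 1e6) {
  chroms <- unique(genes$chrom)
  structure(list(
    chromosomes = data.frame(name = chroms,
                             length = rep(as.integer(chrom_len),
                                          length(chroms)),
                             stringsAsFactors = FALSE),
    genes = genes), class = "genome_annotation")
}

gene_row <- function(gene_id, chrom, strand, start, end,
                     category = "unassigned") {
  data.frame(gene_id = gene_id, chrom = chrom, strand = strand,
             start = start, end = end, category = category,
             stringsAsFactors = FALSE)
}

random_seq <- function(n, bases = c("A", "C", "G", "T")) {
  paste(sample(bases, n, replace = TRUE), collapse = "")
}

# independent brute-force longest-ORF oracle: every ATG scanned forward
# codon by codon to the first in-frame stop
orf_oracle <- function(s) {
  s <- toupper(s)
  n <- nchar(s)
  stops <- c("TAA", "TAG", "TGA")
  best <- list(found = FALSE, start = NA_integer_, length = 0L)
  for (i in seq_len(max(0, n - 5))) {
    if (substr(s, i, i + 2) != "ATG") next
    j <- i + 3
    while (j + 2 <= n) {
      if (substr(s, j, j + 2) %in% stops) {
        len <- j + 2 - i + 1
        if (len > best$length ||
            (len == best$length && (i - 1) < best$start)) {
          best <- list(found = TRUE, start = i - 1L, length = as.integer(len))
        }
        break
      }
      j <- j + 3
    }
  }
  best
}

# independent per-position pairing oracle built from an explicit pair
# dictionary
pairing_oracle <- function(mirna, window) {
  m <- strsplit(toupper(chartr("U", "T", mirna)), "")[[1]]
  w <- strsplit(toupper(chartr("U", "T", window)), "")[[1]]
  L <- length(m)
  matches <- c("A T", "T A", "G C", "C G")
  wobbles <- c("G T", "T G")
  mm <- 0L; wo <- 0L
  for (k in seq_len(L)) {
    pair <- paste(m[k], w[L - k + 1])
    if (pair %in% wobbles) wo <- wo + 1L
    else if (!pair %in% matches) mm <- mm + 1L
  }
  list(n_mismatch = mm, n_wobble = wo)
}

# independent NB pmf via the Gamma-function form, for the exact-test
# enumeration oracle
nb_pmf <- function(k, mu, size) {
  exp(lgamma(k + size) - lgamma(size) - lgamma(k + 1) +
        size * (log(size) - log(size + mu)) +
        k * (log(mu) - log(size + mu)))
}

# the default training recipe for the coding-potential scorer on a
# synthetic dataset
trained_model <- function(ds, n_windows = 300) {
  set.seed(ds$config$seed + 1000003L)
  cds <- ds$genome$cds
  nc <- c(sample_noncoding_windows(ds$genome$sequences, ds$annotation,
                                   n = n_windows, width = 600),
          saltlnc:::revcomp(cds))
  train_coding_model(cds, nc)
}
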