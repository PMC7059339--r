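## Coding-potential scoring: Fickett TESTCODE, in-frame hexamer usage
## bias, a logistic combiner over (ORF length, ORF coverage, Fickett,
## hexamer), and a conservative OR-rule consensus. A precomputed protein
## domain hit table provides the final exclusion step.

## Fickett (1982) TESTCODE lookup tables, embedded verbatim from the
## original publication. Position parameter for base B is
## max(count in codon pos 1..3)/(min + 1); content parameter is the base
## fraction. Each of the 8 parameters maps through its interval table to a
## probability, which enters the score with the published weight.
FICKETT_POSITION_PARA <- c(1.9, 1.8, 1.7, 1.6, 1.5, 1.4, 1.3, 1.2, 1.1, 0)
FICKETT_CONTENT_PARA <- c(0.33, 0.31, 0.29, 0.27, 0.25, 0.23, 0.21, 0.19,
                          0.17, 0)
FICKETT_POSITION_PROB <- list(
  A = c(0.51, 0.55, 0.57, 0.52, 0.48, 0.58, 0.57, 0.54, 0.50, 0.36),
  C = c(0.29, 0.44, 0.55, 0.49, 0.52, 0.60, 0.60, 0.56, 0.51, 0.38),
  G = c(0.62, 0.67, 0.74, 0.65, 0.61, 0.62, 0.52, 0.41, 0.31, 0.17),
  T = c(0.51, 0.60, 0.69, 0.64, 0.62, 0.67, 0.58, 0.48, 0.39, 0.24))
FICKETT_CONTENT_PROB <- list(
  A = c(0.40, 0.55, 0.58, 0.58, 0.52, 0.48, 0.45, 0.45, 0.38, 0.19),
  C = c(0.50, 0.63, 0.59, 0.50, 0.41, 0.30, 0.33, 0.29, 0.29, 0.17),
  G = c(0.21, 0.40, 0.47, 0.50, 0.52, 0.60, 0.61, 0.62, 0.73, 0.70),
  T = c(0.30, 0.49, 0.56, 0.53, 0.48, 0.48, 0.34, 0.20, 0.09, 0.09))
FICKETT_POSITION_WEIGHT <- c(A = 0.26, C = 0.18, G = 0.31, T = 0.33)
FICKETT_CONTENT_WEIGHT <- c(A = 0.11, C = 0.12, G = 0.15, T = 0.14)

fickett_lookup <- function(value, para, prob) {
  prob[match(TRUE, value >= para)]
}

#' Fickett TESTCODE score of a nucleotide sequence
#'
#' Weighted sum of eight looked-up probabilities: for each base, a
#' position-asymmetry parameter (how unevenly the base is distributed over
#' the three codon positions) and a composition parameter, each mapped
#' through the published TESTCODE tables. Higher values indicate coding
#' character; the classic "probably coding" threshold is 0.95.
#'
#' @param sequence nucleotide string (case-insensitive, T/U equivalent).
#' @return numeric score.
#' @export
fickett_score <- function(sequence) {
  s <- toupper(chartr("u", "t", tolower(sequence)))
  if (nchar(s) < 2L) stop("sequence must have length >= 2")
  ch <- strsplit(s, "", fixed = TRUE)[[1]]
  n <- length(ch)
  phase <- rep_len(1:3, n)
  score <- 0
  for (b in c("A", "C", "G", "T")) {
    cnt <- vapply(1:3, function(p) sum(ch == b & phase == p), numeric(1))
    pos_val <- max(cnt) / (min(cnt) + 1)
    cont_val <- sum(cnt) / n
    score <- score +
      fickett_lookup(pos_val, FICKETT_POSITION_PARA,
                     FICKETT_POSITION_PROB[[b]]) *
        FICKETT_POSITION_WEIGHT[[b]] +
      fickett_lookup(cont_val, FICKETT_CONTENT_PARA,
                     FICKETT_CONTENT_PROB[[b]]) *
        FICKETT_CONTENT_WEIGHT[[b]]
  }
  unname(score)
}

all_hexamers <- function() {
  b <- c("A", "C", "G", "T")
  g <- expand.grid(b, b, b, b, b, b, stringsAsFactors = FALSE)[, 6:1]
  sort(apply(g, 1, paste, collapse = ""))
}

count_inframe_hexamers <- function(sequences, step = 3L) {
  hx <- all_hexamers()
  counts <- setNames(numeric(length(hx)), hx)
  for (s in sequences) {
    s <- toupper(chartr("u", "t", tolower(s)))
    n <- nchar(s)
    if (n < 6L) next
    starts <- seq.int(1L, n - 5L, by = step)
    words <- substring(s, starts, starts + 5L)
    words <- words[grepl("^[ACGT]{6}$", words)]
    if (length(words)) {
      tb <- table(words)
      counts[names(tb)] <- counts[names(tb)] + as.numeric(tb)
    }
  }
  counts
}

#' Train a hexamer usage model from coding and noncoding sequences
#'
#' Counts in-frame hexamers (step 3, frame 0) in each training set, adds a
#' pseudocount, and normalizes to frequency tables over all 4096 DNA
#' hexamers.
#'
#' @param coding_seqs character vector of coding sequences (in frame,
#'   e.g. CDSs).
#' @param noncoding_seqs character vector of noncoding sequences.
#' @param pseudocount added to every hexamer count (default 1).
#' @return A `hexamer_model`: list with `coding` and `noncoding` frequency
#'   vectors (each summing to 1) and the pseudocount used.
#' @export
train_hexamer_model <- function(coding_seqs, noncoding_seqs,
                                pseudocount = 1) {
  stopifnot(pseudocount > 0, length(coding_seqs) > 0,
            length(noncoding_seqs) > 0)
  cc <- count_inframe_hexamers(coding_seqs) + pseudocount
  nc <- count_inframe_hexamers(noncoding_seqs) + pseudocount
  structure(list(coding = cc / sum(cc), noncoding = nc / sum(nc),
                 pseudocount = pseudocount),
            class = "hexamer_model")
}

#' Mean in-frame hexamer log-ratio of an ORF sequence
#'
#' Computes `(1/M) * sum(log(f_c(h_k)/f_n(h_k)))` over the M in-frame
#' hexamers obtained by stepping through the ORF sequence by 3. Positive
#' values indicate coding-like hexamer usage. Sequences shorter than 6 nt
#' return 0 by convention.
#'
#' @param orf_sequence nucleotide string, read in frame from its first
#'   position.
#' @param model a `hexamer_model` from [train_hexamer_model()].
#' @return numeric bias (natural log scale).
#' @export
hexamer_bias <- function(orf_sequence, model) {
  if (!inherits(model, "hexamer_model"))
    stop("model must be a trained hexamer_model")
  s <- toupper(chartr("u", "t", tolower(orf_sequence)))
  n <- nchar(s)
  if (n < 6L) return(0)
  starts <- seq.int(1L, n - 5L, by = 3L)
  words <- substring(s, starts, starts + 5L)
  words <- words[grepl("^[ACGT]{6}$", words)]
  if (!length(words)) return(0)
  mean(log(model$coding[words] / model$noncoding[words]))
}

orf_or_self <- function(seqs) {
  vapply(seqs, function(s) {
    o <- find_longest_orf(s)
    if (o$found) substr(s, o$start + 1L, o$end) else s
  }, character(1))
}

#' Sample noncoding genomic windows for model training
#'
#' Draws fixed-width windows from the genome that overlap no annotated
#' gene, for use as noncoding training sequence.
#'
#' @param sequences named character vector of chromosome sequences.
#' @param annotation a `genome_annotation`.
#' @param n number of windows.
#' @param width window width in nt.
#' @return character vector of window sequences.
#' @export
sample_noncoding_windows <- function(sequences, annotation, n = 400,
                                     width = 600) {
  g <- annotation$genes
  out <- character(n)
  for (i in seq_len(n)) {
    for (try in 1:1000) {
      ch <- sample(names(sequences), 1)
      st <- sample.int(nchar(sequences[[ch]]) - width, 1)
      gg <- g[g$chrom == ch, , drop = FALSE]
      if (!any(gg$start <= st + width - 1L & gg$end >= st)) {
        out[i] <- substr(sequences[[ch]], st, st + width - 1L)
        break
      }
    }
    if (out[i] == "") stop("could not sample gene-free windows")
  }
  out
}

#' Train the full coding-potential model
#'
#' Convenience wrapper building both pieces of the scorer from labelled
#' training sequence: the hexamer tables and the logistic combiner. The
#' hexamer tables are trained on the coding sequences versus the longest
#' ORFs extracted from the noncoding sequences, so that both tables
#' describe the same kind of object the bias feature is computed on
#' (in-frame, stop-free sequence). The noncoding training set should
#' represent the whole noncoding population the scorer will meet --
#' including antisense-of-coding sequence, whose base composition matches
#' coding exons; supplying reverse-complemented CDSs alongside intergenic
#' windows achieves this.
#'
#' @param coding_seqs character vector of coding sequences (CDSs).
#' @param noncoding_seqs character vector of noncoding sequences
#'   (e.g. [sample_noncoding_windows()] output plus reverse-complemented
#'   CDSs).
#' @param pseudocount hexamer pseudocount (default 1).
#' @return list with `hexamer` (a `hexamer_model`) and `combiner` (a
#'   `coding_combiner`).
#' @export
train_coding_model <- function(coding_seqs, noncoding_seqs,
                               pseudocount = 1) {
  hm <- train_hexamer_model(coding_seqs, orf_or_self(noncoding_seqs),
                            pseudocount = pseudocount)
  seqs <- c(coding_seqs, noncoding_seqs)
  names(seqs) <- paste0("train", seq_along(seqs))
  sc <- score_transcripts(seqs, hm)
  cmb <- train_combiner(
    sc[, c("orf_length", "orf_coverage", "fickett", "hexamer")],
    rep(c(1, 0), c(length(coding_seqs), length(noncoding_seqs))))
  list(hexamer = hm, combiner = cmb)
}

#' Train the logistic score combiner
#'
#' Fits a logistic regression of the coding label on the standardized
#' feature matrix (orf_length, orf_coverage, fickett, hexamer) by
#' iteratively reweighted least squares.
#'
#' @param features numeric matrix (examples x features) with column names.
#' @param labels logical or 0/1 vector, TRUE/1 = coding.
#' @return A `coding_combiner`: list with `coefficients` (intercept first),
#'   `center` and `scale` used for standardization, and `features` (column
#'   names, in order).
#' @export
train_combiner <- function(features, labels) {
  features <- as.matrix(features)
  y <- as.numeric(labels)
  if (length(unique(y)) < 2L) stop("labels must contain both classes")
  if (min(table(y)) < 10L) stop("need >= 10 examples per class")
  ctr <- colMeans(features)
  scl <- apply(features, 2, sd)
  scl[scl == 0] <- 1
  z <- scale(features, center = ctr, scale = scl)
  fit <- suppressWarnings(
    glm.fit(cbind(1, z), y, family = binomial(),
            control = list(epsilon = 1e-10, maxit = 100)))
  structure(list(coefficients = unname(fit$coefficients),
                 center = ctr, scale = scl,
                 features = colnames(features)),
            class = "coding_combiner")
}

#' Combined coding probability from a trained combiner
#'
#' @param features numeric matrix or data.frame with the combiner's feature
#'   columns.
#' @param combiner a `coding_combiner` from [train_combiner()].
#' @return numeric vector of probabilities in \[0, 1\].
#' @export
combined_probability <- function(features, combiner) {
  if (!inherits(combiner, "coding_combiner"))
    stop("combiner must come from train_combiner()")
  f <- as.matrix(as.data.frame(features)[, combiner$features, drop = FALSE])
  z <- scale(f, center = combiner$center, scale = combiner$scale)
  eta <- drop(cbind(1, z) %*% combiner$coefficients)
  1 / (1 + exp(-eta))
}

#' Score transcripts for coding potential
#'
#' Computes, per transcript: the longest ORF (length and fraction of the
#' transcript covered), the Fickett TESTCODE score of the full sequence,
#' the in-frame hexamer bias of the longest ORF (0 when no ORF is found),
#' and the combined logistic probability when a combiner is supplied.
#'
#' @param sequences named character vector of transcript sequences.
#' @param hexamer_model a `hexamer_model`.
#' @param combiner optional `coding_combiner`; without it `p_coding` is NA.
#' @return data.frame with columns `transcript_id`, `orf_length`,
#'   `orf_coverage`, `fickett`, `hexamer`, `p_coding`.
#' @export
score_transcripts <- function(sequences, hexamer_model, combiner = NULL) {
  ids <- names(sequences)
  if (is.null(ids)) ids <- paste0("seq", seq_along(sequences))
  orfs <- lapply(sequences, find_longest_orf)
  orf_len <- vapply(orfs, `[[`, integer(1), "length")
  orf_seq <- mapply(function(s, o) {
    if (!o$found) "" else substr(s, o$start + 1L, o$end)
  }, sequences, orfs)
  df <- data.frame(
    transcript_id = ids,
    orf_length = orf_len,
    orf_coverage = orf_len / nchar(sequences),
    fickett = vapply(sequences, fickett_score, numeric(1)),
    hexamer = vapply(orf_seq, hexamer_bias, numeric(1),
                     model = hexamer_model),
    stringsAsFactors = FALSE, row.names = NULL)
  df$p_coding <- if (is.null(combiner)) NA_real_ else
    combined_probability(df[, c("orf_length", "orf_coverage", "fickett",
                                "hexamer")], combiner)
  df
}

#' Conservative consensus coding call
#'
#' A transcript is labelled `coding` if ANY scorer exceeds its threshold:
#' combined probability, Fickett score, or hexamer bias. Only transcripts
#' called noncoding by all scorers survive as lncRNA candidates.
#'
#' @param scores data.frame from [score_transcripts()].
#' @param p_threshold combined-probability threshold (default 0.5).
#' @param fickett_threshold Fickett threshold (default 0.95).
#' @param hexamer_threshold hexamer-bias threshold (default 0).
#' @return character vector of labels `"coding"`/`"noncoding"`.
#' @export
consensus_call <- function(scores, p_threshold = 0.5,
                           fickett_threshold = 0.95,
                           hexamer_threshold = 0) {
  p <- scores$p_coding
  p[is.na(p)] <- -Inf  # no combiner: rely on the single-feature scorers
  coding <- (p > p_threshold) | (scores$fickett > fickett_threshold) |
    (scores$hexamer > hexamer_threshold)
  ifelse(coding, "coding", "noncoding")
}

#' Remove transcripts with precomputed protein-domain hits
#'
#' Stands in for a Pfam domain search: the hits are supplied as a table of
#' transcript ids computed elsewhere, and matching transcripts are removed.
#'
#' @param transcript_ids character vector of candidate ids.
#' @param hits data.frame with a `transcript_id` column (may have zero
#'   rows), or a character vector of ids.
#' @return the retained ids, input order preserved.
#' @export
filter_by_domain_hits <- function(transcript_ids, hits) {
  hit_ids <- if (is.data.frame(hits)) as.character(hits$transcript_id)
             else as.character(hits)
  unknown <- setdiff(hit_ids, transcript_ids)
  if (length(unknown))
    warning("domain hits for unknown transcripts ignored: ",
            paste(unknown, collapse = ", "))
  transcript_ids[!transcript_ids %in% hit_ids]
}
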