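## Expression quantification (FPKM), median-of-ratios size factors, a
## negative-binomial exact test for two-group comparisons, BH-FDR control,
## and the pairwise-comparison overlap structure across the time course.

CONDITIONS <- c("H0", "H6", "H12", "H24")

#' Compute FPKM from a count matrix
#'
#' `fpkm_ij = counts_ij / ((length_i / 1e3) * (N_j / 1e6))` with `N_j` the
#' sample's total count.
#'
#' @param counts matrix (features x samples) of non-negative counts.
#' @param lengths transcript lengths in nt, one per feature row.
#' @return FPKM matrix of the same shape.
#' @export
compute_fpkm <- function(counts, lengths) {
  stopifnot(nrow(counts) == length(lengths), all(lengths > 0))
  N <- colSums(counts)
  if (any(N == 0)) stop("sample(s) with zero total count: ",
                        paste(colnames(counts)[N == 0], collapse = ", "))
  sweep(counts / (lengths / 1e3), 2, N / 1e6, "/")
}

#' Median-of-ratios size factors
#'
#' For each sample, the size factor is the median over features (positive
#' in all samples) of the ratio of the count to the feature's geometric
#' mean across samples; factors are rescaled so their geometric mean is 1.
#'
#' @param counts matrix (features x samples) of non-negative counts.
#' @return positive numeric vector of size factors, one per sample.
#' @export
estimate_size_factors <- function(counts) {
  log_gm <- rowMeans(log(counts))
  use <- is.finite(log_gm)
  if (!any(use))
    stop("no feature is positive in all samples; supply a pseudo-reference ",
         "or filter samples")
  s <- apply(counts, 2, function(col)
    median(exp(log(col[use]) - log_gm[use])))
  s / exp(mean(log(s)))
}

mom_dispersion <- function(x) {
  mu <- mean(x)
  v <- var(x)
  if (mu <= 0) return(0)
  max(0, (v - mu) / mu^2)
}

## Method-of-moments dispersion pooled across the two groups: residual
## variance around the group means, so a true between-group difference
## does not inflate the dispersion. The residual sum of squares is
## divided by df - 2 rather than df (the inverse-bias correction
## E[df/chi2_df] = df/(df-2)): the estimate enters the tail probability
## of the test, where underestimating the variance is what costs
## calibration at few replicates.
mom_dispersion_pooled <- function(xa, xb) {
  mu <- mean(c(xa, xb))
  if (mu <= 0) return(0)
  rss <- sum((xa - mean(xa))^2) + sum((xb - mean(xb))^2)
  v <- rss / max(1L, length(xa) + length(xb) - 4L)
  max(0, (v - mu) / mu^2)
}

## per-group total modelled as NB with moments matched to the sum of the
## per-sample NB(mu = s_j * q, dispersion alpha) variables
group_total_density <- function(k_vec, s, q, alpha) {
  mu <- q * sum(s)
  v <- sum(s * q + alpha * (s * q)^2)
  if (v <= mu + 1e-12) dpois(k_vec, lambda = mu)
  else dnbinom(k_vec, size = mu^2 / (v - mu), mu = mu)
}

#' Negative-binomial exact test for one feature
#'
#' Two-sided exact test on the per-group count totals, conditioning on
#' their sum: the per-group totals are modelled as negative binomial with
#' moments matched to the sums of per-sample NB variables sharing a common
#' normalized mean and dispersion; the p-value is the conditional
#' probability mass of all splits `(a, b)` with `a + b = k_A + k_B` no more
#' probable than the observed one. The fold change is
#' `log2((mean normalized B + 1) / (mean normalized A + 1))`; the
#' pseudo-count enters the fold change only, never the test.
#'
#' @param counts_a,counts_b integer counts per replicate in groups A and B.
#' @param sf_a,sf_b size factors of the corresponding samples.
#' @param dispersion NB dispersion `alpha` (variance `mu + alpha*mu^2`);
#'   when NULL it is estimated by method of moments from the pooled
#'   normalized counts. Negative values are clamped to 0 (Poisson) with a
#'   warning.
#' @return list with `log2fc` and `p`.
#' @export
nb_exact_test <- function(counts_a, counts_b, sf_a, sf_b,
                          dispersion = NULL) {
  stopifnot(length(counts_a) >= 2L, length(counts_b) >= 2L,
            length(sf_a) == length(counts_a),
            length(sf_b) == length(counts_b))
  xa <- counts_a / sf_a
  xb <- counts_b / sf_b
  if (is.null(dispersion)) {
    dispersion <- mom_dispersion_pooled(xa, xb)
  } else if (dispersion < 0) {
    warning("negative dispersion clamped to 0 (Poisson)")
    dispersion <- 0
  }
  log2fc <- log2((mean(xb) + 1) / (mean(xa) + 1))

  q <- mean(c(xa, xb))  # pooled normalized mean under the null
  ka <- sum(counts_a)
  kb <- sum(counts_b)
  k <- ka + kb
  if (q <= 0 || k == 0L) return(list(log2fc = log2fc, p = 1))
  a_vec <- 0:k
  pa <- group_total_density(a_vec, sf_a, q, dispersion)
  pb <- group_total_density(k - a_vec, sf_b, q, dispersion)
  pr <- pa * pb
  tot <- sum(pr)
  if (tot <= 0) return(list(log2fc = log2fc, p = 1))
  p_obs <- pr[ka + 1L]
  p <- sum(pr[pr <= p_obs * (1 + 1e-8)]) / tot
  list(log2fc = log2fc, p = min(1, p))
}

#' Benjamini-Hochberg FDR adjustment
#'
#' Step-up adjustment `q_(i) = min_(j>=i) p_(j) * m / j`, capped at 1, with
#' the original order restored.
#'
#' @param pvalues numeric vector of p-values.
#' @return adjusted values in \[0, 1\].
#' @export
bh_adjust <- function(pvalues) {
  p.adjust(pvalues, method = "BH")
}

parse_comparison <- function(comparison) {
  parts <- strsplit(comparison, "_", fixed = TRUE)[[1]]
  if (length(parts) != 2L || !all(parts %in% CONDITIONS))
    stop("comparison must look like 'H0_H6' over conditions ",
         paste(CONDITIONS, collapse = "/"))
  parts
}

#' Pairwise differential expression over the time course
#'
#' Runs the NB exact test feature-by-feature for each requested pairwise
#' comparison, with size factors estimated once from the full matrix,
#' per-feature method-of-moments dispersion pooled over the two groups, and
#' BH adjustment within each comparison. A feature is differentially
#' expressed when `|log2fc| > lfc_threshold` and `fdr < fdr_threshold`.
#'
#' @param counts matrix (features x samples) of non-negative counts.
#' @param conditions character vector, one of H0/H6/H12/H24 per sample.
#' @param comparisons character vector like `"H0_H6"`; default: all six
#'   ordered pairs of the four time points.
#' @param lfc_threshold absolute log2 fold-change threshold (default 1).
#' @param fdr_threshold FDR threshold (default 0.05).
#' @param size_factors optional size factors; estimated when NULL.
#' @return data.frame with columns `feature_id`, `comparison`, `log2fc`,
#'   `p`, `fdr`, `is_de`.
#' @export
pairwise_de <- function(counts, conditions, comparisons = NULL,
                        lfc_threshold = 1, fdr_threshold = 0.05,
                        size_factors = NULL) {
  stopifnot(ncol(counts) == length(conditions))
  if (is.null(comparisons))
    comparisons <- c("H0_H6", "H0_H12", "H0_H24", "H6_H12", "H6_H24",
                     "H12_H24")
  if (is.null(size_factors)) size_factors <- estimate_size_factors(counts)
  out <- lapply(comparisons, function(cmp) {
    grp <- parse_comparison(cmp)
    ia <- which(conditions == grp[1])
    ib <- which(conditions == grp[2])
    if (length(ia) < 2L || length(ib) < 2L)
      stop("need >= 2 replicates per group for ", cmp)
    res <- lapply(seq_len(nrow(counts)), function(i)
      nb_exact_test(counts[i, ia], counts[i, ib],
                    size_factors[ia], size_factors[ib]))
    p <- vapply(res, `[[`, numeric(1), "p")
    fdr <- bh_adjust(p)
    lfc <- vapply(res, `[[`, numeric(1), "log2fc")
    data.frame(feature_id = rownames(counts), comparison = cmp,
               log2fc = lfc, p = p, fdr = fdr,
               is_de = abs(lfc) > lfc_threshold & fdr < fdr_threshold,
               stringsAsFactors = FALSE)
  })
  do.call(rbind, out)
}

#' Venn region sizes of DE calls across three comparisons
#'
#' @param results data.frame from [pairwise_de()].
#' @param comparisons the three comparisons to intersect (default the
#'   against-control set H0_H6, H0_H12, H0_H24).
#' @return named integer vector: the seven Venn regions keyed by
#'   membership pattern (`"100"` = first comparison only, ... `"111"` =
#'   all three, in the order given), plus `"union"`.
#' @export
de_overlaps <- function(results,
                        comparisons = c("H0_H6", "H0_H12", "H0_H24")) {
  stopifnot(length(comparisons) == 3L)
  sets <- lapply(comparisons, function(cmp)
    unique(results$feature_id[results$comparison == cmp & results$is_de]))
  all_ids <- unique(unlist(sets))
  pattern <- vapply(all_ids, function(id)
    paste(as.integer(vapply(sets, function(s) id %in% s, logical(1))),
          collapse = ""), character(1))
  keys <- c("100", "010", "001", "110", "101", "011", "111")
  out <- setNames(integer(8), c(keys, "union"))
  tb <- table(pattern)
  out[names(tb)] <- as.integer(tb)
  out["union"] <- length(all_ids)
  out
}
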