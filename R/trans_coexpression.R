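## Trans-function prediction: Z-scored condition profiles, soft-threshold
## adjacency and topological overlap, average-linkage module detection
## with a static cut, temporal archetype assignment, and Fisher enrichment
## of functional categories.

#' Canonical temporal archetype multipliers (M1-M6)
#'
#' Mean multipliers over the H0/H6/H12/H24 time course for the six
#' canonical salt-response shapes: M1 gradually induced to 24 h; M2
#' induced at 6-12 h then declining; M3 highest at 0 h; M4 highest at 6 h;
#' M5 and M6 both highest at 0 h and decreasing, M5 dropping much lower
#' than M6 by 24 h.
#'
#' @return 6 x 4 numeric matrix, rows M1-M6, columns H0/H6/H12/H24.
#' @export
salt_archetypes <- function() {
  m <- rbind(M1 = c(1, 2, 4, 8),
             M2 = c(1, 6, 6, 2),
             M3 = c(8, 6, 2, 1),
             M4 = c(4, 8, 2, 1),
             M5 = c(8, 3, 2, 0.5),
             M6 = c(8, 3, 2, 2))
  colnames(m) <- CONDITIONS
  m
}

#' Z-score per-condition expression profiles
#'
#' Averages FPKM within each condition, then centers and scales each
#' feature's four condition means to mean 0, sd 1. Constant profiles
#' become all-zero rows with a warning.
#'
#' @param fpkm FPKM matrix (features x samples).
#' @param conditions condition label per sample (H0/H6/H12/H24).
#' @return matrix (features x 4) of Z-scored condition profiles.
#' @export
zscore_profiles <- function(fpkm, conditions) {
  stopifnot(ncol(fpkm) == length(conditions))
  cond <- intersect(CONDITIONS, unique(conditions))
  if (length(cond) < 3L) stop("need >= 3 conditions")
  means <- vapply(cond, function(cd)
    rowMeans(fpkm[, conditions == cd, drop = FALSE]), numeric(nrow(fpkm)))
  if (nrow(fpkm) == 1L) means <- matrix(means, nrow = 1,
                                        dimnames = list(rownames(fpkm), cond))
  ctr <- means - rowMeans(means)
  s <- apply(means, 1, sd)
  flat <- s == 0 | !is.finite(s)
  if (any(flat)) {
    warning(sum(flat), " constant profile(s) set to zero")
    s[flat] <- 1
  }
  z <- ctr / s
  z[flat, ] <- 0
  z
}

#' Soft-threshold co-expression adjacency
#'
#' `a_ij = |cor(x_i, x_j)|^beta` with zero diagonal. Zero-variance
#' profiles are excluded with a warning before the correlation.
#'
#' @param profiles matrix (features x conditions) of expression profiles.
#' @param beta soft-threshold power (default 6).
#' @return symmetric adjacency matrix over the retained features.
#' @export
soft_adjacency <- function(profiles, beta = 6) {
  stopifnot(beta >= 1, ncol(profiles) >= 3)
  s <- apply(profiles, 1, sd)
  keep <- s > 0 & is.finite(s)
  if (!all(keep)) {
    warning(sum(!keep), " zero-variance profile(s) excluded")
    profiles <- profiles[keep, , drop = FALSE]
  }
  a <- abs(cor(t(profiles)))^beta
  diag(a) <- 0
  a
}

#' Topological overlap matrix
#'
#' `TOM_ij = (sum_u a_iu * a_uj + a_ij) / (min(k_i, k_j) + 1 - a_ij)` with
#' `k_i = sum_u a_iu` and unit diagonal: the adjacency smoothed by shared
#' network neighbourhoods.
#'
#' @param adjacency symmetric adjacency matrix with zero diagonal.
#' @return TOM matrix, symmetric, entries in \[0, 1\], unit diagonal.
#' @export
topological_overlap <- function(adjacency) {
  a <- as.matrix(adjacency)
  k <- rowSums(a)
  num <- a %*% a + a
  den <- outer(k, k, pmin) + 1 - a
  tom <- num / den
  diag(tom) <- 1
  tom
}

#' Detect co-expression modules from a TOM
#'
#' Average-linkage hierarchical clustering on the dissimilarity `1 - TOM`
#' with a static tree cut at `cut_height`; clusters smaller than
#' `min_module_size` are merged into the module whose centroid (mean
#' profile) correlates best with theirs, while any module of sufficient
#' size exists.
#'
#' @param tom TOM matrix from [topological_overlap()].
#' @param profiles matrix of (Z-scored) profiles, same row order as `tom`,
#'   used for centroids.
#' @param min_module_size smallest allowed module (default 10).
#' @param cut_height static cut height on `1 - TOM` (default 0.25), or
#'   `"auto"` to scan heights 0.05-0.95 and use the smallest height that
#'   maximizes the number of clusters of at least `min_module_size`
#'   members (a deterministic surrogate for dendrogram inspection when
#'   the dissimilarity scale of a dataset is not known in advance).
#' @return list of modules, each a list with `module_id`, `members`
#'   (feature ids) and `centroid` (mean profile).
#' @export
detect_modules <- function(tom, profiles, min_module_size = 10,
                           cut_height = 0.25) {
  stopifnot(nrow(tom) == nrow(profiles))
  ids <- rownames(profiles)
  if (is.null(ids)) ids <- paste0("f", seq_len(nrow(profiles)))
  if (nrow(tom) == 1L) {
    return(list(list(module_id = "module_1", members = ids,
                     centroid = profiles[1, ])))
  }
  hc <- hclust(stats::as.dist(1 - tom), method = "average")
  if (identical(cut_height, "auto")) {
    heights <- seq(0.05, 0.95, by = 0.05)
    n_big <- vapply(heights, function(h)
      sum(table(cutree(hc, h = h)) >= min_module_size), integer(1))
    cut_height <- heights[which.max(n_big)]
  }
  grp <- cutree(hc, h = cut_height)
  members <- split(ids, grp)
  centroid_of <- function(m)
    colMeans(profiles[match(m, ids), , drop = FALSE])
  repeat {
    sizes <- lengths(members)
    small <- which(sizes < min_module_size)
    big <- which(sizes >= min_module_size)
    if (length(small) == 0L || length(big) == 0L || length(members) == 1L)
      break
    i <- small[which.min(sizes[small])]
    ci <- centroid_of(members[[i]])
    cors <- vapply(big, function(j)
      cor(ci, centroid_of(members[[j]])), numeric(1))
    j <- big[which.max(cors)]
    members[[j]] <- c(members[[j]], members[[i]])
    members[[i]] <- NULL
  }
  ## deterministic order: by first member's position in the input
  ord <- order(vapply(members, function(m) min(match(m, ids)), numeric(1)))
  members <- members[ord]
  lapply(seq_along(members), function(i)
    list(module_id = paste0("module_", i),
         members = unname(members[[i]]),
         centroid = centroid_of(members[[i]])))
}

#' Assign temporal archetypes to modules
#'
#' Labels each module with the archetype (M1-M6) whose Z-scored reference
#' profile correlates best (Pearson) with the module centroid; modules
#' with maximal correlation below `min_cor` are left `"unassigned"`.
#'
#' @param modules list from [detect_modules()].
#' @param multipliers archetype mean-multiplier matrix
#'   (default [salt_archetypes()]).
#' @param min_cor minimal correlation to accept a label (default 0.7).
#' @return the modules with an `archetype` element added to each.
#' @export
assign_archetypes <- function(modules, multipliers = salt_archetypes(),
                              min_cor = 0.7) {
  refs <- t(apply(multipliers, 1, function(x) (x - mean(x)) / sd(x)))
  lapply(modules, function(mod) {
    cors <- apply(refs, 1, function(r) cor(mod$centroid, r))
    best <- which.max(cors)
    mod$archetype <- if (cors[best] >= min_cor) rownames(refs)[best]
                     else "unassigned"
    mod$archetype_cor <- unname(cors[best])
    mod
  })
}

#' Functional-category enrichment of a module (Fisher's exact test)
#'
#' One-sided (over-representation) Fisher's exact p-value for each
#' category, equal to the hypergeometric upper tail
#' `P(X >= k)` with `X ~ Hypergeometric(N, n, K)`, followed by BH
#' adjustment across the categories tested within the module.
#'
#' @param module_members feature ids in the module.
#' @param categories named character vector: category per background
#'   feature (the background is all features carrying a category).
#' @param fdr_threshold significance threshold on the adjusted p
#'   (default 0.05).
#' @return data.frame with columns `category`, `k`, `K`, `n`, `N`, `p`,
#'   `fdr`, `significant`, ordered by p.
#' @export
enrich_categories <- function(module_members, categories,
                              fdr_threshold = 0.05) {
  bg <- names(categories)
  N <- length(bg)
  in_mod <- bg %in% module_members
  K <- sum(in_mod)
  if (K > N) stop("module larger than background")
  cats <- sort(unique(categories))
  res <- lapply(cats, function(cat) {
    hit <- categories == cat
    n <- sum(hit)
    k <- sum(hit & in_mod)
    if (k > n) stop("inconsistent background for category ", cat)
    p <- phyper(k - 1, n, N - n, K, lower.tail = FALSE)
    data.frame(category = cat, k = k, K = K, n = n, N = N, p = p,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, res)
  out$fdr <- bh_adjust(out$p)
  out$significant <- out$fdr < fdr_threshold
  out[order(out$p), , drop = FALSE]
}
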