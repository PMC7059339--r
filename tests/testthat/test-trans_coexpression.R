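test_that("Z-scored profiles have mean 0 and sd 1 per feature", {
  fpkm <- matrix(rep(c(1, 2, 3, 4), each = 3), 1, 12, byrow = TRUE,
                 dimnames = list("f1", NULL))
  conds <- rep(c("H0", "H6", "H12", "H24"), each = 3)
  z <- zscore_profiles(fpkm, conds)
  expect_equal(mean(z), 0, tolerance = 1e-12)
  expect_equal(sd(z), 1, tolerance = 1e-12)

  const <- matrix(5, 1, 12, dimnames = list("f1", NULL))
  expect_warning(zc <- zscore_profiles(const, conds), "constant")
  expect_equal(unname(zc[1, ]), rep(0, 4))

  set.seed(51)
  m <- matrix(rlnorm(240), 20, 12,
              dimnames = list(paste0("f", 1:20), NULL))
  z <- zscore_profiles(m, conds)
  expect_equal(unname(rowMeans(z)), rep(0, 20), tolerance = 1e-12)
  expect_equal(unname(apply(z, 1, sd)), rep(1, 20), tolerance = 1e-12)
})

test_that("soft adjacency and TOM handle degenerate geometries", {
  # two identical profiles: adjacency 1, TOM 1
  p <- rbind(a = c(1, 2, 3, 4), b = c(1, 2, 3, 4))
  a <- soft_adjacency(p)
  expect_equal(a[1, 2], 1)
  expect_equal(diag(a), c(a = 0, b = 0))
  expect_equal(topological_overlap(a)[1, 2], 1)

  # orthogonal profiles in a 2-feature system: adjacency 0, TOM 0
  p2 <- rbind(a = c(1, -1, 1, -1), b = c(1, 1, -1, -1))
  a2 <- soft_adjacency(p2)
  expect_equal(a2[1, 2], 0, tolerance = 1e-12)
  expect_equal(topological_overlap(a2)[1, 2], 0, tolerance = 1e-12)

  expect_warning(soft_adjacency(rbind(a = c(1, 2, 3, 4),
                                      b = c(2, 2, 2, 2))),
                 "zero-variance")
})

test_that("TOM equals the triple-loop oracle and stays in [0, 1]", {
  set.seed(52)
  for (rep in 1:5) {
    p <- matrix(rnorm(80), 20, 4)
    a <- soft_adjacency(p)
    tom <- topological_overlap(a)
    n <- nrow(a)
    oracle <- matrix(0, n, n)
    for (i in 1:n) for (j in 1:n) {
      if (i == j) { oracle[i, j] <- 1; next }
      l <- 0
      for (u in 1:n) l <- l + a[i, u] * a[u, j]
      ki <- sum(a[i, ]); kj <- sum(a[j, ])
      oracle[i, j] <- (l + a[i, j]) / (min(ki, kj) + 1 - a[i, j])
    }
    expect_equal(tom, oracle, tolerance = 1e-10, ignore_attr = TRUE)
    expect_equal(tom, t(tom), tolerance = 1e-12)
    expect_true(all(tom >= 0 & tom <= 1 + 1e-12))
  }
})

test_that("module detection recovers planted blocks", {
  set.seed(53)
  centers <- rbind(c(1, 1, -1, -1), c(1, -1, 1, -1), c(1, -1, -1, 1))
  p <- do.call(rbind, lapply(1:3, function(b)
    t(sapply(1:12, function(i) centers[b, ] + rnorm(4, 0, 0.12)))))
  rownames(p) <- paste0("f", 1:36)
  tom <- topological_overlap(soft_adjacency(p))
  mods <- detect_modules(tom, p, min_module_size = 10, cut_height = 0.25)
  expect_length(mods, 3)
  truth_block <- rep(1:3, each = 12)
  for (m in mods) {
    blocks <- truth_block[match(m$members, rownames(p))]
    expect_length(unique(blocks), 1)  # each module is one planted block
  }

  # all-identical profiles collapse to one module
  p1 <- matrix(rep(c(1, 2, 3, 4), each = 12), 12, 4)
  rownames(p1) <- paste0("g", 1:12)
  tom1 <- topological_overlap(soft_adjacency(p1))
  expect_length(detect_modules(tom1, p1), 1)
})

test_that("module membership is invariant to feature order", {
  set.seed(54)
  centers <- rbind(c(1, 1, -1, -1), c(1, -1, 1, -1))
  p <- do.call(rbind, lapply(1:2, function(b)
    t(sapply(1:12, function(i) centers[b, ] + rnorm(4, 0, 0.1)))))
  rownames(p) <- paste0("f", 1:24)
  tom <- topological_overlap(soft_adjacency(p))
  mods <- detect_modules(tom, p)
  perm <- sample(24)
  mods2 <- detect_modules(tom[perm, perm], p[perm, ])
  sets1 <- lapply(mods, function(m) sort(m$members))
  sets2 <- lapply(mods2, function(m) sort(m$members))
  expect_setequal(vapply(sets1, paste, "", collapse = ","),
                  vapply(sets2, paste, "", collapse = ","))
})

test_that("archetype assignment matches references and thresholds", {
  refs <- salt_archetypes()
  zref <- t(apply(refs, 1, function(x) (x - mean(x)) / sd(x)))
  mods <- lapply(rownames(refs), function(a)
    list(module_id = a, members = "x", centroid = zref[a, ]))
  lab <- assign_archetypes(mods)
  expect_identical(vapply(lab, `[[`, "", "archetype"), rownames(refs))

  # negated M1 must not be labelled M1 (correlation -1)
  neg <- list(list(module_id = "n", members = "x",
                   centroid = -zref["M1", ]))
  expect_false(assign_archetypes(neg)[[1]]$archetype == "M1")

  # a flat centroid correlates with nothing above 0.7
  flat <- list(list(module_id = "f", members = "x",
                    centroid = c(0.1, -0.1, 0.1, -0.1)))
  got <- assign_archetypes(flat)[[1]]$archetype
  expect_true(got %in% c("unassigned", "M2"))
})

test_that("planted archetype modules are labelled 100% correctly", {
  for (seed in 1:3) {
    ds <- small_dataset(seed)
    lens <- setNames(ds$transcripts$spliced_length, ds$transcripts$id)
    fpkm <- compute_fpkm(ds$counts, lens[rownames(ds$counts)])
    de <- ds$truth$de
    z <- zscore_profiles(fpkm[de$feature_id, ], ds$conditions)
    mods <- lapply(split(de$feature_id, de$archetype), function(ids)
      list(module_id = "m", members = ids,
           centroid = colMeans(z[ids, , drop = FALSE])))
    lab <- assign_archetypes(mods)
    expect_identical(unname(vapply(lab, `[[`, "", "archetype")),
                     names(mods))
  }
})

test_that("Fisher enrichment equals the hypergeometric tail", {
  # worked example: module of 10 with 5 hits in a category of 10 within
  # a background of 100
  bg <- setNames(c(rep("X", 10), rep("other", 90)), paste0("f", 1:100))
  module <- c(paste0("f", 1:5), paste0("f", 51:55))
  er <- enrich_categories(module, bg)
  x <- er[er$category == "X", ]
  expect_equal(x$k, 5)
  # oracle: explicit choose-sum upper tail
  oracle <- sum(vapply(5:10, function(i)
    choose(10, i) * choose(90, 10 - i), numeric(1))) / choose(100, 10)
  expect_equal(x$p, oracle, tolerance = 1e-12)

  # category absent from the module -> p = 1
  er2 <- enrich_categories(paste0("f", 91:100), bg)
  expect_equal(er2$p[er2$category == "X"], 1)

  # module equal to background -> no enrichment possible
  er3 <- enrich_categories(names(bg), bg)
  expect_true(all(er3$p == 1))
})

test_that("planted category coupling is recovered by enrichment", {
  # through the true (planted) modules the signature category of each
  # archetype must be significant; through detected modules (auto cut)
  # at least half must be, since mutually correlated archetypes merge
  for (seed in 1:2) {
    ds <- full_dataset(seed)
    truth <- ds$truth
    lens <- setNames(ds$transcripts$spliced_length, ds$transcripts$id)
    fpkm <- compute_fpkm(ds$counts, lens[rownames(ds$counts)])
    z <- zscore_profiles(fpkm[truth$de$feature_id, ], ds$conditions)
    cats <- setNames(ds$annotation$genes$category,
                     truth$mrna_of_gene[ds$annotation$genes$gene_id])
    bg <- cats[truth$de$feature_id[truth$de$kind == "coding"]]
    sig_of <- truth$archetype_category

    hits_true <- 0
    for (A in names(sig_of)) {
      members <- truth$de$feature_id[truth$de$archetype == A]
      er <- enrich_categories(members, bg)
      hits_true <- hits_true +
        (sig_of[[A]] %in% er$category[er$significant])
    }
    expect_equal(hits_true, length(sig_of))

    tom <- topological_overlap(soft_adjacency(z))
    mods <- detect_modules(tom, z, cut_height = "auto")
    hits_det <- 0
    for (A in names(sig_of)) {
      lnc_A <- truth$de$feature_id[truth$de$kind == "lncrna" &
                                     truth$de$archetype == A]
      if (!length(lnc_A)) next
      in_mod <- vapply(mods, function(m) sum(lnc_A %in% m$members),
                       numeric(1))
      er <- enrich_categories(mods[[which.max(in_mod)]]$members, bg)
      hits_det <- hits_det +
        (sig_of[[A]] %in% er$category[er$significant])
    }
    expect_gte(hits_det, length(sig_of) / 2)
  }
})
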