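make_profiles <- function(ratios) {
  structure(list(gene_ids = rownames(ratios), ratios = ratios,
                 log_ratios = log2(ratios)),
            class = "expression_profiles")
}

test_that("profile variance is the population variance in the chosen space", {
  r <- rbind(flat = c(1, 1, 1, 1),
             glod4 = c(2.28, 3.52, 4.24, 3.26))
  colnames(r) <- c("r3", "r10", "r30", "r60")
  v <- profile_variance(make_profiles(r), space = "ratio")
  expect_equal(unname(v["flat"]), 0)
  expect_equal(unname(v["glod4"]), 0.492875)   # mean 3.325, mean sq. dev.
  vlog <- profile_variance(make_profiles(r), space = "log_ratio")
  expect_equal(unname(vlog["flat"]), 0)
  expect_gt(unname(vlog["glod4"]), 0)
})

test_that("the variance filter keeps the top fraction deterministically", {
  r <- matrix(2^seq(0.1, 3.2, length.out = 32), 8, 4)
  rownames(r) <- sprintf("g%02d", 1:8)
  p <- make_profiles(r)
  sel <- select_high_variance(p, 0.75)
  expect_length(sel$retained, 6L)             # ceil(0.75 * 8)
  expect_length(sel$excluded, 2L)
  expect_gte(min(sel$variances[sel$retained]),
             max(sel$variances[sel$excluded]))
  expect_identical(select_high_variance(p, 1)$excluded, character(0))

  # variances (0, 1, 2, 3): the three non-zero ones are retained
  r2 <- rbind(a = c(1, 1, 1, 1), b = 2^c(0, 1, 1, 0) , c = 2^c(0, 2, 2, 0),
              d = 2^c(0, 2.45, 2.45, 0))
  sel2 <- select_high_variance(make_profiles(r2), 0.75)
  expect_setequal(sel2$retained, c("b", "c", "d"))
})

test_that("fuzzy k-means degenerates correctly at k = 1 and on duplicates", {
  set.seed(5)
  x <- matrix(rnorm(40), 10, 4)
  rownames(x) <- sprintf("g%02d", 1:10)
  fit <- fuzzy_kmeans(x, k = 1, seed = 1)
  expect_true(all(fit$membership == 1))

  xd <- rbind(x, x)
  rownames(xd) <- sprintf("g%02d", 1:20)
  fitd <- fuzzy_kmeans(xd, k = 3, seed = 2)
  expect_equal(unname(fitd$membership[1:10, ]),
               unname(fitd$membership[11:20, ]), tolerance = 1e-8)
  expect_error(fuzzy_kmeans(x, k = 11), "exceeds")
})

test_that("two anti-correlated archetype groups separate cleanly at k = 2", {
  up <- c(0, 2, 2, 0)    # hump-like log profile
  dn <- c(2, 0, 0, 2)    # its inversion; Pearson correlation is negative
  x <- rbind(matrix(rep(up, 10), 10, 4, byrow = TRUE) +
               matrix(rnorm(40, 0, 0.05), 10, 4),
             matrix(rep(dn, 10), 10, 4, byrow = TRUE) +
               matrix(rnorm(40, 0, 0.05), 10, 4))
  rownames(x) <- sprintf("g%02d", 1:20)
  fit <- fuzzy_kmeans(x, k = 2, seed = 3)
  own <- apply(fit$membership, 1L, max)
  hard <- apply(fit$membership, 1L, which.max)
  expect_true(all(own > 0.95))
  expect_length(unique(hard[1:10]), 1L)
  expect_length(unique(hard[11:20]), 1L)
  expect_false(hard[1] == hard[20])
})

test_that("membership rows sum to 1 and the objective never increases", {
  for (seed in 1:50) {
    set.seed(seed)
    x <- matrix(rnorm(30 * 4), 30, 4)
    rownames(x) <- sprintf("g%02d", 1:30)
    fit <- fuzzy_kmeans(x, k = 5, seed = seed)
    expect_equal(unname(rowSums(fit$membership)), rep(1, 30),
                 tolerance = 1e-9)
    expect_true(all(diff(fit$objective) <= 1e-10))
  }
})

test_that("the Euclidean variant agrees with an independent implementation", {
  skip_if_not_installed("e1071")
  set.seed(8)
  x <- rbind(matrix(rnorm(40, 0, 0.2), 10, 4),
             matrix(rnorm(40, 5, 0.2), 10, 4))
  rownames(x) <- sprintf("g%02d", 1:20)
  fit <- fuzzy_kmeans(x, k = 2, distance = "euclidean", seed = 1)
  ref <- e1071::cmeans(x, centers = 2, m = 2)
  hard_fit <- apply(fit$membership, 1L, which.max)
  hard_ref <- ref$cluster
  # same partition up to label permutation
  expect_equal(mclust::adjustedRandIndex(hard_fit, hard_ref), 1)
  # membership magnitudes agree after aligning labels
  perm <- if (hard_fit[1] == hard_ref[1]) 1:2 else 2:1
  expect_equal(unname(fit$membership[, perm]), unname(ref$membership),
               tolerance = 1e-3)
})

test_that("a profile at zero distance from a centroid gets membership 1", {
  x <- rbind(a = c(0, 1, 2, 3), b = c(3, 2, 1, 0), c = c(0, 1, 2, 3))
  fit <- fuzzy_kmeans(x, k = 2, seed = 1, max_iter = 50)
  # profiles a and c are identical; after convergence one centroid sits on
  # them exactly (zero correlation distance)
  expect_equal(unname(apply(fit$membership, 1L, max)), rep(1, 3),
               tolerance = 1e-6)
})

test_that("the membership cutoff matches enumeration and its worked example", {
  u <- rbind(c(0.7, 0.3), c(0.6, 0.4))
  expect_equal(select_membership_cutoff(u), 0.6)
  onehot <- diag(3)
  expect_equal(select_membership_cutoff(onehot), 1)
  expect_warning(cut_unif <- select_membership_cutoff(matrix(0.25, 4, 4)),
                 "mean cluster count")
  expect_equal(cut_unif, 0.25)

  set.seed(11)
  for (i in 1:200) {
    u <- random_membership(sample(2:8, 1), sample(2:5, 1))
    expect_equal(select_membership_cutoff(u), cutoff_oracle(u))
  }
})

test_that("correlation linkage orders merges by similarity", {
  cen <- rbind(A = c(0, 1, 2, 3), B = c(0, 1, 2, 3))
  lk <- correlation_linkage(cen)
  expect_equal(lk$similarity, 1)

  expect_equal(nrow(correlation_linkage(cen[1, , drop = FALSE])$merge), 0L)
  expect_error(correlation_linkage(rbind(A = c(1, 1, 1, 1))), "A")

  # A and B nearly parallel, C weakly related to both
  cen3 <- rbind(A = c(0, 1, 2, 3), B = c(0, 1.1, 1.9, 3.2),
                C = c(2, 0, 3, 1))
  cc <- cor(t(cen3))
  lk3 <- correlation_linkage(cen3)
  expect_equal(lk3$similarity[1], cc["A", "B"])
  expect_equal(lk3$similarity[2], max(cc["A", "C"], cc["B", "C"]))
  expect_true(all(diff(lk3$similarity) <= 0))

  groups <- merge_clusters(lk3, merge_r = 0.9)
  expect_true(same_partition(groups, list(c("A", "B"), "C")))
  expect_length(merge_clusters(lk3, merge_r = 0.999), 3L)
  expect_length(merge_clusters(correlation_linkage(
    rbind(A = 1:4, B = 1:4, C = 1:4)), 0.9), 1L)
})

test_that("tree merging equals connected components over the r-graph", {
  set.seed(21)
  for (i in 1:60) {
    q <- sample(2:8, 1)
    cen <- matrix(rnorm(q * 4), q, 4)
    rownames(cen) <- sprintf("K%d", seq_len(q))
    r <- sample(c(-0.5, 0, 0.5, 0.9, 0.95), 1)
    got <- merge_clusters(correlation_linkage(cen), merge_r = r)
    expect_true(same_partition(got, components_oracle(cen, r)),
                info = sprintf("iteration %d, merge_r %.2f", i, r))
  }
})

test_that("final assignment is a thresholded argmax with an outlier bucket", {
  means <- rbind(M01 = c(0, 2, 2, 0), M02 = c(2, 0, 0, 2))
  x <- rbind(hit = c(0, 2, 2, 0),              # equals a mean: r = 1
             far = c(0, 1, -3, 1),             # correlates poorly with both
             flat = c(1, 1, 1, 1))             # zero variance
  cs <- assign_genes(x, means, assign_r = 0.85)
  expect_equal(cs$clusters[[1]]$members, "hit")
  expect_setequal(cs$outliers, c("far", "flat"))
  # partition: members and outliers cover the input exactly once
  all_ids <- c(unlist(lapply(cs$clusters, `[[`, "members")), cs$outliers)
  expect_setequal(all_ids, rownames(x))
  expect_equal(anyDuplicated(all_ids), 0L)
})

test_that("ties at maximal correlation go to the lower cluster id", {
  means <- rbind(M01 = c(0, 1, 2, 3), M02 = c(1, 2, 3, 4))  # r = 1 pair
  x <- rbind(g = c(0.5, 1.5, 2.5, 3.5))
  expect_message(cs <- assign_genes(x, means, assign_r = 0.85), "tied")
  expect_equal(cs$clusters[[1]]$cluster_id, "M01")
  expect_equal(cs$clusters[[1]]$members, "g")
})

test_that("raising the assignment threshold never assigns more genes", {
  set.seed(31)
  means <- rbind(M01 = c(0, 2, 1, 0), M02 = c(2, 0, 0, 2))
  x <- matrix(rnorm(200), 50, 4)
  rownames(x) <- sprintf("g%02d", 1:50)
  n_assigned <- vapply(c(0.2, 0.5, 0.7, 0.85, 0.95), function(r) {
    cs <- assign_genes(x, means, assign_r = r)
    sum(vapply(cs$clusters, function(cl) length(cl$members), integer(1)))
  }, numeric(1))
  expect_true(all(diff(n_assigned) <= 0))
})

test_that("small separable inputs match the exhaustive hard-partition optimum", {
  # zero-noise profiles drawn from well-separated archetypes; the fuzzy
  # pipeline's final hard partition must equal the brute-force optimum of
  # the hard k-partition objective sum(1 - cor(x, cluster mean))
  brute_best <- function(x, k) {
    n <- nrow(x)
    best <- NULL; best_obj <- Inf
    grid <- do.call(expand.grid, rep(list(seq_len(k)), n))
    for (i in seq_len(nrow(grid))) {
      asg <- as.integer(grid[i, ])
      if (length(unique(asg)) < k) next
      obj <- 0
      for (cc in seq_len(k)) {
        mem <- which(asg == cc)
        mu <- colMeans(x[mem, , drop = FALSE])
        if (var(mu) == 0) { obj <- Inf; break }
        obj <- obj + sum(1 - cor(t(x[mem, , drop = FALSE]), mu))
      }
      if (obj < best_obj) { best_obj <- obj; best <- asg }
    }
    best
  }
  arch <- rbind(c(0, 3, 3, 0), c(3, 0, 0, 3), c(0, 0, 3, 3))
  for (k in 2:3) {
    reps <- if (k == 2) 5L else 3L
    x <- arch[rep(seq_len(k), each = reps), ] +
      matrix(rnorm(4 * k * reps, 0, 1e-3), k * reps, 4)
    rownames(x) <- sprintf("g%02d", seq_len(nrow(x)))
    fit <- fuzzy_kmeans(x, k = k, seed = 5)
    cut <- select_membership_cutoff(fit$membership)
    members <- apply(fit$membership >= cut, 2L, function(col) {
      rownames(fit$membership)[col]
    }, simplify = FALSE)
    means <- do.call(rbind, lapply(members, function(g) {
      colMeans(x[g, , drop = FALSE])
    }))
    groups <- merge_clusters(correlation_linkage(means), 0.9)
    merged <- do.call(rbind, lapply(groups, function(ids) {
      colMeans(x[unique(unlist(members[ids])), , drop = FALSE])
    }))
    rownames(merged) <- sprintf("M%02d", seq_len(nrow(merged)))
    cs <- assign_genes(x, merged, assign_r = 0.85)
    got <- lapply(cs$clusters, `[[`, "members")
    want <- split(rownames(x), brute_best(x, k))
    expect_true(same_partition(got, want), info = sprintf("k = %d", k))
    expect_length(cs$outliers, 0L)
  }
})
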