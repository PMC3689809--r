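#' Profile variance
#'
#' Population variance (denominator 4) of a gene's four-element fold-ratio
#' profile, in ratio or log2-ratio space. Used to rank genes before
#' clustering: only the highest-variance fraction enters fuzzy k-means.
#'
#' @param profiles An `expression_profiles` object.
#' @param space `"log_ratio"` (default) or `"ratio"`.
#' @return Named numeric vector of variances, one per gene.
#' @export
profile_variance <- function(profiles, space = c("log_ratio", "ratio")) {
  space <- match.arg(space)
  x <- if (space == "ratio") profiles$ratios else profiles$log_ratios
  mu <- rowMeans(x)
  setNames(rowMeans((x - mu)^2), profiles$gene_ids)
}

#' Select the highest-variance profiles
#'
#' Retains the `ceiling(fraction * n)` profiles with the largest variance.
#' Ties at the boundary are broken by lexicographic gene identifier so runs
#' are deterministic.
#'
#' @param profiles An `expression_profiles` object.
#' @param fraction Fraction to retain, in (0, 1].
#' @param space Variance space, as in [profile_variance()].
#' @return List with character vectors `retained` and `excluded` (gene ids)
#'   and the named `variances`.
#' @export
select_high_variance <- function(profiles, fraction = 0.75,
                                 space = c("log_ratio", "ratio")) {
  stopifnot(fraction > 0, fraction <= 1, length(profiles$gene_ids) > 0)
  v <- profile_variance(profiles, space = match.arg(space))
  n_keep <- as.integer(ceiling(fraction * length(v)))
  ord <- order(-v, names(v), method = "radix")
  ids <- names(v)[ord]
  list(retained = ids[seq_len(n_keep)],
       excluded = if (n_keep < length(ids)) ids[(n_keep + 1L):length(ids)]
                  else character(0),
       variances = v)
}

# Centre each row and scale to unit norm; rows must have non-zero variance.
# In this representation 1 - Pearson(x, y) = 1 - crossprod(zx, zy).
unit_rows <- function(x) {
  z <- x - rowMeans(x)
  nrm <- sqrt(rowSums(z^2))
  if (any(nrm == 0)) {
    stop("zero-variance profile(s): ",
         paste(head(rownames(x)[nrm == 0], 5L), collapse = ", "))
  }
  z / nrm
}

#' Fuzzy k-means clustering of expression profiles
#'
#' Probabilistic clustering in which every profile holds a membership in
#' every cluster (rows of the membership matrix sum to 1). The algorithm
#' alternates the classical fuzzy membership update
#' \deqn{u_{gc} = 1 / \sum_j (d_{gc}/d_{gj})^{1/(m-1)}}
#' with a centroid update using weights \eqn{u^m}, until the objective
#' \eqn{\sum_{g,c} u_{gc}^m d_{gc}} changes by less than `tol`. With the
#' default correlation distance (\eqn{d = 1 - } Pearson), profiles are
#' represented as centred unit vectors and the centroid update is the
#' normalised weighted mean of those unit vectors — the exact minimiser of
#' the objective for a fixed membership, so the objective trace is
#' non-increasing. The Euclidean variant uses squared distance and the
#' weighted-mean centroid.
#'
#' Initial centroids are `k` distinct profiles sampled without replacement
#' under `seed`; if fewer distinct profiles exist than `k`, `k` is lowered
#' with a warning. A collapsed (empty) centroid is re-seeded from the
#' worst-fit profile.
#'
#' @param x Numeric matrix of profiles (genes x time points) in the chosen
#'   clustering space, with row names.
#' @param k Number of clusters (>= 1, <= number of profiles).
#' @param m Fuzziness exponent, > 1.
#' @param distance `"one_minus_pearson"` (default) or `"euclidean"`.
#' @param seed Integer seed for centroid initialisation.
#' @param tol Convergence tolerance on the objective.
#' @param max_iter Iteration cap.
#' @return List of class `fuzzy_kmeans`: `membership` (genes x clusters,
#'   rows sum to 1), `centroids` (k x ncol(x), the weighted mean profile of
#'   each cluster in the input space), `objective` (per-iteration trace),
#'   `iterations`, `k`, `distance`.
#' @export
fuzzy_kmeans <- function(x, k, m = 2, distance = c("one_minus_pearson",
                                                   "euclidean"),
                         seed = 1L, tol = 1e-8, max_iter = 300L) {
  distance <- match.arg(distance)
  stopifnot(is.matrix(x), m > 1, k >= 1)
  n <- nrow(x)
  if (k > n) stop("k (", k, ") exceeds the number of profiles (", n, ")")
  if (is.null(rownames(x))) rownames(x) <- paste0("g", seq_len(n))

  z <- if (distance == "one_minus_pearson") unit_rows(x) else x
  dist_to <- function(centres) {
    # n x k matrix of distances in the working space
    if (distance == "one_minus_pearson") {
      pmax(1 - z %*% t(centres), 0)
    } else {
      # squared Euclidean
      pmax(outer(rowSums(z^2), rep(1, nrow(centres))) -
             2 * z %*% t(centres) +
             outer(rep(1, n), rowSums(centres^2)), 0)
    }
  }
  normalize_centre <- function(cmat) {
    if (distance != "one_minus_pearson") return(cmat)
    nrm <- sqrt(rowSums(cmat^2))
    nrm[nrm == 0] <- 1
    cmat / nrm
  }

  # initialisation: k distinct profiles, sampled without replacement
  distinct <- which(!duplicated(z))
  if (length(distinct) < k) {
    warning("only ", length(distinct), " distinct profile(s); lowering k from ",
            k, " to ", length(distinct))
    k <- length(distinct)
  }
  set.seed(seed)
  init <- sample(distinct, k)
  centres <- normalize_centre(z[init, , drop = FALSE])

  update_membership <- function(d) {
    u <- matrix(0, n, k)
    zero <- d < 1e-12
    has_zero <- rowSums(zero) > 0
    if (any(has_zero)) {
      # a profile coinciding with a centroid belongs there outright
      first0 <- apply(zero[has_zero, , drop = FALSE], 1L, which.max)
      u[cbind(which(has_zero), first0)] <- 1
    }
    reg <- !has_zero
    if (any(reg)) {
      w <- d[reg, , drop = FALSE] ^ (-1 / (m - 1))
      u[reg, ] <- w / rowSums(w)
    }
    u
  }

  obj_trace <- numeric(0)
  prev <- Inf
  u <- NULL
  for (it in seq_len(max_iter)) {
    d <- dist_to(centres)
    u <- update_membership(d)
    w <- u ^ m
    # guard against collapsed clusters before the centroid update
    col_mass <- colSums(w)
    if (any(col_mass < 1e-12)) {
      worst <- which.max(apply(d, 1L, min))
      for (cc in which(col_mass < 1e-12)) {
        message("re-seeding empty cluster ", cc, " from profile ",
                rownames(x)[worst])
        centres[cc, ] <- normalize_centre(z[worst, , drop = FALSE])
      }
      next
    }
    obj <- sum(w * d)
    obj_trace <- c(obj_trace, obj)
    if (is.finite(prev) && abs(prev - obj) < tol) break
    prev <- obj
    centres <- normalize_centre((t(w) %*% z) / col_mass)
  }

  cluster_ids <- sprintf("C%02d", seq_len(k))
  dimnames(u) <- list(rownames(x), cluster_ids)
  # report centroids as weighted mean profiles in the input space
  w <- u ^ m
  centroids <- (t(w) %*% x) / colSums(w)
  rownames(centroids) <- cluster_ids
  structure(list(membership = u, centroids = centroids,
                 objective = obj_trace, iterations = it, k = k,
                 distance = distance),
            class = "fuzzy_kmeans")
}

#' @export
print.fuzzy_kmeans <- function(x, ...) {
  cat("fuzzy k-means: ", nrow(x$membership), " profiles, k = ", x$k,
      ", ", x$iterations, " iteration(s), objective ",
      format(x$objective[length(x$objective)], digits = 6), "\n", sep = "")
  invisible(x)
}

#' Adaptive membership-probability cutoff
#'
#' Chooses the membership threshold such that the *average* profile is
#' assigned to one cluster: over the sorted distinct membership values, the
#' candidate minimising `|mean number of clusters with membership >= t| - 1`
#' is returned; ties go to the smaller threshold, preserving the option of
#' multi-cluster membership.
#'
#' @param u Membership matrix (rows sum to 1).
#' @return The selected cutoff (a value that occurs in `u`).
#' @export
select_membership_cutoff <- function(u) {
  stopifnot(is.matrix(u), all(u >= 0), all(u <= 1))
  n <- nrow(u)
  vals <- sort(unique(as.vector(u)))
  # the mean per-gene cluster count at threshold t is the number of
  # (gene, cluster) entries >= t divided by the number of genes
  cnt <- tabulate(match(as.vector(u), vals), nbins = length(vals))
  n_ge <- rev(cumsum(rev(cnt)))
  mean_count <- n_ge / n
  best <- which.min(abs(mean_count - 1))  # which.min takes the first = smallest t
  if (abs(mean_count[best] - 1) > 0.5) {
    warning("no cutoff brings the mean cluster count near 1 (best: ",
            format(mean_count[best], digits = 3), ")")
  }
  vals[best]
}

#' Single-linkage tree over cluster mean profiles
#'
#' Builds the agglomerative single-linkage tree using similarity = Pearson
#' correlation between mean profiles (most similar pair merged first),
#' implemented as [stats::hclust()] on the distance `1 - r`.
#'
#' @param centroids Numeric matrix (clusters x time points) of mean
#'   profiles with row names; every row needs non-zero variance.
#' @return List of class `correlation_linkage` with `labels`, `merge`
#'   (hclust-style merge matrix) and `similarity` (Pearson r of each
#'   merge, non-increasing). A single centroid yields an empty tree.
#' @export
correlation_linkage <- function(centroids) {
  stopifnot(is.matrix(centroids), nrow(centroids) >= 1)
  if (is.null(rownames(centroids))) {
    rownames(centroids) <- sprintf("C%02d", seq_len(nrow(centroids)))
  }
  v <- apply(centroids, 1L, function(r) var(r) * (length(r) - 1) / length(r))
  if (any(v == 0)) {
    stop("Pearson correlation undefined for zero-variance centroid(s): ",
         paste(rownames(centroids)[v == 0], collapse = ", "))
  }
  if (nrow(centroids) == 1L) {
    return(structure(list(labels = rownames(centroids),
                          merge = matrix(integer(0), 0, 2),
                          similarity = numeric(0)),
                     class = "correlation_linkage"))
  }
  d <- as.dist(1 - cor(t(centroids)))
  hc <- hclust(d, method = "single")
  structure(list(labels = rownames(centroids), merge = hc$merge,
                 similarity = 1 - hc$height),
            class = "correlation_linkage")
}

#' Cut the linkage tree at a correlation threshold
#'
#' Keeps every merge whose similarity strictly exceeds `merge_r` and
#' returns the resulting groups of original clusters. Under single linkage
#' these are exactly the connected components of the graph joining cluster
#' pairs with Pearson correlation > `merge_r`.
#'
#' @param linkage A [correlation_linkage()] tree.
#' @param merge_r Correlation threshold (strict >).
#' @return List of character vectors; each vector holds the cluster labels
#'   of one merged group. Groups are ordered by their first member.
#' @export
merge_clusters <- function(linkage, merge_r = 0.9) {
  stopifnot(inherits(linkage, "correlation_linkage"))
  q <- length(linkage$labels)
  comp <- seq_len(q)                       # union-find over original clusters
  find <- function(i) { while (comp[i] != i) i <- comp[i]; i }
  node_rep <- integer(nrow(linkage$merge)) # representative leaf per tree node
  for (s in seq_len(nrow(linkage$merge))) {
    a <- linkage$merge[s, 1L]
    b <- linkage$merge[s, 2L]
    ra <- if (a < 0) -a else node_rep[a]
    rb <- if (b < 0) -b else node_rep[b]
    node_rep[s] <- ra
    if (linkage$similarity[s] > merge_r) {
      comp[find(rb)] <- find(ra)
    }
  }
  roots <- vapply(seq_len(q), find, integer(1))
  split(linkage$labels, factor(roots, levels = unique(roots)))
}

#' Assign every up-regulated gene to a merged cluster or the outlier bucket
#'
#' Each gene (including those excluded from clustering by the variance
#' filter) goes to the cluster whose mean profile it correlates with best,
#' provided that correlation strictly exceeds `assign_r`; otherwise it is
#' an outlier. Genes with zero-variance profiles (Pearson undefined) are
#' outliers. Ties at the maximal correlation go to the lower cluster id and
#' are reported. After assignment, each cluster's mean profile is
#' recomputed from its final members; clusters left empty are dropped.
#'
#' @param x Numeric matrix of all candidate gene profiles (genes x time
#'   points) in the clustering space, with gene ids as row names.
#' @param means Numeric matrix of merged-cluster mean profiles (clusters x
#'   time points) in the same space, with cluster ids as row names.
#' @param assign_r Correlation threshold (strict >).
#' @param log_profiles Whether `x` holds log2 ratios; controls how the
#'   reported `mean_ratio_profile` is back-transformed.
#' @param merge_log Optional merge-event record carried into the result.
#' @return Object of class `cluster_set`: list with `clusters` (each a list
#'   `cluster_id`, `mean_profile` (clustering space), `mean_ratio_profile`,
#'   `members`), `outliers` (gene ids) and `merge_log`.
#' @export
assign_genes <- function(x, means, assign_r = 0.85, log_profiles = TRUE,
                         merge_log = NULL) {
  stopifnot(is.matrix(x), is.matrix(means))
  if (nrow(means) < 1L) stop("no clusters to assign genes to")
  if (is.null(rownames(means))) {
    rownames(means) <- sprintf("M%02d", seq_len(nrow(means)))
  }
  vm <- apply(means, 1L, var)
  if (any(vm == 0)) {
    stop("Pearson correlation undefined for zero-variance cluster mean(s): ",
         paste(rownames(means)[vm == 0], collapse = ", "))
  }
  gene_ids <- rownames(x)
  vx <- apply(x, 1L, var)
  ok <- vx > 0
  assignment <- rep(NA_character_, nrow(x))
  if (any(ok)) {
    cors <- cor(t(x[ok, , drop = FALSE]), t(means))
    best_idx <- max.col(cors, ties.method = "first")
    best_cor <- cors[cbind(seq_len(nrow(cors)), best_idx)]
    n_tied <- rowSums(abs(cors - best_cor) < 1e-12)
    tied <- which(n_tied > 1 & best_cor > assign_r)
    if (length(tied) > 0) {
      message(length(tied), " gene(s) tied between clusters at maximal ",
              "correlation; assigned to the lower cluster id")
    }
    assignment[ok] <- ifelse(best_cor > assign_r,
                             rownames(means)[best_idx], NA_character_)
  }
  outliers <- gene_ids[is.na(assignment)]
  clusters <- list()
  for (cid in rownames(means)) {
    members <- gene_ids[!is.na(assignment) & assignment == cid]
    if (length(members) == 0L) {
      message("cluster ", cid, " empty after final assignment; dropped")
      next
    }
    prof <- colMeans(x[members, , drop = FALSE])
    clusters[[length(clusters) + 1L]] <- list(
      cluster_id = cid,
      mean_profile = prof,
      mean_ratio_profile = if (log_profiles) 2^prof else prof,
      members = members)
  }
  structure(list(clusters = clusters, outliers = outliers,
                 merge_log = merge_log),
            class = "cluster_set")
}

#' @export
print.cluster_set <- function(x, ...) {
  sizes <- vapply(x$clusters, function(cl) length(cl$members), integer(1))
  cat("cluster set: ", length(x$clusters), " cluster(s) (sizes: ",
      paste(sizes, collapse = ", "), "), ", length(x$outliers),
      " outlier(s)\n", sep = "")
  invisible(x)
}
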