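#' Run the full time-course profiling pipeline
#'
#' Executes the stages in order: fold-ratio computation, regulation
#' classification, variance ranking of the up-regulated profiles and
#' selection of the top fraction, fuzzy k-means, adaptive membership
#' cutoff, single-linkage Pearson tree and merging, final assignment of
#' *all* up-regulated genes (including those the variance filter excluded
#' from clustering), and pattern labelling of the final clusters.
#'
#' Only up-regulated genes enter clustering. If fewer up-regulated
#' profiles than `k_clusters` are available, k is lowered with a warning.
#' Up-regulated genes whose profile has zero variance in the clustering
#' space (Pearson undefined) are withheld from k-means and become outliers
#' at assignment. All randomness flows from `config$seed`.
#'
#' @param matrix A [time_course_matrix()].
#' @param config A [ciliaprof_config()].
#' @return List of class `ciliaprof_run` with elements `calls`, `profiles`,
#'   `fit` (the `fuzzy_kmeans` object, or `NULL`), `cutoff`, `cluster_set`,
#'   `labels`, `summary` (from [summarize_groups()]) and `manifest`.
#' @examples
#' sim <- generate_dataset(simulation_config(n_per_archetype = 20,
#'   n_down = 40, n_unchanged = 40, n_not_expressed = 20, seed = 7))
#' res <- run_pipeline(sim$matrix, ciliaprof_config(k_clusters = 16, seed = 7))
#' res$manifest$category_counts
#' @export
run_pipeline <- function(matrix, config = ciliaprof_config()) {
  stopifnot(inherits(matrix, "time_course_matrix"))
  t0 <- proc.time()[["elapsed"]]
  timing <- c()
  tick <- function(stage) {
    t1 <- proc.time()[["elapsed"]]
    timing[[stage]] <<- round(t1 - t0, 3)
    t0 <<- t1
  }

  profiles <- compute_fold_ratios(matrix, pseudocount = config$pseudocount)
  calls <- classify_regulation(matrix, profiles, config)
  counts <- summarize_categories(calls)
  tick("classification")

  up_ids <- calls$gene_id[calls$status == "up"]
  space <- if (config$log_profiles) "log_ratio" else "ratio"
  xall <- if (config$log_profiles) profiles$log_ratios else profiles$ratios
  rownames(xall) <- profiles$gene_ids

  empty_result <- function(reason) {
    message("clustering skipped: ", reason)
    cs <- structure(list(clusters = list(), outliers = up_ids,
                         merge_log = NULL), class = "cluster_set")
    labels <- label_clusters(cs)
    manifest <- build_manifest(config, counts, k_used = 0L,
                               n_clustered = 0L, cutoff = NA_real_,
                               n_initial = 0L, n_merged = 0L,
                               cs = cs, labels = labels, timing = timing)
    structure(list(calls = calls, profiles = profiles, fit = NULL,
                   cutoff = NA_real_, cluster_set = cs, labels = labels,
                   summary = summarize_groups(cs, labels),
                   manifest = manifest),
              class = "ciliaprof_run")
  }
  if (length(up_ids) < 2L) {
    return(empty_result("fewer than 2 up-regulated genes"))
  }

  up_profiles <- structure(list(
    gene_ids = up_ids,
    ratios = profiles$ratios[up_ids, , drop = FALSE],
    log_ratios = profiles$log_ratios[up_ids, , drop = FALSE]),
    class = "expression_profiles")
  sel <- select_high_variance(up_profiles, config$variance_fraction,
                              space = space)
  clusterable <- sel$retained[sel$variances[sel$retained] > 0]
  n_dropped <- length(sel$retained) - length(clusterable)
  if (n_dropped > 0) {
    message(n_dropped, " zero-variance profile(s) withheld from clustering")
  }
  if (length(clusterable) < 2L) {
    return(empty_result("fewer than 2 clusterable profiles"))
  }
  k <- config$k_clusters
  if (k > length(clusterable)) {
    warning("k_clusters (", k, ") exceeds the ", length(clusterable),
            " clusterable profiles; lowering k")
    k <- length(clusterable)
  }
  fit <- fuzzy_kmeans(xall[clusterable, , drop = FALSE], k = k,
                      m = config$fuzziness_m, seed = config$seed)
  tick("fuzzy_kmeans")

  cutoff <- select_membership_cutoff(fit$membership)
  # initial clusters: genes at or above the cutoff (multi-membership allowed)
  members0 <- apply(fit$membership >= cutoff, 2L, function(col) {
    rownames(fit$membership)[col]
  }, simplify = FALSE)
  keep <- vapply(members0, length, integer(1)) > 0
  if (!all(keep)) {
    message(sum(!keep), " cluster(s) empty at the membership cutoff; dropped")
  }
  members0 <- members0[keep]
  means0 <- do.call(rbind, lapply(members0, function(g) {
    colMeans(xall[g, , drop = FALSE])
  }))
  tick("membership_cutoff")

  linkage <- correlation_linkage(means0)
  groups <- merge_clusters(linkage, merge_r = config$merge_r)
  merge_log <- data.frame(
    step = seq_along(linkage$similarity),
    similarity = linkage$similarity,
    merged = linkage$similarity > config$merge_r)
  # merged cluster mean = unweighted mean over the union of member genes
  merged_means <- do.call(rbind, lapply(groups, function(ids) {
    g <- unique(unlist(members0[ids]))
    colMeans(xall[g, , drop = FALSE])
  }))
  rownames(merged_means) <- sprintf("M%02d", seq_len(nrow(merged_means)))
  tick("linkage_merge")

  cs <- assign_genes(xall[up_ids, , drop = FALSE], merged_means,
                     assign_r = config$assign_r,
                     log_profiles = config$log_profiles,
                     merge_log = merge_log)
  labels <- label_clusters(cs, fold_up = config$fold_up,
                           decline_factor = config$decline_factor)
  summary <- summarize_groups(cs, labels)
  tick("assignment")

  manifest <- build_manifest(config, counts, k_used = fit$k,
                             n_clustered = length(clusterable),
                             cutoff = cutoff,
                             n_initial = length(members0),
                             n_merged = nrow(merged_means),
                             cs = cs, labels = labels, timing = timing)
  structure(list(calls = calls, profiles = profiles, fit = fit,
                 cutoff = cutoff, cluster_set = cs, labels = labels,
                 summary = summary, manifest = manifest),
            class = "ciliaprof_run")
}

build_manifest <- function(config, counts, k_used, n_clustered, cutoff,
                           n_initial, n_merged, cs, labels, timing) {
  sizes <- vapply(cs$clusters, function(cl) length(cl$members), integer(1))
  grp <- summarize_groups(cs, labels)$group
  list(config = unclass(config),
       category_counts = counts,
       n_clustered = n_clustered,
       k_used = k_used,
       membership_cutoff = cutoff,
       clusters_before_merge = n_initial,
       clusters_after_merge = n_merged,
       clusters_final = length(cs$clusters),
       n_assigned = sum(sizes),
       n_outliers = length(cs$outliers),
       group_percent = setNames(grp$percent, grp$group),
       stage_seconds = timing)
}

#' @export
print.ciliaprof_run <- function(x, ...) {
  m <- x$manifest
  cat("ciliaprof pipeline run\n")
  cat("  categories:",
      paste(names(m$category_counts), m$category_counts, collapse = ", "),
      "\n")
  cat("  clusters: ", m$clusters_before_merge, " before merge, ",
      m$clusters_final, " final; cutoff ",
      format(m$membership_cutoff, digits = 3), "\n", sep = "")
  cat("  assigned ", m$n_assigned, " gene(s), ", m$n_outliers,
      " outlier(s)\n", sep = "")
  invisible(x)
}

#' Write the run manifest as a flat key-value text file
#'
#' @param run A `ciliaprof_run` object.
#' @param path Output file path.
#' @return Invisibly, `path`.
#' @export
write_manifest <- function(run, path) {
  m <- run$manifest
  flat <- c(
    setNames(as.character(unlist(m$config)), paste0("config.",
                                                    names(unlist(m$config)))),
    setNames(as.character(m$category_counts),
             paste0("count.", names(m$category_counts))),
    n_clustered = as.character(m$n_clustered),
    k_used = as.character(m$k_used),
    membership_cutoff = as.character(m$membership_cutoff),
    clusters_before_merge = as.character(m$clusters_before_merge),
    clusters_after_merge = as.character(m$clusters_after_merge),
    clusters_final = as.character(m$clusters_final),
    n_assigned = as.character(m$n_assigned),
    n_outliers = as.character(m$n_outliers),
    setNames(as.character(round(m$group_percent, 4)),
             paste0("percent.", names(m$group_percent))),
    setNames(as.character(m$stage_seconds),
             paste0("seconds.", names(m$stage_seconds)))
  )
  writeLines(paste(names(flat), flat, sep = "\t"), path)
  invisible(path)
}
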