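#' The sixteen principal induction patterns and five pattern groups
#'
#' Up-regulated expression profiles fall into five pattern groups:
#' *Arch* (rise at 3 min, peak at 10 min, decline at 30 and 60 min),
#' *Stag* (staggered: a burst at one time point with sustained expression
#' after it), *Pulse* (a single-time-point burst), *Hump* (a burst
#' sustained over two consecutive time points) and *Up-Tick* (up at one
#' time point, down at another, up again at a third). Together with the
#' `Unclassified` bucket for profiles that never reach the induction
#' threshold, these give sixteen principal labels.
#'
#' @format `PATTERN_GROUPS` is a named character vector mapping each
#'   principal label to its pattern group.
#' @export
PATTERN_GROUPS <- c(
  Arch1 = "Arch", Arch2 = "Arch",
  Stag3 = "Stag", Stag10 = "Stag", Stag30 = "Stag", Stag60 = "Stag",
  Pulse3 = "Pulse", Pulse10 = "Pulse", Pulse30 = "Pulse",
  Hump1 = "Hump", Hump2 = "Hump",
  UpTick_a = "UpTick", UpTick_b = "UpTick", UpTick_c = "UpTick",
  UpTick_d = "UpTick",
  Unclassified = "Outlier"
)

#' @rdname PATTERN_GROUPS
#' @param principal Character vector of principal labels.
#' @return `pattern_group()` returns the group of each label.
#' @export
pattern_group <- function(principal) {
  out <- unname(PATTERN_GROUPS[principal])
  if (anyNA(out) && !anyNA(principal)) {
    bad <- setdiff(unique(principal), names(PATTERN_GROUPS))
    if (length(bad) > 0) stop("unknown principal label(s): ",
                              paste(bad, collapse = ", "))
  }
  out
}

#' Up-regulation signature of a mean ratio profile
#'
#' Four booleans, one per post-deflagellation time point, each `TRUE` when
#' the fold ratio at that time point reaches `fold_up` (inclusive).
#'
#' @param mean_ratio_profile Numeric vector of 4 fold ratios
#'   (3, 10, 30, 60 min).
#' @param fold_up Induction threshold.
#' @return Logical vector `c(up3, up10, up30, up60)`.
#' @export
up_signature <- function(mean_ratio_profile, fold_up = 2.5) {
  stopifnot(length(mean_ratio_profile) == 4L,
            all(is.finite(mean_ratio_profile)))
  setNames(mean_ratio_profile >= fold_up, c("up3", "up10", "up30", "up60"))
}

#' Classify a mean ratio profile into a principal pattern
#'
#' The rule table operates on the [up_signature()] of the profile:
#' \itemize{
#'   \item up at all four time points: `Arch1` when the peak sits at 10 or
#'     30 min and exceeds the 60-min ratio by at least `decline_factor`
#'     (peaked-but-still-up); otherwise `Stag3` (sustained from 3 min);
#'   \item contiguous up runs: `Arch2` (3–30), `Stag10/30/60` (up from a
#'     later burst onward), `Pulse3/10/30` (single time point),
#'     `Hump1/2` (two consecutive time points);
#'   \item any signature with a gap between up time points: an Up-Tick
#'     subtype keyed by the dip position — `UpTick_a` (dip at 10 min, not
#'     up at 60), `UpTick_b` (dip at 10 min, up at 60), `UpTick_c` (dip at
#'     30 min), `UpTick_d` (dip at both 10 and 30 min);
#'   \item no up time point: `Unclassified`.
#' }
#'
#' @inheritParams up_signature
#' @param decline_factor Arch1 shape threshold (> 1): the peak ratio must be
#'   at least `decline_factor` times the 60-min ratio.
#' @return A single principal label (see [PATTERN_GROUPS]).
#' @examples
#' classify_pattern(c(9.02, 28.92, 8.38, 0.17))   # Arch2
#' classify_pattern(c(3.86, 21.03, 45.07, 58.38)) # Stag3
#' @export
classify_pattern <- function(mean_ratio_profile, fold_up = 2.5,
                             decline_factor = 1.5) {
  stopifnot(decline_factor > 1)
  s <- up_signature(mean_ratio_profile, fold_up)
  key <- paste(ifelse(s, "T", "F"), collapse = "")
  if (key == "TTTT") {
    peak <- which.max(mean_ratio_profile)
    if (peak %in% c(2L, 3L) &&
        mean_ratio_profile[peak] >= decline_factor * mean_ratio_profile[4L]) {
      return("Arch1")
    }
    return("Stag3")
  }
  switch(key,
         TTTF = "Arch2",
         FTTT = "Stag10", FFTT = "Stag30", FFFT = "Stag60",
         TFFF = "Pulse3", FTFF = "Pulse10", FFTF = "Pulse30",
         TTFF = "Hump1", FTTF = "Hump2",
         TFTF = "UpTick_a",
         TFTT = "UpTick_b",
         FTFT = "UpTick_c", TTFT = "UpTick_c",
         TFFT = "UpTick_d",
         FFFF = "Unclassified")
}

#' Label every cluster of a cluster set with its principal pattern
#'
#' @param cluster_set A `cluster_set` from [assign_genes()].
#' @param fold_up Induction threshold.
#' @param decline_factor See [classify_pattern()].
#' @return Data frame with columns `cluster_id`, `principal`, `group`,
#'   `n_genes`.
#' @export
label_clusters <- function(cluster_set, fold_up = 2.5, decline_factor = 1.5) {
  stopifnot(inherits(cluster_set, "cluster_set"))
  rows <- lapply(cluster_set$clusters, function(cl) {
    principal <- classify_pattern(cl$mean_ratio_profile, fold_up,
                                  decline_factor)
    data.frame(cluster_id = cl$cluster_id, principal = principal,
               group = pattern_group(principal),
               n_genes = length(cl$members), stringsAsFactors = FALSE)
  })
  if (length(rows) == 0L) {
    return(data.frame(cluster_id = character(0), principal = character(0),
                      group = character(0), n_genes = integer(0)))
  }
  do.call(rbind, rows)
}

#' Per-pattern and per-group gene counts and percentages
#'
#' Counts genes (not clusters) under each principal pattern and each
#' pattern group; genes inherit the label of their cluster, and outliers
#' form their own bucket. Percentages are relative to all genes offered for
#' assignment (assigned + outliers).
#'
#' @param cluster_set A `cluster_set` from [assign_genes()].
#' @param labels Output of [label_clusters()] for the same clusters.
#' @return List with data frames `principal` (`principal, group, n_genes,
#'   percent`) and `group` (`group, n_genes, percent`), plus `n_total`.
#' @export
summarize_groups <- function(cluster_set, labels) {
  stopifnot(inherits(cluster_set, "cluster_set"))
  ids <- vapply(cluster_set$clusters, `[[`, character(1), "cluster_id")
  if (!setequal(ids, labels$cluster_id)) {
    stop("labels do not cover the clusters of the cluster set")
  }
  sizes <- setNames(vapply(cluster_set$clusters,
                           function(cl) length(cl$members), integer(1)), ids)
  n_out <- length(cluster_set$outliers)
  n_total <- sum(sizes) + n_out
  principals <- c(names(PATTERN_GROUPS))
  n_prin <- setNames(integer(length(principals)), principals)
  for (i in seq_along(ids)) {
    lab <- labels$principal[labels$cluster_id == ids[i]]
    n_prin[lab] <- n_prin[lab] + sizes[i]
  }
  n_prin["Unclassified"] <- n_prin[["Unclassified"]] + n_out
  principal_df <- data.frame(
    principal = principals,
    group = pattern_group(principals),
    n_genes = as.integer(n_prin),
    percent = if (n_total > 0) 100 * as.integer(n_prin) / n_total else 0,
    stringsAsFactors = FALSE)
  grp_levels <- unique(unname(PATTERN_GROUPS))
  n_grp <- vapply(grp_levels, function(g) {
    sum(principal_df$n_genes[principal_df$group == g])
  }, integer(1))
  group_df <- data.frame(
    group = grp_levels, n_genes = as.integer(n_grp),
    percent = if (n_total > 0) 100 * as.integer(n_grp) / n_total else 0,
    stringsAsFactors = FALSE)
  list(principal = principal_df, group = group_df, n_total = n_total)
}
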