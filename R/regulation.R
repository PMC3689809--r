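#' Compute per-gene fold-ratio profiles relative to the baseline
#'
#' For every gene the expression profile is the ratio of its FPKM at each
#' post-deflagellation time point (3, 10, 30, 60 min) to the FPKM in the
#' pre-deflagellation sample. A pseudocount is added to numerator and
#' denominator alike; with `pseudocount = 0` the printed fold-change
#' arithmetic of published tables is reproduced exactly, but every baseline
#' must then be positive.
#'
#' @param matrix A [time_course_matrix()].
#' @param pseudocount Non-negative value added to both sides of each ratio.
#' @return An object of class `expression_profiles`: a list with
#'   `gene_ids`, `ratios` (genes x 4 matrix, columns `r3, r10, r30, r60`)
#'   and `log_ratios` (base-2 logarithms of `ratios`).
#' @examples
#' m <- time_course_matrix(rbind(GLOD4 = c(3.55, 8.10, 12.50, 15.05, 11.58)))
#' round(compute_fold_ratios(m, pseudocount = 0)$ratios, 2)
#' @export
compute_fold_ratios <- function(matrix, pseudocount = 0.1) {
  stopifnot(inherits(matrix, "time_course_matrix"))
  if (pseudocount < 0) stop("pseudocount must be non-negative")
  pre <- matrix[, "pre"] + pseudocount
  if (any(pre == 0)) {
    stop("division by zero: pseudocount 0 with zero baseline FPKM for gene(s): ",
         paste(head(rownames(matrix)[matrix[, "pre"] + pseudocount == 0], 5L),
               collapse = ", "))
  }
  ratios <- sweep(matrix[, TIMEPOINTS[-1L], drop = FALSE] + pseudocount,
                  1L, pre, "/")
  colnames(ratios) <- c("r3", "r10", "r30", "r60")
  structure(list(gene_ids = rownames(matrix),
                 ratios = ratios,
                 log_ratios = log2(ratios)),
            class = "expression_profiles")
}

#' @export
print.expression_profiles <- function(x, ...) {
  cat("expression profiles for", length(x$gene_ids), "gene(s)\n")
  print(head(round(x$ratios, 3)))
  invisible(x)
}

#' Partition genes into not-expressed / up / down / unchanged
#'
#' A gene is *expressed* if its FPKM reaches `expr_min` (default 3) at one
#' or more of the five time points, the pre-deflagellation baseline
#' included. Among expressed genes, any gene whose fold ratio reaches
#' `fold_up` (default 2.5) at one or more time points is *up-regulated*;
#' otherwise a gene whose minimum ratio falls to `fold_down` (default 1/2.5,
#' inclusive) is *down-regulated*; the rest are *unchanged*. A gene can
#' cross both thresholds at different time points; up-regulation takes
#' precedence and both extremes are retained in the call record.
#'
#' @param matrix The [time_course_matrix()] the profiles derive from.
#' @param profiles [compute_fold_ratios()] output for the same genes.
#' @param config A [ciliaprof_config()].
#' @return Data frame with columns `gene_id`, `status` (factor with levels
#'   `up, down, unchanged, not_expressed`), `max_ratio`, `min_ratio`.
#' @export
classify_regulation <- function(matrix, profiles,
                                config = ciliaprof_config()) {
  stopifnot(inherits(matrix, "time_course_matrix"),
            inherits(profiles, "expression_profiles"))
  if (!identical(profiles$gene_ids, rownames(matrix))) {
    missing <- setdiff(profiles$gene_ids, rownames(matrix))
    if (length(missing) > 0) {
      stop("profile gene(s) missing from matrix: ",
           paste(head(missing, 5L), collapse = ", "))
    }
    stop("profiles and matrix list genes in different order")
  }
  expressed <- apply(matrix >= config$expr_min, 1L, any)
  max_ratio <- apply(profiles$ratios, 1L, max)
  min_ratio <- apply(profiles$ratios, 1L, min)
  status <- ifelse(!expressed, "not_expressed",
            ifelse(max_ratio >= config$fold_up, "up",
            ifelse(min_ratio <= config$fold_down, "down", "unchanged")))
  data.frame(gene_id = profiles$gene_ids,
             status = factor(status,
                             levels = c("up", "down", "unchanged",
                                        "not_expressed")),
             max_ratio = unname(max_ratio),
             min_ratio = unname(min_ratio),
             stringsAsFactors = FALSE)
}

#' Tabulate regulation categories
#'
#' @param calls Output of [classify_regulation()]; must be non-empty.
#' @return Named integer vector with counts for `up`, `down`, `unchanged`,
#'   `not_expressed` and `total`.
#' @export
summarize_categories <- function(calls) {
  if (is.null(calls) || nrow(calls) == 0L) {
    stop("summarize_categories needs a non-empty set of calls")
  }
  counts <- table(calls$status)
  out <- setNames(as.integer(counts), names(counts))
  c(out, total = nrow(calls))
}
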