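#' Pipeline run configuration
#'
#' Collects every tunable threshold of the analysis in one validated object.
#' Defaults are the constants used throughout: 3 FPKM expression floor,
#' 2.5-fold induction threshold (and its reciprocal for repression), top 75%
#' of genes by profile variance entering clustering, cluster merging at
#' Pearson r > 0.9 and final gene assignment at r > 0.85.
#'
#' @param expr_min Minimum FPKM a gene must reach at one or more time points
#'   (including the pre-deflagellation sample) to count as expressed.
#' @param fold_up Fold-ratio threshold at or above which a gene is called
#'   up-regulated. Must be > 1.
#' @param fold_down Fold-ratio threshold at or below which an expressed,
#'   not-up gene is called down-regulated. Must lie in (0, 1). Defaults to
#'   `1 / fold_up`.
#' @param pseudocount Non-negative value added to numerator and denominator
#'   of every fold ratio; prevents division by zero at silent baselines.
#'   Set to 0 to reproduce printed fold-change tables exactly.
#' @param variance_fraction Fraction of up-regulated genes (highest profile
#'   variance first) that enter fuzzy k-means. In (0, 1].
#' @param k_clusters Number of fuzzy k-means clusters before merging (>= 2).
#' @param fuzziness_m Fuzziness exponent of the membership update (> 1).
#' @param merge_r Pearson correlation above which branches of the
#'   single-linkage cluster tree are merged (strict >).
#' @param assign_r Pearson correlation above which a gene is assigned to its
#'   best-matching cluster (strict >); below it the gene is an outlier.
#' @param log_profiles If `TRUE` (default) clustering operates on log2 fold
#'   ratios; if `FALSE`, on raw ratios.
#' @param decline_factor Shape threshold separating the rise-peak-decline
#'   pattern (Arch1) from sustained induction (Stag3) among profiles
#'   up-regulated at all four time points: the peak ratio must exceed the
#'   60-minute ratio by at least this factor. Must be > 1.
#' @param seed Integer seed governing all randomness of a run.
#'
#' @return An object of class `ciliaprof_config` (a validated named list).
#' @examples
#' cfg <- ciliaprof_config(seed = 1)
#' cfg$fold_up
#' @export
ciliaprof_config <- function(expr_min = 3,
                             fold_up = 2.5,
                             fold_down = 1 / fold_up,
                             pseudocount = 0.1,
                             variance_fraction = 0.75,
                             k_clusters = 30L,
                             fuzziness_m = 2.0,
                             merge_r = 0.9,
                             assign_r = 0.85,
                             log_profiles = TRUE,
                             decline_factor = 1.5,
                             seed = 1L) {
  cfg <- list(
    expr_min = as.numeric(expr_min),
    fold_up = as.numeric(fold_up),
    fold_down = as.numeric(fold_down),
    pseudocount = as.numeric(pseudocount),
    variance_fraction = as.numeric(variance_fraction),
    k_clusters = as.integer(k_clusters),
    fuzziness_m = as.numeric(fuzziness_m),
    merge_r = as.numeric(merge_r),
    assign_r = as.numeric(assign_r),
    log_profiles = isTRUE(log_profiles),
    decline_factor = as.numeric(decline_factor),
    seed = as.integer(seed)
  )
  validate_config(cfg)
  structure(cfg, class = "ciliaprof_config")
}

validate_config <- function(cfg) {
  stopifnot(
    "expr_min must be non-negative" = cfg$expr_min >= 0,
    "fold_up must be > 1" = cfg$fold_up > 1,
    "fold_down must be in (0, 1)" = cfg$fold_down > 0 && cfg$fold_down < 1,
    "pseudocount must be non-negative" = cfg$pseudocount >= 0,
    "variance_fraction must be in (0, 1]" =
      cfg$variance_fraction > 0 && cfg$variance_fraction <= 1,
    "k_clusters must be >= 2" = cfg$k_clusters >= 2L,
    "fuzziness_m must be > 1" = cfg$fuzziness_m > 1,
    "merge_r must be in (-1, 1)" = cfg$merge_r > -1 && cfg$merge_r < 1,
    "assign_r must be in (-1, 1)" = cfg$assign_r > -1 && cfg$assign_r < 1,
    "decline_factor must be > 1" = cfg$decline_factor > 1
  )
  invisible(cfg)
}

#' Read a run configuration from a flat YAML key-value file
#'
#' Unknown keys are rejected; missing keys fall back to the
#' [ciliaprof_config()] defaults.
#'
#' @param path Path to a YAML file whose top level is a flat mapping of
#'   `ciliaprof_config()` argument names to values.
#' @return A `ciliaprof_config` object.
#' @export
read_config <- function(path) {
  if (!file.exists(path)) stop("config file not found: ", path)
  vals <- yaml::read_yaml(path)
  if (is.null(vals)) vals <- list()
  known <- names(formals(ciliaprof_config))
  bad <- setdiff(names(vals), known)
  if (length(bad) > 0) {
    stop("unknown config keys: ", paste(bad, collapse = ", "))
  }
  do.call(ciliaprof_config, vals)
}

#' @export
print.ciliaprof_config <- function(x, ...) {
  cat("ciliaprof run configuration\n")
  for (nm in names(x)) cat(sprintf("  %-18s %s\n", nm, format(x[[nm]])))
  invisible(x)
}
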