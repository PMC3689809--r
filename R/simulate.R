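#' Canonical ratio profiles of the fifteen induction archetypes
#'
#' One archetype per principal up-regulation pattern (the `Unclassified`
#' bucket has none). Each canonical profile classifies to its own label
#' under the default thresholds, and the set was chosen so that no two
#' archetypes of *different* pattern groups have log2-profile Pearson
#' correlation above the default 0.9 merge threshold — mirroring the
#' premise that the principal profiles are distinct shapes.
#'
#' @return Data frame with columns `name`, `group` and `r3, r10, r30, r60`
#'   (canonical fold ratios at 3, 10, 30, 60 min).
#' @export
default_archetypes <- function() {
  prof <- rbind(
    Arch1   = c(4, 12, 6, 3),
    Arch2   = c(4, 10, 4, 1),
    Stag3   = c(3, 4, 5, 6),
    Stag10  = c(1, 6, 6, 6),
    Stag30  = c(1, 1, 6, 6),
    Stag60  = c(1, 1, 1, 6),
    Pulse3  = c(8, 1, 1, 1),
    Pulse10 = c(1, 8, 1, 1),
    Pulse30 = c(1, 1, 8, 1),
    Hump1   = c(6, 6, 1, 1),
    Hump2   = c(1, 8, 8, 1),
    UpTick_a = c(6, 1, 6, 1),
    UpTick_b = c(6, 1, 6, 6),
    UpTick_c = c(1, 6, 1, 6),
    UpTick_d = c(6, 1, 1, 6))
  colnames(prof) <- c("r3", "r10", "r30", "r60")
  data.frame(name = rownames(prof),
             group = pattern_group(rownames(prof)),
             prof, row.names = NULL, stringsAsFactors = FALSE)
}

# Repression shapes for the down-regulated background: each drops to <= 0.4
# at two or more time points and never reaches 2.5.
down_shapes <- function() {
  rbind(c(0.25, 0.25, 0.25, 0.25),
        c(1, 0.3, 0.2, 0.2),
        c(0.3, 0.25, 0.6, 1))
}

#' Simulation settings for synthetic FPKM time courses
#'
#' Defaults emulate the composition of a deflagellation time-course
#' transcriptome at the scale of the published study: 100 genes per
#' induction archetype (1500 up-regulated), with down-regulated, unchanged
#' and below-threshold backgrounds in the study's proportions
#' (roughly 1 : 2.4 : 2.5 : 4.3 relative to up), for ~15,000 genes in all.
#' Baseline abundance is log-normal (natural-log mean 2, sd 1), giving the
#' right-skewed FPKM distribution typical of expression data; noise is
#' additive Gaussian on log2 fold ratios (multiplicative on FPKM) with
#' sd 0.25.
#'
#' @param n_per_archetype Up-regulated genes per archetype.
#' @param n_down,n_unchanged,n_not_expressed Background gene counts.
#' @param baseline_log_mean,baseline_log_sd Natural-log parameters of the
#'   log-normal baseline FPKM distribution.
#' @param noise_sd Standard deviation of the Gaussian noise on log2 ratios.
#' @param expr_min Expression floor used to anchor expressed / silent genes.
#' @param seed Integer seed.
#' @return A validated list of class `simulation_config`.
#' @export
simulation_config <- function(n_per_archetype = 100L,
                              n_down = 3560L,
                              n_unchanged = 3690L,
                              n_not_expressed = 6460L,
                              baseline_log_mean = 2.0,
                              baseline_log_sd = 1.0,
                              noise_sd = 0.25,
                              expr_min = 3,
                              seed = 1L) {
  cfg <- list(n_per_archetype = as.integer(n_per_archetype),
              n_down = as.integer(n_down),
              n_unchanged = as.integer(n_unchanged),
              n_not_expressed = as.integer(n_not_expressed),
              baseline_log_mean = as.numeric(baseline_log_mean),
              baseline_log_sd = as.numeric(baseline_log_sd),
              noise_sd = as.numeric(noise_sd),
              expr_min = as.numeric(expr_min),
              seed = as.integer(seed))
  stopifnot(cfg$n_per_archetype >= 0, cfg$n_down >= 0, cfg$n_unchanged >= 0,
            cfg$n_not_expressed >= 0, cfg$noise_sd >= 0,
            cfg$baseline_log_sd >= 0)
  structure(cfg, class = "simulation_config")
}

#' Generate a synthetic FPKM time course with ground truth
#'
#' Up-regulated genes follow one of the induction archetypes: the baseline
#' FPKM is drawn log-normal and floored at `expr_min` (so the gene is
#' expressed), the log2 fold ratio at each time point is the archetype's
#' log2 ratio plus `N(0, noise_sd)`, and the FPKM is the baseline times the
#' realised ratio. Down-regulated genes use repression shapes (ratio <= 0.4
#' at two or more time points), unchanged genes a flat unit-ratio profile,
#' and not-expressed genes are rescaled so that every FPKM stays below
#' `expr_min`. The output is deterministic for a given seed.
#'
#' @param config A [simulation_config()].
#' @param archetypes Archetype table as from [default_archetypes()].
#' @return List with `matrix` (a [time_course_matrix()]) and `truth`
#'   (data frame `gene_id, true_category, true_archetype`).
#' @export
generate_dataset <- function(config = simulation_config(),
                             archetypes = default_archetypes()) {
  stopifnot(inherits(config, "simulation_config"))
  set.seed(config$seed)
  arch_mat <- as.matrix(archetypes[, c("r3", "r10", "r30", "r60")])
  rownames(arch_mat) <- archetypes$name

  rows <- list(); truth <- list()
  add_gene_block <- function(ids, log2_arch, category, arch_names,
                             baseline, cap = NULL) {
    n <- length(ids)
    noise <- matrix(rnorm(n * 4L, 0, config$noise_sd), n, 4L)
    lr <- log2_arch + noise
    fpkm <- cbind(baseline, baseline * 2^lr)
    if (!is.null(cap)) {
      # silent genes: rescale so that no time point reaches the floor,
      # preserving the fold ratios
      mx <- apply(fpkm, 1L, max)
      over <- mx >= cap
      fpkm[over, ] <- fpkm[over, , drop = FALSE] * (0.95 * cap / mx[over])
    }
    rows[[length(rows) + 1L]] <<- fpkm
    truth[[length(truth) + 1L]] <<- data.frame(
      gene_id = ids, true_category = category,
      true_archetype = arch_names, stringsAsFactors = FALSE)
  }

  base_draw <- function(n, floor_at = config$expr_min) {
    pmax(rlnorm(n, config$baseline_log_mean, config$baseline_log_sd), floor_at)
  }

  # up-regulated genes, archetype by archetype
  for (a in seq_len(nrow(arch_mat))) {
    n <- config$n_per_archetype
    if (n == 0L) next
    nm <- rownames(arch_mat)[a]
    ids <- sprintf("UP_%s_%04d", nm, seq_len(n))
    la <- matrix(log2(arch_mat[a, ]), n, 4L, byrow = TRUE)
    add_gene_block(ids, la, "up", nm, base_draw(n))
  }
  # down-regulated background
  if (config$n_down > 0L) {
    shp <- down_shapes()
    pick <- sample.int(nrow(shp), config$n_down, replace = TRUE)
    ids <- sprintf("DOWN_%05d", seq_len(config$n_down))
    add_gene_block(ids, log2(shp[pick, , drop = FALSE]), "down",
                   NA_character_, base_draw(config$n_down))
  }
  # unchanged background: flat unit ratios
  if (config$n_unchanged > 0L) {
    ids <- sprintf("FLAT_%05d", seq_len(config$n_unchanged))
    add_gene_block(ids, matrix(0, config$n_unchanged, 4L), "unchanged",
                   NA_character_, base_draw(config$n_unchanged))
  }
  # silent genes: below the expression floor at every time point
  if (config$n_not_expressed > 0L) {
    ids <- sprintf("OFF_%05d", seq_len(config$n_not_expressed))
    baseline <- pmin(rlnorm(config$n_not_expressed,
                            config$baseline_log_mean - 2.5,
                            config$baseline_log_sd),
                     0.8 * config$expr_min)
    add_gene_block(ids, matrix(0, config$n_not_expressed, 4L),
                   "not_expressed", NA_character_, baseline,
                   cap = config$expr_min)
  }
  truth <- do.call(rbind, truth)
  mat <- time_course_matrix(do.call(rbind, rows), gene_ids = truth$gene_id)
  list(matrix = mat, truth = truth)
}

#' Score pipeline recovery against simulation ground truth
#'
#' Reports (a) the confusion matrix between true and called regulation
#' categories, (b) the fraction of true up-regulated genes whose inherited
#' pattern *group* matches the group of their true archetype (outliers and
#' unassigned genes count as mismatches unless the truth is an outlier),
#' and (c) the adjusted Rand index between the final cluster partition and
#' the archetype partition of the clustered true-up genes.
#'
#' @param truth Truth table from [generate_dataset()].
#' @param calls Regulation calls from [classify_regulation()].
#' @param cluster_set Final `cluster_set` from the pipeline (optional).
#' @param labels Cluster labels from [label_clusters()] (optional).
#' @return List with `confusion` (table), `category_accuracy`,
#'   `group_recovery` and `ari` (the latter two `NA` without clusters).
#' @export
score_recovery <- function(truth, calls, cluster_set = NULL, labels = NULL) {
  missing <- setdiff(truth$gene_id, calls$gene_id)
  if (length(missing) > 0) {
    stop("truth gene(s) missing from calls: ",
         paste(head(missing, 5L), collapse = ", "))
  }
  status <- setNames(as.character(calls$status), calls$gene_id)
  confusion <- table(truth = truth$true_category,
                     called = status[truth$gene_id])
  category_accuracy <-
    mean(truth$true_category == status[truth$gene_id])
  group_recovery <- NA_real_
  ari <- NA_real_
  if (!is.null(cluster_set) && !is.null(labels)) {
    lab_of <- setNames(labels$group, labels$cluster_id)
    gene_cluster <- setNames(rep("outlier",
                                 length(cluster_set$outliers)),
                             cluster_set$outliers)
    for (cl in cluster_set$clusters) {
      gene_cluster[cl$members] <- cl$cluster_id
    }
    up <- truth[truth$true_category == "up", , drop = FALSE]
    inherited <- ifelse(gene_cluster[up$gene_id] == "outlier" |
                          is.na(gene_cluster[up$gene_id]),
                        "Outlier",
                        unname(lab_of[gene_cluster[up$gene_id]]))
    true_group <- pattern_group(up$true_archetype)
    group_recovery <- mean(inherited == true_group)
    clustered <- !is.na(gene_cluster[up$gene_id]) &
      gene_cluster[up$gene_id] != "outlier"
    if (any(clustered)) {
      ari <- mclust::adjustedRandIndex(
        gene_cluster[up$gene_id][clustered],
        up$true_archetype[clustered])
    }
  }
  list(confusion = confusion, category_accuracy = category_accuracy,
       group_recovery = group_recovery, ari = ari)
}
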