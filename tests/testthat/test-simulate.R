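test_that("generated matrices validate and have the expected size", {
  cfg <- simulation_config(n_per_archetype = 100, n_down = 50,
                           n_unchanged = 50, n_not_expressed = 10, seed = 3)
  sim <- generate_dataset(cfg)
  expect_s3_class(sim$matrix, "time_course_matrix")
  expect_equal(nrow(sim$matrix), 100 * 15 + 50 + 50 + 10)   # 1610
  expect_equal(nrow(sim$truth), nrow(sim$matrix))
  expect_equal(anyDuplicated(sim$truth$gene_id), 0L)
  # silent genes stay below the expression floor everywhere
  off <- sim$truth$gene_id[sim$truth$true_category == "not_expressed"]
  expect_true(all(sim$matrix[off, ] < cfg$expr_min))
})

test_that("the generator is deterministic for a fixed seed", {
  cfg <- simulation_config(n_per_archetype = 10, n_down = 20,
                           n_unchanged = 20, n_not_expressed = 10, seed = 42)
  s1 <- generate_dataset(cfg)
  s2 <- generate_dataset(cfg)
  expect_identical(s1$matrix, s2$matrix)
  expect_identical(s1$truth, s2$truth)
  s3 <- generate_dataset(simulation_config(n_per_archetype = 10, n_down = 20,
                                           n_unchanged = 20,
                                           n_not_expressed = 10, seed = 43))
  expect_false(identical(s1$matrix, s3$matrix))
})

test_that("zero-noise up genes realise their archetype ratios exactly", {
  sim <- generate_dataset(simulation_config(
    n_per_archetype = 3, n_down = 0, n_unchanged = 0, n_not_expressed = 0,
    noise_sd = 0, seed = 1))
  prof <- compute_fold_ratios(sim$matrix, pseudocount = 0)
  arch <- default_archetypes()
  for (i in seq_len(nrow(sim$truth))) {
    want <- as.numeric(arch[arch$name == sim$truth$true_archetype[i],
                            c("r3", "r10", "r30", "r60")])
    expect_equal(unname(prof$ratios[sim$truth$gene_id[i], ]), want,
                 tolerance = 1e-12)
  }
})

test_that("category proportions hold within binomial error at larger n", {
  cfg <- simulation_config(n_per_archetype = 40, n_down = 400,
                           n_unchanged = 400, n_not_expressed = 400, seed = 13)
  sim <- generate_dataset(cfg)
  prof <- compute_fold_ratios(sim$matrix)
  calls <- classify_regulation(sim$matrix, prof, ciliaprof_config())
  counts <- summarize_categories(calls)
  # noise can only misclassify a tiny fraction; allow ~3 sd of binomial noise
  expect_equal(counts[["up"]], 600L, tolerance = 0.02)
  expect_equal(counts[["down"]], 400L, tolerance = 0.02)
  expect_equal(counts[["unchanged"]], 400L, tolerance = 0.02)
  expect_equal(counts[["not_expressed"]], 400L, tolerance = 0.02)
})

test_that("score_recovery reports perfect recovery at zero noise", {
  sim <- generate_dataset(simulation_config(
    n_per_archetype = 10, n_down = 10, n_unchanged = 10, n_not_expressed = 5,
    noise_sd = 0, seed = 8))
  res <- suppressWarnings(
    run_pipeline(sim$matrix, ciliaprof_config(k_clusters = 15, seed = 8)))
  sc <- score_recovery(sim$truth, res$calls, res$cluster_set, res$labels)
  expect_equal(sc$category_accuracy, 1)
  expect_equal(sc$group_recovery, 1)
  expect_true(all(sc$confusion[cbind(rownames(sc$confusion),
                                     rownames(sc$confusion))] ==
                    table(sim$truth$true_category)[rownames(sc$confusion)]))
  expect_error(score_recovery(data.frame(gene_id = "ghost",
                                         true_category = "up",
                                         true_archetype = "Arch1"),
                              res$calls), "missing from calls")
})

test_that("a single-archetype dataset clusters with perfect agreement", {
  sim <- generate_dataset(simulation_config(
    n_per_archetype = 25, n_down = 0, n_unchanged = 0, n_not_expressed = 0,
    noise_sd = 0.05, seed = 5),
    archetypes = default_archetypes()[default_archetypes()$name == "Hump2", ])
  res <- suppressWarnings(
    run_pipeline(sim$matrix, ciliaprof_config(k_clusters = 4, seed = 5)))
  sc <- score_recovery(sim$truth, res$calls, res$cluster_set, res$labels)
  expect_equal(sc$group_recovery, 1)
  expect_equal(sc$ari, 1)   # one archetype, however many clusters collapse
})

test_that("permuted labels drop group recovery to chance levels", {
  sim <- generate_dataset(simulation_config(
    n_per_archetype = 20, n_down = 0, n_unchanged = 0, n_not_expressed = 0,
    noise_sd = 0, seed = 14))
  res <- suppressWarnings(
    run_pipeline(sim$matrix, ciliaprof_config(k_clusters = 16, seed = 14)))
  sc <- score_recovery(sim$truth, res$calls, res$cluster_set, res$labels)
  set.seed(14)
  shuffled <- sim$truth
  shuffled$true_archetype <- sample(shuffled$true_archetype)
  sc_perm <- score_recovery(shuffled, res$calls, res$cluster_set, res$labels)
  # the empirical chance baseline: the probability two random genes share a
  # group; with balanced archetypes that is far below true recovery
  expect_gt(sc$group_recovery, 0.99)
  expect_lt(sc_perm$group_recovery, 0.5)
})
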