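# Arithmetic oracle for the balanced-partition sizing rule, implemented
# step by step and independently of the package internals.
partition_size_oracle <- function(n_seeds, n_unlabeled, X, ratio, k) {
  pos <- round(X * n_seeds)
  u <- round(ratio * pos)
  n_full <- n_unlabeled %/% u
  rem <- n_unlabeled %% u
  sizes <- rep(u, n_full)
  if (rem > 0) {
    if (rem >= u / 2 && round(rem / ratio) >= k) {
      sizes <- c(sizes, rem)
    } else if (n_full > 0) {
      sizes[n_full] <- sizes[n_full] + rem
    } else {
      sizes <- rem
    }
  }
  list(pos = pos, u = u, sizes = sizes)
}

test_that("balanced partitioning follows the sizing rule exactly", {
  seeds <- sprintf("s%02d", 1:20)
  unlabeled <- sprintf("u%03d", 1:150)
  cfg <- pu_config(folds_k = 10, master_rng_seed = 5)
  parts <- build_balanced_partitions(seeds, unlabeled, cfg, 1)
  oracle <- partition_size_oracle(20, 150, 0.8, 1.5, 10)
  expect_equal(oracle$pos, 16)
  expect_equal(oracle$u, 24)
  expect_equal(oracle$sizes, c(24, 24, 24, 24, 24, 30))  # 7th chunk of 6 merged
  expect_length(parts, 6)
  expect_equal(vapply(parts, function(p) length(p$unlabeled), integer(1)),
               oracle$sizes)
  expect_true(all(vapply(parts, function(p) length(p$positives), integer(1))
                  == 16))
})

test_that("partitions are exhaustive, disjoint, and ratio-respecting", {
  set.seed(2)
  for (rep in 1:5) {
    n_seeds <- sample(10:40, 1)
    n_unl <- sample(80:400, 1)
    seeds <- sprintf("s%03d", seq_len(n_seeds))
    unl <- sprintf("u%03d", seq_len(n_unl))
    cfg <- pu_config(folds_k = 5, master_rng_seed = rep)
    parts <- build_balanced_partitions(seeds, unl, cfg, rep)
    got <- unlist(lapply(parts, `[[`, "unlabeled"))
    expect_equal(sort(got), sort(unl))        # exhaustive
    expect_equal(anyDuplicated(got), 0L)      # disjoint
    ratios <- vapply(parts, function(p)
      length(p$unlabeled) / length(p$positives), numeric(1))
    for (p in parts) expect_length(intersect(p$positives, p$unlabeled), 0)
    # all but the documented merged/resized final set sit near 1:1.5
    expect_true(all(ratios[-length(ratios)] >= 1.0 &
                      ratios[-length(ratios)] <= 2.0))
    expect_true(ratios[length(ratios)] >= 1.0 &&
                  ratios[length(ratios)] <= 2.25)
  }
})

test_that("partition edge cases behave as specified", {
  seeds <- sprintf("s%02d", 1:20)
  cfg <- pu_config(folds_k = 5, master_rng_seed = 1)
  # |unlabeled| == u exactly -> a single set
  parts <- build_balanced_partitions(seeds, sprintf("u%02d", 1:24), cfg, 1)
  expect_length(parts, 1)
  expect_error(build_balanced_partitions(seeds, c("s01", "x"), cfg, 1),
               "overlap")
  expect_error(build_balanced_partitions("s01", sprintf("u%02d", 1:10),
                                         cfg, 1), "at least 2")
})

test_that("cross-validation predicts each gene exactly once, out of bag", {
  fx <- small_bundle()
  cfg <- pu_config(folds_k = 5, master_rng_seed = 3)
  ds <- build_balanced_partitions(fx$seeds, setdiff(fx$pt$gene, fx$seeds),
                                  cfg, 1)[[1]]
  res <- run_cv_on_balanced(ds, fx$pt, "extra_trees", 5, seed = 12)
  expect_equal(sort(res$oob$gene), sort(c(ds$positives, ds$unlabeled)))
  expect_equal(anyDuplicated(res$oob$gene), 0L)
  expect_length(res$fold_aucs, 5)
  # strong planted signal: every fold separates well
  expect_true(all(res$fold_aucs > 0.8))
})

test_that("shuffled labels drive fold AUC to chance", {
  fx <- small_bundle()
  aucs <- vapply(1:20, function(i) {
    genes <- with_rng_stream(i, "null-pick", sample(fx$pt$gene, 40))
    ds <- list(positives = genes[1:16], unlabeled = genes[17:40],
               iteration_index = 1L, set_index = 1L)
    mean(run_cv_on_balanced(ds, fx$pt, "extra_trees", 4,
                            seed = i)$fold_aucs)
  }, numeric(1))
  expect_true(abs(mean(aucs) - 0.5) < 0.15)
})

test_that("the stochastic engine gives every unlabeled gene L records", {
  fx <- small_bundle()
  cfg <- pu_config(iterations_L = 2, folds_k = 5, master_rng_seed = 7)
  res <- run_stochastic_pu(fx$pt, fx$seeds, cfg, "extra_trees")
  unl <- setdiff(fx$pt$gene, fx$seeds)
  counts <- table(res$store$gene[res$store$gene %in% unl])
  expect_true(all(counts == 2))
  # seed genes: X-fraction sample per set, so between 0 and L * M records
  n_sets <- length(unique(paste(res$store$iteration, res$store$set_index)))
  seed_counts <- table(factor(res$store$gene[res$store$gene %in% fx$seeds],
                              levels = fx$seeds))
  expect_true(all(seed_counts <= n_sets))
})

test_that("identical master seeds reproduce the store byte for byte", {
  fx <- small_bundle()
  cfg <- pu_config(iterations_L = 1, folds_k = 5, master_rng_seed = 99)
  r1 <- run_stochastic_pu(fx$pt, fx$seeds, cfg, "extra_trees")
  r2 <- run_stochastic_pu(fx$pt, fx$seeds, cfg, "extra_trees")
  expect_identical(r1$store, r2$store)
  expect_identical(r1$rankings, r2$rankings)
})

test_that("aggregation ranks by mean with deterministic tie-breaks", {
  store <- tibble::tibble(
    gene = c("b", "a", "c", "c"),
    prob = c(0.3, 0.3, 0.9, 0.7)
  )
  rk <- aggregate_predictions(store, seeds = "c", threshold = 0.5,
                              all_genes = c("a", "b", "c", "d"))
  expect_equal(rk$mean_prob[rk$gene == "c"], 0.8)
  expect_equal(rk$median_prob[rk$gene == "c"], 0.8)
  # a and b tie at 0.3 -> alphabetical order
  expect_equal(rk$gene, c("c", "a", "b", "d"))
  expect_equal(rk$rank, 1:4)
  expect_equal(rk$percentile[1], 100)
  expect_equal(rk$status, c("predicted_known", "unlabeled", "unlabeled",
                            "unsupported"))
  expect_equal(rk$n_predictions[rk$gene == "d"], 0L)
})

test_that("threshold splits predicted known and novel genes", {
  store <- tibble::tibble(gene = c("s1", "n1", "n2"),
                          prob = c(0.9, 0.6, 0.4))
  rk <- aggregate_predictions(store, seeds = "s1", threshold = 0.5)
  expect_equal(rk$status[rk$gene == "s1"], "predicted_known")
  expect_equal(rk$status[rk$gene == "n1"], "predicted_novel")
  expect_equal(rk$status[rk$gene == "n2"], "unlabeled")
})

test_that("consensus requires min_support rankings to agree", {
  mk <- function(novel) {
    tibble::tibble(gene = c("x", "y"), mean_prob = c(0.9, 0.9),
                   status = c(if (novel) "predicted_novel" else "unlabeled",
                              "predicted_novel"))
  }
  rankings <- c(lapply(rep(TRUE, 5), mk), lapply(rep(FALSE, 2), mk))
  cons <- consensus_across_classifiers(rankings, min_support = 5)
  expect_equal(cons$predicted_novel, c("x", "y"))
  cons6 <- consensus_across_classifiers(rankings, min_support = 6)
  expect_equal(cons6$predicted_novel, "y")
  one <- consensus_across_classifiers(rankings[1], min_support = 1)
  expect_equal(one$predicted_novel, c("x", "y"))
})

test_that("stability matrix is a correlation matrix with unit diagonal", {
  fx <- small_bundle()
  cfg <- pu_config(iterations_L = 1, folds_k = 5, master_rng_seed = 55)
  r <- stability_across_L(fx$pt, fx$seeds, cfg, "extra_trees",
                          L_values = c(1L, 1L, 2L))
  expect_equal(dim(r), c(3, 3))
  expect_equal(unname(diag(r)), rep(1, 3))
  expect_equal(r, t(r))
  expect_equal(r[1, 2], 1)  # same seed, same L: identical runs
  expect_gte(r[1, 3], 0.8)  # strong signal: stable across L
})

test_that("tidy and glance expose the ranking and run summary", {
  fx <- small_bundle()
  cfg <- pu_config(iterations_L = 1, folds_k = 5, master_rng_seed = 1)
  res <- run_stochastic_pu(fx$pt, fx$seeds, cfg, "extra_trees")
  rk <- tidy(res)
  expect_s3_class(rk, "gene_ranking")
  expect_equal(sort(rk$gene), sort(fx$pt$gene))
  expect_equal(rk$rank, seq_len(nrow(rk)))
  g <- glance(res)
  expect_equal(g$n_seeds, length(fx$seeds))
  expect_equal(g$iterations_L, 1L)
  expect_true(g$mean_auc > 0.8)
  expect_s3_class(autoplot(res), "ggplot")
})
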