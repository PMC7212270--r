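test_that("hypergeometric tail reproduces enumerated worked values", {
  expect_equal(hypergeom_tail(10, 5, 5, 5), 1 / 252, tolerance = 1e-12)
  expect_equal(hypergeom_tail(4, 2, 2, 2), 1 / 6, tolerance = 1e-12)
  expect_equal(hypergeom_tail(30, 7, 9, 0), 1)
  expect_error(hypergeom_tail(10, 11, 5, 2), "invalid")
  expect_error(hypergeom_tail(10, 5, 5, 6), "invalid")
})

test_that("hypergeometric tail matches the enumeration oracle on a grid", {
  set.seed(1)
  for (i in 1:200) {
    N <- sample(2:40, 1)
    K <- sample(0:N, 1)
    n <- sample(0:N, 1)
    k <- sample(max(0, n - (N - K)):min(n, K), 1)
    expect_equal(hypergeom_tail(N, K, n, k), hyper_tail_oracle(N, K, n, k),
                 tolerance = 1e-12,
                 info = sprintf("N=%d K=%d n=%d k=%d", N, K, n, k))
  }
})

mk_ranking <- function(genes) {
  tibble::tibble(gene = genes, mean_prob = seq(1, 0, length.out =
                                                 length(genes)),
                 rank = seq_along(genes),
                 status = "unlabeled")
}

test_that("stepwise enrichment restricts to the universe and hits the floor", {
  genes <- sprintf("g%02d", 1:40)
  rk <- mk_ranking(genes)
  # external list that puts the top predictions first
  ext <- as_ranked_list(tibble::tibble(
    gene = genes, p_value = seq(0.001, 0.999, length.out = 40)))
  curve <- stepwise_enrichment(rk, ext, top_fraction = 0.1)
  K <- 4  # ceiling(0.1 * 40)
  expect_equal(length(attr(curve, "top_set")), K)
  expect_equal(curve$p[K], hypergeom_tail(40, K, K, K), tolerance = 1e-12)
  expect_equal(curve$overlap[40], K)
  expect_equal(curve$p[40], 1)
  expect_true(all(diff(curve$overlap) >= 0))
  expect_true(all(curve$p > 0 & curve$p <= 1))
  expect_true(all(curve$overlap <= pmin(curve$step, K)))
})

test_that("enrichment only sees genes present in both lists", {
  rk <- mk_ranking(sprintf("g%02d", 1:30))
  ext <- as_ranked_list(tibble::tibble(
    gene = c(sprintf("g%02d", 11:30), sprintf("x%02d", 1:10)),
    p_value = seq(0.001, 0.9, length.out = 30)))
  curve <- stepwise_enrichment(rk, ext, top_fraction = 0.2)
  expect_equal(attr(curve, "universe_size"), 20L)
  expect_equal(nrow(curve), 20L)
  expect_true(all(grepl("^g", curve$gene)))
  expect_error(stepwise_enrichment(mk_ranking("zz"), ext), "universe")
})

test_that("the dual-significance area matches a hand trapezoid", {
  toy <- tibble::tibble(step = 1:3, gene = c("a", "b", "c"),
                        overlap = c(1, 2, 2),
                        p = c(0.01, 0.01, 0.5))
  toy$neglog10p <- -log10(toy$p)
  class(toy) <- c("enrichment_curve", class(toy))
  attr(toy, "cutoff_index") <- 3L
  expect_equal(enrichment_area(toy), 2)
  # all-flat curve has zero area
  flat <- toy; flat$p <- rep(1, 3); flat$neglog10p <- 0
  expect_equal(enrichment_area(flat), 0)
  # region truncated by the external cutoff
  expect_equal(enrichment_area(toy, external_cutoff = 1), 0)
})

test_that("signal comparison reproduces the exact small-sample U test", {
  mk_curve <- function(v, cutoff = length(v)) {
    cv <- tibble::tibble(step = seq_along(v), gene = as.character(seq_along(v)),
                         overlap = 0L, p = 10^(-v), neglog10p = v)
    class(cv) <- c("enrichment_curve", class(cv))
    attr(cv, "cutoff_index") <- cutoff
    cv
  }
  p <- compare_signals(mk_curve(c(3, 3, 3)), mk_curve(c(0.1, 0.1, 0.1)))
  expect_equal(p, 0.1, tolerance = 1e-12)
  # rank statistic: invariant to within-sequence order
  p2 <- compare_signals(mk_curve(c(5, 1, 3)), mk_curve(c(0.2, 0.4, 0.1)))
  p3 <- compare_signals(mk_curve(c(1, 3, 5)), mk_curve(c(0.1, 0.2, 0.4)))
  expect_equal(p2, p3)
  expect_gt(compare_signals(mk_curve(c(2, 2, 2)), mk_curve(c(2, 2, 2))),
            0.9)
  expect_error(compare_signals(mk_curve(3, cutoff = 1), mk_curve(c(1, 2))),
               "at least 2")
})

test_that("shuffled controls keep genes and significance profile", {
  ext <- as_ranked_list(tibble::tibble(
    gene = sprintf("g%02d", 1:30),
    p_value = sort(runif(30)), class = "pLoF"))
  sh <- shuffled_control(ext, seed = 9)
  expect_setequal(sh$gene, ext$gene)
  expect_equal(sh$p_value, ext$p_value)
  expect_equal(attr(sh, "cutoff_index"), attr(ext, "cutoff_index"))
  expect_true(all(sh$class == "shuffled"))
})

test_that("score AUC obeys symmetry and separation limits", {
  scores <- setNames(c(5, 4, 3, 2, 1), letters[1:5])
  expect_equal(score_classification_auc(scores, c("a", "b")), 1)
  expect_equal(score_classification_auc(scores, c("d", "e")), 0)
  expect_equal(score_classification_auc(scores, c("a", "e")) +
                 score_classification_auc(-scores, c("a", "e")), 1)
  expect_error(score_classification_auc(scores, letters[1:5]), "both")
  set.seed(3)
  null_aucs <- replicate(50, {
    s <- setNames(rnorm(200), sprintf("g%03d", 1:200))
    score_classification_auc(s, sample(names(s), 40))
  })
  expect_true(abs(mean(null_aucs) - 0.5) < 0.1)
})

test_that("score AUC equals the AUC of a univariate logistic regression", {
  set.seed(8)
  s <- setNames(rnorm(120), sprintf("g%03d", 1:120))
  pos <- sample(names(s), 30)
  y <- as.integer(names(s) %in% pos)
  lp <- predict(glm(y ~ s, family = binomial), type = "response")
  expect_equal(score_classification_auc(s, pos), rank_auc(lp, y),
               tolerance = 1e-12)
})

test_that("masking zero seeds reduces to a standard run", {
  fx <- small_bundle()
  cfg <- pu_config(iterations_L = 1, folds_k = 5, master_rng_seed = 44)
  mv <- seed_masking_validation(fx$pt, fx$seeds, mask_fraction = 0,
                                config = cfg, classifier = "extra_trees")
  ref <- run_stochastic_pu(fx$pt, fx$seeds, cfg, "extra_trees")
  expect_identical(mv$fit$store, ref$store)
  expect_true(is.na(mv$auc_hidden))
  expect_setequal(mv$unmasked, fx$seeds)
})

test_that("hidden seeds are recovered on strong-signal data", {
  fx <- small_bundle()
  cfg <- pu_config(iterations_L = 2, folds_k = 5, master_rng_seed = 45)
  mv <- seed_masking_validation(fx$pt, fx$seeds, mask_fraction = 0.4,
                                config = cfg, classifier = "extra_trees")
  expect_length(mv$hidden, 8)
  expect_gte(mv$auc_hidden, 0.8)
  expect_equal(sort(unique(mv$distributions$group)),
               c("hidden_seed", "unlabeled_sample", "unmasked_seed"))
  hid <- mv$distributions$mean_prob[mv$distributions$group == "hidden_seed"]
  unl <- mv$distributions$mean_prob[mv$distributions$group ==
                                      "unlabeled_sample"]
  expect_gt(median(hid), median(unl))
})
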