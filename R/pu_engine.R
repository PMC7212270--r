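#' Rank-based AUC of a score against binary labels
#'
#' Equivalent to the Mann-Whitney U statistic scaled to `[0, 1]`: the
#' probability that a random positive outscores a random negative (ties
#' counted half).
#'
#' @param scores Numeric vector.
#' @param labels Binary vector (1 = positive) of the same length.
#' @return AUC in `[0, 1]`.
#' @export
rank_auc <- function(scores, labels) {
  labels <- as.integer(labels)
  n1 <- sum(labels == 1)
  n0 <- sum(labels == 0)
  if (n1 == 0 || n0 == 0) {
    stop("rank_auc() needs both classes present", call. = FALSE)
  }
  r <- rank(scores)
  (sum(r[labels == 1]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}

#' Build one stochastic iteration's balanced datasets
#'
#' Shuffles and partitions the unlabeled gene space into chunks whose target
#' size is `u = round(ratio * round(X * |seeds|))`, pairing each chunk with
#' an independent random sample of `round(X * |seeds|)` seed genes, so the
#' positive-to-unlabeled ratio of every set is close to the configured 1:1.5.
#' Remainder rule: a final chunk smaller than `u / 2` is merged into the
#' previous chunk; otherwise it is kept as a smaller set with its positive
#' sample resized to `round(size / ratio)` provided that stays at least
#' `folds_k` (else it is merged anyway).  Every unlabeled gene appears in
#' exactly one set.
#'
#' @param seeds Character vector of seed genes.
#' @param unlabeled Character vector of unlabeled genes (disjoint from
#'   `seeds`).
#' @param config A [pu_config()].
#' @param iteration Iteration index (feeds the RNG substream labels).
#' @return List of balanced datasets, each a list with elements `positives`,
#'   `unlabeled`, `iteration_index`, `set_index`.
#' @export
build_balanced_partitions <- function(seeds, unlabeled,
                                      config = pu_config(),
                                      iteration = 1L) {
  if (length(intersect(seeds, unlabeled)) > 0) {
    stop("seed and unlabeled gene sets overlap", call. = FALSE)
  }
  if (length(seeds) < 2) stop("need at least 2 seed genes", call. = FALSE)
  if (length(unlabeled) == 0) stop("unlabeled gene set is empty",
                                   call. = FALSE)
  ms <- config$master_rng_seed
  pos_n <- max(2L, round(config$seed_sample_fraction_X * length(seeds)))
  u <- max(1L, round(config$pos_to_unlabeled_ratio * pos_n))
  shuffled <- with_rng_stream(ms, sprintf("iter:%d/partition", iteration),
                              sample(unlabeled))
  n <- length(shuffled)
  n_full <- n %/% u
  rem <- n %% u
  chunks <- if (n_full == 0) {
    list(shuffled)
  } else {
    full <- unname(split(shuffled[seq_len(n_full * u)],
                         rep(seq_len(n_full), each = u)))
    if (rem > 0) {
      tail_genes <- shuffled[(n_full * u + 1):n]
      keep_small <- rem >= u / 2 &&
        round(rem / config$pos_to_unlabeled_ratio) >= config$folds_k
      if (keep_small) {
        full[[n_full + 1]] <- tail_genes
      } else {
        full[[n_full]] <- c(full[[n_full]], tail_genes)
      }
    }
    full
  }
  purrr::imap(chunks, function(chunk, j) {
    size <- length(chunk)
    pos_j <- if (size < u) max(2L, round(size / config$pos_to_unlabeled_ratio))
             else pos_n
    pos_j <- min(pos_j, length(seeds))
    positives <- with_rng_stream(
      ms, sprintf("iter:%d/set:%d/pos", iteration, j),
      sample(seeds, pos_j)
    )
    list(positives = positives, unlabeled = chunk,
         iteration_index = as.integer(iteration), set_index = as.integer(j))
  })
}

#' Stratified k-fold cross-validation on one balanced dataset
#'
#' Each gene in the set is predicted exactly once, by the model trained on
#' the other `k - 1` folds (the out-of-bag fold rule); unlabeled genes are
#' treated as negatives both for training and for the per-fold ROC AUC.
#' `k` is auto-reduced to the smaller class size when a set is too small,
#' with a warning.
#'
#' @param ds A balanced dataset from [build_balanced_partitions()].
#' @param table Pre-processed feature table containing all genes of `ds`.
#' @param spec Classifier spec or id.
#' @param k Fold count.
#' @param seed Integer seed (one substream per fold and classifier).
#' @return List with `oob` (tibble: gene, prob, fold) and `fold_aucs`
#'   (numeric, length k).
#' @export
run_cv_on_balanced <- function(ds, table, spec, k = 10L, seed = 1L) {
  spec <- as_classifier_spec(spec)
  genes <- c(ds$positives, ds$unlabeled)
  y <- c(rep(1L, length(ds$positives)), rep(0L, length(ds$unlabeled)))
  if (min(sum(y == 1), sum(y == 0)) < 2) {
    stop("a class has fewer than 2 members in the balanced set",
         call. = FALSE)
  }
  k_eff <- min(k, sum(y == 1), sum(y == 0))
  if (k_eff < k) {
    warning(sprintf("folds reduced from %d to %d for a small balanced set",
                    k, k_eff))
  }
  idx <- match(genes, table$gene)
  if (anyNA(idx)) {
    stop("balanced-set genes missing from the feature table", call. = FALSE)
  }
  X <- feature_matrix(table)[idx, , drop = FALSE]
  folds <- with_rng_stream(seed, "folds", stratified_folds(y, k_eff))
  prob <- numeric(length(y))
  fold_aucs <- numeric(k_eff)
  for (f in seq_len(k_eff)) {
    test <- folds == f
    m <- fit_classifier(spec, X[!test, , drop = FALSE], y[!test],
                        seed = derive_rng_stream(seed, paste0("fold:", f)))
    prob[test] <- predict_proba(m, X[test, , drop = FALSE])
    fold_aucs[f] <- rank_auc(prob[test], y[test])
  }
  list(
    oob = tibble::tibble(gene = genes, prob = prob, fold = folds),
    fold_aucs = fold_aucs
  )
}

#' Run the stochastic positive-unlabeled scheme
#'
#' For each of `L` iterations a fresh random partition of the unlabeled gene
#' space into balanced sets is drawn, each set is scored by stratified
#' k-fold cross-validation, and every out-of-bag probability is stored with
#' full provenance.  Aggregating the store yields the genome-wide ranking.
#' The whole run is reproducible from `config$master_rng_seed`.
#'
#' @param table Pre-processed feature table.
#' @param seeds Character vector of seed (positively labeled) genes; seeds
#'   absent from the table are dropped with a warning.
#' @param config A [pu_config()].
#' @param classifiers Classifier ids to run (default: `config$classifiers`).
#' @return Object of class `pu_result`: list with `store` (tibble: gene,
#'   prob, iteration, set_index, fold, classifier_id), `auc_summary`,
#'   `rankings` (one [aggregate_predictions()] tibble per classifier),
#'   `config`, `seeds`.
#' @export
run_stochastic_pu <- function(table, seeds, config = pu_config(),
                              classifiers = NULL) {
  classifiers <- classifiers %||% config$classifiers
  missing_seeds <- setdiff(seeds, table$gene)
  if (length(missing_seeds) > 0) {
    warning("dropping ", length(missing_seeds),
            " seed gene(s) absent from the feature table")
    seeds <- intersect(seeds, table$gene)
  }
  unlabeled <- setdiff(table$gene, seeds)
  store_parts <- list()
  auc_parts <- list()
  for (i in seq_len(config$iterations_L)) {
    partitions <- build_balanced_partitions(seeds, unlabeled, config, i)
    for (ds in partitions) {
      for (cl in classifiers) {
        cv_seed <- derive_rng_stream(
          config$master_rng_seed,
          sprintf("iter:%d/set:%d/%s", i, ds$set_index, cl)
        )
        res <- run_cv_on_balanced(ds, table, cl, config$folds_k, cv_seed)
        oob <- res$oob
        oob$iteration <- i
        oob$set_index <- ds$set_index
        oob$classifier_id <- cl
        store_parts[[length(store_parts) + 1]] <- oob
        auc_parts[[length(auc_parts) + 1]] <- tibble::tibble(
          classifier_id = cl, iteration = i, set_index = ds$set_index,
          fold = seq_along(res$fold_aucs), auc = res$fold_aucs
        )
      }
    }
  }
  store <- dplyr::bind_rows(store_parts)
  fold_aucs <- dplyr::bind_rows(auc_parts)
  auc_summary <- fold_aucs |>
    dplyr::group_by(.data$classifier_id) |>
    dplyr::summarise(mean_auc = mean(.data$auc), sd_auc = stats::sd(.data$auc),
                     n_folds = dplyr::n(), .groups = "drop")
  rankings <- purrr::map(rlang::set_names(classifiers), function(cl) {
    aggregate_predictions(store[store$classifier_id == cl, ], seeds,
                          threshold = config$prediction_threshold,
                          all_genes = table$gene)
  })
  structure(
    list(store = store, fold_aucs = fold_aucs, auc_summary = auc_summary,
         rankings = rankings, config = config, seeds = seeds,
         classifiers = classifiers),
    class = "pu_result"
  )
}

#' Aggregate out-of-bag probabilities into a gene ranking
#'
#' Genes are ranked by the mean of their out-of-bag probability
#' distributions (descending; ties broken by gene symbol, ascending).
#' Status: a seed gene above the threshold is `predicted_known`; a non-seed
#' gene above it is `predicted_novel`; below-threshold genes keep `seed` /
#' `unlabeled`; genes with no stored prediction are `unsupported` and rank
#' last.
#'
#' @param store Tibble with at least `gene` and `prob` columns.
#' @param seeds Seed gene symbols.
#' @param threshold Prediction-probability threshold (default 0.5).
#' @param all_genes Optional full gene universe (to surface `unsupported`
#'   genes); defaults to the genes present in `store`.
#' @return Tibble of class `gene_ranking`: gene, mean_prob, median_prob,
#'   n_predictions, rank, percentile, status.
#' @export
aggregate_predictions <- function(store, seeds, threshold = 0.5,
                                  all_genes = NULL) {
  agg <- store |>
    dplyr::group_by(.data$gene) |>
    dplyr::summarise(mean_prob = mean(.data$prob),
                     median_prob = stats::median(.data$prob),
                     n_predictions = dplyr::n(), .groups = "drop")
  all_genes <- all_genes %||% agg$gene
  missing <- setdiff(all_genes, agg$gene)
  if (length(missing) > 0) {
    agg <- dplyr::bind_rows(agg, tibble::tibble(
      gene = missing, mean_prob = NA_real_, median_prob = NA_real_,
      n_predictions = 0L
    ))
  }
  agg <- agg[order(-ifelse(is.na(agg$mean_prob), -Inf, agg$mean_prob),
                   agg$gene), ]
  n <- nrow(agg)
  agg$rank <- seq_len(n)
  agg$percentile <- (1 - (agg$rank - 1) / n) * 100
  is_seed <- agg$gene %in% seeds
  above <- !is.na(agg$mean_prob) & agg$mean_prob > threshold
  agg$status <- dplyr::case_when(
    agg$n_predictions == 0 ~ "unsupported",
    is_seed & above ~ "predicted_known",
    is_seed ~ "seed",
    above ~ "predicted_novel",
    TRUE ~ "unlabeled"
  )
  class(agg) <- c("gene_ranking", class(agg))
  agg
}

#' Cross-classifier consensus gene sets
#'
#' A gene enters a consensus set when at least `min_support` of the supplied
#' rankings flag it (default 5, mirroring the five-of-seven classifier
#' consensus rule).
#'
#' @param rankings List of `gene_ranking` tibbles.
#' @param min_support Minimum number of supporting rankings.
#' @return List with character vectors `predicted_known` and
#'   `predicted_novel` (sorted).
#' @export
consensus_across_classifiers <- function(rankings, min_support = 5L) {
  stopifnot(length(rankings) >= 1, min_support <= length(rankings))
  count_status <- function(status) {
    tab <- table(unlist(purrr::map(rankings,
                                   ~ .x$gene[.x$status == status])))
    sort(names(tab)[tab >= min_support])
  }
  list(predicted_known = count_status("predicted_known"),
       predicted_novel = count_status("predicted_novel"))
}

#' Stability of mean probabilities across iteration counts
#'
#' Re-runs the PU scheme for each value of `L` (independent partitions per
#' run, reproducible from the master seed) and returns the matrix of Pearson
#' correlations between the gene-wise mean probabilities — the check that
#' the ranking profile is insensitive to the iteration count.
#'
#' @param table Pre-processed feature table.
#' @param seeds Seed genes.
#' @param config A [pu_config()] (its `iterations_L` is overridden).
#' @param classifier Classifier id to use.
#' @param L_values Integer vector (>= 2 values).
#' @return Symmetric correlation matrix with `L_values` as dimnames.
#' @export
stability_across_L <- function(table, seeds, config = pu_config(),
                               classifier = "extra_trees",
                               L_values = c(1L, 10L)) {
  stopifnot(length(L_values) >= 2)
  means <- purrr::map(L_values, function(L) {
    cfg <- config
    cfg$iterations_L <- as.integer(L)
    cfg$master_rng_seed <- derive_rng_stream(config$master_rng_seed,
                                             paste0("stability/L:", L))
    res <- run_stochastic_pu(table, seeds, cfg, classifiers = classifier)
    r <- res$rankings[[classifier]]
    stats::setNames(r$mean_prob, r$gene)
  })
  genes <- Reduce(intersect, purrr::map(means, names))
  m <- vapply(means, function(x) x[genes], numeric(length(genes)))
  r <- stats::cor(m)
  dimnames(r) <- list(paste0("L", L_values), paste0("L", L_values))
  r
}

#' @export
print.pu_result <- function(x, ...) {
  cat("<pu_result>", length(unique(x$store$gene)), "genes scored,",
      length(x$seeds), "seeds, L =", x$config$iterations_L, "\n")
  print(x$auc_summary)
  invisible(x)
}

#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' Tidy a PU run into its gene ranking
#'
#' @param x A `pu_result`.
#' @param classifier Which classifier's ranking (default: first run).
#' @param ... Ignored.
#' @return The `gene_ranking` tibble.
#' @export
tidy.pu_result <- function(x, classifier = NULL, ...) {
  classifier <- classifier %||% x$classifiers[1]
  x$rankings[[classifier]]
}

#' One-row summary of a PU run
#'
#' @param x A `pu_result`.
#' @param ... Ignored.
#' @return Tibble with run dimensions and pooled AUC.
#' @export
glance.pu_result <- function(x, ...) {
  tibble::tibble(
    n_genes = length(unique(x$store$gene)),
    n_seeds = length(x$seeds),
    iterations_L = x$config$iterations_L,
    folds_k = x$config$folds_k,
    n_classifiers = length(x$classifiers),
    n_oob_records = nrow(x$store),
    mean_auc = mean(x$fold_aucs$auc),
    sd_auc = stats::sd(x$fold_aucs$auc)
  )
}

#' Plot the aggregated probability distributions of a PU run
#'
#' @param object A `pu_result`.
#' @param classifier Which classifier's ranking to show.
#' @param ... Ignored.
#' @return A ggplot: mean-probability densities by gene status.
#' @export
autoplot.pu_result <- function(object, classifier = NULL, ...) {
  r <- tidy(object, classifier)
  r <- r[!is.na(r$mean_prob), ]
  r$group <- ifelse(r$status %in% c("seed", "predicted_known"),
                    "seed", "non-seed")
  ggplot2::ggplot(r, ggplot2::aes(.data$mean_prob, fill = .data$group)) +
    ggplot2::geom_histogram(bins = 40, alpha = 0.7, position = "identity") +
    ggplot2::labs(x = "mean out-of-bag probability", y = "genes") +
    ggplot2::theme_minimal()
}

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' @importFrom rlang .data
NULL
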