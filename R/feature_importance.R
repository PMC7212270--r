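#' One shadow-feature importance run on a balanced dataset
#'
#' Boruta-style selection: at every internal iteration each feature gets a
#' shadow copy whose values are permuted across genes (destroying any label
#' association), a random-forest importance is computed over real and shadow
#' features together, and a feature scores a hit when its importance exceeds
#' the maximum shadow importance.  After `n_internal` iterations a two-sided
#' binomial test on the hit count (null p = 0.5, alpha 0.01, one-sided tails
#' at alpha/2) labels the feature `confirmed` (significantly above),
#' `rejected` (significantly below) or `tentative`.  The per-iteration Z
#' score is `(importance - mean shadow importance) / sd shadow importance`.
#'
#' The importance backbone is always the random-forest family, regardless of
#' which classifier produces the gene ranking.
#'
#' @param ds Balanced dataset from [build_balanced_partitions()].
#' @param table Pre-processed feature table.
#' @param n_internal Internal iterations (>= 10; 100 in a full run).
#' @param seed Integer seed.
#' @param alpha Two-sided significance level of the binomial test.
#' @param num_trees Trees per internal forest.
#' @return Tibble of class `boruta_run`: feature, hits, n_internal, label,
#'   mean_z, and a `z_scores` list-column of per-iteration Z values.
#' @export
boruta_single_run <- function(ds, table, n_internal = 100L, seed = 1L,
                              alpha = 0.01, num_trees = 100L) {
  stopifnot(n_internal >= 10)
  genes <- c(ds$positives, ds$unlabeled)
  y <- c(rep(1L, length(ds$positives)), rep(0L, length(ds$unlabeled)))
  idx <- match(genes, table$gene)
  stopifnot(!anyNA(idx))
  X <- feature_matrix(table)[idx, , drop = FALSE]
  p <- ncol(X)
  feats <- colnames(X)
  hits <- integer(p)
  z <- matrix(NA_real_, n_internal, p, dimnames = list(NULL, feats))
  df_y <- factor(y, levels = 0:1)
  for (t in seq_len(n_internal)) {
    it_seed <- derive_rng_stream(seed, paste0("boruta:", t))
    imp <- with_rng_stream(seed, paste0("boruta:", t), {
      shadow <- apply(X, 2, sample)
      colnames(shadow) <- paste0(".shadow_", feats)
      df <- as.data.frame(cbind(X, shadow))
      df$.y <- df_y
      fit <- ranger::ranger(.y ~ ., data = df, num.trees = num_trees,
                            importance = "impurity", probability = TRUE,
                            num.threads = 1L, seed = it_seed)
      fit$variable.importance
    })
    real_imp <- imp[feats]
    shadow_imp <- imp[paste0(".shadow_", feats)]
    hits <- hits + (real_imp > max(shadow_imp))
    s <- stats::sd(shadow_imp)
    z[t, ] <- if (s > 0) (real_imp - mean(shadow_imp)) / s else 0
  }
  p_above <- stats::pbinom(hits - 1, n_internal, 0.5, lower.tail = FALSE)
  p_below <- stats::pbinom(hits, n_internal, 0.5)
  label <- dplyr::case_when(
    p_above < alpha / 2 ~ "confirmed",
    p_below < alpha / 2 ~ "rejected",
    TRUE ~ "tentative"
  )
  out <- tibble::tibble(
    feature = feats, hits = hits, n_internal = as.integer(n_internal),
    label = label, mean_z = colMeans(z),
    z_scores = lapply(seq_len(p), function(j) z[, j])
  )
  class(out) <- c("boruta_run", class(out))
  out
}

#' Shadow-feature importance over many stochastic balanced datasets
#'
#' Draws balanced datasets exactly as the PU engine does (fresh partitions
#' per iteration) until `n_sets` have been processed, runs
#' [boruta_single_run()] on each, and returns the list of per-run results
#' ready for [consensus_labels()].
#'
#' @param table Pre-processed feature table.
#' @param seeds Seed genes.
#' @param config A [pu_config()].
#' @param n_sets Number of balanced datasets (100 in a full run).
#' @param n_internal Internal iterations per run.
#' @return List of `boruta_run` tibbles.
#' @export
run_boruta <- function(table, seeds, config = pu_config(), n_sets = 100L,
                       n_internal = 100L) {
  seeds <- intersect(seeds, table$gene)
  unlabeled <- setdiff(table$gene, seeds)
  runs <- list()
  iteration <- 0L
  while (length(runs) < n_sets) {
    iteration <- iteration + 1L
    for (ds in build_balanced_partitions(seeds, unlabeled, config,
                                         iteration)) {
      if (length(runs) >= n_sets) break
      run_seed <- derive_rng_stream(
        config$master_rng_seed,
        sprintf("boruta/iter:%d/set:%d", iteration, ds$set_index)
      )
      runs[[length(runs) + 1]] <-
        boruta_single_run(ds, table, n_internal, seed = run_seed)
    }
  }
  runs
}

#' Consensus feature labels across shadow-importance runs
#'
#' A feature is consensus-`confirmed` when the fraction of runs labelling it
#' confirmed reaches `confirmed_frac` (default 0.9; lowered to 0.6 for
#' small, high-variance seed sets), consensus-`rejected` when its rejected
#' fraction reaches `rejected_frac` (default 0.9), and `tentative`
#' otherwise.  The consensus is a pure function of the label counts.  Mean Z
#' scores are min-max normalized to `[0, 1]` across features.
#'
#' @param runs List of `boruta_run` tibbles.
#' @param confirmed_frac,rejected_frac Label-fraction thresholds.
#' @return Tibble of class `boruta_consensus`: feature, n_runs,
#'   n_confirmed, n_tentative, n_rejected, consensus_label, mean_z,
#'   normalized_z.
#' @export
consensus_labels <- function(runs, confirmed_frac = 0.9,
                             rejected_frac = 0.9) {
  stopifnot(length(runs) >= 1)
  all <- dplyr::bind_rows(purrr::map(runs, ~ .x[c("feature", "label",
                                                  "mean_z")]))
  out <- all |>
    dplyr::group_by(.data$feature) |>
    dplyr::summarise(
      n_runs = dplyr::n(),
      n_confirmed = sum(.data$label == "confirmed"),
      n_tentative = sum(.data$label == "tentative"),
      n_rejected = sum(.data$label == "rejected"),
      mean_z = mean(.data$mean_z),
      .groups = "drop"
    ) |>
    dplyr::mutate(consensus_label = dplyr::case_when(
      .data$n_confirmed / .data$n_runs >= confirmed_frac ~ "confirmed",
      .data$n_rejected / .data$n_runs >= rejected_frac ~ "rejected",
      TRUE ~ "tentative"
    ))
  out$normalized_z <- if (length(unique(out$mean_z)) > 1) {
    normalize_scores(out$mean_z)
  } else rep(NA_real_, nrow(out))
  out <- out[order(-out$mean_z), ]
  class(out) <- c("boruta_consensus", class(out))
  out
}

#' Min-max normalization of importance scores
#'
#' Maps scores affinely onto `[0, 1]`: `(z - min) / (max - min)`.
#'
#' @param mean_z Numeric vector with at least two distinct values.
#' @return Normalized scores attaining 0 and 1 at the extremes.
#' @export
normalize_scores <- function(mean_z) {
  rng <- range(mean_z)
  if (diff(rng) == 0) {
    stop("cannot min-max normalize a constant vector", call. = FALSE)
  }
  (mean_z - rng[1]) / diff(rng)
}

#' Restrict a feature table to consensus-confirmed features
#'
#' The confirmed-features-only training mode: the returned table plugs
#' directly into [run_stochastic_pu()].
#'
#' @param table Feature table.
#' @param consensus A `boruta_consensus` tibble.
#' @return Table with only confirmed feature columns (plus `gene`).
#' @export
confirmed_only_mode <- function(table, consensus) {
  confirmed <- consensus$feature[consensus$consensus_label == "confirmed"]
  confirmed <- intersect(feature_cols(table), confirmed)
  if (length(confirmed) == 0) {
    stop("no consensus-confirmed features; use feature_selection = \"all\"",
         call. = FALSE)
  }
  table[c("gene", confirmed)]
}

#' Plot consensus feature importances
#'
#' @param object A `boruta_consensus`.
#' @param top_n Show this many top features by mean Z.
#' @param ... Ignored.
#' @return A ggplot bar chart of normalized Z scores coloured by label.
#' @export
autoplot.boruta_consensus <- function(object, top_n = 30, ...) {
  df <- utils::head(object[order(-object$mean_z), ], top_n)
  df$feature <- factor(df$feature, levels = rev(df$feature))
  ggplot2::ggplot(df, ggplot2::aes(.data$normalized_z, .data$feature,
                                   fill = .data$consensus_label)) +
    ggplot2::geom_col() +
    ggplot2::labs(x = "normalized mean Z", y = NULL, fill = "consensus") +
    ggplot2::theme_minimal()
}
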