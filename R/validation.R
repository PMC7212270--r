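#' Upper-tail hypergeometric probability
#'
#' `P(X >= k)` when drawing `n` items without replacement from a universe of
#' `N` containing `K` successes — the enrichment direction of the stepwise
#' overlap test.
#'
#' @param N Universe size.
#' @param K Number of successes in the universe.
#' @param n Sample (draw) size.
#' @param k Observed successes in the sample.
#' @return The tail probability in `(0, 1]`.
#' @examples
#' hypergeom_tail(10, 5, 5, 5)  # 1 / choose(10, 5) = 1/252
#' @export
hypergeom_tail <- function(N, K, n, k) {
  if (any(K > N) || any(n > N) || any(k < 0) || any(k > pmin(n, K))) {
    stop("invalid hypergeometric parameters: need 0 <= k <= min(n, K) <= N",
         call. = FALSE)
  }
  stats::phyper(k - 1, K, N - K, n, lower.tail = FALSE)
}

#' Stepwise hypergeometric enrichment along an external ranked list
#'
#' Restricts both the gene ranking and the external list to their common
#' gene universe, takes the top `ceiling(top_fraction * N)` ranked genes as
#' the prediction set, and then walks down the external list one gene at a
#' time: at step `i` the overlap between the top `i` external genes and the
#' prediction set is scored with the upper-tail hypergeometric test.  A
#' deep early dip of the p-value curve means the external study's strongest
#' signals are concentrated among the top predictions.
#'
#' @param ranking A `gene_ranking` tibble (from [aggregate_predictions()]).
#' @param external An `external_ranked_list`.
#' @param top_fraction Fraction of the universe treated as top predictions
#'   (default 0.05).
#' @return Tibble of class `enrichment_curve` with columns `step`, `gene`,
#'   `overlap`, `p`, `neglog10p`; attributes `universe_size`, `top_set`,
#'   `cutoff_index` (last external position with p < 0.05 within the
#'   universe) and `top_fraction`.
#' @export
stepwise_enrichment <- function(ranking, external, top_fraction = 0.05) {
  universe <- intersect(ranking$gene, external$gene)
  if (length(universe) == 0) {
    stop("empty universe: ranking and external list share no genes",
         call. = FALSE)
  }
  rk <- ranking[ranking$gene %in% universe, ]
  rk <- rk[order(rk$rank), ]
  N <- length(universe)
  K <- ceiling(top_fraction * N)
  top_set <- rk$gene[seq_len(K)]
  ext <- external[external$gene %in% universe, ]
  member <- ext$gene %in% top_set
  overlap <- cumsum(member)
  steps <- seq_len(N)
  p <- hypergeom_tail(N, K, steps, overlap)
  cut <- which(ext$p_value < 0.05)
  out <- tibble::tibble(step = steps, gene = ext$gene, overlap = overlap,
                        p = p, neglog10p = -log10(p))
  attr(out, "universe_size") <- N
  attr(out, "top_set") <- top_set
  attr(out, "cutoff_index") <- if (length(cut)) max(cut) else 0L
  attr(out, "top_fraction") <- top_fraction
  class(out) <- c("enrichment_curve", class(out))
  out
}

#' Area under the dual-significance region of an enrichment curve
#'
#' Trapezoidal area of `-log10(p)` over the steps where both the
#' hypergeometric p-value is below 0.05 and the step lies within the
#' external study's own significance cutoff — the shaded-region measure used
#' to compare signal magnitudes (e.g. pLoF vs synonymous area ratios).
#' Disjoint significant sub-regions are summed; an isolated single step has
#' zero width and contributes nothing.
#'
#' @param curve An `enrichment_curve`.
#' @param external_cutoff Step index of the external significance cutoff;
#'   defaults to the curve's `cutoff_index` attribute.
#' @return Non-negative area.
#' @export
enrichment_area <- function(curve,
                            external_cutoff = attr(curve, "cutoff_index")) {
  sig <- curve$p < 0.05 & curve$step <= external_cutoff
  if (!any(sig)) return(0)
  y <- curve$neglog10p
  idx <- which(sig)
  area <- 0
  for (i in idx[-length(idx)]) {
    if (sig[i + 1]) area <- area + (y[i] + y[i + 1]) / 2
  }
  area
}

#' Compare two enrichment signals (Mann-Whitney U)
#'
#' Two-sided Mann-Whitney U test on the `-log10(p)` step sequences of two
#' curves, each truncated at its own external cutoff.  The monotone
#' transform does not affect U; it is kept for presentation symmetry with
#' the curves themselves.  For very small sequences the exact permutation
#' distribution of U is enumerated (valid under ties); longer sequences use
#' the standard normal approximation.
#'
#' @param curve_a,curve_b `enrichment_curve` objects.
#' @return The two-sided p-value.
#' @export
compare_signals <- function(curve_a, curve_b) {
  trunc_seq <- function(cv) {
    cut <- attr(cv, "cutoff_index")
    if (is.null(cut) || cut == 0) cut <- nrow(cv)
    cv$neglog10p[seq_len(cut)]
  }
  a <- trunc_seq(curve_a)
  b <- trunc_seq(curve_b)
  if (length(a) < 2 || length(b) < 2) {
    stop("enrichment signals need at least 2 steps each", call. = FALSE)
  }
  n <- length(a); m <- length(b)
  if (choose(n + m, n) <= 20000) {
    pooled <- c(a, b)
    r <- rank(pooled)
    u_stat <- function(idx) sum(r[idx]) - n * (n + 1) / 2
    obs <- u_stat(seq_len(n))
    perms <- utils::combn(n + m, n)
    us <- apply(perms, 2, u_stat)
    centre <- n * m / 2
    mean(abs(us - centre) >= abs(obs - centre) - 1e-12)
  } else {
    suppressWarnings(stats::wilcox.test(a, b))$p.value
  }
}

#' Shuffled control for an external ranked list
#'
#' Permutes the gene order uniformly while keeping the p-values in their
#' original ascending slots, so the ranking carries no information but the
#' significance profile (and hence `cutoff_index`) is unchanged.  The class
#' label is set to `"shuffled"`.
#'
#' @param external An `external_ranked_list`.
#' @param seed Integer seed.
#' @return A shuffled `external_ranked_list`.
#' @export
shuffled_control <- function(external, seed = 1L) {
  genes <- with_rng_stream(seed, "shuffle", sample(external$gene))
  as_ranked_list(tibble::tibble(gene = genes, p_value = external$p_value,
                                class = "shuffled"))
}

#' Rank-based classification AUC of a gene score
#'
#' AUC of `scores` for discriminating `positives` from all other scored
#' genes.  Identical to the AUC of a univariate logistic regression on the
#' score, since a monotone link cannot change the ranking.
#'
#' @param scores Named numeric vector (names = genes).
#' @param positives Character vector of positive genes.
#' @return AUC in `[0, 1]`.
#' @export
score_classification_auc <- function(scores, positives) {
  labels <- as.integer(names(scores) %in% positives)
  if (length(unique(labels)) < 2) {
    stop("need both positive and negative genes among the scores",
         call. = FALSE)
  }
  rank_auc(scores, labels)
}

#' Seed-masking validation of the PU ranking
#'
#' Hides a random fraction of the seed genes (treating them as unlabeled),
#' reruns the PU engine with only the unmasked seeds as positives, and asks
#' whether the hidden seeds are still recovered: their mean-probability
#' distribution should match the unmasked seeds and separate cleanly from a
#' size-matched random sample of genuinely unlabeled genes.
#'
#' @param table Pre-processed feature table.
#' @param seeds Full seed gene set.
#' @param mask_fraction Fraction of seeds to hide, in `[0, 1)` (default
#'   0.4).
#' @param config A [pu_config()].
#' @param classifier Classifier id for the run.
#' @return List with `distributions` (tibble: gene, group, mean_prob for
#'   unmasked_seed / hidden_seed / unlabeled_sample), `auc_hidden`,
#'   `auc_unmasked` (score AUC of each seed group against all non-seed
#'   genes), `mw_p_hidden_vs_unmasked` (two-sided Mann-Whitney), and the
#'   full `pu_result` as `fit`.
#' @export
seed_masking_validation <- function(table, seeds, mask_fraction = 0.4,
                                    config = pu_config(),
                                    classifier = "extra_trees") {
  stopifnot(mask_fraction >= 0, mask_fraction < 1)
  seeds <- intersect(seeds, table$gene)
  n_hidden <- round(mask_fraction * length(seeds))
  hidden <- with_rng_stream(config$master_rng_seed, "mask",
                            sample(seeds, n_hidden))
  unmasked <- setdiff(seeds, hidden)
  if (length(unmasked) < config$folds_k) {
    stop("too few unmasked seeds (", length(unmasked), ") for folds_k = ",
         config$folds_k, call. = FALSE)
  }
  fit <- run_stochastic_pu(table, unmasked, config,
                           classifiers = classifier)
  rk <- fit$rankings[[classifier]]
  scores <- stats::setNames(rk$mean_prob, rk$gene)
  scores <- scores[!is.na(scores)]
  non_seed <- setdiff(names(scores), seeds)
  sampled_unlabeled <- with_rng_stream(
    config$master_rng_seed, "mask/unlabeled-sample",
    sample(non_seed, min(max(length(hidden), 1L), length(non_seed)))
  )
  grp <- function(genes, g) {
    genes <- intersect(genes, names(scores))
    tibble::tibble(gene = genes, group = g, mean_prob = scores[genes])
  }
  distributions <- dplyr::bind_rows(
    grp(unmasked, "unmasked_seed"),
    grp(hidden, "hidden_seed"),
    grp(sampled_unlabeled, "unlabeled_sample")
  )
  auc_for <- function(pos) {
    sub <- scores[c(intersect(pos, names(scores)), non_seed)]
    score_classification_auc(sub, pos)
  }
  mw <- if (n_hidden > 0) {
    suppressWarnings(stats::wilcox.test(
      scores[intersect(hidden, names(scores))],
      scores[intersect(unmasked, names(scores))]
    ))$p.value
  } else NA_real_
  list(
    distributions = distributions,
    auc_hidden = if (n_hidden > 0) auc_for(hidden) else NA_real_,
    auc_unmasked = auc_for(unmasked),
    mw_p_hidden_vs_unmasked = mw,
    hidden = hidden, unmasked = unmasked,
    fit = fit
  )
}

#' Plot an enrichment curve
#'
#' @param object An `enrichment_curve`.
#' @param ... Ignored.
#' @return A ggplot of `-log10(p)` against the external-list step, with the
#'   hypergeometric and external significance cutoffs marked.
#' @export
autoplot.enrichment_curve <- function(object, ...) {
  cut <- attr(object, "cutoff_index")
  g <- ggplot2::ggplot(object, ggplot2::aes(.data$step, .data$neglog10p)) +
    ggplot2::geom_line() +
    ggplot2::geom_hline(yintercept = -log10(0.05), linetype = "dashed") +
    ggplot2::labs(x = "external ranked-list step",
                  y = expression(-log[10](p))) +
    ggplot2::theme_minimal()
  if (!is.null(cut) && cut > 0) {
    g <- g + ggplot2::geom_vline(xintercept = cut, linetype = "dotted")
  }
  g
}
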