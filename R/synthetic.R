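#' Generate a gene-by-feature table with planted ground truth
#'
#' Emulates the statistical structure the PU scheme relies on: a subset of
#' informative features whose distributions differ between a planted set of
#' true-positive genes and the background.  Background continuous features
#' are standard normal; informative continuous features are shifted by
#' `effect_size_d` standard deviations for true positives.  Binary features
#' are Bernoulli flags (background rate 0.2); informative binary features
#' raise the true-positive rate on the logit scale by `effect_size_d`.
#' Missingness is injected completely at random over all feature cells.
#' Each injected correlated pair appends a near-duplicate of a random
#' continuous column (noise sd 0.15, population `|r| > 0.95`).  Seed genes
#' are the planted true positives, optionally with a `contamination`
#' fraction replaced by random background genes (mislabeled seeds).
#'
#' @param n_genes,n_features Table dimensions (before duplicate columns).
#' @param n_informative Number of informative features (`<= n_features`).
#' @param n_seeds Number of seed genes (`<= n_genes`).
#' @param effect_size_d Standardized mean shift per informative feature.
#' @param missing_fraction MCAR missingness fraction.
#' @param n_corr_pairs Number of appended near-duplicate columns.
#' @param binary_fraction Fraction of features generated as binary flags.
#' @param contamination Fraction of seeds replaced by background genes.
#' @param seed Integer seed; the fixture is a pure function of its
#'   arguments.
#' @return List with `table` (tibble, first column `gene`), `seeds`
#'   (character) and `truth` (list of class `synthetic_truth`:
#'   true_positive_genes, informative_features, effect_size_d,
#'   missing_fraction, n_corr_pairs, binary_fraction).
#' @export
generate_table <- function(n_genes = 1000L, n_features = 50L,
                           n_informative = 10L, n_seeds = 50L,
                           effect_size_d = 2, missing_fraction = 0.1,
                           n_corr_pairs = 0L, binary_fraction = 0.3,
                           contamination = 0, seed = 1L) {
  stopifnot(n_informative <= n_features, n_seeds <= n_genes,
            missing_fraction >= 0, missing_fraction < 1,
            contamination >= 0, contamination <= 1)
  genes <- sprintf("G%05d", seq_len(n_genes))
  with_rng_stream(seed, "synthetic/table", {
    tp <- sample(genes, n_seeds)
    is_tp <- genes %in% tp
    n_binary <- round(binary_fraction * n_features)
    kinds <- sample(c(rep("binary", n_binary),
                      rep("continuous", n_features - n_binary)))
    informative <- sort(sample(n_features, n_informative))
    p0 <- 0.2
    p1 <- stats::plogis(stats::qlogis(p0) + effect_size_d)
    cols <- lapply(seq_len(n_features), function(j) {
      inf <- j %in% informative
      if (kinds[j] == "binary") {
        rate <- ifelse(is_tp & inf, p1, p0)
        stats::rbinom(n_genes, 1, rate)
      } else {
        stats::rnorm(n_genes) + ifelse(is_tp & inf, effect_size_d, 0)
      }
    })
    names(cols) <- sprintf("feat_%03d%s", seq_len(n_features),
                           ifelse(seq_len(n_features) %in% informative,
                                  "_inf", ""))
    cont_idx <- which(kinds == "continuous")
    if (n_corr_pairs > 0) {
      src <- sample(cont_idx, n_corr_pairs, replace = n_corr_pairs >
                      length(cont_idx))
      for (s in seq_along(src)) {
        nm <- paste0(names(cols)[src[s]], "_dup", s)
        cols[[nm]] <- cols[[src[s]]] + stats::rnorm(n_genes, sd = 0.15)
      }
    }
    tbl <- dplyr::bind_cols(tibble::tibble(gene = genes),
                            tibble::as_tibble(cols))
    if (missing_fraction > 0) {
      feats <- setdiff(names(tbl), "gene")
      for (f in feats) {
        miss <- stats::runif(n_genes) < missing_fraction
        tbl[[f]][miss] <- NA_real_
      }
    }
    seeds_out <- tp
    if (contamination > 0) {
      n_cont <- round(contamination * n_seeds)
      if (n_cont > 0) {
        swap_out <- sample(seeds_out, n_cont)
        swap_in <- sample(setdiff(genes, tp), n_cont)
        seeds_out <- c(setdiff(seeds_out, swap_out), swap_in)
      }
    }
    truth <- structure(
      list(true_positive_genes = tp,
           informative_features = names(cols)[informative],
           effect_size_d = effect_size_d,
           missing_fraction = missing_fraction,
           n_corr_pairs = n_corr_pairs,
           binary_fraction = binary_fraction),
      class = "synthetic_truth"
    )
    list(table = tbl, seeds = seeds_out, truth = truth)
  })
}

#' Generate an external ranked gene list correlated with ground truth
#'
#' Stands in for a rare-variant collapsing-analysis ranking.  Each true
#' positive is "detected" with probability `signal_strength`, in which case
#' its p-value is drawn uniformly from `(0, 1e-4)`; all other p-values are
#' uniform on `(0, 1)`.  At `signal_strength = 0` the list is pure noise; at
#' 1 every true positive precedes essentially all null genes.
#'
#' @param truth A `synthetic_truth` (or a character vector of true-positive
#'   genes).
#' @param all_genes Full gene universe.
#' @param signal_strength Detection probability in `[0, 1]`.
#' @param seed Integer seed.
#' @param class_label Class annotation for the list (default `"pLoF"`).
#' @return An `external_ranked_list`.
#' @export
generate_external_list <- function(truth, all_genes, signal_strength = 0.8,
                                   seed = 1L, class_label = "pLoF") {
  stopifnot(signal_strength >= 0, signal_strength <= 1)
  tp <- if (inherits(truth, "synthetic_truth")) truth$true_positive_genes
        else as.character(truth)
  with_rng_stream(seed, "synthetic/external", {
    p <- stats::runif(length(all_genes))
    detected <- all_genes %in% tp &
      stats::runif(length(all_genes)) < signal_strength
    p[detected] <- stats::runif(sum(detected), 0, 1e-4)
    as_ranked_list(tibble::tibble(gene = all_genes, p_value = p,
                                  class = class_label))
  })
}

#' Standard synthetic input bundles
#'
#' Three reproducible profiles: `"small"` (300 genes, 30 features, 20
#' seeds) for unit tests; `"ckd_like"` (5,000 genes, 100 features, 150
#' seeds) emulating a disease with a rich seed set; `"als_like"` (5,000
#' genes, 100 features, 25 seeds) stressing the small-seed path, where many
#' more balanced sets per iteration are needed to cover the unlabeled
#' space.  All profiles plant 10 informative features (8 for `"small"`) at
#' effect size d = 2 with 10% missingness, a few near-duplicate columns and
#' a 30% binary-feature fraction.
#'
#' @param profile One of `"small"`, `"ckd_like"`, `"als_like"`.
#' @param seed Integer seed.
#' @param signal_strength Signal strength of the bundled external list.
#' @return List with `table`, `seeds`, `truth`, `external`.
#' @export
standard_fixture <- function(profile = c("small", "ckd_like", "als_like"),
                             seed = 1L, signal_strength = 0.8) {
  profile <- match.arg(profile)
  args <- switch(profile,
    small = list(n_genes = 300L, n_features = 30L, n_informative = 8L,
                 n_seeds = 20L),
    ckd_like = list(n_genes = 5000L, n_features = 100L, n_informative = 10L,
                    n_seeds = 150L),
    als_like = list(n_genes = 5000L, n_features = 100L, n_informative = 10L,
                    n_seeds = 25L)
  )
  args <- c(args, list(effect_size_d = 2, missing_fraction = 0.1,
                       n_corr_pairs = if (profile == "small") 2L else 5L,
                       binary_fraction = 0.3,
                       seed = derive_rng_stream(seed, paste0("fixture/",
                                                             profile))))
  bundle <- do.call(generate_table, args)
  bundle$external <- generate_external_list(
    bundle$truth, bundle$table$gene, signal_strength,
    seed = derive_rng_stream(seed, paste0("fixture/", profile, "/external"))
  )
  bundle
}
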