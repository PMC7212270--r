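#' Per-feature metadata
#'
#' Derives, for every feature column, its kind (binary = at most two distinct
#' observed values, otherwise continuous), the imputation policy implied by
#' that kind (binary flags impute to zero; continuous annotations impute to
#' the observed median), and the fraction of missing values.
#'
#' @param table Feature table (first column `gene`).
#' @param policies Optional named character vector (`feature = "zero"` or
#'   `"median"`) overriding the kind-based policy per feature.
#' @return A tibble with columns `feature`, `kind`, `impute_policy`,
#'   `missing_fraction`.
#' @export
feature_meta <- function(table, policies = NULL) {
  feats <- feature_cols(table)
  meta <- purrr::imap(table[feats], function(col, nm) {
    obs <- col[!is.na(col)]
    kind <- if (length(unique(obs)) <= 2) "binary" else "continuous"
    pol <- if (!is.null(policies) && nm %in% names(policies)) {
      match.arg(policies[[nm]], c("zero", "median"))
    } else if (kind == "binary") "zero" else "median"
    tibble::tibble(feature = nm, kind = kind, impute_policy = pol,
                   missing_fraction = mean(is.na(col)))
  })
  dplyr::bind_rows(meta)
}

feature_cols <- function(table) {
  stopifnot(is.data.frame(table), names(table)[1] == "gene")
  setdiff(names(table), "gene")
}

feature_matrix <- function(table) {
  m <- as.matrix(table[feature_cols(table)])
  rownames(m) <- table$gene
  storage.mode(m) <- "double"
  m
}

#' Drop highly correlated features
#'
#' Computes pairwise Pearson correlations on pairwise-complete (both
#' observed) entries, before any imputation so that imputed constants cannot
#' bias r, then greedily walks the columns in file order and drops each
#' column whose absolute correlation with an already-kept column exceeds
#' `thres` (the later column of a pair is always the victim).  After the
#' filter no surviving pair has `|r| > thres`.  Pairs with fewer than three
#' complete observations get `r = 0` with a warning.
#'
#' @param table Feature table.
#' @param thres Absolute-correlation threshold in `(0, 1]` (default 0.8).
#' @return The filtered table; dropped columns are recorded in attribute
#'   `dropped_features` (tibble: feature, reason, statistic).
#' @export
filter_correlated <- function(table, thres = 0.8) {
  stopifnot(thres > 0, thres <= 1)
  feats <- feature_cols(table)
  if (length(feats) < 2) return(table)
  m <- feature_matrix(table)
  n_pair <- crossprod(!is.na(m))
  r <- suppressWarnings(stats::cor(m, use = "pairwise.complete.obs"))
  too_few <- n_pair < 3 & upper.tri(n_pair)
  if (any(too_few)) {
    warning("correlation set to 0 for ", sum(too_few),
            " feature pair(s) with < 3 complete observations")
  }
  r[n_pair < 3] <- 0
  r[is.na(r)] <- 0  # constant columns: no linear association measurable
  keep <- character()
  dropped <- list()
  for (f in feats) {
    rmax <- if (length(keep)) max(abs(r[f, keep])) else 0
    if (rmax > thres) {
      dropped[[f]] <- tibble::tibble(feature = f, reason = "high_correlation",
                                     statistic = rmax)
    } else {
      keep <- c(keep, f)
    }
  }
  out <- table[c("gene", keep)]
  attr(out, "dropped_features") <- dplyr::bind_rows(dropped)
  out
}

#' Drop features with too much missing data
#'
#' Removes columns whose missing fraction is strictly greater than `thres`
#' (a column at exactly the threshold survives).
#'
#' @param table Feature table.
#' @param thres Missing-fraction threshold in `[0, 1]` (default 0.25).
#' @return Filtered table with a `dropped_features` attribute.
#' @export
filter_missing <- function(table, thres = 0.25) {
  stopifnot(thres >= 0, thres <= 1)
  meta <- feature_meta(table)
  drop <- meta$feature[meta$missing_fraction > thres]
  if (length(drop) == length(meta$feature)) {
    stop("no features survive the missing-data filter", call. = FALSE)
  }
  out <- table[c("gene", setdiff(meta$feature, drop))]
  attr(out, "dropped_features") <- tibble::tibble(
    feature = drop, reason = "missing_data",
    statistic = meta$missing_fraction[match(drop, meta$feature)]
  )
  out
}

#' Impute missing feature values
#'
#' Binary-kind columns (and any column with an explicit `"zero"` policy) are
#' imputed with zero — absence of an annotation flag is itself the signal.
#' Continuous columns are imputed with the median of their observed values,
#' the appropriate choice for metrics computed on differing reference gene
#' sets where zero would be a misleading penalty.
#'
#' @inheritParams feature_meta
#' @return Table with no missing values.
#' @export
impute_features <- function(table, policies = NULL) {
  meta <- feature_meta(table, policies)
  fully_missing <- meta$feature[meta$missing_fraction >= 1]
  if (length(fully_missing) > 0) {
    stop("column(s) fully missing, cannot impute: ",
         paste(fully_missing, collapse = ", "), call. = FALSE)
  }
  out <- table
  for (i in seq_len(nrow(meta))) {
    f <- meta$feature[i]
    col <- out[[f]]
    if (!anyNA(col)) next
    fill <- if (meta$impute_policy[i] == "zero") 0 else
      stats::median(col, na.rm = TRUE)
    col[is.na(col)] <- fill
    out[[f]] <- col
  }
  out
}

#' Standardize features to zero mean and unit variance
#'
#' Scales every non-constant column to mean 0 and variance 1 using the
#' population convention (divide by n), which makes the transform exactly
#' idempotent.  Constant columns carry no information and are dropped with a
#' warning.
#'
#' @param table Feature table with no missing values.
#' @return Standardized table with a `dropped_features` attribute for any
#'   constant columns.
#' @export
standardize_features <- function(table) {
  feats <- feature_cols(table)
  if (anyNA(table[feats])) {
    stop("standardize_features() requires a fully imputed table", call. = FALSE)
  }
  m <- feature_matrix(table)
  mu <- colMeans(m)
  sigma <- sqrt(colMeans(sweep(m, 2, mu)^2))
  const <- feats[sigma == 0]
  if (length(const) > 0) {
    warning("dropping constant feature(s): ", paste(const, collapse = ", "))
  }
  keep <- setdiff(feats, const)
  out <- table["gene"]
  for (f in keep) out[[f]] <- (table[[f]] - mu[[f]]) / sigma[[f]]
  attr(out, "dropped_features") <- tibble::tibble(
    feature = const, reason = "constant", statistic = rep(0, length(const))
  )
  out
}

#' Full pre-processing pipeline
#'
#' Fixed order: correlation filter, missing-data filter, imputation,
#' standardization.  Correlations are computed pre-imputation on
#' pairwise-complete entries; re-running the pipeline on its own output is a
#' no-op.
#'
#' @param table Feature table.
#' @param config A [pu_config()]; supplies `high_corr_thres` and
#'   `missing_data_thres`.
#' @param policies Optional per-feature imputation policy overrides.
#' @return Processed table; attribute `dropped_features` accumulates the
#'   removal log across stages.
#' @export
preprocess_features <- function(table, config = pu_config(), policies = NULL) {
  log <- list()
  grab <- function(t) {
    log[[length(log) + 1]] <<- attr(t, "dropped_features")
    t
  }
  out <- table |>
    filter_correlated(config$high_corr_thres) |> grab() |>
    filter_missing(config$missing_data_thres) |> grab() |>
    impute_features(policies) |>
    standardize_features() |> grab()
  attr(out, "dropped_features") <- dplyr::bind_rows(log)
  out
}

#' Exploratory summaries: correlation matrix and missing-data ratios
#'
#' @param table Feature table (>= 2 features).
#' @return List with `corr_matrix` (symmetric, unit diagonal; pairwise
#'   complete observations) and `missing_ratios` (tibble: feature,
#'   missing_fraction).
#' @export
eda_summaries <- function(table) {
  feats <- feature_cols(table)
  stopifnot(length(feats) >= 2)
  m <- feature_matrix(table)
  r <- suppressWarnings(stats::cor(m, use = "pairwise.complete.obs"))
  diag(r) <- 1
  list(
    corr_matrix = r,
    missing_ratios = feature_meta(table)[c("feature", "missing_fraction")]
  )
}
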