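#' Run configuration for stochastic positive-unlabeled learning
#'
#' Collects every tunable of the stochastic PU scheme in one validated list.
#' Defaults correspond to the framework's published operating point:
#' `L = 10` stochastic iterations, `k = 10` stratified folds, an `X = 80%`
#' seed-gene subsample per balanced set, a 1:1.5 positive-to-unlabeled
#' ratio, a 0.8 Pearson correlation filter, a 0.25 missing-data filter and a
#' 0.5 prediction-probability threshold for calling predicted known/novel
#' genes.
#'
#' @param iterations_L Number of stochastic iterations (`>= 1`).
#' @param folds_k Stratified cross-validation folds per balanced set (`>= 2`).
#' @param seed_sample_fraction_X Fraction of seed genes sampled into each
#'   balanced set, in `(0, 1]`.
#' @param pos_to_unlabeled_ratio Target unlabeled-to-positive size ratio of a
#'   balanced set (1.5 means 1:1.5).
#' @param high_corr_thres Absolute Pearson correlation above which the later
#'   of a feature pair is dropped during pre-processing.
#' @param missing_data_thres Features with a missing-data fraction strictly
#'   greater than this are dropped.
#' @param prediction_threshold Mean-probability threshold separating
#'   predicted known/novel genes from the rest.
#' @param top_fraction Fraction of the ranked universe taken as the top
#'   prediction set in enrichment analyses.
#' @param feature_selection Either `"all"` (use every pre-processed feature)
#'   or `"boruta_confirmed"` (restrict training to consensus-confirmed
#'   features).
#' @param classifiers Character vector of classifier identifiers (see
#'   [classifier_ids()]).
#' @param master_rng_seed Integer master seed; every random draw in a run is
#'   taken from a named substream derived from it (see
#'   [derive_rng_stream()]).
#'
#' @return An object of class `pu_config` (a named list).
#' @examples
#' cfg <- pu_config(iterations_L = 2, folds_k = 5)
#' cfg$pos_to_unlabeled_ratio
#' @export
pu_config <- function(iterations_L = 10,
                      folds_k = 10,
                      seed_sample_fraction_X = 0.8,
                      pos_to_unlabeled_ratio = 1.5,
                      high_corr_thres = 0.8,
                      missing_data_thres = 0.25,
                      prediction_threshold = 0.5,
                      top_fraction = 0.05,
                      feature_selection = c("all", "boruta_confirmed"),
                      classifiers = "extra_trees",
                      master_rng_seed = 1L) {
  feature_selection <- match.arg(feature_selection)
  cfg <- list(
    iterations_L = as.integer(iterations_L),
    folds_k = as.integer(folds_k),
    seed_sample_fraction_X = seed_sample_fraction_X,
    pos_to_unlabeled_ratio = pos_to_unlabeled_ratio,
    high_corr_thres = high_corr_thres,
    missing_data_thres = missing_data_thres,
    prediction_threshold = prediction_threshold,
    top_fraction = top_fraction,
    feature_selection = feature_selection,
    classifiers = as.character(classifiers),
    master_rng_seed = as.integer(master_rng_seed)
  )
  validate_pu_config(cfg)
  structure(cfg, class = "pu_config")
}

validate_pu_config <- function(cfg) {
  stopifnot(
    "iterations_L must be >= 1" = cfg$iterations_L >= 1L,
    "folds_k must be >= 2" = cfg$folds_k >= 2L,
    "pos_to_unlabeled_ratio must be > 0" = cfg$pos_to_unlabeled_ratio > 0
  )
  for (f in c("seed_sample_fraction_X", "high_corr_thres",
              "missing_data_thres", "prediction_threshold", "top_fraction")) {
    v <- cfg[[f]]
    if (!is.numeric(v) || length(v) != 1L || v <= 0 || v > 1) {
      stop(sprintf("`%s` must be a fraction in (0, 1], got %s", f,
                   format(v)), call. = FALSE)
    }
  }
  unknown <- setdiff(cfg$classifiers, classifier_ids())
  if (length(unknown) > 0) {
    stop("unknown classifier id(s): ", paste(unknown, collapse = ", "),
         call. = FALSE)
  }
  invisible(cfg)
}

#' @export
print.pu_config <- function(x, ...) {
  cat("<pu_config>\n")
  for (nm in names(x)) {
    cat(sprintf("  %-24s %s\n", nm, paste(format(x[[nm]]), collapse = ", ")))
  }
  invisible(x)
}

#' Disease/phenotype query terms
#'
#' Free-text inclusion and exclusion terms describing the phenotype under
#' study.  Matching is case-insensitive with wildcard semantics (`*` matches
#' any substring), mirroring how query terms are used to subset features and
#' annotation sources.  Term-to-resource resolution itself is out of scope
#' here; [term_match()] exposes the matching rule for optional column
#' filtering.
#'
#' @param include_terms Required, non-empty character vector of
#'   disease/phenotype terms.
#' @param additional_terms Optional associated terms.
#' @param exclude_terms Optional terms to exclude.
#' @return An object of class `disease_terms`.
#' @export
disease_terms <- function(include_terms,
                          additional_terms = character(),
                          exclude_terms = character()) {
  include_terms <- as.character(include_terms)
  if (length(include_terms) == 0 || all(!nzchar(include_terms))) {
    stop("`include_terms` (disease/phenotype terms) must be non-empty",
         call. = FALSE)
  }
  structure(
    list(include_terms = include_terms,
         additional_terms = as.character(additional_terms),
         exclude_terms = as.character(exclude_terms)),
    class = "disease_terms"
  )
}

#' Case-insensitive wildcard matching of query terms
#'
#' @param terms Character vector of free-text terms; `*` acts as a wildcard.
#' @param x Character vector to match against.
#' @return Logical vector: does any term match each element of `x`?
#' @export
term_match <- function(terms, x) {
  if (length(terms) == 0) return(rep(FALSE, length(x)))
  pats <- vapply(terms, function(t) utils::glob2rx(paste0("*", t, "*")),
                 character(1))
  out <- rep(FALSE, length(x))
  for (p in pats) out <- out | grepl(p, x, ignore.case = TRUE)
  out
}

#' Parse a YAML run-configuration file
#'
#' One field is required: `disease/phenotype terms`.  Two term fields are
#' optional (`additional associated terms`, `diseases/phenotypes to
#' exclude`); empty cells may simply be omitted.  Every tunable of
#' [pu_config()] can be set under its own name (`iterations_L`, `folds_k`,
#' `seed_sample_fraction_X`, `pos_to_unlabeled_ratio`, `high_corr_thres`,
#' `missing_data_thres`, `prediction_threshold`, `top_fraction`,
#' `feature_selection`, `classifiers`, `master_rng_seed`); omitted tunables
#' take their defaults.
#'
#' @param path Path to a YAML file.
#' @return A list with elements `config` (a [pu_config()]) and `terms`
#'   (a [disease_terms()]).
#' @export
parse_config <- function(path) {
  if (!file.exists(path)) stop("config file not found: ", path, call. = FALSE)
  raw <- tryCatch(
    yaml::read_yaml(path),
    error = function(e) {
      stop("malformed YAML in ", path, ": ", conditionMessage(e),
           call. = FALSE)
    }
  )
  if (is.null(raw[["disease/phenotype terms"]])) {
    stop("configuration error: required field \"disease/phenotype terms\" ",
         "is missing from ", path, call. = FALSE)
  }
  terms <- disease_terms(
    include_terms = unlist(raw[["disease/phenotype terms"]]),
    additional_terms = unlist(raw[["additional associated terms"]]) %||% character(),
    exclude_terms = unlist(raw[["diseases/phenotypes to exclude"]]) %||% character()
  )
  tunables <- intersect(names(raw), names(formals(pu_config)))
  cfg <- do.call(pu_config, raw[tunables])
  list(config = cfg, terms = terms)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

MISSING_TOKENS <- c("", "na", "nan")

#' Read a gene-by-feature table
#'
#' Reads a delimited text file (TSV or CSV, auto-detected from the header
#' line) whose first column holds gene symbols and remaining columns hold
#' numeric features.  Empty strings, `NA` and `NaN` (case-insensitive) are
#' treated as missing.  Gene symbols are whitespace-stripped and must be
#' unique; matching elsewhere in the package is case-sensitive.
#'
#' @param path Path to the table.
#' @return A tibble whose first column is `gene` (character) and whose
#'   remaining columns are numeric features.  Column typing (binary vs
#'   continuous) is derived on demand via [feature_meta()].
#' @export
read_feature_table <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  header <- readLines(path, n = 1L)
  delim <- if (lengths(regmatches(header, gregexpr("\t", header))) >
               lengths(regmatches(header, gregexpr(",", header)))) "\t" else ","
  raw <- readr::read_delim(path, delim = delim, col_types = readr::cols(
    .default = readr::col_character()
  ), na = character(), progress = FALSE)
  if (ncol(raw) < 2) stop("feature table needs a gene column plus >= 1 feature",
                          call. = FALSE)
  genes <- stringr::str_trim(raw[[1]])
  dups <- unique(genes[duplicated(genes)])
  if (length(dups) > 0) {
    stop("duplicate gene symbols: ", paste(dups, collapse = ", "),
         call. = FALSE)
  }
  feats <- raw[-1]
  parsed <- purrr::imap(feats, function(col, nm) {
    col <- stringr::str_trim(col)
    miss <- tolower(col) %in% MISSING_TOKENS | is.na(col)
    out <- suppressWarnings(as.numeric(col))
    bad <- which(!miss & is.na(out))
    if (length(bad) > 0) {
      stop(sprintf("non-numeric value \"%s\" in column \"%s\", row %d",
                   col[bad[1]], nm, bad[1]), call. = FALSE)
    }
    out[miss] <- NA_real_
    out
  })
  dplyr::bind_cols(tibble::tibble(gene = genes), tibble::as_tibble(parsed))
}

#' Write a gene-by-feature table
#'
#' Inverse of [read_feature_table()]: tab-separated, header `Gene_Name`
#' followed by feature names, missing values written as `NA`.
#'
#' @param table Tibble as returned by [read_feature_table()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_feature_table <- function(table, path) {
  stopifnot(names(table)[1] == "gene")
  out <- table
  names(out)[1] <- "Gene_Name"
  readr::write_tsv(out, path, na = "NA", progress = FALSE)
  invisible(path)
}

#' Read a seed-gene list (one symbol per line)
#'
#' @param path Path to a plain-text file.
#' @return Character vector of unique, whitespace-stripped gene symbols.
#' @export
read_seed_genes <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  x <- stringr::str_trim(readLines(path))
  unique(x[nzchar(x)])
}

#' Read an external ranked gene list
#'
#' Expects a TSV with columns `gene` and `p_value` (ascending-significance
#' semantics) and an optional `class` column (e.g. pLoF / synonymous /
#' shuffled).  Rows are ordered by ascending p-value; the input order is
#' preserved among ties.  The attribute `cutoff_index` records the last
#' position with `p < 0.05` (0 if none), matching the external-study
#' significance cutoff used in enrichment plots.
#'
#' @param path Path to the TSV.
#' @return A tibble of class `external_ranked_list` with columns `gene`,
#'   `p_value` and `class`.
#' @export
read_ranked_list <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  raw <- readr::read_tsv(path, col_types = readr::cols(), progress = FALSE)
  if (nrow(raw) == 0) stop("empty ranked list: ", path, call. = FALSE)
  names(raw)[1:2] <- c("gene", "p_value")
  if (ncol(raw) >= 3) names(raw)[3] <- "class" else raw$class <- NA_character_
  as_ranked_list(raw[c("gene", "p_value", "class")])
}

#' Construct an external ranked list from a data frame
#'
#' @param df Data frame with columns `gene`, `p_value`, optional `class`.
#' @return A tibble of class `external_ranked_list`, sorted by ascending
#'   `p_value` (stable among ties) with attribute `cutoff_index`.
#' @export
as_ranked_list <- function(df) {
  stopifnot(all(c("gene", "p_value") %in% names(df)))
  if (!"class" %in% names(df)) df$class <- NA_character_
  if (nrow(df) == 0) stop("ranked list is empty", call. = FALSE)
  if (any(is.na(df$p_value)) || any(df$p_value < 0 | df$p_value > 1)) {
    stop("p_value out of range [0, 1] in ranked list", call. = FALSE)
  }
  out <- tibble::as_tibble(df)[order(df$p_value), , drop = FALSE]
  out <- out[c("gene", "p_value", "class")]
  cut <- which(out$p_value < 0.05)
  attr(out, "cutoff_index") <- if (length(cut)) max(cut) else 0L
  class(out) <- c("external_ranked_list", class(out))
  out
}

#' Derive a named deterministic RNG substream seed
#'
#' A single master seed spawns an independent, reproducible stream per
#' labelled context (e.g. `"iter:3/set:2/fold:5"`), so results do not depend
#' on execution order.  The derivation is a polynomial rolling hash of
#' `master_seed:context` modulo `2^31 - 1`.
#'
#' @param master_seed Integer master seed.
#' @param context Character label of the consumer.
#' @return An integer suitable for [set.seed()].
#' @examples
#' set.seed(derive_rng_stream(42, "iter:3")); runif(2)
#' @export
derive_rng_stream <- function(master_seed, context) {
  m <- 2147483647  # 2^31 - 1; keeps h * 131 + ch exact in doubles
  s <- paste0(format(master_seed, scientific = FALSE), ":", context)
  h <- 17
  for (ch in utf8ToInt(s)) h <- (h * 131 + ch) %% m
  as.integer(h)
}

#' Evaluate code under a named RNG substream
#'
#' Sets the RNG to the substream derived from `(master_seed, context)`,
#' runs `expr`, and restores the caller's RNG state afterwards.
#'
#' @inheritParams derive_rng_stream
#' @param expr Expression to evaluate.
#' @return The value of `expr`.
#' @export
with_rng_stream <- function(master_seed, context, expr) {
  old <- if (exists(".Random.seed", globalenv(), inherits = FALSE)) {
    get(".Random.seed", globalenv())
  } else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      }
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  set.seed(derive_rng_stream(master_seed, context))
  expr
}
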