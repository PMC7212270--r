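#' Two-dimensional projection of a processed feature table
#'
#' Projects genes into 2-D for exploratory visualization.  `"pca"` uses the
#' covariance eigenstructure and additionally returns the cumulative
#' explained-variance fractions of the first 20 principal components
#' (the scree).  `"tsne"` runs the exact (non-approximated) t-SNE algorithm
#' implemented in this package with default perplexity 30.  `"umap"` calls
#' the reference umap-learn implementation through the system `python`
#' (parameters: `n_neighbors = 5`, `min_dist = 0.3`, `metric =
#' "correlation"`).  Stochastic methods are deterministic under a fixed
#' `seed`.
#'
#' @param table Fully pre-processed feature table (no missing values).
#' @param method One of `"pca"`, `"tsne"`, `"umap"`.
#' @param seed Integer seed for the stochastic methods.
#' @param perplexity t-SNE perplexity (default 30).
#' @param n_neighbors,min_dist,metric UMAP parameters.
#' @return An object of class `projection2d`: list with `method`,
#'   `coordinates` (tibble: gene, dim1, dim2), `scree` (PCA only: cumulative
#'   explained-variance fractions) and `params`.
#' @export
project_2d <- function(table, method = c("pca", "tsne", "umap"), seed = 1L,
                       perplexity = 30, n_neighbors = 5, min_dist = 0.3,
                       metric = "correlation") {
  method <- match.arg(method)
  m <- feature_matrix(table)
  if (anyNA(m)) stop("project_2d() requires a fully pre-processed table",
                     call. = FALSE)
  scree <- NULL
  params <- list()
  if (method == "pca") {
    pc <- stats::prcomp(m, center = TRUE, scale. = FALSE)
    coords <- pc$x[, 1:2, drop = FALSE]
    v <- pc$sdev^2 / sum(pc$sdev^2)
    scree <- cumsum(v)[seq_len(min(20, length(v)))]
  } else if (method == "tsne") {
    params <- list(perplexity = perplexity)
    coords <- with_rng_stream(seed, "tsne", tsne_exact(m, perplexity))
  } else {
    if (nrow(m) <= n_neighbors) {
      stop("too few genes (", nrow(m), ") for n_neighbors = ", n_neighbors,
           "; use a smaller n_neighbors", call. = FALSE)
    }
    params <- list(n_neighbors = n_neighbors, min_dist = min_dist,
                   metric = metric)
    coords <- umap_python(m, n_neighbors, min_dist, metric, seed)
  }
  structure(
    list(method = method,
         coordinates = tibble::tibble(gene = table$gene,
                                      dim1 = coords[, 1], dim2 = coords[, 2]),
         scree = scree, params = params),
    class = "projection2d"
  )
}

# Exact t-SNE: Gaussian input kernel with per-point precision calibrated to
# the target perplexity, Student-t embedding kernel, momentum gradient
# descent with early exaggeration.  O(n^2) per iteration; intended for the
# gene-table sizes used in exploratory plots.
tsne_exact <- function(X, perplexity = 30, n_iter = 350, eta = 200) {
  n <- nrow(X)
  if (3 * perplexity >= n) {
    stop("perplexity too large for ", n, " points; need n > 3 * perplexity",
         call. = FALSE)
  }
  D2 <- as.matrix(stats::dist(X))^2
  P <- matrix(0, n, n)
  logU <- log(perplexity)
  for (i in seq_len(n)) {
    Di <- D2[i, -i]
    beta <- 1; betamin <- -Inf; betamax <- Inf
    Pi <- exp(-Di * beta)
    for (it in 1:50) {
      sumP <- sum(Pi)
      if (sumP < .Machine$double.xmin) sumP <- .Machine$double.xmin
      H <- log(sumP) + beta * sum(Di * Pi) / sumP
      d <- H - logU
      if (abs(d) < 1e-5) break
      if (d > 0) {
        betamin <- beta
        beta <- if (is.finite(betamax)) (beta + betamax) / 2 else beta * 2
      } else {
        betamax <- beta
        beta <- if (is.finite(betamin)) (beta + betamin) / 2 else beta / 2
      }
      Pi <- exp(-Di * beta)
    }
    P[i, -i] <- Pi / sum(Pi)
  }
  P <- (P + t(P)) / (2 * n)
  P <- pmax(P, 1e-12)
  Y <- matrix(stats::rnorm(n * 2, sd = 1e-4), n, 2)
  dY <- matrix(0, n, 2)
  gains <- matrix(1, n, 2)
  exaggeration <- 12
  for (iter in seq_len(n_iter)) {
    Pe <- if (iter <= 100) P * exaggeration else P
    sq <- rowSums(Y^2)
    num <- 1 / (1 + outer(sq, sq, "+") - 2 * tcrossprod(Y))
    diag(num) <- 0
    Q <- pmax(num / sum(num), 1e-12)
    L <- (Pe - Q) * num
    grad <- 4 * (diag(rowSums(L)) - L) %*% Y
    momentum <- if (iter <= 20) 0.5 else 0.8
    gains <- ifelse(sign(grad) != sign(dY), gains + 0.2, gains * 0.8)
    gains[gains < 0.01] <- 0.01
    dY <- momentum * dY - eta * gains * grad
    Y <- Y + dY
    Y <- sweep(Y, 2, colMeans(Y))
  }
  Y
}

# Bridge to the reference umap-learn implementation (python on PATH).
umap_python <- function(X, n_neighbors, min_dist, metric, seed) {
  py <- Sys.which("python")
  if (py == "" || nchar(py) == 0) {
    stop("UMAP projection requires `python` with umap-learn on the PATH",
         call. = FALSE)
  }
  fin <- tempfile(fileext = ".csv")
  fout <- tempfile(fileext = ".csv")
  on.exit(unlink(c(fin, fout)))
  utils::write.table(X, fin, sep = ",", row.names = FALSE, col.names = FALSE)
  code <- sprintf(paste0(
    "import warnings; warnings.filterwarnings('ignore')\n",
    "import numpy as np, umap\n",
    "X = np.loadtxt(%s, delimiter=',')\n",
    "emb = umap.UMAP(n_neighbors=%d, min_dist=%s, metric='%s',",
    " random_state=%d).fit_transform(X)\n",
    "np.savetxt(%s, emb, delimiter=',')\n"),
    deparse(fin), as.integer(n_neighbors), format(min_dist), metric,
    as.integer(seed), deparse(fout))
  res <- suppressWarnings(
    system2(py, c("-"), input = code, stdout = TRUE, stderr = TRUE)
  )
  if (!file.exists(fout)) {
    stop("umap-learn call failed:\n", paste(res, collapse = "\n"),
         call. = FALSE)
  }
  as.matrix(utils::read.table(fout, sep = ","))
}

#' @export
print.projection2d <- function(x, ...) {
  cat("<projection2d>", x$method, "on", nrow(x$coordinates), "genes\n")
  if (!is.null(x$scree)) {
    cat("  scree (first 5):",
        paste(round(utils::head(x$scree, 5), 3), collapse = ", "), "\n")
  }
  invisible(x)
}

#' Plot a 2-D projection
#'
#' @param object A `projection2d`.
#' @param highlight Optional character vector of genes (e.g. seed genes) to
#'   colour.
#' @param ... Ignored.
#' @return A ggplot.
#' @export
autoplot.projection2d <- function(object, highlight = NULL, ...) {
  df <- object$coordinates
  df$group <- if (is.null(highlight)) "gene" else
    ifelse(df$gene %in% highlight, "highlighted", "background")
  ggplot2::ggplot(df, ggplot2::aes(.data$dim1, .data$dim2,
                                   colour = .data$group)) +
    ggplot2::geom_point(alpha = 0.6, size = 0.8) +
    ggplot2::labs(title = toupper(object$method), x = "dim 1", y = "dim 2") +
    ggplot2::theme_minimal()
}
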