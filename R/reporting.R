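#' Fit a PCA model on (a gene subset of) a dataset
#'
#' Samples are centered per gene (optionally unit-variance scaled) and
#' decomposed by SVD. Components carry a deterministic sign convention: the
#' loading of largest magnitude in each component is positive. Explained
#' variance fractions are relative to the total variance of the input, so
#' they are non-increasing and sum to at most 1 over the kept components.
#'
#' @param ds a [sensig_dataset()] or a genes x samples matrix.
#' @param genes gene subset (default: all).
#' @param n_components components to keep; must not exceed
#'   `min(#genes, #samples - 1)` nor the actual rank.
#' @param scale_genes also scale genes to unit variance (default FALSE, the
#'   common expression-PCA convention).
#' @return object of class `pca_model` with `rotation`, `center`, `scale`,
#'   `explained`, and the fitting `scores`.
#' @export
fit_pca <- function(ds, genes = NULL, n_components = 3, scale_genes = FALSE) {
  X <- if (inherits(ds, "sensig_dataset")) ds$exprs else ds
  if (!is.null(genes)) {
    missing <- setdiff(genes, rownames(X))
    if (length(missing)) stop("gene(s) not in dataset: ", paste(missing, collapse = ", "))
    X <- X[genes, , drop = FALSE]
  }
  M <- t(X)  # samples x genes
  k_max <- min(ncol(M), nrow(M) - 1)
  if (n_components > k_max)
    stop(sprintf("n_components = %d exceeds min(#genes, #samples - 1) = %d",
                 n_components, k_max))
  pr <- prcomp(M, center = TRUE, scale. = scale_genes)
  if (sum(pr$sdev > 1e-10) < n_components)
    stop(sprintf("data rank %d is below n_components = %d",
                 sum(pr$sdev > 1e-10), n_components))
  rot <- pr$rotation[, seq_len(n_components), drop = FALSE]
  sc <- pr$x[, seq_len(n_components), drop = FALSE]
  for (c in seq_len(n_components)) {       # sign convention
    j <- which.max(abs(rot[, c]))
    if (rot[j, c] < 0) { rot[, c] <- -rot[, c]; sc[, c] <- -sc[, c] }
  }
  explained <- (pr$sdev^2 / sum(pr$sdev^2))[seq_len(n_components)]
  structure(list(genes = rownames(X), center = pr$center,
                 scale = if (scale_genes) pr$scale else NULL,
                 rotation = rot, explained = explained,
                 scores = sc, sample_ids = colnames(X)),
            class = "pca_model")
}

#' Project samples into a fitted PCA space
#'
#' Held-out samples are centered (and scaled, if the model was fitted with
#' scaling) with the model's own statistics and projected onto its
#' loadings. Projecting the fitting samples reproduces their fit scores.
#'
#' @param model a [fit_pca()] model.
#' @param ds a [sensig_dataset()] or genes x samples matrix containing all
#'   model genes.
#' @return samples x components score matrix.
#' @export
project_pca <- function(model, ds) {
  stopifnot(inherits(model, "pca_model"))
  X <- if (inherits(ds, "sensig_dataset")) ds$exprs else ds
  missing <- setdiff(model$genes, rownames(X))
  if (length(missing)) stop("gene(s) missing from data: ", paste(missing, collapse = ", "))
  M <- t(X[model$genes, , drop = FALSE])
  M <- sweep(M, 2, model$center, `-`)
  if (!is.null(model$scale)) M <- sweep(M, 2, model$scale, `/`)
  M %*% model$rotation
}

#' @export
print.pca_model <- function(x, ...) {
  cat(sprintf("pca_model: %d genes, %d components (%.1f%% variance)\n",
              length(x$genes), ncol(x$rotation), 100 * sum(x$explained)))
  invisible(x)
}

#' Z-score the rows of an expression matrix
#'
#' Each gene row is scaled to mean 0 and standard deviation 1 (population
#' sd, i.e. divide by n) — the heatmap display convention. Constant rows
#' become all zeros with a warning.
#'
#' @param mat numeric matrix, genes in rows.
#' @return matrix of the same shape.
#' @export
zscore_rows <- function(mat) {
  m <- rowMeans(mat)
  s <- sqrt(rowMeans((mat - m)^2))
  flat <- s <= 0
  if (any(flat)) {
    warning(sum(flat), " constant row(s) set to zero")
    s[flat] <- 1
  }
  out <- (mat - m) / s
  out[flat, ] <- 0
  out
}

#' Leaf order of hierarchically clustered genes
#'
#' Agglomerative clustering of z-scored gene rows, as used to order heatmap
#' rows. Leaf order is deterministic for a given input.
#'
#' @param mat numeric matrix, genes in rows (>= 2).
#' @param linkage `"average"` (default) or `"complete"`.
#' @param distance `"euclidean"` (default) or `"correlation"`
#'   (1 - Pearson).
#' @return character vector of gene ids in leaf order.
#' @export
hierarchical_order <- function(mat, linkage = c("average", "complete"),
                               distance = c("euclidean", "correlation")) {
  linkage <- match.arg(linkage)
  distance <- match.arg(distance)
  if (nrow(mat) < 2) stop("need at least 2 genes")
  z <- suppressWarnings(zscore_rows(mat))
  d <- if (distance == "euclidean") dist(z) else stats::as.dist(1 - cor(t(z)))
  hc <- hclust(d, method = linkage)
  rownames(mat)[hc$order]
}
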