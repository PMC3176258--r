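# Vectorised one-way fixed-effects ANOVA over the rows of a genes x samples
# matrix. Returns the upper-tail F p-value per gene. Degenerate genes with
# zero between- and zero within-group variation get p = 1; separation so
# perfect that SSW = 0 with SSB > 0 is floored at the smallest positive
# double so p stays in (0, 1].
row_anova_p <- function(X, groups) {
  g <- factor(groups)
  k <- nlevels(g)
  n <- ncol(X)
  if (k < 2) stop("need at least two groups")
  cnt <- table(g)
  small <- names(cnt)[cnt < 2]
  if (length(small))
    stop("group(s) with fewer than 2 samples: ", paste(small, collapse = ", "))
  ind <- stats::model.matrix(~ g - 1)           # samples x groups
  gm <- (X %*% ind) %*% diag(1 / as.numeric(cnt), k)   # group means
  grand <- rowMeans(X)
  ssb <- rowSums(sweep(gm, 1, grand, `-`)^2 %*% diag(as.numeric(cnt), k))
  sst <- rowSums((X - grand)^2)
  ssw <- pmax(sst - ssb, 0)
  f <- (ssb / (k - 1)) / (ssw / (n - k))
  p <- pf(f, k - 1, n - k, lower.tail = FALSE)
  p[ssb <= 0 & ssw <= 0] <- 1          # flat gene: no evidence either way
  p[is.na(p)] <- 1
  pmax(p, .Machine$double.xmin)
}

#' Two-group one-way ANOVA per transcript
#'
#' One-way fixed-effects ANOVA of each transcript across the two chemical
#' classes (sensitizer vs non-sensitizer). With two groups the F statistic
#' equals the squared pooled-variance t statistic, so p-values agree with a
#' two-sided pooled t-test. Vehicle controls are excluded by default; set
#' `include_controls_as_nonsens = TRUE` to pool them with the
#' non-sensitizers.
#'
#' @param ds a [sensig_dataset()] with at least 2 samples per class.
#' @param include_controls_as_nonsens count vehicle controls as
#'   non-sensitizers (default FALSE).
#' @return named numeric vector of p-values, one per gene.
#' @export
anova_two_group <- function(ds, include_controls_as_nonsens = FALSE) {
  stopifnot(inherits(ds, "sensig_dataset"))
  ann <- ds$annot
  if (include_controls_as_nonsens) {
    lab <- ifelse(ann$class_label == "sensitizer", "sensitizer", "non_sensitizer")
    keep <- rep(TRUE, nrow(ann))
  } else {
    keep <- ann$class_label != "vehicle_control"
    lab <- ann$class_label[keep]
  }
  row_anova_p(ds$exprs[, keep, drop = FALSE], lab)
}

#' Multi-group one-way ANOVA per transcript
#'
#' One-way ANOVA of each transcript across all individual stimulations:
#' one group per compound, with the two vehicle controls as their own
#' groups. Every group needs at least 2 samples.
#'
#' @param ds a [sensig_dataset()].
#' @return named numeric vector of p-values, one per gene.
#' @export
anova_multi_group <- function(ds) {
  stopifnot(inherits(ds, "sensig_dataset"))
  row_anova_p(ds$exprs, ds$annot$compound_id)
}

#' Benjamini-Hochberg FDR adjustment
#'
#' Step-up adjusted q-values, capped at 1, mapped back to input order.
#'
#' @param pvals numeric vector of p-values in (0, 1].
#' @return q-values in input order.
#' @export
bh_fdr <- function(pvals) {
  if (!length(pvals)) stop("empty p-value vector")
  if (any(!is.finite(pvals)) || any(pvals <= 0 | pvals > 1))
    stop("p-values must lie in (0, 1]")
  p.adjust(pvals, method = "BH")
}

#' Per-transcript test statistics table
#'
#' Convenience wrapper computing both ANOVA comparisons and their FDR
#' q-values for every transcript.
#'
#' @inheritParams anova_two_group
#' @return data.frame with columns `gene_id`, `p_two_group`, `q_two_group`,
#'   `p_multi_group`, `q_multi_group`.
#' @export
gene_stats <- function(ds, include_controls_as_nonsens = FALSE) {
  p2 <- anova_two_group(ds, include_controls_as_nonsens)
  pm <- anova_multi_group(ds)
  data.frame(gene_id = rownames(ds$exprs),
             p_two_group = unname(p2), q_two_group = unname(bh_fdr(p2)),
             p_multi_group = unname(pm), q_multi_group = unname(bh_fdr(pm)),
             stringsAsFactors = FALSE)
}

#' Select the candidate analyte set for backward elimination
#'
#' Genes whose chosen p-value passes the threshold (or, alternatively, the
#' `top_k` smallest), sorted by ascending p with ties broken by gene id. The
#' default selects on raw p, mirroring the discovery analysis; set
#' `use_q = TRUE` to select on FDR q-values instead.
#'
#' @param stats a [gene_stats()] table (or any data.frame with `gene_id` and
#'   the required p/q column).
#' @param comparison `"two_group"` or `"multi_group"`.
#' @param threshold p-value cutoff in (0, 1]; ignored when `top_k` is given.
#' @param top_k alternatively, keep the k smallest p-values.
#' @param use_q select on q-values rather than raw p.
#' @return object of class `candidate_set`: list with `gene_ids` (ascending
#'   p), `p` (matching), `threshold`, `comparison`.
#' @export
select_candidates <- function(stats, comparison = c("two_group", "multi_group"),
                              threshold = NULL, top_k = NULL, use_q = FALSE) {
  comparison <- match.arg(comparison)
  col <- paste0(if (use_q) "q_" else "p_", comparison)
  if (!col %in% names(stats)) stop("stats table lacks column ", col)
  p <- stats[[col]]
  ord <- order(p, stats$gene_id, method = "radix")
  if (!is.null(top_k)) {
    if (top_k < 1) stop("top_k must be >= 1")
    sel <- head(ord, top_k)
    threshold <- if (length(sel)) max(p[sel]) else NA_real_
  } else {
    if (is.null(threshold) || threshold <= 0 || threshold > 1)
      stop("threshold must be in (0, 1]")
    sel <- ord[p[ord] <= threshold]
  }
  if (!length(sel)) warning("no genes pass the selection; candidate set is empty")
  structure(list(gene_ids = stats$gene_id[sel], p = p[sel],
                 threshold = threshold, comparison = comparison),
            class = "candidate_set")
}

#' @export
print.candidate_set <- function(x, ...) {
  cat(sprintf("candidate_set: %d genes (%s, threshold %.3g)\n",
              length(x$gene_ids), x$comparison, x$threshold))
  invisible(x)
}
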