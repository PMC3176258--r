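# labels -> +1/-1 with the positive class resolved; sensitizer wins if present
resolve_labels <- function(labels, positive = NULL) {
  labels <- as.character(labels)
  lev <- sort_ids(unique(labels))
  if (length(lev) != 2) stop("need exactly two classes, got: ",
                             paste(lev, collapse = ", "))
  if (is.null(positive))
    positive <- if ("sensitizer" %in% lev) "sensitizer" else lev[2]
  if (!positive %in% lev) stop("positive class ", positive, " not among labels")
  list(y = ifelse(labels == positive, 1, -1), positive = positive,
       negative = setdiff(lev, positive))
}

# dataset -> (X genes x samples, labels) over chemical samples only
chem_xy <- function(ds, genes = NULL, labels = NULL) {
  stopifnot(inherits(ds, "sensig_dataset"))
  keep <- ds$annot$class_label != "vehicle_control"
  X <- ds$exprs[, keep, drop = FALSE]
  if (!is.null(genes)) {
    missing <- setdiff(genes, rownames(X))
    if (length(missing)) stop("gene(s) not in dataset: ", paste(missing, collapse = ", "))
    X <- X[genes, , drop = FALSE]
  }
  lab <- labels %||% ds$annot$class_label[keep]
  if (length(lab) != ncol(X)) stop("labels must have one entry per chemical sample")
  list(X = X, labels = lab, compounds = ds$annot$compound_id[keep])
}

svm_ctrl <- function() list(tol = 1e-3, max_pass = 2000)

#' Train a calibrated linear soft-margin SVM
#'
#' Fits a linear maximum-margin classifier with hinge loss (cost parameter
#' `cost`) on per-gene z-scaled training data, then fits a Platt sigmoid on
#' the training decision values so predictions can be returned as class
#' probabilities `1 / (1 + exp(A*d + B))` for the positive class.
#'
#' @param x numeric matrix, samples in rows, genes in columns (colnames
#'   required).
#' @param y two-class labels, one per row of `x`.
#' @param cost soft-margin cost C (default 1).
#' @param positive positive class label; defaults to `"sensitizer"` when
#'   present, else the later class in sort order.
#' @return object of class `margin_classifier` with the gene weights,
#'   offset, per-gene centering/scaling, and sigmoid parameters.
#' @export
train_classifier <- function(x, y, cost = 1, positive = NULL) {
  if (is.null(colnames(x))) stop("`x` must have gene colnames")
  lab <- resolve_labels(y, positive)
  if (length(unique(lab$y)) < 2) stop("training data contains a single class")
  center <- colMeans(x)
  scale <- apply(x, 2, sd)
  scale[!is.finite(scale) | scale <= 0] <- 1
  Zt <- t((t(x) - center) / scale)          # samples x genes, scaled
  ctl <- svm_ctrl()
  fit <- cpp_svm_train(t(Zt), lab$y, cost, ctl$tol, ctl$max_pass)
  cal <- cpp_platt(fit$decision, lab$y)
  structure(list(gene_ids = colnames(x),
                 w = stats::setNames(as.numeric(fit$w), colnames(x)),
                 b = fit$b,
                 calibration = c(A = cal[1], B = cal[2]),
                 center = center, scale = scale,
                 positive = lab$positive, negative = lab$negative,
                 cost = cost),
            class = "margin_classifier")
}

#' Predict from a margin classifier
#'
#' @param object a `margin_classifier`.
#' @param newdata samples x genes matrix containing all classifier genes.
#' @param type `"decision"` (raw margin value), `"probability"` (calibrated
#'   probability of the positive class, clipped to \[1e-6, 1-1e-6\]) or
#'   `"class"`.
#' @param ... unused.
#' @return numeric vector (or character for `type = "class"`), named by
#'   sample.
#' @export
predict.margin_classifier <- function(object, newdata,
                                      type = c("decision", "probability", "class"),
                                      ...) {
  type <- match.arg(type)
  if (is.null(dim(newdata))) newdata <- matrix(newdata, nrow = 1,
                                               dimnames = list(NULL, object$gene_ids))
  missing <- setdiff(object$gene_ids, colnames(newdata))
  if (length(missing)) stop("gene(s) missing from newdata: ",
                            paste(missing, collapse = ", "))
  Z <- t((t(newdata[, object$gene_ids, drop = FALSE]) - object$center) / object$scale)
  d <- as.numeric(Z %*% object$w + object$b)
  names(d) <- rownames(newdata)
  if (type == "decision") return(d)
  p <- 1 / (1 + exp(object$calibration[["A"]] * d + object$calibration[["B"]]))
  p <- pmin(pmax(p, 1e-6), 1 - 1e-6)
  if (type == "probability") return(p)
  stats::setNames(ifelse(d >= 0, object$positive, object$negative), rownames(newdata))
}

#' @export
print.margin_classifier <- function(x, ...) {
  cat(sprintf("margin_classifier: %d genes, cost %.3g, positive class '%s'\n",
              length(x$gene_ids), x$cost, x$positive))
  invisible(x)
}

# fold ids for LOOCV: one per sample, or one per compound
loocv_folds <- function(compounds, by_compound = FALSE) {
  if (by_compound) as.integer(factor(compounds)) else seq_along(compounds)
}

#' Leave-one-out cross-validated class probabilities
#'
#' For each chemical sample, a linear SVM is trained on all other samples
#' (features z-scaled with that fold's training statistics) and the held-out
#' decision value recorded. One Platt sigmoid is then fitted to the full
#' collection of out-of-fold decision values versus true labels, and each
#' sample's calibrated probability of its own true class is returned,
#' clipped to \[`clip`, 1 - `clip`\].
#'
#' @param ds a [sensig_dataset()] (vehicle controls are excluded).
#' @param genes analytes to use (default: all genes).
#' @param cost SVM cost parameter.
#' @param by_compound leave out whole compounds (all replicates) instead of
#'   single samples.
#' @param labels optional replacement class labels (one per chemical
#'   sample), e.g. for permutation nulls.
#' @param clip probability clipping bound (default 1e-6).
#' @return named numeric vector of true-class probabilities with attributes
#'   `decision` (out-of-fold decision values) and `calibration` (A, B).
#' @export
loocv_probabilities <- function(ds, genes = NULL, cost = 1, by_compound = FALSE,
                                labels = NULL, clip = 1e-6) {
  dat <- chem_xy(ds, genes, labels)
  lab <- resolve_labels(dat$labels)
  if (min(table(lab$y)) < 2) stop("need at least 2 samples per class")
  fold <- loocv_folds(dat$compounds, by_compound)
  for (f in unique(fold)) {
    if (length(unique(lab$y[fold != f])) < 2)
      stop("a class would be emptied by leaving out fold ", f)
  }
  ctl <- svm_ctrl()
  dec <- as.numeric(cpp_loocv_decisions(dat$X, lab$y, as.integer(fold),
                                        cost, ctl$tol, ctl$max_pass))
  cal <- cpp_platt(dec, lab$y)
  p_pos <- 1 / (1 + exp(cal[1] * dec + cal[2]))
  p_true <- ifelse(lab$y > 0, p_pos, 1 - p_pos)
  p_true <- pmin(pmax(p_true, clip), 1 - clip)
  names(p_true) <- colnames(dat$X)
  attr(p_true, "decision") <- stats::setNames(dec, colnames(dat$X))
  attr(p_true, "calibration") <- c(A = cal[1], B = cal[2])
  p_true
}

#' Kullback-Leibler divergence of cross-validated predictions
#'
#' Mean over samples of the KL divergence between the one-hot true-label
#' distribution and the predicted class distribution, which reduces to the
#' mean negative natural log of the predicted probability of the true class.
#' This is the objective the backward-elimination wrapper minimises: it
#' falls as uninformative analytes are removed and rises once informative
#' ones start being lost.
#'
#' @param probs per-sample predicted probabilities of the true class, all in
#'   (0, 1).
#' @return non-negative scalar.
#' @export
kld <- function(probs) {
  probs <- as.numeric(probs)
  if (!length(probs)) stop("empty probability vector")
  if (any(!is.finite(probs)) || any(probs <= 0 | probs >= 1))
    stop("probabilities must lie strictly inside (0, 1)")
  -mean(log(probs))
}

# symmetrised Gaussian KLD between class-conditional decision values;
# alternative elimination score (selected by argmax), see kld_variant
gaussian_separation <- function(dec, y) {
  a <- dec[y > 0]; b <- dec[y < 0]
  m1 <- mean(a); m2 <- mean(b)
  v1 <- max(stats::var(a), 1e-12); v2 <- max(stats::var(b), 1e-12)
  0.5 * (v1 / v2 + v2 / v1 - 2) + 0.5 * (m1 - m2)^2 * (1 / v1 + 1 / v2)
}

#' Backward elimination of analytes scored by LOOCV KLD
#'
#' The wrapper feature-selection core. At each step with N remaining
#' analytes, every analyte j is in turn left out and the KLD of the LOOCV
#' SVM predictions computed from the other N-1; the analyte whose removal
#' gives the smallest KLD contributes least and is eliminated (ties broken
#' toward the lexicographically smallest gene id). That minimal KLD is
#' recorded as the step's `kld_after` and the process repeats until `floor`
#' analytes remain. The KLD trajectory typically falls while redundant
#' analytes are removed and rises again once jointly informative ones are
#' lost; [find_breakpoint()] locates the minimum and fixes the signature.
#'
#' @param ds a [sensig_dataset()]; vehicle controls are excluded.
#' @param candidates a `candidate_set` from [select_candidates()], or a
#'   character vector of gene ids.
#' @param cost SVM cost parameter.
#' @param floor stop when this many analytes remain (default 1 = full
#'   trace).
#' @param chunk analytes eliminated per step (default 1, the exact
#'   algorithm; larger values are a labelled approximation for big panels).
#' @param by_compound leave out whole compounds in the inner LOOCV.
#' @param labels optional replacement class labels (permutation tests).
#' @param clip probability clipping bound.
#' @param kld_variant `"cross_entropy"` (default; eliminate the argmin as
#'   described above) or `"separation"` (symmetrised Gaussian KLD between
#'   the two classes' decision-value distributions; eliminate the argmax,
#'   breakpoint at the trajectory maximum).
#' @param verbose print progress.
#' @return object of class `elimination_trace`; see [elimination_trace()].
#' @export
backward_eliminate <- function(ds, candidates, cost = 1, floor = 1, chunk = 1,
                               by_compound = FALSE, labels = NULL, clip = 1e-6,
                               kld_variant = c("cross_entropy", "separation"),
                               verbose = FALSE) {
  kld_variant <- match.arg(kld_variant)
  genes <- if (inherits(candidates, "candidate_set")) candidates$gene_ids
           else as.character(candidates)
  if (length(genes) < 2) stop("need at least 2 candidate analytes")
  if (floor < 1) stop("floor must be >= 1")
  if (chunk < 1) stop("chunk must be >= 1")
  dat <- chem_xy(ds, genes, labels)
  lab <- resolve_labels(dat$labels)
  if (min(table(lab$y)) < 2) stop("need at least 2 samples per class")
  fold <- as.integer(loocv_folds(dat$compounds, by_compound))
  ctl <- svm_ctrl()

  current <- genes
  records <- vector("list", length(genes) - floor)
  nrec <- 0L
  kld_start <- NA_real_
  step <- 0L
  while (length(current) > floor) {
    res <- cpp_step_klds(dat$X[current, , drop = FALSE], lab$y, fold,
                         cost, clip, ctl$tol, ctl$max_pass)
    if (kld_variant == "cross_entropy") {
      scores <- stats::setNames(as.numeric(res$klds), current)
      if (is.na(kld_start)) kld_start <- res$kld_full
      # eliminate the analyte whose removal leaves the lowest KLD
      ord <- order(scores, names(scores), method = "radix")
    } else {
      # higher class separation after removal = analyte was least needed
      scores <- stats::setNames(
        apply(res$D, 1, gaussian_separation, y = lab$y), current)
      if (is.na(kld_start))
        kld_start <- gaussian_separation(as.numeric(res$dec_full), lab$y)
      ord <- order(-scores, names(scores), method = "radix")
    }
    n_drop <- min(chunk, length(current) - floor)
    drop_now <- names(scores)[ord][seq_len(n_drop)]
    for (g in drop_now) {
      step <- step + 1L
      nrec <- nrec + 1L
      records[[nrec]] <- data.frame(step = step, eliminated = g,
                                    kld_after = unname(scores[g]),
                                    n_remaining = length(current) - match(g, drop_now),
                                    stringsAsFactors = FALSE)
    }
    current <- setdiff(current, drop_now)
    if (verbose)
      message(sprintf("step %d: %d analytes remain, kld %.4f",
                      step, length(current), min(scores)))
  }
  steps <- do.call(rbind, records[seq_len(nrec)])
  elimination_trace(steps, start_genes = genes, kld_start = kld_start,
                    variant = kld_variant, cost = cost, floor = floor,
                    chunk = chunk)
}

#' Construct an elimination trace
#'
#' Normally produced by [backward_eliminate()]; the constructor is exported
#' so traces can also be built from recorded step tables (e.g. to locate a
#' breakpoint in a published trajectory).
#'
#' @param steps data.frame with columns `step`, `eliminated`, `kld_after`,
#'   `n_remaining`.
#' @param start_genes the candidate analytes before any elimination.
#' @param kld_start KLD of the full candidate panel (optional).
#' @param variant elimination score variant.
#' @param cost,floor,chunk parameters used (metadata).
#' @return object of class `elimination_trace` with the breakpoint located
#'   and the signature filled in.
#' @export
elimination_trace <- function(steps, start_genes, kld_start = NA_real_,
                              variant = "cross_entropy", cost = 1,
                              floor = 1, chunk = 1) {
  req <- c("step", "eliminated", "kld_after", "n_remaining")
  miss <- setdiff(req, names(steps))
  if (length(miss)) stop("steps table lacks columns: ", paste(miss, collapse = ", "))
  if (nrow(steps) == 0) stop("empty trace")
  if (any(diff(steps$n_remaining) != -1))
    stop("n_remaining must decrease by exactly 1 per step")
  if (!all(steps$eliminated %in% start_genes))
    stop("eliminated analytes must come from start_genes")
  tr <- structure(list(steps = steps, start_genes = start_genes,
                       kld_start = kld_start, variant = variant,
                       cost = cost, floor = floor, chunk = chunk),
                  class = "elimination_trace")
  bp <- find_breakpoint(tr)
  tr$breakpoint_step <- bp$breakpoint_step
  tr$signature <- bp$signature
  tr
}

#' Locate the breakpoint of an elimination trace
#'
#' The breakpoint is the elimination step achieving the global minimum of
#' the recorded KLD trajectory (maximum, for the `"separation"` variant);
#' ties resolve to the latest such step, i.e. the smaller signature. The
#' signature is the set of analytes still remaining after that step.
#'
#' @param trace an `elimination_trace`.
#' @return list with `breakpoint_step` and `signature`.
#' @export
find_breakpoint <- function(trace) {
  stopifnot(inherits(trace, "elimination_trace"))
  v <- trace$steps$kld_after
  best <- if (identical(trace$variant, "separation")) max(v) else min(v)
  i <- max(which(v == best))
  eliminated <- trace$steps$eliminated[seq_len(i)]
  list(breakpoint_step = trace$steps$step[i],
       signature = setdiff(trace$start_genes, eliminated))
}

#' @export
print.elimination_trace <- function(x, ...) {
  cat(sprintf("elimination_trace: %d candidates -> %d steps (%s variant)\n",
              length(x$start_genes), nrow(x$steps), x$variant))
  cat(sprintf("  kld start %.4f, min %.4f at step %d; signature size %d\n",
              x$kld_start, min(x$steps$kld_after), x$breakpoint_step,
              length(x$signature)))
  invisible(x)
}
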