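#' Stratified compound-level train/test split
#'
#' Partitions the chemical compounds (never individual samples — all
#' replicates of a compound travel together) into training and test sets,
#' per class, uniformly at random under the seed. Per class, the training
#' set holds `round(train_frac * class size)` compounds (round half up),
#' clamped so both the training and test side keep at least one compound.
#' Vehicle controls are not part of the split.
#'
#' @param ds a [sensig_dataset()] with at least 2 compounds per class.
#' @param train_frac training fraction in (0, 1); default 0.7.
#' @param seed integer seed.
#' @param iteration optional iteration index carried as metadata.
#' @return object of class `split_plan` with `train_compounds` and
#'   `test_compounds`.
#' @export
stratified_split <- function(ds, train_frac = 0.7, seed = 1, iteration = NA_integer_) {
  stopifnot(inherits(ds, "sensig_dataset"))
  if (train_frac <= 0 || train_frac >= 1) stop("train_frac must be in (0, 1)")
  ann <- ds$annot[ds$annot$class_label != "vehicle_control", ]
  classes <- split(ann$compound_id, ann$class_label)
  classes <- lapply(classes, function(x) sort_ids(unique(x)))
  if (any(vapply(classes, length, 1L) < 2))
    stop("need at least 2 compounds per class to split")
  picks <- withr::with_seed(seed, {
    lapply(classes, function(comps) {
      k <- length(comps)
      n_train <- floor(train_frac * k + 0.5)     # round half up
      n_train <- min(max(n_train, 1L), k - 1L)   # >= 1 compound on each side
      sample(comps, n_train)
    })
  })
  train <- sort_ids(unlist(picks, use.names = FALSE))
  test <- sort_ids(setdiff(unlist(classes, use.names = FALSE), train))
  structure(list(iteration = iteration, seed = seed,
                 train_compounds = train, test_compounds = test),
            class = "split_plan")
}

#' ROC curve and AUC from classifier scores
#'
#' Threshold sweep over the unique scores (higher score = more
#' positive-like). The AUC is the trapezoidal area, which equals the
#' Mann-Whitney concordance probability with half credit for ties.
#'
#' @param scores numeric scores, one per item.
#' @param labels two-class labels; `positive` defaults to `"sensitizer"`
#'   when present, else the later class in sort order.
#' @param positive positive class label.
#' @return object of class `roc_curve`: `thresholds`, `tpr`, `fpr`, `auc`.
#' @export
roc_auc <- function(scores, labels, positive = NULL) {
  if (length(scores) != length(labels)) stop("scores and labels differ in length")
  lab <- resolve_labels(labels, positive)
  pos <- lab$y > 0
  if (!any(pos) || all(pos)) stop("both classes must be present")
  ord <- order(scores, decreasing = TRUE)
  s <- scores[ord]
  p <- pos[ord]
  last <- !duplicated(s, fromLast = TRUE)   # collapse tied scores to one point
  tp <- cumsum(p)[last]
  fp <- cumsum(!p)[last]
  tpr <- c(0, tp / sum(pos))
  fpr <- c(0, fp / sum(!pos))
  thresholds <- c(Inf, s[last])
  auc <- sum(diff(fpr) * (utils::head(tpr, -1) + utils::tail(tpr, -1)) / 2)
  structure(list(thresholds = thresholds, tpr = tpr, fpr = fpr, auc = auc),
            class = "roc_curve")
}

#' @export
print.roc_curve <- function(x, ...) {
  cat(sprintf("roc_curve: %d points, AUC = %.4f\n", length(x$tpr), x$auc))
  invisible(x)
}

#' Sensitivity, specificity and accuracy of binary calls
#'
#' @param calls logical (or 0/1) predicted positives.
#' @param truth logical (or 0/1) true positives; must contain both classes.
#' @return list with `sensitivity` (TP / (TP + FN)), `specificity`
#'   (TN / (TN + FP)) and `accuracy`.
#' @export
confusion_metrics <- function(calls, truth) {
  calls <- as.logical(calls)
  truth <- as.logical(truth)
  if (!length(calls) || length(calls) != length(truth))
    stop("calls and truth must be non-empty and of equal length")
  if (any(is.na(calls)) || any(is.na(truth))) stop("NA in calls or truth")
  if (all(truth) || !any(truth))
    stop("truth contains a single class; sensitivity or specificity undefined")
  tp <- sum(calls & truth); fn <- sum(!calls & truth)
  tn <- sum(!calls & !truth); fp <- sum(calls & !truth)
  list(sensitivity = tp / (tp + fn),
       specificity = tn / (tn + fp),
       accuracy = (tp + tn) / length(truth))
}

#' Single-marker compound screen
#'
#' Baseline against which the multivariate signature is motivated: for one
#' marker gene, each chemical compound's replicates are compared with the
#' matching vehicle-control replicates by a two-sided pooled-variance
#' t-test, and the compound is called positive when p < `alpha` and the
#' marker is elevated. Confusion metrics are computed over chemical
#' compounds against the sensitizer/non-sensitizer labels.
#'
#' @param ds a [sensig_dataset()] containing vehicle controls.
#' @param gene marker gene id.
#' @param alpha significance level (default 0.05).
#' @return list with `calls` (per-compound data.frame) and `metrics` (from
#'   [confusion_metrics()]).
#' @export
single_marker_screen <- function(ds, gene, alpha = 0.05) {
  stopifnot(inherits(ds, "sensig_dataset"))
  if (!gene %in% rownames(ds$exprs)) stop("gene not in dataset: ", gene)
  ann <- ds$annot
  chem <- ann[ann$class_label != "vehicle_control", ]
  comps <- unique(chem$compound_id)
  rows <- lapply(comps, function(cc) {
    sel <- ann$compound_id == cc
    veh <- unique(ann$vehicle[sel])
    ctrl <- ann$class_label == "vehicle_control" & ann$vehicle == veh
    if (sum(ctrl) < 2) stop("no (or too few) ", veh, " vehicle controls for compound ", cc)
    x <- ds$exprs[gene, ann$sample_id[sel]]
    y <- ds$exprs[gene, ann$sample_id[ctrl]]
    tt <- t.test(x, y, var.equal = TRUE, alternative = "two.sided")
    data.frame(compound_id = cc,
               class_label = unique(ann$class_label[sel]),
               delta = mean(x) - mean(y), p = tt$p.value,
               called = tt$p.value < alpha && mean(x) > mean(y),
               stringsAsFactors = FALSE)
  })
  calls <- do.call(rbind, rows)
  list(calls = calls,
       metrics = confusion_metrics(calls$called, calls$class_label == "sensitizer"))
}

#' Permute class labels at the compound level
#'
#' Reassigns the sensitizer / non-sensitizer labels to whole compounds at
#' random (class sizes preserved; replicates keep their compound's new
#' label; potencies are reassigned consistently). Vehicle controls are
#' untouched. Used for permutation-null checks of the validation pipeline.
#'
#' @param ds a [sensig_dataset()].
#' @param seed integer seed.
#' @return the relabelled dataset.
#' @export
permute_compound_labels <- function(ds, seed = 1) {
  stopifnot(inherits(ds, "sensig_dataset"))
  ann <- ds$annot
  chem <- ann$class_label != "vehicle_control"
  comps <- sort_ids(unique(ann$compound_id[chem]))
  old_class <- ann$class_label[chem][match(comps, ann$compound_id[chem])]
  new_class <- withr::with_seed(seed, sample(old_class))
  pot_pool <- ann$potency[chem][match(comps, ann$compound_id[chem])]
  pot_pool <- pot_pool[pot_pool != "none"]
  new_pot <- character(length(comps))
  new_pot[new_class == "sensitizer"] <- pot_pool[seq_len(sum(new_class == "sensitizer"))]
  new_pot[new_class != "sensitizer"] <- "none"
  idx <- match(ann$compound_id, comps)
  ann$class_label[!is.na(idx)] <- new_class[idx[!is.na(idx)]]
  ann$potency[!is.na(idx)] <- new_pot[idx[!is.na(idx)]]
  sensig_dataset(ds$exprs, ann)
}

# deterministic per-iteration seed from the master seed
iter_seed <- function(seed, i) as.integer((as.numeric(seed) + 104729 * i) %% 2147483647L)

#' Resampling validation of the signature-selection procedure
#'
#' The interrogation workflow: in each iteration the chemical compounds are
#' split 70/30 (stratified by class, all replicates travelling together),
#' the whole selection procedure — ANOVA filtering and KLD-scored backward
#' elimination — is re-run on the training samples only, an SVM is trained
#' on the resulting test signature, and the held-out samples are scored.
#' Per-iteration ROC/AUC, test signatures and per-gene call frequencies are
#' aggregated.
#'
#' @param ds a [sensig_dataset()] with both classes.
#' @param n_iter number of random splits (the study used 20).
#' @param train_frac training fraction of compounds per class.
#' @param threshold p-value cutoff for candidate selection on training data.
#' @param top_k alternatively, number of top candidates (by training p) —
#'   the practical choice at reduced gene counts.
#' @param signature_mode `"breakpoint"` re-derives the signature at each
#'   iteration's KLD breakpoint; `"fixed"` eliminates down to
#'   `signature_size` analytes (the study fixed 200 at full scale).
#' @param signature_size panel size for `signature_mode = "fixed"`.
#' @param cost,floor,chunk,clip,by_compound passed to
#'   [backward_eliminate()].
#' @param seed master seed; per-iteration seeds are derived from it by
#'   iteration index.
#' @param verbose print per-iteration progress.
#' @return object of class `validation_result`: per-iteration `splits`,
#'   `signatures` and `roc` curves, `auc` vector, `mean_auc`, and
#'   `call_frequency` (percent of iterations selecting each gene).
#' @export
run_validation <- function(ds, n_iter = 20, train_frac = 0.7,
                           threshold = NULL, top_k = NULL,
                           signature_mode = c("breakpoint", "fixed"),
                           signature_size = NULL, cost = 1, floor = 1,
                           chunk = 1, clip = 1e-6, by_compound = FALSE,
                           seed = 1, verbose = FALSE) {
  signature_mode <- match.arg(signature_mode)
  if (signature_mode == "fixed" && is.null(signature_size))
    stop("signature_size required for signature_mode = 'fixed'")
  if (is.null(threshold) && is.null(top_k))
    stop("give either threshold or top_k for candidate selection")
  splits <- vector("list", n_iter)
  signatures <- vector("list", n_iter)
  rocs <- vector("list", n_iter)
  auc <- numeric(n_iter)
  for (i in seq_len(n_iter)) {
    plan <- stratified_split(ds, train_frac, seed = iter_seed(seed, i), iteration = i)
    train_ds <- subset_samples(ds, compounds = plan$train_compounds)
    p_train <- anova_two_group(train_ds)
    stats_df <- data.frame(gene_id = names(p_train), p_two_group = unname(p_train),
                           stringsAsFactors = FALSE)
    cand <- select_candidates(stats_df, "two_group",
                              threshold = threshold, top_k = top_k)
    elim_floor <- if (signature_mode == "fixed")
      min(signature_size, length(cand$gene_ids)) else floor
    trace <- backward_eliminate(train_ds, cand, cost = cost, floor = elim_floor,
                                chunk = chunk, by_compound = by_compound,
                                clip = clip)
    sig <- if (signature_mode == "fixed")
      setdiff(trace$start_genes, trace$steps$eliminated) else trace$signature
    xy_tr <- chem_xy(train_ds, sig)
    clf <- train_classifier(t(xy_tr$X), xy_tr$labels, cost = cost)
    # orient scores so higher = more sensitizer-like, fixed on training means
    d_tr <- predict(clf, t(xy_tr$X), type = "decision")
    flip <- mean(d_tr[xy_tr$labels == clf$positive]) <
      mean(d_tr[xy_tr$labels != clf$positive])
    test_ds <- subset_samples(ds, compounds = plan$test_compounds)
    xy_te <- chem_xy(test_ds, sig)
    d_te <- predict(clf, t(xy_te$X), type = "decision")
    if (flip) d_te <- -d_te
    rocs[[i]] <- roc_auc(d_te, xy_te$labels, positive = clf$positive)
    auc[i] <- rocs[[i]]$auc
    splits[[i]] <- plan
    signatures[[i]] <- sig
    if (verbose)
      message(sprintf("iteration %d: signature %d genes, AUC %.3f",
                      i, length(sig), auc[i]))
  }
  all_genes <- sort_ids(unique(unlist(signatures)))
  freq <- vapply(all_genes, function(g)
    100 * sum(vapply(signatures, function(s) g %in% s, logical(1))) / n_iter,
    numeric(1))
  structure(list(splits = splits, signatures = signatures, roc = rocs,
                 auc = auc, mean_auc = mean(auc),
                 call_frequency = data.frame(gene_id = all_genes,
                                             call_frequency = unname(freq),
                                             stringsAsFactors = FALSE),
                 n_iter = n_iter, seed = seed,
                 signature_mode = signature_mode),
            class = "validation_result")
}

#' @export
print.validation_result <- function(x, ...) {
  cat(sprintf("validation_result: %d iterations, mean AUC %.3f (range %.3f-%.3f)\n",
              x$n_iter, x$mean_auc, min(x$auc), max(x$auc)))
  cat(sprintf("  %d genes selected at least once; %d in every iteration\n",
              nrow(x$call_frequency), sum(x$call_frequency$call_frequency == 100)))
  invisible(x)
}
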