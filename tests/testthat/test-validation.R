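test_that("stratified splits respect the rounding rule and class sizes", {
  gen <- generate_dataset(synth_config(n_genes = 10, n_sens_compounds = 18,
                                       n_nonsens_compounds = 20, replicates = 2,
                                       n_controls_per_vehicle = 2, seed = 3))
  ds <- gen$dataset
  plan <- stratified_split(ds, train_frac = 0.7, seed = 5)
  ann <- ds$annot[ds$annot$class_label != "vehicle_control", ]
  cls <- function(comps) table(ann$class_label[match(comps, ann$compound_id)])
  tr <- cls(plan$train_compounds)
  te <- cls(plan$test_compounds)
  expect_equal(unname(tr[["sensitizer"]]), 13)        # round(0.7 * 18) = 13
  expect_equal(unname(tr[["non_sensitizer"]]), 14)    # round(0.7 * 20) = 14
  expect_equal(unname(te[["sensitizer"]]), 5)
  expect_equal(unname(te[["non_sensitizer"]]), 6)
  # partition: disjoint and exhaustive over chemical compounds
  expect_length(intersect(plan$train_compounds, plan$test_compounds), 0)
  expect_setequal(c(plan$train_compounds, plan$test_compounds),
                  unique(ann$compound_id))
  # determinism
  expect_identical(plan, stratified_split(ds, train_frac = 0.7, seed = 5))
  expect_false(identical(plan$train_compounds,
                         stratified_split(ds, 0.7, seed = 6)$train_compounds))
})

test_that("extreme train fractions still leave one compound per class per side", {
  ds <- toy_dataset(n_sens = 3, n_nonsens = 3)
  hi <- stratified_split(ds, train_frac = 0.99, seed = 1)
  lo <- stratified_split(ds, train_frac = 0.01, seed = 1)
  ann <- ds$annot[ds$annot$class_label != "vehicle_control", ]
  for (plan in list(hi, lo)) {
    for (side in list(plan$train_compounds, plan$test_compounds)) {
      cls <- ann$class_label[match(side, ann$compound_id)]
      expect_gte(sum(cls == "sensitizer"), 1)
      expect_gte(sum(cls == "non_sensitizer"), 1)
    }
  }
  expect_error(stratified_split(ds, train_frac = 1.2), "train_frac")
})

test_that("roc_auc matches the worked example and closed forms", {
  r <- roc_auc(c(0.9, 0.8, 0.7, 0.6), c("pos", "neg", "pos", "neg"),
               positive = "pos")
  expect_equal(r$auc, 0.75)
  expect_equal(r$tpr[1], 0); expect_equal(r$fpr[1], 0)
  expect_equal(r$tpr[length(r$tpr)], 1); expect_equal(r$fpr[length(r$fpr)], 1)
  expect_true(all(diff(r$tpr) >= 0) && all(diff(r$fpr) >= 0))

  expect_equal(roc_auc(c(5, 4, 1, 0), c("p", "p", "n", "n"), "p")$auc, 1.0)
  expect_equal(roc_auc(rep(2, 6), rep(c("p", "n"), 3), "p")$auc, 0.5)
  expect_error(roc_auc(1:3, c("p", "p", "p"), "p"), "two classes")
})

test_that("roc_auc equals brute-force pair counting and pROC", {
  library(pROC)
  for (i in 1:40) {
    withr::with_seed(3000 + i, {
      n <- sample(6:25, 1)
      sc <- round(rnorm(n), sample(0:1, 1))    # rounding forces ties
      lab <- sample(c("p", "n"), n, replace = TRUE)
      if (length(unique(lab)) < 2) lab[1:2] <- c("p", "n")
    })
    a <- roc_auc(sc, lab, positive = "p")$auc
    expect_equal(a, auc_brute(sc, lab == "p"), tolerance = 1e-12)
    a_ref <- as.numeric(pROC::auc(pROC::roc(response = lab, predictor = sc,
                                            levels = c("n", "p"),
                                            direction = "<", quiet = TRUE)))
    expect_equal(a, a_ref, tolerance = 1e-12)
  }
})

test_that("confusion metrics reproduce the single-marker baseline arithmetic", {
  # 10 of 20 sensitizers called, 0 of 20 non-sensitizers called
  calls <- c(rep(TRUE, 10), rep(FALSE, 10), rep(FALSE, 20))
  truth <- c(rep(TRUE, 20), rep(FALSE, 20))
  m <- confusion_metrics(calls, truth)
  expect_equal(m$sensitivity, 0.5)
  expect_equal(m$specificity, 1.0)
  expect_equal(m$accuracy, 0.75)

  m_all <- confusion_metrics(truth, truth)
  expect_equal(unlist(m_all), c(sensitivity = 1, specificity = 1, accuracy = 1))
  m_inv <- confusion_metrics(!truth, truth)
  expect_equal(unlist(m_inv), c(sensitivity = 0, specificity = 0, accuracy = 0))
  expect_error(confusion_metrics(calls, rep(TRUE, 40)), "single class")
})

test_that("single-marker screen calls shifted compounds against matching controls", {
  ds <- toy_dataset(n_sens = 4, n_nonsens = 4, reps = 3, n_genes = 5,
                    n_signal = 0, noise = 0.1, seed = 53)
  # give exactly half the sensitizers a +5 marker effect on Gene01
  carriers <- c("SENS_01", "SENS_02")
  sel <- ds$annot$compound_id %in% carriers
  m <- ds$exprs
  m["Gene01", sel] <- m["Gene01", sel] + 5
  ds <- sensig_dataset(m, ds$annot)
  scr <- single_marker_screen(ds, "Gene01", alpha = 0.05)
  expect_setequal(scr$calls$compound_id[scr$calls$called], carriers)
  expect_equal(scr$metrics$sensitivity, 0.5)
  expect_equal(scr$metrics$specificity, 1.0)

  # a compound identical to its controls is never called
  scr2 <- single_marker_screen(ds, "Gene02", alpha = 0.05)
  expect_false(any(scr2$calls$called[scr2$calls$compound_id == "SENS_03"]))
  expect_error(single_marker_screen(ds, "NOPE"), "NOPE")
})

test_that("run_validation aggregates per-iteration results coherently", {
  ds <- toy_dataset(n_sens = 5, n_nonsens = 5, reps = 3, n_genes = 12,
                    n_signal = 3, shift = 4, noise = 0.4, seed = 59)
  v <- run_validation(ds, n_iter = 1, top_k = 6, seed = 2)
  expect_length(v$auc, 1)
  expect_true(all(v$call_frequency$call_frequency %in% c(0, 100)))
  expect_equal(v$mean_auc, v$auc[1])

  v3 <- run_validation(ds, n_iter = 3, top_k = 6, seed = 2)
  expect_equal(v3$mean_auc, mean(v3$auc))
  expect_setequal(v3$call_frequency$gene_id, unique(unlist(v3$signatures)))
  expect_true(all(v3$call_frequency$call_frequency >= 0 &
                    v3$call_frequency$call_frequency <= 100))
  # a gene in every iteration's signature is called 100%
  always <- Reduce(intersect, v3$signatures)
  if (length(always))
    expect_true(all(v3$call_frequency$call_frequency[
      v3$call_frequency$gene_id %in% always] == 100))
  # deterministic under the master seed
  v3b <- run_validation(ds, n_iter = 3, top_k = 6, seed = 2)
  expect_identical(v3$auc, v3b$auc)
  expect_identical(v3$signatures, v3b$signatures)
})

test_that("fixed-size signature mode eliminates down to the requested panel", {
  ds <- toy_dataset(n_sens = 4, n_nonsens = 4, reps = 3, n_genes = 10,
                    n_signal = 3, shift = 4, noise = 0.4, seed = 61)
  v <- run_validation(ds, n_iter = 2, top_k = 8, signature_mode = "fixed",
                      signature_size = 4, seed = 9)
  expect_true(all(vapply(v$signatures, length, 1L) == 4))
})

test_that("no test-set leakage: perturbing test samples never changes the signature", {
  ds <- toy_dataset(n_sens = 4, n_nonsens = 4, reps = 3, n_genes = 10,
                    n_signal = 3, shift = 4, noise = 0.4, seed = 67)
  plan <- stratified_split(ds, 0.7, seed = 4)
  derive <- function(d) {
    train <- subset_samples(d, compounds = plan$train_compounds)
    p <- anova_two_group(train)
    cand <- select_candidates(
      data.frame(gene_id = names(p), p_two_group = unname(p)), "two_group",
      top_k = 6)
    backward_eliminate(train, cand, floor = 1)$signature
  }
  sig0 <- derive(ds)
  # garble every test-set sample
  m <- ds$exprs
  test_samples <- ds$annot$sample_id[ds$annot$compound_id %in% plan$test_compounds]
  m[, test_samples] <- withr::with_seed(1, matrix(rnorm(length(m[, test_samples]),
                                                        0, 10),
                                                  nrow(m)))
  sig1 <- derive(sensig_dataset(m, ds$annot))
  expect_identical(sig0, sig1)
})
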