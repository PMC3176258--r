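test_that("a separable one-feature pair is classified correctly", {
  x <- matrix(c(-1, 1), ncol = 1, dimnames = list(c("s1", "s2"), "g1"))
  clf <- train_classifier(x, c("non_sensitizer", "sensitizer"))
  test <- matrix(c(-1, 1), ncol = 1, dimnames = list(c("t1", "t2"), "g1"))
  expect_identical(unname(predict(clf, test, type = "class")),
                   c("non_sensitizer", "sensitizer"))
  expect_error(train_classifier(x, c("sensitizer", "sensitizer")), "class")
})

test_that("duplicating every sample leaves the decision boundary unchanged", {
  withr::with_seed(7, {
    x <- matrix(rnorm(40), 20, 2, dimnames = list(sprintf("s%d", 1:20), c("g1", "g2")))
    y <- rep(c("sensitizer", "non_sensitizer"), each = 10)
    x[y == "sensitizer", 1] <- x[y == "sensitizer", 1] + 6
  })
  # wide-margin separable data: the hard-margin solution is interior, so it
  # is insensitive to duplicating the sample mass (up to the n-1 sd scaling)
  clf1 <- train_classifier(x, y, cost = 5)
  x2 <- rbind(x, x)
  rownames(x2) <- sprintf("s%d", 1:40)
  clf2 <- train_classifier(x2, c(y, y), cost = 5)
  expect_equal(clf1$w, clf2$w, tolerance = 0.02)
  expect_equal(clf1$b, clf2$b, tolerance = 0.05)
  d1 <- predict(clf1, x, type = "class")
  d2 <- predict(clf2, x, type = "class")
  expect_identical(d1, d2)
})

test_that("training accuracy is high with informative features", {
  withr::with_seed(11, {
    x <- matrix(rnorm(40 * 10), 40, 10,
                dimnames = list(sprintf("s%d", 1:40), sprintf("g%d", 1:10)))
    y <- rep(c("sensitizer", "non_sensitizer"), each = 20)
    x[y == "sensitizer", 1:2] <- x[y == "sensitizer", 1:2] + 2.5
  })
  clf <- train_classifier(x, y)
  acc <- mean(predict(clf, x, type = "class") == y)
  expect_gte(acc, 0.95)
  p <- predict(clf, x, type = "probability")
  expect_true(all(p > 0 & p < 1))
})

test_that("the compiled solver agrees with e1071's linear SVM", {
  library(e1071)
  for (i in 1:5) {
    withr::with_seed(200 + i, {
      x <- matrix(rnorm(30 * 5), 30, 5,
                  dimnames = list(sprintf("s%d", 1:30), sprintf("g%d", 1:5)))
      y <- rep(c("a", "b"), 15)
      x[y == "b", 1] <- x[y == "b", 1] + 2
    })
    clf <- train_classifier(x, y, cost = 1)
    d_mine <- predict(clf, x, type = "decision")
    z <- scale(x)
    m <- svm(z, factor(y), kernel = "linear", cost = 1, scale = FALSE)
    d_ref <- as.numeric(attr(predict(m, z, decision.values = TRUE),
                             "decision.values"))
    if (cor(d_mine, d_ref) < 0) d_ref <- -d_ref   # sign is level-order dependent
    expect_gt(cor(d_mine, d_ref), 0.99)
    agree <- mean((d_mine > 0) == (d_ref > 0))
    expect_gte(agree, 0.95)
  }
})

test_that("LOOCV probabilities are confident on separated data and null on permuted labels", {
  ds <- toy_dataset(n_sens = 5, n_nonsens = 5, reps = 3, n_genes = 10,
                    n_signal = 3, shift = 6, noise = 0.1, seed = 13)
  p <- loocv_probabilities(ds)
  expect_true(all(p >= 0.9))
  expect_lt(kld(p), 0.11)

  perm_lab <- withr::with_seed(5, sample(rep(c("sensitizer", "non_sensitizer"),
                                             each = 15)))
  p_null <- loocv_probabilities(ds, labels = perm_lab)
  expect_lt(abs(mean(p_null) - 0.5), 0.1)
})

test_that("kld matches closed forms and is monotone in any single probability", {
  expect_equal(kld(rep(0.5, 10)), log(2), tolerance = 1e-12)
  expect_equal(kld(rep(1 - 1e-6, 4)), 1e-6, tolerance = 1e-5)
  p <- c(0.9, 0.8, 0.6)
  p2 <- c(0.9, 0.5, 0.6)
  expect_gt(kld(p2), kld(p))
  expect_error(kld(numeric()), "empty")
  expect_error(kld(c(0.5, 1)), "inside")
})

test_that("the least informative analyte is eliminated first, the informative one last", {
  # 1 strongly informative + 3 pure-noise analytes
  ds <- toy_dataset(n_sens = 6, n_nonsens = 6, reps = 3, n_genes = 4,
                    n_signal = 1, shift = 5, noise = 0.3, seed = 19)
  tr <- backward_eliminate(ds, rownames(ds$exprs), floor = 1)
  # the informative analyte is never eliminated: it is the one that survives
  # the full trace, and removing it costs by far the most KLD at every step
  expect_identical(setdiff(rownames(ds$exprs), tr$steps$eliminated), "Gene01")
  expect_false("Gene01" %in% tr$steps$eliminated)
  expect_false(anyDuplicated(tr$steps$eliminated) > 0)
  expect_equal(tr$steps$n_remaining, 3:1)
  expect_setequal(c(tr$steps$eliminated,
                    setdiff(rownames(ds$exprs), tr$steps$eliminated)),
                  rownames(ds$exprs))
})

test_that("identical duplicate analytes tie and break lexicographically", {
  ds <- toy_dataset(n_sens = 4, n_nonsens = 4, reps = 3, n_genes = 2,
                    n_signal = 1, shift = 4, noise = 0.3, seed = 23)
  m <- ds$exprs
  m <- rbind(m, GeneCopyB = m["Gene01", ], GeneCopyA = m["Gene01", ])
  ds2 <- sensig_dataset(m, ds$annot)
  tr <- backward_eliminate(ds2, c("Gene01", "GeneCopyA", "GeneCopyB"), floor = 2)
  # removing any of the three identical copies leaves the same panel -> tie;
  # the lexicographically smallest id goes first
  expect_identical(tr$steps$eliminated[1], "Gene01")
})

test_that("elimination traces are deterministic and recover informative analytes", {
  cfg <- synth_config(n_genes = 25, n_informative = 5, n_sens_compounds = 6,
                      n_nonsens_compounds = 6, replicates = 3,
                      n_controls_per_vehicle = 2,
                      potency_effects = c(extreme = 2, strong = 2,
                                          moderate = 2, weak = 2),
                      idiosyncratic_sd = 0.3, noise_sd = 0.5, seed = 29)
  gen <- generate_dataset(cfg)
  tr1 <- backward_eliminate(gen$dataset, rownames(gen$dataset$exprs), floor = 1)
  tr2 <- backward_eliminate(gen$dataset, rownames(gen$dataset$exprs), floor = 1)
  expect_identical(tr1$steps, tr2$steps)
  # KLD trajectory dips below the full-panel starting value
  expect_lt(min(tr1$steps$kld_after), tr1$kld_start)
  # most informative analytes survive to the breakpoint
  expect_gte(sum(gen$truth$informative %in% tr1$signature), 4)
})

test_that("find_breakpoint picks the global minimum, latest on ties", {
  mk <- function(klds) {
    n <- length(klds)
    elimination_trace(
      data.frame(step = seq_len(n), eliminated = sprintf("g%03d", seq_len(n)),
                 kld_after = klds, n_remaining = (n + 1 - seq_len(n)) + 1),
      start_genes = sprintf("g%03d", seq_len(n + 2)))
  }
  tr <- mk(c(0.5, 0.3, 0.4, 0.3, 0.6))       # tie at steps 2 and 4
  expect_equal(tr$breakpoint_step, 4)
  expect_identical(tr$signature, c("g005", "g006", "g007"))

  expect_equal(mk(c(0.5, 0.4, 0.3))$breakpoint_step, 3)  # strictly decreasing
  expect_equal(length(mk(c(0.5, 0.4, 0.3))$signature), 2) # = floor of the trace
  tr_up <- mk(c(0.3, 0.4, 0.5))               # strictly increasing
  expect_equal(tr_up$breakpoint_step, 1)
  expect_equal(length(tr_up$signature), 4)    # N - 1 of the 5 start genes
})

test_that("a 1010-analyte trace with its minimum at step 810 leaves 200 genes", {
  genes <- sprintf("A%04d", 1:1010)
  klds <- c(seq(1, 0.2, length.out = 810), seq(0.25, 0.9, length.out = 199))
  tr <- elimination_trace(
    data.frame(step = 1:1009, eliminated = genes[1:1009], kld_after = klds,
               n_remaining = 1009:1),
    start_genes = genes)
  expect_equal(tr$breakpoint_step, 810)
  expect_equal(length(tr$signature), 200)
})

test_that("trace invariants are validated", {
  expect_error(elimination_trace(data.frame(step = 1, eliminated = "x",
                                            kld_after = 0.1, n_remaining = 3),
                                 start_genes = c("a", "b")),
               "start_genes")
  expect_error(elimination_trace(data.frame(step = 1:2, eliminated = c("a", "b"),
                                            kld_after = c(0.1, 0.2),
                                            n_remaining = c(3, 1)),
                                 start_genes = c("a", "b", "c", "d")),
               "decrease")
})

test_that("chunked elimination approximates the exact trace", {
  ds <- toy_dataset(n_sens = 4, n_nonsens = 4, reps = 3, n_genes = 12,
                    n_signal = 2, shift = 4, noise = 0.4, seed = 37)
  tr <- backward_eliminate(ds, rownames(ds$exprs), floor = 2, chunk = 3)
  expect_equal(tr$chunk, 3)
  expect_equal(nrow(tr$steps), 10)
  expect_equal(tr$steps$n_remaining, 11:2)
  # informative analytes still make it to the final panel
  remaining <- setdiff(rownames(ds$exprs), tr$steps$eliminated)
  expect_setequal(remaining, c("Gene01", "Gene02"))
})

test_that("compound-wise LOOCV folds work and keep replicates together", {
  ds <- toy_dataset(n_sens = 4, n_nonsens = 4, reps = 3, n_genes = 6,
                    n_signal = 2, shift = 4, noise = 0.3, seed = 43)
  p <- loocv_probabilities(ds, by_compound = TRUE)
  expect_true(all(p >= 0.8))
})

test_that("the separation scoring variant also recovers informative analytes", {
  ds <- toy_dataset(n_sens = 5, n_nonsens = 5, reps = 3, n_genes = 8,
                    n_signal = 2, shift = 4, noise = 0.4, seed = 47)
  tr <- backward_eliminate(ds, rownames(ds$exprs), floor = 2,
                           kld_variant = "separation")
  expect_identical(tr$variant, "separation")
  last_two <- setdiff(rownames(ds$exprs), tr$steps$eliminated)
  expect_true("Gene01" %in% last_two)
  expect_true(all(tr$steps$kld_after >= 0))
})
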