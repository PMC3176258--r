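# Small in-code fixtures shared across test files.

# Hand-built dataset: n_sens + n_nonsens compounds x reps, plus vehicle
# controls, genes named Gene01.. . Values are baseline + per-class shift on
# the first `n_signal` genes + N(0, noise) under the seed.
toy_dataset <- function(n_sens = 2, n_nonsens = 2, reps = 3, n_genes = 6,
                        n_controls = 2, n_signal = 2, shift = 3,
                        noise = 0.2, seed = 42) {
  withr::with_seed(seed, {
    comp <- c(sprintf("SENS_%02d", seq_len(n_sens)),
              sprintf("NONS_%02d", seq_len(n_nonsens)))
    cls <- rep(c("sensitizer", "non_sensitizer"), c(n_sens, n_nonsens))
    ann <- list()
    cols <- list()
    genes <- sprintf("Gene%02d", seq_len(n_genes))
    base <- rnorm(n_genes, 7, 1)
    for (ci in seq_along(comp)) {
      mu <- base
      if (cls[ci] == "sensitizer" && n_signal > 0)
        mu[seq_len(n_signal)] <- mu[seq_len(n_signal)] + shift
      for (r in seq_len(reps)) {
        sid <- sprintf("%s_r%d", comp[ci], r)
        ann[[sid]] <- data.frame(
          sample_id = sid, compound_id = comp[ci], class_label = cls[ci],
          vehicle = if (ci %% 2 == 1) "DMSO" else "water", replicate = r,
          potency = if (cls[ci] == "sensitizer") "strong" else "none",
          stringsAsFactors = FALSE)
        cols[[sid]] <- mu + rnorm(n_genes, 0, noise)
      }
    }
    for (v in c("DMSO", "water")) {
      for (r in seq_len(n_controls)) {
        sid <- sprintf("VEHICLE_%s_r%d", toupper(v), r)
        sid <- sub("WATER", "WATER", sid)
        token <- if (v == "DMSO") "VEHICLE_DMSO" else "VEHICLE_WATER"
        sid <- sprintf("%s_r%d", token, r)
        ann[[sid]] <- data.frame(
          sample_id = sid, compound_id = token, class_label = "vehicle_control",
          vehicle = v, replicate = r, potency = "none",
          stringsAsFactors = FALSE)
        cols[[sid]] <- base + rnorm(n_genes, 0, noise)
      }
    }
    m <- do.call(cbind, cols)
    rownames(m) <- genes
    sensig_dataset(m, do.call(rbind, unname(ann)))
  })
}

# brute-force BH step-up, independent of p.adjust
bh_brute <- function(p) {
  m <- length(p)
  o <- order(p)
  q <- numeric(m)
  for (i in seq_len(m)) {
    j <- which(o == i)               # rank of p[i]
    q[i] <- min(1, min(m * p[o][j:m] / (j:m)))
  }
  q
}

# brute-force Mann-Whitney AUC with half credit for ties
auc_brute <- function(scores, positive) {
  s_pos <- scores[positive]
  s_neg <- scores[!positive]
  tot <- 0
  for (a in s_pos) for (b in s_neg)
    tot <- tot + if (a > b) 1 else if (a == b) 0.5 else 0
  tot / (length(s_pos) * length(s_neg))
}
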