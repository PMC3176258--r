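# flat key=value manifest with md5 checksums of written artifacts, so a run
# can be reproduced and its outputs verified
write_manifest <- function(path, config, files = character()) {
  kv <- c(sprintf("package=sensig %s", as.character(utils::packageVersion("sensig"))),
          vapply(names(config), function(k) {
            v <- config[[k]]
            sprintf("%s=%s", k, paste(format(v, digits = 15), collapse = ","))
          }, character(1)))
  if (length(files)) {
    sums <- tools::md5sum(files)
    kv <- c(kv, sprintf("md5:%s=%s", basename(files), unname(sums)))
  }
  writeLines(kv, path)
  invisible(path)
}

write_tsv <- function(df, path) {
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  path
}

#' Simulate a dataset and write it to disk
#'
#' Orchestration front-end for [generate_dataset()]: writes
#' `expression.tsv`, `annotation.tsv`, `truth.tsv` and `manifest.txt` into
#' `out_dir`.
#'
#' @param cfg a [synth_config()]; default [default_study_design()].
#' @param out_dir output directory (created); if `NULL` nothing is written.
#' @return list with `dataset` and `truth`, invisibly.
#' @export
simulate_dataset <- function(cfg = default_study_design(), out_dir = NULL) {
  gen <- generate_dataset(cfg)
  if (!is.null(out_dir)) {
    write_dataset(gen$dataset, out_dir, truth = gen$truth)
    files <- file.path(out_dir, c("expression.tsv", "annotation.tsv", "truth.tsv"))
    keep <- !vapply(cfg, is.null, logical(1))
    write_manifest(file.path(out_dir, "manifest.txt"),
                   c(list(command = "simulate"), unclass(cfg)[keep]), files)
    message(sprintf("simulated %d genes x %d samples -> %s",
                    nrow(gen$dataset$exprs), ncol(gen$dataset$exprs), out_dir))
  }
  invisible(gen)
}

#' Run the discovery workflow
#'
#' End-to-end signature discovery on one dataset: optional sample/compound
#' removal, per-transcript ANOVA statistics, candidate selection, backward
#' elimination with breakpoint detection, PCA of the signature, and a
#' z-scored, cluster-ordered heatmap matrix. With `out_dir` set, writes
#' `gene_stats.tsv`, `candidates.txt`, `elimination_trace.tsv`,
#' `signature.txt`, `pca_scores.tsv`, `heatmap_matrix.tsv` and
#' `manifest.txt`.
#'
#' @param ds a [sensig_dataset()].
#' @param drop_compounds,drop_samples passed to [remove_samples()].
#' @param comparison,threshold,top_k candidate selection (see
#'   [select_candidates()]).
#' @param cost,floor,chunk,clip,kld_variant,by_compound passed to
#'   [backward_eliminate()].
#' @param n_components PCA components for the signature score plot.
#' @param out_dir output directory; if `NULL` nothing is written.
#' @return list with `dataset`, `stats`, `candidates`, `trace`,
#'   `signature`, `pca`, `heatmap_order`, invisibly.
#' @export
discover_signature <- function(ds, drop_compounds = character(),
                               drop_samples = character(),
                               comparison = "two_group", threshold = NULL,
                               top_k = NULL, cost = 1, floor = 1, chunk = 1,
                               clip = 1e-6, kld_variant = "cross_entropy",
                               by_compound = FALSE, n_components = 3,
                               out_dir = NULL) {
  if (length(drop_compounds) || length(drop_samples))
    ds <- remove_samples(ds, drop_compounds, drop_samples)
  stats <- gene_stats(ds)
  message(sprintf("gene stats: %d genes x %d samples", nrow(stats), ncol(ds$exprs)))
  cand <- select_candidates(stats, comparison, threshold = threshold, top_k = top_k)
  message(sprintf("candidates: %d analytes", length(cand$gene_ids)))
  trace <- backward_eliminate(ds, cand, cost = cost, floor = floor,
                              chunk = chunk, clip = clip,
                              kld_variant = kld_variant,
                              by_compound = by_compound)
  sig <- trace$signature
  message(sprintf("breakpoint at step %d; signature %d analytes",
                  trace$breakpoint_step, length(sig)))
  pca <- fit_pca(ds, genes = sig, n_components = n_components)
  hm <- ds$exprs[sig, , drop = FALSE]
  hm_order <- hierarchical_order(hm)
  res <- list(dataset = ds, stats = stats, candidates = cand, trace = trace,
              signature = sig, pca = pca, heatmap_order = hm_order)
  if (!is.null(out_dir)) {
    dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
    files <- c(
      write_tsv(stats, file.path(out_dir, "gene_stats.tsv")),
      {
        p <- file.path(out_dir, "candidates.txt")
        writeLines(c(sprintf("# threshold: %.6g", cand$threshold),
                     sprintf("# comparison: %s", cand$comparison),
                     cand$gene_ids), p)
        p
      },
      write_tsv(trace$steps, file.path(out_dir, "elimination_trace.tsv")),
      {
        p <- file.path(out_dir, "signature.txt")
        writeLines(sig, p)
        p
      },
      write_tsv(
        data.frame(sample_id = ds$annot$sample_id,
                   pca$scores[ds$annot$sample_id, , drop = FALSE],
                   class = ds$annot$class_label, potency = ds$annot$potency,
                   check.names = FALSE),
        file.path(out_dir, "pca_scores.tsv")),
      {
        z <- suppressWarnings(zscore_rows(hm))[hm_order, , drop = FALSE]
        write_expression(z, file.path(out_dir, "heatmap_matrix.tsv"))
        file.path(out_dir, "heatmap_matrix.tsv")
      })
    cfgkv <- list(command = "discover", comparison = comparison,
                  threshold = threshold %||% NA, top_k = top_k %||% NA,
                  cost = cost, floor = floor, chunk = chunk, clip = clip,
                  kld_variant = kld_variant,
                  breakpoint_step = trace$breakpoint_step,
                  signature_size = length(sig))
    write_manifest(file.path(out_dir, "manifest.txt"), cfgkv, files)
  }
  invisible(res)
}

#' Run the interrogation (resampling validation) workflow
#'
#' Front-end for [run_validation()]; with `out_dir` set, writes
#' `auc.tsv` (per-iteration AUC), `call_frequency.tsv`, one signature gene
#' list per iteration, and `manifest.txt`.
#'
#' @inheritParams run_validation
#' @param out_dir output directory; if `NULL` nothing is written.
#' @return the [run_validation()] result, invisibly.
#' @export
validate_signature <- function(ds, n_iter = 20, train_frac = 0.7,
                               threshold = NULL, top_k = NULL,
                               signature_mode = "breakpoint",
                               signature_size = NULL, cost = 1, floor = 1,
                               chunk = 1, clip = 1e-6, by_compound = FALSE,
                               seed = 1, out_dir = NULL, verbose = FALSE) {
  res <- run_validation(ds, n_iter = n_iter, train_frac = train_frac,
                        threshold = threshold, top_k = top_k,
                        signature_mode = signature_mode,
                        signature_size = signature_size, cost = cost,
                        floor = floor, chunk = chunk, clip = clip,
                        by_compound = by_compound, seed = seed,
                        verbose = verbose)
  message(sprintf("validation: %d iterations, mean AUC %.3f",
                  n_iter, res$mean_auc))
  if (!is.null(out_dir)) {
    dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
    files <- c(
      write_tsv(data.frame(iteration = seq_len(n_iter), auc = res$auc),
                file.path(out_dir, "auc.tsv")),
      write_tsv(res$call_frequency, file.path(out_dir, "call_frequency.tsv")))
    for (i in seq_len(n_iter)) {
      p <- file.path(out_dir, sprintf("signature_iter%02d.txt", i))
      writeLines(res$signatures[[i]], p)
      files <- c(files, p)
    }
    cfgkv <- list(command = "validate", n_iter = n_iter,
                  train_frac = train_frac, threshold = threshold %||% NA,
                  top_k = top_k %||% NA, signature_mode = signature_mode,
                  signature_size = signature_size %||% NA, cost = cost,
                  seed = seed, mean_auc = res$mean_auc)
    write_manifest(file.path(out_dir, "manifest.txt"), cfgkv, files)
  }
  invisible(res)
}
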