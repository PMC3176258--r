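#' Construct a dataset of expression values plus sample annotation
#'
#' A dataset couples a genes x samples log2-scale expression matrix with one
#' annotation row per sample, in matrix column order. Vehicle-control samples
#' carry the reserved compound ids `"VEHICLE_DMSO"` / `"VEHICLE_WATER"` and
#' class `"vehicle_control"`; chemical samples are `"sensitizer"` or
#' `"non_sensitizer"`, and only sensitizers carry a potency category other
#' than `"none"`.
#'
#' @param exprs numeric matrix, genes in rows (unique rownames), samples in
#'   columns (unique colnames); all values finite.
#' @param annot data.frame with columns `sample_id`, `compound_id`,
#'   `class_label`, `vehicle`, `replicate`, `potency`; `sample_id` must match
#'   `colnames(exprs)` in order.
#' @return An object of class `sensig_dataset`: a list with elements `exprs`
#'   and `annot`.
#' @export
sensig_dataset <- function(exprs, annot) {
  if (!is.matrix(exprs) || !is.numeric(exprs))
    stop("`exprs` must be a numeric matrix")
  if ((nrow(exprs) > 0 && is.null(rownames(exprs))) ||
      (ncol(exprs) > 0 && is.null(colnames(exprs))))
    stop("`exprs` must have gene rownames and sample colnames")
  if (anyDuplicated(rownames(exprs)))
    stop("duplicated gene ids: ",
         paste(unique(rownames(exprs)[duplicated(rownames(exprs))]), collapse = ", "))
  if (anyDuplicated(colnames(exprs)))
    stop("duplicated sample ids: ",
         paste(unique(colnames(exprs)[duplicated(colnames(exprs))]), collapse = ", "))
  if (any(!is.finite(exprs)))
    stop("expression matrix contains missing or non-finite values")
  annot <- as.data.frame(annot, stringsAsFactors = FALSE)
  req <- c("sample_id", "compound_id", "class_label", "vehicle", "replicate", "potency")
  miss <- setdiff(req, names(annot))
  if (length(miss)) stop("annotation lacks columns: ", paste(miss, collapse = ", "))
  annot <- annot[, req]
  if (nrow(annot) != ncol(exprs) ||
      !identical(as.character(annot$sample_id),
                 as.character(colnames(exprs) %||% character())))
    stop("annotation sample_ids must match expression columns in order")
  bad <- setdiff(unique(annot$class_label), CLASS_LEVELS)
  if (length(bad)) stop("unknown class_label: ", paste(bad, collapse = ", "))
  bad <- setdiff(unique(annot$vehicle), names(VEHICLE_TOKENS))
  if (length(bad)) stop("unknown vehicle: ", paste(bad, collapse = ", "))
  bad <- setdiff(unique(annot$potency), POTENCY_LEVELS)
  if (length(bad)) stop("unknown potency: ", paste(bad, collapse = ", "))
  is_ctrl <- annot$compound_id %in% VEHICLE_TOKENS
  if (!identical(is_ctrl, annot$class_label == "vehicle_control"))
    stop("class_label must be 'vehicle_control' exactly for VEHICLE_* compound ids")
  if (!identical(annot$potency != "none", annot$class_label == "sensitizer"))
    stop("potency must differ from 'none' exactly for sensitizers")
  if (any(annot$replicate < 1 | annot$replicate != round(annot$replicate)))
    stop("replicate must be a positive integer")
  structure(list(exprs = exprs, annot = annot), class = "sensig_dataset")
}

#' @export
print.sensig_dataset <- function(x, ...) {
  cnt <- table(factor(x$annot$class_label, levels = CLASS_LEVELS))
  cat(sprintf("sensig_dataset: %d genes x %d samples\n", nrow(x$exprs), ncol(x$exprs)))
  cat(sprintf("  sensitizer: %d  non_sensitizer: %d  vehicle_control: %d\n",
              cnt[["sensitizer"]], cnt[["non_sensitizer"]], cnt[["vehicle_control"]]))
  cat(sprintf("  compounds: %d\n",
              length(unique(x$annot$compound_id[x$annot$class_label != "vehicle_control"]))))
  invisible(x)
}

#' Read a tab-delimited expression matrix
#'
#' Expects a UTF-8, tab-separated file with genes in rows and samples in
#' columns: first column gene ids, one header row of sample ids. Malformed
#' files fail with the offending location: ragged rows report the file line
#' number, non-numeric cells report (gene row, sample column) coordinates,
#' duplicated ids are named.
#'
#' @param path path to the TSV file.
#' @return numeric matrix with gene rownames and sample colnames.
#' @export
read_expression <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  nf <- count.fields(path, sep = "\t", quote = "", comment.char = "")
  if (length(nf) < 2) stop("expression file needs a header row and at least one gene row: ", path)
  if (length(unique(nf)) != 1) {
    bad <- which(nf != nf[1])
    stop("ragged expression file: line(s) ", paste(bad, collapse = ", "),
         " have a different number of fields than the header")
  }
  raw <- read.delim(path, header = TRUE, sep = "\t", quote = "",
                    check.names = FALSE, colClasses = "character")
  gene_ids <- raw[[1]]
  sample_ids <- colnames(raw)[-1]
  if (anyDuplicated(gene_ids))
    stop("duplicated gene id(s): ",
         paste(unique(gene_ids[duplicated(gene_ids)]), collapse = ", "))
  if (anyDuplicated(sample_ids))
    stop("duplicated sample id(s): ",
         paste(unique(sample_ids[duplicated(sample_ids)]), collapse = ", "))
  vals <- suppressWarnings(
    vapply(raw[-1], as.numeric, numeric(nrow(raw)))
  )
  vals <- matrix(vals, nrow = nrow(raw),
                 dimnames = list(gene_ids, sample_ids))
  bad <- which(!is.finite(vals), arr.ind = TRUE)
  if (nrow(bad)) {
    where <- paste(sprintf("(%d,%d)", bad[, 1], bad[, 2]), collapse = ", ")
    stop("non-numeric or missing expression value at (row,col) ", where)
  }
  vals
}

#' Write an expression matrix as TSV
#'
#' @param exprs numeric matrix with gene rownames and sample colnames.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_expression <- function(exprs, path) {
  df <- data.frame(gene_id = rownames(exprs), exprs,
                   check.names = FALSE, stringsAsFactors = FALSE)
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read / write a sample-annotation table
#'
#' Annotation TSVs have columns `sample_id`, `compound_id`, `class_label`,
#' `vehicle`, `replicate`, `potency`.
#'
#' @param path path to the TSV file.
#' @return data.frame with the six annotation columns.
#' @export
read_annotation <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  ann <- read.delim(path, header = TRUE, sep = "\t", quote = "",
                    check.names = FALSE, stringsAsFactors = FALSE)
  req <- c("sample_id", "compound_id", "class_label", "vehicle", "replicate", "potency")
  miss <- setdiff(req, names(ann))
  if (length(miss)) stop("annotation lacks columns: ", paste(miss, collapse = ", "))
  ann$replicate <- as.integer(ann$replicate)
  ann[, req]
}

#' @rdname read_annotation
#' @param annot annotation data.frame.
#' @export
write_annotation <- function(annot, path) {
  write.table(annot, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Assemble an aligned dataset from a matrix and an annotation table
#'
#' Reorders the annotation to the matrix column order and validates the
#' pairing; every matrix sample must have exactly one annotation row and vice
#' versa. Logs per-class sample counts.
#'
#' @param exprs numeric expression matrix (genes x samples).
#' @param annot annotation data.frame (see [read_annotation()]).
#' @return a [sensig_dataset()].
#' @export
assemble_dataset <- function(exprs, annot) {
  annot <- as.data.frame(annot, stringsAsFactors = FALSE)
  if (anyDuplicated(annot$sample_id))
    stop("duplicated annotation sample id(s): ",
         paste(unique(annot$sample_id[duplicated(annot$sample_id)]), collapse = ", "))
  unannotated <- setdiff(colnames(exprs), annot$sample_id)
  orphans <- setdiff(annot$sample_id, colnames(exprs))
  if (length(unannotated))
    stop("samples without annotation: ", paste(unannotated, collapse = ", "))
  if (length(orphans))
    stop("annotation rows without samples: ", paste(orphans, collapse = ", "))
  annot <- annot[match(colnames(exprs), annot$sample_id), , drop = FALSE]
  rownames(annot) <- NULL
  ds <- sensig_dataset(exprs, annot)
  cnt <- table(factor(ds$annot$class_label, levels = CLASS_LEVELS))
  message(sprintf("assembled %d samples (sensitizer %d, non_sensitizer %d, vehicle_control %d)",
                  ncol(exprs), cnt[["sensitizer"]], cnt[["non_sensitizer"]],
                  cnt[["vehicle_control"]]))
  ds
}

#' Remove compounds and/or individual samples from a dataset
#'
#' Dropping a compound removes all of its replicates; dropping a sample
#' removes that array only. Expression values of retained samples are
#' untouched. Used for the study's bookkeeping of outlier compounds and
#' faulty arrays. Before/after counts are logged.
#'
#' @param ds a [sensig_dataset()].
#' @param drop_compounds character vector of compound ids to remove entirely.
#' @param drop_samples character vector of individual sample ids to remove.
#' @return the reduced dataset.
#' @export
remove_samples <- function(ds, drop_compounds = character(), drop_samples = character()) {
  stopifnot(inherits(ds, "sensig_dataset"))
  drop_compounds <- unique(as.character(drop_compounds))
  drop_samples <- unique(as.character(drop_samples))
  unknown <- setdiff(drop_compounds, ds$annot$compound_id)
  if (length(unknown)) stop("unknown compound(s): ", paste(unknown, collapse = ", "))
  unknown <- setdiff(drop_samples, ds$annot$sample_id)
  if (length(unknown)) stop("unknown sample(s): ", paste(unknown, collapse = ", "))
  gone <- ds$annot$compound_id %in% drop_compounds | ds$annot$sample_id %in% drop_samples
  keep <- ds$annot$sample_id[!gone]
  out <- sensig_dataset(ds$exprs[, keep, drop = FALSE],
                        ds$annot[!gone, , drop = FALSE])
  message(sprintf("removed %d of %d samples (%d compound(s) dropped fully, %d named arrays); %d remain",
                  sum(gone), ncol(ds$exprs), length(drop_compounds),
                  length(drop_samples), length(keep)))
  out
}

#' Keep a subset of samples or compounds
#'
#' @param ds a [sensig_dataset()].
#' @param sample_ids sample ids to keep (default all).
#' @param compounds compound ids to keep (applied after `sample_ids`).
#' @return the subset dataset, columns in original order.
#' @export
subset_samples <- function(ds, sample_ids = NULL, compounds = NULL) {
  stopifnot(inherits(ds, "sensig_dataset"))
  keep <- ds$annot$sample_id
  if (!is.null(sample_ids)) {
    unknown <- setdiff(sample_ids, keep)
    if (length(unknown)) stop("unknown sample(s): ", paste(unknown, collapse = ", "))
    keep <- keep[keep %in% sample_ids]
  }
  if (!is.null(compounds)) {
    unknown <- setdiff(compounds, ds$annot$compound_id)
    if (length(unknown)) stop("unknown compound(s): ", paste(unknown, collapse = ", "))
    keep <- keep[ds$annot$compound_id[match(keep, ds$annot$sample_id)] %in% compounds]
  }
  sel <- ds$annot$sample_id %in% keep
  sensig_dataset(ds$exprs[, sel, drop = FALSE], ds$annot[sel, , drop = FALSE])
}

#' Flag compounds with extreme transcriptional profiles
#'
#' Advisory screen for compounds whose profiles would dominate the analysis
#' (the motivating study removed two such compounds by manual quality
#' control). Samples are projected onto the top `k_components` principal
#' components; each sample's Euclidean distance from the grand centroid is
#' converted to a robust z score (median/MAD), and a compound's score is the
#' median over its replicates. Compounds scoring above `mad_threshold` are
#' flagged. Flags are advisory only; removal stays explicit via
#' [remove_samples()].
#'
#' @param ds a [sensig_dataset()] with at least 3 compounds.
#' @param k_components number of principal components (default 5).
#' @param mad_threshold robust z cutoff (default 6).
#' @return data.frame with `compound_id`, `score`, `flagged`, sorted by
#'   decreasing score.
#' @export
flag_outlier_compounds <- function(ds, k_components = 5, mad_threshold = 6) {
  stopifnot(inherits(ds, "sensig_dataset"))
  comps <- unique(ds$annot$compound_id)
  if (length(comps) < 3) stop("need at least 3 compounds")
  k_max <- min(nrow(ds$exprs), ncol(ds$exprs) - 1)
  if (k_components > k_max)
    stop(sprintf("k_components = %d exceeds feasible rank %d", k_components, k_max))
  pr <- prcomp(t(ds$exprs), center = TRUE, scale. = FALSE, rank. = k_components)
  sc <- pr$x[, seq_len(k_components), drop = FALSE]
  d <- sqrt(rowSums(sc^2))           # centroid is the origin after centering
  md <- median(d)
  s <- mad(d)
  z <- if (s > 0) (d - md) / s else rep(0, length(d))
  score <- vapply(comps, function(cc) {
    median(z[ds$annot$compound_id == cc])
  }, numeric(1))
  out <- data.frame(compound_id = comps, score = unname(score),
                    flagged = unname(score) > mad_threshold,
                    stringsAsFactors = FALSE)
  out <- out[order(-out$score, out$compound_id), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Write a dataset (and optional simulation truth) as TSV files
#'
#' @param ds a [sensig_dataset()].
#' @param dir output directory (created if needed).
#' @param truth optional truth object from [generate_dataset()].
#' @return the directory, invisibly.
#' @export
write_dataset <- function(ds, dir, truth = NULL) {
  stopifnot(inherits(ds, "sensig_dataset"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  write_expression(ds$exprs, file.path(dir, "expression.tsv"))
  write_annotation(ds$annot, file.path(dir, "annotation.tsv"))
  if (!is.null(truth)) {
    tt <- data.frame(gene_id = rownames(ds$exprs),
                     is_informative = rownames(ds$exprs) %in% truth$informative,
                     loading = 0, stringsAsFactors = FALSE)
    tt$loading[match(names(truth$loading), tt$gene_id)] <- truth$loading
    write.table(tt, file.path(dir, "truth.tsv"), sep = "\t",
                quote = FALSE, row.names = FALSE)
  }
  invisible(dir)
}

# chemical (non-control) samples of a dataset
chem_samples <- function(ds) ds$annot$sample_id[ds$annot$class_label != "vehicle_control"]
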