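#' Configuration for the synthetic expression-data generator
#'
#' Defines the generative model used to emulate the statistical structure of
#' the motivating chemical-stimulation study: a panel of sensitizing and
#' non-sensitizing compounds assayed in replicate next to vehicle controls,
#' with a potency-graded shared response axis restricted to an informative
#' gene subset, compound-idiosyncratic expression programs in both classes,
#' i.i.d. replicate noise, and optional extreme-outlier compounds whose whole
#' effect vector is multiplied up. All effects are on the log2 scale.
#'
#' @param n_genes total transcripts simulated (default 2000, a desk-scale
#'   stand-in for a genome-wide array).
#' @param n_informative number of genes carrying the shared sensitizer
#'   response axis; default 5% of `n_genes`.
#' @param n_sens_compounds,n_nonsens_compounds compounds per class.
#' @param replicates stimulations per compound.
#' @param n_controls_per_vehicle replicates per vehicle control (DMSO, water).
#' @param potency_effects named log2 effect scales for the four LLNA-style
#'   potency categories; must satisfy extreme >= strong >= moderate >= weak >= 0.
#' @param idiosyncratic_sd,idiosyncratic_frac each compound (both classes)
#'   shifts a random fraction `idiosyncratic_frac` of genes by
#'   Normal(0, idiosyncratic_sd^2) — the compound-specific heterogeneity that
#'   makes class separation require the informative subset.
#' @param noise_sd per-sample replicate noise sd.
#' @param baseline_mean,baseline_sd per-gene baseline distribution.
#' @param outlier_compounds named numeric vector of effect multipliers, e.g.
#'   `c(SENS_01 = 10)`.
#' @param potency_assignment optional character vector (length
#'   `n_sens_compounds`) fixing each sensitizer's potency; default assigns
#'   the four categories round-robin.
#' @param seed integer seed; the generator is fully determined by it.
#' @return an object of class `synth_config`.
#' @export
synth_config <- function(n_genes = 2000,
                         n_informative = NULL,
                         n_sens_compounds = 20,
                         n_nonsens_compounds = 20,
                         replicates = 3,
                         n_controls_per_vehicle = 12,
                         potency_effects = c(extreme = 2.0, strong = 1.5,
                                             moderate = 1.0, weak = 0.6),
                         idiosyncratic_sd = 0.5,
                         idiosyncratic_frac = 0.05,
                         noise_sd = 0.5,
                         baseline_mean = 7,
                         baseline_sd = 1.5,
                         outlier_compounds = numeric(),
                         potency_assignment = NULL,
                         seed = 1) {
  n_informative <- n_informative %||% max(1, round(0.05 * n_genes))
  cfg <- list(n_genes = as.integer(n_genes),
              n_informative = as.integer(n_informative),
              n_sens_compounds = as.integer(n_sens_compounds),
              n_nonsens_compounds = as.integer(n_nonsens_compounds),
              replicates = as.integer(replicates),
              n_controls_per_vehicle = as.integer(n_controls_per_vehicle),
              potency_effects = potency_effects,
              idiosyncratic_sd = idiosyncratic_sd,
              idiosyncratic_frac = idiosyncratic_frac,
              noise_sd = noise_sd,
              baseline_mean = baseline_mean,
              baseline_sd = baseline_sd,
              outlier_compounds = outlier_compounds,
              potency_assignment = potency_assignment,
              seed = as.integer(seed))
  pe <- cfg$potency_effects
  need <- c("extreme", "strong", "moderate", "weak")
  if (!all(need %in% names(pe))) stop("potency_effects must name extreme, strong, moderate, weak")
  pe <- pe[need]
  if (any(diff(unname(pe)) > 1e-12) || pe[["weak"]] < 0)
    stop("potency_effects must be ordered extreme >= strong >= moderate >= weak >= 0")
  cfg$potency_effects <- pe
  if (cfg$n_informative > cfg$n_genes) stop("n_informative must not exceed n_genes")
  if (cfg$n_informative < 0 || cfg$n_genes < 1) stop("invalid gene counts")
  if (cfg$replicates < 1) stop("replicates must be >= 1")
  if (cfg$idiosyncratic_sd < 0 || cfg$noise_sd < 0 || cfg$baseline_sd < 0)
    stop("standard deviations must be >= 0")
  if (cfg$idiosyncratic_frac < 0 || cfg$idiosyncratic_frac > 1)
    stop("idiosyncratic_frac must be in [0,1]")
  if (!is.null(potency_assignment)) {
    if (length(potency_assignment) != cfg$n_sens_compounds)
      stop("potency_assignment must have one entry per sensitizer compound")
    bad <- setdiff(unique(potency_assignment), need)
    if (length(bad)) stop("unknown potency: ", paste(bad, collapse = ", "))
  }
  structure(cfg, class = "synth_config")
}

#' Default configuration mirroring the study's sample layout
#'
#' 20 sensitizing + 20 non-sensitizing compounds in triplicate plus 12 DMSO
#' and 12 water vehicle-control replicates — 144 samples — at a reduced
#' default gene count of 2000.
#'
#' @param n_genes transcripts to simulate (default 2000).
#' @param seed integer seed.
#' @param ... further arguments passed to [synth_config()].
#' @return a `synth_config`.
#' @export
default_study_design <- function(n_genes = 2000, seed = 1, ...) {
  synth_config(n_genes = n_genes, seed = seed, ...)
}

#' Generate a synthetic dataset with known ground truth
#'
#' Draws, in a single seeded RNG stream and in this documented order:
#' (1) per-gene baselines; (2) the informative gene subset and its shared-axis
#' loadings (random sign, magnitude |Normal(1, 0.25^2)|); (3) per-compound
#' idiosyncratic programs (gene subset and shifts), sensitizers first then
#' non-sensitizers; (4) per-sample replicate noise. Sensitizer compound c
#' shifts informative gene g by `potency_effects[potency_c] * loading_g`;
#' potencies are assigned round-robin unless fixed in the config. Compounds
#' named in `outlier_compounds` have their whole effect vector (everything
#' except baseline) multiplied by the given factor. Vehicle controls are
#' baseline plus noise.
#'
#' @param cfg a [synth_config()].
#' @return list with elements `dataset` (a [sensig_dataset()]) and `truth`
#'   (informative gene ids, their loadings, and a per-compound effect table).
#' @export
generate_dataset <- function(cfg) {
  stopifnot(inherits(cfg, "synth_config"))
  gene_ids <- sprintf("G%05d", seq_len(cfg$n_genes))
  sens_ids <- sprintf("SENS_%02d", seq_len(cfg$n_sens_compounds))
  nons_ids <- sprintf("NONS_%02d", seq_len(cfg$n_nonsens_compounds))
  potencies <- cfg$potency_assignment %||%
    rep(c("extreme", "strong", "moderate", "weak"),
        length.out = cfg$n_sens_compounds)

  res <- withr::with_seed(cfg$seed, {
    baseline <- rnorm(cfg$n_genes, cfg$baseline_mean, cfg$baseline_sd)
    informative <- if (cfg$n_informative > 0)
      sort_ids(sample(gene_ids, cfg$n_informative)) else character()
    loading <- if (cfg$n_informative > 0) {
      sgn <- sample(c(-1, 1), cfg$n_informative, replace = TRUE)
      mag <- abs(rnorm(cfg$n_informative, 1, 0.25))
      stats::setNames(sgn * mag, informative)
    } else stats::setNames(numeric(), character())

    comp_ids <- c(sens_ids, nons_ids)
    comp_class <- rep(c("sensitizer", "non_sensitizer"),
                      c(length(sens_ids), length(nons_ids)))
    n_idio <- round(cfg$idiosyncratic_frac * cfg$n_genes)
    effect <- matrix(0, cfg$n_genes, length(comp_ids),
                     dimnames = list(gene_ids, comp_ids))
    for (ci in seq_along(comp_ids)) {
      if (comp_class[ci] == "sensitizer" && cfg$n_informative > 0) {
        pot <- potencies[ci]
        effect[informative, ci] <- cfg$potency_effects[[pot]] * loading
      }
      if (n_idio > 0 && cfg$idiosyncratic_sd > 0) {
        idio_genes <- sample(gene_ids, n_idio)
        effect[idio_genes, ci] <- effect[idio_genes, ci] +
          rnorm(n_idio, 0, cfg$idiosyncratic_sd)
      }
    }
    mult <- rep(1, length(comp_ids))
    names(mult) <- comp_ids
    if (length(cfg$outlier_compounds)) {
      unknown <- setdiff(names(cfg$outlier_compounds), comp_ids)
      if (length(unknown)) stop("outlier_compounds names unknown compound(s): ",
                                paste(unknown, collapse = ", "))
      mult[names(cfg$outlier_compounds)] <- cfg$outlier_compounds
      effect <- sweep(effect, 2, mult, `*`)
    }

    veh <- rep_len(c("DMSO", "water"), length(comp_ids))
    ann <- list()
    cols <- list()
    for (ci in seq_along(comp_ids)) {
      for (r in seq_len(cfg$replicates)) {
        sid <- sprintf("%s_r%d", comp_ids[ci], r)
        ann[[sid]] <- data.frame(
          sample_id = sid, compound_id = comp_ids[ci],
          class_label = comp_class[ci], vehicle = veh[ci], replicate = r,
          potency = if (comp_class[ci] == "sensitizer") potencies[ci] else "none",
          stringsAsFactors = FALSE)
        cols[[sid]] <- baseline + effect[, ci]
      }
    }
    for (v in c("DMSO", "water")) {
      for (r in seq_len(cfg$n_controls_per_vehicle)) {
        sid <- sprintf("%s_r%d", VEHICLE_TOKENS[[v]], r)
        ann[[sid]] <- data.frame(
          sample_id = sid, compound_id = VEHICLE_TOKENS[[v]],
          class_label = "vehicle_control", vehicle = v, replicate = r,
          potency = "none", stringsAsFactors = FALSE)
        cols[[sid]] <- baseline
      }
    }
    mu <- do.call(cbind, cols)
    noise <- matrix(rnorm(length(mu), 0, cfg$noise_sd), nrow(mu), ncol(mu))
    exprs <- mu + noise
    rownames(exprs) <- gene_ids

    truth <- list(
      informative = informative,
      loading = loading,
      compounds = data.frame(
        compound_id = comp_ids, class_label = comp_class,
        potency = ifelse(comp_class == "sensitizer", potencies, "none"),
        shared_scale = ifelse(comp_class == "sensitizer",
                              unname(cfg$potency_effects[
                                ifelse(comp_class == "sensitizer", potencies, "weak")]),
                              0),
        multiplier = unname(mult), stringsAsFactors = FALSE))
    list(exprs = exprs, annot = do.call(rbind, unname(ann)), truth = truth)
  })
  ds <- sensig_dataset(res$exprs, res$annot)
  list(dataset = ds, truth = res$truth)
}
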