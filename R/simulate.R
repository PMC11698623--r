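# Seeded synthetic-data generator with planted ground truth: block-correlated
# gene modules driven by latent factors, ordinal stage/TNM traits tied to
# chosen module factors, regulator miRNAs anticorrelated with their targeted
# module, and a target map in which those miRNAs' targets are
# over-represented in that module.

#' Configuration for the synthetic dataset generator
#'
#' Defines the planted structure: co-expression modules driven by shared
#' latent factors, stage/TNM traits correlated with selected module
#' factors, regulator miRNAs whose expression opposes a module's factor
#' and whose annotated targets concentrate in that module, plus decoy
#' miRNAs with uniformly random target sets (so their expected module
#' overlap matches the hypergeometric null).
#'
#' @param seed Integer seed; fixes every random draw.
#' @param n_samples Number of analysis samples (untreated, staged).
#' @param module_sizes Integer vector of planted module sizes.
#' @param background_genes Number of unstructured background genes;
#'   `sum(module_sizes) + background_genes` is the gene universe size.
#' @param module_cor Latent-factor loading in (0, 1) shared by all module
#'   genes; within-module gene-gene correlation is approximately
#'   `module_cor^2` at the default residual scale.
#' @param noise_sd Residual standard deviation on the log scale; default
#'   `sqrt(1 - module_cor^2)` so gene signals have unit variance.
#' @param trait_modules List of numeric triples
#'   `(module index, sign, effect size)`: the stage latent variable loads
#'   on that module's factor with the signed effect.
#' @param n_mirnas Number of miRNAs (regulators plus decoys).
#' @param regulators List of numeric quadruples
#'   `(miRNA index, module index, target overlap fraction in (0,1],
#'   anticorrelation strength in (0,1))`.
#' @param decoy_target_fraction Fraction of the gene universe targeted by
#'   each non-regulator miRNA.
#' @param count_depth Expected mRNA library size per sample.
#' @param mirna_count_depth Expected miRNA library size per sample.
#' @param n_treated,n_unstaged Extra samples marked as treated or lacking
#'   stage annotation, appended so the sample filters have work to do.
#' @param stage_probs Marginal probabilities of stages I-IV.
#' @return A `sim_config` list.
#' @export
sim_config <- function(seed = 1L,
                       n_samples = 100L,
                       module_sizes = c(100L, 80L, 60L, 50L, 40L),
                       background_genes = 170L,
                       module_cor = 0.8,
                       noise_sd = NULL,
                       trait_modules = list(c(1, 1, 0.5), c(2, 1, 0.5)),
                       n_mirnas = 100L,
                       regulators = list(c(1, 1, 0.6, 0.7),
                                         c(2, 2, 0.6, 0.7),
                                         c(3, 1, 0.5, 0.6)),
                       decoy_target_fraction = 0.05,
                       count_depth = 1e6,
                       mirna_count_depth = 1e5,
                       n_treated = 6L,
                       n_unstaged = 2L,
                       stage_probs = c(0.20, 0.55, 0.21, 0.04)) {
  if (module_cor <= 0 || module_cor >= 1)
    stopf("module_cor must lie in (0, 1)")
  if (is.null(noise_sd)) noise_sd <- sqrt(1 - module_cor^2)
  cfg <- list(seed = as.integer(seed), n_samples = as.integer(n_samples),
              module_sizes = as.integer(module_sizes),
              background_genes = as.integer(background_genes),
              module_cor = module_cor, noise_sd = noise_sd,
              trait_modules = trait_modules, n_mirnas = as.integer(n_mirnas),
              regulators = regulators,
              decoy_target_fraction = decoy_target_fraction,
              count_depth = count_depth, mirna_count_depth = mirna_count_depth,
              n_treated = as.integer(n_treated),
              n_unstaged = as.integer(n_unstaged),
              stage_probs = stage_probs)
  cfg$n_genes <- sum(cfg$module_sizes) + cfg$background_genes
  validate_sim_config(cfg)
  structure(cfg, class = "sim_config")
}

validate_sim_config <- function(cfg) {
  if (sum(cfg$module_sizes) + cfg$background_genes != cfg$n_genes)
    stopf("module_sizes plus background_genes must sum to n_genes")
  n_mod <- length(cfg$module_sizes)
  for (tm in cfg$trait_modules) {
    if (length(tm) != 3L || tm[1] < 1 || tm[1] > n_mod)
      stopf("trait_modules entry references invalid module index: %s",
            paste(tm, collapse = ","))
    if (abs(tm[3]) >= 1) stopf("trait_modules effect size must be < 1")
  }
  if (length(cfg$trait_modules) &&
      sum(vapply(cfg$trait_modules, function(tm) tm[3]^2, 0)) > 1)
    stopf("trait_modules effect sizes exceed unit variance budget")
  for (rg in cfg$regulators) {
    if (length(rg) != 4L) stopf("regulators entries need 4 values")
    if (rg[1] < 1 || rg[1] > cfg$n_mirnas)
      stopf("regulators miRNA index out of range: %d", rg[1])
    if (rg[2] < 1 || rg[2] > n_mod)
      stopf("regulators module index out of range: %d", rg[2])
    if (rg[3] <= 0 || rg[3] > 1)
      stopf("regulators overlap fraction must lie in (0, 1]")
    if (rg[4] <= 0 || rg[4] >= 1)
      stopf("regulators anticorrelation strength must lie in (0, 1)")
  }
  if (abs(sum(cfg$stage_probs) - 1) > 1e-8)
    stopf("stage_probs must sum to 1")
  invisible(cfg)
}

# Map a standard-normal latent vector to ordinal categories with the given
# marginal probabilities, using fixed population thresholds.
ordinalize <- function(latent, probs) {
  breaks <- c(-Inf, stats::qnorm(cumsum(probs)[-length(probs)]), Inf)
  as.integer(cut(latent, breaks = breaks, labels = FALSE))
}

# Latent log-signal matrix -> integer counts with expected per-sample depth.
# Exponential link: lambda ~ exp(baseline + signal), columns rescaled to the
# target depth, Poisson sampling on top.
signal_to_counts <- function(signal, baseline, depth) {
  lambda <- exp(sweep(signal, 1L, baseline, "+"))
  lambda <- sweep(lambda, 2L, colSums(lambda), "/") * depth
  counts <- matrix(rpois(length(lambda), lambda), nrow = nrow(lambda),
                   dimnames = dimnames(signal))
  storage.mode(counts) <- "double"
  counts
}

#' Simulate a dataset with planted modules, traits and regulator miRNAs
#'
#' Generates raw mRNA and miRNA count matrices, a clinical table, a
#' miRNA-target map and the planted truth. Gene expression arises from a
#' per-module latent factor (loading `module_cor`) plus Gaussian residuals,
#' pushed through an exponential link to Poisson counts with the requested
#' library depth. The ordinal stage covaries with the designated module
#' factors; T/N/M derive from the same stage latent with independent noise.
#' Regulator miRNAs oppose their module's factor and target
#' `overlap_fraction * module_size` of its genes plus random universe
#' genes; decoy miRNAs target uniformly random genes.
#'
#' @param config A [sim_config()].
#' @return A `synthetic_dataset` list with elements `gene_counts`,
#'   `mirna_counts` (features x samples), `clinical` (data frame),
#'   `targets` (a `target_map`), `truth` (planted partition and regulator
#'   table) and `config`.
#' @export
simulate_dataset <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  validate_sim_config(config)
  set.seed(config$seed)
  cfg <- config

  n_tot <- cfg$n_samples + cfg$n_treated + cfg$n_unstaged
  n_mod <- length(cfg$module_sizes)
  samples <- sprintf("sample_%03d", seq_len(n_tot))
  genes <- sprintf("gene_%04d", seq_len(cfg$n_genes))
  mirnas <- sprintf("miR-%03d", seq_len(cfg$n_mirnas))

  # planted partition: modules first, then background (unassigned)
  truth_labels <- rep(unassigned_label(), cfg$n_genes)
  module_names <- sprintf("module_%d", seq_len(n_mod))
  idx <- 1L
  module_members <- vector("list", n_mod)
  for (m in seq_len(n_mod)) {
    members <- seq.int(idx, idx + cfg$module_sizes[m] - 1L)
    module_members[[m]] <- genes[members]
    truth_labels[members] <- module_names[m]
    idx <- idx + cfg$module_sizes[m]
  }
  names(truth_labels) <- genes

  # latent module factors and gene-level signals
  factors <- matrix(rnorm(n_mod * n_tot), n_mod, n_tot,
                    dimnames = list(module_names, samples))
  signal <- matrix(rnorm(cfg$n_genes * n_tot, sd = cfg$noise_sd),
                   cfg$n_genes, n_tot, dimnames = list(genes, samples))
  for (m in seq_len(n_mod)) {
    rows <- which(truth_labels == module_names[m])
    signal[rows, ] <- signal[rows, ] +
      cfg$module_cor * matrix(factors[m, ], length(rows), n_tot, byrow = TRUE)
  }
  bg <- which(truth_labels == unassigned_label())
  if (length(bg))
    signal[bg, ] <- matrix(rnorm(length(bg) * n_tot), length(bg), n_tot)

  gene_baseline <- rnorm(cfg$n_genes, 0, 1.2)
  gene_counts <- signal_to_counts(signal, gene_baseline, cfg$count_depth)

  # stage latent shared by stage and T/N/M, loaded on the trait modules
  effect_var <- 0
  stage_latent <- rep(0, n_tot)
  for (tm in cfg$trait_modules) {
    stage_latent <- stage_latent + tm[2] * tm[3] * factors[tm[1], ]
    effect_var <- effect_var + tm[3]^2
  }
  stage_latent <- stage_latent + rnorm(n_tot, sd = sqrt(max(0, 1 - effect_var)))
  tnm_latent <- function() 0.9 * stage_latent + rnorm(n_tot, sd = sqrt(1 - 0.81))

  stage_code <- ordinalize(stage_latent, cfg$stage_probs)
  t_code <- ordinalize(tnm_latent(), c(0.25, 0.45, 0.25, 0.05))
  n_code <- ordinalize(tnm_latent(), c(0.50, 0.30, 0.15, 0.05)) - 1L
  m_code <- ordinalize(tnm_latent(), c(0.95, 0.05)) - 1L

  stage_label <- c("I", "II", "III", "IV")[stage_code]
  sub <- sample(c("", "A", "B"), n_tot, replace = TRUE)
  stage_label <- ifelse(stage_label %in% c("II", "III"),
                        paste0(stage_label, sub), stage_label)

  pharm <- rep("no", n_tot)
  radio <- rep("no", n_tot)
  if (cfg$n_treated > 0) {
    treated <- seq.int(cfg$n_samples + 1L, cfg$n_samples + cfg$n_treated)
    which_flag <- sample(1:3, cfg$n_treated, replace = TRUE)
    pharm[treated][which_flag != 2] <- "yes"
    radio[treated][which_flag != 1] <- "yes"
  }
  if (cfg$n_unstaged > 0) {
    unstaged <- seq.int(n_tot - cfg$n_unstaged + 1L, n_tot)
    stage_label[unstaged] <- NA_character_
  }

  clinical <- data.frame(
    sample_id = samples,
    stage = stage_label,
    t = paste0("T", t_code),
    n = paste0("N", n_code),
    m = paste0("M", m_code),
    pharmaceutical_treatment = pharm,
    radiation_treatment = radio,
    age = sample(30:90, n_tot, replace = TRUE),
    stringsAsFactors = FALSE)

  # miRNA expression: regulators oppose their module factor
  mir_signal <- matrix(rnorm(cfg$n_mirnas * n_tot), cfg$n_mirnas, n_tot,
                       dimnames = list(mirnas, samples))
  for (rg in cfg$regulators) {
    i <- rg[1]; m <- rg[2]; a <- rg[4]
    mir_signal[i, ] <- -a * factors[m, ] + sqrt(1 - a^2) * rnorm(n_tot)
  }
  mir_baseline <- rnorm(cfg$n_mirnas, 0, 1.2)
  mirna_counts <- signal_to_counts(mir_signal, mir_baseline,
                                   cfg$mirna_count_depth)

  # target map: planted overlap for regulators, uniform sets for decoys
  n_decoy_targets <- max(2L, round(cfg$decoy_target_fraction * cfg$n_genes))
  regulator_mirnas <- vapply(cfg$regulators, function(rg) rg[1], 0)
  pair_list <- vector("list", cfg$n_mirnas)
  truth_reg <- data.frame(mirna = character(0), module = character(0),
                          overlap = numeric(0), anticorrelation = numeric(0),
                          n_targets = integer(0), stringsAsFactors = FALSE)
  for (i in seq_len(cfg$n_mirnas)) {
    hit <- which(regulator_mirnas == i)
    if (length(hit)) {
      rg <- cfg$regulators[[hit[1L]]]
      members <- module_members[[rg[2]]]
      z0 <- max(1L, round(rg[3] * length(members)))
      in_module <- sample(members, z0)
      outside <- sample(setdiff(genes, members), n_decoy_targets)
      tg <- c(in_module, outside)
      truth_reg <- rbind(truth_reg, data.frame(
        mirna = mirnas[i], module = module_names[rg[2]],
        overlap = rg[3], anticorrelation = rg[4],
        n_targets = length(tg), stringsAsFactors = FALSE))
    } else {
      tg <- sample(genes, n_decoy_targets)
    }
    pair_list[[i]] <- data.frame(mirna = mirnas[i], gene = tg,
                                 stringsAsFactors = FALSE)
  }
  targets <- target_map(do.call(rbind, pair_list), universe = genes)

  structure(list(
    gene_counts = gene_counts,
    mirna_counts = mirna_counts,
    clinical = clinical,
    targets = targets,
    truth = list(modules = truth_labels, regulators = truth_reg,
                 factors = factors),
    config = cfg), class = "synthetic_dataset")
}

#' @export
print.synthetic_dataset <- function(x, ...) {
  cat(sprintf(paste0("synthetic_dataset: %d genes x %d samples, %d miRNAs, ",
                     "%d planted modules, %d planted regulators\n"),
              nrow(x$gene_counts), ncol(x$gene_counts), nrow(x$mirna_counts),
              length(unique(setdiff(x$truth$modules, unassigned_label()))),
              nrow(x$truth$regulators)))
  invisible(x)
}

#' Write a synthetic dataset as a fixture directory
#'
#' Emits `genes.tsv`, `mirnas.tsv`, `clinical.tsv`, `targets.tsv` and
#' `truth.json`; the TSV files round-trip losslessly through the package
#' readers.
#'
#' @param dataset A `synthetic_dataset` from [simulate_dataset()].
#' @param directory Output directory (created if absent).
#' @return Named character vector of the five file paths (the manifest).
#' @export
write_fixture <- function(dataset, directory) {
  stopifnot(inherits(dataset, "synthetic_dataset"))
  if (!dir.exists(directory) &&
      !dir.create(directory, recursive = TRUE, showWarnings = FALSE))
    stopf("cannot create fixture directory '%s'", directory)
  paths <- c(
    genes = file.path(directory, "genes.tsv"),
    mirnas = file.path(directory, "mirnas.tsv"),
    clinical = file.path(directory, "clinical.tsv"),
    targets = file.path(directory, "targets.tsv"),
    truth = file.path(directory, "truth.json"))
  write_expression_tsv(dataset$gene_counts, paths[["genes"]])
  write_expression_tsv(dataset$mirna_counts, paths[["mirnas"]])
  write_clinical_tsv(dataset$clinical, paths[["clinical"]])
  write_target_map_tsv(dataset$targets, paths[["targets"]])
  truth <- list(modules = as.list(dataset$truth$modules),
                regulators = dataset$truth$regulators)
  jsonlite::write_json(truth, paths[["truth"]], auto_unbox = TRUE,
                       digits = NA)
  paths
}
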