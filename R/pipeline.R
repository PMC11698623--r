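# End-to-end orchestration: preprocess -> network -> traits -> enrichment ->
# gene-set scoring, with a config object, per-stage error reporting, artifact
# output and a fully synthetic demo mode.

#' Pipeline configuration
#'
#' Collects every input path and threshold of the analysis with its
#' standard default: minimum gene/miRNA total counts 50/10, automatic
#' soft threshold targeting scale-free fit R^2 > 0.9, minimum module
#' size 30, merge cut height 0.25, deep split 2, kME filters 0.3/0.5/10,
#' trait screening |r| > 0.2 at p < 0.05 on at least 2 traits, FDR 0.05
#' and miRNA-eigengene correlation below -0.3.
#'
#' @param genes,mirnas,clinical,targets Input file paths (may stay `NULL`
#'   when in-memory data is passed to [run_pipeline()]).
#' @param out_dir Optional artifact directory.
#' @param min_gene_total,min_mirna_total Low-count filters.
#' @param beta `"auto"` or a fixed soft-threshold power.
#' @param target_r2 Scale-free fit target for automatic beta.
#' @param powers Candidate powers for automatic beta.
#' @param min_module_size,merge_cut_height,deep_split Module detection
#'   parameters.
#' @param min_kme_to_stay,min_core_kme,min_core_kme_size kME filters.
#' @param trait_cor,trait_p,min_traits Important-module screening.
#' @param fdr,mirna_cor Regulator selection thresholds.
#' @param fdr_family BH family: `"joint"` or `"per_module"`.
#' @param gsva_method Gene-level CDF estimator: `"kernel"` or `"ecdf"`.
#' @param seed Seed recorded in the run report (the analysis itself is
#'   deterministic given the data).
#' @return A `pipeline_config` list.
#' @export
pipeline_config <- function(genes = NULL, mirnas = NULL, clinical = NULL,
                            targets = NULL, out_dir = NULL,
                            min_gene_total = 50, min_mirna_total = 10,
                            beta = "auto", target_r2 = 0.9,
                            powers = c(1:10, seq(12L, 20L, 2L)),
                            min_module_size = 30L, merge_cut_height = 0.25,
                            deep_split = 2L, min_kme_to_stay = 0.3,
                            min_core_kme = 0.5, min_core_kme_size = 10L,
                            trait_cor = 0.2, trait_p = 0.05, min_traits = 2L,
                            fdr = 0.05, mirna_cor = -0.3,
                            fdr_family = "joint", gsva_method = "kernel",
                            seed = 1L) {
  cfg <- as.list(environment())
  stopifnot(min_gene_total >= 0, min_mirna_total >= 0,
            min_module_size >= 2, merge_cut_height >= 0,
            trait_cor >= 0, trait_cor <= 1, trait_p > 0, trait_p <= 1,
            min_traits >= 1, fdr > 0, fdr <= 1, mirna_cor >= -1,
            mirna_cor <= 1)
  if (!identical(beta, "auto") && (!is.numeric(beta) || beta < 1))
    stopf("beta must be \"auto\" or a number >= 1")
  structure(cfg, class = "pipeline_config")
}

#' Read a pipeline configuration from YAML
#'
#' Keys mirror the arguments of [pipeline_config()]; unknown keys raise
#' an error.
#'
#' @param path Path to a YAML file.
#' @return A `pipeline_config`.
#' @export
read_pipeline_config <- function(path) {
  if (!requireNamespace("yaml", quietly = TRUE))
    stopf("the 'yaml' package is required to read YAML configs")
  values <- yaml::read_yaml(path)
  unknown <- setdiff(names(values), names(formals(pipeline_config)))
  if (length(unknown))
    stopf("unknown config key(s): %s", paste(unknown, collapse = ", "))
  do.call(pipeline_config, values)
}

with_stage <- function(stage, expr) {
  tryCatch(expr, error = function(e) {
    stopf("[stage %s] %s", stage, conditionMessage(e))
  })
}

#' Run the full regulator-discovery pipeline
#'
#' Executes sample selection, low-count filtering, normalization,
#' universe restriction, network construction and module detection,
#' module-trait screening, the miRNA enrichment screen and gene-set
#' variation scoring of every selected target set. Any stage error is
#' re-raised with the stage name. When `config$out_dir` is set, every
#' intermediate artifact is written there as TSV plus a JSON run report.
#'
#' @param config A [pipeline_config()].
#' @param data Optional in-memory input list with elements `gene_counts`,
#'   `mirna_counts`, `clinical`, `targets` (e.g. a `synthetic_dataset`);
#'   when `NULL` the paths in `config` are read.
#' @return A run report list; see the `report.json` artifact for its
#'   serialized form.
#' @export
run_pipeline <- function(config, data = NULL) {
  stopifnot(inherits(config, "pipeline_config"))
  if (is.null(data)) {
    data <- with_stage("read_inputs", {
      for (f in c("genes", "mirnas", "clinical", "targets")) {
        if (is.null(config[[f]]))
          stopf("no '%s' input path configured", f)
        if (!file.exists(config[[f]]))
          stopf("input file for '%s' not found: %s", f, config[[f]])
      }
      list(gene_counts = read_expression_tsv(config$genes),
           mirna_counts = read_expression_tsv(config$mirnas),
           clinical = read_clinical_tsv(config$clinical),
           targets = read_target_map_tsv(config$targets))
    })
  }

  report <- list(seed = config$seed,
                 thresholds = unclass(config)[
                   !vapply(unclass(config), is.null, TRUE)])

  samples <- with_stage("select_samples", select_samples(
    data$clinical, colnames(data$gene_counts), colnames(data$mirna_counts)))
  gene_counts <- data$gene_counts[, samples, drop = FALSE]
  mirna_counts <- data$mirna_counts[, samples, drop = FALSE]
  report$samples <- list(n_clinical = nrow(data$clinical),
                         n_selected = length(samples))

  gene_counts_f <- with_stage("filter_low_counts",
                              filter_low_counts(gene_counts,
                                                config$min_gene_total))
  mirna_counts_f <- with_stage("filter_low_counts",
                               filter_low_counts(mirna_counts,
                                                 config$min_mirna_total))
  genes_norm <- with_stage("normalize", normalize_log2(gene_counts_f))
  mirnas_norm <- with_stage("normalize", normalize_log2(mirna_counts_f))

  restricted <- with_stage("restrict_universe",
                           restrict_universe(genes_norm, data$targets))
  expr <- restricted$expr
  targets <- restricted$targets
  report$features <- list(
    genes_initial = nrow(data$gene_counts),
    genes_after_count_filter = nrow(gene_counts_f),
    universe = nrow(expr),
    mirnas_initial = nrow(data$mirna_counts),
    mirnas_after_count_filter = nrow(mirna_counts_f))

  qc <- with_stage("sample_qc", sample_qc_dendrogram(expr))
  report$qc <- list(flagged = qc$flagged)

  cor_matrix <- with_stage("network", pearson_matrix(expr))
  if (identical(config$beta, "auto")) {
    st <- with_stage("pick_soft_threshold", pick_soft_threshold(
      expr, powers = config$powers, target_r2 = config$target_r2,
      cor_matrix = cor_matrix))
    beta <- st$power
    if (is.na(beta)) {
      # fall back to the conventional signed-network default power
      beta <- 12
      warning(sprintf(
        "no power reached fit > %g; using signed-network default power %g",
        config$target_r2, beta), call. = FALSE)
    }
    report$soft_threshold <- list(
      chosen = beta,
      fit = st$report$fit[st$report$power == beta],
      mean_connectivity =
        st$report$mean_connectivity[st$report$power == beta],
      report = st$report)
  } else {
    beta <- config$beta
    report$soft_threshold <- list(chosen = beta)
  }

  partition <- with_stage("detect_modules", {
    adj <- signed_adjacency(cor_matrix, beta)
    tom <- tom_similarity(adj)
    p0 <- detect_modules(tom, min_module_size = config$min_module_size,
                         deep_split = config$deep_split)
    if (length(setdiff(unique(p0), unassigned_label())) == 0L)
      stopf("no modules detected")
    p1 <- merge_close_modules(expr, p0,
                              cut_height = config$merge_cut_height)
    apply_kme_filters(expr, p1,
                      min_kme_to_stay = config$min_kme_to_stay,
                      min_core_kme = config$min_core_kme,
                      min_core_size = config$min_core_kme_size)
  })
  module_sizes <- table(partition[partition != unassigned_label()])
  if (length(module_sizes) == 0L)
    with_stage("detect_modules", stopf("all modules dissolved by filters"))
  report$modules <- list(count = length(module_sizes),
                         sizes = as.list(module_sizes),
                         unassigned =
                           sum(partition == unassigned_label()))

  eigengenes <- with_stage("module_eigengenes",
                           module_eigengenes(expr, partition))

  traits <- with_stage("encode_traits",
                       encode_traits(data$clinical, samples = samples))
  mt <- with_stage("module_trait",
                   correlate_eigengene_traits(eigengenes, traits))
  important <- with_stage("module_trait", select_important_modules(
    mt, cor_thr = config$trait_cor, p_thr = config$trait_p,
    min_traits = config$min_traits))
  report$module_trait <- list(
    r = as.data.frame(mt$r), p = as.data.frame(mt$p),
    important = important)
  if (!length(important)) {
    report$enrichment <- list(note = "no important module; screen skipped")
    report$selected <- character(0)
    return(finish_pipeline(report, config, expr, mirnas_norm, partition,
                           eigengenes, NULL, NULL))
  }

  records <- with_stage("enrichment", screen_regulators(
    mirnas_norm, targets, partition, eigengenes, important,
    fdr_thr = config$fdr, cor_thr = config$mirna_cor,
    fdr_family = config$fdr_family))
  report$enrichment <- list(
    n_tested_mirnas = length(unique(records$mirna)),
    n_records = nrow(records),
    n_fdr_pass = sum(records$fdr < config$fdr),
    table = records[records$fdr < config$fdr | records$selected, ,
                    drop = FALSE])
  selected <- records[records$selected, , drop = FALSE]
  report$selected <- selected

  gsva_tab <- NULL
  if (nrow(selected)) {
    sets <- with_stage("gsva", {
      s <- lapply(seq_len(nrow(selected)), function(i) {
        mod_genes <- names(partition)[partition == selected$module[i]]
        intersect(targets$map[[selected$mirna[i]]], mod_genes)
      })
      names(s) <- paste(selected$mirna, selected$module, sep = "|")
      s[lengths(s) >= 2L]
    })
    if (length(sets)) {
      gsva_tab <- with_stage("gsva", {
        sm <- gsva_score_matrix(expr, sets, method = config$gsva_method)
        do.call(rbind, lapply(rownames(sm), function(nm) {
          cs <- correlate_scores_stage(sm[nm, ], traits)
          data.frame(set = nm, stage_r = cs$r, stage_p = cs$p,
                     n = cs$n, stringsAsFactors = FALSE)
        }))
      })
      report$gsva <- gsva_tab
    }
  }
  finish_pipeline(report, config, expr, mirnas_norm, partition, eigengenes,
                  records, gsva_tab)
}

finish_pipeline <- function(report, config, expr, mirnas_norm, partition,
                            eigengenes, records, gsva_tab) {
  if (!is.null(config$out_dir)) {
    dir.create(config$out_dir, recursive = TRUE, showWarnings = FALSE)
    out <- function(f) file.path(config$out_dir, f)
    write_expression_tsv(expr, out("genes_normalized.tsv"))
    write_expression_tsv(mirnas_norm, out("mirnas_normalized.tsv"))
    write.table(data.frame(gene = names(partition), module = partition),
                out("modules.tsv"), sep = "\t", quote = FALSE,
                row.names = FALSE)
    write_expression_tsv(eigengenes, out("eigengenes.tsv"))
    if (!is.null(records))
      write.table(records, out("enrichment.tsv"), sep = "\t",
                  quote = FALSE, row.names = FALSE)
    if (!is.null(gsva_tab))
      write.table(gsva_tab, out("gsva_stage.tsv"), sep = "\t",
                  quote = FALSE, row.names = FALSE)
    jsonlite::write_json(report, out("report.json"), auto_unbox = TRUE,
                         digits = NA, force = TRUE)
  }
  report$partition <- as.list(partition)
  report
}

#' Run a fully synthetic demonstration of the pipeline
#'
#' Simulates a dataset with planted modules, trait effects and regulator
#' miRNAs, runs the complete pipeline on it, and appends a ground-truth
#' evaluation comparing the selected miRNAs with the planted regulators.
#'
#' @param seed Integer seed driving the simulation.
#' @param out_dir Optional artifact directory.
#' @param sim A [sim_config()]; defaults to the standard demo
#'   configuration at the given seed.
#' @param config A [pipeline_config()]; defaults to standard thresholds.
#' @return The run report with an additional `truth_eval` element.
#' @export
run_demo <- function(seed = 7L, out_dir = NULL,
                     sim = sim_config(seed = seed),
                     config = pipeline_config(seed = seed,
                                              out_dir = out_dir)) {
  dataset <- simulate_dataset(sim)
  report <- run_pipeline(config, data = dataset)
  planted <- dataset$truth$regulators$mirna
  selected <- unique(report$selected$mirna)
  report$truth_eval <- list(
    planted_regulators = planted,
    selected_mirnas = selected,
    planted_selected = intersect(planted, selected),
    all_planted_selected = all(planted %in% selected))
  if (!is.null(out_dir))
    jsonlite::write_json(report, file.path(out_dir, "report.json"),
                         auto_unbox = TRUE, digits = NA, force = TRUE)
  report
}
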