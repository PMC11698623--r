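# modulemir

Identifies candidate **regulator miRNAs of cancer-progression gene
modules** from paired mRNA/miRNA expression and clinical staging data —
the module-centric screening workflow used in tumor transcriptomics
(e.g. TCGA-style breast cancer cohorts).

The chain of inference:

1. **Co-expression modules.** A signed weighted network is built from
   log2-CPM expression: adjacency `a_ij = ((1 + cor_ij)/2)^β`, with the
   soft-threshold power β chosen as the smallest value whose connectivity
   distribution fits scale-free topology at R² > 0.9. Modules are
   branches of the average-linkage dendrogram of `1 − TOM` (topological
   overlap), subject to a minimum size (30), eigengene-based merging
   (cut height 0.25) and kME membership filters (0.3 / 0.5 / 10).
2. **Progression modules.** Each module's eigengene (first principal
   component) is correlated with ordinal stage and T/N/M codes; modules
   with |r| > 0.2 and p < 0.05 on at least two traits are *important*.
3. **Regulator screen.** For every miRNA and important module, the
   hypergeometric upper tail
   `P = Σ_{k=z}^{min(x,n)} C(x,k) C(N−x, n−k) / C(N,n)`
   tests whether the miRNA's `n` annotated targets over-represent the
   module (`x` genes) within the `N`-gene network universe, with
   Benjamini–Hochberg FDR across all tests. A miRNA is selected when
   FDR < 0.05 **and** its expression correlates below −0.3 with the
   module eigengene — the signature of a repressive regulator.
4. **Downstream summaries.** Selected target sets get per-sample
   gene-set variation scores (rank-based random walk) correlated with
   stage, and target lists can be clustered on a protein-interaction
   graph with an MCODE-style algorithm (k-core vertex weighting, node
   score cutoff 0.2, edge confidence ≥ 0.7).

A seeded synthetic-data generator plants modules, trait effects,
regulator miRNAs and target maps, giving every stage a ground truth to
validate against.

## Worked example

The one-command demo simulates a cohort (100 analysis samples, 5 planted
modules over a 500-gene universe, 100 miRNAs of which 3 are planted
regulators), runs the whole pipeline, and evaluates against the truth:

```r
library(modulemir)
rep <- run_demo(seed = 7)

rep$modules$count
#> [1] 5
unlist(rep$modules$sizes)
#>      blue     brown     green turquoise    yellow
#>        80        60        40       100        50
rep$module_trait$important
#> [1] "turquoise" "blue"      "yellow"    "green"
rep$selected[, c("mirna", "module", "x", "n", "z", "N", "fdr", "r_me")]
#>       mirna    module   x  n  z   N      fdr   r_me
#> 1   miR-001 turquoise 100 85 60 500 4.14e-28 -0.667
#> 3   miR-003 turquoise 100 75 50 500 1.58e-20 -0.566
#> 102 miR-002      blue  80 73 48 500 5.77e-25 -0.682
rep$truth_eval$all_planted_selected
#> [1] TRUE
```

Reading the selected records: `miR-001` has 85 annotated targets in the
500-gene universe, 60 of them inside the 100-gene `turquoise` module —
overwhelmingly more than chance (FDR ≈ 4e-28) — and its expression runs
opposite the module eigengene (r = −0.67), so it is flagged as a
candidate repressor of that progression program. The per-sample scores of
each selected target set rise with stage, as planted:

```r
rep$gsva
#>                 set stage_r  stage_p   n
#> 1 miR-001|turquoise   0.356 0.000280 100
#> 2 miR-003|turquoise   0.379 0.000102 100
#> 3      miR-002|blue   0.341 0.000525 100
```

Individual stages are exported (`select_samples()`,
`filter_low_counts()`, `normalize_log2()`, `pick_soft_threshold()`,
`tom_similarity()`, `detect_modules()`, `module_eigengenes()`,
`encode_traits()`, `select_important_modules()`, `screen_regulators()`,
`gsva_scores()`, `mcode()` …) and can be driven from the shell via the
thin CLI at `inst/scripts/modulemir` (subcommands `simulate`, `run`,
`preprocess`, `network`, `traits`, `enrich`, `gsva`, `mcode`). See the
methods vignette (`vignettes/modulemir-methods.Rmd`) for the model,
parameter meanings and design choices.

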