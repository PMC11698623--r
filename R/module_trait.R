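# Module-trait screening: encode stage and TNM as ordinal codes, correlate
# them with module eigengenes, and flag modules associated with at least two
# progression traits.

#' Encode clinical stage and TNM as ordinal numeric traits
#'
#' Stage I-IV maps to 1-4 with sub-letters (IIA, IIIB, ...) collapsed to
#' the Roman numeral; T/N/M labels map to their numeric component
#' (T3 -> 3, N0 -> 0). Labels with an `X` component (TX, NX, MX) are
#' unparseable: by default they raise an error naming the sample and
#' field, or the sample is excluded when `on_unparseable = "exclude"`.
#'
#' @param clinical Clinical data frame (see [read_clinical_tsv()]).
#' @param samples Optional sample ids defining row order; defaults to all
#'   clinical samples.
#' @param on_unparseable `"error"` (default) or `"exclude"`.
#' @return Numeric matrix (samples x 4) with columns
#'   `stage`, `t`, `n`, `m`.
#' @export
encode_traits <- function(clinical, samples = NULL,
                          on_unparseable = c("error", "exclude")) {
  check_clinical(clinical)
  on_unparseable <- match.arg(on_unparseable)
  if (is.null(samples)) samples <- clinical$sample_id
  idx <- match(samples, clinical$sample_id)
  if (anyNA(idx))
    stopf("sample(s) missing from clinical table: %s",
          paste(head(samples[is.na(idx)], 5L), collapse = ", "))
  cl <- clinical[idx, , drop = FALSE]

  parse_stage <- function(label) {
    core <- sub("([IV]+)[AB]?$", "\\1", toupper(trimws(label)))
    unname(c(I = 1, II = 2, III = 3, IV = 4)[core])
  }
  parse_tnm <- function(label, prefix) {
    m <- regmatches(label, regexec(paste0("^", prefix, "([0-9]+)"),
                                   toupper(trimws(label))))
    vapply(m, function(g) if (length(g) == 2L) as.numeric(g[2L]) else
      NA_real_, 0)
  }
  traits <- cbind(stage = vapply(cl$stage, parse_stage, 0, USE.NAMES = FALSE),
                  t = parse_tnm(cl$t, "T"),
                  n = parse_tnm(cl$n, "N"),
                  m = parse_tnm(cl$m, "M"))
  rownames(traits) <- cl$sample_id
  bad <- which(is.na(traits), arr.ind = TRUE)
  if (nrow(bad)) {
    if (on_unparseable == "error") {
      stopf("unparseable trait label: sample '%s', field '%s'",
            rownames(traits)[bad[1L, 1L]], colnames(traits)[bad[1L, 2L]])
    }
    traits <- traits[setdiff(seq_len(nrow(traits)), unique(bad[, 1L])), ,
                     drop = FALSE]
  }
  traits
}

#' Correlate module eigengenes with progression traits
#'
#' Pearson correlation per (module, trait) pair with a two-sided p-value
#' from the t statistic `r * sqrt((n - 2) / (1 - r^2))` on `n - 2`
#' degrees of freedom.
#'
#' @param eigengenes Eigengene matrix (modules x samples).
#' @param traits Numeric trait matrix (samples x traits) from
#'   [encode_traits()]; sample sets must overlap in at least 4 samples.
#' @return List with matrices `r` and `p` (modules x traits) and the
#'   sample count `n`.
#' @export
correlate_eigengene_traits <- function(eigengenes, traits) {
  shared <- intersect(colnames(eigengenes), rownames(traits))
  if (length(shared) < 4L)
    stopf("need at least 4 shared samples, got %d", length(shared))
  tr <- traits[shared, , drop = FALSE]
  constant <- apply(tr, 2L, function(x) var(x) == 0)
  if (any(constant))
    stopf("constant trait(s): %s",
          paste(colnames(tr)[constant], collapse = ", "))
  me <- eigengenes[, shared, drop = FALSE]
  r <- cor(t(me), tr)
  p <- matrix(cor_pvalue(r, length(shared)), nrow(r), ncol(r),
              dimnames = dimnames(r))
  list(r = r, p = p, n = length(shared))
}

#' Select important (progression-associated) modules
#'
#' A module is flagged when, for at least `min_traits` traits, the
#' absolute correlation strictly exceeds `cor_thr` and the p-value is
#' strictly below `p_thr`.
#'
#' @param result Output of [correlate_eigengene_traits()].
#' @param cor_thr Absolute-correlation threshold (default 0.2, strict).
#' @param p_thr P-value threshold (default 0.05, strict).
#' @param min_traits Minimum qualifying traits (default 2).
#' @return Character vector of important module labels.
#' @export
select_important_modules <- function(result, cor_thr = 0.2, p_thr = 0.05,
                                     min_traits = 2L) {
  hits <- abs(result$r) > cor_thr & result$p < p_thr
  rownames(result$r)[rowSums(hits) >= min_traits]
}
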