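#' 2^-ddCt relative quantification
#'
#' Comparative-Ct quantification of target genes against a reference gene
#' (beta-actin in the study this package emulates), with one condition as
#' calibrator. Replicate Ct values are arithmetically averaged per
#' (gene, condition) before differencing; then
#' `dCt = Ct_target - Ct_reference`, `ddCt = dCt_test - dCt_calibrator`,
#' relative expression `fold = 2^-ddCt` and `log2fc = -ddCt`. Amplification
#' efficiency is assumed to be 2 (the method's standard assumption).
#'
#' @param ct Data.frame with columns `gene`, `condition`, `replicate`,
#'   `target_ct`, `reference_ct` (see [simulate_qpcr()] / [read_ct_table()]).
#' @param calibrator Calibrator condition (default `"F"`); the remaining
#'   condition is the test condition.
#' @return Data.frame with one row per gene: mean target/reference Ct per
#'   condition, `delta_ct_test`, `delta_ct_calibrator`, `delta_delta_ct`,
#'   `fold`, `log2fc`.
#' @export
delta_delta_ct <- function(ct, calibrator = "F") {
  stopifnot(is.data.frame(ct),
            all(c("gene", "condition", "target_ct", "reference_ct") %in%
                  names(ct)))
  if (any(ct$target_ct < 0) || any(ct$reference_ct < 0)) {
    stop("negative Ct values are not valid cycle counts")
  }
  conds <- unique(ct$condition)
  if (!calibrator %in% conds) stop("calibrator condition not in Ct table")
  if (length(conds) != 2L) stop("exactly two conditions are required")
  test <- setdiff(conds, calibrator)
  agg <- stats::aggregate(cbind(target_ct, reference_ct) ~ gene + condition,
                          data = ct, FUN = mean)
  wide <- merge(agg[agg$condition == test, ],
                agg[agg$condition == calibrator, ],
                by = "gene", suffixes = c("_test", "_cal"))
  incomplete <- setdiff(unique(ct$gene), wide$gene)
  if (length(incomplete) > 0) {
    stop("genes missing a condition: ", paste(incomplete, collapse = ", "))
  }
  dct_t <- wide$target_ct_test - wide$reference_ct_test
  dct_c <- wide$target_ct_cal - wide$reference_ct_cal
  ddct <- dct_t - dct_c
  data.frame(gene = wide$gene,
             target_ct_test = wide$target_ct_test,
             reference_ct_test = wide$reference_ct_test,
             target_ct_calibrator = wide$target_ct_cal,
             reference_ct_calibrator = wide$reference_ct_cal,
             delta_ct_test = dct_t, delta_ct_calibrator = dct_c,
             delta_delta_ct = ddct, fold = 2^(-ddct), log2fc = -ddct,
             row.names = NULL)
}

#' qPCR vs RNA-seq concordance
#'
#' Per-gene sign agreement of the log2 fold changes measured by qPCR and by
#' RNA-seq, plus their Pearson correlation across genes — the standard
#' validation summary for a candidate-gene panel.
#'
#' @param qpcr Data.frame from [delta_delta_ct()] (columns `gene`,
#'   `log2fc`).
#' @param de A `de_result` data.frame from [run_de()] (columns `gene`,
#'   `log2fc`).
#' @return List with `table` (gene, `rnaseq_log2fc`, `qpcr_log2fc`,
#'   `concordant`), `fraction_concordant` and `pearson_r`.
#' @export
qpcr_concordance <- function(qpcr, de) {
  stopifnot(is.data.frame(qpcr), is.data.frame(de))
  shared <- intersect(qpcr$gene, de$gene)
  if (length(shared) == 0) stop("no shared genes between qPCR and RNA-seq")
  qi <- match(shared, qpcr$gene)
  di <- match(shared, de$gene)
  tab <- data.frame(gene = shared,
                    rnaseq_log2fc = de$log2fc[di],
                    qpcr_log2fc = qpcr$log2fc[qi], row.names = NULL)
  tab$concordant <- sign(tab$rnaseq_log2fc) == sign(tab$qpcr_log2fc)
  r <- if (length(shared) >= 3 &&
           stats::sd(tab$rnaseq_log2fc) > 0 && stats::sd(tab$qpcr_log2fc) > 0) {
    stats::cor(tab$rnaseq_log2fc, tab$qpcr_log2fc)
  } else if (length(shared) >= 2) {
    stats::cor(tab$rnaseq_log2fc, tab$qpcr_log2fc)
  } else {
    NA_real_
  }
  list(table = tab, fraction_concordant = mean(tab$concordant), pearson_r = r)
}
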