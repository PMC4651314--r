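#' Quality-filter FASTQ reads
#'
#' Applies the whole-read cleaning rules used for the gonad transcriptome
#' libraries: a read is discarded if strictly more than `max_n_frac` of its
#' bases are ambiguous (`N`/`n`), or if strictly more than `max_lowq_frac`
#' of its bases have Phred quality below `min_q`. Both comparisons are
#' strict, so a 100-bp read with exactly 5 Ns and exactly 30 bases at Q19 is
#' retained. Adapter trimming is assumed done upstream.
#'
#' @param fastq A data.frame of reads (`id`, `sequence`, `quality`) or a
#'   path to a FASTQ file (gzip transparent).
#' @param max_n_frac Maximum tolerated fraction of ambiguous bases (default
#'   0.05, i.e. the ">5% N" rule).
#' @param min_q Phred threshold defining a low-quality base (default 20).
#' @param max_lowq_frac Maximum tolerated fraction of low-quality bases
#'   (default 0.30).
#' @param out Optional path: write the retained reads as FASTQ.
#' @return List of class `filter_result`:
#'   * `reads` — data.frame of retained reads,
#'   * `discarded` — logical vector over the input reads,
#'   * `stats` — `filter_stats` list: `reads_before`, `reads_after`,
#'     `bases_before`, `bases_after`, `retention_pct` (bases retained, in
#'     percent, 2 decimals).
#' @export
filter_reads <- function(fastq, max_n_frac = 0.05, min_q = 20,
                         max_lowq_frac = 0.30, out = NULL) {
  if (is.character(fastq) && length(fastq) == 1L) fastq <- read_fastq(fastq)
  stopifnot(is.data.frame(fastq),
            all(c("id", "sequence", "quality") %in% names(fastq)))
  check_scalar(max_n_frac, "max_n_frac", 0, 1)
  check_scalar(max_lowq_frac, "max_lowq_frac", 0, 1)
  bad_len <- which(nchar(fastq$sequence) != nchar(fastq$quality))
  if (length(bad_len) > 0) {
    stop(sprintf("record %d: sequence/quality length mismatch", bad_len[1]))
  }
  discard <- n_fraction(fastq$sequence) > max_n_frac |
    lowq_fraction(fastq$quality, min_q) > max_lowq_frac
  kept <- fastq[!discard, , drop = FALSE]
  stats <- filter_stats(reads_before = nrow(fastq), reads_after = nrow(kept),
                        bases_before = sum(nchar(fastq$sequence)),
                        bases_after = sum(nchar(kept$sequence)))
  if (!is.null(out)) write_fastq(kept, out)
  structure(list(reads = kept, discarded = discard, stats = stats),
            class = "filter_result")
}

# internal constructor for the retention statistics record
filter_stats <- function(reads_before, reads_after, bases_before, bases_after) {
  stopifnot(reads_after <= reads_before, bases_after <= bases_before,
            reads_after >= 0, bases_after >= 0)
  structure(list(reads_before = reads_before, reads_after = reads_after,
                 bases_before = bases_before, bases_after = bases_after,
                 retention_pct = retention_stats(bases_before, bases_after)),
            class = "filter_stats")
}

#' @export
print.filter_stats <- function(x, ...) {
  cat(sprintf("reads: %s -> %s; bases: %s -> %s (%.2f%% retained)\n",
              format(x$reads_before, big.mark = ","),
              format(x$reads_after, big.mark = ","),
              format(x$bases_before, big.mark = ","),
              format(x$bases_after, big.mark = ","), x$retention_pct))
  invisible(x)
}

#' Base retention percentage after filtering
#'
#' `100 * bases_after / bases_before`, rounded half-up to 2 decimals — the
#' "base filter \%" column of sequencing-run summary tables.
#'
#' @param bases_before Total bases before filtering (> 0).
#' @param bases_after Total bases after filtering (between 0 and
#'   `bases_before`).
#' @return Percentage in `[0, 100]` with 2 decimals.
#' @export
#' @examples
#' retention_stats(5198681376, 5044969881) # 97.04
retention_stats <- function(bases_before, bases_after) {
  if (any(bases_before <= 0)) stop("bases_before must be positive")
  if (any(bases_after < 0) || any(bases_after > bases_before)) {
    stop("bases_after must lie in [0, bases_before]")
  }
  percent_of(bases_after, bases_before, digits = 2)
}
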