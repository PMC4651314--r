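#' Read a FASTQ file (Phred+33, gzip transparent)
#'
#' Thin wrapper around Biostrings' quality-aware FASTQ reader that returns a
#' plain data.frame and, when the file is malformed, rescans it line by line
#' to report the index of the offending record.
#'
#' @param path Path to a `.fq`/`.fastq` file, optionally gzipped.
#' @return Data.frame with columns `id`, `sequence`, `quality`.
#' @export
read_fastq <- function(path) {
  if (!file.exists(path)) stop("FASTQ file not found: ", path)
  validate_fastq(path)
  x <- withCallingHandlers(
    Biostrings::readQualityScaledDNAStringSet(path, quality.scoring = "phred"),
    warning = function(w) {
      # harmless internal notice about dropped metadata columns
      if (grepl("metadata columns", conditionMessage(w))) {
        invokeRestart("muffleWarning")
      }
    })
  data.frame(id = names(x) %||% sprintf("read_%06d", seq_along(x)),
             sequence = as.character(x),
             quality = as.character(Biostrings::quality(x)),
             row.names = NULL)
}

# internal: line-scan a FASTQ file (4-line records, gz transparent) and stop
# at the first malformed record, naming its index; the parser itself does
# not report record positions
validate_fastq <- function(path) {
  con <- gzfile(path, "rt")
  on.exit(close(con))
  lines <- readLines(con, warn = FALSE)
  n_rec <- length(lines) %/% 4L
  if (length(lines) %% 4L != 0L) {
    stop(sprintf("malformed FASTQ '%s': truncated record %d (%d trailing lines)",
                 path, n_rec + 1L, length(lines) %% 4L))
  }
  for (i in seq_len(n_rec)) {
    block <- lines[(4L * (i - 1L) + 1L):(4L * i)]
    if (!startsWith(block[1], "@") || !startsWith(block[3], "+")) {
      stop(sprintf("malformed FASTQ '%s': record %d lacks @/+ markers", path, i))
    }
    if (nchar(block[2]) != nchar(block[4])) {
      stop(sprintf(
        "malformed FASTQ '%s': record %d sequence/quality length mismatch (%d vs %d)",
        path, i, nchar(block[2]), nchar(block[4])))
    }
  }
  invisible(n_rec)
}

#' Write reads to a FASTQ file (Phred+33)
#'
#' @param reads Data.frame with columns `id`, `sequence`, `quality` (as
#'   produced by [read_fastq()] or [simulate_fastq()]).
#' @param path Output path; `.gz` suffix triggers gzip compression.
#' @return `path`, invisibly.
#' @export
write_fastq <- function(reads, path) {
  stopifnot(is.data.frame(reads),
            all(c("id", "sequence", "quality") %in% names(reads)))
  if (any(nchar(reads$sequence) != nchar(reads$quality))) {
    stop("sequence/quality length mismatch in reads to write")
  }
  x <- Biostrings::QualityScaledDNAStringSet(
    Biostrings::DNAStringSet(reads$sequence),
    Biostrings::PhredQuality(reads$quality))
  names(x) <- reads$id
  Biostrings::writeQualityScaledXStringSet(x, path,
                                           compress = grepl("\\.gz$", path))
  invisible(path)
}

# internal: per-read fraction of bases with Phred score < min_q
lowq_fraction <- function(quality, min_q) {
  vapply(quality, function(q) {
    scores <- utf8ToInt(q) - 33L
    if (any(scores < 0L | scores > 93L)) {
      stop("quality characters outside the Phred+33 range")
    }
    mean(scores < min_q)
  }, numeric(1), USE.NAMES = FALSE)
}

# internal: per-read fraction of ambiguous (N/n) bases
n_fraction <- function(sequence) {
  (nchar(sequence) - nchar(gsub("[Nn]", "", sequence))) / nchar(sequence)
}
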