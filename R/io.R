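# Tab-separated readers/writers for the pipeline's tabular formats.
# All tables are UTF-8 TSV with one header row; floats serialise at 6
# significant digits (percent columns are already rounded to 2 decimals).

# internal: read a TSV with basic shape checks, reporting data line numbers
read_tsv_checked <- function(path, required = NULL) {
  if (!file.exists(path)) stop("file not found: ", path)
  df <- utils::read.delim(path, stringsAsFactors = FALSE, check.names = FALSE)
  if (!is.null(required) && !all(required %in% names(df))) {
    stop(sprintf("'%s': missing required column(s): %s", path,
                 paste(setdiff(required, names(df)), collapse = ", ")))
  }
  df
}

# internal: write a data.frame as TSV, numerics at 6 significant digits
write_tsv <- function(df, path) {
  out <- df
  num <- vapply(out, is.double, logical(1))
  out[num] <- lapply(out[num], function(x) signif(x, 6))
  utils::write.table(out, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, fileEncoding = "UTF-8")
  invisible(path)
}

#' Read a gene-by-sample count TSV
#'
#' First column = gene id, remaining columns = integer counts per sample.
#' Negative or non-integer entries are rejected with the offending data
#' line number; so are duplicate gene ids.
#'
#' @param path TSV path.
#' @return Integer matrix with gene rownames and sample colnames.
#' @export
read_counts <- function(path) {
  df <- read_tsv_checked(path)
  if (ncol(df) < 2) stop(sprintf("'%s': need a gene column plus samples", path))
  genes <- as.character(df[[1]])
  dup <- which(duplicated(genes))
  if (length(dup) > 0) {
    stop(sprintf("'%s': duplicate gene id '%s' at line %d", path,
                 genes[dup[1]], dup[1] + 1L))
  }
  m <- as.matrix(df[, -1, drop = FALSE])
  if (!is.numeric(m)) {
    bad <- which(is.na(suppressWarnings(apply(df[, -1, drop = FALSE], 1,
                                              as.numeric))))[1]
    stop(sprintf("'%s': non-numeric count at line %d", path, bad + 1L))
  }
  bad <- which(rowSums(m < 0 | m != floor(m)) > 0)
  if (length(bad) > 0) {
    stop(sprintf("'%s': negative or non-integer count at line %d", path,
                 bad[1] + 1L))
  }
  storage.mode(m) <- "integer"
  rownames(m) <- genes
  m
}

#' Write a count matrix as TSV
#' @param counts A [count_matrix()] or matrix with dimnames.
#' @param path Output path.
#' @export
write_counts <- function(counts, path) {
  m <- if (inherits(counts, "count_matrix")) counts$counts else counts
  df <- data.frame(gene = rownames(m), m, check.names = FALSE,
                   row.names = NULL)
  write_tsv(df, path)
}

#' Read a sample-to-condition map TSV (columns `sample`, `condition`)
#' @param path TSV path.
#' @return Named character vector of conditions.
#' @export
read_conditions <- function(path) {
  df <- read_tsv_checked(path, c("sample", "condition"))
  if (anyDuplicated(df$sample)) stop(sprintf("'%s': duplicate sample id", path))
  stats::setNames(as.character(df$condition), as.character(df$sample))
}

#' Write a sample-to-condition map TSV
#' @param conditions Named character vector.
#' @param path Output path.
#' @export
write_conditions <- function(conditions, path) {
  write_tsv(data.frame(sample = names(conditions),
                       condition = unname(conditions)), path)
}

#' Read gene-set annotations in GMT format
#'
#' One term per line: term id, description, then tab-separated member
#' genes. The description field carries the category (`BP`, `MF`, `CC` or
#' `pathway`); unknown descriptions default to `BP` with a warning.
#'
#' @param path GMT path.
#' @return An [annotation_map()].
#' @export
read_gmt <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  lines <- readLines(path, warn = FALSE, encoding = "UTF-8")
  lines <- lines[nzchar(lines)]
  fields <- strsplit(lines, "\t", fixed = TRUE)
  short <- which(lengths(fields) < 3)
  if (length(short) > 0) {
    stop(sprintf("'%s': line %d has fewer than 3 fields", path, short[1]))
  }
  ids <- vapply(fields, `[[`, character(1), 1)
  cats <- vapply(fields, `[[`, character(1), 2)
  unknown <- !cats %in% c("BP", "MF", "CC", "pathway")
  if (any(unknown)) {
    warning(sprintf("%d term(s) with unrecognised category; using BP",
                    sum(unknown)))
    cats[unknown] <- "BP"
  }
  sets <- lapply(fields, function(f) f[-(1:2)])
  names(sets) <- ids
  annotation_map(sets, stats::setNames(cats, ids))
}

#' Write an annotation map in GMT format
#' @param annotation An [annotation_map()].
#' @param path Output path.
#' @export
write_gmt <- function(annotation, path) {
  stopifnot(inherits(annotation, "annotation_map"))
  lines <- vapply(names(annotation$sets), function(id) {
    paste(c(id, annotation$categories[[id]], annotation$sets[[id]]),
          collapse = "\t")
  }, character(1))
  writeLines(lines, path, useBytes = TRUE)
  invisible(path)
}

#' Read a qPCR Ct table TSV
#' @param path TSV with columns `gene`, `sample`, `condition`, `replicate`,
#'   `target_ct`, `reference_ct`.
#' @return Data.frame.
#' @export
read_ct_table <- function(path) {
  read_tsv_checked(path, c("gene", "sample", "condition", "replicate",
                           "target_ct", "reference_ct"))
}

#' Write a qPCR Ct table TSV
#' @param ct Data.frame as from [simulate_qpcr()].
#' @param path Output path.
#' @export
write_ct_table <- function(ct, path) write_tsv(ct, path)

#' Write a network edge list TSV (`gene_a`, `gene_b`, `r`, `p`, `q`)
#' @param graph A [condition_graph()].
#' @param path Output path.
#' @export
write_edges <- function(graph, path) {
  stopifnot(inherits(graph, "condition_graph"))
  write_tsv(graph$edges, path)
}

#' Read a network edge list TSV back into a condition graph
#' @param path Edge-list TSV.
#' @param condition Condition label for the rebuilt graph.
#' @param nodes Optional full node set (defaults to the genes on edges, so
#'   degree-0 nodes are lost unless supplied).
#' @return A [condition_graph()].
#' @export
read_edges <- function(path, condition = "S", nodes = NULL) {
  df <- read_tsv_checked(path, c("gene_a", "gene_b"))
  nodes <- nodes %||% sort(unique(c(df$gene_a, df$gene_b)))
  condition_graph(condition, nodes, df)
}
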