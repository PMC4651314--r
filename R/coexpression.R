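#' Normalised expression matrix
#'
#' Counts divided by per-sample size factors, optionally log2(x + 1)
#' transformed (default on): the expression values on which co-expression
#' networks are built.
#'
#' @param counts A [count_matrix()] or numeric matrix.
#' @param sf Size factors (positive, one per sample).
#' @param log2_transform Apply `log2(x + 1)` (default `TRUE`).
#' @return Numeric matrix, genes x samples.
#' @export
normalize_expression <- function(counts, sf = size_factors(counts),
                                 log2_transform = TRUE) {
  m <- if (inherits(counts, "count_matrix")) counts$counts else counts
  stopifnot(is.matrix(m), length(sf) == ncol(m))
  if (any(sf <= 0)) stop("size factors must be positive")
  expr <- sweep(m, 2, sf, "/")
  if (log2_transform) expr <- log2(expr + 1)
  expr
}

#' Pairwise Pearson correlation with significance
#'
#' Product-moment correlation for every gene pair across the given samples,
#' with two-sided p-values from the t transform `t = r * sqrt(df / (1 -
#' r^2))`, `df = n_samples - 2`. Pairs with `|r| = 1` (within numerical
#' tolerance) get `p = 0`. Genes with zero variance are dropped with a
#' warning, since their correlation is undefined.
#'
#' @param expr Expression matrix (genes x samples), e.g. from
#'   [normalize_expression()].
#' @param genes Optional subset of row names to correlate (default all).
#' @return List of class `corr_result`: symmetric matrices `r` and `p`
#'   (diagonal `r = 1`, `p = NA`), and `n_samples`.
#' @export
pairwise_correlation <- function(expr, genes = rownames(expr)) {
  stopifnot(is.matrix(expr))
  if (ncol(expr) < 3) stop("at least 3 samples are required for correlation")
  expr <- expr[genes, , drop = FALSE]
  v <- apply(expr, 1, stats::var)
  if (any(v == 0)) {
    warning(sprintf("dropping %d constant gene(s) from correlation",
                    sum(v == 0)))
    expr <- expr[v > 0, , drop = FALSE]
  }
  if (nrow(expr) < 2) stop("fewer than 2 variable genes remain")
  r <- stats::cor(t(expr))
  df <- ncol(expr) - 2
  r_clamped <- pmin(abs(r), 1 - 1e-12)
  tstat <- r_clamped * sqrt(df / (1 - r_clamped^2))
  p <- 2 * stats::pt(tstat, df, lower.tail = FALSE)
  p[abs(r) >= 1 - 1e-10] <- 0
  diag(p) <- NA_real_
  structure(list(r = r, p = p, n_samples = ncol(expr)),
            class = "corr_result")
}

#' Build a per-condition co-expression network
#'
#' Thresholds the pairwise correlations into an undirected gene graph for
#' one condition. Two modes:
#' * `"fdr"` — BH-adjust the correlation p-values across all pairs and keep
#'   pairs with `q < cutoff` (the rule stated for the original study;
#'   rarely attainable with 3 samples per condition);
#' * `"abs_r"` — keep pairs with `|r| >= cutoff` (default mode at study
#'   scale, cutoff 0.95).
#'
#' Edges carry signed `r`; thresholding always uses `|r|`. Genes with no
#' surviving edge remain in the graph as degree-0 nodes.
#'
#' @param corr A `corr_result` from [pairwise_correlation()].
#' @param condition Condition label stored in the graph (`"F"`/`"S"`).
#' @param mode `"abs_r"` or `"fdr"`.
#' @param cutoff Threshold: `|r|` floor for `"abs_r"` (in `[0, 1 + eps]`),
#'   q ceiling for `"fdr"` (in `(0, 1]`).
#' @return Object of class `condition_graph`: list with `condition`,
#'   `nodes`, `edges` (data.frame `gene_a`, `gene_b`, `r`, `p`, `q`) and
#'   `meta` (mode and cutoff).
#' @export
build_network <- function(corr, condition = "S", mode = c("abs_r", "fdr"),
                          cutoff = 0.95) {
  stopifnot(inherits(corr, "corr_result"))
  mode <- match.arg(mode)
  check_scalar(cutoff, "cutoff")
  if (mode == "fdr" && (cutoff <= 0 || cutoff > 1)) {
    stop("fdr cutoff must lie in (0, 1]")
  }
  if (mode == "abs_r" && cutoff < 0) stop("abs_r cutoff must be non-negative")
  genes <- rownames(corr$r)
  ut <- upper.tri(corr$r)
  idx <- which(ut, arr.ind = TRUE)
  pair_r <- corr$r[ut]
  pair_p <- corr$p[ut]
  pair_q <- bh_fdr(pair_p)
  keep <- if (mode == "fdr") pair_q < cutoff else abs(pair_r) >= cutoff
  edges <- data.frame(gene_a = genes[idx[keep, 1]],
                      gene_b = genes[idx[keep, 2]],
                      r = pair_r[keep], p = pair_p[keep], q = pair_q[keep],
                      row.names = NULL)
  # canonical unordered-pair orientation for determinism
  flip <- edges$gene_a > edges$gene_b
  tmp <- edges$gene_a[flip]
  edges$gene_a[flip] <- edges$gene_b[flip]
  edges$gene_b[flip] <- tmp
  edges <- edges[order(edges$gene_a, edges$gene_b), , drop = FALSE]
  rownames(edges) <- NULL
  condition_graph(condition, genes, edges,
                  meta = list(mode = mode, cutoff = cutoff))
}

#' Construct a condition graph from an edge list
#'
#' @param condition Condition label.
#' @param nodes Character vector of node (gene) ids.
#' @param edges Data.frame with at least `gene_a`, `gene_b`; self-loops and
#'   duplicate unordered pairs are rejected.
#' @param meta Optional construction metadata list.
#' @return Object of class `condition_graph`.
#' @export
condition_graph <- function(condition, nodes, edges, meta = list()) {
  stopifnot(is.character(nodes), is.data.frame(edges),
            all(c("gene_a", "gene_b") %in% names(edges)))
  if (anyDuplicated(nodes)) stop("duplicate node ids")
  if (any(edges$gene_a == edges$gene_b)) stop("self-loops are not allowed")
  if (!all(c(edges$gene_a, edges$gene_b) %in% nodes)) {
    stop("edge endpoints must be declared nodes")
  }
  key <- paste(pmin(edges$gene_a, edges$gene_b),
               pmax(edges$gene_a, edges$gene_b))
  if (anyDuplicated(key)) stop("duplicate edges between the same gene pair")
  structure(list(condition = condition, nodes = nodes, edges = edges,
                 meta = meta),
            class = "condition_graph")
}

#' @export
print.condition_graph <- function(x, ...) {
  cat(sprintf("condition_graph '%s': %d nodes, %d edges (%s)\n",
              x$condition, length(x$nodes), nrow(x$edges),
              paste(names(x$meta), unlist(x$meta), sep = "=",
                    collapse = ", ")))
  invisible(x)
}
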