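#' Term-to-gene annotation map
#'
#' @param sets Named list of character gene vectors, one per term; every set
#'   must be non-empty.
#' @param categories Named character vector (one of `BP`, `MF`, `CC`,
#'   `pathway`) aligned to `names(sets)`; a single value is recycled.
#' @return Object of class `annotation_map`: list with `sets` and
#'   `categories`.
#' @export
annotation_map <- function(sets, categories = "BP") {
  stopifnot(is.list(sets), length(sets) > 0, !is.null(names(sets)))
  if (anyDuplicated(names(sets))) stop("duplicate term ids")
  if (any(lengths(sets) == 0)) stop("annotation terms must be non-empty")
  if (length(categories) == 1L) {
    categories <- stats::setNames(rep(categories, length(sets)), names(sets))
  }
  categories <- as.character(categories) |>
    stats::setNames(names(categories) %||% names(sets))
  if (!setequal(names(categories), names(sets))) {
    stop("category names must match term ids")
  }
  if (!all(categories %in% c("BP", "MF", "CC", "pathway"))) {
    stop("categories must be BP, MF, CC or pathway")
  }
  structure(list(sets = lapply(sets, as.character),
                 categories = categories[names(sets)]),
            class = "annotation_map")
}

#' @export
print.annotation_map <- function(x, ...) {
  cat(sprintf("annotation_map: %d terms (%s), %d distinct genes\n",
              length(x$sets),
              paste(sprintf("%s=%d", names(table(x$categories)),
                            table(x$categories)), collapse = ", "),
              length(unique(unlist(x$sets)))))
  invisible(x)
}

#' Fisher's exact test over-representation analysis
#'
#' One-sided hypergeometric over-representation test per term: with `N`
#' universe genes of which `K` carry the term and a DE set of size `n`
#' containing `k` term genes, `p = P(X >= k)` for `X ~ Hypergeom(N, K, n)`.
#' FDR is adjusted by Benjamini-Hochberg within each annotation category
#' (and each call is one direction family).
#'
#' @param de_genes Character vector of selected genes; must be a subset of
#'   `universe`.
#' @param universe Character vector: the gene universe (typically all genes
#'   present in both the annotation and the count matrix).
#' @param annotation An [annotation_map()].
#' @param min_term_size Terms with fewer than this many universe genes are
#'   skipped (default 2).
#' @param direction Label stored in the output (`"up"`, `"down"` or
#'   `"all"`).
#' @return Data.frame sorted by p-value with columns `term`, `category`,
#'   `k`, `K`, `n`, `N`, `expected`, `p_value`, `q_value`, `direction`.
#' @export
fisher_enrichment <- function(de_genes, universe, annotation,
                              min_term_size = 2, direction = "all") {
  stopifnot(inherits(annotation, "annotation_map"))
  universe <- unique(as.character(universe))
  de_genes <- unique(as.character(de_genes))
  missing <- setdiff(de_genes, universe)
  if (length(missing) > 0) {
    stop("DE genes absent from the universe: ",
         paste(utils::head(missing, 5), collapse = ", "))
  }
  empty <- data.frame(term = character(0), category = character(0),
                      k = integer(0), K = integer(0), n = integer(0),
                      N = integer(0), expected = numeric(0),
                      p_value = numeric(0), q_value = numeric(0),
                      direction = character(0))
  if (length(de_genes) == 0) {
    warning("empty DE set; returning no enrichment results")
    return(empty)
  }
  N <- length(universe)
  n <- length(de_genes)
  rows <- lapply(names(annotation$sets), function(id) {
    term_genes <- intersect(annotation$sets[[id]], universe)
    K <- length(term_genes)
    if (K < min_term_size) return(NULL)
    k <- length(intersect(term_genes, de_genes))
    p <- stats::phyper(k - 1, K, N - K, n, lower.tail = FALSE)
    data.frame(term = id, category = unname(annotation$categories[id]),
               k = k, K = K, n = n, N = N, expected = n * K / N,
               p_value = p)
  })
  res <- do.call(rbind, rows)
  if (is.null(res)) return(empty)
  res$q_value <- NA_real_
  for (cat in unique(res$category)) {
    sel <- res$category == cat
    res$q_value[sel] <- bh_fdr(res$p_value[sel])
  }
  res$direction <- direction
  res <- res[order(res$p_value, res$term), , drop = FALSE]
  rownames(res) <- NULL
  res
}

#' Direction-split enrichment
#'
#' Runs [fisher_enrichment()] separately on the up- and down-regulated DE
#' genes, mirroring the paired barplots of enrichment reports. Each run is
#' its own FDR family.
#'
#' @param de_table Data.frame with columns `gene` and `direction`
#'   (`"up"`/`"down"`; other labels ignored), e.g. `filter_de()$table`.
#' @param universe,annotation,min_term_size As in [fisher_enrichment()].
#' @return List with data.frames `up` and `down`.
#' @export
enrich_by_direction <- function(de_table, universe, annotation,
                                min_term_size = 2) {
  stopifnot(is.data.frame(de_table),
            all(c("gene", "direction") %in% names(de_table)))
  run <- function(dir) {
    genes <- de_table$gene[de_table$direction == dir]
    if (length(genes) == 0) {
      return(suppressWarnings(
        fisher_enrichment(character(0), universe, annotation,
                          min_term_size, direction = dir)))
    }
    fisher_enrichment(genes, universe, annotation, min_term_size,
                      direction = dir)
  }
  list(up = run("up"), down = run("down"))
}
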