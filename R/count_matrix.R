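#' Gene-by-sample count matrix with condition labels
#'
#' The pipeline's central container: an integer matrix of read counts (genes
#' as rows, samples as columns) together with a sample-to-condition map. The
#' study design this package targets has two conditions, fertile (`"F"`) and
#' sterile (`"S"`), with three biological replicates each, but any two-group
#' layout with at least two replicates per group is accepted.
#'
#' @param counts Integer matrix, genes x samples, with unique non-empty
#'   dimnames.
#' @param conditions Character (or factor) vector naming each sample's
#'   condition; names must match `colnames(counts)` (order-free).
#' @return An object of class `count_matrix`: a list with elements `counts`
#'   and `conditions` (named character, aligned to the columns).
#' @export
#' @examples
#' m <- matrix(rpois(24, 50), nrow = 4,
#'             dimnames = list(paste0("g", 1:4), paste0("s", 1:6)))
#' cm <- count_matrix(m, setNames(rep(c("F", "S"), each = 3), colnames(m)))
count_matrix <- function(counts, conditions) {
  if (!is.matrix(counts) || !is.numeric(counts)) {
    stop("'counts' must be a numeric matrix")
  }
  if (is.null(rownames(counts)) || is.null(colnames(counts))) {
    stop("'counts' must have gene rownames and sample colnames")
  }
  if (anyDuplicated(rownames(counts))) stop("duplicate gene ids in counts")
  if (anyDuplicated(colnames(counts))) stop("duplicate sample ids in counts")
  if (any(counts < 0) || any(counts != floor(counts))) {
    stop("counts must be non-negative integers")
  }
  if (max(counts) <= .Machine$integer.max) storage.mode(counts) <- "integer"
  conditions <- as.character(conditions) |>
    stats::setNames(names(conditions) %||% colnames(counts))
  if (!setequal(names(conditions), colnames(counts))) {
    stop("condition names must match sample ids")
  }
  conditions <- conditions[colnames(counts)]
  tab <- table(conditions)
  if (length(tab) != 2L) stop("exactly two conditions are required")
  if (any(tab < 2L)) stop("at least 2 samples per condition are required")
  structure(list(counts = counts, conditions = conditions),
            class = "count_matrix")
}

#' @export
print.count_matrix <- function(x, ...) {
  tab <- table(x$conditions)
  cat(sprintf("count_matrix: %d genes x %d samples (%s)\n",
              nrow(x$counts), ncol(x$counts),
              paste(sprintf("%s=%d", names(tab), tab), collapse = ", ")))
  invisible(x)
}

# internal: accept a count_matrix or (matrix, conditions) pair
as_count_matrix <- function(x, conditions = NULL) {
  if (inherits(x, "count_matrix")) return(x)
  count_matrix(x, conditions)
}

# internal: column indices of each condition, fertile-style group first
condition_groups <- function(cm, ref = "F") {
  conds <- cm$conditions
  levels <- unique(conds)
  if (ref %in% levels) levels <- c(ref, setdiff(levels, ref))
  list(a = which(conds == levels[1]), b = which(conds == levels[2]),
       labels = levels)
}
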