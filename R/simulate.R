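#' Configuration for the synthetic two-condition RNA-seq study
#'
#' Collects all parameters of the simulated study in one validated object.
#' Defaults mirror the gonad-transcriptome design the package targets: two
#' conditions (fertile `"F"`, sterile `"S"`) with 3 biological replicates
#' each, negative-binomial counts with moderate overdispersion, a planted
#' differentially-expressed (DE) fraction with symmetric log2 fold changes,
#' and optional gene blocks that are co-expressed in one condition only (the
#' structure the differential k-core statistic is designed to detect).
#'
#' @param n_genes Number of genes.
#' @param n_per_group Replicates per condition (study design: 3).
#' @param de_fraction Fraction of genes that are truly DE; `round(de_fraction
#'   * n_genes)` genes are planted.
#' @param lfc_values Log2 fold changes (sterile relative to fertile) sampled
#'   uniformly for planted DE genes.
#' @param dispersion NB dispersion alpha, so that variance = mu + alpha *
#'   mu^2. Must be > 0.
#' @param base_mean_range Range of baseline expected counts; per-gene
#'   baselines are drawn log-uniformly within it.
#' @param size_factor_range Range of per-sample library-size factors (drawn
#'   log-uniformly); `c(1, 1)` disables library-size variation.
#' @param block_spec List of co-expression blocks, each a list with elements
#'   `size` (number of genes), `rho` (within-block latent correlation, in
#'   (-1, 1)) and `condition` (`"F"` or `"S"`: the condition in which the
#'   block is co-expressed).
#' @param n_terms Number of annotation terms to generate.
#' @param enriched_term_fraction Fraction of terms planted to be enriched in
#'   the DE set.
#' @param term_size_range Range of genes per term.
#' @param de_weight Relative sampling weight of DE genes when drawing members
#'   of a planted enriched term (non-enriched terms sample uniformly).
#' @param seed Integer seed; all generator randomness flows from it.
#' @return A validated list of class `sim_config`.
#' @export
sim_config <- function(n_genes = 2000, n_per_group = 3, de_fraction = 0.1,
                       lfc_values = c(-2, 2), dispersion = 0.1,
                       base_mean_range = c(20, 500),
                       size_factor_range = c(0.8, 1.25),
                       block_spec = list(),
                       n_terms = 100, enriched_term_fraction = 0.1,
                       term_size_range = c(10, 50), de_weight = 20,
                       seed = 1) {
  check_scalar(n_genes, "n_genes", lo = 1)
  check_scalar(n_per_group, "n_per_group", lo = 2)
  check_scalar(de_fraction, "de_fraction", lo = 0, hi = 1)
  check_scalar(dispersion, "dispersion")
  if (dispersion <= 0) stop("'dispersion' must be > 0")
  stopifnot(length(base_mean_range) == 2L, all(base_mean_range > 0),
            length(size_factor_range) == 2L, all(size_factor_range > 0),
            length(term_size_range) == 2L, all(term_size_range >= 1))
  check_scalar(n_terms, "n_terms", lo = 1)
  check_scalar(enriched_term_fraction, "enriched_term_fraction", 0, 1)
  check_scalar(de_weight, "de_weight", lo = 1)
  check_scalar(seed, "seed")
  if (!is.list(block_spec)) stop("'block_spec' must be a list of blocks")
  for (b in block_spec) {
    if (!all(c("size", "rho", "condition") %in% names(b))) {
      stop("each block needs 'size', 'rho' and 'condition'")
    }
    if (b$rho <= -1 || b$rho >= 1) stop("block 'rho' must lie in (-1, 1)")
    if (!b$condition %in% c("F", "S")) stop("block 'condition' must be F or S")
  }
  if (sum(vapply(block_spec, `[[`, numeric(1), "size")) > n_genes) {
    stop("block sizes exceed n_genes")
  }
  structure(list(n_genes = as.integer(n_genes),
                 n_per_group = as.integer(n_per_group),
                 de_fraction = de_fraction, lfc_values = lfc_values,
                 dispersion = dispersion,
                 base_mean_range = base_mean_range,
                 size_factor_range = size_factor_range,
                 block_spec = block_spec, n_terms = as.integer(n_terms),
                 enriched_term_fraction = enriched_term_fraction,
                 term_size_range = term_size_range, de_weight = de_weight,
                 seed = as.integer(seed)),
            class = "sim_config")
}

# internal: NB quantile map of uniforms, mu/alpha parameterisation
q_nb <- function(u, mu, alpha) {
  stats::qnbinom(u, mu = mu, size = 1 / alpha)
}

# internal: n x k matrix of equicorrelated standard normals (correlation rho)
equicorr_normals <- function(n, k, rho) {
  z <- matrix(stats::rnorm(n * k), n, k)
  if (rho == 0 || k == 1L) return(z)
  # Cholesky of the compound-symmetry matrix, valid for rho in (-1/(k-1), 1)
  sigma <- matrix(rho, k, k)
  diag(sigma) <- 1
  z %*% chol(sigma)
}

#' Simulate a two-condition NB count matrix with planted structure
#'
#' Counts are negative binomial with per-gene baseline means, per-sample
#' size factors, and a planted DE fraction whose sterile-condition mean is
#' scaled by `2^lfc`. Co-expression blocks are injected with a Gaussian
#' copula: within the block's condition, each sample draws an equicorrelated
#' latent normal vector across the block's genes, which is mapped through
#' `pnorm` to uniforms and then through the NB quantile function — so the
#' marginal count law of every gene is untouched while within-condition
#' gene-gene correlation is controlled.
#'
#' @param config A [sim_config()].
#' @return A list with elements:
#'   * `cm` — a [count_matrix()] (samples `F1..Fn`, `S1..Sn`),
#'   * `size_factors` — the true per-sample factors used,
#'   * `truth` — list with `de_genes` (named vector of true log2 fold
#'     changes), `module_assignment` (named integer block id per gene, `NA`
#'     for unblocked genes) and `enriched_terms` (filled by
#'     [simulate_annotations()]).
#' @export
simulate_counts <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  set.seed(config$seed)
  n <- config$n_genes
  npg <- config$n_per_group
  m <- 2L * npg
  genes <- sprintf("g%04d", seq_len(n))
  samples <- c(paste0("F", seq_len(npg)), paste0("S", seq_len(npg)))
  conditions <- stats::setNames(rep(c("F", "S"), each = npg), samples)

  bmr <- config$base_mean_range
  base_mu <- exp(stats::runif(n, log(bmr[1]), log(bmr[2])))
  sfr <- config$size_factor_range
  sf <- exp(stats::runif(m, log(sfr[1]), log(sfr[2])))

  n_de <- round(config$de_fraction * n)
  de_idx <- if (n_de > 0) sort(sample.int(n, n_de)) else integer(0)
  lfc <- stats::setNames(numeric(n), genes)
  if (n_de > 0) {
    lfc[de_idx] <- sample(config$lfc_values, n_de, replace = TRUE)
  }

  # expected count per gene/sample: baseline, DE scaling in S, size factor
  mu <- outer(base_mu, sf)
  s_cols <- which(conditions == "S")
  mu[de_idx, s_cols] <- mu[de_idx, s_cols, drop = FALSE] * 2^lfc[de_idx]

  # assign block genes from a single shuffled pool so blocks never overlap
  module <- stats::setNames(rep(NA_integer_, n), genes)
  blocks <- config$block_spec
  if (length(blocks) > 0) {
    pool <- sample.int(n)
    off <- 0L
    for (i in seq_along(blocks)) {
      idx <- pool[(off + 1L):(off + blocks[[i]]$size)]
      module[idx] <- i
      off <- off + blocks[[i]]$size
    }
  }

  # latent uniforms: independent by default, equicorrelated inside a block
  # within its co-expressed condition
  u <- matrix(stats::runif(n * m), n, m)
  for (i in seq_along(blocks)) {
    b <- blocks[[i]]
    gidx <- which(module == i)
    cols <- which(conditions == b$condition)
    z <- equicorr_normals(length(cols), length(gidx), b$rho)
    u[gidx, cols] <- t(stats::pnorm(z))
  }

  counts <- matrix(q_nb(u, mu, config$dispersion), n, m,
                   dimnames = list(genes, samples))
  storage.mode(counts) <- "integer"

  truth <- list(de_genes = lfc[de_idx], module_assignment = module,
                enriched_terms = character(0))
  list(cm = count_matrix(counts, conditions),
       size_factors = stats::setNames(sf, samples), truth = truth)
}

#' Simulate GMT-style gene-set annotations with planted enrichment
#'
#' Terms are assigned cyclically to the categories BP, MF, CC and pathway.
#' A planted fraction of terms samples its members with extra weight on the
#' true DE genes (so downstream Fisher tests have signal to find); all other
#' terms sample genes uniformly.
#'
#' @param genes Character vector: the gene universe.
#' @param truth Truth list from [simulate_counts()] (uses `de_genes`).
#' @param config A [sim_config()].
#' @return An [annotation_map()] whose attribute `"enriched_terms"` holds the
#'   planted term ids; callers typically copy it into `truth$enriched_terms`.
#' @export
simulate_annotations <- function(genes, truth, config) {
  stopifnot(inherits(config, "sim_config"), length(genes) > 0)
  if (config$n_terms <= 0) stop("'n_terms' must be positive")
  set.seed(config$seed + 1000L)
  n_terms <- config$n_terms
  ids <- sprintf("T%04d", seq_len(n_terms))
  categories <- stats::setNames(
    rep(c("BP", "MF", "CC", "pathway"), length.out = n_terms), ids)
  n_enriched <- round(config$enriched_term_fraction * n_terms)
  enriched <- if (n_enriched > 0) sample(ids, n_enriched) else character(0)

  w <- stats::setNames(rep(1, length(genes)), genes)
  w[names(truth$de_genes)] <- config$de_weight
  tsr <- config$term_size_range
  sets <- lapply(ids, function(id) {
    size <- sample(seq(tsr[1], tsr[2]), 1L)
    size <- min(size, length(genes))
    if (id %in% enriched && length(truth$de_genes) > 0) {
      sample(genes, size, prob = w)
    } else {
      sample(genes, size)
    }
  })
  names(sets) <- ids
  ann <- annotation_map(sets, categories)
  attr(ann, "enriched_terms") <- enriched
  ann
}

#' Simulate FASTQ reads with planted filter violations
#'
#' Generates Phred+33 reads of three planted kinds: clean reads, "high-N"
#' reads (strictly more than 5 percent ambiguous bases) and "low-quality"
#' reads (strictly more than 30 percent of bases with quality below 20).
#' Planted reads violate exactly one rule, so a correct filter discards
#' precisely the planted non-clean reads.
#'
#' @param n_reads Number of reads.
#' @param read_length Read length in bp (study platform: 101 bp); must be
#'   positive.
#' @param frac_high_n,frac_low_quality Fractions of reads planted to violate
#'   the N rule and the quality rule; must sum to at most 1.
#' @param seed Integer seed.
#' @return List with `reads` (data.frame `id`, `sequence`, `quality`) and
#'   `labels` (per-read `"clean"`, `"high_n"` or `"low_quality"`, in read
#'   order).
#' @export
simulate_fastq <- function(n_reads, read_length = 101, frac_high_n = 0,
                           frac_low_quality = 0, seed = 1) {
  check_scalar(n_reads, "n_reads", lo = 1)
  if (read_length <= 0) stop("'read_length' must be positive")
  check_scalar(frac_high_n, "frac_high_n", 0, 1)
  check_scalar(frac_low_quality, "frac_low_quality", 0, 1)
  if (frac_high_n + frac_low_quality > 1) {
    stop("planted fractions must sum to at most 1")
  }
  set.seed(seed)
  L <- as.integer(read_length)
  n_hn <- round(frac_high_n * n_reads)
  n_lq <- round(frac_low_quality * n_reads)
  labels <- sample(rep(c("high_n", "low_quality", "clean"),
                       c(n_hn, n_lq, n_reads - n_hn - n_lq)))

  qchar <- function(q) intToUtf8(q + 33L, multiple = FALSE)
  make_read <- function(label) {
    seqv <- sample(c("A", "C", "G", "T"), L, replace = TRUE)
    if (label == "high_n") {
      n_n <- floor(0.05 * L) + 1L        # strictly > 5% of bases are N
      seqv[sample.int(L, n_n)] <- "N"
      q <- sample(30:41, L, replace = TRUE)
    } else if (label == "low_quality") {
      n_low <- floor(0.30 * L) + 1L      # strictly > 30% of bases below Q20
      q <- sample(30:41, L, replace = TRUE)
      q[sample.int(L, n_low)] <- sample(2:19, n_low, replace = TRUE)
    } else {
      q <- sample(28:41, L, replace = TRUE)
    }
    c(paste(seqv, collapse = ""), qchar(q))
  }
  made <- vapply(labels, make_read, character(2))
  reads <- data.frame(id = sprintf("read_%06d", seq_len(n_reads)),
                      sequence = made[1, ], quality = made[2, ],
                      row.names = NULL)
  list(reads = reads, labels = labels)
}

#' Simulate a qPCR Ct table consistent with chosen fold changes
#'
#' Target-gene Ct values are constructed so that the expected relative
#' expression `2^-ddCt` (sterile vs fertile, reference-gene normalised)
#' equals `2^true_log2fc`; the reference gene (beta-actin in the study this
#' emulates) has constant Ct up to measurement noise. Gaussian noise of sd
#' `noise_sd` is added independently to every measured Ct.
#'
#' @param genes Character vector of target genes.
#' @param true_log2fc Numeric vector (recycled) of true log2 fold changes,
#'   sterile relative to fertile.
#' @param ct_reference Mean reference-gene Ct (cycles).
#' @param noise_sd Ct measurement noise sd (cycles); must be >= 0.
#' @param n_replicates Technical replicates per condition (study: 3).
#' @param seed Integer seed.
#' @return Data.frame with columns `gene`, `sample`, `condition`,
#'   `replicate`, `target_ct`, `reference_ct`.
#' @export
simulate_qpcr <- function(genes, true_log2fc, ct_reference = 16,
                          noise_sd = 0.2, n_replicates = 3, seed = 1) {
  stopifnot(length(genes) > 0)
  if (noise_sd < 0) stop("'noise_sd' must be non-negative")
  if (n_replicates < 1) stop("'n_replicates' must be at least 1")
  set.seed(seed)
  lfc <- rep_len(true_log2fc, length(genes))
  base_ct <- stats::runif(length(genes), 20, 28)  # fertile target Ct
  grid <- expand.grid(gene = genes, condition = c("F", "S"),
                      replicate = seq_len(n_replicates),
                      KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
  gi <- match(grid$gene, genes)
  # ddCt = dCt_S - dCt_F = -lfc  =>  Ct_S = Ct_F - lfc (reference constant)
  mu_t <- ifelse(grid$condition == "S", base_ct[gi] - lfc[gi], base_ct[gi])
  grid$target_ct <- mu_t + stats::rnorm(nrow(grid), 0, noise_sd)
  grid$reference_ct <- ct_reference + stats::rnorm(nrow(grid), 0, noise_sd)
  grid$sample <- paste0(grid$condition, "1")
  grid[, c("gene", "sample", "condition", "replicate",
           "target_ct", "reference_ct")]
}
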