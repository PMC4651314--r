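#' Median-of-ratios size factors
#'
#' Per-sample normalisation constants: each sample's factor is the median,
#' over genes with a finite log geometric mean, of that sample's count
#' divided by the gene's geometric mean across samples. Robust to a modest
#' fraction of DE genes, which is why it is the standard normalisation for
#' two-condition count data.
#'
#' @param counts A [count_matrix()] or a numeric count matrix.
#' @return Named positive numeric vector, one factor per sample.
#' @export
size_factors <- function(counts) {
  m <- if (inherits(counts, "count_matrix")) counts$counts else counts
  stopifnot(is.matrix(m), all(m >= 0))
  if (all(m == 0)) stop("size_factors(): all-zero count matrix")
  loggeo <- rowMeans(log(m))
  usable <- is.finite(loggeo)
  if (!any(usable)) {
    stop("size_factors(): no gene has all-positive counts; cannot normalise")
  }
  sf <- apply(m, 2, function(cnts) {
    exp(stats::median((log(cnts) - loggeo)[usable]))
  })
  if (any(!is.finite(sf)) || any(sf <= 0)) {
    stop("size_factors(): a sample yielded a non-positive factor")
  }
  sf
}

#' Method-of-moments NB dispersion with optional mean-dispersion trend
#'
#' The raw gene-wise estimator is the pooled within-condition variance of
#' normalised counts with the sampling (shot-noise) term removed:
#' `alpha_g = max(0, (v_g - mu_g * mean(1/s_j)) / mu_g^2)`,
#' where `v_g` pools the within-group variances and `mu_g` is the mean
#' normalised count; genes with zero mean get dispersion 0.
#'
#' With 3 replicates per group this estimator is extremely noisy, and
#' plugging it straight into the exact test makes the test anti-conservative
#' (genes whose dispersion is underestimated, many floored at 0, look
#' Poisson). The default therefore shares information across genes the way
#' NB differential-expression methods do: the unfloored gene-wise estimates
#' are regressed on `1/mu` (a parametric mean-dispersion trend,
#' `alpha(mu) = a0 + a1/mu`) and each gene receives the fitted value
#' (`method = "trend"`). `method = "max"` takes the maximum of the gene-wise
#' estimate and the trend (more conservative); `method = "gene"` returns the
#' raw gene-wise estimates.
#'
#' @param counts A [count_matrix()].
#' @param sf Size factors (defaults to [size_factors()]).
#' @param method `"trend"` (default), `"max"` or `"gene"`.
#' @return Named non-negative numeric vector of per-gene dispersions.
#' @export
estimate_dispersion <- function(counts, sf = size_factors(counts),
                                method = c("trend", "max", "gene")) {
  method <- match.arg(method)
  cm <- as_count_matrix(counts)
  grp <- condition_groups(cm)
  q <- sweep(cm$counts, 2, sf, "/")
  va <- apply(q[, grp$a, drop = FALSE], 1, stats::var)
  vb <- apply(q[, grp$b, drop = FALSE], 1, stats::var)
  na <- length(grp$a); nb <- length(grp$b)
  v <- ((na - 1) * va + (nb - 1) * vb) / (na + nb - 2)
  mu <- rowMeans(q)
  xim <- mean(1 / sf)
  raw <- ifelse(mu > 0, (v - xim * mu) / mu^2, 0)   # unfloored, can be < 0
  gene <- pmax(0, raw)
  alpha <- if (method == "gene") {
    gene
  } else {
    use <- mu > 0
    trend <- if (sum(use) >= 10) {
      fit <- stats::lm(raw[use] ~ I(1 / mu[use]))
      pred <- stats::coef(fit)[1] + stats::coef(fit)[2] / mu
      pmax(0, ifelse(mu > 0, pred, 0))
    } else {
      # too few genes to fit a trend: fall back to a common median
      rep(pmax(0, stats::median(raw[use])), length(mu))
    }
    if (method == "trend") trend else pmax(gene, trend)
  }
  stats::setNames(alpha, rownames(cm$counts))
}

# internal: NB pmf in (mu, alpha) parameterisation; Poisson limit at alpha ~ 0
d_nb <- function(x, mu, alpha) {
  if (mu <= 0) return(as.numeric(x == 0))
  if (alpha <= 1e-12) stats::dpois(x, mu) else {
    stats::dnbinom(x, mu = mu, size = 1 / alpha)
  }
}

# internal: exact conditioned two-group NB test for one gene.
# Conditions on the observed total K = kA + kB; group-pooled counts are
# modelled as NB with mean mu*S and moment-matched dispersion
# alpha * sum(s^2) / S^2 (exact for sums of iid NB at equal size factors).
# p = sum of conditional probabilities of splits no more likely than the
# observed one. Above `approx_total`, a normal approximation to the
# conditional law is used.
nb_test_gene <- function(ka, kb, mu, alpha, s_a, s_b, approx_total = 10000) {
  K <- ka + kb
  if (K == 0 || mu <= 0) return(1)
  SA <- sum(s_a); SB <- sum(s_b)
  muA <- mu * SA; muB <- mu * SB
  alphaA <- alpha * sum(s_a^2) / SA^2
  alphaB <- alpha * sum(s_b^2) / SB^2
  if (K <= approx_total) {
    a <- 0:K
    joint <- d_nb(a, muA, alphaA) * d_nb(K - a, muB, alphaB)
    tot <- sum(joint)
    if (tot <= 0) return(1)
    p_obs <- joint[ka + 1]
    min(1, sum(joint[joint <= p_obs * (1 + 1e-7)]) / tot)
  } else {
    vA <- muA + alphaA * muA^2
    vB <- muB + alphaB * muB^2
    m <- muA + (K - muA - muB) * vA / (vA + vB)
    v <- vA * vB / (vA + vB)
    min(1, 2 * stats::pnorm(-abs(ka - m) / sqrt(v)))
  }
}

#' Exact conditioned NB test for two-group differential expression
#'
#' For every gene, tests whether the split of its total count between the
#' two conditions is compatible with equal (normalised) expression. The
#' group-pooled counts are modelled as negative binomial with mean
#' `mu * S_group` (`S_group` = sum of the group's size factors) and
#' moment-matched dispersion; conditioning on the observed total, the
#' two-sided p-value sums the probabilities of all splits no more probable
#' than the observed one. Totals above `approx_total` switch to a normal
#' approximation of the conditional law.
#'
#' @param counts A [count_matrix()].
#' @param sf Size factors.
#' @param dispersions Per-gene NB dispersions.
#' @param approx_total Total count above which the normal approximation is
#'   used (default 10000).
#' @return Named numeric vector of two-sided p-values.
#' @export
nb_test <- function(counts, sf = size_factors(counts),
                    dispersions = estimate_dispersion(counts, sf),
                    approx_total = 10000) {
  cm <- as_count_matrix(counts)
  grp <- condition_groups(cm)
  q <- sweep(cm$counts, 2, sf, "/")
  mu <- rowMeans(q)
  ka <- rowSums(cm$counts[, grp$a, drop = FALSE])
  kb <- rowSums(cm$counts[, grp$b, drop = FALSE])
  p <- vapply(seq_len(nrow(cm$counts)), function(g) {
    nb_test_gene(ka[g], kb[g], mu[g], dispersions[g],
                 sf[grp$a], sf[grp$b], approx_total)
  }, numeric(1))
  stats::setNames(p, rownames(cm$counts))
}

#' Benjamini-Hochberg adjusted p-values
#'
#' Step-up FDR adjustment (delegates to [stats::p.adjust()]).
#'
#' @param p Numeric vector of p-values in `[0, 1]`.
#' @return q-values, same length and order as `p`.
#' @export
bh_fdr <- function(p) {
  if (!is.numeric(p) || any(is.na(p)) || any(p < 0 | p > 1)) {
    stop("bh_fdr(): p-values must lie in [0, 1]")
  }
  stats::p.adjust(p, method = "BH")
}

#' Run the full differential-expression stage
#'
#' Size factors, dispersions, exact NB test, BH FDR, and fold change
#' (sterile over fertile, with a 0.5 pseudocount on the normalised means so
#' zero-expressed genes stay finite). `direction` is `"up"` when the gene is
#' higher in the sterile-style (non-reference) condition with
#' `fold_change > fc_hi` and `q < max_fdr`, `"down"` for `fold_change <
#' fc_lo` and `q < max_fdr`, else `"ns"`.
#'
#' @param counts A [count_matrix()] (reference condition `"F"` first).
#' @param fc_hi,fc_lo Strict fold-change cutoffs (defaults 2 and 0.5).
#' @param max_fdr FDR cutoff (default 0.05).
#' @param approx_total Passed to [nb_test()].
#' @return Data.frame of class `de_result` with columns `gene`, `mean_f`,
#'   `mean_s`, `fold_change`, `log2fc`, `p_value`, `q_value`, `direction`.
#' @export
run_de <- function(counts, fc_hi = 2, fc_lo = 0.5, max_fdr = 0.05,
                   approx_total = 10000) {
  cm <- as_count_matrix(counts)
  grp <- condition_groups(cm)
  sf <- size_factors(cm)
  disp <- estimate_dispersion(cm, sf)
  p <- nb_test(cm, sf, disp, approx_total)
  q <- sweep(cm$counts, 2, sf, "/")
  mean_f <- rowMeans(q[, grp$a, drop = FALSE])
  mean_s <- rowMeans(q[, grp$b, drop = FALSE])
  fc <- (mean_s + 0.5) / (mean_f + 0.5)
  qv <- bh_fdr(p)
  direction <- ifelse(qv < max_fdr & fc > fc_hi, "up",
                      ifelse(qv < max_fdr & fc < fc_lo, "down", "ns"))
  res <- data.frame(gene = rownames(cm$counts), mean_f = mean_f,
                    mean_s = mean_s, fold_change = fc, log2fc = log2(fc),
                    p_value = unname(p), q_value = qv, direction = direction,
                    row.names = NULL)
  class(res) <- c("de_result", "data.frame")
  res
}

#' Select differentially expressed genes
#'
#' The study's selection rule: fold change strictly above `fc_hi` or
#' strictly below `fc_lo`, and FDR `q` strictly below `max_fdr`.
#'
#' @param results A `de_result` data.frame from [run_de()].
#' @param fc_hi,fc_lo,max_fdr Cutoffs (defaults 2, 0.5, 0.05).
#' @return List with `table` (the selected rows, direction relabelled under
#'   these cutoffs), `n_up`, `n_down` and `n_total`.
#' @export
filter_de <- function(results, fc_hi = 2, fc_lo = 0.5, max_fdr = 0.05) {
  stopifnot(is.data.frame(results),
            all(c("gene", "fold_change", "q_value") %in% names(results)))
  up <- results$fold_change > fc_hi & results$q_value < max_fdr
  down <- results$fold_change < fc_lo & results$q_value < max_fdr
  tab <- results[up | down, , drop = FALSE]
  tab$direction <- ifelse(tab$fold_change > fc_hi, "up", "down")
  list(table = tab, n_up = sum(up), n_down = sum(down),
       n_total = sum(up) + sum(down))
}

#' Up/down/total accounting of a DE gene list
#'
#' @param direction Character vector of `"up"`/`"down"` labels.
#' @return List with `n_up`, `n_down`, `n_total` (their sum).
#' @export
#' @examples
#' de_counts(rep(c("up", "down"), c(492, 733)))$n_total # 1225
de_counts <- function(direction) {
  if (!all(direction %in% c("up", "down"))) {
    stop("de_counts(): direction labels must be 'up' or 'down'")
  }
  n_up <- sum(direction == "up")
  n_down <- sum(direction == "down")
  list(n_up = n_up, n_down = n_down, n_total = n_up + n_down)
}
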