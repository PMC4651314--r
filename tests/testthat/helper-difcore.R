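# shared fixtures and independent oracles, built in code at test time

# small two-condition count matrix (3 + 3), NB counts
tiny_cm <- function(n_genes = 50, mu = 150, size = 10, seed = 42) {
  set.seed(seed)
  m <- matrix(rnbinom(n_genes * 6, mu = mu, size = size), n_genes, 6,
              dimnames = list(sprintf("g%03d", seq_len(n_genes)),
                              c("F1", "F2", "F3", "S1", "S2", "S3")))
  count_matrix(m, setNames(rep(c("F", "S"), each = 3), colnames(m)))
}

# build a condition_graph from a two-column edge matrix / data.frame
graph_from_edges <- function(edges, nodes = NULL, condition = "S") {
  edges <- as.data.frame(edges)
  names(edges)[1:2] <- c("gene_a", "gene_b")
  edges$gene_a <- as.character(edges$gene_a)
  edges$gene_b <- as.character(edges$gene_b)
  nodes <- nodes %||% sort(unique(c(edges$gene_a, edges$gene_b)))
  condition_graph(condition, as.character(nodes), edges)
}
`%||%` <- function(a, b) if (is.null(a)) b else a

# Erdos-Renyi G(n, p) as an edge data.frame, deterministic under seed
random_edges <- function(n, p, seed) {
  set.seed(seed)
  pairs <- t(combn(n, 2))
  keep <- runif(nrow(pairs)) < p
  data.frame(gene_a = as.character(pairs[keep, 1]),
             gene_b = as.character(pairs[keep, 2]))
}

# brute-force k-core oracle: a node's core number is the largest k at which
# it survives iterative deletion of all nodes with degree < k
peel_oracle <- function(edges, nodes) {
  deg_of <- function(active) {
    d <- setNames(integer(length(nodes)), nodes)
    keep <- edges$gene_a %in% active & edges$gene_b %in% active
    tab <- table(c(edges$gene_a[keep], edges$gene_b[keep]))
    d[names(tab)] <- as.integer(tab)
    d[active]
  }
  core <- setNames(integer(length(nodes)), nodes)
  k <- 1L
  repeat {
    active <- nodes
    repeat {
      d <- deg_of(active)
      drop <- names(d)[d < k]
      if (length(drop) == 0) break
      active <- setdiff(active, drop)
    }
    if (length(active) == 0) break
    core[active] <- k
    k <- k + 1L
  }
  core
}

# direct enumeration oracle for the conditioned two-group NB test,
# written independently of the package internals
nb_enum_oracle <- function(ka, kb, mu, alpha, s_a, s_b) {
  dens <- function(x, m, a) {
    if (a <= 1e-12) dpois(x, m) else dnbinom(x, mu = m, size = 1 / a)
  }
  SA <- sum(s_a); SB <- sum(s_b)
  aA <- alpha * sum(s_a^2) / SA^2
  aB <- alpha * sum(s_b^2) / SB^2
  K <- ka + kb
  a <- 0:K
  joint <- dens(a, mu * SA, aA) * dens(K - a, mu * SB, aB)
  pobs <- joint[ka + 1]
  sum(joint[joint <= pobs * (1 + 1e-7)]) / sum(joint)
}

# hypergeometric upper-tail oracle by direct PMF summation
hyper_tail_oracle <- function(k, K, n, N) {
  x <- k:min(K, n)
  sum(choose(K, x) * choose(N - K, n - x)) / choose(N, n)
}
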