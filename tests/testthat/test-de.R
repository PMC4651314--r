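test_that("size factors follow the median-of-ratios definition", {
  # identical samples -> equal factors
  m <- matrix(rep(c(5L, 9L, 40L), 4), 3, 4,
              dimnames = list(paste0("g", 1:3), paste0("s", 1:4)))
  expect_true(all(size_factors(m) == size_factors(m)[1]))
  # doubling a sample doubles its factor
  m2 <- m
  m2[, 2] <- m[, 2] * 2L
  sf <- size_factors(m2)
  expect_equal(sf[[2]] / sf[[1]], 2)
  # hand-computable grid: counts (g+1)*j -> factors proportional to j
  grid <- outer(2:6, 1:4)
  dimnames(grid) <- list(paste0("g", 1:5), paste0("s", 1:4))
  sfg <- size_factors(grid)
  expect_equal(unname(sfg / sfg[1]), c(1, 2, 3, 4))
  expect_error(size_factors(matrix(0, 2, 2,
                                   dimnames = list(c("a", "b"),
                                                   c("x", "y")))),
               "all-zero")
})

test_that("gene-wise dispersion recovers the simulated truth", {
  set.seed(1)
  dn <- list(sprintf("g%05d", 1:10000), c("F1", "F2", "F3", "S1", "S2", "S3"))
  cond <- setNames(rep(c("F", "S"), each = 3), dn[[2]])
  # Poisson data: median estimate near 0
  pois <- count_matrix(matrix(rpois(60000, 100), 10000, 6, dimnames = dn),
                       cond)
  expect_lte(median(estimate_dispersion(pois, method = "gene")), 0.01)
  # NB with alpha = 0.2 at mu = 200
  set.seed(2)
  nb <- count_matrix(matrix(rnbinom(60000, mu = 200, size = 5), 10000, 6,
                            dimnames = dn), cond)
  med <- median(estimate_dispersion(nb, method = "gene"))
  expect_gte(med, 0.1)
  expect_lte(med, 0.3)
  # the trend fit centres on the true value
  trend <- estimate_dispersion(nb, method = "trend")
  expect_lt(abs(median(trend) - 0.2), 0.05)
  # constant gene -> zero gene-wise dispersion
  const <- count_matrix(matrix(7L, 2, 6, dimnames = list(c("a", "b"),
                                                         dn[[2]])), cond)
  expect_equal(unname(estimate_dispersion(const, method = "gene")), c(0, 0))
})

test_that("the exact NB test matches direct enumeration for small totals", {
  # the documented worked case: factors 1, alpha 0, group sums 2 vs 30
  m <- matrix(c(1L, 1L, 0L, 10L, 10L, 10L), 1,
              dimnames = list("g1", c("F1", "F2", "F3", "S1", "S2", "S3")))
  cm <- count_matrix(m, setNames(rep(c("F", "S"), each = 3), colnames(m)))
  ones <- setNames(rep(1, 6), colnames(m))
  p <- nb_test(cm, ones, setNames(0, "g1"))
  # with equal Poisson groups the conditional law is Binomial(32, 1/2)
  probs <- dbinom(0:32, 32, 0.5)
  expect_equal(unname(p), sum(probs[probs <= dbinom(2, 32, 0.5) * (1 + 1e-7)]),
               tolerance = 1e-12)

  # randomised parameterisations, totals <= 50, against the enumeration
  # oracle written in the helper
  set.seed(13)
  for (i in 1:25) {
    ka <- sample(0:25, 1)
    kb <- sample(0:25, 1)
    mu <- runif(1, 0.5, 8)
    alpha <- sample(c(0, runif(1, 0.01, 0.5)), 1)
    s <- runif(6, 0.5, 2)
    p_impl <- difcore:::nb_test_gene(ka, kb, mu, alpha, s[1:3], s[4:6])
    p_oracle <- nb_enum_oracle(ka, kb, mu, alpha, s[1:3], s[4:6])
    expect_lt(abs(p_impl - p_oracle), 1e-9)
  }
})

test_that("null symmetry, label swap and scaling behave as expected", {
  cm <- tiny_cm(seed = 42)
  # identical group profiles -> p = 1 (observed split is the modal one)
  eq <- matrix(rep(c(500L, 480L, 510L), 2), 1,
               dimnames = list("g1", colnames(cm$counts)))
  cme <- count_matrix(eq, cm$conditions)
  ones <- setNames(rep(1, 6), colnames(eq))
  expect_gte(unname(nb_test(cme, ones, setNames(0.05, "g1"))), 0.5)

  de_fs <- run_de(cm)
  swapped <- count_matrix(cm$counts,
                          setNames(ifelse(cm$conditions == "F", "S", "F"),
                                   names(cm$conditions)))
  de_sf <- run_de(swapped)
  expect_equal(de_fs$p_value, de_sf$p_value)
  expect_equal(de_fs$fold_change * de_sf$fold_change,
               rep(1, nrow(de_fs)))

  # scaling one sample's counts and factor by c leaves every normalised
  # quantity (hence fold changes) unchanged ...
  sf <- size_factors(cm)
  scaled <- cm$counts
  scaled[, 2] <- scaled[, 2] * 3L
  sf2 <- sf
  sf2[2] <- sf[2] * 3
  expect_equal(sweep(cm$counts, 2, sf, "/"),
               sweep(scaled, 2, sf2, "/"))
  # ... and rescaling the whole library leaves p-values nearly unchanged
  disp <- estimate_dispersion(cm, sf)
  p1 <- nb_test(cm, sf, disp)
  cm_all <- count_matrix(cm$counts * 2L, cm$conditions)
  p2 <- nb_test(cm_all, sf * 2, disp)
  expect_lt(max(abs(p1 - p2)), 0.02)
})

test_that("BH adjustment is correct and monotone", {
  expect_equal(bh_fdr(c(0.01, 0.02, 0.03)), c(0.03, 0.03, 0.03))
  expect_equal(bh_fdr(0.2), 0.2)
  set.seed(5)
  p <- runif(200)^2
  q <- bh_fdr(p)
  o <- order(p)
  expect_true(all(diff(q[o]) >= -1e-15))
  expect_true(all(q >= p))
  # oracle: the step-up formula written out directly
  n <- length(p)
  q_direct <- rev(cummin(rev(p[o] * n / seq_len(n))))[order(o)]
  expect_equal(q, pmin(1, q_direct))
  expect_error(bh_fdr(c(0.5, 1.2)), "\\[0, 1\\]")
})

test_that("DE selection uses strict cutoffs and partitions correctly", {
  res <- data.frame(gene = c("a", "b", "c", "d"),
                    fold_change = c(2.0, 2.01, 0.5, 0.49),
                    q_value = c(0.01, 0.01, 0.01, 0.01))
  sel <- filter_de(res)
  expect_setequal(sel$table$gene, c("b", "d"))   # FC exactly 2 or 0.5 excluded
  expect_equal(sel$n_up + sel$n_down, sel$n_total)
  counts <- de_counts(rep(c("up", "down"), c(3, 4)))
  expect_equal(counts$n_total, 7)
})

test_that("planted DE genes are recovered with controlled false discoveries", {
  cfg <- sim_config(n_genes = 2000, de_fraction = 0.1, lfc_values = c(-2, 2),
                    dispersion = 0.1, seed = 5)
  s <- simulate_counts(cfg)
  sel <- filter_de(run_de(s$cm))
  planted <- names(s$truth$de_genes)
  expect_gte(mean(planted %in% sel$table$gene), 0.80)
  expect_lte(mean(!(sel$table$gene %in% planted)), 0.10)
  expect_equal(sel$n_up + sel$n_down, sel$n_total)
})
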