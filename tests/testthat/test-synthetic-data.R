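test_that("count simulation is deterministic and validates its config", {
  cfg <- sim_config(n_genes = 100, seed = 3)
  a <- simulate_counts(cfg)
  b <- simulate_counts(cfg)
  expect_identical(a$cm$counts, b$cm$counts)
  expect_identical(a$truth, b$truth)

  expect_error(sim_config(dispersion = 0), "dispersion")
  expect_error(sim_config(block_spec = list(list(size = 5, rho = 1,
                                                 condition = "S"))), "rho")
  expect_error(sim_config(n_genes = 10,
                          block_spec = list(list(size = 11, rho = 0.5,
                                                 condition = "S"))),
               "exceed")
})

test_that("truth table matches the planted DE fraction and genes exist", {
  cfg <- sim_config(n_genes = 500, de_fraction = 0.13, seed = 9)
  s <- simulate_counts(cfg)
  expect_length(s$truth$de_genes, round(0.13 * 500))
  expect_true(all(names(s$truth$de_genes) %in% rownames(s$cm$counts)))
})

test_that("without planted DE the group means are balanced", {
  cfg <- sim_config(n_genes = 10000, de_fraction = 0, seed = 1)
  s <- simulate_counts(cfg)
  expect_length(s$truth$de_genes, 0)
  q <- sweep(s$cm$counts, 2, size_factors(s$cm), "/")
  grp <- split(colnames(q), s$cm$conditions)
  ratio <- rowMeans(q[, grp$S]) / pmax(rowMeans(q[, grp$F]), 1e-9)
  expect_lt(abs(median(ratio) - 1), 0.05)
})

test_that("NB marginal law and copula margin preservation hold", {
  # marginal: at mu = 100, alpha = 0.1 the variance is mu + alpha*mu^2 = 1100
  set.seed(1)
  draws <- qnbinom(runif(10000), mu = 100, size = 10)
  expect_lt(abs(var(draws) / 1100 - 1), 0.10)

  # copula: per-gene means unaffected by block membership. Within-block
  # correlation slows the averaging over block genes, so enough samples are
  # drawn that the block-mean sampling sd is well below the 5% tolerance.
  blk <- list(list(size = 50, rho = 0.9, condition = "S"))
  cfg <- sim_config(n_genes = 400, n_per_group = 250, de_fraction = 0,
                    dispersion = 0.1, base_mean_range = c(100, 100),
                    size_factor_range = c(1, 1), block_spec = blk, seed = 2)
  s <- simulate_counts(cfg)
  in_block <- !is.na(s$truth$module_assignment)
  mean_in <- mean(s$cm$counts[in_block, s$cm$conditions == "S"])
  mean_out <- mean(s$cm$counts[!in_block, s$cm$conditions == "S"])
  expect_lt(abs(mean_in / mean_out - 1), 0.05)
})

test_that("a planted block is co-expressed only in its condition", {
  blk <- list(list(size = 10, rho = 0.95, condition = "S"))
  cfg <- sim_config(n_genes = 200, block_spec = blk, seed = 1)
  s <- simulate_counts(cfg)
  expr <- normalize_expression(s$cm)
  genes_blk <- names(which(s$truth$module_assignment == 1))
  r_s <- cor(t(expr[, s$cm$conditions == "S"]))
  within <- r_s[genes_blk, genes_blk][upper.tri(diag(length(genes_blk)))]
  others <- setdiff(rownames(expr), genes_blk)
  between <- r_s[genes_blk, others]
  expect_gt(mean(within) - mean(between), 0.5)
})

test_that("annotation generation plants detectable enrichment", {
  cfg <- sim_config(n_genes = 2000, de_fraction = 0.05, n_terms = 50,
                    enriched_term_fraction = 0.02, seed = 1)
  s <- simulate_counts(cfg)
  ann <- simulate_annotations(rownames(s$cm$counts), s$truth, cfg)
  expect_true(all(lengths(ann$sets) >= 1))
  planted <- attr(ann, "enriched_terms")
  expect_length(planted, 1)
  expect_true(all(planted %in% names(ann$sets)))

  # a term of 20 genes with 15 DE members out of a DE set of 100 in 2000 is
  # essentially impossible by chance
  expect_lt(hyper_tail_oracle(15, 20, 100, 2000), 1e-10)
  n_de_in_planted <- length(intersect(ann$sets[[planted]],
                                      names(s$truth$de_genes)))
  expect_gt(n_de_in_planted, length(ann$sets[[planted]]) * 0.05 * 2)
})

test_that("FASTQ simulation plants exactly the requested violations", {
  fq <- simulate_fastq(200, 100, frac_high_n = 0.1, frac_low_quality = 0.2,
                       seed = 7)
  expect_equal(sum(fq$labels == "high_n"), 20)
  expect_equal(sum(fq$labels == "low_quality"), 40)
  # brute-force per-read rule check against the planted labels
  nfrac <- vapply(strsplit(fq$reads$sequence, ""),
                  function(s) mean(s %in% c("N", "n")), numeric(1))
  lowq <- vapply(fq$reads$quality,
                 function(q) mean(utf8ToInt(q) - 33L < 20), numeric(1),
                 USE.NAMES = FALSE)
  expect_identical(nfrac > 0.05, fq$labels == "high_n")
  expect_identical(lowq > 0.30, fq$labels == "low_quality")
  # Phred+33 encoding contract
  scores <- utf8ToInt(paste(fq$reads$quality, collapse = "")) - 33L
  expect_true(all(scores >= 0 & scores <= 41))
  # degenerate configs
  clean <- simulate_fastq(50, 80, 0, 0, seed = 1)
  expect_true(all(clean$labels == "clean"))
  expect_error(simulate_fastq(10, 0), "read_length")
  expect_error(simulate_fastq(10, 50, 0.7, 0.7), "sum")
})

test_that("qPCR simulation reproduces the planted fold changes", {
  # noiseless: recovered values are exact closed forms
  ct0 <- simulate_qpcr(c("a", "b"), c(0, -2), noise_sd = 0, seed = 5)
  rec0 <- delta_delta_ct(ct0)
  expect_equal(rec0$delta_delta_ct[rec0$gene == "a"], 0)
  expect_equal(rec0$fold[rec0$gene == "b"], 0.25)
  # with noise: regression slope of recovered vs true log2fc near 1
  set.seed(99)
  lfc <- runif(50, -3, 3)
  genes <- sprintf("q%02d", 1:50)
  rec <- delta_delta_ct(simulate_qpcr(genes, lfc, noise_sd = 0.2, seed = 3))
  slope <- coef(lm(rec$log2fc ~ lfc[match(rec$gene, genes)]))[2]
  expect_gt(slope, 0.9)
  expect_lt(slope, 1.1)
  expect_error(simulate_qpcr("a", 1, noise_sd = -1), "noise_sd")
})
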