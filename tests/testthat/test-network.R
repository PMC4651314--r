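test_that("degree and core numbers are correct on canonical graphs", {
  tri <- graph_from_edges(data.frame(gene_a = c("a", "b", "c"),
                                     gene_b = c("b", "c", "a")))
  expect_true(all(graph_degree(tri) == 2))
  expect_true(all(graph_kcore(tri) == 2))
  star <- graph_from_edges(data.frame(gene_a = "hub",
                                      gene_b = c("l1", "l2", "l3")))
  deg <- graph_degree(star)
  expect_equal(unname(deg["hub"]), 3)
  expect_true(all(deg[c("l1", "l2", "l3")] == 1))
  expect_true(all(graph_kcore(star) == 1))  # peeling leaves removes the hub
  # isolated node
  iso <- graph_from_edges(data.frame(gene_a = "a", gene_b = "b"),
                          nodes = c("a", "b", "z"))
  expect_equal(unname(graph_degree(iso)["z"]), 0)
  expect_equal(unname(graph_kcore(iso)["z"]), 0)
})

test_that("degrees equal adjacency row sums on a random graph", {
  ed <- random_edges(30, 0.2, seed = 4)
  g <- graph_from_edges(ed, nodes = as.character(1:30))
  adj <- matrix(0L, 30, 30, dimnames = list(as.character(1:30),
                                            as.character(1:30)))
  for (i in seq_len(nrow(ed))) {
    adj[ed$gene_a[i], ed$gene_b[i]] <- 1L
    adj[ed$gene_b[i], ed$gene_a[i]] <- 1L
  }
  expect_equal(graph_degree(g), rowSums(adj))
})

test_that("bucket k-core equals brute-force peeling on 100 random graphs", {
  for (i in 1:100) {
    set.seed(i)
    n <- sample(4:50, 1)
    p <- runif(1, 0.05, 0.4)
    ed <- random_edges(n, p, seed = i + 1000)
    nodes <- as.character(seq_len(n))
    g <- graph_from_edges(ed, nodes = nodes)
    expect_identical(graph_kcore(g), peel_oracle(g$edges, nodes))
  }
})

test_that("core numbers are bounded by degree and edge-monotone", {
  ed <- random_edges(25, 0.15, seed = 7)
  nodes <- as.character(1:25)
  g <- graph_from_edges(ed, nodes = nodes)
  expect_true(all(graph_kcore(g) <= graph_degree(g)))
  # adding an edge never decreases any core number
  core0 <- graph_kcore(g)
  set.seed(99)
  for (i in 1:100) {
    pair <- sample(nodes, 2)
    key <- paste(pmin(g$edges$gene_a, g$edges$gene_b),
                 pmax(g$edges$gene_a, g$edges$gene_b))
    if (paste(min(pair), max(pair)) %in% key) next
    g2 <- condition_graph("S", nodes,
                          rbind(g$edges,
                                data.frame(gene_a = pair[1],
                                           gene_b = pair[2])))
    expect_true(all(graph_kcore(g2) >= core0))
  }
})

test_that("bucket k-core agrees with igraph's coreness", {
  skip_if_not_installed("igraph")
  for (i in 1:20) {
    set.seed(i)
    n <- sample(5:40, 1)
    ig <- igraph::sample_gnp(n, 0.2)
    el <- igraph::as_edgelist(ig)
    g <- graph_from_edges(data.frame(gene_a = as.character(el[, 1]),
                                     gene_b = as.character(el[, 2])),
                          nodes = as.character(seq_len(n)))
    expect_equal(unname(graph_kcore(g)[as.character(seq_len(n))]),
                 unname(igraph::coreness(ig)))
  }
})

test_that("dif-k-core ranking follows its definition and tie-breaks", {
  f <- data.frame(gene = c("a", "b", "c"), degree = c(5, 1, 2),
                  kcore = c(4, 1, 2))
  s <- data.frame(gene = c("a", "b", "d"), degree = c(1, 6, 3),
                  kcore = c(1, 5, 3))
  tab <- dif_kcore(f, s, c(a = "down", b = "up", c = "ns", d = "up"))
  expect_equal(tab$dif_kcore, tab$kcore_f - tab$kcore_s)
  # gene absent from a graph is scored (0, 0) there
  expect_equal(tab[tab$gene == "d", "kcore_f"], 0)
  expect_equal(tab[tab$gene == "c", "kcore_s"], 0)
  # ascending dif order
  expect_true(all(diff(tab$dif_kcore) >= 0))
  # equal core numbers -> dif 0
  same <- dif_kcore(f, f)
  expect_true(all(same$dif_kcore == 0))
  # ties broken by descending sterile degree then gene id
  f2 <- data.frame(gene = c("x", "y"), degree = c(1, 1), kcore = c(1, 1))
  s2 <- data.frame(gene = c("x", "y"), degree = c(9, 2), kcore = c(3, 3))
  expect_equal(dif_kcore(f2, s2)$gene, c("x", "y"))
  expect_error(dif_kcore(rbind(f, f[1, ]), s), "duplicate")
})

test_that("the published 18-gene hub table obeys the dif-k-core identity", {
  hub <- published_hub_genes()
  expect_equal(nrow(hub), 18)
  recomputed <- dif_kcore(
    data.frame(gene = hub$gene, degree = hub$degree_f, kcore = hub$kcore_f),
    data.frame(gene = hub$gene, degree = hub$degree_s, kcore = hub$kcore_s))
  m <- merge(hub, recomputed[, c("gene", "dif_kcore")], by = "gene")
  consistent <- m$gene != "CXCR3"
  expect_equal(m$dif_kcore[consistent], m$dif_kcore_printed[consistent])
  # the CXCR3 row is the table's single known printing inconsistency: its
  # printed value matches its degree difference, not its k-core difference
  cx <- m[m$gene == "CXCR3", ]
  expect_equal(cx$dif_kcore, cx$kcore_f - cx$kcore_s)   # -1
  expect_equal(cx$dif_kcore_printed, cx$degree_f - cx$degree_s)  # -5
  # core number never exceeds degree in either condition
  expect_true(all(hub$kcore_f <= pmax(hub$degree_f, 0)))
  expect_true(all(hub$kcore_s <= hub$degree_s))
})

test_that("a block co-expressed in the sterile condition raises its cores", {
  blk <- list(list(size = 10, rho = 0.95, condition = "S"))
  cfg <- sim_config(n_genes = 100, n_per_group = 10, de_fraction = 0,
                    block_spec = blk, seed = 1)
  s <- simulate_counts(cfg)
  expr <- normalize_expression(s$cm)
  graphs <- lapply(c("F", "S"), function(cond) {
    cols <- names(s$cm$conditions)[s$cm$conditions == cond]
    build_network(pairwise_correlation(expr[, cols]), cond, "abs_r", 0.9)
  })
  tab <- dif_kcore(graphs[[1]], graphs[[2]])
  genes_blk <- names(which(s$truth$module_assignment == 1))
  in_blk <- tab[tab$gene %in% genes_blk, ]
  expect_true(all(in_blk$kcore_s > in_blk$kcore_f))
})
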