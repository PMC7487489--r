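test_that("shortest path lengths come from BFS on the directed graph", {
  net <- toy_network()
  # direct target edge
  expect_equal(shortest_path_length(net, "mir-5", "Gene1"), 1L)
  # the worked two-hop example: mir-5 -> Gene1 -> Gene*
  expect_equal(shortest_path_length(net, "mir-5", "Gene*"), 2L)
  expect_error(shortest_path_length(net, "nope", "Gene*"), "unknown node")
})

test_that("unreachable pairs are signalled distinctly, never 0 or Inf", {
  ge <- edge_df("A", "B", 1L)
  te <- edge_df("m1", "A", -1L, kind = "mirna_gene")
  cf <- data.frame(gene_id = c("B", "Z"),
                   fate_class = c("proliferation", "apoptosis"),
                   stringsAsFactors = FALSE)
  net <- make_migrn(ge, te, cf)
  expect_identical(shortest_path_length(net, "m1", "Z"), NA_integer_)
  expect_error(pair_sign(net, "m1", "Z"), "unreachable")
  expect_null(pair_impact(net, "m1", "Z", log2fc = 1))
})

test_that("path sign is the product of edge signs", {
  net <- toy_network()
  # worked example: (-1) x (+1) = -1
  expect_equal(path_sign(net, c("mir-5", "Gene1", "Gene*")), -1L)
  # double inhibition gives +1
  ge <- edge_df(c("A", "B"), c("B", "C"), c(-1L, -1L))
  cf <- data.frame(gene_id = "C", fate_class = "apoptosis",
                   stringsAsFactors = FALSE)
  net2 <- make_migrn(ge, edge_df(character(), character(), integer(),
                                 kind = character()), cf)
  expect_equal(path_sign(net2, c("A", "B", "C")), 1L)
  expect_error(path_sign(net2, c("A", "C")), "not a path")
})

test_that("path sign equals inhibition-count parity on random chains", {
  set.seed(13)
  for (rep in 1:20) {
    len <- sample(2:8, 1)
    nodes <- sprintf("n%d", seq_len(len + 1))
    signs <- sample(c(-1L, 1L), len, replace = TRUE)
    ge <- edge_df(nodes[-(len + 1)], nodes[-1], signs)
    cf <- data.frame(gene_id = nodes[len + 1],
                     fate_class = "proliferation",
                     stringsAsFactors = FALSE)
    net <- make_migrn(ge, edge_df(character(), character(), integer(),
                                  kind = character()), cf)
    expect_equal(path_sign(net, nodes), (-1L)^sum(signs == -1L))
  }
})

test_that("pair sign policies resolve multiple shortest paths as documented", {
  # unique path: every policy agrees with the worked example
  net <- toy_network()
  for (pol in c("majority", "lexicographic", "all_paths_mean"))
    expect_equal(pair_sign(net, "mir-5", "Gene*", pol), -1L)

  # two equal-length paths of opposite sign: tie
  ge <- edge_df(c("A", "B"), c("C", "C"), c(1L, -1L))
  te <- edge_df(c("m", "m"), c("A", "B"), c(-1L, -1L),
                kind = rep("mirna_gene", 2))
  cf <- data.frame(gene_id = "C", fate_class = "proliferation",
                   stringsAsFactors = FALSE)
  net2 <- make_migrn(ge, te, cf)
  expect_equal(pair_sign(net2, "m", "C", "majority"), 0L)
  expect_equal(pair_sign(net2, "m", "C", "all_paths_mean"), 0L)
  # lexicographic picks m -> A -> C (sign -1 * +1 = -1)
  expect_equal(pair_sign(net2, "m", "C", "lexicographic"), -1L)
})

test_that("pair impacts evaluate S * log2FC / L", {
  net <- toy_network()
  # L = 2, S = -1, log2FC = 2.25 (a strongly up-regulated miRNA)
  pi <- pair_impact(net, "mir-5", "Gene*", log2fc = 2.25)
  expect_equal(pi$L, 2L)
  expect_equal(pi$S, -1L)
  expect_equal(pi$I, -1.125)
  # zero fold change nullifies the impact whatever the topology
  expect_equal(pair_impact(net, "mir-5", "Gene*", log2fc = 0)$I, 0)
  # doubling L halves |I|
  direct <- pair_impact(net, "mir-5", "Gene1", log2fc = 2.25)
  expect_equal(abs(direct$I) / abs(pi$I), 2)
  # invariant |I| <= |log2fc|
  expect_lte(abs(pi$I), 2.25)
})

test_that("impacts match the exhaustive path-enumeration oracle on small graphs", {
  set.seed(101)
  for (rep in 1:30) {
    rg <- random_signed_graph(sample(6:10, 1), sample(1:3, 1),
                              density = 0.25)
    net <- make_migrn(rg$gene_edges, rg$target_edges, rg$cell_fate)
    all_edges <- rbind(rg$gene_edges, rg$target_edges)
    for (pol in c("majority", "lexicographic", "all_paths_mean")) {
      de <- data.frame(feature_id = rg$mirnas,
                       log2fc = rnorm(length(rg$mirnas)),
                       stringsAsFactors = FALSE)
      pairs <- pair_impacts(net, de, pol)
      # every reachable (miRNA, sink) pair must appear exactly once
      for (m in rg$mirnas) {
        for (g in rg$cell_fate$gene_id) {
          o <- oracle_shortest_paths(all_edges, m, g)
          row <- pairs[pairs$mirna == m & pairs$gene == g, ]
          if (is.null(o)) {
            expect_equal(nrow(row), 0)
          } else {
            expect_equal(nrow(row), 1)
            expect_equal(row$L, o$L)
            expect_equal(row$S, oracle_resolve_sign(o$signs, pol))
            lfc <- de$log2fc[de$feature_id == m]
            expect_equal(row$I, row$S * lfc / row$L, tolerance = 1e-12)
          }
        }
      }
    }
  }
})

test_that("per-gene and per-miRNA totals regroup the pair table", {
  set.seed(57)
  rg <- random_signed_graph(12, 4, density = 0.2)
  net <- make_migrn(rg$gene_edges, rg$target_edges, rg$cell_fate)
  de <- data.frame(feature_id = rg$mirnas, log2fc = rnorm(4),
                   stringsAsFactors = FALSE)
  pairs <- pair_impacts(net, de)
  for (g in rg$cell_fate$gene_id) {
    manual <- 0
    for (r in seq_len(nrow(pairs)))
      if (pairs$gene[r] == g) manual <- manual + pairs$I[r]
    expect_equal(as.numeric(gene_impact(pairs, g)), manual)
  }
  for (m in rg$mirnas) {
    manual <- 0
    for (r in seq_len(nrow(pairs)))
      if (pairs$mirna[r] == m) manual <- manual + pairs$I[r]
    expect_equal(as.numeric(mirna_impact(pairs, m)), manual)
  }
  # flags for empty sums
  expect_true(attr(gene_impact(pairs, "not-a-gene"), "no_upstream"))
  expect_true(attr(mirna_impact(pairs, "not-a-mirna"), "no_downstream"))
})

test_that("impact totals are conserved between the gene and miRNA views", {
  set.seed(63)
  for (rep in 1:5) {
    rg <- random_signed_graph(15, 5, density = 0.2)
    net <- make_migrn(rg$gene_edges, rg$target_edges, rg$cell_fate)
    de <- data.frame(feature_id = rg$mirnas, log2fc = rnorm(5, 0, 2),
                     stringsAsFactors = FALSE)
    pairs <- pair_impacts(net, de)
    summ <- impact_summary(pairs, net)
    expect_equal(sum(summ$genes$I_gene), sum(pairs$I), tolerance = 1e-9)
    expect_equal(sum(summ$mirnas$I_miR), sum(pairs$I), tolerance = 1e-9)
  }
})

test_that("lengthening the only path attenuates the impact", {
  # chain of increasing length between the same miRNA and sink
  for (L in 1:5) {
    nodes <- c("m", sprintf("g%d", seq_len(L)))
    src <- nodes[-length(nodes)]
    tgt <- nodes[-1]
    ge <- if (L > 1) edge_df(src[-1], tgt[-1], rep(1L, L - 1)) else
      edge_df(character(), character(), integer())
    te <- edge_df("m", nodes[2], -1L, kind = "mirna_gene")
    cf <- data.frame(gene_id = nodes[length(nodes)],
                     fate_class = "proliferation",
                     stringsAsFactors = FALSE)
    net <- make_migrn(ge, te, cf)
    pi <- pair_impact(net, "m", cf$gene_id, log2fc = 3)
    expect_equal(pi$L, L)
    expect_equal(abs(pi$I), 3 / L)
  }
})

test_that("odd inhibitory parity forces anti-correlation of impact and fold change", {
  # all gene-gene edges activating: each route carries exactly one
  # inhibition (the miRNA's first hop), so sign(I) = -sign(log2FC)
  set.seed(71)
  rg <- random_signed_graph(12, 5, density = 0.3, inhibition = 0)
  net <- make_migrn(rg$gene_edges, rg$target_edges, rg$cell_fate)
  de <- data.frame(feature_id = rg$mirnas,
                   log2fc = runif(5, 0.5, 3) * sample(c(-1, 1), 5, TRUE),
                   stringsAsFactors = FALSE)
  pairs <- pair_impacts(net, de)
  expect_gt(nrow(pairs), 0)
  expect_true(all(pairs$S == -1L))
  expect_true(all(sign(pairs$I) == -sign(pairs$log2fc)))
  summ <- impact_summary(pairs, net)
  scored <- summ$mirnas[summ$mirnas$n_reached > 0, ]
  lfc <- setNames(de$log2fc, de$feature_id)
  expect_true(all(sign(scored$I_miR) == -sign(lfc[scored$mirna])))
})

test_that("ranking sorts by absolute total impact with id tie-breaks", {
  pairs <- data.frame(
    mirna = c("a", "b", "c"), gene = "G",
    fate_class = "proliferation", L = 1L, S = c(-1L, 1L, -1L),
    log2fc = c(3, 2, 1), I = c(-3, 2, -1), ambiguous = FALSE,
    stringsAsFactors = FALSE)
  cf <- data.frame(gene_id = "G", fate_class = "proliferation",
                   stringsAsFactors = FALSE)
  net <- make_migrn(edge_df(character(), character(), integer()),
                    edge_df(c("a", "b", "c"), "G", rep(-1L, 3),
                            kind = rep("mirna_gene", 3)), cf)
  summ <- impact_summary(pairs, net)
  expect_equal(rank_mirnas(summ, 2), c("a", "b"))
  expect_equal(summ$ranking, c("a", "b", "c"))

  # equal magnitudes: lexicographic id order
  pairs$I <- c(-1, 1, 0.5)
  summ2 <- impact_summary(pairs, net)
  expect_equal(rank_mirnas(summ2, 2), c("a", "b"))
  expect_error(rank_mirnas(summ2, 0), "positive")
})

test_that("class averages use both reached and full-class denominators", {
  ge <- edge_df(character(), character(), integer())
  te <- edge_df(c("m", "m"), c("P1", "A1"), c(-1L, -1L),
                kind = rep("mirna_gene", 2))
  cf <- data.frame(gene_id = c("P1", "P2", "A1"),
                   fate_class = c("proliferation", "proliferation",
                                  "apoptosis"),
                   stringsAsFactors = FALSE)
  net <- make_migrn(ge, te, cf)
  de <- data.frame(feature_id = "m", log2fc = 2, stringsAsFactors = FALSE)
  pairs <- pair_impacts(net, de)
  summ <- impact_summary(pairs, net)
  row <- summ$mirnas[summ$mirnas$mirna == "m", ]
  # reaches 1 of 2 proliferation genes with I = -2
  expect_equal(row$avg_I_proliferation, -2)
  expect_equal(row$avg_I_proliferation_all, -1)
  expect_equal(row$avg_I_apoptosis, -2)
  expect_equal(row$avg_I_apoptosis_all, -2)
})
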