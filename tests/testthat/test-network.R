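# Network statistics: class-pair edge counts, permutation tests,
# metabolic edges, coexpression construction, rewiring nulls, the sweep
# chi-square.

grid_graph <- function() {
  # 8 nodes, hand-built mixed-label network
  g <- igraph::make_graph(~ a - b, a - c, b - c, c - d, d - e, e - f,
                          f - g, g - h, h - a)
  igraph::V(g)$class <- c("LF", "LF", "LF", "MF1", "MF1", "MF2", "MF2",
                          "LF")
  g
}

test_that("class-pair edge counts match hand enumeration", {
  # complete graph on 4 same-label nodes: 6 edges
  k4 <- igraph::make_full_graph(4)
  igraph::V(k4)$class <- "LF"
  expect_equal(unname(count_class_edges(k4)["LF-LF"]), 6)
  # bipartite labels: no same-label edges
  b <- igraph::make_full_bipartite_graph(3, 3)
  igraph::V(b)$class <- rep(c("LF", "MF1"), each = 3)
  cc <- count_class_edges(b)
  expect_false("LF-LF" %in% names(cc))
  expect_equal(unname(cc["LF-MF1"]), 9)
  # hand count on the mixed 8-node graph:
  # edges: ab(LF,LF) ac(LF,LF) bc(LF,LF) cd(LF,MF1) de(MF1,MF1)
  #        ef(MF1,MF2) fg(MF2,MF2) gh(MF2,LF) ha(LF,LF)
  cc2 <- count_class_edges(grid_graph())
  expect_equal(unname(cc2["LF-LF"]), 4)
  expect_equal(unname(cc2["MF1-MF1"]), 1)
  expect_equal(unname(cc2["MF2-MF2"]), 1)
  expect_equal(unname(cc2["LF-MF1"]), 1)
  expect_equal(unname(cc2["LF-MF2"]), 1)
  expect_equal(unname(cc2["MF1-MF2"]), 1)
  # node filter restricts both endpoints
  filt <- igraph::V(grid_graph())$class == "LF"
  cc3 <- count_class_edges(grid_graph(), node_filter = filt)
  expect_equal(unname(cc3["LF-LF"]), 4)
  expect_length(cc3, 1L)
})

test_that("label permutation test is calibrated and deterministic", {
  g <- grid_graph()
  same_lf <- function(gr, labels) {
    cc <- count_class_edges(gr, labels)
    if ("LF-LF" %in% names(cc)) unname(cc["LF-LF"]) else 0
  }
  r1 <- label_permutation_test(g, same_lf, n_perm = 199, seed = 9)
  r2 <- label_permutation_test(g, same_lf, n_perm = 199, seed = 9)
  expect_identical(r1$p_upper, r2$p_upper)           # seeded determinism
  expect_identical(r1$null, r2$null)
  # label-invariant statistic: p = 1 in both tails
  rc <- label_permutation_test(g, function(gr, labels) igraph::ecount(gr),
                               n_perm = 99, seed = 1)
  expect_equal(rc$p_upper, 1)
  expect_equal(rc$p_lower, 1)
  # frozen nodes keep their labels
  frozen <- c(TRUE, TRUE, rep(FALSE, 6))
  seen <- label_permutation_test(g, function(gr, labels) {
    expect_identical(labels[1:2], c("LF", "LF"))
    0
  }, n_perm = 5, frozen = frozen, seed = 2)
  expect_error(label_permutation_test(g, same_lf, frozen = rep(TRUE, 8)),
               "frozen")
})

test_that("a planted perfect assortative network reaches the minimal p", {
  # three disjoint 6-cliques, one label per clique: only a label shuffle
  # that maps classes onto cliques as a bijection ties the observed
  # same-class count (probability ~3.5e-7 per draw), so 999 random
  # permutations essentially never match it
  g <- igraph::disjoint_union(igraph::make_full_graph(6),
                              igraph::make_full_graph(6),
                              igraph::make_full_graph(6))
  igraph::V(g)$class <- rep(c("A", "B", "C"), each = 6)
  same <- function(gr, labels) {
    cc <- count_class_edges(gr, labels)
    sum(cc[c("A-A", "B-B", "C-C")], na.rm = TRUE)
  }
  r <- label_permutation_test(g, same, n_perm = 999, seed = 3)
  expect_equal(r$p_upper, 1 / 1000)
})

test_that("permutation p-values are calibrated under an exchangeable null", {
  g <- simulate_labeled_network(60, mean_degree = 5,
                                class_sizes = c(A = 20, B = 20, C = 20),
                                enrichment = 1, seed = 10)
  same <- function(gr, labels) {
    cc <- count_class_edges(gr, labels)
    sum(cc[c("A-A", "B-B", "C-C")], na.rm = TRUE)
  }
  ps <- vapply(1:100, function(s) {
    labs <- local({ set.seed(1000 + s); sample(igraph::V(g)$class) })
    label_permutation_test(g, same, n_perm = 99, labels = labs,
                           seed = s)$p_upper
  }, numeric(1))
  for (alpha in c(0.1, 0.3, 0.5)) {
    expect_lt(abs(mean(ps <= alpha) - alpha),
              0.13)          # binomial noise at 100 replicates plus ties
  }
})

test_that("metabolic edge statistic counts single-copy same-subgenome pairs", {
  g <- igraph::make_graph(~ r1 - r2, r2 - r3, r3 - r4)
  gene_map <- data.frame(
    reaction = c("r1", "r1", "r2", "r3", "r4"),
    gene = c("x1", "x2", "x3", "x4", "x5"))
  labels <- data.frame(
    gene = paste0("x", 1:5),
    subgenome = c("LF", "MF1", "LF", "LF", "MF1"),
    copy_status = c("single", "single", "single", "triplicated", "single"))
  out <- metabolic_edge_stat(g, gene_map, labels)
  # r1-r2 share single-copy LF (x1, x3): LF count 1; no other pair
  expect_equal(unname(out["LF"]), 1)
  expect_equal(unname(out["MF1"]), 0)
  # no single-copy genes at all: zero counts
  labels2 <- transform(labels, copy_status = "triplicated")
  expect_true(all(metabolic_edge_stat(g, gene_map, labels2) == 0))
})

test_that("coexpression construction follows the correlation rules", {
  # identical rank order: rho = 1 -> edge; reversed ranks: rho = -1 -> edge
  base <- seq_len(10)
  expr <- rbind(g1 = base, g2 = base^2, g3 = rev(base),
                g4 = c(5, 1, 4, 2, 6, 3, 8, 10, 7, 9))
  net <- build_coexpression(expr, threshold = 0.9)
  el <- igraph::as_edgelist(net)
  keys <- apply(el, 1, function(r) paste(sort(r), collapse = "-"))
  expect_true("g1-g2" %in% keys)            # monotone transform, rho = 1
  expect_true("g1-g3" %in% keys)            # rho = -1, negative rule
  expect_false("g1-g4" %in% keys)
  rho_attr <- igraph::E(net)$rho[keys == "g1-g3"]
  expect_equal(rho_attr, -1)

  # genes missing more than max_missing conditions are excluded
  expr2 <- rbind(expr, g5 = c(NA, NA, base[3:10]))
  net2 <- build_coexpression(expr2, max_missing = 1)
  expect_false("g5" %in% igraph::V(net2)$name)
  net3 <- build_coexpression(expr2, max_missing = 2)
  expect_true("g5" %in% igraph::V(net3)$name)

  # constant gene is skipped with a warning
  expr3 <- rbind(expr, g6 = rep(1, 10))
  expect_warning(net4 <- build_coexpression(expr3), "constant")
  expect_false("g6" %in% igraph::V(net4)$name)

  # gene order does not matter
  net5 <- build_coexpression(expr[c(3, 1, 4, 2), ])
  expect_equal(igraph::ecount(net5), igraph::ecount(net))

  # independent noise at 32 conditions: no |rho| >= 0.9 edges
  sim <- simulate_expression(40, 32, n_blocks = 0, seed = 12)
  expect_equal(igraph::ecount(build_coexpression(sim$expr)), 0)
})

test_that("rewiring preserves degrees and detects planted enrichment", {
  g <- simulate_labeled_network(90, mean_degree = 6,
                                class_sizes = c(LF = 30, MF1 = 30,
                                                MF2 = 30),
                                enrichment = 6, seed = 5)
  deg0 <- igraph::degree(g)
  res <- rewire_test(g, n_rewire = 100, seed = 8)
  # degree preservation is checked on a fresh rewire with the same code path
  gr <- igraph::rewire(g, igraph::keeping_degseq(niter = 10 *
                                                   igraph::ecount(g)))
  expect_identical(igraph::degree(gr), deg0)
  expect_false(igraph::any_multiple(gr))
  expect_false(any(igraph::which_loop(gr)))
  # planted same-class excess: all three same-class pairs significant
  expect_lt(res$p_upper[["LF-LF"]], 0.05)
  expect_lt(res$p_upper[["MF1-MF1"]], 0.05)
  expect_lt(res$p_upper[["MF2-MF2"]], 0.05)

  # star graph admits no swap: identical counts, p = 1 everywhere
  star <- igraph::make_star(6, mode = "undirected")
  igraph::V(star)$class <- c("A", "A", "B", "B", "A", "B")
  rs <- rewire_test(star, n_rewire = 20, seed = 2)
  expect_true(all(rs$p_upper == 1))
  expect_true(all(rs$p_lower == 1))
  tiny <- igraph::make_graph(~ a - b)
  igraph::V(tiny)$class <- c("A", "B")
  expect_error(rewire_test(tiny, n_rewire = 5), "too small")
})

test_that("sweep association reproduces the textbook chi-square", {
  genes <- data.frame(
    subgenome = rep(c("LF", "MF1"), times = c(30, 30)),
    sweep = rep(c(TRUE, FALSE, TRUE, FALSE), times = c(10, 20, 20, 10)))
  out <- sweep_association(genes)
  # textbook formula on the 2x2 table [[10,20],[20,10]]
  O <- matrix(c(10, 20, 20, 10), 2, byrow = TRUE)
  E <- outer(rowSums(O), colSums(O)) / sum(O)
  expect_equal(out$statistic, sum((O - E)^2 / E))
  expect_equal(out$df, 1)
  # proportional table: statistic 0, p 1
  prop <- data.frame(subgenome = rep(c("LF", "MF1", "MF2"), each = 20),
                     sweep = rep(rep(c(TRUE, FALSE), c(5, 15)), 3))
  out2 <- sweep_association(prop)
  expect_equal(out2$statistic, 0)
  expect_equal(out2$p_value, 1)
  expect_equal(out2$df, 2)                  # (3-1)(2-1)
  expect_equal(dim(out2$stdres), c(3L, 2L))
  # a subgenome level with no genes at all gives an empty row
  degenerate <- data.frame(
    subgenome = factor(c("LF", "LF", "MF1", "MF1"),
                       levels = c("LF", "MF1", "MF2")),
    sweep = c(TRUE, FALSE, TRUE, FALSE))
  expect_error(sweep_association(degenerate), "empty")
})
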