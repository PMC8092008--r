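# Ancestral order reconstruction: adjacency collection, maximum-weight
# matching vs brute force, contig filtering and ordering.

# k collinear genomes over the same sets s1..sn
collinear_input <- function(n_sets = 5, genomes = 4) {
  genes <- do.call(rbind, lapply(seq_len(genomes), function(g) {
    data.frame(genome = paste0("g", g), chrom = "c1", pos = seq_len(n_sets),
               gene = paste0("g", g, "_", seq_len(n_sets)))
  }))
  sets <- data.frame(set_id = rep(paste0("s", seq_len(n_sets)), genomes),
                     genome = genes$genome, gene = genes$gene)
  list(genes = genes, sets = sets)
}

test_that("adjacency weights count supporting genomes", {
  inp <- collinear_input(3, genomes = 2)
  cands <- collect_adjacencies(inp$genes, inp$sets)
  expect_equal(nrow(cands), 2L)
  expect_true(all(cands$weight == 2))
  # two sets adjacent in all 8 copies of a 2-diploid + 2-triplicated design
  genes8 <- do.call(rbind, lapply(1:8, function(k) {
    data.frame(genome = paste0("copy", k), chrom = "c", pos = 1:2,
               gene = paste0("c", k, "_", 1:2))
  }))
  sets8 <- data.frame(set_id = rep(c("sA", "sB"), 8),
                      genome = genes8$genome, gene = genes8$gene)
  c8 <- collect_adjacencies(genes8, sets8)
  expect_equal(c8$weight, 8L)
  # sets never adjacent yield no candidate
  far <- data.frame(genome = "g1", chrom = c("c1", "c2"), pos = c(1, 1),
                    gene = c("x1", "x2"))
  fsets <- data.frame(set_id = c("sX", "sY"), genome = "g1",
                      gene = c("x1", "x2"))
  expect_equal(nrow(collect_adjacencies(far, fsets)), 0L)
  # a gene in two sets is an error
  bad <- rbind(fsets, data.frame(set_id = "sZ", genome = "g1", gene = "x1"))
  expect_error(collect_adjacencies(far, bad), "at most one")
})

test_that("matching selects the maximum weight and resolves conflicts", {
  # 3-set conflict: one endpoint claimed by candidates of weight 5 and 3
  cands <- data.frame(
    set_a = c("s1", "s1"), end_a = c("tail", "tail"),
    set_b = c("s2", "s3"), end_b = c("head", "head"),
    weight = c(5, 3))
  res <- mwm_linearize(cands, set_ids = c("s1", "s2", "s3"))
  expect_equal(res$total_weight, 5)
  expect_true(any(vapply(res$contigs, function(ct)
    identical(ct, c("s1", "s2")) || identical(ct, c("s2", "s1")),
    logical(1))))

  # empty candidate list: every set its own singleton contig
  empty <- mwm_linearize(cands[0, ], set_ids = c("sa", "sb"))
  expect_equal(sort(unlist(empty$contigs)), c("sa", "sb"))
  expect_equal(lengths(empty$contigs), c(1L, 1L))

  # a simple path is selected wholly, one contig
  inp <- collinear_input(5, genomes = 3)
  cands5 <- collect_adjacencies(inp$genes, inp$sets)
  res5 <- mwm_linearize(cands5)
  expect_length(res5$contigs, 1L)
  expect_equal(res5$total_weight, 4 * 3)
  ct <- res5$contigs[[1]]
  expect_true(identical(ct, paste0("s", 1:5)) ||
                identical(ct, paste0("s", 5:1)))
})

test_that("matching weight equals brute force on random small instances", {
  set.seed(17)
  for (rep in 1:12) {
    n_sets <- sample(4:8, 1)
    m <- sample(4:12, 1)
    ids <- paste0("s", seq_len(n_sets))
    cands <- unique(data.frame(
      set_a = sample(ids, m, replace = TRUE),
      end_a = sample(c("head", "tail"), m, replace = TRUE),
      set_b = sample(ids, m, replace = TRUE),
      end_b = sample(c("head", "tail"), m, replace = TRUE),
      weight = sample(1:8, m, replace = TRUE)))
    cands <- cands[cands$set_a != cands$set_b, , drop = FALSE]
    if (!nrow(cands)) next
    sel <- wgtloss:::max_weight_matching(cands)
    got <- sum(cands$weight[sel])
    expect_equal(got, oracle_matching_weight(cands))
    # endpoint used at most once
    eps <- c(paste(cands$set_a[sel], cands$end_a[sel]),
             paste(cands$set_b[sel], cands$end_b[sel]))
    expect_equal(anyDuplicated(eps), 0L)
  }
})

test_that("cycles are broken at the lowest-weight selected edge", {
  cands <- data.frame(
    set_a = c("s1", "s2", "s3"), end_a = rep("tail", 3),
    set_b = c("s2", "s3", "s1"), end_b = rep("head", 3),
    weight = c(5, 4, 2))
  res <- mwm_linearize(cands, set_ids = paste0("s", 1:3))
  expect_equal(nrow(res$broken_cycles), 1L)
  expect_equal(res$broken_cycles$weight, 2)
  expect_equal(res$total_weight, 9)
  expect_length(res$contigs, 1L)
  expect_length(res$contigs[[1]], 3L)
})

test_that("contigs are simple paths and preserve universal adjacencies", {
  inp <- collinear_input(6, genomes = 4)
  res <- mwm_linearize(collect_adjacencies(inp$genes, inp$sets))
  for (ct in res$contigs) expect_equal(anyDuplicated(ct), 0L)
  # genes adjacent in all genomes stay adjacent in the reconstruction
  ct <- res$contigs[[which.max(lengths(res$contigs))]]
  for (k in 1:5) {
    pos <- match(paste0("s", c(k, k + 1)), ct)
    expect_equal(abs(diff(pos)), 1L)
  }
})

test_that("contig filter drops small or mixed-origin contigs", {
  set_genes <- data.frame(
    set_id = rep(paste0("s", 1:10), each = 2),
    genome = rep(c("brassica", "outgroup"), 10),
    gene = paste0("x", 1:20))
  contigs <- list(paste0("s", 1:5), paste0("s", 6:9), "s10")
  kept <- filter_contigs(contigs, set_genes, required_genome = "brassica",
                         min_genes = 4)
  expect_length(kept, 1L)                      # 5 genes kept, 4 and 1 dropped
  expect_identical(kept[[1]], paste0("s", 1:5))
  # majority-label rule at the 0.8 threshold: a 50/50 contig is dropped
  labs <- data.frame(set_id = paste0("s", 1:5),
                     label = c("chr1", "chr1", "chr2", "chr2", "chr1"))
  kept2 <- filter_contigs(contigs, set_genes, "brassica",
                          chrom_labels = labs, majority = 0.8)
  expect_length(kept2, 0L)
  kept3 <- filter_contigs(contigs, set_genes, "brassica",
                          chrom_labels = labs, majority = 0.6)
  expect_length(kept3, 1L)
})

test_that("contig ordering matches the junction evidence", {
  inp <- collinear_input(6, genomes = 3)
  # artificially split into two contigs, junction between s3 and s4
  contigs <- list(paste0("s", 1:3), paste0("s", 4:6))
  res <- order_contigs(contigs, inp$genes, inp$sets)
  expect_length(res$chromosomes, 1L)
  chr <- res$chromosomes[[1]]
  expect_true(identical(chr, paste0("s", 1:6)) ||
                identical(chr, paste0("s", 6:1)))
  # single contig passes through unchanged
  one <- order_contigs(list(paste0("s", 1:6)), inp$genes, inp$sets)
  expect_identical(one$chromosomes[[1]], paste0("s", 1:6))
  # reversed second contig is flipped back at the junction
  contigs_rev <- list(paste0("s", 1:3), paste0("s", 6:4))
  res2 <- order_contigs(contigs_rev, inp$genes, inp$sets)
  chr2 <- res2$chromosomes[[1]]
  expect_true(identical(chr2, paste0("s", 1:6)) ||
                identical(chr2, paste0("s", 6:1)))
})

test_that("homology-set fallback respects per-genome caps", {
  gg <- data.frame(
    gene = c(paste0("b", 1:5), "a1"),
    genome = c(rep("brassica", 5), "arabidopsis"))
  pairs <- data.frame(gene1 = c(paste0("b", 1:5)),
                      gene2 = c("a1", "a1", "a1", "a1", "a1"))
  sets <- build_homology_sets(pairs, gg,
                              caps = c(brassica = 3, arabidopsis = 1))
  tab <- table(sets$set_id, sets$genome)
  expect_true(all(tab[, "brassica"] <= 3))
  expect_true(all(tab[, "arabidopsis"] <= 1))
  expect_equal(sum(tab), 6)                   # every gene placed once
})
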