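# Subgenome-label statistics on interaction and coexpression networks:
# label permutation tests, degree-preserving rewiring nulls, metabolic
# edge statistics and the sweep-association chi-square.

#' Count edges within and between node classes
#'
#' Tabulates the edges of an undirected simple graph by the (unordered)
#' pair of endpoint classes, optionally restricted to nodes passing a
#' filter (e.g. single-copy genes only).
#'
#' @param g an [igraph::graph].
#' @param labels class label per vertex; defaults to the vertex attribute
#'   `class`.
#' @param node_filter optional logical vector: edges are counted only
#'   when both endpoints pass.
#' @return named numeric vector of edge counts, names like `"LF-LF"`,
#'   `"LF-MF1"` (classes in sorted order within a name).
#' @export
count_class_edges <- function(g, labels = igraph::V(g)$class,
                              node_filter = NULL) {
  stopifnot(igraph::is_igraph(g))
  if (is.null(labels)) stop("no class labels found on the network")
  if (igraph::any_multiple(g) || any(igraph::which_loop(g))) {
    stop("the network must be simple (no loops or multi-edges)")
  }
  ends <- igraph::as_edgelist(g, names = FALSE)
  if (!is.null(node_filter)) {
    keep <- node_filter[ends[, 1]] & node_filter[ends[, 2]]
    ends <- ends[keep, , drop = FALSE]
  }
  if (nrow(ends) == 0) return(stats::setNames(numeric(0), character(0)))
  a <- labels[ends[, 1]]
  b <- labels[ends[, 2]]
  key <- ifelse(a <= b, paste(a, b, sep = "-"), paste(b, a, sep = "-"))
  c(table(key))
}

#' Label-permutation test for a network statistic
#'
#' Shuffles the class labels across the non-frozen nodes of the network
#' `n_perm` times, holding the topology unchanged, and compares the
#' observed statistic with the permutation distribution.  Empirical
#' p-values use the add-one convention `p = (r + 1) / (n_perm + 1)` and
#' both tails are reported.
#'
#' @param g an [igraph::graph] with vertex attribute `class` (or supply
#'   `labels`).
#' @param statistic function of `(g, labels)` returning one number.
#' @param n_perm number of permutations (>= 1).
#' @param frozen optional logical vector: nodes whose labels are held
#'   fixed (e.g. retained triplets).
#' @param labels label vector overriding the vertex attribute.
#' @param seed integer seed.
#' @return list with `observed`, `p_upper`, `p_lower`, and the sampled
#'   `null` statistics.
#' @export
label_permutation_test <- function(g, statistic, n_perm = 1000,
                                   frozen = NULL,
                                   labels = igraph::V(g)$class, seed = 1) {
  stopifnot(igraph::is_igraph(g), n_perm >= 1)
  if (is.null(labels)) stop("no class labels found on the network")
  nv <- igraph::vcount(g)
  stopifnot(length(labels) == nv)
  if (is.null(frozen)) frozen <- rep(FALSE, nv)
  if (all(frozen)) stop("all nodes are frozen; nothing to permute")
  set.seed(seed)

  obs <- statistic(g, labels)
  free <- which(!frozen)
  null <- vapply(seq_len(n_perm), function(i) {
    lab <- labels
    lab[free] <- lab[sample(free)]
    statistic(g, lab)
  }, numeric(1))
  list(
    observed = obs,
    p_upper = (sum(null >= obs) + 1) / (n_perm + 1),
    p_lower = (sum(null <= obs) + 1) / (n_perm + 1),
    null = null
  )
}

#' Same-subgenome single-copy edge counts on a reaction network
#'
#' For a metabolic network whose nodes are reactions (edges = shared
#' metabolite), counts, per subgenome, the edges whose two reactions each
#' involve at least one single-copy gene assigned to that subgenome.
#'
#' @param g reaction network ([igraph::graph]).
#' @param gene_map data.frame with columns `reaction` (vertex name) and
#'   `gene`.
#' @param gene_labels data.frame with columns `gene`, `subgenome`,
#'   `copy_status` (`"single"` marks single-copy genes).
#' @return named numeric vector of counts per subgenome.
#' @export
metabolic_edge_stat <- function(g, gene_map, gene_labels) {
  stopifnot(igraph::is_igraph(g),
            all(c("reaction", "gene") %in% names(gene_map)),
            all(c("gene", "subgenome", "copy_status") %in% names(gene_labels)))
  singles <- gene_labels[gene_labels$copy_status == "single", , drop = FALSE]
  m <- merge(gene_map, singles, by = "gene")
  subs <- sort(unique(singles$subgenome))
  rxn_names <- igraph::V(g)$name
  if (is.null(rxn_names)) rxn_names <- as.character(seq_len(igraph::vcount(g)))
  has_sub <- sapply(subs, function(k) {
    rxn_names %in% m$reaction[m$subgenome == k]
  })
  if (is.null(dim(has_sub))) has_sub <- matrix(has_sub, nrow = 1)
  ends <- igraph::as_edgelist(g, names = FALSE)
  out <- stats::setNames(numeric(length(subs)), subs)
  for (j in seq_along(subs)) {
    out[j] <- sum(has_sub[ends[, 1], j] & has_sub[ends[, 2], j])
  }
  out
}

#' Build a coexpression network by thresholded Spearman correlation
#'
#' Genes missing more than `max_missing` condition values are excluded;
#' genes with constant expression (undefined rank correlation) are
#' skipped with a warning.  Spearman's rho is computed on pairwise
#' complete values with average ranks for ties, and an edge joins two
#' genes when `rho >= threshold` or `rho <= -threshold`.
#'
#' @param expr genes x conditions matrix (`NA` = missing).
#' @param max_missing maximum missing conditions per gene (default 1, as
#'   in a 32-library design).
#' @param threshold absolute correlation threshold (default 0.9).
#' @return an [igraph::graph] over the retained genes, with edge
#'   attribute `rho`.
#' @export
build_coexpression <- function(expr, max_missing = 1, threshold = 0.9) {
  stopifnot(is.matrix(expr), ncol(expr) >= 3)
  if (is.null(rownames(expr))) {
    rownames(expr) <- paste0("gene", seq_len(nrow(expr)))
  }
  keep <- rowSums(is.na(expr)) <= max_missing
  expr <- expr[keep, , drop = FALSE]
  const <- apply(expr, 1, function(x) {
    x <- x[!is.na(x)]
    length(unique(x)) <= 1L
  })
  if (any(const)) {
    warning(sum(const), " gene(s) with constant expression skipped")
    expr <- expr[!const, , drop = FALSE]
  }
  n <- nrow(expr)
  g <- igraph::make_empty_graph(n, directed = FALSE)
  igraph::V(g)$name <- rownames(expr)
  if (n < 2) return(g)
  rho <- stats::cor(t(expr), method = "spearman",
                    use = "pairwise.complete.obs")
  hit <- which(upper.tri(rho) & (rho >= threshold | rho <= -threshold),
               arr.ind = TRUE)
  if (nrow(hit)) {
    g <- igraph::add_edges(g, t(hit))
    igraph::E(g)$rho <- rho[hit]
  }
  g
}

#' Degree-preserving rewiring null for class-pair edge counts
#'
#' Randomizes the network `n_rewire` times by double edge swaps that
#' preserve every node's degree (and never create loops or
#' multi-edges), holding the node labels fixed, and compares the
#' class-pair edge counts of the observed network with the rewired
#' distributions.  Add-one empirical p-values are reported for both
#' tails of every class pair.
#'
#' @param g an [igraph::graph] with vertex attribute `class` (or
#'   `labels`).
#' @param n_rewire number of rewired replicates.
#' @param swaps_per_edge double-swap attempts per edge per replicate.
#' @param labels label vector overriding the vertex attribute.
#' @param seed integer seed.
#' @return list with `observed` (named counts), `null` (matrix replicate
#'   x class pair), `p_upper`, `p_lower`.
#' @export
rewire_test <- function(g, n_rewire = 100, swaps_per_edge = 10,
                        labels = igraph::V(g)$class, seed = 1) {
  stopifnot(igraph::is_igraph(g))
  if (is.null(labels)) stop("no class labels found on the network")
  if (igraph::ecount(g) < 2) stop("network too small to rewire")
  set.seed(seed)

  pairs <- sort(unique(names(count_class_edges(g, labels))))
  classes <- sort(unique(labels))
  all_pairs <- outer(classes, classes, function(a, b)
    ifelse(a <= b, paste(a, b, sep = "-"), NA))
  all_pairs <- sort(unique(stats::na.omit(as.vector(all_pairs))))
  fill <- function(counts) {
    out <- stats::setNames(numeric(length(all_pairs)), all_pairs)
    out[names(counts)] <- counts
    out
  }
  obs <- fill(count_class_edges(g, labels))

  niter <- swaps_per_edge * igraph::ecount(g)
  null <- t(vapply(seq_len(n_rewire), function(i) {
    gr <- igraph::rewire(g, igraph::keeping_degseq(loops = FALSE,
                                                   niter = niter))
    fill(count_class_edges(gr, labels))
  }, numeric(length(all_pairs))))

  p_up <- p_lo <- stats::setNames(numeric(length(all_pairs)), all_pairs)
  for (j in seq_along(all_pairs)) {
    p_up[j] <- (sum(null[, j] >= obs[j]) + 1) / (n_rewire + 1)
    p_lo[j] <- (sum(null[, j] <= obs[j]) + 1) / (n_rewire + 1)
  }
  list(observed = obs, null = null, p_upper = p_up, p_lower = p_lo)
}

#' Subgenome x sweep-status association test
#'
#' Pearson chi-square (no continuity correction) on the contingency
#' table of subgenome of origin against selective-sweep status, with the
#' standardized residuals used in association plots.
#'
#' @param genes data.frame with columns `subgenome` and `sweep` (logical
#'   or two-level).
#' @return list with `table`, `statistic`, `df`, `p_value`, `stdres`.
#' @export
sweep_association <- function(genes) {
  stopifnot(all(c("subgenome", "sweep") %in% names(genes)))
  tab <- table(genes$subgenome, genes$sweep)
  if (any(rowSums(tab) == 0) || any(colSums(tab) == 0)) {
    stop("contingency table has an empty row or column")
  }
  ct <- stats::chisq.test(tab, correct = FALSE)
  list(table = tab, statistic = unname(ct$statistic),
       df = unname(ct$parameter), p_value = ct$p.value,
       stdres = ct$stdres)
}
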