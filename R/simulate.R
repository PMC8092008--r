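# Synthetic-data generators.  Pillar data are simulated by exact
# stochastic simulation of the loss chain (competing exponentials) down
# the species tree, so closed-form transition probabilities are
# recovered exactly in expectation, and every sampled path is recorded
# as ground truth.

#' Simulate one CTMC branch for a vector of starting states
#'
#' @param states integer start states.
#' @param Q rate matrix.
#' @param t branch length.
#' @return list `end` (states at the branch bottom) and `counts` (7 x 7
#'   sampled jump counts).
#' @noRd
simulate_branch <- function(states, Q, t) {
  k <- nrow(Q)
  counts <- matrix(0, k, k)
  cur <- as.integer(states)
  time_left <- rep(t, length(cur))
  exit <- -diag(Q)
  active <- which(exit[cur] > 0 & time_left > 0)
  while (length(active)) {
    dt <- stats::rexp(length(active), exit[cur[active]])
    jumped <- active[dt < time_left[active]]
    time_left[active] <- time_left[active] - dt
    if (length(jumped)) {
      s_of <- cur[jumped]               # frozen: one jump per draw
      for (s in unique(s_of)) {
        idx <- jumped[s_of == s]
        pr <- Q[s, ]
        pr[s] <- 0
        tgt <- sample.int(k, length(idx), replace = TRUE, prob = pr)
        tab <- tabulate(tgt, k)
        counts[s, ] <- counts[s, ] + tab
        cur[idx] <- tgt
      }
    }
    active <- jumped[exit[cur[jumped]] > 0 & time_left[jumped] > 0]
  }
  list(end = cur, counts = counts)
}

#' Simulate pillar data under a loss model and the synteny HMM
#'
#' Hidden permutations are drawn along the pillar sequence with
#' per-genome persistence `1 - theta` (synteny-break flags are emitted
#' exactly where a redraw occurred); copy-number states evolve down the
#' tree from the variant's root state by exact continuous-time
#' simulation; tip states are written through the true permutations into
#' track slots.  Because single-copy states are absorbing, every genome
#' retains at least one gene in every pillar.
#'
#' @param tree a [wgt_tree()].
#' @param spec a [loss_model()].
#' @param hmm an [hmm_spec()].
#' @param n_pillars number of pillars.
#' @param seed integer seed (recorded in the truth).
#' @return list with `pillars` (a [pillar_set()]) and `truth`: list of
#'   `perms` (n x G true permutation indices), `node_states` (n x nnode
#'   states at the bottom of each branch), `jump_counts` (list per node
#'   of 7 x 7 sampled transition counts on the branch above it), plus the
#'   generating `spec`, `hmm`, `tree` and `seed`.
#' @examples
#' sim <- simulate_pillars(default_study_tree(),
#'                         loss_model("g3", sigma = 0.8,
#'                                    fT = c(0.6, 0.8, 1),
#'                                    fD = c(0.5, 0.7, 1)),
#'                         hmm_spec(0.05), n_pillars = 50, seed = 42)
#' sim$pillars
#' @export
simulate_pillars <- function(tree, spec, hmm = hmm_spec(), n_pillars,
                             seed = 1) {
  stopifnot(inherits(tree, "wgt_tree"), inherits(spec, "loss_model"),
            inherits(hmm, "hmm_spec"), n_pillars >= 1)
  set.seed(seed)
  G <- n_genomes(tree)
  n <- as.integer(n_pillars)
  theta <- rep_len(hmm$theta, G)

  # hidden permutation chains and break flags
  perms <- matrix(0L, n, G)
  breaks <- matrix(FALSE, n, G)
  for (g in seq_len(G)) {
    redraw <- c(TRUE, stats::runif(n - 1) < theta[g])
    seg <- cumsum(redraw)
    perms[, g] <- sample.int(6L, max(seg), replace = TRUE)[seg]
    breaks[, g] <- c(FALSE, redraw[-1])
  }

  # loss chain down the tree; root first, children after parents
  Qn <- build_generator(spec, "non_root")
  two_step <- spec$variant == "g3root"
  node_states <- matrix(0L, n, tree$nnode)
  jump_counts <- vector("list", tree$nnode)
  arrived <- rep(TRUE, n)
  for (node0 in rev(tree$postorder)) {        # preorder
    node <- node0 + 1L
    if (node0 == tree$root) {
      if (two_step) {
        # expanded chain: pre-arrival states distinct, arrivals one-off
        Q10 <- g3root_expanded_generator(spec)
        sim <- simulate_branch(rep(8L, n), Q10, tree$lengths[node])
        arrived <- sim$end <= 7L
        cmap <- g3root_collapse_map(spec)
        node_states[, node] <- cmap[sim$end]
        jump_counts[[node]] <- sim$counts
        next
      }
      top <- rep(which(root_prior(spec) == 1), n)
      Q <- build_generator(spec, "root")
    } else {
      parent <- which(tree$child1 == node0 | tree$child2 == node0)
      top <- node_states[, parent]
      Q <- Qn
    }
    sim <- simulate_branch(top, Q, tree$lengths[node])
    node_states[, node] <- sim$end
    jump_counts[[node]] <- sim$counts
  }
  names(jump_counts) <- branch_labels(tree)

  # write tip states through the true permutations into slots
  members <- state_members()
  pattern <- matrix(0L, n, G)
  pmat <- track_permutations()
  for (g in seq_len(G)) {
    tip_node <- which(tree$tip_genome == g - 1L)
    st <- node_states[, tip_node]
    for (s in 1:3) {
      sub <- pmat[perms[, g], s]              # subgenome sitting in slot s
      present <- vapply(seq_len(n), function(i) sub[i] %in% members[[st[i]]],
                        logical(1))
      pattern[, g] <- pattern[, g] + as.integer(present) * c(1L, 2L, 4L)[s]
    }
  }

  ps <- pillar_set(pattern, genomes = tree$tips, breaks = breaks)
  list(
    pillars = ps,
    truth = list(perms = perms, node_states = node_states,
                 jump_counts = jump_counts, arrived = arrived,
                 spec = spec, hmm = hmm_spec(theta), tree = tree,
                 seed = seed)
  )
}

#' Simulate an undirected network with class-label enrichment
#'
#' Draws a simple graph in which each pair of nodes is joined
#' independently, with same-class pairs `enrichment`-fold more likely
#' than cross-class pairs; `enrichment = 1` is an exchangeable null.
#' Edge probabilities are scaled so the expected mean degree matches
#' `mean_degree`.
#'
#' @param n_nodes node count.
#' @param mean_degree expected mean degree.
#' @param class_sizes named integer vector of class sizes (summing to at
#'   most `n_nodes`; leftovers are labelled `"unassigned"`).
#' @param enrichment same-class edge-probability multiplier (>= 1).
#' @param seed integer seed.
#' @return an [igraph::graph] with vertex attribute `class`.
#' @export
simulate_labeled_network <- function(n_nodes, mean_degree = 4,
                                     class_sizes, enrichment = 1,
                                     seed = 1) {
  stopifnot(sum(class_sizes) <= n_nodes, enrichment >= 1, n_nodes >= 2)
  set.seed(seed)
  labels <- rep(names(class_sizes), class_sizes)
  if (length(labels) < n_nodes) {
    labels <- c(labels, rep("unassigned", n_nodes - length(labels)))
  }
  labels <- sample(labels)

  ij <- which(upper.tri(matrix(0, n_nodes, n_nodes)), arr.ind = TRUE)
  same <- labels[ij[, 1]] == labels[ij[, 2]]
  w <- ifelse(same, enrichment, 1)
  target_edges <- n_nodes * mean_degree / 2
  p <- pmin(w * target_edges / sum(w), 0.999)
  keep <- stats::runif(nrow(ij)) < p
  g <- igraph::graph_from_edgelist(ij[keep, , drop = FALSE], directed = FALSE)
  g <- igraph::add_vertices(g, max(0, n_nodes - igraph::vcount(g)))
  igraph::V(g)$class <- labels
  g
}

#' Simulate an expression matrix with planted coexpression blocks
#'
#' Genes in the same block share a latent condition profile with
#' within-block correlation `within_block_corr`; expression values are
#' log-normal (RPKM-like) and entries are set missing independently at
#' `missing_rate`.
#'
#' @param n_genes,n_conditions matrix dimensions (the study design has 32
#'   conditions).
#' @param n_blocks number of planted blocks; genes are split evenly, with
#'   any remainder left unblocked (independent noise).
#' @param within_block_corr correlation of genes within a block, in
#'   `[0, 1]`.
#' @param missing_rate probability an entry is missing.
#' @param seed integer seed.
#' @return list with `expr` (genes x conditions matrix, `NA` for
#'   missing) and `blocks` (integer block id per gene, 0 = unblocked).
#' @export
simulate_expression <- function(n_genes, n_conditions = 32, n_blocks = 2,
                                within_block_corr = 0.95,
                                missing_rate = 0, seed = 1) {
  stopifnot(n_conditions >= 3, within_block_corr >= 0,
            within_block_corr <= 1, n_blocks >= 0)
  set.seed(seed)
  per_block <- if (n_blocks > 0) n_genes %/% n_blocks else 0
  blocks <- integer(n_genes)
  if (n_blocks > 0 && per_block > 0) {
    blocks[seq_len(per_block * n_blocks)] <- rep(seq_len(n_blocks),
                                                 each = per_block)
  }
  factors <- matrix(stats::rnorm(n_blocks * n_conditions), n_blocks)
  z <- matrix(stats::rnorm(n_genes * n_conditions), n_genes)
  r <- sqrt(within_block_corr)
  for (i in seq_len(n_genes)) {
    if (blocks[i] > 0) {
      z[i, ] <- r * factors[blocks[i], ] + sqrt(1 - r^2) * z[i, ]
    }
  }
  expr <- exp(1 + z)                 # positive, monotone in the latent score
  if (missing_rate > 0) {
    expr[stats::runif(length(expr)) < missing_rate] <- NA
  }
  dimnames(expr) <- list(paste0("gene", seq_len(n_genes)),
                         paste0("cond", seq_len(n_conditions)))
  list(expr = expr, blocks = blocks)
}
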