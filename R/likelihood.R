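#' Synteny-persistence specification of the pillar HMM
#'
#' Between adjacent pillars, each genome's hidden track-to-subgenome
#' permutation persists with probability `1 - theta_g` and is redrawn
#' uniformly over all six permutations (including the current one) with
#' probability `theta_g`.  At an annotated synteny break the redraw is
#' forced.
#'
#' @param theta redraw probability, either one shared value or one per
#'   genome (recycled against the genome count at evaluation time).
#' @return an object of class `"hmm_spec"`.
#' @export
hmm_spec <- function(theta = 0.05) {
  if (any(!is.finite(theta)) || any(theta < 0) || any(theta > 1)) {
    stop("theta must lie in [0, 1]")
  }
  structure(list(theta = as.numeric(theta)), class = "hmm_spec")
}

#' Assemble the C-side arguments shared by likelihood computations
#' @noRd
hmm_workspace <- function(ps, tree, spec, hmm) {
  stopifnot(inherits(ps, "pillar_set"), inherits(tree, "wgt_tree"),
            inherits(spec, "loss_model"), inherits(hmm, "hmm_spec"))
  G <- n_genomes(tree)
  if (length(ps$genomes) != G) {
    stop("pillar set and tree disagree on the number of genomes")
  }
  if (!identical(ps$genomes, tree$tips)) {
    if (!setequal(ps$genomes, tree$tips)) {
      stop("pillar genomes and tree tips must carry the same labels")
    }
    # align pillar columns to tip order
    ord <- match(tree$tips, ps$genomes)
    ps$pattern <- ps$pattern[, ord, drop = FALSE]
    ps$breaks <- ps$breaks[, ord, drop = FALSE]
    ps$genomes <- tree$tips
  }
  theta <- rep_len(hmm$theta, G)

  key <- as.vector(ps$pattern %*% 8L^(seq_len(G) - 1L))
  uk <- unique(key)
  combo_idx <- match(key, uk) - 1L
  combos <- ps$pattern[match(uk, key), , drop = FALSE]

  list(ps = ps, tree = tree, spec = spec, theta = theta,
       combos = combos, combo_idx = combo_idx,
       breaks = ps$breaks, tip_tab = tip_state_table(),
       prior = root_prior(spec))
}

#' Emission log-likelihood of one pillar under one orthology state
#'
#' Felsenstein pruning of the loss chain over the species tree: the root
#' prior ([root_prior()]) is propagated down every branch, and each tip's
#' likelihood is the indicator of the copy-number state obtained by
#' mapping the pillar's presence pattern through that genome's
#' permutation.
#'
#' @param pattern integer vector of presence masks (1..7), one per genome
#'   in tree-tip order (a single row of a [pillar_set()] `pattern`).
#' @param state integer vector of permutation indices (1..6, rows of
#'   [track_permutations()]), one per genome.
#' @param tree a [wgt_tree()].
#' @param spec a [loss_model()].
#' @return log-probability (`-Inf` when the pattern is unreachable).
#' @export
emission_loglik <- function(pattern, state, tree, spec) {
  G <- n_genomes(tree)
  stopifnot(length(pattern) == G, length(state) == G,
            all(pattern >= 1 & pattern <= 7), all(state >= 1 & state <= 6))
  P <- branch_transition_matrices(tree, spec)
  tab <- tip_state_table()
  prior <- root_prior(spec)

  up <- vector("list", tree$nnode)
  for (node0 in tree$postorder) {
    node <- node0 + 1L
    if (tree$child1[node] < 0L) {
      g <- tree$tip_genome[node] + 1L
      v <- numeric(n_states())
      v[tab[pattern[g], state[g]]] <- 1
    } else {
      v <- up[[tree$child1[node] + 1L]] * up[[tree$child2[node] + 1L]]
    }
    up[[node]] <- as.vector(P[[node]] %*% v)
  }
  lik <- sum(prior * up[[tree$root + 1L]])
  if (lik <= 0) -Inf else log(lik)
}

#' Log-likelihood of an ordered pillar sequence
#'
#' The forward algorithm over the `6^G` combined orthology states:
#' emissions by Felsenstein pruning for every state, transitions by the
#' per-genome persistence/redraw kernel of [hmm_spec()], initial
#' distribution uniform.
#'
#' @param ps a [pillar_set()] (rows in pillar order).
#' @param tree a [wgt_tree()] whose tips are the pillar genomes.
#' @param spec a [loss_model()].
#' @param hmm an [hmm_spec()].
#' @return total log-likelihood (scalar).
#' @examples
#' sim <- simulate_pillars(default_study_tree(), loss_model("null"),
#'                         hmm_spec(0.05), n_pillars = 20, seed = 1)
#' sequence_loglik(sim$pillars, default_study_tree(),
#'                 loss_model("null"), hmm_spec(0.05))
#' @export
sequence_loglik <- function(ps, tree, spec, hmm = hmm_spec()) {
  ws <- hmm_workspace(ps, tree, spec, hmm)
  E <- emission_matrix(ws)
  cpp_forward(E, ws$combo_idx, ws$theta,
              matrix(as.integer(ws$breaks), nrow(ws$breaks)))
}

#' Emission matrix (combined states x unique patterns) for a workspace
#' @noRd
emission_matrix <- function(ws, Pmats = NULL) {
  if (is.null(Pmats)) Pmats <- branch_transition_matrices(ws$tree, ws$spec)
  cpp_emissions(ws$combos, Pmats,
                ws$tree$child1, ws$tree$child2, ws$tree$tip_genome,
                ws$tree$postorder, ws$tree$root, ws$tip_tab, ws$prior)
}

#' Posterior distribution over combined orthology states
#'
#' Forward-backward posteriors per pillar; rows sum to one.
#'
#' @inheritParams sequence_loglik
#' @return list with `loglik` and `posterior` (`n x 6^G` matrix).
#' @export
posterior_states <- function(ps, tree, spec, hmm = hmm_spec()) {
  ws <- hmm_workspace(ps, tree, spec, hmm)
  E <- emission_matrix(ws)
  cpp_forward_backward(E, ws$combo_idx, ws$theta,
                       matrix(as.integer(ws$breaks), nrow(ws$breaks)))
}

#' Evaluate several pillar orderings under one model
#'
#' Computes (or, with `refit = TRUE`, re-fits) the sequence likelihood of
#' each candidate ordering of the same pillars and ranks them.  Break
#' flags are dropped when reordering, so likelihood differences come from
#' synteny persistence alone.
#'
#' @param ps a [pillar_set()].
#' @param orderings list of integer permutations of `1:n`.
#' @param tree,spec,hmm model under which to evaluate.
#' @param refit if `TRUE`, each ordering is refitted with [fit_pillars()]
#'   (slow); otherwise evaluated at the given parameters.
#' @param ... passed to [fit_pillars()] when `refit = TRUE`.
#' @return data.frame with one row per ordering, ranked by `loglik`.
#' @export
compare_orderings <- function(ps, orderings, tree, spec, hmm = hmm_spec(),
                              refit = FALSE, ...) {
  stopifnot(is.list(orderings), length(orderings) >= 1L)
  ll <- vapply(seq_along(orderings), function(i) {
    po <- reorder_pillars(ps, orderings[[i]], breaks = "drop")
    if (refit) {
      fit_pillars(po, tree, spec, hmm, ...)$loglik
    } else {
      sequence_loglik(po, tree, spec, hmm)
    }
  }, numeric(1))
  out <- data.frame(ordering = seq_along(orderings), loglik = ll)
  out[order(-out$loglik), , drop = FALSE]
}
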