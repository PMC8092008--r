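# Posterior accounting on a fitted pillar HMM: marginal subgenome
# assignments, expected gene losses per branch and per subgenome, and the
# pre-arrival loss decomposition of the two-step root model.

#' Recompute the forward-backward state posterior of a fit
#' @noRd
fit_posterior <- function(fit) {
  posterior_states(fit$pillars, fit$tree, fit$spec,
                   hmm_spec(fit$theta))$posterior
}

#' Marginal posterior subgenome assignment of every track
#'
#' Marginalizes the pillar posteriors over permutations: for each pillar,
#' genome and track slot, the probability that the slot derives from each
#' parental subgenome.  Rows (pillar, genome, track) sum to one.
#'
#' @param fit a `"wgt_fit"` from [fit_pillars()].
#' @return numeric array `[pillar, genome, track, subgenome]` with
#'   subgenome dimension named `LF`, `MF1`, `MF2`.
#' @export
posterior_subgenome_assignments <- function(fit) {
  stopifnot(inherits(fit, "wgt_fit"))
  post <- fit_posterior(fit)
  G <- length(fit$pillars$genomes)
  n <- fit$pillars$n
  S <- ncol(post)
  perms <- track_permutations()

  out <- array(0, c(n, G, 3L, 3L),
               dimnames = list(NULL, fit$pillars$genomes,
                               paste0("track", 1:3), c("LF", "MF1", "MF2")))
  z <- seq_len(S) - 1L
  for (g in seq_len(G)) {
    digit <- (z %/% 6L^(g - 1L)) %% 6L + 1L      # permutation index of genome g
    pg <- sapply(1:6, function(p) rowSums(post[, digit == p, drop = FALSE]))
    if (n == 1L) pg <- matrix(pg, nrow = 1L)
    for (tr in 1:3) {
      for (k in 1:3) {
        sel <- which(perms[, tr] == k)
        out[, g, tr, k] <- rowSums(pg[, sel, drop = FALSE])
      }
    }
  }
  out
}

#' Expected endpoint-pair counts for every branch
#'
#' For each branch (identified by the node below it), the 7 x 7 matrix of
#' expected numbers of pillars whose loss chain occupied state `a` at the
#' top and state `b` at the bottom of the branch, summed over pillars and
#' weighted by the joint posterior over hidden orthology states.
#'
#' @param fit a `"wgt_fit"`.
#' @return list of 7 x 7 matrices named by [branch_labels()].
#' @export
branch_endpoint_counts <- function(fit) {
  stopifnot(inherits(fit, "wgt_fit"))
  ws <- hmm_workspace(fit$pillars, fit$tree, fit$spec, hmm_spec(fit$theta))
  post <- fit_posterior(fit)
  # aggregate posterior weight by unique pattern combo
  Wu <- rowsum(post, group = ws$combo_idx)
  Wu <- Wu[order(as.integer(rownames(Wu))), , drop = FALSE]
  Pmats <- branch_transition_matrices(fit$tree, fit$spec)
  C <- cpp_endpoint_counts(Wu, ws$combos, Pmats,
                           fit$tree$child1, fit$tree$child2,
                           fit$tree$tip_genome, fit$tree$postorder,
                           fit$tree$root, ws$tip_tab, ws$prior)
  labs <- branch_labels(fit$tree)
  out <- lapply(seq_len(fit$tree$nnode), function(v) {
    matrix(C[, v], 7, 7, dimnames = list(state_names(), state_names()))
  })
  names(out) <- labs
  out
}

#' Expected gene losses per branch and subgenome
#'
#' Posterior expected numbers of surviving gene copies at both ends of
#' every branch and of copy-loss events on it, per subgenome.  Because a
#' copy, once lost, is never regained, the expected number of loss events
#' on a branch equals the expected count of endpoint pairs in which the
#' copy is present at the top and absent at the bottom.  On the root
#' branch of the two-step model the arriving subgenome can also be
#' gained; the `expected_gains` column accounts for it, and the
#' conservation identity reads
#' `survivors_top - expected_losses + expected_gains = survivors_bottom`.
#'
#' @param fit a `"wgt_fit"`.
#' @return data.frame with columns `branch`, `subgenome`,
#'   `survivors_top`, `survivors_bottom`, `expected_losses`,
#'   `expected_gains`.
#' @export
expected_losses_per_branch <- function(fit) {
  C <- branch_endpoint_counts(fit)
  members <- state_members()
  has <- vapply(members, function(m) 1:3 %in% m, logical(3)) # 3 x 7
  sub_names <- c("LF", "MF1", "MF2")

  rows <- list()
  for (b in names(C)) {
    Cb <- C[[b]]
    for (g in 1:3) {
      in_a <- has[g, ]
      loss <- sum(Cb[in_a, !in_a, drop = FALSE])
      gain <- sum(Cb[!in_a, in_a, drop = FALSE])
      rows[[length(rows) + 1L]] <- data.frame(
        branch = b, subgenome = sub_names[g],
        survivors_top = sum(Cb[in_a, , drop = FALSE]),
        survivors_bottom = sum(Cb[, in_a, drop = FALSE]),
        expected_losses = loss, expected_gains = gain,
        stringsAsFactors = FALSE)
    }
  }
  do.call(rbind, rows)
}

#' Expected labelled transition counts on one branch, jointly with the
#' endpoint pair
#'
#' For a continuous-time chain with generator `Q` run for time `t`,
#' `E[N_ij ; X_t = b | X_0 = a] = q_ij int_0^t P_ai(s) P_jb(t - s) ds`,
#' the top-right block of `expm([[Q, E_ij q_ij], [0, Q]] t)`.  Dividing
#' by `P_ab(t)` conditions on the endpoints.
#'
#' @param Q rate matrix, `t` branch length, `i`, `j` state indices.
#' @return matrix of joint expectations indexed by `(a, b)`.
#' @noRd
joint_jump_counts <- function(Q, t, i, j) {
  k <- nrow(Q)
  M <- matrix(0, 2 * k, 2 * k)
  M[1:k, 1:k] <- Q
  M[k + 1:k, k + 1:k] <- Q
  M[i, k + j] <- Q[i, j]
  Efull <- as.matrix(Matrix::expm(Matrix::Matrix(M * t)))
  Efull[1:k, k + 1:k]
}

#' Decompose root-branch losses of the two-step model by arrival time
#'
#' Under the `"g3root"` variant each pillar starts the root branch in the
#' duplicated state of the two first subgenomes, and the last subgenome
#' arrives at rate `tau` (or jointly with a prior loss at the `beta`
#' rates).  This function estimates, for each of the two first-arriving
#' subgenomes, the fraction of its root-branch losses that happened
#' before the arrival, and the fraction of pillars that never received
#' the arriving subgenome at all.
#'
#' The computation runs on the expanded root chain
#' ([g3root_expanded_generator()]), on which every root-branch loss of a
#' first subgenome is unambiguously dated: a pre-arrival loss is a
#' `beta` transition (a loss folded into the arrival), a post-arrival
#' loss is an ordinary loss transition of the post-arrival block.
#' Expected transition counts are conditioned on the posterior
#' distribution of the (collapsed) root-branch endpoint.
#'
#' @param fit a `"wgt_fit"` of variant `"g3root"`.
#' @return list with `pre_fraction` (named fractions for the two first
#'   subgenomes), `never_arrived` (fraction of pillars with no arrival on
#'   the root branch) and `expected_counts` (the underlying expected
#'   event counts).
#' @export
prearrival_loss_fractions <- function(fit) {
  stopifnot(inherits(fit, "wgt_fit"))
  if (fit$spec$variant != "g3root") {
    stop("pre-arrival fractions are defined for the 'g3root' variant only")
  }
  spec <- fit$spec
  geo <- g3root_geometry(spec$last_subgenome)
  members <- state_members()
  sub_names <- c("LF", "MF1", "MF2")
  last <- spec$last_subgenome
  firsts <- setdiff(1:3, last)                 # sorted: o1 < o2

  Croot <- branch_endpoint_counts(fit)[["root"]]
  n_tot <- sum(Croot)
  t <- fit$tree$lengths[fit$tree$root + 1L]
  Q10 <- g3root_expanded_generator(spec)
  cmap <- g3root_collapse_map(spec)
  P10 <- expm_prob(Q10, t)

  # posterior weight of each collapsed endpoint, all starting from pre-D
  w_end <- Croot[geo$start, ]
  # expected jumps i -> j on the expanded chain, conditioned on the
  # collapsed endpoint class and weighted by the endpoint posterior
  e_jump <- function(i, j) {
    if (Q10[i, j] <= 0) return(0)
    Nraw <- joint_jump_counts(Q10, t, i, j)[8L, ]   # start fixed at pre-D
    tot <- 0
    for (cls in which(w_end > 0)) {
      idx <- which(cmap == cls)
      pcls <- sum(P10[8L, idx])
      if (pcls <= 1e-300) next
      tot <- tot + w_end[cls] * sum(Nraw[idx]) / pcls
    }
    tot
  }

  pre <- post <- stats::setNames(numeric(2), sub_names[firsts])
  for (g in firsts) {
    # beta transition: arrival joint with a prior loss of g
    tgt_beta <- geo$targets[vapply(geo$targets,
                                   function(s) !(g %in% members[[s]]),
                                   logical(1))]
    pre[sub_names[g]] <- e_jump(8L, tgt_beta)
    # post-arrival losses of g out of any post-arrival state holding it
    tot <- 0
    for (s in seq_len(n_states())) {
      m <- members[[s]]
      if (!(g %in% m) || length(m) == 1L) next
      tot <- tot + e_jump(s, state_from_members(setdiff(m, g)))
    }
    post[sub_names[g]] <- tot
  }

  # pillars whose root-branch endpoint is still a pre-arrival state
  never <- 0
  for (cls in which(w_end > 0)) {
    idx <- which(cmap == cls)
    pcls <- sum(P10[8L, idx])
    if (pcls <= 1e-300) next
    never <- never + w_end[cls] * sum(P10[8L, idx[idx > 7L]]) / pcls
  }

  list(
    pre_fraction = pre / pmax(pre + post, 1e-300),
    never_arrived = never / n_tot,
    expected_counts = list(pre_arrival = pre, post_arrival = post,
                           pillars = n_tot)
  )
}
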