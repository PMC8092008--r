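# Independent oracles used across the suite.  All are direct
# enumerations or closed forms, written without the package's pruning /
# forward / matching code paths.

# Pruning oracle for a two-tip tree: explicit sum over the states of the
# WGT point and the single internal node.
oracle_emission_2tip <- function(pattern, state, tree, spec) {
  P1 <- transition_probabilities(build_generator(spec, "non_root"),
                                 tree$lengths[1])
  P2 <- transition_probabilities(build_generator(spec, "non_root"),
                                 tree$lengths[2])
  Pr <- if (spec$variant == "g3root") {
    g3root_root_matrix(spec, tree$lengths[3])
  } else {
    transition_probabilities(build_generator(spec, "root"), tree$lengths[3])
  }
  prior <- root_prior(spec)
  tab <- tip_state_oracle_table()
  t1 <- tab[pattern[1], state[1]]
  t2 <- tab[pattern[2], state[2]]
  tot <- 0
  for (x0 in 1:7) {
    for (xa in 1:7) {
      tot <- tot + prior[x0] * Pr[x0, xa] * P1[xa, t1] * P2[xa, t2]
    }
  }
  if (tot <= 0) -Inf else log(tot)
}

# Pruning oracle for a three-tip caterpillar tree ((t1,t2),t3): sum over
# WGT point and both internal nodes.
oracle_emission_3tip <- function(pattern, state, tree, spec) {
  Pn <- lapply(tree$lengths, function(nu) {
    transition_probabilities(build_generator(spec, "non_root"), nu)
  })
  root_id <- tree$root + 1L
  Pn[[root_id]] <- if (spec$variant == "g3root") {
    g3root_root_matrix(spec, tree$lengths[root_id])
  } else {
    transition_probabilities(build_generator(spec, "root"),
                             tree$lengths[root_id])
  }
  prior <- root_prior(spec)
  tab <- tip_state_oracle_table()
  ts <- sapply(1:3, function(g) tab[pattern[g], state[g]])
  # nodes: tips 1..3, root = 4, inner cherry = 5 (ape numbering)
  tot <- 0
  for (x0 in 1:7) {
    if (prior[x0] == 0) next
    for (xr in 1:7) {
      pr <- prior[x0] * Pn[[root_id]][x0, xr]
      if (pr == 0) next
      for (xi in 1:7) {
        tot <- tot + pr * Pn[[5]][xr, xi] * Pn[[1]][xi, ts[1]] *
          Pn[[2]][xi, ts[2]] * Pn[[3]][xr, ts[3]]
      }
    }
  }
  if (tot <= 0) -Inf else log(tot)
}

# tip-state table built independently of the package internals
tip_state_oracle_table <- function() {
  perms <- rbind(c(1, 2, 3), c(1, 3, 2), c(2, 1, 3),
                 c(2, 3, 1), c(3, 1, 2), c(3, 2, 1))
  sets <- list(1:3, c(1, 2), c(1, 3), c(2, 3), 1, 2, 3)
  tab <- matrix(NA_integer_, 7, 6)
  for (mask in 1:7) {
    present <- as.logical(bitwAnd(mask, c(1L, 2L, 4L)))
    for (p in 1:6) {
      surv <- sort(perms[p, present])
      tab[mask, p] <- which(vapply(sets, function(s)
        identical(as.integer(s), as.integer(surv)), logical(1)))
    }
  }
  tab
}

# Exhaustive hidden-path forward oracle (2 genomes, small n).
oracle_forward_paths <- function(ps, tree, spec, hmm,
                                 emission_fun = oracle_emission_2tip) {
  G <- 2L
  S <- 36L
  n <- ps$n
  theta <- rep_len(hmm$theta, G)
  em <- matrix(0, n, S)
  for (i in seq_len(n)) {
    for (z in 0:(S - 1)) {
      p1 <- z %% 6 + 1
      p2 <- z %/% 6 + 1
      em[i, z + 1] <- exp(emission_fun(ps$pattern[i, ], c(p1, p2),
                                       tree, spec))
    }
  }
  kern <- function(g, from, to, brk) {
    th <- if (brk) 1 else theta[g]
    (1 - th) * (from == to) + th / 6
  }
  paths <- as.matrix(expand.grid(rep(list(1:S), n))) - 1L
  tot <- 0
  for (r in seq_len(nrow(paths))) {
    zs <- paths[r, ]
    p <- em[1, zs[1] + 1] / S
    if (n > 1) {
      for (i in 2:n) {
        for (g in 1:G) {
          d_from <- (zs[i - 1] %/% 6^(g - 1)) %% 6
          d_to <- (zs[i] %/% 6^(g - 1)) %% 6
          p <- p * kern(g, d_from, d_to, ps$breaks[i, g])
        }
        p <- p * em[i, zs[i] + 1]
      }
    }
    tot <- tot + p
  }
  as.numeric(log(tot))
}

# Brute-force maximum-weight matching value by recursion over candidates.
oracle_matching_weight <- function(cands) {
  m <- nrow(cands)
  if (!m) return(0)
  epa <- paste(cands$set_a, cands$end_a)
  epb <- paste(cands$set_b, cands$end_b)
  best <- 0
  rec <- function(i, used, cur) {
    if (cur > best) best <<- cur
    if (i > m) return(invisible())
    if (!(epa[i] %in% used) && !(epb[i] %in% used)) {
      rec(i + 1L, c(used, epa[i], epb[i]), cur + cands$weight[i])
    }
    rec(i + 1L, used, cur)
  }
  rec(1L, character(0), 0)
  best
}

# Exhaustive search over pillar orders (assignments fixed) for the
# synteny objective; small instances only.
oracle_best_order_score <- function(layout, genes, w = 1) {
  n <- length(layout$anchors)
  perms <- gtools_permutations(n)
  best <- -Inf
  for (r in seq_len(nrow(perms))) {
    ord <- perms[r, ]
    lay <- pillar_layout(layout$anchors[ord],
                         layout$assign[ord, , drop = FALSE], layout$genome)
    best <- max(best, unname(tcs_objective(lay, genes, w)))
  }
  best
}

# all permutations of 1:n without extra packages
gtools_permutations <- function(n) {
  if (n == 1L) return(matrix(1L, 1, 1))
  sub <- gtools_permutations(n - 1L)
  out <- matrix(0L, 0, n)
  for (k in seq_len(n)) {
    rest <- setdiff(seq_len(n), k)
    out <- rbind(out, cbind(k, matrix(rest[sub], nrow(sub))))
  }
  unname(out)
}

# small deterministic pillar fixture (genome labels match the toy trees)
toy_pillars <- function(n = 4, G = 2, seed = 99) {
  set.seed(seed)
  pattern <- matrix(sample(1:7, n * G, replace = TRUE), n, G)
  breaks <- matrix(FALSE, n, G)
  if (n > 2) breaks[3, 1] <- TRUE
  pillar_set(pattern, genomes = letters[seq_len(G)], breaks = breaks)
}
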