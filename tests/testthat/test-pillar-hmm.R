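# Pillar HMM: tip states, pruning emissions, the forward recursion,
# posteriors, ordering comparison and topology enumeration.

test_that("tip_state maps presence patterns through permutations", {
  expect_equal(state_names()[tip_state(c(1, 1, 1), 4L)], "T")
  expect_equal(state_names()[tip_state(c(0, 1, 0), c(2, 1, 3))], "S1")
  # slots {1,3} present, slot1 -> 3, slot3 -> 2: survivors {3,2} = D23
  expect_equal(state_names()[tip_state(c(1, 0, 1), c(3, 1, 2))], "D23")
  expect_error(tip_state(c(0, 0, 0), 1L), "at least one")
})

test_that("one-tip emissions follow the root transition row", {
  tr <- single_tip_tree("a", 0)
  expect_identical(emission_loglik(7L, 1L, tr, loss_model("null")), 0)
  expect_identical(emission_loglik(1L, 1L, tr, loss_model("null")), -Inf)
  # with time, the emission is the matching entry of exp(Q nu)
  tr2 <- single_tip_tree("a", 0.3)
  sg <- loss_model("g3", sigma = .8, fT = c(.6, .8, 1), fD = c(.5, .7, 1))
  P <- transition_probabilities(build_generator(sg, "root"), 0.3)
  tab <- tip_state_oracle_table()
  for (mask in 1:7) {
    for (p in 1:6) {
      expect_equal(emission_loglik(mask, p, tr2, sg),
                   log(P["T", tab[mask, p]]), tolerance = 1e-12)
    }
  }
})

test_that("pruning equals internal-state enumeration on 2- and 3-tip trees", {
  specs <- list(
    loss_model("null", sigma = 1.2),
    loss_model("g3", sigma = .8, fT = c(.6, .8, 1), fD = c(.5, .7, 1)),
    loss_model("g3root", sigma = .8, fT = c(.6, .8, 1), fD = c(.5, .7, 1),
               tau = 1, beta12 = .3, beta13 = .2)
  )
  tr2 <- wgt_tree("(a:0.12,b:0.2):0.3;")
  tr3 <- wgt_tree("((a:0.1,b:0.15):0.05,c:0.2):0.35;")
  set.seed(7)
  for (spec in specs) {
    for (i in 1:20) {
      patt <- sample(1:7, 3, replace = TRUE)
      st <- sample(1:6, 3, replace = TRUE)
      a2 <- emission_loglik(patt[1:2], st[1:2], tr2, spec)
      b2 <- oracle_emission_2tip(patt[1:2], st[1:2], tr2, spec)
      a3 <- emission_loglik(patt, st, tr3, spec)
      b3 <- oracle_emission_3tip(patt, st, tr3, spec)
      if (is.finite(a2) || is.finite(b2)) {
        expect_equal(a2, b2, tolerance = 1e-10)
      }
      if (is.finite(a3) || is.finite(b3)) {
        expect_equal(a3, b3, tolerance = 1e-10)
      }
    }
  }
})

test_that("forward equals exhaustive hidden-path enumeration", {
  tr2 <- wgt_tree("(a:0.15,b:0.25):0.4;")
  spec <- loss_model("g3", sigma = .8, fT = c(.6, .8, 1), fD = c(.5, .7, 1))
  hmm <- hmm_spec(c(0.3, 0.1))
  sim <- simulate_pillars(tr2, spec, hmm, n_pillars = 3, seed = 5)
  a <- sequence_loglik(sim$pillars, tr2, spec, hmm)
  b <- oracle_forward_paths(sim$pillars, tr2, spec, hmm)
  expect_equal(a, b, tolerance = 1e-8)

  # with a forced break and distinct theta
  ps <- toy_pillars(n = 3, G = 2)
  a <- sequence_loglik(ps, tr2, spec, hmm_spec(c(0.5, 0.05)))
  b <- oracle_forward_paths(ps, tr2, spec, hmm_spec(c(0.5, 0.05)))
  expect_equal(a, b, tolerance = 1e-8)
})

test_that("degenerate forward cases have closed forms", {
  tr2 <- wgt_tree("(a:0.15,b:0.25):0.4;")
  spec <- loss_model("g3", sigma = .8, fT = c(.6, .8, 1), fD = c(.5, .7, 1))
  # single pillar: log of the prior-weighted emission sum
  ps1 <- pillar_set(matrix(c(7L, 3L), 1), genomes = c("a", "b"))
  direct <- log(mean(sapply(0:35, function(z) {
    exp(emission_loglik(c(7L, 3L), c(z %% 6 + 1, z %/% 6 + 1), tr2, spec))
  })))
  expect_equal(sequence_loglik(ps1, tr2, spec, hmm_spec(0.3)), direct,
               tolerance = 1e-9)

  # theta = 0, no breaks: permutations frozen across pillars
  sim <- simulate_pillars(tr2, spec, hmm_spec(0), n_pillars = 4, seed = 2)
  em <- sapply(0:35, function(z) {
    sapply(1:4, function(i) {
      exp(emission_loglik(sim$pillars$pattern[i, ],
                          c(z %% 6 + 1, z %/% 6 + 1), tr2, spec))
    })
  })
  expect_equal(sequence_loglik(sim$pillars, tr2, spec, hmm_spec(0)),
               log(mean(apply(em, 2, prod))), tolerance = 1e-8)

  expect_error(pillar_set(matrix(integer(0), 0, 2)), "at least one")
})

test_that("posteriors normalize and marginal assignments sum to one", {
  tr <- default_study_tree()
  spec <- loss_model("g3", sigma = .8, fT = c(.6, .8, 1), fD = c(.5, .7, 1))
  sim <- simulate_pillars(tr, spec, hmm_spec(0.1), n_pillars = 30, seed = 8)
  po <- posterior_states(sim$pillars, tr, spec, hmm_spec(0.1))
  expect_lt(max(abs(rowSums(po$posterior) - 1)), 1e-8)
  expect_equal(po$loglik,
               sequence_loglik(sim$pillars, tr, spec, hmm_spec(0.1)),
               tolerance = 1e-8)
  fit <- structure(list(loglik = po$loglik, spec = spec, tree = tr,
                        theta = rep(0.1, 4), pillars = sim$pillars),
                   class = "wgt_fit")
  pa <- posterior_subgenome_assignments(fit)
  sums <- apply(pa, c(1, 2, 3), sum)
  expect_lt(max(abs(sums - 1)), 1e-8)
})

test_that("symmetric data under the null model give uniform assignments", {
  # theta = 1 (independent pillars) and a symmetric model: every track is
  # equally likely to come from every subgenome
  tr2 <- wgt_tree("(a:0.15,b:0.25):0.4;")
  spec <- loss_model("null")
  sim <- simulate_pillars(tr2, spec, hmm_spec(1), n_pillars = 10, seed = 3)
  fit <- structure(list(loglik = NA, spec = spec, tree = tr2,
                        theta = c(1, 1), pillars = sim$pillars),
                   class = "wgt_fit")
  pa <- posterior_subgenome_assignments(fit)
  expect_lt(max(abs(pa - 1 / 3)), 1e-9)
})

test_that("biased-loss data recover the planted assignments", {
  tr <- default_study_tree()
  spec <- loss_model("g3", sigma = .8, fT = c(.6, .8, 1), fD = c(.5, .7, 1))
  sim <- simulate_pillars(tr, spec, hmm_spec(0.05), n_pillars = 300,
                          seed = 21)
  fit <- structure(list(loglik = NA, spec = spec, tree = tr,
                        theta = rep(1e-5, 4), pillars = sim$pillars),
                   class = "wgt_fit")
  pa <- posterior_subgenome_assignments(fit)
  perms <- track_permutations()
  hits <- 0L
  total <- 0L
  for (g in 1:4) {
    for (tr_slot in 1:3) {
      modal <- apply(pa[, g, tr_slot, ], 1, which.max)
      truth <- perms[sim$truth$perms[, g], tr_slot]
      hits <- hits + sum(modal == truth)
      total <- total + length(modal)
    }
  }
  expect_gt(hits / total, 0.5)   # majority of tracks correctly assigned
})

test_that("ordering comparison ranks the planted order above shuffles", {
  tr2 <- wgt_tree("(a:0.15,b:0.25):0.4;")
  spec <- loss_model("g3", sigma = .8, fT = c(.6, .8, 1), fD = c(.5, .7, 1))
  sim <- simulate_pillars(tr2, spec, hmm_spec(0.01), n_pillars = 150,
                          seed = 13)
  ps <- sim$pillars
  set.seed(1)
  orderings <- c(list(seq_len(ps$n)),
                 lapply(1:3, function(i) sample(ps$n)))
  res <- compare_orderings(ps, orderings, tr2, spec, hmm_spec(0.01))
  expect_equal(res$ordering[1], 1L)                 # planted order wins
  expect_equal(nrow(res), 4L)

  # identical orderings give identical likelihoods
  res2 <- compare_orderings(ps, list(seq_len(ps$n), seq_len(ps$n)),
                            tr2, spec, hmm_spec(0.01))
  expect_equal(res2$loglik[1], res2$loglik[2])

  # theta = 1 removes the synteny coupling: ordering irrelevant
  res3 <- compare_orderings(ps, orderings, tr2, spec, hmm_spec(1))
  expect_lt(diff(range(res3$loglik)), 1e-8)

  expect_error(compare_orderings(ps, list(c(1L, 1L)), tr2, spec),
               "permutation")
})

test_that("topology enumeration matches double-factorial counts", {
  # (2n-3)!! rooted binary topologies on n tips
  dfact <- function(n) prod(seq(2 * n - 3, 1, by = -2))
  expect_length(enumerate_topologies(letters[1:3]), dfact(3))   # 3
  expect_length(enumerate_topologies(letters[1:4]), dfact(4))   # 15
  expect_length(enumerate_topologies(letters[1:5]), dfact(5))   # 105
  # all pairwise distinct (ape topology comparison, rooted)
  t4 <- lapply(enumerate_topologies(letters[1:4]),
               function(x) ape::read.tree(text = x))
  for (i in seq_along(t4)) {
    for (j in seq_len(i - 1)) {
      expect_false(ape::all.equal.phylo(t4[[i]], t4[[j]],
                                        use.edge.length = FALSE))
    }
  }
  # a fixed sister pair of four tips leaves the three placements
  expect_length(enumerate_topologies(letters[1:4], sister = c("a", "b")), 3L)
  expect_error(enumerate_topologies(letters[1:2]), "at least 3")
})
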