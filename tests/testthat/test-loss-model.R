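# The seven-state loss chain: generators, transition matrices, free
# parameter counts, serialization.

test_that("state space is the seven nonempty loss states", {
  expect_length(state_names(), 7L)
  ms <- state_members()
  expect_true(all(lengths(ms) >= 1))
  expect_true(all(vapply(ms, function(m) all(m %in% 1:3), logical(1))))
  # pairwise distinct subsets
  expect_equal(anyDuplicated(vapply(ms, paste, collapse = ",",
                                    FUN.VALUE = character(1))), 0L)
})

test_that("generator implements the per-copy loss rates", {
  # no bias: exit rates 3 from T, 2 from D, 0 from S
  Q <- build_generator(loss_model("null", sigma = 1))
  expect_equal(unname(-diag(Q)), c(3, 2, 2, 2, 0, 0, 0))
  expect_equal(max(abs(rowSums(Q))), 0)

  # one dominant subgenome: losing the LF copy is the rare T exit
  f1 <- 0.35
  Q1 <- build_generator(loss_model("1dom", fT = c(f1, 1, 1),
                                   fD = c(0.5, 1, 1)))
  expect_equal(Q1["T", "D23"], f1)
  expect_equal(Q1["T", "D12"], 1)
  expect_equal(Q1["T", "D13"], 1)
  expect_lt(Q1["T", "D23"], Q1["T", "D12"])

  # duplicated-level rates scale with sigma * fD
  sg <- loss_model("g3", sigma = 0.8, fT = c(.6, .8, 1), fD = c(.5, .7, 1))
  Qg <- build_generator(sg)
  expect_equal(Qg["D12", "S2"], 0.8 * 0.5)   # lose copy 1 from {1,2}
  expect_equal(Qg["D12", "S1"], 0.8 * 0.7)   # lose copy 2
  expect_equal(Qg["D23", "S2"], 0.8 * 1)     # lose copy 3 (baseline)
})

test_that("two-step root generator assembles arrivals plus sigma losses", {
  sg <- loss_model("g3root", sigma = 0.8, fT = c(.6, .8, 1),
                   fD = c(.5, .7, 1), tau = 0.5, beta12 = 0.1, beta13 = 0.1)
  Q <- build_generator(sg, "root")
  # hand-assembled row: arrivals to T, D12, D13 plus losses to S2, S3
  expect_equal(Q["D23", "T"], 0.5)
  expect_equal(Q["D23", "D12"], 0.1)
  expect_equal(Q["D23", "D13"], 0.1)
  expect_equal(Q["D23", "S2"], 0.8 * 1)
  expect_equal(Q["D23", "S3"], 0.8 * 0.7)
  expect_equal(sum(Q["D23", ]), 0)
  expect_equal(max(abs(rowSums(Q))), 0)
  # non-root branches carry no arrivals
  Qn <- build_generator(sg, "non_root")
  expect_equal(Qn["D23", "T"], 0)
})

test_that("invalid specifications are rejected", {
  expect_error(loss_model("null", fT = c(.5, 1, 1)), "forces")
  expect_error(loss_model("1dom", fT = c(.5, .9, 1)), "fT\\[2\\]")
  expect_error(loss_model("g3", fT = c(1.2, 1, 1)), "\\[0, 1\\]")
  expect_error(loss_model("g3", fT = c(.5, .5, .9)), "baseline")
  expect_error(loss_model("g3", tau = 1), "g3root")
  expect_error(loss_model("g3root", tau = -1), "nonnegative")
  expect_error(loss_model("g3", root_sigma = 1), "g3rootspec")
  expect_error(loss_model("g3", sigma = -1), "nonnegative")
})

test_that("transition probabilities: identity, closed form, absorbing", {
  Q <- build_generator(loss_model("null", sigma = 1))
  expect_equal(transition_probabilities(Q, 0), diag(7),
               ignore_attr = TRUE)
  P <- transition_probabilities(Q, 0.1)
  # exit from T is a competing-exponentials race with total rate 3
  expect_equal(P["T", "T"], exp(-0.3), tolerance = 1e-10)
  # series-expansion oracle for the same entry
  series <- sum(sapply(0:30, function(k) (-0.3)^k / factorial(k)))
  expect_equal(P["T", "T"], series, tolerance = 1e-10)
  expect_equal(P["S1", "S1"], 1)
  expect_error(transition_probabilities(Q, -0.5), "nonnegative")
})

test_that("rows sum to one across branch lengths and variants", {
  specs <- list(
    loss_model("null", sigma = 2),
    loss_model("1dom", sigma = .5, fT = c(.3, 1, 1), fD = c(.9, 1, 1)),
    loss_model("g3", sigma = .8, fT = c(.6, .8, 1), fD = c(.5, .7, 1)),
    loss_model("g3root", sigma = .8, fT = c(.6, .8, 1), fD = c(.5, .7, 1),
               tau = 2, beta12 = .4, beta13 = .1)
  )
  for (spec in specs) {
    for (cls in c("non_root", "root")) {
      Q <- build_generator(spec, cls)
      for (nu in c(1e-3, 0.1, 1, 10, 100)) {
        P <- transition_probabilities(Q, nu)
        expect_lt(max(abs(rowSums(P) - 1)), 1e-10)
        expect_true(all(P >= 0 & P <= 1))
      }
    }
  }
})

test_that("loss-only monotonicity: no probability flows to unreachable states", {
  members <- state_members()
  sg <- loss_model("g3", sigma = .8, fT = c(.6, .8, 1), fD = c(.5, .7, 1))
  P <- transition_probabilities(build_generator(sg), 0.7)
  for (a in 1:7) {
    for (b in 1:7) {
      if (!all(members[[b]] %in% members[[a]])) {
        expect_identical(P[a, b], 0)
      }
    }
  }
  # root-branch arrivals of the two-step model are the one exception
  sr <- loss_model("g3root", sigma = .8, fT = c(.6, .8, 1),
                   fD = c(.5, .7, 1), tau = 1, beta12 = .3, beta13 = .3)
  Pr <- transition_probabilities(build_generator(sr, "root"), 0.7)
  expect_gt(Pr["D23", "T"], 0)
})

test_that("the null chain is exchangeable under subgenome relabelling", {
  # swapping subgenomes 1 and 2 permutes states (D13<->D23, S1<->S2) and
  # must leave the null transition matrix invariant
  P <- transition_probabilities(build_generator(loss_model("null")), 0.4)
  perm <- c(1, 2, 4, 3, 6, 5, 7)
  expect_equal(P[perm, perm], P, ignore_attr = TRUE)
  # and swapping 2 and 3: D12<->D13, S2<->S3
  perm23 <- c(1, 3, 2, 4, 5, 7, 6)
  expect_equal(P[perm23, perm23], P, ignore_attr = TRUE)
})

test_that("semigroup property holds, including near-defective sigma", {
  for (sg in list(loss_model("g3", sigma = .8, fT = c(.6, .8, 1),
                             fD = c(.5, .7, 1)),
                  loss_model("null", sigma = 1.5))) {   # equal T/D exit rates
    Q <- build_generator(sg)
    P1 <- transition_probabilities(Q, 0.3)
    P2 <- transition_probabilities(Q, 0.9)
    P3 <- transition_probabilities(Q, 1.2)
    expect_lt(max(abs(P1 %*% P2 - P3)), 1e-8)
  }
})

test_that("free parameter counts give the printed LRT degrees of freedom", {
  expect_identical(free_parameter_count("null"), 1L)
  expect_identical(free_parameter_count("1dom") - free_parameter_count("null"),
                   2L)
  expect_identical(free_parameter_count("g3") - free_parameter_count("1dom"),
                   2L)
  expect_identical(free_parameter_count("g3rootspec") -
                     free_parameter_count("g3"), 5L)
  expect_identical(free_parameter_count("g3root") -
                     free_parameter_count("g3"), 3L)
})

test_that("model specs round-trip through the key-value config format", {
  specs <- list(
    loss_model("null", sigma = 2),
    loss_model("g3", sigma = .8, fT = c(.6, .8, 1), fD = c(.5, .7, 1)),
    loss_model("g3rootspec", sigma = .8, fT = c(.6, .8, 1),
               fD = c(.5, .7, 1), root_sigma = 1.2,
               root_fT = c(.4, .9, 1), root_fD = c(.3, .6, 1)),
    loss_model("g3root", sigma = .8, fT = c(.6, .8, 1), fD = c(.5, .7, 1),
               tau = 1, beta12 = .3, beta13 = .2, last_subgenome = 2L)
  )
  for (spec in specs) {
    path <- withr::local_tempfile(fileext = ".yaml")
    write_loss_model(spec, path)
    expect_equal(read_loss_model(path), spec)
  }
})

test_that("expanded two-step root chain collapses consistently", {
  sr <- loss_model("g3root", sigma = .8, fT = c(.6, .8, 1),
                   fD = c(.5, .7, 1), tau = 1, beta12 = .3, beta13 = .2)
  Q10 <- g3root_expanded_generator(sr)
  expect_equal(dim(Q10), c(8L, 8L))
  expect_equal(max(abs(rowSums(Q10))), 0)
  # pre-arrival state exits only through the three arrivals
  expect_equal(sum(Q10[8, 1:7] > 0), 3L)
  P <- g3root_root_matrix(sr, 0.5)
  expect_lt(max(abs(rowSums(P) - 1)), 1e-10)
  # instantaneous arrival reduces the root branch to the g3 chain
  fast <- loss_model("g3root", sigma = .8, fT = c(.6, .8, 1),
                     fD = c(.5, .7, 1), tau = 1e7, beta12 = 0, beta13 = 0)
  Pfast <- g3root_root_matrix(fast, 0.5)
  Pg3 <- transition_probabilities(
    build_generator(loss_model("g3", sigma = .8, fT = c(.6, .8, 1),
                               fD = c(.5, .7, 1))), 0.5)
  expect_lt(max(abs(Pfast["D23", ] - Pg3["T", ])), 1e-5)
})
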