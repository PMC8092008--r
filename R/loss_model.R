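#' Specify a model of post-triplication gene loss
#'
#' Constructs a loss-model specification for the seven-state copy-number
#' chain.  Loss rates are relative to the (branch-length absorbed) base
#' rate: a copy of subgenome `g` is lost at rate `fT[g]` from the
#' triplicated state and at rate `sigma * fD[g]` from a duplicated state.
#' Subgenome 3 (MF2, the most fractionated one) is the baseline:
#' `fT[3] = fD[3] = 1` always.
#'
#' Variants form a nested family:
#' \describe{
#'   \item{`"null"`}{no fractionation bias, all `f = 1`; one free parameter
#'     (`sigma`).}
#'   \item{`"1dom"`}{one dominant (less fractionated) subgenome: `fT[1]`,
#'     `fD[1]` free, `fT[2] = fD[2] = 1`.}
#'   \item{`"g3"`}{all three subgenomes distinct: `fT[1:2]`, `fD[1:2]`
#'     free.}
#'   \item{`"g3rootspec"`}{as `"g3"`, with a second, independent parameter
#'     set (`root_sigma`, `root_fT`, `root_fD`) used on the root branch.}
#'   \item{`"g3root"`}{the two-step hexaploidy model: each pillar starts
#'     the root branch in the duplicated state formed by the two
#'     first-arriving subgenomes, and the last subgenome arrives along the
#'     root branch at rate `tau` (to `T`) or jointly with a prior loss at
#'     rates `beta12`/`beta13` (to the two duplicated states that contain
#'     the last subgenome).}
#' }
#'
#' @param variant one of `"null"`, `"1dom"`, `"g3"`, `"g3rootspec"`,
#'   `"g3root"`.
#' @param sigma positive rate multiplier for losses out of duplicated
#'   states.
#' @param fT,fD numeric length-3 fractionation factors in `[0, 1]` for the
#'   triplicated and duplicated levels; the third entry must be 1.
#' @param root_sigma,root_fT,root_fD root-branch parameter set
#'   (`"g3rootspec"` only).
#' @param tau,beta12,beta13 nonnegative arrival rates (`"g3root"` only).
#'   With `last_subgenome = 1` (the default), `beta12` is the arrival rate
#'   into `D12` and `beta13` into `D13`; for other values of
#'   `last_subgenome` they map, in state-index order, onto the two
#'   duplicated states containing the last subgenome.
#' @param last_subgenome which subgenome arrives second (1 = LF default).
#' @return an object of class `"loss_model"`.
#' @examples
#' loss_model("g3", sigma = 0.8, fT = c(0.6, 0.8, 1), fD = c(0.5, 0.7, 1))
#' @export
loss_model <- function(variant = c("null", "1dom", "g3", "g3rootspec", "g3root"),
                       sigma = 1,
                       fT = c(1, 1, 1),
                       fD = c(1, 1, 1),
                       root_sigma = NULL,
                       root_fT = NULL,
                       root_fD = NULL,
                       tau = NULL,
                       beta12 = NULL,
                       beta13 = NULL,
                       last_subgenome = 1L) {
  variant <- match.arg(variant)

  check_f <- function(f, what) {
    if (length(f) != 3L || anyNA(f)) {
      stop(what, " must be a numeric vector of length 3")
    }
    if (any(f < 0) || any(f > 1)) {
      stop(what, " entries must lie in [0, 1]")
    }
    if (abs(f[3] - 1) > 1e-12) {
      stop(what, "[3] is the baseline and must equal 1")
    }
    as.numeric(f)
  }

  if (!is.numeric(sigma) || length(sigma) != 1L || !is.finite(sigma) ||
      sigma < 0) {
    stop("sigma must be a single nonnegative number")
  }

  if (variant == "null") {
    if (any(abs(c(fT, fD) - 1) > 1e-12)) {
      stop("the null variant forces all fractionation factors to 1")
    }
    fT <- fD <- c(1, 1, 1)
  }
  if (variant == "1dom") {
    if (abs(fT[2] - 1) > 1e-12 || abs(fD[2] - 1) > 1e-12) {
      stop("the 1dom variant forces fT[2] = fD[2] = 1")
    }
  }
  fT <- check_f(fT, "fT")
  fD <- check_f(fD, "fD")

  if (variant == "g3rootspec") {
    if (is.null(root_sigma)) root_sigma <- sigma
    if (is.null(root_fT)) root_fT <- fT
    if (is.null(root_fD)) root_fD <- fD
    if (!is.numeric(root_sigma) || root_sigma <= 0) {
      stop("root_sigma must be positive")
    }
    root_fT <- check_f(root_fT, "root_fT")
    root_fD <- check_f(root_fD, "root_fD")
  } else if (!is.null(root_sigma) || !is.null(root_fT) || !is.null(root_fD)) {
    stop("root-specific parameters are only valid for variant 'g3rootspec'")
  }

  if (variant == "g3root") {
    if (is.null(tau)) tau <- 1
    if (is.null(beta12)) beta12 <- 0
    if (is.null(beta13)) beta13 <- 0
    arr <- c(tau = tau, beta12 = beta12, beta13 = beta13)
    if (any(!is.finite(arr)) || any(arr < 0)) {
      stop("tau, beta12 and beta13 must be nonnegative")
    }
    last_subgenome <- as.integer(last_subgenome)
    if (!last_subgenome %in% 1:3) stop("last_subgenome must be 1, 2 or 3")
  } else if (!is.null(tau) || !is.null(beta12) || !is.null(beta13)) {
    stop("arrival rates tau/beta are only valid for variant 'g3root'")
  }

  structure(
    list(variant = variant, sigma = sigma, fT = fT, fD = fD,
         root_sigma = root_sigma, root_fT = root_fT, root_fD = root_fD,
         tau = tau, beta12 = beta12, beta13 = beta13,
         last_subgenome = as.integer(last_subgenome)),
    class = "loss_model"
  )
}

#' @method print loss_model
#' @export
print.loss_model <- function(x, ...) {
  cat("Loss model variant:", x$variant, "\n")
  cat(sprintf("  sigma = %.4g\n", x$sigma))
  cat(sprintf("  fT = (%.4g, %.4g, %.4g)   fD = (%.4g, %.4g, %.4g)\n",
              x$fT[1], x$fT[2], x$fT[3], x$fD[1], x$fD[2], x$fD[3]))
  if (x$variant == "g3rootspec") {
    cat(sprintf("  root: sigma = %.4g, fT = (%.4g, %.4g, %.4g), fD = (%.4g, %.4g, %.4g)\n",
                x$root_sigma, x$root_fT[1], x$root_fT[2], x$root_fT[3],
                x$root_fD[1], x$root_fD[2], x$root_fD[3]))
  }
  if (x$variant == "g3root") {
    cat(sprintf("  arrivals: tau = %.4g, beta12 = %.4g, beta13 = %.4g (last subgenome %d)\n",
                x$tau, x$beta12, x$beta13, x$last_subgenome))
  }
  invisible(x)
}

#' Pre-arrival start state and arrival targets of the two-step model
#'
#' @param last integer 1..3, the last-arriving subgenome.
#' @return list with `start` (state index of the duplicated state holding
#'   the two first subgenomes) and `targets` (state indices, in state
#'   order, of the two duplicated states that include `last`).
#' @noRd
g3root_geometry <- function(last) {
  others <- setdiff(1:3, last)
  start <- state_from_members(others)
  dup_targets <- integer(0)
  for (s in 2:4) {                      # the three D states
    m <- state_members()[[s]]
    if (last %in% m) dup_targets <- c(dup_targets, s)
  }
  list(start = start, targets = sort(dup_targets))
}

#' Build the instantaneous rate generator of a loss model
#'
#' Returns the 7 x 7 rate matrix `Q` over the canonical state order
#' ([state_names()]).  For each surviving copy `g` in state `s`, the rate
#' of losing `g` is `fT[g]` when `s` is triplicated and `sigma * fD[g]`
#' when `s` is duplicated; single-copy states are absorbing.  On the root
#' branch, the `"g3rootspec"` variant swaps in its root parameter set and
#' the `"g3root"` variant adds the arrival transitions out of its
#' pre-arrival start state (at rates `tau`, `beta12`, `beta13`), alongside
#' the ordinary loss transitions out of that state.
#'
#' @param spec a [loss_model()].
#' @param branch_class `"non_root"` (default) or `"root"`.
#' @return a 7 x 7 rate matrix with zero row sums.
#' @examples
#' Q <- build_generator(loss_model("null"))
#' rowSums(Q)   # all zero
#' @export
build_generator <- function(spec, branch_class = c("non_root", "root")) {
  stopifnot(inherits(spec, "loss_model"))
  branch_class <- match.arg(branch_class)

  sigma <- spec$sigma
  fT <- spec$fT
  fD <- spec$fD
  if (branch_class == "root" && spec$variant == "g3rootspec") {
    sigma <- spec$root_sigma
    fT <- spec$root_fT
    fD <- spec$root_fD
  }

  members <- state_members()
  Q <- matrix(0, n_states(), n_states(),
              dimnames = list(state_names(), state_names()))
  for (s in seq_len(n_states())) {
    surv <- members[[s]]
    if (length(surv) == 1L) next               # absorbing
    for (g in surv) {
      tgt <- state_from_members(setdiff(surv, g))
      rate <- if (length(surv) == 3L) fT[g] else sigma * fD[g]
      Q[s, tgt] <- Q[s, tgt] + rate
    }
  }

  if (branch_class == "root" && spec$variant == "g3root") {
    geo <- g3root_geometry(spec$last_subgenome)
    Q[geo$start, 1L] <- Q[geo$start, 1L] + spec$tau
    Q[geo$start, geo$targets[1]] <- Q[geo$start, geo$targets[1]] + spec$beta12
    Q[geo$start, geo$targets[2]] <- Q[geo$start, geo$targets[2]] + spec$beta13
  }

  diag(Q) <- -rowSums(Q)
  Q
}

#' Expanded root-branch chain of the two-step model
#'
#' On the root branch of the `"g3root"` variant the arrival of the last
#' subgenome is a one-off event, so the pre-arrival duplicated state
#' must be distinguished from post-arrival re-entry into the same
#' copy-number state: otherwise a pillar that received the last
#' subgenome and then lost it again would be allowed to "re-arrive".
#' The expanded chain has eight states: the seven ordinary post-arrival
#' states (indices 1..7, no arrival transitions) plus the pre-arrival
#' start `pre-D` (index 8), whose only exits are the three arrival
#' transitions (`tau` to `T`; `beta12`/`beta13` to the duplicated states
#' recording a loss from one of the first two subgenomes before the
#' arrival).  Pillars still in `pre-D` at the end of the root branch
#' never received the arriving subgenome and collapse onto the
#' corresponding duplicated state for the rest of the tree.
#'
#' @param spec a [loss_model()] of variant `"g3root"`.
#' @return an 8 x 8 rate matrix.
#' @export
g3root_expanded_generator <- function(spec) {
  stopifnot(inherits(spec, "loss_model"))
  if (spec$variant != "g3root") {
    stop("the expanded root chain applies to the 'g3root' variant only")
  }
  geo <- g3root_geometry(spec$last_subgenome)
  # post-arrival block: ordinary losses, no arrivals
  base <- loss_model("g3", sigma = spec$sigma, fT = spec$fT, fD = spec$fD)
  Q <- matrix(0, 8L, 8L)
  Q[1:7, 1:7] <- build_generator(base, "non_root")
  diag(Q) <- 0
  labs <- c(state_names(), "preD")
  dimnames(Q) <- list(labs, labs)
  Q[8L, 1L] <- spec$tau
  Q[8L, geo$targets[1]] <- spec$beta12
  Q[8L, geo$targets[2]] <- spec$beta13
  diag(Q) <- -rowSums(Q)
  Q
}

#' Collapse map of the expanded root chain onto the seven states
#' @return integer vector: for each of the 8 states, its 7-state index.
#' @noRd
g3root_collapse_map <- function(spec) {
  c(seq_len(7L), g3root_geometry(spec$last_subgenome)$start)
}

#' Root-branch transition matrix of the two-step model
#'
#' The 7 x 7 matrix used by the pillar likelihood on the root branch of
#' the `"g3root"` variant: the row of the pre-arrival start state is the
#' collapsed distribution of the expanded chain started in `pre-D`; the
#' remaining rows evolve as ordinary post-arrival states.
#'
#' @param spec a `"g3root"` [loss_model()].
#' @param nu root-branch length.
#' @return a 7 x 7 stochastic matrix.
#' @export
g3root_root_matrix <- function(spec, nu) {
  Q10 <- g3root_expanded_generator(spec)
  P10 <- expm_prob(Q10, nu)
  cmap <- g3root_collapse_map(spec)
  collapse <- function(row) {
    out <- numeric(7L)
    for (k in seq_along(row)) out[cmap[k]] <- out[cmap[k]] + row[k]
    out
  }
  P <- matrix(0, 7L, 7L, dimnames = list(state_names(), state_names()))
  for (a in 1:7) P[a, ] <- collapse(P10[a, ])
  start <- g3root_geometry(spec$last_subgenome)$start
  P[start, ] <- collapse(P10[8L, ])
  P
}

#' Root-state prior of a loss model
#'
#' Point mass on `T` for all variants except the two-step `"g3root"`
#' model, whose pillars start the root branch in the duplicated state
#' formed by the two first-arriving subgenomes.
#'
#' @param spec a [loss_model()].
#' @return numeric length-7 probability vector.
#' @export
root_prior <- function(spec) {
  stopifnot(inherits(spec, "loss_model"))
  p <- numeric(n_states())
  if (spec$variant == "g3root") {
    p[g3root_geometry(spec$last_subgenome)$start] <- 1
  } else {
    p[1L] <- 1
  }
  p
}

#' States reachable from each state (transitive closure of Q's support)
#' @noRd
reachability <- function(Q) {
  A <- (Q > 1e-300)
  diag(A) <- TRUE
  R <- A
  for (i in seq_len(n_states())) {
    R2 <- (R %*% A) > 0
    if (identical(R2, R)) break
    R <- R2
  }
  R
}

#' Matrix exponential of a rate generator scaled by a branch length
#'
#' Computes `P = exp(Q * nu)` by eigendecomposition, falling back to
#' scaling-and-squaring ([Matrix::expm()]) when the eigenvector matrix is
#' ill-conditioned (the cascade structure of the loss chain makes `Q`
#' defective for some parameter combinations).  Round-off negatives are
#' clamped to zero, entries outside the reachable set of each state are
#' forced to exact zeros, and rows are renormalized to sum to one.
#'
#' @param Q a 7 x 7 rate matrix from [build_generator()].
#' @param nu nonnegative branch length (in expected-loss units, `alpha * t`).
#' @return a 7 x 7 stochastic matrix.
#' @examples
#' Q <- build_generator(loss_model("null"))
#' P <- transition_probabilities(Q, 0.1)
#' P["T", "T"]    # exp(-0.3): total exit rate 3 from the triplicated state
#' @export
transition_probabilities <- function(Q, nu) {
  stopifnot(is.matrix(Q), nrow(Q) == n_states(), ncol(Q) == n_states())
  if (!is.numeric(nu) || length(nu) != 1L || !is.finite(nu) || nu < 0) {
    stop("branch length nu must be a single nonnegative number")
  }
  P <- expm_prob(Q, nu)
  P[!reachability(Q)] <- 0
  P <- P / rowSums(P)
  dimnames(P) <- dimnames(Q)
  P
}

#' Stochastic matrix exp(Q * nu) for a general rate matrix
#'
#' Eigendecomposition when well-conditioned, scaling-and-squaring
#' ([Matrix::expm()]) otherwise; round-off negatives clamped and rows
#' renormalized.
#' @noRd
expm_prob <- function(Q, nu) {
  k <- nrow(Q)
  if (nu == 0) {
    P <- diag(k)
    dimnames(P) <- dimnames(Q)
    return(P)
  }
  P <- NULL
  ev <- tryCatch(eigen(Q * nu), error = function(e) NULL)
  if (!is.null(ev) && all(abs(Im(ev$values)) < 1e-9)) {
    V <- Re(ev$vectors)
    rc <- tryCatch(rcond(V), error = function(e) 0)
    if (is.finite(rc) && rc > 1e-7) {
      P <- V %*% (exp(Re(ev$values)) * solve(V))
    }
  }
  if (is.null(P)) {
    P <- as.matrix(Matrix::expm(Matrix::Matrix(Q * nu)))
  }
  P[P < 0] <- 0
  P[P > 1] <- 1
  P <- P / rowSums(P)
  dimnames(P) <- dimnames(Q)
  P
}

#' Number of free loss-model parameters of a variant
#'
#' Counts only the loss-chain parameters; branch lengths and the
#' synteny-persistence parameters are shared by every variant and cancel
#' in likelihood-ratio degrees of freedom.
#'
#' @param spec a [loss_model()] or a variant name.
#' @return integer count.
#' @examples
#' free_parameter_count("g3") - free_parameter_count("1dom")  # 2 df
#' @export
free_parameter_count <- function(spec) {
  variant <- if (inherits(spec, "loss_model")) spec$variant else
    match.arg(spec, c("null", "1dom", "g3", "g3rootspec", "g3root"))
  switch(variant,
         null = 1L,          # sigma
         `1dom` = 3L,        # sigma, fT[1], fD[1]
         g3 = 5L,            # sigma, fT[1:2], fD[1:2]
         g3rootspec = 10L,   # g3 twice
         g3root = 8L)        # g3 + tau, beta12, beta13
}

#' Read and write loss-model specifications as YAML key-value files
#'
#' @param spec a [loss_model()].
#' @param path file path.
#' @return `read_loss_model()` returns a [loss_model()];
#'   `write_loss_model()` returns `path` invisibly.
#' @export
write_loss_model <- function(spec, path) {
  stopifnot(inherits(spec, "loss_model"))
  x <- list(variant = spec$variant, sigma = spec$sigma,
            fT1 = spec$fT[1], fT2 = spec$fT[2],
            fD1 = spec$fD[1], fD2 = spec$fD[2])
  if (spec$variant == "g3rootspec") {
    x <- c(x, list(root_sigma = spec$root_sigma,
                   root_fT1 = spec$root_fT[1], root_fT2 = spec$root_fT[2],
                   root_fD1 = spec$root_fD[1], root_fD2 = spec$root_fD[2]))
  }
  if (spec$variant == "g3root") {
    x <- c(x, list(tau = spec$tau, beta12 = spec$beta12,
                   beta13 = spec$beta13,
                   last_subgenome = spec$last_subgenome))
  }
  yaml::write_yaml(x, path)
  invisible(path)
}

#' @rdname write_loss_model
#' @export
read_loss_model <- function(path) {
  x <- yaml::read_yaml(path)
  f3 <- function(a, b) c(a %||% 1, b %||% 1, 1)
  loss_model(
    variant = x$variant,
    sigma = x$sigma %||% 1,
    fT = f3(x$fT1, x$fT2),
    fD = f3(x$fD1, x$fD2),
    root_sigma = x$root_sigma,
    root_fT = if (!is.null(x$root_fT1)) f3(x$root_fT1, x$root_fT2),
    root_fD = if (!is.null(x$root_fD1)) f3(x$root_fD1, x$root_fD2),
    tau = x$tau, beta12 = x$beta12, beta13 = x$beta13,
    last_subgenome = x$last_subgenome %||% 1L
  )
}

`%||%` <- function(a, b) if (is.null(a)) b else a
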