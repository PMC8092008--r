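# Maximum-likelihood fitting of the pillar HMM.
#
# All loss-model parameters, branch lengths and the synteny-persistence
# probabilities are maximized jointly with box-constrained L-BFGS-B.
# Rates (sigma, tau, beta, branch lengths) are optimized on the log
# scale; fractionation factors and theta are optimized raw inside their
# [0, 1] boxes.  Values are clamped inside bounds before evaluation so
# that the finite-difference gradient can probe just outside the box.

LOG_RATE_BOUNDS <- log(c(1e-4, 1e3))
LOG_ARRIVAL_BOUNDS <- log(c(1e-6, 1e5))
LOG_NU_BOUNDS <- log(c(1e-5, 30))
F_BOUNDS <- c(1e-6, 1)
THETA_BOUNDS <- c(1e-5, 1)

#' Names of the free loss parameters of a variant, in packing order
#' @noRd
variant_free_params <- function(variant) {
  switch(variant,
         null = "sigma",
         `1dom` = c("sigma", "fT1", "fD1"),
         g3 = c("sigma", "fT1", "fT2", "fD1", "fD2"),
         g3rootspec = c("sigma", "fT1", "fT2", "fD1", "fD2",
                        "root_sigma", "root_fT1", "root_fT2",
                        "root_fD1", "root_fD2"),
         g3root = c("sigma", "fT1", "fT2", "fD1", "fD2",
                    "tau", "beta12", "beta13"))
}

param_is_log_rate <- function(nm) {
  nm %in% c("sigma", "root_sigma", "tau", "beta12", "beta13")
}

spec_param_get <- function(spec, nm) {
  switch(nm,
         sigma = spec$sigma, fT1 = spec$fT[1], fT2 = spec$fT[2],
         fD1 = spec$fD[1], fD2 = spec$fD[2],
         root_sigma = spec$root_sigma,
         root_fT1 = spec$root_fT[1], root_fT2 = spec$root_fT[2],
         root_fD1 = spec$root_fD[1], root_fD2 = spec$root_fD[2],
         tau = spec$tau, beta12 = spec$beta12, beta13 = spec$beta13)
}

#' Rebuild a loss_model from a named vector of free parameter values
#' @noRd
spec_from_params <- function(variant, vals, last_subgenome = 1L) {
  v <- function(nm, default) if (nm %in% names(vals)) vals[[nm]] else default
  fT <- c(v("fT1", 1), v("fT2", 1), 1)
  fD <- c(v("fD1", 1), v("fD2", 1), 1)
  if (variant == "1dom") { fT[2] <- 1; fD[2] <- 1 }
  args <- list(variant = variant, sigma = v("sigma", 1), fT = fT, fD = fD,
               last_subgenome = last_subgenome)
  if (variant == "g3rootspec") {
    args$root_sigma <- v("root_sigma", 1)
    args$root_fT <- c(v("root_fT1", 1), v("root_fT2", 1), 1)
    args$root_fD <- c(v("root_fD1", 1), v("root_fD2", 1), 1)
  }
  if (variant == "g3root") {
    args$tau <- v("tau", 1)
    args$beta12 <- v("beta12", 0)
    args$beta13 <- v("beta13", 0)
  }
  do.call(loss_model, args)
}

#' Pack / unpack the full optimization vector
#' @noRd
pack_params <- function(spec, tree, theta) {
  nm <- variant_free_params(spec$variant)
  loss <- vapply(nm, function(p) {
    val <- spec_param_get(spec, p)
    if (param_is_log_rate(p)) log(max(val, exp(LOG_ARRIVAL_BOUNDS[1]))) else val
  }, numeric(1))
  c(loss, log(pmax(tree$lengths, exp(LOG_NU_BOUNDS[1]))), theta)
}

unpack_params <- function(x, variant, tree, last_subgenome = 1L,
                          fixed = list()) {
  nm <- variant_free_params(variant)
  k <- length(nm)
  G <- n_genomes(tree)
  loss <- x[seq_len(k)]
  names(loss) <- nm
  vals <- lapply(nm, function(p) {
    v <- loss[[p]]
    if (param_is_log_rate(p)) {
      exp(min(max(v, LOG_ARRIVAL_BOUNDS[1]), LOG_ARRIVAL_BOUNDS[2]))
    } else {
      min(max(v, 0), 1)
    }
  })
  names(vals) <- nm
  if (length(fixed)) vals[names(fixed)] <- fixed
  spec <- spec_from_params(variant, vals, last_subgenome)
  nu <- exp(pmin(pmax(x[k + seq_len(tree$nnode)], LOG_NU_BOUNDS[1]),
                 LOG_NU_BOUNDS[2]))
  theta <- pmin(pmax(x[k + tree$nnode + seq_len(G)], 0), 1)
  list(spec = spec, tree = set_lengths(tree, nu), theta = theta)
}

param_bounds <- function(variant, tree) {
  nm <- variant_free_params(variant)
  lower <- upper <- numeric(0)
  for (p in nm) {
    if (p %in% c("tau", "beta12", "beta13")) {
      lower <- c(lower, LOG_ARRIVAL_BOUNDS[1]); upper <- c(upper, LOG_ARRIVAL_BOUNDS[2])
    } else if (param_is_log_rate(p)) {
      lower <- c(lower, LOG_RATE_BOUNDS[1]); upper <- c(upper, LOG_RATE_BOUNDS[2])
    } else {
      lower <- c(lower, F_BOUNDS[1]); upper <- c(upper, F_BOUNDS[2])
    }
  }
  G <- n_genomes(tree)
  lower <- c(lower, rep(LOG_NU_BOUNDS[1], tree$nnode), rep(THETA_BOUNDS[1], G))
  upper <- c(upper, rep(LOG_NU_BOUNDS[2], tree$nnode), rep(THETA_BOUNDS[2], G))
  list(lower = lower, upper = upper)
}

#' Fit a loss model and the pillar HMM by maximum likelihood
#'
#' Jointly maximizes [sequence_loglik()] over the loss-model parameters
#' of the template's variant, all branch lengths (including the root
#' branch) and the per-genome synteny-persistence probabilities.  The
#' optimizer is box-constrained L-BFGS-B with multiple starts: the first
#' start uses the template's own values, further starts draw uniformly
#' inside the (transformed) parameter box from the seeded generator.
#'
#' @param ps a [pillar_set()].
#' @param tree a [wgt_tree()]; its branch lengths initialize the first
#'   start.
#' @param spec_template a [loss_model()] giving the variant and initial
#'   parameter values.
#' @param hmm_template an [hmm_spec()] giving initial theta.
#' @param n_starts number of optimizer starts (>= 1).
#' @param seed integer seed controlling the random restarts (recorded in
#'   the result).
#' @param init optional full start vector on the internal scale, e.g.
#'   `$par` of a previous fit of a nested variant mapped through
#'   [warm_start()]; used as the first start in place of the template.
#' @param fixed optional named list of loss-model parameters held fixed
#'   at the given values (e.g. `list(tau = 1e4, beta12 = 0, beta13 = 0)`
#'   to profile the two-step model at an instantaneous arrival).
#' @param control passed to [stats::optim()] (defaults: `maxit = 400`,
#'   `factr = 1e7`).
#' @return an object of class `"wgt_fit"`: list with `loglik`, `spec`,
#'   `tree` (fitted branch lengths), `theta`, `convergence` (per start),
#'   `par` (internal-scale optimum), `seed`, and the data (`pillars`).
#' @examples
#' sim <- simulate_pillars(default_study_tree(), loss_model("null"),
#'                         hmm_spec(0.05), n_pillars = 40, seed = 7)
#' f <- fit_pillars(sim$pillars, default_study_tree(), loss_model("null"),
#'                  n_starts = 1, seed = 1)
#' f$loglik
#' @export
fit_pillars <- function(ps, tree, spec_template, hmm_template = hmm_spec(),
                        n_starts = 5, seed = 1, init = NULL,
                        fixed = list(), control = list()) {
  stopifnot(inherits(ps, "pillar_set"))
  if (ps$n < 1L) stop("cannot fit an empty pillar set")
  ws <- hmm_workspace(ps, tree, spec_template, hmm_template)
  ps <- ws$ps
  tree <- ws$tree
  variant <- spec_template$variant
  last <- spec_template$last_subgenome
  breaks_int <- matrix(as.integer(ws$breaks), nrow(ws$breaks))

  negll <- function(x) {
    up <- unpack_params(x, variant, tree, last, fixed)
    Pmats <- branch_transition_matrices(up$tree, up$spec)
    E <- cpp_emissions(ws$combos, Pmats, tree$child1, tree$child2,
                       tree$tip_genome, tree$postorder, tree$root,
                       ws$tip_tab, root_prior(up$spec))
    ll <- cpp_forward(E, ws$combo_idx, up$theta, breaks_int)
    if (!is.finite(ll)) 1e10 else -ll
  }

  bounds <- param_bounds(variant, tree)
  ctrl <- utils::modifyList(list(maxit = 400, factr = 1e7), control)

  starts <- if (is.null(init)) {
    list(pack_params(spec_template, tree, ws$theta))
  } else if (is.list(init)) {
    init
  } else {
    list(init)
  }
  if (n_starts > 1) {
    rng <- local({ set.seed(seed); lapply(seq_len(n_starts - 1), function(i)
      stats::runif(length(bounds$lower), bounds$lower, bounds$upper)) })
    starts <- c(starts, rng)
  }

  best <- NULL
  convergence <- integer(0)
  for (s in seq_along(starts)) {
    opt <- tryCatch(
      stats::optim(starts[[s]], negll, method = "L-BFGS-B",
                   lower = bounds$lower, upper = bounds$upper,
                   control = ctrl),
      error = function(e) NULL)
    if (is.null(opt)) { convergence <- c(convergence, -1L); next }
    convergence <- c(convergence, opt$convergence)
    if (is.null(best) || opt$value < best$value) best <- opt
  }
  if (is.null(best)) stop("optimization failed in every start")
  if (all(convergence != 0L)) {
    warning("no optimizer start reported clean convergence; ",
            "treating the best value found as the fit")
  }

  up <- unpack_params(best$par, variant, tree, last, fixed)
  canon <- canonicalize_subgenomes(up$spec, best$par)
  up$spec <- canon$spec
  best$par <- canon$par
  structure(
    list(loglik = -best$value, spec = up$spec, tree = up$tree,
         theta = up$theta, par = best$par, convergence = convergence,
         n_starts = length(starts), seed = seed, pillars = ps),
    class = "wgt_fit"
  )
}

#' Enforce the canonical subgenome labelling of a fitted model
#'
#' The `"g3"` and `"g3rootspec"` variants are invariant under exchanging
#' subgenome labels 1 and 2 (swapping `fT1` with `fT2` and `fD1` with
#' `fD2` relabels the states without changing the likelihood), so the
#' optimizer can return either mirror image.  The package's convention -
#' subgenome 1 is LF, the least fractionated - resolves the symmetry:
#' when the fitted subgenome 1 loses copies faster than subgenome 2
#' (larger `fT + fD` sum), the labels are swapped.
#' @noRd
canonicalize_subgenomes <- function(spec, par) {
  if (!spec$variant %in% c("g3", "g3rootspec")) {
    return(list(spec = spec, par = par))
  }
  s1 <- spec$fT[1] + spec$fD[1]
  s2 <- spec$fT[2] + spec$fD[2]
  if (spec$variant == "g3rootspec") {
    s1 <- s1 + spec$root_fT[1] + spec$root_fD[1]
    s2 <- s2 + spec$root_fT[2] + spec$root_fD[2]
  }
  if (s1 <= s2) return(list(spec = spec, par = par))
  swap2 <- function(v) c(v[2], v[1], v[3])
  spec$fT <- swap2(spec$fT)
  spec$fD <- swap2(spec$fD)
  if (spec$variant == "g3rootspec") {
    spec$root_fT <- swap2(spec$root_fT)
    spec$root_fD <- swap2(spec$root_fD)
  }
  for (pair in list(c("fT1", "fT2"), c("fD1", "fD2"),
                    c("root_fT1", "root_fT2"), c("root_fD1", "root_fD2"))) {
    if (all(pair %in% names(par))) {
      par[pair] <- par[rev(pair)]
    }
  }
  list(spec = spec, par = par)
}

#' @method print wgt_fit
#' @export
print.wgt_fit <- function(x, ...) {
  cat("Pillar-HMM fit (", x$spec$variant, " variant)\n", sep = "")
  cat(sprintf("  lnL = %.4f over %d pillars, %d genomes\n", x$loglik,
              x$pillars$n, length(x$pillars$genomes)))
  print(x$spec)
  cat("  theta:", paste(sprintf("%.4g", x$theta), collapse = ", "), "\n")
  cat("  branch lengths (nu):",
      paste(sprintf("%s=%.3g", branch_labels(x$tree), x$tree$lengths),
            collapse = ", "), "\n")
  cat("  converged starts:", sum(x$convergence == 0L), "/",
      length(x$convergence), "\n")
  invisible(x)
}

#' Map a nested fit's optimum into a more general variant's start vector
#'
#' Builds an internal-scale start vector for `general_variant` whose loss
#' parameters equal the fitted values of `fit` (absent parameters take
#' the general variant's neutral defaults) and whose branch lengths and
#' theta are carried over.  Starting the general fit here guarantees its
#' likelihood can only improve on the nested one, which keeps
#' likelihood-ratio statistics nonnegative.
#'
#' @param fit a `"wgt_fit"` of the nested variant.
#' @param general_variant the more general variant name.
#' @param arrival optional overrides for the arrival rates of a
#'   `"g3root"` start (defaults place the fit on the instantaneous
#'   arrival plateau, where it reproduces the nested likelihood).
#' @return numeric start vector for [fit_pillars()]'s `init`.
#' @export
warm_start <- function(fit, general_variant, arrival = NULL) {
  stopifnot(inherits(fit, "wgt_fit"))
  nm <- variant_free_params(general_variant)
  vals <- lapply(nm, function(p) {
    v <- spec_param_get(fit$spec, p)
    if (is.null(v)) {
      v <- switch(p, tau = 1e4, beta12 = 1e-6, beta13 = 1e-6,
                  root_sigma = fit$spec$sigma,
                  root_fT1 = fit$spec$fT[1], root_fT2 = fit$spec$fT[2],
                  root_fD1 = fit$spec$fD[1], root_fD2 = fit$spec$fD[2],
                  1)
    }
    v
  })
  names(vals) <- nm
  if (!is.null(arrival)) vals[names(arrival)] <- arrival
  spec <- spec_from_params(general_variant, vals, fit$spec$last_subgenome)
  pack_params(spec, fit$tree, fit$theta)
}

#' Fit a nested and a general variant with a shared warm start
#'
#' Fits the nested variant first, then fits the general variant starting
#' from the nested optimum (plus any extra random starts), so that
#' `lnL_general >= lnL_nested` up to optimizer tolerance.
#'
#' @param ps,tree,hmm_template,seed,control as in [fit_pillars()].
#' @param nested,general variant names (or [loss_model()] templates).
#' @param n_starts extra starts for each fit.
#' @return list with elements `nested` and `general` (two `"wgt_fit"`s).
#' @export
fit_nested_pair <- function(ps, tree, nested, general,
                            hmm_template = hmm_spec(), n_starts = 1,
                            seed = 1, control = list()) {
  spec_n <- if (inherits(nested, "loss_model")) nested else
    loss_model(nested)
  spec_g_variant <- if (inherits(general, "loss_model")) general$variant else
    general
  fit_n <- fit_pillars(ps, tree, spec_n, hmm_template, n_starts = n_starts,
                       seed = seed, control = control)
  inits <- list(warm_start(fit_n, spec_g_variant))
  if (spec_g_variant == "g3root") {
    # the instantaneous-arrival plateau is flat in tau; add starts with
    # arrival time scales spanning the fitted root-branch length
    nu_root <- max(fit_n$tree$lengths[fit_n$tree$root + 1L], 0.05)
    for (mult in c(0.5, 2, 8)) {
      tau0 <- mult / nu_root
      inits <- c(inits, list(
        warm_start(fit_n, spec_g_variant,
                   arrival = list(tau = tau0, beta12 = tau0 / 4,
                                  beta13 = tau0 / 4))))
    }
  }
  fit_g <- fit_pillars(ps, fit_n$tree,
                       spec_from_params(spec_g_variant, list(),
                                        spec_n$last_subgenome),
                       hmm_spec(fit_n$theta), n_starts = n_starts,
                       seed = seed + 1L, init = inits,
                       control = control)
  list(nested = fit_n, general = fit_g)
}
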