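# Nested likelihood-ratio tests between fitted loss-model variants.

# restriction map of the nested model family
NESTING <- list(
  null = c("1dom", "g3", "g3rootspec", "g3root"),
  `1dom` = c("g3", "g3rootspec", "g3root"),
  g3 = c("g3rootspec", "g3root")
)

#' Is `nested` a restriction of `general`?
#'
#' The family is nested as
#' `null < 1dom < g3 < {g3rootspec, g3root}`; the two root extensions are
#' not nested within each other.
#'
#' @param nested,general variant names.
#' @return logical.
#' @export
is_nested_variant <- function(nested, general) {
  nested <- match.arg(nested, names(free_df_table()))
  general <- match.arg(general, names(free_df_table()))
  general %in% NESTING[[nested]]
}

free_df_table <- function() {
  c(null = 1L, `1dom` = 3L, g3 = 5L, g3rootspec = 10L, g3root = 8L)
}

#' Likelihood-ratio test between two nested fits
#'
#' Computes `2 * (lnL_general - lnL_nested)` and its chi-square upper
#' tail with degrees of freedom equal to the difference in free
#' loss-model parameters (branch lengths and theta are common to both
#' variants and cancel).  The chi-square reference follows the study
#' design even though fractionation factors can sit on the boundary
#' `f = 1` under the nested model, which makes the test conservative
#' there; see the package vignette.
#'
#' @param fit_nested,fit_general two `"wgt_fit"` objects whose variants
#'   are nested (in that order).
#' @param tol tolerance below zero allowed for the statistic before it is
#'   treated as an optimizer failure.
#' @return an object of class `"wgt_lrt"`: list with `lnL_nested`,
#'   `lnL_general`, `statistic`, `df`, `p_value`.
#' @examples
#' # df of the printed comparisons
#' free_parameter_count("1dom") - free_parameter_count("null")   # 2
#' free_parameter_count("g3rootspec") - free_parameter_count("g3") # 5
#' @export
lrt <- function(fit_nested, fit_general, tol = 1e-6) {
  stopifnot(inherits(fit_nested, "wgt_fit"), inherits(fit_general, "wgt_fit"))
  vn <- fit_nested$spec$variant
  vg <- fit_general$spec$variant
  if (!is_nested_variant(vn, vg)) {
    stop("variant '", vn, "' is not nested within '", vg, "'")
  }
  stat <- 2 * (fit_general$loglik - fit_nested$loglik)
  if (stat < -tol) {
    stop(sprintf(
      "negative likelihood-ratio statistic (%.3g): the general model fit ",
      stat), "did not reach the nested optimum; refit (e.g. with ",
      "fit_nested_pair()) before testing")
  }
  stat <- max(stat, 0)
  df <- free_parameter_count(vg) - free_parameter_count(vn)
  structure(
    list(lnL_nested = fit_nested$loglik, lnL_general = fit_general$loglik,
         nested = vn, general = vg,
         statistic = stat, df = df,
         p_value = stats::pchisq(stat, df = df, lower.tail = FALSE)),
    class = "wgt_lrt"
  )
}

#' @method print wgt_lrt
#' @export
print.wgt_lrt <- function(x, ...) {
  cat(sprintf("Likelihood-ratio test: %s (lnL %.3f) vs %s (lnL %.3f)\n",
              x$nested, x$lnL_nested, x$general, x$lnL_general))
  cat(sprintf("  2*dlnL = %.4f on %d df, P = %.4g\n",
              x$statistic, x$df, x$p_value))
  invisible(x)
}
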