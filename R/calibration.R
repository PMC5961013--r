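# Phosphoramidite calibration: a computational twin of the mass-spec
# calibration loop. The incorporation model is single-step multiplicative
# (probability proportional to stock ratio x efficiency, no neighbour or
# context effects), the simplest identifiable model whose corrective is a
# per-base stock ratio. predict/fit/solve are exact algebraic inverses.

.check_probs <- function(p, what) {
  if (!is.numeric(p) || is.null(names(p))) stop(what, " must be a named numeric")
  if (any(!is.finite(p)) || any(p < 0)) stop(what, " must be finite and non-negative")
  if (abs(sum(p) - 1) > 1e-8) stop(what, " must sum to 1")
  p
}

.check_pos <- function(x, what) {
  if (!is.numeric(x) || is.null(names(x))) stop(what, " must be a named numeric")
  if (any(!is.finite(x)) || any(x <= 0)) stop(what, " must be positive")
  x
}

#' Predict post-synthesis base composition
#'
#' Effective incorporation probability per base under a stock mix and
#' relative efficiencies: `p_b = stock_b * eff_b / sum(stock * eff)` over
#' whatever base set the vectors share (A/C/G/T for N positions, G/T for K).
#' Scale-invariant in both arguments.
#'
#' @param stock Named positive numeric: stock molar ratios.
#' @param efficiency Named positive numeric over the same bases.
#' @return Named probability vector summing to 1.
#' @examples
#' predict_composition(c(A = 1.5, C = 1.6, G = 1, T = 1.5),
#'                     c(A = 2/3, C = 0.625, G = 1, T = 2/3))  # 0.25 each
#' @export
predict_composition <- function(stock, efficiency) {
  .check_pos(stock, "stock")
  .check_pos(efficiency, "efficiency")
  if (!setequal(names(stock), names(efficiency))) {
    stop("stock and efficiency must cover the same bases")
  }
  efficiency <- efficiency[names(stock)]
  w <- stock * efficiency
  w / sum(w)
}

#' Fit incorporation efficiencies from observed composition
#'
#' Exact inverse of [predict_composition()]: given the observed
#' post-synthesis base probabilities and the stock ratios that produced
#' them, `eff_b = observed_b / stock_b`, normalized so `eff_G = 1`
#' (efficiencies are identifiable only up to scale). An observed probability
#' of 0 for a base present in the stock is outside the model and errors.
#'
#' @param observed Named probability vector (the composition measurement,
#'   standing in for the mass-spec readout).
#' @param stock Named positive numeric over the same bases.
#' @return Named efficiency vector with `G = 1`.
#' @export
fit_efficiencies <- function(observed, stock) {
  .check_probs(observed, "observed")
  .check_pos(stock, "stock")
  if (!setequal(names(observed), names(stock))) {
    stop("observed and stock must cover the same bases")
  }
  stock <- stock[names(observed)]
  if (any(observed == 0)) {
    stop("observed probability of 0 for base(s) ",
         paste(names(observed)[observed == 0], collapse = ", "),
         ": efficiency 0 is outside the model")
  }
  if (!"G" %in% names(observed)) stop("base set must include G for normalization")
  eff <- observed / stock
  eff / eff[["G"]]
}

#' Solve compensating stock ratios
#'
#' Given efficiencies, the stock mix that yields a target composition is
#' `stock_b = target_b / eff_b`, normalized to `G = 1.0` (the conventional
#' ratio notation). By construction
#' `predict_composition(solve_stock_ratios(eff), eff)` equals the target
#' exactly; the default target is equimolar.
#'
#' @param efficiency Named positive efficiency vector (must include G).
#' @param target Named probability vector over the same bases; default
#'   equimolar.
#' @return Named stock ratio vector with `G = 1.0`.
#' @examples
#' solve_stock_ratios(c(A = 2/3, C = 0.625, G = 1, T = 2/3))
#' # A 1.5, C 1.6, G 1.0, T 1.5
#' @export
solve_stock_ratios <- function(efficiency, target = NULL) {
  .check_pos(efficiency, "efficiency")
  if (is.null(target)) {
    target <- stats::setNames(rep(1 / length(efficiency), length(efficiency)),
                              names(efficiency))
  }
  .check_probs(target, "target")
  if (!setequal(names(efficiency), names(target))) {
    stop("efficiency and target must cover the same bases")
  }
  if (!"G" %in% names(efficiency)) stop("base set must include G for normalization")
  target <- target[names(efficiency)]
  stock <- target / efficiency
  stock / stock[["G"]]
}

#' Calibrate stock ratios from a sequenced library
#'
#' Closes the loop: given the bias report of a library synthesized with an
#' assumed (by default equimolar) stock, pool the observed N-slot
#' composition across positions (read-weighted mean; a single efficiency
#' vector is assumed shared across positions), fit efficiencies, and solve
#' the compensating stock ratios for an equimolar target. K is handled
#' analogously from the third-slot G/T fractions.
#'
#' @param report An `nnk_bias_report` from a library whose synthesis used
#'   `assumed_stock_n` / `assumed_stock_k`.
#' @param assumed_stock_n Named positive numeric over A,C,G,T; default
#'   equimolar.
#' @param assumed_stock_k Named positive numeric over G,T; default equimolar.
#' @return An object of class `nnk_calibration` with fields
#'   `efficiency_n`, `efficiency_k`, `solved_stock_n`, `solved_stock_k`,
#'   `observed_n`, `observed_k`, `predicted_n`, `predicted_k`, `residual`
#'   (max absolute deviation of the predicted corrected composition from
#'   the target).
#' @export
calibrate_from_library <- function(report,
                                   assumed_stock_n = c(A = 1, C = 1, G = 1, T = 1),
                                   assumed_stock_k = c(G = 1, T = 1)) {
  stopifnot(inherits(report, "nnk_bias_report"))
  comp <- report$composition
  n_rows <- comp$slot != 3L
  obs_n <- colMeans(as.matrix(comp[n_rows, NNK_N_BASES]))
  obs_k <- colMeans(as.matrix(comp[!n_rows, NNK_K_BASES]))
  obs_k <- obs_k / sum(obs_k)
  if (any(obs_n < 1e-6) || any(obs_k < 1e-6)) {
    stop("degenerate composition: base(s) ",
         paste(names(c(obs_n, obs_k))[c(obs_n, obs_k) < 1e-6], collapse = ", "),
         " essentially absent; cannot fit an efficiency")
  }
  eff_n <- fit_efficiencies(obs_n / sum(obs_n), assumed_stock_n)
  eff_k <- fit_efficiencies(obs_k, assumed_stock_k)
  solved_n <- solve_stock_ratios(eff_n)
  solved_k <- solve_stock_ratios(eff_k)
  pred_n <- predict_composition(solved_n, eff_n)
  pred_k <- predict_composition(solved_k, eff_k)
  structure(
    list(efficiency_n = eff_n, efficiency_k = eff_k,
         solved_stock_n = solved_n, solved_stock_k = solved_k,
         observed_n = obs_n, observed_k = obs_k,
         predicted_n = pred_n, predicted_k = pred_k,
         residual = max(abs(c(pred_n - 1 / length(pred_n),
                              pred_k - 1 / length(pred_k))))),
    class = "nnk_calibration"
  )
}

#' @export
print.nnk_calibration <- function(x, ...) {
  fmt <- function(v) paste(sprintf("%s:%.2f", names(v), v), collapse = " ")
  cat("NNK synthesis calibration\n")
  cat("  fitted efficiencies  N =", fmt(x$efficiency_n), "\n")
  cat("  fitted efficiencies  K =", fmt(x$efficiency_k), "\n")
  cat("  compensating stock   N =", fmt(x$solved_stock_n), "\n")
  cat("  compensating stock   K =", fmt(x$solved_stock_k), "\n")
  cat(sprintf("  residual vs equimolar target: %.2e\n", x$residual))
  invisible(x)
}

#' @export
coef.nnk_calibration <- function(object, ...) {
  c(object$efficiency_n,
    stats::setNames(object$efficiency_k, paste0("K_", names(object$efficiency_k))))
}

#' Predicted composition under a stock mix
#'
#' Applies the fitted efficiencies to a stock mix (by default the solved
#' compensating mix, recovering the target composition).
#'
#' @param object An `nnk_calibration`.
#' @param stock_n Named stock ratios over A,C,G,T.
#' @param stock_k Named stock ratios over G,T.
#' @param ... Unused.
#' @return List with `N` and `K` probability vectors.
#' @export
predict.nnk_calibration <- function(object, stock_n = object$solved_stock_n,
                                    stock_k = object$solved_stock_k, ...) {
  list(N = predict_composition(stock_n, object$efficiency_n),
       K = predict_composition(stock_k, object$efficiency_k))
}
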