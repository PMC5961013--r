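# Adjusted-complexity pooling: mix libraries of different insert lengths so
# each unique peptide ends up with the same expected copy number regardless
# of length. Short libraries saturate their sequence space (transformants
# can exceed 20^n), so "unique clones" is the coupon-collector expectation
# capped by the transformant count -- an explicit interpretation; a plain
# mode equating uniqueness with transformant counts is also provided.

#' Expected number of distinct types drawn
#'
#' Coupon-collector expectation: after `n_draws` uniform draws from
#' `complexity` equally likely types, the expected number of distinct types
#' is `C * (1 - (1 - 1/C)^n)`. Computed in log space so it is accurate for
#' complexities up to and beyond 1e13. For `n << C` this is approximately
#' `n`; it saturates at `C`.
#'
#' @param n_draws Non-negative number of draws (vectorized).
#' @param complexity Number of types, >= 1 (vectorized).
#' @return Expected distinct-type count (double).
#' @examples
#' expected_unique(2, 2)      # 1.5
#' expected_unique(1e6, 20^10)  # ~ 1e6
#' @export
expected_unique <- function(n_draws, complexity) {
  stopifnot(is.numeric(n_draws), all(n_draws >= 0),
            is.numeric(complexity), all(complexity >= 1))
  out <- complexity * -expm1(n_draws * log1p(-1 / complexity))
  out[n_draws == 0] <- 0
  # log1p(-1) = -Inf for C = 1; any positive n then yields exactly 1
  out[complexity == 1 & n_draws > 0] <- 1
  out
}

#' Specify a library pool
#'
#' @param designs List of `nnk_design` objects.
#' @param titer Positive numeric vector: phage per unit volume per member.
#' @param transformants Integer vector (>= 1): transformant counts per
#'   member (the number of clones actually constructed).
#' @return An object of class `nnk_pool_spec`.
#' @export
pool_spec <- function(designs, titer, transformants) {
  stopifnot(is.list(designs), length(designs) >= 1,
            all(vapply(designs, inherits, logical(1), "nnk_design")),
            length(titer) == length(designs),
            length(transformants) == length(designs),
            all(titer > 0), all(transformants >= 1))
  structure(list(designs = designs, titer = as.numeric(titer),
                 transformants = as.numeric(transformants)),
            class = "nnk_pool_spec")
}

#' Mixing proportions for an adjusted-complexity pool
#'
#' Solves for member phage counts `N_i` such that copies per unique clone
#' `N_i / U_i` are equal across members and `sum(N_i)` equals the target,
#' where `U_i` is the member's effective unique-clone count:
#' `expected_unique(transformants_i, 20^n_i)` capped by `transformants_i`
#' (mode `"adjusted"`), or simply `transformants_i` (mode `"plain"`).
#' Volumes are `N_i / titer_i`. Homogeneous in the target: doubling the
#' target doubles every `N_i`.
#'
#' @param spec An [pool_spec()].
#' @param target Total phage count for the pool (> 0).
#' @param mode `"adjusted"` (coupon-collector uniqueness) or `"plain"`.
#' @return An object of class `nnk_pool`: a data.frame with `name`,
#'   `complexity`, `transformants`, `unique_effective`, `phage`, `volume`,
#'   `copies_per_unique`.
#' @examples
#' ds <- list(library_design("L6", 6), library_design("L10", 10))
#' adjusted_mix(pool_spec(ds, titer = c(1e10, 1e10),
#'                        transformants = c(1e7, 1e7)), target = 1e9)
#' @export
adjusted_mix <- function(spec, target, mode = c("adjusted", "plain")) {
  stopifnot(inherits(spec, "nnk_pool_spec"))
  mode <- match.arg(mode)
  if (!is.numeric(target) || length(target) != 1L || target <= 0) {
    stop("target must be a single positive phage count")
  }
  cx <- vapply(spec$designs, theoretical_complexity, numeric(1))
  u <- if (mode == "adjusted") {
    pmin(expected_unique(spec$transformants, cx), spec$transformants)
  } else {
    spec$transformants
  }
  phage <- target * u / sum(u)
  out <- data.frame(
    name = vapply(spec$designs, `[[`, character(1), "name"),
    complexity = cx,
    transformants = spec$transformants,
    unique_effective = u,
    phage = phage,
    volume = phage / spec$titer,
    copies_per_unique = phage / u)
  structure(out, class = c("nnk_pool", "data.frame"),
            target = target, mode = mode)
}

#' @export
print.nnk_pool <- function(x, ...) {
  cat("Adjusted-complexity pool (", attr(x, "mode"), " mode), target ",
      format(attr(x, "target")), " phages\n", sep = "")
  print.data.frame(x, digits = 4)
  invisible(x)
}
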