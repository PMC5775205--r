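#' Right-hand side of the competition dynamics
#'
#' Evaluates \eqn{dx/dt} for any model variant at a state vector. Extinct
#' species (\eqn{x_i = 0}) have derivative exactly 0, so the nonnegative
#' orthant is forward-invariant.
#'
#' @param spec an [lv_model()] specification.
#' @param x nonnegative state vector of length `spec$n`.
#' @return derivative vector of length `spec$n`.
#' @examples
#' spec <- lv_model("crowding", b = c(1, 1), m0 = 0.1, d = 0, alpha = 1, n = 2)
#' lv_rhs(spec, c(0.3, 0.3))  # (0.09, 0.09)
#' @export
lv_rhs <- function(spec, x) {
  stopifnot(inherits(spec, "lv_model"))
  x <- as.numeric(x)
  if (length(x) != spec$n)
    stop("state has length ", length(x), " but spec has n = ", spec$n)
  if (any(x < 0))
    stop("negative density in state vector (contract violation)")
  fl <- variant_flags(spec)
  cpp_rhs(x, spec$b, spec$m0, spec$d, spec$delta,
          if (is.na(spec$epsilon)) 0 else spec$epsilon, spec$alpha,
          fl$square_comp, fl$agg_mort, fl$delta_zero)
}

#' @rdname lv_rhs
#' @details `rhs_crowding()`, `rhs_aggregation()`,
#'   `rhs_nonlinear_competition()` and `rhs_combined()` are variant-checked
#'   aliases of `lv_rhs()`.
#' @export
rhs_crowding <- function(spec, x) {
  if (!spec$variant %in% c("crowding", "classical"))
    stop("spec variant is '", spec$variant,
         "', expected 'crowding' or 'classical'")
  lv_rhs(spec, x)
}

#' @rdname lv_rhs
#' @export
rhs_aggregation <- function(spec, x) {
  if (spec$variant != "aggregation")
    stop("spec variant is '", spec$variant, "', expected 'aggregation'")
  lv_rhs(spec, x)
}

#' @rdname lv_rhs
#' @export
rhs_nonlinear_competition <- function(spec, x) {
  if (spec$variant != "nonlinear_competition")
    stop("spec variant is '", spec$variant,
         "', expected 'nonlinear_competition'")
  lv_rhs(spec, x)
}

#' @rdname lv_rhs
#' @export
rhs_combined <- function(spec, x) {
  if (spec$variant != "combined")
    stop("spec variant is '", spec$variant, "', expected 'combined'")
  lv_rhs(spec, x)
}

#' Jacobian of the dynamics
#'
#' Analytic Jacobian \eqn{J_{ij} = \partial (dx_i/dt) / \partial x_j} of any
#' variant. Although the mortality law \eqn{m(x) = m_0 + d x^\delta} has an
#' \eqn{x^{\delta-1}} derivative that diverges at 0 for \eqn{\delta < 1},
#' the Jacobian differentiates the product \eqn{m(x)\,x}, whose derivative
#' \eqn{m_0 + d(\delta+1)x^\delta} is finite and continuous for every
#' \eqn{\delta > 0}; the analytic form is therefore valid on the whole
#' closed orthant and no finite-difference fallback is needed.
#'
#' @param spec an [lv_model()] specification.
#' @param x nonnegative state vector.
#' @param method `"analytic"` (default) or `"fd"` (central finite
#'   differences, mainly for cross-checking).
#' @param h finite-difference step (method `"fd"`).
#' @return `n x n` Jacobian matrix.
#' @export
lv_jacobian <- function(spec, x, method = c("analytic", "fd"), h = 1e-6) {
  stopifnot(inherits(spec, "lv_model"))
  method <- match.arg(method)
  x <- as.numeric(x)
  if (length(x) != spec$n)
    stop("state has length ", length(x), " but spec has n = ", spec$n)
  n <- spec$n
  if (method == "fd") {
    J <- matrix(0, n, n)
    for (j in seq_len(n)) {
      e <- numeric(n); e[j] <- h
      xm <- pmax(x - e, 0)  # one-sided near the axis, central inside
      J[, j] <- (lv_rhs(spec, x + e) - lv_rhs(spec, xm)) /
        (x[j] + h - xm[j])
    }
    return(J)
  }
  fl <- variant_flags(spec)
  b <- spec$b; m0 <- spec$m0; d <- spec$d
  delta <- spec$delta; eps <- spec$epsilon; al <- spec$alpha
  pow0 <- function(x, p) ifelse(x > 0, x^p, 0)
  Tx  <- if (fl$square_comp) x^2 else x
  J <- matrix(0, n, n)
  for (i in seq_len(n)) {
    comp <- x[i] + sum(al[i, -i] * Tx[-i])
    for (j in seq_len(n)) {
      if (j == i) {
        g <- b[i] * (1 - comp) - b[i] * x[i]
        dm <- if (fl$agg_mort) {
          m0[i] * (1 + eps) * pow0(x[i], eps)
        } else if (fl$delta_zero) {
          m0[i] + d[i]
        } else {
          m0[i] + d[i] * (delta + 1) * pow0(x[i], delta)
        }
        J[i, i] <- g - dm
      } else {
        Tp <- if (fl$square_comp) 2 * x[j] else 1
        J[i, j] <- -b[i] * x[i] * al[i, j] * Tp
      }
    }
  }
  J
}
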