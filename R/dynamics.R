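#' Integrate a competition model forward in time
#'
#' Solves the ODE system with an adaptive Dormand-Prince 5(4) scheme
#' (embedded error control, default `rtol = 1e-8`, `atol = 1e-10`). Output
#' is reported on an even time grid. Tiny negative excursions produced by
#' the integrator are clamped to 0 after each accepted step; a clamp larger
#' than 1e-9 is surfaced as a warning because it would threaten forward
#' invariance of the nonnegative orthant.
#'
#' @param spec an [lv_model()] specification.
#' @param x0 nonnegative initial densities, length `spec$n`.
#' @param horizon integration horizon (time units), default 2000.
#' @param n_out number of output samples (including t = 0), default 501.
#' @param rtol,atol relative/absolute local error tolerances.
#' @param steady_tol if `early_exit = TRUE`, stop once
#'   \eqn{\max_i |dx_i/dt| <} `steady_tol`.
#' @param early_exit stop early at steady state (default `FALSE`; the
#'   returned trajectory is then truncated at the exit time).
#' @param max_steps safety cap on integration steps.
#' @return an object of class `"lv_trajectory"`: list with `times`, `states`
#'   (matrix, one row per time, columns `x1..xn`), `x0`, `spec`,
#'   `spec_fingerprint` and `diagnostics` (steps, max clamp, status).
#' @examples
#' spec <- lv_model("classical", b = 1, m0 = 0.1, n = 1)
#' traj <- lv_integrate(spec, 0.5, horizon = 200)
#' tail(traj$states, 1)  # ~ 0.9 = 1 - m0/b
#' @export
lv_integrate <- function(spec, x0, horizon = 2000, n_out = 501,
                         rtol = 1e-8, atol = 1e-10, steady_tol = 1e-9,
                         early_exit = FALSE, max_steps = 5e6) {
  stopifnot(inherits(spec, "lv_model"))
  x0 <- as.numeric(x0)
  if (length(x0) != spec$n)
    stop("x0 has length ", length(x0), " but spec has n = ", spec$n)
  if (any(x0 < 0)) stop("initial densities must be nonnegative")
  if (horizon <= 0) stop("horizon must be positive")
  n_out <- max(2L, as.integer(n_out))
  times <- seq(0, horizon, length.out = n_out)
  fl <- variant_flags(spec)
  res <- cpp_integrate(x0, times, spec$b, spec$m0, spec$d, spec$delta,
                       if (is.na(spec$epsilon)) 0 else spec$epsilon,
                       spec$alpha, fl$square_comp, fl$agg_mort,
                       fl$delta_zero, rtol, atol, steady_tol, early_exit,
                       max_steps)
  if (res$status == 2)
    stop("integrator step-size underflow at t = ", signif(res$t_end, 6),
         "; last valid state: ",
         paste(signif(res$states[res$n_filled, ], 6), collapse = ", "))
  if (res$status == 3)
    stop("integrator exceeded max_steps at t = ", signif(res$t_end, 6))
  keep <- seq_len(res$n_filled)
  states <- res$states[keep, , drop = FALSE]
  colnames(states) <- paste0("x", seq_len(spec$n))
  if (res$max_clamp > 1e-9)
    warning("negative overshoot of ", signif(res$max_clamp, 3),
            " clamped to 0 (exceeds 1e-9)")
  structure(list(times = times[keep], states = states, x0 = x0, spec = spec,
                 spec_fingerprint = spec_fingerprint(spec),
                 diagnostics = list(steps = res$steps,
                                    max_clamp = res$max_clamp,
                                    status = res$status,
                                    steady_time = res$steady_time,
                                    rtol = rtol, atol = atol)),
            class = "lv_trajectory")
}

#' @export
print.lv_trajectory <- function(x, ...) {
  cat("<lv_trajectory>", x$spec$variant, "model, n =", x$spec$n,
      "species\n")
  cat("  t in [", x$times[1], ",", x$times[length(x$times)], "], ",
      length(x$times), " samples, ", x$diagnostics$steps,
      " integrator steps\n", sep = "")
  fin <- final_state(x)
  cat("  final state:", paste(signif(fin, 5), collapse = ", "), "\n")
  ss <- detect_steady_state(x)
  cat("  steady state:",
      if (ss$reached) sprintf("reached (from t = %g)", ss$time)
      else "not reached", "\n")
  invisible(x)
}

#' @export
as.data.frame.lv_trajectory <- function(x, ...) {
  data.frame(time = x$times, x$states)
}

#' @export
plot.lv_trajectory <- function(x, log = "", ...) {
  cols <- if (x$spec$n <= 8) seq_len(x$spec$n) else rainbow(x$spec$n)
  matplot(x$times, x$states, type = "l", lty = 1, col = cols,
          xlab = "time", ylab = "density", log = log, ...)
  legend("topright", legend = colnames(x$states), col = cols, lty = 1,
         cex = 0.8, bty = "n")
  invisible(x)
}

final_state <- function(traj) traj$states[nrow(traj$states), ]

#' Detect a steady state on a trajectory
#'
#' A trajectory has reached a steady state when
#' \eqn{\max_i |dx_i/dt| <} `tol` at its final sample. The reported index is
#' the earliest sample from which the criterion holds continuously through
#' the end.
#'
#' @param traj an [lv_integrate()] trajectory.
#' @param tol rate tolerance (per unit time), default `1e-7`.
#' @return list with `reached` (flag), `index` (first index of the steady
#'   tail, `NA` when not reached) and `time`.
#' @export
detect_steady_state <- function(traj, tol = 1e-7) {
  stopifnot(inherits(traj, "lv_trajectory"))
  rates <- apply(traj$states, 1L, function(s) max(abs(lv_rhs(traj$spec, s))))
  ok <- rates < tol
  m <- length(ok)
  if (!ok[m]) return(list(reached = FALSE, index = NA_integer_,
                          time = NA_real_))
  idx <- m
  while (idx > 1L && ok[idx - 1L]) idx <- idx - 1L
  list(reached = TRUE, index = idx, time = traj$times[idx])
}

#' Count surviving species
#'
#' Partitions species by final density above/below an extinction threshold.
#' Densities are on the carrying-capacity scale (K = 1); the default
#' threshold 1e-4 marks species at less than 0.01% of K as extinct.
#'
#' @param x a final state vector or an `lv_trajectory` (its last row is
#'   used).
#' @param threshold extinction threshold (strictly greater than counts as
#'   surviving).
#' @return object of class `"lv_survivors"`: list with `threshold`,
#'   `survivors` (indices), `n_survivors`, `final_state`.
#' @export
count_survivors <- function(x, threshold = 1e-4) {
  if (inherits(x, "lv_trajectory")) x <- final_state(x)
  x <- as.numeric(x)
  if (threshold <= 0) stop("threshold must be positive")
  surv <- which(x > threshold)
  structure(list(threshold = threshold, survivors = surv,
                 n_survivors = length(surv), final_state = x),
            class = "lv_survivors")
}

#' @export
print.lv_survivors <- function(x, ...) {
  cat("<lv_survivors>", x$n_survivors, "of", length(x$final_state),
      "species above threshold", x$threshold, "\n")
  cat("  survivors:", if (length(x$survivors))
    paste(x$survivors, collapse = ", ") else "(none)", "\n")
  invisible(x)
}

#' Interior equilibrium by scalar reduction
#'
#' For the crowding variant with all interspecific coefficients equal to 1,
#' the equilibrium conditions \eqn{b_i(1 - S) - m_{i0} = d_i x_i^\delta}
#' (with \eqn{S = \sum_j x_j}) give each positive density as a function of
#' the total:
#' \deqn{x_i(S) = \max(0, (b_i(1-S) - m_{i0})/d_i)^{1/\delta},}
#' so the n-dimensional problem collapses to the scalar fixed point
#' \eqn{\sum_i x_i(S) = S}, solved by bracketed bisection on
#' \eqn{(0, \max_i(1 - m_{i0}/b_i)]} to a bracket width of 1e-12 (the map
#' \eqn{\sum_i x_i(S) - S} is strictly decreasing, so the root is unique).
#'
#' @param spec a crowding-variant [lv_model()] with all off-diagonal
#'   `alpha = 1`, all `d > 0` and `delta > 0`.
#' @param margin stability margin passed to [classify_stability()].
#' @return object of class `"lv_equilibrium"`: `x_star`, `residual`
#'   (max |RHS|), `eigenvalues`, `classification`, `exists`, `S`.
#'   When no state with at least one positive density solves the system,
#'   `exists` is `FALSE` and `x_star` is `NA`.
#' @examples
#' spec <- lv_model("crowding", b = 1, m0 = 0.1, d = 0.5, alpha = 1,
#'                  delta = 1, n = 2)
#' solve_interior_equilibrium(spec)  # x = (0.36, 0.36)
#' @export
solve_interior_equilibrium <- function(spec, margin = 1e-7) {
  stopifnot(inherits(spec, "lv_model"))
  if (!spec$variant %in% c("crowding"))
    stop("scalar reduction requires the crowding variant; use ",
         "lv_integrate() for variant '", spec$variant, "'")
  off <- spec$alpha[row(spec$alpha) != col(spec$alpha)]
  if (spec$n > 1 && any(off != 1))
    stop("scalar reduction requires all alpha_ij = 1; use lv_integrate() ",
         "for general competition matrices")
  if (any(spec$d <= 0))
    stop("scalar reduction requires all d > 0")
  if (spec$delta <= 0)
    stop("scalar reduction requires delta > 0")

  b <- spec$b; m0 <- spec$m0; d <- spec$d; delta <- spec$delta
  x_of_S <- function(S) {
    r <- (b * (1 - S) - m0) / d
    ifelse(r > 0, r^(1 / delta), 0)
  }
  Smax <- max(1 - m0 / b)
  if (Smax <= 0)
    return(structure(list(x_star = rep(NA_real_, spec$n), residual = NA_real_,
                          eigenvalues = NULL, classification = NA_character_,
                          exists = FALSE, S = NA_real_),
                     class = "lv_equilibrium"))
  g <- function(S) sum(x_of_S(S)) - S
  lo <- 1e-15; hi <- Smax
  if (g(lo) <= 0)  # no positive density anywhere
    return(structure(list(x_star = rep(NA_real_, spec$n), residual = NA_real_,
                          eigenvalues = NULL, classification = NA_character_,
                          exists = FALSE, S = NA_real_),
                     class = "lv_equilibrium"))
  # g(Smax) = -Smax < 0, g decreasing: bisection bracket is guaranteed
  while (hi - lo > 1e-12) {
    mid <- (lo + hi) / 2
    if (g(mid) > 0) lo <- mid else hi <- mid
  }
  S <- (lo + hi) / 2
  x_star <- x_of_S(S)
  residual <- max(abs(lv_rhs(spec, x_star)))
  J <- lv_jacobian(spec, x_star)
  ev <- eigen(J, only.values = TRUE)$values
  cls <- classify_stability(ev, margin = margin)
  structure(list(x_star = x_star, residual = residual, eigenvalues = ev,
                 classification = cls, exists = TRUE, S = S),
            class = "lv_equilibrium")
}

#' @export
print.lv_equilibrium <- function(x, ...) {
  if (!x$exists) {
    cat("<lv_equilibrium> no positive equilibrium exists\n")
    return(invisible(x))
  }
  cat("<lv_equilibrium>", x$classification, "\n")
  cat("  x* =", paste(signif(x$x_star, 6), collapse = ", "), "\n")
  cat("  residual =", format(x$residual, digits = 3),
      " max Re(lambda) =", format(max(Re(x$eigenvalues)), digits = 4), "\n")
  invisible(x)
}

#' Classify local stability from Jacobian eigenvalues
#'
#' An equilibrium is `stable` when the largest real part of the Jacobian
#' spectrum is below `-margin`, `unstable` when above `+margin`, and
#' `marginal` inside the band (e.g. along a line of equilibria in the
#' degenerate classical case with equal parameters and alpha = 1).
#'
#' @param x either a complex eigenvalue vector, an `lv_equilibrium`, or a
#'   state vector (then `spec` is required and the Jacobian is computed at
#'   that state).
#' @param spec an [lv_model()] (only needed when `x` is a state vector).
#' @param margin half-width of the marginal band, default `1e-7`.
#' @return one of `"stable"`, `"unstable"`, `"marginal"`.
#' @export
classify_stability <- function(x, spec = NULL, margin = 1e-7) {
  ev <- if (inherits(x, "lv_equilibrium")) {
    x$eigenvalues
  } else if (is.complex(x)) {
    x
  } else if (!is.null(spec)) {
    eigen(lv_jacobian(spec, as.numeric(x)), only.values = TRUE)$values
  } else {
    as.complex(x)
  }
  mr <- max(Re(ev))
  if (mr < -margin) "stable" else if (mr > margin) "unstable" else "marginal"
}

#' Package an equilibrium state with residual, spectrum and classification
#'
#' Helper that evaluates a candidate equilibrium state under a model:
#' computes the RHS residual, Jacobian eigenvalues and stability class.
#'
#' @param spec an [lv_model()].
#' @param x state vector.
#' @param margin stability margin.
#' @return an `"lv_equilibrium"` object.
#' @export
lv_equilibrium_at <- function(spec, x, margin = 1e-7) {
  x <- as.numeric(x)
  residual <- max(abs(lv_rhs(spec, x)))
  ev <- eigen(lv_jacobian(spec, x), only.values = TRUE)$values
  structure(list(x_star = x, residual = residual, eigenvalues = ev,
                 classification = classify_stability(ev, margin = margin),
                 exists = TRUE, S = sum(x)),
            class = "lv_equilibrium")
}
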