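#' Zero isocline of one species in the two-species phase plane
#'
#' Points where the per-capita growth of species `i` vanishes:
#' \deqn{b_i (1 - x_i - \alpha_{ij} x_j) = m_{i0} + d_i x_i^\delta.}
#' For species 1 (zero condition solved for \eqn{x_2}) the curve is closed
#' form for every \eqn{\delta}, because the crowding term only involves the
#' species' own density \eqn{x_1}. For species 2 the zero condition is
#' solved for \eqn{x_2} at each grid value of \eqn{x_1}: closed form when
#' \eqn{d_2 = 0} (classical straight line) or \eqn{\delta = 1}, otherwise by
#' bracketed root-finding on \eqn{x_2 \in [0, 2]} (the condition is strictly
#' decreasing in \eqn{x_2}). Grid points with no nonnegative solution are
#' omitted.
#'
#' @param spec a 2-species [lv_model()] of variant `crowding` or
#'   `classical`.
#' @param species 1 or 2.
#' @param x1_grid grid of \eqn{x_1} values, default 141 points on [0, 1.4].
#' @return object of class `"lv_isocline"`: list with `species`, `points`
#'   (data frame `x1`, `x2`, sorted by `x1`), `closed_form` flag.
#' @export
zero_isocline <- function(spec, species = 1,
                          x1_grid = seq(0, 1.4, length.out = 141)) {
  stopifnot(inherits(spec, "lv_model"))
  if (spec$n != 2) stop("isoclines are defined for 2-species models only")
  if (!spec$variant %in% c("crowding", "classical"))
    stop("isoclines implemented for linear-competition variants ",
         "(crowding/classical)")
  species <- as.integer(species)
  if (!species %in% 1:2) stop("species must be 1 or 2")
  x1_grid <- sort(as.numeric(x1_grid))
  if (any(x1_grid < 0)) stop("grid must be nonnegative")
  b <- spec$b; m0 <- spec$m0; d <- spec$d; delta <- spec$delta
  a12 <- spec$alpha[1, 2]; a21 <- spec$alpha[2, 1]
  pow0 <- function(x, p) ifelse(x > 0, x^p, 0)

  if (species == 1L) {
    # b1(1 - x1 - a12 x2) = m10 + d1 x1^delta, explicit in x2
    crowd <- if (spec$delta == 0) d[1] else d[1] * pow0(x1_grid, delta)
    x2 <- (b[1] * (1 - x1_grid) - m0[1] - crowd) / (b[1] * a12)
    keep <- x2 >= 0
    pts <- data.frame(x1 = x1_grid[keep], x2 = x2[keep])
    closed <- TRUE
  } else {
    closed <- d[2] == 0 || delta == 1 || delta == 0
    if (d[2] == 0 || delta == 0) {
      dd <- if (delta == 0) d[2] else 0
      x2 <- 1 - (m0[2] + dd) / b[2] - a21 * x1_grid
    } else if (delta == 1) {
      x2 <- (b[2] * (1 - a21 * x1_grid) - m0[2]) / (b[2] + d[2])
    } else {
      # g(x2) = b2(1 - x2 - a21 x1) - m20 - d2 x2^delta, decreasing in x2
      x2 <- vapply(x1_grid, function(x1) {
        g <- function(z) b[2] * (1 - z - a21 * x1) - m0[2] -
          d[2] * pow0(z, delta)
        if (g(0) < 0) return(NA_real_)
        uniroot(g, c(0, 2), tol = 1e-12)$root
      }, numeric(1))
    }
    keep <- !is.na(x2) & x2 >= 0
    pts <- data.frame(x1 = x1_grid[keep], x2 = x2[keep])
  }
  structure(list(species = species, points = pts, closed_form = closed),
            class = "lv_isocline")
}

#' @export
print.lv_isocline <- function(x, ...) {
  cat("<lv_isocline> species", x$species, "-", nrow(x$points), "points",
      if (x$closed_form) "(closed form)" else "(root-finding)", "\n")
  invisible(x)
}

#' Classify the two-species phase plane into the four classical cases
#'
#' Evaluates the textbook isocline-intercept comparisons
#' \eqn{K_2} vs \eqn{K_1/\alpha_{12}} and \eqn{K_1} vs
#' \eqn{K_2/\alpha_{21}} and maps the sign pattern to the labels:
#' \describe{
#'   \item{a}{\eqn{K_2 < K_1/\alpha_{12}}, \eqn{K_1 > K_2/\alpha_{21}}
#'     (species 1 excludes 2)}
#'   \item{b}{\eqn{K_2 > K_1/\alpha_{12}}, \eqn{K_1 < K_2/\alpha_{21}}
#'     (species 2 excludes 1)}
#'   \item{c}{both "<" (stable coexistence)}
#'   \item{d}{both ">" (bistable exclusion)}
#' }
#' An equality within `1e-12` is a degenerate configuration and yields
#' label `"degenerate"`.
#'
#' @param alpha 2x2 competition matrix (or an `lv_model`, from which `alpha`
#'   and `K` are taken).
#' @param K carrying capacities, default `c(1, 1)`.
#' @return object of class `"lv_case"`: list with `label` and the two
#'   inequalities with their truth values.
#' @examples
#' classify_case(matrix(c(1, 1.2, 0.8, 1), 2))  # case "a"
#' @export
classify_case <- function(alpha, K = c(1, 1)) {
  if (inherits(alpha, "lv_model")) {
    if (alpha$n != 2) stop("case classification needs a 2-species model")
    K <- alpha$K
    alpha <- alpha$alpha
  }
  stopifnot(is.matrix(alpha), all(dim(alpha) == 2), length(K) == 2,
            all(K > 0), all(alpha[c(2, 3)] > 0))
  s1 <- K[2] - K[1] / alpha[1, 2]   # sign of K2 - K1/a12
  s2 <- K[1] - K[2] / alpha[2, 1]   # sign of K1 - K2/a21
  tol <- 1e-12
  if (abs(s1) < tol || abs(s2) < tol) {
    label <- "degenerate"
  } else if (s1 < 0 && s2 > 0) {
    label <- "a"
  } else if (s1 > 0 && s2 < 0) {
    label <- "b"
  } else if (s1 < 0 && s2 < 0) {
    label <- "c"
  } else {
    label <- "d"
  }
  structure(list(label = label,
                 inequalities = list(
                   K2_lt_K1_over_a12 = s1 < 0,
                   K1_lt_K2_over_a21 = s2 < 0),
                 margins = c(s1 = s1, s2 = s2)),
            class = "lv_case")
}

#' @export
print.lv_case <- function(x, ...) {
  cat("<lv_case>", x$label, "\n")
  cat("  K2 < K1/a12:", x$inequalities$K2_lt_K1_over_a12,
      " K1 < K2/a21:", x$inequalities$K1_lt_K2_over_a21, "\n")
  invisible(x)
}

#' Equilibrium displacement when the crowding effect is switched on
#'
#' Computes the attractor E1 of the system with crowding coefficient
#' `d_low` (usually 0, the classical system) and E2 with `d_high`, both as
#' the long-time state of an integration from `x0`, each packaged with its
#' stability classification. In exclusion cases E1 is the boundary attractor
#' actually reached from `x0`, not the unstable interior crossing.
#'
#' @param spec a 2-species crowding-variant [lv_model()] (its `d` is
#'   overridden by `d_low` / `d_high`).
#' @param d_low crowding coefficient of the reference system, default 0.
#' @param d_high crowding coefficient of the perturbed system.
#' @param x0 initial densities, default `c(0.5, 0.2)`.
#' @param horizon,steady_tol integration controls; non-convergence (steady
#'   state not reached) is an error with diagnostics.
#' @return object of class `"lv_eqpair"`: `E1`, `E2`
#'   (both `"lv_equilibrium"`), `displacement` (Euclidean distance).
#' @export
equilibrium_shift <- function(spec, d_low = 0, d_high = 0.5,
                              x0 = c(0.5, 0.2), horizon = 2000,
                              steady_tol = 1e-7) {
  stopifnot(inherits(spec, "lv_model"))
  if (spec$n != 2) stop("equilibrium_shift is a 2-species analysis")
  if (!spec$variant %in% c("crowding", "classical"))
    stop("equilibrium_shift requires the crowding/classical variant")
  run <- function(dval) {
    s <- spec
    s$variant <- if (all(dval == 0)) "classical" else "crowding"
    s$d <- rep_len(dval, 2)
    traj <- lv_integrate(s, x0, horizon = horizon)
    ss <- detect_steady_state(traj, tol = steady_tol)
    if (!ss$reached)
      stop("no steady state within horizon ", horizon, " for d = ",
           dval[1], "; final max |RHS| = ",
           signif(max(abs(lv_rhs(s, final_state(traj)))), 3))
    lv_equilibrium_at(s, final_state(traj))
  }
  E1 <- run(d_low)
  E2 <- run(d_high)
  structure(list(E1 = E1, E2 = E2,
                 displacement = sqrt(sum((E1$x_star - E2$x_star)^2)),
                 d_low = d_low, d_high = d_high, x0 = x0),
            class = "lv_eqpair")
}

#' @export
print.lv_eqpair <- function(x, ...) {
  cat("<lv_eqpair> crowding switched from d =", x$d_low, "to", x$d_high,
      "\n")
  cat("  E1 =", paste(signif(x$E1$x_star, 5), collapse = ", "),
      sprintf("(%s)", x$E1$classification), "\n")
  cat("  E2 =", paste(signif(x$E2$x_star, 5), collapse = ", "),
      sprintf("(%s)", x$E2$classification), "\n")
  cat("  displacement =", signif(x$displacement, 5), "\n")
  invisible(x)
}
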