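#' Model variants
#'
#' Variant tags accepted by [lv_model()]:
#' \describe{
#'   \item{classical}{Lotka-Volterra competition with constant per-capita
#'     mortality \eqn{m_{i0}} (equivalently, the crowding model with all
#'     \eqn{d_i = 0}).}
#'   \item{crowding}{mortality \eqn{m_i = m_{i0} + d_i x_i^\delta} rises with
#'     the species' own density.}
#'   \item{aggregation}{mortality term \eqn{m_{i0} x_i^{1+\varepsilon}},
#'     a mortality-only rendering of aggregation-type density dependence.}
#'   \item{nonlinear_competition}{interspecific competition enters squared
#'     (\eqn{\alpha_{ij} x_j^2}, own density linear), constant mortality.}
#'   \item{combined}{squared interspecific competition together with the
#'     crowding mortality law.}
#' }
#' @name lv_variants
#' @keywords internal
NULL

LV_VARIANTS <- c("classical", "crowding", "aggregation",
                 "nonlinear_competition", "combined")

#' Construct a competition model specification
#'
#' Builds a fully validated n-species model specification. Carrying
#' capacities are fixed at \eqn{K_i = 1}, so densities are on a 0--1 scale
#' and the competition matrix has unit diagonal.
#'
#' The dynamics for species \eqn{i} are
#' \deqn{dx_i/dt = b_i x_i (1 - x_i - \sum_{j \ne i} \alpha_{ij} T(x_j))
#'       - M_i(x_i)}
#' where \eqn{T(x) = x} (linear competition) or \eqn{x^2} (squared,
#' variants \code{nonlinear_competition} and \code{combined}) and
#' \eqn{M_i} is the variant's mortality term (see [lv_variants]).
#'
#' @param variant one of `r paste0('"', LV_VARIANTS, '"', collapse = ", ")`.
#' @param b per-species birth rates (recycled to `n`); must be positive.
#' @param m0 baseline (density-independent) mortality rates, `>= 0`.
#' @param d crowding coefficients, `>= 0`. Forced/required to be 0 for the
#'   classical, aggregation and nonlinear_competition variants.
#' @param alpha interspecific competition: either a single scalar applied to
#'   every off-diagonal entry, or a full `n x n` matrix whose diagonal must
#'   equal 1 exactly.
#' @param delta crowding exponent \eqn{\delta > 0}; `delta = 0` is accepted
#'   as an explicit degenerate mode in which mortality is the constant
#'   `m0 + d`.
#' @param epsilon aggregation exponent increment \eqn{\varepsilon > 0}
#'   (aggregation variant only).
#' @param n number of species; inferred from the parameter vectors or
#'   `alpha` when omitted.
#' @return an object of class `"lv_model"`: a list with elements `variant`,
#'   `n`, `b`, `m0`, `d`, `alpha`, `delta`, `epsilon`, `K`.
#' @examples
#' spec <- lv_model("crowding", b = 1, m0 = 0.1, d = 0.5,
#'                  alpha = matrix(c(1, 1.2, 0.8, 1), 2), delta = 1)
#' spec
#' @seealso [lv_validate()] for advisory range checks, [lv_rhs()],
#'   [lv_integrate()]
#' @export
lv_model <- function(variant = c("crowding", "classical", "aggregation",
                                 "nonlinear_competition", "combined"),
                     b, m0, d = 0, alpha = 1, delta = 1, epsilon = NULL,
                     n = NULL) {
  variant <- match.arg(variant)
  if (is.null(n)) {
    n <- max(length(b), length(m0), length(d),
             if (is.matrix(alpha)) nrow(alpha) else 1L)
  }
  n <- as.integer(n)
  if (n < 1L) stop("need at least one species")
  b  <- rep_len(as.numeric(b),  n)
  m0 <- rep_len(as.numeric(m0), n)
  d  <- rep_len(as.numeric(d),  n)
  if (anyNA(c(b, m0, d))) stop("parameters must not contain NA")
  if (any(b <= 0)) stop("birth rates b must be positive")
  if (any(m0 < 0)) stop("baseline mortality m0 must be nonnegative")
  if (any(d < 0)) stop("crowding coefficients d must be nonnegative")

  if (is.matrix(alpha)) {
    if (nrow(alpha) != n || ncol(alpha) != n)
      stop("alpha must be ", n, "x", n, ", got ",
           nrow(alpha), "x", ncol(alpha))
    if (any(diag(alpha) != 1))
      stop("alpha diagonal must be exactly 1 (intraspecific competition ",
           "is fixed by K = 1)")
    if (any(alpha < 0)) stop("alpha entries must be nonnegative")
    alpha <- unname(alpha)
  } else {
    a <- as.numeric(alpha)
    if (length(a) != 1L || is.na(a) || a < 0)
      stop("scalar alpha must be a single nonnegative number")
    alpha <- matrix(a, n, n)
    diag(alpha) <- 1
  }

  delta <- as.numeric(delta)
  if (length(delta) != 1L || is.na(delta) || delta < 0)
    stop("delta must be a single nonnegative number (0 = degenerate ",
         "constant-mortality mode)")

  if (variant == "aggregation") {
    if (is.null(epsilon))
      stop("aggregation variant requires epsilon")
    epsilon <- as.numeric(epsilon)
    if (length(epsilon) != 1L || is.na(epsilon) || epsilon < 0)
      stop("epsilon must be a single nonnegative number")
    if (any(d != 0))
      stop("aggregation variant does not use d; supply d = 0")
  } else {
    if (!is.null(epsilon))
      stop("epsilon is only meaningful for the aggregation variant")
    epsilon <- NA_real_
  }
  if (variant %in% c("classical", "nonlinear_competition") && any(d != 0))
    stop("variant '", variant, "' has no crowding term; supply d = 0 ",
         "(use 'crowding' or 'combined' for d > 0)")

  structure(list(variant = variant, n = n, b = b, m0 = m0, d = d,
                 alpha = alpha, delta = delta, epsilon = epsilon,
                 K = rep(1, n)),
            class = "lv_model")
}

# variant -> integrator flags
variant_flags <- function(spec) {
  list(square_comp = spec$variant %in% c("nonlinear_competition", "combined"),
       agg_mort = spec$variant == "aggregation",
       delta_zero = !is.na(spec$delta) && spec$delta == 0)
}

#' @export
print.lv_model <- function(x, ...) {
  cat("<lv_model> variant:", x$variant, " n =", x$n, "\n")
  cat("  b  =", paste(signif(x$b, 4), collapse = ", "), "\n")
  cat("  m0 =", paste(signif(x$m0, 4), collapse = ", "), "\n")
  if (x$variant %in% c("crowding", "combined"))
    cat("  d  =", paste(signif(x$d, 4), collapse = ", "),
        "  delta =", x$delta,
        if (x$delta == 0) "(degenerate constant-mortality mode)" else "",
        "\n")
  if (x$variant == "aggregation")
    cat("  epsilon =", x$epsilon, "\n")
  off <- x$alpha[row(x$alpha) != col(x$alpha)]
  if (length(off) && length(unique(off)) == 1L) {
    cat("  alpha[i,j] =", off[1], "(all off-diagonal)\n")
  } else if (length(off)) {
    cat("  alpha:\n")
    print(signif(x$alpha, 4))
  }
  viol <- lv_validate(x)
  nw <- sum(viol$severity == "warning")
  if (nw > 0)
    cat("  note:", nw, "advisory range warning(s); see lv_validate()\n")
  invisible(x)
}

#' @export
summary.lv_model <- function(object, ...) {
  print(object)
  v <- lv_validate(object)
  if (nrow(v)) {
    cat("validation report:\n")
    print(v, row.names = FALSE)
  } else cat("validation report: clean\n")
  invisible(v)
}

#' Per-capita crowding mortality rate
#'
#' Evaluates the crowding mortality law \eqn{m(x) = m_0 + d\, x^\delta},
#' with the conventions \eqn{0^\delta = 0} for any \eqn{\delta > 0} and,
#' in the explicit degenerate mode \eqn{\delta = 0},
#' \eqn{m(x) = m_0 + d} (constant).
#'
#' @param x density (vectorized); must be nonnegative.
#' @param m0 baseline mortality.
#' @param d crowding coefficient.
#' @param delta crowding exponent.
#' @return per-capita mortality rate, same length as `x`.
#' @examples
#' mortality_rate(0.6, m0 = 0.1, d = 0.5, delta = 1)  # 0.4
#' @export
mortality_rate <- function(x, m0, d, delta = 1) {
  if (any(x < 0))
    stop("negative density: x^delta is undefined for fractional delta")
  if (delta < 0) stop("delta must be nonnegative")
  if (delta == 0) return(rep_len(m0 + d, length(x)))
  xp <- ifelse(x > 0, x^delta, 0)
  m0 + d * xp
}

#' Advisory and structural validation of a model specification
#'
#' Checks a specification against the parameter ranges used in the source
#' simulation study. Range violations are reported as warnings (several of
#' the study's own figure parameterizations exceed the stated
#' \eqn{\alpha_{ij} \le 1} range, so the ranges are advisory); negative
#' parameters and dimension problems are errors. The function reports and
#' never throws; [lv_model()] is the place where structural errors stop.
#'
#' Ranges checked: \eqn{b_i \in [1, 2]}, off-diagonal
#' \eqn{\alpha_{ij} \in (0, 1]}, \eqn{0 < m_{i0} + d_i \le 1},
#' \eqn{\delta \in [0, 5]}.
#'
#' @param spec an `lv_model`.
#' @return data frame with columns `field`, `rule`, `severity`, `message`;
#'   zero rows when the specification is clean.
#' @export
lv_validate <- function(spec) {
  stopifnot(inherits(spec, "lv_model"))
  out <- list()
  add <- function(field, rule, severity, message)
    out[[length(out) + 1L]] <<- data.frame(field = field, rule = rule,
                                           severity = severity,
                                           message = message)
  n <- spec$n
  if (length(spec$b) != n || length(spec$m0) != n || length(spec$d) != n ||
      !all(dim(spec$alpha) == n))
    add("n", "dimension", "error", "parameter dimensions disagree with n")
  if (any(spec$b < 1 | spec$b > 2))
    add("b", "1 <= b <= 2", "warning",
        sprintf("b outside [1,2] for species %s",
                paste(which(spec$b < 1 | spec$b > 2), collapse = ",")))
  off <- spec$alpha[row(spec$alpha) != col(spec$alpha)]
  if (n > 1 && any(off <= 0 | off > 1))
    add("alpha", "0 < alpha_ij <= 1", "warning",
        "off-diagonal alpha outside (0,1] (advisory range)")
  md <- spec$m0 + spec$d
  if (spec$variant %in% c("crowding", "combined", "classical") &&
      any(md <= 0 | md > 1))
    add("m0+d", "0 < m0 + d <= 1", "warning",
        sprintf("m0 + d outside (0,1] for species %s",
                paste(which(md <= 0 | md > 1), collapse = ",")))
  if (!is.na(spec$delta) && (spec$delta < 0 || spec$delta > 5))
    add("delta", "0 <= delta <= 5", "warning", "delta outside swept range")
  if (!is.na(spec$delta) && spec$delta == 0 &&
      spec$variant %in% c("crowding", "combined"))
    add("delta", "delta > 0", "warning",
        "delta = 0 degenerate mode: mortality is the constant m0 + d")
  if (length(out)) do.call(rbind, out)
  else data.frame(field = character(), rule = character(),
                  severity = character(), message = character())
}

# Stable fingerprint of a spec (used to tag trajectories). No hashing
# package is assumed; md5 of the canonical serialization via tools::md5sum.
spec_fingerprint <- function(spec) {
  tf <- tempfile()
  on.exit(unlink(tf))
  writeBin(serialize(unclass(spec), NULL, version = 2), tf)
  unname(tools::md5sum(tf))
}
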