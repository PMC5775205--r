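#' Parameter sweep of the final state
#'
#' Integrates the model once per grid value of a swept scalar parameter
#' (the crowding exponent `delta`, a shared crowding coefficient `d`, or
#' the aggregation exponent `epsilon`), always from the same initial state,
#' and records the final densities, survivor counts and a steady-state flag
#' per row. Rows are mutually independent (the sweep is embarrassingly
#' parallel by contract); execution is serial and deterministic.
#'
#' `sweep_delta()` is the `param = "delta"` shorthand. A grid value
#' `delta = 0` runs the explicit degenerate constant-mortality mode and is
#' flagged in the result.
#'
#' @param spec base [lv_model()]; the swept parameter is overridden
#'   per row.
#' @param values finite increasing numeric grid.
#' @param x0 initial densities shared by all rows.
#' @param param which scalar to sweep.
#' @param threshold extinction threshold for the per-row survivor count.
#' @param horizon,steady_tol,... passed to [lv_integrate()] /
#'   [detect_steady_state()].
#' @return object of class `"lv_sweep"`: list with `param`, `values`,
#'   `finals` (matrix, rows = grid values), `n_survivors`, `steady`,
#'   `degenerate` (delta-0 flag per row), `errors` (per-row condition
#'   message or `NA`), `spec`, `x0`, `threshold`.
#' @export
lv_sweep <- function(spec, values, x0,
                     param = c("delta", "d", "epsilon"),
                     threshold = 1e-4, horizon = 2000, steady_tol = 1e-7,
                     ...) {
  stopifnot(inherits(spec, "lv_model"))
  param <- match.arg(param)
  values <- as.numeric(values)
  if (!length(values)) stop("empty sweep grid")
  if (is.unsorted(values, strictly = TRUE))
    stop("sweep grid must be strictly increasing")
  if (param == "delta" &&
      !spec$variant %in% c("crowding", "combined"))
    stop("delta sweep requires a crowding or combined variant")
  if (param == "epsilon" && spec$variant != "aggregation")
    stop("epsilon sweep requires the aggregation variant")
  n <- spec$n
  finals <- matrix(NA_real_, length(values), n,
                   dimnames = list(NULL, paste0("x", seq_len(n))))
  nsurv <- integer(length(values))
  steady <- logical(length(values))
  errs <- rep(NA_character_, length(values))
  for (k in seq_along(values)) {
    s <- spec
    if (param == "delta") s$delta <- values[k]
    if (param == "d") s$d <- rep_len(values[k], n)
    if (param == "epsilon") s$epsilon <- values[k]
    res <- tryCatch({
      traj <- lv_integrate(s, x0, horizon = horizon, ...)
      list(traj = traj)
    }, error = function(e) list(error = conditionMessage(e)))
    if (!is.null(res$error)) {
      errs[k] <- res$error
      next
    }
    fin <- final_state(res$traj)
    finals[k, ] <- fin
    nsurv[k] <- count_survivors(fin, threshold)$n_survivors
    steady[k] <- detect_steady_state(res$traj, tol = steady_tol)$reached
  }
  structure(list(param = param, values = values, finals = finals,
                 n_survivors = nsurv, steady = steady,
                 degenerate = param == "delta" & values == 0,
                 errors = errs, spec = spec, x0 = x0,
                 threshold = threshold, horizon = horizon),
            class = "lv_sweep")
}

#' @rdname lv_sweep
#' @param delta_values grid for the `delta` shorthand.
#' @export
sweep_delta <- function(spec, delta_values, x0, ...) {
  lv_sweep(spec, delta_values, x0, param = "delta", ...)
}

#' @export
print.lv_sweep <- function(x, ...) {
  cat("<lv_sweep> over", x$param, "-", length(x$values), "values in [",
      min(x$values), ",", max(x$values), "]\n")
  cat("  survivor counts:", paste(x$n_survivors, collapse = " "), "\n")
  if (any(!x$steady))
    cat("  unsteady rows:", paste(which(!x$steady), collapse = ", "), "\n")
  if (any(!is.na(x$errors)))
    cat("  failed rows:", paste(which(!is.na(x$errors)), collapse = ", "),
        "\n")
  invisible(x)
}

#' @export
plot.lv_sweep <- function(x, ...) {
  matplot(x$values, x$finals, type = "l", lty = 1,
          col = seq_len(ncol(x$finals)), xlab = x$param,
          ylab = "final density", ...)
  legend("topright", legend = colnames(x$finals),
         col = seq_len(ncol(x$finals)), lty = 1, cex = 0.8, bty = "n")
  invisible(x)
}

#' Final-state density ratio surface over (delta, d)
#'
#' For a 2-species model, integrates on the product grid of crowding
#' exponents and shared crowding coefficients (\eqn{d_1 = d_2}) and reports
#' the ratio \eqn{x_1/x_2} at the final state. Cells where species 2 ends
#' at or below the threshold are marked `NA` (ratio undefined).
#'
#' @param spec 2-species crowding-variant [lv_model()].
#' @param delta_values,d_values axis grids; defaults 51 points on [0, 5]
#'   and 26 points on [0, 0.5].
#' @param x0 initial densities.
#' @param threshold extinction threshold for the undefined-cell rule.
#' @param ... passed to [lv_integrate()].
#' @return object of class `"lv_ratio_surface"`: `delta_values`, `d_values`,
#'   `ratio` (matrix, rows = delta, cols = d), plus the final densities
#'   arrays `x1`, `x2`.
#' @export
ratio_surface <- function(spec, delta_values = seq(0, 5, length.out = 51),
                          d_values = seq(0, 0.5, length.out = 26),
                          x0 = c(0.5, 0.5), threshold = 1e-4,
                          horizon = 2000, ...) {
  stopifnot(inherits(spec, "lv_model"))
  if (spec$n != 2) stop("ratio surface is a 2-species analysis")
  if (!spec$variant %in% c("crowding", "classical"))
    stop("ratio surface requires the crowding variant")
  delta_values <- as.numeric(delta_values)
  d_values <- as.numeric(d_values)
  x1 <- x2 <- matrix(NA_real_, length(delta_values), length(d_values))
  for (j in seq_along(d_values)) {
    for (i in seq_along(delta_values)) {
      s <- spec
      s$variant <- if (d_values[j] == 0) "classical" else "crowding"
      s$d <- rep(d_values[j], 2)
      s$delta <- delta_values[i]
      fin <- final_state(lv_integrate(s, x0, horizon = horizon, ...))
      x1[i, j] <- fin[1]; x2[i, j] <- fin[2]
    }
  }
  ratio <- ifelse(x2 > threshold, x1 / x2, NA_real_)
  dimnames(ratio) <- list(delta = signif(delta_values, 6),
                          d = signif(d_values, 6))
  structure(list(delta_values = delta_values, d_values = d_values,
                 ratio = ratio, x1 = x1, x2 = x2, threshold = threshold,
                 spec = spec, x0 = x0),
            class = "lv_ratio_surface")
}

#' @export
print.lv_ratio_surface <- function(x, ...) {
  cat("<lv_ratio_surface>", length(x$delta_values), "delta x",
      length(x$d_values), "d cells;",
      sum(is.na(x$ratio)), "undefined\n")
  rng <- range(x$ratio, na.rm = TRUE)
  cat("  ratio x1/x2 in [", signif(rng[1], 4), ",", signif(rng[2], 4),
      "]\n")
  invisible(x)
}

#' Full-coexistence intervals of a sweep
#'
#' Extracts the maximal contiguous runs of sweep grid values on which all
#' `full_count` species survive. Endpoints are reported at grid resolution;
#' no sub-grid refinement is attempted.
#'
#' @param sweep an [lv_sweep()] result.
#' @param full_count number of species that must survive (defaults to the
#'   model's n).
#' @return data frame with one row per interval: `from_index`, `to_index`,
#'   `from_value`, `to_value`; zero rows when no grid point has full
#'   coexistence.
#' @export
regime_boundary <- function(sweep, full_count = sweep$spec$n) {
  stopifnot(inherits(sweep, "lv_sweep"))
  ok <- sweep$n_survivors == full_count & is.na(sweep$errors)
  if (!any(ok))
    return(data.frame(from_index = integer(), to_index = integer(),
                      from_value = numeric(), to_value = numeric()))
  r <- rle(ok)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  keep <- r$values
  data.frame(from_index = starts[keep], to_index = ends[keep],
             from_value = sweep$values[starts[keep]],
             to_value = sweep$values[ends[keep]])
}
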