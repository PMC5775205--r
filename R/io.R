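#' Export computed results to plain-text files
#'
#' Fixed formats: trajectories and isocline curves as CSV, sweep results and
#' ratio surfaces as TSV, survivor reports and equilibria as JSON.
#' `write_results()` dispatches on the object class.
#'
#' Column orders: trajectory CSV is `time,x1,...,xn`; isocline CSV is
#' `x1,x2`; sweep TSV is `param_value,x1..xn,n_survivors,steady`; the ratio
#' surface TSV has one header row of d values and one leading column of
#' delta values.
#'
#' @param x a result object (`lv_trajectory`, `lv_isocline`, `lv_sweep`,
#'   `lv_ratio_surface`, `lv_survivors`, `lv_equilibrium`, `lv_case`).
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_results <- function(x, path) UseMethod("write_results")

#' @export
write_results.lv_trajectory <- function(x, path) {
  write.csv(as.data.frame(x), path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @export
write_results.lv_isocline <- function(x, path) {
  write.csv(x$points, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @export
write_results.lv_sweep <- function(x, path) {
  df <- data.frame(param_value = x$values, x$finals,
                   n_survivors = x$n_survivors, steady = x$steady)
  utils::write.table(df, path, sep = "\t", row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @export
write_results.lv_ratio_surface <- function(x, path) {
  m <- cbind(delta = x$delta_values, x$ratio)
  colnames(m) <- c("delta", paste0("d=", signif(x$d_values, 6)))
  utils::write.table(m, path, sep = "\t", row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @export
write_results.lv_survivors <- function(x, path) {
  jsonlite::write_json(list(threshold = x$threshold,
                            survivors = as.integer(x$survivors),
                            n_survivors = x$n_survivors,
                            final_state = x$final_state),
                       path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @export
write_results.lv_equilibrium <- function(x, path) {
  jsonlite::write_json(list(exists = x$exists,
                            x_star = x$x_star,
                            residual = x$residual,
                            eigenvalues_re = Re(x$eigenvalues),
                            eigenvalues_im = Im(x$eigenvalues),
                            classification = x$classification),
                       path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @export
write_results.lv_case <- function(x, path) {
  jsonlite::write_json(list(label = x$label,
                            inequalities = x$inequalities),
                       path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}
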