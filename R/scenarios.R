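# Scenario fixtures: one registered entry per reference figure panel.
# Panels whose published content is itself a sweep product (the delta sweeps
# of the four phase-plane cases, the delta/d ratio surface, the final-state-
# vs-delta panels) are registered as "sweep"/"surface" scenarios.

x0_fig56_10 <- c(0.15, 0.25, 0.2, 0.12, 0.18, 0.19, 0.22, 0.14, 0.13, 0.26)
x0_fig56_5 <- x0_fig56_10[1:5]
x0_fig56_2 <- x0_fig56_10[1:2]

case_alphas <- list(a = c(0.8, 1.2), b = c(1.2, 0.8),
                    c = c(0.5, 0.4), d = c(1.2, 1.3))

alpha2 <- function(a12, a21) matrix(c(1, a21, a12, 1), 2, 2)

new_scenario <- function(name, type, spec, x0, horizon = 2000, notes = "",
                         sweep_param = NULL, sweep_values = NULL,
                         d_values = NULL) {
  structure(list(name = name, type = type, spec = spec, x0 = x0,
                 horizon = horizon, notes = notes,
                 sweep_param = sweep_param, sweep_values = sweep_values,
                 d_values = d_values),
            class = "lv_scenario")
}

scenario_builders <- local({
  reg <- list()

  fig1_spec <- function(case, d = 0.5, delta = 1) {
    a <- case_alphas[[case]]
    lv_model(if (d == 0) "classical" else "crowding", b = c(1, 1),
             m0 = c(0.1, 0.1), d = rep(d, 2), alpha = alpha2(a[1], a[2]),
             delta = delta, n = 2)
  }
  for (case in names(case_alphas)) {
    local({
      cs <- case
      reg[[paste0("fig1", cs)]] <<- function(delta = 1) {
        new_scenario(paste0("fig1", cs), "simulate",
                     fig1_spec(cs, 0.5, delta), c(0.5, 0.2),
                     notes = paste0("two-species crowding run, phase-plane ",
                                    "case ", cs, "; d = 0.5, delta = ",
                                    delta, ", x0 = (0.5, 0.2)"))
      }
      reg[[paste0("fig2", cs)]] <<- function(delta = 1) {
        new_scenario(paste0("fig2", cs), "sweep", fig1_spec(cs, 0.5, delta),
                     c(0.5, 0.2),
                     sweep_param = "delta",
                     sweep_values = seq(0, 5, length.out = 51),
                     notes = paste0("delta sweep of phase-plane case ", cs,
                                    ", d = 0.5"))
      }
    })
  }

  fig3_spec <- function(d = 0.3, delta = 1)
    lv_model(if (d == 0) "classical" else "crowding", b = c(1.0, 1.8),
             m0 = 0.1, d = rep(d, 2), alpha = 1, delta = delta, n = 2)
  reg[["fig3a"]] <- function(...)
    new_scenario("fig3a", "surface", fig3_spec(), c(0.5, 0.5),
                 sweep_param = "delta",
                 sweep_values = seq(0, 5, length.out = 51),
                 d_values = seq(0, 0.5, length.out = 26),
                 notes = "density-ratio surface over (delta, d), b = (1, 1.8)")
  reg[["fig3b"]] <- function(...)
    new_scenario("fig3b", "sweep", fig3_spec(0.3), c(0.5, 0.5),
                 sweep_param = "delta",
                 sweep_values = seq(0, 1, length.out = 26),
                 notes = "delta sweep on [0, 1], d = 0.3, b = (1, 1.8)")
  reg[["fig3c"]] <- function(...)
    new_scenario("fig3c", "sweep", fig3_spec(0.3), c(0.5, 0.5),
                 sweep_param = "delta",
                 sweep_values = seq(0, 5, length.out = 51),
                 notes = "delta sweep on [0, 5], d = 0.3, b = (1, 1.8)")

  fig4_spec <- function(n, bstep, d = 0.3, delta = 0.3)
    lv_model(if (d == 0) "classical" else "crowding",
             b = 1.0 + bstep * (seq_len(n) - 1), m0 = 0.1, d = rep(d, n),
             alpha = 1, delta = delta, n = n)
  reg[["fig4a"]] <- function(...)
    new_scenario("fig4a", "simulate", fig4_spec(5, 0.1), rep(0.5, 5),
                 notes = "5-species crowding dynamics, d = 0.3, delta = 0.3")
  reg[["fig4b"]] <- function(...)
    new_scenario("fig4b", "simulate", fig4_spec(10, 0.05), rep(0.5, 10),
                 notes = "10-species crowding dynamics, d = 0.3, delta = 0.3")
  reg[["fig4c"]] <- function(...)
    new_scenario("fig4c", "sweep", fig4_spec(5, 0.1), rep(0.5, 5),
                 sweep_param = "delta",
                 sweep_values = seq(0, 1, length.out = 26),
                 notes = "5-species final states vs delta on [0, 1]")
  reg[["fig4d"]] <- function(...)
    new_scenario("fig4d", "sweep", fig4_spec(10, 0.05), rep(0.5, 10),
                 sweep_param = "delta",
                 sweep_values = seq(0, 1, length.out = 26),
                 notes = "10-species final states vs delta on [0, 1]")

  fig5_spec <- function(n, m0, variant) {
    b <- 1.0 + 0.01 * (seq_len(n) - 1)
    if (variant == "crowding")
      lv_model("crowding", b = b, m0 = m0, d = 0.3, alpha = 1, delta = 0.4,
               n = n)
    else
      lv_model("aggregation", b = b, m0 = m0, d = 0, alpha = 1,
               epsilon = 0.01, n = n)
  }
  fig5 <- list(a = list(2, 0.3, "crowding"),  b = list(2, 0.3, "aggregation"),
               c = list(5, 0.3, "crowding"),  d = list(5, 0.3, "aggregation"),
               e = list(10, 0.1, "crowding"), f = list(10, 0.1, "aggregation"))
  for (p in names(fig5)) {
    local({
      pp <- p; cfg <- fig5[[p]]
      reg[[paste0("fig5", pp)]] <<- function(...) {
        n <- cfg[[1]]
        x0 <- switch(as.character(n), "2" = x0_fig56_2, "5" = x0_fig56_5,
                     x0_fig56_10)
        new_scenario(paste0("fig5", pp), "simulate",
                     fig5_spec(n, cfg[[2]], cfg[[3]]), x0,
                     notes = sprintf(
                       "%d-species %s run, m0 = %g, b_i = 1 + 0.01(i-1)",
                       n, cfg[[3]], cfg[[2]]))
      }
    })
  }

  fig6_spec <- function(n, m0, variant) {
    b <- 1.0 + 0.1 * (seq_len(n) - 1)
    switch(variant,
           crowding = lv_model("crowding", b = b, m0 = m0, d = 0.3,
                               alpha = 1, delta = 0.4, n = n),
           nonlinear_competition =
             lv_model("nonlinear_competition", b = b, m0 = m0, d = 0,
                      alpha = 1, n = n),
           combined = lv_model("combined", b = b, m0 = m0, d = 0.3,
                               alpha = 1, delta = 0.4, n = n))
  }
  fig6 <- list(a = list(2, 0.3, "crowding"),
               b = list(2, 0.3, "nonlinear_competition"),
               c = list(2, 0.3, "combined"),
               d = list(5, 0.3, "crowding"),
               e = list(5, 0.3, "nonlinear_competition"),
               f = list(5, 0.3, "combined"),
               g = list(10, 0.1, "crowding"),
               h = list(10, 0.1, "nonlinear_competition"),
               i = list(10, 0.1, "combined"))
  for (p in names(fig6)) {
    local({
      pp <- p; cfg <- fig6[[p]]
      reg[[paste0("fig6", pp)]] <<- function(...) {
        n <- cfg[[1]]
        x0 <- switch(as.character(n), "2" = x0_fig56_2, "5" = x0_fig56_5,
                     x0_fig56_10)
        new_scenario(paste0("fig6", pp), "simulate",
                     fig6_spec(n, cfg[[2]], cfg[[3]]), x0,
                     notes = sprintf(
                       "%d-species %s run, m0 = %g, b_i = 1 + 0.1(i-1)",
                       n, cfg[[3]], cfg[[2]]))
      }
    })
  }
  reg
})

scenario_aliases <- c(fig4a5 = "fig4a", fig4b10 = "fig4b", fig3bc = "fig3c")

#' Build a registered scenario
#'
#' Returns a ready-to-run scenario: a validated model specification plus
#' initial densities, horizon and (for sweep scenarios) the parameter grid.
#' Registered names are `fig1a`..`fig1d` (two-species crowding runs),
#' `fig2a`..`fig2d` (delta sweeps of the same cases), `fig3a` (ratio
#' surface), `fig3b`/`fig3c` (delta sweeps), `fig4a`--`fig4d` (5/10-species
#' runs and sweeps), `fig5a`--`fig5f` (crowding vs aggregation comparison)
#' and `fig6a`--`fig6i` (crowding vs nonlinear competition vs combined),
#' plus the aliases `fig4a5`, `fig4b10`, `fig3bc`.
#'
#' @param name registered scenario name.
#' @param delta crowding exponent for the `fig1*` / `fig2*` fixtures, whose
#'   published caption lists the swept range rather than a single value;
#'   defaults to 1, the value at which coexistence is reported.
#' @return object of class `"lv_scenario"`.
#' @examples
#' sc <- lv_scenario("fig1a")
#' sc$spec
#' @export
lv_scenario <- function(name, delta = 1) {
  if (name %in% names(scenario_aliases)) name <- scenario_aliases[[name]]
  if (!name %in% names(scenario_builders))
    stop("unknown scenario '", name, "'; registered: ",
         paste(sort(c(names(scenario_builders), names(scenario_aliases))),
               collapse = ", "))
  if (grepl("^fig[12]", name)) scenario_builders[[name]](delta)
  else scenario_builders[[name]]()
}

#' List registered scenarios
#'
#' @return data frame with one row per registered scenario (aliases
#'   excluded): `name`, `type`, `variant`, `n`, `notes`.
#' @export
lv_scenarios <- function() {
  rows <- lapply(sort(names(scenario_builders)), function(nm) {
    sc <- scenario_builders[[nm]](1)
    data.frame(name = nm, type = sc$type, variant = sc$spec$variant,
               n = sc$spec$n, notes = sc$notes)
  })
  do.call(rbind, rows)
}

#' @export
print.lv_scenario <- function(x, ...) {
  cat("<lv_scenario>", x$name, sprintf("(%s)", x$type), "\n")
  cat("  ", x$notes, "\n")
  cat("  x0 =", paste(signif(x$x0, 4), collapse = ", "),
      " horizon =", x$horizon, "\n")
  if (!is.null(x$sweep_param))
    cat("  sweep:", x$sweep_param, "over [",
        min(x$sweep_values), ",", max(x$sweep_values), "] (",
        length(x$sweep_values), "values )\n")
  invisible(x)
}

#' Run a scenario
#'
#' Dispatches on the scenario type: `simulate` scenarios are integrated
#' ([lv_integrate()]), `sweep` scenarios run [lv_sweep()], `surface`
#' scenarios run [ratio_surface()].
#'
#' @param scenario an `lv_scenario` (or its registered name).
#' @param ... passed to the underlying runner.
#' @return an `lv_trajectory`, `lv_sweep` or `lv_ratio_surface`.
#' @export
run_scenario <- function(scenario, ...) {
  if (is.character(scenario)) scenario <- lv_scenario(scenario)
  stopifnot(inherits(scenario, "lv_scenario"))
  switch(scenario$type,
         simulate = lv_integrate(scenario$spec, scenario$x0,
                                 horizon = scenario$horizon, ...),
         sweep = lv_sweep(scenario$spec, scenario$sweep_values,
                          scenario$x0, param = scenario$sweep_param,
                          horizon = scenario$horizon, ...),
         surface = ratio_surface(scenario$spec,
                                 delta_values = scenario$sweep_values,
                                 d_values = scenario$d_values,
                                 x0 = scenario$x0,
                                 horizon = scenario$horizon, ...),
         stop("unknown scenario type ", scenario$type))
}
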