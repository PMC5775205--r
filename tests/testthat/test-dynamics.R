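test_that("integrator reproduces closed-form single-species equilibria", {
  # logistic with constant mortality: x* = 1 - m0/b
  s <- lv_model("classical", b = 1, m0 = 0.1, n = 1)
  traj <- lv_integrate(s, 0.5, horizon = 500)
  expect_equal(unname(traj$states[nrow(traj$states), 1]), 0.9,
               tolerance = 1e-6)
  # crowding, delta = 1: x* = (b - m0)/(b + d)
  s2 <- lv_model("crowding", b = 1, m0 = 0.1, d = 0.5, delta = 1, n = 1)
  traj2 <- lv_integrate(s2, 0.2, horizon = 500)
  expect_equal(unname(traj2$states[nrow(traj2$states), 1]), 0.6,
               tolerance = 1e-6)
})

test_that("trajectory contract: first row is x0, densities nonnegative,
           deterministic replay", {
  spec <- lv_model("crowding", b = c(1, 1.8), m0 = 0.1, d = 0.3, alpha = 1,
                   delta = 0.5, n = 2)
  t1 <- lv_integrate(spec, c(0.5, 0.5), horizon = 300)
  t2 <- lv_integrate(spec, c(0.5, 0.5), horizon = 300)
  expect_identical(unname(t1$states[1, ]), c(0.5, 0.5))
  expect_true(all(t1$states >= 0))
  expect_identical(t1$states, t2$states)
  expect_lt(t1$diagnostics$max_clamp, 1e-9)
  expect_identical(t1$spec_fingerprint, t2$spec_fingerprint)
})

test_that("a fully symmetric two-species model stays symmetric along the
           whole trajectory", {
  spec <- lv_model("crowding", b = c(1.2, 1.2), m0 = 0.2, d = 0.3,
                   alpha = alpha_2x2(0.8, 0.8), delta = 0.7, n = 2)
  traj <- lv_integrate(spec, c(0.5, 0.5), horizon = 500)
  expect_lt(max(abs(traj$states[, 1] - traj$states[, 2])), 1e-9)
})

test_that("classical case-a parameters exclude species 2 (competitive
           exclusion), crowding d=0.5 restores coexistence", {
  a <- fig1_alphas$a
  scl <- lv_model("classical", b = c(1, 1), m0 = 0.1, d = 0,
                  alpha = alpha_2x2(a[1], a[2]), n = 2)
  fin <- lv_integrate(scl, c(0.5, 0.2), horizon = 2000)
  xf <- fin$states[nrow(fin$states), ]
  expect_equal(unname(xf[1]), 0.9, tolerance = 1e-5)
  expect_lt(xf[2], 1e-4)
  scr <- lv_model("crowding", b = c(1, 1), m0 = 0.1, d = 0.5,
                  alpha = alpha_2x2(a[1], a[2]), delta = 1, n = 2)
  xf2 <- lv_integrate(scr, c(0.5, 0.2), horizon = 2000)
  expect_true(all(count_survivors(xf2)$n_survivors == 2))
})

test_that("competitive exclusion principle in the classical limit: with
           alpha = 1 and distinct b only the best competitor survives", {
  spec <- lv_model("classical", b = c(1.1, 1.4, 1.9), m0 = 0.2, d = 0,
                   alpha = 1, n = 3)
  traj <- lv_integrate(spec, rep(0.4, 3), horizon = 3000)
  surv <- count_survivors(traj)
  expect_identical(surv$survivors, 3L)
  expect_identical(surv$n_survivors, 1L)
})

test_that("steady-state detection finds the earliest settled index", {
  spec <- lv_model("crowding", b = 1, m0 = 0.1, d = 0.5, delta = 1, n = 1)
  # frozen at the exact equilibrium: reached at index 1
  traj <- lv_integrate(spec, 0.6, horizon = 10)
  ss <- detect_steady_state(traj, tol = 1e-6)
  expect_true(ss$reached)
  expect_identical(ss$index, 1L)
  # still transient at the end: not reached under a tight tolerance
  traj2 <- lv_integrate(spec, 0.05, horizon = 2, n_out = 10)
  rate_end <- max(abs(lv_rhs(spec, traj2$states[10, ])))
  ss2 <- detect_steady_state(traj2, tol = rate_end / 10)
  expect_false(ss2$reached)
})

test_that("count_survivors partitions by threshold and reports it", {
  r <- count_survivors(c(0.3, 0.0, 0.2), threshold = 1e-4)
  expect_identical(r$survivors, c(1L, 3L))
  expect_identical(r$n_survivors, 2L)
  expect_identical(r$threshold, 1e-4)
  expect_identical(count_survivors(c(0, 0, 0))$n_survivors, 0L)
  expect_error(count_survivors(c(0.1), threshold = 0), "positive")
})

test_that("scalar-reduction equilibrium matches algebra and integration", {
  # two identical species, delta = 1: 1 - 2x = 0.1 + 0.5x => x = 0.36
  s2 <- lv_model("crowding", b = c(1, 1), m0 = 0.1, d = 0.5, alpha = 1,
                 delta = 1, n = 2)
  eq <- solve_interior_equilibrium(s2)
  expect_true(eq$exists)
  expect_equal(eq$x_star, c(0.36, 0.36), tolerance = 1e-10)
  expect_lt(eq$residual, 1e-10)
  expect_identical(eq$classification, "stable")
  # single species: (b - m0)/(b + d) = 0.6
  s1 <- lv_model("crowding", b = 1, m0 = 0.1, d = 0.5, alpha = 1,
                 delta = 1, n = 1)
  expect_equal(solve_interior_equilibrium(s1)$x_star, 0.6,
               tolerance = 1e-10)
  # integration oracle
  traj <- lv_integrate(s2, c(0.5, 0.2), horizon = 2000)
  expect_equal(unname(traj$states[nrow(traj$states), ]), eq$x_star,
               tolerance = 1e-5)
})

test_that("equilibrium solver refuses unsupported configurations and
           reports absence", {
  sa <- lv_model("crowding", b = c(1, 1), m0 = 0.1, d = 0.5,
                 alpha = alpha_2x2(0.8, 1.2), delta = 1, n = 2)
  expect_error(solve_interior_equilibrium(sa), "alpha")
  s0 <- lv_model("crowding", b = c(1, 1), m0 = 0.1, d = 0, alpha = 1,
                 delta = 1, n = 2)
  expect_error(solve_interior_equilibrium(s0), "d > 0")
  # all species below replacement (b <= m0): no positive state
  dead <- lv_model("crowding", b = c(1, 1), m0 = 1, d = 0.5, alpha = 1,
                   delta = 1, n = 2)
  expect_false(solve_interior_equilibrium(dead)$exists)
})

test_that("stability classification: stable node, marginal degenerate
           line", {
  s1 <- lv_model("classical", b = 1, m0 = 0.1, n = 1)
  expect_identical(classify_stability(0.9, spec = s1), "stable")
  # identical species with alpha = 1: a whole line of equilibria, one zero
  # eigenvalue => marginal
  s2 <- lv_model("classical", b = c(1, 1), m0 = 0.1, d = 0, alpha = 1,
                 n = 2)
  expect_identical(classify_stability(c(0.45, 0.45), spec = s2), "marginal")
})

test_that("integration errors carry context when the state explodes", {
  # negative net growth impossible here; force failure via max_steps
  spec <- lv_model("crowding", b = c(1, 1.8), m0 = 0.1, d = 0.3, alpha = 1,
                   delta = 0.5, n = 2)
  expect_error(lv_integrate(spec, c(0.5, 0.5), horizon = 2000,
                            max_steps = 10), "max_steps")
})
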