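test_that("mortality law evaluates correctly, including edge conventions", {
  # d = 0 leaves only the baseline mortality
  expect_identical(mortality_rate(0.5, m0 = 0.1, d = 0, delta = 2), 0.1)
  # 0^delta = 0 for any delta > 0
  expect_identical(mortality_rate(0, m0 = 0.1, d = 0.5, delta = 2), 0.1)
  expect_identical(mortality_rate(0, m0 = 0.1, d = 0.5, delta = 0.3), 0.1)
  # linear case by hand: 0.1 + 0.5 * 0.6
  expect_equal(mortality_rate(0.6, m0 = 0.1, d = 0.5, delta = 1), 0.4)
  # degenerate delta = 0 mode: constant m0 + d
  expect_equal(mortality_rate(c(0, 0.3, 1), m0 = 0.1, d = 0.5, delta = 0),
               rep(0.6, 3))
  expect_error(mortality_rate(-0.1, 0.1, 0.5, 0.5), "negative")
})

test_that("mortality is nondecreasing in x, d and m0", {
  xs <- seq(0, 1.5, by = 0.05)
  for (delta in c(0.3, 1, 2.7)) {
    m <- mortality_rate(xs, m0 = 0.1, d = 0.4, delta = delta)
    expect_true(all(diff(m) >= 0), info = paste("delta =", delta))
  }
  expect_true(all(mortality_rate(0.7, 0.1, seq(0, 1, 0.1), 0.8) ==
                  cummax(mortality_rate(0.7, 0.1, seq(0, 1, 0.1), 0.8))))
  expect_lt(mortality_rate(0.7, 0.1, 0.3, 0.8),
            mortality_rate(0.7, 0.2, 0.3, 0.8))
})

test_that("crowding RHS matches hand-computed values", {
  # extinction state is invariant
  spec <- lv_model("crowding", b = c(1, 1.4), m0 = 0.1, d = 0.3,
                   alpha = 1, delta = 0.4, n = 2)
  expect_identical(rhs_crowding(spec, c(0, 0)), c(0, 0))
  # single-species closed-form equilibrium x* = (b - m0)/(b + d) at delta=1
  s1 <- lv_model("crowding", b = 1, m0 = 0.1, d = 0.5, delta = 1, n = 1)
  expect_equal(lv_rhs(s1, 0.9 / 1.5), 0, tolerance = 1e-14)
  # two symmetric species without crowding, evaluated by hand
  s2 <- lv_model("crowding", b = c(1, 1), m0 = 0.1, d = 0, alpha = 1, n = 2)
  expect_equal(lv_rhs(s2, c(0.3, 0.3)), c(0.09, 0.09))
})

test_that("aggregation RHS obeys its limits and zero conditions", {
  sa <- lv_model("aggregation", b = c(1, 1.2), m0 = 0.2, d = 0, alpha = 1,
                 epsilon = 0.05, n = 2)
  expect_identical(rhs_aggregation(sa, c(0, 0)), c(0, 0))
  # epsilon = 0 degenerate mode equals the classical model (x^(1+0) = x)
  sa0 <- lv_model("aggregation", b = c(1, 1.2), m0 = 0.2, d = 0, alpha = 1,
                  epsilon = 0, n = 2)
  sc <- lv_model("classical", b = c(1, 1.2), m0 = 0.2, d = 0, alpha = 1,
                 n = 2)
  for (x in list(c(0.2, 0.5), c(0.9, 0.1), c(0, 0.7)))
    expect_equal(rhs_aggregation(sa0, x), lv_rhs(sc, x), tolerance = 1e-14)
  # scalar root of b(1 - x) = m0 x^eps is an equilibrium (independent
  # root-find oracle on the stated equation)
  s1 <- lv_model("aggregation", b = 1, m0 = 0.3, d = 0, epsilon = 0.01,
                 n = 1)
  root <- uniroot(function(x) 1 * (1 - x) - 0.3 * x^0.01, c(1e-6, 1),
                  tol = 1e-14)$root
  expect_equal(rhs_aggregation(s1, root), 0, tolerance = 1e-12)
})

test_that("nonlinear-competition RHS squares only interspecific terms", {
  sn <- lv_model("nonlinear_competition", b = c(1, 1), m0 = 0.1, d = 0,
                 alpha = 1, n = 2)
  expect_identical(rhs_nonlinear_competition(sn, c(0, 0)), c(0, 0))
  # absent competitor exerts no effect: hand evaluation
  expect_equal(rhs_nonlinear_competition(sn, c(0.5, 0)), c(0.2, 0))
  # permutation symmetry at a symmetric state
  f <- rhs_nonlinear_competition(sn, c(0.4, 0.4))
  expect_equal(f[1], f[2])
  # squared coupling: the hand value differs from the linear model
  expect_equal(rhs_nonlinear_competition(sn, c(0.3, 0.4)),
               c(1 * 0.3 * (1 - 0.3 - 0.16) - 0.03,
                 1 * 0.4 * (1 - 0.4 - 0.09) - 0.04))
})

test_that("combined RHS reduces to its two parents", {
  set.seed(41)
  sc <- lv_model("combined", b = c(1.1, 1.6), m0 = 0.2, d = 0.3, alpha = 1,
                 delta = 0.7, n = 2)
  expect_identical(rhs_combined(sc, c(0, 0)), c(0, 0))
  # d -> 0 limit equals the nonlinear-competition variant at every state
  sc0 <- lv_model("combined", b = c(1.1, 1.6), m0 = 0.2, d = 0, alpha = 1,
                  delta = 0.7, n = 2)
  sn <- lv_model("nonlinear_competition", b = c(1.1, 1.6), m0 = 0.2, d = 0,
                 alpha = 1, n = 2)
  for (k in 1:10) {
    x <- runif(2, 0, 1.2)
    expect_equal(rhs_combined(sc0, x), rhs_nonlinear_competition(sn, x),
                 tolerance = 1e-15)
  }
  # single species: same closed form as the crowding model
  s1 <- lv_model("combined", b = 1, m0 = 0.1, d = 0.5, delta = 1, n = 1)
  expect_equal(rhs_combined(s1, 0.6), 0, tolerance = 1e-14)
})

test_that("extinct species stay extinct under every variant (forward
           invariance of the axes)", {
  set.seed(7)
  for (variant in c("crowding", "aggregation", "nonlinear_competition",
                    "combined")) {
    for (rep in 1:5) {
      spec <- random_variant_spec(variant, n = 4)
      x <- runif(4, 0, 1)
      dead <- sample(4, 2)
      x[dead] <- 0
      expect_identical(lv_rhs(spec, x)[dead], c(0, 0),
                       label = paste(variant, "rep", rep))
    }
  }
})

test_that("with d = 0 the crowding model is the classical model, with no
           delta dependence", {
  set.seed(11)
  al <- matrix(runif(9, 0.2, 1), 3, 3); diag(al) <- 1
  args <- list(b = c(1.2, 1.5, 1.9), m0 = c(0.1, 0.3, 0.2), alpha = al,
               n = 3)
  scl <- do.call(lv_model, c(list("classical", d = 0), args))
  for (delta in c(0.2, 1, 4.9)) {
    scr <- do.call(lv_model, c(list("crowding", d = 0, delta = delta), args))
    for (k in 1:5) {
      x <- runif(3, 0, 1.2)
      expect_identical(lv_rhs(scr, x), lv_rhs(scl, x))
    }
  }
})

test_that("RHS is equivariant under species permutation", {
  set.seed(23)
  for (variant in c("crowding", "aggregation", "nonlinear_competition",
                    "combined")) {
    spec <- random_variant_spec(variant, n = 4)
    x <- runif(4, 0.05, 1)
    p <- sample(4)
    perm <- spec
    perm$b <- spec$b[p]; perm$m0 <- spec$m0[p]; perm$d <- spec$d[p]
    perm$alpha <- spec$alpha[p, p]
    # equal up to floating-point reassociation of the competition sum
    expect_equal(lv_rhs(perm, x[p]), lv_rhs(spec, x)[p], tolerance = 1e-12,
                 label = variant)
  }
})

test_that("delta = 0 degenerate mode shifts the baseline mortality by d", {
  s0 <- lv_model("crowding", b = c(1, 1.3), m0 = 0.1, d = 0.2, alpha = 1,
                 delta = 0, n = 2)
  seq <- lv_model("classical", b = c(1, 1.3), m0 = 0.3, d = 0, alpha = 1,
                  n = 2)
  for (x in list(c(0.4, 0.6), c(0, 0.2)))
    expect_equal(lv_rhs(s0, x), lv_rhs(seq, x), tolerance = 1e-15)
})

test_that("constructor enforces structure; validation reports ranges", {
  expect_error(lv_model("crowding", b = -1, m0 = 0.1, d = 0.1, n = 1),
               "positive")
  expect_error(lv_model("crowding", b = 1, m0 = 0.1, d = 0.1,
                        alpha = matrix(c(0.9, 1, 1, 1), 2), n = 2),
               "diagonal")
  expect_error(lv_model("crowding", b = 1, m0 = 0.1, d = 0.1,
                        alpha = matrix(1, 3, 3) - diag(0, 3), n = 2),
               "alpha must be")
  expect_error(lv_rhs(lv_model("crowding", b = 1, m0 = 0.1, d = 0.1, n = 1),
                      c(0.1, 0.2)), "length")

  # the published case-a parameter set violates the advisory alpha range:
  # one warning, no errors
  spec <- lv_model("crowding", b = c(1, 1), m0 = 0.1, d = 0.5,
                   alpha = alpha_2x2(0.8, 1.2), delta = 1, n = 2)
  v <- lv_validate(spec)
  expect_identical(v$severity, "warning")
  expect_identical(v$field, "alpha")

  # m0 + d rule
  ok <- lv_validate(lv_model("crowding", b = c(1, 1), m0 = 0.1, d = 0.5,
                             alpha = 1, n = 2))
  expect_false(any(ok$field == "m0+d"))
  bad <- lv_validate(lv_model("crowding", b = c(1, 1), m0 = 0.7, d = 0.5,
                              alpha = 1, n = 2))
  expect_true(any(bad$field == "m0+d" & bad$severity == "warning"))
})
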