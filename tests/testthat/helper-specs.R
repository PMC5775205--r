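# Shared fixtures: parameter sets are built in code, no stored data.

# random crowding spec with all alpha = 1 (the regime the scalar
# equilibrium reduction supports)
random_crowding_spec <- function(n = sample(2:5, 1)) {
  lv_model("crowding",
           b = runif(n, 1, 2),
           m0 = runif(n, 0.05, 0.3),
           d = runif(n, 0.1, 0.5),
           alpha = 1,
           delta = runif(1, 0.2, 2),
           n = n)
}

# random spec of any variant with a general competition matrix
random_variant_spec <- function(variant, n = 3) {
  alpha <- matrix(runif(n * n, 0.2, 1), n, n)
  diag(alpha) <- 1
  switch(variant,
         crowding = lv_model("crowding", b = runif(n, 1, 2),
                             m0 = runif(n, 0.05, 0.3),
                             d = runif(n, 0.1, 0.5), alpha = alpha,
                             delta = runif(1, 0.3, 3), n = n),
         aggregation = lv_model("aggregation", b = runif(n, 1, 2),
                                m0 = runif(n, 0.05, 0.3), d = 0,
                                alpha = alpha, epsilon = runif(1, 0.01, 1),
                                n = n),
         nonlinear_competition =
           lv_model("nonlinear_competition", b = runif(n, 1, 2),
                    m0 = runif(n, 0.05, 0.3), d = 0, alpha = alpha, n = n),
         combined = lv_model("combined", b = runif(n, 1, 2),
                             m0 = runif(n, 0.05, 0.3),
                             d = runif(n, 0.1, 0.5), alpha = alpha,
                             delta = runif(1, 0.3, 3), n = n))
}

fig1_alphas <- list(a = c(0.8, 1.2), b = c(1.2, 0.8),
                    c = c(0.5, 0.4), d = c(1.2, 1.3))

alpha_2x2 <- function(a12, a21) matrix(c(1, a21, a12, 1), 2, 2)
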