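test_that("logistic transfer matches its closed form and contracts", {
  expect_equal(logistic(0, 0.05), 0.5)
  expect_equal(logistic(0, 1), 0.5)
  expect_equal(logistic(0.05, 0.05), 1 / (1 + exp(-1)), tolerance = 1e-12)
  expect_gt(logistic(0.10, 0.05), logistic(0.05, 0.05))
  z <- seq(-0.5, 0.5, by = 0.05)           # representable range at T = 0.05
  expect_true(all(logistic(z, 0.05) > 0 & logistic(z, 0.05) < 1))
  expect_true(all(logistic(c(-5, 5), 0.05) >= 0 &
                    logistic(c(-5, 5), 0.05) <= 1))
  expect_error(logistic(0, 0), "gain")
  expect_error(logistic(0, -1), "gain")
})

test_that("Hopfield weights follow the sparse covariance rule", {
  st <- semantic_structure("a")
  ps <- generate_pattern_set(100, 0.1, st, seed = 1, baseline_id = NULL,
                             unrelated_overlap = "zero")
  J <- hopfield_weights(ps)
  p <- 0.1; N <- 100
  u <- pattern_units(ps, "a")
  i <- u[1]; j <- u[2]; k <- setdiff(seq_len(N), u)[1]
  expect_equal(J[i, j], (1 - p) / (N * p), tolerance = 1e-12)
  expect_equal(J[i, k], -1 / N, tolerance = 1e-12)
  expect_equal(J[k, i], J[i, k])
  expect_true(isSymmetric(J))
  expect_true(all(diag(J) == 0))
})

test_that("episodic links increment exactly the source-to-dest synapses", {
  J <- matrix(0, 100, 100)
  src <- 1:30; dst <- 41:70
  J2 <- add_episodic_link(J, src, dst, kappa = 0.0336)
  expect_identical(sum(J2 != 0), 900L)
  expect_true(all(J2[dst, src] == 0.0336))
  expect_true(all(J2[src, dst] == 0))          # directed
  expect_identical(add_episodic_link(J, src, dst, kappa = 0), J)
  expect_error(add_episodic_link(J, src, dst, kappa = -1), "salience")
  # overlapping patterns never gain a self-connection
  J3 <- add_episodic_link(J, 1:30, 25:54, kappa = 1)
  expect_true(all(diag(J3) == 0))
})

test_that("synaptic depression matches its closed forms within 1% at dt = 0.66", {
  dt <- 0.66; tau_r <- 93; U <- 0.206; x_max <- 100
  J_max <- matrix(c(1, 0.5, -0.2, 0.8), 2, 2)

  # recovery: x = 0, J(0) = J0 -> J(t) = J_max - (J_max - J0) exp(-t/tau_r)
  J <- 0.3 * J_max
  for (s in seq_len(round(tau_r / dt)))
    J <- step_depression(J, J_max, c(0, 0), U, x_max, tau_r, dt)
  t_end <- round(tau_r / dt) * dt
  expect_equal(J, J_max - (J_max - 0.3 * J_max) * exp(-t_end / tau_r),
               tolerance = 0.01)

  # steady state under constant drive c: J_ss = J_max / (1 + tau_r U x_max c)
  cc <- 0.6
  J <- J_max
  for (s in seq_len(round(3000 / dt)))
    J <- step_depression(J, J_max, c(cc, cc), U, x_max, tau_r, dt)
  expect_equal(J, J_max / (1 + tau_r * U * (x_max / 1000) * cc),
               tolerance = 0.01)

  # U = 0 leaves J at the ceiling exactly
  expect_identical(step_depression(J_max, J_max, c(1, 1), 0, x_max, tau_r, dt),
                   J_max)
})

test_that("depression variants scale opposite axes of J", {
  J_max <- matrix(1, 3, 3)
  x <- c(1, 0, 0)
  pre <- step_depression(J_max, J_max, x, 0.206, 100, 93, 0.66,
                         variant = "presynaptic")
  post <- step_depression(J_max, J_max, x, 0.206, 100, 93, 0.66,
                          variant = "postsynaptic")
  expect_lt(pre[2, 1], pre[1, 2])   # column 1 (presynaptic unit 1) depressed
  expect_lt(post[1, 2], post[2, 1]) # row 1 (postsynaptic unit 1) depressed
  expect_equal(pre, t(post))
})

test_that("the noise process is stationary with the stated correlation", {
  dt <- 0.66; tau_corr <- 17; eta <- 0.05
  set.seed(99)
  # exact AR(1): simulate many units in parallel, vectorised
  n_units <- 20; n_steps <- 50000              # 1e6 samples
  pr <- noise_process(n_units, eta, tau_corr)
  X <- matrix(0, n_steps, n_units)
  for (s in seq_len(n_steps)) {
    sn <- sample_noise(pr, dt)
    pr <- sn$process
    X[s, ] <- sn$values
  }
  expect_equal(sd(X), eta, tolerance = 0.05)
  lag1 <- round(tau_corr / dt)
  ac <- function(lag) {
    a <- X[seq_len(n_steps - lag), ]; b <- X[seq_len(n_steps - lag) + lag, ]
    cor(as.vector(a), as.vector(b))
  }
  expect_equal(ac(lag1), exp(-lag1 * dt / tau_corr), tolerance = 0.02)
  expect_equal(ac(2 * lag1), exp(-2 * lag1 * dt / tau_corr), tolerance = 0.02)

  # zero amplitude emits exact zeros
  p0 <- noise_process(5, 0, tau_corr)
  expect_identical(sample_noise(p0, dt)$values, rep(0, 5))
})

test_that("a single layer settles on the scalar fixed point of its ODE", {
  # no weights, no input, no noise: h* = -theta - lambda (g(h*) - p)
  par <- semantic_layer_params(eta_amp = 0)
  par$U <- 0
  N <- 50
  par$n_units <- N
  J0 <- matrix(0, N, N)
  st <- init_layer_state(par, J0, on = NULL, relax = 0)
  for (s in seq_len(ceiling(2000 / 0.66)))
    st <- step_layer(st, par, afferent = numeric(N), dt = 0.66)
  f <- function(h) h + par$theta + par$lambda * (logistic(h, par$gain) - par$sparseness)
  h_star <- uniroot(f, c(-5, 5), tol = 1e-10)$root   # independent oracle
  expect_equal(unique(round(st$h, 6)), round(h_star, 6), tolerance = 1e-4)
})

test_that("step_layer rejects unstable step sizes and rectifies the afferent", {
  par <- semantic_layer_params()
  par$n_units <- 10
  st <- init_layer_state(par, matrix(0, 10, 10), relax = 0)
  expect_error(step_layer(st, par, numeric(10), dt = par$tau_n), "dt")
  # afferent below theta_ext contributes exactly nothing
  par0 <- par; par0$eta_amp <- 0
  st0 <- init_layer_state(par0, matrix(0, 10, 10), relax = 0)
  a <- step_layer(st0, par0, afferent = rep(par0$theta_ext - 1e-9, 10), dt = 0.66)
  b <- step_layer(st0, par0, afferent = numeric(10), dt = 0.66)
  expect_identical(a$h, b$h)
})

test_that("pattern correlation is Pearson on the binary pattern", {
  ps <- generate_pattern_set(200, 0.1, semantic_structure("a"), seed = 1,
                             baseline_id = NULL, unrelated_overlap = "zero")
  u <- pattern_units(ps, "a")
  x <- numeric(200); x[u] <- 1
  expect_equal(pattern_correlation(x, u), 1)
  # complement state: Pearson of 1 - x with x is exactly -1
  xc <- 1 - x
  expect_equal(pattern_correlation(xc, u), -1)
  # a disjoint binary pattern of the same size: closed form -p/(1-p)
  u2 <- setdiff(seq_len(200), u)[seq_along(u)]
  x2 <- numeric(200); x2[u2] <- 1
  p <- 0.1
  expect_equal(pattern_correlation(x2, u), -p / (1 - p), tolerance = 1e-12)
  expect_equal(pattern_correlation(x2, u), cor(x2, x))
  expect_error(pattern_correlation(rep(0.5, 200), u), "constant")
})

test_that("convergence detection needs a 0.95 correlation and breaks ties by order", {
  ps <- generate_pattern_set(500, 0.06, build_named_structure("freq_4x4"),
                             seed = 21)
  x <- numeric(500); x[pattern_units(ps, "nb2_3")] <- 1
  expect_identical(converged_pattern(x, ps), "nb2_3")
  xb <- numeric(500); xb[pattern_units(ps, ps$baseline_id)] <- 1
  expect_identical(converged_pattern(xb, ps), ps$baseline_id)
  expect_identical(converged_pattern(rep(0.5, 500), ps), NA_character_)
  # seeded random states essentially never reach 0.95
  set.seed(5)
  hits <- sum(vapply(seq_len(1000), function(i)
    !is.na(converged_pattern(runif(500), ps)), logical(1)))
  expect_identical(hits, 0L)
})
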