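test_that("drug-free baseline is an exact fixed point of the rhs", {
  p <- ref_params()
  y <- initial_state(p, P0 = 0)
  expect_equal(unname(apap_rhs(y, p)), rep(0, 8))
})

test_that("with all reactions off, a dosed baseline state is stationary", {
  p <- ref_params(k_sul = 0, k_gluc = 0, k_450 = 0, k_rev = 0,
                  k_GSH = 0, k_PSH = 0)
  y <- initial_state(p, P0 = 3)
  d <- apap_rhs(y, p)
  expect_equal(unname(d[c("P", "S", "G", "T")]), rep(0, 4))
})

test_that("rhs matches an independent term-by-term oracle", {
  set.seed(42)
  for (i in 1:20) {
    p <- as_rate_constants(lapply(default_config()$model$rates,
                                  function(v) v * exp(runif(1, -1, 1))))
    y <- setNames(runif(8, 0, 5), state_names())
    expect_equal(apap_rhs(y, p), oracle_rhs(y, p), tolerance = 1e-12)
  }
})

test_that("rhs rejects invalid states", {
  p <- ref_params()
  y <- initial_state(p, P0 = 1)
  y["N"] <- -1e-3
  expect_error(apap_rhs(y, p), "negative")
  y["N"] <- NA_real_
  expect_error(apap_rhs(y, p), "NA")
  expect_error(apap_rhs(c(P = 1), p), "named")
})

test_that("undosed cell stays flat at the healthy baseline", {
  p <- ref_params()
  traj <- simulate_cell(p, P0 = 0, t_end = 48)
  bl <- baseline_steady_state(p)
  s <- traj$states
  expect_equal(max(abs(s$S - bl[["S0"]])), 0, tolerance = 1e-8)
  expect_equal(max(abs(s$G - bl[["G0"]])), 0, tolerance = 1e-8)
  expect_true(all(s$T == 0))
  expect_true(all(s$P == 0) && all(s$N == 0))
})

test_that("perturbed cofactor and GSH pools relax to the beta/delta baselines", {
  p <- ref_params()
  bl <- baseline_steady_state(p)
  t_relax <- 20 / min(p$delta_S, p$delta_G)
  traj <- simulate_cell(p, P0 = 0, t_end = t_relax,
                        S0 = 3 * bl[["S0"]], G0 = 0.1 * bl[["G0"]])
  last <- traj$states[nrow(traj$states), ]
  expect_equal(last$S, bl[["S0"]], tolerance = 1e-6)
  expect_equal(last$G, bl[["G0"]], tolerance = 1e-6)
})

test_that("frozen-pool linear submodel matches the matrix-exponential solution", {
  skip_if_not_installed("Matrix")
  # k_sul = 0 and beta_S = beta_G = 0 with S0 = G0 = 0 freeze both pools,
  # leaving a linear 3x3 system in (P, N, T)
  p <- ref_params(k_sul = 0, beta_S = 0, beta_G = 0,
                  k_gluc = 0.4, k_450 = 0.3, k_rev = 0.1, k_PSH = 0.6)
  A <- rbind(c(-(p$k_gluc + p$k_450), p$k_rev, 0),
             c(p$k_450, -(p$k_rev + p$k_PSH), 0),
             c(0, p$k_PSH, 0))
  P0 <- 2
  times <- seq(0, 12, length.out = 25)
  traj <- simulate_cell(p, P0 = P0, t_end = 12, times = times)
  for (i in seq_along(times)) {
    ref <- as.vector(Matrix::expm(A * times[i]) %*% c(P0, 0, 0))
    got <- unlist(traj$states[i, c("P", "N", "T")])
    expect_equal(unname(got), ref, tolerance = 1e-8)
  }
})

test_that("with detox branches disabled, the adduct pool absorbs the full dose", {
  p <- ref_params(k_sul = 0, k_gluc = 0, k_GSH = 0, beta_G = 0,
                  k_450 = 0.5, k_PSH = 0.8)
  P0 <- 4
  traj <- simulate_cell(p, P0 = P0, t_end = 200 / p$k_450)
  last <- traj$states[nrow(traj$states), ]
  expect_equal(last$T, P0, tolerance = 1e-6)
  expect_lt(last$P + last$N, 1e-6 * P0)
})

test_that("drug mass is conserved across random parameter sets", {
  set.seed(101)
  for (i in 1:25) {
    p <- as_rate_constants(lapply(default_config()$model$rates,
                                  function(v) v * exp(runif(1, -log(10), log(10)))))
    P0 <- exp(runif(1, log(0.5), log(50)))
    traj <- simulate_cell(p, P0 = P0, t_end = 24,
                          times = seq(0, 24, length.out = 41))
    expect_lt(conservation_residual(traj)$max_relative, 1e-6)
  }
})

test_that("broken bookkeeping is detected by the conservation residual", {
  p <- ref_params()
  traj <- simulate_cell(p, P0 = 5, t_end = 24)
  good <- conservation_residual(traj)$max
  traj$states$C_GSH <- 0          # zero out a cumulative pool artificially
  expect_gt(conservation_residual(traj)$max, 1e3 * max(good, 1e-12))
})

test_that("conservation holds in a stiff regime and agrees with a tighter solve", {
  # conjugation flux ~1e4 times faster than pool turnover
  p <- ref_params(k_GSH = 5000, delta_G = 0.5, beta_G = 2)
  traj <- simulate_cell(p, P0 = 10, t_end = 24)
  expect_lt(conservation_residual(traj)$max_relative, 1e-6)
  tight <- simulate_cell(p, P0 = 10, t_end = 24, rtol = 1e-10, atol = 1e-12)
  expect_equal(traj$states$T, tight$states$T, tolerance = 1e-6)
  expect_equal(traj$states$G, tight$states$G, tolerance = 1e-6)
})

test_that("states stay non-negative and cumulative pools are monotone", {
  set.seed(202)
  for (i in 1:10) {
    p <- as_rate_constants(lapply(default_config()$model$rates,
                                  function(v) v * exp(runif(1, -1.5, 1.5))))
    traj <- simulate_cell(p, P0 = 10, t_end = 24,
                          times = seq(0, 24, length.out = 61))
    s <- traj$states
    expect_true(all(as.matrix(s[state_names()]) >= 0))
    for (col in c("T", "E_sul", "E_gluc", "C_GSH")) {
      # monotone up to accumulated solver error on the column scale
      expect_true(all(diff(s[[col]]) >= -1e-8 * max(s[[col]], 1)),
                  label = col)
    }
  }
})

test_that("terminal adduct burden falls as the detox/toxic flux ratio rises", {
  p0 <- ref_params()
  ratios <- 10^seq(-1, 1, length.out = 10)
  base_kGSH <- p0$k_GSH
  terminal <- vapply(ratios, function(r) {
    terminal_adduct(simulate_cell(ref_params(k_GSH = base_kGSH * r),
                                  P0 = 20, t_end = 24))
  }, numeric(1))
  expect_true(all(diff(terminal) < 0))
})

test_that("terminal adduct burden is non-decreasing in dose", {
  p <- ref_params()
  doses <- c(0, 1, 5, 10, 20, 40)
  terminal <- vapply(doses, function(d) {
    terminal_adduct(simulate_cell(p, P0 = d, t_end = 24))
  }, numeric(1))
  expect_true(all(diff(terminal) >= 0))
})

test_that("trajectory output grid is respected and starts at the initial state", {
  p <- ref_params()
  times <- c(0.5, 1, 3, 7)        # 0 is prepended automatically
  traj <- simulate_cell(p, P0 = 2, t_end = 10, times = times)
  expect_equal(traj$states$time, c(0, times))
  expect_equal(unlist(traj$states[1, state_names()]),
               initial_state(p, 2), tolerance = 1e-12)
  expect_error(simulate_cell(p, P0 = 2, t_end = 1, times = c(0, 2)),
               "within")
  expect_error(simulate_cell(p, P0 = 2, t_end = -1), "positive")
  expect_error(simulate_cell(p, P0 = -2, t_end = 1), "non-negative")
})
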