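test_that("peer sampling is uniform, exhaustive at m = n-1, and validated", {
  expect_setequal(sample_peers(12, 3, 11), setdiff(1:12, 3))
  expect_identical(sample_peers(2, 1, 1), 2L)
  expect_error(sample_peers(12, 1, 12), "m")
  set.seed(99)
  draws <- replicate(10000, sample_peers(3, 1, 1))
  expect_equal(mean(draws == 2), 0.5, tolerance = 0.04)
})

test_that("social influence matches hand-computed values", {
  ls <- default_ls
  fx <- make_fixture("two-agent-one-peer")
  expect_equal(social_influence(ls, 0, -1),
               fx$expected$g_0_vs_minus1, tolerance = 1e-12)
  expect_equal(social_influence(ls, 0, c(-1, 3)),
               fx$expected$g_0_vs_minus1_and_3, tolerance = 1e-12)
  expect_equal(social_influence(ls, 1.3, rep(1.3, 5)), 0)
  expect_error(social_influence(ls, 0, numeric()), "peer")
})

test_that("drift combines individual and social forces with weight alpha", {
  ls <- default_ls
  p0 <- dynamics_params(alpha = 0)
  expect_equal(drift(ls, p0, 0, c(5, -2)), -0.12)
  p1 <- dynamics_params(alpha = 1)
  expect_equal(drift(ls, p1, 0, -1), 3.14 * -0.14, tolerance = 1e-12)
  # at a critical point with identical peers both terms vanish
  pmid <- dynamics_params(alpha = 0.4)
  x_old <- default_cp$x_old
  expect_equal(drift(ls, pmid, x_old, rep(x_old, 11)), 0, tolerance = 1e-10)
})

test_that("em_step: fixed point at the old optimum, deterministic Euler update, reproducible", {
  ls <- default_ls
  p <- dynamics_params(alpha = 0, epsilon = 0)
  st <- community_state(rep(default_cp$x_old, 4), ls, p)
  st2 <- em_step(ls, p, st)
  expect_equal(st2$positions, st$positions, tolerance = 1e-10)
  expect_equal(st2$t, p$dt)
  # single noise-free agent at 0, dt = 0.1: x -> 0 + 0.1 * V'(0) = -0.012
  p2 <- dynamics_params(alpha = 0, epsilon = 0, dt = 0.1)
  s0 <- community_state(0, ls, p2)
  expect_equal(em_step(ls, p2, s0)$positions, -0.012)
  # fixed seed reproducibility of the stochastic step
  p3 <- dynamics_params(alpha = 0.3)
  run_once <- function() {
    set.seed(7)
    em_step(ls, p3, community_state(c(-1.2, -1.3, 0.2), ls, p3))$positions
  }
  expect_identical(run_once(), run_once())
})

test_that("no-return reflects only arrived agents at the valley bottom", {
  ls <- default_ls
  p <- dynamics_params()
  xb <- default_cp$x_barrier
  st <- community_state(c(default_cp$x_new, default_cp$x_old, 1.0), ls, p)
  expect_equal(st$arrived, c(TRUE, FALSE, FALSE))
  # arrived agent proposed below the barrier is reflected
  st$positions <- c(xb - 0.1, default_cp$x_old, xb - 0.2)
  out <- apply_no_return(ls, st)
  expect_equal(out$positions[1], xb + 0.1)
  # old-basin and merely-crossed agents move freely
  expect_equal(out$positions[2], default_cp$x_old)
  expect_equal(out$positions[3], xb - 0.2)
  # the boundary itself is a fixed point of the reflection
  st$positions[1] <- xb
  expect_equal(apply_no_return(ls, st)$positions[1], xb)
})

test_that("compiled and reference engines agree on the same noise stream", {
  # both engines consume R's RNG in the same order; the compiled social
  # term uses a telescoped sum, so agreement is to floating-point rounding
  ls <- default_ls
  p <- dynamics_params(alpha = 0.3, t_max = 3)
  a <- simulate_trajectory(ls, p, n = 5, seed = 11, record_every = 10,
                           engine = "cpp")
  b <- simulate_trajectory(ls, p, n = 5, seed = 11, record_every = 10,
                           engine = "r")
  expect_equal(a$position_matrix, b$position_matrix, tolerance = 1e-12)
  expect_equal(a$arrival_times, b$arrival_times, tolerance = 1e-9)
  expect_equal(a$sample_times, b$sample_times, tolerance = 1e-9)
  # and the compiled engine is reproducible under the same seed
  a2 <- simulate_trajectory(ls, p, n = 5, seed = 11, record_every = 10)
  expect_identical(a$position_matrix, a2$position_matrix)
})

test_that("noise-free agents converge to the optimum of their own basin", {
  fx <- make_fixture("noise-free-basins")
  p <- dynamics_params(epsilon = 0, t_max = 1e3, arrival_delta = 1e-9)
  left <- simulate_trajectory(fx$landscape, p, n = 1, seed = 1,
                              init = -0.5)
  expect_equal(left$positions, default_cp$x_old, tolerance = 1e-6)
  expect_true(left$censored)
  right <- simulate_trajectory(fx$landscape, p, n = 1, seed = 1, init = 2)
  expect_equal(right$positions, default_cp$x_new, tolerance = 1e-6)
  expect_false(right$censored)
})

test_that("noise-free ascent time matches the quadrature oracle within 1%", {
  ls <- default_ls
  p <- dynamics_params(alpha = 0, epsilon = 0, dt = 0.01, t_max = 1e3)
  rec <- simulate_trajectory(ls, p, n = 1, seed = 1, init = 2)
  # independent oracle: t = integral of dx / V'(x) from 2 to x_new - delta
  t_oracle <- integrate(function(x) 1 / gradient(ls, x), 2,
                        default_cp$x_new - p$arrival_delta,
                        rel.tol = 1e-10)$value
  expect_equal(rec$arrival_times[1], t_oracle, tolerance = 0.01)
})

test_that("latches are one-way and arrival implies crossing", {
  ls <- default_ls
  p <- dynamics_params(alpha = 0.2, t_max = 5)
  st <- community_state(rep(default_cp$x_old, 6), ls, p)
  set.seed(21)
  prev_crossed <- st$crossed
  prev_arrived <- st$arrived
  for (k in 1:300) {
    st <- em_step(ls, p, st)
    expect_true(all(st$crossed >= prev_crossed))
    expect_true(all(st$arrived >= prev_arrived))
    expect_true(all(!st$arrived | st$crossed))
    prev_crossed <- st$crossed
    prev_arrived <- st$arrived
  }
})

test_that("community shift happens for all agents at moderate social influence", {
  # at alpha = 0.15 shifts complete far below t_max for every seed tried
  ls <- default_ls
  p <- dynamics_params(alpha = 0.15, t_max = 1e5)
  for (seed in 1:10) {
    rec <- simulate_trajectory(ls, p, n = 12, seed = seed)
    expect_true(all(is.finite(rec$arrival_times)))
  }
})

test_that("parameter validation guards the integration", {
  expect_error(dynamics_params(alpha = 1.5), "alpha")
  expect_error(dynamics_params(dt = 0), "dt")
  expect_error(dynamics_params(epsilon = -1), "epsilon")
  ls <- default_ls
  # an absurd step fails the initial stability guard
  p <- dynamics_params(alpha = 0, epsilon = 0, dt = 50)
  expect_error(simulate_trajectory(ls, p, n = 1, seed = 1, init = 3),
               "reduce dt")
  # m too large for the community
  p2 <- dynamics_params(alpha = 0.5, m = 12)
  expect_error(simulate_trajectory(ls, p2, n = 12, seed = 1), "m")
})

test_that("single-agent first-passage time is insensitive to halving dt", {
  ls <- default_ls
  p <- dynamics_params(alpha = 0)
  f1 <- single_agent_oracle(ls, p, 200, 42)
  p$dt <- 0.005
  f2 <- single_agent_oracle(ls, p, 200, 43)
  expect_lt(abs(mean(f1) - mean(f2)) / mean(f1), 0.05)
})
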