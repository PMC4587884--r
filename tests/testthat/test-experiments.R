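test_that("community shift time is the last arrival, with honest censoring", {
  ls <- default_ls
  p <- dynamics_params(epsilon = 0, t_max = 10)
  # all agents initialized at the new paradigm: shift already done at t = 0
  rec <- simulate_trajectory(ls, p, n = 3, seed = 1,
                             init = rep(default_cp$x_new, 3))
  st <- community_shift_time(rec)
  expect_equal(st$t_s, 0)
  expect_false(st$censored)
  # maximum over per-agent arrivals
  rec$arrival_times <- c(3.2, 7.9, 5.5)
  expect_equal(community_shift_time(rec)$t_s, 7.9)
  # a never-arriving agent censors the replicate at t_max
  rec$arrival_times <- c(3.2, Inf, 5.5)
  st <- community_shift_time(rec)
  expect_true(st$censored)
  expect_equal(st$t_s, p$t_max)
})

test_that("replicate batches are reproducible and labelled with their seeds", {
  ls <- default_ls
  p <- dynamics_params(alpha = 0.15)
  r1 <- run_replicates(ls, p, n = 4, reps = 8, master_seed = 31)
  r2 <- run_replicates(ls, p, n = 4, reps = 8, master_seed = 31)
  expect_identical(r1$shift_times, r2$shift_times)
  expect_length(r1$shift_times, 8)
  expect_length(unique(r1$seeds), 8)
  r3 <- run_replicates(ls, p, n = 4, reps = 8, master_seed = 32)
  expect_false(identical(r1$shift_times, r3$shift_times))
})

test_that("an all-censored batch warns and keeps t_max as a lower bound", {
  ls <- default_ls
  p <- dynamics_params(alpha = 0, epsilon = 0, t_max = 5)
  expect_warning(r <- run_replicates(ls, p, n = 2, reps = 3,
                                     master_seed = 1), "censored")
  expect_true(all(r$censored))
  expect_true(all(r$shift_times == 5))
  expect_gt(km_mean_shift_time(r), 0)
})

test_that("alpha sweep tabulates cells sorted by (n, alpha) with an argmin per n", {
  ls <- default_ls
  p <- dynamics_params(t_max = 1e4)
  sw <- alpha_sweep(ls, p, alphas = c(0.2, 0.05, 0.1), ns = c(3, 2),
                    reps = 3, master_seed = 5)
  tab <- sw$table
  expect_equal(nrow(tab), 6)
  expect_equal(tab$n, c(2, 2, 2, 3, 3, 3))
  expect_equal(tab$alpha, rep(c(0.05, 0.1, 0.2), 2))
  expect_true(all(c("mean_ts", "se_ts", "reps", "censored_count")
                  %in% names(tab)))
  expect_equal(nrow(sw$argmin), 2)
  # degenerate one-cell sweep
  sw1 <- alpha_sweep(ls, p, alphas = 0.15, ns = 2, reps = 2,
                     master_seed = 5)
  expect_equal(nrow(sw1$table), 1)
  expect_error(alpha_sweep(ls, p, alphas = c(-0.1, 0.5), ns = 2, reps = 2,
                           master_seed = 1), "\\[0, 1\\]")
})

fake_sweep <- function(alphas, means, n = 12) {
  structure(list(
    table = data.frame(alpha = alphas, n = n, mean_ts = means,
                       se_ts = 0, reps = 1, censored_count = 0),
    argmin = data.frame(n = n, alpha_min = alphas[which.min(means)]),
    reps = 1, master_seed = 1L), class = "sweep_result")
}

test_that("regime detection finds min and max on the synthetic curve and refuses noise", {
  sw <- fake_sweep(seq(0, 1, 0.2), c(5, 3, 4, 6, 5, 2))
  rs <- regime_summary(sw)
  expect_true(rs$three_regimes)
  expect_equal(rs$alpha_min, 0.2)
  expect_equal(rs$alpha_max, 0.6)
  # strictly decreasing curve has no three-regime structure
  rs2 <- regime_summary(fake_sweep(seq(0, 1, 0.2), c(6, 5, 4, 3, 2, 1)))
  expect_false(rs2$three_regimes)
  expect_match(rs2$note, "no three-regime structure")
  # too-coarse grids are flagged, not classified
  rs3 <- regime_summary(fake_sweep(c(0, 0.5, 1), c(3, 1, 2)))
  expect_false(rs3$three_regimes)
  expect_match(rs3$note, "coarse")
})

test_that("single-agent oracle implies community times that grow with n", {
  ls <- default_ls
  p <- dynamics_params()
  fpt <- single_agent_oracle(ls, p, reps = 60, master_seed = 17)
  expect_true(all(is.finite(fpt)))
  # n = 1: the raw draws come back unchanged
  expect_equal(implied_community_times(fpt, 1), as.numeric(fpt))
  # implied mean community time is non-decreasing in n (max of more draws)
  means <- vapply(c(1, 4, 12, 36), function(n)
    mean(implied_community_times(fpt, n, reps = 400, seed = 3)),
    numeric(1))
  expect_true(all(diff(means) >= 0))
})

test_that("oracle and direct simulation are self-consistent at alpha = 0", {
  ls <- default_ls
  p <- dynamics_params(alpha = 0)
  direct <- run_replicates(ls, p, n = 1, reps = 60, master_seed = 23)
  oracle <- single_agent_oracle(ls, p, reps = 60, master_seed = 29)
  expect_gt(ks.test(direct$shift_times, oracle)$p.value, 0.01)
})

test_that("pioneer-to-laggard spread shrinks with moderate social influence", {
  ls <- default_ls
  p0 <- dynamics_params(alpha = 0)
  p15 <- dynamics_params(alpha = 0.15)
  s0 <- migration_spread(ls, p0, n = 12, reps = 50, master_seed = 9)
  s15 <- migration_spread(ls, p15, n = 12, reps = 50, master_seed = 9)
  expect_lt(median(s15), median(s0))
})
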