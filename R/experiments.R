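#' Community paradigm-shift time of one realization
#'
#' The shift time t_s is the first time by which the *complete* community
#' has arrived at the new paradigm, i.e. the maximum over agents of the
#' first-arrival times. If any agent never arrives within `t_max` the
#' replicate is censored and `t_max` is reported as a lower bound.
#'
#' @param record A [simulate_trajectory()] result.
#' @return List with `t_s` (numeric) and `censored` (logical).
#' @export
community_shift_time <- function(record) {
  stopifnot(inherits(record, "trajectory_record"))
  at <- record$arrival_times
  if (any(is.infinite(at)))
    list(t_s = record$params$t_max, censored = TRUE)
  else
    list(t_s = max(at), censored = FALSE)
}

# deterministic per-replicate seed spawning from one master seed
spawn_seeds <- function(master_seed, k) {
  set.seed(as.integer(master_seed))
  sample.int(.Machine$integer.max, k)
}

#' Run a batch of independent replicates
#'
#' Simulates `reps` independent realizations at fixed (alpha, n), each with
#' its own seed spawned deterministically from `master_seed`, and collects
#' the community shift times. Results are identical for identical
#' `master_seed` and independent of execution order.
#'
#' @param landscape A [quartic_landscape()].
#' @param params A [dynamics_params()].
#' @param n Community size.
#' @param reps Number of replicates (>= 1).
#' @param master_seed Integer master seed.
#' @return An object of class `shift_time_result`: list with `alpha`, `n`,
#'   `shift_times`, `censored`, `seeds`.
#' @export
run_replicates <- function(landscape, params, n, reps, master_seed) {
  if (reps < 1) stop("reps must be >= 1", call. = FALSE)
  seeds <- spawn_seeds(master_seed, reps)
  ts <- numeric(reps)
  cen <- logical(reps)
  for (k in seq_len(reps)) {
    rec <- simulate_trajectory(landscape, params, n, seed = seeds[k])
    st <- community_shift_time(rec)
    ts[k] <- st$t_s
    cen[k] <- st$censored
  }
  if (all(cen))
    warning("all ", reps, " replicates censored at t_max = ",
            params$t_max, call. = FALSE)
  structure(list(alpha = params$alpha, n = n, shift_times = ts,
                 censored = cen, seeds = seeds),
            class = "shift_time_result")
}

#' @export
print.shift_time_result <- function(x, ...) {
  ok <- !x$censored
  cat(sprintf(
    "shift_time_result: alpha = %g, n = %d, reps = %d (%d censored)\n",
    x$alpha, x$n, length(x$shift_times), sum(x$censored)))
  if (any(ok))
    cat(sprintf("  mean t_s = %.1f, se = %.1f\n", mean(x$shift_times[ok]),
                sd(x$shift_times[ok]) / sqrt(sum(ok))))
  invisible(x)
}

#' Kaplan-Meier mean shift time for a censored batch
#'
#' Restricted-mean estimate via [survival::survfit()], for cells where
#' excluding censored replicates would bias the plain mean.
#'
#' @param result A [run_replicates()] result.
#' @return Restricted mean survival (shift) time.
#' @export
km_mean_shift_time <- function(result) {
  stopifnot(inherits(result, "shift_time_result"))
  fit <- survival::survfit(
    survival::Surv(result$shift_times, !result$censored) ~ 1)
  unname(summary(fit, rmean = "common")$table["rmean"])
}

# centered moving average (window 3, shrinking at the edges)
moving_average3 <- function(y) {
  k <- length(y)
  vapply(seq_len(k), function(i)
    mean(y[max(1, i - 1):min(k, i + 1)]), numeric(1))
}

#' Sweep the social-influence weight across population sizes
#'
#' The full factorial experiment behind the mean shift-time curve: for
#' every combination of `alpha` in `alphas` and `n` in `ns`, runs `reps`
#' replicates (with `m = n - 1` unless `params_base$m` is set) and tabulates
#' mean and standard error of the community shift time over uncensored
#' replicates, with the censored count reported alongside. The per-`n`
#' argmin of the 3-point moving-average smoothed mean curve is also
#' reported.
#'
#' @param landscape A [quartic_landscape()].
#' @param params_base A [dynamics_params()] supplying everything but alpha.
#' @param alphas Numeric grid in \[0, 1\].
#' @param ns Integer vector of community sizes.
#' @param reps Replicates per cell.
#' @param master_seed Integer master seed; each cell gets an independent
#'   derived seed, so results do not depend on execution order.
#' @return An object of class `sweep_result`: list with `table` (data.frame
#'   of alpha, n, mean_ts, se_ts, reps, censored_count, sorted by (n,
#'   alpha)), `argmin` (data.frame of n, alpha_min on the smoothed curve),
#'   `reps`, `master_seed`.
#' @examples
#' \donttest{
#' ls <- quartic_landscape()
#' p <- dynamics_params()
#' sw <- alpha_sweep(ls, p, alphas = seq(0, 1, 0.1), ns = 12,
#'                   reps = 20, master_seed = 7)
#' sw$argmin
#' }
#' @export
alpha_sweep <- function(landscape, params_base, alphas, ns, reps,
                        master_seed) {
  if (any(alphas < 0 | alphas > 1))
    stop("alpha grid must lie in [0, 1]", call. = FALSE)
  ns <- sort(as.integer(ns))
  alphas <- sort(alphas)
  cells <- expand.grid(alpha = alphas, n = ns, KEEP.OUT.ATTRS = FALSE)
  cells <- cells[order(cells$n, cells$alpha), ]
  cell_seeds <- spawn_seeds(master_seed, nrow(cells))
  rows <- vector("list", nrow(cells))
  for (k in seq_len(nrow(cells))) {
    a <- cells$alpha[k]; n <- cells$n[k]
    p <- params_base; p$alpha <- a
    res <- run_replicates(landscape, p, n, reps, cell_seeds[k])
    ok <- !res$censored
    rows[[k]] <- data.frame(
      alpha = a, n = n,
      mean_ts = if (any(ok)) mean(res$shift_times[ok]) else NA_real_,
      se_ts = if (sum(ok) > 1) sd(res$shift_times[ok]) / sqrt(sum(ok))
              else NA_real_,
      reps = reps, censored_count = sum(res$censored))
  }
  tab <- do.call(rbind, rows)
  argmin <- do.call(rbind, lapply(ns, function(n) {
    sub <- tab[tab$n == n, ]
    sm <- moving_average3(sub$mean_ts)
    data.frame(n = n, alpha_min = sub$alpha[which.min(sm)])
  }))
  structure(list(table = tab, argmin = argmin, reps = reps,
                 master_seed = as.integer(master_seed)),
            class = "sweep_result")
}

#' @export
print.sweep_result <- function(x, ...) {
  cat(sprintf("sweep_result: %d alpha points x n in {%s}, %d reps/cell\n",
              length(unique(x$table$alpha)),
              paste(unique(x$table$n), collapse = ", "), x$reps))
  print(x$argmin, row.names = FALSE)
  invisible(x)
}

#' Detect the three-regime structure of the mean shift-time curve
#'
#' On the 3-point moving-average smoothed mean t_s curve for each n, finds
#' the first interior local minimum and the subsequent local maximum, and
#' classifies the curve into decrease / increase / decrease segments. The
#' characteristic pattern is: a little social influence speeds the shift,
#' intermediate coupling makes the community conservative, and strong
#' coupling lets it migrate as one. Detection failure (e.g. a strictly
#' decreasing curve, or Monte-Carlo noise defeating the smoother) is
#' reported honestly, never forced.
#'
#' @param sweep A [alpha_sweep()] result (>= 5 grid points).
#' @return Data frame with one row per n: `n`, `three_regimes` (logical),
#'   `alpha_min`, `alpha_max` (NA when not detected), `note`.
#' @export
regime_summary <- function(sweep) {
  stopifnot(inherits(sweep, "sweep_result"))
  tab <- sweep$table
  out <- lapply(unique(tab$n), function(n) {
    sub <- tab[tab$n == n, ]
    if (nrow(sub) < 5L)
      return(data.frame(n = n, three_regimes = FALSE, alpha_min = NA_real_,
                        alpha_max = NA_real_, note = "grid too coarse"))
    if (any(!is.finite(sub$mean_ts)))
      return(data.frame(n = n, three_regimes = FALSE, alpha_min = NA_real_,
                        alpha_max = NA_real_,
                        note = "fully censored cell(s) in curve"))
    s <- moving_average3(sub$mean_ts)
    k <- length(s)
    # first interior local minimum: s[i-1] >= s[i] and s[i] < s[i+1]
    i_min <- NA_integer_
    for (i in 2:(k - 1)) {
      if (s[i - 1] >= s[i] && s[i] < s[i + 1]) { i_min <- i; break }
    }
    if (is.na(i_min))
      return(data.frame(n = n, three_regimes = FALSE, alpha_min = NA_real_,
                        alpha_max = NA_real_,
                        note = "no three-regime structure"))
    # subsequent interior local maximum
    i_max <- NA_integer_
    if (i_min < k - 1) for (i in (i_min + 1):(k - 1)) {
      if (s[i - 1] < s[i] && s[i] >= s[i + 1]) { i_max <- i; break }
    }
    if (is.na(i_max))
      return(data.frame(n = n, three_regimes = FALSE,
                        alpha_min = sub$alpha[i_min], alpha_max = NA_real_,
                        note = "no three-regime structure"))
    # final segment must come back down
    if (s[k] >= s[i_max])
      return(data.frame(n = n, three_regimes = FALSE,
                        alpha_min = sub$alpha[i_min],
                        alpha_max = sub$alpha[i_max], note = "inconclusive"))
    data.frame(n = n, three_regimes = TRUE,
               alpha_min = sub$alpha[i_min], alpha_max = sub$alpha[i_max],
               note = "decrease-increase-decrease")
  })
  do.call(rbind, out)
}

#' Single-agent first-passage oracle
#'
#' The independence baseline: with alpha forced to 0 a lone agent's
#' old-to-new first-passage times are drawn, and community shift times for
#' any n are implied as maxima of n independent draws (see
#' [implied_community_times()]). At alpha = 0 the direct n-agent community
#' shift-time distribution must be statistically indistinguishable from
#' this construction.
#'
#' @param landscape A [quartic_landscape()].
#' @param params A [dynamics_params()] (alpha and m are overridden).
#' @param reps Number of draws.
#' @param master_seed Integer master seed.
#' @return Numeric vector of first-passage times (`Inf` kept for censored
#'   draws), with attribute `t_max`.
#' @export
single_agent_oracle <- function(landscape, params, reps, master_seed) {
  p <- params
  p$alpha <- 0
  p$m <- NULL
  seeds <- spawn_seeds(master_seed, reps)
  fpt <- vapply(seeds, function(s) {
    rec <- simulate_trajectory(landscape, p, n = 1L, seed = s)
    rec$arrival_times[1]
  }, numeric(1))
  attr(fpt, "t_max") <- p$t_max
  fpt
}

#' Implied community shift times from single-agent draws
#'
#' Resamples `n` single-agent first-passage times (with replacement) and
#' takes their maximum, `reps` times. For `n = 1` the raw draws are
#' returned unchanged. The implied mean community time is non-decreasing in
#' n (maximum of more iid draws).
#'
#' @param fpt Vector of single-agent first-passage times
#'   ([single_agent_oracle()]).
#' @param n Community size to imply.
#' @param reps Number of implied community times (default `length(fpt)`).
#' @param seed Integer seed for the resampling.
#' @return Numeric vector of implied community shift times.
#' @export
implied_community_times <- function(fpt, n, reps = length(fpt), seed = 1L) {
  if (n == 1L && reps == length(fpt)) return(as.numeric(fpt))
  set.seed(as.integer(seed))
  matrix(sample(fpt, n * reps, replace = TRUE), nrow = reps) |>
    apply(1, max)
}

#' Lead time between pioneer and laggard arrival
#'
#' For each replicate, the time between the first agent's arrival and the
#' last agent's arrival, as a fraction of the community shift time. Small
#' values signal the follow-the-leader effect: once pioneers conquer the
#' new paradigm the rest migrate swiftly.
#'
#' @param landscape,params,n,reps,master_seed As in [run_replicates()].
#' @return Numeric vector (one fraction per uncensored replicate).
#' @export
migration_spread <- function(landscape, params, n, reps, master_seed) {
  seeds <- spawn_seeds(master_seed, reps)
  out <- numeric(0)
  for (s in seeds) {
    rec <- simulate_trajectory(landscape, params, n, seed = s)
    at <- rec$arrival_times
    if (all(is.finite(at)) && max(at) > 0)
      out <- c(out, (max(at) - min(at)) / max(at))
  }
  out
}
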