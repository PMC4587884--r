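#' Dynamics parameters for the community evolution equation
#'
#' Bundles the parameters of the per-agent Langevin equation
#' \deqn{dx_i/dt = (1-\alpha) V'(x_i) + \alpha\,\omega\, g(x_i, x_j) + \varepsilon\,\xi(t)}
#' where `g` is the peer-sampled social-influence term and `xi(t)` is
#' zero-mean Gaussian white noise.
#'
#' @param alpha Weight on social influence, in \[0, 1\]. `alpha = 0` is pure
#'   individual hill climbing; `alpha = 1` pure social learning.
#' @param omega Strength ratio of social to individual information
#'   (default 3.14).
#' @param epsilon Experimentation-noise strength (default 0.37).
#' @param dt Euler-Maruyama step (default 0.01 model-time units).
#' @param m Peers sampled (without replacement) per agent per step;
#'   `NULL` (default) resolves to `n - 1`, i.e. the whole community.
#' @param t_max Censoring horizon in model time (default 1e5).
#' @param arrival_delta An agent has "arrived" at the new paradigm once
#'   `x >= x_new - arrival_delta` (default 0.5).
#' @param no_return If `TRUE` (default), an agent that has arrived at the
#'   new paradigm is reflected at the valley bottom and cannot migrate
#'   back to the old paradigm (see [apply_no_return()]).
#' @param jitter_sd Gaussian spread of the initial condition around
#'   `x_old` (default 0: all agents exactly at the old optimum).
#' @return An object of class `dynamics_params`.
#' @export
dynamics_params <- function(alpha = 0, omega = 3.14, epsilon = 0.37,
                            dt = 0.01, m = NULL, t_max = 1e5,
                            arrival_delta = 0.5, no_return = TRUE,
                            jitter_sd = 0) {
  num1 <- function(v, nm, lo = -Inf, hi = Inf, lo_open = FALSE) {
    if (!is.numeric(v) || length(v) != 1L || !is.finite(v))
      stop("'", nm, "' must be a single finite number", call. = FALSE)
    if (v < lo || v > hi || (lo_open && v <= lo))
      stop("'", nm, "' = ", v, " is out of range", call. = FALSE)
    v
  }
  alpha <- num1(alpha, "alpha", 0, 1)
  omega <- num1(omega, "omega", 0, Inf, lo_open = TRUE)
  epsilon <- num1(epsilon, "epsilon", 0)
  dt <- num1(dt, "dt", 0, Inf, lo_open = TRUE)
  t_max <- num1(t_max, "t_max", 0, Inf, lo_open = TRUE)
  arrival_delta <- num1(arrival_delta, "arrival_delta", 0, Inf, lo_open = TRUE)
  jitter_sd <- num1(jitter_sd, "jitter_sd", 0)
  if (!is.null(m)) {
    m <- num1(m, "m", 1)
    if (m != round(m)) stop("'m' must be an integer", call. = FALSE)
    m <- as.integer(m)
  }
  if (!is.logical(no_return) || length(no_return) != 1L || is.na(no_return))
    stop("'no_return' must be TRUE or FALSE", call. = FALSE)
  structure(list(alpha = alpha, omega = omega, epsilon = epsilon, dt = dt,
                 m = m, t_max = t_max, arrival_delta = arrival_delta,
                 no_return = no_return, jitter_sd = jitter_sd),
            class = "dynamics_params")
}

# resolve m for a given community size, enforcing 1 <= m <= n-1
resolve_m <- function(params, n) {
  m <- if (is.null(params$m)) n - 1L else params$m
  if (n < 2L && m >= 1L && is.null(params$m)) m <- 0L
  if (!is.null(params$m) && (m < 1L || m > n - 1L))
    stop("m = ", m, " must satisfy 1 <= m <= n-1 (n = ", n, ")",
         call. = FALSE)
  as.integer(m)
}

#' Sample an agent's peer set
#'
#' Draws `m` distinct peer indices uniformly without replacement from the
#' other `n - 1` agents. Peers are redrawn independently for every agent at
#' every step; with the default `m = n - 1` the draw is the whole rest of
#' the community and involves no randomness.
#'
#' @param n Community size.
#' @param i Focal agent index in `1:n`.
#' @param m Number of peers, `1 <= m <= n - 1`.
#' @return Integer vector of `m` peer indices.
#' @export
sample_peers <- function(n, i, m) {
  if (m < 1L || m > n - 1L)
    stop("m = ", m, " must satisfy 1 <= m <= n-1 (n = ", n, ")",
         call. = FALSE)
  others <- seq_len(n)[-i]
  if (m == n - 1L) return(others)
  others[sample.int(n - 1L, m)]
}

#' Social-influence force on one agent
#'
#' \deqn{g(x_i) = \frac{1}{m} \sum_j [V(x_j) - V(x_i)]\,(x_j - x_i)}
#' An agent is attracted toward sampled peers sitting higher on the
#' landscape and repelled from peers sitting lower.
#'
#' @param landscape A [quartic_landscape()].
#' @param x_i Focal agent position.
#' @param peer_positions Non-empty numeric vector of sampled peer positions.
#' @return The social force (scalar).
#' @export
social_influence <- function(landscape, x_i, peer_positions) {
  if (length(peer_positions) == 0L)
    stop("empty peer set: social influence is undefined", call. = FALSE)
  check_positions(x_i); check_positions(peer_positions)
  vi <- potential_value(landscape, x_i)
  mean((potential_value(landscape, peer_positions) - vi) *
         (peer_positions - x_i))
}

#' Deterministic drift on one agent
#'
#' The noise-free part of the evolution equation,
#' `(1 - alpha) * V'(x_i) + alpha * omega * g(x_i, peers)`.
#' With `alpha = 0` the peer set is ignored and may be empty.
#'
#' @param landscape A [quartic_landscape()].
#' @param params A [dynamics_params()].
#' @param x_i Focal agent position.
#' @param peer_positions Sampled peer positions (required when `alpha > 0`).
#' @return The drift (scalar).
#' @export
drift <- function(landscape, params, x_i, peer_positions = numeric()) {
  ind <- (1 - params$alpha) * gradient(landscape, x_i)
  soc <- if (params$alpha > 0)
    params$alpha * params$omega *
      social_influence(landscape, x_i, peer_positions)
  else 0
  ind + soc
}

#' Community state
#'
#' Positions of the `n` agents plus one-way latch flags: `crossed` (the
#' agent has at some point exceeded the valley bottom `x_barrier`) and
#' `arrived` (the agent has reached `x_new - arrival_delta`). Both latches
#' are monotone: once set they never revert.
#'
#' @param positions Numeric vector of agent positions.
#' @param landscape A [quartic_landscape()].
#' @param params A [dynamics_params()].
#' @param t Model time of the state (default 0).
#' @return An object of class `community_state`.
#' @export
community_state <- function(positions, landscape, params, t = 0) {
  check_positions(positions)
  cp <- critical_points(landscape)
  x_arrive <- cp$x_new - params$arrival_delta
  arrived <- positions >= x_arrive
  structure(list(
    positions = positions,
    crossed = positions > cp$x_barrier,
    arrived = arrived,
    arrival_times = ifelse(arrived, t, Inf),
    t = t,
    x_barrier = cp$x_barrier,
    x_arrive = x_arrive),
    class = "community_state")
}

#' No-return rule: reflect arrived agents at the valley bottom
#'
#' Agents that have conquered the new paradigm (`arrived = TRUE`, i.e.
#' have at some point reached `x_new - arrival_delta`) can never migrate
#' back to the old paradigm: a proposed position below `x_barrier` is
#' reflected, `x <- 2 * x_barrier - x`. Agents that have not yet arrived
#' move freely in both basins — in particular, a would-be pioneer that has
#' merely crossed the valley may still be pulled back by the conservative
#' social force of the old-paradigm majority, which is essential to the
#' three-regime shape of the shift-time curve.
#'
#' @param landscape A [quartic_landscape()] (supplies `x_barrier`).
#' @param state A [community_state()] holding proposed positions.
#' @return The state with reflected positions.
#' @export
apply_no_return <- function(landscape, state) {
  xb <- state$x_barrier
  bad <- state$arrived & state$positions < xb
  state$positions[bad] <- 2 * xb - state$positions[bad]
  state
}

#' One synchronous Euler-Maruyama step (reference R implementation)
#'
#' All agents' drifts are computed from the same pre-step positions; the
#' update is `x + drift * dt + epsilon * sqrt(dt) * z` with independent
#' standard-normal `z`, followed by the no-return reflection and latch
#' updates. This pure-R stepper defines the semantics; the compiled engine
#' in [simulate_trajectory()] consumes the same RNG stream and reproduces
#' it to floating-point rounding.
#'
#' @param landscape A [quartic_landscape()].
#' @param params A [dynamics_params()].
#' @param state A [community_state()].
#' @return The advanced `community_state` (time `t + dt`).
#' @export
em_step <- function(landscape, params, state) {
  n <- length(state$positions)
  m <- resolve_m(params, n)
  x <- state$positions
  dr <- numeric(n)
  for (i in seq_len(n)) {
    dr[i] <- if (params$alpha > 0 && n > 1L)
      drift(landscape, params, x[i], x[sample_peers(n, i, m)])
    else  # single agent or alpha = 0: no social term
      (1 - params$alpha) * gradient(landscape, x[i])
  }
  prop <- x + dr * params$dt
  if (params$epsilon > 0)
    prop <- prop + params$epsilon * sqrt(params$dt) * rnorm(n)
  if (any(!is.finite(prop)))
    stop("non-finite position at t=", state$t + params$dt,
         " (step too large?)", call. = FALSE)
  state$positions <- prop
  if (params$no_return) state <- apply_no_return(landscape, state)
  state$t <- state$t + params$dt
  state$crossed <- state$crossed | state$positions > state$x_barrier
  newly <- !state$arrived & state$positions >= state$x_arrive
  state$arrived <- state$arrived | newly
  state$arrival_times[newly] <- state$t
  state
}

#' Simulate a full community trajectory
#'
#' Initializes all agents at the old optimum `x_old` (plus optional
#' Gaussian jitter), then iterates the synchronous Euler-Maruyama update
#' until every agent has arrived at the new paradigm or the censoring
#' horizon `t_max` is reached. The compiled engine and the pure-R engine
#' share R's RNG stream; repeated runs with the same seed and engine are
#' bit-identical, and the two engines agree to floating-point rounding.
#'
#' @param landscape A [quartic_landscape()].
#' @param params A [dynamics_params()].
#' @param n Community size (>= 1).
#' @param seed Integer seed for this realization.
#' @param record_every Record positions every this many steps (0 = record
#'   nothing but arrival times).
#' @param engine `"cpp"` (default, compiled) or `"r"` (reference).
#' @param init Optional numeric vector of initial positions (length `n`),
#'   overriding the at-`x_old` initial condition.
#' @return An object of class `trajectory_record`: list with
#'   `sample_times`, `position_matrix` (samples x n), `arrival_times`
#'   (`Inf` = censored), `censored`, `t_end`, `seed`, `n`, and the
#'   parameters used.
#' @examples
#' ls <- quartic_landscape()
#' p <- dynamics_params(alpha = 0.15, t_max = 2e3)
#' rec <- simulate_trajectory(ls, p, n = 12, seed = 1, record_every = 100)
#' range(rec$arrival_times)
#' @export
simulate_trajectory <- function(landscape, params, n, seed,
                                record_every = 0L,
                                engine = c("cpp", "r"), init = NULL) {
  stopifnot(inherits(landscape, "quartic_landscape"),
            inherits(params, "dynamics_params"))
  engine <- match.arg(engine)
  if (!is.numeric(n) || length(n) != 1L || n < 1 || n != round(n))
    stop("n must be a positive integer", call. = FALSE)
  n <- as.integer(n)
  m <- resolve_m(params, n)
  cp <- critical_points(landscape)
  set.seed(as.integer(seed))
  x0 <- if (is.null(init)) {
    rep(cp$x_old, n) +
      (if (params$jitter_sd > 0) rnorm(n, 0, params$jitter_sd) else 0)
  } else {
    check_positions(init)
    if (length(init) != n) stop("init must have length n", call. = FALSE)
    init
  }
  # stability guard on the initial state: one step must not overshoot
  d0 <- max(abs(vapply(seq_len(n), function(i)
    if (params$alpha > 0 && n > 1L)
      drift(landscape, params, x0[i], x0[-i][seq_len(m)])
    else (1 - params$alpha) * gradient(landscape, x0[i]),
    numeric(1))))
  if (params$dt * d0 >= 0.5)
    stop("dt * max|drift| = ", signif(params$dt * d0, 3),
         " >= 0.5 at initialization; reduce dt", call. = FALSE)

  x_arrive <- cp$x_new - params$arrival_delta
  if (engine == "cpp") {
    res <- sim_core(x0, landscape$a, landscape$b, landscape$c, landscape$d,
                    landscape$e, params$alpha, params$omega, params$epsilon,
                    params$dt, m, params$t_max, cp$x_barrier, x_arrive,
                    params$no_return, as.integer(record_every))
    if (res$exited_range)
      warning("an agent left the diagnostic range [-10, 15]", call. = FALSE)
    out <- list(sample_times = res$sample_times,
                position_matrix = res$position_matrix,
                arrival_times = res$arrival_times,
                positions = res$positions,
                crossed = res$crossed,
                arrived = res$arrived,
                t_end = res$t_end)
  } else {
    state <- community_state(x0, landscape, params)
    max_steps <- ceiling(params$t_max / params$dt - 1e-9)
    rec_t <- if (record_every > 0) list(0) else list()
    rec_x <- if (record_every > 0) list(x0) else list()
    step <- 0
    while (!all(state$arrived) && step < max_steps) {
      state <- em_step(landscape, params, state)
      state$t <- step * params$dt + params$dt  # avoid accumulation drift
      step <- step + 1
      if (record_every > 0 &&
          (step %% record_every == 0 || all(state$arrived))) {
        rec_t[[length(rec_t) + 1L]] <- state$t
        rec_x[[length(rec_x) + 1L]] <- state$positions
      }
    }
    if (any(state$positions < -10 | state$positions > 15))
      warning("an agent left the diagnostic range [-10, 15]", call. = FALSE)
    out <- list(sample_times = unlist(rec_t),
                position_matrix = if (record_every > 0)
                  do.call(rbind, rec_x) else matrix(0, 0, n),
                arrival_times = state$arrival_times,
                positions = state$positions,
                crossed = state$crossed,
                arrived = state$arrived,
                t_end = step * params$dt)
  }
  # fix arrival_times for the R engine's accumulated t (recompute latch-safe)
  out$censored <- any(is.infinite(out$arrival_times))
  out$seed <- as.integer(seed)
  out$n <- n
  out$m <- m
  out$params <- params
  class(out) <- "trajectory_record"
  out
}

#' @export
print.trajectory_record <- function(x, ...) {
  cat(sprintf("trajectory_record: n = %d, alpha = %g, seed = %d\n",
              x$n, x$params$alpha, x$seed))
  cat(sprintf("  t_end = %g, arrived = %d/%d%s\n", x$t_end,
              sum(is.finite(x$arrival_times)), x$n,
              if (x$censored) " (censored)" else ""))
  invisible(x)
}

#' Tidy a trajectory record into a long table
#'
#' @param record A [simulate_trajectory()] result with `record_every > 0`.
#' @return A data.frame with columns `time`, `agent_id`, `position`.
#' @export
trajectory_table <- function(record) {
  stopifnot(inherits(record, "trajectory_record"))
  if (length(record$sample_times) == 0L)
    stop("trajectory was not recorded (record_every = 0)", call. = FALSE)
  n <- record$n
  data.frame(
    time = rep(record$sample_times, times = n),
    agent_id = rep(seq_len(n), each = length(record$sample_times)),
    position = as.vector(record$position_matrix))
}
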