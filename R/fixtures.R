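#' Deterministic test fixtures
#'
#' Tiny named scenarios used by the test suite and examples, each a list
#' of a landscape, dynamics parameters and hand-computed expected values:
#'
#' * `"default-landscape"`: the standard parameters with the known
#'   critical structure (gamma = 0.04, roots near -1.27, 0.5, 4.5).
#' * `"two-agent-one-peer"`: hand-expanded potential and social-influence
#'   values at x = 0 with peers at -1 (and 3).
#' * `"noise-free-basins"`: epsilon = 0 convergence endpoints for starts
#'   on either side of the valley bottom.
#'
#' @param name Fixture name.
#' @return List with `landscape`, `params`, `expected`.
#' @export
make_fixture <- function(name) {
  ls <- quartic_landscape()
  switch(
    name,
    "default-landscape" = list(
      landscape = ls,
      params = dynamics_params(),
      expected = list(gamma = 0.04,
                      x_old_2dp = -1.27, x_barrier_1dp = 0.5,
                      x_new_1dp = 4.5)),
    "two-agent-one-peer" = list(
      landscape = ls,
      params = dynamics_params(alpha = 1),
      expected = list(V_at_minus1 = 2.14, V_at_0 = 2.0, V_at_3 = 2.90,
                      g_0_vs_minus1 = -0.14, g_0_vs_minus1_and_3 = 1.28,
                      drift_alpha1_omega_g = 3.14 * -0.14)),
    "noise-free-basins" = list(
      landscape = ls,
      params = dynamics_params(epsilon = 0, t_max = 1e3),
      expected = list(endpoint_from_minus0.5 = "x_old",
                      endpoint_from_2 = "x_new")),
    stop("unknown fixture: ", name, call. = FALSE))
}
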