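#' paradigmflow: collective search and paradigm shifts on a quartic landscape
#'
#' A homogeneous community of n agents explores a fixed one-dimensional
#' "physical-technological" landscape V(x) with a local optimum (the current
#' paradigm) and a higher global optimum (the new paradigm). Each agent
#' follows a Langevin-type evolution equation combining individual gradient
#' ascent, peer-sampled social influence weighted by alpha, and Gaussian
#' experimentation noise. The headline output is the mean community
#' first-passage time from the old optimum to the new one, as a function of
#' alpha and n.
#'
#' @useDynLib paradigmflow, .registration = TRUE
#' @importFrom Rcpp sourceCpp
#' @importFrom stats rnorm sd ks.test wilcox.test complete.cases setNames
#' @importFrom utils write.table read.delim modifyList
#' @keywords internal
"_PACKAGE"

#' Construct a quartic physical-technological landscape
#'
#' The landscape is the inverted double-well quartic
#' \deqn{V(x) = a\,(-x\,(x+b)(x-c)(x-d) + e)}
#' whose two hills represent the current (local optimum) and new (global
#' optimum) paradigms, separated by a valley. Its gradient is a cubic with
#' three real roots \eqn{x_{old} < x_{barrier} < x_{new}} and factors as
#' \eqn{-\gamma (x - x_{new})(x - x_{barrier})(x - x_{old})} with
#' \eqn{\gamma = 4a}. Defaults give \eqn{\gamma = 0.04} and roots near
#' \eqn{-1.27}, \eqn{0.5} and \eqn{4.5}.
#'
#' @param a Overall scale of the potential (positive; default `1e-2`).
#' @param b,c,d Root offsets of the quartic product (positive; defaults
#'   2, 1, 6). The quartic `-x(x+b)(x-c)(x-d)` vanishes at 0, -b, c, d.
#' @param e Vertical offset (positive; default `2e2`) keeping V positive
#'   over the region of interest.
#' @return An object of class `quartic_landscape`: a list with fields
#'   `a`, `b`, `c`, `d`, `e` and the expanded gradient coefficients.
#' @seealso [critical_points()], [potential_value()], [gradient()]
#' @examples
#' ls <- quartic_landscape()
#' potential_value(ls, c(0, 1, -1))
#' critical_points(ls)
#' @export
quartic_landscape <- function(a = 1e-2, b = 2, c = 1, d = 6, e = 2e2) {
  for (nm in c("a", "b", "c", "d", "e")) {
    v <- get(nm)
    if (!is.numeric(v) || length(v) != 1L || !is.finite(v) || v <= 0)
      stop("landscape parameter '", nm, "' must be a single positive finite number",
           call. = FALSE)
  }
  structure(
    list(a = a, b = b, c = c, d = d, e = e,
         # V(x) = a*(-x^4 + q3 x^3 + q2 x^2 + q1 x + e)
         q3 = c + d - b,
         q2 = -(c * d - b * c - b * d),
         q1 = -b * c * d),
    class = "quartic_landscape")
}

#' @export
print.quartic_landscape <- function(x, ...) {
  cat("Quartic physical-technological landscape\n")
  cat(sprintf("  V(x) = %g * (-x(x%+g)(x%+g)(x%+g) + %g)\n",
              x$a, x$b, -x$c, -x$d, x$e))
  cp <- critical_points(x)
  cat(sprintf("  old paradigm x_old = %.4f   V = %.4f\n", cp$x_old,
              potential_value(x, cp$x_old)))
  cat(sprintf("  valley      x_barrier = %.4f   V = %.4f\n", cp$x_barrier,
              potential_value(x, cp$x_barrier)))
  cat(sprintf("  new paradigm x_new = %.4f   V = %.4f\n", cp$x_new,
              potential_value(x, cp$x_new)))
  cat(sprintf("  gamma = %g, barrier height = %.4f, gain = %.4f\n",
              cp$gamma, cp$barrier_from_old, cp$gain))
  invisible(x)
}

check_positions <- function(x) {
  if (!is.numeric(x) || length(x) == 0L)
    stop("positions must be a non-empty numeric vector", call. = FALSE)
  if (any(!is.finite(x)))
    stop("positions must be finite (got ",
         paste(utils::head(x[!is.finite(x)], 3), collapse = ", "), ")",
         call. = FALSE)
  invisible(x)
}

#' Evaluate the landscape potential
#'
#' @param landscape A [quartic_landscape()].
#' @param x Numeric vector of positions (finite).
#' @return `V(x)`, elementwise.
#' @export
potential_value <- function(landscape, x) {
  stopifnot(inherits(landscape, "quartic_landscape"))
  check_positions(x)
  with(landscape, a * (((((-x + q3) * x + q2) * x + q1) * x) + e))
}

#' Evaluate the landscape gradient (the individual-search force)
#'
#' Analytic derivative of the quartic potential, in expanded form. It is
#' algebraically identical to the factored cubic
#' \eqn{-\gamma (x - x_{new})(x - x_{barrier})(x - x_{old})}.
#'
#' @inheritParams potential_value
#' @return `V'(x)`, elementwise.
#' @export
gradient <- function(landscape, x) {
  stopifnot(inherits(landscape, "quartic_landscape"))
  check_positions(x)
  with(landscape, a * (((-4 * x + 3 * q3) * x + 2 * q2) * x + q1))
}

#' Critical points of the landscape
#'
#' Finds the three real roots of `V'(x) = 0` via companion-matrix
#' eigenvalues followed by one Newton polish per root (tolerance 1e-10),
#' and returns them sorted, together with the factored-gradient leading
#' coefficient `gamma = 4a` and the two height differences that govern the
#' search problem: the barrier the community must cross and the gain it
#' stands to make.
#'
#' @param landscape A [quartic_landscape()].
#' @return An object of class `critical_points`: list with `x_old`,
#'   `x_barrier`, `x_new`, `gamma`, `barrier_from_old`
#'   (`V(x_old) - V(x_barrier)`) and `gain` (`V(x_new) - V(x_old)`).
#' @export
critical_points <- function(landscape) {
  stopifnot(inherits(landscape, "quartic_landscape"))
  # monic cubic x^3 + p2 x^2 + p1 x + p0 from V'(x)/(-4a)
  p2 <- -3 * landscape$q3 / 4
  p1 <- -2 * landscape$q2 / 4
  p0 <- -landscape$q1 / 4
  comp <- matrix(0, 3, 3)
  comp[2, 1] <- comp[3, 2] <- 1
  comp[, 3] <- c(-p0, -p1, -p2)
  ev <- eigen(comp, only.values = TRUE)$values
  scale <- max(1, abs(ev))
  real <- abs(Im(ev)) < 1e-8 * scale
  if (sum(real) != 3L)
    stop("landscape is not a double-hill: V' has ",
         sum(real), " real root(s), need 3", call. = FALSE)
  r <- Re(ev[real])
  # Newton polish on the gradient
  for (k in 1:6) {
    g  <- gradient(landscape, r)
    g2 <- with(landscape, a * ((-12 * r + 6 * q3) * r + 2 * q2))
    step <- g / g2
    r <- r - step
    if (all(abs(step) < 1e-12)) break
  }
  r <- sort(r)
  v <- potential_value(landscape, r)
  if (!(v[3] > v[1] && v[1] > v[2]))
    stop("landscape is not a double-hill: expected V(x_new) > V(x_old) > V(x_barrier)",
         call. = FALSE)
  structure(
    list(x_old = r[1], x_barrier = r[2], x_new = r[3],
         gamma = 4 * landscape$a,
         barrier_from_old = v[1] - v[2],
         gain = v[3] - v[1]),
    class = "critical_points")
}

#' @export
print.critical_points <- function(x, ...) {
  cat(sprintf("x_old = %.6f, x_barrier = %.6f, x_new = %.6f\n",
              x$x_old, x$x_barrier, x$x_new))
  cat(sprintf("gamma = %g, barrier_from_old = %.6f, gain = %.6f\n",
              x$gamma, x$barrier_from_old, x$gain))
  invisible(x)
}

#' Rescale the landscape's height differences
#'
#' Multiplies the gradient by `barrier_scale` (a -> a * scale) while
#' preserving `V(0)` (e -> e / scale). Critical-point locations are
#' unchanged; barrier height and paradigm gain scale linearly. Useful for
#' comparative statics: a taller barrier or larger gain lengthens the
#' characteristic shift time.
#'
#' @param landscape A [quartic_landscape()].
#' @param barrier_scale Positive multiplier for all height differences.
#' @return A new `quartic_landscape`.
#' @export
scaled_landscape <- function(landscape, barrier_scale) {
  stopifnot(inherits(landscape, "quartic_landscape"))
  if (!is.numeric(barrier_scale) || length(barrier_scale) != 1L ||
      !is.finite(barrier_scale) || barrier_scale <= 0)
    stop("barrier_scale must be a single positive number", call. = FALSE)
  quartic_landscape(a = landscape$a * barrier_scale,
                    b = landscape$b, c = landscape$c, d = landscape$d,
                    e = landscape$e / barrier_scale)
}

#' Tabulate the landscape's critical structure
#'
#' @param landscape A [quartic_landscape()].
#' @return A data.frame with one row per critical point (position, role,
#'   potential) plus attributes `gamma`, `barrier_from_old`, `gain`.
#' @export
describe_landscape <- function(landscape) {
  cp <- critical_points(landscape)
  xs <- c(cp$x_old, cp$x_barrier, cp$x_new)
  out <- data.frame(
    point = c("x_old", "x_barrier", "x_new"),
    role = c("old paradigm (local optimum)", "valley bottom (barrier)",
             "new paradigm (global optimum)"),
    x = xs,
    V = potential_value(landscape, xs),
    stringsAsFactors = FALSE)
  attr(out, "gamma") <- cp$gamma
  attr(out, "barrier_from_old") <- cp$barrier_from_old
  attr(out, "gain") <- cp$gain
  out
}
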