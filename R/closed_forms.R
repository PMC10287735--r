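#' Periodic orbit of the pulsed recruitment-death scalar system
#'
#' Between pulses a scalar population obeys `u' = Pi - mu*u`; at every pulse
#' time `nT` it is reduced to `(1 - theta1) u`. This impulsive linear system
#' has a unique, globally asymptotically stable `T`-periodic solution. Its
#' post-jump value is
#' `u* = (Pi/mu) (1 - e^{-mu T})(1 - theta1) / (1 - (1 - theta1) e^{-mu T})`
#' and on each inter-pulse interval `(nT, (n+1)T]` the orbit is
#' `u*(t) = (Pi/mu) (1 - theta1 e^{-mu (t - nT)} / (1 - (1 - theta1) e^{-mu T}))`.
#' In the infection-free limit of the epidemic model the susceptible class
#' follows exactly this orbit, so it doubles as the infection-free periodic
#' solution `S*(t)` (with `E = I = A = M = 0`, `N = Pi/mu`).
#'
#' @param Pi recruitment rate (`> 0`).
#' @param mu death rate (`> 0`).
#' @param theta1 pulsed removal fraction in `[0, 1)`; `theta1 = 0` is the
#'   degenerate no-pulse case where the orbit is the constant `Pi/mu`.
#' @param period pulse period `T > 0`.
#' @return `periodic_orbit()` returns a list of class `"pulse_orbit"` with
#'   the post-jump value `u_star`, an `evaluator` function of time, the
#'   per-period contraction factor `(1-theta1) e^{-mu T}` of the
#'   stroboscopic map, and the defining parameters. `s_star()` evaluates the
#'   orbit directly (vectorised in `t`).
#' @examples
#' orb <- periodic_orbit(5.1, 1, 0.1, 1)
#' orb$u_star
#' s_star(c(0.5, 1, 1.5), 5.1, 1, 0.1, 1)
#' @export
periodic_orbit <- function(Pi, mu, theta1, period) {
  if (Pi <= 0 || mu <= 0 || period <= 0) {
    stop("periodic_orbit: Pi, mu and period must be > 0", call. = FALSE)
  }
  if (theta1 < 0 || theta1 >= 1) {
    stop("periodic_orbit: theta1 must lie in [0, 1)", call. = FALSE)
  }
  x <- exp(-mu * period)
  u_star <- Pi / mu * (1 - x) * (1 - theta1) / (1 - (1 - theta1) * x)
  structure(list(
    u_star = u_star,
    evaluator = function(t) s_star(t, Pi, mu, theta1, period),
    contraction = (1 - theta1) * x,
    Pi = Pi, mu = mu, theta1 = theta1, period = period
  ), class = "pulse_orbit")
}

#' @rdname periodic_orbit
#' @param t time(s) at which to evaluate the orbit; the solution is
#'   left-continuous, so `t = nT` yields the pre-jump (end-of-interval)
#'   value. `t` in `[0, T]` is evaluated on the first interval: the orbit is
#'   the asymptotic attractor, not an initial condition.
#' @export
s_star <- function(t, Pi, mu, theta1, period) {
  if (any(t < 0)) stop("s_star: t must be >= 0", call. = FALSE)
  n <- pmax(ceiling(t / period) - 1, 0)
  denom <- 1 - (1 - theta1) * exp(-mu * period)
  Pi / mu * (1 - theta1 * exp(-mu * (t - n * period)) / denom)
}

#' @export
print.pulse_orbit <- function(x, ...) {
  cat("<pulse_orbit>  u* =", format(x$u_star), " period =", x$period,
      " contraction/period =", format(x$contraction), "\n")
  invisible(x)
}

#' One period of the stroboscopic (flow-then-jump) scalar map
#'
#' Maps a post-jump value through one inter-pulse flow of `u' = Pi - mu*u`
#' followed by one pulse `u -> (1 - theta1) u`. Its unique fixed point is
#' `u_star` of [periodic_orbit()]; iterating it is the independent route to
#' that value.
#'
#' @param u current post-jump value(s).
#' @inheritParams periodic_orbit
#' @return The post-jump value(s) one period later.
#' @export
stroboscopic_map <- function(u, Pi, mu, theta1, period) {
  (1 - theta1) * (Pi / mu + (u - Pi / mu) * exp(-mu * period))
}

#' Exact solution of a linear forced-decay equation
#'
#' Solves `x' = source - decay * x` forward by `dt`:
#' `x0 e^{-decay dt} + (source/decay)(1 - e^{-decay dt})`. This elementary
#' closed form is the workhorse of the comparison arguments that bound the
#' infected classes and the reservoir between pulses.
#'
#' @param x0 initial value.
#' @param source constant forcing (any sign).
#' @param decay decay rate (`> 0`).
#' @param dt elapsed time (`>= 0`).
#' @return The solution value at time `dt` (vectorised over `dt`).
#' @examples
#' forced_decay(1, 0.5, 2, 1)
#' @export
forced_decay <- function(x0, source, decay, dt) {
  if (decay <= 0) stop("forced_decay: decay must be > 0", call. = FALSE)
  if (any(dt < 0)) stop("forced_decay: dt must be >= 0", call. = FALSE)
  e <- exp(-decay * dt)
  x0 * e + source / decay * (1 - e)
}

#' Disease-free equilibrium state of the continuous flow
#'
#' `(S, E, I, A, N, M) = (Pi/mu, 0, 0, 0, Pi/mu, 0)` — the fixed point of
#' the flow, and of the jump map in the limit of vanishing pulse fractions.
#'
#' @inheritParams rhs_reduced
#' @param system `"reduced"` or `"full"` bookkeeping (the full-system fifth
#'   component `R` is 0 at the equilibrium).
#' @return A [state_vec()].
#' @export
dfe_state <- function(rates, system = c("reduced", "full")) {
  system <- match.arg(system)
  fifth <- if (system == "reduced") rates$Pi / rates$mu else 0
  state_vec(rates$Pi / rates$mu, 0, 0, 0, fifth, 0, system = system)
}
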