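#' State vectors of the hybrid pest-epidemic system
#'
#' A state is a named numeric vector over six compartments. Two bookkeeping
#' variants exist: the *reduced* system tracks the total pest population
#' `N` as its fifth component (the recovered class is implicit,
#' `R = N - S - E - I - A`), while the *full* system tracks the recovered
#' class `R` explicitly. All theorems and both benchmark scenarios are
#' stated on the reduced system; the full system is provided for the
#' population-conservation cross-check.
#'
#' Tiny negative components in `[-clip_tol, 0)` — the harmless product of
#' adaptive integration near an invariant boundary — are clipped to zero;
#' anything more negative signals a genuine failure and raises an error.
#'
#' @param S,E,I,A susceptible, exposed, symptomatic and asymptomatic pest
#'   densities (nonnegative).
#' @param N total pest population (reduced system) — or `R`, the
#'   recovered/vaccinated class (full system).
#' @param M free-living virus concentration in the environmental reservoir.
#' @param system `"reduced"` (fifth component `N`) or `"full"` (fifth
#'   component `R`).
#' @param clip_tol nonnegative clipping tolerance for tiny negatives.
#' @return A named numeric vector of length 6 with attribute `system`.
#' @examples
#' state_vec(2, 1, 1, 1, 5, 1)
#' @export
state_vec <- function(S, E, I, A, N, M, system = c("reduced", "full"),
                      clip_tol = 1e-10) {
  system <- match.arg(system)
  x <- c(S = S, E = E, I = I, A = A, N = N, M = M)
  if (system == "full") names(x)[5] <- "R"
  validate_state(x, system = system, clip_tol = clip_tol)
}

state_names <- function(system) {
  c("S", "E", "I", "A", if (system == "full") "R" else "N", "M")
}

validate_state <- function(x, system = "reduced", clip_tol = 1e-10) {
  nm <- state_names(system)
  x <- as.numeric(x)
  if (length(x) != 6L) {
    stop("state must have 6 components (", paste(nm, collapse = ", "), ")",
         call. = FALSE)
  }
  names(x) <- nm
  if (any(!is.finite(x))) {
    stop("non-finite state component: ",
         paste(nm[!is.finite(x)], collapse = ", "), call. = FALSE)
  }
  too_neg <- x < -clip_tol
  if (any(too_neg)) {
    stop("state component(s) negative beyond tolerance (",
         format(clip_tol), "): ",
         paste(sprintf("%s = %.6g", nm[too_neg], x[too_neg]), collapse = ", "),
         call. = FALSE)
  }
  x[x < 0] <- 0
  attr(x, "system") <- system
  x
}

# shared S/E/I/A/M right-hand side; `fifth` supplied by the caller
rhs_core <- function(x, p) {
  S <- x[[1]]; E <- x[[2]]; I <- x[[3]]; A <- x[[4]]; M <- x[[6]]
  inf_direct <- p$beta * S * E / (p$K + S)
  inf_env <- p$eta * S * M * E
  c(
    p$Pi - p$mu * S - inf_direct - inf_env,
    inf_direct + inf_env - (p$mu + p$theta * p$rho + (1 - p$theta) * p$varpi) * E,
    (1 - p$theta) * p$varpi * E - (p$tau1 + p$mu + p$d1) * I,
    p$theta * p$rho * E - (p$tau2 + p$mu) * A,
    NA_real_,
    (p$b - p$d) * M + p$lambda1 * I + p$lambda2 * A
  )
}

#' Vector fields of the pest-epidemic flow
#'
#' `rhs_reduced()` is the canonical simulated system: susceptibles are
#' recruited at rate `Pi`, lost to natural death and to two infection
#' routes (saturated direct contact `beta*S*E/(K+S)` and
#' environment-mediated `eta*S*M*E`); exposed pests progress to the
#' symptomatic class at rate `(1-theta)*varpi` and the asymptomatic class at
#' `theta*rho`; both infected classes shed virus into the reservoir, which
#' grows at `b` and is removed at `d` (`b < d`). The fifth equation is the
#' total population `N' = Pi - mu*N - d1*I`.
#'
#' `rhs_full()` replaces the `N` equation with the explicit recovered class
#' `R' = tau1*I + tau2*A - mu*R`; the other five equations are identical.
#'
#' @param state a length-6 state vector (see [state_vec()]); the fifth
#'   component is `N` for `rhs_reduced` and `R` for `rhs_full`.
#' @param rates a [rate_params()] record.
#' @return Named numeric vector of the six time-derivatives.
#' @examples
#' sc <- pest_scenario("extinction")
#' rhs_reduced(state_vec(5.1, 0, 0, 0, 5.1, 0), sc$rates)  # disease-free: all zero
#' @export
rhs_reduced <- function(state, rates) {
  x <- validate_state(state, "reduced")
  dx <- rhs_core(x, rates)
  dx[5] <- rates$Pi - rates$mu * x[[5]] - rates$d1 * x[[3]]
  names(dx) <- state_names("reduced")
  dx
}

#' @rdname rhs_reduced
#' @export
rhs_full <- function(state, rates) {
  x <- validate_state(state, "full")
  dx <- rhs_core(x, rates)
  dx[5] <- rates$tau1 * x[[3]] + rates$tau2 * x[[4]] - rates$mu * x[[5]]
  names(dx) <- state_names("full")
  dx
}

#' Impulsive jump map applied at every pulse instant
#'
#' At each pulse a fraction `theta1` of susceptibles is vaccinated and a
#' fraction `xi` of the reservoir virus is destroyed:
#' `S+ = (1-theta1) S`, `M+ = (1-xi) M`, other compartments unchanged. In
#' the full system the vaccinated mass is transferred, `R+ = R + theta1*S`,
#' with both `S+` and `R+` evaluated from the single pre-jump state so that
#' the total pest population is conserved across the jump.
#'
#' @inheritParams rhs_reduced
#' @param pulses a [pulse_params()] record.
#' @return The post-jump state vector.
#' @examples
#' jump_map(state_vec(10, 1, 1, 1, 5, 2), pulse_params(1, 0.1, 0.02))
#' @export
jump_map <- function(state, pulses) {
  system <- attr(state, "system") %||% "reduced"
  x <- validate_state(state, system)
  out <- x
  out[[1]] <- (1 - pulses$theta1) * x[[1]]
  out[[6]] <- (1 - pulses$xi) * x[[6]]
  if (system == "full") out[[5]] <- x[[5]] + pulses$theta1 * x[[1]]
  attr(out, "system") <- system
  out
}

#' Invariant region of the reduced system
#'
#' The biologically feasible set is the compact region where all
#' compartments are nonnegative, the living classes satisfy
#' `S + E + I + A <= Pi/mu` and `N <= Pi/mu`, and the reservoir satisfies
#' `M <= Pi (lambda1 + lambda2) / (mu (d - b))`. The flow and the jump map
#' both leave this set positively invariant, so trajectories started inside
#' remain inside.
#'
#' @inheritParams rhs_reduced
#' @param tol slack allowed on each inequality.
#' @return `in_omega()` returns `TRUE` iff every inequality holds within
#'   `tol`; `omega_bounds()` returns the two ceilings as a named list
#'   (`pop` for the living classes and `N`, `M` for the reservoir).
#' @examples
#' sc <- pest_scenario("extinction")
#' omega_bounds(sc$rates)
#' in_omega(state_vec(2, 1, 1, 1, 5, 1), sc$rates)
#' @export
in_omega <- function(state, rates, tol = 0) {
  stopifnot(tol >= 0)
  x <- validate_state(state, "reduced")
  bd <- omega_bounds(rates)
  all(x >= -tol) &&
    (x[[1]] + x[[2]] + x[[3]] + x[[4]] <= bd$pop + tol) &&
    (x[[5]] <= bd$pop + tol) &&
    (x[[6]] <= bd$M + tol)
}

#' @rdname in_omega
#' @export
omega_bounds <- function(rates) {
  list(pop = rates$Pi / rates$mu,
       M = rates$Pi * (rates$lambda1 + rates$lambda2) /
         (rates$mu * (rates$d - rates$b)))
}

`%||%` <- function(a, b) if (is.null(a)) b else a
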