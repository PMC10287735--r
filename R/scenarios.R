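#' Built-in benchmark scenarios
#'
#' Two packaged parameter sets, one on each side of the threshold:
#'
#' * `"extinction"` — weak transmission (`beta = 0.1`, `eta = 0.2`) with
#'   fast pest turnover (`mu = 1`); the attractivity threshold is below 1
#'   and the infection dies out while susceptibles settle onto the pulsed
#'   periodic orbit. Default horizon 200 periods.
#' * `"permanence"` — strong transmission (`beta = 5`, `eta = 2`) with slow
#'   turnover (`mu = 0.3`); the permanence threshold exceeds 1 and every
#'   compartment oscillates above a positive floor. Default horizon 500
#'   periods (the slower transients need the longer run).
#'
#' Both use a unit pulse period with `xi = 0.02` disinfection; the
#' vaccinated fractions are 0.1 and 0.13 respectively. The default initial
#' state `(S, E, I, A, N, M) = (2, 1, 1, 1, 5, 1)` is an arbitrary positive
#' point inside the invariant region — the regime classifications are
#' initial-condition independent, and tests probe this with random starts.
#'
#' @param name `"extinction"` or `"permanence"`.
#' @return A list of class `"pest_scenario"`: `name`, `rates`, `pulses`,
#'   `initial`, `t_end`, `expected_regime`.
#' @examples
#' pest_scenario("extinction")$rates$beta
#' @export
pest_scenario <- function(name = c("extinction", "permanence")) {
  name <- match.arg(name)
  if (name == "extinction") {
    rates <- rate_params(Pi = 5.1, mu = 1, beta = 0.1, eta = 0.2, K = 2,
                         theta = 0.5, rho = 1, varpi = 1, tau1 = 1.5,
                         tau2 = 1, d1 = 0.2, lambda1 = 0.1, lambda2 = 0.15,
                         b = 0.3, d = 1)
    pulses <- pulse_params(T = 1, theta1 = 0.1, xi = 0.02)
    t_end <- 200
  } else {
    rates <- rate_params(Pi = 5.1, mu = 0.3, beta = 5, eta = 2, K = 3,
                         theta = 0.5, rho = 1.3, varpi = 2, tau1 = 25,
                         tau2 = 0.2, d1 = 0.2, lambda1 = 0.1, lambda2 = 0.15,
                         b = 0.3, d = 1)
    pulses <- pulse_params(T = 1, theta1 = 0.13, xi = 0.02)
    t_end <- 500
  }
  structure(list(
    name = name, rates = rates, pulses = pulses,
    initial = state_vec(2, 1, 1, 1, 5, 1),
    t_end = t_end, expected_regime = name
  ), class = "pest_scenario")
}

#' @export
print.pest_scenario <- function(x, ...) {
  cat("<pest_scenario>", x$name, " t_end =", x$t_end,
      " expected regime:", x$expected_regime, "\n")
  invisible(x)
}

#' Classify a trajectory as extinction, permanence, or undetermined
#'
#' Operationalizes the two asymptotic regimes on the last `n_last` pulse
#' periods of a trajectory: *extinction* when the per-period maximum of
#' every infection compartment (`E, I, A, M`) stays below `eps_extinct`;
#' *permanence* when the per-period minimum of `S, E, I, A, M` stays above
#' `eps_persist`; *undetermined* otherwise. The default tolerances are
#' separated by orders of magnitude from the dynamic ranges of both
#' benchmark scenarios. Extinction takes precedence, so the two labels are
#' mutually exclusive.
#'
#' @param traj a `"pest_trajectory"`.
#' @param eps_extinct extinction ceiling on the infection compartments.
#' @param eps_persist permanence floor on `S, E, I, A, M`.
#' @param n_last number of trailing complete periods examined.
#' @return A list of class `"regime_classification"`: `regime` (one of
#'   `"extinction"`, `"permanence"`, `"undetermined"`), `evidence` (the
#'   per-period summary tibble), and the tolerances used.
#' @examples
#' sc <- pest_scenario("extinction")
#' traj <- simulate_pest(sc$initial, sc$rates, sc$pulses, t_end = 40,
#'                       rtol = 1e-6, atol = 1e-9)
#' classify_regime(traj)$regime
#' @export
classify_regime <- function(traj, eps_extinct = 1e-4, eps_persist = 1e-6,
                            n_last = 10L) {
  stopifnot(eps_extinct > 0, eps_persist > 0)
  ev <- period_summaries(traj, n_last = n_last)
  infect <- c("E", "I", "A", "M")
  persist <- c("S", "E", "I", "A", "M")
  max_infect <- ev |>
    dplyr::filter(.data$compartment %in% infect) |>
    dplyr::pull(.data$max)
  min_persist <- ev |>
    dplyr::filter(.data$compartment %in% persist) |>
    dplyr::pull(.data$min)
  regime <- if (all(max_infect < eps_extinct)) {
    "extinction"
  } else if (all(min_persist > eps_persist)) {
    "permanence"
  } else {
    "undetermined"
  }
  structure(list(regime = regime, evidence = ev,
                 eps_extinct = eps_extinct, eps_persist = eps_persist,
                 n_last = n_last),
            class = "regime_classification")
}

#' @export
print.regime_classification <- function(x, ...) {
  cat("<regime_classification>", x$regime,
      sprintf(" (last %d periods; eps_extinct = %g, eps_persist = %g)\n",
              x$n_last, x$eps_extinct, x$eps_persist))
  invisible(x)
}

#' @rdname classify_regime
#' @param x a `"regime_classification"`.
#' @param ... unused.
#' @method tidy regime_classification
#' @export
tidy.regime_classification <- function(x, ...) x$evidence

#' @rdname classify_regime
#' @method glance regime_classification
#' @export
glance.regime_classification <- function(x, ...) {
  tibble::tibble(regime = x$regime, n_last = x$n_last,
                 eps_extinct = x$eps_extinct, eps_persist = x$eps_persist)
}

#' Run a scenario end to end
#'
#' Simulates the scenario, evaluates the full [threshold_report()], and
#' classifies the regime. When the scenario declares an expected regime and
#' the classification disagrees, the result is flagged (`consistent =
#' FALSE`) with a warning — never silently.
#'
#' @param scenario a [pest_scenario()] (or a list with the same fields).
#' @param t_end horizon override (defaults to the scenario's).
#' @param out_dir optional directory; when given, writes `trajectory.csv`,
#'   `thresholds.json` and `classification.json` there.
#' @param ... further arguments passed to [simulate_pest()].
#' @return A list of class `"scenario_result"`: `scenario`, `trajectory`,
#'   `thresholds`, `classification`, `consistent`.
#' @examples
#' \donttest{
#' res <- run_scenario(pest_scenario("extinction"))
#' res$classification$regime
#' }
#' @export
run_scenario <- function(scenario, t_end = scenario$t_end, out_dir = NULL, ...) {
  traj <- simulate_pest(scenario$initial, scenario$rates, scenario$pulses,
                        t_end = t_end, ...)
  rep <- threshold_report(scenario$rates, scenario$pulses)
  cls <- classify_regime(traj)
  consistent <- TRUE
  if (!identical(scenario$expected_regime, "unknown") &&
      !is.null(scenario$expected_regime)) {
    consistent <- identical(cls$regime, scenario$expected_regime)
    if (!consistent) {
      warning("scenario '", scenario$name, "' expected regime '",
              scenario$expected_regime, "' but classified as '",
              cls$regime, "'", call. = FALSE)
    }
  }
  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    write_trajectory_csv(traj, file.path(out_dir, "trajectory.csv"))
    report_to_json(rep, file.path(out_dir, "thresholds.json"))
    jsonlite::write_json(
      list(regime = cls$regime, eps_extinct = cls$eps_extinct,
           eps_persist = cls$eps_persist, n_last = cls$n_last,
           evidence = as.data.frame(cls$evidence)),
      file.path(out_dir, "classification.json"),
      auto_unbox = TRUE, digits = NA)
  }
  structure(list(scenario = scenario, trajectory = traj, thresholds = rep,
                 classification = cls, consistent = consistent),
            class = "scenario_result")
}

#' @export
print.scenario_result <- function(x, ...) {
  cat("<scenario_result>", x$scenario$name, "\n")
  print(x$classification)
  cat("consistent with expectation:", x$consistent, "\n")
  invisible(x)
}

#' Sweep one parameter across a grid of values
#'
#' Re-evaluates the attractivity and permanence thresholds (and optionally
#' a short regime-classification run) for each value of one rate or pulse
#' parameter, all else held at the scenario's values.
#'
#' @param scenario a [pest_scenario()].
#' @param param name of a [rate_params()] or [pulse_params()] field.
#' @param values numeric vector of values to sweep.
#' @param simulate also classify the regime at each value with a short run
#'   (default `FALSE`: thresholds only, instant).
#' @param t_end horizon of the classification runs.
#' @param ... passed to [simulate_pest()].
#' @return A tibble with one row per value: `param`, `value`,
#'   `R1_star` (theorem-literal clearance `d_minus_b`, no-factor ceiling),
#'   `R1_lower` (both ceiling variants), and `regime` (`NA` when
#'   `simulate = FALSE`).
#' @examples
#' sweep_parameter(pest_scenario("permanence"), "theta1",
#'                 c(0.05, 0.13, 0.5))
#' @export
sweep_parameter <- function(scenario, param, values, simulate = FALSE,
                            t_end = 60, ...) {
  rate_nm <- names(unclass(scenario$rates))
  pulse_nm <- names(unclass(scenario$pulses))
  if (!(param %in% c(rate_nm, pulse_nm))) {
    stop("sweep_parameter: unknown parameter '", param, "'", call. = FALSE)
  }
  purrr::map_dfr(values, function(v) {
    rates <- scenario$rates
    pulses <- scenario$pulses
    if (param %in% rate_nm) {
      rates[[param]] <- v
      rates <- validate_rate_params(rates)
    } else {
      pulses[[param]] <- v
      pulses <- validate_pulse_params(pulses)
    }
    regime <- NA_character_
    if (simulate) {
      traj <- simulate_pest(scenario$initial, rates, pulses, t_end = t_end, ...)
      regime <- classify_regime(traj)$regime
    }
    tibble::tibble(
      param = param, value = v,
      R1_star = attractivity_threshold(rates, pulses, "without_factor",
                                       "d_minus_b"),
      R1_lower = permanence_threshold(rates, pulses, "without_factor"),
      R1_lower_with = permanence_threshold(rates, pulses, "with_factor"),
      regime = regime
    )
  })
}

#' Draw random initial states inside the invariant region
#'
#' Draws `S, E, I, A` from a Dirichlet-scaled simplex under the population
#' ceiling `Pi/mu`, `N` uniformly in `(0, Pi/mu]` and `M` uniformly in
#' `(0, M_bound]`. Used to probe the initial-condition independence of the
#' regime classifications.
#'
#' @param n number of states.
#' @param rates a [rate_params()] record.
#' @return A list of `n` [state_vec()]s.
#' @export
draw_initial_states <- function(n, rates) {
  bd <- omega_bounds(rates)
  lapply(seq_len(n), function(i) {
    w <- stats::rgamma(5, shape = 1)        # 4 classes + slack coordinate
    frac <- w / sum(w)
    pop <- stats::runif(1, 0.05, 1) * bd$pop
    seia <- frac[1:4] * pop
    state_vec(seia[1], seia[2], seia[3], seia[4],
              N = stats::runif(1, 0.05, 1) * bd$pop,
              M = stats::runif(1, 0.05, 1) * bd$M)
  })
}
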