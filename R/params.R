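#' Continuous-dynamics rate parameters
#'
#' Validated record of the fifteen rates governing the smooth flow of the
#' pest-epidemic model: recruitment and mortality of the pest, the two
#' transmission routes (saturated direct contact and trilinear
#' environment-mediated infection), progression out of the exposed class,
#' recovery, disease-induced death, virus shedding and virus turnover in the
#' environmental reservoir.
#'
#' @param Pi recruitment (birth) rate of the pest (pest / time).
#' @param mu natural per-capita death rate (1 / time).
#' @param beta saturated direct-transmission coefficient (1 / time); the
#'   force of infection on exposure is `beta * S / (K + S)`.
#' @param eta environment-mediated transmission coefficient
#'   (1 / (pest * virus * time)); acts through the trilinear term
#'   `eta * S * M * E`.
#' @param K pathogen half-saturation concentration (pest).
#' @param theta proportion of exposures that become asymptomatic, in
#'   `[0, 1]`. The endpoints are allowed (all-symptomatic / all-asymptomatic
#'   degenerate models).
#' @param rho progression rate of exposed pests into the asymptomatic class
#'   (1 / time).
#' @param varpi progression rate of exposed pests into the symptomatic class
#'   after incubation (1 / time).
#' @param tau1,tau2 recovery rates of the symptomatic (`I`) and asymptomatic
#'   (`A`) classes (1 / time).
#' @param d1 disease-induced death rate of symptomatic pests (1 / time).
#' @param lambda1,lambda2 virus shedding rates of the symptomatic and
#'   asymptomatic classes into the reservoir (1 / time).
#' @param b natural growth rate of the free-living virus (1 / time).
#' @param d removal rate of the free-living virus (1 / time). The model
#'   requires `b < d` so the reservoir decays in the absence of shedding.
#'
#' @return A validated list of class `"rate_params"`.
#' @seealso [pulse_params()], [pest_scenario()]
#' @examples
#' rates <- pest_scenario("extinction")$rates
#' rates$beta
#' @export
rate_params <- function(Pi, mu, beta, eta, K, theta, rho, varpi,
                        tau1, tau2, d1, lambda1, lambda2, b, d) {
  p <- list(Pi = Pi, mu = mu, beta = beta, eta = eta, K = K, theta = theta,
            rho = rho, varpi = varpi, tau1 = tau1, tau2 = tau2, d1 = d1,
            lambda1 = lambda1, lambda2 = lambda2, b = b, d = d)
  validate_rate_params(p)
}

validate_rate_params <- function(p) {
  nm <- c("Pi", "mu", "beta", "eta", "K", "theta", "rho", "varpi",
          "tau1", "tau2", "d1", "lambda1", "lambda2", "b", "d")
  missing <- setdiff(nm, names(p))
  if (length(missing) > 0) {
    stop("rate_params: missing field(s): ", paste(missing, collapse = ", "),
         call. = FALSE)
  }
  p <- p[nm]
  bad <- nm[!vapply(p, function(x) is.numeric(x) && length(x) == 1L && is.finite(x),
                    logical(1))]
  if (length(bad) > 0) {
    stop("rate_params: non-finite or non-scalar field(s): ",
         paste(bad, collapse = ", "), call. = FALSE)
  }
  strict <- setdiff(nm, "theta")
  neg <- strict[vapply(p[strict], function(x) x <= 0, logical(1))]
  if (length(neg) > 0) {
    stop("rate_params: field(s) must be strictly positive: ",
         paste(neg, collapse = ", "), call. = FALSE)
  }
  if (p$theta < 0 || p$theta > 1) {
    stop("rate_params: theta must lie in [0, 1], got ", p$theta, call. = FALSE)
  }
  if (p$b >= p$d) {
    stop("rate_params: virus growth must be dominated by removal (b < d), got b = ",
         p$b, ", d = ", p$d, call. = FALSE)
  }
  structure(p, class = "rate_params")
}

#' Impulsive-control pulse parameters
#'
#' The periodic control acts instantaneously at times `T, 2T, 3T, ...`
#' (no pulse at time zero): a fraction `theta1` of susceptibles is
#' vaccinated into the protected class and a fraction `xi` of the
#' environmental virus is destroyed by disinfection.
#'
#' @param T pulse period (time, `> 0`).
#' @param theta1 vaccinated fraction of susceptibles per pulse, in `(0, 1)`.
#' @param xi destroyed fraction of reservoir virus per pulse, in `(0, 1)`.
#'
#' @return A validated list of class `"pulse_params"`.
#' @examples
#' pulse_params(T = 1, theta1 = 0.1, xi = 0.02)
#' @export
pulse_params <- function(T, theta1, xi) {
  p <- list(T = T, theta1 = theta1, xi = xi)
  validate_pulse_params(p)
}

validate_pulse_params <- function(p) {
  nm <- c("T", "theta1", "xi")
  missing <- setdiff(nm, names(p))
  if (length(missing) > 0) {
    stop("pulse_params: missing field(s): ", paste(missing, collapse = ", "),
         call. = FALSE)
  }
  p <- p[nm]
  bad <- nm[!vapply(p, function(x) is.numeric(x) && length(x) == 1L && is.finite(x),
                    logical(1))]
  if (length(bad) > 0) {
    stop("pulse_params: non-finite or non-scalar field(s): ",
         paste(bad, collapse = ", "), call. = FALSE)
  }
  if (p$T <= 0) stop("pulse_params: T must be > 0", call. = FALSE)
  if (p$theta1 <= 0 || p$theta1 >= 1) {
    stop("pulse_params: theta1 must lie in (0, 1), got ", p$theta1, call. = FALSE)
  }
  if (p$xi <= 0 || p$xi >= 1) {
    stop("pulse_params: xi must lie in (0, 1), got ", p$xi, call. = FALSE)
  }
  structure(p, class = "pulse_params")
}

#' @export
print.rate_params <- function(x, ...) {
  cat("<rate_params>\n")
  print(unlist(unclass(x)))
  invisible(x)
}

#' @export
print.pulse_params <- function(x, ...) {
  cat("<pulse_params>  period T =", x$T, " theta1 =", x$theta1, " xi =", x$xi, "\n")
  invisible(x)
}

#' Read and write model parameters as flat YAML/JSON mappings
#'
#' The on-disk representation is a flat mapping using the romanized rate
#' names (`Pi, mu, beta, eta, K, theta, rho, varpi, tau1, tau2, d1, lambda1,
#' lambda2, b, d`) plus the pulse fields (`T, theta1, xi`); a configuration
#' file may additionally carry `initial` (named mapping of `S,E,I,A,N,M`),
#' `t_end`, and an `integrator` block (`rtol, atol, max_step, dense_dt`).
#'
#' @param file path to a `.yaml`/`.yml` or `.json` file.
#' @return `read_model_config()` returns a list with elements `rates`
#'   (`rate_params`), `pulses` (`pulse_params`), and optionally `initial`,
#'   `t_end`, `integrator`.
#' @export
read_model_config <- function(file) {
  raw <- if (grepl("\\.json$", file, ignore.case = TRUE)) {
    jsonlite::read_json(file, simplifyVector = TRUE)
  } else {
    yaml::read_yaml(file)
  }
  # accept either nested {rates:, pulses:} or one flat mapping
  flat <- raw
  if (!is.null(raw$rates)) flat <- c(raw$rates, raw$pulses)
  rate_nm <- c("Pi", "mu", "beta", "eta", "K", "theta", "rho", "varpi",
               "tau1", "tau2", "d1", "lambda1", "lambda2", "b", "d")
  rates <- validate_rate_params(lapply(flat[rate_nm], as.numeric))
  pulses <- validate_pulse_params(lapply(flat[c("T", "theta1", "xi")], as.numeric))
  out <- list(rates = rates, pulses = pulses)
  if (!is.null(raw$initial)) out$initial <- unlist(raw$initial)
  if (!is.null(raw$t_end)) out$t_end <- as.numeric(raw$t_end)
  if (!is.null(raw$integrator)) out$integrator <- raw$integrator
  out
}

#' @rdname read_model_config
#' @param rates a [rate_params()] record.
#' @param pulses a [pulse_params()] record.
#' @export
write_model_config <- function(rates, pulses, file) {
  rates <- validate_rate_params(rates)
  pulses <- validate_pulse_params(pulses)
  flat <- c(unclass(rates), unclass(pulses))
  if (grepl("\\.json$", file, ignore.case = TRUE)) {
    jsonlite::write_json(flat, file, auto_unbox = TRUE, digits = NA)
  } else {
    yaml::write_yaml(flat, file)
  }
  invisible(file)
}
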