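#' @name threshold-variants
#' @title Formula variants for the closed-form thresholds
#'
#' @description
#' The published closed forms of this model are internally inconsistent in
#' two places, so the package exposes both readings of each as explicit
#' variants rather than silently picking one:
#'
#' * **zeta variant** — the susceptible ceiling `zeta` appears both
#'   *without* a `(1 - theta1)` factor
#'   (`zeta = Pi (e^{mu T} - 1) / (mu (e^{mu T} + theta1 - 1))`, the
#'   supremum of the infection-free periodic orbit) and *with* it
#'   (`zeta * (1 - theta1)`, the post-jump minimum of the same orbit).
#' * **clearance variant** — the environmental-transmission term of the
#'   attractivity threshold divides by the net virus clearance
#'   `mu (d - b)` (`"d_minus_b"`, the form consistent with the reservoir
#'   bound) or by `mu d` (`"d_only"`, the form that reproduces the
#'   published benchmark value 0.6498).
#'
#' [threshold_report()] evaluates every combination so users can see all of
#' them side by side.
NULL

# mean sojourn-rate out of the exposed class
exposed_outflow <- function(rates) {
  (1 - rates$theta) * rates$varpi + rates$theta * rates$rho + rates$mu
}

#' Susceptible ceiling of the infection-free periodic orbit
#'
#' `zeta = Pi (e^{mu T} - 1) / (mu (e^{mu T} + theta1 - 1))` is the
#' supremum (pre-jump value) of the infection-free periodic susceptible
#' orbit; multiplied by `(1 - theta1)` it is the post-jump minimum. Both
#' are strictly increasing in the pulse period and bounded above by
#' `Pi/mu`.
#'
#' @param rates a [rate_params()] record.
#' @param pulses a [pulse_params()] record.
#' @param variant `"without_factor"` (supremum) or `"with_factor"`
#'   (post-jump minimum, i.e. multiplied by `1 - theta1`).
#' @return A positive scalar.
#' @examples
#' sc <- pest_scenario("extinction")
#' susceptible_ceiling(sc$rates, sc$pulses)
#' @export
susceptible_ceiling <- function(rates, pulses,
                                variant = c("without_factor", "with_factor")) {
  variant <- match.arg(variant)
  x <- exp(-rates$mu * pulses$T)  # overflow-safe form of the printed ratio
  z <- rates$Pi / rates$mu * (1 - x) / (1 - (1 - pulses$theta1) * x)
  if (variant == "with_factor") z <- z * (1 - pulses$theta1)
  z
}

#' Global-attractivity threshold of the infection-free periodic solution
#'
#' The infection-free periodic solution is globally attractive when this
#' dimensionless quantity is below 1:
#' `R1* = ((beta/(K + zeta) + eta Pi (lambda1 + lambda2)/clearance) zeta) / alpha`
#' with `alpha = (1 - theta) varpi + theta rho + mu` and `clearance` either
#' `mu (d - b)` or `mu d` (see [threshold-variants]).
#'
#' @inheritParams susceptible_ceiling
#' @param zeta_variant which susceptible ceiling to use.
#' @param clearance `"d_minus_b"` or `"d_only"`.
#' @return A positive scalar; extinction of the infection is expected when
#'   it is `< 1`.
#' @examples
#' sc <- pest_scenario("extinction")
#' attractivity_threshold(sc$rates, sc$pulses, clearance = "d_only")
#' @export
attractivity_threshold <- function(rates, pulses,
                                   zeta_variant = c("without_factor", "with_factor"),
                                   clearance = c("d_minus_b", "d_only")) {
  zeta_variant <- match.arg(zeta_variant)
  clearance <- match.arg(clearance)
  z <- susceptible_ceiling(rates, pulses, zeta_variant)
  den <- if (clearance == "d_only") rates$mu * rates$d
         else rates$mu * (rates$d - rates$b)
  env <- rates$eta * rates$Pi * (rates$lambda1 + rates$lambda2) / den
  (rates$beta / (rates$K + z) + env) * z / exposed_outflow(rates)
}

#' Permanence threshold (direct-transmission reproduction quantity)
#'
#' `R1l = (beta zeta / (K + zeta)) / alpha` — the direct-transmission-only
#' companion of [attractivity_threshold()] (it omits the nonnegative
#' environmental term, so it is never larger). The model is permanent —
#' every compartment eventually stays above a positive floor — when this
#' quantity exceeds 1.
#'
#' @inheritParams attractivity_threshold
#' @return A positive scalar; permanence is expected when it is `> 1`.
#' @examples
#' sc <- pest_scenario("permanence")
#' permanence_threshold(sc$rates, sc$pulses)
#' @export
permanence_threshold <- function(rates, pulses,
                                 zeta_variant = c("without_factor", "with_factor")) {
  zeta_variant <- match.arg(zeta_variant)
  z <- susceptible_ceiling(rates, pulses, zeta_variant)
  rates$beta * z / (rates$K + z) / exposed_outflow(rates)
}

#' Exposed-class lower reference level
#'
#' `Ebar = mu * zeta_w / (alpha (K + zeta_w)) - mu / beta`, with `zeta_w`
#' the with-factor susceptible ceiling. Equivalently
#' `Ebar = (mu/beta) (R1l_with - 1)`: it is positive exactly when the
#' with-factor permanence threshold exceeds 1, and it seeds the permanence
#' floor `q2` of the exposed class. A nonpositive value is reported as-is
#' (the floor is then flagged invalid).
#'
#' @inheritParams susceptible_ceiling
#' @return A scalar (possibly nonpositive).
#' @export
exposed_lower_bound <- function(rates, pulses) {
  zw <- susceptible_ceiling(rates, pulses, "with_factor")
  a <- exposed_outflow(rates)
  rates$mu * zw / (a * (rates$K + zw)) - rates$mu / rates$beta
}

#' Permanence floors for every compartment
#'
#' The five eventual lower bounds of the permanent regime (proof-slack
#' constants set to zero, i.e. floors reported at their supremum):
#' `q1` for `S` (the pulsed recruitment-death floor under the worst-case
#' infection drain `g = beta Pi/(mu K) + eta Pi^2/mu^2 + mu`), `q2 = Ebar
#' e^{-alpha T}` for `E`, `q3` and `q4` for the symptomatic and
#' asymptomatic classes fed by `q1`, and `q5` for the reservoir: the
#' pulsed forced-decay floor
#' `(lambda1 q3 + lambda2 q4)/(d - b) * (1 - e^{-(d-b)T})(1 - xi) /
#' (1 - (1 - xi) e^{-(d-b)T})`.
#'
#' @inheritParams susceptible_ceiling
#' @return A tibble with columns `floor` (`q1`..`q5`), `compartment`,
#'   `value`, and `valid` (`FALSE` where the formula gives a nonpositive
#'   value, e.g. `q2` when `Ebar <= 0`).
#' @examples
#' sc <- pest_scenario("permanence")
#' persistence_floors(sc$rates, sc$pulses)
#' @export
persistence_floors <- function(rates, pulses) {
  p <- rates
  a <- exposed_outflow(p)
  Tp <- pulses$T
  th1 <- pulses$theta1

  g <- p$beta * p$Pi / (p$mu * p$K) + p$eta * p$Pi^2 / p$mu^2 + p$mu
  xg <- exp(-g * Tp)
  q1 <- p$Pi / g * (1 - th1) * (1 - xg) / (1 - (1 - th1) * xg)
  q2 <- exposed_lower_bound(rates, pulses) * exp(-a * Tp)
  q3 <- (1 - p$theta) * p$varpi * q1 / (p$tau1 + p$mu + p$d1)
  q4 <- p$theta * p$rho * q1 / (p$tau2 + p$mu)
  db <- p$d - p$b
  xd <- exp(-db * Tp)
  q5 <- (p$lambda1 * q3 + p$lambda2 * q4) / db *
    (1 - xd) * (1 - pulses$xi) / (1 - (1 - pulses$xi) * xd)

  v <- c(q1 = q1, q2 = q2, q3 = q3, q4 = q4, q5 = q5)
  tibble::tibble(
    floor = names(v),
    compartment = c("S", "E", "I", "A", "M"),
    value = unname(v),
    valid = unname(v) > 0
  )
}

#' Critical pulse period and intermediates for global attractivity
#'
#' When the parameter combination
#' `Pi (beta mu/(Pi + mu K) + eta Pi (lambda1+lambda2)/(mu (d-b))) < mu alpha`
#' holds, the infection-free solution is globally attractive for every
#' pulse period; otherwise it is attractive for periods below
#' `T* = (1/mu) ln(1 + upsilon theta1 mu / (Pi - upsilon mu))`, where
#' `upsilon` is the positive root of the quadratic
#' `A u^2 + (B + K A - B C) u - K B C = 0` with `A = eta Pi
#' (lambda1 + lambda2)`, `B = mu (d - b)`, `C = alpha`.
#'
#' @inheritParams susceptible_ceiling
#' @return A list: `T_star`, `upsilon`, the intermediates `A`, `B`, `C`,
#'   and `unconditional` (`TRUE` when attractivity holds for every period).
#' @export
critical_period_attract <- function(rates, pulses) {
  p <- rates
  A <- p$eta * p$Pi * (p$lambda1 + p$lambda2)
  B <- p$mu * (p$d - p$b)
  C <- exposed_outflow(p)
  bq <- B + p$K * A - B * C
  upsilon <- (-bq + sqrt(bq^2 + 4 * p$K * A * B * C)) / (2 * A)
  lhs <- p$Pi * (p$beta * p$mu / (p$Pi + p$mu * p$K) + A / B)
  uncond <- lhs < p$mu * C
  if (p$Pi - upsilon * p$mu <= 0) {
    stop("critical_period_attract: domain condition Pi - upsilon*mu > 0 fails ",
         "(Pi = ", p$Pi, ", upsilon*mu = ", format(upsilon * p$mu), ")",
         call. = FALSE)
  }
  arg <- 1 + upsilon * pulses$theta1 * p$mu / (p$Pi - upsilon * p$mu)
  if (arg <= 0) {
    stop("critical_period_attract: log argument must be positive", call. = FALSE)
  }
  list(T_star = log(arg) / p$mu, upsilon = upsilon,
       A = A, B = B, C = C, unconditional = uncond)
}

#' Critical vaccination fraction
#'
#' In `"attractivity"` mode: vaccinating more than
#' `theta1* = (Pi - mu upsilon)(e^{mu T} - 1) / (mu upsilon)` per pulse
#' guarantees global attractivity of the infection-free solution
#' (`upsilon` from [critical_period_attract()]). In `"permanence"` mode:
#' vaccinating less than
#' `theta1* = (Pi beta - (Pi + K mu) alpha)(e^{mu T} - 1) /
#' (K mu alpha + Pi (beta - alpha)(e^{mu T} - 1))` keeps the epidemic
#' permanent; this value is the exact root of
#' `permanence_threshold(with_factor) = 1` in `theta1`, and requires the
#' applicability condition `Pi beta > (Pi + K mu) alpha`.
#'
#' @inheritParams susceptible_ceiling
#' @param mode `"attractivity"` or `"permanence"`.
#' @return A scalar critical fraction.
#' @export
critical_vacc_fraction <- function(rates, pulses,
                                   mode = c("attractivity", "permanence")) {
  mode <- match.arg(mode)
  p <- rates
  em1 <- expm1(p$mu * pulses$T)
  if (mode == "attractivity") {
    ups <- critical_period_attract(rates, pulses)$upsilon
    return((p$Pi - p$mu * ups) * em1 / (p$mu * ups))
  }
  a <- exposed_outflow(p)
  if (p$Pi * p$beta <= (p$Pi + p$K * p$mu) * a) {
    stop("critical_vacc_fraction: applicability condition ",
         "Pi*beta > (Pi + K*mu)*alpha fails", call. = FALSE)
  }
  num <- (p$Pi * p$beta - (p$Pi + p$K * p$mu) * a) * em1
  den <- p$K * p$mu * a + p$Pi * (p$beta - a) * em1
  num / den
}

#' Critical pulse period for permanence
#'
#' Pulsing less often than
#' `Tbar = (1/mu) ln((1 - theta1)(K alpha mu - (beta - alpha) Pi) /
#' (K alpha mu - Pi (beta - alpha)(1 - theta1)))` keeps the epidemic
#' permanent; `Tbar` is the exact root of
#' `permanence_threshold(with_factor) = 1` in the pulse period.
#'
#' @inheritParams susceptible_ceiling
#' @return A scalar period.
#' @export
critical_period_perm <- function(rates, pulses) {
  p <- rates
  a <- exposed_outflow(p)
  num <- (1 - pulses$theta1) * (p$K * a * p$mu - (p$beta - a) * p$Pi)
  den <- p$K * a * p$mu - p$Pi * (p$beta - a) * (1 - pulses$theta1)
  if (!is.finite(num / den) || num / den <= 0) {
    stop("critical_period_perm: log argument must be positive ",
         "(got ", format(num / den), ")", call. = FALSE)
  }
  log(num / den) / p$mu
}

#' Evaluate every closed-form threshold at one parameter set
#'
#' Aggregates all variants of the susceptible ceiling, the attractivity and
#' permanence thresholds, the exposed lower reference level, the five
#' permanence floors, the critical pulse periods and vaccination fractions,
#' and the quadratic intermediates, into one tidy table. Quantities whose
#' domain conditions fail are reported as `NA` with the reason in `note`
#' rather than erroring.
#'
#' @inheritParams susceptible_ceiling
#' @return A tibble of class `"threshold_report"` with columns `quantity`,
#'   `variant`, `value`, `note`.
#' @examples
#' sc <- pest_scenario("extinction")
#' threshold_report(sc$rates, sc$pulses)
#' @export
threshold_report <- function(rates, pulses) {
  rates <- validate_rate_params(rates)
  pulses <- validate_pulse_params(pulses)
  rows <- list()
  add <- function(quantity, variant, value, note = "") {
    rows[[length(rows) + 1L]] <<- tibble::tibble(
      quantity = quantity, variant = variant,
      value = value, note = note)
  }
  try_add <- function(quantity, variant, expr, note = "") {
    val <- tryCatch(expr, error = function(e) {
      note <<- conditionMessage(e)
      NA_real_
    })
    add(quantity, variant, val, note)
  }

  for (zv in c("without_factor", "with_factor")) {
    add("zeta", zv, susceptible_ceiling(rates, pulses, zv))
  }
  for (zv in c("without_factor", "with_factor")) {
    for (cv in c("d_minus_b", "d_only")) {
      add("R1_star", paste(zv, cv, sep = "/"),
          attractivity_threshold(rates, pulses, zv, cv))
    }
  }
  for (zv in c("without_factor", "with_factor")) {
    add("R1_lower", zv, permanence_threshold(rates, pulses, zv))
  }
  add("alpha", "", exposed_outflow(rates))
  eb <- exposed_lower_bound(rates, pulses)
  add("E_bar", "", eb, if (eb <= 0) "nonpositive: q2 floor invalid" else "")
  fl <- persistence_floors(rates, pulses)
  for (i in seq_len(nrow(fl))) {
    add(fl$floor[i], "", fl$value[i],
        if (!fl$valid[i]) "nonpositive: floor invalid" else "")
  }
  cp <- tryCatch(critical_period_attract(rates, pulses), error = function(e) e)
  if (inherits(cp, "error")) {
    for (q in c("T_star", "upsilon", "A", "B", "C")) {
      add(q, "", NA_real_, conditionMessage(cp))
    }
  } else {
    add("T_star", "", cp$T_star,
        if (cp$unconditional) "attractivity holds for every period" else "")
    add("upsilon", "", cp$upsilon)
    add("A", "", cp$A); add("B", "", cp$B); add("C", "", cp$C)
  }
  try_add("theta1_star_attract", "",
          critical_vacc_fraction(rates, pulses, "attractivity"))
  try_add("theta1_star_perm", "",
          critical_vacc_fraction(rates, pulses, "permanence"))
  try_add("T_bar", "", critical_period_perm(rates, pulses))

  out <- dplyr::bind_rows(rows)
  class(out) <- c("threshold_report", class(out))
  out
}

#' Write a threshold report to JSON
#'
#' @param report a [threshold_report()] tibble.
#' @param file output path (omit to return the JSON string).
#' @return The file path, or the JSON string when `file` is missing.
#' @export
report_to_json <- function(report, file = NULL) {
  js <- jsonlite::toJSON(as.data.frame(report), dataframe = "rows",
                         auto_unbox = TRUE, digits = NA, na = "null")
  if (is.null(file)) return(js)
  writeLines(js, file)
  invisible(file)
}

#' Read a threshold report back from JSON
#'
#' @param file path written by [report_to_json()], or a JSON string.
#' @return A `"threshold_report"` tibble.
#' @export
report_from_json <- function(file) {
  d <- jsonlite::fromJSON(file)
  d$note[is.na(d$note)] <- ""
  out <- tibble::as_tibble(d)
  out$value <- as.numeric(out$value)
  class(out) <- c("threshold_report", class(out))
  out
}
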