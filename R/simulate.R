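#' Simulate the hybrid (flow plus pulse) pest-epidemic system
#'
#' Integrates the reduced six-compartment system: smooth flow on each
#' inter-pulse interval, with the vaccination/disinfection [jump_map()]
#' applied at every pulse time `T, 2T, ...` (no pulse at time zero unless
#' `pulse_at_zero = TRUE`). The integrator never steps across a pulse —
#' each interval `[nT, (n+1)T]` is integrated separately and restarted from
#' the post-jump state, so no event detection is involved. Solutions are
#' left-continuous: the stored state *at* `t = nT` is the pre-jump value,
#' and the post-jump value opens the next interval (both rows are kept,
#' tagged by `phase`).
#'
#' @param initial length-6 nonnegative initial state (`S, E, I, A, N, M`);
#'   see [state_vec()]. An initial state outside the invariant region only
#'   warns — the region is attracting, not assumed.
#' @param rates a [rate_params()] record.
#' @param pulses a [pulse_params()] record.
#' @param t_end integration horizon (`> 0`).
#' @param rtol,atol relative/absolute tolerances of the adaptive integrator.
#'   The tight defaults make the benchmark-scenario classifications
#'   insensitive to further tightening.
#' @param max_step cap on the internal step; defaults to a tenth of the
#'   pulse period.
#' @param dense_dt output sampling interval within each inter-pulse
#'   interval.
#' @param pulse_at_zero apply a pulse at `t = 0` before integrating
#'   (default `FALSE`: the pulse schedule starts at `t = T`).
#' @param clip_tol components in `[-clip_tol, 0)` are clipped to zero;
#'   anything more negative aborts with an error naming the last valid time.
#' @param method integration method passed to [deSolve::ode()].
#' @return An object of class `"pest_trajectory"`: a list with `data`
#'   (tibble `t, S, E, I, A, N, M, phase` where `phase` is one of `flow`,
#'   `pre_jump`, `post_jump`), `pulse_times`, `pre_jump`/`post_jump`
#'   (one row per pulse), the parameter records and the integrator
#'   configuration. Has [tidy()], [glance()] and
#'   [ggplot2::autoplot()] methods.
#' @seealso [simulate_rk4()] for the fixed-step verification oracle,
#'   [period_summaries()], [classify_regime()].
#' @examples
#' sc <- pest_scenario("extinction")
#' traj <- simulate_pest(sc$initial, sc$rates, sc$pulses, t_end = 20)
#' glance(traj)
#' @export
simulate_pest <- function(initial, rates, pulses, t_end,
                          rtol = 1e-9, atol = 1e-12,
                          max_step = pulses$T / 10,
                          dense_dt = pulses$T / 20,
                          pulse_at_zero = FALSE,
                          clip_tol = 1e-10,
                          method = "lsoda") {
  rates <- validate_rate_params(rates)
  pulses <- validate_pulse_params(pulses)
  stopifnot(t_end > 0, rtol > 0, atol > 0, dense_dt > 0)
  y <- validate_state(initial, "reduced", clip_tol)
  if (!in_omega(y, rates, tol = 1e-9)) {
    warning("initial state lies outside the invariant region; ",
            "the region is attracting, continuing anyway", call. = FALSE)
  }

  f <- make_rhs(rates)
  ode_fn <- function(t, y, parms) list(f(y))
  Tp <- pulses$T
  if (pulse_at_zero) y <- jump_map(y, pulses)
  pulse_times <- seq_len(floor(t_end / Tp + 1e-9)) * Tp
  bounds <- unique(c(0, pulse_times,
                     if (t_end > max(c(0, pulse_times)) + 1e-9 * Tp) t_end))

  rows <- vector("list", length(bounds))  # per-interval data chunks
  pre <- post <- vector("list", length(pulse_times))
  for (k in seq_len(length(bounds) - 1L)) {
    a <- bounds[k]; b <- bounds[k + 1L]
    times <- unique(c(seq(a, b, by = dense_dt), b))
    sol <- deSolve::ode(y = unclass(y), times = times, func = ode_fn,
                        parms = NULL, method = method,
                        rtol = rtol, atol = atol, hmax = max_step)
    m <- unname(sol[, -1, drop = FALSE])
    if (any(!is.finite(m))) {
      bad_row <- which(rowSums(!is.finite(m)) > 0)[1]
      last_ok <- if (bad_row > 1) sol[bad_row - 1, 1] else a
      stop("integration failed (non-finite state); last valid time t = ",
           format(last_ok), call. = FALSE)
    }
    if (any(m < -clip_tol)) {
      bad <- which(m < -clip_tol, arr.ind = TRUE)[1, ]
      stop("integration failed: ", state_names("reduced")[bad[2]],
           " = ", format(m[bad[1], bad[2]]), " at t = ",
           format(sol[bad[1], 1]), " (below -clip_tol)", call. = FALSE)
    }
    m[m < 0] <- 0
    phase <- rep("flow", nrow(m))
    is_pulse <- k <= length(pulse_times)
    if (is_pulse) phase[length(phase)] <- "pre_jump"
    chunk <- cbind(t = sol[, 1], m)
    if (k > 1L) chunk <- chunk[-1L, , drop = FALSE]  # opener duplicates post-jump row
    if (k > 1L) phase <- phase[-1L]
    y_end <- validate_state(m[nrow(m), ], "reduced", clip_tol)
    if (is_pulse) {
      pre[[k]] <- c(t = b, unclass(y_end))
      y <- jump_map(y_end, pulses)
      post[[k]] <- c(t = b, unclass(y))
      chunk <- rbind(chunk, c(b, unclass(y)))
      phase <- c(phase, "post_jump")
    } else {
      y <- y_end
    }
    rows[[k]] <- tibble::as_tibble(as.data.frame(chunk)) |>
      stats::setNames(c("t", state_names("reduced"))) |>
      dplyr::mutate(phase = phase)
  }

  data <- dplyr::bind_rows(rows)
  structure(list(
    data = data,
    pulse_times = pulse_times,
    pre_jump = jump_tbl(pre),
    post_jump = jump_tbl(post),
    rates = rates, pulses = pulses,
    method = method,
    cfg = list(rtol = rtol, atol = atol, max_step = max_step,
               dense_dt = dense_dt, t_end = t_end, clip_tol = clip_tol,
               pulse_at_zero = pulse_at_zero)
  ), class = "pest_trajectory")
}

# pre/post-jump record list -> one-row-per-pulse tibble
jump_tbl <- function(lst) {
  lst <- lst[!vapply(lst, is.null, logical(1))]
  if (length(lst) == 0) {
    return(tibble::as_tibble(stats::setNames(
      as.list(as.data.frame(matrix(numeric(0), ncol = 7))),
      c("t", state_names("reduced")))))
  }
  tibble::as_tibble(as.data.frame(do.call(rbind, lst)))
}

# fast closure over the reduced vector field (no per-call validation)
make_rhs <- function(p) {
  alpha <- p$mu + p$theta * p$rho + (1 - p$theta) * p$varpi
  prog_I <- (1 - p$theta) * p$varpi
  prog_A <- p$theta * p$rho
  out_I <- p$tau1 + p$mu + p$d1
  out_A <- p$tau2 + p$mu
  function(y) {
    S <- y[1]; E <- y[2]; I <- y[3]; A <- y[4]; N <- y[5]; M <- y[6]
    inf <- p$beta * S * E / (p$K + S) + p$eta * S * M * E
    c(p$Pi - p$mu * S - inf,
      inf - alpha * E,
      prog_I * E - out_I * I,
      prog_A * E - out_A * A,
      p$Pi - p$mu * N - p$d1 * I,
      (p$b - p$d) * M + p$lambda1 * I + p$lambda2 * A)
  }
}

#' Fixed-step RK4 verification oracle for the hybrid system
#'
#' Classical fourth-order Runge-Kutta with a constant step between pulses
#' and the exact [jump_map()] applied at every multiple of the pulse period
#' — no adaptivity anywhere. It is deliberately independent of
#' [simulate_pest()] so that the two integrators can be compared against
#' each other.
#'
#' @inheritParams simulate_pest
#' @param h fixed step; must divide the pulse period exactly
#'   (`h = T/m` for integer `m`), and `t_end` must be a multiple of `h`.
#' @param record_every store every `record_every`-th step (interval
#'   endpoints are always stored).
#' @return A `"pest_trajectory"` (with `method = "rk4"`).
#' @export
simulate_rk4 <- function(initial, rates, pulses, h, t_end,
                         record_every = 1L, pulse_at_zero = FALSE,
                         clip_tol = 1e-10) {
  rates <- validate_rate_params(rates)
  pulses <- validate_pulse_params(pulses)
  stopifnot(h > 0, t_end > 0)
  Tp <- pulses$T
  m_per <- Tp / h
  if (abs(m_per - round(m_per)) > 1e-8 * m_per) {
    stop("simulate_rk4: h must divide the pulse period exactly (h = T/m)",
         call. = FALSE)
  }
  y <- unclass(validate_state(initial, "reduced", clip_tol))
  f <- make_rhs(rates)
  if (pulse_at_zero) y <- unclass(jump_map(validate_state(y), pulses))
  pulse_times <- seq_len(floor(t_end / Tp + 1e-9)) * Tp
  bounds <- unique(c(0, pulse_times,
                     if (t_end > max(c(0, pulse_times)) + 1e-9 * Tp) t_end))

  rows <- list(); phases <- list(); pre <- post <- vector("list", length(pulse_times))
  rows[[1]] <- c(0, y); phases[[1]] <- "flow"
  ri <- 1L
  for (k in seq_len(length(bounds) - 1L)) {
    a <- bounds[k]; b <- bounds[k + 1L]
    nstep <- (b - a) / h
    if (abs(nstep - round(nstep)) > 1e-8) {
      stop("simulate_rk4: t_end must be a multiple of h", call. = FALSE)
    }
    nstep <- round(nstep)
    for (s in seq_len(nstep)) {
      k1 <- f(y)
      k2 <- f(y + h / 2 * k1)
      k3 <- f(y + h / 2 * k2)
      k4 <- f(y + h * k3)
      y <- y + h / 6 * (k1 + 2 * k2 + 2 * k3 + k4)
      if (s %% record_every == 0L || s == nstep) {
        ri <- ri + 1L
        rows[[ri]] <- c(a + s * h, y)
        phases[[ri]] <- "flow"
      }
    }
    if (any(!is.finite(y))) {
      stop("simulate_rk4: non-finite state near t = ", format(b), call. = FALSE)
    }
    y <- unclass(validate_state(y, "reduced", clip_tol))
    if (k <= length(pulse_times)) {
      phases[[ri]] <- "pre_jump"
      pre[[k]] <- c(t = b, y)
      y <- unclass(jump_map(validate_state(y), pulses))
      post[[k]] <- c(t = b, y)
      ri <- ri + 1L
      rows[[ri]] <- c(b, y)
      phases[[ri]] <- "post_jump"
    }
  }

  mat <- do.call(rbind, rows)
  data <- tibble::as_tibble(as.data.frame(mat)) |>
    stats::setNames(c("t", state_names("reduced"))) |>
    dplyr::mutate(phase = unlist(phases))
  structure(list(
    data = data, pulse_times = pulse_times,
    pre_jump = jump_tbl(pre), post_jump = jump_tbl(post),
    rates = rates, pulses = pulses, method = "rk4",
    cfg = list(h = h, t_end = t_end, record_every = record_every,
               clip_tol = clip_tol, pulse_at_zero = pulse_at_zero)
  ), class = "pest_trajectory")
}

#' Per-period summaries of a hybrid trajectory
#'
#' Splits the dense output into pulse periods `((k-1)T, kT]` (each period
#' opens with the post-jump state of the previous pulse) and reports the
#' minimum, maximum and mean of every compartment within each of the last
#' `n_last` complete periods. These summaries drive the
#' extinction/permanence classification and the permanence-floor checks.
#'
#' @param traj a `"pest_trajectory"`.
#' @param n_last number of trailing complete periods to summarise.
#' @return A tibble with columns `period`, `t_start`, `t_end`,
#'   `compartment`, `min`, `max`, `mean`.
#' @export
period_summaries <- function(traj, n_last = 10L) {
  stopifnot(inherits(traj, "pest_trajectory"), n_last >= 1)
  Tp <- traj$pulses$T
  t_end <- max(traj$data$t)
  n_per <- floor(t_end / Tp + 1e-9)
  if (t_end + 1e-9 * Tp < (n_last + 1) * Tp) {
    stop("period_summaries: horizon too short (need t_end >= (n_last + 1) * T)",
         call. = FALSE)
  }
  d <- traj$data
  per <- ifelse(d$phase == "post_jump",
                round(d$t / Tp) + 1L,
                pmax(ceiling(d$t / Tp - 1e-9), 1L))
  d$period <- as.integer(per)
  keep <- seq.int(n_per - n_last + 1L, n_per)
  d |>
    dplyr::filter(.data$period %in% keep) |>
    tidyr::pivot_longer(dplyr::all_of(state_names("reduced")),
                        names_to = "compartment", values_to = "value") |>
    dplyr::group_by(.data$period, .data$compartment) |>
    dplyr::summarise(min = min(.data$value), max = max(.data$value),
                     mean = mean(.data$value), .groups = "drop") |>
    dplyr::mutate(t_start = (.data$period - 1) * Tp,
                  t_end = .data$period * Tp,
                  compartment = factor(.data$compartment,
                                       levels = state_names("reduced"))) |>
    dplyr::select("period", "t_start", "t_end", "compartment",
                  "min", "max", "mean") |>
    dplyr::arrange(.data$period, .data$compartment)
}

#' Write a trajectory to CSV
#'
#' Schema `t,S,E,I,A,N,M,phase`; pulse instants appear twice (a `pre_jump`
#' and a `post_jump` row at the same `t`).
#'
#' @param traj a `"pest_trajectory"`.
#' @param file output path.
#' @export
write_trajectory_csv <- function(traj, file) {
  stopifnot(inherits(traj, "pest_trajectory"))
  utils::write.csv(traj$data, file, row.names = FALSE, quote = FALSE)
  invisible(file)
}

#' @export
print.pest_trajectory <- function(x, ...) {
  cat("<pest_trajectory>  method =", x$method,
      " t_end =", format(max(x$data$t)),
      " pulses =", length(x$pulse_times),
      " rows =", nrow(x$data), "\n")
  final <- x$data[nrow(x$data), ]
  cat("final state:\n")
  print(as.data.frame(final[, c("t", state_names("reduced"))]), row.names = FALSE)
  invisible(x)
}

#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' Tidy a hybrid trajectory into long format
#'
#' @param x a `"pest_trajectory"`.
#' @param ... unused.
#' @return Tibble with columns `t`, `compartment`, `value`, `phase`.
#' @method tidy pest_trajectory
#' @export
tidy.pest_trajectory <- function(x, ...) {
  x$data |>
    tidyr::pivot_longer(dplyr::all_of(state_names("reduced")),
                        names_to = "compartment", values_to = "value") |>
    dplyr::mutate(compartment = factor(.data$compartment,
                                       levels = state_names("reduced"))) |>
    dplyr::select("t", "compartment", "value", "phase")
}

#' One-row summary of a hybrid trajectory
#'
#' @param x a `"pest_trajectory"`.
#' @param ... unused.
#' @return One-row tibble: horizon, pulse count, method, and the final
#'   state.
#' @method glance pest_trajectory
#' @export
glance.pest_trajectory <- function(x, ...) {
  fin <- x$data[nrow(x$data), ]
  tibble::tibble(
    t_end = max(x$data$t), n_pulses = length(x$pulse_times),
    n_rows = nrow(x$data), method = x$method,
    S_end = fin$S, E_end = fin$E, I_end = fin$I,
    A_end = fin$A, N_end = fin$N, M_end = fin$M
  )
}

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Plot a hybrid trajectory
#'
#' One facet per compartment (free y-scales), pulse discontinuities drawn
#' faithfully from the pre/post-jump rows.
#'
#' @param object a `"pest_trajectory"`.
#' @param compartments subset of `c("S","E","I","A","N","M")` to draw.
#' @param ... unused.
#' @return A ggplot object.
#' @method autoplot pest_trajectory
#' @export
autoplot.pest_trajectory <- function(object,
                                     compartments = state_names("reduced"),
                                     ...) {
  d <- tidy(object) |> dplyr::filter(.data$compartment %in% compartments)
  ggplot2::ggplot(d, ggplot2::aes(x = .data$t, y = .data$value)) +
    ggplot2::geom_line(linewidth = 0.3) +
    ggplot2::facet_wrap(~compartment, scales = "free_y") +
    ggplot2::labs(x = "time", y = "density",
                  title = "Hybrid pest-epidemic trajectory",
                  subtitle = sprintf("pulse period T = %g, theta1 = %g, xi = %g",
                                     object$pulses$T, object$pulses$theta1,
                                     object$pulses$xi)) +
    ggplot2::theme_minimal()
}
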